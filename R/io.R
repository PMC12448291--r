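# Readers and writers for the normalized plain-text formats the pipeline
# consumes: long-format CSV (one observation per row, comma separator,
# scientific notation accepted) and tab-separated gene tables. Writers go
# through a temp-file-plus-rename so a failed run never leaves a partial
# output behind.

read_checked <- function(path, reader, required, what) {
  if (!file.exists(path)) {
    abort(paste0(what, " file not found: ", path), class = "vitacross_io_error")
  }
  tbl <- reader(path)
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    abort(paste0(what, " file ", path, " is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "vitacross_io_error")
  }
  tbl
}

#' Read a vitamin stock table
#'
#' CSV with header `vitamin_id,name,stock_molarity` (molar).
#'
#' @param path Path to the CSV file.
#' @returns A validated tibble.
#' @export
read_stock_table <- function(path) {
  tbl <- read_checked(
    path, function(p) readr::read_csv(p, show_col_types = FALSE),
    c("vitamin_id", "stock_molarity"), "Stock table"
  )
  validate_stocks(tbl)
}

#' Read a screen plate table
#'
#' Long-format CSV `isolate_id,condition,transfer,replicate,od` with
#' condition tokens `plus_vitamins` / `minus_vitamins`.
#'
#' @param path Path to the CSV file.
#' @returns A validated tibble.
#' @export
read_plate_table <- function(path) {
  tbl <- read_checked(
    path, function(p) readr::read_csv(p, show_col_types = FALSE),
    c("isolate_id", "condition", "transfer", "replicate", "od"), "Plate"
  )
  validate_plate(tbl)
}

#' Read a growth-curve table
#'
#' Long-format CSV `isolate_id,vitamin_id,concentration_molar,time_h,od`
#' (a `replicate` column is kept when present).
#'
#' @param path Path to the CSV file.
#' @returns A tibble.
#' @export
read_growth_curves <- function(path) {
  read_checked(
    path, function(p) readr::read_csv(p, show_col_types = FALSE),
    c("concentration_molar", "time_h", "od"), "Growth-curve"
  )
}

#' Read a gene presence table
#'
#' Tab-separated file with two fields per line: a genome id and a
#' comma-separated gene list (`genome_id<TAB>gene1,gene2,...`).
#'
#' @param path Path to the TSV file.
#' @returns A tibble with `genome_id` and a `genes` list column.
#' @export
read_gene_presence <- function(path) {
  tbl <- read_checked(
    path,
    function(p) readr::read_tsv(p, col_names = c("genome_id", "genes"),
                                col_types = "cc"),
    c("genome_id", "genes"), "Gene presence"
  )
  if (anyDuplicated(tbl$genome_id)) {
    abort("Duplicate genome_id in gene presence table.",
          class = "vitacross_io_error")
  }
  as_genome_table(tbl)
}

write_atomic <- function(tbl, path, writer) {
  tmp <- tempfile(tmpdir = dirname(path))
  on.exit(unlink(tmp), add = TRUE)
  writer(tbl, tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Write screen classification results
#'
#' Tab-separated output, one row per isolate, written atomically.
#'
#' @param results Tibble from [classify_screen()].
#' @param path Output path.
#' @returns The path, invisibly.
#' @export
write_screen_results <- function(results, path) {
  write_atomic(results, path, function(tbl, p) {
    readr::write_tsv(tbl, p)
  })
}

#' Write a phase-diagram grid
#'
#' Long-format CSV `ks_molar,quota,normalized_growth`, written atomically.
#'
#' @param diagram A [compute_phase_diagram()] object.
#' @param path Output path.
#' @returns The path, invisibly.
#' @export
write_phase_grid <- function(diagram, path) {
  if (!inherits(diagram, "phase_diagram")) {
    abort("`diagram` must be a phase_diagram object.", class = "vitacross_bad_input")
  }
  write_atomic(diagram$grid, path, function(tbl, p) {
    readr::write_csv(tbl, p)
  })
}
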