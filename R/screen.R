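#' Residual vitamin concentration after serial growth-dilution transfers
#'
#' Computes the concentration of a vitamin carried over from a supplemented
#' seed culture after `n_transfers` serial dilutions, ignoring consumption
#' and production: each 1:`dilution_factor` transfer divides the
#' concentration by `dilution_factor`, so three 1:40 transfers dilute
#' 1:64,000. This is the arithmetic that takes the stock concentrations of a
#' supplemented marine minimal medium down to the picomolar range at which a
#' growth deficit reveals auxotrophy.
#'
#' @param stocks A data frame with columns `vitamin_id` and `stock_molarity`
#'   (molar concentration in the supplemented medium); typically
#'   [vitamin_stocks()].
#' @param dilution_factor Dimensionless per-transfer dilution factor
#'   (default 40).
#' @param n_transfers Number of serial transfers (default 3).
#' @returns The input tibble with columns `residual_molarity` (molar) and
#'   `residual_pM` (picomolar) appended.
#' @examples
#' residual_concentration(vitamin_stocks())
#' @export
residual_concentration <- function(stocks, dilution_factor = 40, n_transfers = 3) {
  stocks <- validate_stocks(stocks)
  if (!is.numeric(dilution_factor) || length(dilution_factor) != 1 ||
      is.na(dilution_factor) || dilution_factor <= 0) {
    abort("`dilution_factor` must be a single positive number.",
          class = "vitacross_invalid_scheme")
  }
  if (dilution_factor < 1) {
    abort("`dilution_factor` must be >= 1 (a per-transfer dilution).",
          class = "vitacross_invalid_scheme")
  }
  if (n_transfers < 0 || n_transfers != round(n_transfers)) {
    abort("`n_transfers` must be a non-negative integer.",
          class = "vitacross_invalid_scheme")
  }
  stocks |>
    dplyr::mutate(
      residual_molarity = .data$stock_molarity / dilution_factor^n_transfers,
      residual_pM = .data$residual_molarity * 1e12
    )
}

validate_stocks <- function(stocks) {
  stocks <- tibble::as_tibble(stocks)
  required <- c("vitamin_id", "stock_molarity")
  missing <- setdiff(required, names(stocks))
  if (length(missing) > 0) {
    abort(paste0("Stock table is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "vitacross_bad_input")
  }
  if (anyDuplicated(stocks$vitamin_id)) {
    abort("`vitamin_id` must be unique within a stock table.",
          class = "vitacross_bad_input")
  }
  if (any(!is.finite(stocks$stock_molarity)) || any(stocks$stock_molarity <= 0)) {
    abort("`stock_molarity` must be positive and finite.",
          class = "vitacross_bad_input")
  }
  stocks
}

#' Vitamin stock table of the supplemented marine minimal medium
#'
#' The thirteen vitamin and vitamer stocks of the standard MBL+V medium
#' (molar concentrations in the supplemented medium), shipped as a
#' plain-text fixture. Three 1:40 growth-dilution transfers take these
#' stocks to roughly 13 pM (niacin) down to 0.1 pM (cobalamin).
#'
#' @returns A tibble with columns `vitamin_id`, `name`, `stock_molarity`.
#' @export
vitamin_stocks <- function() {
  path <- system.file("extdata", "mbl_vitamin_stocks.csv", package = "vitacross")
  read_stock_table(path)
}

#' Growth-deficit statistic for a vitamin-dropout screen
#'
#' The normalized contrast between growth without and with vitamins,
#' `(od_minus - od_plus) / (od_minus + od_plus)`: -1 when the isolate grows
#' only with vitamins, 0 when vitamins make no difference, +1 when it grows
#' only without. Putative auxotrophs fall below a cutoff (conventionally
#' -0.4).
#'
#' @param od_minus Median optical density (600 nm) without added vitamins.
#' @param od_plus Median optical density with the vitamin mix. Vectors are
#'   recycled in the usual way.
#' @returns A numeric vector in \[-1, 1\]; `NA` where both densities are zero
#'   (no growth in either condition; such isolates are dropped, not scored).
#' @examples
#' growth_deficit(0.06, 0.20) # about -0.54, an auxotroph at cutoff -0.4
#' @export
growth_deficit <- function(od_minus, od_plus) {
  if (any(od_minus < 0, na.rm = TRUE) || any(od_plus < 0, na.rm = TRUE)) {
    abort("Optical densities must be non-negative.", class = "vitacross_bad_input")
  }
  total <- od_minus + od_plus
  ifelse(total > 0, (od_minus - od_plus) / total, NA_real_)
}

#' Classify a serial-dilution screen plate into putative auxotrophs
#'
#' Takes long-format plate records, keeps the requested transfer (the third
#' by default, at which carried-over vitamins have been diluted to picomolar
#' levels), computes the median OD per condition across replicates, scores
#' the growth deficit, and calls putative auxotrophs below the cutoff.
#' Isolates missing a condition at that transfer, or with zero median OD in
#' both conditions, are reported with status `"dropped"` rather than scored;
#' they mirror the screen's rule that isolates failing to grow on the
#' supplemented medium are excluded.
#'
#' @param records Data frame with columns `isolate_id`, `condition` (one of
#'   `"plus_vitamins"`, `"minus_vitamins"`), `transfer`, `replicate`, `od`.
#' @param cutoff Growth-deficit cutoff below which an isolate is a putative
#'   auxotroph (default -0.4).
#' @param transfer Which transfer's growth data to use (default 3).
#' @returns A tibble with one row per isolate: `isolate_id`,
#'   `median_od_minus`, `median_od_plus`, `growth_deficit`,
#'   `putative_auxotroph`, `status` (`"ok"` or `"dropped"`).
#' @export
classify_screen <- function(records, cutoff = -0.4, transfer = 3) {
  records <- validate_plate(records)
  if (nrow(records) == 0) {
    return(tibble::tibble(
      isolate_id = character(), median_od_minus = double(),
      median_od_plus = double(), growth_deficit = double(),
      putative_auxotroph = logical(), status = character()
    ))
  }
  at_transfer <- dplyr::filter(records, .data$transfer == !!transfer)

  n_rep <- at_transfer |>
    dplyr::count(.data$isolate_id, .data$condition)
  if (nrow(n_rep) > 0 && dplyr::n_distinct(n_rep$n) > 1) {
    warn("Replicate counts differ across isolates/conditions; medians are still computed.")
  }

  medians <- at_transfer |>
    dplyr::group_by(.data$isolate_id, .data$condition) |>
    dplyr::summarise(median_od = median(.data$od), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "median_od")
  for (col in c("plus_vitamins", "minus_vitamins")) {
    if (!col %in% names(medians)) medians[[col]] <- NA_real_
  }
  # isolates present in the plate but absent at the requested transfer
  all_iso <- tibble::tibble(isolate_id = unique(records$isolate_id))
  medians <- dplyr::left_join(all_iso, medians, by = "isolate_id")

  medians |>
    dplyr::mutate(
      median_od_minus = .data$minus_vitamins,
      median_od_plus = .data$plus_vitamins,
      growth_deficit = growth_deficit(
        ifelse(is.na(.data$median_od_minus), 0, .data$median_od_minus),
        ifelse(is.na(.data$median_od_plus), 0, .data$median_od_plus)
      ),
      growth_deficit = ifelse(
        is.na(.data$median_od_minus) | is.na(.data$median_od_plus),
        NA_real_, .data$growth_deficit
      ),
      status = ifelse(is.na(.data$growth_deficit), "dropped", "ok"),
      putative_auxotroph = ifelse(
        .data$status == "ok", .data$growth_deficit < cutoff, NA
      )
    ) |>
    dplyr::select("isolate_id", "median_od_minus", "median_od_plus",
                  "growth_deficit", "putative_auxotroph", "status")
}

validate_plate <- function(records) {
  records <- tibble::as_tibble(records)
  required <- c("isolate_id", "condition", "transfer", "replicate", "od")
  missing <- setdiff(required, names(records))
  if (length(missing) > 0) {
    abort(paste0("Plate table is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "vitacross_bad_input")
  }
  bad <- setdiff(unique(records$condition), c("plus_vitamins", "minus_vitamins"))
  if (length(bad) > 0) {
    abort(paste0("Unknown condition token(s): ", paste(bad, collapse = ", "),
                 "; expected plus_vitamins/minus_vitamins."),
          class = "vitacross_bad_input")
  }
  if (any(records$od < 0, na.rm = TRUE)) {
    abort("Optical densities must be non-negative.", class = "vitacross_bad_input")
  }
  records
}

#' Resolve which specific vitamins a putative auxotroph requires
#'
#' Combines the two confirmation designs of the screen: growth with each
#' single vitamin added (`design = "single_supplement"`) and growth in mixes
#' of all vitamins but one (`design = "dropout"`). The dropout design is
#' decisive — a vitamin is required when the isolate consistently fails in
#' the mix lacking it, across at least `min_assays` repeated assays — and
#' the single-supplement design corroborates: a single requirement must
#' grow with that vitamin alone, while a multi-vitamin requirement must
#' fail in every single-supplement condition (no one vitamin suffices).
#' Isolates whose two designs disagree are flagged rather than called.
#' Growth is called from OD against a blank-derived threshold
#' (`blank_od + 3 * blank_sd`, floored at `od_floor`), a conventional
#' plate-reader detection rule.
#'
#' @param matrix_df Long data frame with columns `isolate_id`, `vitamin_id`,
#'   `design` (`"single_supplement"` or `"dropout"`), `assay` (repeat
#'   index), `od`.
#' @param blank_od,blank_sd Blank plate OD mean and standard deviation used
#'   for the growth threshold (defaults 0.04 and 0.003).
#' @param od_floor Absolute lower bound on the growth threshold
#'   (default 0.05).
#' @param min_assays Minimum number of consistent repeats for a confirmed
#'   call (default 2).
#' @returns A tibble with one row per isolate: `isolate_id`, `requirements`
#'   (list column of vitamin ids), `status` (`"confirmed"`, `"prototroph"`,
#'   `"unconfirmed"`, or `"unresolved"`).
#' @export
resolve_requirements <- function(matrix_df, blank_od = 0.04, blank_sd = 0.003,
                                 od_floor = 0.05, min_assays = 2) {
  matrix_df <- tibble::as_tibble(matrix_df)
  required <- c("isolate_id", "vitamin_id", "design", "assay", "od")
  missing <- setdiff(required, names(matrix_df))
  if (length(missing) > 0) {
    abort(paste0("Requirement matrix is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "vitacross_bad_input")
  }
  bad <- setdiff(unique(matrix_df$design), c("single_supplement", "dropout"))
  if (length(bad) > 0) {
    abort(paste0("Unknown design token(s): ", paste(bad, collapse = ", ")),
          class = "vitacross_bad_input")
  }
  threshold <- max(blank_od + 3 * blank_sd, od_floor)

  per_cell <- matrix_df |>
    dplyr::mutate(grew = .data$od >= threshold) |>
    dplyr::group_by(.data$isolate_id, .data$vitamin_id, .data$design) |>
    dplyr::summarise(
      n_assays = dplyr::n(),
      consistent = dplyr::n_distinct(.data$grew) == 1,
      grew = all(.data$grew),
      .groups = "drop"
    )

  vitamins_by_design <- per_cell |>
    dplyr::group_by(.data$isolate_id, .data$design) |>
    dplyr::summarise(vits = list(sort(unique(.data$vitamin_id))), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "design", values_from = "vits")
  incomplete <- purrr::map2_lgl(
    vitamins_by_design$single_supplement %||% list(),
    vitamins_by_design$dropout %||% list(),
    ~ !identical(.x, .y)
  )
  if (!("single_supplement" %in% names(vitamins_by_design)) ||
      !("dropout" %in% names(vitamins_by_design)) || any(incomplete)) {
    abort("Every vitamin tested must appear in both designs for every isolate.",
          class = "vitacross_bad_input")
  }

  per_cell |>
    dplyr::group_by(.data$isolate_id) |>
    dplyr::group_modify(~ resolve_one_isolate(.x, min_assays)) |>
    dplyr::ungroup()
}

resolve_one_isolate <- function(cells, min_assays) {
  wide <- cells |>
    dplyr::select("vitamin_id", "design", "n_assays", "consistent", "grew") |>
    tidyr::pivot_wider(names_from = "design",
                       values_from = c("n_assays", "consistent", "grew"))
  inconsistent <- !wide$consistent_single_supplement | !wide$consistent_dropout
  enough <- wide$n_assays_single_supplement >= min_assays &
    wide$n_assays_dropout >= min_assays
  candidate <- !wide$grew_dropout & !inconsistent & enough
  n_req <- sum(candidate)

  status <- if (any(inconsistent)) {
    "unconfirmed"
  } else if (n_req == 0) {
    if (all(wide$grew_dropout) && all(wide$grew_single_supplement)) {
      "prototroph"
    } else {
      # grows in every dropout yet fails elsewhere: contradictory designs
      "unresolved"
    }
  } else if (n_req == 1) {
    # a single requirement must also grow on that vitamin alone
    if (wide$grew_single_supplement[candidate]) "confirmed" else "unresolved"
  } else {
    # multiple requirements: no single vitamin can suffice
    if (!any(wide$grew_single_supplement)) "confirmed" else "unresolved"
  }
  tibble::tibble(
    requirements = list(if (status == "confirmed") {
      sort(wide$vitamin_id[candidate])
    } else character()),
    status = status
  )
}
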