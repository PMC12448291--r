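#' Load a marker-gene table for auxotrophy prediction
#'
#' Reads the YAML marker configuration: per-vitamin essential biosynthesis
#' genes, the precursor map (which single-gene loss leaves which vitamer
#' usable), and the cobalamin section (pathway gene list, completeness
#' threshold, and the metE/metH dependence markers). Gene symbols are
#' matched case-insensitively throughout, so the table is normalized to
#' lower case at load time and symbol collisions across vitamins are
#' rejected.
#'
#' @param path Path to a marker YAML file; default is the table shipped
#'   with the package (thiamine rules from the three-gene thiC/thiE/thiG
#'   core; conventional B3/B7/B9 marker sets meant to be overridden by
#'   study-specific lists).
#' @returns A list of class `marker_table` with elements `vitamins` (named
#'   list with `essential`, `precursor_map`, `low_confidence`) and `b12`
#'   (`pathway`, `completeness_threshold`, `dependence`).
#' @export
read_marker_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "markers.yaml", package = "vitacross")
  }
  if (!file.exists(path)) {
    abort(paste0("Marker table not found: ", path), class = "vitacross_io_error")
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw$vitamins) || length(raw$vitamins) == 0) {
    abort("Marker table must contain a non-empty `vitamins` section.",
          class = "vitacross_config_error")
  }
  vitamins <- purrr::imap(raw$vitamins, function(v, id) {
    ess <- tolower(unlist(v$essential))
    if (length(ess) == 0) {
      abort(paste0("Marker list for ", id, " is empty."),
            class = "vitacross_config_error")
    }
    pm <- v$precursor_map %||% list()
    names(pm) <- tolower(names(pm))
    list(essential = ess, precursor_map = pm,
         low_confidence = isTRUE(v$low_confidence))
  })
  all_markers <- unlist(purrr::map(vitamins, "essential"))
  if (anyDuplicated(all_markers)) {
    dup <- unique(all_markers[duplicated(all_markers)])
    abort(paste0("Gene symbol(s) assigned to more than one vitamin: ",
                 paste(dup, collapse = ", ")),
          class = "vitacross_config_error")
  }
  b12 <- raw$b12
  if (!is.null(b12)) {
    b12$pathway <- tolower(unlist(b12$pathway))
    thr <- b12$completeness_threshold %||% 0.8
    if (!(thr > 0 && thr <= 1)) {
      abort("B12 completeness threshold must be in (0, 1].",
            class = "vitacross_config_error")
    }
    b12$completeness_threshold <- thr
    b12$dependence <- list(
      b12_independent = tolower(b12$dependence$b12_independent %||% "metE"),
      b12_dependent = tolower(b12$dependence$b12_dependent %||% "metH")
    )
  }
  structure(list(vitamins = vitamins, b12 = b12), class = "marker_table")
}

normalize_genes <- function(genes) unique(tolower(genes))

#' Predict per-vitamin auxotrophy from gene presence/absence
#'
#' Applies the marker rules to one genome: a vitamin is called auxotrophic
#' when any essential biosynthesis marker is absent. The evolutionary mode
#' is `total_loss` when every marker is gone (the whole pathway lost) and
#' `partial_loss` otherwise; for a partial loss of exactly one mapped gene
#' the vitamer that still feeds the remaining pathway is reported (e.g.
#' losing only thiC leaves an HMP requirement, the pyrimidine half of
#' thiamine). The rule is monotone: removing genes can never turn an
#' auxotroph call back into a prototroph call.
#'
#' @param genomes Data frame with columns `genome_id` and `genes` (either a
#'   list column of character vectors or a comma-separated string column).
#' @param markers A [read_marker_table()] object.
#' @returns A tibble with one row per genome x vitamin: `genome_id`,
#'   `vitamin_id`, `status` (`"prototroph"`/`"auxotroph"`), `mode`
#'   (`"partial_loss"`, `"total_loss"`, or `NA`), `required_vitamer`,
#'   `missing_markers` (list column), `low_confidence`.
#' @export
predict_auxotrophy <- function(genomes, markers = read_marker_table()) {
  genomes <- as_genome_table(genomes)
  purrr::map_dfr(seq_len(nrow(genomes)), function(i) {
    present <- normalize_genes(genomes$genes[[i]])
    purrr::imap_dfr(markers$vitamins, function(v, vit) {
      absent <- setdiff(v$essential, present)
      is_aux <- length(absent) > 0
      mode <- if (!is_aux) NA_character_
              else if (length(absent) == length(v$essential)) "total_loss"
              else "partial_loss"
      vitamer <- NA_character_
      if (identical(mode, "partial_loss") && length(absent) == 1 &&
          absent %in% names(v$precursor_map)) {
        vitamer <- v$precursor_map[[absent]]
      }
      tibble::tibble(
        genome_id = genomes$genome_id[i],
        vitamin_id = vit,
        status = if (is_aux) "auxotroph" else "prototroph",
        mode = mode,
        required_vitamer = vitamer,
        missing_markers = list(absent),
        low_confidence = v$low_confidence
      )
    })
  })
}

as_genome_table <- function(genomes) {
  genomes <- tibble::as_tibble(genomes)
  if (!all(c("genome_id", "genes") %in% names(genomes))) {
    abort("`genomes` must have columns genome_id and genes.",
          class = "vitacross_bad_input")
  }
  if (!is.list(genomes$genes)) {
    genomes$genes <- strsplit(trimws(genomes$genes), "\\s*,\\s*")
  }
  genomes
}

#' Three-state cobalamin status from pathway completeness and metE/metH
#'
#' Cobalamin differs from the other B vitamins in that it is not
#' universally essential: many bacteria scavenge it when available but use
#' a B12-independent bypass otherwise. A genome is a `producer` when the
#' fraction of pathway genes present reaches the completeness threshold; a
#' non-producer is a `dependent_auxotroph` when it retains only the
#' B12-dependent methionine synthase (metH present, metE absent), and a
#' `flexible_nonproducer` when metE is present. The completeness score is
#' always reported, exposing the misclassification risk for producers that
#' lost only single pathway genes.
#'
#' @inheritParams predict_auxotrophy
#' @returns A tibble with one row per genome: `genome_id`, `b12_status`,
#'   `completeness`, `metE`, `metH`.
#' @export
predict_b12_status <- function(genomes, markers = read_marker_table()) {
  if (is.null(markers$b12)) {
    abort("Marker table has no B12 section.", class = "vitacross_config_error")
  }
  genomes <- as_genome_table(genomes)
  b12 <- markers$b12
  purrr::map_dfr(seq_len(nrow(genomes)), function(i) {
    present <- normalize_genes(genomes$genes[[i]])
    completeness <- mean(b12$pathway %in% present)
    has_metE <- b12$dependence$b12_independent %in% present
    has_metH <- b12$dependence$b12_dependent %in% present
    status <- if (completeness >= b12$completeness_threshold) {
      "producer"
    } else if (has_metH && !has_metE) {
      "dependent_auxotroph"
    } else {
      "flexible_nonproducer"
    }
    if (!has_metE && !has_metH) {
      warn(sprintf(
        "Genome %s carries neither metE nor metH: methionine synthesis impossible under this rule set.",
        genomes$genome_id[i]))
    }
    tibble::tibble(
      genome_id = genomes$genome_id[i],
      b12_status = status,
      completeness = completeness,
      metE = has_metE,
      metH = has_metH
    )
  })
}

#' Predict whether pairs of auxotrophs complement each other in co-culture
#'
#' Base rule: a pair grows if and only if every vitamin required by either
#' member can be produced by the partner (prototroph for that vitamin; B12
#' producer for a B12 requirement). With the methionine bypass enabled, a
#' B12 requirement is also satisfiable by a partner carrying metE: such a
#' partner can supply methionine itself, removing the need for B12-dependent
#' methionine synthesis. Predictions are symmetric in the pair and always
#' carry a rationale.
#'
#' @param calls Tibble from [predict_auxotrophy()], optionally augmented
#'   with B12 rows: either include `vitamin_id == "B12"` rows with
#'   `status`, or supply `b12` below.
#' @param b12 Optional tibble from [predict_b12_status()]; when given, a
#'   `dependent_auxotroph` contributes a B12 requirement and a `producer`
#'   can satisfy one.
#' @param bypass_methionine Apply the methionine bypass rule (default
#'   FALSE).
#' @returns A tibble with one row per unordered pair: `genome_a`,
#'   `genome_b`, `predicted` (`"grows"`/`"fails"`), `rationale`,
#'   `bypass_applied`.
#' @export
predict_coculture <- function(calls, b12 = NULL, bypass_methionine = FALSE) {
  calls <- tibble::as_tibble(calls)
  genomes <- sort(unique(calls$genome_id))
  if (length(genomes) < 2) {
    abort("Need at least two genomes for co-culture predictions.",
          class = "vitacross_bad_input")
  }
  # per genome: required vitamins, producible vitamins, metE carriage
  profile <- function(g) {
    mine <- dplyr::filter(calls, .data$genome_id == g)
    req <- mine$vitamin_id[mine$status == "auxotroph"]
    prod <- mine$vitamin_id[mine$status == "prototroph"]
    metE <- FALSE
    if (!is.null(b12)) {
      row <- dplyr::filter(b12, .data$genome_id == g)
      if (nrow(row) == 1) {
        if (row$b12_status == "dependent_auxotroph") req <- union(req, "B12")
        if (row$b12_status == "producer") prod <- union(prod, "B12")
        metE <- isTRUE(row$metE)
      }
    }
    list(req = req, prod = prod, metE = metE)
  }
  profiles <- setNames(lapply(genomes, profile), genomes)

  pairs <- utils::combn(genomes, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(p) {
    a <- profiles[[p[1]]]; b <- profiles[[p[2]]]
    check <- function(req, partner) {
      satisfied <- purrr::map_lgl(req, function(v) {
        base <- v %in% partner$prod
        if (!base && bypass_methionine && v == "B12" && partner$metE) {
          return(NA)  # satisfied via methionine, mark bypass
        }
        base
      })
      satisfied
    }
    sat_a <- check(a$req, b)
    sat_b <- check(b$req, a)
    bypass_used <- any(is.na(c(sat_a, sat_b)))
    ok <- all(is.na(sat_a) | sat_a) && all(is.na(sat_b) | sat_b)
    blockers <- c(a$req[!is.na(sat_a) & !sat_a], b$req[!is.na(sat_b) & !sat_b])
    rationale <- if (ok && length(c(a$req, b$req)) == 0) {
      "no vitamin requirements on either side"
    } else if (ok) {
      msg <- sprintf("all requirements covered (%s)",
                     paste(unique(c(a$req, b$req)), collapse = ", "))
      if (bypass_used) paste0(msg, "; B12 need met via partner methionine (metE)")
      else msg
    } else {
      sprintf("unmet requirement(s): %s", paste(unique(blockers), collapse = ", "))
    }
    tibble::tibble(
      genome_a = p[1], genome_b = p[2],
      predicted = if (ok) "grows" else "fails",
      rationale = rationale,
      bypass_applied = bypass_used
    )
  })
}

#' Concordance between predicted and observed auxotrophies
#'
#' Per-vitamin error rate of genotype-based predictions against observed
#' phenotypes: the fraction of scored genomes where the predicted status
#' differs from the observed one, with false positives (predicted
#' auxotroph, observed prototroph) and false negatives counted separately.
#' Genomes missing a phenotype for a vitamin are excluded from the rate and
#' reported in `n_missing`.
#'
#' @param calls Tibble from [predict_auxotrophy()].
#' @param phenotypes Data frame with columns `genome_id`, `vitamin_id`,
#'   `observed` (`"auxotroph"`/`"prototroph"`).
#' @returns A tibble with one row per vitamin: `vitamin_id`, `n`,
#'   `n_missing`, `false_positives`, `false_negatives`, `error_rate`.
#' @export
concordance <- function(calls, phenotypes) {
  calls <- tibble::as_tibble(calls)
  phenotypes <- tibble::as_tibble(phenotypes)
  joined <- calls |>
    dplyr::select("genome_id", "vitamin_id", "status") |>
    dplyr::left_join(phenotypes, by = c("genome_id", "vitamin_id"))
  joined |>
    dplyr::group_by(.data$vitamin_id) |>
    dplyr::summarise(
      n = sum(!is.na(.data$observed)),
      n_missing = sum(is.na(.data$observed)),
      false_positives = sum(.data$status == "auxotroph" &
                              .data$observed == "prototroph", na.rm = TRUE),
      false_negatives = sum(.data$status == "prototroph" &
                              .data$observed == "auxotroph", na.rm = TRUE),
      error_rate = ifelse(.data$n > 0,
                          (.data$false_positives + .data$false_negatives) / .data$n,
                          NA_real_),
      .groups = "drop"
    )
}
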