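# Seeded generators for every input class the pipeline consumes, each
# returning the data together with its ground truth so consuming stages can
# be tested closed-loop. All randomness is confined to `local_seed()`: the
# caller's RNG state is restored on exit and a fixed seed gives identical
# output.

local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# multiplicative log-normal noise with unit mean and the stated CV
lognorm_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

#' Generate Monod-limited exponential growth curves with known truth
#'
#' Emulates the kinetic dose-response design: one auxotroph grown across a
#' zero-vitamin condition plus a series of ten-fold vitamin dilutions, in
#' replicate, with OD sampled on a regular clock. Each curve is exponential
#' at the Monod rate `r(S) = r_max * S / (K_S + S)`, truncated at a
#' carrying OD, with multiplicative log-normal noise of the stated CV.
#'
#' @param seed Integer seed; fixed seed gives identical output.
#' @param r_max True maximal growth rate, h^-1 (default 0.5).
#' @param half_saturation True half-saturation constant, molar.
#' @param concentrations Vitamin concentrations (molar); must include 0 and
#'   at least 4 positive values. Default: 0 plus seven 10-fold dilutions
#'   bracketing `half_saturation`.
#' @param noise_cv Multiplicative OD noise CV (default 0.05).
#' @param n_replicates Replicates per concentration (default 3).
#' @param od0 Inoculum OD (default 0.01).
#' @param carrying_od Saturating OD (default 0.5).
#' @param times Sampling times in hours (default 0 to 24 by 0.5).
#' @returns A list with `curves` (tibble: `concentration_molar`,
#'   `replicate`, `time_h`, `od`) and `truth` (tibble: `r_max`,
#'   `half_saturation`).
#' @export
gen_growth_curves <- function(seed, r_max = 0.5, half_saturation = 1e-9,
                              concentrations = c(0, half_saturation * 10^seq(-3, 3)),
                              noise_cv = 0.05, n_replicates = 3,
                              od0 = 0.01, carrying_od = 0.5,
                              times = seq(0, 24, by = 0.5)) {
  if (!any(concentrations == 0) || sum(concentrations > 0) < 4) {
    abort("`concentrations` must include 0 and >= 4 positive values.",
          class = "vitacross_bad_input")
  }
  local_seed(seed, {
    curves <- tidyr::expand_grid(
      concentration_molar = concentrations,
      replicate = seq_len(n_replicates),
      time_h = times
    ) |>
      dplyr::mutate(
        rate = r_max * .data$concentration_molar /
          (half_saturation + .data$concentration_molar),
        od_clean = pmin(od0 * exp(.data$rate * .data$time_h), carrying_od),
        od = .data$od_clean * lognorm_noise(dplyr::n(), noise_cv)
      ) |>
      dplyr::select("concentration_molar", "replicate", "time_h", "od")
    list(curves = curves,
         truth = tibble::tibble(r_max = r_max, half_saturation = half_saturation))
  })
}

#' Generate a serial-dilution screen plate with planted auxotrophs
#'
#' Emulates the two-condition serial growth-dilution screen: every isolate
#' grows to a set OD in the vitamin-supplemented condition; planted
#' auxotrophs decay toward the blank in the unsupplemented condition as
#' carried-over vitamins dilute away, modelled phenomenologically as a
#' per-transfer growth attenuation. Multiplicative log-normal noise is
#' applied to every well.
#'
#' @param seed Integer seed.
#' @param n_isolates Number of isolates (default 150).
#' @param auxotroph_fraction Fraction of isolates planted as auxotrophs
#'   (default 0.3).
#' @param noise_cv Per-well OD noise CV (default 0.05).
#' @param n_transfers Transfers recorded (default 3).
#' @param n_replicates Replicates per condition (default 3).
#' @param od_grown OD of a well growing normally (default 0.3).
#' @param attenuation Per-transfer multiplicative growth attenuation of an
#'   auxotroph without vitamins (default 0.25; 1 means no auxotrophy
#'   effect).
#' @param blank_od Floor OD of a non-growing well (default 0.02).
#' @returns A list with `records` (tibble: `isolate_id`, `condition`,
#'   `transfer`, `replicate`, `od`) and `truth` (tibble: `isolate_id`,
#'   `is_auxotroph`).
#' @export
gen_screen_plate <- function(seed, n_isolates = 150, auxotroph_fraction = 0.3,
                             noise_cv = 0.05, n_transfers = 3, n_replicates = 3,
                             od_grown = 0.3, attenuation = 0.25,
                             blank_od = 0.02) {
  if (auxotroph_fraction < 0 || auxotroph_fraction > 1) {
    abort("auxotroph_fraction must lie in [0, 1].", class = "vitacross_bad_input")
  }
  local_seed(seed, {
    ids <- sprintf("iso%03d", seq_len(n_isolates))
    n_aux <- round(auxotroph_fraction * n_isolates)
    is_aux <- rep(FALSE, n_isolates)
    is_aux[sample.int(n_isolates, n_aux)] <- TRUE
    truth <- tibble::tibble(isolate_id = ids, is_auxotroph = is_aux)

    records <- tidyr::expand_grid(
      isolate_id = ids,
      condition = c("plus_vitamins", "minus_vitamins"),
      transfer = seq_len(n_transfers),
      replicate = seq_len(n_replicates)
    ) |>
      dplyr::left_join(truth, by = "isolate_id") |>
      dplyr::mutate(
        od_clean = ifelse(
          .data$condition == "minus_vitamins" & .data$is_auxotroph,
          pmax(blank_od, od_grown * attenuation^.data$transfer),
          od_grown
        ),
        od = .data$od_clean * lognorm_noise(dplyr::n(), noise_cv)
      ) |>
      dplyr::select("isolate_id", "condition", "transfer", "replicate", "od")
    list(records = records, truth = truth)
  })
}

#' Generate genomes with rule-consistent losses and annotation errors
#'
#' Draws toy genomes against a marker table: for each vitamin, a genome
#' loses the pathway with probability `loss_rate` (an even split between
#' partial loss of one random marker and total loss of all markers), and
#' cobalamin genomes are drawn as producers, flexible non-producers
#' (metE and metH, no pathway), or dependent auxotrophs (metH only). The
#' ground-truth calls are the rule predictions on the clean genomes;
#' annotation-error flips are then planted at rate `flip_rate` per genome
#' and vitamin, each flip corrupting the annotation just enough to toggle
#' the inferred status (removing a marker from an intact pathway, or
#' restoring the missing markers of a lost one), so the planted flip rate
#' is the expected per-vitamin concordance error.
#'
#' @param seed Integer seed.
#' @param markers A [read_marker_table()] object.
#' @param n_genomes Number of genomes (default 150).
#' @param loss_rate Per-vitamin probability of a biosynthesis loss
#'   (default 0.3).
#' @param flip_rate Per-genome, per-vitamin annotation flip probability
#'   (default 0).
#' @param b12_probs Probabilities of the producer / flexible_nonproducer /
#'   dependent_auxotroph cobalamin states (default 0.2, 0.6, 0.2).
#' @returns A list with `genomes` (tibble: `genome_id`, `genes` list
#'   column, post-flip), `genomes_clean` (pre-flip), `truth` (rule calls on
#'   the clean genomes), and `truth_b12`.
#' @export
gen_genomes <- function(seed, markers = read_marker_table(), n_genomes = 150,
                        loss_rate = 0.3, flip_rate = 0,
                        b12_probs = c(0.2, 0.6, 0.2)) {
  local_seed(seed, {
    ids <- sprintf("g%03d", seq_len(n_genomes))
    b12 <- markers$b12
    genomes_clean <- purrr::map(seq_len(n_genomes), function(i) {
      genes <- character()
      for (vit in names(markers$vitamins)) {
        ess <- markers$vitamins[[vit]]$essential
        if (runif(1) < loss_rate) {
          if (runif(1) < 0.5 && length(ess) > 1) {
            genes <- c(genes, ess[-sample.int(length(ess), 1)])  # partial
          }                                                      # else total
        } else {
          genes <- c(genes, ess)
        }
      }
      if (!is.null(b12)) {
        state <- sample(c("producer", "flexible_nonproducer", "dependent_auxotroph"),
                        1, prob = b12_probs)
        genes <- c(genes, switch(
          state,
          producer = c(b12$pathway, b12$dependence$b12_dependent),
          flexible_nonproducer = c(b12$dependence$b12_independent,
                                   b12$dependence$b12_dependent),
          dependent_auxotroph = b12$dependence$b12_dependent
        ))
      }
      genes
    })
    clean_tbl <- tibble::tibble(genome_id = ids, genes = genomes_clean)
    truth <- predict_auxotrophy(clean_tbl, markers)
    truth_b12 <- if (!is.null(b12)) predict_b12_status(clean_tbl, markers) else NULL

    flipped <- purrr::map(seq_len(n_genomes), function(i) {
      genes <- genomes_clean[[i]]
      for (vit in names(markers$vitamins)) {
        if (runif(1) < flip_rate) {
          ess <- markers$vitamins[[vit]]$essential
          absent <- setdiff(ess, genes)
          if (length(absent) == 0) {
            genes <- setdiff(genes, ess[sample.int(length(ess), 1)])
          } else {
            genes <- union(genes, absent)
          }
        }
      }
      genes
    })
    list(
      genomes = tibble::tibble(genome_id = ids, genes = flipped),
      genomes_clean = clean_tbl,
      truth = truth,
      truth_b12 = truth_b12
    )
  })
}

#' Sample particle-model parameter sets log-uniformly
#'
#' Draws random trait and parameter combinations for cross-oracle property
#' tests: each named bound is sampled log-uniformly between its limits
#' (point bounds give constants).
#'
#' @param seed Integer seed.
#' @param n Number of samples (default 10).
#' @param bounds Named list of `c(min, max)` bounds; defaults span the
#'   measured trait ranges (half-saturation 1e-11 to 1e-6 M, quota 1e1 to
#'   1e6 molecules/cell) plus release rates, particle size and auxotroph
#'   load.
#' @returns A tibble with one row per sample and one column per bound.
#' @export
gen_model_params <- function(seed, n = 10,
                             bounds = list(
                               half_saturation = c(1e-11, 1e-6),
                               quota = c(1e1, 1e6),
                               secretion_rate = c(1, 300),
                               lysis_rate = c(0.05, 0.45),
                               radius_um = c(20, 100),
                               n_auxotrophs = c(1e3, 1e5)
                             )) {
  bad <- purrr::map_lgl(bounds, ~ length(.x) != 2 || any(.x <= 0) || .x[1] > .x[2])
  if (any(bad)) {
    abort("Each bound must be a positive c(min, max) pair.",
          class = "vitacross_bad_input")
  }
  local_seed(seed, {
    cols <- purrr::map(bounds, function(b) {
      exp(runif(n, log(b[1]), log(b[2])))
    })
    tibble::as_tibble(cols) |>
      dplyr::mutate(sample_id = seq_len(n), .before = 1)
  })
}
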