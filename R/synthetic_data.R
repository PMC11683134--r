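#' Specification of a synthetic flow-cytometry population
#'
#' Describes an asynchronous yeast suspension as the measurement model the
#' analysis assumes. Per event i:
#'
#' * ploidy class drawn from `ploidy_fractions`; nuclear DNA is `ndna_1n` Mb
#'   in G1, `ndna_2n` in G2/M and uniform in between for S-phase cells;
#' * log2 cell size drawn from `Normal(size_log2_mean, size_log2_sd)`,
#'   v_i = 2^size;
#' * mtDNA copies `c_i = round(m(ploidy) * (v_i / vbar)^beta * eta_i)` with
#'   `eta_i ~ Gamma(mean 1, CV copies_cv)`; m is `copies_mean_2n` for 2n (and
#'   S) cells and half that for G1 cells; rho0 populations carry zero copies;
#' * fluorescence `gain * (nDNA_i + c_i * mtdna_size) * (v_i/vbar)^background_size_beta
#'   * background_inflation * eps_i` with `eps_i ~ lognormal(mean 1,
#'   CV measurement_cv)`;
#' * forward scatter `2^(size_i + Normal(0, fsc_noise_sd))` (optics noise).
#'
#' `background_size_beta` adds a non-DNA, size-proportional signal component
#' (non-specific dye binding); zero by default. `background_inflation`
#' models a uniform multiplicative signal increase of non-mtDNA origin, such
#' as the moderate stain increase rho0 cells show after arrest.
#'
#' @param n_events Number of events (default 50000).
#' @param mito_status `"rho_plus"` or `"rho_zero"`.
#' @param ploidy_fractions Named fractions for G1, S, G2M; must sum to 1.
#' @param genome [genome_params()].
#' @param copies_mean_2n Mean mtDNA copies per 2n cell (default 30.8).
#' @param copies_cv Per-cell CV of mtDNA copies (default 0.2).
#' @param size_log2_mean,size_log2_sd Log2 cell-size distribution (defaults
#'   16 and 0.35, i.e. a cell-size CV of roughly 25 percent).
#' @param size_coupling_beta Exponent coupling copies to relative size
#'   (0 = decoupled, 1 = proportional; default 0).
#' @param fsc_noise_sd Log2 optics noise on forward scatter (default 0.15).
#' @param measurement_cv CV of multiplicative fluorescence noise (default 0.05).
#' @param background_inflation Multiplicative factor >= 1 on all signals.
#' @param background_size_beta Exponent of the size-proportional non-DNA
#'   signal component (default 0).
#' @param gain Instrument gain: fluorescence units per megabase (default 2000).
#' @param seed Optional integer seed stored with the spec.
#' @return A `population_spec`.
#' @export
population_spec <- function(n_events = 50000L,
                            mito_status = c("rho_plus", "rho_zero"),
                            ploidy_fractions = c(G1 = 0.4, S = 0.2, G2M = 0.4),
                            genome = genome_params(),
                            copies_mean_2n = 30.8,
                            copies_cv = 0.2,
                            size_log2_mean = 16,
                            size_log2_sd = 0.35,
                            size_coupling_beta = 0,
                            fsc_noise_sd = 0.15,
                            measurement_cv = 0.05,
                            background_inflation = 1,
                            background_size_beta = 0,
                            gain = 2000,
                            seed = NULL) {
  mito_status <- match.arg(mito_status)
  pf <- ploidy_fractions[c("G1", "S", "G2M")]
  if (any(is.na(pf)) || any(pf < 0) || abs(sum(pf) - 1) > 1e-6) {
    stop_cytomito("ploidy_fractions must be named G1/S/G2M, non-negative, summing to 1",
                  "cytomito_spec_error")
  }
  stopifnot(n_events >= 1, copies_mean_2n >= 0, copies_cv >= 0,
            size_log2_sd >= 0, fsc_noise_sd >= 0, measurement_cv >= 0,
            background_inflation >= 1, gain > 0)
  structure(list(n_events = as.integer(n_events), mito_status = mito_status,
                 ploidy_fractions = pf, genome = genome,
                 copies_mean_2n = copies_mean_2n, copies_cv = copies_cv,
                 size_log2_mean = size_log2_mean, size_log2_sd = size_log2_sd,
                 size_coupling_beta = size_coupling_beta,
                 fsc_noise_sd = fsc_noise_sd, measurement_cv = measurement_cv,
                 background_inflation = background_inflation,
                 background_size_beta = background_size_beta,
                 gain = gain, seed = seed),
            class = "population_spec")
}

# gamma multiplier with mean 1 and given CV (1 when cv == 0)
rgamma_unit <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  shape <- 1 / cv^2
  rgamma(n, shape = shape, scale = 1 / shape)
}

# lognormal multiplier with mean 1 and given CV
rlnorm_unit <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# core measurement model shared by proliferating and arrested populations
simulate_events <- function(spec, ploidy_class, size_log2, copies) {
  g <- spec$genome
  n <- length(size_log2)
  ndna <- numeric(n)
  ndna[ploidy_class == "G1"] <- g$ndna_1n
  ndna[ploidy_class == "G2M"] <- g$ndna_2n
  is_s <- ploidy_class == "S"
  if (any(is_s)) ndna[is_s] <- runif(sum(is_s), g$ndna_1n, g$ndna_2n)
  v <- 2^size_log2
  vbar <- mean(v)
  eps <- rlnorm_unit(n, spec$measurement_cv)
  fluor <- spec$gain * (ndna + copies * g$mtdna_size) *
    (v / vbar)^spec$background_size_beta *
    spec$background_inflation * eps
  fsc <- 2^(size_log2 + rnorm(n, 0, spec$fsc_noise_sd))
  event_table(fluor, fsc,
              sample_id = sprintf("synthetic_%s", spec$mito_status),
              truth = data.frame(ploidy_class = ploidy_class,
                                 mtdna_copies = copies,
                                 cell_size = v))
}

ploidy_copy_mean <- function(spec, ploidy_class) {
  m <- rep(spec$copies_mean_2n, length(ploidy_class))
  m[ploidy_class == "G1"] <- spec$copies_mean_2n / 2
  m
}

#' Generate a synthetic proliferating population
#'
#' Draws events under the measurement model described in [population_spec()]
#' and returns them with per-event ground-truth labels (`ploidy_class`,
#' `mtdna_copies`, `cell_size`). Identical seeds give identical tables.
#'
#' @param spec A [population_spec()].
#' @param seed Integer seed; overrides `spec$seed`.
#' @return An [event_table()] with truth columns.
#' @export
generate_population <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "population_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n_events
  ploidy_class <- sample(c("G1", "S", "G2M"), n, replace = TRUE,
                         prob = spec$ploidy_fractions)
  size_log2 <- rnorm(n, spec$size_log2_mean, spec$size_log2_sd)
  copies <- if (spec$mito_status == "rho_zero") {
    rep(0L, n)
  } else {
    v <- 2^size_log2
    m <- ploidy_copy_mean(spec, ploidy_class) *
      (v / mean(v))^spec$size_coupling_beta
    as.integer(round(m * rgamma_unit(n, spec$copies_cv)))
  }
  simulate_events(spec, ploidy_class, size_log2, copies)
}

#' Specification of a cell-cycle-arrest experiment
#'
#' Pairs a proliferating control population with an arrested one. Arrest
#' confines all cells to `arrest_ploidy` (thermosensitive CDC mutants arrest
#' unbudded in G1 or at mitotic exit), grows them by `growth_factor` in
#' linear size, and multiplies their expected mtDNA copies by
#' `accumulation_fold` under one of two accumulation models:
#'
#' * `"size_coupled"` — copies track current cell size
#'   (`c_i` proportional to v_i), so within a size class copy number is
#'   tightly set; per-size-bin CV stays at the noise floor.
#' * `"stochastic_walk"` — copies drift multiplicatively with a dispersion
#'   that grows with how much the cell has grown
#'   (`sd of log copies = walk_dispersion * sqrt(relative growth)`), so
#'   larger cells are more heterogeneous and per-size-bin CV rises with size.
#'
#' `arrest_background_inflation` multiplies every arrested signal regardless
#' of mtDNA status, reproducing the moderate stain increase that arrested
#' rho0 cells show (default `2^0.1`, a 0.1 log2-unit shift).
#'
#' @param base A [population_spec()] for the control condition.
#' @param arrest_ploidy `"1n"` or `"2n"`.
#' @param growth_factor Linear size multiplier over the arrest (> 1; default 2).
#' @param accumulation_mode `"size_coupled"` or `"stochastic_walk"`.
#' @param accumulation_fold Mean fold increase of copies (default 3.3).
#' @param walk_dispersion Dispersion rate of the stochastic walk (default 0).
#' @param arrest_background_inflation Multiplicative arrest background
#'   (default `2^0.1`).
#' @return An `arrest_spec`.
#' @export
arrest_spec <- function(base = population_spec(),
                        arrest_ploidy = c("1n", "2n"),
                        growth_factor = 2,
                        accumulation_mode = c("size_coupled", "stochastic_walk"),
                        accumulation_fold = 3.3,
                        walk_dispersion = 0,
                        arrest_background_inflation = 2^0.1) {
  arrest_ploidy <- match.arg(arrest_ploidy)
  accumulation_mode <- match.arg(accumulation_mode)
  stopifnot(inherits(base, "population_spec"), growth_factor >= 1,
            accumulation_fold >= 1, walk_dispersion >= 0,
            arrest_background_inflation >= 1)
  structure(list(base = base, arrest_ploidy = arrest_ploidy,
                 growth_factor = growth_factor,
                 accumulation_mode = accumulation_mode,
                 accumulation_fold = accumulation_fold,
                 walk_dispersion = walk_dispersion,
                 arrest_background_inflation = arrest_background_inflation),
            class = "arrest_spec")
}

#' Generate a matched control/arrested population pair
#'
#' The control table is [generate_population()] of the base spec; the
#' arrested table contains only the arrested ploidy class, grown and loaded
#' with mtDNA per the accumulation model of [arrest_spec()]. With
#' `growth_factor = 1`, `accumulation_fold = 1` and
#' `arrest_background_inflation = 1` the arrested sampling scheme reduces to
#' the control one.
#'
#' @param spec An [arrest_spec()].
#' @param seed Integer seed for the pair.
#' @return List with `control` and `arrested` event tables.
#' @export
generate_arrest_pair <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "arrest_spec"))
  base <- spec$base
  control <- generate_population(base, seed = seed)

  n <- base$n_events
  ploidy_class <- rep(if (spec$arrest_ploidy == "1n") "G1" else "G2M", n)
  size_log2 <- rnorm(n, base$size_log2_mean, base$size_log2_sd) +
    log2(spec$growth_factor)
  copies <- if (base$mito_status == "rho_zero") {
    rep(0L, n)
  } else {
    m0 <- ploidy_copy_mean(base, ploidy_class)
    v <- 2^size_log2
    m <- switch(spec$accumulation_mode,
      size_coupled = m0 * spec$accumulation_fold * (v / mean(v)),
      stochastic_walk = {
        growth <- pmax(size_log2 - base$size_log2_mean, 0) /
          max(log2(spec$growth_factor), .Machine$double.eps)
        sdl <- spec$walk_dispersion * sqrt(growth)
        m0 * spec$accumulation_fold * exp(rnorm(n, -sdl^2 / 2, sdl))
      })
    as.integer(round(m * rgamma_unit(n, base$copies_cv)))
  }
  arr_spec <- base
  arr_spec$background_inflation <- base$background_inflation *
    spec$arrest_background_inflation
  arrested <- simulate_events(arr_spec, ploidy_class, size_log2, copies)
  attr(arrested, "sample_id") <- sprintf("synthetic_%s_arrested_%s",
                                         base$mito_status, spec$arrest_ploidy)
  list(control = control, arrested = arrested)
}

#' Write a truth-label sidecar CSV
#'
#' Companion to [write_events_csv()]: per-event ground-truth labels
#' (`ploidy_class`, `mtdna_copies`, `cell_size`) of a synthetic table, in the
#' same row order as the written events.
#'
#' @param t An [event_table()] with truth columns.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_truth_csv <- function(t, path) {
  if (!all(c("ploidy_class", "mtdna_copies", "cell_size") %in% names(t))) {
    stop_cytomito("event table carries no truth labels", "cytomito_contract_error")
  }
  write.csv(data.frame(ploidy_class = t$ploidy_class,
                       mtdna_copies = t$mtdna_copies,
                       cell_size = t$cell_size),
            path, row.names = FALSE)
  invisible(path)
}
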