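# shared fixtures: small synthetic populations and mode shortcuts

# single-ploidy-class spec, convenient for mode arithmetic tests
pure_spec <- function(status = "rho_plus", class = "G2M", n = 50000L, ...) {
  fr <- c(G1 = 0, S = 0, G2M = 0)
  fr[class] <- 1
  population_spec(n_events = n, mito_status = status, ploidy_fractions = fr, ...)
}

# detected peak set of a (linear) event table
peaks_of <- function(t, expected = "2n", bandwidth = NULL) {
  find_peak_modes(estimate_density(log2_transform(t)$fluor_log2,
                                   bandwidth = bandwidth),
                  expected_ploidy = expected)
}

# recovered 2n-peak shift between a matched rho+/rho0 pair of populations
recovered_shift_2n <- function(seed, copies = 30.8, n = 50000L,
                               measurement_cv = 0.05, copies_cv = 0.2) {
  plus <- generate_population(
    pure_spec("rho_plus", n = n, copies_mean_2n = copies,
              measurement_cv = measurement_cv, copies_cv = copies_cv),
    seed = seed)
  zero <- generate_population(
    pure_spec("rho_zero", n = n, measurement_cv = measurement_cv),
    seed = seed + 5000L)
  peaks_of(plus)$mode_2n - peaks_of(zero)$mode_2n
}

# brute-force oracle: indices of all interior local maxima of a vector
oracle_local_maxima <- function(y) {
  idx <- integer()
  for (i in 2:(length(y) - 1)) {
    if (y[i] > y[i - 1] && y[i] >= y[i + 1]) idx <- c(idx, i)
  }
  idx
}

# four-sample arrest design entry for run_pipeline tests
arrest_design_samples <- function(rep_id, seed, n = 20000L, fold = 3.3) {
  pp <- generate_arrest_pair(
    arrest_spec(population_spec(n_events = n, mito_status = "rho_plus"),
                arrest_ploidy = "1n", accumulation_mode = "size_coupled",
                accumulation_fold = fold),
    seed = seed)
  pz <- generate_arrest_pair(
    arrest_spec(population_spec(n_events = n, mito_status = "rho_zero"),
                arrest_ploidy = "1n"),
    seed = seed + 1L)
  list(
    list(table = pp$control, mito_status = "rho_plus", condition = "control_25C",
         arrest_ploidy = "none", replicate_id = rep_id),
    list(table = pp$arrested, mito_status = "rho_plus", condition = "arrested_37C",
         arrest_ploidy = "1n", replicate_id = rep_id),
    list(table = pz$control, mito_status = "rho_zero", condition = "control_25C",
         arrest_ploidy = "none", replicate_id = rep_id),
    list(table = pz$arrested, mito_status = "rho_zero", condition = "arrested_37C",
         arrest_ploidy = "1n", replicate_id = rep_id))
}
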