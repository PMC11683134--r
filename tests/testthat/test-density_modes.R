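test_that("density estimate is a proper density and finds a Gaussian mode", {
  set.seed(11)
  x <- rnorm(10000, mean = 10, sd = 0.1)
  d <- estimate_density(x)
  expect_true(all(d$y >= 0))
  # trapezoid integral within 1% of 1
  area <- sum(diff(d$x) * (head(d$y, -1) + d$y[-1]) / 2)
  expect_equal(area, 1, tolerance = 0.01)
  p <- find_peak_modes(d)
  expect_lt(abs(p$mode_2n - 10), 0.02)
  expect_equal(p$n_modes_found, 1L)
})

test_that("degenerate and undersized inputs are rejected", {
  expect_error(estimate_density(rep(5, 500)), class = "cytomito_degenerate_error")
  expect_error(estimate_density(rnorm(50)), class = "cytomito_sample_size_error")
})

test_that("a balanced two-component mixture yields two modes one unit apart", {
  set.seed(12)
  x <- c(rnorm(5000, 10, 0.1), rnorm(5000, 11, 0.1))
  p <- find_peak_modes(estimate_density(x))
  expect_equal(p$n_modes_found, 2L)
  expect_lt(abs(p$mode_1n - 10), 0.03)
  expect_lt(abs(p$mode_2n - 11), 0.03)
  expect_true(p$mode_2n > p$mode_1n)
  expect_true(isTRUE(p$spacing_ok))
})

test_that("detected modes agree with the exhaustive local-maximum oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    x <- c(rnorm(4000, 10, 0.12), rnorm(4000, 11, 0.12))
    d <- estimate_density(x)
    oracle_x <- d$x[oracle_local_maxima(d$y)]
    p <- find_peak_modes(d)
    for (m in c(p$mode_1n, p$mode_2n)) {
      if (!is.na(m)) expect_true(m %in% oracle_x)
    }
  }
})

test_that("mode positions are gain-equivariant (additive log2 shift)", {
  set.seed(13)
  t <- generate_population(pure_spec(n = 20000L), seed = 13)
  p1 <- peaks_of(t)
  k <- 3.7
  t2 <- event_table(t$fluor_linear * k, t$fsc_linear)
  p2 <- peaks_of(t2)
  # grid positions move with the data, so agreement is to grid resolution
  expect_equal(p2$mode_2n - p1$mode_2n, log2(k), tolerance = 0.01)
})

test_that("a lone mode is labelled by the expected arrest ploidy", {
  set.seed(14)
  x <- rnorm(5000, 12, 0.1)
  p2 <- find_peak_modes(estimate_density(x), expected_ploidy = "2n")
  expect_false(is.na(p2$mode_2n))
  expect_true(is.na(p2$mode_1n))
  p1 <- find_peak_modes(estimate_density(x), expected_ploidy = "1n")
  expect_false(is.na(p1$mode_1n))
  expect_true(is.na(p1$mode_2n))
})

test_that("rho0 1n-2n spacing approaches one log2 unit as noise shrinks", {
  t <- generate_population(
    population_spec(n_events = 50000L, mito_status = "rho_zero",
                    ploidy_fractions = c(G1 = 0.5, S = 0, G2M = 0.5),
                    measurement_cv = 0.01),
    seed = 15)
  p <- peaks_of(t)
  expect_equal(p$spacing, 1, tolerance = 0.02)
})

test_that("the right-of-2n gate has a closed lower bound and caps its width", {
  t <- log2_transform(event_table(2^c(9.99, 10, 10.3, 10.6, 11.2), rep(100, 5)))
  peaks <- structure(list(mode_1n = 9, mode_2n = 10, prominence_1n = 1,
                          prominence_2n = 1, bandwidth = 0.05,
                          n_modes_found = 2L, spacing = 1, spacing_ok = TRUE),
                     class = "peak_set")
  g <- gate_right_of_2n(t, peaks, width = 0.5)
  expect_equal(g$fluor_log2, c(10, 10.3))        # 10 included: closed bound
  g_wide <- gate_right_of_2n(t, peaks, width = 5) # capped at mode + 1
  expect_equal(max(g_wide$fluor_log2), 10.6)
  peaks$mode_2n <- 12
  expect_error(gate_right_of_2n(t, peaks, width = 0.5),
               class = "cytomito_gate_error")
})

test_that("the gate captures about half of a symmetric 2n peak", {
  # the detected mode wobbles by ~0.01 log2 units per draw, which moves the
  # gated fraction by several percent; average over seeds
  frac <- vapply(16:19, function(seed) {
    t <- generate_population(pure_spec("rho_zero", n = 50000L), seed = seed)
    tt <- log2_transform(t)
    g <- gate_right_of_2n(tt, peaks_of(t), width = 1)
    nrow(g) / nrow(tt)
  }, numeric(1))
  expect_lt(abs(mean(frac) - 0.5), 0.05)
})
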