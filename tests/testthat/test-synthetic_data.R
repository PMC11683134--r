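test_that("rho0 populations carry zero mtDNA copies in their truth labels", {
  t <- generate_population(population_spec(n_events = 2000,
                                           mito_status = "rho_zero"),
                           seed = 51)
  expect_true(all(t$mtdna_copies == 0))
})

test_that("generation is reproducible: same seed, identical tables", {
  spec <- population_spec(n_events = 5000)
  a <- generate_population(spec, seed = 52)
  b <- generate_population(spec, seed = 52)
  expect_identical(as.data.frame(a), as.data.frame(b))
  pair1 <- generate_arrest_pair(arrest_spec(spec), seed = 53)
  pair2 <- generate_arrest_pair(arrest_spec(spec), seed = 53)
  expect_identical(as.data.frame(pair1$arrested), as.data.frame(pair2$arrested))
})

test_that("the noise-free signal equals its closed form", {
  spec <- pure_spec(n = 1000L, copies_mean_2n = 30.8, copies_cv = 0,
                    measurement_cv = 0, size_coupling_beta = 0)
  t <- generate_population(spec, seed = 54)
  g <- spec$genome
  # mean copies of 30.8 rounds to 31 integer copies per cell
  expect_true(all(t$mtdna_copies == 31L))
  expect_true(all(abs(t$fluor_linear -
                        spec$gain * (g$ndna_2n + 31 * g$mtdna_size)) < 1e-9))
  # matched rho0 signal differs by log2(1 + c*s/N)
  t0 <- generate_population(pure_spec("rho_zero", n = 1000L,
                                      measurement_cv = 0), seed = 55)
  shift <- log2(t$fluor_linear[1]) - log2(t0$fluor_linear[1])
  expect_equal(shift, log2(1 + 31 * g$mtdna_size / g$ndna_2n), tolerance = 1e-12)
  expect_equal(shift, 0.15, tolerance = 0.01)
})

test_that("invalid ploidy fractions are a spec error", {
  expect_error(population_spec(ploidy_fractions = c(G1 = 0.7, S = 0.2, G2M = 0.2)),
               class = "cytomito_spec_error")
  expect_error(population_spec(ploidy_fractions = c(G1 = 1.2, S = -0.2, G2M = 0)),
               class = "cytomito_spec_error")
})

test_that("pipeline shift estimate converges to the analytic contrast", {
  # E[shift] = log2(1 + c*s/N); checked at n = 200,000 under low dispersion
  n <- 200000L
  plus <- generate_population(pure_spec(n = n, copies_mean_2n = 30.8,
                                        copies_cv = 0.05, measurement_cv = 0.02),
                              seed = 56)
  zero <- generate_population(pure_spec("rho_zero", n = n,
                                        measurement_cv = 0.02), seed = 57)
  shift <- peaks_of(plus)$mode_2n - peaks_of(zero)$mode_2n
  g <- genome_params()
  expect_lt(abs(shift - log2(1 + 30.8 * g$mtdna_size / g$ndna_2n)), 0.01)
})

test_that("a background applied to both strains leaves the contrast unchanged", {
  shift_at <- function(bg) {
    p <- generate_population(pure_spec(n = 30000L,
                                       background_inflation = bg), seed = 58)
    z <- generate_population(pure_spec("rho_zero", n = 30000L,
                                       background_inflation = bg), seed = 59)
    peaks_of(p)$mode_2n - peaks_of(z)$mode_2n
  }
  # identical seeds: the background multiplies every signal, so the log2
  # contrast and hence the copy estimate are exactly unchanged
  expect_equal(shift_at(1.5), shift_at(1), tolerance = 1e-9)
})

test_that("a null arrest reproduces the control population statistics", {
  # dispersion-free stochastic walk at fold 1 is the control sampling scheme
  base <- pure_spec(n = 30000L)
  pair <- generate_arrest_pair(
    arrest_spec(base, arrest_ploidy = "2n", growth_factor = 1,
                accumulation_mode = "stochastic_walk", walk_dispersion = 0,
                accumulation_fold = 1, arrest_background_inflation = 1),
    seed = 60)
  expect_lt(abs(mean(log2(pair$arrested$fluor_linear)) -
                  mean(log2(pair$control$fluor_linear))), 0.005)
  expect_lt(abs(sd(log2(pair$arrested$fluor_linear)) -
                  sd(log2(pair$control$fluor_linear))), 0.002)
  expect_lt(abs(mean(log2(pair$arrested$fsc_linear)) -
                  mean(log2(pair$control$fsc_linear))), 0.01)
})

test_that("arrest grows cells and restricts them to the arrested ploidy", {
  pair <- generate_arrest_pair(
    arrest_spec(population_spec(n_events = 10000), arrest_ploidy = "1n",
                growth_factor = 2),
    seed = 61)
  expect_true(all(pair$arrested$ploidy_class == "G1"))
  expect_equal(mean(log2(pair$arrested$cell_size)) -
                 mean(log2(pair$control$cell_size)), 1, tolerance = 0.02)
})

test_that("size-coupled arrest keeps per-size-bin CV at the noise floor", {
  base <- pure_spec(n = 50000L, copies_cv = 0, fsc_noise_sd = 0.02,
                    measurement_cv = 0.05)
  pair <- generate_arrest_pair(
    arrest_spec(base, arrest_ploidy = "2n", accumulation_mode = "size_coupled",
                accumulation_fold = 3.3),
    seed = 62)
  p <- compute_binned_cv(log2_transform(pair$arrested), bin_width = 0.1,
                         min_events = 200)
  b <- p$bins[p$bins$qualifies, ]
  expect_true(all(abs(b$cv - 0.05) < 0.01))
})

test_that("stochastic-walk arrest makes per-bin CV grow with cell size", {
  base <- pure_spec(n = 50000L, copies_cv = 0.1, fsc_noise_sd = 0.02,
                    measurement_cv = 0.05)
  pair <- generate_arrest_pair(
    arrest_spec(base, arrest_ploidy = "2n",
                accumulation_mode = "stochastic_walk",
                accumulation_fold = 3.3, walk_dispersion = 0.4),
    seed = 63)
  p <- compute_binned_cv(log2_transform(pair$arrested), bin_width = 0.1,
                         min_events = 200)
  b <- p$bins[p$bins$qualifies, ]
  expect_gt(nrow(b), 4)
  expect_gt(cor(b$center, b$cv, method = "spearman"), 0.5)
})

test_that("truth sidecar CSV round-trips the labels", {
  t <- generate_population(population_spec(n_events = 500), seed = 64)
  path <- withr::local_tempfile(fileext = ".csv")
  write_truth_csv(t, path)
  back <- read.csv(path)
  expect_equal(back$mtdna_copies, t$mtdna_copies)
  expect_equal(back$ploidy_class, t$ploidy_class)
})
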