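test_that("plasmid bound equals its arithmetic recomputation", {
  g <- genome_params()
  expect_equal(plasmid_equivalent_copies(g), 60 * 0.0063 / 0.085)
  expect_equal(plasmid_equivalent_copies(genome_params(plasmid_max_count = 0)), 0)
  g2 <- genome_params(mtdna_size = 0.2, plasmid_unit = 0.01, plasmid_max_count = 17)
  expect_equal(plasmid_equivalent_copies(g2), 17 * 0.01 / 0.2)
})

test_that("rho-contrast copies invert the signal-doubling closed form", {
  g <- genome_params()
  # a one-unit shift means the 2n signal doubled: copies worth one diploid genome
  est <- copies_from_rho_contrast(mode_shift(1, "2n"), g)
  expect_equal(est$copies * g$mtdna_size, g$ndna_2n)
  expect_equal(copies_from_rho_contrast(mode_shift(0, "2n"), g)$copies, 0)
  # the 1n peak uses the haploid genome
  est1 <- copies_from_rho_contrast(mode_shift(1, "1n"), g)
  expect_equal(est1$copies * g$mtdna_size, g$ndna_1n)
})

test_that("copies are strictly increasing and continuous in the shift", {
  g <- genome_params()
  deltas <- seq(0, 1, by = 0.05)
  copies <- vapply(deltas, function(d)
    copies_from_rho_contrast(mode_shift(d, "2n"), g)$copies, numeric(1))
  expect_true(all(diff(copies) > 0))
  near0 <- copies_from_rho_contrast(mode_shift(1e-9, "2n"), g)$copies
  expect_lt(near0, 1e-6)
})

test_that("negative shifts are floored at zero with a warning, never silently", {
  g <- genome_params()
  expect_warning(est <- copies_from_rho_contrast(mode_shift(-0.05, "2n"), g),
                 "floored")
  expect_equal(est$copies, 0)
  expect_true(est$clamped)
})

test_that("replicate shifts aggregate as per-replicate mean and SD", {
  g <- genome_params()
  deltas <- c(0.12, 0.15, 0.18)
  est <- copies_from_rho_contrast(mode_shift(deltas, "2n"), g)
  manual <- (2^deltas - 1) * g$ndna_2n / g$mtdna_size
  expect_equal(est$per_replicate, manual)
  expect_equal(est$copies, mean(manual))
  expect_equal(est$copies_sd, sd(manual))
  expect_true(is.na(copies_from_rho_contrast(mode_shift(0.15, "2n"), g)$copies_sd))
})

test_that("equal arrest shifts give zero surplus and unit fold", {
  g <- genome_params()
  r <- arrest_surplus(mode_shift(0.25, "1n", "arrest_contrast"),
                      mode_shift(0.25, "1n", "arrest_contrast"),
                      baseline = 15.4, genome = g)
  expect_equal(r$surplus_copies, 0)
  expect_equal(r$fold_change, 1)
})

test_that("surplus is antisymmetric in the shift pair", {
  g <- genome_params()
  ms <- function(d) mode_shift(d, "2n", "arrest_contrast")
  a <- arrest_surplus(ms(0.7), ms(0.3), baseline = 30.8, genome = g)
  b <- arrest_surplus(ms(0.3), ms(0.7), baseline = 30.8, genome = g)
  expect_equal(a$surplus_copies + b$surplus_copies, 0)
})

test_that("the fold identity holds for every arrest result", {
  g <- genome_params()
  set.seed(21)
  for (i in 1:20) {
    d <- sort(runif(2, 0, 1))
    base <- runif(1, 5, 60)
    pl <- sample(c("1n", "2n"), 1)
    r <- arrest_surplus(mode_shift(d[2], pl, "arrest_contrast"),
                        mode_shift(d[1], pl, "arrest_contrast"),
                        baseline = base, genome = g)
    expect_equal(r$fold_change, 1 + r$surplus_copies / r$baseline_copies)
  }
})

test_that("mismatched peak ploidies are a contract error", {
  expect_error(
    arrest_surplus(mode_shift(0.4, "1n", "arrest_contrast"),
                   mode_shift(0.1, "2n", "arrest_contrast"), baseline = 15),
    class = "cytomito_contract_error")
})

test_that("a 2n baseline estimate is halved for a 1n arrest", {
  g <- genome_params()
  base2n <- copies_from_rho_contrast(mode_shift(0.15, "2n"), g)
  r <- arrest_surplus(mode_shift(0.4, "1n", "arrest_contrast"),
                      mode_shift(0.1, "1n", "arrest_contrast"),
                      baseline = base2n, genome = g)
  expect_equal(r$baseline_copies, base2n$copies / 2)
})

test_that("both surplus formulas recover the G1-arrest surplus from its shifts", {
  g <- genome_params()
  dp <- mode_shift(0.4, "1n", "arrest_contrast")
  dz <- mode_shift(0.1, "1n", "arrest_contrast")
  default <- arrest_surplus(dp, dz, baseline = 15.4, genome = g)
  expect_equal(default$surplus_copies,
               g$ndna_1n * (2^0.4 - 2^0.1) / g$mtdna_size)
  alt <- arrest_surplus(dp, dz, baseline = 15.4, genome = g,
                        method = "total_scaling")
  expect_equal(alt$surplus_copies,
               (g$ndna_1n + 15.4 * g$mtdna_size) * (2^0.3 - 1) / g$mtdna_size)
  # the two parameterisations agree to within a few copies here
  expect_lt(abs(alt$surplus_copies - default$surplus_copies), 3)
})
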