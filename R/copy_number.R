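#' Genome-size constants
#'
#' Constants that convert log2 fluorescence mode shifts into mtDNA copy
#' numbers. All DNA lengths are in megabases. Defaults: the 85 kb
#' S. cerevisiae mitochondrial genome, a 12.1 Mb haploid (24.2 Mb diploid)
#' nuclear genome, and the endogenous 2-micron plasmid (6.3 kb, up to about
#' 60 molecules per cell), whose maximal load bounds the bias it can add to a
#' total-DNA stain.
#'
#' @param mtdna_size mtDNA genome size, Mb.
#' @param ndna_1n Haploid nuclear genome size, Mb.
#' @param ndna_2n Diploid nuclear genome size, Mb; defaults to `2 * ndna_1n`.
#' @param plasmid_unit 2-micron plasmid size, Mb.
#' @param plasmid_max_count Maximal plasmid copies per cell.
#' @return A `genome_params` object.
#' @export
genome_params <- function(mtdna_size = 0.085, ndna_1n = 12.1,
                          ndna_2n = 2 * ndna_1n,
                          plasmid_unit = 0.0063, plasmid_max_count = 60L) {
  sizes <- c(mtdna_size, ndna_1n, ndna_2n, plasmid_unit)
  if (any(!is.finite(sizes)) || any(sizes <= 0) || plasmid_max_count < 0) {
    stop_cytomito("genome sizes must be positive and plasmid count non-negative",
                  "cytomito_contract_error")
  }
  structure(list(mtdna_size = mtdna_size, ndna_1n = ndna_1n, ndna_2n = ndna_2n,
                 plasmid_unit = plasmid_unit,
                 plasmid_max_count = as.integer(plasmid_max_count)),
            class = "genome_params")
}

ndna_for <- function(g, ploidy) {
  switch(ploidy, "1n" = g$ndna_1n, "2n" = g$ndna_2n,
         stop_cytomito(sprintf("unknown ploidy '%s'", ploidy),
                       "cytomito_contract_error"))
}

#' A log2 mode shift between two samples
#'
#' The primitive the copy-number arithmetic works on: the difference in
#' position of corresponding density modes (same ploidy peak) between two
#' samples, in log2 units. `kind` records which contrast it is: rho+ minus
#' rho0 under the same condition (`rho_contrast`), or 37 degC arrested minus
#' 25 degC control for the same strain (`arrest_contrast`). A vector of
#' deltas represents independent replicates.
#'
#' @param delta Numeric shift(s), log2 units.
#' @param ploidy Peak the shift was read from: `"1n"` or `"2n"`.
#' @param kind `"rho_contrast"` or `"arrest_contrast"`.
#' @return A `mode_shift` object.
#' @export
mode_shift <- function(delta, ploidy = c("2n", "1n"),
                       kind = c("rho_contrast", "arrest_contrast")) {
  ploidy <- match.arg(ploidy)
  kind <- match.arg(kind)
  stopifnot(is.numeric(delta), length(delta) >= 1, all(is.finite(delta)))
  structure(list(delta = as.numeric(delta), ploidy = ploidy, kind = kind),
            class = "mode_shift")
}

#' mtDNA copies from a rho+/rho0 mode shift
#'
#' In a rho0 cell the stain signal at a ploidy peak reflects nuclear DNA
#' alone (N megabases); in a rho+ cell it additionally carries c copies of
#' the s-megabase mitochondrial genome. On the log2 scale the corresponding
#' modes therefore differ by Delta = log2(1 + c*s/N), which inverts to
#'
#'   c = (2^Delta - 1) * N / s.
#'
#' With multiple replicate shifts the copy number is computed per replicate
#' and reported as mean with standard deviation (the transform is nonlinear,
#' so averaging the shifts first would bias the estimate).
#'
#' @param shift A [mode_shift()] of kind `rho_contrast`.
#' @param genome [genome_params()].
#' @return A `copy_number_estimate`: list with `copies`, `copies_sd` (NA with
#'   fewer than two replicates), `per_replicate`, `ploidy`, `basis`, and
#'   `clamped` (TRUE when a negative shift was floored at zero copies).
#' @export
copies_from_rho_contrast <- function(shift, genome = genome_params()) {
  stopifnot(inherits(shift, "mode_shift"))
  if (shift$kind != "rho_contrast") {
    stop_cytomito("copies_from_rho_contrast needs a rho_contrast shift",
                  "cytomito_contract_error")
  }
  N <- ndna_for(genome, shift$ploidy)
  per <- (2^shift$delta - 1) * N / genome$mtdna_size
  clamped <- any(per < 0)
  if (clamped) {
    warning("negative mode shift(s): copy number floored at 0", call. = FALSE)
    per <- pmax(per, 0)
  }
  structure(list(copies = mean(per),
                 copies_sd = if (length(per) >= 2) sd(per) else NA_real_,
                 per_replicate = per,
                 ploidy = shift$ploidy,
                 basis = shift,
                 clamped = clamped),
            class = "copy_number_estimate")
}

#' @export
print.copy_number_estimate <- function(x, ...) {
  sdtxt <- if (is.na(x$copies_sd)) "" else sprintf(" +/- %.1f", x$copies_sd)
  cat(sprintf("<copy_number_estimate> %.1f%s mtDNA copies per %s cell (n = %d replicate(s))\n",
              x$copies, sdtxt, x$ploidy, length(x$per_replicate)))
  invisible(x)
}

#' Upper bound on the 2-micron plasmid contribution, in mtDNA equivalents
#'
#' The endogenous 2-micron plasmid is stained like any other DNA, so a
#' maximal plasmid load inflates the apparent mtDNA copy number by at most
#' `plasmid_max_count * plasmid_unit / mtdna_size` copies.
#'
#' @param genome [genome_params()].
#' @return The bound as a plain number (about 4.45 with the defaults).
#' @export
plasmid_equivalent_copies <- function(genome = genome_params()) {
  genome$plasmid_max_count * genome$plasmid_unit / genome$mtdna_size
}

#' Fold change implied by a copy-number surplus
#'
#' @param surplus Surplus copies accumulated during arrest.
#' @param baseline Pre-arrest copies for the same ploidy.
#' @return `1 + surplus / baseline`.
#' @export
fold_from_surplus <- function(surplus, baseline) {
  stopifnot(baseline > 0)
  1 + surplus / baseline
}

#' Arrest-induced mtDNA surplus and fold change
#'
#' Cell-cycle arrest shifts the mode of the arrested-ploidy peak by delta_plus
#' log2 units in the rho+ strain but also by delta_zero in the matched rho0
#' strain, which lacks mtDNA entirely — a background increase of unidentified
#' origin. The default formula subtracts the background on the linear scale
#' of the nuclear-DNA-dominated signal:
#'
#'   surplus = N * (2^delta_plus - 2^delta_zero) / s
#'
#' The `"total_scaling"` variant instead treats the rho0 shift as a
#' multiplicative factor on the whole baseline signal including its mtDNA
#' term: surplus = (N + c0*s) * (2^(delta_plus - delta_zero) - 1) / s.
#' Vectors of replicate shifts (matched pairwise) give a mean and SD.
#'
#' @param delta_plus [mode_shift()] of kind `arrest_contrast` for the rho+
#'   strain.
#' @param delta_zero [mode_shift()] of kind `arrest_contrast` for the matched
#'   rho0 strain, same ploidy peak.
#' @param baseline Pre-arrest copy number for the arrested ploidy: a
#'   `copy_number_estimate` or a plain number. A 2n-derived estimate supplied
#'   for a 1n arrest is halved.
#' @param genome [genome_params()].
#' @param method `"background_partition"` (default) or `"total_scaling"`.
#' @return An `arrest_result`: `surplus_copies`, `surplus_sd`, `fold_change`,
#'   `delta_rho_plus`, `delta_rho_zero`, `baseline_copies`, `ploidy`,
#'   `method`, `per_replicate`.
#' @export
arrest_surplus <- function(delta_plus, delta_zero, baseline,
                           genome = genome_params(),
                           method = c("background_partition", "total_scaling")) {
  method <- match.arg(method)
  stopifnot(inherits(delta_plus, "mode_shift"), inherits(delta_zero, "mode_shift"))
  if (delta_plus$kind != "arrest_contrast" || delta_zero$kind != "arrest_contrast") {
    stop_cytomito("arrest_surplus needs arrest_contrast shifts",
                  "cytomito_contract_error")
  }
  if (delta_plus$ploidy != delta_zero$ploidy) {
    stop_cytomito(sprintf("shift ploidies differ (%s vs %s): both must be read from the same peak",
                          delta_plus$ploidy, delta_zero$ploidy),
                  "cytomito_contract_error")
  }
  if (length(delta_plus$delta) != length(delta_zero$delta)) {
    stop_cytomito("replicate shift vectors must pair up (equal lengths)",
                  "cytomito_contract_error")
  }
  ploidy <- delta_plus$ploidy
  N <- ndna_for(genome, ploidy)
  s <- genome$mtdna_size

  base_copies <- if (inherits(baseline, "copy_number_estimate")) {
    b <- baseline$copies
    if (baseline$ploidy == "2n" && ploidy == "1n") b / 2 else b
  } else {
    as.numeric(baseline)
  }
  if (!is.finite(base_copies) || base_copies <= 0) {
    stop_cytomito("baseline copy number must be positive", "cytomito_contract_error")
  }

  per <- switch(method,
    background_partition = N * (2^delta_plus$delta - 2^delta_zero$delta) / s,
    total_scaling = (N + base_copies * s) *
      (2^(delta_plus$delta - delta_zero$delta) - 1) / s)
  surplus <- mean(per)
  structure(list(surplus_copies = surplus,
                 surplus_sd = if (length(per) >= 2) sd(per) else NA_real_,
                 fold_change = fold_from_surplus(surplus, base_copies),
                 delta_rho_plus = delta_plus$delta,
                 delta_rho_zero = delta_zero$delta,
                 baseline_copies = base_copies,
                 ploidy = ploidy,
                 method = method,
                 per_replicate = per),
            class = "arrest_result")
}

#' @export
print.arrest_result <- function(x, ...) {
  sdtxt <- if (is.na(x$surplus_sd)) "" else sprintf(" +/- %.1f", x$surplus_sd)
  cat(sprintf("<arrest_result> surplus %.1f%s mtDNA copies (%s peak), fold change %.2f over baseline %.1f\n",
              x$surplus_copies, sdtxt, x$ploidy, x$fold_change, x$baseline_copies))
  invisible(x)
}
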