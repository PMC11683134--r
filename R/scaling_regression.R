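#' Regress stain signal on cell size
#'
#' Ordinary least squares of log2 fluorescence on log2 forward-scatter area
#' within a ploidy-gated subpopulation. In a proliferating population the
#' stain signal within one ploidy class is dominated by the fixed nuclear
#' genome and is nearly independent of cell size; when mtDNA accumulates in
#' proportion to cell volume (as in cell-cycle-arrested cells) the mtDNA term
#' couples signal to size and the slope rises.
#'
#' @param events A log2-transformed, gated [event_table()].
#' @param min_events Minimum number of events required for a fit (default 500).
#' @return A `size_scaling_fit`: `slope`, `slope_se`, `intercept`,
#'   `r_squared`, `n_events`, `gate` (the ploidy label of the gate, if any).
#' @export
fit_size_scaling <- function(events, min_events = 500L) {
  if (!is_transformed(events)) {
    stop_cytomito("events must be log2-transformed before fitting",
                  "cytomito_contract_error")
  }
  if (nrow(events) < min_events) {
    stop_cytomito(sprintf("need at least %d events for the size-scaling fit, got %d",
                          min_events, nrow(events)),
                  "cytomito_sample_size_error")
  }
  if (var(events$fsc_log2) == 0) {
    stop_cytomito("forward-scatter values are degenerate (zero variance)",
                  "cytomito_regression_error")
  }
  fit <- lm(fluor_log2 ~ fsc_log2, data = events)
  sm <- summary(fit)
  structure(list(slope = unname(coef(fit)[2]),
                 slope_se = unname(sm$coefficients[2, 2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = sm$r.squared,
                 n_events = nrow(events),
                 gate = attr(events, "gate_ploidy") %||% NA_character_),
            class = "size_scaling_fit")
}

#' @export
print.size_scaling_fit <- function(x, ...) {
  cat(sprintf("<size_scaling_fit> slope %.3f (se %.3f), intercept %.3f, R^2 %.3f, n = %d%s\n",
              x$slope, x$slope_se, x$intercept, x$r_squared, x$n_events,
              if (is.na(x$gate)) "" else sprintf(" (%s gate)", x$gate)))
  invisible(x)
}

#' Compare size-scaling slopes between rho+ and rho0 samples
#'
#' Reports the ratio and difference of the fluorescence-size slopes of
#' matched rho+ and rho0 fits, and flags whether the rho+ slope is at least
#' twice the rho0 slope — the qualitative signature of size-coupled mtDNA.
#' When the rho0 slope is statistically indistinguishable from zero (within
#' two standard errors) the ratio is reported as `NA` and only the difference
#' is meaningful; the two-fold flag then reduces to the rho+ slope being
#' positive.
#'
#' @param fit_rho_plus,fit_rho_zero `size_scaling_fit` objects from matched
#'   gates and conditions.
#' @return A `scaling_comparison`: `slope_ratio` (possibly `NA`),
#'   `slope_diff`, `plus_at_least_twice`, plus both input fits.
#' @export
compare_scaling <- function(fit_rho_plus, fit_rho_zero) {
  stopifnot(inherits(fit_rho_plus, "size_scaling_fit"),
            inherits(fit_rho_zero, "size_scaling_fit"))
  s0 <- fit_rho_zero$slope
  ratio <- if (abs(s0) <= 2 * fit_rho_zero$slope_se) NA_real_
           else fit_rho_plus$slope / s0
  structure(list(slope_ratio = ratio,
                 slope_diff = fit_rho_plus$slope - s0,
                 plus_at_least_twice = fit_rho_plus$slope >= 2 * s0,
                 fit_rho_plus = fit_rho_plus,
                 fit_rho_zero = fit_rho_zero),
            class = "scaling_comparison")
}

#' @export
print.scaling_comparison <- function(x, ...) {
  cat(sprintf("<scaling_comparison> slope rho+ %.3f vs rho0 %.3f: diff %.3f, ratio %s, >=2x: %s\n",
              x$fit_rho_plus$slope, x$fit_rho_zero$slope, x$slope_diff,
              if (is.na(x$slope_ratio)) "NA (rho0 slope ~ 0)" else sprintf("%.2f", x$slope_ratio),
              x$plus_at_least_twice))
  invisible(x)
}
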