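#' Coefficient of variation of stain signal within cell-size bins
#'
#' Partitions the (gated) events into contiguous half-open bins of log2
#' forward-scatter area and computes, per bin, the coefficient of variation
#' (sd/mean) of the *linear* stain signal, together with the ungated
#' population CV. Binning on size strips the size-attributable component of
#' signal variability: if per-cell mtDNA content tracks cell size, the
#' within-bin CV stays flat at the measurement-noise floor; if copies drift
#' stochastically, within-bin CV grows with size. Bins with fewer than
#' `min_events` cells are retained in the output but flagged excluded, and do
#' not enter downstream comparisons.
#'
#' @param events A log2-transformed [event_table()], typically gated to the
#'   right flank of the 2n peak (see [gate_right_of_2n()]).
#' @param bin_width Bin width in log2 FSC units (default 0.1).
#' @param min_events Minimum events for a bin to qualify (default 200).
#' @param anchor Left edge of the first bin; defaults to the minimum observed
#'   log2 FSC. Supply a common anchor when profiles must share bin edges.
#' @return A `binned_cv_profile`: tibble `bins` with columns `fsc_log2_low`,
#'   `fsc_log2_high`, `center`, `n_events`, `cv`, `qualifies`; plus
#'   `bin_width`, `min_events`, `population_cv`, `n_total`.
#' @export
compute_binned_cv <- function(events, bin_width = 0.1, min_events = 200L,
                              anchor = NULL) {
  if (!is_transformed(events)) {
    stop_cytomito("events must be log2-transformed before CV binning",
                  "cytomito_contract_error")
  }
  stopifnot(bin_width > 0, min_events >= 1)
  x <- events$fsc_log2
  lin <- events$fluor_linear
  anchor <- anchor %||% min(x)
  idx <- floor((x - anchor) / bin_width)
  inrange <- idx >= 0
  idx <- idx[inrange]; lin2 <- lin[inrange]
  cv_of <- function(v) if (length(v) >= 2) sd(v) / mean(v) else NA_real_
  tab <- tibble::tibble(idx = idx, fluor = lin2) |>
    dplyr::group_by(idx) |>
    dplyr::summarise(n_events = dplyr::n(), cv = cv_of(fluor), .groups = "drop") |>
    dplyr::arrange(idx)
  bins <- tibble::tibble(
    fsc_log2_low = anchor + tab$idx * bin_width,
    fsc_log2_high = anchor + (tab$idx + 1) * bin_width,
    center = anchor + (tab$idx + 0.5) * bin_width,
    n_events = tab$n_events,
    cv = tab$cv,
    qualifies = tab$n_events >= min_events
  )
  if (!any(bins$qualifies)) {
    warning(sprintf("no bin reaches %d events; profile has no qualifying bins",
                    min_events), call. = FALSE)
  }
  structure(list(bins = bins, bin_width = bin_width,
                 min_events = as.integer(min_events),
                 population_cv = cv_of(lin),
                 n_total = length(lin)),
            class = "binned_cv_profile")
}

#' @export
print.binned_cv_profile <- function(x, ...) {
  q <- sum(x$bins$qualifies)
  cat(sprintf("<binned_cv_profile> %d bins (%d qualifying, width %.3f log2 FSC), population CV %.4f, n = %d\n",
              nrow(x$bins), q, x$bin_width, x$population_cv, x$n_total))
  print(x$bins[x$bins$qualifies, ])
  invisible(x)
}

qualifying_bins <- function(p) p$bins[p$bins$qualifies, , drop = FALSE]

# slope (and its se) of cv on bin center across qualifying bins
cv_size_trend <- function(p) {
  b <- qualifying_bins(p)
  if (nrow(b) < 3) {
    return(list(slope = NA_real_, slope_se = NA_real_, n_bins = nrow(b)))
  }
  fit <- summary(lm(cv ~ center, data = b))
  list(slope = unname(fit$coefficients[2, 1]),
       slope_se = unname(fit$coefficients[2, 2]),
       n_bins = nrow(b))
}

#' Compare binned CV profiles of arrested and control samples
#'
#' Matches qualifying bins of the two profiles by center (within half a bin
#' width), reports the per-shared-bin CV difference (arrested minus control),
#' the linear trend of CV on bin center for each profile, and a flag per
#' profile for "CV does not increase with cell size" (trend slope not above
#' its standard error).
#'
#' @param arrested,control `binned_cv_profile` objects.
#' @return A `cv_comparison`: tibble `shared_bins` (center, cv_arrested,
#'   cv_control, cv_diff), `trend_arrested`, `trend_control`,
#'   `flat_arrested`, `flat_control`.
#' @export
compare_cv_profiles <- function(arrested, control) {
  stopifnot(inherits(arrested, "binned_cv_profile"),
            inherits(control, "binned_cv_profile"))
  a <- qualifying_bins(arrested)
  c0 <- qualifying_bins(control)
  tol <- min(arrested$bin_width, control$bin_width) / 2
  match_idx <- vapply(a$center, function(ac) {
    j <- which(abs(c0$center - ac) < tol)
    if (length(j)) j[1] else NA_integer_
  }, integer(1))
  keep <- !is.na(match_idx)
  if (!any(keep)) {
    stop_cytomito("profiles share no qualifying size bins", "cytomito_comparison_error")
  }
  shared <- tibble::tibble(center = a$center[keep],
                           cv_arrested = a$cv[keep],
                           cv_control = c0$cv[match_idx[keep]],
                           cv_diff = a$cv[keep] - c0$cv[match_idx[keep]])
  ta <- cv_size_trend(arrested)
  tc <- cv_size_trend(control)
  is_flat <- function(tr) !is.na(tr$slope) && tr$slope <= tr$slope_se
  structure(list(shared_bins = shared,
                 trend_arrested = ta, trend_control = tc,
                 flat_arrested = if (is.na(ta$slope)) NA else is_flat(ta),
                 flat_control = if (is.na(tc$slope)) NA else is_flat(tc)),
            class = "cv_comparison")
}

#' @export
print.cv_comparison <- function(x, ...) {
  cat(sprintf("<cv_comparison> %d shared bins, mean CV difference (arrested - control) %.4f\n",
              nrow(x$shared_bins), mean(x$shared_bins$cv_diff)))
  cat(sprintf("  arrested CV-size trend: slope %.4g (flat: %s); control: slope %.4g (flat: %s)\n",
              x$trend_arrested$slope, x$flat_arrested,
              x$trend_control$slope, x$flat_control))
  invisible(x)
}

#' Write a binned CV profile as CSV
#'
#' Columns: `bin_low`, `bin_high`, `n`, `cv`, `qualifies`.
#'
#' @param profile A `binned_cv_profile`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_cv_profile_csv <- function(profile, path) {
  out <- data.frame(bin_low = profile$bins$fsc_log2_low,
                    bin_high = profile$bins$fsc_log2_high,
                    n = profile$bins$n_events,
                    cv = profile$bins$cv,
                    qualifies = profile$bins$qualifies)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
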