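#' Kernel density estimate of a log2 signal
#'
#' Gaussian kernel density on a fixed grid, used to locate the 1n and 2n modes
#' of a DNA-content histogram. The default bandwidth is Silverman's
#' rule-of-thumb on the supplied values; the grid spans the data range plus
#' three bandwidths on each side.
#'
#' @param values Numeric vector of log2-transformed signals (at least 100).
#' @param bandwidth Positive bandwidth in log2 units, or `NULL` for
#'   Silverman's rule.
#' @param n_grid Number of grid points (default 1024).
#' @return A `density_profile` object: list with `x`, `y`, `bandwidth`, `n`.
#' @export
estimate_density <- function(values, bandwidth = NULL, n_grid = 1024L) {
  values <- values[is.finite(values)]
  if (length(values) < 100) {
    stop_cytomito(sprintf("need at least 100 values for density estimation, got %d",
                          length(values)),
                  "cytomito_sample_size_error")
  }
  if (diff(range(values)) == 0) {
    stop_cytomito("degenerate input: all values identical, density is a point mass",
                  "cytomito_degenerate_error")
  }
  bw <- bandwidth %||% bw.nrd0(values)
  if (!is.finite(bw) || bw <= 0) {
    stop_cytomito("bandwidth must be a positive number", "cytomito_contract_error")
  }
  d <- density(values, bw = bw, kernel = "gaussian", n = n_grid,
               from = min(values) - 3 * bw, to = max(values) + 3 * bw)
  structure(list(x = d$x, y = d$y, bandwidth = bw, n = length(values)),
            class = "density_profile")
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("<density_profile> %d values, bandwidth %.4f, grid %d points on [%.3f, %.3f]\n",
              x$n, x$bandwidth, length(x$x), min(x$x), max(x$x)))
  invisible(x)
}

# indices of local maxima of y (strict rise, non-strict fall handles plateaus)
local_maxima <- function(y) {
  n <- length(y)
  if (n < 3) return(integer())
  which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
}

# topographic prominence: height minus the higher of the two valley floors
# separating the peak from higher ground (or from the grid edge)
peak_prominence <- function(y, peaks) {
  vapply(peaks, function(p) {
    left <- y[seq_len(p - 1)]
    higher_l <- which(left > y[p])
    base_l <- if (length(higher_l)) min(y[(max(higher_l) + 1):p]) else min(c(left, y[p]))
    right <- y[seq(p + 1, length(y))]
    higher_r <- which(right > y[p])
    base_r <- if (length(higher_r)) min(y[p:(p + min(higher_r) - 1)]) else min(c(right, y[p]))
    y[p] - max(base_l, base_r)
  }, numeric(1))
}

#' Locate 1n and 2n density modes
#'
#' Finds local maxima of a density profile, keeps those whose topographic
#' prominence is at least `min_prominence` of the global density maximum, and
#' labels the best pair of modes 1n (lower position) and 2n (higher). A pair
#' is accepted when its spacing is within `spacing_tol` of one log2 unit —
#' the spacing of pure nuclear-DNA peaks; mtDNA signal shared by both peaks
#' compresses the observed gap somewhat below 1, hence the tolerance. With a
#' single qualifying mode the label follows `expected_ploidy` (`"2n"` for an
#' exponentially growing sample whose 1n peak is often not resolvable).
#'
#' @param profile A `density_profile` from [estimate_density()].
#' @param max_modes Maximum number of modes returned (default 2).
#' @param min_prominence Minimum prominence as a fraction of the global
#'   density maximum (default 0.05).
#' @param expected_ploidy Label for a lone mode: `"2n"` (default), `"1n"`, or
#'   `"none"` (treated as `"2n"`).
#' @param spacing_tol Acceptable deviation of a 1n-2n pair spacing from one
#'   log2 unit (default 0.25).
#' @return A `peak_set`: list with `mode_1n` (may be `NA`), `mode_2n` (may be
#'   `NA`), `prominence_1n`, `prominence_2n`, `bandwidth`, `n_modes_found`,
#'   `spacing` and `spacing_ok`.
#' @export
find_peak_modes <- function(profile, max_modes = 2L, min_prominence = 0.05,
                            expected_ploidy = c("2n", "1n", "none"),
                            spacing_tol = 0.25) {
  expected_ploidy <- match.arg(expected_ploidy)
  y <- profile$y
  peaks <- local_maxima(y)
  if (length(peaks) == 0) {
    stop_cytomito("no local maximum found in density profile",
                  "cytomito_peak_error", data = list(profile = profile))
  }
  prom <- peak_prominence(y, peaks)
  qual <- prom >= min_prominence * max(y)
  if (!any(qual)) {
    stop_cytomito(sprintf("no mode reaches the prominence threshold (%.0f%% of max density)",
                          100 * min_prominence),
                  "cytomito_peak_error", data = list(profile = profile))
  }
  peaks <- peaks[qual]; prom <- prom[qual]
  px <- profile$x[peaks]

  res <- list(mode_1n = NA_real_, mode_2n = NA_real_,
              prominence_1n = NA_real_, prominence_2n = NA_real_,
              bandwidth = profile$bandwidth, n_modes_found = length(peaks),
              spacing = NA_real_, spacing_ok = NA)
  pick_pair <- NULL
  if (length(peaks) >= 2 && max_modes >= 2) {
    pairs <- utils::combn(seq_along(peaks), 2)
    score <- prom[pairs[1, ]] + prom[pairs[2, ]]
    gap <- abs(px[pairs[2, ]] - px[pairs[1, ]])
    ok <- abs(gap - 1) <= spacing_tol
    if (any(ok)) {
      cand <- which(ok)
      # most prominent pair; near-ties broken by spacing closest to 1 unit
      best <- cand[order(-score[cand], abs(gap[cand] - 1))][1]
      pick_pair <- pairs[, best]
    }
  }
  if (!is.null(pick_pair)) {
    lo <- pick_pair[which.min(px[pick_pair])]
    hi <- pick_pair[which.max(px[pick_pair])]
    res$mode_1n <- px[lo]; res$prominence_1n <- prom[lo]
    res$mode_2n <- px[hi]; res$prominence_2n <- prom[hi]
    res$spacing <- px[hi] - px[lo]
    res$spacing_ok <- abs(res$spacing - 1) <= spacing_tol
  } else {
    top <- which.max(prom)
    if (expected_ploidy == "1n") {
      res$mode_1n <- px[top]; res$prominence_1n <- prom[top]
    } else {
      res$mode_2n <- px[top]; res$prominence_2n <- prom[top]
    }
    res$n_modes_found <- 1L
  }
  structure(res, class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  f <- function(v) if (is.na(v)) "absent" else sprintf("%.3f", v)
  cat(sprintf("<peak_set> mode_1n = %s, mode_2n = %s (%d mode(s), bw %.4f)\n",
              f(x$mode_1n), f(x$mode_2n), x$n_modes_found, x$bandwidth))
  if (!is.na(x$spacing)) {
    cat(sprintf("  1n-2n spacing %.3f log2 units (%s)\n", x$spacing,
                if (isTRUE(x$spacing_ok)) "ok" else "outside tolerance"))
  }
  invisible(x)
}

#' Gate events on the right flank of the 2n peak
#'
#' Selects events whose log2 fluorescence lies in `[mode_2n, mode_2n + width]`
#' (closed lower bound). Restricting the variability analysis to the right
#' part of the 2n peak removes the nuclear-DNA heterogeneity of an
#' asynchronous population: every gated cell carries fully duplicated
#' chromosomes, so remaining signal variation reflects mtDNA content and
#' noise. `width` is capped at one log2 unit so that putative 4n/doublet
#' signal stays outside the gate.
#'
#' @param t A log2-transformed [event_table()].
#' @param peaks A `peak_set` with `mode_2n` present.
#' @param width Gate width in log2 units above the 2n mode (default 0.5,
#'   capped at 1).
#' @return The gated `event_table` (attribute `gate` records the bounds).
#' @export
gate_right_of_2n <- function(t, peaks, width = 0.5) {
  if (!is_transformed(t)) {
    stop_cytomito("events must be log2-transformed before gating",
                  "cytomito_contract_error")
  }
  if (is.na(peaks$mode_2n)) {
    stop_cytomito("peak set has no 2n mode; cannot gate", "cytomito_gate_error")
  }
  width <- min(width, 1)
  lower <- peaks$mode_2n
  upper <- peaks$mode_2n + width
  keep <- t$fluor_log2 >= lower & t$fluor_log2 <= upper
  if (!any(keep)) {
    stop_cytomito(sprintf("empty gate: no events in [%.3f, %.3f]", lower, upper),
                  "cytomito_gate_error")
  }
  out <- subset_events(t, keep)
  attr(out, "gate") <- c(lower = lower, upper = upper)
  out
}

#' Gate events around a ploidy peak
#'
#' Selects events within `halfwidth` log2 units of the named ploidy mode;
#' used to pick "1n cells" or "2n cells" for the fluorescence-size regression.
#'
#' @param t A log2-transformed [event_table()].
#' @param peaks A `peak_set`.
#' @param ploidy `"1n"` or `"2n"`.
#' @param halfwidth Half-width of the gate in log2 units (default 0.25).
#' @return The gated `event_table`.
#' @export
gate_ploidy <- function(t, peaks, ploidy = c("2n", "1n"), halfwidth = 0.25) {
  ploidy <- match.arg(ploidy)
  centre <- if (ploidy == "1n") peaks$mode_1n else peaks$mode_2n
  if (is.na(centre)) {
    stop_cytomito(sprintf("peak set has no %s mode; cannot gate", ploidy),
                  "cytomito_gate_error")
  }
  keep <- abs(t$fluor_log2 - centre) <= halfwidth
  if (!any(keep)) {
    stop_cytomito("empty ploidy gate", "cytomito_gate_error")
  }
  out <- subset_events(t, keep)
  attr(out, "gate") <- c(lower = centre - halfwidth, upper = centre + halfwidth)
  attr(out, "gate_ploidy") <- ploidy
  out
}
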