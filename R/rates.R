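#' Construct a concentration time series
#'
#' @param time numeric vector of times in hours, strictly increasing.
#' @param concentration numeric vector of concentrations in g/L, >= 0.
#' @param substrate substrate name.
#' @param strain strain name.
#' @return an object of class `time_series`.
#' @export
time_series <- function(time, concentration, substrate = "substrate",
                        strain = "strain") {
  stopifnot(length(time) == length(concentration), length(time) >= 2L)
  if (any(diff(time) <= 0)) stop("times must be strictly increasing",
                                 call. = FALSE)
  if (any(concentration < 0)) stop("concentrations must be >= 0",
                                   call. = FALSE)
  structure(list(substrate = substrate, strain = strain,
                 time = as.numeric(time),
                 concentration = as.numeric(concentration)),
            class = "time_series")
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("<time_series> %s / %s: %d points, %g-%g h\n",
              x$strain, x$substrate, length(x$time),
              min(x$time), max(x$time)))
  invisible(x)
}

#' Fit a substrate consumption rate
#'
#' Ordinary least squares of concentration on time over a window.  The rate
#' is the negated slope, reported as a positive consumption magnitude in
#' g/L/h; a non-negative slope yields rate 0 with a warning.  By default the
#' window is the full series truncated before the first observation at or
#' below 0 g/L, since post-depletion zeros would bias the rate downward.
#' R-squared is the squared Pearson correlation of the fitted points.
#'
#' @param series a [time_series()].
#' @param window optional `c(t_start, t_end)` in hours.
#' @return an object of class `rate_fit`: `rate`, `intercept`, `r_squared`,
#'   `window`, `n_points`, plus `substrate` and `strain`.
#' @examples
#' ts <- time_series(seq(0, 20, 2), 10 - 0.22 * seq(0, 20, 2))
#' fit_rate(ts)
#' @export
fit_rate <- function(series, window = NULL) {
  stopifnot(inherits(series, "time_series"))
  t <- series$time; c_ <- series$concentration
  if (is.null(window)) {
    depleted <- which(c_ <= 0)
    if (length(depleted) > 0L) {
      keep <- seq_len(depleted[[1]] - 1L)
    } else keep <- seq_along(t)
  } else {
    stopifnot(length(window) == 2L, window[1] < window[2])
    keep <- which(t >= window[1] & t <= window[2])
  }
  if (length(keep) < 2L) stop("fewer than 2 points in fitting window",
                              call. = FALSE)
  tw <- t[keep]; cw <- c_[keep]
  if (stats::var(tw) == 0) stop("zero time variance in window", call. = FALSE)
  slope <- stats::cov(tw, cw) / stats::var(tw)
  intercept <- mean(cw) - slope * mean(tw)
  r2 <- if (stats::var(cw) == 0) {
    warning("constant concentrations: rate 0, R-squared undefined (reported 0)")
    0
  } else stats::cor(tw, cw)^2
  rate <- -slope
  if (rate < 0) {
    warning("positive concentration slope; consumption rate reported as 0")
    rate <- 0
  }
  structure(list(rate = rate, intercept = intercept, r_squared = r2,
                 window = c(min(tw), max(tw)), n_points = length(keep),
                 substrate = series$substrate, strain = series$strain),
            class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("<rate_fit> %s / %s: %.3g g/L/h (R2 = %.2f, n = %d, %g-%g h)\n",
              x$strain, x$substrate, x$rate, x$r_squared, x$n_points,
              x$window[1], x$window[2]))
  invisible(x)
}

#' Two-regime consumption rates around a breakpoint
#'
#' Fits independent rates before and after a breakpoint (for example the
#' 22-h diauxic shift when co-substrates run out).  A point sampled exactly
#' at the breakpoint belongs to both windows.
#'
#' @param series a [time_series()].
#' @param breakpoint time in hours; must leave >= 2 points on each side.
#' @return list with elements `before` and `after`, both [fit_rate()]
#'   results.
#' @export
segmented_rates <- function(series, breakpoint) {
  stopifnot(inherits(series, "time_series"))
  t <- series$time
  if (breakpoint <= min(t) || breakpoint >= max(t)) {
    stop("breakpoint outside the sampled time range", call. = FALSE)
  }
  if (sum(t <= breakpoint) < 2L) {
    stop("fewer than 2 points before the breakpoint", call. = FALSE)
  }
  if (sum(t >= breakpoint) < 2L) {
    stop("fewer than 2 points after the breakpoint", call. = FALSE)
  }
  list(before = fit_rate(series, window = c(min(t), breakpoint)),
       after = fit_rate(series, window = c(breakpoint, max(t))))
}

# Round half away from zero to a number of significant figures.
signif_half_up <- function(x, sig_figs) {
  if (x == 0) return(0)
  f <- 10^(sig_figs - 1 - floor(log10(abs(x))))
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Mutant-to-reference rate ratio
#'
#' The ratio of a mutant strain's consumption rate to the reference
#' strain's, stored unrounded, with a display value rounded half away from
#' zero to the requested significant figures (matching how such ratios are
#' printed in strain-panel tables).
#'
#' @param mutant,reference [fit_rate()] results (or numbers); the reference
#'   rate must be positive.
#' @param sig_figs significant figures for the rounded ratio (default 2).
#' @return an object of class `rate_ratio`: `mutant_rate`,
#'   `reference_rate`, `ratio` (unrounded), `ratio_rounded`, `sig_figs`.
#' @export
rate_ratio <- function(mutant, reference, sig_figs = 2L) {
  mrate <- if (inherits(mutant, "rate_fit")) mutant$rate else as.numeric(mutant)
  rrate <- if (inherits(reference, "rate_fit")) reference$rate else
    as.numeric(reference)
  if (!(rrate > 0)) stop("reference rate must be positive", call. = FALSE)
  ratio <- mrate / rrate
  structure(list(mutant_rate = mrate, reference_rate = rrate, ratio = ratio,
                 ratio_rounded = signif_half_up(ratio, sig_figs),
                 sig_figs = as.integer(sig_figs)),
            class = "rate_ratio")
}

#' @export
print.rate_ratio <- function(x, ...) {
  cat(sprintf("<rate_ratio> %.4g / %.4g = %.6g (rounded %g)\n",
              x$mutant_rate, x$reference_rate, x$ratio, x$ratio_rounded))
  invisible(x)
}

#' Strain-by-substrate rate table
#'
#' Assembles fitted rates into one row per strain with a (rate, ratio, R2)
#' column triple per substrate, ratios taken against the reference strain
#' (whose own ratios are exactly 1).
#'
#' @param fits list of [fit_rate()] results carrying `strain` and
#'   `substrate` fields.
#' @param reference_strain name of the reference strain; it must have a fit
#'   with positive rate for every substrate present.
#' @param sig_figs significant figures for the printed ratios.
#' @return data frame, one row per strain, columns
#'   `<substrate>_rate`, `<substrate>_ratio`, `<substrate>_r2`.
#' @export
rate_table <- function(fits, reference_strain, sig_figs = 2L) {
  strains <- unique(vapply(fits, `[[`, "", "strain"))
  substrates <- unique(vapply(fits, `[[`, "", "substrate"))
  find <- function(st, su) {
    for (f in fits) if (f$strain == st && f$substrate == su) return(f)
    NULL
  }
  for (su in substrates) {
    ref <- find(reference_strain, su)
    if (is.null(ref)) {
      stop(sprintf("missing reference fit for substrate '%s'", su),
           call. = FALSE)
    }
    if (!(ref$rate > 0)) {
      stop(sprintf("reference rate for substrate '%s' is zero", su),
           call. = FALSE)
    }
  }
  out <- data.frame(strain = strains, stringsAsFactors = FALSE)
  for (su in substrates) {
    rates <- ratios <- r2s <- rep(NA_real_, length(strains))
    ref <- find(reference_strain, su)
    for (i in seq_along(strains)) {
      f <- find(strains[[i]], su)
      if (is.null(f)) next
      rates[[i]] <- f$rate
      r2s[[i]] <- f$r_squared
      ratios[[i]] <- if (strains[[i]] == reference_strain) 1 else
        rate_ratio(f, ref, sig_figs)$ratio_rounded
    }
    out[[paste0(su, "_rate")]] <- rates
    out[[paste0(su, "_ratio")]] <- ratios
    out[[paste0(su, "_r2")]] <- r2s
  }
  out
}
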