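#' Kinetic titer series
#'
#' A replicated time series of plaque/phage counts: free-phage titers over
#' time for adsorption assays, or PFU counts over time for one-step growth
#' experiments.
#'
#' @param times minutes, strictly increasing, at least 3 points.
#' @param values PFU/ml (or plaque counts), non-negative.
#' @param replicate_id identifier of the replicate.
#' @return data.frame of class `kinetic_series` with columns `time`,
#'   `value`, `replicate_id`.
#' @export
kinetic_series <- function(times, values, replicate_id = "rep1") {
  stopifnot(length(times) == length(values), length(times) >= 3L)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(values < 0)) stop("values must be non-negative")
  out <- data.frame(time = as.numeric(times), value = as.numeric(values),
                    replicate_id = replicate_id, stringsAsFactors = FALSE)
  class(out) <- c("kinetic_series", "data.frame")
  out
}

#' Read kinetic series from CSV
#'
#' Expects columns `time`, `value`, `replicate` (header required).
#'
#' @param path CSV path.
#' @return named list of [kinetic_series()], one per replicate.
#' @export
read_kinetic_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("time", "value", "replicate") %in% names(tab)))
  lapply(split(tab, tab$replicate), function(d) {
    d <- d[order(d$time), ]
    kinetic_series(d$time, d$value, replicate_id = d$replicate[1L])
  })
}

#' Adsorption kinetics: free-phage fraction and first-order rate
#'
#' The free fraction at each time point is the measured free-phage titer
#' divided by the input titer. The adsorption rate constant is estimated
#' by least squares on ln(fraction) versus time over the points with a
#' positive fraction, and reported as a positive first-order constant per
#' minute together with the regression R-squared. Fractions above 1
#' (counting noise) are retained with a warning.
#'
#' @param series a [kinetic_series()] of free-phage titers.
#' @param input_titer input phage titer, PFU/ml (> 0).
#' @return object of class `adsorption_fit`: list with `fractions`
#'   (data.frame `time`, `fraction`), `rate` (per minute), `r_squared`,
#'   `n_points_fit`.
#' @export
adsorption_kinetics <- function(series, input_titer) {
  stopifnot(inherits(series, "kinetic_series"), input_titer > 0)
  if (all(series$value == 0))
    stop("all free-phage counts are zero: no free phage measured")
  frac <- series$value / input_titer
  if (any(frac > 1))
    warning(sum(frac > 1), " point(s) with free fraction > 1 retained ",
            "(counting noise)")
  keep <- frac > 0
  if (sum(keep) < 2L)
    stop("fewer than 2 positive-fraction points: cannot fit a rate")
  fit <- stats::lm(log(frac[keep]) ~ series$time[keep])
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(fractions = data.frame(time = series$time,
                                        fraction = frac),
                 rate = -unname(stats::coef(fit)[2L]),
                 r_squared = if (is.nan(r2)) 1 else r2,
                 n_points_fit = sum(keep)),
            class = "adsorption_fit")
}

#' @export
print.adsorption_fit <- function(x, ...) {
  cat(sprintf("Adsorption fit: k = %.4g /min (R^2 = %.3f, %d points)\n",
              x$rate, x$r_squared, x$n_points_fit))
  invisible(x)
}

#' One-step growth analysis: burst size and latent period
#'
#' Replicates (which must share one time grid; interpolation is refused)
#' are averaged, then:
#'
#' * the rise index is the first time point whose averaged count exceeds
#'   `rise_factor` times the running baseline (the mean of all earlier
#'   points);
#' * the baseline is the mean of the averaged counts before the rise
#'   (the infection-center level);
#' * the first plateau is the earliest maximal run of at least 2
#'   consecutive post-rise points whose relative spread
#'   (max - min) / mean is within `plateau_tol`;
#' * burst size = plateau mean / baseline mean;
#' * latent period = time of the last pre-rise point plus the adsorption
#'   duration.
#'
#' @param series a [kinetic_series()] or list of replicate series.
#' @param adsorption_duration minutes of adsorption before time zero of
#'   the sampling clock.
#' @param rise_factor multiple of the running baseline that defines the
#'   rise (>= 1, default 2).
#' @param plateau_tol relative spread tolerated within a plateau
#'   (default 0.15).
#' @return object of class `one_step_fit`: list with `burst_size`,
#'   `latent_period` (minutes), `baseline`, `plateau_mean`, `rise_index`,
#'   `plateau_window` (times), `mean_curve`.
#' @export
one_step_growth <- function(series, adsorption_duration, rise_factor = 2,
                            plateau_tol = 0.15) {
  if (inherits(series, "kinetic_series")) series <- list(series)
  stopifnot(length(series) >= 1L, rise_factor >= 1)
  grid <- series[[1L]]$time
  for (s in series) {
    stopifnot(inherits(s, "kinetic_series"))
    if (!isTRUE(all.equal(s$time, grid)))
      stop("replicates do not share a time grid; interpolation is refused")
  }
  avg <- rowMeans(do.call(cbind, lapply(series, `[[`, "value")))
  n <- length(avg)

  rise_idx <- NA_integer_
  for (i in 2:n) {
    run_base <- mean(avg[seq_len(i - 1L)])
    if (avg[i] > rise_factor * run_base) { rise_idx <- i; break }
  }
  if (is.na(rise_idx))
    stop("no burst observed: no point exceeds ", rise_factor,
         " x the running baseline")
  if (rise_idx < 3L)
    stop("need at least 2 points before the rise (rise at index ",
         rise_idx, ")")
  baseline <- mean(avg[seq_len(rise_idx - 1L)])

  # earliest maximal run of >=2 post-rise points within plateau_tol spread
  post <- rise_idx:n
  plateau <- NULL
  i <- 1L
  while (i < length(post)) {
    j <- i + 1L
    while (j <= length(post)) {
      w <- avg[post[i:j]]
      if ((max(w) - min(w)) / mean(w) <= plateau_tol) j <- j + 1L else break
    }
    if (j - 1L > i) { plateau <- post[i:(j - 1L)]; break }
    i <- i + 1L
  }
  if (is.null(plateau))
    stop("no plateau detected after the rise (tolerance ", plateau_tol,
         "); post-rise counts: ", paste(signif(avg[post], 3),
                                        collapse = ", "))
  structure(list(burst_size = mean(avg[plateau]) / baseline,
                 latent_period = grid[rise_idx - 1L] + adsorption_duration,
                 baseline = baseline, plateau_mean = mean(avg[plateau]),
                 rise_index = rise_idx,
                 plateau_window = grid[plateau],
                 mean_curve = data.frame(time = grid, value = avg)),
            class = "one_step_fit")
}

#' @export
print.one_step_fit <- function(x, ...) {
  cat(sprintf(paste0("One-step growth: burst size = %.3g particles/cell, ",
                     "latent period = %.3g min\n"),
              x$burst_size, x$latent_period))
  cat(sprintf("  baseline = %.3g, plateau = %.3g over t = [%g, %g] min\n",
              x$baseline, x$plateau_mean, min(x$plateau_window),
              max(x$plateau_window)))
  invisible(x)
}
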