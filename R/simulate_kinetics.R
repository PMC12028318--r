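#' Simulate adsorption and one-step growth curves with known truth
#'
#' Growth curves sit at the baseline infection-center level until the end
#' of the latent period, rise over one sampling interval, and plateau at
#' baseline x burst; multiplicative lognormal noise is applied per point.
#' Adsorption curves are exponential free-phage decay from the input titer.
#' With `noise_sd = 0` the curves are exact, so [one_step_growth()] and
#' [adsorption_kinetics()] recover burst size, latent period and
#' adsorption rate identically (a round-trip identity used throughout the
#' test suite).
#'
#' @param burst burst size, particles per infected cell (> 1).
#' @param latent latent period, minutes; `latent - adsorption_duration`
#'   must lie within the growth time grid.
#' @param adsorption_rate first-order adsorption constant, per minute.
#' @param noise_sd sdlog of the multiplicative lognormal noise
#'   (0.1 ~ 10% noise).
#' @param time_grid sampling times for the growth curves, minutes.
#' @param n_replicates number of replicate curves (default 4).
#' @param seed integer seed.
#' @param adsorption_duration minutes of adsorption preceding the growth
#'   sampling clock (default 5).
#' @param baseline infection-center plaque count at time zero.
#' @param input_titer input phage titer for the adsorption assay, PFU/ml.
#' @param adsorption_grid sampling times for the adsorption curves.
#' @return list with `growth` (list of [kinetic_series()]), `adsorption`
#'   (list of [kinetic_series()]), `input_titer`, `adsorption_duration`
#'   and `truth` (burst, latent, adsorption_rate, baseline, seed).
#' @export
simulate_kinetics <- function(burst = 38, latent = 35,
                              adsorption_rate = 0.5, noise_sd = 0.1,
                              time_grid = seq(0, 90, by = 10),
                              n_replicates = 4, seed = 1,
                              adsorption_duration = 5, baseline = 10,
                              input_titer = 1e7,
                              adsorption_grid = 0:10) {
  stopifnot(burst > 1, adsorption_rate >= 0, baseline > 0)
  t0 <- latent - adsorption_duration
  if (t0 < min(time_grid) || t0 >= max(time_grid))
    stop("latent period lies beyond the time grid")
  set.seed(seed)

  dt <- min(diff(time_grid))
  plateau <- baseline * burst
  truth_curve <- vapply(time_grid, function(t) {
    if (t <= t0) baseline
    else if (t >= t0 + 2 * dt) plateau
    else sqrt(baseline * plateau)   # geometric midpoint during the rise
  }, 0)
  growth <- lapply(seq_len(n_replicates), function(r) {
    noise <- if (noise_sd > 0)
      stats::rlnorm(length(time_grid), 0, noise_sd) else 1
    kinetic_series(time_grid, truth_curve * noise,
                   replicate_id = sprintf("growth_rep%d", r))
  })
  ads_curve <- input_titer * exp(-adsorption_rate * adsorption_grid)
  adsorption <- lapply(seq_len(n_replicates), function(r) {
    noise <- if (noise_sd > 0)
      stats::rlnorm(length(adsorption_grid), 0, noise_sd) else 1
    kinetic_series(adsorption_grid, ads_curve * noise,
                   replicate_id = sprintf("ads_rep%d", r))
  })
  list(growth = growth, adsorption = adsorption,
       input_titer = input_titer,
       adsorption_duration = adsorption_duration,
       truth = list(burst = burst, latent = latent,
                    adsorption_rate = adsorption_rate,
                    baseline = baseline, seed = seed))
}

#' Write kinetic series to CSV
#'
#' Emits the `time`, `value`, `replicate` layout read by
#' [read_kinetic_csv()].
#'
#' @param series list of [kinetic_series()].
#' @param path output CSV path.
#' @export
write_kinetic_csv <- function(series, path) {
  tab <- do.call(rbind, lapply(series, function(s)
    data.frame(time = s$time, value = s$value,
               replicate = s$replicate_id, stringsAsFactors = FALSE)))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
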