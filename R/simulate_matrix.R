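#' Simulate a modular cross-infection titer matrix with known truth
#'
#' Emulates the structure of a phage x host cross-infection assay over a
#' modular network: a minority of specialist phages that infect very few
#' hosts at high titer, generalist phages that infect every susceptible
#' host, and three host classes -- `resistant` (no positive titer at all),
#' `slightly_susceptible` (a minority of phages infect) and `susceptible`
#' (all generalists infect). Log10 titers are drawn normally around
#' class-specific means and clipped to the observable range
#' \[10^2, 10^8\] PFU/ml.
#'
#' @param n_phages,n_hosts matrix dimensions (each >= 2).
#' @param frac_specialists fraction of phages that are specialists.
#' @param class_mix named fractions of `resistant`,
#'   `slightly_susceptible` and `susceptible` hosts (must sum to 1).
#' @param noise_sd standard deviation of log10-titer noise (log10 units).
#' @param seed integer seed; the output is deterministic given the seed.
#' @param impaired_frac fraction of the resistant hosts' cells recorded as
#'   `impaired` rather than `resistant` (adsorption without productive
#'   infection; scored identically).
#' @return list with `matrix` (a [titer_matrix()]) and `truth` (list:
#'   `archetype` per phage, `class` per host, `log_titer_means`, `seed`).
#' @export
simulate_infection_matrix <- function(n_phages = 18, n_hosts = 157,
                                      frac_specialists = 3 / 18,
                                      class_mix = c(resistant = 0.35,
                                                    slightly_susceptible = 0.30,
                                                    susceptible = 0.35),
                                      noise_sd = 0.3, seed = 1,
                                      impaired_frac = 0.2) {
  stopifnot(n_phages >= 2, n_hosts >= 2,
            frac_specialists >= 0, frac_specialists <= 1)
  stopifnot(setequal(names(class_mix),
                     c("resistant", "slightly_susceptible", "susceptible")),
            abs(sum(class_mix) - 1) < 1e-8)
  set.seed(seed)

  n_spec <- round(n_phages * frac_specialists)
  archetype <- rep("generalist", n_phages)
  if (n_spec > 0) archetype[seq_len(n_spec)] <- "specialist"
  phage_ids <- sprintf("P%02d", seq_len(n_phages))
  names(archetype) <- phage_ids

  counts <- round(n_hosts * class_mix)
  counts[3L] <- n_hosts - sum(counts[1:2])
  requested <- class_mix > 0
  if (any(requested & counts[names(class_mix)] == 0))
    stop("degenerate class_mix: a requested class has expected size 0")
  cls <- rep(names(class_mix), counts[names(class_mix)])
  cls <- sample(cls)
  host_ids <- sprintf("H%03d", seq_len(n_hosts))
  names(cls) <- host_ids

  mu <- c(generalist_on_susceptible = 6, generalist_on_slight = 5,
          specialist_on_home = 8)
  values <- matrix(NA_real_, n_phages, n_hosts,
                   dimnames = list(phage_ids, host_ids))
  states <- matrix("resistant", n_phages, n_hosts,
                   dimnames = list(phage_ids, host_ids))

  gen <- which(archetype == "generalist")
  spec <- which(archetype == "specialist")
  susceptible_hosts <- which(cls == "susceptible")
  slight_hosts <- which(cls == "slightly_susceptible")
  resistant_hosts <- which(cls == "resistant")

  draw <- function(n, mean) {
    lt <- mean + stats::rnorm(n, 0, noise_sd)
    10^pmin(pmax(lt, 2), 8)
  }
  # generalists infect every susceptible host
  for (p in gen)
    values[p, susceptible_hosts] <- draw(length(susceptible_hosts),
                                         mu[["generalist_on_susceptible"]])
  # each slightly susceptible host is reached by a minority of generalists
  for (h in slight_hosts) {
    k <- max(1L, min(length(gen),
                     round(stats::runif(1, 0.15, 0.35) * n_phages)))
    infecting <- sample(gen, k)
    values[infecting, h] <- draw(k, mu[["generalist_on_slight"]])
  }
  # each specialist has a few home hosts among the susceptible class
  if (length(spec) && length(susceptible_hosts)) {
    for (p in spec) {
      k <- min(length(susceptible_hosts), sample(2:4, 1L))
      home <- sample(susceptible_hosts, k)
      values[p, home] <- draw(k, mu[["specialist_on_home"]])
    }
  }
  states[!is.na(values)] <- "titer"
  # some resistant hosts show adsorption without productive infection
  if (length(resistant_hosts) && impaired_frac > 0) {
    for (h in resistant_hosts) {
      n_imp <- stats::rbinom(1L, n_phages, impaired_frac)
      if (n_imp > 0) states[sample(n_phages, n_imp), h] <- "impaired"
    }
  }

  mat <- titer_matrix(values, states, provenance =
                        sprintf("simulate_infection_matrix(seed=%d)", seed))
  list(matrix = mat,
       truth = list(archetype = archetype, class = cls,
                    log_titer_means = mu, noise_sd = noise_sd,
                    seed = seed))
}
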