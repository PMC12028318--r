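#' Scoring policy for PDI and susceptibility computations
#'
#' The Paired Difference Index works on log10-transformed infection scores.
#' Two conventions are left open by its definition and are made explicit
#' here:
#'
#' * `null_handling` -- what to do with the cells where no titer was
#'   measured (`resistant`, `impaired`, `not_assessed`). `"floor"` scores
#'   them at the detection limit (`floor_value` PFU/ml, so log-score 0 with
#'   the default floor of 1); `"drop"` excludes them from both the sum and
#'   the denominator, the literal reading of treating null PFU scores as
#'   non-assigned values.
#' * `normalize` -- whether each entity's log-scores are divided by the
#'   row's maximal log-score before the paired differences are taken. With
#'   normalization the index is bounded in \[0, 1\] (0 = uniform
#'   exploitation, 1 = maximal specialization); without it the index is in
#'   raw log10 units and unbounded.
#'
#' @param null_handling `"floor"` or `"drop"`.
#' @param normalize logical; divide log-scores by the row maximum.
#' @param floor_value detection limit in PFU/ml used by `"floor"`
#'   (must be > 0; default 1 PFU/ml, i.e. log-score 0).
#'
#' @return an object of class `scoring_policy`.
#' @export
scoring_policy <- function(null_handling = c("floor", "drop"),
                           normalize = TRUE, floor_value = 1) {
  null_handling <- match.arg(null_handling)
  stopifnot(is.numeric(floor_value), length(floor_value) == 1L,
            floor_value > 0)
  structure(list(null_handling = null_handling,
                 normalize = isTRUE(normalize),
                 floor_value = floor_value, log_base = 10),
            class = "scoring_policy")
}

#' @export
print.scoring_policy <- function(x, ...) {
  cat("PDI scoring policy: null_handling=", x$null_handling,
      ", normalize=", x$normalize, ", floor=", x$floor_value, " PFU/ml\n",
      sep = "")
  invisible(x)
}

# Scores one row of (values, states): log10 infection scores after applying
# the null-handling policy. Returns list(scores, n_used, n_titer).
.row_scores <- function(values, states, policy) {
  is_titer <- states == "titer"
  if (policy$null_handling == "drop") {
    v <- pmax(values[is_titer], policy$floor_value)
    scores <- log10(v)
    n_used <- sum(is_titer)
  } else {
    v <- ifelse(is_titer, pmax(values, policy$floor_value),
                policy$floor_value)
    scores <- log10(v)
    n_used <- length(values)
  }
  list(scores = scores, n_used = n_used, n_titer = sum(is_titer))
}

# PDI of a vector of log-scores, already policy-applied.
.pdi_from_scores <- function(scores, normalize) {
  if (normalize) {
    m <- max(scores)
    if (m <= 0) return(1)         # no score above the detection limit
    scores <- scores / m
  }
  p <- sort(scores, decreasing = TRUE)
  sum(p[1L] - p[-1L]) / (length(p) - 1L)
}

#' Paired Difference Index (PDI)
#'
#' Quantifies how differentially an entity exploits its counterparts: for
#' each phage (or, with `axis = "host"`, each host) the highest log10
#' infection score P1 is contrasted with every other score,
#' PDI = sum(P1 - Pi, i = 2..N) / (N - 1). Under the normalized convention
#' scores are first divided by P1, so PDI = 0 means uniform exploitation of
#' all counterparts and PDI = 1 maximal specialization.
#'
#' Rows containing no measured titer at all have an undefined log profile;
#' they are assigned PDI = 1 (maximal specialization, matching a fully
#' resistant host's susceptibility score of 0) and flagged
#' `"no_positive_titer"`. Under the `"drop"` policy a row can be left with
#' fewer than two usable counterparts; its PDI is `NA` and flagged
#' `"insufficient_counterparts"`.
#'
#' @param x a [titer_matrix()].
#' @param axis `"phage"` (score each phage across hosts, the
#'   specialization index) or `"host"` (score each host across phages, the
#'   basis of the susceptibility score).
#' @param policy a [scoring_policy()].
#'
#' @return a data.frame with columns `entity_id`, `pdi`, `n_used` (number
#'   of counterparts entering the sum's denominator) and `flag`
#'   (`"ok"`, `"no_positive_titer"` or `"insufficient_counterparts"`).
#' @export
compute_pdi <- function(x, axis = c("phage", "host"),
                        policy = scoring_policy()) {
  stopifnot(inherits(x, "titer_matrix"), inherits(policy, "scoring_policy"))
  axis <- match.arg(axis)
  if (axis == "host") {
    values <- t(x$values); states <- t(x$states); ids <- x$host_ids
  } else {
    values <- x$values; states <- x$states; ids <- x$phage_ids
  }
  if (ncol(values) < 2L)
    stop("PDI needs at least 2 counterparts on the chosen axis")
  res <- lapply(seq_along(ids), function(i) {
    rs <- .row_scores(values[i, ], states[i, ], policy)
    if (rs$n_titer == 0L)
      return(list(pdi = 1, n_used = rs$n_used, flag = "no_positive_titer"))
    if (rs$n_used < 2L)
      return(list(pdi = NA_real_, n_used = rs$n_used,
                  flag = "insufficient_counterparts"))
    list(pdi = .pdi_from_scores(rs$scores, policy$normalize),
         n_used = rs$n_used, flag = "ok")
  })
  data.frame(entity_id = ids,
             pdi = vapply(res, `[[`, 0, "pdi"),
             n_used = vapply(res, `[[`, 0L, "n_used"),
             flag = vapply(res, `[[`, "", "flag"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Host susceptibility scores
#'
#' The susceptibility score of a host is 1 - PDI_host: a host exploited
#' uniformly by every phage scores 1, a host reached by a single phage
#' scores near 0, and a host with no measured titer at all scores exactly 0
#' (the resistant class).
#'
#' @inheritParams compute_pdi
#' @return a data.frame with columns `host_id`, `score`, `n_used`, `flag`.
#' @seealso [classify_hosts()]
#' @export
susceptibility_scores <- function(x, policy = scoring_policy()) {
  pdi <- compute_pdi(x, axis = "host", policy = policy)
  data.frame(host_id = pdi$entity_id, score = 1 - pdi$pdi,
             n_used = pdi$n_used, flag = pdi$flag,
             stringsAsFactors = FALSE)
}

#' Classify hosts from susceptibility scores
#'
#' Thresholds: score 0 -> `resistant`; 0 < score < 0.5 ->
#' `slightly_susceptible`; score >= 0.5 -> `susceptible` (boundary
#' inclusive).
#'
#' @param scores data.frame from [susceptibility_scores()] (columns
#'   `host_id`, `score`).
#' @return the input with a `cls` factor column added.
#' @export
classify_hosts <- function(scores) {
  stopifnot(is.data.frame(scores), all(c("host_id", "score") %in%
                                         names(scores)))
  s <- scores$score
  bad <- !is.na(s) & (s < 0 | s > 1)
  if (any(bad))
    stop("susceptibility score(s) outside [0, 1] for host(s): ",
         paste(scores$host_id[bad], collapse = ", "))
  cls <- ifelse(is.na(s), NA_character_,
                ifelse(s == 0, "resistant",
                       ifelse(s < 0.5, "slightly_susceptible",
                              "susceptible")))
  scores$cls <- factor(cls, levels = c("resistant", "slightly_susceptible",
                                       "susceptible"))
  scores
}

#' Export a per-entity result table as JSON
#'
#' @param df a result data.frame (e.g. from [compute_pdi()] or
#'   [classify_hosts()]).
#' @param path output path.
#' @export
write_results_json <- function(df, path) {
  jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, na = "null", factor = "string")
  invisible(path)
}
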