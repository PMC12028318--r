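#' Counting-method dN/dS (Nei-Gojobori style) on a codon alignment
#'
#' An explicit counting estimate of the alignment-wide ratio of
#' nonsynonymous to synonymous substitution rates:
#'
#' 1. codon columns with at least `gap_col_threshold` % gapped sequences
#'    are removed (a codon is gapped when any of its three nucleotides is
#'    `-`);
#' 2. for every unordered sequence pair, synonymous and nonsynonymous
#'    sites are counted per codon (each of the three positions contributes
#'    the fraction of its three possible changes that preserve the amino
#'    acid; changes creating stop codons count as nonsynonymous) and
#'    averaged between the two sequences; observed differences are
#'    classified by equal-weight averaging over all mutational pathways;
#'    codons containing gaps or ambiguous bases in either sequence are
#'    skipped for that pair;
#' 3. sites and differences are summed over pairs, proportions
#'    pN and pS are Jukes-Cantor corrected (d = -3/4 ln(1 - 4/3 p)) and
#'    the ratio dN/dS returned.
#'
#' The ratio is undefined (flagged, `NA`) when dS = 0 or when a proportion
#' exceeds the Jukes-Cantor domain. This simple counting estimate is not a
#' substitute for a codon-model fit; externally computed model-based
#' values can be loaded with [read_dnds_table()].
#'
#' @param codon_aln named character vector of aligned codon sequences
#'   (equal lengths, multiples of 3).
#' @param gap_col_threshold columns with at least this % of gapped codons
#'   are trimmed (default 20).
#' @return an object of class `dnds_estimate`: list with `dN`, `dS`,
#'   `dnds`, `defined`, `pN`, `pS`, `n_sites_N`, `n_sites_S`,
#'   `n_codons_used`, `n_pairs`.
#' @export
counting_dnds <- function(codon_aln, gap_col_threshold = 20) {
  seqs <- .as_aligned_chars(codon_aln)
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  len <- nchar(seqs[[1L]])
  if (len %% 3 != 0) stop("alignment length not a multiple of 3")
  n_codons <- len / 3
  cod <- lapply(seqs, function(s)
    substring(s, 3L * seq_len(n_codons) - 2L, 3L * seq_len(n_codons)))
  cod <- do.call(rbind, cod)   # taxa x codons
  rownames(cod) <- names(seqs)

  code <- Biostrings::GENETIC_CODE
  # in-frame stop codons (ignoring terminal position) are an error
  for (i in seq_len(nrow(cod))) {
    cc <- cod[i, ]
    clean <- which(grepl("^[ACGT]{3}$", cc))
    stops <- clean[code[cc[clean]] == "*"]
    stops <- setdiff(stops, n_codons)  # tolerate a terminal stop
    if (length(stops))
      stop("in-frame stop codon in sequence ", rownames(cod)[i],
           " at codon ", stops[1L])
  }

  gapped <- apply(cod, 2L, function(x) grepl("-", x, fixed = TRUE))
  if (is.null(dim(gapped))) gapped <- matrix(gapped, nrow = nrow(cod))
  col_gap_pct <- 100 * colMeans(gapped)
  cod <- cod[, col_gap_pct < gap_col_threshold, drop = FALSE]

  tot <- c(N = 0, S = 0, Nd = 0, Sd = 0)
  n_pairs <- 0L
  for (i in seq_len(nrow(cod) - 1L)) {
    for (j in (i + 1L):nrow(cod)) {
      usable <- grepl("^[ACGT]{3}$", cod[i, ]) &
        grepl("^[ACGT]{3}$", cod[j, ])
      # drop codons that are stops in either sequence (terminal stops)
      usable <- usable & code[cod[i, ]] != "*" & code[cod[j, ]] != "*"
      if (!any(usable)) next
      n_pairs <- n_pairs + 1L
      for (k in which(usable)) {
        s1 <- .codon_sites(cod[i, k], code)
        s2 <- .codon_sites(cod[j, k], code)
        tot["N"] <- tot["N"] + (s1["N"] + s2["N"]) / 2
        tot["S"] <- tot["S"] + (s1["S"] + s2["S"]) / 2
        d <- .codon_diffs(cod[i, k], cod[j, k], code)
        tot["Nd"] <- tot["Nd"] + d["Nd"]
        tot["Sd"] <- tot["Sd"] + d["Sd"]
      }
    }
  }
  if (n_pairs == 0L) stop("no comparable codons in any pair")
  pN <- unname(tot["Nd"] / tot["N"])
  pS <- unname(tot["Sd"] / tot["S"])
  jc <- function(p) {
    if (p == 0) return(0)
    if (p >= 3 / 4) return(NA_real_)
    -3 / 4 * log(1 - 4 / 3 * p)
  }
  dN <- jc(pN)
  dS <- jc(pS)
  defined <- !is.na(dN) && !is.na(dS) && dS > 0
  structure(list(dN = dN, dS = dS,
                 dnds = if (defined) dN / dS else NA_real_,
                 defined = defined, pN = pN, pS = pS,
                 n_sites_N = unname(tot["N"]), n_sites_S = unname(tot["S"]),
                 n_codons_used = ncol(cod), n_pairs = n_pairs),
            class = "dnds_estimate")
}

#' @export
print.dnds_estimate <- function(x, ...) {
  cat("Counting dN/dS over", x$n_pairs, "pair(s),", x$n_codons_used,
      "codons after trimming\n")
  cat(sprintf("  dN = %.4g, dS = %.4g, dN/dS = %s\n", x$dN, x$dS,
              if (x$defined) format(x$dnds, digits = 4)
              else "undefined (dS = 0)"))
  invisible(x)
}

# synonymous/nonsynonymous site counts of one codon
.codon_sites <- function(codon, code) {
  nts <- c("A", "C", "G", "T")
  aa <- code[codon]
  chars <- strsplit(codon, "")[[1L]]
  syn <- 0
  for (pos in 1:3) {
    for (nt in setdiff(nts, chars[pos])) {
      alt <- chars
      alt[pos] <- nt
      alt_aa <- code[paste(alt, collapse = "")]
      if (alt_aa == aa && alt_aa != "*") syn <- syn + 1 / 3
    }
  }
  c(S = syn, N = 3 - syn)
}

# pathway-averaged synonymous/nonsynonymous differences between two codons
.codon_diffs <- function(c1, c2, code) {
  if (c1 == c2) return(c(Nd = 0, Sd = 0))
  p1 <- strsplit(c1, "")[[1L]]
  p2 <- strsplit(c2, "")[[1L]]
  diff_pos <- which(p1 != p2)
  perms <- .permutations(diff_pos)
  nd <- sd_ <- 0
  for (r in seq_len(nrow(perms))) {
    cur <- p1
    for (pos in perms[r, ]) {
      nxt <- cur
      nxt[pos] <- p2[pos]
      a1 <- code[paste(cur, collapse = "")]
      a2 <- code[paste(nxt, collapse = "")]
      if (a1 == a2 && a1 != "*") sd_ <- sd_ + 1 else nd <- nd + 1
      cur <- nxt
    }
  }
  c(Nd = nd / nrow(perms), Sd = sd_ / nrow(perms))
}

.permutations <- function(x) {
  n <- length(x)
  if (n == 1L) return(matrix(x, 1L))
  out <- NULL
  for (i in seq_len(n))
    out <- rbind(out, cbind(x[i], .permutations(x[-i])))
  out
}

#' Load externally computed dN/dS values
#'
#' Reads a two-column TSV (`family_id`, `dnds`) of alignment-wide dN/dS
#' ratios computed by a codon-model tool, for exact replication of
#' model-based estimates.
#'
#' @param path TSV path (header optional; detected).
#' @return data.frame `family_id`, `dnds`.
#' @export
read_dnds_table <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("family", first, ignore.case = TRUE)
  tab <- utils::read.delim(path, header = has_header,
                           stringsAsFactors = FALSE)
  if (!has_header) names(tab) <- c("family_id", "dnds")[seq_len(ncol(tab))]
  stopifnot(all(c("family_id", "dnds") %in% names(tab)))
  tab$dnds <- as.numeric(tab$dnds)
  tab[, c("family_id", "dnds")]
}

#' Divergence-recombination-selection association tests
#'
#' Given per-family evolutionary statistics, tests (i) whether divergent
#' families (mean pairwise identity below threshold) carry more
#' recombination events than non-divergent ones (two-sided Mann-Whitney U)
#' and (ii) the Spearman rank correlations of mean pairwise identity with
#' the recombination event count and with dN/dS. P-values are reported raw
#' and Benjamini-Hochberg adjusted across the tests performed.
#'
#' @param stats data.frame with columns `family_id`,
#'   `mean_pairwise_identity`, `is_divergent`, `recomb_event_count` and
#'   optionally `dnds`.
#' @return an object of class `divergence_assoc`: data.frame `test`,
#'   `statistic`, `estimate`, `p.value`, `p.adj`, plus a `note` attribute
#'   for degenerate inputs.
#' @export
divergence_association <- function(stats) {
  stopifnot(is.data.frame(stats),
            all(c("family_id", "mean_pairwise_identity", "is_divergent",
                  "recomb_event_count") %in% names(stats)))
  if (nrow(stats) < 5L)
    stop("need at least 5 families with complete fields")
  note <- character(0)
  rows <- list()

  n_div <- sum(stats$is_divergent)
  if (n_div == 0L || n_div == nrow(stats)) {
    note <- c(note, "one divergence group empty: class comparison skipped")
    warning("one of the divergence groups is empty; ",
            "reporting correlations only")
  } else {
    x <- stats$recomb_event_count[stats$is_divergent]
    y <- stats$recomb_event_count[!stats$is_divergent]
    if (length(unique(c(x, y))) == 1L) {
      rows$mw <- data.frame(test = "recomb_divergent_vs_not", statistic =
                              length(x) * length(y) / 2,
                            estimate = 0, p.value = 1)
    } else {
      wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
      rows$mw <- data.frame(test = "recomb_divergent_vs_not",
                            statistic = unname(wt$statistic),
                            estimate = stats::median(x) - stats::median(y),
                            p.value = wt$p.value)
    }
  }

  sp <- function(a, b, label) {
    if (stats::sd(b, na.rm = TRUE) == 0 || all(is.na(b))) {
      note <<- c(note, paste0(label, ": constant values, ",
                              "correlation undefined"))
      return(data.frame(test = label, statistic = NA_real_,
                        estimate = NA_real_, p.value = NA_real_))
    }
    ct <- suppressWarnings(stats::cor.test(a, b, method = "spearman"))
    data.frame(test = label, statistic = unname(ct$statistic),
               estimate = unname(ct$estimate), p.value = ct$p.value)
  }
  rows$sp_rec <- sp(stats$mean_pairwise_identity, stats$recomb_event_count,
                    "identity_vs_recomb")
  if ("dnds" %in% names(stats))
    rows$sp_dnds <- sp(stats$mean_pairwise_identity, stats$dnds,
                       "identity_vs_dnds")

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p.adj <- stats::p.adjust(out$p.value, method = "BH")
  attr(out, "note") <- note
  class(out) <- c("divergence_assoc", "data.frame")
  out
}
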