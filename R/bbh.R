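#' Best-bidirectional-hit (BBH) edges
#'
#' For each ordered pair of genomes (A, B) and each gene `a` of A, the best
#' hit `b` in B is the hit with maximal score (ties broken by higher
#' identity, then by lexicographically smaller target id, so the result is
#' deterministic). The undirected edge (a, b) is kept iff `a` is in turn
#' the best hit of `b` in A, and the hit passes both cutoffs strictly:
#' identity > `id_cutoff` % and coverage of the shorter protein >
#' `cov_cutoff` %. Intra-genome hits never produce BBH edges.
#'
#' @param hits a `similarity_hits` data.frame
#'   (see [all_vs_all_similarity()]).
#' @param id_cutoff minimal amino-acid identity, % (exclusive; default 20).
#' @param cov_cutoff minimal coverage of the shorter protein, % (exclusive;
#'   default 50).
#' @return data.frame with columns `gene_a`, `gene_b`, `genome_a`,
#'   `genome_b`, `identity`, `coverage_shortest`, `score`; one row per
#'   undirected edge with `gene_a < gene_b`.
#' @export
bbh_edges <- function(hits, id_cutoff = 20, cov_cutoff = 50) {
  stopifnot(is.data.frame(hits))
  h <- hits[hits$query_genome != hits$target_genome, , drop = FALSE]
  if (nrow(h) == 0L)
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      genome_a = character(0), genome_b = character(0),
                      identity = numeric(0), coverage_shortest = numeric(0),
                      score = numeric(0)))
  # best hit of each gene in each foreign genome
  grp <- paste(h$query_id, h$target_genome, sep = "\r")
  ord <- order(grp, -h$score, -h$identity, h$target_id)
  h <- h[ord, , drop = FALSE]
  best <- h[!duplicated(paste(h$query_id, h$target_genome, sep = "\r")), ,
            drop = FALSE]
  fwd_key <- paste(best$query_id, best$target_id, sep = "\r")
  rev_key <- paste(best$target_id, best$query_id, sep = "\r")
  mutual <- best[fwd_key %in% rev_key, , drop = FALSE]
  keep <- mutual$identity > id_cutoff & mutual$coverage_shortest > cov_cutoff
  mutual <- mutual[keep, , drop = FALSE]
  # undirected: keep one orientation
  a_first <- mutual$query_id < mutual$target_id
  edges <- data.frame(
    gene_a = ifelse(a_first, mutual$query_id, mutual$target_id),
    gene_b = ifelse(a_first, mutual$target_id, mutual$query_id),
    genome_a = ifelse(a_first, mutual$query_genome, mutual$target_genome),
    genome_b = ifelse(a_first, mutual$target_genome, mutual$query_genome),
    identity = mutual$identity,
    coverage_shortest = mutual$coverage_shortest,
    score = mutual$score, stringsAsFactors = FALSE)
  edges <- edges[!duplicated(paste(edges$gene_a, edges$gene_b, sep = "\r")), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' BBH groups (gene families) as connected components
#'
#' Gene families are the connected components of the BBH graph over the
#' union of all genes: genes without any BBH edge become singleton
#' families. Each family is flagged `is_core` (a member in every genome)
#' and `is_single_copy` (exactly one member per represented genome), and
#' the persistence spectrum reports the fraction of families present in
#' more than 80% of the genomes, in fewer than 20%, and in between.
#'
#' @param edges BBH edges from [bbh_edges()].
#' @param proteomes named list of [proteome()] objects (defines the gene
#'   universe).
#' @return an object of class `bbh_groups`: list with
#'   `membership` (data.frame `genome_id`, `gene_id`, `group_id`),
#'   `groups` (data.frame `group_id`, `n_members`, `genome_count`,
#'   `is_core`, `is_single_copy`), `spectrum` (named fractions
#'   `above_80`, `below_20`, `intermediate`) and `n_genomes`.
#' @export
bbh_groups <- function(edges, proteomes) {
  genes <- .gene_table(proteomes)
  unknown <- setdiff(unique(c(edges$gene_a, edges$gene_b)), genes$gene_id)
  if (length(unknown))
    stop("edges reference unknown genes: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  g <- igraph::graph_from_data_frame(
    edges[, c("gene_a", "gene_b"), drop = FALSE],
    directed = FALSE, vertices = genes$gene_id)
  comp <- igraph::components(g)$membership
  group_id <- sprintf("F%04d", comp[genes$gene_id])
  membership <- data.frame(genome_id = genes$genome_id,
                           gene_id = genes$gene_id,
                           group_id = unname(group_id),
                           stringsAsFactors = FALSE)
  n_genomes <- length(unique(genes$genome_id))
  sp <- split(membership$genome_id, membership$group_id)
  groups <- data.frame(
    group_id = names(sp),
    n_members = lengths(sp),
    genome_count = vapply(sp, function(x) length(unique(x)), 0L),
    stringsAsFactors = FALSE, row.names = NULL)
  groups$is_core <- groups$genome_count == n_genomes
  groups$is_single_copy <- groups$n_members == groups$genome_count
  frac <- groups$genome_count / n_genomes
  spectrum <- c(above_80 = mean(frac > 0.8),
                below_20 = mean(frac < 0.2),
                intermediate = mean(frac >= 0.2 & frac <= 0.8))
  structure(list(membership = membership, groups = groups,
                 spectrum = spectrum, n_genomes = n_genomes),
            class = "bbh_groups")
}

#' @export
print.bbh_groups <- function(x, ...) {
  cat("BBH gene families: ", nrow(x$groups), " families over ",
      x$n_genomes, " genomes\n", sep = "")
  cat("  core (all genomes): ", sum(x$groups$is_core),
      "; single-copy core: ",
      sum(x$groups$is_core & x$groups$is_single_copy), "\n", sep = "")
  cat(sprintf("  persistence spectrum: >80%%: %.1f%%, <20%%: %.1f%%, intermediate: %.1f%%\n",
              100 * x$spectrum[["above_80"]], 100 * x$spectrum[["below_20"]],
              100 * x$spectrum[["intermediate"]]))
  invisible(x)
}
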