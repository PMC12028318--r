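#' Adjacency-weighted pangenome graph
#'
#' Nodes are BBH gene families; an edge joins two families whenever their
#' members are direct neighbors in the gene order of at least one genome,
#' weighted by the number of such adjacencies across all genomes. Tandem
#' genes of the same family produce self-loops. Orientation (strand) is
#' ignored. For linear genomes each genome contributes exactly
#' `n_genes - 1` adjacency counts, so the total edge weight (self-loops
#' included) equals the sum of `n_genes - 1` over genomes.
#'
#' @param groups a [bbh_groups()] object.
#' @param proteomes named list of [proteome()] objects.
#' @param circular treat genomes as circular (adds the last-to-first
#'   adjacency).
#' @return an object of class `pangenome_graph`: list with `nodes`
#'   (data.frame `group_id`, `genome_count`, `is_core`) and `edges`
#'   (data.frame `group_a`, `group_b`, `weight`; `group_a <= group_b`).
#' @export
pangenome_adjacency_graph <- function(groups, proteomes, circular = FALSE) {
  stopifnot(inherits(groups, "bbh_groups"))
  gmap <- setNames(groups$membership$group_id, groups$membership$gene_id)
  adj <- lapply(proteomes, function(p) {
    fams <- gmap[p$gene_id[order(p$rank)]]
    if (anyNA(fams))
      stop("gene(s) without group assignment in genome ", p$genome_id[1L])
    if (length(fams) < 2L) return(NULL)
    a <- fams[-length(fams)]
    b <- fams[-1L]
    if (circular) {
      a <- c(a, fams[length(fams)])
      b <- c(b, fams[1L])
    }
    data.frame(group_a = pmin(a, b), group_b = pmax(a, b),
               stringsAsFactors = FALSE)
  })
  adj <- do.call(rbind, adj)
  tab <- stats::aggregate(list(weight = rep(1L, nrow(adj))),
                          adj[, c("group_a", "group_b")], sum)
  tab <- tab[order(tab$group_a, tab$group_b), , drop = FALSE]
  rownames(tab) <- NULL
  nodes <- groups$groups[, c("group_id", "genome_count", "is_core")]
  structure(list(nodes = nodes, edges = tab, circular = circular),
            class = "pangenome_graph")
}

#' @export
print.pangenome_graph <- function(x, ...) {
  cat("Pangenome graph: ", nrow(x$nodes), " families, ", nrow(x$edges),
      " adjacency edges (total weight ", sum(x$edges$weight), ")\n",
      sep = "")
  invisible(x)
}

#' Convert a pangenome graph to igraph
#'
#' @param x a `pangenome_graph`.
#' @return an [igraph::graph] with a `weight` edge attribute and
#'   `genome_count`/`is_core` vertex attributes.
#' @export
as_igraph <- function(x) {
  stopifnot(inherits(x, "pangenome_graph"))
  igraph::graph_from_data_frame(x$edges, directed = FALSE,
                                vertices = x$nodes)
}

#' Export a pangenome graph
#'
#' @param x a `pangenome_graph`.
#' @param path output path.
#' @param format `"tsv"` (edge list with weights) or `"graphml"`.
#' @export
write_pangenome_graph <- function(x, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(x$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    igraph::write_graph(as_igraph(x), path, format = "graphml")
  }
  invisible(path)
}

#' Synteny links between consecutive genomes of a display order
#'
#' For each pair of genomes adjacent in `genome_order`, emits one link per
#' pair of genes of the same BBH family (one in each genome), annotated
#' with the % amino-acid identity recorded in the similarity hits (NA when
#' the pair was not aligned directly).
#'
#' @param groups a [bbh_groups()] object.
#' @param proteomes named list of [proteome()] objects.
#' @param genome_order character vector of genome ids in display order.
#' @param hits optional `similarity_hits` used to annotate links with
#'   identity.
#' @return data.frame `genome_a`, `genome_b`, `gene_a`, `gene_b`,
#'   `group_id`, `identity`.
#' @export
synteny_links <- function(groups, proteomes, genome_order, hits = NULL) {
  stopifnot(inherits(groups, "bbh_groups"))
  known <- vapply(proteomes, function(p) p$genome_id[1L], "")
  missing <- setdiff(genome_order, known)
  if (length(missing))
    stop("genome(s) not in proteome set: ", paste(missing, collapse = ", "))
  m <- groups$membership
  idmap <- if (!is.null(hits))
    setNames(hits$identity, paste(hits$query_id, hits$target_id, sep = "\r"))
  else character(0)

  out <- list()
  for (i in seq_len(length(genome_order) - 1L)) {
    ga <- genome_order[i]; gb <- genome_order[i + 1L]
    ma <- m[m$genome_id == ga, ]
    mb <- m[m$genome_id == gb, ]
    shared <- intersect(ma$group_id, mb$group_id)
    links <- merge(ma[ma$group_id %in% shared, c("gene_id", "group_id")],
                   mb[mb$group_id %in% shared, c("gene_id", "group_id")],
                   by = "group_id", suffixes = c("_a", "_b"))
    if (nrow(links) == 0L) next
    ident <- idmap[paste(links$gene_id_a, links$gene_id_b, sep = "\r")]
    out[[length(out) + 1L]] <- data.frame(
      genome_a = ga, genome_b = gb,
      gene_a = links$gene_id_a, gene_b = links$gene_id_b,
      group_id = links$group_id,
      identity = as.numeric(ident), stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(genome_a = character(0), genome_b = character(0),
                      gene_a = character(0), gene_b = character(0),
                      group_id = character(0), identity = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Taxonomic rank assignment from an intergenomic similarity matrix
#'
#' Applies the ICTV genome-identity thresholds to a symmetric % similarity
#' matrix (e.g. VIRIDIC output): genomes are clustered by single linkage at
#' each threshold (connected components of the graph joining pairs with
#' similarity >= t). Because the thresholds are increasing, the partitions
#' are nested: every species cluster lies within one genus cluster, every
#' genus within one family.
#'
#' @param sim symmetric numeric matrix of % intergenomic similarities with
#'   100 on the diagonal and genome ids as dimnames.
#' @param thresholds named numeric vector of rank thresholds (default
#'   `c(family = 50, genus = 70, species = 95)`).
#' @return data.frame with one row per genome and one integer cluster-id
#'   column per rank.
#' @export
intergenomic_similarity_classify <- function(sim,
                                             thresholds = c(family = 50,
                                                            genus = 70,
                                                            species = 95)) {
  stopifnot(is.matrix(sim), nrow(sim) == ncol(sim))
  ids <- rownames(sim)
  if (is.null(ids)) stop("similarity matrix must carry genome ids")
  if (max(abs(sim - t(sim))) > 1e-6)
    stop("similarity matrix is asymmetric beyond tolerance 1e-6")
  if (any(abs(diag(sim) - 100) > 1e-6))
    stop("similarity matrix diagonal must be 100")
  out <- data.frame(genome_id = ids, stringsAsFactors = FALSE)
  for (rk in names(thresholds)) {
    keep <- sim >= thresholds[[rk]]
    diag(keep) <- FALSE
    idx <- which(keep & upper.tri(keep), arr.ind = TRUE)
    g <- igraph::graph_from_data_frame(
      data.frame(a = ids[idx[, 1L]], b = ids[idx[, 2L]]),
      directed = FALSE, vertices = ids)
    out[[rk]] <- unname(igraph::components(g)$membership[ids])
  }
  out
}
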