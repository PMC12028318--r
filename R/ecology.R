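#' Patristic distance matrix from a Newick tree
#'
#' The patristic distance between two leaves is the sum of branch lengths
#' along the tree path connecting them.
#'
#' @param tree an `ape::phylo` object, a Newick string, or a path to a
#'   Newick file.
#' @return a symmetric numeric matrix with zero diagonal, row/column names
#'   the leaf labels.
#' @export
patristic_distance_matrix <- function(tree) {
  phy <- .as_phylo(tree)
  if (is.null(phy$edge.length))
    stop("tree has no branch lengths; patristic distances are undefined")
  if (anyNA(phy$edge.length))
    stop("tree has missing branch lengths; no default is substituted")
  if (anyDuplicated(phy$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]),
               collapse = ", "))
  d <- ape::cophenetic.phylo(phy)
  d[phy$tip.label, phy$tip.label, drop = FALSE]
}

.as_phylo <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  stopifnot(is.character(tree), length(tree) == 1L)
  phy <- if (file.exists(tree) && !grepl("\\(", tree)) ape::read.tree(tree)
  else ape::read.tree(text = tree)
  if (is.null(phy)) stop("could not parse Newick input")
  phy
}

#' Phylogenetic neighborhood profile of each host
#'
#' For each host strain, takes the `k` strains at smallest patristic
#' distance (the focal strain excluded; distance ties broken by
#' lexicographically smaller id, so the result is deterministic and
#' invariant to input order) and reports:
#'
#' * `polymorphism` -- the mean patristic distance to those k neighbors, in
#'   branch-length units;
#' * `trait_specificity` -- the fraction (in \[0, 1\]) of the k neighbors
#'   whose trait value equals the focal strain's.
#'
#' @param dist symmetric patristic distance matrix
#'   (see [patristic_distance_matrix()]).
#' @param metadata data.frame with one row per host; must contain a
#'   `host_id` column and the `trait` column.
#' @param k number of nearest neighbors (default 6).
#' @param trait name of the categorical trait column in `metadata`.
#' @return data.frame with columns `host_id`, `polymorphism`,
#'   `trait_specificity`.
#' @export
neighborhood_profile <- function(dist, metadata, k = 6L, trait) {
  stopifnot(is.matrix(dist), nrow(dist) == ncol(dist))
  ids <- rownames(dist)
  if (is.null(ids)) stop("distance matrix must carry taxon ids as dimnames")
  if (k >= nrow(dist))
    stop("k must be smaller than the number of taxa")
  stopifnot(is.data.frame(metadata), "host_id" %in% names(metadata),
            trait %in% names(metadata))
  missing <- setdiff(ids, metadata$host_id)
  if (length(missing))
    stop("host(s) absent from metadata: ", paste(missing, collapse = ", "))
  traits <- setNames(as.character(metadata[[trait]]), metadata$host_id)

  res <- lapply(ids, function(id) {
    others <- setdiff(ids, id)
    d <- dist[id, others]
    ord <- order(d, others)              # distance, then lexicographic id
    nb <- others[ord][seq_len(k)]
    data.frame(host_id = id,
               polymorphism = mean(dist[id, nb]),
               trait_specificity = mean(traits[nb] == traits[id]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Kruskal-Wallis class association test with pairwise post hocs
#'
#' Tests whether a numeric quantity (e.g. neighborhood polymorphism or
#' trait specificity) differs across host susceptibility classes:
#' a tie-corrected Kruskal-Wallis rank test across all classes, followed by
#' all pairwise two-sided Mann-Whitney U tests. Post-hoc p-values are
#' reported both raw and Benjamini-Hochberg adjusted.
#'
#' @param values numeric vector, one value per host.
#' @param classes class label per host (factor or character), same length.
#' @return an object of class `class_assoc` with fields `kruskal`
#'   (`statistic`, `df`, `p.value`) and `pairwise` (data.frame: `group1`,
#'   `group2`, `U`, `p.value`, `p.adj`).
#' @export
class_association_test <- function(values, classes) {
  stopifnot(length(values) == length(classes))
  keep <- !is.na(values) & !is.na(classes)
  values <- values[keep]
  classes <- factor(as.character(classes[keep]))
  if (nlevels(classes) < 2L)
    stop("need at least 2 non-empty classes")
  if (any(table(classes) == 0L)) stop("empty class")

  constant <- length(unique(values)) == 1L
  if (constant) {
    # no rank variance at all: H = 0 by definition, nothing to detect
    kw <- list(statistic = 0, parameter = nlevels(classes) - 1L,
               p.value = 1)
  } else {
    kw <- stats::kruskal.test(values, classes)
  }
  lev <- levels(classes)
  pairs <- utils::combn(lev, 2L)
  pw <- apply(pairs, 2L, function(p) {
    x <- values[classes == p[1L]]
    y <- values[classes == p[2L]]
    if (length(unique(c(x, y))) == 1L)
      return(c(U = length(x) * length(y) / 2, p.value = 1))
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
    c(U = unname(wt$statistic), p.value = wt$p.value)
  })
  pairwise <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                         U = pw["U", ], p.value = pw["p.value", ],
                         stringsAsFactors = FALSE, row.names = NULL)
  pairwise$p.adj <- stats::p.adjust(pairwise$p.value, method = "BH")
  structure(list(kruskal = list(statistic = unname(kw$statistic),
                                df = unname(kw$parameter),
                                p.value = kw$p.value),
                 pairwise = pairwise,
                 n = as.vector(table(classes)), groups = lev),
            class = "class_assoc")
}

#' @export
print.class_assoc <- function(x, ...) {
  cat("Kruskal-Wallis: H =", format(x$kruskal$statistic, digits = 4),
      "df =", x$kruskal$df,
      "p =", format.pval(x$kruskal$p.value, digits = 3), "\n")
  cat("group sizes:", paste(x$groups, x$n, sep = "=", collapse = ", "), "\n")
  cat("pairwise Mann-Whitney (BH-adjusted):\n")
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}
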