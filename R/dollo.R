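#' Dollo parsimony gain/loss reconstruction
#'
#' Under Dollo parsimony a gene family is gained exactly once -- on the
#' branch leading to the most recent common ancestor of the genomes that
#' carry it -- and lost as few times as the presence pattern allows below
#' that gain. The minimal-loss placement puts one loss on each maximal
#' subtree (below the gain node) devoid of the family.
#'
#' Branches are identified by their child node: tip labels for terminal
#' branches, `node_<k>` (ape node numbering) or the tree's own node labels
#' for internal ones. The branch above the root carries gains of families
#' present in all genomes.
#'
#' @param presence 0/1 matrix, families in rows, genomes in columns
#'   (column names must match the tree's tip labels).
#' @param tree rooted tree: an `ape::phylo`, a Newick string or a file
#'   path.
#' @return an object of class `dollo_gain_loss`: list with
#'   `per_family` (data.frame `family`, `gain_branch`, `n_losses`),
#'   `per_branch` (data.frame `branch`, `gains`, `losses`) and `tree`.
#' @export
dollo_gain_loss <- function(presence, tree) {
  phy <- .as_phylo(tree)
  if (!ape::is.rooted(phy))
    stop("Dollo reconstruction needs a rooted tree")
  presence <- as.matrix(presence)
  if (is.null(colnames(presence)))
    stop("presence matrix must carry genome ids as column names")
  if (!setequal(colnames(presence), phy$tip.label))
    stop("presence matrix genomes and tree tips differ")
  presence <- presence[, phy$tip.label, drop = FALSE]
  if (is.null(rownames(presence)))
    rownames(presence) <- paste0("fam", seq_len(nrow(presence)))
  empty <- rowSums(presence > 0) == 0L
  if (any(empty))
    stop("family(ies) absent from every genome: ",
         paste(rownames(presence)[empty], collapse = ", "))

  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  nnode <- ntip + phy$Nnode
  children <- vector("list", nnode)
  for (i in seq_len(nrow(phy$edge)))
    children[[phy$edge[i, 1L]]] <- c(children[[phy$edge[i, 1L]]],
                                     phy$edge[i, 2L])
  branch_name <- function(v) {
    if (v <= ntip) return(phy$tip.label[v])
    if (!is.null(phy$node.label) &&
        nzchar(lbl <- phy$node.label[v - ntip]) && !is.na(lbl)) return(lbl)
    paste0("node_", v)
  }
  all_names <- vapply(seq_len(nnode), branch_name, "")

  # number of present tips below each node, bottom-up, per family
  gains <- setNames(integer(nnode), all_names)
  losses <- setNames(integer(nnode), all_names)
  po <- rev(.preorder_nodes(children, root))   # children before parents
  per_family <- vector("list", nrow(presence))

  for (f in seq_len(nrow(presence))) {
    pres_tip <- presence[f, ] > 0
    cnt <- integer(nnode)
    cnt[seq_len(ntip)] <- as.integer(pres_tip)
    for (v in po) if (v > ntip) cnt[v] <- sum(cnt[children[[v]]])
    total <- cnt[root]
    # gain node: MRCA of present tips = shallowest node with cnt == total
    gain <- root
    while (gain > ntip) {
      kids <- children[[gain]]
      nxt <- kids[cnt[kids] == total]
      if (length(nxt) == 1L) gain <- nxt else break
    }
    gains[gain] <- gains[gain] + 1L
    # minimal losses: maximal empty subtrees below the gain node
    n_loss <- 0L
    if (gain > ntip) {
      stack <- children[[gain]]
      while (length(stack)) {
        v <- stack[[1L]]; stack <- stack[-1L]
        if (cnt[v] == 0L) {
          losses[v] <- losses[v] + 1L
          n_loss <- n_loss + 1L
        } else if (v > ntip) {
          stack <- c(stack, children[[v]])
        }
      }
    }
    per_family[[f]] <- data.frame(family = rownames(presence)[f],
                                  gain_branch = branch_name(gain),
                                  n_losses = n_loss,
                                  stringsAsFactors = FALSE)
  }
  per_branch <- data.frame(branch = all_names, gains = unname(gains),
                           losses = unname(losses),
                           stringsAsFactors = FALSE)
  structure(list(per_family = do.call(rbind, per_family),
                 per_branch = per_branch, tree = phy),
            class = "dollo_gain_loss")
}

#' @export
print.dollo_gain_loss <- function(x, ...) {
  cat("Dollo gain/loss reconstruction: ", nrow(x$per_family),
      " families on ", length(x$tree$tip.label), " genomes\n", sep = "")
  cat("  total gains: ", sum(x$per_branch$gains), " (one per family)",
      "; total losses: ", sum(x$per_branch$losses), "\n", sep = "")
  invisible(x)
}

.preorder_nodes <- function(children, root) {
  out <- integer(0)
  stack <- root
  while (length(stack)) {
    v <- stack[[1L]]; stack <- stack[-1L]
    out <- c(out, v)
    stack <- c(children[[v]], stack)
  }
  out
}
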