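# Independent brute-force oracles used to validate the implementation.
# These deliberately re-derive every quantity from first principles with
# naive loops, sharing no code with the package internals.

# Paired Difference Index evaluated literally: explicit loop over the
# printed sum, on an already log-transformed (and optionally normalized)
# score vector.
oracle_pdi_from_scores <- function(scores, normalize) {
  if (normalize) scores <- scores / max(scores)
  p <- sort(scores, decreasing = TRUE)
  total <- 0
  for (i in 2:length(p)) total <- total + (p[1] - p[i])
  unname(total / (length(p) - 1))
}

# Applies the floor policy by hand and evaluates the PDI of one row of a
# titer matrix (values with NA at non-titer cells).
oracle_pdi_row <- function(values, floor_value = 1, normalize = TRUE) {
  logs <- ifelse(is.na(values), log10(floor_value),
                 log10(pmax(values, floor_value)))
  if (normalize && max(logs) <= 0) return(1)
  oracle_pdi_from_scores(logs, normalize)
}

# Patristic distance by exhaustive path enumeration: walk from each leaf
# to the root recording cumulative distances, then combine at the deepest
# shared ancestor.
oracle_patristic <- function(phy) {
  ntip <- length(phy$tip.label)
  parent_of <- integer(ntip + phy$Nnode)
  edge_len <- numeric(ntip + phy$Nnode)
  for (e in seq_len(nrow(phy$edge))) {
    parent_of[phy$edge[e, 2]] <- phy$edge[e, 1]
    edge_len[phy$edge[e, 2]] <- phy$edge.length[e]
  }
  path_to_root <- function(v) {
    nodes <- v; dists <- 0
    while (parent_of[v] != 0) {
      dists <- c(dists, dists[length(dists)] + edge_len[v])
      v <- parent_of[v]
      nodes <- c(nodes, v)
    }
    stats::setNames(dists, nodes)
  }
  d <- matrix(0, ntip, ntip, dimnames = list(phy$tip.label, phy$tip.label))
  paths <- lapply(seq_len(ntip), path_to_root)
  for (i in seq_len(ntip - 1)) {
    for (j in (i + 1):ntip) {
      shared <- intersect(names(paths[[i]]), names(paths[[j]]))
      dij <- min(paths[[i]][shared] + paths[[j]][shared])
      d[i, j] <- d[j, i] <- dij
    }
  }
  d
}

# Minimal number of losses given exactly one gain, by exhaustive search
# over all internal-node state assignments. Returns list(gains, losses)
# of the best single-gain assignment.
oracle_dollo_min_losses <- function(phy, presence_tips) {
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  internal <- (ntip + 1):nnode
  root <- ntip + 1
  states <- integer(nnode)
  states[seq_len(ntip)] <- as.integer(presence_tips[phy$tip.label])
  best <- Inf
  combos <- expand.grid(rep(list(0:1), length(internal)))
  for (r in seq_len(nrow(combos))) {
    states[internal] <- as.integer(combos[r, ])
    gains <- 0; losses <- 0
    if (states[root] == 1) gains <- gains + 1
    for (e in seq_len(nrow(phy$edge))) {
      a <- states[phy$edge[e, 1]]; b <- states[phy$edge[e, 2]]
      if (a == 0 && b == 1) gains <- gains + 1
      if (a == 1 && b == 0) losses <- losses + 1
    }
    if (gains == 1 && losses < best) best <- losses
  }
  best
}

# Per-family recombination event counts by per-column membership.
oracle_event_counts <- function(events, coords) {
  total <- attr(coords, "total_length")
  counts <- stats::setNames(integer(nrow(coords)), coords$family_id)
  for (k in seq_len(nrow(events))) {
    cols <- seq(events$start[k], events$end[k] - 1)
    for (f in seq_len(nrow(coords))) {
      gene_cols <- seq(coords$start[f], coords$end[f] - 1)
      if (any(cols %in% gene_cols)) counts[f] <- counts[f] + 1L
    }
  }
  counts
}

# Connected components by brute-force reachability (repeated expansion).
oracle_components <- function(vertices, edges) {
  comp <- stats::setNames(seq_along(vertices), vertices)
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(edges))) {
      a <- edges$a[k]; b <- edges$b[k]
      m <- min(comp[a], comp[b])
      if (comp[a] != m || comp[b] != m) {
        comp[comp == comp[a] | comp == comp[b]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

# Kruskal-Wallis H from first principles (tie-corrected).
oracle_kruskal_H <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, groups, function(x) sum(x)^2 / length(x))) - 3 * (N + 1)
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Writes a minimal GenBank flat file for a proteome-like gene table.
write_fake_genbank <- function(path, genome_id, genes) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %s             %d bp    DNA     linear",
                     genome_id, max(genes$end) + 10), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  for (i in seq_len(nrow(genes))) {
    loc <- sprintf("%d..%d", genes$start[i] + 1, genes$end[i])
    if (genes$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
    writeLines(sprintf("     CDS             %s", loc), con)
    writeLines(sprintf('                     /locus_tag="%s"',
                       genes$gene_id[i]), con)
    writeLines(sprintf('                     /translation="%s"',
                       genes$protein[i]), con)
  }
  writeLines("ORIGIN", con)
  writeLines("//", con)
}
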