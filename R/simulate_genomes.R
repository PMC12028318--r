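#' Simulate a phage genome collection with known evolutionary truth
#'
#' Generates a rooted random tree and evolves a collection of proteomes
#' along it with the architecture typical of large-genome phages: a
#' conserved single-copy core backbone in fixed gene order, accessory gene
#' islands gained and lost on known branches, and homologous-recombination
#' injections concentrated in hotspot regions of the core gene order.
#' Every emitted artifact (proteomes, per-family codon alignments,
#' recombination GFF, tree) parses back through the package's own readers,
#' and the complete ground truth is returned alongside.
#'
#' Sequences evolve by per-site nucleotide substitution: along a branch of
#' length `b`, each nucleotide mutates with probability `subst_rate * b`
#' (mutations creating in-frame stop codons are rejected). A recombination
#' event replaces a codon segment of one core family in all genomes below
#' the recipient branch with the donor lineage's allele, further diverged
#' by `donor_divergence` substitutions/site to emulate recombination with
#' unsampled relatives; its true coordinates on the concatenated core
#' alignment are recorded and emitted as a Gubbins-style GFF.
#'
#' @param n_taxa number of genomes (>= 3).
#' @param n_core number of core families (>= 2), present in every genome.
#' @param n_accessory number of accessory families distributed over the
#'   islands.
#' @param hotspot_positions list of integer vectors of core gene-order
#'   indices forming the recombination hotspots / accessory islands;
#'   default: two blocks of 5 genes at ~45% and ~75% of the core order.
#' @param subst_rate substitutions per site per unit branch length.
#' @param recomb_events number of recombination events to inject (all
#'   target hotspot core families), or a data.frame with columns
#'   `family_idx` (core order index), `donor` (tip label), `recipient`
#'   (branch id: tip label or `node_<k>`). Events targeting families
#'   outside the hotspots are an error.
#' @param seed integer seed.
#' @param mean_gene_len mean gene length in codons (lengths are drawn
#'   uniformly within +/- 60% of it).
#' @param loss_prob per-branch probability of losing an accessory family
#'   below its gain branch.
#' @param donor_divergence extra substitutions/site applied to the donor
#'   allele before injection.
#' @param out_dir if non-`NULL`, write all artifacts there (GFF3 + protein
#'   FASTA per genome, codon-alignment FASTA per family, recombination
#'   GFF, Newick tree).
#' @return list with `tree` (`phylo`), `proteomes` (named list of
#'   [proteome()]), `alignments` (named list of codon alignments, named
#'   character vectors), `coord_map` ([concat_gene_coordinates()] over the
#'   core families), `events` (data.frame: `family_id`, `start`, `end` on
#'   the concatenated alignment, 0-based half-open, `branch_type`,
#'   `donor`, `recipient`, `affected_taxa` list column), `truth` (list:
#'   `family_of_gene`, `presence` 0/1 matrix, `gains`, `losses`,
#'   `islands`, `seed`) and `files` (paths, when `out_dir` is used).
#' @export
simulate_phage_genomes <- function(n_taxa = 18, n_core = 285,
                                   n_accessory = 258,
                                   hotspot_positions = NULL,
                                   subst_rate = 0.02, recomb_events = 9,
                                   seed = 1, mean_gene_len = 180,
                                   loss_prob = 0.25,
                                   donor_divergence = 0.15,
                                   out_dir = NULL) {
  stopifnot(n_taxa >= 3, n_core >= 2, n_accessory >= 0)
  set.seed(seed)
  code <- Biostrings::GENETIC_CODE
  sense_codons <- names(code)[code != "*"]

  phy <- ape::rtree(n_taxa)
  phy$tip.label <- sprintf("G%02d", seq_len(n_taxa))
  ntip <- n_taxa
  root <- ntip + 1L
  phy <- stats::reorder(phy, "cladewise")   # parents before children
  branch_of <- function(v) if (v <= ntip) phy$tip.label[v]
  else paste0("node_", v)
  tips_under <- .tips_under(phy)

  if (is.null(hotspot_positions)) {
    anchor <- function(f) {
      s <- max(1L, min(n_core - 4L, round(f * n_core)))
      s:(s + min(4L, n_core - s))
    }
    hotspot_positions <- list(hs1 = anchor(0.45), hs2 = anchor(0.75))
  }
  hotspot_idx <- sort(unique(unlist(hotspot_positions)))
  stopifnot(all(hotspot_idx >= 1 & hotspot_idx <= n_core))

  core_ids <- sprintf("C%03d", seq_len(n_core))
  acc_ids <- if (n_accessory > 0) sprintf("A%03d", seq_len(n_accessory))
  else character(0)
  lens <- stats::setNames(
    pmax(30L, round(stats::runif(n_core + n_accessory,
                                 0.4 * mean_gene_len,
                                 1.6 * mean_gene_len))),
    c(core_ids, acc_ids))

  # --- evolve one family along the tree ------------------------------
  evolve_family <- function(L) {
    anc <- sample(sense_codons, L, replace = TRUE)
    seqs <- vector("list", ntip + phy$Nnode)
    seqs[[root]] <- unlist(strsplit(anc, ""))
    for (e in seq_len(nrow(phy$edge))) {
      par <- phy$edge[e, 1L]; child <- phy$edge[e, 2L]
      seqs[[child]] <- .mutate_cds(seqs[[par]],
                                   subst_rate * phy$edge.length[e], code)
    }
    out <- lapply(seq_len(ntip), function(i) seqs[[i]])
    names(out) <- phy$tip.label
    out
  }
  fam_seqs <- lapply(lens, evolve_family)

  # --- accessory gain/loss script ------------------------------------
  internal_nodes <- (ntip + 1L):(ntip + phy$Nnode)
  presence <- matrix(1L, n_core + n_accessory, ntip,
                     dimnames = list(c(core_ids, acc_ids), phy$tip.label))
  gains <- data.frame(family = core_ids,
                      gain_branch = branch_of(root),
                      stringsAsFactors = FALSE)
  losses <- data.frame(family = character(0), loss_branch = character(0),
                       stringsAsFactors = FALSE)
  island_of <- stats::setNames(
    sample(seq_along(hotspot_positions), n_accessory, replace = TRUE),
    acc_ids)

  for (a in acc_ids) {
    # gain node: root or an internal node with at least 2 tips below
    cand <- c(root, internal_nodes[lengths(tips_under[internal_nodes]) >= 2])
    g <- sample(cand, 1L)
    pres <- tips_under[[g]]
    gains <- rbind(gains, data.frame(family = a,
                                     gain_branch = branch_of(g),
                                     stringsAsFactors = FALSE))
    # script minimal-loss-canonical losses below the gain node
    below <- phy$edge[, 2L][phy$edge[, 1L] %in%
                              .nodes_under(phy, g, ntip)]
    below <- setdiff(below, g)
    accepted <- integer(0)
    for (v in sample(below)) {
      if (stats::runif(1) > loss_prob) next
      if (any(vapply(accepted, function(u)
        length(intersect(tips_under[[u]], tips_under[[v]])) > 0, TRUE)))
        next
      tentative <- setdiff(pres, tips_under[[v]])
      if (length(tentative) == 0L) next
      if (.mrca_node(phy, tentative, tips_under) != g) next
      ok <- TRUE
      for (u in c(accepted, v)) {
        par_u <- phy$edge[phy$edge[, 2L] == u, 1L]
        sib_tips <- setdiff(tips_under[[par_u]], tips_under[[u]])
        if (!length(intersect(sib_tips, tentative))) { ok <- FALSE; break }
      }
      if (!ok) next
      accepted <- c(accepted, v)
      pres <- tentative
      losses <- rbind(losses, data.frame(family = a,
                                         loss_branch = branch_of(v),
                                         stringsAsFactors = FALSE))
    }
    presence[a, ] <- as.integer(seq_len(ntip) %in% pres)
  }

  # --- recombination injections --------------------------------------
  hotspot_fams <- core_ids[hotspot_idx]
  if (is.data.frame(recomb_events)) {
    ev_spec <- recomb_events
    if (!all(ev_spec$family_idx %in% hotspot_idx))
      stop("recombination event(s) outside the hotspot gene range: ",
           paste(setdiff(ev_spec$family_idx, hotspot_idx), collapse = ", "))
  } else {
    n_ev <- as.integer(recomb_events)
    ev_spec <- NULL
    if (n_ev > 0) {
      all_branches <- phy$edge[, 2L]
      ev_spec <- data.frame(
        family_idx = sample(hotspot_idx, n_ev, replace = TRUE),
        donor = NA_character_, recipient = NA_character_,
        stringsAsFactors = FALSE)
      for (i in seq_len(n_ev)) {
        rec <- sample(all_branches, 1L)
        rec_tips <- tips_under[[rec]]
        donor_pool <- setdiff(phy$tip.label, rec_tips)
        ev_spec$recipient[i] <- branch_of(rec)
        ev_spec$donor[i] <- sample(donor_pool, 1L)
      }
    }
  }

  coord_map <- concat_gene_coordinates(stats::setNames(3L * lens[core_ids],
                                                       core_ids))
  events <- NULL
  if (!is.null(ev_spec) && nrow(ev_spec)) {
    name_to_node <- c(stats::setNames(seq_len(ntip), phy$tip.label),
                      stats::setNames(internal_nodes,
                                      paste0("node_", internal_nodes)))
    ev_rows <- vector("list", nrow(ev_spec))
    for (i in seq_len(nrow(ev_spec))) {
      fam <- core_ids[ev_spec$family_idx[i]]
      L <- lens[[fam]]
      seg_len <- max(3L, as.integer(round(stats::runif(1, 0.3, 0.7) * L)))
      seg_start <- sample.int(L - seg_len + 1L, 1L) - 1L   # codons, 0-based
      nt0 <- 3L * seg_start
      nt1 <- 3L * (seg_start + seg_len)
      donor_seq <- fam_seqs[[fam]][[ev_spec$donor[i]]]
      allele <- .mutate_cds(donor_seq[(nt0 + 1L):nt1], donor_divergence,
                            code)
      rec_node <- name_to_node[[ev_spec$recipient[i]]]
      rec_tips <- phy$tip.label[tips_under[[rec_node]]]
      for (tp in rec_tips)
        fam_seqs[[fam]][[tp]][(nt0 + 1L):nt1] <- allele
      off <- coord_map$start[coord_map$family_id == fam]
      ev_rows[[i]] <- data.frame(
        family_id = fam, start = off + nt0, end = off + nt1,
        branch_type = if (rec_node <= ntip) "terminal" else "internal",
        donor = ev_spec$donor[i], recipient = ev_spec$recipient[i],
        stringsAsFactors = FALSE)
      ev_rows[[i]]$affected_taxa <- list(rec_tips)
    }
    events <- do.call(rbind, ev_rows)
  } else {
    events <- data.frame(family_id = character(0), start = integer(0),
                         end = integer(0), branch_type = character(0),
                         donor = character(0), recipient = character(0),
                         stringsAsFactors = FALSE)
    events$affected_taxa <- list()
  }

  # --- assemble proteomes --------------------------------------------
  fam_order <- .family_order(core_ids, acc_ids, hotspot_positions,
                             island_of)
  spacer <- 50L
  proteomes <- lapply(phy$tip.label, function(tp) {
    fams <- fam_order[vapply(fam_order,
                             function(f) presence[f, tp] == 1L, TRUE)]
    prot <- vapply(fams, function(f)
      .translate_cds(fam_seqs[[f]][[tp]], code), "")
    widths <- 3L * lens[fams]
    starts <- cumsum(c(0L, widths[-length(widths)] + spacer))
    proteome(tp, gene_id = paste(tp, fams, sep = "_"),
             strand = sample(c("+", "-"), length(fams), replace = TRUE,
                             prob = c(0.9, 0.1)),
             start = starts, end = starts + widths,
             protein = prot)
  })
  names(proteomes) <- phy$tip.label

  alignments <- lapply(stats::setNames(c(core_ids, acc_ids),
                                       c(core_ids, acc_ids)), function(f) {
    tps <- phy$tip.label[presence[f, ] == 1L]
    vapply(stats::setNames(tps, tps),
           function(tp) paste(fam_seqs[[f]][[tp]], collapse = ""), "")
  })

  gene_ids <- unlist(lapply(proteomes, `[[`, "gene_id"), use.names = FALSE)
  truth <- list(
    family_of_gene = stats::setNames(sub("^G\\d+_", "", gene_ids),
                                     gene_ids),
    presence = presence, gains = gains, losses = losses,
    islands = island_of, hotspot_positions = hotspot_positions,
    subst_rate = subst_rate, seed = seed)

  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- list()
    for (tp in names(proteomes)) {
      gff <- file.path(out_dir, paste0(tp, ".gff3"))
      faa <- file.path(out_dir, paste0(tp, ".faa"))
      write_proteome(proteomes[[tp]], gff, faa)
      files$annotations <- c(files$annotations, gff)
      files$proteins <- c(files$proteins, faa)
    }
    aln_dir <- file.path(out_dir, "alignments")
    dir.create(aln_dir, showWarnings = FALSE)
    for (f in names(alignments)) {
      p <- file.path(aln_dir, paste0(f, ".fna"))
      Biostrings::writeXStringSet(
        Biostrings::DNAStringSet(alignments[[f]]), p)
      files$alignments <- c(files$alignments, p)
    }
    files$tree <- file.path(out_dir, "tree.nwk")
    ape::write.tree(phy, files$tree)
    files$recomb_gff <- file.path(out_dir, "recombination.gff")
    write_recombination_gff(events, files$recomb_gff)
  }

  list(tree = phy, proteomes = proteomes, alignments = alignments,
       coord_map = coord_map, events = events, truth = truth,
       files = files)
}

# mutate a coding nucleotide sequence; mutations creating stops revert
.mutate_cds <- function(nt, p, code) {
  p <- min(max(p, 0), 1)
  if (p == 0) return(nt)
  hit <- which(stats::runif(length(nt)) < p)
  if (!length(hit)) return(nt)
  out <- nt
  nts <- c("A", "C", "G", "T")
  for (i in hit) {
    out[i] <- sample(setdiff(nts, out[i]), 1L)
  }
  cods <- unique((hit - 1L) %/% 3L)
  for (ci in cods) {
    idx <- (3L * ci + 1L):(3L * ci + 3L)
    if (code[paste(out[idx], collapse = "")] == "*") out[idx] <- nt[idx]
  }
  out
}

.translate_cds <- function(nt, code) {
  n <- length(nt) / 3L
  cods <- vapply(seq_len(n), function(i)
    paste(nt[(3L * i - 2L):(3L * i)], collapse = ""), "")
  paste(code[cods], collapse = "")
}

# tip indices below each node (tips included as themselves)
.tips_under <- function(phy) {
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  out <- vector("list", nnode)
  for (i in seq_len(ntip)) out[[i]] <- i
  edges <- stats::reorder(phy, "postorder")$edge
  for (e in seq_len(nrow(edges)))
    out[[edges[e, 1L]]] <- c(out[[edges[e, 1L]]], out[[edges[e, 2L]]])
  out
}

# all nodes (internal and tips) in the subtree rooted at g, g included
.nodes_under <- function(phy, g, ntip) {
  out <- g
  repeat {
    kids <- phy$edge[phy$edge[, 1L] %in% out, 2L]
    new <- setdiff(kids, out)
    if (!length(new)) break
    out <- c(out, new)
  }
  out
}

.mrca_node <- function(phy, tips, tips_under) {
  ntip <- length(phy$tip.label)
  if (length(tips) == 1L) return(tips)
  cand <- which(vapply(tips_under, function(x) all(tips %in% x), TRUE))
  cand[which.min(lengths(tips_under[cand]))]
}

.family_order <- function(core_ids, acc_ids, hotspot_positions, island_of) {
  n_core <- length(core_ids)
  insert_after <- vapply(hotspot_positions, max, 0L)
  order_ <- character(0)
  for (i in seq_len(n_core)) {
    order_ <- c(order_, core_ids[i])
    for (h in seq_along(hotspot_positions)) {
      if (i == insert_after[h]) {
        isl <- acc_ids[island_of == h]
        order_ <- c(order_, isl)
      }
    }
  }
  order_
}
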