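#' Per-family alignment divergence statistics
#'
#' Mean pairwise identity of a protein (or nucleotide) family alignment
#' over a chosen taxon subset: for every unordered pair of sequences,
#' identity = identical columns / columns where both sequences are non-gap,
#' expressed in %, then averaged over pairs. Pairs sharing no non-gap
#' column are excluded with a warning. A family is flagged divergent when
#' the mean pairwise identity falls below `divergence_threshold`.
#'
#' @param aln named character vector (or `Biostrings::XStringSet`) of
#'   aligned, equal-length sequences; names are taxon ids. Gaps are `-`.
#' @param taxa subset of taxon ids to compare (default: all).
#' @param divergence_threshold % identity below which the family is called
#'   divergent (default 95).
#' @param family_id identifier reported in the result.
#' @return data.frame with columns `family_id`, `mean_pairwise_identity`,
#'   `min_pairwise_identity`, `is_divergent`, `n_pairs`.
#' @export
family_alignment_stats <- function(aln, taxa = NULL,
                                   divergence_threshold = 95,
                                   family_id = "family") {
  seqs <- .as_aligned_chars(aln)
  if (!is.null(taxa)) {
    missing <- setdiff(taxa, names(seqs))
    if (length(missing))
      stop("taxa absent from alignment: ", paste(missing, collapse = ", "))
    seqs <- seqs[taxa]
  }
  if (length(seqs) < 2L) stop("need at least 2 taxa")
  mat <- do.call(rbind, strsplit(unname(seqs), ""))
  ids <- numeric(0)
  dropped <- 0L
  for (i in seq_len(nrow(mat) - 1L)) {
    for (j in (i + 1L):nrow(mat)) {
      both <- mat[i, ] != "-" & mat[j, ] != "-"
      if (!any(both)) { dropped <- dropped + 1L; next }
      ids <- c(ids, 100 * sum(mat[i, both] == mat[j, both]) / sum(both))
    }
  }
  if (dropped > 0L)
    warning(dropped, " pair(s) with no mutually non-gap column excluded")
  if (!length(ids)) stop("all pairs excluded: no comparable columns")
  data.frame(family_id = family_id,
             mean_pairwise_identity = mean(ids),
             min_pairwise_identity = min(ids),
             is_divergent = mean(ids) < divergence_threshold,
             n_pairs = length(ids), stringsAsFactors = FALSE)
}

.as_aligned_chars <- function(aln) {
  if (inherits(aln, "XStringSet")) aln <- as.character(aln)
  stopifnot(is.character(aln), !is.null(names(aln)))
  if (length(unique(nchar(aln))) != 1L)
    stop("aligned sequences must have equal length")
  aln
}

#' Gene coordinate map on a concatenated alignment
#'
#' Lays the per-family codon alignments end to end (in the supplied order,
#' conventionally the gene order of a reference genome) and records each
#' family's half-open column interval on the concatenation.
#'
#' @param lengths named integer vector of codon-alignment lengths
#'   (nucleotide columns, each a multiple of 3), in concatenation order.
#' @return an object of class `gene_coordinate_map`: data.frame
#'   `family_id`, `start`, `end` (0-based half-open) with attribute
#'   `total_length`.
#' @export
concat_gene_coordinates <- function(lengths) {
  if (length(lengths) == 0L) {
    out <- data.frame(family_id = character(0), start = integer(0),
                      end = integer(0))
    attr(out, "total_length") <- 0L
    class(out) <- c("gene_coordinate_map", "data.frame")
    return(out)
  }
  stopifnot(!is.null(names(lengths)), all(lengths > 0))
  if (any(lengths %% 3 != 0))
    stop("codon alignment length(s) not a multiple of 3: ",
         paste(names(lengths)[lengths %% 3 != 0], collapse = ", "))
  ends <- cumsum(as.integer(lengths))
  out <- data.frame(family_id = names(lengths),
                    start = c(0L, ends[-length(ends)]),
                    end = ends, stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "total_length") <- ends[length(ends)]
  class(out) <- c("gene_coordinate_map", "data.frame")
  out
}

#' Parse a recombination-event GFF
#'
#' Reads the GFF-dialect file emitted by recombination-detection tools on a
#' concatenated alignment (Gubbins-style): 9 tab-separated columns, 1-based
#' inclusive coordinates in columns 4-5, and an attribute field that may
#' carry the affected taxa (`taxa="A B"`) and the node kind. Coordinates
#' are converted to the internal 0-based half-open convention.
#'
#' @param path GFF file path.
#' @return data.frame of class `recombination_events`: `start`, `end`
#'   (0-based half-open), `branch_type` (`"internal"`, `"terminal"` or
#'   `"unknown"`), `affected_taxa` (list column of character vectors).
#' @export
parse_recombination_gff <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines))
    return(structure(data.frame(start = integer(0), end = integer(0),
                                branch_type = character(0)),
                     affected_taxa = list(),
                     class = c("recombination_events", "data.frame")))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 8L
  if (any(bad))
    stop("malformed GFF record at line ", lineno[which(bad)[1L]],
         ": fewer than 8 fields")
  start1 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 4L)))
  end1 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 5L)))
  if (anyNA(start1) || anyNA(end1))
    stop("non-integer coordinates at line ",
         lineno[which(is.na(start1) | is.na(end1))[1L]])
  rev_ <- start1 > end1
  if (any(rev_))
    stop("start > end at line ", lineno[which(rev_)[1L]])
  attrs <- vapply(fields, function(f) if (length(f) >= 9L) f[[9L]] else "",
                  "")
  taxa <- lapply(attrs, function(a) {
    m <- regmatches(a, regexec('taxa="([^"]*)"', a))[[1L]]
    if (length(m) < 2L) character(0)
    else strsplit(trimws(m[2L]), "\\s+")[[1L]]
  })
  branch_type <- vapply(seq_along(attrs), function(i) {
    a <- attrs[[i]]
    m <- regmatches(a, regexec('node="([^"]*)"', a))[[1L]]
    if (length(m) >= 2L) {
      if (grepl("->", m[2L], fixed = TRUE) || grepl("internal", m[2L]))
        return("internal")
      return("terminal")
    }
    if (length(taxa[[i]]) > 1L) "internal"
    else if (length(taxa[[i]]) == 1L) "terminal"
    else "unknown"
  }, "")
  out <- data.frame(start = start1 - 1L, end = end1,
                    branch_type = branch_type, stringsAsFactors = FALSE)
  out$affected_taxa <- taxa
  class(out) <- c("recombination_events", "data.frame")
  out
}

#' Write recombination events as a GFF file
#'
#' Inverse of [parse_recombination_gff()]: internal 0-based half-open
#' coordinates are rendered 1-based inclusive.
#'
#' @param events data.frame with `start`, `end` (0-based half-open) and
#'   optionally `branch_type` and `affected_taxa` columns.
#' @param path output path.
#' @param seqname sequence name written in column 1.
#' @export
write_recombination_gff <- function(events, path,
                                    seqname = "concatenated_alignment") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(events))) {
    taxa <- if (!is.null(events$affected_taxa))
      paste(events$affected_taxa[[i]], collapse = " ") else ""
    bt <- if (!is.null(events$branch_type)) events$branch_type[i]
    else "unknown"
    attr_ <- sprintf('node="%s";taxa="%s"', bt, taxa)
    writeLines(paste(seqname, "phagetools", "recombination",
                     events$start[i] + 1L, events$end[i], ".", ".", ".",
                     attr_, sep = "\t"), con)
  }
  invisible(path)
}

#' Map recombination events onto gene coordinates
#'
#' A family counts an event whenever their column intervals share at least
#' one column; one event spanning several genes increments each of them.
#'
#' @param events `recombination_events` (0-based half-open `start`/`end`).
#' @param coords a [concat_gene_coordinates()] map.
#' @return list with `per_family` (data.frame `family_id`,
#'   `recomb_event_count`) and `n_families_hit` (families with >= 1
#'   event).
#' @export
map_events_to_genes <- function(events, coords) {
  stopifnot(inherits(coords, "gene_coordinate_map"))
  total <- attr(coords, "total_length")
  counts <- setNames(integer(nrow(coords)), coords$family_id)
  if (nrow(events)) {
    if (any(events$start < 0 | events$end > total | events$start >= events$end))
      stop("event coordinates outside [0, ", total, ")")
    ev <- IRanges::IRanges(start = events$start + 1L, end = events$end)
    gn <- IRanges::IRanges(start = coords$start + 1L, end = coords$end)
    ov <- IRanges::countOverlaps(gn, ev, minoverlap = 1L)
    counts[] <- ov
  }
  list(per_family = data.frame(family_id = coords$family_id,
                               recomb_event_count = unname(counts),
                               stringsAsFactors = FALSE),
       n_families_hit = sum(counts > 0L))
}
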