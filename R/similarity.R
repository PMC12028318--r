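#' All-versus-all protein similarity search
#'
#' Computes, for every ordered pair of proteins from different genomes (and
#' within genomes, used only for reporting), a local alignment summarised
#' as:
#' * `identity` -- % identical residues over aligned columns;
#' * `coverage_shortest` -- % of the shorter protein's length spanned by
#'   the alignment;
#' * `score` -- the alignment score (bit score for the BLAST engine, raw
#'   Smith-Waterman score for the built-in engine).
#'
#' Two engines are available. `"blast"` shells out to `blastp`
#' (NCBI BLAST+), the standard tool for proteome-scale all-vs-all searches.
#' `"pairwise"` is an exact Smith-Waterman via
#' [Biostrings::pairwiseAlignment()] (BLOSUM62, gap open 11 / extend 1 by
#' default, `X` scored 0 against everything); it is exhaustive and
#' deterministic but only practical for small protein sets, and serves as
#' the reference implementation in the test suite.
#'
#' @param proteomes named list of [proteome()] objects; gene ids must be
#'   unique across the whole set.
#' @param engine `"blast"` or `"pairwise"`.
#' @param gap_opening,gap_extension gap penalties for the `"pairwise"`
#'   engine.
#' @param min_score drop alignments below this raw/bit score (default 0 =
#'   keep all reported).
#' @return a data.frame of class `similarity_hits`: `query_id`,
#'   `target_id`, `query_genome`, `target_genome`, `identity`,
#'   `coverage_shortest`, `score`. Self-hits are removed. Both directions
#'   of every aligned pair are present.
#' @export
all_vs_all_similarity <- function(proteomes,
                                  engine = c("blast", "pairwise"),
                                  gap_opening = 11, gap_extension = 1,
                                  min_score = 0) {
  engine <- match.arg(engine)
  genes <- .gene_table(proteomes)
  if (any(!nzchar(genes$protein))) stop("empty protein sequence")
  hits <- switch(engine,
                 blast = .avva_blast(genes),
                 pairwise = .avva_pairwise(genes, gap_opening, gap_extension))
  hits <- hits[hits$query_id != hits$target_id & hits$score >= min_score, ,
               drop = FALSE]
  rownames(hits) <- NULL
  class(hits) <- c("similarity_hits", "data.frame")
  hits
}

# Flat gene table across proteomes; enforces globally unique gene ids.
.gene_table <- function(proteomes) {
  stopifnot(is.list(proteomes), length(proteomes) > 0L)
  tab <- do.call(rbind, lapply(proteomes, function(p) {
    stopifnot(inherits(p, "proteome"))
    as.data.frame(p)
  }))
  rownames(tab) <- NULL
  if (anyDuplicated(tab$gene_id))
    stop("gene ids must be unique across genomes")
  tab
}

.avva_blast <- function(genes) {
  if (Sys.which("blastp") == "" || Sys.which("makeblastdb") == "")
    stop("BLAST+ (blastp/makeblastdb) not found on PATH; ",
         "use engine = 'pairwise' or provide precomputed hits")
  dir <- tempfile("avva")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  faa <- file.path(dir, "all.faa")
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(setNames(genes$protein, genes$gene_id)), faa)
  db <- file.path(dir, "db")
  out <- file.path(dir, "hits.tsv")
  system2("makeblastdb", c("-in", faa, "-dbtype", "prot", "-out", db),
          stdout = FALSE, stderr = FALSE)
  status <- system2("blastp",
                    c("-query", faa, "-db", db, "-num_threads", "1",
                      "-max_target_seqs", "100000", "-evalue", "1e-3",
                      "-outfmt",
                      shQuote(paste("6 qseqid sseqid pident length",
                                    "qstart qend sstart send qlen slen",
                                    "bitscore")),
                      "-out", out),
                    stdout = FALSE, stderr = "")
  if (status != 0L) stop("blastp failed with status ", status)
  cols <- c("query_id", "target_id", "identity", "alnlen", "qstart", "qend",
            "sstart", "send", "qlen", "slen", "score")
  if (file.size(out) == 0L) {
    hits <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
    hits$query_id <- hits$target_id <- character(0)
  } else {
    hits <- utils::read.delim(out, header = FALSE, col.names = cols,
                              stringsAsFactors = FALSE)
  }
  # one HSP per ordered pair: the best-scoring one
  key <- paste(hits$query_id, hits$target_id, sep = "\r")
  hits <- hits[order(key, -hits$score), , drop = FALSE]
  hits <- hits[!duplicated(paste(hits$query_id, hits$target_id, sep = "\r")), ,
               drop = FALSE]
  span <- ifelse(hits$qlen <= hits$slen,
                 hits$qend - hits$qstart + 1L,
                 hits$send - hits$sstart + 1L)
  hits$coverage_shortest <- 100 * span / pmin(hits$qlen, hits$slen)
  gmap <- setNames(genes$genome_id, genes$gene_id)
  data.frame(query_id = hits$query_id, target_id = hits$target_id,
             query_genome = unname(gmap[hits$query_id]),
             target_genome = unname(gmap[hits$target_id]),
             identity = hits$identity,
             coverage_shortest = hits$coverage_shortest,
             score = hits$score, stringsAsFactors = FALSE)
}

.avva_pairwise <- function(genes, gap_opening, gap_extension) {
  mat <- .blosum62_x0()
  seqs <- Biostrings::AAStringSet(setNames(genes$protein, genes$gene_id))
  n <- length(seqs)
  lens <- nchar(genes$protein)
  res <- vector("list", n)
  for (j in seq_len(n)) {
    if (j == n) break
    pats <- seqs[(j + 1L):n]
    aln <- Biostrings::pairwiseAlignment(
      pattern = pats, subject = seqs[[j]], type = "local",
      substitutionMatrix = mat, gapOpening = gap_opening,
      gapExtension = gap_extension)
    aligned_cols <- Biostrings::nchar(aln)
    ident <- 100 * Biostrings::nmatch(aln) / aligned_cols
    # alignment spans on the original (ungapped) sequences
    ps <- Biostrings::start(Biostrings::subject(aln))
    pe <- Biostrings::end(Biostrings::subject(aln))
    qs <- Biostrings::start(Biostrings::pattern(aln))
    qe <- Biostrings::end(Biostrings::pattern(aln))
    span_q <- qe - qs + 1L
    span_s <- pe - ps + 1L
    short_is_q <- lens[(j + 1L):n] <= lens[j]
    cov <- 100 * ifelse(short_is_q, span_q, span_s) /
      pmin(lens[(j + 1L):n], lens[j])
    res[[j]] <- data.frame(
      query_id = names(pats), target_id = genes$gene_id[j],
      identity = ident, coverage_shortest = cov,
      score = Biostrings::score(aln), stringsAsFactors = FALSE)
  }
  half <- do.call(rbind, res)
  # alignment is symmetric: emit both directions
  other <- half
  other$query_id <- half$target_id
  other$target_id <- half$query_id
  hits <- rbind(half, other)
  hits <- hits[is.finite(hits$score) & hits$score > 0, , drop = FALSE]
  gmap <- setNames(genes$genome_id, genes$gene_id)
  hits$query_genome <- unname(gmap[hits$query_id])
  hits$target_genome <- unname(gmap[hits$target_id])
  hits[, c("query_id", "target_id", "query_genome", "target_genome",
           "identity", "coverage_shortest", "score")]
}

# BLOSUM62 with X scored 0 against everything (ambiguous residues neither
# rewarded nor penalised).
.blosum62_x0 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  mat <- e$BLOSUM62
  mat["X", ] <- 0L
  mat[, "X"] <- 0L
  mat
}

#' Load precomputed similarity hits from a tabular file
#'
#' Reads the tab-separated output of an external search tool (e.g. MMseqs2
#' or BLAST+ `-outfmt 6` extended with sequence lengths). Expected columns,
#' in order or by header: `query`, `target`, `pident` (identity %),
#' `alnlen`, `qlen`, `tlen`, `bits` (score).
#'
#' @param path tabular hits file.
#' @param proteomes named list of [proteome()] objects used to attach
#'   genome ids to the gene ids.
#' @param header whether the file carries a header line.
#' @return a `similarity_hits` data.frame (see [all_vs_all_similarity()]).
#' @export
read_similarity_hits <- function(path, proteomes, header = FALSE) {
  cols <- c("query", "target", "pident", "alnlen", "qlen", "tlen", "bits")
  tab <- utils::read.delim(path, header = header, stringsAsFactors = FALSE)
  if (!header) names(tab) <- cols[seq_len(ncol(tab))]
  stopifnot(all(cols %in% names(tab)))
  genes <- .gene_table(proteomes)
  gmap <- setNames(genes$genome_id, genes$gene_id)
  unknown <- setdiff(unique(c(tab$query, tab$target)), names(gmap))
  if (length(unknown))
    stop("hit file references unknown gene ids: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  hits <- data.frame(query_id = tab$query, target_id = tab$target,
                     query_genome = unname(gmap[tab$query]),
                     target_genome = unname(gmap[tab$target]),
                     identity = tab$pident,
                     coverage_shortest = 100 * tab$alnlen /
                       pmin(tab$qlen, tab$tlen),
                     score = tab$bits, stringsAsFactors = FALSE)
  hits <- hits[hits$query_id != hits$target_id, , drop = FALSE]
  class(hits) <- c("similarity_hits", "data.frame")
  hits
}
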