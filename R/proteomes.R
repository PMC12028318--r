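#' Ordered gene calls of one genome
#'
#' A `proteome` is the ordered set of protein-coding gene calls of one
#' (linearized) genome: identifiers, strand, nucleotide coordinates and the
#' protein sequence. Coordinates are stored 0-based half-open internally;
#' GFF3 I/O converts to and from the 1-based inclusive convention.
#'
#' @param genome_id genome identifier.
#' @param gene_id character vector of unique gene identifiers.
#' @param strand `"+"`/`"-"` per gene.
#' @param start,end integer nucleotide coordinates, 0-based half-open
#'   (`start < end`).
#' @param protein amino-acid sequence per gene.
#' @return a data.frame of class `proteome` sorted by `start`, with columns
#'   `genome_id`, `gene_id`, `rank` (0-based order), `strand`, `start`,
#'   `end`, `protein`.
#' @export
proteome <- function(genome_id, gene_id, strand, start, end, protein) {
  stopifnot(length(gene_id) > 0L)
  if (anyDuplicated(gene_id))
    stop("duplicate gene ids in genome ", genome_id)
  if (any(end <= start))
    stop("gene(s) with end <= start in genome ", genome_id, ": ",
         paste(gene_id[end <= start], collapse = ", "))
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(!nzchar(protein)))
    stop("empty protein sequence for gene(s): ",
         paste(gene_id[!nzchar(protein)], collapse = ", "))
  ord <- order(start, end)
  df <- data.frame(genome_id = genome_id, gene_id = gene_id[ord],
                   rank = seq_along(gene_id) - 1L,
                   strand = strand[ord],
                   start = as.integer(start[ord]), end = as.integer(end[ord]),
                   protein = protein[ord], stringsAsFactors = FALSE)
  rownames(df) <- NULL
  class(df) <- c("proteome", "data.frame")
  df
}

#' Read one annotated genome (GFF3 + protein FASTA, or GenBank)
#'
#' Two routes produce the same [proteome()]:
#' * `gff` + `proteins`: CDS features are taken from the GFF3 file and the
#'   protein sequences from a FASTA keyed by the CDS `ID` attribute;
#' * `genbank`: CDS features with `/translation` qualifiers are parsed from
#'   a GenBank flat file.
#'
#' @param gff path to a GFF3 annotation file.
#' @param proteins path to the matching protein FASTA.
#' @param genbank path to a GenBank flat file (alternative to
#'   `gff`/`proteins`).
#' @param genome_id identifier for the genome; defaults to the annotation
#'   file name without extension.
#' @return a [proteome()].
#' @export
read_annotated_genome <- function(gff = NULL, proteins = NULL,
                                  genbank = NULL, genome_id = NULL) {
  if (!is.null(genbank)) {
    if (is.null(genome_id))
      genome_id <- sub("\\.[^.]*$", "", basename(genbank))
    return(.read_genbank_proteome(genbank, genome_id))
  }
  stopifnot(!is.null(gff), !is.null(proteins))
  if (is.null(genome_id)) genome_id <- sub("\\.[^.]*$", "", basename(gff))
  gr <- rtracklayer::import(gff)
  gr <- gr[gr$type == "CDS"]
  if (length(gr) == 0L) stop("no CDS features in ", gff)
  ids <- as.character(gr$ID)
  if (anyNA(ids) || any(!nzchar(ids)))
    stop("CDS feature(s) without ID attribute in ", gff)
  aa <- Biostrings::readAAStringSet(proteins)
  names(aa) <- sub("\\s.*$", "", names(aa))
  missing <- setdiff(ids, names(aa))
  if (length(missing))
    stop("CDS without obtainable protein sequence: ",
         paste(missing, collapse = ", "))
  proteome(genome_id, gene_id = ids,
           strand = as.character(BiocGenerics::strand(gr)),
           start = BiocGenerics::start(gr) - 1L,
           end = BiocGenerics::end(gr),
           protein = as.character(aa[ids]))
}

#' Read a set of annotated genomes
#'
#' @param annotations character vector of GFF3 or GenBank paths (format
#'   guessed from extension: `.gb`, `.gbk`, `.gbff` are GenBank).
#' @param proteins character vector of protein FASTA paths, parallel to
#'   `annotations` (ignored for GenBank entries).
#' @param genome_ids optional identifiers.
#' @return a named list of [proteome()] objects.
#' @export
read_annotated_genomes <- function(annotations, proteins = NULL,
                                   genome_ids = NULL) {
  is_gb <- grepl("\\.(gb|gbk|gbff)$", annotations, ignore.case = TRUE)
  out <- lapply(seq_along(annotations), function(i) {
    gid <- if (!is.null(genome_ids)) genome_ids[i] else NULL
    if (is_gb[i]) read_annotated_genome(genbank = annotations[i],
                                        genome_id = gid)
    else read_annotated_genome(gff = annotations[i],
                               proteins = proteins[i], genome_id = gid)
  })
  names(out) <- vapply(out, function(p) p$genome_id[1L], "")
  out
}

# Minimal GenBank flat-file CDS extractor: simple `a..b` and
# `complement(a..b)` locations with /translation qualifiers. Compound
# (join) locations are refused by name rather than silently mis-parsed.
.read_genbank_proteome <- function(path, genome_id) {
  lines <- readLines(path)
  feat0 <- grep("^FEATURES", lines)
  if (!length(feat0)) stop("not a GenBank flat file: ", path)
  end0 <- grep("^(ORIGIN|CONTIG|//)", lines)
  end0 <- min(end0[end0 > feat0[1L]], length(lines) + 1L)
  block <- lines[(feat0[1L] + 1L):(end0 - 1L)]

  key_line <- grepl("^ {5}\\S", block)
  idx <- which(key_line & grepl("^ {5}CDS\\s", block))
  if (!length(idx)) stop("no CDS features in ", path)
  key_pos <- which(key_line)

  recs <- lapply(idx, function(i) {
    nxt <- key_pos[key_pos > i]
    last <- if (length(nxt)) min(nxt) - 1L else length(block)
    sub_block <- block[i:last]
    loc <- sub("^ {5}CDS\\s+", "", sub_block[1L])
    txt <- paste(gsub("^\\s+", "", sub_block[-1L]), collapse = "\n")

    strand <- "+"
    if (grepl("^complement\\(", loc)) {
      strand <- "-"
      loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
    }
    if (!grepl("^<?\\d+\\.\\.>?\\d+$", loc))
      stop("unsupported CDS location '", loc, "' in ", path)
    coords <- as.integer(gsub("[<>]", "", strsplit(loc, "\\.\\.")[[1L]]))

    get_q <- function(name) {
      m <- regmatches(txt, regexec(paste0('/', name, '="([^"]*)"'), txt))[[1L]]
      if (length(m) < 2L) NA_character_ else gsub("\\s", "", m[2L])
    }
    id <- get_q("locus_tag")
    if (is.na(id)) id <- get_q("protein_id")
    aa <- get_q("translation")
    list(id = id, strand = strand, start = coords[1L] - 1L,
         end = coords[2L], protein = aa)
  })
  ids <- vapply(recs, `[[`, "", "id")
  aas <- vapply(recs, `[[`, "", "protein")
  if (anyNA(aas))
    stop("CDS without /translation in ", path, ": ",
         paste(ids[is.na(aas)], collapse = ", "))
  if (anyNA(ids)) ids[is.na(ids)] <- paste0(genome_id, "_cds",
                                            which(is.na(ids)))
  proteome(genome_id, gene_id = ids,
           strand = vapply(recs, `[[`, "", "strand"),
           start = vapply(recs, `[[`, 0L, "start"),
           end = vapply(recs, `[[`, 0L, "end"),
           protein = aas)
}

#' Write a proteome as GFF3 + protein FASTA
#'
#' Emits the two files [read_annotated_genome()] reads back: a GFF3 with
#' one CDS feature per gene (1-based inclusive coordinates) and a protein
#' FASTA keyed by gene id.
#'
#' @param p a [proteome()].
#' @param gff,proteins output paths.
#' @export
write_proteome <- function(p, gff, proteins) {
  stopifnot(inherits(p, "proteome"))
  gr <- GenomicRanges::GRanges(
    seqnames = p$genome_id[1L],
    ranges = IRanges::IRanges(start = p$start + 1L, end = p$end),
    strand = p$strand)
  gr$type <- "CDS"
  gr$source <- "phagetools"
  gr$ID <- p$gene_id
  gr$phase <- 0L
  rtracklayer::export(gr, gff, format = "gff3")
  aa <- Biostrings::AAStringSet(setNames(p$protein, p$gene_id))
  Biostrings::writeXStringSet(aa, proteins)
  invisible(c(gff = gff, proteins = proteins))
}
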