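#' Cross-infection titer matrix
#'
#' A `titer_matrix` stores the outcome of a phage x host cross-infection
#' assay: a positive titer (PFU/ml) where productive infection was observed,
#' or one of three categorical states where it was not:
#' `"resistant"` (no clearing zone, no plaques), `"impaired"` (clearing zone
#' at high titer but no viable progeny, a sign of adsorption without
#' productive infection) and `"not_assessed"`.
#'
#' @param values numeric matrix, phages in rows and hosts in columns;
#'   strictly positive where a titer was measured, `NA` elsewhere.
#' @param states character matrix of the same dimension with entries in
#'   `c("titer", "resistant", "impaired", "not_assessed")`. May be omitted,
#'   in which case every non-`NA` value is `"titer"` and every `NA` cell is
#'   `"resistant"`.
#' @param phage_ids,host_ids optional identifier vectors; default to the
#'   dimnames of `values`.
#' @param provenance free-text source tag.
#'
#' @return an object of class `titer_matrix` with fields `phage_ids`,
#'   `host_ids`, `values`, `states` and `provenance`.
#' @export
titer_matrix <- function(values, states = NULL, phage_ids = rownames(values),
                         host_ids = colnames(values), provenance = "") {
  values <- as.matrix(values)
  if (is.null(phage_ids) || is.null(host_ids))
    stop("phage and host identifiers are required (dimnames or explicit ids)")
  phage_ids <- as.character(phage_ids)
  host_ids <- as.character(host_ids)
  if (anyDuplicated(phage_ids)) stop("duplicate phage ids")
  if (anyDuplicated(host_ids)) stop("duplicate host ids")
  if (nrow(values) != length(phage_ids) || ncol(values) != length(host_ids))
    stop("matrix dimensions do not match the id vectors")
  if (is.null(states)) {
    states <- matrix("resistant", nrow(values), ncol(values))
    states[!is.na(values)] <- "titer"
  }
  states <- as.matrix(states)
  if (!identical(dim(states), dim(values)))
    stop("'states' and 'values' dimensions differ")
  ok <- states %in% c("titer", "resistant", "impaired", "not_assessed")
  if (!all(ok))
    stop("unknown state(s): ", paste(unique(states[!ok]), collapse = ", "))
  if (any(states == "titer" & (is.na(values) | values <= 0)))
    stop("'titer' cells must carry a strictly positive PFU/ml value")
  if (any(states != "titer" & !is.na(values)))
    stop("non-titer cells must not carry a value")
  dimnames(values) <- dimnames(states) <- list(phage_ids, host_ids)
  structure(
    list(phage_ids = phage_ids, host_ids = host_ids,
         values = values, states = states, provenance = provenance),
    class = "titer_matrix"
  )
}

#' @export
print.titer_matrix <- function(x, ...) {
  cat("Cross-infection titer matrix: ", length(x$phage_ids), " phages x ",
      length(x$host_ids), " hosts\n", sep = "")
  tab <- table(factor(x$states,
                      c("titer", "resistant", "impaired", "not_assessed")))
  cat("  cells:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  if (nzchar(x$provenance)) cat("  source:", x$provenance, "\n")
  invisible(x)
}

#' @export
dim.titer_matrix <- function(x) dim(x$values)

#' Read a cross-infection matrix from a delimited file
#'
#' The table must be rectangular with one axis of identifiers in the header
#' row and the other in the first column. Cells are either positive numbers
#' (PFU/ml) or one of three tokens encoding the categorical states.
#'
#' @param path path to a delimited text file.
#' @param sep field separator (default tab).
#' @param phages_as_rows if `TRUE` (default) rows are phages and columns are
#'   hosts; set `FALSE` for the transposed layout.
#' @param tokens named character vector mapping the three categorical states
#'   to their file tokens; names must be `resistant`, `impaired`,
#'   `not_assessed`.
#' @param zero_as_resistant treat a numeric `0` cell as `resistant` instead
#'   of raising an error.
#' @param provenance free-text source tag stored on the result.
#'
#' @return a [titer_matrix()].
#' @export
read_titer_matrix <- function(path, sep = "\t", phages_as_rows = TRUE,
                              tokens = c(resistant = "R", impaired = "I",
                                         not_assessed = "NA"),
                              zero_as_resistant = FALSE,
                              provenance = basename(path)) {
  stopifnot(all(c("resistant", "impaired", "not_assessed") %in% names(tokens)))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("matrix file needs a header and at least one row")
  cells <- strsplit(lines, sep, fixed = TRUE)
  header <- cells[[1L]]
  body <- cells[-1L]
  ncol_expected <- length(header)
  widths <- lengths(body)
  if (any(widths != ncol_expected))
    stop("ragged table: row(s) ", paste(which(widths != ncol_expected) + 1L,
                                        collapse = ", "),
         " do not have ", ncol_expected, " fields")
  col_ids <- header[-1L]
  row_ids <- vapply(body, `[[`, "", 1L)
  raw <- t(vapply(body, function(r) r[-1L], character(ncol_expected - 1L)))
  if (anyDuplicated(row_ids) || anyDuplicated(col_ids))
    stop("duplicate identifiers in matrix file")

  states <- matrix(NA_character_, nrow(raw), ncol(raw))
  values <- matrix(NA_real_, nrow(raw), ncol(raw))
  for (st in c("resistant", "impaired", "not_assessed"))
    states[raw == tokens[[st]]] <- st
  todo <- is.na(states)
  num <- suppressWarnings(as.numeric(raw[todo]))
  if (anyNA(num))
    stop("unparseable cell value(s): ",
         paste(unique(raw[todo][is.na(num)]), collapse = ", "))
  if (zero_as_resistant) {
    zero <- todo
    zero[todo] <- num == 0
    states[zero] <- "resistant"
    todo <- todo & !zero
    num <- num[num != 0]
  }
  if (any(num <= 0))
    stop("non-positive titer value(s): ", paste(unique(num[num <= 0]),
                                                collapse = ", "))
  states[todo] <- "titer"
  values[todo] <- num

  if (!phages_as_rows) {
    states <- t(states); values <- t(values)
    tmp <- row_ids; row_ids <- col_ids; col_ids <- tmp
  }
  titer_matrix(values, states, phage_ids = row_ids, host_ids = col_ids,
               provenance = provenance)
}

#' Write a cross-infection matrix to a delimited file
#'
#' Inverse of [read_titer_matrix()]: categorical states are rendered with
#' the given tokens, titers with full precision.
#'
#' @inheritParams read_titer_matrix
#' @param x a [titer_matrix()].
#' @export
write_titer_matrix <- function(x, path, sep = "\t",
                               tokens = c(resistant = "R", impaired = "I",
                                          not_assessed = "NA")) {
  stopifnot(inherits(x, "titer_matrix"))
  out <- matrix("", nrow(x$values), ncol(x$values))
  is_t <- x$states == "titer"
  out[is_t] <- format(x$values[is_t], scientific = TRUE, trim = TRUE,
                      digits = 15)
  for (st in c("resistant", "impaired", "not_assessed"))
    out[x$states == st] <- tokens[[st]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("id", x$host_ids), collapse = sep), con)
  for (i in seq_along(x$phage_ids))
    writeLines(paste(c(x$phage_ids[i], out[i, ]), collapse = sep), con)
  invisible(path)
}
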