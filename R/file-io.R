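#' Write a character matrix to NEXUS, relaxed PHYLIP or TNT
#'
#' NEXUS output uses `DATATYPE=STANDARD SYMBOLS="0123"`; the TNT writer emits
#' an `xread` block.  These files are interchange formats only: no external
#' program is invoked by the pipeline.
#'
#' @param x a [morpho_matrix].
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_nexus <- function(x, file) {
  st <- x$states
  lines <- c(
    "#NEXUS",
    "BEGIN DATA;",
    sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(st), ncol(st)),
    "  FORMAT DATATYPE=STANDARD SYMBOLS=\"0123\" MISSING=? GAP=-;",
    "  MATRIX")
  rows <- sprintf("    %-12s %s", rownames(st),
                  apply(st, 1, paste, collapse = ""))
  writeLines(c(lines, rows, "  ;", "END;"), file)
  invisible(file)
}

#' @rdname write_nexus
#' @export
write_phylip <- function(x, file) {
  st <- x$states
  rows <- sprintf("%s  %s", rownames(st), apply(st, 1, paste, collapse = ""))
  writeLines(c(sprintf("%d %d", nrow(st), ncol(st)), rows), file)
  invisible(file)
}

#' @rdname write_nexus
#' @export
write_tnt <- function(x, file) {
  st <- x$states
  rows <- sprintf("%s %s", rownames(st), apply(st, 1, paste, collapse = ""))
  writeLines(c("xread", sprintf("%d %d", ncol(st), nrow(st)), rows, ";"),
             file)
  invisible(file)
}

#' Read a discrete character matrix
#'
#' `read_nexus_matrix()` reads a NEXUS standard-datatype matrix (through
#' [ape::read.nexus.data()]); `read_phylip_matrix()` reads relaxed PHYLIP
#' (name, whitespace, states on one line).  Characters whose observed states
#' exceed 1 are typed multistate unless all states are within \{0,1\}.
#'
#' @param file input path.
#' @return a [morpho_matrix].
#' @export
read_nexus_matrix <- function(file) {
  raw <- ape::read.nexus.data(file)
  states <- do.call(rbind, lapply(raw, function(x) as.integer(x)))
  rownames(states) <- names(raw)
  .matrix_from_states(states)
}

#' @rdname read_nexus_matrix
#' @export
read_phylip_matrix <- function(file) {
  lines <- trimws(readLines(file))
  lines <- lines[nzchar(lines)]
  hdr <- as.integer(strsplit(lines[1], "\\s+")[[1]])
  body <- strsplit(lines[-1], "\\s+")
  states <- do.call(rbind, lapply(body, function(p) {
    as.integer(strsplit(p[2], "")[[1]])
  }))
  rownames(states) <- vapply(body, `[`, "", 1)
  if (nrow(states) != hdr[1] || ncol(states) != hdr[2]) {
    stop("PHYLIP header does not match matrix dimensions")
  }
  .matrix_from_states(states)
}

.matrix_from_states <- function(states) {
  char_type <- ifelse(apply(states, 2, max) <= 1L, "binary", "multistate")
  morpho_matrix(states, char_type)
}
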