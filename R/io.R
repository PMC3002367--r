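# FASTA/CLUSTAL input and output, core-column masks, and SP/TC accuracy
# scoring against a reference alignment.

#' Read protein sequences from FASTA
#'
#' Lower-case residues are upper-cased with a warning; duplicate ids are an
#' error. CRLF line endings are accepted.
#'
#' @param path FASTA file.
#' @return Named character vector of sequences (possibly gapped).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  seqs <- as.character(x)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence ids in ", path)
  if (any(grepl("[a-z]", seqs))) {
    warning("lower-case residues upper-cased")
    seqs <- toupper(seqs)
  }
  seqs
}

#' Read a multiple alignment from aligned FASTA or CLUSTAL
#'
#' @param path Alignment file.
#' @param format `"auto"` (sniff the first line), `"fasta"` or `"clustal"`.
#' @return An [msa].
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "clustal")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (grepl("^CLUSTAL", first)) "clustal" else "fasta"
  }
  if (format == "fasta") {
    seqs <- read_fasta(path)
    if (length(unique(nchar(seqs))) > 1L)
      stop("ragged aligned FASTA: sequences differ in length")
    return(msa(seqs))
  }
  lines <- readLines(path)
  lines <- lines[-1L] # CLUSTAL header
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^\\s", lines)] # drop conservation lines
  parts <- strsplit(trimws(lines), "\\s+")
  ids <- vapply(parts, `[`, "", 1L)
  chunk <- vapply(parts, `[`, "", 2L)
  seqs <- vapply(unique(ids), function(id)
    paste(chunk[ids == id], collapse = ""), "")
  if (any(grepl("[a-z]", seqs))) {
    warning("lower-case residues upper-cased")
    seqs <- toupper(seqs)
  }
  msa(seqs)
}

#' Write sequences or an alignment as FASTA
#'
#' @param x Named character vector or an [msa].
#' @param path Output file.
#' @param width Line width.
#' @export
write_fasta <- function(x, path, width = 60L) {
  if (inherits(x, "msa")) x <- as.character(x)
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(x)) {
    writeLines(paste0(">", id), con)
    s <- x[[id]]
    if (nchar(s) == 0L) next
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Write an alignment in CLUSTAL format
#'
#' @param aln An [msa].
#' @param path Output file.
#' @param width Block width.
#' @export
write_clustal <- function(aln, path, width = 60L) {
  s <- as.character(aln)
  ids <- names(s)
  idw <- max(nchar(ids)) + 3L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("CLUSTAL W multiple sequence alignment", con)
  writeLines("", con)
  L <- unique(nchar(s))
  for (from in seq(1L, max(L, 1L), by = width)) {
    for (id in ids)
      writeLines(paste0(formatC(id, width = -idw),
                        substr(s[[id]], from, min(from + width - 1L, L))),
                 con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read a core-column mask
#'
#' Plain text, one 1-based reference-alignment column index per line.
#'
#' @param path Mask file.
#' @return Sorted integer vector of column indices.
#' @export
read_core_mask <- function(path) {
  v <- as.integer(readLines(path))
  if (any(is.na(v)) || any(v < 1L)) stop("mask must contain positive integers")
  sort(unique(v))
}

# residue-ordinal matrix: entry [r, col] = ordinal of the residue of row r
# in column col, NA for gaps
ordinal_matrix <- function(m) {
  t(apply(m != GAP, 1L, function(ng) {
    o <- cumsum(ng)
    o[!ng] <- NA_integer_
    o
  }))
}

#' SP and TC accuracy of an alignment against a reference
#'
#' SP is the number of reference residue pairs correctly aligned in the
#' test alignment divided by the number of aligned residue pairs in the
#' reference; TC is the number of reference columns whose non-gap cells
#' (as sequence/position sets) are reproduced exactly, divided by the
#' number of reference columns. Both are sensitivity-style: pairs or
#' columns the test aligns but the reference does not carry no penalty.
#' With a core-column mask, `feature_SP`/`feature_TC` restrict the
#' reference pairs and columns to the masked columns.
#'
#' @param test,ref [msa] objects (or gapped named character vectors) over
#'   the same sequences.
#' @param mask Optional integer vector of 1-based reference column indices.
#' @return List with `SP`, `TC` (and `feature_SP`, `feature_TC` when a mask
#'   is given) plus the counts behind each ratio. Ratios with a zero
#'   denominator are `NA`.
#' @export
sp_tc <- function(test, ref, mask = NULL) {
  if (!inherits(test, "msa")) test <- msa(test)
  if (!inherits(ref, "msa")) ref <- msa(ref)
  mt <- as.matrix(test); mr <- as.matrix(ref)
  ids <- rownames(mr)
  if (!setequal(ids, rownames(mt)))
    stop("test and reference alignments have different sequences")
  mt <- mt[ids, , drop = FALSE]
  dt <- degap(msa(mt)); dr <- degap(msa(mr))
  if (!identical(dt, dr))
    stop("test and reference disagree on the ungapped sequences")
  ot <- ordinal_matrix(mt); or <- ordinal_matrix(mr)
  k <- length(ids)
  # test column index of each (row, ordinal)
  colof <- matrix(NA_integer_, k, max(1L, max(ot, na.rm = TRUE)))
  for (r in seq_len(k)) {
    ng <- which(!is.na(ot[r, ]))
    colof[r, ot[r, ng]] <- ng
  }
  score_cols <- function(cols) {
    pairs_total <- 0; pairs_ok <- 0; cols_ok <- 0
    for (cc in cols) {
      rows <- which(!is.na(or[, cc]))
      if (length(rows) >= 2L) {
        for (ai in seq_len(length(rows) - 1L)) for (bi in (ai + 1L):length(rows)) {
          r1 <- rows[ai]; r2 <- rows[bi]
          pairs_total <- pairs_total + 1
          if (colof[r1, or[r1, cc]] == colof[r2, or[r2, cc]])
            pairs_ok <- pairs_ok + 1
        }
      }
      if (length(rows)) {
        tcols <- colof[cbind(rows, or[rows, cc])]
        if (length(unique(tcols)) == 1L) {
          # exact column identity: the test column must not align extra rows
          extra <- which(!is.na(ot[, tcols[1L]]))
          if (identical(sort(extra), sort(rows))) cols_ok <- cols_ok + 1
        }
      }
    }
    list(pairs_total = pairs_total, pairs_ok = pairs_ok,
         cols_total = length(cols), cols_ok = cols_ok)
  }
  all_cols <- seq_len(ncol(mr))
  a <- score_cols(all_cols)
  out <- list(SP = if (a$pairs_total) a$pairs_ok / a$pairs_total else NA_real_,
              TC = if (a$cols_total) a$cols_ok / a$cols_total else NA_real_,
              counts = a)
  if (!is.null(mask)) {
    if (any(mask > ncol(mr))) stop("mask indices exceed reference length")
    f <- score_cols(mask)
    out$feature_SP <- if (f$pairs_total) f$pairs_ok / f$pairs_total else NA_real_
    out$feature_TC <- if (f$cols_total) f$cols_ok / f$cols_total else NA_real_
    out$feature_counts <- f
  }
  out
}
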