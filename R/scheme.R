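# Scoring scheme: substitution matrix, affine gap scores, indel pattern
# matrices, mode and sequence weights.

#' The twenty standard amino-acid one-letter codes
#'
#' Residue alphabet used throughout the package. Gaps are written `"-"`.
#' @export
AA_RESIDUES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

GAP <- "-"

# Row patterns over two adjoining columns, in fixed order. "-" = gap,
# "*" = residue; first character left column, second character right column.
INDEL_PATTERNS <- c("--", "-*", "*-", "**")

#' Create a scoring scheme
#'
#' Bundles everything needed to score alignments and run the dynamic
#' programmes: a symmetric residue similarity matrix, affine gap scores
#' (negative numbers added to the score), the indel pattern matrix derived
#' from them, the scoring mode and optional per-sequence weights.
#'
#' @param matrix Substitution matrix: `NULL` for BLOSUM62 (taken from
#'   Biostrings and restricted to the 20 standard residues), a path to an
#'   NCBI-format matrix file, or a symmetric numeric matrix with residue
#'   dimnames.
#' @param gap_open Gap opening score `OP` (<= 0). A gap run of length L in a
#'   pairwise alignment scores `OP + (L-1)*EX`.
#' @param gap_ext Gap extension score `EX` (<= 0, >= `gap_open`).
#' @param mode `"pairwise"` for the sum-of-pairs similarity and pairwise
#'   column-pair indel scoring, or `"clustalw"` for the ClustalW-imitation
#'   scheme (cross-group similarities only, one gap penalty per full-column
#'   insertion/deletion event).
#' @param weights Optional named positive sequence weights. Usually computed
#'   from the guide tree by [sequence_weights()]; rescaled to mean 1.
#' @param gap_cross Score for the ambiguous `"--"` vs `"-*"`/`"*-"` pattern
#'   pair in the indel matrix: half the opening score (default), the
#'   extension score, or half of it.
#' @return An object of class `"retalign_scheme"`: a list with elements
#'   `s` (similarity matrix), `OP`, `EX`, `mode`, `weights`, `T4` (the 4x4
#'   symmetric indel pattern matrix used by [internal_score()]) and `G4`
#'   (its left-attributed variant used by the dynamic programmes; see the
#'   package vignette).
#' @examples
#' sch <- retalign_scheme()
#' sch$s["A", "A"]
#' sch$T4
#' @export
retalign_scheme <- function(matrix = NULL, gap_open = -10, gap_ext = -1,
                            mode = c("pairwise", "clustalw"),
                            weights = NULL,
                            gap_cross = c("half_open", "ext", "half_ext")) {
  mode <- match.arg(mode)
  gap_cross <- match.arg(gap_cross)
  if (!is.numeric(gap_open) || !is.numeric(gap_ext))
    stop("gap scores must be numeric")
  if (gap_open > gap_ext || gap_ext > 0)
    stop("gap scores must satisfy gap_open <= gap_ext <= 0")

  if (is.null(matrix)) {
    s <- default_blosum62()
  } else if (is.character(matrix) && length(matrix) == 1L) {
    s <- read_score_matrix(matrix)
  } else if (is.matrix(matrix)) {
    s <- check_score_matrix(matrix)
  } else {
    stop("'matrix' must be NULL, a file path, or a numeric matrix")
  }

  if (!is.null(weights)) {
    if (is.null(names(weights)) || any(!is.finite(weights)) || any(weights <= 0))
      stop("weights must be named, finite and positive")
    weights <- weights / mean(weights)
  }

  scheme <- list(
    s = s,
    OP = gap_open,
    EX = gap_ext,
    mode = mode,
    weights = weights,
    gap_cross = gap_cross,
    T4 = indel_matrix(gap_open, gap_ext, gap_cross),
    G4 = NULL
  )
  scheme$G4 <- attributed_indel_matrix(scheme$T4, gap_open)
  class(scheme) <- "retalign_scheme"
  scheme
}

#' @export
print.retalign_scheme <- function(x, ...) {
  cat("Reticular alignment scoring scheme\n")
  cat(sprintf("  residues: %d  gap open: %g  gap ext: %g  mode: %s\n",
              nrow(x$s), x$OP, x$EX, x$mode))
  cat(sprintf("  weights: %s\n",
              if (is.null(x$weights)) "none (all 1)"
              else paste0(length(x$weights), " sequences, mean 1")))
  invisible(x)
}

default_blosum62 <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  m <- env$BLOSUM62[AA_RESIDUES, AA_RESIDUES]
  storage.mode(m) <- "double"
  m
}

check_score_matrix <- function(m) {
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("substitution matrix must have residue dimnames")
  if (!identical(rownames(m), colnames(m)))
    stop("substitution matrix row and column names differ")
  if (!isTRUE(all.equal(m, t(m))))
    stop("substitution matrix is not symmetric")
  storage.mode(m) <- "double"
  m
}

#' Read a substitution matrix in NCBI text format
#'
#' Parses the plain-text matrix format distributed with BLAST: `#` comment
#' lines, a header row of residue codes, then one row per residue. Asymmetric
#' matrices are rejected.
#'
#' @param path Path to the matrix file.
#' @return A symmetric numeric matrix with residue dimnames.
#' @export
read_score_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("not a matrix file: ", path)
  header <- strsplit(trimws(lines[1L]), "\\s+")[[1]]
  body <- strsplit(trimws(lines[-1L]), "\\s+")
  rows <- vapply(body, `[`, "", 1L)
  vals <- t(vapply(body, function(x) as.numeric(x[-1L]),
                   numeric(length(header))))
  if (any(is.na(vals))) stop("non-numeric entries in matrix file: ", path)
  dimnames(vals) <- list(rows, header)
  vals <- vals[header, header, drop = FALSE] # enforce common order
  check_score_matrix(vals)
}

#' Write a substitution matrix in NCBI text format
#'
#' @param m Symmetric numeric matrix with residue dimnames.
#' @param path Output file.
#' @export
write_score_matrix <- function(m, path) {
  m <- check_score_matrix(m)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(" ", paste(colnames(m), collapse = "  ")), con)
  for (r in rownames(m))
    writeLines(paste(r, paste(format(m[r, ], trim = TRUE), collapse = " ")),
               con)
  invisible(path)
}

# The 4x4 indel pattern matrix. Patterns describe one row over two adjoining
# columns; entries score a pair of rows. OP is split half/half between the
# opening and closing transition of an interior gap run, so that a run of
# length L accumulates OP + (L-1)*EX; "--" against "**" extends, "-*" against
# "*-" opens a fresh run in both rows. The "--" vs one-sided patterns are the
# ambiguous case: OP/2 by default, with EX and EX/2 as alternatives.
indel_matrix <- function(OP, EX, gap_cross = "half_open") {
  amb <- switch(gap_cross, half_open = OP / 2, ext = EX, half_ext = EX / 2)
  T4 <- matrix(0, 4, 4, dimnames = list(INDEL_PATTERNS, INDEL_PATTERNS))
  T4["--", "-*"] <- T4["-*", "--"] <- amb
  T4["--", "*-"] <- T4["*-", "--"] <- amb
  T4["--", "**"] <- T4["**", "--"] <- EX
  T4["-*", "*-"] <- T4["*-", "-*"] <- OP
  T4["-*", "**"] <- T4["**", "-*"] <- OP / 2
  T4["*-", "**"] <- T4["**", "*-"] <- OP / 2
  T4
}

# Left-attributed variant of T4: G4[p,q] = T4[p,q] + phi(left) - phi(right)
# where phi is a potential on the gap state of the row pair in one column
# (0 for zero or two gaps, -OP/2 for exactly one). The shift telescopes away
# along complete alignments (virtual all-residue boundary columns on both
# sides), so path totals are unchanged, while per-cell prefix scores match
# the classical affine convention that charges the whole opening score at
# the first gap character.
attributed_indel_matrix <- function(T4, OP) {
  phi <- function(a, b) if (xor(a == "-", b == "-")) -OP / 2 else 0
  G4 <- T4
  for (p in INDEL_PATTERNS) for (q in INDEL_PATTERNS) {
    G4[p, q] <- T4[p, q] +
      phi(substr(p, 1, 1), substr(q, 1, 1)) -
      phi(substr(p, 2, 2), substr(q, 2, 2))
  }
  G4
}

# weights aligned to a vector of sequence ids; 1s when the scheme has none
scheme_weights <- function(scheme, ids) {
  if (is.null(scheme$weights)) return(rep(1, length(ids)))
  w <- scheme$weights[ids]
  if (any(is.na(w)))
    stop("scheme weights missing for: ",
         paste(ids[is.na(w)], collapse = ", "))
  unname(w)
}

residue_check <- function(chars, scheme) {
  ok <- chars %in% c(rownames(scheme$s), GAP)
  if (!all(ok))
    stop("residue(s) without a matrix entry: ",
         paste(unique(chars[!ok]), collapse = ", "))
  invisible(TRUE)
}
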