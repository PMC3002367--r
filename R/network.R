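# The network-of-alignments data structure: a DAG of alignment columns with
# unique Start/End whose every Start->End path is a valid multiple alignment,
# plus the msa (single alignment) container.

#' Multiple sequence alignment container
#'
#' A thin S3 container: a character matrix of residues and `"-"` gaps with
#' one row per sequence, plus an optional per-column M/I/D state tag
#' (relative to the two groups most recently aligned).
#'
#' @param cols Character matrix (rows = sequences, columns = alignment
#'   columns) with rownames, or a named character vector of equal-length
#'   gapped strings.
#' @param state Optional character vector of `"M"`/`"I"`/`"D"` column states.
#' @return An object of class `"msa"`.
#' @export
msa <- function(cols, state = NULL) {
  if (is.character(cols) && !is.matrix(cols)) {
    ids <- names(cols)
    if (is.null(ids)) stop("sequences must be named")
    if (length(unique(nchar(cols))) > 1L)
      stop("aligned sequences must have equal length")
    cols <- matrix(unlist(strsplit(cols, ""), use.names = FALSE),
                   nrow = length(ids), byrow = TRUE,
                   dimnames = list(ids, NULL))
  }
  if (!is.matrix(cols)) stop("'cols' must be a character matrix")
  if (is.null(rownames(cols))) stop("alignment rows must be named")
  if (ncol(cols) > 0L && any(colSums(cols != GAP) == 0L))
    stop("alignment contains an all-gap column")
  structure(list(ids = rownames(cols), cols = cols, state = state),
            class = "msa")
}

#' @export
as.matrix.msa <- function(x, ...) x$cols

#' @export
as.character.msa <- function(x, ...) {
  out <- apply(x$cols, 1L, paste, collapse = "")
  if (ncol(x$cols) == 0L) out <- setNames(rep("", length(x$ids)), x$ids)
  out
}

#' @export
print.msa <- function(x, width = 60, ...) {
  L <- ncol(x$cols)
  cat(sprintf("Multiple sequence alignment: %d sequences, %d columns\n",
              length(x$ids), L))
  idw <- max(nchar(x$ids), 0L)
  for (from in seq(1L, max(L, 1L), by = width)) {
    to <- min(from + width - 1L, L)
    if (L == 0L) break
    for (r in seq_along(x$ids))
      cat(sprintf(paste0("%-", idw, "s %s\n"), x$ids[r],
                  paste(x$cols[r, from:to], collapse = "")))
    cat("\n")
  }
  invisible(x)
}

#' Strip gaps from an alignment row-wise
#'
#' @param aln An [msa].
#' @return Named character vector of ungapped sequences.
#' @export
degap <- function(aln) {
  m <- as.matrix(aln)
  out <- vapply(seq_len(nrow(m)),
                function(r) paste(m[r, m[r, ] != GAP], collapse = ""), "")
  setNames(out, rownames(m))
}

new_aln_network <- function(ids, cols, state, pred, succ, start_succ,
                            end_pred, origin = NULL, meta = list()) {
  structure(list(ids = ids, cols = cols, state = state, pred = pred,
                 succ = succ, start_succ = start_succ, end_pred = end_pred,
                 origin = origin, meta = meta),
            class = "aln_network")
}

n_vertices <- function(net) ncol(net$cols)

#' Turn one sequence into a trivial linear network
#'
#' A single sequence is a formal network of alignments: a chain
#' `Start -> c1 -> ... -> cL -> End` with one single-residue column per
#' position. An empty sequence yields the degenerate `Start -> End` network
#' (accepted with a warning).
#'
#' @param sequence A character string of residues.
#' @param id Sequence identifier (row name).
#' @return An `"aln_network"`.
#' @examples
#' net <- seq_network("AVGQ", "seq1")
#' count_alignments(net) # 1
#' @export
seq_network <- function(sequence, id) {
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  if (L == 0L) {
    warning("empty sequence '", id, "': degenerate Start->End network")
    return(new_aln_network(id, matrix(character(), 1L, 0L,
                                      dimnames = list(id, NULL)),
                           character(), list(), list(),
                           start_succ = 1L, end_pred = 0L))
  }
  cols <- matrix(chars, nrow = 1L, dimnames = list(id, NULL))
  new_aln_network(
    ids = id, cols = cols, state = rep("M", L),
    pred = as.list(0:(L - 1L)), succ = as.list(2:(L + 1L)),
    start_succ = 1L, end_pred = L,
    origin = data.frame(i = seq_len(L), j = NA_integer_,
                        state = rep("M", L), b = NA_real_))
}

#' Validate a network of alignments
#'
#' Diagnostic check of the structural invariants: the stored order is a
#' linear extension (every edge goes forward), Start is the unique source and
#' End the unique sink, every vertex is reachable from Start and co-reachable
#' from End (no dead ends), predecessor/successor lists mirror each other,
#' no column is all-gap, and all Start->End paths spell the same sequence in
#' every row (checked completely through the per-vertex consumed-prefix
#' invariant). Violations are reported, not raised.
#'
#' @param net An `"aln_network"`.
#' @param sequences Optional named character vector; when given, paths are
#'   additionally required to spell exactly these sequences.
#' @return A list with elements `valid` (logical) and `violations`
#'   (character vector, empty when valid).
#' @export
validate_network <- function(net, sequences = NULL) {
  v <- character()
  V <- n_vertices(net)
  k <- length(net$ids)
  END <- V + 1L
  if (length(net$pred) != V || length(net$succ) != V ||
      length(net$state) != V)
    return(list(valid = FALSE,
                violations = "inconsistent component lengths"))

  if (V == 0L) {
    ok <- identical(net$start_succ, 1L) || identical(net$start_succ, END)
    if (!ok) v <- c(v, "degenerate network without Start->End edge")
    return(list(valid = length(v) == 0L, violations = v))
  }

  if (any(colSums(net$cols != GAP) == 0L))
    v <- c(v, "all-gap column present")

  # edge direction / linear extension, and mirror consistency
  for (i in seq_len(V)) {
    if (any(net$pred[[i]] >= i)) v <- c(v, sprintf("edge into %d not forward in order", i))
    if (any(net$succ[[i]] <= i)) v <- c(v, sprintf("edge out of %d not forward in order", i))
    for (p in net$pred[[i]]) if (p > 0L && !(i %in% net$succ[[p]]))
      v <- c(v, sprintf("pred/succ mismatch %d->%d", p, i))
  }
  if (any(net$start_succ < 1L | net$start_succ > V))
    v <- c(v, "Start edge to nonexistent vertex")
  for (s in net$start_succ) if (s <= V && !(0L %in% net$pred[[s]]))
    v <- c(v, sprintf("pred/succ mismatch Start->%d", s))
  for (e in net$end_pred) if (e >= 1L && !(END %in% net$succ[[e]]))
    v <- c(v, sprintf("pred/succ mismatch %d->End", e))

  # unique source/sink: every real vertex has a predecessor and a successor
  no_pred <- which(lengths(net$pred) == 0L)
  no_succ <- which(lengths(net$succ) == 0L)
  if (length(no_pred)) v <- c(v, sprintf("dead end: vertex %d has no predecessor", no_pred))
  if (length(no_succ)) v <- c(v, sprintf("dead end: vertex %d has no successor", no_succ))

  # reachability from Start / co-reachability of End
  reach <- rep(FALSE, V)
  reach[net$start_succ[net$start_succ <= V]] <- TRUE
  for (i in seq_len(V)) if (reach[i])
    for (s in net$succ[[i]]) if (s <= V) reach[s] <- TRUE
  if (!all(reach)) v <- c(v, sprintf("vertex %d unreachable from Start", which(!reach)))
  coreach <- rep(FALSE, V)
  coreach[net$end_pred[net$end_pred >= 1L]] <- TRUE
  for (i in rev(seq_len(V))) if (coreach[i])
    for (p in net$pred[[i]]) if (p >= 1L) coreach[p] <- TRUE
  if (!all(coreach)) v <- c(v, sprintf("dead end: vertex %d cannot reach End", which(!coreach)))

  # consumed-prefix invariant: every path reaching a vertex consumes the
  # same number of characters per row; non-gap cells at the same (row,
  # position) must agree, which makes all paths spell identical sequences.
  if (length(v) == 0L) {
    counts <- matrix(NA_integer_, k, V)
    consume <- (net$cols != GAP) * 1L
    for (i in seq_len(V)) {
      froms <- net$pred[[i]]
      base <- NULL
      for (p in froms) {
        this <- if (p == 0L) integer(k) else counts[, p]
        if (is.null(base)) base <- this
        else if (!identical(this, base)) {
          v <- c(v, sprintf("inconsistent row consumption at vertex %d", i))
          break
        }
      }
      if (is.null(base)) base <- integer(k)
      counts[, i] <- base + consume[, i]
    }
    for (r in seq_len(k)) {
      ng <- which(consume[r, ] == 1L)
      if (!length(ng)) next
      pos <- counts[r, ng]
      res <- net$cols[r, ng]
      agg <- tapply(res, pos, function(x) length(unique(x)))
      if (any(agg > 1L))
        v <- c(v, sprintf("row %s: conflicting residues at position %s",
                          net$ids[r], names(agg)[agg > 1L]))
      if (!is.null(sequences)) {
        ref <- strsplit(sequences[[net$ids[r]]], "")[[1]]
        ends <- counts[r, net$end_pred[net$end_pred >= 1L]]
        if (any(ends != length(ref)))
          v <- c(v, sprintf("row %s: path consumes %s characters, expected %d",
                            net$ids[r], paste(unique(ends), collapse = "/"),
                            length(ref)))
        bad <- which(res != ref[pos])
        if (length(bad))
          v <- c(v, sprintf("row %s: residue mismatch at position %d",
                            net$ids[r], pos[bad]))
      }
    }
  }
  list(valid = length(v) == 0L, violations = v)
}

#' Count Start->End paths of a network
#'
#' Dynamic programme over the DAG; each path is one multiple alignment.
#'
#' @param net An `"aln_network"`.
#' @return Number of distinct alignments the network stores.
#' @export
count_alignments <- function(net) {
  V <- n_vertices(net)
  END <- V + 1L
  if (V == 0L) return(1)
  cnt <- numeric(V)
  from_start <- net$start_succ[net$start_succ <= V]
  for (i in seq_len(V)) {
    cnt[i] <- sum(cnt[net$pred[[i]][net$pred[[i]] >= 1L]]) +
      (i %in% from_start)
  }
  sum(cnt[net$end_pred[net$end_pred >= 1L]])
}

#' Enumerate the alignments stored in a network
#'
#' Depth-first enumeration of Start->End paths in order-respecting DFS
#' order, truncated at `limit` (with an `"overflow"` attribute when
#' truncated).
#'
#' @param net An `"aln_network"`.
#' @param limit Maximum number of alignments to materialise.
#' @return List of [msa] objects; attribute `overflow` is `TRUE` if the
#'   enumeration was truncated.
#' @export
enumerate_alignments <- function(net, limit = 10000L) {
  stopifnot(limit >= 1L)
  V <- n_vertices(net)
  END <- V + 1L
  out <- list()
  overflow <- FALSE
  if (V == 0L) {
    out[[1L]] <- msa(net$cols)
    attr(out, "overflow") <- FALSE
    return(out)
  }
  path <- integer(0)
  dfs <- function(vtx) {
    if (overflow) return()
    if (vtx == END) {
      if (length(out) >= limit) { overflow <<- TRUE; return() }
      cols <- net$cols[, path, drop = FALSE]
      rownames(cols) <- net$ids
      out[[length(out) + 1L]] <<- msa(cols, state = net$state[path])
      return()
    }
    path <<- c(path, vtx)
    nxt <- sort(net$succ[[vtx]])
    for (s in nxt) dfs(s)
    path <<- path[-length(path)]
  }
  for (s in sort(net$start_succ)) dfs(s)
  attr(out, "overflow") <- overflow
  out
}

#' Compute a linear extension of a network
#'
#' Kahn's algorithm with ties broken by column id, so the result is
#' deterministic. Networks built by this package already store their
#' vertices in a certified linear extension; this is the diagnostic/repair
#' path for hand-built graphs.
#'
#' @param net An `"aln_network"`.
#' @return Integer permutation of `1:V` such that every edge goes forward.
#' @export
linear_extension <- function(net) {
  V <- n_vertices(net)
  if (V == 0L) return(integer())
  indeg <- vapply(net$pred, function(p) sum(p >= 1L), 0L)
  avail <- sort(which(indeg == 0L))
  order <- integer(0)
  indeg_w <- indeg
  while (length(avail)) {
    vtx <- avail[1L]
    avail <- avail[-1L]
    order <- c(order, vtx)
    for (s in net$succ[[vtx]]) if (s <= V) {
      indeg_w[s] <- indeg_w[s] - 1L
      if (indeg_w[s] == 0L) avail <- sort(c(avail, s))
    }
  }
  if (length(order) != V) {
    rem <- setdiff(seq_len(V), order)
    stop("cycle detected among vertices: ", paste(rem, collapse = ", "))
  }
  order
}

#' @export
print.aln_network <- function(x, ...) {
  V <- n_vertices(x)
  cat(sprintf("Alignment network: %d sequences, %d columns, %s alignments\n",
              length(x$ids), V, format(count_alignments(x))))
  if (!is.null(x$meta$opt))
    cat(sprintf("  opt = %g, x_effective = %g, size cap = %s\n",
                x$meta$opt, x$meta$x_effective, format(x$meta$size_cap)))
  invisible(x)
}

vertex_label <- function(net, i) {
  paste0(i, ":", net$state[i], ":",
         paste(net$cols[, i], collapse = ""))
}

#' Export a network as a DOT graph
#'
#' @param net An `"aln_network"`.
#' @param path Output file.
#' @export
write_network_dot <- function(net, path) {
  V <- n_vertices(net)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("digraph alignment_network {", con)
  writeLines('  Start [shape=point]; End [shape=point];', con)
  for (i in seq_len(V))
    writeLines(sprintf('  v%d [label="%s"];', i, vertex_label(net, i)), con)
  nm <- function(i) if (i == 0L) "Start" else if (i > V) "End" else paste0("v", i)
  for (i in seq_len(V)) for (p in net$pred[[i]])
    writeLines(sprintf("  %s -> v%d;", nm(p), i), con)
  for (e in net$end_pred) writeLines(sprintf("  %s -> End;", nm(e)), con)
  if (V == 0L) writeLines("  Start -> End;", con)
  writeLines("}", con)
  invisible(path)
}

#' Export a network as a TSV edge list
#'
#' One row per column: id, cells string, state, comma-separated successors
#' (`End` for the sink).
#'
#' @param net An `"aln_network"`.
#' @param path Output file.
#' @export
write_network_tsv <- function(net, path) {
  V <- n_vertices(net)
  rows <- vapply(seq_len(V), function(i) {
    succs <- vapply(net$succ[[i]],
                    function(s) if (s > V) "End" else as.character(s), "")
    paste(i, paste(net$cols[, i], collapse = ""), net$state[i],
          paste(succs, collapse = ","), sep = "\t")
  }, "")
  writeLines(c("column_id\tcells\tstate\tsuccessors", rows), path)
  invisible(path)
}
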