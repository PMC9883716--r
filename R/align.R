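#' Maximum-score local alignment with affine gaps
#'
#' Computes the optimal local alignment score of two sequences under a
#' scoring scheme, by one of two dynamic-programming variants.  Variant
#' `"I"` keeps three tables (X: prefix ends with an aligned pair, Y: ends
#' with a gapped reference letter, Z: ends with a gapped query letter) and
#' allows insertions after deletions but not the reverse; variant `"II"`
#' folds `W = max(X, Y, Z, 0)` into one table.  The two give identical
#' optimal scores whenever `a_D <= b_D` and `a_I <= b_I`; when a first-gap
#' score exceeds its extension score, variant II may split one long gap into
#' several and can then score higher (a warning is issued for variant I).
#'
#' @param R,Q sequences: character strings or letter vectors over the
#'   scheme's alphabet (case-folded; unknown letters are an error).
#' @param scheme a [score_scheme()] with gap scores.
#' @param algorithm `"I"` or `"II"`.
#' @return An object of class `"dp_tables"`: list with the tables (`X` or
#'   `W`, plus `Y`, `Z`), `best_score`, `best_cells` (0-based (i, j)
#'   endpoints attaining the optimum, ordered by i then j), `algorithm`,
#'   the index-coded sequences and the scheme.
#' @examples
#' sch <- score_scheme(builtin_matrix("Simple"), -3, -1, -3, -1)
#' align_local("ACGT", "ACGT", sch)$best_score   # 4
#' @export
align_local <- function(R, Q, scheme, algorithm = c("II", "I")) {
  algorithm <- match.arg(algorithm)
  stopifnot(inherits(scheme, "score_scheme"))
  if (!has_gaps(scheme)) stop("scheme has no gap scores")
  r <- seq_to_idx(R, scheme$alphabet)
  q <- seq_to_idx(Q, scheme$alphabet)
  if (algorithm == "I" &&
      (scheme$a_D > scheme$b_D || scheme$a_I > scheme$b_I))
    warning("first-gap score exceeds extension score: variant I forbids ",
            "splitting a gap and may differ from variant II")
  res <- if (algorithm == "I")
    cpp_align_algI(r, q, scheme$S, scheme$a_D, scheme$b_D,
                   scheme$a_I, scheme$b_I)
  else
    cpp_align_algII(r, q, scheme$S, scheme$a_D, scheme$b_D,
                    scheme$a_I, scheme$b_I)
  top <- if (algorithm == "I") res$X else res$W
  hits <- which(abs(top - res$best_score) <= 1e-9 * (1 + abs(res$best_score)),
                arr.ind = TRUE)
  hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE] - 1L
  out <- c(res, list(best_cells = unname(hits), algorithm = algorithm,
                     r_idx = r, q_idx = q, scheme = scheme))
  class(out) <- "dp_tables"
  out
}

#' @export
print.dp_tables <- function(x, ...) {
  cat("Local alignment DP (variant ", x$algorithm, "): best score ",
      x$best_score, "\n", sep = "")
  invisible(x)
}

## one traceback step helper: pick the first predecessor whose value
## matches, in the stated preference order
.pick <- function(target, values) {
  ok <- which(abs(values - target) <= 1e-9 * (1 + abs(target)))
  if (!length(ok)) stop("traceback inconsistency")   # should not happen
  ok[1L]
}

#' Trace back one optimal local alignment
#'
#' Recovers an alignment attaining the optimal score from the tables of
#' [align_local()].  Ties are broken deterministically: aligned-pair steps
#' are preferred over deletions, deletions over insertions, insertions over
#' a local restart; among equal-scoring endpoints the smallest i, then
#' smallest j is chosen.  A best score of 0 yields the empty alignment.
#'
#' @param tables a `"dp_tables"` object.
#' @return An object of class `"local_alignment"`: `r_start`, `r_end`,
#'   `q_start`, `q_end` (0-based half-open), `ops` (character vector over
#'   M/D/I), `score`, and the two gapped row strings `r_row`, `q_row`.
#' @export
traceback_alignment <- function(tables) {
  stopifnot(inherits(tables, "dp_tables"))
  sch <- tables$scheme
  r <- tables$r_idx; q <- tables$q_idx
  if (tables$best_score <= 0)
    return(local_alignment(0L, 0L, 0L, 0L, character(0), 0,
                           tables$scheme$alphabet, r, q))
  end <- tables$best_cells[1L, ] + 1L        # 1-based table indices
  i <- end[1L]; j <- end[2L]
  ops <- character(0)
  if (tables$algorithm == "I") {
    X <- tables$X; Y <- tables$Y; Z <- tables$Z
    state <- "X"
    repeat {
      if (state == "X") {
        if (i == 1L || j == 1L) break   # empty prefix: alignment starts here
        s <- sch$S[r[i - 1L], q[j - 1L]]
        ops <- c("M", ops)
        pre <- .pick(X[i, j] - s,
                     c(X[i - 1L, j - 1L], Y[i - 1L, j - 1L],
                       Z[i - 1L, j - 1L], 0))
        i <- i - 1L; j <- j - 1L
        if (pre == 4L) break
        state <- c("X", "Y", "Z")[pre]
      } else if (state == "Y") {
        ops <- c("D", ops)
        pre <- .pick(Y[i, j],
                     c(X[i - 1L, j] + sch$a_D, Y[i - 1L, j] + sch$b_D))
        i <- i - 1L
        state <- c("X", "Y")[pre]
      } else {
        ops <- c("I", ops)
        pre <- .pick(Z[i, j],
                     c(X[i, j - 1L] + sch$a_I, Y[i, j - 1L] + sch$a_I,
                       Z[i, j - 1L] + sch$b_I))
        j <- j - 1L
        state <- c("X", "Y", "Z")[pre]
      }
    }
  } else {
    W <- tables$W; Y <- tables$Y; Z <- tables$Z
    state <- "W"
    repeat {
      if (state == "W") {
        w <- W[i, j]
        if (w <= 0) break
        s <- sch$S[r[i - 1L], q[j - 1L]]
        br <- .pick(w, c(W[i - 1L, j - 1L] + s, Y[i, j], Z[i, j], 0))
        if (br == 1L) { ops <- c("M", ops); i <- i - 1L; j <- j - 1L }
        else if (br == 2L) state <- "Y"
        else if (br == 3L) state <- "Z"
        else break
      } else if (state == "Y") {
        ops <- c("D", ops)
        pre <- .pick(Y[i, j],
                     c(W[i - 1L, j] + sch$a_D, Y[i - 1L, j] + sch$b_D))
        i <- i - 1L
        state <- c("W", "Y")[pre]
      } else {
        ops <- c("I", ops)
        pre <- .pick(Z[i, j],
                     c(W[i, j - 1L] + sch$a_I, Z[i, j - 1L] + sch$b_I))
        j <- j - 1L
        state <- c("W", "Z")[pre]
      }
    }
  }
  local_alignment(i - 1L, end[1L] - 1L, j - 1L, end[2L] - 1L, ops,
                  tables$best_score, sch$alphabet, r, q)
}

## internal constructor; start/end are 0-based half-open coordinates
local_alignment <- function(r_start, r_end, q_start, q_end, ops, score,
                            alphabet, r_idx, q_idx) {
  ri <- r_start; qi <- q_start
  r_row <- q_row <- character(length(ops))
  for (k in seq_along(ops)) {
    if (ops[k] != "I") { ri <- ri + 1L; r_row[k] <- alphabet[r_idx[ri]] }
    else r_row[k] <- "-"
    if (ops[k] != "D") { qi <- qi + 1L; q_row[k] <- alphabet[q_idx[qi]] }
    else q_row[k] <- "-"
  }
  structure(list(r_start = as.integer(r_start), r_end = as.integer(r_end),
                 q_start = as.integer(q_start), q_end = as.integer(q_end),
                 ops = ops, score = score,
                 r_row = paste(r_row, collapse = ""),
                 q_row = paste(q_row, collapse = "")),
            class = "local_alignment")
}

#' @export
print.local_alignment <- function(x, ...) {
  cat("Local alignment score ", x$score, "  R[", x$r_start, ",", x$r_end,
      ") x Q[", x$q_start, ",", x$q_end, ")\n", sep = "")
  if (length(x$ops)) cat(x$r_row, "\n", x$q_row, "\n", sep = "")
  invisible(x)
}

#' Recompute an alignment's score under a scheme
#'
#' Sums substitution scores over aligned-pair columns and `a + b * (k - 1)`
#' over each maximal gap run.  Useful to confirm that a traced-back
#' alignment reproduces the DP optimum.
#'
#' @param aln a `"local_alignment"`.
#' @param scheme the [score_scheme()] to score under.
#' @param R,Q the aligned sequences (same as passed to the aligner).
#' @return numeric score.
#' @export
alignment_score <- function(aln, scheme, R, Q) {
  r <- seq_to_idx(R, scheme$alphabet)
  q <- seq_to_idx(Q, scheme$alphabet)
  ri <- aln$r_start; qi <- aln$q_start
  total <- 0
  prev <- ""
  for (op in aln$ops) {
    if (op == "M") {
      ri <- ri + 1L; qi <- qi + 1L
      total <- total + scheme$S[r[ri], q[qi]]
    } else if (op == "D") {
      ri <- ri + 1L
      total <- total + if (prev == "D") scheme$b_D else scheme$a_D
    } else {
      qi <- qi + 1L
      total <- total + if (prev == "I") scheme$b_I else scheme$a_I
    }
    prev <- op
  }
  total
}

#' End-to-end (global) affine-gap alignment
#'
#' Aligns both sequences in full under the `a + b * (k - 1)` gap convention.
#' Abutting deletion and insertion runs count as separate gaps.  Provided
#' chiefly to exercise the global-alignment score transformations (see
#' [transform_scheme()]): adding h to every substitution and deletion score
#' changes every global score by exactly h * m.
#'
#' @inheritParams align_local
#' @return list with `score` and `alignment` (a `"local_alignment"` whose
#'   coordinates span both sequences entirely).
#' @export
align_global <- function(R, Q, scheme) {
  stopifnot(inherits(scheme, "score_scheme"))
  if (!has_gaps(scheme)) stop("scheme has no gap scores")
  r <- seq_to_idx(R, scheme$alphabet)
  q <- seq_to_idx(Q, scheme$alphabet)
  res <- cpp_align_global(r, q, scheme$S, scheme$a_D, scheme$b_D,
                          scheme$a_I, scheme$b_I)
  m <- length(r); n <- length(q)
  X <- res$X; Y <- res$Y; Z <- res$Z
  i <- m + 1L; j <- n + 1L
  state <- c("X", "Y", "Z")[.pick(res$best_score,
                                  c(X[i, j], Y[i, j], Z[i, j]))]
  ops <- character(0)
  while (i > 1L || j > 1L) {
    if (state == "X") {
      s <- scheme$S[r[i - 1L], q[j - 1L]]
      ops <- c("M", ops)
      pre <- .pick(X[i, j] - s,
                   c(X[i - 1L, j - 1L], Y[i - 1L, j - 1L], Z[i - 1L, j - 1L]))
      i <- i - 1L; j <- j - 1L
      state <- c("X", "Y", "Z")[pre]
    } else if (state == "Y") {
      ops <- c("D", ops)
      if (j == 1L) { i <- i - 1L; state <- if (i == 1L) "X" else "Y" }
      else {
        pre <- .pick(Y[i, j], c(X[i - 1L, j] + scheme$a_D,
                                Y[i - 1L, j] + scheme$b_D,
                                Z[i - 1L, j] + scheme$a_D))
        i <- i - 1L
        state <- c("X", "Y", "Z")[pre]
      }
    } else {
      ops <- c("I", ops)
      if (i == 1L) { j <- j - 1L; state <- if (j == 1L) "X" else "Z" }
      else {
        pre <- .pick(Z[i, j], c(X[i, j - 1L] + scheme$a_I,
                                Y[i, j - 1L] + scheme$a_I,
                                Z[i, j - 1L] + scheme$b_I))
        j <- j - 1L
        state <- c("X", "Y", "Z")[pre]
      }
    }
  }
  aln <- local_alignment(0L, m, 0L, n, ops, res$best_score,
                         scheme$alphabet, r, q)
  list(score = res$best_score, alignment = aln)
}
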