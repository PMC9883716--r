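#' Exhaustive path enumeration (oracle for the Forward algorithms)
#'
#' Explicitly enumerates every distinguishable state path of the chosen
#' topology on a tiny instance and sums their probability ratios relative to
#' the null alignment.  For topology A this includes the flank-split
#' variants of the null alignment (one per possible core position, (m+1) *
#' (n+1) in all) and, within each gap run, every way of extending versus
#' re-opening the gap.  By default each run's 2^(k-1) open/extend labelings
#' are summed in closed form, a' (a' + b')^(k-1), which is exact; with
#' `collapse_runs = FALSE` every labeling is an explicit branch (slower,
#' used to validate the closed form).  Intended purely as an independent
#' check of [forward_modelA()] and [forward_modelB()]; cost is exponential.
#'
#' @inheritParams forward_modelA
#' @param topology `"A"` or `"B"`.
#' @param posterior if `TRUE` (topology A only), also accumulate per-path
#'   mass for each aligned letter pair and return posterior probabilities.
#' @param collapse_runs sum gap-run labelings in closed form (default).
#' @param max_size refuse instances with m + n above this (exponential
#'   blow-up guard).
#' @return If `posterior` is `FALSE`, the total ratio (a number >= 1);
#'   otherwise a list with `total_ratio` and `P` (m x n posterior matrix).
#' @export
enumerate_paths <- function(R, Q, primed, topology = c("A", "B"),
                            posterior = FALSE, collapse_runs = TRUE,
                            max_size = 12L) {
  topology <- match.arg(topology)
  stopifnot(inherits(primed, "phmm_primed"))
  r <- seq_to_idx(R, primed$alphabet)
  q <- seq_to_idx(Q, primed$alphabet)
  m <- length(r); n <- length(q)
  if (m + n > max_size)
    stop("refusing to enumerate paths for m + n > ", max_size)
  Sp <- primed$Sprime
  aD <- primed$a_D_pr; bD <- primed$b_D_pr
  aI <- primed$a_I_pr; bI <- primed$b_I_pr
  if (anyNA(c(aD, bD, aI, bI))) stop("primed parameters lack gap factors")
  acc <- new.env(parent = emptyenv())
  acc$total <- 0
  acc$P <- matrix(0, max(m, 1L), max(n, 1L))

  if (topology == "A") {
    ## every node of the search is a complete path (a path may end anywhere)
    dfs <- function(i, j, last, ratio, mcells) {
      acc$total <- acc$total + ratio
      if (posterior && length(mcells))
        acc$P[mcells] <- acc$P[mcells] + ratio
      if (i < m && j < n)
        dfs(i + 1L, j + 1L, "M", ratio * Sp[r[i + 1L], q[j + 1L]],
            if (posterior) c(mcells, i + 1L + m * j) else mcells)
      if (i < m) {
        if (collapse_runs) {
          f <- if (identical(last, "D")) aD + bD else aD
          dfs(i + 1L, j, "D", ratio * f, mcells)
        } else {
          dfs(i + 1L, j, "D", ratio * aD, mcells)
          if (identical(last, "D")) dfs(i + 1L, j, "D", ratio * bD, mcells)
        }
      }
      if (j < n) {
        if (collapse_runs) {
          f <- if (identical(last, "I")) aI + bI else aI
          dfs(i, j + 1L, "I", ratio * f, mcells)
        } else {
          dfs(i, j + 1L, "I", ratio * aI, mcells)
          if (identical(last, "I")) dfs(i, j + 1L, "I", ratio * bI, mcells)
        }
      }
    }
    for (i0 in 0:m) for (j0 in 0:n)
      dfs(i0, j0, "start", 1, integer(0))
  } else {
    ## topology B: paths begin and end with an aligned pair; a deletion may
    ## follow only a match or deletion; runs extend without re-opening
    acc$total <- 1   # the single null path
    dfs <- function(i, j, last, ratio) {
      if (last == "M") acc$total <- acc$total + ratio
      if (i < m && j < n)
        dfs(i + 1L, j + 1L, "M", ratio * Sp[r[i + 1L], q[j + 1L]])
      if (i < m && last %in% c("M", "D"))
        dfs(i + 1L, j, "D", ratio * if (last == "M") aD else bD)
      if (j < n)
        dfs(i, j + 1L, "I", ratio * if (last == "I") bI else aI)
    }
    for (i0 in 0:(max(m - 1L, 0L))) for (j0 in 0:(max(n - 1L, 0L)))
      if (m > 0L && n > 0L)
        dfs(i0 + 1L, j0 + 1L, "M", Sp[r[i0 + 1L], q[j0 + 1L]])
  }
  if (posterior) {
    P <- acc$P / acc$total
    P <- P[seq_len(m), seq_len(n), drop = FALSE]
    list(total_ratio = acc$total, P = P)
  } else acc$total
}
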