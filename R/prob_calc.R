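#' Forward algorithm for the affine-gap topology A
#'
#' Sums the probabilities of every distinguishable path through the
#' topology-A local pair HMM, relative to the probability of a null
#' alignment, using only the primed invariants (S', a', b').  The result is
#' therefore identical for every (omega_D, omega_I) realization of the same
#' scheme.  Computation uses per-row rescaled linear arithmetic with the
#' total accumulated by log-sum-exp (see the package vignette).
#'
#' @param R,Q sequences (character strings or letter vectors).
#' @param primed a `"phmm_primed"` object with `Sprime` and all four gap
#'   factors.
#' @return An object of class `"forward_result"`: `total_ratio` (>= 1; `Inf`
#'   if it overflows a double -- use `log_total` then), `log_total`, `lW`
#'   (the (m+1) x (n+1) table of log W' values), `lX` (log of the
#'   aligned-pair component), `topology`.
#' @export
forward_modelA <- function(R, Q, primed) {
  stopifnot(inherits(primed, "phmm_primed"))
  if (is.null(primed$Sprime)) stop("primed parameters lack Sprime")
  gp <- c(primed$a_D_pr, primed$b_D_pr, primed$a_I_pr, primed$b_I_pr)
  if (anyNA(gp)) stop("primed parameters lack gap factors")
  if (gp[2L] >= 1 || gp[4L] >= 1)
    warning("gap extension factor b' >= 1: gap-length sums do not converge ",
            "globally; per-cell results are still finite")
  r <- seq_to_idx(R, primed$alphabet)
  q <- seq_to_idx(Q, primed$alphabet)
  res <- cpp_forward_A(r, q, primed$Sprime, gp[1L], gp[2L], gp[3L], gp[4L])
  structure(list(total_ratio = exp(res$log_total),
                 log_total = res$log_total,
                 lW = res$lW, lX = res$lX, topology = "A"),
            class = "forward_result")
}

#' Forward algorithm for the affine-gap topology B
#'
#' As [forward_modelA()], but for the stricter topology in which exactly one
#' path corresponds to one alignment: local alignments begin and end with an
#' aligned pair, a deletion may follow only an aligned pair or a deletion,
#' and gap runs extend without re-opening.  Its path set is a subset of
#' topology A's, so its total never exceeds model A's for the same primed
#' parameters.
#'
#' @inheritParams forward_modelA
#' @return A `"forward_result"`; the per-cell table `lX` holds log X'
#'   (paths ending with the aligned pair at each cell).
#' @export
forward_modelB <- function(R, Q, primed) {
  stopifnot(inherits(primed, "phmm_primed"))
  if (is.null(primed$Sprime)) stop("primed parameters lack Sprime")
  gp <- c(primed$a_D_pr, primed$b_D_pr, primed$a_I_pr, primed$b_I_pr)
  if (anyNA(gp)) stop("primed parameters lack gap factors")
  if (gp[2L] >= 1 || gp[4L] >= 1)
    warning("gap extension factor b' >= 1: gap-length sums do not converge ",
            "globally; per-cell results are still finite")
  r <- seq_to_idx(R, primed$alphabet)
  q <- seq_to_idx(Q, primed$alphabet)
  res <- cpp_forward_B(r, q, primed$Sprime, gp[1L], gp[2L], gp[3L], gp[4L])
  structure(list(total_ratio = exp(res$log_total),
                 log_total = res$log_total,
                 lW = NULL, lX = res$lX, topology = "B"),
            class = "forward_result")
}

#' @export
print.forward_result <- function(x, ...) {
  cat("Forward total (topology ", x$topology, "): log ratio = ",
      format(x$log_total), "\n", sep = "")
  invisible(x)
}

#' Probability of the null alignment
#'
#' The null alignment emits every letter from the flanking states and
#' aligns nothing.  Its probability factorizes over the letters and does not
#' depend on where the (empty) core falls: for gapless models
#' mu = prod(omega_D phi_R) prod(omega_I psi_Q) (1-omega_D)^2 (1-omega_I)^2
#' (1-gamma), and for gapped models the last factor becomes
#' (1 - gamma - alpha_D - alpha_I).  This is the denominator of every
#' score-probability ratio.
#'
#' @param params a `"phmm_params"` object (a full realization; unlike the
#'   Forward total, mu depends on the chosen omegas).
#' @param R,Q sequences.
#' @return The probability, a positive number (log also returned as
#'   attribute `"log"` for long sequences).
#' @export
null_probability <- function(params, R, Q) {
  stopifnot(inherits(params, "phmm_params"))
  r <- seq_to_idx(R, params$alphabet)
  q <- seq_to_idx(Q, params$alphabet)
  aD <- if (is.na(params$alpha_D)) 0 else params$alpha_D
  aI <- if (is.na(params$alpha_I)) 0 else params$alpha_I
  lg <- sum(log(params$omega_D * params$phi[r])) +
    sum(log(params$omega_I * params$psi[q])) +
    2 * log(1 - params$omega_D) + 2 * log(1 - params$omega_I) +
    log(1 - params$gamma - aD - aI)
  structure(exp(lg), log = lg)
}

#' Posterior probability that reference letter i aligns to query letter j
#'
#' Runs the Forward and its adjoint (Backward) pass over the topology-A
#' recurrences and assembles, for every letter pair (i, j), the summed
#' probability of all paths whose core aligns R_i with Q_j, divided by the
#' total over all paths.  Row i of the result sums to at most 1 (the
#' remainder being the probability that R_i is unaligned), likewise each
#' column.
#'
#' @inheritParams forward_modelA
#' @return An m x n matrix of probabilities in \[0, 1\].
#' @export
posterior_match_probs <- function(R, Q, primed) {
  stopifnot(inherits(primed, "phmm_primed"))
  if (is.null(primed$Sprime)) stop("primed parameters lack Sprime")
  gp <- c(primed$a_D_pr, primed$b_D_pr, primed$a_I_pr, primed$b_I_pr)
  if (anyNA(gp)) stop("primed parameters lack gap factors")
  r <- seq_to_idx(R, primed$alphabet)
  q <- seq_to_idx(Q, primed$alphabet)
  fw <- cpp_forward_A(r, q, primed$Sprime, gp[1L], gp[2L], gp[3L], gp[4L])
  bw <- cpp_backward_A(r, q, primed$Sprime, gp[1L], gp[2L], gp[3L], gp[4L])
  m <- length(r); n <- length(q)
  if (m == 0L || n == 0L)
    return(matrix(numeric(0), m, n))
  P <- exp(fw$lX[-1L, -1L, drop = FALSE] + bw[-1L, -1L, drop = FALSE] -
             fw$log_total)
  pmin(P, 1)
}

#' Per-column reliability of an alignment
#'
#' For each aligned-pair column (i, j) of an alignment, the posterior
#' probability P\[i, j\] that the pair is correct; for a deletion column over
#' reference letter i, the probability that R_i is *not* aligned to any
#' query letter (1 - sum_j P\[i, j\]), and symmetrically for insertions.
#'
#' @param aln a `"local_alignment"`.
#' @param post posterior matrix from [posterior_match_probs()] for the same
#'   sequence pair.
#' @return numeric vector, one value per alignment column.
#' @export
column_reliability <- function(aln, post) {
  stopifnot(inherits(aln, "local_alignment"))
  if (length(aln$ops) == 0L) return(numeric(0))
  if (aln$r_end > nrow(post) || aln$q_end > ncol(post))
    stop("alignment coordinates exceed the posterior table")
  ri <- aln$r_start; qi <- aln$q_start
  out <- numeric(length(aln$ops))
  for (k in seq_along(aln$ops)) {
    op <- aln$ops[k]
    if (op == "M") {
      ri <- ri + 1L; qi <- qi + 1L
      out[k] <- post[ri, qi]
    } else if (op == "D") {
      ri <- ri + 1L
      out[k] <- max(0, 1 - sum(post[ri, ]))
    } else {
      qi <- qi + 1L
      out[k] <- max(0, 1 - sum(post[, qi]))
    }
  }
  out
}

#' Mapping probabilities from competing alignment scores
#'
#' When one query aligns to several candidate loci with scores s_k, and
#' exactly one locus is correct, the probability that locus k is the right
#' one is exp(s_k / t) / sum_j exp(s_j / t).  Computed with max-subtraction
#' so that large scores do not overflow.
#'
#' @param scores numeric vector of alignment scores (at least one).
#' @param t temperature in score units.
#' @return Probability vector summing to 1.
#' @examples
#' mapping_probability(c(100, 90, 80), t = 10)
#' @export
mapping_probability <- function(scores, t) {
  if (length(scores) == 0L) stop("at least one score is required")
  stopifnot(t > 0, all(is.finite(scores)))
  z <- scores / t
  w <- exp(z - max(z))
  w / sum(w)
}

#' Hybrid local alignment score
#'
#' The Forward summation with the final sum over cells replaced by a
#' maximum: t * max_ij ln W'_ij for the topology-A tables.  Hybrid scores
#' integrate over alternative alignments *within* a locus while still
#' picking out the best locus; for balanced parameters their random-sequence
#' distribution is Gumbel with scale parameter 1/t (see [check_lambda()]).
#'
#' @inheritParams forward_modelA
#' @param t temperature in score units.
#' @return numeric score, >= 0.
#' @export
hybrid_score <- function(R, Q, primed, t) {
  stopifnot(t > 0)
  fw <- forward_modelA(R, Q, primed)
  t * max(fw$lW)
}

#' Match total under background letter probabilities
#'
#' c' = sum_xy Phi_x Psi_y S'_xy for arbitrary background distributions Phi
#' and Psi (for significance calculations, "by chance" means random
#' sequences with these letter probabilities).  With Phi and Psi equal to
#' the model's own letter probabilities this is the usual c'.
#'
#' @param Sprime exponentiated substitution matrix.
#' @param Phi,Psi background letter probability vectors.
#' @return numeric c'.
#' @export
background_cprime <- function(Sprime, Phi, Psi) {
  stopifnot(is.matrix(Sprime), length(Phi) == nrow(Sprime),
            length(Psi) == ncol(Sprime))
  as.numeric(Phi %*% Sprime %*% Psi)
}
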