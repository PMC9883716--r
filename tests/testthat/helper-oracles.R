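## shared fixtures and brute-force oracles, all built in code

DNA <- c("A", "C", "G", "T")
UNIF4 <- stats::setNames(rep(0.25, 4), DNA)

rand_matrix <- function(lo = -4, hi = 3) {
  matrix(round(stats::runif(16, lo, hi), 2), 4, 4,
         dimnames = list(DNA, DNA))
}

rand_seq <- function(len) paste(sample(DNA, len, replace = TRUE),
                                collapse = "")

## gap scores with a <= b < 0 (first gap costs at least as much as extension)
rand_gaps <- function() {
  b <- -round(stats::runif(1, 0.2, 2), 2)
  c(a = b - round(stats::runif(1, 0, 3), 2), b = b)
}

rand_probs <- function() {
  p <- stats::runif(4) + 0.2
  stats::setNames(p / sum(p), DNA)
}

## Exhaustive maximum over local alignments: every substring pair, every
## monotone column sequence; maximal gap runs score a + b*(k-1).
brute_local <- function(r, q, S, aD, bD, aI, bI) {
  m <- length(r); n <- length(q)
  best <- 0
  rec <- function(i, j, sc, last) {
    best <<- max(best, sc)
    if (i < m && j < n) rec(i + 1L, j + 1L, sc + S[r[i + 1L], q[j + 1L]], "M")
    if (i < m) rec(i + 1L, j, sc + if (identical(last, "D")) bD else aD, "D")
    if (j < n) rec(i, j + 1L, sc + if (identical(last, "I")) bI else aI, "I")
  }
  for (i0 in 0:m) for (j0 in 0:n) rec(i0, j0, 0, "")
  best
}

## Exhaustive optimum over end-to-end alignments (same gap convention).
brute_global <- function(r, q, S, aD, bD, aI, bI) {
  m <- length(r); n <- length(q)
  best <- -Inf
  rec <- function(i, j, sc, last) {
    if (i == m && j == n) { best <<- max(best, sc); return(invisible()) }
    if (i < m && j < n) rec(i + 1L, j + 1L, sc + S[r[i + 1L], q[j + 1L]], "M")
    if (i < m) rec(i + 1L, j, sc + if (identical(last, "D")) bD else aD, "D")
    if (j < n) rec(i, j + 1L, sc + if (identical(last, "I")) bI else aI, "I")
  }
  rec(0L, 0L, 0, "")
  best
}

rand_primed <- function(c_pr = 1) {
  Sp <- matrix(exp(stats::runif(16, -2, 1.5)), 4, 4,
               dimnames = list(DNA, DNA))
  phmm_primed(Sp,
              a_D_pr = stats::runif(1, 0, 0.8),
              b_D_pr = stats::runif(1, 0, 0.9),
              a_I_pr = stats::runif(1, 0, 0.8),
              b_I_pr = stats::runif(1, 0, 0.9),
              c_pr = c_pr, alphabet = DNA)
}

## recover primed invariants from one concrete realization (inverse of
## realize_phmm), used to check that different realizations carry the same
## Forward totals
primed_of_params <- function(p) {
  c_pr <- p$gamma / (p$omega_D * p$omega_I)
  Sp <- p$pi / outer(p$phi, p$psi) * c_pr
  phmm_primed(Sp,
              a_D_pr = p$alpha_D * (1 - p$beta_D) / p$omega_D,
              b_D_pr = p$beta_D / p$omega_D,
              a_I_pr = p$alpha_I * (1 - p$beta_I) / p$omega_I,
              b_I_pr = p$beta_I / p$omega_I,
              c_pr = c_pr, alphabet = p$alphabet)
}
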