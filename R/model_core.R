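#' Temperature-exponentiated (primed) invariants of a scoring scheme
#'
#' Every pair HMM that maps to a given scoring scheme at temperature t shares
#' the same "primed" quantities: the exponentiated substitution matrix
#' S'_xy = exp(S_xy / t), exponentiated gap factors a' = exp(a / t) and
#' b' = exp(b / t) for each gap side, the match-total
#' c' = sum_xy phi_x psi_y S'_xy (equal to gamma / (omega_D * omega_I) for any
#' realization), and, when both b' < 1, the balance criterion
#' C' = c' + a'_D / (1 - b'_D) + a'_I / (1 - b'_I).
#'
#' @param scheme a [score_scheme()].
#' @param phi,psi letter probability vectors over the scheme's alphabet for
#'   the reference and query sides.
#' @return An object of class `"phmm_primed"`: list with `Sprime`, `a_D_pr`,
#'   `b_D_pr`, `a_I_pr`, `b_I_pr`, `c_pr`, `C_pr` (NA when undefined, i.e.
#'   when a gap extension factor is >= 1), `alphabet`, and the source
#'   temperature `t`.
#' @examples
#' sch <- score_scheme(builtin_matrix("Simple"), -6, -1, -6, -1, t = 1)
#' pr <- primed_params(sch, rep(.25, 4), rep(.25, 4))
#' pr$c_pr
#' @export
primed_params <- function(scheme, phi, psi) {
  stopifnot(inherits(scheme, "score_scheme"))
  phi <- check_letter_probs(phi, scheme$alphabet, "phi")
  psi <- check_letter_probs(psi, scheme$alphabet, "psi")
  Sp <- exp(scheme$S / scheme$t)
  c_pr <- as.numeric(phi %*% Sp %*% psi)
  ap <- function(x) if (is.na(x)) NA_real_ else exp(x / scheme$t)
  out <- phmm_primed(Sprime = Sp,
                     a_D_pr = ap(scheme$a_D), b_D_pr = ap(scheme$b_D),
                     a_I_pr = ap(scheme$a_I), b_I_pr = ap(scheme$b_I),
                     c_pr = c_pr, alphabet = scheme$alphabet, t = scheme$t)
  out
}

#' Construct primed parameters directly
#'
#' Mostly useful for studying parameter limits in the abstract, where only
#' a', b' and c' matter (e.g. the large-t limit a' = b' = c' = 1).
#'
#' @param Sprime exponentiated substitution matrix (positive entries), or
#'   NULL when only gap/limit computations are needed.
#' @param a_D_pr,b_D_pr,a_I_pr,b_I_pr exponentiated gap factors (positive;
#'   NA for gapless).
#' @param c_pr the match total sum(phi * Sprime * psi).
#' @param alphabet letter vector (taken from `Sprime` dimnames if NULL).
#' @param t source temperature, if known (metadata only).
#' @return A `"phmm_primed"` object; see [primed_params()].
#' @export
phmm_primed <- function(Sprime = NULL, a_D_pr = NA_real_, b_D_pr = NA_real_,
                        a_I_pr = NA_real_, b_I_pr = NA_real_, c_pr,
                        alphabet = NULL, t = NA_real_) {
  if (!is.null(Sprime)) {
    if (any(Sprime < 0)) stop("Sprime entries must be positive")
    if (is.null(alphabet)) alphabet <- rownames(Sprime)
  }
  stopifnot(is.numeric(c_pr), length(c_pr) == 1L, c_pr > 0)
  gap_term <- function(a, b) {
    if (is.na(a) || is.na(b)) return(NA_real_)
    if (b >= 1) return(NA_real_)   # undefined, flagged not an error
    a / (1 - b)
  }
  gD <- gap_term(a_D_pr, b_D_pr)
  gI <- gap_term(a_I_pr, b_I_pr)
  C_pr <- if (is.na(a_D_pr) && is.na(a_I_pr)) c_pr else c_pr + gD + gI
  structure(list(Sprime = Sprime,
                 a_D_pr = a_D_pr, b_D_pr = b_D_pr,
                 a_I_pr = a_I_pr, b_I_pr = b_I_pr,
                 c_pr = c_pr, C_pr = C_pr,
                 alphabet = alphabet, t = t),
            class = "phmm_primed")
}

#' @export
print.phmm_primed <- function(x, ...) {
  cat("Primed pair-HMM invariants: c' =", format(x$c_pr),
      " C' =", format(x$C_pr), "\n")
  cat("a'_D =", x$a_D_pr, " b'_D =", x$b_D_pr,
      " a'_I =", x$a_I_pr, " b'_I =", x$b_I_pr, "\n")
  invisible(x)
}

#' Aligned-pair emission probabilities implied by a scoring scheme
#'
#' Given letter probabilities phi and psi and a temperature, the scheme's
#' substitution scores determine the aligned-pair probabilities
#' pi_xy = phi_x psi_y exp(S_xy / t) / c, where
#' c = sum_xy phi_x psi_y exp(S_xy / t) equals gamma / (omega_D * omega_I)
#' for every pair HMM realizing the scheme.
#'
#' @inheritParams primed_params
#' @return list with `pi` (matrix summing to 1) and `c`.
#' @export
pair_probs_from_scores <- function(scheme, phi, psi) {
  pr <- primed_params(scheme, phi, psi)
  pi <- outer(phi, psi) * pr$Sprime / pr$c_pr
  dimnames(pi) <- dimnames(scheme$S)
  list(pi = pi, c = pr$c_pr)
}

#' Recover the scoring scheme of a pair HMM
#'
#' Inverts the score-to-probability mapping: S_xy = t * ln(pi_xy /
#' (phi_x psi_y) * gamma / (omega_D omega_I)), and for the affine topology A,
#' a_D = t ln(alpha_D (1 - beta_D) / omega_D), b_D = t ln(beta_D / omega_D)
#' (symmetrically for insertions); for the linear-gap topology
#' a = b = t ln(alpha / omega).
#'
#' @param params a `"phmm_params"` object from [realize_phmm()] or
#'   [phmm_params()].
#' @param t temperature of the resulting scheme (score units).
#' @return A [score_scheme()].  Round-tripping through
#'   [pair_probs_from_scores()] recovers the inputs.
#' @export
scores_from_pair_probs <- function(params, t) {
  stopifnot(inherits(params, "phmm_params"))
  need_pos <- function(x, nm) {
    if (any(!is.finite(x)) || any(x <= 0))
      stop("zero or invalid probability in '", nm,
           "': logarithm undefined", call. = FALSE)
    x
  }
  phi <- need_pos(params$phi, "phi"); psi <- need_pos(params$psi, "psi")
  pi <- need_pos(params$pi, "pi")
  wD <- need_pos(params$omega_D, "omega_D")
  wI <- need_pos(params$omega_I, "omega_I")
  gamma <- need_pos(params$gamma, "gamma")
  S <- t * log(pi / outer(phi, psi) * gamma / (wD * wI))
  dimnames(S) <- list(params$alphabet, params$alphabet)
  if (params$topology == "gapless")
    return(score_scheme(S, t = t))
  if (params$topology == "linear") {
    aD <- t * log(need_pos(params$alpha_D, "alpha_D") / wD)
    aI <- t * log(need_pos(params$alpha_I, "alpha_I") / wI)
    return(score_scheme(S, a_D = aD, b_D = aD, a_I = aI, b_I = aI, t = t))
  }
  aD <- t * log(need_pos(params$alpha_D, "alpha_D") *
                  (1 - params$beta_D) / wD)
  bD <- t * log(need_pos(params$beta_D, "beta_D") / wD)
  aI <- t * log(need_pos(params$alpha_I, "alpha_I") *
                  (1 - params$beta_I) / wI)
  bI <- t * log(need_pos(params$beta_I, "beta_I") / wI)
  score_scheme(S, a_D = aD, b_D = bD, a_I = aI, b_I = bI, t = t)
}

#' Homogeneous letter probabilities for a substitution matrix
#'
#' Finds letter distributions that are identical in aligned and unaligned
#' regions: phi_x = sum_y pi_xy and psi_y = sum_x pi_xy.  With
#' S'_xy = exp(S_xy / t) this reduces to the linear system
#' sum_y S'_xy psi'_y = 1 (and its transpose for phi'), after which
#' c = 1 / sum(psi') and psi = psi' * c.  Computation is internally scaled by
#' max(S) / t so that low temperatures do not overflow.
#'
#' @param S substitution matrix with alphabet dimnames.
#' @param t temperature (> 0).
#' @return list with `phi`, `psi`, `c`, and `log_c` (exact even when `c`
#'   overflows at very low temperatures).
#' @section Errors: a singular exponentiated matrix is an error, as is any
#'   solution component below -1e-12 after normalization ("not consistent
#'   with homogeneous letter probabilities"); components within -1e-12 of
#'   zero are clamped to 0.
#' @examples
#' solve_homogeneous(builtin_matrix("Simple"), 10)$c   # 0.955
#' @export
solve_homogeneous <- function(S, t) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S), t > 0)
  kappa <- max(S) / t
  Tm <- exp(S / t - kappa)
  u_psi <- tryCatch(solve(Tm, rep(1, nrow(S))),
                    error = function(e) stop(
                      "exponentiated score matrix is singular at t = ", t,
                      call. = FALSE))
  u_phi <- solve(t(Tm), rep(1, nrow(S)))
  norm_probs <- function(u) {
    p <- u / sum(u)
    if (any(p < -1e-12))
      stop("S and t are not consistent with homogeneous letter probabilities",
           call. = FALSE)
    p[p < 0] <- 0
    p
  }
  s_psi <- sum(u_psi)
  if (s_psi <= 0)
    stop("S and t are not consistent with homogeneous letter probabilities",
         call. = FALSE)
  psi <- norm_probs(u_psi)
  phi <- norm_probs(u_phi)
  log_c <- kappa - log(s_psi)
  names(phi) <- rownames(S); names(psi) <- colnames(S)
  list(phi = phi, psi = psi, c = exp(log_c), log_c = log_c)
}

## log(c(t)) - 0 as a function of t, NA where the solve fails
.log_c_of_t <- function(S, t) {
  tryCatch(solve_homogeneous(S, t)$log_c, error = function(e) NA_real_)
}

#' Temperature of uniform length probability
#'
#' For a substitution matrix under homogeneous letter probabilities, finds
#' the finite temperature at which c = gamma / (omega_D omega_I) equals 1,
#' i.e. gapless alignments of all lengths have uniform prior probability.
#' There is at most one such finite t.  The search scans a log-spaced grid
#' of temperatures for a sign change of log c(t), then bisects.
#'
#' @param S substitution matrix with alphabet dimnames; must contain at
#'   least one positive score (otherwise c(t) < 1 for every t).
#' @param n_scan number of log-spaced scan points.
#' @return The temperature, a positive number.
#' @examples
#' find_uniform_length_temperature(builtin_matrix("Simple"))  # 1 / log(3)
#' @export
find_uniform_length_temperature <- function(S, n_scan = 512L) {
  stopifnot(is.matrix(S))
  if (max(S) <= 0)
    stop("no uniform-length temperature: S has no positive score")
  M <- max(abs(S))
  ts <- exp(seq(log(1e-3 * M), log(1e6 * M), length.out = n_scan))
  f <- vapply(ts, function(t) .log_c_of_t(S, t), numeric(1))
  ok <- which(!is.na(f))
  root <- NULL
  for (k in seq_len(length(ok) - 1L)) {
    i <- ok[k]; j <- ok[k + 1L]
    if (f[i] == 0) { root <- ts[i]; break }
    if (f[i] > 0 && f[j] < 0) {
      root <- stats::uniroot(function(t) .log_c_of_t(S, t),
                             c(ts[i], ts[j]),
                             tol = 1e-12 * ts[j])$root
      break
    }
  }
  if (is.null(root))
    stop("no uniform-length temperature found for this matrix")
  sol <- tryCatch(solve_homogeneous(S, root), error = function(e) NULL)
  if (is.null(sol))
    stop("no uniform-length temperature: candidate root yields letter ",
         "probabilities that are not valid")
  root
}

#' Realize one concrete pair HMM from primed invariants
#'
#' The primed quantities leave omega_D and omega_I free: any choice in (0, 1)
#' that keeps the model feasible gives a pair HMM with exactly the same
#' scoring scheme.  For the affine topology A: beta_D = b'_D omega_D,
#' alpha_D = a'_D omega_D / (1 - beta_D) (symmetrically for I), and
#' gamma = c' omega_D omega_I.
#'
#' @param primed a `"phmm_primed"` object (with `Sprime` present).
#' @param phi,psi letter probabilities used to form pi.
#' @param omega_D,omega_I flank-continuation probabilities, in (0, 1).
#' @param topology `"A"` (affine, default), `"linear"`, or `"gapless"`.
#' @return A `"phmm_params"` object (see [phmm_params()]).
#' @section Errors: if the implied gamma + alpha_D + alpha_I reaches 1 (or
#'   any probability leaves \[0, 1)), the chosen omegas are infeasible and an
#'   error reports the violated sum.
#' @export
realize_phmm <- function(primed, phi, psi, omega_D, omega_I,
                         topology = c("A", "linear", "gapless")) {
  topology <- match.arg(topology)
  stopifnot(inherits(primed, "phmm_primed"))
  if (is.null(primed$Sprime))
    stop("primed parameters lack Sprime; cannot form pair probabilities")
  stopifnot(omega_D > 0, omega_D < 1, omega_I > 0, omega_I < 1)
  phi <- check_letter_probs(phi, primed$alphabet, "phi")
  psi <- check_letter_probs(psi, primed$alphabet, "psi")
  pi <- outer(phi, psi) * primed$Sprime / primed$c_pr
  gamma <- primed$c_pr * omega_D * omega_I
  if (topology == "gapless") {
    if (gamma >= 1)
      stop(sprintf("infeasible omegas: gamma = %.6g >= 1", gamma))
    return(phmm_params(topology, phi, psi, pi, omega_D, omega_I, gamma,
                       t = primed$t))
  }
  if (topology == "linear") {
    alpha_D <- primed$a_D_pr * omega_D
    alpha_I <- primed$a_I_pr * omega_I
    tot <- gamma + alpha_D + alpha_I
    if (!is.finite(tot) || tot >= 1)
      stop(sprintf(
        "infeasible omegas: gamma + alpha_D + alpha_I = %.6g >= 1", tot))
    return(phmm_params(topology, phi, psi, pi, omega_D, omega_I, gamma,
                       alpha_D = alpha_D, alpha_I = alpha_I, t = primed$t))
  }
  beta_D <- primed$b_D_pr * omega_D
  beta_I <- primed$b_I_pr * omega_I
  if (beta_D >= 1 || beta_I >= 1)
    stop(sprintf("infeasible omegas: beta_D = %.6g, beta_I = %.6g",
                 beta_D, beta_I))
  alpha_D <- primed$a_D_pr * omega_D / (1 - beta_D)
  alpha_I <- primed$a_I_pr * omega_I / (1 - beta_I)
  tot <- gamma + alpha_D + alpha_I
  if (!is.finite(tot) || tot >= 1)
    stop(sprintf(
      "infeasible omegas: gamma + alpha_D + alpha_I = %.6g >= 1", tot))
  phmm_params(topology, phi, psi, pi, omega_D, omega_I, gamma,
              alpha_D = alpha_D, beta_D = beta_D,
              alpha_I = alpha_I, beta_I = beta_I, t = primed$t)
}

#' Construct a full pair-HMM parameter set
#'
#' One concrete probability model: emission probabilities (phi, psi, pi) and
#' transition probabilities for one of the local-alignment topologies.
#' Invariants are checked (probability ranges; gamma + alpha_D + alpha_I < 1
#' for gapped topologies).
#'
#' @param topology `"gapless"`, `"linear"`, `"A"`, or `"B"`.
#' @param phi,psi,pi emission probabilities.
#' @param omega_D,omega_I,gamma,alpha_D,beta_D,alpha_I,beta_I transition
#'   probabilities; alpha/beta arguments are NA where the topology lacks
#'   them (gapless: no alpha or beta; linear: no beta).
#' @param t associated temperature, if known (metadata).
#' @return list of class `"phmm_params"`.
#' @export
phmm_params <- function(topology, phi, psi, pi, omega_D, omega_I, gamma,
                        alpha_D = NA_real_, beta_D = NA_real_,
                        alpha_I = NA_real_, beta_I = NA_real_,
                        t = NA_real_) {
  stopifnot(topology %in% c("gapless", "linear", "A", "B"))
  alphabet <- names(phi)
  if (is.null(alphabet)) alphabet <- rownames(pi)
  probs <- c(omega_D = omega_D, omega_I = omega_I, gamma = gamma)
  if (topology != "gapless") probs <- c(probs, alpha_D = alpha_D,
                                        alpha_I = alpha_I)
  if (topology %in% c("A", "B")) probs <- c(probs, beta_D = beta_D,
                                            beta_I = beta_I)
  bad <- probs[!is.na(probs) & (probs < 0 | probs >= 1)]
  if (length(bad))
    stop("transition probabilities out of [0, 1): ",
         paste(names(bad), collapse = ", "))
  if (abs(sum(pi) - 1) > 1e-9) stop("pi must sum to 1")
  tot <- gamma + ifelse(is.na(alpha_D), 0, alpha_D) +
    ifelse(is.na(alpha_I), 0, alpha_I)
  if (tot >= 1)
    stop(sprintf("gamma + alpha_D + alpha_I = %.6g >= 1", tot))
  structure(list(topology = topology, phi = phi, psi = psi, pi = pi,
                 omega_D = omega_D, omega_I = omega_I, gamma = gamma,
                 alpha_D = alpha_D, beta_D = beta_D,
                 alpha_I = alpha_I, beta_I = beta_I,
                 alphabet = alphabet, t = t),
            class = "phmm_params")
}

#' Classify the length-probability balance of a model family
#'
#' A gapped model family has balanced length probability -- no prior bias
#' toward longer or shorter alignments -- when the criterion value equals 1:
#' C' = c' + a'_D / (1 - b'_D) + a'_I / (1 - b'_I) for affine gaps,
#' c' + a'_D + a'_I for linear gaps, and plain c' for gapless models.
#' Values below 1 bias toward shorter alignments (omegas may approach 1 while
#' gamma + alpha_D + alpha_I stays below 1); values above 1 bias toward
#' longer alignments (the omegas acquire an upper bound).
#'
#' @param primed a `"phmm_primed"` object.
#' @param topology `"A"` (affine; also used for `"B"`), `"linear"`, or
#'   `"gapless"`.
#' @param tolerance half-width of the band around 1 treated as balanced.
#' @return list of class `"balance_report"`: `C_pr`, `classification` (one
#'   of `"balanced"`, `"shorter_bias"`, `"longer_bias"`), `tolerance`.
#' @export
classify_balance <- function(primed, topology = c("A", "B", "linear",
                                                  "gapless"),
                             tolerance = 1e-9) {
  topology <- match.arg(topology)
  stopifnot(inherits(primed, "phmm_primed"))
  val <- switch(topology,
    gapless = primed$c_pr,
    linear = primed$c_pr + primed$a_D_pr + primed$a_I_pr,
    { # affine
      if (is.na(primed$C_pr))
        stop("C' undefined: a gap extension factor b' is >= 1")
      primed$C_pr
    })
  cls <- if (abs(val - 1) <= tolerance) "balanced"
         else if (val < 1) "shorter_bias" else "longer_bias"
  structure(list(C_pr = val, classification = cls, tolerance = tolerance),
            class = "balance_report")
}

#' @export
print.balance_report <- function(x, ...) {
  cat("Length-probability balance: C' =", format(x$C_pr), "->",
      x$classification, "\n")
  invisible(x)
}

## C'(t) - 1 for a symmetric-gap scheme under homogeneous letter
## probabilities; NA where the homogeneous solve fails.
.balance_fn <- function(S, a, b) {
  function(t) {
    lc <- .log_c_of_t(S, t)
    if (is.na(lc)) return(NA_real_)
    bp <- exp(b / t)
    if (bp >= 1) return(Inf)
    exp(lc) + 2 * exp(a / t) / (1 - bp) - 1
  }
}

#' Temperatures of balanced length probability
#'
#' For a scheme with symmetric affine gap scores (a_D = a_I = a,
#' b_D = b_I = b) and homogeneous letter probabilities at each temperature,
#' finds all roots of C'(t) = 1.  Unlike the gapless uniform-length
#' condition, balance does not pin down a unique temperature: there may be
#' zero, one (tangency), or two roots.
#'
#' @param S substitution matrix with alphabet dimnames.
#' @param a,b gap scores (first / extension), typically negative.
#' @param n_scan number of log-spaced scan points.
#' @return Numeric vector of balanced temperatures (possibly empty), sorted.
#' @examples
#' length(find_balanced_temperatures(builtin_matrix("Simple"), -6, -1))  # 2
#' @export
find_balanced_temperatures <- function(S, a, b, n_scan = 512L) {
  stopifnot(is.matrix(S))
  M <- max(abs(S))
  ts <- exp(seq(log(1e-3 * M), log(1e6 * M), length.out = n_scan))
  f <- .balance_fn(S, a, b)
  fv <- vapply(ts, f, numeric(1))
  if (anyNA(fv))
    warning(sum(is.na(fv)), " scan temperatures skipped: homogeneous ",
            "letter probabilities not solvable there")
  ok <- which(!is.na(fv) & is.finite(fv))
  roots <- numeric(0)
  for (k in seq_len(length(ok) - 1L)) {
    i <- ok[k]; j <- ok[k + 1L]
    if (fv[i] == 0) roots <- c(roots, ts[i])
    else if (sign(fv[i]) != sign(fv[j]))
      roots <- c(roots, stats::uniroot(f, c(ts[i], ts[j]),
                                       tol = 1e-12 * ts[j])$root)
  }
  sort(unique(roots))
}

#' Upper limit on omega for symmetric gaps
#'
#' With symmetric gaps (a'_D = a'_I = a', b'_D = b'_I = b') and
#' omega_D = omega_I = omega, feasibility requires
#' gamma + alpha_D + alpha_I = c' omega^2 + 2 a' omega / (1 - b' omega) < 1.
#' The boundary is the smallest root in (0, 1) of the cubic
#' b'c' omega^3 - c' omega^2 - (2a' + b') omega + 1 = 0; when no root lies in
#' (0, 1), omega is unconstrained below 1 and 1.0 is returned.
#'
#' @param primed a `"phmm_primed"` object with symmetric gap factors and
#'   b' < 1 (gapless primed parameters are treated as a' = b' = 0).
#' @return The limiting omega (in (0, 1\]).
#' @export
max_omega_symmetric <- function(primed) {
  stopifnot(inherits(primed, "phmm_primed"))
  ap <- primed$a_D_pr; bp <- primed$b_D_pr
  if (is.na(ap)) ap <- 0
  if (is.na(bp)) bp <- 0
  if (!is.na(primed$a_I_pr) &&
      (abs(primed$a_I_pr - ap) > 1e-12 * max(1, ap) ||
       abs(primed$b_I_pr - bp) > 1e-12 * max(1, bp)))
    stop("max_omega_symmetric requires symmetric gap factors")
  cp <- primed$c_pr
  ## ascending coefficients of 1 - (2a'+b') w - c' w^2 + b'c' w^3
  coef <- c(1, -(2 * ap + bp), -cp, bp * cp)
  while (length(coef) > 1L && abs(coef[length(coef)]) < 1e-300)
    coef <- coef[-length(coef)]
  rts <- polyroot(coef)
  re <- Re(rts)[abs(Im(rts)) < 1e-10 * pmax(1, Mod(rts))]
  re <- re[re > 0 & re < 1 - 1e-12]
  if (bp > 0) re <- re[re < 1 / bp]   # gap-extension series must converge
  if (!length(re)) return(1.0)
  min(re)
}

#' Transition-parameter limits at a given omega
#'
#' For symmetric gaps, the transition probabilities implied by primed values
#' at flank-continuation probability omega: beta = b' omega,
#' alpha = a' omega / (1 - b' omega), gamma = c' omega^2.  Evaluated at the
#' limiting omega from [max_omega_symmetric()], these give the extreme
#' feasible parameter values.
#'
#' @param primed a `"phmm_primed"` object (symmetric gaps).
#' @param omega value in (0, 1\].
#' @return list with `gamma`, `alpha`, `beta`.
#' @export
limit_params_at_omega <- function(primed, omega) {
  stopifnot(inherits(primed, "phmm_primed"), omega >= 0, omega <= 1)
  ap <- primed$a_D_pr; bp <- primed$b_D_pr
  if (is.na(ap)) ap <- 0
  if (is.na(bp)) bp <- 0
  if (bp * omega >= 1)
    stop("b' * omega >= 1: gap extensions do not converge")
  list(gamma = primed$c_pr * omega^2,
       alpha = ap * omega / (1 - bp * omega),
       beta = bp * omega)
}

#' Largest omega limit over temperature
#'
#' Sweeps temperatures for a scheme with symmetric gap scores: at each t,
#' homogeneous letter probabilities give c'(t), the gap factors are
#' a' = exp(a / t) and b' = exp(b / t), and the omega limit comes from the
#' feasibility cubic.  Returns the temperature maximizing that limit
#' (golden-section refinement around the best grid point) together with the
#' limit and c' there.
#'
#' @param S substitution matrix with alphabet dimnames.
#' @param a,b symmetric gap scores.
#' @param t_grid temperatures to scan; defaults to 256 log-spaced points
#'   spanning 1e-2 to 1e3 times max(abs(S)).
#' @return list with `t_star`, `omega_star`, `c_pr_star`.
#' @export
sweep_max_omega <- function(S, a, b, t_grid = NULL) {
  stopifnot(is.matrix(S))
  if (is.null(t_grid)) {
    M <- max(abs(S))
    t_grid <- exp(seq(log(1e-2 * M), log(1e3 * M), length.out = 256L))
  }
  om_at <- function(t) {
    lc <- .log_c_of_t(S, t)
    if (is.na(lc)) return(NA_real_)
    if (!is.finite(exp(lc))) return(0)   # c' astronomically large: omega ~ 0
    pr <- phmm_primed(a_D_pr = exp(a / t), b_D_pr = exp(b / t),
                      a_I_pr = exp(a / t), b_I_pr = exp(b / t),
                      c_pr = exp(lc))
    if (pr$b_D_pr >= 1) return(NA_real_)
    max_omega_symmetric(pr)
  }
  om <- vapply(t_grid, om_at, numeric(1))
  if (all(is.na(om))) stop("no feasible temperature in the grid")
  best <- which.max(om)
  lo <- t_grid[max(1L, best - 1L)]
  hi <- t_grid[min(length(t_grid), best + 1L)]
  if (length(t_grid) > 1L && lo < hi) {
    opt <- stats::optimize(function(t) {
      v <- om_at(t); if (is.na(v)) -Inf else v
    }, c(lo, hi), maximum = TRUE, tol = 1e-6 * hi)
    t_star <- opt$maximum
    omega_star <- opt$objective
    if (omega_star < om[best]) { t_star <- t_grid[best]
                                 omega_star <- om[best] }
  } else {
    t_star <- t_grid[best]; omega_star <- om[best]
  }
  list(t_star = t_star, omega_star = omega_star,
       c_pr_star = exp(.log_c_of_t(S, t_star)))
}

#' Matrix shift that balances length probability
#'
#' A scheme whose balance criterion C' exceeds 1 can be fixed by subtracting
#' a constant h from every substitution score: this rescales c' by
#' exp(-h / t) while leaving the gap terms unchanged, so choosing
#' h = t * ln( c' / (1 - a'_D / (1 - b'_D) - a'_I / (1 - b'_I)) )
#' makes C' exactly 1.  This is only possible when the gap terms alone sum
#' to less than 1.
#'
#' @inheritParams primed_params
#' @return The shift h (score units).  Subtract it from every S_xy.
#' @export
balance_shift <- function(scheme, phi, psi) {
  pr <- primed_params(scheme, phi, psi)
  gap_sum <- pr$a_D_pr / (1 - pr$b_D_pr) + pr$a_I_pr / (1 - pr$b_I_pr)
  if (is.na(gap_sum)) stop("gap extension factor b' >= 1")
  if (gap_sum >= 1)
    stop("cannot balance by matrix shift: gap terms alone reach 1")
  h <- scheme$t * log(pr$c_pr / (1 - gap_sum))
  shifted <- scheme
  shifted$S <- scheme$S - h
  chk <- classify_balance(primed_params(shifted, phi, psi), topology = "A")
  stopifnot(abs(chk$C_pr - 1) < 1e-9)
  h
}
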