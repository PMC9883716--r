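test_that("primed parameters and pair probabilities behave in closed-form cases", {
  zero <- matrix(0, 4, 4, dimnames = list(DNA, DNA))
  sch <- score_scheme(zero, t = 2.5)
  pr <- primed_params(sch, UNIF4, UNIF4)
  expect_equal(pr$c_pr, 1)
  pp <- pair_probs_from_scores(sch, UNIF4, UNIF4)
  expect_equal(pp$c, 1)
  expect_equal(pp$pi, outer(UNIF4, UNIF4))   # independence case
  ## skewed letters, still independence
  phi <- c(A = .4, C = .1, G = .2, T = .3)
  pp2 <- pair_probs_from_scores(sch, phi, UNIF4)
  expect_equal(pp2$pi, outer(phi, UNIF4))
  expect_equal(sum(pp2$pi), 1)
})

test_that("scores round-trip through pair probabilities and realizations", {
  set.seed(101)
  for (k in 1:20) {
    S <- rand_matrix()
    g <- rand_gaps()
    t <- stats::runif(1, 0.5, 5)
    sch <- score_scheme(S, g["a"], g["b"], g["a"], g["b"], t)
    phi <- rand_probs(); psi <- rand_probs()
    pr <- primed_params(sch, phi, psi)
    w <- stats::runif(2, 0.05, 0.4)
    params <- tryCatch(realize_phmm(pr, phi, psi, w[1], w[2], "A"),
                       error = function(e) NULL)
    if (is.null(params)) next   # infeasible draw
    back <- scores_from_pair_probs(params, t)
    expect_lt(max(abs(back$S - S)), 1e-9)
    expect_lt(abs(back$a_D - g[["a"]]), 1e-9)
    expect_lt(abs(back$b_D - g[["b"]]), 1e-9)
    ## any other feasible realization yields the exact same scheme
    params2 <- tryCatch(realize_phmm(pr, phi, psi, w[1] / 2, w[2] / 3, "A"),
                        error = function(e) NULL)
    if (!is.null(params2)) {
      back2 <- scores_from_pair_probs(params2, t)
      expect_lt(max(abs(back2$S - back$S)), 1e-9)
      expect_lt(abs(back2$a_I - back$a_I), 1e-9)
    }
  }
})

test_that("trivial and degenerate realizations work, infeasible ones error", {
  zero <- matrix(0, 4, 4, dimnames = list(DNA, DNA))
  sch <- score_scheme(zero, a_D = -1e9, b_D = -1e9,
                      a_I = -1e9, b_I = -1e9, t = 1)
  pr <- primed_params(sch, UNIF4, UNIF4)   # a' = b' ~ 0, c' = 1
  params <- realize_phmm(pr, UNIF4, UNIF4, 0.5, 0.5, "A")
  expect_equal(params$gamma, 0.25)
  expect_equal(params$alpha_D, 0, tolerance = 1e-12)
  expect_equal(params$beta_D, 0, tolerance = 1e-12)
  ## omega above the cubic root must be rejected with the violated sum
  t31 <- find_uniform_length_temperature(builtin_matrix("Simple"))
  sch31 <- score_scheme(builtin_matrix("Simple"), -3, -1, -3, -1, t31)
  pr31 <- primed_params(sch31, UNIF4, UNIF4)
  wmax <- max_omega_symmetric(pr31)
  expect_lt(wmax, 1)
  expect_error(realize_phmm(pr31, UNIF4, UNIF4, min(0.999, wmax + 0.01),
                            min(0.999, wmax + 0.01), "A"),
               "infeasible")
  expect_silent(realize_phmm(pr31, UNIF4, UNIF4, wmax - 0.01, wmax - 0.01,
                             "A"))
})

test_that("zero probabilities give a named domain error when inverting", {
  phi <- UNIF4
  pi <- outer(phi, phi)
  params <- phmm_params("A", phi, phi, pi, 0.4, 0.4, 0.16,
                        alpha_D = 0.1, beta_D = 0.2,
                        alpha_I = 0.1, beta_I = 0.2)
  params$alpha_D <- 0
  expect_error(scores_from_pair_probs(params, 1), "alpha_D")
})

test_that("homogeneous solve reproduces marginals and detects bad input", {
  set.seed(7)
  for (t in c(0.6, 2, 11)) {
    ## near-symmetric matrices with positive diagonal stay consistent with
    ## homogeneous letter probabilities at moderate temperatures
    S <- rand_matrix(-2, -0.5)
    diag(S) <- round(stats::runif(4, 0.5, 2), 2)
    S <- (S + t(S)) / 2
    sol <- solve_homogeneous(S, t)
    sch <- score_scheme(S, t = t)
    pp <- pair_probs_from_scores(sch, sol$phi, sol$psi)
    expect_lt(max(abs(rowSums(pp$pi) - sol$phi)), 1e-9)
    expect_lt(max(abs(colSums(pp$pi) - sol$psi)), 1e-9)
    expect_equal(pp$c, sol$c, tolerance = 1e-12)
  }
  sing <- matrix(0, 4, 4, dimnames = list(DNA, DNA))  # exp(S/t) all-ones
  expect_error(solve_homogeneous(sing, 1), "singular")
})

test_that("uniform-length temperature matches the closed form for Simple", {
  Sx <- builtin_matrix("Simple")
  t <- find_uniform_length_temperature(Sx)
  ## with uniform letters c(t) = (e^{1/t} + 3 e^{-1/t})/4 = 1 at e^{1/t} = 3
  expect_equal(t, 1 / log(3), tolerance = 1e-10)
  expect_equal(solve_homogeneous(Sx, t)$c, 1, tolerance = 1e-10)
  expect_error(find_uniform_length_temperature(-abs(Sx)), "positive")
})

test_that("c(t) approaches 1 from below and mismatch strength lowers it", {
  Sx <- builtin_matrix("Simple")
  c_inf <- solve_homogeneous(Sx, 1e6 * max(abs(Sx)))$c
  expect_gt(c_inf, 1 - 1e-3)
  expect_lt(c_inf, 1)
  S2 <- Sx; S2[S2 == -1] <- -2
  S3 <- Sx; S3[S3 == -1] <- -3
  for (t in exp(seq(log(0.2), log(50), length.out = 12))) {
    c1 <- solve_homogeneous(Sx, t)$c
    c2 <- solve_homogeneous(S2, t)$c
    c3 <- solve_homogeneous(S3, t)$c
    expect_gt(c1, c2); expect_gt(c2, c3)
  }
})

test_that("balance classification covers exact, biased and error cases", {
  pr <- phmm_primed(a_D_pr = 0.25, b_D_pr = 0, a_I_pr = 0.25, b_I_pr = 0,
                    c_pr = 0.5)
  rep1 <- classify_balance(pr, "A")
  expect_equal(rep1$C_pr, 1)
  expect_identical(rep1$classification, "balanced")
  pr_lo <- phmm_primed(a_D_pr = 0.1, b_D_pr = 0.1, a_I_pr = 0.1,
                       b_I_pr = 0.1, c_pr = 0.5)
  expect_identical(classify_balance(pr_lo, "A")$classification,
                   "shorter_bias")
  pr_hi <- phmm_primed(a_D_pr = 0.3, b_D_pr = 0.5, a_I_pr = 0.3,
                       b_I_pr = 0.5, c_pr = 0.9)
  expect_identical(classify_balance(pr_hi, "A")$classification,
                   "longer_bias")
  ## linear and gapless criteria
  prl <- phmm_primed(a_D_pr = 0.25, b_D_pr = 0.25, a_I_pr = 0.25,
                     b_I_pr = 0.25, c_pr = 0.5)
  expect_identical(classify_balance(prl, "linear")$classification,
                   "balanced")
  prg <- phmm_primed(c_pr = 1)
  expect_identical(classify_balance(prg, "gapless")$classification,
                   "balanced")
  bad <- phmm_primed(a_D_pr = 0.1, b_D_pr = 1.2, a_I_pr = 0.1, b_I_pr = 0.1,
                     c_pr = 0.5)
  expect_error(classify_balance(bad, "A"), "undefined")
})

test_that("omega feasibility limit solves the cubic and satisfies the sum rule", {
  ## large-t limit a' = b' = c' = 1
  pr1 <- phmm_primed(a_D_pr = 1, b_D_pr = 1, a_I_pr = 1, b_I_pr = 1,
                     c_pr = 1)
  w <- max_omega_symmetric(pr1)
  expect_equal(w, 0.311, tolerance = 2e-3)
  lp <- limit_params_at_omega(pr1, w)
  expect_equal(lp$gamma + 2 * lp$alpha, 1, tolerance = 1e-9)
  ## gapless reduction: 1 - c' w^2 = 0
  pr2 <- phmm_primed(a_D_pr = 0, b_D_pr = 0, a_I_pr = 0, b_I_pr = 0,
                     c_pr = 4)
  expect_equal(max_omega_symmetric(pr2), 0.5, tolerance = 1e-12)
  ## randomized sum-rule property
  set.seed(11)
  for (k in 1:25) {
    ap <- stats::runif(1, 0, 1); bp <- stats::runif(1, 0, 0.95)
    cp <- stats::runif(1, 0.3, 3)
    pr <- phmm_primed(a_D_pr = ap, b_D_pr = bp, a_I_pr = ap, b_I_pr = bp,
                      c_pr = cp)
    w <- max_omega_symmetric(pr)
    if (w < 1) {
      lp <- limit_params_at_omega(pr, w)
      expect_equal(lp$gamma + 2 * lp$alpha, 1, tolerance = 1e-9)
    } else {
      ## unconstrained: the sum stays below 1 right up to omega = 1
      lp <- limit_params_at_omega(pr, 1 - 1e-9)
      expect_lt(lp$gamma + 2 * lp$alpha, 1)
    }
  }
  expect_equal(limit_params_at_omega(pr1, 0),
               list(gamma = 0, alpha = 0, beta = 0))
})

test_that("balanced-range schemes allow omega arbitrarily close to 1", {
  Sx <- builtin_matrix("Simple")
  ts <- find_balanced_temperatures(Sx, -6, -1)
  expect_length(ts, 2L)
  tmid <- sqrt(prod(ts))    # inside the balanced range
  sol <- solve_homogeneous(Sx, tmid)
  pr <- phmm_primed(a_D_pr = exp(-6 / tmid), b_D_pr = exp(-1 / tmid),
                    a_I_pr = exp(-6 / tmid), b_I_pr = exp(-1 / tmid),
                    c_pr = sol$c)
  expect_identical(max_omega_symmetric(pr), 1.0)
  ## and at each balanced t the criterion value is exactly 1
  for (t in ts) {
    solt <- solve_homogeneous(Sx, t)
    prt <- phmm_primed(a_D_pr = exp(-6 / t), b_D_pr = exp(-1 / t),
                       a_I_pr = exp(-6 / t), b_I_pr = exp(-1 / t),
                       c_pr = solt$c)
    expect_lt(abs(classify_balance(prt, "A")$C_pr - 1), 1e-8)
  }
})

test_that("sweep of the omega limit handles the gapless degenerate grid", {
  Sx <- builtin_matrix("Simple")
  res <- sweep_max_omega(Sx, -1e9, -1e9, t_grid = 2)
  cexp <- solve_homogeneous(Sx, 2)$c
  expect_equal(res$omega_star, min(1, 1 / sqrt(cexp)), tolerance = 1e-9)
})

test_that("the balancing matrix shift restores C' = 1", {
  Sx <- builtin_matrix("Simple")
  ## closed-form case: c' = 2, gap terms 0.5, t = 1  ->  h = ln 4
  S0 <- matrix(0, 4, 4, dimnames = list(DNA, DNA))
  sch0 <- score_scheme(S0 + log(2), a_D = log(0.25), b_D = 0 - 1e9,
                       a_I = log(0.25), b_I = -1e9, t = 1)
  expect_equal(balance_shift(sch0, UNIF4, UNIF4), log(4), tolerance = 1e-9)
  ## already balanced -> 0
  tb <- find_balanced_temperatures(Sx, -6, -1)[1]
  schb <- score_scheme(Sx, -6, -1, -6, -1, tb)
  solb <- solve_homogeneous(Sx, tb)
  expect_equal(balance_shift(schb, solb$phi, solb$psi), 0, tolerance = 1e-7)
  ## a longer-biased scheme gets fixed; re-evaluation is part of the call
  tU <- find_uniform_length_temperature(Sx)
  schU <- score_scheme(Sx, -3, -1, -3, -1, tU)
  h <- balance_shift(schU, UNIF4, UNIF4)
  shifted <- schU; shifted$S <- schU$S - h
  chk <- classify_balance(primed_params(shifted, UNIF4, UNIF4), "A")
  expect_identical(chk$classification, "balanced")
  ## impossible when the gap terms alone reach 1
  schbad <- score_scheme(Sx, a_D = -0.01, b_D = -0.01,
                         a_I = -0.01, b_I = -0.01, t = 10)
  expect_error(balance_shift(schbad, UNIF4, UNIF4), "cannot balance")
})
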