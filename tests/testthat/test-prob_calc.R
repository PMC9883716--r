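test_that("Forward totals match hand-enumerated tiny cases", {
  Sp <- matrix(2, 4, 4, dimnames = list(DNA, DNA))
  pr <- phmm_primed(Sp, a_D_pr = 0.5, b_D_pr = 0.1,
                    a_I_pr = 0.3, b_I_pr = 0.2, c_pr = 2, alphabet = DNA)
  expect_equal(forward_modelA("", "", pr)$total_ratio, 1)
  ## m=1, n=0: two null flank-splits plus one core-deletion path
  expect_equal(forward_modelA("A", "", pr)$total_ratio, 2 + 0.5)
  ## m=n=1, S'=2, a'_D=a'_I=0.25: 4 nulls + M + 2 D + 2 I + D.I both orders
  pr2 <- phmm_primed(Sp, a_D_pr = 0.25, b_D_pr = 0.7,
                     a_I_pr = 0.25, b_I_pr = 0.3, c_pr = 2, alphabet = DNA)
  expect_equal(forward_modelA("A", "C", pr2)$total_ratio,
               4 + 2 + 2 * 0.25 + 2 * 0.25 + 2 * 0.25^2)
  expect_equal(forward_modelB("", "", pr)$total_ratio, 1)
  expect_equal(forward_modelB("A", "C", pr2)$total_ratio, 1 + 2)
})

test_that("the run-collapsed enumerator equals the naive per-path enumerator", {
  set.seed(301)
  for (k in 1:15) {
    m <- sample(0:3, 1); n <- sample(0:3, 1)
    R <- rand_seq(m); Q <- rand_seq(n)
    pr <- rand_primed()
    expect_equal(enumerate_paths(R, Q, pr, "A"),
                 enumerate_paths(R, Q, pr, "A", collapse_runs = FALSE),
                 tolerance = 1e-12)
  }
  expect_error(enumerate_paths(rand_seq(9), rand_seq(9), rand_primed(),
                               "A"), "refusing")
})

test_that("Forward equals exhaustive path enumeration for both topologies", {
  set.seed(302)
  for (k in 1:40) {
    m <- sample(0:4, 1); n <- sample(0:4, 1)
    R <- rand_seq(m); Q <- rand_seq(n)
    pr <- rand_primed()
    eA <- enumerate_paths(R, Q, pr, "A")
    eB <- enumerate_paths(R, Q, pr, "B")
    fA <- forward_modelA(R, Q, pr)$total_ratio
    fB <- forward_modelB(R, Q, pr)$total_ratio
    expect_equal(fA, eA, tolerance = 1e-9)
    expect_equal(fB, eB, tolerance = 1e-9)
    expect_gte(fA, 1)
    ## model A sums over a strictly larger path set (equal only when both
    ## sequences are empty and the null path is all there is)
    if (m + n > 0) expect_gt(fA, fB) else expect_equal(fA, fB)
  }
})

test_that("Forward totals depend only on the primed invariants, never the omegas", {
  set.seed(303)
  Sx <- builtin_matrix("Simple")
  t <- find_uniform_length_temperature(Sx)
  sch <- score_scheme(Sx, -3, -1, -3, -1, t)
  pr <- primed_params(sch, UNIF4, UNIF4)
  R <- rand_seq(8); Q <- rand_seq(7)
  ref <- forward_modelA(R, Q, pr)$log_total
  mus <- numeric(0)
  for (w in list(c(0.2, 0.2), c(0.5, 0.3), c(0.8, 0.1))) {
    params <- realize_phmm(pr, UNIF4, UNIF4, w[1], w[2], "A")
    pr_back <- primed_of_params(params)
    expect_equal(forward_modelA(R, Q, pr_back)$log_total, ref,
                 tolerance = 1e-9)
    mus <- c(mus, null_probability(params, R, Q))
  }
  ## the null probability itself does depend on the realization
  expect_gt(max(mus) / min(mus), 1.0001)
})

test_that("null probability matches its closed form on tiny cases", {
  set.seed(304)
  phi <- rand_probs(); psi <- rand_probs()
  sch <- score_scheme(rand_matrix(-2, 1), -3, -1, -3, -1, t = 2)
  pr <- primed_params(sch, phi, psi)
  params <- realize_phmm(pr, phi, psi, 0.3, 0.4, "A")
  base <- (1 - 0.3)^2 * (1 - 0.4)^2 *
    (1 - params$gamma - params$alpha_D - params$alpha_I)
  expect_equal(as.numeric(null_probability(params, "", "")), base,
               tolerance = 1e-12)
  expect_equal(as.numeric(null_probability(params, "A", "")),
               0.3 * phi[["A"]] * base, tolerance = 1e-12)
})

test_that("posteriors match enumeration and respect normalization", {
  Sp <- matrix(2, 4, 4, dimnames = list(DNA, DNA))
  pr <- phmm_primed(Sp, a_D_pr = 0.25, b_D_pr = 0.7,
                    a_I_pr = 0.25, b_I_pr = 0.3, c_pr = 2, alphabet = DNA)
  P11 <- posterior_match_probs("A", "C", pr)
  expect_equal(P11[1, 1], 2 / 7.125, tolerance = 1e-12)
  set.seed(305)
  for (k in 1:20) {
    m <- sample(1:4, 1); n <- sample(1:4, 1)
    R <- rand_seq(m); Q <- rand_seq(n)
    pr <- rand_primed()
    P <- posterior_match_probs(R, Q, pr)
    E <- enumerate_paths(R, Q, pr, "A", posterior = TRUE)
    expect_lt(max(abs(P - E$P)), 1e-9)
    expect_true(all(P >= 0 & P <= 1))
    expect_true(all(rowSums(P) <= 1 + 1e-9))
    expect_true(all(colSums(P) <= 1 + 1e-9))
  }
  ## vanishing match factors kill all aligned-pair posteriors
  pr0 <- phmm_primed(matrix(1e-12, 4, 4, dimnames = list(DNA, DNA)),
                     a_D_pr = 0.3, b_D_pr = 0.3, a_I_pr = 0.3, b_I_pr = 0.3,
                     c_pr = 1e-12, alphabet = DNA)
  expect_lt(max(posterior_match_probs("ACG", "ACG", pr0)), 1e-10)
})

test_that("identical sequences under a strong scheme give confident columns", {
  S <- matrix(-4, 4, 4, dimnames = list(DNA, DNA)); diag(S) <- 5
  sch <- score_scheme(S, -6, -2, -6, -2, t = 1)
  pr <- primed_params(sch, UNIF4, UNIF4)
  fx <- make_fixture("identity", 20, seed = 99)
  P <- posterior_match_probs(fx$R, fx$Q, pr)
  expect_true(all(diag(P) > 0.99))
  aln <- traceback_alignment(align_local(fx$R, fx$Q, sch, "II"))
  rel <- column_reliability(aln, P)
  expect_length(rel, 20L)
  expect_true(all(rel > 0.99))
})

test_that("column reliability reads match and gap columns correctly", {
  ## single-column alignment: the value is just P[i, j]
  aln <- structure(list(r_start = 1L, r_end = 2L, q_start = 0L, q_end = 1L,
                        ops = "M", score = 1,
                        r_row = "C", q_row = "A"),
                   class = "local_alignment")
  P <- matrix(c(0.1, 0.4, 0.2, 0.3), 2, 2)
  expect_equal(column_reliability(aln, P), P[2, 1])
  ## a deletion column over a letter with no aligned mass is certain
  aln$ops <- "D"; aln$q_end <- 0L
  P0 <- matrix(0, 2, 2)
  expect_equal(column_reliability(aln, P0), 1)
})

test_that("mapping probabilities are a stable softmax", {
  expect_equal(mapping_probability(c(5, 5, 5), 2), rep(1 / 3, 3))
  expect_equal(mapping_probability(c(3 * log(2), 0), 3), c(2 / 3, 1 / 3))
  p <- mapping_probability(c(100, 90, 80), 10)
  expect_equal(p, exp(c(10, 9, 8)) / sum(exp(c(10, 9, 8))),
               tolerance = 1e-12)
  expect_equal(sum(mapping_probability(c(1e6, 2e6, 3e6), 1)), 1)
  expect_error(mapping_probability(numeric(0), 1), "at least one")
})

test_that("hybrid scores reduce to closed forms and dominate at low temperature", {
  Sp <- matrix(2, 4, 4, dimnames = list(DNA, DNA))
  pr <- phmm_primed(Sp, a_D_pr = 0.5, b_D_pr = 0.1, a_I_pr = 0.3,
                    b_I_pr = 0.2, c_pr = 2, alphabet = DNA)
  expect_equal(hybrid_score("", "", pr, 3), 0)
  expect_equal(hybrid_score("A", "", pr, 2), 2 * log(1.5), tolerance = 1e-12)
  ## raising the primed factors to the 50th power makes both the hybrid
  ## score and the scaled Forward log-total collapse onto the optimal score
  S <- matrix(-4, 4, 4, dimnames = list(DNA, DNA)); diag(S) <- 5
  sch <- score_scheme(S, -6, -2, -6, -2, t = 1)
  schT <- sch; schT$t <- 1 / 50
  prT <- primed_params(schT, UNIF4, UNIF4)
  fx <- make_fixture("identity", 8, seed = 17)
  v <- align_local(fx$R, fx$Q, sch, "II")$best_score
  expect_lt(abs(hybrid_score(fx$R, fx$Q, prT, 1 / 50) - v), 0.01)
  expect_lt(abs(forward_modelA(fx$R, fx$Q, prT)$log_total / 50 - v), 0.01)
})

test_that("background c' generalizes the match total", {
  set.seed(306)
  sch <- score_scheme(rand_matrix(), t = 2)
  phi <- rand_probs(); psi <- rand_probs()
  pr <- primed_params(sch, phi, psi)
  expect_equal(background_cprime(pr$Sprime, phi, psi), pr$c_pr)
  expect_equal(background_cprime(matrix(1, 4, 4), rand_probs(),
                                 rand_probs()), 1)
  ## skewing the background toward the high-scoring letter raises c'
  Sp <- matrix(0.5, 4, 4, dimnames = list(DNA, DNA)); Sp["A", "A"] <- 3
  skew <- stats::setNames(rep(0.04, 4), DNA); skew["A"] <- 0.88
  expect_gt(background_cprime(Sp, skew, skew),
            background_cprime(Sp, UNIF4, UNIF4))
})
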