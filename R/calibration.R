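## run code with a deterministic RNG substream, restoring the caller's state
with_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

## deterministic per-replicate seed below 2^31
sub_seed <- function(seed, index) {
  (as.numeric(seed) * 1103L + as.numeric(index) * 7919 + 11) %% 2147483647
}

#' Simulation configuration for hybrid-score calibration
#'
#' @param m,n sequence lengths for the reference and query.
#' @param Phi,Psi letter probability vectors (named by letter); `NULL`
#'   means "use homogeneous letter probabilities of the scheme under test"
#'   (resolved by [check_lambda()]).
#' @param replicates number of random sequence pairs.
#' @param seed integer seed; every replicate derives its own substream from
#'   it, so results are reproducible and independent of ordering.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(m, n, Phi = NULL, Psi = NULL, replicates = 1000L,
                       seed) {
  stopifnot(m >= 1, n >= 1, replicates >= 1)
  if (missing(seed)) stop("an explicit seed is required")
  structure(list(m = as.integer(m), n = as.integer(n), Phi = Phi, Psi = Psi,
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate one random sequence pair
#'
#' Letters are drawn independently: reference letters from Phi, query
#' letters from Psi.  Deterministic given `(config$seed, index)`; the
#' caller's RNG state is left untouched.
#'
#' @param config a [sim_config()] with non-NULL `Phi`, `Psi`.
#' @param index replicate number (1-based).
#' @return list with character strings `R` and `Q`.
#' @export
simulate_pair <- function(config, index) {
  stopifnot(inherits(config, "sim_config"))
  Phi <- config$Phi; Psi <- config$Psi
  if (is.null(Phi) || is.null(Psi))
    stop("config must carry explicit letter probabilities")
  letters_R <- names(Phi); letters_Q <- names(Psi)
  if (is.null(letters_R) || is.null(letters_Q))
    stop("Phi and Psi must be named by alphabet letter")
  with_rng(sub_seed(config$seed, index), {
    R <- paste(sample(letters_R, config$m, replace = TRUE, prob = Phi),
               collapse = "")
    Q <- paste(sample(letters_Q, config$n, replace = TRUE, prob = Psi),
               collapse = "")
    list(R = R, Q = Q)
  })
}

#' Maximum-likelihood Gumbel fit
#'
#' Fits location mu and scale beta = 1/lambda of a Gumbel (type-I extreme
#' value) distribution by maximum likelihood.  The scale solves the standard
#' profile equation beta = mean(x) - sum(x w) / sum(w) with weights
#' w = exp(-x / beta); it is found by Newton iteration (the profile function
#' has derivative 1 + Var_w(x) / beta^2 > 0, so iteration is stable) to
#' relative tolerance 1e-10.  The standard error of lambda comes from the
#' observed information (numeric Hessian of the log-likelihood at the MLE).
#' A moment estimate (beta = sd * sqrt(6) / pi) initializes the iteration
#' and is returned for cross-checking.
#'
#' @param samples numeric vector, at least 10 values, not all equal.
#' @return list of class `"gumbel_fit"`: `lambda_hat`, `mu_hat`,
#'   `se_lambda`, `n`, `beta_hat`, `beta_moment`.
#' @export
fit_gumbel <- function(samples) {
  x <- as.numeric(samples)
  n <- length(x)
  if (n < 10L) stop("at least 10 samples are required")
  if (stats::sd(x) == 0) stop("degenerate (constant) sample")
  xbar <- mean(x); xmin <- min(x)
  beta <- stats::sd(x) * sqrt(6) / pi
  beta_moment <- beta
  for (iter in 1:200) {
    w <- exp(-(x - xmin) / beta)
    sw <- sum(w)
    ew <- sum(x * w) / sw
    g <- beta - xbar + ew
    vw <- sum((x - ew)^2 * w) / sw
    step <- g / (1 + vw / beta^2)
    beta_new <- beta - step
    if (beta_new <= 0) beta_new <- beta / 2
    done <- abs(beta_new - beta) <= 1e-10 * beta
    beta <- beta_new
    if (done) break
  }
  mu <- xmin - beta * log(mean(exp(-(x - xmin) / beta)))
  loglik <- function(p) {
    z <- (x - p[1L]) / p[2L]
    sum(-log(p[2L]) - z - exp(-z))
  }
  h <- c(abs(mu) + beta, beta) * 1e-5
  H <- matrix(0, 2, 2)
  p0 <- c(mu, beta)
  for (a in 1:2) for (b in 1:2) {
    ea <- eb <- c(0, 0); ea[a] <- h[a]; eb[b] <- h[b]
    H[a, b] <- (loglik(p0 + ea + eb) - loglik(p0 + ea - eb) -
                  loglik(p0 - ea + eb) + loglik(p0 - ea - eb)) /
      (4 * h[a] * h[b])
  }
  vc <- tryCatch(solve(-H), error = function(e) matrix(NA_real_, 2, 2))
  se_beta <- sqrt(vc[2L, 2L])
  structure(list(lambda_hat = 1 / beta, mu_hat = mu,
                 se_lambda = se_beta / beta^2, n = n,
                 beta_hat = beta, beta_moment = beta_moment),
            class = "gumbel_fit")
}

#' @export
print.gumbel_fit <- function(x, ...) {
  cat(sprintf("Gumbel ML fit (n = %d): lambda = %.5g (se %.2g), mu = %.5g\n",
              x$n, x$lambda_hat, x$se_lambda, x$mu_hat))
  invisible(x)
}

#' Calibrate the hybrid-score Gumbel scale against 1/t
#'
#' For a scheme with symmetric gap scores, finds every balanced-length
#' temperature, simulates random sequence pairs, computes their hybrid
#' alignment scores, fits a Gumbel by maximum likelihood, and reports
#' lambda_hat * t, which should be close to 1 if hybrid scores under
#' balanced parameters are Gumbel with scale 1/t.
#'
#' @param S substitution matrix with alphabet dimnames.
#' @param a,b symmetric gap scores (first / extension).
#' @param config a [sim_config()]; if its `Phi`/`Psi` are `NULL` the
#'   homogeneous letter probabilities at each balanced temperature are used.
#' @param force with `TRUE` and a scheme without any balanced temperature,
#'   calibrate anyway at the given `t_values` (diagnostic only).
#' @param t_values temperatures to use when `force = TRUE`.
#' @return data.frame with one row per temperature: `t_balanced`,
#'   `lambda_hat`, `se_lambda`, `mu_hat`, `ratio` (= lambda_hat * t), `n`.
#' @export
check_lambda <- function(S, a, b, config, force = FALSE, t_values = NULL) {
  stopifnot(inherits(config, "sim_config"))
  ts <- if (force && !is.null(t_values)) t_values
        else find_balanced_temperatures(S, a, b)
  if (!length(ts))
    stop("no balanced temperature for this scheme; shift the matrix with ",
         "balance_shift() or rerun with force = TRUE")
  rows <- lapply(ts, function(t) {
    hom <- solve_homogeneous(S, t)
    Phi <- config$Phi; Psi <- config$Psi
    if (is.null(Phi)) { Phi <- hom$phi; names(Phi) <- rownames(S) }
    if (is.null(Psi)) { Psi <- hom$psi; names(Psi) <- colnames(S) }
    cfg <- sim_config(config$m, config$n, Phi, Psi, config$replicates,
                      config$seed)
    scheme <- score_scheme(S, a_D = a, b_D = b, a_I = a, b_I = b, t = t)
    pr <- primed_params(scheme, Phi, Psi)
    scores <- vapply(seq_len(cfg$replicates), function(k) {
      pair <- simulate_pair(cfg, k)
      hybrid_score(pair$R, pair$Q, pr, t)
    }, numeric(1))
    fit <- fit_gumbel(scores)
    data.frame(t_balanced = t, lambda_hat = fit$lambda_hat,
               se_lambda = fit$se_lambda, mu_hat = fit$mu_hat,
               ratio = fit$lambda_hat * t, n = fit$n)
  })
  do.call(rbind, rows)
}
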