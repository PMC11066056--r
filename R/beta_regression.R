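#' Simulate beta-distributed proportion data with a logit-linear mean
#'
#' Covariates are drawn from `covariate_law` (default: uniform over
#' \[0, 0.15\], the observed zombie-fraction range) and responses from a
#' mean-precision beta distribution,
#' `y ~ Beta(mu * phi, (1 - mu) * phi)` with
#' `mu = logistic(intercept + slope * x)`.
#'
#' @param intercept,slope logit-scale coefficients of the mean.
#' @param phi precision parameter (> 0); response variance is
#'   `mu (1 - mu) / (1 + phi)`.
#' @param n number of rows (>= 1).
#' @param covariate_law function of `n` returning the covariate draw.
#' @param seed integer seed (`NULL` uses the current RNG stream).
#' @param names character(2): covariate and response column names.
#' @return data.frame with the covariate and response columns plus
#'   attribute `truth` recording the generating parameters.
#' @export
simulate_beta_data <- function(intercept, slope, phi, n,
                               covariate_law = function(n)
                                 runif(n, 0, 0.15),
                               seed = NULL,
                               names = c("x", "y")) {
  if (phi <= 0) stop("phi must be > 0")
  if (n < 1) stop("n must be >= 1")
  with_seed(seed, {
    x <- covariate_law(n)
    mu <- logistic(intercept + slope * x)
    y <- rbeta(n, mu * phi, (1 - mu) * phi)
    # rbeta can return exact 0/1 by underflow at extreme mu; nudge inward
    eps <- .Machine$double.eps
    y <- pmin(pmax(y, eps), 1 - eps)
    out <- data.frame(x, y)
    colnames(out) <- names
    attr(out, "truth") <- c(intercept = intercept, slope = slope,
                            phi = phi)
    out
  })
}

#' Bayesian beta regression with a logit link
#'
#' Fits the mean-precision beta model
#' `y_i ~ Beta(mu_i phi, (1 - mu_i) phi)`,
#' `logit(mu_i) = intercept + slope * x_i`, by adaptive random-walk
#' Metropolis on `(intercept, slope, log phi)`. Priors are improper flat on
#' the two coefficients and half-normal(0, 50) on `phi` (a proper but weak
#' prior; the precision always needs one). The sampling schedule follows
#' the survey's models: 4 chains, 2000 retained iterations per chain after
#' 2000 warmup iterations, giving 8000 posterior draws.
#'
#' The proposal covariance is adapted during warmup (empirical covariance
#' of the warmup history, scaled toward a 0.2-0.45 acceptance rate) and
#' frozen for the retained phase, so the retained draws are a valid Markov
#' chain. Convergence is monitored by split R-hat; values above 1.05 flag
#' the fit as non-converged (reported, never silent).
#'
#' @param data data.frame containing the model variables.
#' @param formula `response ~ covariate` (single covariate).
#' @param chains,iter,warmup MCMC schedule (defaults 4 / 2000 / 2000).
#' @param seed integer seed for the sampler.
#' @param phi_prior_sd sd of the half-normal prior on `phi`.
#' @return a `beta_regression_fit`: list with `summary` (posterior mean,
#'   sd, equal-tailed 95% credible interval and split R-hat per parameter),
#'   `draws` (retained draws, `chains * iter` rows, columns `intercept`,
#'   `slope`, `phi`), `tail` (P(slope <= 0), P(slope >= 0)),
#'   `converged`, `accept_rate`, and the schedule metadata.
#' @examples
#' d <- simulate_beta_data(-3.7, 7, 30, 148, seed = 1)
#' \donttest{fit <- fit_beta_regression(d, y ~ x, seed = 1)}
#' @export
fit_beta_regression <- function(data, formula, chains = 4, iter = 2000,
                                warmup = 2000, seed = NULL,
                                phi_prior_sd = 50) {
  vars <- all.vars(formula)
  if (length(vars) != 2)
    stop("formula must be response ~ covariate with one covariate")
  y <- data[[vars[1]]]
  x <- data[[vars[2]]]
  if (is.null(y) || is.null(x))
    stop("variables ", paste(vars, collapse = ", "), " not found in data")
  if (any(!is.finite(y)) || any(y <= 0) || any(y >= 1))
    stop("response must lie strictly in (0, 1); apply transform_zero() ",
         "to proportions that can be exactly 0")
  n <- length(y)
  if (n < 10) stop("need at least 10 rows")

  log_post <- function(th) {
    phi <- exp(th[3])
    mu <- logistic(th[1] + th[2] * x)
    ll <- sum(dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
    if (!is.finite(ll)) return(-Inf)
    # flat prior on coefficients; half-normal(0, phi_prior_sd) on phi,
    # plus the log-phi Jacobian
    ll - phi^2 / (2 * phi_prior_sd^2) + th[3]
  }

  # initialization: logit-linear least squares + moment-matched precision
  fit0 <- stats::lm.fit(cbind(1, x), logit(y))
  b0 <- fit0$coefficients
  mu0 <- logistic(b0[1] + b0[2] * x)
  v <- stats::var(y - mu0)
  phi0 <- min(max(mean(mu0 * (1 - mu0)) / max(v, 1e-8) - 1, 1), 1e4)
  init <- c(b0[1], b0[2], log(phi0))

  run_chain <- function(chain_seed, jitter) {
    with_seed(chain_seed, {
      th <- init + jitter * rnorm(3, 0, c(0.2, 0.5, 0.3))
      lp <- log_post(th)
      if (!is.finite(lp)) { th <- init; lp <- log_post(th) }
      d <- 3L
      hist <- matrix(0, warmup, d)
      lambda <- 1
      S <- diag(c(0.05, 0.1, 0.05))   # initial proposal chol
      acc_win <- 0L
      for (i in seq_len(warmup)) {
        prop <- th + lambda * as.numeric(S %*% rnorm(d))
        lp_prop <- log_post(prop)
        if (log(runif(1)) < lp_prop - lp) {
          th <- prop; lp <- lp_prop; acc_win <- acc_win + 1L
        }
        hist[i, ] <- th
        if (i %% 100 == 0) {
          rate <- acc_win / 100
          # Robbins-Monro toward ~0.3 acceptance
          lambda <- lambda * exp(0.8 * (rate - 0.3))
          acc_win <- 0L
          if (i >= 400) {
            emp <- stats::cov(hist[max(1, i - 999):i, , drop = FALSE])
            ch <- tryCatch(chol(emp + diag(1e-8, d)),
                           error = function(e) NULL)
            if (!is.null(ch)) S <- t(ch) * (2.38 / sqrt(d))
          }
        }
      }
      # frozen kernel for the retained phase
      draws <- matrix(0, iter, d)
      acc <- 0L
      for (i in seq_len(iter)) {
        prop <- th + lambda * as.numeric(S %*% rnorm(d))
        lp_prop <- log_post(prop)
        if (log(runif(1)) < lp_prop - lp) {
          th <- prop; lp <- lp_prop; acc <- acc + 1L
        }
        draws[i, ] <- th
      }
      list(draws = draws, accept = acc / iter)
    })
  }

  seeds <- if (is.null(seed)) sample.int(.Machine$integer.max, chains)
           else seed + seq_len(chains) - 1L
  chains_out <- lapply(seq_len(chains), function(cc)
    run_chain(seeds[cc], jitter = 1))
  draws_l <- lapply(chains_out, `[[`, "draws")
  draws <- do.call(rbind, draws_l)
  draws[, 3] <- exp(draws[, 3])
  colnames(draws) <- c("intercept", "slope", "phi")

  rhat <- vapply(1:3, function(j)
    split_rhat(lapply(draws_l, function(m) m[, j])), numeric(1))
  summ <- data.frame(
    parameter = colnames(draws),
    mean = colMeans(draws),
    sd = apply(draws, 2, sd),
    ci_lower = apply(draws, 2, quantile, 0.025),
    ci_upper = apply(draws, 2, quantile, 0.975),
    rhat = rhat)
  rownames(summ) <- NULL
  fit <- list(summary = summ,
              draws = draws,
              tail = c(p_le_0 = mean(draws[, "slope"] <= 0),
                       p_ge_0 = mean(draws[, "slope"] >= 0)),
              converged = all(rhat < 1.05),
              accept_rate = mean(vapply(chains_out, `[[`, numeric(1),
                                        "accept")),
              chains = chains, iter = iter, warmup = warmup,
              seed = seed, formula = deparse(formula), n = n)
  class(fit) <- "beta_regression_fit"
  if (!fit$converged)
    warning("split R-hat >= 1.05 for at least one parameter; ",
            "fit flagged as non-converged")
  fit
}

# split R-hat over a list of per-chain draw vectors
split_rhat <- function(chain_draws) {
  halves <- unlist(lapply(chain_draws, function(v) {
    m <- length(v) %/% 2
    list(v[seq_len(m)], v[(m + 1):(2 * m)])
  }), recursive = FALSE)
  n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, var, numeric(1))
  B <- n * var(means)
  W <- mean(vars)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Posterior tail fraction for the slope
#'
#' Fraction of retained posterior draws satisfying a directional predicate,
#' e.g. P(slope <= 0). Reported as a raw fraction together with the draw
#' count.
#'
#' @param fit a `beta_regression_fit`.
#' @param direction `"le"` (<= threshold) or `"ge"` (>= threshold).
#' @param threshold predicate threshold (default 0).
#' @param parameter which parameter column (default `"slope"`).
#' @return the fraction, with attributes `n_draws` and `n_satisfying`.
#' @export
posterior_tail_fraction <- function(fit, direction = c("le", "ge"),
                                    threshold = 0, parameter = "slope") {
  direction <- match.arg(direction)
  stopifnot(inherits(fit, "beta_regression_fit"))
  d <- fit$draws[, parameter]
  if (!length(d)) stop("fit contains no draws")
  hit <- if (direction == "le") d <= threshold else d >= threshold
  structure(mean(hit), n_draws = length(d), n_satisfying = sum(hit))
}

#' @export
print.beta_regression_fit <- function(x, ...) {
  cat("Bayesian beta regression:", x$formula, " (n =", x$n, ")\n")
  cat("  ", x$chains, "chains x", x$iter, "retained after", x$warmup,
      "warmup; mean acceptance", sprintf("%.2f", x$accept_rate),
      if (!x$converged) " [NON-CONVERGED]" else "", "\n")
  print(transform(x$summary, mean = round(mean, 3), sd = round(sd, 3),
                  ci_lower = round(ci_lower, 3),
                  ci_upper = round(ci_upper, 3), rhat = round(rhat, 3)))
  cat(sprintf("  P(slope <= 0) = %.6g, P(slope >= 0) = %.6g of %d draws\n",
              x$tail["p_le_0"], x$tail["p_ge_0"], nrow(x$draws)))
  invisible(x)
}

#' Write a fit summary and raw draws to disk
#'
#' @param fit a `beta_regression_fit`.
#' @param prefix path prefix; writes `<prefix>_summary.tsv` and
#'   `<prefix>_draws.tsv`.
#' @return invisibly, the two paths.
#' @export
write_beta_fit <- function(fit, prefix) {
  stopifnot(inherits(fit, "beta_regression_fit"))
  sp <- paste0(prefix, "_summary.tsv")
  dp <- paste0(prefix, "_draws.tsv")
  utils::write.table(fit$summary, sp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(as.data.frame(fit$draws), dp, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(summary = sp, draws = dp))
}
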