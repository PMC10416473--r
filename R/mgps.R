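# Gamma-Poisson shrinker: the observed count a for each table is modelled
# as Poisson(lambda * E) with E = (a+b)(a+c)/N the expected count under
# independence, and lambda drawn from a two-component gamma mixture prior.
# The marginal of a given E is then a mixture of negative binomials, which
# is what the prior fit maximises.

# Internal: log marginal likelihood of counts `a` given expecteds `e`
# under prior theta = (alpha1, beta1, alpha2, beta2, w).
mgps_loglik <- function(theta, a, e) {
  f1 <- stats::dnbinom(a, size = theta[1], prob = theta[2] / (theta[2] + e))
  f2 <- stats::dnbinom(a, size = theta[3], prob = theta[4] / (theta[4] + e))
  sum(log(pmax(theta[5] * f1 + (1 - theta[5]) * f2, 1e-300)))
}

#' Fit the gamma-Poisson shrinker prior
#'
#' Estimates the five hyperparameters of the two-component gamma mixture
#' prior on the relative reporting rate lambda by maximising the
#' negative-binomial mixture marginal likelihood of the observed counts
#' given their expected counts, over all screened tables at one level.
#' Optimisation runs on unconstrained transforms (log hyperparameters,
#' logit weight) from the conventional starting point
#' (0.2, 0.1, 2, 4, 1/3).
#'
#' @param tbl Contingency tibble (`a`, `b`, `c`, `d`); at least 20 tables
#'   are required for a stable fit.
#' @param start Optional numeric length-5 starting value
#'   `(alpha1, beta1, alpha2, beta2, w)`.
#' @return An object of class `mgps_prior`: list with `theta` (named
#'   hyperparameters), `loglik`, `n_tables`, `convergence`.
#' @export
mgps_fit <- function(tbl, start = c(0.2, 0.1, 2, 4, 1 / 3)) {
  stopifnot(all(c("a", "b", "c", "d") %in% names(tbl)))
  if (nrow(tbl) < 20) {
    abort_bad_arg("mgps_fit() needs at least 20 tables for a stable prior fit")
  }
  a <- as.numeric(tbl$a)
  b <- as.numeric(tbl$b); cc <- as.numeric(tbl$c); d <- as.numeric(tbl$d)
  e <- (a + b) * (a + cc) / (a + b + cc + d)
  par0 <- c(log(start[1:4]), stats::qlogis(start[5]))
  negll <- function(par) {
    theta <- c(exp(par[1:4]), stats::plogis(par[5]))
    -mgps_loglik(theta, a, e)
  }
  fit <- stats::optim(par0, negll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-10))
  theta <- c(exp(fit$par[1:4]), stats::plogis(fit$par[5]))
  names(theta) <- c("alpha1", "beta1", "alpha2", "beta2", "w")
  if (fit$convergence != 0) {
    stop(structure(class = c("mgps_convergence_error", "error", "condition"),
                   list(message = paste0("gamma-Poisson prior fit did not converge ",
                                         "(optim code ", fit$convergence, "); best ",
                                         "log-likelihood ", format(-fit$value)),
                        call = NULL, best_theta = theta, loglik = -fit$value)))
  }
  structure(list(theta = theta, loglik = -fit$value, n_tables = nrow(tbl),
                 convergence = fit$convergence),
            class = "mgps_prior")
}

#' @export
print.mgps_prior <- function(x, ...) {
  cat("Gamma-Poisson shrinker prior (", x$n_tables, " tables)\n", sep = "")
  print(round(x$theta, 4))
  cat("log-likelihood:", format(x$loglik), "\n")
  invisible(x)
}

# Internal: posterior mixture components for one or more tables.
mgps_posterior <- function(theta, a, e) {
  f1 <- stats::dnbinom(a, size = theta[["alpha1"]],
                       prob = theta[["beta1"]] / (theta[["beta1"]] + e))
  f2 <- stats::dnbinom(a, size = theta[["alpha2"]],
                       prob = theta[["beta2"]] / (theta[["beta2"]] + e))
  q <- theta[["w"]] * f1 / (theta[["w"]] * f1 + (1 - theta[["w"]]) * f2)
  list(q = q,
       shape1 = theta[["alpha1"]] + a, rate1 = theta[["beta1"]] + e,
       shape2 = theta[["alpha2"]] + a, rate2 = theta[["beta2"]] + e)
}

#' Empirical Bayes geometric mean under the fitted gamma-Poisson prior
#'
#' Replaces the `ebgm` / `ebgm05` columns with the full shrinkage
#' estimates: the posterior of lambda for each table is a two-component
#' gamma mixture; EBGM = exp(posterior mean of ln lambda) and EBGM05 is the
#' posterior 5th percentile of lambda (found by root-solving the mixture
#' CDF).
#'
#' @param tbl Contingency tibble (`a`, `b`, `c`, `d`).
#' @param prior An `mgps_prior` from [mgps_fit()].
#' @return `tbl` with `ebgm`, `ebgm05` columns overwritten.
#' @export
ebgm_full <- function(tbl, prior) {
  stopifnot(inherits(prior, "mgps_prior"))
  a <- as.numeric(tbl$a)
  b <- as.numeric(tbl$b); cc <- as.numeric(tbl$c); d <- as.numeric(tbl$d)
  e <- (a + b) * (a + cc) / (a + b + cc + d)
  post <- mgps_posterior(prior$theta, a, e)
  tbl$ebgm <- exp(post$q * (digamma(post$shape1) - log(post$rate1)) +
                    (1 - post$q) * (digamma(post$shape2) - log(post$rate2)))
  tbl$ebgm05 <- vapply(seq_along(a), function(i) {
    cdf <- function(l) {
      post$q[i] * stats::pgamma(l, post$shape1[i], rate = post$rate1[i]) +
        (1 - post$q[i]) * stats::pgamma(l, post$shape2[i], rate = post$rate2[i]) - 0.05
    }
    upper <- max(tbl$ebgm[i] * 10, 10)
    stats::uniroot(cdf, c(1e-10, upper), extendInt = "upX", tol = 1e-9)$root
  }, numeric(1))
  tbl
}
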