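#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a Weibull onset fit
#'
#' @param x A `weibull_fit` from [fit_weibull()].
#' @param ... Unused.
#' @return Tibble with one row per parameter: `term`, `estimate`,
#'   `conf.low`, `conf.high`.
#' @method tidy weibull_fit
#' @export
tidy.weibull_fit <- function(x, ...) {
  tibble::tibble(term = c("alpha", "beta"),
                 estimate = c(x$alpha, x$beta),
                 conf.low = c(x$alpha_lo, x$beta_lo),
                 conf.high = c(x$alpha_hi, x$beta_hi))
}

#' Glance at a Weibull onset fit
#'
#' @inheritParams tidy.weibull_fit
#' @return One-row tibble: `n`, `n_zero`, `logLik`, `failure_type`.
#' @method glance weibull_fit
#' @export
glance.weibull_fit <- function(x, ...) {
  tibble::tibble(n = x$n, n_zero = x$n_zero, logLik = x$loglik,
                 failure_type = x$failure_type)
}

#' Tidy a gamma-Poisson shrinker prior
#'
#' @param x An `mgps_prior` from [mgps_fit()].
#' @param ... Unused.
#' @return Tibble with `term` and `estimate` for the five hyperparameters.
#' @method tidy mgps_prior
#' @export
tidy.mgps_prior <- function(x, ...) {
  tibble::tibble(term = names(x$theta), estimate = unname(x$theta))
}

#' Glance at a gamma-Poisson shrinker prior
#'
#' @inheritParams tidy.mgps_prior
#' @return One-row tibble: `logLik`, `n_tables`, `convergence`.
#' @method glance mgps_prior
#' @export
glance.mgps_prior <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, n_tables = x$n_tables,
                 convergence = x$convergence)
}

#' Glance at a disproportionality screen
#'
#' @param x A `signal_screen` from [screen_signals()].
#' @param ... Unused.
#' @return One-row tibble: `n_terms`, `n_signals`, `n_socs_signal`.
#' @method glance signal_screen
#' @export
glance.signal_screen <- function(x, ...) {
  tibble::tibble(n_terms = nrow(x),
                 n_signals = attr(x, "n_signals"),
                 n_socs_signal = attr(x, "n_socs_signal"))
}
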