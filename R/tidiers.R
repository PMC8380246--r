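#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a latent growth model fit
#'
#' @param x An `lgm_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`term`, `estimate`).
#' @method tidy lgm_fit
#' @export
tidy.lgm_fit <- function(x, ...) {
  tibble::tibble(
    term = c("mu_intercept", "mu_slope", "var_intercept", "var_slope",
             "cov_intercept_slope", "theta_t0", "theta_t2", "theta_t8"),
    estimate = c(x$mu_i, x$mu_s, x$psi[1, 1], x$psi[2, 2], x$psi[1, 2],
                 x$theta))
}

#' Glance at a latent growth model fit
#'
#' @param x An `lgm_fit`.
#' @param ... Unused.
#' @return A one-row tibble: log-likelihood, chi-square, df and the fit
#'   indices (CFI, TLI, GFI, RMSEA, SRMR).
#' @method glance lgm_fit
#' @export
glance.lgm_fit <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(loglik = x$loglik, n = x$n,
                                  converged = x$converged),
                   fit_indices(x))
}

#' Tidy a multinomial fit
#'
#' @param x A `multinomial_fit`.
#' @param ... Unused.
#' @return The coefficient tibble (`class`, `term`, `estimate`, `se`, `z`,
#'   `p`).
#' @method tidy multinomial_fit
#' @export
tidy.multinomial_fit <- function(x, ...) x$coefficients

#' Glance at a multinomial fit
#' @inheritParams tidy.multinomial_fit
#' @return One-row tibble: `loglik`, `iterations`, `converged`, `base`.
#' @method glance multinomial_fit
#' @export
glance.multinomial_fit <- function(x, ...) {
  tibble::tibble(loglik = x$loglik, iterations = length(x$loglik_trace) - 1L,
                 converged = x$converged, base = x$base)
}

#' Tidy a logistic fit
#' @param x A `logistic_fit`.
#' @param ... Unused.
#' @return The coefficient tibble.
#' @method tidy logistic_fit
#' @export
tidy.logistic_fit <- function(x, ...) x$coefficients

#' Tidy an association result
#' @param x An `association_result`.
#' @param ... Unused.
#' @return The per-RNA x contrast association tibble.
#' @method tidy association_result
#' @export
tidy.association_result <- function(x, ...) x$table

#' Tidy a k-means trajectory clustering
#' @param x A `kml_result`.
#' @param ... Unused.
#' @return The per-k tibble of Calinski-Harabasz values and inertias.
#' @method tidy kml_result
#' @export
tidy.kml_result <- function(x, ...) x$per_k
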