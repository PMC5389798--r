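#' Fit the H_KS-versus-size scaling of a network family
#'
#' Two fits on the `(N, H_KS)` series of a growing family: an ordinary
#' least-squares line `H_KS = sigma * N + nu` (the extensivity slope) and a
#' log-log fit of `log H_KS` on `log N` whose slope minus one,
#' `theta_hat`, estimates the exponent in `H_KS ~ N^(theta + 1)`. The family
#' is classified `extensive` when `|theta_hat| <= theta_tol` and the linear
#' fit has `R^2 >= r2_min`; otherwise `sub_extensive` or `super_extensive`
#' by the sign of `theta_hat`. Both thresholds are tunable because any
#' finite-size test of an asymptotic property needs explicit tolerances.
#'
#' @param data data frame with columns `n` (sizes, strictly increasing,
#'   at least 3) and `hks`.
#' @param theta_tol tolerance on `theta_hat` for the extensive call.
#' @param r2_min minimum linear-fit `R^2` for the extensive call.
#' @return An object of class `hks_scaling` with fields `data`, `sigma`,
#'   `nu`, `sigma_stderr`, `r_squared`, `theta_hat`, `classification`.
#' @examples
#' fit_hks_scaling(data.frame(n = c(4, 8, 16), hks = log(2) * c(4, 8, 16)))
#' @export
fit_hks_scaling <- function(data, theta_tol = 0.1, r2_min = 0.95) {
  data <- as_tibble(data)
  if (!all(c("n", "hks") %in% names(data))) {
    abort("fit_hks_scaling: data needs columns `n` and `hks`")
  }
  if (nrow(data) < 3) abort("fit_hks_scaling: need at least 3 sizes")
  if (is.unsorted(data$n, strictly = TRUE)) {
    abort("fit_hks_scaling: sizes must be strictly increasing")
  }
  fit <- lm(hks ~ n, data = data)
  sm <- suppressWarnings(summary(fit))
  sigma <- unname(coef(fit)[2])
  nu <- unname(coef(fit)[1])
  sigma_stderr <- unname(sm$coefficients[2, 2])
  r2 <- sm$r.squared

  if (all(data$hks > 0)) {
    lfit <- lm(log(hks) ~ log(n), data = data)
    theta_hat <- unname(coef(lfit)[2]) - 1
  } else {
    # a family that loses all its positive exponents cannot be extensive;
    # the power-law exponent is undefined on non-positive values
    theta_hat <- NA_real_
  }

  classification <- if (!is.na(theta_hat) && abs(theta_hat) <= theta_tol &&
                        r2 >= r2_min) {
    "extensive"
  } else if (!is.na(theta_hat) && theta_hat < 0) {
    "sub_extensive"
  } else {
    "super_extensive"
  }

  structure(
    list(
      data = data, sigma = sigma, nu = nu, sigma_stderr = sigma_stderr,
      r_squared = r2, theta_hat = theta_hat, classification = classification,
      theta_tol = theta_tol, r2_min = r2_min
    ),
    class = "hks_scaling"
  )
}

#' @export
print.hks_scaling <- function(x, ...) {
  cat(sprintf(
    "<hks_scaling> sigma = %.4f +/- %.4f, nu = %.4f, R^2 = %.5f\n",
    x$sigma, x$sigma_stderr, x$nu, x$r_squared
  ))
  cat(sprintf("  theta_hat = %s -> %s\n",
              ifelse(is.na(x$theta_hat), "NA", sprintf("%.4f", x$theta_hat)),
              x$classification))
  invisible(x)
}

#' @export
tidy.hks_scaling <- function(x, ...) {
  dplyr::mutate(x$data, fitted = x$sigma * .data$n + x$nu)
}

#' @export
glance.hks_scaling <- function(x, ...) {
  tibble(
    sigma = x$sigma, sigma_stderr = x$sigma_stderr, nu = x$nu,
    r_squared = x$r_squared, theta_hat = x$theta_hat,
    classification = x$classification, n_sizes = nrow(x$data)
  )
}

#' @export
autoplot.hks_scaling <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$n)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(y = .data$hks)) +
    ggplot2::labs(
      x = "N", y = expression(H[KS]),
      subtitle = sprintf("sigma = %.4f +/- %.4f (%s)", object$sigma,
                         object$sigma_stderr, object$classification)
    )
}

#' Coupling rescaling that maintains extensivity
#'
#' When the intra-degree sum grows as `S ~ N^(theta + 1)` the intra-coupling
#' must shrink as `eps ~ N^-theta` for `H_KS` to stay linear in `N`:
#' `theta = 0` (ring lattices, small worlds, sparse random graphs) keeps
#' `eps` constant, `theta = 1` (all-to-all) gives `eps ~ 1/N`.
#'
#' @param theta degree-sum growth exponent, >= 0.
#' @param n network size.
#' @param base coupling at `n = 1`.
#' @return `base * n^(-theta)`.
#' @export
epsilon_rescaling <- function(theta, n, base) {
  if (theta < 0) abort("epsilon_rescaling: theta must be >= 0")
  base * n^(-theta)
}

#' Spectral invariance constants of a layer
#'
#' The constants that govern whether the normalised Lyapunov spectrum of a
#' growing extensive family collapses onto one curve:
#' `C = mean_degree / omega_max`, `C1 = eps * omega_max` (the largest
#' intra-branch supra eigenvalue) and `C2 = C1 * (C - 1) + 1`. `C2` also
#' equals the layer average `mean(C1 * omega / omega_max + 1 - C1)` — an
#' algebraic identity given the definitions, which the function evaluates
#' independently and returns for self-checking.
#'
#' @param layer a [layer_graph] with `omega_max > 0`.
#' @param epsilon intra-layer coupling (possibly size-dependent).
#' @param zeta optional inter-link growth factor `l12 / N1` recorded
#'   alongside the constants.
#' @return A tibble with one row: `C`, `C1`, `C2`, `lhs_average`, `zeta`.
#' @export
invariance_constants <- function(layer, epsilon, zeta = NA_real_) {
  omega <- layer$omega
  omega_max <- max(omega)
  if (omega_max <= 0) {
    abort("invariance_constants: layer has empty spectrum (omega_max = 0)")
  }
  C <- layer$mean_degree / omega_max
  C1 <- epsilon * omega_max
  C2 <- C1 * (C - 1) + 1
  lhs <- mean(C1 * omega / omega_max + 1 - C1)
  tibble(C = C, C1 = C1, C2 = C2, lhs_average = lhs, zeta = zeta)
}

#' Residual of the linear-growth condition on the coupling budget
#'
#' Extensivity of the first-order entropy proxy requires
#' `eps * sum(omega) + gamma * l12 = sigma * N + nu` along the family; the
#' residual (left minus right) is near zero for every member of an
#' extensive family and grows with `N` when the rescaling is violated.
#'
#' @param layer a [layer_graph] (supplies `sum(omega) = S`).
#' @param epsilon,gamma coupling strengths used at this size.
#' @param l12 number of inter-connections.
#' @param sigma,nu slope and intercept of the family's linear law.
#' @param n total multiplex size `N`.
#' @return Numeric residual.
#' @export
extensivity_condition_residual <- function(layer, epsilon, gamma, l12,
                                           sigma, nu, n) {
  epsilon * sum(layer$omega) + gamma * l12 - (sigma * n + nu)
}

#' Residual of the degree-form linear-growth condition
#'
#' The same condition rewritten through the mean intra-degree and largest
#' eigenvalue: `eps * dbar * N / 2 + (N / 4) (1 - eps * omega_max)
#' = sigma * N + nu`. Returns left minus right.
#'
#' @param n network size `N`.
#' @param epsilon intra-layer coupling at this size.
#' @param mean_degree mean intra-degree `dbar`.
#' @param omega_max largest layer Laplacian eigenvalue.
#' @param sigma,nu linear-law slope and intercept.
#' @return Numeric residual.
#' @export
extensivity_degree_residual <- function(n, epsilon, mean_degree, omega_max,
                                        sigma, nu) {
  epsilon * mean_degree * n / 2 + n / 4 * (1 - epsilon * omega_max) -
    (sigma * n + nu)
}

#' Exponent branches in the reciprocal-coupling case study
#'
#' For the case `eps = 1/N` with the largest intra eigenvalue pinned at
#' `omega_max / N`, the two branches of the mirror shift-map spectrum are
#' `lambda_odd = log(2 - omega_i / N)` and
#' `lambda_even = log(1 - (omega_i - omega_max) / N)`; the density of
#' `omega_i - omega_max` then decides whether the normalised spectrum is
#' size-invariant. Used as a spectrum-density diagnostic.
#'
#' @param omega ascending layer Laplacian eigenvalues.
#' @param n network size `N`.
#' @return Tibble with columns `omega`, `lambda_odd`, `lambda_even`.
#' @export
les_branches_reciprocal_coupling <- function(omega, n) {
  omega <- layer_omega(omega)
  omega_max <- max(omega)
  tibble(
    omega = omega,
    lambda_odd = log(2 - omega / n),
    lambda_even = log(1 - (omega - omega_max) / n)
  )
}

#' Scaling report writer
#'
#' JSON report of an [fit_hks_scaling()] result plus a TSV companion of the
#' fitted series.
#'
#' @param x an `hks_scaling` object.
#' @param path JSON output path; the TSV takes the same stem.
#' @return `path`, invisibly.
#' @export
write_scaling_report <- function(x, path) {
  jsonlite::write_json(
    list(
      sizes = x$data$n, hks = x$data$hks, sigma = x$sigma,
      sigma_stderr = x$sigma_stderr, nu = x$nu, r2 = x$r_squared,
      theta_hat = x$theta_hat, class = x$classification
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  write.table(tidy(x), sub("\\.json$", ".tsv", path), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
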