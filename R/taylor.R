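#' First-order H_KS approximations for shift-map multiplexes
#'
#' In the all-positive-exponent regime each exponent
#' `log(2 - eps * omega_i)` expands as `log 2 + log(1 - eps * omega_i / 2)`,
#' and keeping first-order terms turns the entropy proxy into explicit
#' functions of the degree sum and the number of inter-connections. The
#' expansions are first order: they are accurate for small `eps * omega` and
#' small `gamma * alpha`, and a validity warning (not an error) is emitted
#' when `eps * omega_max > 0.5` or `gamma * alpha > 0.5`.
#'
#' Three regimes are covered:
#' * single layer: `H_KS ~ N1 log 2 - (eps / 2) S`;
#' * mirror multiplex, all exponents positive:
#'   `H_KS ~ N log 2 - (eps / 2) S' - gamma * l12`, with `S' = 2 S` the
#'   degree sum of the whole multiplex;
#' * mirror multiplex with `u` non-positive exponents on the shifted branch
#'   (inter-coupling not small): `H_KS ~ (N - u) log 2 - (eps / 2) S -
#'   (eps / (2 (1 - gamma * alpha))) * sum(omega[1:(N1 - u)]) +
#'   (N1 - u) log(1 - gamma * alpha)`.
#'
#' @return An object of class `taylor_hks`: list with `value` and `regime`.
#' @name hks_taylor
NULL

new_taylor_hks <- function(value, regime) {
  structure(list(value = value, regime = regime), class = "taylor_hks")
}

#' @export
print.taylor_hks <- function(x, ...) {
  cat(sprintf("<taylor_hks> %s: H_KS ~ %.6f\n", x$regime, x$value))
  invisible(x)
}

taylor_validity_warning <- function(eps_omega_max = 0, gamma_alpha = 0) {
  if (eps_omega_max > 0.5 || gamma_alpha > 0.5) {
    warn(sprintf(
      paste("first-order H_KS expansion outside its comfort zone",
            "(eps * omega_max = %.3f, gamma * alpha = %.3f); treat the",
            "value as indicative only"),
      eps_omega_max, gamma_alpha
    ))
  }
}

#' @rdname hks_taylor
#' @param n1 layer size `N1`.
#' @param epsilon intra-layer coupling.
#' @param S intra-degree sum of one layer.
#' @param omega_max optional largest Laplacian eigenvalue, used only for the
#'   validity warning.
#' @export
hks_taylor_single <- function(n1, epsilon, S, omega_max = NULL) {
  if (!is.null(omega_max)) taylor_validity_warning(epsilon * omega_max)
  new_taylor_hks(n1 * log(2) - epsilon / 2 * S, "single_layer")
}

#' @rdname hks_taylor
#' @param n multiplex size `N = 2 N1`.
#' @param S_prime degree sum of the whole multiplex (`2 S`).
#' @param gamma inter-layer coupling.
#' @param l12 number of inter-connections.
#' @export
hks_taylor_multiplex <- function(n, epsilon, S_prime, gamma, l12,
                                 omega_max = NULL) {
  alpha <- 2 * l12 / n
  if (!is.null(omega_max)) {
    taylor_validity_warning(epsilon * omega_max, gamma * alpha)
  }
  new_taylor_hks(n * log(2) - epsilon / 2 * S_prime - gamma * l12,
                 "multiplex_all_positive")
}

#' @rdname hks_taylor
#' @param u number of non-positive exponents (assumed constant, all on the
#'   `eps * omega + 2 gamma alpha` branch).
#' @param alpha inter-connection density `l12 / N1`.
#' @param omega ascending layer Laplacian eigenvalues.
#' @export
hks_taylor_mixed <- function(n, n1, u, epsilon, S, gamma, alpha, omega) {
  if (gamma * alpha >= 1) {
    abort("hks_taylor_mixed: gamma * alpha must be < 1 (log(1 - gamma*alpha))")
  }
  omega <- layer_omega(omega)
  taylor_validity_warning(epsilon * max(omega), gamma * alpha)
  keep <- n1 - u
  partial <- if (keep >= 1) sum(omega[seq_len(keep)]) else 0
  value <- (n - u) * log(2) - epsilon / 2 * S -
    epsilon / (2 * (1 - gamma * alpha)) * partial +
    keep * log(1 - gamma * alpha)
  new_taylor_hks(value, "multiplex_mixed")
}
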