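#' Lyapunov spectra
#'
#' A `lyapunov_spectrum` stores exponents sorted in descending order together
#' with the entropy proxy `hks` (sum of the strictly positive exponents,
#' Pesin-style) and `n_negative`, the count `u` of non-positive exponents
#' (zeros are counted in `u`, making `u` deterministic).
#'
#' @param exponents numeric vector of Lyapunov exponents (any order).
#' @param warning_flag optional logical set by numerical estimators whose
#'   running averages had not settled.
#' @return An object of class `lyapunov_spectrum` with fields `exponents`,
#'   `hks`, `n_negative`, `size`.
#' @export
lyapunov_spectrum <- function(exponents, warning_flag = FALSE) {
  exponents <- sort(as.numeric(exponents), decreasing = TRUE)
  structure(
    list(
      exponents = exponents,
      hks = sum(exponents[exponents > 0]),
      n_negative = sum(exponents <= 0),
      size = length(exponents),
      warning_flag = warning_flag
    ),
    class = "lyapunov_spectrum"
  )
}

#' @export
print.lyapunov_spectrum <- function(x, ...) {
  cat(sprintf(
    "<lyapunov_spectrum> %d exponents, lambda_1 = %.4f, H_KS = %.4f, u = %d%s\n",
    x$size, x$exponents[1], x$hks, x$n_negative,
    if (isTRUE(x$warning_flag)) " [convergence warning]" else ""
  ))
  invisible(x)
}

#' @export
tidy.lyapunov_spectrum <- function(x, ...) {
  tibble(
    index = seq_len(x$size),
    normalised_index = seq_len(x$size) / x$size,
    lambda = x$exponents
  )
}

#' @export
glance.lyapunov_spectrum <- function(x, ...) {
  tibble(
    size = x$size,
    lambda_max = x$exponents[1],
    hks = x$hks,
    n_negative = x$n_negative,
    warning_flag = isTRUE(x$warning_flag)
  )
}

#' @export
autoplot.lyapunov_spectrum <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$normalised_index, y = .data$lambda)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "i / N", y = expression(lambda[i]))
}

#' Sum of positive Lyapunov exponents
#'
#' @param spectrum a [lyapunov_spectrum] or bare numeric vector.
#' @return `H_KS`, the sum of strictly positive exponents (0 if none).
#' @export
hks_of <- function(spectrum) {
  if (inherits(spectrum, "lyapunov_spectrum")) return(spectrum$hks)
  x <- as.numeric(spectrum)
  sum(x[x > 0])
}

#' Shift-map Lyapunov spectrum from supra-Laplacian eigenvalues
#'
#' For the coupled doubling map `x -> (2 x - L x) mod 1` the Jacobian
#' `2 I - L` is constant, so each exponent is `log |2 - mu_i|` with `mu_i`
#' the eigenvalues of the supra-Laplacian. A `mu_i` equal to 2 makes the
#' Jacobian singular and is rejected (perturb the couplings instead).
#'
#' @param mu numeric vector of supra-Laplacian eigenvalues, or a
#'   `supra_laplacian` object.
#' @return A [lyapunov_spectrum].
#' @export
les_from_supra <- function(mu) {
  if (inherits(mu, "supra_laplacian")) mu <- mu$mu
  mu <- as.numeric(mu)
  if (any(abs(2 - mu) < 1e-14)) {
    abort(paste(
      "les_from_supra: an eigenvalue equals 2, the Jacobian 2I - L is",
      "singular (log 0); perturb epsilon or gamma slightly"
    ))
  }
  lyapunov_spectrum(log(abs(2 - mu)))
}

#' Shift-map Lyapunov spectrum of a mirror multiplex, closed form
#'
#' For two identical layers whose nodes link only to their mirror images the
#' supra-Laplacian eigenvalues pair up as `mu = eps * omega_i` and
#' `mu = eps * omega_i + 2 * gamma * alpha` over the layer's Laplacian
#' eigenvalues `omega`, so the full `2 N1` shift-map spectrum needs no
#' matrix diagonalisation.
#'
#' @param omega ascending layer Laplacian eigenvalues (first must be 0), or
#'   a [layer_graph].
#' @param epsilon,gamma coupling strengths.
#' @param alpha inter-connection density `l12 / N1`.
#' @return A [lyapunov_spectrum] of length `2 * length(omega)`.
#' @export
les_from_layer <- function(omega, epsilon, gamma, alpha) {
  omega <- layer_omega(omega)
  mu <- mirror_mu(omega, epsilon, gamma, alpha)
  les_from_supra(mu)
}

layer_omega <- function(omega) {
  if (inherits(omega, "layer_graph")) omega <- omega$omega
  omega <- as.numeric(omega)
  if (is.unsorted(omega)) abort("omega must be ascending")
  if (abs(omega[1]) > 1e-10) abort("omega[1] must be 0 (connected Laplacian)")
  omega
}

mirror_mu <- function(omega, epsilon, gamma, alpha) {
  c(epsilon * omega, epsilon * omega + 2 * gamma * alpha)
}

#' Count non-positive shift-map exponents of a mirror multiplex
#'
#' `u` counts the exponents with `log |2 - mu| <= 0`, i.e. `|2 - mu| <= 1`,
#' over both eigenvalue branches of the mirror pairing. Zero exponents are
#' included in `u`.
#'
#' @inheritParams les_from_layer
#' @return Integer `u`.
#' @export
count_negative_les <- function(omega, epsilon, gamma, alpha) {
  omega <- layer_omega(omega)
  mu <- mirror_mu(omega, epsilon, gamma, alpha)
  sum(abs(2 - mu) <= 1)
}

#' Are all shift-map exponents positive?
#'
#' Evaluated from the exact condition `|2 - mu_i| > 1` on every eigenvalue
#' branch (not from any small-coupling approximation).
#'
#' @inheritParams les_from_layer
#' @return Logical.
#' @export
all_les_positive <- function(omega, epsilon, gamma, alpha) {
  count_negative_les(omega, epsilon, gamma, alpha) == 0L
}

#' Lyapunov exponents of the linear flow `dx/dt = C x - L x`
#'
#' For a linear flow with constant Jacobian `C I - L` the exponents are the
#' Jacobian eigenvalues themselves, `lambda_i = C - mu_i`.
#'
#' @param C scalar drift constant.
#' @param mu Laplacian eigenvalues (or a `supra_laplacian`).
#' @return Numeric vector `C - mu`.
#' @export
linear_flow_les <- function(C, mu) {
  if (inherits(mu, "supra_laplacian")) mu <- mu$mu
  C - as.numeric(mu)
}

#' Iterate the coupled shift map
#'
#' `x[n+1] = (2 x[n] - L x[n]) mod 1`, componentwise. Because the Jacobian
#' `2 I - L` is constant, the mod wrap changes the orbit but not the tangent
#' dynamics, so Lyapunov quantities are unaffected by it.
#'
#' @param state numeric start vector in `[0, 1)` with length matching `L`.
#' @param L a `supra_laplacian` (or bare coupling matrix).
#' @param steps number of iterations.
#' @return Matrix of `steps + 1` rows: the orbit, wrapped to `[0, 1)`.
#' @export
iterate_map <- function(state, L, steps) {
  if (inherits(L, "supra_laplacian")) L <- L$matrix
  L <- as.matrix(L)
  state <- as.numeric(state)
  if (length(state) != nrow(L)) {
    abort("iterate_map: state dimension does not match coupling matrix")
  }
  J <- 2 * diag(length(state)) - L
  orbit <- matrix(NA_real_, steps + 1, length(state))
  orbit[1, ] <- state %% 1
  x <- orbit[1, ]
  for (n in seq_len(steps)) {
    x <- as.numeric(J %*% x) %% 1
    orbit[n + 1, ] <- x
  }
  orbit
}

#' Write a Lyapunov spectrum to TSV with a JSON sidecar
#'
#' TSV columns: `index`, `normalised_index`, `lambda`; the sidecar records
#' `hks`, `n_negative` and the convergence flag.
#'
#' @param spectrum a [lyapunov_spectrum].
#' @param path TSV output path; the sidecar takes the same path with
#'   extension `.json`.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  write.table(tidy(spectrum), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  sidecar <- sub("\\.tsv$", "", path)
  jsonlite::write_json(
    list(hks = spectrum$hks, n_negative = spectrum$n_negative,
         size = spectrum$size, warning_flag = isTRUE(spectrum$warning_flag)),
    paste0(sidecar, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
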