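# Independent closed forms used as oracles against the package's
# eigensolver-based routes.

# circulant Laplacian eigenvalues, ring lattice with k/2 neighbours per side
circulant_omega_oracle <- function(n, k) {
  j <- 0:(n - 1)
  sort(vapply(j, function(jj) {
    k - sum(2 * cos(2 * pi * jj * seq_len(k / 2) / n))
  }, numeric(1)))
}

# exact shift-map H_KS from a mu set, written independently of the package
hks_oracle <- function(mu) {
  lam <- log(abs(2 - mu))
  sum(lam[lam > 0])
}

# dense-eigensolver supra-Laplacian mu for a mirror multiplex assembled by
# hand (identity inter-pattern, multiplicity in the alpha prefactor)
mirror_mu_oracle <- function(layer, l12, epsilon, gamma) {
  n <- layer$n_nodes
  alpha <- l12 / n
  LB <- rbind(cbind(layer$laplacian, matrix(0, n, n)),
              cbind(matrix(0, n, n), layer$laplacian))
  LA <- rbind(cbind(diag(n), -diag(n)), cbind(-diag(n), diag(n)))
  sort(eigen(epsilon * LB + gamma * alpha * LA, symmetric = TRUE,
             only.values = TRUE)$values)
}

# a small bank of layers for property loops
property_layers <- function() {
  list(
    circulant_layer(8, 2),
    circulant_layer(12, 4),
    complete_layer(6),
    small_world_layer(20, 4, 0.2, seed = 11),
    small_world_layer(30, 4, 0.5, seed = 12),
    erdos_renyi_layer(15, 0.4, seed = 13)
  )
}
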