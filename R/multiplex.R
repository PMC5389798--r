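#' Multiplex graphs
#'
#' A `multiplex_graph` couples two layers through `l12` undirected
#' inter-layer connections. The inter-layer Laplacian is assembled from the
#' inter-adjacency `A` (rows = layer-1 nodes, columns = layer-2 nodes) and
#' the degree matrices `D1 = diag(rowSums(A))`, `D2 = diag(colSums(A))` as
#' the block matrix `rbind(cbind(D1, -A), cbind(-t(A), D2))`. The intra-layer
#' Laplacian is the block diagonal of the two layer Laplacians.
#'
#' @name multiplex_graph
NULL

new_multiplex_graph <- function(layer1, layer2, inter_adjacency, l12,
                                inter_edges) {
  n1 <- layer1$n_nodes; n2 <- layer2$n_nodes
  A <- inter_adjacency
  D1 <- diag(rowSums(A), n1)
  D2 <- diag(colSums(A), n2)
  lap_A <- rbind(cbind(D1, -A), cbind(-t(A), D2))
  lap_B <- rbind(
    cbind(layer1$laplacian, matrix(0, n1, n2)),
    cbind(matrix(0, n2, n1), layer2$laplacian)
  )
  structure(
    list(
      layer1 = layer1,
      layer2 = layer2,
      inter_edges = inter_edges,
      inter_adjacency = A,
      l12 = as.integer(l12),
      alpha = l12 / n1,
      laplacian_B = lap_B,
      laplacian_A = lap_A,
      n_nodes = n1 + n2
    ),
    class = "multiplex_graph"
  )
}

#' @export
print.multiplex_graph <- function(x, ...) {
  cat(sprintf(
    "<multiplex_graph> %s + %s, l12 = %d (alpha = %.3f)\n",
    x$layer1$label, x$layer2$label, x$l12, x$alpha
  ))
  invisible(x)
}

#' Mirror multiplex: two identical layers, node-to-mirror inter-links
#'
#' Builds the analytically tractable configuration: two copies of `layer`
#' where every node makes `l12 / N1` inter-connections to its mirror node in
#' the other copy. The inter-adjacency is stored as the unit identity
#' pattern, with the link multiplicity carried by the density
#' `alpha = l12 / N1` that multiplies the inter-layer Laplacian in the supra
#' matrix. Under this convention the supra-Laplacian eigenvalues pair up in
#' closed form (`mu = eps * omega_i` and `eps * omega_i + 2 * gamma * alpha`),
#' which [les_from_layer()] exploits.
#'
#' @param layer a [layer_graph], used for both copies.
#' @param l12 number of inter-connections; must be a positive multiple of
#'   the layer size.
#' @return A [multiplex_graph].
#' @export
mirror_multiplex <- function(layer, l12) {
  n1 <- layer$n_nodes
  l12 <- as.integer(l12)
  if (l12 <= 0 || l12 %% n1 != 0) {
    abort("mirror_multiplex: l12 must be a positive multiple of the layer size")
  }
  inter_edges <- cbind(seq_len(n1), seq_len(n1))[rep(seq_len(n1), l12 / n1), ,
                                                 drop = FALSE]
  g <- new_multiplex_graph(layer, layer, diag(n1), l12,
                           inter_edges = inter_edges)
  g$mirror <- TRUE
  g
}

#' General two-layer multiplex from an inter-edge list
#'
#' No structural restriction: any set of distinct (layer-1 node, layer-2
#' node) pairs. `l12` may reach its maximum `N1 * N2`. Unlike
#' [mirror_multiplex()], no closed-form eigenvalue pairing is implied.
#'
#' @param layer1,layer2 [layer_graph] objects.
#' @param inter_edges two-column matrix (or data frame) of node pairs,
#'   first column indexing layer 1, second layer 2 (1-based); may have zero
#'   rows.
#' @return A [multiplex_graph].
#' @export
build_multiplex <- function(layer1, layer2, inter_edges) {
  inter_edges <- as.matrix(inter_edges)
  if (length(inter_edges) == 0) {
    inter_edges <- matrix(integer(0), 0, 2)
  }
  if (ncol(inter_edges) != 2) abort("inter_edges must have two columns")
  storage.mode(inter_edges) <- "integer"
  n1 <- layer1$n_nodes; n2 <- layer2$n_nodes
  if (nrow(inter_edges) > 0) {
    if (any(inter_edges[, 1] < 1 | inter_edges[, 1] > n1) ||
        any(inter_edges[, 2] < 1 | inter_edges[, 2] > n2)) {
      abort("build_multiplex: inter-edge node index out of range")
    }
    if (anyDuplicated(inter_edges) > 0) {
      abort("build_multiplex: duplicate inter-edges")
    }
  }
  A <- matrix(0, n1, n2)
  A[inter_edges] <- 1
  new_multiplex_graph(layer1, layer2, A, nrow(inter_edges), inter_edges)
}

#' Add one inter-layer edge
#'
#' Returns a new multiplex with the (i, j) inter-connection added; used by
#' the greedy evolution. Errors if the edge already exists.
#'
#' @param g a [multiplex_graph] built by [build_multiplex()].
#' @param i,j node indices in layer 1 and layer 2.
#' @return A [multiplex_graph].
#' @export
add_inter_edge <- function(g, i, j) {
  if (g$inter_adjacency[i, j] != 0) abort("inter-edge already present")
  build_multiplex(g$layer1, g$layer2, rbind(g$inter_edges, c(i, j)))
}

#' Supra-Laplacian of a multiplex
#'
#' The coupling matrix of the stacked two-layer state,
#' `L = eps * L_B + gamma * alpha * L_A`, where `L_B` is the block-diagonal
#' intra-layer Laplacian, `L_A` the inter-layer Laplacian and
#' `alpha = l12 / N1`. Row sums are zero and the eigenvalues `mu` are
#' returned ascending with `mu[1] = 0`.
#'
#' @param g a [multiplex_graph].
#' @param epsilon intra-layer (diffusive) coupling strength, >= 0.
#' @param gamma inter-layer coupling strength, >= 0.
#' @return An object of class `supra_laplacian`: list with `matrix`,
#'   `epsilon`, `gamma`, `mu`.
#' @export
supra_laplacian <- function(g, epsilon, gamma) {
  if (epsilon < 0 || gamma < 0) {
    abort("supra_laplacian: coupling strengths must be non-negative")
  }
  L <- epsilon * g$laplacian_B + gamma * g$alpha * g$laplacian_A
  mu <- sort(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  mu[abs(mu) < 1e-10] <- 0
  structure(
    list(matrix = L, epsilon = epsilon, gamma = gamma, mu = mu),
    class = "supra_laplacian"
  )
}

#' @export
print.supra_laplacian <- function(x, ...) {
  cat(sprintf(
    "<supra_laplacian> %d x %d, eps = %g, gamma = %g, mu_max = %.4f\n",
    nrow(x$matrix), ncol(x$matrix), x$epsilon, x$gamma, max(x$mu)
  ))
  invisible(x)
}
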