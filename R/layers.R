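#' Layer graphs
#'
#' A `layer_graph` is one layer of a two-layer multiplex: an undirected,
#' unweighted graph stored with the derived quantities the coupling theory
#' needs — the combinatorial Laplacian `B = D - A`, its ascending eigenvalues
#' `omega`, the intra-degree sum `S = sum(d_i)` (which equals `sum(omega)`)
#' and the mean intra-degree.
#'
#' @param adjacency symmetric 0/1 matrix with zero diagonal.
#' @param label free-text topology label (e.g. `"C8(k=4)"`).
#'
#' @return An object of class `layer_graph`: a list with elements
#'   `n_nodes`, `adjacency`, `degrees`, `laplacian`, `omega`, `degree_sum`,
#'   `mean_degree`, `label`.
#' @export
layer_graph <- function(adjacency, label = "layer") {
  adjacency <- as.matrix(adjacency)
  n <- nrow(adjacency)
  if (n != ncol(adjacency)) abort("adjacency must be square")
  if (!all(adjacency %in% c(0, 1))) abort("adjacency entries must be 0 or 1")
  if (any(diag(adjacency) != 0)) abort("adjacency must have zero diagonal")
  if (!isTRUE(all.equal(adjacency, t(adjacency)))) {
    abort("adjacency must be symmetric (graphs are undirected)")
  }
  storage.mode(adjacency) <- "double"
  degrees <- as.integer(rowSums(adjacency))
  lap <- diag(degrees, n) - adjacency
  omega <- sort(eigen(lap, symmetric = TRUE, only.values = TRUE)$values)
  # clip the eigenvalue that is 0 up to rounding
  omega[abs(omega) < 1e-10] <- 0
  structure(
    list(
      n_nodes = n,
      adjacency = adjacency,
      degrees = degrees,
      laplacian = lap,
      omega = omega,
      degree_sum = sum(degrees),
      mean_degree = sum(degrees) / n,
      label = label
    ),
    class = "layer_graph"
  )
}

#' @export
print.layer_graph <- function(x, ...) {
  cat(sprintf(
    "<layer_graph> %s: %d nodes, S = %d, mean degree %.3f, omega_max = %.4f\n",
    x$label, x$n_nodes, x$degree_sum, x$mean_degree, max(x$omega)
  ))
  invisible(x)
}

#' Circulant (ring-lattice) layer
#'
#' Every node is connected to its `k/2` nearest neighbours on each side of a
#' ring, so every intra-degree is exactly `k` and the degree sum is `S = k n`.
#' `k` must be even; `k >= n` is rejected.
#'
#' @param n number of nodes (>= 3).
#' @param k total intra-degree per node (even, `0 < k < n`).
#' @return A [layer_graph].
#' @examples
#' circulant_layer(8, 4)
#' @export
circulant_layer <- function(n, k) {
  n <- as.integer(n); k <- as.integer(k)
  if (n < 3) abort("circulant_layer: n must be >= 3")
  if (k <= 0 || k >= n) abort("circulant_layer: need 0 < k < n")
  if (k %% 2 != 0) {
    abort("circulant_layer: k must be even (k/2 neighbours on each side)")
  }
  adj <- matrix(0, n, n)
  for (m in seq_len(k / 2)) {
    idx <- seq_len(n)
    j <- ((idx - 1 + m) %% n) + 1
    adj[cbind(idx, j)] <- 1
    adj[cbind(j, idx)] <- 1
  }
  layer_graph(adj, label = sprintf("C%d(k=%d)", n, k))
}

#' Complete (all-to-all) layer
#'
#' The Laplacian spectrum of `K_n` is `(0, n, ..., n)` and `S = n (n - 1)`,
#' the quadratic-degree-sum regime of the scaling theory.
#'
#' @param n number of nodes (>= 2).
#' @return A [layer_graph].
#' @export
complete_layer <- function(n) {
  n <- as.integer(n)
  if (n < 2) abort("complete_layer: n must be >= 2")
  adj <- matrix(1, n, n) - diag(n)
  layer_graph(adj, label = sprintf("K%d", n))
}

#' Watts-Strogatz small-world layer
#'
#' Starts from [circulant_layer()] and rewires the far endpoint of each ring
#' edge with probability `p_rewire`, avoiding self-loops and duplicate edges.
#' Rewiring moves edges rather than adding or removing them, so the degree
#' sum `S = k n` is preserved for every seed. Disconnected realisations are
#' regenerated with an incremented seed (at most 100 attempts).
#'
#' @inheritParams circulant_layer
#' @param p_rewire rewiring probability in `[0, 1]`.
#' @param seed integer RNG seed.
#' @return A connected [layer_graph].
#' @export
small_world_layer <- function(n, k, p_rewire = 0.2, seed = 1L) {
  n <- as.integer(n); k <- as.integer(k)
  if (p_rewire < 0 || p_rewire > 1) {
    abort("small_world_layer: p_rewire must lie in [0, 1]")
  }
  if (k %% 2 != 0 || k <= 0 || k >= n) {
    abort("small_world_layer: need even k with 0 < k < n")
  }
  for (attempt in 0:99) {
    adj <- withr::with_seed(seed + attempt, ws_rewire(n, k, p_rewire))
    if (graph_connected(adj)) {
      return(layer_graph(
        adj,
        label = sprintf("WS%d(k=%d,p=%.2f)", n, k, p_rewire)
      ))
    }
  }
  abort("small_world_layer: no connected realisation in 100 attempts")
}

# ring lattice + Watts-Strogatz endpoint rewiring; edge count invariant
ws_rewire <- function(n, k, p) {
  adj <- matrix(0, n, n)
  for (m in seq_len(k / 2)) {
    for (i in seq_len(n)) {
      j <- ((i - 1 + m) %% n) + 1
      adj[i, j] <- 1; adj[j, i] <- 1
    }
  }
  if (p == 0) return(adj)
  # sweep offsets then nodes, the generator's documented stream order
  for (m in seq_len(k / 2)) {
    for (i in seq_len(n)) {
      j <- ((i - 1 + m) %% n) + 1
      if (adj[i, j] == 1 && runif(1) < p) {
        free <- which(adj[i, ] == 0)
        free <- free[free != i]
        if (length(free) > 0) {
          newj <- if (length(free) == 1) free else free[sample.int(length(free), 1)]
          adj[i, j] <- 0; adj[j, i] <- 0
          adj[i, newj] <- 1; adj[newj, i] <- 1
        }
      }
    }
  }
  adj
}

#' Erdos-Renyi layer
#'
#' Each of the `n (n - 1) / 2` node pairs is connected independently with
#' probability `p`, giving an expected degree sum `n (n - 1) p` (linear in
#' `n` at fixed mean degree). Connectivity is enforced by regeneration as in
#' [small_world_layer()].
#'
#' @param n number of nodes.
#' @param p edge probability in `(0, 1]`.
#' @param seed integer RNG seed.
#' @return A connected [layer_graph].
#' @export
erdos_renyi_layer <- function(n, p, seed = 1L) {
  n <- as.integer(n)
  if (p <= 0 || p > 1) abort("erdos_renyi_layer: p must lie in (0, 1]")
  for (attempt in 0:99) {
    adj <- withr::with_seed(seed + attempt, {
      a <- matrix(0, n, n)
      up <- upper.tri(a)
      a[up] <- as.numeric(runif(sum(up)) < p)
      a + t(a)
    })
    if (graph_connected(adj)) {
      return(layer_graph(adj, label = sprintf("ER%d(p=%.2f)", n, p)))
    }
  }
  abort("erdos_renyi_layer: no connected realisation in 100 attempts")
}

graph_connected <- function(adj) {
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::is_connected(g)
}
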