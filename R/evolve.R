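#' H_KS estimators for network evolution
#'
#' The greedy evolution is estimator-agnostic: any function
#' `f(g, epsilon, gamma) -> numeric H_KS` qualifies. Two are provided.
#'
#' `map_hks_estimator` is exact and fast: the shift-map entropy proxy from
#' the supra-Laplacian eigenvalues. It is the oracle for the greedy logic.
#'
#' `hr_hks_estimator(params, cfg)` returns an estimator running a Benettin
#' spectrum for each candidate network. For comparability across candidate
#' evaluations the initial state depends only on the seed and network size,
#' not on the candidate edge. A reduced time budget (`cfg`) keeps the inner
#' loop tractable; re-evaluate the final network with a full budget
#' afterwards if needed.
#'
#' @param g a [multiplex_graph].
#' @param epsilon,gamma coupling strengths.
#' @name hks_estimators
NULL

#' @rdname hks_estimators
#' @export
map_hks_estimator <- function(g, epsilon, gamma) {
  hks_of(les_from_supra(supra_laplacian(g, epsilon, gamma)))
}

#' @rdname hks_estimators
#' @param params an [hr_params].
#' @param cfg a [benettin_config]; the default is a screening budget
#'   (`t_total = 5000`) much smaller than the spectrum-quality default,
#'   because the evolution inner loop only needs to rank candidate edges.
#'   Pass a smaller budget still for coarse desk-scale experiments.
#' @export
hr_hks_estimator <- function(params = hr_params(),
                             cfg = benettin_config(t_transient = 500,
                                                   t_total = 5000)) {
  force(params); force(cfg)
  function(g, epsilon, gamma) {
    hks_of(benettin_spectrum(g, params, epsilon, gamma, cfg = cfg))
  }
}

#' Greedy evolution of inter-layer connections maximising H_KS
#'
#' Starting from a multiplex with at least one inter-connection, candidate
#' inter-layer pairs are visited exactly once in a seeded random order;
#' each candidate edge is kept only if it strictly increases the estimated
#' `H_KS` (by more than `margin`), otherwise it is removed again. Layer
#' topologies and both coupling strengths stay fixed throughout — evolution
#' only grows the number of inter-connections. Terminates when every
#' possible pair has been examined.
#'
#' @param g0 initial [multiplex_graph] (>= 1 inter-edge).
#' @param epsilon,gamma coupling strengths, held fixed.
#' @param estimator function `(g, epsilon, gamma) -> H_KS`.
#' @param seed integer seed for the candidate order.
#' @param margin acceptance margin: keep an edge iff
#'   `hks_after > hks_before + margin`. The default 0 applies the strict
#'   "increase" rule literally; a small positive margin can absorb noise of
#'   stochastic estimators.
#' @param max_candidates optionally cap the number of candidate pairs
#'   examined (default: all of them).
#' @return An object of class `evolution_trace`: list with `steps` (tibble:
#'   `candidate_i`, `candidate_j`, `hks_before`, `hks_after`, `accepted`),
#'   `final_graph`, `final_hks`, `initial_hks`, `n_accepted`, `n_rejected`,
#'   `seed`.
#' @export
evolve_multiplex <- function(g0, epsilon, gamma, estimator = map_hks_estimator,
                             seed = 1L, margin = 0,
                             max_candidates = Inf) {
  if (g0$l12 < 1) abort("evolve_multiplex: g0 needs at least one inter-edge")
  n1 <- g0$layer1$n_nodes; n2 <- g0$layer2$n_nodes
  candidates <- which(g0$inter_adjacency == 0, arr.ind = TRUE)
  order_idx <- withr::with_seed(seed, sample.int(nrow(candidates)))
  candidates <- candidates[order_idx, , drop = FALSE]
  if (is.finite(max_candidates)) {
    candidates <- candidates[seq_len(min(nrow(candidates), max_candidates)), ,
                             drop = FALSE]
  }

  g <- g0
  hks_current <- estimator(g, epsilon, gamma)
  initial_hks <- hks_current
  steps <- vector("list", nrow(candidates))
  for (idx in seq_len(nrow(candidates))) {
    i <- candidates[idx, 1]; j <- candidates[idx, 2]
    g_try <- add_inter_edge(g, i, j)
    hks_new <- tryCatch(
      estimator(g_try, epsilon, gamma),
      error = function(e) {
        abort(sprintf(
          "H_KS estimator failed on candidate inter-edge (%d, %d): %s",
          i, j, conditionMessage(e)
        ))
      }
    )
    accepted <- hks_new > hks_current + margin
    steps[[idx]] <- tibble(
      candidate_i = as.integer(i), candidate_j = as.integer(j),
      hks_before = hks_current, hks_after = hks_new, accepted = accepted
    )
    if (accepted) {
      g <- g_try
      hks_current <- hks_new
    }
  }
  steps <- dplyr::bind_rows(steps)
  structure(
    list(
      steps = steps, final_graph = g, final_hks = hks_current,
      initial_hks = initial_hks,
      n_accepted = sum(steps$accepted), n_rejected = sum(!steps$accepted),
      seed = as.integer(seed)
    ),
    class = "evolution_trace"
  )
}

#' @export
print.evolution_trace <- function(x, ...) {
  cat(sprintf(
    "<evolution_trace> %d candidates: %d accepted, %d rejected; H_KS %.4f -> %.4f\n",
    nrow(x$steps), x$n_accepted, x$n_rejected, x$initial_hks, x$final_hks
  ))
  invisible(x)
}

#' @export
tidy.evolution_trace <- function(x, ...) x$steps

#' @export
glance.evolution_trace <- function(x, ...) {
  tibble(
    n_candidates = nrow(x$steps), n_accepted = x$n_accepted,
    n_rejected = x$n_rejected, initial_hks = x$initial_hks,
    final_hks = x$final_hks, final_l12 = x$final_graph$l12
  )
}

#' @export
autoplot.evolution_trace <- function(object, ...) {
  df <- dplyr::mutate(object$steps, step = dplyr::row_number())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$hks_after,
                                   colour = .data$accepted)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = object$initial_hks, linetype = 2) +
    ggplot2::labs(x = "candidate", y = expression(H[KS]))
}

#' Sweep the coupling plane, evolving at every grid point
#'
#' Runs one full greedy evolution from the same initial multiplex at every
#' `(gamma, epsilon)` grid point and reports the final `H_KS` surface and
#' its argmax (the analogue of the optimal coupling pair). Ties are broken
#' deterministically towards the smallest `gamma`, then smallest `epsilon`.
#'
#' @param g0 initial [multiplex_graph].
#' @param gamma_grid,epsilon_grid numeric vectors of coupling values.
#' @inheritParams evolve_multiplex
#' @return An object of class `coupling_sweep`: list with `surface`
#'   (tibble: `gamma`, `epsilon`, `hks_initial`, `hks_final`, `n_accepted`),
#'   `best_point` (one-row tibble) and `traces` (list column order matches
#'   `surface`).
#' @export
coupling_sweep <- function(g0, gamma_grid, epsilon_grid,
                           estimator = map_hks_estimator, seed = 1L,
                           margin = 0, max_candidates = Inf) {
  if (length(gamma_grid) == 0 || length(epsilon_grid) == 0) {
    abort("coupling_sweep: grids must be non-empty")
  }
  grid <- tidyr_expand_grid(gamma_grid, epsilon_grid)
  traces <- purrr::map2(grid$gamma, grid$epsilon, function(gm, ep) {
    evolve_multiplex(g0, ep, gm, estimator, seed = seed, margin = margin,
                     max_candidates = max_candidates)
  })
  surface <- dplyr::mutate(
    grid,
    hks_initial = purrr::map_dbl(traces, "initial_hks"),
    hks_final = purrr::map_dbl(traces, "final_hks"),
    n_accepted = purrr::map_int(traces, "n_accepted")
  )
  ranked <- dplyr::arrange(surface, dplyr::desc(.data$hks_final),
                           .data$gamma, .data$epsilon)
  structure(
    list(surface = surface, best_point = ranked[1, ], traces = traces),
    class = "coupling_sweep"
  )
}

tidyr_expand_grid <- function(gamma_grid, epsilon_grid) {
  as_tibble(expand.grid(epsilon = epsilon_grid, gamma = gamma_grid,
                        KEEP.OUT.ATTRS = FALSE))[, c("gamma", "epsilon")]
}

#' @export
print.coupling_sweep <- function(x, ...) {
  cat(sprintf(
    "<coupling_sweep> %d grid points; best H_KS = %.4f at gamma = %g, eps = %g\n",
    nrow(x$surface), x$best_point$hks_final, x$best_point$gamma,
    x$best_point$epsilon
  ))
  invisible(x)
}

#' @export
tidy.coupling_sweep <- function(x, ...) x$surface

#' @export
autoplot.coupling_sweep <- function(object, ...) {
  ggplot2::ggplot(object$surface,
                  ggplot2::aes(x = .data$gamma, y = .data$epsilon,
                               fill = .data$hks_final)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = object$best_point, shape = 4, size = 3) +
    ggplot2::labs(x = expression(gamma), y = expression(epsilon),
                  fill = expression(H[KS]))
}

#' Extensivity experiment across network sizes
#'
#' For each total size `N`: build the two layers with `layer_factory`,
#' connect them with a single inter-edge, evolve greedily at the fixed
#' couplings, and record the final `H_KS` alongside the initial and final
#' degree sums (`s_in`, `s_fn`, inter-edges counted twice as in any
#' handshake sum). The `(N, H_KS)` series is then classified with
#' [fit_hks_scaling()].
#'
#' @param sizes strictly increasing total sizes `N` (each even; layers get
#'   `N / 2` nodes).
#' @param layer_factory function `(n1, seed) -> layer_graph`; called twice
#'   per size with different seeds so the two layers differ in wiring.
#' @inheritParams evolve_multiplex
#' @param final_estimator optional estimator re-evaluating each evolved end
#'   network (e.g. a fuller Benettin budget than the screening estimator);
#'   default re-uses the screening value.
#' @param theta_tol,r2_min classification thresholds for
#'   [fit_hks_scaling()].
#' @return An object of class `extensivity_experiment`: list with `results`
#'   (tibble: `n`, `hks`, `s_in`, `s_fn`, `l12_final`, `n_accepted`),
#'   `scaling` (an `hks_scaling`), `traces`.
#' @export
extensivity_experiment <- function(sizes, layer_factory, epsilon, gamma,
                                   estimator = map_hks_estimator, seed = 1L,
                                   margin = 0, max_candidates = Inf,
                                   final_estimator = NULL,
                                   theta_tol = 0.1, r2_min = 0.95) {
  if (length(sizes) < 3) abort("extensivity_experiment: need >= 3 sizes")
  if (any(sizes %% 2 != 0)) {
    abort("extensivity_experiment: sizes must be even (two equal layers)")
  }
  rows <- vector("list", length(sizes))
  traces <- vector("list", length(sizes))
  for (si in seq_along(sizes)) {
    n <- sizes[si]
    n1 <- n / 2
    l1 <- layer_factory(n1, seed + 101L * si)
    l2 <- layer_factory(n1, seed + 101L * si + 50L)
    g0 <- build_multiplex(l1, l2, matrix(c(1L, 1L), 1, 2))
    s_in <- l1$degree_sum + l2$degree_sum + 2 * g0$l12
    tr <- evolve_multiplex(g0, epsilon, gamma, estimator,
                           seed = seed + si, margin = margin,
                           max_candidates = max_candidates)
    gf <- tr$final_graph
    hks_final <- if (is.null(final_estimator)) {
      tr$final_hks
    } else {
      final_estimator(gf, epsilon, gamma)
    }
    rows[[si]] <- tibble(
      n = n, hks = hks_final,
      s_in = s_in,
      s_fn = gf$layer1$degree_sum + gf$layer2$degree_sum + 2 * gf$l12,
      l12_final = gf$l12, n_accepted = tr$n_accepted
    )
    traces[[si]] <- tr
  }
  results <- dplyr::bind_rows(rows)
  scaling <- fit_hks_scaling(results[, c("n", "hks")], theta_tol = theta_tol,
                             r2_min = r2_min)
  structure(
    list(results = results, scaling = scaling, traces = traces),
    class = "extensivity_experiment"
  )
}

#' @export
print.extensivity_experiment <- function(x, ...) {
  cat("<extensivity_experiment>\n")
  print(x$results)
  print(x$scaling)
  invisible(x)
}

#' @export
tidy.extensivity_experiment <- function(x, ...) x$results

#' @export
glance.extensivity_experiment <- function(x, ...) glance(x$scaling)

#' @export
autoplot.extensivity_experiment <- function(object, ...) {
  autoplot(object$scaling)
}
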