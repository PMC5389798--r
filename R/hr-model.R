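#' Hindmarsh-Rose model parameters
#'
#' Single-neuron and synapse constants of the three-variable
#' Hindmarsh-Rose bursting neuron: membrane potential `p`, fast recovery
#' `q`, slow adaptation `n`. The defaults put every neuron in the
#' multi-scale chaotic spiking-bursting regime; `theta_syn`, `lambda_sig`
#' and `Vsyn` define the sigmoidal chemical synapse
#' `K(p) = 1 / (1 + exp(-lambda_sig (p - theta_syn)))`, excitatory because
#' `Vsyn = 2` lies above the resting potential.
#'
#' @param a,b,c,d,s,p0,r,Iext single-neuron constants.
#' @param theta_syn sigmoid threshold.
#' @param lambda_sig sigmoid slope.
#' @param Vsyn synaptic reversal potential.
#' @return An object of class `hr_params`.
#' @export
hr_params <- function(a = 1, b = 3, c = 1, d = 5, s = 4, p0 = -1.6,
                      r = 0.005, Iext = 3.25, theta_syn = -0.25,
                      lambda_sig = 10, Vsyn = 2) {
  if (r < 0) abort("hr_params: r must be >= 0 (0 freezes the adaptation)")
  if (lambda_sig <= 0) abort("hr_params: lambda_sig must be > 0")
  structure(
    list(a = a, b = b, c = c, d = d, s = s, p0 = p0, r = r, Iext = Iext,
         theta_syn = theta_syn, lambda_sig = lambda_sig, Vsyn = Vsyn),
    class = "hr_params"
  )
}

hr_par_vec <- function(params) {
  unlist(params[c("a", "b", "c", "d", "s", "p0", "r", "Iext",
                  "theta_syn", "lambda_sig", "Vsyn")])
}

# coupling matrices of the HR network: electrical coupling is diffusive and
# intra-layer only (block-diagonal Laplacian); chemical coupling acts on the
# inter-layer adjacency only, as a full symmetric N x N matrix
hr_coupling_matrices <- function(g) {
  n1 <- g$layer1$n_nodes; n2 <- g$layer2$n_nodes
  A_full <- rbind(
    cbind(matrix(0, n1, n1), g$inter_adjacency),
    cbind(t(g$inter_adjacency), matrix(0, n2, n2))
  )
  list(LB = g$laplacian_B, A = A_full, n = n1 + n2)
}

check_hr_state <- function(state, n) {
  state <- as.numeric(state)
  if (length(state) != 3 * n) {
    abort(sprintf("HR state must have length 3N = %d, got %d",
                  3 * n, length(state)))
  }
  if (!all(is.finite(state))) abort("HR state contains non-finite entries")
  state
}

#' Hindmarsh-Rose multiplex vector field
#'
#' Time derivative of the stacked state `(p, q, n)` (each block of length
#' `N`): the single-neuron dynamics plus diffusive electrical coupling
#' `-eps * L_B p` within each layer and sigmoid-gated excitatory chemical
#' coupling `-gamma (p_i - Vsyn) sum_j A_ij K(p_j)` across the layers.
#'
#' @param state numeric vector of length `3 N`, ordered `(p, q, n)` blocks.
#' @param g a [multiplex_graph].
#' @param params an [hr_params].
#' @param epsilon electrical (intra-layer) coupling strength.
#' @param gamma chemical (inter-layer) coupling strength.
#' @return Numeric derivative vector of length `3 N`.
#' @export
hr_vector_field <- function(state, g, params = hr_params(), epsilon, gamma) {
  cm <- hr_coupling_matrices(g)
  state <- check_hr_state(state, cm$n)
  as.numeric(hr_rhs_cpp(state, hr_par_vec(params), cm$LB, cm$A,
                        epsilon, gamma))
}

#' Analytic Jacobian of the Hindmarsh-Rose multiplex
#'
#' Exact partial derivatives of [hr_vector_field()], including the chemical
#' terms `-gamma (p_i - Vsyn) A_ij K'(p_j)` and the diagonal drive
#' `-gamma sum_j A_ij K(p_j)`, with `K'(p) = lambda_sig K (1 - K)`. Drives
#' the variational (tangent) equations of the Lyapunov computation.
#'
#' @inheritParams hr_vector_field
#' @return `3N x 3N` matrix.
#' @export
hr_jacobian <- function(state, g, params = hr_params(), epsilon, gamma) {
  cm <- hr_coupling_matrices(g)
  state <- check_hr_state(state, cm$n)
  hr_jac_cpp(state, hr_par_vec(params), cm$LB, cm$A, epsilon, gamma)
}

#' Integrate the Hindmarsh-Rose multiplex
#'
#' Fixed-step classical 4th-order Runge-Kutta. A fixed step keeps the
#' tangent-space propagation of the Lyapunov computation consistent with
#' the orbit; the slow adaptation variable (`r = 0.005`) is what forces the
#' long horizons. Aborts with a diagnostic if the orbit diverges
#' (`|p| > 1e3`).
#'
#' @inheritParams hr_vector_field
#' @param state0 initial state (length `3 N`).
#' @param t_span total integration time.
#' @param dt time step (default 0.01).
#' @param record_every record every this many steps.
#' @return A tibble with column `time` and one column per state variable
#'   (`p1..pN`, `q1..qN`, `n1..nN`), plus attribute `final_state`.
#' @export
hr_integrate <- function(state0, g, params = hr_params(), epsilon, gamma,
                         t_span, dt = 0.01, record_every = 10L) {
  cm <- hr_coupling_matrices(g)
  state0 <- check_hr_state(state0, cm$n)
  res <- hr_integrate_cpp(state0, hr_par_vec(params), cm$LB, cm$A,
                          epsilon, gamma, t_span, dt, as.integer(record_every))
  nn <- cm$n
  states <- res$states
  colnames(states) <- c(paste0("p", seq_len(nn)), paste0("q", seq_len(nn)),
                        paste0("n", seq_len(nn)))
  out <- as_tibble(cbind(time = as.numeric(res$times), states))
  attr(out, "final_state") <- as.numeric(res$final_state)
  out
}

#' A single isolated Hindmarsh-Rose neuron as a degenerate multiplex
#'
#' One neuron, no couplings: the container on which single-neuron
#' properties (chaoticity, the flow's zero exponent, dissipation) are
#' checked before any network run.
#'
#' @return A `multiplex_graph`-compatible object with one node.
#' @export
hr_single_neuron <- function() {
  structure(
    list(
      layer1 = list(n_nodes = 1L, degree_sum = 0L, label = "single"),
      layer2 = list(n_nodes = 0L, degree_sum = 0L, label = "empty"),
      inter_edges = matrix(integer(0), 0, 2),
      inter_adjacency = matrix(0, 1, 0),
      l12 = 0L, alpha = 0,
      laplacian_B = matrix(0, 1, 1),
      laplacian_A = matrix(0, 1, 1) * 0,
      n_nodes = 1L
    ),
    class = "multiplex_graph"
  )
}

#' Seeded initial conditions for an HR multiplex
#'
#' Per-neuron uniform draws spread around the attractor:
#' `p in (-1.6, 1.6)`, `q in (-1, 1)`, `n in (2.8, 3.2)`, drawn in that
#' block order from one seeded stream.
#'
#' @param n_neurons number of neurons `N`.
#' @param seed integer seed.
#' @return Numeric state of length `3 N`.
#' @export
hr_initial_state <- function(n_neurons, seed = 1L) {
  withr::with_seed(seed, {
    c(runif(n_neurons, -1.6, 1.6),
      runif(n_neurons, -1, 1),
      runif(n_neurons, 2.8, 3.2))
  })
}
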