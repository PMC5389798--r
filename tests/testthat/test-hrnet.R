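test_that("the vector field matches hand substitution and coupling limits", {
  # isolated neuron at the origin
  d <- hr_vector_field(c(0, 0, 0), hr_single_neuron(), hr_params(),
                       epsilon = 0, gamma = 0)
  expect_equal(d, c(3.25, 1, 0.032), tolerance = 1e-12)

  # identical states in one layer: diffusive coupling annihilates constants
  c3 <- circulant_layer(3, 2)
  g <- build_multiplex(c3, c3, matrix(integer(0), 0, 2))
  state <- c(rep(0.4, 6), rep(-0.1, 6), rep(3, 6))
  d_coupled <- hr_vector_field(state, g, epsilon = 0.7, gamma = 0)
  d_free <- hr_vector_field(state, g, epsilon = 0, gamma = 0)
  expect_equal(d_coupled, d_free, tolerance = 1e-12)

  # saturated sigmoid: chemical current -> -gamma (p_i - Vsyn) * in-degree
  g1 <- build_multiplex(c3, c3, rbind(c(1L, 1L), c(1L, 2L)))
  p_big <- rep(10, 6)
  state <- c(p_big, rep(0, 6), rep(0, 6))
  d <- hr_vector_field(state, g1, epsilon = 0, gamma = 0.5)
  d0 <- hr_vector_field(state, g1, epsilon = 0, gamma = 0)
  expect_equal((d - d0)[1], -0.5 * (10 - 2) * 2, tolerance = 1e-6)
  expect_equal((d - d0)[2], 0, tolerance = 1e-6)

  expect_error(hr_vector_field(rep(0, 5), g, epsilon = 0, gamma = 0),
               "length 3N")
})

test_that("the analytic Jacobian agrees with central finite differences", {
  c3 <- circulant_layer(3, 2)
  g <- build_multiplex(c3, circulant_layer(4, 2),
                       rbind(c(1L, 2L), c(3L, 4L), c(2L, 2L)))
  n <- 7; dim <- 3 * n
  h <- 1e-6
  for (trial in 1:25) {
    state <- withr::with_seed(trial, c(runif(n, -2, 2), runif(n, -2, 2),
                                       runif(n, 2, 4)))
    J <- hr_jacobian(state, g, epsilon = 0.15, gamma = 0.8)
    Jfd <- matrix(0, dim, dim)
    for (j in seq_len(dim)) {
      e <- rep(0, dim); e[j] <- h
      Jfd[, j] <- (hr_vector_field(state + e, g, epsilon = 0.15, gamma = 0.8) -
                   hr_vector_field(state - e, g, epsilon = 0.15, gamma = 0.8)) /
        (2 * h)
    }
    expect_lt(max(abs(J - Jfd)), 1e-5)
  }
})

test_that("uncoupled Jacobian is block-diagonal with the analytic trace", {
  c3 <- circulant_layer(3, 2)
  g <- build_multiplex(c3, c3, matrix(integer(0), 0, 2))
  state <- withr::with_seed(9, runif(18, -1, 1))
  J <- hr_jacobian(state, g, epsilon = 0, gamma = 0)
  # no cross-neuron entries when eps = gamma = 0
  p <- state[1:6]
  for (i in 1:6) for (j in 1:6) {
    if (i != j) expect_equal(J[i, j], 0)
  }
  pars <- hr_params()
  expect_equal(sum(diag(J)),
               sum(-3 * pars$a * p^2 + 2 * pars$b * p - 1 - pars$r),
               tolerance = 1e-10)

  # coupled trace includes the diffusive degree and the chemical drive
  g2 <- build_multiplex(c3, c3, rbind(c(1L, 1L)))
  state <- withr::with_seed(10, runif(18, -1, 1))
  J2 <- hr_jacobian(state, g2, epsilon = 0.2, gamma = 0.4)
  K <- 1 / (1 + exp(-10 * (state[1:6] + 0.25)))
  A <- rbind(cbind(matrix(0, 3, 3), g2$inter_adjacency),
             cbind(t(g2$inter_adjacency), matrix(0, 3, 3)))
  expect_equal(sum(diag(J2)),
               sum(-3 * state[1:6]^2 + 6 * state[1:6] -
                     0.2 * diag(g2$laplacian_B) - 0.4 * as.numeric(A %*% K) -
                     1 - 0.005),
               tolerance = 1e-10)
})

test_that("integration is bounded, convergent and freezes n when r = 0", {
  g <- hr_single_neuron()
  tr <- hr_integrate(hr_initial_state(1, seed = 2), g, epsilon = 0, gamma = 0,
                     t_span = 2000, dt = 0.01, record_every = 20)
  expect_true(all(tr$p1 > -2.5 & tr$p1 < 2.5))
  # bursting: the potential crosses its midline many times
  crossings <- sum(diff(tr$p1 > 0) != 0)
  expect_gt(crossings, 50)

  # frozen adaptation
  tr0 <- hr_integrate(c(0.5, 0, 3), g, hr_params(r = 0), epsilon = 0,
                      gamma = 0, t_span = 50, dt = 0.01)
  expect_equal(tr0$n1, rep(3, nrow(tr0)), tolerance = 1e-12)

  # step halving changes the state at t = 100 only marginally
  s0 <- hr_initial_state(1, seed = 4)
  a <- attr(hr_integrate(s0, g, epsilon = 0, gamma = 0, t_span = 100,
                         dt = 0.01), "final_state")
  b <- attr(hr_integrate(s0, g, epsilon = 0, gamma = 0, t_span = 100,
                         dt = 0.005), "final_state")
  expect_lt(max(abs(a - b)), 1e-4)
})

test_that("the tangent QR machinery reproduces linear-flow exponents", {
  g <- mirror_multiplex(circulant_layer(4, 2), 4)
  L <- supra_laplacian(g, 0.1, 0.05)
  spec <- linear_flow_benettin(0.5, L)
  expect_equal(spec$exponents, sort(0.5 - L$mu, decreasing = TRUE),
               tolerance = 1e-3)
})

test_that("dissipation, degeneracy and reproducibility of HR spectra", {
  # gamma = 0, two identical layers started identically: the spectrum is
  # (numerically) doubly degenerate
  c3 <- circulant_layer(3, 2)
  g <- build_multiplex(c3, c3, matrix(integer(0), 0, 2))
  half <- hr_initial_state(3, seed = 6)
  state0 <- c(half[1:3], half[1:3], half[4:6], half[4:6], half[7:9], half[7:9])
  s <- benettin_spectrum(g, epsilon = 0.1, gamma = 0, state0 = state0,
                         cfg = benettin_config(dt = 0.02, t_transient = 200,
                                               t_total = 1200))
  lam <- s$exponents
  # pairing is tested on the dynamically meaningful part of the spectrum;
  # the deeply contracting directions (lambda < -2) carry the largest
  # finite-time fluctuations
  soft <- lam[abs(lam) < 1]
  expect_gte(length(soft), 12)
  odd <- soft[seq(1, length(soft) - 1, 2)]
  even <- soft[seq(2, length(soft), 2)]
  expect_lt(max(abs(odd - even)), 0.02)
  # dissipation: exponent sum equals the orbit-averaged Jacobian trace
  expect_equal(sum(lam), attr(s, "trace_avg"),
               tolerance = 0.02 * abs(attr(s, "trace_avg")))

  # single-neuron exponents reproducible across seeds
  cfg1 <- benettin_config(t_total = 20000, seed = 21)
  cfg2 <- benettin_config(t_total = 20000, seed = 22)
  s1 <- benettin_spectrum(hr_single_neuron(), epsilon = 0, gamma = 0, cfg = cfg1)
  s2 <- benettin_spectrum(hr_single_neuron(), epsilon = 0, gamma = 0, cfg = cfg2)
  expect_lt(max(abs(s1$exponents - s2$exponents)), 0.005)
})

test_that("hks_of sums only strictly positive exponents across routes", {
  expect_equal(hks_of(c(-1, -0.2)), 0)
  expect_equal(hks_of(c(0.5, 0.1, -0.2)), 0.6)
  s <- les_from_layer(circulant_layer(4, 2), 0.1, 0.05, 1)
  expect_equal(hks_of(s), hks_of(s$exponents))
})
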