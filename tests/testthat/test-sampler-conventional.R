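# Conventional single-site BayesCpi sampler: conditionals, variant
# equivalence, and stationary-distribution correctness.

test_that("starting-value variance follows the allele-frequency formula", {
  expect_equal(starting_sigma2_a(1, 0.95, 250), 0.08)
  expect_equal(starting_sigma2_a(1, 0, 250), 1 / 250)
  expect_error(starting_sigma2_a(1, 0.5, 0), "2 p")
  expect_error(starting_sigma2_a(1, 1, 250), "pi < 1")

  G <- quick_geno(200, 30, seed = 20)
  y <- rnorm(200)
  set.seed(1); s1 <- draw_initial_state(G, y)
  set.seed(1); s2 <- draw_initial_state(G, y)
  expect_identical(s1, s2)
  expect_equal(s1$mu, mean(y))
  expect_true(all(s1$delta == 1L))
})

test_that("marker-effect conditional matches its closed form and edge cases", {
  set.seed(21)
  dr <- sample_marker_effect(rhs = 5, cj = 10, sigma2_e = 2, sigma2_a = 1,
                             pi = 0.5)
  expect_equal(dr$mean, 5 / 12)
  expect_equal(dr$var, 2 / 12)

  # prior mass edge cases
  set.seed(22)
  dr0 <- sample_marker_effect(5, 10, 2, 1, pi = 1)
  expect_equal(dr0$a, 0); expect_equal(dr0$delta, 0L)
  dr1 <- sample_marker_effect(5, 10, 2, 1, pi = 0)
  expect_equal(dr1$delta, 1L)

  expect_error(sample_marker_effect(1, 0, 1, 1, 0.5), "monomorphic")
})

test_that("inclusion probability agrees with quadrature over the effect", {
  # independent oracle: integrate the likelihood against the slab prior
  cases <- expand.grid(cj = c(3, 40), s2e = c(0.5, 2), s2a = c(0.05, 1),
                       rhs = c(-4, 0.3, 8), pi = c(0.2, 0.9))
  for (i in seq_len(nrow(cases))) {
    cc <- cases[i, ]
    # likelihood kernel in a (up to a factor common to both hypotheses)
    lik <- function(a) exp(cc$rhs * a / cc$s2e - cc$cj * a^2 / (2 * cc$s2e))
    m1 <- integrate(function(a) lik(a) * dnorm(a, 0, sqrt(cc$s2a)),
                    -Inf, Inf, rel.tol = 1e-10)$value
    m0 <- 1  # point mass at zero: lik(0) = 1
    p_oracle <- (1 - cc$pi) * m1 / ((1 - cc$pi) * m1 + cc$pi * m0)
    set.seed(1)
    dr <- sample_marker_effect(cc$rhs, cc$cj, cc$s2e, cc$s2a, cc$pi)
    expect_equal(dr$prob_include, p_oracle, tolerance = 1e-6)
  }
})

test_that("variance and pi conditionals reproduce their known laws", {
  G <- quick_geno(50, 10, seed = 23)
  y <- rnorm(50)
  hyper <- resolved <- bayesxii:::resolve_hyper(
    bayescpi_hyper(nu_a = 4, S2_a = 1), G, y)

  # m = 0: sigma2_a is a prior draw with mean nu S2 / (nu - 2) = 2
  st <- draw_initial_state(G, y, bayescpi_hyper())
  st$a <- numeric(10); st$delta <- integer(10)
  set.seed(24)
  draws <- replicate(20000, {
    s <- sample_variances_and_pi(st, y, G$X, resolved)
    s$sigma2_a
  })
  expect_equal(mean(draws), 2, tolerance = 0.1)

  # pi | m: Beta(p - m + 1, m + 1); check first two moments with m = 4, p = 10
  st$delta <- c(rep(1L, 4), rep(0L, 6)); st$a <- c(rnorm(4), numeric(6))
  set.seed(25)
  pis <- replicate(20000, sample_variances_and_pi(st, y, G$X, resolved)$pi)
  expect_lt(abs(mean(pis) - 7 / 12), 0.01)
  expect_lt(abs(var(pis) - 7 * 5 / (144 * 13)), 0.1 * 7 * 5 / (144 * 13))
})

test_that("compiled runner replicates the R reference conditionals draw for draw", {
  G <- quick_geno(40, 8, seed = 26)
  ph <- quick_pheno(G, n_qtl = 3, seed = 27)
  hyper <- bayesxii:::resolve_hyper(bayescpi_hyper(), G, ph$y)
  for (variant in c("I", "II")) {
    set.seed(30)
    st0 <- draw_initial_state(G, ph$y, hyper)
    st_r <- bayesxii:::full_iteration_r(st0, ph$y, G$X, hyper, variant)
    tr <- run_chain(G, ph$y, hyper, n_iter = 1, thin = 1, seed = 30,
                    variant = variant)
    last <- tr$scalars[2, ]
    expect_equal(last$mu, st_r$mu, tolerance = 1e-12)
    expect_equal(last$sigma2_a, st_r$sigma2_a, tolerance = 1e-12)
    expect_equal(last$sigma2_e, st_r$sigma2_e, tolerance = 1e-12)
    expect_equal(last$pi, st_r$pi, tolerance = 1e-12)
    expect_equal(as.numeric(tr$a_thin[2, ]), st_r$a, tolerance = 1e-10)
  }
})

test_that("variants I and II yield the same chain from the same seed", {
  G <- quick_geno(50, 20, seed = 28)
  ph <- quick_pheno(G, n_qtl = 5, seed = 29)
  t1 <- run_chain(G, ph$y, n_iter = 300, thin = 5, seed = 31, variant = "I")
  t2 <- run_chain(G, ph$y, n_iter = 300, thin = 5, seed = 31, variant = "II")
  expect_identical(t1$delta_thin, t2$delta_thin)
  expect_lt(max(abs(t1$a_thin - t2$a_thin)), 1e-8)
  expect_lt(max(abs(t1$scalars$sigma2_e - t2$scalars$sigma2_e)), 1e-8)

  # operation counters reflect the O(np) vs O(p^2) sweep costs
  expect_gt(t1$op_count, 300 * 20 * 50)        # >= n per marker per iter
  expect_lt(t2$op_count, 2 * 300 * (20 + 1) * 20 + 300 * 50)
})

test_that("indicator coherence and determinism hold along the chain", {
  G <- quick_geno(60, 15, seed = 32)
  ph <- quick_pheno(G, seed = 33)
  tr <- run_chain(G, ph$y, n_iter = 400, thin = 10, seed = 34)
  expect_true(all((tr$a_thin != 0) == (tr$delta_thin == 1)))
  tr2 <- run_chain(G, ph$y, n_iter = 400, thin = 10, seed = 34)
  expect_identical(tr$scalars, tr2$scalars)
  expect_identical(tr$a_thin, tr2$a_thin)

  # zero-length chain records only the initial state
  tr0 <- run_chain(G, ph$y, n_iter = 0, seed = 35)
  expect_equal(nrow(tr0$scalars), 1)
  expect_equal(as.numeric(tr0$a_thin[1, ]), tr0$a_mean)
})

test_that("with pi = 0 and fixed variances the chain matches the conjugate posterior", {
  G <- quick_geno(100, 10, seed = 36)
  ph <- quick_pheno(G, n_qtl = 10, h2 = 0.6, seed = 37)
  s2e <- 1.5; s2a <- 0.4
  hyper <- bayescpi_hyper(pi_init = 0, estimate_pi = FALSE,
                          estimate_variances = FALSE)
  st <- draw_initial_state(G, ph$y, bayesxii:::resolve_hyper(hyper, G, ph$y))
  st$sigma2_a <- s2a; st$sigma2_e <- s2e
  tr <- run_chain(G, ph$y, hyper, n_iter = 20000, thin = 5, seed = 38,
                  init = st)
  post <- conjugate_posterior(G$X, ph$y, s2e, s2a)
  psd <- sqrt(diag(post$cov))
  est <- c(posterior_mean_mu(tr, 0.1), posterior_mean_effects(tr, 0.1))
  # Monte-Carlo tolerance: 4 posterior sd / sqrt(effective sample size)
  tol <- 4 * psd / sqrt(20000 / 20)
  expect_true(all(abs(est - post$mean) < tol))
  # marginal variances within 10 percent
  keep <- tr$thin_iters > 2000
  emp_var <- unname(apply(tr$a_thin[keep, ], 2, var))
  expect_equal(emp_var, unname(diag(post$cov)[-1]), tolerance = 0.1)
})
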