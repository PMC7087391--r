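# BayesXII sampler: independence of the per-marker conditionals, scheduling
# invariance, the augmented-model variance update, and posterior equivalence
# with the single-site sampler.

xii_fixture <- function(n = 80, p = 24, seed = 40) {
  G <- quick_geno(n, p, seed = seed)
  ph <- quick_pheno(G, n_qtl = 6, seed = seed + 1)
  aug <- build_oda(G)
  list(G = G, y = ph$y, aug = aug)
}

test_that("effect conditional uses d and the augmented right-hand side", {
  # r = 2, d = 4, s2e = s2a = 1 -> mean 0.4, variance 0.2
  expect_equal(bayesxii:::marker_log_lr(2, 4, 1, 1),
               -0.5 * log(5) + 4 / (2 * 5))
  denom <- 4 + 1
  expect_equal(2 / denom, 0.4)
  expect_equal(1 / denom, 0.2)

  # y = 0 and y_tilde = 0 give zero conditional means for every effect
  fx <- xii_fixture()
  aug0 <- precompute_crossproducts(fx$aug, fx$G, rep(0, nrow(fx$G$X)))
  st <- draw_initial_state(fx$G, fx$y, bayescpi_hyper())
  st$y_tilde <- rep(0, fx$aug$p + 1)
  st$sigma2_e <- 1e-20  # conditional s.d. ~ 0: draws sit at the means
  st$pi <- 0
  set.seed(41)
  st2 <- sample_effects_xii(st, aug0)
  expect_lt(max(abs(st2$a)), 1e-8)
  expect_lt(abs(st2$mu), 1e-8)
})

test_that("missing phenotypes are refreshed independently around their mean", {
  fx <- xii_fixture()
  st <- draw_initial_state(fx$G, fx$y, bayescpi_hyper())
  st$y_tilde <- rep(0, fx$aug$p + 1)

  # sigma2_e -> 0: y_tilde collapses onto J mu + X_tilde a
  st0 <- st; st0$sigma2_e <- 1e-24
  set.seed(42)
  st0 <- sample_missing_phenotypes(st0, fx$aug)
  expect_equal(st0$y_tilde,
               as.numeric(fx$aug$W_a %*% c(st0$mu, st0$a)), tolerance = 1e-8)

  # repeated draws have diagonal covariance (independent elements)
  st1 <- st; st1$sigma2_e <- 2
  set.seed(43)
  reps <- t(replicate(4000, sample_missing_phenotypes(st1, fx$aug)$y_tilde))
  cors <- cor(reps[, 1:8])
  off <- abs(cors[upper.tri(cors)])
  expect_lt(max(off), 4 / sqrt(4000))
  expect_equal(apply(reps[, 1:8], 2, var), rep(2, 8), tolerance = 0.2)
})

test_that("sigma2_e update uses both residual blocks with d.f. nu_e + n + p + 1", {
  fx <- xii_fixture(n = 30, p = 10, seed = 44)
  n <- 30; p <- 10
  hyper <- bayesxii:::resolve_hyper(bayescpi_hyper(), fx$G, fx$y)
  st <- draw_initial_state(fx$G, fx$y, hyper)
  st$y_tilde <- as.numeric(fx$aug$W_a %*% c(st$mu, st$a))
  st$e_tilde <- NULL  # force recomputation from y_tilde
  st$y_tilde <- st$y_tilde + rnorm(p + 1)  # non-trivial augmented residual

  e <- fx$y - st$mu - as.numeric(fx$G$X %*% st$a)
  et <- st$y_tilde - as.numeric(fx$aug$W_a %*% c(st$mu, st$a))
  scale <- hyper$nu_e * hyper$S2_e + sum(e^2) + sum(et^2)
  df <- hyper$nu_e + n + p + 1

  set.seed(45)
  draws <- replicate(10000,
    sample_variances_and_pi_xii(st, fx$y, fx$G$X, fx$aug, hyper)$sigma2_e)
  set.seed(46)
  oracle <- scale / rchisq(10000, df)
  ks <- suppressWarnings(ks.test(draws, oracle))
  expect_gt(ks$p.value, 0.01)

  # a zero augmented residual reduces to the single-site form of the scale
  st0 <- st
  st0$e_tilde <- rep(0, p + 1)
  set.seed(47)
  d0 <- replicate(5000,
    sample_variances_and_pi_xii(st0, fx$y, fx$G$X, fx$aug, hyper)$sigma2_e)
  set.seed(48)
  o0 <- (hyper$nu_e * hyper$S2_e + sum(e^2)) / rchisq(5000, df)
  expect_gt(suppressWarnings(ks.test(d0, o0))$p.value, 0.01)
})

test_that("conditional of one effect is invariant to the other effects", {
  # given y_tilde, overwrite all other effects: the (mean, sd) used for
  # marker j must not move
  fx <- xii_fixture()
  aug <- precompute_crossproducts(fx$aug, fx$G, fx$y)
  st <- draw_initial_state(fx$G, fx$y, bayescpi_hyper())
  st$y_tilde <- rnorm(aug$p + 1)
  set.seed(49)
  st_a <- sample_effects_xii(st, aug)
  st$a <- rnorm(aug$p) * 10  # radically different other effects
  set.seed(49)
  st_b <- sample_effects_xii(st, aug)
  expect_identical(st_a$a, st_b$a)
  expect_identical(st_a$mu, st_b$mu)
})

test_that("the chain is invariant to the worker partition and to reruns", {
  fx <- xii_fixture()
  t1 <- run_chain_xii(fx$G, fx$y, fx$aug, n_iter = 150, thin = 5, seed = 50,
                      workers = 1)
  t4 <- run_chain_xii(fx$G, fx$y, fx$aug, n_iter = 150, thin = 5, seed = 50,
                      workers = 4)
  expect_identical(t1$a_thin, t4$a_thin)
  expect_identical(t1$delta_thin, t4$delta_thin)
  expect_identical(t1$scalars, t4$scalars)
  t1b <- run_chain_xii(fx$G, fx$y, fx$aug, n_iter = 150, thin = 5, seed = 50)
  expect_identical(t1$scalars, t1b$scalars)
})

test_that("a stale augmentation is rejected", {
  fx <- xii_fixture()
  other <- quick_geno(80, 24, seed = 99)
  expect_error(run_chain_xii(other, rnorm(80), fx$aug, n_iter = 5),
               "stale augmentation")
})

test_that("with pi = 0 and fixed variances BayesXII matches the conjugate posterior", {
  G <- quick_geno(100, 10, seed = 51)
  ph <- quick_pheno(G, n_qtl = 10, h2 = 0.6, seed = 52)
  s2e <- 1.5; s2a <- 0.4
  hyper <- bayescpi_hyper(pi_init = 0, estimate_pi = FALSE,
                          estimate_variances = FALSE)
  aug <- build_oda(G)
  st <- draw_initial_state(G, ph$y, bayesxii:::resolve_hyper(hyper, G, ph$y))
  st$sigma2_a <- s2a; st$sigma2_e <- s2e
  tr <- run_chain_xii(G, ph$y, aug, hyper, n_iter = 40000, thin = 10,
                      seed = 53, init = st)
  post <- conjugate_posterior(G$X, ph$y, s2e, s2a)
  psd <- sqrt(diag(post$cov))
  est <- c(posterior_mean_mu(tr, 0.1), posterior_mean_effects(tr, 0.1))
  # BayesXII mixes more slowly (d shrinks every coordinate): generous ESS
  tol <- 4 * psd / sqrt(40000 / 100)
  expect_true(all(abs(est - post$mean) < tol))
})

test_that("grouped ODA sampling agrees with the single-site sampler", {
  G <- quick_geno(150, 40, seed = 54)
  ph <- quick_pheno(G, n_qtl = 8, h2 = 0.5, seed = 55)
  ga <- build_grouped_augmentation(G, contiguous_groups(ncol(G$X), 10))
  tc <- run_chain(G, ph$y, n_iter = 4000, thin = 10, seed = 56)
  tg <- run_chain_xii(G, ph$y, ga, n_iter = 12000, thin = 10, seed = 57)
  expect_gt(method_agreement(tc, tg, G$X), 0.97)
  # indicator coherence holds for the grouped path too
  expect_true(all((tg$a_thin != 0) == (tg$delta_thin == 1)))
})
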