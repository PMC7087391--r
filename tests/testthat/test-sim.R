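# Forward-in-time simulator: founder sampling, drift, QTL architecture,
# heritability, and the train/test split.

test_that("base population has the requested dimensions and founder law", {
  cfg <- sim_config(n_founders = 100, p_loci = 500, seed = 1)
  set.seed(1)
  pop <- simulate_base_population(cfg)
  expect_equal(dim(pop$haplo), c(200, 500))
  expect_true(all(pop$haplo %in% 0:1))

  # degenerate case: 2 founders, 1 locus -> 4 haplotype alleles
  cfg2 <- sim_config(n_founders = 2, p_loci = 1, n_final = 2,
                     n_train = 1, n_test = 1)
  set.seed(2)
  pop2 <- simulate_base_population(cfg2)
  expect_equal(dim(pop2$haplo), c(4, 1))

  # founder allele frequencies follow Uniform(0.05, 0.95) at large p
  cfg3 <- sim_config(n_founders = 10, p_loci = 1e5, n_final = 10,
                     n_train = 5, n_test = 5)
  set.seed(3)
  pop3 <- simulate_base_population(cfg3)
  ks <- suppressWarnings(
    ks.test(pop3$founder_freq, "punif", 0.05, 0.95))
  expect_gt(ks$p.value, 0.01)

  expect_error(sim_config(n_founders = 1), "degenerate")
  expect_error(sim_config(p_loci = 0), "degenerate")
})

test_that("random mating preserves the identity and copy structure", {
  cfg <- sim_config(n_founders = 20, p_loci = 60, n_chromosomes = 3,
                    n_final = 20, n_train = 10, n_test = 10)
  set.seed(4)
  pop <- simulate_base_population(cfg)

  # zero generations at unchanged size returns the founders exactly
  G0 <- random_mating(pop, 0, 20)
  expect_equal(unname(G0$X),
               unname(pop$haplo[seq(1, 39, 2), ] + pop$haplo[seq(2, 40, 2), ]))

  # with chromosome length 0 (no recombination) and a single chromosome,
  # every haplotype in a later generation is a copy of a founder haplotype
  cfg0 <- sim_config(n_founders = 15, p_loci = 40, chromosome_length = 0,
                     n_chromosomes = 1, n_final = 30, n_train = 20,
                     n_test = 10)
  set.seed(5)
  pop0 <- simulate_base_population(cfg0)
  founder_keys <- apply(pop0$haplo, 1, paste, collapse = "")
  adv <- advance_generations(pop0, 5)
  adv <- advance_generations(adv, 1, size = 30)
  child_keys <- apply(adv$haplo, 1, paste, collapse = "")
  expect_true(all(child_keys %in% founder_keys))

  expect_error(random_mating(pop, 2, 0), "final_size")
})

test_that("expansion generation reaches the requested size", {
  cfg <- sim_config(n_founders = 10, p_loci = 30, n_final = 150,
                    n_train = 100, n_test = 50)
  set.seed(6)
  pop <- simulate_base_population(cfg)
  G <- random_mating(pop, 3, 150)
  expect_equal(nrow(G$X), 150)
  expect_true(all(G$X %in% c(0, 1, 2)))
})

test_that("QTL count and genetic-variance scaling are exact", {
  set.seed(7)
  G <- drop_monomorphic(geno_data(
    sapply(runif(1000, 0.2, 0.8), function(f) rbinom(400, 2, f))))
  qtl <- assign_qtl_effects(G, 0.05, target_var = 1)
  expect_equal(length(qtl$qtl_idx), round(0.05 * ncol(G$X)))
  expect_equal(mean((qtl$bv - mean(qtl$bv))^2), 1, tolerance = 1e-10)

  # rescaling is idempotent
  sc1 <- scale_qtl_effects(G, qtl$qtl_idx, qtl$qtl_effects, 1)
  expect_equal(sc1$qtl_effects, qtl$qtl_effects, tolerance = 1e-12)

  # monomorphic-only QTL cannot be scaled
  Gc <- geno_data(cbind(m1 = rep(1, 10), m2 = rbinom(10, 2, 0.5)))
  expect_error(scale_qtl_effects(Gc, 1L, 1, 1), "zero genetic variance")
})

test_that("phenotype simulation hits the configured heritability", {
  set.seed(8)
  bv <- rnorm(60000)
  tr <- simulate_phenotypes(bv, 0.3)
  vb <- mean((bv - mean(bv))^2)
  expect_equal(tr$sigma2_e_sim, vb * 7 / 3, tolerance = 1e-12)
  h2_real <- var(tr$bv) / var(tr$y)
  # ~3 s.e. of the realized-heritability ratio at this n
  se_h2 <- 0.3 * 0.7 * sqrt(2 / length(bv))
  expect_lt(abs(h2_real - 0.3), 3 * se_h2)

  # h2 -> 1 limit: residual variance -> 0
  tr2 <- simulate_phenotypes(bv[1:100], 0.999999)
  expect_equal(tr2$y, tr2$bv, tolerance = 1e-2)
  expect_error(simulate_phenotypes(bv, 1.2), "heritability")
})

test_that("train/test split drops training-monomorphic loci and centers", {
  ds <- tiny_dataset(seed = 9)
  Xtr <- ds$train$geno$X
  expect_equal(nrow(Xtr), 250)
  expect_equal(nrow(ds$test$geno$X), 50)
  expect_true(all(abs(colSums(Xtr)) < 1e-8 * nrow(Xtr)))
  expect_true(all(ds$train$geno$allele_freq > 0 &
                    ds$train$geno$allele_freq < 1))
  # disjoint split
  expect_length(intersect(ds$train$geno$ids, ds$test$geno$ids), 0)
  # test set centered with training means: reconstructed counts are 0/1/2
  raw_test <- sweep(ds$test$geno$X, 2, ds$test$geno$center_means, "+")
  expect_true(all(abs(raw_test - round(raw_test)) < 1e-9))
  expect_true(all(round(raw_test) %in% c(0, 1, 2)))

  G <- ds$train$geno
  expect_error(make_dataset(geno_data(matrix(rbinom(20, 2, 0.5), 10, 2)),
                            trait_data(rnorm(10), rnorm(10)), 8, 5),
               "exceeds")
})

test_that("the same configuration and seed reproduce the dataset exactly", {
  ds1 <- tiny_dataset(seed = 11)
  ds2 <- tiny_dataset(seed = 11)
  expect_identical(ds1$train$geno$X, ds2$train$geno$X)
  expect_identical(ds1$train$trait$y, ds2$train$trait$y)
  expect_identical(ds1$qtl, ds2$qtl)
})

test_that("heterozygosity decays under constant-size random mating", {
  # drift at constant size must erode diversity in expectation
  het_drop <- replicate(20, {
    cfg <- sim_config(n_founders = 30, p_loci = 100, n_chromosomes = 2,
                      n_final = 30, n_train = 20, n_test = 10)
    pop <- simulate_base_population(cfg)
    h0 <- expected_heterozygosity(pop)
    h1 <- expected_heterozygosity(advance_generations(pop, 25))
    h0 - h1
  })
  expect_gt(mean(het_drop), 0)
})
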