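# Shared fixture builders: everything is generated in code at test time.

# small end-to-end simulated dataset (train/test, centered, QTL truth)
tiny_dataset <- function(seed = 42, n_founders = 50, n_generations = 10,
                         n_final = 300, p_loci = 120, n_train = 250,
                         n_test = 50, heritability = 0.3) {
  cfg <- sim_config(n_founders = n_founders, n_generations = n_generations,
                    n_final = n_final, p_loci = p_loci, n_train = n_train,
                    n_test = n_test, heritability = heritability,
                    seed = seed)
  simulate_dataset(cfg)
}

# centered genotype matrix without running the breeding simulation
quick_geno <- function(n, p, seed = 1, maf_range = c(0.1, 0.9)) {
  set.seed(seed)
  f <- runif(p, maf_range[1], maf_range[2])
  X <- sapply(f, function(fr) rbinom(n, 2, fr))
  colnames(X) <- sprintf("m%05d", seq_len(p))
  G <- drop_monomorphic(geno_data(X))
  center_genotypes(G)
}

# phenotypes from a sparse true effect vector on a centered matrix
quick_pheno <- function(G, n_qtl = 10, h2 = 0.5, seed = 2) {
  set.seed(seed)
  p <- ncol(G$X)
  a <- numeric(p)
  a[sample.int(p, min(n_qtl, p))] <- rnorm(min(n_qtl, p))
  g <- as.numeric(G$X %*% a)
  vg <- mean((g - mean(g))^2)
  e <- rnorm(nrow(G$X), 0, sqrt(vg * (1 - h2) / h2))
  list(y = g + e + 3, a = a)
}

# closed-form posterior of (mu, a) for the conjugate normal model with all
# markers included (pi = 0) and fixed variances:
#   mean  = (W'W + Lambda)^-1 W'y,  Lambda = diag(0, s2e/s2a * I)
#   cov   = (W'W + Lambda)^-1 s2e
conjugate_posterior <- function(X, y, sigma2_e, sigma2_a) {
  W <- cbind(1, X)
  lambda <- diag(c(0, rep(sigma2_e / sigma2_a, ncol(X))))
  A <- crossprod(W) + lambda
  mean <- solve(A, crossprod(W, y))
  list(mean = as.numeric(mean), cov = solve(A) * sigma2_e)
}
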