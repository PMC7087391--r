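#' Simulation configuration
#'
#' Parameters of the forward-in-time simulation: a small founder population is
#' mated at random for many generations so that drift generates linkage
#' disequilibrium, one final expansion generation produces the analysis
#' cohort, a random subset of loci act as additive QTL, and phenotypes are
#' built from the breeding values at a fixed heritability.
#'
#' @param n_founders founder population size (default 100).
#' @param n_generations generations of constant-size random mating before the
#'   expansion generation (default 100).
#' @param n_final size of the expansion generation used for analysis.
#' @param p_loci number of biallelic loci on the panel.
#' @param n_chromosomes number of chromosomes (default 10).
#' @param chromosome_length genetic length of each chromosome in Morgans
#'   (default 1); the expected number of crossovers per meiosis per
#'   chromosome.
#' @param qtl_fraction fraction of retained loci acting as QTL (default 0.05).
#' @param target_genetic_variance genetic variance of the expansion
#'   generation after QTL-effect scaling (default 1.0).
#' @param heritability narrow-sense heritability of the simulated trait,
#'   in (0, 1) (default 0.3).
#' @param n_train,n_test sizes of the training/testing split; default 5/6 of
#'   `n_final` for training and the remainder for testing.
#' @param seed integer seed making the whole simulation reproducible.
#'
#' @return an object of class `sim_config` (a validated list).
#' @seealso [simulate_dataset()] for the full pipeline.
#' @export
sim_config <- function(n_founders = 100, n_generations = 100,
                       n_final = 1000, p_loci = 1000,
                       n_chromosomes = 10, chromosome_length = 1,
                       qtl_fraction = 0.05, target_genetic_variance = 1,
                       heritability = 0.3, n_train = NULL, n_test = NULL,
                       seed = NULL) {
  if (n_founders < 2 || p_loci < 1 || n_final < 1 || n_chromosomes < 1)
    stop("non-positive or degenerate simulation dimensions")
  if (n_generations < 0) stop("n_generations must be >= 0")
  if (chromosome_length < 0) stop("chromosome_length must be >= 0")
  if (qtl_fraction <= 0 || qtl_fraction >= 1)
    stop("qtl_fraction must lie in (0, 1)")
  if (heritability <= 0 || heritability >= 1)
    stop("heritability must lie in (0, 1)")
  if (target_genetic_variance <= 0)
    stop("target_genetic_variance must be > 0")
  n_train <- n_train %||% round(n_final * 5 / 6)
  n_test <- n_test %||% (n_final - n_train)
  if (n_train < 1 || n_test < 0 || n_train + n_test > n_final)
    stop("n_train + n_test must not exceed n_final")
  structure(
    list(n_founders = as.integer(n_founders),
         n_generations = as.integer(n_generations),
         n_final = as.integer(n_final), p_loci = as.integer(p_loci),
         n_chromosomes = as.integer(n_chromosomes),
         chromosome_length = chromosome_length,
         qtl_fraction = qtl_fraction,
         target_genetic_variance = target_genetic_variance,
         heritability = heritability,
         n_train = as.integer(n_train), n_test = as.integer(n_test),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "sim_config")
}

#' Simulate a founder population of haplotypes
#'
#' Founder allele frequencies are drawn per locus from Uniform(0.05, 0.95)
#' and haplotype alleles are drawn independently Bernoulli(freq); linkage
#' disequilibrium then accrues through the subsequent generations of drift.
#' Loci are placed evenly along the genetic map, split across chromosomes as
#' evenly as possible.
#'
#' @param cfg a [sim_config].
#' @return an object of class `haplo_pop`: a list with `haplo` (a `2n x p`
#'   0/1 matrix, two consecutive rows per individual), the genetic `map`
#'   (`chrom`, `pos` in Morgans), `chrom_index`, `chrom_len`, `n` and `p`.
#' @export
simulate_base_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_founders; p <- cfg$p_loci
  chrom <- sort(rep_len(seq_len(cfg$n_chromosomes), p))
  pos <- numeric(p)
  for (c in unique(chrom)) {
    idx <- which(chrom == c)
    k <- length(idx)
    # evenly spaced, away from the chromosome ends
    pos[idx] <- cfg$chromosome_length * (seq_len(k) - 0.5) / k
  }
  freq <- runif(p, 0.05, 0.95)
  haplo <- matrix(rbinom(2L * n * p, 1L, rep(freq, each = 2L * n)),
                  nrow = 2L * n, ncol = p)
  structure(
    list(haplo = haplo, map = data.frame(chrom = chrom, pos = pos),
         chrom_index = split(seq_len(p), chrom),
         chrom_len = cfg$chromosome_length, n = n, p = p,
         founder_freq = freq),
    class = "haplo_pop")
}

# one recombination mask for a single meiosis: TRUE where the gamete copies
# the second parental haplotype.  Crossover count per chromosome is
# Poisson(length in Morgans), positions uniform, no interference; the
# starting haplotype of each chromosome is chosen at random.
recombination_mask <- function(pop) {
  mask <- logical(pop$p)
  for (idx in pop$chrom_index) {
    nx <- rpois(1L, pop$chrom_len)
    phase <- runif(1L) < 0.5
    if (nx > 0L) {
      xpos <- sort(runif(nx, 0, pop$chrom_len))
      sel <- (findInterval(pop$map$pos[idx], xpos) %% 2L) == 1L
      if (phase) sel <- !sel
    } else {
      sel <- rep(phase, length(idx))
    }
    mask[idx] <- sel
  }
  mask
}

# gamete produced by individual i of pop
make_gamete <- function(pop, i) {
  h1 <- pop$haplo[2L * i - 1L, ]
  h2 <- pop$haplo[2L * i, ]
  m <- recombination_mask(pop)
  h1[m] <- h2[m]
  h1
}

#' Advance a population by random mating
#'
#' Each offspring draws two distinct parents uniformly at random; each parent
#' contributes one recombinant gamete.  Population size is held at `size`
#' (default: unchanged).
#'
#' @param pop a `haplo_pop`.
#' @param n_generations number of generations to advance.
#' @param size offspring cohort size per generation.
#' @return the advanced `haplo_pop`.
#' @export
advance_generations <- function(pop, n_generations, size = NULL) {
  stopifnot(inherits(pop, "haplo_pop"), pop$n >= 2)
  size <- as.integer(size %||% pop$n)
  if (size < 1) stop("offspring cohort size must be >= 1")
  for (g in seq_len(n_generations)) {
    child <- matrix(0L, nrow = 2L * size, ncol = pop$p)
    for (i in seq_len(size)) {
      par <- sample.int(pop$n, 2L)  # two distinct parents
      child[2L * i - 1L, ] <- make_gamete(pop, par[1L])
      child[2L * i, ] <- make_gamete(pop, par[2L])
    }
    pop$haplo <- child
    pop$n <- size
  }
  pop
}

# convert a haplotype population to 0/1/2 genotype counts
haplo_to_geno <- function(pop) {
  n <- pop$n
  X <- pop$haplo[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
    pop$haplo[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  rownames(X) <- sprintf("ind%05d", seq_len(n))
  colnames(X) <- sprintf("m%05d", seq_len(pop$p))
  geno_data(X)
}

#' Random mating followed by an expansion generation
#'
#' Runs `n_generations` of constant-size random mating, then one further
#' generation that expands the population to `final_size` individuals (the
#' analysis cohort).  The degenerate call with `n_generations = 0` and
#' `final_size` equal to the current size returns the current genotypes
#' unchanged.
#'
#' @param pop a `haplo_pop` (e.g. from [simulate_base_population()]).
#' @param n_generations generations of constant-size mating.
#' @param final_size size of the expansion generation.
#' @return a [geno_data] with 0/1/2 counts for the final generation.
#' @export
random_mating <- function(pop, n_generations, final_size) {
  stopifnot(inherits(pop, "haplo_pop"))
  final_size <- as.integer(final_size)
  if (final_size < 1) stop("final_size must be >= 1")
  if (n_generations == 0L && final_size == pop$n)
    return(haplo_to_geno(pop))
  pop <- advance_generations(pop, n_generations)
  pop <- advance_generations(pop, 1L, size = final_size)
  haplo_to_geno(pop)
}

#' Assign and scale QTL effects
#'
#' Selects `round(qtl_fraction * p)` loci uniformly at random as QTL, draws
#' raw effects from N(0, 1), and rescales them by a single scalar so that the
#' empirical variance (denominator `n`) of the genetic values
#' `X[, qtl] %*% effects` over the supplied generation equals `target_var`
#' exactly.
#'
#' @param G a [geno_data] for the final generation (monomorphic loci already
#'   removed; see [drop_monomorphic()]).
#' @param qtl_fraction fraction of loci acting as QTL.
#' @param target_var target genetic variance after scaling.
#' @return a list with `qtl_idx` (column indices into `G$X`), `qtl_effects`
#'   (scaled) and `bv` (genetic values of the individuals in `G`).
#' @export
assign_qtl_effects <- function(G, qtl_fraction = 0.05, target_var = 1) {
  stopifnot(inherits(G, "geno_data"))
  p <- ncol(G$X)
  if (!any(G$allele_freq > 0 & G$allele_freq < 1))
    stop("no segregating locus available for QTL assignment")
  n_qtl <- round(qtl_fraction * p)
  if (n_qtl < 1) stop("qtl_fraction * p rounds to zero QTL")
  qtl_idx <- sort(sample.int(p, n_qtl))
  effects <- rnorm(n_qtl)
  sc <- scale_qtl_effects(G, qtl_idx, effects, target_var)
  list(qtl_idx = qtl_idx, qtl_effects = sc$qtl_effects, bv = sc$bv)
}

#' Scale QTL effects to a target genetic variance
#'
#' Multiplies the effects by the single scalar that makes the empirical
#' variance (denominator `n`) of the genetic values over the individuals in
#' `G` equal `target_var` exactly.  The operation is idempotent.
#'
#' @inheritParams assign_qtl_effects
#' @param qtl_idx QTL column indices into `G$X`.
#' @param effects current effect sizes.
#' @return list with scaled `qtl_effects` and the implied `bv`.
#' @export
scale_qtl_effects <- function(G, qtl_idx, effects, target_var = 1) {
  g <- as.numeric(G$X[, qtl_idx, drop = FALSE] %*% effects)
  vg <- pop_var(g)
  if (vg <= 0)
    stop("zero genetic variance: all selected QTL are monomorphic")
  s <- sqrt(target_var / vg)
  list(qtl_effects = effects * s, bv = g * s)
}

#' Trait container
#'
#' @param y phenotypes.
#' @param bv true breeding values.
#' @param qtl_idx,qtl_effects QTL truth (optional).
#' @param sigma2_e_sim residual variance used in the simulation.
#' @return object of class `trait_data`.
#' @export
trait_data <- function(y, bv, qtl_idx = NULL, qtl_effects = NULL,
                       sigma2_e_sim = NA_real_) {
  stopifnot(length(y) == length(bv))
  structure(list(y = as.numeric(y), bv = as.numeric(bv),
                 qtl_idx = qtl_idx, qtl_effects = qtl_effects,
                 sigma2_e_sim = sigma2_e_sim),
            class = "trait_data")
}

#' Simulate phenotypes at a fixed heritability
#'
#' Adds iid normal residuals to the breeding values with residual variance
#' `var(bv) * (1 - h2) / h2` (population variance), so that the expected
#' heritability `var(bv) / var(y)` equals `h2`.
#'
#' @param bv breeding values (must have positive variance).
#' @param heritability narrow-sense heritability in (0, 1).
#' @return a [trait_data] with `y = bv + e` and the residual variance used.
#' @export
simulate_phenotypes <- function(bv, heritability = 0.3) {
  if (heritability <= 0 || heritability >= 1)
    stop("heritability must lie in (0, 1)")
  vb <- pop_var(bv)
  if (vb <= 0) stop("breeding values have zero variance")
  s2e <- vb * (1 - heritability) / heritability
  y <- bv + rnorm(length(bv), 0, sqrt(s2e))
  trait_data(y, bv, sigma2_e_sim = s2e)
}

#' Split into training and testing sets
#'
#' Draws a disjoint random train/test split, drops loci that are monomorphic
#' within the training set from both sets, centers the training columns, and
#' centers the test columns using the training means.
#'
#' @param G final-generation [geno_data] (0/1/2 counts).
#' @param trait matching [trait_data].
#' @param n_train,n_test split sizes; `n_train + n_test` must not exceed the
#'   number of individuals.
#' @return a list of class `gp_dataset` with elements `train` and `test`
#'   (each a list of `geno` and `trait`), and `qtl_names` for the QTL that
#'   survived training-set filtering.
#' @export
make_dataset <- function(G, trait, n_train, n_test) {
  stopifnot(inherits(G, "geno_data"), inherits(trait, "trait_data"))
  n <- nrow(G$X)
  if (n_train + n_test > n)
    stop("n_train + n_test exceeds the number of individuals")
  idx <- sample.int(n, n_train + n_test)
  itr <- idx[seq_len(n_train)]
  ite <- idx[n_train + seq_len(n_test)]

  Xtr <- G$X[itr, , drop = FALSE]
  freq_tr <- colMeans(Xtr) / 2
  keep <- freq_tr > 0 & freq_tr < 1
  if (!any(keep)) stop("all loci monomorphic in the training set")

  means <- colMeans(Xtr[, keep, drop = FALSE])
  train_geno <- geno_data(
    sweep(Xtr[, keep, drop = FALSE], 2, means, "-"),
    ids = G$ids[itr], allele_freq = freq_tr[keep], centered = TRUE,
    center_means = as.numeric(means), kept_loci = G$kept_loci[keep])
  test_geno <- geno_data(
    sweep(G$X[ite, keep, drop = FALSE], 2, means, "-"),
    ids = G$ids[ite], allele_freq = freq_tr[keep], centered = TRUE,
    center_means = as.numeric(means), kept_loci = G$kept_loci[keep])

  sub_trait <- function(i) trait_data(
    trait$y[i], trait$bv[i], qtl_idx = trait$qtl_idx,
    qtl_effects = trait$qtl_effects, sigma2_e_sim = trait$sigma2_e_sim)
  qtl_names <- if (!is.null(trait$qtl_idx))
    intersect(colnames(G$X)[trait$qtl_idx], colnames(train_geno$X))
  structure(list(train = list(geno = train_geno, trait = sub_trait(itr)),
                 test = list(geno = test_geno, trait = sub_trait(ite)),
                 qtl_names = qtl_names),
            class = "gp_dataset")
}

#' Simulate a complete genomic-prediction dataset
#'
#' Full pipeline: founder population, `n_generations` of constant-size random
#' mating plus one expansion generation, monomorphic-locus removal, QTL
#' assignment with exact genetic-variance scaling, phenotype simulation at
#' the configured heritability, and a centered train/test split.
#'
#' @param cfg a [sim_config]; if `cfg$seed` is set the result is fully
#'   reproducible.
#' @return a `gp_dataset` (see [make_dataset()]) with extra elements:
#'   `cfg`, `qtl` (truth table: marker name, original panel index, effect),
#'   `p_kept` (loci segregating in the final generation), `bv_final`
#'   (breeding values of the whole expansion generation), `y_final`, and
#'   `sigma2_e_sim`.
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  pop <- simulate_base_population(cfg)
  G_all <- random_mating(pop, cfg$n_generations, cfg$n_final)
  G <- drop_monomorphic(G_all)
  qtl <- assign_qtl_effects(G, cfg$qtl_fraction, cfg$target_genetic_variance)
  trait <- simulate_phenotypes(qtl$bv, cfg$heritability)
  trait$qtl_idx <- qtl$qtl_idx
  trait$qtl_effects <- qtl$qtl_effects
  ds <- make_dataset(G, trait, cfg$n_train, cfg$n_test)
  ds$cfg <- cfg
  ds$qtl <- data.frame(marker = colnames(G$X)[qtl$qtl_idx],
                       panel_index = G$kept_loci[qtl$qtl_idx],
                       effect = qtl$qtl_effects)
  ds$p_kept <- ncol(G$X)
  ds$bv_final <- qtl$bv
  ds$y_final <- trait$y
  ds$sigma2_e_sim <- trait$sigma2_e_sim
  ds
}

#' Mean expected heterozygosity of a population
#'
#' `mean(2 p (1 - p))` over loci, computed from current haplotype allele
#' frequencies; a standard drift diagnostic (decreases in expectation under
#' constant-size random mating).
#'
#' @param pop a `haplo_pop`.
#' @return scalar heterozygosity.
#' @export
expected_heterozygosity <- function(pop) {
  stopifnot(inherits(pop, "haplo_pop"))
  f <- colMeans(pop$haplo)
  mean(2 * f * (1 - f))
}
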