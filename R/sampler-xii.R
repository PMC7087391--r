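# BayesXII: after orthogonal data augmentation every marker-effect full
# conditional is free of the other marker effects, so all effects (and the
# general mean) are drawn from mutually independent normals within each
# iteration, followed by a refresh of the "missing" phenotypes attached to
# the augmented rows.

# contiguous split of 1:p into k blocks (the parallel work partition)
split_blocks <- function(p, k) {
  k <- max(1L, min(as.integer(k), p))
  unname(split(seq_len(p), ceiling(seq_len(p) * k / p)))
}

#' Cache response crossproducts on an augmentation
#'
#' Stores `X'y` and `1'y` on the augmentation object (they never change
#' along the chain) and verifies the augmentation was built from this
#' genotype matrix via its fingerprint.
#'
#' @param aug an `oda_augmentation`.
#' @param G centered [geno_data] the augmentation was built from.
#' @param y phenotype vector.
#' @return the augmentation with `Xty` and `one_ty` fields set.
#' @export
precompute_crossproducts <- function(aug, G, y) {
  stopifnot(inherits(aug, "oda_augmentation"))
  X <- if (inherits(G, "geno_data")) G$X else as.matrix(G)
  if (!is.null(aug$fingerprint) &&
      !identical(aug$fingerprint, genotype_fingerprint(X)))
    stop("stale augmentation: built from a different genotype matrix")
  aug$Xty <- as.numeric(crossprod(X, y))
  aug$one_ty <- sum(y)
  # pre-split the augmented columns into the fixed-width tiles used by the
  # marker map (avoids re-copying submatrices every iteration)
  aug$tile_idx <- split_blocks(aug$p, ceiling(aug$p / 64))
  aug$tile_mats <- lapply(aug$tile_idx, function(b)
    aug$X_tilde[, b, drop = FALSE])
  aug
}

#' Draw all marker effects and the mean in parallel (BayesXII)
#'
#' Under the augmented model the full conditional of each effect is
#' `N((X_j'y + X_tilde_j' y_tilde)/(d + s2e/s2a), s2e/(d + s2e/s2a))`,
#' free of the other effects; the indicator uses the same likelihood-ratio
#' rule as the single-site sampler with `d` in place of `X_j'X_j`, and
#' `mu ~ N((1'y + J_tilde' y_tilde)/d, s2e/d)`.  All random inputs are
#' pre-drawn in fixed marker order before any work is scheduled, and the
#' crossproducts are evaluated over fixed-width marker tiles, so any number
#' of workers (any scheduling of tiles onto processes) yields bit-identical
#' results.
#'
#' @param state an `xii_state` (a `model_state` plus `y_tilde`).
#' @param aug an `oda_augmentation` with cached crossproducts (see
#'   [precompute_crossproducts()]).
#' @param workers number of blocks the marker map is split into
#'   (`parallel::mclapply` when > 1).
#' @return updated state (new `mu`, `a`, `delta`).
#' @export
sample_effects_xii <- function(state, aug, workers = 1) {
  if (is.null(aug$Xty))
    stop("augmentation has no cached crossproducts; ",
         "call precompute_crossproducts() first")
  p <- aug$p
  # per-(iteration, marker) substream: fixed draw order, one (u, z) pair per
  # marker, plus one normal for the mean
  u <- runif(p)
  z <- rnorm(p)
  z_mu <- rnorm(1)
  s2e <- state$sigma2_e; s2a <- state$sigma2_a
  denom <- aug$d + s2e / s2a
  sd_a <- sqrt(s2e / denom)

  draw_block <- function(b, r_b) {
    log_lr <- marker_log_lr(r_b, aug$d, s2e, s2a)
    p1 <- marker_inclusion_prob(log_lr, state$pi)
    delta <- u[b] < p1
    a <- numeric(length(b))
    a[delta] <- r_b[delta] / denom + sd_a * z[b][delta]
    list(a = a, delta = as.integer(delta))
  }

  # fixed-width tiles: the arithmetic is identical for every worker count,
  # workers only change which process evaluates a tile
  if (is.null(aug$tile_idx)) {
    aug$tile_idx <- split_blocks(p, ceiling(p / 64))
    aug$tile_mats <- lapply(aug$tile_idx, function(b)
      aug$X_tilde[, b, drop = FALSE])
  }
  work <- function(i) {
    b <- aug$tile_idx[[i]]
    r_b <- aug$Xty[b] +
      as.numeric(crossprod(aug$tile_mats[[i]], state$y_tilde))
    draw_block(b, r_b)
  }
  out <- if (workers <= 1) lapply(seq_along(aug$tile_idx), work)
         else parallel::mclapply(seq_along(aug$tile_idx), work,
                                 mc.cores = workers)
  state$a <- unlist(lapply(out, `[[`, "a"), use.names = FALSE)
  state$delta <- unlist(lapply(out, `[[`, "delta"), use.names = FALSE)
  j_ty <- as.numeric(crossprod(aug$J_tilde, state$y_tilde))
  state$mu <- (aug$one_ty + j_ty) / aug$d + sqrt(s2e / aug$d) * z_mu
  state
}

#' Refresh the missing phenotypes (BayesXII)
#'
#' Each element of `y_tilde` is drawn independently:
#' `y_tilde | ELSE ~ N(J_tilde mu + X_tilde a, I s2e)`.
#'
#' @inheritParams sample_effects_xii
#' @return updated state (new `y_tilde`, and `e_tilde` set to the realized
#'   augmented residual).
#' @export
sample_missing_phenotypes <- function(state, aug) {
  mean_t <- as.numeric(aug$W_a %*% c(state$mu, state$a))
  noise <- rnorm(aug$p + 1L, 0, sqrt(state$sigma2_e))
  state$y_tilde <- mean_t + noise
  state$e_tilde <- noise
  state
}

#' Variance components and pi under the augmented model (BayesXII)
#'
#' `sigma2_a` and `pi` have the same conditionals as the single-site
#' sampler (they depend only on the effects and indicators).  The residual
#' variance conditions on both residual blocks of the augmented model:
#' `sigma2_e ~ (nu_e S2_e + e'e + e_tilde'e_tilde) / chisq(nu_e + n + p + 1)`
#' with `e = y - 1 mu - X a` and `e_tilde = y_tilde - J_tilde mu -
#' X_tilde a`.
#'
#' @inheritParams sample_effects_xii
#' @param y phenotypes.
#' @param X centered marker matrix.
#' @param hyper resolved [bayescpi_hyper].
#' @return updated state.
#' @export
sample_variances_and_pi_xii <- function(state, y, X, aug, hyper) {
  p <- length(state$a)
  m <- sum(state$delta)
  if (hyper$estimate_variances) {
    state$sigma2_a <- (hyper$nu_a * hyper$S2_a + sum(state$a^2)) /
      rchisq(1, hyper$nu_a + m)
    e <- y - state$mu - as.numeric(X %*% state$a)
    et <- state$e_tilde %||%
      (state$y_tilde - as.numeric(aug$W_a %*% c(state$mu, state$a)))
    state$sigma2_e <- (hyper$nu_e * hyper$S2_e + sum(e^2) + sum(et^2)) /
      rchisq(1, hyper$nu_e + length(y) + p + 1)
  }
  if (hyper$estimate_pi) state$pi <- rbeta(1, p - m + 1, m + 1)
  state
}

# one full BayesXII Gibbs cycle (effects -> missing phenotypes ->
# variances/pi)
xii_step <- function(state, aug, y, X, hyper, workers = 1) {
  state <- sample_effects_xii(state, aug, workers)
  state <- sample_missing_phenotypes(state, aug)
  sample_variances_and_pi_xii(state, y, X, aug, hyper)
}

# one full grouped-ODA BayesXII cycle: groups are processed sequentially
# with a residual-style right-hand side across groups; within a group all
# effects are drawn in parallel via the group's d_i.  y_tilde is the
# concatenation of the per-group missing phenotypes (the grouped
# augmentation has no intercept row, so mu keeps its single-site update and
# the residual-variance d.f. is nu_e + n + p).
xii_step_grouped <- function(state, aug, y, X, hyper) {
  p <- aug$p; n <- length(y)
  u <- runif(p); z <- rnorm(p); z_mu <- rnorm(1)
  s2e <- state$sigma2_e; s2a <- state$sigma2_a
  e_obs <- y - state$mu - as.numeric(X %*% state$a)
  offs <- c(0L, cumsum(lengths(aug$groups)))
  for (i in seq_along(aug$groups)) {
    b <- aug$groups[[i]]
    rows <- (offs[i] + 1L):offs[i + 1L]
    Xi <- X[, b, drop = FALSE]
    Xti <- aug$blocks[[i]]
    eti <- state$y_tilde[rows] - as.numeric(Xti %*% state$a[b])
    r <- as.numeric(crossprod(Xi, e_obs)) + as.numeric(crossprod(Xti, eti)) +
      aug$d[i] * state$a[b]
    log_lr <- marker_log_lr(r, aug$d[i], s2e, s2a)
    p1 <- marker_inclusion_prob(log_lr, state$pi)
    delta <- u[b] < p1
    denom <- aug$d[i] + s2e / s2a
    a_new <- numeric(length(b))
    a_new[delta] <- r[delta] / denom + sqrt(s2e / denom) * z[b][delta]
    e_obs <- e_obs - as.numeric(Xi %*% (a_new - state$a[b]))
    state$a[b] <- a_new
    state$delta[b] <- as.integer(delta)
  }
  mu_new <- mean(e_obs) + state$mu + sqrt(s2e / n) * z_mu
  e_obs <- e_obs - (mu_new - state$mu)
  state$mu <- mu_new
  noise <- rnorm(p, 0, sqrt(s2e))
  for (i in seq_along(aug$groups)) {
    rows <- (offs[i] + 1L):offs[i + 1L]
    state$y_tilde[rows] <- as.numeric(aug$blocks[[i]] %*%
                                        state$a[aug$groups[[i]]]) +
      noise[rows]
  }
  m <- sum(state$delta)
  if (hyper$estimate_variances) {
    state$sigma2_a <- (hyper$nu_a * hyper$S2_a + sum(state$a^2)) /
      rchisq(1, hyper$nu_a + m)
    state$sigma2_e <- (hyper$nu_e * hyper$S2_e + sum(e_obs^2) +
                         sum(noise^2)) / rchisq(1, hyper$nu_e + n + p)
  }
  if (hyper$estimate_pi) state$pi <- rbeta(1, p - m + 1, m + 1)
  state
}

#' Run a BayesXII chain
#'
#' Per iteration: all marker effects and the general mean are drawn from
#' their mutually independent conditionals ([sample_effects_xii()]), the
#' missing phenotypes are refreshed ([sample_missing_phenotypes()]), then
#' the variance components and `pi` are updated.  The missing phenotypes
#' are initialized at their conditional mean `J_tilde mu0 + X_tilde a0`.
#' Results are independent of `workers` (the marker map partition).
#'
#' @inheritParams run_chain
#' @param aug an `oda_augmentation` from [build_oda()], or a `grouped_oda`
#'   from [build_grouped_augmentation()].
#' @param workers number of parallel blocks for the marker map (full
#'   augmentation only).
#' @return a `chain_trace` in the same format as [run_chain()] (method
#'   `"xii"` or `"xii-grouped"`).
#' @export
run_chain_xii <- function(G, y, aug, hyper = bayescpi_hyper(),
                          n_iter = 1000, thin = 10, seed = NULL,
                          workers = 1, init = NULL) {
  stopifnot(inherits(G, "geno_data"))
  if (!G$centered) stop("genotypes must be centered (see center_genotypes)")
  grouped <- inherits(aug, "grouped_oda")
  if (!grouped) stopifnot(inherits(aug, "oda_augmentation"))
  X <- G$X
  y <- as.numeric(y)
  p <- ncol(X)
  stopifnot(aug$p == p, length(y) == nrow(X))
  if (!is.null(aug$fingerprint) &&
      !identical(aug$fingerprint, genotype_fingerprint(X)))
    stop("stale augmentation: built from a different genotype matrix")
  hyper <- resolve_hyper(hyper, G, y)
  if (!is.null(seed)) set.seed(seed)
  state <- init %||% draw_initial_state(G, y, hyper)
  if (!grouped) {
    aug <- precompute_crossproducts(aug, G, y)
    state$y_tilde <- as.numeric(aug$W_a %*% c(state$mu, state$a))
  } else {
    state$y_tilde <- unlist(lapply(seq_along(aug$groups), function(i)
      as.numeric(aug$blocks[[i]] %*% state$a[aug$groups[[i]]])),
      use.names = FALSE)
  }

  n_thin <- n_iter %/% thin + 1L
  scalars <- matrix(NA_real_, n_iter + 1L, 5L)
  a_thin <- matrix(NA_real_, n_thin, p)
  delta_thin <- matrix(NA_integer_, n_thin, p)
  thin_iters <- integer(n_thin)
  scalars[1L, ] <- c(state$mu, state$pi, state$sigma2_a, state$sigma2_e,
                     sum(state$delta))
  a_thin[1L, ] <- state$a
  delta_thin[1L, ] <- state$delta
  thin_iters[1L] <- 0L
  a_mean <- numeric(p)
  thin_row <- 2L
  for (t in seq_len(n_iter)) {
    state <- if (grouped) xii_step_grouped(state, aug, y, X, hyper)
             else xii_step(state, aug, y, X, hyper, workers)
    if (!all(is.finite(c(state$mu, state$sigma2_a, state$sigma2_e))))
      stop("sampler diverged (non-finite state) at iteration ", t)
    a_mean <- a_mean + (state$a - a_mean) / t
    if (t %% thin == 0L) {
      a_thin[thin_row, ] <- state$a
      delta_thin[thin_row, ] <- state$delta
      thin_iters[thin_row] <- t
      thin_row <- thin_row + 1L
    }
    scalars[t + 1L, ] <- c(state$mu, state$pi, state$sigma2_a,
                           state$sigma2_e, sum(state$delta))
  }
  if (n_iter == 0L) a_mean <- state$a
  tr <- new_chain_trace(scalars, a_thin, delta_thin, thin_iters, a_mean,
                        n_iter, thin, seed,
                        if (grouped) "xii-grouped" else "xii",
                        colnames(X),
                        op_count = as.double(n_iter) * p * (p + 1))
  tr
}

#' Iterations needed for BayesXII to agree with a reference
#'
#' Runs a BayesXII chain in chunks and reports the first checkpoint at
#' which the running posterior-mean marker effects give test-set EBVs whose
#' Pearson correlation with a reference EBV vector reaches `threshold`.
#' Used to study how the sampler's convergence depends on the ratio of
#' markers to individuals.
#'
#' @inheritParams run_chain_xii
#' @param X_test centered test genotype matrix.
#' @param ref_ebv reference test-set EBVs (e.g. from a converged
#'   single-site chain).
#' @param threshold agreement correlation (default 0.95).
#' @param check_every checkpoint spacing in iterations.
#' @param max_iter cap on the chain length; reported when agreement is not
#'   reached (with `converged = FALSE`).
#' @return list with `iterations`, `converged`, and the checkpoint
#'   `trajectory` (iteration, correlation).
#' @export
iterations_to_agreement <- function(G, y, aug, hyper = bayescpi_hyper(),
                                    X_test, ref_ebv, threshold = 0.95,
                                    check_every = 250, max_iter = 15000,
                                    seed = NULL) {
  stopifnot(inherits(G, "geno_data"), inherits(aug, "oda_augmentation"))
  X <- G$X
  y <- as.numeric(y)
  if (inherits(X_test, "geno_data")) X_test <- X_test$X
  hyper <- resolve_hyper(hyper, G, y)
  if (!is.null(seed)) set.seed(seed)
  state <- draw_initial_state(G, y, hyper)
  aug <- precompute_crossproducts(aug, G, y)
  state$y_tilde <- as.numeric(aug$W_a %*% c(state$mu, state$a))
  a_sum <- numeric(ncol(X))
  t <- 0L
  traj_it <- integer(0)
  traj_cor <- numeric(0)
  while (t < max_iter) {
    for (s in seq_len(min(check_every, max_iter - t))) {
      state <- xii_step(state, aug, y, X, hyper)
      a_sum <- a_sum + state$a
      t <- t + 1L
    }
    r <- cor(as.numeric(X_test %*% (a_sum / t)), ref_ebv)
    traj_it <- c(traj_it, t)
    traj_cor <- c(traj_cor, r)
    if (is.finite(r) && r >= threshold)
      return(list(iterations = t, converged = TRUE,
                  trajectory = data.frame(iter = traj_it, cor = traj_cor)))
  }
  list(iterations = t, converged = FALSE,
       trajectory = data.frame(iter = traj_it, cor = traj_cor))
}
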