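#' Diagonal constant for orthogonal data augmentation
#'
#' Returns `d = lambda_max(W_o' W_o) + jitter`, the diagonal of the target
#' Gram matrix `D = I d` of the augmented design.  The largest eigenvalue is
#' computed on the symmetric crossproduct; the small jitter (default 0.001)
#' keeps the augmentation numerically stable when the top eigendirection
#' would otherwise make `D - W_o' W_o` exactly singular.
#'
#' @param W_o design matrix (observed rows), e.g. `cbind(1, X)`.
#' @param jitter small positive value added to the largest eigenvalue.
#' @return scalar `d`.
#' @export
compute_d <- function(W_o, jitter = 0.001) {
  W_o <- as.matrix(W_o)
  if (length(W_o) == 0L) stop("empty design matrix")
  if (!all(is.finite(W_o))) stop("design matrix contains non-finite entries")
  C <- crossprod(W_o)
  max(eigen(C, symmetric = TRUE, only.values = TRUE)$values) + jitter
}

#' Build an orthogonal data augmentation
#'
#' Finds a square matrix `W_a` (the augmented rows) such that the stacked
#' design `W_c = rbind(W_o, W_a)` has mutually orthogonal columns with
#' `W_c' W_c = I d`: forms `M = I d - W_o' W_o` and factors `M = L L'`, with
#' `W_a = L'` (upper-triangular Cholesky factor).  When the Cholesky
#' factorization fails on the near-singular `M`, a symmetric
#' eigendecomposition is used instead, clamping eigenvalues in
#' `[-1e-8 d, 0)` to zero; both routes satisfy `W_a' W_a = M`.
#'
#' @param W_o observed design matrix with `q` columns (first column usually
#'   the intercept).
#' @param d diagonal constant; computed by [compute_d()] when `NULL`.
#' @param jitter jitter used when `d` must be computed.
#' @param method factorization route: `"auto"` (Cholesky with eigen
#'   fallback), `"chol"` or `"eigen"`.
#' @return an object of class `oda_augmentation`: a list with `d`, `jitter`,
#'   `W_a` (`q x q`), `J_tilde` (its first column), `X_tilde` (the
#'   remaining columns), `p = q - 1`, the factorization `route` used, and a
#'   `fingerprint` slot (set by [build_oda()]).
#' @export
build_augmentation <- function(W_o, d = NULL, jitter = 0.001,
                               method = c("auto", "chol", "eigen")) {
  method <- match.arg(method)
  W_o <- as.matrix(W_o)
  if (!all(is.finite(W_o))) stop("design matrix contains non-finite entries")
  if (is.null(d)) d <- compute_d(W_o, jitter)
  q <- ncol(W_o)
  M <- diag(d, q) - crossprod(W_o)

  eigen_route <- function() {
    ev <- eigen(M, symmetric = TRUE)
    lam <- ev$values
    if (any(lam < -1e-8 * d))
      stop(sprintf(paste0("augmentation target is not positive ",
                          "semidefinite: smallest eigenvalue %.3e ",
                          "(d = %.6g); increase the jitter"),
                   min(lam), d))
    lam <- pmax(lam, 0)
    list(W_a = diag(sqrt(lam), q) %*% t(ev$vectors), route = "eigen")
  }
  res <- switch(method,
    chol = list(W_a = chol(M), route = "chol"),
    eigen = eigen_route(),
    auto = tryCatch(list(W_a = chol(M), route = "chol"),
                    error = function(e) eigen_route()))
  W_a <- unname(res$W_a)
  structure(
    list(d = d, jitter = jitter, W_a = W_a,
         J_tilde = W_a[, 1L], X_tilde = W_a[, -1L, drop = FALSE],
         p = q - 1L, route = res$route, fingerprint = NULL,
         marker_names = colnames(W_o)[-1L]),
    class = "oda_augmentation")
}

#' @export
print.oda_augmentation <- function(x, ...) {
  cat(sprintf("oda_augmentation: p = %d markers, d = %.6g (jitter %.4g, %s route)\n",
              x$p, x$d, x$jitter, x$route))
  invisible(x)
}

#' Orthogonal data augmentation for a genotype matrix
#'
#' Convenience wrapper: builds the augmentation for `W_o = cbind(1, X)` from
#' a centered genotype object and stamps it with a fingerprint of the source
#' matrix so that a stale augmentation is detected at sampling time.
#'
#' @param G a centered [geno_data] (or a plain centered matrix).
#' @param jitter jitter added to the largest eigenvalue.
#' @param method factorization route, see [build_augmentation()].
#' @return an `oda_augmentation` with the `fingerprint` slot set.
#' @export
build_oda <- function(G, jitter = 0.001, method = "auto") {
  X <- if (inherits(G, "geno_data")) {
    if (!G$centered) stop("genotypes must be centered before augmentation")
    G$X
  } else as.matrix(G)
  aug <- build_augmentation(cbind(1, X), jitter = jitter, method = method)
  aug$fingerprint <- genotype_fingerprint(X)
  aug$marker_names <- colnames(X)
  aug
}

#' Grouped orthogonal data augmentation
#'
#' For high-density panels a full `p x p` augmentation is too large, so the
#' markers are partitioned into groups and each group's columns are
#' orthogonalized separately: for group `i`, a square block `X_tilde_i`
#' satisfies `X_i' X_i + X_tilde_i' X_tilde_i = I d_i`.  Columns in
#' different groups are not orthogonalized against each other.
#'
#' @param X centered marker matrix (no intercept column).
#' @param groups list of integer index vectors partitioning `1:ncol(X)`.
#' @param jitter jitter per group.
#' @return object of class `grouped_oda`: `groups`, per-group `d`, `blocks`
#'   (the `X_tilde_i`), `jitter`, `p`, and a `fingerprint` of `X`.
#' @export
build_grouped_augmentation <- function(X, groups, jitter = 0.001) {
  if (inherits(X, "geno_data")) {
    if (!X$centered) stop("genotypes must be centered before augmentation")
    X <- X$X
  }
  X <- as.matrix(X)
  p <- ncol(X)
  if (any(lengths(groups) == 0L)) stop("empty marker group")
  all_idx <- sort(unlist(groups))
  if (!identical(as.integer(all_idx), seq_len(p)))
    stop("groups must partition the marker indices 1..p")
  d <- numeric(length(groups))
  blocks <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    Xi <- X[, groups[[i]], drop = FALSE]
    d[i] <- compute_d(Xi, jitter)
    q <- ncol(Xi)
    M <- diag(d[i], q) - crossprod(Xi)
    blocks[[i]] <- unname(tryCatch(chol(M), error = function(e) {
      ev <- eigen(M, symmetric = TRUE)
      if (any(ev$values < -1e-8 * d[i]))
        stop(sprintf("group %d augmentation not PSD (min eigenvalue %.3e)",
                     i, min(ev$values)))
      diag(sqrt(pmax(ev$values, 0)), q) %*% t(ev$vectors)
    }))
  }
  structure(list(groups = groups, d = d, blocks = blocks, jitter = jitter,
                 p = p, fingerprint = genotype_fingerprint(X),
                 marker_names = colnames(X)),
            class = "grouped_oda")
}

#' Contiguous marker groups
#'
#' Default partition for the grouped augmentation: contiguous blocks of at
#' most `group_size` markers.
#'
#' @param p number of markers.
#' @param group_size maximum block size (default 1000).
#' @return list of index vectors.
#' @export
contiguous_groups <- function(p, group_size = 1000) {
  stopifnot(p >= 1, group_size >= 1)
  unname(split(seq_len(p), ceiling(seq_len(p) / group_size)))
}

#' Relative orthogonality defect
#'
#' `max |offdiag(W' W)| / d`, a scale-free measure of how far the columns of
#' a (stacked) design are from mutual orthogonality; an exact augmentation
#' gives a defect below 1e-6.
#'
#' @param W_c stacked design matrix.
#' @param d reference diagonal; defaults to `max(diag(W_c' W_c))`.
#' @return scalar defect (0 for exactly orthogonal columns).
#' @export
orthogonality_defect <- function(W_c, d = NULL) {
  C <- crossprod(as.matrix(W_c))
  if (ncol(C) == 1L) return(0)
  off <- max(abs(C - diag(diag(C), ncol(C))))
  d <- d %||% max(diag(C))
  off / d
}
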