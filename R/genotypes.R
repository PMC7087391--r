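#' Genotype container
#'
#' A light container for an `n x p` marker matrix coded 0/1/2 (copies of the
#' counted allele), together with per-locus allele frequencies, the centering
#' state, and the indices of loci retained after monomorphic-locus removal.
#'
#' @param X numeric matrix, individuals in rows, markers in columns.  Entries
#'   must be 0, 1 or 2 unless `centered = TRUE`.
#' @param ids individual labels; defaults to existing rownames or `ind<k>`.
#' @param allele_freq per-locus frequency of the counted allele.  Computed
#'   as `colMeans(X)/2` when `X` is uncentered; must be supplied otherwise.
#' @param centered logical; have the columns been mean-centered?
#' @param center_means column means subtracted during centering (needed to
#'   center a test set consistently); `NULL` when uncentered.
#' @param kept_loci indices of the columns relative to the original panel
#'   (bookkeeping across monomorphic-locus removal).
#'
#' @return An object of class `geno_data`: a list with elements `X`, `ids`,
#'   `allele_freq`, `centered`, `center_means`, `kept_loci`.
#' @export
geno_data <- function(X, ids = NULL, allele_freq = NULL, centered = FALSE,
                      center_means = NULL, kept_loci = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (!all(is.finite(X)))
    stop("genotype matrix contains non-finite entries")
  if (!centered && !all(X %in% c(0, 1, 2)))
    stop("uncentered genotype entries must be 0, 1 or 2")
  n <- nrow(X); p <- ncol(X)
  if (is.null(ids)) ids <- rownames(X) %||% sprintf("ind%05d", seq_len(n))
  if (is.null(colnames(X))) colnames(X) <- sprintf("m%05d", seq_len(p))
  rownames(X) <- ids
  if (is.null(allele_freq)) {
    if (centered)
      stop("allele_freq must be supplied for a centered genotype matrix")
    allele_freq <- colMeans(X) / 2
  }
  structure(
    list(X = X, ids = ids, allele_freq = as.numeric(allele_freq),
         centered = isTRUE(centered), center_means = center_means,
         kept_loci = kept_loci %||% seq_len(p)),
    class = "geno_data")
}

#' @export
print.geno_data <- function(x, ...) {
  cat(sprintf("geno_data: %d individuals x %d markers (%s)\n",
              nrow(x$X), ncol(x$X),
              if (x$centered) "centered" else "0/1/2 counts"))
  invisible(x)
}

#' @export
dim.geno_data <- function(x) dim(x$X)

#' Drop monomorphic loci
#'
#' Removes loci whose allele frequency is 0 or 1.  Such loci carry no
#' information and their per-locus Gibbs conditionals are undefined (the
#' update divides by the column sum of squares), so they are removed rather
#' than kept as zero-variance columns.
#'
#' @param G a [geno_data] object (uncentered).
#' @return a `geno_data` with the monomorphic columns removed and `kept_loci`
#'   updated to track positions in the original panel.
#' @export
drop_monomorphic <- function(G) {
  stopifnot(inherits(G, "geno_data"))
  keep <- G$allele_freq > 0 & G$allele_freq < 1
  geno_data(G$X[, keep, drop = FALSE], ids = G$ids,
            allele_freq = G$allele_freq[keep], centered = G$centered,
            center_means = G$center_means[keep],
            kept_loci = G$kept_loci[keep])
}

#' Center genotype columns
#'
#' Subtracts column means (or supplied means, e.g. training-set means when
#' centering a test set) from the marker matrix.
#'
#' @param G a [geno_data] object.
#' @param means optional vector of column means to subtract; defaults to the
#'   column means of `G$X`.
#' @return a centered `geno_data` carrying `center_means`.
#' @export
center_genotypes <- function(G, means = NULL) {
  stopifnot(inherits(G, "geno_data"))
  if (G$centered) return(G)
  means <- means %||% colMeans(G$X)
  stopifnot(length(means) == ncol(G$X))
  Xc <- sweep(G$X, 2, means, "-")
  geno_data(Xc, ids = G$ids, allele_freq = G$allele_freq, centered = TRUE,
            center_means = as.numeric(means), kept_loci = G$kept_loci)
}

# sum of 2 p_i (1 - p_i) over loci: expected heterozygosity mass used by the
# starting-value formula for the marker-effect variance
sum_2pq <- function(G) sum(2 * G$allele_freq * (1 - G$allele_freq))

# cheap consistency fingerprint of a genotype matrix (dims + moments), used to
# detect an augmentation built from a different matrix; not cryptographic
genotype_fingerprint <- function(G) {
  X <- if (inherits(G, "geno_data")) G$X else as.matrix(G)
  paste(nrow(X), ncol(X),
        format(sum(X), digits = 15), format(sum(X * X), digits = 15),
        format(X[1L, 1L], digits = 15), format(X[nrow(X), ncol(X)], digits = 15),
        sep = ":")
}
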