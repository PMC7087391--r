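# File formats: delimited text for everything a human diffs (genotypes,
# phenotypes, scalar traces, QTL truth, reports), RDS containers for the
# binary arrays (augmentations, thinned effect samples).  Column orders are
# documented in inst/FORMATS.md.

#' Write a genotype matrix
#'
#' Two dialects: `"raw-matrix"` (header of marker names, one row of 0/1/2
#' codes per individual, first column the individual id) and `"plink-raw"`
#' (PLINK `--recode A` style: header `FID IID PAT MAT SEX PHENOTYPE` then
#' one column per marker; PAT/MAT/SEX written as 0 and PHENOTYPE as NA).
#'
#' @param G an uncentered [geno_data].
#' @param path output file.
#' @param dialect `"raw-matrix"` or `"plink-raw"`.
#' @return `path`, invisibly.
#' @export
write_genotype_matrix <- function(G, path, dialect = c("raw-matrix",
                                                       "plink-raw")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(G, "geno_data"))
  if (G$centered) stop("write uncentered 0/1/2 genotypes")
  M <- G$X
  storage.mode(M) <- "integer"
  if (dialect == "raw-matrix") {
    df <- data.frame(id = G$ids, M, check.names = FALSE)
  } else {
    df <- data.frame(FID = G$ids, IID = G$ids, PAT = 0L, MAT = 0L,
                     SEX = 0L, PHENOTYPE = NA, M, check.names = FALSE)
  }
  write.table(df, path, quote = FALSE, sep = " ", row.names = FALSE)
  invisible(path)
}

#' Read a genotype matrix
#'
#' Parses 0/1/2 codes from either dialect written by
#' [write_genotype_matrix()].  The PLINK `.raw` dialect skips the six
#' leading columns (`FID IID PAT MAT SEX PHENOTYPE`) and keeps the marker
#' names from the header.  Missing or out-of-range codes are rejected with
#' the offending individual/marker coordinates.
#'
#' @param path input file.
#' @param dialect `"raw-matrix"` or `"plink-raw"`.
#' @return an uncentered [geno_data].
#' @export
read_genotype_matrix <- function(path, dialect = c("raw-matrix",
                                                   "plink-raw")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(
    read.table(path, header = TRUE, check.names = FALSE,
               stringsAsFactors = FALSE),
    error = function(e) stop("malformed genotype file (", conditionMessage(e),
                             ")"))
  meta_cols <- if (dialect == "raw-matrix") 1L else 6L
  if (dialect == "plink-raw" &&
      !identical(names(df)[1:6],
                 c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")))
    stop("not a PLINK .raw header (expected FID IID PAT MAT SEX PHENOTYPE)")
  if (ncol(df) <= meta_cols) stop("no marker columns found")
  ids <- as.character(df[[if (dialect == "raw-matrix") "id" else "IID"]])
  M <- as.matrix(df[, -(seq_len(meta_cols)), drop = FALSE])
  bad <- which(is.na(M) | !(M %in% c(0, 1, 2)), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("invalid genotype code at individual '%s', marker '%s'",
                 ids[bad[1, 1]], colnames(M)[bad[1, 2]]))
  storage.mode(M) <- "double"
  geno_data(M, ids = ids)
}

#' Write / read phenotypes
#'
#' Delimited text with header `id,y,bv`.
#'
#' @param trait a [trait_data].
#' @param ids individual labels.
#' @param path file path.
#' @return `path` (write) or a data.frame `id, y, bv` (read).
#' @export
write_phenotypes <- function(trait, ids, path) {
  stopifnot(inherits(trait, "trait_data"), length(ids) == length(trait$y))
  write.table(data.frame(id = ids, y = trait$y, bv = trait$bv),
              path, quote = FALSE, sep = ",", row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
  if (!all(c("id", "y") %in% names(df)))
    stop("phenotype file must have columns id, y")
  df
}

#' Write the QTL truth table
#'
#' @param qtl data.frame with columns `marker`, `panel_index`, `effect`
#'   (as produced by [simulate_dataset()]).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_qtl_table <- function(qtl, path) {
  write.table(qtl, path, quote = FALSE, sep = ",", row.names = FALSE)
  invisible(path)
}

#' Persist a chain trace
#'
#' The scalar trace goes to `<path>.tsv` (columns `iter mu pi sigma2_a
#' sigma2_e n_included`, one row per iteration including iteration 0); the
#' array parts (thinned effect and indicator samples, running mean,
#' metadata) go to `<path>.rds`.  [read_trace()] restores the trace
#' exactly; a version mismatch or truncated container is a clean error.
#'
#' @param trace a `chain_trace`.
#' @param path path stem (without extension).
#' @return the path stem, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "chain_trace"))
  write.table(trace$scalars, paste0(path, ".tsv"), quote = FALSE,
              sep = "\t", row.names = FALSE)
  saveRDS(trace, paste0(path, ".rds"))
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  rds <- paste0(path, ".rds")
  if (!file.exists(rds)) stop("trace container not found: ", rds)
  trace <- tryCatch(readRDS(rds),
                    error = function(e) stop("unreadable trace container: ",
                                             conditionMessage(e)))
  if (!inherits(trace, "chain_trace") ||
      !identical(trace$format_version, 1L))
    stop("trace format version mismatch")
  trace
}

#' Persist / restore an augmentation
#'
#' RDS container holding `d`, the jitter, the augmented rows and the source
#' genotype fingerprint (checked at sampling time).
#'
#' @param aug an `oda_augmentation` or `grouped_oda`.
#' @param path file path.
#' @return `path` (write) or the augmentation object (read).
#' @export
write_augmentation <- function(aug, path) {
  stopifnot(inherits(aug, "oda_augmentation") || inherits(aug, "grouped_oda"))
  saveRDS(aug, path)
  invisible(path)
}

#' @rdname write_augmentation
#' @export
read_augmentation <- function(path) {
  if (!file.exists(path)) stop("augmentation file not found: ", path)
  aug <- tryCatch(readRDS(path),
                  error = function(e) stop("unreadable augmentation file: ",
                                           conditionMessage(e)))
  if (!inherits(aug, "oda_augmentation") && !inherits(aug, "grouped_oda"))
    stop("file does not contain an augmentation")
  aug
}

#' Read a flat key = value run configuration
#'
#' One `key = value` pair per line; blank lines and `#` comments are
#' ignored.  Values are auto-converted to numeric where possible.
#' Command-line flags are expected to override file values (the CLI does
#' this).
#'
#' @param path configuration file.
#' @return named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}
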