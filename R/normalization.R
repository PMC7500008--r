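# Between-sample normalization for miRNA-Seq counts: trimmed mean of
# M-values (TMM), relative log expression / median-of-ratios (RLE), upper
# quartile (UQ) and total-count (TC), plus CPM computation, expression
# filtering and cross-method concordance diagnostics.
#
# TMM/RLE/UQ factor vectors are rescaled to geometric mean 1 so that CPM
# values are on a comparable scale across methods; TC is the identity
# (library size alone).

#' Per-sample library sizes
#'
#' @param counts validated count matrix.
#' @return named vector of column totals.
#' @export
lib_sizes <- function(counts) {
  counts <- validate_counts(counts)
  ls <- colSums(counts)
  if (any(ls == 0))
    lm_abort("zero_library_error",
             sprintf("sample(s) with zero total count: %s",
                     paste(colnames(counts)[ls == 0], collapse = ", ")))
  ls
}

.new_norm_factors <- function(factors, samples, method) {
  structure(as.numeric(factors), names = samples, method = method,
            class = "norm_factors")
}

#' @export
print.norm_factors <- function(x, ...) {
  cat(sprintf("%s normalization factors:\n", attr(x, "method")))
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

.geo_rescale <- function(f) f / exp(mean(log(f)))

# TMM factor of one sample against the reference. M/A statistics are
# computed over miRNAs with positive counts in both samples; the extreme
# trim_m (by M) and trim_a (by A) tails are discarded; remaining M-values
# are averaged with inverse asymptotic-variance weights.
.tmm_pair <- function(x, xr, N, Nr, trim_m, trim_a) {
  pos <- x > 0 & xr > 0
  if (!any(pos))
    lm_abort("normalization_error", "no miRNA with positive counts shared with the reference")
  x <- x[pos]; xr <- xr[pos]
  M <- log2((x / N) / (xr / Nr))
  A <- 0.5 * log2((x / N) * (xr / Nr))
  if (max(abs(M)) < 1e-6) return(1)
  w <- (N - x) / (N * x) + (Nr - xr) / (Nr * xr)
  n <- length(M)
  lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
  keep <- rank(M) >= lo_m & rank(M) <= hi_m & rank(A) >= lo_a & rank(A) <= hi_a
  if (!any(keep)) return(1)
  2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
}

#' Trimmed mean of M-values (TMM) normalization factors
#'
#' For each sample, the factor is `2^(weighted trimmed mean of M-values)`
#' against a reference sample, where `M = log2((x/N)/(x_ref/N_ref))` and
#' `A = (1/2) log2((x/N)(x_ref/N_ref))` over miRNAs with positive counts in
#' both samples. The top and bottom `trim_m` fraction by M and `trim_a`
#' fraction by A are removed and the surviving M-values are combined with
#' inverse asymptotic-variance weights
#' `(N - x)/(N x) + (N_ref - x_ref)/(N_ref x_ref)`. The reference defaults
#' to the sample whose 75th percentile of count/library-size is closest to
#' the across-sample mean of that quantity. Factors are rescaled to
#' geometric mean 1.
#'
#' @param counts validated count matrix (>= 2 samples).
#' @param trim_m fraction of M-values trimmed from each tail.
#' @param trim_a fraction trimmed from each tail by A.
#' @param ref optional reference sample id.
#' @return `norm_factors` vector, method `"TMM"`.
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05, ref = NULL) {
  counts <- validate_counts(counts)
  libs <- lib_sizes(counts)
  if (is.null(ref)) {
    uq <- apply(counts, 2, stats::quantile, probs = 0.75) / libs
    ref_idx <- which.min(abs(uq - mean(uq)))
  } else {
    ref_idx <- match(ref, colnames(counts))
    if (is.na(ref_idx))
      lm_abort("unknown_id_error", sprintf("unknown reference sample: %s", ref))
  }
  f <- vapply(seq_len(ncol(counts)), function(j)
    .tmm_pair(counts[, j], counts[, ref_idx], libs[j], libs[ref_idx],
              trim_m, trim_a), numeric(1))
  .new_norm_factors(.geo_rescale(f), colnames(counts), "TMM")
}

#' Relative log expression (median-of-ratios) normalization factors
#'
#' Each sample's factor is the median, over miRNAs detected in every sample,
#' of the ratio of its count to the per-miRNA geometric mean across samples,
#' divided by the library size and rescaled to geometric mean 1.
#'
#' @inheritParams tmm_factors
#' @return `norm_factors` vector, method `"RLE"`.
#' @export
rle_factors <- function(counts) {
  counts <- validate_counts(counts)
  libs <- lib_sizes(counts)
  allpos <- rowSums(counts > 0) == ncol(counts)
  if (!any(allpos))
    lm_abort("normalization_error", "RLE requires at least one miRNA detected in all samples")
  sub <- counts[allpos, , drop = FALSE]
  gm <- exp(rowMeans(log(sub)))
  f <- apply(sub / gm, 2, stats::median) / libs
  .new_norm_factors(.geo_rescale(f), colnames(counts), "RLE")
}

#' Upper-quartile normalization factors
#'
#' Per sample: the chosen quantile of the nonzero counts divided by the
#' library size, rescaled to geometric mean 1.
#'
#' @inheritParams tmm_factors
#' @param quantile quantile of the nonzero counts (default 0.75).
#' @return `norm_factors` vector, method `"UQ"`.
#' @export
uq_factors <- function(counts, quantile = 0.75) {
  counts <- validate_counts(counts)
  libs <- lib_sizes(counts)
  f <- vapply(seq_len(ncol(counts)), function(j) {
    x <- counts[, j]
    stats::quantile(x[x > 0], probs = quantile, names = FALSE)
  }, numeric(1)) / libs
  .new_norm_factors(.geo_rescale(f), colnames(counts), "UQ")
}

#' Total-count normalization factors (all ones)
#'
#' @inheritParams tmm_factors
#' @return `norm_factors` vector of ones, method `"TC"`.
#' @export
tc_factors <- function(counts) {
  counts <- validate_counts(counts)
  .new_norm_factors(rep(1, ncol(counts)), colnames(counts), "TC")
}

#' Normalization factors by method name
#'
#' @inheritParams tmm_factors
#' @param method one of `"TMM"`, `"RLE"`, `"UQ"`, `"TC"`.
#' @return `norm_factors` vector.
#' @export
norm_factors <- function(counts, method = c("TMM", "RLE", "UQ", "TC")) {
  method <- match.arg(method)
  switch(method,
         TMM = tmm_factors(counts),
         RLE = rle_factors(counts),
         UQ = uq_factors(counts),
         TC = tc_factors(counts))
}

.check_aligned_factors <- function(counts, factors) {
  if (length(factors) != ncol(counts))
    lm_abort("alignment_error", "normalization factors do not match the number of samples")
  if (!is.null(names(factors)) && !identical(names(factors), colnames(counts)))
    lm_abort("alignment_error", "normalization factor names do not match sample ids")
  if (any(factors <= 0))
    lm_abort("normalization_error", "normalization factors must be positive")
  invisible(TRUE)
}

#' Counts per million
#'
#' `CPM[m, s] = counts[m, s] / lib_size[s] * 1e6 / factor[s]`.
#'
#' @param counts validated count matrix.
#' @param factors `norm_factors` aligned to samples; `NULL` means total-count
#'   (all factors 1).
#' @param log if `TRUE`, return `log2(CPM + pseudocount)`.
#' @param pseudocount added before the log transform.
#' @return numeric matrix with attribute `norm_method`.
#' @export
cpm <- function(counts, factors = NULL, log = FALSE, pseudocount = 0.5) {
  counts <- validate_counts(counts)
  if (is.null(factors)) factors <- tc_factors(counts)
  .check_aligned_factors(counts, factors)
  libs <- lib_sizes(counts)
  v <- sweep(counts, 2, libs * as.numeric(factors), "/") * 1e6
  if (log) v <- log2(v + pseudocount)
  attr(v, "norm_method") <- attr(factors, "method") %||% "custom"
  v
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Filter miRNAs by CPM detection threshold
#'
#' Retains miRNA m iff `CPM[m, s] >= min_cpm` in at least
#' `ceiling(min_fraction * n_samples)` samples; input order is preserved.
#'
#' @param expr CPM matrix (not log-transformed).
#' @param min_cpm detection threshold in CPM units.
#' @param min_fraction minimum fraction of samples above threshold.
#' @return character vector of retained miRNA ids (possibly empty).
#' @export
filter_by_cpm <- function(expr, min_cpm = 1.0, min_fraction = 0.5) {
  need <- ceiling(min_fraction * ncol(expr))
  keep <- rowSums(expr >= min_cpm) >= need
  rownames(expr)[keep]
}

#' Concordance diagnostics between normalization methods
#'
#' For every method pair: the Spearman correlation between the vectorized
#' `log2(CPM + 0.5)` matrices and the maximum per-sample absolute difference
#' of log2 factors.
#'
#' @param counts validated count matrix.
#' @param methods methods to compare.
#' @return object of class `norm_comparison`: list with `factors` (per
#'   method), `cpm_spearman` and `max_log2_factor_diff` (symmetric matrices).
#' @export
compare_normalizations <- function(counts, methods = c("TMM", "RLE", "UQ", "TC")) {
  counts <- validate_counts(counts)
  facs <- lapply(methods, function(m) norm_factors(counts, m))
  names(facs) <- methods
  # signif() keeps values that are equal up to float noise tied under ranking
  logcpm <- lapply(facs, function(f)
    signif(as.vector(cpm(counts, f, log = TRUE, pseudocount = 0.5)), 10))
  k <- length(methods)
  rho <- diag(1, k); dmax <- matrix(0, k, k)
  dimnames(rho) <- dimnames(dmax) <- list(methods, methods)
  for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
    rho[i, j] <- rho[j, i] <- stats::cor(logcpm[[i]], logcpm[[j]], method = "spearman")
    d <- max(abs(log2(as.numeric(facs[[i]]) / as.numeric(facs[[j]]))))
    dmax[i, j] <- dmax[j, i] <- d
  }
  structure(list(factors = facs, cpm_spearman = rho, max_log2_factor_diff = dmax),
            class = "norm_comparison")
}

#' @export
print.norm_comparison <- function(x, ...) {
  cat("Spearman r of log2 CPM between methods:\n")
  print(round(x$cpm_spearman, 4))
  cat("\nMax per-sample |log2 factor difference|:\n")
  print(round(x$max_log2_factor_diff, 4))
  invisible(x)
}
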