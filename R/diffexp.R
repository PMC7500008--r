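# Two-group differential expression for miRNA counts.
#
# Significance is a consensus of two routes run on the same filtered
# miRNAs: a negative-binomial quasi-likelihood F-test (QLF) on raw counts
# with normalization offsets, and the nonparametric Mann-Whitney test on
# CPM values. Each p-value family gets its own Benjamini-Hochberg FDR, and
# a miRNA is called only if BOTH FDRs clear alpha and the fold change
# clears the threshold.

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' The statistic is `U = #\{(i, j): x_i > y_j\} + (1/2) #\{ties\}`. In
#' `"auto"` mode the exact null distribution is used when
#' `length(x) + length(y) <= 16` and there are no ties; otherwise the
#' normal approximation with tie-corrected variance and a 0.5 continuity
#' correction.
#'
#' @param x,y numeric vectors (>= 2 values each).
#' @param mode `"auto"`, `"exact"` or `"normal"`. Exact mode requires
#'   untied data.
#' @return list with elements `U` and `p` (two-sided, in (0, 1]).
#' @export
mann_whitney <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L)
    lm_abort("group_size_error", "each group needs at least 2 observations")
  if (anyNA(x) || anyNA(y))
    lm_abort("domain_error", "missing values are not allowed")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L
  if (mode == "auto") mode <- if (!ties && n1 + n2 <= 16L) "exact" else "normal"
  if (mode == "exact") {
    if (ties)
      lm_abort("domain_error", "exact mode requires untied data")
    p <- 2 * min(stats::pwilcox(U, n1, n2),
                 stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE))
  } else {
    mu <- n1 * n2 / 2
    nt <- n1 + n2
    tie_tab <- table(c(x, y))
    sigma2 <- n1 * n2 / 12 * ((nt + 1) - sum(tie_tab^3 - tie_tab) / (nt * (nt - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- max(abs(U - mu) - 0.5, 0) / sqrt(sigma2)
      p <- 2 * stats::pnorm(z, lower.tail = FALSE)
    }
  }
  list(U = U, p = max(min(p, 1), .Machine$double.xmin))
}

.two_groups <- function(groups, n, min_per_group = 2L) {
  groups <- as.factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) != 2L)
    lm_abort("group_size_error", "exactly two groups are required")
  if (length(groups) != n)
    lm_abort("alignment_error", "group labels do not match the number of samples")
  if (any(table(groups) < min_per_group))
    lm_abort("group_size_error",
             sprintf("each group needs at least %d samples", min_per_group))
  groups
}

#' Method-of-moments negative-binomial dispersion estimates
#'
#' Counts are scaled to a common effective library size; per-miRNA
#' dispersions come from the pooled within-group moment estimator
#' `phi = sum_g (n_g - 1)(s2_g - mu_g) / sum_g (n_g - 1) mu_g^2`, floored at
#' `floor`. The common dispersion is the median of the per-miRNA values and
#' the tagwise estimate interpolates geometrically between the per-miRNA
#' and common values with weight `min(1, prior_n / df_residual)`.
#'
#' @param counts validated count matrix.
#' @param factors `norm_factors` aligned to samples.
#' @param groups two-level factor over samples, >= 2 samples per level.
#' @param shrinkage_weight optional fixed weight in \[0, 1\] overriding the
#'   `prior_n / df` rule; 1 collapses tagwise onto the common dispersion.
#' @param prior_n prior sample mass for the default shrinkage weight.
#' @param floor lower bound applied to every dispersion.
#' @return object of class `dispersion_estimates`: list with `common`,
#'   `tagwise` (per miRNA) and `shrinkage_weight`.
#' @export
estimate_dispersions <- function(counts, factors, groups,
                                 shrinkage_weight = NULL, prior_n = 20,
                                 floor = 1e-6) {
  counts <- validate_counts(counts)
  .check_aligned_factors(counts, factors)
  groups <- .two_groups(groups, ncol(counts))
  eff <- lib_sizes(counts) * as.numeric(factors)
  y <- sweep(counts, 2, mean(eff) / eff, "*")
  num <- 0; den <- 0
  for (g in levels(groups)) {
    sub <- y[, groups == g, drop = FALSE]
    ng <- ncol(sub)
    mu <- rowMeans(sub)
    s2 <- rowSums((sub - mu)^2) / (ng - 1)
    num <- num + (ng - 1) * (s2 - mu)
    den <- den + (ng - 1) * mu^2
  }
  phi <- ifelse(den > 0, num / den, floor)
  phi <- pmax(phi, floor)
  common <- stats::median(phi)
  df <- ncol(counts) - 2L
  w <- if (is.null(shrinkage_weight)) min(1, prior_n / df) else shrinkage_weight
  if (w < 0 || w > 1)
    lm_abort("domain_error", "shrinkage_weight must be in [0, 1]")
  tagwise <- pmax(exp((1 - w) * log(phi) + w * log(common)), floor)
  structure(list(common = common, tagwise = stats::setNames(tagwise, rownames(counts)),
                 shrinkage_weight = w),
            class = "dispersion_estimates")
}

# Vectorized IRLS fit of per-miRNA NB log-linear models at fixed dispersion.
# All miRNAs share the design (intercept [+ group indicator]) and offsets,
# so each iteration reduces to closed-form 1x1 or 2x2 weighted least
# squares solved with row sums.
.nb_irls <- function(y, offset, g = NULL, phi, max_iter = 50L, tol = 1e-8) {
  m <- nrow(y); n <- ncol(y)
  O <- matrix(offset, m, n, byrow = TRUE)
  b0 <- log((rowSums(y) + 0.5) / sum(exp(offset)))
  b1 <- if (!is.null(g)) rep(0, m) else NULL
  G <- if (!is.null(g)) matrix(g, m, n, byrow = TRUE) else NULL
  active <- rep(TRUE, m)
  iters <- rep(max_iter, m)
  for (it in seq_len(max_iter)) {
    eta <- O + b0
    if (!is.null(g)) eta <- eta + G * b1
    mu <- pmax(exp(eta), 1e-10)
    w <- mu / (1 + phi * mu)
    z <- (y - mu) / mu
    if (is.null(g)) {
      step0 <- rowSums(w * z) / rowSums(w)
      step1 <- 0
    } else {
      a11 <- rowSums(w); a12 <- rowSums(w * G)
      r1 <- rowSums(w * z); r2 <- rowSums(w * G * z)
      det <- a11 * a12 - a12^2           # X = [1, g], g binary: a22 = a12
      det <- ifelse(abs(det) < 1e-12, NA_real_, det)
      step0 <- (a12 * r1 - a12 * r2) / det
      step1 <- (a11 * r2 - a12 * r1) / det
      bad <- is.na(step0) | is.na(step1)
      step0[bad] <- 0; step1[bad] <- 0
    }
    # damp very large steps to keep exp(eta) finite early on
    step0 <- pmin(pmax(step0, -5), 5)
    if (!is.null(g)) step1 <- pmin(pmax(step1, -5), 5)
    b0 <- b0 + ifelse(active, step0, 0)
    if (!is.null(g)) b1 <- b1 + ifelse(active, step1, 0)
    moved <- abs(step0) + (if (is.null(g)) 0 else abs(step1))
    newly_done <- active & moved < tol
    iters[newly_done] <- it
    active <- active & !newly_done
    if (!any(active)) break
  }
  eta <- O + b0
  if (!is.null(g)) eta <- eta + G * b1
  mu <- pmax(exp(eta), 1e-10)
  list(b0 = b0, b1 = b1, mu = mu, converged = !active)
}

# Per-miRNA NB residual deviance; phi per row. phi below 1e-8 falls back to
# the Poisson deviance (the NB limit).
.nb_deviance <- function(y, mu, phi) {
  m <- nrow(y)
  P <- matrix(phi, m, ncol(y))
  t1 <- ifelse(y > 0, y * log(y / mu), 0)
  pois <- P < 1e-8
  k <- 1 / pmax(P, 1e-12)
  d_nb <- 2 * (t1 - (y + k) * log((y + k) / (mu + k)))
  d_po <- 2 * (t1 - (y - mu))
  rowSums(ifelse(pois, d_po, d_nb))
}

#' Negative-binomial quasi-likelihood F-test
#'
#' Per miRNA, full (intercept + group) and null (intercept) NB log-linear
#' models are fitted by iteratively reweighted least squares at fixed
#' tagwise dispersion, with `log(lib_size * factor)` offsets. The
#' quasi-dispersion is the residual deviance over its degrees of freedom,
#' shrunk towards the across-miRNA mean with `prior_df` prior degrees of
#' freedom. `F = (null deviance - full deviance) / quasi-dispersion` is
#' referred to an F distribution with `(1, df_residual + prior_df)` degrees
#' of freedom.
#'
#' Non-converged fits are flagged and reported with `p = 1` (with a
#' warning), never as an error.
#'
#' @inheritParams estimate_dispersions
#' @param dispersions `dispersion_estimates` from [estimate_dispersions()],
#'   or a numeric vector/scalar of NB dispersions.
#' @param prior_df prior degrees of freedom for quasi-dispersion shrinkage.
#' @param max_iter,tol IRLS iteration cap and convergence tolerance.
#' @return data.frame with `mirna_id`, `coef_group` (log2 scale GLM group
#'   coefficient), `F`, `p_qlf`, `converged`.
#' @export
nb_ql_test <- function(counts, factors, groups, dispersions, prior_df = 10,
                       max_iter = 50L, tol = 1e-8) {
  counts <- validate_counts(counts)
  .check_aligned_factors(counts, factors)
  groups <- .two_groups(groups, ncol(counts))
  phi <- if (inherits(dispersions, "dispersion_estimates")) {
    as.numeric(dispersions$tagwise)
  } else {
    rep_len(as.numeric(dispersions), nrow(counts))
  }
  if (length(phi) != nrow(counts))
    lm_abort("alignment_error", "dispersions do not match the number of miRNAs")
  offset <- log(lib_sizes(counts) * as.numeric(factors))
  g <- as.numeric(groups == levels(groups)[2L])

  full <- .nb_irls(counts, offset, g, phi, max_iter = max_iter, tol = tol)
  null <- .nb_irls(counts, offset, NULL, phi, max_iter = max_iter, tol = tol)
  dev_full <- .nb_deviance(counts, full$mu, phi)
  dev_null <- .nb_deviance(counts, null$mu, phi)

  df <- ncol(counts) - 2L
  s2 <- pmax(dev_full, 0) / df
  s2_mean <- mean(s2)
  s2_shr <- pmax((prior_df * s2_mean + df * s2) / (prior_df + df), 1e-10)
  Fstat <- pmax(dev_null - dev_full, 0) / s2_shr
  p <- stats::pf(Fstat, 1, df + prior_df, lower.tail = FALSE)

  conv <- full$converged & null$converged
  if (any(!conv)) {
    lm_warn(sprintf("%d miRNA model fit(s) did not converge; reported with p = 1",
                    sum(!conv)))
    p[!conv] <- 1
    Fstat[!conv] <- 0
  }
  data.frame(mirna_id = rownames(counts),
             coef_group = full$b1 / log(2),
             F = Fstat, p_qlf = pmin(pmax(p, .Machine$double.xmin), 1),
             converged = conv,
             stringsAsFactors = FALSE)
}

#' Log2 fold change of group mean CPM
#'
#' `log2((mean CPM in the second group + pseudocount) /
#' (mean CPM in the first group + pseudocount))`; with groups N0/N1 this is
#' the N1-over-N0 ratio.
#'
#' @param expr CPM matrix.
#' @param groups two-level factor aligned to columns.
#' @param pseudocount stabilizer added to both group means.
#' @return named numeric vector, one value per miRNA.
#' @export
log2_fold_change <- function(expr, groups, pseudocount = 0.5) {
  groups <- .two_groups(groups, ncol(expr), min_per_group = 1L)
  ref <- levels(groups)[1L]; alt <- levels(groups)[2L]
  m_ref <- rowMeans(expr[, groups == ref, drop = FALSE])
  m_alt <- rowMeans(expr[, groups == alt, drop = FALSE])
  stats::setNames(log2((m_alt + pseudocount) / (m_ref + pseudocount)), rownames(expr))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values returned in input order.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return adjusted values in \[0, 1\].
#' @export
bh_adjust <- function(pvals) {
  if (anyNA(pvals) || any(pvals < 0) || any(pvals > 1))
    lm_abort("domain_error", "p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Consensus differential-expression calls
#'
#' BH FDR is computed separately for the Mann-Whitney and QLF p-value
#' families over all supplied miRNAs; a miRNA is called `N1_miR` iff both
#' FDRs are below `alpha` and `log2_fc >= log2(min_fold)` (threshold
#' inclusive), `N0_miR` with `log2_fc <= -log2(min_fold)`, otherwise
#' `not_significant`.
#'
#' @param records data.frame with columns `log2_fc`, `p_mw`, `p_qlf`.
#' @param alpha FDR threshold.
#' @param min_fold fold-change threshold (linear scale).
#' @return the input with columns `fdr_mw`, `fdr_qlf` and `call` added.
#' @export
call_consensus_de <- function(records, alpha = 0.05, min_fold = 1.5) {
  stopifnot(is.data.frame(records),
            all(c("log2_fc", "p_mw", "p_qlf") %in% names(records)))
  records$fdr_mw <- bh_adjust(records$p_mw)
  records$fdr_qlf <- bh_adjust(records$p_qlf)
  lfc <- log2(min_fold)
  sig <- records$fdr_mw < alpha & records$fdr_qlf < alpha
  call <- ifelse(sig & records$log2_fc >= lfc, "N1_miR",
                 ifelse(sig & records$log2_fc <= -lfc, "N0_miR", "not_significant"))
  records$call <- factor(call, levels = c("N1_miR", "N0_miR", "not_significant"))
  records
}

#' High/low relative-expression frequencies per cohort
#'
#' For each miRNA, a sample's relative expression is its CPM divided by the
#' mean CPM over ALL samples. A sample is flagged "high" when the ratio
#' exceeds `fold` and "low" when it is below `1/fold`. Flag frequencies are
#' tabulated per cohort and the cohort difference is tested with two-sided
#' Fisher's exact tests on the high-vs-not and low-vs-not 2x2 tables;
#' `p_fraction_diff` is the smaller of the two BH-adjusted values (each
#' family adjusted across miRNAs). All-zero miRNAs are skipped with a
#' warning and reported as `NA`.
#'
#' @param expr CPM matrix.
#' @param groups two-level factor (first level = N0 cohort).
#' @param fold relative-expression flag threshold.
#' @return data.frame with per-cohort high/low fractions and
#'   `p_fraction_diff`.
#' @export
highlow_fractions <- function(expr, groups, fold = 1.5) {
  groups <- .two_groups(groups, ncol(expr), min_per_group = 1L)
  is_ref <- groups == levels(groups)[1L]
  mu <- rowMeans(expr)
  zero <- mu == 0
  if (any(zero))
    lm_warn(sprintf("%d all-zero miRNA row(s) skipped in high/low analysis", sum(zero)))
  rel <- expr / ifelse(mu == 0, NA, mu)
  high <- rel > fold
  low <- rel < 1 / fold
  n0 <- sum(is_ref); n1 <- sum(!is_ref)
  k <- function(flags, idx) rowSums(flags[, idx, drop = FALSE])
  k_high0 <- k(high, is_ref); k_high1 <- k(high, !is_ref)
  k_low0 <- k(low, is_ref); k_low1 <- k(low, !is_ref)
  out <- data.frame(
    mirna_id = rownames(expr),
    frac_high_N0 = k_high0 / n0, frac_high_N1 = k_high1 / n1,
    frac_low_N0 = k_low0 / n0, frac_low_N1 = k_low1 / n1,
    stringsAsFactors = FALSE)
  p_one <- function(k0, k1) {
    if (is.na(k0) || is.na(k1)) return(NA_real_)
    fisher_exact_2x2(matrix(c(k0, n0 - k0, k1, n1 - k1), 2, 2))
  }
  p_high <- mapply(p_one, k_high0, k_high1)
  p_low <- mapply(p_one, k_low0, k_low1)
  adj <- function(p) { q <- rep(NA_real_, length(p)); ok <- !is.na(p)
                       q[ok] <- bh_adjust(p[ok]); q }
  out$p_fraction_diff <- pmin(adj(p_high), adj(p_low))
  rownames(out) <- NULL
  out
}

#' Full two-group differential-expression table
#'
#' Runs the Mann-Whitney test on CPM, the NB quasi-likelihood F-test on
#' counts, log2 fold change, per-family BH adjustment, the consensus call
#' and the high/low frequency analysis, returning one row per miRNA.
#'
#' @param counts validated count matrix (already expression-filtered).
#' @param groups two-level factor (N0 first level) aligned to samples.
#' @param factors `norm_factors`; computed with TMM when `NULL`.
#' @param alpha,min_fold consensus-call thresholds.
#' @param pseudocount used for log fold change and average log2 CPM.
#' @param mw_mode Mann-Whitney mode (see [mann_whitney()]).
#' @param prior_df QLF quasi-dispersion prior degrees of freedom.
#' @param shrinkage_weight optional dispersion shrinkage override.
#' @param highlow_fold threshold of the high/low relative-expression rule.
#' @return data.frame of per-miRNA statistics (a DE table).
#' @export
run_diffexp <- function(counts, groups, factors = NULL, alpha = 0.05,
                        min_fold = 1.5, pseudocount = 0.5,
                        mw_mode = c("auto", "exact", "normal"), prior_df = 10,
                        shrinkage_weight = NULL, highlow_fold = 1.5) {
  mw_mode <- match.arg(mw_mode)
  counts <- validate_counts(counts)
  if (is.null(factors)) factors <- tmm_factors(counts)
  groups <- .two_groups(groups, ncol(counts))
  expr <- cpm(counts, factors)
  is_ref <- groups == levels(groups)[1L]

  p_mw <- apply(expr, 1, function(v)
    mann_whitney(v[!is_ref], v[is_ref], mode = mw_mode)$p)
  disp <- estimate_dispersions(counts, factors, groups,
                               shrinkage_weight = shrinkage_weight)
  qlf <- nb_ql_test(counts, factors, groups, disp, prior_df = prior_df)

  records <- data.frame(
    mirna_id = rownames(counts),
    log2_fc = as.numeric(log2_fold_change(expr, groups, pseudocount)),
    avg_log2_cpm = rowMeans(log2(expr + pseudocount)),
    coef_group = qlf$coef_group,
    p_qlf = qlf$p_qlf,
    p_mw = as.numeric(p_mw),
    stringsAsFactors = FALSE)
  records <- call_consensus_de(records, alpha = alpha, min_fold = min_fold)
  hl <- highlow_fractions(expr, groups, fold = highlow_fold)
  records <- cbind(records, hl[match(records$mirna_id, hl$mirna_id),
                               setdiff(names(hl), "mirna_id"), drop = FALSE])
  rownames(records) <- NULL
  records[, c("mirna_id", "log2_fc", "avg_log2_cpm", "coef_group",
              "p_qlf", "fdr_qlf", "p_mw", "fdr_mw", "call",
              "frac_high_N0", "frac_high_N1", "frac_low_N0", "frac_low_N1",
              "p_fraction_diff")]
}
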