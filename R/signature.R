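# Per-sample signature scoring and cohort enrichment.
#
# The signature is built from two disjoint miRNA sets: miRNAs elevated in
# node-positive tumors (N1-miRs) and miRNAs elevated in node-negative
# tumors (N0-miRs). Each sample's score is the difference of its average
# row-centered log2 CPM over the two sets; the sign of the score assigns
# the sample to group G1 (positive, N1-like) or G0 (negative, N0-like),
# and enrichment of G1 among N1 samples is tested with Fisher's exact
# test. The correlation structure of the sets (within- and cross-module
# Spearman correlations) and their correlations with clinical features are
# summarized alongside.

#' Row-centered log2 expression
#'
#' `l[m, s] = log2(CPM[m, s] + pseudocount) - mean_s log2(CPM[m, .] +
#' pseudocount)`; every row of the result has mean zero, i.e. values are
#' per-sample log2 deviations from the miRNA's geometric-mean-like
#' reference.
#'
#' @param expr CPM matrix.
#' @param pseudocount added before the log transform.
#' @return numeric matrix of the same shape, rows centered.
#' @export
centered_log_expression <- function(expr, pseudocount = 0.5) {
  l <- log2(expr + pseudocount)
  l - rowMeans(l)
}

.check_sets <- function(ids, n1_set, n0_set) {
  if (length(n1_set) == 0L || length(n0_set) == 0L)
    lm_abort("empty_input_error", "both signature sets must be non-empty")
  unknown <- setdiff(c(n1_set, n0_set), ids)
  if (length(unknown) > 0L)
    lm_abort("unknown_id_error",
             sprintf("miRNA id(s) not in matrix: %s", paste(unknown, collapse = ", ")))
  overlap <- intersect(n1_set, n0_set)
  if (length(overlap) > 0L)
    lm_abort("set_overlap_error",
             sprintf("signature sets overlap: %s", paste(overlap, collapse = ", ")))
  invisible(TRUE)
}

#' Per-sample signature score (difference of average log2 deviations)
#'
#' `score[s] = mean over N1-miRs of cl[., s] - mean over N0-miRs of
#' cl[., s]` on a row-centered log-expression matrix.
#'
#' @param cl row-centered matrix from [centered_log_expression()].
#' @param n1_set,n0_set disjoint, non-empty miRNA id vectors present in `cl`.
#' @return named numeric vector of per-sample scores.
#' @export
sample_signature_score <- function(cl, n1_set, n0_set) {
  .check_sets(rownames(cl), n1_set, n0_set)
  colMeans(cl[n1_set, , drop = FALSE]) - colMeans(cl[n0_set, , drop = FALSE])
}

#' Dichotomize signature scores into G0/G1
#'
#' Negative scores give G0, positive give G1. A score of exactly zero is
#' resolved by the tie policy (default G0, with a warning); `"drop"` yields
#' `NA`.
#'
#' @param scores numeric vector.
#' @param tie `"G0"`, `"G1"` or `"drop"`.
#' @return factor with levels G0, G1 (ties `NA` under `"drop"`).
#' @export
assign_groups <- function(scores, tie = c("G0", "G1", "drop")) {
  tie <- match.arg(tie)
  g <- ifelse(scores < 0, "G0", ifelse(scores > 0, "G1", NA))
  zeros <- !is.na(scores) & scores == 0
  if (any(zeros)) {
    lm_warn(sprintf("%d zero score(s) resolved by tie policy '%s'", sum(zeros), tie))
    if (tie != "drop") g[zeros] <- tie
  }
  factor(g, levels = c("G0", "G1"))
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' The two-sided p-value sums the hypergeometric probabilities of all
#' tables with the observed margins whose point probability does not
#' exceed that of the observed table (point-probability rule).
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  if (!is.matrix(table) || !all(dim(table) == c(2L, 2L)))
    lm_abort("domain_error", "a 2x2 matrix is required")
  if (anyNA(table) || any(table < 0) || any(table != round(table)))
    lm_abort("domain_error", "table cells must be non-negative integers")
  if (sum(table) == 0)
    lm_abort("domain_error", "table total must be positive")
  stats::fisher.test(table)$p.value
}

#' Spearman rank correlation with t-approximate p-value
#'
#' Mid-rank (tie-averaged) Spearman correlation; the p-value uses the t
#' approximation `t = r sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of
#' freedom, with `p = 0` by convention when `|r| = 1`.
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return list with `r` and `p`.
#' @export
spearman <- function(x, y) {
  n <- length(x)
  if (length(y) != n)
    lm_abort("alignment_error", "vectors must have equal length")
  if (n < 3L)
    lm_abort("group_size_error", "at least 3 paired observations are required")
  if (anyNA(x) || anyNA(y))
    lm_abort("domain_error", "missing values are not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    lm_abort("constant_input_error", "constant input vector")
  r <- stats::cor(rank(x), rank(y))
  if (abs(r) >= 1 - 1e-12) {
    p <- 0
  } else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(t), df = n - 2)
  }
  list(r = r, p = p)
}

#' Spearman correlation structure of the signature modules
#'
#' Pairwise Spearman correlations (over samples) among all signature
#' miRNAs; averages are taken over unordered within-set pairs (excluding
#' self pairs) and over all cross-set pairs. Constant rows are dropped
#' with a warning.
#'
#' @param expr CPM matrix (rows include both sets; >= 3 samples).
#' @param n1_set,n0_set disjoint miRNA id sets.
#' @return object of class `correlation_summary`: list with `pairwise_r`
#'   (symmetric matrix over kept signature miRNAs), `avg_within_N1`,
#'   `avg_within_N0`, `avg_cross`, and the kept sets.
#' @export
correlation_structure <- function(expr, n1_set, n0_set) {
  .check_sets(rownames(expr), n1_set, n0_set)
  if (ncol(expr) < 3L)
    lm_abort("group_size_error", "at least 3 samples are required")
  ids <- c(n1_set, n0_set)
  sub <- expr[ids, , drop = FALSE]
  constant <- apply(sub, 1, function(v) stats::sd(v) == 0)
  if (any(constant)) {
    lm_warn(sprintf("dropping constant signature row(s): %s",
                    paste(ids[constant], collapse = ", ")))
    sub <- sub[!constant, , drop = FALSE]
    n1_set <- setdiff(n1_set, ids[constant])
    n0_set <- setdiff(n0_set, ids[constant])
    ids <- c(n1_set, n0_set)
  }
  ranks <- t(apply(sub, 1, rank))
  pr <- stats::cor(t(ranks))
  dimnames(pr) <- list(ids, ids)
  avg_pairs <- function(rows, cols) {
    block <- pr[rows, cols, drop = FALSE]
    if (identical(rows, cols)) {
      if (length(rows) < 2L) return(NA_real_)
      mean(block[upper.tri(block)])
    } else {
      mean(block)
    }
  }
  structure(list(pairwise_r = pr,
                 avg_within_N1 = avg_pairs(n1_set, n1_set),
                 avg_within_N0 = avg_pairs(n0_set, n0_set),
                 avg_cross = avg_pairs(n1_set, n0_set),
                 n1_set = n1_set, n0_set = n0_set),
            class = "correlation_summary")
}

#' @export
print.correlation_summary <- function(x, ...) {
  cat(sprintf("Average pairwise Spearman r: within N1-miRs %.3f, within N0-miRs %.3f, cross %.3f\n",
              x$avg_within_N1, x$avg_within_N0, x$avg_cross))
  invisible(x)
}

#' Correlations of miRNA expression with clinical features
#'
#' Spearman correlation of each miRNA's CPM with the 0/1 node-status
#' feature, and (over samples with a Gleason score) with the Gleason
#' score; also reports the Gleason-vs-node correlation. Fewer than 3
#' Gleason-annotated samples skip the Gleason block with a warning.
#'
#' @param expr CPM matrix.
#' @param annotations annotation data.frame aligned to `colnames(expr)`.
#' @param mirna_ids miRNAs to report (default: all rows).
#' @return list with `per_mirna` (data.frame: `r_node`, `p_node`,
#'   `r_gleason`, `p_gleason`) and `gleason_vs_node` (list `r`, `p`, or
#'   `NULL` when skipped).
#' @export
phenotype_correlations <- function(expr, annotations, mirna_ids = rownames(expr)) {
  if (!identical(annotations$sample_id, colnames(expr)))
    lm_abort("alignment_error", "annotations are not aligned to expression columns")
  unknown <- setdiff(mirna_ids, rownames(expr))
  if (length(unknown) > 0L)
    lm_abort("unknown_id_error",
             sprintf("miRNA id(s) not in matrix: %s", paste(unknown, collapse = ", ")))
  node <- as.numeric(annotations$node_status == "N1")
  if (stats::sd(node) == 0)
    lm_abort("constant_input_error", "node status is constant across samples")
  has_g <- !is.na(annotations$gleason)
  gleason_ok <- sum(has_g) >= 3L && stats::sd(annotations$gleason[has_g]) > 0
  if (!gleason_ok && sum(has_g) > 0L)
    lm_warn("fewer than 3 usable Gleason scores; Gleason correlations skipped")
  one <- function(v, feat) {
    res <- tryCatch(spearman(v, feat),
                    constant_input_error = function(e) list(r = NA_real_, p = NA_real_))
    c(res$r, res$p)
  }
  per <- t(vapply(mirna_ids, function(id) {
    v <- expr[id, ]
    rn <- one(v, node)
    rg <- if (gleason_ok) one(v[has_g], annotations$gleason[has_g]) else c(NA_real_, NA_real_)
    c(rn, rg)
  }, numeric(4)))
  per_df <- data.frame(mirna_id = mirna_ids,
                       r_node = per[, 1], p_node = per[, 2],
                       r_gleason = per[, 3], p_gleason = per[, 4],
                       stringsAsFactors = FALSE, row.names = NULL)
  gl_vs_node <- if (gleason_ok)
    spearman(annotations$gleason[has_g], node[has_g]) else NULL
  list(per_mirna = per_df, gleason_vs_node = gl_vs_node)
}

#' Full signature analysis of a dataset
#'
#' Computes per-sample signature scores from row-centered log2 CPM, the
#' G0/G1 assignment, the G x N contingency table and its Fisher exact
#' p-value, the module correlation structure, and clinical-feature
#' correlations of the signature miRNAs.
#'
#' @param expr CPM matrix.
#' @param annotations annotation data.frame aligned to `colnames(expr)`.
#' @param n1_set,n0_set disjoint signature miRNA sets.
#' @param pseudocount log-transform pseudocount.
#' @param tie zero-score tie policy (see [assign_groups()]).
#' @return object of class `signature_result`: list with `samples`
#'   (data.frame sample_id, score, group, node_status), `contingency`
#'   (G0/G1 x N0/N1), `fisher_p`, `correlation`
#'   ([correlation_structure()] output) and `phenotype`
#'   ([phenotype_correlations()] output).
#' @export
signature_analysis <- function(expr, annotations, n1_set, n0_set,
                               pseudocount = 0.5, tie = c("G0", "G1", "drop")) {
  tie <- match.arg(tie)
  if (!identical(annotations$sample_id, colnames(expr)))
    lm_abort("alignment_error", "annotations are not aligned to expression columns")
  cl <- centered_log_expression(expr, pseudocount)
  scores <- sample_signature_score(cl, n1_set, n0_set)
  grp <- assign_groups(scores, tie)
  keep <- !is.na(grp)
  contingency <- table(group = grp[keep],
                       node = annotations$node_status[keep])
  contingency <- matrix(as.integer(contingency), 2, 2,
                        dimnames = list(c("G0", "G1"), c("N0", "N1")))
  fisher_p <- fisher_exact_2x2(contingency)
  corr <- correlation_structure(expr, n1_set, n0_set)
  pheno <- phenotype_correlations(expr, annotations, c(n1_set, n0_set))
  structure(list(
    samples = data.frame(sample_id = colnames(expr),
                         score = as.numeric(scores),
                         group = grp,
                         node_status = annotations$node_status,
                         stringsAsFactors = FALSE),
    contingency = contingency,
    fisher_p = fisher_p,
    correlation = corr,
    phenotype = pheno), class = "signature_result")
}

#' @export
print.signature_result <- function(x, ...) {
  cat("Signature analysis\n")
  print(x$contingency)
  cat(sprintf("Fisher exact p (G x N): %.4g\n", x$fisher_p))
  print(x$correlation)
  invisible(x)
}

#' Simple signature heatmap
#'
#' Draws row-centered log2 expression of the signature miRNAs with samples
#' ordered by signature score. Diagnostic display only.
#'
#' @param expr CPM matrix.
#' @param result `signature_result` from [signature_analysis()].
#' @param pseudocount log-transform pseudocount.
#' @export
plot_signature <- function(expr, result, pseudocount = 0.5) {
  stopifnot(inherits(result, "signature_result"))
  ids <- c(result$correlation$n1_set, result$correlation$n0_set)
  cl <- centered_log_expression(expr, pseudocount)[ids, , drop = FALSE]
  ord <- order(result$samples$score)
  graphics::image(t(cl[rev(seq_len(nrow(cl))), ord, drop = FALSE]),
                  axes = FALSE, xlab = "samples (by signature score)",
                  ylab = "", main = "Signature miRNAs (row-centered log2 CPM)")
  invisible(NULL)
}
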