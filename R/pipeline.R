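# One-call orchestration: normalize -> filter -> dual-test DE -> consensus
# calls -> signature scoring -> correlation structure -> report, with all
# stage outputs written as TSV. Deterministic given inputs and config.

.config_fields <- c("counts", "annotations", "norm_method", "min_cpm",
                    "min_fraction", "alpha", "min_fold", "pseudocount",
                    "mw_mode", "prior_df", "shrinkage_weight", "highlow_fold",
                    "n1_set", "n0_set", "tie", "outdir", "seed",
                    "compare_norm", "verbose")

#' Pipeline configuration
#'
#' Validates the full set of analysis knobs; unknown keys are rejected.
#' `counts`/`annotations` may be file paths or in-memory objects.
#'
#' @param counts count matrix or path readable by [read_counts()].
#' @param annotations annotation data.frame or path for
#'   [read_annotations()].
#' @param norm_method `"TMM"`, `"RLE"`, `"UQ"` or `"TC"`.
#' @param min_cpm,min_fraction expression-filter thresholds
#'   (see [filter_by_cpm()]).
#' @param alpha,min_fold consensus-call thresholds.
#' @param pseudocount log/fold-change pseudocount.
#' @param mw_mode Mann-Whitney mode.
#' @param prior_df QLF prior degrees of freedom.
#' @param shrinkage_weight optional dispersion shrinkage override.
#' @param highlow_fold high/low relative-expression threshold.
#' @param n1_set,n0_set optional explicit signature sets (character
#'   vectors or files with one id per line); default: the consensus calls.
#' @param tie zero-score tie policy.
#' @param outdir output directory; `NULL` disables file output.
#' @param seed optional RNG seed (the default pipeline is deterministic;
#'   the seed is applied for forward compatibility of stochastic options).
#' @param compare_norm also run [compare_normalizations()].
#' @param verbose print stage progress.
#' @param ... unknown keys: rejected with an error.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(counts, annotations, norm_method = "TMM",
                            min_cpm = 1.0, min_fraction = 0.5, alpha = 0.05,
                            min_fold = 1.5, pseudocount = 0.5,
                            mw_mode = "auto", prior_df = 10,
                            shrinkage_weight = NULL, highlow_fold = 1.5,
                            n1_set = NULL, n0_set = NULL, tie = "G0",
                            outdir = NULL, seed = NULL, compare_norm = FALSE,
                            verbose = FALSE, ...) {
  extra <- list(...)
  if (length(extra) > 0L)
    lm_abort("spec_validation_error",
             sprintf("unknown configuration key(s): %s",
                     paste(names(extra), collapse = ", ")))
  cfg <- mget(.config_fields, envir = environment())
  if (!cfg$norm_method %in% c("TMM", "RLE", "UQ", "TC"))
    lm_abort("spec_validation_error", "norm_method must be TMM, RLE, UQ or TC")
  if (!cfg$mw_mode %in% c("auto", "exact", "normal"))
    lm_abort("spec_validation_error", "mw_mode must be auto, exact or normal")
  if (!cfg$tie %in% c("G0", "G1", "drop"))
    lm_abort("spec_validation_error", "tie must be G0, G1 or drop")
  if (cfg$alpha <= 0 || cfg$alpha >= 1)
    lm_abort("spec_validation_error", "alpha must be in (0, 1)")
  if (cfg$min_fold < 1)
    lm_abort("spec_validation_error", "min_fold must be >= 1")
  structure(cfg, class = "pipeline_config")
}

.load_set <- function(x) {
  if (is.null(x) || is.character(x) && length(x) > 1L) return(x)
  if (is.character(x) && file.exists(x)) return(readLines(x))
  x
}

#' Run the full analysis pipeline
#'
#' Stages: input binding, normalization, CPM + expression filter,
#' dual-test differential expression with consensus calls, high/low
#' frequency analysis, signature scoring with G0/G1 enrichment, module
#' correlation structure and phenotype correlations, optional
#' normalization comparison. When `outdir` is set, every stage result is
#' written as TSV along with a plain-text report.
#'
#' When no explicit signature sets are configured and the consensus caller
#' finds no miRNA of one direction, the signature block is skipped and
#' recorded as such in the report.
#'
#' @param config a `pipeline_config`.
#' @return object of class `run_report`: list with stage summaries and all
#'   result objects (`de_table`, `signature`, `norm_comparison`, ...).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (isTRUE(config$verbose)) message(sprintf(...))
  if (!is.null(config$seed)) set.seed(config$seed)

  counts <- if (is.character(config$counts)) read_counts(config$counts) else validate_counts(config$counts)
  ann <- if (is.character(config$annotations)) read_annotations(config$annotations) else config$annotations
  dataset <- bind_dataset(counts, ann)
  groups <- node_groups(dataset)
  if (any(table(groups) < 2L))
    lm_abort("group_size_error", "both node-status classes need >= 2 samples")
  say("input: %d miRNAs x %d samples", nrow(dataset$counts), ncol(dataset$counts))

  factors <- norm_factors(dataset$counts, config$norm_method)
  expr_all <- cpm(dataset$counts, factors)
  kept <- filter_by_cpm(expr_all, config$min_cpm, config$min_fraction)
  if (length(kept) == 0L)
    lm_abort("empty_input_error", "no miRNA passed the expression filter")
  say("filter: %d of %d miRNAs retained", length(kept), nrow(dataset$counts))
  fcounts <- dataset$counts[kept, , drop = FALSE]
  # factors are recomputed on the filtered matrix so offsets and CPMs
  # reflect the analysis set
  factors <- norm_factors(fcounts, config$norm_method)
  expr <- cpm(fcounts, factors)

  de <- run_diffexp(fcounts, groups, factors = factors, alpha = config$alpha,
                    min_fold = config$min_fold, pseudocount = config$pseudocount,
                    mw_mode = config$mw_mode, prior_df = config$prior_df,
                    shrinkage_weight = config$shrinkage_weight,
                    highlow_fold = config$highlow_fold)
  call_counts <- table(de$call)
  say("DE: %s", paste(sprintf("%s=%d", names(call_counts), call_counts), collapse = ", "))

  n1_set <- .load_set(config$n1_set) %||% de$mirna_id[de$call == "N1_miR"]
  n0_set <- .load_set(config$n0_set) %||% de$mirna_id[de$call == "N0_miR"]
  sig <- NULL
  if (length(n1_set) > 0L && length(n0_set) > 0L) {
    sig <- signature_analysis(expr, dataset$annotations, n1_set, n0_set,
                              pseudocount = config$pseudocount, tie = config$tie)
    say("signature: Fisher p = %.4g", sig$fisher_p)
  } else {
    say("signature: skipped (empty signature set)")
  }
  norm_cmp <- if (isTRUE(config$compare_norm)) compare_normalizations(fcounts) else NULL

  report <- structure(list(
    n_input = nrow(dataset$counts), n_samples = ncol(dataset$counts),
    n_filtered = length(kept),
    call_counts = stats::setNames(as.integer(call_counts), names(call_counts)),
    n1_set = n1_set, n0_set = n0_set,
    norm_method = config$norm_method,
    factors = factors, de_table = de, signature = sig,
    norm_comparison = norm_cmp,
    config = config,
    version = as.character(utils::packageVersion("lymphomiR"))),
    class = "run_report")

  if (!is.null(config$outdir)) .write_report(report, expr, config$outdir)
  report
}

.write_report <- function(report, expr, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_results(data.frame(sample_id = names(report$factors),
                           factor = as.numeric(report$factors),
                           stringsAsFactors = FALSE),
                file.path(outdir, "norm_factors.tsv"))
  write_results(data.frame(mirna_id = rownames(expr), expr,
                           check.names = FALSE, stringsAsFactors = FALSE),
                file.path(outdir, "cpm.tsv"))
  write_results(report$de_table, file.path(outdir, "de_results.tsv"))
  if (!is.null(report$signature)) {
    write_results(report$signature$samples, file.path(outdir, "signature_samples.tsv"))
    ct <- report$signature$contingency
    write_results(data.frame(group = rownames(ct), ct, check.names = FALSE,
                             stringsAsFactors = FALSE),
                  file.path(outdir, "signature_contingency.tsv"))
    pr <- report$signature$correlation$pairwise_r
    write_results(data.frame(mirna_id = rownames(pr), pr, check.names = FALSE,
                             stringsAsFactors = FALSE),
                  file.path(outdir, "correlation_matrix.tsv"))
    write_results(report$signature$phenotype$per_mirna,
                  file.path(outdir, "phenotype_correlations.tsv"))
  }
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(outdir, "report.txt"))
  invisible(outdir)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("lymphomiR run report (v%s)\n", x$version))
  cat(sprintf("input: %d miRNAs x %d samples; %d passed the expression filter\n",
              x$n_input, x$n_samples, x$n_filtered))
  cat(sprintf("normalization: %s\n", x$norm_method))
  cat("consensus calls: ",
      paste(sprintf("%s=%d", names(x$call_counts), x$call_counts), collapse = ", "),
      "\n", sep = "")
  if (!is.null(x$signature)) {
    cat(sprintf("signature sets: %d N1-miRs, %d N0-miRs\n",
                length(x$n1_set), length(x$n0_set)))
    print(x$signature$contingency)
    cat(sprintf("Fisher exact p (G x N): %.4g\n", x$signature$fisher_p))
    cr <- x$signature$correlation
    cat(sprintf("avg Spearman r: within-N1 %.3f, within-N0 %.3f, cross %.3f\n",
                cr$avg_within_N1, cr$avg_within_N0, cr$avg_cross))
  } else {
    cat("signature: skipped (empty signature set)\n")
  }
  if (!is.null(x$norm_comparison)) print(x$norm_comparison)
  invisible(x)
}

#' Simulate a dataset from a spec file and write it to disk
#'
#' Spec files are flat `key: value` text (the format [write_synthetic()]
#' echoes); omitted keys take the [synthetic_spec()] defaults.
#'
#' @param spec_path path to the spec file, or a `synthetic_spec`.
#' @param outdir output directory.
#' @return invisibly, the paths written.
#' @export
simulate_dataset <- function(spec_path, outdir) {
  spec <- if (inherits(spec_path, "synthetic_spec")) spec_path
          else do.call(synthetic_spec, .parse_spec_file(spec_path))
  sim <- generate_dataset(spec)
  write_synthetic(sim, spec, outdir)
}

.parse_spec_file <- function(path) {
  if (!file.exists(path))
    lm_abort("spec_validation_error", sprintf("spec file not found: %s", path))
  lines <- grep("^\\s*(#|$)", readLines(path), invert = TRUE, value = TRUE)
  kv <- strsplit(lines, ":", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, character(1), 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1L], collapse = ":"), character(1)))
  known <- names(formals(synthetic_spec))
  bad <- setdiff(keys, known)
  if (length(bad) > 0L)
    lm_abort("spec_validation_error",
             sprintf("unknown spec field(s): %s", paste(bad, collapse = ", ")))
  out <- lapply(seq_along(keys), function(i) {
    if (keys[i] == "composition_bias") {
      m <- regmatches(vals[i], regexec("fraction=([0-9.eE+-]+)\\s+fold=([0-9.eE+-]+)", vals[i]))[[1L]]
      if (length(m) != 3L)
        lm_abort("spec_validation_error", "composition_bias: expected 'fraction=<x> fold=<y>'")
      list(fraction = as.numeric(m[2L]), fold = as.numeric(m[3L]))
    } else {
      v <- suppressWarnings(as.numeric(strsplit(vals[i], ",", fixed = TRUE)[[1L]]))
      if (anyNA(v))
        lm_abort("spec_validation_error", sprintf("%s: not numeric", keys[i]))
      v
    }
  })
  names(out) <- keys
  out
}
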