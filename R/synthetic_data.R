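# Seeded synthetic miRNA-Seq datasets with known ground truth.
#
# Counts are negative-binomial around mu[m, s] = L_s * p_m * 2^(delta_m *
# z_s), where L_s is a log-normal library size, p_m a log-normal relative
# abundance (renormalized to sum 1), delta_m is +1 for the planted
# up-module, -1 for the down-module and 0 for null miRNAs, and z_s is a
# per-sample latent factor z_s = beta * I[s in N1] + Normal(0, latent_sd).
# Driving both modules with one latent factor makes them mutually
# (anti-)correlated within cohorts as well as between them, which is the
# correlation structure the signature analysis assumes. Optional
# composition bias multiplies a fraction of null miRNAs by a fold in N1
# samples only, creating the directional divergence between total-count
# and trimmed/robust normalization that the concordance diagnostics
# detect.

#' Specification of a synthetic dataset
#'
#' Defaults mirror the study design the package targets: 24 node-negative
#' and 20 node-positive samples, ~300 expressed miRNAs of which 9 are
#' planted up and 9 down in N1 with a one log2-unit group effect, NB
#' dispersion 0.3, and log-normal library sizes around 2 million reads.
#'
#' @param n_mirnas number of miRNAs.
#' @param n_N0,n_N1 cohort sizes (>= 2 each).
#' @param n_up,n_down planted module sizes.
#' @param effect_beta group shift of the latent factor, log2 units.
#' @param latent_sd within-cohort standard deviation of the latent factor.
#' @param dispersion NB dispersion phi (scalar or per-miRNA); variance is
#'   `mu + phi mu^2`, 0 degenerates to Poisson.
#' @param lib_size_log_mean,lib_size_log_sd log-normal library-size
#'   parameters (natural log scale).
#' @param baseline_log_mean,baseline_log_sd log-normal relative-abundance
#'   parameters before renormalization.
#' @param composition_bias `NULL` or `list(fraction =, fold =)`: the given
#'   fraction of null miRNAs is multiplied by `fold` in N1 samples only.
#' @param seed integer RNG seed.
#' @return validated list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_mirnas = 300L, n_N0 = 24L, n_N1 = 20L,
                           n_up = 9L, n_down = 9L, effect_beta = 1.0,
                           latent_sd = 0.5, dispersion = 0.3,
                           lib_size_log_mean = log(2e6), lib_size_log_sd = 0.3,
                           baseline_log_mean = 0, baseline_log_sd = 1.5,
                           composition_bias = NULL, seed = 1L) {
  spec <- list(n_mirnas = as.integer(n_mirnas), n_N0 = as.integer(n_N0),
               n_N1 = as.integer(n_N1), n_up = as.integer(n_up),
               n_down = as.integer(n_down), effect_beta = effect_beta,
               latent_sd = latent_sd, dispersion = dispersion,
               lib_size_log_mean = lib_size_log_mean,
               lib_size_log_sd = lib_size_log_sd,
               baseline_log_mean = baseline_log_mean,
               baseline_log_sd = baseline_log_sd,
               composition_bias = composition_bias, seed = as.integer(seed))
  fail <- function(field, msg) lm_abort("spec_validation_error",
                                        sprintf("%s: %s", field, msg))
  if (spec$n_mirnas < 1L) fail("n_mirnas", "must be >= 1")
  if (spec$n_N0 < 2L || spec$n_N1 < 2L) fail("n_N0/n_N1", "group sizes must be >= 2")
  if (spec$n_up < 0L || spec$n_down < 0L) fail("n_up/n_down", "must be >= 0")
  if (spec$n_up + spec$n_down > spec$n_mirnas)
    fail("n_up/n_down", "planted modules exceed n_mirnas")
  if (spec$latent_sd < 0) fail("latent_sd", "must be >= 0")
  if (any(spec$dispersion < 0)) fail("dispersion", "must be >= 0")
  if (!length(spec$dispersion) %in% c(1L, spec$n_mirnas))
    fail("dispersion", "must be scalar or one value per miRNA")
  if (spec$lib_size_log_sd < 0 || spec$baseline_log_sd < 0)
    fail("lib_size_log_sd/baseline_log_sd", "must be >= 0")
  if (!is.null(spec$composition_bias)) {
    cb <- spec$composition_bias
    if (!is.list(cb) || !all(c("fraction", "fold") %in% names(cb)))
      fail("composition_bias", "must be a list(fraction =, fold =)")
    if (cb$fraction < 0 || cb$fraction > 1) fail("composition_bias$fraction", "must be in [0, 1]")
    if (cb$fold <= 0) fail("composition_bias$fold", "must be > 0")
  }
  structure(spec, class = "synthetic_spec")
}

#' Generate a synthetic dataset with ground truth
#'
#' Fully reproducible from `spec$seed` (the caller's RNG state is
#' preserved). Samples are ordered N0 first, then N1.
#'
#' @param spec a `synthetic_spec` (or a plain list of its arguments).
#' @return list with `dataset` (a `mir_dataset`) and `truth`: list with
#'   `up_set`, `down_set`, `latent_z`, `true_log2fc` (0 for null miRNAs).
#' @export
generate_dataset <- function(spec = synthetic_spec()) {
  if (!inherits(spec, "synthetic_spec")) spec <- do.call(synthetic_spec, spec)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  n <- spec$n_N0 + spec$n_N1
  samples <- sprintf("S%03d", seq_len(n))
  node <- factor(rep(c("N0", "N1"), c(spec$n_N0, spec$n_N1)), levels = c("N0", "N1"))
  mirnas <- sprintf("miR-sim-%04d", seq_len(spec$n_mirnas))
  delta <- rep(0, spec$n_mirnas)
  up_idx <- seq_len(spec$n_up)
  down_idx <- spec$n_up + seq_len(spec$n_down)
  delta[up_idx] <- 1; delta[down_idx] <- -1

  z <- spec$effect_beta * as.numeric(node == "N1") + stats::rnorm(n, 0, spec$latent_sd)
  L <- stats::rlnorm(n, spec$lib_size_log_mean, spec$lib_size_log_sd)
  p <- stats::rlnorm(spec$n_mirnas, spec$baseline_log_mean, spec$baseline_log_sd)
  p <- p / sum(p)

  mu <- outer(p, L) * 2^(outer(delta, z))
  if (!is.null(spec$composition_bias)) {
    nulls <- which(delta == 0)
    n_biased <- round(spec$composition_bias$fraction * spec$n_mirnas)
    biased <- nulls[seq_len(min(n_biased, length(nulls)))]
    mu[biased, node == "N1"] <- mu[biased, node == "N1"] * spec$composition_bias$fold
  }
  phi <- rep_len(spec$dispersion, spec$n_mirnas)
  counts <- matrix(0, spec$n_mirnas, n, dimnames = list(mirnas, samples))
  for (i in seq_len(spec$n_mirnas)) {
    counts[i, ] <- if (phi[i] < 1e-12) stats::rpois(n, mu[i, ])
                   else stats::rnbinom(n, size = 1 / phi[i], mu = mu[i, ])
  }
  ann <- data.frame(sample_id = samples, node_status = node,
                    gleason = NA_integer_, stringsAsFactors = FALSE)
  dataset <- bind_dataset(counts, ann)
  truth <- list(up_set = mirnas[up_idx], down_set = mirnas[down_idx],
                latent_z = stats::setNames(z, samples),
                true_log2fc = stats::setNames(delta * spec$effect_beta, mirnas))
  list(dataset = dataset, truth = truth)
}

#' Evaluate consensus calls against ground truth
#'
#' @param calls DE table from [run_diffexp()] / [call_consensus_de()] with
#'   columns `mirna_id`, `call`, `log2_fc`.
#' @param truth ground-truth list from [generate_dataset()].
#' @return list with `sensitivity` (called true / true), `observed_fdr`
#'   (called null / called; 0 when nothing is called) and `sign_accuracy`
#'   (fraction of called true miRNAs with the correct fold-change sign).
#' @export
truth_evaluation <- function(calls, truth) {
  true_ids <- c(truth$up_set, truth$down_set)
  if (!all(true_ids %in% calls$mirna_id))
    lm_abort("unknown_id_error", "calls do not cover the planted miRNAs")
  called <- calls$mirna_id[calls$call != "not_significant"]
  tp <- intersect(called, true_ids)
  sens <- if (length(true_ids) > 0) length(tp) / length(true_ids) else NA_real_
  fdr <- if (length(called) > 0) length(setdiff(called, true_ids)) / length(called) else 0
  sign_ok <- if (length(tp) > 0) {
    lfc <- calls$log2_fc[match(tp, calls$mirna_id)]
    expected <- ifelse(tp %in% truth$up_set, 1, -1)
    mean(sign(lfc) == expected)
  } else NA_real_
  list(sensitivity = sens, observed_fdr = fdr, sign_accuracy = sign_ok)
}

#' Write a synthetic dataset (and its truth) to disk
#'
#' Emits the same TSV formats [read_counts()] and [read_annotations()]
#' consume, plus `truth.tsv` (mirna_id, delta, true_log2fc) and
#' `spec.yaml`-style `spec.txt` echoing the effective spec.
#'
#' @param sim output of [generate_dataset()].
#' @param spec the `synthetic_spec` used.
#' @param outdir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_synthetic <- function(sim, spec, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(counts = file.path(outdir, "counts.tsv"),
             annotations = file.path(outdir, "annotations.tsv"),
             truth = file.path(outdir, "truth.tsv"),
             spec = file.path(outdir, "spec.txt"))
  write_counts(sim$dataset$counts, paths["counts"])
  utils::write.table(sim$dataset$annotations, paths["annotations"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  delta <- ifelse(names(sim$truth$true_log2fc) %in% sim$truth$up_set, 1L,
                  ifelse(names(sim$truth$true_log2fc) %in% sim$truth$down_set, -1L, 0L))
  write_results(data.frame(mirna_id = names(sim$truth$true_log2fc),
                           delta = delta,
                           true_log2fc = as.numeric(sim$truth$true_log2fc),
                           stringsAsFactors = FALSE), paths["truth"])
  flat <- spec[!vapply(spec, is.null, logical(1))]
  flat$composition_bias <- NULL
  lines <- sprintf("%s: %s", names(flat), vapply(flat, function(v)
    paste(format(v, digits = 15), collapse = ","), character(1)))
  if (!is.null(spec$composition_bias))
    lines <- c(lines, sprintf("composition_bias: fraction=%g fold=%g",
                              spec$composition_bias$fraction, spec$composition_bias$fold))
  writeLines(lines, paths["spec"])
  invisible(paths)
}
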