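test_that("Mann-Whitney matches hand cases and the enumeration oracle", {
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p, 0.1)

  x <- c(2, 5, 9, 11)
  res <- mann_whitney(x, x)
  expect_equal(res$U, length(x)^2 / 2)
  expect_equal(res$p, 1)

  set.seed(202)
  for (k in 1:40) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- rnorm(n1); y <- rnorm(n2)
    expect_equal(mann_whitney(x, y, mode = "exact")$p, oracle_mw_exact(x, y),
                 tolerance = 1e-12, label = sprintf("case %d", k))
  }
  expect_error(mann_whitney(1, c(1, 2)), class = "group_size_error")
})

test_that("Mann-Whitney normal approximation tracks the exact p at the size boundary", {
  set.seed(7)
  for (k in 1:20) {
    x <- rnorm(12); y <- rnorm(12, 0.4)
    pe <- mann_whitney(x, y, mode = "exact")$p
    pn <- mann_whitney(x, y, mode = "normal")$p
    expect_lt(abs(pe - pn), 0.02)
  }
})

test_that("Mann-Whitney is label-antisymmetric", {
  set.seed(11)
  for (k in 1:25) {
    x <- round(rnorm(sample(3:10, 1)), 1)
    y <- round(rnorm(sample(3:10, 1)), 1)
    a <- mann_whitney(x, y); b <- mann_whitney(y, x)
    expect_equal(a$U, length(x) * length(y) - b$U)
    expect_equal(a$p, b$p)
  }
})

test_that("moment dispersion estimation recovers Poisson and NB truth", {
  sim <- generate_dataset(synthetic_spec(
    n_mirnas = 2000, n_N0 = 50, n_N1 = 50, n_up = 0, n_down = 0,
    effect_beta = 0, latent_sd = 0, dispersion = 0, seed = 8))
  d <- sim$dataset
  disp0 <- estimate_dispersions(d$counts, tc_factors(d$counts), node_groups(d))
  expect_lte(disp0$common, 0.05)

  sim4 <- generate_dataset(synthetic_spec(
    n_mirnas = 1000, n_N0 = 30, n_N1 = 30, n_up = 0, n_down = 0,
    effect_beta = 0, latent_sd = 0, dispersion = 0.4, seed = 9))
  d4 <- sim4$dataset
  disp4 <- estimate_dispersions(d4$counts, tc_factors(d4$counts), node_groups(d4))
  expect_gte(disp4$common, 0.2)
  expect_lte(disp4$common, 0.6)

  dispc <- estimate_dispersions(d4$counts, tc_factors(d4$counts), node_groups(d4),
                                shrinkage_weight = 1)
  expect_equal(unname(dispc$tagwise), rep(dispc$common, nrow(d4$counts)))
})

test_that("QLF returns p = 1 without signal and detects strong planted effects", {
  m <- matrix(7L, 20, 8, dimnames = list(sprintf("m%02d", 1:20), sprintf("s%d", 1:8)))
  g <- factor(rep(c("N0", "N1"), each = 4))
  q <- nb_ql_test(m, tc_factors(m), g, dispersions = 0.1)
  expect_equal(q$F, rep(0, 20))
  expect_equal(q$p_qlf, rep(1, 20))

  spec <- synthetic_spec(n_mirnas = 300, n_N0 = 10, n_N1 = 10, n_up = 15,
                         n_down = 15, effect_beta = 2, latent_sd = 0,
                         dispersion = 0.1, seed = 12)
  sim <- generate_dataset(spec)
  d <- sim$dataset
  f <- tmm_factors(d$counts)
  disp <- estimate_dispersions(d$counts, f, node_groups(d))
  q <- nb_ql_test(d$counts, f, node_groups(d), disp)
  planted <- q$mirna_id %in% c(sim$truth$up_set, sim$truth$down_set)
  expect_gte(mean(q$p_qlf[planted] < 0.01), 0.95)
})

test_that("QLF type-I error is near nominal on null NB data", {
  sim <- generate_dataset(synthetic_spec(
    n_mirnas = 1000, n_N0 = 10, n_N1 = 10, n_up = 0, n_down = 0,
    effect_beta = 0, latent_sd = 0, dispersion = 0.3, seed = 33))
  d <- sim$dataset
  f <- tmm_factors(d$counts)
  disp <- estimate_dispersions(d$counts, f, node_groups(d))
  q <- nb_ql_test(d$counts, f, node_groups(d), disp)
  expect_gt(mean(q$p_qlf < 0.05), 0.02)
  expect_lt(mean(q$p_qlf < 0.05), 0.08)
})

test_that("log2 fold change matches hand arithmetic", {
  expr <- matrix(c(10, 20, 30, 40, 50, 60), 1,
                 dimnames = list("m1", paste0("s", 1:6)))
  g <- factor(rep(c("N0", "N1"), each = 3), levels = c("N0", "N1"))
  expect_equal(unname(log2_fold_change(expr, g, pseudocount = 0.5)),
               log2(50.5 / 20.5))
  same <- matrix(c(3, 9, 5, 1, 5, 1, 3, 9), 2,
                 dimnames = list(c("a", "b"), paste0("s", 1:4)))
  expect_equal(unname(log2_fold_change(same, factor(c("N0", "N1", "N0", "N1")))),
               c(0, 0))
  big <- matrix(c(1000, 2000), 1, 2, dimnames = list("m", c("s1", "s2")))
  expect_equal(unname(log2_fold_change(big, factor(c("N0", "N1")))), 1,
               tolerance = 1e-3)
})

test_that("BH adjustment equals the step-up definition and keeps its invariants", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(5)
  for (k in 1:30) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))
    ord <- order(p)
    expect_true(all(diff(adj[ord]) >= -1e-15))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), class = "domain_error")
})

test_that("consensus calls require both tests and treat the fold threshold inclusively", {
  rec <- data.frame(
    mirna_id = c("a", "b", "c", "d"),
    log2_fc = c(2, log2(1.5), -log2(1.5), -2),
    p_mw = c(0.04, 1e-4, 1e-4, 0.5),
    p_qlf = c(0.2, 1e-4, 1e-4, 1e-4))
  out <- call_consensus_de(rec, alpha = 0.05)
  expect_equal(as.character(out$call),
               c("not_significant", "N1_miR", "N0_miR", "not_significant"))
  # invariant to miRNA ordering
  out2 <- call_consensus_de(rec[c(3, 1, 4, 2), ], alpha = 0.05)
  expect_equal(as.character(out2$call[order(out2$mirna_id)]),
               as.character(out$call[order(out$mirna_id)]))
})

test_that("the consensus call set is contained in each single-test call set", {
  sim <- generate_dataset(synthetic_spec(n_mirnas = 200, seed = 14))
  d <- sim$dataset
  de <- run_diffexp(d$counts, node_groups(d))
  consensus <- de$mirna_id[de$call != "not_significant"]
  fold_ok <- abs(de$log2_fc) >= log2(1.5)
  mw_set <- de$mirna_id[de$fdr_mw < 0.05 & fold_ok]
  qlf_set <- de$mirna_id[de$fdr_qlf < 0.05 & fold_ok]
  expect_true(all(consensus %in% mw_set))
  expect_true(all(consensus %in% qlf_set))
})

test_that("high/low relative-expression flags follow the fold rule", {
  g <- factor(rep(c("N0", "N1"), each = 4), levels = c("N0", "N1"))
  const <- matrix(5, 1, 8, dimnames = list("m1", paste0("s", 1:8)))
  out <- highlow_fractions(const, g)
  expect_equal(out$frac_high_N0 + out$frac_high_N1 + out$frac_low_N0 + out$frac_low_N1, 0)
  expect_equal(out$p_fraction_diff, 1)

  one_high <- matrix(c(14, rep(6, 7)), 1, 8, dimnames = list("m1", paste0("s", 1:8)))
  out <- highlow_fractions(one_high, g)   # mean 7; 14 -> rel 2 (high), 6 -> 6/7
  expect_equal(out$frac_high_N0, 0.25)
  expect_equal(out$frac_high_N1 + out$frac_low_N0 + out$frac_low_N1, 0)

  split <- matrix(c(rep(0.5, 4), rep(2, 4)), 1, 8,
                  dimnames = list("m1", paste0("s", 1:8)))
  # mean 1.25: rel 0.4 (low) in all N0, rel 1.6 (high) in all N1
  out <- highlow_fractions(split * 100, g)
  expect_equal(c(out$frac_high_N0, out$frac_high_N1, out$frac_low_N0, out$frac_low_N1),
               c(0, 1, 1, 0))
  expect_equal(out$p_fraction_diff, 2 / 70, tolerance = 1e-12)

  zero <- rbind(m1 = rep(0, 8), m2 = c(rep(1, 4), rep(100, 4)))
  colnames(zero) <- paste0("s", 1:8)
  expect_warning(out <- highlow_fractions(zero, g), "all-zero")
  expect_true(is.na(out$p_fraction_diff[1]))
})

test_that("fold-change sign agrees with the GLM group coefficient away from zero effect", {
  sim <- generate_dataset(synthetic_spec(seed = 15))
  d <- sim$dataset
  de <- run_diffexp(d$counts, node_groups(d))
  strong <- abs(de$log2_fc) > 0.25
  expect_gte(mean(sign(de$log2_fc[strong]) == sign(de$coef_group[strong])), 0.99)
})
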