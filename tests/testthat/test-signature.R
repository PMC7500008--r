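test_that("row centering produces zero-mean log2 deviations", {
  const <- matrix(4, 2, 5, dimnames = list(c("a", "b"), paste0("s", 1:5)))
  expect_equal(unname(centered_log_expression(const)), matrix(0, 2, 5))
  row14 <- matrix(c(1, 4), 1, dimnames = list("m", c("s1", "s2")))
  expect_equal(unname(centered_log_expression(row14, pseudocount = 0))[1, ],
               c(-1, 1), ignore_attr = TRUE)
  set.seed(3)
  r <- matrix(rexp(60), 6, 10, dimnames = list(letters[1:6], paste0("s", 1:10)))
  expect_equal(unname(rowMeans(centered_log_expression(r))), rep(0, 6),
               tolerance = 1e-12)
})

test_that("signature scores are mean differences over the two sets", {
  cl <- matrix(0, 18, 4, dimnames = list(sprintf("m%02d", 1:18), paste0("s", 1:4)))
  n1_set <- rownames(cl)[1:9]; n0_set <- rownames(cl)[10:18]
  cl[n1_set, 1] <- 1; cl[n0_set, 1] <- -1
  cl[, 3] <- seq(0.1, 1.8, by = 0.1)
  s <- sample_signature_score(cl, n1_set, n0_set)
  expect_equal(unname(s[1]), 2)
  expect_equal(unname(s[2]), 0)
  expect_equal(unname(s[3]), mean(cl[n1_set, 3]) - mean(cl[n0_set, 3]))
  expect_error(sample_signature_score(cl, c(n1_set, "nope"), n0_set),
               class = "unknown_id_error")
  expect_error(sample_signature_score(cl, n1_set, c(n0_set, n1_set[1])),
               class = "set_overlap_error")
})

test_that("group assignment follows the sign rule with explicit tie policy", {
  expect_equal(as.character(assign_groups(c(-0.5, 0.3))), c("G0", "G1"))
  expect_warning(g <- assign_groups(c(0, 1)), "tie policy")
  expect_equal(as.character(g), c("G0", "G1"))
  expect_warning(g1 <- assign_groups(0, tie = "G1"))
  expect_equal(as.character(g1), "G1")
  expect_warning(gd <- assign_groups(0, tie = "drop"))
  expect_true(is.na(gd[1]))
  s <- c(-2, -0.1, 0.4, 3)
  flipped <- c(G0 = "G1", G1 = "G0")
  expect_equal(as.character(assign_groups(-s)),
               unname(flipped[as.character(assign_groups(s))]))
})

test_that("Fisher exact p matches hand values and the enumeration oracle", {
  expect_equal(fisher_exact_2x2(matrix(c(2, 2, 2, 2), 2)), 1)
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2)), 2 / 252,
               tolerance = 1e-12)
  set.seed(99)
  for (k in 1:60) {
    tab <- matrix(rpois(4, sample(c(2, 5, 10), 1)), 2)
    if (sum(tab) == 0) tab[1, 1] <- 1
    expect_equal(fisher_exact_2x2(tab), oracle_fisher(tab), tolerance = 1e-9,
                 label = paste("table", k))
    expect_equal(fisher_exact_2x2(tab), fisher_exact_2x2(tab[2:1, ]))
    expect_equal(fisher_exact_2x2(tab), fisher_exact_2x2(tab[, 2:1]))
  }
  expect_error(fisher_exact_2x2(matrix(c(-1, 2, 3, 4), 2)), class = "domain_error")
})

test_that("Spearman correlation handles monotone data, ties and degenerate input", {
  x <- 1:8
  expect_equal(spearman(x, x^2)$r, 1)
  expect_equal(spearman(x, x^2)$p, 0)
  expect_equal(spearman(x, rev(x))$r, -1)
  set.seed(17)
  for (k in 1:30) {
    a <- round(rnorm(8), 1); b <- round(rnorm(8), 1)
    if (sd(a) == 0 || sd(b) == 0) next
    expect_equal(spearman(a, b)$r, oracle_spearman_r(a, b), tolerance = 1e-12)
  }
  expect_error(spearman(rep(1, 5), 1:5), class = "constant_input_error")
  expect_error(spearman(1:2, 2:1), class = "group_size_error")
})

test_that("correlation structure averages behave over trivial and planted modules", {
  expr <- rbind(a = c(1, 5, 2, 9, 3), b = c(2, 10, 4, 18, 6),
                c = c(9, 1, 8, 0.5, 7), d = c(5, 5, 5, 5, 6))
  colnames(expr) <- paste0("s", 1:5)
  cs <- correlation_structure(expr, n1_set = c("a", "b"), n0_set = "c")
  expect_equal(cs$avg_within_N1, 1)           # identical ranks
  expect_equal(cs$avg_cross, -1)
  expect_equal(cs$pairwise_r["a", "b"], cs$avg_within_N1)

  sim <- generate_dataset(synthetic_spec(seed = 23))
  e <- cpm(sim$dataset$counts, tmm_factors(sim$dataset$counts))
  cs2 <- correlation_structure(e, sim$truth$up_set, sim$truth$down_set)
  expect_gt(cs2$avg_within_N1, 0.3)
  expect_gt(cs2$avg_within_N0, 0.3)
  expect_lt(cs2$avg_cross, -0.3)
  # invariant to sample order and monotone per-miRNA transforms
  perm <- sample(ncol(e))
  cs3 <- correlation_structure(e[, perm], sim$truth$up_set, sim$truth$down_set)
  expect_equal(cs3$avg_cross, cs2$avg_cross)
  cs4 <- correlation_structure(e^2, sim$truth$up_set, sim$truth$down_set)
  expect_equal(cs4$avg_within_N1, cs2$avg_within_N1)
})

test_that("phenotype correlations match the mid-rank oracle and validate inputs", {
  expr <- rbind(m1 = c(1, 2, 3, 10, 11, 12), m2 = c(6, 4, 8, 3, 7, 2))
  colnames(expr) <- paste0("s", 1:6)
  ann <- data.frame(sample_id = paste0("s", 1:6),
                    node_status = factor(rep(c("N0", "N1"), each = 3),
                                         levels = c("N0", "N1")),
                    gleason = c(6L, 7L, 7L, 8L, 9L, 9L),
                    stringsAsFactors = FALSE)
  pc <- phenotype_correlations(expr, ann)
  node <- c(0, 0, 0, 1, 1, 1)
  expect_equal(pc$per_mirna$r_node[1], oracle_spearman_r(expr["m1", ], node))
  expect_equal(pc$per_mirna$r_gleason[2],
               oracle_spearman_r(expr["m2", ], ann$gleason))
  expect_gt(pc$per_mirna$r_node[1], 0.8)      # complete separation
  expect_equal(pc$gleason_vs_node$r, oracle_spearman_r(ann$gleason, node))

  ann_const <- ann; ann_const$node_status <- factor(rep("N0", 6), levels = c("N0", "N1"))
  expect_error(phenotype_correlations(expr, ann_const), class = "constant_input_error")
  ann_nog <- ann; ann_nog$gleason <- c(7L, NA, NA, NA, NA, NA)
  expect_warning(pc2 <- phenotype_correlations(expr, ann_nog), "Gleason")
  expect_true(all(is.na(pc2$per_mirna$r_gleason)))
})

test_that("swapping the signature sets negates scores and preserves the Fisher p", {
  sim <- generate_dataset(synthetic_spec(seed = 29))
  d <- sim$dataset
  e <- cpm(d$counts, tmm_factors(d$counts))
  a <- signature_analysis(e, d$annotations, sim$truth$up_set, sim$truth$down_set)
  b <- signature_analysis(e, d$annotations, sim$truth$down_set, sim$truth$up_set)
  expect_equal(b$samples$score, -a$samples$score)
  expect_equal(unname(b$contingency), unname(a$contingency[c("G1", "G0"), ]))
  expect_equal(b$fisher_p, a$fisher_p)
  expect_equal(sum(a$contingency), ncol(e))
})
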