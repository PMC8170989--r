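test_that("promoter aggregation averages the rule's probe set", {
  beta <- matrix(seq(0.1, 0.7, by = 0.1), nrow = 7, ncol = 2,
                 dimnames = list(paste0("p", 1:7), c("s1", "s2")))
  man <- data.frame(probe_id = paste0("p", 1:7), chrom = "chr1",
                    pos = 1:7 * 100, context = "island", cgi_id = "CGI_A",
                    gene_id = "G1", promoter_flag = TRUE,
                    tss_distance = c(-1999L, -2001L, -150L, 0L, 150L, 500L, 2000L),
                    stringsAsFactors = FALSE)
  out <- aggregate_promoter_methylation(beta, man, "promoter_flag_mean")
  expect_equal(unname(out["G1", "s1"]), 0.4)

  # inclusive +/- 2000 bp window: -1999 in, -2001 out
  win <- aggregate_promoter_methylation(beta, man, "tss_window_mean",
                                        window = 2000)
  expect_equal(unname(win["G1", "s1"]), mean(c(0.1, 0.3, 0.4, 0.5, 0.6, 0.7)))

  lst <- aggregate_promoter_methylation(
    beta, man, "listed_probes_mean",
    probe_sets = list(G9 = c("p1", "p2")))
  expect_equal(unname(lst["G9", "s1"]), 0.15)
  two <- matrix(c(0.59, 0.79), nrow = 2,
                dimnames = list(c("cgA", "cgB"), "s"))
  expect_equal(unname(aggregate_promoter_methylation(
    two, man, "listed_probes_mean",
    probe_sets = list(G = c("cgA", "cgB")))["G", ]), 0.69)
  expect_error(aggregate_promoter_methylation(
    beta, man, "listed_probes_mean", probe_sets = list(G = "absent")),
    class = "epimutr_validation_error", regexp = "absent")
  # missing values ignored within the mean
  beta_na <- beta; beta_na["p1", "s1"] <- NA
  out_na <- aggregate_promoter_methylation(beta_na, man, "promoter_flag_mean")
  expect_equal(unname(out_na["G1", "s1"]), mean(seq(0.2, 0.7, by = 0.1)))
})

test_that("rank-sum test matches hand values and enumeration oracles", {
  res <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p.value, 0.1)  # 2 * 1/choose(6,3)
  expect_equal(rank_sum_test(rep(1, 4), rep(1, 5))$p.value, 1)

  # random tie-free instances vs wilcox.test exact and the oracle
  set.seed(11)
  for (i in 1:20) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    x <- rnorm(n1); y <- rnorm(n2)
    expect_equal(rank_sum_test(x, y)$p.value,
                 wilcox.test(x, y, exact = TRUE)$p.value)
    expect_equal(rank_sum_test(x, y)$p.value, oracle_rank_sum_p(x, y))
    for (alt in c("greater", "less")) {
      expect_equal(rank_sum_test(x, y, alt)$p.value,
                   oracle_rank_sum_p(x, y, alt))
    }
  }
  # tied instances vs full enumeration (wilcox.test cannot do these)
  for (i in 1:20) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    x <- sample(1:3, n1, replace = TRUE)
    y <- sample(1:3, n2, replace = TRUE)
    expect_equal(rank_sum_test(x, y)$p.value, oracle_rank_sum_p(x, y),
                 tolerance = 1e-12)
  }
  expect_error(rank_sum_test(numeric(), 1:3),
               class = "epimutr_validation_error")
})

test_that("BH adjustment matches hand values and the step-up oracle", {
  expect_equal(bh_adjust(0.5), 0.5)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(3)
  for (i in 1:25) {
    p <- runif(sample(3:20, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone in sorted order
  }
  expect_error(bh_adjust(c(0.5, 1.2)), class = "epimutr_validation_error")
})

test_that("differential methylation recovers planted probes and is order-invariant", {
  fix <- small_cohort(201)
  A <- fix$sheet$sample_id[fix$sheet$group == "CIMP_high"]
  B <- fix$sheet$sample_id[fix$sheet$group == "non_CIMP"]
  dm <- differential_methylation(fix$beta, A, B, delta_threshold = 0.2,
                                 q_threshold = 0.05)
  called <- signature_ids(dm$signature)
  planted <- fix$truth$planted_cimp_probes
  epi_probes <- fix$manifest$probe_id[fix$manifest$promoter_flag &
    fix$manifest$gene_id %in% fix$truth$planted_epimutation_genes]
  expect_gte(mean(planted %in% called), 0.95)
  fdr <- 1 - mean(called %in% c(planted, epi_probes))
  expect_lte(fdr, 0.1)
  # q respects BH relation to p
  expect_true(all(dm$table$q_value >= dm$table$p_value - 1e-12))

  # invariance to probe and sample order
  perm <- sample(nrow(fix$beta))
  dm2 <- differential_methylation(fix$beta[perm, sample(ncol(fix$beta))],
                                  sample(A), sample(B),
                                  delta_threshold = 0.2, q_threshold = 0.05)
  expect_setequal(signature_ids(dm2$signature), called)

  # identical groups give an empty signature
  same <- differential_methylation(fix$beta[1:500, ], A, A,
                                   delta_threshold = 0.2, q_threshold = 0.05)
  expect_identical(length(same$signature), 0L)
  # thresholds are mandatory
  expect_error(differential_methylation(fix$beta, A, B),
               class = "epimutr_validation_error")
})

test_that("features with too few usable samples are dropped", {
  m <- matrix(runif(40), 4, 10,
              dimnames = list(paste0("f", 1:4), paste0("s", 1:10)))
  m["f2", 1:4] <- NA  # group A only 1 usable value
  dm <- differential_methylation(m, paste0("s", 1:5), paste0("s", 6:10),
                                 delta_threshold = 0.1, q_threshold = 0.5)
  expect_false("f2" %in% dm$table$feature)
  m[] <- NA
  expect_error(differential_methylation(m, paste0("s", 1:5), paste0("s", 6:10),
                                        delta_threshold = 0.1,
                                        q_threshold = 0.5),
               class = "epimutr_validation_error")
})

test_that("differential expression applies FD, q and reference-median filters", {
  # declared epsilon arithmetic
  expr <- rbind(gA = c(rep(0, 4), rep(10, 4)),
                gB = c(rep(5, 4), rep(5, 4)))
  colnames(expr) <- paste0("s", 1:8)
  de <- differential_expression(expr, paste0("s", 1:4), paste0("s", 5:8),
                                fd_threshold = 0.6, q_threshold = 0.9,
                                min_median_reference = 1)
  expect_equal(de$log2_fd[de$gene == "gA"], log2(0.01 / 10.01))
  expect_true(de$down[de$gene == "gA"])

  # huge fold change excluded when reference median < 1
  expr2 <- rbind(g1 = c(rep(0.001, 4), rep(0.5, 4)))
  colnames(expr2) <- paste0("s", 1:8)
  de2 <- differential_expression(expr2, paste0("s", 1:4), paste0("s", 5:8),
                                 fd_threshold = 0.6, q_threshold = 0.9,
                                 min_median_reference = 1)
  expect_false(any(de2$down))

  expect_error(differential_expression(-expr, paste0("s", 1:4),
                                       paste0("s", 5:8), 0.6, 0.05),
               class = "epimutr_validation_error")

  # planted silenced genes all called down at the standard thresholds
  fix <- small_cohort(211)
  A <- fix$sheet$sample_id[fix$sheet$group == "CIMP_high"]
  B <- fix$sheet$sample_id[fix$sheet$group == "non_CIMP"]
  de3 <- differential_expression(fix$expression, A, B, fd_threshold = 0.6,
                                 q_threshold = 0.05, min_median_reference = 1)
  expect_true(all(fix$truth$planted_epimutation_genes %in% de3$gene[de3$down]))
})

test_that("epimutation intersection composes set logic correctly", {
  out <- intersect_epimutations(c("A", "B", "C"), c("B", "C"), "C")
  expect_identical(out$gene[out$candidate], "C")
  expect_identical(attr(out, "mode"), "three_way")
  two <- intersect_epimutations(c("A", "B"), c("B", "C"))
  expect_identical(two$gene[two$candidate], "B")
  expect_identical(attr(two, "mode"), "two_way")
  expect_true(all(is.na(two$protein_pass)))
  expect_error(intersect_epimutations(NULL, c("A")),
               class = "epimutr_validation_error")
  # candidate implies every applicable pass
  expect_true(all(out$meth_pass[out$candidate] & out$rna_pass[out$candidate]))
})

test_that("tri-omic intersection recovers exactly the planted epimutations", {
  for (s in 1:3) {
    fix <- small_cohort(220 + s)
    A <- fix$sheet$sample_id[fix$sheet$group == "CIMP_high"]
    B <- fix$sheet$sample_id[fix$sheet$group == "non_CIMP"]
    gm <- aggregate_promoter_methylation(fix$beta, fix$manifest,
                                         "promoter_flag_mean")
    dm <- differential_methylation(gm, A, B, delta_threshold = 0.3,
                                   q_threshold = 0.1, direction = "hyper",
                                   level = "cgi")
    de <- differential_expression(fix$expression, A, B, fd_threshold = 0.6,
                                  q_threshold = 0.05, min_median_reference = 1)
    dp <- differential_expression(fix$protein, A, B, fd_threshold = 0.25,
                                  q_threshold = 0.05,
                                  min_median_reference = NULL,
                                  log2_input = TRUE)
    out <- intersect_epimutations(signature_ids(dm$signature, "hyper"),
                                  de$gene[de$down], dp$gene[dp$down])
    expect_setequal(out$gene[out$candidate],
                    fix$truth$planted_epimutation_genes)
  }
})

test_that("recurrence analysis reproduces printed-style percentages", {
  # counts 12/14, 2/23, 0/13 as expression vectors around the cut-off
  labels <- c(rep("CIMP_high", 14), rep("CIMP_low", 23), rep("non_CIMP", 13))
  names(labels) <- sprintf("s%02d", seq_along(labels))
  expr <- matrix(c(rep(0.2, 12), rep(5, 2),    # 12 of 14 silenced
                   rep(0.3, 2), rep(8, 21),    # 2 of 23
                   rep(4, 13)),                # 0 of 13
                 nrow = 1, dimnames = list("PANEL1", names(labels)))
  rec <- recurrence_analysis(expr, NULL, labels, silencing_threshold = 1)
  got <- setNames(rec$silencing$percent, rec$silencing$group)
  expect_identical(got[["CIMP_high"]], 85.71)
  expect_identical(got[["CIMP_low"]], 8.69)
  expect_identical(got[["non_CIMP"]], 0)

  # anti-monotone beta/expression gives Spearman r = -1
  meth <- matrix(seq(0.1, 0.9, length.out = 50), 1,
                 dimnames = list("PANEL1", names(labels)))
  expr_mono <- matrix(seq(50, 1, length.out = 50), 1,
                      dimnames = list("PANEL1", names(labels)))
  rec2 <- recurrence_analysis(expr_mono, meth, labels)
  expect_equal(rec2$correlation$rho, -1)
  expect_equal(rec2$correlation$p_value, 0)

  # labels must cover every sample
  expect_error(recurrence_analysis(expr, NULL, labels[-1]),
               class = "epimutr_validation_error")
})

test_that("Fisher exact test matches enumeration over all small tables", {
  expect_equal(fisher_exact_2x2(1, 1, 1, 1),
               list(odds_ratio = 1, p_value = 1), tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(5, 0, 0, 5)$p_value, 2 / 252,
               tolerance = 1e-12)
  deg <- fisher_exact_2x2(0, 0, 0, 0)
  expect_true(is.na(deg$odds_ratio))
  expect_equal(deg$p_value, 1)
  expect_error(fisher_exact_2x2(-1, 0, 0, 0),
               class = "epimutr_validation_error")
  # all tables with total n <= 8 against the hypergeometric oracle
  for (n in 0:8) {
    for (a in 0:n) for (b in 0:(n - a)) for (cc in 0:(n - a - b)) {
      d <- n - a - b - cc
      expect_equal(fisher_exact_2x2(a, b, cc, d)$p_value,
                   oracle_fisher_p(a, b, cc, d), tolerance = 1e-9)
    }
  }
})
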