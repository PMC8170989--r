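test_that("probe-to-CGI mapping applies majority vote and min support", {
  man <- tiny_manifest()
  sig <- meth_signature("cg1", "hyper", "probe", 6)
  cgi <- map_probes_to_cgis(sig, man)
  expect_identical(names(cgi$entries), "CGI_A")
  expect_identical(unname(cgi$entries[["CGI_A"]]), "hyper")
  expect_identical(cgi$universe_size, 2L)  # CGI_A and CGI_B carry islands

  # majority (hyper, hyper, hypo) -> hyper
  sig3 <- meth_signature(c("cg1", "cg2", "cg3"),
                         c("hyper", "hyper", "hypo"), "probe", 6)
  expect_identical(unname(map_probes_to_cgis(sig3, man)$entries[["CGI_A"]]),
                   "hyper")
  # tie dropped with warning
  sig2 <- meth_signature(c("cg1", "cg2"), c("hyper", "hypo"), "probe", 6)
  expect_warning(tied <- map_probes_to_cgis(sig2, man), regexp = "tied")
  expect_identical(length(tied), 0L)
  # min_probes = 2 drops single-probe CGIs
  expect_identical(length(map_probes_to_cgis(sig, man, min_probes = 2)), 0L)
  # signature without island probes warns and returns empty
  sea <- meth_signature("cg6", "hyper", "probe", 6)
  expect_warning(out <- map_probes_to_cgis(sea, man), regexp = "island")
  expect_identical(length(out), 0L)
})

test_that("signature overlap counts with and without direction matching", {
  u <- as.character(1:20)
  a <- meth_signature(as.character(1:5), "hyper", "cgi", 20)
  b_dirs <- c(rep("hypo", 1), rep("hyper", 4))  # id 4 hypo, 5..8 hyper
  b <- meth_signature(as.character(4:8), b_dirs, "cgi", 20)
  ov <- overlap_signatures(a, b, universe = u, direction_matched = TRUE)
  expect_identical(ov$observed, 1L)
  expect_identical(ov$shared_ids, "5")
  ov2 <- overlap_signatures(a, b, universe = u, direction_matched = FALSE)
  expect_identical(ov2$observed, 2L)
  # symmetric counts, not fractions
  expect_identical(overlap_signatures(b, a, u, FALSE)$observed, 2L)
  expect_equal(ov2$fraction_of_a, 2 / 5)

  ident <- overlap_signatures(a, a, u)
  expect_identical(ident$observed, 5L)
  expect_equal(ident$fraction_of_a, 1)
  disj <- meth_signature(as.character(11:13), "hyper", "cgi", 20)
  expect_identical(overlap_signatures(a, disj, u)$observed, 0L)
  out <- meth_signature("99", "hyper", "cgi", 99)
  expect_error(overlap_signatures(a, out, universe = u),
               class = "epimutr_validation_error")
})

test_that("bootstrap overlap p matches the hypergeometric tail", {
  u <- sprintf("id%02d", 1:10)
  b <- meth_signature(u[1:5], "hyper", "cgi", 10)
  res <- bootstrap_overlap_p(size_a = 5, sig_b = b, universe = u,
                             observed = 5, n_iterations = 10000, seed = 31)
  p_exact <- 1 / choose(10, 5)  # P(full overlap) = 1/252
  se <- sqrt(p_exact * (1 - p_exact) / 10000)
  expect_lt(abs(res$empirical_p - p_exact), 3 * se + 2 / 10001)
  # B = universe: every draw overlaps fully
  ball <- meth_signature(u, "hyper", "cgi", 10)
  expect_equal(bootstrap_overlap_p(5, ball, u, observed = 5,
                                   n_iterations = 50, seed = 1)$empirical_p, 1)
  # reproducibility and error paths
  r1 <- bootstrap_overlap_p(3, b, u, 2, n_iterations = 100, seed = 5)
  r2 <- bootstrap_overlap_p(3, b, u, 2, n_iterations = 100, seed = 5)
  expect_identical(r1$null_counts, r2$null_counts)
  expect_error(bootstrap_overlap_p(11, b, u, 2, 10, 1),
               class = "epimutr_validation_error")
  expect_error(bootstrap_overlap_p(5, b, u, 6, 10, 1),
               class = "epimutr_validation_error")
})

test_that("bootstrap overlap tail matches enumeration on small universes", {
  set.seed(17)
  for (i in 1:5) {
    U <- sample(8:12, 1)
    u <- sprintf("x%02d", seq_len(U))
    m <- sample(2:(U - 2), 1)
    sa <- sample(2:(U - 2), 1)
    b <- meth_signature(u[seq_len(m)], "hyper", "cgi", U)
    obs <- sample(0:min(sa, m), 1)
    res <- bootstrap_overlap_p(sa, b, u, obs, n_iterations = 4000,
                               seed = 100 + i)
    p_exact <- oracle_hyper_greater(obs, U, m, sa)
    se <- sqrt(p_exact * (1 - p_exact) / 4000)
    expect_lt(abs(res$empirical_p - p_exact), 3 * se + 2 / 4001)
  }
})

test_that("context enrichment computes exact binomial tails", {
  # n = 10, k = 9, p0 = 0.5 -> greater tail 11/1024, on a custom background
  man10 <- data.frame(
    probe_id = sprintf("p%02d", 1:10), chrom = "chr1", pos = 1:10 * 100,
    context = c(rep("island", 9), "open_sea"),
    cgi_id = c(rep("CGI_1", 9), NA), gene_id = NA, promoter_flag = FALSE,
    tss_distance = NA, stringsAsFactors = FALSE)
  sig10 <- meth_signature(man10$probe_id, "hyper", "probe", 10)
  ce <- context_enrichment(sig10, man10, background = "custom",
                           custom_proportions = c(island = 0.5, shore = 0.2,
                                                  shelf = 0.2, open_sea = 0.1))
  isl <- ce[ce$context == "island" & ce$subset == "hyper", ]
  expect_equal(isl$p_greater, 11 / 1024, tolerance = 1e-12)
  expect_equal(isl$p_greater, oracle_binom_greater(9, 10, 0.5),
               tolerance = 1e-12)
  # k/n = p0 exactly -> greater tail >= 0.5
  man2 <- man10; man2$context <- rep(c("island", "open_sea"), 5)
  man2$cgi_id <- ifelse(man2$context == "island", "CGI_1", NA)
  sig2 <- meth_signature(man2$probe_id, "hyper", "probe", 10)
  ce2 <- context_enrichment(sig2, man2, background = "custom",
                            custom_proportions = c(island = 0.5, shore = 0,
                                                   shelf = 0, open_sea = 0.5))
  expect_gte(ce2$p_greater[ce2$context == "island" & ce2$subset == "hyper"], 0.5)
  # invalid background
  expect_error(context_enrichment(sig10, man10, background = "custom",
                                  custom_proportions = c(island = 0.5,
                                                         shore = 0.2,
                                                         shelf = 0.2,
                                                         open_sea = 0.2)),
               class = "epimutr_validation_error")
  # empty signature
  expect_error(context_enrichment(meth_signature(character(), character(),
                                                 "probe", 0), man10),
               class = "epimutr_validation_error")
  # binomial tails match enumeration for a sweep of k, n <= 20
  for (n in c(5, 12, 20)) {
    for (k in c(0, 1, floor(n / 2), n)) {
      expect_equal(pbinom(k - 1, n, 0.3, lower.tail = FALSE),
                   oracle_binom_greater(k, n, 0.3), tolerance = 1e-12)
    }
  }
})

test_that("planted CIMP signature is island-enriched against the array background", {
  fix <- small_cohort(401)
  sig <- meth_signature(fix$truth$planted_cimp_probes, "hyper", "probe",
                        nrow(fix$beta))
  ce <- context_enrichment(sig, fix$manifest)
  hyper <- ce[ce$subset == "hyper", ]
  expect_lt(hyper$p_greater[hyper$context == "island"], 0.001)
  expect_lt(hyper$p_less[hyper$context == "open_sea"], 0.001)
})

test_that("gene-set overlap matches single-term hypergeometrics and BH", {
  sets <- list(HIT = sprintf("G%02d", 1:5), MISS = sprintf("H%02d", 1:4))
  res <- geneset_overlap(sprintf("G%02d", 1:5), sets, universe_size = 20)
  expect_equal(res$p_value[res$set == "HIT"], 1 / choose(20, 5),
               tolerance = 1e-12)
  expect_equal(res$p_value[res$set == "MISS"], 1)
  expect_equal(res$q_value, bh_adjust(res$p_value))
  expect_warning(geneset_overlap(c("G01", "G01"), sets, 20),
                 regexp = "de-duplicated")
  expect_error(geneset_overlap(sprintf("G%02d", 1:5), sets, universe_size = 3),
               class = "epimutr_validation_error")
  # q-values across many synthetic sets agree with the BH oracle
  set.seed(23)
  big <- setNames(lapply(1:50, function(i) sprintf("G%02d", sample(60, 8))),
                  sprintf("S%02d", 1:50))
  res2 <- geneset_overlap(sprintf("G%02d", sample(60, 10)), big,
                          universe_size = 60)
  expect_equal(res2$q_value, oracle_bh(res2$p_value), tolerance = 1e-12)
})
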