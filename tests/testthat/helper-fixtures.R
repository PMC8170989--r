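# Small in-code fixtures shared across test files.

tiny_manifest <- function() {
  data.frame(
    probe_id = c("cg1", "cg2", "cg3", "cg4", "cg5", "cg6"),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2", "chr2"),
    pos = c(1000L, 1100L, 1200L, 5000L, 2000L, 9000L),
    context = c("island", "island", "island", "shore", "island", "open_sea"),
    cgi_id = c("CGI_A", "CGI_A", "CGI_A", "CGI_A", "CGI_B", NA),
    gene_id = c("GENE1", "GENE1", NA, NA, "GENE2", NA),
    promoter_flag = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE),
    tss_distance = c(-150L, 50L, NA, NA, 0L, NA),
    exclude_flag = FALSE,
    stringsAsFactors = FALSE
  )
}

# Clone-design worked fixture: 2 passages x (parental, control, 2 clones),
# 3 probes. p1 is a clean conserved hyper DMP; p2 fails the both-clones
# condition (clone2 difference only 0.10); p3 fails at passage 2.
clone_fixture <- function() {
  sheet <- expand.grid(role = c("parental", "crispr_control", "clone1", "clone2"),
                       passage = 1:2, stringsAsFactors = FALSE)
  sheet$sample_id <- sprintf("%s_P%d", sheet$role, sheet$passage)
  sheet$group <- ifelse(grepl("^clone", sheet$role), "clone", sheet$role)
  sheet$clone_id <- ifelse(sheet$group == "clone", sheet$role, NA_character_)
  sheet <- sheet[, c("sample_id", "group", "clone_id", "passage")]

  beta <- matrix(NA_real_, nrow = 3, ncol = nrow(sheet),
                 dimnames = list(c("p1", "p2", "p3"), sheet$sample_id))
  is_control <- sheet$group %in% c("parental", "crispr_control")
  beta["p1", ] <- ifelse(is_control, 0.10,
                         ifelse(sheet$clone_id == "clone1", 0.40, 0.35))
  beta["p2", ] <- ifelse(is_control, 0.10,
                         ifelse(sheet$clone_id == "clone1", 0.40, 0.20))
  beta["p3", ] <- ifelse(is_control, 0.10,
                         ifelse(sheet$passage == 1, 0.40, 0.15))
  list(beta = beta, sheet = sheet)
}

# NB: first formal names are chosen so that no sim_config argument passed
# through ... can partially match them (e.g. `s` would match `seed`).
small_cohort <- function(master_seed, ...) {
  args <- utils::modifyList(
    list(mode = "cohort", seed = master_seed, n_probes = 8000,
         n_genes = 200, n_planted_epimutations = 10),
    list(...))
  cfg <- do.call(sim_config, args)
  manifest <- simulate_manifest(cfg)
  c(list(cfg = cfg, manifest = manifest), simulate_cohort(cfg, manifest))
}

small_clone_series <- function(master_seed, manifest = NULL,
                               cimp_probes = NULL, ...) {
  args <- utils::modifyList(
    list(mode = "clone", seed = master_seed, n_probes = 8000,
         n_genes = 200, n_clone_hyper = 150, n_clone_hypo = 100,
         n_clone_silenced_genes = 10, n_clone_private_decoys = 40,
         n_passage_private_decoys = 40),
    list(...))
  cfg <- do.call(sim_config, args)
  if (is.null(manifest)) manifest <- simulate_manifest(cfg)
  c(list(cfg = cfg, manifest = manifest),
    simulate_clone_series(cfg, manifest, cimp_probes = cimp_probes))
}
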