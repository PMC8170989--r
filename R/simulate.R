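#' Simulation configuration
#'
#' Bundles every knob of the synthetic methylation-array generator. The
#' defaults describe the emulated study design: a discovery cohort of
#' 30 cell lines (6 CIMP-high, 8 CIMP-low, 8 non-CIMP tumor, 8
#' non-malignant) measured on a 50,000-probe array whose CpG contexts
#' follow the 450K annotation breakdown, with CIMP hypermethylation
#' (delta-beta 0.35) concentrated at CpG islands and planted epimutation
#' genes silenced below 1 RPKM; and a knockout series of 2 clones plus
#' parental/CRISPR controls across 5 passages with conserved planted
#' shifts of delta-beta 0.3.
#'
#' Beta-value noise is Beta(m*s, (1-m)*s) around the per-probe mean m:
#' this respects the [0,1] support and the mean-dependent variance of
#' array beta values. The concentration s defaults to 100 in cohort mode
#' (distinct cell lines, biological heterogeneity) and 500 in clone mode
#' (repeated measurements of one line; replicate-level array precision,
#' SD about 0.02 at mid-range beta).
#'
#' CIMP-low is planted as two sub-populations at 0.4 and 0.6 of the
#' CIMP-high effect (mean = half the effect) so that the simulated cohort
#' reproduces the four-branch dendrogram topology in which CIMP-low spans
#' two branches.
#'
#' @param mode \code{"cohort"} or \code{"clone"}.
#' @param n_probes total array probes.
#' @param context_proportions named fractions for island/shore/shelf/
#'   open_sea; must sum to 1 (largest-remainder apportionment gives exact
#'   counts).
#' @param island_size probes per CpG island.
#' @param n_genes number of genes with annotated promoters.
#' @param probes_per_promoter island probes flagged per gene promoter.
#' @param group_sizes named cohort sizes (cohort mode).
#' @param baseline_means named baseline beta mean per context.
#' @param s Beta concentration; \code{NULL} picks the mode default.
#' @param cimp_effect planted CIMP delta-beta (added in CIMP-high).
#' @param cimp_fraction fraction of island probes carrying the CIMP shift.
#' @param cimp_low_multipliers effect multipliers for the two CIMP-low
#'   sub-branches.
#' @param n_planted_epimutations genes with coupled promoter
#'   hypermethylation + RNA silencing + protein loss.
#' @param silenced_rpkm_max silenced expression is Uniform(0, this).
#' @param expr_meanlog,expr_sdlog log-normal parameters of background
#'   expression.
#' @param protein_mean_log2,protein_sd_log2 background protein log2 LFQ
#'   (the 0.5 default reflects replicate-level LFQ precision).
#' @param protein_effect_log2 log2 shift of planted genes in CIMP-high
#'   (at most -2: protein loss accompanies silencing).
#' @param protein_coverage fraction of genes quantified at protein level
#'   (shotgun proteomics covers far fewer genes than RNA-seq); planted
#'   epimutation genes are always covered.
#' @param clone_effect planted clone delta-beta.
#' @param n_clone_hyper,n_clone_hypo planted consensus DMP counts
#'   (hyper on islands, hypo on open sea).
#' @param n_clone_silenced_genes genes whose promoter probes are planted
#'   hyper and whose expression drops in both clones.
#' @param n_clone_private_decoys probes shifted in only one clone.
#' @param n_passage_private_decoys probes shifted at only one passage.
#' @param n_passages,n_clones clone design dimensions.
#' @param clone_overlap_fraction fraction of planted hyper DMPs drawn from
#'   a supplied cohort CIMP probe set (see [simulate_clone_series()]).
#' @param mask_fraction fraction of beta cells masked to NA.
#' @param seed master RNG seed (required).
#' @return object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(mode = c("cohort", "clone"),
                       n_probes = 50000,
                       context_proportions = c(island = 0.31, shore = 0.23,
                                               shelf = 0.10, open_sea = 0.36),
                       island_size = 7,
                       n_genes = 1000,
                       probes_per_promoter = 7,
                       group_sizes = c(CIMP_high = 6, CIMP_low = 8,
                                       non_CIMP = 8, normal = 8),
                       baseline_means = c(island = 0.15, shore = 0.35,
                                          shelf = 0.55, open_sea = 0.75),
                       s = NULL,
                       cimp_effect = 0.35,
                       cimp_fraction = 0.2,
                       cimp_low_multipliers = c(0.4, 0.6),
                       n_planted_epimutations = 20,
                       silenced_rpkm_max = 1,
                       expr_meanlog = 2,
                       expr_sdlog = 1,
                       protein_mean_log2 = 25,
                       protein_sd_log2 = 0.5,
                       protein_effect_log2 = -3,
                       protein_coverage = 0.3,
                       clone_effect = 0.3,
                       n_clone_hyper = 500,
                       n_clone_hypo = 400,
                       n_clone_silenced_genes = 30,
                       n_clone_private_decoys = 100,
                       n_passage_private_decoys = 100,
                       n_passages = 5,
                       n_clones = 2,
                       clone_overlap_fraction = 0.35,
                       mask_fraction = 0,
                       seed) {
  mode <- match.arg(mode)
  if (missing(seed) || is.null(seed)) {
    stop_typed("epimutr_validation_error", "sim_config requires a seed")
  }
  if (abs(sum(context_proportions) - 1) > 1e-9) {
    stop_typed("epimutr_validation_error",
               "context proportions must sum to 1")
  }
  if (any(context_proportions < 0) || any(context_proportions > 1)) {
    stop_typed("epimutr_validation_error", "context proportions outside [0,1]")
  }
  stopifnot(identical(sort(names(context_proportions)), sort(CPG_CONTEXTS)),
            identical(sort(names(baseline_means)), sort(CPG_CONTEXTS)))
  for (eff in c(cimp_effect, clone_effect)) {
    if (eff < 0 || eff >= 1) {
      stop_typed("epimutr_validation_error", "effects must lie in [0, 1)")
    }
  }
  counts <- c(n_probes, n_genes, probes_per_promoter, group_sizes,
              n_planted_epimutations, n_clone_hyper, n_clone_hypo,
              n_clone_private_decoys, n_passage_private_decoys, n_clones)
  if (any(counts < 0)) {
    stop_typed("epimutr_validation_error", "counts must be >= 0")
  }
  if (mode == "clone" && n_passages < 1) {
    stop_typed("epimutr_validation_error", "n_passages must be >= 1")
  }
  if (is.null(s)) s <- if (mode == "cohort") 100 else 500
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a synthetic probe manifest
#'
#' Probes are laid out deterministically along 20 synthetic chromosomes:
#' each CpG island is a run of consecutive island probes sharing a
#' \code{cgi_id}, flanked by shore probes and then shelf probes; open-sea
#' probes fill the space between island blocks. The first
#' \code{n_genes} islands become gene promoters: their first
#' \code{probes_per_promoter} probes are promoter-flagged with TSS offsets
#' within +/- 2 kb. Context counts follow largest-remainder apportionment
#' of \code{context_proportions}, so they are exact.
#'
#' @param cfg a [sim_config()].
#' @return validated probe manifest data frame.
#' @export
simulate_manifest <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  props <- cfg$context_proportions[CPG_CONTEXTS]
  counts <- stats::setNames(apportion(cfg$n_probes, props), CPG_CONTEXTS)
  n_isl_probes <- counts[["island"]]
  if (cfg$n_genes * cfg$probes_per_promoter > n_isl_probes) {
    stop_typed("epimutr_validation_error",
               "not enough island probes for the requested promoters")
  }
  n_islands <- max(1L, n_isl_probes %/% cfg$island_size)
  # island sizes: island_size each, remainder folded into the last island
  isl_sizes <- rep(cfg$island_size, n_islands)
  isl_sizes[n_islands] <- isl_sizes[n_islands] + n_isl_probes -
    sum(isl_sizes)
  if (cfg$n_genes > sum(isl_sizes >= cfg$probes_per_promoter)) {
    stop_typed("epimutr_validation_error",
               "fewer islands than requested promoter genes")
  }
  # per-island quotas for flanking/ interleaved probes (largest remainder)
  shore_q <- apportion(counts[["shore"]], rep(1, 2 * n_islands))
  shelf_q <- apportion(counts[["shelf"]], rep(1, 2 * n_islands))
  sea_q <- apportion(counts[["open_sea"]], rep(1, n_islands))

  step <- c(island = 100L, shore = 1000L, shelf = 2000L, open_sea = 10000L)
  ctx <- character(cfg$n_probes)
  cgi <- character(cfg$n_probes)
  k <- 0L
  add <- function(n, context, cgi_id) {
    if (n <= 0) return(invisible())
    idx <- k + seq_len(n)
    ctx[idx] <<- context
    cgi[idx] <<- cgi_id
    k <<- n + k
  }
  for (j in seq_len(n_islands)) {
    cgi_j <- sprintf("CGI_%05d", j)
    add(shelf_q[2 * j - 1], "shelf", cgi_j)
    add(shore_q[2 * j - 1], "shore", cgi_j)
    add(isl_sizes[j], "island", cgi_j)
    add(shore_q[2 * j], "shore", cgi_j)
    add(shelf_q[2 * j], "shelf", cgi_j)
    add(sea_q[j], "open_sea", NA_character_)
  }
  stopifnot(k == cfg$n_probes)

  # chromosomes: 20 near-equal contiguous slices (islands are never split
  # because slice boundaries land between blocks only approximately; the
  # cgi_id, not the chromosome, carries island identity downstream)
  n_chrom <- min(20L, cfg$n_probes)
  chrom_idx <- as.integer(cut(seq_len(cfg$n_probes), n_chrom, labels = FALSE))
  chrom <- paste0("chr", chrom_idx)
  pos <- integer(cfg$n_probes)
  for (cc in unique(chrom_idx)) {
    sel <- which(chrom_idx == cc)
    pos[sel] <- cumsum(step[ctx[sel]])
  }

  gene <- rep(NA_character_, cfg$n_probes)
  prom <- rep(FALSE, cfg$n_probes)
  tssd <- rep(NA_integer_, cfg$n_probes)
  if (cfg$n_genes > 0) {
    eligible_islands <- which(isl_sizes >= cfg$probes_per_promoter)
    promoter_islands <- eligible_islands[seq_len(cfg$n_genes)]
    offsets <- as.integer(seq(-300, by = 100,
                              length.out = cfg$probes_per_promoter))
    island_idx <- split(which(ctx == "island"), cgi[ctx == "island"])
    for (g in seq_len(cfg$n_genes)) {
      j <- promoter_islands[g]
      cgi_j <- sprintf("CGI_%05d", j)
      idx <- island_idx[[cgi_j]][seq_len(cfg$probes_per_promoter)]
      gene[idx] <- sprintf("G%04d", g)
      prom[idx] <- TRUE
      tssd[idx] <- offsets
    }
  }
  manifest <- data.frame(
    probe_id = sprintf("cg%07d", seq_len(cfg$n_probes)),
    chrom = chrom,
    pos = pos,
    context = ctx,
    cgi_id = cgi,
    gene_id = gene,
    promoter_flag = prom,
    tss_distance = tssd,
    exclude_flag = FALSE,
    stringsAsFactors = FALSE
  )
  validate_probe_manifest(manifest)
}

# mean matrix -> Beta draws, means clipped away from 0/1 so the Beta
# parameters stay proper
draw_beta <- function(m, s) {
  m <- pmin(pmax(m, 0.02), 0.98)
  b <- stats::rbeta(length(m), m * s, (1 - m) * s)
  matrix(b, nrow = nrow(m), dimnames = dimnames(m))
}

#' Simulate a CIMP discovery cohort with planted truth
#'
#' Emulates a tumor cell-line panel: per probe and sample, beta is drawn
#' from Beta(m*s, (1-m)*s) around the context baseline m; planted CIMP
#' probes gain \code{cimp_effect} in CIMP-high samples and
#' \code{cimp_low_multipliers} times that in the two CIMP-low
#' sub-branches; planted epimutation genes additionally gain the effect on
#' all promoter probes in CIMP-high samples, with expression drawn
#' Uniform(0, \code{silenced_rpkm_max}) there (log-normal elsewhere) and
#' protein log2 intensity reduced by \code{protein_effect_log2}.
#'
#' RNG streams are derived from the master seed per output (keys: 1 beta,
#' 2 expression, 3 protein, 4 planting, 5 masking), so adding an output
#' does not perturb the others.
#'
#' @param cfg a cohort-mode [sim_config()].
#' @param manifest manifest from [simulate_manifest()].
#' @return list with elements \code{beta}, \code{expression},
#'   \code{protein}, \code{sheet}, \code{truth}.
#' @export
simulate_cohort <- function(cfg, manifest) {
  stopifnot(inherits(cfg, "sim_config"), cfg$mode == "cohort")
  if (cfg$n_planted_epimutations > cfg$n_genes) {
    stop_typed("epimutr_validation_error",
               "more planted epimutations than genes")
  }
  groups <- rep(names(cfg$group_sizes), cfg$group_sizes)
  sample_ids <- unlist(lapply(names(cfg$group_sizes), function(g) {
    sprintf("%s_%02d", g, seq_len(cfg$group_sizes[[g]]))
  }))
  n_s <- length(sample_ids)
  island_probes <- manifest$probe_id[manifest$context == "island"]
  gene_ids <- sort(unique(stats::na.omit(manifest$gene_id)))

  planted <- with_seed(derive_seed(cfg$seed, 4), {
    list(
      cimp_probes = sort(sample(island_probes,
                                round(cfg$cimp_fraction * length(island_probes)))),
      epi_genes = sort(sample(gene_ids, cfg$n_planted_epimutations))
    )
  })

  base_m <- cfg$baseline_means[manifest$context]
  M <- matrix(base_m, nrow = nrow(manifest), ncol = n_s,
              dimnames = list(manifest$probe_id, sample_ids))
  is_high <- groups == "CIMP_high"
  is_low <- groups == "CIMP_low"
  low_mult <- rep(cfg$cimp_low_multipliers,
                  length.out = sum(is_low))
  cimp_idx <- match(planted$cimp_probes, manifest$probe_id)
  M[cimp_idx, is_high] <- M[cimp_idx, is_high] + cfg$cimp_effect
  M[cimp_idx, is_low] <- sweep(M[cimp_idx, is_low, drop = FALSE], 2,
                               cfg$cimp_effect * low_mult, "+")
  epi_probe_idx <- which(manifest$promoter_flag &
                           manifest$gene_id %in% planted$epi_genes)
  M[epi_probe_idx, is_high] <- M[epi_probe_idx, is_high] + cfg$cimp_effect

  beta <- with_seed(derive_seed(cfg$seed, 1), draw_beta(M, cfg$s))
  if (cfg$mask_fraction > 0) {
    beta <- with_seed(derive_seed(cfg$seed, 5), {
      n_mask <- round(cfg$mask_fraction * length(beta))
      beta[sample(length(beta), n_mask)] <- NA_real_
      beta
    })
  }

  expression <- with_seed(derive_seed(cfg$seed, 2), {
    e <- matrix(stats::rlnorm(length(gene_ids) * n_s, cfg$expr_meanlog,
                              cfg$expr_sdlog),
                nrow = length(gene_ids),
                dimnames = list(gene_ids, sample_ids))
    sel <- gene_ids %in% planted$epi_genes
    e[sel, is_high] <- stats::runif(sum(sel) * sum(is_high),
                                    0, cfg$silenced_rpkm_max)
    # an epimutation target is an otherwise-expressed gene: outside
    # CIMP-high its expression is log-normal truncated to stay at or
    # above the silencing cut-off (inverse-CDF truncation)
    lo <- stats::plnorm(cfg$silenced_rpkm_max, cfg$expr_meanlog, cfg$expr_sdlog)
    n_expr <- sum(sel) * sum(!is_high)
    e[sel, !is_high] <- stats::qlnorm(stats::runif(n_expr, lo, 1),
                                      cfg$expr_meanlog, cfg$expr_sdlog)
    e
  })
  protein <- with_seed(derive_seed(cfg$seed, 3), {
    n_prot <- max(length(planted$epi_genes),
                  round(cfg$protein_coverage * length(gene_ids)))
    covered <- sort(union(planted$epi_genes,
                          sample(gene_ids, n_prot)))
    p <- matrix(stats::rnorm(length(covered) * n_s, cfg$protein_mean_log2,
                             cfg$protein_sd_log2),
                nrow = length(covered),
                dimnames = list(covered, sample_ids))
    p[covered %in% planted$epi_genes, is_high] <-
      p[covered %in% planted$epi_genes, is_high] + cfg$protein_effect_log2
    p
  })
  sheet <- data.frame(sample_id = sample_ids, group = groups,
                      stringsAsFactors = FALSE)
  truth <- list(
    planted_cimp_probes = planted$cimp_probes,
    planted_epimutation_genes = planted$epi_genes,
    true_labels = stats::setNames(groups, sample_ids)
  )
  list(beta = validate_beta_matrix(beta),
       expression = validate_expression_matrix(expression, "RPKM"),
       protein = validate_expression_matrix(protein, "LFQ_log2"),
       sheet = sheet, truth = truth)
}

#' Simulate a knockout clone-by-passage series with planted truth
#'
#' One sample per role (parental, CRISPR control, each clone) and passage.
#' Planted consensus DMPs shift the probe mean by +/- \code{clone_effect}
#' in BOTH clones at ALL passages (hyper on island probes, hypo on open
#' sea, mirroring CIMP-like context bias); clone-private decoys shift in
#' only one clone and passage-private decoys at only one passage, so the
#' consensus rule can be exercised against them. Promoter probes of
#' \code{n_clone_silenced_genes} genes are included among the planted
#' hyper DMPs and those genes' expression is reduced in both clones
#' (fold difference Uniform(0.15, 0.45)); other planted hyper probes that
#' happen to sit in promoters model passenger methylation.
#'
#' When \code{cimp_probes} is supplied (the cohort truth's planted CIMP
#' probe set), \code{clone_overlap_fraction} of the hyper DMPs are drawn
#' from it so the clone-vs-cohort CGI overlap has a known planted value.
#'
#' RNG stream keys: 11 beta, 12 expression, 14 planting.
#'
#' @param cfg a clone-mode [sim_config()].
#' @param manifest manifest from [simulate_manifest()].
#' @param cimp_probes optional character vector of cohort CIMP probes.
#' @return list with \code{beta}, \code{sheet}, \code{expression},
#'   \code{truth}.
#' @export
simulate_clone_series <- function(cfg, manifest, cimp_probes = NULL) {
  stopifnot(inherits(cfg, "sim_config"), cfg$mode == "clone")
  if (cfg$n_passages < 1) {
    stop_typed("epimutr_validation_error", "n_passages must be >= 1")
  }
  roles <- c("parental", "crispr_control",
             paste0("clone", seq_len(cfg$n_clones)))
  design <- expand.grid(role = roles, passage = seq_len(cfg$n_passages),
                        stringsAsFactors = FALSE)
  design$sample_id <- sprintf("%s_P%02d", design$role, design$passage)
  n_s <- nrow(design)
  is_clone_role <- grepl("^clone", design$role)

  island_probes <- manifest$probe_id[manifest$context == "island"]
  sea_probes <- manifest$probe_id[manifest$context == "open_sea"]
  gene_ids <- sort(unique(stats::na.omit(manifest$gene_id)))

  planted <- with_seed(derive_seed(cfg$seed, 14), {
    silenced_genes <- sort(sample(gene_ids, cfg$n_clone_silenced_genes))
    prom_probes <- manifest$probe_id[manifest$promoter_flag &
                                       manifest$gene_id %in% silenced_genes]
    if (length(prom_probes) > cfg$n_clone_hyper) {
      stop_typed("epimutr_validation_error",
                 "n_clone_hyper too small for the silenced-gene promoters")
    }
    pool <- setdiff(island_probes, prom_probes)
    common <- character()
    if (!is.null(cimp_probes)) {
      avail <- setdiff(intersect(cimp_probes, island_probes), prom_probes)
      n_common <- min(length(avail),
                      round(cfg$clone_overlap_fraction * cfg$n_clone_hyper))
      common <- sort(sample(avail, n_common))
      pool <- setdiff(pool, cimp_probes)
    }
    n_rest <- cfg$n_clone_hyper - length(prom_probes) - length(common)
    rest <- sort(sample(pool, max(0, n_rest)))
    hyper <- sort(unique(c(prom_probes, common, rest)))
    hypo <- sort(sample(sea_probes, cfg$n_clone_hypo))
    remaining <- setdiff(manifest$probe_id, c(hyper, hypo))
    clone_private <- sort(sample(remaining, cfg$n_clone_private_decoys))
    remaining <- setdiff(remaining, clone_private)
    passage_private <- sort(sample(remaining, cfg$n_passage_private_decoys))
    list(hyper = hyper, hypo = hypo, common = common,
         silenced_genes = silenced_genes,
         clone_private = clone_private, passage_private = passage_private)
  })

  base_m <- cfg$baseline_means[manifest$context]
  M <- matrix(base_m, nrow = nrow(manifest), ncol = n_s,
              dimnames = list(manifest$probe_id, design$sample_id))
  hyper_idx <- match(planted$hyper, manifest$probe_id)
  hypo_idx <- match(planted$hypo, manifest$probe_id)
  M[hyper_idx, is_clone_role] <- M[hyper_idx, is_clone_role] + cfg$clone_effect
  M[hypo_idx, is_clone_role] <- M[hypo_idx, is_clone_role] - cfg$clone_effect
  # decoys: alternate target clone / passage deterministically
  cp_idx <- match(planted$clone_private, manifest$probe_id)
  for (i in seq_along(cp_idx)) {
    target <- paste0("clone", 1 + (i - 1) %% cfg$n_clones)
    M[cp_idx[i], design$role == target] <-
      M[cp_idx[i], design$role == target] + cfg$clone_effect
  }
  pp_idx <- match(planted$passage_private, manifest$probe_id)
  for (i in seq_along(pp_idx)) {
    target <- 1 + (i - 1) %% cfg$n_passages
    sel <- is_clone_role & design$passage == target
    M[pp_idx[i], sel] <- M[pp_idx[i], sel] + cfg$clone_effect
  }

  beta <- with_seed(derive_seed(cfg$seed, 11), draw_beta(M, cfg$s))
  expression <- with_seed(derive_seed(cfg$seed, 12), {
    base <- stats::rlnorm(length(gene_ids), cfg$expr_meanlog, cfg$expr_sdlog)
    e <- matrix(base, nrow = length(gene_ids), ncol = n_s,
                dimnames = list(gene_ids, design$sample_id)) *
      matrix(stats::rlnorm(length(gene_ids) * n_s, 0, 0.1),
             nrow = length(gene_ids))
    fac <- stats::runif(length(planted$silenced_genes), 0.15, 0.45)
    sel <- match(planted$silenced_genes, gene_ids)
    e[sel, is_clone_role] <- e[sel, is_clone_role] * fac
    e
  })

  sheet <- data.frame(
    sample_id = design$sample_id,
    group = ifelse(is_clone_role, "clone", design$role),
    clone_id = ifelse(is_clone_role, design$role, NA_character_),
    passage = design$passage,
    stringsAsFactors = FALSE
  )
  truth <- list(
    planted_clone_dmps = stats::setNames(
      c(rep("hyper", length(planted$hyper)), rep("hypo", length(planted$hypo))),
      c(planted$hyper, planted$hypo)),
    planted_common = planted$common,
    silenced_genes = planted$silenced_genes,
    clone_private_decoys = planted$clone_private,
    passage_private_decoys = planted$passage_private
  )
  list(beta = validate_beta_matrix(beta), sheet = sheet,
       expression = validate_expression_matrix(expression, "FPKM"),
       truth = truth)
}
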