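#' Materialized configuration for the discovery workflow
#'
#' Every stage threshold is an explicit field with its standard default:
#' top-variance probe count \code{k = 10000}, \code{branches = 4},
#' promoter hypermethylation delta-beta \code{>= 0.3} at FDR
#' \code{<= 0.1}, RNA downregulation FD \code{<= 0.6} at q \code{<= 0.05}
#' with reference median \code{>= 1} RPKM, protein log2 FD \code{<= -2}
#' at q \code{<= 0.05}, silencing cut-off 1 RPKM. Overrides (e.g. from
#' [read_pipeline_config()]) are merged over the defaults so the run log
#' always carries a fully materialized configuration.
#'
#' @param ... named overrides.
#' @param seed master seed for the run.
#' @return named list of class \code{discovery_config}.
#' @export
discovery_config <- function(..., seed = 1) {
  cfg <- list(
    k = 10000, branches = 4,
    meth_delta = 0.3, meth_q = 0.1,
    rna_fd = 0.6, rna_q = 0.05, rna_min_median = 1,
    protein_log2fd = -2, protein_q = 0.05,
    silencing_threshold = 1,
    seed = seed
  )
  overrides <- list(...)
  if (length(overrides) == 1 && is.list(overrides[[1]]) &&
      is.null(names(overrides))) {
    overrides <- overrides[[1]]
  }
  cfg[names(overrides)] <- overrides
  structure(cfg, class = "discovery_config")
}

#' Materialized configuration for the clone workflow
#'
#' Conserved-call delta-beta \code{>= 0.2}, random-pairing permutations,
#' bootstrap iterations for the CGI overlap (10000), expression FD
#' threshold 0.6.
#'
#' @inheritParams discovery_config
#' @return named list of class \code{clone_config}.
#' @export
clone_config <- function(..., seed = 1) {
  cfg <- list(
    delta = 0.2, null_permutations = 100,
    bootstrap_iterations = 10000,
    fd_threshold = 0.6, eps = 0.01,
    seed = seed
  )
  overrides <- list(...)
  if (length(overrides) == 1 && is.list(overrides[[1]]) &&
      is.null(names(overrides))) {
    overrides <- overrides[[1]]
  }
  cfg[names(overrides)] <- overrides
  structure(cfg, class = "clone_config")
}

write_run_log <- function(path, title, config) {
  lines <- c(sprintf("# %s", title),
             sprintf("package: epimutr %s",
                     as.character(utils::packageVersion("epimutr"))),
             "materialized configuration:",
             vapply(names(config), function(nm) {
               sprintf("  %s = %s", nm,
                       paste(format(config[[nm]]), collapse = ","))
             }, character(1)))
  writeLines(lines, path)
}

#' Run the cohort epimutation-discovery workflow
#'
#' Subtype the cohort, aggregate promoter methylation, call promoter
#' hypermethylation (CIMP-high vs non-CIMP), RNA downregulation and
#' (when a protein matrix is given) protein downregulation, intersect
#' into candidate epimutations, and run the silencing recurrence
#' analysis on the candidates. Every intermediate table is written to
#' \code{out_dir} together with a deterministic \code{summary.json} and
#' a log echoing the materialized configuration.
#'
#' @param beta probe x sample beta matrix.
#' @param manifest probe manifest.
#' @param expression gene x sample RPKM/FPKM matrix.
#' @param protein optional gene x sample log2 LFQ matrix.
#' @param config a [discovery_config()].
#' @param out_dir output directory (created if needed).
#' @return the summary list, invisibly.
#' @export
run_discovery <- function(beta, manifest, expression, protein = NULL,
                          config = discovery_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("discovery stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  st <- stage("subtype", cimp_subtype(beta, manifest, k = config$k,
                                      branches = config$branches))
  high <- names(st$label_of)[st$label_of == "CIMP_high"]
  ref <- names(st$label_of)[st$label_of == "non_CIMP"]

  gene_meth <- stage("promoter_aggregation",
                     aggregate_promoter_methylation(beta, manifest,
                                                    "promoter_flag_mean"))
  dm <- stage("differential_methylation",
              differential_methylation(gene_meth, high, ref,
                                       delta_threshold = config$meth_delta,
                                       q_threshold = config$meth_q,
                                       direction = "hyper", level = "cgi"))
  de <- stage("differential_expression",
              differential_expression(expression, high, ref,
                                      fd_threshold = config$rna_fd,
                                      q_threshold = config$rna_q,
                                      min_median_reference = config$rna_min_median))
  dp <- NULL
  if (!is.null(protein)) {
    dp <- stage("differential_protein",
                differential_expression(protein, high, ref,
                                        fd_threshold = 2^config$protein_log2fd,
                                        q_threshold = config$protein_q,
                                        min_median_reference = NULL,
                                        log2_input = TRUE))
  }
  epi <- stage("intersection", intersect_epimutations(
    meth_genes = signature_ids(dm$signature, "hyper"),
    rna_genes = de$gene[de$down],
    protein_genes = if (!is.null(dp)) dp$gene[dp$down] else NULL,
    thresholds = config[c("meth_delta", "meth_q", "rna_fd", "rna_q",
                          "rna_min_median", "protein_log2fd", "protein_q")]))
  candidates <- epi$gene[epi$candidate]
  rec <- NULL
  if (length(candidates)) {
    rec <- stage("recurrence", recurrence_analysis(
      expression[candidates, , drop = FALSE],
      gene_meth[intersect(candidates, rownames(gene_meth)), , drop = FALSE],
      labels = st$label_of,
      silencing_threshold = config$silencing_threshold))
  }

  tsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "NA")
  }
  tsv(data.frame(sample_id = names(st$label_of), branch = st$branch_of,
                 label = st$label_of), "subtype_labels.tsv")
  writeLines(st$selected_probes, file.path(out_dir, "selected_probes.txt"))
  tsv(dm$table, "differential_methylation.tsv")
  tsv(de, "differential_expression.tsv")
  if (!is.null(dp)) tsv(dp, "differential_protein.tsv")
  tsv(as.data.frame(epi), "epimutation_calls.tsv")
  if (!is.null(rec)) tsv(rec$silencing, "recurrence.tsv")
  write_signature(dm$signature, file.path(out_dir, "promoter_hyper_signature.tsv"))

  summary <- list(
    mode = if (is.null(protein)) "two_way" else "three_way",
    n_samples = ncol(beta),
    subtype_counts = as.list(table(st$label_of)),
    n_promoter_hyper = length(dm$signature),
    n_rna_down = sum(de$down),
    n_protein_down = if (is.null(dp)) NULL else sum(dp$down),
    candidate_epimutations = as.list(candidates),
    config = unclass(config)
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_run_log(file.path(out_dir, "run.log"), "cohort epimutation discovery",
                config)
  invisible(summary)
}

#' Run the clone conserved-signature workflow
#'
#' Conserved consensus caller, random-pairing permutation null, CpG
#' context enrichment, CGI mapping, overlap against a supplied cohort
#' CIMP signature with bootstrap significance, and passenger /
#' non-passenger expression integration. All outputs are written to
#' \code{out_dir}.
#'
#' @param beta probe x sample beta matrix (clone design).
#' @param sheet clone-design sample sheet.
#' @param manifest probe manifest.
#' @param expression optional gene x sample linear expression matrix;
#'   per-clone fold differences vs the pooled controls are computed from
#'   it for the integration step.
#' @param cimp_signature optional CGI-level [meth_signature()] to overlap
#'   against.
#' @param config a [clone_config()].
#' @param out_dir output directory.
#' @return the summary list, invisibly.
#' @export
run_clone_analysis <- function(beta, sheet, manifest, expression = NULL,
                               cimp_signature = NULL,
                               config = clone_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("clone stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  sig <- stage("conserved_caller",
               call_conserved_dmps(beta, sheet, delta = config$delta))
  null <- stage("random_pairing_null",
                random_pairing_null(beta, sheet,
                                    n_permutations = config$null_permutations,
                                    seed = derive_seed(config$seed, 21),
                                    delta = config$delta))
  ctx <- if (length(sig)) {
    stage("context_enrichment", context_enrichment(sig, manifest))
  }
  cgi_sig <- stage("cgi_mapping", suppressWarnings(
    map_probes_to_cgis(sig, manifest)))

  overlap <- boot <- NULL
  if (!is.null(cimp_signature) && length(cgi_sig)) {
    universe <- unique(manifest$cgi_id[manifest$context == "island"])
    hyper_a <- meth_signature(signature_ids(cgi_sig, "hyper"), "hyper",
                              "cgi", cgi_sig$universe_size)
    hyper_b <- meth_signature(signature_ids(cimp_signature, "hyper"), "hyper",
                              "cgi", cimp_signature$universe_size)
    overlap <- stage("overlap", overlap_signatures(hyper_a, hyper_b,
                                                   universe = universe))
    if (length(hyper_a)) {
      boot <- stage("bootstrap", bootstrap_overlap_p(
        size_a = length(hyper_a), sig_b = hyper_b, universe = universe,
        observed = overlap$observed,
        n_iterations = config$bootstrap_iterations,
        seed = derive_seed(config$seed, 22)))
    }
  }

  integration <- NULL
  if (!is.null(expression) && length(signature_ids(sig, "hyper"))) {
    controls <- sheet$sample_id[sheet$group %in% c("parental", "crispr_control")]
    clones <- sort(unique(stats::na.omit(sheet$clone_id)))
    fd_tables <- lapply(clones, function(cl) {
      cs <- sheet$sample_id[!is.na(sheet$clone_id) & sheet$clone_id == cl]
      (rowMeans(expression[, cs, drop = FALSE]) + config$eps) /
        (rowMeans(expression[, controls, drop = FALSE]) + config$eps)
    })
    names(fd_tables) <- clones
    integration <- stage("expression_integration", suppressWarnings(
      integrate_expression(sig, manifest, fd_tables,
                           fd_threshold = config$fd_threshold)))
  }

  write_signature(sig, file.path(out_dir, "conserved_signature.tsv"))
  write_signature(cgi_sig, file.path(out_dir, "conserved_signature_cgi.tsv"))
  utils::write.table(data.frame(null_count = null$null_counts),
                     file.path(out_dir, "pairing_null_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(ctx)) {
    utils::write.table(ctx, file.path(out_dir, "context_enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(integration)) {
    utils::write.table(as.data.frame(integration),
                       file.path(out_dir, "expression_integration.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  summary <- list(
    n_called = length(sig),
    n_hyper = length(signature_ids(sig, "hyper")),
    n_hypo = length(signature_ids(sig, "hypo")),
    pairing_null = list(observed = null$observed, p_value = null$p_value,
                        max_null = max(null$null_counts)),
    n_cgi = length(cgi_sig),
    overlap = if (!is.null(overlap))
      list(observed = overlap$observed, fraction_of_a = overlap$fraction_of_a,
           empirical_p = if (!is.null(boot)) boot$empirical_p else NULL),
    integration = if (!is.null(integration))
      list(n_non_passenger = attr(integration, "n_non_passenger"),
           n_genes = attr(integration, "n_genes"),
           fraction = attr(integration, "fraction")),
    config = unclass(config)
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_run_log(file.path(out_dir, "run.log"), "clone conserved-signature analysis",
                config)
  invisible(summary)
}
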