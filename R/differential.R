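#' Aggregate probe betas to gene promoter methylation
#'
#' Per gene and sample, the unweighted mean beta over the rule's probe
#' set, ignoring missing values. Three rules: \code{promoter_flag_mean}
#' averages manifest-flagged promoter probes; \code{tss_window_mean}
#' averages probes with \code{|tss_distance| <= window} (inclusive,
#' default 2000 bp, the +/- 2 kb TSS convention); \code{listed_probes_mean}
#' averages an explicit per-gene probe list (the 7-probe promoter-CGI and
#' 2-TSS-probe averages are instances of this rule).
#'
#' @param beta beta matrix (probes x samples).
#' @param manifest probe manifest.
#' @param rule aggregation rule, see Details.
#' @param window TSS window in bp for \code{tss_window_mean}.
#' @param probe_sets named list gene -> probe ids for
#'   \code{listed_probes_mean}.
#' @return gene x sample matrix; genes with zero eligible probes are
#'   omitted and listed in attribute \code{omitted_genes}.
#' @export
aggregate_promoter_methylation <- function(beta, manifest,
                                           rule = c("promoter_flag_mean",
                                                    "tss_window_mean",
                                                    "listed_probes_mean"),
                                           window = 2000,
                                           probe_sets = NULL) {
  rule <- match.arg(rule)
  if (rule == "listed_probes_mean") {
    if (is.null(probe_sets)) {
      stop_typed("epimutr_validation_error",
                 "listed_probes_mean requires probe_sets")
    }
    sets <- probe_sets
    missing_probes <- setdiff(unlist(sets), rownames(beta))
    if (length(missing_probes)) {
      stop_typed("epimutr_validation_error",
                 "probe(s) absent from matrix: %s",
                 paste(utils::head(missing_probes, 3), collapse = ", "))
    }
  } else {
    keep <- manifest$promoter_flag & !is.na(manifest$gene_id)
    if (rule == "tss_window_mean") {
      keep <- !is.na(manifest$gene_id) & !is.na(manifest$tss_distance) &
        abs(manifest$tss_distance) <= window
    }
    sub <- manifest[keep & manifest$probe_id %in% rownames(beta), ]
    sets <- split(sub$probe_id, sub$gene_id)
  }
  genes <- names(sets)
  usable <- vapply(sets, function(p) length(intersect(p, rownames(beta))) > 0,
                   logical(1))
  omitted <- genes[!usable]
  sets <- sets[usable]
  out <- matrix(NA_real_, nrow = length(sets), ncol = ncol(beta),
                dimnames = list(names(sets), colnames(beta)))
  for (g in names(sets)) {
    probes <- intersect(sets[[g]], rownames(beta))
    out[g, ] <- colMeans(beta[probes, , drop = FALSE], na.rm = TRUE)
  }
  attr(out, "omitted_genes") <- omitted
  out
}

#' Differential methylation between two groups
#'
#' Per feature (probe, CGI or gene row): effect delta-beta =
#' mean(A) - mean(B) over non-missing values, rank-sum p, BH q across all
#' retained features. A feature is dropped when either group has fewer
#' than 2 non-missing values. The signature keeps features with
#' \code{|delta| >= delta_threshold} and \code{q <= q_threshold},
#' directed by the sign of delta and filtered to \code{direction} if not
#' \code{"both"}.
#'
#' @param mat feature x sample numeric matrix of beta values.
#' @param group_a,group_b character vectors of sample ids (columns).
#' @param delta_threshold minimum absolute group-mean difference
#'   (inclusive).
#' @param q_threshold maximum BH q (inclusive).
#' @param direction \code{"both"}, \code{"hyper"} (A above B) or
#'   \code{"hypo"}.
#' @param level signature level tag for the result.
#' @return list with \code{table} (data frame: feature, n_a, n_b,
#'   delta_beta, p_value, q_value, direction) and \code{signature}
#'   (a [meth_signature()] whose universe is the tested features).
#' @export
differential_methylation <- function(mat, group_a, group_b,
                                     delta_threshold, q_threshold,
                                     direction = c("both", "hyper", "hypo"),
                                     level = "probe") {
  direction <- match.arg(direction)
  if (missing(delta_threshold) || missing(q_threshold)) {
    stop_typed("epimutr_validation_error",
               "delta_threshold and q_threshold must be given explicitly")
  }
  idx_a <- match(group_a, colnames(mat))
  idx_b <- match(group_b, colnames(mat))
  if (anyNA(idx_a) || anyNA(idx_b) || !length(idx_a) || !length(idx_b)) {
    stop_typed("epimutr_validation_error",
               "group samples missing from matrix columns")
  }
  n_a <- rowSums(!is.na(mat[, idx_a, drop = FALSE]))
  n_b <- rowSums(!is.na(mat[, idx_b, drop = FALSE]))
  keep <- n_a >= 2 & n_b >= 2
  if (!any(keep)) {
    stop_typed("epimutr_validation_error",
               "no feature has >= 2 usable samples in both groups")
  }
  sub <- mat[keep, , drop = FALSE]
  mean_a <- rowMeans(sub[, idx_a, drop = FALSE], na.rm = TRUE)
  mean_b <- rowMeans(sub[, idx_b, drop = FALSE], na.rm = TRUE)
  delta <- mean_a - mean_b
  rs <- row_rank_sum(sub, idx_a, idx_b)
  q <- bh_adjust(rs$p)
  tab <- data.frame(
    feature = rownames(sub),
    n_a = n_a[keep], n_b = n_b[keep],
    delta_beta = delta,
    p_value = rs$p, q_value = q,
    direction = ifelse(delta >= 0, "hyper", "hypo"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  called <- abs(tab$delta_beta) >= delta_threshold & tab$q_value <= q_threshold
  if (direction != "both") called <- called & tab$direction == direction
  sig <- meth_signature(tab$feature[called], tab$direction[called],
                        level = level, universe_size = nrow(tab))
  list(table = tab, signature = sig)
}

#' Differential expression / protein abundance between two groups
#'
#' For linear-scale matrices (RPKM/FPKM) the effect is the fold
#' difference \code{FD = (mean_A + eps) / (mean_B + eps)} with pseudo-value
#' \code{eps = 0.01}; for \code{log2_input = TRUE} (LFQ log2 intensities)
#' the effect is \code{mean_A - mean_B} interpreted as log2 FD. P-values
#' come from the rank-sum test, q from BH. A gene is called down when
#' \code{q <= q_threshold}, \code{FD <= fd_threshold} (linear scale) and,
#' when \code{min_median_reference} is not \code{NULL}, the reference
#' (group B) median is at least that value.
#'
#' @param expr gene x sample numeric matrix.
#' @param group_a,group_b sample id vectors (A = test, B = reference).
#' @param fd_threshold linear fold-difference call threshold (e.g. 0.6,
#'   or 0.25 for a log2 threshold of -2).
#' @param q_threshold BH q threshold.
#' @param min_median_reference minimum reference-group median (linear
#'   scale), or NULL to skip the filter.
#' @param eps pseudo-value guarding zero means.
#' @param log2_input TRUE when \code{expr} holds log2 intensities.
#' @return data frame: gene, mean_a, mean_b, fd, log2_fd, median_ref,
#'   p_value, q_value, down.
#' @export
differential_expression <- function(expr, group_a, group_b,
                                    fd_threshold, q_threshold,
                                    min_median_reference = 1,
                                    eps = 0.01, log2_input = FALSE) {
  if (!log2_input && any(expr < 0, na.rm = TRUE)) {
    stop_typed("epimutr_validation_error", "negative expression values")
  }
  idx_a <- match(group_a, colnames(expr))
  idx_b <- match(group_b, colnames(expr))
  if (anyNA(idx_a) || anyNA(idx_b)) {
    stop_typed("epimutr_validation_error", "group samples missing from matrix")
  }
  mean_a <- rowMeans(expr[, idx_a, drop = FALSE], na.rm = TRUE)
  mean_b <- rowMeans(expr[, idx_b, drop = FALSE], na.rm = TRUE)
  if (log2_input) {
    log2_fd <- mean_a - mean_b
    fd <- 2^log2_fd
    median_ref <- rep(NA_real_, nrow(expr))
  } else {
    fd <- (mean_a + eps) / (mean_b + eps)
    log2_fd <- log2(fd)
    median_ref <- apply(expr[, idx_b, drop = FALSE], 1, stats::median,
                        na.rm = TRUE)
  }
  rs <- row_rank_sum(expr, idx_a, idx_b)
  q <- bh_adjust(rs$p)
  down <- q <= q_threshold & fd <= fd_threshold
  if (!is.null(min_median_reference) && !log2_input) {
    down <- down & median_ref >= min_median_reference
  }
  data.frame(
    gene = rownames(expr),
    mean_a = mean_a, mean_b = mean_b,
    fd = fd, log2_fd = log2_fd, median_ref = median_ref,
    p_value = rs$p, q_value = q, down = down,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Tri-omic (or two-way) epimutation intersection
#'
#' A candidate epimutation is a gene that is promoter hypermethylated AND
#' RNA downregulated AND (when a protein set is provided) protein
#' downregulated. Emits per-gene pass booleans over the union of inputs.
#'
#' @param meth_genes genes passing the promoter hypermethylation filter.
#' @param rna_genes genes called down at RNA level.
#' @param protein_genes optional genes called down at protein level;
#'   omit for two-way intersection.
#' @param thresholds optional named list recording the thresholds used
#'   (stored as an attribute for provenance).
#' @return data frame of class \code{epimutation_calls} with columns
#'   gene, meth_pass, rna_pass, protein_pass, candidate.
#' @export
intersect_epimutations <- function(meth_genes, rna_genes,
                                   protein_genes = NULL, thresholds = NULL) {
  if (is.null(meth_genes) || is.null(rna_genes)) {
    stop_typed("epimutr_validation_error",
               "need methylation and RNA gene sets (protein optional)")
  }
  three_way <- !is.null(protein_genes)
  universe <- sort(unique(c(meth_genes, rna_genes, protein_genes)))
  out <- data.frame(
    gene = universe,
    meth_pass = universe %in% meth_genes,
    rna_pass = universe %in% rna_genes,
    protein_pass = if (three_way) universe %in% protein_genes else NA,
    stringsAsFactors = FALSE
  )
  out$candidate <- out$meth_pass & out$rna_pass &
    (if (three_way) out$protein_pass else TRUE)
  attr(out, "mode") <- if (three_way) "three_way" else "two_way"
  attr(out, "thresholds") <- thresholds
  class(out) <- c("epimutation_calls", "data.frame")
  out
}

#' @export
print.epimutation_calls <- function(x, ...) {
  cat(sprintf("<epimutation_calls> %s: %d candidate(s) of %d gene(s) tested\n",
              attr(x, "mode"), sum(x$candidate), nrow(x)))
  if (sum(x$candidate)) {
    cat(" ", paste(x$gene[x$candidate], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Silencing recurrence and methylation-expression coupling
#'
#' Per gene and subtype, the fraction of samples with expression strictly
#' below \code{silencing_threshold} (RPKM < 1 is "silenced"); fractions
#' are reported as percentages truncated to 2 decimals. Per gene, the
#' Spearman correlation (midrank ties, t-approximation p) between
#' promoter methylation and expression across all shared samples.
#'
#' @param expr gene x sample expression matrix (linear scale).
#' @param meth_gene_matrix gene x sample promoter methylation matrix, or
#'   NULL to skip the correlation.
#' @param labels named character vector sample -> subtype label covering
#'   every expression sample.
#' @param silencing_threshold strict upper bound for "silenced".
#' @return list of class \code{recurrence_result}: \code{silencing}
#'   (gene, group, silenced, total, percent) and \code{correlation}
#'   (gene, rho, p_value).
#' @export
recurrence_analysis <- function(expr, meth_gene_matrix = NULL, labels,
                                silencing_threshold = 1) {
  if (!all(colnames(expr) %in% names(labels))) {
    stop_typed("epimutr_validation_error",
               "labels must cover all expression samples")
  }
  lab <- labels[colnames(expr)]
  groups <- unique(lab)
  rows <- list()
  if (nrow(expr) == 0) {
    stop_typed("epimutr_validation_error", "expression matrix has no genes")
  }
  for (g in groups) {
    sel <- which(lab == g)
    if (!length(sel)) {
      warning(sprintf("subtype '%s' has zero samples", g))
      next
    }
    silenced <- rowSums(expr[, sel, drop = FALSE] < silencing_threshold,
                        na.rm = TRUE)
    total <- rowSums(!is.na(expr[, sel, drop = FALSE]))
    rows[[g]] <- data.frame(
      gene = rownames(expr), group = g,
      silenced = silenced, total = total,
      percent = ifelse(total > 0, trunc_pct(silenced / total), NA_real_),
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  silencing <- do.call(rbind, rows)
  rownames(silencing) <- NULL
  correlation <- NULL
  if (!is.null(meth_gene_matrix)) {
    shared_genes <- intersect(rownames(expr), rownames(meth_gene_matrix))
    shared_samples <- intersect(colnames(expr), colnames(meth_gene_matrix))
    correlation <- do.call(rbind, lapply(shared_genes, function(g) {
      rp <- spearman_rho_p(meth_gene_matrix[g, shared_samples],
                           expr[g, shared_samples])
      data.frame(gene = g, rho = rp[["rho"]], p_value = rp[["p"]],
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(silencing = silencing, correlation = correlation,
                 silencing_threshold = silencing_threshold),
            class = "recurrence_result")
}

#' @export
print.recurrence_result <- function(x, ...) {
  cat(sprintf("<recurrence_result> silencing at expression < %g\n",
              x$silencing_threshold))
  print(x$silencing, row.names = FALSE)
  if (!is.null(x$correlation)) {
    cat("promoter methylation vs expression (Spearman):\n")
    print(x$correlation, row.names = FALSE)
  }
  invisible(x)
}
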