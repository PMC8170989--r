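#' Select the most variable CpG-island probes
#'
#' Eligible probes are island-context probes not on excluded chromosomes,
#' not carrying the manifest exclusion flag (SNP-overlapping probes in
#' real annotation), and with no missing beta value. They are ranked by
#' sample standard deviation (n - 1 denominator) in decreasing order,
#' ties broken by probe id ascending, and the first \code{k} returned.
#'
#' @param beta probe x sample beta matrix.
#' @param manifest probe manifest.
#' @param k number of probes to keep (default 10000).
#' @param exclude_chroms chromosomes to drop (default sex chromosomes).
#' @param exclude_flag name of a logical manifest column flagging probes
#'   to drop, or NULL.
#' @return character vector of probe ids, ranked.
#' @export
select_top_variable_cgi_probes <- function(beta, manifest, k = 10000,
                                           exclude_chroms = c("chrX", "chrY"),
                                           exclude_flag = "exclude_flag") {
  stopifnot(k >= 1)
  keep <- manifest$context == "island" & !(manifest$chrom %in% exclude_chroms)
  if (!is.null(exclude_flag) && exclude_flag %in% names(manifest)) {
    keep <- keep & !manifest[[exclude_flag]]
  }
  ids <- intersect(manifest$probe_id[keep], rownames(beta))
  sub <- beta[ids, , drop = FALSE]
  complete <- rowSums(is.na(sub)) == 0
  sub <- sub[complete, , drop = FALSE]
  if (nrow(sub) == 0) {
    stop_typed("epimutr_validation_error",
               "no eligible island probe with complete data")
  }
  n <- ncol(sub)
  mu <- rowMeans(sub)
  sd_row <- sqrt(pmax(0, (rowSums(sub^2) - n * mu^2) / (n - 1)))
  ord <- order(-sd_row, rownames(sub))
  rownames(sub)[ord][seq_len(min(k, nrow(sub)))]
}

#' Cluster samples by Ward linkage on Euclidean distances
#'
#' Agglomerative clustering of the samples over the selected probe
#' vectors (Ward's minimum-variance criterion, \code{hclust} method
#' \code{ward.D2}), with the tree cut into exactly \code{n_branches}
#' flat branches.
#'
#' @param beta_subset selected-probe x sample matrix, no missing values.
#' @param n_branches number of flat branches B (2 <= B <= n samples).
#' @return list: \code{branch_of} (named integer vector sample ->
#'   branch) and \code{linkage} (the \code{hclust} object holding the
#'   full merge history and heights).
#' @export
cluster_samples <- function(beta_subset, n_branches = 4) {
  if (n_branches < 2) {
    stop_typed("epimutr_validation_error", "n_branches must be >= 2")
  }
  if (n_branches > ncol(beta_subset)) {
    stop_typed("epimutr_validation_error", "more branches than samples")
  }
  if (anyNA(beta_subset)) {
    stop_typed("epimutr_validation_error",
               "missing values in clustering input")
  }
  d <- stats::dist(t(beta_subset), method = "euclidean")
  hc <- stats::hclust(d, method = "ward.D2")
  branch <- stats::cutree(hc, k = n_branches)
  list(branch_of = branch, linkage = hc)
}

#' Assign CIMP labels to dendrogram branches
#'
#' Branches are ordered by their mean beta over the selected probes; the
#' highest-mean branch becomes CIMP_high, the lowest non_CIMP, and the
#' remaining branch(es) CIMP_low (with 4 branches this reproduces the
#' 1 high / 2 low / 1 non assignment; 3 branches is the degenerate
#' 1/1/1 mode). Exactly tied branch means are broken toward the lower
#' branch index for the higher label, with a warning.
#'
#' @param branch_of named integer vector sample -> branch.
#' @param beta_subset selected-probe x sample matrix.
#' @return named character vector sample -> label.
#' @export
assign_cimp_labels <- function(branch_of, beta_subset) {
  branches <- sort(unique(branch_of))
  B <- length(branches)
  if (!B %in% c(3, 4)) {
    stop_typed("epimutr_validation_error",
               "label assignment needs 3 or 4 branches, got %d", B)
  }
  means <- vapply(branches, function(b) {
    mean(beta_subset[, names(branch_of)[branch_of == b], drop = FALSE])
  }, numeric(1))
  if (anyDuplicated(means)) {
    warning("tied branch means; tie broken toward lower branch index")
  }
  ord <- order(-means, branches)
  rank_labels <- if (B == 4) {
    c("CIMP_high", "CIMP_low", "CIMP_low", "non_CIMP")
  } else {
    c("CIMP_high", "CIMP_low", "non_CIMP")
  }
  label_of_branch <- stats::setNames(rank_labels, branches[ord])
  stats::setNames(unname(label_of_branch[as.character(branch_of)]),
                  names(branch_of))
}

#' CIMP subtyping from a beta matrix
#'
#' The full subtyping procedure: select the top-\code{k} most variable
#' CpG-island probes, Ward/Euclidean cluster the samples, cut into
#' \code{branches} branches, and label branches CIMP_high / CIMP_low /
#' non_CIMP by mean methylation.
#'
#' @inheritParams select_top_variable_cgi_probes
#' @param branches number of dendrogram branches to cut (default 4).
#' @return object of class \code{cimp_subtype}: selected_probes,
#'   branch_of, label_of, branch_means, linkage.
#' @export
cimp_subtype <- function(beta, manifest, k = 10000, branches = 4,
                         exclude_chroms = c("chrX", "chrY"),
                         exclude_flag = "exclude_flag") {
  probes <- select_top_variable_cgi_probes(beta, manifest, k,
                                           exclude_chroms, exclude_flag)
  sub <- beta[probes, , drop = FALSE]
  cl <- cluster_samples(sub, branches)
  labels <- assign_cimp_labels(cl$branch_of, sub)
  branch_means <- vapply(sort(unique(cl$branch_of)), function(b) {
    mean(sub[, names(cl$branch_of)[cl$branch_of == b], drop = FALSE])
  }, numeric(1))
  structure(list(selected_probes = probes,
                 branch_of = cl$branch_of,
                 label_of = labels,
                 branch_means = branch_means,
                 linkage = cl$linkage,
                 k = k, branches = branches),
            class = "cimp_subtype")
}

#' @export
print.cimp_subtype <- function(x, ...) {
  tab <- table(factor(x$label_of, levels = c("CIMP_high", "CIMP_low", "non_CIMP")))
  cat(sprintf("<cimp_subtype> %d samples on %d probes, %d branches\n",
              length(x$label_of), length(x$selected_probes), x$branches))
  print(tab)
  invisible(x)
}

#' @export
summary.cimp_subtype <- function(object, ...) {
  cat("CIMP subtyping\n")
  cat(sprintf("  selected probes: %d (top-variance CpG island)\n",
              length(object$selected_probes)))
  cat(sprintf("  branch mean beta: %s\n",
              paste(sprintf("%d=%.3f", seq_along(object$branch_means),
                            object$branch_means), collapse = ", ")))
  for (lab in c("CIMP_high", "CIMP_low", "non_CIMP")) {
    ids <- names(object$label_of)[object$label_of == lab]
    cat(sprintf("  %s (%d): %s\n", lab, length(ids),
                paste(ids, collapse = ", ")))
  }
  invisible(object)
}

#' @export
plot.cimp_subtype <- function(x, ...) {
  plot(x$linkage, main = "CIMP subtyping (Ward/Euclidean)",
       xlab = "", sub = "", ...)
  invisible(x)
}
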