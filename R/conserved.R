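# Internal: validate a clone-design sheet and list the usable passages
# with their control / clone sample columns.
clone_design <- function(beta, sheet, require_both_controls = TRUE) {
  needed <- c("sample_id", "group", "clone_id", "passage")
  if (!all(needed %in% names(sheet))) {
    stop_typed("epimutr_validation_error",
               "clone design sheet needs columns %s",
               paste(needed, collapse = ", "))
  }
  if (!all(sheet$sample_id %in% colnames(beta))) {
    stop_typed("epimutr_validation_error",
               "sheet sample(s) missing from beta matrix")
  }
  clones <- sort(unique(stats::na.omit(sheet$clone_id[sheet$group == "clone"])))
  passages <- sort(unique(sheet$passage))
  usable <- list()
  for (p in passages) {
    at_p <- sheet[sheet$passage == p, ]
    controls <- at_p$sample_id[at_p$group %in% c("parental", "crispr_control")]
    if (require_both_controls) {
      has_controls <- all(c("parental", "crispr_control") %in% at_p$group)
    } else {
      has_controls <- length(controls) >= 1
    }
    clone_samples <- lapply(clones, function(cl) {
      at_p$sample_id[at_p$group == "clone" & at_p$clone_id == cl]
    })
    names(clone_samples) <- clones
    has_clones <- length(clone_samples) >= 1 &&
      all(lengths(clone_samples) >= 1)
    if (has_controls && has_clones) {
      usable[[as.character(p)]] <- list(controls = controls,
                                        clones = clone_samples)
    } else {
      warning(sprintf("passage %s skipped: incomplete design", p))
    }
  }
  if (!length(usable)) {
    stop_typed("epimutr_validation_error", "no usable passage in clone design")
  }
  list(clones = clones, passages = usable)
}

#' Call the conserved clone-consensus differential methylation signature
#'
#' A probe enters the signature when, for every retained passage and every
#' (clone sample, control sample) pair at that passage, the difference
#' clone beta minus control beta satisfies \code{|d| >= delta} with one
#' common sign across all comparisons (hyper for positive). Controls are
#' both the parental and the CRISPR control line at the matched passage.
#' Passages with an incomplete design are skipped with a warning. Probes
#' with a missing value in any required sample are not callable and are
#' excluded from the signature universe (counted in attribute
#' \code{n_not_callable}).
#'
#' @param beta probe x sample beta matrix.
#' @param sheet clone-design sample sheet (columns sample_id, group,
#'   clone_id, passage; groups parental / crispr_control / clone).
#' @param delta minimum beta-value difference (default 0.2).
#' @param strict use \code{>} instead of \code{>=} for the threshold.
#' @param require_both_clones all clones must satisfy the rule (TRUE) or
#'   any one clone suffices (FALSE).
#' @param require_all_passages all retained passages must satisfy the
#'   rule (TRUE) or any one passage suffices (FALSE).
#' @param require_both_controls both parental and CRISPR control must be
#'   present at a passage for it to be retained.
#' @param require_sign_consistency demand one common sign across every
#'   comparison; when FALSE only \code{|d| >= delta} is required and the
#'   direction is taken from the mean difference.
#' @return probe-level [meth_signature()]; universe = callable probes.
#' @export
call_conserved_dmps <- function(beta, sheet, delta = 0.2, strict = FALSE,
                                require_both_clones = TRUE,
                                require_all_passages = TRUE,
                                require_both_controls = TRUE,
                                require_sign_consistency = TRUE) {
  if (delta <= 0 || delta >= 1) {
    stop_typed("epimutr_validation_error", "delta must lie in (0, 1)")
  }
  design <- clone_design(beta, sheet, require_both_controls)
  cmp <- function(d, thr) if (strict) d > thr else d >= thr

  used_samples <- unique(unlist(lapply(design$passages, function(p) {
    c(p$controls, unlist(p$clones))
  })))
  callable <- rowSums(is.na(beta[, used_samples, drop = FALSE])) == 0
  n_probes <- nrow(beta)
  sub <- beta[callable, , drop = FALSE]

  # per (passage, clone): all pairwise clone-vs-control differences
  agg2 <- function(m, all_of) if (all_of) rowSums(m) == ncol(m) else rowSums(m) > 0
  hyper_pc <- list(); hypo_pc <- list(); abs_pc <- list()
  mean_d <- 0; n_pairs <- 0
  for (p in design$passages) {
    for (cl in names(p$clones)) {
      hy <- hp <- ab <- NULL
      for (cs in p$clones[[cl]]) {
        for (ks in p$controls) {
          d <- sub[, cs] - sub[, ks]
          mean_d <- mean_d + d; n_pairs <- n_pairs + 1
          hy <- cbind(hy, cmp(d, delta))
          hp <- cbind(hp, cmp(-d, delta))
          ab <- cbind(ab, cmp(abs(d), delta))
        }
      }
      key <- paste(cl, length(hyper_pc), sep = "_")
      hyper_pc[[key]] <- list(clone = cl, ok = agg2(hy, TRUE))
      hypo_pc[[key]] <- list(clone = cl, ok = agg2(hp, TRUE))
      abs_pc[[key]] <- list(clone = cl, ok = agg2(ab, TRUE))
    }
  }

  combine <- function(pc_list) {
    # first across clones within passage groups, then across passages
    per_clone <- split(pc_list, vapply(pc_list, `[[`, "", "clone"))
    # pc_list entries are (passage x clone); regroup by passage position
    n_pass <- length(design$passages)
    n_cl <- length(design$clones)
    mat <- do.call(cbind, lapply(pc_list, `[[`, "ok"))
    # columns are ordered passage-major then clone; combine clones first
    res <- NULL
    for (i in seq_len(n_pass)) {
      cols <- ((i - 1) * n_cl + 1):(i * n_cl)
      at_p <- mat[, cols, drop = FALSE]
      pass_ok <- agg2(at_p, require_both_clones)
      res <- cbind(res, pass_ok)
    }
    agg2(res, require_all_passages)
  }

  if (require_sign_consistency) {
    hyper <- combine(hyper_pc)
    hypo <- combine(hypo_pc)
    conflict <- hyper & hypo
    hyper[conflict] <- FALSE
    hypo[conflict] <- FALSE
  } else {
    called <- combine(abs_pc)
    dir_pos <- mean_d / n_pairs > 0
    hyper <- called & dir_pos
    hypo <- called & !dir_pos
  }
  ids <- c(rownames(sub)[hyper], rownames(sub)[hypo])
  dirs <- c(rep("hyper", sum(hyper)), rep("hypo", sum(hypo)))
  ord <- order(match(ids, rownames(beta)))
  sig <- meth_signature(ids[ord], dirs[ord], level = "probe",
                        universe_size = nrow(sub))
  attr(sig, "n_not_callable") <- n_probes - nrow(sub)
  attr(sig, "passages_used") <- names(design$passages)
  attr(sig, "delta") <- delta
  sig
}

#' Random-pairing permutation null for the conserved caller
#'
#' For each permutation, the role labels (parental, CRISPR control,
#' clone identities) are shuffled uniformly among the samples of each
#' passage (redrawing any per-passage identity assignment), the consensus
#' caller is rerun, and the called-probe count recorded. The empirical p
#' uses the add-one convention \code{(1 + #(null >= observed)) /
#' (1 + n_permutations)} so it is never zero.
#'
#' @inheritParams call_conserved_dmps
#' @param n_permutations number of random pairings (>= 1).
#' @param seed RNG seed for the permutation stream.
#' @param ... further arguments passed to [call_conserved_dmps()].
#' @return object of class \code{pairing_null}: observed count, null
#'   counts, empirical p, scheme descriptor, seed.
#' @export
random_pairing_null <- function(beta, sheet, n_permutations, seed,
                                delta = 0.2, ...) {
  if (n_permutations < 1) {
    stop_typed("epimutr_validation_error", "n_permutations must be >= 1")
  }
  passages <- unique(sheet$passage)
  if (all(vapply(passages, function(p) sum(sheet$passage == p), 0L) < 2)) {
    stop_typed("epimutr_validation_error",
               "fewer than 2 distinct assignments possible")
  }
  observed <- length(suppressWarnings(
    call_conserved_dmps(beta, sheet, delta = delta, ...)))
  null_counts <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      perm_sheet <- sheet
      for (p in passages) {
        rows <- which(sheet$passage == p)
        if (length(rows) < 2) next
        repeat {
          ord <- sample(length(rows))
          if (!all(ord == seq_along(rows))) break
        }
        perm_sheet$group[rows] <- sheet$group[rows][ord]
        perm_sheet$clone_id[rows] <- sheet$clone_id[rows][ord]
      }
      length(suppressWarnings(
        call_conserved_dmps(beta, perm_sheet, delta = delta, ...)))
    }, integer(1))
  })
  p <- (1 + sum(null_counts >= observed)) / (1 + n_permutations)
  structure(list(observed = observed, null_counts = null_counts,
                 p_value = p, n_permutations = n_permutations,
                 scheme = "within-passage role shuffle, identity excluded",
                 seed = seed),
            class = "pairing_null")
}

#' @export
print.pairing_null <- function(x, ...) {
  cat(sprintf(
    "<pairing_null> observed %d called probes; null max %d over %d pairings; empirical p = %.4g\n",
    x$observed, max(x$null_counts), x$n_permutations, x$p_value))
  invisible(x)
}

#' Partition hypermethylated genes into passenger / non-passenger
#'
#' Genes carrying at least one hypermethylated promoter probe from the
#' conserved signature are non-passenger when their expression fold
#' difference is at or below \code{fd_threshold} in EVERY clone, and
#' passenger otherwise.
#'
#' @param sig probe-level [meth_signature()] (hyper entries used).
#' @param manifest probe manifest with promoter annotation.
#' @param fd_tables named list (one element per clone) of named numeric
#'   vectors gene -> linear fold difference, or data frames with columns
#'   \code{gene} (or \code{gene_id}) and \code{fd}.
#' @param fd_threshold linear FD cut-off (default 0.6).
#' @return data frame of class \code{expression_integration}: gene, one
#'   fd column per clone, class; attributes carry the counts.
#' @export
integrate_expression <- function(sig, manifest, fd_tables, fd_threshold = 0.6) {
  stopifnot(inherits(sig, "meth_signature"))
  as_vec <- function(x) {
    if (is.data.frame(x)) {
      gene_col <- intersect(c("gene", "gene_id"), names(x))[1]
      stats::setNames(x$fd, x[[gene_col]])
    } else x
  }
  tabs <- lapply(fd_tables, as_vec)
  common <- Reduce(intersect, lapply(tabs, names))
  if (!length(common)) {
    stop_typed("epimutr_validation_error",
               "clone FD tables have disjoint gene spaces")
  }
  hyper <- signature_ids(sig, "hyper")
  genes <- sort(unique(manifest$gene_id[manifest$promoter_flag &
                                          manifest$probe_id %in% hyper]))
  dropped <- setdiff(genes, common)
  if (length(dropped)) {
    warning(sprintf("%d hypermethylated gene(s) missing from FD tables",
                    length(dropped)))
  }
  genes <- intersect(genes, common)
  fd_mat <- vapply(tabs, function(v) unname(v[genes]), numeric(length(genes)))
  if (length(genes) == 1) fd_mat <- matrix(fd_mat, nrow = 1)
  non_passenger <- apply(fd_mat <= fd_threshold, 1, all)
  out <- data.frame(gene = genes, fd_mat,
                    class = ifelse(non_passenger, "non_passenger", "passenger"),
                    stringsAsFactors = FALSE, row.names = NULL)
  names(out)[seq_along(tabs) + 1] <- paste0("fd_", names(tabs))
  attr(out, "n_non_passenger") <- sum(non_passenger)
  attr(out, "n_genes") <- length(genes)
  attr(out, "fraction") <- if (length(genes)) sum(non_passenger) / length(genes) else NA_real_
  class(out) <- c("expression_integration", "data.frame")
  out
}

#' @export
print.expression_integration <- function(x, ...) {
  n <- attr(x, "n_genes"); k <- attr(x, "n_non_passenger")
  cat(sprintf("<expression_integration> %d/%d genes non-passenger (%.1f%%)\n",
              k, n, 100 * k / max(1, n)))
  invisible(x)
}
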