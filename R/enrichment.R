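#' Map a probe signature to CGI level
#'
#' A CGI enters the output when at least \code{min_probes} signature
#' probes map to it through the manifest's island annotation; its
#' direction is the majority direction of those probes (ties are dropped
#' with a warning). The output universe is the number of CGIs covered by
#' at least one island probe of the manifest.
#'
#' @param sig probe-level [meth_signature()].
#' @param manifest probe manifest.
#' @param min_probes minimum probe support per CGI (default 1).
#' @return CGI-level [meth_signature()].
#' @export
map_probes_to_cgis <- function(sig, manifest, min_probes = 1) {
  stopifnot(inherits(sig, "meth_signature"), sig$level == "probe")
  island <- manifest[manifest$context == "island", ]
  universe <- length(unique(island$cgi_id))
  idx <- match(names(sig$entries), island$probe_id)
  in_island <- !is.na(idx)
  if (!any(in_island)) {
    warning("signature contains no island probes; empty CGI signature")
    return(meth_signature(character(), character(), "cgi", universe))
  }
  cgi <- island$cgi_id[idx[in_island]]
  dir <- sig$entries[in_island]
  by_cgi <- split(dir, cgi)
  by_cgi <- by_cgi[lengths(by_cgi) >= min_probes]
  n_hyper <- vapply(by_cgi, function(d) sum(d == "hyper"), integer(1))
  n_hypo <- lengths(by_cgi) - n_hyper
  tie <- n_hyper == n_hypo
  if (any(tie)) {
    warning(sprintf("%d CGI(s) with tied directions dropped", sum(tie)))
  }
  keep <- !tie
  meth_signature(names(by_cgi)[keep],
                 ifelse(n_hyper[keep] > n_hypo[keep], "hyper", "hypo"),
                 level = "cgi", universe_size = universe)
}

#' Overlap between two signatures
#'
#' Counts ids present in both signatures, requiring equal direction when
#' \code{direction_matched}. The fraction is relative to signature A.
#'
#' @param sig_a,sig_b [meth_signature()] objects at the same level.
#' @param universe optional character vector of testable ids; every
#'   signature id must belong to it.
#' @param direction_matched require hyper/hypo agreement (default TRUE).
#' @return list: observed, fraction_of_a, size_a, size_b.
#' @export
overlap_signatures <- function(sig_a, sig_b, universe = NULL,
                               direction_matched = TRUE) {
  stopifnot(inherits(sig_a, "meth_signature"),
            inherits(sig_b, "meth_signature"))
  if (!is.null(universe)) {
    outside <- setdiff(c(names(sig_a$entries), names(sig_b$entries)), universe)
    if (length(outside)) {
      stop_typed("epimutr_validation_error",
                 "signature id(s) outside universe (e.g. %s)", outside[1])
    }
  }
  shared <- intersect(names(sig_a$entries), names(sig_b$entries))
  if (direction_matched) {
    shared <- shared[sig_a$entries[shared] == sig_b$entries[shared]]
  }
  list(observed = length(shared),
       fraction_of_a = if (length(sig_a$entries))
         length(shared) / length(sig_a$entries) else NA_real_,
       size_a = length(sig_a$entries),
       size_b = length(sig_b$entries),
       shared_ids = shared)
}

#' Bootstrap significance of a signature overlap
#'
#' Each iteration draws \code{size_a} ids uniformly without replacement
#' from the universe and counts the overlap with signature B; the
#' empirical p is \code{(1 + #(null >= observed)) / (1 + n_iterations)}.
#' Resampling A-sized draws against a fixed B is the conservative
#' standard construction; pass B's ids as \code{sig_b} to resample the
#' other side instead.
#'
#' @param size_a size of the signature being resampled.
#' @param sig_b a [meth_signature()] or character vector of ids.
#' @param universe character vector of testable ids.
#' @param observed the observed overlap count.
#' @param n_iterations bootstrap iterations (>= 1).
#' @param seed RNG seed.
#' @return object of class \code{overlap_test} with the null counts.
#' @export
bootstrap_overlap_p <- function(size_a, sig_b, universe, observed,
                                n_iterations = 10000, seed) {
  ids_b <- if (inherits(sig_b, "meth_signature")) names(sig_b$entries) else sig_b
  U <- length(universe)
  if (size_a > U) {
    stop_typed("epimutr_validation_error", "size_a exceeds universe size")
  }
  if (!all(ids_b %in% universe)) {
    stop_typed("epimutr_validation_error", "sig_b ids outside universe")
  }
  if (observed > min(size_a, length(ids_b))) {
    stop_typed("epimutr_validation_error",
               "observed overlap exceeds min(size_a, |B|)")
  }
  if (n_iterations < 1) {
    stop_typed("epimutr_validation_error", "n_iterations must be >= 1")
  }
  in_b <- universe %in% ids_b
  null_counts <- with_seed(seed, {
    vapply(seq_len(n_iterations), function(i) {
      sum(in_b[sample.int(U, size_a)])
    }, integer(1))
  })
  p <- (1 + sum(null_counts >= observed)) / (1 + n_iterations)
  structure(list(observed = observed, size_a = size_a,
                 size_b = length(ids_b), universe_size = U,
                 n_iterations = n_iterations, null_counts = null_counts,
                 empirical_p = p, seed = seed),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf(
    "<overlap_test> observed %d (|A|=%d, |B|=%d, U=%d); empirical p = %.4g (%d iterations)\n",
    x$observed, x$size_a, x$size_b, x$universe_size, x$empirical_p,
    x$n_iterations))
  invisible(x)
}

#' CpG-context binomial enrichment of a signature
#'
#' For the hyper and hypo subsets separately and each of the four CpG
#' contexts, tests the signature's context proportion k/n against the
#' background proportion p0 with exact binomial tails; both one-sided
#' tails are reported so either reading of a "binomial test" is
#' reproducible. The \code{annotated} background takes p0 from the
#' manifest's own context distribution.
#'
#' @param sig probe-level [meth_signature()] (non-empty).
#' @param manifest probe manifest.
#' @param background \code{"annotated"} or \code{"custom"}.
#' @param custom_proportions named proportions over the four contexts
#'   (must sum to 1) when \code{background = "custom"}.
#' @return data frame: subset, context, k, n, proportion, background,
#'   p_greater, p_less.
#' @export
context_enrichment <- function(sig, manifest,
                               background = c("annotated", "custom"),
                               custom_proportions = NULL) {
  stopifnot(inherits(sig, "meth_signature"))
  background <- match.arg(background)
  if (!length(sig$entries)) {
    stop_typed("epimutr_validation_error", "signature is empty")
  }
  if (background == "annotated") {
    tab <- table(factor(manifest$context, levels = CPG_CONTEXTS))
    p0 <- as.numeric(tab) / sum(tab)
    names(p0) <- CPG_CONTEXTS
  } else {
    p0 <- custom_proportions[CPG_CONTEXTS]
    if (abs(sum(p0) - 1) > 1e-9 || anyNA(p0)) {
      stop_typed("epimutr_validation_error",
                 "custom background proportions must cover the four contexts and sum to 1")
    }
  }
  ctx_of <- stats::setNames(manifest$context, manifest$probe_id)
  rows <- list()
  for (subset in c("hyper", "hypo")) {
    ids <- signature_ids(sig, subset)
    if (!length(ids)) next
    ctx <- factor(ctx_of[ids], levels = CPG_CONTEXTS)
    n <- length(ids)
    k <- table(ctx)
    for (cc in CPG_CONTEXTS) {
      kk <- k[[cc]]
      rows[[paste(subset, cc)]] <- data.frame(
        subset = subset, context = cc, k = kk, n = n,
        proportion = kk / n, background = p0[[cc]],
        p_greater = stats::pbinom(kk - 1, n, p0[[cc]], lower.tail = FALSE),
        p_less = stats::pbinom(kk, n, p0[[cc]]),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Hypergeometric gene-set overlap
#'
#' For each set, k is the size of the intersection with the query and
#' \code{p = P(X >= k)} with X hypergeometric(universe, set, query); q is
#' BH across sets. Repeated query genes are de-duplicated with a warning.
#'
#' @param query_genes character vector of query genes.
#' @param gene_sets named list of gene sets (e.g. from [read_gmt()]).
#' @param universe_size total number of genes the query and sets are
#'   drawn from; must be at least the query and the largest set.
#' @return data frame: set, set_size, k, p_value, q_value.
#' @export
geneset_overlap <- function(query_genes, gene_sets, universe_size) {
  if (anyDuplicated(query_genes)) {
    warning("duplicated query gene(s) de-duplicated")
    query_genes <- unique(query_genes)
  }
  if (universe_size < length(query_genes) ||
      universe_size < max(lengths(gene_sets))) {
    stop_typed("epimutr_validation_error",
               "universe_size smaller than query or largest set")
  }
  nq <- length(query_genes)
  k <- vapply(gene_sets, function(s) length(intersect(query_genes, s)),
              integer(1))
  m <- lengths(gene_sets)
  p <- stats::phyper(k - 1, m, universe_size - m, nq, lower.tail = FALSE)
  data.frame(set = names(gene_sets), set_size = unname(m), k = unname(k),
             p_value = unname(p), q_value = bh_adjust(unname(p)),
             stringsAsFactors = FALSE, row.names = NULL)
}
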