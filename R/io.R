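#' @keywords internal
"_PACKAGE"

CPG_CONTEXTS <- c("island", "shore", "shelf", "open_sea")

# Dialect table for array-annotation context tokens. Applied only in the
# reader so the internal enum stays clean. Matching is case-insensitive.
CONTEXT_DIALECT <- c(
  "island"    = "island",
  "n_shore"   = "shore",
  "s_shore"   = "shore",
  "shore"     = "shore",
  "n_shelf"   = "shelf",
  "s_shelf"   = "shelf",
  "shelf"     = "shelf",
  "opensea"   = "open_sea",
  "open_sea"  = "open_sea",
  "open sea"  = "open_sea"
)

normalize_context <- function(x) {
  key <- tolower(trimws(x))
  out <- unname(CONTEXT_DIALECT[key])
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop_typed("epimutr_validation_error",
               "unknown CpG context token(s): %s", paste(bad, collapse = ", "))
  }
  out
}

#' Validate a beta-value matrix
#'
#' A beta matrix is a plain numeric matrix with probe ids as row names and
#' sample ids as column names; values are methylation fractions in
#' \code{[0, 1]} or \code{NA} for masked probes.
#'
#' @param beta numeric matrix, probes x samples.
#' @param manifest optional probe manifest; when given, probes absent from
#'   it are rejected (\code{strict = TRUE}) or dropped with a warning.
#' @param strict logical, see \code{manifest}.
#' @return the validated (possibly subset) matrix, invisibly unchanged
#'   otherwise.
#' @export
validate_beta_matrix <- function(beta, manifest = NULL, strict = TRUE) {
  if (!is.matrix(beta) || !is.numeric(beta)) {
    stop_typed("epimutr_validation_error", "beta must be a numeric matrix")
  }
  if (is.null(rownames(beta)) || is.null(colnames(beta))) {
    stop_typed("epimutr_validation_error",
               "beta matrix needs probe row names and sample column names")
  }
  if (anyDuplicated(rownames(beta))) {
    stop_typed("epimutr_validation_error", "duplicate probe ids in beta matrix")
  }
  if (anyDuplicated(colnames(beta))) {
    stop_typed("epimutr_validation_error", "duplicate sample ids in beta matrix")
  }
  rng <- range(beta, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 1)) {
    stop_typed("epimutr_validation_error",
               "beta values outside [0, 1] (range %.4g..%.4g)", rng[1], rng[2])
  }
  if (!is.null(manifest)) {
    missing_probes <- setdiff(rownames(beta), manifest$probe_id)
    if (length(missing_probes)) {
      if (strict) {
        stop_typed("epimutr_validation_error",
                   "%d probe(s) absent from manifest (e.g. %s)",
                   length(missing_probes), missing_probes[1])
      }
      warning(sprintf("dropping %d probe(s) absent from manifest",
                      length(missing_probes)))
      beta <- beta[setdiff(rownames(beta), missing_probes), , drop = FALSE]
    }
  }
  beta
}

#' Read a beta-value matrix from TSV
#'
#' Expects a header row of sample ids with the first column holding probe
#' ids. Missing values use the token \code{"NA"}.
#'
#' @inheritParams validate_beta_matrix
#' @param path TSV file path.
#' @return validated numeric matrix (probes x samples).
#' @export
read_beta_matrix <- function(path, manifest = NULL, strict = TRUE) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", na.strings = character(0))
  if (ncol(df) < 2) {
    stop_typed("epimutr_parse_error", "beta matrix file needs >= 2 columns")
  }
  ids <- df[[1]]
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !(vals %in% c("NA", "")), arr.ind = TRUE)
  if (nrow(bad)) {
    stop_typed("epimutr_parse_error",
               "malformed numeric cell at row %d (probe %s), column %s",
               bad[1, 1], ids[bad[1, 1]], colnames(vals)[bad[1, 2]])
  }
  dimnames(num) <- list(ids, colnames(vals))
  validate_beta_matrix(num, manifest = manifest, strict = strict)
}

#' Write a beta-value matrix to TSV
#'
#' Round-trips bit-exactly through [read_beta_matrix()] (values serialized
#' at full precision, missing values as \code{"NA"}).
#'
#' @param beta numeric beta matrix.
#' @param path output path.
#' @export
write_beta_matrix <- function(beta, path) {
  validate_beta_matrix(beta)
  write_numeric_tsv(beta, path, id_col = "probe_id")
}

# full-precision numeric TSV writer shared by matrix writers
write_numeric_tsv <- function(mat, path, id_col) {
  chr <- format(mat, digits = 17, trim = TRUE, scientific = FALSE)
  chr[is.na(mat)] <- "NA"
  out <- cbind(rownames(mat), chr)
  colnames(out) <- c(id_col, colnames(mat))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe manifest from TSV
#'
#' Required columns: \code{probe_id}, \code{chrom}, \code{pos},
#' \code{context}. Optional: \code{cgi_id}, \code{gene_id},
#' \code{promoter_flag}, \code{tss_distance}, \code{exclude_flag}. Context
#' tokens are normalized case-insensitively through the annotation dialect
#' table (\code{N_Shore}/\code{S_Shore} to \code{shore},
#' \code{N_Shelf}/\code{S_Shelf} to \code{shelf}, \code{OpenSea} to
#' \code{open_sea}).
#'
#' @param path TSV file path.
#' @return validated manifest data frame.
#' @export
read_probe_manifest <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  required <- c("probe_id", "chrom", "pos", "context")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop_typed("epimutr_parse_error", "manifest missing column(s): %s",
               paste(missing_cols, collapse = ", "))
  }
  df$context <- normalize_context(df$context)
  if (!"cgi_id" %in% names(df)) df$cgi_id <- NA_character_
  if (!"gene_id" %in% names(df)) df$gene_id <- NA_character_
  if (!"promoter_flag" %in% names(df)) df$promoter_flag <- FALSE
  df$promoter_flag <- as.logical(df$promoter_flag)
  df$promoter_flag[is.na(df$promoter_flag)] <- FALSE
  if (!"tss_distance" %in% names(df)) df$tss_distance <- NA_integer_
  if (!"exclude_flag" %in% names(df)) df$exclude_flag <- FALSE
  df$exclude_flag <- as.logical(df$exclude_flag)
  df$exclude_flag[is.na(df$exclude_flag)] <- FALSE
  df$pos <- as.integer(df$pos)
  validate_probe_manifest(df)
}

#' Validate a probe manifest
#'
#' Enforces unique probe ids, positive 1-based positions, the four-level
#' context enum, \code{cgi_id} on every island probe, and a gene id on
#' every promoter-flagged probe.
#'
#' @param manifest manifest data frame.
#' @return the manifest, invisibly validated.
#' @export
validate_probe_manifest <- function(manifest) {
  if (anyDuplicated(manifest$probe_id)) {
    stop_typed("epimutr_validation_error", "duplicate probe_id in manifest")
  }
  if (any(manifest$pos < 1, na.rm = TRUE) || anyNA(manifest$pos)) {
    stop_typed("epimutr_validation_error", "manifest pos must be >= 1")
  }
  if (!all(manifest$context %in% CPG_CONTEXTS)) {
    stop_typed("epimutr_validation_error", "manifest context outside enum")
  }
  island_no_cgi <- manifest$context == "island" &
    (is.na(manifest$cgi_id) | manifest$cgi_id == "")
  if (any(island_no_cgi)) {
    stop_typed("epimutr_validation_error",
               "island probe(s) without cgi_id (e.g. %s)",
               manifest$probe_id[which(island_no_cgi)[1]])
  }
  promoter_no_gene <- manifest$promoter_flag &
    (is.na(manifest$gene_id) | manifest$gene_id == "")
  if (any(promoter_no_gene)) {
    stop_typed("epimutr_validation_error",
               "promoter-flagged probe(s) without gene_id (e.g. %s)",
               manifest$probe_id[which(promoter_no_gene)[1]])
  }
  manifest
}

#' Write a probe manifest to TSV
#' @param manifest manifest data frame.
#' @param path output path.
#' @export
write_probe_manifest <- function(manifest, path) {
  validate_probe_manifest(manifest)
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a sample sheet from TSV
#'
#' Cohort design: columns \code{sample_id}, \code{group} with group labels
#' among CIMP_high/CIMP_low/non_CIMP/normal. Clone design: additionally
#' \code{clone_id} (for \code{group == "clone"}) and integer
#' \code{passage}.
#'
#' @param path TSV file path.
#' @return sample sheet data frame.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  validate_sample_sheet(df)
}

#' Validate a sample sheet
#' @param sheet sample sheet data frame.
#' @return the sheet, validated.
#' @export
validate_sample_sheet <- function(sheet) {
  if (!all(c("sample_id", "group") %in% names(sheet))) {
    stop_typed("epimutr_validation_error",
               "sample sheet needs sample_id and group columns")
  }
  if (anyDuplicated(sheet$sample_id)) {
    stop_typed("epimutr_validation_error", "duplicate sample_id in sheet")
  }
  if ("passage" %in% names(sheet) && any(sheet$passage < 1, na.rm = TRUE)) {
    stop_typed("epimutr_validation_error", "passage must be >= 1")
  }
  sheet
}

#' Write a sample sheet to TSV
#' @param sheet sample sheet data frame.
#' @param path output path.
#' @export
write_sample_sheet <- function(sheet, path) {
  validate_sample_sheet(sheet)
  utils::write.table(sheet, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read an expression (or protein) matrix from TSV
#'
#' Genes x samples, first column gene ids. RPKM/FPKM matrices are linear
#' scale and non-negative; \code{LFQ_log2} matrices are log2 intensities
#' and may take any real value.
#'
#' @param path TSV file path.
#' @param unit_tag one of \code{"RPKM"}, \code{"FPKM"}, \code{"LFQ_log2"}.
#' @return numeric matrix with attribute \code{unit_tag}.
#' @export
read_expression_matrix <- function(path, unit_tag = c("RPKM", "FPKM", "LFQ_log2")) {
  unit_tag <- match.arg(unit_tag)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- df[[1]]
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  validate_expression_matrix(mat, unit_tag)
}

#' Validate an expression matrix
#' @param mat numeric matrix, genes x samples.
#' @inheritParams read_expression_matrix
#' @return matrix with \code{unit_tag} attribute set.
#' @export
validate_expression_matrix <- function(mat, unit_tag = c("RPKM", "FPKM", "LFQ_log2")) {
  unit_tag <- match.arg(unit_tag)
  if (anyDuplicated(rownames(mat))) {
    stop_typed("epimutr_validation_error", "duplicate gene ids")
  }
  if (anyDuplicated(colnames(mat))) {
    stop_typed("epimutr_validation_error", "duplicate sample ids")
  }
  if (unit_tag %in% c("RPKM", "FPKM") && any(mat < 0, na.rm = TRUE)) {
    stop_typed("epimutr_validation_error",
               "negative values in linear-scale %s matrix", unit_tag)
  }
  attr(mat, "unit_tag") <- unit_tag
  mat
}

#' Write an expression matrix to TSV
#' @param mat numeric matrix.
#' @param path output path.
#' @export
write_expression_matrix <- function(mat, path) {
  write_numeric_tsv(mat, path, id_col = "gene_id")
}

#' Read gene sets in GMT format
#'
#' Standard GMT: \code{name<TAB>description<TAB>gene1<TAB>gene2...}.
#' Duplicate genes within a set are de-duplicated with a warning.
#'
#' @param path GMT file path.
#' @return named list of character vectors with a \code{descriptions}
#'   attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  descriptions <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop_typed("epimutr_parse_error",
                 "GMT line %d has fewer than 3 fields", i)
    }
    name <- fields[1]
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning(sprintf("set '%s': duplicated gene(s) de-duplicated", name))
      genes <- unique(genes)
    }
    if (!length(genes)) {
      stop_typed("epimutr_validation_error", "GMT set '%s' is empty", name)
    }
    if (name %in% names(sets)) {
      stop_typed("epimutr_validation_error", "duplicate GMT set name '%s'", name)
    }
    sets[[name]] <- genes
    descriptions[name] <- fields[2]
  }
  attr(sets, "descriptions") <- descriptions
  sets
}

#' Write gene sets in GMT format
#' @param sets named list of character vectors; optional
#'   \code{descriptions} attribute (named character).
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions") %||%
    stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]] %||% "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a YAML pipeline configuration
#'
#' Thin wrapper over [yaml::read_yaml()]; the result is merged over the
#' stage defaults by [discovery_config()] / [clone_config()].
#'
#' @param path YAML file path.
#' @return named list.
#' @export
read_pipeline_config <- function(path) {
  yaml::read_yaml(path)
}
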