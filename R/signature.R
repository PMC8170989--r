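#' Construct a methylation signature
#'
#' A signature is a directed set of probe- or CGI-level differential
#' methylation calls together with the size of the universe of testable
#' ids it was called from (needed by every overlap statistic downstream).
#'
#' @param ids character vector of probe or CGI ids (unique).
#' @param directions character vector, \code{"hyper"} or \code{"hypo"},
#'   recycled if length 1.
#' @param level \code{"probe"} or \code{"cgi"}.
#' @param universe_size integer count of testable ids, \code{>= length(ids)}.
#' @return object of class \code{meth_signature}.
#' @export
meth_signature <- function(ids, directions, level = c("probe", "cgi"),
                           universe_size) {
  level <- match.arg(level)
  ids <- as.character(ids)
  if (length(directions) == 1) directions <- rep(directions, length(ids))
  if (length(directions) != length(ids)) {
    stop_typed("epimutr_validation_error", "ids/directions length mismatch")
  }
  if (anyDuplicated(ids)) {
    stop_typed("epimutr_validation_error", "duplicate ids in signature")
  }
  if (!all(directions %in% c("hyper", "hypo"))) {
    stop_typed("epimutr_validation_error",
               "directions must be 'hyper' or 'hypo'")
  }
  universe_size <- as.integer(universe_size)
  if (is.na(universe_size) || universe_size < length(ids)) {
    stop_typed("epimutr_validation_error",
               "universe_size must be >= number of signature entries")
  }
  structure(
    list(level = level,
         entries = stats::setNames(as.character(directions), ids),
         universe_size = universe_size),
    class = "meth_signature")
}

#' @export
print.meth_signature <- function(x, ...) {
  tab <- table(factor(x$entries, levels = c("hyper", "hypo")))
  cat(sprintf("<meth_signature> level=%s  %d entries (%d hyper, %d hypo), universe %d\n",
              x$level, length(x$entries), tab[["hyper"]], tab[["hypo"]],
              x$universe_size))
  invisible(x)
}

#' @export
length.meth_signature <- function(x) length(x$entries)

signature_ids <- function(sig, direction = NULL) {
  if (is.null(direction)) return(names(sig$entries))
  names(sig$entries)[sig$entries == direction]
}

#' Write a signature to its canonical TSV form
#'
#' Header comment lines carry the level and universe size; the body has
#' columns \code{id} and \code{direction}. An empty signature writes the
#' header only.
#'
#' @param sig a [meth_signature()].
#' @param path output path.
#' @export
write_signature <- function(sig, path) {
  stopifnot(inherits(sig, "meth_signature"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# level=%s", sig$level),
               sprintf("# universe_size=%d", sig$universe_size),
               "id\tdirection"), con)
  if (length(sig$entries)) {
    writeLines(paste(names(sig$entries), sig$entries, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a signature written by [write_signature()]
#' @param path TSV file path.
#' @return a [meth_signature()].
#' @export
read_signature <- function(path) {
  lines <- readLines(path)
  header <- grep("^#", lines, value = TRUE)
  level <- sub("^# level=", "", grep("^# level=", header, value = TRUE))
  universe <- as.integer(sub("^# universe_size=", "",
                             grep("^# universe_size=", header, value = TRUE)))
  if (!length(level) || !length(universe)) {
    stop_typed("epimutr_parse_error", "signature file missing header comments")
  }
  body <- lines[!grepl("^#", lines)][-1]  # drop column header
  body <- body[nzchar(body)]
  if (!length(body)) {
    return(meth_signature(character(), character(), level, universe))
  }
  parts <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  meth_signature(parts[, 1], parts[, 2], level, universe)
}

#' Export a probe signature as BED intervals
#'
#' Internal coordinates are 1-based inclusive; BED output is 0-based
#' half-open, so a probe at position \code{pos} becomes the interval
#' \code{[pos - 1, pos)}. The name field is \code{<probe>_<direction>}.
#'
#' @param sig probe-level [meth_signature()].
#' @param manifest probe manifest supplying coordinates (required).
#' @param path output BED path.
#' @export
signature_to_bed <- function(sig, manifest, path) {
  stopifnot(inherits(sig, "meth_signature"))
  if (missing(manifest) || is.null(manifest)) {
    stop_typed("epimutr_validation_error",
               "BED export requires a probe manifest for coordinates")
  }
  if (sig$level != "probe") {
    stop_typed("epimutr_validation_error", "BED export is probe-level only")
  }
  idx <- match(names(sig$entries), manifest$probe_id)
  if (anyNA(idx)) {
    stop_typed("epimutr_validation_error",
               "signature probe(s) missing from manifest")
  }
  lines <- sprintf("%s\t%d\t%d\t%s_%s",
                   manifest$chrom[idx], manifest$pos[idx] - 1L,
                   manifest$pos[idx], names(sig$entries), sig$entries)
  writeLines(lines, path)
  invisible(path)
}
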