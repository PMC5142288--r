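#' Read a CASP RR contact file
#'
#' Parses the CASP residue-residue contact exchange format: optional header
#' lines (\code{PFRMAT}, \code{TARGET}, \code{AUTHOR}, \code{METHOD},
#' \code{MODEL}, \code{REMARK}, \code{END}), optional sequence lines, then
#' 5-column contact rows \code{"i j dmin dmax confidence"}. Pairs are
#' canonicalized to \code{i < j}; duplicate pairs keep the higher
#' confidence.
#'
#' Records referencing residues beyond the sequence length are kept at parse
#' time; filtering happens at evaluation time against the native structure.
#'
#' @param path path to an RR file.
#' @param source label for the resulting set; defaults to the file name
#'   without extension.
#' @return A [contact_set].
#' @seealso [write_rr()]
#' @export
read_rr <- function(path, source = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(source)) source <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  seq_parts <- character()
  rec <- list(i = integer(), j = integer(), dmin = numeric(),
              dmax = numeric(), conf = numeric())
  n <- 0L
  for (k in seq_along(lines)) {
    ln <- trimws(lines[k])
    if (ln == "") next
    first <- sub("\\s.*", "", ln)
    if (first %in% c("PFRMAT", "TARGET", "AUTHOR", "METHOD", "MODEL",
                     "REMARK", "END", "TER")) next
    if (grepl("^[A-Za-z]+$", ln)) {            # sequence line
      if (n == 0L) seq_parts <- c(seq_parts, ln)
      next
    }
    fields <- strsplit(ln, "\\s+")[[1]]
    if (length(fields) != 5L)
      stop(sprintf("line %d: expected 5 columns, got %d", k, length(fields)))
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals))
      stop(sprintf("line %d: non-numeric field in contact row", k))
    n <- n + 1L
    rec$i[n] <- vals[1]; rec$j[n] <- vals[2]
    rec$dmin[n] <- vals[3]; rec$dmax[n] <- vals[4]; rec$conf[n] <- vals[5]
  }
  if (n == 0L) stop("no contacts found in ", path)
  if (any(rec$i == rec$j))
    stop("self-contact (i == j) in ", path)
  sequence <- if (length(seq_parts)) paste(seq_parts, collapse = "") else NULL
  contact_set(i = rec$i, j = rec$j, confidence = rec$conf,
              dmin = rec$dmin, dmax = rec$dmax,
              source = source, sequence = sequence,
              L = if (!is.null(sequence)) nchar(sequence) else NULL)
}

#' Write a contact set as a CASP RR file
#'
#' Emits the set's sequence (if any) followed by 5-column contact rows
#' sorted by confidence descending. \code{read_rr(write_rr(S))} reproduces
#' \code{S} up to the emitted numeric precision.
#'
#' @param set a [contact_set]; must be non-empty.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_rr <- function(set, path) {
  stopifnot(inherits(set, "contact_set"))
  if (nrow(set) == 0L) stop("refusing to write an empty contact set")
  lines <- character()
  sq <- attr(set, "sequence")
  if (!is.na(sq))
    lines <- substring(sq, seq(1, nchar(sq), 50),
                       pmin(seq(1, nchar(sq), 50) + 49, nchar(sq)))
  ord <- order(-set$confidence, set$i, set$j)
  rows <- sprintf("%d %d %g %g %.6f",
                  set$i[ord], set$j[ord], set$dmin[ord], set$dmax[ord],
                  set$confidence[ord])
  writeLines(c(lines, rows), path)
  invisible(path)
}

#' Read several RR files, or a zip archive of RR files
#'
#' @param paths character vector of RR file paths and/or \code{.zip}
#'   archives; each archive is expanded and every member parsed as RR.
#' @return A named list of [contact_set] objects.
#' @export
read_rr_multi <- function(paths) {
  files <- character()
  for (p in paths) {
    if (grepl("\\.zip$", p, ignore.case = TRUE)) {
      exdir <- tempfile("rrzip")
      files <- c(files, utils::unzip(p, exdir = exdir))
    } else files <- c(files, p)
  }
  sets <- lapply(files, read_rr)
  names(sets) <- vapply(sets, attr, "", "source")
  if (anyDuplicated(names(sets)))
    names(sets) <- make.unique(names(sets))
  sets
}
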