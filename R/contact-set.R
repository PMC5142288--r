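#' Construct a contact set
#'
#' A contact set is an ordered, canonicalized collection of residue-residue
#' contacts from a single source (one RR file, or the contacts derived from
#' one native structure). Pairs are stored with \code{i < j}, duplicates are
#' collapsed keeping the higher confidence, and rows are ordered by
#' confidence descending with ties broken by \code{(i, j)} ascending.
#'
#' @param i,j integer residue indices (1-based). Order within a pair is
#'   irrelevant; pairs are canonicalized to \code{i < j}.
#' @param confidence numeric prediction confidence. Values outside
#'   \code{[0, 1]} are accepted with a warning and used only for ranking.
#' @param dmin,dmax the RR distance-bound columns (stored, not used by any
#'   metric).
#' @param distance optional observed native distance in Angstrom, filled in
#'   during evaluation.
#' @param source label identifying where the set came from.
#' @param sequence optional one-letter amino-acid sequence the indices refer
#'   to.
#' @param L optional chain length.
#' @return An object of class \code{contact_set}: a data frame with columns
#'   \code{i, j, dmin, dmax, confidence, distance} and attributes
#'   \code{source}, \code{sequence}, \code{L}.
#' @examples
#' cs <- contact_set(i = c(9, 1), j = c(1, 9), confidence = c(0.5, 0.7))
#' nrow(cs)  # duplicates collapsed to one pair
#' @export
contact_set <- function(i = integer(), j = integer(), confidence = numeric(),
                        dmin = 0, dmax = 8, distance = NA_real_,
                        source = "contacts", sequence = NULL, L = NULL) {
  i <- as.integer(i); j <- as.integer(j)
  stopifnot(length(i) == length(j))
  if (any(i == j)) stop("self-contacts (i == j) are not allowed")
  confidence <- as.numeric(rep_len(confidence, length(i)))
  dmin <- as.numeric(rep_len(dmin, length(i)))
  dmax <- as.numeric(rep_len(dmax, length(i)))
  distance <- as.numeric(rep_len(distance, length(i)))
  swap <- i > j
  tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
  df <- data.frame(i = i, j = j, dmin = dmin, dmax = dmax,
                   confidence = confidence, distance = distance)
  if (nrow(df) && any(df$confidence < 0 | df$confidence > 1, na.rm = TRUE))
    warning("confidence values outside [0, 1]; used for ranking only")
  ## duplicates: keep the higher confidence
  if (nrow(df)) {
    df <- df[order(df$i, df$j, -df$confidence), , drop = FALSE]
    df <- df[!duplicated(df[, c("i", "j")]), , drop = FALSE]
    df <- df[order(-df$confidence, df$i, df$j), , drop = FALSE]
    rownames(df) <- NULL
  }
  structure(df,
            source = source,
            sequence = if (is.null(sequence)) NA_character_ else sequence,
            L = if (is.null(L)) NA_integer_ else as.integer(L),
            class = c("contact_set", "data.frame"))
}

## rebuild a contact_set from a plain data frame, preserving metadata of `from`
as_contact_set <- function(df, from, resort = TRUE) {
  if (nrow(df) && resort) {
    df <- df[order(-df$confidence, df$i, df$j), , drop = FALSE]
    rownames(df) <- NULL
  }
  structure(as.data.frame(df),
            source = attr(from, "source"),
            sequence = attr(from, "sequence"),
            L = attr(from, "L"),
            class = c("contact_set", "data.frame"))
}

#' @export
print.contact_set <- function(x, ...) {
  cat(sprintf("Contact set '%s': %d contacts", attr(x, "source"), nrow(x)))
  sq <- attr(x, "sequence")
  if (!is.na(sq)) cat(sprintf(", sequence length %d", nchar(sq)))
  cat("\n")
  if (nrow(x)) {
    print(utils::head(as.data.frame(x), 10))
    if (nrow(x) > 10) cat(sprintf("... %d more rows\n", nrow(x) - 10))
  }
  invisible(x)
}

## integer pair keys for fast set operations; indices are residue numbers,
## comfortably below the 2^26 packing limit
pair_key <- function(i, j) i * 2^26 + j

#' Contact definition
#'
#' The geometric and sequence-separation rules that decide which residue
#' pairs count as contacts. The CASP convention is the default: a pair
#' separated by at least 6 residues is in contact when the representative
#' atoms (Cbeta; Calpha for glycine) are closer than 8 Angstrom. Sequence
#' separation classes default to short [6, 11], medium [12, 23] and long
#' [24, Inf).
#'
#' @param atom representative atom, \code{"CB"} (Calpha substituted for
#'   glycine) or \code{"CA"}.
#' @param d distance threshold in Angstrom; pairs strictly closer than
#'   \code{d} are contacts.
#' @param min_sep minimum sequence separation \code{j - i} for any contact.
#' @param short,medium,long two-element numeric bounds (inclusive) of the
#'   separation classes; \code{Inf} allowed as an upper bound.
#' @return An object of class \code{contact_definition}.
#' @examples
#' contact_definition()            # CASP defaults
#' contact_definition(atom = "CA", d = 7)
#' @export
contact_definition <- function(atom = c("CB", "CA"), d = 8, min_sep = 6,
                               short = c(min_sep, 11), medium = c(12, 23),
                               long = c(24, Inf)) {
  atom <- match.arg(atom)
  stopifnot(d > 0, min_sep >= 1,
            length(short) == 2, length(medium) == 2, length(long) == 2,
            short[1] <= short[2], medium[1] <= medium[2], long[1] <= long[2],
            short[2] < medium[1], medium[2] < long[1])
  structure(list(atom = atom, d = d, min_sep = min_sep,
                 ranges = list(short = short, medium = medium, long = long)),
            class = "contact_definition")
}

#' @export
print.contact_definition <- function(x, ...) {
  cat(sprintf("Contact definition: %s atoms, d < %g A, separation >= %d\n",
              x$atom, x$d, x$min_sep))
  cat(sprintf("  ranges: short [%g, %g], medium [%g, %g], long [%g, %s]\n",
              x$ranges$short[1], x$ranges$short[2],
              x$ranges$medium[1], x$ranges$medium[2],
              x$ranges$long[1],
              if (is.finite(x$ranges$long[2])) format(x$ranges$long[2]) else "Inf"))
  invisible(x)
}

## resolve a range spec ("all"/"short"/"medium"/"long" or c(lo, hi)) to bounds
range_bounds <- function(range, defn) {
  if (is.character(range)) {
    range <- match.arg(range, c("all", "short", "medium", "long"))
    if (range == "all") return(c(defn$min_sep, Inf))
    return(defn$ranges[[range]])
  }
  stopifnot(is.numeric(range), length(range) == 2, range[1] <= range[2])
  range
}
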