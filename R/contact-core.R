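#' Derive the native contacts of a structure
#'
#' Every residue pair separated by at least \code{min_sep} in sequence
#' (author residue numbering) whose representative atoms are strictly
#' closer than the threshold \code{d} is a native contact. The observed
#' distance is recorded on each contact.
#'
#' @param structure a \code{native_structure}.
#' @param defn a [contact_definition].
#' @return A [contact_set] indexed by author residue numbers, with
#'   \code{distance} filled and confidence 1.
#' @export
native_contacts <- function(structure, defn = contact_definition()) {
  stopifnot(inherits(structure, "native_structure"))
  n <- structure$L
  if (n < 2L) {
    return(contact_set(source = "native", sequence = structure$sequence,
                       L = structure$L))
  }
  idx <- which(upper.tri(structure$dist), arr.ind = TRUE)
  ri <- structure$resno[idx[, 1]]
  rj <- structure$resno[idx[, 2]]
  dd <- structure$dist[idx]
  keep <- abs(rj - ri) >= defn$min_sep & dd < defn$d
  contact_set(i = pmin(ri, rj)[keep], j = pmax(ri, rj)[keep],
              confidence = 1, distance = dd[keep],
              source = "native", sequence = structure$sequence,
              L = structure$L)
}

#' Filter a contact set by sequence separation
#'
#' Keeps contacts with \code{lo <= j - i <= hi}; order is preserved.
#'
#' @param set a [contact_set].
#' @param lo,hi separation bounds (inclusive); \code{hi} may be \code{Inf}.
#' @return The filtered [contact_set].
#' @export
filter_range <- function(set, lo, hi = Inf) {
  stopifnot(inherits(set, "contact_set"), lo <= hi)
  sep <- set$j - set$i
  as_contact_set(set[sep >= lo & sep <= hi, , drop = FALSE], set,
                 resort = FALSE)
}

#' Map RR residue indices onto a native structure
#'
#' When the RR file carries a sequence that agrees position-by-position
#' with the structure's sequence, index \code{k} maps to the structure's
#' k-th residue (author numbering may then differ from 1..L). Otherwise
#' RR indices are taken as author residue numbers directly; a disagreement
#' between a supplied RR sequence and the structure raises a warning before
#' falling back to author numbering.
#'
#' @param set a [contact_set].
#' @param structure a \code{native_structure}.
#' @return The set with \code{i, j} rewritten into author-residue-number
#'   space and attribute \code{mapping} (\code{"position"} or
#'   \code{"resno"}).
#' @export
map_to_structure <- function(set, structure) {
  sq <- attr(set, "sequence")
  mapping <- "resno"
  if (!is.na(sq)) {
    if (identical(sq, structure$sequence)) mapping <- "position"
    else warning("RR sequence does not match the structure's sequence; ",
                 "mapping contacts by author residue number")
  }
  if (mapping == "position") {
    ok <- set$i <= structure$L & set$j <= structure$L
    out <- set[ok, , drop = FALSE]
    out$i <- structure$resno[out$i]
    out$j <- structure$resno[out$j]
    out <- as_contact_set(out, set, resort = FALSE)
  } else out <- set
  attr(out, "mapping") <- mapping
  out
}

#' Remove contacts absent from the native structure
#'
#' Drops contacts whose \code{i} or \code{j} has no residue in the
#' structure (domain evaluations routinely cover only part of the
#' predicted sequence). The number removed is recorded in the
#' \code{removed} attribute.
#'
#' @param set a [contact_set] already in author-residue-number space
#'   (see [map_to_structure()]).
#' @param structure a \code{native_structure}.
#' @return The filtered [contact_set] with attribute \code{removed}.
#' @export
filter_against_native <- function(set, structure) {
  stopifnot(inherits(set, "contact_set"),
            inherits(structure, "native_structure"))
  present <- set$i %in% structure$resno & set$j %in% structure$resno
  out <- as_contact_set(set[present, , drop = FALSE], set, resort = FALSE)
  attr(out, "removed") <- sum(!present)
  out
}

#' Select the top-k contacts by confidence
#'
#' Contacts are ranked by confidence descending, ties broken by
#' \code{(i, j)} ascending; the first \code{min(k, n)} are returned.
#'
#' @param set a [contact_set].
#' @param k number of contacts to keep (\code{k >= 1}).
#' @return A [contact_set] of at most \code{k} contacts.
#' @export
select_top <- function(set, k) {
  stopifnot(inherits(set, "contact_set"), k >= 1)
  ord <- order(-set$confidence, set$i, set$j)
  as_contact_set(set[ord[seq_len(min(k, nrow(set)))], , drop = FALSE], set,
                 resort = FALSE)
}

#' Standard contact selection-group sizes
#'
#' The six groups conventionally evaluated: top-5, L/10, L/5, L/2, L and
#' 2L. Fractional sizes use floor with a minimum of 1.
#'
#' @param L chain length (\code{L >= 1}).
#' @return Named integer vector of the six group sizes.
#' @examples
#' selection_sizes(150)  # 5 15 30 75 150 300
#' @export
selection_sizes <- function(L) {
  stopifnot(L >= 1)
  L <- as.integer(L)
  c("top-5" = 5L,
    "L/10" = max(1L, L %/% 10L),
    "L/5"  = max(1L, L %/% 5L),
    "L/2"  = max(1L, L %/% 2L),
    "L"    = L,
    "2L"   = 2L * L)
}

#' Resolve the evaluation length L
#'
#' L is the length of the native chain when a structure is supplied,
#' otherwise the length of the sequence the contacts were predicted for,
#' otherwise (with a warning) the largest residue index in the set.
#'
#' @param set a [contact_set].
#' @param structure optional \code{native_structure}.
#' @return The length L as an integer.
#' @export
resolve_L <- function(set, structure = NULL) {
  if (!is.null(structure)) return(structure$L)
  sq <- attr(set, "sequence")
  if (!is.na(sq)) return(nchar(sq))
  if (!is.na(attr(set, "L"))) return(attr(set, "L"))
  if (nrow(set) == 0L) stop("cannot resolve L: no structure, sequence, or contacts")
  warning("no structure or sequence supplied; using the largest residue index as L")
  max(set$j)
}

#' All candidate residue pairs in a separation range
#'
#' The candidate universe for full-list metrics: every unordered pair of
#' residues (of the native structure if given, else of \code{1..L}) whose
#' sequence separation lies within the bounds.
#'
#' @param lo,hi inclusive separation bounds.
#' @param structure optional \code{native_structure}; pairs are then formed
#'   over its author residue numbers.
#' @param L chain length, used when no structure is given.
#' @return Two-column integer matrix of pairs with \code{i < j}.
#' @export
candidate_pairs <- function(lo, hi = Inf, structure = NULL, L = NULL) {
  res <- if (!is.null(structure)) sort(structure$resno) else seq_len(L)
  n <- length(res)
  if (n < 2L) return(matrix(integer(), ncol = 2,
                            dimnames = list(NULL, c("i", "j"))))
  idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
  i <- res[idx[, 1]]; j <- res[idx[, 2]]
  sep <- j - i
  keep <- sep >= lo & sep <= hi
  cbind(i = i[keep], j = j[keep])
}
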