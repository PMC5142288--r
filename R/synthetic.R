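#' Generate a synthetic chain structure
#'
#' Builds a single-chain structure with one representative atom per residue
#' (a Cbeta surrogate; no side chains are modeled) and consecutive-residue
#' spacing of 3.8 Angstrom:
#' \describe{
#'   \item{compact}{a self-avoiding random walk confined to a sphere,
#'     dense enough that at least L/2 long-range native contacts exist at
#'     the 8-Angstrom definition for \code{L >= 30} (regenerated
#'     deterministically until that holds; below L = 30 too few residue
#'     pairs reach separation 24 for such a guarantee and only chain
#'     closure is required);}
#'   \item{helix}{an ideal alpha-helix (2.3 Angstrom radius, 1.5 Angstrom
#'     rise, 100 degrees per residue) — short-range contacts only;}
#'   \item{extended}{a straight chain — no contacts at any separation
#'     of 3 or more.}
#' }
#' Generation is a pure function of \code{(L, geometry, seed)}.
#'
#' @param L number of residues (\code{L >= 10}).
#' @param geometry \code{"compact"}, \code{"helix"} or \code{"extended"}.
#' @param seed integer seed.
#' @param path optional path; when given, the structure is also written as
#'   a PDB file.
#' @return A \code{native_structure} (chain A, residues numbered 1..L,
#'   alanine with a single CB atom per residue).
#' @export
make_structure <- function(L, geometry = c("compact", "helix", "extended"),
                           seed = 1, path = NULL) {
  geometry <- match.arg(geometry)
  stopifnot(L >= 10)
  xyz <- switch(geometry,
    extended = cbind(3.8 * (seq_len(L) - 1), 0, 0),
    helix = {
      t <- (seq_len(L) - 1) * 100 * pi / 180
      cbind(2.3 * cos(t), 2.3 * sin(t), 1.5 * (seq_len(L) - 1))
    },
    compact = compact_walk(L, seed))
  st <- structure(list(chain = "A", resno = seq_len(L),
                       resid = rep("ALA", L),
                       atom_name = rep("CB", L),
                       xyz = xyz,
                       sequence = paste(rep("A", L), collapse = ""),
                       L = L,
                       dist = as.matrix(stats::dist(xyz))),
                  class = "native_structure")
  if (!is.null(path)) write_structure(st, path)
  st
}

## self-avoiding confined walk; restarts (with advancing sub-seeds) until
## the chain both closes and carries enough long-range contacts. The
## confinement radius grows linearly in L (calibrated for L in [10, 100]):
## tight enough that chain ends fold back, loose enough that the walk can
## still close. Below L = 30 there are too few pairs at separation >= 24
## for an L/2 guarantee, so only chain closure is required there.
compact_walk <- function(L, seed, bond = 3.8, min_sep_dist = 3.5,
                         max_restarts = 200L) {
  R <- 4.8 + 0.108 * L
  n_long_req <- if (L >= 30) L / 2 else 0
  for (attempt in seq_len(max_restarts)) {
    set.seed(seed * 1000L + attempt)
    xyz <- matrix(NA_real_, L, 3)
    xyz[1, ] <- c(0, 0, 0)
    ok <- TRUE
    for (r in 2:L) {
      placed <- FALSE
      for (try in 1:200) {
        u <- stats::rnorm(3)
        cand <- xyz[r - 1, ] + bond * u / sqrt(sum(u^2))
        if (sum(cand^2) > R^2) next
        if (r > 2) {
          dd <- sqrt(rowSums((xyz[1:(r - 2), , drop = FALSE] -
                              matrix(cand, r - 2, 3, byrow = TRUE))^2))
          if (any(dd < min_sep_dist)) next
        }
        xyz[r, ] <- cand
        placed <- TRUE
        break
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (!ok) next
    dm <- as.matrix(stats::dist(xyz))
    sep <- abs(row(dm) - col(dm))
    n_long <- sum(dm < 8 & sep >= 24 & upper.tri(dm))
    if (n_long >= n_long_req) return(xyz)
  }
  stop("could not generate a compact self-avoiding chain; try another seed")
}

#' Generate a prediction set with planted precision
#'
#' Draws \code{ceiling(p * n)} contacts from the native set and the
#' remainder from the non-contact candidate pairs, then assigns
#' confidences so true contacts stochastically rank higher: true contacts
#' Uniform(0.5, 1), decoys Uniform(0, 0.7) (overlapping on purpose, so
#' ranking-based metrics are non-degenerate). Deterministic under
#' \code{seed}.
#'
#' @param native the native [contact_set] (e.g. from [native_contacts()]).
#' @param universe two-column matrix of candidate pairs
#'   ([candidate_pairs()]) from which decoys are drawn.
#' @param n number of contacts to emit.
#' @param p planted precision in \code{[0, 1]}: the fraction of the n
#'   contacts that are native.
#' @param seed integer seed.
#' @param source label for the resulting set.
#' @return A [contact_set] (RR-writable) of exactly \code{n} contacts.
#' @export
make_predictions <- function(native, universe, n, p, seed = 1,
                             source = sprintf("planted_p%g", p)) {
  stopifnot(p >= 0, p <= 1, n >= 1)
  n_true <- ceiling(p * n)
  n_false <- n - n_true
  if (n_true > nrow(native))
    stop("native set too small for ", n_true, " planted true contacts")
  nat_key <- pair_key(native$i, native$j)
  decoys <- universe[!(pair_key(universe[, 1], universe[, 2]) %in% nat_key), ,
                     drop = FALSE]
  if (n_false > nrow(decoys))
    stop("candidate universe too small for ", n_false, " decoys")
  set.seed(seed)
  ti <- sample(nrow(native), n_true)
  fi <- if (n_false > 0) sample(nrow(decoys), n_false) else integer()
  conf <- c(stats::runif(n_true, 0.5, 1.0), stats::runif(n_false, 0.0, 0.7))
  contact_set(i = c(native$i[ti], decoys[fi, 1]),
              j = c(native$j[ti], decoys[fi, 2]),
              confidence = conf,
              source = source,
              L = attr(native, "L"))
}

#' Generate a complete synthetic evaluation instance
#'
#' Convenience wrapper bundling a compact structure, its native contacts,
#' the candidate universe for a separation range, and one or more
#' prediction sets with planted precision — everything the evaluation
#' pipeline consumes, with no external data.
#'
#' @param L chain length.
#' @param p planted precision (vector: one prediction set per element).
#' @param n_contacts contacts per prediction set; default the top-L/5
#'   group size.
#' @param range separation range for the universe (\code{"all"},
#'   \code{"short"}, \code{"medium"}, \code{"long"} or numeric bounds).
#' @param geometry chain geometry, see [make_structure()].
#' @param defn a [contact_definition].
#' @param seed integer seed.
#' @return List with \code{structure}, \code{native} (range-filtered
#'   native contacts), \code{universe}, and \code{predictions} (list of
#'   [contact_set]s).
#' @export
make_instance <- function(L = 60, p = 0.5, n_contacts = NULL, range = "long",
                          geometry = "compact", defn = contact_definition(),
                          seed = 1) {
  st <- make_structure(L, geometry, seed = seed)
  bounds <- range_bounds(range, defn)
  nat <- filter_range(native_contacts(st, defn), bounds[1], bounds[2])
  uni <- candidate_pairs(bounds[1], bounds[2], structure = st)
  if (is.null(n_contacts)) n_contacts <- selection_sizes(L)[["L/5"]]
  preds <- lapply(seq_along(p), function(k)
    make_predictions(nat, uni, n_contacts, p[k], seed = seed + 7 * k,
                     source = sprintf("set%d_p%g", k, p[k])))
  names(preds) <- vapply(preds, attr, "", "source")
  list(structure = st, native = nat, universe = uni, predictions = preds)
}
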