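#' Read a native structure from a PDB file
#'
#' Loads one chain of a PDB file (via \pkg{bio3d}) and reduces it to one
#' representative-atom coordinate per residue. With \code{atom = "CB"} the
#' Cbeta atom is used, falling back to Calpha for glycine or for any residue
#' lacking a Cbeta record; residues with neither atom are dropped. HETATM
#' records are ignored; for alternate locations the highest-occupancy record
#' wins (ties: first encountered); only the first model of a multi-model
#' file is used.
#'
#' @param path path to a PDB file.
#' @param chain chain identifier; default is the first polymer chain.
#' @param atom representative atom, \code{"CB"} (default) or \code{"CA"}.
#' @return An object of class \code{native_structure}: a list with elements
#'   \code{chain}, \code{resno} (author residue numbers), \code{resid}
#'   (3-letter residue names), \code{atom_name} (the representative atom
#'   kept per residue), \code{xyz} (L x 3 coordinate matrix, Angstrom),
#'   \code{sequence}, \code{L}, and \code{dist} (L x L pairwise distance
#'   matrix).
#' @export
read_structure <- function(path, chain = NULL, atom = c("CB", "CA")) {
  atom <- match.arg(atom)
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in ", path)
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain %in% chain, , drop = FALSE]
  if (nrow(at) == 0L) stop("no such chain '", chain, "' in ", path)
  ## residues in file order, insertion codes consuming their own position
  ins <- at$insert
  ins[is.na(ins)] <- ""
  rkey <- paste(at$resno, ins, sep = "|")
  keys <- unique(rkey)
  pick <- function(rows, name) {
    cand <- rows[rows$elety == name, , drop = FALSE]
    if (nrow(cand) == 0L) return(NULL)
    cand[which.max(cand$o), , drop = FALSE]   # ties: which.max keeps first
  }
  resno <- integer(); resid <- character(); aname <- character()
  xyz <- matrix(numeric(), ncol = 3)
  for (k in keys) {
    rows <- at[rkey == k, , drop = FALSE]
    rep_at <- if (atom == "CB") {
      r <- pick(rows, "CB")
      if (is.null(r)) pick(rows, "CA") else r   # glycine / missing CB
    } else pick(rows, "CA")
    if (is.null(rep_at)) next                    # no representative atom
    resno <- c(resno, rep_at$resno)
    resid <- c(resid, rep_at$resid)
    aname <- c(aname, rep_at$elety)
    xyz <- rbind(xyz, c(rep_at$x, rep_at$y, rep_at$z))
  }
  if (length(resno) == 0L)
    stop("no residues with representative atoms in chain '", chain, "'")
  seq1 <- paste(bio3d::aa321(resid), collapse = "")
  structure(list(chain = chain, resno = resno, resid = resid,
                 atom_name = aname, xyz = xyz, sequence = seq1,
                 L = length(resno),
                 dist = as.matrix(stats::dist(xyz))),
            class = "native_structure")
}

#' @export
print.native_structure <- function(x, ...) {
  cat(sprintf("Native structure: chain %s, %d residues (%d-%d), %s\n",
              x$chain, x$L, min(x$resno), max(x$resno),
              paste(unique(x$atom_name), collapse = "/")))
  invisible(x)
}

#' Write a native structure as a PDB file
#'
#' One ATOM record per residue at the stored representative-atom
#' coordinate. [read_structure()] on the output reproduces the structure to
#' the PDB format's coordinate precision (3 decimals).
#'
#' @param structure a \code{native_structure}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_structure <- function(structure, path) {
  stopifnot(inherits(structure, "native_structure"))
  n <- structure$L
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(structure$xyz)),
                   type = rep("ATOM", n),
                   resno = structure$resno,
                   resid = structure$resid,
                   eleno = seq_len(n),
                   elety = structure$atom_name,
                   chain = rep(structure$chain, n),
                   o = rep(1, n), b = rep(0, n))
  invisible(path)
}

## native distance lookup for pairs given by author residue number;
## NA where either residue is absent
native_distance <- function(structure, i, j) {
  pi <- match(i, structure$resno)
  pj <- match(j, structure$resno)
  ok <- !is.na(pi) & !is.na(pj)
  out <- rep(NA_real_, length(i))
  out[ok] <- structure$dist[cbind(pi[ok], pj[ok])]
  out
}
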