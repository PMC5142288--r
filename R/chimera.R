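#' Emit a UCSF Chimera command script for a contact selection
#'
#' Writes a plain-text command script that opens the native structure and
#' draws one distance pseudobond per predicted contact between the
#' representative atoms (author residue numbers, chain id, stored atom
#' name — Calpha for glycine). Correct contacts (native distance below the
#' threshold) are drawn first and colored; incorrect contacts are drawn
#' after the color command, so they keep the distance monitor's default
#' long line and label and the violated distance stays visible. One
#' \code{distance} command is emitted per contact, so the per-contact
#' command count equals the selection size; regeneration is
#' byte-identical.
#'
#' @param pred a [contact_set] already filtered against the structure.
#' @param structure a \code{native_structure}.
#' @param defn a [contact_definition] (decides correct vs incorrect).
#' @param path output script path.
#' @param pdb_path structure path embedded in the script's \code{open}
#'   command (relative by default).
#' @param dialect \code{"chimera"} (classic command syntax) or
#'   \code{"chimerax"}.
#' @param correct_color color applied to the pseudobonds of correct
#'   contacts.
#' @return Invisibly, the script lines, with attribute \code{correct}
#'   (logical per contact, in the input order of \code{pred}).
#' @export
chimera_script <- function(pred, structure, defn = contact_definition(),
                           path, pdb_path = "native.pdb",
                           dialect = c("chimera", "chimerax"),
                           correct_color = "green") {
  dialect <- match.arg(dialect)
  d_ij <- native_distance(structure, pred$i, pred$j)
  if (anyNA(d_ij))
    stop("prediction references residues absent from the structure; ",
         "apply filter_against_native() first")
  if (nrow(pred) == 0L) warning("empty prediction: structure-only script")
  correct <- d_ij < defn$d
  atom_of <- function(r) structure$atom_name[match(r, structure$resno)]
  ch <- structure$chain
  if (dialect == "chimera") {
    preamble <- c(sprintf("open %s", pdb_path), "~display", "ribbon")
    spec <- function(r) sprintf(":%d.%s@%s", r, ch, atom_of(r))
    color_cmd <- sprintf("color %s pseudobonds", correct_color)
  } else {
    preamble <- c(sprintf("open %s", pdb_path), "hide atoms",
                  "show cartoons")
    spec <- function(r) sprintf("/%s:%d@%s", ch, r, atom_of(r))
    color_cmd <- sprintf("color pbonds %s", correct_color)
  }
  dist_cmd <- function(idx) {
    if (!length(idx)) return(character())
    sprintf("distance %s %s", spec(pred$i[idx]), spec(pred$j[idx]))
  }
  lines <- c(preamble,
             sprintf("# %d correct contacts (colored %s)", sum(correct),
                     correct_color),
             dist_cmd(which(correct)),
             if (any(correct)) color_cmd,
             sprintf("# %d incorrect contacts (distance monitors)",
                     sum(!correct)),
             dist_cmd(which(!correct)))
  writeLines(lines, path)
  attr(lines, "correct") <- correct
  invisible(lines)
}
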