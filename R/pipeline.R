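#' Evaluate predicted contacts against a native structure
#'
#' The full assessment pipeline: contacts are sorted by confidence,
#' filtered to the requested sequence-separation range, filtered against
#' the native structure, grouped into the six standard selections (top-5,
#' L/10, L/5, L/2, L, 2L), and scored with the reduced-list measures
#' (precision, coverage, mean false-positive error, Xd, spread) per group
#' plus the full-list measures (MCC at the 0.5 confidence cut, ROC and
#' precision-recall curves with their areas) on the whole filtered list.
#'
#' @param rr RR file path(s) / zip archive(s), a [contact_set], or a list
#'   of contact sets.
#' @param pdb a PDB file path or a \code{native_structure}.
#' @param defn a [contact_definition].
#' @param range separation range to evaluate: \code{"all"},
#'   \code{"short"}, \code{"medium"}, \code{"long"}, or numeric bounds
#'   \code{c(lo, hi)}.
#' @param chain chain identifier passed to [read_structure()] when
#'   \code{pdb} is a path.
#' @param xd_reference reference distribution for [xd_score()]:
#'   \code{"native_contacts"} (default) or \code{"all_pairs"}.
#' @return An object of class \code{contact_evaluation}: list with
#'   \code{metrics} (data frame: source, group, k, n_evaluated, TP, FP,
#'   precision, coverage, mean_fp_error, xd, spread), \code{full}
#'   (per-source MCC, AUCs and curves), \code{counts} (per-source
#'   pipeline stage counts, including contacts not in the native
#'   structure), \code{native}, \code{structure}, \code{universe},
#'   \code{sets} (the filtered per-source sets), \code{defn},
#'   \code{range}, \code{L}.
#' @examples
#' inst <- make_instance(L = 40, p = 0.8, seed = 3)
#' ev <- evaluate_contacts(inst$predictions, inst$structure)
#' summary(ev)
#' @export
evaluate_contacts <- function(rr, pdb, defn = contact_definition(),
                              range = "long", chain = NULL,
                              xd_reference = c("native_contacts",
                                               "all_pairs")) {
  xd_reference <- match.arg(xd_reference)
  sets <- normalize_rr_input(rr)
  st <- if (inherits(pdb, "native_structure")) pdb
        else read_structure(pdb, chain = chain, atom = defn$atom)
  bounds <- range_bounds(range, defn)
  L <- resolve_L(sets[[1]], st)
  native <- filter_range(native_contacts(st, defn),
                         bounds[1], bounds[2])
  universe <- candidate_pairs(bounds[1], bounds[2], structure = st)
  sizes <- selection_sizes(L)

  counts <- list(); metrics <- list(); full <- list(); kept <- list()
  for (lab in names(sets)) {
    s0 <- sets[[lab]]
    s1 <- map_to_structure(s0, st)
    s2 <- filter_range(s1, bounds[1], bounds[2])
    s3 <- filter_against_native(s2, st)
    counts[[lab]] <- data.frame(
      source = lab, n_input = nrow(s0), n_in_range = nrow(s2),
      n_not_in_native = attr(s3, "removed"), n_evaluated = nrow(s3))
    kept[[lab]] <- s3
    for (g in names(sizes)) {
      sel <- select_top(s3, sizes[[g]])
      sc <- score_selection(sel, st, defn)
      cc <- confusion_counts(TP = sc$tp, FP = sc$fp,
                             FN = nrow(native) - sc$tp, Nc = nrow(native))
      metrics[[paste(lab, g)]] <- data.frame(
        source = lab, group = g, k = sizes[[g]], n_evaluated = nrow(sel),
        TP = sc$tp, FP = sc$fp,
        precision = contact_precision(cc),
        coverage = contact_coverage(cc),
        mean_fp_error = mean_fp_error(sel, st, defn),
        xd = xd_from_selection(sel, st, native, defn,
                               reference = xd_reference,
                               universe = universe),
        spread = contact_spread(sel, native))
    }
    cf <- confusion_full(s3, native, universe)
    roc <- roc_points(s3, native, universe)
    pr <- pr_points(s3, native, universe)
    full[[lab]] <- list(confusion = cf, mcc = contact_mcc(cf),
                        auc_roc = roc$auc, auc_pr = pr$auc_pr,
                        roc = roc$points, pr = pr$points)
  }
  structure(list(metrics = do.call(rbind, c(metrics,
                                            make.row.names = FALSE)),
                 full = full,
                 counts = do.call(rbind, c(counts,
                                           make.row.names = FALSE)),
                 native = native, structure = st,
                 universe = universe, sets = kept,
                 defn = defn, range = bounds, L = L),
            class = "contact_evaluation")
}

normalize_rr_input <- function(rr) {
  if (inherits(rr, "contact_set")) rr <- list(rr)
  if (is.character(rr)) rr <- read_rr_multi(rr)
  stopifnot(length(rr) >= 1,
            all(vapply(rr, inherits, TRUE, "contact_set")))
  if (is.null(names(rr)))
    names(rr) <- make.unique(vapply(rr, attr, "", "source"))
  rr
}

#' @export
print.contact_evaluation <- function(x, ...) {
  cat(sprintf("Contact evaluation: %d source(s), L = %d, range [%g, %s], %d native contacts\n",
              length(x$sets), x$L, x$range[1],
              if (is.finite(x$range[2])) format(x$range[2]) else "Inf",
              nrow(x$native)))
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' @export
summary.contact_evaluation <- function(object, digits = 3, ...) {
  cat(sprintf("Contact evaluation over %d candidate pairs (Nc = %d)\n\n",
              nrow(object$universe), nrow(object$native)))
  tab <- object$metrics
  num <- vapply(tab, is.numeric, TRUE)
  tab[num] <- lapply(tab[num], round, digits = digits)
  print(tab, row.names = FALSE)
  cat("\nFull-list measures (positives: confidence > 0.5):\n")
  fl <- do.call(rbind, lapply(names(object$full), function(lab)
    data.frame(source = lab,
               MCC = round(object$full[[lab]]$mcc, digits),
               AUC_ROC = round(object$full[[lab]]$auc_roc, digits),
               AUC_PR = round(object$full[[lab]]$auc_pr, digits))))
  print(fl, row.names = FALSE)
  invisible(object)
}

#' @export
plot.contact_evaluation <- function(x, path = NULL, ...) {
  invisible(plot_measures(x, path = path))
}

#' Compare prediction sets without a native structure
#'
#' Reference-free comparison: per-range contact counts, coordination
#' profiles, and (for two or more sets) the relaxed Jaccard similarity
#' matrix with its clustering order. Sets are truncated to a common
#' selection before comparison (top-L/5 of the requested range by
#' default).
#'
#' @param rr RR file path(s) / zip archive(s), a [contact_set], or a list
#'   of contact sets.
#' @param N neighborhood relaxation for the Jaccard similarity (0..3);
#'   may be a vector, producing one matrix per value.
#' @param defn a [contact_definition].
#' @param range separation range used throughout.
#' @param top selection applied to each set before similarity:
#'   \code{"top-5"}, \code{"L/10"}, \code{"L/5"}, \code{"L/2"},
#'   \code{"L"}, \code{"2L"}, \code{"all"}, or an integer count.
#' @param L chain length; resolved from the first set if missing.
#' @return An object of class \code{contact_comparison}: list with
#'   \code{counts} (contacts per range per source), \code{profiles}
#'   (coordination profiles), \code{similarity} (named list of
#'   \code{contact_similarity}, one per N; \code{NULL} for a single
#'   set), \code{order} (cluster order for the first N), \code{sets},
#'   \code{L}, \code{N}, \code{defn}.
#' @export
compare_contacts <- function(rr, N = 0, defn = contact_definition(),
                             range = "all", top = "L/5", L = NULL) {
  stopifnot(all(N %in% 0:3))
  sets <- normalize_rr_input(rr)
  if (is.null(L)) L <- resolve_L(sets[[1]])
  bounds <- range_bounds(range, defn)
  sizes <- selection_sizes(L)
  k <- if (is.numeric(top)) as.integer(top)
       else if (identical(top, "all")) NA_integer_
       else sizes[[match.arg(top, names(sizes))]]
  counts <- do.call(rbind, lapply(names(sets), function(lab) {
    s <- sets[[lab]]
    data.frame(source = lab, n_total = nrow(s),
               n_short = nrow(filter_range(s, defn$ranges$short[1],
                                           defn$ranges$short[2])),
               n_medium = nrow(filter_range(s, defn$ranges$medium[1],
                                            defn$ranges$medium[2])),
               n_long = nrow(filter_range(s, defn$ranges$long[1],
                                          defn$ranges$long[2])))
  }))
  trimmed <- lapply(sets, function(s) {
    s <- filter_range(s, bounds[1], bounds[2])
    if (!is.na(k)) s <- select_top(s, k)
    s
  })
  profiles <- lapply(trimmed, coordination_numbers, L = L)
  sim <- NULL; ord <- NULL
  if (length(trimmed) >= 2L) {
    sim <- lapply(N, function(nn) similarity_matrix(trimmed, N = nn))
    names(sim) <- paste0("N", N)
    ord <- cluster_order(sim[[1]])
  }
  structure(list(counts = counts, profiles = profiles, similarity = sim,
                 order = ord, sets = trimmed, L = L, N = N, defn = defn),
            class = "contact_comparison")
}

#' @export
print.contact_comparison <- function(x, ...) {
  cat(sprintf("Contact comparison: %d source(s), L = %d\n", length(x$sets),
              x$L))
  print(x$counts, row.names = FALSE)
  if (!is.null(x$similarity)) {
    for (nm in names(x$similarity)) print(x$similarity[[nm]])
  } else cat("(single set: similarity section skipped)\n")
  invisible(x)
}

#' Summarize the native contacts of a structure
#'
#' Structure-only analysis: true-contact counts per separation range for
#' a chosen contact definition, with the native distance histogram —
#' useful to see whether a structure has few or no long-range contacts at
#' all.
#'
#' @param structure a \code{native_structure} or PDB path.
#' @param defn a [contact_definition].
#' @param chain chain identifier when \code{structure} is a path.
#' @return List with \code{L}, per-range counts, the native
#'   [contact_set], and its [distance_histogram].
#' @export
structure_contact_summary <- function(structure,
                                      defn = contact_definition(),
                                      chain = NULL) {
  if (!inherits(structure, "native_structure"))
    structure <- read_structure(structure, chain = chain, atom = defn$atom)
  nat <- native_contacts(structure, defn)
  list(L = structure$L,
       n_contacts = nrow(nat),
       n_short = nrow(filter_range(nat, defn$ranges$short[1],
                                   defn$ranges$short[2])),
       n_medium = nrow(filter_range(nat, defn$ranges$medium[1],
                                    defn$ranges$medium[2])),
       n_long = nrow(filter_range(nat, defn$ranges$long[1],
                                  defn$ranges$long[2])),
       native = nat,
       histogram = distance_histogram(nat$distance))
}

#' Write an evaluation or comparison report directory
#'
#' Serializes the assessment into plain files mirroring the section order
#' of an interactive report: stage-count and metric tables (TSV), ROC and
#' precision-recall curve tables, the measure/contact-map/chord/similarity
#' plots with their data sidecars, and one Chimera command script per
#' source and selection group (evaluation only).
#'
#' @param x a \code{contact_evaluation} or \code{contact_comparison}.
#' @param dir output directory (created if needed).
#' @param plots logical: write image files (data sidecars are always
#'   written with them).
#' @param pdb_path path embedded in the Chimera scripts' \code{open}
#'   command.
#' @return \code{dir}, invisibly.
#' @export
write_report <- function(x, dir, plots = TRUE, pdb_path = "native.pdb") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name, rn = FALSE)
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = rn, col.names = if (rn) NA else TRUE)
  if (inherits(x, "contact_evaluation")) {
    tsv(x$counts, "counts.tsv")
    tsv(x$metrics, "metrics.tsv")
    fl <- do.call(rbind, lapply(names(x$full), function(lab)
      data.frame(source = lab, MCC = x$full[[lab]]$mcc,
                 AUC_ROC = x$full[[lab]]$auc_roc,
                 AUC_PR = x$full[[lab]]$auc_pr)))
    tsv(fl, "full_list.tsv")
    sizes <- selection_sizes(x$L)
    for (lab in names(x$full)) {
      safe <- gsub("[^A-Za-z0-9._-]", "_", lab)
      tsv(x$full[[lab]]$roc, sprintf("roc_%s.tsv", safe))
      tsv(x$full[[lab]]$pr, sprintf("pr_%s.tsv", safe))
      for (g in names(sizes)) {
        sel <- select_top(x$sets[[lab]], sizes[[g]])
        gs <- gsub("[^A-Za-z0-9._-]", "_", g)
        chimera_script(sel, x$structure, x$defn,
                       path = file.path(dir, sprintf("chimera_%s_%s.com",
                                                     safe, gs)),
                       pdb_path = pdb_path)
      }
    }
    if (plots) {
      plot_measures(x, path = file.path(dir, "measures.png"))
      plot_contact_map(x$sets, native = x$native, L = max(x$structure$resno),
                       path = file.path(dir, "contact_map.png"))
    }
  } else if (inherits(x, "contact_comparison")) {
    tsv(x$counts, "counts.tsv")
    prof <- do.call(rbind, lapply(names(x$profiles), function(lab)
      data.frame(source = lab, residue = seq_len(x$L),
                 coordination = as.integer(x$profiles[[lab]]))))
    tsv(prof, "coordination.tsv")
    if (!is.null(x$similarity)) {
      for (nm in names(x$similarity)) {
        write_similarity(x$similarity[[nm]],
                         file.path(dir, sprintf("jaccard_%s.tsv", nm)))
        if (plots)
          plot_similarity(x$similarity[[nm]],
                          path = file.path(dir,
                                           sprintf("similarity_%s.png", nm)))
      }
    }
    if (plots) {
      plot_contact_map(x$sets, L = x$L,
                       path = file.path(dir, "contact_map.png"))
      for (lab in names(x$sets)) {
        safe <- gsub("[^A-Za-z0-9._-]", "_", lab)
        plot_chord(x$sets[[lab]], L = x$L,
                   path = file.path(dir, sprintf("chord_%s.png", safe)))
      }
    }
  } else stop("unsupported report object")
  invisible(dir)
}
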