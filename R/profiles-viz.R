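#' Per-residue coordination numbers
#'
#' The coordination number of a residue is the number of contacts it is
#' involved in; summed over the chain it equals twice the number of
#' contacts (each contact touches two residues).
#'
#' @param set a [contact_set].
#' @param L chain length; all contact indices must be \code{<= L}.
#' @return An object of class \code{coordination_profile}: integer vector
#'   of length L with attributes \code{n_contacts} and \code{n_involved}
#'   (residues with count > 0).
#' @export
coordination_numbers <- function(set, L) {
  stopifnot(L >= 1)
  if (nrow(set) && max(set$j) > L)
    stop("contact index exceeds L = ", L)
  counts <- tabulate(c(set$i, set$j), nbins = L)
  structure(counts, n_contacts = nrow(set),
            n_involved = sum(counts > 0),
            class = "coordination_profile")
}

#' @export
print.coordination_profile <- function(x, ...) {
  cat(sprintf("Coordination profile over %d residues: %d contacts, %d residues involved\n",
              length(x), attr(x, "n_contacts"), attr(x, "n_involved")))
  invisible(x)
}

## open a graphics device chosen by file extension; NULL path = no device
open_device <- function(path, width = 7, height = 7) {
  if (is.null(path)) return(FALSE)
  ext <- tolower(sub(".*\\.", "", path))
  switch(ext,
         png = grDevices::png(path, width = width, height = height,
                              units = "in", res = 120),
         svg = grDevices::svg(path, width = width, height = height),
         pdf = grDevices::pdf(path, width = width, height = height),
         stop("unsupported plot format: .", ext))
  TRUE
}

## sidecar TSV next to a plot file
sidecar_path <- function(path) sub("\\.[^.]*$", ".tsv", path)

write_sidecar <- function(df, path) {
  utils::write.table(df, sidecar_path(path), sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Plot contact maps with an optional native background
#'
#' Square L x L contact map. Native contacts are drawn in gray in both
#' triangles; each predicted set is overlaid with its own color/symbol in
#' both triangles. Alongside the image file a TSV of the plotted
#' coordinates is written, and the same table is returned invisibly so
#' the plot's content is testable as data.
#'
#' @param pred_sets a [contact_set] or list of them.
#' @param native optional native [contact_set] for the background.
#' @param L chain length (axis limit); resolved from the sets if missing.
#' @param path output image path (.png, .svg or .pdf); \code{NULL} draws
#'   on the current device.
#' @return Invisibly, a data frame of plotted points
#'   (\code{source, i, j}).
#' @export
plot_contact_map <- function(pred_sets, native = NULL, L = NULL,
                             path = NULL) {
  if (inherits(pred_sets, "contact_set")) pred_sets <- list(pred_sets)
  if (is.null(L)) {
    idx <- unlist(c(lapply(pred_sets, `[[`, "j"),
                    if (!is.null(native)) native$j))
    L <- max(idx, 1)
  }
  pts <- list()
  if (!is.null(native) && nrow(native))
    pts[["native"]] <- data.frame(source = "native",
                                  i = c(native$i, native$j),
                                  j = c(native$j, native$i))
  for (s in pred_sets) {
    lab <- attr(s, "source")
    if (nrow(s))
      pts[[lab]] <- data.frame(source = lab, i = c(s$i, s$j),
                               j = c(s$j, s$i))
  }
  dat <- if (length(pts)) do.call(rbind, pts) else
    data.frame(source = character(), i = integer(), j = integer())
  rownames(dat) <- NULL
  dev <- open_device(path)
  if (dev || !is.null(grDevices::dev.list())) {
    graphics::plot(NA, xlim = c(1, L), ylim = c(1, L), asp = 1,
                   xlab = "residue i", ylab = "residue j",
                   main = "Contact map")
    if (!is.null(native) && nrow(native)) {
      with(pts[["native"]],
           graphics::points(i, j, pch = 15, col = "gray80", cex = 0.7))
    }
    cols <- grDevices::hcl.colors(max(2, length(pred_sets)), "Dark 3")
    for (k in seq_along(pred_sets)) {
      s <- pred_sets[[k]]
      if (nrow(s))
        graphics::points(c(s$i, s$j), c(s$j, s$i), pch = k,
                         col = cols[k], cex = 0.8)
    }
    labs <- vapply(pred_sets, attr, "", "source")
    graphics::legend("topleft", legend = c(if (!is.null(native)) "native",
                                           labs),
                     pch = c(if (!is.null(native)) 15,
                             seq_along(pred_sets)),
                     col = c(if (!is.null(native)) "gray80",
                             cols[seq_along(pred_sets)]),
                     bty = "n", cex = 0.8)
  }
  if (dev) { grDevices::dev.off(); write_sidecar(dat, path) }
  invisible(dat)
}

#' Chord diagram of a contact set
#'
#' Residues 1..L sit on a circle (residue 1 at angle 0, positions
#' counter-clockwise); each contact is one chord joining its two residue
#' positions, so clustered predictions and untouched regions (e.g.
#' disordered termini with no predicted contacts) are immediately
#' visible.
#'
#' @param set a [contact_set] with indices \code{<= L}.
#' @param L chain length.
#' @param path output image path, or \code{NULL}.
#' @return Invisibly, a data frame of chords with endpoint angles
#'   (\code{i, j, theta_i, theta_j}).
#' @export
plot_chord <- function(set, L, path = NULL) {
  if (nrow(set) && max(set$j) > L) stop("contact index exceeds L = ", L)
  if (nrow(set) == 0L) warning("empty contact set: drawing circle only")
  theta <- function(r) 2 * pi * (r - 1) / L
  dat <- data.frame(i = set$i, j = set$j,
                    theta_i = theta(set$i), theta_j = theta(set$j))
  dev <- open_device(path)
  if (dev || !is.null(grDevices::dev.list())) {
    graphics::plot(NA, xlim = c(-1.2, 1.2), ylim = c(-1.2, 1.2), asp = 1,
                   axes = FALSE, xlab = "", ylab = "",
                   main = sprintf("Chord diagram: %s", attr(set, "source")))
    tt <- seq(0, 2 * pi, length.out = 360)
    graphics::lines(cos(tt), sin(tt), col = "gray60")
    ticks <- unique(c(1, seq(10, L, by = 10)))
    graphics::text(1.12 * cos(theta(ticks)), 1.12 * sin(theta(ticks)),
                   ticks, cex = 0.6)
    if (nrow(dat))
      graphics::segments(cos(dat$theta_i), sin(dat$theta_i),
                         cos(dat$theta_j), sin(dat$theta_j),
                         col = grDevices::adjustcolor("steelblue", 0.6))
  }
  if (dev) { grDevices::dev.off(); write_sidecar(dat, path) }
  invisible(dat)
}

#' Heatmap and dendrogram of a similarity matrix
#'
#' Heatmap with rows and columns in dendrogram leaf order, beside the
#' dendrogram from [cluster_order()]; the matrix is also written as a
#' labeled TSV sidecar.
#'
#' @param matrix a \code{contact_similarity}.
#' @param order result of [cluster_order()]; computed if missing.
#' @param path output image path, or \code{NULL}.
#' @return Invisibly, a list with the reordered matrix and the leaf
#'   order.
#' @export
plot_similarity <- function(matrix, order = NULL, path = NULL) {
  if (is.null(order)) order <- cluster_order(matrix)
  m <- unclass(matrix)[order$order, order$order]
  dev <- open_device(path, width = 9, height = 5)
  if (dev || !is.null(grDevices::dev.list())) {
    op <- graphics::par(mfrow = c(1, 2), mar = c(6, 6, 3, 1))
    on.exit(graphics::par(op), add = TRUE)
    n <- nrow(m)
    graphics::image(seq_len(n), seq_len(n), t(m[n:1, , drop = FALSE]),
                    col = grDevices::hcl.colors(50, "YlOrRd", rev = TRUE),
                    zlim = c(0, 1), axes = FALSE, xlab = "", ylab = "",
                    main = sprintf("Jaccard similarity (N = %d)",
                                   attr(matrix, "N")))
    graphics::axis(1, seq_len(n), colnames(m), las = 2, cex.axis = 0.8)
    graphics::axis(2, seq_len(n), rev(rownames(m)), las = 2, cex.axis = 0.8)
    graphics::plot(order$hclust, main = "Dendrogram (1 - J, average linkage)",
                   xlab = "", sub = "")
  }
  if (dev) {
    grDevices::dev.off()
    utils::write.table(round(m, 6), sidecar_path(path), sep = "\t",
                       quote = FALSE, col.names = NA)
  }
  invisible(list(matrix = m, order = order$order))
}

#' Line charts of evaluation measures across selection groups
#'
#' One chart per measure (precision, coverage, mean FP error, Xd, spread)
#' with the six selection groups on the x axis and one line per
#' prediction source; undefined values appear as gaps.
#'
#' @param report a \code{contact_evaluation} from [evaluate_contacts()].
#' @param path output image path, or \code{NULL}.
#' @return Invisibly, the long-format data frame behind the charts
#'   (\code{source, group, measure, value}).
#' @export
plot_measures <- function(report, path = NULL) {
  tab <- report$metrics
  measures <- c("precision", "coverage", "mean_fp_error", "xd", "spread")
  long <- do.call(rbind, lapply(measures, function(m)
    data.frame(source = tab$source, group = tab$group, measure = m,
               value = tab[[m]])))
  dev <- open_device(path, width = 10, height = 7)
  if (dev || !is.null(grDevices::dev.list())) {
    op <- graphics::par(mfrow = c(2, 3), mar = c(7, 4, 3, 1))
    on.exit(graphics::par(op), add = TRUE)
    groups <- unique(tab$group)
    srcs <- unique(tab$source)
    cols <- grDevices::hcl.colors(max(2, length(srcs)), "Dark 3")
    for (m in measures) {
      sub <- long[long$measure == m, ]
      ylim <- if (all(is.na(sub$value))) c(0, 1)
              else range(sub$value, na.rm = TRUE)
      if (!all(is.finite(ylim))) ylim <- c(0, 1)
      graphics::plot(NA, xlim = c(1, length(groups)), ylim = ylim,
                     xaxt = "n", xlab = "", ylab = m, main = m)
      graphics::axis(1, seq_along(groups), groups, las = 2)
      for (k in seq_along(srcs)) {
        v <- sub$value[sub$source == srcs[k]][match(groups,
                sub$group[sub$source == srcs[k]])]
        graphics::lines(seq_along(groups), v, col = cols[k], type = "b",
                        pch = k)
      }
    }
    graphics::plot.new()
    graphics::legend("center", legend = srcs, col = cols[seq_along(srcs)],
                     pch = seq_along(srcs), lty = 1, bty = "n")
  }
  if (dev) { grDevices::dev.off(); write_sidecar(long, path) }
  invisible(long)
}
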