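#' Confusion counts for contact prediction
#'
#' @param TP,FP,TN,FN non-negative integers.
#' @param Nc number of true contacts in the native structure for the
#'   evaluated range; defaults to \code{TP + FN}.
#' @return An object of class \code{confusion_counts}.
#' @export
confusion_counts <- function(TP, FP, TN = 0, FN = 0, Nc = TP + FN) {
  stopifnot(TP >= 0, FP >= 0, TN >= 0, FN >= 0, TP <= Nc)
  structure(list(TP = TP, FP = FP, TN = TN, FN = FN, Nc = Nc),
            class = "confusion_counts")
}

#' Precision of a predicted contact list
#'
#' The fraction of the evaluated predictions that are native contacts,
#' TP / (TP + FP).
#'
#' @param counts a [confusion_counts].
#' @return Precision in \code{[0, 1]}; \code{NA} when no predictions were
#'   evaluated (TP + FP = 0).
#' @export
contact_precision <- function(counts) {
  with(counts, if (TP + FP == 0) NA_real_ else TP / (TP + FP))
}

#' Coverage of the native contacts
#'
#' The fraction of native contacts recovered by the prediction, TP / Nc.
#'
#' @param counts a [confusion_counts].
#' @return Coverage in \code{[0, 1]}; \code{NA} when the native has no
#'   contacts in the evaluated range (Nc = 0).
#' @export
contact_coverage <- function(counts) {
  with(counts, if (Nc == 0) NA_real_ else TP / Nc)
}

## TP/FP split of a selection against native distances: a prediction is
## correct when its native distance is strictly below d
score_selection <- function(pred, structure, defn) {
  d_ij <- native_distance(structure, pred$i, pred$j)
  if (anyNA(d_ij))
    stop("selection contains pairs absent from the structure; ",
         "apply filter_against_native() first")
  pred$distance <- d_ij
  list(pred = pred, tp = sum(d_ij < defn$d), fp = sum(d_ij >= defn$d))
}

#' Mean false-positive error
#'
#' The mean excess distance over the contact threshold among incorrectly
#' predicted contacts: \eqn{(1/FP) \sum (d_{ij} - d)} where \eqn{d_{ij}} is
#' the native distance of each false-positive pair.
#'
#' @param pred a [contact_set], already filtered against the structure.
#' @param structure a \code{native_structure}.
#' @param defn a [contact_definition].
#' @return Mean error in Angstrom; \code{NA} when there are no false
#'   positives (reported as undefined, never as 0).
#' @export
mean_fp_error <- function(pred, structure, defn = contact_definition()) {
  sc <- score_selection(pred, structure, defn)
  fp_d <- sc$pred$distance[sc$pred$distance >= defn$d]
  if (length(fp_d) == 0L) return(NA_real_)
  mean(fp_d - defn$d)
}

#' Binned distance distribution over 0-60 Angstrom
#'
#' Fifteen 4-Angstrom bins \code{((i-1)*4, i*4]}; distances above 60 are
#' clamped into the last bin; masses are percentages summing to 100 for a
#' non-empty input.
#'
#' @param distances numeric vector of distances in Angstrom.
#' @return An object of class \code{distance_histogram}: numeric length 15
#'   (percent), with attribute \code{n} (number of distances binned).
#' @export
distance_histogram <- function(distances) {
  distances <- distances[!is.na(distances)]
  stopifnot(all(distances >= 0))
  counts <- numeric(15)
  if (length(distances)) {
    bins <- pmin(pmax(ceiling(distances / 4), 1L), 15L)
    tab <- tabulate(bins, nbins = 15L)
    counts <- 100 * tab / length(distances)
  }
  structure(counts, n = length(distances), class = "distance_histogram")
}

#' Distance-distribution score Xd
#'
#' Compares the binned native-distance distribution of the predicted pairs
#' (PiP) against a reference distribution (PiA) over 15 bins spanning
#' 0-60 Angstrom:
#' \deqn{X_d = \sum_{i=1}^{15} \frac{PiP_i - PiA_i}{d_i \cdot 15}}
#' with \eqn{d_i = 4i/60}, the bin's upper limit normalized to 60. By
#' default PiA is built from the native-contact distances (so it is zero in
#' every bin above 8 Angstrom); \code{reference = "all_pairs"} instead uses
#' the distances of all candidate pairs. Values near 0 indicate a random
#' prediction; larger positive values indicate predicted pairs concentrated
#' at short native distances.
#'
#' @param pred_hist [distance_histogram] of the predicted pairs' native
#'   distances.
#' @param native_hist [distance_histogram] of the reference distances.
#' @return The score; \code{NA} if the predicted histogram is empty.
#' @export
xd_score <- function(pred_hist, native_hist) {
  if (attr(pred_hist, "n") == 0L) return(NA_real_)
  d_i <- (4 * seq_len(15)) / 60
  sum((as.numeric(pred_hist) - as.numeric(native_hist)) / (d_i * 15))
}

## convenience wrapper building both histograms from a scored selection
xd_from_selection <- function(pred, structure, native_set,
                              defn = contact_definition(),
                              reference = c("native_contacts", "all_pairs"),
                              universe = NULL) {
  reference <- match.arg(reference)
  sc <- score_selection(pred, structure, defn)
  ref_d <- if (reference == "native_contacts") native_set$distance
           else native_distance(structure, universe[, 1], universe[, 2])
  xd_score(distance_histogram(sc$pred$distance), distance_histogram(ref_d))
}

#' Contact-map spread
#'
#' The mean, over native contacts, of the Euclidean distance in
#' contact-map index space (each residue of sequence separation is one
#' unit) from the native contact to the nearest predicted contact. Zero
#' exactly when every native contact is predicted.
#'
#' @param pred,native [contact_set]s with canonical \code{i < j}.
#' @return Mean distance in index units; \code{NA} when either set is
#'   empty.
#' @export
contact_spread <- function(pred, native) {
  if (nrow(native) == 0L || nrow(pred) == 0L) return(NA_real_)
  di <- outer(native$i, pred$i, "-")
  dj <- outer(native$j, pred$j, "-")
  mean(sqrt(apply(di^2 + dj^2, 1, min)))
}

#' Full-list confusion counts
#'
#' Partitions the candidate universe into TP/FP/TN/FN, taking as predicted
#' positives every listed pair with confidence strictly above 0.5.
#'
#' @param pred a [contact_set] (the full filtered list, not a selection).
#' @param native the native [contact_set] for the same range.
#' @param universe two-column matrix of candidate pairs
#'   (see [candidate_pairs()]).
#' @return A [confusion_counts] with \code{TP + FN = Nc}.
#' @export
confusion_full <- function(pred, native, universe) {
  if (nrow(universe) == 0L) stop("empty candidate universe")
  ukey <- pair_key(universe[, 1], universe[, 2])
  pos_key <- pair_key(pred$i, pred$j)[pred$confidence > 0.5]
  nat_key <- pair_key(native$i, native$j)
  is_pos <- ukey %in% pos_key
  is_nat <- ukey %in% nat_key
  confusion_counts(TP = sum(is_pos & is_nat), FP = sum(is_pos & !is_nat),
                   TN = sum(!is_pos & !is_nat), FN = sum(!is_pos & is_nat))
}

#' Matthews correlation coefficient
#'
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}
#'   {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}}
#' A zero factor in the denominator yields 0 (standard convention).
#'
#' @param counts a [confusion_counts] from [confusion_full()].
#' @return MCC in \code{[-1, 1]}.
#' @export
contact_mcc <- function(counts) {
  with(counts, {
    den <- as.numeric(TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
    if (den == 0) return(0)
    (as.numeric(TP) * TN - as.numeric(FP) * FN) / sqrt(den)
  })
}

## assign every universe pair a score: its RR confidence, or 0 if unlisted;
## returns scores and the true-contact labels
universe_scores <- function(pred, native, universe) {
  ukey <- pair_key(universe[, 1], universe[, 2])
  m <- match(ukey, pair_key(pred$i, pred$j))
  scores <- ifelse(is.na(m), 0, pred$confidence[m])
  labels <- ukey %in% pair_key(native$i, native$j)
  list(scores = scores, labels = labels)
}

## one threshold sweep shared by ROC and PR: descending unique scores,
## each tie group processed as a unit
sweep_thresholds <- function(scores, labels) {
  P <- sum(labels); N <- sum(!labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  grp <- match(scores, thr)
  tp <- cumsum(tabulate(grp[labels], nbins = length(thr)))
  fp <- cumsum(tabulate(grp[!labels], nbins = length(thr)))
  list(threshold = thr, tp = tp, fp = fp, P = P, N = N)
}

#' ROC curve over the candidate universe
#'
#' Every candidate pair is scored by its RR confidence (0 if unlisted);
#' the (FPR, TPR) curve is swept over descending score thresholds with
#' tied scores processed as one group, and the AUC computed by the
#' trapezoid rule.
#'
#' @inheritParams confusion_full
#' @return List with \code{points} (data frame: threshold, fpr, tpr) and
#'   \code{auc}; \code{auc} is \code{NA} when the universe has no
#'   positives or no negatives.
#' @export
roc_points <- function(pred, native, universe) {
  us <- universe_scores(pred, native, universe)
  sw <- sweep_thresholds(us$scores, us$labels)
  if (sw$P == 0L || sw$N == 0L)
    return(list(points = data.frame(threshold = numeric(), fpr = numeric(),
                                    tpr = numeric()),
                auc = NA_real_))
  fpr <- c(0, sw$fp / sw$N); tpr <- c(0, sw$tp / sw$P)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(threshold = c(Inf, sw$threshold),
                           fpr = fpr, tpr = tpr),
       auc = auc)
}

#' Precision-recall curve over the candidate universe
#'
#' Same threshold sweep as [roc_points()]; the area is integrated
#' step-wise, holding the precision observed at each threshold across the
#' recall gained there.
#'
#' @inheritParams confusion_full
#' @return List with \code{points} (data frame: threshold, recall,
#'   precision) and \code{auc_pr}; \code{NA} when the universe has no
#'   positives.
#' @export
pr_points <- function(pred, native, universe) {
  us <- universe_scores(pred, native, universe)
  sw <- sweep_thresholds(us$scores, us$labels)
  if (sw$P == 0L)
    return(list(points = data.frame(threshold = numeric(), recall = numeric(),
                                    precision = numeric()),
                auc_pr = NA_real_))
  recall <- sw$tp / sw$P
  precision <- sw$tp / (sw$tp + sw$fp)
  auc_pr <- sum(diff(c(0, recall)) * precision)
  list(points = data.frame(threshold = sw$threshold,
                           recall = recall, precision = precision),
       auc_pr = auc_pr)
}
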