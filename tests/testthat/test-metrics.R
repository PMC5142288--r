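test_that("precision and coverage follow their defining ratios", {
  expect_equal(contact_precision(confusion_counts(TP = 3, FP = 2, Nc = 10)), 0.6)
  expect_equal(contact_precision(confusion_counts(TP = 5, FP = 0, Nc = 10)), 1)
  expect_equal(contact_precision(confusion_counts(TP = 0, FP = 5, Nc = 10)), 0)
  expect_true(is.na(contact_precision(confusion_counts(TP = 0, FP = 0, Nc = 3))))
  expect_equal(contact_coverage(confusion_counts(TP = 4, FP = 1, Nc = 20)), 0.2)
  expect_equal(contact_coverage(confusion_counts(TP = 20, FP = 5, Nc = 20)), 1)
  expect_equal(contact_coverage(confusion_counts(TP = 0, FP = 5, Nc = 20)), 0)
  expect_true(is.na(contact_coverage(confusion_counts(TP = 0, FP = 2, Nc = 0))))
})

## straight-line structure: residue r at x = (r-1), so pair distances are
## controlled exactly by index differences
line_structure <- function(spacing, L = 40) {
  xyz <- cbind(spacing * (seq_len(L) - 1), 0, 0)
  structure(list(chain = "A", resno = seq_len(L), resid = rep("ALA", L),
                 atom_name = rep("CB", L), xyz = xyz,
                 sequence = paste(rep("A", L), collapse = ""), L = L,
                 dist = as.matrix(stats::dist(xyz))),
            class = "native_structure")
}

test_that("mean FP error averages the excess over the threshold, NA when no FPs", {
  st <- line_structure(1, 40)   # distance(i, j) = j - i
  defn <- contact_definition()
  ## FPs at native distances 10 and 12 -> mean(2, 4) = 3
  pred <- contact_set(c(1, 1), c(11, 13), c(0.9, 0.8))
  expect_equal(mean_fp_error(pred, st, defn), 3)
  ## single FP at 8.5
  st2 <- line_structure(8.5 / 34, 40)  # pair (1, 35) at exactly 8.5
  expect_equal(mean_fp_error(contact_set(1, 35, 0.9), st2, defn), 0.5)
  ## all predictions correct -> undefined, not zero
  st3 <- line_structure(0.2, 40)
  expect_true(is.na(mean_fp_error(contact_set(1, 8, 0.9), st3, defn)))
})

test_that("distance histogram bins, clamps, and normalizes to percent", {
  h <- distance_histogram(c(3, 3, 7))
  expect_equal(as.numeric(h)[1:2], c(200 / 3, 100 / 3))
  expect_equal(sum(as.numeric(h)), 100, tolerance = 1e-9)
  h75 <- distance_histogram(75)
  expect_equal(as.numeric(h75)[15], 100)
  h0 <- distance_histogram(numeric())
  expect_equal(as.numeric(h0), rep(0, 15))
  expect_equal(attr(h0, "n"), 0L)
  ## bin edges are (lo, hi]: 4.0 belongs to bin 1, 4.0001 to bin 2
  expect_equal(which(as.numeric(distance_histogram(4)) > 0), 1)
  expect_equal(which(as.numeric(distance_histogram(4.0001)) > 0), 2)
})

test_that("Xd matches the 15-term sum and its sign convention", {
  ## identical distributions -> 0
  h <- distance_histogram(c(3, 5, 9))
  expect_equal(xd_score(h, h), 0)
  ## constructed two-bin case: PiP all in bin 1, PiA split over bins 1-2
  pp <- distance_histogram(rep(2, 10))
  pa <- distance_histogram(c(rep(2, 5), rep(6, 5)))
  expect_equal(xd_score(pp, pa), 25)
  expect_equal(oracle_xd(rep(2, 10), c(rep(2, 5), rep(6, 5))), 25)
  ## all predicted mass far, reference near -> negative
  far <- distance_histogram(rep(70, 4))
  near <- distance_histogram(rep(2, 4))
  v <- xd_score(far, near)
  expect_lt(v, 0)
  expect_equal(v, oracle_xd(rep(70, 4), rep(2, 4)))
  ## random draws agree with the independent loop oracle
  for (seed in 1:5) {
    set.seed(seed)
    pd <- runif(20, 0, 70); rd <- runif(15, 0, 10)
    expect_equal(xd_score(distance_histogram(pd), distance_histogram(rd)),
                 oracle_xd(pd, rd), tolerance = 1e-12)
  }
  ## empty prediction -> undefined
  expect_true(is.na(xd_score(distance_histogram(numeric()), near)))
})

test_that("spread is the mean nearest-prediction distance in contact-map space", {
  nat <- contact_set(c(1, 2), c(7, 9), 1)
  expect_equal(contact_spread(nat, nat), 0)
  pred <- contact_set(1, 7, 1)
  expect_equal(contact_spread(pred, nat), sqrt(5) / 2, tolerance = 1e-9)
  expect_equal(contact_spread(contact_set(11, 27, 1), contact_set(1, 7, 1)),
               sqrt(500), tolerance = 1e-9)
  ## undefined markers
  expect_true(is.na(contact_spread(contact_set(), nat)))
  expect_true(is.na(contact_spread(pred, contact_set())))
  ## zero iff every native contact is predicted
  sup <- contact_set(c(1, 2, 3), c(7, 9, 30), 1)
  expect_equal(contact_spread(sup, nat), 0)
  expect_gt(contact_spread(contact_set(c(1, 2), c(7, 10), 1), nat), 0)
})

test_that("full-list confusion partitions the universe at the 0.5 cut", {
  uni <- candidate_pairs(6, Inf, L = 20)
  nat <- contact_set(c(1, 2, 3), c(8, 10, 12), 1, L = 20)
  ## perfect prediction above the cut
  perfect <- contact_set(c(1, 2, 3), c(8, 10, 12), 0.9, L = 20)
  cc <- confusion_full(perfect, nat, uni)
  expect_equal(cc$FP, 0); expect_equal(cc$FN, 0)
  expect_equal(cc$TP, 3); expect_equal(cc$TP + cc$FN, cc$Nc)
  ## nothing above the cut
  low <- contact_set(c(1, 2, 3), c(8, 10, 12), 0.4, L = 20)
  cc2 <- confusion_full(low, nat, uni)
  expect_equal(cc2$TP, 0); expect_equal(cc2$FP, 0)
  expect_equal(cc2$FN, cc2$Nc)
  ## exactly 0.5 is NOT a positive (strictly more than 0.5)
  cc3 <- confusion_full(contact_set(1, 8, 0.5, L = 20), nat, uni)
  expect_equal(cc3$TP + cc3$FP, 0)
  expect_error(confusion_full(perfect, nat, matrix(integer(), ncol = 2)),
               "empty")
})

test_that("confusion counts match the exhaustive partition oracle on random instances", {
  for (seed in 1:6) {
    L <- 50
    uni <- candidate_pairs(6, Inf, L = L)
    nat <- random_set(L, 30, seed * 3, source = "nat")
    pred <- random_set(L, 40, seed * 3 + 1)
    cc <- confusion_full(pred, nat, uni)
    or <- oracle_confusion(pred, nat, uni)
    expect_equal(c(TP = cc$TP, FP = cc$FP, TN = cc$TN, FN = cc$FN), or)
  }
})

test_that("MCC follows the printed formula with the degenerate-zero rule", {
  expect_equal(contact_mcc(confusion_counts(TP = 3, FP = 1, TN = 94, FN = 2)),
               280 / sqrt(182400), tolerance = 1e-9)
  expect_equal(contact_mcc(confusion_counts(TP = 10, FP = 0, TN = 90, FN = 0)), 1)
  expect_equal(contact_mcc(confusion_counts(TP = 0, FP = 0, TN = 50, FN = 5)), 0)
  ## invariance under the (TP<->TN, FP<->FN) swap
  a <- contact_mcc(confusion_counts(TP = 7, FP = 3, TN = 80, FN = 10))
  b <- contact_mcc(confusion_counts(TP = 80, FP = 10, TN = 7, FN = 3))
  expect_equal(a, b)
})

test_that("ROC hits the perfect and all-tied identities, with tie groups", {
  uni <- candidate_pairs(6, Inf, L = 15)
  nat <- contact_set(c(1, 2), c(8, 10), 1, L = 15)
  ## all true contacts ranked above everything else
  perfect <- contact_set(c(1, 2), c(8, 10), c(0.9, 0.8), L = 15)
  expect_equal(roc_points(perfect, nat, uni)$auc, 1)
  ## all scores equal -> single tie group -> the diagonal
  flat <- contact_set(uni[, 1], uni[, 2], 0.7, L = 15)
  expect_equal(roc_points(flat, nat, uni)$auc, 0.5)
  ## no positives in the universe -> undefined
  expect_true(is.na(roc_points(perfect, contact_set(), uni)$auc))
})

test_that("ROC AUC equals the exhaustive pairwise-comparison oracle", {
  for (seed in 1:20) {
    L <- 30
    uni <- candidate_pairs(6, Inf, L = L)
    uni <- uni[seq_len(200), , drop = FALSE]
    nat <- random_set(L, 25, seed * 7, source = "nat")
    pred <- random_set(L, 40, seed * 7 + 3)
    r <- roc_points(pred, nat, uni)
    sc <- ifelse(is.na(match(paste(uni[, 1], uni[, 2]),
                             paste(pred$i, pred$j))),
                 0, pred$confidence[match(paste(uni[, 1], uni[, 2]),
                                          paste(pred$i, pred$j))])
    lab <- paste(uni[, 1], uni[, 2]) %in% paste(nat$i, nat$j)
    expect_equal(r$auc, oracle_auc(sc, lab), tolerance = 1e-12)
  }
})

test_that("random scores give chance-level AUC on average", {
  aucs <- vapply(1:20, function(seed) {
    L <- 30
    uni <- candidate_pairs(6, Inf, L = L)[1:200, ]
    set.seed(seed * 13 + 1)
    pos <- sample(200, 100)            # positives drawn within the universe
    nat <- contact_set(uni[pos, 1], uni[pos, 2], 1, source = "nat", L = L)
    set.seed(seed)
    pred <- contact_set(uni[, 1], uni[, 2], runif(200), L = L)
    roc_points(pred, nat, uni)$auc
  }, 0)
  expect_true(all(abs(aucs - 0.5) < 0.12))
})

test_that("precision-recall curve integrates step-wise and shares the sweep", {
  uni <- candidate_pairs(6, Inf, L = 15)
  nat <- contact_set(c(1, 2), c(8, 10), 1, L = 15)
  perfect <- contact_set(c(1, 2), c(8, 10), c(0.9, 0.8), L = 15)
  expect_equal(pr_points(perfect, nat, uni)$auc_pr, 1)
  ## single positive ranked last in a 10-pair universe -> AUC_PR = 0.1
  u10 <- uni[1:10, ]
  nat1 <- contact_set(u10[10, 1], u10[10, 2], 1, L = 15)
  pred10 <- contact_set(u10[, 1], u10[, 2],
                        seq(0.95, 0.05, length.out = 10), L = 15)
  expect_equal(pr_points(pred10, nat1, u10)$auc_pr, 0.1, tolerance = 1e-12)
  ## PR and ROC sweep the same thresholds
  pred <- random_set(15, 12, 99)
  roc <- roc_points(pred, nat, uni)
  pr <- pr_points(pred, nat, uni)
  expect_equal(pr$points$threshold, roc$points$threshold[-1])
  expect_true(is.na(pr_points(perfect, contact_set(), uni)$auc_pr))
})

test_that("per-group precision and coverage stay integral multiples of the counts", {
  inst <- make_instance(L = 40, p = 0.6, seed = 11)
  ev <- evaluate_contacts(inst$predictions, inst$structure)
  tab <- ev$metrics
  ok <- !is.na(tab$precision)
  expect_true(all(abs(tab$precision[ok] * (tab$TP + tab$FP)[ok] -
                      tab$TP[ok]) < 1e-9))
  Nc <- nrow(ev$native)
  expect_true(all(abs(tab$coverage * Nc - tab$TP) < 1e-9))
})

test_that("ROC AUC agrees with an independent ROC library", {
  for (seed in c(3, 17)) {
    L <- 40
    uni <- candidate_pairs(6, Inf, L = L)
    nat <- random_set(L, 60, seed * 19, source = "nat")
    pred <- random_set(L, 80, seed * 19 + 5)
    r <- roc_points(pred, nat, uni)
    key <- paste(uni[, 1], uni[, 2])
    m <- match(key, paste(pred$i, pred$j))
    sc <- ifelse(is.na(m), 0, pred$confidence[m])
    lab <- key %in% paste(nat$i, nat$j)
    ref <- suppressMessages(pROC::auc(pROC::roc(lab, sc, quiet = TRUE)))
    expect_equal(r$auc, as.numeric(ref), tolerance = 1e-9)
  }
})
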