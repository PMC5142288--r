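## Independent brute-force oracles used to validate the package's
## implementations. These deliberately share no code with R/: plain double
## loops and exhaustive enumeration only.

## random contact set over chain length L
random_set <- function(L, n, seed, source = "rand") {
  set.seed(seed)
  pairs <- which(upper.tri(diag(L)), arr.ind = TRUE)
  pairs <- pairs[pairs[, 2] - pairs[, 1] >= 6, , drop = FALSE]
  idx <- sample(nrow(pairs), min(n, nrow(pairs)))
  contact_set(i = pairs[idx, 1], j = pairs[idx, 2],
              confidence = stats::runif(length(idx)),
              source = source, L = L)
}

## random-coordinate structure (no self-avoidance; box scaled so that a
## reasonable fraction of pairs falls under 8 A)
random_structure <- function(L, seed) {
  set.seed(seed)
  side <- 2.8 * L^(1/3) * 2
  xyz <- matrix(stats::runif(3 * L, 0, side), L, 3)
  structure(list(chain = "A", resno = seq_len(L),
                 resid = rep("ALA", L), atom_name = rep("CB", L),
                 xyz = xyz, sequence = paste(rep("A", L), collapse = ""),
                 L = L, dist = as.matrix(stats::dist(xyz))),
            class = "native_structure")
}

## O(L^2) scan for native contacts
oracle_native_pairs <- function(st, d = 8, min_sep = 6) {
  out <- NULL
  for (a in 1:(st$L - 1)) for (b in (a + 1):st$L) {
    ra <- st$resno[a]; rb <- st$resno[b]
    if (abs(rb - ra) < min_sep) next
    dd <- sqrt(sum((st$xyz[a, ] - st$xyz[b, ])^2))
    if (dd < d) out <- rbind(out, c(min(ra, rb), max(ra, rb)))
  }
  if (is.null(out)) matrix(integer(), ncol = 2) else out
}

## mean FP error by definition
oracle_mfe <- function(pred, st, d = 8) {
  errs <- c()
  for (k in seq_len(nrow(pred))) {
    dd <- st$dist[match(pred$i[k], st$resno), match(pred$j[k], st$resno)]
    if (dd >= d) errs <- c(errs, dd - d)
  }
  if (length(errs) == 0) NA_real_ else mean(errs)
}

## spread by double loop
oracle_spread <- function(pred, native) {
  if (nrow(pred) == 0 || nrow(native) == 0) return(NA_real_)
  tot <- 0
  for (t in seq_len(nrow(native))) {
    best <- Inf
    for (p in seq_len(nrow(pred))) {
      dd <- sqrt((native$i[t] - pred$i[p])^2 + (native$j[t] - pred$j[p])^2)
      if (dd < best) best <- dd
    }
    tot <- tot + best
  }
  tot / nrow(native)
}

## exhaustive four-way partition of the universe
oracle_confusion <- function(pred, native, universe, cut = 0.5) {
  tp <- fp <- tn <- fn <- 0
  pk <- paste(pred$i, pred$j)[pred$confidence > cut]
  nk <- paste(native$i, native$j)
  for (r in seq_len(nrow(universe))) {
    key <- paste(universe[r, 1], universe[r, 2])
    pos <- key %in% pk; nat <- key %in% nk
    if (pos && nat) tp <- tp + 1
    else if (pos) fp <- fp + 1
    else if (nat) fn <- fn + 1
    else tn <- tn + 1
  }
  c(TP = tp, FP = fp, TN = tn, FN = fn)
}

## exhaustive maximum-cardinality matching on the +/-N compatibility graph
## (branch over all assignments; use only on small sets)
oracle_match <- function(A, B, N) {
  nA <- nrow(A); nB <- nrow(B)
  if (nA == 0 || nB == 0) return(0L)
  compat <- matrix(FALSE, nA, nB)
  for (a in seq_len(nA)) for (b in seq_len(nB))
    compat[a, b] <- abs(A$i[a] - B$i[b]) <= N && abs(A$j[a] - B$j[b]) <= N
  best <- 0L
  recurse <- function(a, used, count) {
    if (count + (nA - a + 1) <= best) return()
    if (a > nA) { best <<- max(best, count); return() }
    for (b in which(compat[a, ] & !used)) {
      used[b] <- TRUE
      recurse(a + 1, used, count + 1L)
      used[b] <- FALSE
    }
    recurse(a + 1, used, count)
  }
  recurse(1L, logical(nB), 0L)
  best
}

## AUC by exhaustive pairwise comparison (ties count half)
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

## Xd by an independent 15-term loop
oracle_xd <- function(pred_d, ref_d) {
  bin_of <- function(x) min(max(ceiling(x / 4), 1), 15)
  pp <- rep(0, 15); pa <- rep(0, 15)
  for (x in pred_d) pp[bin_of(x)] <- pp[bin_of(x)] + 100 / length(pred_d)
  for (x in ref_d) pa[bin_of(x)] <- pa[bin_of(x)] + 100 / length(ref_d)
  s <- 0
  for (i in 1:15) s <- s + (pp[i] - pa[i]) / ((4 * i / 60) * 15)
  s
}

## minimal hand-written PDB text for reader tests
write_mini_pdb <- function(path, lines) writeLines(lines, path)

pdb_atom_line <- function(serial, name, alt, resn, chain, resno, x, y, z,
                          occ = 1, type = "ATOM") {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          type, serial, ifelse(nchar(name) < 4, paste0(" ", name), name),
          alt, resn, chain, resno, x, y, z, occ, 0)
}
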