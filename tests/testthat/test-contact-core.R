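## a structure with hand-placed distances around the 8 A boundary
boundary_structure <- function() {
  xyz <- rbind(c(0, 0, 0), c(50, 0, 0), c(60, 0, 0), c(70, 0, 0),
               c(80, 0, 0), c(90, 0, 0),
               c(7.9, 0, 0),    # residue 7: 7.9 A from residue 1 (sep 6)
               c(0, 8.1, 0),    # residue 8: 8.1 A from residue 1 (sep 7)
               c(0, 50, 0))     # residue 9: far from everything
  structure(list(chain = "A", resno = 1:9, resid = rep("ALA", 9),
                 atom_name = rep("CB", 9), xyz = xyz,
                 sequence = paste(rep("A", 9), collapse = ""), L = 9,
                 dist = as.matrix(stats::dist(xyz))),
            class = "native_structure")
}

test_that("native contacts use strict inequality at the distance threshold", {
  st <- boundary_structure()
  nat <- native_contacts(st, contact_definition())
  keys <- paste(nat$i, nat$j)
  expect_true("1 7" %in% keys)    # 7.9 A, separation 6
  expect_false("1 8" %in% keys)   # 8.1 A
  expect_false("2 8" %in% keys)   # separation 6 but far apart
  expect_true(all(nat$distance < 8))
  expect_true(all(nat$j - nat$i >= 6))
})

test_that("an extended chain has no long-range contacts", {
  st <- make_structure(40, "extended", seed = 1)
  nat <- filter_range(native_contacts(st), 24, Inf)
  expect_equal(nrow(nat), 0)
})

test_that("native_contacts agrees with the brute-force distance scan", {
  for (seed in 1:8) {
    L <- sample(30:80, 1)
    st <- random_structure(L, seed * 11)
    nat <- native_contacts(st, contact_definition())
    oracle <- oracle_native_pairs(st)
    expect_equal(nrow(nat), nrow(oracle))
    expect_setequal(paste(nat$i, nat$j),
                    if (nrow(oracle)) paste(oracle[, 1], oracle[, 2])
                    else character())
  }
})

test_that("filter_range keeps exactly the in-range separations and is idempotent", {
  cs <- contact_set(i = c(3, 3, 1, 2), j = c(30, 20, 7, 40),
                    confidence = c(0.9, 0.8, 0.7, 0.6))
  lr <- filter_range(cs, 24, Inf)
  expect_setequal(paste(lr$i, lr$j), c("3 30", "2 40"))
  expect_equal(as.data.frame(filter_range(lr, 24, Inf)), as.data.frame(lr))
  ## identity on a canonical set with the minimum separation bound
  all6 <- filter_range(cs, 6, Inf)
  expect_equal(nrow(all6), 4)
})

test_that("select_top ranks by confidence then (i, j), and is idempotent", {
  cs <- contact_set(i = c(1, 2, 3), j = c(9, 10, 11),
                    confidence = c(0.9, 0.8, 0.7))
  expect_equal(select_top(cs, 2)$confidence, c(0.9, 0.8))
  expect_equal(nrow(select_top(cs, 10)), 3)
  tied <- contact_set(i = c(5, 1, 3), j = c(20, 30, 9),
                      confidence = 0.5)
  expect_equal(select_top(tied, 1)$i, 1)  # smallest (i, j) wins the tie
  s2 <- select_top(tied, 2)
  expect_equal(as.data.frame(select_top(s2, 2)), as.data.frame(s2))
})

test_that("selection sizes follow the floor-with-minimum-1 rule", {
  expect_equal(unname(selection_sizes(150)), c(5, 15, 30, 75, 150, 300))
  expect_equal(unname(selection_sizes(7)), c(5, 1, 1, 3, 7, 14))
  expect_equal(selection_sizes(10)[["L/10"]], 1)
  ## sizes non-decreasing across groups for L >= 50
  for (L in c(50, 73, 200)) {
    expect_true(all(diff(unname(selection_sizes(L))) >= 0))
  }
})

test_that("L resolution prefers structure, then sequence, then max index", {
  st <- make_structure(130, "extended", seed = 1)
  cs <- contact_set(1, 97, 0.5, sequence = paste(rep("A", 140), collapse = ""))
  expect_equal(resolve_L(cs, st), 130)
  expect_equal(resolve_L(cs), 140)
  bare <- contact_set(1, 97, 0.5)
  expect_warning(Lhat <- resolve_L(bare), "largest residue index")
  expect_equal(Lhat, 97)
})

test_that("native filtering drops exactly the pairs outside the structure", {
  ## domain covering author residues 30..120 with an internal gap 50..59
  resno <- setdiff(30:120, 50:59)
  L <- length(resno)
  xyz <- cbind(3.8 * seq_len(L), 0, 0)
  st <- structure(list(chain = "A", resno = resno,
                       resid = rep("ALA", L), atom_name = rep("CB", L),
                       xyz = xyz, sequence = paste(rep("A", L), collapse = ""),
                       L = L, dist = as.matrix(stats::dist(xyz))),
                  class = "native_structure")
  cs <- random_set(130, 60, seed = 3)
  kept <- filter_against_native(cs, st)
  ## conservation: kept + removed = input
  expect_equal(nrow(kept) + attr(kept, "removed"), nrow(cs))
  ## brute-force membership oracle
  ok <- vapply(seq_len(nrow(cs)), function(k)
    (cs$i[k] %in% resno) && (cs$j[k] %in% resno), TRUE)
  expect_equal(nrow(kept), sum(ok))
  expect_setequal(paste(kept$i, kept$j), paste(cs$i[ok], cs$j[ok]))
  ## identity when everything is present
  allin <- contact_set(c(30, 40), c(60, 70), c(0.9, 0.8))
  kept2 <- filter_against_native(allin, st)
  expect_equal(nrow(kept2), 2)
  expect_equal(attr(kept2, "removed"), 0)
  ## contact (1, 40): residue 1 outside the domain
  out <- filter_against_native(contact_set(1, 40, 0.9), st)
  expect_equal(nrow(out), 0)
})

test_that("positional mapping applies when the RR sequence matches the structure", {
  st <- make_structure(30, "helix", seed = 2)
  st$resno <- st$resno + 100   # author numbering offset
  cs <- contact_set(c(1, 2), c(10, 28), c(0.9, 0.8),
                    sequence = st$sequence)
  mapped <- map_to_structure(cs, st)
  expect_equal(attr(mapped, "mapping"), "position")
  expect_equal(mapped$i, c(101, 102))
  ## mismatching sequence falls back to author numbering with a warning
  cs2 <- contact_set(1, 10, 0.9, sequence = "MKVLA")
  expect_warning(m2 <- map_to_structure(cs2, st), "does not match")
  expect_equal(attr(m2, "mapping"), "resno")
  expect_equal(m2$i, 1)
})

test_that("candidate pairs enumerate exactly the in-range residue pairs", {
  st <- random_structure(20, 5)
  uni <- candidate_pairs(6, 11, structure = st)
  ## brute force
  cnt <- 0
  for (a in 1:19) for (b in (a + 1):20) if (b - a >= 6 && b - a <= 11)
    cnt <- cnt + 1
  expect_equal(nrow(uni), cnt)
  expect_true(all(uni[, 2] - uni[, 1] >= 6 & uni[, 2] - uni[, 1] <= 11))
  uni2 <- candidate_pairs(24, Inf, L = 30)
  expect_equal(nrow(uni2), sum(30 - (24:29)))
})
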