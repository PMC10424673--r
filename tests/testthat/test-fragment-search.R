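# Superposition solver, window enumeration, scoring and the ranked scan.

test_that("superposition of identical and rigidly moved point sets is exact", {
  set.seed(31)
  P <- matrix(rnorm(24), ncol = 3)
  sp <- superpose(P, P)
  expect_equal(sp$rmsd, 0, tolerance = 1e-12)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-9)
  for (k in 1:5) {
    ang <- runif(3, -pi, pi)
    R <- euler_rotation(ang[1], ang[2], ang[3])
    Q <- P %*% t(R) + matrix(runif(3, -20, 20), nrow(P), 3, byrow = TRUE)
    sp <- superpose(P, Q)
    expect_lt(sp$rmsd, 1e-10)
    expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
    expect_lt(max(abs(apply_superposition(sp, P) - Q)), 1e-9)
  }
})

test_that("solver matches a brute-force rotation-search oracle on 4-point sets", {
  set.seed(33)
  for (k in 1:4) {
    P <- matrix(rnorm(12), ncol = 3)
    Q <- P %*% t(random_rot <- euler_rotation(runif(1, -pi, pi), runif(1, 0, pi),
                                              runif(1, -pi, pi))) +
      matrix(rnorm(12, sd = 1.0), ncol = 3)
    expect_equal(superpose(P, Q)$rmsd, oracle_superpose_rmsd(P, Q),
                 tolerance = 1e-3)
  }
  # a chiral pair: proper-rotation optimum must agree with the oracle,
  # which also only searches rotations
  P <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(0, 0, 2))
  Q <- P
  Q[, 3] <- -Q[, 3]
  expect_equal(superpose(P, Q)$rmsd, oracle_superpose_rmsd(P, Q),
               tolerance = 1e-3)
  expect_gt(superpose(P, Q)$rmsd, 0.5)  # the mirror is not reachable
})

test_that("ill-posed superpositions are rejected", {
  expect_error(superpose(matrix(rnorm(6), 2), matrix(rnorm(6), 2)),
               "at least 3")
  line <- cbind(1:4, 0, 0)
  expect_error(superpose(line, line + 1), "degenerate")
})

test_that("adding query atoms cannot reduce the fitted residual sum of squares", {
  set.seed(35)
  for (k in 1:6) {
    n <- 8
    P <- matrix(rnorm(3 * n), ncol = 3)
    Q <- P + matrix(rnorm(3 * n, sd = 0.5), ncol = 3)
    ss <- function(m) {
      r <- superpose(P[1:m, ], Q[1:m, ])$rmsd
      m * r^2
    }
    vals <- vapply(3:n, ss, 1)
    expect_true(all(diff(vals) >= -1e-9))
  }
})

test_that("window enumeration counts are chain_length - window + 1 per direction", {
  h <- build_ideal_helix(paste(rep("ADE", 14), collapse = ""))  # 42 residues
  h$atoms <- h$atoms[h$atoms$res_seq <= 40, ]
  lib <- build_library(list(h), min_chain_length = 14)
  expect_equal(nrow(enumerate_windows(lib, 14, "forward")), 27)
  expect_equal(nrow(enumerate_windows(lib, 14)), 54)
  expect_equal(nrow(enumerate_windows(lib, 41)), 0)
})

test_that("short chains are dropped from the library with a message", {
  long <- build_ideal_helix(paste(rep("A", 40), collapse = ""), entry_id = "LONG")
  short <- build_ideal_helix(paste(rep("A", 10), collapse = ""), entry_id = "SHORT")
  expect_message(lib <- build_library(list(long, short), min_chain_length = 14),
                 "dropped 1")
  expect_length(lib$entries, 1)
  expect_equal(lib$entries[[1]]$entry_id, "LONG")
  expect_error(build_library(list(short), min_chain_length = 14),
               "no usable chains")
})

test_that("library entries are mirrored: every chiral residue is D-flagged", {
  lib <- glp2_self_library()
  for (e in lib$entries) {
    chiral <- e$res_names != "GLY"
    expect_true(all(e$handedness[chiral] == "D"))
  }
})

test_that("a query matches the mirror of its own source segment in reverse at rmsd ~ 0", {
  h <- glp2_helix()
  qs <- glp2_queries(h)$helix1
  ca_query <- qs[[1]]  # combo 1-1-1: CA-level atoms at the three hotspots
  lib <- glp2_self_library(h)
  wins <- enumerate_windows(lib, 14, "reverse")
  own <- wins[wins$entry_id == "HELIX1" & wins$start == 0, ]
  m <- score_window(lib, ca_query, own)
  expect_null(m$skip)
  expect_lt(m$rmsd, 1e-6)
})

test_that("skips carry reasons: residue identity and missing atoms", {
  h <- glp2_helix()
  qs <- glp2_queries(h)
  lib <- glp2_self_library(h)
  # reverse window of the own segment has mismatched residues at hotspots
  wins <- enumerate_windows(lib, 14, "reverse")
  own <- wins[wins$entry_id == "HELIX1" & wins$start == 0, ]
  m <- score_window(lib, qs$helix1[[1]], own, identity_filter = TRUE)
  expect_equal(m$skip, "identity")
  # a tip-atom query scored on a window whose residues lack those atoms
  tip_query <- qs$helix1[[length(qs$helix1)]]
  wins3 <- enumerate_windows(lib, 14, "forward")
  other <- wins3[wins3$entry_id == "HELIX3", ][1, ]
  m2 <- score_window(lib, tip_query, other)
  expect_equal(m2$skip, "missing_atom")
})

test_that("planted noisy copies are found within the noise bound across seeds", {
  h <- glp2_helix()
  q <- glp2_queries(h)$helix1[[36]]  # full-detail combo
  sigma <- 0.3
  rmsds <- vapply(1:100, function(s) {
    lib <- plant_match(q, noise_sigma = sigma, seed = s, decoys = 0)
    pr <- search_fragments(list(q), lib, top_k = 1)
    pr$table$rmsd[1]
  }, 1)
  expect_true(all(rmsds >= 0 & rmsds <= 3 * sigma))
})

test_that("search equals exhaustive brute-force re-scoring on a small library", {
  set.seed(41)
  decoys <- random_helix_library(6, 20)
  h <- glp2_helix()
  qs <- glp2_queries(h)$helix2[c(1, 5, 14)]
  lib <- build_library(c(decoys, list(extract_segment(h, "A", 7, 19))),
                       min_chain_length = 13)
  wins <- enumerate_windows(lib, 13)
  expect_lte(nrow(wins), 200)
  pr <- search_fragments(qs, lib, top_k = 50)
  oracle <- oracle_search_table(qs, lib, 50, c("forward", "reverse"))
  got <- pr$table[, c("entry_id", "chain_id", "start", "direction",
                      "combo_id", "rmsd")]
  rownames(got) <- NULL
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("equal-RMSD windows are ordered by entry id then start then direction", {
  h <- build_ideal_helix("HAFDAEAAAHARFA", entry_id = "AAA")
  h2 <- h
  h2$entry_id <- "BBB"
  seg <- extract_segment(h, "A", 1, 14)
  hs <- define_hotspots(seg, data.frame(seq_id = c(1, 3, 6),
                                        res_name = c("H", "F", "E")))
  q <- enumerate_queries(hs, list(HIS = list("CA"), PHE = list("CA"),
                                  GLU = list("CA")))[[1]]
  lib <- build_library(list(h, h2), min_chain_length = 14)
  pr <- search_fragments(list(q), lib, top_k = 10, directions = "forward")
  ties <- pr$table[abs(pr$table$rmsd - pr$table$rmsd[1]) < 1e-12, ]
  expect_equal(ties$entry_id, sort(ties$entry_id))
})

test_that("enlarging the library never worsens the best match", {
  h <- glp2_helix()
  q <- glp2_queries(h)$helix1[[2]]
  set.seed(43)
  extra <- random_helix_library(4, 16)
  small <- plant_match(q, noise_sigma = 0.4, seed = 9, decoys = 5)
  big <- small
  big$entries <- c(small$entries,
                   build_library(extra, min_chain_length = 14)$entries)
  r_small <- search_fragments(list(q), small, top_k = 1)$table$rmsd[1]
  r_big <- search_fragments(list(q), big, top_k = 1)$table$rmsd[1]
  expect_lte(r_big, r_small + 1e-12)
})

test_that("rank-1 RMSD does not depend on the mirror plane", {
  h <- glp2_helix()
  q <- glp2_queries(h)$helix1[[36]]
  seg <- q$segment
  seg$entry_id <- "SRC"
  for (pl in c("xy", "yz", "xz")) {
    lib <- build_library(list(seg), min_chain_length = 14, plane = pl)
    pr <- search_fragments(list(q), lib, top_k = 1, directions = "forward")
    expect_lt(pr$table$rmsd[1], 1e-9)
  }
})

test_that("an all-skip scan raises an informative no-match error", {
  h <- glp2_helix()
  q <- glp2_queries(h)$helix1[[36]]
  poly <- build_ideal_helix(paste(rep("A", 20), collapse = ""))
  lib <- build_library(list(poly), min_chain_length = 14)
  expect_error(search_fragments(list(q), lib), "no matches.*missing_atom")
})

test_that("the helix pre-filter accepts ideal helices and rejects scrambled ones", {
  h <- build_ideal_helix(paste(rep("A", 20), collapse = ""))
  lib <- build_library(list(h), min_chain_length = 14)
  wins <- enumerate_windows(lib, 14, "forward")
  expect_true(all(helix_filter(lib, wins)))
  bent <- build_ideal_helix(paste(rep("A", 20), collapse = ""),
                            phi = c(rep(-57, 10), rep(-120, 10)),
                            psi = c(rep(-47, 10), rep(130, 10)))
  lib2 <- build_library(list(bent), min_chain_length = 14)
  expect_false(all(helix_filter(lib2, enumerate_windows(lib2, 14, "forward"))))
})
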