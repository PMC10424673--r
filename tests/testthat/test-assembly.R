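# Placement of matches and splicing into the d-peptide model.

test_that("midpoint crossovers give the canonical 1-10 / 11-17 / 18-31 split", {
  plan <- default_splice_plan(glp2_segment_ranges())
  expect_equal(plan$overlaps[[1]], c(7, 14))
  expect_equal(plan$overlaps[[2]], c(15, 19))
  expect_equal(plan$crossovers, c(10L, 17L))
  expect_equal(plan$contributions$helix1, c(1L, 10L))
  expect_equal(plan$contributions$helix2, c(11L, 17L))
  expect_equal(plan$contributions$helix3, c(18L, 31L))
  expect_error(default_splice_plan(list(a = c(1, 5), b = c(9, 14))),
               "do not overlap")
})

test_that("placed fragments reproduce the match RMSD at the hotspot atoms", {
  d <- make_self_design()
  for (nm in names(d$placed)) {
    pf <- d$placed[[nm]]
    expect_equal(pf$hotspot_residual, pf$match$rmsd, tolerance = 1e-9)
    expect_lt(pf$hotspot_residual, 1e-6)  # self-match overlays the mirror
  }
})

test_that("placement is invariant to rigid pre-displacement of the library copy", {
  h <- glp2_helix()
  q <- glp2_queries(h)$helix1[[36]]
  get_placed <- function(seed) {
    lib <- plant_match(q, noise_sigma = 0, seed = seed, decoys = 0)
    pr <- search_fragments(list(q), lib, top_k = 1, directions = "forward")
    place_match(pr$matches[[1]], lib, q)$atoms
  }
  a <- get_placed(1)
  b <- get_placed(2)  # different random rigid move of the same copy
  expect_equal(as.matrix(a[, c("x", "y", "z")]),
               as.matrix(b[, c("x", "y", "z")]), tolerance = 1e-6)
})

test_that("stale window references are rejected", {
  d <- make_self_design()
  m <- d$profiles$helix1$matches[[1]]
  q <- d$qs$helix1[[1]]
  other <- plant_match(d$qs$helix1[[36]], seed = 1, decoys = 0)
  expect_error(place_match(m, other, q), "not present in this library")
})

test_that("self-assembly recovers the scaffold mirror exactly at CA level", {
  d <- make_self_design()
  asm <- assemble_peptide(d$placed, d$plan)
  expect_equal(nrow(asm$provenance), 31)
  expect_equal(length(unique(asm$atoms$chain_id)), 1)
  mh <- mirror_structure(d$h)
  aca <- asm$atoms[asm$atoms$atom_name == "CA", ]
  scaff_seq <- asm$provenance$scaffold_seq[match(aca$res_seq,
                                                 asm$provenance$assembled_index)]
  mca <- mh$atoms[mh$atoms$atom_name == "CA", ]
  ref <- as.matrix(mca[match(scaff_seq, mca$res_seq), c("x", "y", "z")])
  expect_lt(rmsd_between(as.matrix(aca[, c("x", "y", "z")]), ref), 1e-6)
  # retro orientation: assembled residue 1 realizes scaffold position 31
  expect_equal(asm$provenance$scaffold_seq[1], 31)
  expect_equal(asm$provenance$scaffold_seq[31], 1)
  # chain is uniformly D
  expect_true(asm$geometry$handedness_uniform)
  expect_equal(asm$geometry$handedness, "D")
})

test_that("provenance maps every assembled residue to one source residue and one scaffold position", {
  d <- make_self_design()
  asm <- assemble_peptide(d$placed, d$plan)
  p <- asm$provenance
  expect_equal(p$assembled_index, seq_len(nrow(p)))
  expect_equal(sort(p$scaffold_seq), 1:31)
  expect_false(any(duplicated(p[, c("entry_id", "chain_id", "helix_id",
                                    "source_res_seq")])))
  # hotspot positions are covered and their matched residues recorded
  hot <- c(1, 6, 8, 9, 14, 17, 21, 22, 25)
  expect_true(all(hot %in% p$scaffold_seq))
  expect_true(all(nchar(p$res_name) == 3))
})

test_that("self-assembly passes the geometry report: clean junctions, no clashes", {
  d <- make_self_design()
  asm <- assemble_peptide(d$placed, d$plan)
  g <- asm$geometry
  expect_true(all(g$junctions$ok))
  expect_true(all(abs(g$junctions$c_n_distance - 1.329) < 0.17))
  expect_equal(g$n_clashes, 0)
})

test_that("clash counting agrees with a brute-force all-pairs oracle", {
  d <- make_self_design()
  asm <- assemble_peptide(d$placed, d$plan)
  # push two mid-chain residues onto each other to create contacts
  sel <- asm$atoms$res_seq == 20
  target <- colMeans(asm$atoms[asm$atoms$res_seq == 5, c("x", "y", "z")])
  shift <- target - colMeans(asm$atoms[sel, c("x", "y", "z")])
  for (ax in c("x", "y", "z")) {
    asm$atoms[sel, ax] <- asm$atoms[sel, ax] + shift[[ax]]
  }
  g <- geometry_check(asm)
  # O(n^2) oracle with explicit loops
  a <- asm$atoms
  n_oracle <- 0L
  for (i in seq_len(nrow(a) - 1)) {
    for (j in (i + 1):nrow(a)) {
      if (abs(a$res_seq[i] - a$res_seq[j]) < 2) next
      dij <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 +
                    (a$z[i] - a$z[j])^2)
      if (dij < 2.0) n_oracle <- n_oracle + 1L
    }
  }
  expect_gt(n_oracle, 0)
  expect_equal(g$n_clashes, n_oracle)
})

test_that("a displaced fragment is flagged at the junction, not fatal", {
  d <- make_self_design()
  d$placed$helix3$atoms[, c("x", "y", "z")] <-
    d$placed$helix3$atoms[, c("x", "y", "z")] + 4
  expect_warning(asm <- assemble_peptide(d$placed, d$plan), "junction")
  g <- asm$geometry
  expect_false(all(g$junctions$ok))
  # the break sits at the helix2/helix3 splice (scaffold 17|18)
  bad <- g$junctions$assembled_index[!g$junctions$ok]
  junction_pos <- which(asm$provenance$scaffold_seq == 18)
  expect_true(junction_pos %in% bad)
})

test_that("incomplete coverage is a hard error naming the fragment", {
  d <- make_self_design()
  pf <- d$placed$helix2
  pf$atoms <- pf$atoms[pf$atoms$scaffold_seq != 12, ]
  d$placed$helix2 <- pf
  expect_error(assemble_peptide(d$placed, d$plan),
               "helix2 does not cover scaffold position 12")
})

test_that("an assembled peptide writes as a single 31-residue chain", {
  d <- make_self_design()
  asm <- assemble_peptide(d$placed, d$plan)
  p <- tempfile(fileext = ".pdb")
  write_structure(asm, p)
  back <- read_structure(p)
  expect_equal(nrow(residues(back)), 31)
  expect_equal(unique(back$atoms$chain_id), "A")
  expect_lt(max(abs(coords_of(back) -
                      as.matrix(asm$atoms[, c("x", "y", "z")]))), 1e-3)
})
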