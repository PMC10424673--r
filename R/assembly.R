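# Splicing the per-helix matches into one retro-inverso d-peptide model.

#' Default splice plan for overlapping scaffold segments
#'
#' Assigns each scaffold position to exactly one segment.  Consecutive
#' segments must overlap; the crossover is placed at the midpoint of each
#' overlap, ties toward the N-terminal segment.  For the canonical
#' three-helix split 1-14 / 7-19 / 15-31 (overlaps 7-14 and 15-19) this
#' gives crossovers after positions 10 and 17, hence contributions
#' 1-10, 11-17 and 18-31.
#'
#' @param segments Named list of ranges: each element a `segment` or a
#'   length-2 integer vector `c(start, end)`, ordered N- to C-terminal.
#' @return A `splice_plan`: list with `ranges`, `overlaps`, `crossovers`
#'   and `contributions` (named list of `c(start, end)`).
#' @export
default_splice_plan <- function(segments) {
  rng <- lapply(segments, function(s) {
    if (inherits(s, "segment")) c(s$start, s$end) else as.integer(s)
  })
  k <- length(rng)
  if (k < 1) stopf("no segments in plan")
  overlaps <- list()
  crossovers <- integer(0)
  for (i in seq_len(k - 1)) {
    ov <- c(rng[[i + 1]][1], rng[[i]][2])
    if (ov[1] > ov[2]) {
      stopf("segments %d and %d do not overlap", i, i + 1)
    }
    overlaps[[i]] <- ov
    crossovers[i] <- as.integer(floor((ov[1] + ov[2]) / 2))
  }
  bounds <- c(rng[[1]][1] - 1L, crossovers, rng[[k]][2])
  contributions <- lapply(seq_len(k), function(i) {
    c(bounds[i] + 1L, bounds[i + 1])
  })
  names(contributions) <- names(segments)
  structure(
    list(ranges = rng, overlaps = overlaps, crossovers = crossovers,
         contributions = contributions),
    class = "splice_plan"
  )
}

#' Place a matched fragment window onto the mirrored scaffold
#'
#' Applies the match's stored rotation/translation to the full window so
#' that the hotspot-aligned atoms overlay the mirrored scaffold hotspot
#' atoms; the residual at the hotspot atoms equals the match RMSD.  Each
#' placed residue is annotated with the scaffold position it realizes
#' (forward windows map window offset `j` to span offset `j`; reverse
#' windows to `length - 1 - j`).
#'
#' @param match A `fragment_match` from [score_window()] /
#'   [search_fragments()].
#' @param lib The `fragment_library` the match was found in.
#' @param query The `query_structure` the match was scored against.
#' @return A `placed_fragment`: list with `atoms` (transformed
#'   coordinates, source residue numbering), `map` (data frame
#'   `scaffold_seq`, `window_offset`, `source_res_seq`, `res_name`),
#'   `hotspot_residual` and the match metadata.
#' @export
place_match <- function(match, lib, query) {
  stopifnot(inherits(match, "fragment_match"))
  ei <- match$entry_index
  if (ei > length(lib$entries) ||
      lib$entries[[ei]]$entry_id != match$entry_id ||
      lib$entries[[ei]]$chain_id != match$chain_id) {
    stopf("match references a window not present in this library")
  }
  e <- lib$entries[[ei]]
  L <- match$length
  idx <- match$start + seq_len(L)
  sp <- structure(list(rotation = match$rotation,
                       translation = match$translation,
                       rmsd = match$rmsd), class = "superposition")

  rows <- lapply(seq_along(idx), function(jj) {
    j <- idx[jj]
    m <- apply_superposition(sp, e$res_atoms[[j]])
    off <- jj - 1L
    scaff_off <- if (match$direction == "forward") off else L - 1L - off
    data.frame(
      chain_id = "A", res_seq = e$res_seqs[j], res_name = e$res_names[j],
      atom_name = rownames(e$res_atoms[[j]]),
      element = element_from_name(rownames(e$res_atoms[[j]])),
      x = m[, 1], y = m[, 2], z = m[, 3],
      occupancy = 1, serial = NA_integer_, hydrogen = FALSE,
      handedness = e$handedness[j],
      scaffold_seq = query$span[1] + scaff_off,
      window_offset = off,
      stringsAsFactors = FALSE
    )
  })
  atoms <- do.call(rbind, rows)
  map <- unique(atoms[, c("scaffold_seq", "window_offset", "res_seq",
                          "res_name")])
  names(map)[3] <- "source_res_seq"
  rownames(map) <- NULL

  # bookkeeping identity: the placed hotspot atoms must reproduce the
  # match rmsd against the mirrored scaffold hotspots
  offs <- query$hotspots$seq_id - query$span[1]
  fixed <- d_query_coords(query, lib)
  placed_hot <- do.call(rbind, lapply(seq_along(offs), function(i) {
    sel <- atoms$scaffold_seq == query$hotspots$seq_id[i]
    names <- query$atoms$atom_name[query$atoms$seq_id ==
                                     query$hotspots$seq_id[i]]
    aa <- atoms[sel, , drop = FALSE]
    as.matrix(aa[match(names, aa$atom_name), c("x", "y", "z")])
  }))
  residual <- sqrt(mean(rowSums((fixed - placed_hot)^2)))

  structure(
    list(
      helix_id = match$helix_id, atoms = atoms, map = map,
      match = match, hotspot_residual = residual,
      span = query$span, direction = match$direction
    ),
    class = "placed_fragment"
  )
}

#' Assemble placed fragments into a retro-inverso d-peptide
#'
#' Takes one placed fragment per segment and splices them according to
#' the plan: each scaffold position is realized by the residue the owning
#' fragment maps to it.  The assembled chain is written in retro
#' orientation — its N-terminal residue realizes the scaffold's
#' C-terminal position — matching the chain direction of
#' reverse-direction (retro) matches, whose source residues then run
#' N-to-C within each spliced block.  Junction C-N distances outside
#' [1.2, 1.5] Angstroms are flagged with a warning (recorded in the
#' geometry report, not fatal); chemistry at the junctions is not
#' rebuilt.
#'
#' @param placed Named list of `placed_fragment` objects, names matching
#'   `plan$contributions`.
#' @param plan A `splice_plan`.
#' @return An `assembled_peptide`: single-chain atom table (assembled
#'   numbering 1..n), `provenance` (one row per residue: assembled index,
#'   scaffold position, source entry/chain/residue, helix id, direction),
#'   `scaffold_map`, and `geometry` report (see [geometry_check()]).
#' @export
assemble_peptide <- function(placed, plan) {
  stopifnot(inherits(plan, "splice_plan"))
  contrib <- plan$contributions
  if (!all(names(contrib) %in% names(placed))) {
    stopf("placed fragments missing for: %s",
          paste(setdiff(names(contrib), names(placed)), collapse = ", "))
  }
  scaffold_positions <- unlist(lapply(names(contrib), function(h) {
    seq.int(contrib[[h]][1], contrib[[h]][2])
  }))
  owner <- unlist(lapply(names(contrib), function(h) {
    rep(h, contrib[[h]][2] - contrib[[h]][1] + 1L)
  }))
  # retro orientation: assembled residue 1 realizes the highest scaffold
  # position
  ord <- order(scaffold_positions, decreasing = TRUE)
  scaffold_positions <- scaffold_positions[ord]
  owner <- owner[ord]

  rows <- list()
  prov <- list()
  for (k in seq_along(scaffold_positions)) {
    q <- scaffold_positions[k]
    pf <- placed[[owner[k]]]
    sel <- pf$atoms$scaffold_seq == q
    if (!any(sel)) {
      stopf("fragment %s does not cover scaffold position %d (coverage error)",
            owner[k], q)
    }
    a <- pf$atoms[sel, , drop = FALSE]
    prov[[k]] <- data.frame(
      assembled_index = k, scaffold_seq = q, helix_id = owner[k],
      entry_id = pf$match$entry_id, chain_id = pf$match$chain_id,
      source_res_seq = a$res_seq[1], res_name = a$res_name[1],
      direction = pf$direction, stringsAsFactors = FALSE
    )
    a$res_seq <- k
    a$scaffold_seq <- NULL
    a$window_offset <- NULL
    rows[[k]] <- a
  }
  atoms <- do.call(rbind, rows)
  atoms$serial <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  provenance <- do.call(rbind, prov)

  out <- structure(
    list(atoms = atoms, provenance = provenance,
         scaffold_map = provenance[, c("assembled_index", "scaffold_seq")],
         plan = plan),
    class = "assembled_peptide"
  )
  out$geometry <- geometry_check(out)
  bad <- out$geometry$junctions[!out$geometry$junctions$ok, , drop = FALSE]
  if (nrow(bad) > 0) {
    warning(sprintf("%d junction(s) with C-N distance outside [1.2, 1.5] A (worst %.2f A); see geometry report",
                    nrow(bad), max(abs(bad$c_n_distance - 1.35))),
            call. = FALSE)
  }
  out
}

#' @export
print.assembled_peptide <- function(x, ...) {
  cat(sprintf("assembled_peptide: %d residues (%d atoms), scaffold %d-%d, %d flagged junction(s), %d clash(es)\n",
              nrow(x$provenance), nrow(x$atoms),
              min(x$provenance$scaffold_seq), max(x$provenance$scaffold_seq),
              sum(!x$geometry$junctions$ok), x$geometry$n_clashes))
  invisible(x)
}

#' Geometric sanity report for an assembled peptide
#'
#' Reports consecutive-residue C-N distances (peptide bonds expected in
#' [1.2, 1.5] Angstroms), a steric clash count (atom pairs from residues
#' at least two apart in the assembled chain closer than 2.0 Angstroms),
#' and whether all chiral residues share one handedness.
#'
#' @param p An `assembled_peptide`.
#' @param bond_range Acceptable C-N junction distance range.
#' @param clash_cutoff Non-bonded contact distance defining a clash.
#' @return List with `junctions` data frame, `n_clashes`,
#'   `handedness_uniform`, `handedness`.
#' @export
geometry_check <- function(p, bond_range = c(1.2, 1.5), clash_cutoff = 2.0) {
  a <- p$atoms
  n <- max(a$res_seq)
  cn <- vapply(seq_len(n - 1), function(i) {
    ci <- a[a$res_seq == i & a$atom_name == "C", c("x", "y", "z")]
    nj <- a[a$res_seq == i + 1 & a$atom_name == "N", c("x", "y", "z")]
    if (nrow(ci) == 0 || nrow(nj) == 0) return(NA_real_)
    vnorm(as.numeric(ci) - as.numeric(nj))
  }, 1)
  junctions <- data.frame(
    assembled_index = seq_len(n - 1),
    c_n_distance = cn,
    ok = !is.na(cn) & cn >= bond_range[1] & cn <= bond_range[2]
  )
  xyz <- as.matrix(a[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  sep <- abs(outer(a$res_seq, a$res_seq, "-"))
  clashes <- which(d < clash_cutoff & sep >= 2 & upper.tri(d), arr.ind = TRUE)
  chir <- a$handedness[!duplicated(a$res_seq)]
  chir <- chir[!is.na(chir) & chir %in% c("L", "D")]
  list(
    junctions = junctions,
    n_clashes = nrow(clashes),
    handedness_uniform = length(unique(chir)) <= 1,
    handedness = if (length(chir) > 0) unique(chir) else character(0)
  )
}
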