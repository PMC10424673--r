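# Mirrored fragment library, least-squares superposition, and the
# RMSD-ranked window scan.

mirror_coords <- function(m, plane, center = c(0, 0, 0)) {
  ax <- switch(plane, xy = 3L, xz = 2L, yz = 1L)
  m[, ax] <- 2 * center[ax] - m[, ax]
  m
}

#' Optimal proper-rotation superposition of two point sets
#'
#' Least-squares rigid fit (Kabsch algorithm) of `moving` onto `fixed`
#' with the correspondence given by row order.  Only proper rotations
#' (determinant +1) are allowed: reflections are forbidden, which is
#' essential when scanning a mirrored library — an improper fit would
#' silently undo the mirror.  The returned RMSD is
#' `sqrt(mean(rowSums((fixed - (moving %*% t(R) + t))^2)))`.
#'
#' @param moving,fixed Numeric n x 3 matrices, n >= 3, same n.
#' @param tol Relative singular-value threshold below which a point set
#'   is declared degenerate (collinear).
#' @return A `superposition`: list with `rotation` (3 x 3, det +1),
#'   `translation` (length 3) and `rmsd` (Angstroms).
#' @export
superpose <- function(moving, fixed, tol = 1e-8) {
  moving <- as.matrix(moving)
  fixed <- as.matrix(fixed)
  if (nrow(moving) != nrow(fixed)) stopf("point counts differ")
  n <- nrow(moving)
  if (n < 3) stopf("superposition needs at least 3 points, got %d", n)
  cm <- colMeans(moving)
  cf <- colMeans(fixed)
  P <- sweep(moving, 2, cm)
  Q <- sweep(fixed, 2, cf)
  for (M in list(P, Q)) {
    sv <- svd(M, nu = 0, nv = 0)$d
    if (sv[2] < tol * max(sv[1], 1)) {
      stopf("degenerate (collinear) point set: superposition ill-posed")
    }
  }
  H <- crossprod(P, Q)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- cf - as.numeric(R %*% cm)
  resid <- Q - P %*% t(R)
  structure(
    list(rotation = R, translation = tr,
         rmsd = sqrt(mean(rowSums(resid^2)))),
    class = "superposition"
  )
}

#' Apply a superposition to coordinates
#' @param sp A `superposition`.
#' @param m n x 3 coordinate matrix.
#' @return Transformed n x 3 matrix.
#' @export
apply_superposition <- function(sp, m) {
  sweep(as.matrix(m) %*% t(sp$rotation), 2, -sp$translation)
}

#' Build a mirrored fragment library (d-PDB style)
#'
#' Every chain of every input structure is reflected with
#' [mirror_structure()] (turning deposited L-protein fragments into
#' D-fragments) and indexed by residue for window scanning.  Chains
#' shorter than `min_chain_length` are dropped; the count of dropped
#' chains is reported in a message and stored on the library.  Entries
#' are deduplicated by (entry id, chain id).
#'
#' @param structures List of `structure_model` objects.
#' @param min_chain_length Minimum usable chain length in residues.
#' @param plane,center Mirror plane and a point on it (see
#'   [mirror_structure()]).
#' @return A `fragment_library`.
#' @export
build_library <- function(structures, min_chain_length = 3, plane = "xy",
                          center = c(0, 0, 0)) {
  entries <- list()
  dropped <- 0L
  seen <- character()
  for (s in structures) {
    stopifnot(inherits(s, "structure_model"))
    ms <- mirror_structure(s, plane = plane, center = center)
    for (cid in unique(ms$atoms$chain_id)) {
      key <- paste(ms$entry_id, cid, sep = "/")
      if (key %in% seen) next
      seen <- c(seen, key)
      a <- ms$atoms[ms$atoms$chain_id == cid, , drop = FALSE]
      seqs <- sort(unique(a$res_seq))
      if (length(seqs) < min_chain_length) {
        dropped <- dropped + 1L
        next
      }
      res_atoms <- lapply(seqs, function(q) {
        coords_matrix(a[a$res_seq == q, , drop = FALSE])
      })
      res_names <- vapply(seqs, function(q) a$res_name[a$res_seq == q][1], "")
      handed <- vapply(seqs, function(q) a$handedness[a$res_seq == q][1], "")
      entries[[length(entries) + 1L]] <- list(
        entry_id = ms$entry_id, chain_id = cid, res_seqs = seqs,
        res_names = res_names, res_atoms = res_atoms, handedness = handed
      )
    }
  }
  if (length(entries) == 0) {
    stopf("no usable chains in library (%d dropped below %d residues)",
          dropped, min_chain_length)
  }
  if (dropped > 0) {
    message(sprintf("build_library: dropped %d chain(s) shorter than %d residues",
                    dropped, min_chain_length))
  }
  structure(
    list(entries = entries, plane = plane, center = center,
         n_dropped = dropped),
    class = "fragment_library"
  )
}

#' @export
print.fragment_library <- function(x, ...) {
  lens <- vapply(x$entries, function(e) length(e$res_seqs), 1L)
  cat(sprintf("fragment_library: %d mirrored chain(s), %d-%d residues, plane %s\n",
              length(x$entries), min(lens), max(lens), x$plane))
  invisible(x)
}

#' Enumerate contiguous fragment windows
#'
#' All windows of the given residue length from every library chain,
#' forward and/or reverse.  A chain of length `m` yields `m - length + 1`
#' windows per direction (zero if shorter than the window).
#'
#' @param lib A `fragment_library`.
#' @param length Window length in residues (the query span length).
#' @param directions Character vector, subset of
#'   `c("forward", "reverse")`.
#' @return Data frame with columns `entry_index`, `entry_id`, `chain_id`,
#'   `start` (0-based offset within the chain), `length`, `direction`.
#' @export
enumerate_windows <- function(lib, length,
                              directions = c("forward", "reverse")) {
  stopifnot(inherits(lib, "fragment_library"), length >= 1)
  directions <- match.arg(directions, several.ok = TRUE)
  out <- list()
  for (ei in seq_along(lib$entries)) {
    e <- lib$entries[[ei]]
    m <- base::length(e$res_seqs)
    if (m < length) next
    starts <- 0:(m - length)
    for (dir in directions) {
      out[[base::length(out) + 1L]] <- data.frame(
        entry_index = ei, entry_id = e$entry_id, chain_id = e$chain_id,
        start = starts, length = as.integer(length), direction = dir,
        stringsAsFactors = FALSE
      )
    }
  }
  if (base::length(out) == 0) {
    return(data.frame(entry_index = integer(), entry_id = character(),
                      chain_id = character(), start = integer(),
                      length = integer(), direction = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# Mirrored query coordinates in the library's d-frame: the l-scaffold
# query is reflected once with the library's own mirror so that window
# atoms (already mirrored) are fitted onto it with proper rotations only.
d_query_coords <- function(query, lib) {
  mirror_coords(as.matrix(query$atoms[, c("x", "y", "z")]),
                plane = lib$plane, center = lib$center)
}

#' Score one fragment window against one query
#'
#' The query hotspot at span offset `i` (0-based) corresponds to window
#' offset `i` (forward) or `length - 1 - i` (reverse); atoms correspond
#' by name (CA to CA, CB to CB, tip to tip).  The window atoms are fitted
#' onto the mirrored query coordinates by [superpose()].  Windows lacking
#' a required atom are skipped with reason `"missing_atom"`; with
#' `identity_filter = TRUE`, windows whose residue type differs from the
#' hotspot residue at any hotspot-aligned position are skipped with
#' reason `"identity"`.
#'
#' @param lib A `fragment_library`.
#' @param query A `query_structure`.
#' @param window One row of [enumerate_windows()] output (or an
#'   equivalent list).
#' @param identity_filter Require residue identity at hotspot positions.
#' @param .fixed Precomputed mirrored query coordinates (internal use by
#'   [search_fragments()] to avoid recomputation).
#' @return A `fragment_match` (list with `rmsd`, `rotation`,
#'   `translation`, window identity, `matched_res`), or a skip record
#'   `list(skip = reason)`.
#' @export
score_window <- function(lib, query, window, identity_filter = FALSE,
                         .fixed = NULL) {
  e <- lib$entries[[window$entry_index]]
  L <- query$span_length
  offs <- query$hotspots$seq_id - query$span[1]   # 0-based span offsets
  wpos <- if (window$direction == "forward") {
    window$start + offs + 1L
  } else {
    window$start + (L - 1L - offs) + 1L
  }
  if (identity_filter &&
      !all(e$res_names[wpos] == query$hotspots$res_name)) {
    return(list(skip = "identity"))
  }
  qa <- query$atoms
  moving <- matrix(NA_real_, nrow(qa), 3)
  row <- 0L
  for (i in seq_along(offs)) {
    names <- qa$atom_name[qa$seq_id == query$hotspots$seq_id[i]]
    ra <- e$res_atoms[[wpos[i]]]
    hit <- match(names, rownames(ra))
    if (anyNA(hit)) return(list(skip = "missing_atom"))
    moving[row + seq_along(hit), ] <- ra[hit, , drop = FALSE]
    row <- row + length(hit)
  }
  fixed <- .fixed %||% d_query_coords(query, lib)
  sp <- tryCatch(superpose(moving, fixed),
                 error = function(e2) NULL)
  if (is.null(sp)) return(list(skip = "degenerate"))
  structure(
    list(
      helix_id = query$helix_id, combo_id = query$combo_id,
      entry_index = window$entry_index, entry_id = e$entry_id,
      chain_id = e$chain_id, start = window$start, length = L,
      direction = window$direction,
      rmsd = sp$rmsd, rotation = sp$rotation, translation = sp$translation,
      matched_res = e$res_names[wpos],
      hotspot_seq_ids = query$hotspots$seq_id
    ),
    class = "fragment_match"
  )
}

#' Scan a mirrored library with a set of queries and rank by RMSD
#'
#' Every window of the query span length (forward and/or reverse) is
#' scored against every query combination; each window keeps the minimum
#' RMSD over the query set (ties to the earliest combination).  The
#' resulting profile is sorted ascending by RMSD with stable
#' tie-breaking (entry id, then start, then direction) and truncated to
#' the `top_k` best matches.
#'
#' @param queries List of `query_structure` objects for one helix (all
#'   with the same span).
#' @param lib A `fragment_library`.
#' @param top_k Maximum number of matches kept (default 1000).
#' @param directions Window directions to scan.
#' @param identity_filter Require residue identity at hotspot positions
#'   (default off; identity can instead emerge from side-chain-atom RMSD).
#' @return An `rmsd_profile`: list with `helix_id`, `matches` (list of
#'   `fragment_match`, ranked), `table` (data frame view), `skips`
#'   (named counts by reason), `n_windows`, `n_scored`.
#' @export
search_fragments <- function(queries, lib, top_k = 1000,
                             directions = c("forward", "reverse"),
                             identity_filter = FALSE) {
  stopifnot(length(queries) > 0, inherits(lib, "fragment_library"),
            top_k >= 1)
  spans <- unique(vapply(queries, function(q) q$span_length, 1L))
  if (length(spans) != 1) stopf("queries have differing span lengths")
  helix_id <- queries[[1]]$helix_id

  wins <- enumerate_windows(lib, spans, directions)
  fixed_coords <- lapply(queries, d_query_coords, lib = lib)
  skips <- c(identity = 0L, missing_atom = 0L, degenerate = 0L)
  best <- vector("list", nrow(wins))
  n_scored <- 0L
  for (w in seq_len(nrow(wins))) {
    bw <- NULL
    for (qi in seq_along(queries)) {
      q <- queries[[qi]]
      m <- score_window(lib, q, wins[w, ], identity_filter = identity_filter,
                        .fixed = fixed_coords[[qi]])
      if (!is.null(m$skip)) {
        skips[m$skip] <- skips[m$skip] + 1L
        next
      }
      if (is.null(bw) || m$rmsd < bw$rmsd) bw <- m
    }
    if (!is.null(bw)) {
      n_scored <- n_scored + 1L
      best[[w]] <- bw
    }
  }
  best <- best[!vapply(best, is.null, TRUE)]
  if (length(best) == 0) {
    stopf("no matches: all %d window-query pairs skipped (%s)",
          sum(skips), paste(names(skips), skips, sep = "=", collapse = ", "))
  }
  ord <- order(vapply(best, function(m) m$rmsd, 1),
               vapply(best, function(m) m$entry_id, ""),
               vapply(best, function(m) m$start, 1L),
               vapply(best, function(m) m$direction, ""))
  best <- best[ord][seq_len(min(top_k, length(best)))]
  tab <- data.frame(
    helix_id = helix_id,
    rank = seq_along(best),
    entry_id = vapply(best, function(m) m$entry_id, ""),
    chain_id = vapply(best, function(m) m$chain_id, ""),
    start = vapply(best, function(m) m$start, 1L),
    direction = vapply(best, function(m) m$direction, ""),
    combo_id = vapply(best, function(m) m$combo_id, ""),
    rmsd = vapply(best, function(m) m$rmsd, 1),
    matched_residues = vapply(best, function(m)
      paste(m$matched_res, collapse = "-"), ""),
    stringsAsFactors = FALSE
  )
  structure(
    list(helix_id = helix_id, matches = best, table = tab, skips = skips,
         n_windows = nrow(wins), n_scored = n_scored),
    class = "rmsd_profile"
  )
}

#' @export
print.rmsd_profile <- function(x, ...) {
  cat(sprintf("rmsd_profile %s: %d match(es) from %d window(s) (skips: %s)\n",
              x$helix_id, length(x$matches), x$n_windows,
              paste(names(x$skips), x$skips, sep = "=", collapse = ", ")))
  print(utils::head(x$table, 5))
  invisible(x)
}

#' @export
as.data.frame.rmsd_profile <- function(x, ...) x$table

#' Helical-geometry window filter
#'
#' Optional pre-filter marking windows whose CA(i)-CA(i+4) distances all
#' fall in the canonical alpha-helical band (5.9 to 6.7 Angstroms).
#'
#' @param lib A `fragment_library`.
#' @param windows Output of [enumerate_windows()].
#' @param range Allowed CA(i)-CA(i+4) distance range.
#' @return Logical vector, one per window row.
#' @export
helix_filter <- function(lib, windows, range = c(5.9, 6.7)) {
  vapply(seq_len(nrow(windows)), function(w) {
    e <- lib$entries[[windows$entry_index[w]]]
    idx <- windows$start[w] + seq_len(windows$length[w])
    ca <- t(vapply(e$res_atoms[idx], function(m) {
      j <- match("CA", rownames(m))
      if (is.na(j)) c(NA_real_, NA_real_, NA_real_) else m[j, ]
    }, numeric(3)))
    if (anyNA(ca)) return(FALSE)
    if (nrow(ca) < 5) return(TRUE)
    d <- sqrt(rowSums((ca[-(1:4), , drop = FALSE] -
                         ca[seq_len(nrow(ca) - 4), , drop = FALSE])^2))
    all(d >= range[1] & d <= range[2])
  }, TRUE)
}
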