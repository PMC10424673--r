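# Combinatorial hotspot atom-level query generation.

#' Default atom-level scheme for hotspot queries
#'
#' For each hotspot residue type, an ordered list of atom-name sets
#' ("levels") of increasing side-chain detail: level 1 = CA only, level 2
#' = CA+CB, level 3 = CA+CB+side-chain tip atoms (Phe CG/CZ, Trp CG/CH2,
#' Asp CG/OD1, Glu CD/OE1, Leu CG/CD1, His CG/NE2).  Histidine gets a
#' fourth level anchoring the full imidazole (CA, CB, CG, ND1, NE2).
#' Residue types without a defined tip get levels 1-2 only; glycine gets
#' level 1.  Under this scheme the three GLP-2 scaffold segments with
#' hotspots H1/F6/E9, D8/L14/L17 and D21/F22/W25 yield 4x3x3 = 36 and
#' 3x3x3 = 27 and 27 query combinations.  The scheme is a reconstruction
#' calibrated to those combination counts and is fully user-overridable
#' (see `scheme` arguments and the YAML config).
#'
#' @return Named list: 3-letter residue code to list of character vectors
#'   of atom names.
#' @export
default_atom_scheme <- function() {
  tip <- list(
    PHE = c("CG", "CZ"), TRP = c("CG", "CH2"), ASP = c("CG", "OD1"),
    GLU = c("CD", "OE1"), LEU = c("CG", "CD1"), HIS = c("CG", "NE2")
  )
  scheme <- lapply(stats::setNames(nm = names(AA_3TO1)), function(r3) {
    lv <- list(c("CA"), c("CA", "CB"))
    if (r3 == "GLY") return(list(c("CA")))
    if (!is.null(tip[[r3]])) lv <- c(lv, list(c("CA", "CB", tip[[r3]])))
    lv
  })
  scheme$HIS <- c(scheme$HIS, list(c("CA", "CB", "CG", "ND1", "NE2")))
  scheme
}

#' Validate hotspot residues on a scaffold segment
#'
#' Each hotspot must lie inside the segment range and its residue type
#' must match the scaffold residue at that position; a mismatch (for
#' example expecting Phe at position 6 but finding Ala) is an error that
#' names the offending position.
#'
#' @param segment A `segment` of the scaffold.
#' @param specs Data frame (or list of lists) with columns/fields
#'   `seq_id` and `res_name` (1- or 3-letter code), optional `rationale`.
#' @return A `hotspot_set`: data frame ordered by `seq_id`, with the
#'   segment attached as attribute `segment`.
#' @export
define_hotspots <- function(segment, specs) {
  stopifnot(inherits(segment, "segment"))
  if (is.list(specs) && !is.data.frame(specs)) {
    specs <- do.call(rbind, lapply(specs, function(s) {
      data.frame(seq_id = s$seq_id, res_name = s$res_name,
                 rationale = s$rationale %||% NA_character_,
                 stringsAsFactors = FALSE)
    }))
  }
  if (is.null(specs) || nrow(specs) == 0) {
    stopf("a segment must have at least one hotspot")
  }
  if (is.null(specs$rationale)) specs$rationale <- NA_character_
  specs$res_name <- toupper(specs$res_name)
  one <- nchar(specs$res_name) == 1
  specs$res_name[one] <- unname(AA_1TO3[specs$res_name[one]])
  if (anyNA(specs$res_name)) stopf("unrecognized hotspot residue code")

  res <- residues(segment)
  for (i in seq_len(nrow(specs))) {
    q <- specs$seq_id[i]
    if (q < segment$start || q > segment$end) {
      stopf("hotspot %s%d lies outside segment %d-%d",
            specs$res_name[i], q, segment$start, segment$end)
    }
    found <- res$res_name[res$res_seq == q]
    if (length(found) == 0) stopf("hotspot position %d not in segment", q)
    if (found != specs$res_name[i]) {
      stopf("hotspot mismatch at position %d: expected %s, scaffold has %s",
            q, specs$res_name[i], found)
    }
  }
  specs <- specs[order(specs$seq_id), , drop = FALSE]
  rownames(specs) <- NULL
  structure(specs, segment = segment, class = c("hotspot_set", "data.frame"))
}

#' Enumerate combinatorial atom-level query structures
#'
#' Emits exactly the Cartesian product of the per-hotspot atom levels,
#' one query per combination, in lexicographic order of the level-index
#' tuple.  Query coordinates are taken verbatim from the scaffold
#' segment; no geometry is invented.  Combinations with fewer than three
#' atoms in total are rejected (superposition would be ill-posed).
#'
#' @param hotspots A `hotspot_set` from [define_hotspots()].
#' @param scheme Atom-level scheme (default [default_atom_scheme()]).
#' @param helix_id Label for the parent segment (e.g. `"helix1"`).
#' @return List of `query_structure` objects.  Each carries `helix_id`,
#'   `combo_id` (dash-joined level indices), an ordered `atoms` table
#'   (`seq_id`, `atom_name`, `x`, `y`, `z`), the segment `span`, and the
#'   source `segment`.
#' @export
enumerate_queries <- function(hotspots, scheme = default_atom_scheme(),
                              helix_id = "helix") {
  stopifnot(inherits(hotspots, "hotspot_set"))
  segment <- attr(hotspots, "segment")
  nh <- nrow(hotspots)

  levels <- vector("list", nh)
  for (i in seq_len(nh)) {
    lv <- scheme[[hotspots$res_name[i]]]
    if (is.null(lv) || length(lv) == 0) {
      stopf("scheme defines no atom levels for %s", hotspots$res_name[i])
    }
    ra <- segment$atoms[segment$atoms$res_seq == hotspots$seq_id[i], ,
                        drop = FALSE]
    for (set in lv) {
      missing <- setdiff(set, ra$atom_name)
      if (length(missing) > 0) {
        stopf("scheme atom(s) %s absent from scaffold residue %s%d",
              paste(missing, collapse = ","), hotspots$res_name[i],
              hotspots$seq_id[i])
      }
    }
    levels[[i]] <- lv
  }

  counts <- vapply(levels, length, 1L)
  # lexicographic combination order: last hotspot's level varies fastest
  grid <- expand.grid(rev(lapply(counts, seq_len)))[, rev(seq_len(nh)),
                                                    drop = FALSE]
  queries <- vector("list", nrow(grid))
  for (k in seq_len(nrow(grid))) {
    idx <- as.integer(grid[k, ])
    atoms <- do.call(rbind, lapply(seq_len(nh), function(i) {
      names <- levels[[i]][[idx[i]]]
      ra <- segment$atoms[segment$atoms$res_seq == hotspots$seq_id[i], ,
                          drop = FALSE]
      m <- ra[match(names, ra$atom_name), , drop = FALSE]
      data.frame(seq_id = hotspots$seq_id[i], atom_name = names,
                 x = m$x, y = m$y, z = m$z, stringsAsFactors = FALSE)
    }))
    if (nrow(atoms) < 3) {
      stopf("combination %s yields %d atoms; queries need at least 3",
            paste(idx, collapse = "-"), nrow(atoms))
    }
    queries[[k]] <- structure(
      list(
        helix_id = helix_id,
        combo_id = paste(idx, collapse = "-"),
        levels = idx,
        hotspots = as.data.frame(hotspots),
        atoms = atoms,
        span = c(segment$start, segment$end),
        span_length = segment_length(segment),
        chain_id = segment$chain_id,
        segment = segment
      ),
      class = "query_structure"
    )
  }
  queries
}

#' @export
print.query_structure <- function(x, ...) {
  cat(sprintf("query %s combo %s: %d atoms over hotspots %s (span %d-%d)\n",
              x$helix_id, x$combo_id, nrow(x$atoms),
              paste0(x$hotspots$res_name, x$hotspots$seq_id, collapse = ","),
              x$span[1], x$span[2]))
  invisible(x)
}
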