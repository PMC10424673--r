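# Shared fixtures and independent oracles for the test suite.

# GLP-2 residues 1-31 (the receptor-bound helical region used as the
# design scaffold; hotspots H1, F6, D8, E9, L14, L17, D21, F22, W25).
GLP2_SEQ <- "HADGSFSDEMNTILDNLAARDFINWLIQTKI"

glp2_helix <- function(entry_id = "GLP2") {
  build_ideal_helix(GLP2_SEQ, entry_id = entry_id)
}

glp2_segment_ranges <- function() {
  list(helix1 = c(1L, 14L), helix2 = c(7L, 19L), helix3 = c(15L, 31L))
}

glp2_hotspot_specs <- function() {
  list(
    helix1 = data.frame(seq_id = c(1, 6, 9), res_name = c("H", "F", "E")),
    helix2 = data.frame(seq_id = c(8, 14, 17), res_name = c("D", "L", "L")),
    helix3 = data.frame(seq_id = c(21, 22, 25), res_name = c("D", "F", "W"))
  )
}

glp2_queries <- function(h = glp2_helix()) {
  rng <- glp2_segment_ranges()
  hs <- glp2_hotspot_specs()
  out <- lapply(names(rng), function(nm) {
    seg <- extract_segment(h, "A", rng[[nm]][1], rng[[nm]][2])
    enumerate_queries(define_hotspots(seg, hs[[nm]]), helix_id = nm)
  })
  names(out) <- names(rng)
  out
}

# Library of the scaffold's own three segments (build_library mirrors).
glp2_self_library <- function(h = glp2_helix(), ...) {
  rng <- glp2_segment_ranges()
  structs <- lapply(names(rng), function(nm) {
    s <- extract_segment(h, "A", rng[[nm]][1], rng[[nm]][2])
    s$entry_id <- toupper(nm)
    s
  })
  build_library(structs, min_chain_length = 13, ...)
}

# Writes a complete self-reconstruction design setup (scaffold PDB,
# per-segment library PDBs, config list) under `root`.
write_self_design_inputs <- function(root) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  h <- glp2_helix()
  scaffold <- file.path(root, "scaffold.pdb")
  write_structure(h, scaffold)
  libdir <- file.path(root, "lib")
  dir.create(libdir, showWarnings = FALSE)
  rng <- glp2_segment_ranges()
  for (nm in names(rng)) {
    seg <- extract_segment(h, "A", rng[[nm]][1], rng[[nm]][2])
    write_structure(seg, file.path(libdir, paste0(nm, ".pdb")))
  }
  hs3 <- lapply(glp2_hotspot_specs(), function(df) {
    lapply(seq_len(nrow(df)), function(i)
      list(seq_id = df$seq_id[i], res_name = df$res_name[i]))
  })
  list(
    scaffold = list(path = scaffold, chain = "A"),
    segments = lapply(stats::setNames(nm = names(rng)), function(nm) {
      list(start = rng[[nm]][1], end = rng[[nm]][2],
           hotspots = hs3[[nm]])
    }),
    library = list(libdir),
    directions = "reverse",
    output_dir = file.path(root, "out")
  )
}

# Full in-memory self-design: search each helix's queries against the
# scaffold's own mirrored segments, place the best match, build the plan.
make_self_design <- function(directions = "reverse", top_k = 5) {
  h <- glp2_helix()
  qs <- glp2_queries(h)
  lib <- glp2_self_library(h)
  placed <- list()
  profiles <- list()
  for (nm in names(qs)) {
    pr <- search_fragments(qs[[nm]], lib, top_k = top_k,
                           directions = directions)
    m <- pr$matches[[1]]
    q <- qs[[nm]][[which(vapply(qs[[nm]], function(x) x$combo_id, "") ==
                           m$combo_id)]]
    placed[[nm]] <- place_match(m, lib, q)
    profiles[[nm]] <- pr
  }
  rng <- glp2_segment_ranges()
  segs <- lapply(names(rng), function(nm)
    extract_segment(h, "A", rng[[nm]][1], rng[[nm]][2]))
  names(segs) <- names(rng)
  list(h = h, lib = lib, qs = qs, placed = placed,
       plan = default_splice_plan(segs), profiles = profiles)
}

coords_of <- function(s, atom = NULL, res = NULL) {
  a <- s$atoms
  if (!is.null(atom)) a <- a[a$atom_name %in% atom, , drop = FALSE]
  if (!is.null(res)) a <- a[a$res_seq %in% res, , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}

rmsd_between <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

# --- independent oracles ----------------------------------------------

# Signed volume via base determinant (independent of the package's
# cross-product route).
oracle_triple_product <- function(n, ca, c, cb) {
  det(rbind(n - ca, c - ca, cb - ca))
}

euler_rotation <- function(a, b, c) {
  Rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1),
                           3, byrow = TRUE)
  Ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0, -sin(t), 0, cos(t)),
                           3, byrow = TRUE)
  Rz(a) %*% Ry(b) %*% Rz(c)
}

# Brute-force rotation search oracle for the optimal proper-rotation
# RMSD: coarse random sampling of SO(3) followed by Nelder-Mead
# refinement over Euler angles.  Shares nothing with the Kabsch path.
oracle_superpose_rmsd <- function(moving, fixed, n_coarse = 4000) {
  P <- sweep(moving, 2, colMeans(moving))
  Q <- sweep(fixed, 2, colMeans(fixed))
  obj <- function(ang) {
    R <- euler_rotation(ang[1], ang[2], ang[3])
    sqrt(mean(rowSums((Q - P %*% t(R))^2)))
  }
  set.seed(424242)
  starts <- matrix(stats::runif(3 * n_coarse, -pi, pi), ncol = 3)
  vals <- apply(starts, 1, obj)
  best <- Inf
  for (i in order(vals)[1:5]) {
    o <- stats::optim(starts[i, ], obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, o$value)
  }
  best
}

# Exhaustive re-scoring oracle for search_fragments: scores every window
# against every query and does the min-pooling / sorting / truncation
# with plain data-frame operations.
oracle_search_table <- function(queries, lib, top_k, directions,
                                identity_filter = FALSE) {
  wins <- enumerate_windows(lib, queries[[1]]$span_length, directions)
  rows <- list()
  for (w in seq_len(nrow(wins))) {
    rmsds <- numeric(0)
    combos <- character(0)
    for (q in queries) {
      m <- score_window(lib, q, wins[w, ], identity_filter = identity_filter)
      if (is.null(m$skip)) {
        rmsds <- c(rmsds, m$rmsd)
        combos <- c(combos, m$combo_id)
      }
    }
    if (length(rmsds) == 0) next
    k <- which.min(rmsds)
    rows[[length(rows) + 1]] <- data.frame(
      entry_id = wins$entry_id[w], chain_id = wins$chain_id[w],
      start = wins$start[w], direction = wins$direction[w],
      combo_id = combos[k], rmsd = rmsds[k], stringsAsFactors = FALSE
    )
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$rmsd, tab$entry_id, tab$start, tab$direction), ,
             drop = FALSE]
  tab <- utils::head(tab, top_k)
  rownames(tab) <- NULL
  tab
}

# Minimal hand-written PDB text for parser edge cases.
pdb_line <- function(serial, name, alt = " ", res = "ALA", chain = "A",
                     resno = 1, x = 0, y = 0, z = 0, occ = 1, icode = " ",
                     type = "ATOM  ", element = NULL) {
  element <- element %||% substr(gsub("[0-9]", "", name), 1, 1)
  name4 <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, name4, alt, res, chain, resno, icode, x, y, z, occ,
          0, element)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_pdb_lines <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}
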