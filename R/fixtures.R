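# Deterministic synthetic structures: ideal helices and planted-match
# libraries.  These stand in for downloaded PDB content so that every
# pipeline stage can be exercised offline.

# Backbone internal coordinates (Angstroms / degrees), standard values.
BB_GEOM <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  a_c_n_ca = 121.7, a_n_ca_c = 111.2, a_ca_c_n = 116.6, a_ca_c_o = 120.5,
  # improper torsion(N, C, CA, CB) for an L-residue; negated for D
  b_ca_cb = 1.537, a_c_ca_cb = 110.0, t_cb_improper = 124.0
)

# Side chains are built only out to the atoms the default atom-level
# scheme can ask for (ring/tip atoms of His, Phe, Trp, Asp, Glu, Leu);
# other residue types stop at CB.  Each row: atom placed from three
# previously-placed reference atoms by bond/angle/torsion.  Torsions are
# negated for D-residues so the side chain is the exact mirror build.
SIDECHAIN_ZMAT <- list(
  HIS = list(
    list("CG",  c("N", "CA", "CB"),  1.50, 113.8, -60),
    list("ND1", c("CA", "CB", "CG"), 1.38, 122.7,  90),
    list("CD2", c("CA", "CB", "CG"), 1.36, 131.0, -90),
    list("NE2", c("CB", "CG", "CD2"), 1.37, 107.2, 180)
  ),
  PHE = list(
    list("CG",  c("N", "CA", "CB"),  1.51, 113.8, -60),
    list("CD1", c("CA", "CB", "CG"), 1.39, 120.7,  90),
    list("CD2", c("CA", "CB", "CG"), 1.39, 120.7, -90),
    list("CE1", c("CB", "CG", "CD1"), 1.39, 120.0, 180),
    list("CE2", c("CB", "CG", "CD2"), 1.39, 120.0, 180),
    list("CZ",  c("CG", "CD1", "CE1"), 1.39, 120.0, 0)
  ),
  TRP = list(
    list("CG",  c("N", "CA", "CB"),  1.50, 113.6, -60),
    list("CD1", c("CA", "CB", "CG"), 1.37, 126.9,  90),
    list("CD2", c("CA", "CB", "CG"), 1.43, 126.7, -90),
    list("NE1", c("CB", "CG", "CD1"), 1.38, 110.2, 180),
    list("CE2", c("CB", "CG", "CD2"), 1.41, 107.2, 180),
    list("CE3", c("CB", "CG", "CD2"), 1.40, 133.9, 0),
    list("CZ2", c("CG", "CD2", "CE2"), 1.40, 122.4, 180),
    list("CZ3", c("CG", "CD2", "CE3"), 1.39, 118.8, 180),
    list("CH2", c("CD2", "CE2", "CZ2"), 1.37, 117.5, 0)
  ),
  ASP = list(
    list("CG",  c("N", "CA", "CB"),  1.52, 113.0, -60),
    list("OD1", c("CA", "CB", "CG"), 1.25, 118.5, -20),
    list("OD2", c("CA", "CB", "CG"), 1.25, 118.5, 160)
  ),
  GLU = list(
    list("CG",  c("N", "CA", "CB"),  1.52, 114.1, -60),
    list("CD",  c("CA", "CB", "CG"), 1.52, 112.6, 180),
    list("OE1", c("CB", "CG", "CD"), 1.25, 118.5, -20),
    list("OE2", c("CB", "CG", "CD"), 1.25, 118.5, 160)
  ),
  LEU = list(
    list("CG",  c("N", "CA", "CB"),  1.53, 116.3, -60),
    list("CD1", c("CA", "CB", "CG"), 1.53, 110.7, 180),
    list("CD2", c("CA", "CB", "CG"), 1.53, 110.7, -60)
  )
)

element_from_name <- function(name) substr(gsub("[0-9]", "", name), 1, 1)

#' Build an ideal alpha-helical peptide structure
#'
#' Places backbone atoms (N, CA, C, O) from standard internal coordinates
#' at the given backbone dihedrals, plus CB for all chiral residues and
#' minimal side-chain tip atoms for the hotspot-capable residue types
#' (His, Phe, Trp, Asp, Glu, Leu).  The build is fully deterministic.
#' D-handedness negates every torsion, producing the exact mirror-image
#' internal geometry.
#'
#' @param sequence One-letter amino-acid string (standard 20 letters).
#' @param phi,psi Backbone dihedrals in degrees; scalars or per-residue
#'   vectors (defaults -57/-47, ideal alpha helix).
#' @param omega Peptide-bond dihedral in degrees (default 180).
#' @param handedness `"L"` (default) or `"D"`.
#' @param chain_id,entry_id,start_seq Chain id, entry id and first residue
#'   number of the product.
#' @return A `structure_model`.
#' @export
build_ideal_helix <- function(sequence, phi = -57, psi = -47, omega = 180,
                              handedness = c("L", "D"), chain_id = "A",
                              entry_id = "HELIX", start_seq = 1L) {
  handedness <- match.arg(handedness)
  seq1 <- strsplit(toupper(sequence), "")[[1]]
  if (length(seq1) == 0) stopf("sequence is empty")
  bad <- setdiff(seq1, names(AA_1TO3))
  if (length(bad) > 0) stopf("invalid residue letter(s): %s",
                             paste(unique(bad), collapse = ", "))
  n <- length(seq1)
  res3 <- unname(AA_1TO3[seq1])
  phi <- rep_len(phi, n)
  psi <- rep_len(psi, n)
  omega <- rep_len(omega, n)
  hsign <- if (handedness == "D") -1 else 1
  phi <- hsign * phi
  psi <- hsign * psi
  g <- BB_GEOM

  a_res <- integer(0)
  a_name <- character(0)
  a_xyz <- list()
  add_atom <- function(resi, name, xyz) {
    a_res[length(a_res) + 1L] <<- resi
    a_name[length(a_name) + 1L] <<- name
    a_xyz[[length(a_xyz) + 1L]] <<- xyz
  }

  # backbone trace; per-residue named positions kept for reference lookups
  pos <- vector("list", n)
  for (i in seq_len(n)) {
    if (i == 1) {
      N <- c(0, 0, 0)
      CA <- c(g$b_n_ca, 0, 0)
      C <- place_atom(c(0, 0, 1), N, CA, g$b_ca_c, g$a_n_ca_c, phi[1])
    } else {
      prev <- pos[[i - 1]]
      N <- place_atom(prev$N, prev$CA, prev$C, g$b_c_n, g$a_ca_c_n, psi[i - 1])
      CA <- place_atom(prev$CA, prev$C, N, g$b_n_ca, g$a_c_n_ca, omega[i - 1])
      C <- place_atom(prev$C, N, CA, g$b_ca_c, g$a_n_ca_c, phi[i])
    }
    O <- place_atom(N, CA, C, g$b_c_o, g$a_ca_c_o, psi[i] + 180)
    p <- list(N = N, CA = CA, C = C, O = O)
    if (res3[i] != "GLY") {
      p$CB <- place_atom(N, C, CA, g$b_ca_cb, g$a_c_ca_cb,
                         hsign * g$t_cb_improper)
      zmat <- SIDECHAIN_ZMAT[[res3[i]]]
      for (zm in zmat %||% list()) {
        refs <- lapply(zm[[2]], function(nm) p[[nm]])
        p[[zm[[1]]]] <- place_atom(refs[[1]], refs[[2]], refs[[3]],
                                   zm[[3]], zm[[4]], hsign * zm[[5]])
      }
    }
    pos[[i]] <- p
    for (nm in names(p)) add_atom(i, nm, p[[nm]])
  }

  xyz <- do.call(rbind, a_xyz)
  atoms <- data.frame(
    chain_id = chain_id, res_seq = start_seq + a_res - 1L,
    res_name = res3[a_res], atom_name = a_name,
    element = element_from_name(a_name),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = 1, serial = seq_along(a_name), hydrogen = FALSE,
    handedness = NA_character_, stringsAsFactors = FALSE
  )
  sm <- new_structure_model(atoms, entry_id = entry_id)
  sm$atoms$handedness <- call_handedness(sm)
  sm
}

#' Reverse the residue order of a single-chain structure
#'
#' Renumbers residues so the chain reads in the opposite direction while
#' leaving every atom exactly in place.  Mirroring such a reversed copy
#' produces the ideal retro-inverso partner of the original: a library
#' entry that a reverse-direction window scan matches with the identity
#' transform.  Used to plant exact retro matches in test libraries.
#'
#' @param s A single-chain `structure_model` or `segment`.
#' @param entry_id Entry id of the reversed copy.
#' @return A `structure_model` with residues renumbered `1..n` in
#'   reverse order.
#' @export
reverse_chain <- function(s, entry_id = paste0(s$entry_id, "R")) {
  stopifnot(inherits(s, "structure_model"))
  if (length(unique(s$atoms$chain_id)) != 1) {
    stopf("reverse_chain expects a single chain")
  }
  a <- s$atoms
  seqs <- sort(unique(a$res_seq))
  a$res_seq <- length(seqs) + 1L - match(a$res_seq, seqs)
  a <- a[order(a$res_seq, a$serial), , drop = FALSE]
  a$serial <- seq_len(nrow(a))
  rownames(a) <- NULL
  new_structure_model(a, entry_id = entry_id)
}

# Uniform random rotation matrix (quaternion method).
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / vnorm(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Random ideal-helix decoy structures
#'
#' Generates helices with random sequences and per-residue backbone
#' dihedrals jittered uniformly around ideal alpha-helical values, each
#' given a random rigid placement.  Used as the decoy background for
#' planted-match recovery experiments.
#'
#' @param n Number of decoys.
#' @param length Residues per decoy.
#' @param dihedral_jitter Half-width (degrees) of the uniform jitter on
#'   phi/psi (default 10).
#' @return List of `structure_model` objects (entry ids `DEC001`, ...).
#'   Uses the current RNG state; seed externally for reproducibility.
#' @export
random_helix_library <- function(n, length, dihedral_jitter = 10) {
  lapply(seq_len(n), function(k) {
    seq1 <- paste(sample(names(AA_1TO3), length, replace = TRUE),
                  collapse = "")
    h <- build_ideal_helix(
      seq1,
      phi = -57 + stats::runif(length, -dihedral_jitter, dihedral_jitter),
      psi = -47 + stats::runif(length, -dihedral_jitter, dihedral_jitter),
      entry_id = sprintf("DEC%03d", k)
    )
    R <- random_rotation()
    tr <- stats::runif(3, -10, 10)
    xyz <- as.matrix(h$atoms[, c("x", "y", "z")]) %*% t(R)
    h$atoms$x <- xyz[, 1] + tr[1]
    h$atoms$y <- xyz[, 2] + tr[2]
    h$atoms$z <- xyz[, 3] + tr[3]
    h
  })
}

#' Plant a noisy copy of a query's source segment in a decoy library
#'
#' Builds a `fragment_library` containing one mirrored copy of the
#' query's source segment — perturbed by isotropic Gaussian coordinate
#' noise and moved by a random rigid transform (uniform rotation,
#' translation in a 20 Angstrom box) — plus `decoys` random jittered
#' helices.  The planted window identity is recorded as ground truth in
#' the `planted` attribute.
#'
#' @param query A `query_structure` from [enumerate_queries()] (carries
#'   its source segment).
#' @param noise_sigma Gaussian noise s.d. per coordinate, Angstroms.
#' @param seed Integer RNG seed (all randomness is local to this call).
#' @param decoys Number of decoy helices.
#' @param plane Mirror plane for the library (see [mirror_structure()]).
#' @return A `fragment_library` with attribute `planted` = list(entry_id,
#'   chain_id, start, direction = "forward").
#' @export
plant_match <- function(query, noise_sigma = 0, seed = 1, decoys = 0,
                        plane = "xy") {
  stopifnot(inherits(query, "query_structure"), noise_sigma >= 0)
  seg <- query$segment
  set.seed(seed)
  planted <- new_structure_model(seg$atoms, entry_id = "PLANT")
  L <- segment_length(seg)
  dec <- if (decoys > 0) random_helix_library(decoys, L) else list()
  lib <- build_library(c(list(planted), dec), min_chain_length = L,
                       plane = plane)
  # perturb the planted (already mirrored) entry in place
  pi <- which(vapply(lib$entries, function(e) e$entry_id, "") == "PLANT")
  e <- lib$entries[[pi]]
  R <- random_rotation()
  tr <- stats::runif(3, -10, 10)
  for (j in seq_along(e$res_atoms)) {
    m <- e$res_atoms[[j]]
    m <- m + matrix(stats::rnorm(length(m), sd = noise_sigma), ncol = 3)
    e$res_atoms[[j]] <- sweep(m %*% t(R), 2, -tr)
  }
  lib$entries[[pi]] <- e
  attr(lib, "planted") <- list(entry_id = "PLANT", chain_id = seg$chain_id,
                               start = 0L, direction = "forward")
  lib
}
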