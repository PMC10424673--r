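# Mirror-image (d-PDB) transform and chirality bookkeeping.

# Sign of the scalar triple product det[N-CA, C-CA, CB-CA] for an
# L-amino acid in standard geometry: positive, about +2.5 cubic Angstroms
# (measured on deposited L-protein structures).  The constant records the
# reference orientation used to convert a signed volume into an L/D call.
L_REFERENCE_SIGN <- 1

#' Signed chirality volume of a residue
#'
#' Computes the scalar triple product `det[N-CA, C-CA, CB-CA]` (cubic
#' Angstroms) from a residue's N, CA, C and CB atoms.  The sign flips
#' under reflection and distinguishes L from D amino acids; glycine (no
#' CB) and residues with missing backbone atoms are indeterminate and
#' return `NA` rather than raising an error.
#'
#' @param residue_atoms Data frame of atom records for one residue (rows
#'   of a `structure_model` atom table).
#' @return Signed volume in cubic Angstroms, or `NA` if indeterminate.
#' @export
chirality_sign <- function(residue_atoms) {
  need <- c("N", "CA", "C", "CB")
  idx <- match(need, residue_atoms$atom_name)
  if (anyNA(idx)) return(NA_real_)
  p <- as.matrix(residue_atoms[idx, c("x", "y", "z")])
  ca <- p[2, ]
  triple_product(p[1, ] - ca, p[3, ] - ca, p[4, ] - ca)
}

#' Reflect a structure through a coordinate plane
#'
#' Produces the mirror image of a structure by negating the coordinate
#' component normal to the chosen plane (the d-PDB transform).  The
#' reflection is an exact isometry with determinant -1: all interatomic
#' distances are preserved and the chirality sign of every chiral residue
#' flips, converting L-residues to D and vice versa.  Applying the same
#' mirror twice is the identity.  Any choice of plane yields equivalent
#' mirror images up to a proper rotation; the default (`"xy"`, negate z)
#' is fixed for reproducibility.
#'
#' @param s A `structure_model` or `segment`.
#' @param plane One of `"xy"` (negate z, default), `"xz"` (negate y),
#'   `"yz"` (negate x).
#' @param center Point on the mirror plane (length-3 numeric, default the
#'   origin).  Using the structure centroid keeps the mirror image in
#'   place.
#' @return The mirrored structure, same class as the input, with residue
#'   handedness flags swapped (L to D and D to L; glycine unchanged).
#' @export
mirror_structure <- function(s, plane = c("xy", "xz", "yz"),
                             center = c(0, 0, 0)) {
  stopifnot(inherits(s, "structure_model"))
  plane <- match.arg(plane)
  if (nrow(s$atoms) == 0) stopf("cannot mirror an empty structure")
  axis <- switch(plane, xy = "z", xz = "y", yz = "x")
  c0 <- center[match(axis, c("x", "y", "z"))]
  out <- s
  out$atoms[[axis]] <- 2 * c0 - out$atoms[[axis]]
  h <- out$atoms$handedness
  out$atoms$handedness <- ifelse(h == "L", "D", ifelse(h == "D", "L", h))
  out
}

#' Audit the chirality of every residue in a structure
#'
#' @param s A `structure_model` or `segment`.
#' @param reference Optionally, the same structure before some transform;
#'   if given, `fraction_flipped` reports the fraction of chiral residues
#'   whose signed volume changed sign relative to it.
#' @return A `chirality_report`: data frame with per-residue signed
#'   volume (cubic Angstroms) and handedness call, plus attribute
#'   `fraction_flipped` when `reference` is supplied.
#' @export
chirality_report <- function(s, reference = NULL) {
  res <- residues(s)
  sv <- vapply(seq_len(nrow(res)), function(i) {
    a <- s$atoms[s$atoms$chain_id == res$chain_id[i] &
                   s$atoms$res_seq == res$res_seq[i], , drop = FALSE]
    chirality_sign(a)
  }, numeric(1))
  call <- ifelse(is.na(sv),
                 ifelse(res$res_name == "GLY", "achiral", "unknown"),
                 ifelse(sv * L_REFERENCE_SIGN > 0, "L", "D"))
  rep <- data.frame(res, signed_volume = sv, handedness_call = call,
                    stringsAsFactors = FALSE)
  rep$handedness <- NULL
  if (!is.null(reference)) {
    ref <- chirality_report(reference)
    m <- match(paste(rep$chain_id, rep$res_seq),
               paste(ref$chain_id, ref$res_seq))
    both <- !is.na(rep$signed_volume) & !is.na(ref$signed_volume[m])
    attr(rep, "fraction_flipped") <-
      if (any(both)) mean(sign(rep$signed_volume[both]) !=
                            sign(ref$signed_volume[m][both])) else NA_real_
  }
  class(rep) <- c("chirality_report", class(rep))
  rep
}
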