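#' Read a molecular structure into the internal coordinate model
#'
#' Parses a PDB file (via bio3d) into a `structure_model`: a flat atom
#' table with one row per atom and columns `chain_id`, `res_seq`,
#' `res_name`, `atom_name`, `element`, `x`, `y`, `z`, `occupancy`,
#' `serial`, `hydrogen`, `handedness`.  Alternate locations are resolved
#' to a single atom per (residue, atom name) by highest occupancy, ties
#' broken alphabetically by altloc identifier.  HETATM records are
#' excluded; hydrogens are retained but flagged.  Residue handedness is
#' called from the chirality sign of each residue (see
#' [chirality_sign()]); glycine is `"achiral"`, residues with incomplete
#' N/CA/C/CB sets are `"unknown"`.
#'
#' Insertion codes are not supported and raise an error: the intended
#' inputs are simple peptide/protein chains with plain author numbering.
#'
#' @param path Path to a PDB file.
#' @param model_index Which MODEL to read from a multi-model file,
#'   1-based.  Default 1 (the first model).
#' @param keep_hetatm Keep HETATM records (default `FALSE`).
#' @return An object of class `structure_model`.
#' @seealso [write_structure()], [extract_segment()]
#' @export
read_structure <- function(path, model_index = 1, keep_hetatm = FALSE) {
  if (!file.exists(path)) stopf("structure file not found: %s", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stopf("failed to parse '%s' as PDB: %s", path,
                              conditionMessage(e))
  )
  n_models <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  if (model_index < 1 || model_index > n_models) {
    stopf("model_index %d out of range: file has %d model(s)",
          model_index, n_models)
  }
  at <- pdb$atom
  xyz <- if (is.matrix(pdb$xyz)) pdb$xyz[model_index, ] else pdb$xyz
  at$x <- xyz[seq(1, length(xyz), by = 3)][seq_len(nrow(at))]
  at$y <- xyz[seq(2, length(xyz), by = 3)][seq_len(nrow(at))]
  at$z <- xyz[seq(3, length(xyz), by = 3)][seq_len(nrow(at))]

  if (!keep_hetatm) at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stopf("no ATOM records in %s", path)
  if (any(!is.na(at$insert) & nzchar(at$insert))) {
    stopf("insertion codes are not supported (found in %s)", path)
  }

  # altloc resolution: highest occupancy, tie -> alphabetically first id
  alt <- ifelse(is.na(at$alt), "", at$alt)
  occ <- ifelse(is.na(at$o), 1, at$o)
  key <- paste(at$chain, at$resno, at$elety, sep = "\r")
  ord <- order(key, -occ, alt)
  at <- at[ord[!duplicated(key[ord])], , drop = FALSE]
  at <- at[order(at$chain, at$resno, at$eleno), , drop = FALSE]

  element <- at$elesy
  missing_el <- is.na(element) | !nzchar(trimws(element))
  element[missing_el] <- substr(gsub("[0-9'\"]", "", at$elety[missing_el]), 1, 1)
  element <- toupper(trimws(element))

  atoms <- data.frame(
    chain_id = at$chain,
    res_seq = as.integer(at$resno),
    res_name = at$resid,
    atom_name = at$elety,
    element = element,
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    serial = as.integer(at$eleno),
    hydrogen = element %in% c("H", "D"),
    stringsAsFactors = FALSE
  )

  atoms$handedness <- NA_character_
  sm <- new_structure_model(atoms, entry_id = entry_id_from_path(path),
                            source_path = path)
  sm$atoms$handedness <- call_handedness(sm)
  validate_structure_model(sm)
  sm
}

entry_id_from_path <- function(path) {
  toupper(sub("\\.(pdb|ent|cif)$", "", basename(path), ignore.case = TRUE))
}

new_structure_model <- function(atoms, entry_id, source_path = NA_character_) {
  structure(
    list(entry_id = entry_id, source_path = source_path, atoms = atoms),
    class = "structure_model"
  )
}

validate_structure_model <- function(s) {
  a <- s$atoms
  if (nrow(a) == 0) stopf("structure '%s' has no atoms", s$entry_id)
  if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z))) {
    stopf("structure '%s' has non-finite coordinates", s$entry_id)
  }
  dup <- duplicated(a[, c("chain_id", "res_seq", "atom_name")])
  if (any(dup)) {
    stopf("duplicate atom '%s' in residue %s%d of '%s'",
          a$atom_name[dup][1], a$chain_id[dup][1], a$res_seq[dup][1],
          s$entry_id)
  }
  invisible(s)
}

# Per-residue handedness calls for a whole structure_model.
call_handedness <- function(s) {
  a <- s$atoms
  key <- paste(a$chain_id, a$res_seq, sep = "\r")
  out <- rep(NA_character_, nrow(a))
  for (k in unique(key)) {
    idx <- which(key == k)
    sv <- chirality_sign(a[idx, , drop = FALSE])
    out[idx] <- if (is.na(sv)) {
      if (a$res_name[idx[1]] == "GLY") "achiral" else "unknown"
    } else if (sv * L_REFERENCE_SIGN > 0) "L" else "D"
  }
  out
}

#' @export
print.structure_model <- function(x, ...) {
  ch <- split(x$atoms$res_seq, x$atoms$chain_id)
  cat(sprintf("structure_model '%s': %d chain(s), %d residue(s), %d atom(s)\n",
              x$entry_id, length(ch),
              length(unique(paste(x$atoms$chain_id, x$atoms$res_seq))),
              nrow(x$atoms)))
  for (cid in names(ch)) {
    cat(sprintf("  chain %s: residues %d..%d\n", cid, min(ch[[cid]]),
                max(ch[[cid]])))
  }
  invisible(x)
}

#' Per-residue summary of a structure
#'
#' @param s A `structure_model` or `segment`.
#' @return Data frame with one row per residue: `chain_id`, `res_seq`,
#'   `res_name`, `n_atoms`, `handedness`.
#' @export
residues <- function(s) {
  a <- if (inherits(s, "structure_model")) s$atoms else s$atoms
  key <- paste(a$chain_id, a$res_seq, sep = "\r")
  first <- !duplicated(key)
  data.frame(
    chain_id = a$chain_id[first],
    res_seq = a$res_seq[first],
    res_name = a$res_name[first],
    n_atoms = as.integer(table(key)[key[first]]),
    handedness = a$handedness[first],
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Extract a contiguous residue segment from one chain
#'
#' Residue numbering follows the author `res_seq` values as read from the
#' file (1-based, inclusive range).  Any missing residue number inside the
#' range is an error: segments must be contiguous.
#'
#' @param s A `structure_model`.
#' @param chain_id Chain identifier.
#' @param start_seq_id,end_seq_id First and last residue numbers
#'   (inclusive).
#' @return An object of class `segment` (also a `structure_model`
#'   restricted to the range) with fields `chain_id`, `start`, `end`.
#' @export
extract_segment <- function(s, chain_id, start_seq_id, end_seq_id) {
  stopifnot(inherits(s, "structure_model"))
  if (start_seq_id > end_seq_id) stopf("start_seq_id > end_seq_id")
  a <- s$atoms[s$atoms$chain_id == chain_id, , drop = FALSE]
  if (nrow(a) == 0) stopf("chain '%s' not present in '%s'", chain_id, s$entry_id)
  want <- seq.int(start_seq_id, end_seq_id)
  have <- unique(a$res_seq)
  missing <- setdiff(want, have)
  if (length(missing) > 0) {
    stopf("segment %s:%d-%d has gap(s): missing residue(s) %s",
          chain_id, start_seq_id, end_seq_id,
          paste(missing, collapse = ", "))
  }
  a <- a[a$res_seq %in% want, , drop = FALSE]
  a <- a[order(a$res_seq, a$serial), , drop = FALSE]
  seg <- new_structure_model(a, entry_id = s$entry_id,
                             source_path = s$source_path)
  seg$chain_id <- chain_id
  seg$start <- as.integer(start_seq_id)
  seg$end <- as.integer(end_seq_id)
  class(seg) <- c("segment", class(seg))
  seg
}

#' @export
print.segment <- function(x, ...) {
  cat(sprintf("segment %s:%d-%d of '%s' (%d residues, %d atoms)\n",
              x$chain_id, x$start, x$end, x$entry_id,
              x$end - x$start + 1, nrow(x$atoms)))
  invisible(x)
}

#' Length of a segment in residues
#' @param seg A `segment`.
#' @return Integer residue count.
#' @export
segment_length <- function(seg) seg$end - seg$start + 1L

#' Write a structure or assembled peptide to a PDB file
#'
#' D-residues keep their parent 3-letter code by default; handedness is
#' carried in the in-memory model only.  With `d_prefix = TRUE`,
#' D-flagged residues of standard types are written with D-prefixed codes
#' (e.g. `DAL` for D-alanine, `DPH` for D-phenylalanine) for downstream
#' tools that expect explicit d-residue naming.
#'
#' @param s A `structure_model`, `segment` or `assembled_peptide`.
#' @param path Output file path.
#' @param d_prefix Write D-prefixed residue codes for D-residues.
#' @return Invisibly, the path written.
#' @export
write_structure <- function(s, path, d_prefix = FALSE) {
  atoms <- if (inherits(s, "assembled_peptide")) s$atoms else s$atoms
  if (is.null(atoms) || nrow(atoms) == 0) stopf("nothing to write: empty model")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stopf("refusing to write non-finite coordinates")
  }
  resid <- atoms$res_name
  if (d_prefix) {
    dsel <- !is.na(atoms$handedness) & atoms$handedness == "D" &
      resid %in% names(AA_3TO1) & resid != "GLY"
    resid[dsel] <- paste0("D", substr(resid[dsel], 1, 2))
  }
  ok <- tryCatch({
    bio3d::write.pdb(
      file = path,
      xyz = as.numeric(t(as.matrix(atoms[, c("x", "y", "z")]))),
      type = rep("ATOM", nrow(atoms)),
      resno = atoms$res_seq,
      resid = resid,
      eleno = seq_len(nrow(atoms)),
      elety = atoms$atom_name,
      chain = atoms$chain_id,
      o = atoms$occupancy,
      b = rep(0, nrow(atoms)),
      elesy = atoms$element
    )
    TRUE
  }, error = function(e) stopf("cannot write '%s': %s", path,
                               conditionMessage(e)))
  invisible(path)
}
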