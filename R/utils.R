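# Internal geometry and bookkeeping helpers shared across modules.

AA_3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)
AA_1TO3 <- stats::setNames(names(AA_3TO1), unname(AA_3TO1))

`%||%` <- function(a, b) if (is.null(a)) b else a

vnorm <- function(v) sqrt(sum(v * v))

#' @noRd
deg2rad <- function(x) x * pi / 180

# Place a new atom from three reference positions using internal
# coordinates (NeRF construction): `d` bond length to c, `theta` the
# b-c-new angle (degrees), `chi` the a-b-c-new torsion (degrees).
place_atom <- function(a, b, c, d, theta, chi) {
  theta <- deg2rad(theta)
  chi <- deg2rad(chi)
  bc <- c - b
  bc <- bc / vnorm(bc)
  ab <- b - a
  n <- pracma_cross(ab, bc)
  n <- n / vnorm(n)
  m <- pracma_cross(n, bc)
  d2 <- c(-d * cos(theta), d * sin(theta) * cos(chi), d * sin(theta) * sin(chi))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# cross product (kept local; avoids pulling a package in for one line)
pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# Scalar triple product det[u, v, w].
triple_product <- function(u, v, w) {
  sum(u * pracma_cross(v, w))
}

# Canonical atom-record column order used by every structure-like object.
atom_columns <- function() {
  c("chain_id", "res_seq", "res_name", "atom_name", "element",
    "x", "y", "z", "occupancy", "serial", "hydrogen", "handedness")
}

empty_atom_table <- function() {
  data.frame(
    chain_id = character(), res_seq = integer(), res_name = character(),
    atom_name = character(), element = character(),
    x = numeric(), y = numeric(), z = numeric(),
    occupancy = numeric(), serial = integer(),
    hydrogen = logical(), handedness = character(),
    stringsAsFactors = FALSE
  )
}

coords_matrix <- function(atoms) {
  m <- as.matrix(atoms[, c("x", "y", "z"), drop = FALSE])
  dimnames(m) <- list(atoms$atom_name, c("x", "y", "z"))
  m
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
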