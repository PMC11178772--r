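#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr filter mutate arrange group_by summarise ungroup select
#'   bind_rows left_join distinct n across all_of row_number
#' @importFrom stats setNames
NULL

# three-letter -> one-letter residue codes (20 standard)
AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)
AA1TO3 <- setNames(names(AA3TO1), unname(AA3TO1))
AA_LETTERS <- unname(AA3TO1)

vec_norm <- function(v) sqrt(sum(v * v))

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unit <- function(v) v / vec_norm(v)

#' Dihedral angle of four points
#'
#' Signed torsion angle A-B-C-D in degrees, IUPAC convention: 0 at cis,
#' positive clockwise when looking from B towards C, range (-180, 180].
#'
#' @param a,b,c,d numeric 3-vectors (coordinates, Angstrom).
#' @return angle in degrees.
#' @export
#' @examples
#' dihedral(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(0, 1, 1)) # -90
dihedral <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, n2)
  x <- sum(n1 * n2)
  y <- sum(m1 * unit(b2))
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# deterministic child seeds below 2^31, derived from one master seed
derive_seed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(k) * 7919L %% 2147483647L
}
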