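#' @keywords internal
"_PACKAGE"

# Residue names treated as water throughout the package.
.WATER_NAMES <- c("HOH", "WAT", "DOD", "H2O")

#' Wrap a signed angular difference into (-180, 180]
#'
#' Angular quantities (dihedrals, their differences) live on a circle; the
#' minimal signed difference between two angles near +/-180 degrees must wrap
#' rather than jump by ~360.
#'
#' @param x numeric vector of angles or angle differences, degrees.
#' @return numeric vector in (-180, 180].
#' @examples
#' wrap_angle(179 - (-179))  # -2, not 358
#' @export
wrap_angle <- function(x) {
  out <- ((x + 180) %% 360) - 180
  out[!is.na(out) & out == -180] <- 180
  out
}

# 3-vector cross product
.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.vnorm <- function(v) sqrt(sum(v^2))

.unit <- function(v) {
  n <- .vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues' formula; used to construct known rigid motions for fixtures
#' and invariance checks.
#'
#' @param axis length-3 axis vector (normalised internally).
#' @param deg rotation angle in degrees.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, deg) {
  u <- .unit(axis)
  th <- deg * pi / 180
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# One-letter amino-acid code from 3-letter residue names; nonstandard -> "X".
.AA321 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
            MSE = "M", SEC = "U", PYL = "O")

aa_one_letter <- function(resname) {
  out <- unname(.AA321[toupper(resname)])
  out[is.na(out)] <- "X"
  out
}

.AA123 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
            Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
            L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
            S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

aa_three_letter <- function(aa) {
  out <- unname(.AA123[toupper(aa)])
  out[is.na(out)] <- "UNK"
  out
}
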