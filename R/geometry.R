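#' Signed dihedral angle of four points
#'
#' Standard IUPAC convention: cis = 0, trans = +/-180, sign by the right-hand
#' rule looking down the p2-p3 bond.
#'
#' @param p1,p2,p3,p4 length-3 numeric coordinates (Angstrom).
#' @return angle in degrees, in (-180, 180].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- .cross(b1, b2)
  n2 <- .cross(b2, b3)
  if (.vnorm(n1) < 1e-9 || .vnorm(n2) < 1e-9)
    stop("undefined dihedral: collinear bounding triple")
  m1 <- .cross(n1, b2 / .vnorm(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  wrap_angle(atan2(y, x) * 180 / pi)
}

#' Interior bond angle at the middle point
#'
#' @param p1,p2,p3 length-3 numeric coordinates; the angle is at `p2`.
#' @return angle in degrees, in [0, 180].
#' @export
bond_angle <- function(p1, p2, p3) {
  u <- p1 - p2
  v <- p3 - p2
  nu <- .vnorm(u)
  nv <- .vnorm(v)
  if (nu < 1e-9 || nv < 1e-9) stop("zero-length bond in angle computation")
  acos(max(-1, min(1, sum(u * v) / (nu * nv)))) * 180 / pi
}

# Simplified 4-region Ramachandran partition by phi/psi boxes. The boxes are
# deliberately coarse (the analysis only needs qualitative region shifts):
#   alpha:      phi in [-160, -20], psi in [-120,  50]
#   beta:       phi in [-180, -20], psi in [  90, 180] u [-180, -150]
#   left-alpha: phi in [  20, 120], psi in [ -30, 100]
#   other:      everything else
.rama_region <- function(phi, psi) {
  if (is.na(phi) || is.na(psi)) return(NA_character_)
  if (phi >= -160 && phi <= -20 && psi >= -120 && psi <= 50) return("alpha")
  if (phi >= -180 && phi <= -20 && (psi >= 90 || psi <= -150)) return("beta")
  if (phi >= 20 && phi <= 120 && psi >= -30 && psi <= 100)
    return("left-alpha")
  "other"
}

#' Per-residue backbone geometry of one chain
#'
#' Computes phi/psi/omega dihedrals, the three backbone bond angles
#' (N-CA-C, CA-C-N(+1), C(-1)-N-CA) and a simplified Ramachandran region for
#' every residue of a chain. Quantities whose defining atoms are missing, or
#' that span a chain break (peptide C-N distance > 2.0 Angstrom), are `NA`
#' rather than fabricated. Phi is undefined at the first residue, psi and
#' omega at the last.
#'
#' @param model [structure_model].
#' @param chain chain id.
#' @return data.frame of class `residue_geometry` with columns `chain`,
#'   `resseq`, `icode`, `resname`, `phi`, `psi`, `omega`, `ang_n_ca_c`,
#'   `ang_ca_c_n`, `ang_c_n_ca`, `rama`.
#' @export
chain_geometry <- function(model, chain) {
  res <- chain_residues(model, chain)
  n <- nrow(res)
  sub <- model$atoms[model$atoms$chain == chain & !model$atoms$hetero &
                       !model$atoms$is_water, , drop = FALSE]
  model <- list(atoms = sub)  # lookups below only touch $atoms
  get <- function(i, name) {
    if (i < 1 || i > n) return(NULL)
    .atom_xyz(model, chain, res$resseq[i], name, res$icode[i])
  }
  any_bb <- any(vapply(seq_len(n), function(i)
    !is.null(get(i, "N")) || !is.null(get(i, "CA")) || !is.null(get(i, "C")),
    logical(1)))
  if (!any_bb) stop("chain '", chain, "' has no backbone atoms")
  linked <- function(i) {
    # peptide bond between residue i and i+1 present and unbroken
    c_i <- get(i, "C")
    n_j <- get(i + 1, "N")
    !is.null(c_i) && !is.null(n_j) && .vnorm(n_j - c_i) <= 2.0
  }
  dih <- function(a, b, c, d) {
    if (is.null(a) || is.null(b) || is.null(c) || is.null(d))
      return(NA_real_)
    tryCatch(dihedral_angle(a, b, c, d), error = function(e) NA_real_)
  }
  ang <- function(a, b, c) {
    if (is.null(a) || is.null(b) || is.null(c)) return(NA_real_)
    tryCatch(bond_angle(a, b, c), error = function(e) NA_real_)
  }
  out <- res[, c("chain", "resseq", "icode", "resname")]
  out$phi <- out$psi <- out$omega <- NA_real_
  out$ang_n_ca_c <- out$ang_ca_c_n <- out$ang_c_n_ca <- NA_real_
  for (i in seq_len(n)) {
    Ni <- get(i, "N"); CAi <- get(i, "CA"); Ci <- get(i, "C")
    out$ang_n_ca_c[i] <- ang(Ni, CAi, Ci)
    if (i > 1 && linked(i - 1)) {
      Cp <- get(i - 1, "C")
      out$phi[i] <- dih(Cp, Ni, CAi, Ci)
      out$ang_c_n_ca[i] <- ang(Cp, Ni, CAi)
    }
    if (i < n && linked(i)) {
      Nn <- get(i + 1, "N"); CAn <- get(i + 1, "CA")
      out$psi[i] <- dih(Ni, CAi, Ci, Nn)
      out$omega[i] <- dih(CAi, Ci, Nn, CAn)
      out$ang_ca_c_n[i] <- ang(CAi, Ci, Nn)
    }
  }
  out$rama <- vapply(seq_len(n), function(i)
    .rama_region(out$phi[i], out$psi[i]), character(1))
  class(out) <- c("residue_geometry", "data.frame")
  out
}

#' Backbone-geometry difference profile between two chains
#'
#' For every paired residue, computes the signed minimal angular difference
#' (B minus A, wrapped into (-180, 180]) of each backbone quantity, converts
#' each quantity's differences to z-scores over the chain, and flags residues
#' with any |z| >= `z_threshold`. The z-score normalisation population is the
#' chain itself, so a handful of genuinely remodelled residues stand out
#' against the chain's background variation.
#'
#' @param geom_a,geom_b [chain_geometry()] results for the paired chains.
#' @param pairing [pair_residues()] result mapping chain A to chain B.
#' @param z_threshold flagging threshold in standard deviations (default 2).
#' @return object of class `geometry_diff`: data.frame with one row per
#'   paired residue and columns `resseq_a`, `resseq_b`, `d_<quantity>` and
#'   `z_<quantity>` for each of phi, psi, omega and the three bond angles,
#'   plus `max_abs_z`; sorted by `max_abs_z` (descending). Attribute
#'   `flagged` holds the flagged residue rows.
#' @export
geometry_diff <- function(geom_a, geom_b, pairing, z_threshold = 2.0) {
  ka <- paste(geom_a$resseq, geom_a$icode, sep = "|")
  kb <- paste(geom_b$resseq, geom_b$icode, sep = "|")
  ia <- match(paste(pairing$resseq_a, pairing$icode_a, sep = "|"), ka)
  ib <- match(paste(pairing$resseq_b, pairing$icode_b, sep = "|"), kb)
  ok <- !is.na(ia) & !is.na(ib)
  ia <- ia[ok]; ib <- ib[ok]
  quantities <- c("phi", "psi", "omega",
                  "ang_n_ca_c", "ang_ca_c_n", "ang_c_n_ca")
  out <- data.frame(resseq_a = geom_a$resseq[ia],
                    resseq_b = geom_b$resseq[ib],
                    resname_a = geom_a$resname[ia],
                    stringsAsFactors = FALSE)
  n_def <- 0
  for (q in quantities) {
    d <- wrap_angle(geom_b[[q]][ib] - geom_a[[q]][ia])
    z <- rep(NA_real_, length(d))
    def <- !is.na(d)
    if (sum(def) >= 3) {
      s <- stats::sd(d[def])
      z[def] <- if (is.na(s) || s < 1e-12) 0 else
        (d[def] - mean(d[def])) / s
      n_def <- max(n_def, sum(def))
    }
    out[[paste0("d_", q)]] <- d
    out[[paste0("z_", q)]] <- z
  }
  if (n_def < 3)
    stop("fewer than 3 paired residues with defined angles; cannot form z-scores")
  zc <- as.matrix(out[, paste0("z_", quantities)])
  out$max_abs_z <- apply(abs(zc), 1, function(r)
    if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE))
  out$flagged <- !is.na(out$max_abs_z) & out$max_abs_z >= z_threshold
  out <- out[order(-out$max_abs_z, out$resseq_a), ]
  rownames(out) <- NULL
  structure(out, z_threshold = z_threshold,
            flagged = out[out$flagged, , drop = FALSE],
            class = c("geometry_diff", "data.frame"))
}

#' @export
print.geometry_diff <- function(x, ...) {
  fl <- attr(x, "flagged")
  cat("geometry_diff: ", nrow(x), " paired residues, ", nrow(fl),
      " flagged at |z| >= ", attr(x, "z_threshold"), "\n", sep = "")
  if (nrow(fl))
    cat("  flagged:", paste(fl$resseq_a, collapse = " "), "\n")
  invisible(x)
}

#' Mean peptide-bond non-planarity of a chain or region
#'
#' Operationalises "planarity" of the backbone as the mean absolute
#' deviation of the omega dihedral from 180 degrees (trans peptide) over the
#' requested residues; smaller is more planar.
#'
#' @param geom [chain_geometry()] result.
#' @param resseq optional residue numbers to restrict to.
#' @return mean |omega - 180| in degrees.
#' @export
omega_planarity <- function(geom, resseq = NULL) {
  g <- geom
  if (!is.null(resseq)) g <- g[g$resseq %in% resseq, , drop = FALSE]
  om <- g$omega[!is.na(g$omega)]
  if (length(om) == 0) return(NA_real_)
  mean(abs(wrap_angle(om - 180)))
}
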