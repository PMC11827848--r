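#' Optimal least-squares superposition of paired point sets (Kabsch)
#'
#' Returns the proper rotation and translation minimising the (optionally
#' weighted) RMSD of point set B onto point set A. A reflection arising from
#' the SVD is corrected by flipping the sign of the smallest singular value's
#' axis, so `det(rotation)` is always +1.
#'
#' @param points_a,points_b N x 3 matrices of paired coordinates (Angstrom).
#' @param weights optional non-negative N-vector.
#' @return list with `rotation` (3 x 3), `translation` (length 3) and `rmsd`;
#'   the transform maps B onto A: `x_A ~ rotation %*% x_B + translation`.
#' @export
kabsch <- function(points_a, points_b, weights = NULL) {
  A <- as.matrix(points_a)
  B <- as.matrix(points_b)
  if (!is.matrix(A) || ncol(A) != 3 || !is.matrix(B) || ncol(B) != 3 ||
      nrow(A) != nrow(B))
    stop("points must be matched N x 3 matrices")
  n <- nrow(A)
  if (n < 3) stop("insufficient points: need at least 3 pairs, got ", n)
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (length(w) != n || any(w < 0) || sum(w) <= 0)
    stop("weights must be non-negative with positive sum")
  wa <- colSums(A * w) / sum(w)
  wb <- colSums(B * w) / sum(w)
  Ac <- sweep(A, 2, wa)
  Bc <- sweep(B, 2, wb)
  H <- t(Bc * w) %*% Ac
  s <- svd(H)
  if (sum(svd(Ac)$d > 1e-8 * max(svd(Ac)$d, 1e-12)) < 2)
    stop("degenerate (collinear) point configuration")
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- wa - as.vector(R %*% wb)
  resid <- Ac - Bc %*% t(R)
  rmsd <- sqrt(sum(w * rowSums(resid^2)) / sum(w))
  list(rotation = R, translation = tr, rmsd = rmsd)
}

#' Apply a superposition transform to coordinates
#'
#' @param xyz N x 3 matrix.
#' @param fit list with `rotation` and `translation` (as from [kabsch()]).
#' @return transformed N x 3 matrix.
#' @export
apply_transform <- function(xyz, fit) {
  as.matrix(xyz) %*% t(fit$rotation) +
    matrix(fit$translation, nrow(xyz), 3, byrow = TRUE)
}

# Matched coordinate pairs for a pairing under an atom selector.
# Returns list(A, B, pair_index) where pair_index maps atom rows back to
# rows of the pairing.
.paired_atoms <- function(model_a, model_b, pairing,
                          atom_selector = c("CA", "backbone", "all")) {
  atom_selector <- match.arg(atom_selector)
  sel_names <- switch(atom_selector,
                      CA = "CA",
                      backbone = c("N", "CA", "C", "O"),
                      all = NULL)
  A <- list(); B <- list(); idx <- list()
  for (k in seq_len(nrow(pairing))) {
    ia <- .residue_index(model_a, pairing$chain_a[k], pairing$resseq_a[k],
                         pairing$icode_a[k])
    ib <- .residue_index(model_b, pairing$chain_b[k], pairing$resseq_b[k],
                         pairing$icode_b[k])
    na <- model_a$atoms$name[ia]
    nb <- model_b$atoms$name[ib]
    common <- intersect(na, nb)
    if (!is.null(sel_names)) common <- intersect(common, sel_names)
    if (length(common) == 0) next
    A[[length(A) + 1]] <- atom_coords(model_a, ia[match(common, na)])
    B[[length(B) + 1]] <- atom_coords(model_b, ib[match(common, nb)])
    idx[[length(idx) + 1]] <- rep(k, length(common))
  }
  if (length(A) == 0) stop("empty selection: no common atoms across pairing")
  list(A = do.call(rbind, A), B = do.call(rbind, B),
       pair_index = unlist(idx))
}

#' Iterative superposition with outlier rejection
#'
#' Cycle 0 superposes all residue pairs bearing the selected atoms. Each
#' subsequent cycle computes per-pair deviations under the current fit,
#' rejects pairs whose deviation exceeds `reject_sigma` standard deviations
#' of the retained deviations, and refits; iteration stops early once no
#' pair is rejected. This is the alignment convention behind "r.m.s.d. over
#' N of M C-alpha" statistics reported by common structure-comparison tools.
#'
#' @param model_a,model_b [structure_model]s (A is the reference).
#' @param pairing [pair_residues()] / [pair_protomers()] result.
#' @param atom_selector `"CA"` (default), `"backbone"`, or `"all"`.
#' @param cycles maximum rejection cycles (default 5).
#' @param reject_sigma rejection threshold in multiples of the deviation
#'   standard deviation (default 2.0). Deviations are departures from a
#'   perfect fit, so their standard deviation is taken about zero (the RMS
#'   deviation) rather than about their mean.
#' @param min_deviation absolute floor (Angstrom) below which a pair is
#'   never rejected, so essentially perfect alignments are not eroded by
#'   numerical noise (default 0.01).
#' @return object of class `alignment_result`: list with `rotation`,
#'   `translation`, `rmsd_final`, `n_retained`, `n_initial`, `cycles_run`,
#'   `retained_pairs` (data.frame of pairing rows kept) and `rejected_pairs`
#'   (with the cycle and deviation at rejection).
#' @export
iterative_align <- function(model_a, model_b, pairing,
                            atom_selector = c("CA", "backbone", "all"),
                            cycles = 5, reject_sigma = 2.0,
                            min_deviation = 0.01) {
  atom_selector <- match.arg(atom_selector)
  pa <- .paired_atoms(model_a, model_b, pairing, atom_selector)
  n_initial <- length(unique(pa$pair_index))
  if (n_initial < 3)
    stop("insufficient pairs with selected atoms (need >= 3, got ",
         n_initial, ")")
  retained <- sort(unique(pa$pair_index))
  rejected <- data.frame(pair = integer(0), cycle = integer(0),
                         deviation = numeric(0))
  fit <- NULL
  cycles_run <- 0L
  repeat {
    keep <- pa$pair_index %in% retained
    fit <- kabsch(pa$A[keep, , drop = FALSE], pa$B[keep, , drop = FALSE])
    if (cycles_run >= cycles) break
    # per-pair deviation: RMS over that residue pair's selected atoms
    Bt <- apply_transform(pa$B, fit)
    d2 <- rowSums((pa$A - Bt)^2)
    dev <- sqrt(vapply(retained, function(k)
      mean(d2[pa$pair_index == k]), numeric(1)))
    thr <- max(reject_sigma * sqrt(mean(dev^2)), min_deviation)
    out <- which(dev > thr)
    if (length(out) == 0 || is.na(thr)) break
    if (length(out) >= length(retained))
      stop("all pairs rejected; increase reject_sigma")
    rejected <- rbind(rejected, data.frame(
      pair = retained[out], cycle = cycles_run + 1L, deviation = dev[out]))
    retained <- retained[-out]
    cycles_run <- cycles_run + 1L
  }
  structure(list(
    rotation = fit$rotation, translation = fit$translation,
    rmsd_final = fit$rmsd, n_retained = length(retained),
    n_initial = n_initial, cycles_run = cycles_run,
    retained_pairs = as.data.frame(pairing)[retained, , drop = FALSE],
    rejected_pairs = rejected,
    atom_selector = atom_selector),
    class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf(
    "alignment_result: rmsd %.3f A over %d of %d pairs (%s atoms, %d rejection cycle(s))\n",
    x$rmsd_final, x$n_retained, x$n_initial, x$atom_selector, x$cycles_run))
  invisible(x)
}

#' RMSD between two models over a residue pairing
#'
#' With `transform = NULL` a plain (non-iterative) Kabsch superposition is
#' performed first; with a supplied transform the RMSD is evaluated under it
#' directly (pass `transform = list(rotation = diag(3), translation =
#' c(0,0,0))` for the unfitted deviation).
#'
#' @inheritParams iterative_align
#' @param transform optional list with `rotation` and `translation`.
#' @return RMSD in Angstrom (scalar).
#' @export
rmsd_between <- function(model_a, model_b, pairing,
                         atom_selector = c("CA", "backbone", "all"),
                         transform = NULL) {
  atom_selector <- match.arg(atom_selector)
  if (nrow(pairing) == 0) stop("empty pairing")
  pa <- .paired_atoms(model_a, model_b, pairing, atom_selector)
  if (is.null(transform)) {
    kabsch(pa$A, pa$B)$rmsd
  } else {
    Bt <- apply_transform(pa$B, transform)
    sqrt(mean(rowSums((pa$A - Bt)^2)))
  }
}
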