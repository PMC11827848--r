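#' Parse a residue-range selection expression
#'
#' Selections such as `"C:1-89"` or `"T:199-272,I:40-135"` name a chain (or
#' role) and an author-numbering range; multiple comma-separated terms are
#' allowed.
#'
#' @param x selection string, or an already-parsed data.frame (returned
#'   unchanged).
#' @return data.frame with columns `chain`, `from`, `to`.
#' @export
parse_selection <- function(x) {
  if (is.data.frame(x)) return(x)
  terms <- strsplit(x, ",", fixed = TRUE)[[1]]
  out <- lapply(trimws(terms), function(tm) {
    m <- regmatches(tm, regexec("^([^:]+):(-?[0-9]+)-(-?[0-9]+)$", tm))[[1]]
    if (length(m) != 4) stop("cannot parse selection term '", tm, "'")
    data.frame(chain = m[2], from = as.integer(m[3]), to = as.integer(m[4]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# rows of `pairing` whose A-side residue falls in the selection
.pairing_rows_in <- function(pairing, selection, role_map = NULL) {
  sel <- parse_selection(selection)
  hit <- rep(FALSE, nrow(pairing))
  for (k in seq_len(nrow(sel))) {
    ch <- sel$chain[k]
    # allow role names when the pairing carries a role column
    if (!is.null(pairing$role) && ch %in% pairing$role) {
      rows <- pairing$role == ch
    } else if (!is.null(role_map) && ch %in% role_map$role) {
      rows <- pairing$chain_a %in% role_map$chain[role_map$role == ch]
    } else {
      rows <- pairing$chain_a == ch
    }
    hit <- hit | (rows & pairing$resseq_a >= sel$from[k] &
                    pairing$resseq_a <= sel$to[k])
  }
  which(hit)
}

#' Rigid-body rotation of a sub-domain after core superposition
#'
#' Quantifies how much a domain has rotated between two structures relative
#' to a shared rigid core: (i) the core residue pairs are superposed with
#' [iterative_align()]; (ii) the domain C-alpha pairs are fitted with a
#' separate Kabsch superposition; (iii) the relative rotation between the
#' two fits gives the domain rotation angle and axis (angle from the
#' rotation-matrix trace, axis from the antisymmetric part). Axes of
#' rotations below 0.5 degrees are flagged unreliable.
#'
#' @param model_a,model_b [structure_model]s.
#' @param pairing residue pairing between them (A-side numbering is used for
#'   the selections).
#' @param core_selection,domain_selection selection expressions (see
#'   [parse_selection()]); the defaults target the TnnI/TnnT coiled-coil
#'   (ITarm) as core and the TnnC N-lobe (residues 1-89, which carries the
#'   activation EF-hand) as domain. Role names (`TnnC`/`TnnT`/`TnnI`) may be
#'   used when the pairing has a `role` column.
#' @param cycles,reject_sigma passed to the core [iterative_align()].
#' @return object of class `domain_rotation`: list with `angle` (degrees),
#'   `axis` (unit 3-vector), `axis_reliable`, `core_rmsd`, `domain_rmsd`,
#'   `domain_residuals` (per-residue Angstrom after the domain fit),
#'   `n_core`, `n_domain`.
#' @export
domain_rotation <- function(model_a, model_b, pairing,
                            core_selection = "TnnT:199-272,TnnI:40-135",
                            domain_selection = "TnnC:1-89",
                            cycles = 5, reject_sigma = 2.0) {
  core_rows <- .pairing_rows_in(pairing, core_selection)
  dom_rows <- .pairing_rows_in(pairing, domain_selection)
  if (length(intersect(core_rows, dom_rows)) > 0)
    stop("core and domain selections overlap")
  if (length(core_rows) < 3 || length(dom_rows) < 3)
    stop("need >= 3 paired residues in both core and domain")
  core_pairing <- pairing[core_rows, , drop = FALSE]
  dom_pairing <- pairing[dom_rows, , drop = FALSE]
  core_fit <- iterative_align(model_a, model_b, core_pairing,
                              atom_selector = "CA", cycles = cycles,
                              reject_sigma = reject_sigma)
  dom <- .paired_atoms(model_a, model_b, dom_pairing, "CA")
  dom_fit <- kabsch(dom$A, dom$B)
  # both fits map B-frame coordinates into the A frame; composing core
  # forward with domain inverse gives the rotation carrying the reference
  # domain onto the alternate domain, expressed in the reference frame
  R_rel <- core_fit$rotation %*% t(dom_fit$rotation)
  tr <- sum(diag(R_rel))
  angle <- acos(max(-1, min(1, (tr - 1) / 2))) * 180 / pi
  s <- c(R_rel[3, 2] - R_rel[2, 3],
         R_rel[1, 3] - R_rel[3, 1],
         R_rel[2, 1] - R_rel[1, 2])
  axis <- if (.vnorm(s) > 1e-9) .unit(s) else c(NA_real_, NA_real_, NA_real_)
  Bt <- apply_transform(dom$B, dom_fit)
  resid <- sqrt(rowSums((dom$A - Bt)^2))
  structure(list(
    angle = angle, axis = axis, axis_reliable = angle >= 0.5,
    core_rmsd = core_fit$rmsd_final, domain_rmsd = dom_fit$rmsd,
    domain_residuals = data.frame(
      chain = dom_pairing$chain_a[dom$pair_index],
      resseq = dom_pairing$resseq_a[dom$pair_index],
      residual = resid, stringsAsFactors = FALSE),
    n_core = core_fit$n_retained, n_domain = length(unique(dom$pair_index)),
    core_selection = core_selection, domain_selection = domain_selection),
    class = "domain_rotation")
}

#' @export
print.domain_rotation <- function(x, ...) {
  cat(sprintf(
    "domain_rotation: %.2f deg about [%.3f %.3f %.3f]%s (core rmsd %.3f A over %d CA; domain %d CA)\n",
    x$angle, x$axis[1], x$axis[2], x$axis[3],
    if (x$axis_reliable) "" else " [axis unreliable]",
    x$core_rmsd, x$n_core, x$n_domain))
  invisible(x)
}
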