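#' Construct a structure model from an atom table
#'
#' `structure_model` is the coordinate container used throughout the package:
#' a flat atom table plus metadata, in the spirit of a crystallographic
#' coordinate file. Atoms are stored in file order; residue identity is the
#' author numbering triple `(chain, resseq, icode)`.
#'
#' @param atoms data.frame with columns `serial`, `name`, `altloc`, `resname`,
#'   `chain`, `resseq`, `icode`, `x`, `y`, `z`, `occ`, `b`, `element`,
#'   `hetero`. Missing `serial`/`altloc`/`icode`/`occ`/`b`/`element` columns
#'   are filled with defaults; `element` is inferred from the atom name when
#'   absent.
#' @param identifier short name for the model (PDB code or fixture name).
#' @param metadata optional list; recognised entries are `space_group` and
#'   `cell` (length-6 numeric: a, b, c, alpha, beta, gamma).
#' @return object of class `structure_model`.
#' @export
structure_model <- function(atoms, identifier = "model", metadata = list()) {
  stopifnot(is.data.frame(atoms))
  need <- c("name", "resname", "chain", "resseq", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("atom table missing column(s): ", paste(miss, collapse = ", "))
  n <- nrow(atoms)
  if (n == 0) stop("empty coordinate set: model has no atoms")
  if (is.null(atoms$serial)) atoms$serial <- seq_len(n)
  if (is.null(atoms$altloc)) atoms$altloc <- ""
  if (is.null(atoms$icode)) atoms$icode <- ""
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (is.null(atoms$b)) atoms$b <- 0
  if (is.null(atoms$hetero)) atoms$hetero <- FALSE
  if (is.null(atoms$element))
    atoms$element <- toupper(substr(gsub("[0-9' ]", "", atoms$name), 1, 1))
  atoms$altloc[is.na(atoms$altloc)] <- ""
  atoms$icode[is.na(atoms$icode)] <- ""
  atoms$resseq <- as.integer(atoms$resseq)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite atom coordinates")
  if (any(atoms$occ < 0 | atoms$occ > 1, na.rm = TRUE))
    stop("occupancy outside [0, 1]")
  atoms$is_water <- toupper(atoms$resname) %in% .WATER_NAMES
  cols <- c("serial", "name", "altloc", "resname", "chain", "resseq", "icode",
            "x", "y", "z", "occ", "b", "element", "hetero", "is_water")
  atoms <- atoms[, cols]
  rownames(atoms) <- NULL
  structure(list(identifier = identifier, atoms = atoms, metadata = metadata),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  a <- x$atoms
  ch <- unique(a$chain[!a$hetero])
  het <- sum(a$hetero & !a$is_water)
  wat <- sum(a$is_water)
  cat("structure_model \"", x$identifier, "\": ",
      nrow(a), " atoms, ", length(ch), " polymer chain(s) [",
      paste(ch, collapse = ","), "], ",
      het, " hetero atom(s), ", wat, " water(s)\n", sep = "")
  if (!is.null(x$metadata$space_group))
    cat("  space group: ", x$metadata$space_group, "\n", sep = "")
  invisible(x)
}

#' Coordinates of selected atoms as an N x 3 matrix
#'
#' @param model structure_model.
#' @param sel logical or integer index into the atom table (default all).
#' @return numeric matrix with columns x, y, z.
#' @export
atom_coords <- function(model, sel = TRUE) {
  as.matrix(model$atoms[sel, c("x", "y", "z"), drop = FALSE])
}

#' Residue table of one chain
#'
#' One row per residue of a chain, in file order, with the one-letter code.
#' Hetero residues and waters are excluded.
#'
#' @param model structure_model.
#' @param chain chain identifier.
#' @return data.frame with columns `chain`, `resseq`, `icode`, `resname`, `aa`.
#' @export
chain_residues <- function(model, chain) {
  a <- model$atoms
  a <- a[a$chain == chain & !a$hetero & !a$is_water, , drop = FALSE]
  if (nrow(a) == 0) stop("no polymer atoms in chain '", chain, "'")
  key <- paste(a$resseq, a$icode, sep = "|")
  keep <- !duplicated(key)
  out <- data.frame(chain = a$chain[keep], resseq = a$resseq[keep],
                    icode = a$icode[keep], resname = a$resname[keep],
                    stringsAsFactors = FALSE)
  out$aa <- aa_one_letter(out$resname)
  rownames(out) <- NULL
  out
}

#' One-letter sequence of a chain
#'
#' @inheritParams chain_residues
#' @return character scalar.
#' @export
chain_sequence <- function(model, chain) {
  paste(chain_residues(model, chain)$aa, collapse = "")
}

#' Polymer chain identifiers of a model
#'
#' @param model structure_model.
#' @return character vector in file order.
#' @export
polymer_chains <- function(model) {
  a <- model$atoms
  unique(a$chain[!a$hetero & !a$is_water])
}

# Index of atoms belonging to residue (chain, resseq, icode)
.residue_index <- function(model, chain, resseq, icode = "") {
  a <- model$atoms
  which(a$chain == chain & a$resseq == resseq & a$icode == icode)
}

# Look up one atom's coordinates within a residue; NULL when absent.
.atom_xyz <- function(model, chain, resseq, name, icode = "") {
  i <- .residue_index(model, chain, resseq, icode)
  i <- i[model$atoms$name[i] == name]
  if (length(i) == 0) return(NULL)
  as.numeric(model$atoms[i[1], c("x", "y", "z")])
}

#' Apply a rigid-body transform to a model
#'
#' @param model structure_model.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 numeric.
#' @param sel optional logical/integer atom selection; default all atoms.
#' @return transformed structure_model.
#' @export
transform_model <- function(model, rotation = diag(3),
                            translation = c(0, 0, 0), sel = TRUE) {
  xyz <- atom_coords(model, sel)
  xyz <- xyz %*% t(rotation) + matrix(translation, nrow(xyz), 3, byrow = TRUE)
  model$atoms[sel, c("x", "y", "z")] <- xyz
  model
}
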