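#' Read a PDB or mmCIF coordinate file
#'
#' Parses a macromolecular coordinate file (fixed-column PDB or mmCIF
#' `atom_site` records, via bio3d) into a [structure_model]. All ATOM and
#' HETATM records are retained; alternate locations are resolved to the
#' highest-occupancy conformer (ties broken by the alphabetically first
#' altloc identifier); waters are flagged. Author residue numbering is used
#' throughout.
#'
#' @param path file path.
#' @param format_hint optional `"pdb"` or `"mmcif"`; by default inferred from
#'   the file extension (`.cif`/`.mmcif` vs anything else).
#' @param keep_altlocs if TRUE, keep all alternate-location records instead of
#'   resolving them.
#' @return [structure_model].
#' @export
read_structure <- function(path, format_hint = NULL, keep_altlocs = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  fmt <- format_hint
  if (is.null(fmt)) {
    fmt <- if (grepl("\\.(cif|mmcif)(\\.gz)?$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  fmt <- match.arg(fmt, c("pdb", "mmcif"))
  pdb <- tryCatch(
    if (fmt == "mmcif") {
      # read.cif emits advisory warnings (beta status, secondary-structure
      # records) that are irrelevant to coordinate extraction
      suppressWarnings(bio3d::read.cif(path, verbose = FALSE,
                                       rm.alt = FALSE))
    } else {
      suppressWarnings(bio3d::read.pdb(path, verbose = FALSE,
                                       rm.alt = FALSE))
    },
    error = function(e) stop("could not parse '", path, "' as ", fmt, ": ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0)
    stop("empty coordinate set in '", path, "'")
  atoms <- data.frame(
    serial = as.integer(at$eleno),
    name = as.character(at$elety),
    altloc = ifelse(is.na(at$alt), "", as.character(at$alt)),
    resname = as.character(at$resid),
    chain = ifelse(is.na(at$chain), "", as.character(at$chain)),
    resseq = as.integer(at$resno),
    icode = ifelse(is.na(at$insert), "", as.character(at$insert)),
    x = at$x, y = at$y, z = at$z,
    occ = ifelse(is.na(at$o), 1, at$o),
    b = ifelse(is.na(at$b), 0, at$b),
    element = toupper(ifelse(is.na(at$elesy) | at$elesy == "",
                             substr(gsub("[0-9' ]", "", at$elety), 1, 1),
                             as.character(at$elesy))),
    hetero = at$type == "HETATM",
    stringsAsFactors = FALSE)
  if (!keep_altlocs) atoms <- .resolve_altlocs(atoms)
  meta <- .read_cell_metadata(path, fmt)
  id <- sub("\\.(pdb|ent|cif|mmcif)(\\.gz)?$", "",
            basename(path), ignore.case = TRUE)
  structure_model(atoms, identifier = id, metadata = meta)
}

# Keep, per (chain, resseq, icode, name), the highest-occupancy altloc;
# ties go to the alphabetically first altloc identifier.
.resolve_altlocs <- function(atoms) {
  key <- paste(atoms$chain, atoms$resseq, atoms$icode, atoms$name, sep = "|")
  if (!anyDuplicated(key)) return(atoms)
  ord <- order(key, -atoms$occ, atoms$altloc)
  keep_serial <- atoms$serial[ord][!duplicated(key[ord])]
  out <- atoms[atoms$serial %in% keep_serial, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Unit-cell / space-group metadata: CRYST1 for PDB, _cell/_symmetry for mmCIF.
.read_cell_metadata <- function(path, fmt) {
  meta <- list()
  lines <- tryCatch(readLines(path, n = 5000L, warn = FALSE),
                    error = function(e) character())
  if (fmt == "pdb") {
    cr <- grep("^CRYST1", lines, value = TRUE)
    if (length(cr)) {
      cr <- cr[1]
      cell <- suppressWarnings(as.numeric(c(
        substr(cr, 7, 15), substr(cr, 16, 24), substr(cr, 25, 33),
        substr(cr, 34, 40), substr(cr, 41, 47), substr(cr, 48, 54))))
      if (all(is.finite(cell))) meta$cell <- cell
      sg <- trimws(substr(cr, 56, 66))
      if (nzchar(sg)) meta$space_group <- sg
    }
  } else {
    grab <- function(tag) {
      ln <- grep(paste0("^", tag, "[[:space:]]"), lines, value = TRUE)
      if (!length(ln)) return(NA)
      gsub("['\"]", "", trimws(sub(paste0("^", tag), "", ln[1])))
    }
    cell <- suppressWarnings(as.numeric(c(
      grab("_cell.length_a"), grab("_cell.length_b"), grab("_cell.length_c"),
      grab("_cell.angle_alpha"), grab("_cell.angle_beta"),
      grab("_cell.angle_gamma"))))
    if (all(is.finite(cell))) meta$cell <- cell
    sg <- grab("_symmetry.space_group_name_H-M")
    if (!is.na(sg) && nzchar(sg)) meta$space_group <- sg
  }
  meta
}

#' Write a structure model as a PDB file
#'
#' Fixed-column PDB output (via bio3d), suitable for round-tripping fixtures
#' through [read_structure()].
#'
#' @param model [structure_model].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  a <- model$atoms
  xyz <- as.vector(t(as.matrix(a[, c("x", "y", "z")])))
  bio3d::write.pdb(
    pdb = NULL, file = path, xyz = xyz,
    type = ifelse(a$hetero, "HETATM", "ATOM"),
    resno = a$resseq, resid = a$resname, eleno = a$serial,
    elety = a$name, chain = ifelse(a$chain == "", NA, a$chain),
    insert = ifelse(a$icode == "", NA, a$icode),
    alt = ifelse(a$altloc == "", NA, a$altloc),
    o = a$occ, b = a$b, elesy = a$element, end = TRUE)
  invisible(path)
}
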