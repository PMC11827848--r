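#' Locate metal ions and label the troponin calcium sites
#'
#' Finds hetero atoms of the requested element (calcium ions are HETATM
#' records with element or residue name "CA"; the hetero flag disambiguates
#' them from C-alpha atoms). When a role map is supplied, each ion is
#' labelled: `Ca1-activation` if it sits within `activation_cutoff` of any
#' atom of TnnC residues 60-80 (the activation EF-hand), otherwise
#' `Ca2-structural`/`Ca3-structural` in residue-number order (the C-lobe
#' sites), else `unassigned`.
#'
#' @param model [structure_model].
#' @param roles optional [assign_roles()] map used for labelling and
#'   protomer attribution.
#' @param element element symbol (default `"CA"`).
#' @param activation_range TnnC residue range defining the activation site
#'   neighbourhood (default 60:80).
#' @param activation_cutoff distance (Angstrom) to that neighbourhood for the
#'   Ca1 label (default 5).
#' @return data.frame with one row per ion: `serial`, `chain`, `resseq`,
#'   `element`, `protomer`, `label`. Empty (with a message) when none found.
#' @export
find_metal_sites <- function(model, roles = NULL, element = "CA",
                             activation_range = 60:80,
                             activation_cutoff = 5.0) {
  a <- model$atoms
  hit <- a$hetero & !a$is_water &
    (toupper(a$element) == toupper(element) |
       toupper(a$resname) == toupper(element))
  out <- a[hit, c("serial", "chain", "resseq", "element"), drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0) {
    message("no ", element, " ions found in ", model$identifier)
    out$protomer <- character(0)
    out$label <- character(0)
    return(out)
  }
  out$protomer <- NA_character_
  out$label <- "unassigned"
  if (!is.null(roles)) {
    prot <- attr(roles, "protomers")
    mxyz <- atom_coords(model, which(hit))
    near_min <- function(sel, p) {
      m <- atom_coords(model, sel)
      if (nrow(m) == 0) return(Inf)
      min(sqrt(rowSums((m - matrix(p, nrow(m), 3, byrow = TRUE))^2)))
    }
    for (i in seq_len(nrow(out))) {
      d <- vapply(prot, function(chs)
        near_min(a$chain %in% chs & !a$hetero & !a$is_water, mxyz[i, ]),
        numeric(1))
      out$protomer[i] <- names(prot)[which.min(d)]
    }
    for (p in unique(out$protomer)) {
      tc <- tryCatch(role_chain(roles, "TnnC", p), error = function(e) NULL)
      rows <- which(out$protomer == p)
      if (is.null(tc)) next
      act_sel <- a$chain == tc & !a$hetero & !a$is_water &
        a$resseq %in% activation_range
      d_act <- vapply(rows, function(i)
        near_min(act_sel, as.numeric(mxyz[i, ])), numeric(1))
      is_ca1 <- d_act <= activation_cutoff
      out$label[rows[is_ca1]] <- "Ca1-activation"
      struct <- rows[!is_ca1][order(out$resseq[rows[!is_ca1]])]
      if (length(struct) >= 1) out$label[struct[1]] <- "Ca2-structural"
      if (length(struct) >= 2) out$label[struct[2]] <- "Ca3-structural"
    }
  }
  out
}

# Ligand category from residue/atom identity.
.ligand_category <- function(resname, atom, element, is_water) {
  ifelse(is_water, "water",
         ifelse(element == "O" & atom %in% c("O", "OXT"), "backbone-O",
                ifelse(element == "O", "sidechain-O", "other")))
}

#' Coordination sphere of one metal ion
#'
#' Enumerates oxygen (and optionally nitrogen) atoms within `cutoff` of the
#' metal, with exact distances and ligand categories. Bidentate carboxylates
#' contribute one ligand per coordinating atom. Waters are listed when
#' requested but never counted in `n_protein_bonds`, matching the convention
#' of reporting protein coordination bonds.
#'
#' @param model [structure_model].
#' @param metal one row of [find_metal_sites()], or a serial number.
#' @param cutoff metal-ligand distance cutoff in Angstrom (default 3.2;
#'   typical Ca-O coordination distances are 2.3-2.9).
#' @param include_waters list water ligands (default FALSE).
#' @param include_nitrogen also consider nitrogen ligands (default FALSE).
#' @return object of class `coordination_site`: list with `metal` (row of
#'   the atom table), `label`, `ligands` (data.frame: `chain`, `resseq`,
#'   `resname`, `atom`, `distance`, `category`), `n_protein_bonds`,
#'   `mean_protein_distance`, `cutoff`.
#' @export
coordination_sphere <- function(model, metal, cutoff = 3.2,
                                include_waters = FALSE,
                                include_nitrogen = FALSE) {
  if (cutoff <= 0) stop("cutoff must be positive")
  if (is.numeric(metal)) metal <- list(serial = metal, label = "unassigned")
  a <- model$atoms
  mi <- which(a$serial == metal$serial)
  if (length(mi) != 1) stop("metal atom with serial ", metal$serial,
                            " not found")
  mp <- as.numeric(a[mi, c("x", "y", "z")])
  elems <- "O"
  if (include_nitrogen) elems <- c(elems, "N")
  cand <- which(toupper(a$element) %in% elems &
                  seq_len(nrow(a)) != mi &
                  (!a$is_water | include_waters) &
                  !(a$hetero & !a$is_water))
  if (length(cand) > 0) {
    m <- atom_coords(model, cand)
    d <- sqrt(rowSums((m - matrix(mp, nrow(m), 3, byrow = TRUE))^2))
    keep <- d <= cutoff
    cand <- cand[keep]
    d <- d[keep]
  } else d <- numeric(0)
  lig <- data.frame(chain = a$chain[cand], resseq = a$resseq[cand],
                    resname = a$resname[cand], atom = a$name[cand],
                    distance = d,
                    category = .ligand_category(a$resname[cand],
                                                a$name[cand],
                                                toupper(a$element[cand]),
                                                a$is_water[cand]),
                    stringsAsFactors = FALSE)
  lig <- lig[order(lig$distance), ]
  rownames(lig) <- NULL
  prot <- lig$category != "water"
  structure(list(
    metal = a[mi, ], label = metal$label %||% "unassigned",
    ligands = lig,
    n_protein_bonds = sum(prot),
    mean_protein_distance = if (any(prot)) mean(lig$distance[prot]) else
      NA_real_,
    cutoff = cutoff),
    class = "coordination_site")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.coordination_site <- function(x, ...) {
  cat(sprintf("coordination_site [%s]: %d protein bond(s), mean %.2f A (cutoff %.2f A)\n",
              x$label, x$n_protein_bonds,
              x$mean_protein_distance, x$cutoff))
  if (nrow(x$ligands)) print.data.frame(x$ligands, row.names = FALSE)
  invisible(x)
}

#' Differential comparison of two coordination sites
#'
#' Matches ligand identities (residue, atom) across the two sites via the
#' residue pairing, reporting ligands lost (present in A only), gained
#' (present in B only), the per-shared-ligand distance change and the change
#' in mean protein-ligand distance. A side-chain rearrangement such as the
#' S69 flip appears as a lost (or regained) `OG` ligand.
#'
#' @param site_a,site_b [coordination_sphere()] results sharing a label.
#' @param pairing optional [pair_residues()]/[pair_protomers()] result used
#'   to translate residue numbering of A into B (required when the two
#'   structures' numbering differs, e.g. across a deletion). With `NULL`,
#'   residues are matched by (chain, resseq) directly.
#' @return object of class `site_comparison`: list with `lost`, `gained`
#'   (data.frames of ligands), `shared` (with `distance_a`, `distance_b`,
#'   `d_distance`), and `d_mean_distance`.
#' @export
compare_sites <- function(site_a, site_b, pairing = NULL) {
  if (!identical(site_a$label, site_b$label))
    stop("site labels differ: ", site_a$label, " vs ", site_b$label)
  la <- site_a$ligands[site_a$ligands$category != "water", , drop = FALSE]
  lb <- site_b$ligands[site_b$ligands$category != "water", , drop = FALSE]
  # map A residues into B numbering
  if (!is.null(pairing)) {
    pk <- paste(pairing$chain_a, pairing$resseq_a, sep = "|")
    i <- match(paste(la$chain, la$resseq, sep = "|"), pk)
    chain_m <- ifelse(is.na(i), la$chain, pairing$chain_b[i])
    res_m <- ifelse(is.na(i), la$resseq, pairing$resseq_b[i])
  } else {
    chain_m <- la$chain
    res_m <- la$resseq
  }
  key_a <- paste(chain_m, res_m, la$atom, sep = "|")
  key_b <- paste(lb$chain, lb$resseq, lb$atom, sep = "|")
  lost <- la[!(key_a %in% key_b), , drop = FALSE]
  gained <- lb[!(key_b %in% key_a), , drop = FALSE]
  sh_a <- la[key_a %in% key_b, , drop = FALSE]
  sh_b <- lb[match(key_a[key_a %in% key_b], key_b), , drop = FALSE]
  shared <- data.frame(chain = sh_b$chain, resseq = sh_b$resseq,
                       resname = sh_b$resname, atom = sh_b$atom,
                       distance_a = sh_a$distance, distance_b = sh_b$distance,
                       d_distance = sh_b$distance - sh_a$distance,
                       stringsAsFactors = FALSE)
  rownames(lost) <- rownames(gained) <- rownames(shared) <- NULL
  structure(list(lost = lost, gained = gained, shared = shared,
                 d_mean_distance =
                   site_b$mean_protein_distance - site_a$mean_protein_distance),
            class = "site_comparison")
}

#' @export
print.site_comparison <- function(x, ...) {
  cat(sprintf("site_comparison: %d lost, %d gained, %d shared; mean distance change %+.2f A\n",
              nrow(x$lost), nrow(x$gained), nrow(x$shared),
              x$d_mean_distance))
  if (nrow(x$lost))
    cat("  lost:  ", paste0(x$lost$resname, x$lost$resseq, ":", x$lost$atom,
                            collapse = " "), "\n")
  if (nrow(x$gained))
    cat("  gained:", paste0(x$gained$resname, x$gained$resseq, ":",
                            x$gained$atom, collapse = " "), "\n")
  invisible(x)
}

#' Side-chain flip metric: chi1 and side-chain oxygen to metal distance
#'
#' Quantifies a serine/threonine-type side-chain flip relative to a metal:
#' the chi1 dihedral (N-CA-CB-gamma atom) and the distance from the
#' side-chain gamma oxygen to the metal.
#'
#' @param model [structure_model].
#' @param chain,resseq residue identity (author numbering).
#' @param metal one row of [find_metal_sites()] or a serial number.
#' @param icode insertion code (default none).
#' @return list with `chi1` (degrees) and `distance` (Angstrom).
#' @export
sidechain_flip_metric <- function(model, chain, resseq, metal, icode = "") {
  if (is.numeric(metal)) metal <- list(serial = metal)
  a <- model$atoms
  mi <- which(a$serial == metal$serial)
  if (length(mi) != 1) stop("metal atom not found")
  mp <- as.numeric(a[mi, c("x", "y", "z")])
  N <- .atom_xyz(model, chain, resseq, "N", icode)
  CA <- .atom_xyz(model, chain, resseq, "CA", icode)
  CB <- .atom_xyz(model, chain, resseq, "CB", icode)
  gamma_names <- c("OG", "OG1", "SG", "CG", "CG1")
  G <- NULL
  for (g in gamma_names) {
    G <- .atom_xyz(model, chain, resseq, g, icode)
    if (!is.null(G)) { gname <- g; break }
  }
  if (is.null(N) || is.null(CA) || is.null(CB) || is.null(G))
    stop("residue ", chain, ":", resseq,
         " lacks the side-chain atoms needed for chi1")
  ox <- .atom_xyz(model, chain, resseq, "OG", icode)
  if (is.null(ox)) ox <- .atom_xyz(model, chain, resseq, "OG1", icode)
  if (is.null(ox)) stop("residue ", chain, ":", resseq,
                        " has no side-chain gamma oxygen")
  list(chi1 = dihedral_angle(N, CA, CB, G),
       distance = .vnorm(ox - mp))
}
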