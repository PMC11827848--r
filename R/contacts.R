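# Atom-name sets used by the contact classifier.
.POS_SIDECHAIN_N <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                         HIS = c("ND1", "NE2"))
.NEG_SIDECHAIN_O <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
.APOLAR_RES <- c("ALA", "VAL", "LEU", "ILE", "MET", "PHE", "PRO", "TRP")

#' Classify ionic, hydrogen-bond and hydrophobic contacts
#'
#' Distance-criterion contact classification over a set of chains:
#' * ionic: side-chain nitrogen of Arg/Lys (and His when `his_charged`)
#'   within `cutoffs$ionic` of a side-chain carboxylate oxygen of Asp/Glu;
#' * hbond: any protein N/O within `cutoffs$hbond` of another N/O (distance
#'   criterion only -- crystallographic models carry no hydrogens, so no
#'   donor-H-acceptor angle term is applied);
#' * hydrophobic: side-chain carbon of an apolar residue within
#'   `cutoffs$hydrophobic` of another such carbon.
#'
#' Each residue pair is reported once per type at its minimum qualifying
#' distance; intra-chain pairs require a sequence separation of at least
#' `min_seqsep`.
#'
#' @param model [structure_model].
#' @param chains chain ids to analyse (default: all polymer chains).
#' @param cutoffs named list of distance cutoffs in Angstrom
#'   (default ionic 4.0, hbond 3.5, hydrophobic 4.5).
#' @param min_seqsep minimum |residue separation| for intra-chain contacts
#'   (default 2).
#' @param his_charged treat histidine side-chain nitrogens as charged
#'   (default TRUE; protonation is not knowable from coordinates).
#' @return object of class `contact_list`: data.frame with columns
#'   `chain_a`, `resseq_a`, `resname_a`, `atom_a`, `chain_b`, `resseq_b`,
#'   `resname_b`, `atom_b`, `type`, `distance`, `span`.
#' @export
classify_contacts <- function(model, chains = NULL,
                              cutoffs = list(ionic = 4.0, hbond = 3.5,
                                             hydrophobic = 4.5),
                              min_seqsep = 2, his_charged = TRUE) {
  if (is.null(chains)) chains <- polymer_chains(model)
  a <- model$atoms
  sel <- a$chain %in% chains & !a$hetero & !a$is_water
  a <- a[sel, , drop = FALSE]
  if (nrow(a) < 2) stop("fewer than 2 atoms selected for contact analysis")
  a$el <- toupper(a$element)

  pos_names <- .POS_SIDECHAIN_N
  if (!his_charged) pos_names$HIS <- NULL
  in_set <- function(tab) {
    idx <- rep(FALSE, nrow(a))
    for (rn in names(tab)) idx <- idx | (a$resname == rn & a$name %in% tab[[rn]])
    idx
  }
  sets <- list(
    ionic = list(i = which(in_set(pos_names)),
                 j = which(in_set(.NEG_SIDECHAIN_O)),
                 cut = cutoffs$ionic),
    hbond = list(i = which(a$el %in% c("N", "O")),
                 j = which(a$el %in% c("N", "O")),
                 cut = cutoffs$hbond),
    hydrophobic = list(
      i = which(a$el == "C" & !(a$name %in% c("C", "CA")) &
                  a$resname %in% .APOLAR_RES),
      j = which(a$el == "C" & !(a$name %in% c("C", "CA")) &
                  a$resname %in% .APOLAR_RES),
      cut = cutoffs$hydrophobic))

  res <- list()
  for (ty in names(sets)) {
    s <- sets[[ty]]
    if (length(s$i) == 0 || length(s$j) == 0) next
    xi <- as.matrix(a[s$i, c("x", "y", "z")])
    xj <- as.matrix(a[s$j, c("x", "y", "z")])
    d2 <- outer(rowSums(xi^2), rep(1, nrow(xj))) +
      outer(rep(1, nrow(xi)), rowSums(xj^2)) - 2 * xi %*% t(xj)
    hit <- which(d2 <= s$cut^2 + 1e-12, arr.ind = TRUE)
    if (nrow(hit) == 0) next
    ii <- s$i[hit[, 1]]
    jj <- s$j[hit[, 2]]
    keep <- (a$chain[ii] != a$chain[jj]) |
      (abs(a$resseq[ii] - a$resseq[jj]) >= min_seqsep)
    keep <- keep & !(ii == jj)
    ii <- ii[keep]; jj <- jj[keep]
    if (length(ii) == 0) next
    dd <- sqrt(pmax(0, d2[hit][keep]))
    # canonical residue-pair orientation, then one row per pair at min dist
    swap <- paste(a$chain[ii], sprintf("%06d", a$resseq[ii])) >
      paste(a$chain[jj], sprintf("%06d", a$resseq[jj]))
    i1 <- ifelse(swap, jj, ii)
    j1 <- ifelse(swap, ii, jj)
    key <- paste(a$chain[i1], a$resseq[i1], a$chain[j1], a$resseq[j1])
    ord <- order(key, dd)
    first <- !duplicated(key[ord])
    pick <- ord[first]
    res[[ty]] <- data.frame(
      chain_a = a$chain[i1[pick]], resseq_a = a$resseq[i1[pick]],
      resname_a = a$resname[i1[pick]], atom_a = a$name[i1[pick]],
      chain_b = a$chain[j1[pick]], resseq_b = a$resseq[j1[pick]],
      resname_b = a$resname[j1[pick]], atom_b = a$name[j1[pick]],
      type = ty, distance = dd[pick],
      span = ifelse(a$chain[i1[pick]] == a$chain[j1[pick]],
                    "intra-chain", "inter-chain"),
      stringsAsFactors = FALSE)
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(chain_a = character(0), resseq_a = integer(0),
               resname_a = character(0), atom_a = character(0),
               chain_b = character(0), resseq_b = integer(0),
               resname_b = character(0), atom_b = character(0),
               type = character(0), distance = numeric(0),
               span = character(0), stringsAsFactors = FALSE)
  out <- out[order(out$type, out$chain_a, out$resseq_a,
                   out$chain_b, out$resseq_b), ]
  rownames(out) <- NULL
  structure(out, cutoffs = cutoffs,
            class = c("contact_list", "data.frame"))
}

#' Gained and lost contacts between two structures
#'
#' Contacts are keyed by (residue pair, type) with chain B's residues
#' translated into chain A's numbering through the residue pairing, so that
#' a deletion-induced numbering offset does not masquerade as contact
#' turnover. `gained` are keys present in B only; `lost` in A only.
#'
#' @param contacts_a,contacts_b [classify_contacts()] results.
#' @param pairing [pair_protomers()] (or [pair_residues()]) result mapping
#'   structure A residues to structure B residues. `NULL` matches by
#'   (chain, resseq) directly.
#' @return object of class `contact_diff`: list with `gained`, `lost`
#'   (contact data.frames) and `summary` (counts per chain pair and type).
#' @export
contact_diff <- function(contacts_a, contacts_b, pairing = NULL) {
  map_b_to_a <- function(chain, resseq) {
    if (is.null(pairing)) return(list(chain = chain, resseq = resseq))
    pk <- paste(pairing$chain_b, pairing$resseq_b, sep = "|")
    i <- match(paste(chain, resseq, sep = "|"), pk)
    list(chain = ifelse(is.na(i), chain, pairing$chain_a[i]),
         resseq = ifelse(is.na(i), NA_integer_, pairing$resseq_a[i]))
  }
  key_of <- function(chain_a, res_a, chain_b, res_b, type) {
    if (length(chain_a) == 0) return(character(0))
    left <- paste0(chain_a, ":", res_a)
    right <- paste0(chain_b, ":", res_b)
    swap <- left > right
    paste(ifelse(swap, right, left), ifelse(swap, left, right), type)
  }
  ka <- key_of(contacts_a$chain_a, contacts_a$resseq_a,
               contacts_a$chain_b, contacts_a$resseq_b, contacts_a$type)
  mb1 <- map_b_to_a(contacts_b$chain_a, contacts_b$resseq_a)
  mb2 <- map_b_to_a(contacts_b$chain_b, contacts_b$resseq_b)
  kb <- key_of(mb1$chain, mb1$resseq, mb2$chain, mb2$resseq,
               contacts_b$type)
  lost <- contacts_a[!(ka %in% kb), , drop = FALSE]
  gained <- contacts_b[!(kb %in% ka), , drop = FALSE]
  rownames(lost) <- rownames(gained) <- NULL
  sum_tab <- function(x, what) {
    if (nrow(x) == 0) return(NULL)
    agg <- stats::aggregate(list(n = rep(1L, nrow(x))),
                            by = list(chain_a = x$chain_a,
                                      chain_b = x$chain_b,
                                      type = x$type,
                                      change = rep(what, nrow(x))),
                            FUN = sum)
    agg
  }
  smry <- rbind(sum_tab(gained, "gained"), sum_tab(lost, "lost"))
  structure(list(gained = gained, lost = lost, summary = smry),
            class = "contact_diff")
}

#' @export
print.contact_diff <- function(x, ...) {
  cat("contact_diff: ", nrow(x$gained), " gained, ",
      nrow(x$lost), " lost\n", sep = "")
  if (!is.null(x$summary)) print.data.frame(x$summary, row.names = FALSE)
  invisible(x)
}
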