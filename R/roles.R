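#' Expected author-numbering ranges of the troponin construct chains
#'
#' The crystallised construct spans TnnT2 residues 183-288, TnnI residues
#' 32-166 and TnnC residues 1-161; chains are assigned roles by overlap of
#' their observed author numbering with these ranges.
#'
#' @return named list of length-2 integer ranges.
#' @export
troponin_role_ranges <- function() {
  list(TnnC = c(1L, 161L), TnnT = c(183L, 288L), TnnI = c(32L, 166L))
}

#' Assign troponin chain roles and group chains into protomers
#'
#' Each polymer chain is assigned the role whose expected residue-number
#' range maximally overlaps the chain's observed author numbering (ties and
#' zero overlap give role `"other"`). Chains are then grouped into protomers:
#' complexes frequently crystallise with more than one copy of the
#' heterotrimer per asymmetric unit, and each copy is the mutually nearest
#' TnnC/TnnT/TnnI triple by chain-centroid distance. The protomer containing
#' the first chain in file order is labelled `"A"`, the next `"B"`, and so on.
#'
#' @param model [structure_model].
#' @param expected_ranges named list of `c(from, to)` author-numbering ranges,
#'   one per role (default [troponin_role_ranges()]).
#' @return object of class `chain_role_map`: a data.frame with columns
#'   `chain`, `role`, `protomer`, plus attribute `protomers` (named list of
#'   chain-id vectors).
#' @export
assign_roles <- function(model, expected_ranges = troponin_role_ranges()) {
  chains <- polymer_chains(model)
  if (length(chains) == 0) stop("model has no polymer chains")
  roles <- vapply(chains, function(ch) {
    obs <- unique(model$atoms$resseq[model$atoms$chain == ch &
                                       !model$atoms$hetero &
                                       !model$atoms$is_water])
    ov <- vapply(expected_ranges, function(r)
      sum(obs >= r[1] & obs <= r[2]), integer(1))
    if (max(ov) == 0) "other" else names(expected_ranges)[which.max(ov)]
  }, character(1))
  cents <- t(vapply(chains, function(ch) {
    sel <- model$atoms$chain == ch & !model$atoms$hetero & !model$atoms$is_water
    colMeans(atom_coords(model, sel))
  }, numeric(3)))

  map <- data.frame(chain = chains, role = unname(roles),
                    protomer = NA_character_, stringsAsFactors = FALSE)

  # group mutually nearest C/T/I triples; seed each group from the first
  # unassigned chain in file order so labels are deterministic
  core_roles <- intersect(c("TnnC", "TnnT", "TnnI"), unique(map$role))
  unassigned <- which(map$role %in% core_roles)
  label_i <- 0L
  while (length(unassigned) > 0) {
    seed <- unassigned[1]
    members <- seed
    for (r in setdiff(core_roles, map$role[seed])) {
      cand <- unassigned[map$role[unassigned] == r]
      if (length(cand) == 0) next
      d <- sqrt(rowSums((cents[cand, , drop = FALSE] -
                           matrix(cents[seed, ], length(cand), 3,
                                  byrow = TRUE))^2))
      members <- c(members, cand[which.min(d)])
    }
    label_i <- label_i + 1L
    map$protomer[members] <- LETTERS[label_i]
    unassigned <- setdiff(unassigned, members)
  }

  # a complete protomer has one chain per role
  for (p in unique(stats::na.omit(map$protomer))) {
    tab <- table(map$role[!is.na(map$protomer) & map$protomer == p])
    if (any(tab > 1))
      stop("ambiguous role assignment in protomer ", p, ": ",
           paste(names(tab)[tab > 1], collapse = ", "),
           " claimed by multiple chains (",
           paste(map$chain[map$protomer == p], collapse = ","), ")")
  }
  prot <- split(map$chain[!is.na(map$protomer)],
                map$protomer[!is.na(map$protomer)])
  structure(map, protomers = prot, class = c("chain_role_map", "data.frame"))
}

#' @export
print.chain_role_map <- function(x, ...) {
  cat("chain_role_map:\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Extract one protomer (plus its hetero atoms) as a sub-model
#'
#' Polymer chains of the requested protomer are retained together with
#' hetero atoms (metal ions, ligands, waters) nearer to this protomer than to
#' any other.
#'
#' @param model [structure_model].
#' @param roles [assign_roles()] result for `model`.
#' @param protomer protomer label (default `"A"`).
#' @return [structure_model] restricted to the protomer.
#' @export
select_protomer <- function(model, roles, protomer = "A") {
  prot <- attr(roles, "protomers")
  if (!protomer %in% names(prot))
    stop("no protomer '", protomer, "' (available: ",
         paste(names(prot), collapse = ", "), ")")
  keep_ch <- prot[[protomer]]
  a <- model$atoms
  poly <- a$chain %in% keep_ch & !a$hetero
  het <- which(a$hetero | a$is_water)
  keep_het <- integer(0)
  if (length(het) > 0) {
    pcoords <- lapply(prot, function(chs)
      atom_coords(model, a$chain %in% chs & !a$hetero & !a$is_water))
    hxyz <- atom_coords(model, het)
    nearest <- vapply(seq_along(het), function(i) {
      d <- vapply(pcoords, function(m)
        min(sqrt(rowSums((m - matrix(hxyz[i, ], nrow(m), 3,
                                     byrow = TRUE))^2))), numeric(1))
      names(prot)[which.min(d)]
    }, character(1))
    keep_het <- het[nearest == protomer]
  }
  sub <- a[sort(c(which(poly), keep_het)), , drop = FALSE]
  structure_model(sub, identifier = paste0(model$identifier, ":", protomer),
                  metadata = model$metadata)
}

#' Chain id playing a given role within a protomer
#'
#' @param roles [assign_roles()] result.
#' @param role role name, e.g. `"TnnC"`.
#' @param protomer protomer label.
#' @return chain id (character) or error when absent.
#' @export
role_chain <- function(roles, role, protomer = "A") {
  i <- which(roles$role == role & !is.na(roles$protomer) &
               roles$protomer == protomer)
  if (length(i) != 1)
    stop("no unique chain with role ", role, " in protomer ", protomer)
  roles$chain[i]
}
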