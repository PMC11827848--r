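#' Default configuration of the comparison pipeline
#'
#' Every cutoff and threshold used by [run_comparison()], overridable via
#' its `config` argument. All effective values are echoed into the report's
#' provenance block.
#'
#' @return named list of parameters.
#' @export
comparison_config <- function() {
  list(
    protomer = "A",
    atom_selector = "CA",
    align_cycles = 5,
    align_sigma = 2.0,
    z_threshold = 2.0,
    coordination_cutoff = 3.2,
    include_waters = FALSE,
    contact_cutoffs = list(ionic = 4.0, hbond = 3.5, hydrophobic = 4.5),
    core_selection = "TnnT:199-272,TnnI:40-135",
    domain_selection = "TnnC:1-89")
}

.as_model <- function(x) {
  if (inherits(x, "structure_model")) return(x)
  read_structure(x)
}

.input_provenance <- function(x) {
  if (inherits(x, "structure_model"))
    return(list(identifier = x$identifier, source = "in-memory"))
  list(identifier = basename(x), source = x,
       md5 = unname(tools::md5sum(x)))
}

# run one analysis stage, capturing failure as a record instead of aborting
.stage <- function(expr) {
  tryCatch(list(ok = TRUE, value = expr, error = NULL),
           error = function(e) list(ok = FALSE, value = NULL,
                                    error = conditionMessage(e)))
}

.site_summary <- function(site) {
  list(label = site$label, n_protein_bonds = site$n_protein_bonds,
       mean_protein_distance = site$mean_protein_distance,
       ligands = site$ligands)
}

#' Run the full structural comparison pipeline
#'
#' Orchestrates the whole WT-versus-variant comparison for one reference
#' structure against any number of alternates, in a fixed stage order:
#' parse, role assignment, residue pairing, iterative alignment, backbone
#' geometry difference, calcium coordination comparison, contact difference
#' and domain rotation. A failing stage is recorded for that pair without
#' aborting the others.
#'
#' @param reference path or [structure_model] of the reference structure.
#' @param alternates list (possibly empty) of paths or models to compare
#'   against the reference.
#' @param config named list overriding entries of [comparison_config()].
#' @return object of class `comparison_report`: nested list with
#'   `provenance`, `reference` (roles + per-site coordination) and
#'   `comparisons` (one entry per alternate). Use [write_report()] for JSON.
#' @export
run_comparison <- function(reference, alternates = list(), config = list()) {
  cfg <- utils::modifyList(comparison_config(), config)
  prov <- list(
    schema_version = "1.0",
    package_version = as.character(utils::packageVersion("tncomp")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    parameters = cfg,
    reference_input = .input_provenance(reference),
    alternate_inputs = lapply(alternates, .input_provenance))

  ref <- .as_model(reference)
  ref_roles <- assign_roles(ref)
  ref_sites <- find_metal_sites(ref, ref_roles)
  ref_prot <- cfg$protomer
  ref_site_rows <- which(ref_sites$protomer %in% ref_prot)
  ref_spheres <- lapply(ref_site_rows, function(i)
    coordination_sphere(ref, ref_sites[i, ], cutoff = cfg$coordination_cutoff,
                        include_waters = cfg$include_waters))
  names(ref_spheres) <- ref_sites$label[ref_site_rows]
  ref_geoms <- lapply(
    stats::setNames(nm = intersect(c("TnnC", "TnnT", "TnnI"),
                                   ref_roles$role)),
    function(r) chain_geometry(ref, role_chain(ref_roles, r, ref_prot)))
  ref_contacts <- classify_contacts(
    ref, chains = attr(ref_roles, "protomers")[[ref_prot]],
    cutoffs = cfg$contact_cutoffs)

  compare_one <- function(alt_input) {
    alt <- .as_model(alt_input)
    out <- list(identifier = alt$identifier)
    roles <- .stage(assign_roles(alt))
    if (!roles$ok) return(c(out, list(failed_stage = "roles",
                                      error = roles$error)))
    pairing <- .stage(pair_protomers(ref, alt, ref_roles, roles$value,
                                     ref_prot, cfg$protomer))
    if (!pairing$ok) return(c(out, list(failed_stage = "pairing",
                                        error = pairing$error)))
    pr <- pairing$value
    aln <- .stage(iterative_align(ref, alt, pr,
                                  atom_selector = cfg$atom_selector,
                                  cycles = cfg$align_cycles,
                                  reject_sigma = cfg$align_sigma))
    out$alignment <- if (aln$ok) {
      a <- aln$value
      list(rmsd_final = a$rmsd_final, n_retained = a$n_retained,
           n_initial = a$n_initial, cycles_run = a$cycles_run)
    } else list(error = aln$error)

    geom <- .stage({
      lapply(stats::setNames(nm = names(ref_geoms)), function(r) {
        ch <- role_chain(roles$value, r, cfg$protomer)
        gd <- geometry_diff(ref_geoms[[r]], chain_geometry(alt, ch),
                            pr[pr$role == r, , drop = FALSE],
                            z_threshold = cfg$z_threshold)
        list(n_flagged = nrow(attr(gd, "flagged")),
             flagged_resseq = attr(gd, "flagged")$resseq_a)
      })
    })
    out$geometry <- if (geom$ok) geom$value else list(error = geom$error)

    coord <- .stage({
      sites <- find_metal_sites(alt, roles$value)
      rows <- which(sites$protomer %in% cfg$protomer)
      spheres <- lapply(rows, function(i)
        coordination_sphere(alt, sites[i, ],
                            cutoff = cfg$coordination_cutoff,
                            include_waters = cfg$include_waters))
      names(spheres) <- sites$label[rows]
      comp <- list()
      for (lab in intersect(names(ref_spheres), names(spheres))) {
        sc <- compare_sites(ref_spheres[[lab]], spheres[[lab]], pr)
        comp[[lab]] <- list(
          n_protein_bonds = spheres[[lab]]$n_protein_bonds,
          mean_protein_distance = spheres[[lab]]$mean_protein_distance,
          lost = sc$lost, gained = sc$gained,
          d_mean_distance = sc$d_mean_distance)
      }
      comp
    })
    out$coordination <- if (coord$ok) coord$value else
      list(error = coord$error)

    cont <- .stage({
      alt_contacts <- classify_contacts(
        alt, chains = attr(roles$value, "protomers")[[cfg$protomer]],
        cutoffs = cfg$contact_cutoffs)
      cd <- contact_diff(ref_contacts, alt_contacts, pr)
      list(n_gained = nrow(cd$gained), n_lost = nrow(cd$lost),
           gained = cd$gained, lost = cd$lost)
    })
    out$contacts <- if (cont$ok) cont$value else list(error = cont$error)

    dr <- .stage(domain_rotation(ref, alt, pr,
                                 core_selection = cfg$core_selection,
                                 domain_selection = cfg$domain_selection,
                                 cycles = cfg$align_cycles,
                                 reject_sigma = cfg$align_sigma))
    out$domain_rotation <- if (dr$ok) {
      d <- dr$value
      list(angle = d$angle, axis = d$axis,
           axis_reliable = d$axis_reliable, core_rmsd = d$core_rmsd,
           n_core = d$n_core, n_domain = d$n_domain)
    } else list(error = dr$error)
    out$failed <- !all(aln$ok, geom$ok, coord$ok, cont$ok, dr$ok)
    out
  }

  comparisons <- lapply(alternates, compare_one)
  structure(list(
    provenance = prov,
    reference = list(
      identifier = ref$identifier,
      roles = as.data.frame(ref_roles),
      metal_sites = ref_sites,
      coordination = lapply(ref_spheres, .site_summary)),
    comparisons = comparisons,
    any_failed = any(vapply(comparisons, function(x)
      isTRUE(x$failed), logical(1)))),
    class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("comparison_report: reference ", x$reference$identifier, ", ",
      length(x$comparisons), " comparison(s)",
      if (x$any_failed) " [with failures]" else "", "\n", sep = "")
  for (cmp in x$comparisons) {
    cat("  vs ", cmp$identifier, ": ", sep = "")
    if (!is.null(cmp$alignment$rmsd_final))
      cat(sprintf("rmsd %.3f A (%d/%d), ", cmp$alignment$rmsd_final,
                  cmp$alignment$n_retained, cmp$alignment$n_initial))
    if (!is.null(cmp$domain_rotation$angle))
      cat(sprintf("domain rotation %.2f deg", cmp$domain_rotation$angle))
    cat("\n")
  }
  invisible(x)
}

#' Write a comparison report as JSON
#'
#' @param report [run_comparison()] result.
#' @param path output file.
#' @param mask_timestamp replace the timestamp with a constant (for
#'   byte-reproducible output).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, mask_timestamp = FALSE) {
  if (mask_timestamp) report$provenance$timestamp <- "(masked)"
  json <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = 8,
                           dataframe = "rows", null = "null", na = "null",
                           pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}
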