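# Ideal backbone geometry used by the generators (lengths in Angstrom,
# angles in degrees; standard peptide values).
.BB <- list(
  len_n_ca = 1.458, len_ca_c = 1.525, len_c_n = 1.329, len_c_o = 1.231,
  ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.8)

# Natural-extension-reference-frame placement: position D given A-B-C with
# bond length |C-D|, angle B-C-D and dihedral A-B-C-D.
.place_atom <- function(A, B, C, length, angle_deg, dihedral_deg) {
  th <- angle_deg * pi / 180
  chi <- -dihedral_deg * pi / 180  # sign matched to dihedral_angle()
  bc <- .unit(C - B)
  n <- .unit(.cross(B - A, bc))
  m <- .cross(n, bc)
  d_local <- length * c(-cos(th), sin(th) * cos(chi), sin(th) * sin(chi))
  as.numeric(C + cbind(bc, m, n) %*% d_local)
}

#' Build an ideal helix (or any repeating phi/psi backbone) fixture
#'
#' Generates an N/CA/C/O backbone by sequential placement with ideal bond
#' lengths and angles and the requested phi/psi dihedrals (omega fixed at
#' 180, trans). With `noise_sd = 0` the measured dihedrals of the output
#' reproduce the requests to well under half a degree. Optional isotropic
#' Gaussian coordinate noise (R's Mersenne-Twister `rnorm`, seeded) makes the
#' output deterministic per seed.
#'
#' @param n_residues number of residues (>= 4).
#' @param phi,psi target dihedrals in degrees (default ideal alpha helix,
#'   -57/-47).
#' @param noise_sd coordinate noise standard deviation in Angstrom.
#' @param seed RNG seed used when `noise_sd > 0`.
#' @param chain chain id, `resseq_start` first residue number.
#' @param sequence optional one-letter sequence (length `n_residues`);
#'   default poly-alanine. Side chains are not built; residue names only.
#' @param identifier model identifier.
#' @return [structure_model] with atoms N, CA, C, O per residue.
#' @export
build_helix <- function(n_residues, phi = -57, psi = -47, noise_sd = 0,
                        seed = 1, chain = "A", resseq_start = 1L,
                        sequence = NULL, identifier = "helix") {
  if (n_residues < 4) stop("need at least 4 residues")
  if (is.null(sequence)) sequence <- strrep("A", n_residues)
  aa <- strsplit(sequence, "")[[1]]
  if (length(aa) != n_residues) stop("sequence length != n_residues")
  resnames <- aa_three_letter(aa)
  # residue 1 placed by hand in the xy-plane
  N <- matrix(NA_real_, n_residues, 3)
  CA <- matrix(NA_real_, n_residues, 3)
  C <- matrix(NA_real_, n_residues, 3)
  O <- matrix(NA_real_, n_residues, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(.BB$len_n_ca, 0, 0)
  th <- .BB$ang_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + .BB$len_ca_c * c(-cos(th), sin(th), 0)
  for (i in 2:n_residues) {
    N[i, ] <- .place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                          .BB$len_c_n, .BB$ang_ca_c_n, psi)
    CA[i, ] <- .place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                           .BB$len_n_ca, .BB$ang_c_n_ca, 180)
    C[i, ] <- .place_atom(C[i - 1, ], N[i, ], CA[i, ],
                          .BB$len_ca_c, .BB$ang_n_ca_c, phi)
  }
  for (i in seq_len(n_residues)) {
    # carbonyl O in the peptide plane: dihedral N-CA-C-O = psi + 180
    O[i, ] <- .place_atom(N[i, ], CA[i, ], C[i, ],
                          .BB$len_c_o, .BB$ang_ca_c_o, psi + 180)
  }
  per_res <- function(i) {
    data.frame(name = c("N", "CA", "C", "O"),
               resname = resnames[i], chain = chain,
               resseq = resseq_start + i - 1L,
               x = c(N[i, 1], CA[i, 1], C[i, 1], O[i, 1]),
               y = c(N[i, 2], CA[i, 2], C[i, 2], O[i, 2]),
               z = c(N[i, 3], CA[i, 3], C[i, 3], O[i, 3]),
               element = c("N", "C", "C", "O"),
               hetero = FALSE, stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, lapply(seq_len(n_residues), per_res))
  if (noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    atoms$x <- atoms$x + stats::rnorm(nrow(atoms), 0, noise_sd)
    atoms$y <- atoms$y + stats::rnorm(nrow(atoms), 0, noise_sd)
    atoms$z <- atoms$z + stats::rnorm(nrow(atoms), 0, noise_sd)
  }
  structure_model(atoms, identifier = identifier)
}

# save/restore the global RNG state so generators are seeded but do not
# disturb the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Build a synthetic metal coordination site
#'
#' One calcium hetero atom at the origin surrounded by serine-like oxygen
#' ligands (atom OG, with CB and CA further out along the ligand direction)
#' at exactly the stated distance, in an octahedral or pentagonal
#' (bipyramidal) arrangement. Optional water oxygens can be placed at the
#' same distance to exercise water filtering.
#'
#' @param n_ligands number of protein oxygen ligands (4-8; at most 6 for
#'   octahedral, 7 for pentagonal).
#' @param distance metal-oxygen distance in Angstrom (> 0).
#' @param geometry `"octahedral"` or `"pentagonal"`.
#' @param seed retained for interface symmetry with the other generators
#'   (the construction is deterministic).
#' @param n_waters number of water oxygens to add at `distance` (default 0).
#' @return [structure_model]; the calcium has serial 1.
#' @export
build_metal_site <- function(n_ligands = 6, distance = 2.40,
                             geometry = c("octahedral", "pentagonal"),
                             seed = 1, n_waters = 0) {
  geometry <- match.arg(geometry)
  if (distance <= 0) stop("ligand distance must be positive")
  if (n_ligands < 4 || n_ligands > 8)
    stop("n_ligands must be between 4 and 8")
  dirs <- switch(geometry,
    octahedral = rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                       c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)),
    pentagonal = {
      ang <- 2 * pi * (0:4) / 5
      rbind(cbind(cos(ang), sin(ang), 0), c(0, 0, 1), c(0, 0, -1))
    })
  if (n_ligands > nrow(dirs))
    stop("geometry '", geometry, "' supports at most ", nrow(dirs),
         " ligands")
  dirs <- dirs[seq_len(n_ligands), , drop = FALSE]
  rows <- list(data.frame(
    name = "CA", resname = "CA", chain = "M", resseq = 500L,
    x = 0, y = 0, z = 0, element = "CA", hetero = TRUE,
    stringsAsFactors = FALSE))
  for (i in seq_len(n_ligands)) {
    u <- dirs[i, ]
    tang <- if (abs(u[3]) < 0.9) .unit(.cross(u, c(0, 0, 1))) else
      .unit(.cross(u, c(1, 0, 0)))
    # serine-like branch geometry: CB-OG and CB-CA both at ~60 degrees to
    # the ligand direction, so a chi1 rotation genuinely swings OG
    og <- u * distance
    cb <- og + 1.43 * (0.5 * u + 0.866 * tang)
    ca <- cb + 1.53 * (0.5 * u - 0.866 * tang)
    nn <- ca + 1.46 * (0.5 * u + 0.866 * tang)
    rows[[length(rows) + 1]] <- data.frame(
      name = c("N", "CA", "CB", "OG"), resname = "SER", chain = "A",
      resseq = 10L + i,
      x = c(nn[1], ca[1], cb[1], og[1]), y = c(nn[2], ca[2], cb[2], og[2]),
      z = c(nn[3], ca[3], cb[3], og[3]),
      element = c("N", "C", "C", "O"), hetero = FALSE,
      stringsAsFactors = FALSE)
  }
  if (n_waters > 0) {
    # waters on face-diagonal directions, away from the ligands
    wd <- rbind(c(1, 1, 1), c(-1, -1, 1), c(1, -1, -1), c(-1, 1, -1),
                c(1, 1, -1), c(-1, -1, -1), c(1, -1, 1), c(-1, 1, 1)) / sqrt(3)
    for (i in seq_len(min(n_waters, nrow(wd)))) {
      w <- wd[i, ] * distance
      rows[[length(rows) + 1]] <- data.frame(
        name = "O", resname = "HOH", chain = "W", resseq = 600L + i,
        x = w[1], y = w[2], z = w[3], element = "O", hetero = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  atoms <- do.call(rbind, rows)
  atoms$serial <- seq_len(nrow(atoms))
  structure_model(atoms, identifier = sprintf("site-%s-%d", geometry,
                                              n_ligands))
}

# deterministic pseudo-random chain sequences for the complex generator;
# seeded independently of the caller's RNG
.random_sequence <- function(n, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  paste(sample(names(.AA123), n, replace = TRUE), collapse = "")
}

#' Build a synthetic two-protomer troponin-like complex
#'
#' Emulates the layout of a troponin crystal's asymmetric unit: two copies
#' (protomers) of a TnnC/TnnT/TnnI chain triple, related by a known rigid
#' motion. Chains are ideal helices with seeded pseudo-random sequences
#' spanning the construct's author numbering (TnnC 1-161, TnnT 183-288,
#' TnnI 32-166). Options engineer the deformations the analyses must
#' detect:
#' * `deletion_at = list(role, resseq)` removes that residue from the role's
#'   chain in both protomers, leaving the author-numbering gap in place
#'   (as the K210 deletion does);
#' * `domain_rotation_deg` rotates the TnnC N-lobe (residues 1-89) of both
#'   protomers by the stated angle about a recorded axis through the lobe
#'   centroid;
#' * `displace = list(role, resseq_range, offset)` rigidly displaces a
#'   residue range by an offset vector (for outlier-rejection tests).
#'
#' @param deletion_at optional `list(role =, resseq =)`.
#' @param domain_rotation_deg rotation of the TnnC N-lobe in degrees.
#' @param rotation_axis axis for that rotation (default c(0, 0, 1)).
#' @param displace optional `list(role =, resseq =, offset =)` with `resseq`
#'   a vector of residue numbers and `offset` a length-3 vector in Angstrom.
#' @param noise_sd isotropic coordinate noise (Angstrom), seeded.
#' @param seed seed for sequences and noise.
#' @return [structure_model] with chains C/T/I (protomer A) and D/E/F
#'   (protomer B); attributes `domain_axis`, `domain_angle`, `deletion`.
#' @export
build_two_protomer_complex <- function(deletion_at = NULL,
                                       domain_rotation_deg = 0,
                                       rotation_axis = c(0, 0, 1),
                                       displace = NULL,
                                       noise_sd = 0, seed = 1) {
  ranges <- troponin_role_ranges()
  specs <- list(
    list(role = "TnnC", chain = "C", range = ranges$TnnC, offset = c(0, 0, 0)),
    list(role = "TnnT", chain = "T", range = ranges$TnnT,
         offset = c(14, 0, 0)),
    list(role = "TnnI", chain = "I", range = ranges$TnnI,
         offset = c(28, 0, 0)))
  parts <- list()
  for (s in specs) {
    n <- s$range[2] - s$range[1] + 1L
    seq_s <- .random_sequence(n, seed = seed * 1000L + match(s$role,
                                                             names(ranges)))
    if (s$role == "TnnT" && 210 >= s$range[1] && 210 <= s$range[2])
      substr(seq_s, 210 - s$range[1] + 1, 210 - s$range[1] + 1) <- "K"
    h <- build_helix(n, chain = s$chain, resseq_start = s$range[1],
                     sequence = seq_s, identifier = s$role)
    at <- h$atoms
    at$x <- at$x + s$offset[1]
    at$y <- at$y + s$offset[2]
    at$z <- at$z + s$offset[3]
    parts[[s$chain]] <- at
  }
  if (!is.null(deletion_at)) {
    ch <- c(TnnC = "C", TnnT = "T", TnnI = "I")[[deletion_at$role]]
    rng <- ranges[[deletion_at$role]]
    if (deletion_at$resseq < rng[1] || deletion_at$resseq > rng[2])
      stop("deletion at ", deletion_at$resseq, " outside ", deletion_at$role,
           " range ", rng[1], "-", rng[2])
    at <- parts[[ch]]
    parts[[ch]] <- at[at$resseq != deletion_at$resseq, , drop = FALSE]
  }
  if (!is.null(displace)) {
    ch <- c(TnnC = "C", TnnT = "T", TnnI = "I")[[displace$role]]
    at <- parts[[ch]]
    hit <- at$resseq %in% displace$resseq
    at$x[hit] <- at$x[hit] + displace$offset[1]
    at$y[hit] <- at$y[hit] + displace$offset[2]
    at$z[hit] <- at$z[hit] + displace$offset[3]
    parts[[ch]] <- at
  }
  if (domain_rotation_deg != 0) {
    at <- parts[["C"]]
    hit <- at$resseq <= 89
    R <- rotation_about_axis(rotation_axis, domain_rotation_deg)
    xyz <- as.matrix(at[hit, c("x", "y", "z")])
    ctr <- colMeans(xyz)
    xyz <- sweep(sweep(xyz, 2, ctr) %*% t(R), 2, ctr, `+`)
    at[hit, c("x", "y", "z")] <- xyz
    parts[["C"]] <- at
  }
  prot_a <- do.call(rbind, parts)
  # protomer B: a known rigid motion of protomer A
  Rb <- rotation_about_axis(c(0, 1, 0), 150)
  tb <- c(70, 8, 0)
  prot_b <- prot_a
  xyz <- as.matrix(prot_b[, c("x", "y", "z")]) %*% t(Rb)
  prot_b[, c("x", "y", "z")] <- sweep(xyz, 2, tb, `+`)
  prot_b$chain <- c(C = "D", T = "E", I = "F")[prot_b$chain]
  atoms <- rbind(prot_a, prot_b)
  if (noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed + 7777L)
    atoms$x <- atoms$x + stats::rnorm(nrow(atoms), 0, noise_sd)
    atoms$y <- atoms$y + stats::rnorm(nrow(atoms), 0, noise_sd)
    atoms$z <- atoms$z + stats::rnorm(nrow(atoms), 0, noise_sd)
  }
  atoms$serial <- seq_len(nrow(atoms))
  m <- structure_model(atoms, identifier = "two-protomer")
  attr(m, "domain_axis") <- .unit(rotation_axis)
  attr(m, "domain_angle") <- domain_rotation_deg
  attr(m, "deletion") <- deletion_at
  m
}

#' Pose an isolated residue pair for contact tests
#'
#' Builds a minimal two-residue model in which a named atom of residue B is
#' placed at an exact distance from a named atom of residue A, with the
#' standard side-chain atom names of the requested residue types. Only the
#' atoms named in `atoms_a`/`atoms_b` are created, along a line, so the
#' stated inter-atom distance is exact.
#'
#' @param resname_a,resname_b 3-letter residue names.
#' @param atoms_a,atoms_b atom names for each residue (first atom of each is
#'   the "contact" atom).
#' @param distance distance between the two contact atoms, Angstrom.
#' @param chain_a,chain_b chain ids (default "A"/"B").
#' @return [structure_model].
#' @export
build_residue_pair <- function(resname_a, resname_b, atoms_a, atoms_b,
                               distance, chain_a = "A", chain_b = "B") {
  mk <- function(resname, atoms, chain, resseq, origin, step) {
    data.frame(name = atoms, resname = resname, chain = chain,
               resseq = resseq,
               x = origin[1] + step * (seq_along(atoms) - 1),
               y = origin[2], z = origin[3],
               element = toupper(substr(gsub("[0-9]", "", atoms), 1, 1)),
               hetero = FALSE, stringsAsFactors = FALSE)
  }
  a <- mk(resname_a, atoms_a, chain_a, 10L, c(0, 0, 0), -1.5)
  b <- mk(resname_b, atoms_b, chain_b, 20L, c(distance, 0, 0), 1.5)
  structure_model(rbind(a, b), identifier = "residue-pair")
}

#' Simulate a calcium-titration series from the Hill model
#'
#' Evaluates the variable-slope sigmoid at the requested pCa points and adds
#' seeded Gaussian noise, emulating a fluorescence or force-pCa titration.
#'
#' @param pca50,hill_slope,top,bottom Hill parameters (descending-in-pCa
#'   orientation: response `top` at maximal calcium).
#' @param x pCa sampling points (default `n_points` evenly spaced over
#'   pCa 6.8-4.4, bracketing the transition like a force-pCa buffer
#'   series).
#' @param n_points number of points when `x` is not given (>= 5).
#' @param noise_sd Gaussian noise standard deviation in response units.
#' @param seed RNG seed.
#' @return data.frame with columns `x`, `y` (class `titration_series`).
#' @export
build_titration <- function(pca50 = 5.6, hill_slope = 2.5, top = 38,
                            bottom = 0, x = NULL, n_points = 7,
                            noise_sd = 0, seed = 1) {
  if (is.null(x)) {
    if (n_points < 5) stop("need at least 5 points")
    x <- seq(6.8, 4.4, length.out = n_points)
  }
  if (!is.finite(pca50) || !is.finite(hill_slope) || top <= bottom)
    stop("invalid Hill parameters (need top > bottom)")
  y <- .hill_eval(x, bottom, top, pca50, hill_slope)
  if (noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    y <- y + stats::rnorm(length(y), 0, noise_sd)
  }
  structure(data.frame(x = x, y = y),
            class = c("titration_series", "data.frame"))
}
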