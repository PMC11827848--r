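# independent all-atom distance scan used as oracle against
# coordination_sphere()
brute_ligands <- function(model, metal_serial, cutoff,
                          include_waters = FALSE) {
  a <- model$atoms
  mi <- which(a$serial == metal_serial)
  mp <- as.numeric(a[mi, c("x", "y", "z")])
  hits <- character(0)
  for (i in seq_len(nrow(a))) {
    if (i == mi) next
    if (toupper(a$element[i]) != "O") next
    if (a$is_water[i] && !include_waters) next
    if (a$hetero[i] && !a$is_water[i]) next
    d <- sqrt(sum((as.numeric(a[i, c("x", "y", "z")]) - mp)^2))
    if (d <= cutoff)
      hits <- c(hits, paste(a$chain[i], a$resseq[i], a$name[i]))
  }
  sort(hits)
}

test_that("constructed octahedral and pentagonal sites return exact counts", {
  s6 <- build_metal_site(6, 2.40, "octahedral")
  cs6 <- coordination_sphere(s6, find_metal_sites(s6)$serial[1])
  expect_equal(cs6$n_protein_bonds, 6)
  expect_equal(cs6$mean_protein_distance, 2.40, tolerance = 1e-9)
  expect_true(all(cs6$ligands$category == "sidechain-O"))

  s5 <- build_metal_site(5, 2.90, "pentagonal")
  cs5 <- coordination_sphere(s5, find_metal_sites(s5)$serial[1])
  expect_equal(cs5$n_protein_bonds, 5)
  expect_equal(cs5$mean_protein_distance, 2.90, tolerance = 1e-9)

  expect_error(build_metal_site(4, 0), "positive")
  expect_error(build_metal_site(3, 2.4), "between 4 and 8")
  expect_error(build_metal_site(7, 2.4, "octahedral"), "at most 6")
})

test_that("an apo model yields an empty site list with a notice", {
  h <- build_helix(10)
  expect_message(sites <- find_metal_sites(h), "no CA ions")
  expect_equal(nrow(sites), 0)
})

test_that("waters are listed on request but never counted as protein bonds", {
  s <- build_metal_site(6, 2.40, "octahedral", n_waters = 2)
  serial <- find_metal_sites(s)$serial[1]
  dry <- coordination_sphere(s, serial, include_waters = FALSE)
  wet <- coordination_sphere(s, serial, include_waters = TRUE)
  expect_equal(dry$n_protein_bonds, 6)
  expect_equal(wet$n_protein_bonds, 6)
  expect_equal(nrow(dry$ligands), 6)
  expect_equal(nrow(wet$ligands), 8)
  expect_equal(sum(wet$ligands$category == "water"), 2)
  expect_equal(wet$mean_protein_distance, 2.40, tolerance = 1e-9)
})

test_that("shrinking the cutoff never increases the bond count", {
  s <- build_metal_site(6, 2.55, "octahedral")
  serial <- find_metal_sites(s)$serial[1]
  cuts <- seq(3.6, 2.4, by = -0.2)
  counts <- vapply(cuts, function(ct)
    coordination_sphere(s, serial, cutoff = ct)$n_protein_bonds, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(coordination_sphere(s, serial, cutoff = -1), "positive")
})

test_that("neighbour listing equals a brute-force distance scan", {
  for (spec in list(list(6, 2.4, "octahedral", 0), list(5, 2.9, "pentagonal", 0),
                    list(6, 2.4, "octahedral", 3))) {
    s <- build_metal_site(spec[[1]], spec[[2]], spec[[3]],
                          n_waters = spec[[4]])
    serial <- find_metal_sites(s)$serial[1]
    cs <- coordination_sphere(s, serial, include_waters = TRUE)
    got <- sort(paste(cs$ligands$chain, cs$ligands$resseq, cs$ligands$atom))
    expect_identical(got, brute_ligands(s, serial, 3.2,
                                        include_waters = TRUE))
  }
})

test_that("distances are invariant under rigid motion of the whole model", {
  s <- build_metal_site(6, 2.40, "octahedral")
  serial <- find_metal_sites(s)$serial[1]
  d0 <- coordination_sphere(s, serial)$ligands$distance
  mot <- random_rigid_motion(33)
  s2 <- transform_model(s, mot$rotation, mot$translation)
  expect_equal(coordination_sphere(s2, serial)$ligands$distance, d0,
               tolerance = 1e-9)
})

test_that("site comparison localizes a serine flip as a lost then regained ligand", {
  wt_site <- build_metal_site(6, 2.40, "octahedral")
  serial <- find_metal_sites(wt_site)$serial[1]
  # flip one serine's OG out of the pocket by rotating chi1 120 degrees
  flip_serine <- function(m, resseq) {
    i <- which(m$atoms$resseq == resseq & m$atoms$name == "OG")
    ca <- as.numeric(m$atoms[m$atoms$resseq == resseq &
                               m$atoms$name == "CA", c("x", "y", "z")])
    cb <- as.numeric(m$atoms[m$atoms$resseq == resseq &
                               m$atoms$name == "CB", c("x", "y", "z")])
    R <- rotation_about_axis(cb - ca, 120)
    og <- as.numeric(m$atoms[i, c("x", "y", "z")])
    m$atoms[i, c("x", "y", "z")] <- as.numeric(R %*% (og - cb)) + cb
    m
  }
  mut_site <- flip_serine(wt_site, 11)
  cs_wt <- coordination_sphere(wt_site, serial)
  cs_mut <- coordination_sphere(mut_site, serial)
  expect_equal(cs_mut$n_protein_bonds, 5)
  cmp <- compare_sites(cs_wt, cs_mut)
  expect_equal(nrow(cmp$lost), 1)
  expect_equal(cmp$lost$resseq, 11)
  expect_equal(cmp$lost$atom, "OG")
  expect_equal(nrow(cmp$gained), 0)
  # the reverse comparison reports the same ligand as regained
  back <- compare_sites(cs_mut, cs_wt)
  expect_equal(back$gained$resseq, 11)
  expect_equal(back$gained$atom, "OG")
  # lost and gained are disjoint by construction
  expect_length(intersect(paste(cmp$lost$resseq, cmp$lost$atom),
                          paste(cmp$gained$resseq, cmp$gained$atom)), 0)
})

test_that("identical sites compare empty with zero mean-distance change", {
  s <- build_metal_site(6, 2.40, "octahedral")
  cs <- coordination_sphere(s, find_metal_sites(s)$serial[1])
  cmp <- compare_sites(cs, cs)
  expect_equal(nrow(cmp$lost), 0)
  expect_equal(nrow(cmp$gained), 0)
  expect_equal(cmp$d_mean_distance, 0)
})

test_that("sidechain flip metric reports chi1 and oxygen-metal distance", {
  s <- build_metal_site(6, 2.40, "octahedral")
  serial <- find_metal_sites(s)$serial[1]
  fm <- sidechain_flip_metric(s, "A", 11, serial)
  expect_equal(fm$distance, 2.40, tolerance = 1e-9)
  # chi1 rotation by 120 degrees moves the oxygen out of coordination range
  # (analytic rebuild of the OG position about the CA-CB axis)
  i <- which(s$atoms$resseq == 11 & s$atoms$name == "OG")
  ca <- as.numeric(s$atoms[s$atoms$resseq == 11 & s$atoms$name == "CA",
                           c("x", "y", "z")])
  cb <- as.numeric(s$atoms[s$atoms$resseq == 11 & s$atoms$name == "CB",
                           c("x", "y", "z")])
  R <- rotation_about_axis(cb - ca, 120)
  og <- as.numeric(s$atoms[i, c("x", "y", "z")])
  s$atoms[i, c("x", "y", "z")] <- as.numeric(R %*% (og - cb)) + cb
  fm2 <- sidechain_flip_metric(s, "A", 11, serial)
  expect_gt(fm2$distance, 3.2)
  expect_equal(abs(wrap_angle(fm2$chi1 - fm$chi1)), 120, tolerance = 1e-6)
  # residue without a gamma oxygen errors
  h <- build_helix(5)
  h$atoms <- rbind(h$atoms, s$atoms[s$atoms$name == "CA" & s$atoms$hetero, ])
  h$atoms$serial <- seq_len(nrow(h$atoms))
  met <- h$atoms$serial[h$atoms$hetero][1]
  expect_error(sidechain_flip_metric(h, "A", 2, met), "side-chain")
})
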