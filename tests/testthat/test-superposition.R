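test_that("kabsch recovers exact rigid motions and rejects degenerate input", {
  set.seed(42)
  A <- matrix(rnorm(60), 20, 3)
  f0 <- kabsch(A, A)
  expect_equal(f0$rotation, diag(3), tolerance = 1e-9)
  expect_equal(f0$translation, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(f0$rmsd, 0, tolerance = 1e-9)

  R <- rotation_about_axis(c(0, 0, 1), 90)
  B <- A %*% t(R) + matrix(c(1, 2, 3), 20, 3, byrow = TRUE)
  f <- kabsch(A, B)
  expect_lt(f$rmsd, 1e-9)
  expect_equal(det(f$rotation), 1, tolerance = 1e-9)
  expect_lt(max(abs(apply_transform(B, f) - A)), 1e-9)

  expect_error(kabsch(A[1:2, ], A[1:2, ]), "insufficient")
  line <- cbind(1:5, 1:5, 1:5) + 0
  expect_error(kabsch(line, line), "degenerate|collinear")
})

test_that("kabsch matches brute-force rotational minimization on noisy clouds", {
  for (seed in 1:5) {
    set.seed(seed)
    A <- matrix(rnorm(150, sd = 5), 50, 3)
    mot <- random_rigid_motion(seed + 100)
    B <- (A + matrix(rnorm(150, sd = 0.5), 50, 3)) %*% t(mot$rotation) +
      matrix(mot$translation, 50, 3, byrow = TRUE)
    expect_equal(kabsch(A, B)$rmsd, brute_force_rmsd(A, B),
                 tolerance = 1e-4)
  }
})

test_that("uniformly weighted kabsch equals the unweighted result", {
  set.seed(7)
  A <- matrix(rnorm(90), 30, 3)
  B <- A + matrix(rnorm(90, sd = 0.3), 30, 3)
  fu <- kabsch(A, B)
  fw <- kabsch(A, B, weights = rep(2.5, 30))
  expect_equal(fu$rotation, fw$rotation, tolerance = 1e-12)
  expect_equal(fu$rmsd, fw$rmsd, tolerance = 1e-12)
})

test_that("A-onto-B and B-onto-A transforms are mutual inverses", {
  set.seed(9)
  A <- matrix(rnorm(90), 30, 3)
  mot <- random_rigid_motion(11)
  B <- (A + matrix(rnorm(90, sd = 0.2), 30, 3)) %*% t(mot$rotation)
  f_ab <- kabsch(A, B)
  f_ba <- kabsch(B, A)
  expect_equal(f_ab$rotation %*% f_ba$rotation, diag(3), tolerance = 1e-6)
  expect_equal(as.vector(f_ab$rotation %*% f_ba$translation +
                           f_ab$translation),
               c(0, 0, 0), tolerance = 1e-6)
})

test_that("identical protomers align with zero rejections and zero rmsd", {
  pp <- pair_protomers(wt_complex, wt_complex, wt_roles, wt_roles, "A", "A")
  a <- iterative_align(wt_complex, wt_complex, pp)
  expect_equal(a$n_retained, a$n_initial)
  expect_equal(nrow(a$rejected_pairs), 0)
  expect_lt(a$rmsd_final, 1e-9)
})

test_that("displaced residues are rejected exactly and rmsd is monotone", {
  disp <- build_two_protomer_complex(
    displace = list(role = "TnnI", resseq = 60:69, offset = c(5, 0, 0)),
    seed = 1)
  pp <- pair_protomers(wt_complex, disp, wt_roles, assign_roles(disp))
  a <- iterative_align(wt_complex, disp, pp)
  rejected <- pp[unique(a$rejected_pairs$pair), ]
  expect_setequal(rejected$resseq_a, 60:69)
  expect_true(all(rejected$role == "TnnI"))
  expect_equal(a$n_initial - a$n_retained, 10)
  expect_lt(a$rmsd_final, 0.01)
  # rmsd non-increasing across cycles: recompute rmsd of all pairs vs final
  expect_lte(a$rmsd_final,
             rmsd_between(wt_complex, disp, pp, atom_selector = "CA"))
})

test_that("alignment statistics are invariant under rigid motion of one input", {
  pp <- pair_protomers(wt_complex, mut_complex, wt_roles, mut_roles)
  ref <- iterative_align(wt_complex, mut_complex, pp)
  for (seed in 1:20) {
    mot <- random_rigid_motion(seed)
    moved <- transform_model(mut_complex, mot$rotation, mot$translation)
    a <- iterative_align(wt_complex, moved, pp)
    expect_equal(a$rmsd_final, ref$rmsd_final, tolerance = 1e-6)
    expect_equal(a$n_retained, ref$n_retained)
  }
})

test_that("rmsd_between handles supplied transforms and self-comparison", {
  pp <- pair_protomers(wt_complex, wt_complex, wt_roles, wt_roles)
  expect_equal(rmsd_between(wt_complex, wt_complex, pp), 0, tolerance = 1e-9)
  shifted <- transform_model(wt_complex, diag(3), c(3, 4, 0))
  # translation-only copy: fitted rmsd 0, unfitted rmsd = |t|
  expect_equal(rmsd_between(wt_complex, shifted, pp), 0, tolerance = 1e-9)
  ident <- list(rotation = diag(3), translation = c(0, 0, 0))
  expect_equal(rmsd_between(wt_complex, shifted, pp, transform = ident), 5,
               tolerance = 1e-9)
})

test_that("protomer B aligns onto protomer A across the asymmetric unit", {
  # the two protomers of the fixture are built as an exact rigid copy, so
  # the A<->B alignment must be exact with everything retained
  pp <- pair_protomers(wt_complex, wt_complex, wt_roles, wt_roles, "A", "B")
  a <- iterative_align(wt_complex, wt_complex, pp)
  expect_equal(a$n_retained, a$n_initial)
  expect_lt(a$rmsd_final, 1e-9)
})
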