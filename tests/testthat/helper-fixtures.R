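# Shared fixtures, built once per test run. Generators are deterministic
# per seed, so these are stable across runs.

wt_complex <- build_two_protomer_complex(seed = 1)
wt_roles <- assign_roles(wt_complex)

mut_complex <- build_two_protomer_complex(
  deletion_at = list(role = "TnnT", resseq = 210),
  domain_rotation_deg = 4, seed = 1)
mut_roles <- assign_roles(mut_complex)

wt_mut_pairing <- pair_protomers(wt_complex, mut_complex,
                                 wt_roles, mut_roles)

# independent brute-force RMSD minimiser over a rotation parameterisation
# (Euler angles, Nelder-Mead from several starts); translation is optimal
# analytically once the rotation is fixed
brute_force_rmsd <- function(A, B) {
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  euler_R <- function(p) {
    ca <- cos(p[1]); sa <- sin(p[1])
    cb <- cos(p[2]); sb <- sin(p[2])
    cc <- cos(p[3]); sc <- sin(p[3])
    Rz1 <- matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
    Ry <- matrix(c(cb, 0, -sb, 0, 1, 0, sb, 0, cb), 3, 3)
    Rz2 <- matrix(c(cc, sc, 0, -sc, cc, 0, 0, 0, 1), 3, 3)
    Rz1 %*% Ry %*% Rz2
  }
  obj <- function(p) sqrt(mean(rowSums((Ac - Bc %*% t(euler_R(p)))^2)))
  starts <- rbind(c(0, 0, 0), c(pi / 2, pi / 2, 0), c(pi, 0, 0),
                  c(0, pi / 2, pi), c(pi / 2, pi, pi / 2))
  best <- Inf
  for (k in seq_len(nrow(starts))) {
    o <- stats::optim(starts[k, ], obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
    o <- stats::optim(o$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, o$value)
  }
  best
}

random_rigid_motion <- function(seed) {
  set.seed(seed)
  ax <- stats::rnorm(3)
  list(rotation = rotation_about_axis(ax, stats::runif(1, 0, 360)),
       translation = stats::rnorm(3, 0, 20))
}
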