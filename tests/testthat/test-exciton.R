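# minimal hand-built unit set for coupling-formula oracles
hand_units <- function(r, e, omega = 1690, rho = 0.25, params = exciton_params()) {
  n <- nrow(r)
  alpha <- t(vapply(seq_len(n), function(i)
    as.vector(rho * diag(3) + (1 - rho) * tcrossprod(e[i, ])), numeric(9)))
  structure(list(r = r, e = e, alpha = alpha, omega = rep(omega, n),
                 chain = rep("A", n), donor_resno = seq(1, by = 2, length.out = n),
                 proline = rep(FALSE, n), params = params),
            class = "vs_units")
}

test_that("a chain of n residues yields n-1 amide units with unit dipoles", {
  u <- extract_amide_units(build_ideal_helix(10))
  expect_length(u$omega, 9)
  expect_equal(sqrt(rowSums(u$e^2)), rep(1, 9), tolerance = 1e-10)
  # Raman tensors symmetric with principal values (1, rho, rho)
  for (i in c(1, 5, 9)) {
    A <- matrix(u$alpha[i, ], 3, 3)
    expect_equal(A, t(A), tolerance = 1e-12)
    expect_equal(sort(eigen(A, symmetric = TRUE)$values),
                 c(0.25, 0.25, 1), tolerance = 1e-10)
  }
})

test_that("dipole geometry: theta_dip = 0 gives e parallel to C->O", {
  h <- build_ideal_helix(5)
  u0 <- extract_amide_units(h, exciton_params(theta_dip = 0))
  a <- h$atoms
  C1 <- as.numeric(a[a$resno == 1 & a$elety == "C", c("x", "y", "z")])
  O1 <- as.numeric(a[a$resno == 1 & a$elety == "O", c("x", "y", "z")])
  co <- (O1 - C1) / sqrt(sum((O1 - C1)^2))
  expect_equal(as.numeric(u0$e[1, ]), co, tolerance = 1e-10)
  # anchor sits d_off along C=O from the carbonyl carbon
  expect_equal(as.numeric(u0$r[1, ]), C1 + 0.868 * co, tolerance = 1e-10)
  # at 20 degrees the dipole stays in the O-C-N plane, 20 deg from C->O
  u20 <- extract_amide_units(h)
  expect_equal(sum(u20$e[1, ] * co), cos(20 * pi / 180), tolerance = 1e-10)
})

test_that("proline is flagged, chain breaks skip units, missing atoms error", {
  h <- build_ideal_helix(6)
  h$atoms$resid[h$atoms$resno == 3] <- "PRO"
  u <- extract_amide_units(h)
  expect_length(u$omega, 5)
  expect_equal(which(u$proline), 2)  # bond 2-3 has the proline acceptor N
  broken <- build_ideal_helix(8)
  broken$atoms[broken$atoms$resno > 4, c("x", "y", "z")] <-
    broken$atoms[broken$atoms$resno > 4, c("x", "y", "z")] + 50
  expect_warning(ub <- extract_amide_units(broken), "chain break")
  expect_length(ub$omega, 6)
  missing <- build_ideal_helix(5)
  missing$atoms <- missing$atoms[!(missing$atoms$resno == 2 &
                                     missing$atoms$elety == "O"), ]
  expect_error(extract_amide_units(missing), "residue|backbone|bond")
})

test_that("TDC matches the point-dipole closed form", {
  A <- exciton_params()$A
  # parallel dipoles along z, separated along x: J = A / r^3
  for (r in c(4, 7, 12)) {
    u <- hand_units(rbind(c(0, 0, 0), c(r, 0, 0)),
                    rbind(c(0, 0, 1), c(0, 0, 1)))
    expect_equal(tdc_coupling(u, 1, 2), A / r^3, tolerance = 1e-12)
    expect_equal(tdc_coupling(u, 2, 1), tdc_coupling(u, 1, 2))
  }
  # collinear dipoles along z, separated along z: J = -2 A / r^3
  u <- hand_units(rbind(c(0, 0, 0), c(0, 0, 5)),
                  rbind(c(0, 0, 1), c(0, 0, 1)))
  expect_equal(tdc_coupling(u, 1, 2), -2 * A / 5^3, tolerance = 1e-12)
  # decay limit
  ufar <- hand_units(rbind(c(0, 0, 0), c(1e6, 0, 0)),
                     rbind(c(0, 0, 1), c(0, 0, 1)))
  expect_lt(abs(tdc_coupling(ufar, 1, 2)), 1e-12 * A)
  # clashing chromophores are a geometry error
  uclash <- hand_units(rbind(c(0, 0, 0), c(0.2, 0, 0)),
                       rbind(c(0, 0, 1), c(0, 0, 1)))
  expect_error(tdc_coupling(uclash, 1, 2), "geometry")
})

test_that("Hamiltonian assembly: diagonal, nearest-neighbor rule, symmetry", {
  p <- exciton_params()
  u1 <- hand_units(matrix(c(0, 0, 0), 1), matrix(c(0, 0, 1), 1))
  H1 <- build_hamiltonian(u1, p)
  expect_equal(H1$H, matrix(1690, 1, 1))
  # three sequential units: H12 = H23 = J_nn, H13 from TDC
  u3 <- extract_amide_units(build_ideal_helix(4), p)
  H3 <- build_hamiltonian(u3, p)
  expect_equal(H3$H[1, 2], p$J_nn)
  expect_equal(H3$H[2, 3], p$J_nn)
  expect_equal(H3$H[1, 3], tdc_coupling(u3, 1, 3, p), tolerance = 1e-12)
  expect_equal(H3$H, t(H3$H), tolerance = 1e-10)
  expect_true(all(abs(diag(H3$H) - p$omega0) <= 100))
})

test_that("dimer eigenmodes follow the 2x2 closed form", {
  # two non-adjacent identical units -> omega0 +- J, dipoles (m1 +- m2)/sqrt(2)
  u <- hand_units(rbind(c(0, 0, 0), c(6, 0, 0)),
                  rbind(c(0, 0, 1), c(0, 0, 1)))
  H <- build_hamiltonian(u)
  J <- H$H[1, 2]
  expect_gt(abs(J), 0.1)
  md <- diagonalize(H)
  expect_equal(md$omega, 1690 + c(-abs(J), abs(J)), tolerance = 1e-10)
  Mexp <- (u$e[1, ] + u$e[2, ]) / sqrt(2)
  got <- md$M[which.min(abs(md$omega - (1690 + J))), ]
  expect_equal(abs(as.numeric(got)), abs(Mexp), tolerance = 1e-10)
})

test_that("diagonalization conserves trace, orthonormality and dipole strength", {
  set.seed(31)
  for (rep in 1:4) {
    n <- 6
    r <- matrix(runif(3 * n, 0, 25), n)
    e <- matrix(rnorm(3 * n), n)
    e <- e / sqrt(rowSums(e^2))
    u <- hand_units(r, e)
    H <- build_hamiltonian(u)
    md <- diagonalize(H)
    expect_equal(sum(md$omega), sum(diag(H$H)), tolerance = 1e-6 * 1690)
    expect_equal(crossprod(md$C), diag(n), tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(sum(md$M^2), sum(u$e^2), tolerance = 1e-8 * n)
    expect_true(all(diff(md$omega) >= 0))
  }
  expect_error(diagonalize(matrix(c(1, 2, 0, 1), 2), hand_units(
    rbind(c(0, 0, 0), c(5, 0, 0)), rbind(c(0, 0, 1), c(0, 0, 1)))),
    "symmetric")
})

test_that("zero coupling reproduces uncoupled local modes exactly", {
  p0 <- exciton_params(A = 0, J_nn = 0, delta_omega = c(0, 2, -3, 1, 0, 4, -1, 2, 0))
  u <- extract_amide_units(build_ideal_helix(10), p0)
  md <- diagonalize(build_hamiltonian(u, p0))
  expect_equal(md$omega, sort(u$omega), tolerance = 1e-12)
  expect_equal(abs(md$C[md$C != 0]), rep(1, 9), tolerance = 1e-12)
})

test_that("relabeling the chain in reverse leaves the eigenspectrum unchanged", {
  u <- extract_amide_units(build_ideal_helix(12))
  md <- diagonalize(build_hamiltonian(u))
  rev_idx <- rev(seq_along(u$omega))
  urev <- u
  urev$r <- u$r[rev_idx, ]; urev$e <- u$e[rev_idx, ]
  urev$alpha <- u$alpha[rev_idx, ]; urev$omega <- u$omega[rev_idx]
  urev$donor_resno <- rev(max(u$donor_resno) + 1 - u$donor_resno)
  mdr <- diagonalize(build_hamiltonian(urev))
  expect_equal(md$omega, mdr$omega, tolerance = 1e-9)
})

test_that("ideal helix delocalizes: band splits and the bright mode is axial", {
  h <- build_ideal_helix(25)
  u <- extract_amide_units(h)
  md <- diagonalize(build_hamiltonian(u))
  p <- exciton_params()
  expect_gt(max(md$omega) - min(md$omega), 20)   # exciton band, not local modes
  expect_true(any(md$omega < p$omega0) && any(md$omega > p$omega0))
  ax <- helix_axis(h)
  bright <- md$M[which.max(rowSums(md$M^2)), ]
  axial <- abs(sum(bright * ax))
  transverse <- sqrt(sum(bright^2) - axial^2)
  expect_gt(axial, transverse)
})
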