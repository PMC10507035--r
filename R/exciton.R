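#' Exciton model parameters
#'
#' Physical parameters of the amide-I one-exciton model. Defaults are the
#' standard parameterization of transition-dipole-coupling (TDC) exciton
#' calculations for the amide-I' band in a D2O subphase; every value is
#' overridable here or from the run configuration file.
#'
#' @param omega0 base local-mode frequency (cm^-1). Default 1690: the
#'   delocalized exciton band of helical chains is red-shifted by up to
#'   ~50 cm^-1 from the local mode by nearest-neighbor and transition-dipole
#'   coupling, so this places the calculated amide-I' band near the observed
#'   ~1640 cm^-1 center, inside the 1600-1700 cm^-1 scoring window.
#' @param delta_omega optional per-unit frequency shifts (cm^-1), recycled or
#'   indexed by unit; `NULL` means uniform `omega0`.
#' @param A TDC prefactor (cm^-1 Angstrom^3). Default 580, giving typical
#'   non-neighbor couplings of ~1-10 cm^-1 at backbone distances.
#' @param theta_dip transition-dipole tilt (degrees) from the C=O bond toward
#'   the amide N, in the O-C-N plane. Default 20.
#' @param d_off dipole anchor offset (Angstrom) along C=O from the carbonyl
#'   carbon. Default 0.868.
#' @param J_nn nearest-neighbor (through-bond) coupling constant (cm^-1).
#'   Default -8.5.
#' @param nn_map optional function `(phi, psi) -> J` overriding `J_nn`
#'   (dihedral-map hook; not used by default).
#' @param gamma homogeneous Lorentzian linewidth, FWHM of the single-mode
#'   squared-modulus peak (cm^-1). Default 12.
#' @param rho Raman tensor anisotropy: local tensor is axially symmetric
#'   about the dipole with principal values (1, rho, rho). Default 0.25.
#' @return object of class `vs_params`.
#' @export
exciton_params <- function(omega0 = 1690, delta_omega = NULL, A = 580,
                           theta_dip = 20, d_off = 0.868, J_nn = -8.5,
                           nn_map = NULL, gamma = 12, rho = 0.25) {
  stopifnot(is.finite(A), gamma > 0, theta_dip >= 0, theta_dip < 90)
  structure(list(omega0 = omega0, delta_omega = delta_omega, A = A,
                 theta_dip = theta_dip, d_off = d_off, J_nn = J_nn,
                 nn_map = nn_map, gamma = gamma, rho = rho),
            class = "vs_params")
}

#' Extract amide-I chromophores from a protein frame
#'
#' Each peptide bond between consecutive residues i, i+1 of a chain yields
#' one amide unit: anchor at `C + d_off * (O - C)/|O - C|`, unit transition
#' dipole in the O-C-N plane rotated `theta_dip` degrees from the C->O
#' direction toward N, a local Raman tensor axially symmetric about the
#' dipole, and a local frequency. A chain of n residues yields n-1 units;
#' chain breaks (C-N distance > 2.5 Angstrom) produce no unit and a warning.
#' Proline amides are included with identical parameters and flagged.
#'
#' @param protein a [vs_frame] containing only protein atoms.
#' @param params [exciton_params()].
#' @return object of class `vs_units`: matrices `r` (n x 3 anchors), `e`
#'   (n x 3 unit dipoles), `alpha` (n x 9 row-flattened lab-frame Raman
#'   tensors), vector `omega`, plus `chain`, `donor_resno`, `proline`.
#' @export
extract_amide_units <- function(protein, params = exciton_params()) {
  a <- protein$atoms
  r_list <- list(); e_list <- list(); om <- c(); ch <- c(); dres <- c(); pro <- c()
  th <- params$theta_dip * pi / 180
  for (cid in unique(a$chain)) {
    ac <- a[a$chain == cid, , drop = FALSE]
    resnos <- sort(unique(ac$resno))
    for (k in seq_len(length(resnos) - 1)) {
      i <- resnos[k]; j <- resnos[k + 1]
      if (j != i + 1) next  # sequence gap: no peptide bond
      Ci <- bb_atom(ac, i, "C"); Oi <- bb_atom(ac, i, "O"); Nj <- bb_atom(ac, j, "N")
      if (is.null(Ci) || is.null(Oi) || is.null(Nj))
        stop("missing backbone atom for peptide bond ", i, "-", j,
             " in chain ", cid)
      if (sqrt(sum((Nj - Ci)^2)) > 2.5) {
        warning("chain break between residues ", i, " and ", j,
                " in chain ", cid, "; no amide unit created")
        next
      }
      u <- Oi - Ci; u <- u / sqrt(sum(u^2))
      t_ <- Nj - Ci
      w <- t_ - sum(t_ * u) * u
      w <- w / sqrt(sum(w^2))
      e <- cos(th) * u + sin(th) * w
      r_list[[length(r_list) + 1]] <- Ci + params$d_off * u
      e_list[[length(e_list) + 1]] <- e
      ch <- c(ch, cid); dres <- c(dres, i)
      pro <- c(pro, any(ac$resno == j & ac$resid == "PRO"))
    }
  }
  n <- length(r_list)
  if (n == 0) stop("no amide units (need at least one intact peptide bond)")
  r <- do.call(rbind, r_list)
  e <- do.call(rbind, e_list)
  dom <- params$delta_omega
  if (is.null(dom)) dom <- 0
  om <- params$omega0 + rep_len(dom, n)
  alpha <- t(vapply(seq_len(n), function(i) {
    m <- params$rho * diag(3) + (1 - params$rho) * tcrossprod(e[i, ])
    as.vector(m)  # column-major 3x3 -> length 9; symmetric so order moot
  }, numeric(9)))
  structure(list(r = r, e = e, alpha = alpha, omega = om, chain = ch,
                 donor_resno = dres, proline = pro, params = params),
            class = "vs_units")
}

bb_atom <- function(ac, resno, name) {
  k <- which(ac$resno == resno & ac$elety == name)
  if (length(k) == 0) return(NULL)
  as.numeric(ac[k[1], c("x", "y", "z")])
}

#' @export
print.vs_units <- function(x, ...) {
  cat(sprintf("<vs_units> %d amide units on %d chain(s)\n",
              length(x$omega), length(unique(x$chain))))
  invisible(x)
}

#' Transition dipole coupling between two amide units
#'
#' Point-dipole interaction `J = A * (e_i.e_j - 3 (e_i.n)(e_j.n)) / r^3`
#' with `n` the unit vector from anchor i to anchor j, for non-nearest
#' neighbors.
#'
#' @param units a `vs_units` set.
#' @param i,j unit indices with `|i - j| > 1` within a chain.
#' @param params [exciton_params()].
#' @return coupling in cm^-1.
#' @export
tdc_coupling <- function(units, i, j, params = units$params) {
  d <- units$r[j, ] - units$r[i, ]
  rij <- sqrt(sum(d^2))
  if (rij < 0.5) stop("geometry error: chromophores ", i, " and ", j,
                      " closer than 0.5 Angstrom")
  n <- d / rij
  params$A * (sum(units$e[i, ] * units$e[j, ]) -
                3 * sum(units$e[i, ] * n) * sum(units$e[j, ] * n)) / rij^3
}

#' Build the one-exciton Hamiltonian
#'
#' Diagonal entries are local frequencies; sequence-adjacent units within a
#' chain couple through the nearest-neighbor constant (or map), all other
#' pairs through transition dipole coupling.
#'
#' @param units a `vs_units` set from [extract_amide_units()].
#' @param params [exciton_params()].
#' @return object of class `vs_hamiltonian`: symmetric matrix `H` (cm^-1)
#'   plus its `units`.
#' @export
build_hamiltonian <- function(units, params = units$params) {
  n <- length(units$omega)
  pos <- units$r; e <- units$e
  if (n == 1) {
    H <- matrix(units$omega, 1, 1)
    return(structure(list(H = H, units = units, params = params),
                     class = "vs_hamiltonian"))
  }
  dx <- -outer(pos[, 1], pos[, 1], "-")  # dx[i,j] = x_j - x_i
  dy <- -outer(pos[, 2], pos[, 2], "-")
  dz <- -outer(pos[, 3], pos[, 3], "-")
  r <- sqrt(dx^2 + dy^2 + dz^2)
  diag(r) <- Inf
  ein <- (dx * e[, 1] + dy * e[, 2] + dz * e[, 3]) / r
  ejn <- (sweep(dx, 2, e[, 1], "*") + sweep(dy, 2, e[, 2], "*") +
            sweep(dz, 2, e[, 3], "*")) / r
  H <- params$A * (tcrossprod(e) - 3 * ein * ejn) / r^3
  # nearest neighbors: consecutive peptide bonds of the same chain
  nn <- which(units$chain[-n] == units$chain[-1] &
                diff(units$donor_resno) == 1)
  for (k in nn) {
    H[k, k + 1] <- H[k + 1, k] <- params$J_nn
  }
  clash <- which(r < 0.5 & upper.tri(r), arr.ind = TRUE)
  clash <- clash[!(clash[, 2] - clash[, 1] == 1 & (clash[, 1] %in% nn)), , drop = FALSE]
  if (nrow(clash) > 0)
    stop("geometry error: chromophores ", clash[1, 1], " and ", clash[1, 2],
         " closer than 0.5 Angstrom")
  diag(H) <- units$omega
  structure(list(H = H, units = units, params = params),
            class = "vs_hamiltonian")
}

#' Diagonalize an exciton Hamiltonian into eigenmodes
#'
#' Eigenfrequencies come back ascending; each mode carries a collective
#' transition dipole `M_q = sum_i c_qi mu_i` and Raman tensor
#' `A_q = sum_i c_qi alpha_i`. The orthogonal transform preserves the trace
#' and the dipole-strength sum rule.
#'
#' @param ham a `vs_hamiltonian` (or a plain symmetric matrix together with
#'   `units`).
#' @param units required when `ham` is a plain matrix.
#' @param params [exciton_params()]; defaults to the set carried by `units`.
#' @return object of class `vs_modes`: `omega` (ascending, cm^-1), `M`
#'   (n x 3), `Araman` (n x 9, row-flattened symmetric 3x3), eigenvector
#'   matrix `C` (columns = modes), `gamma`.
#' @export
diagonalize <- function(ham, units = NULL, params = NULL) {
  if (inherits(ham, "vs_hamiltonian")) {
    H <- ham$H; units <- ham$units
    if (is.null(params)) params <- ham$params
  } else H <- ham
  if (is.null(params)) params <- units$params
  if (max(abs(H - t(H))) > 1e-8) stop("Hamiltonian is not symmetric")
  ev <- eigen((H + t(H)) / 2, symmetric = TRUE)
  ord <- order(ev$values)
  omega <- ev$values[ord]
  C <- ev$vectors[, ord, drop = FALSE]
  M <- crossprod(C, units$e)        # q x 3
  Araman <- crossprod(C, units$alpha)  # q x 9
  structure(list(omega = omega, M = M, Araman = Araman, C = C,
                 gamma = params$gamma, params = params),
            class = "vs_modes")
}

#' Assemble eigenmodes directly (for tests and custom models)
#'
#' @param omega mode frequencies (cm^-1).
#' @param M n x 3 matrix of mode transition dipoles.
#' @param Araman n x 9 matrix of row-flattened symmetric mode Raman tensors;
#'   if `NULL`, axially symmetric tensors about each dipole with ratio `rho`.
#' @param gamma Lorentzian FWHM (cm^-1).
#' @param rho Raman anisotropy used when `Araman` is `NULL`.
#' @return a `vs_modes` object.
#' @export
make_modes <- function(omega, M, Araman = NULL, gamma = 12, rho = 0.25) {
  M <- matrix(M, ncol = 3)
  if (is.null(Araman) && nrow(M) == 0) Araman <- matrix(0, 0, 9)
  if (is.null(Araman)) {
    Araman <- t(apply(M, 1, function(m) {
      n2 <- sum(m^2)
      if (n2 == 0) return(as.vector(rho * diag(3)))
      as.vector(rho * diag(3) + (1 - rho) * tcrossprod(m / sqrt(n2)))
    }))
  }
  structure(list(omega = omega, M = M, Araman = matrix(Araman, ncol = 9),
                 C = diag(length(omega)), gamma = gamma,
                 params = exciton_params(gamma = gamma, rho = rho)),
            class = "vs_modes")
}
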