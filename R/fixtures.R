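# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  force(seed)  # evaluate caller RNG draws before snapshotting the state
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# place atom D from A-B-C with given bond length, bond angle (B-C-D, deg)
# and dihedral (A-B-C-D, deg): the standard internal-coordinate construction
place_atom <- function(a, b, c_, bond, angle, dihedral) {
  th <- angle * pi / 180
  chi <- dihedral * pi / 180
  bc <- unitv(c_ - b)
  n <- unitv(cross3(b - a, bc))
  mm <- cross3(n, bc)
  c_ + bond * (-cos(th) * bc + sin(th) * cos(chi) * mm + sin(th) * sin(chi) * n)
}

#' Backbone dihedral angle
#' @param a,b,c,d points (length-3 numeric).
#' @return dihedral in degrees, in (-180, 180].
#' @export
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * unitv(b2))
  atan2(y, x) * 180 / pi
}

build_backbone <- function(phi, psi, omega = 180, resid = "ALA",
                           chain = "A", resno_start = 1) {
  n <- length(phi)
  stopifnot(length(psi) == n, n >= 2)
  bNCa <- 1.458; bCaC <- 1.525; bCN <- 1.329; bCO <- 1.231
  aNCaC <- 111.2; aCaCN <- 116.2; aCNCa <- 121.7; aCaCO <- 120.8
  N <- matrix(0, n, 3); CA <- N; C <- N; O <- N; H <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(bNCa, 0, 0)
  C[1, ] <- place_atom(c(0, -1, 0), N[1, ], CA[1, ], bCaC, aNCaC, phi[1])
  for (i in 2:n) {
    N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ], bCN, aCaCN, psi[i - 1])
    CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ], bNCa, aCNCa, omega)
    C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ], bCaC, aCNCa * 0 + aNCaC, phi[i])
    O[i - 1, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ], bCO, aCaCO,
                             psi[i - 1] + 180)
    H[i, ] <- N[i, ] + 1.01 * unitv(C[i - 1, ] - O[i - 1, ])
  }
  O[n, ] <- place_atom(N[n, ], CA[n, ], C[n, ], bCO, aCaCO, psi[n] + 180)
  rows <- list()
  for (i in seq_len(n)) {
    at <- rbind(N[i, ], CA[i, ], C[i, ], O[i, ])
    nm <- c("N", "CA", "C", "O")
    el <- c("N", "C", "C", "O")
    if (!any(is.na(H[i, ]))) { at <- rbind(at, H[i, ]); nm <- c(nm, "H"); el <- c(el, "H") }
    rows[[i]] <- data.frame(elety = nm, resid = resid, chain = chain,
                            resno = resno_start + i - 1,
                            x = at[, 1], y = at[, 2], z = at[, 3], element = el,
                            stringsAsFactors = FALSE)
  }
  vs_frame(do.call(rbind, rows))
}

#' Build an ideal poly-alanine helix
#'
#' Backbone (N, CA, C, O and amide H) constructed from canonical internal
#' coordinates at uniform dihedrals, then optionally tilted, twisted and
#' translated. The default (-57, -47) gives an ideal alpha-helix with a rise
#' of ~1.5 Angstrom per residue; recomputing the dihedrals from the output
#' reproduces the inputs to well under 0.5 degrees.
#'
#' @param n residue count (>= 2).
#' @param phi,psi backbone dihedrals (degrees).
#' @param tilt,twist,z_offset rigid placement, see [orient_structure()].
#' @param chain,resno_start metadata for the generated residues.
#' @return a [vs_frame].
#' @export
build_ideal_helix <- function(n, phi = -57, psi = -47, tilt = 0, twist = 0,
                              z_offset = 0, chain = "A", resno_start = 1) {
  stopifnot(n >= 2)
  fr <- build_backbone(rep(phi, n), rep(psi, n), chain = chain,
                       resno_start = resno_start)
  orient_structure(fr, tilt = tilt, twist = twist, z_offset = z_offset)
}

#' Build a reproducible random coil
#'
#' Dihedrals are drawn uniformly from a broad coil region (phi in
#' `[-180, -50]`; psi in `[60, 180] U [-180, -150]`, covering polyproline-II
#' and extended conformations) under a fixed seed.
#'
#' @param n residue count (>= 2).
#' @param seed RNG seed; the generator is a pure function of `(n, seed)`.
#' @param chain,resno_start metadata.
#' @return a [vs_frame].
#' @export
build_coil <- function(n, seed = 1, chain = "A", resno_start = 1) {
  stopifnot(n >= 2)
  with_seed(seed, {
    phi <- runif(n, -180, -50)
    u <- runif(n, 0, 150)
    psi <- ifelse(u < 120, 60 + u, -180 + (u - 120))
    build_backbone(phi, psi, chain = chain, resno_start = resno_start)
  })
}

#' Rigidly reorient a structure at the interface
#'
#' Applies a twist about the lab z axis followed by a tilt about the
#' (horizontal) x axis, both about the structure's centroid, then a z
#' translation. Internal geometry is preserved exactly.
#'
#' @param frame a [vs_frame].
#' @param tilt rotation about x (degrees).
#' @param twist rotation about z (degrees), applied first.
#' @param z_offset translation along the interface normal (Angstrom).
#' @param center rotation center; default the centroid.
#' @return the reoriented [vs_frame].
#' @export
orient_structure <- function(frame, tilt = 0, twist = 0, z_offset = 0,
                             center = NULL) {
  X <- as.matrix(frame$atoms[, c("x", "y", "z")])
  if (is.null(center)) center <- colMeans(X)
  tw <- twist * pi / 180; ti <- tilt * pi / 180
  Rz <- matrix(c(cos(tw), sin(tw), 0, -sin(tw), cos(tw), 0, 0, 0, 1), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(ti), sin(ti), 0, -sin(ti), cos(ti)), 3, 3)
  Xp <- sweep(sweep(X, 2, center) %*% t(Rz) %*% t(Rx), 2, center, "+")
  Xp[, 3] <- Xp[, 3] + z_offset
  frame$atoms$x <- Xp[, 1]; frame$atoms$y <- Xp[, 2]; frame$atoms$z <- Xp[, 3]
  frame
}

#' Principal axis of a structure's CA trace
#' @param frame a [vs_frame].
#' @return unit 3-vector along the chain's principal axis, oriented from the
#'   first toward the last CA.
#' @export
helix_axis <- function(frame) {
  ca <- frame$atoms[frame$atoms$elety == "CA", c("x", "y", "z")]
  X <- sweep(as.matrix(ca), 2, colMeans(as.matrix(ca)))
  v <- svd(X)$v[, 1]
  if (sum(v * (as.numeric(ca[nrow(ca), ]) - as.numeric(ca[1, ]))) < 0) v <- -v
  unitv(v)
}

# rotate frame so its helix axis points along `target` (unit vector)
align_axis <- function(frame, target) {
  ax <- helix_axis(frame)
  target <- unitv(target)
  v <- cross3(ax, target)
  s <- sqrt(sum(v^2)); cth <- sum(ax * target)
  X <- as.matrix(frame$atoms[, c("x", "y", "z")])
  ctr <- colMeans(X)
  if (s < 1e-12) {
    R <- if (cth > 0) diag(3) else diag(c(1, -1, -1))  # 180 deg about x
  } else {
    K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
    R <- diag(3) + K + K %*% K * ((1 - cth) / s^2)
  }
  Xp <- sweep(sweep(X, 2, ctr) %*% t(R), 2, ctr, "+")
  frame$atoms$x <- Xp[, 1]; frame$atoms$y <- Xp[, 2]; frame$atoms$z <- Xp[, 3]
  frame
}

# roll a helix about its own axis so the first carbonyl C=O points as much
# toward +z as the axis allows (amphipathic helices bind with a fixed face,
# which fixes the roll); degenerate for a near-vertical axis, where the roll
# is azimuthal and irrelevant
roll_to_z <- function(frame, axis, jitter_deg = 0) {
  ax <- unitv(axis)
  tz <- c(0, 0, 1) - sum(c(0, 0, 1) * ax) * ax
  if (sqrt(sum(tz^2)) < 1e-6) return(frame)
  tz <- unitv(tz)
  a <- frame$atoms
  r1 <- min(a$resno)
  C1 <- as.numeric(a[a$resno == r1 & a$elety == "C", c("x", "y", "z")])
  O1 <- as.numeric(a[a$resno == r1 & a$elety == "O", c("x", "y", "z")])
  v <- (O1 - C1) - sum((O1 - C1) * ax) * ax
  if (sqrt(sum(v^2)) < 1e-6) return(frame)
  v <- unitv(v)
  ang <- atan2(sum(cross3(v, tz) * ax), sum(v * tz)) + jitter_deg * pi / 180
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
  X <- as.matrix(a[, c("x", "y", "z")])
  ctr <- colMeans(X)
  Xp <- sweep(sweep(X, 2, ctr) %*% t(R), 2, ctr, "+")
  frame$atoms$x <- Xp[, 1]; frame$atoms$y <- Xp[, 2]; frame$atoms$z <- Xp[, 3]
  frame
}

translate_frame <- function(frame, d) {
  frame$atoms$x <- frame$atoms$x + d[1]
  frame$atoms$y <- frame$atoms$y + d[2]
  frame$atoms$z <- frame$atoms$z + d[3]
  frame
}

#' Antiparallel two-strand beta-sheet fixture
#'
#' Two extended strands (phi = -139, psi = 135) of the same handedness, the
#' second rotated 180 degrees about y and offset so that Kabsch-Sander
#' backbone hydrogen bonds form between the strands. Used as the
#' chiral-VSFG-active reference structure: unlike helices and coils,
#' antiparallel sheets produce a clear PSP response.
#'
#' @param n residues per strand (default 8).
#' @return a [vs_frame] with chains A and B.
#' @export
build_beta_sheet <- function(n = 8) {
  s1 <- build_ideal_helix(n, phi = -139, psi = 135, chain = "A")
  s2 <- build_ideal_helix(n, phi = -139, psi = 135, chain = "B")
  X <- as.matrix(s2$atoms[, c("x", "y", "z")])
  ctr <- colMeans(X)
  Xp <- sweep(sweep(X, 2, ctr) %*% diag(c(-1, 1, -1)), 2, ctr, "+")
  s2$atoms$x <- Xp[, 1] - 0.75
  s2$atoms$y <- Xp[, 2] + 4.4
  s2$atoms$z <- Xp[, 3] - 0.5
  vs_frame(rbind(s1$atoms, s2$atoms))
}

#' Pseudo-lipid slab
#'
#' A square grid of pseudo-lipid atoms (residue name DPPG, one atom per
#' "lipid") at a fixed height: a geometric stand-in for a lipid monolayer in
#' distance and orientation tests, with no lipid chemistry.
#'
#' @param nx,ny grid counts (>= 1).
#' @param spacing grid spacing (Angstrom).
#' @param z0 slab height (Angstrom); the lab z origin sits at the lipid
#'   layer by convention.
#' @return a [vs_frame] with `nx * ny` atoms.
#' @export
make_lipid_slab <- function(nx, ny, spacing = 8, z0 = 0) {
  stopifnot(nx >= 1, ny >= 1)
  g <- expand.grid(ix = seq_len(nx) - 1, iy = seq_len(ny) - 1)
  x <- (g$ix - (nx - 1) / 2) * spacing
  y <- (g$iy - (ny - 1) / 2) * spacing
  vs_frame(data.frame(elety = "P", resid = "DPPG", chain = "L",
                      resno = seq_len(nrow(g)), x = x, y = y, z = z0,
                      element = "P", stringsAsFactors = FALSE))
}

#' Synthetic flat-vs-upright frame library
#'
#' Emulates the study geometry: a protein whose first 50 residues form a
#' helix lying on a pseudo-lipid slab (the lipid-anchored N-terminal
#' segment), continued by a second helical arm (residues 51-140) that either
#' stays flat on the surface or protrudes upright into the subphase, plus
#' disordered random-coil frames above the slab. Arm orientations carry
#' per-frame jitter so each class is an ensemble, not a point.
#'
#' @param n_flat,n_upright,n_coil frames per class (defaults total 200).
#' @param seed RNG seed; the library is a pure function of its arguments.
#' @param n_res total residue count (default 140, the alpha-synuclein
#'   length).
#' @param anchor_len residues in the surface-anchored first arm (default 50).
#' @param dihedral_jitter per-residue s.d. (degrees) of Gaussian disorder on
#'   the helical dihedrals (default 6), giving each frame an individual
#'   broken-helix geometry and the classes a realistic spectral spread.
#' @param slab pseudo-lipid slab frame; default `make_lipid_slab(30, 30, 8)`.
#' @return list with `library` (a `vs_ensemble` whose frames contain protein
#'   plus slab atoms), `class` (character vector per frame), `slab`.
#' @export
fixture_library <- function(n_flat = 70, n_upright = 70, n_coil = 60,
                            seed = 7, n_res = 140, anchor_len = 50,
                            dihedral_jitter = 6,
                            slab = make_lipid_slab(30, 30, 8)) {
  slab_top <- max(slab$atoms$z)
  # reject self-intersecting backbones (the builder has no sterics):
  # chromophore anchors sit up to d_off = 0.868 A from their carbonyl
  # carbons, so non-neighboring carbons must stay > 0.5 + 2*0.868 A apart
  # for every anchor pair to clear the 0.5 A chromophore-clash bound
  clash_free <- function(frame) {
    Cc <- frame$atoms[frame$atoms$elety == "C", c("x", "y", "z")]
    n <- nrow(Cc)
    if (n < 3) return(TRUE)
    d <- pdist(as.matrix(Cc), as.matrix(Cc))
    d[abs(outer(seq_len(n), seq_len(n), "-")) <= 1] <- Inf
    min(d) > 2.5
  }
  retry <- function(gen) {
    for (i in 1:50) {
      fr <- gen()
      if (clash_free(fr)) return(fr)
    }
    stop("could not generate a clash-free backbone in 50 draws")
  }
  jhelix <- function(n, resno_start = 1) {
    retry(function() build_backbone(rnorm(n, -57, dihedral_jitter),
                                    rnorm(n, -47, dihedral_jitter),
                                    resno_start = resno_start))
  }
  two_arm <- function(theta2_deg, phi2_deg, wobble) {
    arm1 <- align_axis(jhelix(anchor_len), c(1, 0, 0))
    arm1 <- roll_to_z(arm1, c(1, 0, 0), runif(1, -10, 10))
    a1 <- arm1$atoms
    arm1 <- translate_frame(arm1, c(-mean(a1$x), -mean(a1$y),
                                    slab_top + 5 + wobble - mean(a1$z)))
    arm2 <- jhelix(n_res - anchor_len, resno_start = anchor_len + 1)
    th <- theta2_deg * pi / 180; ph <- phi2_deg * pi / 180
    dir2 <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
    arm2 <- align_axis(arm2, dir2)
    arm2 <- roll_to_z(arm2, dir2, runif(1, -10, 10))
    # connect: N(51) sits one peptide-bond length beyond C(50) along arm 2
    a1 <- arm1$atoms
    C50 <- as.numeric(a1[a1$resno == anchor_len & a1$elety == "C", c("x", "y", "z")])
    a2 <- arm2$atoms
    N51 <- as.numeric(a2[a2$resno == anchor_len + 1 & a2$elety == "N", c("x", "y", "z")])
    arm2 <- translate_frame(arm2, C50 + 1.33 * dir2 - N51)
    atoms <- rbind(arm1$atoms, arm2$atoms)
    # drop amide hydrogens so all library frames share one atom layout
    # (DSSP re-places them geometrically with the same construction)
    atoms <- atoms[atoms$elety != "H", ]
    prot <- vs_frame(atoms)
    if (!clash_free(prot)) return(prot)  # caught by the retry wrapper
    # keep the molecule over the middle of the slab footprint
    atoms$x <- atoms$x - mean(atoms$x)
    atoms$y <- atoms$y - mean(atoms$y)
    vs_frame(rbind(atoms, slab$atoms))
  }
  with_seed(seed, {
    frames <- list(); cls <- character(0)
    for (k in seq_len(n_flat)) {
      frames[[length(frames) + 1]] <-
        retry(function() two_arm(runif(1, 83, 97), runif(1, -40, 40),
                                 runif(1, 0, 2)))
      cls <- c(cls, "flat")
    }
    for (k in seq_len(n_upright)) {
      frames[[length(frames) + 1]] <-
        retry(function() two_arm(runif(1, 0, 20), runif(1, 0, 360),
                                 runif(1, 0, 2)))
      cls <- c(cls, "upright")
    }
    for (k in seq_len(n_coil)) {
      co <- retry(function() build_coil(n_res, seed = sample.int(1e6, 1)))
      co <- orient_structure(co, tilt = runif(1, 0, 180), twist = runif(1, 0, 360))
      a <- co$atoms
      co <- translate_frame(co, c(-mean(a$x), -mean(a$y),
                                  slab_top + 12 + runif(1, 0, 6) - min(a$z)))
      co$atoms <- co$atoms[co$atoms$elety != "H", ]
      frames[[length(frames) + 1]] <- vs_frame(rbind(co$atoms, slab$atoms))
      cls <- c(cls, "coil")
    }
    list(library = as_ensemble(frames), class = cls, slab = slab)
  })
}

#' Synthesize a noisy replicate "experimental" dataset from known frames
#'
#' The true spectrum is the weight-averaged calculated intensity of the
#' generating frames; each replicate adds i.i.d. Gaussian per-point noise
#' (homoscedastic per polarization combination). Replicates are averaged and
#' their per-point sample standard deviation retained, mirroring how
#' experimental datasets are composed from 10-50 repeated acquisitions.
#'
#' @param library a `vs_ensemble` (or list of `vs_spectra` to skip
#'   recalculation).
#' @param indices generating frame indices into the library.
#' @param weights mixture weights (>= 0, renormalized to sum 1); default
#'   uniform.
#' @param sigma_noise per-point Gaussian noise s.d., absolute, or relative to
#'   the true-spectrum maximum when `relative_noise = TRUE`.
#' @param m replicate count (2-50).
#' @param seed RNG seed.
#' @param params,grid,n_phi,weights_pc spectral-calculation settings.
#' @param relative_noise interpret `sigma_noise` as a fraction of the peak
#'   intensity (default TRUE).
#' @param label dataset label.
#' @return list with `exp` (a `vs_experiment`), `pooled_std`, `true`
#'   (intensity matrix), `replicates` (list of matrices), `indices`,
#'   `weights`, `sigma_abs`, `seed`.
#' @export
synth_experiment <- function(library, indices, weights = NULL,
                             sigma_noise = 0.005, m = 30, seed = 1,
                             params = exciton_params(), grid = frequency_grid(),
                             n_phi = 36, weights_pc = fresnel_weights(),
                             relative_noise = TRUE, label = NULL) {
  if (sigma_noise < 0) stop("sigma_noise must be >= 0")
  stopifnot(m >= 2)
  if (length(indices) == 0 || anyNA(indices))
    stop("generating frame indices must be a non-empty index vector")
  if (is.null(weights)) weights <- rep(1, length(indices))
  if (length(weights) != length(indices) || any(weights < 0))
    stop("weights must be non-negative and match indices")
  weights <- weights / sum(weights)
  specs <- if (inherits(library, "vs_ensemble")) {
    lapply(indices, function(i)
      calc_frame_spectra(library$frames[[i]], params, grid, n_phi, weights_pc))
  } else library[indices]
  truth <- Reduce(`+`, Map(function(s, w) w * s$I, specs, as.list(weights)))
  sig <- if (relative_noise) sigma_noise * max(truth) else sigma_noise
  reps <- with_seed(seed, lapply(seq_len(m), function(k) {
    truth + matrix(rnorm(length(truth), sd = sig), nrow(truth), ncol(truth))
  }))
  es <- experimental_std(reps, grid = grid,
                         window = range(grid), pcs = colnames(truth))
  exp <- vs_experiment(grid, es$mean, es$sd, n_rep = m, label = label)
  list(exp = exp, pooled_std = es$pooled, true = truth, replicates = reps,
       indices = indices, weights = weights, sigma_abs = sig, seed = seed)
}

#' Lipid-to-protein molar ratio of a monolayer experiment
#'
#' `LPR = (A_int / a_L) / (N_A * c * V)`: moles of interfacial lipid (trough
#' area over area per lipid) divided by moles of added protein.
#'
#' @param conc protein concentration (mol/L).
#' @param volume subphase volume (L).
#' @param area interfacial area (Angstrom^2).
#' @param area_per_lipid area per lipid molecule (Angstrom^2); default 50,
#'   the idealized mammalian plasma-membrane value at ~30 mN/m.
#' @return dimensionless LPR.
#' @export
compute_lpr <- function(conc, volume, area, area_per_lipid = 50) {
  stopifnot(conc > 0, volume > 0, area > 0, area_per_lipid > 0)
  NA_AVOG <- 6.02214076e23
  (area / area_per_lipid) / (NA_AVOG * conc * volume)
}

#' Interfacial area implied by a known LPR
#'
#' Inverse of [compute_lpr()]: fixes the trough area from a stated LPR at
#' given protein concentration and volume.
#'
#' @inheritParams compute_lpr
#' @param lpr target lipid-to-protein ratio.
#' @return interfacial area (Angstrom^2).
#' @export
lpr_interface_area <- function(lpr, conc, volume, area_per_lipid = 50) {
  stopifnot(lpr > 0, conc > 0, volume > 0)
  NA_AVOG <- 6.02214076e23
  lpr * NA_AVOG * conc * volume * area_per_lipid
}
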