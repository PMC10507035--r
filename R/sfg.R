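PCS <- c("ssp", "ppp", "sps", "psp")

#' Regular wavenumber grid
#'
#' @param from,to window edges (cm^-1). Default 1600-1700, the amide-I region.
#' @param by spacing (cm^-1).
#' @return strictly increasing numeric vector.
#' @export
frequency_grid <- function(from = 1600, to = 1700, by = 1) {
  g <- seq(from, to, by = by)
  if (length(g) < 2 || any(diff(g) <= 0)) stop("grid must be strictly increasing")
  g
}

# Lab tensor element (I,J,K) -> row of the flattened 27-vector.
chi_idx <- function(el) {
  ax <- c(x = 1, y = 2, z = 3)
  i <- ax[substr(el, 1, 1)]; j <- ax[substr(el, 2, 2)]; k <- ax[substr(el, 3, 3)]
  unname(i + 3 * (j - 1) + 9 * (k - 1))
}

#' Second-order susceptibility spectrum of an eigenmode set
#'
#' Evaluates the molecular hyperpolarizability response
#' `beta_abc(w) = sum_q A_q,ab M_q,c / (w_q - w - i Gamma/2)` and averages it
#' over uniform rotations about the interface normal z (the azimuthal
#' isotropy of the monolayer). The average of a rank-3 tensor is a trig
#' polynomial of degree <= 3, so any `n_phi >= 4` evaluates it exactly;
#' `n_phi = 0` is an "analytic" sentinel using the minimal 4-point rule.
#'
#' @param modes a `vs_modes` set ([diagonalize()] or [make_modes()]).
#' @param grid wavenumber grid (cm^-1), see [frequency_grid()].
#' @param n_phi number of azimuthal rotations (>= 4), or 0 for the analytic
#'   minimal rule. Default 36.
#' @return object of class `vs_chi`: complex matrix `chi` (27 x n_grid; lab
#'   elements IJK flattened with I fastest), `grid`, `gamma`.
#' @export
susceptibility <- function(modes, grid = frequency_grid(), n_phi = 36) {
  if (!(n_phi == 0 || n_phi >= 4)) stop("n_phi must be 0 (analytic) or >= 4")
  if (n_phi == 0) n_phi <- 4
  nq <- length(modes$omega)
  if (nq == 0 || all(modes$M == 0)) {
    if (nq == 0) warning("empty mode set: zero spectrum")
    chi <- matrix(0 + 0i, 27, length(grid))
    return(structure(list(chi = chi, grid = grid, gamma = modes$gamma),
                     class = "vs_chi"))
  }
  T27 <- matrix(0, nq, 27)
  ia <- rep(1:9, times = 3)
  ic <- rep(1:3, each = 9)
  for (phi in (seq_len(n_phi) - 1) * 2 * pi / n_phi) {
    cs <- cos(phi); sn <- sin(phi)
    R <- matrix(c(cs, sn, 0, -sn, cs, 0, 0, 0, 1), 3, 3)
    Mp <- modes$M %*% t(R)
    Ap <- modes$Araman %*% t(R %x% R)
    T27 <- T27 + Ap[, ia, drop = FALSE] * Mp[, ic, drop = FALSE]
  }
  T27 <- T27 / n_phi
  L <- 1 / (outer(modes$omega, grid, "-") - 1i * modes$gamma / 2)  # nq x nw
  chi <- t(T27) %*% L  # 27 x nw (T27 real)
  structure(list(chi = chi, grid = grid, gamma = modes$gamma), class = "vs_chi")
}

#' Extract one lab-frame susceptibility element
#' @param chi a `vs_chi`.
#' @param el three-letter element such as `"yyz"` (indices SFG, visible, IR).
#' @return complex vector over the grid.
#' @export
chi_element <- function(chi, el) chi$chi[chi_idx(el), ]

#' Default per-polarization-combination Fresnel weights
#'
#' All-unity weights by convention; the experimental normalization (gold
#' reference) fixes only relative intensities, so weights are exposed rather
#' than hard-coded. PPP weights apply to (xxz, xzx, zxx, zzz), PSP weights to
#' the chiral pair (xyz, zyx).
#'
#' @return list with components `ssp`, `sps`, `ppp` (length 4), `psp`
#'   (length 2), `nonres` (per-PC complex non-resonant background, zero).
#' @export
fresnel_weights <- function() {
  list(ssp = 1, sps = 1, ppp = c(1, 1, 1, 1), psp = c(1, 1),
       nonres = c(ssp = 0i, ppp = 0i, sps = 0i, psp = 0i))
}

#' Polarized VSFG intensities from a susceptibility spectrum
#'
#' Under C-infinity-v interface symmetry the four recorded polarization
#' combinations probe: SSP ~ |chi_yyz|^2, SPS ~ |chi_yzy|^2, PPP ~ a weighted
#' coherent sum of (xxz, xzx, zxx, zzz), PSP ~ the chiral pair (xyz, zyx).
#'
#' @param chi a `vs_chi`.
#' @param weights [fresnel_weights()]-style list.
#' @return object of class `vs_spectra`: matrix `I` (n_grid x 4, columns
#'   ssp/ppp/sps/psp), `grid`, the `weights` used, and the underlying `chi`
#'   (kept for coherent susceptibility-level averaging).
#' @export
polarized_intensities <- function(chi, weights = fresnel_weights()) {
  w <- weights
  amp <- cbind(
    ssp = w$ssp[1] * chi_element(chi, "yyz"),
    ppp = w$ppp[1] * chi_element(chi, "xxz") + w$ppp[2] * chi_element(chi, "xzx") +
      w$ppp[3] * chi_element(chi, "zxx") + w$ppp[4] * chi_element(chi, "zzz"),
    sps = w$sps[1] * chi_element(chi, "yzy"),
    psp = w$psp[1] * chi_element(chi, "xyz") + w$psp[2] * chi_element(chi, "zyx"))
  amp <- sweep(amp, 2, w$nonres[PCS], "+")
  I <- abs(amp)^2
  colnames(I) <- PCS
  structure(list(I = I, grid = chi$grid, weights = w, chi = chi),
            class = "vs_spectra")
}

#' @export
print.vs_spectra <- function(x, ...) {
  cat(sprintf("<vs_spectra> %d points (%g-%g cm^-1), PCs: %s\n",
              length(x$grid), min(x$grid), max(x$grid),
              paste(colnames(x$I), collapse = "/")))
  invisible(x)
}

#' Calculate polarized spectra for one structure frame
#'
#' Pipeline: protein extraction -> amide units -> exciton Hamiltonian ->
#' eigenmodes -> azimuthally averaged susceptibility -> polarized
#' intensities. Deterministic for fixed inputs.
#'
#' @param frame a [vs_frame] (lipid/solvent atoms, if present, are split off).
#' @param params [exciton_params()].
#' @param grid wavenumber grid.
#' @param n_phi azimuthal rotations, see [susceptibility()].
#' @param weights [fresnel_weights()]-style list.
#' @return a `vs_spectra`.
#' @export
calc_frame_spectra <- function(frame, params = exciton_params(),
                               grid = frequency_grid(), n_phi = 36,
                               weights = fresnel_weights()) {
  if (!all(frame$atoms$resid %in% AA3))
    frame <- split_components(frame)$protein
  units <- extract_amide_units(frame, params)
  modes <- diagonalize(build_hamiltonian(units, params))
  polarized_intensities(susceptibility(modes, grid, n_phi), weights)
}

#' Average polarized spectra
#'
#' `mode = "intensity"` averages the squared intensities (incoherent,
#' appropriate for frames far apart in time); `mode = "susceptibility"`
#' averages the complex susceptibilities first and squares afterwards
#' (coherent, appropriate for one fluctuating emitter).
#'
#' @param spectra list of `vs_spectra` on a shared grid.
#' @param mode `"intensity"` or `"susceptibility"`.
#' @param weights weights applied when re-squaring in susceptibility mode.
#' @return a `vs_spectra`.
#' @export
average_spectra <- function(spectra, mode = c("intensity", "susceptibility"),
                            weights = fresnel_weights()) {
  mode <- match.arg(mode)
  stopifnot(length(spectra) >= 1)
  g <- spectra[[1]]$grid
  for (s in spectra) if (!isTRUE(all.equal(s$grid, g))) stop("grid mismatch")
  if (length(spectra) == 1) return(spectra[[1]])
  if (mode == "intensity") {
    I <- Reduce(`+`, lapply(spectra, function(s) s$I)) / length(spectra)
    out <- spectra[[1]]
    out$I <- I
    out$chi <- NULL
    out
  } else {
    chis <- lapply(spectra, function(s) {
      if (is.null(s$chi)) stop("susceptibility-mode averaging needs spectra that carry chi")
      s$chi$chi
    })
    cbar <- spectra[[1]]$chi
    cbar$chi <- Reduce(`+`, chis) / length(spectra)
    polarized_intensities(cbar, weights)
  }
}

#' Write spectra to a tabular text file
#'
#' Long format, one row per grid point per polarization combination, with
#' columns `wavenumber_cm1`, `pc`, `intensity` (plus `std` and `n_rep` for
#' experimental datasets).
#'
#' @param x a `vs_spectra` or `vs_experiment`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(x, path) {
  if (inherits(x, "vs_experiment")) {
    df <- data.frame(wavenumber_cm1 = rep(x$grid, times = 4),
                     pc = rep(PCS, each = length(x$grid)),
                     intensity = as.vector(x$I[, PCS]),
                     std = as.vector(x$sd[, PCS]),
                     n_rep = x$n_rep)
  } else {
    df <- data.frame(wavenumber_cm1 = rep(x$grid, times = 4),
                     pc = rep(PCS, each = length(x$grid)),
                     intensity = as.vector(x$I[, PCS]))
  }
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read spectra or an experimental dataset from a tabular text file
#'
#' @param path TSV path as written by [write_spectra()]; a `std` column makes
#'   the result a `vs_experiment`.
#' @param label optional dataset label (e.g. `"low-LPR"`).
#' @return `vs_spectra` or `vs_experiment`.
#' @export
read_spectra <- function(path, label = NULL) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  pcs <- sort(unique(df$pc))
  if (!all(pcs %in% PCS)) stop("unknown polarization combination in ", path)
  g <- sort(unique(df$wavenumber_cm1))
  I <- matrix(0, length(g), 4, dimnames = list(NULL, PCS))
  has_sd <- "std" %in% names(df)
  sdm <- I
  for (pc in pcs) {
    sub <- df[df$pc == pc, ]
    sub <- sub[order(sub$wavenumber_cm1), ]
    if (!isTRUE(all.equal(sub$wavenumber_cm1, g))) stop("grids differ across PCs")
    I[, pc] <- sub$intensity
    if (has_sd) sdm[, pc] <- sub$std
  }
  if (has_sd) {
    nr <- if ("n_rep" %in% names(df)) df$n_rep[1] else NA
    vs_experiment(g, I, sdm, n_rep = nr, label = label)
  } else {
    structure(list(I = I, grid = g, weights = fresnel_weights(), chi = NULL),
              class = "vs_spectra")
  }
}

#' Construct an experimental dataset
#'
#' @param grid wavenumber grid (cm^-1).
#' @param I n_grid x 4 matrix of mean intensities (columns ssp/ppp/sps/psp).
#' @param sd matching per-point standard deviations (>= 0).
#' @param n_rep replicate count behind the means.
#' @param label free-text label (e.g. `"high-LPR"`).
#' @return object of class `vs_experiment`.
#' @export
vs_experiment <- function(grid, I, sd, n_rep = NA, label = NULL) {
  I <- as.matrix(I); sd <- as.matrix(sd)
  stopifnot(nrow(I) == length(grid), all(dim(I) == dim(sd)))
  if (any(sd < 0)) stop("negative standard deviation")
  if (is.null(colnames(I))) colnames(I) <- PCS
  colnames(sd) <- colnames(I)
  structure(list(grid = grid, I = I[, PCS], sd = sd[, PCS], n_rep = n_rep,
                 label = label), class = "vs_experiment")
}

#' @export
print.vs_experiment <- function(x, ...) {
  cat(sprintf("<vs_experiment>%s %d points (%g-%g cm^-1), n_rep = %s\n",
              if (is.null(x$label)) "" else paste0(" [", x$label, "]"),
              length(x$grid), min(x$grid), max(x$grid), x$n_rep))
  invisible(x)
}
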