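score_mask <- function(grid, window) {
  m <- grid >= window[1] & grid <= window[2]
  if (!any(m)) stop("scoring window does not overlap the grid")
  m
}

align_calc <- function(calc, exp) {
  if (!isTRUE(all.equal(calc$grid, exp$grid)))
    stop("calculated and experimental grids differ; resample first")
  invisible(TRUE)
}

#' Fit a single intensity scale between calculated and experimental spectra
#'
#' One joint non-negative least-squares scale across all scored polarization
#' combinations (preserving inter-PC intensity ratios):
#' `s = max(0, sum(I_exp * I_calc) / sum(I_calc^2))` over the scoring window.
#'
#' @param calc a `vs_spectra`.
#' @param exp a `vs_experiment` on the same grid.
#' @param window wavenumber interval scored, default `c(1600, 1700)`.
#' @param pcs polarization combinations included, default all four.
#' @return non-negative scalar scale.
#' @export
fit_scale <- function(calc, exp, window = c(1600, 1700), pcs = PCS) {
  align_calc(calc, exp)
  m <- score_mask(calc$grid, window)
  ic <- as.vector(calc$I[m, pcs])
  ie <- as.vector(exp$I[m, pcs])
  den <- sum(ic^2)
  if (den == 0) {
    warning("all-zero calculated spectra: scale = 0")
    return(0)
  }
  max(0, sum(ie * ic) / den)
}

#' Residual-sum-of-squares score of one frame's spectra
#'
#' The experimental and (scale-fitted) calculated spectra are differenced at
#' each frequency point of the scoring window; residuals are squared and
#' summed over points and polarization combinations.
#'
#' @inheritParams fit_scale
#' @param scale optional fixed scale; `NULL` (default) fits it.
#' @return list with `scale` and `rss`.
#' @export
rss_score <- function(calc, exp, window = c(1600, 1700), pcs = PCS,
                      scale = NULL) {
  if (length(pcs) == 0) stop("empty polarization-combination subset")
  align_calc(calc, exp)
  if (is.null(scale)) scale <- fit_scale(calc, exp, window, pcs)
  m <- score_mask(calc$grid, window)
  res <- exp$I[m, pcs, drop = FALSE] - scale * calc$I[m, pcs, drop = FALSE]
  list(scale = scale, rss = sum(res^2))
}

#' Score and rank every frame of a library against an experiment
#'
#' Computes polarized spectra per frame, fits the intensity scale, scores the
#' RSS, and sorts ascending (ties broken by global frame index).
#'
#' @param library a `vs_ensemble` (or list of [vs_frame]s).
#' @param exp a `vs_experiment`.
#' @param params [exciton_params()].
#' @param grid wavenumber grid (must match the experiment's).
#' @param window,pcs scoring window and polarization subset.
#' @param n_phi azimuthal rotations for [susceptibility()].
#' @param weights [fresnel_weights()]-style list.
#' @param keep_spectra keep each frame's spectra (needed by
#'   [select_ensemble()]). Default `TRUE`.
#' @param on_error `"stop"` (default) or `"skip"` frames whose spectral
#'   calculation fails (skips are counted in the result).
#' @return object of class `vs_ranking`: `scores` data.frame (`frame_index`,
#'   `traj`, `time_ps`, `scale`, `rss`, ascending `rss`), list `spectra`
#'   indexed by frame, `n_skipped`.
#' @export
rank_frames <- function(library, exp, params = exciton_params(),
                        grid = frequency_grid(), window = c(1600, 1700),
                        pcs = PCS, n_phi = 36, weights = fresnel_weights(),
                        keep_spectra = TRUE, on_error = c("stop", "skip")) {
  on_error <- match.arg(on_error)
  if (!inherits(library, "vs_ensemble")) library <- as_ensemble(library)
  n <- length(library$frames)
  scores <- vector("list", n)
  spectra <- if (keep_spectra) vector("list", n) else NULL
  skipped <- 0L
  for (i in seq_len(n)) {
    sp <- tryCatch(calc_frame_spectra(library$frames[[i]], params, grid,
                                      n_phi, weights),
                   error = function(e) if (on_error == "skip") NULL else stop(e))
    if (is.null(sp)) { skipped <- skipped + 1L; next }
    sc <- rss_score(sp, exp, window, pcs)
    scores[[i]] <- data.frame(frame_index = i,
                              traj = library$index$traj[i],
                              time_ps = library$index$time_ps[i],
                              scale = sc$scale, rss = sc$rss,
                              stringsAsFactors = FALSE)
    if (keep_spectra) spectra[[i]] <- sp
  }
  scores <- do.call(rbind, scores)
  scores <- scores[order(scores$rss, scores$frame_index), ]
  rownames(scores) <- NULL
  structure(list(scores = scores, spectra = spectra, n_skipped = skipped,
                 window = window, pcs = pcs, exp_label = exp$label),
            class = "vs_ranking")
}

#' @export
print.vs_ranking <- function(x, ...) {
  cat(sprintf("<vs_ranking> %d frames scored (%d skipped); best RSS = %.4g\n",
              nrow(x$scores), x$n_skipped, x$scores$rss[1]))
  invisible(x)
}

#' Pooled experimental standard deviation over replicates
#'
#' Per-point sample standard deviation (n-1 denominator) across replicate
#' spectra, pooled as the mean of the per-point values over the scoring
#' window and polarization combinations.
#'
#' @param replicates list (length >= 2) of `vs_spectra` (or intensity
#'   matrices) on a common grid.
#' @param grid grid of the replicates (taken from the first `vs_spectra` if
#'   not given).
#' @param window,pcs pooling window and polarization subset.
#' @return list with `pooled` (scalar), `sd` (per-point matrix), `mean`
#'   (per-point matrix), `grid`, `n_rep`.
#' @export
experimental_std <- function(replicates, grid = NULL,
                             window = c(1600, 1700), pcs = PCS) {
  if (length(replicates) < 2) stop("need at least 2 replicates")
  mats <- lapply(replicates, function(r) if (inherits(r, "vs_spectra")) r$I else as.matrix(r))
  if (is.null(grid)) {
    if (!inherits(replicates[[1]], "vs_spectra")) stop("supply the grid")
    grid <- replicates[[1]]$grid
  }
  arr <- simplify2array(mats)             # nw x 4 x m
  mu <- apply(arr, c(1, 2), mean)
  sdm <- apply(arr, c(1, 2), sd)
  colnames(mu) <- colnames(sdm) <- colnames(mats[[1]])
  m <- score_mask(grid, window)
  list(pooled = mean(sdm[m, pcs]), sd = sdm, mean = mu, grid = grid,
       n_rep = length(replicates))
}

pooled_calc_std <- function(Ilist, mask, pcs) {
  if (length(Ilist) < 2) return(0)
  arr <- simplify2array(lapply(Ilist, function(I) I[mask, pcs, drop = FALSE]))
  mean(apply(arr, c(1, 2), sd))
}

#' Select the best-matching ensemble by matching spectral spread
#'
#' Frames are added in ascending-RSS order; the ensemble stops growing at the
#' first size where the pooled standard deviation of the (scale-fitted)
#' calculated spectra inside the ensemble reaches the experimental standard
#' deviation. The RSS of the last included frame is the selection threshold,
#' and membership is exactly all frames at or below it.
#'
#' @param ranking a `vs_ranking` from [rank_frames()] with kept spectra.
#' @param sigma_exp pooled experimental standard deviation (scalar, e.g.
#'   `experimental_std(...)$pooled` or from a `vs_experiment`'s `sd`).
#' @param window,pcs pooling window/PC subset (defaults: those of the
#'   ranking).
#' @return object of class `vs_selected`: `members` (frame indices, ascending
#'   RSS), `threshold`, `pooled_calc_std`, `pooled_exp_std`, `size`,
#'   `crossed` (FALSE when even the full library spread stays below
#'   `sigma_exp`), per-PC `mean`, `lo`, `hi` band matrices, `grid`, and the
#'   member rows of the score table.
#' @export
select_ensemble <- function(ranking, sigma_exp, window = ranking$window,
                            pcs = ranking$pcs) {
  sc <- ranking$scores
  if (nrow(sc) == 0) stop("empty ranking")
  if (is.null(ranking$spectra)) stop("ranking was built with keep_spectra = FALSE")
  grid <- ranking$spectra[[sc$frame_index[1]]]$grid
  mask <- score_mask(grid, window)
  scaledI <- lapply(seq_len(nrow(sc)), function(k) {
    sc$scale[k] * ranking$spectra[[sc$frame_index[k]]]$I
  })
  if (sigma_exp <= 0) {
    kstop <- max(which(sc$rss <= sc$rss[1]))
    crossed <- TRUE
  } else {
    kstop <- NA
    for (k in seq_len(nrow(sc))) {
      if (pooled_calc_std(scaledI[seq_len(k)], mask, pcs) >= sigma_exp) {
        kstop <- k; break
      }
    }
    crossed <- !is.na(kstop)
    if (!crossed) kstop <- nrow(sc)
  }
  threshold <- sc$rss[kstop]
  members <- which(sc$rss <= threshold)     # positions in the ranking
  psd <- pooled_calc_std(scaledI[members], mask, pcs)
  arr <- simplify2array(scaledI[members])
  if (length(members) == 1) arr <- array(arr, c(dim(scaledI[[1]]), 1))
  mu <- apply(arr, c(1, 2), mean)
  lo <- apply(arr, c(1, 2), min)
  hi <- apply(arr, c(1, 2), max)
  dimnames(mu) <- dimnames(lo) <- dimnames(hi) <- list(NULL, colnames(scaledI[[1]]))
  structure(list(members = sc$frame_index[members], threshold = threshold,
                 pooled_calc_std = psd, pooled_exp_std = sigma_exp,
                 size = length(members), crossed = crossed,
                 mean = mu, lo = lo, hi = hi, grid = grid,
                 scores = sc[members, ]),
            class = "vs_selected")
}

#' @export
print.vs_selected <- function(x, ...) {
  cat(sprintf(paste0("<vs_selected> %d frames, RSS threshold %.4g, ",
                     "calc std %.4g vs exp std %.4g\n"),
              x$size, x$threshold, x$pooled_calc_std, x$pooled_exp_std))
  invisible(x)
}

#' Orientation scan of a rigid structure against an experiment
#'
#' For every (tilt, twist) pair the structure is twisted about z, tilted
#' about a horizontal axis, its spectra computed and scored by RSS; the full
#' map and the best orientation are returned. The map is periodic in twist
#' (360 degrees) and, at zero tilt, constant across twist (azimuthal
#' invariance of the interface).
#'
#' @param structure a [vs_frame] (protein; rigid).
#' @param exp a `vs_experiment`.
#' @param theta_grid tilt angles (degrees), covering `[0, 180]`.
#' @param psi_grid twist angles (degrees), covering `[0, 360)`.
#' @param params,grid,window,pcs,n_phi,weights as in [rank_frames()].
#' @return object of class `vs_orientscan`: data.frame `map` (`theta`,
#'   `psi`, `scale`, `rss`) and `best` (row with minimal RSS).
#' @export
orientation_scan <- function(structure, exp, theta_grid = seq(0, 180, by = 5),
                             psi_grid = seq(0, 350, by = 10),
                             params = exciton_params(), grid = frequency_grid(),
                             window = c(1600, 1700), pcs = PCS, n_phi = 0,
                             weights = fresnel_weights()) {
  if (length(theta_grid) == 0 || length(psi_grid) == 0)
    stop("empty angle grid")
  rows <- vector("list", length(theta_grid) * length(psi_grid))
  k <- 0
  for (th in theta_grid) for (ps in psi_grid) {
    fr <- orient_structure(structure, tilt = th, twist = ps)
    sp <- calc_frame_spectra(fr, params, grid, n_phi, weights)
    sc <- rss_score(sp, exp, window, pcs)
    k <- k + 1
    rows[[k]] <- data.frame(theta = th, psi = ps, scale = sc$scale, rss = sc$rss)
  }
  map <- do.call(rbind, rows)
  structure(list(map = map, best = map[which.min(map$rss), ]),
            class = "vs_orientscan")
}

#' @export
print.vs_orientscan <- function(x, ...) {
  cat(sprintf("<vs_orientscan> %d orientations; best RSS %.4g at theta=%g psi=%g\n",
              nrow(x$map), x$best$rss, x$best$theta, x$best$psi))
  invisible(x)
}
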