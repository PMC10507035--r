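pdist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

unitv <- function(v) v / sqrt(sum(v^2))

#' Simplified DSSP secondary-structure assignment
#'
#' Kabsch-Sander hydrogen bonds are detected from the electrostatic energy
#' `E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)` kcal/mol between
#' each backbone C=O acceptor and N-H donor, with a bond where `E < -0.5`.
#' Helices come from pairs of consecutive n-turns (n = 3, 4, 5), strands from
#' parallel/antiparallel bridges; the full states are reduced to three:
#' \{H, G, I\} -> `H`, \{E, B\} -> `E`, else `C`. Amide hydrogens missing from
#' the input are placed 1.01 Angstrom from N opposite the preceding carbonyl
#' C=O bond (the classic DSSP construction).
#'
#' @param frame a [vs_frame]; non-protein atoms are ignored.
#' @return data.frame with `chain`, `resno`, `ss` (one of `"H"`, `"E"`,
#'   `"C"`). Residues with missing backbone atoms are assigned `C` with a
#'   warning.
#' @export
dssp_assign <- function(frame) {
  a <- frame$atoms
  a <- a[a$resid %in% AA3, , drop = FALSE]
  key <- paste(a$chain, a$resno)
  ord <- order(a$chain, a$resno)
  ids <- unique(key[ord])
  m <- length(ids)
  chains <- sub(" .*", "", ids)
  resnos <- as.integer(sub(".* ", "", ids))
  getm <- function(name, alt = NULL) {
    M <- matrix(NA_real_, m, 3)
    for (i in seq_len(m)) {
      k <- which(key == ids[i] & a$elety == name)
      if (length(k) == 0 && !is.null(alt))
        k <- which(key == ids[i] & a$elety %in% alt)
      if (length(k) > 0) M[i, ] <- as.numeric(a[k[1], c("x", "y", "z")])
    }
    M
  }
  N <- getm("N"); CA <- getm("CA"); C <- getm("C"); O <- getm("O")
  Hx <- getm("H", alt = c("HN", "H1"))
  ok <- rowSums(is.na(cbind(N, CA, C, O))) == 0
  if (any(!ok))
    warning("missing backbone atoms for ", sum(!ok),
            " residue(s); assigned coil")
  cont <- c(FALSE, chains[-1] == chains[-m] & resnos[-1] == resnos[-m] + 1)
  is_pro <- vapply(seq_len(m), function(i)
    any(key == ids[i] & a$resid == "PRO"), TRUE)
  # place missing amide hydrogens
  H <- Hx
  for (i in seq_len(m)) {
    if (!ok[i] || is_pro[i]) { H[i, ] <- NA; next }
    if (any(is.na(H[i, ]))) {
      if (cont[i] && ok[i - 1]) {
        d <- C[i - 1, ] - O[i - 1, ]
        H[i, ] <- N[i, ] + 1.01 * d / sqrt(sum(d^2))
      } else H[i, ] <- NA
    }
  }
  donor_ok <- ok & rowSums(is.na(H)) == 0
  # hb[acceptor, donor]
  hb <- matrix(FALSE, m, m)
  acc <- which(ok); don <- which(donor_ok)
  if (length(acc) > 0 && length(don) > 0) {
    rON <- pdist(O[acc, , drop = FALSE], N[don, , drop = FALSE])
    rCH <- pdist(C[acc, , drop = FALSE], H[don, , drop = FALSE])
    rOH <- pdist(O[acc, , drop = FALSE], H[don, , drop = FALSE])
    rCN <- pdist(C[acc, , drop = FALSE], N[don, , drop = FALSE])
    E <- 0.084 * 332 * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
    E[rON < 0.5 | rCH < 0.5 | rOH < 0.5 | rCN < 0.5] <- -9.9
    hb[acc, don] <- E < -0.5
  }
  same_run <- function(i, j) {
    # residues i..j contiguous within one chain
    j <= m && i >= 1 && chains[i] == chains[j] && resnos[j] - resnos[i] == j - i &&
      all(cont[seq(i + 1, length.out = j - i)])
  }
  turn <- function(n) vapply(seq_len(m), function(i)
    i + n <= m && same_run(i, i + n) && hb[i, i + n], TRUE)
  t3 <- turn(3); t4 <- turn(4); t5 <- turn(5)
  ss <- rep("C", m)
  mark <- function(ss, tn, n, code) {
    for (i in seq_len(m)) {
      if (i > 1 && tn[i - 1] && tn[i]) {
        idx <- i:(i + n - 1)
        ss[idx][ss[idx] == "C"] <- code
      }
    }
    ss
  }
  ss <- mark(ss, t4, 4, "H")
  # bridges (parallel/antiparallel); both B and E reduce to E
  hbs <- function(i, j) i >= 1 && j >= 1 && i <= m && j <= m && hb[i, j]
  bridge <- rep(FALSE, m)
  cand <- which(ok)
  for (i in cand) for (j in cand) {
    if (j <= i) next
    if (chains[i] == chains[j] && abs(resnos[i] - resnos[j]) <= 2) next
    par <- (hbs(i - 1, j) && hbs(j, i + 1)) || (hbs(j - 1, i) && hbs(i, j + 1))
    anti <- (hbs(i, j) && hbs(j, i)) || (hbs(i - 1, j + 1) && hbs(j - 1, i + 1))
    if (par || anti) bridge[c(i, j)] <- TRUE
  }
  ss[bridge & ss == "C"] <- "E"
  ss <- mark(ss, t3, 3, "H")
  ss <- mark(ss, t5, 5, "H")
  ss[!ok] <- "C"  # incomplete backbone cannot carry an assignment
  data.frame(chain = chains, resno = resnos, ss = ss, stringsAsFactors = FALSE)
}

#' Per-residue helicity fraction over an ensemble
#'
#' Fraction of ensemble members in which each residue is assigned `H` by
#' [dssp_assign()], with the standard error of the mean over members.
#'
#' @param ensemble list of [vs_frame]s (or a `vs_ensemble`) sharing residue
#'   numbering.
#' @return data.frame `resno`, `helicity`, `helicity_sem`, plus attribute
#'   `n` (ensemble size).
#' @export
helicity_profile <- function(ensemble) {
  if (inherits(ensemble, "vs_ensemble")) ensemble <- ensemble$frames
  N <- length(ensemble)
  stopifnot(N >= 1)
  assigns <- lapply(ensemble, dssp_assign)
  ref <- assigns[[1]]$resno
  ind <- vapply(assigns, function(d) {
    if (!identical(d$resno, ref)) stop("inconsistent residue numbering across frames")
    as.numeric(d$ss == "H")
  }, numeric(length(ref)))
  ind <- matrix(ind, nrow = length(ref))
  h <- rowMeans(ind)
  sem <- if (N > 1) apply(ind, 1, sd) / sqrt(N) else rep(0, length(ref))
  out <- data.frame(resno = ref, helicity = h, helicity_sem = sem)
  attr(out, "n") <- N
  out
}

#' Per-residue minimum distance to the lipid layer over an ensemble
#'
#' For each frame, the minimum Euclidean distance from any atom of each
#' protein residue to any lipid atom; profiles are averaged over frames with
#' the standard error of the mean.
#'
#' @param ensemble list of [vs_frame]s containing protein and lipid atoms, or
#'   list of `list(protein =, lipid =)` pairs from [split_components()].
#' @return data.frame `resno`, `min_dist`, `min_dist_sem`, attribute `n`.
#' @export
min_distance_profile <- function(ensemble) {
  if (inherits(ensemble, "vs_ensemble")) ensemble <- ensemble$frames
  N <- length(ensemble)
  stopifnot(N >= 1)
  per_frame <- lapply(ensemble, function(fr) {
    if (inherits(fr, "vs_frame")) fr <- split_components(fr)
    if (n_atoms(fr$lipid) == 0) stop("empty lipid subset")
    P <- as.matrix(fr$protein$atoms[, c("x", "y", "z")])
    L <- as.matrix(fr$lipid$atoms[, c("x", "y", "z")])
    dmin <- apply(pdist(P, L), 1, min)
    tapply(dmin, fr$protein$atoms$resno, min)
  })
  ref <- as.integer(names(per_frame[[1]]))
  M <- vapply(per_frame, function(v) {
    if (!identical(as.integer(names(v)), ref))
      stop("inconsistent residue numbering across frames")
    as.numeric(v)
  }, numeric(length(ref)))
  M <- matrix(M, nrow = length(ref))
  out <- data.frame(resno = ref, min_dist = rowMeans(M),
                    min_dist_sem = if (N > 1) apply(M, 1, sd) / sqrt(N)
                    else rep(0, length(ref)))
  attr(out, "n") <- N
  out
}

#' Default alpha-synuclein segments
#'
#' N-terminal lipid-anchoring region (1-60), amyloidogenic NAC core (61-95),
#' acidic C-terminal region (96-140), residue numbering per UniProt P37840.
#' @return named list of residue index vectors.
#' @export
alpha_synuclein_segments <- function() {
  list("N-term" = 1:60, "NAC" = 61:95, "C-term" = 96:140)
}

#' Per-segment means of a residue profile
#'
#' @param profile data.frame with a `resno` column plus numeric profile
#'   columns (e.g. from [helicity_profile()] or [min_distance_profile()]).
#' @param segments named list of residue index vectors; default the
#'   alpha-synuclein segmentation.
#' @return data.frame, one row per segment, with the mean of every numeric
#'   profile column over the segment's residues.
#' @export
segment_summary <- function(profile, segments = alpha_synuclein_segments()) {
  cols <- setdiff(names(profile), "resno")
  rows <- lapply(names(segments), function(nm) {
    idx <- segments[[nm]]
    if (!all(idx %in% profile$resno))
      stop("segment ", nm, " outside the profile's residue range")
    sub <- profile[profile$resno %in% idx, cols, drop = FALSE]
    cbind(data.frame(segment = nm, from = min(idx), to = max(idx)),
          as.data.frame(as.list(colMeans(sub))))
  })
  do.call(rbind, rows)
}

#' Write a residue profile table
#'
#' @param helicity data.frame from [helicity_profile()].
#' @param dist optional data.frame from [min_distance_profile()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(helicity, dist = NULL, path) {
  out <- helicity
  if (!is.null(dist)) out <- merge(out, dist, by = "resno", all = TRUE)
  write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
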