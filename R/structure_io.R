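#' @importFrom stats sd setNames rnorm runif aggregate
#' @importFrom utils read.table write.table head tail
NULL

# Standard amino-acid residue names used when partitioning frames.
AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL", "HSD", "HSE", "HSP")

SOLVENT3 <- c("SOL", "HOH", "WAT", "TIP", "TIP3", "SPC", "NA", "CL", "NA+",
              "CL-", "K", "K+", "MG", "CA2", "POT", "CLA", "SOD")

#' Construct a structure frame
#'
#' A `vs_frame` holds one timestamped set of atomic coordinates in the lab
#' frame, where `z` is the interface normal pointing from the lipid layer into
#' the water subphase. Coordinates are in Angstrom, residue numbering is
#' 1-based (for alpha-synuclein it matches UniProt P37840, residues 1-140).
#'
#' @param atoms data.frame with columns `elety` (atom name), `resid`
#'   (residue name), `chain`, `resno` (1-based residue index), `x`, `y`, `z`
#'   (Angstrom) and optionally `element`.
#' @param time frame time in ps.
#' @param traj trajectory identifier.
#' @param box optional box vectors (Angstrom).
#' @return object of class `vs_frame`.
#' @export
vs_frame <- function(atoms, time = 0, traj = "traj1", box = NULL) {
  req <- c("elety", "resid", "chain", "resno", "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss) > 0)
    stop("atom table lacks column(s): ", paste(miss, collapse = ", "))
  if (is.null(atoms$element))
    atoms$element <- guess_element(atoms$elety)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite atom coordinates")
  if (any(atoms$resno < 1)) stop("residue indices must be >= 1")
  structure(list(atoms = atoms, time = time, traj = traj, box = box),
            class = "vs_frame")
}

#' @export
print.vs_frame <- function(x, ...) {
  cat(sprintf("<vs_frame> %d atoms, %d residues, t = %g ps (%s)\n",
              nrow(x$atoms), length(unique(paste(x$atoms$chain, x$atoms$resno))),
              x$time, x$traj))
  invisible(x)
}

#' Number of atoms in a frame
#' @param frame a `vs_frame`.
#' @return integer atom count.
#' @export
n_atoms <- function(frame) nrow(frame$atoms)

guess_element <- function(elety) {
  e <- sub("^[0-9]*", "", toupper(elety))
  two <- substr(e, 1, 2)
  el <- substr(e, 1, 1)
  el[two %in% c("CL", "NA", "MG", "FE", "ZN")] <- two[two %in% c("CL", "NA", "MG", "FE", "ZN")]
  el
}

#' Read a single structure frame from PDB or GRO
#'
#' PDB files are parsed with \pkg{bio3d}; GRO files with a built-in
#' fixed-column reader (GRO stores nm, converted to Angstrom here).
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"gro"`.
#' @param multi_model policy when a PDB holds several MODEL records:
#'   `"error"` (default) or `"first"`.
#' @return a [vs_frame].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "gro"),
                           multi_model = c("error", "first")) {
  format <- match.arg(format)
  multi_model <- match.arg(multi_model)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (ext %in% c("pdb", "ent")) format <- "pdb"
    else if (ext == "gro") format <- "gro"
    else stop("unsupported structure format: .", ext)
  }
  if (format == "pdb") read_pdb_frame(path, multi_model)
  else read_gro_frame(path)
}

read_pdb_frame <- function(path, multi_model) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  nmod <- nrow(pdb$xyz)
  if (is.null(nmod)) nmod <- 1
  if (nmod > 1 && multi_model == "error")
    stop("PDB contains ", nmod, " MODEL records; pass multi_model = \"first\" ",
         "or use read_trajectory()")
  a <- pdb$atom
  xyz <- matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE)
  chain <- a$chain
  chain[is.na(chain) | chain == ""] <- "A"
  atoms <- data.frame(elety = a$elety, resid = a$resid, chain = chain,
                      resno = a$resno,
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      element = ifelse(is.na(a$elesy) | a$elesy == "",
                                       guess_element(a$elety), trimws(a$elesy)),
                      stringsAsFactors = FALSE)
  vs_frame(atoms, time = 0, traj = basename(path))
}

read_gro_frame <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) stop("GRO parse error at line 1: truncated file")
  nat <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(nat)) stop("GRO parse error at line 2: bad atom count")
  if (length(lines) < 2 + nat) stop("GRO parse error: fewer atom lines than declared")
  al <- lines[3:(2 + nat)]
  resno <- suppressWarnings(as.integer(substr(al, 1, 5)))
  resid <- trimws(substr(al, 6, 10))
  elety <- trimws(substr(al, 11, 15))
  x <- suppressWarnings(as.numeric(substr(al, 21, 28)))
  y <- suppressWarnings(as.numeric(substr(al, 29, 36)))
  z <- suppressWarnings(as.numeric(substr(al, 37, 44)))
  bad <- which(is.na(resno) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad) > 0)
    stop("GRO parse error at line ", bad[1] + 2)
  box <- suppressWarnings(as.numeric(strsplit(trimws(lines[3 + nat]), "\\s+")[[1]])) * 10
  atoms <- data.frame(elety = elety, resid = resid, chain = "A", resno = resno,
                      x = x * 10, y = y * 10, z = z * 10,  # nm -> Angstrom
                      stringsAsFactors = FALSE)
  vs_frame(atoms, time = 0, traj = basename(path), box = box)
}

#' Read a coordinate stream into a trajectory ensemble
#'
#' Supports multi-model PDB streams and DCD binary trajectories (read with
#' \pkg{bio3d}) over a PDB or GRO topology. Frames are strided; with `n`
#' stored frames and stride `s`, `floor((n-1)/s) + 1` frames are returned,
#' always including the first.
#'
#' @param topology path to a PDB/GRO file defining atoms.
#' @param coordinates path to a multi-model PDB or a DCD file; may equal
#'   `topology` for a multi-model PDB.
#' @param stride positive integer frame stride.
#' @param dt_ps time between stored frames in ps (default 50, the standard
#'   saving interval used here).
#' @param traj_id trajectory identifier attached to every frame.
#' @return a `vs_ensemble`: list with `frames` (list of [vs_frame]) and
#'   `index` (data.frame `frame`, `traj`, `time_ps`).
#' @export
read_trajectory <- function(topology, coordinates = topology, stride = 1,
                            dt_ps = 50, traj_id = basename(coordinates)) {
  stopifnot(stride >= 1, stride == round(stride))
  top <- read_structure(topology, multi_model = "first")
  ext <- tolower(tools::file_ext(coordinates))
  if (ext %in% c("pdb", "ent")) {
    pdb <- bio3d::read.pdb(coordinates, multi = TRUE, verbose = FALSE)
    xyz <- pdb$xyz
    if (is.null(nrow(xyz))) xyz <- matrix(xyz, nrow = 1)
  } else if (ext == "dcd") {
    xyz <- bio3d::read.dcd(coordinates, verbose = FALSE)
    if (is.null(nrow(xyz))) xyz <- matrix(xyz, nrow = 1)
  } else stop("unsupported coordinate stream format: .", ext)
  if (ncol(xyz) != 3 * n_atoms(top))
    stop("topology error: topology has ", n_atoms(top), " atoms but stream has ",
         ncol(xyz) / 3)
  keep <- seq(1, nrow(xyz), by = stride)
  frames <- lapply(seq_along(keep), function(k) {
    i <- keep[k]
    f <- top
    m <- matrix(xyz[i, ], ncol = 3, byrow = TRUE)
    f$atoms$x <- m[, 1]; f$atoms$y <- m[, 2]; f$atoms$z <- m[, 3]
    f$time <- (i - 1) * dt_ps
    f$traj <- traj_id
    f
  })
  as_ensemble(frames)
}

#' Bundle frames into a trajectory ensemble
#' @param frames list of [vs_frame] objects.
#' @return a `vs_ensemble` with unique global frame indices.
#' @export
as_ensemble <- function(frames) {
  stopifnot(length(frames) >= 1)
  idx <- data.frame(frame = seq_along(frames),
                    traj = vapply(frames, function(f) as.character(f$traj), ""),
                    time_ps = vapply(frames, function(f) as.numeric(f$time), 0),
                    stringsAsFactors = FALSE)
  structure(list(frames = frames, index = idx), class = "vs_ensemble")
}

#' @export
print.vs_ensemble <- function(x, ...) {
  cat(sprintf("<vs_ensemble> %d frames from %d trajectorie(s)\n",
              length(x$frames), length(unique(x$index$traj))))
  invisible(x)
}

#' @export
length.vs_ensemble <- function(x) length(x$frames)

#' Frame-count bookkeeping for a sampling schedule
#'
#' For `n_traj` trajectories of `length_ns` each with frames saved every
#' `save_ps` inclusive of t = 0, the stored frame count per trajectory is
#' `length_ns * 1000 / save_ps + 1`. The default schedule (16 x 150 ns at
#' 50 ps) gives 48,016 frames and 2.4 us of total simulated time.
#'
#' @param n_traj number of trajectories.
#' @param length_ns trajectory length (ns).
#' @param save_ps saving interval (ps).
#' @return list with `frames_per_traj`, `total_frames`, `total_time_us`.
#' @export
frame_schedule <- function(n_traj = 16, length_ns = 150, save_ps = 50) {
  fpt <- length_ns * 1000 / save_ps + 1
  list(frames_per_traj = fpt,
       total_frames = n_traj * fpt,
       total_time_us = n_traj * length_ns / 1000)
}

#' Split a frame into protein and lipid components
#'
#' Atoms are classified by residue name; solvent and ions are dropped at
#' split time. The two outputs are disjoint and cover all matched atoms.
#'
#' @param frame a [vs_frame].
#' @param protein_residues residue names treated as protein (default: the 20
#'   standard amino acids plus common histidine variants).
#' @param lipid_residues residue names treated as lipid (default `"DPPG"`).
#' @return list with elements `protein` and `lipid` ([vs_frame]s; `lipid` may
#'   have zero atoms, in which case attribute `empty_lipid` is set).
#' @export
split_components <- function(frame, protein_residues = AA3,
                             lipid_residues = c("DPPG", "DPPC", "POPG", "POPC")) {
  if (length(intersect(protein_residues, lipid_residues)) > 0)
    stop("protein and lipid residue name sets overlap")
  a <- frame$atoms
  is_p <- a$resid %in% protein_residues
  is_l <- a$resid %in% lipid_residues
  if (!any(is_p)) stop("no protein atoms")
  prot <- frame; prot$atoms <- a[is_p, , drop = FALSE]
  lip <- frame
  lip$atoms <- a[is_l, , drop = FALSE]
  if (!any(is_l)) attr(lip, "empty_lipid") <- TRUE
  list(protein = prot, lipid = lip)
}

#' Write frames as a (multi-model) PDB file
#'
#' All frames must share atom ordering and counts. Each frame becomes one
#' MODEL block numbered from 1; coordinates round-trip through
#' [read_structure()]/[read_trajectory()] to 0.001 Angstrom (PDB precision).
#'
#' @param frames a [vs_frame], a list of them, or a `vs_ensemble`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(frames, path) {
  if (inherits(frames, "vs_frame")) frames <- list(frames)
  if (inherits(frames, "vs_ensemble")) frames <- frames$frames
  nat <- vapply(frames, n_atoms, 0L)
  if (length(unique(nat)) != 1)
    stop("frames have heterogeneous atom counts")
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(frames)) {
    a <- frames[[m]]$atoms
    writeLines(sprintf("MODEL     %4d", m), con)
    nm <- ifelse(nchar(a$elety) <= 3, paste0(" ", a$elety), a$elety)
    # resName occupies columns 18-21 (left-justified) so that 4-character
    # lipid names like DPPG stay parseable; chain lands on column 22
    writeLines(sprintf("ATOM  %5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                       seq_len(nrow(a)) %% 100000, nm, a$resid,
                       substr(a$chain, 1, 1), a$resno %% 10000,
                       a$x, a$y, a$z, 1, 0, a$element), con)
    writeLines(c("TER", "ENDMDL"), con)
  }
  writeLines("END", con)
  invisible(path)
}
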