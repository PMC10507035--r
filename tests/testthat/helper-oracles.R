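# Independent reference DSSP (mdtraj, simplified 3-state) on a frame.
# Returns a character vector of codes, or NULL when python/mdtraj is broken
# (callers then fail loudly rather than silently passing).
mdtraj_dssp <- function(frame) {
  f <- tempfile(fileext = ".pdb")
  on.exit(unlink(f))
  write_ensemble(frame, f)
  py <- sprintf(
    "import mdtraj as md; t = md.load(%s); print(''.join(md.compute_dssp(t, simplified=True)[0]))",
    deparse(f))
  out <- suppressWarnings(system2("python", c("-c", shQuote(py)), stdout = TRUE,
                                  stderr = FALSE))
  if (length(out) == 0) return(NULL)
  codes <- strsplit(gsub("NA", "C", tail(out, 1)), "")[[1]]
  codes
}

# brute-force per-residue minimum lipid distance (O(N^2) double loop)
brute_min_dist <- function(protein, lipid) {
  P <- protein$atoms
  L <- lipid$atoms
  out <- sapply(sort(unique(P$resno)), function(r) {
    sub <- P[P$resno == r, ]
    best <- Inf
    for (i in seq_len(nrow(sub))) for (j in seq_len(nrow(L))) {
      d <- sqrt((sub$x[i] - L$x[j])^2 + (sub$y[i] - L$y[j])^2 +
                  (sub$z[i] - L$z[j])^2)
      if (d < best) best <- d
    }
    best
  })
  names(out) <- sort(unique(P$resno))
  out
}

# hand-written PDB text for parser fixtures
write_tiny_pdb <- function(path, models = 1) {
  lines <- character(0)
  for (m in seq_len(models)) {
    lines <- c(lines, sprintf("MODEL     %4d", m),
      "ATOM      1  N   ALA A   1       1.234   2.345   3.456  1.00  0.00           N",
      "ATOM      2  CA  ALA A   1       2.468   3.579   4.690  1.00  0.00           C",
      sprintf("ATOM      3  C   ALA A   1       3.702%8.3f   5.924  1.00  0.00           C",
              4.813 + (m - 1)),
      "TER", "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}

# small oriented-helix library plus a noiseless experiment from one member
tiny_library <- function(n = 12, nres = 10, seed = 42) {
  with_seed_test(seed, {
    frames <- lapply(seq_len(n), function(k)
      orient_structure(build_ideal_helix(nres),
                       tilt = runif(1, 0, 180), twist = runif(1, 0, 360)))
    as_ensemble(frames)
  })
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# vs_experiment built directly from a spectra object (+ optional sd)
as_exp <- function(sp, sd_val = 0) {
  vs_experiment(sp$grid, sp$I, matrix(sd_val, nrow(sp$I), ncol(sp$I)))
}
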