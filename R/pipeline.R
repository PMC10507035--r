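#' Read and validate a run configuration
#'
#' YAML configuration with blocks: `paths` (topology, trajectories,
#' experiment, outdir), `exciton` (arguments of [exciton_params()]; an
#' optional `delta_omega_file` names a two-column text file of unit index and
#' frequency shift), `grid` (from/to/by, n_phi), `selection` (window, pcs),
#' `analysis` (named segments from/to), `seed`.
#'
#' @param path YAML file path.
#' @return validated config list of class `vs_config`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$paths <- cfg$paths %||% list()
  for (p in c("topology", "experiment")) {
    if (!is.null(cfg$paths[[p]]) && !file.exists(cfg$paths[[p]]))
      stop("configured path does not exist: ", cfg$paths[[p]])
  }
  for (tr in cfg$paths$trajectories)
    if (!file.exists(tr)) stop("configured path does not exist: ", tr)
  ex <- cfg$exciton %||% list()
  if (!is.null(ex$delta_omega_file)) {
    tb <- read.table(ex$delta_omega_file, header = FALSE)
    dom <- numeric(max(tb[[1]]))
    dom[tb[[1]]] <- tb[[2]]
    ex$delta_omega <- dom
    ex$delta_omega_file <- NULL
  }
  cfg$exciton <- do.call(exciton_params, ex)
  g <- cfg$grid %||% list()
  cfg$grid_values <- frequency_grid(g$from %||% 1600, g$to %||% 1700,
                                    g$by %||% 1)
  cfg$n_phi <- g$n_phi %||% 36
  s <- cfg$selection %||% list()
  cfg$window <- c(s$window_from %||% 1600, s$window_to %||% 1700)
  cfg$pcs <- s$pcs %||% PCS
  an <- cfg$analysis %||% list()
  cfg$segments <- if (length(an$segments) > 0) {
    lapply(an$segments, function(sg) sg$from:sg$to)
  } else alpha_synuclein_segments()
  cfg$seed <- cfg$seed %||% 1
  class(cfg) <- "vs_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full calc-rank-select-analyze pipeline
#'
#' Reads the trajectory library (all trajectories pooled) and the
#' experimental dataset, scores every frame, selects the std-matched
#' ensemble, characterizes it, and writes the run artifacts into the output
#' directory: `scores.tsv`, `ensemble.json`, `ensemble.pdb`, `profiles.tsv`,
#' `run.log`, `manifest.json` (config hash, input checksums, package
#' version, skip counts). Deterministic for fixed config and inputs.
#'
#' @param config a `vs_config` from [read_config()], or a path to one.
#' @param outdir output directory (default from the config).
#' @return list with `ranking`, `selected`, `helicity`, `dist`, `outdir`,
#'   invisibly.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config)) {
    config_path <- config
    config <- read_config(config)
  } else config_path <- NULL
  outdir <- outdir %||% config$paths$outdir %||% stop("no output directory configured")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(outdir, "run.log")
  logi <- function(...) cat(sprintf(...), "\n", sep = "", file = logf, append = TRUE)
  cat("", file = logf)

  trajs <- config$paths$trajectories %||% config$paths$topology
  ens <- NULL
  for (tr in trajs) {
    e <- read_trajectory(config$paths$topology, tr)
    ens <- if (is.null(ens)) e$frames else c(ens, e$frames)
    logi("read %d frames from %s", length(e$frames), tr)
  }
  library_ens <- as_ensemble(ens)
  exp <- read_spectra(config$paths$experiment)
  if (!inherits(exp, "vs_experiment"))
    stop("experiment file lacks a std column")
  logi("library: %d frames; experiment: %d grid points",
       length(library_ens$frames), length(exp$grid))

  ranking <- rank_frames(library_ens, exp, config$exciton, config$grid_values,
                         config$window, config$pcs, config$n_phi,
                         on_error = "skip")
  mask <- score_mask(exp$grid, config$window)
  sigma_exp <- mean(exp$sd[mask, config$pcs])
  sel <- select_ensemble(ranking, sigma_exp)
  logi("selected %d frames; RSS threshold %.6g; calc std %.6g vs exp std %.6g",
       sel$size, sel$threshold, sel$pooled_calc_std, sel$pooled_exp_std)

  write.table(ranking$scores, file.path(outdir, "scores.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  members <- library_ens$frames[sel$members]
  prot <- lapply(members, function(f) split_components(f)$protein)
  write_ensemble(prot, file.path(outdir, "ensemble.pdb"))
  hel <- helicity_profile(prot)
  has_lipid <- tryCatch(n_atoms(split_components(members[[1]])$lipid) > 0,
                        error = function(e) FALSE)
  dst <- if (has_lipid) min_distance_profile(members) else NULL
  write_profile(hel, dst, file.path(outdir, "profiles.tsv"))
  seg <- segment_summary(hel, config$segments)

  jsonlite::write_json(
    list(members = sel$members, threshold = sel$threshold,
         pooled_calc_std = sel$pooled_calc_std,
         pooled_exp_std = sel$pooled_exp_std, size = sel$size,
         grid = sel$grid,
         mean = as.data.frame(sel$mean), lo = as.data.frame(sel$lo),
         hi = as.data.frame(sel$hi),
         segments = seg),
    file.path(outdir, "ensemble.json"), auto_unbox = TRUE, digits = NA)

  inputs <- c(config$paths$topology, trajs, config$paths$experiment)
  manifest <- list(
    package = "viscaselect",
    version = as.character(utils::packageVersion("viscaselect")),
    config = config_path,
    config_md5 = if (!is.null(config_path)) unname(tools::md5sum(config_path)) else NA,
    input_md5 = as.list(tools::md5sum(unique(inputs))),
    window = config$window, pcs = config$pcs, n_phi = config$n_phi,
    seed = config$seed, n_frames = length(library_ens$frames),
    n_skipped = ranking$n_skipped, ensemble_size = sel$size)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(ranking = ranking, selected = sel, helicity = hel,
                 dist = dst, outdir = outdir))
}
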