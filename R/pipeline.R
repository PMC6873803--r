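#' Canonical simulation presets for the three diffusion regimes
#'
#' Paired simulation and optics configurations representing free,
#' domain-confined and meshwork-hop diffusion under one fixed imaging
#' geometry (0.24 um pixel, 0.24 um PSF 1/e^2 radius, 3 ms exposure,
#' 16 x 16 px ROI). These are the package's reference conditions for
#' end-to-end runs: the three regimes produce diffusion-law intercepts of
#' the corresponding sign.
#'
#' @param mode \code{"free"}, \code{"domain"} or \code{"hop"}.
#' @param seed integer master seed; expanded with [stage_seed()] into
#'   simulation and camera seeds.
#' @param n_frames frames to render; free runs default to 10000 frames (30 s
#'   of data), the hindered regimes to 20000, whose slower correlation
#'   decays need the longer lag range.
#' @param roi ROI in pixels (default 16 x 16).
#' @return list with elements \code{sim} ([sim_config()]) and \code{optics}
#'   ([optics_config()]).
#' @export
regime_preset <- function(mode = c("free", "domain", "hop"), seed = 1,
                          n_frames = NULL, roi = c(16L, 16L)) {
  mode <- match.arg(mode)
  n_frames <- n_frames %||% if (mode == "free") 10000L else 20000L
  sim <- sim_config(mode = mode, box_side = 6, n_particles = 60,
                    D_out = 0.5, dt = 0.003,
                    n_steps = as.integer(n_frames),
                    seed = stage_seed(seed, 1))
  optics <- optics_config(roi = roi, n_frames = n_frames,
                          seed = stage_seed(seed, 2))
  list(sim = sim, optics = optics)
}

#' Run the imaging-FCS / conformer pipeline
#'
#' Orchestrates the stages simulate -> correlate & fit -> diffusion law (or
#' the conformer RMSD analysis) as one reproducible, configured run. All
#' intermediate tables are written as CSV, stacks as TIFF + JSON sidecar,
#' and the final report as JSON plus a human-readable summary.
#'
#' @param config a named list, or the path of a JSON file holding one.
#'   Required field \code{subcommand}: one of \code{"simulate"},
#'   \code{"imfcs"}, \code{"difflaw"}, \code{"conformers"}, \code{"demo"}.
#'   Stage parameters live in a section of the same name (see the package
#'   vignette for the schema).
#' @param out output directory (created if missing).
#' @param seed integer master seed recorded in the report and expanded
#'   deterministically into per-stage seeds.
#' @return a \code{run_report} (invisibly written to
#'   \code{<out>/report.json}).
#' @export
#' @examples
#' \donttest{
#' rep <- run_pipeline(list(subcommand = "demo",
#'                          demo = list(n_frames = 3000)),
#'                     out = tempfile("demo"), seed = 1)
#' rep$stages$difflaw$mode
#' }
run_pipeline <- function(config, out, seed = 1) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  sub <- config$subcommand %||%
    stop("config must name a 'subcommand'", call. = FALSE)
  sub <- match.arg(sub, c("simulate", "imfcs", "difflaw", "conformers",
                          "demo"))
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out, 2) != 0)
    stop("output directory not writable: ", out, call. = FALSE)
  seed <- chk_count(seed, "seed", min = 0L)

  artifacts <- switch(sub,
    simulate = list(stage_simulate(config$simulate %||% list(), out, seed)),
    imfcs = list(stage_imfcs(config$imfcs %||% list(), out)),
    difflaw = list(stage_difflaw(config$difflaw %||% list(), out)),
    conformers = list(stage_conformers(config$conformers %||% list(), out)),
    demo = {
      d <- config$demo %||% list()
      preset <- regime_preset(d$mode %||% "free", seed = seed,
                              n_frames = d$n_frames %||% 10000)
      a1 <- stage_simulate(list(sim = preset$sim, optics = preset$optics),
                           out, seed)
      a2 <- stage_difflaw(list(stacks = a1$stack,
                               binnings = d$binnings %||% 1:5), out)
      list(a1, a2)
    })
  report <- make_report(artifacts, config = config, seed = seed, out = out)
  invisible(report)
}

stage_simulate <- function(cfg, out, seed) {
  sim <- if (inherits(cfg$sim, "sim_config")) cfg$sim else
    do.call(sim_config, c(cfg$sim %||% list(),
                          if (is.null((cfg$sim %||% list())$seed))
                            list(seed = stage_seed(seed, 1))))
  optics <- if (inherits(cfg$optics, "optics_config")) cfg$optics else
    do.call(optics_config, c(cfg$optics %||% list(),
                             if (is.null((cfg$optics %||% list())$seed))
                               list(seed = stage_seed(seed, 2))))
  traj <- simulate_trajectories(sim)
  stack <- render_stack(traj, optics)
  path <- file.path(out, "stack.tif")
  write_stack(stack, path)
  list(stage = "simulate", stack = path, config_hash = stack$config_hash,
       summary = list(mode = sim$mode, n_particles = sim$n_particles,
                      n_frames = optics$n_frames,
                      mean_counts = mean(stack$counts)))
}

stage_imfcs <- function(cfg, out) {
  stack <- load_stack_cfg(cfg)
  binnings <- as.integer(cfg$binnings %||% 1:5)
  fit_rows <- list()
  for (nb in binnings) {
    bs <- bin_pixels(stack, nb)
    n <- nrow(bs$traces)
    lags <- multitau_lags(n)
    mean_G <- NULL
    for (j in seq_len(ncol(bs$traces))) {
      res <- tryCatch(suppressWarnings({
        crv <- compute_acf(bs$traces[, j], frame_time = bs$frame_time,
                           lags = lags)
        ft <- fit_acf(crv, a = bs$a_bin, omega0 = bs$omega0,
                      triplet = isTRUE(cfg$triplet))
        list(crv = crv, ft = ft)
      }), error = function(e) NULL)
      if (is.null(res)) next
      p <- coef(res$ft)
      fit_rows[[length(fit_rows) + 1L]] <- data.frame(
        n_bin = nb, pixel = j, a_bin_um = bs$a_bin,
        A_eff_um2 = res$ft$A_eff, D = p[["D"]], N = p[["N"]],
        F_t = if (isTRUE(cfg$triplet)) p[["F_t"]] else 0,
        t_f = if (isTRUE(cfg$triplet)) p[["t_f"]] else NA_real_,
        G_inf = p[["G_inf"]], tau_D_s = res$ft$tau_D,
        chi2 = res$ft$chi2_reduced, converged = res$ft$converged)
      mean_G <- if (is.null(mean_G)) res$crv$G else mean_G + res$crv$G
    }
    if (!is.null(mean_G)) {
      acf_tab <- data.frame(lag_s = lags * stack$exposure,
                            G = mean_G / ncol(bs$traces),
                            var_G = NA_real_)
      write.csv(acf_tab, file.path(out, sprintf("acf_bin%d.csv", nb)),
                row.names = FALSE)
    }
  }
  fits <- do.call(rbind, fit_rows)
  write.csv(fits, file.path(out, "fits.csv"), row.names = FALSE)
  list(stage = "imfcs", fits = file.path(out, "fits.csv"),
       config_hash = stack$config_hash,
       summary = list(n_fits = nrow(fits),
                      n_converged = sum(fits$converged),
                      D_median = median(fits$D[fits$converged])))
}

stage_difflaw <- function(cfg, out) {
  paths <- cfg$stacks %||% stop("difflaw stage needs 'stacks'",
                                call. = FALSE)
  paths <- unlist(lapply(paths, function(p)
    if (file.exists(p)) p else Sys.glob(p)))
  if (length(paths) == 0)
    stop("input error: no stack found", call. = FALSE)
  binnings <- as.integer(cfg$binnings %||% 1:5)
  fits <- list()
  hashes <- character(0)
  for (i in seq_along(paths)) {
    stack <- read_stack(paths[i])
    hashes <- c(hashes, stack$config_hash)
    pts <- build_diffusion_law(stack, binnings = binnings,
                               triplet = isTRUE(cfg$triplet))
    fit <- fit_diffusion_law(pts, threshold = cfg$threshold %||% 0.2)
    fits[[i]] <- fit
    tag <- if (length(paths) > 1) sprintf("_%d", i) else ""
    write.csv(as.data.frame(pts),
              file.path(out, sprintf("diffusion_law%s.csv", tag)),
              row.names = FALSE)
    jsonlite::write_json(summary(fit),
                         file.path(out, sprintf("difflaw_fit%s.json", tag)),
                         auto_unbox = TRUE, digits = NA)
  }
  agg <- aggregate_replicates(fits, label = cfg$label %||% "")
  write.csv(data.frame(condition = agg$condition_label,
                       tau_0_mean_s = agg$tau_0_mean,
                       tau_0_sd_s = agg$tau_0_sd, n = agg$n),
            file.path(out, "replicates.csv"), row.names = FALSE)
  f1 <- fits[[1]]
  list(stage = "difflaw",
       config_hash = if (length(unique(hashes[!is.na(hashes)])) == 1)
         hashes[1] else NA_character_,
       summary = list(tau_0_s = f1$tau_0, D_eff = f1$D_eff, r2 = f1$r2,
                      mode = f1$mode, n_replicates = length(fits),
                      tau_0_mean_s = agg$tau_0_mean,
                      tau_0_sd_s = agg$tau_0_sd),
       tau_0_s = f1$tau_0, D_eff = f1$D_eff, mode = f1$mode)
}

stage_conformers <- function(cfg, out) {
  code <- cfg$ligand %||% "PLM"
  paths <- if (!is.null(cfg$pdb_dir))
    list.files(cfg$pdb_dir, pattern = "\\.(pdb|ent)$", full.names = TRUE)
  else unlist(cfg$pdb_files)
  if (length(paths) == 0)
    stop("input error: no PDB files found", call. = FALSE)
  conformers <- read_ligands(paths, code)
  if (length(conformers) == 0)
    stop("no ", code, " residues found in the inputs", call. = FALSE)
  ref_cfg <- cfg$reference %||% stop("conformers stage needs 'reference'",
                                     call. = FALSE)
  refs <- parse_ligands(readLines(ref_cfg$file, warn = FALSE),
                        ref_cfg$code %||% code,
                        source_id = basename(ref_cfg$file))
  if (!is.null(ref_cfg$chain))
    refs <- Filter(function(x) x$chain == ref_cfg$chain, refs)
  if (!is.null(ref_cfg$res_seq))
    refs <- Filter(function(x) x$res_seq == ref_cfg$res_seq, refs)
  if (length(refs) == 0)
    stop("reference residue not found in ", ref_cfg$file, call. = FALSE)
  reference <- refs[[1]]
  dens <- rmsd_density(conformers, reference,
                       n_bins = cfg$bins %||% 20,
                       bin_range = cfg$bin_range)
  closest <- closest_conformer(conformers, reference)
  write.csv(dens$rmsd, file.path(out, "rmsd.csv"), row.names = FALSE)
  write.csv(data.frame(bin_lo_A = head(dens$bin_edges, -1),
                       bin_hi_A = tail(dens$bin_edges, -1),
                       frequency = dens$frequencies),
            file.path(out, "density.csv"), row.names = FALSE)
  jsonlite::write_json(list(source_id = closest$source_id,
                            rmsd_A = closest$rmsd),
                       file.path(out, "closest.json"), auto_unbox = TRUE,
                       digits = NA)
  list(stage = "conformers", config_hash = NA_character_,
       summary = list(n_conformers = length(conformers),
                      n_excluded = dens$n_excluded,
                      closest = closest$source_id,
                      closest_rmsd_A = closest$rmsd))
}

load_stack_cfg <- function(cfg) {
  path <- cfg$stack %||% stop("stage needs a 'stack' path", call. = FALSE)
  if (!file.exists(path))
    stop("input error: stack not found: ", path, call. = FALSE)
  read_stack(path, a = cfg$pixel_size, omega0 = cfg$psf_e2_radius,
             exposure = cfg$exposure)
}

#' Assemble a run report from stage artifacts
#'
#' Collects per-stage summaries into a JSON report plus a human-readable
#' text summary. Stage config hashes must agree where present.
#'
#' @param artifacts list of stage artifact lists (>= 1).
#' @param config the run configuration (hashed into the report).
#' @param seed master seed of the run.
#' @param out optional directory; when given, \code{report.json} and
#'   \code{report.txt} are written there.
#' @return an object of class \code{run_report}.
#' @export
make_report <- function(artifacts, config = list(), seed = NA_integer_,
                        out = NULL) {
  if (length(artifacts) < 1)
    stop("no stage artifacts to report", call. = FALSE)
  hashes <- vapply(artifacts, function(a) a$config_hash %||% NA_character_,
                   character(1))
  hset <- unique(hashes[!is.na(hashes)])
  if (length(hset) > 1)
    stop("inconsistent stage metadata: config hashes differ", call. = FALSE)
  stages <- setNames(lapply(artifacts, function(a) a$summary),
                     vapply(artifacts, `[[`, character(1), "stage"))
  report <- structure(list(
    config_hash = config_hash(config),
    stage_config_hash = if (length(hset)) hset else NA_character_,
    software_version = as.character(packageVersion("rafttrace")),
    seed = seed, stages = stages, warnings = character(0),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "run_report")
  if (!is.null(out)) {
    jsonlite::write_json(unclass(report), file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    txt <- c(sprintf("rafttrace %s run report (seed %s)",
                     report$software_version, seed),
             vapply(names(stages), function(nm) sprintf(
               "  %s: %s", nm,
               paste(names(stages[[nm]]),
                     vapply(stages[[nm]], function(v)
                       paste(format(v), collapse = ","), character(1)),
                     sep = "=", collapse = ", ")), character(1)))
    writeLines(txt, file.path(out, "report.txt"))
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("rafttrace run report (version %s, seed %s)\n",
              x$software_version, x$seed))
  for (nm in names(x$stages)) {
    s <- x$stages[[nm]]
    cat(sprintf("  %s: %s\n", nm,
                paste(names(s), vapply(s, function(v)
                  paste(format(v), collapse = ","), character(1)),
                  sep = "=", collapse = ", ")))
  }
  invisible(x)
}
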