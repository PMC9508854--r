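#' Experiment configuration
#'
#' Declarative description of an end-to-end unfolding experiment: toy-model
#' parameters, the umbrella window layout, the pulling forces to analyse,
#' sampling lengths and seeds.  The default window layout follows the
#' standard protocol for this analysis (q_wrap centers 0.45-0.90 step 0.15
#' with spring 50 kcal/mol; d_stack centers 10-30 nm step 5 with spring
#' 0.05 kcal/(mol nm^2)); the default extension windows and step counts are
#' desk-scale so a full run completes in minutes.
#'
#' @param n_nucleosomes chain length.
#' @param model a [toy_energy_model()] (or a named list of overrides).
#' @param forces_pN pulling forces to analyse.
#' @param ee_centers umbrella centers for the per-nucleosome z-extension
#'   windows used to build the 0 pN profile, nm.
#' @param ee_spring spring constant for those windows, kcal/(mol nm^2).
#' @param qwrap_centers,qwrap_spring q_wrap umbrella layout (kcal/mol).
#' @param dstack_centers,dstack_spring d_stack umbrella layout
#'   (kcal/(mol nm^2)).
#' @param steps Monte Carlo sweeps per window.
#' @param stride snapshot stride.
#' @param seed base seed; window w runs with `seed + w`.
#' @param compare_unwrap also run the paired 4 pN comparison with unwrapping
#'   prohibited and report both alpha profiles.
#' @param outdir output directory.
#' @export
experiment_config <- function(n_nucleosomes = 12,
                              model = toy_energy_model(),
                              forces_pN = c(0, 1, 2, 3, 4),
                              ee_centers = seq(2, 14, by = 2),
                              ee_spring = 2,
                              qwrap_centers = seq(0.45, 0.90, by = 0.15),
                              qwrap_spring = 50,
                              dstack_centers = seq(10, 30, by = 5),
                              dstack_spring = 0.05,
                              steps = 20000, stride = 20, seed = 1L,
                              compare_unwrap = FALSE, outdir = tempfile("exp")) {
  if (!inherits(model, "toy_energy_model")) model <- do.call(toy_energy_model, model)
  if (any(forces_pN < 0)) stop("forces must be non-negative")
  if (!length(ee_centers)) stop("window layout must be non-empty")
  structure(list(n_nucleosomes = n_nucleosomes, model = model,
                 forces_pN = forces_pN, ee_centers = ee_centers,
                 ee_spring = ee_spring, qwrap_centers = qwrap_centers,
                 qwrap_spring = qwrap_spring, dstack_centers = dstack_centers,
                 dstack_spring = dstack_spring, steps = as.integer(steps),
                 stride = as.integer(stride), seed = as.integer(seed),
                 compare_unwrap = isTRUE(compare_unwrap), outdir = outdir),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML
#'
#' Top-level keys mirror the arguments of [experiment_config()]; the `model`
#' key holds [toy_energy_model()] overrides.
#'
#' @param path YAML file path.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$model)) y$model <- do.call(toy_energy_model, y$model)
  do.call(experiment_config, y)
}

#' Run the end-to-end unfolding experiment
#'
#' Pipeline: umbrella windows on the per-nucleosome z extension at 0 pN
#' (started from the two-start fiber) are combined by [wham()] into the
#' zero-force free-energy profile with three-block errors; the profile is
#' tilted to every requested force to predict mean extensions
#' (force-extension table); direct constant-force runs at each force supply
#' the alpha free-energy profile and representative structures near the
#' mean extension.  All artifacts (profile TSVs, force-extension TSV, alpha
#' profiles, representative PDBs) land in `config$outdir` together with a
#' `manifest.json` recording seeds, file hashes and the package version;
#' re-running the same configuration is bit-identical.
#'
#' @param config an [experiment_config()].
#' @param quiet suppress progress messages.
#' @return the manifest, invisibly; its `summary` element holds the
#'   force-extension table and alpha minima.
#' @export
run_experiment <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  n <- config$n_nucleosomes
  start <- generate_fiber(n)
  stage <- "umbrella"
  res <- tryCatch({
    say("stage umbrella: ", length(config$ee_centers), " windows")
    windows <- lapply(seq_along(config$ee_centers), function(w) {
      sample_window(config$model, start,
                    umbrella_bias("ee_z", config$ee_centers[w], config$ee_spring),
                    steps = config$steps, seed = config$seed + w,
                    stride = config$stride)
    })
    stage <<- "wham"
    gs <- grid_from_windows(windows)
    prof <- wham(windows, gs)
    prof$err <- block_errors(windows, function(wb) wham(wb, gs)$F)$err
    write_profile_tsv(prof, file.path(config$outdir, "F_ee_0pN.tsv"))

    stage <<- "force-extension"
    fx <- data.frame(force_pN = config$forces_pN)
    fx$mean_ee_per_nuc <- vapply(config$forces_pN, function(f)
      mean_extension(prof, f, n_scale = n), numeric(1))
    fx$err <- vapply(config$forces_pN, function(f)
      sd(block_errors(windows, function(wb)
        mean_extension(wham(wb, gs), f, n_scale = n))$blocks), numeric(1))
    utils::write.table(fx, file.path(config$outdir, "force_extension.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)

    stage <<- "constant-force"
    alpha_min <- numeric(0)
    rep_files <- character(0)
    for (f in config$forces_pN) {
      say("stage constant-force: ", f, " pN")
      traj <- run_mc(config$model, start, list(force_bias(f)),
                     steps = config$steps, seed = config$seed + 1000L + round(f),
                     stride = config$stride)
      keep <- seq_along(traj$configs) > length(traj$configs) %/% 5
      configs <- traj$configs[keep]
      av <- vapply(configs, compute_cv, numeric(1), name = "alpha")
      ap <- profile_from_samples(av)
      write_profile_tsv(ap, file.path(config$outdir,
                                      sprintf("F_alpha_%gpN.tsv", f)))
      alpha_min[as.character(f)] <- ap$grid[which.min(ap$F)]
      target <- fx$mean_ee_per_nuc[match(f, fx$force_pN)]
      reps <- select_representatives(configs, target_ee = target,
                                     tolerance = max(1, 2 * fx$err[match(f, fx$force_pN)]),
                                     cutoff = 3, n_rep = 1)
      if (length(reps)) {
        pf <- file.path(config$outdir, sprintf("rep_%gpN.pdb", f))
        write_config_pdb(reps[[1]]$config, pf)
        rep_files <- c(rep_files, pf)
      }
    }

    unwrap_cmp <- NULL
    if (config$compare_unwrap) {
      stage <<- "unwrap-comparison"
      m2 <- config$model; m2$allow_unwrap <- FALSE
      traj <- run_mc(m2, start, list(force_bias(4)), steps = config$steps,
                     seed = config$seed + 2000L, stride = config$stride)
      keep <- seq_along(traj$configs) > length(traj$configs) %/% 5
      av <- vapply(traj$configs[keep], compute_cv, numeric(1), name = "alpha")
      ap <- profile_from_samples(av)
      write_profile_tsv(ap, file.path(config$outdir, "F_alpha_4pN_nounwrap.tsv"))
      unwrap_cmp <- list(alpha_min_unwrap = unname(alpha_min["4"]),
                         alpha_min_rigid = ap$grid[which.min(ap$F)])
    }
    list(fx = fx, alpha_min = alpha_min, unwrap_cmp = unwrap_cmp)
  }, error = function(e)
    stop("experiment failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE))

  files <- sort(list.files(config$outdir, full.names = TRUE,
                           pattern = "\\.(tsv|pdb)$"))
  manifest <- list(
    package = as.character(utils::packageVersion("chromoclutch")),
    seed = config$seed, steps = config$steps,
    n_nucleosomes = config$n_nucleosomes,
    forces_pN = config$forces_pN,
    files = setNames(as.list(unname(tools::md5sum(files))), basename(files)),
    summary = list(force_extension = res$fx, alpha_min = as.list(res$alpha_min),
                   unwrap_comparison = res$unwrap_cmp))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(manifest)
}
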