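#!/usr/bin/env Rscript

# Thin command-line wrapper over the chromoclutch package.
#
#   Rscript scripts/chromoclutch.R simulate --config sim.yaml --out windows/
#   Rscript scripts/chromoclutch.R cv       --traj traj.xyz --cv d_stack,alpha --out cv.tsv
#   Rscript scripts/chromoclutch.R wham     --windows windows/ --out F.tsv
#   Rscript scripts/chromoclutch.R fx       --profile F.tsv --forces 0:6:0.5 --n 12 --out fx.tsv
#   Rscript scripts/chromoclutch.R cluster  --traj traj.xyz --target-ee 14.5 --tol 0.5 --out reps/
#   Rscript scripts/chromoclutch.R report   --config exp.yaml
#
# The simulate config (YAML) mirrors experiment_config(); windows are written
# as extended-XYZ trajectories plus JSON metadata.

suppressMessages({
  library(optparse)
  library(chromoclutch)
})

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1) stop("usage: chromoclutch.R <simulate|cv|wham|fx|cluster|report> ...")
cmd <- args[1]
rest <- args[-1]

opt <- function(spec) parse_args(OptionParser(option_list = spec), args = rest)

read_windows_dir <- function(dir) {
  metas <- sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))
  lapply(metas, function(mp) {
    meta <- read_window_meta(mp)
    traj <- read_xyz_trajectory(sub("\\.json$", ".xyz", mp))
    cv <- vapply(traj$configs, compute_cv, numeric(1), name = meta$cv)
    umbrella_window(umbrella_bias(meta$cv, meta$center, meta$spring_k), cv)
  })
}

if (cmd == "simulate") {
  o <- opt(list(make_option("--config", type = "character"),
                make_option("--out", type = "character", default = "windows")))
  cfg <- read_experiment_config(o$config)
  dir.create(o$out, showWarnings = FALSE, recursive = TRUE)
  start <- generate_fiber(cfg$n_nucleosomes)
  for (w in seq_along(cfg$ee_centers)) {
    bias <- umbrella_bias("ee_z", cfg$ee_centers[w], cfg$ee_spring)
    traj <- run_mc(cfg$model, start, list(bias), steps = cfg$steps,
                   seed = cfg$seed + w, stride = cfg$stride)
    stem <- file.path(o$out, sprintf("window_%02d", w))
    write_xyz_trajectory(traj, paste0(stem, ".xyz"))
    write_window_meta(list(cv = "ee_z", center = cfg$ee_centers[w],
                           spring_k = cfg$ee_spring, force_pN = 0,
                           seed = cfg$seed + w), paste0(stem, ".json"))
    message("wrote ", stem, ".{xyz,json}")
  }
} else if (cmd == "cv") {
  o <- opt(list(make_option("--traj", type = "character"),
                make_option("--cv", type = "character", default = "d_stack,q_wrap,alpha,ee_z"),
                make_option("--out", type = "character", default = "cv.tsv")))
  traj <- read_xyz_trajectory(o$traj)
  tab <- cv_table(traj, strsplit(o$cv, ",")[[1]])
  write.table(tab, o$out, sep = "\t", row.names = FALSE, quote = FALSE)
  message("wrote ", o$out)
} else if (cmd == "wham") {
  o <- opt(list(make_option("--windows", type = "character", default = "windows"),
                make_option("--out", type = "character", default = "F.tsv")))
  wins <- read_windows_dir(o$windows)
  gs <- grid_from_windows(wins)
  prof <- wham(wins, gs)
  prof$err <- block_errors(wins, function(wb) wham(wb, gs)$F)$err
  write_profile_tsv(prof, o$out)
  message("wrote ", o$out)
} else if (cmd == "fx") {
  o <- opt(list(make_option("--profile", type = "character"),
                make_option("--forces", type = "character", default = "0:6:0.5"),
                make_option("--n", type = "integer", default = 12L),
                make_option("--out", type = "character", default = "fx.tsv")))
  tab <- read.delim(o$profile)
  prof <- structure(list(grid = tab$x, F = tab$F, err = tab$err, dims = 1,
                         overlap_ok = TRUE, n_samples = NA,
                         temperature_K = 300), class = "free_energy_profile")
  fr <- as.numeric(strsplit(o$forces, ":")[[1]])
  forces <- seq(fr[1], fr[2], by = if (length(fr) > 2) fr[3] else 1)
  fx <- data.frame(force_pN = forces,
                   mean_ext = vapply(forces, function(f)
                     mean_extension(prof, f, n_scale = o$n), numeric(1)))
  write.table(fx, o$out, sep = "\t", row.names = FALSE, quote = FALSE)
  message("wrote ", o$out)
} else if (cmd == "cluster") {
  o <- opt(list(make_option("--traj", type = "character"),
                make_option("--target-ee", type = "double", dest = "target_ee"),
                make_option("--tol", type = "double", default = 0.5),
                make_option("--cutoff", type = "double", default = 3),
                make_option("--n-rep", type = "integer", default = 1L, dest = "n_rep"),
                make_option("--out", type = "character", default = "reps")))
  traj <- read_xyz_trajectory(o$traj)
  reps <- select_representatives(traj$configs, o$target_ee, o$tol, o$cutoff,
                                 o$n_rep)
  dir.create(o$out, showWarnings = FALSE, recursive = TRUE)
  summary <- lapply(seq_along(reps), function(i) {
    pf <- file.path(o$out, sprintf("rep_%02d.pdb", i))
    write_config_pdb(reps[[i]]$config, pf)
    list(file = basename(pf), trajectory_index = reps[[i]]$index,
         cluster_size = reps[[i]]$cluster_size)
  })
  jsonlite::write_json(summary, file.path(o$out, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  message("wrote ", length(reps), " representative(s) to ", o$out)
} else if (cmd == "report") {
  o <- opt(list(make_option("--config", type = "character")))
  man <- run_experiment(read_experiment_config(o$config))
  message("experiment complete; outputs hashed in manifest.json")
} else {
  stop("unknown subcommand: ", cmd)
}
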