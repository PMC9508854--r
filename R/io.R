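FRAME_COLS <- c("chain", "index", "cx", "cy", "cz", "ax", "ay", "az",
                "bx", "by", "bz", "nx", "ny", "nz", "wrap")

#' Read / write a nucleosome frame table
#'
#' The frame-table CSV is the canonical interchange format: one row per
#' nucleosome with columns `chain, index, cx, cy, cz, ax, ay, az, bx, by, bz,
#' nx, ny, nz, wrap`.  Frames whose axes deviate from orthonormality by less
#' than 1e-6 are re-orthonormalized (via SVD projection onto the nearest
#' rotation); larger deviations are an error, as are duplicate
#' `(chain, index)` rows and wrap fractions outside `[0.5, 1]`.
#'
#' @param path file path.
#' @return `read_frames` returns a `chromatin_config`; `write_frames` returns
#'   `path` invisibly.  A write/read round trip reproduces all fields to
#'   better than 1e-9.
#' @export
read_frames <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  missing <- setdiff(FRAME_COLS, names(df))
  if (length(missing))
    stop("frame table is missing columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(df[, c("chain", "index")]))
    stop("duplicate (chain, index) rows in frame table")
  if (any(df$wrap < WRAP_MIN - 1e-12 | df$wrap > 1 + 1e-12))
    stop("wrap fraction out of range [", WRAP_MIN, ", 1]")
  df <- df[order(df$chain, df$index), ]
  chains <- lapply(split(df, df$chain), function(d) {
    if (!identical(as.integer(d$index), seq_len(nrow(d)) - 1L))
      stop("nucleosome indices must be consecutive from 0")
    aa <- as.matrix(d[, c("ax", "ay", "az")])
    bb <- as.matrix(d[, c("bx", "by", "bz")])
    nn <- as.matrix(d[, c("nx", "ny", "nz")])
    for (i in seq_len(nrow(d))) {
      R <- rbind(aa[i, ], bb[i, ], nn[i, ])
      dev <- max(abs(R %*% t(R) - diag(3)))
      if (dev >= 1e-6)
        stop("non-orthonormal frame beyond tolerance at chain ", d$chain[i],
             " index ", d$index[i], " (deviation ", signif(dev, 3), ")")
      if (dev > 1e-12) {           # re-orthonormalize: nearest rotation
        sv <- svd(R)
        R <- sv$u %*% t(sv$v)
        aa[i, ] <- R[1, ]; bb[i, ] <- R[2, ]; nn[i, ] <- R[3, ]
      }
    }
    list(centers = as.matrix(d[, c("cx", "cy", "cz")]),
         axis_a = aa, axis_b = bb, normal = nn, wrap = d$wrap)
  })
  names(chains) <- NULL
  chromatin_config(chains)
}

#' @rdname read_frames
#' @param config a `chromatin_config`.
#' @export
write_frames <- function(config, path) {
  rows <- lapply(seq_along(config$chains), function(ci) {
    ch <- config$chains[[ci]]
    data.frame(chain = ci, index = seq_len(nrow(ch$centers)) - 1L,
               cx = ch$centers[, 1], cy = ch$centers[, 2], cz = ch$centers[, 3],
               ax = ch$axis_a[, 1], ay = ch$axis_a[, 2], az = ch$axis_a[, 3],
               bx = ch$axis_b[, 1], by = ch$axis_b[, 2], bz = ch$axis_b[, 3],
               nx = ch$normal[, 1], ny = ch$normal[, 2], nz = ch$normal[, 3],
               wrap = ch$wrap)
  })
  df <- do.call(rbind, rows)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.15g", x))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read an extended-XYZ trajectory of nucleosome centers
#'
#' One pseudo-atom (`NUC`) per nucleosome; the comment line carries the step
#' number and pulling force, and per-atom columns store position, wrap
#' fraction and chain id.  Frame axes are not serialized in this format (use
#' the frame-table CSV for full fidelity); on reading, identity frames are
#' attached.
#'
#' @param traj a `chromatin_trajectory` (see [run_mc()]).
#' @param path file path.
#' @export
write_xyz_trajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  force_pN <- traj$metadata$force_pN %||% 0
  steps <- traj$metadata$steps %||% seq_along(traj$configs)
  for (k in seq_along(traj$configs)) {
    cfg <- traj$configs[[k]]
    n_tot <- sum(vapply(cfg$chains, function(ch) nrow(ch$centers), integer(1)))
    writeLines(as.character(n_tot), con)
    writeLines(sprintf(
      "step=%d force_pN=%.6g Properties=species:S:1:pos:R:3:wrap:R:1:chain:I:1",
      steps[k], force_pN), con)
    for (ci in seq_along(cfg$chains)) {
      ch <- cfg$chains[[ci]]
      writeLines(sprintf("NUC %.8f %.8f %.8f %.6f %d",
                         ch$centers[, 1], ch$centers[, 2], ch$centers[, 3],
                         ch$wrap, ci), con)
    }
  }
  invisible(path)
}

#' @rdname write_xyz_trajectory
#' @export
read_xyz_trajectory <- function(path) {
  lines <- readLines(path)
  configs <- list(); steps <- integer(0); force_pN <- 0
  i <- 1
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    comment <- lines[i + 1]
    steps <- c(steps, as.integer(sub(".*step=([0-9]+).*", "\\1", comment)))
    force_pN <- as.numeric(sub(".*force_pN=([-0-9.eE+]+).*", "\\1", comment))
    body <- do.call(rbind, strsplit(lines[(i + 2):(i + 1 + n)], "[ \t]+"))
    xyzw <- matrix(as.numeric(body[, 2:5]), ncol = 4)
    chain <- as.integer(body[, 6])
    chains <- lapply(sort(unique(chain)), function(ci) {
      sel <- chain == ci
      m <- sum(sel)
      list(centers = xyzw[sel, 1:3, drop = FALSE],
           axis_a = matrix(rep(c(1, 0, 0), each = m), m),
           axis_b = matrix(rep(c(0, 1, 0), each = m), m),
           normal = matrix(rep(c(0, 0, 1), each = m), m),
           wrap = xyzw[sel, 4])
    })
    configs[[length(configs) + 1]] <- chromatin_config(chains)
    i <- i + 2 + n
  }
  structure(list(configs = configs,
                 metadata = list(force_pN = force_pN, steps = steps)),
            class = "chromatin_trajectory")
}

#' Read / write umbrella-window metadata as JSON
#'
#' Window metadata records the biased collective variable, umbrella center,
#' spring constant, constant pulling force and RNG seed of one umbrella
#' window: `{cv, center, spring_k, force_pN, seed}`.
#'
#' @param meta a named list with fields `cv`, `center`, `spring_k`,
#'   `force_pN`, `seed`.
#' @param path file path.
#' @export
write_window_meta <- function(meta, path) {
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_window_meta
#' @export
read_window_meta <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)

#' Write a configuration as a pseudo-atom PDB file
#'
#' One atom per nucleosome center with the wrap fraction stored in the
#' B-factor column, suitable for quick visual inspection of representative
#' structures.  Coordinates are written in Angstrom (nm x 10) per PDB
#' convention.
#'
#' @param config a `chromatin_config`.
#' @param path output path.
#' @export
write_config_pdb <- function(config, path) {
  centers <- do.call(rbind, lapply(config$chains, `[[`, "centers"))
  wrap <- unlist(lapply(config$chains, `[[`, "wrap"))
  chain_id <- rep(LETTERS[seq_along(config$chains)],
                  vapply(config$chains, function(ch) nrow(ch$centers), integer(1)))
  n <- nrow(centers)
  bio3d::write.pdb(file = path, xyz = as.numeric(t(centers * 10)),
                   type = rep("ATOM", n), resno = seq_len(n),
                   resid = rep("NUC", n), elety = rep("CA", n),
                   chain = chain_id, b = wrap, o = rep(1, n))
  invisible(path)
}

#' Read a LAMMPS text dump of bead coordinates
#'
#' Parses `ITEM: TIMESTEP / NUMBER OF ATOMS / BOX BOUNDS / ATOMS id ... x y z`
#' blocks of a plain-text LAMMPS dump.  Combined with a bead map this allows
#' converting bead-level trajectories to nucleosome frames via
#' [frames_from_beads()].
#'
#' @param path file path.
#' @return a list of snapshots, each `list(timestep, coords)` with `coords`
#'   an N x 3 matrix ordered by atom id.
#' @export
read_lammps_dump <- function(path) {
  lines <- readLines(path)
  snaps <- list()
  i <- 1
  while (i <= length(lines)) {
    if (!startsWith(lines[i], "ITEM: TIMESTEP")) stop("malformed dump at line ", i)
    ts <- as.integer(lines[i + 1])
    stopifnot(startsWith(lines[i + 2], "ITEM: NUMBER OF ATOMS"))
    n <- as.integer(lines[i + 3])
    i <- i + 4
    while (!startsWith(lines[i], "ITEM: ATOMS")) i <- i + 1  # skip box bounds
    cols <- strsplit(sub("ITEM: ATOMS ", "", lines[i]), " ")[[1]]
    ix <- match(c("id", "x", "y", "z"), cols)
    if (anyNA(ix)) stop("dump must provide id x y z columns")
    body <- do.call(rbind, strsplit(trimws(lines[(i + 1):(i + n)]), "[ \t]+"))
    id <- as.integer(body[, ix[1]])
    coords <- matrix(as.numeric(body[, ix[2:4]]), ncol = 3)[order(id), , drop = FALSE]
    snaps[[length(snaps) + 1]] <- list(timestep = ts, coords = coords)
    i <- i + n + 1
  }
  snaps
}

`%||%` <- function(a, b) if (is.null(a)) b else a
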