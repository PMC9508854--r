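#' Umbrella window container
#'
#' One biased time series plus its bias specification.  `cv_series` holds
#' the values of the biased collective variable(s): a numeric vector for 1D
#' windows or an n x 2 matrix for 2D (q_wrap, d_stack)-style windows; the
#' `bias` is a single [umbrella_bias()] or a list of two for 2D.
#'
#' @param bias an `mc_bias` umbrella (or list of two for 2D windows).
#' @param cv_series numeric vector or n x d matrix of CV samples.
#' @return an object of class `umbrella_window`.
#' @export
umbrella_window <- function(bias, cv_series) {
  if (inherits(bias, "mc_bias")) bias <- list(bias)
  cv_series <- as.matrix(cv_series)
  if (nrow(cv_series) < 3) stop("a window needs at least 3 samples (block splitting)")
  if (length(bias) != ncol(cv_series))
    stop("number of biases must match number of CV columns")
  for (b in bias) if (b$kind != "umbrella") stop("window biases must be umbrellas")
  structure(list(bias = bias, cv_series = cv_series,
                 n_samples = nrow(cv_series)), class = "umbrella_window")
}

#' Build an umbrella window by running the toy simulator
#'
#' Convenience wrapper: runs [run_mc()] under the given umbrella (plus an
#' optional constant force), tabulates the biased CV over the trajectory and
#' returns an [umbrella_window()].
#'
#' @inheritParams run_mc
#' @param bias an umbrella bias (or list of umbrellas for 2D).
#' @param force_pN additional constant pulling force, pN.
#' @param discard fraction of initial snapshots discarded as equilibration.
#' @export
sample_window <- function(model, start, bias, steps, force_pN = 0, seed = 1L,
                          stride = 10L, discard = 0.2, temperature_K = 300) {
  if (inherits(bias, "mc_bias")) bias <- list(bias)
  biases <- bias
  if (force_pN != 0) biases <- c(biases, list(force_bias(force_pN)))
  traj <- run_mc(model, start, biases, steps = steps, seed = seed,
                 stride = stride, temperature_K = temperature_K)
  keep <- seq_along(traj$configs) > floor(discard * length(traj$configs))
  series <- vapply(traj$configs[keep], function(cfg)
    vapply(bias, function(b) compute_cv(cfg, b$cv), numeric(1)),
    numeric(length(bias)))
  umbrella_window(bias, t(matrix(series, nrow = length(bias))))
}

#' Grid specification for free-energy profiles
#'
#' @param lo,hi per-dimension lower/upper edges (length 1 or 2).
#' @param nbins per-dimension bin counts (default 100 in 1D, 50 per axis
#'   in 2D).
#' @export
grid_spec <- function(lo, hi, nbins = if (length(lo) == 1) 100 else c(50, 50)) {
  stopifnot(length(lo) == length(hi), all(hi > lo))
  nbins <- rep_len(as.integer(nbins), length(lo))
  list(lo = lo, hi = hi, nbins = nbins)
}

#' Grid spanning the sampled range of a window set
#'
#' Fixing one grid across [wham()] calls keeps block estimates bin-aligned
#' for [block_errors()].
#' @param windows list of [umbrella_window()]s.
#' @param nbins per-dimension bin counts.
#' @export
grid_from_windows <- function(windows, nbins = NULL) {
  cv <- do.call(rbind, lapply(windows, `[[`, "cv_series"))
  d <- ncol(cv)
  lo <- apply(cv, 2, min); hi <- apply(cv, 2, max)
  pad <- (hi - lo) * 1e-9 + 1e-12
  if (is.null(nbins)) nbins <- if (d == 1) 100L else c(50L, 50L)
  grid_spec(lo - pad, hi + pad, nbins)
}

bin_centers <- function(gs, dim) {
  w <- (gs$hi[dim] - gs$lo[dim]) / gs$nbins[dim]
  gs$lo[dim] + (seq_len(gs$nbins[dim]) - 0.5) * w
}

bin_index <- function(x, gs) {
  # flat bin index over the (possibly 2D) grid; NA outside
  d <- length(gs$lo)
  ix <- matrix(0L, nrow(x), d)
  for (k in seq_len(d)) {
    w <- (gs$hi[k] - gs$lo[k]) / gs$nbins[k]
    i <- floor((x[, k] - gs$lo[k]) / w) + 1L
    i[i < 1L | i > gs$nbins[k]] <- NA_integer_
    ix[, k] <- i
  }
  if (d == 1) ix[, 1] else (ix[, 2] - 1L) * gs$nbins[1] + ix[, 1]
}

logsumexp <- function(m) {
  mx <- max(m)
  if (!is.finite(mx)) return(mx)
  mx + log(sum(exp(m - mx)))
}

#' Weighted histogram analysis (WHAM)
#'
#' Combines biased histograms from a set of umbrella windows into one
#' unbiased free-energy profile by self-consistent iteration of the window
#' free energies, to a tolerance of `tol` (kcal/mol) on the maximum change
#' per iteration.  Works in 1D and 2D.  Bins never visited by any window are
#' left undefined (`NA`), not zero; the profile is shifted so its minimum
#' over defined bins is 0.
#'
#' A connectivity check flags window sets whose occupied bins do not overlap:
#' if the graph joining windows that share at least one occupied bin is
#' disconnected, a warning is emitted and the profile is flagged
#' (`overlap_ok = FALSE`).
#'
#' @param windows a list of [umbrella_window()]s sharing one CV space.
#' @param gs a [grid_spec()]; defaults to 100 bins (1D) / 50 x 50 (2D)
#'   spanning the sampled range.
#' @param temperature_K temperature in Kelvin.
#' @param tol convergence tolerance on window free energies, kcal/mol.
#' @param max_iter iteration cap.
#' @return an object of class `free_energy_profile`: `grid` (bin centers;
#'   a list of two axes in 2D), `F` (kcal/mol, min 0), `err` (NA until
#'   [block_errors()] fills it), `dims`, `overlap_ok`, `n_samples`.
#' @export
wham <- function(windows, gs = NULL, temperature_K = 300, tol = 1e-7,
                 max_iter = 1e5) {
  if (length(windows) < 1) stop("need at least one window")
  d <- ncol(windows[[1]]$cv_series)
  for (w in windows) if (ncol(w$cv_series) != d)
    stop("all windows must share the same CV space")
  if (is.null(gs)) gs <- grid_from_windows(windows)
  if (prod(gs$nbins) < 1) stop("empty grid")
  kT <- kT_kcal(temperature_K)
  nb <- prod(gs$nbins); nw <- length(windows)

  H <- matrix(0, nb, nw)      # histogram per window
  Nw <- numeric(nw)
  for (j in seq_len(nw)) {
    ix <- bin_index(windows[[j]]$cv_series, gs)
    ix <- ix[!is.na(ix)]
    tb <- tabulate(ix, nbins = nb)
    H[, j] <- tb
    Nw[j] <- sum(tb)
  }
  if (any(Nw == 0)) stop("a window has no samples on the grid")

  # bias energy of each window at each bin center
  centers <- lapply(seq_len(d), function(k) bin_centers(gs, k))
  grid_pts <- if (d == 1) matrix(centers[[1]], ncol = 1) else
    as.matrix(expand.grid(centers[[1]], centers[[2]]))
  C <- matrix(0, nb, nw)
  for (j in seq_len(nw)) {
    bj <- windows[[j]]$bias
    for (k in seq_len(d))
      C[, j] <- C[, j] + 0.5 * bj[[k]]$spring_k * (grid_pts[, k] - bj[[k]]$center)^2
  }

  # window-overlap connectivity over occupied bins
  occ <- H > 0
  adj <- crossprod(occ) > 0
  comp <- components_from_adjacency(adj)
  overlap_ok <- max(comp) == 1
  if (!overlap_ok)
    warning("umbrella windows do not overlap: free-energy profile flagged")

  Htot <- rowSums(H)
  f <- numeric(nw)                        # window free energies, kcal/mol
  lnN <- log(Nw)
  for (it in seq_len(max_iter)) {
    # ln denominator_b = lse_j [ ln N_j + (f_j - C_bj)/kT ]
    M <- sweep(-C / kT, 2, lnN + f / kT, `+`)
    mx <- apply(M, 1, max)
    lden <- mx + log(rowSums(exp(M - mx)))
    lnP <- ifelse(Htot > 0, log(Htot) - lden, -Inf)
    fnew <- vapply(seq_len(nw), function(j) {
      v <- lnP - C[, j] / kT
      -kT * logsumexp(v[is.finite(v)])
    }, numeric(1))
    fnew <- fnew - fnew[1]
    delta <- max(abs(fnew - f))
    f <- fnew
    if (delta < tol) break
  }
  Fb <- -kT * lnP
  Fb[!is.finite(Fb)] <- NA_real_
  Fb <- Fb - min(Fb, na.rm = TRUE)
  structure(list(grid = if (d == 1) centers[[1]] else centers,
                 F = if (d == 1) Fb else matrix(Fb, gs$nbins[1], gs$nbins[2]),
                 err = NA_real_, dims = d, gs = gs,
                 overlap_ok = overlap_ok, n_samples = sum(Nw),
                 temperature_K = temperature_K),
            class = "free_energy_profile")
}

components_from_adjacency <- function(adj) {
  n <- nrow(adj)
  comp <- rep(0L, n); cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (comp[v] > 0) next
      comp[v] <- cur
      stack <- c(stack, which(adj[v, ] & comp == 0L))
    }
  }
  comp
}

#' Three-block error estimates
#'
#' Splits every window's time series into `n_blocks` equal-length,
#' non-overlapping consecutive blocks, re-runs the estimator on each block
#' independently, and reports the sample standard deviation (ddof 1) of the
#' block estimates as the error of the mean — the block-averaging protocol
#' used throughout the analysis.
#'
#' @param windows a list of [umbrella_window()]s.
#' @param estimator a function taking a list of windows and returning a
#'   numeric vector (e.g. the `F` field of a [wham()] profile on a fixed
#'   grid, or a scalar such as a reweighted mean extension).
#' @param n_blocks number of blocks (3 in the standard protocol).
#' @return a list with `err` (per-component sd of the block estimates) and
#'   `blocks` (the raw per-block estimates, columns = blocks).
#' @export
block_errors <- function(windows, estimator, n_blocks = 3) {
  ests <- lapply(seq_len(n_blocks), function(b) {
    wb <- lapply(windows, function(w) {
      n <- w$n_samples
      len <- n %/% n_blocks
      idx <- ((b - 1) * len + 1):(b * len)
      umbrella_window(w$bias, w$cv_series[idx, , drop = FALSE])
    })
    estimator(wb)
  })
  blocks <- do.call(cbind, lapply(ests, as.numeric))
  list(err = apply(blocks, 1, sd), blocks = blocks)
}

#' Tilt a free-energy profile by a pulling force
#'
#' Applies `F_f(x) = F_0(x) - f * x * n_scale / 6.948` (pN nm to kcal/mol)
#' and re-references the minimum to 0.  `n_scale` converts the profile axis
#' to a total extension: use `n_scale = n_nucleosomes` when the axis is a
#' per-nucleosome extension, 1 when it is the total extension.
#'
#' @param profile a 1D `free_energy_profile`.
#' @param force_pN pulling force, pN.
#' @param n_scale axis scale factor (see above).
#' @export
tilt <- function(profile, force_pN, n_scale = 1) {
  stopifnot(inherits(profile, "free_energy_profile"), profile$dims == 1)
  profile$F <- profile$F - force_pN * profile$grid * n_scale / PN_PER_KCAL_NM
  profile$F <- profile$F - min(profile$F, na.rm = TRUE)
  profile
}

#' Boltzmann mean extension under a pulling force
#'
#' Tilts the profile by `force_pN` and returns the Boltzmann-weighted mean
#' of the extension axis over the defined bins:
#' `<x>(f) = sum x exp(-F_f(x)/kBT) / sum exp(-F_f(x)/kBT)`.
#'
#' @inheritParams tilt
#' @param temperature_K temperature in Kelvin.
#' @export
mean_extension <- function(profile, force_pN, temperature_K = 300,
                           n_scale = 1) {
  p <- tilt(profile, force_pN, n_scale)
  ok <- is.finite(p$F)
  if (!any(ok)) stop("all bins of the profile are undefined")
  kT <- kT_kcal(temperature_K)
  w <- exp(-(p$F[ok] - min(p$F[ok])) / kT)
  sum(p$grid[ok] * w) / sum(w)
}

#' Harmonic fit near the free-energy minimum
#'
#' Least-squares quadratic fit `F = F0 + 0.5 k (x - x0)^2` restricted to the
#' bins within `delta_F` kcal/mol of the minimum.  Strongly anharmonic
#' profiles (flat-bottomed wells) are flagged when the RMS residual exceeds
#' `residual_max` or the fitted curvature is not positive.
#'
#' @param profile a 1D `free_energy_profile`.
#' @param delta_F fit window above the minimum, kcal/mol.
#' @param residual_max RMS-residual threshold for the anharmonicity flag,
#'   kcal/mol.
#' @return list with `k` (kcal/(mol nm^2)), `x0` (nm), `rms_residual`,
#'   `anharmonic` (logical), `n_bins`.
#' @export
harmonic_fit <- function(profile, delta_F = 2, residual_max = 0.25) {
  stopifnot(inherits(profile, "free_energy_profile"), profile$dims == 1)
  ok <- is.finite(profile$F)
  sel <- ok & profile$F <= min(profile$F[ok]) + delta_F
  x <- profile$grid[sel]; y <- profile$F[sel]
  if (sum(sel) < 3) stop("fewer than 3 bins within the fit window")
  fit <- lm(y ~ x + I(x^2))
  a <- coef(fit)[[3]]; b <- coef(fit)[[2]]
  rms <- sqrt(mean(fit$residuals^2))
  if (a <= 0)
    return(list(k = NA_real_, x0 = NA_real_, rms_residual = rms,
                anharmonic = TRUE, n_bins = sum(sel)))
  list(k = 2 * a, x0 = -b / (2 * a), rms_residual = rms,
       anharmonic = rms > residual_max, n_bins = sum(sel))
}

#' Marginalize a 2D free-energy profile onto one axis
#'
#' Boltzmann-integrates a 2D profile over the other axis:
#' `F(x) = -kBT ln sum_y exp(-F(x, y)/kBT)`, re-referenced to min 0.
#'
#' @param profile a 2D `free_energy_profile`.
#' @param margin axis to keep (1 or 2).
#' @param temperature_K temperature in Kelvin.
#' @export
marginalize <- function(profile, margin = 2, temperature_K = 300) {
  stopifnot(profile$dims == 2)
  kT <- kT_kcal(temperature_K)
  Fm <- apply(profile$F, margin, function(col) {
    ok <- is.finite(col)
    if (!any(ok)) return(NA_real_)
    -kT * logsumexp(-col[ok] / kT)
  })
  Fm <- Fm - min(Fm, na.rm = TRUE)
  structure(list(grid = profile$grid[[margin]], F = Fm, err = NA_real_,
                 dims = 1, overlap_ok = profile$overlap_ok,
                 n_samples = profile$n_samples,
                 temperature_K = temperature_K),
            class = "free_energy_profile")
}

#' Free-energy profile from an unbiased sample
#'
#' Histogram estimate `F = -kBT ln h(x)` with empty bins undefined and the
#' minimum referenced to 0; used for constant-force (non-umbrella) runs,
#' e.g. profiles of the clutch ratio alpha.
#'
#' @param x numeric samples of the collective variable.
#' @param gs a [grid_spec()] (default 50 bins over the sampled range).
#' @param temperature_K temperature in Kelvin.
#' @export
profile_from_samples <- function(x, gs = NULL, temperature_K = 300) {
  if (is.null(gs)) {
    pad <- diff(range(x)) * 1e-9 + 1e-12
    gs <- grid_spec(min(x) - pad, max(x) + pad, 50)
  }
  ix <- bin_index(matrix(x, ncol = 1), gs)
  h <- tabulate(ix[!is.na(ix)], nbins = gs$nbins[1])
  kT <- kT_kcal(temperature_K)
  Fb <- ifelse(h > 0, -kT * log(h), NA_real_)
  Fb <- Fb - min(Fb, na.rm = TRUE)
  structure(list(grid = bin_centers(gs, 1), F = Fb, err = NA_real_, dims = 1,
                 gs = gs, overlap_ok = TRUE, n_samples = length(x),
                 temperature_K = temperature_K),
            class = "free_energy_profile")
}

#' @export
print.free_energy_profile <- function(x, ...) {
  cat("<free_energy_profile> ", if (x$dims == 1) length(x$F) else
    paste(dim(x$F), collapse = " x "), " bins, ", x$n_samples, " samples",
    if (!isTRUE(x$overlap_ok)) " [overlap warning]", "\n", sep = "")
  invisible(x)
}

#' Write a free-energy profile as TSV
#'
#' Columns: bin center(s), `F` (kcal/mol), `err`.
#' @param profile a `free_energy_profile`.
#' @param path output path.
#' @export
write_profile_tsv <- function(profile, path) {
  if (profile$dims == 1) {
    df <- data.frame(x = profile$grid, F = profile$F,
                     err = if (length(profile$err) == length(profile$F))
                       profile$err else NA_real_)
  } else {
    g <- expand.grid(x = profile$grid[[1]], y = profile$grid[[2]])
    df <- data.frame(g, F = as.numeric(profile$F), err = NA_real_)
  }
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
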