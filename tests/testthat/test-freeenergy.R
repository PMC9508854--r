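test_that("Debye screening length matches the closed form and its scalings", {
  expect_equal(debye_cutoff(0.15), 3.14, tolerance = 0.01 / 3.14)
  # quadrupling the ionic strength halves the screening length
  expect_equal(debye_length(0.6), debye_length(0.15) / 2, tolerance = 1e-12)
  # monotone decrease toward zero at high salt
  ls <- sapply(c(0.1, 1, 10, 100, 1e4), debye_length)
  expect_true(all(diff(ls) < 0))
  expect_lt(ls[length(ls)], 0.01)
  expect_error(debye_length(0), "positive")
})

test_that("WHAM recovers a known quadratic free energy from biased samples", {
  set.seed(201)
  k <- 0.5; x0 <- 10
  wins <- quadratic_truth_windows(seq(6, 14, length.out = 8), K = 1.5,
                                  k = k, x0 = x0, n_samples = 2e4)
  prof <- wham(wins)
  expect_true(prof$overlap_ok)
  ok <- is.finite(prof$F)
  truth <- 0.5 * k * (prof$grid - x0)^2
  rng <- range(prof$grid[ok]); span <- diff(rng)
  central <- ok & prof$grid >= rng[1] + 0.1 * span & prof$grid <= rng[2] - 0.1 * span
  truth_c <- truth[central] - min(truth[central])
  est_c <- prof$F[central] - min(prof$F[central])
  expect_lt(sqrt(mean((est_c - truth_c)^2)), 0.1)
})

test_that("an unbiased uniform window yields a flat profile", {
  set.seed(202)
  w <- umbrella_window(umbrella_bias("ee_z", 5, 0), runif(5e4, 0, 10))
  prof <- wham(w = list(w), gs = grid_spec(0, 10, 40))
  spread <- max(prof$F, na.rm = TRUE) - min(prof$F, na.rm = TRUE)
  expect_lt(spread, 0.1)   # noise bound: ~kT * sqrt(nbins/n) << 0.1
})

test_that("disjoint windows are flagged as non-overlapping", {
  set.seed(203)
  w1 <- umbrella_window(umbrella_bias("ee_z", 0, 10), rnorm(1000, 0, 0.1))
  w2 <- umbrella_window(umbrella_bias("ee_z", 50, 10), rnorm(1000, 50, 0.1))
  expect_warning(prof <- wham(list(w1, w2)), "overlap")
  expect_false(prof$overlap_ok)
  expect_error(wham(list()), "at least one")
})

test_that("2D WHAM marginalizes onto the 1D profile of a separable truth", {
  set.seed(204)
  kT <- kT_kcal(300)
  kx <- 0.8; ky <- 2.0; x0 <- 15; y0 <- 0.7   # separable quadratic truth
  centers_x <- seq(10, 20, by = 2.5); Kx <- 1.2
  centers_y <- seq(0.45, 0.90, by = 0.15); Ky <- 50
  wins <- list()
  for (cx in centers_x) for (cy in centers_y) {
    mux <- (kx * x0 + Kx * cx) / (kx + Kx)
    muy <- (ky * y0 + Ky * cy) / (ky + Ky)
    n <- 4000
    cv <- cbind(rnorm(n, mux, sqrt(kT / (kx + Kx))),
                rnorm(n, muy, sqrt(kT / (ky + Ky))))
    wins[[length(wins) + 1]] <- umbrella_window(
      list(umbrella_bias("ee_z", cx, Kx), umbrella_bias("q_wrap", cy, Ky)), cv)
  }
  prof2 <- wham(wins, grid_spec(c(10, 0.45), c(20, 0.95), c(40, 25)))
  marg <- marginalize(prof2, margin = 1)
  truth <- 0.5 * kx * (marg$grid - x0)^2
  ok <- is.finite(marg$F) & abs(marg$grid - x0) < 4
  expect_lt(max(abs((marg$F - min(marg$F[ok])) - (truth - min(truth[ok])))[ok]),
            0.2)
})

test_that("block errors follow the three-block protocol", {
  # estimator returning the block mean: blocks {1,2,3} -> sd 1
  mk_win <- function(vals) umbrella_window(umbrella_bias("ee_z", 0, 1), vals)
  w <- mk_win(rep(c(1, 2, 3), each = 10))
  be <- block_errors(list(w), function(wb) mean(wb[[1]]$cv_series))
  expect_equal(be$err, 1)
  expect_equal(as.numeric(be$blocks), c(1, 2, 3))
  # identical blocks -> zero error
  be0 <- block_errors(list(mk_win(rep(5, 30))),
                      function(wb) mean(wb[[1]]$cv_series))
  expect_equal(be0$err, 0)
})

test_that("block error magnitude tracks the block-level noise", {
  # when block estimates are N(mu, sigma), the mean reported error is
  # E[sd of 3 draws] = c4(3) sigma ~ 0.886 sigma
  set.seed(205)
  sigma <- 0.3
  errs <- replicate(1000, sd(rnorm(3, 0, sigma)))
  expect_equal(mean(errs) / sigma, 0.886, tolerance = 0.05)
  # and block_errors reports exactly that sd for per-block estimates
  w <- umbrella_window(umbrella_bias("ee_z", 0, 1), rnorm(300, 0, 1))
  be <- block_errors(list(w), function(wb) mean(wb[[1]]$cv_series))
  blocks <- as.numeric(be$blocks)
  expect_equal(be$err, sd(blocks))
})

test_that("tilting shifts a harmonic profile by f / (6.948 k)", {
  x <- seq(0, 20, length.out = 400)
  k <- 0.8; x0 <- 9
  prof <- analytic_profile(x, 0.5 * k * (x - x0)^2)
  t0 <- tilt(prof, 0)
  expect_equal(t0$F, prof$F)           # f = 0 is the identity
  for (f in c(1, 2.5, 4)) {
    tf <- tilt(prof, f)
    shift <- f / (PN_PER_KCAL_NM * k)
    expect_equal(tf$grid[which.min(tf$F)], x0 + shift, tolerance = diff(x)[1])
    # pointwise arithmetic oracle (up to the common re-referencing constant)
    manual <- prof$F - f * x / PN_PER_KCAL_NM
    manual <- manual - min(manual)
    expect_equal(tf$F, manual, tolerance = 1e-12)
  }
})

test_that("mean extension obeys the Gaussian and truncated-exponential forms", {
  x <- seq(-10, 30, length.out = 4000)
  k <- 0.5; x0 <- 10
  prof <- analytic_profile(x, 0.5 * k * (x - x0)^2)
  for (f in c(0, 1, 2, 3))
    expect_equal(mean_extension(prof, f), x0 + f / (PN_PER_KCAL_NM * k),
                 tolerance = 1e-6)
  # flat profile on [a, b] under force: truncated exponential mean, checked
  # against numeric quadrature
  a <- 2; b <- 12; f <- 1.5
  dx <- (b - a) / 5000
  xf <- seq(a + dx / 2, b - dx / 2, length.out = 5000)   # bin centers
  flat <- analytic_profile(xf, rep(0, length(xf)))
  lam <- f / (PN_PER_KCAL_NM * kT_kcal(300))
  quad <- integrate(function(u) u * exp(lam * u), a, b)$value /
    integrate(function(u) exp(lam * u), a, b)$value
  expect_equal(mean_extension(flat, f), quad, tolerance = 1e-5)
  expect_error(suppressWarnings(
    mean_extension(analytic_profile(1:3, rep(NA_real_, 3)), 1)), "undefined")
})

test_that("mean extension is non-decreasing in force for any profile", {
  set.seed(206)
  x <- seq(0, 15, length.out = 150)
  for (rep in 1:100) {
    Fx <- cumsum(rnorm(length(x), sd = 0.3))   # rough random landscape
    prof <- analytic_profile(x, Fx - min(Fx))
    means <- sapply(seq(0, 6, by = 0.5), function(f) mean_extension(prof, f))
    expect_true(all(diff(means) >= -1e-9))
  }
})

test_that("harmonic fits recover curvature and flag anharmonic wells", {
  x <- seq(5, 15, length.out = 200)
  k <- 1.2; x0 <- 10.3
  exact <- harmonic_fit(analytic_profile(x, 0.5 * k * (x - x0)^2))
  expect_equal(exact$k, k, tolerance = 1e-9)
  expect_equal(exact$x0, x0, tolerance = 1e-9)
  expect_false(exact$anharmonic)
  set.seed(207)
  noisy <- harmonic_fit(analytic_profile(x, 0.5 * k * (x - x0)^2 +
                                           rnorm(length(x), sd = 0.05)))
  expect_equal(noisy$k, k, tolerance = 0.05)
  # flat-bottomed well: large residual, flagged
  flatF <- pmax(abs(x - x0) - 3, 0)^2
  flat <- harmonic_fit(analytic_profile(x, flatF))
  expect_true(flat$anharmonic)
})

test_that("profiles serialize to TSV with bin centers, F and errors", {
  x <- seq(0, 10, length.out = 50)
  prof <- analytic_profile(x, 0.1 * (x - 5)^2)
  prof$err <- rep(0.05, 50)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_profile_tsv(prof, path)
  back <- read.delim(path)
  expect_equal(back$x, x)
  expect_equal(back$F, prof$F)
  expect_equal(back$err, prof$err)
})
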