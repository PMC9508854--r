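test_that("distance features have the documented length, order and invariance", {
  set.seed(301)
  cfg12 <- random_config(12)
  expect_length(featurize(cfg12), 66)
  cfg4 <- random_config(4)
  f4 <- featurize(cfg4)
  expect_length(f4, 6)
  # fixed (i < j) ordering: first entry is the (0, 1) distance
  x <- cfg4$chains[[1]]$centers
  expect_equal(f4[1], sqrt(sum((x[1, ] - x[2, ])^2)))
  expect_equal(f4[6], sqrt(sum((x[3, ] - x[4, ])^2)))
  # rigid motion leaves features unchanged
  moved <- transform_config(cfg4, random_rotation(), rnorm(3, sd = 20))
  expect_equal(featurize(moved), featurize(cfg4), tolerance = 1e-9)
})

test_that("predicted forces are the exact negative gradient of the energy", {
  set.seed(302)
  configs <- replicate(120, random_tetra(), simplify = FALSE)
  forces <- lapply(configs, tetra_truth_force)
  mod <- train_force_matching(configs, forces, hidden = c(8, 8), epochs = 50,
                              val_frac = 0, seed = 3)
  x <- random_tetra()
  Fp <- matrix(predict_forces(mod, list(x)), ncol = 3)
  h <- 1e-5
  for (i in c(1, 4)) for (d in 1:3) {
    xp <- x; xp[i, d] <- xp[i, d] + h
    xm <- x; xm[i, d] <- xm[i, d] - h
    num <- -(surrogate_energy(mod, xp) - surrogate_energy(mod, xm)) / (2 * h)
    expect_equal(Fp[i, d], num, tolerance = 1e-5)
  }
})

test_that("force matching recovers an analytic quadratic energy surface", {
  set.seed(303)
  configs <- replicate(800, random_tetra(), simplify = FALSE)
  forces <- lapply(configs, tetra_truth_force)
  mod <- train_force_matching(configs, forces, epochs = 2000, seed = 1)
  expect_lt(mod$val_rmse / mod$val_rms_ref, 0.10)
  expect_true(all(diff(range(tail(mod$loss_curve, 50))) < 0.01))
  # free-energy differences correlate with the truth on held-out pairs
  held <- replicate(200, random_tetra(), simplify = FALSE)
  e_pred <- vapply(held, function(x) surrogate_energy(mod, x), numeric(1))
  e_true <- vapply(held, tetra_truth_energy, numeric(1))
  i <- seq(1, 199, by = 2); j <- i + 1
  expect_gt(cor(e_pred[i] - e_pred[j], e_true[i] - e_true[j]), 0.95)
})

test_that("zero reference forces train to a near-constant model", {
  set.seed(304)
  configs <- replicate(150, random_tetra(), simplify = FALSE)
  forces <- replicate(150, matrix(0, 4, 3), simplify = FALSE)
  mod <- train_force_matching(configs, forces, hidden = c(16, 16),
                              epochs = 400, val_frac = 0, seed = 2)
  Fp <- predict_forces(mod, lapply(configs, function(cfg) cfg))
  expect_lt(sqrt(mean(Fp^2)), 0.01)   # < 1% of a 1 kcal/(mol nm) unit scale
})

test_that("duplicating every training example leaves the model unchanged", {
  set.seed(305)
  configs <- replicate(120, random_tetra(), simplify = FALSE)
  forces <- lapply(configs, tetra_truth_force)
  m1 <- train_force_matching(configs, forces, hidden = c(8, 8), epochs = 150,
                             val_frac = 0, seed = 9)
  m2 <- train_force_matching(c(configs, configs), c(forces, forces),
                             hidden = c(8, 8), epochs = 150, val_frac = 0,
                             seed = 9)
  expect_equal(m1$par, m2$par, tolerance = 1e-12)
})

test_that("training validates its inputs", {
  set.seed(306)
  configs <- replicate(120, random_tetra(), simplify = FALSE)
  forces <- lapply(configs, tetra_truth_force)
  expect_error(train_force_matching(configs[1:50], forces[1:50]), "100")
  badf <- forces; badf[[3]][1, 1] <- NaN
  expect_error(train_force_matching(configs, badf), "non-finite")
  expect_error(train_force_matching(configs, forces[-1]), "align")
  mod <- train_force_matching(configs, forces, hidden = c(4, 4), epochs = 5,
                              val_frac = 0, seed = 1)
  expect_error(predict_forces(mod, list(random_config(12))), "mismatch")
})

test_that("surrogate sampling finds the minimizer and respects stiff biases", {
  set.seed(307)
  configs <- replicate(800, random_tetra(), simplify = FALSE)
  forces <- lapply(configs, tetra_truth_force)
  mod <- train_force_matching(configs, forces, epochs = 1500, seed = 1)
  best <- mc_most_probable(mod, 4, steps = 1200, seed = 5,
                           start = random_tetra(sd = 0.5))
  x <- best$chains[[1]]$centers
  for (p in list(c(1, 3), c(2, 4)))
    expect_equal(sqrt(sum((x[p[1], ] - x[p[2], ])^2)), 6, tolerance = 0.5)
  # a stiff umbrella dominates the landscape
  stiff <- mc_most_probable(mod, 4, biases = list(umbrella_bias("d_stack", 20, 50)),
                            steps = 1200, seed = 6)
  expect_equal(compute_cv(stiff, "d_stack"), 20, tolerance = 1)
  # an all-zero network reduces to the minimizer of the bias alone
  zero <- mod
  zero$par$c <- zero$par$c * 0
  z <- mc_most_probable(zero, 4, biases = list(umbrella_bias("d_stack", 12, 50)),
                        steps = 1200, seed = 7)
  expect_equal(compute_cv(z, "d_stack"), 12, tolerance = 0.5)
  # biases the surrogate cannot see are rejected
  expect_error(mc_most_probable(mod, 4, biases = list(tether_bias(0, c(0, 0, 0), 1))),
               "umbrella")
  # minimum separation keeps features inside the training domain
  xb <- best$chains[[1]]$centers
  dmin <- min(dist(xb))
  expect_gte(dmin, 4)
})

test_that("surrogate energies are rigid-motion invariant", {
  set.seed(308)
  configs <- replicate(120, random_tetra(), simplify = FALSE)
  forces <- lapply(configs, tetra_truth_force)
  mod <- train_force_matching(configs, forces, hidden = c(8, 8), epochs = 100,
                              val_frac = 0, seed = 4)
  cfg <- random_config(4)
  moved <- transform_config(cfg, random_rotation(), rnorm(3, sd = 10))
  expect_equal(surrogate_energy(mod, moved), surrogate_energy(mod, cfg),
               tolerance = 1e-8)
  # 12mer scoring is the sum over sliding tetranucleosome windows
  cfg12 <- random_config(12)
  x <- cfg12$chains[[1]]$centers
  manual <- sum(vapply(0:8, function(s)
    surrogate_energy(mod, x[(s + 1):(s + 4), ]), numeric(1)))
  expect_equal(surrogate_energy(mod, cfg12), manual, tolerance = 1e-9)
})

test_that("surrogate models serialize losslessly to JSON", {
  set.seed(309)
  configs <- replicate(120, random_tetra(), simplify = FALSE)
  forces <- lapply(configs, tetra_truth_force)
  mod <- train_force_matching(configs, forces, hidden = c(8, 8), epochs = 50,
                              val_frac = 0, seed = 8)
  path <- withr::local_tempfile(fileext = ".json")
  write_surrogate(mod, path)
  back <- read_surrogate(path)
  x <- list(random_tetra())
  expect_equal(predict_forces(back, x), predict_forces(mod, x),
               tolerance = 1e-12)
})
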