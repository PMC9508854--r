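test_that("d_stack matches construction and a brute-force pair loop", {
  # 12 collinear nucleosomes spaced 5 nm: every (i, i+2) distance is 10
  expect_equal(d_stack(generate_uniform(12, 5)), 10)
  # ideal two-start fiber: all (i, i+2) distances equal the stacking distance
  expect_equal(d_stack(generate_fiber(12, 2.5, 6)), 6)
  set.seed(41)
  cfg <- random_config(12)
  x <- cfg$chains[[1]]$centers
  oracle <- mean(sapply(1:10, function(i) sqrt(sum((x[i, ] - x[i + 2, ])^2))))
  expect_equal(d_stack(cfg), oracle, tolerance = 1e-12)
  expect_error(d_stack(config_from_centers(rbind(c(0, 0, 0), c(9, 0, 0)))),
               "at least 3")
})

test_that("q_wrap is the mean wrap fraction", {
  cfg <- config_from_centers(matrix(runif(36, 0, 50), 12))
  expect_equal(q_wrap(cfg), 1)
  cfg2 <- config_from_centers(matrix(runif(36, 0, 50), 12),
                              wrap = rep(c(0.9, 0.5), each = 6))
  expect_equal(q_wrap(cfg2), 0.7)
  # lowest attainable value: the fully unwrapped outer layer
  cfg3 <- config_from_centers(matrix(runif(36, 0, 50), 12), wrap = rep(0.5, 12))
  expect_equal(q_wrap(cfg3), 0.5)
})

test_that("alpha is max/min over (i, i+2) distances", {
  expect_equal(alpha(generate_uniform(12, 7)), 1)
  # clutch construction: within-clutch 6 nm, bridges exactly 24 nm
  expect_equal(alpha(generate_clutch(12, c(3, 3, 3, 3), 6, 24)), 4)
  set.seed(42)
  cfg <- random_config(12)
  x <- cfg$chains[[1]]$centers
  d <- sapply(1:10, function(i) sqrt(sum((x[i, ] - x[i + 2, ])^2)))
  expect_equal(alpha(cfg), max(d) / min(d), tolerance = 1e-12)
  # coincident (i, i+2) centers are a domain error
  xx <- x; xx[3, ] <- xx[1, ]
  expect_error(alpha(config_from_centers(xx)), "coincident")
})

test_that("alpha >= 1, with equality iff all (i, i+2) distances are equal", {
  set.seed(43)
  for (rep in 1:50) expect_gte(alpha(random_config(sample(3:12, 1))), 1)
  expect_equal(alpha(generate_fiber(12)), 1, tolerance = 1e-12)
})

test_that("shear/normal decomposition obeys Pythagoras", {
  f0 <- get_frame(generate_fiber(3), 1, 0)
  mk <- function(center) nucleosome_frame(1, 1, center, c(1, 0, 0),
                                          c(0, 1, 0), c(0, 0, 1), 1)
  # purely normal displacement (f0's normal is z)
  expect_equal(shear_normal(f0, mk(f0$center + c(0, 0, 3))),
               c(shear = 0, normal = 3))
  # purely in-plane
  expect_equal(shear_normal(f0, mk(f0$center + c(4, 0, 0))),
               c(shear = 4, normal = 0))
  # 3-4-5 triangle
  sn <- shear_normal(f0, mk(f0$center + c(0, 4, 3)))
  expect_equal(unname(sn), c(4, 3))
  set.seed(44)
  for (rep in 1:1000) {
    a <- get_frame(random_config(2), 1, 0)
    b <- get_frame(random_config(2), 1, 1)
    sn <- shear_normal(a, b)
    expect_equal(sum(sn^2), sum((b$center - a$center)^2), tolerance = 1e-10)
  }
})

test_that("symmetrized shear/normal is symmetric, plain one need not be", {
  set.seed(45)
  a <- get_frame(random_config(2), 1, 0)
  b <- get_frame(random_config(2), 1, 1)
  expect_equal(shear_normal_sym(a, b), shear_normal_sym(b, a), tolerance = 1e-12)
})

test_that("inter-chain contacts count pairs within the cutoff", {
  fib <- generate_fiber(12)
  far <- pair_chains(fib, fib, offset = c(1000, 0, 0))
  expect_equal(inter_chain_contacts(far), 0)
  # two identical superposed compact 12mers (diameter < cutoff): all pairs
  compact <- config_from_centers(matrix(runif(36, 0, 7), 12))
  superposed <- chromatin_config(list(compact$chains[[1]], compact$chains[[1]]))
  expect_equal(inter_chain_contacts(superposed), 144)
  set.seed(46)
  two <- random_config(12, chains = 2, spread = 40)
  a <- two$chains[[1]]$centers; b <- two$chains[[2]]$centers
  oracle <- 0
  for (i in 1:12) for (j in 1:12)
    if (sqrt(sum((a[i, ] - b[j, ])^2)) < 15) oracle <- oracle + 1
  expect_equal(inter_chain_contacts(two), oracle)
  expect_error(inter_chain_contacts(fib), "two chains")
})

test_that("two-chain unstacking is the mean of the per-chain d_stack", {
  fib <- generate_fiber(12, stack_dist = 6)
  both <- pair_chains(fib, fib, offset = c(40, 0, 0))
  expect_equal(d_stack_2chain(both), 6)
  mixed <- pair_chains(generate_uniform(12, 4), generate_uniform(12, 6),
                       offset = c(40, 0, 0))
  expect_equal(d_stack_2chain(mixed), 10)    # chains at 8 and 12
  set.seed(47)
  two <- random_config(12, chains = 2)
  expect_equal(d_stack_2chain(two), mean(c(d_stack(two, 1), d_stack(two, 2))),
               tolerance = 1e-12)
})

test_that("end-to-end extension per nucleosome follows the endpoint convention", {
  cfg <- generate_uniform(12, 5)          # endpoints at the terminal centers
  expect_equal(ee_per_nuc(cfg), 55 / 12)
  expect_equal(ee_per_nuc(generate_uniform(12, 120 / 11)), 10)
  # stored endpoints take precedence
  ch <- cfg$chains[[1]]; ch$endpoints <- rbind(c(0, 0, 0), c(0, 0, 0))
  expect_equal(ee_per_nuc(chromatin_config(list(ch))), 0)
  # clutch-breakup extensions around 23.5 nm per nucleosome are representable
  big <- generate_uniform(12, 23.5 * 12 / 11)
  expect_equal(ee_per_nuc(big), 23.5, tolerance = 1e-12)
  # signed z projection picks up orientation
  expect_equal(ee_z_per_nuc(cfg), 55 / 12)
  flipped <- transform_config(cfg, R = diag(c(1, -1, -1)))
  expect_equal(ee_z_per_nuc(flipped), -55 / 12)
})

test_that("all collective variables are rigid-motion invariant", {
  set.seed(48)
  for (rep in 1:5) {
    cfg <- random_config(12, chains = 2, spread = 40)
    R <- random_rotation(); tr <- rnorm(3, sd = 50)
    # rotations about z would trivially preserve ee_z; use full rotations for
    # the rotation-invariant CVs and translations for ee_z
    moved <- transform_config(cfg, R, tr)
    for (nm in c("d_stack", "q_wrap", "alpha", "ee_per_nuc",
                 "d_stack_2chain"))
      expect_equal(compute_cv(moved, nm), compute_cv(cfg, nm),
                   tolerance = 1e-9)
    expect_equal(inter_chain_contacts(moved), inter_chain_contacts(cfg))
    shifted <- transform_config(cfg, diag(3), rnorm(3, sd = 100))
    expect_equal(compute_cv(shifted, "ee_z"), compute_cv(cfg, "ee_z"),
                 tolerance = 1e-9)
  }
})

test_that("cv_table tabulates a trajectory and bead-level q_wrap calibrates to 1", {
  m <- toy_energy_model()
  traj <- run_mc(m, generate_fiber(12), list(), steps = 100, seed = 9,
                 stride = 25)
  tab <- cv_table(traj, c("d_stack", "alpha", "q_wrap"))
  expect_equal(nrow(tab), length(traj$configs))
  expect_true(all(c("step", "d_stack", "alpha", "q_wrap") %in% names(tab)))
  expect_true(all(tab$alpha >= 1))
  ref <- matrix(rnorm(60), 20)
  expect_equal(q_wrap_beads(ref, ref), 1)
  expect_equal(q_wrap_beads(ref + 5, ref), 0)
})
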