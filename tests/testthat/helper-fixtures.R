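# Shared fixtures: all built in code at test time.

# uniformly distributed random rotation matrix (QR with sign fix)
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# chain of n nucleosomes with random well-separated centers and random
# orthonormal frames
random_chain <- function(n, spread = 30, wrap = NULL) {
  centers <- matrix(runif(3 * n, 0, spread), n, 3)
  aa <- bb <- nn <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    R <- random_rotation()
    aa[i, ] <- R[, 1]; bb[i, ] <- R[, 2]; nn[i, ] <- R[, 3]
  }
  if (is.null(wrap)) wrap <- runif(n, 0.5, 1)
  list(centers = centers, axis_a = aa, axis_b = bb, normal = nn, wrap = wrap)
}

random_config <- function(n, chains = 1, spread = 30) {
  chromatin_config(lapply(seq_len(chains), function(i) random_chain(n, spread)))
}

# chain with identity frames from a center matrix
config_from_centers <- function(centers, wrap = rep(1, nrow(centers))) {
  n <- nrow(centers)
  chromatin_config(list(list(
    centers = centers,
    axis_a = matrix(rep(c(1, 0, 0), each = n), n),
    axis_b = matrix(rep(c(0, 1, 0), each = n), n),
    normal = matrix(rep(c(0, 0, 1), each = n), n),
    wrap = wrap)))
}

# analytic tetranucleosome truth: F = sum over (i, i+2) of 0.5 k (d - d0)^2
tetra_truth_force <- function(x, k = 2, d0 = 6) {
  Fm <- matrix(0, 4, 3)
  for (p in list(c(1, 3), c(2, 4))) {
    dv <- x[p[1], ] - x[p[2], ]
    d <- sqrt(sum(dv^2))
    g <- k * (d - d0) * dv / d
    Fm[p[1], ] <- Fm[p[1], ] - g
    Fm[p[2], ] <- Fm[p[2], ] + g
  }
  Fm
}

tetra_truth_energy <- function(x, k = 2, d0 = 6) {
  s <- 0
  for (p in list(c(1, 3), c(2, 4)))
    s <- s + 0.5 * k * (sqrt(sum((x[p[1], ] - x[p[2], ])^2)) - d0)^2
  s
}

random_tetra <- function(sd = 1.5) {
  rbind(c(0, 0, 0), c(8, 0, 3), c(0, 0, 6), c(8, 0, 9)) +
    matrix(rnorm(12, sd = sd), 4, 3)
}

# exact sampler for umbrella windows on a quadratic truth F = 0.5 k (x-x0)^2:
# the biased density is Gaussian with precision (k + K)/kT
quadratic_truth_windows <- function(centers, K, k = 0.5, x0 = 10,
                                    n_samples = 5e4, kT = kT_kcal(300)) {
  lapply(centers, function(c0) {
    mu <- (k * x0 + K * c0) / (k + K)
    sdv <- sqrt(kT / (k + K))
    umbrella_window(umbrella_bias("ee_z", c0, K), rnorm(n_samples, mu, sdv))
  })
}

# analytic free-energy profile object on a fixed grid
analytic_profile <- function(x, F) {
  structure(list(grid = x, F = F - min(F), err = NA_real_, dims = 1,
                 overlap_ok = TRUE, n_samples = length(x),
                 temperature_K = 300),
            class = "free_energy_profile")
}

# brute-force connected components of a graph with edges dist < cutoff
brute_components <- function(D, cutoff) {
  n <- nrow(D)
  lab <- rep(0L, n); cur <- 0L
  for (s in seq_len(n)) {
    if (lab[s]) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (lab[v]) next
      lab[v] <- cur
      nb <- which(D[v, ] < cutoff & lab == 0L & seq_len(n) != v)
      queue <- c(queue, nb)
    }
  }
  lab
}

# do two labelings describe the same partition?
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(outer(a, a, `==`) == outer(b, b, `==`))
}
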