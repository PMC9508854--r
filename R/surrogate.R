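#' Inter-nucleosome distance features
#'
#' The surrogate free-energy model sees a configuration only through its
#' vector of pairwise nucleosome center distances, in fixed (i < j) order:
#' (0,1), (0,2), ..., (0,n-1), (1,2), ... — length n(n-1)/2 (66 for a 12mer,
#' 6 for a tetranucleosome).  Distances make the model invariant under rigid
#' motion by construction.
#'
#' @param config a `chromatin_config` (single chain) or an n x 3 center
#'   matrix.
#' @return numeric feature vector of pairwise distances, nm.
#' @export
featurize <- function(config) {
  x <- config_centers(config)
  p <- pair_indices(nrow(x))
  d <- x[p[, 1], , drop = FALSE] - x[p[, 2], , drop = FALSE]
  sqrt(rowSums(d^2))
}

config_centers <- function(config) {
  if (inherits(config, "chromatin_config")) {
    if (n_chains(config) != 1) stop("surrogate features need a single chain")
    config$chains[[1]]$centers
  } else matrix(as.numeric(config), ncol = 3)
}

pair_indices <- function(n) {
  if (n < 2) stop("need at least 2 nucleosomes")
  t(utils::combn(n, 2))
}

init_mlp <- function(n_input, hidden) {
  stopifnot(length(hidden) == 2)
  n1 <- hidden[1]; n2 <- hidden[2]
  list(W1 = matrix(rnorm(n1 * n_input, sd = sqrt(1 / n_input)), n1, n_input),
       b1 = numeric(n1),
       W2 = matrix(rnorm(n2 * n1, sd = sqrt(1 / n1)), n2, n1),
       b2 = numeric(n2),
       c = rnorm(n2, sd = sqrt(1 / n2)),
       d = 0)
}

# forward pass caching activations; Z is m x B
mlp_forward <- function(par, Z) {
  U1 <- par$W1 %*% Z + par$b1
  H <- tanh(U1)
  V <- par$W2 %*% H + par$b2
  S <- tanh(V)
  E <- drop(crossprod(S, par$c)) + par$d
  list(U1 = U1, H = H, V = V, S = S, E = E)
}

# gradient of the scalar output with respect to the inputs, g = dE/dz (m x B)
mlp_gradz <- function(par, fw) {
  P <- (1 - fw$S^2) * par$c                 # n2 x B
  Q <- crossprod(par$W2, P)                 # n1 x B
  Rr <- (1 - fw$H^2) * Q                    # n1 x B
  list(g = crossprod(par$W1, Rr), P = P, Q = Q, Rr = Rr)
}

# backprop of dL/dg = Gamma (m x B) into parameter gradients; exact reverse
# mode through the gradient network (force matching needs d(dE/dz)/dtheta).
mlp_grad_backprop <- function(par, fw, gz, Gamma) {
  H <- fw$H; S <- fw$S
  rho <- par$W1 %*% Gamma                        # n1 x B
  dW1 <- gz$Rr %*% t(Gamma)                      # from g = W1^T r
  dq <- (1 - H^2) * rho
  du1 <- (-2 * H * (1 - H^2)) * gz$Q * rho       # through phi'(u1) in r
  dp <- par$W2 %*% dq                            # n2 x B
  dW2 <- tcrossprod(gz$P, dq)                    # q = W2^T p
  dc <- rowSums((1 - S^2) * dp)
  dv <- (-2 * S * (1 - S^2)) * par$c * dp
  db2 <- rowSums(dv)
  dW2 <- dW2 + tcrossprod(dv, H)
  dH <- crossprod(par$W2, dv)
  du1 <- du1 + (1 - H^2) * dH
  db1 <- rowSums(du1)
  dW1 <- dW1 + tcrossprod(du1, fw$Z)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, c = dc, d = 0)
}

# assemble predicted forces from feature-space gradients
# G: m x B feature gradients dE/dz; returns 3n x B force matrix (-dE/dx)
assemble_forces <- function(G, geom) {
  m <- nrow(G); B <- ncol(G); n <- geom$n
  Fx <- matrix(0, n, B); Fy <- matrix(0, n, B); Fz <- matrix(0, n, B)
  for (k in seq_len(m)) {
    gk <- G[k, ] / geom$sd[k]
    i <- geom$pairs[k, 1]; j <- geom$pairs[k, 2]
    Fx[i, ] <- Fx[i, ] - gk * geom$Ux[k, ]; Fx[j, ] <- Fx[j, ] + gk * geom$Ux[k, ]
    Fy[i, ] <- Fy[i, ] - gk * geom$Uy[k, ]; Fy[j, ] <- Fy[j, ] + gk * geom$Uy[k, ]
    Fz[i, ] <- Fz[i, ] - gk * geom$Uz[k, ]; Fz[j, ] <- Fz[j, ] + gk * geom$Uz[k, ]
  }
  rbind(Fx, Fy, Fz)
}

# feature-space residual from Cartesian residual R (3n x B)
project_residual <- function(R, geom) {
  m <- nrow(geom$pairs); B <- ncol(R); n <- geom$n
  Rx <- R[1:n, , drop = FALSE]
  Ry <- R[(n + 1):(2 * n), , drop = FALSE]
  Rz <- R[(2 * n + 1):(3 * n), , drop = FALSE]
  Gamma <- matrix(0, m, B)
  for (k in seq_len(m)) {
    i <- geom$pairs[k, 1]; j <- geom$pairs[k, 2]
    Gamma[k, ] <- (geom$Ux[k, ] * (Rx[j, ] - Rx[i, ]) +
                   geom$Uy[k, ] * (Ry[j, ] - Ry[i, ]) +
                   geom$Uz[k, ] * (Rz[j, ] - Rz[i, ])) / geom$sd[k]
  }
  Gamma
}

build_geometry <- function(centers_list, mu = NULL, sdv = NULL) {
  n <- nrow(centers_list[[1]])
  pairs <- pair_indices(n)
  m <- nrow(pairs); B <- length(centers_list)
  D <- matrix(0, m, B); Ux <- matrix(0, m, B); Uy <- matrix(0, m, B)
  Uz <- matrix(0, m, B)
  for (b in seq_len(B)) {
    x <- centers_list[[b]]
    dv <- x[pairs[, 1], , drop = FALSE] - x[pairs[, 2], , drop = FALSE]
    d <- sqrt(rowSums(dv^2))
    D[, b] <- d
    Ux[, b] <- dv[, 1] / d; Uy[, b] <- dv[, 2] / d; Uz[, b] <- dv[, 3] / d
  }
  if (is.null(mu)) {
    mu <- rowMeans(D)
    sdv <- sqrt(rowMeans((D - mu)^2))   # population sd: invariant under duplication
    sdv[sdv < 1e-8] <- 1
  }
  list(n = n, pairs = pairs, D = D, Z = (D - mu) / sdv,
       Ux = Ux, Uy = Uy, Uz = Uz, mu = mu, sd = sdv)
}

#' Train the surrogate free-energy model by force matching
#'
#' Fits a small smooth multilayer perceptron `E(z)` over standardized
#' inter-nucleosome distances so that its Cartesian gradients reproduce the
#' supplied mean forces: the loss is the mean squared deviation between
#' `-dE/dx` and the reference forces, minimized with full-batch Adam (exact
#' analytic gradients through the force computation).  Training is
#' deterministic given `seed`.
#'
#' @param configs list of configurations (each a `chromatin_config` single
#'   chain or an n x 3 center matrix), all with the same nucleosome count.
#' @param forces list of n x 3 matrices of mean forces on the centers,
#'   kcal/(mol nm), aligned with `configs`.
#' @param hidden sizes of the two hidden layers.
#' @param epochs Adam iterations (full batch).
#' @param lr initial learning rate (halved twice over the schedule).
#' @param val_frac held-out fraction for the reported force RMSE (the last
#'   `val_frac` of the supplied order; set 0 to train on everything).
#' @param seed RNG seed.
#' @return an object of class `surrogate_model` with the network parameters,
#'   the feature standardization statistics, the loss curve and the held-out
#'   force RMSE (`val_rmse`, plus `val_rms_ref` for scale).
#' @export
train_force_matching <- function(configs, forces, hidden = c(64, 64),
                                 epochs = 4000, lr = 0.01, val_frac = 0.1,
                                 seed = 1L) {
  if (length(configs) < 100) stop("need at least 100 training configurations")
  if (length(configs) != length(forces)) stop("configs and forces must align")
  centers <- lapply(configs, config_centers)
  n <- nrow(centers[[1]])
  Fref_all <- lapply(forces, function(f) {
    f <- matrix(as.numeric(f), ncol = 3)
    if (!all(is.finite(f))) stop("non-finite forces supplied")
    if (nrow(f) != n) stop("force rows must match nucleosome count")
    c(f[, 1], f[, 2], f[, 3])
  })
  B <- length(centers)
  n_val <- floor(val_frac * B)
  idx_tr <- seq_len(B - n_val)
  idx_va <- setdiff(seq_len(B), idx_tr)

  geom_tr <- build_geometry(centers[idx_tr])
  Ftr <- do.call(cbind, Fref_all[idx_tr])
  m <- nrow(geom_tr$pairs)

  set.seed(seed)
  par <- init_mlp(m, hidden)
  mom <- lapply(par, function(p) p * 0)
  vel <- lapply(par, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; epsA <- 1e-8
  loss_curve <- numeric(epochs)
  denom <- length(Ftr)
  for (it in seq_len(epochs)) {
    fw <- mlp_forward(par, geom_tr$Z); fw$Z <- geom_tr$Z
    gz <- mlp_gradz(par, fw)
    Fp <- assemble_forces(gz$g, geom_tr)
    Rres <- 2 * (Fp - Ftr) / denom
    loss_curve[it] <- mean((Fp - Ftr)^2)
    Gamma <- project_residual(Rres, geom_tr)   # dL/dg; (R_j - R_i) carries the F = -J^T g sign
    grad <- mlp_grad_backprop(par, fw, gz, Gamma)
    lr_t <- lr * if (it > 0.75 * epochs) 0.25 else if (it > 0.5 * epochs) 0.5 else 1
    for (nm in names(par)) {
      mom[[nm]] <- beta1 * mom[[nm]] + (1 - beta1) * grad[[nm]]
      vel[[nm]] <- beta2 * vel[[nm]] + (1 - beta2) * grad[[nm]]^2
      mhat <- mom[[nm]] / (1 - beta1^it)
      vhat <- vel[[nm]] / (1 - beta2^it)
      par[[nm]] <- par[[nm]] - lr_t * mhat / (sqrt(vhat) + epsA)
    }
  }
  model <- structure(list(par = par, mu = geom_tr$mu, sd = geom_tr$sd,
                          n_input = m, n_nucleosomes = n, hidden = hidden,
                          loss_curve = loss_curve, seed = seed),
                     class = "surrogate_model")
  if (length(idx_va)) {
    pv <- predict_forces(model, centers[idx_va])
    Fva <- do.call(cbind, Fref_all[idx_va])
    model$val_rmse <- sqrt(mean((pv - Fva)^2))
    model$val_rms_ref <- sqrt(mean(Fva^2))
  } else {
    model$val_rmse <- NA_real_; model$val_rms_ref <- NA_real_
  }
  model
}

#' Predicted forces for a list of configurations
#'
#' @param model a `surrogate_model`.
#' @param centers_list list of n x 3 center matrices (n equal to the model's
#'   nucleosome count).
#' @return a 3n x B matrix of forces, kcal/(mol nm), stacked (x, y, z).
#' @export
predict_forces <- function(model, centers_list) {
  centers_list <- lapply(centers_list, config_centers)
  if (nrow(centers_list[[1]]) != model$n_nucleosomes)
    stop("feature-length mismatch: model expects ", model$n_nucleosomes,
         " nucleosomes")
  geom <- build_geometry(centers_list, model$mu, model$sd)
  fw <- mlp_forward(model$par, geom$Z)
  gz <- mlp_gradz(model$par, fw)
  assemble_forces(gz$g, geom)
}

#' Surrogate free energy of a configuration
#'
#' Configurations with the model's native nucleosome count are evaluated
#' directly.  Longer chains are scored as the sum of the model over all
#' sliding windows of its native size (windows i..i+3 for a
#' tetranucleosome-trained model) — the natural composition rule for
#' transferring tetranucleosome energetics to a 12mer, documented as this
#' package's reading.
#'
#' @param model a `surrogate_model`.
#' @param config a `chromatin_config` (single chain) or n x 3 center matrix.
#' @return free energy, kcal/mol (arbitrary additive constant).
#' @export
surrogate_energy <- function(model, config) {
  x <- config_centers(config)
  nm <- model$n_nucleosomes
  if (nrow(x) < nm) stop("configuration smaller than the model's native size")
  wins <- lapply(0:(nrow(x) - nm), function(s) x[(s + 1):(s + nm), , drop = FALSE])
  geom <- build_geometry(wins, model$mu, model$sd)
  sum(mlp_forward(model$par, geom$Z)$E)
}

#' Most probable configuration under the surrogate model and biases
#'
#' Exhaustive Metropolis Monte Carlo over nucleosome centers (and wrap
#' fractions when a `q_wrap` umbrella is present) with energy
#' `surrogate + biases`; returns the lowest-energy configuration visited.
#' A minimum center separation of `min_sep` nm is enforced to keep the
#' features inside the model's training domain.  Supported bias CVs:
#' `d_stack`, `ee_z` (functions of centers) and `q_wrap` (wrap coordinate,
#' bias energy only); anything else is an error since the surrogate cannot
#' see it.
#'
#' @param model a `surrogate_model`.
#' @param n_nucleosomes chain length to sample.
#' @param biases list of umbrella biases (see [umbrella_bias()]).
#' @param steps Monte Carlo sweeps.
#' @param seed RNG seed.
#' @param start optional starting `chromatin_config` / center matrix.
#' @param d_trans translation amplitude, nm.
#' @param min_sep minimum allowed center separation, nm.
#' @param temperature_K sampling temperature, Kelvin.
#' @return the lowest-energy `chromatin_config` visited (identity frames;
#'   wrap 1 unless sampled).
#' @export
mc_most_probable <- function(model, n_nucleosomes, biases = list(), steps = 2000,
                             seed = 1L, start = NULL, d_trans = 0.6,
                             min_sep = 4, temperature_K = 300) {
  biases <- check_biases(biases)
  sample_wrap <- FALSE
  for (b in biases) {
    if (b$kind != "umbrella") stop("mc_most_probable takes umbrella biases only")
    if (!b$cv %in% c("d_stack", "ee_z", "q_wrap"))
      stop("bias on a CV the surrogate cannot see: ", b$cv)
    if (b$cv == "q_wrap") sample_wrap <- TRUE
  }
  n <- n_nucleosomes
  x <- if (is.null(start)) config_centers(generate_uniform(n, spacing = 7)) else
    config_centers(start)
  wrap <- rep(1, n)
  kT <- kT_kcal(temperature_K)

  bias_e <- function(x, wrap) {
    e <- 0
    for (b in biases) {
      v <- switch(b$cv,
                  d_stack = mean(sqrt(rowSums((x[3:n, , drop = FALSE] -
                                               x[1:(n - 2), , drop = FALSE])^2))),
                  ee_z = (x[n, 3] - x[1, 3]) / n,
                  q_wrap = mean(wrap))
      e <- e + 0.5 * b$spring_k * (v - b$center)^2
    }
    e
  }
  energy <- function(x, wrap) surrogate_energy(model, x) + bias_e(x, wrap)
  min_sep_ok <- function(x, i) {
    d2 <- rowSums(sweep(x[-i, , drop = FALSE], 2, x[i, ])^2)
    all(d2 >= min_sep^2)
  }

  set.seed(seed)
  e <- energy(x, wrap)
  best <- list(x = x, wrap = wrap, e = e)
  for (sw in seq_len(steps)) {
    for (i in seq_len(n)) {
      xi <- x[i, ]
      x[i, ] <- xi + runif(3, -d_trans, d_trans)
      if (!min_sep_ok(x, i)) { x[i, ] <- xi; next }
      e_new <- energy(x, wrap)
      if (e_new <= e || runif(1) < exp(-(e_new - e) / kT)) {
        e <- e_new
        if (e < best$e) best <- list(x = x, wrap = wrap, e = e)
      } else x[i, ] <- xi
      if (sample_wrap) {
        wi <- wrap[i]
        w <- wi + runif(1, -0.05, 0.05)
        if (w > 1) w <- 2 - w
        if (w < WRAP_MIN) w <- 2 * WRAP_MIN - w
        wrap[i] <- w
        e_new <- energy(x, wrap)
        if (e_new <= e || runif(1) < exp(-(e_new - e) / kT)) {
          e <- e_new
          if (e < best$e) best <- list(x = x, wrap = wrap, e = e)
        } else wrap[i] <- wi
      }
    }
  }
  chromatin_config(list(identity_frames(best$x, best$wrap)))
}

#' Serialize / load a surrogate model as JSON
#'
#' @param model a `surrogate_model`.
#' @param path file path.
#' @export
write_surrogate <- function(model, path) {
  obj <- unclass(model)
  obj$loss_curve <- NULL
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_surrogate
#' @export
read_surrogate <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("W1", "W2")) obj$par[[nm]] <- as.matrix(obj$par[[nm]])
  obj$par$c <- as.numeric(obj$par$c)
  structure(obj, class = "surrogate_model")
}
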