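#' Toy chromatin energy model
#'
#' A nucleosome-level stand-in energy function that reproduces the
#' statistical structure the analysis pipeline assumes: face-face stacking is
#' energetically favorable while side-side contact is not, linker DNA is
#' contour-limited but bends cheaply, and unwrapping the outer DNA layer
#' costs energy while releasing extra linker contour.  It is a toy model at
#' nucleosome resolution, not a residue-level force field.
#'
#' Terms (kcal/mol, nm):
#' * stacking: well of depth `eps_stack` at center distance `r_stack`
#'   (Gaussian radial width `stack_width`), gated by the squared normal-normal
#'   alignment and the coaxiality of the displacement, applied to all pairs
#'   `|i - j| >= 2` and all cross-chain pairs;
#' * excluded volume: ellipsoidal inverse-12 repulsion of scale `eps_rep` with
#'   in-plane semi-axis `sigma_inplane` and normal semi-axis `sigma_normal`;
#' * linker: spring about rest length `L0 + (lambda_release / 2)
#'   ((1 - w_i) + (1 - w_j))`, with stiffness `k_link` beyond the rest length
#'   (DNA cannot stretch past its contour) and `k_link_compress` below it
#'   (slack linkers bend cheaply);
#' * unwrapping: `eps_unwrap * (1 - w)` per nucleosome; with
#'   `allow_unwrap = FALSE` the wrap coordinate is frozen at its starting
#'   value, mirroring control simulations in which the full 147 bp of
#'   nucleosomal DNA is rigidified.
#'
#' @param eps_stack stacking well depth, kcal/mol.
#' @param r_stack stacking distance at the well minimum, nm.
#' @param stack_width radial width of the stacking well, nm.
#' @param sigma_inplane,sigma_normal ellipsoidal excluded-volume semi-axes, nm.
#' @param eps_rep repulsion energy scale, kcal/mol.
#' @param k_link linker stretch stiffness, kcal/(mol nm^2).
#' @param k_link_compress linker compression stiffness, kcal/(mol nm^2).
#' @param L0 linker rest length at full wrap, nm.
#' @param lambda_release linker contour released per unit unwrapping, nm.
#' @param eps_unwrap unwrapping penalty per unit (1 - wrap), kcal/mol.
#' @param allow_unwrap logical; `FALSE` freezes all wrap fractions.
#' @param cutoff nonbonded cutoff, nm.
#' @return a list of class `toy_energy_model`.
#' @export
toy_energy_model <- function(eps_stack = 3, r_stack = 6, stack_width = 1.5,
                             sigma_inplane = 10, sigma_normal = 5.5,
                             eps_rep = 0.5, k_link = 30,
                             k_link_compress = 0.2, L0 = 10.5,
                             lambda_release = 13.6, eps_unwrap = 8,
                             allow_unwrap = TRUE, cutoff = 25) {
  m <- list(eps_stack = eps_stack, r_stack = r_stack, stack_width = stack_width,
            sigma_inplane = sigma_inplane, sigma_normal = sigma_normal,
            eps_rep = eps_rep, k_link = k_link,
            k_link_compress = k_link_compress, L0 = L0,
            lambda_release = lambda_release, eps_unwrap = eps_unwrap,
            allow_unwrap = isTRUE(allow_unwrap), cutoff = cutoff)
  if (any(unlist(m[c("eps_stack", "eps_rep", "k_link", "k_link_compress",
                     "eps_unwrap", "lambda_release")]) < 0))
    stop("energy scales and lambda_release must be non-negative")
  class(m) <- "toy_energy_model"
  m
}

BIAS_CVS <- c(d_stack = 0L, q_wrap = 1L, ee_z = 2L)

#' Bias specifications for the toy simulator
#'
#' `umbrella_bias` restrains a collective variable harmonically
#' (`0.5 k (cv - center)^2`); supported CVs are `d_stack` (spring in
#' kcal/(mol nm^2)), `q_wrap` (spring in kcal/mol) and `ee_z` (the signed
#' per-nucleosome z extension).  `force_bias` applies a constant pulling
#' force in pN along the z axis to the terminal nucleosome centers of each
#' chain (energy `-f * extension / 6.948`).  `tether_bias` tethers one
#' nucleosome center harmonically to a reference point (used for sampler
#' calibration).
#'
#' @param cv collective variable name.
#' @param center umbrella center.
#' @param spring_k spring constant.
#' @param force_pN pulling force, pN.
#' @param nuc 0-based global nucleosome index (tether).
#' @param ref length-3 reference point, nm (tether).
#' @export
umbrella_bias <- function(cv, center, spring_k) {
  if (!cv %in% names(BIAS_CVS)) stop("unknown CV in bias: ", cv)
  # zero spring = unbiased window (still usable in WHAM); negative is an error
  if (spring_k < 0) stop("umbrella spring constant cannot be negative")
  structure(list(kind = "umbrella", kind_code = 0L, cv = cv,
                 cv_code = BIAS_CVS[[cv]], center = center,
                 spring_k = spring_k, force_pN = 0, nuc = 0L,
                 ref = c(0, 0, 0)), class = "mc_bias")
}

#' @rdname umbrella_bias
#' @export
force_bias <- function(force_pN) {
  structure(list(kind = "constant_force", kind_code = 1L, cv = "ee_z",
                 cv_code = 2L, center = 0, spring_k = 0,
                 force_pN = force_pN, nuc = 0L, ref = c(0, 0, 0)),
            class = "mc_bias")
}

#' @rdname umbrella_bias
#' @export
tether_bias <- function(nuc, ref, spring_k) {
  structure(list(kind = "tether", kind_code = 2L, cv = "none", cv_code = 0L,
                 center = 0, spring_k = spring_k, force_pN = 0,
                 nuc = as.integer(nuc), ref = as.numeric(ref)),
            class = "mc_bias")
}

config_to_state <- function(config) {
  chains <- config$chains
  list(centers = do.call(rbind, lapply(chains, `[[`, "centers")),
       axis_a = do.call(rbind, lapply(chains, `[[`, "axis_a")),
       normal = do.call(rbind, lapply(chains, `[[`, "normal")),
       wrap = unlist(lapply(chains, `[[`, "wrap")),
       chain = rep(seq_along(chains),
                   vapply(chains, function(ch) nrow(ch$centers), integer(1))))
}

state_to_config <- function(centers, axis_a, normal, wrap, chain) {
  chains <- lapply(sort(unique(chain)), function(ci) {
    sel <- chain == ci
    a <- axis_a[sel, , drop = FALSE]
    nn <- normal[sel, , drop = FALSE]
    b <- cbind(nn[, 2] * a[, 3] - nn[, 3] * a[, 2],   # b = n x a
               nn[, 3] * a[, 1] - nn[, 1] * a[, 3],
               nn[, 1] * a[, 2] - nn[, 2] * a[, 1])
    list(centers = centers[sel, , drop = FALSE], axis_a = a, axis_b = b,
         normal = nn, wrap = wrap[sel])
  })
  chromatin_config(chains)
}

check_biases <- function(biases) {
  if (inherits(biases, "mc_bias")) biases <- list(biases)
  for (b in biases) if (!inherits(b, "mc_bias"))
    stop("biases must be built with umbrella_bias() / force_bias() / tether_bias()")
  biases
}

#' Run the toy-model Metropolis Monte Carlo sampler
#'
#' Samples the toy chromatin model with single-nucleosome moves (rigid
#' translation, rigid rotation and, when unwrapping is allowed, a reflected
#' wrap increment in `[-d_wrap, d_wrap]`) under an optional set of biases.
#' Acceptance follows the Metropolis rule at `kB T` (0.596 kcal/mol at
#' 300 K).  The total energy is updated incrementally from per-move deltas;
#' the returned trajectory carries both the incremental and the
#' recomputed-from-scratch final energy so the bookkeeping can be audited.
#'
#' @param model a [toy_energy_model()].
#' @param start a `chromatin_config` starting structure.
#' @param biases a list of bias objects (see [umbrella_bias()]).
#' @param steps number of Monte Carlo sweeps (each sweep attempts one move
#'   per nucleosome).
#' @param temperature_K temperature in Kelvin.
#' @param seed RNG seed; identical seeds give bitwise-identical trajectories.
#' @param stride record a snapshot every `stride` sweeps.
#' @param d_trans,d_rot,d_wrap move amplitudes (nm, rad, wrap units).
#' @param collect `"configs"` stores full `chromatin_config` snapshots;
#'   `"centers"` stores bare center matrices (cheap for long, thin time
#'   series such as sampler-calibration runs).
#' @return a `chromatin_trajectory`: list with `configs` (snapshots),
#'   and `metadata` (`steps`, `energy`, `acceptance`, `force_pN`, `biases`,
#'   `seed`, `stride`, `e_incremental`, `e_scratch`).
#' @export
run_mc <- function(model, start, biases = list(), steps, temperature_K = 300,
                   seed = 1L, stride = max(1L, steps %/% 200L),
                   d_trans = 0.8, d_rot = 0.35, d_wrap = 0.05,
                   collect = c("configs", "centers")) {
  collect <- match.arg(collect)
  stopifnot(inherits(model, "toy_energy_model"), steps >= 1)
  if (temperature_K <= 0) stop("temperature must be positive")
  biases <- check_biases(biases)
  st <- config_to_state(start)
  set.seed(seed)
  res <- cpp_run_mc(st, unclass(model), lapply(biases, unclass),
                    as.integer(steps), as.integer(stride),
                    kT_kcal(temperature_K), d_trans, d_rot, d_wrap)
  configs <- if (collect == "centers") res$centers else
    lapply(seq_along(res$centers), function(k)
      state_to_config(res$centers[[k]], res$axis_a[[k]], res$normal[[k]],
                      res$wrap[[k]], st$chain))
  force_pN <- sum(vapply(biases, function(b)
    if (b$kind == "constant_force") b$force_pN else 0, numeric(1)))
  structure(list(configs = configs,
                 metadata = list(steps = res$step, energy = res$energy,
                                 acceptance = res$acceptance,
                                 force_pN = force_pN, biases = biases,
                                 seed = seed, stride = stride,
                                 e_incremental = res$e_incremental,
                                 e_scratch = res$e_scratch)),
            class = "chromatin_trajectory")
}

#' @export
print.chromatin_trajectory <- function(x, ...) {
  cat("<chromatin_trajectory> ", length(x$configs), " snapshots, acceptance ",
      signif(x$metadata$acceptance %||% NA, 3), "\n", sep = "")
  invisible(x)
}

#' Total toy-model energy of a configuration
#'
#' Recomputes the full energy (all terms plus biases) from scratch; used to
#' audit the sampler's incremental bookkeeping and to inspect generated
#' structures.
#'
#' @inheritParams run_mc
#' @param config a `chromatin_config`.
#' @return energy in kcal/mol.
#' @export
toy_energy <- function(model, config, biases = list()) {
  biases <- check_biases(biases)
  cpp_total_energy(config_to_state(config), unclass(model),
                   lapply(biases, unclass))
}
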