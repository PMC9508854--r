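#' Collective variables for chromatin configurations
#'
#' These functions implement the geometric statistics used to monitor
#' chromatin unfolding: the stacking distance `d_stack` (mean center distance
#' between nucleosomes i and i+2; small in a two-start zigzag fiber), the
#' wrapping degree `q_wrap` (mean outer-layer wrap fraction; 1 = fully
#' wrapped), the clutch ratio `alpha` (max over (i, i+2) distances divided by
#' the min; near 1 for uniform extension, large for clutched configurations),
#' the per-nucleosome DNA end-to-end distance, its signed z projection used
#' under pulling forces, the shear/normal decomposition of an
#' inter-nucleosome displacement, and inter-chain nucleosome contacts.
#'
#' @name colvars
NULL

stack_distances <- function(config, chain = 1) {
  x <- config$chains[[chain]]$centers
  n <- nrow(x)
  if (n < 3) stop("d_stack needs at least 3 nucleosomes in the chain")
  d <- x[3:n, , drop = FALSE] - x[1:(n - 2), , drop = FALSE]
  sqrt(rowSums(d^2))
}

#' @rdname colvars
#' @param config a `chromatin_config`.
#' @param chain chain index (1-based).
#' @return `d_stack`: mean (i, i+2) center distance, nm.
#' @export
d_stack <- function(config, chain = 1) mean(stack_distances(config, chain))

#' @rdname colvars
#' @return `q_wrap`: mean wrap fraction, dimensionless in `[0.5, 1]`.
#' @export
q_wrap <- function(config, chain = 1) mean(config$chains[[chain]]$wrap)

#' @rdname colvars
#' @return `alpha`: clutch ratio `d_max / d_min` over (i, i+2) distances,
#'   `>= 1`.
#' @export
alpha <- function(config, chain = 1) {
  d <- stack_distances(config, chain)
  if (min(d) <= 0) stop("coincident (i, i+2) centers: alpha undefined")
  max(d) / min(d)
}

#' @rdname colvars
#' @return `d_stack_2chain`: unweighted mean of `d_stack` over the two chains
#'   (the two-chain extension coordinate `d-bar_stack`).
#' @export
d_stack_2chain <- function(config) {
  if (n_chains(config) != 2) stop("d_stack_2chain needs a two-chain configuration")
  mean(c(d_stack(config, 1), d_stack(config, 2)))
}

#' @rdname colvars
#' @param cutoff contact distance in nm (strict `<`; pairs at exactly the
#'   cutoff are excluded).
#' @return `inter_chain_contacts`: number of nucleosome pairs, one from each
#'   chain, closer than `cutoff`.
#' @export
inter_chain_contacts <- function(config, cutoff = 15) {
  if (n_chains(config) != 2) stop("inter-chain contacts need two chains")
  a <- config$chains[[1]]$centers
  b <- config$chains[[2]]$centers
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * a %*% t(b)
  sum(d2 < cutoff^2)
}

#' @rdname colvars
#' @param overhang endpoint extrapolation, see [dna_endpoints()].
#' @return `ee_per_nuc`: DNA end-to-end distance divided by the number of
#'   nucleosomes, nm.
#' @export
ee_per_nuc <- function(config, chain = 1, overhang = 0) {
  e <- dna_endpoints(config, chain, overhang)
  sqrt(sum((e[2, ] - e[1, ])^2)) / chain_length(config, chain)
}

#' @rdname colvars
#' @return `ee_z_per_nuc`: signed z component of the end-to-end vector per
#'   nucleosome, nm — the extension coordinate under a z-axis pulling force.
#' @export
ee_z_per_nuc <- function(config, chain = 1, overhang = 0) {
  e <- dna_endpoints(config, chain, overhang)
  (e[2, 3] - e[1, 3]) / chain_length(config, chain)
}

#' Shear / normal decomposition of an inter-nucleosome displacement
#'
#' Decomposes the center-to-center vector `r` (from center i to center j)
#' into the component
#' perpendicular to nucleosome i's plane (`normal = |r . n_i|`) and the
#' in-plane remainder (`shear = |r - (r . n_i) n_i|`), so that
#' `shear^2 + normal^2 = |r|^2`.  The decomposition uses nucleosome i's plane
#' and is therefore asymmetric in (i, j); `shear_normal_sym` averages both
#' orderings.
#'
#' @param frame_i,frame_j `nucleosome_frame` objects.
#' @return named numeric vector `c(shear =, normal =)`, nm.
#' @export
shear_normal <- function(frame_i, frame_j) {
  r <- frame_j$center - frame_i$center
  nrm <- sum(r * frame_i$normal)
  inpl <- r - nrm * frame_i$normal
  c(shear = sqrt(sum(inpl^2)), normal = abs(nrm))
}

#' @rdname shear_normal
#' @export
shear_normal_sym <- function(frame_i, frame_j) {
  (shear_normal(frame_i, frame_j) + shear_normal(frame_j, frame_i)) / 2
}

#' Evaluate a named collective variable on a configuration
#'
#' Dispatcher used by the Monte Carlo biases, the trajectory tabulator and
#' the CLI.  Chain-level CVs (`d_stack`, `q_wrap`, `ee_z`, `ee_per_nuc`,
#' `alpha`) are averaged over chains when the configuration has two, so that
#' `d_stack` evaluates to the two-chain `d-bar_stack` automatically.
#'
#' @param config a `chromatin_config`.
#' @param name one of `d_stack`, `q_wrap`, `alpha`, `ee_per_nuc`, `ee_z`,
#'   `d_stack_2chain`, `inter_chain_contacts`.
#' @param ... passed to the underlying CV function.
#' @export
compute_cv <- function(config, name, ...) {
  per_chain <- function(f) mean(vapply(seq_len(n_chains(config)),
                                       function(ci) f(config, ci, ...), numeric(1)))
  switch(name,
         d_stack = per_chain(function(cfg, ci, ...) d_stack(cfg, ci)),
         q_wrap = per_chain(function(cfg, ci, ...) q_wrap(cfg, ci)),
         alpha = per_chain(function(cfg, ci, ...) alpha(cfg, ci)),
         ee_per_nuc = per_chain(ee_per_nuc),
         ee_z = per_chain(ee_z_per_nuc),
         d_stack_2chain = d_stack_2chain(config),
         inter_chain_contacts = inter_chain_contacts(config, ...),
         stop("unknown collective variable: ", name))
}

#' Tabulate collective variables along a trajectory
#'
#' @param traj a `chromatin_trajectory`.
#' @param cvs character vector of CV names (see [compute_cv()]).
#' @return a data frame with a `step` column and one column per CV.
#' @export
cv_table <- function(traj, cvs = c("d_stack", "q_wrap", "alpha", "ee_z")) {
  steps <- traj$metadata$steps %||% seq_along(traj$configs)
  out <- data.frame(step = steps)
  for (nm in cvs)
    out[[nm]] <- vapply(traj$configs, compute_cv, numeric(1), name = nm)
  out
}

#' Bead-level wrapping degree against a wrapped reference
#'
#' Model-variant of `q_wrap` for bead-level input: the fraction of
#' outer-layer DNA beads within `tol` nm of their positions in the fully
#' wrapped reference structure, so a fully wrapped nucleosome scores 1.
#'
#' @param coords,ref_coords N x 3 matrices of current and reference bead
#'   positions (outer-layer DNA beads only), nm.
#' @param tol contact tolerance, nm.
#' @export
q_wrap_beads <- function(coords, ref_coords, tol = 1) {
  d <- sqrt(rowSums((coords - ref_coords)^2))
  mean(d <= tol)
}
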