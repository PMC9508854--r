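#' Parametric chromatin structure generators
#'
#' Deterministic generators for the three structural motifs of the analysis:
#' a two-start zigzag fiber (nucleosome i stacks on i+2, forming two
#' interleaved stacks), a clutched configuration (compact groups of
#' nucleosomes separated by long stretches of unwrapped DNA) and a uniformly
#' extended chain.  They serve as Monte Carlo starting points and as exact
#' fixtures for the collective variables: by construction `alpha` is 1 for
#' the fiber and uniform chain and `gap/intra` for the clutch generator.
#'
#' @name generators
NULL

#' @rdname generators
#' @param n number of nucleosomes (>= 3 for the fiber).
#' @param rise axial offset between the two stacks, nm.
#' @param stack_dist center distance between stacked (i, i+2) nucleosomes, nm.
#' @param stack_sep lateral separation between the two stacks, nm.
#' @return a `chromatin_config` with all wrap fractions 1 (fiber/uniform) and
#'   nucleosome normals along the stacking axis.
#' @export
generate_fiber <- function(n, rise = 2.5, stack_dist = 6, stack_sep = 10) {
  if (n < 3) stop("a two-start fiber needs at least 3 nucleosomes")
  i <- seq_len(n) - 1L
  centers <- cbind((i %% 2) * stack_sep, 0,
                   (i %/% 2) * stack_dist + (i %% 2) * rise)
  chromatin_config(list(identity_frames(centers)))
}

identity_frames <- function(centers, wrap = rep(1, nrow(centers))) {
  n <- nrow(centers)
  list(centers = centers,
       axis_a = matrix(rep(c(1, 0, 0), each = n), n),
       axis_b = matrix(rep(c(0, 1, 0), each = n), n),
       normal = matrix(rep(c(0, 0, 1), each = n), n),
       wrap = wrap)
}

#' @rdname generators
#' @param clutch_sizes integer vector of clutch sizes summing to `n`; each
#'   clutch needs at least 2 members unless it is the only one.
#' @param intra (i, i+2) center distance within a clutch, nm.
#' @param gap (i, i+2) center distance across clutch boundaries, nm; must
#'   exceed `intra` and the lateral stack separation.
#' @param boundary_wrap wrap fraction assigned to clutch-boundary nucleosomes
#'   (the unwrapped DNA that separates clutches).
#' @export
generate_clutch <- function(n, clutch_sizes, intra = 6, gap = 24,
                            stack_sep = 8, boundary_wrap = 0.6) {
  if (sum(clutch_sizes) != n) stop("clutch sizes must sum to n")
  if (length(clutch_sizes) > 1) {
    if (any(clutch_sizes < 2)) stop("clutches need at least 2 nucleosomes")
    if (intra >= gap) stop("intra-clutch distance must be smaller than the gap")
  }
  r <- intra / 2                      # axial rise within a clutch
  centers <- matrix(0, n, 3)
  # lateral alternation follows the global index, so every (i, i+2) pair is
  # purely axial: within-clutch distances are exactly `intra` and bridging
  # distances exactly `gap` (axial clutch offset gap - r), with no rounding
  i <- seq_len(n) - 1L
  centers[, 1] <- (i %% 2) * stack_sep
  wrap <- rep(1, n)
  z0 <- 0; at <- 1
  for (c_i in seq_along(clutch_sizes)) {
    s <- clutch_sizes[c_i]
    centers[at:(at + s - 1), 3] <- z0 + r * (seq_len(s) - 1)
    if (c_i > 1) wrap[at] <- boundary_wrap
    if (c_i < length(clutch_sizes)) wrap[at + s - 1] <- boundary_wrap
    z0 <- z0 + r * (s - 1) + (gap - r)
    at <- at + s
  }
  chromatin_config(list(identity_frames(centers, wrap)))
}

#' @rdname generators
#' @param spacing center spacing of the collinear chain, nm.
#' @export
generate_uniform <- function(n, spacing = 10) {
  if (n < 1) stop("need at least one nucleosome")
  centers <- cbind(0, 0, (seq_len(n) - 1) * spacing)
  chromatin_config(list(identity_frames(centers)))
}

#' Place two chains side by side
#'
#' Convenience constructor for two-chain (crowding) analyses: takes two
#' single-chain configurations and offsets the second by `offset` nm.
#'
#' @param a,b single-chain `chromatin_config`s.
#' @param offset length-3 translation applied to `b`, nm.
#' @export
pair_chains <- function(a, b, offset = c(30, 0, 0)) {
  stopifnot(n_chains(a) == 1, n_chains(b) == 1)
  b <- transform_config(b, t = offset)
  chromatin_config(list(a$chains[[1]], b$chains[[1]]))
}
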