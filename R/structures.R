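#' Nucleosome rigid-body frame
#'
#' A nucleosome is represented by its geometric center, an orthonormal
#' right-handed frame (two in-plane axes and the plane normal) and the wrap
#' fraction of its outer DNA layer.  The wrap fraction lives in
#' `[w_min, 1]` with `w_min = 0.5`: only the outer DNA layer can detach,
#' the inner wrap stays bound to the histone core.
#'
#' @param chain_id integer chain identifier (1-based).
#' @param index 0-based position of the nucleosome along its chain.
#' @param center numeric length-3 center, nm.
#' @param axis_a,axis_b in-plane unit vectors.
#' @param normal unit vector normal to the nucleosomal plane.
#' @param wrap wrap fraction in `[0.5, 1]`.
#' @return an object of class `nucleosome_frame`.
#' @export
nucleosome_frame <- function(chain_id, index, center, axis_a, axis_b, normal,
                             wrap = 1) {
  f <- list(chain_id = as.integer(chain_id), index = as.integer(index),
            center = as.numeric(center), axis_a = as.numeric(axis_a),
            axis_b = as.numeric(axis_b), normal = as.numeric(normal),
            wrap = as.numeric(wrap))
  validate_frame(f)
  class(f) <- "nucleosome_frame"
  f
}

WRAP_MIN <- 0.5

validate_frame <- function(f, tol = 1e-8) {
  stopifnot(length(f$center) == 3, length(f$axis_a) == 3,
            length(f$axis_b) == 3, length(f$normal) == 3)
  R <- rbind(f$axis_a, f$axis_b, f$normal)
  dev <- max(abs(R %*% t(R) - diag(3)))
  if (dev > tol)
    stop("frame axes are not orthonormal (deviation ", signif(dev, 3), ")")
  if (is.na(f$wrap) || f$wrap < WRAP_MIN - 1e-12 || f$wrap > 1 + 1e-12)
    stop("wrap fraction must lie in [", WRAP_MIN, ", 1], got ", f$wrap)
  invisible(TRUE)
}

#' Chromatin configuration
#'
#' An ordered set of nucleosome frames organised in one or two chains.  Each
#' chain is stored column-wise as matrices (`centers`, `axis_a`, `axis_b`,
#' `normal`, each n x 3) plus a `wrap` vector, which is the natural layout for
#' collective-variable computation.  DNA endpoints may be stored explicitly
#' (2 x 3 matrix per chain); when absent they are derived from the terminal
#' nucleosome centers extrapolated along the terminal linker direction by
#' `overhang` nm (default 0, i.e. endpoints coincide with terminal centers).
#'
#' @param chains a list of 1 or 2 chains; each chain is a list with elements
#'   `centers`, `axis_a`, `axis_b`, `normal` (n x 3 matrices), `wrap`
#'   (length n), and optionally `endpoints` (2 x 3 matrix, nm).
#' @return an object of class `chromatin_config`.
#' @export
chromatin_config <- function(chains) {
  if (length(chains) < 1 || length(chains) > 2)
    stop("a configuration holds one or two chains")
  chains <- lapply(chains, normalize_chain)
  structure(list(chains = chains), class = "chromatin_config")
}

normalize_chain <- function(ch) {
  for (nm in c("centers", "axis_a", "axis_b", "normal"))
    ch[[nm]] <- matrix(as.numeric(ch[[nm]]), ncol = 3)
  n <- nrow(ch$centers)
  if (n < 1) stop("every chain needs at least one nucleosome")
  if (is.null(ch$wrap)) ch$wrap <- rep(1, n)
  if (length(ch$wrap) != n) stop("wrap length does not match chain length")
  if (any(ch$wrap < WRAP_MIN - 1e-12 | ch$wrap > 1 + 1e-12))
    stop("wrap fractions must lie in [", WRAP_MIN, ", 1]")
  for (i in seq_len(n)) {
    R <- rbind(ch$axis_a[i, ], ch$axis_b[i, ], ch$normal[i, ])
    dev <- max(abs(R %*% t(R) - diag(3)))
    if (dev > 1e-8) stop("non-orthonormal frame at nucleosome ", i - 1)
  }
  ch[c("centers", "axis_a", "axis_b", "normal", "wrap", "endpoints")]
}

#' @export
print.chromatin_config <- function(x, ...) {
  ns <- vapply(x$chains, function(ch) nrow(ch$centers), integer(1))
  cat("<chromatin_config> ", length(x$chains), " chain(s): ",
      paste(ns, collapse = " + "), " nucleosomes\n", sep = "")
  invisible(x)
}

#' Number of chains / chain length helpers
#' @param config a `chromatin_config`.
#' @param chain chain index (1-based).
#' @export
n_chains <- function(config) length(config$chains)

#' @rdname n_chains
#' @export
chain_length <- function(config, chain = 1) nrow(config$chains[[chain]]$centers)

#' Extract one nucleosome frame from a configuration
#' @inheritParams n_chains
#' @param index 0-based nucleosome index along the chain.
#' @export
get_frame <- function(config, chain, index) {
  ch <- config$chains[[chain]]
  i <- index + 1L
  nucleosome_frame(chain, index, ch$centers[i, ], ch$axis_a[i, ],
                   ch$axis_b[i, ], ch$normal[i, ], ch$wrap[i])
}

#' DNA endpoints of a chain
#'
#' Stored endpoints are returned as-is.  Otherwise endpoints are derived from
#' the terminal nucleosome centers, extrapolated outward along the terminal
#' linker direction by `overhang` nm:
#' `e_first = c_1 - overhang * unit(c_2 - c_1)` and symmetrically for the
#' last nucleosome.  For a single-nucleosome chain both endpoints equal the
#' center.
#'
#' @inheritParams n_chains
#' @param overhang extrapolation length in nm (default 0).
#' @return a 2 x 3 matrix (first endpoint, last endpoint).
#' @export
dna_endpoints <- function(config, chain = 1, overhang = 0) {
  ch <- config$chains[[chain]]
  if (!is.null(ch$endpoints)) return(matrix(ch$endpoints, ncol = 3))
  x <- ch$centers
  n <- nrow(x)
  if (n == 1) return(rbind(x[1, ], x[1, ]))
  u1 <- x[2, ] - x[1, ]; u1 <- u1 / sqrt(sum(u1^2))
  u2 <- x[n, ] - x[n - 1, ]; u2 <- u2 / sqrt(sum(u2^2))
  rbind(x[1, ] - overhang * u1, x[n, ] + overhang * u2)
}

#' Bead accounting for a residue-level coarse-grained nucleosome array
#'
#' Counts the coarse-grained sites of an n-nucleosome array modelled with one
#' bead per amino acid and three sites per nucleotide, where the 5'-terminal
#' nucleotide of each DNA strand lacks its phosphate site.  Each nucleosome
#' wraps `wrapped_bp` base pairs (147) and consecutive nucleosomes are joined
#' by `linker_bp` base pairs of linker DNA.
#'
#' @param n_nucleosomes number of nucleosomes (>= 1).
#' @param linker_bp linker length in base pairs (>= 0).
#' @param octamer_residues residues per histone octamer (974: the 1KX5
#'   construct, 2 x (135 + 102 + 128 + 122)).
#' @param wrapped_bp base pairs wrapped per nucleosome (147).
#' @return a list of class `bead_topology` with fields `n_nucleosomes`,
#'   `linker_bp`, `wrapped_bp`, `octamer_residues`, `total_bp`,
#'   `protein_beads`, `dna_beads`, `total_beads`.
#' @examples
#' build_topology(12, 20)$total_beads  # 23590
#' @export
build_topology <- function(n_nucleosomes, linker_bp = 20,
                           octamer_residues = 974, wrapped_bp = 147) {
  if (n_nucleosomes < 1) stop("need at least one nucleosome")
  if (linker_bp < 0) stop("linker length cannot be negative")
  total_bp <- n_nucleosomes * wrapped_bp + (n_nucleosomes - 1) * linker_bp
  dna_beads <- 2 * (3 * total_bp - 1)   # per strand: 3 sites/nt minus one 5' phosphate
  protein_beads <- n_nucleosomes * octamer_residues
  structure(list(n_nucleosomes = n_nucleosomes, linker_bp = linker_bp,
                 wrapped_bp = wrapped_bp, octamer_residues = octamer_residues,
                 total_bp = total_bp, protein_beads = protein_beads,
                 dna_beads = dna_beads,
                 total_beads = protein_beads + dna_beads),
            class = "bead_topology")
}

#' Build nucleosome frames from bead coordinates
#'
#' Reduces a bead-level snapshot to nucleosome frames.  The center of each
#' nucleosome is the unweighted mean of its beads; the frame axes are the
#' principal components of its wrapped-DNA beads (or of all its beads when no
#' `role` column distinguishes them), with the normal along the
#' smallest-variance direction.  Normal signs are aligned so consecutive
#' nucleosome normals have non-negative dot product where possible.
#'
#' @param bead_coords N x 3 matrix of bead positions, nm.
#' @param bead_map data frame with one row per bead: columns `chain` (integer),
#'   `nucleosome` (0-based index, `NA` for linker beads) and optionally `role`
#'   (`"dna_wrapped"` beads define the principal axes when present).
#' @return a `chromatin_config` (wrap fractions set to 1).
#' @export
frames_from_beads <- function(bead_coords, bead_map) {
  bead_coords <- matrix(as.numeric(bead_coords), ncol = 3)
  stopifnot(nrow(bead_coords) == nrow(bead_map))
  chains <- list()
  for (cid in sort(unique(bead_map$chain))) {
    sel_chain <- bead_map$chain == cid & !is.na(bead_map$nucleosome)
    idx <- sort(unique(bead_map$nucleosome[sel_chain]))
    if (!identical(as.integer(idx), seq_along(idx) - 1L))
      stop("nucleosome indices must be consecutive from 0 in chain ", cid)
    n <- length(idx)
    centers <- aa <- bb <- nn <- matrix(0, n, 3)
    for (k in seq_len(n)) {
      sel <- sel_chain & bead_map$nucleosome == idx[k]
      pts <- bead_coords[sel, , drop = FALSE]
      if (nrow(pts) < 3) stop("nucleosome ", idx[k], " has fewer than 3 beads")
      centers[k, ] <- colMeans(pts)
      axsel <- sel
      if (!is.null(bead_map$role) && any(bead_map$role[sel] == "dna_wrapped"))
        axsel <- sel & bead_map$role == "dna_wrapped"
      apts <- bead_coords[axsel, , drop = FALSE]
      apts <- sweep(apts, 2, colMeans(apts))
      ev <- eigen(crossprod(apts) / nrow(apts), symmetric = TRUE)
      if (ev$values[2] < 1e-12)
        stop("degenerate (collinear) bead set for nucleosome ", idx[k])
      a <- ev$vectors[, 1]; b <- ev$vectors[, 2]
      nrm <- c(a[2] * b[3] - a[3] * b[2],     # right-handed: n = a x b
               a[3] * b[1] - a[1] * b[3],
               a[1] * b[2] - a[2] * b[1])
      if (k > 1 && sum(nrm * nn[k - 1, ]) < 0) { nrm <- -nrm; b <- -b }
      aa[k, ] <- a; bb[k, ] <- b; nn[k, ] <- nrm
    }
    chains[[length(chains) + 1]] <-
      list(centers = centers, axis_a = aa, axis_b = bb, normal = nn,
           wrap = rep(1, n))
  }
  chromatin_config(chains)
}

#' Apply a rigid motion to a configuration
#'
#' @inheritParams n_chains
#' @param R 3 x 3 rotation matrix.
#' @param t length-3 translation, nm.
#' @return the transformed `chromatin_config`.
#' @export
transform_config <- function(config, R = diag(3), t = c(0, 0, 0)) {
  config$chains <- lapply(config$chains, function(ch) {
    ch$centers <- sweep(ch$centers %*% t(R), 2, t, `+`)
    for (nm in c("axis_a", "axis_b", "normal")) ch[[nm]] <- ch[[nm]] %*% t(R)
    if (!is.null(ch$endpoints))
      ch$endpoints <- sweep(ch$endpoints %*% t(R), 2, t, `+`)
    ch
  })
  config
}
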