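## Molecular electrostatic potential on shell grids and model comparison.
## The shell grid keeps cubic-lattice points whose distance to the closest
## protein atom lies in [r_min, r_max] (defaults 2.5-4.5 Angstrom);
## potentials are point-charge Coulomb sums in atomic units.

#' Generate a shell grid around a structure
#'
#' Regular cubic lattice over the bounding box padded by `r_max`, filtered
#' to points whose closest-atom distance lies in [r_min, r_max].
#' Deterministic.
#'
#' @param structure a Structure.
#' @param r_min,r_max shell bounds in Angstrom (default 2.5 / 4.5).
#' @param spacing lattice spacing, Angstrom.
#' @return object of class `ShellGrid`: list(points, dmin, r_min, r_max,
#'   spacing).
#' @export
generate_shell_grid <- function(structure, r_min = 2.5, r_max = 4.5,
                                spacing = 0.8) {
  if (!(r_max > r_min && r_min > 0)) stop("need r_max > r_min > 0")
  xyz <- coords(structure)
  lo <- apply(xyz, 2, min) - r_max
  hi <- apply(xyz, 2, max) + r_max
  ax <- lapply(1:3, function(k) seq(lo[k], hi[k], by = spacing))
  pts <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]],
                               KEEP.OUT.ATTRS = FALSE))
  colnames(pts) <- NULL
  # chunked min-distance to avoid a huge single allocation
  dmin <- numeric(nrow(pts))
  step <- 20000L
  for (s in seq(1L, nrow(pts), by = step)) {
    e <- min(s + step - 1L, nrow(pts))
    dmin[s:e] <- sqrt(apply(cross_dist2(pts[s:e, , drop = FALSE], xyz),
                            1, min))
  }
  keep <- dmin >= r_min & dmin <= r_max
  if (!any(keep)) stop("empty shell grid; decrease spacing")
  structure(list(points = pts[keep, , drop = FALSE], dmin = dmin[keep],
                 r_min = r_min, r_max = r_max, spacing = spacing),
            class = "ShellGrid")
}

#' Evaluate the point-charge potential on grid points
#'
#' V(g) = sum_k q_k / |g - r_k| in atomic units (hartree/e), with the
#' Angstrom -> bohr conversion applied to distances.
#'
#' @param charges a ChargeSet.
#' @param structure the Structure carrying the charge positions.
#' @param grid a `ShellGrid` or a plain m x 3 matrix (Angstrom).
#' @return numeric vector of potentials (au).
#' @export
evaluate_potential <- function(charges, structure, grid) {
  pts <- if (inherits(grid, "ShellGrid")) grid$points else as.matrix(grid)
  xyz <- coords(structure)
  if (length(charges$charges) != nrow(xyz))
    stop("charges not aligned to structure")
  v <- numeric(nrow(pts))
  step <- 20000L
  for (s in seq(1L, nrow(pts), by = step)) {
    e <- min(s + step - 1L, nrow(pts))
    d <- sqrt(cross_dist2(pts[s:e, , drop = FALSE], xyz))
    if (any(d < 1e-9)) stop("grid point coincides with an atom")
    v[s:e] <- (d^-1 %*% charges$charges) / ANG_PER_BOHR
  }
  v
}

#' Compare two potentials on a shared grid
#'
#' @param a,b numeric potential vectors on the same grid.
#' @return object of class `MEPComparison`: list(rmsd, pearson, n).
#'   Pearson is reported as 1 for identical constant vectors.
#' @export
compare_mep <- function(a, b) {
  if (length(a) != length(b)) stop("potential length mismatch")
  d <- a - b
  rmsd <- sqrt(mean(d^2))
  r <- if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    if (all(d == d[1])) 1 else NA_real_
  } else stats::cor(a, b)
  structure(list(rmsd = rmsd, pearson = r, n = length(a)),
            class = "MEPComparison")
}

#' @export
print.MEPComparison <- function(x, ...) {
  cat(sprintf("MEP comparison over %d points: RMSD %.3e au, r = %.6f\n",
              x$n, x$rmsd, x$pearson))
  invisible(x)
}

#' MEP RMSD as a function of the two-body distance threshold
#'
#' Assembles charges at each lambda, evaluates the potential on the shell
#' grid, and reports RMSD (and Pearson r) against a reference potential.
#'
#' @param structure a Structure.
#' @param backend a `qm_backend`.
#' @param reference embedding ChargeSet.
#' @param lambdas ascending thresholds, Angstrom.
#' @param grid a `ShellGrid`.
#' @param ref_potential reference potential on the grid; defaults to the
#'   potential of `reference` itself.
#' @param config a [fit_config()].
#' @return data.frame(lambda, n_pairs, rmsd, pearson).
#' @export
lambda_sweep <- function(structure, backend, reference, lambdas, grid,
                         ref_potential = NULL, config = fit_config()) {
  stopifnot(all(diff(lambdas) >= 0))
  if (is.null(ref_potential))
    ref_potential <- evaluate_potential(reference, structure, grid)
  rows <- lapply(lambdas, function(lam) {
    res <- ee_gmfcc_charges(structure, backend, reference, lambda = lam,
                            config = config)
    v <- evaluate_potential(res$charges, structure, grid)
    cmp <- compare_mep(v, ref_potential)
    data.frame(lambda = lam,
               n_pairs = length(find_two_body_pairs(structure, lam)),
               rmsd = cmp$rmsd, pearson = cmp$pearson)
  })
  do.call(rbind, rows)
}
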