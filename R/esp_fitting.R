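## ESP / RESP charge fitting on Merz-Kollman shell grids.
##
## The fit minimizes sum_g (V_model(g) - V_QM(g))^2 plus quadratic penalty
## restraints, subject to the hard total-charge constraint sum(q) = Q. The
## hard constraint is eliminated through a null-space parametrization and
## the remaining least-squares problem solved by QR, which is substantially
## better conditioned than the normal-equation KKT system. Link-atom
## equality restraints (concap link H constrained to the corresponding
## fragment link H) enter as penalty rows with weight w_link.

#' Merz-Kollman surface grid
#'
#' Deterministic Fibonacci-lattice points on scaled van der Waals spheres,
#' excluding points falling inside any other atom's sphere at the same
#' scale. No randomness is involved.
#'
#' @param positions n x 3 matrix (Angstrom).
#' @param radii per-atom vdW radii (Angstrom), positive.
#' @param shells ascending scale factors, all > 1.
#' @param density surface point density, points per square Angstrom.
#' @return m x 3 matrix of grid points.
#' @export
generate_mk_grid <- function(positions, radii,
                             shells = c(1.4, 1.6, 1.8, 2.0),
                             density = 1.0) {
  stopifnot(all(radii > 0), all(diff(shells) > 0) || length(shells) == 1,
            all(shells > 1))
  positions <- as.matrix(positions)
  n <- nrow(positions)
  ga <- pi * (3 - sqrt(5))  # golden angle
  fib_sphere <- function(m) {
    i <- seq_len(m) - 0.5
    z <- 1 - 2 * i / m
    r <- sqrt(pmax(0, 1 - z^2))
    th <- ga * (seq_len(m) - 1)
    cbind(r * cos(th), r * sin(th), z)
  }
  out <- list()
  for (s in shells) {
    rs <- s * radii
    for (a in seq_len(n)) {
      m <- max(1L, round(4 * pi * rs[a]^2 * density))
      pts <- matrix(positions[a, ], m, 3, byrow = TRUE) + rs[a] * fib_sphere(m)
      if (n > 1) {
        d2 <- cross_dist2(pts, positions[-a, , drop = FALSE])
        keep <- rowSums(d2 < matrix((rs[-a] - 1e-9)^2, m, n - 1,
                                    byrow = TRUE)) == 0
        pts <- pts[keep, , drop = FALSE]
      }
      out[[length(out) + 1L]] <- pts
    }
  }
  grid <- do.call(rbind, out)
  if (!nrow(grid)) stop("empty MK grid; increase density or shells")
  grid
}

#' Fit point charges to an ESP (constrained linear least squares)
#'
#' @param grid m x 3 matrix of grid points (Angstrom).
#' @param esp ESP values at the grid points (atomic units).
#' @param positions n x 3 matrix of fitted-charge sites (Angstrom).
#' @param total_charge hard constraint on sum(q), satisfied to machine
#'   precision.
#' @param restraints optional data.frame(atom, target, weight) of quadratic
#'   equality restraints, weight in au/e^2.
#' @param resp if TRUE apply the iterative hyperbolic RESP zero-restraint
#'   to atoms flagged heavy in `heavy` (off by default).
#' @param resp_a,resp_b hyperbolic restraint strength and width (au).
#' @param heavy logical vector marking non-hydrogen sites (required when
#'   `resp` is TRUE).
#' @return object of class `FittedCharges`: list(charges, rms, condition,
#'   n_grid).
#' @export
fit_charges <- function(grid, esp, positions, total_charge,
                        restraints = NULL, resp = FALSE,
                        resp_a = 5e-4, resp_b = 0.1, heavy = NULL) {
  grid <- as.matrix(grid)
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (nrow(grid) < n)
    stop("grid must contain at least as many points as fitted charges")
  if (length(esp) != nrow(grid)) stop("esp length != grid length")

  A <- 1 / (sqrt(cross_dist2(grid, positions)) * ANG_PER_BOHR)
  B <- A
  rhs <- esp
  if (!is.null(restraints) && nrow(restraints)) {
    stopifnot(all(restraints$weight >= 0))
    E <- matrix(0, nrow(restraints), n)
    E[cbind(seq_len(nrow(restraints)), restraints$atom)] <-
      sqrt(restraints$weight)
    B <- rbind(B, E)
    rhs <- c(rhs, sqrt(restraints$weight) * restraints$target)
  }

  # null-space elimination of the hard constraint sum(q) = Q
  Z <- qr.Q(qr(matrix(1, n, 1)), complete = TRUE)[, -1, drop = FALSE]
  q0 <- rep(total_charge / n, n)

  solve_ls <- function(Bm, rv) {
    BZ <- Bm %*% Z
    dec <- qr(BZ)
    if (dec$rank < ncol(BZ))
      stop("singular ESP-fit system; add grid points or restraints")
    list(q = q0 + as.numeric(Z %*% qr.coef(dec, rv - Bm %*% q0)),
         cond = kappa(dec$qr, exact = FALSE))
  }
  sol <- solve_ls(B, rhs)
  q <- sol$q

  if (resp) {
    if (is.null(heavy)) stop("resp = TRUE requires the 'heavy' flag vector")
    for (it in 1:25) {
      w <- ifelse(heavy, resp_a / sqrt(q^2 + resp_b^2), 0)
      Er <- diag(sqrt(w), n)
      sol2 <- solve_ls(rbind(B, Er), c(rhs, rep(0, n)))
      if (max(abs(sol2$q - q)) < 1e-9) { q <- sol2$q; break }
      q <- sol2$q
    }
    sol$cond <- sol2$cond
  }

  resid <- as.numeric(A %*% q) - esp
  structure(list(charges = q, rms = sqrt(mean(resid^2)),
                 condition = sol$cond, n_grid = nrow(grid)),
            class = "FittedCharges")
}

#' Fitting configuration
#'
#' @param shells MK shell scale factors.
#' @param density grid density, points / A^2.
#' @param w_link penalty weight (au/e^2) tying concap link-atom charges to
#'   the corresponding fragment link-atom charges.
#' @param resp enable the hyperbolic RESP zero-restraint on heavy atoms.
#' @param resp_a,resp_b hyperbolic restraint parameters (au).
#' @export
fit_config <- function(shells = c(1.4, 1.6, 1.8, 2.0), density = 1.0,
                       w_link = 0.1, resp = FALSE,
                       resp_a = 5e-4, resp_b = 0.1) {
  list(shells = shells, density = density, w_link = w_link,
       resp = resp, resp_a = resp_a, resp_b = resp_b)
}

#' Fit the charges of one embedded subsystem
#'
#' Builds the MK grid over the subsystem (parent + link atoms), obtains the
#' embedded ESP from the backend, and fits charges with the hard net-charge
#' constraint. For concaps, `link_targets` supplies per-label equality
#' restraints toward the already-fitted fragment link-atom values.
#'
#' @param structure a Structure.
#' @param subsystem a Subsystem.
#' @param backend a `qm_backend`.
#' @param reference ChargeSet for the embedding background.
#' @param config a [fit_config()].
#' @param link_targets optional named numeric vector (names = link labels).
#' @param extra_background optional data.frame (x, y, z, q) appended to the
#'   embedding background (e.g. PB surface charges).
#' @return list(subsystem, parent_charges, link_charges, rms, condition).
#' @export
fit_subsystem <- function(structure, subsystem, backend, reference,
                          config = fit_config(), link_targets = NULL,
                          extra_background = NULL) {
  np <- length(subsystem$atom_idx)
  nl <- nrow(subsystem$link_atoms)
  pos <- rbind(coords(structure)[subsystem$atom_idx, , drop = FALSE],
               as.matrix(subsystem$link_atoms[, c("x", "y", "z"),
                                              drop = FALSE]))
  radii <- c(structure$atoms$radius[subsystem$atom_idx],
             rep(.DEFAULT_VDW[["H"]], nl))
  grid <- generate_mk_grid(pos, radii, config$shells, config$density)

  bg <- background_charges(structure, subsystem, reference)
  if (!is.null(extra_background) && nrow(extra_background))
    bg <- rbind(bg, extra_background[, c("x", "y", "z", "q")])

  task <- qm_task(structure, subsystem, grid = grid, background = bg)
  res <- compute_esp(backend, task)
  if (!isTRUE(res$converged))
    warning("backend flagged non-convergence for ", subsystem$id)

  restraints <- NULL
  if (!is.null(link_targets) && nl > 0) {
    lab <- subsystem$link_atoms$label
    hit <- lab %in% names(link_targets)
    if (any(!hit))
      stop("no fragment link-atom correspondence for label(s): ",
           paste(lab[!hit], collapse = ", "))
    restraints <- data.frame(atom = np + which(hit),
                             target = unname(link_targets[lab[hit]]),
                             weight = config$w_link)
  }

  fit <- fit_charges(grid, res$esp, pos, subsystem$net_charge,
                     restraints = restraints, resp = config$resp,
                     resp_a = config$resp_a, resp_b = config$resp_b,
                     heavy = c(structure$atoms$element[subsystem$atom_idx],
                               rep("H", nl)) != "H")
  lq <- fit$charges[np + seq_len(nl)]
  names(lq) <- subsystem$link_atoms$label
  list(subsystem = subsystem,
       parent_charges = fit$charges[seq_len(np)],
       link_charges = lq, rms = fit$rms, condition = fit$condition,
       n_grid = fit$n_grid, energy = res$energy)
}

#' Fit every subsystem of a fragmented structure
#'
#' Fragments are fitted first; concap link atoms are then restrained to the
#' fragment values matched by cut-bond label; two-body pair subsystems and
#' their monomers are fitted last under identical grid rules.
#'
#' @param structure a Structure.
#' @param backend a `qm_backend`.
#' @param reference embedding ChargeSet.
#' @param lambda two-body distance threshold, Angstrom.
#' @param config a [fit_config()].
#' @param extra_background optional surface-charge background.
#' @return list(fragments, concaps, pairs) of fit results.
#' @export
fit_all_subsystems <- function(structure, backend, reference, lambda = 4.0,
                               config = fit_config(),
                               extra_background = NULL) {
  frags <- build_fragments(structure)
  caps <- build_concaps(structure)
  pairs <- build_pair_subsystems(structure,
                                 find_two_body_pairs(structure, lambda))

  frag_fits <- lapply(frags, fit_subsystem, structure = structure,
                      backend = backend, reference = reference,
                      config = config, extra_background = extra_background)

  # label -> fitted fragment link charge
  link_targets <- unlist(lapply(frag_fits, `[[`, "link_charges"))
  cap_fits <- lapply(caps, fit_subsystem, structure = structure,
                     backend = backend, reference = reference,
                     config = config, link_targets = link_targets,
                     extra_background = extra_background)

  pair_fits <- lapply(pairs, function(p) {
    list(i = p$i, j = p$j, dist = p$dist,
         pair = fit_subsystem(structure, p$pair, backend, reference,
                              config, extra_background = extra_background),
         mono_i = fit_subsystem(structure, p$mono_i, backend, reference,
                                config, extra_background = extra_background),
         mono_j = fit_subsystem(structure, p$mono_j, backend, reference,
                                config, extra_background = extra_background))
  })

  list(fragments = frag_fits, concaps = cap_fits, pairs = pair_fits)
}
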