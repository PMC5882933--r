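## QM backend contract: compute the ESP of a capped, electrostatically
## embedded subsystem on a grid. Ships a deterministic mock backend whose
## ESP is the Coulomb potential of the bundled reference charges, with an
## optional linear polarization response to the embedding field. The
## returned ESP always excludes the background charges' own Coulomb field:
## fitted charges must represent the subsystem alone.

# per-element mock atomic energy constants (hartree), used by the mock
# backend's energy; arbitrary but fixed values
.MOCK_EATOM <- c(H = -0.5, C = -37.8, N = -54.4, O = -74.8, S = -397.5)

#' Create a QM task
#'
#' @param structure a Structure (parent geometry).
#' @param subsystem a Subsystem (atoms + link atoms).
#' @param grid numeric g x 3 matrix of ESP evaluation points (Angstrom);
#'   may be NULL for energy-only tasks.
#' @param background data.frame (x, y, z, q) of embedding point charges.
#' @param multiplicity spin multiplicity (>= 1).
#' @return object of class `QMTask`.
#' @export
qm_task <- function(structure, subsystem, grid = NULL,
                    background = NULL, multiplicity = 1L) {
  stopifnot(multiplicity >= 1)
  pos <- coords(structure)[subsystem$atom_idx, , drop = FALSE]
  lpos <- as.matrix(subsystem$link_atoms[, c("x", "y", "z"), drop = FALSE])
  structure(list(parent_idx = subsystem$atom_idx,
                 positions = pos, link_positions = lpos,
                 elements = structure$atoms$element[subsystem$atom_idx],
                 net_charge = subsystem$net_charge,
                 multiplicity = as.integer(multiplicity),
                 background = background, grid = grid,
                 label = subsystem$id),
            class = "QMTask")
}

# content key for result caching (bit-stable for identical inputs)
.task_key <- function(task) {
  num <- c(task$positions, task$link_positions, task$grid,
           if (!is.null(task$background) && nrow(task$background))
             unlist(task$background[, c("x", "y", "z", "q")]))
  paste0(task$label, "|", task$net_charge, "|",
         paste(format(num, digits = 17), collapse = ","))
}

#' Deterministic mock ESP backend
#'
#' The mock ESP is the Coulomb potential (atomic units) of the reference
#' charges placed on the subsystem's parent atoms, link atoms carrying zero
#' charge so parent-residue totals are preserved. With
#' `polarization_gain > 0` each parent charge is shifted by
#' `gain * (E_bg . u_k)` where `E_bg` is the embedding field at the atom
#' (e/A^2) and `u_k` the unit vector from the subsystem centroid to the
#' atom; shifts are mean-centered so the subsystem net charge is preserved.
#' `gain = 0` gives the exact-recovery oracle. Results are memoized on a
#' content key of the task.
#'
#' @param reference a ChargeSet aligned to the parent structure.
#' @param polarization_gain dimensionless linear-response gain
#'   (e per unit field, e/A^2).
#' @param energy_mode "coulomb" (atomic constants + internal Coulomb +
#'   background interaction) or "additive" (atomic constants only).
#' @return object of class `qm_backend`.
#' @export
mock_esp_backend <- function(reference, polarization_gain = 0,
                             energy_mode = c("coulomb", "additive")) {
  energy_mode <- match.arg(energy_mode)
  structure(list(kind = "mock", reference = reference,
                 gain = polarization_gain, energy_mode = energy_mode,
                 cache = new.env(parent = emptyenv())),
            class = "qm_backend")
}

#' Adapter stub for a real ab initio backend
#'
#' The package defines the backend contract only; an external engine must
#' be supplied by the user. Calling it without one raises an informative
#' error.
#'
#' @param engine a function(task) -> QMResult, or NULL.
#' @export
ab_initio_backend <- function(engine = NULL) {
  structure(list(kind = "ab_initio", engine = engine,
                 cache = new.env(parent = emptyenv())),
            class = "qm_backend")
}

# effective mock charges of a task (parent charges + polarization response,
# link atoms zero)
.mock_charges <- function(backend, task) {
  q <- backend$reference$charges[task$parent_idx]
  if (backend$gain != 0 && !is.null(task$background) &&
      nrow(task$background) > 0) {
    bg <- as.matrix(task$background[, c("x", "y", "z")])
    bq <- task$background$q
    ctr <- colMeans(task$positions)
    shift <- vapply(seq_len(nrow(task$positions)), function(k) {
      r <- task$positions[k, ]
      dv <- matrix(r, nrow(bg), 3, byrow = TRUE) - bg
      d3 <- pmax(rowSums(dv * dv), 1e-12)^1.5
      E <- colSums(dv * bq / d3)           # field in e / A^2
      u <- r - ctr
      nu <- sqrt(sum(u * u))
      if (nu < 1e-9) 0 else sum(E * u) / nu
    }, numeric(1))
    q <- q + backend$gain * (shift - mean(shift))
  }
  q
}

#' Compute the ESP (and mock energy) of a task
#'
#' @param backend a `qm_backend`.
#' @param task a `QMTask`.
#' @return a `QMResult`: list with `esp` (au, one value per grid point),
#'   `energy` (hartree), `charges_used`, `converged`, `backend`.
#' @export
compute_esp <- function(backend, task) {
  stopifnot(inherits(backend, "qm_backend"), inherits(task, "QMTask"))
  key <- .task_key(task)
  cache <- backend$cache
  if (is.null(cache$keys)) { cache$keys <- character(); cache$vals <- list() }
  hit <- match(key, cache$keys)
  if (!is.na(hit)) return(cache$vals[[hit]])
  res <- if (backend$kind == "mock") {
    .mock_compute(backend, task)
  } else {
    if (is.null(backend$engine))
      stop("ab initio backend requested but no engine is configured")
    backend$engine(task)
  }
  cache$keys <- c(cache$keys, key)
  cache$vals <- c(cache$vals, list(res))
  res
}

.mock_compute <- function(backend, task) {
  qp <- .mock_charges(backend, task)
  allpos <- rbind(task$positions, task$link_positions)
  allq <- c(qp, rep(0, nrow(task$link_positions)))
  esp <- NULL
  if (!is.null(task$grid) && nrow(task$grid) > 0) {
    d <- sqrt(cross_dist2(task$grid, allpos))     # Angstrom
    esp <- as.numeric((d^-1 %*% allq) / ANG_PER_BOHR)   # hartree / e
  }
  # mock energy in hartree
  energy <- sum(.MOCK_EATOM[task$elements]) +
    sum(.MOCK_EATOM[["H"]] * rep(1, nrow(task$link_positions)))
  if (backend$energy_mode == "coulomb") {
    if (nrow(allpos) > 1) {
      d <- sqrt(cross_dist2(allpos, allpos)) * ANG_PER_BOHR
      iu <- upper.tri(d)
      energy <- energy + sum((outer(allq, allq)[iu]) / d[iu])
    }
    if (!is.null(task$background) && nrow(task$background) > 0) {
      bg <- as.matrix(task$background[, c("x", "y", "z")])
      d <- sqrt(cross_dist2(allpos, bg)) * ANG_PER_BOHR
      energy <- energy + sum(outer(allq, task$background$q) / d)
    }
  }
  structure(list(esp = esp, energy = energy, charges_used = allq,
                 converged = TRUE, backend = "mock"),
            class = "QMResult")
}
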