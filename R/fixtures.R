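## Ideal-geometry peptide fixture generator: small polypeptides built from
## standard bond lengths/angles with configurable backbone torsions,
## conformer ensembles, and a guaranteed-contact (helical) fixture.
##
## Geometry constants (Angstrom / degrees), Engh-Huber-like ideal values:
##   N-CA 1.458   CA-C 1.525   C-N 1.329   C=O 1.231   C-OXT 1.350 (acid)
##   C-OXT 1.250 (carboxylate)   N-H 1.010   C-H 1.090   O-H 0.960
##   N-CA-C 111.2   CA-C-N 116.2   C-N-CA 121.7   CA-C-O 120.8   omega 180

.AA1TO3 <- c(A = "ALA", G = "GLY", S = "SER", V = "VAL", E = "GLU",
             K = "LYS")

# run code under a temporary RNG seed, restoring global RNG state after
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# append one atom row to the growing builder state
.add_atom <- function(state, name, element, pos) {
  state$rows[[length(state$rows) + 1L]] <-
    list(name = name, element = element, x = pos[1], y = pos[2], z = pos[3],
         residue_index = state$ri, resname = state$resname)
  state
}

.methylene <- function(state, names, center, n1, n2, bond = 1.090) {
  dirs <- tetrahedral_pair(vunit(n1 - center), vunit(n2 - center))
  state <- .add_atom(state, names[1], "H", center + bond * dirs[1, ])
  .add_atom(state, names[2], "H", center + bond * dirs[2, ])
}

.methyl <- function(state, names, a, b, c, bond = 1.090, angle = 109.5,
                    el = "H") {
  for (k in 1:3) {
    state <- .add_atom(state, names[k], el,
                       place_atom(a, b, c, bond, angle, 60 + 120 * (k - 1)))
  }
  state
}

.sidechain <- function(state, res, N, CA, C, CB, chi) {
  u <- function(p) vunit(p - CB)
  if (res == "ALA") {
    state <- .methyl(state, c("HB1", "HB2", "HB3"), N, CA, CB)
  } else if (res == "SER") {
    OG <- place_atom(N, CA, CB, 1.417, 110.5, chi[1])
    state <- .add_atom(state, "OG", "O", OG)
    state <- .methylene(state, c("HB2", "HB3"), CB, CA, OG)
    state <- .add_atom(state, "HG", "H", place_atom(CA, CB, OG, 0.96, 108.5, 180))
  } else if (res == "VAL") {
    CG1 <- place_atom(N, CA, CB, 1.527, 110.5, chi[1])
    CG2 <- place_atom(N, CA, CB, 1.527, 110.5, chi[1] - 120)
    state <- .add_atom(state, "CG1", "C", CG1)
    state <- .add_atom(state, "CG2", "C", CG2)
    hb <- -vunit(u(CA) + u(CG1) + u(CG2))
    state <- .add_atom(state, "HB", "H", CB + 1.090 * hb)
    state <- .methyl(state, c("HG11", "HG12", "HG13"), CA, CB, CG1)
    state <- .methyl(state, c("HG21", "HG22", "HG23"), CA, CB, CG2)
  } else if (res == "GLU") {
    CG <- place_atom(N, CA, CB, 1.530, 111.0, chi[1])
    CD <- place_atom(CA, CB, CG, 1.522, 112.0, chi[2])
    state <- .add_atom(state, "CG", "C", CG)
    state <- .add_atom(state, "CD", "C", CD)
    state <- .add_atom(state, "OE1", "O", place_atom(CB, CG, CD, 1.250, 117.0, 0))
    state <- .add_atom(state, "OE2", "O", place_atom(CB, CG, CD, 1.250, 117.0, 180))
    state <- .methylene(state, c("HB2", "HB3"), CB, CA, CG)
    state <- .methylene(state, c("HG2", "HG3"), CG, CB, CD)
  } else if (res == "LYS") {
    CG <- place_atom(N, CA, CB, 1.530, 111.0, chi[1])
    CD <- place_atom(CA, CB, CG, 1.530, 111.0, chi[2])
    CE <- place_atom(CB, CG, CD, 1.530, 111.0, chi[3])
    NZ <- place_atom(CG, CD, CE, 1.470, 110.0, chi[4])
    state <- .add_atom(state, "CG", "C", CG)
    state <- .add_atom(state, "CD", "C", CD)
    state <- .add_atom(state, "CE", "C", CE)
    state <- .add_atom(state, "NZ", "N", NZ)
    state <- .methylene(state, c("HB2", "HB3"), CB, CA, CG)
    state <- .methylene(state, c("HG2", "HG3"), CG, CB, CD)
    state <- .methylene(state, c("HD2", "HD3"), CD, CG, CE)
    state <- .methylene(state, c("HE2", "HE3"), CE, CD, NZ)
    state <- .methyl(state, c("HZ1", "HZ2", "HZ3"), CD, CE, NZ,
                     bond = 1.010, angle = 109.5)
  }
  state
}

#' Build an ideal-geometry peptide fixture
#'
#' Constructs a polypeptide from standard bond lengths and angles with the
#' given backbone torsions. Supported residues: A, G, S, V, E, K (GLU is
#' modeled deprotonated, LYS protonated). Deterministic for a given seed
#' (side-chain chi angles receive optional Gaussian jitter).
#'
#' @param sequence one-letter string, length 2-12, letters in AGSVEK.
#' @param phi,psi backbone torsions in degrees, scalars or per-residue
#'   vectors; defaults are alpha-helical (-57, -47).
#' @param termini "neutral" (NH2 / COOH) or "zwitterionic" (NH3+ / COO-).
#' @param seed RNG seed for chi jitter.
#' @param chi_jitter standard deviation (degrees) of side-chain chi jitter.
#' @param charges if TRUE also return the bundled reference ChargeSet.
#' @return a Structure, or if `charges` a list(structure, charges).
#' @export
build_peptide <- function(sequence, phi = -57, psi = -47,
                          termini = c("neutral", "zwitterionic"),
                          seed = 1L, chi_jitter = 0, charges = FALSE) {
  termini <- match.arg(termini)
  seq1 <- strsplit(toupper(sequence), "")[[1]]
  if (length(seq1) < 2 || length(seq1) > 12)
    stop("sequence length must be 2-12")
  if (!all(seq1 %in% names(.AA1TO3)))
    stop("unsupported residue letter(s): ",
         paste(unique(seq1[!seq1 %in% names(.AA1TO3)]), collapse = ", "))
  nres <- length(seq1)
  res3 <- unname(.AA1TO3[seq1])
  phi <- rep_len(phi, nres)
  psi <- rep_len(psi, nres)
  if (any(phi <= -180 | phi > 180 | psi <= -180 | psi > 180))
    stop("torsions must lie in (-180, 180]")

  chis <- with_seed(seed, lapply(seq_len(nres), function(i) {
    base <- c(180, 180, 180, 180)
    base + if (chi_jitter > 0) stats::rnorm(4, 0, chi_jitter) else 0
  }))

  # backbone trace
  N <- CA <- C <- O <- vector("list", nres)
  N[[1]] <- c(0, 0, 0)
  CA[[1]] <- c(1.458, 0, 0)
  a1 <- 111.2 * pi / 180
  C[[1]] <- CA[[1]] + 1.525 * c(-cos(a1), sin(a1), 0)
  for (i in 2:nres) {
    N[[i]] <- place_atom(N[[i - 1]], CA[[i - 1]], C[[i - 1]],
                         1.329, 116.2, psi[i - 1])
    CA[[i]] <- place_atom(CA[[i - 1]], C[[i - 1]], N[[i]],
                          1.458, 121.7, 180)
    C[[i]] <- place_atom(C[[i - 1]], N[[i]], CA[[i]],
                         1.525, 111.2, phi[i])
  }
  for (i in seq_len(nres))
    O[[i]] <- place_atom(N[[i]], CA[[i]], C[[i]], 1.231, 120.8, psi[i] + 180)

  state <- list(rows = list(), ri = 0L, resname = "")
  for (i in seq_len(nres)) {
    state$ri <- i
    state$resname <- res3[i]
    state <- .add_atom(state, "N", "N", N[[i]])
    if (i == 1L) {
      tors <- if (termini == "neutral") c(60, 300) else c(60, 180, 300)
      for (k in seq_along(tors)) {
        state <- .add_atom(state, paste0("H", k), "H",
                           place_atom(C[[1]], CA[[1]], N[[1]],
                                      1.010, 109.5, tors[k]))
      }
    } else {
      state <- .add_atom(state, "H", "H",
                         place_atom(CA[[i - 1]], C[[i - 1]], N[[i]],
                                    1.010, 119.0, 0))
    }
    state <- .add_atom(state, "CA", "C", CA[[i]])
    uN <- vunit(N[[i]] - CA[[i]])
    uC <- vunit(C[[i]] - CA[[i]])
    dirs <- tetrahedral_pair(uN, uC)
    if (res3[i] == "GLY") {
      state <- .add_atom(state, "HA2", "H", CA[[i]] + 1.090 * dirs[1, ])
      state <- .add_atom(state, "HA3", "H", CA[[i]] + 1.090 * dirs[2, ])
    } else {
      CB <- CA[[i]] + 1.530 * dirs[1, ]
      state <- .add_atom(state, "HA", "H", CA[[i]] + 1.090 * dirs[2, ])
      state <- .add_atom(state, "CB", "C", CB)
      state <- .sidechain(state, res3[i], N[[i]], CA[[i]], C[[i]], CB,
                          chis[[i]])
    }
    state <- .add_atom(state, "C", "C", C[[i]])
    state <- .add_atom(state, "O", "O", O[[i]])
    if (i == nres) {
      if (termini == "neutral") {
        OXT <- place_atom(N[[i]], CA[[i]], C[[i]], 1.350, 117.0, psi[i])
        state <- .add_atom(state, "OXT", "O", OXT)
        state <- .add_atom(state, "HXT", "H",
                           place_atom(CA[[i]], C[[i]], OXT, 0.96, 106.0, 180))
      } else {
        state <- .add_atom(state, "OXT", "O",
                           place_atom(N[[i]], CA[[i]], C[[i]],
                                      1.250, 117.0, psi[i]))
      }
    }
  }

  rows <- state$rows
  atoms <- data.frame(
    serial = seq_along(rows),
    name = vapply(rows, `[[`, "", "name"),
    element = vapply(rows, `[[`, "", "element"),
    resname = vapply(rows, `[[`, "", "resname"),
    residue_index = vapply(rows, `[[`, 0L, "residue_index"),
    x = vapply(rows, `[[`, 0, "x"),
    y = vapply(rows, `[[`, 0, "y"),
    z = vapply(rows, `[[`, 0, "z"),
    stringsAsFactors = FALSE)

  # steric sanity: any two atoms closer than 0.8 A is a hard clash
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  d2 <- cross_dist2(xyz, xyz)
  diag(d2) <- Inf
  if (min(d2) < 0.8^2)
    stop(sprintf(paste0("steric clash (%.2f A) in generated peptide; ",
                        "try different torsions"), sqrt(min(d2))))

  st <- new_structure(atoms)
  if (!charges) return(st)
  list(structure = st,
       charges = load_reference_charges(st, provenance = "mock_reference"))
}

#' Generate a conformer ensemble by torsion jitter
#'
#' Produces `n` structures of identical covalent topology whose backbone
#' torsions are Gaussian-jittered around the base `phi`/`psi`; clashing
#' draws are rejected and retried (up to 100 times per conformer).
#'
#' @param sequence,phi,psi,termini as in [build_peptide()].
#' @param n number of conformers.
#' @param sigma torsion jitter standard deviation, degrees.
#' @param seed RNG seed; the ensemble is reproducible given the seed.
#' @return list of Structures.
#' @export
make_conformers <- function(sequence, n, sigma = 15, phi = -57, psi = -47,
                            termini = "neutral", seed = 1L) {
  stopifnot(n >= 1)
  nres <- nchar(sequence)
  phi <- rep_len(phi, nres)
  psi <- rep_len(psi, nres)
  wrap <- function(x) ((x + 180) %% 360) - 180  # keep in (-180, 180]
  with_seed(seed, lapply(seq_len(n), function(i) {
    for (try in 1:100) {
      dphi <- if (sigma > 0) stats::rnorm(nres, 0, sigma) else 0
      dpsi <- if (sigma > 0) stats::rnorm(nres, 0, sigma) else 0
      st <- tryCatch(
        build_peptide(sequence, wrap(phi + dphi), wrap(psi + dpsi),
                      termini = termini, seed = i),
        error = function(e) NULL)
      if (!is.null(st)) return(st)
    }
    stop("could not generate a clash-free conformer after 100 retries")
  }))
}

#' Build a fixture guaranteed to contain two-body contacts
#'
#' Returns an alpha-helical peptide (helix turns bring residues i and i+3 /
#' i+4 into close contact) verified post-construction to contain at least
#' `min_pairs` two-body pairs at threshold `lambda`.
#'
#' @param min_pairs minimum number of (i, j >= i+3) contact pairs required.
#' @param lambda distance threshold in Angstrom.
#' @param sequence helix sequence (default 8 alanines with a serine).
#' @return a Structure.
#' @export
make_contact_fixture <- function(min_pairs = 1, lambda = 4.0,
                                 sequence = "AASAAASA") {
  stopifnot(min_pairs >= 1)
  st <- build_peptide(sequence, -57, -47, termini = "neutral")
  pairs <- find_two_body_pairs(st, lambda)
  if (length(pairs) < min_pairs)
    stop(sprintf(paste0("contact fixture construction failed: %d pair(s) ",
                        "found at lambda = %.2f A, %d required"),
                 length(pairs), lambda, min_pairs))
  st
}
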