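## Assembly of per-atom protein charges from subsystem fits, and of the
## total fragment energy with the double-counting deduction.
##
## Per-atom charge: q_k = sum_frag q_k - sum_concap q_k
##                        - sum_pairs [ q_k(AiAj) - q_k(Ai) - q_k(Aj) ].
## Because each atom appears in exactly (multiplicity) fragments and
## (multiplicity - 1) concaps, the concap subtraction removes the double
## counting exactly; under a zero-response backend the two-body bracket
## vanishes atom-by-atom. Link-atom fitted charges map to no parent atom
## and are discarded here.

#' Assemble per-atom charges from subsystem fits
#'
#' @param structure a Structure.
#' @param fits output of [fit_all_subsystems()].
#' @return list with `charges` (a ChargeSet, provenance "ee_gmfcc") and
#'   `ledger` (data.frame of every per-atom contribution: atom, subsystem,
#'   sign, value).
#' @export
assemble_charges <- function(structure, fits) {
  n <- n_atoms(structure)
  q <- numeric(n)
  led <- list()
  push <- function(idx, sign, vals, id) {
    led[[length(led) + 1L]] <<- data.frame(atom = idx, subsystem = id,
                                           sign = sign, value = vals)
    q[idx] <<- q[idx] + sign * vals
  }
  for (f in fits$fragments)
    push(f$subsystem$atom_idx, +1, f$parent_charges, f$subsystem$id)
  for (cc in fits$concaps)
    push(cc$subsystem$atom_idx, -1, cc$parent_charges, cc$subsystem$id)
  for (p in fits$pairs) {
    push(p$pair$subsystem$atom_idx, -1, p$pair$parent_charges,
         p$pair$subsystem$id)
    push(p$mono_i$subsystem$atom_idx, +1, p$mono_i$parent_charges,
         p$mono_i$subsystem$id)
    push(p$mono_j$subsystem$atom_idx, +1, p$mono_j$parent_charges,
         p$mono_j$subsystem$id)
  }
  mult <- multiplicity_check(structure,
                             lapply(fits$fragments, `[[`, "subsystem"),
                             lapply(fits$concaps, `[[`, "subsystem"))
  if (any(mult != 1L))
    stop("assembly multiplicity check failed for atom(s) ",
         paste(which(mult != 1L), collapse = ", "),
         " (fragmentation bug)")
  list(charges = charge_set(q, "ee_gmfcc"),
       ledger = do.call(rbind, led))
}

#' Report (and optionally repair) total-charge deviation
#'
#' @param charges a ChargeSet.
#' @param formal integer formal charge of the molecule.
#' @param renormalize if TRUE, distribute the deviation equally over atoms
#'   so the total matches exactly (off by default).
#' @return list(deviation, charges).
#' @export
total_charge_report <- function(charges, formal, renormalize = FALSE) {
  dev <- charges$total - formal
  out <- charges
  if (renormalize && length(charges$charges)) {
    out <- charge_set(charges$charges - dev / length(charges$charges),
                      charges$provenance)
  }
  list(deviation = dev, charges = out)
}

#' Interaction-count matrix of the embedded energy bookkeeping
#'
#' For every atom pair (a, b) counts how many times their pairwise
#' interaction is included across the signed subsystem terms. Each embedded
#' term counts a pair if at least one of its atoms is inside the subsystem
#' (subsystem-internal or subsystem-background). Writing t_a for the signed
#' per-atom membership total (1 for fragments minus concaps; the two-body
#' triplets cancel) and M_ab for the signed co-membership count, the pair
#' count is n_ab = t_a + t_b - M_ab. Pairs with n_ab > 1 are doubly counted
#' and enter E_DC with weight (n_ab - 1).
#'
#' @param structure a Structure.
#' @param subsystems list of Subsystem objects.
#' @param signs +1/-1 per subsystem matching its term's sign in the total.
#' @return integer n x n matrix of pair counts.
#' @export
interaction_counts <- function(structure, subsystems, signs) {
  n <- n_atoms(structure)
  t <- numeric(n)
  M <- matrix(0, n, n)
  for (k in seq_along(subsystems)) {
    idx <- subsystems[[k]]$atom_idx
    t[idx] <- t[idx] + signs[k]
    M[idx, idx] <- M[idx, idx] + signs[k]
  }
  outer(t, rep(1, n)) + outer(rep(1, n), t) - M
}

#' Assemble the total fragment energy with double-count deduction
#'
#' Total = sum(fragment energies) - sum(concap energies)
#'         - sum(E_ij - E_i - E_j) - E_DC, where E_DC is the classical
#' charge-charge interaction of every doubly counted atom pair,
#' sum (n_ab - 1) q_a q_b / r_ab in atomic units (see
#' [interaction_counts()]).
#'
#' @param structure a Structure.
#' @param fits output of [fit_all_subsystems()] whose entries carry backend
#'   energies.
#' @param charges ChargeSet used for the E_DC pairwise interactions.
#' @return an `EnergyLedger`: list(fragment_energies, concap_energies,
#'   two_body_terms, e_dc, total), energies in hartree.
#' @export
assemble_total_energy <- function(structure, fits, charges) {
  fe <- vapply(fits$fragments, `[[`, numeric(1), "energy")
  ce <- vapply(fits$concaps, `[[`, numeric(1), "energy")
  tb <- vapply(fits$pairs, function(p) {
    p$pair$energy - p$mono_i$energy - p$mono_j$energy
  }, numeric(1))
  if (any(!is.finite(c(fe, ce, tb))))
    stop("missing subsystem energies; backend did not return energies")

  subsystems <- c(lapply(fits$fragments, `[[`, "subsystem"),
                  lapply(fits$concaps, `[[`, "subsystem"),
                  lapply(fits$pairs, function(p) p$pair$subsystem),
                  lapply(fits$pairs, function(p) p$mono_i$subsystem),
                  lapply(fits$pairs, function(p) p$mono_j$subsystem))
  signs <- c(rep(1, length(fits$fragments)),
             rep(-1, length(fits$concaps)),
             rep(-1, length(fits$pairs)),
             rep(1, 2 * length(fits$pairs)))
  e_dc <- e_double_count(structure, charges,
                         interaction_counts(structure, subsystems, signs))
  total <- sum(fe) - sum(ce) - sum(tb) - e_dc
  structure(list(fragment_energies = fe, concap_energies = ce,
                 two_body_terms = tb, e_dc = e_dc, total = total),
            class = "EnergyLedger")
}

#' Classical double-count energy for a given pair-count matrix
#' @param structure a Structure.
#' @param charges a ChargeSet.
#' @param counts matrix from [interaction_counts()].
#' @return energy in hartree.
#' @export
e_double_count <- function(structure, charges, counts) {
  xyz <- coords(structure)
  d <- sqrt(cross_dist2(xyz, xyz)) * ANG_PER_BOHR
  q <- charges$charges
  iu <- upper.tri(d)
  excess <- pmax(counts - 1, 0)
  sum((excess * outer(q, q) / ifelse(d > 0, d, Inf))[iu])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' End-to-end fragment charge pipeline
#'
#' Fragment -> embedded ESP -> fit -> assemble, returning the assembled
#' ChargeSet plus the full fit and ledger detail.
#'
#' @param structure a Structure.
#' @param backend a `qm_backend`.
#' @param reference embedding ChargeSet (force-field-like background).
#' @param lambda two-body threshold, Angstrom (0 disables pairs).
#' @param config a [fit_config()].
#' @param extra_background optional surface-charge background.
#' @return list(charges, ledger, fits).
#' @export
ee_gmfcc_charges <- function(structure, backend, reference, lambda = 4.0,
                             config = fit_config(),
                             extra_background = NULL) {
  fits <- fit_all_subsystems(structure, backend, reference, lambda, config,
                             extra_background)
  out <- assemble_charges(structure, fits)
  out$fits <- fits
  out
}
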