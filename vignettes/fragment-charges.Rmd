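---
title: "Fragment-based ESP charges and continuum solvation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment-based ESP charges and continuum solvation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragcharge)
```

## The problem

Fixed point-charge force fields describe protein electrostatics in a
mean-field way: they carry no structure-specific polarization or charge
transfer. A charge model fitted to quantum-mechanical electrostatic
potentials (ESP) of the actual structure does, but a whole-protein QM
calculation scales prohibitively. `fragcharge` implements the
fragment-based route: the chain is cut through its backbone peptide bonds
into overlapping capped fragments, each fragment's ESP is computed with the
rest of the protein represented as embedding point charges, per-fragment
ESP charges are fitted, and per-atom protein charges are assembled so that
the overlap is deducted exactly. The same charge model is then coupled
self-consistently to a finite-difference Poisson–Boltzmann (PB) continuum
solvent to produce electrostatic solvation energies.

## Fragmentation and charge assembly

For a chain of $N$ residues $A_1 \dots A_N$ (per continuous segment), the
subsystems are:

* **Capped fragments** ($i = 2 \dots N-1$): residues $i-1$, $i$, $i+1$ in
  full, truncated at the two distal peptide bonds. Each cut X–H valence is
  saturated by a hydrogen link atom placed along the cut-bond direction at
  the donor element's standard bond length (C–H 1.090 Å, N–H 1.010 Å).
* **Concaps** ($i = 2 \dots N-2$): residues $i$, $i+1$ in full, capped the
  same way. A concap is exactly the pairwise overlap of consecutive
  fragments.
* **Two-body pairs**: residue pairs $(i, j)$, $j \ge i+3$, whose minimum
  interatomic distance (all atoms, hydrogens included) is at most a
  threshold $\lambda$ (default 4.0 Å). Each pair contributes three capped
  calculations: the combined two-residue system and the two isolated
  residues.

With full-residue caps, every atom belongs to $m$ fragments and $m-1$
concaps (`multiplicity_check()` asserts this *multiplicity identity*), so
the assembled charge

$$q_k \;=\; \sum_{\text{frag}} q_k \;-\; \sum_{\text{concap}} q_k
\;-\; \sum_{(i,j)} \bigl[\, q_k(A_iA_j) - q_k(A_i) - q_k(A_j) \,\bigr]$$

counts each atom exactly once. Link-atom charges are fitted but map to no
parent atom and are discarded at assembly. The analogous energy assembly
subtracts, in addition, the classical double-count term $E_{DC}$ (below).

Every subsystem calculation is electrostatically embedded: the atoms not in
the subsystem enter as background point charges taken from the bundled
Amber-like reference table (and, in the solvation loop, the PB surface
charges are appended to that background).

### The double-count term

The embedded energy of a subsystem contains its self-energy plus its
interaction with all background charges, so summing signed subsystem
energies counts some pairwise interactions more than once. The complete
bookkeeping behind the published method's deduction is defined in work not
reproduced here, so this package implements one explicit, testable rule:
an embedded term counts the pair $(a, b)$ whenever at least one of the two
atoms is inside the subsystem. By inclusion–exclusion the signed count is
$n_{ab} = t_a + t_b - M_{ab}$, with $t$ the signed per-atom membership
total and $M$ the signed co-membership count (`interaction_counts()`), and

$$E_{DC} = \sum_{a<b} (n_{ab} - 1)\, q_a q_b / r_{ab}.$$

For a chain with no two-body pairs this reduces to one correction per atom
pair in residues three or more apart, and to zero for a molecule covered by
a single fragment — both covered by constructed oracles in the tests.

## ESP fitting

Fit grids are deterministic Merz–Kollman constructions: Fibonacci-lattice
points on scaled van der Waals spheres (default shells 1.4, 1.6, 1.8, 2.0;
density 1.0 point/Å²), excluding points inside any other atom's sphere at
the same scale. No random numbers are used anywhere in fitting.

The fit minimizes the squared ESP misfit plus quadratic penalty restraints,
subject to the **hard** total-charge constraint $\sum q = Q$. Rather than
solving the normal-equation KKT system, the constraint is eliminated by a
null-space parametrization and the stacked least-squares problem is solved
by QR — this is what makes the exact-recovery oracle hold to ~1e-14 e
rather than 1e-8. Concap link-atom charges are restrained to the value
fitted for the geometrically identical link atom of the neighboring
fragment (matched by cut-bond label), with penalty weight `w_link`
(default 0.1 au/e²): a soft restraint keeps the system well-posed while
preventing the concap subtraction from injecting spurious charge. The
hyperbolic RESP zero-restraint on heavy atoms is implemented but **off** by
default: the stated constraints (net charge + link equality) are the
literal reading of the method, and the restraint is a config switch for
users who want classic RESP behavior.

## The mock backend and what a green test establishes

The package ships a deterministic mock backend whose ESP is the Coulomb
field of the bundled reference charges on the subsystem's parent atoms
(link atoms neutral, so residue totals are preserved). With
`polarization_gain > 0`, each parent charge is shifted by the projection of
the embedding field onto the centroid→atom axis; shifts are mean-centered
so the subsystem's net charge — and hence the hard constraint — remains
exact. Gain 0 makes the whole pipeline an *exact-recovery oracle*: the
assembled charges must reproduce the reference table to machine precision
for any fragmentation and any $\lambda$, because fragment sums, concap
deductions and two-body brackets cancel algebraically.

This is a strong test of the bookkeeping (fragmentation, link atoms,
embedding, constrained fitting, assembly) and of nothing else: the mock is
a linear point-charge world, so green tests do **not** establish fidelity
to real QM charge distributions, charge transfer between fragments, or
basis-set effects. Those require the `ab_initio` backend adapter with an
external engine, which this package deliberately does not bundle.

## Poisson–Boltzmann solvation and the SCRF loop

The linearized PB equation is discretized on a node-centered cubic grid
(default spacing 0.4 Å for production, padding 8 Å) with the dielectric
interior defined as the union of probe-inflated atom spheres
(ε_in = 1 inside, ε_out = 80 outside, probe 1.4 Å; the probe-rolling
re-entrant correction is not applied). Face dielectrics are harmonic means
of adjacent node values; charges spread trilinearly; boundary conditions
are the screened Coulomb field in ε_out. The system is solved by red–black
SOR (compiled), and the reaction-field energy is
$\tfrac12 \sum_k q_k [\phi_{het}(r_k) - \phi_{hom}(r_k)]$ where the
homogeneous solve reuses the identical grid and charge assignment so the
discrete self-energy cancels. Induced surface charge at each interface
node is the discrete vacuum Laplacian of the solution minus the assigned
free charge — a definition under which Gauss's law
($\sum q_{ind} = -q_{net}(1 - \varepsilon_{in}/\varepsilon_{out})$) holds
to discretization accuracy automatically. Validation: the Born ion
(q = 1 e, R = 2 Å) agrees with the closed form within 1.7% at 0.25 Å
spacing, with monotone error decay under refinement.

The self-consistent reaction-field (SCRF) loop alternates charge assembly
(surface charges appended to the embedding background) with PB solves until
$|\Delta E_{rf}|$ < `tol` (default 0.1 kcal/mol, a value chosen because the
published workflow reports convergence "within five iterations" but no
numeric criterion). Two design points worth noting:

* The loop always performs **two** PB solves before it can declare
  convergence, because the criterion is a difference of successive
  energies; a zero-response backend therefore converges at iteration 2
  with $\Delta E_{rf} = 0$ exactly.
* Optional damping mixes old and new surface charges; it is off
  (factor 1.0) by default since the mock linear-response world contracts
  geometrically without it. A growing, sign-alternating energy sequence
  raises an error suggesting damping.

## The fixture generator

`build_peptide()` constructs ideal-geometry polypeptides (residues
A, G, S, V, E, K; 2–12 residues) from standard bond lengths and angles
(N–CA 1.458 Å, CA–C 1.525 Å, C–N 1.329 Å, C=O 1.231 Å, ω = 180°,
tetrahedral side-chain branching) with user-set backbone torsions, neutral
(NH₂/COOH) or zwitterionic (NH₃⁺/COO⁻) termini, and deterministic
side-chain placement. Glutamate is modeled deprotonated and lysine
protonated. Any two atoms closer than 0.8 Å abort construction. The
α-helical default (φ = −57°, ψ = −47°) doubles as the guaranteed-contact
fixture: helix turns bring residues $i$ and $i+3$/$i+4$ within 4 Å, which
is what the two-body machinery needs to be exercised. `make_conformers()`
jitters torsions to stand in for an MD conformer ensemble.

The bundled charge table is Amber-*like*, not Amber: values are
force-field-plausible and are repaired per residue variant so each
(residue, terminus) group sums **exactly** to its formal charge. The
pipeline only needs internal consistency (the exact-recovery oracle), not
force-field fidelity, and the table is documented accordingly.

What the fixtures do not emulate: real rotamer distributions, strained MD
geometries, disulfides or other non-peptide cross-links (structures
containing them are rejected), protonation equilibria, and solvent
molecules.

## Numerical choices and defaults

| parameter | default | units | rationale |
|---|---|---|---|
| λ (two-body threshold) | 4.0 | Å | published sweep converges by 4 Å |
| MK shells / density | 1.4–2.0 / 1.0 | – / pts Å⁻² | standard construction; fit grid unspecified in the method |
| `w_link` | 0.1 | au/e² | soft enough to keep the KKT system well-posed |
| shell-grid bounds | 2.5–4.5 | Å | the method's MEP comparison shell |
| shell-grid spacing | 0.8 | Å | unspecified upstream; recorded per run |
| PB spacing / padding | 0.4 / 8 | Å | Born error ≲ 2% at 0.25 Å; 0.5–0.6 Å used in tests for speed |
| SCRF tol / max_iter | 0.1 / 10 | kcal/mol / – | criterion unspecified upstream |
| Coulomb constant | 332.06 | kcal Å mol⁻¹ e⁻² | practical-unit convention |
| Å → bohr | 1.8897259886 | – | atomic-unit potentials |

Configuration files are JSON (`jsonlite`), not YAML: no YAML parser is
among the package's guaranteed dependencies, and the schema is unchanged by
the serialization choice. QM results are memoized in-memory per backend on
a content key of the task (geometry, background, grid, net charge), which
is what keeps SCRF loops and λ sweeps affordable; the cache is not
persisted to disk.

## Known limitations

* The real-QM backend is an adapter contract only; all quantitative claims
  in this package's test battery are about the mock world.
* Linearized PB, zero default ionic strength, no nonpolar solvation terms.
* The E_DC bookkeeping is one faithful reading of an incompletely
  published definition and is flagged as such in output metadata.
* Chains are fragmented per continuous segment; disulfide-linked or
  otherwise cross-linked topologies are out of scope.

## A minimal end-to-end run

```{r example, eval = FALSE}
st  <- build_peptide("AASAAASA")            # helical 8-mer with contacts
ref <- load_reference_charges(st, provenance = "mock_reference")
be  <- mock_esp_backend(ref, polarization_gain = 0.05)

res  <- ee_gmfcc_charges(st, be, ref, lambda = 4.0)
grid <- generate_shell_grid(st)
compare_mep(evaluate_potential(res$charges, st, grid),
            evaluate_potential(ref, st, grid))

scrf <- scrf_iterate(st, be, ref, lambda = 4.0,
                     spacing = 0.5, padding = 6)
scrf$history
```
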