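# fragcharge

Fragment-based ESP atomic charges and continuum solvation for
polypeptides, in R.

## What it does, and for whom

Fixed force-field point charges miss the structure-specific polarization
and charge-transfer content of a protein's electrostatics; whole-protein
quantum calculations that would capture it do not scale. `fragcharge` is
for molecular-modelling researchers who want the middle road: cut the
chain through its peptide bonds into overlapping capped fragments, compute
each fragment's electrostatic potential (ESP) with the remainder of the
protein as embedding point charges, fit per-fragment ESP charges under a
hard net-charge constraint with link-atom restraints, and assemble per-atom
protein charges so the fragment overlap cancels exactly:

    q_k = Σ_frag q_k(Cap*_{i-1} A_i Cap_{i+1}) − Σ_concap q_k(Cap*_i Cap_{i+1})
          − Σ_{(i,j): d_min ≤ λ} [ q_k(A_i A_j) − q_k(A_i) − q_k(A_j) ]

with one fragment per residue i = 2..N−1, one conjugate cap (concap) per
cut, and quantum two-body corrections for residue pairs j ≥ i+3 closer
than a threshold λ (default 4 Å). The resulting charge set can be compared
to any reference potential on a 2.5–4.5 Å shell grid (RMSD / Pearson r, in
atomic units), and coupled self-consistently to a finite-difference
linearized Poisson–Boltzmann solver (ε_in = 1, ε_out = 80, probe 1.4 Å) to
give electrostatic solvation energies: PB-induced surface charges are fed
back into the fragment calculations as extra background until the
reaction-field energy converges.

Everything runs without external software: an ideal-geometry peptide
generator supplies fixtures, a bundled Amber-like charge table supplies
embedding charges, and a deterministic mock QM backend (Coulomb field of
the reference charges, with optional linear polarization response) makes
the whole pipeline testable to machine precision. A real *ab initio*
backend is an adapter contract the user can plug an engine into.

## Worked example

An α-helical 8-mer has i/i+3 contacts, so the two-body machinery engages.
The mock backend is given a small polarization gain so the assembled
charges differ from the reference table, and the λ sweep shows the
two-body correction pulling the potential back toward the reference:

```r
library(fragcharge)
st  <- build_peptide("AASAAASA")            # helical by default
ref <- load_reference_charges(st, provenance = "mock_reference")
be  <- mock_esp_backend(ref, polarization_gain = 0.05)

res  <- ee_gmfcc_charges(st, be, ref, lambda = 4.0)
res$charges
#> ChargeSet: 85 charges, total +0.000000 e (ee_gmfcc)

grid <- generate_shell_grid(st)             # 2.5-4.5 A shell, 0.8 A lattice
compare_mep(evaluate_potential(res$charges, st, grid),
            evaluate_potential(ref, st, grid))
#> MEP comparison over 3852 points: RMSD 3.541e-04 au, r = 0.999964

res0 <- ee_gmfcc_charges(st, be, ref, lambda = 0)   # no two-body terms
compare_mep(evaluate_potential(res0$charges, st, grid),
            evaluate_potential(ref, st, grid))
#> MEP comparison over 3852 points: RMSD 8.231e-04 au, r = 0.999925
```

The net charge is conserved exactly (hard constraint); the MEP RMSD halves
when the λ = 4 Å two-body corrections are included (3.5e-4 vs 8.2e-4 au).
With the gain set to 0 the assembled charges equal the reference table to
~1e-14 e — the package's central exactness oracle.

Solvation, self-consistently:

```r
scrf <- scrf_iterate(st, be, ref, lambda = 4.0, spacing = 0.5, padding = 6)
round(scrf$history, 4)
#> [1] -20.3153 -19.7508 -19.7611
scrf$state
#> SolvationState: E_rf = -19.761 kcal/mol, induced surface charge 0.0000 e,
#>   grid 49x47x50 @ 0.50 A
```

The reaction-field energy converges in three iterations (the published
workflow reports "within five"); the total induced surface charge is
−q_net(1 − 1/80) = 0 here because the peptide is neutral.

There is also a small CLI:

```sh
Rscript -e 'fragcharge::fragcharge_main()' fixture --seq AAGAA --out pep.pdb
Rscript -e 'fragcharge::fragcharge_main()' charges pep.pdb --lambda 4.0 --out run1
```

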