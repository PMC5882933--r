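test_that("zero-gain pipeline reproduces the reference charges exactly", {
  st <- build_peptide("AAGA")
  ref <- mock_ref(st)
  be <- mock_esp_backend(ref, 0)
  res <- ee_gmfcc_charges(st, be, ref, lambda = 4.0)
  expect_lt(max(abs(res$charges$charges - ref$charges)), 1e-10)
  expect_equal(res$charges$provenance, "ee_gmfcc")
  # ledger covers every contribution and no link atoms leak in
  expect_true(all(res$ledger$atom %in% seq_len(n_atoms(st))))

  # lambda = 0 (no pairs) gives the identical result under zero gain
  res0 <- ee_gmfcc_charges(st, be, ref, lambda = 0)
  expect_equal(res0$charges$charges, res$charges$charges, tolerance = 1e-10)
})

test_that("per-atom two-body corrections vanish at zero gain", {
  st <- make_contact_fixture(1, 4.0)
  ref <- mock_ref(st)
  fits <- fit_all_subsystems(st, mock_esp_backend(ref, 0), ref, lambda = 4.0)
  expect_gt(length(fits$pairs), 0)
  for (p in fits$pairs) {
    corr <- p$pair$parent_charges -
      c(p$mono_i$parent_charges, p$mono_j$parent_charges)
    expect_lt(max(abs(corr)), 1e-9)
  }
})

test_that("total-charge report and renormalization", {
  st <- build_peptide("AGA")
  ref <- mock_ref(st)
  res0 <- ee_gmfcc_charges(st, mock_esp_backend(ref, 0), ref, lambda = 0)
  rep0 <- total_charge_report(res0$charges, formal_charge(st))
  expect_equal(rep0$deviation, 0, tolerance = 1e-10)

  # a perturbed set: deviation reported, charges untouched by default
  cs <- charge_set(ref$charges + 0.01, "ee_gmfcc")
  rep1 <- total_charge_report(cs, formal_charge(st))
  expect_equal(rep1$deviation, 0.01 * n_atoms(st), tolerance = 1e-9)
  expect_identical(rep1$charges$charges, cs$charges)
  rep2 <- total_charge_report(cs, formal_charge(st), renormalize = TRUE)
  expect_equal(rep2$charges$total, formal_charge(st), tolerance = 1e-12)
  expect_equal(rep2$charges$charges, cs$charges - 0.01, tolerance = 1e-12)
})

test_that("permutation of atom order within residues leaves assembly invariant", {
  st <- build_peptide("AGA")
  ref <- mock_ref(st)
  res <- ee_gmfcc_charges(st, mock_esp_backend(ref, 0.05), ref, lambda = 0)

  # reverse atom order inside each residue (geometry unchanged)
  perm <- unlist(lapply(1:3, function(i) rev(residue_atoms(st, i))))
  at2 <- st$atoms[perm, ]
  at2$serial <- seq_len(nrow(at2))
  st2 <- new_structure(at2)
  ref2 <- charge_set(ref$charges[perm], "mock_reference")
  res2 <- ee_gmfcc_charges(st2, mock_esp_backend(ref2, 0.05), ref2,
                           lambda = 0)
  expect_equal(res2$charges$charges, res$charges$charges[perm],
               tolerance = 1e-9)
})

test_that("E_DC bookkeeping counts each pair interaction once", {
  # two point charges double counted -> E_DC = q1 q2 / r (atomic units)
  st2 <- new_structure(data.frame(
    serial = 1:2, name = c("O", "O"), element = "O", resname = "GLY",
    residue_index = 1:2, x = c(0, 4), y = 0, z = 0, radius = 1.52))
  q <- charge_set(c(0.5, -0.4), "force_field")
  counts <- matrix(2, 2, 2)
  expect_equal(e_double_count(st2, q, counts),
               0.5 * -0.4 / (4 * 1.8897259886), tolerance = 1e-12)

  # N=3 single fragment: every pair counted exactly once, E_DC = 0
  st <- build_peptide("AGA")
  ref <- mock_ref(st)
  fits <- fit_all_subsystems(st, mock_esp_backend(ref, 0), ref, lambda = 0)
  subs <- lapply(fits$fragments, `[[`, "subsystem")
  n <- interaction_counts(st, subs, rep(1, length(subs)))
  expect_true(all(n[upper.tri(n)] == 1))
  el <- assemble_total_energy(st, fits, ref)
  expect_equal(el$e_dc, 0, tolerance = 1e-12)
  expect_equal(el$total, el$fragment_energies[[1]], tolerance = 1e-12)
})

test_that("additive mock energies satisfy the assembly identity (N=5)", {
  st <- build_peptide("AAGAA")
  ref <- mock_ref(st)
  be <- mock_esp_backend(ref, 0, energy_mode = "additive")
  fits <- fit_all_subsystems(st, be, ref, lambda = 4.0)
  el <- assemble_total_energy(st, fits, charge_set(rep(0, n_atoms(st)),
                                                   "force_field"))
  # with per-atom constant energies the multiplicity identity makes the
  # assembled total equal the direct sum over parent atoms plus one link-H
  # pair per interior cut (fragment and concap link terms cancel likewise)
  eat <- c(H = -0.5, C = -37.8, N = -54.4, O = -74.8, S = -397.5)
  direct <- sum(eat[st$atoms$element])
  fr <- build_fragments(st)
  cc <- build_concaps(st)
  ps <- build_pair_subsystems(st, find_two_body_pairs(st, 4.0))
  nlink <- sum(vapply(fr, function(f) nrow(f$link_atoms), numeric(1))) -
    sum(vapply(cc, function(f) nrow(f$link_atoms), numeric(1))) -
    sum(vapply(ps, function(p) -nrow(p$mono_i$link_atoms) -
                 nrow(p$mono_j$link_atoms) + nrow(p$pair$link_atoms),
               numeric(1)))
  expect_equal(el$total, direct + nlink * eat[["H"]], tolerance = 1e-9)
  # ledger arithmetic identity
  expect_equal(el$total,
               sum(el$fragment_energies) - sum(el$concap_energies) -
                 sum(el$two_body_terms) - el$e_dc,
               tolerance = 1e-12)
})
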