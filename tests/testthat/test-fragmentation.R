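test_that("fragment counts and membership follow the cutting scheme", {
  # N=3: one fragment, whole molecule, no link atoms
  st3 <- build_peptide("AGA")
  fr3 <- build_fragments(st3)
  expect_length(fr3, 1)
  expect_equal(sort(fr3[[1]]$atom_idx), seq_len(n_atoms(st3)))
  expect_equal(nrow(fr3[[1]]$link_atoms), 0)
  expect_length(build_concaps(st3), 0)

  # N=5: 3 fragments; residue 3 appears in all three (cap, center, cap)
  st5 <- build_peptide("AAGAA")
  fr5 <- build_fragments(st5)
  expect_length(fr5, 3)
  in_frag <- vapply(fr5, function(f) 3 %in% f$residues, logical(1))
  expect_true(all(in_frag))
  expect_length(build_concaps(st5), 2)

  # N=4: residue-1 atoms appear only in fragment i=2
  st4 <- build_peptide("AAGA")
  fr4 <- build_fragments(st4)
  expect_length(fr4, 2)
  a1 <- residue_atoms(st4, 1)
  expect_true(all(a1 %in% fr4[[1]]$atom_idx))
  expect_false(any(a1 %in% fr4[[2]]$atom_idx))
})

test_that("multiplicity identity holds for N = 3..8 (counting oracle)", {
  for (n in 3:8) {
    st <- build_peptide(strrep("A", n), phi = -57, psi = -47)
    fr <- build_fragments(st)
    cc <- build_concaps(st)
    expect_length(fr, n - 2)
    expect_length(cc, max(0, n - 3))
    # brute-force per-atom count over the atom index maps
    cnt <- integer(n_atoms(st))
    for (f in fr) for (a in f$atom_idx) cnt[a] <- cnt[a] + 1L
    for (s in cc) for (a in s$atom_idx) cnt[a] <- cnt[a] - 1L
    expect_true(all(cnt == 1L), info = paste("N =", n))
    expect_equal(multiplicity_check(st, fr, cc), cnt)
  }
})

test_that("link hydrogens sit on the cut bond at standard lengths", {
  # collinear placement at the donor element's X-H length
  h <- place_link_hydrogen(c(0, 0, 0), c(1.33, 0, 0), "C")
  expect_equal(h, c(1.090, 0, 0))
  h2 <- place_link_hydrogen(c(0, 0, 0), c(0, 1.33, 0), "N")
  expect_equal(sqrt(sum(h2^2)), 1.010)
  expect_error(place_link_hydrogen(c(0, 0, 0), c(0, 0, 0), "C"), "zero-length")

  # concap link atoms coincide with the corresponding fragment link atoms
  st <- build_peptide("AAGAA")
  fr <- build_fragments(st)
  cc <- build_concaps(st)
  frag_links <- do.call(rbind, lapply(fr, `[[`, "link_atoms"))
  for (s in cc) {
    for (r in seq_len(nrow(s$link_atoms))) {
      m <- frag_links[frag_links$label == s$link_atoms$label[r], ]
      expect_gte(nrow(m), 1)
      expect_equal(unlist(s$link_atoms[r, c("x", "y", "z")]),
                   unlist(m[1, c("x", "y", "z")]),
                   ignore_attr = TRUE)
    }
  }
})

test_that("link atoms keep clear of atoms outside their subsystem", {
  st <- make_contact_fixture(1, 4.0)
  fr <- build_fragments(st)
  xyz <- coords(st)
  for (f in fr) {
    if (!nrow(f$link_atoms)) next
    outside <- setdiff(seq_len(n_atoms(st)), f$atom_idx)
    lpos <- as.matrix(f$link_atoms[, c("x", "y", "z")])
    for (r in seq_len(nrow(lpos))) {
      d <- sqrt(rowSums((xyz[outside, , drop = FALSE] -
                         matrix(lpos[r, ], length(outside), 3,
                                byrow = TRUE))^2))
      # the replaced atom itself is the nearest outside atom by construction
      expect_gt(min(d), 0.2)
      expect_gt(sort(d)[2], 0.5)
    }
  }
})

test_that("two-body pair enumeration matches the brute-force oracle", {
  # helix, extended strand, and jittered conformers at several lambdas
  fixtures <- c(list(build_peptide("AAAAAA", -57, -47),
                     build_peptide("AAAAAA", -135, 135)),
                make_conformers("AAGAAA", n = 4, sigma = 25, seed = 3))
  for (st in fixtures) {
    for (lam in c(2.0, 2.7, 4.0)) {
      got <- lapply(find_two_body_pairs(st, lam), function(p) c(p$i, p$j))
      expect_equal(got, brute_pairs(st, lam))
    }
    # monotone set inclusion in lambda
    p1 <- find_two_body_pairs(st, 2.0)
    p2 <- find_two_body_pairs(st, 4.0)
    key <- function(ps) vapply(ps, function(p) paste(p$i, p$j), character(1))
    expect_true(all(key(p1) %in% key(p2)))
  }
  expect_length(find_two_body_pairs(build_peptide("AAAAAA", -57, -47), 0), 0)
})

test_that("pair subsystems are capped monomers plus their union", {
  st <- make_contact_fixture(1, 4.0)
  ps <- build_pair_subsystems(st, find_two_body_pairs(st, 4.0))
  for (p in ps) {
    expect_setequal(p$pair$atom_idx, c(p$mono_i$atom_idx, p$mono_j$atom_idx))
    expect_equal(nrow(p$pair$link_atoms),
                 nrow(p$mono_i$link_atoms) + nrow(p$mono_j$link_atoms))
    expect_true(p$j >= p$i + 3)
  }
})

test_that("background charges are the complement of the subsystem", {
  st <- build_peptide("AAGAA")
  ref <- mock_ref(st)
  fr <- build_fragments(st)
  # fragment i=3 spans residues 2..4 -> background is residues 1 and 5
  f3 <- fr[[2]]
  expect_equal(f3$residues, 2:4)
  bg <- background_charges(st, f3, ref)
  expect_equal(nrow(bg), n_atoms(st) - length(f3$atom_idx))
  expect_setequal(
    round(bg$x, 6),
    round(st$atoms$x[st$atoms$residue_index %in% c(1, 5)], 6))
  # partition: background total + subsystem reference total = protein total
  expect_equal(sum(bg$q) + sum(ref$charges[f3$atom_idx]), ref$total,
               tolerance = 1e-12)

  # whole structure as subsystem -> empty background
  whole <- fr[[1]]
  whole$atom_idx <- seq_len(n_atoms(st))
  expect_equal(nrow(background_charges(st, whole, ref)), 0)
})

test_that("chain breaks split fragmentation into segments", {
  st <- build_peptide("AAGAA")
  # displace residues 4-5 far away to break the 3-4 peptide bond
  idx <- st$atoms$residue_index >= 4
  st$atoms$x[idx] <- st$atoms$x[idx] + 50
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(st, pdb)
  st2 <- read_pdb(pdb)
  expect_equal(st2$chain_breaks, 3L)
  expect_warning(fr <- build_fragments(st2), "fewer than 3")
  # segment 1-3 gives one whole fragment, segment 4-5 one fallback fragment
  expect_length(fr, 2)
  expect_length(build_concaps(st2), 0)
})
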