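test_that("dielectric boundary follows the probe-inflated sphere union", {
  stO <- single_atom_structure(radius = 2.0)
  b <- build_dielectric_boundary(stO, spacing = 0.5, padding = 6,
                                 probe = 1.4)
  # node classification equals the analytic sphere test at 3.4 A
  idx <- which(b$inside | !b$inside, arr.ind = TRUE)[seq(1, 15^3, 37), ]
  for (r in seq_len(nrow(idx))) {
    p <- c(b$axes[[1]][idx[r, 1]], b$axes[[2]][idx[r, 2]],
           b$axes[[3]][idx[r, 3]])
    expect_equal(b$inside[idx[r, 1], idx[r, 2], idx[r, 3]],
                 sqrt(sum(p^2)) <= 3.4)
  }
  # probe = 0 puts the interface at the vdW surface
  b0 <- build_dielectric_boundary(stO, spacing = 0.5, padding = 6, probe = 0)
  ins <- which(b0$inside, arr.ind = TRUE)
  pmax_in <- max(sqrt((b0$axes[[1]][ins[, 1]])^2 +
                      (b0$axes[[2]][ins[, 2]])^2 +
                      (b0$axes[[3]][ins[, 3]])^2))
  expect_lte(pmax_in, 2.0 + 1e-9)

  # two overlapping spheres classify as the analytic union (no seam)
  st2 <- new_structure(data.frame(
    serial = 1:2, name = "O", element = "O", resname = "GLY",
    residue_index = 1:2, x = c(0, 2.5), y = 0, z = 0, radius = 2.0))
  b2 <- build_dielectric_boundary(st2, spacing = 0.5, padding = 5, probe = 0)
  g <- expand.grid(i = seq_along(b2$axes[[1]]), j = seq_along(b2$axes[[2]]),
                   k = seq_along(b2$axes[[3]]))
  sel <- g[seq(1, nrow(g), 53), ]
  for (r in seq_len(nrow(sel))) {
    p <- c(b2$axes[[1]][sel$i[r]], b2$axes[[2]][sel$j[r]],
           b2$axes[[3]][sel$k[r]])
    analytic <- sqrt(sum(p^2)) <= 2 || sqrt(sum((p - c(2.5, 0, 0))^2)) <= 2
    expect_equal(b2$inside[sel$i[r], sel$j[r], sel$k[r]], analytic)
  }
  expect_error(build_dielectric_boundary(stO, spacing = 2.5), "too coarse")
})

test_that("Born ion: closed form within tolerance, monotone refinement", {
  stO <- single_atom_structure(radius = 2.0)
  q <- charge_set(1, "force_field")
  exact <- born_exact(1, 2.0, 80)
  model <- dielectric_model(1, 80, probe = 0)
  e_coarse <- solve_pb(stO, q, model, spacing = 0.5, padding = 8)$e_rf
  e_fine <- solve_pb(stO, q, model, spacing = 0.25, padding = 8)$e_rf
  expect_lt(abs(e_fine - exact) / abs(exact), 0.03)
  expect_lt(abs(e_fine - exact), abs(e_coarse - exact))
})

test_that("eps_out = eps_in is a null solvent", {
  stO <- single_atom_structure(radius = 2.0)
  s <- solve_pb(stO, charge_set(1, "force_field"),
                dielectric_model(1, 1, probe = 0),
                spacing = 0.5, padding = 6)
  expect_lt(abs(s$e_rf), 1e-6)
  expect_lt(abs(s$total_induced), 1e-6)
})

test_that("Gauss law: induced surface charge matches -q(1 - 1/80)", {
  # monoatomic
  stO <- single_atom_structure(radius = 2.0)
  s1 <- solve_pb(stO, charge_set(1, "force_field"),
                 dielectric_model(1, 80, probe = 0),
                 spacing = 0.4, padding = 7)
  expect_lt(abs(s1$total_induced - (-1 * (1 - 1 / 80))) / (1 - 1 / 80), 0.02)

  # multi-atom, net charge -1 (glutamate tripeptide)
  st <- build_peptide("AEA")
  ref <- load_reference_charges(st)
  s2 <- solve_pb(st, ref, dielectric_model(1, 80, probe = 1.4),
                 spacing = 0.5, padding = 7)
  target <- -ref$total * (1 - 1 / 80)
  expect_lt(abs(s2$total_induced - target) / abs(target), 0.02)
})

test_that("reaction-field energy is invariant under rigid motion", {
  st <- build_peptide("AGA")
  ref <- load_reference_charges(st)
  model <- dielectric_model(1, 80, probe = 1.4)
  e0 <- solve_pb(st, ref, model, spacing = 0.5, padding = 6)$e_rf

  shift <- c(0.23, -0.17, 0.31)
  st_t <- st
  st_t$atoms$x <- st$atoms$x + shift[1]
  st_t$atoms$y <- st$atoms$y + shift[2]
  st_t$atoms$z <- st$atoms$z + shift[3]
  e_t <- solve_pb(st_t, ref, model, spacing = 0.5, padding = 6)$e_rf
  expect_lt(abs(e_t - e0) / abs(e0), 0.005)

  # 90-degree rotation about z maps the lattice onto itself up to origin
  st_r <- st
  st_r$atoms$x <- -st$atoms$y
  st_r$atoms$y <- st$atoms$x
  e_r <- solve_pb(st_r, ref, model, spacing = 0.5, padding = 6)$e_rf
  expect_lt(abs(e_r - e0) / abs(e0), 0.005)
})

test_that("charges outside the cavity are rejected", {
  stO <- single_atom_structure(radius = 2.0)
  b <- build_dielectric_boundary(stO, spacing = 0.5, padding = 6, probe = 0)
  st2 <- new_structure(data.frame(
    serial = 1:2, name = "O", element = "O", resname = "GLY",
    residue_index = 1:2, x = c(0, 4.5), y = 0, z = 0, radius = 2.0))
  expect_error(
    solve_pb(st2, charge_set(c(1, 1), "force_field"),
             dielectric_model(1, 80, probe = 0), spacing = 0.5,
             padding = 6, boundary = b),
    "outside")
})

test_that("SCRF: zero-gain fixed point and small-gain contraction", {
  st <- build_peptide("AGA")
  ref <- mock_ref(st)
  out0 <- scrf_iterate(st, mock_esp_backend(ref, 0), ref, lambda = 0,
                       spacing = 0.6, padding = 5, tol = 0.1)
  expect_true(out0$converged)
  expect_equal(out0$iterations, 2)
  expect_equal(out0$history[2] - out0$history[1], 0, tolerance = 1e-12)
  # charges never changed
  expect_lt(max(abs(out0$charges$charges - ref$charges)), 1e-9)

  out <- scrf_iterate(st, mock_esp_backend(ref, 0.05), ref, lambda = 0,
                      spacing = 0.6, padding = 5, tol = 1e-5, max_iter = 10)
  expect_true(out$converged)
  d <- abs(diff(out$history))
  expect_true(all(diff(d) < 0))   # monotone geometric contraction

  # huge tolerance stops at the first energy comparison
  fast <- scrf_iterate(st, mock_esp_backend(ref, 0.05), ref, lambda = 0,
                       spacing = 0.6, padding = 5, tol = 1e6)
  expect_equal(fast$iterations, 2)
})

test_that("relative solvation energies: duplicates give zero, table shape", {
  st <- build_peptide("AGA")
  confs <- list(st, st, st)
  tab <- relative_solvation_energies(confs, gain = 0, lambda = 0,
                                     spacing = 0.6, padding = 5, tol = 0.1)
  expect_equal(tab$relative, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(tab$conformer, 1:3)

  # distinct conformers: iterative result close to single-shot PB on the
  # reference charges (zero gain -> identical by construction)
  confs2 <- make_conformers("AGA", n = 3, sigma = 10, seed = 5)
  tab2 <- relative_solvation_energies(confs2, gain = 0, lambda = 0,
                                      spacing = 0.6, padding = 5, tol = 0.1)
  single <- vapply(confs2, function(s) {
    solve_pb(s, load_reference_charges(s),
             dielectric_model(), spacing = 0.6, padding = 5)$e_rf
  }, numeric(1))
  expect_equal(tab2$relative, single - single[1], tolerance = 1e-6)

  # topology mismatch is rejected
  expect_error(relative_solvation_energies(list(st, build_peptide("ASA")),
                                           gain = 0),
               "topology")
})
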