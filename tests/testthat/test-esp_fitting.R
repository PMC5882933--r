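test_that("MK grid geometry: shell radius, counts, exclusion", {
  g <- generate_mk_grid(matrix(0, 1, 3), 1.5, shells = 1.4, density = 1.0)
  d <- sqrt(rowSums(g^2))
  expect_equal(nrow(g), round(4 * pi * 2.1^2 * 1.0))
  expect_equal(range(d), c(2.1, 2.1), tolerance = 1e-9)

  # two overlapping atoms: no point inside either scaled sphere
  pos <- rbind(c(0, 0, 0), c(1.0, 0, 0))
  g2 <- generate_mk_grid(pos, c(1.5, 1.5), shells = 1.4, density = 2.0)
  d1 <- sqrt(rowSums(sweep(g2, 2, pos[1, ])^2))
  d2 <- sqrt(rowSums(sweep(g2, 2, pos[2, ])^2))
  expect_true(all(pmin(d1, d2) >= 2.1 - 1e-6))
  expect_error(generate_mk_grid(pos, c(1.5, 1.5), shells = 0.9),
               "shells")
})

test_that("MK surface coverage matches a rejection-sampling oracle", {
  pos <- rbind(c(0, 0, 0), c(2.0, 0, 0))
  rad <- c(1.5, 1.4)
  s <- 1.4
  g <- generate_mk_grid(pos, rad, shells = s, density = 4.0)
  # fraction of atom-1 sphere points kept by the Fibonacci construction
  on1 <- abs(sqrt(rowSums(sweep(g, 2, pos[1, ])^2)) - s * rad[1]) < 1e-6
  frac_fib <- sum(on1) / round(4 * pi * (s * rad[1])^2 * 4.0)
  # Monte-Carlo estimate of the exposed fraction of that sphere
  set.seed(11)
  m <- 40000
  u <- matrix(rnorm(3 * m), m, 3)
  u <- u / sqrt(rowSums(u^2))
  pts <- sweep(s * rad[1] * u, 2, pos[1, ], "+")
  keep <- sqrt(rowSums(sweep(pts, 2, pos[2, ])^2)) >= s * rad[2]
  expect_equal(frac_fib, mean(keep), tolerance = 0.02)
})

test_that("fit recovers generating charges exactly and honors constraints", {
  xyz <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3.5, 0))
  qtrue <- c(0.41, -0.73, 0.32)
  grid <- generate_mk_grid(xyz, rep(1.5, 3), density = 1.0)
  esp <- direct_potential(qtrue, xyz, grid)
  fit <- fit_charges(grid, esp, xyz, sum(qtrue))
  expect_lt(max(abs(fit$charges - qtrue)), 1e-8)
  expect_lt(fit$rms, 1e-10)
  expect_lt(abs(sum(fit$charges) - sum(qtrue)), 1e-10)

  # consistent restraint leaves the solution unchanged
  r <- data.frame(atom = 1, target = qtrue[1], weight = 5)
  fit2 <- fit_charges(grid, esp, xyz, sum(qtrue), restraints = r)
  expect_equal(fit2$charges, fit$charges, tolerance = 1e-8)

  # grid must be at least as large as the number of charges
  expect_error(fit_charges(grid[1:2, ], esp[1:2], xyz, 0), "at least")
})

test_that("w -> Inf penalty limit reproduces the equality-constrained solve", {
  xyz <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3.5, 0), c(2, 2, 2))
  qtrue <- c(0.2, -0.5, 0.4, -0.1)
  grid <- generate_mk_grid(xyz, rep(1.5, 4), density = 1.0)
  esp <- direct_potential(qtrue, xyz, grid)
  # inconsistent target forces a genuine penalty-vs-equality comparison
  target <- qtrue[2] + 0.05
  A <- coulomb_design(grid, xyz)
  q_eq <- equality_fit_oracle(A, esp, sum(qtrue), 2, target)
  fit <- fit_charges(grid, esp, xyz, sum(qtrue),
                     restraints = data.frame(atom = 2, target = target,
                                             weight = 1e6))
  expect_lt(max(abs(fit$charges - q_eq)), 1e-5)
  expect_lt(abs(sum(fit$charges) - sum(qtrue)), 1e-10)
})

test_that("subsystem fits: exact recovery, link restraints, density stability", {
  st <- build_peptide("AAGAA")
  ref <- mock_ref(st)
  be0 <- mock_esp_backend(ref, 0)
  fits <- fit_all_subsystems(st, be0, ref, lambda = 0)
  for (f in fits$fragments) {
    expect_lt(max(abs(f$parent_charges - ref$charges[f$subsystem$atom_idx])),
              1e-8)
    expect_true(all(abs(f$link_charges) < 1e-8))
  }
  # concap link charges match fragment link charges (all ~0 at gain 0)
  for (cc in fits$concaps) expect_true(all(abs(cc$link_charges) < 1e-8))

  # perturbed ESP: concap link charge deviates from its fragment target by
  # less than the penalty-algebra bound sqrt(residual SS / w_link)
  be <- mock_esp_backend(ref, 0.05)
  fits2 <- fit_all_subsystems(st, be, ref, lambda = 0)
  targets <- unlist(lapply(fits2$fragments, `[[`, "link_charges"))
  cfg <- fit_config()
  for (cc in fits2$concaps) {
    dev <- abs(cc$link_charges - targets[names(cc$link_charges)])
    ss <- cc$rms^2 * cc$n_grid   # residual sum of squares
    expect_true(all(dev < sqrt(ss / cfg$w_link) + 1e-6))
  }

  # doubling grid density moves fitted charges by < 1e-3 e
  f1 <- fit_subsystem(st, build_fragments(st)[[1]], be, ref,
                      fit_config(density = 1.0))
  f2 <- fit_subsystem(st, build_fragments(st)[[1]], be, ref,
                      fit_config(density = 2.0))
  expect_lt(max(abs(f1$parent_charges - f2$parent_charges)), 1e-3)
})

test_that("hyperbolic RESP restraint shrinks heavy-atom charges", {
  xyz <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3.5, 0))
  qtrue <- c(0.41, -0.73, 0.32)
  grid <- generate_mk_grid(xyz, rep(1.5, 3), density = 1.0)
  esp <- direct_potential(qtrue, xyz, grid)
  plain <- fit_charges(grid, esp, xyz, sum(qtrue))
  resp <- fit_charges(grid, esp, xyz, sum(qtrue), resp = TRUE,
                      resp_a = 0.01, heavy = rep(TRUE, 3))
  expect_lt(sum(abs(resp$charges[1:2])), sum(abs(plain$charges[1:2])))
  expect_lt(abs(sum(resp$charges) - sum(qtrue)), 1e-10)
})
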