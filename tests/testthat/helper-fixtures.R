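# Shared fixtures and independent brute-force oracles. Oracles are written
# as plainly as possible (double loops, closed forms) and never call the
# code paths they check.

single_atom_structure <- function(radius = 1.5, element = "O",
                                  pos = c(0, 0, 0), name = element) {
  new_structure(data.frame(
    serial = 1L, name = name, element = element, resname = "GLY",
    residue_index = 1L, x = pos[1], y = pos[2], z = pos[3],
    radius = radius))
}

mock_ref <- function(st) {
  load_reference_charges(st, provenance = "mock_reference")
}

# O(n^2) double-loop residue-pair search, independent of find_two_body_pairs
brute_pairs <- function(st, lambda) {
  xyz <- coords(st)
  ridx <- st$atoms$residue_index
  out <- list()
  for (i in seq_len(st$nres)) {
    for (j in seq_len(st$nres)) {
      if (j < i + 3) next
      dmin <- Inf
      for (a in which(ridx == i)) {
        for (b in which(ridx == j)) {
          d <- sqrt(sum((xyz[a, ] - xyz[b, ])^2))
          if (d < dmin) dmin <- d
        }
      }
      if (dmin <= lambda) out[[length(out) + 1L]] <- c(i, j)
    }
  }
  out
}

# plain double-loop Coulomb sum in atomic units
direct_potential <- function(q, xyz, pts) {
  v <- numeric(nrow(pts))
  for (g in seq_len(nrow(pts))) {
    s <- 0
    for (k in seq_along(q)) {
      s <- s + q[k] / (sqrt(sum((pts[g, ] - xyz[k, ])^2)) * 1.8897259886)
    }
    v[g] <- s
  }
  v
}

# equality-constrained least-squares oracle: min |Aq - V|^2 subject to
# sum(q) = Q and q[fix_idx] = fix_val (KKT with two hard constraints)
equality_fit_oracle <- function(A, V, Q, fix_idx, fix_val) {
  n <- ncol(A)
  C <- rbind(rep(1, n), as.numeric(seq_len(n) == fix_idx))
  M <- rbind(cbind(crossprod(A), t(C)),
             cbind(C, matrix(0, 2, 2)))
  rhs <- c(crossprod(A, V), Q, fix_val)
  solve(M, rhs)[seq_len(n)]
}

# design matrix of the charge-fit model (1/r in bohr), for oracles
coulomb_design <- function(pts, xyz) {
  A <- matrix(0, nrow(pts), nrow(xyz))
  for (g in seq_len(nrow(pts))) {
    for (k in seq_len(nrow(xyz))) {
      A[g, k] <- 1 / (sqrt(sum((pts[g, ] - xyz[k, ])^2)) * 1.8897259886)
    }
  }
  A
}

born_exact <- function(q, R, eps_out) {
  -0.5 * (1 - 1 / eps_out) * 332.06 * q^2 / R
}
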