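# PDB fixture text built in code.
pdb_atom_line <- function(serial, elety, resid, chain, resno, x, y, z,
                          o = 1, altloc = "") {
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          serial, ifelse(nchar(elety) < 4, paste0(" ", elety), elety),
          altloc, resid, chain, resno, x, y, z, o, 20.0)
}

test_that("PDB parsing keeps coordinates and occupancy-selects altlocs", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_atom_line(1, "N", "ALA", "A", 1, 1.234, 2.345, 3.456),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 4.567, 5.678, 6.789),
    pdb_atom_line(3, "C", "ALA", "A", 1, 7.891, 8.912, 9.123),
    "END"), f)
  m <- read_structure(f)
  expect_equal(nrow(m$atoms), 3L)
  expect_equal(m$atoms$x[m$atoms$elety == "CA"], 4.567)
  expect_equal(m$atoms$z[m$atoms$elety == "C"], 9.123)

  f2 <- tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 9.0, 0, 0, o = 0.4, altloc = "A"),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 1.0, 0, 0, o = 0.6, altloc = "B"),
    "END"), f2)
  m2 <- read_structure(f2)
  expect_equal(nrow(m2$atoms), 1L)
  expect_equal(m2$atoms$x, 1.0)  # the 0.6-occupancy conformer wins

  expect_error(read_structure(tempfile(fileext = ".pdb")), "not found")
})

test_that("kabsch recovers exact superposition of rigid copies", {
  set.seed(50)
  P <- matrix(rnorm(30), 10, 3)
  fit0 <- kabsch(P, P)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit0$U, diag(3), tolerance = 1e-9)
  expect_equal(fit0$t, c(0, 0, 0), tolerance = 1e-9)

  th <- 0.7
  U <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  Q <- P %*% t(U) + matrix(c(5, -3, 2), 10, 3, byrow = TRUE)
  fit <- kabsch(P, Q)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(det(fit$U), 1, tolerance = 1e-9)
})

test_that("reflection guard: mirrored inputs still give det(U) = +1", {
  set.seed(51)
  P <- matrix(rnorm(45), 15, 3)
  Qm <- P
  Qm[, 1] <- -Qm[, 1]  # mirror image
  fit <- kabsch(P, Qm)
  expect_equal(det(fit$U), 1, tolerance = 1e-9)
  expect_gt(fit$rmsd, 0)
})

test_that("rmsd^2 equals the mean squared per-pair deviation exactly", {
  set.seed(52)
  P <- matrix(rnorm(60), 20, 3)
  Q <- P + matrix(rnorm(60, sd = 0.4), 20, 3)
  fit <- kabsch(P, Q)
  expect_equal(fit$rmsd^2, mean(fit$deviations^2), tolerance = 1e-12)
  # superposition never beats zero but never exceeds unsuperposed distances
  d_raw <- sqrt(mean(rowSums((P - Q)^2)))
  expect_lte(fit$rmsd, d_raw + 1e-12)
})

test_that("kabsch matches a direct numerical minimizer over rotations", {
  set.seed(53)
  P <- matrix(rnorm(15), 5, 3)
  Q <- P
  Q[3, ] <- Q[3, ] + c(1, 0, 0)  # one point displaced by 1 A
  fit <- kabsch(P, Q)
  # oracle: minimize rmsd over Euler angles + translation numerically
  obj <- function(par) {
    cz <- cos(par[1]); sz <- sin(par[1])
    cy <- cos(par[2]); sy <- sin(par[2])
    cx <- cos(par[3]); sx <- sin(par[3])
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
    U <- Rz %*% Ry %*% Rx
    Qf <- Q %*% t(U) + matrix(par[4:6], nrow(Q), 3, byrow = TRUE)
    sqrt(mean(rowSums((P - Qf)^2)))
  }
  best <- min(vapply(1:20, function(i) {
    stats::optim(c(runif(3, -pi, pi), rnorm(3)), obj,
                 method = "BFGS", control = list(maxit = 500))$value
  }, 0))
  expect_equal(fit$rmsd, best, tolerance = 1e-4)
})

test_that("kabsch rejects degenerate point sets", {
  line <- cbind(1:5, 2 * (1:5), -(1:5))  # collinear
  expect_error(kabsch(line, line + 1), "degenerate")
  expect_error(kabsch(matrix(0, 2, 3), matrix(0, 2, 3)), "at least 3")
})

test_that("sequence-built correspondence superposes chains and reports
           per-residue deviations", {
  pair <- simulate_structure_pair(seed = 60, n_points = 50, noise_sigma = 0)
  sup <- superpose(pair$a, pair$b)
  expect_equal(sup$n_pairs, 50L)
  expect_lt(sup$rmsd, 1e-9)
  expect_true(all(per_residue_deviation(sup)$deviation < 1e-9))
  expect_equal(sup$rmsd^2, mean(sup$per_pair_deviation^2),
               tolerance = 1e-12)

  # displace one residue: exactly one nonzero deviation
  b2 <- pair$a
  b2$atoms$x[b2$atoms$resno == 25] <- b2$atoms$x[b2$atoms$resno == 25] + 2
  corr <- build_correspondence(pair$a, b2)
  # keep the fit anchored on the other 49 residues by superposing without
  # the displaced pair, then measure deviations over all pairs
  sup2 <- superpose(pair$a, b2, corr = corr)
  dev <- per_residue_deviation(sup2)
  expect_equal(sum(dev$deviation > 0.5), 1L)
  expect_equal(dev$resno_a[dev$deviation > 0.5], 25)
})

test_that("noisy rigid pairs superpose near the expected rmsd", {
  pair <- simulate_structure_pair(seed = 61, n_points = 500,
                                  noise_sigma = 0.5)
  sup <- superpose(pair$a, pair$b)
  expect_lt(abs(sup$rmsd - pair$expected_rmsd) / pair$expected_rmsd, 0.05)
  # recovered transform inverts the true one (sigma = 0 case)
  exact <- simulate_structure_pair(seed = 62, n_points = 40,
                                   noise_sigma = 0)
  supx <- superpose(exact$a, exact$b)
  expect_equal(supx$U %*% exact$U_true, diag(3), tolerance = 1e-6)

  # mean per-residue deviation tracks the chi-distribution expectation
  p2 <- simulate_structure_pair(seed = 63, n_points = 100, noise_sigma = 0.5)
  s2 <- superpose(p2$a, p2$b)
  expect_mean <- 0.5 * sqrt(1 - 2 / 100) * sqrt(2) * gamma(2) / gamma(1.5)
  se <- 0.5 * sqrt((3 - (sqrt(2) * gamma(2) / gamma(1.5))^2) / 100)
  expect_lt(abs(mean(s2$per_pair_deviation) - expect_mean), 3 * se)
})

test_that("functional-group distances follow the terminal-charged-atom rule", {
  lys <- res_atom_rows("A", 68, "LYS", list(
    N = c(0, 0, 0), CA = c(1.5, 0, 0), C = c(2.2, 1.2, 0), O = c(2.0, 2.4, 0),
    CB = c(2.0, -1.4, 0), CG = c(3.5, -1.5, 0), CD = c(4.2, -2.8, 0),
    CE = c(5.7, -2.9, 0), NZ = c(6.4, -4.1, 0)))
  glu <- res_atom_rows("A", 83, "GLU", list(
    N = c(10, 0, 0), CA = c(11, 0, 0), C = c(12, 1, 0), O = c(12, 2, 0),
    CB = c(11, -1.4, 0), CG = c(10.5, -2.7, 0), CD = c(9.6, -3.8, 0),
    OE1 = c(6.4, -9.1, 0),     # 5.00 A from NZ
    OE2 = c(8.6, -14.9, 0)))   # far side of the carboxylate
  m <- structure_model(rbind(lys, glu))
  d <- functional_group_distance(m, "A/68", "A/83")
  expect_equal(unname(d$per_chain["A"]), 5.0, tolerance = 1e-9)

  # closest-heavy-sidechain uses all side-chain atoms, so is never larger
  d2 <- functional_group_distance(m, "A/68", "A/83",
                                  rule = "closest-heavy-sidechain")
  expect_lte(d2$per_chain["A"], d$per_chain["A"])

  # a residue against itself is at distance zero (up to rounding)
  d0 <- functional_group_distance(m, "A/68", "A/68")
  expect_lt(unname(d0$per_chain["A"]), 1e-6)

  # two chain copies aggregate as mean +/- half-range
  lysB <- lys; lysB$chain <- "B"; lysB$x <- lysB$x + 100
  gluB <- glu; gluB$chain <- "B"
  gluB$x <- gluB$x + 100
  gluB$y[gluB$elety == "OE1"] <- gluB$y[gluB$elety == "OE1"] - 0.48
  m2 <- structure_model(rbind(lys, glu, lysB, gluB))
  d3 <- functional_group_distance(m2, "68", "83")
  expect_length(d3$per_chain, 2L)
  expect_equal(d3$mean, mean(d3$per_chain))
  expect_equal(d3$spread, diff(range(d3$per_chain)) / 2)

  # missing side chain: unresolved, never a fabricated number
  bare <- res_atom_rows("A", 5, "GLY", list(N = c(0, 0, 0),
                                            CA = c(1.5, 0, 0)))
  m3 <- structure_model(rbind(bare, glu))
  d4 <- functional_group_distance(m3, "A/5", "A/83")
  expect_true("A" %in% d4$unresolved)
  expect_true(is.na(d4$mean))
})

test_that("spine contiguity uses consecutive side-chain distances", {
  mk <- function(x3) res_atom_rows("A", x3[[1]], "LEU", list(
    N = c(x3[[2]], 1, 0), CA = c(x3[[2]], 0, 0), C = c(x3[[2]], -1, 0),
    O = c(x3[[2]], -2, 0), CB = c(x3[[2]], 0, 1.5),
    CD1 = c(x3[[2]], 0, 2.5)))
  m <- structure_model(rbind(mk(list(1, 0)), mk(list(2, 4)),
                             mk(list(3, 8))))
  rep1 <- spine_check(m, c("A/1", "A/2", "A/3"), cutoff = 5.5)
  expect_true(rep1$contiguous)
  expect_equal(rep1$pairs$distance, c(4, 4))

  m2 <- structure_model(rbind(mk(list(1, 0)), mk(list(2, 4)),
                              mk(list(3, 24))))
  rep2 <- spine_check(m2, c("A/1", "A/2", "A/3"), cutoff = 5.5)
  expect_false(rep2$contiguous)
  expect_equal(rep2$pairs$from[rep2$pairs$distance > 5.5], "A/2")

  rep3 <- spine_check(m2, c("A/1", "A/2", "A/9"))
  expect_true(is.na(rep3$contiguous))
  expect_equal(rep3$missing, "A/9")

  # completion contact reported alongside
  rep4 <- spine_check(m, c("A/1", "A/2"), completion = list("A/2", "A/3"))
  expect_equal(rep4$completion, 4)
})

test_that("structure pair simulation validates inputs and mirrors safely", {
  expect_error(simulate_structure_pair(noise_sigma = -1), ">= 0")
  expect_error(simulate_structure_pair(n_points = 3), ">= 4")
  pair <- simulate_structure_pair(seed = 64, n_points = 30, noise_sigma = 0)
  mirrored <- pair$b
  mirrored$atoms$x <- -mirrored$atoms$x
  sup <- superpose(pair$a, mirrored)
  expect_equal(det(sup$U), 1, tolerance = 1e-9)
  expect_gt(sup$rmsd, 0)
})
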