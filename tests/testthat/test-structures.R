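test_that("parse_structure reads a minimal PDB, drops hydrogens, resolves altlocs", {
  f <- tempfile(fileext = ".pdb")
  writeLines(minimal_pdb_lines(), f)
  m <- parse_structure(f, "A")
  expect_s3_class(m, "monomer_structure")
  expect_equal(m$L, 2L)
  expect_equal(nrow(m$atoms), 3L)
  expect_equal(m$sequence, "AG")

  # added hydrogen must not change the heavy-atom count
  lines <- minimal_pdb_lines()
  hline <- "ATOM      4  H   GLY A   2       4.500   1.500   0.000  1.00  0.00           H"
  writeLines(append(lines, hline, after = 3), f)
  m2 <- parse_structure(f, "A")
  expect_equal(nrow(m2$atoms), 3L)

  # altloc duplicates: exactly one copy kept, the higher occupancy
  alt <- c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       2.000   0.000   0.000  0.60  0.00           C",
    "END")
  writeLines(alt, f)
  m3 <- parse_structure(f, "A")
  expect_equal(nrow(m3$atoms), 1L)
  expect_equal(m3$atoms$x, 2.0)   # occupancy 0.60 wins

  expect_error(parse_structure(f, "Z"), "available chains")
})

test_that("numbering gaps become unobserved placeholder residues", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   4       9.000   0.000   0.000  1.00  0.00           C",
    "END"), f)
  m <- parse_structure(f, "A")
  expect_equal(m$L, 4L)
  expect_equal(m$observed, c(TRUE, FALSE, FALSE, TRUE))
  dm <- intra_distance_map(m)
  expect_false(any(dm$mask[2, ]))
  expect_true(dm$mask[1, 4])
})

test_that("min heavy-atom distance matches the exhaustive pair minimum", {
  ra <- list(name = "ALA", observed = TRUE, xyz = rbind(c(0, 0, 0)))
  rb <- list(name = "ALA", observed = TRUE, xyz = rbind(c(0, 0, 7.5)))
  expect_equal(min_heavy_atom_distance(ra, rb), 7.5)
  rb2 <- list(name = "ALA", observed = TRUE,
              xyz = rbind(c(0, 0, 7.5), c(0, 0, 3)))
  expect_equal(min_heavy_atom_distance(ra, rb2), 3.0)

  set.seed(42)
  r5 <- list(name = "X", observed = TRUE, xyz = matrix(rnorm(15, sd = 3), 5, 3))
  r4 <- list(name = "X", observed = TRUE, xyz = matrix(rnorm(12, sd = 3), 4, 3))
  brute <- Inf
  for (i in 1:5) for (j in 1:4) {
    brute <- min(brute, sqrt(sum((r5$xyz[i, ] - r4$xyz[j, ])^2)))
  }
  expect_equal(min_heavy_atom_distance(r5, r4), brute)

  runobs <- list(name = "X", observed = FALSE, xyz = matrix(0, 0, 3))
  expect_error(min_heavy_atom_distance(ra, runobs), "undefined")
})

test_that("intra distance map is symmetric and equals pairwise brute force", {
  m <- helix_monomer(10)
  dm <- intra_distance_map(m)
  expect_equal(dim(dm$values), c(10L, 10L))
  expect_equal(dm$values, t(dm$values))
  expect_true(all(diag(dm$values) == 0))
  for (i in 1:10) for (j in 1:10) {
    expect_equal(dm$values[i, j],
                 min_heavy_atom_distance(residue(m, i), residue(m, j)))
  }
  m1 <- point_monomer(matrix(0, 1, 3))
  expect_equal(intra_distance_map(m1)$values, matrix(0, 1, 1))
})

test_that("inter contacts respect the 8 A cutoff inclusively and monotonically", {
  mk_pair <- function(dz) {
    a <- point_monomer(matrix(c(0, 0, 0), 1))
    b <- point_monomer(matrix(c(0, 0, dz), 1))
    dimer_structure(a, b)
  }
  expect_equal(inter_contact_map(mk_pair(7.9))$values[1, 1], 1L)
  expect_equal(inter_contact_map(mk_pair(8.0))$values[1, 1], 1L)  # inclusive
  expect_equal(inter_contact_map(mk_pair(8.1))$values[1, 1], 0L)

  fx <- make_c2_dimer(fixture_spec(n_residues = 30, seed = 9, n_interface = 3))
  c8 <- inter_contact_map(fx$dimer, 8)$values
  c6 <- inter_contact_map(fx$dimer, 6)$values
  expect_true(all(c6 <= c8))   # contacts(6) subset of contacts(8)
  want <- matrix(0L, 30, 30)
  want[fx$interface_pairs] <- 1L
  expect_equal(c8, symmetrize_labels(want))
})

test_that("dataset filter predicates report exactly the violated rules", {
  good <- structure_record(2.0, 2, 200, 1.0, "C2", 1500)
  r <- passes_dataset_filters(good)
  expect_true(r$pass)
  expect_length(r$failed, 0)

  # resolution bound is strict
  at_bound <- structure_record(3.0, 2, 200, 1.0, "C2", 1500)
  r2 <- passes_dataset_filters(at_bound)
  expect_false(r2$pass)
  expect_equal(r2$failed, "resolution")

  # synthetic table with known violations; k failing rules reported as k
  recs <- list(
    structure_record(2.5, 2, 100, 1.0, "C2", 1200),   # pass
    structure_record(3.5, 2, 100, 1.0, "C2", 1200),   # resolution
    structure_record(2.5, 3, 100, 1.0, "C2", 1200),   # n_chains
    structure_record(2.5, 2, 30, 1.0, "C2", 1200),    # length (short)
    structure_record(2.5, 2, 600, 1.0, "C2", 1200),   # length (long)
    structure_record(2.5, 2, 100, 0.95, "C2", 1200),  # identity
    structure_record(2.5, 2, 100, 1.0, "D2", 1200),   # symmetry
    structure_record(2.5, 2, 100, 1.0, "C2", 900),    # interface
    structure_record(2.5, 2, 100, 1.0, "C2", 1000),   # interface (strict)
    structure_record(3.2, 4, 100, 1.0, "C2", 1200),   # 2 rules
    structure_record(3.2, 4, 20, 0.5, "D7", 1200)     # 5 rules
  )
  recs <- c(recs, replicate(9, recs[[1]], simplify = FALSE))  # 20 records
  res <- lapply(recs, passes_dataset_filters)
  expect_equal(sum(vapply(res, `[[`, logical(1), "pass")), 10L)
  expect_length(res[[10]]$failed, 2L)
  expect_length(res[[11]]$failed, 5L)
  expect_setequal(res[[11]]$failed,
                  c("resolution", "n_chains", "length", "identity", "symmetry"))
})
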