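test_that("generated dimers plant exactly the requested interface", {
  sp <- fixture_spec(n_residues = 30, seed = 12, n_interface = 3)
  fx <- make_c2_dimer(sp)
  cm <- inter_contact_map(fx$dimer, 8.0)
  want <- matrix(0L, 30, 30)
  want[fx$interface_pairs] <- 1L
  want <- symmetrize_labels(want)
  expect_equal(unname(cm$values), unname(want))

  # the returned transform maps chain A onto chain B
  ca <- as.matrix(fx$dimer$chain_a$atoms[, c("x", "y", "z")])
  cb <- as.matrix(fx$dimer$chain_b$atoms[, c("x", "y", "z")])
  moved <- ca %*% t(fx$transform$rotation) +
    matrix(fx$transform$translation, nrow(ca), 3, byrow = TRUE)
  expect_lt(max(abs(moved - cb)), 1e-9)

  # the transform is an exact two-fold
  R <- fx$transform$rotation
  expect_lt(max(abs(R %*% R - diag(3))), 1e-12)
})

test_that("fixture generation is deterministic and files are reproducible", {
  sp <- fixture_spec(n_residues = 18, seed = 77, n_interface = 2)
  fx1 <- make_c2_dimer(sp)
  fx2 <- make_c2_dimer(sp)
  expect_identical(fx1$sequence, fx2$sequence)
  expect_identical(fx1$dimer$chain_a$atoms, fx2$dimer$chain_a$atoms)

  f1 <- tempfile(fileext = ".pdb"); f2 <- tempfile(fileext = ".pdb")
  write_dimer_pdb(fx1$dimer, f1)
  write_dimer_pdb(fx2$dimer, f2)
  expect_identical(readLines(f1), readLines(f2))

  # round trip through the structure parser preserves the contact map
  pa <- parse_structure(f1, chain = "A")
  pb <- parse_structure(f1, chain = "B")
  d <- dimer_structure(pa, pb)
  cm <- inter_contact_map(d, 8.0)
  expect_equal(unname(cm$values), unname(inter_contact_map(fx1$dimer)$values))
})

test_that("planted covariation is visible to a direct mutual-information scan", {
  mi_matrix <- function(mat) {
    L <- ncol(mat)
    MI <- matrix(0, L, L)
    for (i in 1:(L - 1)) for (j in (i + 1):L) {
      tab <- table(mat[, i], mat[, j])
      pxy <- tab / sum(tab)
      px <- rowSums(pxy); py <- colSums(pxy)
      mi <- 0
      for (a in seq_along(px)) for (b in seq_along(py)) {
        if (pxy[a, b] > 0) {
          mi <- mi + pxy[a, b] * log(pxy[a, b] / (px[a] * py[b]))
        }
      }
      MI[i, j] <- MI[j, i] <- mi
    }
    MI
  }
  pair <- rbind(c(3L, 9L))
  sp1 <- fixture_spec(n_residues = 12, seed = 4, msa_depth = 500,
                      coupling_strength = 1, interface_pairs = pair)
  m1 <- make_synthetic_msa(sp1)
  MI1 <- mi_matrix(m1$mat)
  ut <- which(upper.tri(MI1), arr.ind = TRUE)
  top <- ut[which.max(MI1[ut]), ]
  expect_equal(sort(unname(top)), c(3L, 9L))

  # with the coupling switched off all pairs look alike
  sp0 <- fixture_spec(n_residues = 12, seed = 4, msa_depth = 500,
                      coupling_strength = 0, interface_pairs = pair)
  MI0 <- mi_matrix(make_synthetic_msa(sp0)$mat)
  expect_lt(MI0[3, 9], 0.5 * MI1[3, 9])
  expect_lt(max(MI0[ut]), 0.5 * MI1[3, 9])
})

test_that("training sets follow the deterministic split and carry full bundles", {
  ts <- make_training_set(5, seed = 3, n_residues = 16, msa_depth = 40,
                          n_interface = 2, dock_interval = 90, dock_top_t = 5)
  expect_equal(length(ts$all), 5L)
  expect_equal(length(ts$val), 1L)
  expect_equal(length(ts$train), 4L)
  tg <- ts$val[[1]]
  expect_s3_class(tg$bundle, "feature_bundle")
  expect_equal(dim(tg$labels$values), c(16L, 16L))
  expect_equal(tg$labels$values, t(tg$labels$values))
  expect_true(sum(tg$labels$values) > 0)
})

test_that("infeasible plantings are rejected", {
  expect_error(
    make_c2_dimer(fixture_spec(n_residues = 20, seed = 1,
                               interface_pairs = rbind(c(4L, 4L)))),
    "infeasible")
  expect_error(
    make_c2_dimer(fixture_spec(n_residues = 20, seed = 1,
                               interface_pairs = rbind(c(2L, 5L), c(5L, 9L)))),
    "infeasible")
  expect_error(
    make_c2_dimer(fixture_spec(n_residues = 20, seed = 1,
                               interface_pairs = rbind(c(2L, 25L)))),
    "out of range")
})
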