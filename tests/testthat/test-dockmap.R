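test_that("C2 rotation samples are orthonormal, distinct, and scale with interval", {
  rots <- sample_rotations(90)
  expect_gte(length(rots), 1)
  for (R in rots) {
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-12)
    expect_equal(det(R), 1, tolerance = 1e-12)
    # an involution: applying the C2 rotation twice is the identity
    expect_lt(max(abs(R %*% R - diag(3))), 1e-12)
  }
  # no two rotations equivalent under the chain swap (R is self-inverse,
  # so distinctness of the matrices is the full check)
  r30 <- sample_rotations(30)
  for (i in seq_along(r30)) {
    for (j in seq_along(r30)) {
      if (i < j) expect_gt(max(abs(r30[[i]] - r30[[j]])), 1e-9)
    }
  }
  # halving the interval grows the axis count ~4x (area scaling)
  n1 <- length(sample_rotations(24))
  n2 <- length(sample_rotations(12))
  expect_gte(n2 / n1, 3.5)
  expect_lte(n2 / n1, 8.5)
})

test_that("grid projection labels are exclusive and translation-equivariant", {
  g <- grid_project(matrix(c(5, 5, 5), 1, 3), spacing = 1.0)
  expect_true(any(g$labels == 2))
  expect_true(any(g$labels == 1))
  # exclusivity is structural: one label array
  expect_true(all(g$labels %in% 0:2))

  coords <- matrix(runif(30, 3, 9), 10, 3)
  g1 <- grid_project(coords, spacing = 1.2, dims = c(16L, 16L, 16L),
                     origin = c(0, 0, 0))
  g2 <- grid_project(coords + 1.2, spacing = 1.2, dims = c(17L, 17L, 17L),
                     origin = c(0, 0, 0))
  expect_equal(g1$labels[1:16, 1:16, 1:16],
               g2$labels[2:17, 2:17, 2:17])
  expect_error(grid_project(coords, spacing = 0), "spacing")
})

test_that("FFT translation scan equals brute-force direct-space correlation", {
  mk <- function(n, seed) {
    set.seed(seed)
    grid_project(matrix(runif(n * 3, 2, 12), n, 3), spacing = 1.2,
                 dims = c(16L, 16L, 16L), origin = c(0, 0, 0))
  }
  ga <- mk(18, 1); gb <- mk(14, 2)
  top <- fft_translation_scan(ga, gb, top_t = 10, core_penalty = 15)
  expect_equal(nrow(top), 10L)
  expect_true(all(diff(top$score) <= 1e-9))

  brute <- function(ga, gb, s, penalty = 15) {
    sa <- (ga$labels == 1) + 0; ca <- (ga$labels == 2) + 0
    sb <- (gb$labels == 1) + 0; cb <- (gb$labels == 2) + 0
    tot <- 0
    for (x in 1:16) for (y in 1:16) for (z in 1:16) {
      bx <- x - s[1]; by <- y - s[2]; bz <- z - s[3]
      if (bx >= 1 && bx <= 16 && by >= 1 && by <= 16 && bz >= 1 && bz <= 16) {
        tot <- tot + sa[x, y, z] * sb[bx, by, bz] -
          penalty * ca[x, y, z] * cb[bx, by, bz]
      }
    }
    tot
  }
  for (k in 1:10) {
    s <- round((as.numeric(top[k, c("tx", "ty", "tz")]) -
                  (ga$origin - gb$origin)) / 1.2)
    expect_equal(top$score[k], brute(ga, gb, s), tolerance = 1e-6)
  }
  # a heavily clashing placement scores below the retained list
  expect_lt(brute(ga, gb, c(0, 0, 0)), min(top$score))
  expect_error(fft_translation_scan(ga, gb, top_t = 0), "top_t")
})

test_that("pose contact maps: separation empties, native transform reproduces", {
  fx <- make_c2_dimer(fixture_spec(n_residues = 24, seed = 6, n_interface = 2))
  m <- fx$dimer$chain_a
  far <- dock_pose(diag(3), c(500, 0, 0))
  expect_equal(sum(pose_contact_map(m, far)$values), 0)

  native <- dock_pose(fx$transform$rotation, fx$transform$translation)
  pm <- pose_contact_map(m, native)
  nm <- inter_contact_map(fx$dimer)
  nm_sym <- symmetrize_labels(nm$values)
  expect_equal(pm$values, nm_sym)
  expect_equal(pm$values, t(pm$values))
})

test_that("docking map is a monotone union and covers a single-pose base case", {
  fx <- make_c2_dimer(fixture_spec(n_residues = 24, seed = 6, n_interface = 2))
  m <- fx$dimer$chain_a
  one_rot <- list(diag(c(-1, -1, 1)))
  attr(one_rot, "axes") <- matrix(c(0, 0, 1), 1)
  dm1 <- docking_map(m, top_t = 1, rotations = one_rot)
  expect_equal(dm1$n_poses, 1L)
  # reconstruct that single pose and compare
  ga <- grid_project(cbind(m$atoms$x, m$atoms$y, m$atoms$z))
  cb <- cbind(m$atoms$x, m$atoms$y, m$atoms$z) %*% t(one_rot[[1]])
  gb <- grid_project(cb)
  top <- fft_translation_scan(ga, gb, top_t = 1)
  t1 <- as.numeric(top[1, c("tx", "ty", "tz")])
  t1 <- t1 - sum(t1 * c(0, 0, 1)) * c(0, 0, 1)
  pose <- dock_pose(one_rot[[1]], t1)
  expect_equal(dm1$values, pose_contact_map(m, pose)$values)

  # increasing top_t gives a superset; so does adding rotations
  rots <- sample_rotations(60)
  dm_small <- docking_map(m, top_t = 5, rotations = rots)
  dm_big <- docking_map(m, top_t = 20, rotations = rots)
  expect_true(all(dm_small$values <= dm_big$values))
  dm_fewrot <- docking_map(m, top_t = 5, rotations = rots[1:3])
  expect_true(all(dm_fewrot$values <= dm_small$values))

  # rotation-list order does not change the union
  dm_perm <- docking_map(m, top_t = 5, rotations = rev(rots))
  expect_equal(dm_perm$values, dm_small$values)
})
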