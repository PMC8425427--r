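test_that("alignments with no covariation give flat coupling scores", {
  mat <- matrix(rep(strsplit("ACDEFGHIKL", "")[[1]], each = 20), 20, 10)
  msa <- c2contact:::new_msa(mat)
  S <- mean_field_dca(msa)
  off <- S[upper.tri(S)]
  expect_lt(diff(range(off)), 1e-6 * (abs(mean(off)) + 1))
  expect_equal(S, t(S))
  expect_true(all(diag(S) == 0))
})

test_that("a planted covarying column pair ranks first", {
  sp <- fixture_spec(n_residues = 20, seed = 31, msa_depth = 250,
                     coupling_strength = 1,
                     interface_pairs = rbind(c(4L, 15L)))
  msa <- make_synthetic_msa(sp)
  S <- apc_correct(mean_field_dca(msa))
  ut <- which(upper.tri(S), arr.ind = TRUE)
  top <- ut[which.max(S[ut]), ]
  expect_equal(sort(unname(top)), c(4L, 15L))
})

test_that("engine agrees with an independently coded mean-field oracle", {
  # oracle: explicit loops over sequences and states, no shared code path
  mf_oracle <- function(mat, w, lambda) {
    aa <- c(c2contact::aa_alphabet(), "-")
    M <- nrow(mat); L <- ncol(mat); q <- 21; qr <- 20
    W <- sum(w)
    fi <- matrix(lambda / q, L, qr)
    for (i in 1:L) for (a in 1:qr) {
      s <- 0
      for (m in 1:M) if (mat[m, i] == aa[a]) s <- s + w[m]
      fi[i, a] <- lambda / q + (1 - lambda) * s / W
    }
    n <- L * qr
    Fij <- matrix(lambda / q^2, n, n)
    for (i in 1:L) for (j in 1:L) for (a in 1:qr) for (b in 1:qr) {
      s <- 0
      for (m in 1:M) if (mat[m, i] == aa[a] && mat[m, j] == aa[b]) s <- s + w[m]
      Fij[(i - 1) * qr + a, (j - 1) * qr + b] <-
        lambda / q^2 + (1 - lambda) * s / W
    }
    for (i in 1:L) {
      blk <- ((i - 1) * qr + 1):(i * qr)
      Fij[blk, blk] <- diag(fi[i, ])
    }
    fvec <- as.numeric(t(fi))
    C <- Fij - outer(fvec, fvec)
    J <- solve(C)
    S <- matrix(0, L, L)
    for (i in 1:(L - 1)) for (j in (i + 1):L) {
      e <- matrix(0, q, q)
      e[1:qr, 1:qr] <- J[((i - 1) * qr + 1):(i * qr),
                         ((j - 1) * qr + 1):(j * qr)]
      e <- e - outer(rowMeans(e), rep(1, q)) -
        outer(rep(1, q), colMeans(e)) + mean(e)
      S[i, j] <- S[j, i] <- sqrt(sum(e[1:qr, 1:qr]^2))
    }
    S
  }
  set.seed(5)
  mat <- matrix(sample(aa_alphabet(), 25 * 4, replace = TRUE), 25, 4)
  msa <- c2contact:::new_msa(mat)
  w <- sequence_weights(msa)
  got <- mean_field_dca(msa, w)
  want <- mf_oracle(mat, w$weights, 0.5)
  expect_equal(got, want, tolerance = 1e-8)
})

test_that("scores are invariant to alignment row order", {
  sp <- fixture_spec(n_residues = 12, seed = 3, msa_depth = 60)
  msa <- make_synthetic_msa(sp)
  S1 <- mean_field_dca(msa)
  set.seed(1)
  perm <- sample(msa$M)
  msa2 <- c2contact:::new_msa(msa$mat[perm, , drop = FALSE])
  expect_equal(mean_field_dca(msa2), S1, tolerance = 1e-9)
})

test_that("APC nullifies rank-one structure and preserves a dominant pair", {
  set.seed(3)
  a <- runif(12, 0.5, 2)
  S <- tcrossprod(a)
  Sc <- apc_correct(S)
  expect_lt(max(abs(Sc)) / max(S), 1e-8)
  expect_equal(Sc, t(Sc))
  expect_true(all(diag(Sc) == 0))

  # single large entry on a flat background stays on top
  S2 <- matrix(0.1, 10, 10); diag(S2) <- 0
  S2[2, 7] <- S2[7, 2] <- 5
  Sc2 <- apc_correct(S2)
  ut <- which(upper.tri(Sc2), arr.ind = TRUE)
  expect_equal(unname(ut[which.max(Sc2[ut]), ]), c(2L, 7L))

  # zero matrix: warning, unchanged
  Z <- matrix(0, 4, 4)
  expect_warning(Zc <- apc_correct(Z), "zero")
  expect_equal(Zc, Z)
})

test_that("coupling ingestion round-trips and validates dimensions", {
  set.seed(8)
  S <- matrix(runif(9), 3, 3); S <- (S + t(S)) / 2; diag(S) <- 0
  f <- tempfile()
  write_score_matrix(S, f)
  cs <- load_couplings(f, 3)
  expect_equal(cs$raw, S, tolerance = 1e-9)
  expect_equal(cs$apc, suppressWarnings(apc_correct(cs$raw)))
  expect_equal(cs$provenance, f)
  expect_error(load_couplings(f, 4), "expected 4 x 4")

  # internal engine: apc channel equals apc_correct(raw) exactly
  sp <- fixture_spec(n_residues = 10, seed = 2, msa_depth = 40)
  cpl <- compute_couplings(make_synthetic_msa(sp))
  expect_identical(cpl$apc, apc_correct(cpl$raw))
})
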