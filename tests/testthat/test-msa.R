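test_that("alignment readers handle FASTA, A3M inserts, and round trips", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">q", "ACDE"), f)
  m1 <- read_msa(f)
  expect_equal(m1$M, 1L)
  expect_equal(m1$ncols, 4L)

  # A3M: lowercase inserts removed, width equals query length
  writeLines(c(">q", "ACDE", ">h", "AcaCD-"), f)
  m2 <- read_msa(f, format = "a3m")
  expect_equal(m2$ncols, 4L)
  expect_equal(paste(m2$mat[2, ], collapse = ""), "ACD-")

  # round trip
  out <- tempfile(fileext = ".fasta")
  write_msa(m2, out)
  m3 <- read_msa(out)
  expect_equal(m3$mat, m2$mat)

  # ragged alignment is an error
  writeLines(c(">q", "ACDE", ">h", "ACD"), f)
  expect_error(read_msa(f), "ragged")
})

test_that("sequence identity follows the full-column denominator", {
  expect_equal(seq_identity("ACDE", "ACDE"), 1.0)
  expect_equal(seq_identity("ACDE", "CDEA"), 0.0)
  expect_equal(seq_identity("AC-D", "ACED"), 3 / 4)  # gap column mismatches
  expect_equal(seq_identity("AC-D", "AWED"), 2 / 4)  # 2 matches / 4 columns
  # non-gap denominator: columns 1, 2, 4 comparable, 2 of them match
  expect_equal(seq_identity("AC-D", "AWED", denominator = "non_gap"), 2 / 3)
  expect_equal(seq_identity("AC-D", "ACED"), seq_identity("ACED", "AC-D"))
  expect_error(seq_identity("AC", "ACD"), "length")
})

test_that("Meff matches the formula on hand-built and random alignments", {
  # M identical rows -> Meff = 1
  mat <- matrix(rep(strsplit("ACDEF", "")[[1]], each = 6), 6, 5)
  expect_equal(meff(c2contact:::new_msa(mat)), 1.0)

  # mutually dissimilar rows -> Meff = M
  mat2 <- rbind(strsplit("AAAAA", "")[[1]], strsplit("CCCCC", "")[[1]],
                strsplit("DDDDD", "")[[1]])
  expect_equal(meff(c2contact:::new_msa(mat2)), 3.0)

  # {x, x, y} with identity(x, y) < 0.7 -> m = (2, 2, 1), Meff = 2
  mat3 <- rbind(strsplit("ACDEF", "")[[1]], strsplit("ACDEF", "")[[1]],
                strsplit("WWWWW", "")[[1]])
  expect_equal(meff(c2contact:::new_msa(mat3)), 2.0)

  # brute-force O(M^2) oracle on random alignments
  set.seed(7)
  for (rep in 1:10) {
    M <- sample(3:30, 1); L <- sample(5:15, 1)
    mat <- matrix(sample(c(aa_alphabet(), "-"), M * L, replace = TRUE), M, L)
    mat[1, mat[1, ] == "-"] <- "A"
    msa <- c2contact:::new_msa(mat)
    brute <- 0
    for (i in 1:M) {
      mi <- 0
      for (j in 1:M) {
        id <- sum(mat[i, ] == mat[j, ] & mat[i, ] != "-") / L
        if (id > 0.7) mi <- mi + 1
      }
      brute <- brute + 1 / max(mi, 1)
    }
    expect_equal(meff(msa), brute)
    # permutation invariance
    perm <- sample(M)
    expect_equal(meff(c2contact:::new_msa(mat[perm, , drop = FALSE])),
                 brute)
  }
})

test_that("PSSM frequencies: indicators, weighted counts, unit row sums", {
  # single query, no pseudocount -> indicator rows
  msa1 <- c2contact:::new_msa(matrix("A", 1, 4))
  p1 <- pssm(msa1, pseudocount = 0)
  expect_equal(unname(p1$values[, "A"]), rep(1, 4))
  expect_equal(rowSums(p1$values), rep(1, 4))

  # weighted counts by hand: column 1 has A (w=1), C (w=0.5), C (w=0.5)
  mat <- rbind(c("A", "A"), c("C", "A"), c("C", "A"))
  msa3 <- c2contact:::new_msa(mat)
  w <- structure(list(weights = c(1, 0.5, 0.5), identity_cutoff = 0.7),
                 class = "seq_weights")
  p3 <- pssm(msa3, weights = w, pseudocount = 0)
  expect_equal(unname(p3$values[1, "A"]), 1 / 2)
  expect_equal(unname(p3$values[1, "C"]), 1 / 2)
  expect_equal(unname(p3$values[2, "A"]), 1)

  # rows sum to 1 with gaps present
  matg <- rbind(c("A", "-"), c("-", "-"), c("C", "G"))
  pg <- pssm(c2contact:::new_msa(matg), pseudocount = 1)
  expect_equal(rowSums(pg$values), rep(1, 2), tolerance = 1e-9)

  # deep uniform alignment: log-odds near zero when background matches
  set.seed(11)
  matu <- matrix(sample(aa_alphabet(), 3000 * 2, replace = TRUE,
                        prob = c2contact:::aa_background()), 3000, 2)
  lo <- pssm(c2contact:::new_msa(matu),
             weights = structure(list(weights = rep(1, 3000)),
                                 class = "seq_weights"),
             encoding = "log_odds")
  expect_lt(max(abs(lo$values)), 0.4)
})
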