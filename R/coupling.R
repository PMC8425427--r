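# Co-evolutionary couplings: an in-package mean-field DCA engine (inverse
# covariance + Frobenius norm in the zero-sum gauge) and the average product
# correction. External coupling matrices (CCMpred-style flat text) can be
# ingested instead.

msa_state_matrix <- function(mat) {
  aa <- c(aa_alphabet(), "-")
  st <- matrix(match(mat, aa), nrow(mat), ncol(mat))
  st[is.na(st)] <- 21L   # unknown residues treated as gap
  st
}

#' Mean-field direct-coupling analysis scores
#'
#' Computes per-pair coupling scores from an alignment: reweighted single and
#' pair frequencies with pseudocounts over a 21-state alphabet (20 amino
#' acids + gap), the covariance matrix over the 20 non-gap states, its
#' inverse, and finally the Frobenius norm of each 20 x 20 coupling block
#' after zero-sum gauge fixing. The result is the "raw" coupling channel;
#' apply [apc_correct()] for the corrected channel.
#'
#' @param msa An `msa`.
#' @param weights Optional `seq_weights` (defaults to weights at the 0.7
#'   identity cutoff, matching the Meff convention).
#' @param pseudocount_fraction Fraction `lambda` of the total statistical
#'   weight assigned to the uniform pseudocount (default 0.5).
#' @return L x L symmetric numeric matrix with zero diagonal.
#' @export
mean_field_dca <- function(msa, weights = NULL, pseudocount_fraction = 0.5) {
  stopifnot(inherits(msa, "msa"))
  L <- msa$ncols
  if (L < 2) stop("need at least 2 columns")
  if (is.null(weights)) weights <- sequence_weights(msa)
  w <- weights$weights
  W <- sum(w)
  q <- 21L; qr <- 20L
  lambda <- pseudocount_fraction
  st <- msa_state_matrix(msa$mat)

  # one-hot over the 20 non-gap states
  X <- matrix(0, msa$M, L * qr)
  for (a in seq_len(qr)) {
    idx <- which(st == a, arr.ind = TRUE)
    if (nrow(idx) > 0) {
      X[cbind(idx[, 1], (idx[, 2] - 1L) * qr + a)] <- 1
    }
  }
  fi <- lambda / q + (1 - lambda) * colSums(X * w) / W
  Fij <- lambda / q^2 + (1 - lambda) * crossprod(X * w, X) / W
  # diagonal blocks: f_ii(a,b) = delta_ab * f_i(a)
  for (i in seq_len(L)) {
    blk <- ((i - 1L) * qr + 1L):(i * qr)
    Fij[blk, blk] <- diag(fi[blk])
  }
  C <- Fij - tcrossprod(fi)
  J <- tryCatch(solve(C), error = function(e) {
    stop("covariance matrix is singular; increase pseudocount_fraction ",
         "(lambda > 0) or supply a deeper alignment", call. = FALSE)
  })

  S <- matrix(0, L, L)
  for (i in seq_len(L - 1L)) {
    bi <- ((i - 1L) * qr + 1L):(i * qr)
    for (j in (i + 1L):L) {
      bj <- ((j - 1L) * qr + 1L):(j * qr)
      e <- matrix(0, q, q)
      e[1:qr, 1:qr] <- J[bi, bj]
      # zero-sum gauge
      e <- e - outer(rowMeans(e), rep(1, q)) -
        outer(rep(1, q), colMeans(e)) + mean(e)
      S[i, j] <- S[j, i] <- sqrt(sum(e[1:qr, 1:qr]^2))
    }
  }
  diag(S) <- 0
  S
}

#' Average product correction of a coupling score matrix
#'
#' `S'_ij = S_ij - mean_i(S) * mean_j(S) / mean(S)`, with row and overall
#' means taken over all entries, so a rank-one product background
#' `S_ij = a_i * a_j` is cancelled exactly. Suppresses background coupling
#' caused by per-column conservation and phylogeny.
#'
#' @param S Symmetric L x L score matrix.
#' @return Corrected matrix, symmetric with zero diagonal. If the overall
#'   mean is zero the input is returned unchanged with a warning.
#' @export
apc_correct <- function(S) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S))
  if (max(abs(S - t(S))) > 1e-8) stop("S must be symmetric")
  L <- nrow(S)
  if (L < 2) return(S)
  mi <- rowMeans(S)
  mall <- mean(S)
  if (mall == 0) {
    warning("mean coupling score is zero; APC left the matrix unchanged")
    return(S)
  }
  out <- S - tcrossprod(mi) / mall
  diag(out) <- 0
  out
}

#' Bundle raw and APC-corrected coupling channels
#'
#' @param raw L x L raw coupling scores.
#' @param apc Optional APC channel; computed by [apc_correct()] if omitted.
#' @param provenance `"internal_dca"` or the path couplings were loaded from.
#' @return Object of class `coupling_scores` with fields `raw`, `apc`,
#'   `provenance`.
#' @export
coupling_scores <- function(raw, apc = NULL, provenance = "internal_dca") {
  if (is.null(apc)) apc <- suppressWarnings(apc_correct(raw))
  stopifnot(all(dim(raw) == dim(apc)))
  structure(list(raw = raw, apc = apc, provenance = provenance),
            class = "coupling_scores")
}

#' Compute both coupling channels from an alignment
#'
#' @inheritParams mean_field_dca
#' @return A `coupling_scores` object with `raw` and `apc` channels.
#' @export
compute_couplings <- function(msa, weights = NULL,
                              pseudocount_fraction = 0.5) {
  raw <- mean_field_dca(msa, weights, pseudocount_fraction)
  coupling_scores(raw, provenance = "internal_dca")
}

#' Load externally computed coupling scores
#'
#' Reads a CCMpred-style whitespace-delimited L x L plain-text matrix as the
#' raw channel; the APC channel is computed by [apc_correct()] unless a
#' second matrix file is supplied.
#'
#' @param path Path to the raw score matrix.
#' @param L Expected dimension.
#' @param apc_path Optional path to a precomputed APC matrix.
#' @return A `coupling_scores` object.
#' @export
load_couplings <- function(path, L, apc_path = NULL) {
  raw <- as.matrix(read.table(path, header = FALSE))
  dimnames(raw) <- NULL
  if (!all(dim(raw) == c(L, L))) {
    stop("coupling matrix in '", path, "' is ", nrow(raw), " x ", ncol(raw),
         ", expected ", L, " x ", L)
  }
  raw <- (raw + t(raw)) / 2
  diag(raw) <- 0
  apc <- NULL
  if (!is.null(apc_path)) {
    apc <- as.matrix(read.table(apc_path, header = FALSE))
    dimnames(apc) <- NULL
    if (!all(dim(apc) == c(L, L))) stop("APC matrix dimension mismatch")
  }
  coupling_scores(raw, apc, provenance = path)
}

#' Write a score matrix as flat whitespace-delimited text
#'
#' @param S Numeric matrix.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_score_matrix <- function(S, path) {
  write.table(format(S, digits = 10, scientific = TRUE, trim = TRUE),
              path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
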