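# Assembly of the network input tensors.

#' Average a square matrix with its transpose
#'
#' The input symmetrization applied to every pairwise feature channel.
#'
#' @param X Square numeric matrix.
#' @return `(X + t(X)) / 2`, exactly symmetric.
#' @export
symmetrize_pairwise <- function(X) {
  if (!is.matrix(X) || nrow(X) != ncol(X)) stop("X must be square")
  (X + t(X)) / 2
}

#' Symmetrize a binary label matrix
#'
#' If pair (i, j) is labelled 1, pair (j, i) becomes 1 too (element-wise OR
#' with the transpose).
#'
#' @param Y Square binary matrix (entries 0/1).
#' @return Symmetric binary matrix.
#' @export
symmetrize_labels <- function(Y) {
  if (!is.matrix(Y) || nrow(Y) != ncol(Y)) stop("Y must be square")
  if (!all(Y %in% c(0, 1))) stop("Y must be binary (0/1)")
  ((Y + t(Y)) > 0) + 0L
}

#' Assemble the feature bundle fed to the contact network
#'
#' Stacks the 1D sequential features (PSSM 20 + secondary-structure one-hot
#' 8 + hydrophobicity 3 = 31 channels) and the 2D pairwise features
#' (intra-monomer distance map, docking map, raw coupling, APC coupling = 4
#' channels). The distance channel is clipped at `d_max` and scaled to
#' `[0, 1]`; all pairwise channels are symmetrized by averaging with their
#' transpose.
#'
#' @param m A `monomer_structure`.
#' @param msa An `msa` for the same sequence (query length must equal
#'   `m$L`).
#' @param couplings A `coupling_scores` of matching dimension.
#' @param dmap A `docking_map` of matching dimension.
#' @param ss Optional precomputed secondary-structure labels (length L).
#' @param hydro Optional precomputed L x 3 hydrophobicity matrix.
#' @param d_max Distance clip value in Angstrom for the distance channel.
#' @return Object of class `feature_bundle`: list with `seq_features`
#'   (L x 31), `pair_features` (L x L x 4 array), `mask` (L x L logical),
#'   `L`, and `channel_order`.
#' @export
build_features <- function(m, msa, couplings, dmap, ss = NULL, hydro = NULL,
                           d_max = 50) {
  stopifnot(inherits(m, "monomer_structure"))
  L <- m$L
  if (msa$ncols != L) {
    stop("MSA width (", msa$ncols, ") does not match structure length (",
         L, ")")
  }
  if (!all(dim(couplings$raw) == c(L, L))) {
    stop("coupling matrices do not match structure length ", L)
  }
  if (!all(dim(dmap$values) == c(L, L))) {
    stop("docking map does not match structure length ", L)
  }
  w <- sequence_weights(msa)
  p <- pssm(msa, w)$values
  if (is.null(ss)) ss <- secondary_structure(m)
  if (is.null(hydro)) hydro <- hydrophobicity_features(m)
  seq_features <- cbind(p, ss8_onehot(ss), hydro)
  colnames(seq_features) <- NULL

  dm <- intra_distance_map(m)
  dvals <- pmin(dm$values, d_max) / d_max
  dvals[!dm$mask] <- 1
  pair <- array(0, dim = c(L, L, 4))
  pair[, , 1] <- symmetrize_pairwise(dvals)
  pair[, , 2] <- symmetrize_pairwise(dmap$values + 0)
  pair[, , 3] <- symmetrize_pairwise(couplings$raw)
  pair[, , 4] <- symmetrize_pairwise(couplings$apc)
  mask <- outer(m$observed, m$observed, "&") & dm$mask
  structure(list(seq_features = seq_features, pair_features = pair,
                 mask = mask, L = L,
                 channel_order = c("distance", "docking", "coupling_raw",
                                   "coupling_apc")),
            class = "feature_bundle")
}

#' Random contiguous crop of a feature bundle and its labels
#'
#' Training-time length limit: when `L > max_len`, one contiguous window of
#' `max_len` residues is sampled and applied to the sequence axis of the 1D
#' features and to both axes of the pairwise features, labels and mask. A
#' no-op when `L <= max_len`.
#'
#' @param bundle A `feature_bundle`.
#' @param labels A `contact_map` aligned with the bundle.
#' @param max_len Maximum length (default 400).
#' @param seed Optional integer seed for a reproducible window.
#' @return List with cropped `bundle`, `labels`, and the `offset` (0-based)
#'   of the window.
#' @export
random_crop <- function(bundle, labels, max_len = 400, seed = NULL) {
  if (max_len < 1) stop("max_len must be >= 1")
  stopifnot(inherits(bundle, "feature_bundle"))
  L <- bundle$L
  if (!all(dim(labels$values) == c(L, L))) stop("labels do not match bundle")
  if (L <= max_len) {
    return(list(bundle = bundle, labels = labels, offset = 0L))
  }
  if (!is.null(seed)) set.seed(seed)
  off <- sample.int(L - max_len + 1L, 1L) - 1L
  win <- (off + 1L):(off + max_len)
  nb <- bundle
  nb$seq_features <- bundle$seq_features[win, , drop = FALSE]
  nb$pair_features <- bundle$pair_features[win, win, , drop = FALSE]
  nb$mask <- bundle$mask[win, win, drop = FALSE]
  nb$L <- max_len
  nl <- labels
  nl$values <- labels$values[win, win, drop = FALSE]
  nl$mask <- labels$mask[win, win, drop = FALSE]
  list(bundle = nb, labels = nl, offset = off)
}
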