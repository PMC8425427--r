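# Focal loss for the heavily unbalanced contact/non-contact classification.

check_prob <- function(p) {
  if (any(p <= 0 | p >= 1)) {
    stop("predicted probabilities must lie strictly inside (0, 1)")
  }
}

#' Focal loss of a predicted contact map
#'
#' Per pair, `FL(p_t) = -alpha_t * (1 - p_t)^gamma * log(p_t)` with
#' `alpha_t = alpha` and `p_t = p_ij` for contacts (`y = 1`), and
#' `alpha_t = 1 - alpha`, `p_t = 1 - p_ij` for non-contacts. Down-weights
#' the abundant easy negatives via the `(1 - p_t)^gamma` factor. Masked
#' pairs (missing residues) are excluded; the reduction is the mean over
#' unmasked pairs, so the loss scale is length-independent. With
#' `gamma = 0` this reduces to alpha-weighted binary cross-entropy.
#'
#' @param p Predicted probabilities: matrix in (0, 1).
#' @param y Binary label matrix of the same shape.
#' @param mask Optional logical matrix; FALSE entries are excluded.
#' @param alpha Class balance weight (default 0.25).
#' @param gamma Focusing parameter (default 1.5).
#' @return Non-negative scalar loss.
#' @export
focal_loss <- function(p, y, mask = NULL, alpha = 0.25, gamma = 1.5) {
  stopifnot(all(dim(p) == dim(y)), alpha > 0, alpha < 1, gamma >= 0)
  check_prob(p)
  if (is.null(mask)) mask <- array(TRUE, dim = dim(p))
  pt <- ifelse(y == 1, p, 1 - p)
  at <- ifelse(y == 1, alpha, 1 - alpha)
  pt <- pmin(pmax(pt, 1e-12), 1 - 1e-12)
  fl <- -at * (1 - pt)^gamma * log(pt)
  mean(fl[mask])
}

# d(mean focal loss) / d(logits), for p = sigmoid(z). Masked entries get
# zero gradient, so they can never influence training.
focal_loss_grad <- function(p, y, mask = NULL, alpha = 0.25, gamma = 1.5) {
  if (is.null(mask)) mask <- array(TRUE, dim = dim(p))
  pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  pt <- ifelse(y == 1, pc, 1 - pc)
  at <- ifelse(y == 1, alpha, 1 - alpha)
  dpt_dz <- ifelse(y == 1, 1, -1) * pc * (1 - pc)
  if (gamma == 0) {
    dfl_dpt <- -at / pt
  } else {
    dfl_dpt <- at * (gamma * (1 - pt)^(gamma - 1) * log(pt) -
                       (1 - pt)^gamma / pt)
  }
  g <- dfl_dpt * dpt_dz
  g[!mask] <- 0
  g / sum(mask)
}
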