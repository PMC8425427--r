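# Direct-coupling baselines and the contact-guided post-docking pose filter.

#' DCA baseline contact predictor with intra-monomer distance filter
#'
#' Candidate inter-chain contacts are the unique residue pairs whose
#' intra-monomer minimal heavy-atom distance exceeds `intra_cutoff` (strong
#' couplings at short intra-monomer range are explained by the monomer fold,
#' not the interface). Candidates are ranked by the chosen coupling channel,
#' descending, ties broken by `(i, j)` ascending.
#'
#' @param couplings A `coupling_scores`.
#' @param dmap A `distance_map` of the monomer (same L).
#' @param score_type `"apc"` or `"raw_di"`.
#' @param intra_cutoff Intra-monomer distance filter in Angstrom
#'   (default 12).
#' @return A `ranked_contacts` data frame (empty, with a warning, when no
#'   pair survives the filter).
#' @export
dca_baseline <- function(couplings, dmap, score_type = c("apc", "raw_di"),
                         intra_cutoff = 12.0) {
  score_type <- match.arg(score_type)
  stopifnot(inherits(couplings, "coupling_scores"))
  S <- if (score_type == "apc") couplings$apc else couplings$raw
  L <- nrow(S)
  if (!all(dim(dmap$values) == c(L, L))) {
    stop("distance map and couplings differ in dimension")
  }
  keep <- dmap$values > intra_cutoff & dmap$mask
  keep <- keep & upper.tri(keep, diag = TRUE)
  if (!any(keep)) {
    warning("no residue pair survives the ", intra_cutoff,
            " A intra-monomer filter; returning an empty prediction")
    df <- data.frame(i = integer(0), j = integer(0), score = numeric(0))
    attr(df, "L") <- L
    class(df) <- c("ranked_contacts", "data.frame")
    return(df)
  }
  idx <- which(keep, arr.ind = TRUE)
  df <- data.frame(i = idx[, 1], j = idx[, 2], score = S[idx])
  df <- df[order(-df$score, df$i, df$j), ]
  rownames(df) <- NULL
  attr(df, "L") <- L
  class(df) <- c("ranked_contacts", "data.frame")
  df
}

#' Re-rank docking poses by a predicted contact
#'
#' Stable promotion: poses whose contact map contains the given residue pair
#' keep their relative order and move ahead of all non-satisfying poses; no
#' pose is deleted, so a fixed-length top list can still be reported. When
#' no pose satisfies the contact the original order is returned with a
#' warning.
#'
#' @param poses List of poses; each element needs a `contact_map` element
#'   (a `contact_map` or plain binary matrix).
#' @param top_contact Length-2 integer vector `(i, j)`.
#' @return The reordered pose list; satisfying poses carry
#'   `satisfies_contact = TRUE`.
#' @export
filter_poses <- function(poses, top_contact) {
  stopifnot(length(top_contact) == 2)
  i <- top_contact[1]; j <- top_contact[2]
  sat <- vapply(poses, function(p) {
    cm <- p$contact_map
    v <- if (is.list(cm)) cm$values else cm
    v[i, j] == 1 || v[j, i] == 1
  }, logical(1))
  if (!any(sat)) {
    warning("no pose satisfies the predicted contact (", i, ", ", j,
            "); keeping the original ranking")
    return(poses)
  }
  out <- c(poses[sat], poses[!sat])
  for (k in seq_along(out)) {
    out[[k]]$satisfies_contact <- c(rep(TRUE, sum(sat)),
                                    rep(FALSE, sum(!sat)))[k]
  }
  out
}
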