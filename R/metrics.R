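# Evaluation statistics for inter-chain contact prediction.

truth_lookup <- function(truth) {
  v <- if (is.list(truth)) truth$values else truth
  ((v + t(v)) > 0) + 0L
}

#' Precision of the top n predicted contacts
#'
#' Fraction of true positives among the first `n` predictions; when fewer
#' than `n` candidates exist the denominator is the list length.
#'
#' @param pred A `ranked_contacts`.
#' @param truth A `contact_map` (or binary matrix); consulted as unordered
#'   pairs.
#' @param n Number of top predictions considered.
#' @return Fraction in `[0, 1]`.
#' @export
precision_at <- function(pred, truth, n) {
  stopifnot(n >= 1)
  if (nrow(pred) == 0L) stop("empty prediction list")
  tv <- truth_lookup(truth)
  k <- min(n, nrow(pred))
  top <- pred[seq_len(k), ]
  sum(tv[cbind(top$i, top$j)] == 1) / k
}

#' Top-L/K precision
#'
#' Precision of the top `floor(L/K)` predictions (minimum 1, so the metric
#' is defined for short chains), for the conventional K of 30, 20, 10, 5, 2.
#'
#' @param pred A `ranked_contacts` (its `L` attribute supplies the length
#'   unless `L` is given).
#' @param truth A `contact_map` or binary matrix.
#' @param K Divisor.
#' @param L Protein length override.
#' @return Fraction in `[0, 1]`.
#' @export
topLK_precision <- function(pred, truth, K, L = attr(pred, "L")) {
  if (is.null(L)) stop("protein length unknown; pass L")
  n <- max(1L, floor(L / K))
  precision_at(pred, truth, n)
}

#' Dataset-level accuracy rate
#'
#' Fraction of targets with at least one true contact among their top `n`
#' predictions.
#'
#' @param per_target_preds List of targets, each a list with `pred`
#'   (a `ranked_contacts`) and `truth` (a `contact_map`).
#' @param n Number of top predictions considered per target.
#' @return Fraction in `[0, 1]`, non-decreasing in `n`.
#' @export
accuracy_rate <- function(per_target_preds, n) {
  stopifnot(length(per_target_preds) >= 1)
  hit <- vapply(per_target_preds, function(tg) {
    if (nrow(tg$pred) == 0L) return(FALSE)
    precision_at(tg$pred, tg$truth, n) > 0
  }, logical(1))
  mean(hit)
}

#' Accuracy order of a prediction
#'
#' The 1-based rank of the first correct prediction divided by the total
#' number of unique residue pairs `L(L+1)/2`, reported in per mille. `NA`
#' when the target has no true contact or none is ranked.
#'
#' @param pred A `ranked_contacts`.
#' @param truth A `contact_map` or binary matrix.
#' @param L Protein length override.
#' @return Accuracy order in per mille, or `NA`.
#' @export
accuracy_order <- function(pred, truth, L = attr(pred, "L")) {
  if (is.null(L)) stop("protein length unknown; pass L")
  tv <- truth_lookup(truth)
  if (sum(tv) == 0) return(NA_real_)
  hits <- tv[cbind(pred$i, pred$j)] == 1
  if (!any(hits)) return(NA_real_)
  rank1 <- which(hits)[1]
  1000 * rank1 / (L * (L + 1) / 2)
}

#' Full evaluation report for a set of targets
#'
#' @param per_target_preds List of targets with `pred` and `truth`.
#' @param n_values Top-n values for precision and accuracy rate.
#' @param K_values Divisors for top-L/K precision.
#' @return Object of class `eval_report`: list with `precision_at`
#'   (averaged over targets), `topLK`, `accuracy_rate_at`, and
#'   `accuracy_order` (median per-mille over targets with a defined value).
#' @export
eval_report <- function(per_target_preds, n_values = c(1, 10, 100),
                        K_values = c(30, 20, 10, 5, 2)) {
  prec <- vapply(n_values, function(n) {
    mean(vapply(per_target_preds, function(tg) {
      precision_at(tg$pred, tg$truth, n)
    }, numeric(1)))
  }, numeric(1))
  lk <- vapply(K_values, function(K) {
    mean(vapply(per_target_preds, function(tg) {
      topLK_precision(tg$pred, tg$truth, K)
    }, numeric(1)))
  }, numeric(1))
  ar <- vapply(n_values, function(n) accuracy_rate(per_target_preds, n),
               numeric(1))
  ao <- vapply(per_target_preds, function(tg) {
    accuracy_order(tg$pred, tg$truth)
  }, numeric(1))
  structure(list(
    precision_at = setNames(prec, n_values),
    topLK = setNames(lk, K_values),
    accuracy_rate_at = setNames(ar, n_values),
    accuracy_order = stats::median(ao, na.rm = TRUE)
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Contact prediction evaluation\n")
  cat("  precision@n:   ",
      paste(sprintf("n=%s %.3f", names(x$precision_at), x$precision_at),
            collapse = "  "), "\n")
  cat("  top-L/K:       ",
      paste(sprintf("K=%s %.3f", names(x$topLK), x$topLK),
            collapse = "  "), "\n")
  cat("  accuracy rate: ",
      paste(sprintf("n=%s %.3f", names(x$accuracy_rate_at),
                    x$accuracy_rate_at), collapse = "  "), "\n")
  cat(sprintf("  accuracy order (median): %.3f permille\n",
              x$accuracy_order))
  invisible(x)
}
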