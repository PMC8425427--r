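# Multiple sequence alignments and the scalar sequence features derived from
# them: pairwise identity, reweighting, Meff, and the PSSM.

#' Read a multiple sequence alignment
#'
#' Reads an aligned FASTA or A3M file. The first record is taken as the
#' query. A3M insert states (lowercase letters and `.`) are removed so that
#' the alignment width equals the query length; for aligned FASTA, columns
#' where the query is gapped are dropped for the same reason. `.` and `-`
#' are unified to the gap character `-` and letters are uppercased.
#'
#' @param path File path.
#' @param format `"aligned_fasta"` or `"a3m"`.
#' @return An object of class `msa`: list with `mat` (M x L character
#'   matrix), `names`, `M`, `ncols`.
#' @export
read_msa <- function(path, format = c("aligned_fasta", "a3m")) {
  format <- match.arg(format)
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             set.attributes = FALSE)
  if (length(recs) == 0L) stop("empty alignment file: ", path)
  seqs <- unlist(recs, use.names = FALSE)
  if (format == "a3m") {
    seqs <- vapply(seqs, function(s) {
      gsub("[a-z.]", "", s)
    }, character(1), USE.NAMES = FALSE)
  }
  seqs <- toupper(seqs)
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) {
    stop("ragged alignment: row widths ", paste(unique(widths), collapse = ", "))
  }
  mat <- do.call(rbind, strsplit(seqs, ""))
  mat[mat == "."] <- "-"
  mat[!(mat %in% c(aa_alphabet(), "-"))] <- "X"
  if (format == "aligned_fasta") {
    keep <- mat[1, ] != "-"
    mat <- mat[, keep, drop = FALSE]
  }
  if (any(mat[1, ] == "-")) stop("query row still contains gaps")
  new_msa(mat, names(recs))
}

new_msa <- function(mat, names = NULL) {
  structure(list(mat = mat,
                 names = if (is.null(names)) paste0("seq", seq_len(nrow(mat))) else names,
                 M = nrow(mat), ncols = ncol(mat)),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat("MSA:", x$M, "sequences x", x$ncols, "columns; query",
      substr(paste(x$mat[1, ], collapse = ""), 1, 40), "...\n")
  invisible(x)
}

#' Write an alignment as aligned FASTA
#'
#' @param msa An `msa`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_msa <- function(msa, path) {
  seqs <- apply(msa$mat, 1, paste, collapse = "")
  writeLines(paste0(">", msa$names, "\n", seqs), path)
  invisible(path)
}

#' Pairwise sequence identity of two aligned rows
#'
#' The fraction of alignment columns carrying the identical non-gap residue
#' in both rows; the denominator is the full alignment length, so gapped
#' columns count as mismatches (set `denominator = "non_gap"` for the
#' alternative convention).
#'
#' @param a,b Aligned rows: character vectors of residues, or single strings.
#' @param denominator `"columns"` (default) or `"non_gap"`.
#' @return Identity fraction in `[0, 1]`.
#' @export
seq_identity <- function(a, b, denominator = c("columns", "non_gap")) {
  denominator <- match.arg(denominator)
  if (length(a) == 1L) a <- strsplit(a, "")[[1]]
  if (length(b) == 1L) b <- strsplit(b, "")[[1]]
  if (length(a) != length(b)) stop("aligned rows differ in length")
  match_ <- a == b & a != "-"
  den <- if (denominator == "columns") length(a) else sum(a != "-" & b != "-")
  if (den == 0L) return(0)
  sum(match_) / den
}

pairwise_identity_matrix <- function(mat) {
  M <- nrow(mat); L <- ncol(mat)
  out <- matrix(0, M, M)
  for (i in seq_len(M)) {
    qm <- matrix(mat[i, ], M, L, byrow = TRUE)
    out[i, ] <- rowSums(mat == qm & qm != "-") / L
  }
  out
}

#' Sequence weights under an identity cutoff
#'
#' Each row gets weight `1/m_i`, where `m_i` counts the rows (itself
#' included) with pairwise identity strictly greater than `identity_cutoff`
#' to row `i`.
#'
#' @param msa An `msa`.
#' @param identity_cutoff Identity threshold (default 0.7).
#' @return Object of class `seq_weights`: list with `weights` (in `(0, 1]`)
#'   and `identity_cutoff`.
#' @export
sequence_weights <- function(msa, identity_cutoff = 0.7) {
  stopifnot(inherits(msa, "msa"))
  idm <- pairwise_identity_matrix(msa$mat)
  m <- rowSums(idm > identity_cutoff)
  m <- pmax(m, 1L)   # a row is always similar to itself
  structure(list(weights = 1 / m, identity_cutoff = identity_cutoff),
            class = "seq_weights")
}

#' Effective number of sequences in an alignment
#'
#' `Meff = sum_i 1/m_i`, where `m_i` is the number of rows with identity
#' greater than the cutoff to row `i` (itself included). Lies in `[1, M]`.
#'
#' @param msa An `msa`.
#' @param identity_cutoff Identity threshold (default 0.7, i.e. >70%).
#' @return A single number.
#' @export
meff <- function(msa, identity_cutoff = 0.7) {
  sum(sequence_weights(msa, identity_cutoff)$weights)
}

#' Position-specific scoring matrix of an alignment
#'
#' Column-wise weighted amino-acid frequencies with `pseudocount/20` added to
#' every cell; gaps are excluded from the normalisation, so frequency rows
#' always sum to 1. With `encoding = "log_odds"` the frequencies are divided
#' by a fixed background distribution and logged.
#'
#' @param msa An `msa`.
#' @param weights Optional `seq_weights` computed on the same alignment
#'   (defaults to uniform weights).
#' @param pseudocount Total pseudocount mass per column (default 1).
#' @param encoding `"frequency"` or `"log_odds"`.
#' @return Object of class `pssm`: list with `values` (L x 20 matrix, columns
#'   in [aa_alphabet()] order) and `encoding`.
#' @export
pssm <- function(msa, weights = NULL, pseudocount = 1.0,
                 encoding = c("frequency", "log_odds")) {
  encoding <- match.arg(encoding)
  stopifnot(inherits(msa, "msa"))
  w <- if (is.null(weights)) rep(1, msa$M) else weights$weights
  stopifnot(length(w) == msa$M)
  aa <- aa_alphabet()
  L <- msa$ncols
  counts <- matrix(0, L, 20, dimnames = list(NULL, aa))
  for (k in seq_along(aa)) {
    counts[, k] <- colSums((msa$mat == aa[k]) * w)
  }
  tot <- rowSums(counts)
  freq <- (counts + pseudocount / 20) / (tot + pseudocount)
  if (encoding == "log_odds") {
    vals <- log(sweep(freq, 2, aa_background(), "/"))
  } else {
    vals <- freq
  }
  structure(list(values = vals, encoding = encoding), class = "pssm")
}
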