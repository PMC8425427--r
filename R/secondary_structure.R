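# Eight-state secondary structure: DSSP output ingestion and an internal
# backbone hydrogen-bond assigner (DSSP-style electrostatic energy).

#' Assign 8-state secondary structure
#'
#' Either parses a DSSP output file (the fidelity path) or assigns secondary
#' structure internally from backbone geometry using the DSSP hydrogen-bond
#' electrostatic approximation with a -0.5 kcal/mol cutoff. The internal
#' assigner covers H/G/I (helices), E/B (strand/bridge), T (turn) and S
#' (bend); exact parity with the DSSP program is not promised. Residues with
#' missing backbone atoms are labeled `"-"`.
#'
#' @param m A `monomer_structure`.
#' @param source `"internal"` or a DSSP output file path given via
#'   `dssp_file`.
#' @param dssp_file Optional path to a DSSP output file matching the chain.
#' @return Character vector of length `m$L` over the alphabet
#'   `H B E G I T S -`.
#' @export
secondary_structure <- function(m, source = c("internal", "dssp_file"),
                                dssp_file = NULL) {
  source <- match.arg(source)
  if (source == "dssp_file") {
    if (is.null(dssp_file)) stop("source = 'dssp_file' needs a dssp_file path")
    return(read_dssp_ss(dssp_file, m))
  }
  assign_ss_internal(m)
}

read_dssp_ss <- function(path, m) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^  #  RESIDUE", lines)
  if (length(hdr) != 1L) stop("not a DSSP output file: ", path)
  body <- lines[(hdr + 1L):length(lines)]
  body <- body[nchar(body) >= 17]
  aa <- substr(body, 14, 14)
  keep <- aa != "!"
  body <- body[keep]; aa <- aa[keep]
  ch <- substr(body, 12, 12)
  sel <- ch == m$chain_id | all(ch == " ")
  body <- body[sel]; aa <- aa[sel]
  ss <- substr(body, 17, 17)
  ss[!ss %in% SS8_ALPHABET] <- "-"
  ss[ss == " "] <- "-"
  obs <- which(m$observed)
  if (length(ss) != length(obs)) {
    stop("DSSP record count (", length(ss), ") does not match the ",
         length(obs), " observed residues of chain ", m$chain_id)
  }
  mseq <- strsplit(m$sequence, "")[[1]][obs]
  cmp <- aa
  cmp[cmp %in% letters] <- "C"   # DSSP marks half-cystines with lowercase
  mismatch <- cmp != mseq & mseq != "X" & cmp %in% aa_alphabet()
  if (mean(mismatch) > 0.1) {
    stop("DSSP sequence does not align with the structure (",
         sum(mismatch), " mismatches)")
  }
  out <- rep("-", m$L)
  out[obs] <- ss
  out
}

backbone_xyz <- function(m) {
  bb <- array(NA_real_, dim = c(m$L, 4, 3),
              dimnames = list(NULL, c("N", "CA", "C", "O"), NULL))
  at <- m$atoms
  for (nm in c("N", "CA", "C", "O")) {
    sel <- at$name == nm
    bb[at$res[sel], nm, ] <- cbind(at$x[sel], at$y[sel], at$z[sel])
  }
  bb
}

assign_ss_internal <- function(m) {
  L <- m$L
  ss <- rep("-", L)
  if (L < 3) return(ss)
  bb <- backbone_xyz(m)
  has_bb <- apply(!is.na(bb[, , 1, drop = FALSE]), 1, all) & m$observed

  # amide H built from the previous residue's carbonyl
  H <- matrix(NA_real_, L, 3)
  for (i in 2:L) {
    if (!has_bb[i] || !has_bb[i - 1]) next
    d <- bb[i - 1, "C", ] - bb[i - 1, "O", ]
    d <- d / sqrt(sum(d^2))
    H[i, ] <- bb[i, "N", ] + d
  }
  is_pro <- m$res_name3 == "PRO"

  # hbond[i, j]: backbone N-H of donor i bonded to C=O of acceptor j
  hbond <- matrix(FALSE, L, L)
  q <- 0.084 * 332
  for (i in 2:L) {
    if (!has_bb[i] || is_pro[i] || any(is.na(H[i, ]))) next
    for (j in seq_len(L)) {
      if (!has_bb[j] || abs(i - j) < 2) next
      dON <- sqrt(sum((bb[i, "N", ] - bb[j, "O", ])^2))
      if (dON > 5.2) next
      dCH <- sqrt(sum((H[i, ] - bb[j, "C", ])^2))
      dOH <- sqrt(sum((H[i, ] - bb[j, "O", ])^2))
      dCN <- sqrt(sum((bb[i, "N", ] - bb[j, "C", ])^2))
      E <- q * (1 / dON + 1 / dCH - 1 / dOH - 1 / dCN)
      hbond[i, j] <- E < -0.5
    }
  }

  turn <- function(n) {
    t <- rep(FALSE, L)
    idx <- seq_len(L - n)
    t[idx] <- hbond[cbind(idx + n, idx)]
    t
  }
  t3 <- turn(3); t4 <- turn(4); t5 <- turn(5)

  mark <- function(ss, tn, n, code) {
    for (i in 2:max(1, L - n)) {
      if (tn[i - 1] && tn[i]) {
        span <- i:min(L, i + n - 1)
        free <- ss[span] == "-"
        ss[span][free] <- code
      }
    }
    ss
  }
  ss <- mark(ss, t4, 4, "H")

  # beta bridges
  bridge <- matrix(FALSE, L, L)
  for (i in 2:(L - 1)) {
    for (j in 2:(L - 1)) {
      if (abs(i - j) < 3) next
      par <- (hbond[j, i - 1] && hbond[i + 1, j]) ||
        (hbond[i, j - 1] && hbond[j + 1, i])
      anti <- (hbond[i, j] && hbond[j, i]) ||
        (hbond[j + 1, i - 1] && hbond[i + 1, j - 1])
      if (par || anti) bridge[i, j] <- TRUE
    }
  }
  for (i in which(rowSums(bridge) > 0)) {
    if (ss[i] != "-" && ss[i] != "T") next
    ext <- (i > 1 && rowSums(bridge)[max(1, i - 1)] > 0) ||
      (i < L && rowSums(bridge)[min(L, i + 1)] > 0)
    ss[i] <- if (ext) "E" else "B"
  }

  ss <- mark(ss, t3, 3, "G")
  ss <- mark(ss, t5, 5, "I")

  # turns: interior of any single n-turn
  for (n in 3:5) {
    tn <- switch(as.character(n), "3" = t3, "4" = t4, "5" = t5)
    for (i in which(tn)) {
      span <- (i + 1):min(L, i + n - 1)
      ss[span][ss[span] == "-"] <- "T"
    }
  }

  # bends from the CA direction change
  for (i in 3:(L - 2)) {
    if (ss[i] != "-") next
    if (!all(has_bb[c(i - 2, i, i + 2)])) next
    u <- bb[i, "CA", ] - bb[i - 2, "CA", ]
    v <- bb[i + 2, "CA", ] - bb[i, "CA", ]
    kap <- acos(pmin(1, pmax(-1, sum(u * v) /
                               sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
    if (kap > 70) ss[i] <- "S"
  }
  ss[!has_bb] <- "-"
  ss
}

#' One-hot encode 8-state secondary structure labels
#'
#' @param ss Character vector over the alphabet `H B E G I T S -`.
#' @return L x 8 binary matrix; column order `H, B, E, G, I, T, S, -`.
#' @export
ss8_onehot <- function(ss) {
  stopifnot(all(ss %in% SS8_ALPHABET))
  out <- matrix(0, length(ss), 8, dimnames = list(NULL, SS8_ALPHABET))
  out[cbind(seq_along(ss), match(ss, SS8_ALPHABET))] <- 1
  out
}

#' Per-residue hydrophobicity channels
#'
#' Returns the three hydrophobicity channels of the 1D feature block:
#' point-sampled (Shrake-Rupley) SASA, slice-based (Lee-Richards) SASA, and
#' the Wimley-White whole-residue scale value of each residue type. Unknown
#' residue types receive a Wimley-White value of 0 with a warning.
#'
#' @param m A `monomer_structure`.
#' @param n_points Points per atom for the Shrake-Rupley channel.
#' @return L x 3 numeric matrix with columns `sasa_sr`, `sasa_lr`, `ww`.
#' @export
hydrophobicity_features <- function(m, n_points = 960) {
  ch1 <- sasa(m, "shrake_rupley", n_points = n_points)
  ch2 <- sasa(m, "lee_richards")
  ww <- wimley_white_scale()
  aa <- strsplit(m$sequence, "")[[1]]
  ch3 <- ww[aa]
  if (anyNA(ch3)) {
    warning("unknown residue type(s) at ",
            paste(which(is.na(ch3)), collapse = ", "),
            "; Wimley-White value set to 0")
    ch3[is.na(ch3)] <- 0
  }
  cbind(sasa_sr = ch1, sasa_lr = ch2, ww = unname(ch3))
}
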