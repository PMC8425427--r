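# Synthetic, fully self-contained test inputs: C2 dimers with a known
# planted interface, alignments with planted inter-chain covariation, and
# bundled mini-datasets for training and evaluation.

#' Specification of a synthetic fixture
#'
#' @param n_residues Chain length (>= 5).
#' @param seed Integer seed; every generator below is deterministic in it.
#' @param interface_pairs Optional 2-column matrix (or list of length-2
#'   vectors) of residue pairs to plant at the interface; auto-chosen when
#'   omitted.
#' @param n_interface Number of pairs to plant when auto-choosing.
#' @param msa_depth Number of alignment rows M.
#' @param coupling_strength Probability in `[0, 1]` that a planted column
#'   pair is drawn jointly from the compatible-couple set.
#' @return A `fixture_spec`.
#' @export
fixture_spec <- function(n_residues = 40, seed = 1, interface_pairs = NULL,
                         n_interface = 3, msa_depth = 200,
                         coupling_strength = 0.9) {
  stopifnot(n_residues >= 5, msa_depth >= 1,
            coupling_strength >= 0, coupling_strength <= 1)
  if (!is.null(interface_pairs)) {
    if (is.list(interface_pairs)) {
      interface_pairs <- do.call(rbind, interface_pairs)
    }
    interface_pairs <- matrix(as.integer(interface_pairs), ncol = 2)
  }
  structure(list(n_residues = as.integer(n_residues), seed = as.integer(seed),
                 interface_pairs = interface_pairs,
                 n_interface = as.integer(n_interface),
                 msa_depth = as.integer(msa_depth),
                 coupling_strength = coupling_strength),
            class = "fixture_spec")
}

choose_interface_pairs <- function(L, k, rng_offset = 0L) {
  # spaced pairs i < j, no shared residues
  stopifnot(2L * k <= L - 2L)
  res <- round(seq(2, L - 1, length.out = 2L * k))
  res <- unique(as.integer(res))
  if (length(res) < 2L * k) stop("cannot place ", k, " disjoint pairs in L = ", L)
  cbind(res[seq_len(k)], rev(res)[seq_len(k)])
}

# local heavy-atom offsets (A): compact dummy residue, max norm ~1.2
RES_ATOM_OFFSETS <- rbind(
  N  = c(-0.8,  0.2, 0.0),
  CA = c( 0.0,  0.0, 0.0),
  C  = c( 0.8,  0.2, 0.0),
  O  = c( 0.8,  0.9, 0.2),
  CB = c( 0.0, -0.7, 0.5)
)

#' Generate a synthetic C2 homodimer with a planted interface
#'
#' Chain A is a perturbed coil trace whose body stays far from the two-fold
#' (z) axis; the residues of each planted pair dart towards the axis so that
#' exactly the planted pairs fall within 8 A across the interface while
#' every other inter-chain residue pair stays beyond 10 A. Chain B is the
#' exact 180-degree rotation of chain A about the z axis, so the dimer is an
#' exact C2 two-fold and the generating transform is returned.
#'
#' @param spec A `fixture_spec`.
#' @return List with `dimer` (a `dimer_structure`), `transform` (list with
#'   `rotation`, `translation`), `interface_pairs`, and `sequence`.
#' @export
make_c2_dimer <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  L <- spec$n_residues
  set.seed(spec$seed)
  pairs <- spec$interface_pairs
  if (is.null(pairs)) pairs <- choose_interface_pairs(L, spec$n_interface)
  if (any(pairs < 1) || any(pairs > L)) stop("planted pairs out of range")
  if (any(pairs[, 1] == pairs[, 2]) ||
      anyDuplicated(as.vector(pairs)) > 0) {
    stop("infeasible planting: pairs must use distinct residues ",
         "(a residue cannot sit on both sides of the two-fold axis)")
  }
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  K <- nrow(pairs)

  sequence <- sample(aa_alphabet(), L, replace = TRUE,
                     prob = aa_background())

  centers <- matrix(NA_real_, L, 3)
  # interface fingers near the two-fold axis, spread along z
  for (k in seq_len(K)) {
    zk <- 13 * k
    # the two partners sit on opposite sides of the axis; the y offset is
    # chosen so their intra-monomer heavy-atom distance exceeds the 12 A
    # baseline filter while the inter-chain contact distance (which is
    # independent of y under the two-fold) stays at 4 A
    centers[pairs[k, 1], ] <- c(2.0, -7.5, zk)
    centers[pairs[k, 2], ] <- c(2.0,  7.5, zk)
  }
  # body: smooth coil at a safe distance from the axis
  body <- setdiff(seq_len(L), as.vector(pairs))
  t <- seq(0, 4 * pi, length.out = length(body))
  zspan <- range(c(0, 13 * K + 6))
  centers[body, ] <- cbind(
    14 + 2 * cos(t),
    2 * sin(t),
    seq(zspan[1], zspan[2], length.out = length(body))
  )
  centers <- centers + matrix(runif(3 * L, -0.4, 0.4), L, 3)

  atoms <- do.call(rbind, lapply(seq_len(L), function(i) {
    off <- RES_ATOM_OFFSETS
    data.frame(res = i, name = rownames(off),
               elem = substr(rownames(off), 1, 1),
               x = centers[i, 1] + off[, 1],
               y = centers[i, 2] + off[, 2],
               z = centers[i, 3] + off[, 3],
               occ = 1, altloc = "", stringsAsFactors = FALSE)
  }))
  rownames(atoms) <- NULL

  res3 <- aa_one_to_three(sequence)
  chain_a <- new_monomer("A", res3, as.character(seq_len(L)),
                         rep(TRUE, L), atoms)
  Rz <- diag(c(-1, -1, 1))
  atoms_b <- atoms
  ab <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(Rz)
  atoms_b$x <- ab[, 1]; atoms_b$y <- ab[, 2]; atoms_b$z <- ab[, 3]
  chain_b <- new_monomer("B", res3, as.character(seq_len(L)),
                         rep(TRUE, L), atoms_b)

  # verify the planting before returning
  d <- dimer_structure(chain_a, chain_b)
  cm <- inter_contact_map(d, 8.0)
  want <- matrix(0L, L, L)
  want[pairs] <- 1L
  want <- symmetrize_labels(want)
  if (!identical(unname(cm$values), unname(want))) {
    stop("infeasible planting: generated contacts do not equal the planted set")
  }
  list(dimer = d,
       transform = list(rotation = Rz, translation = c(0, 0, 0)),
       interface_pairs = pairs,
       sequence = paste(sequence, collapse = ""))
}

# amino-acid couples used for planted covariation (salt bridges and
# conservative substitutions: strong joint signal, weak marginals)
COVARYING_COUPLES <- rbind(
  c("E", "R"), c("R", "E"), c("K", "D"), c("D", "K"),
  c("L", "I"), c("F", "Y")
)

#' Generate a synthetic alignment with planted covariation
#'
#' The query is the fixture sequence; the remaining `M - 1` rows are drawn
#' i.i.d. per column from the background amino-acid distribution, except at
#' planted pair columns, which with probability `coupling_strength` are
#' drawn jointly from a fixed set of compatible residue couples. No gaps are
#' introduced, so the alignment width equals the query length.
#'
#' @param spec A `fixture_spec`.
#' @param sequence Optional query sequence (string); random otherwise.
#' @param interface_pairs Optional pair matrix override.
#' @return An `msa`.
#' @export
make_synthetic_msa <- function(spec, sequence = NULL,
                               interface_pairs = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  L <- spec$n_residues
  M <- spec$msa_depth
  set.seed(spec$seed + 7919L)
  pairs <- interface_pairs
  if (is.null(pairs)) pairs <- spec$interface_pairs
  if (is.null(pairs)) pairs <- choose_interface_pairs(L, spec$n_interface)
  if (is.null(sequence)) {
    sequence <- paste(sample(aa_alphabet(), L, replace = TRUE,
                             prob = aa_background()), collapse = "")
  }
  query <- strsplit(sequence, "")[[1]]
  stopifnot(length(query) == L)
  mat <- matrix("", M, L)
  mat[1, ] <- query
  if (M > 1) {
    for (col in seq_len(L)) {
      mat[2:M, col] <- sample(aa_alphabet(), M - 1, replace = TRUE,
                              prob = aa_background())
    }
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      couple <- sample(nrow(COVARYING_COUPLES), M - 1, replace = TRUE)
      use <- runif(M - 1) < spec$coupling_strength
      mat[2:M, i][use] <- COVARYING_COUPLES[couple[use], 1]
      mat[2:M, j][use] <- COVARYING_COUPLES[couple[use], 2]
    }
  }
  new_msa(mat, c("query", if (M > 1) paste0("synth", seq_len(M - 1))))
}

#' Write a fixture dimer as a PDB file
#'
#' @param d A `dimer_structure`.
#' @param path Output PDB path.
#' @return The path, invisibly.
#' @export
write_dimer_pdb <- function(d, path) {
  fmt <- function(m, serial0) {
    at <- m$atoms
    sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial0 + seq_len(nrow(at)),
            ifelse(nchar(at$name) < 4, paste0(" ", at$name), at$name),
            m$res_name3[at$res], m$chain_id,
            as.integer(m$author[at$res]),
            at$x, at$y, at$z, 1.0, 0.0, at$elem)
  }
  writeLines(c(fmt(d$chain_a, 0L), "TER",
               fmt(d$chain_b, nrow(d$chain_a$atoms)), "TER", "END"), path)
  invisible(path)
}

#' Build a bundled synthetic training set
#'
#' Runs the full feature pipeline on generated fixtures: for each target a
#' C2 dimer and a covarying alignment are generated, couplings are computed
#' with the mean-field engine, the docking map is produced with coarse
#' rotation sampling (suitable for desk-scale training), features are
#' assembled, and labels come from the dimer's inter-chain contact map.
#' Targets are split into train/validation by a deterministic rule on the
#' target index (every fifth target validates).
#'
#' @param n_targets Number of targets (>= 1).
#' @param seed Base seed; target `t` uses `seed + t`.
#' @param n_residues,msa_depth,n_interface,coupling_strength Fixture
#'   parameters.
#' @param dock_interval,dock_top_t Docking-map sampling for the training
#'   features.
#' @return List with `train`, `val` (lists of `list(bundle, labels,
#'   fixture)`), and `all`.
#' @export
make_training_set <- function(n_targets, seed = 1, n_residues = 40,
                              msa_depth = 200, n_interface = 3,
                              coupling_strength = 0.9,
                              dock_interval = 30, dock_top_t = 50) {
  stopifnot(n_targets >= 1)
  all <- vector("list", n_targets)
  for (t in seq_len(n_targets)) {
    sp <- fixture_spec(n_residues = n_residues, seed = seed + t,
                       msa_depth = msa_depth, n_interface = n_interface,
                       coupling_strength = coupling_strength)
    fx <- make_c2_dimer(sp)
    msa <- make_synthetic_msa(sp, sequence = fx$sequence,
                              interface_pairs = fx$interface_pairs)
    cpl <- compute_couplings(msa)
    dmap <- docking_map(fx$dimer$chain_a, interval = dock_interval,
                        top_t = dock_top_t)
    bundle <- build_features(fx$dimer$chain_a, msa, cpl, dmap)
    labels <- inter_contact_map(fx$dimer, 8.0)
    labels$values <- symmetrize_labels(labels$values)
    all[[t]] <- list(bundle = bundle, labels = labels, fixture = fx)
  }
  is_val <- (seq_len(n_targets) %% 5L) == 0L
  if (!any(is_val)) is_val[n_targets] <- TRUE
  list(train = all[!is_val], val = all[is_val], all = all)
}
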