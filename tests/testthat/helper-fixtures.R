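# Shared helpers: tiny structures and bundles built in code.

# monomer with arbitrary residue centres and one CA-like atom each
point_monomer <- function(centers, elem = "C", names3 = NULL) {
  L <- nrow(centers)
  atoms <- data.frame(res = seq_len(L), name = "CA", elem = elem,
                      x = centers[, 1], y = centers[, 2], z = centers[, 3],
                      occ = 1, altloc = "", stringsAsFactors = FALSE)
  if (is.null(names3)) names3 <- rep("ALA", L)
  c2contact:::new_monomer("A", names3, as.character(seq_len(L)),
                          rep(TRUE, L), atoms)
}

# monomer from an explicit atom table
table_monomer <- function(atoms, L, names3 = rep("ALA", L),
                          observed = rep(TRUE, L)) {
  c2contact:::new_monomer("A", names3, as.character(seq_len(L)),
                          observed, atoms)
}

# ideal poly-Ala helix with full backbone
helix_monomer <- function(n, phi = -57, psi = -47) {
  bb <- c2contact:::build_backbone(n, phi, psi)
  atoms <- do.call(rbind, lapply(seq_along(bb), function(i) {
    data.frame(res = i, name = rownames(bb[[i]]),
               elem = substr(rownames(bb[[i]]), 1, 1),
               x = bb[[i]][, 1], y = bb[[i]][, 2], z = bb[[i]][, 3],
               occ = 1, altloc = "", stringsAsFactors = FALSE)
  }))
  table_monomer(atoms, n)
}

# random feature bundle for network tests (no pipeline dependency)
random_bundle <- function(L, seed = 1) {
  set.seed(seed)
  structure(list(
    seq_features = matrix(rnorm(L * 31), L, 31),
    pair_features = array(rnorm(L * L * 4), c(L, L, 4)),
    mask = matrix(TRUE, L, L),
    L = L,
    channel_order = c("distance", "docking", "coupling_raw", "coupling_apc")
  ), class = "feature_bundle")
}

# random ranked contact list plus a random truth map over unique pairs
random_toy_target <- function(L, seed) {
  set.seed(seed)
  idx <- which(upper.tri(matrix(0, L, L), diag = TRUE), arr.ind = TRUE)
  df <- data.frame(i = idx[, 1], j = idx[, 2], score = runif(nrow(idx)))
  df <- df[order(-df$score, df$i, df$j), ]
  rownames(df) <- NULL
  attr(df, "L") <- L
  class(df) <- c("ranked_contacts", "data.frame")
  truth <- matrix(rbinom(L * L, 1, 0.1), L, L)
  truth <- c2contact::symmetrize_labels(truth)
  list(pred = df, truth = list(values = truth, mask = matrix(TRUE, L, L)))
}

# independent scalar focal loss (the oracle: plain loops, no vectorisation)
focal_oracle <- function(p, y, mask, alpha, gamma) {
  tot <- 0; n <- 0
  for (k in seq_along(p)) {
    if (!mask[k]) next
    if (y[k] == 1) { at <- alpha; pt <- p[k] } else { at <- 1 - alpha; pt <- 1 - p[k] }
    tot <- tot + (-at * (1 - pt)^gamma * log(pt))
    n <- n + 1
  }
  tot / n
}

minimal_pdb_lines <- function() {
  c("ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  GLY A   2       4.000   1.000   0.000  1.00  0.00           C",
    "TER",
    "END")
}
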