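# Per-record dataset curation predicates.

#' Construct a structure record for dataset filtering
#'
#' Bundles the per-assembly metadata the curation predicates look at.
#'
#' @param resolution Crystallographic resolution in Angstrom.
#' @param n_chains Number of protein chains in the biological unit.
#' @param chain_length Number of residues per chain.
#' @param chain_identity Sequence identity between the two chains (fraction).
#' @param symmetry_label Author-assigned symmetry type, e.g. `"C2"`.
#' @param interface_area Buried interface area in Angstrom^2.
#' @return A `structure_record`.
#' @export
structure_record <- function(resolution, n_chains, chain_length,
                             chain_identity, symmetry_label, interface_area) {
  stopifnot(resolution > 0, chain_identity >= 0, chain_identity <= 1)
  structure(list(resolution = resolution, n_chains = n_chains,
                 chain_length = chain_length, chain_identity = chain_identity,
                 symmetry_label = symmetry_label,
                 interface_area = interface_area),
            class = "structure_record")
}

#' Apply the homodimer dataset filters to a structure record
#'
#' A record passes when all of the following hold: author symmetry is C2, the
#' biological unit has exactly two chains, resolution is better than (strictly
#' below) `max_resolution`, chain length lies in `[min_len, max_len]`, the two
#' chains share more than `min_identity` sequence identity, and the buried
#' interface exceeds `min_interface`.
#'
#' @param r A `structure_record`.
#' @param min_len,max_len Allowed chain length range (residues).
#' @param max_resolution Strict resolution bound in Angstrom.
#' @param min_identity Strict lower bound on chain sequence identity.
#' @param min_interface Strict lower bound on interface area in Angstrom^2.
#' @return List with `pass` (logical) and `failed` (character vector naming
#'   every violated rule: `symmetry`, `n_chains`, `resolution`, `length`,
#'   `identity`, `interface`).
#' @export
passes_dataset_filters <- function(r, min_len = 50, max_len = 500,
                                   max_resolution = 3.0, min_identity = 0.99,
                                   min_interface = 1000.0) {
  stopifnot(inherits(r, "structure_record"))
  failed <- character(0)
  if (!identical(r$symmetry_label, "C2")) failed <- c(failed, "symmetry")
  if (r$n_chains != 2L) failed <- c(failed, "n_chains")
  if (!(r$resolution < max_resolution)) failed <- c(failed, "resolution")
  if (r$chain_length < min_len || r$chain_length > max_len) {
    failed <- c(failed, "length")
  }
  if (!(r$chain_identity > min_identity)) failed <- c(failed, "identity")
  if (!(r$interface_area > min_interface)) failed <- c(failed, "interface")
  list(pass = length(failed) == 0L, failed = failed)
}
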