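# Structure parsing and structure-derived features.

#' Parse a single protein chain from a PDB or mmCIF file
#'
#' Reads one chain and returns a monomer structure holding per-residue heavy
#' atoms. Hydrogens (and deuterium) and waters are dropped; for atoms with
#' alternate locations exactly one copy is retained (highest occupancy, ties
#' resolved towards altloc "A"). Gaps in the author residue numbering are kept
#' as unobserved placeholder residues so that internal indices match the full
#' sequence and downstream masks line up.
#'
#' @param path Path to a PDB or mmCIF file (format chosen by extension:
#'   `.cif`/`.mmcif` is read as mmCIF, anything else as PDB).
#' @param chain Chain identifier to extract.
#' @return An object of class `monomer_structure` with fields `chain_id`,
#'   `L`, `sequence`, `res_name3`, `author` (author residue numbers with
#'   insertion codes), `observed`, and an `atoms` data frame
#'   (`res`, `name`, `elem`, `x`, `y`, `z`, `occ`, `altloc`).
#' @export
parse_structure <- function(path, chain) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  pdb <- tryCatch(
    if (ext %in% c("cif", "mmcif")) bio3d::read.cif(path, rm.alt = FALSE)
    else bio3d::read.pdb(path, rm.alt = FALSE),
    error = function(e) stop("could not parse structure file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  at <- pdb$atom
  chains <- sort(unique(at$chain))
  if (!chain %in% chains) {
    stop("chain '", chain, "' not found; available chains: ",
         paste(chains, collapse = ", "))
  }
  at <- at[at$chain == chain, , drop = FALSE]
  # waters and hydrogens out
  at <- at[!toupper(at$resid) %in% c("HOH", "WAT", "DOD"), , drop = FALSE]
  elem <- toupper(trimws(at$elesy))
  noel <- is.na(elem) | elem == ""
  if (any(noel)) elem[noel] <- guess_element(at$elety[noel])
  keep <- !(elem %in% c("H", "D"))
  at <- at[keep, , drop = FALSE]
  elem <- elem[keep]
  if (nrow(at) == 0L) stop("chain '", chain, "' has no heavy atoms")

  ins <- at$insert
  ins[is.na(ins)] <- ""
  occ <- at$o
  occ[is.na(occ)] <- 1
  alt <- at$alt
  alt[is.na(alt)] <- ""
  df <- data.frame(
    resno = at$resno, ins = ins, resid = at$resid, name = trimws(at$elety),
    elem = elem, x = at$x, y = at$y, z = at$z, occ = occ, altloc = alt,
    stringsAsFactors = FALSE
  )
  # altloc resolution: one copy per (residue, atom name)
  key <- paste(df$resno, df$ins, df$name, sep = "\r")
  if (anyDuplicated(key)) {
    ord <- order(key, -df$occ, df$altloc != "A", df$altloc)
    df <- df[ord, , drop = FALSE]
    df <- df[!duplicated(key[ord]), , drop = FALSE]
  }
  df <- df[order(df$resno, df$ins), , drop = FALSE]

  rkey <- paste(df$resno, df$ins, sep = "\r")
  ridx <- match(rkey, unique(rkey))
  resno_u <- df$resno[!duplicated(rkey)]
  ins_u <- df$ins[!duplicated(rkey)]
  name_u <- df$resid[!duplicated(rkey)]

  # insert placeholders for numbering gaps (missing residues)
  full_no <- integer(0); full_ins <- character(0)
  full_name <- character(0); full_obs <- logical(0)
  map_obs <- integer(length(resno_u))
  for (k in seq_along(resno_u)) {
    if (k > 1L) {
      gap <- resno_u[k] - resno_u[k - 1L]
      if (!is.na(gap) && gap > 1L && gap <= 10000L) {
        miss <- seq(resno_u[k - 1L] + 1L, resno_u[k] - 1L)
        full_no <- c(full_no, miss)
        full_ins <- c(full_ins, rep("", length(miss)))
        full_name <- c(full_name, rep("UNK", length(miss)))
        full_obs <- c(full_obs, rep(FALSE, length(miss)))
      }
    }
    full_no <- c(full_no, resno_u[k]); full_ins <- c(full_ins, ins_u[k])
    full_name <- c(full_name, name_u[k]); full_obs <- c(full_obs, TRUE)
    map_obs[k] <- length(full_no)
  }

  atoms <- data.frame(
    res = map_obs[ridx], name = df$name, elem = df$elem,
    x = df$x, y = df$y, z = df$z, occ = df$occ, altloc = df$altloc,
    stringsAsFactors = FALSE
  )
  new_monomer(
    chain_id = chain,
    res_name3 = full_name,
    author = paste0(full_no, full_ins),
    observed = full_obs,
    atoms = atoms
  )
}

guess_element <- function(atom_names) {
  nm <- gsub("[0-9'\"]", "", trimws(atom_names))
  el <- substr(nm, 1, 1)
  two <- toupper(substr(nm, 1, 2))
  el[two %in% c("SE", "FE", "ZN", "MG", "MN", "CL", "BR")] <- two[two %in%
    c("SE", "FE", "ZN", "MG", "MN", "CL", "BR")]
  toupper(el)
}

new_monomer <- function(chain_id, res_name3, author, observed, atoms) {
  L <- length(res_name3)
  stopifnot(length(author) == L, length(observed) == L,
            all(atoms$res >= 1L), all(atoms$res <= L),
            all(is.finite(atoms$x)), all(is.finite(atoms$y)),
            all(is.finite(atoms$z)))
  m <- list(
    chain_id = chain_id,
    L = L,
    sequence = paste(aa_three_to_one(res_name3), collapse = ""),
    res_name3 = res_name3,
    author = author,
    observed = observed,
    atoms = atoms
  )
  class(m) <- "monomer_structure"
  m
}

#' @export
print.monomer_structure <- function(x, ...) {
  cat("Monomer structure: chain", x$chain_id, "-", x$L, "residues (",
      sum(x$observed), "observed ),", nrow(x$atoms), "heavy atoms\n")
  invisible(x)
}

#' Extract one residue of a monomer structure
#'
#' @param m A `monomer_structure`.
#' @param i 1-based internal residue index.
#' @return List with `name` (3-letter code), `observed`, and `xyz`
#'   (heavy-atom coordinate matrix, possibly 0-row).
#' @export
residue <- function(m, i) {
  stopifnot(inherits(m, "monomer_structure"), i >= 1L, i <= m$L)
  sel <- m$atoms$res == i
  list(
    name = m$res_name3[i],
    observed = m$observed[i],
    xyz = cbind(x = m$atoms$x[sel], y = m$atoms$y[sel], z = m$atoms$z[sel])
  )
}

res_coords <- function(m) {
  list(coords = cbind(m$atoms$x, m$atoms$y, m$atoms$z),
       res = as.integer(m$atoms$res))
}

#' Minimal heavy-atom distance between two residues
#'
#' @param res_a,res_b Residues as returned by [residue()].
#' @return Distance in Angstrom: the minimum over all heavy-atom pairs.
#' @export
min_heavy_atom_distance <- function(res_a, res_b) {
  if (!isTRUE(res_a$observed) || !isTRUE(res_b$observed) ||
      nrow(res_a$xyz) == 0L || nrow(res_b$xyz) == 0L) {
    stop("distance undefined: residue without observed coordinates")
  }
  d <- cpp_min_dist_map(res_a$xyz, rep(1L, nrow(res_a$xyz)), 1L,
                        res_b$xyz, rep(1L, nrow(res_b$xyz)), 1L)
  d[1, 1]
}

#' Intra-monomer minimal heavy-atom distance map
#'
#' @param m A `monomer_structure`.
#' @return A `distance_map`: list with `values` (L x L, Angstrom, `Inf` where
#'   a residue is unobserved) and logical `mask` (FALSE where either residue
#'   is unobserved).
#' @export
intra_distance_map <- function(m) {
  stopifnot(inherits(m, "monomer_structure"))
  rc <- res_coords(m)
  vals <- cpp_min_dist_map(rc$coords, rc$res, m$L, rc$coords, rc$res, m$L)
  mask <- outer(m$observed, m$observed, "&")
  structure(list(values = vals, mask = mask), class = "distance_map")
}

#' Pair two copies of a monomer into a homodimer
#'
#' @param chain_a,chain_b `monomer_structure` objects for the two chains.
#' @param correspondence Integer vector mapping residue `i` of chain A to its
#'   equivalent residue in chain B (NA for no equivalent). Defaults to the
#'   identity map when the chains have equal length.
#' @return A `dimer_structure`.
#' @export
dimer_structure <- function(chain_a, chain_b, correspondence = NULL) {
  stopifnot(inherits(chain_a, "monomer_structure"),
            inherits(chain_b, "monomer_structure"))
  if (is.null(correspondence)) {
    if (chain_a$L != chain_b$L) {
      stop("chains have different lengths (", chain_a$L, " vs ", chain_b$L,
           "); supply an explicit residue correspondence")
    }
    correspondence <- seq_len(chain_a$L)
  }
  sa <- strsplit(chain_a$sequence, "")[[1]]
  sb <- strsplit(chain_b$sequence, "")[[1]]
  ok <- which(!is.na(correspondence) & chain_a$observed &
                chain_b$observed[pmax(correspondence, 1L)])
  if (length(ok) > 0L) {
    ident <- mean(sa[ok] == sb[correspondence[ok]])
    if (ident < 0.99) {
      warning(sprintf(
        "chains share only %.1f%% sequence identity over corresponding residues; not a strict homodimer",
        100 * ident))
    }
  }
  structure(list(chain_a = chain_a, chain_b = chain_b,
                 correspondence = as.integer(correspondence)),
            class = "dimer_structure")
}

#' Inter-chain residue contact map of a homodimer
#'
#' Two residues from different chains are in contact when any two heavy atoms
#' are within `cutoff` (inclusive). The map is indexed in chain A's residue
#' frame on both axes, with chain B residues mapped through the dimer's
#' residue correspondence.
#'
#' @param d A `dimer_structure`.
#' @param cutoff Contact distance threshold in Angstrom (default 8; 6 is the
#'   common stricter alternative).
#' @return A `contact_map`: list with binary `values` and logical `mask`.
#' @export
inter_contact_map <- function(d, cutoff = 8.0) {
  stopifnot(inherits(d, "dimer_structure"))
  if (all(is.na(d$correspondence))) stop("empty residue correspondence")
  L <- d$chain_a$L
  ra <- res_coords(d$chain_a)
  rb <- res_coords(d$chain_b)
  dm <- cpp_min_dist_map(ra$coords, ra$res, L,
                         rb$coords, rb$res, d$chain_b$L)
  vals <- matrix(0L, L, L)
  mask <- matrix(FALSE, L, L)
  corr <- d$correspondence
  jb <- corr[seq_len(L)]
  okj <- which(!is.na(jb) & d$chain_b$observed[pmax(jb, 1L)])
  oki <- which(d$chain_a$observed)
  mask[oki, okj] <- TRUE
  vals[oki, okj] <- as.integer(dm[oki, jb[okj], drop = FALSE] <= cutoff)
  vals[!mask] <- 0L
  structure(list(values = vals, mask = mask), class = "contact_map")
}
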