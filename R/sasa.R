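# Solvent accessible surface area: point-sampling (Shrake-Rupley) and
# slice-based (Lee-Richards) implementations, plus the buried interface area.

# Deterministic golden-spiral point set on the unit sphere.
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

sasa_atoms_sr <- function(coords, radii, probe_radius, n_points) {
  n <- nrow(coords)
  pts <- sphere_points(n_points)
  R <- radii + probe_radius
  areas <- numeric(n)
  # neighbour lists via a coarse distance screen
  dmat <- as.matrix(stats::dist(coords))
  for (i in seq_len(n)) {
    nb <- which(dmat[i, ] < R[i] + R & seq_len(n) != i)
    surf <- sweep(pts * R[i], 2, coords[i, ], "+")
    if (length(nb) > 0L) {
      free <- rep(TRUE, n_points)
      for (j in nb) {
        if (!any(free)) break
        dx <- surf[free, 1] - coords[j, 1]
        dy <- surf[free, 2] - coords[j, 2]
        dz <- surf[free, 3] - coords[j, 3]
        free[free] <- dx * dx + dy * dy + dz * dz > R[j]^2
      }
      frac <- mean(free)
    } else {
      frac <- 1
    }
    areas[i] <- frac * 4 * pi * R[i]^2
  }
  areas
}

sasa_atoms_lr <- function(coords, radii, probe_radius, slice = 0.25) {
  n <- nrow(coords)
  R <- radii + probe_radius
  dmat <- as.matrix(stats::dist(coords))
  areas <- numeric(n)
  for (i in seq_len(n)) {
    Ri <- R[i]
    nb <- which(dmat[i, ] < Ri + R & seq_len(n) != i)
    zs <- seq(coords[i, 3] - Ri + slice / 2, coords[i, 3] + Ri - slice / 2,
              by = slice)
    ai <- 0
    for (z in zs) {
      ri <- sqrt(max(0, Ri^2 - (z - coords[i, 3])^2))
      if (ri <= 0) next
      blocked <- list()
      fully <- FALSE
      for (j in nb) {
        dzj <- z - coords[j, 3]
        if (abs(dzj) >= R[j]) next
        rj <- sqrt(R[j]^2 - dzj^2)
        d <- sqrt((coords[i, 1] - coords[j, 1])^2 +
                    (coords[i, 2] - coords[j, 2])^2)
        if (d >= ri + rj) next
        if (d + ri <= rj) { fully <- TRUE; break }
        if (d + rj <= ri) next
        alpha <- acos(pmin(1, pmax(-1, (d^2 + ri^2 - rj^2) / (2 * d * ri))))
        mid <- atan2(coords[j, 2] - coords[i, 2], coords[j, 1] - coords[i, 1])
        blocked[[length(blocked) + 1L]] <- c(mid - alpha, mid + alpha)
      }
      if (fully) next
      acc <- 2 * pi - merged_arc_length(blocked)
      # surface strip of a sphere between parallel planes: 2*pi*R*dz scaled
      # by the accessible arc fraction of the slice circle
      ai <- ai + acc / (2 * pi) * 2 * pi * Ri * slice
    }
    areas[i] <- ai
  }
  areas
}

# total length of a union of angular intervals (radians, any origin)
merged_arc_length <- function(intervals) {
  if (length(intervals) == 0L) return(0)
  segs <- matrix(0, 0, 2)
  for (iv in intervals) {
    a <- iv[1] %% (2 * pi); b <- a + (iv[2] - iv[1])
    if (b > 2 * pi) {
      segs <- rbind(segs, c(a, 2 * pi), c(0, b - 2 * pi))
    } else {
      segs <- rbind(segs, c(a, b))
    }
  }
  segs <- segs[order(segs[, 1]), , drop = FALSE]
  tot <- 0; cur_a <- segs[1, 1]; cur_b <- segs[1, 2]
  for (k in seq_len(nrow(segs))[-1]) {
    if (segs[k, 1] <= cur_b) {
      cur_b <- max(cur_b, segs[k, 2])
    } else {
      tot <- tot + cur_b - cur_a
      cur_a <- segs[k, 1]; cur_b <- segs[k, 2]
    }
  }
  tot + cur_b - cur_a
}

#' Per-residue solvent accessible surface area
#'
#' Computes absolute SASA per residue with either Shrake and Rupley's
#' point-sampling method (the surface of each atom is approximated by a
#' deterministic golden-spiral point set) or Lee and Richards' slice method
#' (accessible arcs on z-slices through each atom sphere).
#'
#' @param m A `monomer_structure`, or a list with `coords` (n x 3 matrix),
#'   `radii` and optional `res` (residue index per atom).
#' @param algorithm `"shrake_rupley"` or `"lee_richards"`.
#' @param probe_radius Solvent probe radius in Angstrom.
#' @param n_points Points per atom sphere (Shrake-Rupley only).
#' @param slice Slice spacing in Angstrom (Lee-Richards only).
#' @return Numeric vector of per-residue areas in Angstrom^2 (length L for a
#'   monomer; unobserved residues get 0). The sum over residues is the
#'   molecule's total SASA.
#' @export
sasa <- function(m, algorithm = c("shrake_rupley", "lee_richards"),
                 probe_radius = 1.4, n_points = 960, slice = 0.25) {
  algorithm <- match.arg(algorithm)
  if (n_points < 1) stop("n_points must be >= 1")
  if (inherits(m, "monomer_structure")) {
    coords <- cbind(m$atoms$x, m$atoms$y, m$atoms$z)
    radii <- vdw_radius(m$atoms$elem)
    res <- m$atoms$res
    L <- m$L
  } else {
    coords <- m$coords
    radii <- m$radii
    res <- if (is.null(m$res)) seq_len(nrow(coords)) else m$res
    L <- max(res)
  }
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  at <- if (algorithm == "shrake_rupley") {
    sasa_atoms_sr(coords, radii, probe_radius, n_points)
  } else {
    sasa_atoms_lr(coords, radii, probe_radius, slice)
  }
  out <- numeric(L)
  agg <- tapply(at, res, sum)
  out[as.integer(names(agg))] <- agg
  out
}

#' Buried interface area of a homodimer
#'
#' Half the change in solvent accessible surface area upon binding:
#' `(SASA(A) + SASA(B) - SASA(AB)) / 2`.
#'
#' @param d A `dimer_structure`.
#' @param n_points Points per atom for the Shrake-Rupley sampling.
#' @param probe_radius Probe radius in Angstrom.
#' @return Interface area in Angstrom^2 (non-negative up to sampling noise).
#' @export
interface_area <- function(d, n_points = 960, probe_radius = 1.4) {
  stopifnot(inherits(d, "dimer_structure"))
  ca <- cbind(d$chain_a$atoms$x, d$chain_a$atoms$y, d$chain_a$atoms$z)
  cb <- cbind(d$chain_b$atoms$x, d$chain_b$atoms$y, d$chain_b$atoms$z)
  ra <- vdw_radius(d$chain_a$atoms$elem)
  rb <- vdw_radius(d$chain_b$atoms$elem)
  sa <- sum(sasa_atoms_sr(ca, ra, probe_radius, n_points))
  sb <- sum(sasa_atoms_sr(cb, rb, probe_radius, n_points))
  sab <- sum(sasa_atoms_sr(rbind(ca, cb), c(ra, rb), probe_radius, n_points))
  (sa + sb - sab) / 2
}
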