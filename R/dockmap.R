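# FFT shape-complementarity docking restricted to C2 poses, and the docking
# map feature: the union of inter-chain contact maps over all retained poses.

#' Sample C2 rotations at a given angular resolution
#'
#' A C2 pose places the second copy by a 180-degree rotation about an axis;
#' the rotation space is therefore the hemisphere of axis directions (axis
#' and anti-axis give the same rotation). Axes are drawn from a deterministic
#' Fibonacci lattice with approximately one axis per
#' `angle_interval_deg^2` patch of solid angle.
#'
#' @param angle_interval_deg Angular resolution in degrees (0, 90].
#' @return List of 3 x 3 rotation matrices (each orthonormal, det +1) with
#'   the sampled axes in `attr(, "axes")`.
#' @export
sample_rotations <- function(angle_interval_deg = 6.0) {
  stopifnot(angle_interval_deg > 0, angle_interval_deg <= 90)
  theta <- angle_interval_deg * pi / 180
  n <- max(1L, as.integer(round(2 * pi / theta^2)))
  axes <- fibonacci_hemisphere(n)
  rots <- lapply(seq_len(n), function(k) {
    u <- axes[k, ]
    2 * (u %o% u) - diag(3)
  })
  attr(rots, "axes") <- axes
  rots
}

#' Project a structure onto a labelled cubic grid
#'
#' Cells within the van der Waals envelope of any atom are labelled core;
#' cells within `surface_thickness` of the envelope (and not core) are
#' labelled surface; the rest are empty.
#'
#' @param m A `monomer_structure` or an n x 3 coordinate matrix.
#' @param spacing Grid spacing in Angstrom.
#' @param surface_thickness Thickness of the surface shell in Angstrom.
#' @param fill_radius Atom envelope radius in Angstrom.
#' @param dims,origin Optional fixed grid geometry (used by the docking scan
#'   to keep all grids commensurate); computed from the coordinates with a
#'   snug margin when omitted.
#' @return Object of class `dock_grid`: list with `spacing`, `origin`,
#'   `dims`, and `labels` (integer array: 0 empty, 1 surface, 2 core).
#' @export
grid_project <- function(m, spacing = 1.2, surface_thickness = 1.5,
                         fill_radius = 1.8, dims = NULL, origin = NULL) {
  if (spacing <= 0) stop("spacing must be positive")
  coords <- if (inherits(m, "monomer_structure")) {
    cbind(m$atoms$x, m$atoms$y, m$atoms$z)
  } else {
    as.matrix(m)
  }
  if (nrow(coords) == 0L) stop("empty structure")
  margin <- fill_radius + surface_thickness + spacing
  if (is.null(origin)) origin <- apply(coords, 2, min) - margin
  if (is.null(dims)) {
    dims <- as.integer(ceiling((apply(coords, 2, max) + margin - origin) /
                                 spacing)) + 1L
  }
  labels <- cpp_fill_grid(coords, as.integer(dims), as.numeric(origin),
                          spacing, fill_radius, surface_thickness)
  structure(list(spacing = spacing, origin = as.numeric(origin),
                 dims = as.integer(dims), labels = labels),
            class = "dock_grid")
}

grid_complex <- function(g, core_penalty) {
  s <- (g$labels == 1L) + 0
  co <- (g$labels == 2L) + 0
  array(complex(real = s, imaginary = sqrt(core_penalty) * co), dim = g$dims)
}

# Embed an array into the corner of a larger zero array.
pad_array <- function(a, dims) {
  out <- array(0 + 0i, dim = dims)
  out[seq_len(dim(a)[1]), seq_len(dim(a)[2]), seq_len(dim(a)[3])] <- a
  out
}

scan_core <- function(FA, gb, common, top_t, core_penalty, origin_a) {
  B <- pad_array(grid_complex(gb, core_penalty), common)
  FB <- fft(Conj(B))
  corr <- Re(fft(FA * Conj(FB), inverse = TRUE)) / prod(common)
  # circular index -> signed lattice shift
  n1 <- common[1]; n2 <- common[2]; n3 <- common[3]
  v <- as.numeric(corr)
  k <- min(length(v), max(top_t * 4L, 256L))
  thr <- -sort.int(-v, partial = k)[k]
  cand <- which(v >= thr)
  idx0 <- cand - 1L
  ix <- idx0 %% n1
  iy <- (idx0 %/% n1) %% n2
  iz <- idx0 %/% (n1 * n2)
  sx <- ifelse(ix > n1 / 2, ix - n1, ix)
  sy <- ifelse(iy > n2 / 2, iy - n2, iy)
  sz <- ifelse(iz > n3 / 2, iz - n3, iz)
  sc <- corr[cand]
  ord <- order(-sc, sz, sy, sx)
  take <- head(ord, top_t)
  spacing <- gb$spacing
  off <- origin_a - gb$origin
  data.frame(
    score = sc[take],
    tx = sx[take] * spacing + off[1],
    ty = sy[take] * spacing + off[2],
    tz = sz[take] * spacing + off[3]
  )
}

#' FFT translation scan of two grids
#'
#' Scores every lattice translation of grid B against grid A with the shape
#' complementarity weights surface x surface = +1 and core x core =
#' `-core_penalty` (computed as one complex FFT correlation), and returns the
#' `top_t` translations by score, ties broken lexicographically by the
#' (z, y, x) lattice shift.
#'
#' @param grid_a,grid_b `dock_grid` objects with equal spacing.
#' @param top_t Number of translations to keep.
#' @param core_penalty Weight of core-core overlap (positive number).
#' @return Data frame with columns `score`, `tx`, `ty`, `tz` (translations in
#'   Angstrom applied to grid B's coordinate frame).
#' @export
fft_translation_scan <- function(grid_a, grid_b, top_t = 100,
                                 core_penalty = 15) {
  if (top_t < 1) stop("top_t must be >= 1")
  stopifnot(inherits(grid_a, "dock_grid"), inherits(grid_b, "dock_grid"))
  if (abs(grid_a$spacing - grid_b$spacing) > 1e-9) {
    stop("grids must share spacing")
  }
  common <- vapply(1:3, function(k) {
    stats::nextn(grid_a$dims[k] + grid_b$dims[k], c(2, 3, 5))
  }, integer(1))
  FA <- fft(pad_array(grid_complex(grid_a, core_penalty), common))
  scan_core(FA, grid_b, common, top_t, core_penalty, grid_a$origin)
}

#' Construct a docking pose
#'
#' @param rotation 3 x 3 rotation matrix applied to the second copy.
#' @param translation Length-3 translation in Angstrom.
#' @param score Shape-complementarity score.
#' @return A `dock_pose`.
#' @export
dock_pose <- function(rotation, translation, score = NA_real_) {
  stopifnot(all(dim(rotation) == c(3, 3)),
            max(abs(crossprod(rotation) - diag(3))) < 1e-6,
            abs(det(rotation) - 1) < 1e-6,
            length(translation) == 3)
  structure(list(rotation = rotation, translation = as.numeric(translation),
                 score = score),
            class = "dock_pose")
}

#' Inter-chain contact map of a single docking pose
#'
#' Applies the pose to a copy of the monomer (x' = R x + t) and computes the
#' inter-chain contact map at `cutoff`, symmetrized by element-wise OR with
#' its transpose.
#'
#' @param m A `monomer_structure`.
#' @param pose A `dock_pose`.
#' @param cutoff Contact cutoff in Angstrom.
#' @return A `contact_map`.
#' @export
pose_contact_map <- function(m, pose, cutoff = 8.0) {
  stopifnot(inherits(m, "monomer_structure"), inherits(pose, "dock_pose"))
  rc <- res_coords(m)
  cb <- rc$coords %*% t(pose$rotation)
  cb <- sweep(cb, 2, pose$translation, "+")
  dm <- cpp_min_dist_map(rc$coords, rc$res, m$L, cb, rc$res, m$L)
  vals <- (dm <= cutoff) + 0L
  vals <- ((vals + t(vals)) > 0) + 0L
  mask <- outer(m$observed, m$observed, "&")
  vals[!mask] <- 0L
  structure(list(values = vals, mask = mask), class = "contact_map")
}

#' Docking map of a monomer under the C2 constraint
#'
#' Samples C2 rotations, scans translations for each rotation by FFT shape
#' complementarity, keeps the `top_t` translations per rotation, projects
#' each retained translation onto the plane perpendicular to the C2 axis (so
#' every pose is an exact two-fold), and returns the union of all per-pose
#' inter-chain contact maps.
#'
#' @param m A `monomer_structure`.
#' @param interval Rotation sampling interval in degrees.
#' @param top_t Translations kept per rotation.
#' @param cutoff Contact cutoff in Angstrom.
#' @param spacing,surface_thickness,core_penalty Grid scan parameters.
#' @param rotations Optional pre-sampled rotation list (overrides
#'   `interval`).
#' @return Object of class `docking_map`: list with binary `values`
#'   (L x L) and `n_poses`.
#' @export
docking_map <- function(m, interval = 6.0, top_t = 100, cutoff = 8.0,
                        spacing = 1.2, surface_thickness = 1.5,
                        core_penalty = 15, rotations = NULL) {
  stopifnot(inherits(m, "monomer_structure"))
  if (is.null(rotations)) rotations <- sample_rotations(interval)
  axes <- attr(rotations, "axes")
  rc <- res_coords(m)
  coords <- rc$coords
  cen <- colMeans(coords)
  rad <- sqrt(max(rowSums(sweep(coords, 2, cen)^2)))
  margin <- 1.8 + surface_thickness + spacing
  # tight box for the fixed copy; rotation-independent bound for the moving
  # copy so the FFT of the fixed grid can be cached across rotations
  ga <- grid_project(coords, spacing, surface_thickness)
  side_b <- as.integer(ceiling((2 * rad + 2 * margin) / spacing)) + 1L
  common <- vapply(1:3, function(k) {
    stats::nextn(ga$dims[k] + side_b, c(2, 3, 5))
  }, integer(1))
  FA <- fft(pad_array(grid_complex(ga, core_penalty), common))

  L <- m$L
  union_vals <- matrix(FALSE, L, L)
  n_poses <- 0L
  for (k in seq_along(rotations)) {
    R <- rotations[[k]]
    # two-fold axis of R = 2uu' - I, recovered from the matrix itself when
    # the sampling metadata is absent (e.g. a subsetted rotation list)
    u <- if (!is.null(axes)) {
      axes[k, ]
    } else {
      P <- (R + diag(3)) / 2
      v <- P[, which.max(diag(P))]
      v / sqrt(sum(v^2))
    }
    cb <- coords %*% t(R)
    gb <- grid_project(cb, spacing, surface_thickness)
    top <- scan_core(FA, gb, common, top_t, core_penalty, ga$origin)
    tmat <- as.matrix(top[, c("tx", "ty", "tz")])
    # exact C2: remove the translation component along the rotation axis
    proj <- tmat %*% u
    tmat <- tmat - proj %*% t(u)
    hits <- cpp_union_pose_contacts(coords, rc$res, cb, rc$res, L,
                                    tmat, cutoff)
    union_vals <- union_vals | hits
    n_poses <- n_poses + nrow(tmat)
  }
  union_vals <- union_vals | t(union_vals)
  structure(list(values = union_vals + 0L, n_poses = n_poses),
            class = "docking_map")
}
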