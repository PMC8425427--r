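# The residual contact network: a 1D ResNet-v2 stack over sequential
# features, outer concatenation to pairwise planes, a 2D ResNet-v2 stack over
# the pairwise channels, and a sigmoid output head. Forward and backward
# passes are implemented directly on matrices (im2col + BLAS); feature maps
# live as (L or L^2) x channels matrices.

#' Network architecture configuration
#'
#' `preset = "full"` is the production-scale architecture: six 1D ResNet-v2
#' blocks with filters 35, 40, 45, 50, 55, 60 and kernel size 17, a 1 x 1
#' compression to two channels, and thirty-six 2D ResNet-v2 blocks in nine
#' filter groups (32, 32, 48, 64, 64, 64, 48, 32, 32) with 3 x 3 kernels,
#' ELU activations and zero padding throughout. `preset = "tiny"` is a
#' desk-scale variant (two 1D and four 2D blocks) used for tests and small
#' training runs.
#'
#' @param preset `"full"` or `"tiny"`.
#' @param filters_1d,filters_2d Optional filter count overrides.
#' @param kernel_1d,kernel_2d Optional kernel size overrides.
#' @return A `network_config` list.
#' @export
network_config <- function(preset = c("full", "tiny"), filters_1d = NULL,
                           filters_2d = NULL, kernel_1d = NULL,
                           kernel_2d = NULL) {
  preset <- match.arg(preset)
  cfg <- if (preset == "full") {
    list(filters_1d = c(35, 40, 45, 50, 55, 60),
         filters_2d = rep(c(32, 32, 48, 64, 64, 64, 48, 32, 32), each = 4),
         kernel_1d = 17L, kernel_2d = 3L)
  } else {
    list(filters_1d = c(16, 16),
         filters_2d = c(16, 16, 16, 16),
         kernel_1d = 17L, kernel_2d = 3L)
  }
  if (!is.null(filters_1d)) cfg$filters_1d <- filters_1d
  if (!is.null(filters_2d)) cfg$filters_2d <- filters_2d
  if (!is.null(kernel_1d)) cfg$kernel_1d <- as.integer(kernel_1d)
  if (!is.null(kernel_2d)) cfg$kernel_2d <- as.integer(kernel_2d)
  cfg$in_1d <- 31L
  cfg$in_2d <- 4L
  cfg$compress_filters <- 2L
  cfg$preset <- preset
  stopifnot(all(cfg$filters_1d > 0), all(cfg$filters_2d > 0),
            cfg$kernel_1d %% 2L == 1L, cfg$kernel_2d %% 2L == 1L)
  class(cfg) <- "network_config"
  cfg
}

# ---- parameter construction -------------------------------------------------

he_init <- function(nin, nout) {
  matrix(rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
}

init_block <- function(cin, cout, k) {
  p <- list(
    bn1_gamma = rep(1, cin), bn1_beta = rep(0, cin),
    conv1_W = he_init(k * cin, cout), conv1_b = rep(0, cout),
    bn2_gamma = rep(1, cout), bn2_beta = rep(0, cout),
    conv2_W = he_init(k * cout, cout), conv2_b = rep(0, cout)
  )
  if (cin != cout) {
    p$proj_W <- he_init(cin, cout)
    p$proj_b <- rep(0, cout)
  }
  p
}

#' Initialise network parameters
#'
#' Fan-in scaled Gaussian initialisation for convolution weights, unit/zero
#' batch-norm parameters, and fresh running statistics.
#'
#' @param cfg A `network_config`.
#' @param seed Integer seed for reproducible initialisation.
#' @return List with `params` (named nested list) and `state` (batch-norm
#'   running means/variances).
#' @export
init_network <- function(cfg, seed = 1L) {
  set.seed(seed)
  params <- list(blocks_1d = list(), blocks_2d = list())
  cin <- cfg$in_1d
  for (b in seq_along(cfg$filters_1d)) {
    cout <- cfg$filters_1d[b]
    params$blocks_1d[[b]] <- init_block(cin, cout, cfg$kernel_1d)
    cin <- cout
  }
  params$compress_W <- he_init(cin, cfg$compress_filters)
  params$compress_b <- rep(0, cfg$compress_filters)
  cin2 <- 2L * cfg$compress_filters + cfg$in_2d
  for (b in seq_along(cfg$filters_2d)) {
    cout <- cfg$filters_2d[b]
    params$blocks_2d[[b]] <- init_block(cin2, cout, cfg$kernel_2d^2)
    cin2 <- cout
  }
  params$out_bn_gamma <- rep(1, cin2)
  params$out_bn_beta <- rep(0, cin2)
  params$out_W <- he_init(cin2, 1L)
  params$out_b <- 0
  state <- make_bn_state(params)
  list(params = params, state = state)
}

make_bn_state <- function(params) {
  st <- list(blocks_1d = list(), blocks_2d = list())
  for (side in c("blocks_1d", "blocks_2d")) {
    for (b in seq_along(params[[side]])) {
      p <- params[[side]][[b]]
      st[[side]][[b]] <- list(
        bn1_mean = rep(0, length(p$bn1_gamma)),
        bn1_var = rep(1, length(p$bn1_gamma)),
        bn2_mean = rep(0, length(p$bn2_gamma)),
        bn2_var = rep(1, length(p$bn2_gamma))
      )
    }
  }
  st$out_mean <- rep(0, length(params$out_bn_gamma))
  st$out_var <- rep(1, length(params$out_bn_gamma))
  st
}

#' Total number of trainable parameters
#'
#' @param params Parameter list from [init_network()].
#' @return Integer parameter count.
#' @export
count_parameters <- function(params) {
  n <- 0L
  walk <- function(x) {
    if (is.list(x)) {
      for (el in x) walk(el)
    } else {
      n <<- n + length(x)
    }
  }
  walk(params)
  n
}

# ---- layer primitives -------------------------------------------------------

neighbor_index_1d <- function(L, k) {
  half <- (k - 1L) %/% 2L
  out <- matrix(L + 1L, L, k)
  for (o in seq_len(k)) {
    src <- seq_len(L) + (o - half - 1L)
    ok <- src >= 1L & src <= L
    out[ok, o] <- src[ok]
  }
  out
}

neighbor_index_2d <- function(L, k) {
  half <- (k - 1L) %/% 2L
  n <- L * L
  out <- matrix(n + 1L, n, k * k)
  i <- rep(seq_len(L), times = L)
  j <- rep(seq_len(L), each = L)
  o <- 0L
  for (dj in -half:half) {
    for (di in -half:half) {
      o <- o + 1L
      ni <- i + di; nj <- j + dj
      ok <- ni >= 1L & ni <= L & nj >= 1L & nj <= L
      out[ok, o] <- ni[ok] + (nj[ok] - 1L) * L
    }
  }
  out
}

im2col <- function(X, nidx) {
  k <- ncol(nidx)
  Xp <- rbind(X, 0)
  out <- matrix(0, nrow(nidx), k * ncol(X))
  C <- ncol(X)
  for (o in seq_len(k)) {
    out[, ((o - 1L) * C + 1L):(o * C)] <- Xp[nidx[, o], , drop = FALSE]
  }
  out
}

conv_fwd <- function(X, W, b, nidx) {
  patches <- im2col(X, nidx)
  out <- patches %*% W
  out <- sweep(out, 2, b, "+")
  list(out = out)
}

conv_bwd <- function(dY, X, W, nidx) {
  patches <- im2col(X, nidx)
  dW <- crossprod(patches, dY)
  db <- colSums(dY)
  dpatch <- dY %*% t(W)
  C <- ncol(X)
  k <- ncol(nidx)
  n <- nrow(X)
  dX <- matrix(0, n, C)
  for (o in seq_len(k)) {
    idx <- nidx[, o]
    ok <- idx <= n
    block <- dpatch[ok, ((o - 1L) * C + 1L):(o * C), drop = FALSE]
    dX[idx[ok], ] <- dX[idx[ok], , drop = FALSE] + block
  }
  list(dX = dX, dW = dW, db = db)
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

bn_fwd <- function(X, gamma, beta, rmean, rvar, train) {
  if (train) {
    mu <- colMeans(X)
    va <- colMeans(X * X) - mu^2
    new_mean <- BN_MOMENTUM * rmean + (1 - BN_MOMENTUM) * mu
    new_var <- BN_MOMENTUM * rvar + (1 - BN_MOMENTUM) * va
  } else {
    mu <- rmean; va <- rvar
    new_mean <- rmean; new_var <- rvar
  }
  inv_std <- 1 / sqrt(va + BN_EPS)
  xh <- sweep(sweep(X, 2, mu), 2, inv_std, "*")
  out <- sweep(sweep(xh, 2, gamma, "*"), 2, beta, "+")
  list(out = out, xh = xh, inv_std = inv_std,
       new_mean = new_mean, new_var = new_var)
}

bn_bwd <- function(dY, cache, gamma) {
  n <- nrow(dY)
  dgamma <- colSums(dY * cache$xh)
  dbeta <- colSums(dY)
  dxh <- sweep(dY, 2, gamma, "*")
  term <- sweep(dxh, 2, colMeans(dxh)) -
    sweep(cache$xh, 2, colMeans(dxh * cache$xh), "*")
  dX <- sweep(term, 2, cache$inv_std, "*")
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

elu_fwd <- function(X) {
  out <- X
  neg <- X < 0
  out[neg] <- exp(X[neg]) - 1
  out
}

elu_bwd <- function(dY, out) {
  d <- matrix(1, nrow(out), ncol(out))
  neg <- out < 0
  d[neg] <- out[neg] + 1
  dY * d
}

# ---- residual blocks --------------------------------------------------------

block_fwd <- function(X, p, st, nidx, train) {
  b1 <- bn_fwd(X, p$bn1_gamma, p$bn1_beta, st$bn1_mean, st$bn1_var, train)
  r1 <- elu_fwd(b1$out)
  c1 <- conv_fwd(r1, p$conv1_W, p$conv1_b, nidx)$out
  b2 <- bn_fwd(c1, p$bn2_gamma, p$bn2_beta, st$bn2_mean, st$bn2_var, train)
  r2 <- elu_fwd(b2$out)
  c2 <- conv_fwd(r2, p$conv2_W, p$conv2_b, nidx)$out
  sc <- if (!is.null(p$proj_W)) {
    sweep(X %*% p$proj_W, 2, p$proj_b, "+")
  } else {
    X
  }
  new_st <- list(bn1_mean = b1$new_mean, bn1_var = b1$new_var,
                 bn2_mean = b2$new_mean, bn2_var = b2$new_var)
  list(out = sc + c2,
       cache = list(X = X, b1 = b1, r1 = r1, c1 = c1, b2 = b2, r2 = r2),
       new_state = new_st)
}

block_bwd <- function(dOut, p, cache, nidx) {
  g <- list()
  cb2 <- conv_bwd(dOut, cache$r2, p$conv2_W, nidx)
  g$conv2_W <- cb2$dW; g$conv2_b <- cb2$db
  da2 <- elu_bwd(cb2$dX, cache$r2)
  bb2 <- bn_bwd(da2, cache$b2, p$bn2_gamma)
  g$bn2_gamma <- bb2$dgamma; g$bn2_beta <- bb2$dbeta
  cb1 <- conv_bwd(bb2$dX, cache$r1, p$conv1_W, nidx)
  g$conv1_W <- cb1$dW; g$conv1_b <- cb1$db
  da1 <- elu_bwd(cb1$dX, cache$r1)
  bb1 <- bn_bwd(da1, cache$b1, p$bn1_gamma)
  g$bn1_gamma <- bb1$dgamma; g$bn1_beta <- bb1$dbeta
  dX <- bb1$dX
  if (!is.null(p$proj_W)) {
    g$proj_W <- crossprod(cache$X, dOut)
    g$proj_b <- colSums(dOut)
    dX <- dX + dOut %*% t(p$proj_W)
  } else {
    dX <- dX + dOut
  }
  list(dX = dX, grads = g)
}

# ---- full network -----------------------------------------------------------

transpose_perm <- function(L) as.vector(t(matrix(seq_len(L * L), L, L)))

#' Forward pass of the contact network
#'
#' Runs the 1D stack, compresses to two channels, forms pairwise planes by
#' outer concatenation (`[v_i ; v_j]`, each plane symmetrized by averaging
#' with its transpose), concatenates the four pairwise input channels, runs
#' the 2D stack and the sigmoid output head. The returned probability map is
#' symmetrized by averaging with its transpose. Accepts any sequence length.
#'
#' @param params,state Parameters and batch-norm state from
#'   [init_network()].
#' @param bundle A `feature_bundle`.
#' @param cfg The `network_config` the parameters were built with.
#' @param train Logical; training mode uses batch statistics and returns the
#'   caches needed for the backward pass.
#' @return List with `prob` (L x L symmetric matrix strictly inside (0, 1)),
#'   `prob_raw` (pre-symmetrization), `logits`, and (in training mode)
#'   `cache` and `new_state`.
#' @export
network_forward <- function(params, state, bundle, cfg, train = FALSE) {
  L <- bundle$L
  x1 <- bundle$seq_features
  if (ncol(x1) != cfg$in_1d) stop("seq feature width mismatch")
  nidx1 <- neighbor_index_1d(L, cfg$kernel_1d)
  nidx2 <- neighbor_index_2d(L, cfg$kernel_2d)

  caches_1d <- list()
  new_state <- state
  h <- x1
  for (b in seq_along(params$blocks_1d)) {
    r <- block_fwd(h, params$blocks_1d[[b]], state$blocks_1d[[b]], nidx1,
                   train)
    caches_1d[[b]] <- r$cache
    new_state$blocks_1d[[b]] <- r$new_state
    h <- r$out
  }
  v <- sweep(h %*% params$compress_W, 2, params$compress_b, "+")

  cf <- cfg$compress_filters
  P <- matrix(0, L * L, 2L * cf)
  for (a in seq_len(cf)) {
    P[, a] <- rep(v[, a], times = L)        # v_i plane
    P[, cf + a] <- rep(v[, a], each = L)    # v_j plane
  }
  tp <- transpose_perm(L)
  Psym <- (P + P[tp, , drop = FALSE]) / 2
  pf <- matrix(bundle$pair_features, L * L, cfg$in_2d)
  x2 <- cbind(Psym, pf)

  caches_2d <- list()
  g <- x2
  for (b in seq_along(params$blocks_2d)) {
    r <- block_fwd(g, params$blocks_2d[[b]], state$blocks_2d[[b]], nidx2,
                   train)
    caches_2d[[b]] <- r$cache
    new_state$blocks_2d[[b]] <- r$new_state
    g <- r$out
  }
  ob <- bn_fwd(g, params$out_bn_gamma, params$out_bn_beta, state$out_mean,
               state$out_var, train)
  new_state$out_mean <- ob$new_mean
  new_state$out_var <- ob$new_var
  orr <- elu_fwd(ob$out)
  z <- sweep(orr %*% params$out_W, 2, params$out_b, "+")
  # clamp logits so the sigmoid never saturates to exactly 0 or 1 in
  # double precision (the loss requires strictly interior probabilities)
  p <- 1 / (1 + exp(-pmin(pmax(z, -30), 30)))
  pr <- matrix(p, L, L)
  out <- list(prob = (pr + t(pr)) / 2, prob_raw = pr,
              logits = matrix(z, L, L))
  if (train) {
    out$cache <- list(caches_1d = caches_1d, caches_2d = caches_2d,
                      h = h, v = v, P = P, x2 = x2, ob = ob, orr = orr,
                      p = p, nidx1 = nidx1, nidx2 = nidx2, tp = tp, L = L)
    out$new_state <- new_state
  }
  out
}

# Backward pass from d(loss)/d(logits), flattened L^2 x 1.
network_backward <- function(params, cfg, cache, dz) {
  grads <- list(blocks_1d = vector("list", length(params$blocks_1d)),
                blocks_2d = vector("list", length(params$blocks_2d)))
  grads$out_W <- crossprod(cache$orr, dz)
  grads$out_b <- sum(dz)
  dorr <- dz %*% t(params$out_W)
  dob <- elu_bwd(dorr, cache$orr)
  bb <- bn_bwd(dob, cache$ob, params$out_bn_gamma)
  grads$out_bn_gamma <- bb$dgamma
  grads$out_bn_beta <- bb$dbeta
  dg <- bb$dX
  for (b in rev(seq_along(params$blocks_2d))) {
    r <- block_bwd(dg, params$blocks_2d[[b]], cache$caches_2d[[b]],
                   cache$nidx2)
    grads$blocks_2d[[b]] <- r$grads
    dg <- r$dX
  }
  cf <- cfg$compress_filters
  dPsym <- dg[, seq_len(2L * cf), drop = FALSE]
  dP <- (dPsym + dPsym[cache$tp, , drop = FALSE]) / 2
  L <- cache$L
  dv <- matrix(0, L, cf)
  for (a in seq_len(cf)) {
    dv[, a] <- rowSums(matrix(dP[, a], L, L)) +
      colSums(matrix(dP[, cf + a], L, L))
  }
  grads$compress_W <- crossprod(cache$h, dv)
  grads$compress_b <- colSums(dv)
  dh <- dv %*% t(params$compress_W)
  for (b in rev(seq_along(params$blocks_1d))) {
    r <- block_bwd(dh, params$blocks_1d[[b]], cache$caches_1d[[b]],
                   cache$nidx1)
    grads$blocks_1d[[b]] <- r$grads
    dh <- r$dX
  }
  grads
}
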