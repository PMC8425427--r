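# Desk-scale training: Adam with L2 weight decay on convolution weights and
# a reduce-on-plateau learning-rate schedule.

#' Training hyper-parameter configuration
#'
#' Defaults: mini-batch size 1, Adam at learning
#' rate 1e-3, L2 regularisation 1e-4 on convolution weights, plateau decay
#' by a factor of 0.2 with patience 2 epochs and floor 1e-6, and a random
#' 400-residue crop for long chains.
#'
#' @param learning_rate Initial Adam learning rate.
#' @param l2 L2 regularisation coefficient on convolution weights.
#' @param lr_factor Plateau decay factor.
#' @param lr_patience Epochs without validation improvement before decay.
#' @param min_lr Learning-rate floor.
#' @param max_crop Maximum training length before random cropping.
#' @param epochs Training epochs.
#' @param seed Integer seed.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-3, l2 = 1e-4, lr_factor = 0.2,
                         lr_patience = 2L, min_lr = 1e-6, max_crop = 400L,
                         epochs = 15L, seed = 1L) {
  stopifnot(learning_rate > 0, l2 >= 0, lr_factor > 0, lr_factor < 1,
            lr_patience >= 1, min_lr > 0, max_crop >= 1, epochs >= 1)
  structure(list(learning_rate = learning_rate, l2 = l2,
                 lr_factor = lr_factor, lr_patience = as.integer(lr_patience),
                 min_lr = min_lr, max_crop = as.integer(max_crop),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "train_config")
}

#' Reduce-on-plateau learning-rate scheduler
#'
#' Tracks the validation loss; when it fails to improve for `patience`
#' consecutive epochs the learning rate is multiplied by `factor`, never
#' dropping below `min_lr`.
#'
#' @param lr Initial learning rate.
#' @param factor Multiplicative decay.
#' @param patience Epochs without improvement tolerated.
#' @param min_lr Floor.
#' @return An environment with `$step(val_loss)` returning the updated
#'   learning rate and a `$lr` field.
#' @export
plateau_scheduler <- function(lr = 1e-3, factor = 0.2, patience = 2L,
                              min_lr = 1e-6) {
  env <- new.env(parent = emptyenv())
  env$lr <- lr
  env$best <- Inf
  env$wait <- 0L
  env$step <- function(val_loss) {
    if (val_loss < env$best - 1e-12) {
      env$best <- val_loss
      env$wait <- 0L
    } else {
      env$wait <- env$wait + 1L
      if (env$wait >= patience) {
        env$lr <- max(env$lr * factor, min_lr)
        env$wait <- 0L
      }
    }
    env$lr
  }
  env
}

# order the leaves of `tree` (gradients) like `like` (parameters)
reorder_like <- function(like, tree) {
  if (!is.list(like)) return(tree)
  nm <- names(like)
  if (is.null(nm)) {
    out <- vector("list", length(like))
    for (k in seq_along(like)) out[[k]] <- reorder_like(like[[k]], tree[[k]])
  } else {
    out <- setNames(vector("list", length(nm)), nm)
    for (k in nm) out[[k]] <- reorder_like(like[[k]], tree[[k]])
  }
  out
}

#' Fit the contact network on a set of feature bundles
#'
#' Desk-scale trainer: one target per step (mini-batch size 1), Adam updates
#' with L2 weight decay on convolution weights, random 400-residue crops for
#' long targets, and a reduce-on-plateau learning-rate schedule driven by
#' the validation loss.
#'
#' @param train_set List of targets, each a list with elements `bundle`
#'   (a `feature_bundle`) and `labels` (a `contact_map`).
#' @param val_set Validation targets in the same format (at least one).
#' @param net_cfg A `network_config` (default the tiny preset).
#' @param cfg A `train_config`.
#' @param alpha,gamma Focal loss parameters.
#' @param verbose Print per-epoch losses.
#' @return An object of class `contact_cnn` with elements `params`, `state`,
#'   `net_cfg`, `train_cfg`, `history` (per-epoch data frame), and
#'   `channel_order`.
#' @export
fit_contact_cnn <- function(train_set, val_set, net_cfg = network_config("tiny"),
                            cfg = train_config(), alpha = 0.25, gamma = 1.5,
                            verbose = FALSE) {
  if (length(train_set) == 0L || length(val_set) == 0L) {
    stop("need non-empty training and validation sets")
  }
  net <- init_network(net_cfg, seed = cfg$seed)
  params <- net$params
  state <- net$state

  theta <- unlist(params)
  skeleton <- params
  decay_mask <- grepl("conv1_W|conv2_W|proj_W|compress_W|out_W", names(theta))
  m_adam <- numeric(length(theta))
  v_adam <- numeric(length(theta))
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8
  t_step <- 0L

  sched <- plateau_scheduler(cfg$learning_rate, cfg$lr_factor,
                             cfg$lr_patience, cfg$min_lr)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0), lr = numeric(0))
  set.seed(cfg$seed)

  eval_loss <- function(params, state, targets) {
    tot <- 0
    for (tg in targets) {
      fw <- network_forward(params, state, tg$bundle, net_cfg, train = FALSE)
      tot <- tot + focal_loss(fw$prob_raw, tg$labels$values, tg$bundle$mask,
                              alpha, gamma)
    }
    tot / length(targets)
  }

  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample(length(train_set))
    ep_loss <- 0
    for (ti in ord) {
      tg <- train_set[[ti]]
      cropped <- random_crop(tg$bundle, tg$labels, cfg$max_crop)
      bundle <- cropped$bundle; labels <- cropped$labels
      fw <- network_forward(params, state, bundle, net_cfg, train = TRUE)
      state <- fw$new_state
      loss <- focal_loss(fw$prob_raw, labels$values, bundle$mask,
                         alpha, gamma)
      ep_loss <- ep_loss + loss
      dz <- focal_loss_grad(fw$prob_raw, labels$values, bundle$mask,
                            alpha, gamma)
      grads <- network_backward(params, net_cfg, fw$cache,
                                matrix(as.numeric(dz), ncol = 1))
      gvec <- unlist(reorder_like(skeleton, grads))
      gvec[decay_mask] <- gvec[decay_mask] + cfg$l2 * theta[decay_mask]
      t_step <- t_step + 1L
      m_adam <- beta1 * m_adam + (1 - beta1) * gvec
      v_adam <- beta2 * v_adam + (1 - beta2) * gvec^2
      mhat <- m_adam / (1 - beta1^t_step)
      vhat <- v_adam / (1 - beta2^t_step)
      theta <- theta - sched$lr * mhat / (sqrt(vhat) + adam_eps)
      params <- utils::relist(theta, skeleton)
    }
    val_loss <- eval_loss(params, state, val_set)
    lr_now <- sched$step(val_loss)
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = ep_loss / length(train_set),
      val_loss = val_loss, lr = lr_now))
    if (verbose) {
      message(sprintf("epoch %3d  train %.5f  val %.5f  lr %.2e",
                      epoch, ep_loss / length(train_set), val_loss, lr_now))
    }
  }

  structure(list(params = params, state = state, net_cfg = net_cfg,
                 train_cfg = cfg, history = history,
                 channel_order = c("distance", "docking", "coupling_raw",
                                   "coupling_apc"),
                 alpha = alpha, gamma = gamma),
            class = "contact_cnn")
}

#' @export
print.contact_cnn <- function(x, ...) {
  cat("Contact network (", x$net_cfg$preset, " preset): ",
      length(x$net_cfg$filters_1d), " 1D + ", length(x$net_cfg$filters_2d),
      " 2D residual blocks, ", count_parameters(x$params),
      " parameters\n", sep = "")
  if (nrow(x$history) > 0) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("trained %d epochs; final train loss %.5f, val loss %.5f\n",
                nrow(x$history), last$train_loss, last$val_loss))
  }
  invisible(x)
}

#' @export
summary.contact_cnn <- function(object, ...) {
  print(object)
  cat("focal loss: alpha =", object$alpha, ", gamma =", object$gamma, "\n")
  cat("pairwise channel order:",
      paste(object$channel_order, collapse = ", "), "\n")
  if (nrow(object$history) > 0) {
    cat("learning-rate trajectory:",
        paste(unique(signif(object$history$lr, 3)), collapse = " -> "), "\n")
  }
  invisible(object)
}

#' @export
plot.contact_cnn <- function(x, ...) {
  h <- x$history
  if (nrow(h) == 0) stop("no training history to plot")
  plot(h$epoch, h$train_loss, type = "l", xlab = "epoch", ylab = "focal loss",
       ylim = range(c(h$train_loss, h$val_loss)), ...)
  lines(h$epoch, h$val_loss, lty = 2)
  legend("topright", legend = c("train", "validation"), lty = c(1, 2),
         bty = "n")
  invisible(x)
}

#' Predict a contact probability map from a feature bundle
#'
#' @param object A fitted `contact_cnn`.
#' @param bundle A `feature_bundle`.
#' @param ... Unused.
#' @return A `ranked_contacts` data frame (see [rank_contacts()]); the full
#'   symmetric probability map is attached as `attr(, "prob")`.
#' @export
predict.contact_cnn <- function(object, bundle, ...) {
  stopifnot(inherits(bundle, "feature_bundle"))
  fw <- network_forward(object$params, object$state, bundle, object$net_cfg,
                        train = FALSE)
  rc <- rank_contacts(fw$prob, bundle$mask)
  attr(rc, "prob") <- fw$prob
  rc
}

#' Collapse a symmetric probability map into ranked unique pairs
#'
#' Keeps the unique unordered pairs `i <= j` (for a homodimer interface,
#' `i = j` pairs residue i of chain A with residue i of chain B and is a
#' valid candidate), ranked by probability descending with ties broken by
#' `(i, j)` ascending. Masked pairs are dropped.
#'
#' @param prob Symmetric L x L probability or score matrix.
#' @param mask Optional logical matrix.
#' @return Object of class `ranked_contacts`: data frame with columns `i`,
#'   `j`, `score`; `attr(, "L")` holds the protein length.
#' @export
rank_contacts <- function(prob, mask = NULL) {
  L <- nrow(prob)
  stopifnot(ncol(prob) == L)
  if (is.null(mask)) mask <- matrix(TRUE, L, L)
  idx <- which(upper.tri(prob, diag = TRUE) & mask, arr.ind = TRUE)
  df <- data.frame(i = idx[, 1], j = idx[, 2],
                   score = prob[idx])
  df <- df[order(-df$score, df$i, df$j), ]
  rownames(df) <- NULL
  attr(df, "L") <- L
  class(df) <- c("ranked_contacts", "data.frame")
  df
}

#' Write ranked contacts as TSV
#'
#' Columns `res_i res_j probability` with 1-based residue numbering (author
#' numbering when a monomer is supplied).
#'
#' @param rc A `ranked_contacts`.
#' @param path Output path.
#' @param monomer Optional `monomer_structure` for author numbering.
#' @return The path, invisibly.
#' @export
write_contacts_tsv <- function(rc, path, monomer = NULL) {
  out <- data.frame(
    res_i = if (is.null(monomer)) rc$i else monomer$author[rc$i],
    res_j = if (is.null(monomer)) rc$j else monomer$author[rc$j],
    probability = rc$score
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
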