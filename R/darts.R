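# Bilevel architecture search: alternating architecture (alpha) and weight
# (omega) updates, per-epoch genotype derivation, best-epoch selection.

#' Search hyperparameters
#'
#' Defaults follow the reference setting: batch size 100, 50 epochs, weight
#' learning rate cosine-annealed from 0.0025 to 0.001, SGD momentum 0.9,
#' weight decay 3e-4, cross-entropy loss, and an adaptive-moment (Adam)
#' optimizer with learning rate 3e-4 and decay 1e-3 for the architecture
#' parameters.  `order` selects the first-order approximation of the
#' architecture gradient (default) or the second-order variant that
#' differentiates through one virtual weight step using a finite-difference
#' curvature product.
#'
#' @param batch_size,epochs Integers.
#' @param weight_lr_init,weight_lr_min Cosine schedule endpoints for the
#'   weight optimizer.
#' @param arch_lr Architecture optimizer learning rate (0 freezes alpha).
#' @param weight_decay Weight decay on omega.
#' @param momentum SGD momentum on omega.
#' @param arch_weight_decay Weight decay on alpha.
#' @param arch_optimizer `"adam"` or `"sgd"` for the architecture step.
#' @param order `"first"` or `"second"`.
#' @param seed Integer; drives every source of randomness in the search.
#' @return A `search_config` list.
#' @export
search_config <- function(batch_size = 100L, epochs = 50L,
                          weight_lr_init = 0.0025, weight_lr_min = 0.001,
                          arch_lr = 0.0003, weight_decay = 0.0003,
                          momentum = 0.9, arch_weight_decay = 1e-3,
                          arch_optimizer = c("adam", "sgd"),
                          order = c("first", "second"), seed = 1L) {
  stopifnot(batch_size >= 1L, epochs >= 1L, weight_lr_init > 0,
            weight_lr_min > 0, arch_lr >= 0, weight_decay >= 0,
            momentum >= 0, momentum < 1)
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 weight_lr_init = weight_lr_init,
                 weight_lr_min = weight_lr_min,
                 arch_lr = arch_lr, weight_decay = weight_decay,
                 momentum = momentum, arch_weight_decay = arch_weight_decay,
                 arch_optimizer = match.arg(arch_optimizer),
                 order = match.arg(order), seed = as.integer(seed)),
            class = "search_config")
}

#' Initialize architecture parameters
#'
#' Draws small zero-centered values (scale 1e-3) so the initial mixture on
#' every edge is essentially uniform while symmetric ties are broken.
#'
#' @param num_edges Edges per cell kind (14 for 4 intermediate nodes).
#' @param set_size Number of candidate primitives.
#' @param seed Integer seed.
#' @return `num_edges x set_size` matrix.
#' @export
init_architecture_params <- function(num_edges, set_size, seed = 1L) {
  stopifnot(num_edges >= 1L, set_size >= 1L)
  with_local_seed(seed,
    matrix(stats::rnorm(num_edges * set_size, sd = 1e-3), num_edges, set_size))
}

#' @noRd
cosine_lr <- function(epoch, epochs, lr_init, lr_min) {
  lr_min + 0.5 * (lr_init - lr_min) * (1 + cos(pi * (epoch - 1) / epochs))
}

# mean cross-entropy over a batch; labels are 0/1
#' @noRd
ce_loss <- function(logits, labels) {
  n <- nrow(logits)
  m <- apply(logits, 1L, max)
  z <- exp(logits - m)
  p <- z / rowSums(z)
  idx <- cbind(seq_len(n), labels + 1L)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  g <- p
  g[idx] <- g[idx] - 1
  list(loss = loss, glogits = g / n)
}

# ---- optimizer kernels ------------------------------------------------------

#' @noRd
sgd_update <- function(p, g, v, lr, momentum, wd) {
  v2 <- momentum * v + g + wd * p
  list(p = p - lr * v2, v = v2)
}

#' @noRd
adam_update <- function(p, g, m, v, t, lr, b1 = 0.9, b2 = 0.999,
                        eps = 1e-8, wd = 0) {
  g <- g + wd * p
  m2 <- b1 * m + (1 - b1) * g
  v2 <- b2 * v + (1 - b2) * g * g
  mh <- m2 / (1 - b1^t)
  vh <- v2 / (1 - b2^t)
  list(p = p - lr * mh / (sqrt(vh) + eps), m = m2, v = v2)
}

# ---- search state -----------------------------------------------------------

#' Create a bilevel search state
#'
#' Builds the search-mode mixture network (weights and near-uniform alpha
#' initialized from the current RNG state) together with the optimizer
#' moments.  [run_search()] seeds the RNG from the search config before
#' calling this; seed the RNG yourself (`set.seed()`) for standalone use.
#'
#' @param net_config A [network_config()].
#' @param config A [search_config()].
#' @return A `darts_state` object with fields `model`, `L_train`, `L_val`.
#' @export
search_state <- function(net_config, config) {
  model <- build_network(NULL, net_config, mode = "search")
  vel <- lapply(flat_leaves(model_params_tree(model)), function(p) 0 * p)
  arch <- list(m = lapply(model$alphas, function(a) 0 * a),
               v = lapply(model$alphas, function(a) 0 * a),
               t = 0L)
  structure(list(model = model, vel = vel, arch = arch, config = config,
                 weight_lr = config$weight_lr_init,
                 L_train = NA_real_, L_val = NA_real_),
            class = "darts_state")
}

#' One bilevel optimization step
#'
#' Performs one iteration of the alternating scheme: the architecture
#' parameters are updated by one optimizer step on the validation loss
#' (first-order: gradient at the current weights; second-order: gradient
#' through one virtual weight step), then the network weights are updated by
#' one momentum-SGD step on the training loss.  Both losses are recorded on
#' the returned state.
#'
#' @param state A `darts_state` (from [search_state()]) or a scalar
#'   surrogate state (internal, for testing the update rule).
#' @param train_batch,val_batch Lists with fields `x` (feature array, dim
#'   `(n_d, 4, 1, N)`) and `y` (0/1 labels).
#' @param ... Unused.
#' @return The updated state.
#' @export
bilevel_step <- function(state, train_batch, val_batch, ...) {
  UseMethod("bilevel_step")
}

#' @noRd
arch_apply <- function(state, galphas) {
  cfg <- state$config
  if (cfg$arch_optimizer == "adam") {
    state$arch$t <- state$arch$t + 1L
    for (k in names(state$model$alphas)) {
      u <- adam_update(state$model$alphas[[k]], galphas[[k]],
                       state$arch$m[[k]], state$arch$v[[k]], state$arch$t,
                       lr = cfg$arch_lr, wd = cfg$arch_weight_decay)
      state$model$alphas[[k]] <- u$p
      state$arch$m[[k]] <- u$m
      state$arch$v[[k]] <- u$v
    }
  } else {
    for (k in names(state$model$alphas)) {
      state$model$alphas[[k]] <- state$model$alphas[[k]] -
        cfg$arch_lr * (galphas[[k]] +
                         cfg$arch_weight_decay * state$model$alphas[[k]])
    }
  }
  state
}

#' @noRd
fwd_loss <- function(model, batch) {
  fw <- network_forward(model, batch$x, train = TRUE)
  cl <- ce_loss(fw$logits, batch$y)
  if (!is.finite(cl$loss)) stop("non-finite loss encountered")
  list(loss = cl$loss, glogits = cl$glogits, cache = fw$cache)
}

#' @export
bilevel_step.darts_state <- function(state, train_batch, val_batch, ...) {
  cfg <- state$config
  model <- state$model

  # -- architecture step on L_val
  if (cfg$order == "first") {
    fv <- fwd_loss(model, val_batch)
    bv <- network_backward(model, fv$cache, fv$glogits, need_gw = FALSE)
    galphas <- bv$galphas
    state$L_val <- fv$loss
  } else {
    xi <- state$weight_lr
    ft <- fwd_loss(model, train_batch)
    bt <- network_backward(model, ft$cache, ft$glogits, need_galpha = FALSE)
    gt <- flat_leaves(bt$grads)
    w0 <- flat_leaves(model_params_tree(model))
    wplus <- Map(function(p, g) p - xi * g, w0, gt)
    mplus <- set_model_params(model, wplus)
    fv <- fwd_loss(mplus, val_batch)
    bv <- network_backward(mplus, fv$cache, fv$glogits)
    state$L_val <- fv$loss
    r <- flat_leaves(bv$grads)
    rn <- sqrt(sum(vapply(r, function(g) sum(g^2), 0)))
    galphas <- bv$galphas
    if (rn > 0) {
      eps <- 0.01 / rn
      gal <- lapply(c(1, -1), function(sgn) {
        mp <- set_model_params(model,
                               Map(function(p, g) p + sgn * eps * g, w0, r))
        fp <- fwd_loss(mp, train_batch)
        network_backward(mp, fp$cache, fp$glogits, need_gw = FALSE)$galphas
      })
      for (k in names(galphas)) {
        galphas[[k]] <- galphas[[k]] -
          xi * (gal[[1L]][[k]] - gal[[2L]][[k]]) / (2 * eps)
      }
    }
  }
  state$model <- model
  state <- arch_apply(state, galphas)
  model <- state$model

  # -- weight step on L_train
  ft <- fwd_loss(model, train_batch)
  bt <- network_backward(model, ft$cache, ft$glogits, need_galpha = FALSE)
  state$L_train <- ft$loss
  w <- flat_leaves(model_params_tree(model))
  g <- flat_leaves(bt$grads)
  for (i in seq_along(w)) {
    u <- sgd_update(w[[i]], g[[i]], state$vel[[i]], state$weight_lr,
                    cfg$momentum, cfg$weight_decay)
    w[[i]] <- u$p
    state$vel[[i]] <- u$v
  }
  state$model <- set_model_params(model, w)
  state
}

# Scalar surrogate of the bilevel problem, for validating the update rule
# against hand-derived iterates: supply closed-form gradient functions.
#' @noRd
scalar_bilevel_state <- function(omega, alpha, gw_train, ga_train,
                                 gw_val, ga_val, config) {
  structure(list(omega = omega, alpha = alpha,
                 gw_train = gw_train, ga_train = ga_train,
                 gw_val = gw_val, ga_val = ga_val,
                 vel = 0, arch = list(m = 0, v = 0, t = 0L),
                 config = config, weight_lr = config$weight_lr_init),
            class = "scalar_bilevel")
}

#' @export
bilevel_step.scalar_bilevel <- function(state, train_batch = NULL,
                                        val_batch = NULL, ...) {
  cfg <- state$config
  w <- state$omega; a <- state$alpha
  if (cfg$order == "first") {
    ga <- state$ga_val(w, a)
  } else {
    xi <- state$weight_lr
    wp <- w - xi * state$gw_train(w, a)
    r <- state$gw_val(wp, a)
    ga <- state$ga_val(wp, a)
    if (abs(r) > 0) {
      eps <- 0.01 / abs(r)
      ga <- ga - xi * (state$ga_train(w + eps * r, a) -
                         state$ga_train(w - eps * r, a)) / (2 * eps)
    }
  }
  if (cfg$arch_optimizer == "adam") {
    state$arch$t <- state$arch$t + 1L
    u <- adam_update(a, ga, state$arch$m, state$arch$v, state$arch$t,
                     lr = cfg$arch_lr, wd = cfg$arch_weight_decay)
    state$alpha <- u$p; state$arch$m <- u$m; state$arch$v <- u$v
  } else {
    state$alpha <- a - cfg$arch_lr * (ga + cfg$arch_weight_decay * a)
  }
  u <- sgd_update(w, state$gw_train(w, state$alpha), state$vel,
                  state$weight_lr, cfg$momentum, cfg$weight_decay)
  state$omega <- u$p
  state$vel <- u$v
  state
}

# ---- genotype derivation ----------------------------------------------------

#' Discretize architecture parameters into a genotype
#'
#' For each intermediate node, incoming edges are ranked by their strongest
#' non-zero-primitive softmax weight and the top `keep_edges` (default 2)
#' are retained; each kept edge carries its argmax non-zero primitive.  Ties
#' are broken deterministically: lowest primitive index, then lowest
#' predecessor index.  With `per_edge = TRUE` the raw per-edge rule is used
#' instead: every edge is kept with its argmax primitive, zero included.
#'
#' @param alphas List with `normal` and `reduce` matrices (as on a search
#'   model), or one matrix used for both kinds.
#' @param primitives Candidate names matching the alpha columns.
#' @param nodes Intermediate nodes per cell.
#' @param keep_edges Edges kept per node (default 2).
#' @param per_edge Logical; use the keep-every-edge variant.
#' @return A [cell_genotype()].
#' @export
derive_genotype <- function(alphas, primitives = primitive_set(), nodes = 4L,
                            keep_edges = 2L, per_edge = FALSE) {
  if (is.matrix(alphas)) alphas <- list(normal = alphas, reduce = alphas)
  if (any(!is.finite(unlist(alphas)))) stop("alpha contains non-finite values")
  nz <- which(primitives != ZERO_PRIMITIVE)
  if (length(nz) == 0L && !per_edge)
    stop("cannot derive a genotype: all primitives are the zero operation")
  derive_part <- function(A) {
    stopifnot(nrow(A) == n_cell_edges(nodes), ncol(A) == length(primitives))
    off <- 0L
    lapply(seq_len(nodes), function(i) {
      npred <- i + 1L
      rows <- off + seq_len(npred)
      off <<- off + npred
      W <- matrix(0, npred, length(primitives))
      for (j in seq_len(npred)) W[j, ] <- mixed_op_weights(A[rows[j], ])
      if (per_edge) {
        pairs <- lapply(seq_len(npred), function(j)
          list(op = primitives[which.max(W[j, ])], pred = j - 1L))
      } else {
        score <- apply(W[, nz, drop = FALSE], 1L, max)
        best <- nz[max.col(W[, nz, drop = FALSE], ties.method = "first")]
        keep <- order(-score, seq_len(npred))[seq_len(min(keep_edges, npred))]
        keep <- sort(keep)
        pairs <- lapply(keep, function(j)
          list(op = primitives[best[j]], pred = j - 1L))
      }
      pairs
    })
  }
  cell_genotype(derive_part(alphas$normal), derive_part(alphas$reduce),
                nodes = nodes)
}

# ---- the search loop --------------------------------------------------------

#' @noRd
make_batch <- function(X, labels, idx) {
  list(x = X[, , , idx, drop = FALSE], y = labels[idx])
}

#' @noRd
chunk_indices <- function(perm, size) {
  split(perm, ceiling(seq_along(perm) / size))
}

#' @noRd
eval_accuracy <- function(model, X, labels, batch_size) {
  n <- length(labels)
  correct <- 0L
  for (idx in chunk_indices(seq_len(n), batch_size)) {
    lg <- network_forward(model, X[, , , idx, drop = FALSE],
                          train = FALSE)$logits
    correct <- correct + sum(max.col(lg, ties.method = "first") - 1L ==
                               labels[idx])
  }
  correct / n
}

#' Run the architecture search
#'
#' Optimizes the mixture network by alternating bilevel steps over paired
#' train/validation batches for `config$epochs` epochs, annealing the weight
#' learning rate by a cosine schedule from `weight_lr_init` to
#' `weight_lr_min`.  Validation batches are cycled when the validation part
#' is smaller than the training part.  At the end of each epoch the
#' validation accuracy is computed (inference mode) and the epoch's genotype
#' is derived from the current alpha; the result carries the genotype of the
#' best-validation-accuracy epoch (earliest epoch on ties) and the full
#' history.
#'
#' @param data A [split_dataset()] of encoded sequences with non-empty train
#'   and validation parts.
#' @param net_config A [network_config()].
#' @param config A [search_config()].
#' @param verbose Print a line per epoch.
#' @return A `search_result`: list(best_genotype, best_epoch,
#'   best_val_accuracy, history (data.frame epoch/L_train/L_val/
#'   val_accuracy), genotypes, model).
#' @export
run_search <- function(data, net_config, config = search_config(),
                       verbose = FALSE) {
  if (length(data$train) == 0L) stop("empty training part")
  if (length(data$validation) == 0L) stop("empty validation part")
  Xtr <- batch_tensor(data$train); ytr <- attr(Xtr, "labels")
  Xva <- batch_tensor(data$validation); yva <- attr(Xva, "labels")
  with_local_seed(config$seed, {
    state <- search_state(net_config, config)
    nE <- config$epochs
    hist <- data.frame(epoch = seq_len(nE), L_train = NA_real_,
                       L_val = NA_real_, val_accuracy = NA_real_)
    genotypes <- vector("list", nE)
    for (epoch in seq_len(nE)) {
      state$weight_lr <- cosine_lr(epoch, nE, config$weight_lr_init,
                                   config$weight_lr_min)
      tb <- chunk_indices(sample.int(length(ytr)), config$batch_size)
      vb <- chunk_indices(sample.int(length(yva)), config$batch_size)
      lt <- lv <- numeric(length(tb))
      for (t in seq_along(tb)) {
        state <- bilevel_step(state,
                              make_batch(Xtr, ytr, tb[[t]]),
                              make_batch(Xva, yva, vb[[(t - 1L) %% length(vb) + 1L]]))
        lt[t] <- state$L_train
        lv[t] <- state$L_val
      }
      hist$L_train[epoch] <- mean(lt)
      hist$L_val[epoch] <- mean(lv)
      hist$val_accuracy[epoch] <- eval_accuracy(state$model, Xva, yva,
                                                config$batch_size)
      genotypes[[epoch]] <- derive_genotype(state$model$alphas,
                                            net_config$primitives,
                                            nodes = net_config$nodes)
      if (verbose)
        message(sprintf("epoch %3d  lr %.5f  L_train %.4f  L_val %.4f  val_acc %.4f",
                        epoch, state$weight_lr, hist$L_train[epoch],
                        hist$L_val[epoch], hist$val_accuracy[epoch]))
    }
    best <- which.max(hist$val_accuracy)
    structure(list(best_genotype = genotypes[[best]],
                   best_epoch = best,
                   best_val_accuracy = hist$val_accuracy[best],
                   history = hist, genotypes = genotypes,
                   model = state$model),
              class = "search_result")
  })
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf("<search_result> best epoch %d (val accuracy %.4f) of %d\n",
              x$best_epoch, x$best_val_accuracy, nrow(x$history)))
  print(x$best_genotype)
  invisible(x)
}

#' Write a search history table
#'
#' @param result A `search_result`.
#' @param path TSV output path (columns epoch, L_train, L_val,
#'   val_accuracy).
#' @export
write_search_history <- function(result, path) {
  utils::write.table(result$history, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
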