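# Assembling stacked cells into a full classifier network.

#' Network configuration
#'
#' Structural hyperparameters of the cell-stacked classifier.  Reduction
#' cells sit at depths `floor(layers/3)` and `floor(2*layers/3)` (0-based)
#' when `layers >= 3`; shallower networks have no reductions.  The per-node
#' channel count starts at `init_channels` and doubles at every reduction.
#'
#' @param input_length Sequence length n_d.
#' @param layers Number of stacked cells (default 3).
#' @param init_channels Initial per-node channel count (default 16).
#' @param nodes Intermediate nodes per cell (default 4).
#' @param num_classes Output classes (default 2: true/false splice site).
#' @param primitives Candidate operation names used by search-mode networks
#'   (default the full set).
#' @return A `network_config` list.
#' @export
network_config <- function(input_length, layers = 3L, init_channels = 16L,
                           nodes = 4L, num_classes = 2L,
                           primitives = primitive_set()) {
  stopifnot(layers >= 1L, init_channels >= 1L, nodes >= 1L,
            input_length >= 1L, num_classes >= 2L)
  structure(list(input_length = as.integer(input_length),
                 layers = as.integer(layers),
                 init_channels = as.integer(init_channels),
                 nodes = as.integer(nodes),
                 num_classes = as.integer(num_classes),
                 primitives = primitives),
            class = "network_config")
}

#' @noRd
reduction_positions <- function(layers) {
  if (layers < 3L) return(integer(0))
  unique(c(layers %/% 3L, (2L * layers) %/% 3L))   # 0-based cell indices
}

#' Build the classifier network
#'
#' Assembles stem, stacked cells and classifier head.  The stem is one 3x3
#' same-padded convolution (with batch norm) from the single input channel
#' to `init_channels`.  Cell k receives the outputs of cells k-2 and k-1
#' (the stem standing in for both below depth 2).  Reduction cells halve
#' height and width and double the per-node channels.  The head applies
#' global average pooling over the spatial dimensions and one linear map to
#' the class logits.
#'
#' In `mode = "search"` the genotype is ignored: every possible edge of
#' every cell carries a softmax mixture over the candidate primitives, and
#' the two architecture matrices (one shared by all normal cells, one by all
#' reduction cells) live in `model$alphas`.
#'
#' @param genotype A [cell_genotype()] (`fixed` mode) or NULL (`search`).
#' @param config A [network_config()].
#' @param mode `"fixed"` or `"search"`.
#' @return A `splice_network` model object.
#' @export
build_network <- function(genotype, config, mode = c("fixed", "search")) {
  mode <- match.arg(mode)
  if (mode == "fixed" && !inherits(genotype, "cell_genotype"))
    stop("fixed mode requires a cell_genotype")
  nodes <- if (mode == "fixed") genotype$nodes else config$nodes
  C0 <- config$init_channels
  stem <- op_seq(op_conv(1L, C0, 3L, 3L), op_bn(C0))
  red_at <- reduction_positions(config$layers)

  # static shape plan: (channels, H, W) of each state
  shp <- list(c(C0, config$input_length, 4L))   # stem output
  prev_prev <- shp[[1L]]; prev <- shp[[1L]]
  cells <- vector("list", config$layers)
  C <- C0
  n_concat <- if (mode == "fixed") length(genotype$concat) else nodes
  for (k in seq_len(config$layers)) {
    reduction <- (k - 1L) %in% red_at
    if (reduction) C <- 2L * C
    stride_in0 <- if (!identical(prev_prev[2:3], prev[2:3])) 2L else 1L
    cells[[k]] <- build_cell(genotype,
                             kind = if (reduction) "reduction" else "normal",
                             channels = C, c_in0 = prev_prev[1L],
                             c_in1 = prev[1L], stride_in0 = stride_in0,
                             mode = mode, primitives = config$primitives)
    out_hw <- if (reduction) ceiling(prev[2:3] / 2) else prev[2:3]
    if (any(out_hw < 1L))
      stop("spatial dimension vanished at layer ", k,
           " for input_length ", config$input_length)
    prev_prev <- prev
    prev <- c(n_concat * C, out_hw)
  }

  feat <- prev[1L]
  bound <- 1 / sqrt(feat)
  head <- list(params = list(
    w = matrix(stats::runif(config$num_classes * feat, -bound, bound),
               config$num_classes, feat),
    b = stats::runif(config$num_classes, -bound, bound)))

  alphas <- NULL
  if (mode == "search") {
    ne <- n_cell_edges(nodes)
    np <- length(config$primitives)
    alphas <- list(
      normal = matrix(stats::rnorm(ne * np, sd = 1e-3), ne, np),
      reduce = matrix(stats::rnorm(ne * np, sd = 1e-3), ne, np))
  }
  structure(list(mode = mode, config = config, genotype = genotype,
                 stem = stem, cells = cells, head = head, alphas = alphas,
                 feat = feat, reductions = red_at),
            class = "splice_network")
}

#' @export
print.splice_network <- function(x, ...) {
  pc <- count_parameters(x)
  cat(sprintf(paste0("<splice_network> mode=%s layers=%d init_channels=%d ",
                     "input_length=%d\n  reduction cells at {%s}; %d weight",
                     " parameters%s\n"),
              x$mode, x$config$layers, x$config$init_channels,
              x$config$input_length,
              paste(x$reductions, collapse = ","), pc$omega,
              if (x$mode == "search")
                sprintf("; %d architecture parameters", pc$alpha) else ""))
  invisible(x)
}

#' @noRd
cell_alpha <- function(model, cell) {
  if (cell$mode != "search") return(NULL)
  if (cell$kind == "reduction") model$alphas$reduce else model$alphas$normal
}

# Forward pass: returns list(logits (N x num_classes), cache).
#' @noRd
network_forward <- function(model, x, train = TRUE) {
  rs <- op_forward(model$stem, x, train)
  s0 <- rs$y; s1 <- rs$y
  L <- length(model$cells)
  cell_caches <- vector("list", L)
  for (k in seq_len(L)) {
    cl <- model$cells[[k]]
    r <- cell_forward(cl, s0, s1, alpha = cell_alpha(model, cl), train)
    cell_caches[[k]] <- r$cache
    s0 <- s1; s1 <- r$y
  }
  d <- dim(s1)
  hw <- d[1L] * d[2L]
  feat <- t(matrix(colMeans(matrix(s1, nrow = hw)), d[3L], d[4L]))  # N x C
  logits <- feat %*% t(model$head$params$w) +
    matrix(model$head$params$b, nrow = d[4L], ncol = length(model$head$params$b),
           byrow = TRUE)
  list(logits = logits,
       cache = list(stem = rs$cache, cells = cell_caches, feat = feat,
                    out_dim = d))
}

# Backward pass from d(loss)/d(logits).  Returns the parameter-gradient
# tree (stem/cells/head) and the alpha gradients (search mode).
#' @noRd
network_backward <- function(model, cache, glogits, need_gw = TRUE,
                             need_galpha = TRUE) {
  W <- model$head$params$w
  feat <- cache$feat
  gw <- t(glogits) %*% feat
  gb <- colSums(glogits)
  gfeat <- glogits %*% W                    # N x C
  d <- cache$out_dim
  hw <- d[1L] * d[2L]
  gmap <- array(rep(as.numeric(t(gfeat)), each = hw) / hw, d)

  L <- length(model$cells)
  gacc <- vector("list", L + 1L)            # [[1]] = stem, [[k+1]] = cell k
  add_g <- function(slot, g) {
    gacc[[slot]] <<- if (is.null(gacc[[slot]])) g else gacc[[slot]] + g
  }
  add_g(L + 1L, gmap)
  need_galpha <- need_galpha && model$mode == "search"
  galphas <- if (need_galpha)
    list(normal = 0 * model$alphas$normal, reduce = 0 * model$alphas$reduce)
    else NULL
  cell_grads <- vector("list", L)
  for (k in rev(seq_len(L))) {
    cl <- model$cells[[k]]
    br <- cell_backward(cl, cache$cells[[k]], gacc[[k + 1L]], need_gw,
                        need_galpha)
    cell_grads[[k]] <- br$grads
    add_g(max(k - 2L, 0L) + 1L, br$gs0)     # input k-2 (stem below depth 2)
    add_g(max(k - 1L, 0L) + 1L, br$gs1)     # input k-1
    if (need_galpha) {
      kind <- if (cl$kind == "reduction") "reduce" else "normal"
      galphas[[kind]] <- galphas[[kind]] + br$galpha
    }
  }
  bs <- op_backward(model$stem, cache$stem, gacc[[1L]], need_gw)
  list(grads = list(stem = bs$grads, cells = cell_grads,
                    head = list(w = gw, b = gb)),
       galphas = galphas)
}

#' @noRd
model_params_tree <- function(model) {
  list(stem = params_tree(model$stem),
       cells = lapply(model$cells, cell_params_tree),
       head = model$head$params)
}

#' @noRd
map_model_params <- function(model, fun) {
  model$stem <- map_op_params(model$stem, fun)
  model$cells <- lapply(model$cells, function(cl) {
    cl$pre0 <- map_op_params(cl$pre0, fun)
    cl$pre1 <- map_op_params(cl$pre1, fun)
    cl$inner <- map_op_params(cl$inner, fun)
    cl
  })
  model$head$params <- lapply(model$head$params, fun)
  model
}

# Replace all weights with the flat list `leaves` (same order as
# flat_leaves(model_params_tree(model))).
#' @noRd
set_model_params <- function(model, leaves) {
  i <- 0L
  map_model_params(model, function(p) {
    i <<- i + 1L
    stopifnot(length(leaves[[i]]) == length(p))
    q <- leaves[[i]]
    if (!is.null(dim(p))) dim(q) <- dim(p)
    q
  })
}

#' Clone a network
#'
#' Deep-copies a model, including the mutable batch-norm running statistics
#' (which are otherwise shared between copies by reference).
#'
#' @param model A `splice_network`.
#' @return An independent copy.
#' @export
clone_network <- function(model) {
  model$stem <- clone_op(model$stem)
  model$cells <- lapply(model$cells, function(cl) {
    cl$pre0 <- clone_op(cl$pre0)
    cl$pre1 <- clone_op(cl$pre1)
    cl$inner <- clone_op(cl$inner)
    cl
  })
  model
}

#' Count trainable parameters
#'
#' Totals the trainable scalar weights of stem, cells and head; for a
#' search-mode model the architecture parameters alpha are counted
#' separately (they are not network weights).
#'
#' @param model A `splice_network`.
#' @return List with `omega` (weight count), `alpha` (architecture
#'   parameter count, 0 for fixed networks), `total`, and `by_component`.
#' @export
count_parameters <- function(model) {
  comp <- c(stem = n_params(model$stem),
            cells = sum(vapply(model$cells, function(cl)
              n_params(list(cl$pre0, cl$pre1, cl$inner)), 0L)),
            head = sum(vapply(model$head$params, length, 0L)))
  alpha <- if (is.null(model$alphas)) 0L
           else sum(vapply(model$alphas, length, 0L))
  list(omega = as.integer(sum(comp)), alpha = as.integer(alpha),
       total = as.integer(sum(comp) + alpha), by_component = comp)
}

#' Class probabilities for encoded sequences
#'
#' Runs the network in inference mode (batch-norm running statistics) and
#' returns softmax class probabilities.
#'
#' @param object A trained `splice_network`.
#' @param encs List of encoded sequences, or a ready (n_d, 4, 1, N) batch
#'   array.
#' @param batch_size Mini-batch size used during inference.
#' @param ... Unused.
#' @return Matrix (N x num_classes) of probabilities; column 2 is the
#'   true-splice-site score.
#' @export
predict.splice_network <- function(object, encs, batch_size = 100L, ...) {
  x <- if (is.array(encs) && length(dim(encs)) == 4L) encs else batch_tensor(encs)
  n <- dim(x)[4L]
  probs <- matrix(NA_real_, n, object$config$num_classes)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    xb <- x[, , , idx, drop = FALSE]
    lg <- network_forward(object, xb, train = FALSE)$logits
    e <- exp(lg - apply(lg, 1L, max))
    probs[idx, ] <- e / rowSums(e)
  }
  probs
}
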