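# Minimal explicit-gradient layer framework.
#
# Feature maps are dense arrays with dim (H, W, C, N); batches of encoded DNA
# sequences enter the network as (n_d, 4, 1, batch).  Every op is a plain list
# with a `kind` field, trainable arrays under `$params`, and (for batch norm)
# a mutable `$stats` environment holding running moments.  `op_forward()`
# returns list(y, cache); `op_backward()` returns list(gx, grads) where
# `grads` mirrors the structure of `$params` (NULL when the op has none, or
# when weight gradients were not requested).  The heavy arithmetic lives in
# src/ops.cpp (im2col + BLAS convolutions, single-pass batch norm / ReLU).

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

#' @noRd
op_conv <- function(c_in, c_out, kh, kw, stride = c(1L, 1L),
                    dilation = c(1L, 1L), groups = 1L) {
  stopifnot(c_in %% groups == 0, c_out %% groups == 0)
  fan_in <- (c_in / groups) * kh * kw
  w <- array(stats::rnorm(kh * kw * (c_in / groups) * c_out,
                          sd = sqrt(2 / fan_in)),
             dim = c(kh, kw, c_in / groups, c_out))
  list(kind = "conv", params = list(w = w),
       stride = as.integer(rep_len(stride, 2L)),
       dilation = as.integer(rep_len(dilation, 2L)),
       groups = as.integer(groups), c_in = c_in, c_out = c_out)
}

#' @noRd
op_bn <- function(c) {
  stats <- new.env(parent = emptyenv())
  stats$mean <- numeric(c)
  stats$var <- rep(1, c)
  list(kind = "bn", params = list(gamma = rep(1, c), beta = numeric(c)),
       c = c, stats = stats)
}

#' @noRd
op_relu <- function() list(kind = "relu", params = NULL)

#' @noRd
op_pool <- function(kind = c("maxpool", "avgpool"), k = 3L, stride = c(1L, 1L)) {
  kind <- match.arg(kind)
  list(kind = kind, params = NULL, k = as.integer(k),
       stride = as.integer(rep_len(stride, 2L)))
}

#' @noRd
op_zero <- function(stride = c(1L, 1L)) {
  list(kind = "zero", params = NULL, stride = as.integer(rep_len(stride, 2L)))
}

#' @noRd
op_identity <- function() list(kind = "identity", params = NULL)

#' @noRd
op_seq <- function(...) {
  ops <- list(...)
  if (length(ops) == 1L && is.null(ops[[1L]]$kind)) ops <- ops[[1L]]
  list(kind = "seq", params = NULL, ops = ops)
}

#' @noRd
op_forward <- function(op, x, train = TRUE) {
  switch(op$kind,
    conv = {
      y <- .conv2d_fwd(x, dim(x), op$params$w, dim(op$params$w),
                       op$stride[1L], op$stride[2L],
                       op$dilation[1L], op$dilation[2L], op$groups)
      list(y = y, cache = x)
    },
    bn = {
      st <- op$stats
      r <- .bn_fwd(x, dim(x), op$params$gamma, op$params$beta,
                   st$mean, st$var, train, BN_EPS)
      if (train) {
        st$mean <- (1 - BN_MOMENTUM) * st$mean + BN_MOMENTUM * r$mean
        st$var <- (1 - BN_MOMENTUM) * st$var + BN_MOMENTUM * r$var
      }
      list(y = r$y, cache = list(x = x, mean = r$mean, var = r$var,
                                 train = train))
    },
    relu = {
      y <- .relu_fwd(x)
      list(y = y, cache = y)
    },
    maxpool = {
      y <- .maxpool_fwd(x, dim(x), op$k, op$stride[1L], op$stride[2L])
      list(y = y, cache = list(x = x, y = y))
    },
    avgpool = {
      y <- .avgpool_fwd(x, dim(x), op$k, op$stride[1L], op$stride[2L])
      list(y = y, cache = dim(x))
    },
    zero = {
      d <- dim(x)
      od <- c(ceiling(d[1L] / op$stride[1L]), ceiling(d[2L] / op$stride[2L]),
              d[3L], d[4L])
      list(y = array(0, od), cache = d)
    },
    identity = list(y = x, cache = NULL),
    seq = {
      caches <- vector("list", length(op$ops))
      for (i in seq_along(op$ops)) {
        r <- op_forward(op$ops[[i]], x, train)
        x <- r$y
        caches[[i]] <- r$cache
      }
      list(y = x, cache = caches)
    },
    stop("unknown op kind: ", op$kind)
  )
}

#' @noRd
# `gscale` multiplies the incoming gradient; it is folded into the batch-norm
# backward (the last stage of every non-zero primitive), so the softmax
# mixture weights can be applied without materializing scaled copies of gy.
#' @noRd
op_backward <- function(op, cache, gy, need_gw = TRUE, gscale = 1) {
  if (gscale != 1 && !op$kind %in% c("bn", "seq", "zero"))
    gy <- .scale_arr(gy, gscale)
  switch(op$kind,
    conv = {
      r <- .conv2d_bwd(cache, dim(cache), op$params$w, dim(op$params$w), gy,
                       op$stride[1L], op$stride[2L],
                       op$dilation[1L], op$dilation[2L], op$groups, need_gw)
      list(gx = r$gx, grads = if (need_gw) list(w = r$gw) else NULL)
    },
    bn = {
      cc <- cache
      r <- .bn_bwd(cc$x, dim(cc$x), gy, op$params$gamma, cc$mean, cc$var,
                   cc$train, BN_EPS, gscale)
      list(gx = r$gx,
           grads = if (need_gw) list(gamma = r$ggamma, beta = r$gbeta)
                   else NULL)
    },
    relu = list(gx = .relu_bwd(cache, gy), grads = NULL),
    maxpool = {
      gx <- .maxpool_bwd(cache$x, dim(cache$x), cache$y, gy, op$k,
                         op$stride[1L], op$stride[2L])
      list(gx = gx, grads = NULL)
    },
    avgpool = {
      gx <- .avgpool_bwd(gy, cache, op$k, op$stride[1L], op$stride[2L])
      list(gx = gx, grads = NULL)
    },
    zero = list(gx = array(0, cache), grads = NULL),
    identity = list(gx = gy, grads = NULL),
    seq = {
      nops <- length(op$ops)
      grads <- vector("list", nops)
      for (i in rev(seq_len(nops))) {
        r <- op_backward(op$ops[[i]], cache[[i]], gy, need_gw,
                         gscale = if (i == nops) gscale else 1)
        gy <- r$gx
        grads[[i]] <- r$grads
      }
      list(gx = gy, grads = grads)
    },
    stop("unknown op kind: ", op$kind)
  )
}

# ---- parameter tree helpers -------------------------------------------------

# Extract the tree of trainable arrays from an op (or nested list of ops);
# mirrors exactly the `grads` structure returned by op_backward.
#' @noRd
params_tree <- function(x) {
  if (is.list(x) && !is.null(x$kind)) {
    if (x$kind == "seq") lapply(x$ops, params_tree)
    else if (x$kind == "mixed") lapply(x$prims, params_tree)
    else x$params
  } else if (is.list(x)) {
    lapply(x, params_tree)
  } else {
    NULL
  }
}

# Flatten a params/grads tree into an ordered list of numeric arrays.
#' @noRd
flat_leaves <- function(tree) {
  acc <- vector("list", 0L)
  rec <- function(x) {
    if (is.null(x)) return(invisible(NULL))
    if (is.numeric(x)) {
      acc[[length(acc) + 1L]] <<- x
    } else if (is.list(x)) {
      for (e in x) rec(e)
    }
    invisible(NULL)
  }
  rec(tree)
  acc
}

# Replace every trainable array in an op tree, visiting leaves in the same
# order as flat_leaves(params_tree(x)).  `fun` is called with the current
# value and must return the replacement (same shape).
#' @noRd
map_op_params <- function(x, fun) {
  if (is.list(x) && !is.null(x$kind)) {
    if (x$kind == "seq") {
      x$ops <- lapply(x$ops, map_op_params, fun = fun)
    } else if (x$kind == "mixed") {
      x$prims <- lapply(x$prims, map_op_params, fun = fun)
    } else if (!is.null(x$params)) {
      x$params <- lapply(x$params, fun)
    }
    x
  } else if (is.list(x)) {
    lapply(x, map_op_params, fun = fun)
  } else {
    x
  }
}

# Deep-copy the mutable batch-norm statistics environments so that cloned
# models do not share running moments.
#' @noRd
clone_op <- function(x) {
  if (is.list(x) && !is.null(x$kind)) {
    if (x$kind == "seq") {
      x$ops <- lapply(x$ops, clone_op)
    } else if (x$kind == "mixed") {
      x$prims <- lapply(x$prims, clone_op)
    } else if (x$kind == "bn") {
      st <- new.env(parent = emptyenv())
      st$mean <- x$stats$mean
      st$var <- x$stats$var
      x$stats <- st
    }
    x
  } else if (is.list(x)) {
    lapply(x, clone_op)
  } else {
    x
  }
}

#' @noRd
n_params <- function(x) {
  sum(vapply(flat_leaves(params_tree(x)), length, integer(1)), 0L)
}
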