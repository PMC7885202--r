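#' Candidate operation set
#'
#' The eight candidate primitives considered on every edge of a cell:
#' separable convolutions (3x3, 5x5, 7x7), a dilated separable convolution
#' (3x3, dilation 2), a composite 7x1-then-1x7 convolution, max and average
#' pooling over a 3x3 window, and the zero operation which deletes an edge.
#' All convolutional primitives follow the ReLU-Conv-BN order; pooling
#' primitives are followed by batch normalization so that all candidates on a
#' mixed edge output on comparable scales.
#'
#' @return Character vector of the canonical primitive names, in the fixed
#'   index order used by architecture parameter matrices and genotype files.
#' @export
#' @examples
#' primitive_set()
primitive_set <- function() {
  c("sep_conv_3x3", "sep_conv_5x5", "sep_conv_7x7", "dil_conv_3x3",
    "conv_7x1_1x7", "max_pool_3x3", "avg_pool_3x3", "zero")
}

ZERO_PRIMITIVE <- "zero"

#' Instantiate a candidate primitive
#'
#' Builds one feature-map transform from the candidate set.  Convolutional
#' primitives apply rectifier activation, then convolution, then batch
#' normalization (ReLU-Conv-BN); separable convolutions factor into a
#' depthwise stage followed by a pointwise (1x1) stage; `conv_7x1_1x7`
#' applies a 7x1 convolution and then a 1x7 convolution.  All primitives use
#' same-padding, so a stride-1 primitive preserves the spatial shape and a
#' stride-2 primitive maps (H, W) to (ceil(H/2), ceil(W/2)).
#'
#' @param name One of [primitive_set()].
#' @param c_in,c_out Input/output channel counts.  Pooling and zero require
#'   `c_in == c_out`.
#' @param stride 1 or 2, applied to both spatial dimensions.
#' @return An op object usable with the internal forward/backward engine.
#' @export
#' @examples
#' p <- make_primitive("zero", 4, 4, stride = 1)
make_primitive <- function(name, c_in, c_out, stride = 1L) {
  stopifnot(c_in > 0, c_out > 0, stride %in% c(1L, 2L))
  s <- as.integer(stride)
  sep <- function(k) {
    op_seq(op_relu(),
           op_conv(c_in, c_in, k, k, stride = s, groups = c_in),
           op_conv(c_in, c_out, 1L, 1L),
           op_bn(c_out))
  }
  same_c <- function() {
    if (c_in != c_out)
      stop("primitive '", name, "' cannot change the channel count")
  }
  prim <- switch(name,
    sep_conv_3x3 = sep(3L),
    sep_conv_5x5 = sep(5L),
    sep_conv_7x7 = sep(7L),
    dil_conv_3x3 = op_seq(op_relu(),
                          op_conv(c_in, c_in, 3L, 3L, stride = s,
                                  dilation = 2L, groups = c_in),
                          op_conv(c_in, c_out, 1L, 1L),
                          op_bn(c_out)),
    conv_7x1_1x7 = op_seq(op_relu(),
                          op_conv(c_in, c_out, 7L, 1L, stride = c(s, 1L)),
                          op_conv(c_out, c_out, 1L, 7L, stride = c(1L, s)),
                          op_bn(c_out)),
    max_pool_3x3 = { same_c(); op_seq(op_pool("maxpool", 3L, s), op_bn(c_out)) },
    avg_pool_3x3 = { same_c(); op_seq(op_pool("avgpool", 3L, s), op_bn(c_out)) },
    zero = { same_c(); op_zero(s) },
    stop("unknown primitive name: ", name)
  )
  prim$prim_name <- name
  prim
}

#' Softmax mixture weights of a mixed edge
#'
#' Converts the architecture parameter vector alpha of one edge into the
#' probability vector that weights the candidate operations:
#' `w_o = exp(alpha_o) / sum_o' exp(alpha_o')`.  The computation subtracts
#' `max(alpha)` first, so it is invariant to constant shifts and stable for
#' large entries.
#'
#' @param alpha Numeric vector (one entry per candidate operation), or a
#'   mixed-edge object created by [mixed_edge()].
#' @return Probability vector of the same length (sums to 1).
#' @export
#' @examples
#' mixed_op_weights(c(log(2), 0))   # (2/3, 1/3)
mixed_op_weights <- function(alpha) {
  if (is.list(alpha)) alpha <- alpha$alpha
  if (!is.numeric(alpha) || length(alpha) < 1L)
    stop("alpha must be a non-empty numeric vector")
  if (any(!is.finite(alpha))) stop("alpha contains non-finite entries")
  e <- exp(alpha - max(alpha))
  e / sum(e)
}

#' Construct a mixed edge
#'
#' A mixed edge carries one instantiated primitive per element of the
#' candidate set plus the architecture parameter vector `alpha`; applying it
#' computes the softmax-weighted sum of all primitive outputs.
#'
#' @param c_in,c_out Channel counts shared by all primitives.
#' @param stride Shared stride (1 or 2).
#' @param alpha Numeric vector, one entry per primitive (default all zero:
#'   uniform mixture).
#' @param primitives Character vector of primitive names (default the full
#'   candidate set).
#' @return A mixed-edge object.
#' @export
mixed_edge <- function(c_in, c_out, stride = 1L, alpha = NULL,
                       primitives = primitive_set()) {
  if (length(primitives) < 1L) stop("need at least one primitive")
  if (is.null(alpha)) alpha <- numeric(length(primitives))
  if (length(alpha) != length(primitives))
    stop("length(alpha) must equal the number of primitives (",
         length(primitives), ")")
  prims <- lapply(primitives, make_primitive, c_in = c_in, c_out = c_out,
                  stride = stride)
  structure(list(kind = "mixed", params = NULL, alpha = alpha, prims = prims,
                 primitives = primitives),
            class = "mixed_edge")
}

#' Apply a mixed edge to a feature map
#'
#' Computes the continuous relaxation of the discrete operation choice:
#' `sum_o softmax(alpha)_o * o(x)`.  All primitives share one stride, so
#' their outputs have a common shape, which is also the output shape.
#'
#' @param edge A [mixed_edge()] object.
#' @param x Feature map array with dim (H, W, C, N).
#' @param train Logical; use batch statistics (and update running moments)
#'   in the batch-norm stages.
#' @return Feature map array of the common primitive output shape.
#' @export
apply_mixed_op <- function(edge, x, train = TRUE) {
  mixed_forward(edge, x, alpha = edge$alpha, train = train)$y
}

# forward with caches (alpha may be supplied externally, e.g. from the
# network-level shared matrices)
#' @noRd
mixed_forward <- function(edge, x, alpha = edge$alpha, train = TRUE) {
  w <- mixed_op_weights(alpha)
  np <- length(edge$prims)
  outs <- vector("list", np)
  caches <- vector("list", np)
  for (i in seq_len(np)) {
    r <- op_forward(edge$prims[[i]], x, train)
    if (i > 1L && !identical(dim(r$y), dim(outs[[1L]])))
      stop("primitives on a mixed edge produced inconsistent output shapes")
    outs[[i]] <- r$y
    caches[[i]] <- r$cache
  }
  list(y = .wsum(outs, w), cache = list(w = w, outs = outs, caches = caches))
}

# backward through the mixture: returns gx, per-primitive grads, and galpha
#' @noRd
mixed_backward <- function(edge, cache, gy, need_gw = TRUE,
                           need_galpha = TRUE) {
  w <- cache$w
  np <- length(edge$prims)
  grads <- vector("list", np)
  gxs <- vector("list", np)
  for (i in seq_len(np)) {
    r <- op_backward(edge$prims[[i]], cache$caches[[i]], gy, need_gw,
                     gscale = w[i])
    grads[[i]] <- r$grads
    gxs[[i]] <- r$gx
  }
  galpha <- NULL
  if (need_galpha) {
    # softmax Jacobian: dL/dalpha = w * (gw - sum(w * gw))
    gw <- as.numeric(.dots(gy, cache$outs))
    galpha <- w * (gw - sum(w * gw))
  }
  list(gx = .wsum(gxs, rep(1, np)), grads = grads, galpha = galpha)
}
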