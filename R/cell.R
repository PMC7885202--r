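# Cell genotypes and cell construction.
#
# A cell is a DAG over 2 input states (the outputs of cells k-2 and k-1,
# after 1x1 preprocessing) and `nodes` intermediate nodes.  Intermediate
# node i is the elementwise sum of transformed predecessor states; the cell
# output depth-concatenates the intermediate nodes listed in `concat`.
# Predecessor ("state") indices are 0-based: 0 and 1 are the two cell
# inputs, 2 + m is intermediate node m.

#' Construct / validate a cell genotype
#'
#' The discrete architecture of the two cell kinds.  For each intermediate
#' node, `normal` and `reduce` list the chosen (primitive, predecessor)
#' pairs; predecessor indices are 0-based with 0,1 denoting the outputs of
#' cells k-2 and k-1.
#'
#' @param normal,reduce Lists with one entry per intermediate node; each
#'   entry is a list of pairs, a pair being `list(op = <primitive name>,
#'   pred = <state index>)` or an unnamed `list(<name>, <index>)`.
#' @param concat Integer vector of intermediate-node indices (0-based) whose
#'   outputs are concatenated into the cell output (default all nodes).
#' @param nodes Number of intermediate nodes (default 4).
#' @return A `cell_genotype` object.
#' @export
cell_genotype <- function(normal, reduce = normal, concat = NULL, nodes = 4L) {
  nodes <- as.integer(nodes)
  if (is.null(concat)) concat <- seq_len(nodes) - 1L
  canon <- function(part, what) {
    if (length(part) != nodes)
      stop(what, " must list exactly ", nodes, " nodes")
    lapply(seq_along(part), function(i) {
      pairs <- part[[i]]
      if (length(pairs) < 1L)
        stop(what, " node ", i - 1L, " has no incoming edges")
      lapply(pairs, function(p) {
        op <- if (!is.null(p$op)) p$op else p[[1L]]
        pred <- if (!is.null(p$pred)) p$pred else p[[2L]]
        if (!op %in% primitive_set())
          stop("unknown primitive '", op, "' in ", what, " node ", i - 1L)
        pred <- as.integer(pred)
        if (pred < 0L || pred > i)   # states 0..(i+1): i-1 earlier nodes + 2 inputs
          stop("predecessor index ", pred, " out of range for ", what,
               " node ", i - 1L)
        list(op = op, pred = pred)
      })
    })
  }
  concat <- as.integer(concat)
  if (any(concat < 0L | concat >= nodes)) stop("concat indices out of range")
  structure(list(normal = canon(normal, "normal"),
                 reduce = canon(reduce, "reduce"),
                 concat = concat, nodes = nodes),
            class = "cell_genotype")
}

#' @export
print.cell_genotype <- function(x, ...) {
  show <- function(part, nm) {
    cat(nm, ":\n", sep = "")
    for (i in seq_along(part)) {
      cat(sprintf("  node %d: %s\n", i - 1L,
                  paste(vapply(part[[i]], function(p)
                    sprintf("%s(%d)", p$op, p$pred), ""), collapse = " + ")))
    }
  }
  cat("<cell_genotype> ", x$nodes, " nodes, concat = [",
      paste(x$concat, collapse = ","), "]\n", sep = "")
  show(x$normal, "normal")
  show(x$reduce, "reduce")
  invisible(x)
}

#' Write a genotype to JSON
#'
#' Canonical file form: object with keys `normal`, `reduce` (each a list of
#' per-node lists of `[primitive_name, predecessor_index]` pairs), `concat`
#' and `nodes`.
#'
#' @param genotype A [cell_genotype()].
#' @param path Output path.
#' @export
write_genotype <- function(genotype, path) {
  enc <- function(part) lapply(part, function(pairs)
    lapply(pairs, function(p) list(p$op, p$pred)))
  obj <- list(normal = enc(genotype$normal), reduce = enc(genotype$reduce),
              concat = as.list(genotype$concat), nodes = genotype$nodes)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Read a genotype from JSON
#'
#' @param path File written by [write_genotype()].
#' @return A [cell_genotype()].
#' @export
read_genotype <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  dec <- function(part) lapply(part, function(pairs)
    lapply(pairs, function(p) list(op = p[[1L]], pred = p[[2L]])))
  cell_genotype(dec(obj$normal), dec(obj$reduce),
                concat = unlist(obj$concat), nodes = obj$nodes)
}

# number of mixed edges in a search cell with `nodes` intermediate nodes
#' @noRd
n_cell_edges <- function(nodes) sum(seq_len(nodes) + 1L)

#' Sum transformed predecessor feature maps into a node output
#'
#' Computes the defining node operation of the cell DAG: the elementwise sum
#' of the (optionally transformed) predecessor outputs.
#'
#' @param preds List of feature-map arrays of one common shape.
#' @param transforms Optional list of functions, one per predecessor,
#'   applied before summation (default: identity).
#' @return Feature-map array of the common shape.
#' @export
compute_node <- function(preds, transforms = NULL) {
  if (length(preds) < 1L) stop("need at least one predecessor")
  outs <- if (is.null(transforms)) preds
          else Map(function(f, p) f(p), transforms, preds)
  d <- dim(outs[[1L]]) %||% length(outs[[1L]])
  for (o in outs[-1L]) {
    if (!identical(dim(o) %||% length(o), d))
      stop("edge outputs have mismatched shapes")
  }
  Reduce(`+`, outs)
}

# ReLU-Conv(1x1)-BN used to bring cell inputs to the per-node channel count
#' @noRd
preprocess_op <- function(c_in, c_out, stride = 1L) {
  op_seq(op_relu(), op_conv(c_in, c_out, 1L, 1L, stride = stride),
         op_bn(c_out))
}

#' Build one cell
#'
#' Constructs a cell transform over two input feature maps (the outputs of
#' cells k-2 and k-1).  Both inputs are first preprocessed to the per-node
#' channel count by a pointwise ReLU-Conv-BN (with stride 2 on the first
#' input when its spatial shape is twice the second's, i.e. after a
#' reduction cell).  In a reduction cell, edges that consume the cell inputs
#' use stride 2 so height and width halve; edges between intermediate nodes
#' keep stride 1.  The cell output concatenates the `concat` nodes along the
#' channel axis, so it has `length(concat) * channels` channels.
#'
#' @param genotype A [cell_genotype()]; ignored when `mode = "search"`.
#' @param kind `"normal"` or `"reduction"`.
#' @param channels Per-node channel count C.
#' @param c_in0,c_in1 Channel counts of the two input maps.
#' @param stride_in0 Stride for preprocessing input 0 (2 after a reduction).
#' @param mode `"fixed"` (use the genotype) or `"search"` (a mixed edge over
#'   `primitives` on every possible edge).
#' @param primitives Candidate set for search mode.
#' @return A cell object; apply it with the internal `cell_forward()`.
#' @export
build_cell <- function(genotype, kind = c("normal", "reduction"),
                       channels, c_in0, c_in1, stride_in0 = 1L,
                       mode = c("fixed", "search"),
                       primitives = primitive_set()) {
  kind <- match.arg(kind)
  mode <- match.arg(mode)
  reduction <- kind == "reduction"
  nodes <- if (mode == "fixed") genotype$nodes else 4L
  if (mode == "search" && !is.null(genotype)) nodes <- genotype$nodes
  cell <- list(kind = kind, mode = mode, C = channels, nodes = nodes,
               pre0 = preprocess_op(c_in0, channels, stride_in0),
               pre1 = preprocess_op(c_in1, channels))
  edge_stride <- function(pred) if (reduction && pred < 2L) 2L else 1L
  if (mode == "search") {
    edges <- vector("list", n_cell_edges(nodes))
    e <- 0L
    for (i in seq_len(nodes)) {          # node i has i+1 candidate states
      for (j in seq_len(i + 1L)) {
        e <- e + 1L
        edges[[e]] <- mixed_edge(channels, channels,
                                 stride = edge_stride(j - 1L),
                                 primitives = primitives)
      }
    }
    cell$inner <- edges
    cell$concat <- seq_len(nodes) - 1L
  } else {
    part <- if (reduction) genotype$reduce else genotype$normal
    cell$inner <- lapply(seq_along(part), function(i)
      lapply(part[[i]], function(p) {
        prim <- make_primitive(p$op, channels, channels,
                               stride = edge_stride(p$pred))
        prim$pred <- p$pred
        prim
      }))
    cell$concat <- genotype$concat
  }
  cell
}

#' @noRd
concat_channels <- function(maps) {
  d <- dim(maps[[1L]])
  cs <- vapply(maps, function(m) dim(m)[3L], 0)
  y <- array(0, c(d[1L], d[2L], sum(cs), d[4L]))
  off <- 0L
  for (m in maps) {
    cc <- dim(m)[3L]
    y[, , off + seq_len(cc), ] <- m
    off <- off + cc
  }
  y
}

# Forward through one cell.  `alpha` is the (n_edges x |O|) matrix of the
# cell's kind (search mode only).
#' @noRd
cell_forward <- function(cell, s0, s1, alpha = NULL, train = TRUE) {
  r0 <- op_forward(cell$pre0, s0, train)
  r1 <- op_forward(cell$pre1, s1, train)
  states <- list(r0$y, r1$y)
  inner_caches <- vector("list", cell$nodes)
  if (cell$mode == "search") {
    e <- 0L
    for (i in seq_len(cell$nodes)) {
      outs <- vector("list", i + 1L)
      ec <- vector("list", i + 1L)
      for (j in seq_len(i + 1L)) {
        e <- e + 1L
        fr <- mixed_forward(cell$inner[[e]], states[[j]],
                            alpha = alpha[e, ], train = train)
        outs[[j]] <- fr$y
        ec[[j]] <- fr$cache
      }
      states[[i + 2L]] <- .wsum(outs, rep(1, i + 1L))
      inner_caches[[i]] <- ec
    }
  } else {
    for (i in seq_len(cell$nodes)) {
      pairs <- cell$inner[[i]]
      outs <- vector("list", length(pairs))
      ec <- vector("list", length(pairs))
      for (k in seq_along(pairs)) {
        prim <- pairs[[k]]
        fr <- op_forward(prim, states[[prim$pred + 1L]], train)
        outs[[k]] <- fr$y
        ec[[k]] <- fr$cache
      }
      states[[i + 2L]] <- .wsum(outs, rep(1, length(pairs)))
      inner_caches[[i]] <- ec
    }
  }
  y <- concat_channels(states[cell$concat + 3L])
  list(y = y,
       cache = list(pre0 = r0$cache, pre1 = r1$cache, inner = inner_caches,
                    state_dims = lapply(states, dim)))
}

# Backward through one cell.  Returns gradients w.r.t. the two inputs, the
# parameter tree (pre0/pre1/inner) and, in search mode, the alpha matrix.
#' @noRd
cell_backward <- function(cell, cache, gy, need_gw = TRUE,
                          need_galpha = TRUE) {
  nd <- cell$nodes
  gstates <- lapply(cache$state_dims, function(d) array(0, d))
  # un-concat
  C <- cell$C
  for (k in seq_along(cell$concat)) {
    st <- cell$concat[[k]] + 3L
    gstates[[st]] <- gstates[[st]] + gy[, , (k - 1L) * C + seq_len(C), , drop = FALSE]
  }
  inner_grads <- vector("list", nd)
  galpha <- NULL
  if (cell$mode == "search") {
    if (need_galpha)
      galpha <- matrix(0, n_cell_edges(nd), length(cell$inner[[1L]]$prims))
    e_end <- n_cell_edges(nd)
    for (i in rev(seq_len(nd))) {
      gnode <- gstates[[i + 2L]]
      ec <- cache$inner[[i]]
      egr <- vector("list", i + 1L)
      for (j in rev(seq_len(i + 1L))) {
        e <- e_end - (i + 1L) + j
        br <- mixed_backward(cell$inner[[e]], ec[[j]], gnode, need_gw,
                             need_galpha)
        gstates[[j]] <- gstates[[j]] + br$gx
        if (need_galpha) galpha[e, ] <- galpha[e, ] + br$galpha
        egr[[j]] <- br$grads
      }
      inner_grads[[i]] <- egr
      e_end <- e_end - (i + 1L)
    }
    # flatten per-node edge grads back into the flat edge list order
    inner_grads <- unlist(inner_grads, recursive = FALSE)
  } else {
    for (i in rev(seq_len(nd))) {
      gnode <- gstates[[i + 2L]]
      pairs <- cell$inner[[i]]
      pgr <- vector("list", length(pairs))
      for (k in rev(seq_along(pairs))) {
        prim <- pairs[[k]]
        br <- op_backward(prim, cache$inner[[i]][[k]], gnode, need_gw)
        gstates[[prim$pred + 1L]] <- gstates[[prim$pred + 1L]] + br$gx
        pgr[[k]] <- br$grads
      }
      inner_grads[[i]] <- pgr
    }
  }
  b0 <- op_backward(cell$pre0, cache$pre0, gstates[[1L]], need_gw)
  b1 <- op_backward(cell$pre1, cache$pre1, gstates[[2L]], need_gw)
  list(gs0 = b0$gx, gs1 = b1$gx,
       grads = list(pre0 = b0$grads, pre1 = b1$grads, inner = inner_grads),
       galpha = galpha)
}

#' @noRd
cell_params_tree <- function(cell) {
  list(pre0 = params_tree(cell$pre0), pre1 = params_tree(cell$pre1),
       inner = params_tree(cell$inner))
}
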