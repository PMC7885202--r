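test_that("alpha initialization is near-uniform, seeded, right-sized", {
  # 4 nodes with 2,3,4,5 candidate predecessors -> 14 edges per cell kind
  expect_equal(splicedarts:::n_cell_edges(4), 14L)
  a <- init_architecture_params(14, 8, seed = 5)
  expect_equal(dim(a), c(14L, 8L))
  expect_identical(a, init_architecture_params(14, 8, seed = 5))
  for (e in seq_len(nrow(a)))
    expect_true(all(abs(mixed_op_weights(a[e, ]) - 1 / 8) < 1e-2))
})

test_that("cosine schedule spans [lr_min, lr_init] monotonically", {
  lr <- vapply(1:50, splicedarts:::cosine_lr, 0, epochs = 50,
               lr_init = 0.0025, lr_min = 0.001)
  expect_equal(lr[1], 0.0025)
  expect_true(all(diff(lr) < 0))
  expect_gte(min(lr), 0.001)
})

test_that("cross-entropy loss and gradient match a direct computation", {
  set.seed(2)
  lg <- matrix(rnorm(10), 5, 2)
  y <- c(0L, 1L, 1L, 0L, 1L)
  r <- splicedarts:::ce_loss(lg, y)
  p <- exp(lg) / rowSums(exp(lg))
  expect_equal(r$loss, -mean(log(p[cbind(1:5, y + 1)])))
  for (j in seq_along(lg)) {
    l2 <- lg; l2[j] <- l2[j] + 1e-6
    l3 <- lg; l3[j] <- l3[j] - 1e-6
    num <- (splicedarts:::ce_loss(l2, y)$loss -
              splicedarts:::ce_loss(l3, y)$loss) / 2e-6
    expect_equal(r$glogits[j], num, tolerance = 1e-5)
  }
})

test_that("scalar bilevel iterates match hand-derived gradient descent", {
  # L_train = (w - a)^2, L_val = w^2, plain SGD on both levels
  cfg <- search_config(weight_lr_init = 0.1, weight_lr_min = 0.1,
                       arch_lr = 0.05, weight_decay = 0, momentum = 0,
                       arch_weight_decay = 0, arch_optimizer = "sgd",
                       order = "first", epochs = 1)
  st <- splicedarts:::scalar_bilevel_state(
    omega = 2, alpha = 0.5,
    gw_train = function(w, a) 2 * (w - a),
    ga_train = function(w, a) -2 * (w - a),
    gw_val = function(w, a) 2 * w,
    ga_val = function(w, a) 0,
    config = cfg)
  w <- 2; a <- 0.5
  for (i in 1:5) {
    st <- bilevel_step(st)
    # first-order: dL_val/da = 0, so alpha never moves; w chases alpha
    w <- w - 0.1 * 2 * (w - a)
    expect_equal(st$alpha, a)
    expect_equal(st$omega, w, tolerance = 1e-12)
  }

  # second-order: hand-derived unrolled update with the finite-difference
  # curvature term, iterated independently
  cfg2 <- cfg; cfg2$order <- "second"
  st2 <- splicedarts:::scalar_bilevel_state(
    omega = 2, alpha = 0.5,
    gw_train = function(w, a) 2 * (w - a),
    ga_train = function(w, a) -2 * (w - a),
    gw_val = function(w, a) 2 * w,
    ga_val = function(w, a) 0,
    config = cfg2)
  w <- 2; a <- 0.5; xi <- 0.1
  for (i in 1:5) {
    st2 <- bilevel_step(st2)
    wp <- w - xi * 2 * (w - a)
    r <- 2 * wp
    eps <- 0.01 / abs(r)
    ga <- 0 - xi * ((-2 * (w + eps * r - a)) - (-2 * (w - eps * r - a))) / (2 * eps)
    a <- a - 0.05 * ga
    w <- w - xi * 2 * (w - a)
    expect_equal(st2$alpha, a, tolerance = 1e-10)
    expect_equal(st2$omega, w, tolerance = 1e-10)
  }
})

test_that("zero learning rates freeze the respective variables", {
  sp <- tiny_split(n = 60, len = 16)
  nc <- network_config(input_length = 16, layers = 1, init_channels = 2)
  mkstate <- function(arch_lr, wlr, mom) {
    cfg <- search_config(batch_size = 20, epochs = 1, arch_lr = arch_lr,
                         weight_lr_init = wlr, weight_lr_min = wlr,
                         momentum = mom, weight_decay = 0, seed = 2)
    splicedarts:::with_local_seed(2, search_state(nc, cfg))
  }
  b <- rand_batch(16, 20, seed = 3)
  st <- mkstate(arch_lr = 0, wlr = 0.01, mom = 0.9)
  a0 <- st$model$alphas
  st2 <- bilevel_step(st, b, b)
  expect_identical(st2$model$alphas, a0)   # arch_lr = 0 leaves alpha alone
  expect_false(identical(
    splicedarts:::flat_leaves(splicedarts:::model_params_tree(st2$model)),
    splicedarts:::flat_leaves(splicedarts:::model_params_tree(st$model))))

  st <- mkstate(arch_lr = 0.1, wlr = 1e-12, mom = 0)
  w0 <- splicedarts:::flat_leaves(splicedarts:::model_params_tree(st$model))
  st2 <- bilevel_step(st, b, b)
  w1 <- splicedarts:::flat_leaves(splicedarts:::model_params_tree(st2$model))
  expect_equal(w0, w1, tolerance = 1e-9)   # ~zero weight lr freezes omega
  expect_false(identical(st2$model$alphas, st$model$alphas))
  expect_true(is.finite(st2$L_train) && is.finite(st2$L_val))
})

test_that("derive_genotype keeps the dominant operation and top-2 edges", {
  np <- length(primitive_set())
  sc3 <- which(primitive_set() == "sep_conv_3x3")
  A <- matrix(0, 14, np)
  A[1, sc3] <- 10   # edge 0 -> node0
  A[2, sc3] <- 10   # edge 1 -> node0
  g <- derive_genotype(list(normal = A, reduce = A))
  expect_equal(g$normal[[1]],
               list(list(op = "sep_conv_3x3", pred = 0L),
                    list(op = "sep_conv_3x3", pred = 1L)))
  # all-equal alpha: tie rule gives the two lowest predecessors with the
  # lowest-indexed non-zero primitive
  gt <- derive_genotype(list(normal = matrix(0, 14, np),
                             reduce = matrix(0, 14, np)))
  for (i in 1:4) {
    expect_equal(vapply(gt$normal[[i]], `[[`, 0L, "pred"), c(0L, 1L))
    expect_equal(vapply(gt$normal[[i]], `[[`, "", "op"),
                 rep(primitive_set()[1], 2))
  }
  # invariant to per-edge constant shifts
  set.seed(11)
  A1 <- matrix(rnorm(14 * np), 14, np)
  A2 <- A1 + matrix(runif(14, -30, 30), 14, np)
  expect_equal(derive_genotype(list(normal = A1, reduce = A1)),
               derive_genotype(list(normal = A2, reduce = A2)))
})

test_that("derive_genotype agrees with a brute-force enumeration oracle", {
  prims <- primitive_set()
  np <- length(prims)
  oracle <- function(A) {
    off <- 0L
    lapply(1:4, function(i) {
      rows <- off + seq_len(i + 1L); off <<- off + i + 1L
      # brute force: all softmaxes, mask zero, rank edges, pick maxima
      W <- t(sapply(rows, function(r) exp(A[r, ]) / sum(exp(A[r, ]))))
      nzW <- W[, prims != "zero", drop = FALSE]
      score <- apply(nzW, 1, max)
      keep <- sort(order(-score, seq_along(rows))[1:2])
      lapply(keep, function(j) {
        wj <- W[j, ]
        wj[prims == "zero"] <- -Inf
        list(op = prims[which.max(wj)], pred = j - 1L)
      })
    })
  }
  set.seed(11)
  for (rep in 1:5) {
    A <- matrix(rnorm(14 * np, sd = 2), 14, np)
    B <- matrix(rnorm(14 * np, sd = 2), 14, np)
    g <- derive_genotype(list(normal = A, reduce = B))
    expect_equal(g$normal, oracle(A))
    expect_equal(g$reduce, oracle(B))
  }
  # per-edge variant keeps every edge, zero allowed
  A <- matrix(0, 14, np)
  A[, np] <- 5   # zero dominates everywhere
  gpe <- derive_genotype(list(normal = A, reduce = A), per_edge = TRUE)
  expect_equal(length(gpe$normal[[4]]), 5L)
  expect_true(all(vapply(gpe$normal[[4]], `[[`, "", "op") == "zero"))
})

test_that("run_search history and best-epoch bookkeeping are consistent", {
  sp <- tiny_split(n = 90, len = 16)
  nc <- network_config(input_length = 16, layers = 1, init_channels = 2,
                       primitives = c("sep_conv_3x3", "max_pool_3x3", "zero"))
  res <- run_search(sp, nc, search_config(batch_size = 24, epochs = 3,
                                          seed = 4))
  expect_equal(nrow(res$history), 3L)
  expect_true(all(is.finite(res$history$L_train)))
  expect_equal(res$best_val_accuracy, max(res$history$val_accuracy))
  expect_equal(res$best_epoch, which.max(res$history$val_accuracy))
  expect_equal(res$genotypes[[res$best_epoch]], res$best_genotype)
  # alpha count never changes during search
  expect_equal(dim(res$model$alphas$normal), c(14L, 3L))

  # single epoch: the best epoch is that epoch
  res1 <- run_search(sp, nc, search_config(batch_size = 24, epochs = 1,
                                           seed = 4))
  expect_equal(res1$best_epoch, 1L)
  expect_equal(res1$best_genotype, res1$genotypes[[1]])

  # |O| = 1: every edge of the derived genotype uses that primitive
  nc1 <- network_config(input_length = 16, layers = 1, init_channels = 2,
                        primitives = "sep_conv_3x3")
  resd <- run_search(sp, nc1, search_config(batch_size = 24, epochs = 1,
                                            seed = 4))
  ops <- unlist(lapply(c(resd$best_genotype$normal,
                         resd$best_genotype$reduce),
                       function(nd) vapply(nd, `[[`, "", "op")))
  expect_true(all(ops == "sep_conv_3x3"))

  expect_error(run_search(list(train = sp$train, validation = list()),
                          nc, search_config(epochs = 1)), "validation")
})

test_that("run_search is deterministic for a fixed seed", {
  sp <- tiny_split(n = 60, len = 12)
  nc <- network_config(input_length = 12, layers = 1, init_channels = 2,
                       primitives = c("sep_conv_3x3", "zero"))
  cfg <- search_config(batch_size = 20, epochs = 2, seed = 9)
  r1 <- run_search(sp, nc, cfg)
  r2 <- run_search(sp, nc, cfg)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$best_genotype, r2$best_genotype)
})
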