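test_that("compute_node sums transformed predecessors (explicit-loop oracle)", {
  a <- array(1.5, c(4, 4, 2, 1))
  b <- array(-0.5, c(4, 4, 2, 1))
  # two constant predecessors: a + b, verified by direct elementwise addition
  expect_equal(compute_node(list(a, b)), a + b)
  # zero summands give the zero map
  expect_equal(compute_node(list(0 * a, 0 * b)), array(0, dim(a)))
  # single predecessor with an identity stand-in transform
  expect_equal(compute_node(list(a), list(identity)), a)
  # random case against an explicit loop
  set.seed(3)
  maps <- lapply(1:4, function(i) rand_map(5, 4, 2, 2))
  want <- array(0, dim(maps[[1]]))
  for (m in maps) want <- want + m
  expect_equal(compute_node(maps), want)
  expect_error(compute_node(list(a, array(0, c(3, 4, 2, 1)))), "shape")
})

test_that("cells preserve (normal) or halve (reduction) the spatial shape", {
  g <- rand_genotype(seed = 2)
  s0 <- rand_map(60, 4, 6, 2, seed = 1)
  s1 <- rand_map(60, 4, 6, 2)
  cn <- build_cell(g, "normal", channels = 4, c_in0 = 6, c_in1 = 6)
  yn <- splicedarts:::cell_forward(cn, s0, s1)$y
  expect_equal(dim(yn), c(60, 4, 16, 2))        # 4 nodes x 4 channels
  cr <- build_cell(g, "reduction", channels = 4, c_in0 = 6, c_in1 = 6)
  yr <- splicedarts:::cell_forward(cr, s0, s1)$y
  expect_equal(dim(yr), c(30, 2, 16, 2))
  # search-mode cell obeys the same contracts
  cs <- build_cell(NULL, "reduction", channels = 4, c_in0 = 6, c_in1 = 6,
                   mode = "search")
  alpha <- matrix(0, splicedarts:::n_cell_edges(4), 8)
  ys <- splicedarts:::cell_forward(cs, s0, s1, alpha = alpha)$y
  expect_equal(dim(ys), c(30, 2, 16, 2))
})

test_that("an all-zero genotype propagates zeros through the cell", {
  zg <- cell_genotype(lapply(1:4, function(i)
    list(list(op = "zero", pred = 0L), list(op = "zero", pred = 1L))))
  cl <- build_cell(zg, "normal", channels = 3, c_in0 = 2, c_in1 = 2)
  y <- splicedarts:::cell_forward(cl, rand_map(6, 4, 2, 2, seed = 4),
                                  rand_map(6, 4, 2, 2))$y
  expect_equal(y, array(0, c(6, 4, 12, 2)))
})

test_that("genotype validation and JSON round trip are faithful", {
  g <- rand_genotype(seed = 9)
  p <- tempfile(fileext = ".json")
  write_genotype(g, p)
  g2 <- read_genotype(p)
  expect_equal(unclass(g2), unclass(g))
  expect_error(cell_genotype(list(list(list(op = "zero", pred = 0L)))),
               "exactly 4")
  bad <- list(list(list(op = "zero", pred = 3L)), list(), list(), list())
  expect_error(cell_genotype(rep(list(list(list(op = "zero", pred = 9L),
                                           list(op = "zero", pred = 0L))), 4)),
               "out of range")
  expect_error(cell_genotype(rep(list(list(list(op = "warp", pred = 0L),
                                           list(op = "zero", pred = 0L))), 4)),
               "unknown primitive")
})

test_that("reduction cells sit at floor(L/3) and floor(2L/3)", {
  expect_equal(splicedarts:::reduction_positions(9), c(3L, 6L))
  expect_equal(splicedarts:::reduction_positions(3), c(1L, 2L))
  expect_equal(splicedarts:::reduction_positions(2), integer(0))
  expect_equal(splicedarts:::reduction_positions(1), integer(0))
  g <- rand_genotype(seed = 5)
  net <- build_network(g, network_config(input_length = 60, layers = 9,
                                         init_channels = 2))
  kinds <- vapply(net$cells, `[[`, "", "kind")
  expect_equal(which(kinds == "reduction") - 1L, c(3L, 6L))
  net2 <- build_network(g, network_config(input_length = 20, layers = 2,
                                          init_channels = 2))
  expect_false(any(vapply(net2$cells, `[[`, "", "kind") == "reduction"))
})

test_that("network shape plan composes per-cell contracts (layers=3, n_d=60)", {
  g <- rand_genotype(seed = 6)
  net <- build_network(g, network_config(input_length = 60, layers = 3,
                                         init_channels = 4))
  x <- batch_tensor(encode_dataset(list(
    dna_sequence("a", strrep("ACGT", 15), 1),
    dna_sequence("b", strrep("TTTA", 15), 0))))
  fw <- splicedarts:::network_forward(net, x, train = FALSE)
  # stem (60,4) -> normal -> reduction (30,2) -> reduction -> (15,1)
  expect_equal(fw$cache$out_dim, c(15, 1, 4 * 4 * 4, 2))
  expect_equal(dim(fw$logits), c(2L, 2L))
})

test_that("forward yields exactly 2 logits per sequence for varied genotypes", {
  for (seed in 1:3) {
    g <- rand_genotype(seed = seed)
    nd <- c(9, 24, 61)[seed]
    net <- build_network(g, network_config(input_length = nd, layers = 3,
                                           init_channels = 2))
    x <- array(rnorm(nd * 4 * 5), c(nd, 4, 1, 5))
    lg <- splicedarts:::network_forward(net, x, train = TRUE)$logits
    expect_equal(dim(lg), c(5L, 2L))
    expect_true(all(is.finite(lg)))
  }
})

test_that("parameter counts: closed-form head, zero-genotype cells, scaling", {
  zg <- cell_genotype(lapply(1:4, function(i)
    list(list(op = "zero", pred = 0L), list(op = "zero", pred = 1L))))
  net <- build_network(zg, network_config(input_length = 20, layers = 1,
                                          init_channels = 4))
  pc <- count_parameters(net)
  # head: 2 classes x F features + 2 biases
  F <- net$feat
  expect_equal(unname(pc$by_component["head"]), 2L * F + 2L)
  # zero ops carry no weights: cell params = the two 1x1 preprocessing blocks
  pre_params <- function(cin, cout) cin * cout + 2L * cout  # conv + bn
  expect_equal(unname(pc$by_component["cells"]),
               2L * pre_params(4L, 4L))
  # stem: 3x3 conv 1->C plus bn
  expect_equal(unname(pc$by_component["stem"]), 9L * 4L + 2L * 4L)
  expect_equal(pc$omega, as.integer(sum(pc$by_component)))
  expect_equal(pc$alpha, 0L)

  # per-layer arithmetic for a pointwise-dominated genotype: doubling
  # init_channels multiplies conv weight counts by ~4
  g <- cell_genotype(lapply(1:4, function(i)
    list(list(op = "sep_conv_3x3", pred = 0L),
         list(op = "sep_conv_3x3", pred = 1L))))
  n1 <- build_network(g, network_config(input_length = 20, layers = 1,
                                        init_channels = 4))
  n2 <- build_network(g, network_config(input_length = 20, layers = 1,
                                        init_channels = 8))
  # hand tally for one sep_conv_3x3 at C channels: dw 9C + pw C^2 + bn 2C
  sep <- function(C) 9L * C + C * C + 2L * C
  cells1 <- 8L * sep(4L) + 2L * pre_params(4L, 4L)
  cells2 <- 8L * sep(8L) + 2L * pre_params(8L, 8L)
  expect_equal(unname(count_parameters(n1)$by_component["cells"]), cells1)
  expect_equal(unname(count_parameters(n2)$by_component["cells"]), cells2)

  # search mode reports alpha separately: 2 kinds x 14 edges x |O|
  ns <- build_network(NULL, network_config(input_length = 20, layers = 2,
                                           init_channels = 2),
                      mode = "search")
  expect_equal(count_parameters(ns)$alpha, 2L * 14L * 8L)
})

test_that("search net with |O|=1 equals the fixed net built from its genotype", {
  # the mixture collapses to the single primitive; transplanting weights
  # into the fixed network over the same DAG must reproduce the outputs
  cfgs <- network_config(input_length = 18, layers = 3, init_channels = 2,
                         primitives = "sep_conv_3x3")
  set.seed(31)
  net_s <- build_network(NULL, cfgs, mode = "search")
  net_s$alphas$normal[] <- 0
  net_s$alphas$reduce[] <- 0
  g <- derive_genotype(net_s$alphas, primitives = "sep_conv_3x3",
                       per_edge = TRUE)   # keeps all 14 edges per cell
  net_f <- build_network(g, cfgs, mode = "fixed")
  leaves <- splicedarts:::flat_leaves(splicedarts:::model_params_tree(net_s))
  net_f <- splicedarts:::set_model_params(net_f, leaves)
  x <- array(rnorm(18 * 4 * 3), c(18, 4, 1, 3))
  ls <- splicedarts:::network_forward(net_s, x, train = FALSE)$logits
  lf <- splicedarts:::network_forward(net_f, x, train = FALSE)$logits
  expect_equal(ls, lf, tolerance = 1e-5)
})

test_that("whole-network gradients match finite differences (search mode)", {
  set.seed(17)
  cfg <- network_config(input_length = 10, layers = 2, init_channels = 2,
                        primitives = c("sep_conv_3x3", "max_pool_3x3", "zero"))
  net <- build_network(NULL, cfg, mode = "search")
  x <- array(rnorm(10 * 4 * 3), c(10, 4, 1, 3))
  gy <- matrix(rnorm(6), 3, 2)
  loss <- function(m) sum(splicedarts:::network_forward(m, x, TRUE)$logits * gy)
  fw <- splicedarts:::network_forward(net, x, train = TRUE)
  bw <- splicedarts:::network_backward(net, fw$cache, gy)
  gl <- splicedarts:::flat_leaves(bw$grads)
  fl <- splicedarts:::flat_leaves(splicedarts:::model_params_tree(net))
  # weight gradients at random coordinates across the whole model
  for (k in sample(length(fl), 6)) {
    j <- sample(length(fl[[k]]), 1)
    pert <- function(v) {
      i <- 0L
      m2 <- splicedarts:::map_model_params(net, function(p) {
        i <<- i + 1L
        if (i == k) p[j] <- p[j] + v
        p
      })
      loss(m2)
    }
    expect_equal(as.numeric(gl[[k]])[j], (pert(1e-5) - pert(-1e-5)) / 2e-5,
                 tolerance = 1e-4)
  }
  # alpha gradients for both cell kinds
  for (kind in c("normal", "reduce")) {
    e <- sample(nrow(net$alphas[[kind]]), 1)
    o <- sample(ncol(net$alphas[[kind]]), 1)
    fa <- function(v) {
      m2 <- net
      m2$alphas[[kind]][e, o] <- m2$alphas[[kind]][e, o] + v
      loss(m2)
    }
    expect_equal(bw$galphas[[kind]][e, o], (fa(1e-5) - fa(-1e-5)) / 2e-5,
                 tolerance = 1e-4)
  }
})

test_that("clone_network separates batch-norm running statistics", {
  g <- rand_genotype(seed = 8)
  net <- build_network(g, network_config(input_length = 12, layers = 1,
                                         init_channels = 2))
  cl <- clone_network(net)
  x <- rand_map(12, 4, 1, 4, seed = 1)
  invisible(splicedarts:::network_forward(net, x, train = TRUE))
  # training the original must not move the clone's running stats
  expect_equal(cl$stem$ops[[2]]$stats$mean, numeric(2))
  expect_false(isTRUE(all.equal(net$stem$ops[[2]]$stats$mean, numeric(2))))
})
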