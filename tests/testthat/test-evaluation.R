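test_that("confusion-based metrics match direct arithmetic", {
  # scores engineered to give TP=90, FN=10, TN=80, FP=20
  labels <- c(rep(1, 100), rep(0, 100))
  scores <- c(rep(0.9, 90), rep(0.1, 10), rep(0.2, 80), rep(0.8, 20))
  m <- compute_metrics(labels, scores)
  expect_equal(unname(m$confusion), c(90L, 20L, 80L, 10L))
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$sensitivity, 0.90)
  expect_equal(m$specificity, 0.80)
  # F1 from precision 90/110 and recall 0.9
  p <- 90 / 110
  expect_equal(m$f_score, 2 * p * 0.9 / (p + 0.9))
  expect_error(compute_metrics(c(1, 0), 0.5), "equal length")
  expect_error(compute_metrics(c(1, 0), c(0.1, NaN)), "finite")
})

test_that("perfect and uninformative scorers give the expected metrics", {
  m <- compute_metrics(c(1, 1, 0, 0), c(1, 1, 0, 0))
  for (k in c("accuracy", "sensitivity", "specificity", "f_score", "auc"))
    expect_equal(m[[k]], 1)
  # all scores identical: AUC 0.5 under the midrank tie convention
  m2 <- compute_metrics(c(1, 0, 1, 0), rep(0.5, 4))
  expect_equal(m2$auc, 0.5)
  expect_equal(compute_metrics(c(1, 0), c(0.9, 0.1))$auc, 1)
  # the reversed scorer also has empty precision/F denominators: warnings
  # are part of the contract here, values checked below
  mr <- suppressWarnings(compute_metrics(c(1, 0), c(0.1, 0.9)))
  expect_equal(mr$auc, 0)
  expect_true(is.na(mr$f_score))
})

test_that("AUC equals the exhaustive pairwise oracle (ties count half)", {
  pair_auc <- function(y, s) {
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
  }
  set.seed(3)
  for (n in c(10, 50, 200)) {
    y <- rbinom(n, 1, 0.4)
    if (sum(y) == 0 || sum(y) == n) y[1:2] <- c(0, 1)
    s <- round(runif(n), 2)              # rounding forces ties
    expect_equal(compute_metrics(y, s)$auc, pair_auc(y, s))
  }
})

test_that("ROC passes through (0,0) and (1,1); degenerate inputs warn", {
  set.seed(4)
  y <- rbinom(60, 1, 0.5); y[1:2] <- c(0, 1)
  s <- runif(60)
  m <- compute_metrics(y, s)
  expect_equal(unlist(m$roc_points[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(m$roc_points[nrow(m$roc_points), ]),
               c(fpr = 1, tpr = 1))
  expect_true(all(diff(m$roc_points$fpr) >= 0))
  expect_true(all(m$pr_points$precision >= 0 & m$pr_points$precision <= 1))
  # single-class input: AUC undefined but other metrics still returned
  # (specificity is also 0/0 here, hence suppressWarnings + value checks)
  ws <- capture_warnings(compute_metrics(c(1, 1), c(0.9, 0.2)))
  expect_true(any(grepl("single class", ws)))
  ms <- suppressWarnings(compute_metrics(c(1, 1), c(0.9, 0.2)))
  expect_true(is.na(ms$auc))
  expect_equal(ms$sensitivity, 0.5)
  expect_equal(nrow(ms$roc_points), 0L)
  # no predicted positives: precision undefined, not silently 0/0
  wp <- capture_warnings(compute_metrics(c(1, 0), c(0.1, 0.2),
                                         threshold = 0.9))
  expect_true(any(grepl("precision undefined", wp)))
  mp <- suppressWarnings(compute_metrics(c(1, 0), c(0.1, 0.2),
                                         threshold = 0.9))
  expect_true(is.na(mp$f_score))
})

test_that("trim_for_transfer slices so the dimer lands at the target offset", {
  set.seed(8)
  # synthetic 602-mer with GT planted at source offset 300
  bases <- paste(sample(c("A", "C", "G", "T"), 602, TRUE), collapse = "")
  substr(bases, 301, 302) <- "GT"
  s <- dna_sequence("x", bases, 1)
  out <- trim_for_transfer(s, source_offset = 300, target_length = 141,
                           target_offset = 70)
  expect_equal(nchar(out$bases), 141L)
  expect_equal(substr(out$bases, 71, 72), "GT")       # 0-based offset 70
  # oracle: window start = 300 - 70 (0-based)
  expect_equal(out$bases, substr(bases, 231, 231 + 140))
  expect_equal(out$label, 1L)

  # no-op trim
  expect_equal(trim_for_transfer(s, 300, 602, 300)$bases, bases)
  # out-of-bounds windows error instead of padding
  expect_error(trim_for_transfer(s, 10, 141, 70), "bounds")
  expect_error(trim_for_transfer(s, 600, 141, 2), "bounds")
  short <- dna_sequence("y", "ACGTACGT", 0)
  expect_error(trim_for_transfer(short, 4, 10, 2), "padding")
})

test_that("trimming preserves base identity as a substring", {
  cfg <- synthetic_config(10, 80, motif = donor_motif(40), seed = 6)
  for (s in generate_splice_dataset(cfg)) {
    out <- trim_for_transfer(s, 40, 30, 10)
    expect_equal(nchar(out$bases), 30L)
    expect_true(grepl(out$bases, s$bases, fixed = TRUE))
    expect_equal(substr(out$bases, 11, 12),
                 substr(s$bases, 41, 42))
  }
})

test_that("train_fixed: epochs=0 returns the initialization; seeds reproduce", {
  sp <- tiny_split(n = 60, len = 16)
  nc <- network_config(input_length = 16, layers = 1, init_channels = 2)
  g <- rand_genotype(seed = 3)
  m0 <- train_fixed(g, sp, nc, train_config(epochs = 0, batch_size = 20,
                                            seed = 5))
  ref <- splicedarts:::with_local_seed(5, build_network(g, nc))
  expect_equal(splicedarts:::flat_leaves(splicedarts:::model_params_tree(m0)),
               splicedarts:::flat_leaves(splicedarts:::model_params_tree(ref)))

  m1 <- train_fixed(g, sp, nc, train_config(epochs = 2, batch_size = 20,
                                            seed = 5))
  m2 <- train_fixed(g, sp, nc, train_config(epochs = 2, batch_size = 20,
                                            seed = 5))
  expect_identical(attr(m1, "history"), attr(m2, "history"))
  expect_identical(
    splicedarts:::flat_leaves(splicedarts:::model_params_tree(m1)),
    splicedarts:::flat_leaves(splicedarts:::model_params_tree(m2)))
  # training moved the weights and recorded finite losses
  expect_false(identical(
    splicedarts:::flat_leaves(splicedarts:::model_params_tree(m1)),
    splicedarts:::flat_leaves(splicedarts:::model_params_tree(m0))))
  expect_true(all(is.finite(attr(m1, "history")$L_train)))
})

test_that("evaluate_model scores encoded test sets end to end", {
  sp <- tiny_split(n = 60, len = 16)
  nc <- network_config(input_length = 16, layers = 1, init_channels = 2)
  m <- train_fixed(rand_genotype(seed = 2), sp, nc,
                   train_config(epochs = 1, batch_size = 20, seed = 1))
  # a 1-epoch model may predict a single class, making precision/F NA
  em <- suppressWarnings(evaluate_model(m, sp$test))
  expect_s3_class(em, "eval_metrics")
  expect_true(em$accuracy >= 0 && em$accuracy <= 1)
  expect_equal(sum(em$confusion), length(sp$test))
  expect_error(evaluate_model(m, list()), "empty")
})

test_that("metrics TSV writer reports mean and sd over repeats", {
  m1 <- compute_metrics(c(1, 0, 1, 0), c(0.9, 0.2, 0.8, 0.4))
  m2 <- compute_metrics(c(1, 0, 1, 0), c(0.6, 0.2, 0.3, 0.4))
  p <- tempfile(fileext = ".tsv")
  write_metrics(list(m1, m2), p)
  tab <- read.delim(p)
  expect_equal(tab$metric,
               c("accuracy", "sensitivity", "specificity", "f_score", "auc"))
  expect_equal(tab$mean[1], mean(c(m1$accuracy, m2$accuracy)))
  expect_equal(tab$sd[1], sd(c(m1$accuracy, m2$accuracy)))
  expect_true(file.exists(paste0(p, ".roc.tsv")))
  expect_true(file.exists(paste0(p, ".pr.tsv")))
})
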