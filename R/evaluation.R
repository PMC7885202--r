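# Retraining a derived architecture and evaluating it.

#' Training hyperparameters for the fixed network
#'
#' Defaults mirror the reference evaluation protocol: 70 epochs at batch
#' size 100 with the weight-optimizer settings of the search stage (SGD,
#' momentum 0.9, cosine learning rate 0.0025 -> 0.001, weight decay 3e-4).
#'
#' @param epochs Integer >= 0 (0 returns the freshly initialized network).
#' @param batch_size Integer.
#' @param weight_lr_init,weight_lr_min,momentum,weight_decay As in
#'   [search_config()].
#' @param seed Integer; drives initialization and batch shuffling.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 70L, batch_size = 100L,
                         weight_lr_init = 0.0025, weight_lr_min = 0.001,
                         momentum = 0.9, weight_decay = 0.0003, seed = 1L) {
  stopifnot(epochs >= 0L, batch_size >= 1L, weight_lr_init > 0,
            weight_lr_min > 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 weight_lr_init = weight_lr_init,
                 weight_lr_min = weight_lr_min,
                 momentum = momentum, weight_decay = weight_decay,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Train a fixed derived architecture
#'
#' Builds the fixed-mode network from a genotype and trains it by
#' cross-entropy with momentum SGD under the cosine learning-rate schedule.
#' Fully deterministic given `config$seed` (single-threaded).
#'
#' @param genotype A [cell_genotype()].
#' @param data A [split_dataset()] of encoded sequences; the validation
#'   part, when non-empty, is scored once per epoch for the log.
#' @param net_config A [network_config()].
#' @param config A [train_config()].
#' @param verbose Print a line per epoch.
#' @return The trained `splice_network`, with a `history` attribute
#'   (data.frame epoch/L_train/val_accuracy).
#' @export
train_fixed <- function(genotype, data, net_config, config = train_config(),
                        verbose = FALSE) {
  if (length(data$train) == 0L) stop("empty training part")
  Xtr <- batch_tensor(data$train); ytr <- attr(Xtr, "labels")
  has_val <- length(data$validation) > 0L
  if (has_val) {
    Xva <- batch_tensor(data$validation); yva <- attr(Xva, "labels")
  }
  with_local_seed(config$seed, {
    model <- build_network(genotype, net_config, mode = "fixed")
    vel <- lapply(flat_leaves(model_params_tree(model)), function(p) 0 * p)
    nE <- config$epochs
    hist <- data.frame(epoch = seq_len(nE), L_train = rep(NA_real_, nE),
                       val_accuracy = rep(NA_real_, nE))
    for (epoch in seq_len(nE)) {
      lr <- cosine_lr(epoch, nE, config$weight_lr_init, config$weight_lr_min)
      losses <- c()
      for (idx in chunk_indices(sample.int(length(ytr)), config$batch_size)) {
        fl <- fwd_loss(model, make_batch(Xtr, ytr, idx))
        bt <- network_backward(model, fl$cache, fl$glogits)
        w <- flat_leaves(model_params_tree(model))
        g <- flat_leaves(bt$grads)
        for (i in seq_along(w)) {
          u <- sgd_update(w[[i]], g[[i]], vel[[i]], lr, config$momentum,
                          config$weight_decay)
          w[[i]] <- u$p
          vel[[i]] <- u$v
        }
        model <- set_model_params(model, w)
        losses <- c(losses, fl$loss)
      }
      hist$L_train[epoch] <- mean(losses)
      if (has_val)
        hist$val_accuracy[epoch] <- eval_accuracy(model, Xva, yva,
                                                  config$batch_size)
      if (verbose)
        message(sprintf("epoch %3d  lr %.5f  L_train %.4f  val_acc %s",
                        epoch, lr, hist$L_train[epoch],
                        if (has_val) sprintf("%.4f", hist$val_accuracy[epoch])
                        else "-"))
    }
    attr(model, "history") <- hist
    model
  })
}

#' Binary classification metrics
#'
#' Computes the standard suite from labels and class-1 scores: confusion
#' matrix at the threshold, accuracy, sensitivity (TP/(TP+FN)), specificity
#' (TN/(TN+FP)), F-score (F1, the harmonic mean of precision and recall)
#' and AUC.  AUC is the rank statistic: the probability that a random
#' positive outranks a random negative, ties counted half (equivalent to
#' trapezoidal integration of the ROC curve).  Degenerate denominators
#' yield `NA` with a warning, never a silent 0/0; a single-class input
#' yields `NA` AUC and empty curves with a warning.
#'
#' @param labels 0/1 vector.
#' @param scores Numeric vector of the same length (higher = more positive).
#' @param threshold Decision threshold for the confusion-based metrics
#'   (default 0.5; prediction is positive when `score >= threshold`).
#' @return An `eval_metrics` object: list(accuracy, sensitivity,
#'   specificity, f_score, auc, confusion (TP/FP/TN/FN), roc_points
#'   (data.frame fpr/tpr), pr_points (data.frame recall/precision)).
#' @export
#' @examples
#' compute_metrics(c(1, 0), c(0.9, 0.1))$auc   # 1
compute_metrics <- function(labels, scores, threshold = 0.5) {
  if (length(labels) != length(scores))
    stop("labels and scores must have equal length")
  if (any(!is.finite(scores))) stop("scores must be finite")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0 or 1")
  y <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  TP <- sum(pred == 1L & y == 1L); FP <- sum(pred == 1L & y == 0L)
  TN <- sum(pred == 0L & y == 0L); FN <- sum(pred == 0L & y == 1L)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator)", call. = FALSE)
      return(NA_real_)
    }
    num / den
  }
  accuracy <- (TP + TN) / length(y)
  sensitivity <- safe_div(TP, TP + FN, "sensitivity")
  specificity <- safe_div(TN, TN + FP, "specificity")
  precision <- safe_div(TP, TP + FP, "precision")
  f_score <- if (is.na(precision) || is.na(sensitivity) ||
                 precision + sensitivity == 0) {
    warning("F-score undefined", call. = FALSE)
    NA_real_
  } else 2 * precision * sensitivity / (precision + sensitivity)

  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) {
    warning("AUC undefined: test set contains a single class", call. = FALSE)
    auc <- NA_real_
    roc <- data.frame(fpr = numeric(0), tpr = numeric(0))
    pr <- data.frame(recall = numeric(0), precision = numeric(0))
  } else {
    r <- rank(scores)                       # midranks for ties
    auc <- (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    ord <- order(scores, decreasing = TRUE)
    ys <- y[ord]; ss <- scores[ord]
    cut <- c(which(diff(ss) != 0), length(ss))   # last index of each distinct score
    ctp <- cumsum(ys == 1L)[cut]
    cfp <- cumsum(ys == 0L)[cut]
    roc <- data.frame(fpr = c(0, cfp / n0), tpr = c(0, ctp / n1))
    pr <- data.frame(recall = ctp / n1, precision = ctp / (ctp + cfp))
  }
  structure(list(accuracy = accuracy, sensitivity = sensitivity,
                 specificity = specificity, f_score = f_score, auc = auc,
                 confusion = c(TP = TP, FP = FP, TN = TN, FN = FN),
                 threshold = threshold, roc_points = roc, pr_points = pr),
            class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf(paste0("<eval_metrics> accuracy %.4f  sensitivity %s  ",
                     "specificity %s  F-score %s  AUC %s\n"),
              x$accuracy, .fmt(x$sensitivity), .fmt(x$specificity),
              .fmt(x$f_score), .fmt(x$auc)))
  cat(sprintf("  confusion @%.2f: TP=%d FP=%d TN=%d FN=%d\n", x$threshold,
              x$confusion[["TP"]], x$confusion[["FP"]],
              x$confusion[["TN"]], x$confusion[["FN"]]))
  invisible(x)
}

.fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.4f", v)

#' Evaluate a trained model on a held-out set
#'
#' Scores each sequence with the class-1 (true splice site) probability in
#' inference mode and computes the metric suite at the given threshold.
#'
#' @param model A trained `splice_network`.
#' @param test_set List of encoded sequences with label attributes.
#' @param threshold Decision threshold (default 0.5).
#' @param batch_size Inference batch size.
#' @return An `eval_metrics` object (see [compute_metrics()]); the ROC and
#'   precision-recall point lists are suitable for plotting.
#' @export
evaluate_model <- function(model, test_set, threshold = 0.5,
                           batch_size = 100L) {
  if (length(test_set) == 0L) stop("empty test set")
  probs <- predict(model, test_set, batch_size = batch_size)
  labels <- vapply(test_set, function(e) as.integer(attr(e, "label")), 0L)
  compute_metrics(labels, probs[, 2L], threshold)
}

#' Write metrics and curves as TSV
#'
#' @param metrics An `eval_metrics` (or list of them, interpreted as
#'   repeated runs whose mean and standard deviation are reported).
#' @param path Metrics TSV path (columns metric, mean, sd); the ROC and PR
#'   curves of the first run are written next to it as `<path>.roc.tsv` and
#'   `<path>.pr.tsv`.
#' @export
write_metrics <- function(metrics, path) {
  if (inherits(metrics, "eval_metrics")) metrics <- list(metrics)
  keys <- c("accuracy", "sensitivity", "specificity", "f_score", "auc")
  vals <- sapply(keys, function(k)
    vapply(metrics, function(m) m[[k]], 0))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1,
                                         dimnames = list(NULL, keys))
  tab <- data.frame(metric = keys,
                    mean = colMeans(vals),
                    sd = apply(vals, 2L, stats::sd))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(metrics[[1L]]$roc_points, paste0(path, ".roc.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(metrics[[1L]]$pr_points, paste0(path, ".pr.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Trim a sequence for cross-dataset transfer
#'
#' Extracts the window that places the splice dimer of a longer sequence at
#' the position it occupies in a shorter-window dataset: pure slicing, no
#' padding (a window that exceeds the sequence bounds is an error).  Offsets
#' are 0-based positions of the dimer start.
#'
#' @param seq A [dna_sequence()].
#' @param source_offset Dimer position in `seq`.
#' @param target_length Desired window length.
#' @param target_offset Dimer position in the output window.
#' @return A [dna_sequence()] of length `target_length` with the same id
#'   and label.
#' @export
trim_for_transfer <- function(seq, source_offset, target_length,
                              target_offset) {
  n <- nchar(seq$bases)
  if (source_offset < 0L || source_offset > n - 2L)
    stop("source offset ", source_offset, " out of bounds for length ", n)
  if (target_offset < 0L || target_offset > target_length - 2L)
    stop("target offset ", target_offset, " out of bounds for target length ",
         target_length)
  start <- source_offset - target_offset        # 0-based window start
  if (start < 0L || start + target_length > n)
    stop("trim window [", start, ", ", start + target_length,
         ") exceeds sequence bounds (length ", n, "); padding is not applied")
  structure(list(id = seq$id,
                 bases = substr(seq$bases, start + 1L, start + target_length),
                 label = seq$label),
            class = "dna_sequence")
}
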