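# Training/evaluation protocol: stratified splits (rotating-quarters
# cross-validation or a fixed held-out test set), Adam + cross-entropy with
# minimum-validation-loss checkpointing, and paired two-tailed t tests for
# per-subject comparisons.

#' Split scheme
#'
#' @param mode `"cv4"`: trials are partitioned into four stratified quarters;
#'   fold i uses quarter i as test, quarter (i mod 4)+1 as validation and the
#'   remaining two as training (50/25/25). `"fixed-test"`: the given test
#'   indices are kept untouched; the remainder is split 80/20 into training
#'   and validation with seeded shuffling, once per repeat.
#' @param n_repeats number of folds/repeats (4, matching the protocol).
#' @param seed integer seed for the shuffles.
#' @param test_indices trial indices of the held-out test set
#'   (`"fixed-test"` only).
#' @param shuffle shuffle trials before cutting quarters (`"cv4"`); without
#'   it quarters are contiguous in recording order.
#' @return an object of class `split_scheme`.
#' @export
split_scheme <- function(mode = c("cv4", "fixed-test"), n_repeats = 4L,
                         seed = 1L, test_indices = NULL, shuffle = TRUE) {
  mode <- match.arg(mode)
  if (mode == "fixed-test" && is.null(test_indices))
    stop_eegtrm("fixed-test mode needs test_indices",
                class = "eegtrm_config_error")
  structure(list(mode = mode, n_repeats = as.integer(n_repeats),
                 seed = as.integer(seed), test_indices = test_indices,
                 shuffle = isTRUE(shuffle)),
            class = "split_scheme")
}

#' Partition trials into train/validation/test folds
#'
#' Splitting is stratified by label in both modes; an error is raised if any
#' class would be absent from any role.
#'
#' @param epochs an [epoch_set] with labels (or a bare label vector).
#' @param scheme a [split_scheme].
#' @return list of folds, each `list(train, val, test)` of disjoint trial
#'   indices whose union is all trials (cv4) or the pool plus test set
#'   (fixed-test).
#' @export
split_trials <- function(epochs, scheme = split_scheme()) {
  labels <- if (inherits(epochs, "epoch_set")) epochs$labels else epochs
  if (is.null(labels))
    stop_eegtrm("labels are required for stratified splitting",
                class = "eegtrm_stratification_error")
  labels <- as.factor(labels)
  n <- length(labels)
  if (scheme$mode == "cv4") {
    if (any(table(labels) < 4L))
      stop_eegtrm("every class needs >= 4 trials for rotating quarters (have: %s)",
                  paste(table(labels), collapse = ", "),
                  class = "eegtrm_stratification_error")
    quarter <- integer(n)
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      if (scheme$shuffle)
        idx <- with_seed(scheme$seed + match(cl, levels(labels)),
                         sample(idx))
      quarter[idx] <- rep_len(1:4, length(idx))
    }
    lapply(seq_len(scheme$n_repeats), function(f) {
      ti <- ((f - 1L) %% 4L) + 1L
      vi <- (ti %% 4L) + 1L
      list(train = which(!quarter %in% c(ti, vi)),
           val = which(quarter == vi),
           test = which(quarter == ti))
    })
  } else {
    test <- as.integer(scheme$test_indices)
    pool <- setdiff(seq_len(n), test)
    if (any(table(labels[test]) == 0L) || any(table(labels[pool]) == 0L))
      stop_eegtrm("a class is absent from the test set or the train pool",
                  class = "eegtrm_stratification_error")
    lapply(seq_len(scheme$n_repeats), function(f) {
      val <- integer(0)
      for (cl in levels(labels)) {
        idx <- pool[labels[pool] == cl]
        n_val <- max(1L, round(0.2 * length(idx)))
        val <- c(val, with_seed(scheme$seed + 131L * f +
                                  match(cl, levels(labels)),
                                sample(idx, n_val)))
      }
      list(train = setdiff(pool, val), val = sort(val), test = test)
    })
  }
}

#' Training configuration
#'
#' @param learning_rate Adam step size (optimizer default).
#' @param weight_decay L2 penalty added to the gradient (0.001, per protocol).
#' @param batch_size minibatch size (32).
#' @param max_epochs training epochs (300 in the full protocol; scale down
#'   for quick runs).
#' @param seed integer seed controlling initialization, shuffling and
#'   dropout; identical seeds give identical runs.
#' @return an object of class `training_config`.
#' @export
training_config <- function(learning_rate = 1e-3, weight_decay = 1e-3,
                            batch_size = 32L, max_epochs = 300L, seed = 1L) {
  stopifnot(learning_rate > 0, weight_decay >= 0, batch_size >= 1,
            max_epochs >= 1)
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed)),
            class = "training_config")
}

# epoch index of the minimum validation loss under strict-improvement
# checkpointing (the first occurrence of the minimum)
best_checkpoint_epoch <- function(val_losses) which.min(val_losses)

eval_network <- function(net, x, y_int, chunk = 256L) {
  n <- dim(x)[1L]
  loss <- 0; correct <- 0L
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    sc <- network_forward(net, x[idx, , , drop = FALSE], training = FALSE)
    l <- softmax_xent(t(sc), y_int[idx])
    loss <- loss + l$loss * length(idx)
    correct <- correct + sum(max.col(sc) == y_int[idx])
  }
  list(loss = loss / n, accuracy = 100 * correct / n)
}

#' Train and evaluate a network over folds
#'
#' For each fold the network is freshly initialized (seed + fold index),
#' trained with Adam and cross-entropy loss, and checkpointed on strict
#' validation-loss improvement after every epoch; the checkpoint with the
#' lowest validation loss is restored for testing. A fold whose loss turns
#' non-finite is marked failed, reported with a warning and excluded from the
#' mean.
#'
#' @param net an [eeg_network] (its parameters are re-initialized per fold).
#' @param epochs a labeled [epoch_set].
#' @param splits fold list from [split_trials()].
#' @param config a [training_config].
#' @param verbose print per-epoch losses to stderr.
#' @return an object of class `run_result`: per-fold test accuracies (%),
#'   mean and sd, loss curves, epoch of minimum validation loss, parameter
#'   count.
#' @export
train_eval <- function(net, epochs, splits, config = training_config(),
                       verbose = FALSE) {
  x <- epochs$data
  y <- as.factor(epochs$labels)
  y_int <- as.integer(y)
  n_folds <- length(splits)
  acc <- rep(NA_real_, n_folds)
  best_ep <- rep(NA_integer_, n_folds)
  failed <- logical(n_folds)
  train_curves <- val_curves <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    sp <- splits[[f]]
    res <- with_seed(config$seed + 7919L * f, {
      network_init(net, config$seed + 7919L * f)
      opt <- adam_new(net$layers, lr = config$learning_rate,
                      weight_decay = config$weight_decay)
      tl <- vl <- numeric(config$max_epochs)
      best <- Inf; best_state <- NULL; diverged <- FALSE
      for (ep in seq_len(config$max_epochs)) {
        ord <- sample(sp$train)
        eloss <- 0
        for (s in seq(1L, length(ord), by = config$batch_size)) {
          bi <- ord[s:min(s + config$batch_size - 1L, length(ord))]
          sc <- network_forward(net, x[bi, , , drop = FALSE], training = TRUE)
          l <- softmax_xent(t(sc), y_int[bi])
          if (!is.finite(l$loss)) { diverged <- TRUE; break }
          network_backward(net, t(l$grad))
          adam_step(net$layers, opt)
          eloss <- eloss + l$loss * length(bi)
        }
        if (diverged) break
        tl[ep] <- eloss / length(ord)
        ev <- eval_network(net, x[sp$val, , , drop = FALSE], y_int[sp$val])
        vl[ep] <- ev$loss
        if (!is.finite(vl[ep])) { diverged <- TRUE; break }
        if (vl[ep] < best) {          # strict improvement only
          best <- vl[ep]
          best_state <- seq_get_state(net$layers)
        }
        if (verbose)
          message(sprintf("fold %d epoch %d: train %.4f val %.4f",
                          f, ep, tl[ep], vl[ep]))
      }
      if (diverged || is.null(best_state))
        list(failed = TRUE, tl = tl[seq_len(ep)], vl = vl[seq_len(ep)])
      else {
        seq_set_state(net$layers, best_state)
        te <- eval_network(net, x[sp$test, , , drop = FALSE], y_int[sp$test])
        list(failed = FALSE, tl = tl, vl = vl,
             best_epoch = best_checkpoint_epoch(vl),
             accuracy = te$accuracy)
      }
    })
    train_curves[[f]] <- res$tl
    val_curves[[f]] <- res$vl
    failed[f] <- res$failed
    if (res$failed)
      warning(sprintf("fold %d diverged (non-finite loss); excluded", f))
    else {
      acc[f] <- res$accuracy
      best_ep[f] <- res$best_epoch
    }
  }
  ok <- !failed
  structure(list(fold_accuracy = acc,
                 mean_accuracy = mean(acc[ok]),
                 sd_accuracy = if (sum(ok) > 1L) stats::sd(acc[ok]) else 0,
                 single_fold = sum(ok) == 1L,
                 failed_folds = which(failed),
                 train_loss = train_curves, val_loss = val_curves,
                 best_epoch = best_ep,
                 param_count = count_parameters(net),
                 n_classes = nlevels(y), network = net$name),
            class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("<run_result '%s'> %.2f%% +/- %.2f%% over %d folds (%d parameters)\n",
              x$network, x$mean_accuracy, x$sd_accuracy,
              sum(!is.na(x$fold_accuracy)), x$param_count))
  if (length(x$failed_folds))
    cat("  failed folds:", paste(x$failed_folds, collapse = ", "), "\n")
  invisible(x)
}

#' Paired two-tailed t test on per-subject accuracies
#'
#' Closed form: t = mean(d) / (sd(d)/sqrt(n)) on the paired differences
#' d = b - a, with a two-tailed p-value from the t distribution on n - 1
#' degrees of freedom. Identical vectors give a mean difference of 0 and
#' p = 1; zero-variance differences with a nonzero mean are reported as
#' degenerate with an undefined p.
#'
#' @param a,b equal-length numeric vectors (e.g. per-subject mean
#'   accuracies of two variants), n >= 2.
#' @return list with `mean_diff` (mean of b - a), `t`, `df`, `p` and
#'   `degenerate`.
#' @export
#' @examples
#' compare_paired(c(80, 82, 78, 85), c(81, 84, 81, 89))
compare_paired <- function(a, b) {
  if (length(a) != length(b))
    stop_eegtrm("paired vectors differ in length (%d vs %d)",
                length(a), length(b), class = "eegtrm_pairing_error")
  n <- length(a)
  if (n < 2L)
    stop_eegtrm("need n >= 2 pairs", class = "eegtrm_pairing_error")
  d <- b - a
  md <- mean(d)
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    return(list(mean_diff = md, t = if (md == 0) 0 else sign(md) * Inf,
                df = n - 1L, p = if (md == 0) 1 else NA_real_,
                degenerate = TRUE))
  }
  t <- md / (sd_d / sqrt(n))
  list(mean_diff = md, t = t, df = n - 1L,
       p = 2 * stats::pt(-abs(t), df = n - 1L), degenerate = FALSE)
}

#' Summarize runs across subjects and variants
#'
#' @param results data.frame with columns `subject`, `backbone`, `variant`
#'   (`"original"`, `"trm-5"`, `"trm-3"`) and `accuracy` (per-subject mean,
#'   %). Missing cells leave explicit `NA` gaps.
#' @return list with `table` (subjects x backbone+variant columns, plus an
#'   `Average` row) and `deltas` (per backbone and TRM variant: mean
#'   improvement over the original and the paired two-tailed p-value).
#' @export
summarize_runs <- function(results) {
  stopifnot(all(c("subject", "backbone", "variant", "accuracy") %in%
                  names(results)))
  subjects <- unique(results$subject)
  bbs <- unique(results$backbone)
  vars <- c("original", "trm-5", "trm-3")
  cols <- as.vector(outer(vars, bbs, function(v, b) paste(b, v, sep = "+")))
  tab <- matrix(NA_real_, length(subjects), length(cols),
                dimnames = list(subjects, cols))
  for (i in seq_len(nrow(results)))
    tab[as.character(results$subject[i]),
        paste(results$backbone[i], results$variant[i], sep = "+")] <-
      results$accuracy[i]
  tab <- rbind(tab, Average = colMeans(tab, na.rm = TRUE))
  deltas <- do.call(rbind, lapply(bbs, function(b) {
    do.call(rbind, lapply(c("trm-5", "trm-3"), function(v) {
      a <- tab[seq_along(subjects), paste(b, "original", sep = "+")]
      x <- tab[seq_along(subjects), paste(b, v, sep = "+")]
      ok <- !is.na(a) & !is.na(x)
      cmp <- if (sum(ok) >= 2L) compare_paired(a[ok], x[ok])
             else list(mean_diff = mean(x[ok]) - mean(a[ok]), p = NA_real_)
      data.frame(backbone = b, variant = v, delta = cmp$mean_diff,
                 p = cmp$p, n = sum(ok))
    }))
  }))
  list(table = as.data.frame(tab), deltas = deltas)
}
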