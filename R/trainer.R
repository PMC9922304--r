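#' Binarize a continuous drug response into NR/R labels
#'
#' Samples with logIC50 above the threshold statistic become non-respondents
#' (`"NR"`, resistant); samples below become respondents (`"R"`). Values
#' exactly at the threshold are assigned to `"NR"` (fixed tie rule for
#' determinism). With the median statistic the class counts differ by at
#' most one.
#'
#' @param values Numeric vector of logIC50 values (optionally named by
#'   sample id).
#' @param statistic `"median"` (default) or `"mean"`.
#' @return Factor with levels `c("NR", "R")`, names preserved.
#' @export
binarize_response <- function(values, statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  if (length(values) < 2L || !all(is.finite(values))) {
    abort("need at least 2 finite response values.")
  }
  if (diff(range(values)) == 0) {
    abort("all response values identical: no separation possible.")
  }
  thr <- if (statistic == "median") median(values) else mean(values)
  lab <- factor(ifelse(values >= thr, "NR", "R"), levels = c("NR", "R"))
  names(lab) <- names(values)
  lab
}

#' Stratified train/validation split
#'
#' Deterministic under the seed. The training count is `floor(n * ratio)`
#' (per class when stratified, with at least one validation sample per
#' class); validation takes the remainder, so per-class proportions are
#' within one sample of the ratio.
#'
#' @param labels Factor of class labels named by sample id (or a
#'   `multiomics_dataset`, whose labels are used).
#' @param ratio Training fraction (default 0.9).
#' @param seed Integer seed.
#' @param stratified Stratify by class (default `TRUE`).
#' @return A `split_plan`: list with `train`, `validation` (sample ids),
#'   `ratio`, `seed`, `stratified`.
#' @export
split_train_val <- function(labels, ratio = 0.9, seed = 1L, stratified = TRUE) {
  if (inherits(labels, "multiomics_dataset")) {
    if (is.null(labels$labels)) abort("dataset has no labels.")
    labels <- labels$labels
  }
  labels <- factor(labels)
  ids <- names(labels) %||% as.character(seq_along(labels))
  if (ratio <= 0 || ratio >= 1) abort("`ratio` must be in (0, 1).")
  set.seed(seed)
  if (stratified) {
    cnt <- table(labels)
    if (any(cnt < 2L)) {
      abort(paste0("class '", names(cnt)[which(cnt < 2L)[1L]],
                   "' has fewer than 2 samples; use stratified = FALSE."))
    }
    train <- character()
    for (cl in levels(labels)) {
      cl_ids <- ids[labels == cl]
      n_tr <- min(floor(length(cl_ids) * ratio), length(cl_ids) - 1L)
      train <- c(train, sample(cl_ids, n_tr))
    }
  } else {
    n_tr <- floor(length(ids) * ratio)
    if (n_tr < 1L || n_tr >= length(ids)) abort("split leaves an empty portion.")
    train <- sample(ids, n_tr)
  }
  train <- ids[ids %in% train]  # restore original ordering
  structure(list(train = train, validation = setdiff(ids, train),
                 ratio = ratio, seed = as.integer(seed), stratified = stratified),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat("<split_plan> ", length(x$train), " train / ", length(x$validation),
      " validation (ratio ", x$ratio, ", seed ", x$seed,
      if (x$stratified) ", stratified", ")\n", sep = "")
  invisible(x)
}

#' Pair-averaging augmentation
#'
#' Synthetic samples are generated by averaging two distinct images with the
#' same class label (elementwise mean); the label is inherited and the
#' originals are retained. `factor` scales the number of synthetic samples:
#' each class gains `round(factor * n_class)` new images.
#'
#' @param images An `image_set` with labels (or labels supplied separately).
#' @param labels Optional factor overriding `images$labels`.
#' @param factor Non-negative augmentation factor (0 = no-op).
#' @param seed Integer seed for pair sampling.
#' @return An `image_set` with originals plus synthetic samples; synthetic
#'   ids are suffixed `_aug<k>`.
#' @export
augment_pairs <- function(images, labels = NULL, factor = 1, seed = 1L) {
  labels <- labels %||% images$labels
  if (is.null(labels)) abort("labels are required for augmentation.")
  labels <- factor(labels)
  if (factor < 0) abort("`factor` must be non-negative.")
  if (factor == 0) return(images)
  d <- dim(images$values)
  cnt <- table(labels)
  if (any(cnt < 2L)) abort("each class needs at least 2 samples to form pairs.")
  set.seed(seed)
  new_vals <- list(); new_ids <- character(); new_lab <- character()
  k <- 0L
  for (cl in levels(labels)) {
    members <- which(labels == cl)
    n_new <- round(factor * length(members))
    for (t in seq_len(n_new)) {
      pr <- sample(members, 2L)
      k <- k + 1L
      new_vals[[k]] <- (images$values[, , , pr[1L], drop = FALSE] +
                        images$values[, , , pr[2L], drop = FALSE]) / 2
      new_ids[k] <- paste0(cl, "_aug", k)
      new_lab[k] <- cl
    }
  }
  vals <- array(0, c(d[1:3], d[4L] + k))
  vals[, , , seq_len(d[4L])] <- images$values
  for (t in seq_len(k)) vals[, , , d[4L] + t] <- new_vals[[t]]
  structure(
    list(values = vals, sample_ids = c(images$sample_ids, new_ids),
         layer_names = images$layer_names, occupancy = images$occupancy,
         labels = factor(c(as.character(labels), new_lab), levels = levels(labels)),
         frame = images$frame),
    class = "image_set"
  )
}

#' Train the convolutional classifier
#'
#' Trains the desk-scale CNN (3 convolution blocks, global average pooling,
#' linear head) on the training portion of the split, monitoring the
#' validation portion each epoch. Images are bilinearly resized to the
#' configured input contract when their frame differs. Augmentation, the
#' pixel map and the normalization must all be fitted on the training
#' portion only; this function only ever trains on `split$train`.
#'
#' @param images An `image_set` covering (at least) all split samples.
#' @param labels Factor named by sample id (defaults to `images$labels`).
#' @param split A `split_plan` from [split_train_val()]; `NULL` trains on all
#'   samples with no validation monitoring.
#' @param config A [cnn_config()].
#' @param augment Augmentation factor applied to the training portion
#'   (0 disables; see [augment_pairs()]).
#' @return A `cnn_model` with fitted parameters, per-epoch history tibble,
#'   class order and the config snapshot.
#' @export
train_cnn <- function(images, labels = NULL, split = NULL, config = cnn_config(),
                      augment = 0) {
  labels <- labels %||% images$labels
  if (is.null(labels)) abort("labels are required.")
  labels <- setNames(factor(labels), names(labels) %||% images$sample_ids)
  tr_ids <- if (is.null(split)) images$sample_ids else split$train
  va_ids <- if (is.null(split)) character() else split$validation
  tr <- subset_images(images, tr_ids)
  tr$labels <- droplevels(labels[tr_ids])
  if (nlevels(tr$labels) < 2L) abort("training portion contains a single class.")
  if (augment > 0) tr <- augment_pairs(tr, factor = augment, seed = config$seed)
  Xtr <- tr$values
  if (!is.null(config$input_size)) Xtr <- resize_batch(Xtr, config$input_size)
  Xva <- NULL; yva <- NULL
  if (length(va_ids)) {
    va <- subset_images(images, va_ids)
    Xva <- va$values
    if (!is.null(config$input_size)) Xva <- resize_batch(Xva, config$input_size)
    yva <- factor(labels[va_ids], levels = levels(tr$labels))
  }
  fit <- cnn_fit(Xtr, tr$labels, config, Xva, yva)
  structure(
    list(architecture = "conv3-gap", params = fit$params, classes = fit$classes,
         history = fit$history, config = config,
         layer_names = images$layer_names,
         split = split, input_size = config$input_size %||% images$frame),
    class = "cnn_model"
  )
}

#' @export
print.cnn_model <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat("<cnn_model> ", x$architecture, ", classes: ",
      paste(x$classes, collapse = "/"), ", ", nrow(x$history),
      " epochs (final train acc ", sprintf("%.3f", last$accuracy),
      if (!is.null(last$val_accuracy)) sprintf(", val acc %.3f", last$val_accuracy),
      ")\n", sep = "")
  invisible(x)
}

#' Predict class probabilities for an image set
#'
#' @param object A `cnn_model`.
#' @param images An `image_set`.
#' @param ... Unused.
#' @return Matrix n x c of probabilities (columns named by class), rows
#'   named by sample id.
#' @export
predict.cnn_model <- function(object, images, ...) {
  X <- images$values
  if (!identical(dim(X)[1:2], as.integer(object$input_size))) {
    X <- resize_batch(X, object$input_size)
  }
  n <- dim(X)[4L]
  probs <- matrix(0, n, length(object$classes),
                  dimnames = list(images$sample_ids, object$classes))
  for (start in seq(1L, n, by = 64L)) {
    bi <- start:min(start + 63L, n)
    probs[bi, ] <- cnn_forward(object$params, X[, , , bi, drop = FALSE])$probs
  }
  probs
}

#' @export
tidy.cnn_model <- function(x, ...) x$history

#' @export
glance.cnn_model <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  tibble(architecture = x$architecture, epochs = nrow(x$history),
         loss = last$loss, accuracy = last$accuracy,
         val_accuracy = last$val_accuracy %||% NA_real_)
}

#' Area under the ROC curve by the rank statistic
#'
#' Mann-Whitney formulation: the probability that a random positive scores
#' above a random negative, with ties counted half.
#'
#' @param scores Numeric predicted scores for the positive class.
#' @param truth Logical (or 0/1) vector: `TRUE` for positives.
#' @return AUC in `[0, 1]`, or `NA` if only one class is present.
#' @export
rank_auc <- function(scores, truth) {
  truth <- as.logical(truth)
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a trained model on labelled images
#'
#' AUC is computed from the predicted probability of the positive class
#' (the second class level) via the rank statistic; the confusion matrix is
#' taken at probability 0.5. All metrics are recomputable from the stored
#' counts and probabilities.
#'
#' @param model A `cnn_model`.
#' @param images An `image_set`.
#' @param labels Factor named by sample id (defaults to `images$labels`).
#' @param positive Class treated as positive (default: second model class).
#' @return An `eval_report` with `auc`, `accuracy`, `sensitivity`,
#'   `specificity`, `f1`, `confusion` and the per-sample probabilities.
#' @export
evaluate <- function(model, images, labels = NULL, positive = NULL) {
  labels <- labels %||% images$labels
  if (is.null(labels)) abort("labels are required for evaluation.")
  labels <- factor(labels, levels = model$classes)
  probs <- predict(model, images)
  positive <- positive %||% model$classes[min(2L, length(model$classes))]
  p_pos <- probs[, positive]
  truth <- labels == positive
  auc <- if (length(unique(truth)) < 2L) NA_real_ else rank_auc(p_pos, truth)
  pred <- p_pos >= 0.5
  tp <- sum(pred & truth); fn <- sum(!pred & truth)
  fp <- sum(pred & !truth); tn <- sum(!pred & !truth)
  sens <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0L) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0L) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0) {
    2 * prec * sens / (prec + sens)
  } else NA_real_
  structure(
    list(auc = auc, accuracy = (tp + tn) / length(truth),
         sensitivity = sens, specificity = spec, f1 = f1,
         confusion = c(tp = tp, fn = fn, fp = fp, tn = tn),
         positive = positive, probabilities = probs,
         labels = labels),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> AUC %.3f | acc %.3f | sens %.3f | spec %.3f | F1 %.3f (positive: %s)\n",
    x$auc, x$accuracy, x$sensitivity, x$specificity, x$f1, x$positive
  ))
  invisible(x)
}

#' @export
tidy.eval_report <- function(x, ...) {
  tibble(metric = c("auc", "accuracy", "sensitivity", "specificity", "f1",
                    names(x$confusion)),
         value = c(x$auc, x$accuracy, x$sensitivity, x$specificity, x$f1,
                   unname(x$confusion)))
}

#' @export
glance.eval_report <- function(x, ...) {
  tibble(auc = x$auc, accuracy = x$accuracy, sensitivity = x$sensitivity,
         specificity = x$specificity, f1 = x$f1, n = sum(x$confusion))
}

#' Hyperparameter search with a pluggable strategy
#'
#' Samples up to `budget` configurations from the declared space, evaluates
#' each with the user objective, and returns the configuration minimizing
#' validation error. The default strategy is seeded random search; any
#' function drawing a configuration from the space can be plugged in.
#'
#' @param objective Function `config -> validation error` (lower is better).
#' @param space Named list of ranges: each entry either `c(lo, hi)` for
#'   numeric (sampled log-uniformly if `log = TRUE` attribute or the name is
#'   `lr`/`l2`) or a vector of discrete candidates.
#' @param strategy `"random"` or a function `(space, i, seed) -> config list`.
#' @param budget Maximum number of evaluations (default 10).
#' @param seed Integer seed for the sampling sequence.
#' @return List with `best` (config), `best_error` and `trials` tibble.
#' @export
hyperparameter_search <- function(objective, space, strategy = "random",
                                  budget = 10L, seed = 1L) {
  if (!length(space)) abort("empty search space.")
  draw <- if (is.function(strategy)) {
    strategy
  } else if (identical(strategy, "random")) {
    function(space, i, seed) {
      set.seed(seed + i)
      lapply(setNames(names(space), names(space)), function(nm) {
        rg <- space[[nm]]
        if (is.numeric(rg) && length(rg) == 2L && rg[1L] < rg[2L]) {
          if (isTRUE(attr(rg, "log")) || nm %in% c("lr", "l2")) {
            exp(runif(1L, log(rg[1L]), log(rg[2L])))
          } else {
            runif(1L, rg[1L], rg[2L])
          }
        } else {
          rg[[sample.int(length(rg), 1L)]]
        }
      })
    }
  } else {
    abort("unknown strategy.")
  }
  trials <- vector("list", budget)
  best <- NULL; best_err <- Inf
  for (i in seq_len(budget)) {
    cfg <- draw(space, i, seed)
    err <- objective(cfg)
    trials[[i]] <- as_tibble(c(cfg, list(error = err, trial = i)))
    if (err < best_err) {
      best <- cfg
      best_err <- err
    }
  }
  list(best = best, best_error = best_err, trials = dplyr::bind_rows(trials))
}
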