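test_that("binarization thresholds at the median or mean with NR ties", {
  expect_identical(as.character(binarize_response(c(1, 2, 3, 4))),
                   c("R", "R", "NR", "NR"))
  # mean of [0,0,0,10] is 2.5: 3 respondents vs 1 non-respondent
  expect_identical(table(binarize_response(c(0, 0, 0, 10), "mean"))[["R"]], 3L)
  # odd n: the median sample itself is deterministically assigned to NR
  lab <- binarize_response(c(1, 2, 3))
  expect_identical(as.character(lab), c("R", "NR", "NR"))
  # median balance: class counts differ by at most one
  set.seed(1)
  v <- rnorm(101)
  expect_lte(abs(diff(table(binarize_response(v)))), 1L)
  expect_error(binarize_response(c(2, 2, 2)), "identical")
  expect_error(binarize_response(3), "at least 2")
})

test_that("train/validation split follows the floor rule and stratifies", {
  labs <- setNames(factor(rep(c("NR", "R"), c(195, 194))), paste0("s", 1:389))
  sp <- split_train_val(labs, 0.9, seed = 3L, stratified = FALSE)
  expect_length(sp$train, 350L)        # floor(389 * 0.9)
  expect_length(sp$validation, 39L)
  expect_setequal(c(sp$train, sp$validation), names(labs))

  # stratified 10-sample case: exactly 1 of each class in validation
  labs10 <- setNames(factor(rep(c("a", "b"), each = 5L)), paste0("x", 1:10))
  sp10 <- split_train_val(labs10, 0.9, seed = 1L)
  expect_identical(as.integer(table(labs10[sp10$validation])), c(1L, 1L))

  # per-class proportions within one sample of the ratio
  sp_s <- split_train_val(labs, 0.9, seed = 3L)
  for (cl in levels(labs)) {
    n_cl <- sum(labs == cl)
    n_tr <- sum(labs[sp_s$train] == cl)
    expect_lte(abs(n_tr - n_cl * 0.9), 1)
  }

  # determinism
  expect_identical(split_train_val(labs, 0.9, seed = 7L),
                   split_train_val(labs, 0.9, seed = 7L))
  expect_error(split_train_val(factor(c("a", "a", "b")), 0.9, seed = 1L),
               "stratified")
})

test_that("pair averaging produces elementwise means within the parent envelope", {
  set.seed(9)
  imgs <- toy_image_set(lapply(1:6, function(i) matrix(runif(16), 4L)),
                        labels = rep(c("NR", "R"), 3L))
  aug <- augment_pairs(imgs, factor = 1, seed = 2L)
  expect_identical(dim(aug$values)[4L], 12L)
  expect_identical(aug$sample_ids[1:6], imgs$sample_ids)
  expect_identical(aug$values[, , , 1:6], imgs$values[, , , 1:6])
  # every synthetic image lies inside the per-pixel min/max envelope of its class
  for (j in 7:12) {
    cl <- as.character(aug$labels[j])
    members <- imgs$values[, , , imgs$labels == cl, drop = FALSE]
    lo <- apply(members, 1:3, min); hi <- apply(members, 1:3, max)
    synth <- aug$values[, , , j, drop = FALSE]
    expect_true(all(c(synth) >= c(lo) - 1e-12))
    expect_true(all(c(synth) <= c(hi) + 1e-12))
  }
  # explicit elementwise oracle on a forced pair
  two <- toy_image_set(list(matrix(0, 2L, 2L), matrix(1, 2L, 2L)),
                       labels = c("a", "a"))
  aug2 <- augment_pairs(two, factor = 0.5, seed = 1L)
  expect_equal(aug2$values[, , 1L, 3L], matrix(0.5, 2L, 2L))
  # averaging an image with itself would be idempotent; pairs are distinct,
  # but identical content still averages to itself
  same <- toy_image_set(list(matrix(0.3, 2L, 2L), matrix(0.3, 2L, 2L)),
                        labels = c("a", "a"))
  aug3 <- augment_pairs(same, factor = 0.5, seed = 1L)
  expect_equal(aug3$values[, , 1L, 3L], matrix(0.3, 2L, 2L))
  # factor 0 is a no-op; determinism under seed
  expect_identical(augment_pairs(imgs, factor = 0, seed = 1L), imgs)
  expect_identical(augment_pairs(imgs, factor = 2, seed = 5L)$values,
                   augment_pairs(imgs, factor = 2, seed = 5L)$values)
  expect_error(augment_pairs(imgs, factor = -1), "non-negative")
})

test_that("rank AUC equals brute-force pairwise concordance and pROC", {
  set.seed(30)
  for (rep in 1:10) {
    n <- sample(4:30, 1L)
    scores <- round(runif(n), 2L)  # rounding forces some ties
    truth <- runif(n) > 0.5
    if (length(unique(truth)) < 2L) truth[1:2] <- c(TRUE, FALSE)
    expect_equal(rank_auc(scores, truth), brute_auc(scores, truth))
  }
  skip_if_not_installed("pROC")
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.55, 0.1)
  truth <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  expect_equal(rank_auc(scores, truth),
               as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE))))
})

test_that("the CNN backward pass matches finite-difference gradients", {
  set.seed(77)
  X <- array(runif(10 * 8 * 2 * 3), c(10L, 8L, 2L, 3L))
  y <- factor(c("a", "b", "a"))
  params <- pixelomics:::cnn_init(2L, 2L, c(3L, 4L, 5L), seed = 1L)
  onehot <- diag(2L)[as.integer(y), ]
  loss_fn <- function(par) {
    fwd <- pixelomics:::cnn_forward(par, X)
    -mean(log(pmax(fwd$probs[cbind(1:3, as.integer(y))], 1e-12)))
  }
  fwd <- pixelomics:::cnn_forward(params, X, keep = TRUE)
  grads <- pixelomics:::cnn_backward(params, fwd, onehot, l2 = 0)
  eps <- 1e-5
  for (nm in c("W1", "b2", "W3", "Wd", "bd")) {
    # probe a handful of coordinates per parameter block
    coords <- sample(length(params[[nm]]), min(4L, length(params[[nm]])))
    for (ci in coords) {
      pp <- params; pp[[nm]][ci] <- pp[[nm]][ci] + eps
      pm <- params; pm[[nm]][ci] <- pm[[nm]][ci] - eps
      num <- (loss_fn(pp) - loss_fn(pm)) / (2 * eps)
      expect_equal(grads[[nm]][ci], num, tolerance = 1e-4)
    }
  }
})

test_that("training separates a strongly separable toy set and is seeded", {
  fx <- tiny_trained()
  hist <- fx$model$history
  expect_identical(nrow(hist), 4L)
  expect_gt(hist$accuracy[4L], hist$accuracy[1L] - 0.2)  # learning happens
  ev <- evaluate(fx$model, subset_images(fx$images, fx$split$validation),
                 labels = fx$dataset$labels[fx$split$validation])
  expect_gte(ev$auc, 0.75)

  # determinism: the same config and seed reproduce the training history
  m2 <- train_cnn(fx$images, split = fx$split,
                  config = cnn_config(epochs = 4L, batch_size = 8L, seed = 7L))
  expect_identical(m2$history, fx$model$history)
  expect_identical(m2$params, fx$model$params)
  expect_error(train_cnn(subset_images(fx$images, which(fx$images$labels == "R")),
                         config = cnn_config(epochs = 1L)),
               "single class")
})

test_that("images are resized to the architecture's input contract", {
  fx <- tiny_trained()
  cfg <- cnn_config(epochs = 1L, batch_size = 8L, input_size = c(12L, 12L),
                    seed = 1L)
  m <- train_cnn(fx$images, split = fx$split, config = cfg)
  expect_identical(m$input_size, c(12L, 12L))
  probs <- predict(m, fx$images)  # 16x16 input resized internally
  expect_identical(dim(probs), c(length(fx$images$sample_ids), 2L))
  expect_equal(unname(rowSums(probs)), rep(1, nrow(probs)))
})

test_that("evaluation metrics follow the confusion counts", {
  imgs <- toy_image_set(lapply(1:4, function(i) matrix(i / 4, 3L, 3L)),
                        labels = c("NR", "NR", "R", "R"))
  fx <- tiny_trained()
  ev <- evaluate(fx$model, subset_images(fx$images, fx$split$validation),
                 labels = fx$dataset$labels[fx$split$validation])
  with(ev, {
    expect_equal(accuracy, unname((confusion["tp"] + confusion["tn"]) / sum(confusion)))
    expect_equal(sum(confusion), length(fx$split$validation))
  })
  expect_identical(dim(tidy(ev)), c(9L, 2L))

  # degenerate single-class test set: AUC undefined, others still emitted
  one_cl <- which(fx$dataset$labels[fx$split$validation] == "NR")
  ids <- fx$split$validation[one_cl]
  ev1 <- evaluate(fx$model, subset_images(fx$images, ids),
                  labels = fx$dataset$labels[ids])
  expect_true(is.na(ev1$auc))
  expect_false(is.na(ev1$accuracy))
})

test_that("perfect and uninformative scores give AUC 1 and 0.5", {
  expect_equal(rank_auc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(rank_auc(rep(0.5, 6L), c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)), 0.5)
})

test_that("hyperparameter search returns the minimum-error configuration", {
  # deterministic objective: grid point nearest 0.3 wins
  grid <- list(x = seq(0, 1, by = 0.05))
  res <- hyperparameter_search(function(cfg) (cfg$x - 0.3)^2, grid,
                               budget = 40L, seed = 2L)
  expect_equal(res$best$x, 0.3, tolerance = 0.051)
  expect_identical(nrow(res$trials), 40L)
  expect_equal(min(res$trials$error), res$best_error)

  # budget 1 returns the single sampled configuration
  one <- hyperparameter_search(function(cfg) cfg$lr, list(lr = c(1e-4, 1e-1)),
                               budget = 1L, seed = 5L)
  expect_identical(nrow(one$trials), 1L)
  expect_equal(one$best$lr, one$trials$lr[1L])

  # fixed seed reproduces the whole trial sequence
  a <- hyperparameter_search(function(cfg) cfg$lr + cfg$momentum,
                             list(lr = c(1e-4, 1e-1), momentum = c(0.5, 0.99),
                                  l2 = c(1e-6, 1e-2)),
                             budget = 10L, seed = 4L)
  b <- hyperparameter_search(function(cfg) cfg$lr + cfg$momentum,
                             list(lr = c(1e-4, 1e-1), momentum = c(0.5, 0.99),
                                  l2 = c(1e-6, 1e-2)),
                             budget = 10L, seed = 4L)
  expect_identical(a$trials, b$trials)
  expect_error(hyperparameter_search(identity, list(), budget = 2L), "empty")
})
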