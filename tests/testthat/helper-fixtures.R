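# Shared fixture builders. Everything is generated in code; seeds are fixed
# so all tests are reproducible.

# small omics matrix with deterministic values
toy_matrix <- function(d = 5L, n = 4L, layer = "expression", seed = 1L) {
  set.seed(seed)
  m <- matrix(rnorm(d * n, mean = 5), d, n,
              dimnames = list(sprintf("g%02d", seq_len(d)),
                              sprintf("s%02d", seq_len(n))))
  omics_matrix(m, layer)
}

# aligned three-layer dataset with labels
toy_dataset <- function(d = 12L, n = 8L, seed = 1L) {
  set.seed(seed)
  mk <- function(layer, vals) {
    omics_matrix(matrix(vals, d, n,
                        dimnames = list(sprintf("g%02d", seq_len(d)),
                                        sprintf("s%02d", seq_len(n)))),
                 layer)
  }
  labels <- setNames(factor(rep(c("NR", "R"), length.out = n)),
                     sprintf("s%02d", seq_len(n)))
  assemble_dataset(
    list(mk("expression", rnorm(d * n, 5)),
         mk("cna", round(rnorm(d * n, 0, 0.7))),
         mk("mutation", rbinom(d * n, 1L, 0.15))),
    labels = labels
  )
}

# image_set built directly from a list of p x q x L arrays
toy_image_set <- function(arrays, labels = NULL, layer_names = NULL) {
  d <- dim(arrays[[1L]])
  if (length(d) == 2L) {
    arrays <- lapply(arrays, function(a) array(a, c(dim(a), 1L)))
    d <- c(d, 1L)
  }
  vals <- array(0, c(d, length(arrays)))
  for (j in seq_along(arrays)) vals[, , , j] <- arrays[[j]]
  ids <- sprintf("s%02d", seq_along(arrays))
  structure(
    list(values = vals, sample_ids = ids,
         layer_names = layer_names %||% paste0("layer", seq_len(d[3L])),
         occupancy = matrix(1L, d[1L], d[2L]),
         labels = if (!is.null(labels)) setNames(factor(labels), ids),
         frame = d[1:2]),
    class = "image_set"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent brute-force AUC: fraction of concordant positive/negative
# pairs, ties counted half
brute_auc <- function(scores, truth) {
  pos <- scores[truth]
  neg <- scores[!truth]
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

# independent minimum-area rectangle: brute force over a dense grid of
# angles, refined locally (grid search only, no hull geometry) until the
# discretization error is negligible
brute_min_rect_area <- function(xy, n_angles = 3600L, refinements = 3L) {
  area_at <- function(a) {
    r <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2L)
    rot <- xy %*% r
    diff(range(rot[, 1L])) * diff(range(rot[, 2L]))
  }
  lo <- 0; hi <- pi / 2
  best_a <- 0; best <- Inf
  for (stage in seq_len(refinements + 1L)) {
    grid <- seq(lo, hi, length.out = n_angles)
    areas <- vapply(grid, area_at, numeric(1))
    k <- which.min(areas)
    best <- areas[k]; best_a <- grid[k]
    step <- grid[2L] - grid[1L]
    lo <- best_a - step; hi <- best_a + step
  }
  best
}

# a quickly trained tiny model + its images, shared across CAM tests
tiny_trained <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    sc <- synthetic_scenario(n_per_class = 10L, d = 40L, m = 8L, delta = 4,
                             seed = 7L)
    gen <- generate_multiomics(sc)
    split <- split_train_val(gen$dataset$labels, 0.8, seed = 7L)
    train_ds <- subset_samples(gen$dataset, split$train)
    pm <- build_pixel_map(train_ds, frame = 16L, method = "pca", seed = 7L)
    ns <- fit_norm_dataset(train_ds)
    imgs <- transform_dataset(gen$dataset, pm, ns)
    model <- train_cnn(imgs, split = split,
                       config = cnn_config(epochs = 4L, batch_size = 8L, seed = 7L))
    cache <<- list(model = model, images = imgs, pixel_map = pm,
                   split = split, dataset = gen$dataset, planted = gen$planted)
    cache
  }
})
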