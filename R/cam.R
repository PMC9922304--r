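#' Class-activation map from the final activation channels
#'
#' GAP-architecture CAM: the heatmap is the classifier-weight-weighted sum of
#' the channels of the last ReLU activation block, measured relative to the
#' network's zero-input baseline, clipped at zero, bilinearly upsampled to
#' the image frame and normalized. With a global average pooling head this
#' decomposition is exact: the class logit is the spatial mean of the
#' (weighted) map plus the bias. The baseline subtraction anchors "no
#' evidence" at zero (an empty input produces a constant map from the biases
#' alone), and clipping discards negative values, which mark evidence
#' *against* the class; without both, min-max normalization assigns high
#' scores to background pixels whenever a class is encoded purely by the
#' absence of the other class's evidence.
#'
#' @param model A `cnn_model` (the architecture exposes its final
#'   pre-pooling activations and classifier weights).
#' @param images An `image_set`.
#' @param target_class Class whose evidence is mapped (label or index).
#' @param samples Sample ids/indices to map (default: all in `images`).
#' @param normalize `"minmax"` (default): each heatmap min-max normalized to
#'   `[0, 1]`, with flat maps normalizing to all zeros; `"evidence"`: the
#'   clipped above-baseline maps are returned unscaled, so maps of different
#'   samples and classes stay mutually comparable (used for gene selection).
#' @return List of `cam_result` objects: each has `sample_id`, `heatmap`
#'   and `target_class`.
#' @export
compute_cam <- function(model, images, target_class, samples = NULL,
                        normalize = c("minmax", "evidence")) {
  normalize <- match.arg(normalize)
  if (is.numeric(target_class)) target_class <- model$classes[target_class]
  ci <- match(target_class, model$classes)
  if (is.na(ci)) abort(paste0("unknown class '", target_class, "'."))
  idx <- samples %||% seq_along(images$sample_ids)
  if (is.character(idx)) idx <- match(idx, images$sample_ids)
  X <- images$values[, , , idx, drop = FALSE]
  if (!identical(dim(X)[1:2], as.integer(model$input_size))) {
    X <- resize_batch(X, model$input_size)
  }
  w <- model$params$Wd[, ci]
  frame <- images$frame
  # zero-input baseline: the constant evidence produced by biases alone
  zero <- array(0, c(dim(X)[1:3], 1L))
  ref <- cam_from_activations(
    cnn_forward(model$params, zero)$last_relu[, , , 1L, drop = TRUE], w
  )
  out <- vector("list", length(idx))
  for (k in seq(1L, length(idx), by = 64L)) {
    bk <- k:min(k + 63L, length(idx))
    act <- cnn_forward(model$params, X[, , , bk, drop = FALSE])$last_relu
    for (t in seq_along(bk)) {
      raw <- cam_from_activations(act[, , , t, drop = TRUE], w) - ref
      raw[raw < 0] <- 0
      up <- bilinear_resize(raw, frame[1L], frame[2L])
      out[[bk[t]]] <- structure(
        list(sample_id = images$sample_ids[idx[bk[t]]],
             heatmap = if (normalize == "minmax") normalize01(up) else up,
             target_class = target_class),
        class = "cam_result"
      )
    }
  }
  out
}

#' Weighted sum of activation channels (raw CAM)
#'
#' @param activations h x w x K activation array (one sample).
#' @param weights Length-K classifier weight vector for the target class.
#' @return h x w matrix (not normalized, not upsampled).
#' @export
cam_from_activations <- function(activations, weights) {
  d <- dim(activations)
  if (length(d) == 2L) d <- c(d, 1L)
  if (d[3L] != length(weights)) abort("weights do not match activation channels.")
  matrix(matrix(activations, d[1L] * d[2L], d[3L]) %*% weights, d[1L], d[2L])
}

normalize01 <- function(m) {
  rng <- range(m)
  if (rng[2L] - rng[1L] <= 0) return(m * 0)
  (m - rng[1L]) / (rng[2L] - rng[1L])
}

#' Aggregate per-sample CAMs
#'
#' `"class_mean"` (the default used for gene selection) averages the maps of
#' the training samples within each class: `avgR_i = (1/n_i) sum_{j in w_i}
#' R_j`. `"overall_mean"` averages over all samples; `"per_sample"` passes
#' the maps through unchanged.
#'
#' @param cams List of `cam_result` maps (training samples only).
#' @param labels Factor of class labels aligned with `cams` (required for
#'   `"class_mean"`).
#' @param mode Aggregation mode.
#' @param threshold Red-zone threshold stored on each aggregate (default 0.6).
#' @param rescale `"none"` (default): the average maps are the plain
#'   arithmetic means of the member heatmaps. `"class_max"`: all average maps
#'   (and their members) are additionally divided by the largest average-map
#'   value across the returned aggregates, so the strongest class evidence
#'   peaks at exactly 1 and the threshold reads as a fraction of it — the
#'   shared color scale under which the "red zone" of a jet colormap is
#'   defined. Meant for `normalize = "evidence"` maps; a class with no
#'   above-baseline evidence then shows a near-zero map instead of amplified
#'   noise.
#' @return List of `class_cam` objects (one per class for `"class_mean"`,
#'   a single element for `"overall_mean"`, one per sample for
#'   `"per_sample"`), each with `avg_map`, `n`, `threshold` and `mask`.
#' @export
aggregate_cams <- function(cams, labels = NULL,
                           mode = c("class_mean", "overall_mean", "per_sample"),
                           threshold = 0.6, rescale = c("none", "class_max")) {
  mode <- match.arg(mode)
  rescale <- match.arg(rescale)
  maps <- lapply(cams, `[[`, "heatmap")
  make_cc <- function(label, mm, n) {
    avg <- Reduce(`+`, mm) / length(mm)
    structure(list(class_label = label, avg_map = avg, n = n,
                   threshold = threshold, mask = avg > threshold),
              class = "class_cam")
  }
  out <- if (mode == "per_sample") {
    lapply(cams, function(cm) make_cc(cm$sample_id, list(cm$heatmap), 1L))
  } else if (mode == "overall_mean") {
    list(make_cc("all", maps, length(maps)))
  } else {
    if (is.null(labels)) abort("labels are required for class_mean aggregation.")
    labels <- factor(labels)
    if (length(labels) != length(cams)) abort("labels must align with cams.")
    lapply(setNames(levels(labels), levels(labels)), function(cl) {
      members <- which(labels == cl)
      if (!length(members)) abort(paste0("class '", cl, "' has no samples."))
      make_cc(cl, maps[members], length(members))
    })
  }
  if (rescale == "class_max") {
    top <- max(vapply(out, function(cc) max(cc$avg_map), numeric(1)))
    if (top > 0) {
      out <- lapply(out, function(cc) {
        cc$avg_map <- cc$avg_map / top
        cc$mask <- cc$avg_map > cc$threshold
        cc
      })
    }
  }
  out
}

#' @export
print.class_cam <- function(x, ...) {
  cat("<class_cam> class '", x$class_label, "': mean over ", x$n,
      " map(s), threshold ", x$threshold, " selects ", sum(x$mask),
      " pixel(s)\n", sep = "")
  invisible(x)
}

#' @export
autoplot.class_cam <- function(object, ...) {
  m <- object$avg_map
  df <- tibble(row = as.vector(row(m)) - 1L, col = as.vector(col(m)) - 1L,
               value = as.vector(m), selected = as.vector(object$mask))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::geom_point(data = df[df$selected, ], size = 0.3, colour = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(option = "inferno", limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = paste0("Class CAM: ", object$class_label),
                  fill = "activation") +
    ggplot2::theme_minimal()
}

#' Red-zone mask of a class CAM
#'
#' The most informative ("red") zone of the averaged map: a strict
#' greater-than comparison per pixel, `avg_map > threshold`.
#'
#' @param class_cam A `class_cam`.
#' @param threshold Threshold in `[0, 1]` (defaults to the stored one).
#' @return Logical p x q mask.
#' @export
red_zone_mask <- function(class_cam, threshold = NULL) {
  threshold <- threshold %||% class_cam$threshold
  if (threshold < 0 || threshold > 1) abort("`threshold` must be in [0, 1].")
  class_cam$avg_map > threshold
}

#' Decode activated pixels back to gene identifiers
#'
#' The element decoder: returns every gene whose assigned pixel lies inside
#' the mask. Co-located ("batch") genes are all returned.
#'
#' @param mask Logical p x q matrix.
#' @param pixel_map A `pixel_map` with the same frame.
#' @return Character vector of gene ids (possibly empty).
#' @export
decode_elements <- function(mask, pixel_map) {
  p <- attr(pixel_map, "frame_rows"); q <- attr(pixel_map, "frame_cols")
  if (!identical(dim(mask), c(p, q))) abort("mask shape does not match the pixel frame.")
  hit <- mask[cbind(pixel_map$row + 1L, pixel_map$col + 1L)]
  pixel_map$gene[hit]
}

#' Select class-discriminative genes via class-based CAMs
#'
#' Computes training-sample CAMs targeted at each sample's own class on the
#' shared evidence scale, averages them per class, rescales the averages so
#' the strongest class evidence peaks at 1, thresholds the red zone and
#' decodes the masks: `G = union_i G_i`, where genes may be shared between
#' classes. A class whose evidence is only the absence of another class's
#' signal contributes few or no genes, rather than noise.
#'
#' @param model A `cnn_model`.
#' @param images Training-portion `image_set`.
#' @param labels Factor named by sample id (defaults to `images$labels`).
#' @param pixel_map The `pixel_map` the images were built with.
#' @param threshold Red-zone threshold (default 0.6).
#' @param mode Aggregation mode (see [aggregate_cams()]).
#' @return A `gene_subset`: list with `per_class` (named list of gene id
#'   vectors), `union`, `counts` tibble, `threshold` and `class_cams`.
#' @export
select_genes <- function(model, images, labels = NULL, pixel_map,
                         threshold = 0.6, mode = "class_mean") {
  labels <- labels %||% images$labels
  if (is.null(labels)) abort("labels are required.")
  labels <- factor(labels)
  cams <- vector("list", length(images$sample_ids))
  for (cl in levels(labels)) {
    members <- which(labels == cl)
    if (!length(members)) next
    cams[members] <- compute_cam(model, images, target_class = cl,
                                 samples = members, normalize = "evidence")
  }
  ccs <- aggregate_cams(cams, labels, mode = mode, threshold = threshold,
                        rescale = "class_max")
  per_class <- lapply(ccs, function(cc) {
    decode_elements(red_zone_mask(cc), pixel_map)
  })
  names(per_class) <- vapply(ccs, `[[`, character(1), "class_label")
  union_g <- unique(unlist(per_class, use.names = FALSE)) %||% character()
  if (!length(union_g)) warn("all red-zone masks are empty: no genes selected.")
  structure(
    list(per_class = per_class, union = union_g,
         counts = tibble(class = names(per_class),
                         n_genes = lengths(per_class)),
         threshold = threshold, class_cams = ccs, stage = 1L),
    class = "gene_subset"
  )
}

#' @export
print.gene_subset <- function(x, ...) {
  cat("<gene_subset> stage ", x$stage, ": ",
      paste(sprintf("%s=%d", x$counts$class, x$counts$n_genes), collapse = ", "),
      "; union ", length(x$union), " genes\n", sep = "")
  invisible(x)
}

#' @export
tidy.gene_subset <- function(x, ...) {
  dplyr::bind_rows(lapply(names(x$per_class), function(cl) {
    tibble(class = cl, gene = x$per_class[[cl]])
  }))
}

#' Write a gene subset as TSV (one column per class plus the union)
#'
#' @param subset A `gene_subset`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_gene_subset <- function(subset, path) {
  cols <- c(subset$per_class, list(union = subset$union))
  n <- max(lengths(cols))
  df <- as.data.frame(lapply(cols, function(v) c(v, rep("", n - length(v)))))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Iterative gene-subset refinement
#'
#' Stage k + 1 re-runs the full pipeline (arrangement, mapping, training,
#' CAM, decoding) on the genes selected at stage k, producing gradually
#' smaller subsets. Each stage trains a fresh model (stages change the input
#' dimensionality, so weights are never reused). Stops early with a notice
#' when a stage selects fewer than 3 genes (too few to arrange).
#'
#' @param dataset A labelled `multiomics_dataset` (training pool).
#' @param stages Number of stages (>= 1).
#' @param frame `c(p, q)` pixel frame.
#' @param mode,dominant_layer,method,distance Passed to [build_pixel_map()].
#' @param config A [cnn_config()].
#' @param split_ratio,augment,threshold Stage training/selection parameters.
#' @param seed Integer seed (per-stage seeds are derived from it).
#' @return List of `gene_subset` objects, one per completed stage; each
#'   carries its stage index and the stage artifacts (`pixel_map`, `model`,
#'   `eval`).
#' @export
iterative_select <- function(dataset, stages = 2L, frame = c(64L, 64L),
                             mode = "dominant", dominant_layer = "expression",
                             method = "tsne", distance = "cosine",
                             config = cnn_config(), split_ratio = 0.9,
                             augment = 1, threshold = 0.6, seed = 1L) {
  if (stages < 1L) abort("`stages` must be at least 1.")
  out <- list()
  current <- dataset
  for (st in seq_len(stages)) {
    if (length(dataset_genes(current)) < 3L) {
      inform(paste0("stopping before stage ", st, ": fewer than 3 genes remain."))
      break
    }
    stage_seed <- seed + (st - 1L) * 1000L
    split <- split_train_val(current$labels, ratio = split_ratio,
                             seed = stage_seed)
    train_ds <- subset_samples(current, split$train)
    pm <- build_pixel_map(train_ds, mode = mode, dominant_layer = dominant_layer,
                          frame = frame, method = method, distance = distance,
                          seed = stage_seed)
    ns <- fit_norm_dataset(train_ds)
    images <- transform_dataset(current, pm, ns)
    cfg <- config
    cfg$seed <- stage_seed
    model <- train_cnn(images, split = split, config = cfg, augment = augment)
    ev <- evaluate(model, subset_images(images, split$validation),
                   labels = current$labels[split$validation])
    gs <- select_genes(model, subset_images(images, split$train),
                       labels = current$labels[split$train],
                       pixel_map = pm, threshold = threshold)
    gs$stage <- st
    gs$pixel_map <- pm
    gs$model <- model
    gs$eval <- ev
    out[[st]] <- gs
    if (!length(gs$union)) break
    current <- subset_genes(current, gs$union)
  }
  out
}
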