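#' Fit the log/min-max ("norm-2") normalization on training samples
#'
#' Per layer: values are shifted by the training minimum, log-transformed
#' (`y = ln(x - min_train + 1)`), then scaled to `[0, 1]` by the global
#' training extremes of `y`. Validation/test values are clipped into the
#' training range before the log and into `[0, 1]` after scaling, so the
#' statistics never leak information from held-out samples.
#'
#' @param x An [omics_matrix()] or numeric matrix of TRAINING samples.
#' @return A `norm_stats` object (shift, y-range, layer name).
#' @export
fit_norm <- function(x) {
  m <- if (inherits(x, "omics_matrix")) x$values else x
  layer <- if (inherits(x, "omics_matrix")) x$layer_name else NA_character_
  shift <- min(m)
  y <- log(m - shift + 1)
  if (!all(is.finite(y))) {
    bad <- which(!is.finite(y), arr.ind = TRUE)[1L, 1L]
    abort(paste0("non-finite value after log transform at gene ",
                 rownames(m)[bad] %||% bad))
  }
  ymin <- min(y); ymax <- max(y)
  if (ymax <= ymin) {
    # a constant layer can arise when an iterative stage keeps only a few
    # genes; it carries no information and maps to the background value
    warn(paste0("layer ", layer %||% "", " is constant on the training samples; ",
                "all its values will normalize to 0."))
    ymax <- ymin + 1
  }
  structure(list(layer = layer, shift = shift, ymin = ymin, ymax = ymax,
                 scheme = "norm-2"),
            class = "norm_stats")
}

#' @rdname fit_norm
#' @param stats_obj A `norm_stats` fitted by [fit_norm()].
#' @return `apply_norm()`: matrix of the same shape with values in `[0, 1]`.
#' @export
apply_norm <- function(x, stats_obj) {
  stopifnot(inherits(stats_obj, "norm_stats"))
  m <- if (inherits(x, "omics_matrix")) x$values else x
  y <- log(pmax(m, stats_obj$shift) - stats_obj$shift + 1)
  z <- (y - stats_obj$ymin) / (stats_obj$ymax - stats_obj$ymin)
  z[z < 0] <- 0
  z[z > 1] <- 1
  z
}

#' Fit normalization statistics for every layer of a dataset
#'
#' @param dataset A `multiomics_dataset` restricted to training samples.
#' @return Named list of `norm_stats`, one per layer.
#' @export
fit_norm_dataset <- function(dataset) {
  lapply(dataset$layers, fit_norm)
}

#' Map one normalized sample vector onto the pixel frame
#'
#' Every gene deposits its value at its assigned pixel; when several genes
#' share a pixel ("batch genes") the pixel takes their arithmetic mean.
#' Unoccupied pixels keep the background value 0.
#'
#' @param values Numeric vector of length d (one layer of one sample,
#'   normalized), in pixel-map gene order or named by gene id.
#' @param pixel_map A `pixel_map`.
#' @return List with `image` (p x q matrix) and `occupancy` (p x q integer
#'   matrix of gene counts per pixel).
#' @export
map_to_image <- function(values, pixel_map) {
  p <- attr(pixel_map, "frame_rows"); q <- attr(pixel_map, "frame_cols")
  if (!is.null(names(values))) values <- values[pixel_map$gene]
  if (length(values) != nrow(pixel_map)) {
    abort("`values` length does not match the number of mapped genes.")
  }
  idx <- pixel_map$row + 1L + pixel_map$col * p  # column-major flat index
  cnt <- tabulate(idx, nbins = p * q)
  sums <- numeric(p * q)
  agg <- rowsum(values, group = idx)
  sums[as.integer(rownames(agg))] <- agg[, 1L]
  img <- sums
  img[cnt > 0L] <- img[cnt > 0L] / cnt[cnt > 0L]
  list(image = matrix(img, p, q), occupancy = matrix(cnt, p, q))
}

#' Build the shared pixel map for a multi-omics dataset
#'
#' In `"dominant"` mode the arrangement transform is applied once, to the
#' named dominant layer (typically expression, the most informative layer),
#' and all layers are later mapped onto those common pixel locations. In
#' `"equal"` mode the arrangement is performed twice: each layer is embedded
#' separately, then the per-gene concatenation of the stage-1 coordinates
#' (a 2L-dimensional point per gene) is embedded again to a single 2D layout.
#' Either way the layout is completed by the minimum-area bounding rectangle,
#' rotation to the axes, and pixel quantization.
#'
#' @param dataset A `multiomics_dataset` restricted to TRAINING samples.
#' @param mode `"dominant"` or `"equal"`.
#' @param dominant_layer Layer name used in dominant mode.
#' @param frame Integer vector `c(p, q)` (or one integer for a square frame).
#' @param method,distance,seed,perplexity Passed to [arrange_elements()].
#' @return A `pixel_map`.
#' @export
build_pixel_map <- function(dataset, mode = c("dominant", "equal"),
                            dominant_layer = "expression", frame = c(64L, 64L),
                            method = "tsne", distance = "cosine", seed = 1L,
                            perplexity = NULL) {
  mode <- match.arg(mode)
  if (length(frame) == 1L) frame <- c(frame, frame)
  emb <- if (mode == "dominant" || length(dataset$layers) == 1L) {
    if (mode == "dominant" && !dominant_layer %in% names(dataset$layers)) {
      abort(paste0("unknown dominant layer '", dominant_layer, "'."))
    }
    lay <- if (mode == "dominant") dataset$layers[[dominant_layer]] else dataset$layers[[1L]]
    arrange_elements(lay, method = method, distance = distance,
                     seed = seed, perplexity = perplexity)
  } else {
    stage1 <- lapply(seq_along(dataset$layers), function(i) {
      e <- arrange_elements(dataset$layers[[i]], method = method,
                            distance = distance, seed = seed + i - 1L,
                            perplexity = perplexity)
      cbind(e$x, e$y)
    })
    concat <- do.call(cbind, stage1)
    rownames(concat) <- dataset_genes(dataset)
    arrange_elements(concat, method = method, distance = distance,
                     seed = seed, perplexity = perplexity)
  }
  rect <- min_area_rectangle(emb)
  rot <- rotate_to_axes(emb, rect$angle)
  pm <- quantize_to_pixels(rot, p = frame[1L], q = frame[2L])
  new_pixel_map(
    tibble(gene = pm$gene, row = pm$row, col = pm$col),
    p = frame[1L], q = frame[2L], embedding = emb,
    source_mode = mode,
    dominant_layer = if (mode == "dominant") dominant_layer else NA_character_,
    rotation_angle = rect$angle, method = method, seed = seed
  )
}

#' Transform a dataset into multi-channel images
#'
#' Applies the per-layer normalization and maps every layer of every sample
#' onto the common pixel locations, yielding one p x q x L tensor per sample
#' with values in `[0, 1]`.
#'
#' @param dataset A `multiomics_dataset` (any split; the pixel map and norm
#'   stats must come from the training portion).
#' @param pixel_map A `pixel_map` built by [build_pixel_map()].
#' @param norm_stats Named list from [fit_norm_dataset()] (training fit).
#' @return An `image_set`: list with `values` (p x q x L x n array),
#'   `sample_ids`, `layer_names`, `occupancy` (p x q gene counts, shared by
#'   all samples) and `labels` carried over from the dataset.
#' @export
transform_dataset <- function(dataset, pixel_map, norm_stats) {
  genes <- dataset_genes(dataset)
  if (!setequal(genes, pixel_map$gene)) {
    abort("dataset genes do not match the pixel map.")
  }
  p <- attr(pixel_map, "frame_rows"); q <- attr(pixel_map, "frame_cols")
  L <- length(dataset$layers); n <- length(dataset_samples(dataset))
  vals <- array(0, dim = c(p, q, L, n))
  occupancy <- NULL
  for (l in seq_len(L)) {
    lay <- dataset$layers[[l]]
    ns <- norm_stats[[lay$layer_name]] %||% norm_stats[[l]]
    if (is.null(ns)) abort(paste0("no norm stats for layer '", lay$layer_name, "'."))
    z <- apply_norm(lay, ns)
    for (j in seq_len(n)) {
      mp <- map_to_image(z[pixel_map$gene, j], pixel_map)
      vals[, , l, j] <- mp$image
      occupancy <- occupancy %||% mp$occupancy
    }
  }
  structure(
    list(values = vals, sample_ids = dataset_samples(dataset),
         layer_names = names(dataset$layers), occupancy = occupancy,
         labels = dataset$labels, frame = c(p, q)),
    class = "image_set"
  )
}

#' @export
print.image_set <- function(x, ...) {
  d <- dim(x$values)
  cat("<image_set> ", d[4L], " images of ", d[1L], " x ", d[2L], " x ", d[3L],
      " [", paste(x$layer_names, collapse = ", "), "]\n", sep = "")
  invisible(x)
}

#' Extract one sample's image tensor
#'
#' @param images An `image_set`.
#' @param sample Sample id or index.
#' @return List with `sample_id`, `values` (p x q x L) and `occupancy`.
#' @export
get_image <- function(images, sample) {
  j <- if (is.character(sample)) match(sample, images$sample_ids) else sample
  if (is.na(j) || j < 1L || j > length(images$sample_ids)) abort("unknown sample.")
  list(sample_id = images$sample_ids[j],
       values = images$values[, , , j, drop = FALSE][, , , 1L],
       occupancy = images$occupancy)
}

#' Restrict an image set to a subset of samples
#'
#' @param images An `image_set`.
#' @param idx Sample ids or indices.
#' @return An `image_set` over the subset.
#' @export
subset_images <- function(images, idx) {
  if (is.character(idx)) idx <- match(idx, images$sample_ids)
  structure(
    list(values = images$values[, , , idx, drop = FALSE],
         sample_ids = images$sample_ids[idx],
         layer_names = images$layer_names, occupancy = images$occupancy,
         labels = if (!is.null(images$labels)) images$labels[idx],
         frame = images$frame),
    class = "image_set"
  )
}

#' @export
autoplot.image_set <- function(object, sample = 1L, ...) {
  img <- get_image(object, sample)
  df <- do.call(rbind, lapply(seq_along(object$layer_names), function(l) {
    m <- if (length(dim(img$values)) == 3L) img$values[, , l] else img$values
    tibble(
      row = as.vector(row(m)) - 1L, col = as.vector(col(m)) - 1L,
      value = as.vector(m), layer = object$layer_names[l]
    )
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_wrap(~layer) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = paste("Sample", img$sample_id)) +
    ggplot2::theme_minimal()
}

#' Write an image set to disk
#'
#' `"rds"` stores the full-precision tensor per sample (lossless round trip);
#' `"png"` writes an 8-bit image and is limited to at most 4 channels
#' (grayscale / RGB / RGBA).
#'
#' @param images An `image_set`.
#' @param dir Output directory (created if needed).
#' @param format `"rds"` or `"png"`.
#' @return Manifest tibble (`sample_id`, `file`); also written to
#'   `manifest.json` in `dir`.
#' @export
write_images <- function(images, dir, format = c("rds", "png")) {
  format <- match.arg(format)
  L <- dim(images$values)[3L]
  if (format == "png" && L > 4L) {
    abort("png supports at most 4 channels; use format = \"rds\".")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(images$sample_ids))
  for (j in seq_along(images$sample_ids)) {
    fn <- file.path(dir, paste0(images$sample_ids[j], ".", format))
    arr <- images$values[, , , j, drop = FALSE][, , , 1L, drop = TRUE]
    if (format == "rds") {
      saveRDS(arr, fn)
    } else {
      png::writePNG(if (L == 1L) matrix(arr, images$frame[1L]) else arr, fn)
    }
    files[j] <- fn
  }
  manifest <- tibble(sample_id = images$sample_ids, file = files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}

#' Read an image set back from a manifest
#'
#' @param dir Directory containing `manifest.json` written by [write_images()].
#' @param layer_names Optional channel names to attach.
#' @return An `image_set` (labels are not stored on disk and come back NULL).
#' @export
read_images <- function(dir, layer_names = NULL) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  if (!nrow(manifest)) abort("empty manifest.")
  read_one <- function(fn) {
    if (grepl("\\.rds$", fn)) readRDS(fn) else png::readPNG(fn)
  }
  first <- read_one(manifest$file[1L])
  if (length(dim(first)) == 2L) first <- array(first, c(dim(first), 1L))
  d <- dim(first)
  vals <- array(0, dim = c(d[1L], d[2L], d[3L], nrow(manifest)))
  vals[, , , 1L] <- first
  for (j in seq_len(nrow(manifest))[-1L]) {
    a <- read_one(manifest$file[j])
    if (length(dim(a)) == 2L) a <- array(a, c(dim(a), 1L))
    vals[, , , j] <- a
  }
  structure(
    list(values = vals, sample_ids = manifest$sample_id,
         layer_names = layer_names %||% paste0("layer", seq_len(d[3L])),
         occupancy = NULL, labels = NULL, frame = d[1:2]),
    class = "image_set"
  )
}
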