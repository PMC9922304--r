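#' Arrange genes as points in the plane
#'
#' The arrangement step of the data-to-image transform: the training matrix
#' is embedded with genes as observations and samples as features (i.e. the
#' transpose of the samples x genes table), so that co-expressed genes land
#' close together in the 2D frame. Must be run on the training portion only;
#' the resulting layout is frozen and reused for validation/test samples.
#'
#' @param x An [omics_matrix()] (training samples only) or a plain numeric
#'   matrix with genes as rows.
#' @param method Embedding method: `"tsne"` (exact t-SNE), `"umap"`,
#'   `"kpca"` (Gaussian kernel PCA) or `"pca"`.
#' @param distance Point-pair metric for t-SNE: `"cosine"` (default) or
#'   `"euclidean"`. Ignored by the other methods.
#' @param seed Integer seed; the embedding is deterministic given the seed.
#' @param perplexity t-SNE perplexity; defaults to `min(30, (d - 1) / 3)`.
#' @return An `embedding2d`: tibble with columns `gene`, `x`, `y`, plus
#'   `method`, `distance` and `seed` attributes.
#' @export
arrange_elements <- function(x, method = c("tsne", "umap", "kpca", "pca"),
                             distance = c("cosine", "euclidean"),
                             seed = 1L, perplexity = NULL) {
  method <- match.arg(method)
  distance <- match.arg(distance)
  m <- if (inherits(x, "omics_matrix")) x$values else x
  if (!is.matrix(m)) abort("`x` must be an omics_matrix or numeric matrix.")
  d <- nrow(m); n <- ncol(m)
  if (d < 3L || n < 3L) abort("need at least 3 genes and 3 samples (d > 2, n > 2).")
  if (all(m == m[1L])) abort("degenerate all-constant matrix: no arrangement possible.")
  ids <- rownames(m) %||% paste0("g", seq_len(d))
  coords <- switch(method,
    pca = {
      pc <- prcomp(m, center = TRUE, scale. = FALSE, rank. = 2L)
      sc <- pc$x
      if (ncol(sc) < 2L) sc <- cbind(sc, 0)
      sc[, 1:2, drop = FALSE]
    },
    kpca = {
      set.seed(seed)
      kp <- kernlab::kpca(m, kernel = "rbfdot", features = 2L)
      rot <- kernlab::rotated(kp)
      if (ncol(rot) < 2L) rot <- cbind(rot, 0)
      rot[, 1:2, drop = FALSE]
    },
    tsne = {
      perplexity <- perplexity %||% min(30, (d - 1) / 3)
      dd <- if (distance == "cosine") cosine_dist(m) else as.matrix(stats::dist(m))
      set.seed(seed)
      fit <- Rtsne::Rtsne(
        stats::as.dist(dd), dims = 2L, perplexity = perplexity,
        theta = 0, max_iter = 500L, verbose = FALSE,
        check_duplicates = FALSE, is_distance = TRUE
      )
      fit$Y
    },
    umap = {
      set.seed(seed)
      uwot::umap(m, n_components = 2L, n_threads = 1L, n_sgd_threads = 1L,
                 seed = seed, metric = if (distance == "cosine") "cosine" else "euclidean")
    }
  )
  out <- tibble(gene = unname(ids), x = unname(coords[, 1L]),
                y = unname(coords[, 2L]))
  structure(out, class = c("embedding2d", class(out)),
            method = method, distance = distance, seed = seed)
}

# cosine distance between rows; constant (zero-norm) rows get distance 1 to
# everything except identical rows
cosine_dist <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  nrm[nrm == 0] <- 1
  s <- tcrossprod(m / nrm)
  d <- 1 - s
  d[d < 0] <- 0
  diag(d) <- 0
  d
}

coords_matrix <- function(points) {
  if (is.data.frame(points)) cbind(points$x, points$y)
  else as.matrix(points)[, 1:2, drop = FALSE]
}

#' Minimum-area bounding rectangle of a point cloud
#'
#' Rotating-calipers search over convex-hull edges: the minimal-area
#' enclosing rectangle has one side collinear with a hull edge, so only hull
#' edge directions need to be examined. Collinear/degenerate clouds fall back
#' to the segment's direction with unit-thickness padding.
#'
#' @param points An `embedding2d` or two-column matrix/data frame of x, y.
#' @return List with `angle` (radians, in `[0, pi/2)`; rotating the points by
#'   `-angle` aligns the rectangle with the axes), `width`, `height`, `area`
#'   and `center`.
#' @export
min_area_rectangle <- function(points) {
  xy <- coords_matrix(points)
  if (nrow(xy) < 1L) abort("need at least one point.")
  if (nrow(xy) == 1L) {
    return(list(angle = 0, width = 1, height = 1, area = 1, center = xy[1L, ]))
  }
  hull <- grDevices::chull(xy)
  h <- xy[hull, , drop = FALSE]
  degenerate <- nrow(h) < 3L || collinear(h)
  if (degenerate) {
    # direction of maximal extent; pad thickness to 1
    i <- which.max(stats::dist(h))
    pr <- which(lower.tri(matrix(0, nrow(h), nrow(h))), arr.ind = TRUE)[i, ]
    v <- h[pr[1L], ] - h[pr[2L], ]
    ang <- atan2(v[2L], v[1L]) %% (pi / 2)
    rot <- rotate_xy(xy, -ang)
    w <- diff(range(rot[, 1L]))
    ht <- diff(range(rot[, 2L]))
    return(list(angle = ang, width = max(w, 1), height = max(ht, 1),
                area = max(w, 1) * max(ht, 1),
                center = colMeans(xy[c(pr[1L], pr[2L]), , drop = FALSE])))
  }
  edges <- cbind(seq_len(nrow(h)), c(seq_len(nrow(h))[-1L], 1L))
  best <- NULL
  for (k in seq_len(nrow(edges))) {
    v <- h[edges[k, 2L], ] - h[edges[k, 1L], ]
    ang <- atan2(v[2L], v[1L]) %% (pi / 2)
    rot <- rotate_xy(h, -ang)
    w <- diff(range(rot[, 1L]))
    ht <- diff(range(rot[, 2L]))
    area <- w * ht
    if (is.null(best) || area < best$area - 1e-12 ||
        (abs(area - best$area) <= 1e-12 && ang < best$angle)) {
      cx <- mean(range(rot[, 1L])); cy <- mean(range(rot[, 2L]))
      ctr <- rotate_xy(matrix(c(cx, cy), 1L), ang)
      best <- list(angle = ang, width = w, height = ht, area = area,
                   center = ctr[1L, ])
    }
  }
  best
}

collinear <- function(xy, tol = 1e-12) {
  if (nrow(xy) < 3L) return(TRUE)
  v1 <- xy[2L, ] - xy[1L, ]
  for (i in 3:nrow(xy)) {
    v2 <- xy[i, ] - xy[1L, ]
    if (abs(v1[1L] * v2[2L] - v1[2L] * v2[1L]) > tol) return(FALSE)
  }
  TRUE
}

# counter-clockwise rotation of row-vector points by `angle` radians
rotate_xy <- function(xy, angle) {
  r <- matrix(c(cos(angle), -sin(angle), sin(angle), cos(angle)), 2L)
  xy %*% r
}

#' Rotate embedded points so the bounding rectangle aligns with the axes
#'
#' A rigid rotation (distance preserving to machine precision) by the
#' negative of the rectangle angle found by [min_area_rectangle()].
#'
#' @param points An `embedding2d` or two-column matrix.
#' @param angle Rectangle angle in radians.
#' @return Object of the same shape with rotated coordinates.
#' @export
rotate_to_axes <- function(points, angle) {
  if (is.data.frame(points)) {
    xy <- rotate_xy(coords_matrix(points), -angle)
    points$x <- xy[, 1L]
    points$y <- xy[, 2L]
    points
  } else {
    rotate_xy(coords_matrix(points), -angle)
  }
}

#' Quantize axis-aligned coordinates to integer pixel locations
#'
#' Half-open binning with the extremes pinned to the frame edges: the minimum
#' y maps to row p-1, the maximum y to row 0 (image rows grow downward), and
#' analogously for columns; every gene gets exactly one pixel.
#'
#' @param points An `embedding2d` or two-column matrix of rotated coordinates.
#' @param p,q Frame rows and columns (positive integers).
#' @param gene_ids Gene identifiers if `points` is a bare matrix.
#' @return A `pixel_map`: tibble with `gene`, `row`, `col` (0-based) and
#'   frame metadata attributes.
#' @export
quantize_to_pixels <- function(points, p, q, gene_ids = NULL) {
  if (p < 1L || q < 1L) abort("frame dimensions must be at least 1 x 1.")
  xy <- coords_matrix(points)
  ids <- if (is.data.frame(points)) points$gene else gene_ids %||% paste0("g", seq_len(nrow(xy)))
  col <- bin_axis(xy[, 1L], q)
  row <- bin_axis(-xy[, 2L], p)  # top of the plot becomes row 0
  pm <- tibble(gene = as.character(ids), row = row, col = col)
  new_pixel_map(pm, p = p, q = q, embedding = points)
}

bin_axis <- function(v, k) {
  rng <- range(v)
  if (rng[2L] - rng[1L] <= 0) return(rep(0L, length(v)))
  idx <- floor((v - rng[1L]) / (rng[2L] - rng[1L]) * k)
  as.integer(pmin(idx, k - 1L))
}

new_pixel_map <- function(pm, p, q, embedding = NULL, source_mode = "dominant",
                          dominant_layer = NA_character_, rotation_angle = NA_real_,
                          method = NA_character_, seed = NA_integer_) {
  stopifnot(all(pm$row >= 0L & pm$row < p), all(pm$col >= 0L & pm$col < q))
  structure(pm, class = c("pixel_map", class(tibble())),
            frame_rows = as.integer(p), frame_cols = as.integer(q),
            embedding = embedding, source_mode = source_mode,
            dominant_layer = dominant_layer, rotation_angle = rotation_angle,
            method = method, seed = seed)
}

#' @export
print.pixel_map <- function(x, ...) {
  cat("<pixel_map> ", nrow(x), " genes in a ", attr(x, "frame_rows"), " x ",
      attr(x, "frame_cols"), " frame (mode: ", attr(x, "source_mode"),
      ", ", dplyr::n_distinct(x$row * attr(x, "frame_cols") + x$col),
      " occupied pixels)\n", sep = "")
  NextMethod()
}

#' Serialize / restore a pixel map as JSON
#'
#' @param pixel_map A `pixel_map`.
#' @param path JSON output path.
#' @return `path` invisibly; `read_pixel_map()` returns the `pixel_map`.
#' @export
write_pixel_map <- function(pixel_map, path) {
  obj <- list(
    frame_rows = attr(pixel_map, "frame_rows"),
    frame_cols = attr(pixel_map, "frame_cols"),
    source_mode = attr(pixel_map, "source_mode"),
    dominant_layer = attr(pixel_map, "dominant_layer"),
    rotation_angle = attr(pixel_map, "rotation_angle"),
    method = attr(pixel_map, "method"),
    seed = attr(pixel_map, "seed"),
    pixels = setNames(
      lapply(seq_len(nrow(pixel_map)), function(i) c(pixel_map$row[i], pixel_map$col[i])),
      pixel_map$gene
    )
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pixel_map
#' @export
read_pixel_map <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  px <- obj$pixels
  pm <- tibble(
    gene = names(px),
    row = unname(vapply(px, function(v) as.integer(v[[1L]]), integer(1))),
    col = unname(vapply(px, function(v) as.integer(v[[2L]]), integer(1)))
  )
  new_pixel_map(pm, p = obj$frame_rows, q = obj$frame_cols,
                source_mode = obj$source_mode,
                dominant_layer = obj$dominant_layer %||% NA_character_,
                rotation_angle = obj$rotation_angle %||% NA_real_,
                method = obj$method %||% NA_character_,
                seed = obj$seed %||% NA_integer_)
}

#' @export
autoplot.pixel_map <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_bin2d(binwidth = 1) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "column", y = "row", fill = "genes / pixel",
                  title = "Gene pixel assignments") +
    ggplot2::theme_minimal()
}
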