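make_class_cam <- function(avg_map, threshold = 0.6) {
  structure(list(class_label = "x", avg_map = avg_map, n = 1L,
                 threshold = threshold, mask = avg_map > threshold),
            class = "class_cam")
}

make_cam_result <- function(heatmap, id = "s", cl = "a") {
  structure(list(sample_id = id, heatmap = heatmap, target_class = cl),
            class = "cam_result")
}

test_that("raw CAM equals the hand-computed weighted channel sum", {
  act <- array(c(1, 2, 3, 4,   10, 20, 30, 40), c(2L, 2L, 2L))
  w <- c(0.5, -0.1)
  expect_equal(cam_from_activations(act, w),
               matrix(c(1, 2, 3, 4), 2L) * 0.5 - matrix(c(10, 20, 30, 40), 2L) * 0.1)
  expect_error(cam_from_activations(act, c(1, 2, 3)), "channels")
})

# zero out the classifier weights so every raw CAM is constant
within_model_zero_head <- function(model) {
  model$params$Wd[] <- 0
  model
}

test_that("per-sample heatmaps respect the normalization contract", {
  fx <- tiny_trained()
  cams <- compute_cam(fx$model, fx$images, target_class = "R", samples = 1:4)
  for (cm in cams) {
    expect_true(all(cm$heatmap >= 0 & cm$heatmap <= 1))
    expect_identical(dim(cm$heatmap), c(16L, 16L))
    if (diff(range(cm$heatmap)) > 0) {
      expect_equal(min(cm$heatmap), 0)
      expect_equal(max(cm$heatmap), 1)
    }
  }
  # constant head weights with zero weight vector: flat map normalizes to zeros
  flat <- compute_cam(
    within_model_zero_head(fx$model), fx$images, target_class = "R",
    samples = 1L
  )[[1L]]
  expect_true(all(flat$heatmap == 0))
})

test_that("class-averaged CAM equals the brute-force mean to 1e-12", {
  set.seed(44)
  maps <- lapply(1:6, function(i) matrix(runif(30), 5L, 6L))
  cams <- purrr::map2(maps, paste0("s", 1:6), make_cam_result)
  labels <- factor(c("a", "a", "b", "b", "b", "a"))
  ccs <- aggregate_cams(cams, labels, mode = "class_mean")
  for (cl in c("a", "b")) {
    ref <- Reduce(`+`, maps[labels == cl]) / sum(labels == cl)
    expect_lt(max(abs(ccs[[cl]]$avg_map - ref)), 1e-12)
    expect_identical(ccs[[cl]]$n, sum(labels == cl))
  }
  # two identical maps average to either one
  twin <- aggregate_cams(cams[c(1L, 1L)], factor(c("a", "a")))
  expect_identical(twin$a$avg_map, maps[[1L]])
  # elementwise mean of two maps
  ab <- aggregate_cams(cams[1:2], factor(c("a", "a")))
  expect_equal(ab$a$avg_map, (maps[[1L]] + maps[[2L]]) / 2)
  # c = 2 classes in, 2 aggregates out
  expect_length(ccs, 2L)
  # other modes
  overall <- aggregate_cams(cams, mode = "overall_mean")
  expect_length(overall, 1L)
  expect_equal(overall[[1L]]$avg_map, Reduce(`+`, maps) / 6)
  per <- aggregate_cams(cams, mode = "per_sample")
  expect_length(per, 6L)
  expect_error(aggregate_cams(cams, factor(rep("a", 2L))), "align")
})

test_that("class_max rescaling pins the strongest class average at 1", {
  maps <- list(matrix(2, 2L, 2L), matrix(c(8, 0, 0, 0), 2L))
  cams <- purrr::map2(maps, c("s1", "s2"), make_cam_result)
  ccs <- aggregate_cams(cams, factor(c("a", "b")), threshold = 0.6,
                        rescale = "class_max")
  expect_equal(max(ccs$b$avg_map), 1)
  expect_equal(ccs$a$avg_map, matrix(0.25, 2L, 2L))
  # rescaling is a shared linear map: relative structure preserved
  expect_equal(ccs$b$avg_map, maps[[2L]] / 8)
})

test_that("red-zone masks use a strict threshold", {
  m <- matrix(c(0.2, 0.9, 0.7, 0.5), 2L)
  cc <- make_class_cam(m)
  expect_identical(sum(red_zone_mask(cc, 0.6)), 2L)
  expect_identical(sum(red_zone_mask(cc, 1.0)), 0L)   # strict: nothing at 1
  expect_identical(sum(red_zone_mask(cc, 0)), 4L)      # positive map, all in
  expect_identical(red_zone_mask(cc), cc$mask)
  expect_error(red_zone_mask(cc, 1.5), "0, 1")
})

test_that("the decoder partitions genes between a mask and its complement", {
  set.seed(3)
  pm <- quantize_to_pixels(
    tibble::tibble(gene = paste0("g", 1:40), x = runif(40), y = runif(40)),
    6L, 6L
  )
  mask <- matrix(runif(36) > 0.5, 6L, 6L)
  inside <- decode_elements(mask, pm)
  outside <- decode_elements(!mask, pm)
  expect_setequal(c(inside, outside), pm$gene)
  expect_length(intersect(inside, outside), 0L)
  # totality and vacuity
  expect_setequal(decode_elements(matrix(TRUE, 6L, 6L), pm), pm$gene)
  expect_identical(decode_elements(matrix(FALSE, 6L, 6L), pm), character(0))
  expect_error(decode_elements(matrix(TRUE, 3L, 3L), pm), "shape")
})

test_that("co-located batch genes are all decoded together", {
  pm <- quantize_to_pixels(
    tibble::tibble(gene = c("a", "b", "c", "d"),
                   x = c(0, 0.01, 0.02, 1), y = c(0, 0.01, 0.02, 1)),
    3L, 3L
  )
  mask <- matrix(FALSE, 3L, 3L)
  mask[pm$row[1L] + 1L, pm$col[1L] + 1L] <- TRUE
  expect_setequal(decode_elements(mask, pm), c("a", "b", "c"))
})

test_that("raising the threshold never adds genes", {
  set.seed(9)
  pm <- quantize_to_pixels(
    tibble::tibble(gene = paste0("g", 1:50), x = runif(50), y = runif(50)),
    8L, 8L
  )
  cc <- make_class_cam(matrix(runif(64), 8L))
  prev <- decode_elements(red_zone_mask(cc, 0), pm)
  for (thr in seq(0.1, 1, by = 0.1)) {
    cur <- decode_elements(red_zone_mask(cc, thr), pm)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("select_genes reports per-class sets whose union follows set algebra", {
  fx <- tiny_trained()
  train_imgs <- subset_images(fx$images, fx$split$train)
  labs <- fx$dataset$labels[fx$split$train]
  gs <- suppressWarnings(
    select_genes(fx$model, train_imgs, labels = labs,
                 pixel_map = fx$pixel_map, threshold = 0.5)
  )
  expect_s3_class(gs, "gene_subset")
  expect_setequal(gs$union, unique(unlist(gs$per_class)))
  expect_identical(gs$counts$n_genes, lengths(gs$per_class))
  # every selected gene's pixel lies inside its class mask
  for (cl in names(gs$per_class)) {
    mask <- red_zone_mask(gs$class_cams[[cl]])
    expect_setequal(gs$per_class[[cl]], decode_elements(mask, fx$pixel_map))
  }
  td <- tidy(gs)
  expect_identical(nrow(td), sum(lengths(gs$per_class)))

  path <- withr::local_tempfile(fileext = ".tsv")
  write_gene_subset(gs, path)
  expect_true(file.exists(path))
})

test_that("disjoint and identical class masks obey union arithmetic", {
  pm <- quantize_to_pixels(
    tibble::tibble(gene = paste0("g", 1:9),
                   x = rep(c(0, 0.5, 1), 3L), y = rep(c(0, 0.5, 1), each = 3L)),
    3L, 3L
  )
  m1 <- matrix(FALSE, 3L, 3L); m1[1L, 1L] <- TRUE
  m2 <- matrix(FALSE, 3L, 3L); m2[3L, 3L] <- TRUE
  g1 <- decode_elements(m1, pm); g2 <- decode_elements(m2, pm)
  expect_length(union(g1, g2), length(g1) + length(g2))  # disjoint masks add
  expect_identical(union(g1, g1), g1)                     # identical masks idempotent
})

test_that("iterative selection chains stage outputs into stage inputs", {
  sc <- synthetic_scenario(n_per_class = 8L, d = 30L, m = 6L, delta = 4,
                           seed = 3L)
  gen <- generate_multiomics(sc)
  stages <- iterative_select(
    gen$dataset, stages = 2L, frame = c(12L, 12L), method = "pca",
    config = cnn_config(epochs = 3L, batch_size = 8L), split_ratio = 0.8,
    augment = 0, threshold = 0.4, seed = 2L
  )
  expect_lte(length(stages), 2L)
  expect_identical(stages[[1L]]$stage, 1L)
  if (length(stages) == 2L) {
    # stage 2 operated exactly on the stage-1 union
    expect_setequal(stages[[2L]]$pixel_map$gene, stages[[1L]]$union)
    expect_true(all(stages[[2L]]$union %in% stages[[1L]]$union))
  }
  expect_error(iterative_select(gen$dataset, stages = 0L), "at least 1")
})
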