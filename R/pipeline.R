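#' Default run configuration
#'
#' Full parameter set for an end-to-end run, writable as YAML. Fields mirror
#' the stages: synthetic scenario (or input paths), mutation propagation,
#' image transform, CNN training, CAM selection and enrichment.
#'
#' @param seed Master seed; every stochastic stage derives its seed from it.
#' @return Nested named list (class `run_config`).
#' @export
default_config <- function(seed = 42L) {
  structure(list(
    seed = as.integer(seed),
    data = list(source = "simulate",
                scenario = unclass(synthetic_scenario(seed = seed)),
                layers = NULL, labels = NULL, response = NULL,
                binarize = "median"),
    netprop = list(enabled = TRUE, edges = NULL, steps = 7L, weighted = FALSE),
    transform = list(mode = "dominant", dominant_layer = "expression",
                     frame = c(64L, 64L), method = "tsne",
                     distance = "cosine"),
    train = list(split_ratio = 0.9, stratified = TRUE, augment = 1,
                 epochs = 30L, batch_size = 16L, lr = 0.05, momentum = 0.9,
                 l2 = 1e-4, filters = c(8L, 16L, 32L), input_size = NULL),
    select = list(threshold = 0.6, mode = "class_mean", stages = 1L),
    enrich = list(gmt = NULL)
  ), class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_config()`: a `run_config`; `write_config()`: `path`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config(seed = cfg$seed %||% 42L)
  for (section in names(base)) {
    if (section %in% names(cfg) && is.list(base[[section]])) {
      base[[section]] <- modifyList(base[[section]], cfg[[section]])
    } else if (section %in% names(cfg)) {
      base[[section]] <- cfg[[section]]
    }
  }
  base
}

#' @rdname read_config
#' @param config A `run_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

stage_file <- function(out_dir, stage, key) {
  file.path(out_dir, paste0(stage, "-", key, ".rds"))
}

run_stage <- function(manifest, stage, out_dir, key, compute, cache = TRUE) {
  fn <- stage_file(out_dir, stage, key)
  cached <- cache && file.exists(fn)
  value <- if (cached) readRDS(fn) else compute()
  if (!cached) saveRDS(value, fn)
  manifest$stages[[stage]] <- list(artifact = fn, cached = cached,
                                   completed = TRUE,
                                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  list(manifest = manifest, value = value)
}

#' Run the full pipeline
#'
#' Executes the stages in order — data (simulate or load), mutation-layer
#' propagation, image transform, CNN training, CAM gene selection,
#' enrichment — caching every stage artifact under `out_dir` keyed by a hash
#' of the configuration, so an identical rerun reuses the cached artifacts.
#' A JSON manifest recording the config hash, per-stage artifacts and seeds
#' is written at the end (or on failure, naming the failing stage).
#'
#' @param config A `run_config` (see [default_config()], [read_config()]).
#' @param out_dir Output/cache directory.
#' @param cache Reuse cached stage artifacts when present (default `TRUE`).
#' @return A `run_manifest`: list with `config_hash`, `stages`, `results`
#'   (gene subsets, evaluation, enrichment table) and the config snapshot.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("run"),
                         cache = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  key <- substr(rlang::hash(unclass(config)), 1L, 12L)
  manifest <- list(config_hash = key, seed = config$seed,
                   package_version = as.character(utils::packageVersion("pixelomics")),
                   stages = list())
  fail <- function(stage, err) {
    manifest$failed_stage <- stage
    manifest$error <- conditionMessage(err)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    abort(paste0("pipeline failed at stage '", stage, "': ",
                 conditionMessage(err)))
  }

  # -- data ------------------------------------------------------------------
  st <- tryCatch(run_stage(manifest, "data", out_dir, key, function() {
    if (identical(config$data$source, "simulate")) {
      sc <- do.call(synthetic_scenario, config$data$scenario[
        setdiff(names(config$data$scenario), character())])
      gen <- generate_multiomics(sc)
      net <- generate_network(dataset_genes(gen$dataset),
                              topology = sc$topology,
                              attach_planted = gen$planted, seed = sc$seed)
      list(dataset = gen$dataset, planted = gen$planted, network = net)
    } else {
      layers <- purrr::imap(config$data$layers, ~read_omics_layer(.x, .y))
      labels <- if (!is.null(config$data$labels)) read_labels(config$data$labels)
      ds <- assemble_dataset(unname(layers), labels = labels)
      if (is.null(labels) && !is.null(config$data$response)) {
        resp <- read.delim(config$data$response)
        v <- setNames(as.numeric(resp[[2L]]), resp[[1L]])
        ds$labels <- binarize_response(v[dataset_samples(ds)],
                                       statistic = config$data$binarize)
        ds$response <- v[dataset_samples(ds)]
      }
      net <- if (!is.null(config$netprop$edges)) read_edge_list(config$netprop$edges)
      list(dataset = ds, planted = NULL, network = net)
    }
  }, cache = cache), error = function(e) fail("data", e))
  manifest <- st$manifest
  data <- st$value

  # -- netprop ---------------------------------------------------------------
  st <- tryCatch(run_stage(manifest, "netprop", out_dir, key, function() {
    if (isTRUE(config$netprop$enabled) && !is.null(data$network) &&
        "mutation" %in% names(data$dataset$layers)) {
      preprocess_mutation_layer(data$dataset, data$network,
                                steps = config$netprop$steps,
                                weighted = config$netprop$weighted)
    } else {
      data$dataset
    }
  }, cache = cache), error = function(e) fail("netprop", e))
  manifest <- st$manifest
  dataset <- st$value
  image_layers <- setdiff(names(dataset$layers), grep("_raw$", names(dataset$layers), value = TRUE))
  img_ds <- dataset
  img_ds$layers <- dataset$layers[image_layers]

  # -- transform -------------------------------------------------------------
  st <- tryCatch(run_stage(manifest, "transform", out_dir, key, function() {
    split <- split_train_val(img_ds$labels, ratio = config$train$split_ratio,
                             seed = config$seed,
                             stratified = config$train$stratified)
    train_ds <- subset_samples(img_ds, split$train)
    pm <- build_pixel_map(train_ds, mode = config$transform$mode,
                          dominant_layer = config$transform$dominant_layer,
                          frame = config$transform$frame,
                          method = config$transform$method,
                          distance = config$transform$distance,
                          seed = config$seed)
    ns <- fit_norm_dataset(train_ds)
    images <- transform_dataset(img_ds, pm, ns)
    list(split = split, pixel_map = pm, norm_stats = ns, images = images)
  }, cache = cache), error = function(e) fail("transform", e))
  manifest <- st$manifest
  tr <- st$value

  # -- train -----------------------------------------------------------------
  st <- tryCatch(run_stage(manifest, "train", out_dir, key, function() {
    cfg <- cnn_config(epochs = config$train$epochs,
                      batch_size = config$train$batch_size,
                      lr = config$train$lr, momentum = config$train$momentum,
                      l2 = config$train$l2, filters = config$train$filters,
                      input_size = config$train$input_size, seed = config$seed)
    model <- train_cnn(tr$images, split = tr$split, config = cfg,
                       augment = config$train$augment)
    ev <- evaluate(model, subset_images(tr$images, tr$split$validation),
                   labels = img_ds$labels[tr$split$validation])
    list(model = model, eval = ev)
  }, cache = cache), error = function(e) fail("train", e))
  manifest <- st$manifest
  trained <- st$value

  # -- select ----------------------------------------------------------------
  st <- tryCatch(run_stage(manifest, "select", out_dir, key, function() {
    if (config$select$stages > 1L) {
      iterative_select(img_ds, stages = config$select$stages,
                       frame = config$transform$frame,
                       mode = config$transform$mode,
                       dominant_layer = config$transform$dominant_layer,
                       method = config$transform$method,
                       distance = config$transform$distance,
                       config = cnn_config(epochs = config$train$epochs,
                                           batch_size = config$train$batch_size,
                                           lr = config$train$lr,
                                           momentum = config$train$momentum,
                                           l2 = config$train$l2,
                                           filters = config$train$filters,
                                           seed = config$seed),
                       split_ratio = config$train$split_ratio,
                       augment = config$train$augment,
                       threshold = config$select$threshold,
                       seed = config$seed)
    } else {
      gs <- select_genes(trained$model,
                         subset_images(tr$images, tr$split$train),
                         labels = img_ds$labels[tr$split$train],
                         pixel_map = tr$pixel_map,
                         threshold = config$select$threshold,
                         mode = config$select$mode)
      list(gs)
    }
  }, cache = cache), error = function(e) fail("select", e))
  manifest <- st$manifest
  subsets <- st$value
  final <- subsets[[length(subsets)]]

  # -- enrich ----------------------------------------------------------------
  st <- tryCatch(run_stage(manifest, "enrich", out_dir, key, function() {
    collection <- if (!is.null(config$enrich$gmt)) {
      read_gmt(config$enrich$gmt)
    } else if (!is.null(data$planted)) {
      list(planted_module = data$planted)
    }
    if (is.null(collection) || !length(final$union)) return(NULL)
    fisher_enrichment(final$union, collection,
                      universe = dataset_genes(img_ds))
  }, cache = cache), error = function(e) fail("enrich", e))
  manifest <- st$manifest

  manifest$results <- list(
    validation_auc = trained$eval$auc,
    n_selected = length(final$union),
    stages_run = length(subsets)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  structure(
    c(manifest, list(out_dir = out_dir, config = config,
                     gene_subsets = subsets, eval = trained$eval,
                     model = trained$model, pixel_map = tr$pixel_map,
                     split = tr$split, enrichment = st$value,
                     planted = data$planted)),
    class = "run_manifest"
  )
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest> config ", x$config_hash, " (seed ", x$seed, ")\n", sep = "")
  for (nm in names(x$stages)) {
    cat("  ", format(nm, width = 10), if (x$stages[[nm]]$cached) "[cached]" else "[run]   ",
        " ", x$stages[[nm]]$artifact, "\n", sep = "")
  }
  cat("  validation AUC ", sprintf("%.3f", x$results$validation_auc),
      "; ", x$results$n_selected, " genes selected\n", sep = "")
  invisible(x)
}
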