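#' Construct a single-layer omics matrix
#'
#' An `omics_matrix` holds one omics layer as a genes x samples numeric
#' matrix with unique gene and sample identifiers. It is the unit of input
#' for the image transform: rows are elements (genes), columns are samples.
#'
#' @param values Numeric matrix, d genes x n samples. Row names are taken as
#'   gene identifiers and column names as sample identifiers unless
#'   `gene_ids` / `sample_ids` are given.
#' @param layer_name Label for the layer, e.g. `"expression"`, `"cna"`,
#'   `"mutation"`.
#' @param gene_ids,sample_ids Optional identifier vectors overriding dimnames.
#' @param impute One of `"none"` (non-finite values are an error) or
#'   `"median"` (per-gene median imputation of missing entries).
#'
#' @return An `omics_matrix` object.
#' @export
omics_matrix <- function(values, layer_name, gene_ids = NULL,
                         sample_ids = NULL, impute = c("none", "median")) {
  impute <- match.arg(impute)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (genes x samples).")
  }
  gene_ids <- as.character(gene_ids %||% rownames(values))
  sample_ids <- as.character(sample_ids %||% colnames(values))
  if (length(gene_ids) != nrow(values) || anyNA(gene_ids)) {
    abort("gene identifiers missing or of wrong length.")
  }
  if (length(sample_ids) != ncol(values) || anyNA(sample_ids)) {
    abort("sample identifiers missing or of wrong length.")
  }
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g)) {
    abort(paste0("duplicate gene id(s): ", paste(head(dup_g, 5), collapse = ", ")))
  }
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s)) {
    abort(paste0("duplicate sample id(s): ", paste(head(dup_s, 5), collapse = ", ")))
  }
  if (!all(is.finite(values))) {
    if (impute == "median") {
      for (i in which(!apply(is.finite(values), 1L, all))) {
        bad <- !is.finite(values[i, ])
        med <- median(values[i, !bad])
        if (!is.finite(med)) {
          abort(paste0("gene ", gene_ids[i], " has no finite values to impute from."))
        }
        values[i, bad] <- med
      }
    } else {
      bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
      abort(paste0(
        "non-finite value at gene ", gene_ids[bad[1L]], ", sample ",
        sample_ids[bad[2L]], " (use impute = \"median\" to impute)."
      ))
    }
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(
    list(layer_name = as.character(layer_name), values = values),
    class = "omics_matrix"
  )
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(
    "<omics_matrix> layer '", x$layer_name, "': ", nrow(x$values),
    " genes x ", ncol(x$values), " samples\n",
    sep = ""
  )
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

gene_ids <- function(x) rownames(x$values)
sample_ids <- function(x) colnames(x$values)

#' Read one omics layer from a delimited file
#'
#' Expects a header row of sample identifiers and a first column of gene
#' identifiers; the delimiter is inferred from the extension (`.csv` gives
#' comma, anything else tab).
#'
#' @param path File path.
#' @param layer_name Layer label to attach.
#' @param impute Passed to [omics_matrix()].
#' @return An [omics_matrix()].
#' @export
read_omics_layer <- function(path, layer_name, impute = c("none", "median")) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L) abort("expected a gene-id column plus at least one sample column.")
  ids <- df[[1L]]
  num <- suppressWarnings(vapply(df[-1L], as.numeric, numeric(nrow(df))))
  if (nrow(df) == 1L) num <- matrix(num, nrow = 1L, dimnames = list(NULL, names(df)[-1L]))
  bad <- which(is.na(num) & df[-1L] != "NA" & df[-1L] != "", arr.ind = TRUE)
  if (nrow(bad)) {
    abort(paste0(
      "non-numeric cell at gene ", ids[bad[1L, 1L]], ", sample ",
      colnames(num)[bad[1L, 2L]], " in ", path
    ))
  }
  omics_matrix(num, layer_name, gene_ids = ids,
               sample_ids = colnames(num), impute = impute)
}

#' Write one omics layer to a delimited file
#'
#' Full-precision inverse of [read_omics_layer()]: values are written with 17
#' significant digits so that a write/read round trip is bit-identical.
#'
#' @param x An [omics_matrix()].
#' @param path Output path; `.csv` selects comma separation, otherwise tab.
#' @return `path`, invisibly.
#' @export
write_omics_layer <- function(x, path) {
  stopifnot(inherits(x, "omics_matrix"))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(
    gene_id = gene_ids(x),
    format(x$values, digits = 17, trim = TRUE, scientific = FALSE),
    check.names = FALSE
  )
  names(df) <- c("gene_id", sample_ids(x))
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble aligned omics layers into a multi-omics dataset
#'
#' All layers must cover the same gene and sample identifier sets. Layers
#' whose ordering differs from the first layer but whose id sets match are
#' silently reindexed to the first layer's order; genuine id-set mismatches
#' are an error listing the symmetric difference.
#'
#' @param layers List of [omics_matrix()] objects (length L >= 1).
#' @param labels Optional per-sample class labels (named by sample id, or in
#'   sample order). Coerced to factor.
#' @param response Optional per-sample continuous response (e.g. logIC50),
#'   same conventions as `labels`.
#' @return A `multiomics_dataset`: named list of aligned layers plus labels.
#' @export
assemble_dataset <- function(layers, labels = NULL, response = NULL) {
  if (inherits(layers, "omics_matrix")) layers <- list(layers)
  if (!length(layers)) abort("need at least one layer.")
  stopifnot(all(vapply(layers, inherits, logical(1), "omics_matrix")))
  ref_g <- gene_ids(layers[[1L]])
  ref_s <- sample_ids(layers[[1L]])
  layers <- lapply(layers, function(l) {
    sd_g <- c(setdiff(ref_g, gene_ids(l)), setdiff(gene_ids(l), ref_g))
    sd_s <- c(setdiff(ref_s, sample_ids(l)), setdiff(sample_ids(l), ref_s))
    if (length(sd_g) || length(sd_s)) {
      abort(paste0(
        "layer '", l$layer_name, "' id sets differ from layer '",
        layers[[1L]]$layer_name, "'; symmetric difference: ",
        paste(head(c(sd_g, sd_s), 10L), collapse = ", ")
      ))
    }
    l$values <- l$values[ref_g, ref_s, drop = FALSE]
    l
  })
  names(layers) <- vapply(layers, `[[`, character(1), "layer_name")
  if (anyDuplicated(names(layers))) abort("duplicate layer names.")
  align_vec <- function(v, what) {
    if (is.null(v)) return(NULL)
    if (!is.null(names(v))) {
      miss <- setdiff(ref_s, names(v))
      if (length(miss)) abort(paste0(what, " missing for sample(s): ",
                                     paste(head(miss, 5), collapse = ", ")))
      v <- v[ref_s]
    } else if (length(v) != length(ref_s)) {
      abort(paste0(what, " must have one entry per sample."))
    }
    setNames(v, ref_s)
  }
  labels <- align_vec(labels, "labels")
  if (!is.null(labels)) labels <- factor(labels)
  response <- align_vec(response, "response")
  structure(
    list(layers = layers, labels = labels, response = response),
    class = "multiomics_dataset"
  )
}

#' @export
print.multiomics_dataset <- function(x, ...) {
  d <- dim(x$layers[[1L]]$values)
  cat("<multiomics_dataset> ", length(x$layers), " layer(s) [",
      paste(names(x$layers), collapse = ", "), "], ",
      d[1L], " genes x ", d[2L], " samples",
      if (!is.null(x$labels)) paste0(", ", nlevels(x$labels), " classes"),
      "\n", sep = "")
  invisible(x)
}

#' Gene and sample identifiers of a dataset
#'
#' @param dataset A `multiomics_dataset`.
#' @return Character vector of ids, in dataset order.
#' @export
dataset_genes <- function(dataset) gene_ids(dataset$layers[[1L]])

#' @rdname dataset_genes
#' @export
dataset_samples <- function(dataset) sample_ids(dataset$layers[[1L]])

#' Restrict a dataset to a gene subset
#'
#' @param dataset A `multiomics_dataset`.
#' @param genes Character vector of gene ids to keep (order preserved as given).
#' @return A `multiomics_dataset` over the subset.
#' @export
subset_genes <- function(dataset, genes) {
  genes <- as.character(genes)
  miss <- setdiff(genes, dataset_genes(dataset))
  if (length(miss)) abort(paste0("unknown gene id(s): ",
                                 paste(head(miss, 5), collapse = ", ")))
  layers <- lapply(dataset$layers, function(l) {
    l$values <- l$values[genes, , drop = FALSE]
    l
  })
  structure(list(layers = layers, labels = dataset$labels,
                 response = dataset$response),
            class = "multiomics_dataset")
}

#' Restrict a dataset to a sample subset
#'
#' @param dataset A `multiomics_dataset`.
#' @param samples Character vector of sample ids to keep.
#' @return A `multiomics_dataset` over the subset.
#' @export
subset_samples <- function(dataset, samples) {
  samples <- as.character(samples)
  miss <- setdiff(samples, dataset_samples(dataset))
  if (length(miss)) abort(paste0("unknown sample id(s): ",
                                 paste(head(miss, 5), collapse = ", ")))
  layers <- lapply(dataset$layers, function(l) {
    l$values <- l$values[, samples, drop = FALSE]
    l
  })
  structure(list(
    layers = layers,
    labels = if (!is.null(dataset$labels)) dataset$labels[samples],
    response = if (!is.null(dataset$response)) dataset$response[samples]
  ), class = "multiomics_dataset")
}

#' Read per-sample labels from a two-column file
#'
#' @param path Two-column TSV (sample_id, class), with header.
#' @return Named factor of class labels.
#' @export
read_labels <- function(path) {
  df <- read.delim(path, sep = "\t", colClasses = "character")
  if (ncol(df) < 2L) abort("expected columns: sample_id, class.")
  setNames(factor(df[[2L]]), df[[1L]])
}

#' Write per-sample labels
#'
#' @param labels Named vector/factor of class labels (names are sample ids).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  write.table(
    data.frame(sample_id = names(labels), class = as.character(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
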