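#' Construct a protein-protein interaction network
#'
#' @param edges Data frame or tibble with columns `from`, `to` and optional
#'   `weight` (confidence). Self-loops are dropped; the graph is undirected
#'   and simplified.
#' @param nodes Optional extra node ids to include as isolated vertices.
#' @return An `interaction_network` (an igraph graph with a class tag and
#'   connected-component labels precomputed).
#' @export
interaction_network <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges)
  if (ncol(edges) < 2L) abort("edge list needs at least two columns (from, to).")
  names(edges)[1:2] <- c("from", "to")
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges <- edges[edges$from != edges$to, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = unique(c(edges$from, edges$to, as.character(nodes %||% character())))
  )
  g <- igraph::simplify(g, edge.attr.comb = "max")
  comp <- igraph::components(g)
  igraph::V(g)$component <- comp$membership
  class(g) <- c("interaction_network", class(g))
  g
}

#' Read / write an interaction edge list
#'
#' Tab-separated columns: gene_a, gene_b and an optional confidence weight.
#'
#' @param path Edge-list TSV path.
#' @return `read_edge_list()`: an [interaction_network()].
#' @export
read_edge_list <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, colClasses = "character")
  if (ncol(df) >= 3L) df[[3L]] <- as.numeric(df[[3L]])
  names(df)[1:2] <- c("from", "to")
  if (ncol(df) >= 3L) names(df)[3L] <- "weight"
  interaction_network(df)
}

#' @rdname read_edge_list
#' @param network An `interaction_network`.
#' @return `write_edge_list()`: `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  df <- igraph::as_data_frame(network, what = "edges")
  names(df)[1:2] <- c("gene_a", "gene_b")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Diffusion state distance (DSD) matrix of a network
#'
#' For a b-step simple random walk started at node u, `He_b(u)` is the vector
#' of expected visit counts over all nodes, counting the start visit:
#' `He_b(u) = sum_{t=0}^{b} e_u' P^t` with `P` the (uniform) transition
#' matrix. The diffusion state distance is the L1 distance between these
#' profiles, `DSD(u, v) = ||He_b(u) - He_b(v)||_1`, which satisfies the
#' metric axioms because it is an L1 norm of a linear map. Distances are
#' computed within connected components; node pairs in different components
#' (and isolated nodes) get `Inf`.
#'
#' @param network An [interaction_network()].
#' @param steps Number of walk steps b (default 7), or `"converged"` for the
#'   closed-form limit `||(e_u - e_v)' (I - P + W)^{-1}||_1`, where each row
#'   of `W` is the stationary distribution.
#' @param weighted Use edge weights for walk transition probabilities
#'   (default `FALSE`: uniform over neighbors).
#' @return A `dsd_matrix`: symmetric matrix with zero diagonal, plus a
#'   `steps` attribute.
#' @export
compute_dsd <- function(network, steps = 7L, weighted = FALSE) {
  nodes <- igraph::V(network)$name
  n <- length(nodes)
  D <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(D) <- 0
  comp <- igraph::components(network)
  for (ci in seq_len(comp$no)) {
    members <- which(comp$membership == ci)
    if (length(members) < 2L) next
    sg <- igraph::induced_subgraph(network, members)
    A <- igraph::as_adjacency_matrix(
      sg, sparse = FALSE,
      attr = if (weighted && "weight" %in% igraph::edge_attr_names(sg)) "weight" else NULL
    )
    P <- A / rowSums(A)
    m <- nrow(P)
    if (identical(steps, "converged")) {
      deg <- rowSums(A)
      pi_s <- deg / sum(deg)
      W <- matrix(pi_s, m, m, byrow = TRUE)
      H <- solve(diag(m) - P + W)
    } else {
      steps <- as.integer(steps)
      if (steps < 0L) abort("`steps` must be non-negative or \"converged\".")
      H <- diag(m)
      acc <- diag(m)
      for (t in seq_len(steps)) {
        acc <- acc %*% P
        H <- H + acc
      }
    }
    Dm <- as.matrix(stats::dist(H, method = "manhattan"))
    D[members, members] <- Dm
  }
  structure(D, class = c("dsd_matrix", "matrix", "array"),
            steps = if (identical(steps, "converged")) "converged" else as.integer(steps))
}

#' Propagate a binary mutation vector over the network
#'
#' Mutated genes keep the highest possible score (1). Every other in-network
#' gene gets the inverse of its DSD to the closest mutated gene, normalized
#' by the largest finite inverse among non-mutated genes and scaled to
#' `[0, 0.99]`, so that actual mutations always remain strictly above
#' propagated scores. Genes disconnected from all mutated genes score 0;
#' genes absent from the network keep their raw binary value.
#'
#' @param mutations Binary vector named by gene id (1 = mutated).
#' @param dsd A `dsd_matrix` from [compute_dsd()].
#' @return Numeric vector of scores in `[0, 1]`, same names and order.
#' @export
propagate_mutations <- function(mutations, dsd) {
  if (is.null(names(mutations))) abort("`mutations` must be named by gene id.")
  genes <- names(mutations)
  scores <- as.numeric(mutations != 0)
  if (!any(scores > 0)) {
    warn("all-zero mutation vector: no propagation possible.")
    return(setNames(numeric(length(genes)), genes))
  }
  in_net <- genes %in% rownames(dsd)
  mut_net <- genes[in_net & scores > 0]
  nonmut_net <- genes[in_net & scores == 0]
  if (length(mut_net) && length(nonmut_net)) {
    dmin <- apply(dsd[nonmut_net, mut_net, drop = FALSE], 1L, min)
    inv <- ifelse(is.finite(dmin) & dmin > 0, 1 / dmin,
                  ifelse(dmin == 0, Inf, 0))
    fin <- inv[is.finite(inv) & inv > 0]
    if (length(fin)) {
      top <- max(fin)
      sc <- ifelse(is.infinite(inv), 0.99, inv / top * 0.99)
      scores[match(nonmut_net, genes)] <- sc
    } else {
      scores[match(nonmut_net, genes)][is.infinite(inv)] <- 0.99
    }
  }
  setNames(pmin(pmax(scores, 0), 1), genes)
}

#' Replace the sparse mutation layer by propagated scores
#'
#' Applies [propagate_mutations()] sample by sample, replacing the named
#' binary layer; the original binary layer is retained alongside under
#' `<layer>_raw` for audit.
#'
#' @param dataset A `multiomics_dataset` with a binary mutation layer.
#' @param network An [interaction_network()].
#' @param layer Name of the binary layer (default `"mutation"`).
#' @param steps,weighted Passed to [compute_dsd()].
#' @param dsd Optional precomputed `dsd_matrix` (cache).
#' @return The dataset with the layer replaced (plus the `_raw` copy).
#' @export
preprocess_mutation_layer <- function(dataset, network, layer = "mutation",
                                      steps = 7L, weighted = FALSE, dsd = NULL) {
  if (!layer %in% names(dataset$layers)) {
    abort(paste0("no layer named '", layer, "' in the dataset."))
  }
  lay <- dataset$layers[[layer]]
  if (!all(lay$values %in% c(0, 1))) {
    abort(paste0("layer '", layer, "' is not binary."))
  }
  genes <- gene_ids(lay)
  coverage <- mean(genes %in% igraph::V(network)$name)
  if (coverage < 0.5) {
    warn(sprintf("only %.1f%% of genes map to the network; propagation will be sparse.",
                 100 * coverage))
  }
  dsd <- dsd %||% compute_dsd(network, steps = steps, weighted = weighted)
  prop <- lay$values
  for (j in seq_len(ncol(prop))) {
    v <- setNames(lay$values[, j], genes)
    prop[, j] <- if (any(v > 0)) propagate_mutations(v, dsd) else v
  }
  raw <- lay
  raw$layer_name <- paste0(layer, "_raw")
  new_lay <- omics_matrix(prop, layer, gene_ids = genes, sample_ids = sample_ids(lay))
  layers <- dataset$layers
  layers[[layer]] <- new_lay
  layers[[raw$layer_name]] <- raw
  structure(list(layers = layers, labels = dataset$labels,
                 response = dataset$response),
            class = "multiomics_dataset")
}

#' Cache a DSD matrix on disk keyed by network content
#'
#' @param network An [interaction_network()].
#' @param dir Cache directory.
#' @param steps,weighted Passed to [compute_dsd()].
#' @return The `dsd_matrix`, loaded from cache when available.
#' @export
cached_dsd <- function(network, dir, steps = 7L, weighted = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  edf <- igraph::as_data_frame(network, what = "edges")
  key <- rlang::hash(list(edf, igraph::V(network)$name, steps, weighted))
  fn <- file.path(dir, paste0("dsd-", key, ".rds"))
  if (file.exists(fn)) return(readRDS(fn))
  dsd <- compute_dsd(network, steps = steps, weighted = weighted)
  saveRDS(dsd, fn)
  dsd
}
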