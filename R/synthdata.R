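#' Define a synthetic multi-omics scenario
#'
#' The generator plants a class-discriminative gene module in a three-layer
#' dataset shaped like typical drug-response panels: a dense expression
#' layer, a discretized copy-number layer correlated with the same signal,
#' and a sparse binary mutation layer enriched for the module in one class.
#' All randomness derives from the single seed. The default scenario
#' (d = 600 genes, module of 40, 60 samples per class) is sized so the full
#' pipeline runs end to end on one CPU in minutes while keeping d >> n.
#'
#' @param n_per_class Samples per class (two classes, NR and R).
#' @param d Number of genes.
#' @param m Planted module size (m < d).
#' @param delta Expression effect size: mean shift of module genes in the R
#'   class, in units of the noise SD.
#' @param cna_effect Copy-number effect on module genes in the R class
#'   (integer dosage shift before discretization).
#' @param mut_rate Background per-gene mutation probability.
#' @param mut_enriched_rate Mutation probability of module genes in the R
#'   class.
#' @param topology Network topology for [generate_network()]:
#'   `"scale_free"`, `"lattice"` or `"path"`.
#' @param seed Integer seed.
#' @return A `synthetic_scenario` list.
#' @export
synthetic_scenario <- function(n_per_class = 60L, d = 600L, m = 40L,
                               delta = 3, cna_effect = 1, mut_rate = 0.02,
                               mut_enriched_rate = 0.3,
                               topology = c("scale_free", "lattice", "path"),
                               seed = 42L) {
  topology <- match.arg(topology)
  if (m >= d) abort("planted module size m must be smaller than d.")
  stopifnot(n_per_class >= 2L, mut_rate >= 0, mut_rate <= 1,
            mut_enriched_rate >= 0, mut_enriched_rate <= 1)
  structure(list(n_per_class = as.integer(n_per_class), d = as.integer(d),
                 m = as.integer(m), delta = delta, cna_effect = cna_effect,
                 mut_rate = mut_rate, mut_enriched_rate = mut_enriched_rate,
                 topology = topology, seed = as.integer(seed)),
            class = "synthetic_scenario")
}

#' Generate a synthetic multi-omics dataset with a planted module
#'
#' Expression is Gaussian background (mean 6, SD 1, non-negative scale so the
#' log-based normalization is exercised without guards) with a `delta`-SD
#' mean shift on the planted module in the R class. Copy number is an
#' integer-discretized correlated copy of the same shift with independent
#' noise, clipped to typical dosage calls [-2, 2]. Mutation is Bernoulli
#' background, enriched on the module in the R class. A continuous response
#' (logIC50-like, lower in respondents) is attached alongside the labels.
#'
#' @param scenario A [synthetic_scenario()].
#' @return List with `dataset` (a labelled `multiomics_dataset`) and
#'   `planted` (the module gene ids).
#' @export
generate_multiomics <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  set.seed(scenario$seed)
  d <- scenario$d; m <- scenario$m; npc <- scenario$n_per_class
  n <- 2L * npc
  genes <- sprintf("gene%04d", seq_len(d))
  samples <- sprintf("s%03d", seq_len(n))
  labels <- setNames(factor(rep(c("NR", "R"), each = npc), levels = c("NR", "R")),
                     samples)
  planted <- genes[seq_len(m)]
  is_r <- labels == "R"

  expr <- matrix(rnorm(d * n, mean = 6, sd = 1), d, n,
                 dimnames = list(genes, samples))
  expr[seq_len(m), is_r] <- expr[seq_len(m), is_r] + scenario$delta
  expr[expr < 0] <- 0

  cna <- matrix(rnorm(d * n, mean = 0, sd = 0.5), d, n,
                dimnames = list(genes, samples))
  cna[seq_len(m), is_r] <- cna[seq_len(m), is_r] + scenario$cna_effect
  cna <- pmin(pmax(round(cna), -2), 2)

  mut <- matrix(rbinom(d * n, 1L, scenario$mut_rate), d, n,
                dimnames = list(genes, samples))
  mut[seq_len(m), is_r] <- rbinom(m * sum(is_r), 1L, scenario$mut_enriched_rate)

  # continuous response on the logIC50 scale: respondents are lower
  response <- setNames(rnorm(n, mean = ifelse(is_r, -1, 1), sd = 0.5), samples)

  dataset <- assemble_dataset(
    list(omics_matrix(expr, "expression"),
         omics_matrix(cna, "cna"),
         omics_matrix(mut, "mutation")),
    labels = labels, response = response
  )
  list(dataset = dataset, planted = planted, scenario = scenario)
}

#' Generate a toy interaction network over the dataset's genes
#'
#' `"path"` chains the genes; `"lattice"` is a near-square grid;
#' `"scale_free"` is a Barabasi-Albert preferential-attachment graph. All
#' are connected. With `attach_planted`, the planted genes are relabelled
#' onto a connected subgraph (a breadth-first neighborhood), so mutation
#' propagation concentrates into hotspots.
#'
#' @param gene_ids Character vector of gene ids (nodes).
#' @param topology `"scale_free"`, `"lattice"` or `"path"`.
#' @param attach_planted Optional character vector of planted gene ids to
#'   place on a connected neighborhood.
#' @param seed Integer seed.
#' @return An [interaction_network()].
#' @export
generate_network <- function(gene_ids, topology = c("scale_free", "lattice", "path"),
                             attach_planted = NULL, seed = 42L) {
  topology <- match.arg(topology)
  gene_ids <- as.character(gene_ids)
  d <- length(gene_ids)
  if (d < 3L) abort("need at least 3 genes.")
  set.seed(seed)
  g <- switch(topology,
    path = igraph::make_lattice(length = d, dim = 1L),
    lattice = {
      r <- floor(sqrt(d))
      cpl <- ceiling(d / r)
      gl <- igraph::make_lattice(c(r, cpl))
      igraph::induced_subgraph(gl, seq_len(d))
    },
    scale_free = igraph::sample_pa(d, m = 2L, directed = FALSE)
  )
  # map vertices to gene ids; optionally pin the planted module to a
  # connected neighborhood found by breadth-first search
  perm <- seq_len(d)
  if (!is.null(attach_planted)) {
    planted_idx <- match(attach_planted, gene_ids)
    if (anyNA(planted_idx)) abort("planted genes must be part of `gene_ids`.")
    root <- which.max(igraph::degree(g))
    bfs_order <- igraph::bfs(g, root = root, order = TRUE)$order
    target_vertices <- as.integer(bfs_order[seq_along(planted_idx)])
    # vertex target_vertices[k] gets gene attach_planted[k]
    perm <- rep(NA_integer_, d)
    perm[target_vertices] <- planted_idx
    perm[is.na(perm)] <- setdiff(seq_len(d), planted_idx)
  }
  igraph::V(g)$name <- gene_ids[perm]
  edges <- igraph::as_data_frame(g, what = "edges")
  interaction_network(edges, nodes = gene_ids)
}

#' Write a complete synthetic fixture set to disk
#'
#' Emits the standard files consumed by the command-line interface: one TSV
#' per layer, labels, response values, the interaction edge list, and a GMT
#' collection in which the planted module doubles as the "true" pathway
#' (plus random decoy sets). The scenario is serialized alongside.
#'
#' @param scenario A [synthetic_scenario()].
#' @param dir Output directory.
#' @param n_decoy_sets Number of random decoy gene sets in the GMT.
#' @return Invisibly, a list with the dataset, planted genes and file paths.
#' @export
write_scenario_fixtures <- function(scenario, dir, n_decoy_sets = 20L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_multiomics(scenario)
  net <- generate_network(dataset_genes(gen$dataset), topology = scenario$topology,
                          attach_planted = gen$planted, seed = scenario$seed)
  paths <- list()
  for (nm in names(gen$dataset$layers)) {
    paths[[nm]] <- file.path(dir, paste0(nm, ".tsv"))
    write_omics_layer(gen$dataset$layers[[nm]], paths[[nm]])
  }
  paths$labels <- write_labels(gen$dataset$labels, file.path(dir, "labels.tsv"))
  resp <- gen$dataset$response
  write.table(data.frame(sample_id = names(resp), logIC50 = resp),
              file.path(dir, "response.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths$response <- file.path(dir, "response.tsv")
  paths$edges <- write_edge_list(net, file.path(dir, "ppi.tsv"))
  set.seed(scenario$seed + 1L)
  genes <- dataset_genes(gen$dataset)
  sets <- c(list(planted_module = gen$planted),
            setNames(lapply(seq_len(n_decoy_sets), function(i) {
              sample(genes, scenario$m)
            }), paste0("decoy_", seq_len(n_decoy_sets))))
  paths$gmt <- write_gmt(sets, file.path(dir, "pathways.gmt"))
  jsonlite::write_json(unclass(scenario), file.path(dir, "scenario.json"),
                       auto_unbox = TRUE, digits = NA)
  paths$scenario <- file.path(dir, "scenario.json")
  invisible(list(dataset = gen$dataset, planted = gen$planted,
                 network = net, paths = paths))
}
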