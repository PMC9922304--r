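#' Read a GMT gene-set collection
#'
#' @param path GMT file (tab-separated: set name, description, member genes).
#' @return Named list of gene id vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write a GMT gene-set collection
#'
#' @param sets Named list of gene id vectors.
#' @param path Output path.
#' @param descriptions Optional per-set description strings.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Over-representation enrichment by Fisher's exact test
#'
#' For each pathway, tests over-representation of the selected gene subset
#' with a one-sided Fisher exact test on the 2x2 table (subset vs rest,
#' in-pathway vs out), i.e. the upper hypergeometric tail, followed by
#' Benjamini-Hochberg correction across all tested pathways. The universe
#' defaults to the gene space the selection operated on; subset genes outside
#' the universe are dropped (and counted in the `dropped` attribute).
#'
#' @param subset Character vector of selected gene ids (or a `gene_subset`,
#'   whose union is used).
#' @param collection Named list of gene sets (e.g. from [read_gmt()]).
#' @param universe Character vector of all candidate gene ids.
#' @return Tibble sorted by q: `pathway`, `overlap`, `set_size`,
#'   `subset_size`, `universe_size`, `p`, `q`.
#' @export
fisher_enrichment <- function(subset, collection, universe) {
  if (inherits(subset, "gene_subset")) subset <- subset$union
  subset <- unique(as.character(subset))
  universe <- unique(as.character(universe))
  dropped <- sum(!subset %in% universe)
  if (dropped) {
    inform(paste0(dropped, " selected gene(s) outside the universe were dropped."))
  }
  subset <- intersect(subset, universe)
  if (!length(subset)) abort("empty subset after restricting to the universe.")
  N <- length(universe)
  n_sub <- length(subset)
  res <- purrr::map_dfr(names(collection), function(nm) {
    set <- intersect(unique(collection[[nm]]), universe)
    K <- length(set)
    if (!K) return(NULL)
    k <- length(intersect(subset, set))
    tab <- matrix(c(k, n_sub - k, K - k, N - K - (n_sub - k)), 2L)
    p <- fisher.test(tab, alternative = "greater")$p.value
    tibble(pathway = nm, overlap = k, set_size = K,
           subset_size = n_sub, universe_size = N, p = p)
  })
  if (!nrow(res)) abort("no pathway overlaps the universe.")
  res$q <- p.adjust(res$p, method = "BH")
  res <- dplyr::arrange(res, .data$q, .data$p, .data$pathway)
  attr(res, "dropped") <- dropped
  res
}

#' Hypergeometric enrichment p-value of one gene set
#'
#' Upper-tail probability `P(X >= overlap)` for the overlap between a
#' selected subset and a target set within a universe. Used to score how
#' strongly a selection recovers a planted module.
#'
#' @param subset,target,universe Character vectors of gene ids.
#' @return One-sided p-value.
#' @export
hypergeom_p <- function(subset, target, universe) {
  subset <- intersect(unique(subset), universe)
  target <- intersect(unique(target), universe)
  k <- length(intersect(subset, target))
  phyper(k - 1L, length(target), length(universe) - length(target),
         length(subset), lower.tail = FALSE)
}
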