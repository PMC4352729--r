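#' Assemble the whole-genome integrative network
#'
#' Combines the per-gene regression models whose adjusted R-squared passes
#' the cutoff (inclusive, `adj_r2 >= cutoff`) into one typed directed
#' network: each selected regulator contributes an edge regulator-node ->
#' mrna:target carrying the refit coefficient as weight and the source
#' model's adjusted R2. Unusable models and models below the cutoff
#' contribute nothing; isolated nodes are omitted.
#'
#' @param results A `vif_fits` tibble from [fit_all()].
#' @param cutoff Adjusted R-squared cutoff in \[0, 1\] (default 0.4).
#' @return An `integrative_network`.
#' @export
assemble_network <- function(results, cutoff = 0.4) {
  stopifnot(is.data.frame(results))
  if (!(cutoff >= 0 && cutoff <= 1)) stop("cutoff must be in [0, 1]", call. = FALSE)
  keep <- results[results$usable & !is.na(results$adj_r2) &
                    results$adj_r2 >= cutoff, , drop = FALSE]
  if (nrow(keep) == 0) {
    return(new_network(tibble::tibble(from = character(), to = character())))
  }
  edges <- tidyr::unnest(
    dplyr::select(tibble::as_tibble(keep), "target_gene", "adj_r2", "selected"),
    "selected")
  edges <- tibble::tibble(from = edges$node,
                          to = paste0("mrna:", edges$target_gene),
                          weight = edges$coefficient, adj_r2 = edges$adj_r2,
                          directed = TRUE)
  edges <- dplyr::distinct(edges, .data$from, .data$to, .keep_all = TRUE)
  new_network(edges)
}

#' Score recovered edges against ground truth
#'
#' Edge-level precision and recall of a network (or any edge table with
#' `from`/`to` node-id columns) against the generator's true
#' regulator -> gene edges. For refined networks an undirected edge counts
#' as recovering the pair in either orientation.
#'
#' @param net An `omics_network` or tibble of edges.
#' @param truth A `ground_truth` or its `true_edges` tibble.
#' @return Tibble with `n_true`, `n_found`, `tp`, `precision`, `recall`.
#' @export
score_edges <- function(net, truth) {
  edges <- if (inherits(net, "omics_network")) net$edges else tibble::as_tibble(net)
  te <- if (inherits(truth, "ground_truth")) truth$true_edges else
    tibble::as_tibble(truth)
  true_keys <- paste(te$regulator_node, qualify(te$target_gene))
  if (nrow(edges)) {
    found <- paste(edges$from, edges$to)
    if ("directed" %in% names(edges)) {
      rev_keys <- paste(edges$to, edges$from)[!edges$directed]
      found <- c(found, rev_keys)
    }
  } else {
    found <- character(0)
  }
  tp <- sum(true_keys %in% found)
  n_found <- if (nrow(edges)) nrow(edges) else 0L
  tibble::tibble(
    n_true = length(true_keys), n_found = n_found, tp = tp,
    precision = if (n_found > 0) tp / n_found else NA_real_,
    recall = if (length(true_keys) > 0) tp / length(true_keys) else NA_real_)
}

#' Extract the seed-gene subnetwork
#'
#' Isolates the subnetwork of seed (e.g. pathway) genes and their direct
#' regulators: the node set is the seed genes' mrna nodes (those present in
#' the network or named by the prior) plus the in-neighbors of those nodes
#' in the integrative network; the edge set is the induced regression edges
#' plus, when `include_prior_edges`, the prior gene-gene regulations mapped
#' onto mrna nodes. "Direct regulators" is strictly one hop: regulators of
#' regulators are excluded.
#'
#' @param net An `integrative_network`.
#' @param prior A `prior_edge_set` supplying the seed genes and prior edges.
#' @param include_prior_edges Keep the prior gene-gene edges in the output
#'   (they serve as the whitelist for Bayesian refinement downstream).
#' @return An `integrative_network` restricted to the seed neighborhood.
#' @export
extract_subnetwork <- function(net, prior, include_prior_edges = TRUE) {
  stopifnot(inherits(net, "omics_network"), inherits(prior, "prior_edge_set"))
  seed_nodes <- qualify(prior$seed_genes)
  present <- seed_nodes %in% net$nodes$node
  prior_nodes <- unique(qualify(c(prior$edges$source, prior$edges$target)))
  kept_seed <- unique(c(seed_nodes[present], prior_nodes))
  absent <- prior$seed_genes[!present &
                               !(seed_nodes %in% prior_nodes)]
  if (length(kept_seed) == 0) {
    stop("no seed gene is present in the network or the prior", call. = FALSE)
  }
  if (length(absent)) {
    warning("seed genes absent from network and prior: ",
            paste(utils::head(absent, 10), collapse = ", "), call. = FALSE)
  }
  vif_edges <- net$edges[net$edges$to %in% kept_seed, , drop = FALSE]
  nodes <- unique(c(kept_seed, vif_edges$from))
  edges <- vif_edges
  if (include_prior_edges && nrow(prior$edges)) {
    pe <- tibble::tibble(from = qualify(prior$edges$source),
                         to = qualify(prior$edges$target),
                         weight = NA_real_, adj_r2 = NA_real_, directed = TRUE)
    edges <- dplyr::distinct(dplyr::bind_rows(edges, pe),
                             .data$from, .data$to, .keep_all = TRUE)
    nodes <- unique(c(nodes, pe$from, pe$to))
  }
  new_network(edges, nodes = tibble::tibble(node = nodes))
}
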