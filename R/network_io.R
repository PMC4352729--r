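#' Typed multi-omics networks
#'
#' Networks are stored as two tibbles: `nodes` (`node`, `layer`, `feature`)
#' and `edges`. Node identity is layer-qualified (`"layer:feature"`), so the
#' methylation of gene X and the expression of gene X are distinct nodes.
#' An integrative network (the VIF-regression assembly) has only directed
#' edges carrying the refit coefficient and the source model's adjusted R2;
#' a refined network (the Bayesian stage output) additionally distinguishes
#' directed (compelled) from undirected (reversible) edges.
#'
#' @param edges Tibble/data frame with columns `from`, `to` (layer-qualified
#'   node ids); optional `weight`, `adj_r2`, `directed`.
#' @param nodes Optional tibble with a `node` column; defaults to the nodes
#'   appearing in `edges`.
#' @param refined Logical: construct a `refined_network` rather than an
#'   `integrative_network`.
#' @param score Network score of the learned DAG (refined networks).
#' @param whitelist `prior_edge_set` used during refinement, if any.
#' @return An object of class `integrative_network` or `refined_network`
#'   (both inherit `omics_network`).
#' @export
new_network <- function(edges, nodes = NULL, refined = FALSE,
                        score = NULL, whitelist = NULL) {
  edges <- tibble::as_tibble(edges)
  if (nrow(edges) == 0 && !all(c("from", "to") %in% names(edges))) {
    edges <- tibble::tibble(from = character(), to = character())
  }
  stopifnot(all(c("from", "to") %in% names(edges)))
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (!"weight" %in% names(edges)) edges$weight <- rep(NA_real_, nrow(edges))
  if (!"adj_r2" %in% names(edges)) edges$adj_r2 <- rep(NA_real_, nrow(edges))
  if (!"directed" %in% names(edges)) edges$directed <- rep(TRUE, nrow(edges))
  if (any(edges$from == edges$to)) stop("self-loop edges are not allowed", call. = FALSE)
  if (anyDuplicated(edges[, c("from", "to")])) {
    stop("duplicate edges are not allowed", call. = FALSE)
  }
  node_ids <- if (is.null(nodes)) {
    sort(unique(c(edges$from, edges$to)))
  } else {
    sort(unique(as.character(tibble::as_tibble(nodes)$node)))
  }
  nodes <- node_table(node_ids)
  cls <- if (refined) c("refined_network", "omics_network") else
    c("integrative_network", "omics_network")
  structure(list(nodes = nodes, edges = edges, score = score,
                 whitelist = whitelist), class = cls)
}

# layer-qualify gene symbols, safe for empty input (paste0 recycles "" otherwise)
qualify <- function(features, layer = "mrna") {
  if (length(features) == 0) character(0) else paste0(layer, ":", features)
}

node_table <- function(node_ids) {
  if (length(node_ids) == 0) {
    return(tibble::tibble(node = character(), layer = character(),
                          feature = character()))
  }
  parts <- strsplit(node_ids, ":", fixed = TRUE)
  qualified <- lengths(parts) == 2L
  tibble::tibble(
    node = node_ids,
    layer = ifelse(qualified, vapply(parts, `[`, "", 1L), NA_character_),
    feature = ifelse(qualified, vapply(parts, `[`, "", 2L), node_ids))
}

#' @export
print.omics_network <- function(x, ...) {
  kind <- if (inherits(x, "refined_network")) "refined_network" else "integrative_network"
  nu <- sum(!x$edges$directed)
  cat(sprintf("<%s> %d nodes, %d edges (%d undirected)\n",
              kind, nrow(x$nodes), nrow(x$edges), nu))
  if (!is.null(x$score)) cat(sprintf("  network score: %.3f\n", x$score))
  invisible(x)
}

#' Summarise a network's composition
#'
#' Node counts by molecular layer, edge counts, and the degree distribution.
#'
#' @param net An `omics_network`.
#' @return A list with `n_nodes`, `nodes_by_layer` (named integer vector over
#'   mrna/mirna/methylation/cnv), `n_edges`, `n_undirected`, and `degree`
#'   (tibble `node`, `in_degree`, `out_degree`).
#' @export
network_stats <- function(net) {
  stopifnot(inherits(net, "omics_network"))
  layers <- c("mrna", "mirna", "methylation", "cnv")
  by_layer <- vapply(layers, function(l) sum(net$nodes$layer == l), 0L)
  deg <- tibble::tibble(
    node = net$nodes$node,
    in_degree = vapply(net$nodes$node, function(v) sum(net$edges$to == v), 0L),
    out_degree = vapply(net$nodes$node, function(v) sum(net$edges$from == v), 0L)
  )
  list(n_nodes = nrow(net$nodes), nodes_by_layer = by_layer,
       n_edges = nrow(net$edges), n_undirected = sum(!net$edges$directed),
       degree = deg)
}

#' Write a network to disk
#'
#' Three formats are supported. `edge_tsv` is the lossless flat form (one
#' edge per row with layer tags and the directedness flag). `sif` writes
#' `source<TAB>relation<TAB>target` with relation `regulates` for directed
#' and `associated` for undirected edges; isolated nodes get a bare-node
#' line. `graphml` carries the node attribute `layer` and edge attribute
#' `directed`. Node ids are layer-qualified in every format, so layer tags
#' survive round-trips.
#'
#' @param net An `omics_network`.
#' @param path Output path.
#' @param format One of `"edge_tsv"`, `"sif"`, `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("edge_tsv", "sif", "graphml")) {
  stopifnot(inherits(net, "omics_network"))
  format <- match.arg(format)
  if (format == "edge_tsv") {
    tb <- dplyr::mutate(
      net$edges,
      from_layer = sub(":.*$", "", .data$from),
      to_layer = sub(":.*$", "", .data$to)
    )
    iso <- setdiff(net$nodes$node, c(tb$from, tb$to))
    if (length(iso)) {
      tb <- dplyr::bind_rows(tb, tibble::tibble(
        from = iso, to = NA_character_, weight = NA_real_, adj_r2 = NA_real_,
        directed = NA, from_layer = sub(":.*$", "", iso), to_layer = NA_character_))
    }
    readr::write_tsv(tb, path, na = "", progress = FALSE)
  } else if (format == "sif") {
    lines <- character(0)
    if (nrow(net$edges)) {
      rel <- ifelse(net$edges$directed, "regulates", "associated")
      lines <- paste(net$edges$from, rel, net$edges$to, sep = "\t")
    }
    iso <- setdiff(net$nodes$node, c(net$edges$from, net$edges$to))
    writeLines(c(lines, iso), path)
  } else {
    write_graphml(net, path)
  }
  invisible(path)
}

write_graphml <- function(net, path) {
  doc <- xml2::xml_new_root("graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns")
  k1 <- xml2::xml_add_child(doc, "key", id = "layer", `for` = "node",
                            attr.name = "layer", attr.type = "string")
  k2 <- xml2::xml_add_child(doc, "key", id = "directed", `for` = "edge",
                            attr.name = "directed", attr.type = "boolean")
  k3 <- xml2::xml_add_child(doc, "key", id = "weight", `for` = "edge",
                            attr.name = "weight", attr.type = "double")
  g <- xml2::xml_add_child(doc, "graph", id = "G", edgedefault = "directed")
  for (i in seq_len(nrow(net$nodes))) {
    nd <- xml2::xml_add_child(g, "node", id = net$nodes$node[i])
    dt <- xml2::xml_add_child(nd, "data", key = "layer")
    xml2::xml_text(dt) <- net$nodes$layer[i]
  }
  for (i in seq_len(nrow(net$edges))) {
    ed <- xml2::xml_add_child(g, "edge", source = net$edges$from[i],
                              target = net$edges$to[i])
    dd <- xml2::xml_add_child(ed, "data", key = "directed")
    xml2::xml_text(dd) <- if (isTRUE(net$edges$directed[i])) "true" else "false"
    if (!is.na(net$edges$weight[i])) {
      dw <- xml2::xml_add_child(ed, "data", key = "weight")
      xml2::xml_text(dw) <- format(net$edges$weight[i], digits = 17)
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a network written by [write_network()]
#'
#' @param path File path.
#' @param format One of `"edge_tsv"`, `"sif"`, `"graphml"`.
#' @return An `omics_network`; a `refined_network` when any edge is
#'   undirected, otherwise an `integrative_network`.
#' @export
read_network <- function(path, format = c("edge_tsv", "sif", "graphml")) {
  format <- match.arg(format)
  if (format == "edge_tsv") {
    tb <- readr::read_tsv(path, col_types = readr::cols(
      from = readr::col_character(), to = readr::col_character(),
      weight = readr::col_double(), adj_r2 = readr::col_double(),
      directed = readr::col_logical(), .default = readr::col_character()),
      progress = FALSE, na = "")
    iso <- tb$from[is.na(tb$to)]
    tb <- tb[!is.na(tb$to), c("from", "to", "weight", "adj_r2", "directed")]
    nodes <- tibble::tibble(node = unique(c(tb$from, tb$to, iso)))
  } else if (format == "sif") {
    raw <- readLines(path)
    raw <- raw[nzchar(raw)]
    parts <- strsplit(raw, "\t", fixed = TRUE)
    is_edge <- lengths(parts) == 3L
    ep <- parts[is_edge]
    tb <- tibble::tibble(
      from = vapply(ep, `[`, "", 1L), to = vapply(ep, `[`, "", 3L),
      weight = NA_real_, adj_r2 = NA_real_,
      directed = vapply(ep, `[`, "", 2L) == "regulates")
    iso <- vapply(parts[!is_edge], `[`, "", 1L)
    nodes <- tibble::tibble(node = unique(c(tb$from, tb$to, iso)))
  } else {
    doc <- xml2::read_xml(path)
    ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
    nnodes <- xml2::xml_find_all(doc, ".//g:node", ns)
    nodes <- tibble::tibble(node = xml2::xml_attr(nnodes, "id"))
    eedges <- xml2::xml_find_all(doc, ".//g:edge", ns)
    get_data <- function(e, key) {
      d <- xml2::xml_find_first(e, sprintf("./g:data[@key='%s']", key), ns)
      if (inherits(d, "xml_missing")) NA_character_ else xml2::xml_text(d)
    }
    tb <- tibble::tibble(
      from = xml2::xml_attr(eedges, "source"),
      to = xml2::xml_attr(eedges, "target"),
      weight = as.numeric(vapply(eedges, get_data, "", key = "weight")),
      adj_r2 = NA_real_,
      directed = vapply(eedges, get_data, "", key = "directed") == "true")
  }
  refined <- nrow(tb) > 0 && any(!tb$directed)
  new_network(tb, nodes = nodes, refined = refined)
}

#' Prior (known-regulation) edge set over seed genes
#'
#' Holds directed gene-to-gene regulations taken as prior knowledge, e.g. a
#' pathway extraction, together with the seed-gene set they live on. Every
#' edge endpoint must be a seed gene; self-loops and duplicates are rejected.
#'
#' @param edges Data frame with columns `source` and `target` (gene
#'   symbols), or NULL/empty for no prior edges.
#' @param seed_genes Character vector of seed gene symbols.
#' @return A `prior_edge_set`.
#' @export
prior_edge_set <- function(edges = NULL, seed_genes) {
  seed_genes <- unique(as.character(seed_genes))
  if (length(seed_genes) == 0) stop("seed_genes must be nonempty", call. = FALSE)
  if (is.null(edges) || nrow(as.data.frame(edges)) == 0) {
    edges <- tibble::tibble(source = character(), target = character())
  }
  edges <- tibble::as_tibble(edges)[, c("source", "target")]
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  if (any(edges$source == edges$target)) {
    stop("prior edges may not be self-loops", call. = FALSE)
  }
  if (anyDuplicated(edges)) stop("duplicate prior edges", call. = FALSE)
  missing <- setdiff(unique(c(edges$source, edges$target)), seed_genes)
  if (length(missing)) {
    stop("prior edge endpoints not in seed_genes: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  structure(list(edges = edges, seed_genes = seed_genes),
            class = "prior_edge_set")
}

#' @export
print.prior_edge_set <- function(x, ...) {
  cat(sprintf("<prior_edge_set> %d seed genes, %d prior edges\n",
              length(x$seed_genes), nrow(x$edges)))
  invisible(x)
}

#' Read prior edges and seed genes from disk
#'
#' `read_prior_edges()` expects a 2-column TSV (`source`, `target`, header
#' optional gene pairs); `read_seed_genes()` a one-gene-per-line text file.
#' The seed set defaults to the union of seed file genes and prior-edge
#' endpoints.
#'
#' @param path File path.
#' @param seed_genes Seed genes; defaults to the edge endpoints.
#' @return A `prior_edge_set` / character vector.
#' @export
read_prior_edges <- function(path, seed_genes = NULL) {
  tb <- readr::read_tsv(path, col_names = c("source", "target"),
                        col_types = "cc", progress = FALSE)
  if (nrow(tb) && identical(tolower(unlist(tb[1, ])), c("source", "target"))) {
    tb <- tb[-1, ]
  }
  if (is.null(seed_genes)) seed_genes <- unique(c(tb$source, tb$target))
  prior_edge_set(tb, seed_genes = unique(c(seed_genes, tb$source, tb$target)))
}

#' @rdname read_prior_edges
#' @export
read_seed_genes <- function(path) {
  g <- trimws(readLines(path))
  unique(g[nzchar(g)])
}

#' Read / write a survival table
#'
#' A survival table has one row per sample: `sample_id`, `time`
#' (non-negative follow-up), `event` (1 = death observed, 0 = censored) and
#' `covariate` (the expression value used for median dichotomization).
#'
#' @param path TSV path with columns sample, time, event, expression.
#' @return A tibble with validated columns.
#' @export
read_survival_table <- function(path) {
  tb <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(), time = readr::col_double(),
    event = readr::col_integer(), covariate = readr::col_double()),
    progress = FALSE)
  validate_survival_table(tb)
}

#' @rdname read_survival_table
#' @param table Survival tibble.
#' @export
write_survival_table <- function(table, path) {
  readr::write_tsv(validate_survival_table(table), path, progress = FALSE)
  invisible(path)
}

validate_survival_table <- function(table) {
  tb <- tibble::as_tibble(table)
  need <- c("sample_id", "time", "event", "covariate")
  if (!all(need %in% names(tb))) {
    stop("survival table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(tb$sample_id)) stop("duplicate sample_id in survival table",
                                        call. = FALSE)
  if (any(tb$time < 0, na.rm = TRUE)) stop("negative survival time", call. = FALSE)
  if (!all(tb$event %in% c(0L, 1L))) stop("event must be 0 or 1", call. = FALSE)
  tb[, need]
}
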