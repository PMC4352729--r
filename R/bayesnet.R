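#' Bayesian-network refinement configuration
#'
#' Settings for score-based structure learning over the subnetwork
#' variables. The search is hill climbing with random restarts over DAGs
#' that contain every whitelist (prior) edge; by default it is restricted to
#' the candidate edges handed in (the regression and prior edges, in their
#' proposed orientations) rather than a de-novo search over all pairs.
#'
#' @param score `"bic_gaussian"` (default; Gaussian log-likelihood penalized
#'   by `log(n)/2` per parameter) or `"loglik_gaussian"` (unpenalized).
#' @param restarts Number of random restarts (>= 1; the first start is the
#'   whitelist-only DAG).
#' @param max_parents Maximum parents per node (>= 1).
#' @param candidate_edges_only Restrict the search to the candidate edges
#'   and the whitelist, in their proposed orientations (an edge may be
#'   reversed only where the reversed pair is itself a candidate).
#' @param layer_blacklist When TRUE, forbid edges INTO cnv and methylation
#'   nodes (copy number and methylation as root causes only). Off by
#'   default.
#' @param seed Integer seed; learning is deterministic given the seed.
#' @return A `bn_config` list.
#' @export
bn_config <- function(score = c("bic_gaussian", "loglik_gaussian"),
                      restarts = 10L, max_parents = 5L,
                      candidate_edges_only = TRUE, layer_blacklist = FALSE,
                      seed = 1L) {
  score <- match.arg(score)
  if (restarts < 1) stop("restarts must be >= 1", call. = FALSE)
  if (max_parents < 1) stop("max_parents must be >= 1", call. = FALSE)
  structure(list(score = score, restarts = as.integer(restarts),
                 max_parents = as.integer(max_parents),
                 candidate_edges_only = isTRUE(candidate_edges_only),
                 layer_blacklist = isTRUE(layer_blacklist),
                 seed = as.integer(seed)),
            class = "bn_config")
}

# ---- scoring ---------------------------------------------------------------

# Gaussian local score of `v` given `parents`; data is samples x variables
local_score <- function(data, v, parents, score = "bic_gaussian") {
  y <- data[, v]
  n <- length(y)
  if (length(parents)) {
    fit <- stats::lm.fit(cbind(1, data[, parents, drop = FALSE]), y)
    rss <- sum(fit$residuals^2)
  } else {
    rss <- sum((y - mean(y))^2)
  }
  sigma2 <- max(rss / n, 1e-300)
  ll <- -n / 2 * (log(2 * pi * sigma2) + 1)
  if (score == "bic_gaussian") ll - log(n) / 2 * (length(parents) + 2) else ll
}

#' Score a DAG structure on data
#'
#' Decomposable Gaussian network score: the sum over nodes of the local
#' score of each node given its parents (BIC-penalized by default). Exposed
#' so that small instances can be scored exhaustively, e.g. to check the
#' search against full DAG enumeration.
#'
#' @param data Numeric matrix, samples x variables, with column names.
#' @param edges Data frame with `from`, `to` columns (variable names), or an
#'   empty data frame for the empty graph.
#' @param cfg A [bn_config()] (only `score` is used).
#' @return The network score (a real number; higher is better).
#' @export
bn_score <- function(data, edges, cfg = bn_config()) {
  vars <- colnames(data)
  parents <- parents_from_edges(edges, vars)
  sum(vapply(vars, function(v) local_score(data, v, parents[[v]], cfg$score), 0))
}

parents_from_edges <- function(edges, vars) {
  parents <- stats::setNames(vector("list", length(vars)), vars)
  for (v in vars) parents[[v]] <- character(0)
  edges <- as.data.frame(edges)
  if (nrow(edges)) {
    for (i in seq_len(nrow(edges))) {
      parents[[edges$to[i]]] <- c(parents[[edges$to[i]]], edges$from[i])
    }
  }
  parents
}

# is there a directed path from `from` to `to`?
has_path <- function(parents, from, to) {
  # parents: named list; walk backwards from `to`
  stack <- to
  seen <- character(0)
  while (length(stack)) {
    v <- stack[[1]]
    stack <- stack[-1]
    if (v %in% seen) next
    seen <- c(seen, v)
    ps <- parents[[v]]
    if (from %in% ps) return(TRUE)
    stack <- c(stack, ps)
  }
  FALSE
}

edges_from_parents <- function(parents) {
  rows <- purrr::imap(parents, function(ps, v) {
    if (length(ps)) tibble::tibble(from = ps, to = v) else NULL
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) tibble::tibble(from = character(), to = character()) else out
}

# ---- hill climbing ---------------------------------------------------------

#' Learn a Bayesian-network structure with whitelisted prior edges
#'
#' Hill climbing with random restarts over DAGs containing all whitelist
#' edges, under the parent-count cap and (optionally) the candidate-edge
#' restriction and layer blacklist. Moves are single-edge additions,
#' deletions and reversals; whitelist edges can be neither deleted nor
#' reversed. The best-scoring DAG across restarts is returned; the result is
#' deterministic under a fixed seed.
#'
#' @param data Numeric matrix, samples x variables; column names are the
#'   (layer-qualified) node ids.
#' @param whitelist Edges forced present: a two-column data frame
#'   (`from`, `to`) of node ids, a `prior_edge_set` (gene symbols mapped to
#'   `mrna:` nodes), or NULL.
#' @param cfg A [bn_config()].
#' @param candidates Optional two-column data frame (`from`, `to`) of
#'   allowed edges; used when `cfg$candidate_edges_only` is TRUE (whitelist
#'   edges are always allowed too).
#' @return A `bn_dag`: list with `nodes`, `edges` (tibble `from`, `to`),
#'   `parents`, `score`.
#' @export
learn_structure <- function(data, whitelist = NULL, cfg = bn_config(),
                            candidates = NULL) {
  data <- as.matrix(data)
  vars <- colnames(data)
  if (is.null(vars) || length(vars) < 3) {
    stop("need a named data matrix with >= 3 variables", call. = FALSE)
  }
  if (nrow(data) < 10) stop("need >= 10 samples", call. = FALSE)
  wl <- normalize_whitelist(whitelist)
  if (nrow(wl)) {
    missing <- setdiff(unique(c(wl$from, wl$to)), vars)
    if (length(missing)) {
      stop("whitelist node(s) absent from data: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    wl_parents <- parents_from_edges(wl, vars)
    for (i in seq_len(nrow(wl))) {
      # cycle in the whitelist itself: path to -> from via other wl edges
      tmp <- wl_parents
      tmp[[wl$to[i]]] <- setdiff(tmp[[wl$to[i]]], wl$from[i])
      if (has_path(tmp, wl$to[i], wl$from[i])) {
        stop("whitelist is cyclic", call. = FALSE)
      }
    }
  }
  allowed <- allowed_pairs(vars, wl, cfg, candidates)
  wl_key <- paste(wl$from, wl$to)

  score_env <- new.env(parent = emptyenv())
  get_score <- function(v, ps) {
    key <- paste(v, paste(sort(ps), collapse = ","), sep = "|")
    hit <- score_env[[key]]
    if (!is.null(hit)) return(hit)
    val <- local_score(data, v, ps, cfg$score)
    score_env[[key]] <- val
    val
  }

  climb <- function(parents) {
    node_scores <- vapply(vars, function(v) get_score(v, parents[[v]]), 0)
    repeat {
      best_delta <- 1e-8
      best_move <- NULL
      for (k in seq_len(nrow(allowed))) {
        a <- allowed$from[k]; b <- allowed$to[k]
        if (a %in% parents[[b]]) next                      # already present
        if (length(parents[[b]]) >= cfg$max_parents) next
        if (has_path(parents, b, a)) next                  # would close a cycle
        delta <- get_score(b, c(parents[[b]], a)) - node_scores[[b]]
        if (delta > best_delta) {
          best_delta <- delta
          best_move <- list(type = "add", from = a, to = b)
        }
      }
      cur <- edges_from_parents(parents)
      for (k in seq_len(nrow(cur))) {
        a <- cur$from[k]; b <- cur$to[k]
        if (paste(a, b) %in% wl_key) next
        new_b <- setdiff(parents[[b]], a)
        delta_del <- get_score(b, new_b) - node_scores[[b]]
        if (delta_del > best_delta) {
          best_delta <- delta_del
          best_move <- list(type = "del", from = a, to = b)
        }
        # reversal: b -> a must itself be an allowed orientation and acyclic
        if (paste(b, a) %in% allowed$key &&
            length(parents[[a]]) < cfg$max_parents) {
          tmp <- parents
          tmp[[b]] <- new_b
          if (!has_path(tmp, a, b)) {
            delta_rev <- delta_del + get_score(a, c(parents[[a]], b)) -
              node_scores[[a]]
            if (delta_rev > best_delta) {
              best_delta <- delta_rev
              best_move <- list(type = "rev", from = a, to = b)
            }
          }
        }
      }
      if (is.null(best_move)) break
      a <- best_move$from; b <- best_move$to
      if (best_move$type == "add") {
        parents[[b]] <- c(parents[[b]], a)
      } else if (best_move$type == "del") {
        parents[[b]] <- setdiff(parents[[b]], a)
      } else {
        parents[[b]] <- setdiff(parents[[b]], a)
        parents[[a]] <- c(parents[[a]], b)
        node_scores[[a]] <- get_score(a, parents[[a]])
      }
      node_scores[[b]] <- get_score(b, parents[[b]])
    }
    list(parents = parents, score = sum(node_scores))
  }

  wl_start <- parents_from_edges(wl, vars)
  with_seed(cfg$seed, {
    best <- climb(wl_start)
    if (cfg$restarts > 1) {
      for (r in seq_len(cfg$restarts - 1)) {
        parents <- wl_start
        extra <- allowed[!(allowed$key %in% wl_key), , drop = FALSE]
        if (nrow(extra)) {
          extra <- extra[sample.int(nrow(extra)), , drop = FALSE]
          n_add <- stats::rbinom(1, nrow(extra), 0.15)
          for (k in seq_len(n_add)) {
            a <- extra$from[k]; b <- extra$to[k]
            if (a %in% parents[[b]] || b %in% parents[[a]]) next
            if (length(parents[[b]]) >= cfg$max_parents) next
            if (has_path(parents, b, a)) next
            parents[[b]] <- c(parents[[b]], a)
          }
        }
        cand <- climb(parents)
        if (cand$score > best$score + 1e-9) best <- cand
      }
    }
    structure(list(nodes = vars, edges = edges_from_parents(best$parents),
                   parents = best$parents, score = best$score,
                   whitelist = wl),
              class = "bn_dag")
  })
}

normalize_whitelist <- function(whitelist) {
  if (is.null(whitelist)) {
    return(tibble::tibble(from = character(), to = character()))
  }
  if (inherits(whitelist, "prior_edge_set")) {
    return(tibble::tibble(from = qualify(whitelist$edges$source),
                          to = qualify(whitelist$edges$target)))
  }
  wl <- tibble::as_tibble(whitelist)
  stopifnot(all(c("from", "to") %in% names(wl)))
  tibble::tibble(from = as.character(wl$from), to = as.character(wl$to))
}

# Edge universe for the search. When restricted to candidates, both
# additions and reversals respect the candidate / prior orientations: an
# edge can only point the way a regression or prior edge proposed. The
# unrestricted search allows every ordered pair, so reversals are free.
allowed_pairs <- function(vars, wl, cfg, candidates) {
  if (cfg$candidate_edges_only && !is.null(candidates)) {
    cand <- tibble::as_tibble(candidates)[, c("from", "to")]
    pairs <- dplyr::distinct(dplyr::bind_rows(cand, wl))
  } else {
    pairs <- tidyr::expand_grid(from = vars, to = vars)
    pairs <- pairs[pairs$from != pairs$to, ]
  }
  pairs <- pairs[pairs$from %in% vars & pairs$to %in% vars, ]
  if (cfg$layer_blacklist) {
    to_layer <- sub(":.*$", "", pairs$to)
    blocked <- to_layer %in% c("cnv", "methylation") &
      !(paste(pairs$from, pairs$to) %in% paste(wl$from, wl$to))
    pairs <- pairs[!blocked, ]
  }
  pairs$key <- paste(pairs$from, pairs$to)
  pairs
}

#' @export
print.bn_dag <- function(x, ...) {
  cat(sprintf("<bn_dag> %d nodes, %d edges, score %.3f\n",
              length(x$nodes), nrow(x$edges), x$score))
  invisible(x)
}

# ---- CPDAG -----------------------------------------------------------------

#' Label compelled and reversible edges of a learned DAG
#'
#' Converts the learned DAG to its completed partially directed form:
#' v-structure edges and whitelist edges are pinned as directed, the
#' orientation closure (Meek rules R1-R3) is applied, and every remaining
#' edge -- one whose orientation differs across the DAG's score-equivalence
#' class -- is reported as undirected ("two-arrow") regulation.
#'
#' @param dag A `bn_dag` from [learn_structure()].
#' @param whitelist Optional extra pinned edges (defaults to the whitelist
#'   stored in `dag`).
#' @return A `refined_network` whose `edges$directed` flags compelled
#'   (TRUE) versus reversible (FALSE) regulations; carries the DAG score.
#' @export
to_cpdag <- function(dag, whitelist = NULL) {
  stopifnot(inherits(dag, "bn_dag"))
  wl <- normalize_whitelist(whitelist %||% dag$whitelist)
  ed <- dag$edges
  vars <- dag$nodes
  if (nrow(ed) == 0) {
    return(new_network(tibble::tibble(from = character(), to = character()),
                       nodes = tibble::tibble(node = vars), refined = TRUE,
                       score = dag$score,
                       whitelist = if (nrow(wl)) wl else NULL))
  }
  adj <- function(a, b) {
    any(ed$from == a & ed$to == b) || any(ed$from == b & ed$to == a)
  }
  # start: v-structure edges and whitelist edges are directed
  directed <- rep(FALSE, nrow(ed))
  parents <- parents_from_edges(ed, vars)
  for (v in vars) {
    ps <- parents[[v]]
    if (length(ps) >= 2) {
      for (i in seq_len(length(ps) - 1)) for (j in seq((i + 1), length(ps))) {
        if (!adj(ps[i], ps[j])) {
          directed[ed$to == v & ed$from %in% c(ps[i], ps[j])] <- TRUE
        }
      }
    }
  }
  directed[paste(ed$from, ed$to) %in% paste(wl$from, wl$to)] <- TRUE

  # Meek closure; orientations inherit the learned DAG's direction
  repeat {
    changed <- FALSE
    for (k in which(!directed)) {
      a <- ed$from[k]; b <- ed$to[k]
      # R1: c -> a directed, c not adjacent to b  =>  a -> b
      cs <- ed$from[directed & ed$to == a]
      r1 <- any(vapply(cs, function(cc) !adj(cc, b) && cc != b, TRUE))
      # R2: a -> c -> b fully directed  =>  a -> b
      mid <- intersect(ed$to[directed & ed$from == a],
                       ed$from[directed & ed$to == b])
      r2 <- length(mid) > 0
      # R3: a - c, a - d (undirected), c -> b, d -> b, c,d nonadjacent
      und_nb <- function(x) {
        u <- !directed
        unique(c(ed$to[u & ed$from == x], ed$from[u & ed$to == x]))
      }
      into_b <- ed$from[directed & ed$to == b]
      cands <- intersect(und_nb(a), into_b)
      r3 <- FALSE
      if (length(cands) >= 2) {
        for (i in seq_len(length(cands) - 1)) {
          for (j in seq((i + 1), length(cands))) {
            if (!adj(cands[i], cands[j])) r3 <- TRUE
          }
        }
      }
      if (isTRUE(r1) || isTRUE(r2) || r3) {
        directed[k] <- TRUE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  edges <- tibble::tibble(from = ed$from, to = ed$to, weight = NA_real_,
                          adj_r2 = NA_real_, directed = directed)
  new_network(edges, nodes = tibble::tibble(node = vars), refined = TRUE,
              score = dag$score, whitelist = if (nrow(wl)) wl else NULL)
}

# ---- refinement ------------------------------------------------------------

#' Refine a subnetwork by Bayesian structure learning
#'
#' Assembles the node-by-sample matrix for every subnetwork node (mRNA
#' expression, miRNA expression, methylation value or copy-number call),
#' learns the structure with the prior edges whitelisted and the subnetwork
#' edges as search candidates, and labels compelled versus reversible
#' regulations. Regression edges that the learned structure does not
#' support are dropped -- the pruning of indirect (false positive) edges
#' that motivates the refinement stage.
#'
#' @param subnet An `integrative_network` (typically from
#'   [extract_subnetwork()]).
#' @param dataset The `multiomics_dataset` the network was learned from.
#' @param prior A `prior_edge_set` (whitelist), or NULL.
#' @param cfg A [bn_config()].
#' @return A `refined_network`.
#' @export
refine_network <- function(subnet, dataset, prior = NULL, cfg = bn_config()) {
  stopifnot(inherits(subnet, "omics_network"),
            inherits(dataset, "multiomics_dataset"))
  nodes <- subnet$nodes$node
  if (length(nodes) == 0) stop("subnetwork is empty", call. = FALSE)
  data <- vapply(nodes, function(v) node_values(dataset, v),
                 numeric(length(dataset$sample_ids)))
  colnames(data) <- nodes
  wl <- if (!is.null(prior)) normalize_whitelist(prior) else NULL
  dag <- learn_structure(data, whitelist = wl, cfg = cfg,
                         candidates = subnet$edges[, c("from", "to")])
  to_cpdag(dag)
}
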