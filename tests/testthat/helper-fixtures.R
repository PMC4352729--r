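# Small builders shared across the suite. Everything is generated in code;
# no binary fixtures.

make_layer <- function(tag, features, samples, fill = NULL) {
  if (is.null(fill)) {
    fill <- switch(tag,
      cnv = sample(-2:2, length(features) * length(samples), replace = TRUE),
      methylation = stats::runif(length(features) * length(samples)),
      stats::rnorm(length(features) * length(samples), mean = 6))
  }
  omics_layer(matrix(fill, nrow = length(features),
                     dimnames = list(features, samples)), tag)
}

# four aligned toy layers over shared samples
tiny_dataset <- function(n_genes = 6, n_mirna = 4, n_meth = 5, n_cnv = 5,
                         n_samples = 30, seed = 1) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    s <- sprintf("S%02d", seq_len(n_samples))
    intersect_samples(
      mrna = make_layer("mrna", sprintf("G%03d", seq_len(n_genes)), s),
      mirna = make_layer("mirna", sprintf("mir-%02d", seq_len(n_mirna)), s),
      methylation = make_layer("methylation", sprintf("G%03d", seq_len(n_meth)), s),
      cnv = make_layer("cnv", sprintf("G%03d", seq_len(n_cnv)), s))
  })
}

write_layer_tsv <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

# exhaustive best subset of exactly size k by adjusted R^2 (independent oracle)
best_subset_k <- function(y, X, k) {
  n <- length(y)
  cols <- colnames(X)
  if (k == 0) return(list(adj = 0, set = character(0)))
  best <- list(adj = -Inf, set = character(0))
  for (idx in utils::combn(length(cols), k, simplify = FALSE)) {
    f <- stats::lm.fit(cbind(1, X[, idx, drop = FALSE]), y)
    r2 <- 1 - sum(f$residuals^2) / sum((y - mean(y))^2)
    adj <- 1 - (1 - r2) * (n - 1) / (n - k - 1)
    if (adj > best$adj) best <- list(adj = adj, set = sort(cols[idx]))
  }
  best
}

# all DAGs over three labeled nodes (25 of them), as from/to tibbles
enum_dags3 <- function(vars = c("X", "Y", "Z")) {
  pairs <- expand.grid(from = vars, to = vars, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  is_acyclic <- function(edges) {
    rem <- vars
    repeat {
      sources <- rem[vapply(rem, function(v) {
        !any(edges$to == v & edges$from %in% rem)
      }, TRUE)]
      if (!length(sources)) return(length(rem) == 0)
      rem <- setdiff(rem, sources)
      if (!length(rem)) return(TRUE)
    }
  }
  out <- list()
  for (mask in 0:(2^6 - 1)) {
    sel <- pairs[bitwAnd(mask, 2^(0:5)) > 0, , drop = FALSE]
    if (is_acyclic(sel)) out[[length(out) + 1]] <- tibble::tibble(
      from = sel$from, to = sel$to)
  }
  out
}

# skeleton + v-structure signature identifying a Markov equivalence class
dag_class_signature <- function(edges, vars = c("X", "Y", "Z")) {
  skel <- sort(apply(cbind(pmin(edges$from, edges$to),
                           pmax(edges$from, edges$to)), 1,
                     paste, collapse = "~"))
  adj <- function(a, b) {
    any(edges$from == a & edges$to == b) || any(edges$from == b & edges$to == a)
  }
  vstr <- character(0)
  for (v in vars) {
    ps <- edges$from[edges$to == v]
    if (length(ps) >= 2) {
      cmb <- utils::combn(sort(ps), 2)
      for (i in seq_len(ncol(cmb))) {
        if (!adj(cmb[1, i], cmb[2, i])) {
          vstr <- c(vstr, paste(cmb[1, i], cmb[2, i], v, sep = ">"))
        }
      }
    }
  }
  paste(paste(skel, collapse = ";"), paste(sort(vstr), collapse = ";"), sep = "|")
}

# one survival table draw
toy_surv <- function(n = 40, seed = 1, rate = 0.2, censor = 0.3) {
  set.seed(seed)
  ev <- rexp(n, rate)
  cs <- if (censor > 0) rexp(n, rate * censor / (1 - censor)) else rep(Inf, n)
  tibble::tibble(sample_id = sprintf("s%03d", seq_len(n)),
                 time = pmin(ev, cs), event = as.integer(ev <= cs),
                 covariate = rnorm(n))
}
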