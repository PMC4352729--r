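#' VIF-regression configuration
#'
#' Tuning parameters of the streamwise selection engine. `m` is the size of
#' the random row subsample used to estimate each candidate's variance
#' inflation (the ratio of its marginal variance to its partial variance
#' given the current model); `w0` and `dw` are the alpha-investing initial
#' wealth and payout. Defaults follow the published defaults of the
#' streamwise VIF algorithm: m = 200 (capped at n), w0 = 0.50, dw = 0.05,
#' a single streamwise pass.
#'
#' @param m Subsample size for variance-inflation estimation.
#' @param w0 Initial alpha-investing wealth, in (0, 1).
#' @param dw Wealth payout added on each accepted feature (> 0).
#' @param max_selected Hard cap on selected features per gene.
#' @param standardize Standardize target and candidates to zero mean / unit
#'   variance before selection (coefficients are reported on the original
#'   scale after the final refit).
#' @param n_passes Number of streamwise passes over the candidate stream.
#' @param seed Integer seed controlling the candidate streaming order and
#'   the estimation subsample.
#' @return A `vif_config` list.
#' @export
vif_config <- function(m = 200L, w0 = 0.5, dw = 0.05, max_selected = 50L,
                       standardize = TRUE, n_passes = 1L, seed = 1L) {
  if (!(w0 > 0 && w0 < 1)) stop("w0 must be in (0, 1)", call. = FALSE)
  if (dw <= 0) stop("dw must be positive", call. = FALSE)
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  structure(list(m = as.integer(m), w0 = w0, dw = dw,
                 max_selected = as.integer(max_selected),
                 standardize = isTRUE(standardize),
                 n_passes = as.integer(n_passes), seed = as.integer(seed)),
            class = "vif_config")
}

#' Adjusted R-squared
#'
#' `1 - (1 - r2) * (n - 1) / (n - p - 1)`: the coefficient of determination
#' penalized for model size; the whole-genome network keeps only per-gene
#' models whose adjusted R2 passes a cutoff (0.4 by default downstream).
#'
#' @param r2 R-squared in \[0, 1\].
#' @param n Number of observations.
#' @param p Number of predictors (excluding the intercept).
#' @return Adjusted R-squared (can be negative).
#' @export
#' @examples
#' adjusted_r2(0.5, n = 10, p = 2) # 1 - 0.5 * 9/7
adjusted_r2 <- function(r2, n, p) {
  if (any(n - p - 1 < 1)) stop("need n - p - 1 >= 1", call. = FALSE)
  if (any(r2 < 0 | r2 > 1)) stop("r2 must be in [0, 1]", call. = FALSE)
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

# deterministic per-gene seed from (global seed, gene id); stays < 2^31
gene_seed <- function(seed, gene) {
  h <- 0
  for (cc in utf8ToInt(gene)) h <- (h * 131 + cc) %% 2147480009
  as.integer((h + as.numeric(seed) * 7919) %% 2147480009)
}

#' Streamwise VIF-corrected selection for one target gene
#'
#' Runs one (by default) streamwise pass over all candidate regulators
#' (every miRNA, gene methylation and gene copy-number feature) in a
#' seed-determined random order. For each candidate the marginal
#' t-statistic against the current model residual is corrected by the
#' estimated variance inflation factor -- the fraction of the candidate's
#' variance left unexplained by the already-selected predictors, estimated
#' on a random m-row subsample -- and tested against the current
#' alpha-investing threshold `w_i / (2 i)`. Acceptance adds the candidate to
#' the model (which is refit) and pays `dw` into the wealth; rejection spends
#' the tested alpha. After the pass the selected set is refit jointly by
#' ordinary least squares on the original scale and the adjusted R-squared
#' of that refit is reported.
#'
#' Complete-case filtering is per model: samples missing the target or any
#' candidate value are dropped for this gene only. Zero-variance candidates
#' are skipped without spending alpha. A constant target yields an empty
#' selection with adjusted R2 = 0; fewer than 10 usable samples yields a
#' result flagged unusable.
#'
#' @param dataset A `multiomics_dataset`.
#' @param target_gene Gene symbol present in the mrna layer.
#' @param cfg A [vif_config()]; the effective per-gene seed is derived
#'   deterministically from `cfg$seed` and `target_gene`, so batch results
#'   do not depend on execution order.
#' @return A `vif_fit`: list with `target_gene`, tibble `selected` (`node`,
#'   `coefficient`), `intercept`, `r2`, `adj_r2`, `n_used`, `n_candidates`,
#'   `n_tests`, `wealth`, `usable`.
#' @export
fit_gene <- function(dataset, target_gene, cfg = vif_config()) {
  stopifnot(inherits(dataset, "multiomics_dataset"))
  if (!(target_gene %in% dataset$mrna$feature_ids)) {
    stop("target gene '", target_gene, "' not found in mrna layer", call. = FALSE)
  }
  X_all <- regulator_matrix(dataset)
  y_all <- dataset$mrna$values[target_gene, ]
  fit_gene_matrix(y_all, X_all, target_gene, cfg)
}

# engine proper: y (named or plain numeric), X samples x candidates
fit_gene_matrix <- function(y, X, target_gene, cfg = vif_config()) {
  n_candidates <- ncol(X)
  keep <- stats::complete.cases(cbind(y, X))
  y <- y[keep]
  X <- X[keep, , drop = FALSE]
  n <- length(y)

  base <- list(target_gene = target_gene,
               selected = tibble::tibble(node = character(), coefficient = numeric()),
               intercept = NA_real_, r2 = 0, adj_r2 = 0, n_used = n,
               n_candidates = n_candidates, n_tests = 0L, wealth = cfg$w0,
               usable = TRUE)
  class(base) <- "vif_fit"
  if (n < 10) {
    warning("gene ", target_gene, ": only ", n,
            " complete samples (< 10); result flagged unusable", call. = FALSE)
    base$usable <- FALSE
    return(base)
  }
  if (stats::sd(y) == 0) {
    base$intercept <- mean(y)
    return(base)
  }
  res <- with_seed(gene_seed(cfg$seed, target_gene), {
    vif_stream(y, X, cfg)
  })
  sel <- res$selected

  # final joint refit on the original scale
  if (length(sel)) {
    Xs <- X[, sel, drop = FALSE]
    fit <- stats::lm.fit(cbind(`(Intercept)` = 1, Xs), y)
    coefs <- fit$coefficients
    coefs[is.na(coefs)] <- 0
    rss <- sum(fit$residuals^2)
    tss <- sum((y - mean(y))^2)
    r2 <- max(0, min(1, 1 - rss / tss))
    p <- length(sel)
    adj <- if (n - p - 1 >= 1) adjusted_r2(r2, n, p) else -Inf
    base$selected <- tibble::tibble(node = sel, coefficient = unname(coefs[-1]))
    base$intercept <- unname(coefs[1])
    base$r2 <- r2
    base$adj_r2 <- adj
  } else {
    base$intercept <- mean(y)
  }
  base$n_tests <- res$n_tests
  base$wealth <- res$wealth
  base
}

# one or more streamwise alpha-investing passes; returns selected column names
vif_stream <- function(y, X, cfg) {
  n <- length(y)
  sds <- apply(X, 2, stats::sd)
  live <- which(sds > 0)
  if (cfg$standardize) {
    y_w <- (y - mean(y)) / stats::sd(y)
    X_w <- X
    X_w[, live] <- scale(X[, live, drop = FALSE])
  } else {
    y_w <- y
    X_w <- X
  }
  m <- min(cfg$m, n)
  sub <- sample.int(n, m)
  order_all <- sample(live)

  css <- colSums(X_w[, live, drop = FALSE]^2)  # x'x per live candidate
  names(css) <- colnames(X_w)[live]

  selected <- character(0)
  wealth <- cfg$w0
  i_test <- 0L

  # caches refreshed whenever the selected set changes
  refresh <- function() {
    if (length(selected)) {
      fit <- stats::lm.fit(cbind(1, X_w[, selected, drop = FALSE]), y_w)
      r <- fit$residuals
      Qs <- qr.Q(qr(cbind(1, X_w[sub, selected, drop = FALSE])))
    } else {
      r <- y_w - mean(y_w)
      Qs <- matrix(1 / sqrt(m), m, 1)
    }
    xtr <- as.numeric(crossprod(X_w[, live, drop = FALSE], r))
    names(xtr) <- colnames(X_w)[live]
    Xsub <- X_w[sub, live, drop = FALSE]
    proj <- crossprod(Qs, Xsub)                       # (p+1) x live
    ss_sub <- colSums(Xsub^2)
    csub <- colSums(Xsub) / m
    tss_sub <- ss_sub - m * csub^2
    rss_sub <- pmax(ss_sub - colSums(proj^2), 0)
    rho <- ifelse(tss_sub > 0, pmin(rss_sub / tss_sub, 1), 0)
    rho <- pmax(rho, 1e-8)
    names(rho) <- colnames(X_w)[live]
    sigma2 <- sum(r^2) / max(n - length(selected) - 1, 1)
    list(r = r, xtr = xtr, rho = rho, sigma = sqrt(sigma2))
  }
  cache <- refresh()

  for (pass in seq_len(cfg$n_passes)) {
    for (j in order_all) {
      node <- colnames(X_w)[j]
      if (node %in% selected) next
      i_test <- i_test + 1L
      alpha_i <- wealth / (2 * i_test)
      t_naive <- cache$xtr[node] / (cache$sigma * sqrt(css[node]))
      t_corr <- t_naive / sqrt(cache$rho[node])
      p_val <- 2 * stats::pnorm(-abs(t_corr))
      if (p_val <= alpha_i && length(selected) < cfg$max_selected) {
        selected <- c(selected, node)
        wealth <- wealth + cfg$dw
        cache <- refresh()
      } else {
        wealth <- wealth - alpha_i
      }
    }
  }
  list(selected = selected, n_tests = i_test, wealth = wealth)
}

#' @export
print.vif_fit <- function(x, ...) {
  cat(sprintf("<vif_fit> %s: %d/%d candidates selected, adj R2 = %.3f (n = %d)%s\n",
              x$target_gene, nrow(x$selected), x$n_candidates, x$adj_r2,
              x$n_used, if (x$usable) "" else " [unusable]"))
  invisible(x)
}

#' Fit the VIF-regression model for every gene
#'
#' One regression per (requested) mRNA gene, each streaming over all
#' candidate regulators. Per-gene seeds are derived deterministically from
#' `cfg$seed` and the gene symbol, so the result is identical however the
#' batch is ordered or split. Per-gene failures are captured as unusable
#' rows rather than aborting the batch.
#'
#' @param dataset A `multiomics_dataset`.
#' @param cfg A [vif_config()].
#' @param genes Optional character vector restricting (and ordering) the
#'   targets; defaults to every gene in the mrna layer.
#' @return A `vif_fits` tibble: one row per gene with `target_gene`,
#'   `n_used`, `n_selected`, `r2`, `adj_r2`, `usable`, and a list-column
#'   `selected` of per-gene coefficient tibbles.
#' @export
fit_all <- function(dataset, cfg = vif_config(), genes = NULL) {
  stopifnot(inherits(dataset, "multiomics_dataset"))
  genes <- genes %||% dataset$mrna$feature_ids
  missing <- setdiff(genes, dataset$mrna$feature_ids)
  if (length(missing)) {
    stop("genes not in mrna layer: ", paste(utils::head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  X_all <- regulator_matrix(dataset)
  rows <- purrr::map(genes, function(g) {
    fit <- tryCatch(
      suppressWarnings(fit_gene_matrix(dataset$mrna$values[g, ], X_all, g, cfg)),
      error = function(e) NULL)
    if (is.null(fit)) {
      return(tibble::tibble(target_gene = g, n_used = 0L, n_selected = 0L,
                            r2 = NA_real_, adj_r2 = NA_real_, intercept = NA_real_,
                            usable = FALSE, selected = list(
                              tibble::tibble(node = character(), coefficient = numeric()))))
    }
    tibble::tibble(target_gene = g, n_used = fit$n_used,
                   n_selected = nrow(fit$selected), r2 = fit$r2,
                   adj_r2 = fit$adj_r2, intercept = fit$intercept,
                   usable = fit$usable, selected = list(fit$selected))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("vif_fits", class(out))
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-gene VIF fits to edge-level rows
#'
#' @param x A `vif_fits` tibble from [fit_all()] or a single `vif_fit`.
#' @param ... Unused.
#' @return One row per (target gene, selected regulator): `target_gene`,
#'   `node`, `coefficient`, `adj_r2`.
#' @method tidy vif_fits
#' @export
tidy.vif_fits <- function(x, ...) {
  out <- tidyr::unnest(
    dplyr::select(tibble::as_tibble(x), "target_gene", "adj_r2", "selected"),
    "selected")
  dplyr::select(out, "target_gene", "node", "coefficient", "adj_r2")
}

#' @rdname tidy.vif_fits
#' @method tidy vif_fit
#' @export
tidy.vif_fit <- function(x, ...) {
  dplyr::mutate(x$selected, target_gene = x$target_gene, adj_r2 = x$adj_r2,
                .before = 1)
}

#' One-row summaries of VIF fits
#'
#' @param x A `vif_fits` tibble or `vif_fit`.
#' @param ... Unused.
#' @return For a batch: one row with gene counts and adjusted-R2 summary;
#'   for a single fit: its headline numbers.
#' @method glance vif_fits
#' @export
glance.vif_fits <- function(x, ...) {
  tibble::tibble(n_genes = nrow(x), n_usable = sum(x$usable),
                 n_selected_total = sum(x$n_selected),
                 median_adj_r2 = stats::median(x$adj_r2, na.rm = TRUE),
                 max_adj_r2 = max(x$adj_r2, na.rm = TRUE))
}

#' @rdname glance.vif_fits
#' @method glance vif_fit
#' @export
glance.vif_fit <- function(x, ...) {
  tibble::tibble(target_gene = x$target_gene, n_selected = nrow(x$selected),
                 r2 = x$r2, adj_r2 = x$adj_r2, n_used = x$n_used,
                 n_tests = x$n_tests, wealth = x$wealth, usable = x$usable)
}
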