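#' Simulation configuration
#'
#' Describes a synthetic multi-omics study with known sparse regulatory
#' structure. The defaults are the package's desk-scale study conditions:
#' 200 genes, 50 miRNAs, 200 gene methylation values and 200 gene-level
#' copy-number calls over 150 samples, so each per-gene regression faces 450
#' candidate predictors with p substantially larger than n, as in genome-scale
#' practice. Half of the genes are regulated by 2-5 regulators drawn across
#' the three non-mRNA layers; the remaining genes are pure noise.
#'
#' @param n_samples,n_genes,n_mirna,n_meth,n_cnv Layer dimensions.
#' @param k_regulators Integer vector of admissible regulator counts per
#'   regulated gene; one value is sampled uniformly per gene.
#' @param target_r2 Population proportion of variance explained by the true
#'   regulators in each regulated gene, strictly inside (0, 1).
#' @param frac_regulated Fraction of genes receiving true regulators.
#' @param effect_signs Named numeric (+1/-1) giving the effect-sign
#'   convention per regulator layer. The default encodes the usual biology:
#'   miRNA and promoter methylation repress, copy-number gain activates.
#' @param baseline_hazard Exponential baseline hazard for simulated survival.
#' @param log_hr Log hazard ratio per standard deviation of the driver
#'   gene's expression.
#' @param censoring_rate Expected fraction of censored subjects (independent
#'   exponential censoring; 0 disables censoring).
#' @param seed Integer seed; the same configuration regenerates bit-identical
#'   data.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_samples = 150, n_genes = 200, n_mirna = 50,
                       n_meth = 200, n_cnv = 200, k_regulators = 2:5,
                       target_r2 = 0.6, frac_regulated = 0.5,
                       effect_signs = c(mirna = -1, methylation = -1, cnv = 1),
                       baseline_hazard = 0.1, log_hr = 1.0,
                       censoring_rate = 0.3, seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
              n_mirna = as.integer(n_mirna), n_meth = as.integer(n_meth),
              n_cnv = as.integer(n_cnv), k_regulators = as.integer(k_regulators),
              target_r2 = target_r2, frac_regulated = frac_regulated,
              effect_signs = effect_signs, baseline_hazard = baseline_hazard,
              log_hr = log_hr, censoring_rate = censoring_rate,
              seed = as.integer(seed))
  counts <- c(cfg$n_samples, cfg$n_genes, cfg$n_mirna, cfg$n_meth, cfg$n_cnv)
  if (any(counts < 1)) stop("all dimension counts must be >= 1", call. = FALSE)
  if (!(cfg$target_r2 > 0 && cfg$target_r2 < 1)) {
    stop("target_r2 must be strictly inside (0, 1)", call. = FALSE)
  }
  if (!(cfg$frac_regulated >= 0 && cfg$frac_regulated <= 1)) {
    stop("frac_regulated must be in [0, 1]", call. = FALSE)
  }
  pool <- cfg$n_mirna + cfg$n_meth + cfg$n_cnv
  if (max(cfg$k_regulators) > pool) {
    stop("k_regulators exceeds the available regulator pool (", pool, ")",
         call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

# evaluate `code` under `seed` without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic multi-omics dataset with known structure
#'
#' Draws the three regulator layers from their natural supports (miRNA:
#' Gaussian on the log2 scale; methylation: Beta-distributed in \[0, 1\];
#' CNV: categorical over \{-2..2\} with most mass at 0), then builds gene
#' expression by a sparse linear model: each regulated gene is an intercept
#' plus a weighted sum of its true regulators plus Gaussian noise, with the
#' noise standard deviation set so the signal explains `target_r2` of the
#' variance. Unregulated genes are pure noise. The true edge list, per-gene
#' noise SD and the designated survival driver gene are returned alongside
#' the data as the ground truth for recovery scoring.
#'
#' @param cfg A [sim_config()].
#' @return A list with `dataset` (a `multiomics_dataset`) and `truth` (a
#'   `ground_truth`: tibble `true_edges` with columns `regulator_node`,
#'   `target_gene`, `effect_size`; tibble `noise_sd`; `driver_gene`; `seed`).
#' @export
generate_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    samples <- sprintf("S%03d", seq_len(cfg$n_samples))
    gene_ids <- sprintf("G%04d", seq_len(cfg$n_genes))
    mirna_ids <- sprintf("mir-%03d", seq_len(cfg$n_mirna))
    meth_ids <- sprintf("G%04d", seq_len(cfg$n_meth))
    cnv_ids <- sprintf("G%04d", seq_len(cfg$n_cnv))

    mirna <- matrix(stats::rnorm(cfg$n_mirna * cfg$n_samples,
                                 mean = rep(stats::runif(cfg$n_mirna, 4, 10), cfg$n_samples)),
                    nrow = cfg$n_mirna, dimnames = list(mirna_ids, samples))
    mu <- stats::runif(cfg$n_meth, 0.2, 0.8)
    conc <- 10
    meth <- matrix(stats::rbeta(cfg$n_meth * cfg$n_samples,
                                shape1 = rep(mu * conc, cfg$n_samples),
                                shape2 = rep((1 - mu) * conc, cfg$n_samples)),
                   nrow = cfg$n_meth, dimnames = list(meth_ids, samples))
    cnv <- matrix(sample(-2:2, cfg$n_cnv * cfg$n_samples, replace = TRUE,
                         prob = c(0.03, 0.12, 0.70, 0.12, 0.03)),
                  nrow = cfg$n_cnv, dimnames = list(cnv_ids, samples))
    storage.mode(cnv) <- "double"

    pool <- c(paste0("mirna:", mirna_ids), paste0("methylation:", meth_ids),
              paste0("cnv:", cnv_ids))
    pool_values <- rbind(mirna, meth, cnv)
    rownames(pool_values) <- pool

    n_reg <- round(cfg$frac_regulated * cfg$n_genes)
    regulated <- if (n_reg > 0) sort(sample(gene_ids, n_reg)) else character(0)

    expr <- matrix(NA_real_, cfg$n_genes, cfg$n_samples,
                   dimnames = list(gene_ids, samples))
    edges <- vector("list", length(regulated))
    noise_sd <- stats::setNames(rep(1, cfg$n_genes), gene_ids)
    for (g in gene_ids) {
      icpt <- stats::runif(1, 5, 10)
      if (g %in% regulated) {
        k <- if (length(cfg$k_regulators) == 1) cfg$k_regulators else
          sample(cfg$k_regulators, 1)
        regs <- sample(pool, k)
        layer <- sub(":.*$", "", regs)
        raw <- pool_values[regs, , drop = FALSE]
        sds <- apply(raw, 1, stats::sd)
        sds[sds == 0] <- 1
        mag <- stats::runif(k, 0.5, 1.5)
        beta_std <- mag * cfg$effect_signs[layer]
        # effect on the raw regulator scale (signal built on standardized scale)
        beta_raw <- beta_std / sds
        signal <- as.numeric(beta_std %*% ((raw - rowMeans(raw)) / sds))
        s_sd <- stats::sd(signal)
        if (s_sd == 0) s_sd <- 1
        nsd <- s_sd * sqrt((1 - cfg$target_r2) / cfg$target_r2)
        noise_sd[g] <- nsd
        expr[g, ] <- icpt + signal + stats::rnorm(cfg$n_samples, sd = nsd)
        edges[[match(g, regulated)]] <- tibble::tibble(
          regulator_node = regs, target_gene = g, effect_size = unname(beta_raw))
      } else {
        expr[g, ] <- icpt + stats::rnorm(cfg$n_samples)
      }
    }
    true_edges <- if (length(edges)) dplyr::bind_rows(edges) else
      tibble::tibble(regulator_node = character(), target_gene = character(),
                     effect_size = numeric())
    driver <- if (length(regulated)) regulated[1] else gene_ids[1]

    dataset <- intersect_samples(
      mrna = omics_layer(expr, "mrna"),
      mirna = omics_layer(mirna, "mirna"),
      methylation = omics_layer(meth, "methylation"),
      cnv = omics_layer(cnv, "cnv"))
    truth <- structure(
      list(true_edges = true_edges,
           noise_sd = tibble::tibble(target_gene = gene_ids,
                                     noise_sd = unname(noise_sd)),
           regulated_genes = regulated, driver_gene = driver, seed = cfg$seed),
      class = "ground_truth")
    list(dataset = dataset, truth = truth)
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d true edges over %d regulated genes; driver: %s\n",
              nrow(x$true_edges), length(x$regulated_genes), x$driver_gene))
  invisible(x)
}

#' Simulate survival outcomes coupled to a driver gene
#'
#' Event times are exponential with a log-hazard linear in the driver gene's
#' standardized expression: hazard = `baseline_hazard * exp(log_hr * z)`.
#' Censoring is an independent exponential time whose rate is calibrated so
#' that roughly `censoring_rate` of subjects are censored at `log_hr = 0`;
#' `censoring_rate = 0` yields fully observed events.
#'
#' @param dataset A `multiomics_dataset`.
#' @param truth The matching `ground_truth` (supplies `driver_gene`), or a
#'   gene symbol.
#' @param cfg The [sim_config()] (supplies hazard parameters and seed).
#' @return A survival tibble: `sample_id`, `time`, `event`, `covariate`
#'   (the driver's expression).
#' @export
generate_survival <- function(dataset, truth, cfg) {
  stopifnot(inherits(dataset, "multiomics_dataset"), inherits(cfg, "sim_config"))
  driver <- if (inherits(truth, "ground_truth")) truth$driver_gene else
    as.character(truth)
  if (!(driver %in% dataset$mrna$feature_ids)) {
    stop("driver gene '", driver, "' not present in the mrna layer", call. = FALSE)
  }
  with_seed(cfg$seed + 1L, {
    x <- dataset$mrna$values[driver, ]
    z <- if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x) else x * 0
    n <- length(x)
    rate <- cfg$baseline_hazard * exp(cfg$log_hr * z)
    t_event <- stats::rexp(n, rate = rate)
    if (cfg$censoring_rate > 0) {
      c_rate <- cfg$baseline_hazard * cfg$censoring_rate / (1 - cfg$censoring_rate)
      t_cens <- stats::rexp(n, rate = c_rate)
    } else {
      t_cens <- rep(Inf, n)
    }
    tibble::tibble(
      sample_id = dataset$sample_ids,
      time = pmin(t_event, t_cens),
      event = as.integer(t_event <= t_cens),
      covariate = unname(x))
  })
}

#' Run the generator and optionally write a study directory
#'
#' Convenience wrapper producing the dataset, ground truth and survival
#' table in one call. When `out_dir` is given, writes the four layer TSVs
#' (`mrna.tsv`, `mirna.tsv`, `methylation.tsv`, `cnv.tsv`), the true edge
#' list (`truth_edges.tsv`) and the survival table (`survival.tsv`).
#'
#' @param cfg A [sim_config()].
#' @param out_dir Optional output directory.
#' @return List with `dataset`, `truth`, `survival`.
#' @export
simulate_study <- function(cfg = sim_config(), out_dir = NULL) {
  gen <- generate_dataset(cfg)
  surv <- generate_survival(gen$dataset, gen$truth, cfg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (tag in c("mrna", "mirna", "methylation", "cnv")) {
      write_omics_layer(gen$dataset[[tag]], file.path(out_dir, paste0(tag, ".tsv")))
    }
    readr::write_tsv(gen$truth$true_edges, file.path(out_dir, "truth_edges.tsv"),
                     progress = FALSE)
    write_survival_table(surv, file.path(out_dir, "survival.tsv"))
  }
  list(dataset = gen$dataset, truth = gen$truth, survival = surv)
}
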