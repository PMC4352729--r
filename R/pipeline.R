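#' Assemble and validate a pipeline configuration
#'
#' A pipeline configuration names the four layer TSVs, the seed-gene and
#' (optional) prior-edge files, the survival table, the stage parameters
#' and the output directory. `pipeline_config()` validates field types and
#' that every referenced file exists, before any computation starts;
#' `read_pipeline_config()` loads the same structure from YAML.
#'
#' @param layers Named list/character of four TSV paths: `mrna`, `mirna`,
#'   `methylation`, `cnv`.
#' @param seed_genes Path to a one-gene-per-line seed file.
#' @param prior_edges Optional path to a 2-column (source, target) TSV of
#'   prior gene-gene regulations.
#' @param survival Optional path to a survival TSV.
#' @param out_dir Output directory (created if needed).
#' @param cutoff Adjusted R-squared assembly cutoff in \[0, 1\].
#' @param vif List of [vif_config()] overrides.
#' @param bn List of [bn_config()] overrides.
#' @param seed Global seed; stage seeds are derived from it.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(layers, seed_genes, prior_edges = NULL,
                            survival = NULL, out_dir = tempfile("vifnet_run_"),
                            cutoff = 0.4, vif = list(), bn = list(),
                            seed = 1L) {
  layers <- as.list(layers)
  need <- c("mrna", "mirna", "methylation", "cnv")
  if (!all(need %in% names(layers))) {
    stop("`layers` must name paths for: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!(cutoff >= 0 && cutoff <= 1)) stop("cutoff must be in [0, 1]", call. = FALSE)
  paths <- c(unlist(layers[need]), seed_genes, prior_edges, survival)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("configured file(s) do not exist: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  structure(list(layers = layers[need], seed_genes = seed_genes,
                 prior_edges = prior_edges, survival = survival,
                 out_dir = out_dir, cutoff = cutoff, vif = vif, bn = bn,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file with the fields above.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' Run the five-stage pipeline end to end
#'
#' Executes sample intersection, per-gene VIF regression, adjusted-R2
#' network assembly, seed-subnetwork extraction, Bayesian refinement and
#' (when a survival table is configured) median-split log-rank validation
#' of the top refined driver. Every artifact is written under
#' `config$out_dir` and recorded in a manifest with its MD5 checksum, so a
#' rerun under the same seed can be verified bit-identical.
#'
#' @param config A [pipeline_config()] (or path to its YAML form).
#' @return A list: `manifest` (tibble: stage, artifact, md5, seconds),
#'   `dataset`, `fits`, `network`, `subnet`, `refined`, `survival`
#'   (validation list or NULL).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  note <- function(stage, files, secs) {
    manifest[[length(manifest) + 1]] <<- tibble::tibble(
      stage = stage, artifact = files,
      md5 = unname(tools::md5sum(files)), seconds = secs)
  }
  stage <- function(name, code) {
    message("== stage: ", name, " ==")
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(code, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    attr(out, "secs") <- proc.time()[["elapsed"]] - t0
    out
  }

  dataset <- stage("intersect", {
    intersect_samples(
      mrna = read_omics_layer(config$layers$mrna, "mrna"),
      mirna = read_omics_layer(config$layers$mirna, "mirna"),
      methylation = read_omics_layer(config$layers$methylation, "methylation"),
      cnv = read_omics_layer(config$layers$cnv, "cnv"))
  })

  vif_cfg <- do.call(vif_config, utils::modifyList(list(seed = config$seed),
                                                   config$vif))
  fits <- stage("vif_regression", fit_all(dataset, vif_cfg))
  f_fits <- file.path(config$out_dir, "models.tsv")
  f_genes <- file.path(config$out_dir, "genes.tsv")
  readr::write_tsv(tidy(fits), f_fits, progress = FALSE)
  readr::write_tsv(dplyr::select(tibble::as_tibble(fits), -"selected"),
                   f_genes, progress = FALSE)
  note("vif_regression", c(f_fits, f_genes), attr(fits, "secs"))

  net <- stage("assemble", assemble_network(fits, cutoff = config$cutoff))
  f_net <- file.path(config$out_dir, "network.tsv")
  write_network(net, f_net, "edge_tsv")
  note("assemble", f_net, attr(net, "secs"))

  seeds <- read_seed_genes(config$seed_genes)
  prior <- if (!is.null(config$prior_edges)) {
    read_prior_edges(config$prior_edges, seed_genes = seeds)
  } else {
    prior_edge_set(NULL, seed_genes = seeds)
  }
  subnet <- stage("extract", extract_subnetwork(net, prior))
  f_sub <- file.path(config$out_dir, "subnetwork.tsv")
  write_network(subnet, f_sub, "edge_tsv")
  note("extract", f_sub, attr(subnet, "secs"))

  bn_cfg <- do.call(bn_config, utils::modifyList(list(seed = config$seed + 1L),
                                                 config$bn))
  refined <- stage("refine", refine_network(subnet, dataset, prior, bn_cfg))
  f_ref <- file.path(config$out_dir, "refined.tsv")
  f_refg <- file.path(config$out_dir, "refined.graphml")
  write_network(refined, f_ref, "edge_tsv")
  write_network(refined, f_refg, "graphml")
  note("refine", c(f_ref, f_refg), attr(refined, "secs"))

  surv <- NULL
  if (!is.null(config$survival)) {
    surv <- stage("survival", {
      tb <- read_survival_table(config$survival)
      survival_validation(tb)
    })
    f_km <- file.path(config$out_dir, "km.tsv")
    f_lr <- file.path(config$out_dir, "logrank.tsv")
    readr::write_tsv(surv$km, f_km, progress = FALSE)
    readr::write_tsv(tidy(surv$logrank), f_lr, progress = FALSE)
    note("survival", c(f_km, f_lr), attr(surv, "secs"))
  }

  manifest <- dplyr::bind_rows(manifest)
  readr::write_tsv(manifest, file.path(config$out_dir, "manifest.tsv"),
                   progress = FALSE)
  list(manifest = manifest, dataset = dataset, fits = fits, network = net,
       subnet = subnet, refined = refined, survival = surv)
}
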