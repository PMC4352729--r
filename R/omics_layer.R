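#' Construct an omics layer
#'
#' An omics layer is one feature-by-sample numeric matrix tagged with the
#' molecular level it measures. Four layer tags are understood: `"mrna"`
#' (log2 gene expression), `"mirna"` (log2 microRNA expression),
#' `"methylation"` (per-gene methylation level in \[0, 1\]) and `"cnv"`
#' (GISTIC-style gene-level copy-number calls in \{-2, -1, 0, 1, 2\}).
#'
#' Values are validated against the layer's declared support: methylation
#' outside \[0, 1\] or a non-integer / out-of-range copy-number call is an
#' error. Missing values (`NA`) are allowed in any layer and are kept as
#' missing, never recoded to zero.
#'
#' @param values Numeric matrix, features in rows, samples in columns.
#'   Row names are feature identifiers, column names sample identifiers;
#'   alternatively pass `feature_ids` / `sample_ids` explicitly.
#' @param layer_tag One of `"mrna"`, `"mirna"`, `"methylation"`, `"cnv"`.
#' @param feature_ids,sample_ids Optional character vectors overriding
#'   `dimnames(values)`.
#' @return An `omics_layer` object.
#' @export
#' @examples
#' m <- matrix(rnorm(6), 3, 2,
#'             dimnames = list(c("TP53", "EGFR", "KRAS"), c("s1", "s2")))
#' omics_layer(m, "mrna")
omics_layer <- function(values, layer_tag, feature_ids = NULL, sample_ids = NULL) {
  layer_tag <- match.arg(layer_tag, c("mrna", "mirna", "methylation", "cnv"))
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (features x samples)", call. = FALSE)
  }
  feature_ids <- feature_ids %||% rownames(values)
  sample_ids <- sample_ids %||% colnames(values)
  if (is.null(feature_ids) || is.null(sample_ids)) {
    stop("feature and sample identifiers are required (dimnames or arguments)",
         call. = FALSE)
  }
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (length(feature_ids) != nrow(values) || length(sample_ids) != ncol(values)) {
    stop("identifier lengths do not match matrix dimensions", call. = FALSE)
  }
  if (anyDuplicated(feature_ids)) {
    dup <- unique(feature_ids[duplicated(feature_ids)])
    stop("duplicate feature IDs in ", layer_tag, " layer: ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample IDs in ", layer_tag, " layer", call. = FALSE)
  }
  dimnames(values) <- list(feature_ids, sample_ids)
  validate_layer_support(values, layer_tag)
  structure(
    list(layer_tag = layer_tag, feature_ids = feature_ids,
         sample_ids = sample_ids, values = values),
    class = "omics_layer"
  )
}

validate_layer_support <- function(values, layer_tag) {
  v <- values[!is.na(values)]
  if (any(!is.finite(v))) {
    stop("non-finite values in ", layer_tag, " layer", call. = FALSE)
  }
  if (layer_tag == "cnv") {
    bad <- v[!(v %in% c(-2, -1, 0, 1, 2))]
    if (length(bad)) {
      stop("cnv layer values must be integers in {-2,...,2}; found ",
           paste(utils::head(unique(bad), 5), collapse = ", "), call. = FALSE)
    }
  }
  if (layer_tag == "methylation") {
    if (any(v < 0 | v > 1)) {
      stop("methylation values must lie in [0, 1]; found value outside range",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.omics_layer <- function(x, ...) {
  cat(sprintf("<omics_layer: %s> %d features x %d samples\n",
              x$layer_tag, length(x$feature_ids), length(x$sample_ids)))
  invisible(x)
}

#' @export
dim.omics_layer <- function(x) dim(x$values)

#' Read one omics layer from a TSV matrix
#'
#' The expected dialect matches common TCGA-style matrix exports:
#' tab-separated, UTF-8, header row of sample IDs, first column of feature
#' IDs, `.` decimal separator, no quoting. Empty cells become `NA` (missing,
#' not zero).
#'
#' @param path Path to the TSV file.
#' @param layer_tag Layer tag, see [omics_layer()].
#' @return An `omics_layer`.
#' @export
read_omics_layer <- function(path, layer_tag) {
  tb <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE, na = c("", "NA"))
  if (ncol(tb) < 2) stop("layer TSV needs a feature-ID column plus >= 1 sample column",
                         call. = FALSE)
  feats <- as.character(tb[[1]])
  body <- as.data.frame(tb[-1])
  num <- suppressWarnings(vapply(body, as.numeric, numeric(nrow(body))))
  if (nrow(body) == 1L) num <- matrix(num, nrow = 1L, dimnames = list(NULL, names(body)))
  bad <- which(is.na(num) & !is.na(as.matrix(body)), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric cell in %s at feature '%s', sample '%s'",
                 path, feats[bad[1, 1]], colnames(num)[bad[1, 2]]), call. = FALSE)
  }
  omics_layer(num, layer_tag, feature_ids = feats, sample_ids = colnames(num))
}

#' Write an omics layer to TSV
#'
#' Inverse of [read_omics_layer()]: first column `feature_id`, one column per
#' sample, tab-separated, missing values written as empty cells.
#'
#' @param layer An `omics_layer`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_omics_layer <- function(layer, path) {
  stopifnot(inherits(layer, "omics_layer"))
  tb <- tibble::as_tibble(layer$values, rownames = "feature_id")
  readr::write_tsv(tb, path, na = "", progress = FALSE)
  invisible(path)
}

#' Restrict four layers to their common samples
#'
#' Computes the exact-string intersection of the four layers' sample sets,
#' sorts it, and reorders every layer's columns to that common order. This is
#' the four-way patient intersection step used when only subjects measured on
#' all four molecular levels enter the analysis.
#'
#' @param mrna,mirna,methylation,cnv `omics_layer` objects with the matching
#'   tags.
#' @return A `multiomics_dataset`: the four aligned layers plus the common
#'   `sample_ids`.
#' @export
intersect_samples <- function(mrna, mirna, methylation, cnv) {
  layers <- list(mrna = mrna, mirna = mirna, methylation = methylation, cnv = cnv)
  for (tag in names(layers)) {
    if (!inherits(layers[[tag]], "omics_layer") || layers[[tag]]$layer_tag != tag) {
      stop("argument `", tag, "` must be an omics_layer tagged '", tag, "'",
           call. = FALSE)
    }
  }
  common <- Reduce(intersect, lapply(layers, function(l) l$sample_ids))
  if (length(common) == 0L) {
    stop("no samples are shared by all four layers", call. = FALSE)
  }
  common <- sort(common)
  layers <- lapply(layers, function(l) {
    omics_layer(l$values[, common, drop = FALSE], l$layer_tag,
                feature_ids = l$feature_ids, sample_ids = common)
  })
  structure(c(layers, list(sample_ids = common)), class = "multiomics_dataset")
}

#' @export
print.multiomics_dataset <- function(x, ...) {
  cat(sprintf(
    "<multiomics_dataset> %d common samples\n  mrna: %d  mirna: %d  methylation: %d  cnv: %d features\n",
    length(x$sample_ids), length(x$mrna$feature_ids), length(x$mirna$feature_ids),
    length(x$methylation$feature_ids), length(x$cnv$feature_ids)))
  invisible(x)
}

#' Number of candidate regulators per gene model
#'
#' Each per-gene regression treats every miRNA, every gene methylation value
#' and every gene copy-number call as a candidate predictor, so the candidate
#' count is the sum of the three regulator layers' feature counts.
#'
#' @param dataset A `multiomics_dataset`.
#' @return Integer candidate count.
#' @export
count_candidates <- function(dataset) {
  stopifnot(inherits(dataset, "multiomics_dataset"))
  length(dataset$mirna$feature_ids) + length(dataset$methylation$feature_ids) +
    length(dataset$cnv$feature_ids)
}

# samples x candidates predictor matrix with layer-qualified column names
regulator_matrix <- function(dataset) {
  blocks <- lapply(c("mirna", "methylation", "cnv"), function(tag) {
    l <- dataset[[tag]]
    m <- t(l$values)
    colnames(m) <- paste0(tag, ":", l$feature_ids)
    m
  })
  do.call(cbind, blocks)
}

# resolve a "layer:feature" node id to its row of data across samples
node_values <- function(dataset, node) {
  parts <- strsplit(node, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2L) stop("node id must be 'layer:feature', got '", node, "'",
                                call. = FALSE)
  layer <- dataset[[parts[1]]]
  if (is.null(layer) || !(parts[2] %in% layer$feature_ids)) {
    stop("node '", node, "' cannot be resolved to a data row", call. = FALSE)
  }
  layer$values[parts[2], ]
}
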