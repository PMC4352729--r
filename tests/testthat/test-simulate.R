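test_that("the generator is bit-identical under a fixed seed", {
  a <- generate_dataset(sim_config(n_genes = 30, n_meth = 30, n_cnv = 30,
                                   n_mirna = 10, n_samples = 40, seed = 5))
  b <- generate_dataset(sim_config(n_genes = 30, n_meth = 30, n_cnv = 30,
                                   n_mirna = 10, n_samples = 40, seed = 5))
  expect_identical(a$dataset$mrna$values, b$dataset$mrna$values)
  expect_identical(a$dataset$cnv$values, b$dataset$cnv$values)
  expect_identical(a$truth$true_edges, b$truth$true_edges)

  c <- generate_dataset(sim_config(n_genes = 30, n_meth = 30, n_cnv = 30,
                                   n_mirna = 10, n_samples = 40, seed = 6))
  expect_false(identical(a$dataset$mrna$values, c$dataset$mrna$values))
})

test_that("layer marginals respect their declared supports", {
  g <- generate_dataset(sim_config(n_genes = 20, n_samples = 60, seed = 3,
                                   n_mirna = 15, n_meth = 40, n_cnv = 40))
  expect_true(all(g$dataset$cnv$values %in% -2:2))
  expect_true(all(g$dataset$methylation$values >= 0 &
                    g$dataset$methylation$values <= 1))
  expect_true(all(is.finite(g$dataset$mrna$values)))
})

test_that("ground truth structure matches the configuration", {
  cfg <- sim_config(n_genes = 50, frac_regulated = 0.4, k_regulators = 2:4,
                    n_samples = 50, n_mirna = 10, n_meth = 50, n_cnv = 50,
                    seed = 8)
  g <- generate_dataset(cfg)
  te <- g$truth$true_edges
  expect_length(g$truth$regulated_genes, 20)
  ks <- table(te$target_gene)
  expect_true(all(ks >= 2 & ks <= 4))
  expect_true(all(sub(":.*$", "", te$regulator_node) %in%
                    c("mirna", "methylation", "cnv")))
  expect_true(all(te$effect_size != 0))
  # declared sign conventions: mirna/methylation repress, cnv activates
  layer <- sub(":.*$", "", te$regulator_node)
  expect_true(all(te$effect_size[layer != "cnv"] < 0))
  expect_true(all(te$effect_size[layer == "cnv"] > 0))

  none <- generate_dataset(sim_config(n_genes = 10, frac_regulated = 0,
                                      n_samples = 20, n_mirna = 5, n_meth = 5,
                                      n_cnv = 5, seed = 1))
  expect_identical(nrow(none$truth$true_edges), 0L)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(target_r2 = 1), "target_r2")
  expect_error(sim_config(n_genes = 0), ">= 1")
  expect_error(sim_config(n_mirna = 2, n_meth = 2, n_cnv = 2,
                          k_regulators = 10), "pool")
})

test_that("oracle least-squares on true regulators attains the target R2", {
  cfg <- sim_config(n_genes = 200, n_samples = 200, target_r2 = 0.6,
                    frac_regulated = 1, seed = 21)
  g <- generate_dataset(cfg)
  X <- t(rbind(g$dataset$mirna$values, g$dataset$methylation$values,
               g$dataset$cnv$values))
  colnames(X) <- c(paste0("mirna:", g$dataset$mirna$feature_ids),
                   paste0("methylation:", g$dataset$methylation$feature_ids),
                   paste0("cnv:", g$dataset$cnv$feature_ids))
  r2s <- vapply(g$truth$regulated_genes, function(gene) {
    regs <- g$truth$true_edges$regulator_node[
      g$truth$true_edges$target_gene == gene]
    y <- g$dataset$mrna$values[gene, ]
    f <- stats::lm.fit(cbind(1, X[, regs, drop = FALSE]), y)
    1 - sum(f$residuals^2) / sum((y - mean(y))^2)
  }, 0)
  expect_gte(mean(r2s >= 0.45 & r2s <= 0.75), 0.95)
})

test_that("true regulators out-fit random disjoint sets of the same size", {
  cfg <- sim_config(n_genes = 40, n_samples = 150, target_r2 = 0.6,
                    frac_regulated = 1, seed = 33)
  g <- generate_dataset(cfg)
  X <- vifnet:::regulator_matrix(g$dataset)
  set.seed(99)
  adj <- function(y, regs) {
    f <- stats::lm.fit(cbind(1, X[, regs, drop = FALSE]), y)
    r2 <- 1 - sum(f$residuals^2) / sum((y - mean(y))^2)
    adjusted_r2(max(0, min(1, r2)), length(y), length(regs))
  }
  wins <- vapply(g$truth$regulated_genes, function(gene) {
    regs <- g$truth$true_edges$regulator_node[
      g$truth$true_edges$target_gene == gene]
    y <- g$dataset$mrna$values[gene, ]
    rand <- sample(setdiff(colnames(X), regs), length(regs))
    adj(y, regs) > adj(y, rand)
  }, TRUE)
  expect_gte(mean(wins), 0.99)
})

test_that("survival generation couples hazard to the driver and censors as asked", {
  cfg <- sim_config(n_genes = 10, n_samples = 120, n_mirna = 5, n_meth = 10,
                    n_cnv = 10, seed = 13, censoring_rate = 0, log_hr = 1)
  g <- generate_dataset(cfg)
  sv <- generate_survival(g$dataset, g$truth, cfg)
  expect_true(all(sv$event == 1L))
  expect_identical(sv$sample_id, g$dataset$sample_ids)
  expect_equal(sv$covariate,
               unname(g$dataset$mrna$values[g$truth$driver_gene, ]))
  # higher driver expression means shorter expected survival
  expect_lt(stats::cor(sv$covariate, sv$time, method = "spearman"), 0)

  cfg2 <- cfg; cfg2$censoring_rate <- 0.4
  sv2 <- generate_survival(g$dataset, g$truth, cfg2)
  expect_true(any(sv2$event == 0L))

  expect_error(generate_survival(g$dataset, "NOPE", cfg), "driver gene")

  # deterministic under the same configuration seed
  expect_identical(generate_survival(g$dataset, g$truth, cfg),
                   generate_survival(g$dataset, g$truth, cfg))
})

test_that("simulate_study writes a complete, reloadable study directory", {
  dir <- tempfile("study_")
  st <- simulate_study(sim_config(n_genes = 12, n_samples = 25, n_mirna = 5,
                                  n_meth = 12, n_cnv = 12, seed = 2), dir)
  expect_true(all(file.exists(file.path(
    dir, c("mrna.tsv", "mirna.tsv", "methylation.tsv", "cnv.tsv",
           "truth_edges.tsv", "survival.tsv")))))
  back <- read_omics_layer(file.path(dir, "mrna.tsv"), "mrna")
  expect_equal(back$values, st$dataset$mrna$values)
})
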