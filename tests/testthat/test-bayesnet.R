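chain_data <- function(n = 400, seed = 1) {
  set.seed(seed)
  x <- rnorm(n); y <- 0.8 * x + rnorm(n); z <- 0.8 * y + rnorm(n)
  cbind(X = x, Y = y, Z = z)
}
collider_data <- function(n = 400, seed = 1) {
  set.seed(seed)
  x <- rnorm(n); y <- rnorm(n); z <- 0.8 * x + 0.8 * y + rnorm(n)
  cbind(X = x, Y = y, Z = z)
}

test_that("the network score agrees with an lm-based BIC computed independently", {
  d <- chain_data(200, seed = 5)
  edges <- tibble::tibble(from = c("X", "Y"), to = c("Y", "Z"))
  mine <- bn_score(d, edges, bn_config())
  df <- as.data.frame(d)
  # per-node Gaussian BIC with ML variance: loglik - log(n)/2 * (k_params)
  ll_node <- function(form, k) {
    f <- stats::lm(form, data = df)
    s2 <- mean(stats::residuals(f)^2)
    -nrow(df) / 2 * (log(2 * pi * s2) + 1) - log(nrow(df)) / 2 * k
  }
  ref <- ll_node(X ~ 1, 2) + ll_node(Y ~ X, 3) + ll_node(Z ~ Y, 3)
  expect_equal(mine, ref, tolerance = 1e-8)
})

test_that("hill climbing finds the exhaustive-search optimum on 3-node data", {
  hits <- 0
  for (r in 1:10) {
    d <- if (r %% 2) chain_data(seed = 40 + r) else collider_data(seed = 40 + r)
    cfg <- bn_config(seed = r, candidate_edges_only = FALSE)
    dag <- learn_structure(d, cfg = cfg)
    exh <- max(vapply(enum_dags3(), function(e) bn_score(d, e, cfg), 0))
    if (abs(dag$score - exh) < 1e-6) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("chain and collider equivalence classes are recovered", {
  cfg <- bn_config(seed = 2, candidate_edges_only = FALSE)
  dag_c <- learn_structure(chain_data(500, 7), cfg = cfg)
  exh <- enum_dags3()
  scores <- vapply(exh, function(e) bn_score(chain_data(500, 7), e, cfg), 0)
  best <- exh[[which.max(scores)]]
  expect_identical(dag_class_signature(dag_c$edges),
                   dag_class_signature(best))
  # chain: skeleton X-Y-Z, no v-structure at Y -> both edges reversible
  cp <- to_cpdag(dag_c)
  expect_identical(nrow(cp$edges), 2L)
  expect_true(all(!cp$edges$directed))

  dag_v <- learn_structure(collider_data(500, 7), cfg = cfg)
  cp_v <- to_cpdag(dag_v)
  expect_identical(nrow(cp_v$edges), 2L)
  expect_true(all(cp_v$edges$directed))
  expect_true(all(cp_v$edges$to == "Z"))
})

test_that("compelled-edge labels agree with brute-force equivalence-class enumeration", {
  cfg <- bn_config(seed = 3, candidate_edges_only = FALSE)
  for (seed in c(11, 23)) {
    for (gen in list(chain_data, collider_data)) {
      d <- gen(500, seed)
      dag <- learn_structure(d, cfg = cfg)
      cp <- to_cpdag(dag)
      sig <- dag_class_signature(dag$edges)
      members <- Filter(function(e) dag_class_signature(e) == sig, enum_dags3())
      expect_gt(length(members), 0)
      for (i in seq_len(nrow(cp$edges))) {
        a <- cp$edges$from[i]; b <- cp$edges$to[i]
        same_dir <- vapply(members, function(e) {
          any(e$from == a & e$to == b)
        }, TRUE)
        compelled_brute <- all(same_dir)
        expect_identical(cp$edges$directed[i], compelled_brute)
      }
    }
  }
})

test_that("whitelist edges are always present, directed, and validated", {
  d <- chain_data(300, 9)
  wl <- tibble::tibble(from = "X", to = "Y")
  dag <- learn_structure(d, whitelist = wl,
                         cfg = bn_config(seed = 1, candidate_edges_only = FALSE))
  expect_true(any(dag$edges$from == "X" & dag$edges$to == "Y"))
  cp <- to_cpdag(dag)
  expect_true(cp$edges$directed[cp$edges$from == "X" & cp$edges$to == "Y"])

  expect_error(learn_structure(d, whitelist = tibble::tibble(
    from = c("X", "Y"), to = c("Y", "X")), cfg = bn_config(seed = 1)),
    "cyclic")
  expect_error(learn_structure(d, whitelist = tibble::tibble(
    from = "X", to = "Q"), cfg = bn_config(seed = 1)), "absent")
})

test_that("independent variables yield an empty graph under BIC", {
  empty_n <- 0
  for (r in 1:10) {
    set.seed(60 + r)
    d <- matrix(rnorm(1200), 400, 3, dimnames = list(NULL, c("X", "Y", "Z")))
    dag <- learn_structure(d, cfg = bn_config(seed = r,
                                              candidate_edges_only = FALSE))
    if (nrow(dag$edges) == 0) empty_n <- empty_n + 1
  }
  expect_gte(empty_n, 9)
})

test_that("the learned graph is acyclic and never below the whitelist-only score", {
  set.seed(71)
  for (r in 1:5) {
    p <- 5; n <- 150
    d <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, sprintf("V%d", 1:p)))
    d[, 2] <- 0.7 * d[, 1] + rnorm(n, sd = 0.5)
    d[, 4] <- 0.7 * d[, 3] + rnorm(n, sd = 0.5)
    wl <- tibble::tibble(from = "V1", to = "V5")
    cfg <- bn_config(seed = r, candidate_edges_only = FALSE)
    dag <- learn_structure(d, whitelist = wl, cfg = cfg)
    # acyclic: topological elimination consumes every node
    parents <- vifnet:::parents_from_edges(dag$edges, dag$nodes)
    rem <- dag$nodes
    repeat {
      src <- rem[vapply(rem, function(v) {
        !length(intersect(parents[[v]], rem))
      }, TRUE)]
      if (!length(src)) break
      rem <- setdiff(rem, src)
    }
    expect_length(rem, 0)
    expect_gte(dag$score, bn_score(d, wl, cfg) - 1e-9)
  }
})

test_that("an indirect regulator is pruned when its signal flows through another", {
  resolved <- 0
  for (r in 1:10) {
    set.seed(300 + r)
    b <- rnorm(400)
    a <- 0.9 * b + rnorm(400, sd = 0.5)
    m <- 0.9 * b + rnorm(400, sd = 0.5)
    d <- cbind(`methylation:B` = b, `mrna:A` = a, `mirna:m` = m)
    cand <- tibble::tibble(from = c("methylation:B", "mirna:m"),
                           to = c("mrna:A", "mrna:A"))
    e <- learn_structure(d, cfg = bn_config(seed = r), candidates = cand)$edges
    kept <- any(e$from == "methylation:B" & e$to == "mrna:A")
    pruned <- !any((e$from == "mirna:m" & e$to == "mrna:A") |
                     (e$from == "mrna:A" & e$to == "mirna:m"))
    if (kept && pruned) resolved <- resolved + 1
  }
  expect_gte(resolved, 7)
})

test_that("refinement is a fixed point on a whitelisted single-edge subnet", {
  st <- simulate_study(sim_config(n_genes = 8, n_samples = 80, n_mirna = 4,
                                  n_meth = 8, n_cnv = 8, frac_regulated = 0.5,
                                  seed = 44))
  g1 <- st$truth$regulated_genes[1]
  g2 <- st$truth$regulated_genes[2]
  prior <- prior_edge_set(tibble::tibble(source = g1, target = g2),
                          seed_genes = c(g1, g2))
  subnet <- new_network(tibble::tibble(
    from = c(paste0("mrna:", g1), paste0("cnv:", g1)),
    to = c(paste0("mrna:", g2), paste0("mrna:", g1))))
  ref <- refine_network(subnet, st$dataset, prior, bn_config(seed = 1))
  expect_true(any(ref$edges$from == paste0("mrna:", g1) &
                    ref$edges$to == paste0("mrna:", g2) & ref$edges$directed))
  # refined edges never leave the candidate + prior universe
  expect_true(all(paste(ref$edges$from, ref$edges$to) %in%
                    paste(subnet$edges$from, subnet$edges$to)))

  empty <- new_network(tibble::tibble(from = character(), to = character()))
  expect_error(refine_network(empty, st$dataset, prior), "empty")

  bad <- new_network(tibble::tibble(from = "mirna:nope", to = paste0("mrna:", g1)))
  expect_error(refine_network(bad, st$dataset, prior, bn_config(seed = 1)),
               "nope")
})
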