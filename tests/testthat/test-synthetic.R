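test_that("generation is bit-identical under a fixed seed", {
  cfg <- sim_config(n_genes = 15, seed = 77)
  a1 <- sim_annotation(cfg)
  a2 <- sim_annotation(cfg)
  expect_identical(rlang::hash(a1), rlang::hash(a2))
  m1 <- sim_methylome(a1, cfg, group = "A")
  m2 <- sim_methylome(a2, cfg, group = "A")
  expect_identical(rlang::hash(m1), rlang::hash(m2))
  e1 <- sim_expression(sim_truth(a1, cfg), cfg)
  e2 <- sim_expression(sim_truth(a2, cfg), cfg)
  expect_identical(rlang::hash(e1), rlang::hash(e2))
  l1 <- sim_lambda_control(100, 10, 0.01, seed = 3)
  l2 <- sim_lambda_control(100, 10, 0.01, seed = 3)
  expect_identical(l1, l2)
})

test_that("an empty gene request yields an all-intergenic genome", {
  cfg <- sim_config(n_genes = 0, seed = 1)
  ann <- sim_annotation(cfg)
  expect_equal(nrow(ann$features), 0L)
  expect_gt(nchar(ann$genome[[1]]), 0L)
})

test_that("genes are disjoint and structured, TEs hit all three contexts", {
  cfg <- sim_config(n_genes = 40, seed = 10)
  ann <- sim_annotation(cfg)
  genes <- ann$features[ann$features$kind == "gene", ]
  expect_equal(nrow(genes), 40L)
  ord <- genes[order(genes$start), ]
  expect_true(all(head(ord$end, -1) <= tail(ord$start, -1)))
  # every gene has exons and at least one intron
  for (kind in c("exon", "intron")) {
    per_gene <- table(
      ann$features$parent[ann$features$kind == kind]
    )
    expect_setequal(names(per_gene), genes$id)
  }
  tes <- ann$features[grepl("^te_", ann$features$id), ]
  ctx <- classify_te_location(tes, genes)
  expect_setequal(unique(ctx$te_context),
                  c("intergenic", "boundary", "genic"))
  # ids record the intended context; verify against interval logic
  intended <- sub("^te_([a-z]+)_.*$", "\\1", ctx$te_id)
  expect_equal(ctx$te_context, intended)
})

test_that("infeasible packing is reported", {
  cfg <- sim_config(n_genes = 50, genome_length = 1000, seed = 1)
  expect_error(sim_annotation(cfg), "Infeasible packing")
})

test_that("the spike-in control is purely conversion noise", {
  zero <- sim_lambda_control(500, 10, 0, seed = 1)
  expect_true(all(zero$count_meth == 0))

  big <- sim_lambda_control(1e5, 10, 0.01, seed = 2)
  frac <- sum(big$count_meth) / sum(big$depth)
  mc_err <- sqrt(0.01 * 0.99 / sum(big$depth))
  expect_lt(abs(frac - 0.01), 3 * mc_err)
})

test_that("a zero-error methylome of unmethylated genes reports no methylation", {
  cfg <- sim_config(
    n_genes = 5, frac_methylated_genes = 0, intergenic_meth_rate = 0,
    conversion_failure = 0, seed = 9
  )
  ann <- sim_annotation(cfg)
  meth <- sim_methylome(ann, cfg, group = "A")
  expect_true(all(meth$sites$count_meth == 0))
})

test_that("observed per-gene weighted levels converge to the true level", {
  cfg <- sim_config(
    n_genes = 40, frac_methylated_genes = 1, depth_mean = 200,
    depth_dispersion = 50, seed = 33
  )
  ann <- sim_annotation(cfg)
  truth <- sim_truth(ann, cfg)
  meth <- sim_methylome(ann, cfg, truth, group = "A", contexts = "CpG")
  genes <- ann$features[ann$features$kind == "gene", ]
  tbl <- feature_methylation_table(meth$sites, genes, min_cpg_sites = 0)
  # W estimates level*(1-eps) + (1-level)*eps; over 40 genes the mean
  # should sit tightly on it
  expected <- cfg$meth_level_high * (1 - cfg$conversion_failure) +
    (1 - cfg$meth_level_high) * cfg$conversion_failure
  expect_equal(mean(tbl$w_level), expected, tolerance = 0.02)
})

test_that("CHH and CHG cytosines carry only conversion noise", {
  cfg <- sim_config(n_genes = 10, seed = 44)
  ann <- sim_annotation(cfg)
  meth <- sim_methylome(ann, cfg, group = "A")
  non_cpg <- meth$sites[meth$sites$context != "CpG", ]
  expect_gt(nrow(non_cpg), 0L)
  frac <- sum(non_cpg$count_meth) / sum(non_cpg$depth)
  expect_lt(abs(frac - cfg$conversion_failure), 0.005)
  expect_false(any(
    meth$site_truth$true_methylated[meth$site_truth$context != "CpG"]
  ))
})

test_that("depth draws follow the truncated negative binomial law", {
  cfg <- sim_config(n_genes = 20, seed = 55)
  ann <- sim_annotation(cfg)
  meth <- sim_methylome(ann, cfg, group = "A")
  expect_true(all(meth$sites$depth >= 1L))
  expect_equal(mean(meth$sites$depth), 15, tolerance = 0.5)
})

test_that("mixture-generated sequences hit their O/E targets", {
  seqs <- sim_mixture_sequences(
    60, length = 1000, weights = 1, means = 0.35, sds = 0.10, seed = 5
  )
  tg <- attr(seqs, "targets")
  comp <- seq_composition(seqs)
  realized <- cpg_oe(comp)
  expect_true(all(abs(realized - tg$target_oe) <= 0.03))
  expect_equal(mean(realized), 0.35, tolerance = 0.05)
  # base composition fixed: every sequence has the same C and G counts
  expect_equal(length(unique(comp$n_c)), 1L)
  expect_equal(length(unique(comp$n_g)), 1L)
})

test_that("an undepleted target yields CpG O/E near 1", {
  seqs <- sim_mixture_sequences(
    20, length = 1000, weights = 1, means = 1, sds = 0.01, seed = 6
  )
  expect_equal(mean(cpg_oe(seq_composition(seqs))), 1, tolerance = 0.03)
})

test_that("unattainable O/E targets are rejected", {
  # O/E of 5 needs more CpGs than the fixed composition allows
  expect_error(
    sim_mixture_sequences(5, length = 1000, weights = 1, means = 5,
                          sds = 1e-6, seed = 1),
    "Unattainable"
  )
  expect_error(
    sim_mixture_sequences(5, length = 100, weights = 1, means = 0.5,
                          sds = 0.1, seed = 1),
    ">= 500"
  )
})

test_that("config invariants are enforced", {
  expect_error(sim_config(frac_methylated_genes = 1.5), "probability")
  expect_error(sim_config(depth_mean = 0.5), "depth_mean")
  expect_error(sim_config(n_genes = -1), "n_genes")
  expect_error(sim_config(expression_mean_ratio = 0), "positive")
})
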