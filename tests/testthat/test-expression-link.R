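test_that("group means and log2 fold changes follow their formulas", {
  expr <- tibble::tibble(
    gene_id = rep("g1", 4),
    sample_id = c("a1", "a2", "a3", "b1"),
    group = c("A", "A", "A", "B"),
    fpkm = c(2, 4, 6, 5)
  )
  expect_equal(group_mean_fpkm(expr, "A")$mean_fpkm, 4)
  expect_equal(group_mean_fpkm(expr, "B")$mean_fpkm, 5)
  expect_error(group_mean_fpkm(expr, "Z"), "No samples")

  expect_equal(log2_fold_change(8, 2, pseudocount = 0), 2)
  expect_equal(log2_fold_change(3, 3, pseudocount = 0), 0)
  expect_equal(log2_fold_change(0, 1, pseudocount = 0.01),
               log2(0.01 / 1.01))
  expect_error(log2_fold_change(0, 0, pseudocount = 0), "undefined")
})

test_that("methylation classes use lower-closed bins", {
  w <- c(0, 0.2, 0.21, 0.7, 0.71, 1)
  cls <- methylation_classes(w)
  expect_equal(
    as.character(cls),
    c("low", "low", "medium", "medium", "high", "high")
  )
  expect_error(methylation_classes(1.2), "\\[0, 1\\]")
})

test_that("pairwise Wilcoxon reproduces the exact enumeration p-value", {
  vals <- c(1, 2, 3, 10, 20, 30)
  cls <- rep(c("low", "high"), each = 3)
  res <- pairwise_wilcoxon(vals, cls)
  expect_equal(res$p_value, 0.1)  # 2/20 arrangements are as extreme

  expect_warning(
    res2 <- pairwise_wilcoxon(c(1, 2, 3, 9), c("a", "a", "a", "b")),
    "fewer than 2"
  )
  expect_true(is.na(res2$p_value))
})

test_that("wilcox.test agrees with the enumeration oracle on small samples", {
  set.seed(42)
  for (rep in 1:60) {
    n_a <- sample(2:4, 1)
    n_b <- sample(2:4, 1)
    a <- sample(100, n_a)   # tie-free for the exact method
    b <- sample(200, n_b) + 0.5
    got <- suppressWarnings(wilcox.test(a, b)$p.value)
    expect_equal(got, wilcoxon_exact_oracle(a, b), tolerance = 1e-12)
  }
})

test_that("spearman_cor matches rank formulas and the enumeration oracle", {
  expect_equal(spearman_cor(1:5, (1:5)^3)$rho, 1)
  expect_equal(spearman_cor(1:5, -(1:5))$rho, -1)
  # rank differences (-1, 1, -1, 1): sum d^2 = 4, rho = 1 - 6*4/(4*15) = 0.6
  expect_equal(spearman_cor(1:4, c(2, 1, 4, 3))$rho, 1 - 6 * 4 / (4 * 15))
  expect_error(spearman_cor(1:5, rep(1, 5)), "constant")

  set.seed(43)
  for (rep in 1:40) {
    n <- sample(4:6, 1)
    x <- sample(100, n)
    y <- sample(100, n)
    got <- spearman_cor(x, y)
    want <- spearman_exact_oracle(x, y)
    expect_equal(got$rho, want$rho, tolerance = 1e-12)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-12)
  }
})

make_meth_table <- function(gene_ids, w, n_sites = 30L) {
  tibble::tibble(
    feature_id = gene_ids, kind = "gene", w_level = w,
    n_cpg_sites = n_sites,
    total_meth_reads = round(w * 100), total_reads = 100L,
    frac_sites_called = w
  )
}

test_that("differential_table flags ceiling(top_fraction * n) genes", {
  set.seed(9)
  for (n in c(1L, 7L, 20L, 100L, 333L)) {
    ids <- sprintf("g%04d", seq_len(n))
    wa <- runif(n)
    wb <- runif(n)
    expr <- tibble::tibble(
      gene_id = rep(ids, 2),
      sample_id = rep(c("a1", "b1"), each = n),
      group = rep(c("A", "B"), each = n),
      fpkm = rexp(2 * n)
    )
    dt <- suppressWarnings(differential_table(
      make_meth_table(ids, wa), make_meth_table(ids, wb),
      expr, "A", "B"
    ))
    expect_equal(sum(dt$passed_top), ceiling(0.05 * n))
  }
})

test_that("genes below the CpG filter are excluded from the differential set", {
  ids <- sprintf("g%d", 1:4)
  ma <- make_meth_table(ids, c(0.1, 0.5, 0.9, 0.3),
                        n_sites = c(10L, 11L, 30L, 5L))
  mb <- make_meth_table(ids, c(0.2, 0.1, 0.2, 0.4), n_sites = 30L)
  expr <- tibble::tibble(
    gene_id = rep(ids, 2), sample_id = rep(c("a1", "b1"), each = 4),
    group = rep(c("A", "B"), each = 4), fpkm = 1
  )
  dt <- suppressWarnings(differential_table(ma, mb, expr, "A", "B"))
  expect_setequal(dt$gene_id, c("g2", "g3"))
})

test_that("stability SDs use the n-1 denominator and the expressed-in-all rule", {
  expr <- tibble::tibble(
    gene_id = rep(c("g1", "g2", "g3"), each = 2),
    sample_id = rep(c("i1", "i2"), 3),
    group = "A",
    fpkm = c(4, 4, 2, 8, 0, 5)
  )
  meth <- make_meth_table(c("g1", "g2", "g3"), c(0.8, 0.1, 0.5))
  st <- expression_stability(expr, c("i1", "i2"), meth)
  expect_setequal(st$gene_id, c("g1", "g2"))  # g3 has a zero
  expect_equal(st$sd_log2_fpkm[st$gene_id == "g1"], 0)
  expect_equal(st$sd_log2_fpkm[st$gene_id == "g2"], sqrt(2))

  st_all <- suppressWarnings(expression_stability(
    expr, c("i1", "i2"), meth, require_expressed_in_all = FALSE
  ))
  expect_setequal(st_all$gene_id, c("g1", "g2", "g3"))
})

test_that("simulated coupling yields the expected qualitative signals", {
  cfg <- sim_config(n_genes = 600, expr_coupling = 2, seed = 4)
  ann <- sim_annotation(cfg)
  truth <- sim_truth(ann, cfg)
  expr <- sim_expression(truth, cfg, n_reps = 8)

  # methylated genes are higher expressed on average
  mean_a <- group_mean_fpkm(expr, "A")
  merged <- dplyr::inner_join(mean_a, truth, by = "gene_id")
  p_expr <- suppressWarnings(wilcox.test(
    merged$mean_fpkm[merged$is_methylated],
    merged$mean_fpkm[!merged$is_methylated],
    alternative = "greater"
  )$p.value)
  expect_lt(p_expr, 1e-6)

  # methylated genes are more stably expressed
  meth_tbl <- make_meth_table(truth$gene_id, truth$level_a)
  inds <- unique(expr$sample_id[expr$group == "A"])
  st <- expression_stability(expr, inds, meth_tbl)
  st <- dplyr::inner_join(st, truth, by = "gene_id")
  p_sd <- suppressWarnings(wilcox.test(
    st$sd_log2_fpkm[st$is_methylated],
    st$sd_log2_fpkm[!st$is_methylated],
    alternative = "less"
  )$p.value)
  expect_lt(p_sd, 1e-6)
})

test_that("null expression simulations show no class difference", {
  cfg <- sim_config(
    n_genes = 400, expression_mean_ratio = 1, expression_cv_ratio = 1,
    seed = 15
  )
  ann <- sim_annotation(cfg)
  truth <- sim_truth(ann, cfg)
  expr <- sim_expression(truth, cfg, n_reps = 5)
  merged <- dplyr::inner_join(group_mean_fpkm(expr, "A"), truth,
                              by = "gene_id")
  p <- suppressWarnings(wilcox.test(
    merged$mean_fpkm[merged$is_methylated],
    merged$mean_fpkm[!merged$is_methylated]
  )$p.value)
  expect_gt(p, 0.001)
})
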