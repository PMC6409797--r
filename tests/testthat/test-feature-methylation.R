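make_sites <- function(pos, m, u, context = "CpG", chrom = "chr1") {
  tibble::tibble(
    chrom = chrom, pos = as.integer(pos), strand = "+",
    context = context, count_meth = as.integer(m),
    count_unmeth = as.integer(u)
  )
}

test_that("sites land in nested features and in intergenic space", {
  features <- tibble::tibble(
    chrom = "chr1",
    start = c(100L, 100L, 150L, 130L),
    end = c(200L, 130L, 200L, 150L),
    strand = "+",
    kind = c("gene", "exon", "exon", "intron"),
    id = c("g1", "g1.e1", "g1.e2", "g1.i1"),
    parent = c(NA, "g1", "g1", "g1")
  )
  sites <- make_sites(c(110, 140, 500), 1, 9)
  hits <- assign_sites_to_features(sites, features)
  in_exon <- hits[hits$pos == 110, ]
  expect_setequal(in_exon$kind, c("gene", "exon"))
  in_intron <- hits[hits$pos == 140, ]
  expect_setequal(in_intron$kind, c("gene", "intron"))
  outside <- hits[hits$pos == 500, ]
  expect_equal(outside$kind, "intergenic")
})

test_that("interval assignment matches the O(N*M) scan on random fixtures", {
  set.seed(31)
  for (rep in 1:8) {
    n_feat <- 30L
    starts <- sample.int(2000, n_feat)
    features <- tibble::tibble(
      chrom = sample(c("c1", "c2"), n_feat, replace = TRUE),
      start = starts,
      end = starts + sample.int(300, n_feat),
      strand = "+",
      kind = sample(c("gene", "exon", "DNA_TE"), n_feat, replace = TRUE),
      id = sprintf("f%02d", seq_len(n_feat)),
      parent = NA_character_
    )
    sites <- tibble::tibble(
      chrom = sample(c("c1", "c2"), 80, replace = TRUE),
      pos = sample.int(2500, 80), strand = "+", context = "CpG",
      count_meth = 1L, count_unmeth = 1L
    )
    got <- assign_sites_to_features(sites, features)
    got <- got[got$kind != "intergenic", c("chrom", "pos", "feature_id")]
    got <- got[order(got$pos, got$feature_id), ]
    want <- interval_assign_oracle(sites, features)
    want$chrom <- sites$chrom[want$site]
    want$pos <- sites$pos[want$site]
    want <- want[order(want$pos, want$feature_id), c("chrom", "pos", "feature_id")]
    expect_equal(as.data.frame(got), as.data.frame(want),
                 ignore_attr = TRUE)
  }
})

test_that("weighted methylation is read-weighted, not site-averaged", {
  expect_equal(weighted_methylation(make_sites(1:2, c(3, 7), c(7, 3))), 0.5)
  expect_equal(weighted_methylation(make_sites(1, 0, 8)), 0)
  # {1/1, 0/9}: site-mean would be 0.5; read-weighting gives 1/10
  expect_equal(weighted_methylation(make_sites(1:2, c(1, 0), c(0, 9))), 0.1)
  expect_true(is.na(weighted_methylation(make_sites(integer(), integer(),
                                                    integer()))))
})

test_that("W is associative under site-list partition", {
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(2:40, 1)
    sites <- make_sites(
      seq_len(n), rbinom(n, 20, 0.3), rbinom(n, 20, 0.7)
    )
    cut_at <- sample(n - 1, 1)
    part1 <- sites[1:cut_at, ]
    part2 <- sites[(cut_at + 1):n, ]
    w_split <- (sum(part1$count_meth) + sum(part2$count_meth)) /
      (sum(part1$count_meth, part1$count_unmeth) +
         sum(part2$count_meth, part2$count_unmeth))
    expect_equal(weighted_methylation(sites), w_split)
    expect_gte(weighted_methylation(sites), 0)
    expect_lte(weighted_methylation(sites), 1)
  }
})

test_that("the more-than-10-CpG filter keeps genes with 11 sites or more", {
  features <- tibble::tibble(
    chrom = "chr1", start = c(0L, 1000L), end = c(500L, 1500L),
    strand = "+", kind = "gene", id = c("g10", "g11"),
    parent = NA_character_
  )
  sites <- dplyr::bind_rows(
    make_sites(seq(10, 100, by = 10), 1, 9),          # 10 sites in g10
    make_sites(seq(1010, 1110, by = 10), 1, 9)        # 11 sites in g11
  )
  tbl <- feature_methylation_table(sites, features, min_cpg_sites = 10)
  expect_equal(tbl$feature_id, "g11")
  all_tbl <- feature_methylation_table(sites, features, min_cpg_sites = 0)
  expect_setequal(all_tbl$feature_id, c("g10", "g11"))
})

test_that("TE context classification matches the brute-force oracle", {
  genes <- tibble::tibble(
    chrom = "chr1", start = 50L, end = 500L, strand = "+",
    kind = "gene", id = "g1", parent = NA_character_
  )
  tes <- tibble::tibble(
    chrom = "chr1",
    start = c(100L, 600L, 480L),
    end = c(200L, 700L, 520L),
    strand = "+", kind = "DNA_TE",
    id = c("te_in", "te_out", "te_edge"), parent = NA_character_
  )
  ctx <- classify_te_location(tes, genes)
  expect_equal(ctx$te_context, c("genic", "intergenic", "boundary"))

  set.seed(77)
  n <- 2000L
  starts <- sample.int(50000, n)
  rand_tes <- tibble::tibble(
    chrom = "chr1", start = starts,
    end = starts + sample.int(400, n, replace = TRUE),
    strand = "+", kind = "DNA_TE",
    id = sprintf("te%04d", seq_len(n)), parent = NA_character_
  )
  g_starts <- sort(sample.int(50000, 40))
  rand_genes <- tibble::tibble(
    chrom = "chr1", start = g_starts, end = g_starts + 600L,
    strand = "+", kind = "gene",
    id = sprintf("g%02d", 1:40), parent = NA_character_
  )
  got <- classify_te_location(rand_tes, rand_genes)
  want <- vapply(seq_len(n), function(i) {
    te_context_oracle(rand_tes[i, ], rand_genes)
  }, character(1))
  expect_equal(got$te_context, want)
})

test_that("element summary conserves the overall fraction and survives no TEs", {
  cfg <- sim_config(n_genes = 25, seed = 13)
  ann <- sim_annotation(cfg)
  meth <- sim_methylome(ann, cfg, group = "A")
  calls <- call_methylation(meth$sites, error_rate = 0.01)
  es <- element_summary(calls, ann$features)
  overall <- es$by_class[es$by_class$class == "overall", ]
  cpg_calls <- calls[calls$context == "CpG", ]
  expect_equal(overall$frac_methylated, mean(cpg_calls$is_methylated))
  # gene + intergenic partition the CpGs exactly once each
  parts <- es$by_class[es$by_class$class %in% c("gene", "intergenic"), ]
  expect_equal(sum(parts$n_cpg), overall$n_cpg)
  expect_equal(
    sum(parts$n_cpg * parts$frac_methylated) / overall$n_cpg,
    overall$frac_methylated,
    tolerance = 1e-12
  )

  no_te <- ann$features[!ann$features$kind %in%
                          c("DNA_TE", "RNA_TE", "unclassified_repeat"), ]
  es2 <- element_summary(calls, no_te)
  expect_equal(nrow(es2$te_median_w), 0L)
})

test_that("per-class methylated fractions recover the generating rates", {
  cfg <- sim_config(n_genes = 120, seed = 99)
  ann <- sim_annotation(cfg)
  truth <- sim_truth(ann, cfg)
  meth <- sim_methylome(ann, cfg, truth, group = "A", contexts = "CpG")
  calls <- call_methylation(meth$sites, error_rate = 0.01)
  es <- element_summary(calls, ann$features)
  genic <- es$by_class[es$by_class$class == "gene", ]
  inter <- es$by_class[es$by_class$class == "intergenic", ]
  # genes: frac_methylated_genes * meth_level_high of CpGs truly methylated,
  # minus sensitivity losses at moderate depth
  expected_genic <- cfg$frac_methylated_genes * cfg$meth_level_high
  expect_gt(genic$frac_methylated, expected_genic - 0.08)
  expect_lt(genic$frac_methylated, expected_genic + 0.08)
  expect_lt(inter$frac_methylated, cfg$intergenic_meth_rate + 0.03)
})
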