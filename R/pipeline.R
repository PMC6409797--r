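#' Run the full synthetic-to-analysis pipeline
#'
#' Orchestrates an end-to-end run: simulate a genome, two population
#' methylomes, a spike-in control, expression and mixture-distributed
#' gene sequences; write them to disk in their standard formats; then
#' read everything back and run calling, per-feature aggregation, element
#' summaries, the differential methylation/expression analysis, the
#' expression stability analysis, CpG O/E with mixture decomposition, and
#' reciprocal-best-hit ortholog correlations. Plain files plus a manifest
#' — reproducibility comes from the seed and the serialized config, not
#' from a workflow engine.
#'
#' @param config A named list (or path to a JSON file) overriding
#'   defaults; see [pipeline_defaults()]. `out_dir` and `seed` are the
#'   two most useful entries.
#' @return A `gbmeth_run` list: per-stage summaries (counts in/out,
#'   conversion error, mixture parameters, correlations) plus the paths
#'   written. The same report is serialized as `report.json` in
#'   `out_dir`, and the config as `config.json`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- utils::modifyList(pipeline_defaults(), config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- cfg$stages
  report <- list(seed = cfg$seed)

  paths <- list(
    coverage_a = file.path(cfg$out_dir, "coverage_A.tsv"),
    coverage_b = file.path(cfg$out_dir, "coverage_B.tsv"),
    control = file.path(cfg$out_dir, "lambda_control.tsv"),
    gff = file.path(cfg$out_dir, "annotation.gff3"),
    expression = file.path(cfg$out_dir, "expression.tsv"),
    genes_a = file.path(cfg$out_dir, "genes_A.fasta"),
    genes_b = file.path(cfg$out_dir, "genes_B.fasta")
  )

  if ("simulate" %in% stages) {
    sim <- sim_config(
      n_genes = cfg$n_genes,
      frac_dm_genes = cfg$frac_dm_genes,
      expr_coupling = cfg$expr_coupling,
      seed = cfg$seed
    )
    ann <- sim_annotation(sim)
    truth <- sim_truth(ann, sim)
    meth_a <- sim_methylome(ann, sim, truth, group = "A")
    meth_b <- sim_methylome(ann, sim, truth, group = "B")
    ctrl <- sim_lambda_control(
      cfg$control_sites, depth = 15L,
      conversion_failure = sim$conversion_failure, seed = cfg$seed + 7L
    )
    expr <- sim_expression(truth, sim, n_reps = cfg$n_reps)
    seeds <- derive_seeds(cfg$seed + 11L, 2L)
    seqs_a <- sim_mixture_sequences(
      cfg$n_mixture_genes, length = 1000L,
      weights = cfg$mixture_weights, means = cfg$mixture_means,
      sds = cfg$mixture_sds, seed = seeds[1L]
    )
    # species B: the same genes with jittered O/E targets, so the
    # cross-species correlation is positive by construction
    tg <- attr(seqs_a, "targets")
    set.seed(seeds[2L])
    tgt_b <- pmax(tg$target_oe + rnorm(nrow(tg), 0, 0.1), 0.05)
    seqs_b <- vapply(tgt_b, function(t) {
      n_c <- round(1000 * 0.5 / 2)
      k <- min(round(t * n_c * n_c / 1000), n_c)
      paste(build_sequence_with_cpg_count(1000L, n_c, n_c, k), collapse = "")
    }, character(1L))
    names(seqs_b) <- sub("^simgene", "simgeneB", names(seqs_a))
    write_coverage(meth_a$sites, paths$coverage_a)
    write_coverage(meth_b$sites, paths$coverage_b)
    write_coverage(ctrl, paths$control)
    write_gff3(ann$features, paths$gff)
    write_expression(expr, paths$expression)
    write_fasta(seqs_a, paths$genes_a)
    write_fasta(seqs_b, paths$genes_b)
    report$simulate <- list(
      n_genes = sim$n_genes,
      genome_length = nchar(ann$genome[[1L]]),
      n_sites_a = nrow(meth_a$sites),
      n_sites_b = nrow(meth_b$sites),
      n_control_sites = nrow(ctrl),
      n_expression_rows = nrow(expr),
      n_mixture_genes = cfg$n_mixture_genes
    )
  }

  need <- function(path, stage) {
    if (!file.exists(path)) {
      abort(sprintf("Stage '%s': missing upstream artifact '%s'.",
                    stage, path))
    }
    path
  }

  calls <- list()
  if ("call" %in% stages) {
    eps <- estimate_conversion_error(
      read_coverage(need(paths$control, "call"))
    )
    for (pop in c("a", "b")) {
      sites <- read_coverage(
        need(paths[[paste0("coverage_", pop)]], "call")
      )
      calls[[pop]] <- call_methylation(
        sites, eps,
        q_threshold = cfg$q_threshold,
        min_depth = cfg$min_depth, max_depth = cfg$max_depth
      )
    }
    report$call <- list(
      error_rate = eps$error_rate,
      conversion_rate = eps$conversion_rate,
      n_retained_a = nrow(calls$a),
      n_retained_b = nrow(calls$b),
      frac_methylated_cpg_a = with(
        calls$a[calls$a$context == "CpG", ], mean(is_methylated)
      )
    )
  }

  features <- if (file.exists(paths$gff)) read_features(paths$gff) else NULL
  featmeth <- list()
  if ("featmeth" %in% stages) {
    need(paths$gff, "featmeth")
    if (length(calls) == 0L) abort("Stage 'featmeth': run 'call' first.")
    for (pop in names(calls)) {
      featmeth[[pop]] <- feature_methylation_table(
        calls[[pop]], features, min_cpg_sites = 0L
      )
    }
    report$featmeth <- list(
      n_genes_a = nrow(featmeth$a), n_genes_b = nrow(featmeth$b)
    )
  }

  if ("elements" %in% stages) {
    if (length(calls) == 0L) abort("Stage 'elements': run 'call' first.")
    es <- element_summary(calls$a, features)
    report$elements <- list(by_class = es$by_class,
                            te_median_w = es$te_median_w)
  }

  if ("diff" %in% stages) {
    if (length(featmeth) < 2L) abort("Stage 'diff': run 'featmeth' first.")
    expr <- read_expression(need(paths$expression, "diff"))
    dt <- differential_table(
      featmeth$a, featmeth$b, expr, "A", "B",
      top_fraction = cfg$top_fraction, min_cpg = cfg$min_cpg
    )
    report$diff <- list(
      n_genes = nrow(dt),
      n_flagged = sum(dt$passed_top),
      spearman = attr(dt, "spearman")
    )
  }

  if ("stability" %in% stages) {
    if (length(featmeth) == 0L) {
      abort("Stage 'stability': run 'featmeth' first.")
    }
    expr <- read_expression(need(paths$expression, "stability"))
    inds <- unique(expr$sample_id[expr$group == "A"])
    st <- expression_stability(
      expr, inds, featmeth$a,
      require_expressed_in_all = TRUE
    )
    report$stability <- list(
      n_genes = nrow(st),
      median_sd = stats::median(st$sd_log2_fpkm)
    )
  }

  oe_a <- NULL
  if ("cpgoe" %in% stages) {
    seqs <- read_fasta(need(paths$genes_a, "cpgoe"))
    oe_a <- gene_set_cpgoe(seqs)
    report$cpgoe <- list(
      n_genes = nrow(oe_a),
      mean_cpg_oe = mean(oe_a$cpg_oe, na.rm = TRUE),
      mean_gpc_oe = mean(oe_a$gpc_oe, na.rm = TRUE)
    )
  }

  if ("mixture" %in% stages) {
    if (is.null(oe_a)) abort("Stage 'mixture': run 'cpgoe' first.")
    fit <- fit_normal_mixture(
      oe_a$cpg_oe, k = cfg$mixture_k,
      n_starts = cfg$n_starts, seed = cfg$seed + 13L
    )
    report$mixture <- c(
      list(components = tidy(fit)), as.list(glance(fit))
    )
  }

  if ("orthologs" %in% stages) {
    seqs_a <- read_fasta(need(paths$genes_a, "orthologs"))
    seqs_b <- read_fasta(need(paths$genes_b, "orthologs"))
    oe_a2 <- gene_set_cpgoe(seqs_a)
    oe_b <- gene_set_cpgoe(seqs_b)
    # synthetic all-vs-self best hits: gene i of A pairs with gene i of B
    hits_ab <- tibble(
      query = oe_a2$id, subject = oe_b$id, score = 100
    )
    hits_ba <- tibble(
      query = oe_b$id, subject = oe_a2$id, score = 100
    )
    pairs <- reciprocal_best_hits(hits_ab, hits_ba)
    records <- ortholog_table(pairs, oe_a2, oe_b)
    report$orthologs <- list(
      n_pairs = nrow(pairs),
      correlations = ortholog_correlations(records)
    )
  }

  jsonlite::write_json(
    cfg, file.path(cfg$out_dir, "config.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  jsonlite::write_json(
    report, file.path(cfg$out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows", null = "null"
  )
  structure(c(report, list(paths = paths)), class = "gbmeth_run")
}

#' Default pipeline configuration
#'
#' Every threshold echoes its conventional default: FDR 0.01, depth band
#' \[5, 30\], more-than-10-CpG gene filter, top 5% differential
#' methylation, 1000-bp genome fragments, 60-bp/10-mismatch/180-bp codon
#' filter.
#'
#' @return A named list of defaults, overridable via [run_pipeline()].
#' @export
pipeline_defaults <- function() {
  list(
    out_dir = file.path(tempdir(), "gbmeth_run"),
    seed = 1L,
    stages = c("simulate", "call", "featmeth", "elements", "diff",
               "stability", "cpgoe", "mixture", "orthologs"),
    n_genes = 200L,
    n_reps = 10L,
    frac_dm_genes = 0.2,
    expr_coupling = 0,
    control_sites = 5000L,
    q_threshold = 0.01,
    min_depth = 5L,
    max_depth = 30L,
    min_cpg = 10L,
    top_fraction = 0.05,
    fragment = 1000L,
    n_mixture_genes = 400L,
    mixture_weights = c(0.5, 0.5),
    mixture_means = c(0.35, 0.65),
    mixture_sds = c(0.10, 0.19),
    mixture_k = 2L,
    n_starts = 10L
  )
}

#' @export
print.gbmeth_run <- function(x, ...) {
  cat("gbmeth pipeline run (seed", x$seed, ")\n")
  for (stage in setdiff(names(x), c("seed", "paths"))) {
    cat("-", stage, "\n")
  }
  invisible(x)
}
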