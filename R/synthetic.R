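#' Configuration for the synthetic methylome generator
#'
#' Bundles every tunable of the generator with defaults that emulate the
#' statistical structure of a bimodally methylated invertebrate genome:
#' a bimodal gene methylation distribution, negative-binomially
#' distributed sequencing depth, a small bisulfite conversion-failure
#' rate calibrated against an unmethylated spike-in, and expression that
#' is higher on average and less variable in methylated genes.
#'
#' @param n_genes Number of genes (default 200).
#' @param genome_length Genome length in bp; `NULL` (default) sizes the
#'   genome to fit the genes plus intergenic spacers. When given, gene
#'   packing must fit or generation fails.
#' @param frac_methylated_genes Fraction of genes in the methylated class
#'   (default 0.45, giving a clearly bimodal distribution).
#' @param meth_level_high True per-site methylation probability inside
#'   methylated genes (default 0.8).
#' @param meth_level_low Same inside unmethylated genes (default 0).
#' @param intergenic_meth_rate True per-site methylation probability of
#'   intergenic CpGs (default 0.05).
#' @param depth_mean,depth_dispersion Negative-binomial sequencing-depth
#'   law (mean 15, size 5), truncated to depth >= 1.
#' @param conversion_failure Per-read probability that an unmethylated
#'   cytosine reads as methylated (default 0.01, i.e. 99% conversion).
#' @param expression_mean_ratio Mean FPKM of methylated relative to
#'   unmethylated genes (default 4).
#' @param expression_cv_ratio Coefficient of variation of methylated
#'   relative to unmethylated genes (default 0.5; < 1 means methylated
#'   genes are more stably expressed).
#' @param base_fpkm Mean FPKM of unmethylated genes (default 10).
#' @param base_cv Coefficient of variation of unmethylated genes
#'   (default 1).
#' @param frac_dm_genes Fraction of methylated genes differentially
#'   methylated between the two simulated populations (default 0.2).
#' @param dm_delta Absolute between-population difference in the true
#'   per-site methylation probability of those genes (default 0.2).
#' @param expr_coupling Log2-FPKM shift per unit of between-population
#'   methylation difference; positive couples differential methylation to
#'   differential expression (default 0: no coupling).
#' @param gc_content Genome GC content (default 0.33, a typical
#'   AT-rich invertebrate genome).
#' @param n_te_per_context Number of transposable elements placed in each
#'   genomic context (intergenic, boundary-spanning, genic); default
#'   `max(2, n_genes %/% 20)`.
#' @param seed Master seed; every generator draws its own stream from it.
#' @return A `sim_config` object (a validated list).
#' @export
sim_config <- function(n_genes = 200L,
                       genome_length = NULL,
                       frac_methylated_genes = 0.45,
                       meth_level_high = 0.8,
                       meth_level_low = 0,
                       intergenic_meth_rate = 0.05,
                       depth_mean = 15,
                       depth_dispersion = 5,
                       conversion_failure = 0.01,
                       expression_mean_ratio = 4,
                       expression_cv_ratio = 0.5,
                       base_fpkm = 10,
                       base_cv = 1,
                       frac_dm_genes = 0.2,
                       dm_delta = 0.2,
                       expr_coupling = 0,
                       gc_content = 0.33,
                       n_te_per_context = NULL,
                       seed = 1L) {
  for (nm in c("frac_methylated_genes", "meth_level_high", "meth_level_low",
               "intergenic_meth_rate", "conversion_failure",
               "frac_dm_genes", "dm_delta", "gc_content")) {
    stop_if_not_scalar_prob(get(nm), nm)
  }
  if (depth_mean < 1) abort("`depth_mean` must be >= 1.")
  if (n_genes < 0L) abort("`n_genes` must be >= 0.")
  if (expression_mean_ratio <= 0 || expression_cv_ratio <= 0) {
    abort("Expression ratios must be positive.")
  }
  structure(
    list(
      n_genes = as.integer(n_genes),
      genome_length = genome_length,
      frac_methylated_genes = frac_methylated_genes,
      meth_level_high = meth_level_high,
      meth_level_low = meth_level_low,
      intergenic_meth_rate = intergenic_meth_rate,
      depth_mean = depth_mean,
      depth_dispersion = depth_dispersion,
      conversion_failure = conversion_failure,
      expression_mean_ratio = expression_mean_ratio,
      expression_cv_ratio = expression_cv_ratio,
      base_fpkm = base_fpkm,
      base_cv = base_cv,
      frac_dm_genes = frac_dm_genes,
      dm_delta = dm_delta,
      expr_coupling = expr_coupling,
      gc_content = gc_content,
      n_te_per_context = n_te_per_context %||% max(2L, n_genes %/% 20L),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# draw gene structures (exon/intron lengths) for layout
draw_gene_structures <- function(n_genes) {
  purrr::map(seq_len(n_genes), function(i) {
    n_exons <- sample(2:4, 1L)
    exon_len <- sample(120:300, n_exons, replace = TRUE)
    intron_len <- sample(60:150, n_exons - 1L, replace = TRUE)
    list(exon_len = exon_len, intron_len = intron_len,
         span = sum(exon_len) + sum(intron_len))
  })
}

#' Generate a synthetic genome and feature annotation
#'
#' Lays out `n_genes` non-overlapping genes (each with at least two exons
#' and one intron) separated by intergenic spacers on a single contig,
#' places transposable elements in all three genomic contexts
#' (intergenic, boundary-spanning, fully genic), and draws an i.i.d.
#' genome sequence at the configured GC content.
#'
#' @param cfg A [sim_config()] object.
#' @return A list of class `sim_annotation`: `genome` (named character
#'   vector of contigs) and `features` (tibble in 0-based half-open
#'   coordinates; kinds `gene`, `exon`, `intron`, `DNA_TE`, `RNA_TE`).
#' @export
sim_annotation <- function(cfg) {
  set.seed(cfg$seed)
  min_gap <- 200L
  if (cfg$n_genes == 0L) {
    len <- cfg$genome_length %||% 10000L
    genome <- c(chr1 = random_genome(len, cfg$gc_content))
    return(structure(
      list(
        genome = genome,
        features = tibble(
          chrom = character(), start = integer(), end = integer(),
          strand = character(), kind = character(), id = character(),
          parent = character()
        )
      ),
      class = "sim_annotation"
    ))
  }
  structures <- draw_gene_structures(cfg$n_genes)
  spans <- vapply(structures, `[[`, numeric(1L), "span")
  required <- sum(spans) + (cfg$n_genes + 1L) * min_gap
  len <- cfg$genome_length %||%
    as.integer(ceiling(required * 1.25))
  if (len < required) {
    abort(sprintf(
      "Infeasible packing: %d genes need >= %d bp but genome_length is %d.",
      cfg$n_genes, required, len
    ))
  }
  # distribute the slack across the n_genes + 1 gaps
  slack <- len - required
  extra <- if (slack > 0L) {
    tabulate(
      sample.int(cfg$n_genes + 1L, slack, replace = TRUE),
      nbins = cfg$n_genes + 1L
    )
  } else {
    integer(cfg$n_genes + 1L)
  }
  gaps <- min_gap + extra

  gene_starts <- cumsum(gaps[seq_len(cfg$n_genes)]) +
    c(0L, cumsum(spans))[seq_len(cfg$n_genes)]
  gene_ends <- as.integer(gene_starts + spans)
  gene_starts <- as.integer(gene_starts)
  gene_ids <- sprintf("gene_%04d", seq_len(cfg$n_genes))
  gene_strands <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  gene_bounds <- cbind(gene_starts, gene_ends)

  # flatten exon/intron coordinates across genes in one pass
  part_list <- purrr::map2(structures, gene_starts, function(st, gs) {
    k <- length(st$exon_len)
    segs <- integer(2L * k - 1L)
    segs[seq(1L, 2L * k - 1L, by = 2L)] <- st$exon_len
    if (k > 1L) {
      segs[seq(2L, 2L * k - 2L, by = 2L)] <- st$intron_len
    }
    offsets <- gs + cumsum(c(0L, segs))
    list(
      start = offsets[-length(offsets)],
      end = offsets[-1L],
      kind = rep(c("exon", "intron"), length.out = 2L * k - 1L),
      # exon j sits at part 2j - 1, intron j at part 2j
      ord = as.integer(ceiling(seq_len(2L * k - 1L) / 2))
    )
  })
  n_parts <- vapply(part_list, function(p) length(p$start), integer(1L))
  part_parent <- rep(gene_ids, n_parts)
  part_strand <- rep(gene_strands, n_parts)
  part_kind <- unlist(lapply(part_list, `[[`, "kind"))
  part_ord <- unlist(lapply(part_list, `[[`, "ord"))
  features <- dplyr::bind_rows(
    tibble(
      chrom = "chr1", start = gene_starts, end = gene_ends,
      strand = gene_strands, kind = "gene", id = gene_ids,
      parent = NA_character_
    ),
    tibble(
      chrom = "chr1",
      start = as.integer(unlist(lapply(part_list, `[[`, "start"))),
      end = as.integer(unlist(lapply(part_list, `[[`, "end"))),
      strand = part_strand,
      kind = part_kind,
      id = sprintf("%s.%s%d", part_parent, part_kind, part_ord),
      parent = part_parent
    )
  )
  features <- dplyr::bind_rows(
    features,
    place_tes(cfg, gene_bounds, gaps, len)
  )
  genome <- c(chr1 = random_genome(len, cfg$gc_content))
  structure(
    list(genome = genome, features = dplyr::arrange(
      features, .data$start, .data$end
    )),
    class = "sim_annotation"
  )
}

random_genome <- function(len, gc) {
  paste(
    sample(
      c("A", "C", "G", "T"), len, replace = TRUE,
      prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    ),
    collapse = ""
  )
}

place_tes <- function(cfg, gene_bounds, gaps, genome_len) {
  n_ctx <- cfg$n_te_per_context
  n_genes <- nrow(gene_bounds)
  te_rows <- list()
  te_id <- 0L
  add_te <- function(start, end, context) {
    te_id <<- te_id + 1L
    tibble(
      chrom = "chr1", start = as.integer(start), end = as.integer(end),
      strand = sample(c("+", "-"), 1L),
      kind = sample(c("DNA_TE", "RNA_TE"), 1L),
      id = sprintf("te_%s_%03d", context, te_id),
      parent = NA_character_
    )
  }
  # intergenic: inside the gap preceding a random gene
  for (i in seq_len(n_ctx)) {
    g <- sample.int(n_genes, 1L)
    gap_start <- gene_bounds[g, 1L] - gaps[g]
    te_len <- sample(80:150, 1L)
    if (gaps[g] > te_len + 20L) {
      st <- gap_start + sample.int(gaps[g] - te_len - 10L, 1L)
      te_rows[[length(te_rows) + 1L]] <- add_te(st, st + te_len, "intergenic")
    }
  }
  # genic: fully inside a random gene's span
  for (i in seq_len(n_ctx)) {
    g <- sample.int(n_genes, 1L)
    span <- gene_bounds[g, 2L] - gene_bounds[g, 1L]
    te_len <- sample(80:150, 1L)
    if (span > te_len + 20L) {
      st <- gene_bounds[g, 1L] + sample.int(span - te_len - 10L, 1L)
      te_rows[[length(te_rows) + 1L]] <- add_te(st, st + te_len, "genic")
    }
  }
  # boundary: straddling a random gene's start
  for (i in seq_len(n_ctx)) {
    g <- sample.int(n_genes, 1L)
    te_len <- sample(80:150, 1L)
    overhang <- te_len %/% 2L
    st <- gene_bounds[g, 1L] - overhang
    if (st >= 0L) {
      te_rows[[length(te_rows) + 1L]] <- add_te(st, st + te_len, "boundary")
    }
  }
  if (length(te_rows) == 0L) {
    return(tibble(
      chrom = character(), start = integer(), end = integer(),
      strand = character(), kind = character(), id = character(),
      parent = character()
    ))
  }
  dplyr::bind_rows(te_rows)
}

#' Draw per-gene ground truth for methylation and expression
#'
#' Assigns each gene to the methylated or unmethylated class, sets its
#' true per-site methylation probability in two populations (a configured
#' fraction of methylated genes is differentially methylated by
#' `dm_delta`), and derives its expression mean and log2-scale standard
#' deviation from the class ratios.
#'
#' @param annotation A [sim_annotation()] object.
#' @param cfg The [sim_config()].
#' @return A tibble: `gene_id`, `is_methylated`, `level_a`, `level_b`,
#'   `expr_mean`, `sd_log2`.
#' @export
sim_truth <- function(annotation, cfg) {
  set.seed(cfg$seed + 1L)
  genes <- annotation$features[annotation$features$kind == "gene", ]
  n <- nrow(genes)
  is_meth <- runif(n) < cfg$frac_methylated_genes
  level_a <- ifelse(is_meth, cfg$meth_level_high, cfg$meth_level_low)
  is_dm <- is_meth & runif(n) < cfg$frac_dm_genes
  dm_sign <- sample(c(-1, 1), n, replace = TRUE)
  level_b <- pmin(pmax(
    level_a + ifelse(is_dm, dm_sign * cfg$dm_delta, 0), 0
  ), 1)
  cv <- ifelse(
    is_meth, cfg$base_cv * cfg$expression_cv_ratio, cfg$base_cv
  )
  tibble(
    gene_id = genes$id,
    is_methylated = is_meth,
    level_a = level_a,
    level_b = level_b,
    expr_mean = ifelse(
      is_meth, cfg$base_fpkm * cfg$expression_mean_ratio, cfg$base_fpkm
    ),
    # sd of log2(FPKM) for a lognormal with the class CV
    sd_log2 = sqrt(log(1 + cv^2)) / log(2)
  )
}

# negative-binomial depth truncated to >= 1 by resampling zeros
draw_depth <- function(n, mean, dispersion) {
  d <- rnbinom(n, mu = mean, size = dispersion)
  zero <- which(d == 0L)
  while (length(zero) > 0L) {
    d[zero] <- rnbinom(length(zero), mu = mean, size = dispersion)
    zero <- zero[d[zero] == 0L]
  }
  d
}

# locate cytosines on both strands with their context
cytosine_sites <- function(chrom, seq) {
  b <- strsplit(seq, "", fixed = TRUE)[[1L]]
  len <- length(b)
  nxt1 <- c(b[-1L], "X")
  nxt2 <- c(b[-(1:2)], "X", "X")
  prv1 <- c("X", b[-len])
  prv2 <- c("X", "X", b[-((len - 1L):len)])
  plus_c <- which(b == "C")
  plus_ctx <- ifelse(
    nxt1[plus_c] == "G", "CpG",
    ifelse(nxt2[plus_c] == "G", "CHG", "CHH")
  )
  minus_c <- which(b == "G")
  # on the minus strand the 3' neighbours are the complemented bases at
  # pos-1 and pos-2 on the plus strand
  minus_ctx <- ifelse(
    prv1[minus_c] == "C", "CpG",
    ifelse(prv2[minus_c] == "C", "CHG", "CHH")
  )
  tibble(
    chrom = chrom,
    pos = c(plus_c, minus_c),
    strand = c(rep("+", length(plus_c)), rep("-", length(minus_c))),
    context = c(plus_ctx, minus_ctx)
  ) |>
    dplyr::arrange(.data$pos, .data$strand)
}

#' Simulate a whole-genome bisulfite methylome
#'
#' Emits one record per cytosine of the synthetic genome (both strands).
#' Each CpG site's true state is Bernoulli with the probability of its
#' containing feature: the gene's true level from the ground truth
#' (population-specific), or the intergenic rate outside genes. CHG/CHH
#' cytosines are always truly unmethylated. Observed methylated counts
#' are Binomial(depth, 1 - eps) at truly methylated sites and
#' Binomial(depth, eps) at truly unmethylated sites, with eps the
#' conversion-failure rate and depth drawn from the truncated
#' negative-binomial depth law.
#'
#' @param annotation A [sim_annotation()] object.
#' @param cfg The [sim_config()].
#' @param truth Ground truth from [sim_truth()]; generated on the fly
#'   when `NULL`.
#' @param group `"A"` or `"B"`: which population's true levels to use.
#' @param contexts Contexts to emit (default all three; restrict to
#'   `"CpG"` for speed in large simulations).
#' @param seed Integer seed; defaults to a stream derived from
#'   `cfg$seed` and the group.
#' @return A list of class `sim_methylome`: `sites` (coverage-style site
#'   tibble), `site_truth` (per-site true state and containing gene),
#'   `truth` (the gene-level ground truth, with the realised per-gene
#'   true weighted level appended as `true_w`).
#' @export
sim_methylome <- function(annotation, cfg, truth = NULL, group = "A",
                          contexts = c("CpG", "CHG", "CHH"), seed = NULL) {
  group <- match.arg(group, c("A", "B"))
  truth <- truth %||% sim_truth(annotation, cfg)
  set.seed(seed %||% (cfg$seed + 100L + (group == "B")))
  sites <- purrr::map_dfr(
    names(annotation$genome),
    function(ch) cytosine_sites(ch, annotation$genome[[ch]])
  )
  sites <- sites[sites$context %in% contexts, , drop = FALSE]
  genes <- annotation$features[annotation$features$kind == "gene", ]
  level_col <- if (group == "A") "level_a" else "level_b"
  gene_of_site <- rep(NA_character_, nrow(sites))
  if (nrow(genes) > 0L && nrow(sites) > 0L) {
    ov <- GenomicRanges::findOverlaps(
      GenomicRanges::GRanges(
        sites$chrom, IRanges::IRanges(start = sites$pos, width = 1L)
      ),
      GenomicRanges::GRanges(
        genes$chrom,
        IRanges::IRanges(start = genes$start + 1L, end = genes$end)
      )
    )
    gene_of_site[S4Vectors::queryHits(ov)] <-
      genes$id[S4Vectors::subjectHits(ov)]
  }
  p_true <- rep(cfg$intergenic_meth_rate, nrow(sites))
  in_gene <- !is.na(gene_of_site)
  p_true[in_gene] <- truth[[level_col]][
    match(gene_of_site[in_gene], truth$gene_id)
  ]
  p_true[sites$context != "CpG"] <- 0
  true_state <- runif(nrow(sites)) < p_true
  depth <- draw_depth(nrow(sites), cfg$depth_mean, cfg$depth_dispersion)
  eps <- cfg$conversion_failure
  m <- integer(nrow(sites))
  m[true_state] <- rbinom(sum(true_state), depth[true_state], 1 - eps)
  m[!true_state] <- rbinom(sum(!true_state), depth[!true_state], eps)
  out_sites <- tibble(
    chrom = sites$chrom, pos = sites$pos, strand = sites$strand,
    context = sites$context,
    count_meth = m, count_unmeth = depth - m, depth = depth
  )
  site_truth <- tibble(
    chrom = sites$chrom, pos = sites$pos, strand = sites$strand,
    context = sites$context,
    true_methylated = true_state, gene_id = gene_of_site
  )
  true_w <- site_truth |>
    dplyr::filter(!is.na(.data$gene_id), .data$context == "CpG") |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(true_w = mean(.data$true_methylated), .groups = "drop")
  structure(
    list(
      sites = out_sites,
      site_truth = site_truth,
      truth = dplyr::left_join(truth, true_w, by = "gene_id")
    ),
    class = "sim_methylome"
  )
}

#' Simulate an unmethylated spike-in conversion control
#'
#' Every site is truly unmethylated; observed methylated counts are
#' Binomial(depth, conversion_failure), so the pooled methylated-read
#' fraction estimates the conversion-failure rate.
#'
#' @param n_sites Number of control cytosines (>= 1).
#' @param depth Read depth per site: a scalar or a vector of length
#'   `n_sites`.
#' @param conversion_failure Per-read conversion-failure probability.
#' @param seed Optional integer seed.
#' @return A coverage-style site tibble on chromosome `"lambda"`.
#' @export
sim_lambda_control <- function(n_sites, depth, conversion_failure,
                               seed = NULL) {
  if (n_sites < 1L) abort("`n_sites` must be >= 1.")
  stop_if_not_scalar_prob(conversion_failure, "conversion_failure")
  if (!is.null(seed)) set.seed(seed)
  depth <- as.integer(rep_len(depth, n_sites))
  m <- rbinom(n_sites, depth, conversion_failure)
  tibble(
    chrom = "lambda", pos = seq_len(n_sites), strand = "+",
    context = "CpG",
    count_meth = m, count_unmeth = depth - m, depth = depth
  )
}

#' Simulate a gene-by-sample FPKM expression matrix
#'
#' Per-gene FPKM is lognormal: methylated genes have a mean
#' `expression_mean_ratio` times the unmethylated mean and a coefficient
#' of variation scaled by `expression_cv_ratio`. With a positive
#' `expr_coupling` the group-specific mean is shifted on the log2 scale
#' in proportion to the gene's between-group difference in true
#' methylation level, coupling differential methylation to differential
#' expression.
#'
#' @param truth Ground truth from [sim_truth()].
#' @param cfg The [sim_config()].
#' @param groups Population labels (default `c("A", "B")`).
#' @param n_reps Replicate individuals per group (default 10).
#' @param seed Optional integer seed (default derived from `cfg$seed`).
#' @return A long expression tibble: `gene_id`, `sample_id`, `group`,
#'   `fpkm`.
#' @export
sim_expression <- function(truth, cfg, groups = c("A", "B"), n_reps = 10L,
                           seed = NULL) {
  set.seed(seed %||% (cfg$seed + 200L))
  level_cols <- c(A = "level_a", B = "level_b")
  grid <- tidyr::expand_grid(
    gene_id = truth$gene_id,
    group = groups,
    rep = seq_len(n_reps)
  )
  tr <- truth[match(grid$gene_id, truth$gene_id), ]
  level_here <- ifelse(
    grid$group == groups[1L] | length(groups) == 1L,
    tr$level_a, tr$level_b
  )
  level_mean <- (tr$level_a + tr$level_b) / 2
  shift <- cfg$expr_coupling * (level_here - level_mean)
  log2_fpkm <- rnorm(
    nrow(grid),
    mean = log2(tr$expr_mean) + shift,
    sd = tr$sd_log2
  )
  tibble(
    gene_id = grid$gene_id,
    sample_id = sprintf("%s_ind%02d", grid$group, grid$rep),
    group = grid$group,
    fpkm = 2^log2_fpkm
  )
}

#' Generate sequences whose CpG O/E follows a normal mixture
#'
#' For each sequence a target CpG O/E is drawn from the given mixture
#' (truncated at 0); a sequence of fixed base composition is then built
#' whose realised CpG O/E matches the target to within `tol`, by
#' permuting base placements: starting from a random shuffle, individual
#' bases are swapped until the CG dinucleotide count equals the target
#' count. Base composition is held fixed so that CpG depletion is
#' isolated from GC-content effects, mirroring the GpC O/E control logic.
#'
#' @param n Number of sequences.
#' @param length Sequence length in bp (>= 500).
#' @param weights,means,sds Mixture parameters (component means must be
#'   positive).
#' @param gc GC content of every sequence (default 0.5).
#' @param tol Maximum allowed |realised - target| O/E (default 0.03).
#' @param seed Optional integer seed.
#' @return A named character vector of sequences with a tibble attribute
#'   `"targets"` (`id`, `target_oe`, `realized_oe`).
#' @export
sim_mixture_sequences <- function(n, length = 1000L, weights, means, sds,
                                  gc = 0.5, tol = 0.03, seed = NULL) {
  if (length < 500L) abort("`length` must be >= 500 bp.")
  if (any(means <= 0)) abort("Component means must be positive.")
  if (!is.null(seed)) set.seed(seed)
  targets <- sample_normal_mixture(
    n, weights, means, sds, truncate_positive = TRUE
  )
  n_c <- round(length * gc / 2)
  n_g <- n_c
  seqs <- character(n)
  realized <- numeric(n)
  for (i in seq_len(n)) {
    k <- round(targets[i] * n_c * n_g / length)
    max_k <- min(n_c, n_g)
    if (targets[i] <= 0 || k > max_k) {
      abort(sprintf(
        "Unattainable CpG O/E target %.3f at GC content %.2f.",
        targets[i], gc
      ))
    }
    x <- build_sequence_with_cpg_count(length, n_c, n_g, k)
    seqs[i] <- paste(x, collapse = "")
    realized[i] <- length * k / (n_c * n_g)
    if (abs(realized[i] - targets[i]) > tol) {
      abort(sprintf(
        "Sequence %d: realised CpG O/E %.3f misses target %.3f by more than %.3f.",
        i, realized[i], targets[i], tol
      ))
    }
  }
  names(seqs) <- sprintf("simgene_%05d", seq_len(n))
  attr(seqs, "targets") <- tibble(
    id = names(seqs), target_oe = targets, realized_oe = realized
  )
  seqs
}

# Random base vector with the given composition, then local swaps until the
# CG dinucleotide count equals k exactly. Swaps that would change the GC
# dinucleotide count are rejected, so GpC O/E keeps its unconditioned
# permutation distribution (mean 1): conditioning on a low CG count alone
# would drag GC down with it via shared CGC/GCG triples.
build_sequence_with_cpg_count <- function(len, n_c, n_g, k) {
  n_at <- len - n_c - n_g
  x <- sample(c(
    rep("C", n_c), rep("G", n_g),
    sample(c("A", "T"), n_at, replace = TRUE)
  ))
  count_cg <- function(v) sum(v[-len] == "C" & v[-1L] == "G")
  count_gc <- function(v) sum(v[-len] == "G" & v[-1L] == "C")
  cur <- count_cg(x)
  gc0 <- count_gc(x)
  max_iter <- 40L * len
  iter <- 0L
  while (cur != k) {
    iter <- iter + 1L
    if (iter > max_iter) {
      abort("CpG placement did not converge; target may be infeasible.")
    }
    if (cur > k) {
      # break a CG: move its G to a random non-G position
      cg_pos <- which(x[-len] == "C" & x[-1L] == "G")
      i <- cg_pos[sample.int(length(cg_pos), 1L)] + 1L
      non_g <- which(x != "G")
      j <- non_g[sample.int(length(non_g), 1L)]
    } else {
      # forge a CG: put a G right after a C currently followed by non-G
      c_pos <- which(x == "C")
      c_pos <- c_pos[c_pos < len & x[c_pos + 1L] != "G"]
      g_pos <- which(x == "G")
      i <- c_pos[sample.int(length(c_pos), 1L)] + 1L
      j <- g_pos[sample.int(length(g_pos), 1L)]
    }
    prop <- x
    prop[c(i, j)] <- x[c(j, i)]
    new <- count_cg(prop)
    closer <- if (cur > k) new < cur else new > cur
    if (closer && count_gc(prop) == gc0) {
      x <- prop
      cur <- new
    }
  }
  x
}
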