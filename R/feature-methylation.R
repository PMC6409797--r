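#' Assign cytosine sites to genomic features
#'
#' A site belongs to a feature when its (1-based) position falls inside the
#' feature's 0-based half-open interval. Sites may belong to several nested
#' features (a gene and one of its exons); sites overlapping no gene are
#' additionally assigned to a synthetic `intergenic` feature per
#' chromosome.
#'
#' @param sites Site tibble (see [read_coverage()]).
#' @param features Feature tibble (see [read_features()]).
#' @return A tibble joining each site to each feature containing it:
#'   all site columns plus `feature_id`, `kind`, `parent`.
#' @export
assign_sites_to_features <- function(sites, features) {
  site_cols <- sites
  site_cols$.site <- seq_len(nrow(sites))
  hits_tbl <- if (nrow(sites) > 0L && nrow(features) > 0L) {
    gr_sites <- GenomicRanges::GRanges(
      sites$chrom, IRanges::IRanges(start = sites$pos, width = 1L)
    )
    gr_feat <- GenomicRanges::GRanges(
      features$chrom,
      IRanges::IRanges(start = features$start + 1L, end = features$end)
    )
    ov <- GenomicRanges::findOverlaps(gr_sites, gr_feat, ignore.strand = TRUE)
    tibble(
      .site = S4Vectors::queryHits(ov),
      feature_id = features$id[S4Vectors::subjectHits(ov)],
      kind = features$kind[S4Vectors::subjectHits(ov)],
      parent = features$parent[S4Vectors::subjectHits(ov)]
    )
  } else {
    tibble(
      .site = integer(), feature_id = character(),
      kind = character(), parent = character()
    )
  }
  in_gene <- unique(hits_tbl$.site[hits_tbl$kind == "gene"])
  inter <- setdiff(site_cols$.site, in_gene)
  if (length(inter) > 0L) {
    hits_tbl <- dplyr::bind_rows(hits_tbl, tibble(
      .site = inter,
      feature_id = paste0("intergenic_", sites$chrom[inter]),
      kind = "intergenic",
      parent = NA_character_
    ))
  }
  dplyr::inner_join(site_cols, hits_tbl, by = ".site") |>
    dplyr::arrange(.data$.site) |>
    dplyr::select(-".site")
}

#' Weighted methylation level of a set of sites
#'
#' The weighted methylation level W of a region is the total methylated
#' read count divided by the total read count over all its cytosines:
#' W = sum(m_i) / sum(m_i + u_i). Read-weighting makes deeply covered
#' sites count more than shallow ones, unlike a mean of per-site fractions.
#'
#' @param sites Site tibble with `count_meth` and `count_unmeth` columns.
#' @return W in \[0, 1\], or `NA_real_` for an empty site list or zero
#'   total depth.
#' @examples
#' weighted_methylation(tibble::tibble(count_meth = c(3, 7),
#'                                     count_unmeth = c(7, 3)))
#' @export
weighted_methylation <- function(sites) {
  if (nrow(sites) == 0L) {
    return(NA_real_)
  }
  total <- sum(sites$count_meth) + sum(sites$count_unmeth)
  if (total == 0L) {
    return(NA_real_)
  }
  sum(sites$count_meth) / total
}

#' Per-feature weighted methylation table
#'
#' Aggregates CpG sites into one row per feature: the weighted methylation
#' level `w_level`, the number of covered CpG sites, total read counts,
#' and (when calls are supplied) the fraction of sites called methylated.
#' Features with `n_cpg_sites <= min_cpg_sites` are dropped, so the
#' conventional "more than 10 CpG sites" filter (`min_cpg_sites = 10`)
#' keeps a feature only when it has at least 11 covered CpGs.
#'
#' W is computed from raw counts of all retained CpG sites regardless of
#' their call status; calls feed only `frac_sites_called`.
#'
#' @param sites Site tibble; only rows with `context == "CpG"` contribute.
#'   If an `is_methylated` column is present (output of
#'   [call_methylation()]) it is used for `frac_sites_called`.
#' @param features Feature tibble.
#' @param min_cpg_sites Drop features with this many covered CpG sites or
#'   fewer (default 0: keep every feature with at least one site).
#' @param kinds Feature kinds to tabulate (default `"gene"`).
#' @return A tibble: `feature_id`, `kind`, `w_level`, `n_cpg_sites`,
#'   `total_meth_reads`, `total_reads`, `frac_sites_called`.
#' @export
feature_methylation_table <- function(sites, features, min_cpg_sites = 0L,
                                      kinds = "gene") {
  cpg <- sites[sites$context == "CpG", , drop = FALSE]
  if (!"is_methylated" %in% names(cpg)) {
    cpg$is_methylated <- NA
  }
  assigned <- assign_sites_to_features(cpg, features)
  assigned <- assigned[assigned$kind %in% kinds, , drop = FALSE]
  assigned |>
    dplyr::group_by(.data$feature_id, .data$kind) |>
    dplyr::summarise(
      w_level = sum(.data$count_meth) /
        pmax(sum(.data$count_meth) + sum(.data$count_unmeth), 1L),
      n_cpg_sites = dplyr::n(),
      total_meth_reads = sum(.data$count_meth),
      total_reads = sum(.data$count_meth) + sum(.data$count_unmeth),
      frac_sites_called = mean(.data$is_methylated),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_cpg_sites > min_cpg_sites)
}

#' Classify transposable elements by genomic context
#'
#' A TE is `genic` when fully contained in some gene, `intergenic` when it
#' overlaps no gene at all, and `boundary` otherwise (it spans a
#' gene/intergenic edge). TEs nested in introns count as genic: context is
#' defined by gene-span overlap, not exon overlap.
#'
#' @param tes Feature tibble of TEs (0-based half-open intervals).
#' @param genes Feature tibble of genes.
#' @return A tibble: `te_id`, `te_context` in
#'   `{"intergenic", "boundary", "genic"}`.
#' @export
classify_te_location <- function(tes, genes) {
  if (nrow(tes) == 0L) {
    return(tibble(te_id = character(), te_context = character()))
  }
  ctx <- rep("intergenic", nrow(tes))
  if (nrow(genes) > 0L) {
    gr_te <- GenomicRanges::GRanges(
      tes$chrom, IRanges::IRanges(start = tes$start + 1L, end = tes$end)
    )
    gr_gene <- GenomicRanges::GRanges(
      genes$chrom, IRanges::IRanges(start = genes$start + 1L, end = genes$end)
    )
    any_ov <- GenomicRanges::countOverlaps(
      gr_te, gr_gene, ignore.strand = TRUE
    ) > 0L
    within <- GenomicRanges::countOverlaps(
      gr_te, gr_gene, type = "within", ignore.strand = TRUE
    ) > 0L
    ctx[any_ov] <- "boundary"
    ctx[within] <- "genic"
  }
  tibble(te_id = tes$id, te_context = ctx)
}

#' Summarise methylation by genomic element class
#'
#' Produces the per-class overview of a methylome: the number of covered
#' CpG sites and the fraction called methylated for the whole genome and
#' each element class (gene, exon, intron, intergenic and TE classes), plus
#' weighted methylation distributions of individual TEs split by their
#' genomic context (intergenic / boundary / genic), with medians.
#'
#' @param calls Called site tibble from [call_methylation()].
#' @param features Feature tibble.
#' @param te_kinds Feature kinds treated as transposable elements
#'   (default `c("DNA_TE", "RNA_TE", "unclassified_repeat")`).
#' @return A list with class `element_summary`:
#'   `by_class` (class, n_cpg, frac_methylated, w_level) and
#'   `te_by_context` (per-TE rows with kind, context and W, plus a
#'   `median_w` summary tibble).
#' @export
element_summary <- function(calls, features,
                            te_kinds = c("DNA_TE", "RNA_TE",
                                         "unclassified_repeat")) {
  cpg <- calls[calls$context == "CpG", , drop = FALSE]
  assigned <- assign_sites_to_features(cpg, features)
  overall <- tibble(
    class = "overall",
    n_cpg = nrow(cpg),
    frac_methylated = if (nrow(cpg) > 0L) mean(cpg$is_methylated) else NA_real_,
    w_level = weighted_methylation(cpg)
  )
  by_class <- assigned |>
    dplyr::group_by(class = .data$kind) |>
    dplyr::summarise(
      n_cpg = dplyr::n(),
      frac_methylated = mean(.data$is_methylated),
      w_level = sum(.data$count_meth) /
        pmax(sum(.data$count_meth) + sum(.data$count_unmeth), 1L),
      .groups = "drop"
    )
  tes <- features[features$kind %in% te_kinds, , drop = FALSE]
  te_ctx <- classify_te_location(tes, features[features$kind == "gene", ])
  te_w <- feature_methylation_table(
    cpg, features, min_cpg_sites = 0L, kinds = te_kinds
  ) |>
    dplyr::left_join(te_ctx, by = c(feature_id = "te_id"))
  median_w <- te_w |>
    dplyr::group_by(.data$kind, .data$te_context) |>
    dplyr::summarise(
      n_te = dplyr::n(),
      median_w = stats::median(.data$w_level),
      .groups = "drop"
    )
  structure(
    list(
      by_class = dplyr::bind_rows(overall, by_class),
      te_by_context = te_w,
      te_median_w = median_w
    ),
    class = "element_summary"
  )
}

#' @export
print.element_summary <- function(x, ...) {
  cat("Methylation by genomic element class:\n")
  print(x$by_class, n = Inf)
  if (nrow(x$te_median_w) > 0L) {
    cat("\nTE weighted methylation by genomic context (medians):\n")
    print(x$te_median_w, n = Inf)
  }
  invisible(x)
}
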