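#' Per-gene mean FPKM within a sample group
#'
#' @param expr Long expression tibble (see [read_expression()]).
#' @param group Group label whose samples are averaged.
#' @return A tibble: `gene_id`, `mean_fpkm`.
#' @export
group_mean_fpkm <- function(expr, group) {
  sub <- expr[!is.na(expr$group) & expr$group == group, , drop = FALSE]
  if (nrow(sub) == 0L) {
    abort(sprintf("No samples with group label '%s'.", group))
  }
  sub |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(mean_fpkm = mean(.data$fpkm), .groups = "drop")
}

#' Log2 fold change between two expression means
#'
#' Computes `log2((mean_a + pseudocount) / (mean_b + pseudocount))`. A
#' small pseudocount keeps the ratio finite for genes silent in one group.
#'
#' @param mean_a,mean_b Non-negative mean expression values (vectorised).
#' @param pseudocount Constant added to both means (default 0.01 FPKM).
#' @return Log2 fold changes.
#' @export
log2_fold_change <- function(mean_a, mean_b, pseudocount = 0.01) {
  if (any(mean_a < 0) || any(mean_b < 0)) {
    abort("Expression means must be non-negative.")
  }
  if (pseudocount == 0 && any(mean_a == 0 & mean_b == 0)) {
    abort("log2 fold change undefined: both means are 0 and pseudocount is 0.")
  }
  log2((mean_a + pseudocount) / (mean_b + pseudocount))
}

#' Bin weighted methylation levels into low / medium / high classes
#'
#' Bins: low \[0, 0.2\], medium (0.2, 0.7\], high (0.7, 1\]. Values on a
#' bin edge fall in the lower class.
#'
#' @param w Weighted methylation levels in \[0, 1\].
#' @return A factor with levels `low`, `medium`, `high`.
#' @export
methylation_classes <- function(w) {
  if (any(w < 0 | w > 1, na.rm = TRUE)) {
    abort("Methylation levels must lie in [0, 1].")
  }
  cut(
    w,
    breaks = c(-Inf, 0.2, 0.7, 1),
    labels = c("low", "medium", "high"),
    right = TRUE
  )
}

#' Pairwise Wilcoxon rank-sum tests across methylation classes
#'
#' Two-sided rank-sum test for every pair of classes; exact when both
#' classes are small and tie-free, normal approximation with tie
#' correction otherwise (the [stats::wilcox.test()] rules).
#'
#' @param values Numeric vector (e.g. per-gene FPKM).
#' @param classes Factor or character vector of the same length.
#' @return A tibble: `class_a`, `class_b`, `n_a`, `n_b`, `p_value`. Pairs
#'   with fewer than 2 observations in a class are skipped with a warning.
#' @export
pairwise_wilcoxon <- function(values, classes) {
  classes <- as.factor(classes)
  keep <- !is.na(values) & !is.na(classes)
  values <- values[keep]
  classes <- droplevels(classes[keep])
  lv <- levels(classes)
  if (length(lv) < 2L) {
    abort("Need at least two non-empty classes.")
  }
  pairs <- utils::combn(lv, 2L)
  purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- values[classes == pairs[1L, i]]
    b <- values[classes == pairs[2L, i]]
    if (length(a) < 2L || length(b) < 2L) {
      warn(sprintf(
        "Skipping pair %s/%s: a class has fewer than 2 observations.",
        pairs[1L, i], pairs[2L, i]
      ))
      return(tibble(
        class_a = pairs[1L, i], class_b = pairs[2L, i],
        n_a = length(a), n_b = length(b), p_value = NA_real_
      ))
    }
    p <- suppressWarnings(
      wilcox.test(a, b, alternative = "two.sided")$p.value
    )
    tibble(
      class_a = pairs[1L, i], class_b = pairs[2L, i],
      n_a = length(a), n_b = length(b), p_value = p
    )
  })
}

#' Spearman rank correlation with p-value
#'
#' Rank correlation with average ranks for ties; exact p for small
#' tie-free samples, t-approximation otherwise (the [stats::cor.test()]
#' rules).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A list with `rho` and `p_value`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    abort("`x` and `y` must have equal length >= 3.")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Spearman correlation undefined for a constant vector.")
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Differential methylation versus differential expression
#'
#' For each gene present in both populations' methylation tables, computes
#' the between-population difference in weighted methylation level
#' (`delta_w`, population A minus population B) and the log2 fold change in
#' mean FPKM (A over B). Genes must clear the CpG coverage filter in both
#' populations (`n_cpg_sites > min_cpg` in each). Genes are ranked by
#' |delta_w| and the top fraction flagged; ties at the cutoff are all kept.
#' The Spearman correlation of `log2_fc` against `delta_w` over the
#' flagged genes is attached as attribute `"spearman"`.
#'
#' @param meth_a,meth_b Feature methylation tables
#'   (see [feature_methylation_table()]) for populations A and B.
#' @param expr Long expression tibble with group labels.
#' @param group_a,group_b Group labels of the two populations in `expr`.
#' @param top_fraction Fraction of genes (by |delta_w|) flagged for the
#'   correlation (default 0.05).
#' @param min_cpg Keep genes with more than this many covered CpGs
#'   (default 10, i.e. at least 11).
#' @param pseudocount Pseudocount for [log2_fold_change()].
#' @return A tibble: `gene_id`, `delta_w`, `log2_fc`, `passed_top`;
#'   attribute `"spearman"` holds the correlation over flagged genes.
#' @export
differential_table <- function(meth_a, meth_b, expr, group_a, group_b,
                               top_fraction = 0.05, min_cpg = 10L,
                               pseudocount = 0.01) {
  ma <- meth_a[meth_a$n_cpg_sites > min_cpg, c("feature_id", "w_level")]
  mb <- meth_b[meth_b$n_cpg_sites > min_cpg, c("feature_id", "w_level")]
  meth <- dplyr::inner_join(
    ma, mb, by = "feature_id", suffix = c("_a", "_b")
  )
  ea <- group_mean_fpkm(expr, group_a)
  eb <- group_mean_fpkm(expr, group_b)
  dat <- meth |>
    dplyr::inner_join(ea, by = c(feature_id = "gene_id")) |>
    dplyr::inner_join(
      eb, by = c(feature_id = "gene_id"), suffix = c("_a", "_b")
    ) |>
    dplyr::transmute(
      gene_id = .data$feature_id,
      delta_w = .data$w_level_a - .data$w_level_b,
      log2_fc = log2_fold_change(
        .data$mean_fpkm_a, .data$mean_fpkm_b, pseudocount
      )
    )
  n <- nrow(dat)
  if (n == 0L) {
    dat$passed_top <- logical(0)
    attr(dat, "spearman") <- list(rho = NA_real_, p_value = NA_real_)
    return(dat)
  }
  n_flag <- ceiling(top_fraction * n)
  cut_val <- sort(abs(dat$delta_w), decreasing = TRUE)[n_flag]
  dat$passed_top <- abs(dat$delta_w) >= cut_val
  if (sum(dat$passed_top) > n_flag) {
    message(sprintf(
      "Ties at the top-%g%% cutoff: %d genes flagged (nominal %d).",
      100 * top_fraction, sum(dat$passed_top), n_flag
    ))
  }
  flagged <- dat[dat$passed_top, , drop = FALSE]
  sp <- if (nrow(flagged) >= 3L &&
            sd(flagged$delta_w) > 0 && sd(flagged$log2_fc) > 0) {
    if (nrow(flagged) < 10L) {
      warn("Fewer than 10 genes pass the top filter; correlation is unstable.")
    }
    spearman_cor(flagged$delta_w, flagged$log2_fc)
  } else {
    list(rho = NA_real_, p_value = NA_real_)
  }
  attr(dat, "spearman") <- sp
  dat
}

#' Expression stability versus methylation
#'
#' For each gene, the sample standard deviation (n - 1 denominator) of
#' log2(FPKM) across a designated set of individuals, paired with the
#' gene's weighted methylation level and fraction of sites called
#' methylated from the same individuals. By default only genes expressed
#' (FPKM > 0) in every individual are included; the alternate mode keeps
#' genes expressed in at least one individual and applies the pseudocount
#' before taking logs.
#'
#' @param expr Long expression tibble.
#' @param individuals Sample ids defining the individual set.
#' @param meth_table Feature methylation table for the same individuals.
#' @param require_expressed_in_all Keep only genes with FPKM > 0 in every
#'   individual (default `TRUE`).
#' @param pseudocount Pseudocount used when
#'   `require_expressed_in_all = FALSE` (default 0.01).
#' @return A tibble: `gene_id`, `sd_log2_fpkm`, `w_level`,
#'   `frac_sites_called`, `n_individuals`.
#' @export
expression_stability <- function(expr, individuals, meth_table,
                                 require_expressed_in_all = TRUE,
                                 pseudocount = 0.01) {
  if (length(individuals) < 2L) {
    abort("Need at least two individuals to compute a standard deviation.")
  }
  sub <- expr[expr$sample_id %in% individuals, , drop = FALSE]
  stats_tbl <- sub |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      n_individuals = dplyr::n(),
      n_expressed = sum(.data$fpkm > 0),
      sd_log2_fpkm = if (require_expressed_in_all) {
        sd(log2(.data$fpkm))
      } else {
        sd(log2(.data$fpkm + pseudocount))
      },
      .groups = "drop"
    )
  keep <- if (require_expressed_in_all) {
    stats_tbl$n_expressed == stats_tbl$n_individuals
  } else {
    stats_tbl$n_expressed >= 1L
  }
  stats_tbl[keep, , drop = FALSE] |>
    dplyr::inner_join(
      dplyr::select(
        meth_table, "feature_id", "w_level", "frac_sites_called"
      ),
      by = c(gene_id = "feature_id")
    ) |>
    dplyr::select(
      "gene_id", "sd_log2_fpkm", "w_level", "frac_sites_called",
      "n_individuals"
    )
}
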