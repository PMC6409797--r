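#' Reciprocal best hits between two gene sets
#'
#' Pairs gene `a` of species A with gene `b` of species B when `b` is the
#' unique highest-scoring hit of `a` and `a` is the unique
#' highest-scoring hit of `b`. A score tie at the top of either list
#' disqualifies that query: ambiguous best hits yield no pair.
#'
#' @param hits_ab Tibble of hits from A against B: `query`, `subject`,
#'   `score` (higher is better).
#' @param hits_ba Tibble of hits from B against A, same columns.
#' @return A tibble of ortholog pairs: `gene_a`, `gene_b`.
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba) {
  best_ab <- unique_best(hits_ab)
  best_ba <- unique_best(hits_ba)
  dplyr::inner_join(
    best_ab, best_ba,
    by = c(query = "subject", subject = "query")
  ) |>
    dplyr::transmute(gene_a = .data$query, gene_b = .data$subject) |>
    dplyr::arrange(.data$gene_a)
}

# the unique top-scoring subject per query; queries whose top score is tied
# are dropped
unique_best <- function(hits) {
  if (any(!is.finite(hits$score))) {
    abort("Hit scores must be finite.")
  }
  hits |>
    dplyr::group_by(.data$query) |>
    dplyr::filter(.data$score == max(.data$score)) |>
    dplyr::filter(dplyr::n() == 1L) |>
    dplyr::ungroup() |>
    dplyr::select("query", "subject")
}

#' Assemble an ortholog record table
#'
#' Joins reciprocal-best-hit pairs with per-gene CpG O/E values of both
#' species and, optionally, externally computed substitution rates.
#'
#' @param pairs Pair tibble from [reciprocal_best_hits()].
#' @param cpgoe_a,cpgoe_b Per-gene CpG O/E tables
#'   (see [gene_set_cpgoe()]) for species A and B.
#' @param rates Optional tibble `gene_a`, `dn`, `ds` of substitution-rate
#'   estimates keyed by the species-A gene id.
#' @return A tibble: `gene_a`, `gene_b`, `cpg_oe_a`, `cpg_oe_b`,
#'   `mean_cpg_oe`, and when rates are given `dn`, `ds`, `dn_ds`
#'   (`NA` when `ds` is 0 or missing).
#' @export
ortholog_table <- function(pairs, cpgoe_a, cpgoe_b, rates = NULL) {
  out <- pairs |>
    dplyr::inner_join(
      dplyr::select(cpgoe_a, "id", cpg_oe_a = "cpg_oe"),
      by = c(gene_a = "id")
    ) |>
    dplyr::inner_join(
      dplyr::select(cpgoe_b, "id", cpg_oe_b = "cpg_oe"),
      by = c(gene_b = "id")
    ) |>
    dplyr::mutate(mean_cpg_oe = (.data$cpg_oe_a + .data$cpg_oe_b) / 2)
  if (!is.null(rates)) {
    out <- out |>
      dplyr::left_join(rates, by = "gene_a") |>
      dplyr::mutate(
        dn_ds = ifelse(
          !is.na(.data$ds) & .data$ds > 0, .data$dn / .data$ds, NA_real_
        )
      )
  }
  out
}

#' Filter a pairwise codon alignment by local identity
#'
#' Keeps a codon exactly when it lies fully inside at least one 60-bp
#' window (codon-aligned, sliding in 3-bp steps) with at most
#' `max_mismatch` non-identical positions; mismatches and gap positions
#' both count as non-identical. Kept codons are concatenated, and the
#' alignment is retained only when the filtered length strictly exceeds
#' `min_length` bp.
#'
#' @param seq_a,seq_b Aligned nucleotide sequences of equal length
#'   divisible by 3; gaps as `-`.
#' @param window Window size in bp (default 60; must be a multiple of 3).
#' @param max_mismatch Maximum non-identical positions per passing window
#'   (default 10).
#' @param min_length Minimum filtered length in bp, exclusive
#'   (default 180).
#' @return A list: `a`, `b` (filtered sequences), `kept_codons` (logical
#'   per input codon), `length` (filtered bp), `retained` (whether the
#'   alignment survives the length rule).
#' @export
filter_codon_alignment <- function(seq_a, seq_b, window = 60L,
                                   max_mismatch = 10L, min_length = 180L) {
  seq_a <- toupper(seq_a)
  seq_b <- toupper(seq_b)
  la <- nchar(seq_a)
  if (la != nchar(seq_b)) {
    abort("Aligned sequences must have equal length.")
  }
  if (la %% 3L != 0L) {
    abort("Alignment length must be divisible by 3 (codon frame).")
  }
  if (window %% 3L != 0L) {
    abort("`window` must be a multiple of 3 to respect the codon frame.")
  }
  n_codons <- la %/% 3L
  w_codons <- window %/% 3L
  a_chars <- strsplit(seq_a, "", fixed = TRUE)[[1L]]
  b_chars <- strsplit(seq_b, "", fixed = TRUE)[[1L]]
  mismatch <- a_chars != b_chars | a_chars == "-" | b_chars == "-"
  kept <- rep(FALSE, n_codons)
  if (n_codons >= w_codons) {
    # per-codon mismatch totals, then a running window sum over codons
    per_codon <- colSums(matrix(mismatch, nrow = 3L))
    win_sums <- vapply(
      seq_len(n_codons - w_codons + 1L),
      function(i) sum(per_codon[i:(i + w_codons - 1L)]),
      numeric(1L)
    )
    for (i in which(win_sums <= max_mismatch)) {
      kept[i:(i + w_codons - 1L)] <- TRUE
    }
  }
  idx <- which(rep(kept, each = 3L))
  out_a <- paste(a_chars[idx], collapse = "")
  out_b <- paste(b_chars[idx], collapse = "")
  flen <- length(idx)
  list(
    a = out_a, b = out_b, kept_codons = kept,
    length = flen, retained = flen > min_length
  )
}

#' Pearson correlations over an ortholog table
#'
#' Reports Pearson's r with a Fisher-z 95% confidence interval and
#' p-value for the cross-species CpG O/E correlation and, when rates are
#' present, for each substitution-rate measure against the per-pair mean
#' CpG O/E. Rows with missing values are dropped pairwise.
#'
#' @param records Ortholog tibble from [ortholog_table()].
#' @param conf_level Confidence level for the Fisher-z interval
#'   (default 0.95).
#' @return A tibble: `comparison`, `r`, `ci_low`, `ci_high`, `p_value`,
#'   `n`.
#' @export
ortholog_correlations <- function(records, conf_level = 0.95) {
  if (nrow(records) < 3L) {
    abort("Need at least 3 ortholog records.")
  }
  wanted <- list(
    cpg_oe_a_vs_b = c("cpg_oe_a", "cpg_oe_b"),
    dn_vs_mean_cpg_oe = c("dn", "mean_cpg_oe"),
    ds_vs_mean_cpg_oe = c("ds", "mean_cpg_oe"),
    dn_ds_vs_mean_cpg_oe = c("dn_ds", "mean_cpg_oe")
  )
  wanted <- wanted[vapply(
    wanted, function(v) all(v %in% names(records)), logical(1L)
  )]
  purrr::imap_dfr(wanted, function(v, nm) {
    x <- records[[v[1L]]]
    y <- records[[v[2L]]]
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]
    y <- y[ok]
    if (length(x) < 3L) {
      return(tibble(
        comparison = nm, r = NA_real_, ci_low = NA_real_,
        ci_high = NA_real_, p_value = NA_real_, n = length(x)
      ))
    }
    if (sd(x) == 0 || sd(y) == 0) {
      abort(sprintf("Constant column in comparison '%s'.", nm))
    }
    ct <- cor.test(x, y, method = "pearson")
    ci <- fisher_z_ci(unname(ct$estimate), length(x), conf_level)
    tibble(
      comparison = nm, r = unname(ct$estimate),
      ci_low = ci[1L], ci_high = ci[2L],
      p_value = ct$p.value, n = length(x)
    )
  })
}

# Fisher z-transform confidence interval for a Pearson correlation
fisher_z_ci <- function(r, n, conf_level = 0.95) {
  if (abs(r) >= 1) {
    return(c(r, r))
  }
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  crit <- qnorm(1 - (1 - conf_level) / 2)
  tanh(c(z - crit * se, z + crit * se))
}
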