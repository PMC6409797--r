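#' Estimate the bisulfite conversion error rate from an unmethylated control
#'
#' Unmethylated spike-in DNA (classically phage lambda) carries no true
#' methylation, so every methylated read observed on it reflects a
#' conversion failure. The per-read error rate is the pooled fraction of
#' methylated reads over all control cytosines; the conversion rate
#' reported alongside is its complement.
#'
#' @param control Site tibble of control cytosines (see [read_coverage()]).
#' @return An object of class `conversion_control`: a list with
#'   `error_rate`, `conversion_rate` and `n_read_observations`.
#' @examples
#' ctrl <- sim_lambda_control(n_sites = 1000, depth = 10,
#'                            conversion_failure = 0.01, seed = 1)
#' estimate_conversion_error(ctrl)
#' @export
estimate_conversion_error <- function(control) {
  if (nrow(control) == 0L) {
    abort("Control site table is empty.")
  }
  total <- sum(control$count_meth) + sum(control$count_unmeth)
  if (total == 0L) {
    abort("Control sites have zero total depth; cannot estimate error rate.")
  }
  eps <- sum(control$count_meth) / total
  if (total < 1000L) {
    warn(sprintf(
      "Conversion error estimated from only %d read observations; low confidence.",
      total
    ))
  }
  structure(
    list(
      error_rate = eps,
      conversion_rate = 1 - eps,
      n_read_observations = total
    ),
    class = "conversion_control"
  )
}

#' @export
print.conversion_control <- function(x, ...) {
  cat(sprintf(
    "Bisulfite conversion control: error rate %.4g (conversion %.2f%%), %d read observations\n",
    x$error_rate, 100 * x$conversion_rate, x$n_read_observations
  ))
  invisible(x)
}

#' Filter cytosine sites by sequencing depth
#'
#' Retains sites whose depth lies in `[min_depth, max_depth]`, both ends
#' inclusive. Low-depth sites give unreliable estimates; very high depth
#' flags collapsed repeats or PCR artefacts.
#'
#' @param sites Site tibble.
#' @param min_depth,max_depth Inclusive depth bounds (defaults 5 and 30).
#' @return The filtered site tibble.
#' @export
filter_by_depth <- function(sites, min_depth = 5L, max_depth = 30L) {
  if (min_depth > max_depth) {
    abort("`min_depth` must not exceed `max_depth`.")
  }
  depth <- sites$count_meth + sites$count_unmeth
  sites[depth >= min_depth & depth <= max_depth, , drop = FALSE]
}

#' One-sided binomial p-value for methylation at a cytosine
#'
#' Tests whether the methylated read count m at a site exceeds what
#' conversion failure alone explains: p = P(X >= m) for
#' X ~ Binomial(depth, error_rate). `m = 0` gives p = 1. Vectorised.
#'
#' @param count_meth Methylated read count(s).
#' @param depth Total read count(s), >= 1.
#' @param error_rate Per-read conversion-failure probability.
#' @return Upper-tail p-value(s).
#' @examples
#' binomial_pvalue(2, 10, 0.01)
#' @export
binomial_pvalue <- function(count_meth, depth, error_rate) {
  stop_if_not_scalar_prob(error_rate, "error_rate")
  if (any(depth < 1L)) abort("`depth` must be >= 1.")
  if (any(count_meth < 0L) || any(count_meth > depth)) {
    abort("`count_meth` must lie in [0, depth].")
  }
  if (error_rate == 0 && any(count_meth > 0L)) {
    warn("error_rate = 0 with methylated reads observed: p-values are exactly 0.")
  }
  pbinom(count_meth - 1L, depth, error_rate, lower.tail = FALSE)
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up adjustment of p-values to FDR q-values, preserving input order.
#' A thin, validating wrapper around [stats::p.adjust()].
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0L) {
    return(numeric(0))
  }
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    abort("p-values must be in [0, 1] with no missing values.")
  }
  p.adjust(p_values, method = "BH")
}

#' Call methylated cytosines genome-wide
#'
#' Composes the calling pipeline: depth filtering, spike-in-calibrated
#' one-sided binomial tests, Benjamini-Hochberg FDR across all retained
#' sites as one family (optionally per context), and thresholding at
#' `q_threshold`.
#'
#' @param sites Site tibble (see [read_coverage()]).
#' @param error_rate Conversion-failure rate: a number or a
#'   `conversion_control` object from [estimate_conversion_error()].
#' @param q_threshold FDR threshold below which a site is called
#'   methylated (default 0.01).
#' @param min_depth,max_depth Inclusive depth bounds (defaults 5, 30).
#' @param by_context Run the FDR procedure separately per sequence context
#'   instead of one genome-wide family (default `FALSE`).
#' @return The retained site rows with `p_value`, `q_value` and
#'   `is_methylated` columns appended. The per-context fractions called
#'   methylated are attached as attribute `"context_summary"`.
#' @examples
#' ctrl <- sim_lambda_control(2000, 12, 0.01, seed = 1)
#' eps <- estimate_conversion_error(ctrl)
#' calls <- call_methylation(ctrl, eps)
#' mean(calls$is_methylated)  # close to zero: the control is unmethylated
#' @export
call_methylation <- function(sites, error_rate, q_threshold = 0.01,
                             min_depth = 5L, max_depth = 30L,
                             by_context = FALSE) {
  if (inherits(error_rate, "conversion_control")) {
    error_rate <- error_rate$error_rate
  }
  stop_if_not_scalar_prob(error_rate, "error_rate")
  kept <- filter_by_depth(sites, min_depth, max_depth)
  if (nrow(kept) == 0L) {
    out <- dplyr::mutate(
      kept,
      p_value = numeric(0), q_value = numeric(0), is_methylated = logical(0)
    )
    attr(out, "context_summary") <- tibble(
      context = character(), n_sites = integer(), frac_methylated = numeric()
    )
    return(out)
  }
  depth <- kept$count_meth + kept$count_unmeth
  p <- binomial_pvalue(kept$count_meth, depth, error_rate)
  q <- if (by_context) {
    ave_q <- numeric(length(p))
    for (ctx in unique(kept$context)) {
      idx <- kept$context == ctx
      ave_q[idx] <- bh_fdr(p[idx])
    }
    ave_q
  } else {
    bh_fdr(p)
  }
  out <- dplyr::mutate(
    kept,
    p_value = p, q_value = q, is_methylated = q < q_threshold
  )
  attr(out, "context_summary") <- out |>
    dplyr::group_by(.data$context) |>
    dplyr::summarise(
      n_sites = dplyr::n(),
      frac_methylated = mean(.data$is_methylated),
      .groups = "drop"
    )
  out
}
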