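#' @importFrom rlang %||% abort warn .data
#' @import dplyr
#' @importFrom tibble tibble as_tibble
#' @importFrom stats pbinom p.adjust dnorm rnorm rbinom rnbinom runif quantile
#'   sd density wilcox.test cor.test setNames complete.cases qnorm rlnorm
#' @importFrom utils head tail
NULL

# single place for the coverage-file column contract (Bismark coverage +
# strand/context columns)
coverage_cols <- c(
  "chrom", "start", "end", "percent_methylation",
  "count_meth", "count_unmeth", "strand", "context"
)

meth_contexts <- c("CpG", "CHG", "CHH")

stop_if_not_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single probability in [0, 1].", name))
  }
  invisible(x)
}

# draw seeds for sub-tasks reproducibly from one master seed, staying within
# 32-bit integer range
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
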