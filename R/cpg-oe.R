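#' Base and dinucleotide composition of sequences
#'
#' Counts the C and G bases and the CG ("CpG") and GC ("GpC")
#' dinucleotides of each sequence, scanning overlapping dinucleotide
#' positions in single-base steps. Case-insensitive; positions holding a
#' non-ACGT symbol are excluded from base counts, and any dinucleotide
#' touching such a position is excluded from dinucleotide counts.
#'
#' @param seqs Character vector (optionally named) or
#'   [Biostrings::DNAStringSet] of sequences.
#' @return A tibble: `id`, `length`, `n_c`, `n_g`, `n_cpg`, `n_gpc`.
#' @examples
#' seq_composition(c(a = "ACGT", b = "CGCG"))
#' @export
seq_composition <- function(seqs) {
  if (inherits(seqs, "XStringSet")) {
    nm <- names(seqs) %||% paste0("seq_", seq_along(seqs))
    seqs <- setNames(as.character(seqs), nm)
  }
  if (is.null(names(seqs))) {
    names(seqs) <- paste0("seq_", seq_along(seqs))
  }
  seqs <- toupper(seqs)
  bs <- Biostrings::BStringSet(seqs)
  base_counts <- Biostrings::letterFrequency(bs, letters = c("C", "G"))
  # count all 2-mers then keep the pure-ACGT ones; mixed pairs (with N etc.)
  # are thereby skipped
  di <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(chartr("URYSWKMBDHVN", "NNNNNNNNNNNN", seqs)),
    width = 2L, step = 1L
  )
  tibble(
    id = names(seqs),
    length = unname(nchar(seqs)),
    n_c = as.integer(base_counts[, "C"]),
    n_g = as.integer(base_counts[, "G"]),
    n_cpg = as.integer(di[, "CG"]),
    n_gpc = as.integer(di[, "GC"])
  )
}

#' CpG and GpC observed/expected ratios
#'
#' The CpG O/E of a sequence is `(L * n_CpG) / (n_C * n_G)`: the CpG
#' dinucleotide count relative to its expectation under independent base
#' placement. Methylated cytosines deaminate to thymine over evolutionary
#' time, so a CpG O/E well below 1 marks current or historical CpG
#' methylation. GpC O/E, the same ratio for GC dinucleotides, is a control
#' unaffected by CpG-specific deamination.
#'
#' @param comp Composition tibble from [seq_composition()].
#' @return Numeric vector of ratios; `NA` where the sequence has no C or
#'   no G.
#' @examples
#' cpg_oe(seq_composition("CGCG"))  # 2.0
#' gpc_oe(seq_composition("CGCG"))  # 1.0
#' @export
cpg_oe <- function(comp) {
  undef <- comp$n_c == 0L | comp$n_g == 0L
  out <- ifelse(
    undef, NA_real_,
    comp$length * comp$n_cpg / (as.numeric(comp$n_c) * comp$n_g)
  )
  if (any(undef)) {
    message(sprintf(
      "%d sequence(s) lack C or G; CpG O/E undefined (NA).", sum(undef)
    ))
  }
  out
}

#' @rdname cpg_oe
#' @export
gpc_oe <- function(comp) {
  undef <- comp$n_c == 0L | comp$n_g == 0L
  ifelse(
    undef, NA_real_,
    comp$length * comp$n_gpc / (as.numeric(comp$n_c) * comp$n_g)
  )
}

#' Per-gene CpG O/E table
#'
#' @param seqs Named character vector or `DNAStringSet` of gene sequences.
#' @param exclude Optional character vector of gene ids to drop (e.g.
#'   genes located in repetitive regions).
#' @return A tibble: `id`, `length`, `cpg_oe`, `gpc_oe`, `is_zero`
#'   (flagging exact-zero O/E values, typically very short genes, for
#'   removal before density estimation and mixture fitting).
#' @export
gene_set_cpgoe <- function(seqs, exclude = NULL) {
  if (length(seqs) == 0L) {
    abort("No sequences supplied.")
  }
  comp <- seq_composition(seqs)
  if (!is.null(exclude)) {
    comp <- comp[!comp$id %in% exclude, , drop = FALSE]
  }
  tibble(
    id = comp$id,
    length = comp$length,
    cpg_oe = cpg_oe(comp),
    gpc_oe = gpc_oe(comp),
    is_zero = !is.na(cpg_oe(comp)) & cpg_oe(comp) == 0
  )
}

#' CpG O/E along a genome in fixed-size fragments
#'
#' Tiles each contig with non-overlapping fragments starting at position
#' 0; a trailing fragment shorter than `fragment` is dropped so that all
#' values share the same length term. Fragments lacking C or G yield `NA`.
#'
#' @param genome Named character vector or `DNAStringSet` of contigs.
#' @param fragment Fragment length in bp (default 1000, minimum 100).
#' @return A tibble: `chrom`, `start` (0-based), `end`, `cpg_oe`,
#'   `gpc_oe`.
#' @export
genome_fragment_scan <- function(genome, fragment = 1000L) {
  if (fragment < 100L) {
    abort("`fragment` must be at least 100 bp.")
  }
  if (inherits(genome, "XStringSet")) {
    genome <- setNames(
      as.character(genome),
      names(genome) %||% paste0("contig_", seq_along(genome))
    )
  }
  if (is.null(names(genome))) {
    names(genome) <- paste0("contig_", seq_along(genome))
  }
  purrr::map_dfr(names(genome), function(chrom) {
    len <- nchar(genome[[chrom]])
    n_frag <- len %/% fragment
    if (n_frag == 0L) {
      return(tibble(
        chrom = character(), start = integer(), end = integer(),
        cpg_oe = numeric(), gpc_oe = numeric()
      ))
    }
    starts <- (seq_len(n_frag) - 1L) * fragment
    pieces <- substring(genome[[chrom]], starts + 1L, starts + fragment)
    comp <- seq_composition(setNames(pieces, paste0(chrom, ":", starts)))
    tibble(
      chrom = chrom, start = starts, end = starts + fragment,
      cpg_oe = suppressMessages(cpg_oe(comp)), gpc_oe = gpc_oe(comp)
    )
  })
}

#' Gaussian kernel density estimate of CpG O/E values
#'
#' Thin wrapper around [stats::density()] with a Gaussian kernel and
#' Silverman's rule-of-thumb bandwidth. Exact zeroes are removed by
#' default before estimation: in gene sets they come from very short
#' genes, not from real depletion.
#'
#' @param values Numeric vector of O/E values.
#' @param bandwidth Kernel bandwidth; `NULL` (default) for Silverman's
#'   rule.
#' @param drop_zeros Remove exact zeroes first (default `TRUE`).
#' @return An object of class `cpgoe_kde`: list with `x` (grid), `y`
#'   (density), `bandwidth`, `n`.
#' @export
cpgoe_kde <- function(values, bandwidth = NULL, drop_zeros = TRUE) {
  v <- values[is.finite(values)]
  if (drop_zeros) {
    v <- v[v != 0]
  }
  if (length(v) < 2L) {
    abort("Need at least 2 finite values after zero removal.")
  }
  bw <- bandwidth %||% stats::bw.nrd0(v)
  d <- density(v, bw = bw, kernel = "gaussian", cut = 3)
  structure(
    list(x = d$x, y = d$y, bandwidth = d$bw, n = length(v)),
    class = "cpgoe_kde"
  )
}

#' Draw from a (positively truncated) normal mixture
#'
#' Samples component labels with the given weights, then normal deviates;
#' with `truncate_positive` non-positive draws are rejected and redrawn,
#' matching the support of O/E ratios.
#'
#' @param n Number of draws.
#' @param weights,means,sds Component parameters (equal-length vectors;
#'   weights are normalised to sum to 1).
#' @param truncate_positive Reject non-positive values (default `TRUE`).
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n`.
#' @export
sample_normal_mixture <- function(n, weights, means, sds,
                                  truncate_positive = TRUE, seed = NULL) {
  k <- length(means)
  if (length(weights) != k || length(sds) != k) {
    abort("`weights`, `means` and `sds` must have equal length.")
  }
  if (!is.null(seed)) set.seed(seed)
  weights <- weights / sum(weights)
  comp <- sample.int(k, n, replace = TRUE, prob = weights)
  x <- rnorm(n, means[comp], sds[comp])
  if (truncate_positive) {
    bad <- which(x <= 0)
    while (length(bad) > 0L) {
      comp_b <- sample.int(k, length(bad), replace = TRUE, prob = weights)
      x[bad] <- rnorm(length(bad), means[comp_b], sds[comp_b])
      bad <- bad[x[bad] <= 0]
    }
  }
  x
}

#' Fit a univariate normal mixture by expectation-maximisation
#'
#' Maximum-likelihood fit of a k-component Gaussian mixture via EM with
#' responsibilities, restarted from `n_starts` random initialisations
#' (k-quantiles of the data plus jitter) and keeping the best
#' log-likelihood. Component standard deviations are floored at
#' `1e-4 * sd(values)` to prevent collapse onto single points.
#' Components are reported sorted by mean.
#'
#' @param values Numeric data (exact zeroes dropped by default, matching
#'   [cpgoe_kde()]).
#' @param k Number of components (>= 1); `n >= 10 * k` required.
#' @param n_starts Number of random restarts (default 10).
#' @param tol Relative log-likelihood convergence tolerance
#'   (default 1e-8).
#' @param max_iter Maximum EM iterations per start (default 2000).
#' @param seed Optional integer seed for the restarts.
#' @param drop_zeros Remove exact zeroes first (default `TRUE`).
#' @return An object of class `mixture_fit`: `weights`, `means`, `sds`
#'   (sorted by mean), `log_likelihood`, `n_iterations`, `converged`,
#'   `k`, `n`.
#' @examples
#' x <- sample_normal_mixture(2000, c(.5, .5), c(0, 5), c(1, 1), seed = 1)
#' fit_normal_mixture(x, k = 2, seed = 1)
#' @export
fit_normal_mixture <- function(values, k, n_starts = 10L, tol = 1e-8,
                               max_iter = 2000L, seed = NULL,
                               drop_zeros = TRUE) {
  x <- values[is.finite(values)]
  if (drop_zeros) x <- x[x != 0]
  n <- length(x)
  if (k < 1L) abort("`k` must be >= 1.")
  # k = 1 is a plain Gaussian MLE and works from 2 points; true mixtures
  # need data to populate every component
  if ((k == 1L && n < 2L) || (k > 1L && n < 10L * k)) {
    abort("Need at least 10 observations per component.")
  }
  if (!is.null(seed)) set.seed(seed)
  sd_floor <- 1e-4 * sd(x)
  if (!is.finite(sd_floor) || sd_floor == 0) {
    abort("Data are constant; mixture fit is degenerate.")
  }

  best <- NULL
  for (s in seq_len(n_starts)) {
    init_means <- quantile(
      x, probs = (seq_len(k) - 0.5) / k, names = FALSE
    ) + rnorm(k, 0, if (s == 1L) 0 else 0.25 * sd(x))
    fit <- em_normal_mixture_once(
      x, k, init_means,
      init_sds = rep(sd(x) / k, k), tol = tol,
      max_iter = max_iter, sd_floor = sd_floor
    )
    if (!is.null(fit) &&
        (is.null(best) || fit$log_likelihood > best$log_likelihood)) {
      best <- fit
    }
  }
  if (is.null(best)) {
    abort("All EM starts were degenerate.")
  }
  ord <- order(best$means)
  structure(
    list(
      weights = best$weights[ord],
      means = best$means[ord],
      sds = best$sds[ord],
      log_likelihood = best$log_likelihood,
      n_iterations = best$n_iterations,
      converged = best$converged,
      k = k, n = n
    ),
    class = "mixture_fit"
  )
}

# one EM run; returns NULL if it degenerates
em_normal_mixture_once <- function(x, k, init_means, init_sds, tol,
                                   max_iter, sd_floor) {
  n <- length(x)
  w <- rep(1 / k, k)
  mu <- init_means
  sigma <- pmax(init_sds, sd_floor)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # E step in log space for numerical safety
    log_dens <- vapply(
      seq_len(k),
      function(j) log(w[j]) + dnorm(x, mu[j], sigma[j], log = TRUE),
      numeric(n)
    )
    m <- log_dens[, 1L]
    if (k > 1L) {
      for (j in 2:k) m <- pmax(m, log_dens[, j])
    }
    if (any(!is.finite(m))) {
      return(NULL)
    }
    dens <- exp(log_dens - m)
    row_sum <- rowSums(dens)
    ll <- sum(m + log(row_sum))
    # EM guarantees a non-decreasing likelihood; tolerate only float noise
    if (ll < ll_old - 1e-8 * (abs(ll_old) + 1)) {
      abort("EM log-likelihood decreased; numerical failure.")
    }
    resp <- dens / row_sum
    # M step
    nk <- colSums(resp)
    if (any(nk < 1e-10)) {
      return(NULL)
    }
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sigma <- pmax(
      sqrt(colSums(resp * (x - rep(mu, each = n))^2) / nk),
      sd_floor
    )
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll_old) + 1e-12)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    if (iter >= max_iter) break
  }
  list(
    weights = w, means = mu, sds = sigma,
    log_likelihood = ll, n_iterations = iter, converged = converged
  )
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(
    "Normal mixture fit: k = %d, n = %d, logLik = %.2f, %s after %d iterations\n",
    x$k, x$n, x$log_likelihood,
    if (x$converged) "converged" else "NOT converged", x$n_iterations
  ))
  print(tidy(x))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a normal mixture fit into one row per component
#'
#' @param x A `mixture_fit` object.
#' @param ... Unused.
#' @return A tibble: `component`, `weight`, `mean`, `sd`.
#' @method tidy mixture_fit
#' @export
tidy.mixture_fit <- function(x, ...) {
  tibble(
    component = seq_len(x$k),
    weight = x$weights,
    mean = x$means,
    sd = x$sds
  )
}

#' One-row summary of a normal mixture fit
#'
#' @param x A `mixture_fit` object.
#' @param ... Unused.
#' @return A tibble with `k`, `n`, `log_likelihood`, `bic`,
#'   `n_iterations`, `converged`. BIC uses 3k - 1 free parameters.
#' @method glance mixture_fit
#' @export
glance.mixture_fit <- function(x, ...) {
  n_par <- 3L * x$k - 1L
  tibble(
    k = x$k, n = x$n,
    log_likelihood = x$log_likelihood,
    bic = -2 * x$log_likelihood + n_par * log(x$n),
    n_iterations = x$n_iterations,
    converged = x$converged
  )
}

#' Compare mixture sizes by BIC
#'
#' Fits mixtures for each candidate `k` and reports their likelihoods and
#' BIC. The component count is a scientific choice; this report informs
#' it rather than automating it.
#'
#' @inheritParams fit_normal_mixture
#' @param k_values Candidate component counts (default 1:4).
#' @return A tibble of [glance.mixture_fit()] rows, one per `k`.
#' @export
mixture_bic_report <- function(values, k_values = 1:4, n_starts = 10L,
                               seed = NULL) {
  seeds <- if (is.null(seed)) {
    rep(list(NULL), length(k_values))
  } else {
    as.list(derive_seeds(seed, length(k_values)))
  }
  purrr::map2_dfr(k_values, seeds, function(k, s) {
    glance(fit_normal_mixture(values, k, n_starts = n_starts, seed = s))
  })
}
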