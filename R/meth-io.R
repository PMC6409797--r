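#' Read an extended Bismark coverage file
#'
#' Reads a tab-separated methylation coverage file in the extended Bismark
#' coverage dialect: the six standard columns (chromosome, start, end,
#' percent methylation, methylated read count, unmethylated read count)
#' plus two extra columns giving the strand of the cytosine and its
#' sequence context (`CpG`, `CHG` or `CHH`). Positions are 1-based and
#' start equals end for the single cytosine.
#'
#' The percent column is advisory only: counts are the source of truth and
#' the methylation fraction is recomputed on demand. A mismatch between the
#' stated percentage and the counts triggers a warning, not an error.
#'
#' @param path Path to the coverage file (optionally gzip-compressed).
#' @return A tibble with one row per cytosine: `chrom`, `pos` (1-based),
#'   `strand`, `context`, `count_meth`, `count_unmeth`, `depth`.
#' @seealso [write_coverage()], [call_methylation()]
#' @export
read_coverage <- function(path) {
  raw <- readr::read_tsv(
    path,
    col_names = FALSE,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (nrow(raw) == 0L) {
    return(empty_site_table())
  }
  if (ncol(raw) != 8L) {
    abort(sprintf(
      paste0(
        "Expected an 8-column extended Bismark coverage file ",
        "(chrom, start, end, %%meth, count_meth, count_unmeth, strand, ",
        "context); got %d columns in '%s'."
      ),
      ncol(raw), path
    ))
  }
  names(raw) <- coverage_cols
  num <- suppressWarnings(dplyr::mutate(
    raw,
    start = as.integer(.data$start),
    end = as.integer(.data$end),
    percent_methylation = as.numeric(.data$percent_methylation),
    count_meth = as.integer(.data$count_meth),
    count_unmeth = as.integer(.data$count_unmeth)
  ))
  bad <- which(!complete.cases(
    num[, c("start", "end", "count_meth", "count_unmeth")]
  ))
  if (length(bad) > 0L) {
    abort(sprintf(
      "Malformed coverage line %d in '%s': non-numeric coordinate or count.",
      bad[1L], path
    ))
  }
  bad_ctx <- which(!num$context %in% meth_contexts)
  if (length(bad_ctx) > 0L) {
    abort(sprintf(
      "Malformed coverage line %d in '%s': context '%s' not one of %s.",
      bad_ctx[1L], path, num$context[bad_ctx[1L]],
      paste(meth_contexts, collapse = "/")
    ))
  }
  depth <- num$count_meth + num$count_unmeth
  stated <- num$percent_methylation
  recomputed <- ifelse(depth > 0, 100 * num$count_meth / depth, 0)
  off <- is.finite(stated) & abs(stated - recomputed) > 0.51
  if (any(off)) {
    warn(sprintf(
      "%d line(s) in '%s' have a percent column inconsistent with counts; counts are used.",
      sum(off), path
    ))
  }
  tibble(
    chrom = num$chrom,
    pos = num$start,
    strand = num$strand,
    context = num$context,
    count_meth = num$count_meth,
    count_unmeth = num$count_unmeth,
    depth = depth
  )
}

empty_site_table <- function() {
  tibble(
    chrom = character(), pos = integer(), strand = character(),
    context = character(), count_meth = integer(),
    count_unmeth = integer(), depth = integer()
  )
}

#' Write a methylation site table as an extended Bismark coverage file
#'
#' @param sites A site tibble as returned by [read_coverage()] or
#'   [sim_methylome()].
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(sites, path) {
  depth <- sites$count_meth + sites$count_unmeth
  out <- tibble(
    chrom = sites$chrom,
    start = sites$pos,
    end = sites$pos,
    percent_methylation = ifelse(depth > 0, 100 * sites$count_meth / depth, 0),
    count_meth = sites$count_meth,
    count_unmeth = sites$count_unmeth,
    strand = sites$strand,
    context = sites$context
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read genomic features from GFF3 or BED
#'
#' Both dialects are normalised to the internal convention: 0-based,
#' half-open intervals. GFF3 coordinates (1-based inclusive) are shifted at
#' the boundary; BED coordinates are taken as-is. When a gene's exons are
#' present but no introns are, introns are derived as the gaps between
#' consecutive exons of the gene.
#'
#' @param path Path to the annotation file.
#' @param dialect `"gff3"` or `"bed"`; defaults from the file extension.
#' @param derive_introns Derive introns from exon gaps when absent
#'   (default `TRUE`).
#' @return A feature tibble: `chrom`, `start`, `end` (0-based half-open),
#'   `strand`, `kind`, `id`, `parent`.
#' @export
read_features <- function(path, dialect = NULL, derive_introns = TRUE) {
  if (is.null(dialect)) {
    dialect <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) {
      "bed"
    } else {
      "gff3"
    }
  }
  dialect <- match.arg(tolower(dialect), c("gff3", "bed"))
  gr <- if (dialect == "gff3") {
    rtracklayer::import(path, format = "gff3")
  } else {
    rtracklayer::import(path, format = "bed")
  }
  md <- S4Vectors::mcols(gr)
  kind <- if (dialect == "gff3" && "type" %in% names(md)) {
    as.character(md$type)
  } else if ("name" %in% names(md) && !all(is.na(md$name))) {
    sub("\\..*$", "", as.character(md$name))
  } else {
    rep("region", length(gr))
  }
  id <- if ("ID" %in% names(md)) {
    as.character(md$ID)
  } else if ("name" %in% names(md)) {
    as.character(md$name)
  } else {
    paste0("feat_", seq_along(gr))
  }
  parent <- if ("Parent" %in% names(md)) {
    vapply(md$Parent, function(p) {
      if (length(p) == 0L) NA_character_ else as.character(p[[1L]])
    }, character(1L))
  } else {
    rep(NA_character_, length(gr))
  }
  feats <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    # GRanges is 1-based inclusive internally for both dialects
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    kind = kind,
    id = id,
    parent = parent
  )
  feats$strand[!feats$strand %in% c("+", "-")] <- "+"
  check_exon_overlap(feats)
  if (derive_introns && !"intron" %in% feats$kind) {
    feats <- dplyr::bind_rows(feats, derive_introns_from_exons(feats))
  }
  dplyr::arrange(feats, .data$chrom, .data$start, .data$end)
}

check_exon_overlap <- function(feats) {
  ex <- feats[feats$kind == "exon" & !is.na(feats$parent), ]
  if (nrow(ex) == 0L) {
    return(invisible(NULL))
  }
  bad <- ex |>
    dplyr::group_by(.data$parent) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::summarise(
      overlap = dplyr::n() > 1L &&
        any(.data$start[-1L] < head(.data$end, -1L)),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$overlap)
  if (nrow(bad) > 0L) {
    abort(sprintf(
      "Overlapping exons within gene '%s'.", bad$parent[1L]
    ))
  }
  invisible(NULL)
}

derive_introns_from_exons <- function(feats) {
  ex <- feats[feats$kind == "exon" & !is.na(feats$parent), ]
  if (nrow(ex) == 0L) {
    return(feats[0L, ])
  }
  ex |>
    dplyr::group_by(.data$chrom, .data$strand, .data$parent) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::reframe(
      intron_start = head(.data$end, -1L),
      intron_end = .data$start[-1L]
    ) |>
    dplyr::filter(.data$intron_end > .data$intron_start) |>
    dplyr::rename(start = "intron_start", end = "intron_end") |>
    dplyr::group_by(.data$parent) |>
    dplyr::mutate(
      kind = "intron",
      id = paste0(.data$parent, ".intron", dplyr::row_number())
    ) |>
    dplyr::ungroup()
}

#' Write a feature tibble as GFF3
#'
#' Internal 0-based half-open coordinates are converted back to the GFF3
#' 1-based inclusive convention at the boundary.
#'
#' @param features A feature tibble (see [read_features()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path) {
  lines <- sprintf(
    "%s\tgbmeth\t%s\t%d\t%d\t.\t%s\t.\t%s",
    features$chrom, features$kind,
    features$start + 1L, features$end, features$strand,
    ifelse(
      is.na(features$parent),
      sprintf("ID=%s", features$id),
      sprintf("ID=%s;Parent=%s", features$id, features$parent)
    )
  )
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read a gene-by-sample FPKM expression table
#'
#' Expects a TSV whose first column is the gene id and whose remaining
#' column names are sample ids, optionally prefixed with a group label as
#' `group:sample`. Returned in long (tidy) form.
#'
#' @param path Path to the TSV.
#' @param groups Optional named character vector mapping sample id to group
#'   label; overrides header-encoded groups.
#' @return A long tibble: `gene_id`, `sample_id`, `group`, `fpkm`.
#' @export
read_expression <- function(path, groups = NULL) {
  wide <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  names(wide)[1L] <- "gene_id"
  if (anyDuplicated(wide$gene_id) > 0L) {
    dup <- wide$gene_id[duplicated(wide$gene_id)][1L]
    abort(sprintf("Duplicate gene id '%s' in '%s'.", dup, path))
  }
  long <- tidyr::pivot_longer(
    wide, -"gene_id",
    names_to = "sample_raw", values_to = "fpkm"
  )
  if (any(long$fpkm < 0, na.rm = TRUE)) {
    abort(sprintf("Negative FPKM values in '%s'.", path))
  }
  has_grp <- grepl(":", long$sample_raw, fixed = TRUE)
  long$group <- ifelse(
    has_grp, sub(":.*$", "", long$sample_raw), NA_character_
  )
  long$sample_id <- ifelse(
    has_grp, sub("^[^:]*:", "", long$sample_raw), long$sample_raw
  )
  if (!is.null(groups)) {
    long$group <- unname(groups[long$sample_id])
  }
  dplyr::select(long, "gene_id", "sample_id", "group", "fpkm")
}

#' Write an expression table to TSV
#'
#' @param expr Long expression tibble (see [read_expression()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  wide <- expr |>
    dplyr::mutate(
      column = ifelse(
        is.na(.data$group), .data$sample_id,
        paste0(.data$group, ":", .data$sample_id)
      )
    ) |>
    dplyr::select("gene_id", "column", "fpkm") |>
    tidyr::pivot_wider(names_from = "column", values_from = "fpkm")
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' @param path Path to the FASTA file.
#' @return A named uppercase character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm) > 0L) {
    abort(sprintf(
      "Duplicate FASTA header '%s' in '%s'.", nm[duplicated(nm)][1L], path
    ))
  }
  seqs <- toupper(as.character(ss))
  names(seqs) <- nm
  if (any(nchar(seqs) == 0L)) {
    warn(sprintf("Empty sequence(s) in '%s'.", path))
  }
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}
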