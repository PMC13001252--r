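ESSENTIALITY_LEVELS <- c("non-essential", "high-fitness", "essential",
                         "unknown")

#' Construct or validate a gene model table
#'
#' Genes are 1-based, inclusive intervals on a single circular-or-linear
#' reference, each carrying a strand and an essentiality class from prior
#' high-density transposon fitness data (`non-essential`, `high-fitness`,
#' `essential`, or `unknown`).
#'
#' @param gene_id Character vector of unique gene identifiers.
#' @param start,end Integer vectors, 1-based inclusive, `start <= end`.
#' @param strand `"+"` or `"-"` per gene.
#' @param essentiality Essentiality class per gene (defaults to `"unknown"`).
#' @return Data frame of class `gene_models` with the five columns above.
#' @export
gene_models <- function(gene_id, start, end, strand,
                        essentiality = "unknown") {
  n <- length(gene_id)
  g <- data.frame(gene_id = as.character(gene_id),
                  start = as.integer(start), end = as.integer(end),
                  strand = as.character(strand),
                  essentiality = rep_len(as.character(essentiality), n))
  if (anyDuplicated(g$gene_id)) stop("gene_id values must be unique")
  if (any(g$start < 1) || any(g$end < g$start))
    stop("gene intervals must satisfy 1 <= start <= end")
  if (!all(g$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (!all(g$essentiality %in% ESSENTIALITY_LEVELS))
    stop("essentiality must be one of: ",
         paste(ESSENTIALITY_LEVELS, collapse = ", "))
  class(g) <- c("gene_models", "data.frame")
  g
}

#' Read a gene annotation (GFF3 or TSV)
#'
#' GFF3 files are parsed with `rtracklayer`; gene features are expected to
#' carry an `essentiality` attribute (missing values become `"unknown"`).
#' The TSV form has columns `gene_id`, `start`, `end`, `strand`,
#' `essentiality`.
#'
#' @param path Annotation file.
#' @param format `"auto"` (by extension), `"gff3"` or `"tsv"`.
#' @return A [gene_models()] data frame.
#' @export
read_annotation <- function(path, format = c("auto", "gff3", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "tsv"
  if (format == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    mc <- GenomicRanges::mcols(gr)
    ids <- if (!is.null(mc$ID)) as.character(mc$ID) else
      paste0("gene_", seq_along(gr))
    ess <- if (!is.null(mc$essentiality)) as.character(mc$essentiality) else
      rep("unknown", length(gr))
    ess[is.na(ess)] <- "unknown"
    gene_models(ids, GenomicRanges::start(gr), GenomicRanges::end(gr),
                as.character(GenomicRanges::strand(gr)), ess)
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    gene_models(tab$gene_id, tab$start, tab$end, tab$strand,
                if (is.null(tab$essentiality)) "unknown" else tab$essentiality)
  }
}

#' Write a gene annotation (GFF3 or TSV)
#'
#' @param genes A [gene_models()] table.
#' @param path Output file.
#' @param format `"gff3"` or `"tsv"`.
#' @param seqname Reference sequence name used in GFF3 output.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(genes, path, format = c("gff3", "tsv"),
                             seqname = "chr") {
  format <- match.arg(format)
  if (format == "gff3") {
    gr <- GenomicRanges::GRanges(
      seqname, IRanges::IRanges(genes$start, genes$end),
      strand = genes$strand)
    GenomicRanges::mcols(gr)$type <- "gene"
    GenomicRanges::mcols(gr)$ID <- genes$gene_id
    GenomicRanges::mcols(gr)$essentiality <- genes$essentiality
    rtracklayer::export(gr, path, format = "gff3")
  } else {
    utils::write.table(as.data.frame(genes)[c("gene_id", "start", "end",
                                              "strand", "essentiality")],
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Round half away from zero
#'
#' Unlike base `round()`'s round-half-even, halves always round away from
#' zero (so 85.65 -> 85.7 at one decimal).  This is the rounding convention
#' used for every reported percentage in this package.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage of a count over a total, rounded half-up
#'
#' Convention used in all coverage tables: percentages are reported to
#' `digits` decimals with halves rounded away from zero.
#'
#' @param hit Numerator count.
#' @param total Denominator count.
#' @param digits Decimal places (default 1).
#' @return Numeric percentage.
#' @examples
#' percent_of(2687, 3135)  # 85.7
#' @export
percent_of <- function(hit, total, digits = 1) {
  round_half_up(100 * hit / total, digits)
}

#' Largest-remainder apportionment of counts to proportions
#'
#' Distributes `n` items over categories so category counts match the target
#' proportions as closely as integer counts allow: each category first gets
#' the floor of its exact share, then remaining items go to the largest
#' fractional remainders (ties broken by category order).
#'
#' @param proportions Non-negative numeric vector summing to 1.
#' @param n Total count to distribute.
#' @return Integer vector of counts summing to `n`, named like `proportions`.
#' @examples
#' apportion_largest_remainder(c(0.8, 0.05, 0.15), 100)  # 80 5 15
#' @export
apportion_largest_remainder <- function(proportions, n) {
  if (any(proportions < 0) || abs(sum(proportions) - 1) > 1e-8)
    stop("proportions must be non-negative and sum to 1")
  exact <- proportions * n
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    take <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
    base[take] <- base[take] + 1
  }
  stats::setNames(as.integer(base), names(proportions))
}
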