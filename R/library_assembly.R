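#' Map insertion positions to genes with strand-aware gene fractions
#'
#' An insertion at `position` hits a gene when `start <= position <= end`.
#' The gene fraction measures how far into the coding sequence the insertion
#' lies, from the translational start: `(position - start) / length` for a
#' `+` strand gene and `(end - position) / length` for a `-` strand gene
#' (`length = end - start + 1`), so fraction 0 is the first codon on either
#' strand and values approach 1 at the stop.  Positions in no gene are
#' intergenic (`gene_id` `NA`).  When genes overlap, one row is returned per
#' containing gene and the caller chooses.
#'
#' @param position Integer vector of insertion positions (1-based).
#' @param genes A [gene_models()] table.
#' @return Data frame with one row per (position, containing gene) pair —
#'   plus one `NA`-gene row for each intergenic position — and columns
#'   `position`, `gene_id`, `fraction`, `essentiality`.
#' @examples
#' g <- gene_models(c("a", "b"), c(1001, 3001), c(2000, 4000), c("+", "-"))
#' locate_in_gene(c(1001, 2000, 4000, 500), g)
#' @export
locate_in_gene <- function(position, genes) {
  stopifnot(all(position >= 1))
  out <- vector("list", length(position))
  for (i in seq_along(position)) {
    p <- position[i]
    hit <- which(genes$start <= p & genes$end >= p)
    if (length(hit) == 0) {
      out[[i]] <- data.frame(position = p, gene_id = NA_character_,
                             fraction = NA_real_,
                             essentiality = NA_character_)
    } else {
      len <- genes$end[hit] - genes$start[hit] + 1
      frac <- ifelse(genes$strand[hit] == "+",
                     (p - genes$start[hit]) / len,
                     (genes$end[hit] - p) / len)
      out[[i]] <- data.frame(position = p, gene_id = genes$gene_id[hit],
                             fraction = frac,
                             essentiality = genes$essentiality[hit])
    }
  }
  do.call(rbind, out)
}

#' Assemble the ordered library manifest from assignments
#'
#' Keeps only placed (`auto`/`triangulated`) insertions.  For each gene, up
#' to `max_redundancy` distinct insertion sites are retained, chosen by
#' ascending gene fraction (most upstream first; ties broken by position,
#' then `site_id`) and ranked 1..`max_redundancy`.  The rank-1 entry — the
#' most upstream insertion, most likely to disrupt the gene product — is
#' flagged as the consolidated representative.  Intergenic placements are
#' retained as internal controls (rank `NA`, not consolidated).
#'
#' @param assignments A `tn_assignments` (or its `table`).
#' @param genes A [gene_models()] table.
#' @param max_redundancy Maximum entries per gene (default 3: triplicate
#'   collection).
#' @return Data frame of class `library_manifest`: columns `site_id`,
#'   `position`, `strand`, `plate_row`, `plate_col`, `well_row`, `well_col`,
#'   `gene_id`, `gene_fraction`, `essentiality`, `rank`, `consolidated`,
#'   `intergenic`.
#' @export
build_collection <- function(assignments, genes, max_redundancy = 3) {
  tab <- if (inherits(assignments, "tn_assignments")) assignments$table else
    assignments
  tab <- tab[tab$status %in% c("auto", "triangulated"), , drop = FALSE]
  if (nrow(tab) == 0)
    return(structure(data.frame(), class = c("library_manifest",
                                             "data.frame")))
  # one row per (placed site, gene hit); intergenic sites keep their NA row
  ent <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    h <- locate_in_gene(tab$position[i], genes)
    ent[[i]] <- data.frame(
      site_id = tab$site_id[i], position = tab$position[i],
      strand = tab$strand[i], plate_row = tab$plate_row[i],
      plate_col = tab$plate_col[i], well_row = tab$well_row[i],
      well_col = tab$well_col[i], gene_id = h$gene_id,
      gene_fraction = h$fraction, essentiality = h$essentiality,
      stringsAsFactors = FALSE)
  }
  ent <- do.call(rbind, ent)
  ent$intergenic <- is.na(ent$gene_id)
  ent$rank <- NA_integer_
  ent$consolidated <- FALSE

  keep <- ent$intergenic
  for (g in unique(ent$gene_id[!ent$intergenic])) {
    rows <- which(!ent$intergenic & ent$gene_id == g)
    # distinct insertion sites only
    rows <- rows[!duplicated(ent$site_id[rows])]
    ord <- rows[order(ent$gene_fraction[rows], ent$position[rows],
                      ent$site_id[rows])]
    sel <- ord[seq_len(min(length(ord), max_redundancy))]
    ent$rank[sel] <- seq_along(sel)
    ent$consolidated[sel[1]] <- TRUE
    keep[sel] <- TRUE
  }
  out <- ent[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("library_manifest", "data.frame"))
}

#' Redundancy summary of a library manifest
#'
#' Counts genes represented by exactly 1, 2, ... insertions and checks the
#' identity that total mutant entries equal the redundancy-weighted gene
#' counts.
#'
#' @param manifest A [build_collection()] manifest.
#' @return List with `genes_by_redundancy` (named integer vector),
#'   `n_mutants` (genic entries), `n_intergenic`, `n_genes`.
#' @export
redundancy_summary <- function(manifest) {
  genic <- manifest[!manifest$intergenic & !is.na(manifest$rank), ,
                    drop = FALSE]
  per_gene <- table(genic$gene_id)
  by_r <- table(factor(as.integer(per_gene)))
  list(genes_by_redundancy = stats::setNames(as.integer(by_r), names(by_r)),
       n_mutants = nrow(genic),
       n_intergenic = sum(manifest$intergenic),
       n_genes = length(per_gene))
}

#' Total mutants implied by per-redundancy gene counts
#'
#' The book-keeping identity of a redundant collection: genes represented
#' once, twice and three times contribute 1, 2 and 3 mutants each.
#'
#' @param genes_by_redundancy Integer vector of gene counts, named or
#'   ordered by redundancy level 1, 2, 3, ...
#' @return Total mutant count.
#' @examples
#' collection_size(c(625, 717, 1560))  # 6739
#' @export
collection_size <- function(genes_by_redundancy) {
  k <- suppressWarnings(as.integer(names(genes_by_redundancy)))
  if (is.null(names(genes_by_redundancy)) || anyNA(k))
    k <- seq_along(genes_by_redundancy)
  sum(k * as.integer(genes_by_redundancy))
}

#' Coverage of the annotated genome, stratified by essentiality
#'
#' For each essentiality stratum and overall: genes hit by at least one
#' placed insertion, genes missing, totals, and percentages (one decimal,
#' half-up).
#'
#' @param x A `library_manifest`, a `tn_assignments`, or a data frame with
#'   a `gene_id` column of hit genes.
#' @param genes A [gene_models()] table.
#' @return Data frame with columns `stratum`, `orfs_hit`, `orfs_missing`,
#'   `total`, `pct_hit`, `pct_missing`.
#' @export
coverage_report <- function(x, genes) {
  hit_genes <- if (inherits(x, "tn_assignments")) {
    tab <- x$table[x$table$status %in% c("auto", "triangulated"), ]
    if (nrow(tab) == 0) character(0) else {
      h <- locate_in_gene(tab$position, genes)
      unique(h$gene_id[!is.na(h$gene_id)])
    }
  } else if (is.data.frame(x)) {
    unique(x$gene_id[!is.na(x$gene_id)])
  } else stop("x must be a manifest, assignments, or data frame")

  strata <- intersect(ESSENTIALITY_LEVELS, unique(genes$essentiality))
  rows <- lapply(c(strata, "Total"), function(s) {
    g <- if (s == "Total") genes$gene_id else
      genes$gene_id[genes$essentiality == s]
    nh <- sum(g %in% hit_genes)
    data.frame(stratum = s, orfs_hit = nh, orfs_missing = length(g) - nh,
               total = length(g),
               pct_hit = percent_of(nh, length(g)),
               pct_missing = percent_of(length(g) - nh, length(g)))
  })
  do.call(rbind, rows)
}

#' Histogram of insertion positions as gene fractions
#'
#' Bins genic insertions by the fraction of the gene at which the
#' transposon inserted, on `[0, 1)` with left-closed bins.
#'
#' @param hits Data frame with a `fraction` column (e.g. from
#'   [locate_in_gene()] or a `library_manifest`'s `gene_fraction`), and an
#'   `essentiality` column when stratifying.
#' @param bin_width Bin width; `1 / bin_width` must be an integer (default
#'   0.05, i.e. 20 bins).
#' @param by_essentiality Stratify counts by essentiality class.
#' @return Data frame with `bin_start`, `bin_end`, (`stratum`,) `count`.
#' @export
fraction_histogram <- function(hits, bin_width = 0.05,
                               by_essentiality = FALSE) {
  nb <- 1 / bin_width
  if (abs(nb - round(nb)) > 1e-9)
    stop("bin_width must divide 1 evenly")
  nb <- as.integer(round(nb))
  frac <- if (!is.null(hits$fraction)) hits$fraction else hits$gene_fraction
  keep <- !is.na(frac)
  frac <- frac[keep]
  if (any(frac < 0 | frac >= 1)) stop("fractions must lie in [0, 1)")
  bin <- pmin(floor(frac / bin_width) + 1L, nb)
  edges <- data.frame(bin_start = (seq_len(nb) - 1) * bin_width,
                      bin_end = seq_len(nb) * bin_width)
  if (!by_essentiality) {
    edges$count <- tabulate(bin, nbins = nb)
    return(edges)
  }
  strata <- intersect(ESSENTIALITY_LEVELS, unique(hits$essentiality[keep]))
  out <- do.call(rbind, lapply(strata, function(s) {
    e <- edges
    e$stratum <- s
    e$count <- tabulate(bin[hits$essentiality[keep] == s], nbins = nb)
    e
  }))
  out[c("bin_start", "bin_end", "stratum", "count")]
}

#' Expected annotation accuracy of a redundant collection
#'
#' With per-mutant annotation accuracy `p`, a gene represented by `k`
#' independent insertions is correctly represented by at least one with
#' probability `a_k = 1 - (1 - p)^k`.  The collection-wide expectation is
#' the redundancy-share-weighted mean of the `a_k`.  `p` defaults to 40/53,
#' the fraction of independently re-sequenced mutants whose insertion fell
#' in the predicted or immediately adjacent gene.
#'
#' @param shares Numeric vector of redundancy shares (gene fraction
#'   represented by 1, 2, ... insertions); must sum to 1.
#' @param p Per-mutant annotation accuracy in `[0, 1]`.
#' @param round_ak_digits Optionally round each `a_k` to this many decimals
#'   before weighting (the reporting convention for the headline figure).
#' @return Expected fraction of genes accurately represented.
#' @examples
#' expected_accuracy(c(0, 1, 0))            # ~0.94: all genes in duplicate
#' expected_accuracy(c(0.21, 0.25, 0.54), round_ak_digits = 2)  # ~0.93
#' @export
expected_accuracy <- function(shares, p = 40 / 53, round_ak_digits = NULL) {
  if (any(shares < 0) || abs(sum(shares) - 1) > 1e-8)
    stop("shares must be non-negative and sum to 1")
  if (p < 0 || p > 1) stop("p must be in [0, 1]")
  a <- 1 - (1 - p)^seq_along(shares)
  if (!is.null(round_ak_digits)) a <- round_half_up(a, round_ak_digits)
  sum(shares * a)
}

#' Write a library manifest as TSV
#'
#' @param manifest A [build_collection()] manifest.
#' @param path File path.
#' @param consolidated_only Keep only the consolidated (rank-1) entries.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path, consolidated_only = FALSE) {
  tab <- as.data.frame(manifest)
  if (consolidated_only) tab <- tab[tab$consolidated, , drop = FALSE]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
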