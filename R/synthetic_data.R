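#' Generate a synthetic reference genome with annotated genes
#'
#' Emulates a small bacterial chromosome: non-overlapping genes on both
#' strands separated by intergenic spacers, each gene labelled with an
#' essentiality class.  Gene lengths are gamma-distributed (bacterial gene
#' lengths are right-skewed), spacers share the intergenic budget via a
#' multinomial draw, and class labels are apportioned to the requested
#' proportions exactly by largest-remainder rounding, then shuffled over
#' genes.  Fully deterministic given `seed`.
#'
#' Default essentiality proportions (83% non-essential, 4% high-fitness, 13%
#' essential) reflect typical high-density transposon fitness calls for an
#' alpha-proteobacterial genome.
#'
#' @param n_genes Number of genes (>= 1).
#' @param gene_length_mean,gene_length_sd Mean and sd of gene length in bp.
#' @param min_gene_length Lower truncation for gene length.
#' @param intergenic_fraction Fraction of the genome outside genes, in
#'   `[0, 1)`.
#' @param essentiality_proportions Named numeric vector over
#'   `non-essential`, `high-fitness`, `essential` (must sum to 1).
#' @param seed RNG seed.
#' @return An object of class `reference_bundle`: list with `genome`
#'   (character), `genome_length`, `genes` (a [gene_models()] table), `seed`.
#' @export
generate_reference <- function(n_genes, gene_length_mean = 900,
                               gene_length_sd = 500, min_gene_length = 150,
                               intergenic_fraction = 0.12,
                               essentiality_proportions = c(
                                 "non-essential" = 0.83,
                                 "high-fitness" = 0.04,
                                 "essential" = 0.13),
                               seed = 1) {
  if (n_genes < 1) stop("generation error: n_genes must be >= 1")
  if (intergenic_fraction < 0 || intergenic_fraction >= 1)
    stop("generation error: intergenic_fraction must be in [0, 1)")
  counts <- apportion_largest_remainder(essentiality_proportions, n_genes)

  set.seed(seed)
  shape <- (gene_length_mean / gene_length_sd)^2
  lens <- pmax(min_gene_length,
               round(stats::rgamma(n_genes, shape = shape,
                                   rate = shape / gene_length_mean)))
  gene_bp <- sum(lens)
  genome_length <- ceiling(gene_bp / (1 - intergenic_fraction))
  inter_bp <- genome_length - gene_bp
  # spread the intergenic budget over n_genes + 1 gaps
  gaps <- as.integer(stats::rmultinom(1, inter_bp, rep(1, n_genes + 1)))
  starts <- integer(n_genes)
  pos <- 1L + gaps[1]
  for (i in seq_len(n_genes)) {
    starts[i] <- pos
    pos <- pos + lens[i] + gaps[i + 1]
  }
  ends <- starts + lens - 1L
  if (ends[n_genes] > genome_length)
    stop("generation error: genes exceed requested genome")

  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  labels <- sample(rep(names(counts), counts))
  genes <- gene_models(sprintf("gene_%04d", seq_len(n_genes)),
                       starts, ends, strand, labels)
  genome <- paste(sample(c("A", "C", "G", "T"), genome_length,
                         replace = TRUE), collapse = "")
  structure(list(genome = genome, genome_length = genome_length,
                 genes = genes, seed = seed),
            class = "reference_bundle")
}

#' @export
print.reference_bundle <- function(x, ...) {
  tab <- table(factor(x$genes$essentiality, ESSENTIALITY_LEVELS))
  cat(sprintf("Synthetic reference: %d bp, %d genes (%s)\n",
              x$genome_length, nrow(x$genes),
              paste(sprintf("%s %d", names(tab)[tab > 0], tab[tab > 0]),
                    collapse = ", ")))
  invisible(x)
}

#' Write a reference bundle to FASTA + annotation files
#'
#' @param reference A [generate_reference()] bundle.
#' @param dir Output directory (created if needed).
#' @param name Base file name.
#' @return Named character vector of the files written (`fasta`, `gff3`,
#'   `tsv`), invisibly.
#' @export
write_reference <- function(reference, dir, name = "reference") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, paste0(name, ".fasta"))
  seqs <- Biostrings::DNAStringSet(stats::setNames(reference$genome, name))
  Biostrings::writeXStringSet(seqs, fa)
  gff <- file.path(dir, paste0(name, ".gff3"))
  write_annotation(reference$genes, gff, format = "gff3", seqname = name)
  tsv <- file.path(dir, paste0(name, "_genes.tsv"))
  write_annotation(reference$genes, tsv, format = "tsv")
  invisible(c(fasta = fa, gff3 = gff, tsv = tsv))
}

#' Simulate colony picking into an ordered array
#'
#' Fills the first `n_picked` wells of the design in plate order, one clone
#' per well.  Each fresh clone gets a random insertion position and
#' orientation; with probability `duplicate_rate` a pick instead re-picks an
#' existing clone (same insertion site) into the new well, modelling the
#' duplicate colonies inevitable in a hand-picked collection.
#'
#' Essential-gene handling mimics the insertion patterns seen in real
#' libraries: under `"exclude"` no insertions land in essential genes; under
#' `"ends-only"` (default) insertions in essential genes are accepted only
#' within the terminal `ends_fraction` of the gene at either end, where
#' enough product can remain to keep the cell viable; `"allow"` applies no
#' filter.
#'
#' @param reference A [generate_reference()] bundle.
#' @param design A [pooling_design()].
#' @param n_picked Number of wells to fill (<= design capacity).
#' @param duplicate_rate Probability a pick duplicates an existing clone.
#' @param essential_policy `"ends-only"`, `"exclude"` or `"allow"`.
#' @param ends_fraction Width of the permissive terminal region under
#'   `"ends-only"` (gene fraction below it or at/above `1 - ends_fraction`).
#' @param seed RNG seed.
#' @return Object of class `truth_placement`: list with `sites` (data frame
#'   `site_id`, `position`, `strand`) and `wells` (data frame `plate_row`,
#'   `plate_col`, `well_row`, `well_col`, `site_id`).
#' @export
simulate_picking <- function(reference, design, n_picked,
                             duplicate_rate = 0.36,
                             essential_policy = c("ends-only", "exclude",
                                                  "allow"),
                             ends_fraction = 0.1, seed = 1) {
  essential_policy <- match.arg(essential_policy)
  if (n_picked > design_capacity(design))
    stop("capacity error: n_picked exceeds design capacity")
  if (duplicate_rate < 0 || duplicate_rate > 1)
    stop("duplicate_rate must be in [0, 1]")
  genes <- reference$genes
  ess <- genes[genes$essentiality == "essential", , drop = FALSE]
  G <- reference$genome_length

  position_ok <- function(pos) {
    if (essential_policy == "allow" || nrow(ess) == 0) return(TRUE)
    inside <- pos >= ess$start & pos <= ess$end
    if (!any(inside)) return(TRUE)
    if (essential_policy == "exclude") return(FALSE)
    g <- ess[which(inside)[1], ]
    len <- g$end - g$start + 1
    frac <- if (g$strand == "+") (pos - g$start) / len else (g$end - pos) / len
    frac < ends_fraction || frac >= 1 - ends_fraction
  }

  set.seed(seed)
  wt <- well_pool_table(design)[seq_len(n_picked), , drop = FALSE]
  positions <- integer(0)
  strands <- character(0)
  site_of_pick <- integer(n_picked)
  pos_index <- new.env(hash = TRUE)
  for (i in seq_len(n_picked)) {
    if (length(positions) > 0 && stats::runif(1) < duplicate_rate) {
      site_of_pick[i] <- sample.int(length(positions), 1)
      next
    }
    repeat {  # fresh clones always carry a new, policy-compliant site
      pos <- sample.int(G, 1)
      if (position_ok(pos) && is.null(pos_index[[as.character(pos)]])) break
    }
    positions <- c(positions, pos)
    strands <- c(strands, sample(c("+", "-"), 1))
    pos_index[[as.character(pos)]] <- length(positions)
    site_of_pick[i] <- length(positions)
  }
  sites <- data.frame(site_id = sprintf("site_%05d", seq_along(positions)),
                      position = positions, strand = strands)
  wells <- data.frame(plate_row = wt$plate_row, plate_col = wt$plate_col,
                      well_row = wt$well_row, well_col = wt$well_col,
                      site_id = sites$site_id[site_of_pick])
  structure(list(sites = sites, wells = wells, seed = seed),
            class = "truth_placement")
}

#' @export
print.truth_placement <- function(x, ...) {
  cat(sprintf("Truth placement: %d wells, %d unique insertion sites\n",
              nrow(x$wells), nrow(x$sites)))
  invisible(x)
}

#' Noise model for pooled sequencing counts
#'
#' Member pools of a clone receive negative-binomial read counts (bacterial
#' pool sequencing is overdispersed relative to Poisson); per-pool expected
#' depth varies lognormally around `depth`.  Each (well, pool) membership
#' independently drops out with probability `dropout`.  Non-member pools are
#' contaminated (index hopping, well-to-well carry-over) with probability
#' `epsilon`, receiving a Poisson(`lambda`) count.
#'
#' @param depth Expected member read count per (well, pool).
#' @param dispersion Negative-binomial size parameter (> 0); `Inf` gives
#'   Poisson member counts.
#' @param epsilon Contamination probability per non-member (site, pool) cell,
#'   in `[0, 1]`.
#' @param lambda Mean contamination count (>= 0).
#' @param dropout Probability a member (well, pool) reads zero, in `[0, 1]`.
#' @param depth_sdlog Lognormal sd of per-pool depth variation (0 = equal
#'   depth in every pool).
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(depth = 500, dispersion = 5, epsilon = 0.005,
                        lambda = 3, dropout = 0.01, depth_sdlog = 0.25) {
  stopifnot(depth > 0, dispersion > 0,
            epsilon >= 0, epsilon <= 1, lambda >= 0,
            dropout >= 0, dropout <= 1, depth_sdlog >= 0)
  structure(list(depth = depth, dispersion = dispersion, epsilon = epsilon,
                 lambda = lambda, dropout = dropout,
                 depth_sdlog = depth_sdlog),
            class = "noise_model")
}

#' A noise-free pooled-count configuration
#'
#' Poisson member counts at the given depth, no contamination, no dropout,
#' equal depth across pools — every non-zero cell is a true pool membership.
#'
#' @param depth Expected member read count.
#' @return A [noise_model()].
#' @export
noise_free <- function(depth = 500) {
  noise_model(depth = depth, dispersion = Inf, epsilon = 0, lambda = 0,
              dropout = 0, depth_sdlog = 0)
}

#' Simulate the pooled sequencing count matrix
#'
#' The forward model for deconvolution: each clone contributes member reads
#' to the four pools of every well it occupies, and background contamination
#' may hit any other pool (see [noise_model()]).
#'
#' Contamination is coupled across `epsilon` values by common random
#' numbers: for a fixed `seed`, the set of contaminated cells at a smaller
#' `epsilon` is a subset of the set at a larger one and shared cells receive
#' identical counts, so noise ladders are directly comparable.
#'
#' @param placement A [simulate_picking()] truth placement.
#' @param design The [pooling_design()] used for picking.
#' @param noise A [noise_model()].
#' @param seed RNG seed.
#' @return Object of class `pool_count_matrix`: list with `counts` (integer
#'   matrix, sites x pools), `sites` (data frame `site_id`, `position`,
#'   `strand`) and `pools` (character vector).
#' @export
simulate_pool_counts <- function(placement, design, noise = noise_model(),
                                 seed = 1) {
  stopifnot(inherits(placement, "truth_placement"),
            inherits(noise, "noise_model"))
  pools <- design_pools(design)
  np <- length(pools)
  sites <- placement$sites
  ns <- nrow(sites)
  counts <- matrix(0L, ns, np, dimnames = list(sites$site_id, pools))

  # membership: pools of each occupied well, attributed to the well's clone
  wp <- placement$wells
  site_idx <- match(wp$site_id, sites$site_id)
  mem <- cbind(
    match(design$pools$WELL_COL[wp$well_col], pools),
    match(design$pools$WELL_ROW[match(wp$well_row, LETTERS)], pools),
    match(design$pools$PLATE_COL[wp$plate_col], pools),
    match(design$pools$PLATE_ROW[wp$plate_row], pools))

  set.seed(seed)
  pool_depth <- if (noise$depth_sdlog > 0)
    noise$depth * stats::rlnorm(np, -noise$depth_sdlog^2 / 2,
                                noise$depth_sdlog)
  else rep(noise$depth, np)
  for (k in 1:4) {
    mu <- pool_depth[mem[, k]]
    draw <- if (is.finite(noise$dispersion))
      stats::rnbinom(nrow(mem), size = noise$dispersion, mu = mu)
    else stats::rpois(nrow(mem), mu)
    if (noise$dropout > 0)
      draw[stats::runif(nrow(mem)) < noise$dropout] <- 0L
    cell <- cbind(site_idx, mem[, k])
    for (j in seq_len(nrow(mem)))
      counts[cell[j, 1], cell[j, 2]] <- counts[cell[j, 1], cell[j, 2]] +
        draw[j]
  }

  # contamination stream: independent of the member stream and of epsilon,
  # drawn for every cell so smaller epsilon contaminates a subset of cells
  if (ns > 0 && np > 0) {
    set.seed((seed + 104729L) %% .Machine$integer.max)
    u <- matrix(stats::runif(ns * np), ns, np)
    mag <- matrix(stats::rpois(ns * np, noise$lambda), ns, np)
    member_mask <- matrix(FALSE, ns, np)
    member_mask[cbind(rep(site_idx, 4), as.vector(mem))] <- TRUE
    hit <- u < noise$epsilon & !member_mask
    counts[hit] <- counts[hit] + mag[hit]
  }
  structure(list(counts = counts, sites = sites, pools = pools),
            class = "pool_count_matrix")
}

#' @export
print.pool_count_matrix <- function(x, ...) {
  cat(sprintf("Pool count matrix: %d insertion sites x %d pools, %s reads\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' Write / read a pool count matrix as TSV
#'
#' Columns: `site_id`, `position`, `strand`, then one column per pool
#' identifier.  `read_pool_counts` validates the pool columns against a
#' design when one is given.
#'
#' @param pcm A `pool_count_matrix`.
#' @param path File path.
#' @param design Optional [pooling_design()] to validate against.
#' @return `write_pool_counts` returns `path` invisibly; `read_pool_counts`
#'   returns a `pool_count_matrix`.
#' @export
write_pool_counts <- function(pcm, path) {
  stopifnot(inherits(pcm, "pool_count_matrix"))
  tab <- cbind(pcm$sites, as.data.frame(pcm$counts, check.names = FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pool_counts
#' @export
read_pool_counts <- function(path, design = NULL) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  meta <- c("site_id", "position", "strand")
  if (!all(meta %in% names(tab)))
    stop("counts table must have columns site_id, position, strand")
  pool_cols <- setdiff(names(tab), meta)
  counts <- as.matrix(tab[pool_cols])
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("read counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  rownames(counts) <- tab$site_id
  if (!is.null(design)) {
    want <- design_pools(design)
    if (!setequal(pool_cols, want))
      stop("counts columns do not match the design's pools")
    counts <- counts[, want, drop = FALSE]
    pool_cols <- want
  }
  structure(list(counts = counts,
                 sites = tab[meta], pools = pool_cols),
            class = "pool_count_matrix")
}

#' Emit per-pool junction-read FASTQ files from simulated counts
#'
#' For each (site, pool) cell, writes `count` reads consisting of the
#' transposon end followed by the genomic flank at the insertion site (the
#' flank is taken 3' of the junction on the site's strand).  Used to
#' exercise the read-mapping path at toy scale.
#'
#' @param pcm A `pool_count_matrix` (typically noise-free and small).
#' @param reference The [generate_reference()] bundle the sites refer to.
#' @param dir Output directory.
#' @param tn_end Transposon end sequence prepended to every read.
#' @param flank_length Genomic flank length in bp.
#' @param max_reads_per_cell Cap on reads written per cell (keeps toy
#'   fixtures small); `Inf` writes every read.
#' @return Data frame manifest (`pool`, `fastq`) also written to
#'   `pool_manifest.tsv` in `dir`.
#' @export
emit_pool_fastq <- function(pcm, reference, dir,
                            tn_end = "ACTTGTGTATAAGAGTCAG",
                            flank_length = 30, max_reads_per_cell = Inf) {
  stopifnot(inherits(pcm, "pool_count_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome <- Biostrings::DNAString(reference$genome)
  G <- length(genome)
  flank_of <- function(pos, strand) {
    if (strand == "+") {
      e <- min(G, pos + flank_length - 1)
      as.character(genome[pos:e])
    } else {
      s <- max(1, pos - flank_length + 1)
      as.character(Biostrings::reverseComplement(genome[s:pos]))
    }
  }
  manifest <- data.frame(pool = pcm$pools,
                         fastq = file.path(dir, paste0(pcm$pools, ".fastq")))
  for (p in seq_along(pcm$pools)) {
    reads <- character(0)
    ids <- character(0)
    for (s in seq_len(nrow(pcm$counts))) {
      n <- min(pcm$counts[s, p], max_reads_per_cell)
      if (n > 0) {
        fl <- flank_of(pcm$sites$position[s], pcm$sites$strand[s])
        reads <- c(reads, rep(paste0(tn_end, fl), n))
        ids <- c(ids, sprintf("%s_%s_%d", pcm$sites$site_id[s],
                              pcm$pools[p], seq_len(n)))
      }
    }
    set <- Biostrings::DNAStringSet(stats::setNames(reads, ids))
    Biostrings::writeXStringSet(set, manifest$fastq[p], format = "fastq")
  }
  utils::write.table(manifest, file.path(dir, "pool_manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest
}

#' Write a truth placement as TSV
#'
#' One row per occupied well: `site_id`, `position`, `strand`, `plate_row`,
#' `plate_col`, `well_row`, `well_col`.
#'
#' @param placement A [simulate_picking()] truth placement.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(placement, path) {
  stopifnot(inherits(placement, "truth_placement"))
  tab <- merge(placement$wells, placement$sites, by = "site_id", sort = FALSE)
  utils::write.table(tab[c("site_id", "position", "strand", "plate_row",
                           "plate_col", "well_row", "well_col")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
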