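#' Extract the genomic fragment downstream of the transposon end
#'
#' Exact-match trimming for junction reads: if `transposon_end` occurs in a
#' read, the suffix after its first occurrence is returned, provided it is at
#' least `min_fragment` bp; otherwise `NA`.
#'
#' @param reads Character vector of read sequences.
#' @param transposon_end Transposon end sequence (non-empty).
#' @param min_fragment Minimum genomic fragment length to keep.
#' @return Character vector parallel to `reads` (`NA` where no usable
#'   fragment).
#' @export
extract_junction <- function(reads, transposon_end, min_fragment = 20) {
  if (!nzchar(transposon_end)) stop("transposon_end must be non-empty")
  hit <- regexpr(transposon_end, reads, fixed = TRUE)
  frag <- ifelse(hit > 0,
                 substr(reads, hit + nchar(transposon_end), nchar(reads)),
                 NA_character_)
  frag[!is.na(frag) & nchar(frag) < min_fragment] <- NA_character_
  frag
}

#' Locate genomic fragments by exact match on both strands
#'
#' Each fragment is searched as an exact match against the genome and its
#' reverse complement.  A unique hit yields an insertion site; the position
#' convention is the coordinate of the first fragment base adjacent to the
#' junction on the read's strand: the leftmost matched base for a `+` hit,
#' the rightmost matched base for a `-` hit (the fragment matching the minus
#' strand).  Fragments with no hit are tallied unmapped; fragments with two
#' or more hits (repeats) are ambiguous and excluded.
#'
#' @param fragments Character vector of genomic fragments (`NA` entries are
#'   counted as unmapped).
#' @param genome Genome sequence (character or `DNAString`).
#' @return List with `sites` (data frame `fragment` index, `position`,
#'   `strand` for uniquely located fragments), `n_unmapped`, `n_ambiguous`.
#' @export
locate_fragments <- function(fragments, genome) {
  genome <- Biostrings::DNAString(as.character(genome))
  if (length(genome) == 0) stop("genome must be non-empty")
  uniq <- unique(fragments[!is.na(fragments)])
  loc <- lapply(uniq, function(f) {
    fwd <- Biostrings::start(Biostrings::matchPattern(f, genome))
    rev <- Biostrings::matchPattern(
      Biostrings::reverseComplement(Biostrings::DNAString(f)), genome)
    n <- length(fwd) + length(rev)
    if (n == 1) {
      if (length(fwd) == 1) c(fwd, 1L) else c(Biostrings::end(rev), 2L)
    } else c(NA_integer_, if (n == 0) 0L else 3L)
  })
  code <- vapply(loc, `[`, integer(1), 2)
  pos <- vapply(loc, `[`, integer(1), 1)
  lk_pos <- pos[match(fragments, uniq)]
  lk_code <- code[match(fragments, uniq)]
  lk_code[is.na(fragments)] <- 0L
  ok <- which(!is.na(lk_pos))
  list(sites = data.frame(fragment = ok, position = lk_pos[ok],
                          strand = c("+", "-")[lk_code[ok]]),
       n_unmapped = sum(lk_code == 0L, na.rm = TRUE),
       n_ambiguous = sum(lk_code == 3L, na.rm = TRUE))
}

#' Tally located junction reads into a pool count matrix
#'
#' @param located Data frame with one row per uniquely located read:
#'   columns `pool`, `position`, `strand`.
#' @param design A [pooling_design()]; every `pool` value must be one of its
#'   pool identifiers.
#' @param merge_window Sites on the same strand within this many bp are
#'   collapsed into one row (junction jitter); 0 disables merging.  The
#'   representative position of a merged cluster is its most frequent
#'   position (ties: smallest).
#' @return A `pool_count_matrix`.
#' @export
tally_counts <- function(located, design, merge_window = 0) {
  pools <- design_pools(design)
  if (nrow(located) > 0 && !all(located$pool %in% pools))
    stop("input error: unknown pool id in located reads")
  if (nrow(located) == 0) {
    counts <- matrix(0L, 0, length(pools), dimnames = list(NULL, pools))
    return(structure(list(counts = counts,
                          sites = data.frame(site_id = character(0),
                                             position = integer(0),
                                             strand = character(0)),
                          pools = pools),
                     class = "pool_count_matrix"))
  }
  located <- located[order(located$strand, located$position), ]
  key_pos <- located$position
  if (merge_window > 0) {
    for (s in c("+", "-")) {
      i <- which(located$strand == s)
      if (length(i) < 2) next
      p <- located$position[i]
      cluster <- cumsum(c(1L, as.integer(diff(p) > merge_window)))
      for (cl in unique(cluster)) {
        j <- i[cluster == cl]
        tab <- table(located$position[j])
        rep_pos <- as.integer(names(tab)[which.max(tab)])
        key_pos[j] <- rep_pos
      }
    }
  }
  key <- paste(key_pos, located$strand)
  ukey <- unique(key)
  site_pos <- key_pos[match(ukey, key)]
  site_strand <- located$strand[match(ukey, key)]
  ord <- order(site_pos, site_strand)
  ukey <- ukey[ord]; site_pos <- site_pos[ord]; site_strand <- site_strand[ord]
  sites <- data.frame(site_id = sprintf("site_%05d", seq_along(ukey)),
                      position = site_pos, strand = site_strand)
  counts <- matrix(0L, length(ukey), length(pools),
                   dimnames = list(sites$site_id, pools))
  ij <- cbind(match(key, ukey), match(located$pool, pools))
  for (r in seq_len(nrow(ij)))
    counts[ij[r, 1], ij[r, 2]] <- counts[ij[r, 1], ij[r, 2]] + 1L
  structure(list(counts = counts, sites = sites, pools = pools),
            class = "pool_count_matrix")
}

#' Map per-pool junction FASTQ files to a pool count matrix
#'
#' Toy-scale pipeline: read each pool's FASTQ, trim the transposon end
#' ([extract_junction()]), locate fragments exactly on both strands
#' ([locate_fragments()]), and tally uniquely located reads per pool
#' ([tally_counts()]).  Real datasets should instead supply a precomputed
#' counts TSV via [read_pool_counts()].
#'
#' @param manifest Data frame with columns `pool`, `fastq`, or the path of
#'   such a TSV (as written by [emit_pool_fastq()]).
#' @param genome Genome sequence (character, `DNAString`, or FASTA path).
#' @param design A [pooling_design()].
#' @param tn_end Transposon end sequence.
#' @param min_fragment Minimum genomic fragment length.
#' @param merge_window See [tally_counts()].
#' @return A `pool_count_matrix`; attributes `n_unmapped` and `n_ambiguous`
#'   carry the discard tallies.
#' @export
map_pools <- function(manifest, genome, design,
                      tn_end = "ACTTGTGTATAAGAGTCAG", min_fragment = 20,
                      merge_window = 0) {
  if (is.character(manifest) && length(manifest) == 1)
    manifest <- utils::read.delim(manifest, stringsAsFactors = FALSE)
  if (is.character(genome) && length(genome) == 1 &&
      file.exists(genome) && grepl("\\.fa(sta)?$", genome, ignore.case = TRUE))
    genome <- as.character(Biostrings::readDNAStringSet(genome)[[1]])
  located <- list()
  n_unmapped <- 0L
  n_ambiguous <- 0L
  for (i in seq_len(nrow(manifest))) {
    reads <- as.character(Biostrings::readDNAStringSet(manifest$fastq[i],
                                                       format = "fastq"))
    frags <- extract_junction(reads, tn_end, min_fragment)
    loc <- locate_fragments(frags, genome)
    n_unmapped <- n_unmapped + loc$n_unmapped
    n_ambiguous <- n_ambiguous + loc$n_ambiguous
    if (nrow(loc$sites) > 0)
      located[[length(located) + 1]] <-
        data.frame(pool = manifest$pool[i], position = loc$sites$position,
                   strand = loc$sites$strand)
  }
  located <- if (length(located)) do.call(rbind, located) else
    data.frame(pool = character(0), position = integer(0),
               strand = character(0))
  pcm <- tally_counts(located, design, merge_window = merge_window)
  attr(pcm, "n_unmapped") <- n_unmapped
  attr(pcm, "n_ambiguous") <- n_ambiguous
  pcm
}
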