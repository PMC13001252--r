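# Shared fixtures: everything is generated in code at test time.

# a tiny 2x2 grid of 4x6 plates (96 wells, 14 pools)
tiny_design <- function() pooling_design(2, 2, 4, 6)

# a small synthetic reference used across modules
tiny_reference <- function(seed = 11, n_genes = 30)
  generate_reference(n_genes, gene_length_mean = 600, gene_length_sd = 200,
                     intergenic_fraction = 0.2, seed = seed)

# build a count row for one site from per-axis coordinate counts
row_from_axes <- function(design, wc = NULL, wr = NULL, pc = NULL,
                          pr = NULL) {
  pools <- design_pools(design)
  row <- stats::setNames(numeric(length(pools)), pools)
  fill <- function(vals, ids) {
    if (!is.null(vals)) row[ids[seq_along(vals)]] <<- vals
  }
  fill(wc, design$pools$WELL_COL)
  fill(wr, design$pools$WELL_ROW)
  fill(pc, design$pools$PLATE_COL)
  fill(pr, design$pools$PLATE_ROW)
  row
}

# wrap count rows into a pool_count_matrix
pcm_from_rows <- function(rows, design, positions = NULL) {
  counts <- if (length(rows) == 0)
    matrix(0L, 0, length(design_pools(design)),
           dimnames = list(NULL, design_pools(design)))
  else do.call(rbind, rows)
  n <- nrow(counts)
  ids <- sprintf("site_%05d", seq_len(n))
  rownames(counts) <- ids
  storage.mode(counts) <- "integer"
  structure(list(counts = counts,
                 sites = data.frame(
                   site_id = ids,
                   position = if (is.null(positions)) seq_len(n) else
                     positions,
                   strand = rep("+", n)),
                 pools = design_pools(design)),
            class = "pool_count_matrix")
}

# compare pipeline output with the brute-force oracle
expect_oracle_equal <- function(res, orc) {
  got <- res$table[names(orc)]
  rownames(got) <- NULL
  rownames(orc) <- NULL
  expect_equal(got, orc)
}
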