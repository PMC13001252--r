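test_that("gene fractions are strand-aware with fraction 0 at the start", {
  g <- gene_models(c("plus", "minus"), c(1001, 3001), c(2000, 4000),
                   c("+", "-"))
  h <- locate_in_gene(c(1001, 2000, 4000, 3001, 500), g)
  expect_equal(h$gene_id, c("plus", "plus", "minus", "minus", NA))
  expect_equal(h$fraction[1], 0)
  expect_equal(h$fraction[2], 0.999)
  expect_equal(h$fraction[3], 0)        # translational start of a - gene
  expect_equal(h$fraction[4], 0.999)
  expect_true(is.na(h$fraction[5]))     # intergenic
})

test_that("fraction is invariant under strand relabeling with reflection", {
  s <- 501; e <- 1700
  gp <- gene_models("g", s, e, "+")
  gm <- gene_models("g", s, e, "-")
  for (pos in c(s, s + 13, 777, e - 1, e)) {
    fp <- locate_in_gene(pos, gp)$fraction
    fm <- locate_in_gene(s + e - pos, gm)$fraction
    expect_equal(fp, fm)
  }
})

test_that("build_collection keeps the most-upstream insertions, at most
           three per gene, and flags the rank-1 entry consolidated", {
  g <- gene_models("g1", 1000, 1999, "+", "non-essential")
  fr <- c(0.9, 0.5, 0.1, 0.3, 0.7)
  tab <- data.frame(
    site_id = sprintf("s%02d", 1:5),
    position = as.integer(1000 + fr * 1000),
    strand = "+", status = "auto",
    plate_row = 1L, plate_col = 1L, well_row = "A", well_col = 1:5,
    stringsAsFactors = FALSE)
  man <- build_collection(tab, g)
  expect_equal(nrow(man), 3)
  expect_equal(sort(man$gene_fraction), c(0.1, 0.3, 0.5))
  expect_equal(man$rank[order(man$gene_fraction)], 1:3)
  expect_equal(man$site_id[man$consolidated], "s03")

  # single-entry gene: kept, rank 1, consolidated
  one <- build_collection(tab[1, ], g)
  expect_equal(one$rank, 1L)
  expect_true(one$consolidated)

  # intergenic assignments are retained as controls
  tabi <- tab[1, ]; tabi$position <- 10L
  mani <- build_collection(tabi, g)
  expect_true(mani$intergenic)
  expect_false(mani$consolidated)
})

test_that("redundancy-weighted gene counts reproduce the collection size", {
  expect_equal(collection_size(c(625, 717, 1560)), 6739)
  # identity holds on a simulated collection
  ref <- tiny_reference(seed = 51, n_genes = 40)
  d <- tiny_design()
  pl <- simulate_picking(ref, d, 90, duplicate_rate = 0, seed = 6)
  pcm <- simulate_pool_counts(pl, d, noise_free(), seed = 7)
  man <- build_collection(deconvolve(pcm, d), ref$genes)
  rs <- redundancy_summary(man)
  expect_equal(collection_size(rs$genes_by_redundancy), rs$n_mutants)
  expect_equal(sum(man$consolidated), rs$n_genes)
  # consolidated entry minimises gene fraction within each gene
  for (g in unique(man$gene_id[!man$intergenic])) {
    rows <- man[!man$intergenic & man$gene_id == g, ]
    expect_equal(rows$gene_fraction[rows$consolidated],
                 min(rows$gene_fraction))
  }
})

test_that("coverage percentages use half-up rounding to one decimal", {
  expect_equal(percent_of(2687, 3135), 85.7)
  expect_equal(percent_of(2902, 3767), 77.0)
  expect_equal(percent_of(3225, 3767), 85.6)
  expect_equal(percent_of(40, 53, digits = 0), 75)
  # half-up, not banker's
  expect_equal(percent_of(1, 8, digits = 1), 12.5)
  expect_equal(round_half_up(0.125 * 100, 1), 12.5)
  expect_equal(round_half_up(85.65, 1), 85.7)
})

test_that("coverage_report stratifies by essentiality and self-checks", {
  g <- gene_models(paste0("g", 1:6), (0:5) * 1000 + 1, (0:5) * 1000 + 500,
                   "+", c("non-essential", "non-essential", "non-essential",
                          "essential", "essential", "high-fitness"))
  hits <- data.frame(gene_id = c("g1", "g2", "g4"))
  rep <- coverage_report(hits, g)
  expect_equal(rep$orfs_hit[rep$stratum == "non-essential"], 2)
  expect_equal(rep$orfs_hit[rep$stratum == "essential"], 1)
  expect_equal(rep$orfs_hit[rep$stratum == "Total"], 3)
  expect_equal(rep$total[rep$stratum == "Total"], 6)
  # percentages recompute from their own counts
  expect_equal(rep$pct_hit, percent_of(rep$orfs_hit, rep$total))
  # zero assignments: 0 hit, 100% missing everywhere
  rep0 <- coverage_report(data.frame(gene_id = character(0)), g)
  expect_true(all(rep0$orfs_hit == 0))
  expect_true(all(rep0$pct_missing == 100))
})

test_that("fraction histograms conserve counts and show the ends-only
           pattern for essential genes", {
  h <- data.frame(fraction = c(0, 0.01, 0.04, 0.55),
                  essentiality = "non-essential")
  out <- fraction_histogram(h)
  expect_equal(nrow(out), 20)
  expect_equal(sum(out$count), 4)
  expect_equal(out$count[1], 3)
  expect_error(fraction_histogram(h, bin_width = 0.03), "divide 1 evenly")

  ref <- generate_reference(40, essentiality_proportions = c(
    "non-essential" = 0.5, "high-fitness" = 0, "essential" = 0.5),
    seed = 61)
  d <- tiny_design()
  pl <- simulate_picking(ref, d, 96, duplicate_rate = 0,
                         essential_policy = "ends-only", seed = 9)
  hits <- locate_in_gene(pl$sites$position, ref$genes)
  hits <- hits[!is.na(hits$gene_id), ]
  hist <- fraction_histogram(hits, by_essentiality = TRUE)
  ess <- hist[hist$stratum == "essential", ]
  central <- ess$count[ess$bin_start >= 0.1 & ess$bin_end <= 0.9]
  expect_true(all(central == 0))
  expect_equal(sum(hist$count), nrow(hits))
})

test_that("expected accuracy reproduces the redundancy model", {
  p <- 40 / 53
  expect_equal(round_half_up(expected_accuracy(c(0, 1, 0), p), 2), 0.94)
  expect_equal(round_half_up(expected_accuracy(c(0, 0, 1), p), 2), 0.99)
  expect_equal(expected_accuracy(c(0.2, 0.3, 0.5), p = 1), 1)
  w <- expected_accuracy(c(0.21, 0.25, 0.54), p, round_ak_digits = 2)
  expect_equal(w, 0.9271, tolerance = 1e-12)
  expect_equal(round_half_up(w, 2), 0.93)
  expect_error(expected_accuracy(c(0.5, 0.2), p), "sum to 1")
  # a_k is non-decreasing in k
  a <- 1 - (1 - p)^(1:3)
  expect_true(all(diff(a) > 0))
})
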