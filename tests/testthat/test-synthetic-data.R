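test_that("generated references are structurally valid and deterministic", {
  ref <- generate_reference(10, essentiality_proportions = c(
    "non-essential" = 1, "high-fitness" = 0, "essential" = 0), seed = 2)
  g <- ref$genes
  expect_equal(nrow(g), 10)
  expect_true(all(g$essentiality == "non-essential"))
  expect_true(all(g$start >= 1 & g$end <= ref$genome_length))
  ord <- order(g$start)
  expect_true(all(g$start[ord][-1] > g$end[ord][-10]))  # non-overlapping

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_reference(generate_reference(15, seed = 8), d1)
  write_reference(generate_reference(15, seed = 8), d2)
  expect_identical(readLines(file.path(d1, "reference.fasta")),
                   readLines(file.path(d2, "reference.fasta")))
  expect_identical(readLines(file.path(d1, "reference_genes.tsv")),
                   readLines(file.path(d2, "reference_genes.tsv")))
})

test_that("essentiality labels follow largest-remainder apportionment", {
  expect_equal(unname(apportion_largest_remainder(c(0.8, 0.05, 0.15), 100)),
               c(80L, 5L, 15L))
  expect_equal(sum(apportion_largest_remainder(c(1, 2, 4) / 7, 100)), 100)
  ref <- generate_reference(100, essentiality_proportions = c(
    "non-essential" = 0.8, "high-fitness" = 0.05, "essential" = 0.15),
    seed = 4)
  tab <- table(ref$genes$essentiality)
  expect_equal(tab[["non-essential"]], 80)
  expect_equal(tab[["high-fitness"]], 5)
  expect_equal(tab[["essential"]], 15)
})

test_that("annotation round-trips through GFF3 and TSV", {
  ref <- tiny_reference(seed = 21, n_genes = 12)
  gff <- withr::local_tempfile(fileext = ".gff3")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_annotation(ref$genes, gff, format = "gff3")
  write_annotation(ref$genes, tsv, format = "tsv")
  g1 <- read_annotation(gff)
  g2 <- read_annotation(tsv)
  for (g in list(g1, g2)) {
    expect_equal(g$gene_id, ref$genes$gene_id)
    expect_equal(g$start, ref$genes$start)
    expect_equal(g$strand, ref$genes$strand)
    expect_equal(g$essentiality, ref$genes$essentiality)
  }
})

test_that("picking respects capacity, duplicates and essential policies", {
  ref <- generate_reference(40, essentiality_proportions = c(
    "non-essential" = 0.5, "high-fitness" = 0, "essential" = 0.5),
    seed = 13)
  d <- tiny_design()
  expect_error(simulate_picking(ref, d, 1000, seed = 1), "capacity")

  pl0 <- simulate_picking(ref, d, 50, duplicate_rate = 0, seed = 3)
  expect_equal(nrow(pl0$sites), 50)          # all picks unique
  expect_equal(nrow(pl0$wells), 50)
  expect_false(anyDuplicated(pl0$wells[1:4]) > 0)

  pld <- simulate_picking(ref, d, 80, duplicate_rate = 0.5, seed = 3)
  expect_lt(nrow(pld$sites), 80)

  ess <- ref$genes[ref$genes$essentiality == "essential", ]
  plx <- simulate_picking(ref, d, 96, duplicate_rate = 0,
                          essential_policy = "exclude", seed = 5)
  in_ess <- vapply(plx$sites$position, function(p)
    any(p >= ess$start & p <= ess$end), logical(1))
  expect_false(any(in_ess))

  ple <- simulate_picking(ref, d, 96, duplicate_rate = 0,
                          essential_policy = "ends-only", seed = 5)
  hits <- locate_in_gene(ple$sites$position, ref$genes)
  ess_hits <- hits[!is.na(hits$essentiality) &
                     hits$essentiality == "essential", ]
  if (nrow(ess_hits) > 0)
    expect_true(all(ess_hits$fraction < 0.1 | ess_hits$fraction >= 0.9))
})

test_that("noise-free counts are non-zero exactly on member pools", {
  ref <- tiny_reference(seed = 17)
  d <- tiny_design()
  pl <- simulate_picking(ref, d, 20, duplicate_rate = 0, seed = 7)
  pcm <- simulate_pool_counts(pl, d, noise_free(), seed = 9)
  expect_true(all(rowSums(pcm$counts > 0) == 4))
  # member pools match pools_for_well of the occupied well
  for (i in seq_len(nrow(pcm$counts))) {
    w <- pl$wells[pl$wells$site_id == pcm$sites$site_id[i], ]
    expected <- unname(pools_for_well(d, list(
      plate_row = w$plate_row, plate_col = w$plate_col,
      well_row = w$well_row, well_col = w$well_col)))
    expect_setequal(names(which(pcm$counts[i, ] > 0)), expected)
  }
})

test_that("a clone duplicated across two fully distinct wells lights 8 pools", {
  ref <- tiny_reference(seed = 19)
  d <- tiny_design()
  sites <- data.frame(site_id = "site_00001", position = 500, strand = "+")
  wells <- data.frame(plate_row = c(1, 2), plate_col = c(1, 2),
                      well_row = c("A", "B"), well_col = c(1, 2),
                      site_id = "site_00001")
  pl <- structure(list(sites = sites, wells = wells, seed = 1),
                  class = "truth_placement")
  pcm <- simulate_pool_counts(pl, d, noise_free(), seed = 3)
  expect_equal(sum(pcm$counts > 0), 8)
})

test_that("contamination rate matches epsilon in expectation and is coupled
           across epsilon by common random numbers", {
  ref <- generate_reference(60, seed = 23)
  d <- pooling_design(3, 3, 8, 12)
  pl <- simulate_picking(ref, d, 500, duplicate_rate = 0, seed = 11)
  eps <- 0.01
  nm <- noise_model(epsilon = eps, lambda = 5, dropout = 0, depth_sdlog = 0)
  pcm <- simulate_pool_counts(pl, d, nm, seed = 31)
  pcm0 <- simulate_pool_counts(pl, d, noise_free(), seed = 31)
  member <- pcm0$counts > 0
  n_cells <- sum(!member)
  n_contam <- sum(pcm$counts[!member] > 0)
  # lambda = 5 so a contaminated cell is zero only exp(-5) of the time
  p_obs <- 1 - exp(-5)
  expect_lt(abs(n_contam / n_cells - eps * p_obs),
            3 * sqrt(eps * (1 - eps) / n_cells) + 0.001)

  # CRN coupling: cells contaminated at eps are a subset of those at 2*eps
  nm2 <- noise_model(epsilon = 2 * eps, lambda = 5, dropout = 0,
                     depth_sdlog = 0)
  pcm2 <- simulate_pool_counts(pl, d, nm2, seed = 31)
  extra1 <- pcm$counts - pcm0$counts
  extra2 <- pcm2$counts - pcm0$counts
  expect_true(all(extra2[extra1 > 0] == extra1[extra1 > 0]))
})

test_that("total member reads scale linearly with depth in expectation", {
  ref <- tiny_reference(seed = 29)
  d <- tiny_design()
  pl <- simulate_picking(ref, d, 60, duplicate_rate = 0, seed = 2)
  t1 <- sum(simulate_pool_counts(pl, d, noise_free(depth = 100),
                                 seed = 5)$counts)
  t2 <- sum(simulate_pool_counts(pl, d, noise_free(depth = 1000),
                                 seed = 5)$counts)
  expect_lt(abs(t2 / t1 - 10), 0.5)
})

test_that("pool count matrices round-trip through TSV", {
  ref <- tiny_reference(seed = 31)
  d <- tiny_design()
  pl <- simulate_picking(ref, d, 25, duplicate_rate = 0, seed = 4)
  pcm <- simulate_pool_counts(pl, d, noise_model(), seed = 6)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_pool_counts(pcm, f)
  back <- read_pool_counts(f, d)
  expect_equal(unname(back$counts), unname(pcm$counts))
  expect_equal(back$sites$position, pcm$sites$position)
  d_wrong <- pooling_design(3, 3, 4, 6)
  expect_error(read_pool_counts(f, d_wrong), "do not match")
})
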