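test_that("axis profiles partition a pool row by axis and compute SNR", {
  d <- pooling_design(19, 19, 8, 12)
  row <- stats::setNames(numeric(58), design_pools(d))
  prof <- axis_profiles(row, d)
  expect_equal(lengths(lapply(prof, `[[`, "counts")),
               c(WELL_COL = 12, WELL_ROW = 8, PLATE_COL = 19,
                 PLATE_ROW = 19))
  expect_true(all(vapply(prof, `[[`, numeric(1), "top") == 0))
  expect_true(all(vapply(prof, `[[`, numeric(1), "snr") == 0))

  row["WC01"] <- 450; row["WC02"] <- 30
  prof <- axis_profiles(row, d)
  expect_equal(prof$WELL_COL$top_coord, 1L)
  expect_equal(prof$WELL_COL$second, 30)
  expect_equal(prof$WELL_COL$snr, 15)
  expect_error(axis_profiles(numeric(10), d), "row length")
})

test_that("resolve_axis applies primary and secondary thresholds", {
  d <- pooling_design(19, 19, 8, 12)
  cfg <- deconvolution_config()   # 50 reads, SNR 9
  prof_of <- function(wc) axis_profiles(row_from_axes(d, wc = wc),
                                        d)$WELL_COL

  r <- resolve_axis(prof_of(c(450, 30)), cfg)
  expect_true(r$resolved)
  expect_equal(r$coordinate, 1L)

  r <- resolve_axis(prof_of(c(450, 60)), cfg)        # snr 7.5 < 9
  expect_false(r$resolved)
  expect_equal(r$candidates, c(1L, 2L))              # 60 >= max(10, 50)

  r <- resolve_axis(prof_of(c(40, 3)), cfg)          # top < 50
  expect_false(r$resolved)
  expect_equal(r$candidates, 1L)                     # 3 < floor 10

  r <- resolve_axis(prof_of(c(500)), cfg)            # second = 0: snr Inf
  expect_true(r$resolved)

  r <- resolve_axis(prof_of(c(400, 400)), cfg)       # exact tie
  expect_false(r$resolved)
  expect_equal(r$candidates, c(1L, 2L))
})

test_that("first pass recovers a noise-free library and flags duplicates", {
  ref <- tiny_reference(seed = 41)
  d <- tiny_design()
  pl <- simulate_picking(ref, d, 60, duplicate_rate = 0, seed = 8)
  pcm <- simulate_pool_counts(pl, d, noise_free(), seed = 10)
  res <- assign_first_pass(pcm, d)
  expect_true(all(res$table$status == "auto"))
  acc <- assignment_accuracy(res, pl)
  expect_equal(acc$n_correct, nrow(pl$sites))

  # a clone in two wells differing on every axis is multilocated
  wells <- data.frame(plate_row = c(1, 2), plate_col = c(1, 2),
                      well_row = c("A", "B"), well_col = c(1, 2),
                      site_id = "site_00001")
  dup <- structure(list(sites = data.frame(site_id = "site_00001",
                                           position = 100, strand = "+"),
                        wells = wells, seed = 1),
                   class = "truth_placement")
  pcm2 <- simulate_pool_counts(dup, d, noise_free(), seed = 3)
  res2 <- assign_first_pass(pcm2, d)
  expect_equal(res2$table$status, "multilocated")

  # empty matrix in, empty assignment out
  empty <- pcm_from_rows(list(), tiny_design())
  expect_equal(nrow(assign_first_pass(empty, tiny_design())$table), 0)
})

test_that("conflicting auto assignments are demoted to ambiguous", {
  d <- tiny_design()
  same_well <- row_from_axes(d, wc = 500, wr = 500, pc = 500, pr = 500)
  pcm <- pcm_from_rows(list(same_well, same_well), d)
  res <- assign_first_pass(pcm, d)
  expect_equal(res$table$status, c("ambiguous", "ambiguous"))
  expect_true(all(is.na(res$table$well_col)))
})

test_that("triangulation places a site the first pass could not", {
  d <- tiny_design()
  # X: clean signal at (PR1, PC1, A, 1)
  x <- row_from_axes(d, wc = 500, wr = 500, pc = 500, pr = 500)
  # Y: resolved on WR/PC/PR but WELL_COL splits between coords 1 and 2
  y <- row_from_axes(d, wc = c(450, 60), wr = 400, pc = 400, pr = 400)
  pcm <- pcm_from_rows(list(x, y), d)
  first <- assign_first_pass(pcm, d)
  expect_equal(first$table$status, c("auto", "unresolved"))
  res <- triangulate(first)
  expect_equal(res$table$status, c("auto", "triangulated"))
  expect_equal(res$table$well_col, c(1L, 2L))
  expect_equal(res$table$well_row, c("A", "A"))
  # oracle agrees on this fixture
  expect_oracle_equal(res, brute_force_oracle(pcm, d))
})

test_that("symmetric candidates stay ambiguous; fixpoint is stable", {
  d <- tiny_design()
  y <- row_from_axes(d, wc = c(450, 60), wr = 400, pc = 400, pr = 400)
  pcm <- pcm_from_rows(list(y, y), d)
  res <- deconvolve(pcm, d)
  expect_equal(res$table$status, c("ambiguous", "ambiguous"))
  # no unresolved sites: triangulate is the identity
  d2 <- tiny_design()
  x <- row_from_axes(d2, wc = 500, wr = 500, pc = 500, pr = 500)
  one <- assign_first_pass(pcm_from_rows(list(x), d2), d2)
  expect_equal(triangulate(one)$table, one$table)
  # oracle agrees
  expect_oracle_equal(res, brute_force_oracle(pcm, d))
})

test_that("pipeline equals the brute-force oracle on random noisy instances", {
  d <- pooling_design(3, 3, 4, 6)
  ref <- generate_reference(40, seed = 101)
  for (seed in 1:25) {
    pl <- simulate_picking(ref, d, 70, duplicate_rate = 0.2, seed = seed)
    pcm <- simulate_pool_counts(
      pl, d, noise_model(epsilon = 0.02, lambda = 40, dropout = 0.05),
      seed = seed)
    res <- deconvolve(pcm, d)
    expect_oracle_equal(res, brute_force_oracle(pcm, d))
  }
  expect_error(brute_force_oracle(pcm, pooling_design(5, 5, 4, 6)),
               "refuses")
})

test_that("assigned wells are always distinct and triangulation only grows
           the assignment", {
  d <- pooling_design(3, 3, 4, 6)
  ref <- generate_reference(40, seed = 103)
  for (seed in 1:10) {
    pl <- simulate_picking(ref, d, 80, duplicate_rate = 0.3, seed = seed)
    pcm <- simulate_pool_counts(
      pl, d, noise_model(epsilon = 0.03, lambda = 30, dropout = 0.05),
      seed = seed)
    first <- assign_first_pass(pcm, d)
    res <- triangulate(first)
    placed <- res$table[res$table$status %in% c("auto", "triangulated"), ]
    keys <- paste(placed$plate_row, placed$plate_col, placed$well_row,
                  placed$well_col)
    expect_equal(anyDuplicated(keys), 0L)
    auto_before <- first$table$site_id[first$table$status == "auto"]
    auto_after <- res$table$site_id[res$table$status == "auto"]
    expect_identical(auto_before, auto_after)
    expect_gte(nrow(placed), length(auto_before))
  }
})

test_that("raising the SNR threshold never adds auto assignments", {
  d <- pooling_design(3, 3, 4, 6)
  ref <- generate_reference(40, seed = 107)
  pl <- simulate_picking(ref, d, 80, duplicate_rate = 0.2, seed = 1)
  pcm <- simulate_pool_counts(
    pl, d, noise_model(epsilon = 0.05, lambda = 60, dropout = 0.02),
    seed = 1)
  n_auto <- vapply(c(2, 5, 9, 20, 50), function(s) {
    cfg <- deconvolution_config(snr_threshold = s)
    sum(assign_first_pass(pcm, d, cfg)$table$status == "auto")
  }, numeric(1))
  expect_true(all(diff(n_auto) <= 0))
})

test_that("counts-per-million mode rescales before thresholding", {
  d <- tiny_design()
  x <- row_from_axes(d, wc = 20, wr = 20, pc = 20, pr = 20)  # below 50 raw
  pcm <- pcm_from_rows(list(x), d)
  raw <- assign_first_pass(pcm, d)
  expect_equal(raw$table$status, "unresolved")
  cpm <- assign_first_pass(pcm, d, deconvolution_config(cpm = TRUE))
  expect_equal(cpm$table$status, "auto")  # each pool scaled to 1e6
})
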