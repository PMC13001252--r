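#' Deconvolution thresholds
#'
#' Pool-count deconvolution resolves each insertion's four coordinates by a
#' primary threshold on the absolute read count of the top coordinate of
#' each axis and a secondary threshold on the signal-to-noise ratio (SNR):
#' the top count divided by the next-highest count on that axis.  The
#' defaults (50 reads, SNR 9) are the operating point used to build the
#' library this package models.
#'
#' @param primary_threshold Minimum top read count per axis (>= 1).
#' @param snr_threshold Minimum top/second ratio (> 1).
#' @param candidate_floor Minimum count for a coordinate to remain a
#'   triangulation candidate on an unresolved axis (must not exceed
#'   `primary_threshold`).
#' @param max_rounds Iteration cap for triangulation.
#' @param cpm If `TRUE`, scale each pool column to counts-per-million before
#'   thresholding.  Off by default: thresholds apply to absolute counts.
#' @return Object of class `deconvolution_config`.
#' @export
deconvolution_config <- function(primary_threshold = 50, snr_threshold = 9,
                                 candidate_floor = 10, max_rounds = 100,
                                 cpm = FALSE) {
  stopifnot(primary_threshold >= 1, snr_threshold > 1,
            candidate_floor <= primary_threshold, max_rounds >= 1)
  structure(list(primary_threshold = primary_threshold,
                 snr_threshold = snr_threshold,
                 candidate_floor = candidate_floor,
                 max_rounds = max_rounds, cpm = cpm),
            class = "deconvolution_config")
}

# Column indices of each axis within the pool-ordered count matrix.
.axis_columns <- function(design) {
  ax <- design_pool_axes(design)
  lapply(stats::setNames(nm = names(design$pools)), function(a) which(ax == a))
}

# Row-wise top value, top index and second-highest value of a matrix.
.axis_top2 <- function(sub) {
  n <- nrow(sub)
  top <- rep(-Inf, n); second <- rep(-Inf, n); idx <- rep(NA_integer_, n)
  for (j in seq_len(ncol(sub))) {
    v <- sub[, j]
    newmax <- v > top
    second <- ifelse(newmax, top, pmax(second, v))
    idx[newmax] <- j
    top <- pmax(top, v)
  }
  second <- pmax(second, 0)
  list(top = top, idx = idx, second = second)
}

.snr <- function(top, second) {
  ifelse(top <= 0, 0, ifelse(second <= 0, Inf, top / second))
}

#' Per-axis count profiles of one insertion's pool row
#'
#' Partitions a row of the pool count matrix into the four coordinate axes
#' and computes, for each, the top coordinate, its count, the next-highest
#' count, and their ratio (SNR; defined as `Inf` when the second count is 0
#' and the top is positive, and 0 when the top is 0).
#'
#' @param row Numeric vector of counts, one per pool of `design`, in the
#'   design's pool order (names, if present, are checked).
#' @param design A [pooling_design()].
#' @return Named list of four `axis_profile` objects (`WELL_COL`,
#'   `WELL_ROW`, `PLATE_COL`, `PLATE_ROW`), each with `axis`, `counts`,
#'   `top_coord`, `top`, `second`, `snr`.
#' @export
axis_profiles <- function(row, design) {
  pools <- design_pools(design)
  if (length(row) != length(pools))
    stop("input error: row length does not match the design's pool count")
  if (!is.null(names(row)) && !identical(names(row), pools))
    row <- row[pools]
  cols <- .axis_columns(design)
  lapply(stats::setNames(nm = names(cols)), function(a) {
    counts <- as.numeric(row[cols[[a]]])
    t2 <- .axis_top2(matrix(counts, nrow = 1))
    structure(list(axis = a, counts = stats::setNames(counts, pools[cols[[a]]]),
                   top_coord = t2$idx, top = t2$top,
                   second = t2$second, snr = .snr(t2$top, t2$second)),
              class = "axis_profile")
  })
}

#' Resolve one axis or return its candidate coordinates
#'
#' An axis is resolved when its top count meets the primary threshold and
#' its SNR meets the secondary threshold (an exact tie between the two
#' highest counts gives SNR 1 and is never resolved).  Otherwise the axis
#' contributes a candidate set: every coordinate whose count is at least
#' `max(candidate_floor, top / snr_threshold)`.  A resolved axis's candidate
#' set is the singleton top coordinate.
#'
#' @param profile An `axis_profile` from [axis_profiles()].
#' @param config A [deconvolution_config()].
#' @return List with `resolved` (logical), `coordinate` (integer or `NA`),
#'   `candidates` (integer vector).
#' @export
resolve_axis <- function(profile, config) {
  resolved <- profile$top >= config$primary_threshold &&
    .snr(profile$top, profile$second) >= config$snr_threshold
  if (resolved)
    return(list(resolved = TRUE, coordinate = profile$top_coord,
                candidates = profile$top_coord))
  floor_c <- max(config$candidate_floor,
                 profile$top / config$snr_threshold)
  list(resolved = FALSE, coordinate = NA_integer_,
       candidates = unname(which(profile$counts >= floor_c)))
}

# well key helpers: a well is encoded "pr.pc.wr.wc"
.well_key <- function(pr, pc, wr, wc) paste(pr, pc, wr, wc, sep = ".")

#' First-pass assignment by thresholding
#'
#' Applies [resolve_axis()] to all four axes of every insertion.  Sites with
#' all four axes resolved become `auto`, their well the intersection of the
#' four coordinates.  Sites where two or more axes each have two or more
#' coordinates at or above the primary threshold are flagged `multilocated`
#' (duplicate clones occupying several wells) and excluded from well
#' assignment.  Remaining sites are `unresolved` and keep per-axis candidate
#' sets for triangulation.  Two `auto` sites claiming the same well are both
#' demoted to `ambiguous`.
#'
#' @param pcm A `pool_count_matrix`.
#' @param design A [pooling_design()] matching the matrix's pools.
#' @param config A [deconvolution_config()].
#' @return Object of class `tn_assignments`: list with `table` (one row per
#'   site: `site_id`, `position`, `strand`, `status`, well columns, per-axis
#'   `snr_*`, `total_reads`), `candidates` (per-site list of axis candidate
#'   sets for unresolved sites), `design`, `config`.
#' @export
assign_first_pass <- function(pcm, design, config = deconvolution_config()) {
  stopifnot(inherits(pcm, "pool_count_matrix"),
            inherits(design, "pooling_design"),
            inherits(config, "deconvolution_config"))
  pools <- design_pools(design)
  if (!identical(pcm$pools, pools))
    stop("input error: count matrix pools do not match the design")
  M <- pcm$counts
  if (config$cpm && nrow(M) > 0) {
    tot <- pmax(colSums(M), 1)
    M <- sweep(M, 2, 1e6 / tot, "*")
  }
  n <- nrow(M)
  cols <- .axis_columns(design)
  axes <- names(cols)

  stat <- lapply(cols, function(ix) .axis_top2(M[, ix, drop = FALSE]))
  snr <- lapply(stat, function(s) .snr(s$top, s$second))
  resolved <- mapply(function(s, r)
    s$top >= config$primary_threshold & r >= config$snr_threshold,
    stat, snr, SIMPLIFY = FALSE)
  n_ge_T <- lapply(cols, function(ix)
    rowSums(M[, ix, drop = FALSE] >= config$primary_threshold))

  all_resolved <- Reduce(`&`, resolved)
  multi_axes <- Reduce(`+`, lapply(n_ge_T, function(x) as.integer(x >= 2)))
  status <- rep("unresolved", n)
  status[all_resolved] <- "auto"
  status[!all_resolved & multi_axes >= 2] <- "multilocated"

  well <- data.frame(plate_row = rep(NA_integer_, n),
                     plate_col = rep(NA_integer_, n),
                     well_row_i = rep(NA_integer_, n),
                     well_col = rep(NA_integer_, n))
  auto <- which(status == "auto")
  well$well_col[auto] <- stat$WELL_COL$idx[auto]
  well$well_row_i[auto] <- stat$WELL_ROW$idx[auto]
  well$plate_col[auto] <- stat$PLATE_COL$idx[auto]
  well$plate_row[auto] <- stat$PLATE_ROW$idx[auto]

  # auto wells must sit on occupied plates and be claimed only once
  if (length(auto)) {
    on_grid <- paste(well$plate_row[auto], well$plate_col[auto]) %in%
      paste(design$plates$plate_row, design$plates$plate_col)
    keys <- .well_key(well$plate_row[auto], well$plate_col[auto],
                      well$well_row_i[auto], well$well_col[auto])
    dup <- keys %in% keys[duplicated(keys)]
    bad <- !on_grid | dup
    if (any(bad)) {
      status[auto[bad]] <- "ambiguous"
      well[auto[bad], ] <- NA_integer_
    }
  }

  # candidate sets for unresolved sites (resolved axes give singletons)
  candidates <- vector("list", n)
  floor_base <- config$candidate_floor
  for (i in which(status == "unresolved")) {
    candidates[[i]] <- lapply(stats::setNames(nm = axes), function(a) {
      if (resolved[[a]][i]) return(stat[[a]]$idx[i])
      v <- M[i, cols[[a]]]
      which(v >= max(floor_base, stat[[a]]$top[i] / config$snr_threshold))
    })
  }

  tab <- data.frame(
    site_id = if (is.null(pcm$sites$site_id)) rownames(M) else
      pcm$sites$site_id,
    position = if (is.null(pcm$sites$position)) NA_integer_ else
      pcm$sites$position,
    strand = if (is.null(pcm$sites$strand)) NA_character_ else
      pcm$sites$strand,
    status = status,
    plate_row = well$plate_row, plate_col = well$plate_col,
    well_row = ifelse(is.na(well$well_row_i), NA_character_,
                      LETTERS[well$well_row_i]),
    well_col = well$well_col,
    snr_wc = snr$WELL_COL, snr_wr = snr$WELL_ROW,
    snr_pc = snr$PLATE_COL, snr_pr = snr$PLATE_ROW,
    total_reads = if (n > 0) rowSums(pcm$counts) else numeric(0),
    stringsAsFactors = FALSE)
  structure(list(table = tab, candidates = candidates, design = design,
                 config = config),
            class = "tn_assignments")
}

# deterministic processing order: descending total reads, ties by site_id
.site_order <- function(tab, idx) {
  idx[order(-tab$total_reads[idx], tab$site_id[idx])]
}

#' Triangulate unresolved insertions against occupied wells
#'
#' Iteratively places unresolved sites: a site's candidate wells are the
#' Cartesian product of its per-axis candidate sets, restricted to occupied
#' plates and excluding wells already claimed by `auto` or `triangulated`
#' sites.  When exactly one candidate well remains, the site is placed
#' (`triangulated`) and its well eliminated for everyone else.  Rounds
#' repeat until a full pass adds nothing or `max_rounds` is reached (then a
#' warning).  Sites are processed in descending total-read order, ties
#' broken by `site_id`, so the outcome is deterministic.  Sites left with
#' two or more candidate wells end `ambiguous`; others stay `unresolved`.
#'
#' @param x A `tn_assignments` from [assign_first_pass()].
#' @return The updated `tn_assignments`.
#' @export
triangulate <- function(x) {
  stopifnot(inherits(x, "tn_assignments"))
  tab <- x$table
  design <- x$design
  config <- x$config
  plate_ok <- paste(design$plates$plate_row, design$plates$plate_col)

  assigned <- which(tab$status %in% c("auto", "triangulated"))
  occupied <- new.env(hash = TRUE)
  for (i in assigned)
    occupied[[.well_key(tab$plate_row[i], tab$plate_col[i],
                        match(tab$well_row[i], LETTERS),
                        tab$well_col[i])]] <- TRUE

  viable_wells <- function(i) {
    cs <- x$candidates[[i]]
    if (any(lengths(cs) == 0)) return(NULL)
    wells <- expand.grid(wc = cs$WELL_COL, wr = cs$WELL_ROW,
                         pc = cs$PLATE_COL, pr = cs$PLATE_ROW)
    wells <- wells[paste(wells$pr, wells$pc) %in% plate_ok, , drop = FALSE]
    if (nrow(wells) == 0) return(NULL)
    keys <- .well_key(wells$pr, wells$pc, wells$wr, wells$wc)
    free <- !vapply(keys, function(k) isTRUE(occupied[[k]]), logical(1))
    wells[free, , drop = FALSE]
  }

  pending <- .site_order(tab, which(tab$status == "unresolved"))
  round <- 0L
  repeat {
    round <- round + 1L
    changed <- FALSE
    for (i in pending) {
      if (tab$status[i] != "unresolved") next
      w <- viable_wells(i)
      if (!is.null(w) && nrow(w) == 1) {
        tab$status[i] <- "triangulated"
        tab$plate_row[i] <- w$pr; tab$plate_col[i] <- w$pc
        tab$well_row[i] <- LETTERS[w$wr]; tab$well_col[i] <- w$wc
        occupied[[.well_key(w$pr, w$pc, w$wr, w$wc)]] <- TRUE
        changed <- TRUE
      }
    }
    pending <- pending[tab$status[pending] == "unresolved"]
    if (!changed || length(pending) == 0) break
    if (round >= config$max_rounds) {
      warning("triangulation stopped at max_rounds with pending changes")
      break
    }
  }
  for (i in pending) {
    w <- viable_wells(i)
    if (!is.null(w) && nrow(w) >= 2) tab$status[i] <- "ambiguous"
  }
  x$table <- tab
  x
}

#' Deconvolve a pool count matrix into well assignments
#'
#' Runs [assign_first_pass()] followed by [triangulate()].
#'
#' @inheritParams assign_first_pass
#' @return A `tn_assignments` object.
#' @examples
#' d <- pooling_design(2, 2, 2, 3)
#' pl <- simulate_picking(generate_reference(20, seed = 1), d, 12,
#'                        duplicate_rate = 0, seed = 1)
#' pcm <- simulate_pool_counts(pl, d, noise_free(), seed = 1)
#' deconvolve(pcm, d)
#' @export
deconvolve <- function(pcm, design, config = deconvolution_config()) {
  triangulate(assign_first_pass(pcm, design, config))
}

#' @export
print.tn_assignments <- function(x, ...) {
  tab <- table(factor(x$table$status,
                      c("auto", "triangulated", "ambiguous", "multilocated",
                        "unresolved")))
  cat(sprintf("Deconvolution of %d insertion sites:\n", nrow(x$table)))
  for (s in names(tab))
    cat(sprintf("  %-12s %6d (%s%%)\n", s, tab[[s]],
                format(percent_of(tab[[s]], max(nrow(x$table), 1)),
                       nsmall = 1)))
  invisible(x)
}

#' @export
summary.tn_assignments <- function(object, ...) {
  tab <- object$table
  placed <- tab$status %in% c("auto", "triangulated")
  out <- list(n_sites = nrow(tab),
              status = table(tab$status),
              n_placed = sum(placed),
              pct_placed = percent_of(sum(placed), max(nrow(tab), 1)))
  class(out) <- "summary.tn_assignments"
  out
}

#' @export
print.summary.tn_assignments <- function(x, ...) {
  cat(sprintf("%d sites, %d placed (%.1f%%)\n", x$n_sites, x$n_placed,
              x$pct_placed))
  print(x$status)
  invisible(x)
}

#' Write deconvolution assignments as TSV
#'
#' @param x A `tn_assignments`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(x, path) {
  stopifnot(inherits(x, "tn_assignments"))
  utils::write.table(x$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Brute-force deconvolution oracle by well enumeration
#'
#' Independent re-derivation of the deconvolution result for small designs:
#' every well of the design is enumerated, a well is consistent for a site
#' iff each of its four coordinates lies in that axis's candidate set
#' (computed from the raw counts with the same threshold rules), and the
#' unique-elimination fixpoint is applied by re-scanning all wells each
#' time.  Must agree exactly with [deconvolve()]; used as a property-test
#' oracle.
#'
#' @inheritParams assign_first_pass
#' @return A data frame like the `table` component of `tn_assignments`
#'   (columns `site_id`, `status`, `plate_row`, `plate_col`, `well_row`,
#'   `well_col`).
#' @export
brute_force_oracle <- function(pcm, design, config = deconvolution_config()) {
  if (design$grid_rows * design$grid_cols > 16)
    stop("oracle refuses designs larger than a 4x4 plate grid")
  M <- pcm$counts
  if (config$cpm && nrow(M) > 0) {
    tot <- pmax(colSums(M), 1)
    M <- sweep(M, 2, 1e6 / tot, "*")
  }
  n <- nrow(M)
  # axis column ranges, re-derived from first principles
  k <- c(design$plate_cols, design$plate_rows, design$grid_cols,
         design$grid_rows)
  off <- cumsum(c(0, k[-4]))
  axis_counts <- function(i, a) M[i, off[a] + seq_len(k[a])]

  cand <- vector("list", n)       # per site: list of 4 integer vectors
  resolved4 <- matrix(FALSE, n, 4)
  for (i in seq_len(n)) {
    cand[[i]] <- vector("list", 4)
    for (a in 1:4) {
      v <- axis_counts(i, a)
      top <- max(v, 0)
      second <- if (length(v) > 1) sort(v, decreasing = TRUE)[2] else 0
      snr <- if (top <= 0) 0 else if (second <= 0) Inf else top / second
      if (top >= config$primary_threshold && snr >= config$snr_threshold) {
        resolved4[i, a] <- TRUE
        cand[[i]][[a]] <- which.max(v)
      } else {
        cand[[i]][[a]] <- which(v >= max(config$candidate_floor,
                                         top / config$snr_threshold))
      }
    }
  }

  status <- rep("unresolved", n)
  for (i in seq_len(n)) {
    if (all(resolved4[i, ])) status[i] <- "auto"
    else {
      m <- 0
      for (a in 1:4)
        if (sum(axis_counts(i, a) >= config$primary_threshold) >= 2)
          m <- m + 1
      if (m >= 2) status[i] <- "multilocated"
    }
  }

  # full well enumeration
  wells <- expand.grid(wc = seq_len(k[1]), wr = seq_len(k[2]),
                       pc = seq_len(k[3]), pr = seq_len(k[4]))
  wells <- wells[paste(wells$pr, wells$pc) %in%
                   paste(design$plates$plate_row, design$plates$plate_col), ]
  wkey <- paste(wells$pr, wells$pc, wells$wr, wells$wc)

  pr <- pc <- wr <- wc <- rep(NA_integer_, n)
  for (i in which(status == "auto")) {
    wc[i] <- cand[[i]][[1]]; wr[i] <- cand[[i]][[2]]
    pc[i] <- cand[[i]][[3]]; pr[i] <- cand[[i]][[4]]
  }
  auto <- which(status == "auto")
  if (length(auto)) {
    keys <- paste(pr[auto], pc[auto], wr[auto], wc[auto])
    bad <- !(keys %in% wkey) | keys %in% keys[duplicated(keys)]
    if (any(bad)) {
      status[auto[bad]] <- "ambiguous"
      pr[auto[bad]] <- pc[auto[bad]] <- wr[auto[bad]] <- wc[auto[bad]] <-
        NA_integer_
    }
  }

  consistent <- function(i) {
    m <- wells$wc %in% cand[[i]][[1]] & wells$wr %in% cand[[i]][[2]] &
      wells$pc %in% cand[[i]][[3]] & wells$pr %in% cand[[i]][[4]]
    which(m)
  }
  occupied <- character(0)
  for (i in which(status %in% c("auto", "triangulated")))
    occupied <- c(occupied, paste(pr[i], pc[i], wr[i], wc[i]))
  total <- if (n > 0) rowSums(pcm$counts) else numeric(0)
  ids <- if (is.null(pcm$sites$site_id)) rownames(M) else pcm$sites$site_id
  pend <- which(status == "unresolved")
  pend <- pend[order(-total[pend], ids[pend])]
  rounds <- 0L
  repeat {
    rounds <- rounds + 1L
    changed <- FALSE
    for (i in pend) {
      if (status[i] != "unresolved") next
      vi <- consistent(i)
      vi <- vi[!(wkey[vi] %in% occupied)]
      if (length(vi) == 1) {
        status[i] <- "triangulated"
        wc[i] <- wells$wc[vi]; wr[i] <- wells$wr[vi]
        pc[i] <- wells$pc[vi]; pr[i] <- wells$pr[vi]
        occupied <- c(occupied, wkey[vi])
        changed <- TRUE
      }
    }
    pend <- pend[status[pend] == "unresolved"]
    if (!changed || length(pend) == 0 || rounds >= config$max_rounds) break
  }
  for (i in pend) {
    vi <- consistent(i)
    vi <- vi[!(wkey[vi] %in% occupied)]
    if (length(vi) >= 2) status[i] <- "ambiguous"
  }
  data.frame(site_id = ids, status = status,
             plate_row = pr, plate_col = pc,
             well_row = ifelse(is.na(wr), NA_character_, LETTERS[wr]),
             well_col = wc, stringsAsFactors = FALSE)
}

#' Score assignments against a simulated ground truth
#'
#' A placed (`auto` or `triangulated`) site is correct when its assigned
#' well is one of the wells the truth placement put that clone in.
#'
#' @param x A `tn_assignments` (or its `table`).
#' @param placement The [simulate_picking()] truth.
#' @return List with `n_sites`, `n_placed`, `n_correct`, `pct_correct`
#'   (of placed) and `pct_sites_correct` (of all sites).
#' @export
assignment_accuracy <- function(x, placement) {
  tab <- if (inherits(x, "tn_assignments")) x$table else x
  truth_key <- paste(placement$wells$site_id, placement$wells$plate_row,
                     placement$wells$plate_col, placement$wells$well_row,
                     placement$wells$well_col)
  placed <- tab$status %in% c("auto", "triangulated")
  got_key <- paste(tab$site_id, tab$plate_row, tab$plate_col, tab$well_row,
                   tab$well_col)
  correct <- placed & got_key %in% truth_key
  list(n_sites = nrow(tab), n_placed = sum(placed),
       n_correct = sum(correct),
       pct_correct = percent_of(sum(correct), max(sum(placed), 1)),
       pct_sites_correct = percent_of(sum(correct), max(nrow(tab), 1)))
}
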