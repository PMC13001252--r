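#' Combinatorial pooling design for an ordered transposon library
#'
#' A pooling design arranges 96-well (or other rectangular) plates into a
#' higher-order grid of `grid_rows` x `grid_cols` plates and pools the wells
#' along four axes: well columns (pooled across all plates), well rows,
#' plate columns and plate rows of the higher-order grid.  Sequencing each
#' pool then identifies every mutant from four coordinates, one per axis.
#'
#' Pool identifiers are deterministic and axis-tagged: `WC01..WCnn` for well
#' columns, `WRA..` for well rows (alphabetic, as on a microtiter plate),
#' `PC01..` for plate columns and `PR01..` for plate rows.  The total pool
#' count is the sum of the four axis sizes (58 for a 19x19 grid of 96-well
#' plates) and the well capacity is their product (34,656 for that geometry).
#'
#' Partial grids are supported through `plates`: a data frame of occupied
#' `(plate_row, plate_col)` positions.  Pools belonging to absent plates
#' simply receive no members; capacity counts occupied plates only.
#'
#' @param grid_rows Number of plate rows in the higher-order array.
#' @param grid_cols Number of plate columns in the higher-order array.
#' @param plate_rows Well rows per plate (labelled `A`, `B`, ...; at most 26).
#' @param plate_cols Well columns per plate (numeric labels).
#' @param plates Optional data frame with columns `plate_row`, `plate_col`
#'   listing occupied plate positions; defaults to the full grid.
#' @return An object of class `pooling_design`.
#' @examples
#' d <- pooling_design(19, 19, 8, 12)
#' design_capacity(d)        # 34656
#' length(design_pools(d))   # 58
#' @export
pooling_design <- function(grid_rows, grid_cols, plate_rows = 8L,
                           plate_cols = 12L, plates = NULL) {
  dims <- c(grid_rows = grid_rows, grid_cols = grid_cols,
            plate_rows = plate_rows, plate_cols = plate_cols)
  if (any(!is.finite(dims)) || any(dims < 1) || any(dims != floor(dims)))
    stop("invalid design: all dimensions must be positive integers")
  if (plate_rows > 26L)
    stop("invalid design: at most 26 well rows (alphabetic labels)")
  storage.mode(dims) <- "integer"

  pools_wc <- sprintf("WC%02d", seq_len(dims[["plate_cols"]]))
  pools_wr <- paste0("WR", LETTERS[seq_len(dims[["plate_rows"]])])
  pools_pc <- sprintf("PC%02d", seq_len(dims[["grid_cols"]]))
  pools_pr <- sprintf("PR%02d", seq_len(dims[["grid_rows"]]))

  if (is.null(plates)) {
    plates <- expand.grid(plate_col = seq_len(dims[["grid_cols"]]),
                          plate_row = seq_len(dims[["grid_rows"]]))[, 2:1]
  } else {
    plates <- as.data.frame(plates)
    stopifnot(all(c("plate_row", "plate_col") %in% names(plates)))
    if (any(plates$plate_row < 1 | plates$plate_row > dims[["grid_rows"]] |
            plates$plate_col < 1 | plates$plate_col > dims[["grid_cols"]]))
      stop("invalid design: occupied plate outside the grid")
    if (anyDuplicated(plates[c("plate_row", "plate_col")]))
      stop("invalid design: duplicated occupied plate")
  }
  plates <- data.frame(plate_row = as.integer(plates$plate_row),
                       plate_col = as.integer(plates$plate_col))

  structure(
    list(grid_rows = dims[["grid_rows"]], grid_cols = dims[["grid_cols"]],
         plate_rows = dims[["plate_rows"]], plate_cols = dims[["plate_cols"]],
         plates = plates,
         pools = list(WELL_COL = pools_wc, WELL_ROW = pools_wr,
                      PLATE_COL = pools_pc, PLATE_ROW = pools_pr)),
    class = "pooling_design")
}

#' @export
print.pooling_design <- function(x, ...) {
  cat(sprintf("Pooling design: %d x %d grid of %d x %d well plates\n",
              x$grid_rows, x$grid_cols, x$plate_rows, x$plate_cols))
  cat(sprintf("  occupied plates: %d   capacity: %d wells   pools: %d\n",
              nrow(x$plates), design_capacity(x), length(design_pools(x))))
  invisible(x)
}

#' Pool identifiers of a design
#'
#' @param design A [pooling_design()].
#' @return Character vector of all pool identifiers, ordered by axis
#'   (well columns, well rows, plate columns, plate rows).
#' @export
design_pools <- function(design) {
  stopifnot(inherits(design, "pooling_design"))
  unlist(design$pools, use.names = FALSE)
}

#' Axis tag for each pool of a design
#'
#' @param design A [pooling_design()].
#' @return Character vector parallel to [design_pools()], each element one of
#'   `WELL_COL`, `WELL_ROW`, `PLATE_COL`, `PLATE_ROW`.
#' @export
design_pool_axes <- function(design) {
  stopifnot(inherits(design, "pooling_design"))
  rep(names(design$pools), lengths(design$pools))
}

#' Well capacity of a pooling design
#'
#' The number of distinct well addresses: occupied plates times wells per
#' plate (the product of all four dimensions for a full grid).
#'
#' @param design A [pooling_design()].
#' @return Integer well count.
#' @export
design_capacity <- function(design) {
  stopifnot(inherits(design, "pooling_design"))
  nrow(design$plates) * design$plate_rows * design$plate_cols
}

#' Validate a well address against a design
#'
#' @param design A [pooling_design()].
#' @param plate_row,plate_col Plate coordinates in the higher-order grid
#'   (1-based).
#' @param well_row Well row, as an integer or a letter label (`"A"` = 1).
#' @param well_col Well column (1-based).
#' @return A named list with integer `plate_row`, `plate_col`, `well_row`,
#'   `well_col`, of class `well_address`.
#' @export
well_address <- function(design, plate_row, plate_col, well_row, well_col) {
  stopifnot(inherits(design, "pooling_design"))
  if (is.character(well_row))
    well_row <- match(toupper(well_row), LETTERS)
  ok <- !is.na(well_row) &&
    plate_row >= 1 && plate_row <= design$grid_rows &&
    plate_col >= 1 && plate_col <= design$grid_cols &&
    well_row >= 1 && well_row <= design$plate_rows &&
    well_col >= 1 && well_col <= design$plate_cols
  if (!ok) stop("well address out of design bounds")
  structure(list(plate_row = as.integer(plate_row),
                 plate_col = as.integer(plate_col),
                 well_row = as.integer(well_row),
                 well_col = as.integer(well_col)),
            class = "well_address")
}

#' The four pools a well belongs to
#'
#' Each well belongs to exactly one pool per axis; the intersection of its
#' four pools recovers the well uniquely.
#'
#' @param design A [pooling_design()].
#' @param well A [well_address()], or a list/data-frame row with components
#'   `plate_row`, `plate_col`, `well_row`, `well_col`.
#' @return Named character vector of 4 pool identifiers
#'   (`WELL_COL`, `WELL_ROW`, `PLATE_COL`, `PLATE_ROW`).
#' @export
pools_for_well <- function(design, well) {
  if (!inherits(well, "well_address"))
    well <- well_address(design, well$plate_row, well$plate_col,
                         well$well_row, well$well_col)
  c(WELL_COL = design$pools$WELL_COL[well$well_col],
    WELL_ROW = design$pools$WELL_ROW[well$well_row],
    PLATE_COL = design$pools$PLATE_COL[well$plate_col],
    PLATE_ROW = design$pools$PLATE_ROW[well$plate_row])
}

#' Enumerate all wells of a design with their pool memberships
#'
#' Wells are listed in plate order: occupied plates (row-major across the
#' grid), then well rows, then well columns within each plate.  This is the
#' order in which colonies are picked into the array.
#'
#' @param design A [pooling_design()].
#' @return Data frame with columns `plate_row`, `plate_col`, `well_row`
#'   (letter), `well_col`, `pool_wc`, `pool_wr`, `pool_pc`, `pool_pr`.
#' @export
well_pool_table <- function(design) {
  stopifnot(inherits(design, "pooling_design"))
  pl <- design$plates[order(design$plates$plate_row, design$plates$plate_col), ]
  per <- expand.grid(well_col = seq_len(design$plate_cols),
                     well_row = seq_len(design$plate_rows))[, 2:1]
  n_per <- nrow(per)
  idx <- rep(seq_len(nrow(pl)), each = n_per)
  out <- data.frame(
    plate_row = pl$plate_row[idx],
    plate_col = pl$plate_col[idx],
    well_row = LETTERS[rep(per$well_row, nrow(pl))],
    well_col = rep(per$well_col, nrow(pl)))
  out$pool_wc <- design$pools$WELL_COL[out$well_col]
  out$pool_wr <- design$pools$WELL_ROW[match(out$well_row, LETTERS)]
  out$pool_pc <- design$pools$PLATE_COL[out$plate_col]
  out$pool_pr <- design$pools$PLATE_ROW[out$plate_row]
  out
}

#' Read/write a pooling design as a plain YAML config
#'
#' The config stores the four dimensions and, for partial grids, the list of
#' occupied plates.
#'
#' @param design A [pooling_design()].
#' @param path File path.
#' @return `read_design` returns a [pooling_design()]; `write_design` returns
#'   `path` invisibly.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "pooling_design"))
  full <- nrow(design$plates) == design$grid_rows * design$grid_cols
  cfg <- list(grid_rows = design$grid_rows, grid_cols = design$grid_cols,
              plate_rows = design$plate_rows, plate_cols = design$plate_cols)
  if (!full)
    cfg$plates <- lapply(seq_len(nrow(design$plates)), function(i)
      list(plate_row = design$plates$plate_row[i],
           plate_col = design$plates$plate_col[i]))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  cfg <- yaml::read_yaml(path)
  plates <- NULL
  if (!is.null(cfg$plates))
    plates <- do.call(rbind, lapply(cfg$plates, as.data.frame))
  pooling_design(cfg$grid_rows, cfg$grid_cols, cfg$plate_rows, cfg$plate_cols,
                 plates = plates)
}
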