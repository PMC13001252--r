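#' A crystal-violet screen plate
#'
#' Holds raw OD540 (crystal violet, i.e. surface-attached biomass) and OD660
#' (culture growth) readings for one plate replicate, plus control-well
#' designations.
#'
#' @param od540,od660 Numeric matrices of the same dimensions (conventionally
#'   8 rows `A`-`H` by 12 columns).  Dimnames default to letters/numbers.
#' @param plate_id,replicate Identifiers.
#' @param controls Character vector of control wells (e.g. `"A1"`).
#' @return Object of class `screen_plate`.
#' @export
screen_plate <- function(od540, od660, plate_id = "plate1", replicate = 1,
                         controls = character()) {
  od540 <- as.matrix(od540); od660 <- as.matrix(od660)
  if (!all(dim(od540) == dim(od660)))
    stop("od540 and od660 must have identical dimensions")
  if (any(od540 < 0, na.rm = TRUE) || any(od660 < 0, na.rm = TRUE))
    stop("OD readings must be non-negative")
  dn <- list(LETTERS[seq_len(nrow(od540))],
             as.character(seq_len(ncol(od540))))
  dimnames(od540) <- dn; dimnames(od660) <- dn
  wells <- as.vector(outer(dn[[1]], dn[[2]], paste0))
  if (!all(controls %in% wells)) stop("unknown control well")
  structure(list(od540 = od540, od660 = od660, plate_id = plate_id,
                 replicate = replicate, controls = controls),
            class = "screen_plate")
}

#' Normalize crystal-violet signal by growth
#'
#' Biofilm signal per well is OD540 / OD660; wells with OD660 of zero (no
#' measurable growth) are masked (`NA`) with a warning and excluded from all
#' downstream statistics.
#'
#' @param plate A [screen_plate()].
#' @return Numeric matrix of normalized values, `NA` for masked wells.
#' @export
normalize_plate <- function(plate) {
  stopifnot(inherits(plate, "screen_plate"))
  bad <- plate$od660 <= 0
  if (any(bad))
    warning(sprintf("%d well(s) masked: OD660 is zero", sum(bad)))
  out <- plate$od540 / plate$od660
  out[bad] <- NA_real_
  out
}

#' Call biofilm hits by the plate-relative fold rule
#'
#' For each well, the replicate-averaged normalized value `m` is compared
#' with the plate mean `mu` (computed per replicate over unmasked wells,
#' then averaged across replicates): `increased` if `m >= fold * mu`,
#' `decreased` if `m <= mu / fold`, otherwise `none`.  The default 1.5-fold
#' rule is the screening threshold this package models.
#'
#' @param plates List of [screen_plate()] replicates with identical layouts.
#' @param fold Fold-change threshold (> 1).
#' @param exclude_controls Exclude designated control wells from the plate
#'   mean (default) — they are still called.
#' @param well_map Optional data frame `well`, `mutant` mapping wells to
#'   mutant identifiers.
#' @return Data frame with `well`, (`mutant`,) `value`, `plate_mean`,
#'   `fold_change` (`value / plate_mean`), `direction`.
#' @export
call_fold_hits <- function(plates, fold = 1.5, exclude_controls = TRUE,
                           well_map = NULL) {
  if (inherits(plates, "screen_plate")) plates <- list(plates)
  if (length(plates) < 1) stop("at least one replicate plate is required")
  if (fold <= 1) stop("fold must be > 1")
  norm <- lapply(plates, normalize_plate)
  dn <- dimnames(norm[[1]])
  wells <- as.vector(outer(dn[[1]], dn[[2]], paste0))
  ctrl <- unique(unlist(lapply(plates, `[[`, "controls")))
  in_mean <- matrix(TRUE, nrow(norm[[1]]), ncol(norm[[1]]), dimnames = dn)
  if (exclude_controls && length(ctrl))
    in_mean[match(ctrl, wells)] <- FALSE
  mu_r <- vapply(norm, function(m) mean(m[in_mean], na.rm = TRUE),
                 numeric(1))
  mu <- mean(mu_r)
  stack <- simplify2array(norm)            # rows x cols x reps
  m <- apply(stack, c(1, 2), function(v)
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  if (is.na(mu) || mu <= 0) return(data.frame())
  out <- data.frame(well = wells, value = as.vector(m),
                    plate_mean = mu,
                    fold_change = as.vector(m) / mu)
  out$direction <- ifelse(is.na(out$value), NA_character_,
                          ifelse(out$value >= fold * mu, "increased",
                                 ifelse(out$value <= mu / fold, "decreased",
                                        "none")))
  out <- out[!is.na(out$value), , drop = FALSE]
  if (!is.null(well_map))
    out$mutant <- well_map$mutant[match(out$well, well_map$well)]
  rownames(out) <- NULL
  out
}

#' Unpaired t-test of a mutant against the control
#'
#' Two-sided unpaired t-test of replicate measurements; classic pooled-
#' variance form by default, Welch's unequal-variance form on request.
#'
#' @param mutant,control Numeric vectors of replicate values (>= 2 each).
#' @param welch Use Welch's correction instead of pooled variance.
#' @return List with `t`, `df`, `p`.
#' @export
ttest_vs_control <- function(mutant, control, welch = FALSE) {
  if (length(mutant) < 2 || length(control) < 2)
    stop("at least 2 values per group are required")
  res <- stats::t.test(mutant, control, var.equal = !welch)
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Screen a fold-rule hit table with significance tests
#'
#' Runs [ttest_vs_control()] for each candidate well's replicate values
#' against the control values, optionally adjusting p-values.
#'
#' @param plates List of [screen_plate()] replicates.
#' @param control_wells Wells whose replicate values form the control group.
#' @param fold Fold threshold for [call_fold_hits()].
#' @param welch See [ttest_vs_control()].
#' @param adjust `"none"` (default) or any method of [stats::p.adjust()].
#' @param well_map Optional well-to-mutant map.
#' @return The [call_fold_hits()] table with added `t` and `p` columns
#'   (and `p_adj` when `adjust != "none"`).
#' @export
screen_hits <- function(plates, control_wells, fold = 1.5, welch = FALSE,
                        adjust = "none", well_map = NULL) {
  if (inherits(plates, "screen_plate")) plates <- list(plates)
  hits <- call_fold_hits(plates, fold = fold, well_map = well_map)
  norm <- lapply(plates, normalize_plate)
  dn <- dimnames(norm[[1]])
  wells <- as.vector(outer(dn[[1]], dn[[2]], paste0))
  values_of <- function(w) {
    i <- match(w, wells)
    v <- vapply(norm, function(m) m[i], numeric(1))
    v[!is.na(v)]
  }
  ctrl_vals <- unlist(lapply(control_wells, values_of))
  hits$t <- NA_real_; hits$p <- NA_real_
  for (r in seq_len(nrow(hits))) {
    v <- values_of(hits$well[r])
    if (length(v) >= 2 && length(ctrl_vals) >= 2) {
      tt <- ttest_vs_control(v, ctrl_vals, welch = welch)
      hits$t[r] <- tt$t; hits$p[r] <- tt$p
    }
  }
  if (adjust != "none") hits$p_adj <- stats::p.adjust(hits$p, adjust)
  hits
}

#' Read a plate CSV of OD readings
#'
#' Expects an 8 x 12 (or similar) grid of numbers; an optional first column
#' of row letters is detected and dropped.
#'
#' @param path CSV file.
#' @return Numeric matrix with letter row names and numeric column names.
#' @export
read_plate_csv <- function(path) {
  tab <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE)
  if (is.character(tab[[1]]) &&
      all(toupper(tab[[1]]) %in% LETTERS))
    tab <- tab[-1]
  m <- as.matrix(tab)
  storage.mode(m) <- "double"
  dimnames(m) <- list(LETTERS[seq_len(nrow(m))],
                      as.character(seq_len(ncol(m))))
  m
}
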