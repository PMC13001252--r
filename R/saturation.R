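#' Closed-form expected ORF coverage under uniform insertion
#'
#' Under uniform insertion over a genome of `genome_length` bp, a gene of
#' length `L` is missed by all of `n` independent insertions with probability
#' `(1 - L/G)^n`.  Expected coverage is the mean over genes of
#' `1 - (1 - L/G)^n`.  This closed form is the oracle against which the Monte
#' Carlo simulation is checked; unlike a Poisson approximation it accounts
#' for each gene's length exactly.
#'
#' @param genes A [gene_models()] table (only `start`/`end` are used).
#' @param genome_length Genome length in bp.
#' @param n Number of insertions (colonies picked).
#' @return Expected fraction of genes with at least one insertion, in
#'   `[0, 1]`.  Vectorised over `n`.
#' @examples
#' g <- gene_models("g1", 1, 100, "+")
#' expected_coverage_analytic(g, 1000, 10)  # 1 - 0.9^10
#' @export
expected_coverage_analytic <- function(genes, genome_length, n) {
  if (nrow(genes) == 0)
    stop("undefined coverage: empty gene list")
  if (any(genes$end > genome_length))
    stop("genes extend beyond genome_length")
  if (any(n < 0)) stop("n must be >= 0")
  L <- genes$end - genes$start + 1
  vapply(n, function(ni) mean(1 - (1 - L / genome_length)^ni), numeric(1))
}

#' Monte Carlo estimate of ORF coverage from n picked mutants
#'
#' Draws `n` insertion positions per replicate — uniform per bp, or uniform
#' over TA dinucleotide sites for a mariner-family transposon — and counts
#' the fraction of genes containing at least one insertion.  Deterministic
#' for a fixed `seed`.
#'
#' @param genes A [gene_models()] table; genes are treated as non-overlapping
#'   intervals and an insertion inside a gene marks it hit.
#' @param genome_length Genome length in bp.
#' @param n Number of insertions per replicate.
#' @param reps Number of Monte Carlo replicates.
#' @param seed RNG seed.
#' @param model `"uniform-bp"` (default) or `"ta-site"`; the TA-site model
#'   requires `genome` and draws positions from the first base of each TA
#'   dinucleotide.
#' @param genome Genome sequence (character or `DNAString`), needed for the
#'   TA-site model.
#' @return An object of class `saturation_estimate`: a list with
#'   `n_mutants`, `mean_coverage`, `sd`, `reps`, `seed`, `model`.
#' @export
simulate_coverage <- function(genes, genome_length, n, reps = 100, seed = 1,
                              model = c("uniform-bp", "ta-site"),
                              genome = NULL) {
  model <- match.arg(model)
  if (nrow(genes) == 0) stop("undefined coverage: empty gene list")
  if (reps < 1) stop("reps must be >= 1")
  if (n < 0) stop("n must be >= 0")

  if (model == "ta-site") {
    if (is.null(genome)) stop("ta-site model requires a genome sequence")
    ta <- Biostrings::start(
      Biostrings::matchPattern("TA", Biostrings::DNAString(as.character(genome))))
    if (length(ta) == 0) stop("ta-site model: genome contains no TA sites")
  }

  ord <- order(genes$start)
  starts <- genes$start[ord]
  ends <- genes$end[ord]
  ng <- nrow(genes)

  set.seed(seed)
  cov <- numeric(reps)
  if (n == 0) {
    cov[] <- 0
  } else {
    for (r in seq_len(reps)) {
      pos <- if (model == "uniform-bp")
        sample.int(genome_length, n, replace = TRUE)
      else
        ta[sample.int(length(ta), n, replace = TRUE)]
      idx <- findInterval(pos, starts)
      hit <- idx >= 1 & pos <= ends[pmax(idx, 1)]
      cov[r] <- length(unique(idx[hit])) / ng
    }
  }
  structure(list(n_mutants = as.integer(n), mean_coverage = mean(cov),
                 sd = stats::sd(cov), reps = as.integer(reps),
                 seed = seed, model = model),
            class = "saturation_estimate")
}

#' @export
print.saturation_estimate <- function(x, ...) {
  cat(sprintf(
    "Saturation estimate (%s): n = %d mutants -> %.4f +/- %.4f ORF coverage (%d reps)\n",
    x$model, x$n_mutants, x$mean_coverage,
    if (is.na(x$sd)) 0 else x$sd, x$reps))
  invisible(x)
}

#' Smallest number of mutants reaching a target ORF coverage
#'
#' Inverts the analytic coverage curve by doubling then bisection: returns
#' the smallest `n` with expected coverage at least `target`.  Optionally
#' confirms the returned `n` by Monte Carlo simulation (`reps > 0`), attached
#' as attribute `"simulated"`.
#'
#' @param genes,genome_length As in [expected_coverage_analytic()].
#' @param target Target coverage fraction, strictly between 0 and 1.
#' @param reps If positive, replicates for a confirming simulation.
#' @param seed RNG seed for the confirming simulation.
#' @return Integer `n`; coverage at `n` meets `target`, coverage at `n - 1`
#'   does not.
#' @export
mutants_for_target <- function(genes, genome_length, target, reps = 0,
                               seed = 1) {
  if (target <= 0 || target >= 1)
    stop("target must be strictly between 0 and 1")
  if (nrow(genes) == 0) stop("target unreachable: empty gene list")
  f <- function(n) expected_coverage_analytic(genes, genome_length, n)
  hi <- 1L
  while (f(hi) < target) {
    hi <- hi * 2L
    if (hi > .Machine$integer.max / 2)
      stop("target unreachable within integer range")
  }
  lo <- 0L  # f(0) = 0 < target
  while (hi - lo > 1L) {       # invariant: f(lo) < target <= f(hi)
    mid <- lo + (hi - lo) %/% 2L
    if (f(mid) >= target) hi <- mid else lo <- mid
  }
  n <- hi
  if (reps > 0)
    attr(n, "simulated") <- simulate_coverage(genes, genome_length, n,
                                              reps = reps, seed = seed)
  n
}

#' Saturation curve over a range of pick counts
#'
#' @param genes,genome_length As in [expected_coverage_analytic()].
#' @param n_values Pick counts to evaluate.
#' @param reps Monte Carlo replicates per point (0 for analytic only).
#' @param seed RNG seed.
#' @param model Insertion model, see [simulate_coverage()].
#' @param genome Genome sequence for the TA-site model.
#' @return Data frame with columns `n`, `analytic`, and when `reps > 0`
#'   `mean` and `sd` from simulation.
#' @export
saturation_curve <- function(genes, genome_length, n_values, reps = 0,
                             seed = 1, model = "uniform-bp", genome = NULL) {
  out <- data.frame(n = as.integer(n_values),
                    analytic = expected_coverage_analytic(genes, genome_length,
                                                          n_values))
  if (reps > 0) {
    sims <- lapply(seq_along(n_values), function(i)
      simulate_coverage(genes, genome_length, n_values[i], reps = reps,
                        seed = seed + i - 1, model = model, genome = genome))
    out$mean <- vapply(sims, `[[`, numeric(1), "mean_coverage")
    out$sd <- vapply(sims, `[[`, numeric(1), "sd")
  }
  out
}
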