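# Trafficking-screen statistics: traffic efficiency, deviation scores,
# the global siRNA effect and its full-matrix permutation test, plus the
# halide-quenching decay fit and surface-retention normalisation.

#' Per-image traffic efficiency with cell-count quality control
#'
#' Traffic efficiency of a cell is the ratio of its surface signal
#' (extracellular-tag immunofluorescence) to its total signal (whole-cell
#' fluorophore), i.e. the fraction of the protein that reached the plasma
#' membrane. The per-image value is the median over cells, robust against
#' segmentation outliers. Images with fewer than `min_cells` cells are
#' flagged `qc_pass = FALSE` and must be excluded downstream. If the input
#' carries a logical `qc_pass` column (upstream image-analysis QC), cells
#' failing it are discarded before anything else.
#'
#' @param cells Data frame with columns `image_id`, `surface_signal`,
#'   `total_signal`, optionally `qc_pass` per cell.
#' @param min_cells Minimum cells per image (default 20).
#' @return Data frame per image: `image_id`, `n_cells`, `te` (median
#'   ratio), `qc_pass`.
#' @export
traffic_efficiency <- function(cells, min_cells = 20L) {
  stopifnot(all(c("image_id", "surface_signal", "total_signal") %in%
                  names(cells)))
  if ("qc_pass" %in% names(cells)) {
    cells <- cells[as.logical(cells$qc_pass), , drop = FALSE]
  }
  bad <- which(!(cells$total_signal > 0))
  if (length(bad)) {
    stop("non-positive total signal for cell ", bad[1L], " (image ",
         cells$image_id[bad[1L]], ")")
  }
  ratio <- cells$surface_signal / cells$total_signal
  images <- split(ratio, cells$image_id)
  data.frame(
    image_id = names(images),
    n_cells = lengths(images),
    te = vapply(images, stats::median, numeric(1)),
    qc_pass = lengths(images) >= min_cells,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Per-well mean traffic efficiency
#'
#' Averages the per-image median traffic efficiencies over the QC-passing
#' images of each well. Wells with no passing image are dropped with a
#' message.
#'
#' @param cells Data frame with columns `image_id`, `well_id`, `condition`,
#'   `surface_signal`, `total_signal` (and optionally `qc_pass`).
#' @inheritParams traffic_efficiency
#' @return Data frame per well: `well_id`, `condition`, `n_images_passed`,
#'   `mean_te`.
#' @export
well_traffic_efficiency <- function(cells, min_cells = 20L) {
  stopifnot(all(c("well_id", "condition") %in% names(cells)))
  img <- traffic_efficiency(cells, min_cells = min_cells)
  map <- unique(cells[, c("image_id", "well_id", "condition")])
  img <- merge(img, map, by = "image_id")
  img <- img[img$qc_pass, , drop = FALSE]
  if (nrow(img) == 0L) stop("no image passed quality control")
  key <- interaction(img$well_id, img$condition, drop = TRUE)
  out <- data.frame(
    well_id = tapply(as.character(img$well_id), key, `[`, 1L),
    condition = tapply(as.character(img$condition), key, `[`, 1L),
    n_images_passed = as.integer(tapply(img$te, key, length)),
    mean_te = as.numeric(tapply(img$te, key, mean)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out[order(out$condition, out$well_id), , drop = FALSE]
}

#' Negative-control statistics for deviation scoring
#'
#' Mean and standard error of the per-well mean traffic efficiencies of
#' the negative-control wells (e.g. EGFP siRNA) of a plate. The SEM's unit
#' of replication is the control well: sample SD over control wells divided
#' by the square root of their number.
#'
#' @param wells Output of [well_traffic_efficiency()].
#' @param control Condition label of the negative control (default
#'   `"EGFP"`).
#' @return List with `mean`, `sem`, `n_wells`.
#' @export
control_stats <- function(wells, control = "EGFP") {
  te <- wells$mean_te[wells$condition == control]
  if (length(te) < 2L) {
    stop("need at least two control wells for '", control, "'")
  }
  list(mean = mean(te), sem = stats::sd(te) / sqrt(length(te)),
       n_wells = length(te))
}

#' Deviation score of a test traffic efficiency
#'
#' `DS = (TE_test - TE_control) / (2 * SEM_control)`: the test traffic
#' efficiency expressed in units of twice the negative-control standard
#' error, so a DS of 1 equals double the control SEM and values are
#' comparable across plates and replicates. Positive scores are traffic
#' enhancers, negative scores inhibitors.
#'
#' @param te_test Mean traffic efficiency of the test condition.
#' @param control_mean,control_sem Negative-control mean and SEM (same
#'   plate); `control_sem` must be positive.
#' @return Numeric deviation score (vectorised over `te_test`).
#' @export
deviation_score <- function(te_test, control_mean, control_sem) {
  if (!(control_sem > 0)) stop("control SEM must be positive")
  (te_test - control_mean) / (2 * control_sem)
}

# internal: validate a deviation-score matrix (long format) and build the
# grouping machinery shared by sirna_effect and permutation_test.
ds_groups <- function(ds) {
  stopifnot(all(c("sirna", "cftr_type", "replicate", "ds") %in% names(ds)))
  if (any(!is.finite(ds$ds))) stop("non-finite deviation scores")
  sirna <- factor(ds$sirna)
  type <- factor(ds$cftr_type)
  cell <- interaction(sirna, type, drop = FALSE, lex.order = TRUE)
  counts <- as.vector(table(cell))
  if (any(counts == 0L)) {
    bad <- levels(cell)[counts == 0L][1L]
    stop("missing deviation scores for combination ", bad)
  }
  list(sirna = sirna, type = type, cell = cell, counts = counts,
       cell_sirna = factor(rep(levels(sirna),
                               each = nlevels(type)),
                           levels = levels(sirna)))
}

# internal: per-siRNA sum of absolute per-type mean DS for one value vector
# laid out as `ds$ds` (used on observed and permuted data alike).
effect_sums <- function(v, g) {
  cell_means <- rowsum(v, g$cell) / g$counts
  as.vector(rowsum(abs(cell_means), g$cell_sirna))
}

#' Global effect of one siRNA: sum of absolute per-type mean DS
#'
#' For a siRNA assayed against the three CFTR types (wild type, mutant,
#' corrector-rescued mutant), the per-type effect is the mean deviation
#' score over replicates, and the global effect is the sum of the three
#' absolute means. Taking absolute values before summing captures siRNAs
#' that enhance trafficking of one CFTR type while inhibiting another.
#'
#' @param ds Deviation-score table in long format: columns `sirna`,
#'   `cftr_type`, `replicate`, `ds`.
#' @param sirna siRNA label present in the table; it must have scores for
#'   every CFTR type in the table.
#' @return List with `effect` (the summed absolute means) and `type_means`
#'   (named vector of per-type mean DS).
#' @export
sirna_effect <- function(ds, sirna) {
  ds <- as.data.frame(ds)
  sub <- ds[ds$sirna == sirna, , drop = FALSE]
  if (nrow(sub) == 0L) stop("siRNA '", sirna, "' not in the table")
  types <- unique(as.character(ds$cftr_type))
  missing <- setdiff(types, unique(as.character(sub$cftr_type)))
  if (length(missing)) {
    stop("siRNA '", sirna, "' lacks scores for CFTR type(s): ",
         paste(missing, collapse = ", "))
  }
  means <- tapply(sub$ds, factor(sub$cftr_type, levels = types), mean)
  means <- stats::setNames(as.numeric(means), names(means))
  list(effect = sum(abs(means)), type_means = means)
}

#' Full-matrix permutation test of siRNA effects
#'
#' Null distribution of the global effect statistic (see [sirna_effect()])
#' obtained by shuffling *all* individual deviation scores across the
#' entire matrix — every siRNA, CFTR type and replicate exchangeable, which
#' is justified because all scores are normalised to the same-plate
#' negative controls. For each of `n_perm` shuffles the per-siRNA
#' effect sums are recomputed; the p-value of each siRNA is the fraction of
#' shuffles with an effect greater than or equal to its observed one,
#' floored at `1/n_perm` so it is never zero. An effect is called
#' significant when p < `alpha` (conventionally 0.05).
#'
#' @param ds Deviation-score table in long format (`sirna`, `cftr_type`,
#'   `replicate`, `ds`), complete for every siRNA x type combination.
#' @param n_perm Number of shuffles (default 10000).
#' @param seed Optional integer seed.
#' @return Object of class `permutation_result`: data frame with columns
#'   `sirna`, `observed` and `p`, plus attributes `n_perm` and `seed`.
#' @export
permutation_test <- function(ds, n_perm = 10000L, seed = NULL) {
  set_seed_if(seed)
  n_perm <- as.integer(n_perm)
  if (n_perm < 100L) {
    warning("n_perm < 100 gives a very coarse null distribution")
  }
  ds <- as.data.frame(ds)
  g <- ds_groups(ds)
  v <- ds$ds
  observed <- effect_sums(v, g)

  # all shuffles at once: one column per permutation of the full matrix
  perm <- vapply(seq_len(n_perm), function(i) sample(v), numeric(length(v)))
  cell_means <- rowsum(perm, g$cell) / g$counts
  rand_sums <- rowsum(abs(cell_means), g$cell_sirna)   # siRNA x n_perm

  tol <- 1e-12
  count <- rowSums(rand_sums >= (observed - tol))
  p <- pmax(count, 1L) / n_perm

  out <- data.frame(sirna = levels(g$sirna), observed = observed, p = p,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  class(out) <- c("permutation_result", "data.frame")
  out
}

#' Exponential-decay fit of a quenching trace and its initial slope
#'
#' Fits the normalised fluorescence trace of a halide-quenching functional
#' assay to `F/F0(t) = offset + amplitude * exp(-rate * t)` on the samples
#' after quencher addition and reports the maximal (initial) slope
#' `d(F/F0)/dt` at `t = 0`, which equals `-amplitude * rate` and is
#' proportional to the initial anion influx rate. The trace is first
#' normalised to the mean of the pre-addition baseline samples, so the
#' baseline sits at 1. A flat post-addition trace short-circuits to
#' amplitude 0, rate 0. Set `offset_term = FALSE` for a two-parameter fit
#' decaying to zero.
#'
#' @param trace Data frame with columns `t` (seconds) and `F`
#'   (fluorescence, arbitrary units).
#' @param baseline_end Time of quencher addition: samples with
#'   `t <= baseline_end` form the baseline; the fit runs on later samples
#'   with time re-zeroed at `baseline_end`.
#' @param offset_term Include the plateau offset (default `TRUE`).
#' @return List of class `decay_fit`: `amplitude`, `rate`, `offset`,
#'   `initial_slope`, `resid_norm`, `n_points`.
#' @export
fit_decay <- function(trace, baseline_end, offset_term = TRUE) {
  stopifnot(all(c("t", "F") %in% names(trace)))
  base <- trace$F[trace$t <= baseline_end]
  post <- trace[trace$t > baseline_end, , drop = FALSE]
  if (length(base) < 1L) stop("no baseline samples before 'baseline_end'")
  if (nrow(post) < 10L) stop("need at least 10 post-addition samples")
  f0 <- mean(base)
  if (!(f0 > 0)) stop("baseline fluorescence must be positive")
  y <- post$F / f0
  tt <- post$t - baseline_end

  if (stats::sd(y) < 1e-10) {
    return(structure(list(amplitude = 0, rate = 0, offset = mean(y),
                          initial_slope = 0, resid_norm = 0,
                          n_points = length(y)),
                     class = "decay_fit"))
  }

  off0 <- if (offset_term) min(y) else 0
  amp0 <- max(y[1L] - off0, 1e-6)
  # crude rate start from the time to reach ~1/e of the drop
  drop <- (y - off0) / amp0
  below <- which(drop < exp(-1))
  k0 <- if (length(below)) 1 / max(tt[below[1L]], 1e-6) else
    1 / max(tt[length(tt)], 1e-6)

  fit <- tryCatch({
    if (offset_term) {
      minpack.lm::nlsLM(y ~ offset + amplitude * exp(-rate * tt),
                        start = list(offset = off0, amplitude = amp0,
                                     rate = k0),
                        lower = c(-Inf, -Inf, 0),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(y ~ amplitude * exp(-rate * tt),
                        start = list(amplitude = amp0, rate = k0),
                        lower = c(-Inf, 0),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }, error = function(e) {
    stop("decay fit did not converge: ", conditionMessage(e))
  })
  cf <- stats::coef(fit)
  amplitude <- unname(cf["amplitude"])
  rate <- unname(cf["rate"])
  offset <- if (offset_term) unname(cf["offset"]) else 0
  structure(list(amplitude = amplitude, rate = rate, offset = offset,
                 initial_slope = -amplitude * rate,
                 resid_norm = sqrt(sum(stats::resid(fit)^2)),
                 n_points = length(y)),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("Exponential decay fit on", x$n_points, "points:\n")
  cat(sprintf("  F/F0(t) = %.4g + %.4g * exp(-%.4g t)\n",
              x$offset, x$amplitude, x$rate))
  cat(sprintf("  initial slope d(F/F0)/dt at t=0: %.4g per s\n",
              x$initial_slope))
  invisible(x)
}

#' Surface retention as a percentage of a reference condition
#'
#' Normalises a surface/total fluorescence ratio to a reference condition
#' (e.g. mutant protein stabilised at permissive temperature) and expresses
#' it as a percentage.
#'
#' @param signal Surface/total ratio(s) of the condition(s) of interest.
#' @param reference Positive ratio of the reference condition.
#' @return `100 * signal / reference` (vectorised).
#' @export
surface_retention <- function(signal, reference) {
  if (!(reference > 0)) stop("reference ratio must be positive")
  100 * signal / reference
}
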