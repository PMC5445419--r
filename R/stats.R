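# Polarity statistics: median-centred confidence boxes, anterior-vs-
# posterior comparisons (overall and by stream position), and the
# mRNA-protein posterior-fraction correlation.

#' Median-centred box summary with order-statistic confidence intervals
#'
#' Summarises a sample by its median and distribution-free confidence
#' intervals for the median built from order statistics (binomial method):
#' the box covers the 50% confidence region from the median and the bars a
#' 99% region. Points outside the 99% interval are flagged as outliers.
#' Quartiles are also reported for comparison with conventional box plots.
#'
#' @param values numeric vector, `n >= 3`.
#' @param levels two confidence levels `c(box, bar)`.
#' @return An object of class `box_summary`: `n`, `median`, `box_lo`,
#'   `box_hi`, `bar_lo`, `bar_hi`, `outliers` (the values beyond the bars),
#'   `quartiles`, `levels`.
#' @export
summarize_box <- function(values, levels = c(0.50, 0.99)) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3L) stop("need at least 3 values")
  s <- sort(values)
  ci <- lapply(levels, function(g) median_order_ci(s, g))
  box <- ci[[1L]]; bar <- ci[[2L]]
  structure(
    list(n = n, median = stats::median(values),
         box_lo = box$lo, box_hi = box$hi,
         bar_lo = bar$lo, bar_hi = bar$hi,
         outliers = values[values < bar$lo | values > bar$hi],
         quartiles = stats::quantile(values, c(0.25, 0.75), names = FALSE),
         levels = levels),
    class = "box_summary")
}

# Distribution-free CI for the median from order statistics: the interval
# [x_(l), x_(n-l+1)] with the largest l whose exact binomial coverage
# P(l <= B <= n - l), B ~ Bin(n, 1/2), is still >= the requested level.
median_order_ci <- function(sorted, level) {
  n <- length(sorted)
  l_max <- floor((n + 1) / 2)
  cov <- function(l) stats::pbinom(n - l, n, 0.5) -
    stats::pbinom(l - 1, n, 0.5)
  l <- 1L
  for (cand in seq_len(l_max)) {
    if (cov(cand) >= level) l <- cand else break
  }
  list(lo = sorted[l], hi = sorted[n - l + 1L], order_rank = l,
       coverage = cov(l))
}

#' @export
print.box_summary <- function(x, ...) {
  cat(sprintf(
    "<box_summary> n = %d, median = %.4g, %d%% box [%.4g, %.4g], %d%% bars [%.4g, %.4g], %d outlier(s)\n",
    x$n, x$median, round(100 * x$levels[1L]), x$box_lo, x$box_hi,
    round(100 * x$levels[2L]), x$bar_lo, x$bar_hi, length(x$outliers)))
  invisible(x)
}

# Pick the anterior/posterior count columns for an estimator.
count_columns <- function(estimator = c("linear", "simulated")) {
  estimator <- match.arg(estimator)
  suff <- if (estimator == "linear") "linear" else "sim"
  c(anterior = paste0("anterior_", suff),
    posterior = paste0("posterior_", suff))
}

#' Compare anterior and posterior unit counts across cells
#'
#' Two-sample t test (Welch by default, or paired per cell) of posterior
#' versus anterior unit counts, with median-centred box summaries per side.
#' The t statistic is signed posterior minus anterior.
#'
#' @param records data frame of cell records (see [cohort_records()]), with
#'   columns `anterior_<est>`, `posterior_<est>` and `qc_pass`.
#' @param estimator `"linear"` or `"simulated"`.
#' @param paired logical; pair anterior and posterior within each cell.
#' @return An object of class `group_comparison`: group labels, `n`,
#'   medians, per-side `box` summaries, `t_statistic`, `p_value` (`NA` with
#'   a note when the test is undefined, e.g. zero variance), `method`.
#' @export
compare_anterior_posterior <- function(records,
                                       estimator = c("linear", "simulated"),
                                       paired = FALSE) {
  cols <- count_columns(estimator)
  rec <- records[records$qc_pass, , drop = FALSE]
  if (nrow(rec) < 2L) stop("need at least 2 records passing QC")
  ant <- rec[[cols["anterior"]]]
  post <- rec[[cols["posterior"]]]
  tt <- tryCatch(
    stats::t.test(post, ant, paired = paired, var.equal = FALSE),
    error = function(e) NULL)
  structure(
    list(groups = c("anterior", "posterior"),
         n = c(anterior = length(ant), posterior = length(post)),
         medians = c(anterior = stats::median(ant),
                     posterior = stats::median(post)),
         box = list(anterior = summarize_box(ant),
                    posterior = summarize_box(post)),
         t_statistic = if (is.null(tt)) 0 else unname(tt$statistic),
         p_value = if (is.null(tt)) NA_real_ else tt$p.value,
         note = if (is.null(tt)) "t test undefined (data essentially constant)"
                else NULL,
         method = if (paired) "paired t test" else "Welch two-sample t test",
         estimator = match.arg(estimator)),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "<group_comparison> %s, %s estimator\n  medians: anterior %.4g, posterior %.4g (n = %d, %d)\n  t = %.4g, p = %s%s\n",
    x$method, x$estimator, x$medians["anterior"], x$medians["posterior"],
    x$n["anterior"], x$n["posterior"], x$t_statistic,
    format.pval(x$p_value),
    if (!is.null(x$note)) paste0(" [", x$note, "]") else ""))
  invisible(x)
}

#' Plot a group comparison in the median-centred box convention
#'
#' One box per side: the filled box spans the 50% confidence region of the
#' median, the whiskers the 99% region, the heavy line the median, and
#' points beyond the whiskers are drawn as outliers.
#'
#' @param x a `group_comparison`.
#' @param ... passed to [graphics::plot()] (e.g. `main`, `ylab`).
#' @return `x`, invisibly.
#' @export
plot.group_comparison <- function(x, ...) {
  sides <- x$groups
  rng <- range(unlist(lapply(x$box, function(b)
    c(b$bar_lo, b$bar_hi, b$outliers))))
  graphics::plot(NA, xlim = c(0.5, length(sides) + 0.5), ylim = rng,
                 xaxt = "n", xlab = "", ylab = "unit count", ...)
  graphics::axis(1, at = seq_along(sides), labels = sides)
  for (i in seq_along(sides)) {
    b <- x$box[[sides[i]]]
    graphics::segments(i, b$bar_lo, i, b$bar_hi)
    graphics::rect(i - 0.25, b$box_lo, i + 0.25, b$box_hi,
                   col = "grey85")
    graphics::segments(i - 0.3, b$median, i + 0.3, b$median, lwd = 2,
                       col = "red3")
    if (length(b$outliers))
      graphics::points(rep(i, length(b$outliers)), b$outliers,
                       pch = 1, col = "red3")
  }
  invisible(x)
}

#' Anterior/posterior comparison by stream position
#'
#' Splits the records by `stream_position` and runs
#' [compare_anterior_posterior()] within each group, also reporting the
#' per-position mean mRNA posterior fraction.
#'
#' @inheritParams compare_anterior_posterior
#' @return A named list of `group_comparison` objects (one per position, in
#'   beginning/middle/end/single order), each with an extra field
#'   `mean_mrna_posterior_fraction`. Positions with fewer than 2 records are
#'   skipped with a warning.
#' @export
compare_by_stream_position <- function(records,
                                       estimator = c("linear", "simulated"),
                                       paired = FALSE) {
  estimator <- match.arg(estimator)
  order_pref <- c("beginning", "middle", "end", "single")
  present <- unique(records$stream_position)
  positions <- c(intersect(order_pref, present),
                 setdiff(present, order_pref))
  out <- list()
  for (pos in positions) {
    rec <- records[records$stream_position == pos, , drop = FALSE]
    if (sum(rec$qc_pass) < 2L) {
      warning("skipping position \"", pos, "\": fewer than 2 records")
      next
    }
    cmp <- compare_anterior_posterior(rec, estimator, paired)
    cmp$stream_position <- pos
    cmp$mean_mrna_posterior_fraction <-
      mean(rec$mrna_posterior_fraction[rec$qc_pass], na.rm = TRUE)
    out[[pos]] <- cmp
  }
  out
}

#' Correlation of mRNA and protein posterior fractions
#'
#' Pearson product-moment correlation of the mRNA posterior fraction against
#' the protein posterior fraction, computed two ways: across cells, and
#' across stream-position group means (three points when three positions are
#' present).
#'
#' @param records data frame of cell records with columns
#'   `mrna_posterior_fraction`, `protein_posterior_fraction`,
#'   `stream_position`, `qc_pass`.
#' @return A list with elements `per_cell` and `per_position`, each a list
#'   `(r, n)`; `r` is `NA` when either vector has zero variance.
#' @export
mrna_protein_correlation <- function(records) {
  rec <- records[records$qc_pass, , drop = FALSE]
  if (nrow(rec) < 3L) stop("need at least 3 paired values")
  safe_cor <- function(x, y) {
    if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0)
      return(NA_real_)
    stats::cor(x, y)
  }
  per_cell <- list(
    r = safe_cor(rec$mrna_posterior_fraction,
                 rec$protein_posterior_fraction),
    n = nrow(rec))
  mx <- tapply(rec$mrna_posterior_fraction, rec$stream_position, mean)
  my <- tapply(rec$protein_posterior_fraction, rec$stream_position, mean)
  per_position <- list(r = safe_cor(as.numeric(mx), as.numeric(my)),
                       n = length(mx))
  list(per_cell = per_cell, per_position = per_position)
}

#' Build per-cell records from a synthetic cohort
#'
#' Runs the quantification pipeline on each cell of a
#' [make_stream_cohort()] cohort: background subtraction (median outside the
#' cell mask), nucleus-centred bisection, per-half unit counts by the linear
#' estimator (and optionally the simulated estimator), the protein and mRNA
#' posterior intensity fractions, and the cell eccentricity.
#'
#' @param cohort list returned by [make_stream_cohort()].
#' @param unit a [unit_model()]; defaults to the generator's ground-truth
#'   unit (each scene's `unit_amplitude`, `unit_sigma`).
#' @param simulated logical; also run [simulated_estimate()] per cell.
#' @param n_reps,master_seed,jitter_px passed to [simulated_estimate()].
#' @return A data frame with one row per cell: `cell_id`,
#'   `stream_position`, `anterior_linear`, `posterior_linear`,
#'   `anterior_sim`, `posterior_sim` (NA unless `simulated`),
#'   `true_anterior`, `true_posterior`, `mrna_posterior_fraction`,
#'   `protein_posterior_fraction`, `eccentricity`, `qc_pass`.
#' @export
cohort_records <- function(cohort, unit = NULL, simulated = FALSE,
                           n_reps = 10L, master_seed = 1L, jitter_px = 1) {
  seeds <- derive_seeds(master_seed, length(cohort))
  rows <- lapply(seq_along(cohort), function(i) {
    cell <- cohort[[i]]
    sc <- cell$scene
    u <- if (is.null(unit))
      unit_model(sc$params$unit_amplitude, sc$params$unit_sigma)
    else unit
    mrna <- subtract_background(cell$mrna, sc$cell_mask)
    protein <- subtract_background(cell$protein, sc$cell_mask)
    rois <- scene_roi_pair(sc)
    # split the whole image, not just the cell outline: spot tails extend
    # past the ellipse boundary and the count must not lose them (the ROI
    # approach is insensitive to the exact cell boundary)
    shape <- dim(mrna$pixels)
    masks <- roi_pair_masks(rois, shape,
                            cell_mask = matrix(TRUE, shape[1L], shape[2L]))
    ant <- linear_estimate(mrna, masks$anterior, u)
    post <- linear_estimate(mrna, masks$posterior, u)
    if (simulated) {
      est <- simulated_estimate(mrna, rois, u, n_reps = n_reps,
                                master_seed = seeds[i],
                                jitter_px = jitter_px)
      ant_s <- est$sim_count_mean[est$roi_id == "anterior"]
      post_s <- est$sim_count_mean[est$roi_id == "posterior"]
    } else {
      ant_s <- NA_real_; post_s <- NA_real_
    }
    ax <- sc$params$cell_axes
    data.frame(
      cell_id = sprintf("cell_%03d", i),
      stream_position = cell$position %||% "single",
      anterior_linear = ant, posterior_linear = post,
      anterior_sim = ant_s, posterior_sim = post_s,
      true_anterior = sc$true_anterior_count,
      true_posterior = sc$true_posterior_count,
      mrna_posterior_fraction = if (ant + post > 0) post / (ant + post)
                                else NA_real_,
      protein_posterior_fraction =
        suppressWarnings(posterior_intensity_fraction(protein, masks)),
      eccentricity = eccentricity(ax[1L], ax[2L]),
      qc_pass = TRUE)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
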