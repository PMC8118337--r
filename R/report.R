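# Sample-level aggregation: class fractions, the SDE score distribution
# (mean, central 95% interval, kernel density on a fixed grid) and the
# confusion matrix against manual labels using the +/- 0.17 score-matching
# rule for SDE cells.

#' Aggregate per-cell results into a sample report
#'
#' @param results a `cell_results` data.frame from [predict_pipeline()].
#' @param sample_id free-text sample label.
#' @param kde_bandwidth Gaussian kernel bandwidth for the score density
#'   (default: Silverman's rule).
#' @param grid_points density evaluation points over \[-1, 1\]
#'   (default 201).
#' @return a `sample_report`: `sample_id`, `n_cells`, `class_fractions`
#'   (over all labels including unknown), `sde_scores`, `mu` (mean score),
#'   `ci95` (central 2.5th / 97.5th percentiles), `density` (data.frame
#'   `score`, `density`).
#' @export
build_sample_report <- function(results, sample_id = "sample",
                                kde_bandwidth = NULL, grid_points = 201L) {
  if (!nrow(results))
    .stop_erythro("no cell results to report", "invalid_argument")
  labels <- sort(unique(results$predicted_class))
  fractions <- as.numeric(table(factor(results$predicted_class,
                                       levels = labels))) / nrow(results)
  names(fractions) <- labels
  scores <- results$sde_score[!is.na(results$sde_score)]
  if (length(scores)) {
    mu <- mean(scores)
    # inverse-ECDF quantiles (type 1): invariant under duplicating the
    # sample, so a report of a sample concatenated with itself is unchanged
    ci95 <- unname(quantile(scores, c(0.025, 0.975), type = 1))
    grid <- seq(-1, 1, length.out = grid_points)
    if (length(scores) > 1 && sd(scores) > 0) {
      bw <- kde_bandwidth %||% stats::bw.nrd0(scores)
      dens <- vapply(grid, function(g)
        mean(stats::dnorm(g, mean = scores, sd = bw)), numeric(1))
    } else {
      # degenerate distribution: unit point mass at the single value
      dens <- as.numeric(abs(grid - scores[1]) ==
                           min(abs(grid - scores[1])))
    }
    density <- data.frame(score = grid, density = dens)
  } else {
    warning("no SDE-scored cells in this sample; mu/ci95 are absent")
    mu <- NA_real_
    ci95 <- c(NA_real_, NA_real_)
    density <- data.frame(score = numeric(0), density = numeric(0))
  }
  structure(list(sample_id = sample_id, n_cells = nrow(results),
                 class_fractions = fractions, sde_scores = scores,
                 mu = mu, ci95 = ci95, density = density),
            class = "sample_report")
}

#' @export
print.sample_report <- function(x, ...) {
  cat(sprintf("<sample_report> '%s': %d cells\n", x$sample_id, x$n_cells))
  print(round(x$class_fractions, 3))
  if (!is.na(x$mu))
    cat(sprintf("  SDE scores: mu = %+.3f, CI95 = [%+.3f, %+.3f] (n = %d)\n",
                x$mu, x$ci95[1], x$ci95[2], length(x$sde_scores)))
  invisible(x)
}

#' Does a predicted SDE score match a manually assigned SDE class?
#'
#' True when the score lies within the matching half-interval (0.17, half
#' the canonical spacing between adjacent perfect shapes) of the class's
#' canonical score.
#'
#' @param predicted_score numeric score(s) in \[-1, 1\].
#' @param actual_class SDE class name(s).
#' @return logical.
#' @export
sde_match <- function(predicted_score, actual_class) {
  if (any(predicted_score < -1 | predicted_score > 1, na.rm = TRUE))
    .stop_erythro("scores must lie in [-1, 1]", "invalid_argument")
  target <- canonical_sde_score(actual_class)  # errors on non-SDE input
  abs(predicted_score - target) <= sde_half_interval() &
    !is.na(predicted_score)
}

#' Confusion matrix of predictions against manual labels
#'
#' Rows are manual (actual) classes, columns predicted classes. SDE rows
#' credit a prediction to the actual class when the routed label is
#' `"sde"` and [sde_match()] holds; otherwise the prediction lands in the
#' `"sde_mismatch"` column (routed SDE, score off) or its non-SDE label.
#'
#' @param results a `cell_results` data.frame from [predict_pipeline()].
#' @param manual data.frame with `cell_id` and `shape_class` (manual
#'   labels, SDE shapes by their fine class).
#' @return a `confusion_matrix`: list with `counts`, `percent`
#'   (row-normalized), `accuracy_by_class`, `overall_accuracy`.
#' @export
build_confusion <- function(results, manual) {
  idx <- match(results$cell_id, manual$cell_id)
  if (anyNA(idx))
    .stop_erythro(paste("missing manual labels for:",
                        paste(head(results$cell_id[is.na(idx)], 5),
                              collapse = ", ")), "join_error")
  actual <- manual$shape_class[idx]
  is_sde_actual <- actual %in% sde_classes()
  predicted <- results$predicted_class
  outcome <- character(nrow(results))
  for (i in seq_len(nrow(results))) {
    if (is_sde_actual[i]) {
      outcome[i] <- if (predicted[i] == "sde" &&
                        sde_match(results$sde_score[i], actual[i]))
        actual[i]
      else if (predicted[i] == "sde") "sde_mismatch"
      else predicted[i]
    } else {
      outcome[i] <- predicted[i]
    }
  }
  # full taxonomy rows, so classes absent from the evaluation subset show
  # up as flagged 0% rows rather than disappearing
  row_levels <- unique(c(sde_classes(),
                         setdiff(stage1_classes(), c("sde", "unknown")),
                         sort(unique(actual))))
  col_levels <- unique(c(row_levels, "sde_mismatch", "unknown",
                         sort(unique(outcome))))
  counts <- table(factor(actual, levels = row_levels),
                  factor(outcome, levels = col_levels))
  percent <- counts / pmax(1, rowSums(counts)) * 100
  correct <- diag(counts[, row_levels, drop = FALSE][row_levels, ,
                                                     drop = FALSE])
  acc <- as.numeric(correct) / pmax(1, rowSums(counts))
  names(acc) <- row_levels
  structure(list(counts = unclass(counts), percent = unclass(percent),
                 accuracy_by_class = acc,
                 overall_accuracy = sum(correct) / sum(counts),
                 empty_classes = row_levels[rowSums(counts) == 0]),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> row-normalized percent (actual x predicted)\n")
  print(round(x$percent, 1))
  cat(sprintf("overall accuracy: %.1f%%\n", 100 * x$overall_accuracy))
  invisible(x)
}

#' Write a sample report to TSV files
#' @param report a [build_sample_report()] result.
#' @param dir output directory (created if needed).
#' @export
write_sample_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fr <- data.frame(label = names(report$class_fractions),
                   fraction = as.numeric(report$class_fractions))
  write.table(fr, file.path(dir, "class_fractions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  summ <- data.frame(sample_id = report$sample_id,
                     n_cells = report$n_cells, mu = report$mu,
                     ci95_low = report$ci95[1], ci95_high = report$ci95[2])
  write.table(summ, file.path(dir, "summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(report$density, file.path(dir, "score_density.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
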