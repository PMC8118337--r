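# Leakage-safe dataset assembly for the two network stages: a stratified
# split of the measured spectra first, then linear spectrum interpolation
# within each partition (so no augmented sample ever mixes information
# across the train/validation boundary).

#' First-stage class label of a shape class
#'
#' The classifier's seven mutually exclusive outputs: the seven SDE shapes
#' collapse to one `"sde"` class; knizocyte, keratocyte, acanthocyte,
#' multilobate and cell_cluster keep their names; `"unknown"` is the
#' catch-all slot.
#'
#' @param shape_class character vector of shape classes.
#' @return character vector of stage-1 labels.
#' @export
stage1_label <- function(shape_class) {
  ifelse(shape_class %in% sde_classes(), "sde", shape_class)
}

#' The classifier's output classes
#' @return character vector of length 7 (including `"unknown"`).
#' @export
stage1_classes <- function() {
  c("sde", "knizocyte", "keratocyte", "acanthocyte", "multilobate",
    "cell_cluster", "unknown")
}

#' Labeled spectrum collection
#'
#' @param x matrix of normalized descriptor vectors (rows = cells).
#' @param shape_class character vector of shape classes per row.
#' @param sde_score optional numeric scores (NA for non-SDE rows); filled
#'   from [canonical_sde_score()] when missing.
#' @param origin `"measured"` or `"augmented"` per row.
#' @param parents optional character vector of parent ids.
#' @param ids row ids (default from rownames).
#' @return a `spectrum_set`: list with `x`, `meta` (data.frame).
#' @export
spectrum_set <- function(x, shape_class, sde_score = NULL,
                         origin = "measured", parents = NA_character_,
                         ids = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (length(shape_class) != n)
    .stop_erythro("one shape_class per spectrum required",
                  "invalid_argument")
  if (is.null(sde_score)) {
    sde_score <- rep(NA_real_, n)
    is_sde <- shape_class %in% sde_classes()
    sde_score[is_sde] <- canonical_sde_score(shape_class[is_sde])
  }
  ids <- ids %||% rownames(x) %||% sprintf("cell_%05d", seq_len(n))
  meta <- data.frame(id = as.character(ids), shape_class = shape_class,
                     stage1 = stage1_label(shape_class),
                     sde_score = sde_score,
                     origin = rep_len(origin, n),
                     parents = rep_len(parents, n),
                     stringsAsFactors = FALSE)
  rownames(x) <- meta$id
  structure(list(x = x, meta = meta), class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set> %d spectra x %d features\n",
              nrow(x$x), ncol(x$x)))
  print(table(x$meta$stage1))
  invisible(x)
}

.bind_spectra <- function(a, b) {
  structure(list(x = rbind(a$x, b$x), meta = rbind(a$meta, b$meta)),
            class = "spectrum_set")
}

.subset_spectra <- function(s, idx) {
  structure(list(x = s$x[idx, , drop = FALSE],
                 meta = s$meta[idx, , drop = FALSE]),
            class = "spectrum_set")
}

#' Stratified split of measured spectra before any augmentation
#'
#' @param spectra a [spectrum_set()] of measured cells.
#' @param fraction training fraction (default 0.8).
#' @param seed integer seed.
#' @return a `split_dataset`: list with `train`, `validation`
#'   (spectrum_sets), `fraction`, `seed`.
#' @export
split_before_augmentation <- function(spectra, fraction = 0.8, seed = 1L) {
  meta <- spectra$meta
  counts <- table(meta$shape_class)
  if (any(counts < 2L) && fraction < 1)
    .stop_erythro(paste("cannot stratify classes with < 2 members:",
                        paste(names(counts)[counts < 2L], collapse = ", ")),
                  "stratification_error")
  train_idx <- .with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(meta)), meta$shape_class),
                  function(idx) {
                    n_tr <- round(fraction * length(idx))
                    sample(idx, n_tr)
                  }), use.names = FALSE)
  })
  if (fraction >= 1) {
    warning("fraction 1: validation partition is empty")
    train_idx <- seq_len(nrow(meta))
  }
  val_idx <- setdiff(seq_len(nrow(meta)), train_idx)
  structure(list(train = .subset_spectra(spectra, sort(train_idx)),
                 validation = .subset_spectra(spectra, sort(val_idx)),
                 fraction = fraction, seed = as.integer(seed)),
            class = "split_dataset")
}

#' @export
print.split_dataset <- function(x, ...) {
  cat(sprintf("<split_dataset> %d train / %d validation (fraction %.2f)\n",
              nrow(x$train$x), nrow(x$validation$x), x$fraction))
  invisible(x)
}

# row-wise min-max normalization (vectorized normalize_descriptor)
.normalize_rows <- function(v) {
  i <- seq_len(nrow(v))
  rmin <- v[cbind(i, max.col(-v, ties.method = "first"))]
  rmax <- v[cbind(i, max.col(v, ties.method = "first"))]
  rng <- rmax - rmin
  rng[rng <= 0] <- 1  # constant rows map to all zeros
  (v - rmin) / rng
}

# interpolate random same-group pairs until the group holds n_target rows
.interpolate_group <- function(s, idx, n_target, label, score_fun = NULL) {
  n_have <- length(idx)
  n_new <- n_target - n_have
  if (n_new <= 0) return(NULL)
  i <- sample(idx, n_new, replace = TRUE)
  j <- sample(idx, n_new, replace = TRUE)
  t <- runif(n_new)
  v <- (1 - t) * s$x[i, , drop = FALSE] + t * s$x[j, , drop = FALSE]
  v <- .normalize_rows(v)
  score <- if (is.null(score_fun)) rep(NA_real_, n_new)
  else score_fun(i, j, t)
  spectrum_set(v, shape_class = rep(label, n_new), sde_score = score,
               origin = "augmented",
               parents = paste(s$meta$id[i], s$meta$id[j], sep = "|"),
               ids = sprintf("aug_%s_%05d", label, seq_len(n_new)))
}

#' Balance the classification set by within-class spectrum interpolation
#'
#' Within each partition and each first-stage class, random pairs of
#' spectra from the same class are linearly interpolated (uniform weight)
#' and re-normalized until the class holds exactly `n_per_class` samples
#' (originals included). If `unknown` is `TRUE`, an `"unknown"` class of
#' the same size is synthesized from cross-class mixtures (weights in
#' \[0.3, 0.7\]), emulating ambiguous in-between shapes.
#'
#' @param split a [split_before_augmentation()] result.
#' @param n_per_class per-class budget (default 2000).
#' @param seed integer seed.
#' @param unknown synthesize the trained catch-all class (default `TRUE`).
#' @return the `split_dataset` with augmented partitions.
#' @export
augment_classification <- function(split, n_per_class = 2000L, seed = 1L,
                                   unknown = TRUE) {
  aug_one <- function(s, part_seed) {
    .with_seed(part_seed, {
      groups <- split(seq_len(nrow(s$x)), s$meta$stage1)
      add <- list()
      for (lab in names(groups)) {
        ext <- .interpolate_group(s, groups[[lab]], n_per_class, lab)
        # augmented rows keep NA scores; class identity is what matters here
        if (!is.null(ext)) add[[length(add) + 1L]] <- ext
      }
      if (unknown && length(unique(s$meta$stage1)) < 2L) {
        warning("only one class present; skipping unknown-class synthesis")
        unknown <- FALSE
      }
      if (unknown) {
        n_unk <- n_per_class
        i <- sample(seq_len(nrow(s$x)), n_unk, replace = TRUE)
        j <- sample(seq_len(nrow(s$x)), n_unk, replace = TRUE)
        # force cross-class pairs
        same <- s$meta$stage1[i] == s$meta$stage1[j]
        while (any(same)) {
          j[same] <- sample(seq_len(nrow(s$x)), sum(same), replace = TRUE)
          same <- s$meta$stage1[i] == s$meta$stage1[j]
        }
        t <- runif(n_unk, 0.3, 0.7)
        v <- (1 - t) * s$x[i, , drop = FALSE] + t * s$x[j, , drop = FALSE]
        v <- .normalize_rows(v)
        add[[length(add) + 1L]] <- spectrum_set(
          v, shape_class = rep("unknown", n_unk),
          sde_score = rep(NA_real_, n_unk), origin = "augmented",
          parents = paste(s$meta$id[i], s$meta$id[j], sep = "|"),
          ids = sprintf("aug_unknown_%05d", seq_len(n_unk)))
      }
      for (ext in add) s <- .bind_spectra(s, ext)
      s
    })
  }
  split$train <- aug_one(split$train, seed)
  split$validation <- if (nrow(split$validation$x))
    aug_one(split$validation, seed + 1L) else split$validation
  split
}

# shape_class of "unknown" is not in all_shape_classes(); spectrum_set must
# accept it, so stage1_label maps it to itself via the ifelse fallthrough

#' Build the regression set over the SDE continuum
#'
#' Keeps only SDE spectra and interpolates random pairs drawn from the same
#' or adjacent classes on the SDE ladder; the target score interpolates the
#' parents' scores with the same weight. Each partition is filled to
#' `n_total` samples (originals included).
#'
#' @param split a [split_before_augmentation()] result (measured spectra).
#' @param n_total per-partition budget (default 2000).
#' @param seed integer seed.
#' @return a `split_dataset` of scored SDE spectra.
#' @export
augment_regression <- function(split, n_total = 2000L, seed = 1L) {
  ladder <- sde_classes()
  aug_one <- function(s, part_seed) {
    sde_idx <- which(s$meta$shape_class %in% ladder)
    if (!length(sde_idx)) return(.subset_spectra(s, integer(0)))
    s <- .subset_spectra(s, sde_idx)
    missing <- setdiff(ladder, unique(s$meta$shape_class))
    if (length(missing))
      .stop_erythro(paste("SDE classes missing from the partition:",
                          paste(missing, collapse = ", ")),
                    "coverage_error")
    .with_seed(part_seed, {
      n_new <- n_total - nrow(s$x)
      if (n_new <= 0) return(s)
      pos <- match(s$meta$shape_class, ladder)
      by_pos <- split(seq_len(nrow(s$x)), pos)
      # pick a rung, then a neighbor rung (same, up or down)
      rung_a <- sample(seq_along(ladder), n_new, replace = TRUE)
      step <- sample(c(-1L, 0L, 1L), n_new, replace = TRUE)
      rung_b <- pmin(length(ladder), pmax(1L, rung_a + step))
      i <- vapply(rung_a, function(r)
        by_pos[[as.character(r)]][sample.int(length(by_pos[[as.character(r)]]), 1L)],
        integer(1))
      j <- vapply(rung_b, function(r)
        by_pos[[as.character(r)]][sample.int(length(by_pos[[as.character(r)]]), 1L)],
        integer(1))
      t <- runif(n_new)
      v <- (1 - t) * s$x[i, , drop = FALSE] + t * s$x[j, , drop = FALSE]
      v <- .normalize_rows(v)
      score <- (1 - t) * s$meta$sde_score[i] + t * s$meta$sde_score[j]
      # label by the nearest rung, purely informational for regression
      lab <- ladder[pmax(1, pmin(7, round((score + 1) * 3) + 1))]
      ext <- spectrum_set(v, shape_class = lab, sde_score = score,
                          origin = "augmented",
                          parents = paste(s$meta$id[i], s$meta$id[j],
                                          sep = "|"),
                          ids = sprintf("aug_sde_%05d", seq_len(n_new)))
      .bind_spectra(s, ext)
    })
  }
  split$train <- aug_one(split$train, seed)
  split$validation <- if (nrow(split$validation$x))
    aug_one(split$validation, seed + 1L)
  else .subset_spectra(split$validation, integer(0))
  split
}
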