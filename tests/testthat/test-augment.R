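# Leakage-safe splitting and spectrum interpolation.

test_that("the stratified split honours the 80/20 contract", {
  s <- toy_spectra(sde_classes(), 10L, seed = 1L)
  sp <- split_before_augmentation(s, 0.8, seed = 2L)
  expect_equal(nrow(sp$train$x), 56L)       # 8 per class
  expect_equal(nrow(sp$validation$x), 14L)  # 2 per class
  tr_counts <- table(sp$train$meta$shape_class)
  expect_true(all(tr_counts == 8L))
  # determinism
  sp2 <- split_before_augmentation(s, 0.8, seed = 2L)
  expect_identical(sp$train$meta$id, sp2$train$meta$id)
  # boundary and error cases
  expect_warning(sp3 <- split_before_augmentation(s, 1.0, seed = 2L))
  expect_equal(nrow(sp3$validation$x), 0L)
  tiny <- toy_spectra(c("discocyte", "spherocyte"), 1L, seed = 3L)
  expect_error(split_before_augmentation(tiny, 0.8, seed = 1L),
               class = "stratification_error")
})

test_that("classification augmentation balances every class exactly", {
  s <- toy_spectra(c(sde_classes(), "knizocyte", "cell_cluster"), 6L,
                   seed = 4L)
  sp <- split_before_augmentation(s, 0.8, seed = 5L)
  aug <- augment_classification(sp, 100L, seed = 6L)
  counts <- table(aug$train$meta$stage1)
  expect_true(all(counts == 100L))
  expect_setequal(names(counts),
                  c("sde", "knizocyte", "cell_cluster", "unknown"))
  counts_v <- table(aug$validation$meta$stage1)
  expect_true(all(counts_v == 100L))
  # all augmented vectors stay inside [0, 1]^544 with full range
  augd <- aug$train$x[aug$train$meta$origin == "augmented", ]
  expect_true(all(augd >= 0 & augd <= 1))
  # leakage freedom: augmented parents never cross the partition boundary
  parents <- function(part) unique(unlist(
    strsplit(part$meta$parents[part$meta$origin == "augmented"],
             "|", fixed = TRUE)))
  expect_length(intersect(parents(aug$train), aug$validation$meta$id), 0L)
  expect_length(intersect(parents(aug$validation), aug$train$meta$id), 0L)
})

test_that("interpolation endpoints behave like the originals", {
  s <- toy_spectra("discocyte", 4L, seed = 7L)
  # (u, u) at any weight reproduces u: interpolate a class of one vector
  one <- spectrum_set(s$x[c(1, 1), ], rep("discocyte", 2))
  sp <- split_before_augmentation(one, 1.0, seed = 1L) |>
    suppressWarnings()
  aug <- augment_classification(sp, 10L, seed = 2L, unknown = FALSE)
  augd <- aug$train$x[aug$train$meta$origin == "augmented", , drop = FALSE]
  expect_lt(max(abs(sweep(augd, 2, s$x[1, ]))), 1e-12)
})

test_that("regression augmentation walks only adjacent SDE rungs", {
  s <- toy_spectra(sde_classes(), 6L, seed = 8L)
  sp <- split_before_augmentation(s, 0.8, seed = 9L)
  reg <- augment_regression(sp, 400L, seed = 10L)
  expect_equal(nrow(reg$train$x), 400L)
  meta <- reg$train$meta
  aug <- meta[meta$origin == "augmented", ]
  expect_true(all(aug$sde_score >= -1 & aug$sde_score <= 1))
  # parent classes differ by at most one rung
  pid <- strsplit(aug$parents, "|", fixed = TRUE)
  pos <- function(ids) match(meta$shape_class[match(ids, meta$id)],
                             sde_classes())
  gaps <- vapply(pid, function(p) abs(diff(pos(p))), numeric(1))
  expect_true(all(gaps <= 1))
  # score linearity at the anchors (uniform weights over parent scores)
  par_scores <- vapply(pid, function(p)
    range(meta$sde_score[match(p, meta$id)]), numeric(2))
  expect_true(all(aug$sde_score >= par_scores[1, ] - 1e-12 &
                    aug$sde_score <= par_scores[2, ] + 1e-12))
  # score coverage: no empty 0.1-wide bin over [-1, 1] at n >= 2000
  reg2k <- augment_regression(sp, 2000L, seed = 11L)
  hist_counts <- table(cut(reg2k$train$meta$sde_score,
                           seq(-1, 1, by = 0.1), include.lowest = TRUE))
  expect_true(all(hist_counts > 0))
  # a missing SDE class is a coverage error
  s_no <- toy_spectra(sde_classes()[-3], 6L, seed = 12L)
  sp_no <- split_before_augmentation(s_no, 0.8, seed = 1L)
  expect_error(augment_regression(sp_no, 100L, seed = 1L),
               class = "coverage_error")
})
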