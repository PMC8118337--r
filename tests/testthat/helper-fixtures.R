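# Shared fixtures, memoised across test files (test_dir runs everything in
# one process). Expensive objects -- canonical meshes, the trained
# acceptance models -- are built once on first use.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(key, builder) {
  hit <- .fixtures[[key]]
  if (!is.null(hit)) return(hit)
  val <- builder()
  .fixtures[[key]] <- val
  val
}

canonical_mesh <- function(cls) {
  fixture(paste0("mesh_", cls),
          function() make_canonical_mesh(shape_spec(cls)))
}

# fast synthetic spectra for exercising the training machinery without
# building meshes: one random prototype per class + small jitter
toy_spectra <- function(classes, n_per_class, seed = 1L, noise = 0.03) {
  set.seed(seed)
  protos <- lapply(classes, function(cls) runif(544))
  x <- do.call(rbind, lapply(seq_along(classes), function(k) {
    t(vapply(seq_len(n_per_class), function(i) {
      v <- protos[[k]] + rnorm(544, sd = noise)
      (v - min(v)) / (max(v) - min(v))
    }, numeric(544)))
  }))
  spectrum_set(x, rep(classes, each = n_per_class))
}

# analytic solid-ball stack for preprocessing oracles
ball_stack <- function(radius_vox = 20, n = 64L, pitch_nm = 100,
                       center = c(0, 0, 0)) {
  ctr <- (n - 1) / 2 + center
  ax <- 0:(n - 1)
  dx2 <- outer(outer((ax - ctr[1])^2, (ax - ctr[2])^2, "+"),
               (ax - ctr[3])^2, "+")
  voxel_stack(array(as.numeric(sqrt(dx2) <= radius_vox), dim = rep(n, 3L)),
              rep(pitch_nm, 3L))
}

# --- the acceptance "world": the scaled-down training study -------------
# 7 SDE classes x 200 cells + 5 non-SDE x 100, descriptors from the clean
# meshes, 80/20 split, augmentation to 2000 per class / 2000 regression
# samples, stage 1 trained 100 epochs and stage 2 40 epochs with 3
# restarts each. Built once; used by the parameter-recovery and
# end-to-end acceptance criteria.
acceptance_world <- function() {
  fixture("acceptance_world", function() {
    seed <- 20210406L
    cells <- c(
      generate_dataset(sde_classes(), 200L, seed = seed + 1L),
      generate_dataset(setdiff(all_shape_classes(), sde_classes()), 100L,
                       seed = seed + 2L))
    x <- describe_meshes(lapply(cells, `[[`, "mesh"),
                         ids = sprintf("cell_%04d", seq_along(cells)))
    spectra <- spectrum_set(
      x, vapply(cells, function(c) c$spec$shape_class, character(1)))
    split <- split_before_augmentation(spectra, 0.8, seed = seed + 3L)
    cls_set <- augment_classification(split, 2000L, seed = seed + 4L)
    reg_set <- augment_regression(split, 2000L, seed = seed + 5L)
    stage1 <- multi_restart_select(
      stage1_config(epochs = 100L),
      list(x = cls_set$train$x, y = cls_set$train$meta$stage1),
      list(x = cls_set$validation$x, y = cls_set$validation$meta$stage1),
      n_restarts = 3L, base_seed = seed + 10L)
    stage2 <- multi_restart_select(
      stage2_config(epochs = 40L),
      list(x = reg_set$train$x, y = reg_set$train$meta$sde_score),
      list(x = reg_set$validation$x, y = reg_set$validation$meta$sde_score),
      n_restarts = 3L, base_seed = seed + 40L)
    list(split = split, stage1 = stage1, stage2 = stage2, seed = seed)
  })
}
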