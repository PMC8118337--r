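# End-to-end orchestration: simulate -> (optionally rasterize + preprocess)
# -> describe -> split/augment -> train both stages -> predict -> report,
# with one global seed fanned out deterministically to every stage.

#' Pipeline run configuration
#'
#' @param out_dir run directory (created; must not require parents).
#' @param classes shape classes to simulate.
#' @param n_per_class simulated cells per class.
#' @param seed global seed; stage sub-seeds are fixed offsets of it
#'   (simulate +1, split +2, augment +3, stage-1 training +10, stage-2
#'   training +40).
#' @param restarts training restarts per stage (default 3; the full
#'   protocol uses 100).
#' @param n_augment_class,n_augment_reg augmentation budgets per class /
#'   per partition.
#' @param epochs1,epochs2 training epochs per stage.
#' @param via_stacks if `TRUE`, every simulated cell is rasterized to a
#'   synthetic confocal stack and recovered through preprocessing before
#'   description (slow, full-fidelity); if `FALSE` (default) descriptors
#'   are built from the simulated meshes directly.
#' @param descriptor a [descriptor_config()].
#' @param preprocess a [preprocess_config()].
#' @param write_meshes write per-cell OBJ/PLY meshes into the run dir.
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir, classes = all_shape_classes(),
                       n_per_class = 50L, seed = 1L, restarts = 3L,
                       n_augment_class = 2000L, n_augment_reg = 2000L,
                       epochs1 = 100L, epochs2 = 40L, via_stacks = FALSE,
                       descriptor = descriptor_config(),
                       preprocess = preprocess_config(),
                       write_meshes = FALSE) {
  structure(list(out_dir = out_dir, classes = classes,
                 n_per_class = as.integer(n_per_class),
                 seed = as.integer(seed), restarts = as.integer(restarts),
                 n_augment_class = as.integer(n_augment_class),
                 n_augment_reg = as.integer(n_augment_reg),
                 epochs1 = as.integer(epochs1),
                 epochs2 = as.integer(epochs2),
                 via_stacks = isTRUE(via_stacks), descriptor = descriptor,
                 preprocess = preprocess,
                 write_meshes = isTRUE(write_meshes)),
            class = "run_config")
}

.stage_msg <- function(verbose, ...) if (verbose) message(...)

#' Run the full phenotyping pipeline
#'
#' Executes every stage on synthetic data and writes all artifacts
#' (descriptor table, models, per-cell results, sample report, confusion
#' matrix, manifest) into `config$out_dir`. Re-running the same
#' configuration reproduces the results tables byte for byte.
#'
#' @param config a [run_config()].
#' @param verbose print stage progress (default `TRUE`).
#' @return invisibly, a list with `results`, `report`, `confusion`,
#'   `stage1`, `stage2`, `manifest`.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  if (!inherits(config, "run_config"))
    .stop_erythro("config must be a run_config", "invalid_argument")
  parent <- dirname(config$out_dir)
  if (!dir.exists(parent))
    .stop_erythro(sprintf("parent directory '%s' does not exist", parent),
                  "invalid_argument")
  dir.create(config$out_dir, showWarnings = FALSE)
  step <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  .stage_msg(verbose, "simulate: ", length(config$classes), " classes x ",
             config$n_per_class, " cells")
  cells <- step("simulate",
                generate_dataset(config$classes, config$n_per_class,
                                 seed = config$seed + 1L))
  ids <- vapply(cells, function(c) c$mesh$provenance, character(1))
  if (config$write_meshes) {
    mdir <- file.path(config$out_dir, "meshes")
    dir.create(mdir, showWarnings = FALSE)
    for (i in seq_along(cells)) {
      write_obj(cells[[i]]$mesh,
                file.path(mdir, sprintf("cell_%04d.obj", i)))
      write_ply(cells[[i]]$mesh,
                file.path(mdir, sprintf("cell_%04d.ply", i)))
    }
  }
  .stage_msg(verbose, "describe: ", length(cells), " cells",
             if (config$via_stacks) " (via synthetic stacks)" else "")
  meshes <- step("describe", {
    if (config$via_stacks) {
      lapply(seq_along(cells), function(i) {
        stack <- rasterize_to_stack(cells[[i]]$mesh,
                                    seed = config$seed + 1000L + i)
        preprocess_stack(stack, config$preprocess)
      })
    } else {
      lapply(cells, `[[`, "mesh")
    }
  })
  descriptors <- step("describe",
                      describe_meshes(meshes, config$descriptor, ids = ids))
  write_descriptors(descriptors,
                    file.path(config$out_dir, "descriptors.tsv"))
  spectra <- spectrum_set(descriptors,
                          vapply(cells, function(c) c$spec$shape_class,
                                 character(1)))
  .stage_msg(verbose, "split + augment")
  split <- step("split",
                split_before_augmentation(spectra, 0.8,
                                          seed = config$seed + 2L))
  cls_set <- step("augment",
                  augment_classification(split, config$n_augment_class,
                                         seed = config$seed + 3L))
  reg_set <- step("augment",
                  augment_regression(split, config$n_augment_reg,
                                     seed = config$seed + 3L))
  .stage_msg(verbose, "train stage 1 (", config$restarts, " restarts)")
  cfg1 <- stage1_config(epochs = config$epochs1,
                        restarts = config$restarts)
  stage1 <- step("train_stage1", multi_restart_select(
    cfg1,
    list(x = cls_set$train$x, y = cls_set$train$meta$stage1),
    list(x = cls_set$validation$x, y = cls_set$validation$meta$stage1),
    n_restarts = config$restarts, base_seed = config$seed + 10L))
  .stage_msg(verbose, "train stage 2 (", config$restarts, " restarts)")
  cfg2 <- stage2_config(epochs = config$epochs2,
                        restarts = config$restarts)
  stage2 <- step("train_stage2", multi_restart_select(
    cfg2,
    list(x = reg_set$train$x, y = reg_set$train$meta$sde_score),
    list(x = reg_set$validation$x, y = reg_set$validation$meta$sde_score),
    n_restarts = config$restarts, base_seed = config$seed + 40L))
  save_model(stage1, file.path(config$out_dir, "stage1_model.json"),
             config$descriptor)
  save_model(stage2, file.path(config$out_dir, "stage2_model.json"),
             config$descriptor)
  .stage_msg(verbose, "predict held-out cells + report")
  holdout <- split$validation
  results <- step("predict",
                  predict_pipeline(stage1, stage2, holdout$x,
                                   ids = holdout$meta$id))
  utils::write.table(results, file.path(config$out_dir, "results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report <- step("report",
                 build_sample_report(results, sample_id = "held_out"))
  write_sample_report(report, file.path(config$out_dir, "report"))
  manual <- data.frame(cell_id = holdout$meta$id,
                       shape_class = holdout$meta$shape_class)
  confusion <- step("report", build_confusion(results, manual))
  utils::write.table(
    data.frame(actual = rownames(confusion$percent),
               round(as.data.frame.matrix(confusion$percent), 2)),
    file.path(config$out_dir, "confusion.tsv"), sep = "\t",
    quote = FALSE, row.names = FALSE)
  manifest <- list(
    package = "erythroshape",
    config = unclass(config)[setdiff(names(config),
                                     c("descriptor", "preprocess"))],
    descriptor = unclass(config$descriptor),
    preprocess = unclass(config$preprocess),
    config_hash = .config_hash(config),
    seeds = list(global = config$seed, simulate = config$seed + 1L,
                 split = config$seed + 2L, augment = config$seed + 3L,
                 stage1 = config$seed + 10L, stage2 = config$seed + 40L),
    n_cells = length(cells),
    stage1_val_loss = stage1$final_val_loss,
    stage2_val_loss = stage2$final_val_loss,
    files = c("descriptors.tsv", "stage1_model.json", "stage2_model.json",
              "results.tsv", "confusion.tsv", "report/"))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(results = results, report = report,
                 confusion = confusion, stage1 = stage1, stage2 = stage2,
                 manifest = manifest))
}
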