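# The dual-stage network, implemented directly in base R matrix algebra.
# Stage 1: 544 -> 54 (ReLU) -> 7 (softmax), crossentropy, Adam, 100 epochs.
# Stage 2: 544 -> 544 (ReLU) -> 1 (tanh, bounded to [-1, 1]), MSE, Adam,
# 40 epochs. Both train in batches of 100 with multi-restart selection of
# the lowest-validation-loss model. Everything is seeded and deterministic.

#' Configuration of the 7-way shape classifier (stage 1)
#'
#' @param hidden_dim hidden neurons (default 54).
#' @param classes output class labels (default [stage1_classes()]).
#' @param epochs training epochs (default 100).
#' @param batch_size spectra per batch (default 100).
#' @param restarts random restarts for [multi_restart_select()]
#'   (default 100; scale down for quick runs).
#' @param confidence_threshold softmax confidence below which a cell is
#'   relabeled `"unknown"` (default 0.75).
#' @param learning_rate Adam step size (default 1e-3; Adam moments 0.9 /
#'   0.999, epsilon 1e-8).
#' @return a `stage_config`.
#' @export
stage1_config <- function(hidden_dim = 54L, classes = stage1_classes(),
                          epochs = 100L, batch_size = 100L,
                          restarts = 100L, confidence_threshold = 0.75,
                          learning_rate = 1e-3) {
  if (confidence_threshold <= 0 || confidence_threshold >= 1)
    .stop_erythro("confidence_threshold must be in (0, 1)",
                  "invalid_argument")
  structure(list(stage = 1L, input_dim = 544L,
                 hidden_dim = as.integer(hidden_dim), classes = classes,
                 output_dim = length(classes), loss = "crossentropy",
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 restarts = as.integer(restarts),
                 confidence_threshold = confidence_threshold,
                 learning_rate = learning_rate), class = "stage_config")
}

#' Configuration of the SDE-score regressor (stage 2)
#'
#' @param hidden_dim hidden neurons (default 544).
#' @param output_activation `"tanh"` (default; output bounded to
#'   \[-1, 1\] by construction) or `"linear_clip"` (linear output clipped
#'   at prediction time).
#' @inheritParams stage1_config
#' @return a `stage_config`.
#' @export
stage2_config <- function(hidden_dim = 544L, epochs = 40L,
                          batch_size = 100L, restarts = 100L,
                          learning_rate = 1e-3,
                          output_activation = c("tanh", "linear_clip")) {
  structure(list(stage = 2L, input_dim = 544L,
                 hidden_dim = as.integer(hidden_dim), classes = NULL,
                 output_dim = 1L, loss = "mse",
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 restarts = as.integer(restarts),
                 output_activation = match.arg(output_activation),
                 learning_rate = learning_rate), class = "stage_config")
}

# He / fan-in scaled initialization, seeded by the caller's RNG state.
# The tanh regression head starts with a much smaller output layer so the
# initial pre-activations sit in the linear region: a saturated tanh has a
# vanishing (1 - out^2) gradient factor and can freeze training for good.
.mlp_init <- function(config) {
  d <- config$input_dim; h <- config$hidden_dim; o <- config$output_dim
  out_scale <- if (config$stage == 2L &&
                   identical(config$output_activation, "tanh")) 0.05 else 1
  list(W1 = matrix(rnorm(d * h, sd = sqrt(2 / d)), d, h),
       b1 = rep(0, h),
       W2 = matrix(rnorm(h * o, sd = out_scale * sqrt(2 / h)), h, o),
       b2 = rep(0, o))
}

.softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# forward pass; returns activations needed for the backward pass
.mlp_forward <- function(par, x, config) {
  a1 <- x %*% par$W1
  a1 <- sweep(a1, 2, par$b1, "+")
  h <- pmax(a1, 0)
  z <- h %*% par$W2
  z <- sweep(z, 2, par$b2, "+")
  out <- if (config$stage == 1L) .softmax(z)
  else if (config$output_activation == "tanh") tanh(z)
  else z
  list(h = h, z = z, out = out)
}

.mlp_loss <- function(out, y, config) {
  if (config$stage == 1L) {
    p <- pmax(out[cbind(seq_len(nrow(out)), y)], 1e-12)
    mean(-log(p))
  } else {
    mean((out - y)^2)
  }
}

# gradient of the loss w.r.t. parameters for one batch
.mlp_grad <- function(par, x, y, config) {
  fw <- .mlp_forward(par, x, config)
  n <- nrow(x)
  if (config$stage == 1L) {
    dz <- fw$out
    dz[cbind(seq_len(n), y)] <- dz[cbind(seq_len(n), y)] - 1
    dz <- dz / n
  } else {
    err <- fw$out - y
    dz <- if (config$output_activation == "tanh")
      2 * err * (1 - fw$out^2) / n
    else 2 * err / n
  }
  dW2 <- crossprod(fw$h, dz)
  db2 <- colSums(dz)
  dh <- tcrossprod(dz, par$W2)
  dh[fw$h <= 0] <- 0
  dW1 <- crossprod(x, dh)
  db1 <- colSums(dh)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
       loss = .mlp_loss(fw$out, y, config))
}

#' Train one network stage
#'
#' Adam on shuffled mini-batches; deterministic for a fixed seed. Records
#' per-epoch training loss, validation loss and (stage 1) categorical
#' accuracy.
#'
#' @param config a [stage1_config()] or [stage2_config()].
#' @param train,validation lists with `x` (n x 544 matrix) and `y`
#'   (stage 1: class labels among `config$classes`; stage 2: scores in
#'   \[-1, 1\]).
#' @param seed integer seed (initialization and batch order).
#' @return an `rbc_model`: list with `par`, `config`, `history`, `seed`,
#'   `final_val_loss`.
#' @export
train_stage <- function(config, train, validation = NULL, seed = 1L) {
  x <- as.matrix(train$x)
  if (ncol(x) != config$input_dim)
    .stop_erythro(sprintf("input has %d features, expected %d", ncol(x),
                          config$input_dim), "training_error")
  if (!nrow(x)) .stop_erythro("empty training set", "training_error")
  y <- .encode_targets(train$y, config)
  has_val <- !is.null(validation) && NROW(validation$x) > 0
  if (has_val) {
    xv <- as.matrix(validation$x)
    yv <- .encode_targets(validation$y, config)
  }
  lr <- config$learning_rate
  b1m <- 0.9; b2m <- 0.999; eps <- 1e-8
  .with_seed(seed, {
    par <- .mlp_init(config)
    m <- lapply(par, function(p) p * 0)
    v <- lapply(par, function(p) p * 0)
    step <- 0
    hist <- data.frame(epoch = seq_len(config$epochs), train_loss = NA_real_,
                       val_loss = NA_real_, val_accuracy = NA_real_)
    n <- nrow(x)
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = config$batch_size)
      ep_loss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + config$batch_size - 1, n)]
        g <- .mlp_grad(par, x[idx, , drop = FALSE],
                       if (config$stage == 1L) y[idx]
                       else y[idx, , drop = FALSE], config)
        ep_loss <- ep_loss + g$loss * length(idx)
        step <- step + 1
        for (nm in names(par)) {
          m[[nm]] <- b1m * m[[nm]] + (1 - b1m) * g[[nm]]
          v[[nm]] <- b2m * v[[nm]] + (1 - b2m) * g[[nm]]^2
          mhat <- m[[nm]] / (1 - b1m^step)
          vhat <- v[[nm]] / (1 - b2m^step)
          par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
        }
      }
      hist$train_loss[ep] <- ep_loss / n
      if (has_val) {
        fw <- .mlp_forward(par, xv, config)
        hist$val_loss[ep] <- .mlp_loss(fw$out, yv, config)
        if (config$stage == 1L)
          hist$val_accuracy[ep] <-
            mean(max.col(fw$out, ties.method = "first") == yv)
      }
    }
    structure(list(par = par, config = config, history = hist,
                   seed = as.integer(seed),
                   final_val_loss = if (has_val)
                     hist$val_loss[config$epochs] else
                       hist$train_loss[config$epochs]),
              class = "rbc_model")
  })
}

.encode_targets <- function(y, config) {
  if (config$stage == 1L) {
    yi <- match(as.character(y), config$classes)
    if (anyNA(yi))
      .stop_erythro(paste("labels outside the configured classes:",
                          paste(unique(y[is.na(yi)]), collapse = ", ")),
                    "training_error")
    yi
  } else {
    matrix(as.numeric(y), ncol = 1)
  }
}

#' @export
print.rbc_model <- function(x, ...) {
  cat(sprintf(
    "<rbc_model> stage %d (%d-%d-%d), %d epochs, final val loss %.4g\n",
    x$config$stage, x$config$input_dim, x$config$hidden_dim,
    x$config$output_dim, x$config$epochs, x$final_val_loss))
  invisible(x)
}

#' Train with several random restarts and keep the best model
#'
#' `n_restarts` independent trainings seeded `base_seed .. base_seed +
#' n - 1`; the model with the lowest final validation loss wins (stage-1
#' ties broken by validation accuracy). The per-restart selection log is
#' attached as `selection_log`.
#'
#' @inheritParams train_stage
#' @param n_restarts number of restarts (>= 1).
#' @param base_seed first seed.
#' @return the winning `rbc_model`.
#' @export
multi_restart_select <- function(config, train, validation = NULL,
                                 n_restarts = config$restarts,
                                 base_seed = 1L) {
  if (n_restarts < 1L)
    .stop_erythro("n_restarts must be >= 1", "invalid_argument")
  best <- NULL
  log <- data.frame(seed = integer(0), val_loss = numeric(0),
                    val_accuracy = numeric(0))
  for (k in seq_len(n_restarts)) {
    mod <- train_stage(config, train, validation, seed = base_seed + k - 1L)
    acc <- tail(mod$history$val_accuracy, 1)
    log <- rbind(log, data.frame(seed = mod$seed,
                                 val_loss = mod$final_val_loss,
                                 val_accuracy = acc))
    better <- is.null(best) || mod$final_val_loss < best$final_val_loss ||
      (config$stage == 1L && !is.na(acc) &&
         mod$final_val_loss == best$final_val_loss &&
         isTRUE(acc > tail(best$history$val_accuracy, 1)))
    if (better) best <- mod
  }
  best$selection_log <- log
  best
}

#' Classify descriptors with the confidence threshold
#'
#' Softmax over the 7 classes; cells whose top probability does not exceed
#' the threshold -- and cells whose top class is the trained catch-all
#' slot -- are labeled `"unknown"`.
#'
#' @param model a trained stage-1 `rbc_model`.
#' @param x descriptor matrix (rows) or single vector.
#' @param threshold override of the config threshold.
#' @return list with `probabilities` (n x 7, named columns) and `label`
#'   (character).
#' @export
classify_with_threshold <- function(model, x,
                                    threshold =
                                      model$config$confidence_threshold) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != model$config$input_dim)
    .stop_erythro(sprintf("descriptor has %d features, expected %d",
                          ncol(x), model$config$input_dim), "input_error")
  p <- .mlp_forward(model$par, as.matrix(x), model$config)$out
  colnames(p) <- model$config$classes
  top <- max.col(p, ties.method = "first")
  label <- model$config$classes[top]
  conf <- p[cbind(seq_len(nrow(p)), top)]
  label[conf <= threshold] <- "unknown"
  list(probabilities = p, label = label)
}

#' Predict SDE scores with the stage-2 regressor
#' @param model a trained stage-2 `rbc_model`.
#' @param x descriptor matrix or vector.
#' @return numeric scores clipped to \[-1, 1\].
#' @export
predict_score <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  out <- .mlp_forward(model$par, as.matrix(x), model$config)$out
  pmin(1, pmax(-1, as.numeric(out)))
}

#' Run the full dual-stage prediction
#'
#' Every cell gets class probabilities and a thresholded label; cells
#' labeled `"sde"` are forwarded to the regressor for a score in
#' \[-1, 1\], all others get `NA`.
#'
#' @param stage1,stage2 trained `rbc_model`s.
#' @param x descriptor matrix (rows = cells).
#' @param ids cell ids (default rownames).
#' @return a `cell_results` data.frame: `cell_id`, `predicted_class`,
#'   `confidence`, `sde_score`, plus one `p_<class>` column per class.
#' @export
predict_pipeline <- function(stage1, stage2, x, ids = NULL) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (!nrow(x)) {
    return(structure(data.frame(cell_id = character(0),
                                predicted_class = character(0),
                                confidence = numeric(0),
                                sde_score = numeric(0)),
                     class = c("cell_results", "data.frame")))
  }
  ids <- ids %||% rownames(x) %||% sprintf("cell_%05d", seq_len(nrow(x)))
  cls <- classify_with_threshold(stage1, x)
  score <- rep(NA_real_, nrow(x))
  is_sde <- cls$label == "sde"
  if (any(is_sde))
    score[is_sde] <- predict_score(stage2, x[is_sde, , drop = FALSE])
  res <- data.frame(cell_id = as.character(ids),
                    predicted_class = cls$label,
                    confidence = apply(cls$probabilities, 1, max),
                    sde_score = score,
                    stringsAsFactors = FALSE)
  p <- as.data.frame(cls$probabilities)
  colnames(p) <- paste0("p_", colnames(cls$probabilities))
  structure(cbind(res, p), class = c("cell_results", "data.frame"))
}

#' Save / load a trained model
#'
#' Portable JSON container: architecture, weights and a hash of the
#' descriptor configuration. Loading verifies the hash when a config is
#' supplied and reproduces predictions exactly.
#'
#' @param model an `rbc_model`.
#' @param path JSON file.
#' @param descriptor_config the [descriptor_config()] the training
#'   descriptors were built with (hashed into the container).
#' @export
save_model <- function(model, path, descriptor_config = NULL) {
  obj <- list(
    format = "erythroshape_model_v1",
    stage = model$config$stage,
    config = unclass(model$config),
    # weights as %.17g strings: decimal JSON numbers do not round-trip
    # doubles bit-exactly through jsonlite, 17 significant digits do
    par = lapply(model$par, function(p)
      if (is.matrix(p)) list(dim = dim(p),
                             data = sprintf("%.17g", as.numeric(p)))
      else list(dim = length(p), data = sprintf("%.17g", as.numeric(p)))),
    seed = model$seed,
    final_val_loss = model$final_val_loss,
    descriptor_hash = if (!is.null(descriptor_config))
      .config_hash(descriptor_config) else NA)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path, descriptor_config = NULL) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    .stop_erythro(sprintf("cannot parse model file '%s'",
                                          path), "format_error"))
  if (!identical(obj$format, "erythroshape_model_v1"))
    .stop_erythro("not an erythroshape model file", "format_error")
  if (!is.null(descriptor_config) && !is.na(obj$descriptor_hash) &&
      !identical(.config_hash(descriptor_config), obj$descriptor_hash))
    .stop_erythro("model was trained with a different descriptor config",
                  "compatibility_error")
  cfg <- obj$config
  cfg$stage <- as.integer(cfg$stage)
  class(cfg) <- "stage_config"
  par <- lapply(obj$par, function(p) {
    v <- as.numeric(p$data)
    if (length(p$dim) == 2L) matrix(v, p$dim[1], p$dim[2]) else v
  })
  structure(list(par = par, config = cfg,
                 history = NULL, seed = obj$seed,
                 final_val_loss = obj$final_val_loss),
            class = "rbc_model")
}

# tiny polynomial rolling hash of a canonical JSON rendering (compatibility
# fingerprint only; avoids an external digest dependency)
.config_hash <- function(config) {
  strip <- function(x)
    if (is.list(x)) lapply(unclass(x), strip) else unclass(x)
  s <- jsonlite::toJSON(strip(config), auto_unbox = TRUE, digits = NA,
                        null = "null")
  bytes <- utf8ToInt(as.character(s))
  h <- 7
  mod <- 2^31 - 1
  for (b in bytes) h <- (h * 31 + b) %% mod
  sprintf("%08x", as.integer(h))
}
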