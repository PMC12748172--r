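# Training loop (Adam, BCE + soft Dice), evaluation, checkpoints, and the
# SE-placement ablation driver.

#' Training configuration
#'
#' Defaults mirror the reference training recipe (300 epochs, batch size 2,
#' Adam, learning rate 0.001); the CPU test profile uses far fewer epochs.
#'
#' @param epochs number of passes over the training set.
#' @param batch_size gradient-accumulation batch size.
#' @param learning_rate Adam step size.
#' @param optimizer only `"adam"` is implemented.
#' @param seed integer seed controlling weight init and data order.
#' @param bce_weight,dice_weight loss mixing weights (default equal).
#' @param log_file optional path for JSON-lines per-epoch logs.
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs = 300L, batch_size = 2L,
                         learning_rate = 0.001, optimizer = "adam",
                         seed = 1L, bce_weight = 0.5, dice_weight = 0.5,
                         log_file = NULL) {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate >= 0,
            identical(optimizer, "adam"))
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, optimizer = optimizer,
                 seed = as.integer(seed), bce_weight = bce_weight,
                 dice_weight = dice_weight, log_file = log_file),
            class = "train_config")
}

# combined loss on logits; returns a scalar tensor
segmentation_loss <- function(logits, mask, bce_weight = 0.5,
                              dice_weight = 0.5) {
  bce <- v_bce_with_logits(logits, mask)
  dice <- v_dice_loss(v_sigmoid(logits), mask)
  v_add(v_mul(bce, bce_weight), v_mul(dice, dice_weight))
}

# embed all captions once (frozen embedder)
.embed_samples <- function(samples, cfg, seed) {
  lapply(samples, function(s) {
    if (is.null(s$caption) || !nzchar(s$caption)) return(NULL)
    embed_text(s$caption, cfg$text_embedder, d_text = cfg$text_dim,
               seed = seed)
  })
}

#' Train a model
#'
#' Gradient-accumulation minibatches with Adam on the BCE + soft Dice loss.
#' Fully deterministic for a fixed `tcfg$seed` (weights, data order and
#' every update are driven by R's RNG in single-threaded code).
#'
#' @param model a `vv_model` from [build_model()].
#' @param dataset list of samples, each `list(image, mask, caption)` with
#'   `image` an (H, W) matrix in [0, 1] and `mask` binary; e.g. from
#'   [load_dataset()].
#' @param tcfg a [train_config()].
#' @param val_set optional validation sample list; when given, pooled
#'   validation metrics are recorded per epoch in the history.
#' @param checkpoint_path optional path; the checkpoint is saved there on
#'   every improvement (validation F1 when `val_set` is given, otherwise
#'   training loss).
#' @return object of class `vv_checkpoint`: trained parameter arrays, both
#'   configurations, the per-epoch loss history, and the final epoch index.
#' @export
train <- function(model, dataset, tcfg = train_config(), val_set = NULL,
                  checkpoint_path = NULL) {
  stopifnot(inherits(model, "vv_model"), length(dataset) >= 1)
  set.seed(tcfg$seed)
  wrapped <- model
  wrapped$params <- wrap_params(model$params)
  flat <- flatten_params(wrapped$params)
  opt <- adam_init(flat, lr = tcfg$learning_rate)
  embs <- .embed_samples(dataset, model$cfg, tcfg$seed)
  history <- data.frame(epoch = integer(0), loss = numeric(0))
  n <- length(dataset)
  data_order <- matrix(0L, tcfg$epochs, n)
  best_score <- -Inf
  for (epoch in seq_len(tcfg$epochs)) {
    ord <- sample.int(n)
    data_order[epoch, ] <- ord
    epoch_loss <- 0
    done <- 0L
    while (done < n) {
      take <- ord[(done + 1L):min(done + tcfg$batch_size, n)]
      zero_grads(flat)
      batch_loss <- 0
      for (j in take) {
        s <- dataset[[j]]
        out <- forward_model(wrapped, s$image, embs[[j]])
        loss <- segmentation_loss(out$logits, s$mask + 0,
                                  tcfg$bce_weight, tcfg$dice_weight)
        lv <- vt_value(loss)
        if (!is.finite(lv)) {
          stop("non-finite loss at epoch ", epoch, ", sample ", j,
               "; aborting training", call. = FALSE)
        }
        vt_backward(loss)
        batch_loss <- batch_loss + lv
      }
      # average accumulated gradients over the batch
      for (p in flat) if (!is.null(p$grad)) p$grad <- p$grad / length(take)
      if (tcfg$learning_rate > 0) opt <- adam_step(opt, flat)
      epoch_loss <- epoch_loss + batch_loss
      done <- done + length(take)
    }
    epoch_loss <- epoch_loss / n
    row <- data.frame(epoch = epoch, loss = epoch_loss)
    score <- -epoch_loss
    if (!is.null(val_set)) {
      snapshot <- structure(
        list(params = unwrap_params(wrapped$params), model_config = model$cfg,
             train_config = tcfg, epoch = epoch, history = history),
        class = "vv_checkpoint")
      vm <- evaluate(snapshot, val_set)
      row$val_f1 <- vm$f1; row$val_acc <- vm$acc
      row$val_se <- vm$se; row$val_sp <- vm$sp
      score <- if (is.na(vm$f1)) -Inf else vm$f1
    }
    history <- rbind(history, row)
    if (score > best_score) {
      best_score <- score
      if (!is.null(checkpoint_path)) {
        save_checkpoint(structure(
          list(params = unwrap_params(wrapped$params),
               model_config = model$cfg, train_config = tcfg, epoch = epoch,
               history = history,
               data_order = data_order[seq_len(epoch), , drop = FALSE]),
          class = "vv_checkpoint"), checkpoint_path)
      }
    }
    if (!is.null(tcfg$log_file)) {
      cat(jsonlite::toJSON(c(as.list(row), list(seed = tcfg$seed)),
                           auto_unbox = TRUE, digits = NA),
          "\n", sep = "", file = tcfg$log_file, append = TRUE)
    }
  }
  structure(list(params = unwrap_params(wrapped$params),
                 model_config = model$cfg, train_config = tcfg,
                 epoch = tcfg$epochs, history = history,
                 data_order = data_order),
            class = "vv_checkpoint")
}

#' Reconstruct a model from a checkpoint
#' @param ckpt a `vv_checkpoint`.
#' @return a `vv_model` with the trained parameters.
#' @export
checkpoint_model <- function(ckpt) {
  stopifnot(inherits(ckpt, "vv_checkpoint"))
  structure(list(cfg = ckpt$model_config, params = ckpt$params),
            class = "vv_model")
}

#' Save / load a checkpoint
#'
#' Binary round-trip via R serialization; reloading reproduces bitwise
#' identical forward outputs.
#'
#' @param ckpt a `vv_checkpoint`.
#' @param path file path (conventionally `.rds`).
#' @export
save_checkpoint <- function(ckpt, path) {
  stopifnot(inherits(ckpt, "vv_checkpoint"))
  saveRDS(ckpt, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ckpt <- readRDS(path)
  stopifnot(inherits(ckpt, "vv_checkpoint"))
  ckpt
}

#' Evaluate a checkpoint on a dataset
#'
#' Runs binarize -> confusion -> metrics per image and pooled over pixels
#' (micro-average); a per-image macro average is attached for transparency.
#'
#' @param ckpt a `vv_checkpoint` (or `vv_model`).
#' @param dataset list of samples as in [train()]; must be non-empty.
#' @param threshold binarization threshold.
#' @param embed_seed stub-embedder seed (must match training for identical
#'   text features).
#' @return a `metrics_report` for pooled counts, with attributes
#'   `per_image` (data.frame) and `macro` (mean of per-image metrics).
#' @export
evaluate <- function(ckpt, dataset, threshold = 0.5, embed_seed = NULL) {
  model <- if (inherits(ckpt, "vv_checkpoint")) checkpoint_model(ckpt)
           else ckpt
  if (length(dataset) == 0) stop("empty dataset", call. = FALSE)
  if (is.null(embed_seed)) {
    embed_seed <- if (inherits(ckpt, "vv_checkpoint"))
      ckpt$train_config$seed else 1L
  }
  embs <- .embed_samples(dataset, model$cfg, embed_seed)
  counts <- vector("list", length(dataset))
  rows <- vector("list", length(dataset))
  for (i in seq_along(dataset)) {
    s <- dataset[[i]]
    prob <- forward_model(model, s$image, embs[[i]])$prob
    cc <- confusion(binarize(prob, threshold), s$mask)
    counts[[i]] <- cc
    m <- compute_metrics(cc)
    rows[[i]] <- data.frame(image_id = if (is.null(s$image_id)) i else
                              s$image_id,
                            f1 = m$f1, acc = m$acc, se = m$se, sp = m$sp)
  }
  pooled <- compute_metrics(pool_confusion(counts))
  per_image <- do.call(rbind, rows)
  attr(pooled, "per_image") <- per_image
  attr(pooled, "macro") <- colMeans(per_image[, c("f1", "acc", "se", "sp")],
                                    na.rm = TRUE)
  pooled
}

#' SE-placement / gating ablation driver
#'
#' Trains one model per (placement, gating) configuration with a shared seed
#' and dataset, then evaluates each on the test set. Mirrors the structure
#' of the published ablation tables: one row per configuration, four metric
#' columns.
#'
#' @param placements character vector of SE placements (length of grid with
#'   `gating` must be at least 2).
#' @param gating logical vector of gating settings.
#' @param base_model_config a [model_config()] used as a template.
#' @param tcfg shared [train_config()].
#' @param train_set,test_set sample lists as in [train()].
#' @return data.frame: se_placement, gating, f1, acc, se, sp (+ n_params).
#' @export
run_ablation <- function(placements, gating, base_model_config, tcfg,
                         train_set, test_set) {
  grid <- expand.grid(se_placement = placements, gating = gating,
                      stringsAsFactors = FALSE)
  if (nrow(grid) < 2L) stop("ablation needs at least 2 configurations",
                            call. = FALSE)
  rows <- vector("list", nrow(grid))
  orders <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- base_model_config
    cfg$se_placement <- grid$se_placement[i]
    cfg$gating_enabled <- grid$gating[i]
    model <- build_model(cfg, seed = tcfg$seed)
    ckpt <- train(model, train_set, tcfg)
    rep <- evaluate(ckpt, test_set)
    rows[[i]] <- data.frame(se_placement = cfg$se_placement,
                            gating = cfg$gating_enabled,
                            f1 = rep$f1, acc = rep$acc, se = rep$se,
                            sp = rep$sp,
                            n_params = model_n_params(model))
    orders[[i]] <- ckpt$data_order
  }
  out <- do.call(rbind, rows)
  attr(out, "data_order") <- orders  # controlled-comparison audit trail
  out
}
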