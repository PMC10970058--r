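# Training and evaluation: AdamW with optional cosine decay on the hybrid
# cross-entropy/focal objective, per-epoch validation, best-checkpoint
# tracking, and JSON history/manifest output so a run is reproducible from
# its manifest.

#' Training configuration
#'
#' @param variant model variant (`"pegg"`, `"msff"`, or a backbone preset)
#' @param epochs training epochs (0 = evaluation-only pass)
#' @param batch_size minibatch size
#' @param lr peak AdamW learning rate
#' @param weight_decay decoupled weight decay (skipped for biases, gains
#'   and layer-scale parameters)
#' @param schedule `"cosine"` or `"constant"`
#' @param loss a [loss_params()]
#' @param input_size input spatial size, divisible by 32
#' @param drop_path_rate stochastic-depth rate during training
#' @param seeds named list or vector with `split`, `augment`, `init` seeds
#' @param out_dir run directory for history/manifest/checkpoint (created);
#'   `NULL` keeps everything in memory
#' @return an object of class `train_config`
#' @export
train_config <- function(variant = "pegg", epochs = 100L, batch_size = 20L,
                         lr = 5e-4, weight_decay = 0.05,
                         schedule = c("cosine", "constant"),
                         loss = loss_params(alpha = "inverse_frequency"),
                         input_size = 224L, drop_path_rate = 0,
                         seeds = list(split = 0L, augment = 0L, init = 0L),
                         out_dir = NULL) {
  schedule <- match.arg(schedule)
  if (input_size %% 32L != 0L) stop("input_size must be divisible by 32")
  structure(list(variant = variant, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 weight_decay = weight_decay, schedule = schedule,
                 loss = loss, input_size = as.integer(input_size),
                 drop_path_rate = drop_path_rate,
                 seeds = lapply(seeds, as.integer), out_dir = out_dir),
            class = "train_config")
}

build_variant <- function(variant, num_classes = 5L, drop_path_rate = 0) {
  switch(variant,
    pegg = build_pegg(backbone_config("nano", num_classes = num_classes,
                                      drop_path_rate = drop_path_rate)),
    msff = build_pegg(backbone_config("nano", num_classes = num_classes,
                                      drop_path_rate = drop_path_rate),
                      with_gam = FALSE),
    build_backbone(backbone_config(variant, num_classes = num_classes,
                                   drop_path_rate = drop_path_rate))
  )
}

# stack a list of (H, W, 3) arrays into an (H, W, 3, N) batch
stack_images <- function(images) {
  d <- dim(images[[1L]])
  out <- array(0, c(d, length(images)))
  for (i in seq_along(images)) out[, , , i] <- images[[i]]
  out
}

predict_labels <- function(model, images, batch_size = 16L) {
  n <- length(images)
  out <- integer(n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    p <- classify(model, stack_images(images[idx]))
    out[idx] <- max.col(p, ties.method = "first")
  }
  factor(egg_labels()[out], levels = egg_labels())
}

eval_accuracy <- function(model, dataset, batch_size = 16L) {
  pred <- predict_labels(model, dataset$images, batch_size)
  mean(pred == dataset$labels)
}

#' Train a model
#'
#' Minimises the combined cross-entropy/focal objective with AdamW,
#' evaluating on the validation set after every epoch and keeping the
#' best-validation-accuracy weights. When `config$out_dir` is set, writes
#' `history.json` (per-epoch combined/CE/FL losses and accuracies),
#' `manifest.json` (full configuration and seeds) and `checkpoint.rds`.
#'
#' @param config a [train_config()]
#' @param train_data dataset list (`images`, `labels`); images must match
#'   `config$input_size`. Missing data is an error suggesting
#'   [generate_synthetic_dataset()].
#' @param val_data validation dataset; defaults to `train_data`
#' @param stop_at_train_acc optionally stop early once training accuracy
#'   reaches this value (e.g. 1.0 for an overfitting smoke test)
#' @param verbose print per-epoch progress
#' @return list with `model`, `history` (data.frame), `best` (epoch and
#'   accuracy), `manifest`
#' @export
run_training <- function(config, train_data, val_data = NULL,
                         stop_at_train_acc = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "train_config"))
  if (missing(train_data) || is.null(train_data) || !length(train_data$images)) {
    stop("no training data; generate a synthetic set with ",
         "generate_synthetic_dataset() or point to an image folder")
  }
  if (is.null(val_data)) val_data <- train_data
  d1 <- dim(train_data$images[[1L]])
  if (d1[1L] != config$input_size) {
    stop(sprintf("images are %dx%d but config$input_size is %d",
                 d1[1L], d1[2L], config$input_size))
  }
  model <- build_variant(config$variant, drop_path_rate = config$drop_path_rate)
  init_parameters(model, config$seeds$init)

  params <- config$loss
  if (is.character(params$alpha)) {
    params$alpha <- resolve_alpha(params, as.integer(as_egg_factor(train_data$labels)), 5L)
  }
  labels <- as.integer(as_egg_factor(train_data$labels))
  n <- length(labels)
  hist <- list()
  best <- list(epoch = 0L, val_acc = -Inf)
  best_state <- NULL
  set.seed(config$seeds$init + 1L)
  step <- 0L
  for (epoch in seq_len(config$epochs)) {
    lr <- if (config$schedule == "cosine") {
      config$lr * 0.5 * (1 + cos(pi * (epoch - 1) / max(config$epochs, 1L)))
    } else {
      config$lr
    }
    ord <- sample.int(n)
    ep_loss <- ep_ce <- ep_fl <- 0
    correct <- 0L
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      x <- stack_images(train_data$images[idx])
      zero_grads(model)
      logits <- nn_forward(model, x, training = TRUE)
      lg <- softmax_loss_grad(logits, labels[idx], params)
      nn_bw(model, lg$grad, need_dx = FALSE)
      step <- step + 1L
      adamw_step(model, lr = lr, weight_decay = config$weight_decay, t = step)
      clear_caches(model)
      w <- length(idx) / n
      ep_loss <- ep_loss + lg$loss * w
      ep_ce <- ep_ce + lg$ce * w
      ep_fl <- ep_fl + lg$fl * w
      correct <- correct + sum(max.col(lg$prob, ties.method = "first") == labels[idx])
    }
    train_acc <- correct / n
    val_acc <- eval_accuracy(model, val_data)
    hist[[epoch]] <- data.frame(epoch = epoch, lr = lr, loss = ep_loss,
                                ce = ep_ce, fl = ep_fl,
                                train_acc = train_acc, val_acc = val_acc)
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f (ce %.4f, fl %.4f)  train %.3f  val %.3f",
                      epoch, ep_loss, ep_ce, ep_fl, train_acc, val_acc))
    }
    if (val_acc > best$val_acc) {
      best <- list(epoch = epoch, val_acc = val_acc)
      best_state <- get_state(model)
    }
    if (!is.null(stop_at_train_acc) && train_acc >= stop_at_train_acc) break
  }
  if (!is.null(best_state)) set_state(model, best_state)
  history <- if (length(hist)) do.call(rbind, hist) else
    data.frame(epoch = integer(), lr = numeric(), loss = numeric(),
               ce = numeric(), fl = numeric(), train_acc = numeric(),
               val_acc = numeric())
  manifest <- list(package = "peggnet",
                   version = as.character(utils::packageVersion("peggnet")),
                   config = unclass(config[setdiff(names(config), "loss")]),
                   loss = unclass(params),
                   n_train = n, n_val = length(val_data$images),
                   parameters = count_parameters(model))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(history, file.path(config$out_dir, "history.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    save_checkpoint(model, file.path(config$out_dir, "checkpoint.rds"),
                    variant = config$variant)
  }
  list(model = model, history = history, best = best, manifest = manifest)
}

#' Save / load model checkpoints
#'
#' A checkpoint stores the variant name and the full state from
#' [get_state()]; loading rebuilds the architecture and restores weights.
#'
#' @param model an initialised model
#' @param path file path (`.rds`)
#' @param variant variant name recorded alongside the weights
#' @return `save_checkpoint`: the path, invisibly; `load_checkpoint`: the
#'   restored model
#' @export
save_checkpoint <- function(model, path, variant = "pegg") {
  saveRDS(list(variant = variant, state = get_state(model)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_variant(ck$variant)
  set_state(model, ck$state)
  model
}

#' Evaluate a model on a labelled dataset
#'
#' Predicts every image, builds the five-class confusion matrix and its
#' three-grade consolidation, and returns both report tables (per-class F1
#' plus accuracy, with the model's rounded parameter count).
#'
#' @param model an initialised model, or a checkpoint path
#' @param dataset dataset list (`images`, `labels`)
#' @param model_name label used in the report tables
#' @return list of class `peggnet_evaluation` with elements `cm5`, `cm3`,
#'   `classification` and `grading` reports, `accuracy5`, `accuracy3`,
#'   `param_count`
#' @export
evaluate_checkpoint <- function(model, dataset, model_name = NULL) {
  if (is.character(model)) {
    if (is.null(model_name)) model_name <- basename(model)
    model <- load_checkpoint(model)
  }
  if (is.null(model_name)) model_name <- model$kind
  pred <- predict_labels(model, dataset$images)
  truth <- as_egg_factor(dataset$labels)
  cm5 <- confusion(truth, pred, labels = egg_labels())
  cm3 <- consolidate_grades(cm5)
  np <- count_parameters(model)
  structure(list(
    cm5 = cm5, cm3 = cm3,
    classification = classification_report(cm5, model_name, np),
    grading = classification_report(cm3, model_name, np),
    accuracy5 = accuracy(cm5), accuracy3 = accuracy(cm3),
    param_count = np
  ), class = "peggnet_evaluation")
}

#' @export
print.peggnet_evaluation <- function(x, ...) {
  cat("Classification (5 classes):\n")
  print(x$classification)
  cat("\nGrading (3 grades):\n")
  print(x$grading)
  invisible(x)
}

#' Write evaluation reports as CSV
#'
#' @param evaluation a `peggnet_evaluation`
#' @param dir output directory
#' @return invisibly, the written paths
#' @export
write_evaluation <- function(evaluation, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, "classification_report.csv")
  p2 <- file.path(dir, "grading_report.csv")
  utils::write.csv(evaluation$classification, p1, row.names = FALSE)
  utils::write.csv(evaluation$grading, p2, row.names = FALSE)
  invisible(c(p1, p2))
}
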