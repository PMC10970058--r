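# Configurable ConvNeXt feature extractor: 4x4/stride-4 patchify stem,
# four stages of residual blocks with LN + 2x2/stride-2 downsamplers in
# between, global-average-pool head. Six named sizes are provided; "nano"
# is the reduced [64,128,256,512] dimensioning used by the grading network.

convnext_presets <- list(
  tiny   = list(depths = c(3L, 3L, 9L, 3L),  dims = c(96L, 192L, 384L, 768L)),
  small  = list(depths = c(3L, 3L, 27L, 3L), dims = c(96L, 192L, 384L, 768L)),
  base   = list(depths = c(3L, 3L, 27L, 3L), dims = c(128L, 256L, 512L, 1024L)),
  large  = list(depths = c(3L, 3L, 27L, 3L), dims = c(192L, 384L, 768L, 1536L)),
  xlarge = list(depths = c(3L, 3L, 27L, 3L), dims = c(256L, 512L, 1024L, 2048L)),
  nano   = list(depths = c(3L, 3L, 9L, 3L),  dims = c(64L, 128L, 256L, 512L))
)

#' Backbone configuration
#'
#' Per-stage block counts and feature dimensions, the knob distinguishing
#' the ConvNeXt variants. Either give a named `preset` (`"tiny"`, `"small"`,
#' `"base"`, `"large"`, `"xlarge"`, `"nano"`) or explicit `depths`/`dims`.
#'
#' @param preset optional preset name
#' @param depths 4 positive integers, block repeats per stage
#' @param dims 4 positive integers, output channels per stage
#' @param num_classes width of the classification head (5 for the
#'   preserved-egg task)
#' @param drop_path_rate stochastic-depth rate in `[0, 1)`; the per-block
#'   rate increases linearly with depth up to this value
#' @param layer_scale_init initial value of the per-channel residual scale
#' @return an object of class `backbone_config`
#' @examples
#' cfg <- backbone_config("nano")
#' cfg$dims
#' @export
backbone_config <- function(preset = NULL, depths = NULL, dims = NULL,
                            num_classes = 5L, drop_path_rate = 0,
                            layer_scale_init = 1e-6) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, names(convnext_presets))
    p <- convnext_presets[[preset]]
    if (is.null(depths)) depths <- p$depths
    if (is.null(dims)) dims <- p$dims
  }
  if (length(depths) != 4L || length(dims) != 4L) {
    stop("depths and dims must each have length 4")
  }
  depths <- as.integer(depths)
  dims <- as.integer(dims)
  if (any(depths <= 0L) || any(dims <= 0L)) stop("depths and dims must be positive")
  if (num_classes <= 0L) stop("num_classes must be positive")
  if (drop_path_rate < 0 || drop_path_rate >= 1) stop("drop_path_rate must be in [0, 1)")
  structure(list(preset = preset, depths = depths, dims = dims,
                 num_classes = as.integer(num_classes),
                 drop_path_rate = drop_path_rate,
                 layer_scale_init = layer_scale_init),
            class = "backbone_config")
}

stage_blocks <- function(dim, n, dp_rates, layer_scale_init) {
  blocks <- lapply(seq_len(n), function(i) {
    mod_block(dim, drop_path = dp_rates[i], layer_scale_init = layer_scale_init)
  })
  names(blocks) <- sprintf("b%d", seq_len(n))
  mod_seq(blocks)
}

build_trunk <- function(cfg) {
  total <- sum(cfg$depths)
  dp <- if (cfg$drop_path_rate > 0) {
    seq(0, cfg$drop_path_rate, length.out = total)
  } else {
    rep(0, total)
  }
  off <- c(0L, cumsum(cfg$depths))
  children <- list(stem = mod_stem(3L, cfg$dims[1L]))
  for (i in 1:4) {
    if (i > 1L) {
      children[[sprintf("down%d", i - 1L)]] <-
        mod_downsample(cfg$dims[i - 1L], cfg$dims[i])
    }
    children[[sprintf("stage%d", i)]] <-
      stage_blocks(cfg$dims[i], cfg$depths[i], dp[(off[i] + 1L):off[i + 1L]],
                   cfg$layer_scale_init)
  }
  children
}

#' Build a ConvNeXt backbone
#'
#' Assembles the feature extractor plus classification head described by a
#' [backbone_config()]. The returned model is uninitialised (weights are
#' materialised by [init_parameters()]), so even the largest variants can be
#' built and counted cheaply.
#'
#' @param config a [backbone_config()]
#' @return a model handle (class `peggnet_module`)
#' @examples
#' model <- build_backbone(backbone_config("nano"))
#' format_param_count(count_parameters(model))  # "12.5M"
#' @export
build_backbone <- function(config) {
  stopifnot(inherits(config, "backbone_config"))
  children <- build_trunk(config)
  children$head <- mod_head(config$dims[4L], config$num_classes)
  new_module("backbone", cfg = config, children = children)
}

check_image_input <- function(x) {
  d <- dim(x)
  if (d[3L] != 3L) stop(sprintf("expected 3 input channels, got %d", d[3L]))
  if (d[1L] %% 32L != 0L || d[2L] %% 32L != 0L) {
    stop(sprintf("input spatial size %dx%d is not divisible by 32", d[1L], d[2L]))
  }
  invisible(NULL)
}

trunk_features <- function(m, x, training = FALSE) {
  feats <- vector("list", 4L)
  h <- nn_fw(m$children$stem, x, training)
  h <- nn_fw(m$children$stage1, h, training)
  feats[[1L]] <- h
  for (i in 2:4) {
    h <- nn_fw(m$children[[sprintf("down%d", i - 1L)]], h, training)
    h <- nn_fw(m$children[[sprintf("stage%d", i)]], h, training)
    feats[[i]] <- h
  }
  feats
}

nn_fw.mod_backbone <- function(m, x, training = FALSE) {
  check_image_input(x)
  feats <- trunk_features(m, x, training)
  nn_fw(m$children$head, feats[[4L]], training)
}

nn_bw.mod_backbone <- function(m, dy, need_dx = FALSE) {
  dh <- nn_bw(m$children$head, dy, need_dx = TRUE)
  for (i in 4:2) {
    dh <- nn_bw(m$children[[sprintf("stage%d", i)]], dh, need_dx = TRUE)
    dh <- nn_bw(m$children[[sprintf("down%d", i - 1L)]], dh, need_dx = TRUE)
  }
  dh <- nn_bw(m$children$stage1, dh, need_dx = TRUE)
  nn_bw(m$children$stem, dh, need_dx = need_dx)
}

#' Per-stage feature maps
#'
#' Runs an image batch through a backbone (or the trunk of the grading
#' network) and returns the outputs of the four stages. For an input of
#' spatial size `S` (divisible by 32) the stage outputs have sizes `S/4`,
#' `S/8`, `S/16`, `S/32` with channel counts `dims[1..4]`.
#'
#' @param model a model from [build_backbone()] or [build_pegg()]
#' @param x image array `(H, W, 3)` or batch `(H, W, 3, N)`
#' @return list of four activation arrays `(H_i, W_i, C_i, N)`
#' @export
forward_features <- function(model, x) {
  stopifnot(inherits(model, "peggnet_module"))
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  check_image_input(x)
  if (!is_initialized(model)) stop("model parameters not initialised; call init_parameters()")
  trunk_features(model, x, training = FALSE)
}
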