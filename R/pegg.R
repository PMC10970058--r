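# The preserved-egg grading network: a "nano" [64,128,256,512] ConvNeXt
# trunk, global attention on the stage-2 and stage-3 lateral maps, a
# two-step multi-scale feature-fusion neck, and a 5-way head.
#
# Channel plan (frozen; it fixes the published parameter budget):
#   fusion 1: stage-4 map (512 ch, S/32) -> 1x1 conv to 256 ch + 2x upsample,
#             concatenated with the attended stage-3 map (256 ch, S/16)
#             -> 512 ch, refined by three ConvNeXt blocks at width 512;
#   fusion 2: fused map -> 1x1 conv to 128 ch + 2x upsample, concatenated
#             with the attended stage-2 map (128 ch, S/8) -> 256 ch,
#             refined by three ConvNeXt blocks at width 256;
#   head: global average pool -> LN -> linear to 5 logits.

#' Multi-scale feature-fusion configuration
#'
#' @param fusion_block_count ConvNeXt blocks per fusion step (3 in the
#'   published model)
#' @param fuse1_channels width of the first fused stream (512)
#' @param fuse2_channels width of the second fused stream (256)
#' @param upsample_mode `"bilinear"` (default) or `"nearest"`
#' @return an object of class `msff_config`
#' @export
msff_config <- function(fusion_block_count = 3L, fuse1_channels = 512L,
                        fuse2_channels = 256L,
                        upsample_mode = c("bilinear", "nearest")) {
  upsample_mode <- match.arg(upsample_mode)
  stopifnot(fusion_block_count >= 1L, fuse1_channels >= 2L, fuse2_channels >= 2L)
  structure(list(fusion_block_count = as.integer(fusion_block_count),
                 fuse1_channels = as.integer(fuse1_channels),
                 fuse2_channels = as.integer(fuse2_channels),
                 upsample_mode = upsample_mode),
            class = "msff_config")
}

#' Reduce channels and double spatial extent
#'
#' The neck's lateral transition: a 1x1 convolution to `target_channels`
#' followed by 2x spatial interpolation, e.g. `(512, 7, 7) -> (256, 14, 14)`.
#'
#' @param cin input channel count
#' @param target_channels output channel count (positive)
#' @param mode interpolation mode
#' @return a module; apply with [nn_forward()]
#' @export
build_reduce_upsample <- function(cin, target_channels,
                                  mode = c("bilinear", "nearest")) {
  mod_reduce_upsample(cin, target_channels, match.arg(mode))
}

#' Build a fusion step
#'
#' Channel-concatenates two same-size streams in a fixed order (upsampled
#' deep stream first, lateral stream second) and refines the result with
#' `n_blocks` ConvNeXt blocks at the concatenated width. Apply with
#' [nn_forward()] on `list(a, b)`.
#'
#' @param c_a,c_b channel counts of the two streams
#' @param n_blocks number of ConvNeXt blocks
#' @param layer_scale_init residual-scale initial value
#' @return a module
#' @export
build_fuse <- function(c_a, c_b, n_blocks = 3L, layer_scale_init = 1e-6) {
  mod_fuse(c_a, c_b, n_blocks = n_blocks, layer_scale_init = layer_scale_init)
}

#' Build the preserved-egg grading network
#'
#' Assembles the full model: nano backbone trunk, attention on the stage-2
#' and stage-3 lateral maps (`with_gam = FALSE` gives the fusion-only
#' ablation), the two fusion steps, and the 5-class head.
#'
#' @param backbone_cfg a [backbone_config()]; the published model uses
#'   `backbone_config("nano")`
#' @param gam2_cfg,gam3_cfg [gam_config()]s for the stage-2 (128 ch) and
#'   stage-3 (256 ch) placements; defaults fix the bottleneck width at 8
#' @param msff_cfg an [msff_config()]
#' @param with_gam include the attention modules (`FALSE` for the ablation)
#' @return a model handle (class `peggnet_module`)
#' @examples
#' model <- build_pegg()
#' format_param_count(count_parameters(model))  # "21.0M"
#' @export
build_pegg <- function(backbone_cfg = backbone_config("nano"),
                       gam2_cfg = gam_config(backbone_cfg$dims[2L]),
                       gam3_cfg = gam_config(backbone_cfg$dims[3L]),
                       msff_cfg = msff_config(),
                       with_gam = TRUE) {
  dims <- backbone_cfg$dims
  if (msff_cfg$fuse1_channels != 2L * dims[3L] ||
      msff_cfg$fuse2_channels != 2L * dims[2L]) {
    stop("backbone dims incompatible with the fusion channel plan: need ",
         "fuse1_channels == 2*dims[3] and fuse2_channels == 2*dims[2]")
  }
  if (with_gam) {
    if (gam2_cfg$channels != dims[2L] || gam3_cfg$channels != dims[3L]) {
      stop("gam configs must match stage-2 and stage-3 channel counts")
    }
  }
  lsi <- backbone_cfg$layer_scale_init
  children <- build_trunk(backbone_cfg)
  children$ru1 <- mod_reduce_upsample(dims[4L], dims[3L], msff_cfg$upsample_mode)
  children$fuse1 <- mod_fuse(dims[3L], dims[3L],
                             n_blocks = msff_cfg$fusion_block_count,
                             layer_scale_init = lsi)
  children$ru2 <- mod_reduce_upsample(msff_cfg$fuse1_channels, dims[2L],
                                      msff_cfg$upsample_mode)
  children$fuse2 <- mod_fuse(dims[2L], dims[2L],
                             n_blocks = msff_cfg$fusion_block_count,
                             layer_scale_init = lsi)
  children$head <- mod_head(msff_cfg$fuse2_channels, backbone_cfg$num_classes)
  if (with_gam) {
    children$gam2 <- mod_gam(gam2_cfg)
    children$gam3 <- mod_gam(gam3_cfg)
  }
  new_module("pegg", cfg = backbone_cfg, msff = msff_cfg, with_gam = with_gam,
             children = children)
}

nn_fw.mod_pegg <- function(m, x, training = FALSE) {
  check_image_input(x)
  feats <- trunk_features(m, x, training)
  g3 <- if (m$with_gam) nn_fw(m$children$gam3, feats[[3L]], training) else feats[[3L]]
  g2 <- if (m$with_gam) nn_fw(m$children$gam2, feats[[2L]], training) else feats[[2L]]
  u1 <- nn_fw(m$children$ru1, feats[[4L]], training)
  f1 <- nn_fw(m$children$fuse1, list(u1, g3), training)
  u2 <- nn_fw(m$children$ru2, f1, training)
  f2 <- nn_fw(m$children$fuse2, list(u2, g2), training)
  nn_fw(m$children$head, f2, training)
}

nn_bw.mod_pegg <- function(m, dy, need_dx = FALSE) {
  df2 <- nn_bw(m$children$head, dy, need_dx = TRUE)
  d2 <- nn_bw(m$children$fuse2, df2, need_dx = TRUE)
  df1 <- nn_bw(m$children$ru2, d2[[1L]], need_dx = TRUE)
  d1 <- nn_bw(m$children$fuse1, df1, need_dx = TRUE)
  ds4 <- nn_bw(m$children$ru1, d1[[1L]], need_dx = TRUE)
  dg3 <- if (m$with_gam) nn_bw(m$children$gam3, d1[[2L]], need_dx = TRUE) else d1[[2L]]
  dg2 <- if (m$with_gam) nn_bw(m$children$gam2, d2[[2L]], need_dx = TRUE) else d2[[2L]]
  ds3 <- nn_bw(m$children$stage4, ds4, need_dx = TRUE)
  ds3 <- nn_bw(m$children$down3, ds3, need_dx = TRUE) + dg3
  ds2 <- nn_bw(m$children$stage3, ds3, need_dx = TRUE)
  ds2 <- nn_bw(m$children$down2, ds2, need_dx = TRUE) + dg2
  ds1 <- nn_bw(m$children$stage2, ds2, need_dx = TRUE)
  ds1 <- nn_bw(m$children$down1, ds1, need_dx = TRUE)
  ds0 <- nn_bw(m$children$stage1, ds1, need_dx = TRUE)
  nn_bw(m$children$stem, ds0, need_dx = need_dx)
}

#' Classify candling images
#'
#' Softmax class probabilities over the five internal-quality classes (or
#' however many classes the model's head has). Deterministic in evaluation
#' mode. Input spatial size must be divisible by 32 (preprocessed images;
#' see [preprocess_image()]).
#'
#' @param model an initialised model from [build_pegg()] or
#'   [build_backbone()]
#' @param image array `(H, W, 3)` or batch `(H, W, 3, N)`
#' @return an `N x K` matrix of probabilities (rows sum to 1), with class
#'   labels as column names when `K = 5`
#' @export
classify <- function(model, image) {
  stopifnot(inherits(model, "peggnet_module"))
  logits <- nn_forward(model, image, training = FALSE)
  p <- softmax_rows(logits)
  if (ncol(p) == 5L) colnames(p) <- egg_labels()
  p
}

#' Parameter counts of the named model variants
#'
#' Builds the requested variant with a 5-class head and reports its exact
#' and 0.1M-rounded trainable parameter count. `"msff"` is the fusion-only
#' ablation of the grading network (no attention); `"pegg"` is the full
#' model.
#'
#' @param variant one of `"tiny"`, `"small"`, `"base"`, `"large"`,
#'   `"xlarge"`, `"nano"`, `"msff"`, `"pegg"`
#' @return list with elements `variant`, `exact`, `millions`, `formatted`
#' @export
count_params_variant <- function(variant) {
  valid <- c(names(convnext_presets), "msff", "pegg")
  if (!is.character(variant) || length(variant) != 1L || !variant %in% valid) {
    stop("unknown variant; valid names: ", paste(valid, collapse = ", "))
  }
  model <- switch(variant,
    msff = build_pegg(with_gam = FALSE),
    pegg = build_pegg(),
    build_backbone(backbone_config(variant))
  )
  n <- count_parameters(model)
  list(variant = variant, exact = n, millions = floor(n / 1e5 + 0.5) / 10,
       formatted = format_param_count(n))
}
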