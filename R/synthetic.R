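# Seeded synthetic candling-image generator. Renders the five transmitted-
# light phenotypes as simple parametric scenes: a dark box background, an
# elliptical egg silhouette with a soft shell falloff, a bright air-chamber
# cap, a class-conditional translucent albumen colour, an opaque yolk disk
# whose boundary is an angular harmonic curve, and optional yolk-rim
# recolouring. Not a light-transport simulation: it reproduces the
# *relative* pixel statistics that distinguish the classes (dark IP,
# pale PP, reddish QP, ragged yolk boundary BYP, yellow rim YYP) so that
# classifiers and the training loop can be exercised end to end.

#' Synthetic candling-image parameters
#'
#' Appearance parameters shared by all classes; per-class differences
#' (albumen colour and translucency, yolk-boundary irregularity, rim hue
#' shift, global opacity) are built in. All randomness (geometry jitter,
#' boundary harmonics, pixel noise) derives from `seed`, so a given
#' `(params, counts)` pair renders identical pixels on every call.
#'
#' @param size square image size in pixels (default 224)
#' @param background dark-box background level
#' @param noise_sd pixel noise standard deviation
#' @param byp_boundary_amp relative amplitude of the yolk-boundary
#'   harmonics for broken-yolk (BYP) eggs; other classes use
#'   `base_boundary_amp`
#' @param base_boundary_amp boundary jitter for non-BYP classes
#' @param seed integer RNG seed
#' @return an object of class `synthetic_egg_params`
#' @export
synthetic_egg_params <- function(size = 224L, background = 0.03,
                                 noise_sd = 0.015, byp_boundary_amp = 0.16,
                                 base_boundary_amp = 0.02, seed = 0L) {
  size <- as.integer(size)
  if (size <= 0L) stop("image size must be positive")
  structure(list(size = size, background = background, noise_sd = noise_sd,
                 byp_boundary_amp = byp_boundary_amp,
                 base_boundary_amp = base_boundary_amp,
                 seed = as.integer(seed)),
            class = "synthetic_egg_params")
}

# class-conditional albumen transmission colours (R, G, B)
albumen_colour <- function(label) {
  switch(label,
    QP = c(0.88, 0.42, 0.14),   # reddish/orange translucency
    PP = c(0.42, 0.38, 0.16),   # weak pale-yellow translucency
    BYP = c(0.84, 0.44, 0.15),
    YYP = c(0.82, 0.46, 0.16),
    IP = c(0.10, 0.08, 0.06)    # near-total opacity
  )
}

render_egg <- function(label, p) {
  s <- p$size
  xs <- (rep(seq_len(s), each = s) - 0.5) / s   # column coordinate
  ys <- (rep(seq_len(s), times = s) - 0.5) / s  # row coordinate
  cx <- 0.5 + stats::runif(1, -0.02, 0.02)
  cy <- 0.52 + stats::runif(1, -0.02, 0.02)
  ea <- 0.30 + stats::runif(1, -0.02, 0.02)     # semi-axis along x
  eb <- 0.40 + stats::runif(1, -0.02, 0.02)     # semi-axis along y
  e <- ((xs - cx) / ea)^2 + ((ys - cy) / eb)^2
  shell <- pmin(pmax((1 - e) * 6, 0), 1)        # soft silhouette

  # yolk: harmonic-perturbed disk in the lower half of the egg
  yx <- cx + stats::runif(1, -0.01, 0.01)
  yy <- cy + 0.10 + stats::runif(1, -0.01, 0.01)
  ry <- 0.16 + stats::runif(1, -0.01, 0.01)
  amp <- if (label == "BYP") p$byp_boundary_amp else p$base_boundary_amp
  theta <- atan2(ys - yy, xs - yx)
  rmod <- 1
  for (k in 2:5) {
    rmod <- rmod + amp * stats::runif(1, 0.3, 1) * sin(k * theta + stats::runif(1, 0, 2 * pi))
  }
  rho <- sqrt((xs - yx)^2 + ((ys - yy) * 0.92)^2) / ry
  yolk <- as.numeric(rho <= rmod)

  # air chamber: bright cap at the top of the egg
  cap <- as.numeric(e <= 1 & ys < cy - 0.62 * eb)

  col <- albumen_colour(label)
  img <- array(p$background, c(s, s, 3L))
  falloff <- (1 - 0.45 * pmin(e, 1))
  for (ch in 1:3) {
    plane <- p$background + shell * col[ch] * falloff
    if (label != "IP") {
      plane <- plane * (1 - 0.88 * yolk * shell)        # opaque yolk
      plane <- plane + cap * shell * c(0.10, 0.10, 0.08)[ch]
    } else {
      plane <- plane + cap * shell * 0.02               # faint cap only
    }
    if (label == "YYP") {
      ring <- as.numeric(rho > 0.85 * rmod & rho <= 1.18 * rmod)
      plane <- plane + ring * shell * c(0.30, 0.34, 0.04)[ch]
    }
    img[, , ch] <- plane
  }
  img <- img + stats::rnorm(length(img), 0, p$noise_sd)
  pmin(pmax(img, 0), 1)
}

#' Generate a synthetic candling dataset
#'
#' Renders `counts[label]` images per class under the given parameters.
#' Deterministic for a fixed `(params, counts)`.
#'
#' @param params a [synthetic_egg_params()]
#' @param counts named integer vector of per-class image counts; names in
#'   `QP, PP, BYP, YYP, IP` (missing classes get 0)
#' @return dataset list with `images` and `labels`
#' @examples
#' ds <- generate_synthetic_dataset(synthetic_egg_params(size = 64, seed = 1),
#'                                  c(QP = 2, IP = 2))
#' table(ds$labels)
#' @export
generate_synthetic_dataset <- function(params = synthetic_egg_params(),
                                       counts = c(QP = 4, PP = 4, BYP = 4,
                                                  YYP = 4, IP = 4)) {
  stopifnot(inherits(params, "synthetic_egg_params"))
  if (is.null(names(counts))) stop("counts must be named by class label")
  bad <- setdiff(names(counts), egg_labels())
  if (length(bad)) stop("unknown labels in counts: ", paste(bad, collapse = ", "))
  if (any(counts < 0)) stop("counts must be nonnegative")
  full <- stats::setNames(rep(0L, 5L), egg_labels())
  full[names(counts)] <- as.integer(counts)
  set.seed(params$seed)
  images <- vector("list", sum(full))
  labels <- character(sum(full))
  k <- 0L
  for (cl in egg_labels()) {
    for (i in seq_len(full[[cl]])) {
      k <- k + 1L
      images[[k]] <- render_egg(cl, params)
      labels[k] <- cl
    }
  }
  list(images = images, labels = factor(labels, levels = egg_labels()))
}

#' Write a synthetic dataset to a directory-per-class folder
#'
#' @param dataset from [generate_synthetic_dataset()]
#' @param root output directory (created if needed)
#' @return invisibly, the written file paths
#' @export
write_image_folder <- function(dataset, root) {
  paths <- character(length(dataset$images))
  counter <- stats::setNames(rep(0L, 5L), egg_labels())
  for (i in seq_along(dataset$images)) {
    cl <- as.character(dataset$labels[i])
    dir.create(file.path(root, cl), recursive = TRUE, showWarnings = FALSE)
    counter[cl] <- counter[cl] + 1L
    paths[i] <- file.path(root, cl, sprintf("%s_%03d.png", tolower(cl), counter[cl]))
    write_rgb_image(dataset$images[[i]], paths[i])
  }
  invisible(paths)
}
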