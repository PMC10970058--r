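# Dataset plumbing: the five-class taxonomy and its grade surjection,
# per-class 7:2:1 splitting, seeded tenfold augmentation, and a
# directory-per-class image loader.
#
# A dataset is a plain list with elements `images` (list of (H, W, 3)
# arrays in [0, 1]) and `labels` (factor over the five classes), plus an
# optional `paths` character vector.

#' The five internal-quality classes
#'
#' Candling phenotypes in their canonical order: qualified (QP), pale (PP),
#' broken-yolk (BYP), yellow-yolk (YYP) and inferior (IP) preserved eggs.
#'
#' @return character vector of the five class labels
#' @export
egg_labels <- function() c("QP", "PP", "BYP", "YYP", "IP")

#' The three sorting grades
#'
#' @return character vector `c("QP", "SP", "IP")`
#' @export
egg_grades <- function() c("QP", "SP", "IP")

#' Map classes to grades
#'
#' The total surjection used for sorting: QP stays QP, the three
#' substandard classes (PP, BYP, YYP) collapse to SP, IP stays IP.
#'
#' @param labels factor or character vector of class labels
#' @return factor of grades with levels `QP, SP, IP`
#' @export
egg_grade <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), egg_labels())
  if (length(bad)) stop("unknown labels: ", paste(bad, collapse = ", "))
  map <- c(QP = "QP", PP = "SP", BYP = "SP", YYP = "SP", IP = "IP")
  factor(unname(map[labels]), levels = egg_grades())
}

as_egg_factor <- function(labels) {
  f <- factor(as.character(labels), levels = egg_labels())
  if (anyNA(f)) stop("unknown labels; expected one of: ", paste(egg_labels(), collapse = ", "))
  f
}

#' Split specification
#'
#' Per-class floor-floor-remainder rule: each class contributes
#' `floor(r1 * n)` items to the training set, `floor(r2 * n)` to the
#' validation set, and the remainder to the test set, after a seeded
#' within-class shuffle.
#'
#' @param ratios train/validation/test proportions summing to 1
#'   (default 0.7/0.2/0.1)
#' @param seed integer shuffle seed
#' @return an object of class `split_spec`
#' @export
split_spec <- function(ratios = c(0.7, 0.2, 0.1), seed = 0L) {
  if (length(ratios) != 3L || any(ratios < 0) || abs(sum(ratios) - 1) > 1e-8) {
    stop("ratios must be three nonnegative numbers summing to 1")
  }
  structure(list(ratios = ratios, seed = as.integer(seed)), class = "split_spec")
}

#' Split a labelled collection 7:2:1 per class
#'
#' @param labels factor or character vector of class labels, one per item
#' @param spec a [split_spec()]
#' @return factor of subset assignments (`train`, `validation`, `test`)
#'   aligned with `labels`
#' @examples
#' subsets <- split_dataset(rep(egg_labels(), c(692, 332, 523, 323, 257)),
#'                          split_spec(seed = 1))
#' table(subsets)  # 1487 / 423 / 217
#' @export
split_dataset <- function(labels, spec = split_spec()) {
  stopifnot(inherits(spec, "split_spec"))
  f <- as_egg_factor(labels)
  counts <- table(f)
  if (any(counts == 0)) {
    stop("empty classes: ", paste(levels(f)[counts == 0], collapse = ", "))
  }
  out <- factor(rep(NA_character_, length(f)),
                levels = c("train", "validation", "test"))
  set.seed(spec$seed)
  for (cl in levels(f)) {
    idx <- which(f == cl)
    idx <- idx[sample.int(length(idx))]
    n <- length(idx)
    ntr <- floor(spec$ratios[1L] * n)
    nva <- floor(spec$ratios[2L] * n)
    out[idx[seq_len(ntr)]] <- "train"
    if (nva > 0) out[idx[ntr + seq_len(nva)]] <- "validation"
    if (n > ntr + nva) out[idx[(ntr + nva + 1L):n]] <- "test"
  }
  out
}

#' Tabulate a split
#'
#' Class-by-subset count table in the conventional report layout (rows
#' train/validation/test/total, columns per class plus a total).
#'
#' @param labels class labels
#' @param subsets assignment factor from [split_dataset()]
#' @return integer matrix
#' @export
split_table <- function(labels, subsets) {
  f <- as_egg_factor(labels)
  tab <- table(subsets, f)
  m <- rbind(tab, Total = colSums(tab))
  m <- cbind(m, Total = rowSums(m))
  storage.mode(m) <- "integer"
  m
}

#' Augmentation specification
#'
#' Each source image yields `factor` copies; the first is the identity and
#' each further copy applies, independently with probability 1/2 each:
#' horizontal flip, vertical flip, rotation by a uniform angle in
#' `rotation` degrees (bilinear, black fill), contrast scaling and
#' brightness scaling with factors uniform in the given ranges.
#'
#' @param factor copies per image (>= 1); 10 reproduces the tenfold
#'   expansion of the training set
#' @param rotation max absolute rotation in degrees
#' @param brightness,contrast multiplicative factor ranges
#' @param seed integer RNG seed; the augmented set is reproducible
#'   bit-for-bit under a fixed seed
#' @return an object of class `augment_spec`
#' @export
augment_spec <- function(factor = 10L, rotation = 30, brightness = c(0.8, 1.2),
                         contrast = c(0.8, 1.2), seed = 0L) {
  if (factor < 1L) stop("factor must be >= 1")
  structure(list(factor = as.integer(factor), rotation = rotation,
                 brightness = brightness, contrast = contrast,
                 seed = as.integer(seed)),
            class = "augment_spec")
}

flip_h <- function(img) img[, rev(seq_len(dim(img)[2L])), , drop = FALSE]
flip_v <- function(img) img[rev(seq_len(dim(img)[1L])), , , drop = FALSE]

# Bilinear rotation about the image centre, black fill outside the frame.
rotate_image <- function(img, degrees) {
  d <- dim(img)
  h <- d[1L]
  w <- d[2L]
  th <- degrees * pi / 180
  cy <- (h + 1) / 2
  cx <- (w + 1) / 2
  gy <- rep(seq_len(h), times = w) - cy
  gx <- rep(seq_len(w), each = h) - cx
  sy <- cos(th) * gy - sin(th) * gx + cy
  sx <- sin(th) * gy + cos(th) * gx + cx
  y0 <- floor(sy)
  x0 <- floor(sx)
  fy <- sy - y0
  fx <- sx - x0
  out <- array(0, d)
  gather <- function(yy, xx) {
    ok <- yy >= 1 & yy <= h & xx >= 1 & xx <= w
    yy <- pmin(pmax(yy, 1L), h)
    xx <- pmin(pmax(xx, 1L), w)
    base <- yy + (xx - 1L) * h
    function(ch) {
      v <- img[base + (ch - 1L) * h * w]
      v[!ok] <- 0
      v
    }
  }
  g00 <- gather(y0, x0)
  g01 <- gather(y0, x0 + 1L)
  g10 <- gather(y0 + 1L, x0)
  g11 <- gather(y0 + 1L, x0 + 1L)
  for (ch in seq_len(d[3L])) {
    v <- (1 - fy) * (1 - fx) * g00(ch) + (1 - fy) * fx * g01(ch) +
      fy * (1 - fx) * g10(ch) + fy * fx * g11(ch)
    out[, , ch] <- v
  }
  out
}

adjust_brightness <- function(img, f) pmin(pmax(img * f, 0), 1)

adjust_contrast <- function(img, f) {
  m <- mean(img)
  pmin(pmax((img - m) * f + m, 0), 1)
}

augment_one <- function(img, spec) {
  if (stats::runif(1) < 0.5) img <- flip_h(img)
  if (stats::runif(1) < 0.5) img <- flip_v(img)
  if (stats::runif(1) < 0.5) {
    img <- rotate_image(img, stats::runif(1, -spec$rotation, spec$rotation))
  }
  if (stats::runif(1) < 0.5) {
    img <- adjust_contrast(img, stats::runif(1, spec$contrast[1L], spec$contrast[2L]))
  }
  if (stats::runif(1) < 0.5) {
    img <- adjust_brightness(img, stats::runif(1, spec$brightness[1L], spec$brightness[2L]))
  }
  img
}

#' Augment a training set
#'
#' Expands a labelled image set `factor`-fold (1487 training images with
#' the default factor 10 give 14,870 samples). Labels and image dimensions
#' are preserved; the output is deterministic under the spec's seed.
#'
#' @param dataset list with `images` (list of `(H, W, 3)` arrays) and
#'   `labels`
#' @param spec an [augment_spec()]
#' @return an augmented dataset with `source` indices attached
#' @export
augment_training_set <- function(dataset, spec = augment_spec()) {
  stopifnot(inherits(spec, "augment_spec"))
  n <- length(dataset$images)
  labels <- as_egg_factor(dataset$labels)
  stopifnot(length(labels) == n)
  set.seed(spec$seed)
  images <- vector("list", n * spec$factor)
  src <- integer(n * spec$factor)
  k <- 0L
  for (i in seq_len(n)) {
    img <- dataset$images[[i]]
    if (!is.numeric(img) || length(dim(img)) != 3L) {
      stop("unreadable image at index ", i)
    }
    for (j in seq_len(spec$factor)) {
      k <- k + 1L
      images[[k]] <- if (j == 1L) img else augment_one(img, spec)
      src[k] <- i
    }
  }
  list(images = images, labels = labels[src], source = src)
}

# ---- folder IO and preprocessing -------------------------------------

#' Load a directory-per-class image folder
#'
#' `root` must contain one subdirectory per class label (any subset of
#' QP/PP/BYP/YYP/IP; other subdirectory names are an error). Images are
#' decoded to RGB arrays in `[0, 1]`; unreadable files are skipped with a
#' warning.
#'
#' @param root path to the dataset root
#' @return dataset list with `images`, `labels`, `paths`
#' @export
load_image_folder <- function(root) {
  if (!dir.exists(root)) stop("dataset root not found: ", root)
  subdirs <- list.dirs(root, recursive = FALSE, full.names = FALSE)
  bad <- setdiff(subdirs, egg_labels())
  if (length(bad)) {
    stop("unknown class directories (", paste(bad, collapse = ", "),
         "); expected: ", paste(egg_labels(), collapse = ", "))
  }
  images <- list()
  labels <- character()
  paths <- character()
  for (cl in intersect(egg_labels(), subdirs)) {
    files <- list.files(file.path(root, cl), pattern = "\\.(png|jpe?g)$",
                        ignore.case = TRUE, full.names = TRUE)
    if (!length(files)) {
      warning("no images found for class ", cl)
      next
    }
    for (f in files) {
      img <- tryCatch(read_rgb_image(f), error = function(e) {
        warning("skipping unreadable image ", f, ": ", conditionMessage(e))
        NULL
      })
      if (is.null(img)) next
      images[[length(images) + 1L]] <- img
      labels <- c(labels, cl)
      paths <- c(paths, f)
    }
  }
  list(images = images, labels = factor(labels, levels = egg_labels()),
       paths = paths)
}

read_rgb_image <- function(path) {
  im <- EBImage::readImage(path)
  a <- EBImage::imageData(im)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
  if (dim(a)[3L] > 3L) a <- a[, , 1:3, drop = FALSE]
  aperm(a, c(2L, 1L, 3L))  # EBImage stores (x, y, c); we use (H, W, C)
}

write_rgb_image <- function(img, path) {
  EBImage::writeImage(EBImage::Image(aperm(img, c(2L, 1L, 3L)),
                                     colormode = "Color"), path)
}

resize_matrix <- function(n_out, n_in) {
  # bilinear resampling weights, half-pixel centres
  a <- matrix(0, n_out, n_in)
  src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
  i0 <- pmin(pmax(floor(src), 0), n_in - 1)
  i1 <- pmin(i0 + 1, n_in - 1)
  fr <- pmin(pmax(src - i0, 0), 1)
  for (i in seq_len(n_out)) {
    a[i, i0[i] + 1L] <- a[i, i0[i] + 1L] + (1 - fr[i])
    a[i, i1[i] + 1L] <- a[i, i1[i] + 1L] + fr[i]
  }
  a
}

#' Preprocess an image for the network
#'
#' Resizes so the shorter side is `8/7` of the target (256 for a 224
#' input), centre-crops to `size` and optionally standardises channels
#' with training-split statistics.
#'
#' @param img `(H, W, 3)` array in `[0, 1]`
#' @param size target spatial size (divisible by 32)
#' @param stats optional list with `mean` and `sd` length-3 vectors, e.g.
#'   from [channel_stats()]
#' @return `(size, size, 3)` array
#' @export
preprocess_image <- function(img, size = 224L, stats = NULL) {
  d <- dim(img)
  short <- round(size * 8 / 7)
  scale <- short / min(d[1:2])
  h2 <- max(short, round(d[1L] * scale))
  w2 <- max(short, round(d[2L] * scale))
  if (h2 != d[1L] || w2 != d[2L]) {
    x <- array(img, c(d, 1L))
    x <- interp_hw(x, resize_matrix(h2, d[1L]), resize_matrix(w2, d[2L]))
    img <- array(x, c(h2, w2, 3L))
  }
  y0 <- (dim(img)[1L] - size) %/% 2L
  x0 <- (dim(img)[2L] - size) %/% 2L
  img <- img[y0 + seq_len(size), x0 + seq_len(size), , drop = FALSE]
  if (!is.null(stats)) {
    for (ch in 1:3) img[, , ch] <- (img[, , ch] - stats$mean[ch]) / stats$sd[ch]
  }
  img
}

#' Per-channel mean and standard deviation of a dataset
#'
#' Computed from the training split (candling images are unlike natural
#' images, so external-dataset statistics are not used).
#'
#' @param dataset dataset list with `images`
#' @return list with `mean` and `sd` length-3 vectors
#' @export
channel_stats <- function(dataset) {
  sums <- numeric(3L)
  sq <- numeric(3L)
  npx <- 0
  for (img in dataset$images) {
    d <- dim(img)
    m <- matrix(img, d[1L] * d[2L], d[3L])
    sums <- sums + colSums(m)
    sq <- sq + colSums(m * m)
    npx <- npx + nrow(m)
  }
  mu <- sums / npx
  list(mean = mu, sd = sqrt(pmax(sq / npx - mu^2, 1e-12)))
}
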