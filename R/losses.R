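# Classification losses: cross-entropy, focal loss, and their 0.5/0.5
# blend. User-facing functions take explicit probability vectors; the
# training loop uses the logit-level gradient helper at the bottom.

LOG_EPS <- 1e-12  # clamp for log arguments on degenerate predictions

#' Loss hyperparameters
#'
#' @param alpha per-class weights (length-K nonnegative vector) or the
#'   string `"inverse_frequency"`, resolved against the training labels at
#'   fit time (weights proportional to 1/class frequency, normalised to
#'   mean 1)
#' @param gamma focusing exponent (>= 0); 0 recovers weighted cross-entropy
#' @param mix_ce,mix_fl mixing weights of the cross-entropy and focal terms
#'   (0.5/0.5 in the published model)
#' @return an object of class `loss_params`
#' @export
loss_params <- function(alpha = rep(1, 5), gamma = 2, mix_ce = 0.5, mix_fl = 0.5) {
  if (is.character(alpha)) {
    alpha <- match.arg(alpha, "inverse_frequency")
  } else {
    if (any(alpha < 0)) stop("alpha entries must be nonnegative")
  }
  if (gamma < 0) stop("gamma must be nonnegative")
  structure(list(alpha = alpha, gamma = gamma, mix_ce = mix_ce, mix_fl = mix_fl),
            class = "loss_params")
}

resolve_alpha <- function(params, labels, K) {
  if (!is.character(params$alpha)) return(params$alpha)
  freq <- tabulate(labels, nbins = K)
  freq[freq == 0L] <- 1L
  a <- 1 / freq
  a / mean(a)
}

check_pred <- function(pred, labels, tol = 1e-5) {
  if (is.null(dim(pred))) pred <- matrix(pred, nrow = 1L)
  if (any(pred < -tol) || any(pred > 1 + tol)) {
    stop("predictions must be probabilities in [0, 1]")
  }
  rs <- rowSums(pred)
  if (any(abs(rs - 1) > tol)) stop("prediction rows must sum to 1")
  labels <- as.integer(labels)
  if (length(labels) != nrow(pred)) stop("length(labels) must match nrow(pred)")
  if (any(labels < 1L) || any(labels > ncol(pred))) {
    stop("labels must index prediction columns (1..K)")
  }
  list(pred = pred, labels = labels)
}

p_true <- function(pred, labels) {
  pmax(pred[cbind(seq_along(labels), labels)], LOG_EPS)
}

#' Cross-entropy loss
#'
#' Mean over the batch of `-log q(true class)` for one-hot truths, i.e.
#' `-sum_x p(x) log q(x)` per sample with `p` the true distribution and `q`
#' the predicted one.
#'
#' @param pred `N x K` matrix of predicted probability vectors (rows sum
#'   to 1 within 1e-5)
#' @param labels integer true classes in `1..K` (a factor is accepted)
#' @return nonnegative scalar
#' @examples
#' cross_entropy(matrix(rep(0.2, 5), 1), 3)  # -log(0.2) = 1.6094
#' @export
cross_entropy <- function(pred, labels) {
  ck <- check_pred(pred, labels)
  mean(-log(p_true(ck$pred, ck$labels)))
}

#' Focal loss
#'
#' Mean over the batch of `-alpha_t (1 - p_t)^gamma log(p_t)` where `p_t`
#' is the predicted probability of the true class. Down-weights easy
#' samples (large `p_t`) and re-weights classes through `alpha`.
#'
#' @inheritParams cross_entropy
#' @param params a [loss_params()]; `alpha = "inverse_frequency"` is
#'   resolved against `labels`
#' @return nonnegative scalar
#' @examples
#' focal_loss(matrix(c(0.5, 0.5, 0, 0, 0), 1), 1,
#'            loss_params(alpha = rep(0.25, 5), gamma = 2))
#' @export
focal_loss <- function(pred, labels, params = loss_params()) {
  ck <- check_pred(pred, labels)
  alpha <- resolve_alpha(params, ck$labels, ncol(ck$pred))
  pt <- p_true(ck$pred, ck$labels)
  mean(-alpha[ck$labels] * (1 - pt)^params$gamma * log(pt))
}

#' Combined cross-entropy / focal loss
#'
#' `mix_ce * cross_entropy + mix_fl * focal_loss`, the hybrid objective of
#' the grading network (both weights 0.5 by default).
#'
#' @inheritParams focal_loss
#' @return nonnegative scalar
#' @export
combined_loss <- function(pred, labels, params = loss_params()) {
  params$mix_ce * cross_entropy(pred, labels) +
    params$mix_fl * focal_loss(pred, labels, params)
}

# Loss and gradient at the logit level, used by the training loop.
# Per sample the objective depends on the true-class softmax probability
# p_t only; with L'(p) its derivative, dL/dz_j = L'(p_t) p_t (1[j==t] - p_j).
softmax_loss_grad <- function(logits, labels, params = loss_params()) {
  labels <- as.integer(labels)
  n <- nrow(logits)
  p <- softmax_rows(logits)
  alpha <- resolve_alpha(params, labels, ncol(p))
  idx <- cbind(seq_len(n), labels)
  pt <- pmax(p[idx], LOG_EPS)
  g <- params$gamma
  at <- alpha[labels]
  ce <- -log(pt)
  fl <- at * (1 - pt)^g * ce
  dce <- -1 / pt
  dfl <- at * (g * (1 - pt)^pmax(g - 1, 0) * log(pt) - (1 - pt)^g / pt)
  dl_dpt <- (params$mix_ce * dce + params$mix_fl * dfl) / n
  onehot <- matrix(0, n, ncol(p))
  onehot[idx] <- 1
  dz <- (dl_dpt * pt) * (onehot - p)
  list(loss = params$mix_ce * mean(ce) + params$mix_fl * mean(fl),
       ce = mean(ce), fl = mean(fl), grad = dz, prob = p)
}
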