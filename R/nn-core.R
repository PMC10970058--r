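# Minimal module system: each layer/composite is an environment carrying
# parameter shape metadata (`shapes`), initialiser tags (`inits`), optionally
# materialised parameters (`par`), accumulated gradients (`grad`), persistent
# buffers (`buf`, e.g. batch-norm running statistics) and named `children`.
# Parameters are only allocated by `init_parameters()`, so very large
# variants can be built and counted without touching memory for weights.

new_module <- function(.kind, ...) {
  m <- new.env(parent = emptyenv())
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = m)
  m$kind <- .kind
  if (is.null(m$children)) m$children <- list()
  if (is.null(m$shapes)) m$shapes <- list()
  if (is.null(m$inits)) m$inits <- list()
  if (is.null(m$buf)) m$buf <- list()
  class(m) <- c(paste0("mod_", .kind), "peggnet_module")
  m
}

#' @export
print.peggnet_module <- function(x, ...) {
  cat(sprintf("<peggnet %s module: %s parameters%s>\n", x$kind,
              format(count_parameters(x), big.mark = ","),
              if (is_initialized(x)) "" else " (uninitialised)"))
  invisible(x)
}

walk_modules <- function(m, fn) {
  fn(m)
  for (ch in m$children) walk_modules(ch, fn)
  invisible(NULL)
}

#' Count trainable parameters
#'
#' Exact number of trainable scalar parameters of a model, computed from
#' layer shape metadata (weights need not be materialised). Persistent
#' buffers such as batch-norm running statistics are not trainable and are
#' not counted.
#'
#' @param model a module returned by [build_backbone()], [build_pegg()] or
#'   any sub-module constructor
#' @return integer-valued numeric scalar
#' @seealso [format_param_count()] for the 0.1M reporting convention
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "peggnet_module"))
  total <- 0
  walk_modules(model, function(m) {
    for (s in m$shapes) total <<- total + prod(s)
  })
  total
}

#' Format a parameter count in millions
#'
#' Rounds half-up to one decimal in millions (e.g. `20955653` -> `"21.0M"`),
#' the convention used in the package's reports.
#'
#' @param n parameter count
#' @return character scalar like `"27.8M"`
#' @export
format_param_count <- function(n) {
  sprintf("%.1fM", floor(n / 1e5 + 0.5) / 10)
}

is_initialized <- function(m) {
  ok <- TRUE
  walk_modules(m, function(x) {
    if (length(x$shapes) && is.null(x$par)) ok <<- FALSE
  })
  ok
}

alloc_param <- function(shape, init, layer_scale_init) {
  n <- prod(shape)
  v <- switch(init,
    tn = trunc_normal(n),
    zeros = numeric(n),
    ones = rep(1, n),
    lscale = rep(layer_scale_init, n),
    stop("unknown initialiser: ", init)
  )
  if (length(shape) > 1L) dim(v) <- shape
  v
}

#' Initialise model weights
#'
#' Materialises all parameters of a model in place: truncated-normal
#' (sd 0.02) convolution/linear weights, zero biases, unit normalisation
#' gains, and layer-scale multipliers at their configured initial value.
#' Deterministic given `seed`.
#'
#' @param model a module
#' @param seed integer RNG seed
#' @return the model, invisibly (modified in place)
#' @export
init_parameters <- function(model, seed = 0L) {
  set.seed(seed)
  walk_modules(model, function(m) {
    if (!length(m$shapes)) return(invisible(NULL))
    lsi <- if (is.null(m$layer_scale_init)) 1e-6 else m$layer_scale_init
    m$par <- lapply(names(m$shapes), function(nm) {
      alloc_param(m$shapes[[nm]], m$inits[[nm]], lsi)
    })
    names(m$par) <- names(m$shapes)
  })
  zero_grads(model)
  invisible(model)
}

#' Zero all model weights
#'
#' Sets every trainable parameter to zero; used for closed-form limit checks
#' (e.g. an attention module with all-zero weights gates with exactly 0.5).
#'
#' @param model a module
#' @return the model, invisibly (modified in place)
#' @export
zero_parameters <- function(model) {
  walk_modules(model, function(m) {
    if (!length(m$shapes)) return(invisible(NULL))
    m$par <- lapply(m$shapes, function(s) {
      v <- numeric(prod(s))
      if (length(s) > 1L) dim(v) <- s
      v
    })
  })
  invisible(model)
}

zero_grads <- function(model) {
  walk_modules(model, function(m) {
    if (!length(m$shapes)) return(invisible(NULL))
    m$grad <- lapply(m$shapes, function(s) {
      v <- numeric(prod(s))
      if (length(s) > 1L) dim(v) <- s
      v
    })
  })
  invisible(model)
}

clear_caches <- function(model) {
  walk_modules(model, function(m) m$cache <- NULL)
  invisible(model)
}

walk_named <- function(m, path, fn) {
  fn(m, path)
  for (nm in names(m$children)) {
    walk_named(m$children[[nm]], paste0(path, "/", nm), fn)
  }
  invisible(NULL)
}

#' Extract model state
#'
#' Flat named list of all parameters and persistent buffers, keyed by
#' module path. Together with the model configuration this fully determines
#' the model; used by [save_checkpoint()].
#'
#' @param model a module
#' @return named list of numeric arrays
#' @export
get_state <- function(model) {
  out <- list()
  walk_named(model, "", function(m, path) {
    for (nm in names(m$par)) out[[paste0(path, ".", nm)]] <<- m$par[[nm]]
    for (nm in names(m$buf)) out[[paste0(path, ".buf.", nm)]] <<- m$buf[[nm]]
  })
  out
}

#' Restore model state
#'
#' Inverse of [get_state()]; shapes must match the model's layout.
#'
#' @param model a module
#' @param state named list from [get_state()]
#' @return the model, invisibly (modified in place)
#' @export
set_state <- function(model, state) {
  walk_named(model, "", function(m, path) {
    if (length(m$shapes) && is.null(m$par)) {
      m$par <- vector("list", length(m$shapes))
      names(m$par) <- names(m$shapes)
    }
    for (nm in names(m$shapes)) {
      key <- paste0(path, ".", nm)
      if (is.null(state[[key]])) stop("missing parameter in state: ", key)
      stopifnot(length(state[[key]]) == prod(m$shapes[[nm]]))
      m$par[[nm]] <- state[[key]]
    }
    for (nm in names(m$buf)) {
      key <- paste0(path, ".buf.", nm)
      if (!is.null(state[[key]])) m$buf[[nm]] <- state[[key]]
    }
  })
  zero_grads(model)
  invisible(model)
}

#' Run a module forward
#'
#' Applies a module to an input activation array (layout `(H, W, C, N)`; a
#' 3-d `(H, W, C)` input is treated as a single-image batch). In training
#' mode, layers cache what backpropagation needs and stochastic layers
#' (stochastic depth, batch-norm batch statistics) are active; in evaluation
#' mode the forward pass is deterministic.
#'
#' @param m a module
#' @param x input array (or list of two arrays for fusion modules)
#' @param training logical
#' @return output activation array
#' @export
nn_forward <- function(m, x, training = FALSE) {
  if (is.numeric(x) && length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  if (!is_initialized(m)) stop("model parameters not initialised; call init_parameters()")
  nn_fw(m, x, training)
}

nn_fw <- function(m, x, training = FALSE) UseMethod("nn_fw")
nn_bw <- function(m, dy, need_dx = TRUE) UseMethod("nn_bw")

# dispatch for the internal generics happens from inside the namespace,
# so external callers (tests) go through this wrapper
nn_backward <- function(m, dy, need_dx = TRUE) nn_bw(m, dy, need_dx)

# ---- AdamW ------------------------------------------------------------

decay_exempt <- function(nm) {
  nm %in% c("b", "b1", "b2", "ln_w", "ln_b", "bn_w", "bn_b", "gamma")
}

adamw_step <- function(model, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                       weight_decay = 0.05, t = 1L) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  walk_modules(model, function(m) {
    if (!length(m$shapes)) return(invisible(NULL))
    if (is.null(m$opt)) {
      m$opt <- lapply(m$par, function(p) list(m = p * 0, v = p * 0))
    }
    for (nm in names(m$par)) {
      g <- m$grad[[nm]]
      st <- m$opt[[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g * g
      m$opt[[nm]] <- st
      upd <- (st$m / bc1) / (sqrt(st$v / bc2) + eps)
      p <- m$par[[nm]] - lr * upd
      if (weight_decay > 0 && !decay_exempt(nm)) p <- p - lr * weight_decay * m$par[[nm]]
      m$par[[nm]] <- p
    }
  })
  invisible(model)
}
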