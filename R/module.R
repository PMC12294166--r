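#' @title Minimal layer/module framework
#' @description Layers are environments (reference semantics) carrying
#'   `params` (named list of numeric arrays), `buffers` (non-learnable
#'   state, e.g. running statistics) and `children` (named list of
#'   sub-modules). `nn_forward()` returns `list(out, cache)`;
#'   `nn_backward()` consumes the cache and the upstream gradient and
#'   returns `list(dx, grads)` where `grads` mirrors the module tree as
#'   `list(params = ..., children = ...)`.
#' @name bbs-module
#' @keywords internal
NULL

new_module <- function(cls, ...) {
  e <- new.env(parent = emptyenv())
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  if (is.null(e$params)) e$params <- list()
  if (is.null(e$children)) e$children <- list()
  if (is.null(e$buffers)) e$buffers <- list()
  class(e) <- c(cls, "bbs_module")
  e
}

#' @export
print.bbs_module <- function(x, ...) {
  np <- length(unlist(lapply(collect_params(x), length)))
  cat(sprintf("<bbs_module: %s> %d parameters\n", class(x)[1], np))
  invisible(x)
}

nn_forward <- function(mod, x, training = FALSE, ...) UseMethod("nn_forward")
nn_backward <- function(mod, cache, dout) UseMethod("nn_backward")

## --- parameter bookkeeping -------------------------------------------------

# flat list of references (env + local name) for every learnable array
param_refs <- function(mod, path = "") {
  out <- list()
  for (nm in names(mod$params)) {
    out[[paste0(path, nm)]] <- list(env = mod, name = nm)
  }
  for (cn in names(mod$children)) {
    out <- c(out, param_refs(mod$children[[cn]], paste0(path, cn, ".")))
  }
  out
}

# flatten a nested grads structure into the same order/naming as param_refs
flatten_grads <- function(grads, path = "") {
  out <- list()
  for (nm in names(grads$params)) out[[paste0(path, nm)]] <- grads$params[[nm]]
  for (cn in names(grads$children)) {
    out <- c(out, flatten_grads(grads$children[[cn]], paste0(path, cn, ".")))
  }
  out
}

# named list of parameter values keyed by path (copy)
collect_params <- function(mod) {
  lapply(param_refs(mod), function(r) r$env$params[[r$name]])
}

set_params <- function(mod, values) {
  refs <- param_refs(mod)
  for (nm in names(values)) {
    if (is.null(refs[[nm]])) stop("unknown parameter path: ", nm)
    r <- refs[[nm]]
    old <- r$env$params[[r$name]]
    new <- values[[nm]]
    if (length(old) != length(new)) {
      stop("parameter ", nm, " has wrong length")
    }
    dim(new) <- dim(old)
    r$env$params[[r$name]] <- new
  }
  invisible(mod)
}

buffer_refs <- function(mod, path = "") {
  out <- list()
  for (nm in names(mod$buffers)) {
    out[[paste0(path, nm)]] <- list(env = mod, name = nm)
  }
  for (cn in names(mod$children)) {
    out <- c(out, buffer_refs(mod$children[[cn]], paste0(path, cn, ".")))
  }
  out
}

collect_buffers <- function(mod) {
  lapply(buffer_refs(mod), function(r) r$env$buffers[[r$name]])
}

set_buffers <- function(mod, values) {
  refs <- buffer_refs(mod)
  for (nm in names(values)) {
    if (is.null(refs[[nm]])) stop("unknown buffer path: ", nm)
    r <- refs[[nm]]
    r$env$buffers[[r$name]] <- values[[nm]]
  }
  invisible(mod)
}

# zero-filled grads structure matching a module (used for skipped branches)
zero_grads <- function(mod) {
  list(
    params = lapply(mod$params, function(p) array(0, dim = dim(p) %||% length(p))),
    children = lapply(mod$children, zero_grads)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## --- Adam ------------------------------------------------------------------

adam_init <- function(refs) {
  zero_like <- function(r) r$env$params[[r$name]] * 0
  list(t = 0L, m = lapply(refs, zero_like), v = lapply(refs, zero_like))
}

adam_step <- function(refs, grads_flat, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(refs)) {
    g <- grads_flat[[nm]]
    if (is.null(g)) stop("missing gradient for ", nm)
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * as.vector(g)
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * as.vector(g)^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    r <- refs[[nm]]
    p <- r$env$params[[r$name]]
    np <- p - lr * as.vector(mhat) / (sqrt(as.vector(vhat)) + eps)
    attributes(np) <- attributes(p)
    r$env$params[[r$name]] <- np
  }
  state
}
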