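# A minimal reverse-mode autodiff tape over dense R arrays.
#
# Tensors are environments holding a value, an accumulated gradient, the
# parent tensors and a backward closure that maps the output gradient to a
# list of parent gradients. This is deliberately small: just enough machinery
# to differentiate the voxel-flow network and its losses.

.hf_counter <- local({
  i <- 0L
  function() {
    i <<- i + 1L
    i
  }
})

#' @keywords internal
hf_tensor <- function(value, parents = list(), backward = NULL) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$parents <- parents
  e$backward <- backward
  e$id <- .hf_counter()
  class(e) <- "hf_tensor"
  e
}

#' @keywords internal
hf_param <- function(value) {
  t <- hf_tensor(value)
  t$is_param <- TRUE
  t
}

#' @keywords internal
as_hf_tensor <- function(x) {
  if (inherits(x, "hf_tensor")) x else hf_tensor(x)
}

hf_value <- function(x) if (inherits(x, "hf_tensor")) x$value else x

# Accumulate g into tensor t$grad (shapes assumed consistent).
.hf_accum <- function(t, g) {
  if (is.null(g)) return(invisible(NULL))
  if (is.null(t$grad)) t$grad <- g else t$grad <- t$grad + g
  invisible(NULL)
}

# Reverse pass from a scalar root. Gradients accumulate in each tensor's
# $grad field; call hf_zero_grad() on parameters between steps.
#' @keywords internal
hf_backward <- function(root) {
  stopifnot(inherits(root, "hf_tensor"), length(root$value) == 1L)
  # iterative topological sort
  order <- vector("list", 256L)
  n_ord <- 0L
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = root, stage = 1L))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top$node
    key <- as.character(node$id)
    if (top$stage == 1L) {
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      stack[[length(stack) + 1L]] <- list(node = node, stage = 2L)
      for (p in node$parents) {
        if (inherits(p, "hf_tensor") && is.null(seen[[as.character(p$id)]])) {
          stack[[length(stack) + 1L]] <- list(node = p, stage = 1L)
        }
      }
    } else {
      n_ord <- n_ord + 1L
      if (n_ord > length(order)) order <- c(order, vector("list", length(order)))
      order[[n_ord]] <- node
    }
  }
  root$grad <- 1
  for (i in rev(seq_len(n_ord))) {
    node <- order[[i]]
    if (is.null(node$backward) || is.null(node$grad)) next
    gs <- node$backward(node$grad)
    for (k in seq_along(node$parents)) {
      p <- node$parents[[k]]
      if (inherits(p, "hf_tensor")) .hf_accum(p, gs[[k]])
    }
  }
  invisible(root)
}

#' @keywords internal
hf_zero_grad <- function(params) {
  for (p in hf_flatten_params(params)) p$grad <- NULL
  invisible(NULL)
}

# Flatten a nested list of parameter tensors into a flat named list.
#' @keywords internal
hf_flatten_params <- function(x, prefix = "") {
  if (inherits(x, "hf_tensor")) {
    out <- list(x)
    names(out) <- prefix
    return(out)
  }
  out <- list()
  nms <- names(x)
  for (i in seq_along(x)) {
    nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
    out <- c(out, hf_flatten_params(x[[i]], paste0(prefix, if (nzchar(prefix)) "." else "", nm)))
  }
  out
}
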