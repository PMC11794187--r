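#' @keywords internal
"_PACKAGE"

# Reverse-mode autodiff tape over plain numeric arrays.
#
# A node is an environment holding $value (numeric array), $grad, $parents
# (list of parent nodes) and $vjp, a function(g) returning one cotangent per
# parent. Environments give reference semantics: the optimizer mutates
# parameter values in place and every module that captured the node sees the
# update.

.ag <- new.env(parent = emptyenv())
.ag$grad_enabled <- TRUE
.ag$training <- FALSE
.ag$count_flops <- FALSE
.ag$flops <- 0
.ag$next_id <- 0

#' Test for / unwrap autodiff nodes
#'
#' `ag_value` returns the plain numeric array behind a forward-pass result
#' (which is an autodiff node while gradient recording is on, and already a
#' plain array otherwise).
#'
#' @param x a forward result or plain array.
#' @return `ag_is_node`: logical; `ag_value`: numeric array.
#' @export
ag_value <- function(x) if (ag_is_node(x)) x$value else x

#' @rdname ag_value
#' @export
ag_is_node <- function(x) inherits(x, "agnode")

#' Create an autodiff leaf tensor
#'
#' Wraps a numeric array as a leaf on the autodiff tape. Leaves with
#' `requires_grad = TRUE` accumulate gradients during [ag_backward()] and are
#' what the optimizer updates.
#'
#' @param value numeric array.
#' @param requires_grad accumulate a gradient for this leaf?
#' @param name optional label used in parameter reports.
#' @return an `agnode` environment.
#' @keywords internal
ag_leaf <- function(value, requires_grad = FALSE, name = NULL) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$parents <- list()
  e$vjp <- NULL
  e$requires_grad <- requires_grad
  e$name <- name
  e$id <- (.ag$next_id <- .ag$next_id + 1)
  class(e) <- "agnode"
  e
}

# Internal node from an op. `parents` may mix nodes and plain arrays; plain
# parents are dropped from the graph. If grad mode is off, or no parent is a
# node, the plain value is returned and no graph is built.
ag_node <- function(value, parents, vjp) {
  keep <- vapply(parents, ag_is_node, logical(1))
  if (!.ag$grad_enabled || !any(keep)) return(value)
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$parents <- parents[keep]
  e$parent_mask <- keep
  e$vjp <- vjp
  e$requires_grad <- FALSE
  e$id <- (.ag$next_id <- .ag$next_id + 1)
  class(e) <- "agnode"
  e
}

#' Run a closure with gradient recording disabled
#' @param expr expression to evaluate.
#' @keywords internal
ag_no_grad <- function(expr) {
  old <- .ag$grad_enabled
  .ag$grad_enabled <- FALSE
  on.exit(.ag$grad_enabled <- old)
  force(expr)
}

# Iterative topological order (children before parents after reversal).
ag_toposort <- function(root) {
  order <- list()
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = root, stage = 1L))
  while (length(stack) > 0) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nd <- top$node
    key <- as.character(nd$id)
    if (top$stage == 1L) {
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      stack[[length(stack) + 1L]] <- list(node = nd, stage = 2L)
      for (p in nd$parents) {
        if (ag_is_node(p)) stack[[length(stack) + 1L]] <- list(node = p, stage = 1L)
      }
    } else {
      order[[length(order) + 1L]] <- nd
    }
  }
  order
}

#' Backpropagate from a scalar loss node
#'
#' Accumulates `$grad` on every reachable leaf created with
#' `requires_grad = TRUE`. Intermediate gradients are freed as soon as all
#' consumers have used them (the whole tape is discarded after the call).
#'
#' @param loss an `agnode` holding a scalar.
#' @keywords internal
ag_backward <- function(loss) {
  stopifnot(ag_is_node(loss))
  order <- ag_toposort(loss)           # parents before children
  loss$grad <- array(1, dim = dim(loss$value) %||% 1L)
  for (i in rev(seq_along(order))) {
    nd <- order[[i]]
    if (is.null(nd$vjp) || is.null(nd$grad)) next
    gs <- nd$vjp(nd$grad)
    j <- 0L
    for (p in nd$parents) {
      j <- j + 1L
      g <- gs[[j]]
      if (is.null(g)) next
      if (p$requires_grad || !is.null(p$vjp)) {
        p$grad <- if (is.null(p$grad)) g else p$grad + g
      }
    }
    if (!nd$requires_grad) nd$grad <- NULL  # free intermediate storage
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reset and read the FLOP meter
#'
#' Convolution and linear ops add `2 x multiply-accumulates` to a global meter
#' while it is armed; everything else counts zero, matching the convention
#' detector papers use when printing GFLOPs.
#' @keywords internal
ag_flops_start <- function() { .ag$flops <- 0; .ag$count_flops <- TRUE }
#' @rdname ag_flops_start
#' @keywords internal
ag_flops_stop <- function() { .ag$count_flops <- FALSE; .ag$flops }

ag_add_flops <- function(macs) {
  if (.ag$count_flops) .ag$flops <- .ag$flops + 2 * macs
  invisible(NULL)
}

#' Switch between training and evaluation behaviour
#'
#' Controls whether batch normalization uses batch statistics (and updates its
#' running moments) or the frozen running statistics.
#' @param on logical.
#' @keywords internal
ag_set_training <- function(on) { .ag$training <- isTRUE(on); invisible(NULL) }

ag_is_training <- function() .ag$training
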