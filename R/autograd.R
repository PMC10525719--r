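# Minimal reverse-mode automatic differentiation over dense matrices.
#
# Every differentiable quantity is a "node": an environment holding a numeric
# matrix `value`, its parent nodes, and a backward closure mapping the upstream
# gradient to per-parent gradients. Nodes are registered on a tape in creation
# order, so reverse iteration over the tape is a valid topological order.
# Plain numeric matrices/vectors are accepted anywhere a node is and are
# treated as constants (no gradient is propagated into them).
#
# Scalars are represented as 1x1 matrices throughout.

ag_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

ag_is_node <- function(x) is.environment(x)

ag_value <- function(x) if (ag_is_node(x)) x$value else x

new_node <- function(tape, value, parents = list(), backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$parents <- parents
  nd$backward <- backward
  nd$grad <- NULL
  if (!is.null(tape)) {
    if (tape$n >= length(tape$nodes)) {
      length(tape$nodes) <- 2L * length(tape$nodes)
    }
    tape$n <- tape$n + 1L
    tape$nodes[[tape$n]] <- nd
  }
  nd
}

#' @noRd
ag_leaf <- function(tape, x) {
  new_node(tape, as.matrix(x))
}

# Run the backward sweep seeding d(root)/d(root) = 1. Gradients accumulate in
# each node's `grad` field; leaves keep theirs for the optimizer to read.
ag_backward <- function(tape, root) {
  stopifnot(length(root$value) == 1L)
  root$grad <- matrix(1, 1L, 1L)
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$backward)) next
    gs <- nd$backward(nd$grad)
    ps <- nd$parents
    for (k in seq_along(ps)) {
      p <- ps[[k]]
      g <- gs[[k]]
      if (is.null(g) || !ag_is_node(p)) next
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(NULL)
}

ag_matmul <- function(tape, a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  new_node(tape, av %*% bv, list(a, b), function(g) {
    list(
      if (ag_is_node(a)) tcrossprod(g, bv) else NULL,
      if (ag_is_node(b)) crossprod(av, g) else NULL
    )
  })
}

# Elementwise add/sub with row-vector broadcasting (1 x K against M x K).
ag_add <- function(tape, a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  if (is.matrix(bv) && nrow(bv) == 1L && nrow(av) > 1L) {
    val <- av + rep(as.vector(bv), each = nrow(av))
    return(new_node(tape, val, list(a, b), function(g) {
      list(
        if (ag_is_node(a)) g else NULL,
        if (ag_is_node(b)) matrix(colSums(g), 1L) else NULL
      )
    }))
  }
  new_node(tape, av + bv, list(a, b), function(g) {
    list(if (ag_is_node(a)) g else NULL, if (ag_is_node(b)) g else NULL)
  })
}

ag_sub <- function(tape, a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  if (is.matrix(bv) && nrow(bv) == 1L && nrow(av) > 1L) {
    val <- av - rep(as.vector(bv), each = nrow(av))
    return(new_node(tape, val, list(a, b), function(g) {
      list(
        if (ag_is_node(a)) g else NULL,
        if (ag_is_node(b)) matrix(-colSums(g), 1L) else NULL
      )
    }))
  }
  new_node(tape, av - bv, list(a, b), function(g) {
    list(if (ag_is_node(a)) g else NULL, if (ag_is_node(b)) -g else NULL)
  })
}

ag_mul <- function(tape, a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  new_node(tape, av * bv, list(a, b), function(g) {
    list(
      if (ag_is_node(a)) g * bv else NULL,
      if (ag_is_node(b)) g * av else NULL
    )
  })
}

ag_div <- function(tape, a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  val <- av / bv
  new_node(tape, val, list(a, b), function(g) {
    list(
      if (ag_is_node(a)) g / bv else NULL,
      if (ag_is_node(b)) -g * av / (bv * bv) else NULL
    )
  })
}

ag_scale <- function(tape, a, k) {
  av <- ag_value(a)
  new_node(tape, av * k, list(a), function(g) list(g * k))
}

ag_relu <- function(tape, a) {
  av <- ag_value(a)
  mask <- av > 0
  new_node(tape, av * mask, list(a), function(g) list(g * mask))
}

ag_exp <- function(tape, a) {
  val <- exp(ag_value(a))
  new_node(tape, val, list(a), function(g) list(g * val))
}

ag_square <- function(tape, a) {
  av <- ag_value(a)
  new_node(tape, av * av, list(a), function(g) list(2 * g * av))
}

ag_sum <- function(tape, a) {
  av <- ag_value(a)
  dims <- dim(av)
  new_node(tape, matrix(sum(av), 1L, 1L), list(a), function(g) {
    list(matrix(as.numeric(g), dims[1L], dims[2L]))
  })
}

ag_mean <- function(tape, a) {
  av <- ag_value(a)
  dims <- dim(av)
  n <- length(av)
  new_node(tape, matrix(mean(av), 1L, 1L), list(a), function(g) {
    list(matrix(as.numeric(g) / n, dims[1L], dims[2L]))
  })
}

ag_colsums <- function(tape, a) {
  av <- ag_value(a)
  m <- nrow(av)
  new_node(tape, matrix(colSums(av), 1L), list(a), function(g) {
    list(matrix(rep(as.vector(g), each = m), m))
  })
}

ag_colmeans <- function(tape, a) {
  av <- ag_value(a)
  m <- nrow(av)
  new_node(tape, matrix(colMeans(av), 1L), list(a), function(g) {
    list(matrix(rep(as.vector(g) / m, each = m), m))
  })
}

ag_rows <- function(tape, a, idx) {
  av <- ag_value(a)
  dims <- dim(av)
  new_node(tape, av[idx, , drop = FALSE], list(a), function(g) {
    out <- matrix(0, dims[1L], dims[2L])
    out[idx, ] <- out[idx, ] + g
    list(out)
  })
}

ag_cols <- function(tape, a, idx) {
  av <- ag_value(a)
  dims <- dim(av)
  new_node(tape, av[, idx, drop = FALSE], list(a), function(g) {
    out <- matrix(0, dims[1L], dims[2L])
    out[, idx] <- out[, idx] + g
    list(out)
  })
}

ag_cbind <- function(tape, a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  ka <- ncol(av)
  new_node(tape, cbind(av, bv), list(a, b), function(g) {
    list(
      if (ag_is_node(a)) g[, seq_len(ka), drop = FALSE] else NULL,
      if (ag_is_node(b)) g[, -seq_len(ka), drop = FALSE] else NULL
    )
  })
}

ag_rbind <- function(tape, nodes) {
  vals <- lapply(nodes, ag_value)
  ns <- vapply(vals, nrow, 1L)
  ends <- cumsum(ns)
  starts <- ends - ns + 1L
  new_node(tape, do.call(rbind, vals), nodes, function(g) {
    lapply(seq_along(nodes), function(k) {
      if (ag_is_node(nodes[[k]])) g[starts[k]:ends[k], , drop = FALSE] else NULL
    })
  })
}

# Custom op: caller supplies the forward value and a backward closure.
ag_custom <- function(tape, value, parents, backward) {
  new_node(tape, value, parents, backward)
}
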