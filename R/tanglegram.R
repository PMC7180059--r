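# Tanglegram optimization: rotate two trees to minimize total vertical
# displacement between matched tips.

# children lists per internal node of a phylo object, preserving order
.phylo_children <- function(tree) {
  ch <- split(tree$edge[, 2], tree$edge[, 1])
  lapply(ch, as.integer)
}

# tip order (labels) implied by a children list via depth-first traversal
.tip_order <- function(tree, children, flips) {
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  out <- integer(0)
  stack <- list(root)
  while (length(stack)) {
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (node <= ntip) {
      out <- c(out, node)
    } else {
      kids <- children[[as.character(node)]]
      if (isTRUE(flips[node - ntip])) kids <- rev(kids)
      # push in reverse so first child is visited first
      for (k in rev(kids)) stack[[length(stack) + 1L]] <- k
    }
  }
  tree$tip.label[out]
}

# total link length between two tip orderings on unit-spaced ladders
.link_length <- function(ord1, ord2) {
  sum(abs(seq_along(ord1) - match(ord1, ord2)))
}

#' Optimize tip matching between a phylogeny and a dendrogram
#'
#' Greedily searches node rotations of both trees to minimize the total
#' vertical displacement between matched tips when the trees face each
#' other on unit-spaced ladders.  Optionally computes a permutation null
#' (shuffling the tip labels of the second tree) for the minimized link
#' length; a significantly low value indicates topological concordance.
#'
#' @param tree A `phylo` object.
#' @param dendrogram An `hclust` or `phylo` with the same tip set.
#' @param n_perm Permutations for the null (0 to skip the test).
#' @param seed Integer seed.
#' @return List of class `tanglegram`: `order1`, `order2` (optimized tip
#'   orderings), `link_length`, and `p` when `n_perm > 0`.
#' @export
tanglegram <- function(tree, dendrogram, n_perm = 0, seed = 1) {
  t1 <- tree
  t2 <- if (inherits(dendrogram, "hclust")) ape::as.phylo(dendrogram) else
    dendrogram
  if (!setequal(t1$tip.label, t2$tip.label)) {
    stop("tip sets do not match", call. = FALSE)
  }
  res <- .optimize_rotations(t1, t2)
  out <- list(order1 = res$ord1, order2 = res$ord2,
              link_length = res$cost)
  if (n_perm > 0) {
    obs <- res$cost
    with_seed(seed, {
      hits <- 0L
      for (k in seq_len(n_perm)) {
        t2p <- t2
        t2p$tip.label <- sample(t2$tip.label)
        if (.optimize_rotations(t1, t2p)$cost <= obs) hits <- hits + 1L
      }
      out$p <- (1 + hits) / (1 + n_perm)
      out$n_perm <- n_perm
    })
  }
  structure(out, class = "tanglegram")
}

.optimize_rotations <- function(t1, t2, max_sweeps = 25) {
  ch1 <- .phylo_children(t1); ch2 <- .phylo_children(t2)
  f1 <- logical(t1$Nnode); f2 <- logical(t2$Nnode)
  cost <- .link_length(.tip_order(t1, ch1, f1), .tip_order(t2, ch2, f2))
  for (sweep in seq_len(max_sweeps)) {
    improved <- FALSE
    for (side in 1:2) {
      tr <- if (side == 1) t1 else t2
      nn <- tr$Nnode
      for (nd in seq_len(nn)) {
        if (side == 1) f1[nd] <- !f1[nd] else f2[nd] <- !f2[nd]
        new_cost <- .link_length(.tip_order(t1, ch1, f1),
                                 .tip_order(t2, ch2, f2))
        if (new_cost < cost) {
          cost <- new_cost
          improved <- TRUE
        } else {
          if (side == 1) f1[nd] <- !f1[nd] else f2[nd] <- !f2[nd]
        }
      }
    }
    if (!improved) break
  }
  list(ord1 = .tip_order(t1, ch1, f1), ord2 = .tip_order(t2, ch2, f2),
       cost = cost)
}

#' @export
print.tanglegram <- function(x, ...) {
  cat("Tanglegram over", length(x$order1), "tips: total link length",
      x$link_length, "\n")
  if (!is.null(x$p)) cat("Permutation p =", signif(x$p, 3), "(",
                         x$n_perm, "permutations )\n")
  invisible(x)
}
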