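## Colinear anchor chaining. Score of a chain ending at anchor i:
##   f(i) = max{ max_{j<i} { f(j) + alpha(j,i) - beta(j,i) }, w_i }
## alpha(j,i) = min{min{dy, dx}, w_i} (matching bases), and the gap cost
##   beta = Inf            if g > G
##        = c1*g + c2*dmin + log2(g)  if 0 < g <= G
##        = 0              if g == 0
## with g = |dy - dx|, dmin = min(dy, dx). The DP combines an exact search
## in a G' window with an RMQ-accelerated search under the linear cost
## c1*(dx+dy) over the full G window (src/chain.cpp).

#' Chaining parameters
#'
#' Defaults are the graph-construction constants: max gap `G` = 100 kb,
#' exact-search window `G_prime` = 10 kb, expected per-base divergence
#' `d` = 0.01, minimizer length `k` = 19, and the derived gap coefficients
#' `c1 = exp(-d*k)` and `c2 = 0.05*exp(-d*k)`.
#'
#' @param G maximum gap in bp.
#' @param G_prime exact-search window in bp (`G_prime <= G`).
#' @param d expected per-base divergence.
#' @param k minimizer length.
#' @param min_score,min_anchors chain acceptance thresholds.
#' @param c1,c2 gap coefficients; derived from `d` and `k` unless given.
#' @return list of class `chain_params`.
#' @export
chain_params <- function(G = 100000, G_prime = 10000, d = 0.01, k = 19,
                         min_score = 40, min_anchors = 3,
                         c1 = exp(-d * k), c2 = 0.05 * exp(-d * k)) {
  stopifnot(G_prime > 0, G_prime <= G, d > 0, d < 1, c1 > 0, c2 > 0)
  structure(list(G = G, G_prime = G_prime, d = d, k = k,
                 min_score = min_score, min_anchors = min_anchors,
                 c1 = c1, c2 = c2),
            class = "chain_params")
}

#' Matching bases between two chained anchors
#'
#' `alpha(j, i) = min{min{y_i - y_j, x_i - x_j}, w_i}`.
#'
#' @param anchor_j,anchor_i lists or one-row data.frames with `x`, `y`,
#'   `w`; `j` precedes `i`.
#' @return number of matching bases credited to anchor i.
#' @export
alpha_score <- function(anchor_j, anchor_i) {
  min(min(anchor_i$y - anchor_j$y, anchor_i$x - anchor_j$x), anchor_i$w)
}

#' Gap penalty between two chained anchors
#'
#' Three-case cost on the gap `g = |dy - dx|`: 0 when `g = 0`; `c1*g +
#' c2*dmin + log2(g)` when `0 < g <= G`; `Inf` (rejection) when `g > G`.
#'
#' @param anchor_j,anchor_i anchors as in [alpha_score()].
#' @param params a `chain_params`.
#' @return penalty (possibly `Inf`).
#' @export
gap_penalty <- function(anchor_j, anchor_i, params = chain_params()) {
  dx <- anchor_i$x - anchor_j$x
  dy <- anchor_i$y - anchor_j$y
  g <- abs(dy - dx)
  if (g > params$G) return(Inf)
  if (g == 0) return(0)
  params$c1 * g + params$c2 * min(dx, dy) + log2(g)
}

## ---- dynamic RMQ tree (AVL with subtree-min pointers) ----

#' Dynamic 1-D range-min-query tree
#'
#' A balanced (AVL) search tree over `(y, s)` tuples in which every
#' subtree carries a pointer to its minimum-`s` node, so
#' `rmq_query(tree, a, b)` returns `min{s_j : a <= y_j <= b}` in
#' O(log m), and inserts/deletes keep the tree balanced.
#'
#' @return an empty `rmq_tree`.
#' @export
rmq_tree <- function() {
  structure(list(ptr = .rmq_new()), class = "rmq_tree")
}

#' @rdname rmq_tree
#' @param tree an `rmq_tree`.
#' @param y key.
#' @param s value.
#' @export
rmq_insert <- function(tree, y, s) {
  .rmq_insert(tree$ptr, y, s)
  invisible(tree)
}

#' @rdname rmq_tree
#' @export
rmq_delete <- function(tree, y) {
  ok <- .rmq_delete(tree$ptr, y)
  if (!ok) warning("rmq_delete: key ", y, " not in tree (no-op)")
  invisible(tree)
}

#' @rdname rmq_tree
#' @param a,b closed query interval on the keys.
#' @return `rmq_query`: the minimum `s` over keys in `[a, b]`, or `NA`
#'   when the interval is empty.
#' @export
rmq_query <- function(tree, a, b) .rmq_query(tree$ptr, a, b)

#' @rdname rmq_tree
#' @export
rmq_size <- function(tree) .rmq_size(tree$ptr)

#' @rdname rmq_tree
#' @export
rmq_height <- function(tree) .rmq_height(tree$ptr)

#' @export
print.rmq_tree <- function(x, ...) {
  cat(sprintf("rmq_tree: %d nodes, height %d\n", rmq_size(x), rmq_height(x)))
  invisible(x)
}

## backtrack chains from DP arrays, minimap2-style: repeatedly take the
## unused anchor with the highest f, follow prev until an anchor already
## in a chain is met; score is f at the head minus f at the truncation.
backtrack_chains <- function(dp, anchors, params) {
  n <- length(dp$f)
  used <- logical(n)
  ord <- order(dp$f, decreasing = TRUE)
  chains <- list()
  for (h in ord) {
    if (used[h]) next
    path <- integer(0)
    i <- h
    trunc_f <- 0
    while (i > 0 && !used[i]) {
      path <- c(i, path)
      used[i] <- TRUE
      i <- dp$prev[i]
    }
    if (i > 0) trunc_f <- dp$f[i]
    score <- dp$f[h] - trunc_f
    if (score < params$min_score || length(path) < params$min_anchors) next
    a <- anchors[path, , drop = FALSE]
    rownames(a) <- NULL
    chains[[length(chains) + 1L]] <- structure(
      list(anchors = a, score = score,
           segment = a$segment[1], strand = a$strand[1],
           query_start = min(a$y - a$w + 1), query_end = max(a$y) + 1,
           target_start = min(a$x - a$w + 1), target_end = max(a$x) + 1),
      class = "linear_chain")
  }
  chains
}

#' @export
print.linear_chain <- function(x, ...) {
  cat(sprintf("linear_chain: %s%s q[%d,%d) t[%d,%d) score %.1f (%d anchors)\n",
              x$segment, x$strand, x$query_start, x$query_end,
              x$target_start, x$target_end, x$score, nrow(x$anchors)))
  invisible(x)
}

#' Chain anchors into scored linear chains
#'
#' Anchors are partitioned by (segment, strand) and chained per run with
#' the combined exact/RMQ dynamic programme; backtracking yields
#' non-overlapping chains ranked by score. Chains below `min_score` or
#' with fewer than `min_anchors` anchors are dropped.
#'
#' @param anchors data.frame(segment, x, y, w, strand) as from
#'   [collect_anchors()].
#' @param params a `chain_params`.
#' @return list of `linear_chain` objects, best first.
#' @export
chain_anchors <- function(anchors, params = chain_params()) {
  if (is.null(anchors) || !nrow(anchors)) return(list())
  key <- paste(anchors$segment, anchors$strand)
  chains <- list()
  for (grp in unique(key)) {
    a <- anchors[key == grp, , drop = FALSE]
    a <- a[order(a$x, a$y), , drop = FALSE]
    rownames(a) <- NULL
    dp <- .chain_dp(a$x, a$y, a$w, params$G, params$G_prime,
                    params$c1, params$c2, TRUE)
    chains <- c(chains, backtrack_chains(dp, a, params))
  }
  chains[order(vapply(chains, `[[`, numeric(1), "score"),
               decreasing = TRUE)]
}
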