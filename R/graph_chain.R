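## Graph chaining: join linear chains across the graph topology. Linear
## chain L_j precedes L_i when L_j ends before L_i on the query and a walk
## of length <= G connects them in the graph; up to the 16 shortest walks
## are enumerated and the one whose graph length is closest to the query
## distance supplies the gap. DP:
##   g(i) = max{ max_{L_j < L_i} { g(j) + omega(L_i) - beta(j, i) },
##               omega(L_i) }
## with beta the linear-chaining gap cost on (query distance, walk length).

## uniform-cost enumeration of the k shortest walks between oriented
## segment ends; walk length = total bp of intermediate segments.
enumerate_walks <- function(graph, from_segment, from_orient,
                            to_segment, to_orient,
                            max_len, k_walks = 16, max_pops = 5000) {
  walks <- list()
  ## frontier of partial walks: list(len, path=data.frame(orient,name),
  ## at=c(seg, orient))
  frontier <- list(list(len = 0, path = NULL,
                        at = c(from_segment, from_orient)))
  pops <- 0
  while (length(frontier) && length(walks) < k_walks && pops < max_pops) {
    lens <- vapply(frontier, `[[`, numeric(1), "len")
    i <- which.min(lens)
    st <- frontier[[i]]
    frontier[[i]] <- NULL
    pops <- pops + 1
    nb <- pg_neighbors(graph, st$at[1], st$at[2])
    if (!nrow(nb)) next
    for (r in seq_len(nrow(nb))) {
      seg <- nb$segment[r]; ori <- nb$orient[r]
      if (seg == to_segment && ori == to_orient) {
        walks[[length(walks) + 1L]] <- structure(
          list(path = st$path, graph_length = st$len), class = "pg_walk")
        if (length(walks) >= k_walks) break
        next
      }
      newlen <- st$len + nchar(graph$segments$sequence[seg_row(graph, seg)])
      if (newlen > max_len) next
      step <- data.frame(orient = ifelse(ori == "+", ">", "<"), name = seg,
                         stringsAsFactors = FALSE)
      frontier[[length(frontier) + 1L]] <-
        list(len = newlen, path = rbind(st$path, step), at = c(seg, ori))
    }
  }
  walks
}

#' Does one linear chain precede another on the graph?
#'
#' `L_i` precedes `L_j` iff (1) `L_i` ends before `L_j` on the query and
#' (2) a walk of length at most `G` connects the end of `L_i` to the start
#' of `L_j` in the graph. Up to 16 shortest witness walks are returned
#' (walks may revisit segments, so cycles are supported).
#'
#' @param chain_i,chain_j `linear_chain` objects on the same strand.
#' @param graph a `pangraph`.
#' @param params a `chain_params`.
#' @return list(ok = logical, walks = list of walks, query_distance).
#' @export
precedes <- function(chain_i, chain_j, graph, params = chain_params()) {
  ai <- chain_i$anchors[nrow(chain_i$anchors), ]  # last anchor of L_i
  aj <- chain_j$anchors[1, ]                      # first anchor of L_j
  qd <- aj$y - ai$y
  if (chain_i$query_end > chain_j$query_end || qd <= 0)
    return(list(ok = FALSE, walks = list(), query_distance = qd))
  if (chain_i$segment == chain_j$segment) {
    if (aj$x > ai$x) {
      w <- structure(list(path = NULL, graph_length = aj$x - ai$x),
                     class = "pg_walk")
      return(list(ok = TRUE, walks = list(w), query_distance = qd))
    }
    ## same segment but target does not advance: fall through to walks
  }
  li <- nchar(graph$segments$sequence[seg_row(graph, chain_i$segment)])
  tail_i <- li - 1 - ai$x      # bp after the last matched base on seg i
  head_j <- aj$x + 1           # bp up to and incl. first-anchor end on seg j
  ws <- enumerate_walks(graph, chain_i$segment, "+", chain_j$segment, "+",
                        max_len = params$G)
  ws <- lapply(ws, function(w) {
    w$graph_length <- w$graph_length + tail_i + head_j
    w
  })
  ws <- ws[vapply(ws, `[[`, numeric(1), "graph_length") <= params$G]
  list(ok = length(ws) > 0, walks = ws, query_distance = qd)
}

#' Choose the walk closest to the query distance
#'
#' Argmin of `|graph_length - query_distance|`; ties broken by the shorter
#' walk, then by lexicographic path.
#'
#' @param walks list of walks (from [precedes()]).
#' @param query_distance bp between the two chains on the query.
#' @return the chosen walk.
#' @export
choose_walk <- function(walks, query_distance) {
  if (!length(walks)) stop("choose_walk: empty walk list")
  len <- vapply(walks, `[[`, numeric(1), "graph_length")
  dev <- abs(len - query_distance)
  key <- vapply(walks, function(w)
    if (is.null(w$path)) "" else format_path(w$path), character(1))
  ord <- order(dev, len, key)
  walks[[ord[1]]]
}

#' @export
print.pg_walk <- function(x, ...) {
  cat(sprintf("walk: %s (%d bp)\n",
              if (is.null(x$path)) "<empty>" else format_path(x$path),
              x$graph_length), sep = "")
  invisible(x)
}

## alpha-sum (matching bases) of one linear chain
chain_alpha_sum <- function(chain) {
  a <- chain$anchors
  n <- nrow(a)
  if (n == 1) return(a$w[1])
  dx <- diff(a$x); dy <- diff(a$y)
  a$w[1] + sum(pmin(pmin(dx, dy), a$w[-1]))
}

#' Join linear chains into graph chains
#'
#' Dynamic programme over the precedence relation; the gap penalty between
#' two chains is the linear-chaining cost evaluated on the query distance
#' and the graph length of the walk closest to it. Backtracking yields
#' graph chains; chains are labeled primary when less than half of their
#' query span overlaps a higher-scoring primary chain.
#'
#' @param linear_chains list of `linear_chain` (one strand).
#' @param graph a `pangraph`.
#' @param params a `chain_params`.
#' @return list of `graph_chain` objects, best first, each with `anchors`
#'   (with path offsets), `path`, `score`, query/path intervals, `matches`,
#'   and `primary` flag.
#' @export
chain_graph <- function(linear_chains, graph, params = chain_params()) {
  if (!length(linear_chains)) return(list())
  qe <- vapply(linear_chains, `[[`, numeric(1), "query_end")
  lc <- linear_chains[order(qe)]
  n <- length(lc)
  omega <- vapply(lc, `[[`, numeric(1), "score")
  g <- omega
  prev <- integer(n)
  joinwalk <- vector("list", n)
  for (i in seq_len(n)) {
    if (i == 1) next
    yi <- lc[[i]]$anchors$y[1]
    for (j in seq_len(i - 1)) {
      ## cheap pruning: beta >= 0, so g[j] + omega[i] bounds the candidate;
      ## query distances beyond 2G cannot yield a finite gap
      if (g[j] + omega[i] <= g[i]) next
      yj <- lc[[j]]$anchors$y[nrow(lc[[j]]$anchors)]
      if (yi - yj <= 0 || yi - yj > 2 * params$G) next
      pr <- precedes(lc[[j]], lc[[i]], graph, params)
      if (!pr$ok) next
      wk <- choose_walk(pr$walks, pr$query_distance)
      dxg <- wk$graph_length
      dyq <- pr$query_distance
      gap <- abs(dyq - dxg)
      beta <- if (gap > params$G) Inf
              else if (gap == 0) 0
              else params$c1 * gap + params$c2 * min(dxg, dyq) + log2(gap)
      if (!is.finite(beta)) next
      cand <- g[j] + omega[i] - beta
      if (cand > g[i]) { g[i] <- cand; prev[i] <- j; joinwalk[[i]] <- wk }
    }
  }
  ## backtrack
  used <- logical(n)
  out <- list()
  for (h in order(g, decreasing = TRUE)) {
    if (used[h]) next
    members <- integer(0); i <- h
    while (i > 0 && !used[i]) {
      members <- c(i, members); used[i] <- TRUE
      i <- prev[i]
    }
    out[[length(out) + 1L]] <- assemble_graph_chain(
      lc, members, joinwalk, g[h], graph)
  }
  ## primary labeling: < 50% query overlap with a better primary chain
  out <- out[order(vapply(out, `[[`, numeric(1), "score"),
                   decreasing = TRUE)]
  prim <- list()
  for (i in seq_along(out)) {
    qc <- c(out[[i]]$query_start, out[[i]]$query_end)
    span <- qc[2] - qc[1]
    ovl <- 0
    for (p in prim) {
      o <- min(qc[2], p[2]) - max(qc[1], p[1])
      if (o > 0) ovl <- ovl + o
    }
    out[[i]]$primary <- ovl < 0.5 * span
    if (out[[i]]$primary) prim[[length(prim) + 1L]] <- qc
  }
  out
}

## concatenate member chains and join walks into one graph chain object
assemble_graph_chain <- function(lc, members, joinwalk, score, graph) {
  path <- NULL
  anchors <- NULL
  el_of_anchor <- integer(0)
  for (m in seq_along(members)) {
    i <- members[m]
    if (m > 1 && !is.null(joinwalk[[i]]) && !is.null(joinwalk[[i]]$path))
      path <- rbind(path, joinwalk[[i]]$path)
    ## the chain's own segment, forward traversal; merge with previous
    ## element if it is the same oriented segment (same-segment join)
    el <- data.frame(orient = ">", name = lc[[i]]$segment,
                     stringsAsFactors = FALSE)
    if (is.null(path) || path$name[nrow(path)] != el$name ||
        path$orient[nrow(path)] != ">")
      path <- rbind(path, el)
    a <- lc[[i]]$anchors
    el_of_anchor <- c(el_of_anchor, rep(nrow(path), nrow(a)))
    anchors <- rbind(anchors, a)
  }
  seg_lens <- vapply(path$name, function(s)
    nchar(graph$segments$sequence[seg_row(graph, s)]), numeric(1))
  cum0 <- cumsum(c(0, seg_lens[-length(seg_lens)]))
  anchors$path_offset <- cum0[el_of_anchor] + anchors$x
  strand <- lc[[members[1]]]$strand
  matches <- sum(vapply(members, function(i)
    chain_alpha_sum(lc[[i]]), numeric(1)))
  structure(list(
    anchors = anchors, path = path, score = score, strand = strand,
    query_start = min(anchors$y - anchors$w + 1),
    query_end = max(anchors$y) + 1,
    path_start = min(anchors$path_offset - anchors$w + 1),
    path_end = max(anchors$path_offset) + 1,
    path_length = sum(seg_lens),
    matches = matches, primary = NA), class = "graph_chain")
}

#' @export
print.graph_chain <- function(x, ...) {
  cat(sprintf("graph_chain: %s q[%d,%d) path %s [%d,%d) score %.1f%s\n",
              x$strand, x$query_start, x$query_end, format_path(x$path),
              x$path_start, x$path_end, x$score,
              if (isTRUE(x$primary)) " primary" else ""))
  invisible(x)
}

## minimap2-style mapping quality from best/second-best scores
chain_mapq <- function(s1, s2, n_anchors) {
  if (s1 <= 0) return(0)
  q <- 40 * (1 - s2 / s1) * min(1, n_anchors / 10)
  max(0L, min(60L, as.integer(round(q))))
}

#' Render graph chains as GAF records
#'
#' @param chains list of `graph_chain` for one query.
#' @param graph a `pangraph`.
#' @param query_name,query_length query identity.
#' @param coord `"segment"` (default) or `"stable"`; stable paths are
#'   merged per the adjacency rule and single-reference records are
#'   reduced to PAF form.
#' @return list of `gaf_record`.
#' @export
graph_chains_to_gaf <- function(chains, graph, query_name, query_length,
                                coord = c("segment", "stable")) {
  coord <- match.arg(coord)
  if (!length(chains)) return(list())
  scores <- vapply(chains, `[[`, numeric(1), "score")
  s1 <- max(scores)
  s2 <- if (length(scores) > 1) sort(scores, decreasing = TRUE)[2] else 0
  lapply(chains, function(ch) {
    qs <- ch$query_start; qe <- ch$query_end
    if (ch$strand == "-") {
      qs <- query_length - ch$query_end
      qe <- query_length - ch$query_start
    }
    mapq <- if (ch$score == s1) chain_mapq(s1, s2, nrow(ch$anchors)) else
      chain_mapq(s1 * 2, s1 * 2 - ch$score, nrow(ch$anchors))
    r <- gaf_record(query_name, query_length, qs, qe, ch$strand,
                    ch$path, ch$path_length, ch$path_start, ch$path_end,
                    round(ch$matches),
                    max(qe - qs, ch$path_end - ch$path_start), mapq)
    if (coord == "stable") {
      r$path <- path_to_stable(graph, r$path)
      r <- reduce_to_reference(r, graph)
    }
    r
  })
}

#' Map query sequences to an indexed graph
#'
#' The full mapping pipeline: anchor collection, linear chaining per
#' segment/strand run, graph chaining, GAF emission.
#'
#' @param index a `pg_index` from [build_index()].
#' @param queries named character vector of DNA sequences (or
#'   `DNAStringSet`).
#' @param params a `chain_params`.
#' @param coord output coordinates, `"segment"` or `"stable"`.
#' @param all_chains keep secondary chains (default TRUE).
#' @return list with `records` (GAF) and `chains` (per-query graph
#'   chains).
#' @export
map_sequences <- function(index, queries, params = chain_params(),
                          coord = "segment", all_chains = TRUE) {
  if (methods::is(queries, "DNAStringSet")) {
    nm <- names(queries)
    queries <- as.character(queries)
    names(queries) <- nm
  }
  if (is.null(names(queries)))
    names(queries) <- paste0("query", seq_along(queries))
  graph <- index$graph
  recs <- list(); all_gc <- list()
  for (qn in names(queries)) {
    q <- queries[[qn]]
    anchors <- collect_anchors(index, q)
    lcs <- chain_anchors(anchors, params)
    gcs <- list()
    for (strand in c("+", "-")) {
      sl <- Filter(function(ch) ch$strand == strand, lcs)
      gcs <- c(gcs, chain_graph(sl, graph, params))
    }
    gcs <- gcs[order(vapply(gcs, `[[`, numeric(1), "score"),
                     decreasing = TRUE)]
    if (!all_chains) gcs <- Filter(function(g) isTRUE(g$primary), gcs)
    all_gc[[qn]] <- gcs
    recs <- c(recs, graph_chains_to_gaf(gcs, graph, qn, nchar(q), coord))
  }
  list(records = recs, chains = all_gc)
}
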