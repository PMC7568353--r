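## Incremental graph construction: map an assembly, score inter-anchor
## gaps along primary graph chains, find maximal divergent regions
## (Ruzzo-Tompa), verify them by base alignment, and insert qualifying SV
## paths (100 bp - 100 kb, host alignment >= 100 kb) into the graph.

#' Orthogonal regions of a query
#'
#' A query region is orthogonal to the reference when it is contained in a
#' primary chain longer than `min_primary` (100 kb) and does not intersect
#' any other primary chain longer than `min_other` (20 kb). This avoids
#' augmenting from paralogous regions of the sample.
#'
#' @param primary_chains list of `graph_chain` (primary-labeled).
#' @param min_primary,min_other bp thresholds (paper defaults 1e5, 2e4).
#' @return data.frame(start, end, chain) of query intervals (half-open)
#'   with the index of the hosting chain.
#' @export
orthogonal_regions <- function(primary_chains, min_primary = 1e5,
                               min_other = 2e4) {
  prim <- which(vapply(primary_chains, function(ch) isTRUE(ch$primary),
                       logical(1)))
  span <- function(ch) ch$query_end - ch$query_start
  out <- NULL
  for (i in prim) {
    ch <- primary_chains[[i]]
    if (span(ch) <= min_primary) next
    host <- IRanges::IRanges(ch$query_start + 1, ch$query_end)
    others <- prim[prim != i]
    others <- others[vapply(primary_chains[others],
                            function(o) span(o) > min_other, logical(1))]
    if (length(others)) {
      block <- IRanges::reduce(IRanges::IRanges(
        vapply(primary_chains[others], function(o) o$query_start + 1,
               numeric(1)),
        vapply(primary_chains[others], `[[`, numeric(1), "query_end")))
      host <- IRanges::setdiff(host, block)
    }
    if (length(host))
      out <- rbind(out, data.frame(start = IRanges::start(host) - 1,
                                   end = IRanges::end(host), chain = i))
  }
  if (is.null(out))
    out <- data.frame(start = numeric(), end = numeric(), chain = integer())
  out
}

#' Divergence score per adjacent anchor pair
#'
#' The graph-generation score: `-10` when the graph distance equals the
#' query distance and both are at most the next anchor's minimizer span
#' (the colinear, gap-free case), else `eta * max(dx, dy)` where `eta` is
#' the anchor density averaged across primary graph chains. Summed over a
#' run of pairs, a large total marks a divergent region.
#'
#' @param dx graph distances between adjacent anchors (bp).
#' @param dy query distances between adjacent anchors (bp).
#' @param w_next minimizer span of the second anchor of each pair.
#' @param eta anchor density (anchors per query bp), > 0.
#' @return numeric vector of scores, one per pair.
#' @export
gap_scores <- function(dx, dy, w_next, eta) {
  stopifnot(eta > 0, length(dx) == length(dy))
  ifelse(dx == dy & dx <= w_next, -10, eta * pmax(dx, dy))
}

## gap scores along one graph chain (uses path offsets for dx)
chain_gap_scores <- function(chain, eta) {
  a <- chain$anchors
  if (nrow(a) < 2) return(numeric(0))
  gap_scores(diff(a$path_offset), diff(a$y), a$w[-1], eta)
}

#' All maximal positive-scoring subsequences (Ruzzo-Tompa)
#'
#' Linear-time enumeration of the disjoint subsequences of a real score
#' list that are maximal: each has positive total, and none can be
#' extended or merged with a neighbour to a higher total.
#'
#' @param scores numeric vector.
#' @return data.frame(start, end, score) with 1-based inclusive indices,
#'   sorted by start; zero rows when no positive subsequence exists.
#' @export
ruzzo_tompa <- function(scores) {
  n <- length(scores)
  Ls <- numeric(0); Rs <- numeric(0)   # cumulative before start / through end
  starts <- integer(0); ends <- integer(0)
  cum <- 0
  for (i in seq_len(n)) {
    x <- scores[i]
    if (x <= 0) { cum <- cum + x; next }
    L <- cum; R <- cum + x
    s <- i; e <- i
    cum <- R
    repeat {
      k <- length(Ls)
      ## rightmost j with L_j < L
      j <- if (k) { w <- which(Ls < L); if (length(w)) max(w) else 0L } else 0L
      if (j == 0L || Rs[j] >= R) {
        Ls <- c(Ls, L); Rs <- c(Rs, R)
        starts <- c(starts, s); ends <- c(ends, e)
        break
      }
      ## merge with I_j and retest
      L <- Ls[j]; s <- starts[j]
      keep <- seq_len(j - 1L)
      Ls <- Ls[keep]; Rs <- Rs[keep]
      starts <- starts[keep]; ends <- ends[keep]
    }
  }
  data.frame(start = starts, end = ends, score = Rs - Ls)
}

## chunked global affine alignment; chunking only triggers above the cap
align_global <- function(q, g, cap = 2e5, match = 2, mismatch = -4,
                         gap_open = 6, gap_ext = 2) {
  if (max(nchar(q), nchar(g)) > cap) {
    warning("divergent region above alignment cap; using chunked alignment")
    nq <- nchar(q); ng <- nchar(g)
    k <- ceiling(max(nq, ng) / cap)
    qb <- floor(seq(0, nq, length.out = k + 1))
    gb <- floor(seq(0, ng, length.out = k + 1))
    pieces <- lapply(seq_len(k), function(i) {
      align_global(substr(q, qb[i] + 1, qb[i + 1]),
                   substr(g, gb[i] + 1, gb[i + 1]), cap = Inf,
                   match = match, mismatch = mismatch,
                   gap_open = gap_open, gap_ext = gap_ext)
    })
    return(list(q = paste(vapply(pieces, `[[`, "", "q"), collapse = ""),
                g = paste(vapply(pieces, `[[`, "", "g"), collapse = "")))
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(q), Biostrings::DNAString(g), type = "global",
    substitutionMatrix = mat, gapOpening = gap_open, gapExtension = gap_ext)
  ## global alignment: the gapped aligned ranges cover both sequences fully
  list(q = as.character(Biostrings::pattern(aln)),
       g = as.character(Biostrings::subject(aln)))
}

#' Verify a candidate divergent region by base alignment
#'
#' Globally aligns the query subsequence against the graph subsequence
#' (affine gaps). The region is retained iff the alignment contains a
#' single indel run of at least `min_indel` bp, or a window of
#' `ident_window` alignment columns with identity below `max_identity`.
#'
#' @param query_subseq,graph_subseq DNA strings (the graph side spelled
#'   from the chain's walk between the flanking anchors).
#' @param min_indel minimum indel run (default 100 bp).
#' @param ident_window identity window (default 100 columns).
#' @param max_identity identity threshold (default 0.8).
#' @return list(retain, reason, event, min_identity): `event` is
#'   data.frame(g_start, g_end, q_start, q_end) in 0-based offsets within
#'   the two subsequences (the leftmost largest indel run, or the whole
#'   region for identity-only evidence); NULL when rejected.
#' @export
verify_divergent_region <- function(query_subseq, graph_subseq,
                                    min_indel = 100, ident_window = 100,
                                    max_identity = 0.8) {
  stopifnot(nchar(query_subseq) > 0, nchar(graph_subseq) > 0)
  al <- align_global(query_subseq, graph_subseq)
  qc <- strsplit(al$q, "")[[1]]
  gc <- strsplit(al$g, "")[[1]]
  ncol <- length(qc)
  qoff <- cumsum(qc != "-")   # query bases consumed through column i
  goff <- cumsum(gc != "-")
  ## indel runs
  ins <- gc == "-"; del <- qc == "-"
  runs <- function(flag) {
    r <- rle(flag)
    e <- cumsum(r$lengths)
    s <- e - r$lengths + 1L
    data.frame(start = s[r$values], end = e[r$values],
               len = r$lengths[r$values])
  }
  ir <- runs(ins); dr <- runs(del)
  ir$type <- rep("INS", nrow(ir)); dr$type <- rep("DEL", nrow(dr))
  rr <- rbind(ir, dr)
  big <- rr[rr$len >= min_indel, , drop = FALSE]
  ## identity windows over aligned base pairs (gap columns excluded, so a
  ## short clean indel does not masquerade as low identity; sub-threshold
  ## indels are the SV filter's business, not this branch's)
  paired <- which(qc != "-" & gc != "-")
  m <- as.numeric(qc[paired] == gc[paired])
  np <- length(m)
  min_ident <- 1
  low_ident <- FALSE
  if (np >= ident_window) {
    cm <- cumsum(m)
    widents <- (cm[ident_window:np] -
                c(0, cm)[1:(np - ident_window + 1L)]) / ident_window
    min_ident <- min(widents)
    low_ident <- min_ident < max_identity
  }
  if (nrow(big)) {
    big <- big[order(-big$len, big$start), , drop = FALSE]
    r <- big[1, ]
    ev <- data.frame(
      g_start = goff[r$start] - as.numeric(gc[r$start] != "-"),
      g_end = goff[r$end],
      q_start = qoff[r$start] - as.numeric(qc[r$start] != "-"),
      q_end = qoff[r$end])
    return(list(retain = TRUE, reason = "indel", event = ev,
                min_identity = min_ident, indel_len = r$len))
  }
  if (low_ident) {
    ev <- data.frame(g_start = 0, g_end = nchar(graph_subseq),
                     q_start = 0, q_end = nchar(query_subseq))
    return(list(retain = TRUE, reason = "identity", event = ev,
                min_identity = min_ident, indel_len = 0))
  }
  list(retain = FALSE, reason = "none", event = NULL,
       min_identity = min_ident, indel_len = 0)
}

#' Structural-variant size/context filter
#'
#' Keep an event iff `min_sv <= sv_len <= max_sv` and the hosting
#' alignment is at least `min_aln` long (defaults: 100 bp, 100 kb, 100
#' kb).
#'
#' @param sv_len SV length in bp.
#' @param aln_len host alignment (primary chain) query span in bp.
#' @param min_sv,max_sv,min_aln thresholds.
#' @return logical.
#' @export
sv_filter <- function(sv_len, aln_len, min_sv = 100, max_sv = 1e5,
                      min_aln = 1e5) {
  sv_len >= min_sv & sv_len <= max_sv & aln_len >= min_aln
}

## map an absolute path offset of a graph chain to a graph position
path_pos <- function(graph, path, offset) {
  lens <- vapply(path$name, function(s)
    nchar(graph$segments$sequence[seg_row(graph, s)]), numeric(1))
  cum0 <- cumsum(c(0, lens))
  el <- findInterval(offset, cum0[-length(cum0)], rightmost.closed = FALSE)
  el <- max(1L, min(el, nrow(path)))
  within <- offset - cum0[el]
  seg_offset <- if (path$orient[el] == ">") within else lens[el] - 1 - within
  i <- seg_row(graph, path$name[el])
  list(segment = path$name[el], orient = path$orient[el],
       seg_offset = seg_offset,
       rank = graph$segments$rank[i],
       stable_name = graph$segments$stable_name[i],
       stable_offset = graph$segments$stable_offset[i] + seg_offset)
}

## split the backbone at a stable position unless a boundary already
## exists there; returns the updated graph
split_at_stable <- function(graph, stable_name, pos) {
  hit <- find_segment(graph, stable_name, pos)
  if (is.null(hit)) stop("stable position not covered: ", stable_name, ":", pos)
  if (hit$seg_offset == 0) return(graph)  # boundary already present
  split_segment(graph, hit$segment, hit$seg_offset)
}

## segment ending exactly at stable position `pos` (left flank) and
## segment starting at `pos` (right flank), rank 0
flank_segments <- function(graph, stable_name, pos) {
  segs <- graph$segments
  sel <- segs$stable_name == stable_name & segs$rank == 0
  endpos <- segs$stable_offset + nchar(segs$sequence)
  left <- segs$name[sel & endpos == pos]
  right <- segs$name[sel & segs$stable_offset == pos]
  list(left = if (length(left)) left[1] else NULL,
       right = if (length(right)) right[1] else NULL)
}

next_seg_name <- function(graph) {
  n <- nrow(graph$segments) + 1L
  nm <- paste0("s", n)
  while (nm %in% graph$segments$name) { n <- n + 1L; nm <- paste0("s", n) }
  nm
}

#' Augment a graph with verified SV events
#'
#' Each event replaces the reference interval `[ref_start, ref_end)` on a
#' stable sequence by the query sequence `seq` (empty for pure
#' deletions): the backbone is split at both breakpoints, a new segment
#' carrying `seq` is added with `SN = query_name`, `SO = query_start`,
#' `SR = rank`, and links attach it between the flanks. Events whose
#' breakpoints cannot be placed on rank-0 segments are skipped with a
#' message. Stable coordinates of existing bases never change.
#'
#' @param graph a `pangraph`.
#' @param query_name origin (contig) name for new segments.
#' @param events data.frame(stable_name, ref_start, ref_end, query_start,
#'   query_end, seq).
#' @param rank SR value for new material (the assembly's 1-based index).
#' @return the updated `pangraph`, with attribute `n_applied`.
#' @export
augment_graph <- function(graph, query_name, events, rank = 1) {
  applied <- 0
  if (!is.null(events) && nrow(events)) for (e in seq_len(nrow(events))) {
    ev <- events[e, ]
    total <- stable_length(graph, ev$stable_name)
    if (ev$ref_start <= 0 || ev$ref_end >= total) {
      message("skipping event at ", ev$stable_name, ":", ev$ref_start,
              " (no flank)")
      next
    }
    g2 <- try({
      g <- split_at_stable(graph, ev$stable_name, ev$ref_start)
      split_at_stable(g, ev$stable_name, ev$ref_end)
    }, silent = TRUE)
    if (inherits(g2, "try-error")) {
      message("skipping event at ", ev$stable_name, ":", ev$ref_start,
              " (ambiguous flank)")
      next
    }
    fl <- flank_segments(g2, ev$stable_name, ev$ref_start)
    fr <- flank_segments(g2, ev$stable_name, ev$ref_end)
    if (is.null(fl$left) || is.null(fr$right)) {
      message("skipping event at ", ev$stable_name, ":", ev$ref_start,
              " (flank not on rank-0 backbone)")
      next
    }
    lk <- g2$links
    add_link <- function(lk, from, to) {
      key <- link_key(from, "+", to, "+")
      old <- link_key(lk$from, lk$from_orient, lk$to, lk$to_orient)
      if (key %in% old) return(lk)
      rbind(lk, data.frame(from = from, from_orient = "+", to = to,
                           to_orient = "+", stringsAsFactors = FALSE))
    }
    if (nzchar(ev$seq)) {
      nm <- next_seg_name(g2)
      g2$segments <- rbind(g2$segments, data.frame(
        name = nm, sequence = ev$seq, stable_name = query_name,
        stable_offset = ev$query_start, rank = as.integer(rank),
        stringsAsFactors = FALSE))
      lk <- add_link(lk, fl$left, nm)
      lk <- add_link(lk, nm, fr$right)
    } else {
      lk <- add_link(lk, fl$left, fr$right)
    }
    g2$links <- lk
    g2 <- pangraph(g2$segments, g2$links)   # re-validate
    graph <- g2
    applied <- applied + 1
  }
  attr(graph, "n_applied") <- applied
  graph
}

## discover SV events on one query contig mapped to the graph
discover_events <- function(graph, chains, query, query_name,
                            params = chain_params(), min_sv = 100,
                            max_sv = 1e5, min_aln = 1e5) {
  orth <- orthogonal_regions(chains, min_primary = min_aln)
  if (!nrow(orth)) return(NULL)
  prim_idx <- unique(orth$chain)
  prim <- chains[prim_idx]
  tot_anchor <- sum(vapply(prim, function(ch) nrow(ch$anchors), numeric(1)))
  tot_span <- sum(vapply(prim, function(ch)
    ch$query_end - ch$query_start, numeric(1)))
  eta <- max(tot_anchor / max(tot_span, 1), 1e-9)
  events <- NULL
  for (ci in prim_idx) {
    ch <- chains[[ci]]
    if (ch$strand != "+") next   # inversion augmentation out of scope
    aln_len <- ch$query_end - ch$query_start
    h <- chain_gap_scores(ch, eta)
    if (!length(h)) next
    iv <- ruzzo_tompa(h)
    if (!nrow(iv)) next
    a <- ch$anchors
    path_seq <- NULL
    myorth <- orth[orth$chain == ci, , drop = FALSE]
    for (r in seq_len(nrow(iv))) {
      i <- iv$start[r]; j <- iv$end[r] + 1L   # flanking anchors i .. j
      q1 <- a$y[i] - a$w[i] + 1; q2 <- a$y[j] + 1        # query, incl. flanks
      g1 <- a$path_offset[i] - a$w[i] + 1
      g2 <- a$path_offset[j] + 1
      if (!any(myorth$start <= q1 & myorth$end >= q2)) next
      if (g2 - g1 > 2 * max_sv + 2e4 || q2 - q1 > 2 * max_sv + 2e4) next
      ## a region in which neither side reaches min_sv bp can satisfy
      ## neither retention branch; skip the alignment
      if (max(g2 - g1, q2 - q1) < min_sv) next
      if (is.null(path_seq)) path_seq <- spell_walk(graph, ch$path)
      qs <- substr(query, q1 + 1, q2)
      gs <- substr(path_seq, g1 + 1, g2)
      if (qs == gs) next
      ver <- verify_divergent_region(qs, gs)
      if (!ver$retain) next
      ev <- ver$event
      sv_len <- max(ev$g_end - ev$g_start, ev$q_end - ev$q_start)
      if (!sv_filter(sv_len, aln_len, min_sv, max_sv, min_aln)) next
      ## absolute coordinates
      p_from <- path_pos(graph, ch$path, g1 + ev$g_start)
      p_to <- path_pos(graph, ch$path, g1 + max(ev$g_end - 1, ev$g_start))
      if (p_from$rank != 0 || p_to$rank != 0 ||
          p_from$orient != ">" || p_to$orient != ">" ||
          p_from$stable_name != p_to$stable_name) {
        message("skipping event (breakpoint off the rank-0 backbone)")
        next
      }
      ref_start <- p_from$stable_offset
      ref_end <- if (ev$g_end > ev$g_start)
        p_to$stable_offset + 1 else ref_start
      qa <- q1 + ev$q_start; qb <- q1 + ev$q_end
      events <- rbind(events, data.frame(
        stable_name = p_from$stable_name, ref_start = ref_start,
        ref_end = ref_end, query_start = qa, query_end = qb,
        seq = if (qb > qa) substr(query, qa + 1, qb) else "",
        stringsAsFactors = FALSE))
    }
  }
  events
}

#' Build a pangenome graph incrementally from assemblies
#'
#' The reference contigs become rank-0 segments; each assembly in turn is
#' mapped to the current graph, divergent regions on orthogonal parts of
#' its primary chains are verified by base alignment, events passing the
#' SV filter (100 bp - 100 kb, host alignment >= 100 kb) are inserted, and
#' new material receives the assembly's 1-based rank.
#'
#' @param reference named character vector / `DNAStringSet` of reference
#'   contigs, or a FASTA path.
#' @param assemblies list of assemblies (each as `reference`), in order.
#' @param params a `chain_params`.
#' @param k,window,max_occ minimizer parameters.
#' @param min_sv,max_sv,min_aln SV filter thresholds.
#' @param verbose log per-assembly event counts.
#' @return the final `pangraph`.
#' @export
build_incremental <- function(reference, assemblies = list(),
                              params = chain_params(), k = 19, window = 10,
                              max_occ = 250, min_sv = 100, max_sv = 1e5,
                              min_aln = 1e5, verbose = FALSE) {
  reference <- as_seq_vector(reference)
  segs <- data.frame(name = paste0("s", seq_along(reference)),
                     sequence = unname(reference),
                     stable_name = names(reference),
                     stable_offset = 0, rank = 0L, stringsAsFactors = FALSE)
  graph <- pangraph(segs)
  for (ai in seq_along(assemblies)) {
    asm <- as_seq_vector(assemblies[[ai]])
    ## map and discover against a snapshot of the graph; augment after all
    ## contigs of this assembly are processed
    g0 <- graph
    idx <- build_index(g0, k, window, max_occ)
    n_applied <- 0
    for (cn in names(asm)) {
      q <- asm[[cn]]
      anchors <- collect_anchors(idx, q)
      lcs <- chain_anchors(anchors, params)
      gcs <- list()
      for (strand in c("+", "-")) {
        sl <- Filter(function(ch) ch$strand == strand, lcs)
        gcs <- c(gcs, chain_graph(sl, g0, params))
      }
      events <- discover_events(g0, gcs, q, cn, params,
                                min_sv, max_sv, min_aln)
      if (!is.null(events) && nrow(events)) {
        graph <- augment_graph(graph, cn, events, rank = ai)
        n_applied <- n_applied + attr(graph, "n_applied")
      }
    }
    if (verbose)
      message(sprintf("assembly %d: %d events incorporated", ai, n_applied))
  }
  graph
}

## accept FASTA path, DNAStringSet, or named character vector
as_seq_vector <- function(x) {
  if (is.character(x) && length(x) == 1 && nchar(x) < 4096 &&
      file.exists(x)) {
    ss <- Biostrings::readDNAStringSet(x)
    v <- as.character(ss)
    names(v) <- sub("\\s.*$", "", names(ss))
    return(toupper(v))
  }
  if (methods::is(x, "DNAStringSet")) {
    v <- as.character(x)
    names(v) <- sub("\\s.*$", "", names(x))
    return(toupper(v))
  }
  if (is.null(names(x)))
    names(x) <- paste0("contig", seq_along(x))
  toupper(x)
}
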