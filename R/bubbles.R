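## Variations (bubbles): minimal single-source/single-sink subgraphs with
## rank-0 endpoints; alleles are source-to-sink paths. Blacklist regions:
## I0 union I(0, 0.99) minus I(0.998, 1) on the reference coordinate.

## all non-backbone segments reachable from the right end of `from`
## without passing through a rank-0 segment of this stable sequence
reach_interior <- function(graph, from, backbone_names) {
  seen <- character(0)
  stack <- list(c(from, "+"))
  hit_backbone <- character(0)
  while (length(stack)) {
    at <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nb <- pg_neighbors(graph, at[1], at[2])
    if (!nrow(nb)) next
    for (r in seq_len(nrow(nb))) {
      seg <- nb$segment[r]; ori <- nb$orient[r]
      if (seg %in% backbone_names) {
        hit_backbone <- union(hit_backbone, seg)
        next
      }
      key <- paste(seg, ori)
      if (key %in% seen) next
      seen <- c(seen, key)
      stack[[length(stack) + 1L]] <- c(seg, ori)
    }
  }
  list(interior = unique(vapply(strsplit(seen, " "), `[`, "", 1)),
       backbone_hits = hit_backbone)
}

## all links incident to a set of segments
incident_links <- function(graph, segs) {
  lk <- graph$links
  lk[lk$from %in% segs | lk$to %in% segs, , drop = FALSE]
}

## enumerate source->sink paths through the bubble (DFS, capped)
enumerate_alleles <- function(graph, source, sink, interior, cap = 64) {
  paths <- list()
  walk <- function(at, ori, acc) {
    if (length(paths) >= cap) return()
    nb <- pg_neighbors(graph, at, ori)
    if (!nrow(nb)) return()
    for (r in seq_len(nrow(nb))) {
      seg <- nb$segment[r]; o <- nb$orient[r]
      if (seg == sink) {
        paths[[length(paths) + 1L]] <<- acc
        next
      }
      if (!(seg %in% interior)) next
      key <- paste(seg, o)
      if (key %in% acc$key) next  # no revisits within one allele
      step <- data.frame(orient = ifelse(o == "+", ">", "<"), name = seg,
                         key = key, stringsAsFactors = FALSE)
      walk(seg, o, rbind(acc, step))
    }
  }
  walk(source, "+",
       data.frame(orient = character(), name = character(),
                  key = character(), stringsAsFactors = FALSE))
  paths
}

#' Enumerate variations (bubbles) in a pangenome graph
#'
#' Walks each rank-0 backbone in stable order and reports every minimal
#' source/sink pair of backbone segments whose strictly-interior subgraph
#' has no edge to the outside. Each variation carries its reference
#' interval (between source end and sink start), its alleles (paths
#' source to sink, up to `max_alleles`), their spelled lengths, and the
#' reference-allele flag. Side branches that never rejoin the backbone are
#' reported separately as tips.
#'
#' @param graph a `pangraph`.
#' @param max_alleles allele enumeration cap (default 64).
#' @return list(variations = data.frame, alleles = list, tips =
#'   character). The data.frame has one row per variation: stable_name,
#'   start, end (half-open reference interval), source, sink,
#'   allele_count, type ("biallelic"/"multiallelic").
#' @export
enumerate_variations <- function(graph, max_alleles = 64) {
  segs <- graph$segments
  vars <- NULL
  alleles_out <- list()
  tips <- character(0)
  for (sn in unique(segs$stable_name[segs$rank == 0])) {
    bb <- backbone_segments(graph, sn)
    bn <- bb$name
    if (nrow(bb) < 2) next
    i <- 1L
    while (i < nrow(bb)) {
      src <- bb$name[i]
      ## expand from the source: pull in every backbone position whose
      ## right-end branches fall inside the growing locus, until the
      ## furthest backbone hit (the sink) stabilises
      jmax <- i
      interior_nb <- character(0)
      done <- integer(0)
      pending <- i
      any_alt <- FALSE
      while (length(pending)) {
        kpos <- pending[1]; pending <- pending[-1]
        done <- c(done, kpos)
        rc <- reach_interior(graph, bn[kpos], bn)
        newint <- setdiff(rc$interior, bn)
        if (length(newint)) any_alt <- TRUE
        interior_nb <- union(interior_nb, newint)
        hits <- match(rc$backbone_hits, bn)
        hits <- hits[!is.na(hits)]
        if (any(hits > kpos + 1L)) any_alt <- TRUE
        if (length(hits)) jmax <- max(jmax, hits)
        inside <- setdiff(seq.int(i, max(jmax - 1L, i)), c(done, pending))
        pending <- c(pending, inside)
      }
      j <- jmax
      if (!any_alt || j <= i) { i <- i + 1L; next }
      interior <- union(interior_nb,
                        bn[seq_len(nrow(bb)) > i & seq_len(nrow(bb)) < j])
      sinkname <- bn[j]
      al <- enumerate_alleles(graph, src, sinkname, interior,
                              cap = max_alleles)
      if (!length(al)) { i <- i + 1L; next }
      spell_len <- vapply(al, function(p)
        if (!nrow(p)) 0 else sum(vapply(p$name, function(s)
          nchar(segs$sequence[match(s, segs$name)]), numeric(1))),
        numeric(1))
      is_ref <- vapply(al, function(p)
        nrow(p) > 0 && all(p$name %in% bn) && all(p$orient == ">") ||
          (nrow(p) == 0 && j == i + 1L), logical(1))
      spelled <- lapply(al, function(p)
        if (!nrow(p)) "" else spell_walk(graph, p[, c("orient", "name")]))
      dup <- duplicated(unlist(spelled))
      if (any(dup)) warning("collapsing alleles spelling identical sequences")
      keep <- !dup
      in_allele <- unique(unlist(lapply(al, function(p) p$name)))
      tips <- union(tips, setdiff(interior_nb, in_allele))
      src_end <- bb$stable_offset[i] + nchar(bb$sequence[i])
      sink_start <- bb$stable_offset[j]
      vars <- rbind(vars, data.frame(
        stable_name = sn, start = src_end, end = sink_start,
        source = src, sink = sinkname,
        allele_count = sum(keep),
        type = ifelse(sum(keep) > 2, "multiallelic", "biallelic"),
        stringsAsFactors = FALSE))
      alleles_out[[length(alleles_out) + 1L]] <- list(
        paths = al[keep], lengths = spell_len[keep],
        is_reference = is_ref[keep])
      i <- j
    }
  }
  if (is.null(vars))
    vars <- data.frame(stable_name = character(), start = numeric(),
                       end = numeric(), source = character(),
                       sink = character(), allele_count = integer(),
                       type = character(), stringsAsFactors = FALSE)
  list(variations = vars, alleles = alleles_out, tips = tips)
}

## interval set <-> IRanges helpers (0-based half-open externally)
iv_to_ir <- function(iv) {
  split(IRanges::IRanges(iv$start + 1, iv$end), iv$stable_name)
}
ir_to_iv <- function(irl) {
  out <- NULL
  for (sn in names(irl)) {
    ir <- IRanges::reduce(irl[[sn]])
    if (length(ir))
      out <- rbind(out, data.frame(stable_name = sn,
                                   start = IRanges::start(ir) - 1,
                                   end = IRanges::end(ir),
                                   stringsAsFactors = FALSE))
  }
  if (is.null(out))
    out <- data.frame(stable_name = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE)
  out[order(out$stable_name, out$start), , drop = FALSE]
}

#' Pad variation intervals (the I0 set)
#'
#' Extends each interval by `pad` bp on each side, clamped to the
#' sequence; overlaps are not merged at this stage.
#'
#' @param intervals data.frame(stable_name, start, end), half-open.
#' @param pad bp per side (default 50).
#' @param seq_lengths named vector of stable-sequence lengths for
#'   clamping (optional).
#' @return padded data.frame in the same form.
#' @export
extend_intervals <- function(intervals, pad = 50, seq_lengths = NULL) {
  out <- intervals
  out$start <- pmax(0, out$start - pad)
  out$end <- out$end + pad
  if (!is.null(seq_lengths)) {
    lim <- seq_lengths[out$stable_name]
    out$end <- pmin(out$end, lim)
  }
  out
}

#' Read PAF alignments
#'
#' @param text lines, a string with newlines, or a file path.
#' @return data.frame with the 12 mandatory PAF columns plus `identity`
#'   (matches / block length).
#' @export
read_paf <- function(text) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text))
    text <- readLines(text)
  else if (length(text) == 1 && grepl("\n", text))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  text <- text[nzchar(text)]
  rows <- lapply(seq_along(text), function(i) {
    f <- strsplit(text[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 12) stop("PAF line ", i, ": expected 12 columns")
    data.frame(query_name = f[1], query_length = as.numeric(f[2]),
               query_start = as.numeric(f[3]), query_end = as.numeric(f[4]),
               strand = f[5], target_name = f[6],
               target_length = as.numeric(f[7]),
               target_start = as.numeric(f[8]),
               target_end = as.numeric(f[9]),
               matches = as.numeric(f[10]),
               block_length = as.numeric(f[11]),
               mapq = as.numeric(f[12]), stringsAsFactors = FALSE)
  })
  p <- do.call(rbind, rows)
  if (anyNA(p[, c(2:4, 7:12)])) stop("non-numeric PAF column")
  p$identity <- p$matches / p$block_length
  p
}

#' Identity strata of PAF alignments
#'
#' After dropping records with mapping quality below `mapq_min`, returns
#' the accessor `I(a, b)`: the set of target (reference) intervals of
#' alignments whose identity (matches / block length) lies in `[a, b]`.
#'
#' @param paf data.frame from [read_paf()].
#' @param mapq_min minimum mapping quality (default 5).
#' @return function(a, b) returning data.frame(stable_name, start, end).
#' @export
identity_strata <- function(paf, mapq_min = 5) {
  paf <- paf[paf$mapq >= mapq_min, , drop = FALSE]
  function(a, b) {
    sel <- paf$identity >= a & paf$identity <= b
    data.frame(stable_name = paf$target_name[sel],
               start = paf$target_start[sel],
               end = paf$target_end[sel], stringsAsFactors = FALSE)
  }
}

#' Blacklist regions
#'
#' `I0 union I(0, 0.99) minus I(0.998, 1)`: the padded variation
#' intervals, together with reference intervals matched at below 99%
#' identity by inserted sequences, minus intervals matched at 99.8% or
#' better. Union binds before subtraction. The result is sorted, merged
#' and half-open.
#'
#' @param I0 data.frame(stable_name, start, end) (see
#'   [extend_intervals()]).
#' @param strata accessor from [identity_strata()] (or NULL for I0 only).
#' @return data.frame(stable_name, start, end).
#' @export
blacklist_regions <- function(I0, strata = NULL) {
  lowset <- if (is.null(strata)) I0[0, ] else strata(0, 0.99)
  hiset <- if (is.null(strata)) I0[0, ] else strata(0.998, 1)
  uni <- rbind(I0, lowset)
  if (!nrow(uni)) return(ir_to_iv(list()))
  u <- iv_to_ir(uni)
  u <- lapply(u, IRanges::reduce)
  if (nrow(hiset)) {
    h <- iv_to_ir(hiset)
    for (sn in names(u)) {
      if (!is.null(h[[sn]]))
        u[[sn]] <- IRanges::setdiff(u[[sn]], IRanges::reduce(h[[sn]]))
    }
  }
  ir_to_iv(u)
}

#' Write intervals as BED
#' @param intervals data.frame(stable_name, start, end).
#' @param path optional file.
#' @return character lines.
#' @export
write_bed <- function(intervals, path = NULL) {
  out <- sprintf("%s\t%d\t%d", intervals$stable_name,
                 as.integer(intervals$start), as.integer(intervals$end))
  if (!is.null(path)) { writeLines(out, path); return(invisible(out)) }
  out
}
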