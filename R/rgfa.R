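#' @useDynLib pangraphr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## rGFA / bidirected sequence-graph data model.
##
## A pangraph is an S3 list with two data frames:
##   segments: name, sequence, stable_name, stable_offset (0-based), rank
##   links:    from, from_orient, to, to_orient
## All coordinates are 0-based, half-open internally.

other_orient <- function(o) ifelse(o == "+", "-", "+")

#' Construct a pangenome graph
#'
#' Builds and validates a bidirected sequence graph with rGFA stable
#' coordinates. Each segment carries its origin on a stable (linear)
#' sequence: `stable_name` (SN), `stable_offset` (SO, 0-based) and `rank`
#' (SR; 0 = linear reference backbone, >0 = sample-derived).
#'
#' @param segments data.frame with columns `name`, `sequence`,
#'   `stable_name`, `stable_offset`, `rank`.
#' @param links data.frame with columns `from`, `from_orient`, `to`,
#'   `to_orient` (orientations `"+"`/`"-"`). May have zero rows.
#' @param validate check all rGFA invariants (default TRUE).
#' @return an object of class `pangraph`.
#' @export
pangraph <- function(segments, links = NULL, validate = TRUE) {
  if (is.null(links))
    links <- data.frame(from = character(), from_orient = character(),
                        to = character(), to_orient = character(),
                        stringsAsFactors = FALSE)
  segments <- as.data.frame(segments, stringsAsFactors = FALSE)
  links <- as.data.frame(links, stringsAsFactors = FALSE)
  need <- c("name", "sequence", "stable_name", "stable_offset", "rank")
  if (!all(need %in% names(segments)))
    stop("segments must have columns: ", paste(need, collapse = ", "))
  segments$stable_offset <- as.numeric(segments$stable_offset)
  segments$rank <- as.integer(segments$rank)
  rownames(segments) <- NULL
  g <- structure(list(segments = segments, links = links),
                 class = "pangraph")
  if (validate) validate_pangraph(g)
  g
}

#' @export
print.pangraph <- function(x, ...) {
  cat(sprintf("pangraph: %d segments, %d links, %d bp\n",
              nrow(x$segments), nrow(x$links),
              sum(nchar(x$segments$sequence))))
  sn <- unique(x$segments$stable_name[x$segments$rank == 0])
  cat(sprintf("  rank-0 stable sequences: %s\n",
              paste(utils::head(sn, 5), collapse = ", ")))
  invisible(x)
}

seg_row <- function(graph, name) {
  i <- match(name, graph$segments$name)
  if (is.na(i)) stop("unknown segment: ", name)
  i
}

seg_len <- function(graph, name) nchar(graph$segments$sequence[seg_row(graph, name)])

## canonical key of a bidirected link: (a,o1)->(b,o2) and (b,!o2)->(a,!o1)
## are the same edge.
link_key <- function(from, fo, to, to_) {
  k1 <- paste(from, fo, to, to_, sep = "\t")
  k2 <- paste(to, other_orient(to_), from, other_orient(fo), sep = "\t")
  pmin(k1, k2)
}

#' Validate rGFA invariants
#'
#' Checks: link endpoints exist; no duplicate bidirected links; per stable
#' sequence the stable intervals of its segments are pairwise disjoint (the
#' no-collapse rule); every rank-0 stable sequence is tiled without gaps by
#' its rank-0 segments.
#'
#' @param graph a `pangraph`.
#' @return invisibly TRUE, or stops with a validation error.
#' @export
validate_pangraph <- function(graph) {
  segs <- graph$segments
  if (anyDuplicated(segs$name))
    stop("duplicate segment name: ",
         segs$name[duplicated(segs$name)][1])
  if (any(nchar(segs$sequence) < 1)) stop("zero-length segment sequence")
  if (any(segs$stable_offset < 0)) stop("negative stable offset")
  if (any(segs$rank < 0)) stop("negative rank")
  bad <- grepl("[<>[:space:]]", segs$name)
  if (any(bad)) stop("segment name contains whitespace or '<'/'>': ",
                     segs$name[bad][1])
  lk <- graph$links
  if (nrow(lk)) {
    miss <- setdiff(c(lk$from, lk$to), segs$name)
    if (length(miss)) stop("link references unknown segment: ", miss[1])
    keys <- link_key(lk$from, lk$from_orient, lk$to, lk$to_orient)
    if (anyDuplicated(keys))
      stop("duplicate bidirected link: ", keys[duplicated(keys)][1])
  }
  ## no-collapse: per SN, stable intervals pairwise disjoint
  for (sn in unique(segs$stable_name)) {
    s <- segs[segs$stable_name == sn, , drop = FALSE]
    if (nrow(s) < 2) next
    o <- order(s$stable_offset)
    s <- s[o, , drop = FALSE]
    ends <- s$stable_offset + nchar(s$sequence)
    ov <- which(s$stable_offset[-1] < ends[-nrow(s)])
    if (length(ov))
      stop(sprintf("stable-interval collapse on %s between segments %s and %s",
                   sn, s$name[ov[1]], s$name[ov[1] + 1L]))
  }
  ## rank-0 tiling without gaps
  r0 <- segs[segs$rank == 0, , drop = FALSE]
  for (sn in unique(r0$stable_name)) {
    s <- r0[r0$stable_name == sn, , drop = FALSE]
    o <- order(s$stable_offset)
    s <- s[o, , drop = FALSE]
    ends <- s$stable_offset + nchar(s$sequence)
    if (nrow(s) > 1 && any(s$stable_offset[-1] != ends[-nrow(s)]))
      stop("rank-0 tiling of ", sn, " has a gap")
  }
  invisible(TRUE)
}

gfa_tag <- function(fields, tag) {
  hit <- grep(paste0("^", tag, ":"), fields, value = TRUE)
  if (!length(hit)) return(NA_character_)
  sub(sprintf("^%s:[A-Za-z]:", tag), "", hit[1])
}

#' Parse rGFA/GFA text into a pangenome graph
#'
#' Reads TAB-delimited S- and L-lines. In strict mode every S-line must
#' carry SN/SO/SR tags; in permissive mode missing tags are synthesized as
#' SN = segment name, SO = 0, SR = 0 (with a warning), so plain GFA from
#' other tools remains mappable. Non-zero overlap fields on L-lines are
#' rejected (the rGFA dialect forbids overlaps). Unknown line types are
#' skipped.
#'
#' @param text character vector of lines, a single string with newlines, or
#'   a file path (detected by existence on disk).
#' @param permissive allow S-lines without rGFA tags (default FALSE).
#' @return a validated `pangraph`.
#' @export
parse_rgfa <- function(text, permissive = FALSE) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text))
    text <- readLines(text)
  else if (length(text) == 1 && grepl("\n", text))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  text <- text[nzchar(text)]
  segs <- list(); lks <- list()
  synthesized <- FALSE
  for (ln in text) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (f[1] == "S") {
      if (length(f) < 3) stop("malformed S-line: ", ln)
      sn <- gfa_tag(f, "SN"); so <- gfa_tag(f, "SO"); sr <- gfa_tag(f, "SR")
      if (is.na(sn) || is.na(so) || is.na(sr)) {
        if (!permissive)
          stop("S-line lacks SN/SO/SR rGFA tags (strict mode): ", f[2])
        synthesized <- TRUE
        sn <- f[2]; so <- "0"; sr <- "0"
      }
      segs[[length(segs) + 1L]] <- data.frame(
        name = f[2], sequence = toupper(f[3]), stable_name = sn,
        stable_offset = as.numeric(so), rank = as.integer(sr),
        stringsAsFactors = FALSE)
    } else if (f[1] == "L") {
      if (length(f) < 6) stop("malformed L-line: ", ln)
      if (!(f[6] %in% c("0M", "*", "")))
        stop("rGFA forbids overlaps between linked segments; got CIGAR '",
             f[6], "' on link ", f[2], f[3], "->", f[4], f[5])
      lks[[length(lks) + 1L]] <- data.frame(
        from = f[2], from_orient = f[3], to = f[4], to_orient = f[5],
        stringsAsFactors = FALSE)
    } ## other line types skipped
  }
  if (!length(segs)) stop("no S-lines found")
  if (synthesized)
    warning("synthesized SN/SO/SR tags for plain-GFA S-lines (permissive mode)")
  segments <- do.call(rbind, segs)
  if (anyDuplicated(segments$name))
    stop("duplicate segment name: ",
         segments$name[duplicated(segments$name)][1])
  links <- if (length(lks)) do.call(rbind, lks) else NULL
  pangraph(segments, links)
}

#' Write a pangenome graph as rGFA text
#'
#' Output is canonical and byte-stable: segments sorted by name, links
#' sorted lexicographically, tags in SN (Z), SO (i), SR (i) order, overlap
#' field `0M`.
#'
#' @param graph a `pangraph`.
#' @param path optional file path; if NULL the text is returned.
#' @return character vector of lines (invisibly when writing to a file).
#' @export
write_rgfa <- function(graph, path = NULL) {
  segs <- graph$segments[order(graph$segments$name), , drop = FALSE]
  s_lines <- sprintf("S\t%s\t%s\tSN:Z:%s\tSO:i:%d\tSR:i:%d",
                     segs$name, segs$sequence, segs$stable_name,
                     as.integer(segs$stable_offset), segs$rank)
  lk <- graph$links
  l_lines <- character()
  if (nrow(lk)) {
    l_lines <- sprintf("L\t%s\t%s\t%s\t%s\t0M",
                       lk$from, lk$from_orient, lk$to, lk$to_orient)
    l_lines <- sort(l_lines)
  }
  out <- c(s_lines, l_lines)
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Segment coordinate to stable coordinate
#'
#' @param graph a `pangraph`.
#' @param segment_name segment identifier.
#' @param seg_offset 0-based offset on the segment.
#' @return list(stable_name, offset).
#' @export
stable_of <- function(graph, segment_name, seg_offset) {
  i <- seg_row(graph, segment_name)
  len <- nchar(graph$segments$sequence[i])
  if (any(seg_offset < 0) || any(seg_offset >= len))
    stop("segment offset out of range for ", segment_name)
  list(stable_name = graph$segments$stable_name[i],
       offset = graph$segments$stable_offset[i] + seg_offset)
}

#' Stable coordinate to segment coordinate
#'
#' Inverse of [stable_of()]; uniqueness is guaranteed by the no-collapse
#' invariant. Returns NULL if no segment's stable interval contains the
#' position.
#'
#' @param graph a `pangraph`.
#' @param stable_name stable sequence name.
#' @param offset 0-based position on the stable sequence.
#' @return list(segment, seg_offset) or NULL.
#' @export
find_segment <- function(graph, stable_name, offset) {
  segs <- graph$segments
  hit <- which(segs$stable_name == stable_name &
               segs$stable_offset <= offset &
               segs$stable_offset + nchar(segs$sequence) > offset)
  if (!length(hit)) return(NULL)
  list(segment = segs$name[hit[1]],
       seg_offset = offset - segs$stable_offset[hit[1]])
}

#' Base at a segment position
#'
#' @param graph a `pangraph`.
#' @param segment_name segment identifier.
#' @param seg_offset 0-based offset.
#' @return single character; callers complement separately for reverse
#'   traversals.
#' @export
segment_base <- function(graph, segment_name, seg_offset) {
  i <- seg_row(graph, segment_name)
  s <- graph$segments$sequence[i]
  if (seg_offset < 0 || seg_offset >= nchar(s))
    stop("offset out of range")
  substr(s, seg_offset + 1, seg_offset + 1)
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

#' Oriented neighbours of a segment end
#'
#' Links are bidirected: `(a,o1)->(b,o2)` can be traversed as written and
#' as `(b,-o2)->(a,-o1)`.
#'
#' @param graph a `pangraph`.
#' @param segment segment name.
#' @param orient `"+"` or `"-"`: the orientation in which the segment is
#'   being traversed.
#' @return data.frame(segment, orient) of oriented successors.
#' @export
pg_neighbors <- function(graph, segment, orient = "+") {
  lk <- graph$links
  if (!nrow(lk))
    return(data.frame(segment = character(), orient = character(),
                      stringsAsFactors = FALSE))
  fwd <- lk$from == segment & lk$from_orient == orient
  rev <- lk$to == segment & lk$to_orient == other_orient(orient)
  out <- rbind(
    data.frame(segment = lk$to[fwd], orient = lk$to_orient[fwd],
               stringsAsFactors = FALSE),
    data.frame(segment = lk$from[rev],
               orient = other_orient(lk$from_orient[rev]),
               stringsAsFactors = FALSE))
  unique(out)
}

#' Split a segment at an internal offset
#'
#' Replaces the segment by two halves covering `[0, seg_offset)` and
#' `[seg_offset, len)`. Both inherit SN and SR; the right half's SO is
#' incremented by `seg_offset`; a +/+ link joins them and incident links
#' are re-homed, so every base keeps its stable coordinate and the spelled
#' sequences of all walks are unchanged.
#'
#' @param graph a `pangraph`.
#' @param segment_name segment to split.
#' @param seg_offset split point, `0 < seg_offset < len`.
#' @param names optional length-2 character vector naming the halves;
#'   default `<name>a` / `<name>b`.
#' @return the updated `pangraph`.
#' @export
split_segment <- function(graph, segment_name, seg_offset, names = NULL) {
  i <- seg_row(graph, segment_name)
  s <- graph$segments[i, ]
  len <- nchar(s$sequence)
  if (seg_offset <= 0 || seg_offset >= len)
    stop("split offset must be strictly inside the segment (no-op split)")
  if (is.null(names)) {
    names <- paste0(segment_name, c("a", "b"))
    while (any(names %in% graph$segments$name))
      names <- paste0(names, "x")
  }
  left <- s; right <- s
  left$name <- names[1]
  left$sequence <- substr(s$sequence, 1, seg_offset)
  right$name <- names[2]
  right$sequence <- substr(s$sequence, seg_offset + 1, len)
  right$stable_offset <- s$stable_offset + seg_offset
  segs <- graph$segments[-i, , drop = FALSE]
  segs <- rbind(segs, left, right)
  lk <- graph$links
  if (nrow(lk)) {
    ## links at the left end of the old segment (entering its start) attach
    ## to the left half; links at its right end attach to the right half
    rehome <- function(seg, orient, is_from) {
      ## a 'from' endpoint uses the end of the oriented segment;
      ## a 'to' endpoint uses its start.
      at_end <- if (is_from) orient == "+" else orient == "-"
      ifelse(seg != segment_name, seg,
             ifelse(at_end, names[2], names[1]))
    }
    lk$from <- rehome(lk$from, lk$from_orient, TRUE)
    lk$to <- rehome(lk$to, lk$to_orient, FALSE)
  }
  lk <- rbind(lk, data.frame(from = names[1], from_orient = "+",
                             to = names[2], to_orient = "+",
                             stringsAsFactors = FALSE))
  pangraph(segs, lk)
}

#' Spell the sequence of an oriented walk
#'
#' @param graph a `pangraph`.
#' @param walk data.frame(orient, name) of oriented segments (orient in
#'   `">"`/`"<"` or `"+"`/`"-"`).
#' @return character string of the spelled DNA.
#' @export
spell_walk <- function(graph, walk) {
  if (!nrow(walk)) return("")
  ori <- walk$orient
  ori[ori == ">"] <- "+"; ori[ori == "<"] <- "-"
  pieces <- vapply(seq_len(nrow(walk)), function(i) {
    s <- graph$segments$sequence[seg_row(graph, walk$name[i])]
    if (ori[i] == "+") s else revcomp(s)
  }, character(1))
  paste(pieces, collapse = "")
}

#' Total length of a stable sequence in the graph
#'
#' Length of the rank-0 tiling of `stable_name` (maximum stable end over
#' its segments).
#' @param graph a `pangraph`.
#' @param stable_name stable sequence name.
#' @return length in bp.
#' @export
stable_length <- function(graph, stable_name) {
  segs <- graph$segments
  sel <- segs$stable_name == stable_name & segs$rank == 0
  if (!any(sel)) stop("no rank-0 segments for ", stable_name)
  max(segs$stable_offset[sel] + nchar(segs$sequence[sel]))
}

#' Rank-0 backbone of a stable sequence
#'
#' @param graph a `pangraph`.
#' @param stable_name stable sequence name.
#' @return data.frame of rank-0 segments in stable order.
#' @export
backbone_segments <- function(graph, stable_name) {
  segs <- graph$segments
  s <- segs[segs$stable_name == stable_name & segs$rank == 0, , drop = FALSE]
  s[order(s$stable_offset), , drop = FALSE]
}
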