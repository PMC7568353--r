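## GAF: 12-column TAB-delimited sequence-to-graph mapping format, a
## superset of PAF. Column 6 is an oriented path over segments or stable
## intervals, or a bare stable name (the PAF-reduced form).

#' Parse a GAF path string
#'
#' Grammar: `([><][^\s><]+(:\d+-\d+)?)+ | ([^\s><]+)`. The second
#' alternative is the PAF-reduced form: a bare stable sequence name.
#'
#' @param text path string (column 6 of GAF).
#' @return data.frame(orient, name, start, end). Oriented elements have
#'   orient `">"`/`"<"`; a bare name is a single row with orient `NA` and
#'   `NA` interval. Stable-interval suffixes `:a-b` fill start/end
#'   (0-based, half-open).
#' @export
parse_path <- function(text) {
  stopifnot(length(text) == 1, nzchar(text))
  oriented <- "^([><][^[:space:]><]+(:[0-9]+-[0-9]+)?)+$"
  bare <- "^[^[:space:]><]+$"
  if (grepl(bare, text)) {
    return(data.frame(orient = NA_character_, name = text,
                      start = NA_real_, end = NA_real_,
                      stringsAsFactors = FALSE))
  }
  if (!grepl(oriented, text))
    stop("malformed GAF path: ", text)
  m <- gregexpr("[><][^[:space:]><]+", text)[[1]]
  parts <- regmatches(text, list(m))[[1]]
  orient <- substr(parts, 1, 1)
  body <- substring(parts, 2)
  has_iv <- grepl(":[0-9]+-[0-9]+$", body)
  name <- ifelse(has_iv, sub(":[0-9]+-[0-9]+$", "", body), body)
  start <- rep(NA_real_, length(body)); end <- start
  if (any(has_iv)) {
    iv <- sub("^.*:([0-9]+)-([0-9]+)$", "\\1,\\2", body[has_iv])
    sp <- strsplit(iv, ",", fixed = TRUE)
    start[has_iv] <- as.numeric(vapply(sp, `[`, "", 1))
    end[has_iv] <- as.numeric(vapply(sp, `[`, "", 2))
  }
  if (any(has_iv & !(start < end | is.na(start))))
    stop("empty stable interval in path: ", text)
  data.frame(orient = orient, name = name, start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Format a parsed path back to its string form
#' @param path data.frame as returned by [parse_path()].
#' @return path string.
#' @export
format_path <- function(path) {
  if (nrow(path) == 1 && is.na(path$orient[1])) return(path$name[1])
  iv <- ifelse(is.na(path$start), "",
               sprintf(":%d-%d", as.integer(path$start), as.integer(path$end)))
  paste0(path$orient, path$name, iv, collapse = "")
}

#' Convert a segment-coordinate path to stable coordinates
#'
#' Each segment element becomes its stable interval `(SN, SO, SO+len)` with
#' the element's orientation. Consecutive elements on the same stable
#' sequence with the same orientation whose intervals abut (forward: first
#' end == second start; reverse: first start == second end) are merged
#' greedily left-to-right to a fixed point, so `>s1>s2>s3` spanning
#' chr1:0-5,5-8,8-12 renders as `>chr1:0-12`.
#'
#' @param graph a `pangraph`.
#' @param path data.frame of oriented segment elements.
#' @return data.frame of oriented stable-interval elements.
#' @export
path_to_stable <- function(graph, path) {
  if (nrow(path) == 1 && is.na(path$orient[1])) return(path)
  n <- nrow(path)
  idx <- match(path$name, graph$segments$name)
  if (anyNA(idx)) stop("unknown segment in path: ",
                       path$name[which(is.na(idx))[1]])
  segs <- graph$segments
  el <- data.frame(orient = path$orient,
                   name = segs$stable_name[idx],
                   start = segs$stable_offset[idx],
                   end = segs$stable_offset[idx] + nchar(segs$sequence[idx]),
                   stringsAsFactors = FALSE)
  out <- el[1, , drop = FALSE]
  for (i in seq_len(n)[-1]) {
    last <- nrow(out)
    a <- out[last, ]; b <- el[i, ]
    mergeable <- a$orient == b$orient && a$name == b$name &&
      ((a$orient == ">" && a$end == b$start) ||
       (a$orient == "<" && a$start == b$end))
    if (mergeable) {
      out$start[last] <- min(a$start, b$start)
      out$end[last] <- max(a$end, b$end)
    } else {
      out <- rbind(out, b)
    }
  }
  rownames(out) <- NULL
  out
}

#' GAF record constructor
#'
#' @param query_name,query_length,query_start,query_end query columns
#'   (0-based, half-open).
#' @param strand `"+"`/`"-"` relative to the path.
#' @param path data.frame as from [parse_path()].
#' @param path_length,path_start,path_end path columns in bp.
#' @param matches,block_length residue matches / block length incl. gaps.
#' @param mapq 0-255; 255 = missing.
#' @param tags named character vector of pre-rendered SAM-style tags.
#' @return object of class `gaf_record`.
#' @export
gaf_record <- function(query_name, query_length, query_start, query_end,
                       strand, path, path_length, path_start, path_end,
                       matches, block_length, mapq = 255,
                       tags = character()) {
  r <- list(query_name = query_name, query_length = query_length,
            query_start = query_start, query_end = query_end,
            strand = strand, path = path, path_length = path_length,
            path_start = path_start, path_end = path_end,
            matches = matches, block_length = block_length,
            mapq = mapq, tags = tags)
  class(r) <- "gaf_record"
  validate_gaf_record(r)
  r
}

#' @export
print.gaf_record <- function(x, ...) {
  cat(format_gaf_record(x), "\n")
  invisible(x)
}

validate_gaf_record <- function(r) {
  with(r, {
    if (!(query_start >= 0 && query_start <= query_end &&
          query_end <= query_length))
      stop("invalid query interval in GAF record for ", query_name)
    if (!(path_start >= 0 && path_start <= path_end &&
          path_end <= path_length))
      stop("invalid path interval in GAF record for ", query_name)
    if (matches > block_length) stop("matches > block_length")
    if (mapq < 0 || mapq > 255) stop("mapq outside 0-255")
  })
  invisible(TRUE)
}

format_gaf_record <- function(r) {
  line <- paste(r$query_name, r$query_length, r$query_start, r$query_end,
                r$strand, format_path(r$path), r$path_length, r$path_start,
                r$path_end, r$matches, r$block_length, r$mapq, sep = "\t")
  if (length(r$tags)) line <- paste(c(line, r$tags), collapse = "\t")
  line
}

#' Write GAF records
#' @param records list of `gaf_record`.
#' @param path optional output file.
#' @return character vector of lines.
#' @export
write_gaf <- function(records, path = NULL) {
  if (inherits(records, "gaf_record")) records <- list(records)
  out <- vapply(records, format_gaf_record, character(1))
  if (!is.null(path)) { writeLines(out, path); return(invisible(out)) }
  out
}

#' Read GAF records
#' @param text lines, a single string with newlines, or a file path.
#' @return list of `gaf_record`.
#' @export
read_gaf <- function(text) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text))
    text <- readLines(text)
  else if (length(text) == 1 && grepl("\n", text))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  text <- text[nzchar(text)]
  lapply(seq_along(text), function(i) {
    f <- strsplit(text[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 12)
      stop("GAF line ", i, ": expected 12 columns, got ", length(f))
    num <- suppressWarnings(as.numeric(f[c(2:4, 7:12)]))
    if (anyNA(num))
      stop("GAF line ", i, ": non-integer numeric column")
    if (num[9] < 0 || num[9] > 255)
      stop("GAF line ", i, ": mapq outside 0-255")
    gaf_record(f[1], num[1], num[2], num[3], f[5], parse_path(f[6]),
               num[4], num[5], num[6], num[7], num[8], num[9],
               tags = if (length(f) > 12) f[-(1:12)] else character())
  })
}

#' Reduce a single-reference GAF record to PAF form
#'
#' If every path element lies on one stable sequence with one orientation,
#' the path is replaced by the bare stable name on the forward strand:
#' column 7 becomes the full stable-sequence length, columns 8-9 become
#' coordinates on that sequence, and column 5 carries the orientation.
#' Such a line is a valid PAF line. Mixed paths are returned unchanged.
#'
#' @param record a `gaf_record` whose path is in stable coordinates (see
#'   [path_to_stable()]).
#' @param graph the `pangraph` (needed for the total stable length).
#' @return the (possibly reduced) `gaf_record`.
#' @export
reduce_to_reference <- function(record, graph) {
  p <- record$path
  if (nrow(p) == 1 && is.na(p$orient[1])) return(record)
  if (anyNA(p$start)) return(record)   # segment-coordinate path: convert first
  if (length(unique(p$name)) != 1 || length(unique(p$orient)) != 1)
    return(record)
  sn <- p$name[1]
  total <- stable_length(graph, sn)
  lo <- min(p$start); hi <- max(p$end)
  ## offsets within the old path become offsets on the stable sequence
  r <- record
  rev_path <- p$orient[1] == "<"
  if (!rev_path) {
    r$path_start <- lo + record$path_start
    r$path_end <- lo + record$path_end
  } else {
    r$path_start <- hi - record$path_end
    r$path_end <- hi - record$path_start
  }
  ## strand relative to the forward reference combines the record strand
  ## with the traversal orientation of the path
  r$strand <- if (xor(record$strand == "-", rev_path)) "-" else "+"
  r$path <- data.frame(orient = NA_character_, name = sn,
                       start = NA_real_, end = NA_real_,
                       stringsAsFactors = FALSE)
  r$path_length <- total
  validate_gaf_record(r)
  r
}
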