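## Minimizer seeding: windowed minimizers over an invertible hash of the
## 2-bit canonical k-mer encoding; hash index over graph segments; anchor
## collection for a query.

## rolling min/max over a fixed window, O(n), via the two-pass block trick
roll_extreme <- function(v, w, op = c("min", "max")) {
  op <- match.arg(op)
  n <- length(v)
  if (w <= 1 || n == 0) return(v)
  pad <- (-n) %% w
  fill <- if (op == "min") Inf else -Inf
  m <- matrix(c(v, rep(fill, pad)), nrow = w)
  f <- if (op == "min") function(x) apply(x, 2, cummin) else function(x) apply(x, 2, cummax)
  pre <- f(m)                                   # prefix extreme within block
  suf <- f(m[w:1, , drop = FALSE])[w:1, , drop = FALSE]  # suffix extreme
  pre <- as.vector(pre); suf <- as.vector(suf)
  i <- seq_len(n - w + 1L)
  j <- i + w - 1L
  if (op == "min") pmin(suf[i], pre[j]) else pmax(suf[i], pre[j])
}

## 2-bit codes; N (or any other letter) -> NA
base_codes <- function(seq) {
  v <- utf8ToInt(seq)
  code <- rep(NA_real_, length(v))
  code[v == 65L] <- 0; code[v == 67L] <- 1  # A C
  code[v == 71L] <- 2; code[v == 84L] <- 3  # G T
  code
}

## invertible mix: multiply by a fixed odd constant modulo 4^k; exact in
## doubles for k <= 26 via split multiplication
kmer_mix <- function(x, k) {
  M <- 4^k
  half_bits <- ceiling(2 * k / 2)
  H <- 2^half_bits
  A <- 648053  # odd, < 2^20
  x0 <- x %% H
  x1 <- (x - x0) / H
  ((x0 * A) %% M + ((x1 * A) %% (M / H)) * H) %% M
}

#' Extract windowed minimizers from a DNA sequence
#'
#' For every window of `window` consecutive k-mers, the k-mer whose
#' canonical-strand hash is smallest is reported once (all tied positions
#' are reported). K-mers containing N are excluded; strand-symmetric
#' palindromic k-mers are skipped. The hash is an invertible mix of the
#' 2-bit canonical encoding, so index lookups are exact k-mer matches.
#'
#' @param sequence DNA string.
#' @param k k-mer length (default 19; must be <= 26).
#' @param window number of consecutive k-mers per window (default 10).
#' @return data.frame(pos, hash, strand): `pos` is the 0-based position of
#'   the k-mer's last base; `strand` is `"+"` if the forward k-mer is
#'   canonical.
#' @export
extract_minimizers <- function(sequence, k = 19, window = 10) {
  stopifnot(k >= 1, k <= 26, window >= 1)
  empty <- data.frame(pos = numeric(), hash = numeric(),
                      strand = character(), stringsAsFactors = FALSE)
  n <- nchar(sequence)
  if (n < k) return(empty)
  code <- base_codes(toupper(sequence))
  nk <- n - k + 1L
  ## forward and reverse-complement codes by weighted sums (exact doubles)
  fwd <- numeric(nk); rev <- numeric(nk)
  isn <- is.na(code)
  code0 <- ifelse(isn, 0, code)
  for (t in 0:(k - 1)) {
    idx <- (1 + t):(nk + t)
    fwd <- fwd + code0[idx] * 4^(k - 1 - t)
    rev <- rev + (3 - code0[idx]) * 4^t
  }
  ## k-mers containing N
  csn <- cumsum(isn)
  hasN <- (csn[seq_len(nk) + k - 1L] - c(0, csn)[seq_len(nk)]) > 0
  canon <- pmin(fwd, rev)
  strand <- ifelse(fwd <= rev, "+", "-")
  h <- kmer_mix(canon, k)
  h[hasN] <- Inf
  h[fwd == rev] <- Inf   # strand-ambiguous palindrome
  if (all(!is.finite(h))) return(empty)
  if (nk <= window) {
    m <- min(h)
    keep <- which(h == m & is.finite(h))
  } else {
    winmin <- roll_extreme(h, window, "min")
    ## position i is selected iff some window covering i has min == h[i],
    ## i.e. the max of winmin over windows covering i equals h[i]
    nw <- length(winmin)
    cover <- roll_extreme(c(rep(-Inf, window - 1L), winmin,
                            rep(-Inf, window - 1L)), window, "max")
    keep <- which(is.finite(h) & h == cover[seq_len(nk)])
  }
  data.frame(pos = keep - 1L + (k - 1L), hash = h[keep],
             strand = strand[keep], stringsAsFactors = FALSE)
}

#' Build a minimizer index over graph segments
#'
#' Minimizers are extracted per segment (never across segment junctions,
#' so variation shorter than a segment boundary context cannot be seeded
#' across it; a documented limitation). Hashes whose posting count exceeds
#' `max_occ` are dropped.
#'
#' @param graph a `pangraph`.
#' @param k,window minimizer parameters (defaults 19, 10).
#' @param max_occ occurrence cap per hash (default 250).
#' @return object of class `pg_index`.
#' @export
build_index <- function(graph, k = 19, window = 10, max_occ = 250) {
  per <- lapply(seq_len(nrow(graph$segments)), function(i) {
    mm <- extract_minimizers(graph$segments$sequence[i], k, window)
    if (!nrow(mm)) return(NULL)
    mm$segment <- graph$segments$name[i]
    mm
  })
  post <- do.call(rbind, per)
  if (is.null(post))
    post <- data.frame(pos = numeric(), hash = numeric(),
                       strand = character(), segment = character(),
                       stringsAsFactors = FALSE)
  if (nrow(post)) {
    cnt <- table(post$hash)
    drop <- as.numeric(names(cnt)[cnt > max_occ])
    if (length(drop)) post <- post[!(post$hash %in% drop), , drop = FALSE]
    post <- post[order(post$hash, post$segment, post$pos), , drop = FALSE]
  }
  structure(list(postings = post, k = k, window = window,
                 max_occ = max_occ, graph = graph),
            class = "pg_index")
}

#' @export
print.pg_index <- function(x, ...) {
  cat(sprintf("pg_index: k=%d window=%d, %d postings over %d segments\n",
              x$k, x$window, nrow(x$postings),
              length(unique(x$postings$segment))))
  invisible(x)
}

#' Collect anchors between an indexed graph and a query
#'
#' An anchor `(segment, x, y, w)` records that the k-long interval ending
#' at `x` (0-based, inclusive) on the segment matches the interval ending
#' at `y` on the query; `strand` is the relative orientation. For
#' reverse-strand matches `y` is the end position of the match on the
#' reverse-complemented query.
#'
#' @param index a `pg_index`.
#' @param query DNA string.
#' @return data.frame(segment, x, y, w, strand) sorted by (segment, strand,
#'   x, y).
#' @export
collect_anchors <- function(index, query) {
  k <- index$k
  empty <- data.frame(segment = character(), x = numeric(), y = numeric(),
                      w = numeric(), strand = character(),
                      stringsAsFactors = FALSE)
  qm <- extract_minimizers(query, k, index$window)
  if (!nrow(qm) || !nrow(index$postings)) return(empty)
  post <- index$postings   # sorted by hash
  first <- match(qm$hash, post$hash)
  last <- findInterval(qm$hash, post$hash)
  keep <- which(!is.na(first))
  if (!length(keep)) return(empty)
  cnt <- last[keep] - first[keep] + 1L
  pidx <- sequence(cnt) + rep(first[keep] - 1L, cnt)
  qidx <- rep(keep, cnt)
  qlen <- nchar(query)
  rel <- ifelse(post$strand[pidx] == qm$strand[qidx], "+", "-")
  y <- ifelse(rel == "+", qm$pos[qidx],
              qlen - 1 - (qm$pos[qidx] - (k - 1)))
  a <- data.frame(segment = post$segment[pidx], x = post$pos[pidx],
                  y = y, w = k, strand = rel, stringsAsFactors = FALSE)
  a <- a[order(a$segment, a$strand, a$x, a$y), , drop = FALSE]
  rownames(a) <- NULL
  a
}
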