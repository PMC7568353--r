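# fixtures built in code: worked-example graph, random graph generator

# two-reference graph: chr1 tiled by s1,s2,s3; foo-derived s4 (alt allele),
# s5,s6 (insertion path continuing onto foo)
example_graph <- function() {
  parse_rgfa(c(
    "S\ts1\tGTCGA\tSN:Z:chr1\tSO:i:0\tSR:i:0",
    "S\ts2\tGTG\tSN:Z:chr1\tSO:i:5\tSR:i:0",
    "S\ts3\tGCTT\tSN:Z:chr1\tSO:i:8\tSR:i:0",
    "S\ts4\tCC\tSN:Z:foo\tSO:i:0\tSR:i:1",
    "S\ts5\tTTTT\tSN:Z:foo\tSO:i:8\tSR:i:1",
    "S\ts6\tCCCC\tSN:Z:foo\tSO:i:12\tSR:i:1",
    "L\ts1\t+\ts2\t+\t0M", "L\ts2\t+\ts3\t+\t0M",
    "L\ts1\t+\ts4\t+\t0M", "L\ts4\t+\ts3\t+\t0M",
    "L\ts2\t+\ts5\t+\t0M", "L\ts5\t+\ts6\t+\t0M"))
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# random valid rGFA graph: a tiled backbone plus alt segments bridging
# backbone boundaries
random_graph <- function(n_backbone = 4, n_alt = 2, seg_len = c(5, 30)) {
  lens <- sample(seg_len[1]:seg_len[2], n_backbone, replace = TRUE)
  off <- cumsum(c(0, lens[-n_backbone]))
  segs <- data.frame(
    name = paste0("b", seq_len(n_backbone)),
    sequence = vapply(lens, random_dna_str, character(1)),
    stable_name = "ref", stable_offset = off, rank = 0L,
    stringsAsFactors = FALSE)
  links <- NULL
  if (n_backbone > 1)
    links <- data.frame(from = segs$name[-n_backbone], from_orient = "+",
                        to = segs$name[-1], to_orient = "+",
                        stringsAsFactors = FALSE)
  if (n_alt > 0) {
    qoff <- 0
    for (i in seq_len(n_alt)) {
      at <- sample(n_backbone - 1, 1)
      len <- sample(seg_len[1]:seg_len[2], 1)
      nm <- paste0("a", i)
      segs <- rbind(segs, data.frame(
        name = nm, sequence = random_dna_str(len),
        stable_name = "alt", stable_offset = qoff, rank = 1L,
        stringsAsFactors = FALSE))
      qoff <- qoff + len
      links <- rbind(links,
        data.frame(from = segs$name[at], from_orient = "+", to = nm,
                   to_orient = "+", stringsAsFactors = FALSE),
        data.frame(from = nm, from_orient = "+", to = segs$name[at + 1],
                   to_orient = "+", stringsAsFactors = FALSE))
    }
  }
  key <- paste(links$from, links$from_orient, links$to, links$to_orient)
  pangraph(segs, links[!duplicated(key), ])
}

seg_len_of <- function(g, nm) nchar(g$segments$sequence[g$segments$name == nm])

within_record_stable <- function(r, g) {
  r$path <- path_to_stable(g, r$path)
  r
}

graphs_equal <- function(a, b) {
  sa <- a$segments[order(a$segments$name), ]
  sb <- b$segments[order(b$segments$name), ]
  rownames(sa) <- rownames(sb) <- NULL
  la <- a$links[do.call(order, a$links), ]
  lb <- b$links[do.call(order, b$links), ]
  rownames(la) <- rownames(lb) <- NULL
  isTRUE(all.equal(sa, sb)) && isTRUE(all.equal(la, lb))
}

# full-cost chaining DP by brute force, optionally windowed
brute_chain_dp <- function(a, params, window = Inf) {
  n <- nrow(a)
  f <- numeric(n)
  for (i in seq_len(n)) {
    best <- a$w[i]
    for (j in seq_len(i - 1)) {
      dx <- a$x[i] - a$x[j]; dy <- a$y[i] - a$y[j]
      if (dx <= 0 || dy <= 0 || dx > window || dy > window) next
      g <- abs(dy - dx)
      if (g > params$G) next
      beta <- if (g == 0) 0 else
        params$c1 * g + params$c2 * min(dx, dy) + log2(g)
      sc <- f[j] + min(min(dx, dy), a$w[i]) - beta
      if (sc > best) best <- sc
    }
    f[i] <- best
  }
  if (n) max(f) else 0
}

random_anchor_set <- function(n, spread = 4000, noise = 50) {
  x <- sort(sample(spread, n))
  y <- pmax(x + round(rnorm(n, 0, noise)), 19)
  a <- data.frame(segment = "s", x = x, y = y, w = 19, strand = "+",
                  stringsAsFactors = FALSE)
  a[order(a$x, a$y), ]
}
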