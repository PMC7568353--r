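test_that("a minimal rGFA parses into segments and links", {
  g <- parse_rgfa(c("S\ts1\tACGT\tSN:Z:chr1\tSO:i:0\tSR:i:0",
                    "S\ts2\tGG\tSN:Z:chr1\tSO:i:4\tSR:i:0",
                    "L\ts1\t+\ts2\t+\t0M"))
  expect_equal(nrow(g$segments), 2)
  expect_equal(nrow(g$links), 1)
  expect_equal(g$segments$stable_offset[g$segments$name == "s2"], 4)
})

test_that("format errors are rejected with informative messages", {
  expect_error(parse_rgfa(c("S\ts1\tACGT\tSN:Z:c\tSO:i:0\tSR:i:0",
                            "S\ts1\tGG\tSN:Z:c\tSO:i:4\tSR:i:0")),
               "duplicate segment")
  expect_error(parse_rgfa(c("S\ts1\tACGT\tSN:Z:c\tSO:i:0\tSR:i:0",
                            "L\ts1\t+\tsX\t+\t0M")),
               "unknown segment")
  expect_error(parse_rgfa(c("S\ts1\tACGT\tSN:Z:c\tSO:i:0\tSR:i:0",
                            "S\ts2\tGG\tSN:Z:c\tSO:i:4\tSR:i:0",
                            "L\ts1\t+\ts2\t+\t3M")),
               "forbids overlaps")
  expect_error(parse_rgfa("S\ts1\tACGT"), "SN/SO/SR")
  expect_warning(g <- parse_rgfa("S\ts1\tACGT", permissive = TRUE),
                 "synthesized")
  expect_equal(g$segments$stable_name, "s1")
})

test_that("overlapping stable intervals of one sequence are a collapse", {
  expect_error(parse_rgfa(c("S\ts1\tAAAAA\tSN:Z:chr1\tSO:i:0\tSR:i:0",
                            "S\ts2\tCCCCC\tSN:Z:chr1\tSO:i:3\tSR:i:1")),
               "collapse.*s1.*s2")
})

test_that("duplicate bidirected links are detected in either writing", {
  segs <- data.frame(name = c("a", "b"), sequence = c("ACG", "TTG"),
                     stable_name = c("a", "b"), stable_offset = 0,
                     rank = 0:1)
  lk <- data.frame(from = c("a", "b"), from_orient = c("+", "-"),
                   to = c("b", "a"), to_orient = c("+", "-"))
  expect_error(pangraph(segs, lk), "duplicate bidirected link")
})

test_that("write -> parse -> write is byte-stable and parse(write(G)) == G", {
  set.seed(42)
  for (i in 1:50) {
    g <- random_graph(sample(2:6, 1), sample(0:3, 1))
    txt <- write_rgfa(g)
    g2 <- parse_rgfa(txt)
    expect_true(graphs_equal(g, g2))
    expect_identical(write_rgfa(g2), txt)
  }
})

test_that("writing emits S-lines then sorted L-lines with 0M overlaps", {
  g <- parse_rgfa(c("S\ts1\tACGT\tSN:Z:chr1\tSO:i:0\tSR:i:0",
                    "S\ts2\tGG\tSN:Z:chr1\tSO:i:4\tSR:i:0",
                    "L\ts1\t+\ts2\t+\t0M"))
  out <- write_rgfa(g)
  expect_length(out, 3)
  expect_match(out[3], "^L\t.*\t0M$")
  g0 <- pangraph(g$segments)   # no links
  expect_true(all(grepl("^S\t", write_rgfa(g0))))
})

test_that("stable_of adds the segment offset to SO", {
  g <- example_graph()
  expect_equal(stable_of(g, "s2", 2),
               list(stable_name = "chr1", offset = 7))
  expect_equal(stable_of(g, "s5", 0),
               list(stable_name = "foo", offset = 8))
  expect_error(stable_of(g, "s2", 3), "out of range")
  expect_error(stable_of(g, "nope", 0), "unknown segment")
})

test_that("find_segment inverts stable_of everywhere, matching a scan", {
  set.seed(7)
  g <- random_graph(5, 3)
  segs <- g$segments
  for (i in seq_len(nrow(segs))) {
    for (off in c(0, nchar(segs$sequence[i]) - 1)) {
      sp <- stable_of(g, segs$name[i], off)
      hit <- find_segment(g, sp$stable_name, sp$offset)
      expect_equal(hit$segment, segs$name[i])
      expect_equal(hit$seg_offset, off)
    }
  }
  # brute-force interval scan over random positions
  for (r in 1:200) {
    sn <- sample(unique(segs$stable_name), 1)
    pos <- sample(0:(max(segs$stable_offset + nchar(segs$sequence)) + 5), 1)
    expwant <- NULL
    for (i in seq_len(nrow(segs))) {
      if (segs$stable_name[i] == sn && segs$stable_offset[i] <= pos &&
          segs$stable_offset[i] + nchar(segs$sequence[i]) > pos)
        expwant <- list(segment = segs$name[i],
                        seg_offset = pos - segs$stable_offset[i])
    }
    expect_equal(find_segment(g, sn, pos), expwant)
  }
  expect_null(find_segment(g, "ref", 10^9))
})

test_that("segment_base indexes the sequence like the (s2,2) convention", {
  g <- pangraph(data.frame(name = "s2", sequence = "ATGC",
                           stable_name = "c", stable_offset = 0, rank = 0))
  expect_equal(segment_base(g, "s2", 2), "G")
  expect_equal(segment_base(g, "s2", 0), "A")
  expect_error(segment_base(g, "s2", 4), "out of range")
})

test_that("spelled forward walks concatenate member sequences", {
  set.seed(8)
  for (r in 1:10) {
    g <- random_graph(4, 0)
    walk <- data.frame(orient = ">", name = paste0("b", 1:4))
    expect_equal(spell_walk(g, walk), paste(g$segments$sequence, collapse = ""))
  }
})

test_that("split_segment preserves stable coordinates of every base", {
  g <- example_graph()
  g2 <- split_segment(g, "s1", 2)
  expect_false("s1" %in% g2$segments$name)
  for (nm in g$segments$name) {
    for (off in seq_len(seg_len_of(g, nm)) - 1) {
      want <- stable_of(g, nm, off)
      hit <- find_segment(g2, want$stable_name, want$offset)
      expect_equal(stable_of(g2, hit$segment, hit$seg_offset), want)
    }
  }
  expect_error(split_segment(g, "s1", 0), "no-op")
  expect_error(split_segment(g, "s1", 5), "no-op")
})

test_that("split_segment yields the forced stable intervals and keeps walks", {
  seq12 <- strrep("ACGT", 3)
  g <- pangraph(data.frame(name = "s", sequence = seq12,
                           stable_name = "chr9", stable_offset = 100,
                           rank = 0))
  g2 <- split_segment(g, "s", 5)
  s <- g2$segments[order(g2$segments$stable_offset), ]
  expect_equal(s$stable_offset, c(100, 105))
  expect_equal(nchar(s$sequence), c(5, 7))
  # spelled sequences preserved across the split
  expect_equal(spell_walk(g2, data.frame(orient = ">", name = s$name)),
               seq12)
})

test_that("split_segment re-homes incident links to the correct half", {
  set.seed(9)
  for (r in 1:20) {
    g <- random_graph(4, 2)
    nm <- sample(g$segments$name[nchar(g$segments$sequence) > 2], 1)
    at <- sample(nchar(g$segments$sequence[g$segments$name == nm]) - 1, 1)
    g2 <- split_segment(g, nm, at)
    validate_pangraph(g2)
    # k-long spelled walks from every backbone start are preserved
    spell_from <- function(graph, start, depth = 3) {
      out <- character()
      rec <- function(seg, ori, acc, d) {
        seqv <- graph$segments$sequence[graph$segments$name == seg]
        if (ori == "-") seqv <- pangraphr:::revcomp(seqv)
        acc <- paste0(acc, seqv)
        nb <- pg_neighbors(graph, seg, ori)
        if (d == 0 || !nrow(nb)) { out <<- c(out, acc); return() }
        for (q in seq_len(nrow(nb))) rec(nb$segment[q], nb$orient[q], acc, d - 1)
      }
      rec(start, "+", "", depth)
      sort(unique(out))
    }
    w1 <- spell_from(g, "b1", 3)
    w2 <- spell_from(g2, if ("b1" %in% g2$segments$name) "b1" else "b1a", 4)
    # every walk of the original graph is a prefix of some split-graph walk
    expect_true(all(vapply(w1, function(s)
      any(startsWith(w2, s) | startsWith(s, w2)), logical(1))))
  }
})
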