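mk_chain <- function(segment, xs, ys, score, strand = "+", w = 19) {
  a <- data.frame(segment = segment, x = xs, y = ys, w = w,
                  strand = strand, stringsAsFactors = FALSE)
  structure(list(anchors = a, score = score, segment = segment,
                 strand = strand,
                 query_start = min(ys) - w + 1, query_end = max(ys) + 1,
                 target_start = min(xs) - w + 1, target_end = max(xs) + 1),
            class = "linear_chain")
}

# linear graph ref1 -> ref2 -> ref3 plus a detached pair iso1 -> iso2
linked_graph <- function() {
  pangraph(
    data.frame(name = c("ref1", "ref2", "ref3", "iso1", "iso2"),
               sequence = c(strrep("A", 200), strrep("C", 150),
                            strrep("G", 200), strrep("T", 100),
                            strrep("A", 100)),
               stable_name = c("chr", "chr", "chr", "iso", "iso"),
               stable_offset = c(0, 200, 350, 0, 100),
               rank = c(0, 0, 0, 0, 0)),
    data.frame(from = c("ref1", "ref2", "iso1"), from_orient = "+",
               to = c("ref2", "ref3", "iso2"), to_orient = "+"))
}

test_that("precedence holds on one segment and fails across components", {
  g <- linked_graph()
  c1 <- mk_chain("ref1", c(30, 60), c(30, 60), 40)
  c2 <- mk_chain("ref1", c(100, 130), c(100, 130), 40)
  pr <- precedes(c1, c2, g)
  expect_true(pr$ok)
  expect_null(pr$walks[[1]]$path)   # empty walk
  c3 <- mk_chain("iso1", c(30, 60), c(300, 330), 40)
  expect_false(precedes(c1, c3, g)$ok)
  expect_false(precedes(c2, c1, g)$ok)   # wrong query order
})

test_that("witness walk lengths match exhaustive bounded enumeration on cycles", {
  # X <-> Y cycle with an exit to Z
  g <- pangraph(
    data.frame(name = c("X", "Y", "Z"),
               sequence = c(strrep("A", 50), strrep("C", 30), strrep("G", 40)),
               stable_name = c("sx", "sy", "sz"),
               stable_offset = 0, rank = c(0, 1, 1)),
    data.frame(from = c("X", "Y", "X"), from_orient = "+",
               to = c("Y", "X", "Z"), to_orient = "+"))
  ws <- pangraphr:::enumerate_walks(g, "X", "+", "Z", "+",
                                    max_len = 500, k_walks = 16)
  got <- sort(vapply(ws, `[[`, numeric(1), "graph_length"))
  # oracle: recursive enumeration of all walks with length <= 500
  lens <- c()
  rec <- function(seg, ori, len) {
    if (len > 500) return()
    nb <- pg_neighbors(g, seg, ori)
    for (i in seq_len(nrow(nb))) {
      s2 <- nb$segment[i]; o2 <- nb$orient[i]
      if (s2 == "Z" && o2 == "+") lens <<- c(lens, len)
      else rec(s2, o2, len + seg_len_of(g, s2))
    }
  }
  rec("X", "+", 0)
  expect_identical(got, sort(lens)[seq_along(got)])
  expect_gt(length(got), 3)   # the cycle is actually traversed
})

test_that("choose_walk minimizes |graph length - query distance|", {
  mkw <- function(len) structure(list(path = NULL, graph_length = len),
                                 class = "pg_walk")
  ws <- list(mkw(100), mkw(480), mkw(900))
  expect_equal(choose_walk(ws, 500)$graph_length, 480)
  expect_equal(choose_walk(list(mkw(7)), 99)$graph_length, 7)
  # tie: equal deviation, shorter walk wins
  expect_equal(choose_walk(list(mkw(600), mkw(400)), 500)$graph_length, 400)
  expect_error(choose_walk(list(), 10), "empty")
})

test_that("graph-chain DP equals a brute-force DP over precedence pairs", {
  set.seed(40)
  g <- linked_graph()
  p <- chain_params(min_score = 0, min_anchors = 1)
  for (rep in 1:10) {
    n <- sample(4:12, 1)
    segs <- sort(sample(c("ref1", "ref2", "ref3"), n, replace = TRUE))
    offs <- c(ref1 = 0, ref2 = 200, ref3 = 350)
    chains <- list()
    ystart <- 20
    for (i in seq_len(n)) {
      x0 <- sample(20:80, 1)
      chains[[i]] <- mk_chain(segs[i], c(x0, x0 + 19),
                              offs[[segs[i]]] + c(x0, x0 + 19) +
                                sample(-10:10, 1),
                              score = sample(20:60, 1))
    }
    ord <- order(vapply(chains, `[[`, numeric(1), "query_end"))
    chains <- chains[ord]
    got <- chain_graph(chains, g, p)
    got_best <- max(vapply(got, `[[`, numeric(1), "score"))
    # independent memoized recursion on the same recurrence
    memo <- rep(NA_real_, n)
    best_ending <- function(i) {
      if (!is.na(memo[i])) return(memo[i])
      omega_i <- chains[[i]]$score
      best <- omega_i
      for (j in seq_len(n)) {
        if (j == i) next
        pr <- precedes(chains[[j]], chains[[i]], g, p)
        if (!pr$ok) next
        if (chains[[j]]$query_end > chains[[i]]$query_end) next
        wk <- choose_walk(pr$walks, pr$query_distance)
        gap <- abs(pr$query_distance - wk$graph_length)
        beta <- if (gap == 0) 0 else
          p$c1 * gap + p$c2 * min(pr$query_distance, wk$graph_length) +
          log2(gap)
        if (gap > p$G) next
        cand <- best_ending(j) + omega_i - beta
        if (cand > best) best <- cand
      }
      memo[i] <<- best
      best
    }
    oracle <- max(vapply(seq_len(n), best_ending, numeric(1)))
    expect_equal(got_best, oracle, tolerance = 1e-9)
  }
})

test_that("every emitted graph chain satisfies the chain conditions", {
  set.seed(41)
  cfg <- sim_config(seed = 41, ref_length = 3e4, snp_rate = 0.002,
                    sv_spec = data.frame(type = "INS", length = 300,
                                         count = 1),
                    min_sv_spacing = 600)
  ref <- simulate_reference(cfg)
  mut <- mutate_assembly(ref, cfg)
  graph <- build_incremental(ref, list(mut$assembly), min_aln = 2e4)
  idx <- build_index(graph)
  reads <- simulate_reads(mut$assembly,
                          sim_config(seed = 42, read_length_mean = 4000,
                                     read_error_rate = 0, coverage = 2))
  res <- map_sequences(idx, reads$reads)
  expect_gt(length(res$records), 0)
  for (qn in names(res$chains)) {
    for (ch in res$chains[[qn]]) {
      a <- ch$anchors
      expect_true(all(diff(a$y) > 0))
      for (s in unique(a$segment))
        expect_true(all(diff(a$x[a$segment == s]) > 0))
      # consecutive distinct segments are adjacent in the path
      expect_true(all(a$segment %in% ch$path$name))
    }
  }
  # GAF invariants hold on every record
  for (r in res$records) expect_true(pangraphr:::validate_gaf_record(r))
})

test_that("on a single linear backbone graph chaining degenerates to linear", {
  set.seed(43)
  seqv <- random_dna_str(5000)
  g <- pangraph(data.frame(name = "s1", sequence = seqv,
                           stable_name = "chr1", stable_offset = 0,
                           rank = 0))
  idx <- build_index(g, k = 15, window = 5)
  q <- substr(seqv, 1001, 3000)
  a <- collect_anchors(idx, q)
  p <- chain_params()
  lcs <- chain_anchors(a, p)
  gcs <- chain_graph(lcs, g, p)
  expect_equal(length(gcs), length(lcs))
  expect_equal(gcs[[1]]$score, lcs[[1]]$score)
  expect_equal(nrow(gcs[[1]]$path), 1)
  expect_equal(gcs[[1]]$query_start, lcs[[1]]$query_start)
})
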