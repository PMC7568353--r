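mk_gc <- function(qs, qe, score = 1000, primary = TRUE) {
  structure(list(anchors = data.frame(), path = NULL, score = score,
                 strand = "+", query_start = qs, query_end = qe,
                 path_start = qs, path_end = qe, path_length = qe,
                 matches = qe - qs, primary = primary),
            class = "graph_chain")
}

test_that("orthogonal regions follow the stated set algebra", {
  one <- list(mk_gc(0, 150000))
  r <- orthogonal_regions(one)
  expect_equal(r$start, 0); expect_equal(r$end, 150000)
  # a 30 kb chain cuts its overlap out of a 150 kb chain
  two <- list(mk_gc(0, 150000), mk_gc(100000, 130000))
  r2 <- orthogonal_regions(two)
  host <- r2[r2$chain == 1, ]
  expect_true(all(host$end <= 100000 | host$start >= 130000))
  # chains at or below 20 kb do not block
  three <- list(mk_gc(0, 150000), mk_gc(50000, 69000))
  r3 <- orthogonal_regions(three)
  expect_equal(sum(r3$end - r3$start), 150000)
})

test_that("orthogonal regions agree with a per-base oracle", {
  set.seed(50)
  for (rep in 1:20) {
    n <- sample(2:5, 1)
    chains <- lapply(seq_len(n), function(i) {
      s <- sample(0:400, 1) * 1000
      mk_gc(s, s + sample(c(10, 30, 90, 120, 200), 1) * 1000)
    })
    got <- orthogonal_regions(chains)
    L <- 800000
    mask <- rep(FALSE, L)
    for (i in seq_len(n)) {
      ci <- chains[[i]]
      if (ci$query_end - ci$query_start <= 1e5) next
      cover <- rep(FALSE, L)
      cover[(ci$query_start + 1):ci$query_end] <- TRUE
      for (j in seq_len(n)) {
        cj <- chains[[j]]
        if (j == i || cj$query_end - cj$query_start <= 2e4) next
        lo <- max(ci$query_start, cj$query_start) + 1
        hi <- min(ci$query_end, cj$query_end)
        if (lo <= hi) cover[lo:hi] <- FALSE
      }
      mask <- mask | cover
    }
    gotmask <- rep(FALSE, L)
    for (r in seq_len(nrow(got)))
      if (got$end[r] > got$start[r])
        gotmask[(got$start[r] + 1):min(got$end[r], L)] <- TRUE
    expect_equal(sum(gotmask), sum(mask))
    expect_true(all(gotmask == mask))
  }
})

test_that("the divergence score has the colinear and divergent branches", {
  expect_equal(gap_scores(10, 10, 19, 0.05), -10)
  expect_equal(gap_scores(500, 200, 19, 0.05), 25)
  expect_equal(gap_scores(0, 0, 19, 0.05), -10)
  expect_equal(gap_scores(30, 30, 19, 0.05), 0.05 * 30)  # equal but > w
  expect_equal(gap_scores(c(10, 500), c(10, 200), c(19, 19), 0.05),
               c(-10, 25))
})

test_that("ruzzo_tompa enumerates exactly the maximal scoring intervals", {
  expect_equal(nrow(ruzzo_tompa(c(-1, -3, -0.5))), 0)
  expect_equal(ruzzo_tompa(5),
               data.frame(start = 1L, end = 1L, score = 5))
  got <- ruzzo_tompa(c(4, -5, 3, -3, 1, 2, -2, 2, -2, 1, 5))
  got <- got[order(got$start), ]; rownames(got) <- NULL
  expect_equal(got$start, c(1L, 3L, 5L))
  expect_equal(got$end, c(1L, 3L, 11L))
  expect_equal(got$score, c(4, 3, 7))
})

test_that("ruzzo_tompa agrees with recursive max-subsequence splitting", {
  exhaustive_rt <- function(s) {
    f <- function(lo, hi) {
      if (lo > hi) return(NULL)
      bestsc <- -Inf; bi <- NA; bj <- NA
      for (i in lo:hi) for (j in i:hi) {
        sc <- sum(s[i:j])
        if (sc > bestsc + 1e-12) { bestsc <- sc; bi <- i; bj <- j }
      }
      if (bestsc <= 0) return(NULL)
      rbind(f(lo, bi - 1), data.frame(start = bi, end = bj, score = bestsc),
            f(bj + 1, hi))
    }
    f(1, length(s))
  }
  set.seed(51)
  for (rep in 1:100) {
    s <- rnorm(sample(1:50, 1), 0, 3)
    got <- ruzzo_tompa(s); got <- got[order(got$start), ]
    expd <- exhaustive_rt(s)
    if (is.null(expd))
      expd <- data.frame(start = integer(), end = integer(),
                         score = numeric())
    rownames(got) <- rownames(expd) <- NULL
    expect_equal(got$start, expd$start)
    expect_equal(got$end, expd$end)
    expect_equal(got$score, expd$score, tolerance = 1e-9)
  }
})

test_that("identical sequences are rejected by verification", {
  s <- random_dna_str(400)
  v <- verify_divergent_region(s, s)
  expect_false(v$retain)
  expect_equal(v$min_identity, 1)
})

test_that("a 150 bp insertion triggers the indel branch with its position", {
  set.seed(52)
  g <- random_dna_str(600)
  ins <- random_dna_str(150)
  q <- paste0(substr(g, 1, 300), ins, substr(g, 301, 600))
  v <- verify_divergent_region(q, g)
  expect_true(v$retain)
  expect_equal(v$reason, "indel")
  expect_equal(v$indel_len, 150)
  expect_equal(v$event$q_end - v$event$q_start, 150)
  expect_equal(v$event$g_end, v$event$g_start)
  expect_lt(abs(v$event$q_start - 300), 25)   # leftmost placement near truth
  # and the mirrored deletion
  vd <- verify_divergent_region(g, q)
  expect_true(vd$retain)
  expect_equal(vd$event$g_end - vd$event$g_start, 150)
})

test_that("a low-identity window triggers the identity branch", {
  set.seed(53)
  g <- random_dna_str(500)
  v <- strsplit(g, "")[[1]]
  idx <- 201:320
  flip <- idx[runif(length(idx)) < 0.35]
  alts <- c(A = "C", C = "G", G = "T", T = "A")
  v[flip] <- alts[v[flip]]
  q <- paste(v, collapse = "")
  ver <- verify_divergent_region(q, g)
  expect_true(ver$retain)
  expect_equal(ver$reason, "identity")
  # window recount oracle on the (gap-free) alignment
  m <- strsplit(q, "")[[1]] == strsplit(g, "")[[1]]
  wid <- sapply(1:(500 - 99), function(i) mean(m[i:(i + 99)]))
  expect_equal(ver$min_identity, min(wid), tolerance = 1e-9)
})

test_that("the SV filter enforces length and alignment bounds", {
  expect_false(sv_filter(99, 2e5))
  expect_true(sv_filter(150, 1.5e5))
  expect_false(sv_filter(150, 5e4))
  expect_false(sv_filter(2e5, 3e5))
  expect_true(sv_filter(100, 1e5))
  expect_true(sv_filter(1e5, 1e5))
})

test_that("augmenting one insertion yields the constructive counts", {
  seqv <- random_dna_str(2000)
  g <- pangraph(data.frame(name = "s1", sequence = seqv,
                           stable_name = "chr1", stable_offset = 0,
                           rank = 0))
  ins <- random_dna_str(200)
  ev <- data.frame(stable_name = "chr1", ref_start = 900, ref_end = 900,
                   query_start = 900, query_end = 1100, seq = ins,
                   stringsAsFactors = FALSE)
  g2 <- augment_graph(g, "asm1", ev, rank = 1)
  expect_equal(attr(g2, "n_applied"), 1)
  expect_equal(sum(g2$segments$rank == 0), 2)   # one split
  expect_equal(sum(g2$segments$rank == 1), 1)
  expect_equal(nrow(g2$links), 3)
  new <- g2$segments[g2$segments$rank == 1, ]
  expect_equal(new$sequence, ins)
  expect_equal(new$stable_name, "asm1")
  expect_equal(new$stable_offset, 900)
  # a replacement event with two breakpoints: 3 backbone pieces, 4 links
  ev2 <- data.frame(stable_name = "chr1", ref_start = 400, ref_end = 600,
                    query_start = 400, query_end = 650,
                    seq = random_dna_str(250), stringsAsFactors = FALSE)
  g3 <- augment_graph(g, "asm1", ev2, rank = 1)
  expect_equal(sum(g3$segments$rank == 0), 3)
  expect_equal(nrow(g3$links), 4)
})

test_that("a pure deletion adds one link and no segments", {
  seqv <- random_dna_str(2000)
  g <- pangraph(data.frame(name = "s1", sequence = seqv,
                           stable_name = "chr1", stable_offset = 0,
                           rank = 0))
  ev <- data.frame(stable_name = "chr1", ref_start = 500, ref_end = 800,
                   query_start = 500, query_end = 500, seq = "",
                   stringsAsFactors = FALSE)
  g2 <- augment_graph(g, "asm1", ev, rank = 1)
  expect_equal(sum(g2$segments$rank > 0), 0)
  expect_equal(sum(g2$segments$rank == 0), 3)
  expect_equal(nrow(g2$links), 3)   # 2 backbone + 1 deletion
  # stable coordinates of all pre-existing bases unchanged
  for (pos in c(0, 499, 500, 1999)) {
    hit <- find_segment(g2, "chr1", pos)
    expect_equal(stable_of(g2, hit$segment, hit$seg_offset)$offset, pos)
  }
})

test_that("re-mapping an augmented copy reaches a fixed point", {
  set.seed(54)
  cfg <- sim_config(seed = 54, ref_length = 6e4, snp_rate = 0.005,
                    sv_spec = data.frame(type = c("INS", "DEL"),
                                         length = 400, count = 1),
                    min_sv_spacing = 800)
  ref <- simulate_reference(cfg)
  mut <- mutate_assembly(ref, cfg)
  g1 <- build_incremental(ref, list(mut$assembly), min_aln = 4e4)
  n1 <- nrow(g1$segments)
  expect_gt(sum(g1$segments$rank == 1), 0)
  g2 <- build_incremental(ref, list(mut$assembly, mut$assembly),
                          min_aln = 4e4)
  expect_equal(sum(g2$segments$rank == 2), 0)
  expect_equal(nrow(g2$segments), n1)
})

test_that("zero assemblies and identical copies leave the graph linear", {
  ref <- c(chrA = random_dna_str(50000))
  g0 <- build_incremental(ref)
  expect_equal(nrow(g0$segments), 1)
  expect_equal(g0$segments$rank, 0L)
  g1 <- build_incremental(ref, list(c(copy = unname(ref))), min_aln = 4e4)
  expect_equal(nrow(g1$segments), 1)
})
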