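## Seeded synthetic data: random references, SV-mutated haplotypes with
## exact truth records, and error-bearing long reads. Everything the
## mapper and graph builder need, without downloads.

#' Simulation configuration
#'
#' Defaults emulate the evaluation regime the pipeline targets: a megabase
#' reference, 1% SNP divergence between haplotypes, insertions/deletions
#' in the 100 bp - 10 kb range with wide spacing, and 15 kb-scale long
#' reads.
#'
#' @param seed RNG seed.
#' @param ref_length reference length in bp (default 1e6).
#' @param snp_rate per-base substitution rate between haplotypes
#'   (default 0.01).
#' @param sv_spec data.frame(type, length, count) with type in
#'   INS/DEL/VNTR_EXPANSION; default 10 INS + 10 DEL of 100 bp - 10 kb.
#' @param read_length_mean mean read length (default 15000).
#' @param read_error_rate per-base read error rate (default 0.05).
#' @param coverage target read coverage (default 5).
#' @param min_sv_spacing minimum bp between implanted events (default
#'   2 x the maximum SV length).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, ref_length = 1e6, snp_rate = 0.01,
                       sv_spec = data.frame(
                         type = c("INS", "DEL"),
                         length = c(1000, 1000),
                         count = c(10, 10)),
                       read_length_mean = 15000, read_error_rate = 0.05,
                       coverage = 5,
                       min_sv_spacing = 2 * max(c(sv_spec$length, 1))) {
  stopifnot(snp_rate >= 0, snp_rate < 1, read_error_rate >= 0,
            read_error_rate < 1, all(sv_spec$length > 0),
            min_sv_spacing >= 2 * max(c(sv_spec$length, 1)))
  structure(list(seed = seed, ref_length = ref_length, snp_rate = snp_rate,
                 sv_spec = sv_spec, read_length_mean = read_length_mean,
                 read_error_rate = read_error_rate, coverage = coverage,
                 min_sv_spacing = min_sv_spacing),
            class = "sim_config")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a random reference
#'
#' @param config a `sim_config`; the RNG is seeded from it, so output is
#'   bit-identical for identical seeds.
#' @param name contig name (default "chr1").
#' @return named character vector of length 1.
#' @export
simulate_reference <- function(config, name = "chr1") {
  set.seed(config$seed)
  r <- random_dna(config$ref_length)
  names(r) <- name
  r
}

## substitute bases at `rate`, never to the original base
apply_snps <- function(seq, rate) {
  if (rate <= 0) return(seq)
  v <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(v)) < rate)
  if (length(hit)) {
    alts <- matrix(c("C", "G", "T", "A", "G", "T", "A", "C", "T",
                     "A", "C", "G"), nrow = 3)
    colnames(alts) <- c("A", "C", "G", "T")
    pick <- sample.int(3, length(hit), replace = TRUE)
    v[hit] <- alts[cbind(pick, match(v[hit], colnames(alts)))]
  }
  paste(v, collapse = "")
}

#' Mutate a reference into an assembly haplotype with a truth set
#'
#' Implants the configured SVs at positions at least `min_sv_spacing`
#' apart (and away from the ends), then applies SNPs at `snp_rate`.
#' VNTR expansions duplicate a 10-100 bp motif taken from the reference
#' at the site. Truth positions are reference coordinates (0-based),
#' sorted.
#'
#' @param reference named character vector (one contig).
#' @param config a `sim_config`.
#' @param seed_offset added to the config seed so successive assemblies
#'   differ (default 0).
#' @param name contig name for the mutated haplotype; the default keys it
#'   by `seed_offset` so assemblies of one reference stay distinct.
#' @return list(assembly = named character, truth = data.frame(type, pos,
#'   length, seq)).
#' @export
mutate_assembly <- function(reference, config, seed_offset = 0,
                            name = sprintf("%s_hap%d",
                                           names(reference)[1],
                                           seed_offset + 1)) {
  set.seed(config$seed + 1000 + seed_offset)
  ref <- unname(reference[1])
  n <- nchar(ref)
  spec <- config$sv_spec
  events <- NULL
  total <- sum(spec$count)
  if (total > 0) {
    margin <- max(spec$length) + 1000
    span <- n - 2 * margin
    need <- total * config$min_sv_spacing
    if (span < need)
      stop("sv config infeasible: ", total, " events with spacing ",
           config$min_sv_spacing, " do not fit in ", n, " bp")
    ## evenly strided positions with jitter, guaranteeing the spacing
    step <- span / total
    jitter <- stats::runif(total, 0, max(step - config$min_sv_spacing, 1))
    pos <- round(margin + (seq_len(total) - 1) * step + jitter)
    types <- rep(spec$type, spec$count)
    lens <- rep(spec$length, spec$count)
    ord <- sample.int(total)
    types <- types[ord]; lens <- lens[ord]
    events <- data.frame(type = types, pos = pos, length = lens,
                         seq = "", stringsAsFactors = FALSE)
    for (i in seq_len(total)) {
      if (events$type[i] == "INS") {
        events$seq[i] <- random_dna(events$length[i])
      } else if (events$type[i] == "VNTR_EXPANSION") {
        motif_len <- sample(10:100, 1)
        motif <- substr(ref, events$pos[i] + 1, events$pos[i] + motif_len)
        reps <- max(2, ceiling(events$length[i] / motif_len))
        events$seq[i] <- paste(rep(motif, reps), collapse = "")
        events$length[i] <- nchar(events$seq[i])
      }
    }
  }
  ## apply right-to-left so earlier positions stay valid
  out <- ref
  if (!is.null(events)) {
    ord <- order(-events$pos)
    for (i in ord) {
      p <- events$pos[i]
      if (events$type[i] == "DEL") {
        out <- paste0(substr(out, 1, p),
                      substr(out, p + events$length[i] + 1, nchar(out)))
      } else {
        out <- paste0(substr(out, 1, p), events$seq[i],
                      substr(out, p + 1, nchar(out)))
      }
    }
    events <- events[order(events$pos), , drop = FALSE]
    rownames(events) <- NULL
  } else {
    events <- data.frame(type = character(), pos = numeric(),
                         length = numeric(), seq = character(),
                         stringsAsFactors = FALSE)
  }
  out <- apply_snps(out, config$snp_rate)
  names(out) <- name
  list(assembly = out, truth = events)
}

#' Simulate long reads with recorded origins
#'
#' Read lengths are exponential around the configured mean (clamped to
#' [500, sequence length]); origins are uniform; half the reads are
#' reverse-complemented; substitution and short-indel errors are applied
#' at the configured rate (4:3:3 sub:ins:del).
#'
#' @param sequence DNA string (or named character of length 1).
#' @param config a `sim_config`.
#' @return list(reads = named character, truth = data.frame(read, start,
#'   end, strand), qualities = character).
#' @export
simulate_reads <- function(sequence, config) {
  set.seed(config$seed + 2000)
  seq <- unname(sequence[1])
  n <- nchar(seq)
  n_reads <- max(1, round(config$coverage * n / config$read_length_mean))
  lens <- pmin(n, pmax(500, round(stats::rexp(n_reads,
                                              1 / config$read_length_mean))))
  starts <- floor(stats::runif(n_reads, 0, n - lens + 1))
  strands <- sample(c("+", "-"), n_reads, replace = TRUE)
  reads <- character(n_reads)
  for (i in seq_len(n_reads)) {
    r <- substr(seq, starts[i] + 1, starts[i] + lens[i])
    if (strands[i] == "-") r <- revcomp(r)
    if (config$read_error_rate > 0) r <- apply_read_errors(r, config)
    reads[i] <- r
  }
  names(reads) <- sprintf("read%04d", seq_len(n_reads))
  truth <- data.frame(read = names(reads), start = starts,
                      end = starts + lens, strand = strands,
                      stringsAsFactors = FALSE)
  list(reads = reads, truth = truth)
}

apply_read_errors <- function(read, config) {
  v <- strsplit(read, "")[[1]]
  err <- which(stats::runif(length(v)) < config$read_error_rate)
  if (!length(err)) return(read)
  kind <- sample(c("sub", "ins", "del"), length(err), replace = TRUE,
                 prob = c(0.4, 0.3, 0.3))
  for (k in seq_along(err)) {
    i <- err[k]
    v[i] <- switch(kind[k],
      sub = sample(setdiff(c("A", "C", "G", "T"), v[i]), 1),
      ins = paste0(v[i], sample(c("A", "C", "G", "T"), 1)),
      del = "")
  }
  paste(v, collapse = "")
}

#' Write sequences as FASTA / reads as FASTQ
#' @param seqs named character vector.
#' @param path output file.
#' @return invisibly the path.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
write_fastq <- function(seqs, path) {
  ## records written directly: FASTQ is unwrapped four-line records, and
  ## long-read lengths exceed the width limit of the XStringSet writer
  qual <- vapply(nchar(seqs), function(n)
    paste(rep("I", n), collapse = ""), character(1))
  lines <- as.vector(rbind(paste0("@", names(seqs)), unname(seqs),
                           "+", qual))
  writeLines(lines, path)
  invisible(path)
}

#' Write a truth set as BED (+ JSON sidecar)
#' @param truth data.frame(type, pos, length, seq).
#' @param path BED path; a `.json` sidecar is written when jsonlite is
#'   available.
#' @param stable_name reference contig name for the BED column.
#' @return invisibly the path.
#' @export
write_truth <- function(truth, path, stable_name = "chr1") {
  ends <- truth$pos + ifelse(truth$type == "DEL", truth$length, 0)
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d", stable_name,
                     as.integer(truth$pos), as.integer(ends),
                     truth$type, as.integer(truth$length)), path)
  if (requireNamespace("jsonlite", quietly = TRUE))
    jsonlite::write_json(truth, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
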