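# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# A moderately sized synthetic bundle shared across module tests.
small_bundle <- function() {
  if (is.null(.fixtures$small)) {
    spec <- simulation_spec(genome_length = 60000L, n_genes = 50L,
                            library_size_ap = 150000L,
                            library_size_gp = 150000L,
                            n_srnas = 4L, seed = 7L)
    .fixtures$small <- simulate_bundle(spec)
  }
  .fixtures$small
}

# Full-default-conditions bundle used by the synthetic property suite.
default_bundle <- function() {
  if (is.null(.fixtures$default)) {
    .fixtures$default <- simulate_bundle(simulation_spec(seed = 424242L))
  }
  .fixtures$default
}

rand_dna <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# A 50-base promoter, optionally carrying TTAAG-N16-CCGATA with the -10 box
# ending 7 nt before the TSS (the geometry the generator plants).
synthetic_promoter <- function(with_motif = TRUE, background = NULL) {
  p <- strsplit(background %||% rand_dna(50), "")[[1]]
  if (with_motif) {
    p[18:22] <- strsplit("TTAAG", "")[[1]]
    p[39:44] <- strsplit("CCGATA", "")[[1]]
  }
  paste(p, collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Build a GRanges of genes from begin/end/strand vectors; seqlengths are set
# only when a genome length is given (mixing lengths across objects breaks
# overlap counting).
gene_ranges <- function(start, end, strand, ids = NULL,
                        genome_length = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = rep("bdsyn1", length(start)),
    ranges = IRanges::IRanges(start, end), strand = strand,
    gene_id = ids %||% sprintf("g%02d", seq_along(start)))
  if (!is.null(genome_length))
    GenomeInfoDb::seqlengths(gr) <- c(bdsyn1 = as.integer(genome_length))
  gr
}

read_ranges <- function(start, width = 36L, strand = "+",
                        genome_length = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = rep("bdsyn1", length(start)),
    ranges = IRanges::IRanges(start, width = width),
    strand = rep(strand, length.out = length(start)))
  if (!is.null(genome_length))
    GenomeInfoDb::seqlengths(gr) <- c(bdsyn1 = as.integer(genome_length))
  gr
}

track_of <- function(pos, strand, count, treatment, total = NULL) {
  five_prime_track(data.frame(pos = pos, strand = strand, count = count),
                   treatment = treatment, total = total)
}

# Independent exhaustive-placement scan oracle: scores every (offset, spacer)
# pair via substring extraction, unrelated to the package's matrix-indexed
# scorer. Distinct placements can score exactly equal (shared PWM column
# values), so the oracle reports the full set of maximal placements.
oracle_best_placement <- function(promoter, motif, tol = 1e-9) {
  w35 <- ncol(motif$pwm35); w10 <- ncol(motif$pwm10)
  rows <- list()
  for (s in motif$spacer_min:motif$spacer_max) {
    for (o in 0:(nchar(promoter) - w35 - s - w10)) {
      b35 <- substr(promoter, o + 1, o + w35)
      b10 <- substr(promoter, o + w35 + s + 1, o + w35 + s + w10)
      sc <- log2(motif$spacer_weights[[as.character(s)]])
      for (j in seq_len(w35)) {
        ch <- substr(b35, j, j)
        sc <- sc + log2(motif$pwm35[ch, j] / motif$background[[ch]])
      }
      for (j in seq_len(w10)) {
        ch <- substr(b10, j, j)
        sc <- sc + log2(motif$pwm10[ch, j] / motif$background[[ch]])
      }
      rows[[length(rows) + 1L]] <- data.frame(offset_35 = o, spacer = s,
                                              score = unname(sc))
    }
  }
  all <- do.call(rbind, rows)
  top <- max(all$score)
  list(score = top,
       placements = all[all$score >= top - tol, c("offset_35", "spacer")])
}

# +-tol matching of called vs true TSS positions.
tss_match <- function(pos, strand, true_pos, true_strand, tol = 2) {
  vapply(seq_along(pos), function(i)
    any(true_strand == strand[i] & abs(true_pos - pos[i]) <= tol),
    logical(1))
}
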