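test_that("TSS calling enforces support, enrichment and upstream criteria", {
  # equal depths; positions 100..400 carry assorted signals
  tp <- track_of(c(100L, 200L, 300L, 400L), "+", c(10L, 4L, 9L, 50L),
                 "TAP_plus", total = 1000L)
  tm <- track_of(c(100L, 300L, 400L), "+", c(2L, 8L, 2L), "TAP_minus",
                 total = 1000L)
  calls <- call_tss(tp, tm, NULL)
  # 100: enr = 10/3 >= 3 called; 200: support 4 < 5 rejected;
  # 300: enr = 1 rejected (processed site); 400: called
  expect_equal(calls$position, c(100L, 400L))
  expect_equal(calls$enrichment[1], (10 / 1000) / (3 / 1000))
  # the upstream-of-a-gene criterion
  genes <- gene_ranges(c(450L, 2000L), c(1400L, 2900L), c("+", "-"))
  with_ann <- call_tss(tp, tm, genes)
  # 100 is 350 nt upstream of g01 (beyond 300) and drops out; 400 is kept
  expect_equal(with_ann$position, 400L)
  expect_equal(with_ann$assigned_genes, "g01")
  expect_equal(with_ann$distance_to_start, 50L)
  far <- call_tss(track_of(1600L, "+", 50L, "TAP_plus", total = 1000L),
                  tm, genes)
  expect_equal(nrow(far), 0L)  # wrong strand side for g02, too far from g01
  expect_error(call_tss(tp, track_of(integer(), character(), integer(),
                                     "TAP_minus"), NULL),
               "total is 0")
})

test_that("minus-strand gene starts anchor the upstream window", {
  genes <- gene_ranges(2000L, 2900L, "-")
  tp <- track_of(c(2950L, 1990L), "-", c(30L, 30L), "TAP_plus",
                 total = 1000L)
  tm <- track_of(2950L, "-", 1L, "TAP_minus", total = 1000L)
  calls <- call_tss(tp, tm, genes)
  # 2950 is 50 nt 5' of the minus-strand start (the right edge);
  # 1990 is downstream (3') and beyond the first 3 codons
  expect_equal(calls$position, 2950L)
  expect_equal(calls$distance_to_start, 50L)
})

test_that("deduplication keeps the strongest call per window with 5'-ward ties", {
  base <- data.frame(strand = "+", raw_plus = 0L, raw_minus = 0L,
                     enrichment = 10, assigned_genes = "g",
                     distance_to_start = 30L)
  calls <- do.call(rbind, list(
    transform(base, position = 100L, raw_plus = 50L),
    transform(base, position = 103L, raw_plus = 8L),
    transform(base, position = 120L, raw_plus = 8L)))
  dd <- deduplicate_tss(calls, window = 5L)
  expect_equal(dd$position, c(100L, 120L))
  ties <- rbind(transform(base, position = 100L, raw_plus = 9L),
                transform(base, position = 102L, raw_plus = 9L))
  expect_equal(deduplicate_tss(ties, 5L)$position, 100L)
  ties_minus <- transform(ties, strand = "-")
  expect_equal(deduplicate_tss(ties_minus, 5L)$position, 102L)
  # chained windows collapse to one survivor
  chain <- do.call(rbind, lapply(seq(100L, 120L, 4L), function(p)
    transform(base, position = p, raw_plus = as.integer(p))))
  expect_equal(deduplicate_tss(chain, 5L)$position, 120L)
})

test_that("operon extension follows gap, orientation and own-TSS rules", {
  L <- 3000L
  cov_on <- rep(100L, L)
  cov_off <- integer(L)
  call_at <- function(pos, strand = "+", genes = "g01")
    data.frame(position = pos, strand = strand, raw_plus = 50L,
               raw_minus = 0L, enrichment = 10, assigned_genes = genes,
               distance_to_start = 30L)
  # gap 20 <= max_gap: both genes joined even without coverage
  g2 <- gene_ranges(c(200L, 721L), c(700L, 1200L), c("+", "+"),
                    genome_length = L)
  ops <- assign_operons(call_at(170L), g2, cov_off)
  expect_equal(ops$assigned_genes, "g01,g02")
  # opposite strand: never joined
  g_opp <- gene_ranges(c(200L, 721L), c(700L, 1200L), c("+", "-"),
                       genome_length = L)
  expect_equal(assign_operons(call_at(170L), g_opp, cov_on)$assigned_genes,
               "g01")
  # second gene with its own TSS call breaks the operon
  calls2 <- rbind(call_at(170L), call_at(690L, genes = "g02"))
  ops2 <- assign_operons(calls2, g2, cov_off)
  expect_equal(ops2$assigned_genes[1], "g01")
  # a wide gap is bridged only by read-through coverage
  g_far <- gene_ranges(c(200L, 901L), c(700L, 1400L), c("+", "+"),
                       genome_length = L)
  expect_equal(assign_operons(call_at(170L), g_far, cov_off)$assigned_genes,
               "g01")
  expect_equal(assign_operons(call_at(170L), g_far, cov_on)$assigned_genes,
               "g01,g02")
})

test_that("promoter extraction is exact, strand-symmetric and round-trips", {
  seqchr <- rand_dna(2000)
  genome <- Biostrings::DNAStringSet(c(bdsyn1 = seqchr))
  calls <- data.frame(position = c(1000L, 1000L), strand = c("+", "-"))
  proms <- extract_promoters(calls, genome)
  expect_equal(unname(proms["1000+"]), substr(seqchr, 950, 999))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(seqchr, 1001, 1050))))
  expect_equal(unname(proms["1000-"]), rc)
  expect_true(all(nchar(proms) == 50))
  # re-extraction yields the identical string (round trip)
  expect_identical(extract_promoters(calls, genome), proms)
  # calls at the contig edge are skipped with a warning
  expect_warning(out <- extract_promoters(
    data.frame(position = c(10L, 1990L), strand = c("+", "-")), genome),
    "skipped")
  expect_length(out, 0L)
})

test_that("planted TSSs are recovered with high sensitivity and precision", {
  b <- small_bundle()
  calls <- deduplicate_tss(call_tss(b$tracks$tap_plus, b$tracks$tap_minus,
                                    b$annotation))
  truth <- subset(b$truth$true_tss, kind == "gene")
  sens <- mean(tss_match(truth$position, truth$strand,
                         calls$position, calls$strand))
  prec <- mean(tss_match(calls$position, calls$strand,
                         truth$position, truth$strand))
  expect_gte(sens, 0.95)
  expect_gte(prec, 0.95)
  # every emitted call re-checks against the raw tracks
  tp <- b$tracks$tap_plus; tm <- b$tracks$tap_minus
  for (i in seq_len(nrow(calls))) {
    raw_p <- tp$counts$count[tp$counts$pos == calls$position[i] &
                               tp$counts$strand == calls$strand[i]]
    expect_gte(raw_p, 5L)
    expect_gte(calls$enrichment[i], 3)
    expect_true(calls$distance_to_start[i] <= 300 &&
                  calls$distance_to_start[i] >= -9)
  }
})

test_that("five-prime tracks round-trip through strand-split bedGraph files", {
  b <- small_bundle()
  d <- withr::local_tempdir()
  trk <- b$tracks$tap_plus
  bdellotx:::write_track_bedgraph(trk, "+", file.path(d, "fwd.bedGraph"),
                                  b$spec$genome_length)
  bdellotx:::write_track_bedgraph(trk, "-", file.path(d, "rev.bedGraph"),
                                  b$spec$genome_length)
  back <- read_five_prime_track(file.path(d, "fwd.bedGraph"),
                                file.path(d, "rev.bedGraph"), "TAP_plus")
  a <- trk$counts[order(trk$counts$strand, trk$counts$pos), ]
  bdf <- back$counts[order(back$counts$strand, back$counts$pos), ]
  rownames(a) <- rownames(bdf) <- NULL
  expect_equal(bdf, a)
  expect_equal(back$total, trk$total)
})
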