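test_that("intergenic regions are the complement of the gene union", {
  genes <- gene_ranges(c(100L, 300L), c(200L, 400L), c("+", "+"),
                       genome_length = 500L)
  ig <- intergenic_regions(genes, 500L, min_len = 1L)
  expect_equal(GenomicRanges::start(ig), c(1L, 201L, 401L))
  expect_equal(GenomicRanges::end(ig), c(99L, 299L, 500L))
  adjacent <- gene_ranges(c(100L, 201L), c(200L, 300L), c("+", "-"),
                          genome_length = 500L)
  ig2 <- intergenic_regions(adjacent, 500L, min_len = 1L)
  expect_equal(GenomicRanges::start(ig2), c(1L, 301L))
  none <- intergenic_regions(GenomicRanges::GRanges(), 500L)
  expect_equal(GenomicRanges::start(none), 1L)
  expect_equal(GenomicRanges::end(none), 500L)
  # the min_len floor drops slivers
  expect_equal(length(intergenic_regions(genes, 500L, min_len = 100L)), 1L)
})

test_that("region screening keeps significant >4-fold AP-biased regions only", {
  L <- 2000L
  regions <- GenomicRanges::GRanges("bdsyn1",
    IRanges::IRanges(c(1L, 501L, 1001L), c(400L, 900L, 1400L)))
  # region 1: strong AP bias; region 2: mild (~3x); region 3: empty
  ap <- read_ranges(c(sample(1:365, 800, TRUE), sample(501:865, 150, TRUE)),
                    genome_length = L)
  gp <- read_ranges(c(sample(1:365, 50, TRUE), sample(501:865, 50, TRUE)),
                    genome_length = L)
  out <- screen_regions(regions, ap, gp, total_ap = 1e5, total_gp = 1e5)
  expect_equal(attr(out, "n_regions"), 3L)
  expect_equal(nrow(out), 1L)
  expect_equal(out$start, 1L)
  expect_gt(out$fold, 4)
  expect_lte(out$p_adj, 0.05)
})

test_that("fold changes use the one-read RPKM floor for empty denominators", {
  expect_equal(fold_increase(100, 50), 2)
  eps <- eps_rpkm(200, 1e6)
  expect_equal(fold_increase(100, 0, eps), 100 / eps)
  expect_true(is.finite(fold_increase(100, 0, eps)))
  # published worked example: 50451/3181 rounds to 16-fold
  expect_equal(round(fold_increase(50451, 3181)), 16)
})

test_that("5'UTR read-through exclusion follows coverage and strand rules", {
  L <- 1000L
  genes <- gene_ranges(501L, 800L, "+", ids = "gA", genome_length = L)
  cand <- data.frame(start = 301L, end = 500L, length = 200L)
  cov_connected <- integer(L); cov_connected[301:800] <- c(rep(100L, 200),
                                                           rep(80L, 300))
  cov_gap <- cov_connected; cov_gap[480:500] <- 0L
  # continuous coverage at 80% of candidate mean into an expressed gene
  expect_equal(nrow(exclude_utr_readthrough(cand, cov_connected, genes,
                                            expressed_ap = "gA")), 0L)
  # a coverage gap breaks the connection
  expect_equal(nrow(exclude_utr_readthrough(cand, cov_gap, genes,
                                            expressed_ap = "gA")), 1L)
  # unexpressed downstream gene: retained
  expect_equal(nrow(exclude_utr_readthrough(cand, cov_connected, genes,
                                            expressed_ap = character())), 1L)
  # downstream gene on the opposite strand: retained regardless of coverage
  genes_minus <- gene_ranges(501L, 800L, "-", ids = "gA", genome_length = L)
  expect_equal(nrow(exclude_utr_readthrough(cand, cov_connected, genes_minus,
                                            expressed_ap = "gA")), 1L)
})

test_that("boundary refinement anchors on the TSS and maps an abrupt cliff exactly", {
  L <- 2000L
  cov <- integer(L); cov[501:944] <- 200L   # abrupt cliff at 944
  tss <- data.frame(position = 501L, strand = "+", raw_plus = 100L,
                    raw_minus = 0L, enrichment = 10,
                    assigned_genes = "", distance_to_start = NA)
  cand <- data.frame(start = 450L, end = 1100L)
  ap <- read_ranges(sample(501:909, 300, TRUE), genome_length = L)
  gp <- read_ranges(1500L, genome_length = L)
  r <- refine_boundaries(cand, tss, cov, ap, gp, n_tests = 1L)
  expect_equal(r$start, 501L)
  expect_equal(r$end, 944L)
  expect_equal(r$size, 444L)
  expect_equal(r$strand, "+")
  # no qualifying TSS: dropped with a logged reason
  expect_message(
    out <- refine_boundaries(data.frame(start = 1500L, end = 1600L),
                             tss, cov, ap, gp),
    "no qualifying TSS")
  expect_null(out)
})

test_that("minus-strand refinement scans leftwards from the TSS", {
  L <- 2000L
  cov <- integer(L); cov[500:944] <- 150L
  tss <- data.frame(position = 944L, strand = "-", raw_plus = 80L,
                    raw_minus = 0L, enrichment = 8,
                    assigned_genes = "", distance_to_start = NA)
  cand <- data.frame(start = 400L, end = 1000L)
  ap <- read_ranges(sample(500:909, 200, TRUE), genome_length = L)
  gp <- read_ranges(1500L, genome_length = L)
  r <- refine_boundaries(cand, tss, cov, ap, gp)
  expect_equal(r$strand, "-")
  expect_equal(r$end, 944L)
  expect_equal(r$start, 500L)
})

test_that("the closed-ORF filter flags long ORFs and only long closed ORFs", {
  no_orf <- gsub("ATG", "ACG", rand_dna(150))
  expect_false(bdellotx:::has_long_orf(no_orf, 50L))
  orf60 <- paste0("ATG", strrep("GCT", 59), "TAA")
  expect_true(bdellotx:::has_long_orf(paste0(rand_dna(30), orf60,
                                             rand_dna(30)), 50L))
  # ATG with no in-frame stop is not a closed ORF
  open_frame <- paste0("ATG", strrep("GCT", 80))
  expect_false(bdellotx:::has_long_orf(open_frame, 50L))
  # minus-strand candidates are filtered on their sense sequence
  genome <- Biostrings::DNAStringSet(c(bdsyn1 = paste0(
    rand_dna(20),
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(orf60))),
    rand_dna(20))))
  expect_true(orf_filter(21L, 20L + nchar(orf60), "-", genome, 50L))
  expect_false(orf_filter(21L, 20L + nchar(orf60), "+", genome, 50L))
  # the codon threshold is respected
  expect_false(bdellotx:::has_long_orf(orf60, 61L))
})

test_that("promoter annotation requires a TSS and detects the planted element", {
  b <- small_bundle()
  proms <- c(replicate(66, synthetic_promoter(TRUE)),
             replicate(34, synthetic_promoter(FALSE)))
  set.seed(20)
  m <- discover_motif(proms)
  sr_motif <- b$truth$true_srnas[b$truth$true_srnas$has_motif, ][1, ]
  cand <- data.frame(start = sr_motif$start, end = sr_motif$end,
                     strand = sr_motif$strand)
  expect_true(annotate_promoter(cand, m, b$genome))
  expect_error(annotate_promoter(transform(cand, has_tss = FALSE), m,
                                 b$genome), "TSS")
})

test_that("planted sRNAs are recovered with tight boundaries and honest stats", {
  b <- small_bundle()
  free <- deduplicate_tss(call_tss(b$tracks$tap_plus, b$tracks$tap_minus,
                                   NULL))
  sr <- discover_srnas(b$annotation, b$genome, b$alignments$ap,
                       b$alignments$gp, free)
  truth <- b$truth$true_srnas
  emitted <- sr[!sr$orf_filtered, ]
  # every planted sRNA matched within 10 nt on both boundaries
  for (i in seq_len(nrow(truth))) {
    hit <- emitted[emitted$strand == truth$strand[i] &
                     abs(emitted$start - truth$start[i]) <= 10 &
                     abs(emitted$end - truth$end[i]) <= 10, ]
    expect_equal(nrow(hit), 1L, info = truth$srna_id[i])
  }
  # emitted candidates lie in intergenic space and re-screen reproducibly
  genes <- b$truth$genes
  tot_ap <- length(b$alignments$ap); tot_gp <- length(b$alignments$gp)
  for (i in seq_len(nrow(emitted))) {
    expect_false(any(emitted$start[i] <= genes$end &
                       emitted$end[i] >= genes$start))
    gr <- GenomicRanges::GRanges("bdsyn1",
      IRanges::IRanges(emitted$start[i], emitted$end[i]))
    ca <- GenomicRanges::countOverlaps(gr, b$alignments$ap,
                                       ignore.strand = TRUE)
    cg <- GenomicRanges::countOverlaps(gr, b$alignments$gp,
                                       ignore.strand = TRUE)
    ra <- rpkm(ca, emitted$size[i], tot_ap)
    rg <- rpkm(cg, emitted$size[i], tot_gp)
    expect_gt(fold_increase(ra, rg, eps_rpkm(emitted$size[i], tot_gp)), 4)
    expect_lte(chi2_differential(ra, rg, 1L)$p_adj, 0.05)
    expect_equal(emitted$size[i],
                 interval_size(emitted$start[i], emitted$end[i]))
  }
})

test_that("null simulations with no planted sRNAs emit no candidates", {
  spec <- simulation_spec(genome_length = 50000L, n_genes = 40L,
                          n_srnas = 0L, library_size_ap = 80000L,
                          library_size_gp = 80000L, seed = 17L)
  b <- simulate_bundle(spec)
  free <- deduplicate_tss(call_tss(b$tracks$tap_plus, b$tracks$tap_minus,
                                   NULL))
  sr <- discover_srnas(b$annotation, b$genome, b$alignments$ap,
                       b$alignments$gp, free)
  expect_equal(nrow(sr), 0L)
})
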