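test_that("spec validation rejects inconsistent parameters", {
  expect_error(simulation_spec(program_fractions = c(AP_only = 0.5,
                                                     GP_only = 0.6,
                                                     AP_dominant = 0,
                                                     GP_dominant = 0,
                                                     shared = 0, silent = 0)),
               "sum to 1")
  expect_error(simulation_spec(read_length = 900, mean_gene_length = 800),
               "read_length")
  expect_error(simulation_spec(srna_fold_range = c(100, 10)), "increasing")
})

test_that("generation is deterministic at file level and fails on infeasible packing", {
  spec <- simulation_spec(genome_length = 40000L, n_genes = 30L,
                          library_size_ap = 20000L, library_size_gp = 20000L,
                          tap_plus_depth = 20000L, tap_minus_depth = 22000L,
                          n_srnas = 2L, seed = 11L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_synthetic_bundle(simulate_bundle(spec), d1)
  write_synthetic_bundle(simulate_bundle(spec), d2)
  files <- sort(list.files(d1))
  expect_identical(files, sort(list.files(d2)))
  for (f in files)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)

  expect_error(generate_genome(simulation_spec(genome_length = 10000L,
                                               n_genes = 50L)),
               "infeasible packing")
})

test_that("an empty spec yields an empty genome and truth", {
  spec <- simulation_spec(n_genes = 0L, n_srnas = 0L)
  g <- generate_genome(spec)
  expect_length(g$annotation, 0L)
  expect_length(g$truth$gene_programs, 0L)
  expect_equal(Biostrings::width(g$genome), spec$genome_length)
})

test_that("AP genes are GC-richer than GP genes when gc_ap > gc_gp", {
  spec <- simulation_spec(genome_length = 80000L, n_genes = 60L,
                          gc_ap = 0.55, gc_gp = 0.45, n_srnas = 0L,
                          library_size_ap = 1000L, library_size_gp = 1000L,
                          seed = 13L)
  g <- generate_genome(spec)
  gene_gc <- vapply(seq_len(nrow(g$truth$genes)), function(i)
    gc_content(Biostrings::subseq(g$genome[[1]], g$truth$genes$start[i],
                                  g$truth$genes$end[i])), numeric(1))
  prog <- g$truth$genes$program
  ap <- gene_gc[prog %in% c("AP_only", "AP_dominant")]
  gp <- gene_gc[prog %in% c("GP_only", "GP_dominant")]
  expect_gt(mean(ap), mean(gp))
  expect_lt(compare_gc(ap, gp)$p, 0.001)
})

test_that("planted gene and sRNA layout respects the ground-truth invariants", {
  b <- small_bundle()
  genes <- b$truth$genes
  # non-overlapping genes
  o <- order(genes$start)
  expect_true(all(genes$start[o][-1] > genes$end[o][-nrow(genes)]))
  # sRNAs intergenic
  sr <- b$truth$true_srnas
  for (i in seq_len(nrow(sr)))
    expect_false(any(sr$start[i] <= genes$end & sr$end[i] >= genes$start))
  # every non-silent gene reachable from a true TSS
  tss_genes <- unlist(strsplit(subset(b$truth$true_tss,
                                      kind == "gene")$gene_ids, ","))
  expect_setequal(tss_genes, genes$gene_id[genes$program != "silent"])
  # TSS 20-150 bases upstream of its operon's first codon
  tt <- subset(b$truth$true_tss, kind == "gene")
  for (i in seq_len(nrow(tt))) {
    first <- strsplit(tt$gene_ids[i], ",")[[1]][1]
    gi <- genes[genes$gene_id == first, ]
    d <- if (tt$strand[i] == "+") gi$start - tt$position[i]
         else tt$position[i] - gi$end
    expect_true(d >= 20 && d <= 150)
  }
})

test_that("motif-bearing promoters carry TTAAG-N16-CCGATA ending 7 nt before the TSS", {
  b <- small_bundle()
  tt <- b$truth$true_tss[b$truth$true_tss$has_motif, ]
  expect_gt(nrow(tt), 0)
  proms <- extract_promoters(
    data.frame(position = tt$position, strand = tt$strand), b$genome)
  for (p in proms) {
    expect_identical(substr(p, 18, 22), "TTAAG")
    expect_identical(substr(p, 39, 44), "CCGATA")
  }
})

test_that("alignment simulation conserves read mass and respects programs", {
  b <- small_bundle()
  expect_identical(length(b$alignments$ap), b$spec$library_size_ap)
  expect_identical(length(b$alignments$gp), b$spec$library_size_gp)
  L <- b$spec$genome_length
  for (aln in b$alignments) {
    expect_true(all(GenomicRanges::start(aln) >= 1))
    expect_true(all(GenomicRanges::end(aln) <= L))
    expect_true(all(GenomicRanges::width(aln) == b$spec$read_length))
    expect_false(is.unsorted(GenomicRanges::start(aln)))
  }
  # phase-exclusive programs receive zero reads in the other condition
  genes <- b$truth$genes
  ap_only <- gene_ranges(genes$start[genes$program == "AP_only"],
                         genes$end[genes$program == "AP_only"],
                         genes$strand[genes$program == "AP_only"],
                         genome_length = L)
  expect_identical(sum(GenomicRanges::countOverlaps(ap_only,
                                                    b$alignments$gp)), 0L)
  gp_only <- gene_ranges(genes$start[genes$program == "GP_only"],
                         genes$end[genes$program == "GP_only"],
                         genes$strand[genes$program == "GP_only"],
                         genome_length = L)
  expect_identical(sum(GenomicRanges::countOverlaps(gp_only,
                                                    b$alignments$ap)), 0L)
})

test_that("a transcript holding 40% of the AP mass draws a binomial read share", {
  genome <- Biostrings::DNAStringSet(c(bdsyn1 = rand_dna(3000)))
  # one AP_only gene of 1200 nt (weight 1200) and one sRNA of 160 nt at the
  # sRNA level 5 (weight 800): the sRNA holds 800/2000 = 40% of the AP mass
  truth <- list(
    genes = data.frame(gene_id = "g1", start = 101L, end = 1300L,
                       strand = "+", program = "AP_only", operon_id = "op1"),
    true_srnas = data.frame(srna_id = "s1", start = 1501L, end = 1660L,
                            strand = "+", fold = 100, has_motif = FALSE,
                            tss = 1501L))
  spec <- simulation_spec(genome_length = 3000L, n_genes = 1L, n_srnas = 1L,
                          library_size_ap = 200000L, library_size_gp = 1000L,
                          seed = 5L)
  aln <- simulate_alignments(genome, truth, spec)
  srna_reads <- sum(GenomicRanges::countOverlaps(
    read_ranges(1501L, width = 160L, genome_length = 3000L),
    aln$ap, minoverlap = 36L))
  n <- 200000; p <- 0.4
  expect_lt(abs(srna_reads - n * p), 3 * sqrt(n * p * (1 - p)))
})

test_that("5'-end tracks match requested depths and enrich true TSSs", {
  b <- small_bundle()
  tp <- b$tracks$tap_plus; tm <- b$tracks$tap_minus
  expect_lt(abs(tp$total - b$spec$tap_plus_depth) / b$spec$tap_plus_depth,
            0.05)
  expect_lt(abs(tm$total - b$spec$tap_minus_depth) / b$spec$tap_minus_depth,
            0.05)
  # every true TSS passes both caller thresholds (planted recoverability)
  tt <- b$truth$true_tss
  key <- function(df) paste(df$pos, df$strand)
  ip <- match(paste(tt$position, tt$strand), key(tp$counts))
  im <- match(paste(tt$position, tt$strand), key(tm$counts))
  raw_plus <- tp$counts$count[ip]
  raw_minus <- ifelse(is.na(im), 0L, tm$counts$count[im])
  enr <- (raw_plus / tp$total) / ((raw_minus + 1) / tm$total)
  expect_true(all(raw_plus >= 5))
  expect_true(all(enr >= 3))
})

test_that("a zero-depth TAP(-) request yields an empty track", {
  spec <- simulation_spec(genome_length = 40000L, n_genes = 20L,
                          tap_minus_depth = 0L, processed_site_rate = 0,
                          library_size_ap = 1000L, library_size_gp = 1000L,
                          n_srnas = 0L, seed = 3L)
  g <- generate_genome(spec)
  trk <- simulate_five_prime_tracks(g$truth, spec)
  expect_identical(trk$tap_minus$total, 0L)
  expect_identical(nrow(trk$tap_minus$counts), 0L)
})
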