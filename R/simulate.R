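#' Specification for a synthetic predator transcriptome experiment
#'
#' Bundles every tunable of the synthetic-data generator: a toy circular-free
#' genome with phase-programmed gene clusters, whole-transcriptome read sets
#' for the attack phase (AP) and growth phase (GP), and paired TAP(+)/TAP(-)
#' 5'-end count tracks with planted transcription start sites (TSSs).
#'
#' Defaults emulate the study conditions of a dimorphic predatory
#' bacterium sequenced with 36 bp reads: most genes are exclusive to one
#' phase, two thirds of AP promoters carry a two-box sigma-28-like element
#' (TTAAG-N16-CCGATA), and a handful of intergenic sRNAs are massively
#' AP-biased (16- to 5300-fold).
#'
#' @param genome_length Genome size in bases.
#' @param n_genes Number of gene models to place.
#' @param program_fractions Named fractions over the six phase programs
#'   `AP_only, GP_only, AP_dominant, GP_dominant, shared, silent`; must sum
#'   to 1.
#' @param mean_gene_length Mean gene length in bases.
#' @param read_length Read length in bases (default 36).
#' @param library_size_ap,library_size_gp Whole-transcriptome read counts per
#'   condition.
#' @param tap_plus_depth,tap_minus_depth Total 5'-end read counts for the
#'   TAP(+) and TAP(-) tracks.
#' @param tss_enrichment_factor Ratio of TAP(+) to TAP(-) signal planted at
#'   true TSSs.
#' @param processed_site_rate Density (sites per kb) of processed 5' ends
#'   that appear equally in both TAP libraries.
#' @param motif_fraction Fraction of AP-program promoters carrying the
#'   planted two-box motif (default 0.66).
#' @param n_srnas Number of intergenic sRNAs to plant.
#' @param srna_fold_range Interval of planted AP/GP transcript-level fold
#'   differences for sRNAs (log-uniformly sampled).
#' @param gc_ap,gc_gp Target GC fractions for AP- versus GP-program gene
#'   sequences.
#' @param background_frac Fraction of each library emitted as stray reads
#'   uniform over the genome (default 0).
#' @param seed Integer seed; all generator randomness derives from it.
#' @return An object of class `simulation_spec` (a validated list).
#' @export
simulation_spec <- function(genome_length = 100000L,
                            n_genes = 80L,
                            program_fractions = c(AP_only = 0.10,
                                                  GP_only = 0.43,
                                                  AP_dominant = 0.03,
                                                  GP_dominant = 0.02,
                                                  shared = 0.07,
                                                  silent = 0.35),
                            mean_gene_length = 800L,
                            read_length = 36L,
                            library_size_ap = 500000L,
                            library_size_gp = 500000L,
                            tap_plus_depth = 68000L,
                            tap_minus_depth = 75000L,
                            tss_enrichment_factor = 10,
                            processed_site_rate = 10,
                            motif_fraction = 0.66,
                            n_srnas = 8L,
                            srna_fold_range = c(16, 5300),
                            gc_ap = 0.52,
                            gc_gp = 0.47,
                            background_frac = 0,
                            seed = 1L) {
  spec <- list(genome_length = as.integer(genome_length),
               n_genes = as.integer(n_genes),
               program_fractions = program_fractions,
               mean_gene_length = as.integer(mean_gene_length),
               read_length = as.integer(read_length),
               library_size_ap = as.integer(library_size_ap),
               library_size_gp = as.integer(library_size_gp),
               tap_plus_depth = as.integer(tap_plus_depth),
               tap_minus_depth = as.integer(tap_minus_depth),
               tss_enrichment_factor = tss_enrichment_factor,
               processed_site_rate = processed_site_rate,
               motif_fraction = motif_fraction,
               n_srnas = as.integer(n_srnas),
               srna_fold_range = srna_fold_range,
               gc_ap = gc_ap, gc_gp = gc_gp,
               background_frac = background_frac,
               seed = as.integer(seed))
  class(spec) <- "simulation_spec"
  validate_spec(spec)
  spec
}

PROGRAMS <- c("AP_only", "GP_only", "AP_dominant", "GP_dominant",
              "shared", "silent")

# Relative per-base transcription levels per program and condition. Dominant
# programs are expressed in both phases with a 20-fold transcript-level bias,
# comfortably beyond the 5-fold classification rule after library-composition
# effects.
PROGRAM_LEVELS <- list(
  AP = c(AP_only = 1, GP_only = 0, AP_dominant = 1, GP_dominant = 0.05,
         shared = 1, silent = 0),
  GP = c(AP_only = 0, GP_only = 1, AP_dominant = 0.05, GP_dominant = 1,
         shared = 1, silent = 0)
)
SRNA_AP_LEVEL <- 5  # sRNAs are massively AP-expressed

validate_spec <- function(spec) {
  pf <- spec$program_fractions
  if (!setequal(names(pf), PROGRAMS))
    abort("program_fractions must be named exactly: %s",
          paste(PROGRAMS, collapse = ", "))
  if (abs(sum(pf) - 1) > 1e-9)
    abort("program_fractions must sum to 1 (got %.12f)", sum(pf))
  if (any(pf < 0)) abort("program_fractions must be non-negative")
  if (spec$read_length >= spec$mean_gene_length)
    abort("read_length (%d) must be smaller than mean_gene_length (%d)",
          spec$read_length, spec$mean_gene_length)
  for (f in c("library_size_ap", "library_size_gp",
              "tap_plus_depth", "tap_minus_depth"))
    if (spec[[f]] < 0) abort("%s must be >= 0", f)
  if (spec$tss_enrichment_factor <= 0) abort("tss_enrichment_factor must be > 0")
  if (spec$motif_fraction < 0 || spec$motif_fraction > 1)
    abort("motif_fraction must be in [0, 1]")
  if (length(spec$srna_fold_range) != 2L ||
      spec$srna_fold_range[1] > spec$srna_fold_range[2])
    abort("srna_fold_range must be an increasing length-2 interval")
  invisible(spec)
}

# Largest-remainder allocation of n items to the program fractions.
allocate_programs <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    idx <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[idx] <- base[idx] + 1
  }
  stats::setNames(as.integer(base), names(fractions))
}

SEQNAME <- "bdsyn1"

#' Generate a synthetic genome with phase-programmed genes and planted truth
#'
#' Places non-overlapping gene models in program-homogeneous clusters (runs of
#' 3--10 same-program genes, emulating the mosaic of phase-specific islands),
#' grouped into operons of 1--3 genes. Every expressed operon receives a true
#' TSS 20--150 bases upstream of its first codon; a `motif_fraction` of
#' AP-program promoters carries the two-box element TTAAG-N16-CCGATA with the
#' -10 box ending 7 nt upstream of the TSS. Intergenic sRNAs with their own
#' TSSs are planted between clusters. AP-program gene sequences are drawn at
#' `gc_ap`, GP-program genes at `gc_gp`.
#'
#' @param spec A [simulation_spec()].
#' @return A list with elements `genome` (a [Biostrings::DNAStringSet] of one
#'   sequence), `annotation` (a [GenomicRanges::GRanges] of genes with a
#'   `gene_id` column), and `truth` (ground truth: `genes`, `gene_programs`,
#'   `true_tss`, `true_srnas` data frames).
#' @export
generate_genome <- function(spec) {
  validate_spec(spec)
  set.seed(spec$seed)
  L <- spec$genome_length
  rc <- function(n, gc) random_dna(n, gc)

  empty_truth <- list(
    genes = data.frame(gene_id = character(), start = integer(),
                       end = integer(), strand = character(),
                       program = character(), operon_id = character()),
    gene_programs = stats::setNames(character(), character()),
    true_tss = data.frame(position = integer(), strand = character(),
                          gene_ids = character(), has_motif = logical(),
                          kind = character()),
    true_srnas = data.frame(srna_id = character(), start = integer(),
                            end = integer(), strand = character(),
                            fold = numeric(), has_motif = logical(),
                            tss = integer()))

  if (spec$n_genes == 0L && spec$n_srnas == 0L) {
    genome <- Biostrings::DNAStringSet(stats::setNames(rc(L, 0.5), SEQNAME))
    return(list(genome = genome,
                annotation = GenomicRanges::GRanges(seqnames = character()),
                truth = empty_truth))
  }

  ## --- assign programs and chunk into clusters of 3-10 same-program genes
  counts <- allocate_programs(spec$n_genes, spec$program_fractions)
  clusters <- list()
  for (prog in PROGRAMS) {
    left <- counts[[prog]]
    while (left > 0L) {
      sz <- min(left, sample_one(3:10))
      clusters[[length(clusters) + 1L]] <- list(program = prog, size = sz)
      left <- left - sz
    }
  }
  if (length(clusters) > 1L) clusters <- clusters[sample.int(length(clusters))]

  ## --- interleave sRNA slots between clusters
  elements <- clusters
  if (spec$n_srnas > 0L) {
    table2_sizes <- c(207L, 134L, 128L, 98L, 176L, 445L, 655L, 275L)
    srna_len <- if (spec$n_srnas == length(table2_sizes)) table2_sizes
                else sample(98:655, spec$n_srnas, replace = TRUE)
    n_motif <- round(spec$n_srnas * 3 / 8)
    motif_ids <- sample.int(spec$n_srnas, n_motif)
    lfr <- log(spec$srna_fold_range)
    for (i in seq_len(spec$n_srnas)) {
      elements[[length(elements) + 1L]] <- list(
        program = "srna", size = 1L, srna_len = srna_len[i],
        fold = exp(stats::runif(1, lfr[1], lfr[2])),
        has_motif = i %in% motif_ids)
    }
    elements <- elements[sample.int(length(elements))]
  }

  ## --- lay out elements left to right
  genes <- list(); tss <- list(); srnas <- list()
  cursor <- sample_one(250:400)  # leading margin leaves promoter room
  gidx <- 0L; oidx <- 0L; sidx <- 0L
  gene_len <- function() {
    len <- max(99L, as.integer(round(stats::rnorm(1, spec$mean_gene_length,
                                                  0.25 * spec$mean_gene_length))))
    len - len %% 3L
  }
  for (el in elements) {
    if (identical(el$program, "srna")) {
      sidx <- sidx + 1L
      cursor <- cursor + sample_one(220:300)
      start <- cursor
      end <- start + el$srna_len - 1L
      strand <- sample_one(c("+", "-"))
      srnas[[sidx]] <- data.frame(
        srna_id = sprintf("sRNA%02d", sidx), start = start, end = end,
        strand = strand, fold = el$fold, has_motif = el$has_motif,
        tss = if (strand == "+") start else end)
      # a minus-strand promoter occupies the 50 bases right of the TSS
      cursor <- if (strand == "+") end else end + 50L
      next
    }
    strand <- sample_one(c("+", "-"))
    left <- el$size
    while (left > 0L) {
      osz <- min(left, sample_one(1:3))
      oidx <- oidx + 1L
      cursor <- cursor + sample_one(220:350)  # inter-operon gap: promoter room
      op_genes <- character(osz)
      op_start <- cursor + 1L
      for (k in seq_len(osz)) {
        gidx <- gidx + 1L
        len <- gene_len()
        start <- cursor + 1L
        end <- start + len - 1L
        id <- sprintf("bdsg%04d", gidx)
        genes[[gidx]] <- data.frame(gene_id = id, start = start, end = end,
                                    strand = strand, program = el$program,
                                    operon_id = sprintf("op%04d", oidx))
        op_genes[k] <- id
        cursor <- end + if (k < osz) sample_one(5:40) else 0L
      }
      op_end <- cursor
      if (el$program != "silent") {
        d <- sample_one(20:150)
        pos <- if (strand == "+") op_start - d else op_end + d
        has_motif <- el$program %in% c("AP_only", "AP_dominant") &&
          stats::runif(1) < spec$motif_fraction
        ord <- if (strand == "+") op_genes else rev(op_genes)
        tss[[length(tss) + 1L]] <- data.frame(
          position = pos, strand = strand,
          gene_ids = paste(ord, collapse = ","),
          has_motif = has_motif, kind = "gene")
        # keep downstream elements clear of a minus-strand promoter
        if (strand == "-") cursor <- max(cursor, pos + 50L)
      }
      left <- left - osz
    }
    cursor <- cursor + sample_one(30:150)  # extra inter-cluster spacing
  }
  need <- cursor + 250L
  if (need > L)
    abort("infeasible packing: layout requires %d bases but genome_length is %d",
          need, L)

  genes <- if (gidx > 0L) do.call(rbind, genes) else empty_truth$genes
  srnas <- if (sidx > 0L) do.call(rbind, srnas) else empty_truth$true_srnas
  tss <- if (length(tss)) do.call(rbind, tss) else empty_truth$true_tss

  ## --- sRNA TSSs (each sRNA is its own primary transcript)
  if (nrow(srnas)) {
    tss <- rbind(tss, data.frame(position = srnas$tss, strand = srnas$strand,
                                 gene_ids = srnas$srna_id,
                                 has_motif = srnas$has_motif, kind = "srna"))
  }

  ## --- build the sequence: background, program-GC genes, promoters
  gc_bg <- mean(c(spec$gc_ap, spec$gc_gp))
  seq_chr <- strsplit(rc(L, gc_bg), "")[[1]]
  gc_of <- function(prog) switch(prog,
    AP_only = , AP_dominant = spec$gc_ap,
    GP_only = , GP_dominant = spec$gc_gp,
    gc_bg)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    seq_chr[g$start:g$end] <-
      strsplit(rc(g$end - g$start + 1L, gc_of(g$program)), "")[[1]]
  }
  ## sRNA bodies: regenerate until free of long closed ORFs so the ORF filter
  ## never discards a planted sRNA
  for (i in seq_len(nrow(srnas))) {
    s <- srnas[i, ]
    for (try in 1:50) {
      body <- rc(s$end - s$start + 1L, gc_bg)
      oriented <- if (s$strand == "+") body else revcomp_chr(body)
      if (!has_long_orf(oriented, 50L)) break
    }
    seq_chr[s$start:s$end] <- strsplit(body, "")[[1]]
  }
  ## promoters: 50 bases upstream of each TSS in transcript orientation;
  ## motif-bearing ones carry TTAAG at offsets 18-22 and CCGATA at 39-44
  ## (1-based), i.e. the -10 box ends 7 nt before the TSS with a 16 nt spacer
  for (i in seq_len(nrow(tss))) {
    t <- tss[i, ]
    prom <- strsplit(rc(50L, gc_bg), "")[[1]]
    if (t$has_motif) {
      prom[18:22] <- strsplit("TTAAG", "")[[1]]
      prom[39:44] <- strsplit("CCGATA", "")[[1]]
    }
    if (t$strand == "+") {
      seq_chr[(t$position - 50L):(t$position - 1L)] <- prom
    } else {
      seq_chr[(t$position + 1L):(t$position + 50L)] <-
        strsplit(revcomp_chr(paste(prom, collapse = "")), "")[[1]]
    }
  }

  genome <- Biostrings::DNAStringSet(
    stats::setNames(paste(seq_chr, collapse = ""), SEQNAME))

  annotation <- GenomicRanges::GRanges(
    seqnames = rep(SEQNAME, nrow(genes)),
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand,
    gene_id = genes$gene_id)
  GenomeInfoDb::seqlengths(annotation) <- stats::setNames(L, SEQNAME)

  truth <- list(genes = genes,
                gene_programs = stats::setNames(genes$program, genes$gene_id),
                true_tss = tss,
                true_srnas = srnas)
  list(genome = genome, annotation = annotation, truth = truth)
}

#' Simulate whole-transcriptome alignment sets for both phases
#'
#' Reads of length `read_length` with 5' ends uniform within each transcript
#' (gene or sRNA); read counts are multinomial over transcripts with weights
#' proportional to program-specific expression level times transcript length.
#' Phase-exclusive programs receive zero reads in the other condition; an
#' optional `background_frac` of stray reads is uniform over the genome.
#'
#' @param genome A `DNAStringSet` as returned by [generate_genome()] (used
#'   for the genome length bound).
#' @param truth Ground truth from [generate_genome()].
#' @param spec The [simulation_spec()] used for generation.
#' @return A list with `ap` and `gp`: sorted [GenomicRanges::GRanges] of
#'   aligned read intervals.
#' @export
simulate_alignments <- function(genome, truth, spec) {
  validate_spec(spec)
  set.seed(spec$seed + 1L)
  L <- Biostrings::width(genome)[1]
  rl <- spec$read_length

  tx <- rbind(
    if (nrow(truth$genes))
      data.frame(start = truth$genes$start, end = truth$genes$end,
                 strand = truth$genes$strand, program = truth$genes$program,
                 srna_fold = NA_real_),
    if (nrow(truth$true_srnas))
      data.frame(start = truth$true_srnas$start, end = truth$true_srnas$end,
                 strand = truth$true_srnas$strand, program = "srna",
                 srna_fold = truth$true_srnas$fold))

  one_library <- function(size, cond) {
    if (size == 0L || is.null(tx) || nrow(tx) == 0L)
      return(GenomicRanges::GRanges(seqlengths = stats::setNames(L, SEQNAME)))
    lev <- ifelse(tx$program == "srna",
                  if (cond == "AP") SRNA_AP_LEVEL else SRNA_AP_LEVEL / tx$srna_fold,
                  PROGRAM_LEVELS[[cond]][tx$program])
    len <- tx$end - tx$start + 1L
    w <- lev * len
    n_bg <- round(size * spec$background_frac)
    n_tx <- size - n_bg
    starts <- integer(0); strands <- character(0)
    if (sum(w) > 0 && n_tx > 0) {
      cnt <- as.vector(stats::rmultinom(1, n_tx, w))
      for (i in which(cnt > 0L)) {
        span <- len[i] - rl + 1L
        if (span < 1L) next
        starts <- c(starts, tx$start[i] + sample.int(span, cnt[i],
                                                     replace = TRUE) - 1L)
        strands <- c(strands, rep(tx$strand[i], cnt[i]))
      }
    }
    if (n_bg > 0L) {
      starts <- c(starts, sample.int(L - rl + 1L, n_bg, replace = TRUE))
      strands <- c(strands, sample(c("+", "-"), n_bg, replace = TRUE))
    }
    o <- order(starts)
    gr <- GenomicRanges::GRanges(
      seqnames = rep(SEQNAME, length(starts)),
      ranges = IRanges::IRanges(start = starts[o], width = rl),
      strand = strands[o])
    GenomeInfoDb::seqlengths(gr) <- stats::setNames(L, SEQNAME)
    gr
  }

  list(ap = one_library(spec$library_size_ap, "AP"),
       gp = one_library(spec$library_size_gp, "GP"))
}

#' Simulate TAP(+)/TAP(-) 5'-end count tracks
#'
#' At every true TSS the TAP(+) count is Poisson with mean inflated by
#' `tss_enrichment_factor`; processed 5'-end sites receive equal Poisson
#' means in both tracks. Per-track Poisson means are scaled so realized track
#' totals match `tap_plus_depth` and `tap_minus_depth` in expectation.
#'
#' @param truth Ground truth from [generate_genome()].
#' @param spec The [simulation_spec()].
#' @return A list with `tap_plus` and `tap_minus`, each a
#'   [five_prime_track()].
#' @export
simulate_five_prime_tracks <- function(truth, spec) {
  validate_spec(spec)
  set.seed(spec$seed + 2L)
  L <- spec$genome_length
  tss <- truth$true_tss
  n_proc <- round(spec$processed_site_rate * L / 1000)
  if (nrow(tss) == 0L && n_proc == 0L)
    abort("nothing to simulate: no true TSSs and processed_site_rate = 0")

  proc <- data.frame(position = integer(0), strand = character(0))
  if (n_proc > 0L) {
    pos <- sample.int(L, n_proc, replace = FALSE)
    strand <- sample(c("+", "-"), n_proc, replace = TRUE)
    clash <- paste(pos, strand) %in% paste(tss$position, tss$strand)
    proc <- data.frame(position = pos[!clash], strand = strand[!clash])
  }

  E <- spec$tss_enrichment_factor
  n_tss <- nrow(tss); n_pr <- nrow(proc)
  lam_plus <- spec$tap_plus_depth / max(E * n_tss + n_pr, 1)
  lam_minus <- spec$tap_minus_depth / max(n_tss + n_pr, 1)

  build <- function(lam_tss, lam_proc, treatment) {
    df <- rbind(
      if (n_tss) data.frame(pos = tss$position, strand = tss$strand,
                            count = stats::rpois(n_tss, lam_tss)),
      if (n_pr) data.frame(pos = proc$position, strand = proc$strand,
                           count = stats::rpois(n_pr, lam_proc)))
    if (is.null(df)) df <- data.frame(pos = integer(), strand = character(),
                                      count = integer())
    df <- df[df$count > 0L, , drop = FALSE]
    df <- df[order(df$strand, df$pos), , drop = FALSE]
    rownames(df) <- NULL
    five_prime_track(df, treatment = treatment)
  }
  list(tap_plus = build(lam_plus * E, lam_plus, "TAP_plus"),
       tap_minus = build(lam_minus, lam_minus, "TAP_minus"))
}

#' Generate a full synthetic bundle in memory
#'
#' Convenience wrapper running [generate_genome()], [simulate_alignments()]
#' and [simulate_five_prime_tracks()] under one spec.
#'
#' @param spec A [simulation_spec()].
#' @return A list: `spec`, `genome`, `annotation`, `truth`, `alignments`
#'   (list `ap`/`gp`), `tracks` (list `tap_plus`/`tap_minus`).
#' @export
simulate_bundle <- function(spec = simulation_spec()) {
  g <- generate_genome(spec)
  aln <- simulate_alignments(g$genome, g$truth, spec)
  trk <- simulate_five_prime_tracks(g$truth, spec)
  list(spec = spec, genome = g$genome, annotation = g$annotation,
       truth = g$truth, alignments = aln, tracks = trk)
}

#' Write a synthetic bundle to disk
#'
#' Serializes the genome (FASTA), annotation (GFF3, gene features only), a
#' ground-truth GFF3 copy carrying a `program` attribute, alignments (BED6),
#' 5'-end tracks (bedGraph, one file per strand per treatment) and the ground
#' truth (JSON). All coordinates in GFF3/JSON are 1-based inclusive; BED and
#' bedGraph follow their native 0-based half-open convention.
#'
#' @param bundle Output of [simulate_bundle()].
#' @param dir Output directory, created if needed.
#' @return Invisibly, a named character vector of written paths.
#' @export
write_synthetic_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, paste0(...))
  paths <- c(genome = p("genome.fasta"),
             annotation = p("annotation.gff3"),
             annotation_truth = p("annotation_truth.gff3"),
             ap = p("alignments_ap.bed"), gp = p("alignments_gp.bed"),
             truth = p("ground_truth.json"))
  Biostrings::writeXStringSet(bundle$genome, paths[["genome"]])

  ann <- bundle$annotation
  if (length(ann)) {
    S4Vectors::mcols(ann)$type <- "gene"
    S4Vectors::mcols(ann)$ID <- S4Vectors::mcols(ann)$gene_id
  }
  rtracklayer::export(ann, paths[["annotation"]], format = "gff3")
  ann_truth <- ann
  if (length(ann_truth))
    S4Vectors::mcols(ann_truth)$program <-
      unname(bundle$truth$gene_programs[S4Vectors::mcols(ann_truth)$gene_id])
  rtracklayer::export(ann_truth, paths[["annotation_truth"]], format = "gff3")

  export_bed6 <- function(gr, path) {
    if (length(gr)) {
      S4Vectors::mcols(gr)$name <- sprintf("r%07d", seq_along(gr))
      S4Vectors::mcols(gr)$score <- 0L
    }
    rtracklayer::export(gr, path, format = "bed")
  }
  export_bed6(bundle$alignments$ap, paths[["ap"]])
  export_bed6(bundle$alignments$gp, paths[["gp"]])

  for (tr in c("tap_plus", "tap_minus")) {
    trk <- bundle$tracks[[tr]]
    for (s in c("+", "-")) {
      tag <- if (s == "+") "fwd" else "rev"
      path <- p(tr, "_", tag, ".bedGraph")
      paths[[paste0(tr, "_", tag)]] <- path
      write_track_bedgraph(trk, strand = s, path = path,
                           genome_length = bundle$spec$genome_length)
    }
  }

  truth <- bundle$truth
  jsonlite::write_json(
    list(gene_programs = as.list(truth$gene_programs),
         genes = truth$genes, true_tss = truth$true_tss,
         true_srnas = truth$true_srnas),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
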