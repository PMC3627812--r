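#' Intergenic regions of an annotation
#'
#' Complement of the (strand-ignoring) union of gene intervals within
#' `[1, genome_length]`, dropping intervals shorter than `min_len`.
#'
#' @param annotation Gene [GenomicRanges::GRanges].
#' @param genome_length Genome length in bases.
#' @param min_len Minimum reported interval length (default 50).
#' @return A [GenomicRanges::GRanges] of intergenic intervals (strand `*`).
#' @export
intergenic_regions <- function(annotation, genome_length, min_len = 50L) {
  whole <- GenomicRanges::GRanges(
    seqnames = SEQNAME,
    ranges = IRanges::IRanges(1L, as.integer(genome_length)))
  if (length(annotation) == 0L) {
    out <- whole
  } else {
    genes <- GenomicRanges::GRanges(
      seqnames = rep(SEQNAME, length(annotation)),
      ranges = IRanges::ranges(annotation))
    out <- GenomicRanges::setdiff(whole, GenomicRanges::reduce(genes))
  }
  out <- out[GenomicRanges::width(out) >= min_len]
  GenomeInfoDb::seqlengths(out) <- stats::setNames(as.integer(genome_length),
                                                    SEQNAME)
  out
}

#' RPKM floor equivalent to a single read on an interval
#'
#' Used when a fold change has a zero denominator: the smallest non-zero
#' RPKM the library could have produced on this interval.
#'
#' @param length Interval length in bases.
#' @param total_mapped Library total.
#' @return Numeric RPKM floor.
#' @export
eps_rpkm <- function(length, total_mapped)
  1e9 / (as.numeric(length) * as.numeric(total_mapped))

#' AP/GP fold increase with an RPKM floor
#'
#' `fold = rpkm_ap / max(rpkm_gp, eps)`; with `eps = 0` this is the plain
#' RPKM ratio. Report with `round()` for nearest-integer folds.
#'
#' @param rpkm_ap,rpkm_gp RPKM values.
#' @param eps Denominator floor, typically [eps_rpkm()].
#' @return Numeric fold change(s).
#' @examples
#' round(fold_increase(50451, 3181))  # 16
#' @export
fold_increase <- function(rpkm_ap, rpkm_gp, eps = 0) {
  rpkm_ap / pmax(rpkm_gp, eps)
}

#' Screen intergenic regions for AP-biased expression
#'
#' Counts reads per region in both conditions (overlap rule as in
#' [count_reads()]), computes region RPKM, applies the chi-square test with
#' Bonferroni correction over the number of screened regions, and keeps
#' regions with AP/GP fold (RPKM-floored) above `min_fold` and adjusted
#' p-value at most `alpha`.
#'
#' @param regions [intergenic_regions()] output.
#' @param ap_alignments,gp_alignments Read [GenomicRanges::GRanges].
#' @param total_ap,total_gp Mapped-read totals for RPKM normalization.
#' @param min_fold Retention fold threshold (strict `>`; default 4).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return Data frame of retained candidate regions (`start`, `end`,
#'   `length`, `count_ap`, `count_gp`, `rpkm_ap`, `rpkm_gp`, `fold`,
#'   `p_raw`, `p_adj`), with the screening family size as attribute
#'   `n_regions`.
#' @export
screen_regions <- function(regions, ap_alignments, gp_alignments,
                           total_ap = length(ap_alignments),
                           total_gp = length(gp_alignments),
                           min_fold = 4, alpha = 0.05) {
  n_regions <- length(regions)
  if (n_regions == 0L) {
    out <- data.frame(start = integer(), end = integer(), length = integer(),
                      count_ap = integer(), count_gp = integer(),
                      rpkm_ap = numeric(), rpkm_gp = numeric(),
                      fold = numeric(), p_raw = numeric(), p_adj = numeric())
    attr(out, "n_regions") <- 0L
    return(out)
  }
  len <- GenomicRanges::width(regions)
  ca <- GenomicRanges::countOverlaps(regions, ap_alignments,
                                     ignore.strand = TRUE)
  cg <- GenomicRanges::countOverlaps(regions, gp_alignments,
                                     ignore.strand = TRUE)
  ra <- rpkm(ca, len, total_ap)
  rg <- rpkm(cg, len, total_gp)
  test <- chi2_differential(ra, rg, n_regions)
  fold <- fold_increase(ra, rg, eps_rpkm(len, total_gp))
  out <- data.frame(start = GenomicRanges::start(regions),
                    end = GenomicRanges::end(regions),
                    length = len, count_ap = ca, count_gp = cg,
                    rpkm_ap = ra, rpkm_gp = rg, fold = fold,
                    p_raw = test$p_raw, p_adj = test$p_adj)
  out <- out[out$fold > min_fold & out$p_adj <= alpha, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_regions") <- n_regions
  out
}

#' Discard candidates that are long 5'UTRs of a downstream gene
#'
#' A candidate is discarded when the per-base AP coverage between one of its
#' ends and the adjacent gene pointing away from the candidate (right
#' neighbour on the plus strand, left neighbour on the minus strand) never
#' falls below `connect_frac` times the candidate's mean coverage, and that
#' gene is expressed in AP — i.e. the candidate's expression is connected to
#' the downstream gene.
#'
#' @param candidates [screen_regions()] output.
#' @param coverage Per-base AP coverage vector.
#' @param annotation Gene [GenomicRanges::GRanges] with `gene_id`.
#' @param expressed_ap Character vector of gene_ids expressed in AP.
#' @param connect_frac Connection floor as a fraction of candidate mean
#'   coverage (default 0.25).
#' @return The retained subset of `candidates`.
#' @export
exclude_utr_readthrough <- function(candidates, coverage, annotation,
                                    expressed_ap, connect_frac = 0.25) {
  if (nrow(candidates) == 0L) return(candidates)
  ids <- S4Vectors::mcols(annotation)$gene_id
  gstr <- as.character(GenomicRanges::strand(annotation))
  gstart <- GenomicRanges::start(annotation)
  gend <- GenomicRanges::end(annotation)

  connected <- function(lo, hi, floor_val) {
    if (lo > hi) return(TRUE)  # abutting: trivially connected
    min(coverage[lo:hi]) >= floor_val
  }
  drop <- logical(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    cand <- candidates[i, ]
    floor_val <- connect_frac * mean(coverage[cand$start:cand$end])
    # right neighbour transcribed rightwards (+); the candidate's own edge
    # base is included so an uncovered edge breaks the connection even when
    # the candidate abuts the gene
    r <- which(gstart > cand$end & gstr == "+")
    if (length(r)) {
      r <- r[which.min(gstart[r])]
      if (ids[r] %in% expressed_ap &&
          connected(cand$end, gstart[r] - 1L, floor_val))
        drop[i] <- TRUE
    }
    # left neighbour transcribed leftwards (-)
    l <- which(gend < cand$start & gstr == "-")
    if (length(l)) {
      l <- l[which.max(gend[l])]
      if (ids[l] %in% expressed_ap &&
          connected(gend[l] + 1L, cand$start, floor_val))
        drop[i] <- TRUE
    }
  }
  out <- candidates[!drop, , drop = FALSE]
  attr(out, "n_regions") <- attr(candidates, "n_regions")
  out
}

#' Fix sRNA boundaries from TSS data and coverage
#'
#' The start and strand come from the strongest TSS call inside or within 50
#' nt upstream of the raw region; the end is the last position downstream of
#' the start where coverage holds at least `end_frac` of the candidate's
#' peak, scanning until coverage stays below that floor for `persistence`
#' consecutive bases; the thresholded end is then extended through the
#' trailing covered taper by at most `read_length` bases (the 3' coverage
#' taper left by fixed-length reads). An abrupt coverage cliff therefore maps
#' to the cliff exactly. RPKM and the differential test are recomputed on the
#' refined interval.
#'
#' @param candidate One row of [screen_regions()] output.
#' @param tss_calls [call_tss()] output (typically called with
#'   `annotation = NULL` so sRNA TSSs are retained).
#' @param coverage Per-base AP coverage vector.
#' @param ap_alignments,gp_alignments Read sets for the re-test.
#' @param total_ap,total_gp Library totals.
#' @param n_tests Bonferroni family size carried over from screening.
#' @param end_frac Coverage floor as a fraction of peak (default 0.1).
#' @param persistence Consecutive sub-floor bases ending the scan
#'   (default 20).
#' @param read_length Maximum taper extension in bases (default 36).
#' @return A one-row data frame (`start`, `end`, `strand`, `size`,
#'   `tss_position`, `tss_raw_plus`, `count_ap`, `count_gp`, `rpkm_ap`,
#'   `rpkm_gp`, `fold`, `p_raw`, `p_adj`), or `NULL` when no qualifying TSS
#'   exists or the refined end does not extend past the start (reason in
#'   attribute `reason`).
#' @export
refine_boundaries <- function(candidate, tss_calls, coverage,
                              ap_alignments, gp_alignments,
                              total_ap = length(ap_alignments),
                              total_gp = length(gp_alignments),
                              n_tests = 1L, end_frac = 0.1,
                              persistence = 20L, read_length = 36L) {
  hits <- qualifying_tss(candidate, tss_calls)
  if (nrow(hits) == 0L) {
    message(sprintf("candidate %d-%d dropped: no qualifying TSS",
                    candidate$start, candidate$end))
    return(NULL)
  }
  hits <- hits[order(-hits$raw_plus), , drop = FALSE]
  for (h in seq_len(nrow(hits))) {
    r <- refine_at_tss(hits[h, , drop = FALSE], candidate, coverage,
                       ap_alignments, gp_alignments, total_ap, total_gp,
                       n_tests, end_frac, persistence, read_length)
    if (!is.null(r)) return(r)
  }
  message(sprintf("candidate %d-%d dropped: refined end does not extend past start",
                  candidate$start, candidate$end))
  NULL
}

# TSS calls anchoring a candidate region: inside it or within 50 nt upstream
# in transcript orientation.
qualifying_tss <- function(candidate, tss_calls) {
  sel <- (tss_calls$strand == "+" &
            tss_calls$position >= candidate$start - 50L &
            tss_calls$position <= candidate$end) |
         (tss_calls$strand == "-" &
            tss_calls$position >= candidate$start &
            tss_calls$position <= candidate$end + 50L)
  tss_calls[sel, , drop = FALSE]
}

# Refinement anchored at one TSS call. Two-pass coverage scan, bounded to the
# candidate's (intergenic) extent so refined sRNAs never cross into annotated
# genes: first the contiguous covered block downstream of the TSS (gaps up to
# `persistence` bases bridged), then the end_frac floor relative to the
# block's own peak, then a taper extension of at most read_length covered
# bases. Returns NULL when the transcript has no extent at this TSS.
refine_at_tss <- function(tss, candidate, coverage,
                          ap_alignments, gp_alignments, total_ap, total_gp,
                          n_tests, end_frac, persistence, read_length) {
  L <- length(coverage)
  strand <- tss$strand
  tstart <- tss$position
  dirn <- if (strand == "+") 1L else -1L
  lo_bound <- max(1L, min(candidate$start, tstart))
  hi_bound <- min(L, max(candidate$end, tstart))

  scan <- function(floor_val) {
    p <- tstart
    last_good <- tstart
    below <- 0L
    while (p >= lo_bound && p <= hi_bound && below < persistence) {
      if (coverage[p] >= floor_val) {
        last_good <- p
        below <- 0L
      } else below <- below + 1L
      p <- p + dirn
    }
    last_good
  }
  block_end <- scan(1)
  if (block_end == tstart && coverage[tstart] == 0L) return(NULL)
  peak <- max(coverage[tstart:block_end])
  if (peak <= 0) return(NULL)
  ext <- scan(end_frac * peak)
  # extend through the 3' taper left by fixed-length reads
  q <- ext + dirn
  steps <- 0L
  while (q >= lo_bound && q <= hi_bound && steps < read_length &&
         coverage[q] > 0L) {
    ext <- q
    q <- q + dirn
    steps <- steps + 1L
  }
  if (ext == tstart) return(NULL)
  start <- min(tstart, ext)
  end <- max(tstart, ext)
  len <- end - start + 1L
  gr <- GenomicRanges::GRanges(SEQNAME, IRanges::IRanges(start, end))
  ca <- GenomicRanges::countOverlaps(gr, ap_alignments, ignore.strand = TRUE)
  cg <- GenomicRanges::countOverlaps(gr, gp_alignments, ignore.strand = TRUE)
  ra <- rpkm(ca, len, total_ap)
  rg <- rpkm(cg, len, total_gp)
  test <- chi2_differential(ra, rg, max(1L, n_tests))
  data.frame(start = start, end = end, strand = strand, size = len,
             tss_position = tstart, tss_raw_plus = tss$raw_plus,
             count_ap = ca, count_gp = cg, rpkm_ap = ra, rpkm_gp = rg,
             fold = fold_increase(ra, rg, eps_rpkm(len, total_gp)),
             p_raw = test$p_raw, p_adj = test$p_adj)
}

# TRUE when the oriented sequence contains a closed ORF (ATG..in-frame stop)
# of at least max_orf_aa codons (ATG through the codon before the stop).
has_long_orf <- function(seq, max_orf_aa = 50L) {
  s <- toupper(as.character(seq))
  n <- nchar(s)
  for (f in 0:2) {
    if (n - f < 6L) next
    starts <- seq(1L + f, n - 2L, by = 3L)
    codons <- substring(s, starts, starts + 2L)
    atg <- which(codons == "ATG")
    if (!length(atg)) next
    stops <- which(codons %in% c("TAA", "TAG", "TGA"))
    for (a in atg) {
      st <- stops[stops > a]
      if (length(st) && st[1] - a >= max_orf_aa) return(TRUE)
    }
  }
  FALSE
}

#' Flag candidates containing a long closed ORF
#'
#' A local stand-in for protein-homology screening: a candidate is flagged
#' for exclusion when its sense-strand sequence contains an open reading
#' frame (ATG through an in-frame stop, any frame) of at least `max_orf_aa`
#' codons. A start codon with no in-frame stop before the sequence end is
#' not a closed ORF and does not flag.
#'
#' @param start,end,strand Candidate coordinates (1-based inclusive).
#' @param genome `DNAStringSet` of the genome.
#' @param max_orf_aa Codon threshold (default 50).
#' @return Logical: `TRUE` when the candidate should be excluded.
#' @export
orf_filter <- function(start, end, strand, genome, max_orf_aa = 50L) {
  sq <- as.character(Biostrings::subseq(genome[[1]], start, end))
  if (strand == "-") sq <- revcomp_chr(sq)
  has_long_orf(sq, max_orf_aa)
}

#' Does an sRNA candidate carry the two-box promoter motif?
#'
#' Extracts the candidate's 50-base promoter (upstream of its TSS-anchored
#' start, in transcript orientation) and scans it with the discovered motif.
#'
#' @param candidate A refined candidate row (needs `start`, `end`, `strand`;
#'   the TSS-anchored 5' end is `start` on `+` and `end` on `-`).
#' @param motif A `two_box_motif`.
#' @param genome `DNAStringSet` of the genome.
#' @return Logical.
#' @export
annotate_promoter <- function(candidate, motif, genome) {
  if (!is.null(candidate$has_tss) && !isTRUE(candidate$has_tss))
    abort("candidate lacks a TSS-anchored start")
  if (is.null(candidate$start) || is.null(candidate$strand))
    abort("candidate needs start/end/strand fields")
  pos <- if (candidate$strand == "+") candidate$start else candidate$end
  calls <- data.frame(position = pos, strand = candidate$strand,
                      raw_plus = NA, raw_minus = NA, enrichment = NA,
                      assigned_genes = "", distance_to_start = NA)
  prom <- suppressWarnings(extract_promoters(calls, genome))
  if (!length(prom)) return(FALSE)
  !is.null(scan_motif(prom[[1]], motif))
}

#' Discover attack-phase-specific intergenic sRNAs
#'
#' Full sRNA stage: intergenic regions are screened for >`min_fold` AP-biased
#' significant expression, long-5'UTR read-through candidates are discarded,
#' boundaries are fixed from TSS calls plus coverage and the differential
#' test is recomputed on the refined coordinates, candidates containing long
#' closed ORFs are excluded, and promoters are scanned for the two-box motif
#' when one is supplied.
#'
#' @param annotation Gene [GenomicRanges::GRanges] with `gene_id`.
#' @param genome `DNAStringSet` of the genome.
#' @param ap_alignments,gp_alignments Read sets.
#' @param tss_calls Unrestricted [call_tss()] output (`annotation = NULL`).
#' @param motif Optional `two_box_motif` for promoter annotation.
#' @param total_ap,total_gp Library totals.
#' @param expressed_ap Character vector of AP-expressed gene ids (for the
#'   5'UTR filter); computed from the alignments when missing.
#' @param min_fold,alpha,connect_frac,end_frac,persistence,read_length,max_orf_aa
#'   Stage parameters; see the stage functions.
#' @return A data frame, one row per emitted sRNA, sorted by coordinate:
#'   `name`, `start`, `end`, `strand`, `size`, `rpkm_ap`, `rpkm_gp`, `fold`,
#'   `fold_rounded`, `p_adj`, `has_tss`, `fliA_promoter`, `orf_filtered`.
#'   ORF-flagged candidates are reported with `orf_filtered = TRUE` but not
#'   counted as sRNAs by downstream summaries.
#' @export
discover_srnas <- function(annotation, genome, ap_alignments, gp_alignments,
                           tss_calls, motif = NULL,
                           total_ap = length(ap_alignments),
                           total_gp = length(gp_alignments),
                           expressed_ap = NULL,
                           min_fold = 4, alpha = 0.05, connect_frac = 0.25,
                           end_frac = 0.1, persistence = 20L,
                           read_length = 36L, max_orf_aa = 50L) {
  L <- Biostrings::width(genome)[1]
  regions <- intergenic_regions(annotation, L)
  screened <- screen_regions(regions, ap_alignments, gp_alignments,
                             total_ap, total_gp, min_fold, alpha)
  n_regions <- attr(screened, "n_regions")
  cov_ap <- coverage_vector(ap_alignments, L)

  if (is.null(expressed_ap) && length(annotation)) {
    ca <- count_reads(ap_alignments, annotation)
    ra <- rpkm(ca, GenomicRanges::width(annotation), total_ap)
    expressed_ap <- names(ra)[ra > 50]
  }
  screened <- exclude_utr_readthrough(screened, cov_ap, annotation,
                                      expressed_ap %||% character(),
                                      connect_frac)

  refined <- list()
  for (i in seq_len(nrow(screened))) {
    cand <- screened[i, ]
    hits <- qualifying_tss(cand, tss_calls)
    if (nrow(hits) == 0L) {
      message(sprintf("candidate %d-%d dropped: no qualifying TSS",
                      cand$start, cand$end))
      next
    }
    # a region may host several independent transcripts, each with its own
    # TSS; refine every anchored block
    for (h in seq_len(nrow(hits))) {
      r <- refine_at_tss(hits[h, , drop = FALSE], cand, cov_ap,
                         ap_alignments, gp_alignments, total_ap, total_gp,
                         n_tests = n_regions, end_frac = end_frac,
                         persistence = persistence,
                         read_length = read_length)
      if (!is.null(r)) refined[[length(refined) + 1L]] <- r
    }
  }
  if (!length(refined)) {
    return(data.frame(name = character(), start = integer(), end = integer(),
                      strand = character(), size = integer(),
                      rpkm_ap = numeric(), rpkm_gp = numeric(),
                      fold = numeric(), fold_rounded = integer(),
                      p_adj = numeric(), has_tss = logical(),
                      fliA_promoter = logical(), orf_filtered = logical()))
  }
  out <- do.call(rbind, refined)
  out <- out[!duplicated(out[, c("start", "end", "strand")]), , drop = FALSE]
  out <- out[out$fold > min_fold & out$p_adj <= alpha, , drop = FALSE]
  # overlapping same-strand refinements (two calls anchoring one block):
  # keep the better-supported one
  out <- out[order(-out$tss_raw_plus), , drop = FALSE]
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    for (j in seq_len(i - 1L)) {
      if (keep[j] && out$strand[i] == out$strand[j] &&
          out$start[i] <= out$end[j] && out$end[i] >= out$start[j]) {
        keep[i] <- FALSE
        break
      }
    }
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]

  orf <- vapply(seq_len(nrow(out)), function(i)
    orf_filter(out$start[i], out$end[i], out$strand[i], genome, max_orf_aa),
    logical(1))
  flia <- vapply(seq_len(nrow(out)), function(i) {
    if (is.null(motif)) return(NA)
    annotate_promoter(out[i, ], motif, genome)
  }, logical(1))

  data.frame(name = sprintf("APsRNA%d", seq_len(nrow(out))),
             start = out$start, end = out$end, strand = out$strand,
             size = out$size, rpkm_ap = out$rpkm_ap, rpkm_gp = out$rpkm_gp,
             fold = out$fold, fold_rounded = as.integer(round(out$fold)),
             p_adj = out$p_adj, has_tss = TRUE, fliA_promoter = flia,
             orf_filtered = orf)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
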