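#' A per-position, per-strand 5'-end read-start count track
#'
#' Container for one TAP-treated or untreated 5'-end library: read-start
#' counts indexed by (position, strand), plus the library total used for
#' depth normalization.
#'
#' @param counts Data frame with columns `pos` (1-based), `strand`
#'   (`"+"`/`"-"`) and `count` (non-negative integers).
#' @param treatment `"TAP_plus"` or `"TAP_minus"`.
#' @param total Library total; defaults to the sum of counts.
#' @return An object of class `five_prime_track`.
#' @export
five_prime_track <- function(counts, treatment = c("TAP_plus", "TAP_minus"),
                             total = NULL) {
  treatment <- match.arg(treatment)
  stopifnot(all(c("pos", "strand", "count") %in% names(counts)))
  if (any(counts$count < 0)) abort("5'-end counts must be non-negative")
  if (is.null(total)) total <- sum(counts$count)
  structure(list(counts = counts[, c("pos", "strand", "count")],
                 total = total, treatment = treatment),
            class = "five_prime_track")
}

#' @export
print.five_prime_track <- function(x, ...) {
  cat(sprintf("five_prime_track [%s]: %d positions, %s reads\n",
              x$treatment, nrow(x$counts), format(x$total, big.mark = ",")))
  invisible(x)
}

# Write one strand of a track as bedGraph (0-based half-open).
write_track_bedgraph <- function(track, strand, path, genome_length) {
  df <- track$counts[track$counts$strand == strand, , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = rep(SEQNAME, nrow(df)),
    ranges = IRanges::IRanges(start = df$pos, width = 1L),
    score = as.numeric(df$count))
  GenomeInfoDb::seqlengths(gr) <- stats::setNames(genome_length, SEQNAME)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a pair of strand-split bedGraph files into a track
#'
#' @param fwd_path,rev_path bedGraph paths holding plus- and minus-strand
#'   single-base 5'-end counts.
#' @param treatment Track treatment label.
#' @return A [five_prime_track()].
#' @export
read_five_prime_track <- function(fwd_path, rev_path,
                                  treatment = c("TAP_plus", "TAP_minus")) {
  treatment <- match.arg(treatment)
  one <- function(path, strand) {
    gr <- rtracklayer::import(path, format = "bedGraph")
    if (length(gr) == 0L)
      return(data.frame(pos = integer(), strand = character(),
                        count = integer()))
    # expand any multi-base runs back to single positions
    pos <- unlist(mapply(seq, GenomicRanges::start(gr), GenomicRanges::end(gr),
                         SIMPLIFY = FALSE))
    cnt <- rep(S4Vectors::mcols(gr)$score,
               GenomicRanges::width(gr))
    data.frame(pos = as.integer(pos), strand = strand,
               count = as.integer(cnt))
  }
  five_prime_track(rbind(one(fwd_path, "+"), one(rev_path, "-")),
                   treatment = treatment)
}

#' Call transcription start sites from TAP(+)/TAP(-) 5'-end tracks
#'
#' A position is called as a TSS when (i) it is supported by at least
#' `min_reads` TAP(+) reads, (ii) its depth-normalized TAP(+)/TAP(-)
#' enrichment is at least `min_enrichment`, and (iii) it lies within
#' `max_upstream` bases 5' of some same-strand gene start (or within the
#' first three codons, to tolerate annotation slack). Enrichment is computed
#' as `(raw_plus / total_plus) / ((raw_minus + 1) / total_minus)`; the
#' pseudocount guards zero TAP(-) counts. With `annotation = NULL` criterion
#' (iii) is skipped and calls carry no gene assignment (used for sRNA starts,
#' which have no annotated downstream gene).
#'
#' @param tap_plus,tap_minus [five_prime_track()] objects.
#' @param annotation Gene [GenomicRanges::GRanges] with `gene_id`, or `NULL`.
#' @param min_reads Minimum raw TAP(+) support (default 5).
#' @param min_enrichment Minimum normalized enrichment (default 3).
#' @param max_upstream Maximum distance 5' of a gene start (default 300).
#' @return A data frame of calls sorted by position: `position`, `strand`,
#'   `raw_plus`, `raw_minus`, `enrichment`, `assigned_genes` (comma-joined;
#'   `""` when unassigned), `distance_to_start` (`NA` when unassigned).
#' @export
call_tss <- function(tap_plus, tap_minus, annotation = NULL,
                     min_reads = 5L, min_enrichment = 3.0,
                     max_upstream = 300L) {
  if (tap_plus$total <= 0 || tap_minus$total <= 0)
    abort("both 5'-end tracks must contain reads (a total is 0)")
  plus <- tap_plus$counts
  minus <- tap_minus$counts
  key <- function(df) paste(df$pos, df$strand)
  m <- minus$count[match(key(plus), key(minus))]
  m[is.na(m)] <- 0L
  enr <- (plus$count / tap_plus$total) / ((m + 1) / tap_minus$total)
  keep <- plus$count >= min_reads & enr >= min_enrichment
  calls <- data.frame(position = plus$pos[keep], strand = plus$strand[keep],
                      raw_plus = plus$count[keep], raw_minus = m[keep],
                      enrichment = enr[keep],
                      assigned_genes = "", distance_to_start = NA_integer_)

  if (!is.null(annotation) && nrow(calls)) {
    starts5 <- ifelse(as.character(GenomicRanges::strand(annotation)) == "+",
                      GenomicRanges::start(annotation),
                      GenomicRanges::end(annotation))
    ids <- S4Vectors::mcols(annotation)$gene_id
    gstr <- as.character(GenomicRanges::strand(annotation))
    assigned <- character(nrow(calls))
    dist <- rep(NA_integer_, nrow(calls))
    for (i in seq_len(nrow(calls))) {
      p <- calls$position[i]; s <- calls$strand[i]
      d <- if (s == "+") starts5 - p else p - starts5
      d[gstr != s] <- NA_integer_
      ok <- which(!is.na(d) & d <= max_upstream & d >= -9L)
      if (length(ok)) {
        ok <- ok[order(d[ok])]
        assigned[i] <- paste(ids[ok], collapse = ",")
        dist[i] <- d[ok[1]]
      }
    }
    calls$assigned_genes <- assigned
    calls$distance_to_start <- dist
    calls <- calls[nzchar(calls$assigned_genes), , drop = FALSE]
  }
  calls <- calls[order(calls$position), , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

#' Collapse redundant TSS calls within a window
#'
#' Within any run of same-strand calls where consecutive positions differ by
#' at most `window`, only the call with maximal TAP(+) support survives (ties
#' broken toward the most 5' position in transcript orientation). A
#' deterministic surrogate for manual redundancy curation.
#'
#' @param calls Output of [call_tss()], sorted by position.
#' @param window Maximum spacing chained into one cluster (default 5).
#' @return Filtered calls; positions on each strand are pairwise separated by
#'   more than `window`.
#' @export
deduplicate_tss <- function(calls, window = 5L) {
  if (nrow(calls) < 2L) return(calls)
  out <- list()
  for (s in unique(calls$strand)) {
    cs <- calls[calls$strand == s, , drop = FALSE]
    cs <- cs[order(cs$position), , drop = FALSE]
    grp <- cumsum(c(1L, diff(cs$position) > window))
    for (g in unique(grp)) {
      cl <- cs[grp == g, , drop = FALSE]
      best <- which(cl$raw_plus == max(cl$raw_plus))
      # ties: most 5' in transcript orientation
      pick <- if (s == "+") best[1] else best[length(best)]
      out[[length(out) + 1L]] <- cl[pick, , drop = FALSE]
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$position), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Per-base read coverage from an alignment set
#'
#' @param alignments Read [GenomicRanges::GRanges].
#' @param genome_length Genome length (used when alignments carry no
#'   seqlengths).
#' @return An integer vector of per-base coverage (1-based index).
#' @export
coverage_vector <- function(alignments, genome_length = NULL) {
  sl <- GenomeInfoDb::seqlengths(alignments)
  if (is.null(genome_length)) {
    if (length(sl) == 0L || is.na(sl[1]))
      abort("genome_length required when alignments carry no seqlengths")
    genome_length <- sl[[1]]
  }
  if (length(alignments) == 0L) return(integer(genome_length))
  nm <- GenomeInfoDb::seqlevels(alignments)[1]
  cov <- GenomicRanges::coverage(
    alignments, width = stats::setNames(as.integer(genome_length), nm))
  as.integer(cov[[1]])
}

#' Extend TSS calls into operons
#'
#' Starting from a call's first downstream gene, genes are appended while the
#' next gene is co-oriented, has no own TSS call, and either its intergenic
#' gap is at most `max_gap` or the gap's minimum coverage is at least 25% of
#' the upstream gene's mean coverage (transcriptional read-through).
#'
#' @param calls Deduplicated [call_tss()] output with gene assignments.
#' @param annotation Gene [GenomicRanges::GRanges] with `gene_id`.
#' @param coverage Per-base coverage vector for the relevant condition (see
#'   [coverage_vector()]).
#' @param max_gap Maximum silent intergenic gap bridged (default 50).
#' @return `calls` with `assigned_genes` replaced by the operon gene list
#'   (comma-joined, transcription order). Calls with no downstream gene are
#'   dropped with a warning.
#' @export
assign_operons <- function(calls, annotation, coverage, max_gap = 50L) {
  if (nrow(calls) == 0L) return(calls)
  ids <- S4Vectors::mcols(annotation)$gene_id
  gstr <- as.character(GenomicRanges::strand(annotation))
  gstart <- GenomicRanges::start(annotation)
  gend <- GenomicRanges::end(annotation)
  has_own_tss <- ids %in% unlist(lapply(
    strsplit(calls$assigned_genes, ","), function(x) x[1]))

  drop <- logical(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    first <- strsplit(calls$assigned_genes[i], ",")[[1]][1]
    j <- match(first, ids)
    if (is.na(j)) { drop[i] <- TRUE; next }
    s <- gstr[j]
    operon <- j
    repeat {
      cur <- operon[length(operon)]
      # next co-oriented gene downstream in transcription direction
      if (s == "+") {
        cand <- which(gstart > gend[cur])
        cand <- cand[order(gstart[cand])]
      } else {
        cand <- which(gend < gstart[cur])
        cand <- cand[order(gend[cand], decreasing = TRUE)]
      }
      if (!length(cand)) break
      nxt <- cand[1]
      if (gstr[nxt] != s || has_own_tss[nxt]) break
      gap_lo <- if (s == "+") gend[cur] + 1L else gend[nxt] + 1L
      gap_hi <- if (s == "+") gstart[nxt] - 1L else gstart[cur] - 1L
      gap <- gap_hi - gap_lo + 1L
      if (gap > max_gap) {
        up_mean <- mean(coverage[gstart[cur]:gend[cur]])
        gap_min <- if (gap_lo <= gap_hi) min(coverage[gap_lo:gap_hi]) else Inf
        # read-through evidence requires actual upstream coverage
        if (up_mean <= 0 || !(gap_min >= 0.25 * up_mean)) break
      }
      operon <- c(operon, nxt)
    }
    calls$assigned_genes[i] <- paste(ids[operon], collapse = ",")
  }
  if (any(drop))
    warning(sprintf("%d TSS call(s) had no downstream gene and were excluded",
                    sum(drop)))
  calls[!drop, , drop = FALSE]
}

#' Extract promoter sequences upstream of TSS calls
#'
#' For a plus-strand TSS at position `p`, returns genomic bases
#' `[p - upstream_len, p - 1]`; for a minus-strand TSS, the reverse
#' complement of `[p + 1, p + upstream_len]`. Sequences are 5' to 3' relative
#' to transcription, each exactly `upstream_len` long. Calls too close to a
#' contig edge are skipped with a warning.
#'
#' @param calls [call_tss()] output (any subset).
#' @param genome `DNAStringSet` of the genome.
#' @param upstream_len Promoter length (default 50).
#' @return Named character vector of promoter sequences; names are
#'   `"<position><strand>"`.
#' @export
extract_promoters <- function(calls, genome, upstream_len = 50L) {
  L <- Biostrings::width(genome)[1]
  seqs <- character(0)
  skipped <- 0L
  for (i in seq_len(nrow(calls))) {
    p <- calls$position[i]; s <- calls$strand[i]
    if ((s == "+" && p - upstream_len < 1L) ||
        (s == "-" && p + upstream_len > L)) {
      skipped <- skipped + 1L
      next
    }
    sq <- if (s == "+") {
      as.character(Biostrings::subseq(genome[[1]], p - upstream_len, p - 1L))
    } else {
      revcomp_chr(as.character(Biostrings::subseq(genome[[1]], p + 1L,
                                                  p + upstream_len)))
    }
    seqs[paste0(p, s)] <- sq
  }
  if (skipped > 0L)
    warning(sprintf("%d TSS call(s) too close to the contig edge were skipped",
                    skipped))
  seqs
}
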