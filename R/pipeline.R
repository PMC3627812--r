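#' Pipeline run configuration
#'
#' Collects input paths and every stage parameter (defaults are the
#' published analysis settings; overrides are recorded alongside the default
#' in output metadata).
#'
#' @param genome,annotation,ap_alignments,gp_alignments Paths to FASTA, GFF3
#'   and BED6 inputs.
#' @param tap_plus_fwd,tap_plus_rev,tap_minus_fwd,tap_minus_rev Paths to the
#'   four strand-split 5'-end bedGraph tracks.
#' @param out_dir Output directory.
#' @param expressed_threshold RPKM above which a gene is expressed
#'   (default 50).
#' @param dominance_fold Fold for AP/GP dominance (default 5).
#' @param min_reads,min_enrichment,max_upstream TSS-calling thresholds
#'   (defaults 5, 3, 300).
#' @param dedup_window TSS redundancy window (default 5).
#' @param max_gap Operon gap rule (default 50).
#' @param upstream_len Promoter length (default 50).
#' @param spacer_range Motif spacer range (default 14--18).
#' @param srna_min_fold,srna_alpha,connect_frac,end_frac sRNA stage
#'   parameters (defaults 4, 0.05, 0.25, 0.1).
#' @param read_length Read length for the sRNA taper bound (default 36).
#' @param seed Seed recorded in output metadata (the pipeline itself is
#'   deterministic given its inputs).
#' @return A `run_config` list.
#' @export
run_config <- function(genome, annotation, ap_alignments, gp_alignments,
                       tap_plus_fwd, tap_plus_rev,
                       tap_minus_fwd, tap_minus_rev,
                       out_dir = "bdellotx_out",
                       expressed_threshold = 50, dominance_fold = 5,
                       min_reads = 5L, min_enrichment = 3.0,
                       max_upstream = 300L, dedup_window = 5L,
                       max_gap = 50L, upstream_len = 50L,
                       spacer_range = c(14L, 18L),
                       srna_min_fold = 4, srna_alpha = 0.05,
                       connect_frac = 0.25, end_frac = 0.1,
                       read_length = 36L, seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Point a run configuration at a written synthetic bundle
#'
#' @param dir Directory written by [write_synthetic_bundle()].
#' @param out_dir Output directory for the pipeline.
#' @param ... Further arguments to [run_config()].
#' @return A `run_config`.
#' @export
bundle_config <- function(dir, out_dir = file.path(dir, "out"), ...) {
  p <- function(f) file.path(dir, f)
  run_config(genome = p("genome.fasta"), annotation = p("annotation.gff3"),
             ap_alignments = p("alignments_ap.bed"),
             gp_alignments = p("alignments_gp.bed"),
             tap_plus_fwd = p("tap_plus_fwd.bedGraph"),
             tap_plus_rev = p("tap_plus_rev.bedGraph"),
             tap_minus_fwd = p("tap_minus_fwd.bedGraph"),
             tap_minus_rev = p("tap_minus_rev.bedGraph"),
             out_dir = out_dir, ...)
}

#' Read a gene annotation from GFF3
#'
#' Keeps `gene` features (or all features when none are typed `gene`) and
#' derives `gene_id` from the `gene_id`, `ID` or `Name` attribute, in that
#' order.
#'
#' @param path GFF3 path.
#' @return A [GenomicRanges::GRanges] with a `gene_id` column.
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  if ("type" %in% names(mc) && any(mc$type == "gene"))
    gr <- gr[mc$type == "gene"]
  mc <- S4Vectors::mcols(gr)
  id <- NULL
  for (f in c("gene_id", "ID", "Name"))
    if (is.null(id) && f %in% names(mc)) id <- as.character(mc[[f]])
  if (is.null(id)) id <- sprintf("gene%05d", seq_along(gr))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(gene_id = id)
  gr
}

#' Read a BED6 alignment file
#'
#' @param path BED path.
#' @param genome_length Optional genome length to set as seqlengths.
#' @return A [GenomicRanges::GRanges].
#' @export
read_alignments <- function(path, genome_length = NULL) {
  gr <- rtracklayer::import(path, format = "bed")
  if (!is.null(genome_length) && length(GenomeInfoDb::seqlevels(gr)))
    GenomeInfoDb::seqlengths(gr) <-
      stats::setNames(as.integer(genome_length),
                      GenomeInfoDb::seqlevels(gr)[1])
  gr
}

# Metadata header written atop every output table.
meta_header <- function(cfg, extra = character()) {
  cfg_flat <- vapply(cfg[setdiff(names(cfg), "out_dir")],
                     function(x) paste(format(x), collapse = ","),
                     character(1))
  tf <- tempfile(); on.exit(unlink(tf))
  writeLines(paste(names(cfg_flat), cfg_flat, sep = "="), tf)
  hash <- unname(tools::md5sum(tf))
  c(sprintf("# bdellotx %s", as.character(utils::packageVersion("bdellotx"))),
    sprintf("# config_md5=%s seed=%s", hash, cfg$seed),
    extra)
}

write_table_with_meta <- function(df, path, cfg, extra = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta_header(cfg, extra), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline output table, skipping metadata headers
#' @param path TSV path written by [run_all()].
#' @return A data frame.
#' @export
read_stage_table <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Run the full transcriptome-dissection pipeline
#'
#' Executes expression calling, TSS/promoter mapping, motif discovery and
#' sRNA discovery against files on disk, writing per-stage TSVs (with
#' metadata headers), a program-summary JSON, per-base coverage bedGraphs,
#' the motif in MEME format and a static HTML report. Fails fast: a stage
#' error aborts the run before later stages execute.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with each stage's in-memory result
#'   (`expression`, `summary`, `tss`, `promoters`, `motif`, `prevalence`,
#'   `srna`, `paths`).
#' @export
run_all <- function(config) {
  cfg <- config
  for (f in c("genome", "annotation", "ap_alignments", "gp_alignments",
              "tap_plus_fwd", "tap_plus_rev", "tap_minus_fwd",
              "tap_minus_rev")) {
    if (!file.exists(cfg[[f]]))
      abort("missing input file for stage setup: %s (%s)", cfg[[f]], f)
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(cfg$out_dir, f)

  genome <- Biostrings::readDNAStringSet(cfg$genome)
  names(genome) <- sub("\\s.*", "", names(genome))
  L <- Biostrings::width(genome)[1]
  annotation <- read_annotation(cfg$annotation)
  if (length(annotation) == 0L)
    abort("expression stage: annotation %s contains no genes", cfg$annotation)
  ap <- read_alignments(cfg$ap_alignments, L)
  gp <- read_alignments(cfg$gp_alignments, L)
  tap_plus <- read_five_prime_track(cfg$tap_plus_fwd, cfg$tap_plus_rev,
                                    "TAP_plus")
  tap_minus <- read_five_prime_track(cfg$tap_minus_fwd, cfg$tap_minus_rev,
                                     "TAP_minus")

  ## --- expression stage
  message("[expression] counting reads for ", length(annotation), " genes")
  expr <- expression_table(ap, gp, annotation,
                           expressed_threshold = cfg$expressed_threshold,
                           fold = cfg$dominance_fold)
  write_table_with_meta(expr, p("expression.tsv"), cfg,
                        sprintf("# n_tests=%d", attr(expr, "n_tests")))
  summ <- program_summary(expr)
  jsonlite::write_json(summ, p("program_summary.json"), auto_unbox = TRUE,
                       digits = NA)

  ## --- coverage tracks
  cov_ap <- coverage_vector(ap, L)
  cov_gp <- coverage_vector(gp, L)
  write_coverage_bedgraph(cov_ap, p("coverage_ap.bedGraph"))
  write_coverage_bedgraph(cov_gp, p("coverage_gp.bedGraph"))

  ## --- TSS stage
  message("[tss] calling TSSs")
  calls <- call_tss(tap_plus, tap_minus, annotation,
                    min_reads = cfg$min_reads,
                    min_enrichment = cfg$min_enrichment,
                    max_upstream = cfg$max_upstream)
  calls <- deduplicate_tss(calls, cfg$dedup_window)
  # curation surrogate: drop calls whose first assigned gene is unexpressed
  first_gene <- vapply(strsplit(calls$assigned_genes, ","), `[`, "", 1)
  expressed_any <- expr$gene_id[expr$category != "silent"]
  calls <- calls[first_gene %in% expressed_any, , drop = FALSE]
  calls <- assign_operons(calls, annotation, cov_ap, cfg$max_gap)
  promoters <- extract_promoters(calls, genome, cfg$upstream_len)
  keep <- paste0(calls$position, calls$strand) %in% names(promoters)
  calls <- calls[keep, , drop = FALSE]

  ## --- motif stage on AP-specific promoters
  ap_categories <- c("AP_only", "AP_dominant")
  first_gene <- vapply(strsplit(calls$assigned_genes, ","), `[`, "", 1)
  ap_cat <- expr$category[match(first_gene, expr$gene_id)]
  is_ap <- !is.na(ap_cat) & ap_cat %in% ap_categories
  ap_promoters <- promoters[is_ap]
  message("[motif] ", length(ap_promoters), " AP-specific promoters")
  motif <- if (length(ap_promoters) >= 20L) {
    discover_motif(ap_promoters, spacer_range = cfg$spacer_range)
  } else no_motif()
  prevalence <- NULL
  motif_hit <- rep(NA, nrow(calls))
  if (motif$found) {
    write_meme(motif, p("motif.meme"))
    prevalence <- motif_prevalence(ap_promoters, motif)
    motif_hit <- vapply(promoters, function(x)
      !is.null(scan_motif(x, motif)), logical(1))
  }
  tss_tab <- cbind(calls, promoter = unname(promoters),
                   motif_hit = unname(motif_hit))
  write_table_with_meta(tss_tab, p("tss.tsv"), cfg)
  write_tss_bed(calls, p("tss.bed"), L)

  ## --- sRNA stage
  message("[srna] screening intergenic regions")
  free_calls <- deduplicate_tss(call_tss(tap_plus, tap_minus, NULL,
                                         min_reads = cfg$min_reads,
                                         min_enrichment = cfg$min_enrichment),
                                cfg$dedup_window)
  srna <- discover_srnas(annotation, genome, ap, gp, free_calls,
                         motif = if (motif$found) motif else NULL,
                         expressed_ap = expr$gene_id[expr$expressed_ap],
                         min_fold = cfg$srna_min_fold,
                         alpha = cfg$srna_alpha,
                         connect_frac = cfg$connect_frac,
                         end_frac = cfg$end_frac,
                         read_length = cfg$read_length)
  write_table_with_meta(srna, p("srna.tsv"), cfg)
  write_srna_outputs(srna, genome, p("srna.bed"), p("srna.fasta"), L)

  write_html_report(p("report.html"), expr, summ, calls, motif, prevalence,
                    srna, cov_ap, cov_gp, annotation)

  invisible(list(expression = expr, summary = summ, tss = tss_tab,
                 promoters = promoters, motif = motif,
                 prevalence = prevalence, srna = srna,
                 paths = cfg$out_dir))
}

write_coverage_bedgraph <- function(cov, path) {
  r <- rle(cov)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values > 0
  gr <- GenomicRanges::GRanges(
    seqnames = rep(SEQNAME, sum(keep)),
    ranges = IRanges::IRanges(starts[keep], ends[keep]),
    score = as.numeric(r$values[keep]))
  GenomeInfoDb::seqlengths(gr) <- stats::setNames(length(cov), SEQNAME)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

write_tss_bed <- function(calls, path, genome_length) {
  gr <- GenomicRanges::GRanges(
    seqnames = rep(SEQNAME, nrow(calls)),
    ranges = IRanges::IRanges(calls$position, width = 1L),
    strand = calls$strand,
    name = sprintf("TSS%04d", seq_len(nrow(calls))),
    score = pmin(1000L, calls$raw_plus))
  GenomeInfoDb::seqlengths(gr) <- stats::setNames(as.integer(genome_length),
                                                    SEQNAME)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

write_srna_outputs <- function(srna, genome, bed_path, fasta_path,
                               genome_length) {
  emitted <- srna[!srna$orf_filtered, , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = rep(SEQNAME, nrow(emitted)),
    ranges = IRanges::IRanges(emitted$start, emitted$end),
    strand = emitted$strand,
    name = emitted$name, score = pmin(1000L, as.integer(emitted$fold_rounded)))
  GenomeInfoDb::seqlengths(gr) <- stats::setNames(as.integer(genome_length),
                                                    SEQNAME)
  rtracklayer::export(gr, bed_path, format = "bed")
  seqs <- vapply(seq_len(nrow(emitted)), function(i) {
    s <- as.character(Biostrings::subseq(genome[[1]], emitted$start[i],
                                         emitted$end[i]))
    if (emitted$strand[i] == "-") revcomp_chr(s) else s
  }, character(1))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(seqs, emitted$name)), fasta_path)
  invisible(bed_path)
}

# Static HTML report: category summary, per-gene AP/GP expression track
# (compact inline bars emulating a browser view), TSS and sRNA tables.
write_html_report <- function(path, expr, summ, calls, motif, prevalence,
                              srna, cov_ap, cov_gp, annotation) {
  esc <- function(x) gsub("<", "&lt;", gsub("&", "&amp;", as.character(x)))
  tab <- function(df, n = Inf) {
    df <- utils::head(df, n)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) signif(x, 4))
    paste0("<table border='1' cellspacing='0' cellpadding='3'><tr>",
           paste0("<th>", esc(names(df)), "</th>", collapse = ""), "</tr>",
           paste(apply(df, 1, function(r) paste0(
             "<tr>", paste0("<td>", esc(r), "</td>", collapse = ""),
             "</tr>")), collapse = "\n"),
           "</table>")
  }
  bar <- function(v, col) {
    h <- round(40 * pmin(1, log10(1 + v) / 6))
    paste0("<span style='display:inline-block;width:3px;height:",
           h + 1, "px;background:", col, ";vertical-align:bottom'></span>",
           collapse = "")
  }
  expr_track <- paste0(
    "<div><b>AP</b><br>", bar(expr$rpkm_ap, "#c0392b"),
    "<br><b>GP</b><br>", bar(expr$rpkm_gp, "#2980b9"),
    "<br><small>one bar per gene, genome order; bar height ~ log10 RPKM</small></div>")
  motif_html <- if (motif$found) {
    cons <- motif_consensus(motif)
    sprintf("<p>Two-box element: <code>%s</code>-N%d-<code>%s</code>; %d/%d AP promoters carry it (%d%%).</p>",
            cons$box35, cons$modal_spacer, cons$box10,
            prevalence$n_hit, prevalence$n_total, prevalence$percent)
  } else "<p>No two-box element detected.</p>"
  cnt <- summ$counts
  html <- c(
    "<!DOCTYPE html><html><head><meta charset='utf-8'>",
    "<title>bdellotx report</title></head><body>",
    "<h1>Attack/growth phase transcriptome report</h1>",
    "<h2>Expression programs</h2>",
    tab(data.frame(category = names(cnt), genes = as.integer(cnt),
                   percent_of_expressed =
                     as.integer(summ$percent_of_expressed))),
    sprintf("<p>%d genes; %d expressed in at least one phase.</p>",
            summ$total_genes, summ$total_expressed),
    "<h2>Per-gene expression (AP vs GP)</h2>", expr_track,
    "<h2>Promoter element</h2>", motif_html,
    sprintf("<h2>TSS calls (%d)</h2>", nrow(calls)), tab(calls, 200),
    sprintf("<h2>Intergenic sRNAs (%d emitted)</h2>",
            sum(!srna$orf_filtered)),
    tab(srna),
    "</body></html>")
  writeLines(html, path)
  invisible(path)
}
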