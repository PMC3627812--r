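BASES <- c("A", "C", "G", "T")

# Promoter set as a character matrix (rows = promoters).
promoter_matrix <- function(promoters) {
  do.call(rbind, strsplit(toupper(promoters), ""))
}

# Laplace-smoothed background base composition of a promoter set.
promoter_background <- function(promoters) {
  chars <- unlist(strsplit(toupper(promoters), ""))
  cnt <- table(factor(chars, levels = BASES))
  stats::setNames(as.numeric(cnt + 1) / (sum(cnt) + 4), BASES)
}

# Position-weight matrix (4 x width) from aligned instance strings,
# pseudocount per base per column.
build_pwm <- function(instances, width, pseudocount = 0.5) {
  m <- promoter_matrix(instances)
  pwm <- sapply(seq_len(width), function(j) {
    cnt <- table(factor(m[, j], levels = BASES))
    (as.numeric(cnt) + pseudocount) / (nrow(m) + 4 * pseudocount)
  })
  rownames(pwm) <- BASES
  pwm
}

new_two_box_motif <- function(pwm35, pwm10, spacer_weights, score_threshold,
                              background) {
  structure(list(found = TRUE, pwm35 = pwm35, pwm10 = pwm10,
                 spacer_min = min(as.integer(names(spacer_weights))),
                 spacer_max = max(as.integer(names(spacer_weights))),
                 spacer_weights = spacer_weights,
                 score_threshold = score_threshold,
                 background = background),
            class = "two_box_motif")
}

#' An explicit "no motif found" result
#' @return A `two_box_motif` object with `found = FALSE`.
#' @export
no_motif <- function() structure(list(found = FALSE), class = "two_box_motif")

#' @export
print.two_box_motif <- function(x, ...) {
  if (!x$found) {
    cat("two_box_motif: no motif found\n")
    return(invisible(x))
  }
  cat(sprintf("two_box_motif: %s-N[%d-%d]-%s (modal spacer %s), threshold %.2f bits\n",
              consensus_string(x$pwm35), x$spacer_min, x$spacer_max,
              consensus_string(x$pwm10),
              names(which.max(x$spacer_weights))[1], x$score_threshold))
  invisible(x)
}

consensus_string <- function(pwm) {
  paste(rownames(pwm)[apply(pwm, 2, which.max)], collapse = "")
}

#' Consensus words of a two-box motif
#'
#' @param motif A `two_box_motif`.
#' @return A list with `box35`, `box10` (argmax-per-column consensus strings)
#'   and `modal_spacer` (integer).
#' @export
motif_consensus <- function(motif) {
  if (!motif$found) return(list(box35 = NA, box10 = NA, modal_spacer = NA))
  list(box35 = consensus_string(motif$pwm35),
       box10 = consensus_string(motif$pwm10),
       modal_spacer = as.integer(names(which.max(motif$spacer_weights))[1]))
}

# Best placement of the model in one promoter (char vector), exhaustive over
# (offset_35, spacer). Returns list(score, offset_35, offset_10, spacer) with
# ties broken toward smallest offset_35 then smallest spacer.
best_placement <- function(chars, pwm35, pwm10, spacer_weights, background) {
  P <- length(chars)
  w35 <- ncol(pwm35); w10 <- ncol(pwm10)
  spacers <- as.integer(names(spacer_weights))
  best <- NULL
  for (o in 0:(P - w35 - min(spacers) - w10)) {
    for (s in spacers) {
      o10 <- o + w35 + s
      if (o10 + w10 > P) next
      b35 <- chars[(o + 1):(o + w35)]
      b10 <- chars[(o10 + 1):(o10 + w10)]
      if (!all(c(b35, b10) %in% BASES)) next
      sc <- sum(log2(pwm35[cbind(match(b35, BASES), seq_len(w35))] /
                       background[b35])) +
        sum(log2(pwm10[cbind(match(b10, BASES), seq_len(w10))] /
                   background[b10])) +
        log2(spacer_weights[[as.character(s)]])
      if (is.null(best) || sc > best$score)
        best <- list(score = sc, offset_35 = o, offset_10 = o10, spacer = s)
    }
  }
  best
}

#' Discover a two-box sigma-factor-like promoter element
#'
#' Seeding is exhaustive over gapped words present in the data: every
#' (5-mer, spacer, 6-mer) triple occurring exactly in at least two promoters
#' is scored for mismatch-tolerant support (promoters containing the gapped
#' word with at most one total mismatch); triples reaching the 10% support
#' floor are ranked by enrichment over the expectation under the promoter
#' set's own base composition. The top seed is refined by iterative
#' realignment: the best-scoring placement per promoter (zero or one
#' occurrence; promoters scoring below 0 bits are skipped) rebuilds the
#' position-weight matrices (pseudocount 0.5) and the spacer-length
#' distribution, until assignments stabilize or `n_iter` is reached. The
#' final `score_threshold` is the 5th percentile of retained promoter scores.
#'
#' Discovery is deterministic: seeding is exhaustive and ties are broken
#' lexicographically.
#'
#' @param promoters Character vector of equal-length (50-base) promoter
#'   sequences, oriented 5' to 3'; at least 20 are required.
#' @param w35,w10 Box widths (defaults 5 and 6).
#' @param spacer_range Allowed spacer lengths (default 14--18).
#' @param n_iter Maximum refinement iterations (default 20).
#' @param support_floor Minimum fraction of promoters supporting a seed
#'   (default 0.10).
#' @return A `two_box_motif`, or [no_motif()] when no seed reaches the
#'   support floor.
#' @export
discover_motif <- function(promoters, w35 = 5L, w10 = 6L,
                           spacer_range = c(14L, 18L), n_iter = 20L,
                           support_floor = 0.10) {
  promoters <- toupper(promoters)
  N <- length(promoters)
  if (N < 20L) abort("motif discovery requires at least 20 promoters (got %d)", N)
  P <- unique(nchar(promoters))
  if (length(P) != 1L) abort("promoters must all have the same length")
  spacers <- seq(spacer_range[1], spacer_range[2])
  if (P < w35 + min(spacers) + w10)
    abort("promoters too short for the requested box/spacer geometry")
  bg <- promoter_background(promoters)
  pset <- Biostrings::DNAStringSet(promoters)

  ## --- exact gapped-word enumeration
  keys_by_prom <- lapply(promoters, function(pr) {
    out <- character(0)
    for (s in spacers) {
      n_off <- P - (w35 + s + w10) + 1L
      if (n_off < 1L) next
      for (o in seq_len(n_off)) {
        k <- paste(substr(pr, o, o + w35 - 1L), s,
                   substr(pr, o + w35 + s, o + w35 + s + w10 - 1L), sep = "|")
        out <- c(out, k)
      }
    }
    unique(out)
  })
  tab <- table(unlist(keys_by_prom))
  cand <- names(tab)[tab >= 2L]
  cand <- cand[!grepl("[^ACGT0-9|]", cand)]
  if (!length(cand)) return(no_motif())

  ## --- mismatch-tolerant support and background enrichment
  support <- numeric(length(cand))
  enrich <- numeric(length(cand))
  for (i in seq_along(cand)) {
    parts <- strsplit(cand[i], "|", fixed = TRUE)[[1]]
    word35 <- parts[1]; s <- as.integer(parts[2]); word10 <- parts[3]
    pat <- paste0(word35, strrep("N", s), word10)
    hits <- Biostrings::vcountPattern(pat, pset, max.mismatch = 1,
                                      fixed = FALSE)
    support[i] <- mean(hits > 0)
    ch <- strsplit(paste0(word35, word10), "")[[1]]
    p_exact <- prod(bg[ch])
    p_le1 <- p_exact * (1 + sum((1 - bg[ch]) / bg[ch]))
    n_off <- P - (w35 + s + w10) + 1L
    exp_frac <- 1 - (1 - min(p_le1, 1))^n_off
    enrich[i] <- support[i] / max(exp_frac, 1e-12)
  }
  ok <- support >= support_floor
  if (!any(ok)) return(no_motif())
  cand <- cand[ok]; enrich <- enrich[ok]
  seed <- cand[order(-enrich, cand)][1]

  parts <- strsplit(seed, "|", fixed = TRUE)[[1]]
  pat <- paste0(parts[1], strrep("N", as.integer(parts[2])), parts[3])
  seed_spacer <- as.integer(parts[2])

  ## --- initial alignment from seed matches (<= 1 mismatch)
  assign <- data.frame(offset_35 = rep(NA_integer_, N),
                       spacer = NA_integer_, retained = FALSE)
  for (i in seq_len(N)) {
    m <- Biostrings::matchPattern(pat, pset[[i]], max.mismatch = 1,
                                  fixed = FALSE)
    if (length(m)) {
      assign$offset_35[i] <- Biostrings::start(m)[1] - 1L
      assign$spacer[i] <- seed_spacer
      assign$retained[i] <- TRUE
    }
  }
  if (!any(assign$retained)) return(no_motif())

  rebuild <- function(assign) {
    idx <- which(assign$retained)
    i35 <- substr(promoters[idx], assign$offset_35[idx] + 1L,
                  assign$offset_35[idx] + w35)
    o10 <- assign$offset_35[idx] + w35 + assign$spacer[idx]
    i10 <- substr(promoters[idx], o10 + 1L, o10 + w10)
    scnt <- table(factor(assign$spacer[idx], levels = spacers))
    sw <- (as.numeric(scnt) + 0.5) / (length(idx) + 0.5 * length(spacers))
    names(sw) <- spacers
    list(pwm35 = build_pwm(i35, w35), pwm10 = build_pwm(i10, w10),
         spacer_weights = sw)
  }

  model <- rebuild(assign)
  chars_list <- strsplit(promoters, "")
  scores <- rep(NA_real_, N)
  for (iter in seq_len(n_iter)) {
    new_assign <- assign
    for (i in seq_len(N)) {
      bp <- best_placement(chars_list[[i]], model$pwm35, model$pwm10,
                           model$spacer_weights, bg)
      if (!is.null(bp) && bp$score > 0) {
        new_assign$offset_35[i] <- bp$offset_35
        new_assign$spacer[i] <- bp$spacer
        new_assign$retained[i] <- TRUE
        scores[i] <- bp$score
      } else {
        new_assign$retained[i] <- FALSE
        scores[i] <- if (is.null(bp)) NA_real_ else bp$score
      }
    }
    if (!any(new_assign$retained)) return(no_motif())
    converged <- identical(new_assign, assign)
    assign <- new_assign
    model <- rebuild(assign)
    if (converged) break
  }
  ## --- phase polishing: the aligned element can converge one column out of
  ## phase (a shifted gapped word has near-identical support); try +-1 shifts
  ## of each box and keep the alignment with maximal information content
  total_ic <- function(m) {
    ic <- function(pwm) sum(apply(pwm, 2, function(p) {
      p <- p[p > 0]
      2 + sum(p * log2(p))
    }))
    ic(m$pwm35) + ic(m$pwm10)
  }
  best_cfg <- list(d35 = 0L, d10 = 0L, model = model, ic = total_ic(model))
  idx <- which(assign$retained)
  for (d35 in c(-1L, 0L, 1L)) for (d10 in c(-1L, 0L, 1L)) {
    if (d35 == 0L && d10 == 0L) next
    o35 <- assign$offset_35[idx] + d35
    sp <- assign$spacer[idx] - d35 + d10
    feasible <- o35 >= 0L & sp %in% spacers &
      (o35 + w35 + sp + w10) <= P
    if (mean(feasible) < 0.9) next
    sh_assign <- data.frame(offset_35 = rep(NA_integer_, N),
                            spacer = NA_integer_, retained = FALSE)
    sh_assign$offset_35[idx[feasible]] <- o35[feasible]
    sh_assign$spacer[idx[feasible]] <- sp[feasible]
    sh_assign$retained[idx[feasible]] <- TRUE
    m2 <- rebuild(sh_assign)
    ic2 <- total_ic(m2)
    if (ic2 > best_cfg$ic + 1e-9) best_cfg <- list(d35 = d35, d10 = d10,
                                                   model = m2, ic = ic2)
  }
  if (best_cfg$d35 != 0L || best_cfg$d10 != 0L) {
    model <- best_cfg$model
    # one final realignment under the polished model
    for (i in seq_len(N)) {
      bp <- best_placement(chars_list[[i]], model$pwm35, model$pwm10,
                           model$spacer_weights, bg)
      if (!is.null(bp) && bp$score > 0) {
        assign$offset_35[i] <- bp$offset_35
        assign$spacer[i] <- bp$spacer
        assign$retained[i] <- TRUE
        scores[i] <- bp$score
      } else {
        assign$retained[i] <- FALSE
        scores[i] <- if (is.null(bp)) NA_real_ else bp$score
      }
    }
    if (!any(assign$retained)) return(no_motif())
    model <- rebuild(assign)
  }

  # threshold from retained promoter scores under the *final* model
  final_scores <- vapply(which(assign$retained), function(i)
    best_placement(chars_list[[i]], model$pwm35, model$pwm10,
                   model$spacer_weights, bg)$score, numeric(1))
  thr <- stats::quantile(final_scores, 0.05, names = FALSE)
  motif <- new_two_box_motif(model$pwm35, model$pwm10, model$spacer_weights,
                             thr, bg)
  motif$n_promoters <- N
  motif$n_retained <- sum(assign$retained)
  motif
}

#' Scan one promoter with a two-box motif
#'
#' Evaluates the log-odds score (both boxes plus log2 spacer weight) at every
#' admissible `(offset_35, spacer)` pair and returns the maximal-scoring hit
#' if it reaches the motif's score threshold. Ties are broken toward the
#' smallest `offset_35`, then the smallest spacer. Scanning is single-strand:
#' promoters are pre-oriented 5' to 3'.
#'
#' @param promoter A single promoter sequence.
#' @param motif A `two_box_motif` from [discover_motif()].
#' @return A one-row data frame (`offset_35`, `offset_10`, `spacer`,
#'   `score`), or `NULL` when no placement reaches the threshold (or the
#'   motif is [no_motif()]).
#' @export
scan_motif <- function(promoter, motif) {
  if (!motif$found) return(NULL)
  chars <- strsplit(toupper(promoter), "")[[1]]
  if (length(chars) < ncol(motif$pwm35) + motif$spacer_min + ncol(motif$pwm10))
    abort("promoter shorter than the minimal motif span")
  bp <- best_placement(chars, motif$pwm35, motif$pwm10, motif$spacer_weights,
                       motif$background)
  if (is.null(bp) || bp$score < motif$score_threshold) return(NULL)
  data.frame(offset_35 = bp$offset_35, offset_10 = bp$offset_10,
             spacer = bp$spacer, score = bp$score)
}

#' Fraction of promoters carrying the motif
#'
#' @param promoters Character vector of promoter sequences.
#' @param motif A `two_box_motif`.
#' @return A list with `n_hit`, `n_total`, `fraction` and `percent`
#'   (nearest-integer percent).
#' @export
motif_prevalence <- function(promoters, motif) {
  if (!length(promoters)) abort("no promoters supplied")
  hit <- vapply(promoters, function(p) !is.null(scan_motif(p, motif)),
                logical(1))
  n <- sum(hit)
  list(n_hit = n, n_total = length(promoters),
       fraction = n / length(promoters),
       percent = percent_of(n, length(promoters)))
}

#' Per-position information content of a motif
#'
#' Information content per column in bits, `2 + sum(p * log2(p))`, for both
#' boxes; the table is suitable for sequence-logo plotting.
#'
#' @param motif A `two_box_motif`.
#' @return A data frame with columns `box` (`"-35"`/`"-10"`), `position`
#'   (1-based within the box) and `bits`.
#' @export
logo_matrix <- function(motif) {
  if (!motif$found) abort("no motif to summarize")
  ic <- function(pwm) apply(pwm, 2, function(p) {
    p <- p[p > 0]
    2 + sum(p * log2(p))
  })
  rbind(data.frame(box = "-35", position = seq_len(ncol(motif$pwm35)),
                   bits = ic(motif$pwm35)),
        data.frame(box = "-10", position = seq_len(ncol(motif$pwm10)),
                   bits = ic(motif$pwm10)))
}

#' Serialize a motif as a minimal MEME-format text block with a JSON sidecar
#'
#' @param motif A `two_box_motif`.
#' @param path Output path for the MEME text; the sidecar is written next to
#'   it as `<path>.json` (spacer weights and score threshold).
#' @return Invisibly, the MEME path.
#' @export
write_meme <- function(motif, path) {
  if (!motif$found) abort("no motif to write")
  fmt_pwm <- function(pwm, name) {
    c(sprintf("MOTIF %s", name),
      sprintf("letter-probability matrix: alength= 4 w= %d", ncol(pwm)),
      apply(pwm, 2, function(p) paste(sprintf("%.6f", p), collapse = "  ")))
  }
  lines <- c("MEME version 4", "",
             "ALPHABET= ACGT", "",
             sprintf("Background letter frequencies"),
             paste(sprintf("%s %.6f", names(motif$background),
                           motif$background), collapse = " "), "",
             fmt_pwm(motif$pwm35, "box35"), "",
             fmt_pwm(motif$pwm10, "box10"))
  writeLines(lines, path)
  jsonlite::write_json(
    list(spacer_weights = as.list(motif$spacer_weights),
         score_threshold = motif$score_threshold),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
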