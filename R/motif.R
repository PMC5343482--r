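DNA <- c("A", "C", "G", "T")

#' Construct a position weight matrix object
#'
#' @param id motif identifier.
#' @param matrix 4 x L numeric matrix of per-position probabilities, rows
#'   A, C, G, T; each column must sum to 1 (within 1e-6).
#' @param is_shuffled_control flag for shuffled control motifs.
#' @return object of class `PWMotif`: list with `id`, `matrix`,
#'   `gc_content`, `is_shuffled_control`.
#' @export
pwmotif <- function(id, matrix, is_shuffled_control = FALSE) {
  stopifnot(is.matrix(matrix), nrow(matrix) == 4L)
  rownames(matrix) <- DNA
  sums <- colSums(matrix)
  if (any(abs(sums - 1) > 1e-6)) stop("PWM columns must sum to 1")
  structure(
    list(id = id, matrix = matrix,
         gc_content = mean(matrix["C", ] + matrix["G", ]),
         is_shuffled_control = isTRUE(is_shuffled_control)),
    class = "PWMotif"
  )
}

#' @export
print.PWMotif <- function(x, ...) {
  cat(sprintf("PWMotif %s: %d positions, GC %.3f%s\n", x$id,
              ncol(x$matrix), x$gc_content,
              if (x$is_shuffled_control) " (shuffled control)" else ""))
  invisible(x)
}

#' Build a PWM from aligned site sequences
#'
#' Column frequencies are computed from the provided equal-length site
#' sequences with a pseudo-count per matrix cell (default 0.5, i.e. a
#' pseudo-frequency of 0.5/n), which avoids log-odds infinities downstream.
#'
#' @param site_sequences character vector of equal-length DNA sequences.
#' @param id motif identifier.
#' @param pseudo_count count added to every cell before normalization; set
#'   to 0 for raw frequencies.
#' @return a `PWMotif`.
#' @export
pwm_from_sites <- function(site_sequences, id = "motif", pseudo_count = 0.5) {
  stopifnot(length(site_sequences) >= 1L)
  lens <- nchar(site_sequences)
  if (length(unique(lens)) != 1L) stop("site sequences differ in length")
  chars <- do.call(rbind, strsplit(toupper(site_sequences), ""))
  if (!all(chars %in% DNA)) stop("sequences contain non-ACGT characters")
  n <- nrow(chars)
  mat <- vapply(seq_len(ncol(chars)), function(j) {
    counts <- table(factor(chars[, j], levels = DNA))
    (as.numeric(counts) + pseudo_count) / (n + 4 * pseudo_count)
  }, numeric(4))
  rownames(mat) <- DNA
  pwmotif(id, mat)
}

reverse_complement_pwm <- function(mat) {
  mat[c("T", "G", "C", "A"), rev(seq_len(ncol(mat))), drop = FALSE]
}

encode_dna <- function(seq) {
  match(strsplit(toupper(seq), "")[[1]], DNA)
}

#' Scan sequences for PWM matches with exact background p-values
#'
#' A log-odds scanner over both strands: the match score at a position is
#' the summed log2 ratio of PWM probability to background mononucleotide
#' frequency. Match p-values come from the exact distribution of the score
#' under the background model, computed by dynamic programming over motif
#' positions on a discretized score grid (0.001-bit resolution).
#'
#' @param pwm a `PWMotif`.
#' @param genome_sequences named character vector of DNA sequences.
#' @param pvalue_threshold report matches with p at or below this value.
#' @param background length-4 background frequencies (A, C, G, T); default
#'   is the mononucleotide composition of `genome_sequences`.
#' @return data.frame with columns `seqname`, `position` (1-based start of
#'   the match on the forward strand), `strand`, `score`, `p`.
#' @export
scan_genome <- function(pwm, genome_sequences, pvalue_threshold = 1e-4,
                        background = NULL) {
  stopifnot(inherits(pwm, "PWMotif"), length(genome_sequences) >= 1L)
  if (is.null(names(genome_sequences))) {
    names(genome_sequences) <- paste0("seq", seq_along(genome_sequences))
  }
  codes <- lapply(genome_sequences, encode_dna)
  if (is.null(background)) {
    all_codes <- unlist(codes, use.names = FALSE)
    background <- tabulate(all_codes, 4L) / length(all_codes)
  }
  background <- pmax(background, 1e-9)
  L <- ncol(pwm$matrix)
  score_cap <- -20
  lo_fwd <- pmax(log2(pwm$matrix / background), score_cap)
  lo_rev <- pmax(log2(reverse_complement_pwm(pwm$matrix) / background),
                 score_cap)
  pfun <- score_pvalue_fun(lo_fwd, background)
  hits <- list()
  for (sn in names(codes)) {
    code <- codes[[sn]]
    if (length(code) < L) next
    np <- length(code) - L + 1L
    for (strand in c("+", "-")) {
      lo <- if (strand == "+") lo_fwd else lo_rev
      s <- numeric(np)
      for (j in seq_len(L)) {
        s <- s + lo[cbind(code[j:(j + np - 1L)], j)]
      }
      p <- pfun(s)
      keep <- which(p <= pvalue_threshold)
      if (length(keep)) {
        hits[[length(hits) + 1L]] <- data.frame(
          seqname = sn, position = keep, strand = strand,
          score = s[keep], p = p[keep], stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(seqname = character(), position = integer(),
                      strand = character(), score = numeric(),
                      p = numeric()))
  }
  out <- do.call(rbind, hits)
  out[order(out$seqname, out$position, out$strand), , drop = FALSE]
}

# Exact null distribution of the integer-discretized log-odds score by DP
# convolution over motif positions; returns a vectorized score -> upper-tail
# p-value function.
score_pvalue_fun <- function(log_odds, background, scale = 1000) {
  int_scores <- round(log_odds * scale)
  offsets <- apply(int_scores, 2, min)
  spans <- apply(int_scores, 2, max) - offsets
  pmf <- 1
  for (j in seq_len(ncol(int_scores))) {
    col <- int_scores[, j] - offsets[j]
    colpmf <- numeric(spans[j] + 1L)
    for (b in 1:4) {
      colpmf[col[b] + 1L] <- colpmf[col[b] + 1L] + background[b]
    }
    new_pmf <- numeric(length(pmf) + spans[j])
    nz <- which(colpmf > 0)
    for (k in nz) {
      idx <- seq_along(pmf) + (k - 1L)
      new_pmf[idx] <- new_pmf[idx] + pmf * colpmf[k]
    }
    pmf <- new_pmf
  }
  base <- sum(offsets)
  upper <- rev(cumsum(rev(pmf)))  # P(int score >= base + i - 1)
  function(s) {
    i <- round(s * scale) - base + 1L
    i <- pmin(pmax(i, 1L), length(upper))
    upper[i]
  }
}

#' Count-match motif candidates to a target map size
#'
#' Keeps the best-scoring matches up to the largest p-value cutoff that
#' yields at most `target_n` matches; candidates tied at a cutoff that
#' would overshoot the target are all dropped.
#'
#' @param candidates data.frame with a `p` column (e.g. from
#'   [scan_genome()]).
#' @param target_n the number of matches in the reference map to emulate.
#' @return the filtered data.frame.
#' @export
match_count_threshold <- function(candidates, target_n) {
  stopifnot(!is.null(candidates$p), target_n >= 0)
  if (target_n == 0L || !nrow(candidates)) {
    return(candidates[0, , drop = FALSE])
  }
  p_sorted <- sort(unique(candidates$p))
  counts <- vapply(p_sorted, function(pc) sum(candidates$p <= pc), numeric(1))
  ok <- which(counts <= target_n)
  if (!length(ok)) return(candidates[0, , drop = FALSE])
  cutoff <- p_sorted[max(ok)]
  candidates[candidates$p <= cutoff, , drop = FALSE]
}

#' Classify enhancer sensitivity from H3K27ac fold-changes
#'
#' Two rule sets are supported. With a single fold-change per enhancer
#' (`mode = "human"`, e.g. an unreplicated re-expression experiment),
#' sensitive means a change beyond 2-fold in the direction of interest and
#' insensitive means a fold-change within (1/1.5, 1.5). With replicate
#' pairs (`mode = "mef"`), sensitive means more than 2x reduction in each
#' replicate and more than 4x reduction on (geometric) average; insensitive
#' means less than 2x change in each replicate and less than 1.5-fold
#' change on average. Everything else is neither and excluded from
#' enrichment counts.
#'
#' @param fc1 fold-changes (condition of interest over reference).
#' @param fc2 second-replicate fold-changes (required for `mode = "mef"`).
#' @param mode `"mef"` (replicated, loss-oriented) or `"human"` (single
#'   comparison).
#' @param direction for `mode = "human"`: whether sensitivity means signal
#'   `"gain"` (fold-change > 2) or `"loss"` (fold-change < 1/2).
#' @return factor with levels sensitive, insensitive, neither.
#' @export
classify_enhancer_sensitivity <- function(fc1, fc2 = NULL,
                                          mode = c("mef", "human"),
                                          direction = c("gain", "loss")) {
  mode <- match.arg(mode)
  direction <- match.arg(direction)
  if (mode == "mef") {
    if (is.null(fc2)) stop("mode 'mef' requires fold-changes for both replicates")
    stopifnot(length(fc1) == length(fc2))
    gm <- sqrt(fc1 * fc2)
    sensitive <- fc1 < 0.5 & fc2 < 0.5 & gm < 0.25
    insensitive <- fc1 > 0.5 & fc1 < 2 & fc2 > 0.5 & fc2 < 2 &
      gm > 1 / 1.5 & gm < 1.5
  } else {
    sensitive <- if (direction == "gain") fc1 > 2 else fc1 < 0.5
    insensitive <- fc1 > 1 / 1.5 & fc1 < 1.5
  }
  cls <- rep("neither", length(fc1))
  cls[insensitive] <- "insensitive"
  cls[sensitive] <- "sensitive"
  factor(cls, levels = c("sensitive", "insensitive", "neither"))
}

#' Count motif occurrences inside a region set
#'
#' @param motif_map data.frame of motif occurrences with columns
#'   `motif_id`, `chrom`, `position`.
#' @param regions `GRanges` of regions.
#' @param motif_ids motifs to report (defaults to those present).
#' @return named integer vector of occurrence counts per motif.
#' @export
count_motif_occurrences <- function(motif_map, regions,
                                    motif_ids = unique(motif_map$motif_id)) {
  occ <- GenomicRanges::GRanges(motif_map$chrom,
                                IRanges::IRanges(motif_map$position,
                                                 width = 1L))
  inside <- IRanges::overlapsAny(occ, regions, ignore.strand = TRUE)
  counts <- table(factor(motif_map$motif_id[inside], levels = motif_ids))
  stats::setNames(as.integer(counts), motif_ids)
}

#' GC-corrected motif enrichment in sensitive versus insensitive enhancers
#'
#' Raw sensitive/insensitive count ratios are confounded by sequence
#' composition: GC-rich motifs track the GC content of the regions they
#' fall in. A lowess curve of the log count ratio (pseudocount 1 on both
#' counts) against motif GC content models this trend across all motifs;
#' the expected sensitive count per motif is its insensitive count times
#' the curve value at its GC, and enrichment is observed/expected.
#'
#' @param counts data.frame with columns `motif_id`, `gc`,
#'   `observed_sensitive`, `observed_insensitive` (one row per motif). Use
#'   [count_motif_occurrences()] on each region class to build it.
#' @param span lowess span.
#' @param iterations lowess robustness iterations.
#' @param pseudocount added to both counts before the log-ratio.
#' @param min_motifs minimum number of motifs with non-zero insensitive
#'   counts.
#' @return the input data.frame with added columns `expected_sensitive` and
#'   `enrichment`, sorted by decreasing enrichment.
#' @export
gc_corrected_enrichment <- function(counts, span = 0.3, iterations = 3L,
                                    pseudocount = 1, min_motifs = 20L) {
  required <- c("motif_id", "gc", "observed_sensitive", "observed_insensitive")
  stopifnot(all(required %in% names(counts)))
  if (all(counts$observed_sensitive == 0 & counts$observed_insensitive == 0)) {
    stop("all motif counts are zero")
  }
  if (sum(counts$observed_insensitive > 0) < min_motifs) {
    stop("need at least ", min_motifs,
         " motifs with non-zero insensitive counts")
  }
  lr <- log((counts$observed_sensitive + pseudocount) /
              (counts$observed_insensitive + pseudocount))
  lo <- stats::lowess(counts$gc, lr, f = span, iter = iterations)
  fit <- stats::approx(lo$x, lo$y, xout = counts$gc, rule = 2, ties = mean)$y
  counts$expected_sensitive <- counts$observed_insensitive * exp(fit)
  counts$enrichment <- ifelse(counts$expected_sensitive > 0,
                              counts$observed_sensitive /
                                counts$expected_sensitive, NA_real_)
  counts[order(-counts$enrichment), , drop = FALSE]
}

#' Motif similarity as the best-alignment Pearson correlation of PWMs
#'
#' The two matrices are compared over all ungapped column offsets up to
#' `max_offset` in both orientations (the second motif is also
#' reverse-complemented); unaligned columns are padded with the uniform
#' background 0.25. The reported similarity is the maximal Pearson
#' correlation of the flattened aligned matrices.
#'
#' @param pwm_a,pwm_b `PWMotif` objects.
#' @param max_offset largest column offset searched.
#' @return correlation in \[-1, 1\].
#' @export
motif_similarity <- function(pwm_a, pwm_b, max_offset = 3L) {
  a <- pwm_a$matrix
  best <- -1
  for (b in list(pwm_b$matrix, reverse_complement_pwm(pwm_b$matrix))) {
    for (off in -max_offset:max_offset) {
      la <- ncol(a); lb <- ncol(b)
      lo <- min(1L, 1L + off)
      hi <- max(la, lb + off)
      width <- hi - lo + 1L
      pa <- matrix(0.25, 4, width)
      pb <- matrix(0.25, 4, width)
      pa[, (1L - lo + 1L):(1L - lo + la)] <- a
      pb[, (1L + off - lo + 1L):(1L + off - lo + lb)] <- b
      r <- suppressWarnings(stats::cor(as.vector(pa), as.vector(pb)))
      if (!is.na(r) && r > best) best <- r
    }
  }
  best
}
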