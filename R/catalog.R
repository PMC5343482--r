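#' Define active TSSs as those overlapping an H3K4me3 RoE in any condition
#'
#' @param tss `GRanges` of width-1 TSS positions with a `gene_id` metadata
#'   column (see [read_tss_tsv()]).
#' @param h3k4me3_roe_sets list of `GRanges` of H3K4me3 regions of
#'   enrichment, one per condition (a single `GRanges` is accepted).
#' @return the subset of `tss` overlapping at least one RoE in at least one
#'   condition.
#' @export
active_tss <- function(tss, h3k4me3_roe_sets) {
  if (inherits(h3k4me3_roe_sets, "GRanges")) {
    h3k4me3_roe_sets <- list(h3k4me3_roe_sets)
  }
  hit <- Reduce(`|`, lapply(h3k4me3_roe_sets, function(g) {
    IRanges::overlapsAny(tss, g, ignore.strand = TRUE)
  }))
  tss[hit]
}

#' Read a TSS annotation table (chrom, tss_pos, strand, gene_id TSV)
#'
#' @param path 4-column TSV with header.
#' @return `GRanges` of width-1 TSS positions with `gene_id` metadata.
#' @export
read_tss_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$tss_pos, width = 1L),
                         strand = df$strand, gene_id = df$gene_id)
}

#' Classify H3K27ac regions into promoters, enhancers and ambiguous
#'
#' A region overlapping both an active TSS and an H3K4me3 RoE is a
#' promoter. A region more than 1 kb from any H3K4me3 RoE and more than
#' 2 kb from any active TSS is an enhancer. All other regions are
#' ambiguous and excluded from element-specific analyses. Distances are
#' minimal bp separations (0 when overlapping).
#'
#' @param h3k27ac_regions `GRanges` of reproducibility-filtered H3K27ac
#'   regions.
#' @param h3k4me3_roes `GRanges` union of H3K4me3 RoEs.
#' @param tss `GRanges` of active TSSs.
#' @param promoter_dist distance from an H3K4me3 RoE beyond which a region
#'   can be an enhancer (bp).
#' @param tss_dist distance from an active TSS beyond which a region can be
#'   an enhancer (bp).
#' @return the input `GRanges` with metadata columns `cre_class` (factor:
#'   promoter/enhancer/ambiguous), `dist_h3k4me3`, `dist_active_tss`.
#' @export
classify_elements <- function(h3k27ac_regions, h3k4me3_roes, tss,
                              promoter_dist = 1000L, tss_dist = 2000L) {
  n <- length(h3k27ac_regions)
  if (!length(tss)) {
    warning("empty active-TSS set: no promoters can be called")
  }
  dist_k4 <- distance_to_nearest(h3k27ac_regions, h3k4me3_roes)
  dist_tss <- distance_to_nearest(h3k27ac_regions, tss)
  is_promoter <- dist_tss == 0 & dist_k4 == 0
  is_enhancer <- dist_k4 > promoter_dist & dist_tss > tss_dist
  cls <- rep("ambiguous", n)
  cls[is_enhancer] <- "enhancer"
  cls[is_promoter] <- "promoter"
  out <- h3k27ac_regions
  S4Vectors::mcols(out)$cre_class <-
    factor(cls, levels = c("promoter", "enhancer", "ambiguous"))
  S4Vectors::mcols(out)$dist_h3k4me3 <- dist_k4
  S4Vectors::mcols(out)$dist_active_tss <- dist_tss
  out
}

distance_to_nearest <- function(query, subject) {
  d <- rep(Inf, length(query))
  if (!length(subject) || !length(query)) return(d)
  hits <- GenomicRanges::distanceToNearest(query, subject,
                                           ignore.strand = TRUE)
  d[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  d
}

#' Stitch H3K27ac RoEs into candidate super-enhancer regions
#'
#' RoEs within `gap` bp of each other (edge to edge, transitive closure,
#' i.e. single-linkage clustering) are stitched into one region.
#' TSS-proximal RoEs are deliberately kept; instead, the signal intervals
#' of each stitched region are its constituents minus all H3K4me3 RoEs, so
#' that promoter-driven signal does not inflate super-enhancer ranking.
#'
#' @param h3k27ac_roes `GRanges` of reproducibility-filtered H3K27ac RoEs.
#' @param h3k4me3_roes `GRanges` union of H3K4me3 RoEs used as the signal
#'   mask.
#' @param gap maximal stitching gap in bp.
#' @return `GRanges` of stitched regions with metadata columns
#'   `constituents` (IntegerList of input indices) and `signal_intervals`
#'   (GRangesList of mask-subtracted intervals).
#' @export
stitch_enhancers <- function(h3k27ac_roes, h3k4me3_roes = NULL,
                             gap = 12500L) {
  roes <- GenomicRanges::granges(h3k27ac_roes)
  stitched <- GenomicRanges::reduce(roes, min.gapwidth = gap + 1L)
  hits <- GenomicRanges::findOverlaps(roes, stitched)
  constituents <- S4Vectors::splitAsList(S4Vectors::queryHits(hits),
                                       S4Vectors::subjectHits(hits))
  mask <- if (is.null(h3k4me3_roes)) {
    GenomicRanges::GRanges()
  } else {
    GenomicRanges::reduce(GenomicRanges::granges(h3k4me3_roes))
  }
  signal_ivs <- lapply(seq_along(stitched), function(i) {
    cons <- GenomicRanges::reduce(roes[constituents[[i]]])
    GenomicRanges::setdiff(cons, mask, ignore.strand = TRUE)
  })
  S4Vectors::mcols(stitched)$constituents <- constituents
  S4Vectors::mcols(stitched)$signal_intervals <-
    GenomicRanges::GRangesList(signal_ivs)
  stitched
}

#' Flag super-enhancers among stitched regions by ranked-signal geometry
#'
#' Each stitched region's signal is the input-subtracted IP tag density
#' (reads per million, floored at zero) over its mask-subtracted signal
#' intervals. Regions are ranked by signal; with both axes scaled to
#' \[0, 1\], the cutoff is placed where the discrete slope of the ranked
#' curve first exceeds 1, and every region with signal strictly above the
#' cutoff signal is a super-enhancer. Regions whose signal intervals have
#' zero width are excluded from ranking.
#'
#' @param stitched `GRanges` from [stitch_enhancers()].
#' @param ip,input `TagLibrary` objects used for signal.
#' @return `stitched` with metadata columns `se_signal` (NA for excluded
#'   regions) and `is_super`.
#' @export
call_super_enhancers <- function(stitched, ip, input) {
  n <- length(stitched)
  sig <- rep(NA_real_, n)
  ivs <- S4Vectors::mcols(stitched)$signal_intervals
  widths <- vapply(seq_len(n), function(i) {
    sum(GenomicRanges::width(ivs[[i]]))
  }, numeric(1))
  usable <- widths > 0
  for (i in which(usable)) {
    ip_rpm <- sum(region_tag_counts(ip, ivs[[i]])) / (total_mapped(ip) / 1e6)
    in_rpm <- sum(region_tag_counts(input, ivs[[i]])) /
      (total_mapped(input) / 1e6)
    sig[i] <- max(ip_rpm - in_rpm, 0)
  }
  is_super <- rep(FALSE, n)
  if (sum(usable) < 3L) {
    warning("fewer than 3 rankable stitched regions; none flagged super")
  } else {
    s <- sort(sig[usable])
    cut <- rose_cutoff(s)
    if (!is.na(cut)) is_super <- !is.na(sig) & sig > cut
  }
  S4Vectors::mcols(stitched)$se_signal <- sig
  S4Vectors::mcols(stitched)$is_super <- is_super
  stitched
}

# Ranked-signal slope-1 cutoff: s must be sorted ascending. Returns the
# signal value at the first point where the [0,1]-scaled curve's discrete
# slope exceeds 1, or NA when no point does (e.g. all signals equal).
rose_cutoff <- function(s) {
  n <- length(s)
  if (n < 2L || max(s) <= 0) return(NA_real_)
  x <- seq_len(n) / n
  y <- s / max(s)
  slope <- diff(y) / diff(x)
  j <- which(slope > 1)
  if (!length(j)) return(NA_real_)
  s[min(j)]
}

#' Segment a genome track into transcribed and untranscribed regions
#'
#' Segmentation of paired case/control bin counts under a Bayesian
#' information criterion: each segment models its case counts as binomial
#' draws from the case+control totals, and the objective is
#' -2 logL + lambda * 2 * log(N) per breakpoint, where N is the total
#' number of reads (the binomial observations) and the factor 2 counts the
#' two quantities each breakpoint introduces, its location and a new
#' segment rate. The exact optimum is found by dynamic programming over
#' candidate breakpoints. A segment is transcribed when its library-size
#' normalized mean log2 enrichment of case over control exceeds
#' `min_log2`.
#'
#' @param case_counts,control_counts equal-length vectors of per-bin tag
#'   counts (e.g. PolII IP and input in 100 bp bins).
#' @param lambda breakpoint penalty multiplier.
#' @param min_log2 log2-enrichment threshold for the transcribed flag.
#' @param bin_size bin width in bp, used only to report coordinates.
#' @param max_lookback longest segment considered, in bins (bounds the
#'   quadratic dynamic program on long chromosomes).
#' @return data.frame with columns `start_bin`, `end_bin`, `start`, `end`,
#'   `case`, `control`, `mean_log2_enrichment`, `transcribed`.
#' @export
segment_transcription <- function(case_counts, control_counts, lambda = 1,
                                  min_log2 = 0.1, bin_size = 100L,
                                  max_lookback = 5000L) {
  stopifnot(length(case_counts) == length(control_counts))
  if (all(control_counts == 0)) stop("control count vector is all zero")
  n <- length(case_counts)
  x <- as.numeric(case_counts)
  y <- as.numeric(control_counts)
  cx <- c(0, cumsum(x))
  cy <- c(0, cumsum(y))
  seg_m2ll <- function(i, j) {
    # -2 log binomial likelihood of segments (i..j), vectorized over i
    X <- cx[j + 1] - cx[i]
    Y <- cy[j + 1] - cy[i]
    t <- X + Y
    ll <- numeric(length(X))
    pos <- X > 0
    ll[pos] <- ll[pos] + X[pos] * log(X[pos] / t[pos])
    pos <- Y > 0
    ll[pos] <- ll[pos] + Y[pos] * log(Y[pos] / t[pos])
    -2 * ll
  }
  penalty <- lambda * 2 * log(max(cx[n + 1] + cy[n + 1], 2))
  best <- c(0, rep(NA_real_, n))
  back <- integer(n)
  for (j in seq_len(n)) {
    i0 <- max(1L, j - max_lookback + 1L)
    i <- i0:j
    cand <- best[i] + seg_m2ll(i, j) + penalty
    cand[1] <- cand[1] - if (i0 == 1L) penalty else 0  # no breakpoint before bin 1
    # ties (within float tolerance) break toward the longer segment
    k <- which(cand <= min(cand) + 1e-9)[1]
    best[j + 1] <- cand[k]
    back[j] <- i[k]
  }
  starts <- integer(0)
  j <- n
  while (j > 0) {
    starts <- c(back[j], starts)
    j <- back[j] - 1L
  }
  heads <- starts
  ends <- c(heads[-1] - 1L, n)
  seg_x <- cx[ends + 1] - cx[heads]
  seg_y <- cy[ends + 1] - cy[heads]
  tx <- max(sum(x), 1)
  ty <- max(sum(y), 1)
  l2 <- log2(((seg_x + 0.5) / (seg_y + 0.5)) * (ty / tx))
  data.frame(
    start_bin = heads, end_bin = ends,
    start = (heads - 1L) * bin_size + 1L, end = ends * bin_size,
    case = seg_x, control = seg_y,
    mean_log2_enrichment = l2,
    transcribed = l2 > min_log2
  )
}
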