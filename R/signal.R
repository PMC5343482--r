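#' Per-region ChIP-seq signal: reads per million plus pseudocount
#'
#' Signal in a region is the number of tags falling inside it per million
#' mapped tags in the library, plus a pseudocount (default 1) that floors
#' every value and stabilizes ratios at low counts.
#'
#' @param lib a `TagLibrary` with at least one mapped tag.
#' @param regions a `GRanges` of regions; must lie within chromosome bounds.
#' @param pseudocount value added to every RPM.
#' @return numeric vector of signals, one per region.
#' @export
region_signal <- function(lib, regions, pseudocount = 1) {
  stopifnot(inherits(lib, "TagLibrary"))
  total <- total_mapped(lib)
  if (total == 0L) stop("library has no mapped tags")
  lens <- lib$chrom_lengths
  chr <- as.character(GenomicRanges::seqnames(regions))
  if (!all(chr %in% names(lens))) {
    stop("regions on chromosomes absent from the library")
  }
  if (any(GenomicRanges::start(regions) < 1L) ||
      any(GenomicRanges::end(regions) > lens[chr])) {
    stop("regions extend outside chromosome bounds")
  }
  counts <- region_tag_counts(lib, regions)
  counts / (total / 1e6) + pseudocount
}

region_tag_counts <- function(lib, regions) {
  counts <- numeric(length(regions))
  if (!nrow(lib$tags)) return(counts)
  tag_gr <- GenomicRanges::GRanges(
    lib$tags$chrom, IRanges::IRanges(lib$tags$pos, width = 1L))
  hits <- GenomicRanges::findOverlaps(tag_gr, regions, ignore.strand = TRUE)
  if (length(hits)) {
    agg <- rowsum(lib$tags$count[S4Vectors::queryHits(hits)],
                  S4Vectors::subjectHits(hits))
    counts[as.integer(rownames(agg))] <- agg[, 1]
  }
  counts
}

#' Signal enrichment: IP signal over input signal
#'
#' @param ip_signal,input_signal signal vectors from [region_signal()] over
#'   the same regions in the same order.
#' @return elementwise ratio; values above 1 indicate enrichment.
#' @export
signal_enrichment <- function(ip_signal, input_signal) {
  stopifnot(length(ip_signal) == length(input_signal))
  ip_signal / input_signal
}

#' Signal fold-change between two IP samples
#'
#' Fold-change compares IP signal between conditions directly; input signal
#' is deliberately not involved, because ratios of ratios inflate the
#' statistical variability. Optional per-sample multiplicative factors (from
#' [fit_ip_efficiency()]) correct for differential IP efficiency.
#'
#' @param signal_a,signal_b IP signal vectors over the same regions.
#' @param factor_a,factor_b multiplicative normalization factors.
#' @return elementwise (factor_a * signal_a) / (factor_b * signal_b).
#' @export
fold_change <- function(signal_a, signal_b, factor_a = 1, factor_b = 1) {
  stopifnot(length(signal_a) == length(signal_b))
  (factor_a * signal_a) / (factor_b * signal_b)
}

#' Fit IP-efficiency correction factors from promoter signal
#'
#' Chromatin-mark levels at the bulk of promoters are assumed unchanged
#' between conditions; any constant offset in promoter log fold-change
#' therefore reflects differential immunoprecipitation efficiency. For each
#' sample the mode of the log2 fold-change distribution at promoters versus
#' the reference sample is estimated by Gaussian kernel density (Silverman
#' bandwidth) evaluated on a 0.01 log2-unit grid over \[-3, 3\], and the
#' sample's factor is 2^(-mode), so that the corrected promoter mode is
#' zero. The reference sample's factor is 1.
#'
#' @param signal_matrix numeric matrix, regions x samples (named columns).
#' @param promoter_rows indices (or logical mask) of promoter rows.
#' @param reference column name or index of the reference sample.
#' @param min_promoters minimum number of promoter rows required.
#' @return object of class `NormalizationFactors`: list with `factors`
#'   (named numeric), `reference`, and `modes` diagnostics.
#' @export
fit_ip_efficiency <- function(signal_matrix, promoter_rows, reference = 1L,
                              min_promoters = 50L) {
  stopifnot(is.matrix(signal_matrix))
  prom <- signal_matrix[promoter_rows, , drop = FALSE]
  if (nrow(prom) < min_promoters) {
    stop("need at least ", min_promoters, " promoter rows, got ", nrow(prom))
  }
  if (is.character(reference)) {
    reference <- match(reference, colnames(signal_matrix))
  }
  samples <- colnames(signal_matrix)
  if (is.null(samples)) samples <- paste0("sample", seq_len(ncol(signal_matrix)))
  modes <- numeric(ncol(prom))
  for (s in seq_len(ncol(prom))) {
    if (s == reference) next
    l2 <- log2(prom[, s] / prom[, reference])
    modes[s] <- density_mode(l2)
  }
  factors <- 2^(-modes)
  names(factors) <- samples
  names(modes) <- samples
  structure(
    list(factors = factors, reference = samples[reference], modes = modes),
    class = "NormalizationFactors"
  )
}

density_mode <- function(x, from = -3, to = 3, n = 601L) {
  if (stats::sd(x) < .Machine$double.eps^0.5) {
    # degenerate distribution: the mode is the common value, snapped to grid
    grid <- seq(from, to, length.out = n)
    return(grid[which.min(abs(grid - x[1]))])
  }
  d <- stats::density(x, bw = "nrd0", from = from, to = to, n = n)
  d$x[which.max(d$y)]
}

#' @export
print.NormalizationFactors <- function(x, ...) {
  cat("IP-efficiency normalization factors (reference:", x$reference, ")\n")
  print(round(x$factors, 3))
  invisible(x)
}

#' Gaussian-smoothed genomic signal profile
#'
#' Tags are accumulated in `step`-bp bins and convolved with a Gaussian
#' kernel (truncated at four bandwidths), after library-size normalization
#' to tags per million. Values are per-bp smoothed tag densities.
#'
#' @param lib a `TagLibrary`.
#' @param sigma Gaussian bandwidth in bp.
#' @param step profile sampling step in bp (must not exceed `sigma`).
#' @return named list, one data.frame(`pos`, `value`) per chromosome, where
#'   `pos` is the bin center; attributes `step` and `sigma` are set.
#' @export
smooth_profile <- function(lib, sigma = 100, step = 10L) {
  stopifnot(inherits(lib, "TagLibrary"), step <= sigma)
  total <- total_mapped(lib)
  scale <- if (total > 0) 1e6 / total else 0
  kern <- stats::dnorm(seq(-4 * sigma, 4 * sigma, by = step), sd = sigma)
  half <- (length(kern) - 1L) %/% 2L
  lens <- lib$chrom_lengths
  out <- lapply(names(lens), function(chrom) {
    nb <- ceiling(lens[[chrom]] / step)
    counts <- window_counts(lib, chrom, step, nb)
    padded <- c(numeric(half), counts * scale, numeric(half))
    sm <- stats::filter(padded, kern, sides = 2)
    v <- as.numeric(sm[(half + 1L):(half + nb)])
    data.frame(pos = as.integer((seq_len(nb) - 1L) * step + step %/% 2L),
               value = v)
  })
  names(out) <- names(lens)
  attr(out, "step") <- as.integer(step)
  attr(out, "sigma") <- sigma
  out
}
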