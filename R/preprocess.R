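#' Blacklist anomalously high-signal genome bins from an input library
#'
#' Spurious high-signal regions are identified from an input (non-IP)
#' sample: the genome is tiled in `bin_size` bins and every bin whose tag
#' count exceeds mean + `k_sd` standard deviations of all genome bins
#' (zero-count bins included, population SD) is blacklisted.
#'
#' @param input_library a `TagLibrary` for an input sample.
#' @param bin_size bin width in bp.
#' @param k_sd number of standard deviations above the mean defining the
#'   threshold.
#' @return a `GRanges` of blacklisted intervals (unions of whole bins,
#'   adjacent bins merged), sorted and non-overlapping.
#' @export
build_blacklist <- function(input_library, bin_size = 1000L, k_sd = 3) {
  stopifnot(inherits(input_library, "TagLibrary"))
  lens <- input_library$chrom_lengths
  if (!nrow(input_library$tags)) {
    warning("empty input library; returning empty blacklist")
    return(GenomicRanges::GRanges(seqlengths = lens))
  }
  nbins <- ceiling(lens / bin_size)
  counts <- lapply(names(lens), function(chrom) {
    t <- input_library$tags[input_library$tags$chrom == chrom, ]
    b <- numeric(nbins[[chrom]])
    if (nrow(t)) {
      idx <- (t$pos - 1L) %/% bin_size + 1L
      agg <- rowsum(t$count, idx)
      b[as.integer(rownames(agg))] <- agg[, 1]
    }
    b
  })
  names(counts) <- names(lens)
  all_counts <- unlist(counts, use.names = FALSE)
  mu <- mean(all_counts)
  sdev <- sqrt(mean((all_counts - mu)^2))  # population SD: deterministic at any N
  thr <- mu + k_sd * sdev
  hits <- lapply(names(lens), function(chrom) {
    bad <- which(counts[[chrom]] > thr)
    if (!length(bad)) return(GenomicRanges::GRanges(seqlengths = lens))
    GenomicRanges::GRanges(
      seqnames = chrom,
      ranges = IRanges::IRanges(start = (bad - 1L) * bin_size + 1L,
                                end = pmin(bad * bin_size, lens[[chrom]])),
      seqlengths = lens
    )
  })
  GenomicRanges::reduce(do.call(c, hits))
}

#' Merge blacklists from several input samples into their union
#'
#' @param ... `GRanges` blacklists as returned by [build_blacklist()].
#' @return a single reduced `GRanges` union.
#' @export
merge_blacklists <- function(...) {
  args <- unname(list(...))
  if (length(args) == 1L && is.list(args[[1]])) args <- unname(args[[1]])
  GenomicRanges::reduce(do.call(c, args))
}

#' Library complexity: fraction of tags at unique (position, strand) pairs
#'
#' @param lib a `TagLibrary` with at least one tag.
#' @return proportion in (0, 1]: number of distinct strand-aware positions
#'   divided by the total number of mapped tags.
#' @export
library_complexity <- function(lib) {
  stopifnot(inherits(lib, "TagLibrary"))
  n <- total_mapped(lib)
  if (n == 0L) stop("library complexity undefined for an empty library")
  nrow(lib$tags) / n
}

#' Collapse duplicate tags to one per (position, strand)
#'
#' Applied by the pipeline only to sample batches whose library complexity
#' falls below the configured threshold (default 0.90).
#'
#' @param lib a `TagLibrary`.
#' @return a `TagLibrary` with every multiplicity capped at 1.
#' @export
deduplicate <- function(lib) {
  stopifnot(inherits(lib, "TagLibrary"))
  tags <- lib$tags
  tags$count <- rep(1L, nrow(tags))
  tag_library(tags, lib$chrom_lengths, lib$fragment_size)
}

#' Shift tags to fragment centers and remove blacklisted positions
#'
#' Each tag represents signal at half the fragment size from the read 5'
#' end: plus-strand tags move by +fragment_size/2 and minus-strand tags by
#' -fragment_size/2 (integer division, rounding toward zero). Shifted
#' positions are clamped to chromosome bounds; tags landing inside the
#' blacklist are discarded. Tags at the same shifted position are pooled.
#'
#' @param lib a `TagLibrary` with `fragment_size` set.
#' @param blacklist `GRanges` of excluded intervals (may be empty or NULL).
#' @return a shifted, masked `TagLibrary`.
#' @export
shift_and_mask <- function(lib, blacklist = NULL) {
  stopifnot(inherits(lib, "TagLibrary"))
  tags <- lib$tags
  if (nrow(tags)) {
    half <- lib$fragment_size %/% 2L
    shifted <- tags$pos + ifelse(tags$strand == "+", half, -half)
    lens <- lib$chrom_lengths[tags$chrom]
    tags$pos <- pmin(pmax(shifted, 1L), as.integer(lens))
    if (!is.null(blacklist) && length(blacklist)) {
      pos_gr <- GenomicRanges::GRanges(tags$chrom,
                                       IRanges::IRanges(tags$pos, width = 1L))
      keep <- !IRanges::overlapsAny(pos_gr, blacklist)
      tags <- tags[keep, , drop = FALSE]
    }
    if (nrow(tags)) {
      key <- paste(tags$chrom, tags$pos, tags$strand, sep = "\r")
      agg <- rowsum(tags$count, key)
      parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
      tags <- data.frame(
        chrom = vapply(parts, `[`, "", 1L),
        pos = as.integer(vapply(parts, `[`, "", 2L)),
        strand = vapply(parts, `[`, "", 3L),
        count = as.integer(agg[, 1]),
        stringsAsFactors = FALSE
      )
      tags <- tags[order(tags$chrom, tags$pos, tags$strand), , drop = FALSE]
      rownames(tags) <- NULL
    }
  }
  tag_library(tags, lib$chrom_lengths, lib$fragment_size)
}

#' Restrict a library to a chromosome whitelist
#'
#' @param lib a `TagLibrary`.
#' @param chroms chromosomes to keep (e.g. assembled autosomes).
#' @return a `TagLibrary` restricted to `chroms`.
#' @export
filter_chromosomes <- function(lib, chroms) {
  stopifnot(inherits(lib, "TagLibrary"))
  keep <- lib$tags$chrom %in% chroms
  tag_library(lib$tags[keep, , drop = FALSE],
              lib$chrom_lengths[names(lib$chrom_lengths) %in% chroms],
              lib$fragment_size)
}
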