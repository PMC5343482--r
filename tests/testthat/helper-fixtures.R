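# In-code fixtures shared across test files.

# Quick tag library: positions (1-based), one chromosome by default.
make_lib <- function(pos, strand = "+", count = 1L, chrom = "chr1",
                     len = 100000L, fragment_size = 160L) {
  n <- length(pos)
  tags <- data.frame(chrom = rep_len(chrom, n), pos = pos,
                     strand = rep_len(strand, n),
                     count = rep_len(count, n), stringsAsFactors = FALSE)
  chroms <- if (n) unique(tags$chrom) else chrom[1]
  lens <- stats::setNames(rep(len, length(chroms)), chroms)
  tag_library(tags, lens, fragment_size)
}

# A library whose 1 kb-bin counts equal `counts` (one tag row per non-zero
# bin placed at the bin start, multiplicity = count).
lib_from_bin_counts <- function(counts, bin_size = 1000L, chrom = "chr1") {
  nz <- which(counts > 0)
  make_lib(pos = (nz - 1L) * bin_size + 1L, count = counts[nz],
           chrom = chrom, len = length(counts) * bin_size)
}

gr <- function(chrom, start, end) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
}

# Brute-force single-linkage stitching oracle (edge-to-edge gap <= gap).
oracle_stitch <- function(starts, ends, gap) {
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  grp <- integer(length(starts)); g <- 0L; cur_end <- -Inf
  for (i in seq_along(starts)) {
    if (starts[i] - cur_end - 1L > gap) g <- g + 1L
    grp[i] <- g
    cur_end <- max(cur_end, ends[i])
  }
  data.frame(start = tapply(starts, grp, min),
             end = tapply(ends, grp, max))
}

# Synthetic PWM with target GC: two informative columns of the requested
# composition plus soft flanks, so gc_content is controllable.
pwm_with_gc <- function(id, gc, width = 6L) {
  stopifnot(gc >= 0, gc <= 1)
  col <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  m <- matrix(rep(col, width), nrow = 4,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  pwmotif(id, m)
}
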