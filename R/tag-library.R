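#' Tag library: strand-aware 5' tag positions for one ChIP-seq sample
#'
#' A `TagLibrary` holds the single-bp 5'-end positions of aligned reads
#' ("tags") for one sample, with per-position multiplicities, alongside the
#' chromosome lengths and the typical sequenced-fragment size of the library.
#' Positions are 1-based, as throughout the package.
#'
#' @param tags data.frame with columns `chrom` (character), `pos` (integer,
#'   1-based 5' position), `strand` (`"+"` or `"-"`) and `count`
#'   (multiplicity, >= 1).
#' @param chrom_lengths named integer vector of chromosome lengths (bp).
#' @param fragment_size typical sequenced-fragment size in bp; tags represent
#'   signal at half this distance from the 5' end.
#' @return An object of class `TagLibrary`: a list with elements `tags`,
#'   `chrom_lengths`, `fragment_size`.
#' @export
tag_library <- function(tags, chrom_lengths, fragment_size = 160L) {
  stopifnot(is.data.frame(tags))
  required <- c("chrom", "pos", "strand", "count")
  missing_cols <- setdiff(required, names(tags))
  if (length(missing_cols)) {
    stop("tag table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths)))) {
    stop("chrom_lengths must be a named vector")
  }
  tags <- data.frame(
    chrom = as.character(tags$chrom),
    pos = as.integer(tags$pos),
    strand = as.character(tags$strand),
    count = as.integer(tags$count),
    stringsAsFactors = FALSE
  )
  if (nrow(tags)) {
    if (!all(tags$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
    if (any(tags$count < 1L)) stop("multiplicities must be >= 1")
    unknown <- setdiff(unique(tags$chrom), names(chrom_lengths))
    if (length(unknown)) {
      stop("tags on chromosomes absent from chrom_lengths: ",
           paste(unknown, collapse = ", "))
    }
    lens <- chrom_lengths[tags$chrom]
    if (any(tags$pos < 1L) || any(tags$pos > lens)) {
      stop("tag positions outside chromosome bounds")
    }
  }
  structure(
    list(
      tags = tags,
      chrom_lengths = stats::setNames(as.integer(chrom_lengths),
                                      names(chrom_lengths)),
      fragment_size = as.integer(fragment_size)
    ),
    class = "TagLibrary"
  )
}

#' @export
print.TagLibrary <- function(x, ...) {
  cat(sprintf(
    "TagLibrary: %d tag positions, %d mapped tags, %d chromosome(s), fragment size %d bp\n",
    nrow(x$tags), total_mapped(x), length(x$chrom_lengths), x$fragment_size
  ))
  invisible(x)
}

#' Total number of mapped tags in a library
#'
#' @param lib a `TagLibrary`.
#' @return integer: the sum of tag multiplicities.
#' @export
total_mapped <- function(lib) {
  stopifnot(inherits(lib, "TagLibrary"))
  if (!nrow(lib$tags)) return(0L)
  sum(lib$tags$count)
}

#' Convert tag positions to a GRanges of width-1 signal positions
#'
#' @param lib a `TagLibrary`.
#' @return `GRanges` with one range per tag-table row and a `count` column.
#' @export
tags_as_granges <- function(lib) {
  stopifnot(inherits(lib, "TagLibrary"))
  gr <- GenomicRanges::GRanges(
    seqnames = lib$tags$chrom,
    ranges = IRanges::IRanges(start = lib$tags$pos, width = 1L),
    strand = lib$tags$strand,
    count = lib$tags$count,
    seqlengths = lib$chrom_lengths
  )
  gr
}

#' Read / write tag libraries as 4-column TSV
#'
#' The on-disk format is a plain TSV with header
#' `chrom  pos  strand  count`, one row per distinct (position, strand).
#'
#' @param path file path.
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param fragment_size fragment size recorded on the returned library.
#' @return `read_tag_tsv` returns a `TagLibrary`; `write_tag_tsv` returns
#'   `path` invisibly.
#' @export
read_tag_tsv <- function(path, chrom_lengths, fragment_size = 160L) {
  tags <- utils::read.table(path, header = TRUE, sep = "\t",
                            colClasses = c("character", "integer",
                                           "character", "integer"))
  tag_library(tags, chrom_lengths, fragment_size)
}

#' @param lib a `TagLibrary` to write.
#' @rdname read_tag_tsv
#' @export
write_tag_tsv <- function(lib, path) {
  stopifnot(inherits(lib, "TagLibrary"))
  utils::write.table(lib$tags, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
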