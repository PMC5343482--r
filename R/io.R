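#' Write genomic intervals as BED
#'
#' Converts 1-based closed `GRanges` to 0-based half-open BED. Metadata
#' columns named by `name_col` / `score_col` populate the BED name and score
#' fields when present.
#'
#' @param gr a `GRanges`.
#' @param path output file.
#' @param name_col,score_col optional metadata column names for BED fields
#'   4 and 5.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path, name_col = NULL, score_col = NULL) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  mc <- S4Vectors::mcols(gr)
  if (!is.null(name_col) && name_col %in% names(mc)) {
    df$name <- as.character(mc[[name_col]])
    if (!is.null(score_col) && score_col %in% names(mc)) {
      df$score <- mc[[score_col]]
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file into GRanges
#'
#' @param path BED file (0-based half-open); columns beyond the third are
#'   read into `name` and `score` metadata when present.
#' @return a `GRanges`.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  gr <- GenomicRanges::GRanges(
    seqnames = df[[1]],
    ranges = IRanges::IRanges(start = df[[2]] + 1L, end = df[[3]])
  )
  if (ncol(df) >= 4) S4Vectors::mcols(gr)$name <- df[[4]]
  if (ncol(df) >= 5) S4Vectors::mcols(gr)$score <- df[[5]]
  gr
}

#' Write a smoothed signal profile as bedGraph or fixed-step wiggle
#'
#' @param profile a profile as returned by [smooth_profile()]: a named list
#'   (one element per chromosome) of data.frames with columns `pos`, `value`,
#'   with attributes `step` and `sigma`.
#' @param path output file.
#' @param track_name track name written in the header line.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(profile, path, track_name = "signal") {
  step <- attr(profile, "step")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=\"%s\"", track_name), con)
  for (chrom in names(profile)) {
    p <- profile[[chrom]]
    df <- data.frame(chrom, p$pos - 1L, p$pos - 1L + step,
                     signif(p$value, 6))
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_bedgraph
#' @export
write_wig <- function(profile, path, track_name = "signal") {
  step <- attr(profile, "step")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=wiggle_0 name=\"%s\"", track_name), con)
  for (chrom in names(profile)) {
    p <- profile[[chrom]]
    writeLines(sprintf("fixedStep chrom=%s start=%d step=%d span=%d",
                       chrom, p$pos[1], step, step), con)
    writeLines(format(signif(p$value, 6), trim = TRUE, scientific = FALSE),
               con)
  }
  invisible(path)
}

#' Read and write position weight matrices in MEME minimal motif format
#'
#' @param path file path.
#' @param pwms list of `PWMotif` objects (see [pwm_from_sites()]).
#' @param background background letter frequencies written in the header.
#' @return `read_meme` returns a named list of `PWMotif`; `write_meme`
#'   returns `path` invisibly.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  motif_idx <- grep("^MOTIF\\b", lines)
  pwms <- list()
  for (i in seq_along(motif_idx)) {
    header <- strsplit(trimws(lines[motif_idx[i]]), "\\s+")[[1]]
    id <- header[2]
    j <- motif_idx[i] + 1L
    while (j <= length(lines) && !grepl("^letter-probability", lines[j])) {
      j <- j + 1L
    }
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[j]))
    rows <- lines[(j + 1L):(j + w)]
    mat <- t(vapply(strsplit(trimws(rows), "\\s+"),
                    function(x) as.numeric(x[1:4]), numeric(4)))
    m <- t(mat)  # 4 x w, rows A C G T
    rownames(m) <- c("A", "C", "G", "T")
    pwms[[id]] <- pwmotif(id, m,
                          is_shuffled_control = grepl("shuf", id,
                                                      ignore.case = TRUE))
  }
  pwms
}

#' @rdname read_meme
#' @export
write_meme <- function(pwms, path, background = rep(0.25, 4)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f", background[1],
                       background[2], background[3], background[4]), ""),
             con)
  for (p in pwms) {
    writeLines(sprintf("MOTIF %s", p$id), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
      ncol(p$matrix)), con)
    apply(p$matrix, 2, function(col) {
      writeLines(paste(sprintf("%.6f", col), collapse = "  "), con)
    })
    writeLines("", con)
  }
  invisible(path)
}
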