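#' Specification of a synthetic genome and ChIP experiment
#'
#' Defines the toy-genome layout and signal model used by the generators:
#' a Poisson tag background everywhere, TSS-proximal sites carrying both
#' H3K4me3 and H3K27ac, TSS-distal sites carrying H3K27ac only, a subset
#' of distal sites losing signal in mutant conditions, and per-sample
#' multiplicative IP-efficiency distortion of the enriched (pulled-down)
#' fragment fraction.
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_length chromosome length in bp; the total genome must be at
#'   least 10 times the summed site widths so sites can be placed without
#'   crowding.
#' @param n_promoter_sites,n_distal_sites numbers of TSS-proximal and
#'   TSS-distal enriched sites.
#' @param fraction_sensitive proportion of distal sites losing signal in
#'   mutant conditions.
#' @param sensitive_fold true mutant/WT signal ratio at sensitive sites
#'   (< 1).
#' @param background_rate background tag rate (tags per bp, Poisson mean).
#' @param enrichment_fold IP tag rate at enriched sites relative to
#'   background (> 1).
#' @param fragment_size sequenced-fragment size in bp; tags sit at half
#'   this distance from fragment centers.
#' @param site_width width of every enriched site in bp.
#' @param seed integer seed fixing the site layout and all downstream
#'   generator defaults.
#' @return object of class `SyntheticGenomeSpec`.
#' @export
synthetic_genome_spec <- function(n_chroms = 2L, chrom_length = 2e6,
                                  n_promoter_sites = 100L,
                                  n_distal_sites = 100L,
                                  fraction_sensitive = 0.3,
                                  sensitive_fold = 0.25,
                                  background_rate = 0.004,
                                  enrichment_fold = 25,
                                  fragment_size = 160L,
                                  site_width = 1000L,
                                  seed = 1L) {
  stopifnot(n_chroms >= 1L, n_promoter_sites >= 0L, n_distal_sites >= 0L,
            fraction_sensitive >= 0, fraction_sensitive <= 1,
            sensitive_fold > 0, sensitive_fold < 1)
  if (background_rate <= 0) stop("background_rate must be positive")
  if (enrichment_fold < 1) stop("enrichment_fold must be at least 1")
  n_sites <- n_promoter_sites + n_distal_sites
  if (n_sites > 0 && n_chroms * chrom_length < 10 * n_sites * site_width) {
    stop("genome too small: need chrom space >= 10 x total site width")
  }
  structure(
    list(n_chroms = as.integer(n_chroms), chrom_length = as.integer(chrom_length),
         n_promoter_sites = as.integer(n_promoter_sites),
         n_distal_sites = as.integer(n_distal_sites),
         fraction_sensitive = fraction_sensitive,
         sensitive_fold = sensitive_fold,
         background_rate = background_rate,
         enrichment_fold = enrichment_fold,
         fragment_size = as.integer(fragment_size),
         site_width = as.integer(site_width),
         seed = as.integer(seed)),
    class = "SyntheticGenomeSpec"
  )
}

spec_chrom_lengths <- function(spec) {
  stats::setNames(rep(spec$chrom_length, spec$n_chroms),
                  paste0("chr", seq_len(spec$n_chroms)))
}

#' Deterministic ground truth layout for a synthetic genome
#'
#' Places promoter and distal sites on an even grid (shuffled class
#' assignment), marks the sensitive distal subset, defines one TSS at each
#' promoter-site center, and designates one transcribed block per
#' chromosome (the third quarter) for the PolII mark.
#'
#' @param spec a `SyntheticGenomeSpec`.
#' @return object of class `GroundTruth`: list with `sites` (data.frame:
#'   chrom, start, end, class, sensitive, fold_change), `tss` (data.frame:
#'   chrom, tss_pos, strand, gene_id), `transcribed` (`GRanges`),
#'   `chrom_lengths`, and the originating `spec`.
#' @export
ground_truth <- function(spec) {
  stopifnot(inherits(spec, "SyntheticGenomeSpec"))
  lens <- spec_chrom_lengths(spec)
  n_sites <- spec$n_promoter_sites + spec$n_distal_sites
  withr::with_seed(spec$seed, {
    per_chrom <- diff(round(seq(0, n_sites, length.out = spec$n_chroms + 1)))
    classes <- sample(c(rep("promoter", spec$n_promoter_sites),
                        rep("distal", spec$n_distal_sites)))
    sites <- do.call(rbind, lapply(seq_len(spec$n_chroms), function(ci) {
      k <- per_chrom[ci]
      if (k == 0) return(NULL)
      spacing <- spec$chrom_length %/% (k + 1L)
      centers <- spacing * seq_len(k)
      data.frame(chrom = names(lens)[ci],
                 start = centers - spec$site_width %/% 2L + 1L,
                 end = centers + spec$site_width %/% 2L,
                 stringsAsFactors = FALSE)
    }))
    sites$class <- classes
    sites$sensitive <- FALSE
    distal_idx <- which(sites$class == "distal")
    n_sens <- round(spec$fraction_sensitive * length(distal_idx))
    if (n_sens > 0) {
      sites$sensitive[sample(distal_idx, n_sens)] <- TRUE
    }
    sites$fold_change <- ifelse(sites$sensitive, spec$sensitive_fold, 1)
    prom <- sites[sites$class == "promoter", , drop = FALSE]
    tss <- data.frame(
      chrom = prom$chrom,
      tss_pos = as.integer((prom$start + prom$end) %/% 2L),
      strand = rep_len(c("+", "-"), nrow(prom)),
      gene_id = sprintf("gene_%04d", seq_len(nrow(prom))),
      stringsAsFactors = FALSE
    )
    transcribed <- GenomicRanges::GRanges(
      seqnames = names(lens),
      ranges = IRanges::IRanges(start = lens %/% 2L + 1L,
                                end = lens %/% 2L + lens %/% 4L),
      seqlengths = lens
    )
    structure(
      list(sites = sites, tss = tss, transcribed = transcribed,
           chrom_lengths = lens, spec = spec),
      class = "GroundTruth"
    )
  })
}

#' Generate a synthetic tag library for one sample
#'
#' Background fragments arrive as a Poisson process at `background_rate`
#' per bp genome-wide. In IP samples, each enriched site receives extra
#' fragments so that its total tag rate is background x enrichment_fold x
#' condition fold-change x ip_efficiency: the IP-efficiency multiplier
#' thins only the pulled-down (enriched) fraction, leaving the background
#' admixture constant, which is exactly the distortion promoter-mode
#' normalization must invert. Input samples ignore enrichment entirely.
#' Every fragment yields one tag at +/- fragment_size/2 from its center on
#' a random strand.
#'
#' @param spec a `SyntheticGenomeSpec`.
#' @param condition condition label; any condition other than `"WT"`
#'   applies the sensitive-site fold-change.
#' @param sample_role `"IP"` or `"input"`.
#' @param mark which mark the sample assays: `"H3K27ac"` (all sites),
#'   `"H3K4me3"` (promoter sites only), or `"PolII"` (transcribed blocks).
#' @param ip_efficiency multiplicative efficiency of the pulldown (> 0).
#' @param truth optional precomputed [ground_truth()] for `spec`.
#' @param seed integer seed; same seed gives a bit-identical library.
#' @return a `TagLibrary`.
#' @export
generate_tag_library <- function(spec, condition = "WT",
                                 sample_role = c("IP", "input"),
                                 mark = c("H3K27ac", "H3K4me3", "PolII"),
                                 ip_efficiency = 1,
                                 truth = NULL, seed = spec$seed) {
  stopifnot(inherits(spec, "SyntheticGenomeSpec"))
  sample_role <- match.arg(sample_role)
  mark <- match.arg(mark)
  if (ip_efficiency <= 0) stop("ip_efficiency must be positive")
  if (is.null(truth)) truth <- ground_truth(spec)
  lens <- spec_chrom_lengths(spec)
  half <- spec$fragment_size %/% 2L
  withr::with_seed(seed, {
    parts <- list()
    for (chrom in names(lens)) {
      L <- lens[[chrom]]
      n_bg <- stats::rpois(1, spec$background_rate * L)
      centers <- floor(stats::runif(n_bg, 0, L)) + 1L
      parts[[length(parts) + 1L]] <-
        data.frame(chrom = chrom, center = centers)
    }
    if (sample_role == "IP") {
      targets <- switch(mark,
        H3K27ac = truth$sites,
        H3K4me3 = truth$sites[truth$sites$class == "promoter", , drop = FALSE],
        PolII = data.frame(
          chrom = as.character(GenomicRanges::seqnames(truth$transcribed)),
          start = GenomicRanges::start(truth$transcribed),
          end = GenomicRanges::end(truth$transcribed),
          class = "transcribed", sensitive = FALSE, fold_change = 1,
          stringsAsFactors = FALSE)
      )
      if (nrow(targets)) {
        fold <- if (mark == "H3K27ac" && condition != "WT") {
          targets$fold_change
        } else {
          rep(1, nrow(targets))
        }
        width <- targets$end - targets$start + 1L
        extra_rate <- spec$background_rate * width *
          pmax(spec$enrichment_fold * fold * ip_efficiency - 1, 0)
        n_extra <- stats::rpois(nrow(targets), extra_rate)
        idx <- rep.int(seq_len(nrow(targets)), n_extra)
        if (length(idx)) {
          centers <- targets$start[idx] +
            floor(stats::runif(length(idx), 0, width[idx]))
          parts[[length(parts) + 1L]] <-
            data.frame(chrom = targets$chrom[idx], center = centers)
        }
      }
    }
    frag <- do.call(rbind, parts)
    strand <- sample(c("+", "-"), nrow(frag), replace = TRUE)
    pos <- frag$center + ifelse(strand == "+", -half, half)
    pos <- pmin(pmax(pos, 1L), lens[frag$chrom])
    tags <- data.frame(chrom = frag$chrom, pos = as.integer(pos),
                       strand = strand, stringsAsFactors = FALSE)
    key <- paste(tags$chrom, tags$pos, tags$strand, sep = "\r")
    agg <- rowsum(rep(1L, nrow(tags)), key)
    p <- strsplit(rownames(agg), "\r", fixed = TRUE)
    tags <- data.frame(
      chrom = vapply(p, `[`, "", 1L),
      pos = as.integer(vapply(p, `[`, "", 2L)),
      strand = vapply(p, `[`, "", 3L),
      count = as.integer(agg[, 1]),
      stringsAsFactors = FALSE
    )
    tags <- tags[order(tags$chrom, tags$pos, tags$strand), , drop = FALSE]
    rownames(tags) <- NULL
    tag_library(tags, lens, spec$fragment_size)
  })
}

#' Generate a GC track and motif occurrence map with a GC confound
#'
#' Each distal ground-truth site receives a local GC content; when
#' `gc_confound_strength` is positive, sensitive sites are shifted toward
#' higher GC and motif placement rates couple the motif's own GC content
#' to the site's local GC, so that raw sensitive/insensitive count ratios
#' drift with motif GC, the artifact the lowess correction removes. At
#' strength 0 placement is uniform across sites. A motif can additionally
#' be planted at a multiplied density in sensitive sites.
#'
#' @param truth a [ground_truth()] object.
#' @param pwm_set non-empty named list of `PWMotif` objects.
#' @param gc_confound_strength confound strength (>= 0); 0 disables it.
#' @param occurrences_per_site baseline expected motif occurrences per site.
#' @param plant_motif,plant_fold optionally multiply one motif's placement
#'   rate in sensitive sites by `plant_fold`.
#' @param seed integer seed.
#' @return list with `sites` (data.frame: chrom, start, end, sensitive,
#'   gc), `gc_track` (the same intervals as a GRanges with a `gc` column),
#'   and `motif_map` (data.frame: motif_id, chrom, position).
#' @export
generate_motif_landscape <- function(truth, pwm_set,
                                     gc_confound_strength = 0,
                                     occurrences_per_site = 8,
                                     plant_motif = NULL, plant_fold = 1,
                                     seed = truth$spec$seed) {
  stopifnot(inherits(truth, "GroundTruth"))
  if (!length(pwm_set)) stop("pwm_set must be non-empty")
  if (is.null(names(pwm_set))) {
    names(pwm_set) <- vapply(pwm_set, `[[`, "", "id")
  }
  sites <- truth$sites[truth$sites$class == "distal", , drop = FALSE]
  if (!nrow(sites)) stop("ground truth has no distal sites")
  withr::with_seed(seed, {
    shift <- 0.04 * gc_confound_strength * ifelse(sites$sensitive, 1, -1)
    sites$gc <- pmin(pmax(stats::rnorm(nrow(sites), 0.5 + shift, 0.04),
                          0.2), 0.8)
    gc_m <- vapply(pwm_set, `[[`, numeric(1), "gc_content")
    beta <- 15 * gc_confound_strength
    rows <- list()
    for (m in names(pwm_set)) {
      rate <- occurrences_per_site *
        exp(beta * (gc_m[[m]] - 0.5) * (sites$gc - 0.5))
      if (!is.null(plant_motif) && m == plant_motif) {
        rate <- rate * ifelse(sites$sensitive, plant_fold, 1)
      }
      n <- stats::rpois(nrow(sites), rate)
      idx <- rep.int(seq_len(nrow(sites)), n)
      if (length(idx)) {
        rows[[length(rows) + 1L]] <- data.frame(
          motif_id = m, chrom = sites$chrom[idx],
          position = sites$start[idx] +
            floor(stats::runif(length(idx), 0,
                               sites$end[idx] - sites$start[idx] + 1L)),
          stringsAsFactors = FALSE
        )
      }
    }
    motif_map <- if (length(rows)) do.call(rbind, rows) else {
      data.frame(motif_id = character(), chrom = character(),
                 position = integer())
    }
    gc_track <- GenomicRanges::GRanges(
      sites$chrom, IRanges::IRanges(sites$start, sites$end),
      gc = sites$gc, seqlengths = truth$chrom_lengths
    )
    list(sites = sites, gc_track = gc_track, motif_map = motif_map)
  })
}

#' Generate a gene-level differential expression table coupled to enhancers
#'
#' Each distal site is assigned to its nearest gene TSS; a gene's true
#' mutant/WT log2 expression change is `coupling` times the mean log2
#' fold-change of its assigned enhancers (zero for genes with none).
#' Per-condition counts are negative-binomial around a lognormal baseline;
#' at `dispersion = 0` the counts equal their means exactly. The output
#' mimics a cuffdiff gene_exp.diff table.
#'
#' @param truth a [ground_truth()] object.
#' @param coupling scaling from enhancer log2 change to expression log2
#'   change.
#' @param dispersion negative-binomial dispersion (variance = mu +
#'   dispersion * mu^2); 0 gives noiseless means.
#' @param base_mean median baseline expression level.
#' @param n_reps replicates per condition used for the significance column.
#' @param seed integer seed.
#' @return data.frame with columns `gene_id`, `status`, `value_1` (WT),
#'   `value_2` (mutant), `log2_fold`, `fdr`; attribute `true_log2_change`
#'   carries the per-gene truth.
#' @export
generate_expression_table <- function(truth, coupling = 1, dispersion = 0.05,
                                      base_mean = 200, n_reps = 2L,
                                      seed = truth$spec$seed) {
  stopifnot(inherits(truth, "GroundTruth"))
  genes <- truth$tss
  distal <- truth$sites[truth$sites$class == "distal", , drop = FALSE]
  true_change <- stats::setNames(numeric(nrow(genes)), genes$gene_id)
  if (nrow(distal) && nrow(genes)) {
    site_gr <- GenomicRanges::GRanges(
      distal$chrom, IRanges::IRanges(distal$start, distal$end))
    tss_gr <- GenomicRanges::GRanges(
      genes$chrom, IRanges::IRanges(genes$tss_pos, width = 1L))
    hits <- GenomicRanges::distanceToNearest(site_gr, tss_gr,
                                             ignore.strand = TRUE)
    assigned <- stats::setNames(rep(NA_integer_, nrow(distal)), NULL)
    assigned[S4Vectors::queryHits(hits)] <- S4Vectors::subjectHits(hits)
    l2 <- log2(distal$fold_change)
    agg <- tapply(l2, assigned, mean)
    true_change[as.integer(names(agg))] <- coupling * agg
  }
  withr::with_seed(seed, {
    mu <- base_mean * exp(stats::rnorm(nrow(genes), 0, 1))
    draw <- function(means) {
      if (dispersion <= 0) {
        matrix(rep(means, n_reps), ncol = n_reps)
      } else {
        matrix(stats::rnbinom(length(means) * n_reps,
                              mu = rep(means, n_reps),
                              size = 1 / dispersion), ncol = n_reps)
      }
    }
    wt <- draw(mu)
    mut <- draw(mu * 2^true_change)
    value_1 <- rowMeans(wt)
    value_2 <- rowMeans(mut)
    p <- vapply(seq_len(nrow(genes)), function(i) {
      tryCatch(stats::t.test(log2(wt[i, ] + 5), log2(mut[i, ] + 5))$p.value,
               error = function(e) 1)
    }, numeric(1))
    out <- data.frame(
      gene_id = genes$gene_id, status = "OK",
      value_1 = value_1, value_2 = value_2,
      log2_fold = log2(value_2 / value_1),
      fdr = stats::p.adjust(p, "BH"),
      stringsAsFactors = FALSE
    )
    attr(out, "true_log2_change") <- true_change
    out
  })
}

#' Write ground truth tables to disk
#'
#' @param truth a [ground_truth()] object.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_ground_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(truth$sites, file.path(dir, "truth_sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truth$tss, file.path(dir, "tss.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
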