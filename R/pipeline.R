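#' Pipeline configuration with the analysis' standard constants
#'
#' Collects every numeric constant of the analysis in one overridable
#' object, serialized (YAML) with every run for provenance.
#'
#' @param ... overrides of the defaults listed below.
#' @return list of class `PipelineConfig`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    bin_size = 1000L,          # blacklist bin width (bp)
    k_sd = 3,                  # blacklist threshold: mean + k_sd * SD
    window = 500L,             # RoE calling window (bp)
    z_thr = 4,                 # RoE window z threshold
    min_samples = 2L,          # reproducibility: called in >= this many samples
    promoter_dist = 1000L,     # enhancer must be > this from H3K4me3 RoE
    tss_dist = 2000L,          # enhancer must be > this from active TSS
    stitch_gap = 12500L,       # super-enhancer stitching gap (bp)
    segment_lambda = 1,        # BIC breakpoint penalty
    transcribed_min_log2 = 0.1,# transcribed-segment log2 enrichment cutoff
    segment_bin = 100L,        # segmentation bin width (bp)
    smoothing_sigma = 100,     # profile Gaussian bandwidth (bp)
    profile_step = 10L,        # profile sampling step (bp)
    signal_pseudocount = 1,    # RPM pseudocount
    expression_pseudocount = 5,# expression log-ratio pseudocount
    link_min_dist = 5000L,     # expression linkage band (bp)
    link_max_dist = 100000L,
    peak_match_dist = 90L,     # replicate peak matching distance (bp)
    idr_threshold = 0.01,
    complexity_threshold = 0.90,
    sensitivity_each = 2,      # per-replicate reduction for 'sensitive'
    sensitivity_mean = 4,      # mean reduction for 'sensitive'
    insensitive_mean = 1.5,
    go_fdr = 0.05,
    min_promoters = 50L,       # promoters required for efficiency fitting
    seed = 1L,
    chrom_lengths = NULL       # named vector; required by run_pipeline
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    stop("unknown config entries: ", paste(unknown, collapse = ", "))
  }
  defaults[names(overrides)] <- overrides
  structure(defaults, class = "PipelineConfig")
}

#' Validate a sample manifest
#'
#' @param manifest data.frame with columns `sample_id`, `mark`,
#'   `condition`, `replicate`, `tag_file`, `fragment_size`.
#' @return the manifest, invisibly; errors if any IP sample has no input
#'   sample with the same condition and replicate.
#' @export
validate_manifest <- function(manifest) {
  required <- c("sample_id", "mark", "condition", "replicate", "tag_file",
                "fragment_size")
  missing_cols <- setdiff(required, names(manifest))
  if (length(missing_cols)) {
    stop("manifest lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  inputs <- manifest[manifest$mark == "input", , drop = FALSE]
  ips <- manifest[manifest$mark != "input", , drop = FALSE]
  key <- function(df) paste(df$condition, df$replicate)
  orphan <- !(key(ips) %in% key(inputs))
  if (any(orphan)) {
    stop("IP sample(s) without matching input (same condition/replicate): ",
         paste(ips$sample_id[orphan], collapse = ", "))
  }
  invisible(manifest)
}

#' Simulate a complete multi-sample ChIP experiment on disk
#'
#' Generates tag libraries for H3K27ac (all condition/replicate pairs),
#' H3K4me3 (one replicate per condition), PolII (wild type), and matched
#' inputs; writes them as TSV together with the TSS annotation and ground
#' truth, and returns the manifest. Per-sample IP efficiencies are drawn
#' uniformly from `efficiency_range`.
#'
#' @param spec a `SyntheticGenomeSpec`.
#' @param dir output directory.
#' @param conditions condition labels; the first is the reference.
#' @param replicates replicate labels.
#' @param efficiency_range range of the per-sample IP-efficiency draw.
#' @param seed integer seed controlling efficiencies and all libraries.
#' @return list with `manifest` (data.frame), `truth`, `efficiencies`
#'   (named per H3K27ac sample), and `dir`.
#' @export
simulate_experiment <- function(spec, dir,
                                conditions = c("WT", "mutantA", "mutantB"),
                                replicates = c("I", "II"),
                                efficiency_range = c(0.6, 1.4),
                                seed = spec$seed) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- ground_truth(spec)
  write_ground_truth(truth, dir)
  design <- expand.grid(condition = conditions, replicate = replicates,
                        stringsAsFactors = FALSE)
  effs <- withr::with_seed(seed, stats::runif(nrow(design),
                                              efficiency_range[1],
                                              efficiency_range[2]))
  names(effs) <- paste0("H3K27ac_", design$condition, design$replicate)
  rows <- list()
  lib_seed <- seed
  emit <- function(sample_id, mark, condition, replicate, lib) {
    path <- file.path(dir, paste0(sample_id, ".tsv"))
    write_tag_tsv(lib, path)
    rows[[length(rows) + 1L]] <<- data.frame(
      sample_id = sample_id, mark = mark, condition = condition,
      replicate = replicate, tag_file = path,
      fragment_size = spec$fragment_size, stringsAsFactors = FALSE
    )
  }
  for (i in seq_len(nrow(design))) {
    cond <- design$condition[i]; rep_ <- design$replicate[i]
    sid <- paste0("H3K27ac_", cond, rep_)
    lib_seed <- lib_seed + 1L
    emit(sid, "H3K27ac", cond, rep_,
         generate_tag_library(spec, cond, "IP", "H3K27ac",
                              ip_efficiency = effs[[sid]], truth = truth,
                              seed = lib_seed))
    lib_seed <- lib_seed + 1L
    emit(paste0("input_", cond, rep_), "input", cond, rep_,
         generate_tag_library(spec, cond, "input", truth = truth,
                              seed = lib_seed))
  }
  for (cond in conditions) {
    for (rep_ in replicates) {
      lib_seed <- lib_seed + 1L
      emit(paste0("H3K4me3_", cond, rep_), "H3K4me3", cond, rep_,
           generate_tag_library(spec, cond, "IP", "H3K4me3", truth = truth,
                                seed = lib_seed))
    }
  }
  lib_seed <- lib_seed + 1L
  emit(paste0("PolII_", conditions[1], replicates[1]), "PolII",
       conditions[1], replicates[1],
       generate_tag_library(spec, conditions[1], "IP", "PolII",
                            truth = truth, seed = lib_seed))
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(chrom = names(truth$chrom_lengths),
               length = unname(truth$chrom_lengths)),
    file.path(dir, "chrom_lengths.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  list(manifest = manifest, truth = truth, efficiencies = effs, dir = dir)
}

#' Run the full cis-regulatory analysis pipeline
#'
#' Executes preprocessing (complexity check, optional deduplication,
#' blacklist, tag shifting), RoE calling per IP sample against its matched
#' input, reproducibility-filtered unions, active-TSS definition, element
#' classification, per-sample signal quantification, promoter-mode
#' IP-efficiency normalization per replicate pair, corrected fold-changes
#' and sensitive-enhancer selection per mutant, super-enhancer calling,
#' transcribed-region segmentation (when a PolII sample is present), and,
#' when expression tables / a GO map are supplied, enhancer-gene linkage,
#' expression comparison and GO enrichment. All artifacts are written to
#' `out_dir` together with the serialized configuration.
#'
#' @param config a `PipelineConfig` with non-NULL `chrom_lengths`.
#' @param manifest a sample manifest (see [validate_manifest()]).
#' @param out_dir results directory.
#' @param tss TSS annotation: `GRanges` with `gene_id`, or path to a
#'   4-column TSV (see [read_tss_tsv()]).
#' @param expression_tables optional named list (one per mutant condition)
#'   of cuffdiff-like differential tables.
#' @param go_map optional data.frame with columns `term`, `gene`.
#' @return list with elements `elements`, `signal_matrix`, `factors`,
#'   `fold_changes`, `sensitive`, `super_enhancers`, `transcribed`,
#'   `linkage`, `expression`, `go`, `blacklist`, `roes`.
#' @export
run_pipeline <- function(config, manifest, out_dir, tss,
                         expression_tables = NULL, go_map = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (is.null(config$chrom_lengths)) {
    stop("config$chrom_lengths must be set")
  }
  validate_manifest(manifest)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "run.log")
  log_line <- function(...) {
    msg <- sprintf(...)
    cat(msg, "\n", file = logf, append = TRUE, sep = "")
    message(msg)
  }
  cfg_out <- config
  cfg_out$chrom_lengths <- as.list(config$chrom_lengths)
  yaml::write_yaml(unclass(cfg_out), file.path(out_dir, "config.yaml"))
  if (is.character(tss)) tss <- read_tss_tsv(tss)

  stage <- function(name, expr) {
    log_line("stage: %s", name)
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  libs <- stage("load", {
    ls <- lapply(seq_len(nrow(manifest)), function(i) {
      read_tag_tsv(manifest$tag_file[i], config$chrom_lengths,
                   manifest$fragment_size[i])
    })
    names(ls) <- manifest$sample_id
    ls
  })

  libs <- stage("complexity", {
    lapply(libs, function(lib) {
      if (library_complexity(lib) < config$complexity_threshold) {
        deduplicate(lib)
      } else lib
    })
  })

  blacklist <- stage("blacklist", {
    input_ids <- manifest$sample_id[manifest$mark == "input"]
    bls <- lapply(unname(libs[input_ids]), build_blacklist,
                  bin_size = config$bin_size, k_sd = config$k_sd)
    merge_blacklists(bls)
  })
  log_line("blacklist: %d intervals, %d bp", length(blacklist),
           sum(GenomicRanges::width(blacklist)))

  libs <- stage("shift_and_mask", {
    lapply(libs, shift_and_mask, blacklist = blacklist)
  })

  input_for <- function(i) {
    j <- which(manifest$mark == "input" &
                 manifest$condition == manifest$condition[i] &
                 manifest$replicate == manifest$replicate[i])[1]
    manifest$sample_id[j]
  }

  roes <- stage("call_roe", {
    ip_rows <- which(manifest$mark %in% c("H3K27ac", "H3K4me3"))
    rs <- lapply(ip_rows, function(i) {
      call_roe(libs[[manifest$sample_id[i]]], libs[[input_for(i)]],
               window = config$window, z_thr = config$z_thr)
    })
    names(rs) <- manifest$sample_id[ip_rows]
    rs
  })

  k27_ids <- manifest$sample_id[manifest$mark == "H3K27ac"]
  k4_ids <- manifest$sample_id[manifest$mark == "H3K4me3"]
  k27_union <- stage("reproducible_union", {
    reproducible_roe_union(roes[k27_ids], min_samples = config$min_samples)
  })
  k4_union <- stage("h3k4me3_union", {
    if (length(k4_ids) >= config$min_samples) {
      reproducible_roe_union(roes[k4_ids], min_samples = config$min_samples)
    } else {
      GenomicRanges::reduce(do.call(c, unname(lapply(roes[k4_ids],
                                                     GenomicRanges::granges))))
    }
  })
  log_line("H3K27ac reproducible regions: %d; H3K4me3 union: %d",
           length(k27_union), length(k4_union))

  atss <- stage("active_tss", {
    active_tss(tss, lapply(roes[k4_ids], identity))
  })
  elements <- stage("classify", {
    classify_elements(k27_union, k4_union, atss,
                      promoter_dist = config$promoter_dist,
                      tss_dist = config$tss_dist)
  })
  cls <- S4Vectors::mcols(elements)$cre_class
  log_line("elements: %d promoters, %d enhancers, %d ambiguous",
           sum(cls == "promoter"), sum(cls == "enhancer"),
           sum(cls == "ambiguous"))

  signal_matrix <- stage("quantify", {
    m <- vapply(k27_ids, function(sid) {
      region_signal(libs[[sid]], elements,
                    pseudocount = config$signal_pseudocount)
    }, numeric(length(elements)))
    colnames(m) <- k27_ids
    m
  })

  k27_manifest <- manifest[manifest$mark == "H3K27ac", , drop = FALSE]
  reference_condition <- k27_manifest$condition[1]
  factors <- stage("normalize", {
    f <- stats::setNames(rep(NA_real_, length(k27_ids)), k27_ids)
    diag <- list()
    for (rep_ in unique(k27_manifest$replicate)) {
      ids <- k27_manifest$sample_id[k27_manifest$replicate == rep_]
      ref <- k27_manifest$sample_id[k27_manifest$replicate == rep_ &
                                      k27_manifest$condition ==
                                      reference_condition][1]
      nf <- fit_ip_efficiency(signal_matrix[, ids, drop = FALSE],
                              cls == "promoter", reference = ref,
                              min_promoters = config$min_promoters)
      f[ids] <- nf$factors
      diag[[rep_]] <- nf
    }
    attr(f, "fits") <- diag
    f
  })
  log_line("normalization factors: %s",
           paste(sprintf("%s=%.3f", names(factors), factors),
                 collapse = ", "))

  mutants <- setdiff(unique(k27_manifest$condition), reference_condition)
  fold_changes <- stage("fold_change", {
    out <- list()
    for (mut in mutants) {
      per_rep <- list()
      for (rep_ in unique(k27_manifest$replicate)) {
        sid <- k27_manifest$sample_id[k27_manifest$condition == mut &
                                        k27_manifest$replicate == rep_]
        ref <- k27_manifest$sample_id[k27_manifest$condition ==
                                        reference_condition &
                                        k27_manifest$replicate == rep_]
        per_rep[[rep_]] <- fold_change(signal_matrix[, sid],
                                       signal_matrix[, ref],
                                       factors[[sid]], factors[[ref]])
      }
      out[[mut]] <- per_rep
    }
    out
  })

  sensitive <- stage("sensitive_enhancers", {
    lapply(fold_changes, function(per_rep) {
      sel <- select_sensitive_enhancers(per_rep[[1]], per_rep[[2]])
      sel & cls == "enhancer"
    })
  })
  for (mut in mutants) {
    log_line("sensitive enhancers (%s): %d", mut, sum(sensitive[[mut]]))
  }

  wt_rows <- which(manifest$mark == "H3K27ac" &
                     manifest$condition == reference_condition)
  super_enhancers <- stage("super_enhancers", {
    stitched <- stitch_enhancers(k27_union, k4_union,
                                 gap = config$stitch_gap)
    sid <- manifest$sample_id[wt_rows[1]]
    call_super_enhancers(stitched, libs[[sid]], libs[[input_for(wt_rows[1])]])
  })
  log_line("super-enhancers: %d of %d stitched regions",
           sum(S4Vectors::mcols(super_enhancers)$is_super),
           length(super_enhancers))

  pol2_rows <- which(manifest$mark == "PolII")
  transcribed <- NULL
  if (length(pol2_rows)) {
    transcribed <- stage("transcribed", {
      sid <- manifest$sample_id[pol2_rows[1]]
      inp <- input_for(pol2_rows[1])
      segs <- lapply(names(config$chrom_lengths), function(chrom) {
        nb <- ceiling(config$chrom_lengths[[chrom]] / config$segment_bin)
        s <- segment_transcription(
          window_counts(libs[[sid]], chrom, config$segment_bin, nb),
          window_counts(libs[[inp]], chrom, config$segment_bin, nb),
          lambda = config$segment_lambda,
          min_log2 = config$transcribed_min_log2,
          bin_size = config$segment_bin
        )
        cbind(chrom = chrom, s)
      })
      do.call(rbind, segs)
    })
  }

  linkage <- NULL; expression <- NULL; go <- NULL
  if (!is.null(expression_tables)) {
    linkage <- stage("linkage", {
      link_enhancers(elements, atss, max_dist = config$link_max_dist,
                     min_dist_expr = config$link_min_dist)
    })
    expression <- stage("expression", {
      lapply(mutants, function(mut) {
        tab <- expression_tables[[mut]]
        if (is.null(tab)) return(NULL)
        tab <- tab[tab$status == "OK", , drop = FALSE]
        expr <- stats::setNames(
          expression_change(tab$value_2, tab$value_1,
                            config$expression_pseudocount),
          tab$gene_id)
        fc_avg <- sqrt(fold_changes[[mut]][[1]] * fold_changes[[mut]][[2]])
        enh_links <- linkage[cls[linkage$enhancer] == "enhancer", ,
                             drop = FALSE]
        categorize_and_compare(enh_links, fc_avg, expr)
      })
    })
    names(expression) <- mutants
    if (!is.null(go_map)) {
      go <- stage("go", {
        lapply(mutants, function(mut) {
          enh_links <- linkage[cls[linkage$enhancer] == "enhancer", ,
                               drop = FALSE]
          universe <- unique(enh_links$gene_id)
          sel <- unique(enh_links$gene_id[
            sensitive[[mut]][enh_links$enhancer]])
          if (!length(sel)) return(NULL)
          go_enrichment(sel, universe, go_map)
        })
      })
      names(go) <- mutants
    }
  }

  stage("write_outputs", {
    write_bed(elements, file.path(out_dir, "elements.bed"),
              name_col = "cre_class")
    el_df <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(elements)),
      start = GenomicRanges::start(elements) - 1L,
      end = GenomicRanges::end(elements),
      class = cls,
      dist_h3k4me3 = S4Vectors::mcols(elements)$dist_h3k4me3,
      dist_active_tss = S4Vectors::mcols(elements)$dist_active_tss
    )
    utils::write.table(cbind(el_df, signal_matrix),
                       file.path(out_dir, "element_signals.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(sample = names(factors), factor = unname(factors)),
      file.path(out_dir, "normalization_factors.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    se <- super_enhancers
    S4Vectors::mcols(se)$name <- ifelse(S4Vectors::mcols(se)$is_super,
                                        "super", "typical")
    S4Vectors::mcols(se)$score <- S4Vectors::mcols(se)$se_signal
    write_bed(se, file.path(out_dir, "super_enhancers.bed"),
              name_col = "name", score_col = "score")
    if (!is.null(transcribed)) {
      utils::write.table(transcribed,
                         file.path(out_dir, "transcribed_segments.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    for (mut in mutants) {
      utils::write.table(
        data.frame(el_df, fc_rep1 = fold_changes[[mut]][[1]],
                   fc_rep2 = fold_changes[[mut]][[2]],
                   sensitive = sensitive[[mut]]),
        file.path(out_dir, paste0("fold_changes_", mut, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
  })
  log_line("pipeline complete")

  list(elements = elements, signal_matrix = signal_matrix,
       factors = factors, fold_changes = fold_changes,
       sensitive = sensitive, super_enhancers = super_enhancers,
       transcribed = transcribed, linkage = linkage,
       expression = expression, go = go, blacklist = blacklist,
       roes = roes)
}
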