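#' Link enhancers to their closest active TSS within a distance limit
#'
#' Each enhancer is associated to the nearest active TSS (edge-to-TSS
#' distance, 0 when the TSS lies inside the enhancer). Links farther than
#' `max_dist` are dropped; links closer than `min_dist_expr` are kept but
#' flagged as excluded from expression analyses, which are restricted to
#' the 5-100 kb band.
#'
#' @param enhancers `GRanges` of enhancers.
#' @param tss `GRanges` of width-1 active TSSs with `gene_id` metadata.
#' @param max_dist maximal linking distance in bp.
#' @param min_dist_expr minimal distance for use in expression comparisons.
#' @return data.frame with columns `enhancer` (index into `enhancers`),
#'   `gene_id`, `distance`, `use_for_expression`.
#' @export
link_enhancers <- function(enhancers, tss, max_dist = 100000L,
                           min_dist_expr = 5000L) {
  if (!length(enhancers) || !length(tss)) {
    return(data.frame(enhancer = integer(), gene_id = character(),
                      distance = numeric(), use_for_expression = logical()))
  }
  hits <- GenomicRanges::distanceToNearest(enhancers, tss,
                                           ignore.strand = TRUE)
  d <- S4Vectors::mcols(hits)$distance
  keep <- d <= max_dist
  data.frame(
    enhancer = S4Vectors::queryHits(hits)[keep],
    gene_id = S4Vectors::mcols(tss)$gene_id[S4Vectors::subjectHits(hits)[keep]],
    distance = d[keep],
    use_for_expression = d[keep] >= min_dist_expr,
    stringsAsFactors = FALSE
  )
}

#' Gene expression log2 change with pseudocount
#'
#' @param count_mut,count_wt normalized gene-level count values
#'   (e.g. cuffdiff output) in mutant and reference condition.
#' @param pseudocount added to both counts.
#' @return log2((count_mut + pseudocount) / (count_wt + pseudocount)).
#' @export
expression_change <- function(count_mut, count_wt, pseudocount = 5) {
  log2((count_mut + pseudocount) / (count_wt + pseudocount))
}

#' Categorize enhancer H3K27ac fold-changes into signal-change groups
#'
#' Groups: more than 3-fold loss, 1.5- to 3-fold loss, less than 1.5-fold
#' change (stable), and more than 1.5-fold gain. Boundary values fall into
#' the milder category.
#'
#' @param fc fold-changes (mutant over reference).
#' @return ordered factor with levels `loss_gt3`, `loss_1.5_3`, `stable`,
#'   `gain`.
#' @export
categorize_fold_change <- function(fc) {
  cls <- ifelse(fc < 1 / 3, "loss_gt3",
         ifelse(fc < 1 / 1.5, "loss_1.5_3",
         ifelse(fc <= 1.5, "stable", "gain")))
  factor(cls, levels = c("loss_gt3", "loss_1.5_3", "stable", "gain"),
         ordered = TRUE)
}

#' Compare expression changes across enhancer fold-change categories
#'
#' Joins enhancer-gene links with enhancer H3K27ac fold-changes and gene
#' expression log2 changes, groups genes by the enhancer signal-change
#' category, and reports per-group boxplot statistics (quartiles and
#' 1.5 x IQR whiskers) plus pairwise two-sided Welch t-test p-values.
#' Only links flagged `use_for_expression` are used.
#'
#' @param links data.frame from [link_enhancers()].
#' @param enhancer_fold_changes numeric vector indexed like the `enhancers`
#'   passed to [link_enhancers()].
#' @param expression_changes named numeric vector of gene log2 expression
#'   changes (names are gene ids); genes absent from it are dropped.
#' @return list with `groups` (data.frame of gene-level category/change),
#'   `summary` (per-category boxplot statistics), and `p_values` (matrix of
#'   pairwise Welch t-test p-values, NA where a group is empty or the test
#'   is undefined).
#' @export
categorize_and_compare <- function(links, enhancer_fold_changes,
                                   expression_changes) {
  use <- links[links$use_for_expression &
                 links$gene_id %in% names(expression_changes), , drop = FALSE]
  groups <- data.frame(
    gene_id = use$gene_id,
    category = categorize_fold_change(enhancer_fold_changes[use$enhancer]),
    expr_log2 = unname(expression_changes[use$gene_id]),
    stringsAsFactors = FALSE
  )
  lv <- levels(groups$category)
  summ <- do.call(rbind, lapply(lv, function(g) {
    v <- groups$expr_log2[groups$category == g]
    if (!length(v)) {
      return(data.frame(category = g, n = 0L, q1 = NA, median = NA, q3 = NA,
                        whisker_low = NA, whisker_high = NA))
    }
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    data.frame(category = g, n = length(v), q1 = q[1], median = q[2],
               q3 = q[3],
               whisker_low = min(v[v >= q[1] - 1.5 * iqr]),
               whisker_high = max(v[v <= q[3] + 1.5 * iqr]))
  }))
  pmat <- matrix(NA_real_, length(lv), length(lv), dimnames = list(lv, lv))
  for (i in seq_along(lv)) {
    for (j in seq_along(lv)) {
      if (j <= i) next
      vi <- groups$expr_log2[groups$category == lv[i]]
      vj <- groups$expr_log2[groups$category == lv[j]]
      if (length(vi) >= 2 && length(vj) >= 2) {
        p <- tryCatch(stats::t.test(vi, vj)$p.value, error = function(e) NA_real_)
        pmat[i, j] <- p
        pmat[j, i] <- p
      }
    }
  }
  list(groups = groups, summary = summ, p_values = pmat)
}

#' Select enhancers sensitive to subunit loss from replicate fold-changes
#'
#' An enhancer is sensitive when (i) the mutant/WT signal change is below 1
#' in each replicate comparison and (ii) the geometric mean of the two
#' changes is below 1/2.
#'
#' @param fold_change_rep1,fold_change_rep2 positive fold-change vectors,
#'   one per replicate comparison.
#' @return logical vector.
#' @export
select_sensitive_enhancers <- function(fold_change_rep1, fold_change_rep2) {
  stopifnot(length(fold_change_rep1) == length(fold_change_rep2))
  if (any(fold_change_rep1 <= 0) || any(fold_change_rep2 <= 0)) {
    stop("fold-changes must be positive")
  }
  fold_change_rep1 < 1 & fold_change_rep2 < 1 &
    sqrt(fold_change_rep1 * fold_change_rep2) < 0.5
}

#' Select significantly downregulated genes from a differential table
#'
#' @param diff_table data.frame in cuffdiff-like shape with columns
#'   `gene_id`, `status`, `value_1` (reference), `value_2` (mutant),
#'   `log2_fold` (mutant over reference), `fdr`.
#' @param fdr false discovery rate cutoff.
#' @param min_fold minimal fold reduction (mutant versus reference).
#' @return character vector of selected gene ids.
#' @export
select_downregulated_genes <- function(diff_table, fdr = 0.05,
                                       min_fold = 2) {
  required <- c("gene_id", "status", "log2_fold", "fdr")
  missing_cols <- setdiff(required, names(diff_table))
  if (length(missing_cols)) {
    stop("differential table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  }
  sel <- diff_table$status == "OK" & diff_table$fdr < fdr &
    2^diff_table$log2_fold < 1 / min_fold
  diff_table$gene_id[sel]
}

#' Gene ontology enrichment by hypergeometric test with BH correction
#'
#' For each term, the p-value is the upper-tail hypergeometric probability
#' of observing at least the seen number of annotated genes among the
#' selected set, drawn from the universe; q-values are Benjamini-Hochberg
#' over all tested terms.
#'
#' @param selected_genes character vector, a subset of `universe_genes`.
#' @param universe_genes character vector of background genes.
#' @param go_map data.frame with columns `term` and `gene`.
#' @return data.frame with columns `term`, `k` (selected, annotated), `K`
#'   (universe, annotated), `n` (selected), `N` (universe), `p`, `q`,
#'   sorted by p.
#' @export
go_enrichment <- function(selected_genes, universe_genes, go_map) {
  selected_genes <- unique(selected_genes)
  universe_genes <- unique(universe_genes)
  if (!all(selected_genes %in% universe_genes)) {
    stop("selected genes must be a subset of the universe")
  }
  map <- go_map[go_map$gene %in% universe_genes, , drop = FALSE]
  terms <- unique(map$term)
  N <- length(universe_genes)
  n <- length(selected_genes)
  res <- do.call(rbind, lapply(terms, function(tm) {
    genes <- unique(map$gene[map$term == tm])
    K <- length(genes)
    k <- sum(selected_genes %in% genes)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  }))
  if (is.null(res)) {
    return(data.frame(term = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      q = numeric()))
  }
  res$q <- stats::p.adjust(res$p, method = "BH")
  res[order(res$p), , drop = FALSE]
}
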