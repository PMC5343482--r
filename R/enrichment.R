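#' Call regions of enrichment (RoE) from IP versus input tag libraries
#'
#' Chromosomes are tiled in non-overlapping windows; the expected IP count
#' per window is the input window count (plus a pseudocount to avoid zero
#' expectations) rescaled by the IP/input library-size ratio, and the window
#' z score is (observed - expected)/sqrt(expected). Windows at or above
#' `z_thr` are merged when adjacent into regions of enrichment.
#'
#' @param ip,input preprocessed `TagLibrary` objects on the same chromosome
#'   set.
#' @param window window size in bp.
#' @param z_thr z-score threshold for a window to be called enriched.
#' @param pseudocount added to input window counts before scaling.
#' @return `GRanges` of non-overlapping enriched regions with metadata
#'   column `max_window_z` (the maximum window z inside each region).
#' @export
call_roe <- function(ip, input, window = 500L, z_thr = 4, pseudocount = 0.5) {
  stopifnot(inherits(ip, "TagLibrary"), inherits(input, "TagLibrary"))
  n_ip <- total_mapped(ip)
  n_in <- total_mapped(input)
  if (n_in == 0L) stop("input library has no mapped tags")
  if (!setequal(names(ip$chrom_lengths), names(input$chrom_lengths))) {
    stop("IP and input libraries cover different chromosome sets")
  }
  ratio <- n_ip / n_in
  lens <- ip$chrom_lengths
  out <- lapply(names(lens), function(chrom) {
    nw <- ceiling(lens[[chrom]] / window)
    obs <- window_counts(ip, chrom, window, nw)
    bg <- window_counts(input, chrom, window, nw)
    expd <- (bg + pseudocount) * ratio
    z <- (obs - expd) / sqrt(expd)
    hot <- is.finite(z) & z >= z_thr
    if (!any(hot)) return(NULL)
    r <- rle(hot)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    GenomicRanges::GRanges(
      seqnames = chrom,
      ranges = IRanges::IRanges(
        start = (starts[runs] - 1L) * window + 1L,
        end = pmin(ends[runs] * window, lens[[chrom]])
      ),
      max_window_z = vapply(runs, function(i) {
        max(z[starts[i]:ends[i]])
      }, numeric(1)),
      seqlengths = lens
    )
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(GenomicRanges::GRanges(seqlengths = lens))
  sort(do.call(c, out))
}

window_counts <- function(lib, chrom, window, nw) {
  t <- lib$tags[lib$tags$chrom == chrom, ]
  counts <- numeric(nw)
  if (nrow(t)) {
    idx <- (t$pos - 1L) %/% window + 1L
    agg <- rowsum(t$count, idx)
    counts[as.integer(rownames(agg))] <- agg[, 1]
  }
  counts
}

#' Reproducibility-filtered union of per-sample RoE sets
#'
#' Base pairs covered by RoE calls from at least `min_samples` distinct
#' samples are retained and merged into intervals; call portions supported
#' by fewer samples are dropped as non-reproducible.
#'
#' @param roe_sets list of `GRanges`, one per sample.
#' @param min_samples minimum number of distinct supporting samples.
#' @return `GRanges` of merged reproducible intervals.
#' @export
reproducible_roe_union <- function(roe_sets, min_samples = 2L) {
  stopifnot(is.list(roe_sets), length(roe_sets) >= min_samples)
  lens <- GenomeInfoDb::seqlengths(roe_sets[[1]])
  pooled <- do.call(c, lapply(seq_along(roe_sets), function(i) {
    g <- GenomicRanges::reduce(GenomicRanges::granges(roe_sets[[i]]))
    S4Vectors::mcols(g)$sample <- i
    g
  }))
  cov <- GenomicRanges::coverage(pooled)
  hits <- IRanges::slice(cov, lower = min_samples, rangesOnly = TRUE)
  out <- GenomicRanges::GRanges(hits)
  if (!all(is.na(lens))) {
    GenomeInfoDb::seqlengths(out) <-
      lens[GenomeInfoDb::seqlevels(out)]
  }
  sort(out)
}

#' Call point peaks from the smoothed enrichment profile
#'
#' Candidate peaks are local maxima of the Gaussian-smoothed, library-size
#' normalized IP profile minus the equally smoothed input profile. The
#' height threshold is set by an empirical false discovery rate: the same
#' caller is run on a null library whose IP positions are uniformly
#' re-drawn per chromosome, and the threshold is the smallest height at
#' which (null peaks passing)/(observed peaks passing) <= `fdr`.
#'
#' @param ip,input preprocessed `TagLibrary` objects.
#' @param fdr empirical false discovery rate for peak heights.
#' @param sigma Gaussian smoothing bandwidth (bp).
#' @param step profile sampling step (bp).
#' @param seed seed for the permutation null.
#' @return data.frame with columns `chrom`, `position`, `signal`, sorted by
#'   chromosome and position.
#' @export
call_point_peaks <- function(ip, input, fdr = 0.05, sigma = 100, step = 10L,
                             seed = 1L) {
  stopifnot(inherits(ip, "TagLibrary"))
  obs <- profile_local_maxima(ip, input, sigma, step)
  null_lib <- withr::with_seed(seed, {
    t <- ip$tags
    lens <- ip$chrom_lengths[t$chrom]
    t$pos <- as.integer(floor(stats::runif(nrow(t), 0, as.numeric(lens))) + 1L)
    tag_library(t, ip$chrom_lengths, ip$fragment_size)
  })
  null <- profile_local_maxima(null_lib, input, sigma, step)
  heights <- sort(unique(obs$signal), decreasing = TRUE)
  thr <- Inf
  for (h in heights) {
    n_obs <- sum(obs$signal >= h)
    n_null <- sum(null$signal >= h)
    if (n_obs > 0 && n_null / n_obs <= fdr) thr <- h else break
  }
  out <- obs[obs$signal >= thr, , drop = FALSE]
  rownames(out) <- NULL
  out
}

profile_local_maxima <- function(ip, input, sigma, step) {
  prof_ip <- smooth_profile(ip, sigma = sigma, step = step)
  prof_in <- smooth_profile(input, sigma = sigma, step = step)
  res <- lapply(names(prof_ip), function(chrom) {
    d <- prof_ip[[chrom]]$value - prof_in[[chrom]]$value
    n <- length(d)
    if (n < 3) return(NULL)
    i <- which(d[2:(n - 1)] > d[1:(n - 2)] & d[2:(n - 1)] >= d[3:n]) + 1L
    i <- i[d[i] > 0]
    if (!length(i)) return(NULL)
    data.frame(chrom = chrom, position = prof_ip[[chrom]]$pos[i],
               signal = d[i], stringsAsFactors = FALSE)
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) {
    return(data.frame(chrom = character(), position = integer(),
                      signal = numeric()))
  }
  do.call(rbind, res)
}

#' Match point peaks between two replicates
#'
#' Peaks from two replicates are considered the same when within `max_dist`
#' bp of each other. Matching is greedy one-to-one by increasing distance
#' (ties broken toward the lower coordinate); a peak with no partner is
#' paired with signal y = 0 on the missing side.
#'
#' @param peaks_a,peaks_b data.frames with columns `chrom`, `position`,
#'   `signal` (as from [call_point_peaks()]).
#' @param max_dist maximum pairing distance in bp.
#' @return data.frame with columns `chrom`, `pos_a`, `pos_b`, `y_a`, `y_b`;
#'   unmatched peaks have `NA` position and 0 signal on the missing side.
#' @export
match_peaks <- function(peaks_a, peaks_b, max_dist = 90L) {
  chroms <- union(unique(peaks_a$chrom), unique(peaks_b$chrom))
  out <- lapply(chroms, function(chrom) {
    a <- peaks_a[peaks_a$chrom == chrom, , drop = FALSE]
    b <- peaks_b[peaks_b$chrom == chrom, , drop = FALSE]
    na <- nrow(a); nb <- nrow(b)
    pairs <- NULL
    if (na && nb) {
      cand <- expand.grid(i = seq_len(na), j = seq_len(nb))
      cand$dist <- abs(a$position[cand$i] - b$position[cand$j])
      cand <- cand[cand$dist <= max_dist, , drop = FALSE]
      cand <- cand[order(cand$dist,
                         pmin(a$position[cand$i], b$position[cand$j])), ,
                   drop = FALSE]
      used_a <- logical(na); used_b <- logical(nb)
      keep <- logical(nrow(cand))
      for (k in seq_len(nrow(cand))) {
        i <- cand$i[k]; j <- cand$j[k]
        if (!used_a[i] && !used_b[j]) {
          keep[k] <- TRUE
          used_a[i] <- TRUE
          used_b[j] <- TRUE
        }
      }
      pairs <- cand[keep, , drop = FALSE]
    } else {
      used_a <- logical(na); used_b <- logical(nb)
    }
    rows <- list()
    if (!is.null(pairs) && nrow(pairs)) {
      rows[[1]] <- data.frame(
        chrom = chrom,
        pos_a = a$position[pairs$i], pos_b = b$position[pairs$j],
        y_a = a$signal[pairs$i], y_b = b$signal[pairs$j],
        stringsAsFactors = FALSE
      )
    }
    if (any(!used_a)) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, pos_a = a$position[!used_a], pos_b = NA_integer_,
        y_a = a$signal[!used_a], y_b = 0, stringsAsFactors = FALSE
      )
    }
    if (any(!used_b)) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, pos_a = NA_integer_, pos_b = b$position[!used_b],
        y_a = 0, y_b = b$signal[!used_b], stringsAsFactors = FALSE
      )
    }
    if (!length(rows)) return(NULL)
    do.call(rbind, rows)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(chrom = character(), pos_a = integer(),
                      pos_b = integer(), y_a = numeric(), y_b = numeric()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Build two pseudoreplicates by random partition of pooled reads
#'
#' Tags from both replicates are pooled and each read is assigned uniformly
#' at random to one of two halves of equal size (within one tag).
#'
#' @param lib_a,lib_b `TagLibrary` replicates to pool.
#' @param seed integer seed; the partition is deterministic given the seed.
#' @return list of two `TagLibrary` pseudoreplicates.
#' @export
make_pseudoreplicates <- function(lib_a, lib_b, seed = 1L) {
  stopifnot(inherits(lib_a, "TagLibrary"), inherits(lib_b, "TagLibrary"))
  pooled <- rbind(lib_a$tags, lib_b$tags)
  n <- sum(pooled$count)
  units <- rep.int(seq_len(nrow(pooled)), pooled$count)
  half1 <- withr::with_seed(seed, sample.int(n, n %/% 2L))
  mk <- function(unit_rows) {
    if (!length(unit_rows)) {
      t <- pooled[0, , drop = FALSE]
    } else {
      agg <- rowsum(rep(1L, length(unit_rows)), units[unit_rows])
      rows <- as.integer(rownames(agg))
      t <- pooled[rows, , drop = FALSE]
      t$count <- as.integer(agg[, 1])
    }
    t <- t[order(t$chrom, t$pos, t$strand), , drop = FALSE]
    rownames(t) <- NULL
    tag_library(t, lib_a$chrom_lengths, lib_a$fragment_size)
  }
  list(mk(half1), mk(setdiff(seq_len(n), half1)))
}

#' Per-pair irreproducibility from a two-component rank mixture
#'
#' An analog of the irreproducible discovery rate: replicate peak signals
#' are rank-transformed to normal scores and fitted by EM with a mixture of
#' a reproducible component (a correlated bivariate normal with common mean
#' and variance) and an irreproducible component (independent standard
#' normal). The returned value per pair is the posterior probability of the
#' irreproducible component.
#'
#' @param y_a,y_b numeric signal vectors for matched peak pairs.
#' @param max_iter,tol EM iteration controls.
#' @return numeric vector of per-pair irreproducibility posteriors in
#'   \[0, 1\].
#' @export
idr_estimate <- function(y_a, y_b, max_iter = 200L, tol = 1e-6) {
  stopifnot(length(y_a) == length(y_b), length(y_a) >= 10L)
  n <- length(y_a)
  z_a <- stats::qnorm(rank(y_a, ties.method = "average") / (n + 1))
  z_b <- stats::qnorm(rank(y_b, ties.method = "average") / (n + 1))
  p <- 0.5; mu <- 1; sigma2 <- 1; rho <- 0.5
  loglik_old <- -Inf
  dnoise <- stats::dnorm(z_a) * stats::dnorm(z_b)
  for (iter in seq_len(max_iter)) {
    dsig <- dbvnorm(z_a, z_b, mu, sigma2, rho)
    num <- p * dsig
    den <- num + (1 - p) * dnoise
    den[den < .Machine$double.xmin] <- .Machine$double.xmin
    w <- num / den
    loglik <- sum(log(den))
    p <- min(max(mean(w), 1e-3), 1 - 1e-3)
    sw <- sum(w)
    mu <- sum(w * (z_a + z_b)) / (2 * sw)
    va <- sum(w * ((z_a - mu)^2 + (z_b - mu)^2)) / (2 * sw)
    sigma2 <- max(va, 1e-4)
    rho <- sum(w * (z_a - mu) * (z_b - mu)) / (sw * sigma2)
    rho <- min(max(rho, 0), 0.999)
    if (abs(loglik - loglik_old) < tol * abs(loglik_old + 1)) break
    loglik_old <- loglik
  }
  dsig <- dbvnorm(z_a, z_b, mu, sigma2, rho)
  den <- p * dsig + (1 - p) * dnoise
  den[den < .Machine$double.xmin] <- .Machine$double.xmin
  1 - p * dsig / den
}

dbvnorm <- function(x, y, mu, sigma2, rho) {
  det <- sigma2^2 * (1 - rho^2)
  q <- ((x - mu)^2 - 2 * rho * (x - mu) * (y - mu) + (y - mu)^2) /
    (sigma2 * (1 - rho^2))
  exp(-q / 2) / (2 * pi * sqrt(det))
}

#' Replicate reproducibility report from true and pseudoreplicate peaks
#'
#' Counts matched peak pairs below the irreproducibility threshold in the
#' true-replicate comparison (Nt) and in the pseudoreplicate comparison
#' (Np). The experiment passes when Nt exceeds half of Np.
#'
#' @param matched_pairs_true,matched_pairs_pseudo data.frames from
#'   [match_peaks()] with columns `y_a`, `y_b`.
#' @param idr_threshold reproducibility cutoff on the per-pair posterior.
#' @param estimator function(y_a, y_b) returning per-pair
#'   irreproducibility; defaults to [idr_estimate()].
#' @return list of class `ReproducibilityReport` with elements
#'   `n_peaks_idr_true`, `n_peaks_idr_pseudo`, `pass`, `diagnostic`.
#' @export
idr_assess <- function(matched_pairs_true, matched_pairs_pseudo,
                       idr_threshold = 0.01, estimator = idr_estimate) {
  count_rep <- function(pairs) {
    idr <- estimator(pairs$y_a, pairs$y_b)
    sum(idr < idr_threshold)
  }
  res <- tryCatch({
    nt <- count_rep(matched_pairs_true)
    np <- count_rep(matched_pairs_pseudo)
    list(n_peaks_idr_true = nt, n_peaks_idr_pseudo = np,
         pass = nt > 0.5 * np, diagnostic = "ok")
  }, error = function(e) {
    list(n_peaks_idr_true = NA_integer_, n_peaks_idr_pseudo = NA_integer_,
         pass = FALSE, diagnostic = conditionMessage(e))
  })
  structure(res, class = "ReproducibilityReport")
}

#' @export
print.ReproducibilityReport <- function(x, ...) {
  cat(sprintf("Reproducibility: Nt=%s, Np=%s -> %s (%s)\n",
              x$n_peaks_idr_true, x$n_peaks_idr_pseudo,
              if (isTRUE(x$pass)) "PASS" else "FAIL", x$diagnostic))
  invisible(x)
}
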