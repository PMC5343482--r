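test_that("identical IP and input produce no enriched regions", {
  set.seed(7)
  lib <- make_lib(pos = sample(100000L, 2000, replace = TRUE))
  expect_length(call_roe(lib, lib), 0)
})

test_that("an infinite z threshold returns nothing", {
  set.seed(8)
  ip <- make_lib(pos = sample(100000L, 2000, replace = TRUE))
  expect_length(call_roe(ip, ip, z_thr = Inf), 0)
})

test_that("a strong multi-window site is called as one region", {
  # background 2 tags per 500 bp window, one 5-window site at 20x
  bg <- rep(2L, 200)
  ip_counts <- bg
  ip_counts[101:105] <- 40L
  ip <- lib_from_bin_counts(ip_counts, bin_size = 500L)
  input <- lib_from_bin_counts(bg, bin_size = 500L)
  roe <- call_roe(ip, input)
  expect_length(roe, 1)
  expect_equal(GenomicRanges::start(roe), 100 * 500 + 1)
  expect_equal(GenomicRanges::end(roe), 105 * 500)
})

test_that("call_roe matches a brute-force window z computation", {
  set.seed(21)
  nw <- 400
  ip_counts <- rpois(nw, 3) + rbinom(nw, 50, 0.02) * 20L
  in_counts <- rpois(nw, 3)
  in_counts[1] <- in_counts[1] + 1L  # guarantee non-zero input total
  ip <- lib_from_bin_counts(ip_counts, bin_size = 500L)
  input <- lib_from_bin_counts(in_counts, bin_size = 500L)
  ratio <- sum(ip_counts) / sum(in_counts)
  z <- (ip_counts - (in_counts + 0.5) * ratio) / sqrt((in_counts + 0.5) * ratio)
  hot <- z >= 4
  r <- rle(hot)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  expected <- data.frame(start = (starts[r$values] - 1) * 500 + 1,
                         end = ends[r$values] * 500)
  roe <- call_roe(ip, input)
  expect_equal(GenomicRanges::start(roe), expected$start)
  expect_equal(GenomicRanges::end(roe), expected$end)
})

test_that("reproducible union equals the per-bp vote oracle", {
  set.seed(31)
  for (rep_i in 1:5) {
    sets <- lapply(1:6, function(i) {
      n <- sample(5:15, 1)
      s <- sort(sample(95000L, n))
      gr("chr1", s, s + sample(500:3000, n, replace = TRUE))
    })
    out <- reproducible_roe_union(sets, min_samples = 2L)
    # oracle: per-bp vote on a 100 kb toy genome
    votes <- integer(100000)
    for (s in sets) {
      covered <- logical(100000)
      for (k in seq_along(s)) {
        covered[GenomicRanges::start(s)[k]:GenomicRanges::end(s)[k]] <- TRUE
      }
      votes <- votes + covered
    }
    keep <- votes >= 2
    r <- rle(keep)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    expect_equal(GenomicRanges::start(out), starts[r$values])
    expect_equal(GenomicRanges::end(out), ends[r$values])
  }
})

test_that("identical calls in all samples survive the union unchanged", {
  calls <- gr("chr1", c(1000, 5000), c(2000, 6000))
  out <- reproducible_roe_union(list(calls, calls, calls))
  expect_equal(GenomicRanges::start(out), c(1000, 5000))
  expect_equal(GenomicRanges::end(out), c(2000, 6000))
  # called in only 1 of 6 samples -> dropped
  sets <- c(list(gr("chr1", 50000, 51000)),
            rep(list(gr("chr1", 1000, 2000)), 5))
  out2 <- reproducible_roe_union(sets)
  expect_equal(GenomicRanges::start(out2), 1000)
})

test_that("peak matching follows the 90 bp window and nearest-first rule", {
  pk <- function(pos, y = seq_along(pos)) {
    data.frame(chrom = "chr1", position = pos, signal = y)
  }
  m <- match_peaks(pk(100), pk(150))
  expect_equal(nrow(m), 1)
  expect_equal(m$pos_b, 150)

  m2 <- match_peaks(pk(100), pk(250))
  expect_equal(sort(c(m2$y_a, m2$y_b)), c(0, 0, 1, 1))
  expect_true(all(is.na(m2$pos_b[!is.na(m2$pos_a)])))

  # chain: B at 150 pairs with its nearest partner A at 180
  m3 <- match_peaks(pk(c(100, 180, 260)), pk(150))
  matched <- m3[!is.na(m3$pos_a) & !is.na(m3$pos_b), ]
  expect_equal(matched$pos_a, 180)
  expect_equal(sum(is.na(m3$pos_b)), 2)
})

test_that("peak matching is symmetric in its arguments", {
  set.seed(41)
  a <- data.frame(chrom = "chr1", position = sort(sample(10000, 30)),
                  signal = runif(30))
  b <- data.frame(chrom = "chr1", position = sort(sample(10000, 25)),
                  signal = runif(25))
  ab <- match_peaks(a, b)
  ba <- match_peaks(b, a)
  key_ab <- sort(paste(ab$pos_a, ab$pos_b))
  key_ba <- sort(paste(ba$pos_b, ba$pos_a))
  expect_equal(key_ab, key_ba)
})

test_that("pseudoreplicates split the pool in half, deterministically", {
  set.seed(51)
  a <- make_lib(pos = sample(100000L, 500), count = 1L)
  b <- make_lib(pos = sample(100000L, 500), count = 1L)
  pr <- make_pseudoreplicates(a, b, seed = 9)
  expect_equal(total_mapped(pr[[1]]), 500L)
  expect_equal(total_mapped(pr[[2]]), 500L)
  pr2 <- make_pseudoreplicates(a, b, seed = 9)
  expect_identical(pr[[1]]$tags, pr2[[1]]$tags)
  # conservation
  expect_equal(total_mapped(pr[[1]]) + total_mapped(pr[[2]]),
               total_mapped(a) + total_mapped(b))
})

test_that("pseudoreplicate per-chromosome counts stay in the binomial envelope", {
  set.seed(52)
  lens <- c(chr1 = 100000L, chr2 = 100000L)
  tags <- data.frame(chrom = sample(names(lens), 5000, replace = TRUE),
                     pos = sample(100000L, 5000, replace = TRUE),
                     strand = "+", count = 1L)
  a <- tag_library(tags[1:2500, ], lens)
  b <- tag_library(tags[2501:5000, ], lens)
  pr <- make_pseudoreplicates(a, b, seed = 3)
  pooled_per_chrom <- table(tags$chrom)
  for (chrom in names(lens)) {
    n <- pooled_per_chrom[[chrom]]
    got <- sum(pr[[1]]$tags$count[pr[[1]]$tags$chrom == chrom])
    env <- qbinom(c(0.005, 0.995), n, 0.5)
    expect_gte(got, env[1])
    expect_lte(got, env[2])
  }
})

test_that("idr mixture separates correlated from permuted replicates", {
  set.seed(61)
  y <- rexp(400)
  rep_pairs <- data.frame(y_a = y, y_b = y + rnorm(400, 0, 0.01))
  perm_pairs <- data.frame(y_a = y, y_b = sample(y))
  rep_out <- idr_assess(rep_pairs, rep_pairs)
  expect_true(rep_out$pass)  # Nt == Np by construction
  expect_equal(rep_out$n_peaks_idr_true, rep_out$n_peaks_idr_pseudo)
  perm_out <- idr_assess(perm_pairs, rep_pairs)
  expect_false(perm_out$pass)
  expect_lt(perm_out$n_peaks_idr_true,
            0.1 * perm_out$n_peaks_idr_pseudo + 1)
})

test_that("the Nt > Np/2 decision rule and failure path are honoured", {
  fake <- function(values) {
    force(values)
    i <- 0
    function(y_a, y_b) {
      i <<- i + 1
      values[[i]]
    }
  }
  # Nt = 60, Np = 100 -> pass
  est <- fake(list(c(rep(0, 60), rep(1, 40)), rep(0, 100)))
  out <- idr_assess(data.frame(y_a = 1:100, y_b = 1:100),
                    data.frame(y_a = 1:100, y_b = 1:100), estimator = est)
  expect_equal(out$n_peaks_idr_true, 60)
  expect_equal(out$n_peaks_idr_pseudo, 100)
  expect_true(out$pass)

  failing <- function(y_a, y_b) stop("estimator blew up")
  bad <- idr_assess(data.frame(y_a = 1, y_b = 1),
                    data.frame(y_a = 1, y_b = 1), estimator = failing)
  expect_false(bad$pass)
  expect_match(bad$diagnostic, "blew up")
})

test_that("point peaks recover planted sites at the empirical FDR", {
  spec <- synthetic_genome_spec(n_chroms = 1L, chrom_length = 1e6,
                                n_promoter_sites = 20L, n_distal_sites = 20L,
                                seed = 71)
  tr <- ground_truth(spec)
  ip <- shift_and_mask(generate_tag_library(spec, seed = 72))
  input <- shift_and_mask(generate_tag_library(spec, sample_role = "input",
                                               seed = 73))
  peaks <- call_point_peaks(ip, input, seed = 74)
  sites <- gr(tr$sites$chrom, tr$sites$start, tr$sites$end)
  pk_gr <- gr(peaks$chrom, peaks$position, peaks$position)
  # most called peaks sit in true sites, most sites get a peak
  expect_gt(mean(IRanges::overlapsAny(pk_gr, sites)), 0.8)
  expect_gt(mean(IRanges::overlapsAny(sites, pk_gr)), 0.8)
})
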