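test_that("pwm_from_sites counts column frequencies and GC", {
  p <- pwm_from_sites(c("GG", "GG"), pseudo_count = 0)
  expect_equal(unname(p$matrix["G", ]), c(1, 1))
  expect_equal(p$gc_content, 1.0)

  p2 <- pwm_from_sites(c("AC", "AC", "AT", "AG"), pseudo_count = 0)
  expect_equal(unname(p2$matrix[, 2]),
               c(0, 0.5, 0.25, 0.25))  # A C G T
  expect_equal(p2$gc_content, mean(c(0, 0.5 + 0.25)))

  expect_error(pwm_from_sites(c("AC", "ACG")), "length")
  expect_error(pwm_from_sites(c("AX")), "non-ACGT")

  set.seed(121)
  sites <- vapply(1:2000, function(i) {
    paste(sample(c("A", "C", "G", "T"), 6, replace = TRUE), collapse = "")
  }, "")
  expect_equal(pwm_from_sites(sites)$gc_content, 0.5, tolerance = 0.03)
})

test_that("MEME minimal format round-trips PWMs", {
  pwms <- list(m1 = pwm_with_gc("m1", 0.7),
               shuf_m1 = pwm_with_gc("shuf_m1", 0.3))
  path <- withr::local_tempfile(fileext = ".meme")
  write_meme(pwms, path)
  back <- read_meme(path)
  expect_equal(names(back), c("m1", "shuf_m1"))
  expect_equal(back$m1$matrix, pwms$m1$matrix, tolerance = 1e-5)
  expect_true(back$shuf_m1$is_shuffled_control)
  expect_false(back$m1$is_shuffled_control)
})

test_that("consensus p-value matches the closed form under uniform background", {
  p <- pwm_from_sites("GGGG", pseudo_count = 0)
  hits <- scan_genome(p, c(s = "AAAGGGGAAA"), pvalue_threshold = 1,
                      background = rep(0.25, 4))
  best <- hits[which.max(hits$score), ]
  expect_equal(best$position, 4L)
  expect_equal(best$p, 0.25^4)
})

test_that("scanning is strand symmetric", {
  set.seed(131)
  genome <- paste(sample(c("A", "C", "G", "T"), 4000, replace = TRUE),
                  collapse = "")
  revcomp <- chartr("ACGT", "TGCA", paste(rev(strsplit(genome, "")[[1]]),
                                          collapse = ""))
  pwm <- pwm_from_sites(c("ACGTAC", "ACGTAC", "ACGGAC", "TCGTAC"))
  h1 <- scan_genome(pwm, c(g = genome), pvalue_threshold = 0.01,
                    background = rep(0.25, 4))
  h2 <- scan_genome(pwm, c(g = revcomp), pvalue_threshold = 0.01,
                    background = rep(0.25, 4))
  expect_equal(nrow(h1), nrow(h2))
  expect_equal(sort(h1$score), sort(h2$score), tolerance = 1e-9)
})

test_that("planted consensus sites are recovered", {
  set.seed(132)
  chars <- sample(c("A", "C", "G", "T"), 5000, replace = TRUE)
  planted <- seq(100, by = 500, length.out = 10)
  for (s in planted) chars[s:(s + 7)] <- strsplit("ACGGTCAT", "")[[1]]
  genome <- paste(chars, collapse = "")
  pwm <- pwm_from_sites(rep("ACGGTCAT", 5))
  hits <- scan_genome(pwm, c(g = genome), pvalue_threshold = 1e-3)
  expect_gte(nrow(hits), 10)
  expect_true(all(planted %in% hits$position[hits$strand == "+"]))
})

test_that("match p-values are super-uniform under the background model", {
  set.seed(133)
  genome <- paste(sample(c("A", "C", "G", "T"), 20000, replace = TRUE),
                  collapse = "")
  pwm <- pwm_with_gc("x", 0.6, width = 8L)
  hits <- scan_genome(pwm, c(g = genome), pvalue_threshold = 1,
                      background = rep(0.25, 4))
  n <- nrow(hits)
  for (t in c(0.01, 0.05, 0.2)) {
    frac <- sum(hits$p <= t) / n
    expect_lte(frac, t + 3 * sqrt(t * (1 - t) / n) + 0.01)
  }
})

test_that("count-matching keeps the best matches and drops overshooting ties", {
  cand <- data.frame(p = c(0.001, 0.002, 0.01, 0.01, 0.01, 0.2,
                           0.3, 0.4, 0.5, 0.6))
  kept <- match_count_threshold(cand, 6)
  expect_equal(nrow(kept), 6)
  expect_equal(max(kept$p), 0.2)
  # ties at ranks 3-5 overshoot a target of 3: all dropped
  kept3 <- match_count_threshold(cand, 3)
  expect_equal(nrow(kept3), 2)
  expect_true(all(kept3$p <= 0.002))
  expect_equal(nrow(match_count_threshold(cand, 100)), nrow(cand))
  expect_equal(nrow(match_count_threshold(cand, 0)), 0)
})

test_that("replicated sensitivity rules match hand-computed labels", {
  # each reduction > 2x but average reduction ~3.54x < 4x -> neither
  expect_equal(as.character(classify_enhancer_sensitivity(0.4, 0.2)),
               "neither")
  expect_equal(as.character(classify_enhancer_sensitivity(0.2, 0.2)),
               "sensitive")
  expect_equal(as.character(classify_enhancer_sensitivity(0.9, 1.1)),
               "insensitive")
  expect_error(classify_enhancer_sensitivity(0.5, mode = "mef"),
               "both replicates")
})

test_that("single-comparison sensitivity rules follow the thresholds", {
  expect_equal(as.character(classify_enhancer_sensitivity(1.2, mode = "human")),
               "insensitive")
  expect_equal(as.character(classify_enhancer_sensitivity(2.5, mode = "human")),
               "sensitive")
  expect_equal(as.character(
    classify_enhancer_sensitivity(0.3, mode = "human", direction = "loss")),
    "sensitive")
})

test_that("sensitivity classes are mutually exclusive on random inputs", {
  set.seed(141)
  fc1 <- exp(rnorm(500)); fc2 <- exp(rnorm(500))
  cls <- classify_enhancer_sensitivity(fc1, fc2)
  gm <- sqrt(fc1 * fc2)
  sens <- fc1 < 0.5 & fc2 < 0.5 & gm < 0.25
  insens <- fc1 > 0.5 & fc1 < 2 & fc2 > 0.5 & fc2 < 2 &
    gm > 1 / 1.5 & gm < 1.5
  expect_false(any(sens & insens))
  expect_equal(cls == "sensitive", sens, ignore_attr = TRUE)
  expect_equal(cls == "insensitive", insens, ignore_attr = TRUE)
})

test_that("GC-corrected enrichment is near 1 under a confounded null", {
  set.seed(151)
  n_motifs <- 80
  gc <- runif(n_motifs, 0.2, 0.8)
  # confound: raw ratio drifts with motif GC, no differential planting
  drift <- exp(2 * (gc - 0.5))
  base <- rpois(n_motifs, 400)
  counts <- data.frame(
    motif_id = paste0("m", seq_len(n_motifs)), gc = gc,
    observed_sensitive = rpois(n_motifs, 400 * drift),
    observed_insensitive = base + 1L
  )
  out <- gc_corrected_enrichment(counts)
  # conditional-binomial envelope: accounts for Poisson noise in both counts
  cr <- out$expected_sensitive / out$observed_insensitive
  n_tot <- out$observed_sensitive + out$observed_insensitive
  p_null <- cr / (1 + cr)
  in_env <- out$observed_sensitive >= qbinom(0.025, n_tot, p_null) &
    out$observed_sensitive <= qbinom(0.975, n_tot, p_null)
  expect_gte(mean(in_env), 0.9)
})

test_that("a differentially planted motif tops the corrected ranking", {
  set.seed(152)
  n_motifs <- 60
  gc <- runif(n_motifs, 0.2, 0.8)
  drift <- exp(2 * (gc - 0.5))
  counts <- data.frame(
    motif_id = paste0("m", seq_len(n_motifs)), gc = gc,
    observed_sensitive = rpois(n_motifs, 300 * drift),
    observed_insensitive = rpois(n_motifs, 300) + 1L
  )
  counts$observed_sensitive[7] <- rpois(1, 3 * 300 * drift[7])
  out <- gc_corrected_enrichment(counts)
  expect_equal(out$motif_id[1], "m7")
  expect_equal(out$enrichment[1], 3, tolerance = 0.35)
})

test_that("corrected enrichment is stable under uniform count rescaling", {
  set.seed(153)
  gc <- runif(50, 0.25, 0.75)
  counts <- data.frame(motif_id = paste0("m", 1:50), gc = gc,
                       observed_sensitive = rpois(50, 500),
                       observed_insensitive = rpois(50, 500))
  a <- gc_corrected_enrichment(counts)
  counts2 <- counts
  counts2$observed_sensitive <- counts2$observed_sensitive * 2L
  counts2$observed_insensitive <- counts2$observed_insensitive * 2L
  b <- gc_corrected_enrichment(counts2)
  m <- match(a$motif_id, b$motif_id)
  expect_equal(a$enrichment, b$enrichment[m], tolerance = 0.01)
})

test_that("corrected enrichment rejects degenerate inputs", {
  base <- data.frame(motif_id = paste0("m", 1:30), gc = runif(30),
                     observed_sensitive = 0L, observed_insensitive = 0L)
  expect_error(gc_corrected_enrichment(base), "zero")
  few <- data.frame(motif_id = paste0("m", 1:30), gc = runif(30),
                    observed_sensitive = 5L,
                    observed_insensitive = rep(c(1L, 0L), c(5, 25)))
  expect_error(gc_corrected_enrichment(few), "at least")
})

test_that("motif similarity finds identity, reverse complements and rejects shuffles", {
  set.seed(161)
  consensus <- sample(c("A", "C", "G", "T"), 10, replace = TRUE)
  m <- matrix(0.04, 4, 10, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in 1:10) m[consensus[j], j] <- 0.88
  pwm <- pwmotif("m", m)
  expect_equal(motif_similarity(pwm, pwm), 1)
  rc <- pwmotif("rc", enhancerscape:::reverse_complement_pwm(m))
  expect_equal(motif_similarity(pwm, rc), 1)
  worst <- 0
  for (i in 1:100) {
    perm <- sample(10)
    while (all(perm == 1:10)) perm <- sample(10)
    shuf <- pwmotif("s", m[, perm])
    r <- motif_similarity(pwm, shuf)
    worst <- max(worst, r)
  }
  expect_lt(worst, 0.85)
})
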