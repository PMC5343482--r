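small_spec <- function(...) {
  synthetic_genome_spec(n_chroms = 1L, chrom_length = 1e6,
                        n_promoter_sites = 30L, n_distal_sites = 30L, ...)
}

test_that("the genome spec enforces its invariants", {
  expect_error(synthetic_genome_spec(background_rate = 0), "positive")
  expect_error(synthetic_genome_spec(enrichment_fold = 0.5), "at least 1")
  expect_error(synthetic_genome_spec(n_chroms = 1, chrom_length = 1e5,
                                     n_promoter_sites = 50,
                                     n_distal_sites = 50), "too small")
  expect_error(generate_tag_library(small_spec(), ip_efficiency = -1),
               "positive")
})

test_that("generators are bit-identical under a fixed seed", {
  spec <- small_spec(seed = 7L)
  a <- generate_tag_library(spec, seed = 7L)
  b <- generate_tag_library(spec, seed = 7L)
  expect_identical(a$tags, b$tags)
  c <- generate_tag_library(spec, seed = 8L)
  expect_false(identical(a$tags, c$tags))
  expect_identical(ground_truth(spec)$sites, ground_truth(spec)$sites)
})

test_that("without enrichment IP and input libraries are exchangeable", {
  spec <- small_spec(enrichment_fold = 1, seed = 9L)
  tr <- ground_truth(spec)
  ip <- generate_tag_library(spec, sample_role = "IP", seed = 10L)
  input <- generate_tag_library(spec, sample_role = "input", seed = 11L)
  sites <- gr(tr$sites$chrom, tr$sites$start, tr$sites$end)
  n_ip <- sum(enhancerscape:::region_tag_counts(ip, sites))
  n_in <- sum(enhancerscape:::region_tag_counts(input, sites))
  # both are Poisson draws with the same mean: rate * total site width
  lambda <- spec$background_rate * 1000 * 60
  expect_gte(min(n_ip, n_in), qpois(1e-5, lambda))
  expect_lte(max(n_ip, n_in), qpois(1 - 1e-5, lambda))
})

test_that("sensitive sites lose signal at the planted fold", {
  spec <- synthetic_genome_spec(n_chroms = 1L, chrom_length = 2e6,
                                n_promoter_sites = 0L, n_distal_sites = 100L,
                                fraction_sensitive = 0.5,
                                sensitive_fold = 0.25, seed = 12L)
  tr <- ground_truth(spec)
  wt <- generate_tag_library(spec, "WT", seed = 13L)
  mut <- generate_tag_library(spec, "mutant", seed = 14L)
  sens <- gr(tr$sites$chrom, tr$sites$start, tr$sites$end)[tr$sites$sensitive]
  n_wt <- sum(enhancerscape:::region_tag_counts(wt, sens))
  n_mut <- sum(enhancerscape:::region_tag_counts(mut, sens))
  ratio <- n_mut / n_wt
  # Poisson-thinning expectation: ratio = 0.25 within sampling error
  se <- 0.25 * sqrt(1 / n_mut + 1 / n_wt)
  expect_lt(abs(ratio - 0.25), 4 * se + 0.01)
})

test_that("tag totals scale with IP efficiency, region ratios do not", {
  spec <- small_spec(seed = 15L)
  tr <- ground_truth(spec)
  lo <- generate_tag_library(spec, ip_efficiency = 0.5, seed = 16L)
  hi <- generate_tag_library(spec, ip_efficiency = 1.0, seed = 16L)
  # expected totals: bg * G + bg * w * n_sites * (E * e - 1)
  tot <- function(e) {
    spec$background_rate * 1e6 +
      spec$background_rate * 1000 * 60 * (spec$enrichment_fold * e - 1)
  }
  expect_equal(total_mapped(lo) / total_mapped(hi), tot(0.5) / tot(1),
               tolerance = 0.05)
  # within-sample site-to-site count ratios are efficiency-independent
  sites <- gr(tr$sites$chrom, tr$sites$start, tr$sites$end)
  c_lo <- enhancerscape:::region_tag_counts(lo, sites)
  c_hi <- enhancerscape:::region_tag_counts(hi, sites)
  half <- seq_len(30)
  r_lo <- sum(c_lo[half]) / sum(c_lo[-half])
  r_hi <- sum(c_hi[half]) / sum(c_hi[-half])
  expect_equal(r_lo, r_hi, tolerance = 0.1)
})

test_that("motif landscape is uniform without the GC confound", {
  spec <- synthetic_genome_spec(n_chroms = 1L, chrom_length = 4e6,
                                n_promoter_sites = 0L, n_distal_sites = 200L,
                                fraction_sensitive = 0.5, seed = 17L)
  tr <- ground_truth(spec)
  pwms <- lapply(seq(0.2, 0.8, length.out = 10), function(g) {
    pwm_with_gc(sprintf("m%.2f", g), g)
  })
  names(pwms) <- vapply(pwms, `[[`, "", "id")
  land <- generate_motif_landscape(tr, pwms, gc_confound_strength = 0,
                                   occurrences_per_site = 20, seed = 18L)
  sens <- gr(land$sites$chrom, land$sites$start,
             land$sites$end)[land$sites$sensitive]
  insens <- gr(land$sites$chrom, land$sites$start,
               land$sites$end)[!land$sites$sensitive]
  cs <- count_motif_occurrences(land$motif_map, sens, names(pwms))
  ci <- count_motif_occurrences(land$motif_map, insens, names(pwms))
  # equal region counts, equal rates: ratios compatible with 1
  for (m in names(pwms)) {
    expect_gt(binom.test(cs[[m]], cs[[m]] + ci[[m]], 0.5)$p.value, 1e-4)
  }
  expect_error(generate_motif_landscape(tr, list()), "non-empty")
})

test_that("a planted motif is flagged by the corrected enrichment", {
  spec <- synthetic_genome_spec(n_chroms = 1L, chrom_length = 4e6,
                                n_promoter_sites = 0L, n_distal_sites = 200L,
                                fraction_sensitive = 0.5, seed = 19L)
  tr <- ground_truth(spec)
  pwms <- lapply(seq(0.2, 0.8, length.out = 30), function(g) {
    pwm_with_gc(sprintf("m%.3f", g), g)
  })
  names(pwms) <- vapply(pwms, `[[`, "", "id")
  land <- generate_motif_landscape(tr, pwms, gc_confound_strength = 1,
                                   occurrences_per_site = 15,
                                   plant_motif = names(pwms)[15],
                                   plant_fold = 3, seed = 20L)
  sens <- gr(land$sites$chrom, land$sites$start,
             land$sites$end)[land$sites$sensitive]
  insens <- gr(land$sites$chrom, land$sites$start,
               land$sites$end)[!land$sites$sensitive]
  counts <- data.frame(
    motif_id = names(pwms),
    gc = vapply(pwms, `[[`, numeric(1), "gc_content"),
    observed_sensitive = count_motif_occurrences(land$motif_map, sens,
                                                 names(pwms)),
    observed_insensitive = count_motif_occurrences(land$motif_map, insens,
                                                   names(pwms))
  )
  out <- gc_corrected_enrichment(counts)
  expect_equal(out$motif_id[1], names(pwms)[15])
})

test_that("expression coupling limits behave as designed", {
  spec <- synthetic_genome_spec(n_chroms = 1L, chrom_length = 8e6,
                                n_promoter_sites = 200L,
                                n_distal_sites = 300L,
                                fraction_sensitive = 0.4, seed = 21L)
  tr <- ground_truth(spec)
  # coupling 1, dispersion 0: gene log2 change equals the enhancer change
  exact <- generate_expression_table(tr, coupling = 1, dispersion = 0,
                                     seed = 22L)
  truth <- attr(exact, "true_log2_change")
  expect_equal(log2(exact$value_2 / exact$value_1), unname(truth))
  # coupling 0: no association between sensitivity and expression change
  null <- generate_expression_table(tr, coupling = 0, dispersion = 0.05,
                                    seed = 23L)
  truth1 <- attr(generate_expression_table(tr, coupling = 1, dispersion = 0,
                                           seed = 23L), "true_log2_change")
  obs <- log2(null$value_2 / null$value_1)
  affected <- truth1 < 0
  expect_gt(t.test(obs[affected], obs[!affected])$p.value, 0.001)
})

test_that("group medians follow enhancer fold-change categories", {
  spec <- synthetic_genome_spec(n_chroms = 1L, chrom_length = 2e7,
                                n_promoter_sites = 500L,
                                n_distal_sites = 500L, seed = 24L)
  tr <- ground_truth(spec)
  set.seed(25)
  folds <- c(0.2, 0.5, 1, 2)
  tr$sites$fold_change[tr$sites$class == "distal"] <-
    sample(folds, sum(tr$sites$class == "distal"), replace = TRUE)
  tab <- generate_expression_table(tr, coupling = 0.5, dispersion = 0.02,
                                   seed = 26L)
  obs <- log2(tab$value_2 / tab$value_1)
  truth <- attr(tab, "true_log2_change")
  meds <- vapply(0.5 * log2(folds), function(t) {
    median(obs[abs(truth - t) < 1e-9])
  }, numeric(1))
  expect_true(all(diff(meds) > 0))
})
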