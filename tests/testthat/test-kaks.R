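test_that("identical sequences give zero rates and an undefined ratio", {
  res <- ng86("ATGGCTAAATTA", "ATGGCTAAATTA")
  expect_identical(res$ka, 0)
  expect_identical(res$ks, 0)
  expect_true(is.na(res$ratio))
  expect_identical(res$category, "undefined")
})

test_that("a single synonymous Leu change matches hand-computed NG86 arithmetic", {
  # Bare TTA vs TTG: the hand count gives S = 2/3 sites and one synonymous
  # difference, so pS = 1.5 >= 3/4 and the Jukes-Cantor correction is
  # undefined while Ka stays exactly 0.
  bare <- ng86("TTA", "TTG")
  expect_identical(bare$ka, 0)
  expect_true(is.na(bare$ks))
  expect_identical(bare$category, "undefined")
  expect_equal(bare$n_syn_sites, 2 / 3, tolerance = 1e-12)

  # GGATTA vs GGATTG, fully by hand under the stop-excluded site counting:
  # s(GGA) = 1 (third position wholly synonymous), s(TTA) = s(TTG) = 2/3,
  # so S = (5/3 + 5/3)/2 = 5/3, N = 6 - 5/3; Sd = 1, Nd = 0;
  # pS = 3/5, Ks = -(3/4) log(1 - 4/5) = 1.2070784...
  res <- ng86("GGATTA", "GGATTG")
  expect_equal(res$n_syn_sites, 5 / 3, tolerance = 1e-12)
  expect_equal(res$n_syn_diffs, 1, tolerance = 1e-12)
  expect_identical(res$n_nonsyn_diffs, 0)
  expect_identical(res$ka, 0)
  expect_equal(res$ks, -0.75 * log(1 - 0.8), tolerance = 1e-12)
  expect_equal(res$ratio, 0)
  expect_identical(res$category, "strong_purifying")
})

test_that("multi-substitution codons average over stop-free minimal pathways", {
  # TTA (Leu) vs CTG (Leu): positions 1 and 3 differ; both orders stay
  # stop-free and each path has 2 synonymous steps (TTA->CTA->CTG and
  # TTA->TTG->CTG), so Sd = 2, Nd = 0.
  res <- ng86("GGAGGAGGATTA", "GGAGGAGGACTG")
  expect_equal(res$n_syn_diffs, 2, tolerance = 1e-12)
  expect_identical(res$n_nonsyn_diffs, 0)
})

test_that("ng86 is symmetric and conserves sites on random diverged pairs", {
  set.seed(71)
  probs <- codon_probs_from_gc3(0.4)
  for (i in 1:5) {
    cds <- paste0("ATG", paste(draw_codons(150, probs), collapse = ""), "TAA")
    pair <- make_homolog_pair(cds, t = 0.5, omega = 0.8)
    ab <- ng86(pair$seq_a, pair$seq_b)
    ba <- ng86(pair$seq_b, pair$seq_a)
    for (field in c("ka", "ks", "ratio", "n_syn_sites", "n_nonsyn_sites",
                    "n_syn_diffs", "n_nonsyn_diffs")) {
      expect_equal(ab[[field]], ba[[field]], tolerance = 1e-12)
    }
    expect_equal(ab$n_syn_sites + ab$n_nonsyn_sites, 3 * ab$n_codons,
                 tolerance = 1e-9)
  }
})

test_that("gap or N codon columns are removed before analysis", {
  res <- ng86("ATGGC-GGATTA", "ATGGCAGGATTG")
  expect_identical(res$n_dropped_codons, 1L)
  expect_identical(res$n_codons, 3L)
  res2 <- ng86("ATGNCAGGATTA", "ATGGCAGGATTA")
  expect_identical(res2$n_dropped_codons, 1L)
})

test_that("purely synonymous divergence yields ka exactly 0", {
  set.seed(72)
  probs <- codon_probs_from_gc3(0.4)
  cds <- paste0("ATG", paste(draw_codons(200, probs), collapse = ""), "TAA")
  pair <- make_homolog_pair(cds, t = 0.4, omega = 1e-12)
  expect_identical(pair$truth$n_nonsyn, 0L)
  expect_gt(pair$truth$n_syn, 0L)
  res <- ng86(pair$seq_a, pair$seq_b)
  expect_identical(res$ka, 0)
  expect_gt(res$ks, 0)
})

test_that("ks grows with divergence time in expectation", {
  set.seed(73)
  probs <- codon_probs_from_gc3(0.4)
  cds <- paste0("ATG", paste(draw_codons(300, probs), collapse = ""), "TAA")
  mean_ks <- vapply(c(0.1, 0.4, 0.9), function(t) {
    mean(vapply(1:8, function(i) {
      pair <- make_homolog_pair(cds, t = t, omega = 0.5)
      ng86(pair$seq_a, pair$seq_b)$ks
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_ks) > 0))
})

test_that("selection categories tally with exact 0.5/1.0 thresholds", {
  tab <- classify_selection(c(0.1, 0.7, 1.5))
  expect_identical(tab$n[tab$category != "undefined"], c(1L, 1L, 1L))
  # boundary values: 0.5 and 1.0 are relaxed purifying
  tab2 <- classify_selection(c(0.5, 1.0, 0.499999, 1.000001))
  expect_identical(tab2$n[tab2$category == "relaxed_purifying"], 2L)
  expect_identical(tab2$n[tab2$category == "strong_purifying"], 1L)
  expect_identical(tab2$n[tab2$category == "positive"], 1L)
  tab3 <- classify_selection(c(NA_real_, NA_real_))
  expect_identical(tab3$n[tab3$category == "undefined"], 2L)
  expect_true(all(is.na(tab3$percent)))
})

test_that("a simulated omega mixture is recovered within binomial bands", {
  set.seed(74)
  probs <- codon_probs_from_gc3(0.4)
  mix <- c(rep(0.2, 100), rep(0.7, 60), rep(1.5, 40))
  ratios <- vapply(mix, function(w) {
    cds <- paste0("ATG", paste(draw_codons(300, probs), collapse = ""), "TAA")
    pair <- make_homolog_pair(cds, t = 0.5, omega = w)
    ng86(pair$seq_a, pair$seq_b)$ratio
  }, numeric(1))
  tab <- classify_selection(ratios)
  n_def <- sum(tab$n[tab$category != "undefined"])
  for (want in list(c("strong_purifying", 0.5), c("relaxed_purifying", 0.3),
                    c("positive", 0.2))) {
    p <- as.numeric(want[2])
    obs <- tab$n[tab$category == want[1]] / n_def
    # 3-sigma binomial band plus a small allowance for estimates leaking
    # across the 0.5/1.0 category boundaries (estimation noise, not
    # sampling noise, so it is not covered by the binomial term)
    expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / n_def) + 0.03)
  }
})

test_that("kaks_pairs pairs homologs by gene name across genomes", {
  base <- make_plastome(small_spec(seed = 75))
  d1 <- derive_plastome(base, t = 0.15, omega = 0.3, seed = 1)
  d2 <- derive_plastome(base, t = 0.15, omega = 0.3, seed = 2)
  ref <- kaks_pairs(list(base$genome, d1$genome, d2$genome), mode = "reference")
  expect_true(all(ref$genome_a == base$genome$id))
  expect_identical(sort(unique(ref$genome_b)), sort(c(d1$genome$id, d2$genome$id)))
  pw <- kaks_pairs(list(base$genome, d1$genome, d2$genome), mode = "pairwise")
  expect_gt(nrow(pw), nrow(ref))
  defined <- ref$ratio[is.finite(ref$ratio)]
  expect_gt(length(defined), 5)
  expect_lt(median(defined), 1)
})
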