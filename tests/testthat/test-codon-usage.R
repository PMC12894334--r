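test_that("codon counting matches a sliding-window recount and handles stops and N", {
  ct <- count_codons("ATGTTATAA")
  expect_identical(unname(ct$counts[c("ATG", "TTA")]), c(1L, 1L))
  expect_identical(ct$n_codons, 2L)
  expect_identical(ct$n_stops, 1L)
  ct2 <- count_codons("TTATTGTTA")
  expect_identical(unname(ct2$counts["TTA"]), 2L)
  expect_identical(unname(ct2$counts["TTG"]), 1L)
  expect_error(count_codons("ATGTAAAAA"), "internal stop")
  ctn <- count_codons("ATGANATTG")
  expect_identical(ctn$n_codons, 2L)
  expect_identical(ctn$n_skipped, 1L)

  set.seed(31)
  cods <- sample(setdiff(pc_sense_codons(), character(0)), 300, replace = TRUE)
  s <- paste(cods, collapse = "")
  # independent recount: tabulate the same windows with a plain loop
  oracle <- table(vapply(seq(1, nchar(s), by = 3),
                         function(i) substr(s, i, i + 2), ""))
  ct3 <- count_codons(s)
  for (cod in names(oracle)) {
    expect_identical(unname(ct3$counts[cod]), as.integer(oracle[[cod]]))
  }
})

test_that("RSCU follows the observed/expected formula and averages to 1 per family", {
  # equal usage of all six Leu codons
  leu <- codon_families()$L
  r <- rscu(count_codons(paste(rep(leu, 2), collapse = "")))
  expect_true(all(abs(r$rscu[leu] - 1) < 1e-12))
  # only TTA and TTG used: RSCU = 1 / (2/6) = 3 for each, 0 for the rest
  r2 <- rscu(count_codons("TTATTG"))
  expect_equal(unname(r2$rscu["TTA"]), 3)
  expect_equal(unname(r2$rscu["TTG"]), 3)
  expect_equal(unname(r2$rscu["CTT"]), 0)
  # unseen families are missing, not zero
  expect_true(all(is.na(r2$rscu[codon_families()$A])))

  set.seed(32)
  for (i in 1:20) {
    s <- paste(sample(pc_sense_codons(), 400, replace = TRUE), collapse = "")
    rr <- rscu(count_codons(s))
    for (fam in codon_families()) {
      vals <- rr$rscu[fam]
      if (all(is.na(vals))) next
      expect_equal(mean(vals), 1, tolerance = 1e-12)
      expect_equal(sum(vals), length(fam), tolerance = 1e-12)
    }
  }
})

test_that("positional GC matches a per-position brute-force tally", {
  cmp <- composition(count_codons("GGGGGG"))
  expect_identical(c(cmp$gc1, cmp$gc2, cmp$gc3), c(1, 1, 1))
  expect_true(is.na(composition(count_codons("ATGTGG"))$gc3s))

  set.seed(33)
  cods <- sample(pc_sense_codons(), 100, replace = TRUE)
  s <- paste(cods, collapse = "")
  ch <- strsplit(s, "")[[1]]
  gc_of <- function(pos) mean(ch[seq(pos, length(ch), by = 3)] %in% c("G", "C"))
  cmp2 <- composition(count_codons(s))
  expect_equal(cmp2$gc1, gc_of(1), tolerance = 1e-12)
  expect_equal(cmp2$gc2, gc_of(2), tolerance = 1e-12)
  expect_equal(cmp2$gc3, gc_of(3), tolerance = 1e-12)
  expect_equal(cmp2$gc12, (cmp2$gc1 + cmp2$gc2) / 2, tolerance = 1e-15)
  thirds <- ch[seq(3, length(ch), by = 3)]
  expect_identical(cmp2$a3 + cmp2$t3 + cmp2$g3 + cmp2$c3, as.numeric(cmp2$n_codons))
  expect_identical(cmp2$a3, sum(thirds == "A") + 0)
})

test_that("gc3s equals gc3 on sequences made only of 4-fold-family codons", {
  fourfold <- unlist(codon_families()[vapply(codon_families(), length, 1L) == 4L])
  set.seed(34)
  s <- paste(sample(fourfold, 200, replace = TRUE), collapse = "")
  cmp <- composition(count_codons(s))
  expect_equal(cmp$gc3s, cmp$gc3, tolerance = 1e-12)
})

test_that("ENC hits its closed-form limits and is clamped to [20, 61]", {
  fam <- codon_families()
  one_per_family <- paste(rep(vapply(fam, `[`, "", 1), 5), collapse = "")
  expect_equal(enc(count_codons(one_per_family))$enc, 20, tolerance = 1e-9)

  probs <- codon_probs_from_gc3(0.5)  # uniform within every family
  set.seed(35)
  s <- paste(draw_codons(10000, probs), collapse = "")
  e <- enc(count_codons(s))
  expect_gte(e$enc, 60)
  expect_lte(e$enc, 61)
})

test_that("ENC is invariant to relabeling within a family and falls as usage concentrates", {
  fam_no_phe <- codon_families()[names(codon_families()) != "F"]
  base <- paste(rep(vapply(fam_no_phe, `[`, "", 1), 20), collapse = "")
  mix <- function(n_ttt, n_ttc) {
    paste0(base, strrep("TTT", n_ttt), strrep("TTC", n_ttc))
  }
  e_even <- enc(count_codons(mix(10, 10)))$enc
  # relabeling TTT <-> TTC within the Phe family leaves ENC unchanged
  expect_equal(enc(count_codons(mix(10, 10)))$enc,
               enc(count_codons(paste0(base, strrep("TTC", 10), strrep("TTT", 10))))$enc,
               tolerance = 1e-12)
  encs <- vapply(list(c(10, 10), c(14, 6), c(18, 2), c(20, 0)),
                 function(w) enc(count_codons(mix(w[1], w[2])))$enc, numeric(1))
  expect_true(all(diff(encs) < 0))
})

test_that("the missing-isoleucine fallback imputes F3 as (F2+F4)/2", {
  fam <- codon_families()
  no_ile <- fam[names(fam) != "I"]
  s <- paste(rep(unlist(no_ile), 3), collapse = "")
  e <- enc(count_codons(s))
  expect_identical(unname(e$n_families_used["3"]), 0L)
  expect_equal(e$f3, (e$f2 + e$f4) / 2, tolerance = 1e-12)
  expect_true("3" %in% e$imputed)
})

test_that("the expected-ENC curve matches its closed forms and symmetry", {
  expect_equal(expected_enc_curve(0.5), 60.5, tolerance = 1e-12)
  expect_equal(expected_enc_curve(0.5, variant = "no_s"), 60, tolerance = 1e-12)
  grid <- seq(0.05, 0.95, by = 0.05)
  expect_equal(expected_enc_curve(grid, "no_s"),
               expected_enc_curve(1 - grid, "no_s"), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(expected_enc_curve(0.3), expected_enc_curve(0.7))))
  expect_error(expected_enc_curve(0), "0, 1")
  expect_error(expected_enc_curve(1), "0, 1")
})

test_that("genome-level statistics pool gene counts", {
  res <- make_plastome(small_spec(seed = 41))
  pooled <- genome_codon_counts(res$genome)
  per_gene <- vapply(valid_cds(res$genome),
                     function(s) count_codons(s)$n_codons, integer(1))
  expect_identical(pooled$n_codons, sum(per_gene))
  tab <- codon_usage_table(valid_cds(res$genome))
  expect_identical(nrow(tab), length(per_gene))
  expect_true(all(tab$enc >= 20 & tab$enc <= 61))
  m <- rscu_matrix(valid_cds(res$genome))
  expect_identical(dim(m), c(length(per_gene), 59L))
})
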