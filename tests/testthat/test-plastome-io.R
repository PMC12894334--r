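test_that("a minimal handwritten record parses to the written sequence and CDS", {
  seqn <- paste0("CCCCC", "ATGTAA", paste(rep("G", 49), collapse = ""))
  path <- withr::local_tempfile(fileext = ".gb")
  write_fixture_gb(path, seqn, c(
    "     CDS             6..11",
    "                     /gene=\"toy1\""))
  g <- parse_genbank(path)
  expect_s3_class(g, "plastid_genome")
  expect_identical(g$sequence, seqn)
  expect_identical(g$length, nchar(seqn))
  expect_true(g$circular)
  expect_identical(g$id, "TEST0001")
  kinds <- vapply(g$features, `[[`, "", "kind")
  expect_identical(sum(kinds == "CDS"), 1L)
  ext <- extract_cds(g)
  expect_identical(ext$gene, "toy1")
  expect_identical(ext$sequence, "ATGTAA")
  expect_true(ext$valid)
})

test_that("origin-spanning and complement locations splice correctly", {
  set.seed(5)
  seqn <- rand_dna(60)
  # hand-built oracle: join(55..60,1..9) splices the two slices in order
  oracle_wrap <- paste0(substr(seqn, 55, 60), substr(seqn, 1, 9))
  # complement(11..22): reverse complement of the slice
  oracle_minus <- revcomp(substr(seqn, 11, 22))
  path <- withr::local_tempfile(fileext = ".gb")
  write_fixture_gb(path, seqn, c(
    "     CDS             join(55..60,1..9)",
    "                     /gene=\"wrapA\"",
    "     CDS             complement(11..22)",
    "                     /gene=\"minusB\""))
  g <- parse_genbank(path)
  f1 <- g$features[[which(vapply(g$features, `[[`, "", "gene_name") == "wrapA")]]
  expect_identical(nrow(f1$parts), 2L)
  ext <- extract_cds(g)
  expect_identical(ext$sequence[ext$gene == "wrapA"], oracle_wrap)
  expect_identical(ext$sequence[ext$gene == "minusB"], oracle_minus)
})

test_that("multi-line locations and complement(join()) resolve in transcript order", {
  set.seed(6)
  seqn <- rand_dna(120)
  oracle <- revcomp(paste0(substr(seqn, 10, 30), substr(seqn, 61, 90)))
  path <- withr::local_tempfile(fileext = ".gb")
  write_fixture_gb(path, seqn, c(
    "     CDS             complement(join(10..30,",
    "                     61..90))",
    "                     /gene=\"ij\""))
  g <- parse_genbank(path)
  ext <- extract_cds(g)
  expect_identical(ext$sequence, oracle)
  p <- g$features[[1]]$parts
  expect_identical(p$strand, c(-1L, -1L))
  expect_identical(p$start[1], 61L)  # transcript order reversed
})

test_that("parse failures and unknown kinds behave as contracted", {
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("LOCUS       X 10 bp DNA linear", "FEATURES", "ORIGIN", "//"), path)
  expect_error(parse_genbank(path), "sequence")
  path2 <- withr::local_tempfile(fileext = ".gb")
  write_fixture_gb(path2, rand_dna(60), c(
    "     misc_feature    5..10",
    "                     /gene=\"odd\""))
  expect_warning(g <- parse_genbank(path2), "other")
  expect_identical(g$features[[1]]$kind, "other")
})

test_that("CDS QC flags length and internal-stop problems without dropping them", {
  set.seed(7)
  seqn <- paste0("ATGTAATAA", "ATGAAAG", rand_dna(44))
  path <- withr::local_tempfile(fileext = ".gb")
  write_fixture_gb(path, seqn, c(
    "     CDS             1..9",
    "                     /gene=\"stopper\"",
    "     CDS             10..16",
    "                     /gene=\"offframe\""))
  g <- parse_genbank(path)
  ext <- extract_cds(g)
  expect_identical(nrow(ext), 2L)
  expect_false(any(ext$valid))
  expect_setequal(ext$reason, c("internal_stop", "length_not_multiple_of_3"))
  expect_length(valid_cds(g), 0L)
})

test_that("region labels partition the genome with CDS > intron > IGS precedence", {
  g1 <- plastid_genome("r1", rand_dna(1000), features = list(
    gene_feature("a", "CDS", data.frame(start = 1, end = 300, strand = 1))))
  ann1 <- classify_regions(g1)
  tab1 <- region_table(ann1)
  expect_identical(tab1$bases, c(300L, 0L, 700L))

  g2 <- plastid_genome("r2", rand_dna(1000), features = list(
    gene_feature("b", "CDS", data.frame(start = c(1, 201), end = c(100, 300),
                                        strand = 1))))
  ann2 <- classify_regions(g2)
  expect_true(all(region_at(ann2, 101:200) == "intron"))
  expect_true(all(region_at(ann2, 1:100) == "CDS"))

  # overlapping CDS and intron-bearing tRNA, checked against per-base brute force
  g3 <- plastid_genome("r3", rand_dna(500), features = list(
    gene_feature("c", "CDS", data.frame(start = 50, end = 130, strand = 1)),
    gene_feature("t", "tRNA", data.frame(start = c(100, 200), end = c(150, 240),
                                         strand = 1))))
  ann3 <- classify_regions(g3)
  brute <- rep("IGS", 500)
  brute[151:199] <- "intron"  # gap between the tRNA's parts
  brute[50:130] <- "CDS"      # CDS precedence over everything
  expect_identical(region_at(ann3, 1:500), brute)
  expect_identical(sum(region_table(ann3)$bases), 500L)
})

test_that("generator output round-trips through GenBank without warnings", {
  res <- make_plastome(small_spec(seed = 3))
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(res$genome, path)
  expect_no_warning(g2 <- parse_genbank(path))
  expect_identical(g2$sequence, res$genome$sequence)
  expect_identical(g2$id, res$genome$id)
  ext1 <- extract_cds(res$genome)
  ext2 <- extract_cds(g2)
  expect_identical(ext1$sequence, ext2$sequence)
  expect_true(all(ext2$valid))
})

test_that("extraction is invariant under whole-genome reverse complement", {
  res <- make_plastome(small_spec(seed = 8))
  g <- res$genome
  n <- g$length
  flip <- function(f) {
    p <- f$parts
    q <- data.frame(start = n - p$end + 1L, end = n - p$start + 1L,
                    strand = -p$strand, wraps = p$wraps)  # transcript order kept
    gene_feature(f$gene_name, f$kind, q, f$product)
  }
  g_rc <- plastid_genome(g$id, revcomp(g$sequence), g$species, g$circular,
                         lapply(g$features, flip))
  ext <- extract_cds(g)
  ext_rc <- extract_cds(g_rc)
  expect_setequal(paste(ext$gene, ext$sequence), paste(ext_rc$gene, ext_rc$sequence))
})
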