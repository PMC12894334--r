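# Synthetic plastome generator with exact ground truth for every pipeline
# stage: quadripartite structure, codon usage, SSR content and Ka/Ks.
#
# Design: the genome is assembled as LSC + IRb + SSC + IRa with IRa the exact
# reverse complement of IRb. Protein-coding genes are drawn codon-by-codon
# from per-family codon probability vectors (start codon ATG, one terminal
# stop); tRNA/rRNA genes are composition-matched filler with features.
# Planted SSRs are inserted with 10 bp guards whose junction bases are fixed
# so the planted locus is exactly maximal; all remaining filler is swept by
# the package's own scanner and point-mutated until no unplanned
# threshold-passing repeat survives outside coding sequence (rare emergent
# repeats inside CDS are recorded in the truth table instead of mutated, to
# keep codon draws untouched).

DNA_BASES <- c("A", "C", "G", "T")
BASE_COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Codon sampling probabilities from a GC3 target
#'
#' Amino acids are used uniformly (1/20 each); within each synonymous family
#' a codon's weight is `gc3` if its third base is G/C and `1 - gc3`
#' otherwise, normalized within the family. ATG and TGG receive the full
#' 1/20 of their amino acids.
#'
#' @param gc3 Target GC fraction at synonymous third positions, in (0, 1).
#' @return Named probability vector over the 61 sense codons (sums to 1).
#' @export
codon_probs_from_gc3 <- function(gc3) {
  stopifnot(gc3 > 0, gc3 < 1)
  bm <- codon_base_matrix()
  code <- plastid_genetic_code()
  sense <- pc_sense_codons()
  aa <- code[sense]
  n_aa <- length(unique(aa))
  probs <- stats::setNames(numeric(length(sense)), sense)
  for (a in unique(aa)) {
    codons <- sense[aa == a]
    w <- ifelse(bm[codons, 3] %in% c("G", "C"), gc3, 1 - gc3)
    probs[codons] <- (1 / n_aa) * w / sum(w)
  }
  probs
}

#' Draw sense codons from a probability vector
#'
#' @param n Number of codons.
#' @param probs Named probability vector over sense codons (e.g. from
#'   [codon_probs_from_gc3()]).
#' @param seed Optional integer seed.
#' @return Character vector of codons.
#' @export
draw_codons <- function(n, probs, seed = NULL) {
  with_seed(seed, sample(names(probs), n, replace = TRUE, prob = probs))
}

random_filler <- function(len, at_frac) {
  if (len <= 0L) return("")
  p <- c(A = at_frac / 2, C = (1 - at_frac) / 2,
         G = (1 - at_frac) / 2, T = at_frac / 2)
  paste(sample(DNA_BASES, len, replace = TRUE, prob = p[DNA_BASES]), collapse = "")
}

#' Default planted SSR set
#'
#' Twelve loci spanning all unit-length categories and the three genomic
#' region classes. CDS-planted motifs are trinucleotide, stop-free in frame,
#' with spans that are multiples of 3.
#'
#' @return Data frame with columns `motif`, `copies`, `region`.
#' @export
default_planted_ssrs <- function() {
  data.frame(
    motif = c("A", "T", "AT", "TA", "AG", "AAT", "AAAT", "AATAT", "AATGCT",
              "A", "GCT", "AAG"),
    copies = c(12L, 11L, 6L, 5L, 5L, 5L, 3L, 3L, 3L, 13L, 4L, 4L),
    region = c(rep("IGS", 9L), "intron", "CDS", "CDS"))
}

#' Specification for a synthetic plastome
#'
#' Defaults mirror the canonical citrus-type plastome: a circle
#' with LSC 87,673 bp, SSC 15,866 bp and 26,802 bp inverted repeats,
#' 86 protein-coding genes, 37 tRNA and 8 rRNA (4 per IR) features, a
#' synonymous third-position GC target of 0.32 and AT-rich (0.70)
#' intergenic filler.
#'
#' @param seed Integer seed; one seed drives every random draw.
#' @param lsc_len,ssc_len,ir_len Region lengths in bp.
#' @param n_genes Number of protein-coding genes.
#' @param gene_len_range Range of internal codons per gene (start/stop added).
#' @param intron_fraction Fraction of coding genes given one intron.
#' @param intron_len_range Intron length range in bp.
#' @param gc3 Third-position GC target used when `codon_probs` is NULL.
#' @param codon_probs Optional named probability vector over sense codons.
#' @param igs_at AT fraction of intergenic/intron/structural filler.
#' @param n_trna Number of tRNA features (placed in the LSC).
#' @param n_rrna_per_ir Number of rRNA features per inverted repeat.
#' @param planted_ssrs Data frame of SSRs to plant (see
#'   [default_planted_ssrs()]).
#' @param id,species Identifiers for the emitted genome.
#' @return An object of class `synthetic_plastome_spec`.
#' @export
synthetic_plastome_spec <- function(seed = 1L,
                                    lsc_len = 87673L, ssc_len = 15866L,
                                    ir_len = 26802L,
                                    n_genes = 86L,
                                    gene_len_range = c(100L, 300L),
                                    intron_fraction = 0.15,
                                    intron_len_range = c(250L, 600L),
                                    gc3 = 0.32, codon_probs = NULL,
                                    igs_at = 0.63,
                                    n_trna = 37L, n_rrna_per_ir = 4L,
                                    planted_ssrs = default_planted_ssrs(),
                                    id = NULL, species = "synthetic plastome") {
  stopifnot(lsc_len > 0, ssc_len > 0, ir_len > 0, n_genes >= 1,
            gene_len_range[1] >= 10L, gene_len_range[2] >= gene_len_range[1],
            intron_fraction >= 0, intron_fraction <= 1,
            igs_at > 0, igs_at < 1, n_trna >= 0, n_rrna_per_ir >= 0)
  if (lsc_len < ssc_len) stop("lsc_len must be >= ssc_len (LSC is the larger region)",
                              call. = FALSE)
  if (!is.null(codon_probs)) {
    stopifnot(setequal(names(codon_probs), pc_sense_codons()),
              abs(sum(codon_probs) - 1) < 1e-8, all(codon_probs >= 0))
  }
  planted_ssrs <- as.data.frame(planted_ssrs)
  if (nrow(planted_ssrs)) {
    stopifnot(all(c("motif", "copies", "region") %in% names(planted_ssrs)))
    planted_ssrs$motif <- toupper(planted_ssrs$motif)
    stopifnot(all(nchar(planted_ssrs$motif) >= 1L),
              all(nchar(planted_ssrs$motif) <= 6L),
              all(planted_ssrs$region %in% c("CDS", "intron", "IGS")))
    ok_prim <- vapply(planted_ssrs$motif, is_primitive_motif, logical(1))
    if (!all(ok_prim)) stop("planted motifs must be primitive", call. = FALSE)
    thr <- ssr_thresholds()
    below <- planted_ssrs$copies < thr[as.character(nchar(planted_ssrs$motif))]
    if (any(below)) stop("planted copy numbers below scanning thresholds",
                         call. = FALSE)
    cds_rows <- planted_ssrs$region == "CDS"
    if (any(cds_rows)) {
      span <- nchar(planted_ssrs$motif[cds_rows]) * planted_ssrs$copies[cds_rows]
      if (any(span %% 3L != 0L)) stop("CDS-planted SSR spans must be multiples of 3",
                                      call. = FALSE)
      code <- plastid_genetic_code()
      for (i in which(cds_rows)) {
        rep_seq <- strrep(planted_ssrs$motif[i], planted_ssrs$copies[i])
        cods <- split_codons(rep_seq)
        if (any(code[cods] == "*")) stop("CDS-planted SSR contains an in-frame stop",
                                         call. = FALSE)
      }
    }
  }
  structure(list(seed = as.integer(seed), lsc_len = as.integer(lsc_len),
                 ssc_len = as.integer(ssc_len), ir_len = as.integer(ir_len),
                 n_genes = as.integer(n_genes),
                 gene_len_range = as.integer(gene_len_range),
                 intron_fraction = intron_fraction,
                 intron_len_range = as.integer(intron_len_range),
                 gc3 = gc3, codon_probs = codon_probs, igs_at = igs_at,
                 n_trna = as.integer(n_trna),
                 n_rrna_per_ir = as.integer(n_rrna_per_ir),
                 planted_ssrs = planted_ssrs,
                 id = if (is.null(id)) sprintf("SYN%06d", as.integer(seed)) else id,
                 species = species),
            class = "synthetic_plastome_spec")
}

# Guard of `len` filler bases whose boundary bases are fixed so a planted
# repeat cannot extend across it. `forbid_last`/`forbid_first`: base the
# guard must not end/start with (NA = unconstrained).
make_guard <- function(len, at_frac, forbid_first = NA, forbid_last = NA) {
  g <- strsplit(random_filler(len, at_frac), "")[[1]]
  if (!is.na(forbid_first) && g[1] == forbid_first) {
    g[1] <- sample(setdiff(DNA_BASES, forbid_first), 1L)
  }
  if (!is.na(forbid_last) && g[len] == forbid_last) {
    g[len] <- sample(setdiff(DNA_BASES, forbid_last), 1L)
  }
  paste(g, collapse = "")
}

# Insert `strrep(motif, copies)` into the middle of `filler`, flanked by
# 10 bp guards. Returns list(seq, offset) with 1-based offset of the repeat
# within the returned string.
plant_in_filler <- function(filler, motif, copies, at_frac) {
  k <- nchar(motif)
  span <- k * copies
  need <- span + 20L
  flen <- nchar(filler)
  if (flen < need + 2L) stop("filler too short to plant SSR ", motif, "x", copies,
                             call. = FALSE)
  left_len <- (flen - need) %/% 2L
  right_len <- flen - need - left_len
  gl <- make_guard(10L, at_frac, forbid_last = substr(motif, k, k))
  gr <- make_guard(10L, at_frac, forbid_first = substr(motif, 1L, 1L))
  list(seq = paste0(substr(filler, 1L, left_len), gl, strrep(motif, copies), gr,
                    substr(filler, flen - right_len + 1L, flen)),
       offset = left_len + 10L + 1L)
}

# Pick a sense codon satisfying boundary constraints for CDS planting.
flank_codon <- function(forbid_first = NA, forbid_last = NA) {
  sense <- pc_sense_codons()
  ok <- rep(TRUE, length(sense))
  if (!is.na(forbid_first)) ok <- ok & substr(sense, 1, 1) != forbid_first
  if (!is.na(forbid_last)) ok <- ok & substr(sense, 3, 3) != forbid_last
  sense[ok][1]
}

# ---- region assembly --------------------------------------------------------

# elements: list of lists with fields name, kind ("CDS","tRNA","rRNA"),
# strand, pieces (character vector), piece_types ("exon"/"intron").
# igs_plants: data.frame(motif, copies) to place in intergenic gaps.
# Returns seq plus placement tables with coordinates local to the region.
build_region <- function(total_len, elements, igs_plants, at_frac) {
  elem_len <- vapply(elements, function(e) sum(nchar(e$pieces)), numeric(1))
  n_gaps <- length(elements) + 1L
  base_gap <- 30L
  plant_span <- if (nrow(igs_plants)) {
    nchar(igs_plants$motif) * igs_plants$copies + 22L
  } else integer(0)
  if (nrow(igs_plants) > n_gaps) stop("more IGS plants than intergenic gaps",
                                      call. = FALSE)
  # spread plant-host gaps evenly
  hosts <- if (nrow(igs_plants)) {
    unique(round(seq(1L, n_gaps, length.out = nrow(igs_plants))))
  } else integer(0)
  while (length(hosts) < nrow(igs_plants)) {
    hosts <- c(hosts, setdiff(seq_len(n_gaps), hosts)[1])
  }
  required <- rep(base_gap, n_gaps)
  required[hosts] <- required[hosts] + plant_span
  extra_total <- total_len - sum(elem_len) - sum(required)
  if (extra_total < 0) {
    stop("region of ", total_len, " bp too small for requested content (",
         sum(elem_len) + sum(required), " bp needed)", call. = FALSE)
  }
  w <- stats::runif(n_gaps)
  extra <- floor(extra_total * w / sum(w))
  extra[n_gaps] <- extra[n_gaps] + (extra_total - sum(extra))
  gap_len <- required + extra

  pieces_out <- character(0)
  placed <- list()
  ssrs <- list()
  pos <- 0L
  for (gi in seq_len(n_gaps)) {
    gseq <- random_filler(gap_len[gi], at_frac)
    hi <- match(gi, hosts)
    if (!is.na(hi)) {
      pl <- plant_in_filler(gseq, igs_plants$motif[hi], igs_plants$copies[hi], at_frac)
      gseq <- pl$seq
      span <- nchar(igs_plants$motif[hi]) * igs_plants$copies[hi]
      ssrs[[length(ssrs) + 1L]] <- data.frame(
        motif = igs_plants$motif[hi], copies = igs_plants$copies[hi],
        start = pos + pl$offset, end = pos + pl$offset + span - 1L,
        region = "IGS")
    }
    pieces_out <- c(pieces_out, gseq)
    pos <- pos + nchar(gseq)
    if (gi > length(elements)) break
    e <- elements[[gi]]
    eseq <- paste(e$pieces, collapse = "")
    elen <- nchar(eseq)
    intron_i <- which(e$piece_types == "intron")
    intron_start <- NA_integer_
    intron_end <- NA_integer_
    if (length(intron_i) == 1L) {
      before <- sum(nchar(e$pieces[seq_len(intron_i - 1L)]))
      ilen <- nchar(e$pieces[intron_i])
      if (e$strand == 1L) {
        intron_start <- pos + before + 1L
      } else {
        after <- elen - before - ilen
        intron_start <- pos + after + 1L
      }
      intron_end <- intron_start + ilen - 1L
      if (!is.null(e$intron_ssr)) {
        off <- e$intron_ssr$offset  # offset within intron (plus orientation)
        span <- nchar(e$intron_ssr$motif) * e$intron_ssr$copies
        ssrs[[length(ssrs) + 1L]] <- data.frame(
          motif = e$intron_ssr$motif, copies = e$intron_ssr$copies,
          start = intron_start + off - 1L,
          end = intron_start + off + span - 2L, region = "intron")
      }
    }
    if (!is.null(e$cds_ssr)) {
      off <- e$cds_ssr$offset  # offset within spliced CDS (plus strand only)
      span <- nchar(e$cds_ssr$motif) * e$cds_ssr$copies
      l1 <- if (length(intron_i) == 1L) {
        sum(nchar(e$pieces[seq_len(intron_i - 1L)]))
      } else elen
      gstart <- if (off + span - 1L <= l1) pos + off
      else pos + off + (intron_end - intron_start + 1L)
      ssrs[[length(ssrs) + 1L]] <- data.frame(
        motif = e$cds_ssr$motif, copies = e$cds_ssr$copies,
        start = gstart, end = gstart + span - 1L, region = "CDS")
    }
    genomic <- if (e$strand == 1L) eseq else revcomp(eseq)
    pieces_out <- c(pieces_out, genomic)
    placed[[length(placed) + 1L]] <- data.frame(
      name = e$name, kind = e$kind, strand = e$strand,
      start = pos + 1L, end = pos + elen,
      intron_start = intron_start, intron_end = intron_end,
      sequence = if (e$kind == "CDS") paste(e$pieces[e$piece_types == "exon"],
                                            collapse = "") else eseq)
    pos <- pos + elen
  }
  list(seq = paste(pieces_out, collapse = ""),
       placed = if (length(placed)) do.call(rbind, placed) else NULL,
       ssrs = if (length(ssrs)) do.call(rbind, ssrs) else NULL)
}

# Convert a placed-gene row (genomic coords, intron interval, strand) into
# transcript-ordered feature parts.
gene_parts <- function(row) {
  if (is.na(row$intron_start)) {
    return(data.frame(start = row$start, end = row$end,
                      strand = row$strand, wraps = FALSE))
  }
  ex_low <- c(row$start, row$intron_start - 1L)
  ex_high <- c(row$intron_end + 1L, row$end)
  if (row$strand == 1L) {
    data.frame(start = c(ex_low[1], ex_high[1]), end = c(ex_low[2], ex_high[2]),
               strand = 1L, wraps = FALSE)
  } else {
    data.frame(start = c(ex_high[1], ex_low[1]), end = c(ex_high[2], ex_low[2]),
               strand = -1L, wraps = FALSE)
  }
}

# ---- main generator ---------------------------------------------------------

#' Generate a synthetic annotated plastome with ground truth
#'
#' Deterministic under the spec's seed. IRa is the exact reverse complement
#' of IRb; planted SSRs are exactly maximal; intergenic, intron and
#' structural-RNA filler carries no unplanned threshold-passing repeat
#' (emergent repeats inside coding sequence, which are never mutated, are
#' recorded in the truth table with `planted = FALSE`).
#'
#' @param spec A [synthetic_plastome_spec()].
#' @param path Optional path: write the genome as a GenBank flat file.
#' @return List with `genome` (a [plastid_genome()]) and `truth` (class
#'   `plastome_truth`: `spec`, `regions`, `genes`, `ssrs`, `codon_probs`).
#' @export
make_plastome <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "synthetic_plastome_spec"))
  res <- with_seed(spec$seed, build_plastome_impl(spec))
  if (!is.null(path)) write_genbank(res$genome, path)
  res
}

build_plastome_impl <- function(spec) {
  probs <- if (is.null(spec$codon_probs)) codon_probs_from_gc3(spec$gc3)
  else spec$codon_probs
  code <- plastid_genetic_code()
  at <- spec$igs_at
  n <- spec$n_genes

  n_ssc <- max(1L, round(0.2 * n))
  n_lsc <- n - n_ssc
  gene_len <- sample(seq(spec$gene_len_range[1], spec$gene_len_range[2]),
                     n, replace = TRUE)
  gene_names <- sprintf("cds%03d", seq_len(n))
  in_lsc <- c(rep(TRUE, n_lsc), rep(FALSE, n_ssc))
  strand <- sample(c(1L, -1L), n, replace = TRUE)
  n_intron <- round(spec$intron_fraction * n)
  has_intron <- rep(FALSE, n)
  if (n_intron > 0) has_intron[sample(n, n_intron)] <- TRUE

  planted <- spec$planted_ssrs
  cds_plants <- planted[planted$region == "CDS", , drop = FALSE]
  intron_plants <- planted[planted$region == "intron", , drop = FALSE]
  igs_plants <- planted[planted$region == "IGS", , drop = FALSE]

  # hosts must be plus-strand so the planted motif appears as written
  if (nrow(cds_plants)) {
    cand <- which(in_lsc & gene_len >= 60L)
    cand <- cand[order(-gene_len[cand])][seq_len(nrow(cds_plants))]
    if (anyNA(cand)) stop("not enough genes to host CDS-planted SSRs", call. = FALSE)
    strand[cand] <- 1L
    has_intron[cand] <- FALSE  # keep the planted repeat within one exon
    cds_hosts <- cand
  } else cds_hosts <- integer(0)
  if (nrow(intron_plants)) {
    cand <- setdiff(which(in_lsc & has_intron), cds_hosts)
    if (length(cand) < nrow(intron_plants)) {
      extra <- setdiff(which(in_lsc), c(cds_hosts, cand))[
        seq_len(nrow(intron_plants) - length(cand))]
      has_intron[extra] <- TRUE
      cand <- c(cand, extra)
    }
    intron_hosts <- cand[seq_len(nrow(intron_plants))]
    strand[intron_hosts] <- 1L
  } else intron_hosts <- integer(0)

  codon_lists <- lapply(gene_len, function(L) {
    sample(names(probs), L, replace = TRUE, prob = probs)
  })
  cds_ssr_info <- vector("list", n)
  for (i in seq_along(cds_hosts)) {
    g <- cds_hosts[i]
    motif <- cds_plants$motif[i]
    copies <- cds_plants$copies[i]
    k <- nchar(motif)
    n_rep_codons <- (k * copies) %/% 3L
    cods <- codon_lists[[g]]
    at_codon <- max(2L, (length(cods) - n_rep_codons) %/% 2L)
    rep_codons <- split_codons(strrep(motif, copies))
    cods[at_codon:(at_codon + n_rep_codons - 1L)] <- rep_codons
    # boundary codons prevent the repeat extending into the flanks
    cods[at_codon - 1L] <- flank_codon(forbid_last = substr(motif, k, k))
    cods[at_codon + n_rep_codons] <- flank_codon(forbid_first = substr(motif, 1, 1))
    codon_lists[[g]] <- cods
    # offset of repeat within spliced CDS (ATG occupies codon 0)
    cds_ssr_info[[g]] <- list(motif = motif, copies = copies,
                              offset = 3L * at_codon + 1L)
  }

  make_element <- function(g) {
    cds <- paste0("ATG", paste(codon_lists[[g]], collapse = ""), "TAA")
    e <- list(name = gene_names[g], kind = "CDS", strand = strand[g])
    if (has_intron[g]) {
      ilen <- sample(seq(spec$intron_len_range[1], spec$intron_len_range[2]), 1L)
      iseq <- random_filler(ilen, at)
      hi <- match(g, intron_hosts)
      if (!is.na(hi)) {
        pl <- plant_in_filler(iseq, intron_plants$motif[hi],
                              intron_plants$copies[hi], at)
        iseq <- pl$seq
        e$intron_ssr <- list(motif = intron_plants$motif[hi],
                             copies = intron_plants$copies[hi],
                             offset = pl$offset)
      }
      split_at <- 3L * (nchar(cds) %/% 6L)  # codon-boundary split near middle
      e$pieces <- c(substr(cds, 1L, split_at), iseq,
                    substr(cds, split_at + 1L, nchar(cds)))
      e$piece_types <- c("exon", "intron", "exon")
    } else {
      e$pieces <- cds
      e$piece_types <- "exon"
    }
    if (!is.null(cds_ssr_info[[g]])) e$cds_ssr <- cds_ssr_info[[g]]
    e
  }

  lsc_elements <- lapply(which(in_lsc), make_element)
  if (spec$n_trna > 0) {
    trna <- lapply(seq_len(spec$n_trna), function(i) {
      list(name = sprintf("trn%02d", i), kind = "tRNA",
           strand = sample(c(1L, -1L), 1L),
           pieces = random_filler(sample(70:90, 1L), at), piece_types = "exon")
    })
    ord <- sample(length(lsc_elements) + length(trna))
    lsc_elements <- c(lsc_elements, trna)[ord]
  }
  ssc_elements <- lapply(which(!in_lsc), make_element)
  rrna_len <- c(2900L, 1500L, 120L, 95L)
  ir_elements <- if (spec$n_rrna_per_ir > 0) {
    lapply(seq_len(spec$n_rrna_per_ir), function(i) {
      len <- if (i <= 4L) rrna_len[i] else sample(100:300, 1L)
      list(name = sprintf("rrn%02d", i), kind = "rRNA", strand = 1L,
           pieces = random_filler(len, at), piece_types = "exon")
    })
  } else list()

  lsc <- build_region(spec$lsc_len, lsc_elements, igs_plants, at)
  empty_plants <- igs_plants[0, , drop = FALSE]
  ssc <- build_region(spec$ssc_len, ssc_elements, empty_plants, at)
  irb <- build_region(spec$ir_len, ir_elements, empty_plants, at)

  off_irb <- spec$lsc_len
  off_ssc <- off_irb + spec$ir_len
  off_ira <- off_ssc + spec$ssc_len
  glen <- off_ira + spec$ir_len

  shift <- function(df, off) {
    if (is.null(df)) return(NULL)
    for (col in intersect(c("start", "end", "intron_start", "intron_end"), names(df))) {
      df[[col]] <- df[[col]] + off
    }
    df
  }
  genes <- rbind(shift(lsc$placed, 0L), shift(irb$placed, off_irb),
                 shift(ssc$placed, off_ssc))
  ssr_truth <- rbind(shift(lsc$ssrs, 0L), shift(ssc$ssrs, off_ssc))

  # IRa = exact reverse complement of IRb; rRNA features mirrored
  ira_seq <- revcomp(irb$seq)
  if (!is.null(irb$placed)) {
    mirrored <- irb$placed
    for (ri in seq_len(nrow(mirrored))) {
      s_local <- irb$placed$start[ri]
      e_local <- irb$placed$end[ri]
      mirrored$start[ri] <- off_ira + (spec$ir_len - e_local) + 1L
      mirrored$end[ri] <- off_ira + (spec$ir_len - s_local) + 1L
      mirrored$strand[ri] <- -irb$placed$strand[ri]
      mirrored$sequence[ri] <- irb$placed$sequence[ri]
    }
    genes <- rbind(genes, mirrored)
  }

  sv <- strsplit(paste0(lsc$seq, irb$seq, ssc$seq, ira_seq), "")[[1]]
  stopifnot(length(sv) == glen)

  protected <- rep(FALSE, glen)
  if (!is.null(ssr_truth)) {
    for (ri in seq_len(nrow(ssr_truth))) {
      protected[ssr_truth$start[ri]:ssr_truth$end[ri]] <- TRUE
    }
  }
  cds_mask <- rep(FALSE, glen)
  for (ri in seq_len(nrow(genes))) {
    if (genes$kind[ri] != "CDS") next
    p <- gene_parts(genes[ri, ])
    for (pi in seq_len(nrow(p))) cds_mask[p$start[pi]:p$end[pi]] <- TRUE
    if (!is.na(genes$intron_start[ri])) {
      cds_mask[genes$intron_start[ri]:genes$intron_end[ri]] <- FALSE
    }
  }

  irb_span <- c(off_irb + 1L, off_irb + spec$ir_len)
  ira_span <- c(off_ira + 1L, off_ira + spec$ir_len)
  mirror_pos <- function(p) {
    if (p >= irb_span[1] && p <= irb_span[2]) {
      ira_span[2] - (p - irb_span[1])
    } else if (p >= ira_span[1] && p <= ira_span[2]) {
      irb_span[2] - (p - ira_span[1])
    } else NA_integer_
  }

  # junction guards: the maximal reverse-complementary pair must be exactly
  # the planted IRs, so the flanking bases must not extend the match
  # (IRb's left flank pairs with the base after IRa, i.e. position 1; the
  # SSC's two ends pair with each other).
  fix_ir_junctions <- function(sv) {
    if (sv[off_irb] == BASE_COMP[[sv[1]]]) {
      sv[1] <- setdiff(DNA_BASES, c(BASE_COMP[[sv[off_irb]]], sv[2]))[1]
    }
    s_first <- off_ssc + 1L
    s_last <- off_ira
    if (sv[s_first] == BASE_COMP[[sv[s_last]]]) {
      sv[s_first] <- setdiff(DNA_BASES,
                             c(BASE_COMP[[sv[s_last]]], sv[s_first + 1L]))[1]
    }
    sv
  }
  sv <- fix_ir_junctions(sv)

  truth_key <- if (!is.null(ssr_truth)) {
    paste(ssr_truth$start, ssr_truth$end, ssr_truth$motif)
  } else character(0)
  emergent <- list()
  emergent_key <- character(0)
  for (iter in seq_len(100L)) {
    sv <- fix_ir_junctions(sv)
    loci <- scan_ssrs(paste(sv, collapse = ""))
    if (nrow(loci)) {
      key <- paste(loci$start, loci$end, loci$motif)
      loci <- loci[!(key %in% c(truth_key, emergent_key)), , drop = FALSE]
    }
    if (!nrow(loci)) break
    changed <- FALSE
    for (ri in seq_len(nrow(loci))) {
      span <- loci$start[ri]:loci$end[ri]
      mut <- span[!protected[span] & !cds_mask[span]]
      if (!length(mut)) {  # emergent repeat inside coding sequence: record
        emergent[[length(emergent) + 1L]] <- data.frame(
          motif = loci$motif[ri], copies = loci$copies[ri],
          start = loci$start[ri], end = loci$end[ri], region = "CDS")
        emergent_key <- c(emergent_key,
                          paste(loci$start[ri], loci$end[ri], loci$motif[ri]))
        next
      }
      p <- mut[ceiling(length(mut) / 2)]
      nb <- unique(c(sv[p], sv[max(1L, p - 1L)], sv[min(glen, p + 1L)]))
      choices <- setdiff(DNA_BASES, nb)
      if (!length(choices)) choices <- setdiff(DNA_BASES, sv[p])
      sv[p] <- sample(choices, 1L)
      mp <- mirror_pos(p)
      if (!is.na(mp)) sv[mp] <- BASE_COMP[[sv[p]]]
      changed <- TRUE
    }
    if (!changed) break
    if (iter == 100L) stop("SSR cleanup did not converge", call. = FALSE)
  }

  sequence <- paste(sv, collapse = "")
  features <- lapply(seq_len(nrow(genes)), function(ri) {
    gene_feature(genes$name[ri], genes$kind[ri], gene_parts(genes[ri, ]))
  })
  genome <- plastid_genome(id = spec$id, sequence = sequence,
                           species = spec$species, circular = TRUE,
                           features = features)

  ssrs_all <- rbind(
    if (!is.null(ssr_truth)) cbind(ssr_truth, planted = TRUE) else NULL,
    if (length(emergent)) cbind(do.call(rbind, emergent), planted = FALSE) else NULL)
  if (!is.null(ssrs_all)) {
    ssrs_all$unit_length <- nchar(ssrs_all$motif)
    ssrs_all$canonical_motif <- vapply(ssrs_all$motif, canonical_rotation,
                                       character(1), USE.NAMES = FALSE)
    ssrs_all <- ssrs_all[order(ssrs_all$start), , drop = FALSE]
    rownames(ssrs_all) <- NULL
  }
  regions <- data.frame(
    region = c("LSC", "IRb", "SSC", "IRa"),
    start = c(1L, off_irb + 1L, off_ssc + 1L, off_ira + 1L),
    end = c(off_irb, off_ssc, off_ira, glen))
  rownames(genes) <- NULL
  truth <- structure(list(spec = spec, regions = regions, genes = genes,
                          ssrs = ssrs_all, codon_probs = probs),
                     class = "plastome_truth")
  list(genome = genome, truth = truth)
}

#' @export
print.plastome_truth <- function(x, ...) {
  cat("<plastome_truth>", x$spec$id, "-", nrow(x$genes), "genes,",
      if (is.null(x$ssrs)) 0L else nrow(x$ssrs), "SSR loci\n")
  invisible(x)
}

#' Check a truth table against its emitted genome
#'
#' Re-derives every claim of the truth table directly from the sequence:
#' regions tile the genome and IRa is the exact reverse complement of IRb;
#' every CDS re-extracted from the annotated features equals the recorded
#' coding sequence; every SSR span equals its motif repeated.
#'
#' @param genome A [plastid_genome()] from [make_plastome()].
#' @param truth The matching `plastome_truth`.
#' @return TRUE (invisibly); errors on any inconsistency.
#' @export
validate_truth <- function(genome, truth) {
  r <- truth$regions
  stopifnot(r$start[1] == 1L, all(r$start[-1] == r$end[-4] + 1L),
            r$end[4] == genome$length)
  irb <- substr(genome$sequence, r$start[r$region == "IRb"], r$end[r$region == "IRb"])
  ira <- substr(genome$sequence, r$start[r$region == "IRa"], r$end[r$region == "IRa"])
  if (!identical(ira, revcomp(irb))) stop("IRa is not the reverse complement of IRb",
                                          call. = FALSE)
  ext <- extract_cds(genome)
  for (ri in which(truth$genes$kind == "CDS")) {
    g <- truth$genes[ri, ]
    hit <- ext$sequence[ext$gene == g$name]
    if (!length(hit) || !identical(hit[1], g$sequence)) {
      stop("extracted CDS differs from truth for ", g$name, call. = FALSE)
    }
  }
  if (!is.null(truth$ssrs)) {
    for (ri in seq_len(nrow(truth$ssrs))) {
      s <- truth$ssrs[ri, ]
      obs <- substr(genome$sequence, s$start, s$end)
      if (!identical(obs, strrep(s$motif, s$copies))) {
        stop("SSR span mismatch at ", s$start, call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

# ---- homolog simulation -----------------------------------------------------

#' Simulate a diverged homolog of a coding sequence
#'
#' Single-nucleotide mutation simulation with an acceptance rule that fixes
#' the nonsynonymous/synonymous rate ratio at `omega`: proposed mutations
#' are accepted with probability `min(1, 1/omega)` if synonymous and
#' `min(1, omega)` if nonsynonymous (so `omega > 1` accelerates
#' nonsynonymous fixation instead of requiring probabilities above 1).
#' Mutations creating a stop codon are always rejected, and a terminal stop
#' codon is never mutated. Realized substitution counts are recorded as
#' ground truth.
#'
#' @param cds Coding sequence (length multiple of 3, no internal stop).
#' @param t Expected proposed mutations per codon (divergence dial).
#' @param omega True Ka/Ks of the acceptance rule; must be > 0.
#' @param seed Optional integer seed.
#' @return List of class `homolog_pair`: `seq_a` (input), `seq_b` (mutated),
#'   `gene`, and `truth` with realized counts (`n_syn`, `n_nonsyn`,
#'   `n_proposed`, `n_rejected_stop`, `n_rejected_omega`).
#' @export
make_homolog_pair <- function(cds, t, omega, seed = NULL, gene = NA_character_) {
  if (omega <= 0) stop("omega must be > 0", call. = FALSE)
  if (t < 0) stop("t must be >= 0", call. = FALSE)
  cds <- check_dna(cds, "coding sequence")
  code <- plastid_genetic_code()
  cods <- split_codons(cds)
  aa <- code[cods]
  if (any(aa[-length(aa)] == "*")) stop("internal stop codon in cds", call. = FALSE)
  n_codons <- length(cods)
  editable <- if (aa[length(aa)] == "*") 3L * (n_codons - 1L) else 3L * n_codons
  with_seed(seed, {
    n_prop <- stats::rpois(1L, t * n_codons)
    sv <- strsplit(cds, "")[[1]]
    acc_syn <- min(1, 1 / omega)
    acc_non <- min(1, omega)
    n_syn <- 0L
    n_nonsyn <- 0L
    n_stop <- 0L
    n_omega <- 0L
    for (i in seq_len(n_prop)) {
      p <- sample.int(editable, 1L)
      newb <- sample(setdiff(DNA_BASES, sv[p]), 1L)
      ci <- (p - 1L) %/% 3L
      cod <- paste(sv[(3L * ci + 1L):(3L * ci + 3L)], collapse = "")
      v <- strsplit(cod, "")[[1]]
      v[p - 3L * ci] <- newb
      newcod <- paste(v, collapse = "")
      if (code[[newcod]] == "*") {
        n_stop <- n_stop + 1L
        next
      }
      syn <- code[[newcod]] == code[[cod]]
      acc <- if (syn) acc_syn else acc_non
      if (stats::runif(1L) < acc) {
        sv[p] <- newb
        if (syn) n_syn <- n_syn + 1L else n_nonsyn <- n_nonsyn + 1L
      } else {
        n_omega <- n_omega + 1L
      }
    }
    structure(list(seq_a = cds, seq_b = paste(sv, collapse = ""), gene = gene,
                   truth = list(n_syn = n_syn, n_nonsyn = n_nonsyn,
                                n_proposed = n_prop, n_rejected_stop = n_stop,
                                n_rejected_omega = n_omega,
                                t = t, omega = omega)),
              class = "homolog_pair")
  })
}

#' Derive a diverged genome from a synthetic ancestor
#'
#' Evolves every protein-coding gene of a [make_plastome()] output through
#' [make_homolog_pair()] (so the true omega is known) while leaving
#' non-coding sequence, SSRs and the quadripartite layout untouched. Genes
#' hosting an SSR recorded in the truth table are left unevolved so the
#' recorded repeat spans stay exact; repeats newly emerging from coding
#' mutations are appended to the derived truth with `planted = FALSE`. The
#' result is a cohort member suitable for cross-species codon-usage and
#' Ka/Ks analyses with exact ground truth.
#'
#' @param base List `(genome, truth)` from [make_plastome()].
#' @param t Expected proposed mutations per codon per gene.
#' @param omega True Ka/Ks of the acceptance rule.
#' @param seed Integer seed.
#' @param id,species Identifiers for the derived genome.
#' @return List with `genome`, `truth` (updated coding sequences plus an
#'   `evolution` table of realized per-gene substitution counts).
#' @export
derive_plastome <- function(base, t = 0.05, omega = 0.3, seed = 1L,
                            id = NULL, species = NULL) {
  genome <- base$genome
  truth <- base$truth
  if (is.null(id)) id <- paste0(genome$id, "d", seed)
  sv <- strsplit(genome$sequence, "")[[1]]
  evo <- list()
  frozen <- character(0)
  if (!is.null(truth$ssrs)) {
    in_cds <- truth$ssrs[truth$ssrs$region == "CDS", , drop = FALSE]
    if (nrow(in_cds)) {
      for (ri in which(truth$genes$kind == "CDS")) {
        g <- truth$genes[ri, ]
        if (any(in_cds$start <= g$end & in_cds$end >= g$start)) {
          frozen <- c(frozen, g$name)
        }
      }
    }
  }
  with_seed(seed, {
    for (ri in which(truth$genes$kind == "CDS")) {
      g <- truth$genes[ri, ]
      if (g$name %in% frozen) next
      pair <- make_homolog_pair(g$sequence, t, omega, seed = NULL, gene = g$name)
      new_cds <- pair$seq_b
      parts <- gene_parts(g)
      off <- 0L
      for (pi in seq_len(nrow(parts))) {
        len <- parts$end[pi] - parts$start[pi] + 1L
        piece <- substr(new_cds, off + 1L, off + len)
        if (parts$strand[pi] == -1L) piece <- revcomp(piece)
        sv[parts$start[pi]:parts$end[pi]] <- strsplit(piece, "")[[1]]
        off <- off + len
      }
      truth$genes$sequence[ri] <- new_cds
      evo[[length(evo) + 1L]] <- data.frame(
        gene = g$name, n_syn = pair$truth$n_syn, n_nonsyn = pair$truth$n_nonsyn)
    }
  })
  new_genome <- plastid_genome(id = id, sequence = paste(sv, collapse = ""),
                               species = if (is.null(species))
                                 paste(genome$species, "derived") else species,
                               circular = genome$circular,
                               features = genome$features)
  truth$spec$id <- id
  truth$evolution <- do.call(rbind, evo)
  # coding mutations can create new maximal repeats: record them
  loci <- scan_ssrs(new_genome)
  if (nrow(loci)) {
    have <- if (is.null(truth$ssrs)) character(0)
    else paste(truth$ssrs$start, truth$ssrs$end, truth$ssrs$motif)
    new_rows <- loci[!(paste(loci$start, loci$end, loci$motif) %in% have), ,
                     drop = FALSE]
    if (nrow(new_rows)) {
      ann <- classify_regions(new_genome)
      add <- data.frame(motif = new_rows$motif, copies = new_rows$copies,
                        start = new_rows$start, end = new_rows$end,
                        region = region_at(ann, (new_rows$start + new_rows$end) %/% 2L),
                        planted = FALSE,
                        unit_length = new_rows$unit_length,
                        canonical_motif = new_rows$canonical_motif)
      truth$ssrs <- rbind(truth$ssrs, add[, names(truth$ssrs)])
      truth$ssrs <- truth$ssrs[order(truth$ssrs$start), , drop = FALSE]
      rownames(truth$ssrs) <- NULL
    }
  }
  list(genome = new_genome, truth = truth)
}
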