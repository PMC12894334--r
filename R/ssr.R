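# Perfect microsatellite (SSR) detection with per-unit-length copy-number
# thresholds, genomic-region classification, and cross-species presence
# summaries.
#
# The scanner reports all maximal perfect tandem repeats with primitive
# motifs of unit length 1-6 meeting the thresholds. For each unit length k
# the match vector m[i] = (s[i] == s[i+k]) is run-length encoded; a maximal
# TRUE-run of length L starting at i is a tandem span of length L + k whose
# copy number is floor((L + k) / k). Partial trailing units never add a
# copy. N never matches anything, so it breaks any repeat. The scan is
# linear in sequence length and does not wrap the circular origin, matching
# common scanners.

#' Default SSR copy-number thresholds
#'
#' Minimum copy numbers by motif unit length: 10 for mononucleotide, 5 for
#' dinucleotide, 4 for trinucleotide, and 3 for tetra-, penta- and
#' hexanucleotide repeats.
#'
#' @return Named integer vector (names `"1"`..`"6"`).
#' @export
ssr_thresholds <- function() {
  c(`1` = 10L, `2` = 5L, `3` = 4L, `4` = 3L, `5` = 3L, `6` = 3L)
}

# Is motif primitive, i.e. not a whole power of a shorter string?
is_primitive_motif <- function(motif) {
  k <- nchar(motif)
  if (k == 1L) return(TRUE)
  for (d in seq_len(k - 1L)) {
    if (k %% d == 0L && strrep(substr(motif, 1L, d), k %/% d) == motif) return(FALSE)
  }
  TRUE
}

# Lexicographically minimal rotation of a motif.
canonical_rotation <- function(motif) {
  k <- nchar(motif)
  if (k == 1L) return(motif)
  doubled <- paste0(motif, motif)
  min(substring(doubled, seq_len(k), seq_len(k) + k - 1L))
}

#' Scan a sequence for perfect SSRs
#'
#' @param x A [plastid_genome()] or DNA string.
#' @param thresholds Named integer vector mapping unit length (as name) to
#'   minimum copy number; defaults to [ssr_thresholds()]. Unit lengths absent
#'   from the map are not scanned.
#' @return Data frame with one row per locus: `genome`, `motif`,
#'   `canonical_motif`, `unit_length`, `copies`, `start`, `end`
#'   (1-based inclusive; `end - start + 1 == copies * unit_length`), ordered
#'   by `start` then `unit_length`. Loci sharing an identical span keep only
#'   the shortest unit.
#' @export
scan_ssrs <- function(x, thresholds = ssr_thresholds()) {
  if (inherits(x, "plastid_genome")) {
    s <- x$sequence
    id <- x$id
  } else {
    s <- check_dna(x)
    id <- NA_character_
  }
  n <- nchar(s)
  sv <- charToRaw(s)
  not_n <- sv != charToRaw("N")
  units <- sort(as.integer(names(thresholds)))
  out <- list()
  for (k in units) {
    if (n < 2L * k) next
    thr <- thresholds[[as.character(k)]]
    idx <- seq_len(n - k)
    m <- (sv[idx] == sv[idx + k]) & not_n[idx] & not_n[idx + k]
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    good <- which(r$values & (r$lengths + k) %/% k >= thr)
    for (ri in good) {
      i <- starts[ri]
      copies <- (r$lengths[ri] + k) %/% k
      motif <- substr(s, i, i + k - 1L)
      if (!is_primitive_motif(motif)) next
      out[[length(out) + 1L]] <- data.frame(
        genome = id, motif = motif,
        canonical_motif = canonical_rotation(motif),
        unit_length = k, copies = copies,
        start = i, end = i + copies * k - 1L)
    }
  }
  if (!length(out)) {
    return(data.frame(genome = character(0), motif = character(0),
                      canonical_motif = character(0), unit_length = integer(0),
                      copies = integer(0), start = integer(0), end = integer(0)))
  }
  loci <- do.call(rbind, out)
  loci <- loci[order(loci$start, loci$unit_length), , drop = FALSE]
  # identical spans: keep the shortest unit
  loci <- loci[!duplicated(loci[, c("start", "end")]), , drop = FALSE]
  rownames(loci) <- NULL
  loci
}

#' Classify SSR loci by genomic region
#'
#' Each locus is labelled by the region containing its midpoint
#' (`floor((start + end) / 2)`), the documented tie-break for loci
#' straddling a boundary.
#'
#' @param loci Data frame from [scan_ssrs()].
#' @param annotation Result of [classify_regions()] for the same genome.
#' @return List with `loci` (input plus a `region` column) and `density`
#'   (data frame `region`, `n`, `percent` — the share of loci per region).
#' @export
classify_ssr_regions <- function(loci, annotation) {
  if (nrow(loci)) {
    mid <- (loci$start + loci$end) %/% 2L
    loci$region <- region_at(annotation, mid)
  } else {
    loci$region <- character(0)
  }
  tab <- table(factor(loci$region, levels = c("CDS", "intron", "IGS")))
  density <- data.frame(region = names(tab), n = as.integer(tab),
                        percent = if (sum(tab) > 0) 100 * as.numeric(tab) / sum(tab)
                        else rep(0, length(tab)))
  list(loci = loci, density = density)
}

#' Motif presence/absence matrix across genomes
#'
#' @param loci Data frame of loci from one or more genomes (must carry a
#'   `genome` column).
#' @param strand_merge Also merge motifs with their reverse complements
#'   (default FALSE: motifs are reported as scanned, canonicalized only by
#'   rotation).
#' @return List of class `ssr_matrix`: `presence` (0/1 integer matrix, rows =
#'   canonical motifs, columns = genomes) and `conservation_pct` (per-motif
#'   percentage of genomes carrying it).
#' @export
ssr_presence_matrix <- function(loci, strand_merge = FALSE) {
  stopifnot(nrow(loci) >= 1L)
  key <- loci$canonical_motif
  if (strand_merge) {
    key <- vapply(key, function(m) min(m, canonical_rotation(revcomp(m))),
                  character(1), USE.NAMES = FALSE)
  }
  tab <- table(key, loci$genome)
  presence <- matrix(as.integer(tab > 0), nrow = nrow(tab),
                     dimnames = dimnames(tab))
  structure(list(presence = presence,
                 conservation_pct = 100 * rowMeans(presence)),
            class = "ssr_matrix")
}

#' @export
print.ssr_matrix <- function(x, ...) {
  cat("<ssr_matrix>", nrow(x$presence), "motifs x", ncol(x$presence), "genomes\n")
  invisible(x)
}

#' Per-genome SSR category summary
#'
#' @param loci Data frame of loci (with `genome` and `unit_length`).
#' @return List with `by_genome` (counts per genome x category) and
#'   `category` (overall counts and percentages per unit-length category,
#'   Mono- through HexaSSR).
#' @export
ssr_summary <- function(loci) {
  cats <- c("MonoSSR", "DiSSR", "TriSSR", "TetraSSR", "PentaSSR", "HexaSSR")
  f <- factor(cats[loci$unit_length], levels = cats)
  by_genome <- as.data.frame.matrix(table(loci$genome, f))
  by_genome <- cbind(genome = rownames(by_genome), by_genome, row.names = NULL)
  tot <- table(f)
  category <- data.frame(category = cats, n = as.integer(tot),
                         percent = if (sum(tot) > 0) 100 * as.numeric(tot) / sum(tot)
                         else rep(0, length(tot)))
  list(by_genome = by_genome, category = category)
}

#' Export SSR loci as BED
#'
#' Coordinates are converted to BED's 0-based half-open convention at write
#' time.
#'
#' @param loci Data frame from [scan_ssrs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ssr_bed <- function(loci, path) {
  bed <- data.frame(chrom = loci$genome, start = loci$start - 1L, end = loci$end,
                    name = paste0(loci$motif, "x", loci$copies))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
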