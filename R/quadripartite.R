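# Detection of the quadripartite plastome layout (LSC / IRb / SSC / IRa) by
# exact inverted-repeat search: k-mer anchoring between the doubled sequence
# and its reverse complement, followed by maximal mismatch-free extension
# along each anchored diagonal. Doubling the sequence makes the search
# rotation-invariant (an IR split by the linearization point is still found).

#' Detect the quadripartite structure of a circular plastome
#'
#' Finds the longest pair of disjoint, exactly reverse-complementary segments
#' of length at least `min_ir` and names the two intervening single-copy
#' regions LSC (the larger) and SSC (the smaller). IRb is the inverted repeat
#' immediately following the LSC in input orientation. Intervals are 1-based
#' inclusive on the input orientation; an interval with `start > end` wraps
#' the circular origin.
#'
#' Only exact reverse-complement identity is considered; near-identical IRs
#' with isolated mismatches are not matched (a mismatch-tolerant mode is
#' future work).
#'
#' @param genome A [plastid_genome()] or a DNA string.
#' @param min_ir Minimum inverted-repeat length in bp.
#' @param seed_k Anchor k-mer length.
#' @return An object of class `quadripartite`: list with intervals `lsc`,
#'   `ssc`, `ira`, `irb` (each `c(start, end)`), the region lengths,
#'   `genome_length` and `id`.
#' @export
detect_quadripartite <- function(genome, min_ir = 10000L, seed_k = 25L) {
  if (inherits(genome, "plastid_genome")) {
    s <- genome$sequence
    id <- genome$id
  } else {
    s <- check_dna(genome)
    id <- NA_character_
  }
  n <- nchar(s)
  if (n <= 2L * min_ir) {
    stop("genome length (", n, ") must exceed 2*min_ir (", 2L * min_ir, ")",
         call. = FALSE)
  }
  s2 <- paste0(s, s)
  rc2 <- revcomp(s2)
  sv <- charToRaw(s2)
  rv <- charToRaw(rc2)
  L2 <- 2L * n
  rawN <- charToRaw("N")
  ok_s <- sv != rawN
  ok_r <- rv != rawN

  # anchors: strided k-mers of the doubled sequence, looked up in all k-mers
  # of its reverse complement; stride chosen so any match of length >= min_ir
  # contains one full anchor k-mer.
  k <- as.integer(seed_k)
  stride <- max(1L, as.integer(min_ir) - k + 1L)
  a_pos <- seq.int(1L, L2 - k + 1L, by = stride)
  a_kmer <- substring(s2, a_pos, a_pos + k - 1L)
  keep <- !grepl("N", a_kmer, fixed = TRUE)
  a_pos <- a_pos[keep]
  a_kmer <- a_kmer[keep]
  r_pos <- seq_len(L2 - k + 1L)
  r_kmer <- substring(rc2, r_pos, r_pos + k - 1L)
  hit <- match(r_kmer, a_kmer)
  j <- which(!is.na(hit))
  diags <- unique(a_pos[hit[j]] - j)

  cands <- list()
  seen <- character(0)
  for (d in diags) {
    lo <- max(1L, 1L + d)
    hi <- min(L2, L2 + d)
    ii <- lo:hi
    eq <- (sv[ii] == rv[ii - d]) & ok_s[ii] & ok_r[ii - d]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    run_i <- which(r$values & r$lengths >= min_ir)
    for (ri in run_i) {
      i1 <- ii[starts[ri]]
      len <- min(r$lengths[ri], n)
      if (i1 > n) next  # same circular segment as the first-copy run
      j1 <- i1 - d
      j2 <- j1 + len - 1L
      # rc2 position j corresponds to s2 position L2 - j + 1
      b1 <- L2 - j2 + 1L
      a_start <- ((i1 - 1L) %% n) + 1L
      b_start <- ((b1 - 1L) %% n) + 1L
      # circular overlap check
      off <- (b_start - a_start) %% n
      if (off < len || off + len > n) next  # self-overlapping (palindromic)
      key <- paste(min(a_start, b_start), max(a_start, b_start), len)
      if (key %in% seen) next
      seen <- c(seen, key)
      cands[[length(cands) + 1L]] <- c(a_start, b_start, len)
    }
  }
  if (!length(cands)) {
    stop(structure(class = c("plastocodon_no_ir", "error", "condition"),
                   list(message = paste0("no inverted repeat of length >= ",
                                         min_ir, " bp found",
                                         if (!is.na(id)) paste0(" in ", id)),
                        call = sys.call(-1))))
  }
  m <- do.call(rbind, cands)
  m <- m[order(-m[, 3], pmin(m[, 1], m[, 2])), , drop = FALSE]
  a_start <- min(m[1, 1], m[1, 2])
  b_start <- max(m[1, 1], m[1, 2])
  len <- m[1, 3]

  iv <- function(start, length) {
    end <- ((start + length - 2L) %% n) + 1L
    c(start = start, end = end)
  }
  gap_after <- function(ir_start, next_start) {
    gs <- ((ir_start + len - 1L) %% n) + 1L
    glen <- (next_start - gs) %% n
    list(start = gs, len = glen)
  }
  gap1 <- gap_after(a_start, b_start)  # between IR1 and IR2
  gap2 <- gap_after(b_start, a_start)  # wraps back to IR1
  if (gap1$len == 0L || gap2$len == 0L) {
    stop(structure(class = c("plastocodon_no_ir", "error", "condition"),
                   list(message = "inverted repeats are adjacent; no quadripartite structure",
                        call = sys.call(-1))))
  }
  if (gap1$len >= gap2$len) {
    lsc <- gap1; ssc <- gap2
    irb_start <- b_start; ira_start <- a_start  # IRb follows the LSC
  } else {
    lsc <- gap2; ssc <- gap1
    irb_start <- a_start; ira_start <- b_start
  }
  stopifnot(lsc$len + ssc$len + 2L * len == n)
  structure(list(lsc = iv(lsc$start, lsc$len),
                 ssc = iv(ssc$start, ssc$len),
                 ira = iv(ira_start, len),
                 irb = iv(irb_start, len),
                 lsc_length = lsc$len,
                 ssc_length = ssc$len,
                 ir_length = len,
                 genome_length = n,
                 id = id),
            class = "quadripartite")
}

#' @export
print.quadripartite <- function(x, ...) {
  fmt <- function(v) paste0(format(v["start"], big.mark = ","), "..",
                            format(v["end"], big.mark = ","))
  cat("<quadripartite> ", if (!is.na(x$id)) x$id, "\n",
      "  LSC ", fmt(x$lsc), " (", format(x$lsc_length, big.mark = ","), " bp)\n",
      "  IRb ", fmt(x$irb), " (", format(x$ir_length, big.mark = ","), " bp)\n",
      "  SSC ", fmt(x$ssc), " (", format(x$ssc_length, big.mark = ","), " bp)\n",
      "  IRa ", fmt(x$ira), " (", format(x$ir_length, big.mark = ","), " bp)\n",
      sep = "")
  invisible(x)
}

#' One-row structure summary of a genome
#'
#' @param genome A [plastid_genome()].
#' @param ... Passed to [detect_quadripartite()].
#' @return Data frame with id, length, GC percent and region lengths (NA if
#'   no inverted repeat is found).
#' @export
structure_summary <- function(genome, ...) {
  gc_pct <- 100 * gc_fraction(genome$sequence)
  qp <- tryCatch(detect_quadripartite(genome, ...),
                 plastocodon_no_ir = function(e) NULL)
  data.frame(id = genome$id, length = genome$length,
             gc_percent = gc_pct,
             lsc_length = if (is.null(qp)) NA_integer_ else qp$lsc_length,
             ssc_length = if (is.null(qp)) NA_integer_ else qp$ssc_length,
             ir_length = if (is.null(qp)) NA_integer_ else qp$ir_length)
}

# Overall GC fraction of a DNA string (N excluded from the denominator).
gc_fraction <- function(s) {
  v <- charToRaw(toupper(s))
  gc <- sum(v == charToRaw("G") | v == charToRaw("C"))
  acgt <- sum(v != charToRaw("N"))
  if (acgt == 0L) return(NA_real_)
  gc / acgt
}
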