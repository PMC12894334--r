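# Independent oracles and fixture builders used across the suite.

rand_dna <- function(n, at = 0.5) {
  p <- c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p), collapse = "")
}

rotate_seq <- function(s, k) {
  n <- nchar(s)
  k <- k %% n
  if (k == 0) return(s)
  paste0(substr(s, k + 1, n), substr(s, 1, k))
}

# Exhaustive window scanner: for every position and unit length, count whole
# repeat units directly by string comparison; keep left-maximal,
# threshold-passing, primitive-motif loci; identical spans keep the shortest
# unit. Quadratic and dumb on purpose.
brute_force_ssr <- function(s, thresholds = ssr_thresholds()) {
  n <- nchar(s)
  ch <- strsplit(s, "")[[1]]
  hits <- list()
  for (k in as.integer(names(thresholds))) {
    thr <- thresholds[[as.character(k)]]
    if (n < k * thr) next
    for (i in seq_len(n - k * thr + 1L)) {
      motif <- substr(s, i, i + k - 1L)
      if (grepl("N", motif, fixed = TRUE)) next
      # left maximality: the unit must not extend one base to the left
      if (i > 1L && ch[i - 1L] != "N" && ch[i - 1L + k] != "N" &&
          ch[i - 1L] == ch[i - 1L + k]) next
      copies <- 1L
      while (i + copies * k + k - 1L <= n &&
             substr(s, i + copies * k, i + copies * k + k - 1L) == motif) {
        copies <- copies + 1L
      }
      if (copies < thr) next
      prim <- TRUE
      if (k > 1L) {
        for (d in seq_len(k - 1L)) {
          if (k %% d == 0L && strrep(substr(motif, 1L, d), k %/% d) == motif) {
            prim <- FALSE
            break
          }
        }
      }
      if (!prim) next
      hits[[length(hits) + 1L]] <- data.frame(
        motif = motif, unit_length = k, copies = copies,
        start = i, end = i + copies * k - 1L)
    }
  }
  if (!length(hits)) {
    return(data.frame(motif = character(0), unit_length = integer(0),
                      copies = integer(0), start = integer(0), end = integer(0)))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$start, out$unit_length), , drop = FALSE]
  out <- out[!duplicated(out[, c("start", "end")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

ssr_key <- function(df) sort(paste(df$start, df$end, df$motif, df$copies))

# Planted quadripartite genome with junction-safe flanks so the planted IR
# pair is exactly maximal.
make_ir_genome <- function(lsc_len = 9000L, irb_len = 2500L, ssc_len = 1600L) {
  guard <- function(s) paste0("A", substr(s, 2, nchar(s) - 1), "A")
  lsc <- guard(rand_dna(lsc_len))
  irb <- rand_dna(irb_len)
  ssc <- guard(rand_dna(ssc_len))
  list(seq = paste0(lsc, irb, ssc, revcomp(irb)),
       lsc = as.integer(lsc_len), ir = as.integer(irb_len),
       ssc = as.integer(ssc_len))
}

# Dense eigendecomposition oracle for correspondence analysis: eigenvalues of
# the cross-product of the standardized residual matrix, plus principal
# coordinates rebuilt from the eigenvectors.
ca_eigen_oracle <- function(x) {
  P <- x / sum(x)
  r <- rowSums(P)
  cc <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - r %o% cc) %*% diag(1 / sqrt(cc))
  ev <- eigen(t(S) %*% S, symmetric = TRUE)
  lambda <- pmax(ev$values, 0)
  keep <- lambda > max(lambda, 0) * 1e-12
  sigma <- sqrt(lambda[keep])
  V <- ev$vectors[, keep, drop = FALSE]
  U <- S %*% V %*% diag(1 / sigma, length(sigma))
  list(inertia = lambda[keep],
       row_coords = diag(1 / sqrt(r)) %*% U %*% diag(sigma, length(sigma)),
       col_coords = diag(1 / sqrt(cc)) %*% V %*% diag(sigma, length(sigma)))
}

# A small handwritten GenBank record writer for parser fixtures.
write_fixture_gb <- function(path, sequence, feature_lines,
                             name = "TEST0001", circular = TRUE) {
  n <- nchar(sequence)
  lines <- c(
    sprintf("LOCUS       %s %d bp    DNA     %s PLN 01-JAN-2026",
            name, n, if (circular) "circular" else "linear"),
    "DEFINITION  parser fixture.",
    sprintf("ACCESSION   %s", name),
    "SOURCE      test",
    "  ORGANISM  Testus fixturis",
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", n),
    feature_lines,
    "ORIGIN")
  s <- tolower(sequence)
  for (st in seq(1, n, by = 60)) {
    chunk <- substr(s, st, min(st + 59, n))
    tens <- substring(chunk, seq(1, nchar(chunk), by = 10),
                      pmin(seq(10, nchar(chunk) + 9, by = 10), nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", st, paste(tens, collapse = " ")))
  }
  writeLines(c(lines, "//"), path)
  path
}

small_spec <- function(seed = 7, ...) {
  synthetic_plastome_spec(seed = seed, lsc_len = 12000L, ssc_len = 2600L,
                          ir_len = 6000L, n_genes = 12L, n_trna = 6L,
                          n_rrna_per_ir = 2L, gene_len_range = c(60L, 150L),
                          ...)
}
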