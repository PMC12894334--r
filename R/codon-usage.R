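# Codon usage statistics: codon counts, RSCU, positional GC content, GC3s,
# and Wright's effective number of codons (ENC).

#' Count codons of a coding sequence
#'
#' Frame-0 triplets are tallied. A terminal stop codon is recorded but
#' excluded from `n_codons`; codons containing N are skipped. An internal
#' stop codon is an error (such sequences are filtered by [extract_cds()]).
#'
#' @param cds Coding sequence (length a multiple of 3).
#' @param id Optional source label (gene or genome id).
#' @return An object of class `codon_counts`: list with `counts` (named
#'   integer vector over all 64 codons; stop-codon entries count terminal
#'   stops), `n_codons` (sense codons counted), `n_stops`, `n_skipped`
#'   (codons containing N) and `source`.
#' @export
count_codons <- function(cds, id = NULL) {
  cds <- check_dna(cds, "coding sequence")
  cods <- split_codons(cds)
  code <- plastid_genetic_code()
  has_n <- grepl("N", cods, fixed = TRUE)
  kept <- cods[!has_n]
  aa <- code[kept]
  is_stop <- aa == "*"
  if (any(is_stop & seq_along(kept) < length(kept))) {
    stop("internal stop codon in coding sequence", if (!is.null(id)) paste0(" ", id),
         call. = FALSE)
  }
  counts <- table(factor(kept, levels = pc_codons()))
  counts <- stats::setNames(as.integer(counts), pc_codons())
  new_codon_counts(counts, n_skipped = sum(has_n), source = id)
}

new_codon_counts <- function(counts, n_skipped = 0L, source = NULL) {
  stops <- pc_stop_codons()
  structure(list(counts = counts,
                 n_codons = sum(counts[setdiff(names(counts), stops)]),
                 n_stops = sum(counts[stops]),
                 n_skipped = n_skipped,
                 source = if (is.null(source)) NA_character_ else source),
            class = "codon_counts")
}

#' Sum codon counts across genes
#'
#' Used for species-level statistics computed on the concatenated coding
#' complement of a genome.
#'
#' @param x List of `codon_counts` objects.
#' @param id Label for the pooled counts.
#' @return A `codon_counts` object.
#' @export
sum_codon_counts <- function(x, id = NULL) {
  stopifnot(length(x) >= 1L, all(vapply(x, inherits, TRUE, "codon_counts")))
  counts <- Reduce(`+`, lapply(x, `[[`, "counts"))
  new_codon_counts(counts,
                   n_skipped = sum(vapply(x, `[[`, 0L, "n_skipped")),
                   source = id)
}

#' Pooled codon counts of a genome's valid CDS
#'
#' @param genome A [plastid_genome()].
#' @param unique_genes Drop inverted-repeat duplicate features (by gene name).
#' @return A `codon_counts` object labelled with the genome id.
#' @export
genome_codon_counts <- function(genome, unique_genes = TRUE) {
  cds <- valid_cds(genome, unique_genes = unique_genes)
  if (!length(cds)) stop("no valid CDS in genome ", genome$id, call. = FALSE)
  sum_codon_counts(mapply(count_codons, cds, names(cds),
                          SIMPLIFY = FALSE, USE.NAMES = FALSE),
                   id = genome$id)
}

#' @export
print.codon_counts <- function(x, ...) {
  cat("<codon_counts>", if (!is.na(x$source)) x$source,
      "-", x$n_codons, "sense codons,", x$n_stops, "stop(s)\n")
  invisible(x)
}

as_codon_counts <- function(x, id = NULL) {
  if (inherits(x, "codon_counts")) x else count_codons(x, id = id)
}

# ---- RSCU -------------------------------------------------------------------

#' Relative synonymous codon usage
#'
#' For codon `c` in a `k`-fold synonymous family with family total `T > 0`,
#' `RSCU(c) = count(c) / (T / k)`: the observed count divided by the count
#' expected under equal usage of the family's synonyms. Families with no
#' observation are reported as `NA` (missing), never 0. Methionine (ATG) and
#' tryptophan (TGG) have no synonyms: their RSCU is exactly 1 by definition
#' and they are excluded from the 59-codon analysis vector.
#'
#' @param counts A `codon_counts` object (or a coding sequence).
#' @return An object of class `rscu_profile`: list with `rscu` (named numeric
#'   over the 59 informative codons), `families`, and `source`.
#' @export
rscu <- function(counts) {
  counts <- as_codon_counts(counts)
  fam <- codon_families()
  vals <- stats::setNames(rep(NA_real_, length(pc_informative_codons())),
                          pc_informative_codons())
  for (codons in fam) {
    tot <- sum(counts$counts[codons])
    if (tot > 0L) vals[codons] <- counts$counts[codons] * length(codons) / tot
  }
  structure(list(rscu = vals, families = fam, source = counts$source),
            class = "rscu_profile")
}

#' @export
print.rscu_profile <- function(x, ...) {
  cat("<rscu_profile>", if (!is.na(x$source)) x$source, "-",
      sum(!is.na(x$rscu)), "of 59 informative codons observed\n")
  invisible(x)
}

# ---- Positional composition -------------------------------------------------

# 64 x 3 matrix of codon bases, rows named by codon.
codon_base_matrix <- function() {
  if (is.null(.pc_cache$base_mat)) {
    cods <- pc_codons()
    .pc_cache$base_mat <- matrix(unlist(strsplit(cods, "")), ncol = 3, byrow = TRUE,
                                 dimnames = list(cods, NULL))
  }
  .pc_cache$base_mat
}

#' Positional GC composition of coding sequence
#'
#' Computes overall GC, GC at each codon position (GC1-GC3, over all sense
#' codons), GC12 = (GC1+GC2)/2, GC3s (GC at third positions of codons in
#' synonymously degenerate families: ATG, TGG and stops excluded), and the
#' third-position base tallies A3/T3/G3/C3.
#'
#' @param x A `codon_counts` object or coding sequence.
#' @return An object of class `composition_stats`.
#' @export
composition <- function(x) {
  counts <- as_codon_counts(x)
  if (counts$n_codons == 0L) stop("no sense codons to analyse", call. = FALSE)
  bm <- codon_base_matrix()
  sense <- pc_sense_codons()
  cnt <- counts$counts[sense]
  tot <- sum(cnt)
  gc_at <- function(pos, codons, weights) {
    w <- weights[codons]
    sum(w[bm[codons, pos] %in% c("G", "C")]) / sum(w)
  }
  gc1 <- gc_at(1, sense, counts$counts)
  gc2 <- gc_at(2, sense, counts$counts)
  gc3 <- gc_at(3, sense, counts$counts)
  info <- pc_informative_codons()
  tot_s <- sum(counts$counts[info])
  gc3s <- if (tot_s > 0L) gc_at(3, info, counts$counts) else NA_real_
  third <- bm[sense, 3]
  base3 <- vapply(c("A", "T", "G", "C"),
                  function(b) sum(cnt[third == b]), numeric(1))
  structure(list(gc = (gc1 + gc2 + gc3) / 3,
                 gc1 = gc1, gc2 = gc2, gc3 = gc3,
                 gc12 = (gc1 + gc2) / 2,
                 gc3s = gc3s,
                 a3 = base3[["A"]], t3 = base3[["T"]],
                 g3 = base3[["G"]], c3 = base3[["C"]],
                 n_codons = tot, source = counts$source),
            class = "composition_stats")
}

#' @export
print.composition_stats <- function(x, ...) {
  cat(sprintf("<composition_stats>%s GC %.4f | GC1 %.4f GC2 %.4f GC3 %.4f GC3s %s | n=%d\n",
              if (!is.na(x$source)) paste0(" ", x$source) else "",
              x$gc, x$gc1, x$gc2, x$gc3,
              if (is.na(x$gc3s)) "NA" else sprintf("%.4f", x$gc3s),
              x$n_codons))
  invisible(x)
}

# ---- ENC --------------------------------------------------------------------

#' Wright's effective number of codons
#'
#' Per synonymous family with `n >= 2` observations, the homozygosity is
#' `F = (n * sum(p_i^2) - 1) / (n - 1)` with `p_i` the within-family codon
#' frequencies. `F_k` is the mean over observed families of degeneracy `k`
#' (2-fold x9, 3-fold x1, 4-fold x5, 6-fold x3 under the plastid code), and
#' `ENC = 2 + 9/F_2 + 1/F_3 + 5/F_4 + 3/F_6`, clamped to `[20, 61]`.
#'
#' When a degeneracy class has no estimable family (or a non-positive mean
#' homozygosity), it is imputed: `F_3` as `(F_2 + F_4)/2` (Wright's
#' prescription for a missing isoleucine family), any other class as the
#' family-count-weighted mean of the estimable classes. Imputation is
#' recorded in the result.
#'
#' @param counts A `codon_counts` object or coding sequence.
#' @return An object of class `enc_stats`: `f2`, `f3`, `f4`, `f6`, `enc`,
#'   `n_families_used` (per class) and `imputed` (class labels).
#' @export
enc <- function(counts) {
  counts <- as_codon_counts(counts)
  fam <- codon_families()
  deg <- vapply(fam, length, 1L)
  f_hat <- vapply(fam, function(codons) {
    n <- sum(counts$counts[codons])
    if (n < 2L) return(NA_real_)
    p <- counts$counts[codons] / n
    (n * sum(p^2) - 1) / (n - 1)
  }, numeric(1))
  classes <- c(2L, 3L, 4L, 6L)
  mult <- c(`2` = 9, `3` = 1, `4` = 5, `6` = 3)  # families per class
  f_class <- stats::setNames(rep(NA_real_, 4), classes)
  n_used <- stats::setNames(integer(4), classes)
  for (k in classes) {
    v <- f_hat[deg == k & !is.na(f_hat)]
    n_used[as.character(k)] <- length(v)
    if (length(v)) {
      m <- mean(v)
      if (m > 0) f_class[as.character(k)] <- m
    }
  }
  imputed <- character(0)
  if (all(is.na(f_class))) {
    return(structure(list(f2 = NA_real_, f3 = NA_real_, f4 = NA_real_,
                          f6 = NA_real_, enc = NA_real_,
                          n_families_used = n_used, imputed = imputed,
                          source = counts$source),
                     class = "enc_stats"))
  }
  if (is.na(f_class[["3"]]) && !is.na(f_class[["2"]]) && !is.na(f_class[["4"]])) {
    f_class[["3"]] <- (f_class[["2"]] + f_class[["4"]]) / 2
    imputed <- c(imputed, "3")
  }
  for (k in as.character(classes)) {
    if (is.na(f_class[[k]])) {
      avail <- !is.na(f_class) & names(f_class) != k
      f_class[[k]] <- sum(f_class[avail] * mult[avail]) / sum(mult[avail])
      imputed <- c(imputed, k)
    }
  }
  enc_val <- 2 + 9 / f_class[["2"]] + 1 / f_class[["3"]] +
    5 / f_class[["4"]] + 3 / f_class[["6"]]
  enc_val <- min(61, max(20, enc_val))
  structure(list(f2 = f_class[["2"]], f3 = f_class[["3"]],
                 f4 = f_class[["4"]], f6 = f_class[["6"]],
                 enc = enc_val, n_families_used = n_used, imputed = imputed,
                 source = counts$source),
            class = "enc_stats")
}

#' @export
print.enc_stats <- function(x, ...) {
  cat(sprintf("<enc_stats>%s ENC = %s (F2 %.3f, F3 %.3f, F4 %.3f, F6 %.3f)%s\n",
              if (!is.na(x$source)) paste0(" ", x$source) else "",
              if (is.na(x$enc)) "NA" else sprintf("%.2f", x$enc),
              x$f2, x$f3, x$f4, x$f6,
              if (length(x$imputed)) paste0(" [imputed class ",
                                            paste(x$imputed, collapse = ","), "]") else ""))
  invisible(x)
}

#' Expected ENC under pure compositional bias
#'
#' Wright's expectation for the ENC of a gene whose codon usage is determined
#' solely by its GC3s, `s`: the standard form is
#' `2 + s + 29 / (s^2 + (1 - s)^2)`. A widely reproduced variant omits the
#' `+ s` term; both are available (`variant = "no_s"`). The curve is the
#' reference line of the ENC-GC3s plot.
#'
#' @param gc3s Numeric vector in (0, 1).
#' @param variant `"standard"` (default) or `"no_s"`.
#' @return Numeric vector of expected ENC values.
#' @export
expected_enc_curve <- function(gc3s, variant = c("standard", "no_s")) {
  variant <- match.arg(variant)
  if (any(!is.finite(gc3s)) || any(gc3s <= 0) || any(gc3s >= 1)) {
    stop("gc3s must lie strictly within (0, 1)", call. = FALSE)
  }
  base <- 29 / (gc3s^2 + (1 - gc3s)^2)
  if (variant == "standard") 2 + gc3s + base else 2 + base
}

# ---- Tabulation -------------------------------------------------------------

#' Per-sequence codon usage table
#'
#' @param cds Named character vector of coding sequences, or a list of
#'   `codon_counts` objects.
#' @return Data frame with one row per input: `id`, `n_codons`, `gc`, `gc1`,
#'   `gc2`, `gc3`, `gc12`, `gc3s`, `enc`.
#' @export
codon_usage_table <- function(cds) {
  counts <- if (is.character(cds)) {
    ids <- names(cds)
    if (is.null(ids)) ids <- paste0("seq", seq_along(cds))
    mapply(count_codons, cds, ids, SIMPLIFY = FALSE)
  } else cds
  rows <- lapply(counts, function(ct) {
    comp <- composition(ct)
    e <- enc(ct)
    data.frame(id = ct$source, n_codons = comp$n_codons, gc = comp$gc,
               gc1 = comp$gc1, gc2 = comp$gc2, gc3 = comp$gc3,
               gc12 = comp$gc12, gc3s = comp$gc3s, enc = e$enc)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' RSCU matrix over the 59 informative codons
#'
#' @param cds Named character vector of coding sequences, or a list of
#'   `codon_counts` objects.
#' @param na_as_zero Replace missing families (no observation) by 0, as
#'   required for correspondence analysis input.
#' @return Numeric matrix, rows = sequences, columns = the 59 informative
#'   codons.
#' @export
rscu_matrix <- function(cds, na_as_zero = FALSE) {
  counts <- if (is.character(cds)) {
    ids <- names(cds)
    if (is.null(ids)) ids <- paste0("seq", seq_along(cds))
    mapply(count_codons, cds, ids, SIMPLIFY = FALSE)
  } else cds
  mat <- t(vapply(counts, function(ct) rscu(ct)$rscu,
                  numeric(length(pc_informative_codons()))))
  rownames(mat) <- vapply(counts, `[[`, "", "source")
  if (na_as_zero) mat[is.na(mat)] <- 0
  mat
}
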