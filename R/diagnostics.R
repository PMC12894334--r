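# Evolutionary-force diagnostics over gene-level codon statistics:
# neutrality plot regression (GC12 on GC3), PR2 bias points, and classical
# correspondence analysis of the gene x codon RSCU matrix.

#' Neutrality plot regression
#'
#' Ordinary least squares of GC12 on GC3 across a species' protein-coding
#' genes. A slope near 1 implicates mutational pressure as the dominant
#' force on codon usage; a slope near 0 implicates selection.
#'
#' @param gc3 Numeric vector of per-gene GC3 values.
#' @param gc12 Numeric vector of per-gene GC12 values.
#' @param species Species label.
#' @return An object of class `neutrality_fit`: `slope`, `intercept`, `r2`,
#'   `n_genes`, `species`; on degenerate input (fewer than 3 complete genes
#'   or zero GC3 variance) the coefficients are `NA` and `reason` says why.
#' @export
neutrality_fit <- function(gc3, gc12, species = NA_character_) {
  ok <- is.finite(gc3) & is.finite(gc12)
  x <- gc3[ok]
  y <- gc12[ok]
  undefined <- function(reason) {
    structure(list(slope = NA_real_, intercept = NA_real_, r2 = NA_real_,
                   n_genes = length(x), species = species, reason = reason),
              class = "neutrality_fit")
  }
  if (length(x) < 3L) return(undefined("fewer_than_3_genes"))
  if (stats::var(x) == 0) return(undefined("zero_gc3_variance"))
  fit <- stats::lm(y ~ x)
  # R^2 of simple OLS equals the squared correlation; avoids summary.lm's
  # perfect-fit warning on exactly collinear input
  r2 <- if (stats::var(y) == 0) 0 else stats::cor(x, y)^2
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = r2, n_genes = length(x), species = species,
                 reason = NA_character_),
            class = "neutrality_fit")
}

#' @export
print.neutrality_fit <- function(x, ...) {
  if (is.na(x$slope)) {
    cat("<neutrality_fit>", x$species, "- undefined (", x$reason, ")\n")
  } else {
    cat(sprintf("<neutrality_fit> %s: GC12 = %.4f + %.4f * GC3 (R2 = %.4f, n = %d)\n",
                x$species, x$intercept, x$slope, x$r2, x$n_genes))
  }
  invisible(x)
}

# ---- PR2 --------------------------------------------------------------------

#' PR2 bias point of a gene
#'
#' Parity rule 2 analysis: third-codon-position ratios
#' `A3/(A3+T3)` and `G3/(G3+C3)`. The point (0.5, 0.5) is the theoretical
#' equilibrium where A = T and G = C in the absence of bias. The default
#' tallies third positions over all sense codons; `codon_set = "fourfold"`
#' restricts to the five strictly 4-fold degenerate families, the classical
#' PR2 definition.
#'
#' @param counts A `codon_counts` object or coding sequence.
#' @param codon_set `"all"` (default) or `"fourfold"`.
#' @return An object of class `pr2_point`: `gene`, `g3_ratio`, `a3_ratio`
#'   (NA on a zero denominator) and the four third-position tallies.
#' @export
pr2 <- function(counts, codon_set = c("all", "fourfold")) {
  codon_set <- match.arg(codon_set)
  counts <- as_codon_counts(counts)
  codons <- if (codon_set == "all") {
    pc_sense_codons()
  } else {
    fam <- codon_families()
    unlist(fam[vapply(fam, length, 1L) == 4L], use.names = FALSE)
  }
  bm <- codon_base_matrix()
  third <- bm[codons, 3]
  cnt <- counts$counts[codons]
  tally <- vapply(c("A", "T", "G", "C"), function(b) sum(cnt[third == b]), numeric(1))
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  structure(list(gene = counts$source,
                 g3_ratio = ratio(tally[["G"]], tally[["G"]] + tally[["C"]]),
                 a3_ratio = ratio(tally[["A"]], tally[["A"]] + tally[["T"]]),
                 a3 = tally[["A"]], t3 = tally[["T"]],
                 g3 = tally[["G"]], c3 = tally[["C"]],
                 codon_set = codon_set),
            class = "pr2_point")
}

#' @export
print.pr2_point <- function(x, ...) {
  cat(sprintf("<pr2_point>%s G3/(G3+C3) = %s, A3/(A3+T3) = %s [%s codons]\n",
              if (!is.na(x$gene)) paste0(" ", x$gene) else "",
              if (is.na(x$g3_ratio)) "NA" else sprintf("%.4f", x$g3_ratio),
              if (is.na(x$a3_ratio)) "NA" else sprintf("%.4f", x$a3_ratio),
              x$codon_set))
  invisible(x)
}

#' PR2 table over many genes
#'
#' @param cds Named character vector of coding sequences or list of
#'   `codon_counts`.
#' @param codon_set Passed to [pr2()].
#' @return Data frame with `gene`, `g3_ratio`, `a3_ratio`.
#' @export
pr2_table <- function(cds, codon_set = c("all", "fourfold")) {
  codon_set <- match.arg(codon_set)
  counts <- if (is.character(cds)) {
    ids <- names(cds)
    if (is.null(ids)) ids <- paste0("seq", seq_along(cds))
    mapply(count_codons, cds, ids, SIMPLIFY = FALSE)
  } else cds
  rows <- lapply(counts, function(ct) {
    p <- pr2(ct, codon_set)
    data.frame(gene = p$gene, g3_ratio = p$g3_ratio, a3_ratio = p$a3_ratio)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---- Correspondence analysis ------------------------------------------------

#' Correspondence analysis of a non-negative matrix
#'
#' Classical (chi-square metric) correspondence analysis, applied here to the
#' gene x 59-codon RSCU matrix: with `P = X / sum(X)`, row and column
#' marginals `r`, `c`, the standardized residual matrix
#' `S = D_r^{-1/2} (P - r c') D_c^{-1/2}` is decomposed by SVD; principal
#' coordinates are the marginal-scaled singular vectors times the singular
#' values, and the inertia fraction of axis `i` is `sigma_i^2 / sum(sigma^2)`.
#' Axes are ordered by decreasing inertia with a deterministic sign
#' convention: on each axis the column loading of largest magnitude is made
#' positive. All-zero rows or columns are dropped with a message. A rank-zero
#' matrix yields a zero-inertia result, not an error.
#'
#' @param x Non-negative numeric matrix (`NA` entries treated as 0).
#' @param n_axes Number of axes for which coordinates are returned.
#' @return An object of class `coa_result`: `row_coords`, `col_coords`
#'   (principal coordinates), `inertia_fraction` (over all positive axes),
#'   `total_inertia`, `dropped_rows`, `dropped_cols`.
#' @export
coa <- function(x, n_axes = 5L) {
  x <- as.matrix(x)
  x[is.na(x)] <- 0
  if (any(x < 0)) stop("correspondence analysis requires a non-negative matrix",
                       call. = FALSE)
  rs <- rowSums(x)
  cs <- colSums(x)
  dropped_rows <- rownames(x)[rs == 0]
  dropped_cols <- colnames(x)[cs == 0]
  if (length(dropped_rows)) {
    message("coa: dropping ", length(dropped_rows), " all-zero row(s)")
  }
  if (length(dropped_cols)) {
    message("coa: dropping ", length(dropped_cols), " all-zero column(s)")
  }
  x <- x[rs > 0, cs > 0, drop = FALSE]
  if (nrow(x) == 0L || ncol(x) == 0L) stop("matrix has no non-zero entries", call. = FALSE)
  P <- x / sum(x)
  r <- rowSums(P)
  cc <- colSums(P)
  E <- tcrossprod(r, cc)
  S <- (P - E) / sqrt(E)
  sv <- svd(S)
  tol <- max(max(dim(S)) * max(sv$d, 0) * .Machine$double.eps * 100, 1e-12)
  pos <- which(sv$d > tol)
  total <- sum(sv$d[pos]^2)
  frac <- if (total > 0) sv$d[pos]^2 / total else numeric(0)
  k <- min(n_axes, length(pos))
  if (k > 0L) {
    U <- sv$u[, pos[seq_len(k)], drop = FALSE]
    V <- sv$v[, pos[seq_len(k)], drop = FALSE]
    d <- sv$d[pos[seq_len(k)]]
    for (a in seq_len(k)) {
      lead <- which.max(abs(V[, a]))
      if (V[lead, a] < 0) {
        V[, a] <- -V[, a]
        U[, a] <- -U[, a]
      }
    }
    row_coords <- sweep(U / sqrt(r), 2, d, `*`)
    col_coords <- sweep(V / sqrt(cc), 2, d, `*`)
    dimnames(row_coords) <- list(rownames(x), paste0("axis", seq_len(k)))
    dimnames(col_coords) <- list(colnames(x), paste0("axis", seq_len(k)))
  } else {
    row_coords <- matrix(0, nrow(x), 0, dimnames = list(rownames(x), NULL))
    col_coords <- matrix(0, ncol(x), 0, dimnames = list(colnames(x), NULL))
  }
  structure(list(row_coords = row_coords, col_coords = col_coords,
                 inertia_fraction = frac, total_inertia = total,
                 dropped_rows = dropped_rows, dropped_cols = dropped_cols),
            class = "coa_result")
}

#' @export
print.coa_result <- function(x, ...) {
  cat("<coa_result>", nrow(x$row_coords), "rows x", nrow(x$col_coords),
      "columns, total inertia", format(x$total_inertia, digits = 6), "\n")
  if (length(x$inertia_fraction)) {
    k <- min(3L, length(x$inertia_fraction))
    cat("  axis inertia:",
        paste(sprintf("%.3f%%", 100 * x$inertia_fraction[seq_len(k)]),
              collapse = ", "),
        if (length(x$inertia_fraction) > k) "...", "\n")
  }
  invisible(x)
}
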