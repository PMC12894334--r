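# NG86 (Nei-Gojobori counting) Ka/Ks estimation with Jukes-Cantor
# multiple-hit correction, and classification of genes into selection
# regimes (thresholds exactly 0.5 and 1.0).
#
# Site counting: for each codon position the synonymous fraction is the
# proportion of synonymous changes among the changes that do not create a
# stop codon; mutations to stops are excluded and the fractions renormalized
# so that synonymous + nonsynonymous sites always total 3 per codon.
# Multi-substitution codon pairs are averaged over all minimal mutational
# pathways with equal weights; pathways passing through a stop codon are
# excluded (unless all are, in which case all pathways are used).

perms2 <- list(c(1L, 2L), c(2L, 1L))
perms3 <- list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
               c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))

ng86_tables <- function() {
  if (!is.null(.pc_cache$ng86)) return(.pc_cache$ng86)
  code <- plastid_genetic_code()
  cods <- pc_codons()
  bases <- c("A", "C", "G", "T")
  bm <- codon_base_matrix()
  mutate1 <- function(codon, pos, base) {
    v <- bm[codon, ]
    v[pos] <- base
    paste(v, collapse = "")
  }
  # fractional synonymous sites per codon
  syn_sites <- stats::setNames(rep(NA_real_, 64), cods)
  for (cd in cods) {
    if (code[[cd]] == "*") next
    total <- 0
    for (pos in 1:3) {
      alts <- setdiff(bases, bm[cd, pos])
      alt_codons <- vapply(alts, mutate1, "", codon = cd, pos = pos)
      nonstop <- alt_codons[code[alt_codons] != "*"]
      if (!length(nonstop)) next
      total <- total + sum(code[nonstop] == code[[cd]]) / length(nonstop)
    }
    syn_sites[cd] <- total
  }
  # pathway-averaged synonymous / nonsynonymous differences per codon pair
  sd_mat <- matrix(NA_real_, 64, 64, dimnames = list(cods, cods))
  nd_mat <- sd_mat
  for (a in cods) {
    if (code[[a]] == "*") next
    for (b in cods) {
      if (code[[b]] == "*") next
      diffpos <- which(bm[a, ] != bm[b, ])
      ndiff <- length(diffpos)
      if (ndiff == 0L) {
        sd_mat[a, b] <- 0
        nd_mat[a, b] <- 0
        next
      }
      orders <- switch(ndiff, list(1L), perms2, perms3)
      paths <- lapply(orders, function(ord) {
        cur <- a
        syn <- 0
        nonsyn <- 0
        blocked <- FALSE
        for (step in seq_len(ndiff)) {
          pos <- diffpos[ord[step]]
          nxt <- mutate1(cur, pos, bm[b, pos])
          if (code[[nxt]] == "*" && step < ndiff) blocked <- TRUE
          if (code[[nxt]] == code[[cur]] && code[[nxt]] != "*") syn <- syn + 1
          else nonsyn <- nonsyn + 1
          cur <- nxt
        }
        c(syn = syn, nonsyn = nonsyn, blocked = as.numeric(blocked))
      })
      pm <- do.call(rbind, paths)
      use <- pm[pm[, "blocked"] == 0, , drop = FALSE]
      if (!nrow(use)) use <- pm
      sd_mat[a, b] <- mean(use[, "syn"])
      nd_mat[a, b] <- mean(use[, "nonsyn"])
    }
  }
  .pc_cache$ng86 <- list(syn_sites = syn_sites, sd = sd_mat, nd = nd_mat)
  .pc_cache$ng86
}

jc_correct <- function(p) {
  if (!is.finite(p)) return(NA_real_)
  if (p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

#' NG86 pairwise Ka, Ks and selection category
#'
#' Nei-Gojobori counting on an aligned codon pair of sequences: fractional
#' synonymous/nonsynonymous site counts averaged over the two sequences,
#' pathway-averaged difference counts, Jukes-Cantor correction
#' `d = -(3/4) log(1 - (4/3) p)`, and the three-way selection category
#' (`strong_purifying` for Ka/Ks < 0.5, `relaxed_purifying` for
#' 0.5 <= Ka/Ks <= 1, `positive` for Ka/Ks > 1; `undefined` when the ratio
#' cannot be formed).
#'
#' Codon columns containing gaps (`-`) or `N` are removed before analysis
#' (count reported); a shared terminal stop codon is dropped. A proportion
#' `p >= 3/4` makes the corresponding rate undefined; `ks = 0` makes the
#' ratio undefined.
#'
#' @param seq_a,seq_b Equal-length coding sequences (aligned, lengths a
#'   multiple of 3; no internal stops).
#' @param gene Optional gene label.
#' @return An object of class `kaks_result`: `ka`, `ks`, `ratio`, `category`,
#'   `n_syn_sites`, `n_nonsyn_sites`, `n_syn_diffs`, `n_nonsyn_diffs`,
#'   `p_syn`, `p_nonsyn`, `n_codons`, `n_dropped_codons`, `gene`.
#' @export
ng86 <- function(seq_a, seq_b, gene = NA_character_) {
  seq_a <- toupper(seq_a)
  seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b)) {
    stop("aligned sequences must have equal length", call. = FALSE)
  }
  if (nchar(seq_a) %% 3L != 0L) stop("alignment length is not a multiple of 3",
                                     call. = FALSE)
  ca <- split_codons(seq_a)
  cb <- split_codons(seq_b)
  bad <- grepl("[^ACGT]", ca) | grepl("[^ACGT]", cb)
  n_dropped <- sum(bad)
  ca <- ca[!bad]
  cb <- cb[!bad]
  code <- plastid_genetic_code()
  stop_a <- code[ca] == "*"
  stop_b <- code[cb] == "*"
  ncod <- length(ca)
  if (ncod && stop_a[ncod] && stop_b[ncod]) {  # shared terminal stop
    ca <- ca[-ncod]
    cb <- cb[-ncod]
    stop_a <- stop_a[-ncod]
    stop_b <- stop_b[-ncod]
  }
  if (any(stop_a) || any(stop_b)) {
    stop("internal stop codon in alignment", if (!is.na(gene)) paste0(" for ", gene),
         call. = FALSE)
  }
  n_codons <- length(ca)
  if (n_codons == 0L) stop("no analysable codon columns", call. = FALSE)
  tabs <- ng86_tables()
  S <- (sum(tabs$syn_sites[ca]) + sum(tabs$syn_sites[cb])) / 2
  N <- 3 * n_codons - S
  Sd <- sum(tabs$sd[cbind(ca, cb)])
  Nd <- sum(tabs$nd[cbind(ca, cb)])
  p_syn <- if (S > 0) Sd / S else NA_real_
  p_nonsyn <- if (N > 0) Nd / N else NA_real_
  ks <- jc_correct(p_syn)
  ka <- jc_correct(p_nonsyn)
  ratio <- if (is.finite(ka) && is.finite(ks) && ks > 0) ka / ks else NA_real_
  category <- if (!is.finite(ratio)) "undefined"
  else if (ratio < 0.5) "strong_purifying"
  else if (ratio <= 1.0) "relaxed_purifying"
  else "positive"
  structure(list(ka = ka, ks = ks, ratio = ratio, category = category,
                 n_syn_sites = S, n_nonsyn_sites = N,
                 n_syn_diffs = Sd, n_nonsyn_diffs = Nd,
                 p_syn = p_syn, p_nonsyn = p_nonsyn,
                 n_codons = n_codons, n_dropped_codons = n_dropped,
                 gene = gene),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  fmt <- function(v) if (is.finite(v)) sprintf("%.4f", v) else "NA"
  cat(sprintf("<kaks_result>%s Ka = %s, Ks = %s, Ka/Ks = %s (%s; %d codons)\n",
              if (!is.na(x$gene)) paste0(" ", x$gene) else "",
              fmt(x$ka), fmt(x$ks), fmt(x$ratio), x$category, x$n_codons))
  invisible(x)
}

#' Tally selection categories
#'
#' @param results List of `kaks_result` objects, or a numeric vector of
#'   Ka/Ks ratios (NA = undefined).
#' @return Data frame `category`, `n`, `percent`; percentages are over
#'   defined ratios, with the undefined count reported as its own row
#'   (`percent = NA`).
#' @export
classify_selection <- function(results) {
  ratios <- if (is.numeric(results)) results
  else vapply(results, `[[`, numeric(1), "ratio")
  defined <- ratios[is.finite(ratios)]
  cats <- c("strong_purifying", "relaxed_purifying", "positive")
  lab <- ifelse(defined < 0.5, cats[1], ifelse(defined <= 1.0, cats[2], cats[3]))
  tab <- table(factor(lab, levels = cats))
  out <- data.frame(category = cats, n = as.integer(tab),
                    percent = if (length(defined)) 100 * as.numeric(tab) / length(defined)
                    else rep(NA_real_, 3))
  rbind(out, data.frame(category = "undefined",
                        n = sum(!is.finite(ratios)), percent = NA_real_))
}

#' Pairwise Ka/Ks across genomes by shared gene name
#'
#' Homologs are paired by identical gene name (first feature per name, so
#' inverted-repeat duplicates are not double-counted). Only equal-length
#' CDS pairs are analysable (codon alignment is assumed as input); unequal
#' pairs are reported with `NA` and a reason.
#'
#' @param genomes List of [plastid_genome()] objects.
#' @param mode `"reference"` (all genomes vs one) or `"pairwise"` (all
#'   genome pairs).
#' @param reference Index or id of the reference genome (reference mode).
#' @return Data frame: `gene`, `genome_a`, `genome_b`, `ka`, `ks`, `ratio`,
#'   `category`, `n_codons`, `note`.
#' @export
kaks_pairs <- function(genomes, mode = c("reference", "pairwise"), reference = 1L) {
  mode <- match.arg(mode)
  stopifnot(length(genomes) >= 2L)
  ids <- vapply(genomes, `[[`, "", "id")
  cds <- lapply(genomes, valid_cds)
  if (is.character(reference)) reference <- match(reference, ids)
  pairs <- if (mode == "reference") {
    cbind(reference, setdiff(seq_along(genomes), reference))
  } else {
    t(utils::combn(seq_along(genomes), 2L))
  }
  rows <- list()
  for (pi in seq_len(nrow(pairs))) {
    ia <- pairs[pi, 1]
    ib <- pairs[pi, 2]
    shared <- intersect(names(cds[[ia]]), names(cds[[ib]]))
    for (g in shared) {
      a <- cds[[ia]][[g]]
      b <- cds[[ib]][[g]]
      if (nchar(a) != nchar(b)) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene = g, genome_a = ids[ia], genome_b = ids[ib],
          ka = NA_real_, ks = NA_real_, ratio = NA_real_,
          category = "undefined", n_codons = NA_integer_,
          note = "unequal_length")
        next
      }
      res <- ng86(a, b, gene = g)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, genome_a = ids[ia], genome_b = ids[ib],
        ka = res$ka, ks = res$ks, ratio = res$ratio,
        category = res$category, n_codons = res$n_codons, note = NA_character_)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(gene = character(0), genome_a = character(0),
                  genome_b = character(0), ka = numeric(0), ks = numeric(0),
                  ratio = numeric(0), category = character(0),
                  n_codons = integer(0), note = character(0))
  rownames(out) <- NULL
  out
}
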