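# End-to-end orchestration: structure -> codon usage -> diagnostics -> SSR ->
# (optional) Ka/Ks over a set of genomes, with per-genome failure isolation
# and a TSV report bundle.

#' Pipeline configuration
#'
#' Validates every tunable of the analysis; unknown options are rejected.
#'
#' @param ssr_thresholds Named map unit length -> minimum copies.
#' @param min_ir Minimum inverted-repeat length (bp) for structure detection.
#' @param seed_k Anchor k-mer length for inverted-repeat search.
#' @param min_codons Genes with fewer codons are excluded from gene-level
#'   diagnostics (neutrality, PR2, correspondence analysis); exclusions are
#'   reported.
#' @param pr2_codon_set `"all"` or `"fourfold"` third-position tally.
#' @param coa_mode `"pooled"` (all genomes' genes in one matrix) or
#'   `"per_species"`.
#' @param enc_level `"genome"` (concatenated CDS per genome) and/or gene-level
#'   rows are always written; this picks which level the summary reports.
#' @param curve_variant Expected-ENC curve form (see [expected_enc_curve()]).
#' @param kaks Run pairwise Ka/Ks.
#' @param kaks_mode `"reference"` or `"pairwise"` (see [kaks_pairs()]).
#' @param reference Reference genome index or id for Ka/Ks.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(ssr_thresholds = plastocodon::ssr_thresholds(),
                            min_ir = 10000L, seed_k = 25L,
                            min_codons = 30L,
                            pr2_codon_set = c("all", "fourfold"),
                            coa_mode = c("pooled", "per_species"),
                            enc_level = c("genome", "gene"),
                            curve_variant = c("standard", "no_s"),
                            kaks = TRUE,
                            kaks_mode = c("reference", "pairwise"),
                            reference = 1L) {
  cfg <- list(ssr_thresholds = ssr_thresholds,
              min_ir = as.integer(min_ir), seed_k = as.integer(seed_k),
              min_codons = as.integer(min_codons),
              pr2_codon_set = match.arg(pr2_codon_set),
              coa_mode = match.arg(coa_mode),
              enc_level = match.arg(enc_level),
              curve_variant = match.arg(curve_variant),
              kaks = isTRUE(kaks),
              kaks_mode = match.arg(kaks_mode),
              reference = reference)
  stopifnot(cfg$min_ir > 0, cfg$seed_k > 5, cfg$min_codons >= 0,
            all(names(cfg$ssr_thresholds) %in% as.character(1:6)))
  structure(cfg, class = "pipeline_config")
}

write_tsv <- function(x, dir, name) {
  utils::write.table(x, file.path(dir, name), sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Run the full comparative plastome pipeline
#'
#' Executes structure detection, codon usage statistics, evolutionary-force
#' diagnostics, SSR scanning and (optionally) pairwise Ka/Ks over a set of
#' genomes, writing a TSV bundle to `out_dir`. A failure in any stage for
#' one genome is logged and the remaining genomes are still processed.
#'
#' Files written: `structure.tsv`, `summary.tsv`, `cds_qc.tsv`,
#' `codon_usage.tsv` (gene- and genome-level rows), `rscu_matrix.tsv`,
#' `neutrality.tsv`, `pr2.tsv`, `coa_rows.tsv`, `coa_cols.tsv`,
#' `coa_inertia.tsv`, `ssrs.tsv`, `ssr_summary.tsv`, `ssr_matrix.tsv`,
#' `failures.tsv` and, when enabled, `kaks.tsv` + `selection_summary.tsv`.
#'
#' @param input Character vector of GenBank file paths, or a list of
#'   [plastid_genome()] objects.
#' @param out_dir Output directory (created if needed).
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all result tables and a `failures` data
#'   frame (zero rows on full success).
#' @export
run_pipeline <- function(input, out_dir, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (length(input) == 0L) stop("no input genomes", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  failures <- list()
  note_failure <- function(id, stage, message) {
    failures[[length(failures) + 1L]] <<- data.frame(
      id = id, stage = stage, message = conditionMessage(message))
  }

  genomes <- list()
  if (is.character(input)) {
    for (path in input) {
      g <- tryCatch(parse_genbank(path), error = function(e) e)
      if (inherits(g, "error")) {
        note_failure(basename(path), "parse", g)
      } else {
        genomes[[length(genomes) + 1L]] <- g
      }
    }
  } else {
    genomes <- input
  }
  if (!length(genomes)) stop("no parseable genomes", call. = FALSE)
  ids <- vapply(genomes, `[[`, "", "id")

  structure_rows <- list()
  summary_rows <- list()
  qc_rows <- list()
  usage_rows <- list()
  gene_counts_all <- list()   # per gene, for diagnostics (>= min_codons)
  neutrality_rows <- list()
  pr2_rows <- list()
  ssr_all <- list()
  excluded_genes <- 0L

  for (g in genomes) {
    id <- g$id
    st <- tryCatch(structure_summary(g, min_ir = config$min_ir,
                                     seed_k = config$seed_k),
                   error = function(e) {
                     note_failure(id, "structure", e)
                     NULL
                   })
    if (!is.null(st)) structure_rows[[id]] <- st

    step <- tryCatch({
      ext <- extract_cds(g)
      qc <- ext[, setdiff(names(ext), "sequence")]
      qc <- cbind(id = id, qc)
      valid <- ext[ext$valid & !duplicated(ext$gene), , drop = FALSE]
      counts <- mapply(count_codons, valid$sequence,
                       paste0(id, ":", valid$gene),
                       SIMPLIFY = FALSE, USE.NAMES = FALSE)
      pooled <- sum_codon_counts(counts, id = id)
      gene_tab <- codon_usage_table(counts)
      gene_tab <- cbind(level = "gene", genome = id, gene_tab)
      genome_tab <- cbind(level = "genome", genome = id,
                          codon_usage_table(list(pooled)))
      keep <- vapply(counts, `[[`, 0L, "n_codons") >= config$min_codons
      excluded_genes <- excluded_genes + sum(!keep)
      kept <- counts[keep]
      comp <- lapply(kept, composition)
      nf <- neutrality_fit(vapply(comp, `[[`, 0, "gc3"),
                           vapply(comp, `[[`, 0, "gc12"),
                           species = id)
      p2 <- pr2_table(kept, codon_set = config$pr2_codon_set)
      p2 <- cbind(genome = id, p2)
      ann <- classify_regions(g)
      loci <- scan_ssrs(g, thresholds = config$ssr_thresholds)
      loci <- classify_ssr_regions(loci, ann)$loci
      feats <- vapply(g$features, `[[`, "", "kind")
      summ <- data.frame(id = id, length = g$length,
                         gc_percent = 100 * gc_fraction(g$sequence),
                         protein_genes = sum(feats == "CDS"),
                         rrna_genes = sum(feats == "rRNA"),
                         trna_genes = sum(feats == "tRNA"),
                         total_genes = sum(feats %in% c("CDS", "rRNA", "tRNA")))
      list(qc = qc, gene_tab = gene_tab, genome_tab = genome_tab,
           kept = kept, nf = nf, p2 = p2, loci = loci, summ = summ)
    }, error = function(e) {
      note_failure(id, "analysis", e)
      NULL
    })
    if (is.null(step)) next
    qc_rows[[id]] <- step$qc
    usage_rows[[id]] <- rbind(step$gene_tab, step$genome_tab)
    gene_counts_all[[id]] <- step$kept
    nf <- step$nf
    neutrality_rows[[id]] <- data.frame(
      species = id, slope = nf$slope, intercept = nf$intercept,
      r2 = nf$r2, n_genes = nf$n_genes)
    pr2_rows[[id]] <- step$p2
    ssr_all[[id]] <- step$loci
    summary_rows[[id]] <- step$summ
  }

  out <- list()
  out$structure <- do.call(rbind, c(structure_rows, list(make.row.names = FALSE)))
  out$summary <- do.call(rbind, c(summary_rows, list(make.row.names = FALSE)))
  out$cds_qc <- do.call(rbind, c(qc_rows, list(make.row.names = FALSE)))
  out$codon_usage <- do.call(rbind, c(usage_rows, list(make.row.names = FALSE)))
  out$neutrality <- do.call(rbind, c(neutrality_rows, list(make.row.names = FALSE)))
  out$pr2 <- do.call(rbind, c(pr2_rows, list(make.row.names = FALSE)))

  if (length(gene_counts_all)) {
    all_counts <- do.call(c, unname(gene_counts_all))
    rmat <- rscu_matrix(all_counts, na_as_zero = TRUE)
    out$rscu_matrix <- cbind(id = rownames(rmat), as.data.frame(rmat))
    if (config$coa_mode == "pooled") {
      ca <- suppressMessages(coa(rmat))
      out$coa_rows <- cbind(id = rownames(ca$row_coords),
                            as.data.frame(ca$row_coords))
      out$coa_cols <- cbind(codon = rownames(ca$col_coords),
                            as.data.frame(ca$col_coords))
      out$coa_inertia <- data.frame(
        axis = seq_along(ca$inertia_fraction),
        inertia_fraction = ca$inertia_fraction,
        inertia_percent = 100 * ca$inertia_fraction)
    } else {
      rows <- list()
      cols <- list()
      inert <- list()
      for (id in names(gene_counts_all)) {
        m <- rscu_matrix(gene_counts_all[[id]], na_as_zero = TRUE)
        ca <- suppressMessages(coa(m))
        rows[[id]] <- cbind(species = id, id = rownames(ca$row_coords),
                            as.data.frame(ca$row_coords))
        cols[[id]] <- cbind(species = id, codon = rownames(ca$col_coords),
                            as.data.frame(ca$col_coords))
        inert[[id]] <- data.frame(species = id,
                                  axis = seq_along(ca$inertia_fraction),
                                  inertia_fraction = ca$inertia_fraction,
                                  inertia_percent = 100 * ca$inertia_fraction)
      }
      out$coa_rows <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
      out$coa_cols <- do.call(rbind, c(cols, list(make.row.names = FALSE)))
      out$coa_inertia <- do.call(rbind, c(inert, list(make.row.names = FALSE)))
    }
  }

  if (length(ssr_all)) {
    loci <- do.call(rbind, c(ssr_all, list(make.row.names = FALSE)))
    out$ssrs <- loci
    if (nrow(loci)) {
      ss <- ssr_summary(loci)
      out$ssr_summary <- ss$category
      out$ssr_by_genome <- ss$by_genome
      pm <- ssr_presence_matrix(loci)
      out$ssr_matrix <- cbind(motif = rownames(pm$presence),
                              as.data.frame(pm$presence),
                              conservation_pct = pm$conservation_pct)
    }
  }

  if (config$kaks && length(genomes) >= 2L) {
    kk <- tryCatch(kaks_pairs(genomes, mode = config$kaks_mode,
                              reference = config$reference),
                   error = function(e) {
                     note_failure("(all)", "kaks", e)
                     NULL
                   })
    if (!is.null(kk)) {
      out$kaks <- kk
      out$selection_summary <- classify_selection(kk$ratio)
    }
  }

  out$failures <- if (length(failures)) {
    do.call(rbind, c(failures, list(make.row.names = FALSE)))
  } else data.frame(id = character(0), stage = character(0), message = character(0))
  out$excluded_genes <- excluded_genes

  files <- c(structure = "structure.tsv", summary = "summary.tsv",
             cds_qc = "cds_qc.tsv", codon_usage = "codon_usage.tsv",
             rscu_matrix = "rscu_matrix.tsv", neutrality = "neutrality.tsv",
             pr2 = "pr2.tsv", coa_rows = "coa_rows.tsv",
             coa_cols = "coa_cols.tsv", coa_inertia = "coa_inertia.tsv",
             ssrs = "ssrs.tsv", ssr_summary = "ssr_summary.tsv",
             ssr_by_genome = "ssr_by_genome.tsv", ssr_matrix = "ssr_matrix.tsv",
             kaks = "kaks.tsv", selection_summary = "selection_summary.tsv",
             failures = "failures.tsv")
  for (nm in names(files)) {
    if (!is.null(out[[nm]])) write_tsv(out[[nm]], out_dir, files[[nm]])
  }
  invisible(out)
}
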