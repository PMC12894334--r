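# Plastome input/output: GenBank flat-file parsing, coding-sequence
# extraction, and per-base genomic-region classification.
#
# Coordinates are 1-based inclusive (GenBank convention) throughout the
# package; conversion to other conventions happens only at serialization
# boundaries (e.g. BED export).

#' Construct a plastid genome object
#'
#' The unit consumed by every analysis stage: a circular (by default) DNA
#' sequence plus typed gene features.
#'
#' @param id Accession-like identifier.
#' @param sequence DNA string over `{A,C,G,T,N}` (case-insensitive input).
#' @param species Species label.
#' @param circular Logical; is the molecule circular?
#' @param features List of gene features as built by [gene_feature()].
#' @return An object of class `plastid_genome` with elements `id`, `species`,
#'   `sequence`, `length`, `circular`, `features`.
#' @export
plastid_genome <- function(id, sequence, species = NA_character_,
                           circular = TRUE, features = list()) {
  sequence <- check_dna(sequence, "genome sequence")
  n <- nchar(sequence)
  for (f in features) {
    p <- f$parts
    if (nrow(p) == 0L) stop("feature ", f$gene_name, " has no parts", call. = FALSE)
    if (any(p$start < 1L | p$start > n | p$end < 1L | p$end > n)) {
      stop("feature ", f$gene_name, " has parts outside [1, ", n, "]", call. = FALSE)
    }
  }
  structure(list(id = id, species = species, sequence = sequence,
                 length = n, circular = circular, features = features),
            class = "plastid_genome")
}

#' @export
print.plastid_genome <- function(x, ...) {
  kinds <- vapply(x$features, `[[`, "", "kind")
  cat("<plastid_genome> ", x$id, if (!is.na(x$species)) paste0(" (", x$species, ")"),
      "\n  ", format(x$length, big.mark = ","), " bp, ",
      if (x$circular) "circular" else "linear", "\n", sep = "")
  if (length(kinds)) {
    tab <- table(factor(kinds, levels = c("CDS", "tRNA", "rRNA", "intron", "other")))
    cat("  features:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' Construct a gene feature
#'
#' @param gene_name Gene symbol or identifier.
#' @param kind One of `"CDS"`, `"tRNA"`, `"rRNA"`, `"intron"`, `"other"`.
#' @param parts Data frame with columns `start`, `end`, `strand` (+1/-1) and
#'   optionally `wraps` (logical; the part crosses the circular origin), rows
#'   ordered in transcript (5'-to-3') order.
#' @param product Optional product description.
#' @return An object of class `gene_feature`.
#' @export
gene_feature <- function(gene_name, kind, parts, product = NA_character_) {
  kind <- match.arg(kind, c("CDS", "tRNA", "rRNA", "intron", "other"))
  parts <- as.data.frame(parts)
  if (is.null(parts$wraps)) parts$wraps <- FALSE
  if (is.null(parts$strand)) parts$strand <- 1L
  if (nrow(parts) == 0L) stop("parts must be non-empty", call. = FALSE)
  bad <- parts$start > parts$end & !parts$wraps
  if (any(bad)) stop("part with start > end not flagged as wrapping in ", gene_name,
                     call. = FALSE)
  structure(list(gene_name = gene_name, kind = kind,
                 parts = parts[, c("start", "end", "strand", "wraps")],
                 product = product),
            class = "gene_feature")
}

# ---- GenBank flat-file parsing ----------------------------------------------

# Recursive-descent parser for a GenBank location string. Returns a data frame
# of (start, end, strand, wraps) rows in transcript order.
parse_gb_location <- function(loc) {
  loc <- gsub("[[:space:]<>]", "", loc)
  if (grepl("^complement\\(", loc)) {
    inner <- parse_gb_location(sub("^complement\\((.*)\\)$", "\\1", loc))
    inner <- inner[rev(seq_len(nrow(inner))), , drop = FALSE]
    inner$strand <- -inner$strand
    rownames(inner) <- NULL
    return(inner)
  }
  if (grepl("^(join|order)\\(", loc)) {
    inner <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
    # split on commas at parenthesis depth 0
    chars <- strsplit(inner, "")[[1]]
    depth <- cumsum((chars == "(") - (chars == ")"))
    cuts <- which(chars == "," & depth == 0L)
    starts <- c(1L, cuts + 1L)
    ends <- c(cuts - 1L, length(chars))
    pieces <- mapply(function(s, e) paste(chars[s:e], collapse = ""), starts, ends)
    return(do.call(rbind, lapply(pieces, parse_gb_location)))
  }
  m <- regmatches(loc, regexec("^([0-9]+)(\\.\\.([0-9]+))?$", loc))[[1]]
  if (length(m) == 0L) stop("cannot parse GenBank location: ", loc, call. = FALSE)
  start <- as.integer(m[2])
  end <- if (nzchar(m[4])) as.integer(m[4]) else start
  data.frame(start = start, end = end, strand = 1L, wraps = start > end)
}

#' Parse a GenBank flat file into a plastid genome
#'
#' Resolves `join()`/`complement()` locations into ordered feature parts.
#' Duplicate gene features (e.g. genes annotated in both inverted repeats)
#' are retained as separate features. Feature keys other than `CDS`, `tRNA`,
#' `rRNA`, `intron` and `gene` are collected under kind `"other"` with a
#' single warning; `source` entries are skipped.
#'
#' @param path Path to a GenBank flat file with a feature table and an
#'   `ORIGIN` sequence block (first record only).
#' @return A [plastid_genome()].
#' @export
parse_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty GenBank file: ", path, call. = FALSE)

  locus_i <- grep("^LOCUS", lines)
  if (!length(locus_i)) stop("no LOCUS line in ", path, call. = FALSE)
  end_i <- grep("^//", lines)
  last <- if (length(end_i)) end_i[1] else length(lines)
  rec <- lines[locus_i[1]:last]

  circular <- grepl("circular", rec[1], ignore.case = TRUE)
  locus_name <- strsplit(trimws(sub("^LOCUS", "", rec[1])), "[[:space:]]+")[[1]][1]
  acc_i <- grep("^ACCESSION", rec)
  id <- if (length(acc_i)) {
    strsplit(trimws(sub("^ACCESSION", "", rec[acc_i[1]])), "[[:space:]]+")[[1]][1]
  } else locus_name
  if (is.na(id) || !nzchar(id)) id <- locus_name
  org_i <- grep("^ {2,}ORGANISM", rec)
  species <- if (length(org_i)) trimws(sub("^ *ORGANISM", "", rec[org_i[1]])) else NA_character_

  feat_i <- grep("^FEATURES", rec)
  origin_i <- grep("^ORIGIN", rec)
  if (!length(origin_i)) stop("no ORIGIN sequence block in ", path, call. = FALSE)
  seq_lines <- rec[(origin_i[1] + 1L):(length(rec) - 1L)]
  sequence <- toupper(paste(gsub("[^A-Za-z]", "", seq_lines), collapse = ""))
  if (!nzchar(sequence)) stop("missing sequence in ", path, call. = FALSE)

  features <- list()
  unknown <- character(0)
  if (length(feat_i)) {
    block <- rec[(feat_i[1] + 1L):(origin_i[1] - 1L)]
    # group lines into features: a new feature has a non-blank key in cols 6-20
    keys <- substr(block, 6L, 20L)
    is_new <- grepl("^[A-Za-z0-9_'-]", trimws(keys)) & nzchar(trimws(keys)) &
      grepl("^ {3,10}[A-Za-z]", block)
    idx <- cumsum(is_new)
    for (g in split(block[idx > 0], idx[idx > 0])) {
      key <- trimws(substr(g[1], 6L, 20L))
      rest <- trimws(substr(g[1], 21L, nchar(g[1])))
      body <- trimws(g[-1])
      qual_start <- which(startsWith(body, "/"))
      loc_extra <- if (length(qual_start)) body[seq_len(min(qual_start) - 1L)] else body
      loc <- paste(c(rest, loc_extra), collapse = "")
      quals <- if (length(qual_start)) body[min(qual_start):length(body)] else character(0)
      qual_text <- paste(quals, collapse = " ")
      get_qual <- function(name) {
        m <- regmatches(qual_text,
                        regexec(paste0("/", name, "=\"([^\"]*)\""), qual_text))[[1]]
        if (length(m) >= 2L) m[2] else NA_character_
      }
      if (key == "source") next
      kind <- switch(key, CDS = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                     intron = "intron", gene = "other", NULL)
      if (is.null(kind)) {
        unknown <- c(unknown, key)
        kind <- "other"
      }
      gene <- get_qual("gene")
      if (is.na(gene)) gene <- get_qual("locus_tag")
      if (is.na(gene)) gene <- get_qual("product")
      if (is.na(gene)) gene <- key
      parts <- parse_gb_location(loc)
      features[[length(features) + 1L]] <-
        gene_feature(gene, kind, parts, product = get_qual("product"))
    }
  }
  if (length(unknown)) {
    warning("unknown feature kinds collected under 'other': ",
            paste(sort(unique(unknown)), collapse = ", "), call. = FALSE)
  }
  plastid_genome(id = id, sequence = sequence, species = species,
                 circular = circular, features = features)
}

# ---- GenBank writing --------------------------------------------------------

format_gb_location <- function(parts, genome_length) {
  seg <- function(s, e, wraps) {
    if (wraps) paste0("join(", s, "..", genome_length, ",1..", e, ")")
    else paste0(s, "..", e)
  }
  minus <- all(parts$strand == -1L)
  p <- parts
  if (minus) p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
  pieces <- mapply(seg, p$start, p$end, p$wraps)
  body <- if (length(pieces) > 1L || any(p$wraps)) {
    paste0("join(", paste(pieces, collapse = ","), ")")
  } else pieces
  if (minus) paste0("complement(", body, ")") else body
}

#' Write a plastid genome as a GenBank flat file
#'
#' Emits a minimal but standards-shaped record (LOCUS, ACCESSION, ORGANISM,
#' FEATURES, ORIGIN) that [parse_genbank()] round-trips without warnings.
#'
#' @param genome A [plastid_genome()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(genome, path) {
  n <- genome$length
  con <- file(path, "w")
  on.exit(close(con))
  topo <- if (genome$circular) "circular" else "linear"
  writeLines(sprintf("LOCUS       %-16s %d bp    DNA     %s PLN %s",
                     genome$id, n, topo, format(Sys.Date(), "%d-%b-%Y")), con)
  writeLines(c(sprintf("DEFINITION  %s chloroplast, complete genome.",
                       ifelse(is.na(genome$species), genome$id, genome$species)),
               sprintf("ACCESSION   %s", genome$id),
               "SOURCE      synthetic construct",
               sprintf("  ORGANISM  %s", ifelse(is.na(genome$species), "synthetic", genome$species)),
               "FEATURES             Location/Qualifiers",
               sprintf("     source          1..%d", n)), con)
  for (f in genome$features) {
    key <- switch(f$kind, CDS = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                  intron = "intron", "gene")
    loc <- format_gb_location(f$parts, n)
    writeLines(sprintf("     %-16s%s", key, loc), con)
    writeLines(sprintf("                     /gene=\"%s\"", f$gene_name), con)
    if (!is.na(f$product)) {
      writeLines(sprintf("                     /product=\"%s\"", f$product), con)
    }
  }
  writeLines("ORIGIN", con)
  s <- tolower(genome$sequence)
  starts <- seq(1L, n, by = 60L)
  for (st in starts) {
    chunk <- substr(s, st, min(st + 59L, n))
    tens <- substring(chunk, seq(1L, nchar(chunk), by = 10L),
                      pmin(seq(10L, nchar(chunk) + 9L, by = 10L), nchar(chunk)))
    writeLines(sprintf("%9d %s", st, paste(tens, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}

# ---- CDS extraction ---------------------------------------------------------

# Extract the sequence of one part, honouring origin wrap and strand.
part_seq <- function(sequence, start, end, strand, wraps) {
  s <- if (wraps) {
    paste0(substr(sequence, start, nchar(sequence)), substr(sequence, 1L, end))
  } else substr(sequence, start, end)
  if (strand == -1L) revcomp(s) else s
}

splice_feature <- function(genome, feature) {
  p <- feature$parts
  paste(mapply(part_seq, MoreArgs = list(sequence = genome$sequence),
               p$start, p$end, p$strand, p$wraps), collapse = "")
}

#' Extract spliced coding sequences with quality control
#'
#' Minus-strand parts are reverse-complemented before concatenation in
#' transcript order. Sequences whose length is not a multiple of 3, or that
#' contain an internal stop codon under translation table 11, are flagged
#' (`valid = FALSE`) and should be excluded from codon statistics; they are
#' never silently dropped.
#'
#' @param genome A [plastid_genome()].
#' @return Data frame with one row per CDS feature: `gene`, `sequence`,
#'   `length`, `n_codons`, `valid`, `reason`.
#' @export
extract_cds <- function(genome) {
  is_cds <- vapply(genome$features, function(f) f$kind == "CDS", logical(1))
  feats <- genome$features[is_cds]
  if (!length(feats)) {
    return(data.frame(gene = character(0), sequence = character(0),
                      length = integer(0), n_codons = integer(0),
                      valid = logical(0), reason = character(0)))
  }
  code <- plastid_genetic_code()
  rows <- lapply(feats, function(f) {
    s <- splice_feature(genome, f)
    n <- nchar(s)
    valid <- TRUE
    reason <- NA_character_
    if (n == 0L || n %% 3L != 0L) {
      valid <- FALSE
      reason <- "length_not_multiple_of_3"
    } else {
      cods <- split_codons(s)
      known <- cods %in% names(code)
      aa <- rep(NA_character_, length(cods))
      aa[known] <- code[cods[known]]
      internal_stop <- any(aa[-length(aa)] == "*", na.rm = TRUE)
      if (internal_stop) {
        valid <- FALSE
        reason <- "internal_stop"
      }
    }
    data.frame(gene = f$gene_name, sequence = s, length = n,
               n_codons = n %/% 3L, valid = valid, reason = reason)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Named vector of valid CDS sequences (IR duplicates deduplicated by name
# when `unique_genes`), convenience for codon statistics.
#' Valid coding sequences of a genome
#'
#' @param genome A [plastid_genome()].
#' @param unique_genes Keep only the first feature per gene name (drops
#'   inverted-repeat duplicates).
#' @return Named character vector of spliced, QC-passing CDS.
#' @export
valid_cds <- function(genome, unique_genes = TRUE) {
  tab <- extract_cds(genome)
  tab <- tab[tab$valid, , drop = FALSE]
  if (unique_genes && nrow(tab)) tab <- tab[!duplicated(tab$gene), , drop = FALSE]
  stats::setNames(tab$sequence, tab$gene)
}

# ---- Region classification --------------------------------------------------

#' Classify every base as CDS, intron or IGS
#'
#' Each base is labelled `CDS` if covered by any CDS part; otherwise `intron`
#' if it lies in the gap between consecutive parts of a multi-part gene
#' (CDS, tRNA or rRNA); otherwise `IGS`. Precedence on overlap is
#' CDS > intron > IGS. The labels partition the genome exactly.
#'
#' @param genome A [plastid_genome()].
#' @return An [S4Vectors::Rle] of a factor with levels CDS, intron, IGS and
#'   length equal to the genome length.
#' @export
classify_regions <- function(genome) {
  n <- genome$length
  lab <- rep.int(3L, n)  # 1 = CDS, 2 = intron, 3 = IGS
  positions <- function(start, end, wraps) {
    if (wraps) c(start:n, 1:end) else start:end
  }
  for (f in genome$features) {
    if (!f$kind %in% c("CDS", "tRNA", "rRNA")) next
    p <- f$parts
    if (nrow(p) < 2L) next
    q <- p[order(p$start), , drop = FALSE]
    if (any(q$wraps)) next  # intron gaps across the origin are not labelled
    for (i in seq_len(nrow(q) - 1L)) {
      gs <- q$end[i] + 1L
      ge <- q$start[i + 1L] - 1L
      if (gs <= ge) lab[gs:ge] <- pmin(lab[gs:ge], 2L)
    }
  }
  for (f in genome$features) {
    if (f$kind != "CDS") next
    p <- f$parts
    for (i in seq_len(nrow(p))) {
      lab[positions(p$start[i], p$end[i], p$wraps[i])] <- 1L
    }
  }
  S4Vectors::Rle(factor(c("CDS", "intron", "IGS")[lab],
                        levels = c("CDS", "intron", "IGS")))
}

#' Region label at given positions
#'
#' @param annotation Result of [classify_regions()].
#' @param pos Integer vector of 1-based positions.
#' @return Character vector of labels.
#' @export
region_at <- function(annotation, pos) {
  as.character(S4Vectors::decode(annotation[pos]))
}

#' Tabulate region coverage
#'
#' @param annotation Result of [classify_regions()].
#' @return Data frame with `region`, `bases`, `fraction`.
#' @export
region_table <- function(annotation) {
  lev <- c("CDS", "intron", "IGS")
  rv <- as.character(S4Vectors::runValue(annotation))
  rl <- S4Vectors::runLength(annotation)
  bases <- vapply(lev, function(l) sum(rl[rv == l]), numeric(1))
  data.frame(region = lev, bases = as.integer(bases),
             fraction = bases / sum(bases), row.names = NULL)
}
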