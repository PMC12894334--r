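# Genetic-code tables and small sequence utilities shared by all modules.
# The fixed code is translation table 11 (plant plastid / bacterial); its sense
# codons and synonymous families are identical to the standard code.

.pc_cache <- new.env(parent = emptyenv())

#' The plastid genetic code (translation table 11)
#'
#' Named character vector mapping the 64 codons (DNA alphabet, e.g. `"ATG"`)
#' to one-letter amino acids, with `"*"` for the three stop codons.
#'
#' @return Named character vector of length 64.
#' @export
plastid_genetic_code <- function() {
  if (is.null(.pc_cache$code)) {
    code <- Biostrings::getGeneticCode("11")
    attributes(code) <- list(names = names(code))
    .pc_cache$code <- code
  }
  .pc_cache$code
}

pc_codons <- function() names(plastid_genetic_code())

pc_stop_codons <- function() {
  code <- plastid_genetic_code()
  names(code)[code == "*"]
}

pc_sense_codons <- function() {
  setdiff(pc_codons(), pc_stop_codons())
}

#' Synonymous codon families under the plastid code
#'
#' Families are the sets of sense codons sharing an amino acid, restricted to
#' amino acids with at least two synonymous codons (so methionine ATG and
#' tryptophan TGG are excluded). Six-fold families (Leu, Ser, Arg) are kept
#' whole rather than split 2+4, following the CodonW convention.
#'
#' @return Named list (by amino acid) of codon character vectors; 18 families
#'   covering the 59 informative codons.
#' @export
codon_families <- function() {
  if (is.null(.pc_cache$families)) {
    code <- plastid_genetic_code()
    sense <- pc_sense_codons()
    fam <- split(sense, code[sense])
    fam <- fam[order(names(fam))]
    .pc_cache$families <- fam[vapply(fam, length, 1L) >= 2L]
  }
  .pc_cache$families
}

# The 59 informative codons (all sense codons minus ATG, TGG), ordered by
# amino acid then codon so tables/matrices have a stable, readable layout.
pc_informative_codons <- function() {
  if (is.null(.pc_cache$informative)) {
    .pc_cache$informative <- unlist(codon_families(), use.names = FALSE)
  }
  .pc_cache$informative
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences over `{A,C,G,T,N}`.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    if (!nzchar(s)) return("")
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

# Split a coding sequence into its frame-0 codons.
split_codons <- function(cds) {
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("coding sequence length is not a multiple of 3", call. = FALSE)
  if (n == 0L) return(character(0))
  substring(cds, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards. With seed = NULL the code runs on the ambient stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Validate an uppercase DNA string; returns the cleaned sequence or errors.
check_dna <- function(sequence, what = "sequence") {
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop(what, " has length 0", call. = FALSE)
  bad <- gsub("[ACGTN]", "", sequence)
  if (nzchar(bad)) {
    stop(what, " contains characters outside {A,C,G,T,N}: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ","), call. = FALSE)
  }
  sequence
}
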