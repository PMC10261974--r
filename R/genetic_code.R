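# Genetic-code helpers shared by the codon-usage, NG86 and GY94 machinery.
# Code tables come from Biostrings::getGeneticCode(); the default throughout
# the package is NCBI translation table 5 (invertebrate mitochondrial).

SUPPORTED_CODES <- c("1", "2", "4", "5")

#' Genetic code lookup
#'
#' Returns the codon-to-amino-acid map for a supported NCBI translation
#' table. Stop codons are encoded as `"*"`.
#'
#' @param genetic_code_id Character or integer id; one of 1 (standard),
#'   2 (vertebrate mitochondrial), 4 (mold/coelenterate mitochondrial),
#'   5 (invertebrate mitochondrial, the package default).
#' @return Named character vector of length 64 (names are codons).
#' @export
genetic_code <- function(genetic_code_id = "5") {
  id <- as.character(genetic_code_id)
  if (!id %in% SUPPORTED_CODES)
    stopf("unknown genetic_code_id '%s'; supported codes: %s",
          id, paste(SUPPORTED_CODES, collapse = ", "))
  Biostrings::getGeneticCode(id)
}

#' Sense codons of a genetic code
#'
#' @inheritParams genetic_code
#' @return Character vector of non-stop codons, in fixed lexicographic order.
#' @export
sense_codons <- function(genetic_code_id = "5") {
  gc <- genetic_code(genetic_code_id)
  sort(names(gc)[gc != "*"])
}

NUCS <- c("A", "C", "G", "T")

is_transition <- function(from, to) {
  (from %in% c("A", "G") && to %in% c("A", "G")) ||
    (from %in% c("C", "T") && to %in% c("C", "T"))
}

# Split a codon string vector into a character matrix of codons.
split_codons <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n %% 3 != 0) {
    cm_log$add(sprintf("sequence length %d not divisible by 3; trailing %d nt dropped",
                       n, n %% 3))
    seq <- substr(seq, 1, n - n %% 3)
    n <- nchar(seq)
  }
  if (n == 0) return(character(0))
  substring(seq, seq(1, n, 3), seq(3, n, 3))
}

codon_is_unambiguous <- function(codons) {
  !grepl("[^ACGT]", codons)
}

#' Translate codons under a genetic code
#'
#' @param codons Character vector of 3-letter codons.
#' @inheritParams genetic_code
#' @return Character vector of single-letter amino acids ("*" for stops,
#'   NA for codons containing ambiguity).
#' @export
translate_codons <- function(codons, genetic_code_id = "5") {
  gc <- genetic_code(genetic_code_id)
  out <- gc[codons]
  out[!codon_is_unambiguous(codons)] <- NA_character_
  unname(out)
}

# Single-nucleotide neighbours of a codon (9 codons).
codon_neighbours <- function(codon) {
  chars <- strsplit(codon, "")[[1]]
  out <- character(0)
  for (p in 1:3) for (n in setdiff(NUCS, chars[p])) {
    x <- chars; x[p] <- n
    out <- c(out, paste(x, collapse = ""))
  }
  out
}

#' F3x4 codon frequency estimator
#'
#' Estimates equilibrium codon frequencies from position-specific nucleotide
#' frequencies (the F3x4 estimator used by codon models): the frequency of a
#' codon is the product of its nucleotides' frequencies at codon positions
#' 1-3, with stop codons removed and the rest renormalised.
#'
#' @param codon_seqs Character vector of in-frame nucleotide sequences.
#' @inheritParams genetic_code
#' @return Named numeric vector over the code's sense codons, summing to 1.
#' @export
f3x4_frequencies <- function(codon_seqs, genetic_code_id = "5") {
  codons <- unlist(lapply(codon_seqs, split_codons))
  codons <- codons[codon_is_unambiguous(codons)]
  if (length(codons) == 0) stopf("no unambiguous codons to estimate frequencies from")
  mat <- matrix(unlist(strsplit(codons, "")), ncol = 3, byrow = TRUE)
  pos_freq <- lapply(1:3, function(p) {
    f <- table(factor(mat[, p], levels = NUCS))
    as.numeric(f) / sum(f)
  })
  sc <- sense_codons(genetic_code_id)
  pieces <- strsplit(sc, "")
  freq <- vapply(pieces, function(ch) {
    pos_freq[[1]][match(ch[1], NUCS)] *
      pos_freq[[2]][match(ch[2], NUCS)] *
      pos_freq[[3]][match(ch[3], NUCS)]
  }, numeric(1))
  if (sum(freq) <= 0) stopf("degenerate F3x4 frequencies")
  setNames(freq / sum(freq), sc)
}

#' Uniform codon frequencies
#'
#' @inheritParams genetic_code
#' @return Named numeric vector, equal mass on every sense codon.
#' @export
uniform_codon_frequencies <- function(genetic_code_id = "5") {
  sc <- sense_codons(genetic_code_id)
  setNames(rep(1 / length(sc), length(sc)), sc)
}
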