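# Per-gene alignment filtering, polymorphic-site counts and nucleotide
# diversity (Nei's pi). Alignments are plain character matrices over
# A,C,G,T,-,N with sequence ids as rownames.

#' Construct an alignment object
#'
#' @param seqs Named character vector of equal-length aligned sequences
#'   (characters A,C,G,T,-,N), or a character matrix with rownames.
#' @param gene Gene symbol label.
#' @return An `alignment` list with `gene`, `ids`, `matrix` (rows =
#'   sequences), `length` (columns).
#' @export
alignment <- function(seqs, gene = "") {
  if (is.matrix(seqs)) {
    mat <- toupper(seqs)
    ids <- rownames(mat) %||% paste0("seq", seq_len(nrow(mat)))
  } else {
    stopifnot(is.character(seqs), length(seqs) >= 2)
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1) stopf("aligned sequences have unequal lengths")
    mat <- do.call(rbind, strsplit(toupper(seqs), ""))
    ids <- names(seqs) %||% paste0("seq", seq_along(seqs))
  }
  if (nrow(mat) < 2) stopf("alignment needs >= 2 sequences")
  rownames(mat) <- ids
  structure(list(gene = gene, ids = ids, matrix = mat, length = ncol(mat)),
            class = "alignment")
}

#' Read per-gene aligned FASTA
#'
#' @param path FASTA path.
#' @param gene Gene label (defaults to the file name stem).
#' @return An [alignment()].
#' @export
read_alignment_fasta <- function(path, gene = sub("\\.[^.]*$", "", basename(path))) {
  ss <- Biostrings::readDNAStringSet(path)
  alignment(setNames(as.character(ss), names(ss)), gene = gene)
}

#' Filter alignment columns
#'
#' Stand-in for automated block filtering of poorly aligned regions: policy
#' `"strict"` (default) drops every column containing a gap or ambiguity in
#' any sequence; `"none"` passes through unchanged.
#'
#' @param aln An [alignment()].
#' @param policy "strict" or "none".
#' @return Filtered [alignment()] with an added `kept` attribute (column
#'   indices retained).
#' @export
filter_columns <- function(aln, policy = c("strict", "none")) {
  policy <- match.arg(policy)
  mat <- aln$matrix
  if (policy == "none") {
    keep <- seq_len(ncol(mat))
  } else {
    clean <- apply(mat, 2, function(col) all(col %in% NUCS))
    keep <- which(clean)
  }
  if (!length(keep))
    stopf("no columns survive policy '%s'; consider policy 'none'", policy)
  out <- alignment(mat[, keep, drop = FALSE], gene = aln$gene)
  attr(out, "kept") <- keep
  out
}

#' Polymorphic and monomorphic site counts
#'
#' A column is polymorphic iff at least two distinct unambiguous bases occur
#' in it; columns with fewer than two unambiguous bases, or a single distinct
#' base, are monomorphic.
#'
#' @param aln An [alignment()].
#' @return List with `S` (polymorphic) and `monomorphic` counts.
#' @export
polymorphic_sites <- function(aln) {
  poly <- apply(aln$matrix, 2, function(col) {
    b <- unique(col[col %in% NUCS])
    length(b) >= 2
  })
  list(S = sum(poly), monomorphic = sum(!poly))
}

#' Nucleotide diversity (Nei's pi)
#'
#' Average over all unordered sequence pairs of (pairwise differences /
#' pairwise comparable sites); a site is comparable for a pair when both
#' members carry an unambiguous base there. Every distinct base mismatch
#' counts equally (no multiple-hit correction). Pairs with zero comparable
#' sites are excluded with a log entry.
#'
#' @param aln An [alignment()].
#' @return Per-site diversity in \[0, 1\].
#' @export
nucleotide_diversity <- function(aln) {
  mat <- aln$matrix
  n <- nrow(mat)
  stopifnot(n >= 2)
  vals <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    ok <- mat[i, ] %in% NUCS & mat[j, ] %in% NUCS
    if (!any(ok)) {
      cm_log$add(sprintf("pair (%s, %s) has no comparable sites; excluded",
                         aln$ids[i], aln$ids[j]))
      next
    }
    vals <- c(vals, sum(mat[i, ok] != mat[j, ok]) / sum(ok))
  }
  if (!length(vals)) stopf("all sequence pairs lack comparable sites")
  mean(vals)
}

#' Per-gene diversity report
#'
#' Applies the column filter then reports usable length, segregating sites,
#' monomorphic sites, and nucleotide diversity per gene.
#'
#' @param alignments Named list of [alignment()] objects (names = genes).
#' @param policy Column filter policy, see [filter_columns()].
#' @return Data frame: gene, bp, pi, monomorphic, polymorphic.
#' @export
diversity_table <- function(alignments, policy = "strict") {
  do.call(rbind, lapply(names(alignments), function(g) {
    f <- filter_columns(alignments[[g]], policy)
    ps <- polymorphic_sites(f)
    data.frame(gene = g, bp = f$length, pi = nucleotide_diversity(f),
               monomorphic = ps$monomorphic, polymorphic = ps$S,
               stringsAsFactors = FALSE)
  }))
}
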