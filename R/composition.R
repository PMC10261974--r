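# Per-genome and per-group composition statistics: length, A+T%, strand
# skews, codon usage / RSCU, group summaries and rank tests. Skews follow
# AT-skew = (A - T)/(A + T), GC-skew = (G - C)/(G + C); undefined
# denominators yield NA rather than an error.

#' Base composition of a sequence
#'
#' Counts unambiguous bases only; N and other ambiguity codes are excluded
#' from every denominator. A+T% is reported among A+C+G+T.
#'
#' @param sequence Nucleotide string.
#' @return List with `length`, counts `A`,`C`,`G`,`T`, `at_percent`,
#'   `at_skew`, `gc_skew` (NA where the denominator is zero).
#' @export
base_composition <- function(sequence) {
  stopifnot(is_scalar_string(sequence), nzchar(sequence))
  s <- toupper(sequence)
  chars <- strsplit(s, "")[[1]]
  cnt <- table(factor(chars, levels = NUCS))
  A <- unname(cnt["A"]); C <- unname(cnt["C"])
  G <- unname(cnt["G"]); T <- unname(cnt["T"])
  tot <- A + C + G + T
  list(length = nchar(s),
       A = as.integer(A), C = as.integer(C), G = as.integer(G), T = as.integer(T),
       at_percent = if (tot > 0) 100 * (A + T) / tot else NA_real_,
       at_skew = at_skew(list(A = A, T = T)),
       gc_skew = gc_skew(list(G = G, C = C)))
}

#' AT and GC strand skew
#'
#' AT-skew = (A - T)/(A + T); GC-skew = (G - C)/(G + C). A zero denominator
#' gives NA, never an error.
#'
#' @param counts List or vector with components `A`,`T` (resp. `G`,`C`).
#' @return Numeric in \[-1, 1\] or NA.
#' @export
at_skew <- function(counts) {
  A <- as.numeric(counts[["A"]]); T <- as.numeric(counts[["T"]])
  if (A + T == 0) return(NA_real_)
  (A - T) / (A + T)
}

#' @rdname at_skew
#' @export
gc_skew <- function(counts) {
  G <- as.numeric(counts[["G"]]); C <- as.numeric(counts[["C"]])
  if (G + C == 0) return(NA_real_)
  (G - C) / (G + C)
}

#' Composition table for a set of records
#'
#' @param records List of [mitogenome_record()].
#' @return Data frame with one row per record: record_id, length, A, C, G, T,
#'   at_percent, at_skew, gc_skew.
#' @export
composition_table <- function(records) {
  do.call(rbind, lapply(records, function(r) {
    bc <- base_composition(r$sequence)
    data.frame(record_id = r$record_id, length = bc$length,
               A = bc$A, C = bc$C, G = bc$G, T = bc$T,
               at_percent = bc$at_percent, at_skew = bc$at_skew,
               gc_skew = bc$gc_skew, stringsAsFactors = FALSE)
  }))
}

#' Relative synonymous codon usage
#'
#' RSCU(c) = observed(c) * family_size / family_total, where a family is the
#' set of sense codons translating to the same amino acid under the chosen
#' genetic code. Stop codons are excluded; codons containing ambiguity are
#' skipped; sequences whose length is not a multiple of 3 have the remainder
#' dropped with a log entry. Families with zero total get NA for all members.
#'
#' @param cds_sequences Character vector of in-frame coding sequences.
#' @inheritParams genetic_code
#' @return List with `genetic_code_id`, `counts` and `rscu` (both named
#'   numeric vectors over sense codons), and `amino_acid` labels.
#' @export
rscu <- function(cds_sequences, genetic_code_id = "5") {
  gc <- genetic_code(genetic_code_id)
  sc <- sense_codons(genetic_code_id)
  codons <- unlist(lapply(cds_sequences, split_codons))
  codons <- codons[codon_is_unambiguous(codons)]
  codons <- codons[codons %in% sc]           # drop stops
  counts <- table(factor(codons, levels = sc))
  counts <- setNames(as.numeric(counts), sc)
  aa <- gc[sc]
  vals <- rep(NA_real_, length(sc))
  names(vals) <- sc
  for (a in unique(aa)) {
    fam <- sc[aa == a]
    tot <- sum(counts[fam])
    if (tot > 0) vals[fam] <- counts[fam] * length(fam) / tot
  }
  list(genetic_code_id = as.character(genetic_code_id),
       counts = counts, rscu = vals, amino_acid = unname(aa))
}

#' Group summaries of composition statistics
#'
#' Mean and sample standard deviation (n-1 denominator) per group at a
#' chosen taxonomy level for each numeric statistic; SD is reported as 0 and
#' flagged when a group has a single member. Records without a label at the
#' level are excluded with a log entry.
#'
#' @param stats_table Data frame from [composition_table()] (any extra
#'   numeric columns, e.g. gene counts, are summarised too).
#' @param taxonomy Data frame with columns record_id and the taxonomy level.
#' @param level Column of `taxonomy` to group by ("class", "subclass", "order").
#' @return Data frame: group, n, then mean_/sd_ columns per statistic, and a
#'   `single_member` flag.
#' @export
summarize_groups <- function(stats_table, taxonomy, level = "order") {
  stopifnot(is.data.frame(stats_table), nrow(stats_table) >= 1)
  if (!level %in% names(taxonomy)) stopf("taxonomy has no '%s' column", level)
  lab <- taxonomy[[level]][match(stats_table$record_id, taxonomy$record_id)]
  usable <- !is.na(lab) & nzchar(lab)
  if (any(!usable))
    cm_log$add(sprintf("%d records without a '%s' label excluded from group summary",
                       sum(!usable), level))
  stats_table <- stats_table[usable, , drop = FALSE]
  lab <- lab[usable]
  if (!nrow(stats_table)) stopf("no records with a '%s' label", level)
  num_cols <- names(stats_table)[vapply(stats_table, is.numeric, TRUE)]
  groups <- sort(unique(lab))
  do.call(rbind, lapply(groups, function(g) {
    sub <- stats_table[lab == g, num_cols, drop = FALSE]
    n <- nrow(sub)
    row <- data.frame(group = g, n = n, stringsAsFactors = FALSE)
    for (cn in num_cols) {
      row[[paste0("mean_", cn)]] <- mean(sub[[cn]], na.rm = TRUE)
      row[[paste0("sd_", cn)]] <- if (n == 1) 0 else sd(sub[[cn]], na.rm = TRUE)
    }
    row$single_member <- n == 1
    row
  }))
}

#' Two-group rank comparison (Wilcoxon rank-sum / Mann-Whitney)
#'
#' Two-sided; exact enumeration when both groups have n <= 8 and no ties,
#' tie-corrected normal approximation otherwise (stats::wilcox.test).
#'
#' @param values_by_group Named list of numeric vectors.
#' @param a,b Names of the two groups to compare.
#' @return List with `statistic` (W), `p`, `method`, and group sizes.
#' @export
compare_groups <- function(values_by_group, a, b) {
  for (g in c(a, b)) {
    if (is.null(values_by_group[[g]]) || length(values_by_group[[g]]) == 0)
      stopf("group '%s' is empty or absent", g)
  }
  x <- values_by_group[[a]]; y <- values_by_group[[b]]
  exact <- length(x) <= 8 && length(y) <= 8 && !anyDuplicated(c(x, y))
  wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided",
                                     exact = exact, correct = !exact))
  list(statistic = unname(wt$statistic), p = wt$p.value,
       method = if (exact) "exact" else "normal approximation",
       n = c(length(x), length(y)))
}

#' Significance stars for p values
#'
#' Thresholds .05 / .01 / .001, matching the convention of the report tables.
#'
#' @param p Numeric vector of p values.
#' @return Character vector of "", "*", "**", "***".
#' @export
p_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
}

#' Correlation between AT and GC skew across genomes
#'
#' Pearson product-moment correlation over records whose skews are both
#' defined.
#'
#' @param stats_table Data frame with at_skew and gc_skew columns.
#' @return List with `r`, `p`, `n`.
#' @export
skew_correlation <- function(stats_table) {
  ok <- !is.na(stats_table$at_skew) & !is.na(stats_table$gc_skew)
  if (sum(ok) < 3) stopf("need >= 3 records with both skews defined, have %d", sum(ok))
  ct <- cor.test(stats_table$at_skew[ok], stats_table$gc_skew[ok], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}
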