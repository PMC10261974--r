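# Reading/writing the formats the pipeline touches, and normalisation of
# gene identities and coordinates. Coordinates are 0-based half-open on the
# plus strand internally; GenBank's 1-based inclusive convention is converted
# at the boundary. Features crossing the origin of a circular molecule carry
# wraps_origin = TRUE with start > end.

CANONICAL_PCGS <- c("ATP6", "ATP8", "COX1", "COX2", "COX3", "CYTB",
                    "NAD1", "NAD2", "NAD3", "NAD4", "NAD4L", "NAD5", "NAD6")
CANONICAL_RRNAS <- c("rrnS", "rrnL")

#' The 15-gene mitochondrial alphabet
#'
#' The 13 protein-coding genes plus the two rRNAs used for gene-order
#' analysis (tRNA content varies too much across cnidarians to be usable).
#'
#' @return Character vector of 15 canonical gene symbols.
#' @export
gene_alphabet <- function() c(CANONICAL_PCGS, CANONICAL_RRNAS)

.synonym_table <- local({
  syn <- list(
    COX1 = c("cox1", "coi", "co1", "coxi", "mt-co1", "cox-1",
             "cytochrome c oxidase subunit 1", "cytochrome c oxidase subunit i",
             "cytochrome oxidase subunit i", "cytochrome oxidase subunit 1"),
    COX2 = c("cox2", "coii", "co2", "coxii", "mt-co2", "cox-2",
             "cytochrome c oxidase subunit 2", "cytochrome c oxidase subunit ii"),
    COX3 = c("cox3", "coiii", "co3", "coxiii", "mt-co3", "cox-3",
             "cytochrome c oxidase subunit 3", "cytochrome c oxidase subunit iii"),
    CYTB = c("cytb", "cob", "cyb", "mt-cyb", "cyt b", "cytochrome b",
             "apocytochrome b"),
    ATP6 = c("atp6", "atpase6", "atpase 6", "atp synthase f0 subunit 6",
             "atp synthase subunit 6", "atp6 gene"),
    ATP8 = c("atp8", "atpase8", "atpase 8", "atp synthase f0 subunit 8",
             "atp synthase subunit 8"),
    NAD1 = c("nad1", "nd1", "nadh1", "nadh dehydrogenase subunit 1"),
    NAD2 = c("nad2", "nd2", "nadh2", "nadh dehydrogenase subunit 2"),
    NAD3 = c("nad3", "nd3", "nadh3", "nadh dehydrogenase subunit 3"),
    NAD4 = c("nad4", "nd4", "nadh4", "nadh dehydrogenase subunit 4"),
    NAD4L = c("nad4l", "nd4l", "nadh4l", "nadh dehydrogenase subunit 4l"),
    NAD5 = c("nad5", "nd5", "nadh5", "nadh dehydrogenase subunit 5"),
    NAD6 = c("nad6", "nd6", "nadh6", "nadh dehydrogenase subunit 6"),
    rrnS = c("rrns", "rns", "12s", "12s rrna", "12s ribosomal rna", "s-rrna",
             "srrna", "rrn12", "small subunit ribosomal rna", "ssu rrna", "mt-rnr1"),
    rrnL = c("rrnl", "rnl", "16s", "16s rrna", "16s ribosomal rna", "l-rrna",
             "lrrna", "rrn16", "large subunit ribosomal rna", "lsu rrna", "mt-rnr2"),
    trnM = c("trnm", "trna-met", "trnm(cau)", "trna met"),
    trnW = c("trnw", "trna-trp", "trnw(uca)", "trna trp")
  )
  tab <- character(0)
  for (canon in names(syn)) {
    keys <- unique(c(tolower(canon), syn[[canon]]))
    tab[keys] <- canon
  }
  tab["other"] <- "OTHER"
  tab
})

#' Normalise a raw gene name to its canonical symbol
#'
#' Total function: case-insensitive lookup over a synonym table covering the
#' common mitochondrial naming dialects (COI/CO1 -> COX1, ND4L -> NAD4L,
#' 16S/rnl -> rrnL, ...); anything unmapped (additional ORFs, mutS, HEG, ...)
#' maps to "OTHER". Idempotent.
#'
#' @param raw_name Raw gene or product name.
#' @param kind_hint Optional feature kind ("PCG", "rRNA", "tRNA"); used only
#'   to disambiguate bare "12S"/"16S"-style names, never to override a match.
#' @return Canonical symbol (one of [gene_alphabet()], "trnM", "trnW", "OTHER").
#' @export
normalize_gene_name <- function(raw_name, kind_hint = NULL) {
  stopifnot(is_scalar_string(raw_name), nzchar(raw_name))
  key <- tolower(trimws(raw_name))
  key <- sub("^mt[-_]", "mt-", key)
  hit <- .synonym_table[key]
  if (!is.na(hit)) return(unname(hit))
  # tolerate trailing annotations like "COX1 (partial)"
  key2 <- sub("[ _-]*\\(.*\\)$", "", key)
  hit <- .synonym_table[key2]
  if (!is.na(hit)) return(unname(hit))
  "OTHER"
}

feature_kind_for <- function(gene, feature_key = NULL) {
  if (gene %in% CANONICAL_PCGS) return("PCG")
  if (gene %in% CANONICAL_RRNAS) return("rRNA")
  if (grepl("^trn", gene)) return("tRNA")
  if (!is.null(feature_key)) {
    if (feature_key == "CDS") return("PCG")
    if (feature_key == "rRNA") return("rRNA")
    if (feature_key == "tRNA") return("tRNA")
  }
  "other"
}

#' Construct a gene feature
#'
#' @param raw_name Name as annotated.
#' @param gene Canonical symbol (defaults to `normalize_gene_name(raw_name)`).
#' @param kind One of "PCG", "rRNA", "tRNA", "other".
#' @param strand "+" or "-".
#' @param start,end 0-based half-open plus-strand coordinates; `start > end`
#'   only when `wraps_origin` is TRUE.
#' @param wraps_origin Does the feature cross the origin of a circular
#'   molecule?
#' @return A `gene_feature` list.
#' @export
gene_feature <- function(raw_name, gene = normalize_gene_name(raw_name),
                         kind = feature_kind_for(gene),
                         strand = "+", start, end, wraps_origin = FALSE) {
  stopifnot(strand %in% c("+", "-"), start >= 0, end >= 0)
  if (start == end) stopf("feature '%s' has start == end", raw_name)
  if (!wraps_origin && start > end)
    stopf("feature '%s' has start > end but wraps_origin is FALSE", raw_name)
  structure(list(raw_name = raw_name, gene = gene, kind = kind,
                 strand = strand, start = as.integer(start),
                 end = as.integer(end), wraps_origin = isTRUE(wraps_origin)),
            class = "gene_feature")
}

#' Construct a mitogenome record
#'
#' The per-genome unit of analysis: sequence plus typed features plus an
#' optional taxonomy label.
#'
#' @param record_id Accession-like identifier, unique within a dataset.
#' @param sequence Nucleotide string over A,C,G,T,N.
#' @param features List of [gene_feature()] objects.
#' @param taxon Binomial name (may be empty).
#' @param taxonomy Named character vector with entries class, subclass,
#'   order (any may be empty strings).
#' @param topology "circular" or "linear".
#' @return A `mitogenome_record` list.
#' @export
mitogenome_record <- function(record_id, sequence, features = list(),
                              taxon = "", taxonomy = c(class = "", subclass = "", order = ""),
                              topology = "circular") {
  stopifnot(is_scalar_string(record_id), is_scalar_string(sequence),
            topology %in% c("circular", "linear"))
  sequence <- toupper(sequence)
  if (nchar(sequence) < 1) stopf("record '%s': empty sequence", record_id)
  if (grepl("[^ACGTN]", sequence))
    stopf("record '%s': sequence contains characters outside A,C,G,T,N", record_id)
  len <- nchar(sequence)
  for (f in features) {
    if (f$start >= len || f$end > len)
      stopf("record '%s': feature '%s' outside [0, %d)", record_id, f$raw_name, len)
    if (f$wraps_origin && topology == "linear")
      stopf("record '%s': feature '%s' wraps origin on a linear record",
            record_id, f$raw_name)
  }
  tax <- c(class = "", subclass = "", order = "")
  tax[names(taxonomy)] <- taxonomy
  structure(list(record_id = record_id, taxon = taxon, taxonomy = tax,
                 topology = topology, sequence = sequence, features = features),
            class = "mitogenome_record")
}

#' @export
print.mitogenome_record <- function(x, ...) {
  cat(sprintf("<mitogenome_record %s: %s, %d bp, %s, %d features>\n",
              x$record_id, if (nzchar(x$taxon)) x$taxon else "unknown taxon",
              nchar(x$sequence), x$topology, length(x$features)))
  invisible(x)
}

## ---- GenBank flat-file parsing ------------------------------------------

parse_gb_location <- function(loc, seq_len) {
  loc <- gsub("[<>[:space:]]", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  if (grepl("complement|order", loc))
    stopf("unsupported location string: %s", loc)
  parts <- strsplit(loc, ",")[[1]]
  seg <- do.call(rbind, lapply(parts, function(p) {
    if (grepl("\\.\\.", p)) {
      as.integer(strsplit(p, "\\.\\.")[[1]][1:2])
    } else as.integer(c(p, p))
  }))
  wraps <- nrow(seg) > 1 && seg[1, 2] == seq_len && seg[2, 1] == 1
  if (wraps) {
    start <- seg[1, 1] - 1L
    end <- seg[nrow(seg), 2]
  } else {
    start <- min(seg[, 1]) - 1L
    end <- max(seg[, 2])
  }
  list(strand = strand, start = as.integer(start), end = as.integer(end),
       wraps_origin = wraps)
}

parse_one_genbank <- function(lines) {
  locus <- lines[grepl("^LOCUS", lines)][1]
  if (is.na(locus)) stopf("record without LOCUS line")
  locus_fields <- strsplit(trimws(locus), "[[:space:]]+")[[1]]
  topology <- if (any(tolower(locus_fields) == "circular")) "circular" else "linear"
  record_id <- locus_fields[2]
  acc_line <- lines[grepl("^ACCESSION", lines)]
  if (length(acc_line)) {
    acc <- strsplit(trimws(acc_line[1]), "[[:space:]]+")[[1]][2]
    if (!is.na(acc) && nzchar(acc)) record_id <- acc
  }
  org_line <- lines[grepl("^[[:space:]]+ORGANISM", lines)]
  taxon <- if (length(org_line)) trimws(sub("^[[:space:]]+ORGANISM", "", org_line[1])) else ""

  ori_at <- grep("^ORIGIN", lines)
  if (!length(ori_at)) stopf("record %s: no ORIGIN block", record_id)
  seq_lines <- lines[(ori_at[1] + 1):length(lines)]
  sequence <- toupper(gsub("[^a-zA-Z]", "", paste(seq_lines, collapse = "")))
  sequence <- gsub("[^ACGTN]", "N", sequence)
  seq_len <- nchar(sequence)

  feat_at <- grep("^FEATURES", lines)
  features <- list()
  if (length(feat_at)) {
    flines <- lines[(feat_at[1] + 1):(ori_at[1] - 1)]
    # feature headers have the key in columns 6-20
    is_header <- grepl("^ {5}[A-Za-z_'-]+ ", flines) & !grepl("^ {21}", flines)
    idx <- which(is_header)
    for (k in seq_along(idx)) {
      block <- flines[idx[k]:(if (k < length(idx)) idx[k + 1] - 1 else length(flines))]
      key <- trimws(substr(block[1], 1, 20))
      if (!key %in% c("CDS", "rRNA", "tRNA")) next
      # location may continue across lines until the first qualifier
      qual_start <- grep("^ {21}/", block)
      loc_end <- if (length(qual_start)) qual_start[1] - 1 else length(block)
      loc <- paste(trimws(substr(block[1], 21, nchar(block[1]))),
                   paste(trimws(block[seq_len_safe(2, loc_end)]), collapse = ""),
                   sep = "")
      quals <- block[grepl("^ {21}/", block)]
      getq <- function(name) {
        m <- quals[grepl(paste0("^ {21}/", name, "="), quals)]
        if (!length(m)) return(NULL)
        gsub("\"", "", sub(paste0("^ {21}/", name, "="), "", m[1]))
      }
      raw_name <- getq("gene") %||% getq("product") %||% key
      pl <- tryCatch(parse_gb_location(loc, seq_len), error = function(e) NULL)
      if (is.null(pl)) {
        cm_log$add(sprintf("record %s: unparseable location '%s' skipped", record_id, loc))
        next
      }
      g <- normalize_gene_name(raw_name)
      features <- c(features, list(gene_feature(
        raw_name = raw_name, gene = g, kind = feature_kind_for(g, key),
        strand = pl$strand, start = pl$start, end = pl$end,
        wraps_origin = pl$wraps_origin)))
    }
  }
  mitogenome_record(record_id = record_id, sequence = sequence,
                    features = features, taxon = taxon, topology = topology)
}

seq_len_safe <- function(from, to) if (to < from) integer(0) else from:to

#' Read mitogenome records from a GenBank flat file
#'
#' A focused parser for the GenBank dialect this pipeline consumes: LOCUS
#' topology, ACCESSION, ORGANISM, CDS/rRNA/tRNA features with
#' `complement()`/`join()` locations (origin-spanning joins on circular
#' molecules are resolved to a wrap flag), and the ORIGIN sequence. One
#' record per LOCUS entry; a record that fails to parse is reported with its
#' index and skipped.
#'
#' @param path Path to a GenBank flat file (one or more entries).
#' @return List of [mitogenome_record()] objects.
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  ends <- grep("^//", lines)
  if (!length(ends)) stopf("no GenBank records found in %s", path)
  starts <- c(1, head(ends, -1) + 1)
  records <- list()
  for (i in seq_along(ends)) {
    chunk <- lines[starts[i]:(ends[i] - 1)]
    if (!any(grepl("^LOCUS", chunk))) next
    rec <- tryCatch(parse_one_genbank(chunk), error = function(e) {
      cm_log$add(sprintf("GenBank record %d in %s failed to parse: %s",
                         i, path, conditionMessage(e)))
      NULL
    })
    if (!is.null(rec)) records <- c(records, list(rec))
  }
  if (!length(records)) stopf("no parseable GenBank records in %s", path)
  ids <- vapply(records, `[[`, "", "record_id")
  if (anyDuplicated(ids)) stopf("duplicate record ids: %s",
                                paste(unique(ids[duplicated(ids)]), collapse = ", "))
  records
}

## ---- sequence extraction -------------------------------------------------

#' Extract a feature's nucleotide sequence from its record
#'
#' Takes the plus-strand slice (joining across the origin for wrapping
#' features on circular molecules) and reverse-complements it when the
#' feature is on the minus strand.
#'
#' @param record A [mitogenome_record()].
#' @param feature A [gene_feature()] belonging to `record`.
#' @return Nucleotide string.
#' @export
extract_gene_sequence <- function(record, feature) {
  len <- nchar(record$sequence)
  if (feature$wraps_origin) {
    if (record$topology == "linear")
      stopf("feature '%s' wraps origin on linear record '%s'",
            feature$raw_name, record$record_id)
    s <- paste0(substr(record$sequence, feature$start + 1, len),
                substr(record$sequence, 1, feature$end))
  } else {
    s <- substr(record$sequence, feature$start + 1, feature$end)
  }
  if (feature$strand == "-") revcomp(s) else s
}

## ---- tables ---------------------------------------------------------------

#' Write a data frame as a deterministic TSV
#'
#' UTF-8, tab-separated, header row, no quoting, no row names; column order
#' as given. The inverse of [read_tsv_strict()].
#'
#' @param rows A data frame.
#' @param path Output path.
#' @export
write_table <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  write.table(rows, file = path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a TSV written by [write_table()], validating row widths
#'
#' @param path Input path.
#' @return Data frame.
#' @export
read_tsv_strict <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (!length(lines)) stopf("empty table: %s", path)
  # field count = tab count + 1 (strsplit would drop trailing empty fields)
  widths <- vapply(lines, function(x)
    sum(gregexpr("\t", x, fixed = TRUE)[[1]] > 0) + 1L, 0L, USE.NAMES = FALSE)
  ncol_expected <- widths[1]
  bad <- which(widths != ncol_expected)
  if (length(bad))
    stopf("%s: line %d has %d of %d columns", path, bad[1], widths[bad[1]], ncol_expected)
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

FEATURE_TABLE_COLS <- c("record_id", "gene", "kind", "strand", "start", "end", "wraps_origin")

#' Write records' features as a feature-table TSV
#'
#' @param records List of [mitogenome_record()].
#' @param path Output path.
#' @export
write_feature_table <- function(records, path) {
  rows <- do.call(rbind, lapply(records, function(r) {
    if (!length(r$features)) return(NULL)
    do.call(rbind, lapply(r$features, function(f) {
      data.frame(record_id = r$record_id, gene = f$gene, kind = f$kind,
                 strand = f$strand, start = f$start, end = f$end,
                 wraps_origin = f$wraps_origin, stringsAsFactors = FALSE)
    }))
  }))
  write_table(rows[, FEATURE_TABLE_COLS], path)
}

#' Read mitogenome records from FASTA plus a feature table
#'
#' The FASTA supplies sequences (names are record ids); the TSV supplies
#' typed features with columns record_id, gene, kind, strand, start, end,
#' wraps_origin (0-based half-open). An optional taxonomy TSV (record_id,
#' taxon, class, subclass, order) attaches labels.
#'
#' @param fasta Path to a FASTA of genome sequences.
#' @param tsv Path to the feature-table TSV.
#' @param taxonomy Optional path to a taxonomy TSV.
#' @param topology Topology for all records ("circular" default) or a named
#'   character vector by record id.
#' @return List of [mitogenome_record()].
#' @export
read_feature_table <- function(fasta, tsv, taxonomy = NULL, topology = "circular") {
  seqs <- Biostrings::readDNAStringSet(fasta)
  feats <- read_tsv_strict(tsv)
  missing_cols <- setdiff(FEATURE_TABLE_COLS, names(feats))
  if (length(missing_cols))
    stopf("feature table %s missing columns: %s", tsv, paste(missing_cols, collapse = ", "))
  tax <- if (!is.null(taxonomy)) read_tsv_strict(taxonomy) else NULL
  ids <- names(seqs)
  lapply(ids, function(id) {
    sub <- feats[feats$record_id == id, , drop = FALSE]
    fl <- lapply(seq_len(nrow(sub)), function(i) {
      gene_feature(raw_name = sub$gene[i], gene = sub$gene[i], kind = sub$kind[i],
                   strand = sub$strand[i], start = sub$start[i], end = sub$end[i],
                   wraps_origin = as.logical(sub$wraps_origin[i]))
    })
    topo <- if (length(topology) > 1) unname(topology[id]) else topology
    tx <- c(class = "", subclass = "", order = "")
    taxon <- ""
    if (!is.null(tax) && id %in% tax$record_id) {
      row <- tax[match(id, tax$record_id), ]
      taxon <- row$taxon %||% ""
      for (lv in c("class", "subclass", "order"))
        if (lv %in% names(row)) tx[lv] <- as.character(row[[lv]])
    }
    mitogenome_record(record_id = id, sequence = as.character(seqs[[id]]),
                      features = fl, taxon = taxon, taxonomy = tx, topology = topo)
  })
}

#' Read / write newick trees
#'
#' Thin wrappers over ape preserving branch lengths and internal labels.
#'
#' @param path File path.
#' @param tree An `ape::phylo` object.
#' @return `read_newick` returns a `phylo`; `write_newick` returns the path.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  ape::read.tree(path)
}

#' @rdname read_newick
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Keep the first feature per canonical gene symbol
#'
#' Duplicate annotations with the same canonical symbol are resolved by
#' keeping the earliest start coordinate; the rest are logged and dropped.
#' "OTHER" features are never deduplicated.
#'
#' @param record A [mitogenome_record()].
#' @return The record with deduplicated features.
#' @export
dedupe_features <- function(record) {
  feats <- record$features
  if (!length(feats)) return(record)
  ord <- order(vapply(feats, `[[`, 0L, "start"))
  feats <- feats[ord]
  seen <- character(0)
  keep <- logical(length(feats))
  for (i in seq_along(feats)) {
    g <- feats[[i]]$gene
    if (g == "OTHER" || !(g %in% seen)) {
      keep[i] <- TRUE
      seen <- c(seen, g)
    } else {
      cm_log$add(sprintf("record %s: duplicate feature %s at %d dropped",
                         record$record_id, g, feats[[i]]$start))
    }
  }
  record$features <- feats[keep]
  record
}
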