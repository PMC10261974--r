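# Signed gene-order analysis over the 15-gene mitochondrial alphabet:
# extraction from annotated records, canonical circular form, exact-match
# pattern grouping, common-interval similarity, rearrangement events
# (inversion, transposition, reverse transposition, TDRL), scenario
# inference, and distance matrices. Orders are stored as parallel `genes`
# (symbols) and `signs` (+1/-1) vectors; rearrangement arithmetic is done on
# signed integer permutations and mapped back.

#' Construct a signed gene order
#'
#' @param genes Character vector of gene symbols, each exactly once.
#' @param signs Integer vector of +1/-1 orientations (or "+"/"-" characters).
#' @param record_id Identifier of the source record.
#' @param from "circular" or "linear" (provenance note; linear orders are
#'   compared in the same circular embedding).
#' @return A `signed_gene_order`.
#' @export
signed_gene_order <- function(genes, signs = rep(1L, length(genes)),
                              record_id = "", from = "circular") {
  stopifnot(length(genes) == length(signs), length(genes) >= 1)
  if (is.character(signs)) signs <- ifelse(signs == "-", -1L, 1L)
  signs <- as.integer(sign(signs))
  if (any(signs == 0)) stopf("signs must be +1 or -1")
  if (anyDuplicated(genes)) stopf("duplicate genes in order: %s",
                                  paste(genes[duplicated(genes)], collapse = ", "))
  structure(list(genes = as.character(genes), signs = signs,
                 record_id = record_id, from = from),
            class = "signed_gene_order")
}

#' @export
print.signed_gene_order <- function(x, ...) {
  cat(order_string(x), "\n")
  invisible(x)
}

#' Render a signed gene order as a string
#'
#' @param order A [signed_gene_order()].
#' @return String like `"+COX1 -NAD4 ..."`.
#' @export
order_string <- function(order) {
  paste0(ifelse(order$signs < 0, "-", "+"), order$genes, collapse = " ")
}

#' Parse a signed gene order from its string form
#'
#' @param s String like `"+COX1 -NAD4 ..."` (a bare symbol means "+").
#' @inheritParams signed_gene_order
#' @return A [signed_gene_order()].
#' @export
parse_order <- function(s, record_id = "", from = "circular") {
  toks <- strsplit(trimws(s), "[[:space:]]+")[[1]]
  signs <- ifelse(substr(toks, 1, 1) == "-", -1L, 1L)
  genes <- sub("^[+-]", "", toks)
  signed_gene_order(genes, signs, record_id = record_id, from = from)
}

#' Canonical circular form of a signed gene order
#'
#' Rotates the order so the anchor gene (COX1 by default) comes first; if
#' the anchor is on the minus strand the whole order is reflected (reversed
#' with all signs flipped) first, so the anchor is always "+". Rotations and
#' full reflections of the same circular arrangement therefore share one
#' canonical form. Linear orders are embedded as circular for comparison;
#' their provenance is kept in `$from`.
#'
#' @param order A [signed_gene_order()].
#' @param anchor Gene used as the rotation anchor.
#' @return Canonicalised [signed_gene_order()].
#' @export
canonicalize <- function(order, anchor = "COX1") {
  i <- match(anchor, order$genes)
  if (is.na(i)) stopf("anchor gene '%s' absent from order", anchor)
  genes <- order$genes; signs <- order$signs
  if (signs[i] < 0) {
    genes <- rev(genes); signs <- rev(-signs)
    i <- match(anchor, genes)
  }
  n <- length(genes)
  rot <- ((seq_len(n) + i - 2) %% n) + 1
  signed_gene_order(genes[rot], signs[rot], record_id = order$record_id,
                    from = order$from)
}

#' Extract the signed gene order of a record
#'
#' Orders the alphabet genes by start coordinate (a feature wrapping the
#' origin of a circular record sorts by its start; the rotation is
#' immaterial after canonicalisation), takes orientation from the strand,
#' and canonicalises. Records missing any alphabet gene are rejected
#' (callers exclude them with a log entry; see [extract_gene_orders()]).
#'
#' @param record A [mitogenome_record()] (deduplicated features).
#' @param alphabet Gene symbols required, default [gene_alphabet()].
#' @return A [signed_gene_order()].
#' @export
extract_gene_order <- function(record, alphabet = gene_alphabet()) {
  record <- dedupe_features(record)
  feats <- Filter(function(f) f$gene %in% alphabet, record$features)
  genes <- vapply(feats, `[[`, "", "gene")
  if (anyDuplicated(genes))
    stopf("record %s: duplicate gene symbols after dedup", record$record_id)
  missing <- setdiff(alphabet, genes)
  if (length(missing))
    stopf("record %s missing genes: %s", record$record_id,
          paste(missing, collapse = ", "))
  ord <- order(vapply(feats, `[[`, 0L, "start"))
  so <- signed_gene_order(
    genes[ord],
    ifelse(vapply(feats, `[[`, "", "strand")[ord] == "-", -1L, 1L),
    record_id = record$record_id,
    from = if (record$topology == "circular") "circular" else "linear")
  canonicalize(so, default_anchor(so$genes))
}

# COX1 when present, else the first alphabet gene present, else the first gene.
default_anchor <- function(genes) {
  if ("COX1" %in% genes) return("COX1")
  hit <- intersect(gene_alphabet(), genes)
  if (length(hit)) hit[1] else genes[1]
}

#' Extract gene orders for a set of records, excluding incomplete ones
#'
#' @param records List of [mitogenome_record()].
#' @inheritParams extract_gene_order
#' @return List of [signed_gene_order()]; records missing alphabet genes
#'   are skipped with a log entry.
#' @export
extract_gene_orders <- function(records, alphabet = gene_alphabet()) {
  out <- list()
  for (r in records) {
    o <- tryCatch(extract_gene_order(r, alphabet), error = function(e) {
      cm_log$add(sprintf("record %s excluded from gene-order analysis: %s",
                         r$record_id, conditionMessage(e)))
      NULL
    })
    if (!is.null(o)) out <- c(out, list(o))
  }
  out
}

#' Group identical canonical orders into patterns
#'
#' Exact-match grouping on the canonical form; patterns sorted by
#' descending member count, ties broken lexicographically on the canonical
#' string; pattern ids GO1, GO2, ... assigned in that order.
#'
#' @param orders List of [signed_gene_order()] (canonicalised internally).
#' @return List of patterns, each with `pattern_id`, `order`
#'   (a [signed_gene_order()]), `members` (record ids), `count`.
#' @export
group_patterns <- function(orders) {
  stopifnot(length(orders) >= 1)
  canon <- lapply(orders, function(o) canonicalize(o, default_anchor(o$genes)))
  keys <- vapply(canon, order_string, "")
  ids <- vapply(orders, `[[`, "", "record_id")
  uk <- unique(keys)
  counts <- vapply(uk, function(k) sum(keys == k), 0L)
  ord <- order(-counts, uk)
  uk <- uk[ord]; counts <- counts[ord]
  lapply(seq_along(uk), function(i) {
    members <- ids[keys == uk[i]]
    list(pattern_id = paste0("GO", i),
         order = canon[[match(uk[i], keys)]],
         members = members, count = counts[[i]])
  })
}

## ---- signed-integer workspace --------------------------------------------

# Map a signed_gene_order into signed integers relative to a reference gene
# vector (value = index of the gene in `ref`, sign = orientation).
so_to_ints <- function(order, ref) {
  idx <- match(order$genes, ref)
  if (anyNA(idx)) stopf("order contains genes absent from reference: %s",
                        paste(order$genes[is.na(idx)], collapse = ", "))
  idx * order$signs
}

ints_to_so <- function(v, ref, record_id = "", from = "circular") {
  signed_gene_order(ref[abs(v)], sign(v), record_id = record_id, from = from)
}

## ---- common intervals -----------------------------------------------------

#' Common intervals of two gene orders
#'
#' A common interval is a gene subset, of size 1 up to n, that occupies a
#' contiguous block in both orders (signs ignored). Counts include the n
#' singletons and the full set, so identical orders of n genes share
#' n(n+1)/2 common intervals. Enumeration is over all windows of the first
#' order, checking contiguity in the second via position spans.
#'
#' @param order_a,order_b [signed_gene_order()] objects over the same genes.
#' @return List with `count` and `intervals` (list of gene-symbol vectors).
#' @export
common_intervals <- function(order_a, order_b) {
  if (!setequal(order_a$genes, order_b$genes))
    stopf("orders have different gene sets")
  n <- length(order_a$genes)
  posb <- match(order_a$genes, order_b$genes)
  count <- 0L
  intervals <- list()
  for (i in seq_len(n)) {
    lo <- posb[i]; hi <- posb[i]
    for (j in i:n) {
      lo <- min(lo, posb[j]); hi <- max(hi, posb[j])
      if (hi - lo == j - i) {
        count <- count + 1L
        intervals <- c(intervals, list(order_a$genes[i:j]))
      }
    }
  }
  list(count = count, intervals = intervals)
}

#' Maximum possible common-interval count for n genes
#'
#' @param n Number of genes.
#' @return n(n+1)/2.
#' @export
ci_max <- function(n) n * (n + 1) / 2

## ---- rearrangement events -------------------------------------------------

#' Construct a rearrangement event
#'
#' Event vocabulary: `inversion` reverses a contiguous block and flips its
#' signs; `transposition` moves a block so it starts at `dest` (position in
#' the resulting order); `reverse_transposition` moves and inverts it; `TDRL`
#' duplicates the whole order in tandem and keeps, for each position, the
#' copy named by `partition` ("L" = left copy, "R" = right copy), so the
#' result is the "L" genes in order followed by the "R" genes in order.
#'
#' @param type One of "inversion", "transposition", "reverse_transposition",
#'   "TDRL".
#' @param block Integer c(i, j), 1-based inclusive positions.
#' @param dest Destination start position (transpositions only).
#' @param partition Character vector of "L"/"R", one per position (TDRL only).
#' @return A `rearrangement_event`.
#' @export
rearrangement_event <- function(type, block = NULL, dest = NULL, partition = NULL) {
  type <- match.arg(type, c("inversion", "transposition",
                            "reverse_transposition", "TDRL"))
  structure(list(type = type, block = block, dest = dest, partition = partition),
            class = "rearrangement_event")
}

#' @export
print.rearrangement_event <- function(x, ...) {
  detail <- switch(x$type,
    inversion = sprintf("[%d..%d]", x$block[1], x$block[2]),
    transposition = ,
    reverse_transposition = sprintf("[%d..%d] -> %d", x$block[1], x$block[2], x$dest),
    TDRL = paste(x$partition, collapse = ""))
  cat(sprintf("<%s %s>\n", x$type, detail))
  invisible(x)
}

apply_event_ints <- function(v, event) {
  n <- length(v)
  if (event$type == "TDRL") {
    if (length(event$partition) != n || !all(event$partition %in% c("L", "R")))
      stopf("TDRL partition must be 'L'/'R' of length %d", n)
    return(c(v[event$partition == "L"], v[event$partition == "R"]))
  }
  i <- event$block[1]; j <- event$block[2]
  if (is.null(i) || i < 1 || j > n || i > j) stopf("block [%s..%s] out of range",
                                                   event$block[1], event$block[2])
  if (event$type == "inversion") {
    v[i:j] <- -rev(v[i:j])
    return(v)
  }
  blk <- v[i:j]
  if (event$type == "reverse_transposition") blk <- -rev(blk)
  rest <- v[-(i:j)]
  d <- event$dest
  if (is.null(d) || d < 1 || d > length(rest) + 1)
    stopf("destination %s out of range", d)
  append(rest, blk, after = d - 1)
}

#' Apply a rearrangement event to an order
#'
#' @param order A [signed_gene_order()] or a signed integer vector.
#' @param event A [rearrangement_event()].
#' @return Object of the same representation as `order`.
#' @export
apply_event <- function(order, event) {
  if (inherits(order, "signed_gene_order")) {
    v <- seq_along(order$genes) * order$signs
    w <- apply_event_ints(v, event)
    return(signed_gene_order(order$genes[abs(w)], sign(w),
                             record_id = order$record_id, from = order$from))
  }
  apply_event_ints(order, event)
}

#' Replay a list of events
#'
#' @param order Starting order (either representation).
#' @param events List of [rearrangement_event()].
#' @return Final order.
#' @export
replay_events <- function(order, events) {
  for (e in events) order <- apply_event(order, e)
  order
}

## ---- TDRL distance --------------------------------------------------------

# Number of maximal runs of consecutive values sitting at increasing
# positions: k = 1 + #{v : pos(v+1) < pos(v)} for an unsigned permutation.
tdrl_runs <- function(perm) {
  pos <- order(perm)            # pos[v] = position of value v
  1L + sum(diff(pos) < 0)
}

#' TDRL distance between two orders
#'
#' Minimum number of tandem-duplication-random-loss events transforming
#' `order` into `target`: relabel so the target is the identity, then
#' ceil(log2(k)) where k is the number of maximal runs of consecutive
#' values at increasing positions. TDRL preserves signs, so the two orders
#' must agree in orientation gene-by-gene.
#'
#' @param order,target [signed_gene_order()] objects (or signed integer
#'   vectors) over the same gene set.
#' @return Non-negative integer.
#' @export
tdrl_distance <- function(order, target) {
  v <- relabel_to_target(order, target)
  if (any(v < 0))
    stopf("orders differ in gene orientation; compose with inversions first")
  k <- tdrl_runs(v)
  if (k == 1) 0L else as.integer(ceiling(log2(k)))
}

# Express `order` in coordinates where `target` is +1..+n.
relabel_to_target <- function(order, target) {
  if (inherits(order, "signed_gene_order")) {
    if (!setequal(order$genes, target$genes)) stopf("orders have different gene sets")
    pos <- match(order$genes, target$genes)
    pos * order$signs * target$signs[pos]
  } else {
    pos <- match(abs(order), abs(target))
    if (anyNA(pos)) stopf("orders have different gene sets")
    pos * sign(order) * sign(target)[pos]
  }
}

# Constructive TDRL sorting of an unsigned permutation to the identity:
# each round keeps the odd-indexed value-runs in the left copy, halving the
# run count. Returns the list of TDRL events (partitions refer to the
# permutation state they apply to).
sort_tdrl <- function(perm) {
  events <- list()
  v <- perm
  while (tdrl_runs(v) > 1) {
    pos <- order(v)
    run_id <- cumsum(c(1, diff(pos) < 0))     # run index per value
    run_of_pos <- run_id[v]                   # run index per position
    part <- ifelse(run_of_pos %% 2 == 1, "L", "R")
    ev <- rearrangement_event("TDRL", partition = part)
    events <- c(events, list(ev))
    v <- apply_event_ints(v, ev)
  }
  events
}

## ---- scenario inference ---------------------------------------------------

# Detect whether signed permutation s is one event away from the identity;
# returns the correcting event or NULL. O(n).
detect_single_to_identity <- function(s) {
  n <- length(s)
  if (all(s == seq_len(n))) return(NULL)
  mism <- which(s != seq_len(n))
  i <- mism[1]; j <- mism[length(mism)]
  mid <- s[i:j]
  w <- j - i + 1
  # inversion: mid = -(j), ..., -(i)
  if (all(mid == -(j:i)))
    return(rearrangement_event("inversion", block = c(i, j)))
  # transposition: mid is a rotation [c..j, i..c-1], all positive
  if (all(mid > 0)) {
    ci <- match(i, mid)
    if (!is.na(ci) && ci > 1) {
      c0 <- mid[1]
      if (all(mid == c(c0:j, i:(c0 - 1))))
        return(rearrangement_event("transposition",
                                   block = c(i, i + j - c0), dest = c0))
    }
  }
  # reverse transposition, inverted block on the left: [-(j)..-(c), i..c-1]
  if (mid[1] < 0 && mid[w] > 0) {
    c0 <- abs(mid[sum(mid < 0)])              # value of last negative entry
    if (c0 > i && all(mid == c(-(j:c0), i:(c0 - 1))))
      return(rearrangement_event("reverse_transposition",
                                 block = c(i, i + j - c0), dest = c0))
  }
  # reverse transposition, inverted block on the right: [c..j, -(c-1)..-(i)]
  if (mid[1] > 0 && mid[w] < 0) {
    c0 <- mid[1]
    if (c0 > i && c0 <= j && all(mid == c(c0:j, -((c0 - 1):i))))
      return(rearrangement_event("reverse_transposition",
                                 block = c(i + j - c0 + 1, j), dest = i))
  }
  NULL
}

# Deterministic enumeration of all candidate single events on n positions.
enumerate_events <- function(n) {
  out <- list()
  for (i in 1:n) for (j in i:n)
    out <- c(out, list(rearrangement_event("inversion", block = c(i, j))))
  if (n >= 2) {
    for (len in 1:(n - 1)) for (i in 1:(n - len + 1)) {
      j <- i + len - 1
      for (d in 1:(n - len + 1)) {
        if (d == i) next
        out <- c(out, list(rearrangement_event("transposition", block = c(i, j), dest = d)))
      }
    }
    for (len in 1:(n - 1)) for (i in 1:(n - len + 1)) {
      j <- i + len - 1
      for (d in 1:(n - len + 1))
        out <- c(out, list(rearrangement_event("reverse_transposition",
                                               block = c(i, j), dest = d)))
    }
  }
  out
}

#' Infer a rearrangement scenario between two gene orders
#'
#' Layered heuristic. (1) equal orders: empty scenario; (2) a single
#' inversion / transposition / reverse transposition detected directly;
#' (3) two-event composites found by trying every candidate first event and
#' re-running single-event detection; (4) otherwise, sign differences are
#' resolved by inverting each maximal run of wrongly-oriented genes, then
#' the minimum number of TDRL events finishes the sort. The returned events
#' always replay the source into the target (verified internally); the
#' `heuristic` flag is TRUE when layer 4 was used, where minimality is not
#' guaranteed.
#'
#' @param source,target [signed_gene_order()] objects over the same genes
#'   (canonicalised internally when they carry the anchor gene), or signed
#'   integer vectors.
#' @return A `scenario`: `source`, `target`, `events`, `counts` (by type),
#'   `heuristic`.
#' @export
infer_scenario <- function(source, target) {
  if (inherits(source, "signed_gene_order")) {
    anchor <- default_anchor(source$genes)
    source <- canonicalize(source, anchor)
    target <- canonicalize(target, anchor)
  }
  s <- relabel_to_target(source, target)
  n <- length(s)
  events <- list()
  heuristic <- FALSE

  if (!all(s == seq_len(n))) {
    e1 <- detect_single_to_identity(s)
    if (!is.null(e1)) {
      events <- list(e1)
    } else {
      # two preference passes: composites of elementary events (inversions,
      # transpositions) first, reverse transpositions only when needed
      found <- NULL
      cands <- enumerate_events(n)
      elementary <- c("inversion", "transposition")
      for (pass in 1:2) {
        for (cand in cands) {
          if (pass == 1 && !cand$type %in% elementary) next
          s2 <- apply_event_ints(s, cand)
          e2 <- detect_single_to_identity(s2)
          if (all(s2 == seq_len(n))) { found <- list(cand); break }
          if (!is.null(e2)) {
            if (pass == 1 && !e2$type %in% elementary) next
            found <- list(cand, e2); break
          }
        }
        if (!is.null(found)) break
      }
      if (!is.null(found)) {
        events <- found
      } else {
        heuristic <- TRUE
        v <- s
        # fix signs: invert each maximal run of negative entries
        neg <- which(v < 0)
        while (length(neg)) {
          i <- neg[1]
          j <- i
          while (j < n && v[j + 1] < 0) j <- j + 1
          ev <- rearrangement_event("inversion", block = c(i, j))
          events <- c(events, list(ev))
          v <- apply_event_ints(v, ev)
          neg <- which(v < 0)
        }
        events <- c(events, sort_tdrl(v))
      }
    }
  }
  # soundness: replay must transform source into target exactly
  check <- replay_events(s, events)
  if (!all(check == seq_len(n)))
    stopf("internal error: scenario does not replay source into target")
  types <- vapply(events, `[[`, "", "type")
  counts <- vapply(c("inversion", "transposition", "reverse_transposition", "TDRL"),
                   function(t) sum(types == t), 0L)
  structure(list(source = source, target = target, events = events,
                 counts = counts, heuristic = heuristic),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario: %d events (%s)%s>\n", length(x$events),
              paste(sprintf("%s=%d", names(x$counts), x$counts), collapse = ", "),
              if (x$heuristic) ", heuristic" else ""))
  invisible(x)
}

#' Distance matrix between gene-order patterns
#'
#' Metric `"ci"`: d = 1 - CI(a,b)/CI_max(n), a dissimilarity in \[0, 1\];
#' metric `"events"`: the replayed scenario length from [infer_scenario()]
#' (computed once per unordered pair, so the matrix is symmetric with a zero
#' diagonal).
#'
#' @param patterns List of patterns from [group_patterns()].
#' @param metric "ci" or "events".
#' @return Numeric matrix with pattern ids as dimnames.
#' @export
pattern_distance_matrix <- function(patterns, metric = c("ci", "events")) {
  metric <- match.arg(metric)
  if (length(patterns) < 2) stopf("need >= 2 patterns")
  np <- length(patterns)
  ids <- vapply(patterns, `[[`, "", "pattern_id")
  m <- matrix(0, np, np, dimnames = list(ids, ids))
  n <- length(patterns[[1]]$order$genes)
  for (i in 1:(np - 1)) for (j in (i + 1):np) {
    d <- if (metric == "ci") {
      1 - common_intervals(patterns[[i]]$order, patterns[[j]]$order)$count / ci_max(n)
    } else {
      length(infer_scenario(patterns[[i]]$order, patterns[[j]]$order)$events)
    }
    m[i, j] <- d; m[j, i] <- d
  }
  m
}
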