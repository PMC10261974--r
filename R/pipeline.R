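# Orchestration: validate a flat key=value (or list) configuration, run the
# analysis stages over a dataset, and write the report tables. Stages are
# isolated: a failing stage is recorded and the rest still run. All tables
# are sorted deterministically and written once.

PIPELINE_DEFAULTS <- list(
  records_fasta = NULL, features_tsv = NULL, taxonomy_tsv = NULL,
  tree_path = NULL, alignments_dir = NULL,
  genetic_code_id = "5", filter_policy = "strict",
  selection_models = "one_ratio,two_ratio", foreground_class = NULL,
  gene_order_metric = "ci", bootstrap_B = 100,
  stages = "composition,diversity,selection,geneorder,tree",
  outdir = "results", seed = NULL, log_level = "info")

#' Validate and normalise a pipeline configuration
#'
#' Accepts a named list or a path to a flat `key = value` text file
#' (comments with `#`). Unknown keys are rejected by name; defaults fill
#' the rest; comma-separated fields are split. Normalisation is
#' idempotent.
#'
#' @param config Named list or file path.
#' @return A `pipeline_config` list.
#' @export
validate_config <- function(config) {
  if (inherits(config, "pipeline_config")) config <- unclass(config)
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    lines <- readLines(config, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- lines[grepl("=", lines)]
    kv <- strsplit(lines, "=", fixed = TRUE)
    config <- setNames(lapply(kv, function(x) trimws(paste(x[-1], collapse = "="))),
                       trimws(vapply(kv, `[[`, "", 1)))
  }
  unknown <- setdiff(names(config), names(PIPELINE_DEFAULTS))
  if (length(unknown)) stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  cfg <- PIPELINE_DEFAULTS
  cfg[names(config)] <- config
  for (k in c("selection_models", "stages"))
    if (is.character(cfg[[k]]) && length(cfg[[k]]) == 1)
      cfg[[k]] <- trimws(strsplit(cfg[[k]], ",")[[1]])
  cfg$bootstrap_B <- as.integer(cfg$bootstrap_B)
  if (!is.null(cfg$seed)) cfg$seed <- as.integer(cfg$seed)
  stochastic <- "tree" %in% cfg$stages && cfg$bootstrap_B > 0
  if (stochastic && is.null(cfg$seed))
    stopf("a seed is required when stochastic stages run")
  for (k in c("records_fasta", "features_tsv", "taxonomy_tsv", "tree_path")) {
    if (!is.null(cfg[[k]]) && !file.exists(cfg[[k]]))
      stopf("config path %s does not exist: %s", k, cfg[[k]])
  }
  structure(cfg, class = "pipeline_config")
}

# Gap-free per-gene alignments straight from annotated records (usable when
# the per-gene sequences are already equal-length, as simulated data are).
alignments_from_records <- function(records, genes = CANONICAL_PCGS) {
  out <- list()
  for (g in genes) {
    seqs <- c()
    for (r in records) {
      f <- Filter(function(x) x$gene == g, dedupe_features(r)$features)
      if (length(f)) seqs[r$record_id] <- extract_gene_sequence(r, f[[1]])
    }
    if (length(seqs) < 2) { cm_log$add(sprintf("gene %s: <2 sequences, skipped", g)); next }
    if (length(unique(nchar(seqs))) != 1) {
      cm_log$add(sprintf("gene %s: unequal lengths, not pre-aligned; skipped", g))
      next
    }
    out[[g]] <- alignment(seqs, gene = g)
  }
  out
}

#' Run the analysis pipeline
#'
#' Reads the dataset named by the configuration, runs the requested stages
#' (composition, diversity, selection, geneorder, tree), writes the report
#' tables into `outdir`, and returns the in-memory results plus a per-stage
#' status. Failing stages are isolated and reported, not fatal.
#'
#' @param config A [validate_config()]-acceptable configuration.
#' @return Invisible list with per-stage results, `status`, and `outdir`.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  if (is.null(cfg$records_fasta) || is.null(cfg$features_tsv))
    stopf("records_fasta and features_tsv are required")
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  cm_log_clear()
  records <- read_feature_table(cfg$records_fasta, cfg$features_tsv,
                                taxonomy = cfg$taxonomy_tsv)
  if (!length(records)) stopf("no records read")
  taxonomy <- if (!is.null(cfg$taxonomy_tsv)) read_tsv_strict(cfg$taxonomy_tsv) else NULL
  tree <- if (!is.null(cfg$tree_path)) read_newick(cfg$tree_path) else NULL

  results <- list()
  status <- list()
  run_stage <- function(name, fun) {
    if (!name %in% cfg$stages) { status[[name]] <<- "skipped"; return(invisible()) }
    res <- tryCatch(fun(), error = function(e) {
      status[[name]] <<- paste("failed:", conditionMessage(e))
      NULL
    })
    if (!is.null(res)) { results[[name]] <<- res; status[[name]] <<- "ok" }
  }

  run_stage("composition", function() {
    comp <- composition_table(records)
    comp <- comp[order(comp$record_id), ]
    write_table(comp, file.path(cfg$outdir, "composition.tsv"))
    if (!is.null(taxonomy)) {
      gs <- summarize_groups(comp, taxonomy, "class")
      write_table(gs, file.path(cfg$outdir, "group_summary.tsv"))
    }
    cds <- unlist(lapply(records, function(r) {
      vapply(Filter(function(f) f$kind == "PCG", dedupe_features(r)$features),
             function(f) extract_gene_sequence(r, f), "")
    }))
    ru <- rscu(cds, cfg$genetic_code_id)
    rscu_tab <- data.frame(codon = names(ru$counts), amino_acid = ru$amino_acid,
                           count = as.integer(ru$counts), rscu = ru$rscu,
                           stringsAsFactors = FALSE)
    write_table(rscu_tab, file.path(cfg$outdir, "rscu.tsv"))
    sk <- tryCatch(skew_correlation(comp), error = function(e) NULL)
    list(composition = comp, rscu = rscu_tab, skew_correlation = sk)
  })

  alns <- NULL
  get_alignments <- function() {
    if (!is.null(alns)) return(alns)
    alns <<- if (!is.null(cfg$alignments_dir)) {
      files <- list.files(cfg$alignments_dir, pattern = "\\.fa(sta)?$", full.names = TRUE)
      setNames(lapply(files, read_alignment_fasta),
               sub("\\.[^.]*$", "", basename(files)))
    } else alignments_from_records(records)
    alns
  }

  run_stage("diversity", function() {
    div <- diversity_table(get_alignments(), policy = cfg$filter_policy)
    div <- div[order(div$gene), ]
    write_table(div, file.path(cfg$outdir, "diversity.tsv"))
    div
  })

  run_stage("selection", function() {
    if (is.null(tree)) stopf("selection stage requires tree_path")
    fg <- NULL
    if (!is.null(cfg$foreground_class)) {
      if (is.null(taxonomy)) stopf("foreground_class requires taxonomy_tsv")
      fg <- taxonomy$record_id[taxonomy$class == cfg$foreground_class]
      fg <- intersect(fg, tree$tip.label)
      if (!length(fg)) stopf("foreground class '%s' has no tips in the tree",
                             cfg$foreground_class)
    }
    fits_rows <- NULL
    fits <- list()
    for (g in names(get_alignments())) {
      aseqs <- apply(get_alignments()[[g]]$matrix, 1, paste, collapse = "")
      caln <- codon_alignment(aseqs, gene = g, genetic_code_id = cfg$genetic_code_id)
      gene_fits <- list()
      for (m in cfg$selection_models) {
        fit <- fit_branch_model(caln, tree, m, foreground_set = fg)
        gene_fits[[m]] <- fit
        fits_rows <- rbind(fits_rows, data.frame(
          gene = g, model = m, kappa = fit$kappa,
          omega = paste(sprintf("%s=%.5f", names(fit$omega), fit$omega),
                        collapse = ";"),
          lnL = fit$lnL, converged = fit$convergence, lrt_p = NA_real_,
          stringsAsFactors = FALSE))
      }
      if (all(c("one_ratio", "two_ratio") %in% names(gene_fits))) {
        lr <- lrt(gene_fits$one_ratio, gene_fits$two_ratio)
        fits_rows$lrt_p[fits_rows$gene == g & fits_rows$model == "two_ratio"] <- lr$p
      }
      fits[[g]] <- gene_fits
    }
    write_table(fits_rows, file.path(cfg$outdir, "selection_fits.tsv"))
    if ("free_ratio" %in% cfg$selection_models && !is.null(taxonomy)) {
      clade_map <- split(taxonomy$record_id, taxonomy$class)
      clade_map <- lapply(clade_map, intersect, tree$tip.label)
      fr <- lapply(fits, `[[`, "free_ratio")
      fr <- fr[!vapply(fr, is.null, TRUE)]
      if (length(fr)) {
        oc <- compare_clade_omegas(fr, clade_map)
        write_table(oc, file.path(cfg$outdir, "omega_comparisons.tsv"))
      }
    }
    list(fits = fits, table = fits_rows)
  })

  run_stage("geneorder", function() {
    seen <- unique(unlist(lapply(records, function(r)
      vapply(r$features, `[[`, "", "gene"))))
    alpha <- intersect(gene_alphabet(), seen)
    if (length(alpha) < 3) stopf("fewer than 3 alphabet genes annotated")
    orders <- extract_gene_orders(records, alphabet = alpha)
    if (!length(orders)) stopf("no records with a complete gene order")
    patterns <- group_patterns(orders)
    pat_tab <- do.call(rbind, lapply(patterns, function(p) data.frame(
      pattern_id = p$pattern_id, order = order_string(p$order),
      count = p$count, members = paste(p$members, collapse = ","),
      stringsAsFactors = FALSE)))
    write_table(pat_tab, file.path(cfg$outdir, "patterns.tsv"))
    scen_tab <- NULL
    anc <- NULL
    if (length(patterns) >= 2) {
      dm <- pattern_distance_matrix(patterns, cfg$gene_order_metric)
      dm_tab <- data.frame(pattern_id = rownames(dm), dm, check.names = FALSE)
      write_table(dm_tab, file.path(cfg$outdir, "distances.tsv"))
      for (j in 2:length(patterns)) {
        sc <- infer_scenario(patterns[[1]]$order, patterns[[j]]$order)
        scen_tab <- rbind(scen_tab, data.frame(
          source = patterns[[1]]$pattern_id, target = patterns[[j]]$pattern_id,
          n_events = length(sc$events),
          inversions = sc$counts[["inversion"]],
          transpositions = sc$counts[["transposition"]],
          reverse_transpositions = sc$counts[["reverse_transposition"]],
          tdrls = sc$counts[["TDRL"]],
          heuristic = sc$heuristic, stringsAsFactors = FALSE))
      }
      write_table(scen_tab, file.path(cfg$outdir, "scenarios.tsv"))
      if (length(patterns) >= 3) {
        gt <- gene_order_tree(dm)
        write_newick(gt, file.path(cfg$outdir, "geneorder_tree.nwk"))
      }
    }
    if (!is.null(tree) && all(tree$tip.label %in%
                              vapply(orders, `[[`, "", "record_id"))) {
      lo <- setNames(orders, vapply(orders, `[[`, "", "record_id"))
      anc <- ancestral_orders(tree, lo[tree$tip.label])
    }
    list(patterns = patterns, scenarios = scen_tab, ancestral = anc)
  })

  run_stage("tree", function() {
    al <- get_alignments()
    if (!length(al)) stopf("no alignments for tree stage")
    mats <- lapply(al, function(a) a$matrix[sort(rownames(a$matrix)), , drop = FALSE])
    shared <- Reduce(intersect, lapply(mats, rownames))
    if (length(shared) < 3) stopf("fewer than 3 shared taxa across genes")
    concat <- do.call(cbind, lapply(mats, function(m) m[shared, , drop = FALSE]))
    aln <- alignment(concat, gene = "concatenated")
    tr <- bootstrap_support(aln, B = cfg$bootstrap_B, seed = cfg$seed)
    write_newick(tr, file.path(cfg$outdir, "nj_tree.nwk"))
    tr
  })

  log_lines <- c(
    sprintf("cnidmito %s | R %s", as.character(utils::packageVersion("cnidmito")),
            paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("seed: %s", cfg$seed %||% "none"),
    sprintf("records read: %d", length(records)),
    paste0("stage ", names(status), ": ", unlist(status)),
    if (length(cm_log_entries())) paste("note:", cm_log_entries()) else character(0))
  writeLines(log_lines, file.path(cfg$outdir, "run_log.txt"))
  invisible(list(results = results, status = status, outdir = cfg$outdir,
                 config = cfg))
}
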