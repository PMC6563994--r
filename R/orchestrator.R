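#' Default run configuration
#'
#' Nested stage-parameter blocks consumed by [run_all()]; every block
#' validates against its module's contract via [validate_config()].
#'
#' @param outdir output directory.
#' @param seed global integer seed.
#' @return nested list of class `run_config`.
#' @export
default_run_config <- function(outdir = tempfile("troutmir_run_"),
                               seed = 1L) {
  cfg <- list(
    outdir = outdir,
    seed = as.integer(seed),
    synthetic = list(n_samples_per_group = 3L, de_fraction = 0.25,
                     de_log2fc = 1, nb_mean = 200, nb_dispersion = 0.1,
                     frac_no_adapter = 0.05, frac_contaminant = 0.10),
    preprocess = list(min_len = 15L, max_len = 32L, min_phred = 30),
    annotate = list(flank = 80L, external_folds = NULL),
    diffexp = list(alpha = 0.05, method = "welch", pseudocount = 0.5),
    targets = list(s_min = 140, dg_max = -20),
    enrichment = list(min_bg = 2L),
    correlate = list(mrna_table = NULL))
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML or JSON
#'
#' Values present in the file override the defaults; unknown keys are
#' rejected by [validate_config()].
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return `run_config` list.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  user <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
          else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
          else stop("unsupported config format: ", ext)
  cfg <- default_run_config()
  for (k in names(user)) {
    if (is.list(user[[k]]) && k %in% names(cfg) && is.list(cfg[[k]])) {
      for (k2 in names(user[[k]])) cfg[[k]][[k2]] <- user[[k]][[k2]]
    } else cfg[[k]] <- user[[k]]
  }
  errs <- validate_config(cfg)
  if (length(errs)) stop("invalid config:\n  ", paste(errs, collapse = "\n  "))
  cfg
}

#' Validate a run configuration
#'
#' Checks all parameter bounds and rejects unknown keys; errors are
#' aggregated into a human-readable character vector (empty when valid).
#'
#' @param cfg a `run_config` list.
#' @return character vector of error messages (length 0 when ok).
#' @export
validate_config <- function(cfg) {
  errs <- character(0)
  push <- function(msg) errs[[length(errs) + 1L]] <<- msg
  known_top <- c("outdir", "seed", "synthetic", "preprocess", "annotate",
                 "diffexp", "targets", "enrichment", "correlate")
  for (k in setdiff(names(cfg), known_top)) push(paste0("unknown key: ", k))
  known_sub <- list(
    synthetic = c("n_samples_per_group", "n_mirna_per_group_label",
                  "de_fraction", "de_log2fc", "nb_mean", "nb_dispersion",
                  "adapter", "frac_no_adapter", "frac_contaminant",
                  "length_jitter", "seed"),
    preprocess = c("adapter", "min_len", "max_len", "min_phred",
                   "min_overlap", "max_mismatch_rate"),
    annotate = c("flank", "external_folds"),
    diffexp = c("alpha", "method", "pseudocount"),
    targets = c("s_min", "dg_max"),
    enrichment = c("min_bg"),
    correlate = c("mrna_table"))
  for (blk in names(known_sub))
    for (k in setdiff(names(cfg[[blk]]), known_sub[[blk]]))
      push(paste0("unknown key: ", blk, "$", k))
  chk <- function(cond, msg) if (!isTRUE(cond)) push(msg)
  sy <- cfg$synthetic
  if (!is.null(sy$n_samples_per_group))
    chk(sy$n_samples_per_group >= 2, "synthetic$n_samples_per_group must be >= 2")
  for (p in c("de_fraction", "frac_no_adapter", "frac_contaminant"))
    if (!is.null(sy[[p]]))
      chk(sy[[p]] >= 0 && sy[[p]] <= 1,
          paste0("synthetic$", p, " must lie in [0, 1]"))
  if (!is.null(sy$nb_dispersion))
    chk(sy$nb_dispersion > 0, "synthetic$nb_dispersion must be > 0")
  pp <- cfg$preprocess
  if (!is.null(pp$min_len) && !is.null(pp$max_len))
    chk(pp$min_len >= 1 && pp$min_len <= pp$max_len,
        "preprocess length bounds must satisfy 1 <= min_len <= max_len")
  an <- cfg$annotate
  if (!is.null(an$flank))
    chk(an$flank > 0, "annotate$flank must be positive")
  de <- cfg$diffexp
  if (!is.null(de$alpha))
    chk(de$alpha > 0 && de$alpha < 1, "diffexp$alpha must lie in (0, 1)")
  if (!is.null(de$method))
    chk(de$method %in% c("welch", "nbinom"),
        "diffexp$method must be 'welch' or 'nbinom'")
  tg <- cfg$targets
  if (!is.null(tg$s_min)) chk(tg$s_min > 0, "targets$s_min must be positive")
  if (!is.null(tg$dg_max))
    chk(tg$dg_max < 0, "targets$dg_max must be negative")
  en <- cfg$enrichment
  if (!is.null(en$min_bg))
    chk(en$min_bg >= 1, "enrichment$min_bg must be >= 1")
  errs
}

# Aggregate tag counts to miRNA-level counts: tags annotated to a database
# reference are summed under its id, novel (gp4) tags under their own
# sequence. Contaminant and nohit tags are excluded.
.aggregate_counts <- function(tags, records) {
  mir_labels <- c("gp1a", "gp1b", "gp2a", "gp2b", "gp3a", "gp3b",
                  "gp4a", "gp4b")
  keep <- records$label %in% mir_labels
  if (!any(keep)) return(NULL)
  rec <- records[keep, , drop = FALSE]
  key <- ifelse(nzchar(rec$ref_id), rec$ref_id, rec$sequence)
  count_cols <- setdiff(names(tags), "sequence")
  cm <- as.matrix(tags[match(rec$sequence, tags$sequence), count_cols,
                       drop = FALSE])
  agg <- rowsum(cm, group = key)
  storage.mode(agg) <- "integer"
  # representative mature per key = most abundant member tag
  totals <- rowSums(cm)
  rep_seq <- vapply(rownames(agg), function(k) {
    i <- which(key == k)
    rec$sequence[i[which.max(totals[i])]]
  }, character(1))
  list(counts = agg, mature = rep_seq)
}

#' Run the whole pipeline on synthetic data
#'
#' Chains simulate -> preprocess -> annotate -> diffexp -> targets ->
#' enrich (and, when an mRNA expression table is configured, correlate),
#' writing every intermediate artifact as a flat file under
#' `cfg$outdir` and returning a consolidated report. Identical
#' configuration and seed reproduce byte-identical outputs.
#'
#' @param cfg a `run_config` (see [default_run_config()],
#'   [read_run_config()]).
#' @return list of class `run_report`: `accounting`, `group_counts`,
#'   `de_summary`, `targets`, `enrichment`, `truth_recovery`, `paths`.
#' @export
run_all <- function(cfg = default_run_config()) {
  errs <- validate_config(cfg)
  if (length(errs)) stop("invalid config:\n  ", paste(errs, collapse = "\n  "))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  sy_args <- cfg$synthetic
  sy_args$seed <- cfg$seed
  scfg <- do.call(synthetic_config, sy_args)

  ref <- generate_references(scfg)
  write_truth(ref$truth, file.path(cfg$outdir, "truth.tsv"))
  sim <- simulate_library(ref, scfg, file.path(cfg$outdir, "fastq"))
  write.table(sim$manifest, file.path(cfg$outdir, "manifest.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  pp <- cfg$preprocess
  prep <- preprocess_fastq(sim$fastq_paths,
                           adapter = pp$adapter %||% scfg$adapter,
                           min_len = pp$min_len %||% 15L,
                           max_len = pp$max_len %||% 32L,
                           min_phred = pp$min_phred %||% 30)
  write.table(prep$tags, file.path(cfg$outdir, "tags.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  ext <- if (!is.null(cfg$annotate$external_folds))
    read_rnafold(cfg$annotate$external_folds) else NULL
  records <- annotate_tags(prep$tags, ref$bundle,
                           flank = cfg$annotate$flank %||% 80L,
                           external_folds = ext)
  write.table(records, file.path(cfg$outdir, "annotation.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  groups_rep <- group_report(records, prep$tags)

  agg <- .aggregate_counts(prep$tags, records)
  de <- NULL; split_calls <- list(up_SS = character(0), up_SD = character(0))
  predictions <- data.frame()
  enr <- data.frame()
  if (!is.null(agg) && nrow(agg$counts) >= 2L) {
    de <- de_test(agg$counts, sim$groups,
                  method = cfg$diffexp$method %||% "welch",
                  pseudocount = cfg$diffexp$pseudocount %||% 0.5,
                  alpha = cfg$diffexp$alpha %||% 0.05)
    write.table(de, file.path(cfg$outdir, "de_results.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    split_calls <- call_and_split(de)
    sig <- de$mirna[de$significant]
    if (length(sig)) {
      matures <- setNames(agg$mature[sig], sig)
      predictions <- scan_targets(matures, ref$bundle$utrs,
                                  s_min = cfg$targets$s_min %||% 140,
                                  dg_max = cfg$targets$dg_max %||% -20)
      write.table(predictions, file.path(cfg$outdir, "predictions.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      tset <- build_target_set(predictions)
      if (length(tset)) {
        enr <- enrich(tset, ref$bundle$go_map, names(ref$bundle$utrs),
                      min_bg = cfg$enrichment$min_bg %||% 2L)
        write.table(enr, file.path(cfg$outdir, "enrichment.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
  }

  correlations <- NULL
  if (!is.null(cfg$correlate$mrna_table) && !is.null(de)) {
    mrna <- as.matrix(read.delim(cfg$correlate$mrna_table, row.names = 1L))
    norm <- sweep(agg$counts, 2L, size_factors(agg$counts), "/")
    shared <- intersect(colnames(norm), colnames(mrna))
    rows <- list()
    for (p in seq_len(nrow(predictions))) {
      mi <- predictions$mirna[p]; g <- predictions$gene[p]
      if (!(mi %in% rownames(norm)) || !(g %in% rownames(mrna))) next
      pc <- pearson(log2(norm[mi, shared] + 0.5),
                    log2(mrna[g, shared] + 0.5))
      rows[[length(rows) + 1L]] <- data.frame(
        mirna = mi, gene = g, r = pc$r, n = pc$n, p = pc$p,
        significant = pc$significant, stringsAsFactors = FALSE)
    }
    if (length(rows)) {
      correlations <- do.call(rbind, rows)
      write.table(correlations, file.path(cfg$outdir, "correlations.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  recovery <- label_recovery(records, ref$truth)
  # directional truth for DE among called miRNAs
  truth_de <- ref$truth$mirnas
  called <- c(split_calls$up_SS, split_calls$up_SD)
  dir_ok <- NA_real_
  if (length(called)) {
    td <- truth_de$de_status[match(called, truth_de$id)]
    pred_dir <- c(rep("up_SS", length(split_calls$up_SS)),
                  rep("up_SD", length(split_calls$up_SD)))
    comp <- !is.na(td) & td != "null"
    dir_ok <- if (any(comp)) mean(td[comp] == pred_dir[comp]) else NA_real_
  }

  report <- list(
    accounting = prep$report,
    group_counts = groups_rep,
    de_summary = list(n_tested = if (is.null(de)) 0L else nrow(de),
                      n_significant = length(called),
                      up_SS = length(split_calls$up_SS),
                      up_SD = length(split_calls$up_SD)),
    targets = list(n_predictions = nrow(predictions),
                   n_target_genes = length(unique(predictions$gene))),
    enrichment = list(n_terms_tested = nrow(enr),
                      top_terms = head(enr, 5L)),
    truth_recovery = list(label_recovery = recovery$recovery,
                          n_tags_matched = recovery$n_matched,
                          de_direction_agreement = dir_ok),
    correlations = correlations,
    paths = list(outdir = cfg$outdir))
  class(report) <- "run_report"
  jsonlite::write_json(.report_json(report),
                       file.path(cfg$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.report_json <- function(report) {
  r <- unclass(report)
  r$accounting$length_histogram <- as.list(r$accounting$length_histogram)
  r$paths <- NULL   # keep the serialized report free of absolute paths
  r
}
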