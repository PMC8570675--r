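# One-command orchestration: preprocess -> annotate -> hairpin -> quantify
# -> diffexp -> biomarker, from a single config, with per-stage TSV outputs
# and a line-delimited JSON run log. A single global seed is fanned out to
# per-stage seeds by fixed offsets so stages stay independently
# reproducible.

#' Pipeline configuration
#'
#' @param fastq named character vector of FASTQ paths (names = sample ids).
#' @param reference_fasta path to the precursor FASTA.
#' @param matures_tsv path to the mature-annotation TSV (`precursor_id`,
#'   `mature_id`, `arm`, `start`, `end`).
#' @param contaminants_fasta optional contaminant FASTA (`NULL` to skip).
#' @param cohort_tsv path to the cohort table; must contain `sample`,
#'   `group` and `pain` columns.
#' @param out_dir output directory (created if absent).
#' @param adapter 3' adapter sequence.
#' @param clean [clean_params()] overrides as a named list.
#' @param max_mismatch,max_end_shift,flank annotation tolerances.
#' @param thresholds hairpin criteria thresholds.
#' @param pseudocount normalization zero-handling flag.
#' @param alpha,lfc_min differential-expression gates.
#' @param markers miRNA ids used in the biomarker stage (`NULL`: the two
#'   strongest DE rows).
#' @param seed global seed recorded in every output.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(fastq, reference_fasta, matures_tsv,
                            contaminants_fasta = NULL, cohort_tsv, out_dir,
                            adapter, clean = list(), max_mismatch = 1L,
                            max_end_shift = 2L, flank = 80L,
                            thresholds = criteria_thresholds(),
                            pseudocount = FALSE, alpha = 0.05, lfc_min = 1,
                            markers = NULL, seed = 1L) {
  stopifnot(!is.null(names(fastq)), nzchar(adapter))
  structure(list(fastq = fastq, reference_fasta = reference_fasta,
                 matures_tsv = matures_tsv,
                 contaminants_fasta = contaminants_fasta,
                 cohort_tsv = cohort_tsv, out_dir = out_dir,
                 adapter = adapter, clean = clean,
                 max_mismatch = max_mismatch, max_end_shift = max_end_shift,
                 flank = flank, thresholds = thresholds,
                 pseudocount = pseudocount, alpha = alpha,
                 lfc_min = lfc_min, markers = markers,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @noRd
validate_config <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  paths <- c(config$fastq, config$reference_fasta, config$matures_tsv,
             config$cohort_tsv, config$contaminants_fasta)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("missing input path(s): ", paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

#' Run the full pipeline
#'
#' Executes every stage in order and writes, per stage, its result table
#' and a log line (JSON) reconciling records in = records out + records
#' rejected. Identical config + seed produces byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list with all in-memory stage results.
#' @export
run_pipeline <- function(config) {
  validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$out_dir, "log.jsonl")
  if (file.exists(logf)) file.remove(logf)
  log_stage <- function(stage, ...) {
    rec <- c(list(stage = stage, seed = config$seed), list(...))
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n", file = logf,
        append = TRUE, sep = "")
  }

  # preprocess ----------------------------------------------------------------
  params <- do.call(clean_params, c(list(adapter = config$adapter),
                                    config$clean))
  pre <- preprocess_fastq(config$fastq, params)
  write_tsv(pre$table, file.path(config$out_dir, "unique_sequences.tsv"))
  write_tsv(cbind(sample = rownames(pre$stats), as.data.frame(pre$stats)),
            file.path(config$out_dir, "preprocess_stats.tsv"))
  log_stage("preprocess", input = sum(pre$stats[, "input"]),
            accepted = sum(pre$stats[, "accepted"]),
            rejected = sum(pre$stats[, "input"]) - sum(pre$stats[, "accepted"]),
            unique_sequences = nrow(pre$table))

  # annotate ------------------------------------------------------------------
  prec <- read_fasta(config$reference_fasta)
  matures <- read_tsv(config$matures_tsv)
  reference <- precursor_reference(
    data.frame(id = names(prec), sequence = unname(prec),
               stringsAsFactors = FALSE), matures)
  contaminants <- if (!is.null(config$contaminants_fasta)) {
    read_fasta(config$contaminants_fasta)
  } else {
    character(0)
  }
  ann <- annotate_table(pre$table, reference, contaminants,
                        config$max_mismatch, config$max_end_shift,
                        config$flank)
  write_tsv(ann, file.path(config$out_dir, "annotation.tsv"))
  cls <- table(ann$class)
  ncls <- function(k) if (k %in% names(cls)) as.integer(cls[[k]]) else 0L
  log_stage("annotate", rows = nrow(ann),
            known_mature = ncls("known_mature"),
            novel_arm_candidate = ncls("novel_arm_candidate"),
            contaminant = ncls("contaminant"),
            unmapped = ncls("unmapped"))

  # hairpin: assess novel candidates ------------------------------------------
  nov <- ann[ann$class == "novel_arm_candidate", , drop = FALSE]
  accepted_novel <- character(0)
  crit_rows <- list()
  if (nrow(nov)) {
    for (i in seq_len(nrow(nov))) {
      pseq <- reference$precursors$sequence[
        reference$precursors$id == nov$precursor_id[i]]
      win <- substr(pseq, nov$window_start[i], nov$window_end[i])
      mat <- c(nov$start[i] - nov$window_start[i] + 1L,
               nov$end[i] - nov$window_start[i] + 1L)
      res <- assess_candidate(win, mat, config$thresholds)
      if (res$criteria[["overall"]]) {
        accepted_novel <- c(accepted_novel, nov$sequence[i])
      }
      crit_rows[[i]] <- data.frame(
        sequence = nov$sequence[i], precursor_id = nov$precursor_id[i],
        energy = res$structure$energy,
        t(as.integer(res$criteria)), stringsAsFactors = FALSE)
    }
    crit <- do.call(rbind, crit_rows)
    names(crit)[4:15] <- c(paste0("c", 1:11), "overall")
    write_tsv(crit, file.path(config$out_dir, "criteria.tsv"))
  }
  log_stage("hairpin", candidates = nrow(nov),
            accepted = length(accepted_novel))

  # quantify ------------------------------------------------------------------
  counts <- build_count_matrix(ann, accepted_novel)
  factors <- library_size_factors(counts, pseudocount = config$pseudocount)
  normalized <- normalize_counts(counts, factors)
  write_tsv(cbind(id = rownames(counts), as.data.frame(counts)),
            file.path(config$out_dir, "counts.tsv"))
  write_tsv(data.frame(sample = names(factors), S = as.numeric(factors)),
            file.path(config$out_dir, "size_factors.tsv"))
  write_tsv(cbind(id = rownames(normalized), as.data.frame(normalized)),
            file.path(config$out_dir, "normalized.tsv"))
  log_stage("quantify", rows = nrow(counts), samples = ncol(counts),
            total_counts = sum(counts))

  # diffexp -------------------------------------------------------------------
  cohort <- read_tsv(config$cohort_tsv)
  stopifnot(all(c("sample", "group", "pain") %in% names(cohort)))
  cohort <- cohort[match(colnames(counts), cohort$sample), , drop = FALSE]
  if (anyNA(cohort$sample)) stop("cohort table lacks some FASTQ samples")
  de <- call_de(compare_two_groups(normalized, cohort$group, "t"),
                alpha = config$alpha, lfc_min = config$lfc_min)
  write_tsv(de, file.path(config$out_dir, "de.tsv"))
  write_tsv(de[, c("id", "log2fc", "neg_log10_p", "direction")],
            file.path(config$out_dir, "volcano.tsv"))
  log_stage("diffexp", rows = nrow(de), de = sum(de$de))

  # biomarker -----------------------------------------------------------------
  markers <- config$markers
  if (is.null(markers)) {
    pool <- if (any(de$de)) de[de$de, ] else de
    ord <- pool[order(pool$p, -abs(pool$log2fc)), ]
    markers <- head(ord$id, 2)
  }
  biom <- list()
  if (length(unique(cohort$pain)) == 2 && length(markers)) {
    rocs <- lapply(markers, function(m) {
      roc_auc(normalized[m, ], cohort$pain)
    })
    names(rocs) <- markers
    combined <- if (length(markers) >= 2) {
      combined_roc(normalized[markers[1], ], normalized[markers[2], ],
                   cohort$pain)
    }
    mdat <- cbind(cohort, as.data.frame(t(normalized[markers, , drop = FALSE])))
    preds <- c(markers, intersect(c("sex_male", "age", "opioid", "smoker"),
                                  names(cohort)))
    uni <- univariate_fits(mdat, "interference_mood", preds)
    multi <- multivariable_fit(mdat, "interference_mood", preds,
                               univariate = uni)
    biom <- list(auc = lapply(rocs, `[[`, "auc"),
                 auc_combined = if (!is.null(combined)) combined$auc,
                 univariate = uni, multivariable = multi)
    jsonlite::write_json(
      list(markers = markers, auc = biom$auc,
           auc_combined = biom$auc_combined,
           univariate = uni,
           multivariable = multi[c("included", "coefficients", "model_p",
                                   "r2", "n")]),
      file.path(config$out_dir, "biomarker.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  log_stage("biomarker", markers = length(markers))

  invisible(list(preprocess = pre, annotation = ann,
                 accepted_novel = accepted_novel, counts = counts,
                 factors = factors, normalized = normalized, de = de,
                 biomarker = biom, cohort = cohort))
}

#' Write a one-command synthetic demo data set
#'
#' Emits a seeded reference (8 precursors, 4 contaminants), two groups of
#' five FASTQ samples with two 4-fold upregulated miRNAs planted in the
#' second group, a cohort table, and a ready-to-run [pipeline_config()].
#'
#' @param dir output directory.
#' @param seed global seed; derived per-sample seeds use fixed offsets.
#' @return the [pipeline_config()] for [run_pipeline()].
#' @export
make_demo <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- generate_reference(8, 4, seed = seed)
  write_fasta(setNames(ref$precursors$sequence, ref$precursors$id),
              file.path(dir, "reference.fasta"))
  write_tsv(ref$matures, file.path(dir, "matures.tsv"))
  write_fasta(setNames(ref$contaminants$sequence, ref$contaminants$id),
              file.path(dir, "contaminants.fasta"))

  mirs <- ref$matures$mature_id
  base <- setNames(rep(200, length(mirs)), mirs)
  planted <- mirs[1:2]
  groups <- rep(c("control", "case"), each = 5)
  samples <- sprintf("%s%02d", ifelse(groups == "case", "P", "C"),
                     rep(1:5, 2))
  fastq <- character(0)
  for (i in seq_along(samples)) {
    expr <- base
    if (groups[i] == "case") expr[planted] <- expr[planted] * 4
    cfg <- read_sim_config(n_reads = 5000L, seed = seed + 100L + i)
    reads <- simulate_sample_reads(ref, expr, cfg)
    path <- file.path(dir, paste0(samples[i], ".fastq"))
    write_fastq(reads, path)
    fastq[samples[i]] <- path
  }

  ccfg <- cohort_sim_config(
    n_per_group = c(control = 5L, case = 5L),
    pain_prevalence = c(control = 0, case = 1),
    planted_log2fc = setNames(c(2, 2), planted),
    seed = seed + 200L)
  cohort <- simulate_cohort(ccfg)
  cohort$sample <- samples
  write_tsv(cohort, file.path(dir, "cohort.tsv"))

  config <- pipeline_config(
    fastq = fastq,
    reference_fasta = file.path(dir, "reference.fasta"),
    matures_tsv = file.path(dir, "matures.tsv"),
    contaminants_fasta = file.path(dir, "contaminants.fasta"),
    cohort_tsv = file.path(dir, "cohort.tsv"),
    out_dir = file.path(dir, "out"),
    adapter = read_sim_config()$adapter,
    seed = seed)
  cfg_json <- config[setdiff(names(config), "thresholds")]
  cfg_json$fastq <- as.list(config$fastq)   # keep sample ids as JSON keys
  jsonlite::write_json(cfg_json, file.path(dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  config
}
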