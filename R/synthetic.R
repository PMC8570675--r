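# Seeded synthetic data: a hairpin precursor reference with annotated
# mature arms, per-sample FASTQ reads (miRNA inserts + adapter, junk,
# contaminant fragments), and a cohort table with planted group effects.
#
# Precursors are built as stem + loop + reverse-complement stem, so every
# generated hairpin passes the stem-size, hairpin-length and loop-length
# criteria by construction. Counts are negative-binomial around the
# requested expectation (Poisson in the dispersion -> 0 limit). Desk-scale
# library sizes (1e4--1e5 reads) stand in for the 7--10 million reads of a
# production plasma library; the generator models composition, not depth.

RNA_BASES <- c("A", "C", "G", "U")

#' @noRd
rand_seq <- function(n) paste(sample(RNA_BASES, n, replace = TRUE), collapse = "")

# a base guaranteed not to pair (Watson-Crick or GU wobble) with `partner`
#' @noRd
non_pairing_base <- function(partner) {
  choices <- switch(partner,
                    A = c("A", "C", "G"),
                    C = c("A", "C", "U"),
                    G = c("A", "G"),
                    U = c("C", "U"))
  sample(choices, 1)
}

#' Generate a synthetic precursor reference with contaminants
#'
#' Each precursor is a designed hairpin: a random stem of 24--30 bp with at
#' most 2 planted internal mismatches, a 4--12 nt terminal loop, and the
#' reverse-complement stem. One 20--24 nt mature arm per side is placed
#' inside the stems (never overlapping the loop); exactly one side carries
#' the "annotated" mature, leaving the opposite arm available as
#' novel-candidate territory. Contaminants are random 70--120 nt records
#' labelled with an ncRNA family.
#'
#' @param n_precursors number of precursors (>= 1).
#' @param n_contaminants number of contaminant records.
#' @param seed RNG seed; output is byte-deterministic given the seed.
#' @return a `simulated_reference`: list with `precursors` (data.frame
#'   `id`, `sequence`), `arms` (both arms per precursor: `precursor_id`,
#'   `mature_id`, `arm`, `start`, `end`, `annotated`), `matures` (the
#'   annotated subset, as consumed by [precursor_reference()]) and
#'   `contaminants` (data.frame `id`, `sequence`, `family`).
#' @export
generate_reference <- function(n_precursors, n_contaminants = 0L, seed = 1L) {
  stopifnot(n_precursors >= 1, n_contaminants >= 0)
  set.seed(seed)
  prec <- list(); arms <- list()
  for (i in seq_len(n_precursors)) {
    pid <- sprintf("pre-%03d", i)
    # rejection-sample: planted mismatch bases can occasionally base-pair
    # elsewhere (e.g. into the loop), splitting the fold into a multiloop;
    # redraw until the designed hairpin really passes criteria 2, 4, 5
    for (try in 1:50) {
      stem_len <- sample(24:30, 1)
      loop_len <- sample(4:12, 1)
      arm5 <- strsplit(rand_seq(stem_len), "")[[1]]
      arm3 <- rev(chartr("ACGU", "UGCA", arm5))
      n_mm <- sample(0:2, 1)
      if (n_mm > 0) {
        # interior positions only, so the designed outermost pairs survive
        # and the folded hairpin spans the full 2*stem + loop length
        pos <- sample(4:(stem_len - 3), n_mm)
        for (p in pos) arm3[p] <- non_pairing_base(arm5[stem_len - p + 1])
      }
      loop <- rand_seq(loop_len)
      pseq <- paste0(paste(arm5, collapse = ""), loop,
                     paste(arm3, collapse = ""))
      crit <- assess_candidate(pseq, mature = c(1L, 20L))$criteria
      if (crit[["c2"]] && crit[["c4"]] && crit[["c5"]]) break
      if (try == 50) stop("could not construct a criteria-passing precursor")
    }
    annotated_arm <- sample(c("5p", "3p"), 1)
    mk_arm <- function(arm) {
      L <- sample(20:24, 1)
      off <- sample(seq_len(stem_len - L + 1), 1)
      start <- if (arm == "5p") off else stem_len + loop_len + off
      data.frame(precursor_id = pid,
                 mature_id = paste0("mir-", sprintf("%03d", i), "-", arm),
                 arm = arm, start = start, end = start + L - 1L,
                 annotated = arm == annotated_arm, stringsAsFactors = FALSE)
    }
    arms[[i]] <- rbind(mk_arm("5p"), mk_arm("3p"))
    prec[[i]] <- data.frame(id = pid, sequence = pseq, stringsAsFactors = FALSE)
  }
  cont <- if (n_contaminants > 0) {
    fam <- rep(c("rRNA", "tRNA", "snRNA", "snoRNA"),
               length.out = n_contaminants)
    data.frame(id = sprintf("%s-%03d", fam, seq_len(n_contaminants)),
               sequence = vapply(seq_len(n_contaminants),
                                 function(i) rand_seq(sample(70:120, 1)),
                                 character(1)),
               family = fam, stringsAsFactors = FALSE)
  } else {
    data.frame(id = character(0), sequence = character(0),
               family = character(0))
  }
  arms <- do.call(rbind, arms)
  structure(list(precursors = do.call(rbind, prec),
                 arms = arms,
                 matures = arms[arms$annotated,
                                c("precursor_id", "mature_id", "arm",
                                  "start", "end")],
                 contaminants = cont),
            class = "simulated_reference")
}

#' @noRd
arm_sequence <- function(reference, mature_id) {
  a <- reference$arms[reference$arms$mature_id == mature_id, ]
  stopifnot(nrow(a) == 1)
  p <- reference$precursors$sequence[reference$precursors$id == a$precursor_id]
  substr(p, a$start, a$end)
}

#' Read-simulation configuration
#'
#' @param adapter 3' adapter ligated to every insert (default: the
#'   Illumina TruSeq small-RNA 3' adapter).
#' @param n_reads nominal library size used to scale the junk, contaminant
#'   and novel-arm read counts.
#' @param fraction_junk,fraction_contaminant,fraction_novel_arm expected
#'   fractions of `n_reads` (sum <= 1).
#' @param end_variation_max maximum isomiR-style end shift in nt (<= 2).
#' @param mismatch_rate per-read probability of one internal substitution.
#' @param dispersion negative-binomial dispersion of per-miRNA counts;
#'   0 gives Poisson counts.
#' @param qual_char Phred+33 character used for every base (default "I",
#'   Phred 40).
#' @param seed RNG seed.
#' @return a `read_sim_config` list.
#' @export
read_sim_config <- function(adapter = "UGGAAUUCUCGGGUGCCAAGG",
                            n_reads = 20000L, fraction_junk = 0.05,
                            fraction_contaminant = 0.10,
                            fraction_novel_arm = 0.05,
                            end_variation_max = 1L, mismatch_rate = 0.02,
                            dispersion = 0.05, qual_char = "I", seed = 1L) {
  stopifnot(fraction_junk >= 0, fraction_contaminant >= 0,
            fraction_novel_arm >= 0,
            fraction_junk + fraction_contaminant + fraction_novel_arm <= 1,
            end_variation_max <= 2L, end_variation_max >= 0L,
            mismatch_rate >= 0, mismatch_rate <= 1, dispersion >= 0)
  structure(list(adapter = as_rna(adapter), n_reads = as.integer(n_reads),
                 fraction_junk = fraction_junk,
                 fraction_contaminant = fraction_contaminant,
                 fraction_novel_arm = fraction_novel_arm,
                 end_variation_max = as.integer(end_variation_max),
                 mismatch_rate = mismatch_rate, dispersion = dispersion,
                 qual_char = qual_char, seed = as.integer(seed)),
            class = "read_sim_config")
}

#' @noRd
nb_count <- function(mu, dispersion) {
  if (mu <= 0) return(0L)
  if (dispersion <= 0) rpois(1L, mu) else rnbinom(1L, mu = mu, size = 1 / dispersion)
}

#' Simulate one sample's FASTQ reads
#'
#' miRNA reads are the mature-arm sequence with optional end variation
#' (extended/trimmed against the precursor context) and an optional single
#' internal substitution, 3'-concatenated with the adapter. Per-miRNA read
#' counts are negative binomial around the requested expectation. Junk
#' reads are homopolymer-rich; contaminant reads are exact substrings of
#' contaminant records. All bases carry one uniform high quality.
#'
#' @param reference a `simulated_reference` from [generate_reference()].
#' @param expression named numeric vector: expected read count per
#'   annotated mature id; an empty vector emits only junk/contaminant
#'   (and novel-arm) reads.
#' @param config a [read_sim_config()].
#' @return data.frame (`id`, `seq`, `qual`) ready for [write_fastq()].
#' @export
simulate_sample_reads <- function(reference, expression, config) {
  stopifnot(inherits(reference, "simulated_reference"),
            inherits(config, "read_sim_config"))
  if (length(expression)) {
    stopifnot(!is.null(names(expression)),
              all(names(expression) %in%
                    reference$arms$mature_id[reference$arms$annotated]))
  }
  set.seed(config$seed)
  e <- config$end_variation_max
  mk_mirna_read <- function(mature_id) {
    a <- reference$arms[reference$arms$mature_id == mature_id, ]
    p <- reference$precursors$sequence[
      reference$precursors$id == a$precursor_id]
    s <- a$start; t <- a$end
    if (e > 0) {
      s <- max(1L, s + sample(seq.int(-e, e), 1))
      t <- min(nchar(p), t + sample(seq.int(-e, e), 1))
    }
    ins <- substr(p, s, t)
    if (config$mismatch_rate > 0 && runif(1) < config$mismatch_rate) {
      pos <- sample(2:(nchar(ins) - 1L), 1)   # internal, never at an end
      old <- substr(ins, pos, pos)
      substr(ins, pos, pos) <- sample(setdiff(RNA_BASES, old), 1)
    }
    ins
  }
  inserts <- character(0)
  for (m in names(expression)) {
    k <- nb_count(expression[[m]], config$dispersion)
    if (k > 0) inserts <- c(inserts, vapply(seq_len(k),
                                            function(i) mk_mirna_read(m),
                                            character(1)))
  }
  novel_arms <- reference$arms$mature_id[!reference$arms$annotated]
  if (config$fraction_novel_arm > 0 && length(novel_arms)) {
    mu <- config$fraction_novel_arm * config$n_reads / length(novel_arms)
    for (m in novel_arms) {
      k <- nb_count(mu, config$dispersion)
      if (k > 0) {
        a <- reference$arms[reference$arms$mature_id == m, ]
        p <- reference$precursors$sequence[
          reference$precursors$id == a$precursor_id]
        inserts <- c(inserts, rep(substr(p, a$start, a$end), k))
      }
    }
  }
  n_cont <- round(config$fraction_contaminant * config$n_reads)
  if (n_cont > 0 && nrow(reference$contaminants)) {
    for (i in seq_len(n_cont)) {
      rec <- reference$contaminants$sequence[
        sample.int(nrow(reference$contaminants), 1)]
      L <- sample(18:26, 1)
      s <- sample.int(nchar(rec) - L + 1L, 1)
      inserts <- c(inserts, substr(rec, s, s + L - 1L))
    }
  }
  n_junk <- round(config$fraction_junk * config$n_reads)
  if (n_junk > 0) {
    for (i in seq_len(n_junk)) {
      L <- sample(18:26, 1)
      base <- sample(RNA_BASES, 1)
      x <- rep(base, L)
      n_other <- sample(0:2, 1)
      if (n_other > 0) x[sample.int(L, n_other)] <- sample(RNA_BASES, n_other,
                                                           replace = TRUE)
      inserts <- c(inserts, paste(x, collapse = ""))
    }
  }
  if (length(inserts) > 1) inserts <- inserts[sample.int(length(inserts))]
  reads <- paste0(inserts, config$adapter)
  data.frame(id = sprintf("read-%06d", seq_along(reads)),
             seq = reads,
             qual = strrep(config$qual_char, nchar(reads)),
             stringsAsFactors = FALSE)
}

#' Cohort-simulation configuration
#'
#' Defaults mirror the screening cohort: 23 uninjured, 14 acute SCI and 26
#' chronic SCI participants; neuropathic-pain prevalence 0, 0.54 and 0.65
#' by group; pain-interference slope 0.0004 score units per normalized
#' count; an opioid effect of 2 score units; residual SD 1 on the 0--10
#' interference scale; intercept 2.
#'
#' @param n_per_group named integer vector (`no_sci`, `acute_sci`,
#'   `chronic_sci`), each >= 2.
#' @param pain_prevalence per-group probability of neuropathic pain.
#' @param interference_slope interference-score units per unit of
#'   normalized marker count.
#' @param opioid_beta additive interference effect of opioid use.
#' @param intercept baseline interference score.
#' @param noise_sd residual standard deviation (> 0).
#' @param planted_log2fc named numeric: log2 effect of pain on selected
#'   simulated markers (used when markers are simulated internally).
#' @param seed RNG seed.
#' @return a `cohort_sim_config` list.
#' @export
cohort_sim_config <- function(n_per_group = c(no_sci = 23L, acute_sci = 14L,
                                              chronic_sci = 26L),
                              pain_prevalence = c(no_sci = 0, acute_sci = 0.54,
                                                  chronic_sci = 0.65),
                              interference_slope = 4e-4, opioid_beta = 2,
                              intercept = 2, noise_sd = 1,
                              planted_log2fc = numeric(0), seed = 1L) {
  stopifnot(all(n_per_group >= 2), noise_sd > 0,
            all(pain_prevalence >= 0 & pain_prevalence <= 1),
            identical(names(n_per_group), names(pain_prevalence)))
  structure(list(n_per_group = n_per_group,
                 pain_prevalence = pain_prevalence,
                 interference_slope = interference_slope,
                 opioid_beta = opioid_beta, intercept = intercept,
                 noise_sd = noise_sd, planted_log2fc = planted_log2fc,
                 seed = as.integer(seed)),
            class = "cohort_sim_config")
}

#' Simulate a cohort table with planted effects
#'
#' Group labels, a dichotomous neuropathic-pain variable drawn at the
#' per-group prevalence, demographic and medication covariates drawn from
#' fixed marginals, and pain-interference scores generated as
#' `intercept + slope * marker + opioid_beta * opioid + N(0, noise_sd)`,
#' clipped to the 0--10 scale.
#'
#' @param config a [cohort_sim_config()].
#' @param marker_levels numeric matrix of normalized marker counts
#'   (samples x miRNAs; rownames are sample ids), or `NULL` to simulate
#'   markers internally (log-normal around 2000, multiplied by
#'   `2^planted_log2fc` in pain samples). The first column drives the
#'   interference slope.
#' @return data.frame: `sample`, `group`, `pain`, `pain_intensity`,
#'   `interference_mood`, `interference_activities`, `interference_sleep`,
#'   `sex_male`, `age`, `opioid`, `smoker`, `pack_years`, `alcohol_g`,
#'   then one column per marker.
#' @export
simulate_cohort <- function(config, marker_levels = NULL) {
  stopifnot(inherits(config, "cohort_sim_config"))
  set.seed(config$seed)
  groups <- rep(names(config$n_per_group), config$n_per_group)
  n <- length(groups)
  samples <- if (!is.null(marker_levels)) {
    stopifnot(nrow(marker_levels) == n, !anyDuplicated(rownames(marker_levels)))
    rownames(marker_levels)
  } else {
    sprintf("S%03d", seq_len(n))
  }
  pain <- rbinom(n, 1L, config$pain_prevalence[groups])
  if (is.null(marker_levels)) {
    mir_ids <- if (length(config$planted_log2fc)) {
      names(config$planted_log2fc)
    } else {
      "mir-sim-1"
    }
    marker_levels <- vapply(mir_ids, function(m) {
      fc <- 2^(config$planted_log2fc[m] %||% 0)
      base <- exp(rnorm(n, log(2000), 0.4))
      ifelse(pain == 1L, base * ifelse(is.na(fc), 1, fc), base)
    }, numeric(n))
    marker_levels <- matrix(marker_levels, nrow = n,
                            dimnames = list(samples, mir_ids))
  }
  marker <- marker_levels[, 1]
  sex_male <- rbinom(n, 1L, 0.72)
  age <- pmin(pmax(rnorm(n, 38, 11), 18), 75)
  opioid <- rbinom(n, 1L, ifelse(pain == 1L, 0.5, 0.15))
  smoker <- rbinom(n, 1L, 0.25)
  py <- ifelse(smoker == 1L, round(pmax(rnorm(n, 10, 6), 0.5), 1), 0)
  alc <- round(exp(rnorm(n, log(5000), 1)), 0)
  interf <- function() {
    pmin(pmax(config$intercept + config$interference_slope * marker +
                config$opioid_beta * opioid + rnorm(n, 0, config$noise_sd),
              0), 10)
  }
  out <- data.frame(sample = samples, group = groups, pain = pain,
                    pain_intensity = ifelse(pain == 1L,
                                            pmin(10, round(runif(n, 3, 10))), 0),
                    interference_mood = interf(),
                    interference_activities = interf(),
                    interference_sleep = interf(),
                    sex_male = sex_male, age = age, opioid = opioid,
                    smoker = smoker, pack_years = py, alcohol_g = alc,
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(marker_levels))
}
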