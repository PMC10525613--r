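# Cohort pipeline: per-subject feature extraction and cohort-level
# statistical analysis, plus the command-line entry point.

FEATURES <- c("tvsa_hz2", "amr_pa", "amr_ta", "amr_ka", "smr_pataka")
CLINICAL_COVARIATES <- c("age", "disease_duration", "pumns", "alsfrs_r",
                         "alsfrs_r_b", "doss", "dras")
SCHEMA_VERSION <- "1"

#' Pipeline configuration
#'
#' @param formant A \code{\link{formant_config}}.
#' @param ddk A \code{\link{ddk_config}}.
#' @param round_rates Use rates rounded to one decimal (the clinically
#'   reported form) instead of full precision in the feature table.
#' @param n_boot Bootstrap resamples for ROC confidence intervals.
#' @param seed Seed for the ROC bootstrap.
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(formant = formant_config(), ddk = ddk_config(),
                            round_rates = FALSE, n_boot = 2000L,
                            seed = NULL) {
  structure(list(formant = formant, ddk = ddk, round_rates = round_rates,
                 n_boot = n_boot, seed = seed), class = "pipeline_config")
}

#' Extract acoustic features for one subject
#'
#' Computes the maximum phonation time from the /a:/ recording; when the
#' subject is eligible (phonation longer than 5 s) the three sustained
#' vowels are analyzed and reduced to the triangular vowel space area.  The
#' four DDK tasks are analyzed independently of vowel eligibility.  A
#' failure in one task is recorded and does not abort the others.
#'
#' @param record One-row data frame (or list) with \code{subject_id} and
#'   WAV path columns \code{wav_a}, \code{wav_i}, \code{wav_u},
#'   \code{wav_pa}, \code{wav_ta}, \code{wav_ka}, \code{wav_pataka}.
#' @param config A \code{\link{pipeline_config}}.
#' @param base_dir Directory that relative WAV paths are resolved against.
#' @return A one-row data frame with columns \code{subject_id},
#'   \code{mpt_s}, \code{mpt_eligible}, \code{tvsa_hz2}, \code{amr_pa},
#'   \code{amr_ta}, \code{amr_ka}, \code{smr_pataka}; failed features are
#'   NA and per-task messages are attached as attribute \code{"notes"}.
#' @export
extract_features <- function(record, config = pipeline_config(),
                             base_dir = NULL) {
  rec <- as.list(record)
  notes <- character(0)
  path_of <- function(task) {
    p <- rec[[paste0("wav_", task)]]
    if (is.null(p) || is.na(p) || !nzchar(p)) return(NA_character_)
    if (!is.null(base_dir) && !file.exists(p)) p <- file.path(base_dir, p)
    p
  }
  note <- function(task, e) {
    notes <<- c(notes, sprintf("%s: %s", task, conditionMessage(e)))
    NULL
  }

  mpt_s <- NA_real_; eligible <- FALSE
  sig_a <- tryCatch(read_wav(path_of("a")), error = function(e) note("a", e))
  if (!is.null(sig_a)) {
    res <- maximum_phonation_time(sig_a, config$formant)
    mpt_s <- res$mpt; eligible <- res$eligible
  }

  tvsa_hz2 <- NA_real_
  if (eligible) {
    targets <- lapply(c(a = "a", i = "i", u = "u"), function(v) {
      tryCatch({
        sig <- if (v == "a") sig_a else read_wav(path_of(v))
        vowel_targets(track_formants(sig, config$formant), vowel = v)
      }, error = function(e) note(v, e))
    })
    if (!any(vapply(targets, is.null, logical(1)))) {
      tv <- tryCatch(tvsa(targets$a, targets$i, targets$u),
                     error = function(e) note("tvsa", e))
      if (!is.null(tv)) tvsa_hz2 <- tv$area
    }
  } else {
    notes <- c(notes, sprintf(
      "tvsa: skipped, phonation time %.2f s does not exceed %.1f s",
      if (is.na(mpt_s)) 0 else mpt_s, config$formant$mpt_threshold))
  }

  rates <- stats::setNames(rep(NA_real_, 4L),
                           c("pa", "ta", "ka", "pataka"))
  for (task in names(rates)) {
    val <- tryCatch({
      sig <- read_wav(path_of(task))
      env <- amplitude_envelope(sig, config$ddk$frame_len, config$ddk$hop,
                                config$ddk$smooth)
      seg <- detect_syllable_nuclei(env, config$ddk)
      ar <- articulation_rate(seg, config$ddk$n_syllables, task, config$ddk)
      if (config$round_rates) ar$rate_reported else ar$rate
    }, error = function(e) note(task, e))
    if (!is.null(val)) rates[[task]] <- val
  }

  out <- data.frame(subject_id = rec$subject_id %||% NA_character_,
                    mpt_s = mpt_s, mpt_eligible = eligible,
                    tvsa_hz2 = tvsa_hz2,
                    amr_pa = rates[["pa"]], amr_ta = rates[["ta"]],
                    amr_ka = rates[["ka"]], smr_pataka = rates[["pataka"]],
                    stringsAsFactors = FALSE)
  attr(out, "notes") <- notes
  out
}

#' Extract features for a whole cohort
#'
#' @param cohort Cohort data frame (one row per subject, schema of
#'   \code{\link{generate_cohort}}).
#' @param config A \code{\link{pipeline_config}}.
#' @param base_dir Directory that relative WAV paths are resolved against.
#' @return Feature data frame, one row per subject; extraction notes are
#'   collected in attribute \code{"notes"}.
#' @export
extract_cohort_features <- function(cohort, config = pipeline_config(),
                                    base_dir = NULL) {
  rows <- vector("list", nrow(cohort))
  notes <- character(0)
  for (i in seq_len(nrow(cohort))) {
    rows[[i]] <- extract_features(cohort[i, , drop = FALSE], config, base_dir)
    nt <- attr(rows[[i]], "notes")
    if (length(nt))
      notes <- c(notes, paste0(cohort$subject_id[i], " ", nt))
  }
  out <- do.call(rbind, rows)
  attr(out, "notes") <- notes
  out
}

mw_row <- function(contrast, feature, x, y, g1, g2) {
  if (sum(is.finite(x)) < 2L || sum(is.finite(y)) < 2L) {
    return(data.frame(contrast = contrast, feature = feature,
                      group1 = g1, group2 = g2,
                      n1 = sum(is.finite(x)), n2 = sum(is.finite(y)),
                      median1 = NA_real_, median2 = NA_real_,
                      U = NA_real_, p = NA_real_,
                      method = "skipped: fewer than 2 values on a side",
                      stringsAsFactors = FALSE))
  }
  mw <- mann_whitney_u(x, y)
  data.frame(contrast = contrast, feature = feature, group1 = g1,
             group2 = g2, n1 = mw$n_x, n2 = mw$n_y,
             median1 = stats::median(x, na.rm = TRUE),
             median2 = stats::median(y, na.rm = TRUE),
             U = mw$statistic, p = mw$p_two_sided, method = mw$method,
             stringsAsFactors = FALSE)
}

#' Cohort-level statistical analysis
#'
#' Reproduces the full analysis program on an extracted feature table:
#' median/IQR summaries per group; Mann-Whitney contrasts of patients vs
#' controls, prevalent-UMN vs prevalent-LMN patients (median split of the
#' UMN-burden score, ties to the high group), and the three pairwise onset
#' contrasts; Spearman correlations of each feature with age, disease
#' duration and the clinical scales (patients only, pairwise-complete); and
#' ROC curves discriminating pUMN from pLMN (lower feature values indicate
#' pUMN).  Raw p-values are reported without multiplicity adjustment.
#'
#' @param cohort Cohort data frame with clinical columns \code{group},
#'   \code{onset_type}, \code{pumns}, \code{alsfrs_r}, \code{alsfrs_r_b},
#'   \code{doss}, \code{dras}, \code{age}, \code{disease_duration}.
#' @param features Feature data frame from
#'   \code{\link{extract_cohort_features}}.
#' @param config A \code{\link{pipeline_config}} (ROC bootstrap settings).
#' @return An \code{analysis_report}: list of data frames
#'   \code{summaries}, \code{contrasts}, \code{correlations}, \code{roc},
#'   a named list \code{roc_curves}, and \code{meta}.
#' @export
run_analysis <- function(cohort, features, config = pipeline_config()) {
  need <- c("subject_id", "group", "onset_type", CLINICAL_COVARIATES[-1L],
            "age")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop(sprintf("cohort table is missing column(s): %s",
                 paste(miss, collapse = ", ")))
  df <- merge(cohort, features, by = "subject_id", sort = TRUE)
  if (!any(df$group == "ALS")) stop("no ALS subjects in cohort")
  als <- df[df$group == "ALS", , drop = FALSE]

  # pUMN/pLMN by median split of the UMN-burden score within patients.
  umn <- rep(NA_character_, nrow(df))
  has_p <- df$group == "ALS" & is.finite(df$pumns)
  if (sum(has_p) >= 2L) {
    split <- median_split(df$pumns[has_p])
    umn[has_p] <- ifelse(split == "high", "pUMN", "pLMN")
  }
  df$umn_class <- umn

  group_sets <- list(
    HC = df$group == "HC", ALS = df$group == "ALS",
    pUMN = !is.na(umn) & umn == "pUMN",
    pLMN = !is.na(umn) & umn == "pLMN",
    bulbar = df$onset_type == "bulbar",
    spinal_bulbar = df$onset_type == "spinal_bulbar",
    spinal_only = df$onset_type == "spinal_only")

  summaries <- do.call(rbind, lapply(names(group_sets), function(g) {
    do.call(rbind, lapply(FEATURES, function(f) {
      v <- df[[f]][group_sets[[g]]]
      v <- v[is.finite(v)]
      if (length(v) == 0L)
        return(data.frame(group = g, feature = f, n = 0L,
                          median = NA_real_, q1 = NA_real_, q3 = NA_real_,
                          stringsAsFactors = FALSE))
      s <- summarize_values(v)
      data.frame(group = g, feature = f, n = s$n, median = s$median,
                 q1 = s$q1, q3 = s$q3, stringsAsFactors = FALSE)
    }))
  }))

  pairs <- list(
    list("ALS_vs_HC", "ALS", "HC"),
    list("pUMN_vs_pLMN", "pUMN", "pLMN"),
    list("bulbar_vs_spinal_bulbar", "bulbar", "spinal_bulbar"),
    list("spinal_bulbar_vs_spinal_only", "spinal_bulbar", "spinal_only"),
    list("bulbar_vs_spinal_only", "bulbar", "spinal_only"))
  contrasts <- do.call(rbind, lapply(pairs, function(pr) {
    do.call(rbind, lapply(FEATURES, function(f) {
      mw_row(pr[[1L]], f, df[[f]][group_sets[[pr[[2L]]]]],
             df[[f]][group_sets[[pr[[3L]]]]], pr[[2L]], pr[[3L]])
    }))
  }))

  correlations <- do.call(rbind, lapply(FEATURES, function(f) {
    do.call(rbind, lapply(CLINICAL_COVARIATES, function(cv) {
      x <- als[[f]]; y <- als[[cv]]
      res <- tryCatch(spearman_cor(x, y), error = function(e) e)
      if (inherits(res, "error"))
        return(data.frame(feature = f, covariate = cv,
                          n = sum(is.finite(x) & is.finite(y)),
                          rho = NA_real_, p = NA_real_,
                          note = conditionMessage(res),
                          stringsAsFactors = FALSE))
      data.frame(feature = f, covariate = cv, n = res$n, rho = res$rho,
                 p = res$p_two_sided, note = "", stringsAsFactors = FALSE)
    }))
  }))

  roc_curves <- list()
  roc <- do.call(rbind, lapply(FEATURES, function(f) {
    sel <- !is.na(df$umn_class) & is.finite(df[[f]])
    if (length(unique(df$umn_class[sel])) < 2L)
      return(data.frame(feature = f, auc = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, n_pos = NA_integer_,
                        n_neg = NA_integer_, direction = "lower",
                        stringsAsFactors = FALSE))
    rr <- roc_auc(df[[f]][sel], df$umn_class[sel], "pUMN",
                  direction = "lower", n_boot = config$n_boot,
                  seed = config$seed)
    roc_curves[[f]] <<- rr$curve
    data.frame(feature = f, auc = rr$auc, ci_low = rr$ci_low,
               ci_high = rr$ci_high, n_pos = rr$n_pos, n_neg = rr$n_neg,
               direction = "lower", stringsAsFactors = FALSE)
  }))

  structure(list(summaries = summaries, contrasts = contrasts,
                 correlations = correlations, roc = roc,
                 roc_curves = roc_curves,
                 meta = list(schema_version = SCHEMA_VERSION,
                             n_subjects = nrow(df),
                             n_als = sum(df$group == "ALS"),
                             n_hc = sum(df$group == "HC"),
                             n_pumn = sum(umn == "pUMN", na.rm = TRUE),
                             n_plmn = sum(umn == "pLMN", na.rm = TRUE))),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report: %d subjects (%d ALS / %d HC; %d pUMN / %d pLMN)>\n",
              x$meta$n_subjects, x$meta$n_als, x$meta$n_hc,
              x$meta$n_pumn, x$meta$n_plmn))
  sig <- x$contrasts[!is.na(x$contrasts$p) & x$contrasts$p < 0.05, ]
  cat(sprintf("  %d of %d contrasts at p < 0.05\n",
              nrow(sig), sum(!is.na(x$contrasts$p))))
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Writes \code{report.json} (full report), \code{results.csv} (flat table
#' of contrasts, correlations and ROC results) and one
#' \code{roc_<feature>.csv} per ROC curve.
#'
#' @param report An \code{\link{run_analysis}} result.
#' @param out_dir Output directory (created if needed).
#' @return The output directory, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(schema_version = SCHEMA_VERSION, meta = report$meta,
         summaries = report$summaries, contrasts = report$contrasts,
         correlations = report$correlations, roc = report$roc),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  flat <- rbind(
    data.frame(kind = "contrast", name = paste(report$contrasts$contrast,
                                               report$contrasts$feature),
               value = report$contrasts$U, p = report$contrasts$p,
               stringsAsFactors = FALSE),
    data.frame(kind = "correlation",
               name = paste(report$correlations$feature,
                            report$correlations$covariate),
               value = report$correlations$rho, p = report$correlations$p,
               stringsAsFactors = FALSE),
    data.frame(kind = "roc", name = report$roc$feature,
               value = report$roc$auc, p = NA_real_,
               stringsAsFactors = FALSE))
  utils::write.csv(flat, file.path(out_dir, "results.csv"),
                   row.names = FALSE)
  for (f in names(report$roc_curves))
    utils::write.csv(report$roc_curves[[f]],
                     file.path(out_dir, sprintf("roc_%s.csv", f)),
                     row.names = FALSE)
  invisible(out_dir)
}

read_pipeline_config <- function(path, seed, round_rates, n_boot) {
  overrides <- list()
  if (!is.null(path)) {
    overrides <- if (grepl("\\.ya?ml$", path)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("YAML config requires the 'yaml' package; use JSON instead")
      yaml::read_yaml(path)
    } else jsonlite::read_json(path, simplifyVector = TRUE)
  }
  fc <- do.call(formant_config, overrides$formant %||% list())
  dc <- do.call(ddk_config, overrides$ddk %||% list())
  cohort_args <- overrides$cohort %||% list()
  cohort_args$seed <- seed
  list(pipeline = pipeline_config(fc, dc, round_rates = round_rates,
                                  n_boot = n_boot, seed = seed),
       cohort_args = cohort_args)
}

#' Command-line entry point
#'
#' Subcommands: \code{synth-cohort} (write synthetic WAVs, cohort CSV and
#' ground truth), \code{extract} (features CSV from a cohort CSV),
#' \code{analyze} (report JSON/CSV from cohort + features) and \code{all}
#' (chain the three).  Shared flags: \code{--seed}, \code{--out-dir},
#' \code{--config} (JSON/YAML overrides for cohort, formant and DDK
#' parameters), \code{--round-rates}, \code{--n-boot}.
#'
#' @param argv Character vector of command-line arguments (excluding the
#'   program name), e.g. \code{commandArgs(trailingOnly = TRUE)}.
#' @return Integer exit status: 0 on success, 2 on validation/usage error.
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: motorspeech <synth-cohort|extract|analyze|all> [options]"
  if (length(argv) == 0L || !argv[1L] %in%
        c("synth-cohort", "extract", "analyze", "all")) {
    message(usage)
    return(2L)
  }
  cmd <- argv[1L]
  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--out-dir", dest = "out_dir", type = "character",
                          default = "motorspeech_out"),
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--round-rates", dest = "round_rates",
                          action = "store_true", default = FALSE),
    optparse::make_option("--n-boot", dest = "n_boot", type = "integer",
                          default = 2000L),
    optparse::make_option("--cohort-csv", dest = "cohort_csv",
                          type = "character", default = NULL),
    optparse::make_option("--features-csv", dest = "features_csv",
                          type = "character", default = NULL)))
  opts <- tryCatch(optparse::parse_args(parser, args = argv[-1L]),
                   error = function(e) e)
  if (inherits(opts, "error")) {
    message(conditionMessage(opts)); message(usage)
    return(2L)
  }

  run <- function() {
    cfg <- read_pipeline_config(opts$config, opts$seed, opts$round_rates,
                                opts$n_boot)
    out_dir <- opts$out_dir
    cohort_csv <- opts$cohort_csv %||% file.path(out_dir, "cohort.csv")
    features_csv <- opts$features_csv %||% file.path(out_dir, "features.csv")

    if (cmd %in% c("synth-cohort", "all")) {
      spec <- do.call(cohort_spec, cfg$cohort_args)
      message(sprintf("[synth-cohort] writing cohort to %s (seed %d)",
                      out_dir, opts$seed))
      generate_cohort(spec, out_dir)
    }
    if (cmd %in% c("extract", "all")) {
      if (!file.exists(cohort_csv))
        stop(sprintf("cohort CSV not found: %s", cohort_csv))
      cohort <- utils::read.csv(cohort_csv, stringsAsFactors = FALSE)
      message(sprintf("[extract] %d subjects", nrow(cohort)))
      feats <- extract_cohort_features(cohort, cfg$pipeline,
                                       base_dir = dirname(cohort_csv))
      for (nt in attr(feats, "notes")) message("[extract] ", nt)
      utils::write.csv(feats, features_csv, row.names = FALSE)
    }
    if (cmd %in% c("analyze", "all")) {
      if (!file.exists(cohort_csv))
        stop(sprintf("cohort CSV not found: %s", cohort_csv))
      if (!file.exists(features_csv))
        stop(sprintf("features CSV not found: %s", features_csv))
      cohort <- utils::read.csv(cohort_csv, stringsAsFactors = FALSE)
      feats <- utils::read.csv(features_csv, stringsAsFactors = FALSE)
      report <- run_analysis(cohort, feats, cfg$pipeline)
      write_report(report, out_dir)
      message(sprintf("[analyze] report written to %s", out_dir))
    }
    0L
  }
  tryCatch(run(), error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  })
}
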