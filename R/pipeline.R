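# End-to-end orchestration: one declarative run configuration drives
# synthesis (or file loading), both detectors, evaluation against both
# knowledge bases, Venn partitioning, novel-hypothesis ranking and
# demographic summaries, with every resolved default echoed to the run log.

#' Demographic summary of a report table or a patient cohort
#'
#' For spontaneous reports (`source = "faers"`), counts and percentages by
#' gender for the reports mentioning the drug; percentages are taken
#' against the full total including unknown-gender reports, so female and
#' male percentages need not sum to 100. For a patient cohort
#' (`source = "emr"`), percentages are taken against the female + male sum
#' and race counts are included. The female:male ratio is rounded half-up
#' to one decimal and reported as `NA` when there are no male records.
#'
#' @param x report data frame (`faers`) or demographics data frame (`emr`,
#'   already restricted to the cohort of interest).
#' @param drug optional drug code used to filter reports (`faers` only).
#' @param source `"faers"` or `"emr"`.
#' @return A list of class `demographics_summary`.
#' @export
demographics_summary <- function(x, drug = NULL,
                                 source = c("faers", "emr")) {
  source <- match.arg(source)
  if (source == "faers") {
    if (!is.null(drug)) x <- x[.has_member(x$drug_ids, drug), , drop = FALSE]
    total <- nrow(x)
    pct_denom <- total
  } else {
    total <- nrow(x)
    pct_denom <- sum(x$gender %in% c("F", "M"))
  }
  n_f <- sum(x$gender == "F")
  n_m <- sum(x$gender == "M")
  n_u <- total - n_f - n_m
  pct <- function(n) {
    if (pct_denom == 0) return(NA_real_)
    .round_half_up(100 * n / pct_denom, 1)
  }
  ratio <- if (n_m == 0) NA_real_ else .round_half_up(n_f / n_m, 1)
  out <- list(source = toupper(source), drug = drug, total = total,
              n_female = n_f, n_male = n_m, n_unknown = n_u,
              pct_female = pct(n_f), pct_male = pct(n_m),
              fm_ratio = ratio)
  if (source == "emr") {
    race <- table(x$race)
    out$race_counts <- as.list(stats::setNames(as.integer(race), names(race)))
  }
  structure(out, class = "demographics_summary")
}

#' @export
print.demographics_summary <- function(x, ...) {
  cat("<demographics_summary ", x$source, ">",
      if (!is.null(x$drug)) paste0(" drug ", x$drug), " total ", x$total,
      ": F ", x$n_female, " (", x$pct_female, "%), M ", x$n_male,
      " (", x$pct_male, "%), F:M ",
      if (is.na(x$fm_ratio)) "undefined" else paste0(x$fm_ratio, ":1"),
      "\n", sep = "")
  invisible(x)
}

.default_thresholds <- function() {
  list(min_a = 1L, min_patients = 1L, z = 1.96, p_method = "auto",
       bonferroni_m = NULL, strategy = "both", top_k = 10L,
       comparator = "all", exposure_tail_days = 0L)
}

.resolve_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  thr <- utils::modifyList(.default_thresholds(),
                           config$thresholds %||% list())
  config$thresholds <- thr
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full detection and evaluation pipeline
#'
#' The configuration is a list (or the path of a YAML file) with either a
#' `synthetic` block of [synth_config()] fields or an `inputs` block of
#' file paths (`hierarchy`, `reports`, `events`, `demographics`,
#' `kb_sider_indications`, `kb_sider_se`, `kb_adrecs`), plus `drug`,
#' `indication` (CUI), `sider_drug_id`, `indication_name`, an optional
#' `thresholds` block (`min_a`, `min_patients`, `z`, `p_method`,
#' `bonferroni_m`, `strategy`, `top_k`, `comparator`,
#' `exposure_tail_days`) and `out_dir`.
#'
#' Per run it writes `signals_faers.tsv`, `signals_emr.tsv`,
#' `metrics.json` (per source and combined, exact and flexible, for each
#' knowledge base), `venn.json`, `novel.tsv`, `demographics.json` and
#' `run_log.json` into `out_dir`. Any stage failure aborts with the stage
#' name and removes partial outputs.
#'
#' @param config list or YAML path.
#' @return Invisibly, a list with the signal sets, metrics, venn counts,
#'   novel-candidate table and demographic summaries.
#' @export
run_pipeline <- function(config) {
  config <- .resolve_config(config)
  out_dir <- config$out_dir %||% stop("config needs an out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  stage <- "configuration"
  on_fail <- function(e) {
    unlink(written)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }
  emit <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    written <<- c(written, path)
    path
  }

  tryCatch({
    stage <- "inputs"
    if (!is.null(config$synthetic)) {
      cfg <- do.call(synth_config, config$synthetic)
      scen <- gen_scenario(cfg)
      h <- scen$hierarchy
      reports <- scen$reports
      events <- scen$events
      demo <- scen$demographics
      drug <- cfg$drug
      indication <- scen$terms$indication_cui
      kb_sider <- load_sider_kb_df(scen$sider_indications, scen$sider_se,
                                   cfg$sider_drug_id,
                                   scen$terms$indication_name)
      kb_adrecs <- load_adrecs_kb_df(scen$adrecs, cfg$drug)
    } else {
      ins <- config$inputs %||% stop("config needs a synthetic or inputs block")
      h <- load_hierarchy(ins$hierarchy)
      reports <- read_reports(ins$reports)
      events <- read_events(ins$events)
      demo <- read_demographics(ins$demographics)
      drug <- config$drug %||% stop("config needs a drug")
      indication <- config$indication %||% stop("config needs an indication")
      kb_sider <- load_sider_kb(ins$kb_sider_indications, ins$kb_sider_se,
                                config$sider_drug_id,
                                config$indication_name)
      kb_adrecs <- load_adrecs_kb(ins$kb_adrecs, drug)
    }
    thr <- config$thresholds

    stage <- "faers signal detection"
    s_faers <- detect_signals_faers(reports, drug, indication,
                                    min_a = thr$min_a, z = thr$z,
                                    comparator = thr$comparator)
    emit("signals_faers.tsv", function(p) write_signals(s_faers, p))

    stage <- "emr signal detection"
    s_emr <- detect_signals_emr(events, drug, indication,
                                min_patients = thr$min_patients, z = thr$z,
                                p_method = thr$p_method,
                                bonferroni_m = thr$bonferroni_m,
                                exposure_tail_days = thr$exposure_tail_days,
                                hierarchy = h)
    emit("signals_emr.tsv", function(p) write_signals(s_emr, p))

    stage <- "evaluation"
    s_comb <- combine_sources(s_faers, s_emr)
    strategies <- if (thr$strategy == "both") c("EXACT", "FLEXIBLE") else {
      toupper(thr$strategy)
    }
    kbs <- list(sider = kb_sider, adrecs = kb_adrecs)
    metrics <- list()
    for (kb_name in names(kbs)) {
      for (strat in strategies) {
        for (src in c("faers", "emr", "combined")) {
          s <- switch(src, faers = s_faers, emr = s_emr, combined = s_comb)
          m <- match_signals(s, kbs[[kb_name]], h, strat)
          metrics[[kb_name]][[tolower(strat)]][[src]] <- compute_metrics(m)
        }
      }
    }
    emit("metrics.json", function(p) {
      jsonlite::write_json(metrics, p, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
    })

    kb_flex <- expand_kb_flexible(kb_sider, h)
    venn <- venn_partition(s_faers, s_emr, kb_flex)
    emit("venn.json", function(p) {
      jsonlite::write_json(as.list(venn), p, auto_unbox = TRUE, pretty = TRUE)
    })

    stage <- "hypothesis generation"
    kb_flex_both <- union(kb_flex, expand_kb_flexible(kb_adrecs, h))
    novel <- novel_candidates(s_comb, kb_flex_both, top_k = thr$top_k)
    emit("novel.tsv", function(p) {
      utils::write.table(novel, p, sep = "\t", quote = FALSE,
                         row.names = FALSE, fileEncoding = "UTF-8")
    })

    stage <- "demographics"
    cohort <- extract_cohort(events, drug, indication,
                             thr$exposure_tail_days)
    demo_cohort <- demo[demo$patient_id %in% cohort$patient_id, ,
                        drop = FALSE]
    demos <- list(faers = demographics_summary(reports, drug, "faers"),
                  emr = demographics_summary(demo_cohort, drug, "emr"))
    emit("demographics.json", function(p) {
      jsonlite::write_json(lapply(demos, unclass), p, auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
    })

    stage <- "run log"
    log <- list(package_version = as.character(utils::packageVersion("pharmsig")),
                r_version = R.version.string,
                timestamp = format(Sys.time(), tz = "UTC"),
                drug = drug, indication = indication,
                thresholds = thr[!vapply(thr, is.null, logical(1))],
                synthetic_seed = config$synthetic$seed)
    emit("run_log.json", function(p) {
      jsonlite::write_json(log, p, auto_unbox = TRUE, pretty = TRUE)
    })

    invisible(list(signals_faers = s_faers, signals_emr = s_emr,
                   signals_combined = s_comb, metrics = metrics,
                   venn = venn, novel = novel, demographics = demos,
                   hierarchy = h, kb_sider = kb_sider,
                   kb_adrecs = kb_adrecs))
  }, error = on_fail)
}

#' In-memory variants of the knowledge-base loaders
#'
#' Same semantics as [load_sider_kb()] / [load_adrecs_kb()] but taking data
#' frames instead of file paths; used by the synthetic pipeline to avoid a
#' write-read round trip.
#'
#' @param indications,se,df data frames in the respective dialects.
#' @param drug_id,indication_name,drug_name as in the file-based loaders.
#' @return An `ade_kb`.
#' @export
load_sider_kb_df <- function(indications, se, drug_id, indication_name) {
  tmp_i <- tempfile(fileext = ".tsv")
  tmp_s <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(tmp_i, tmp_s)))
  utils::write.table(indications, tmp_i, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.table(se, tmp_s, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  load_sider_kb(tmp_i, tmp_s, drug_id, indication_name)
}

#' @rdname load_sider_kb_df
#' @export
load_adrecs_kb_df <- function(df, drug_name) {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  load_adrecs_kb(tmp, drug_name)
}
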