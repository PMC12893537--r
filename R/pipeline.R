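# End-to-end orchestration: ingest (or simulate) -> deduplicate ->
# primary-suspect filter -> contingency -> prior fit -> scoring ->
# strata / exclusion / comparator / onset profiles -> CSV export, with a
# run manifest recording the configuration hash, seed and per-stage row
# counts. Reruns with an identical configuration and seed reproduce
# byte-identical outputs.

default_run_config <- function() {
  list(target_drug = "fondaparinux", level = "PT", soc_level = TRUE,
       thresholds = list(min_cases = 3, combine = "all"),
       strata = c("age_group", "sex"), exclusion = TRUE,
       comparators = character(0), onset = TRUE, seed = 20040101)
}

read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      pv_stop(sprintf("config file '%s' not found", config), "pv_config_error")
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) pv_stop("config must be a list or a YAML path",
                                "pv_config_error")
  cfg <- utils::modifyList(default_run_config(), config)
  has_input <- !is.null(cfg$input)
  has_synth <- !is.null(cfg$synthetic)
  if (has_input == has_synth) {
    pv_stop("exactly one of 'input' (paths) or 'synthetic' (generator config) is required",
            "pv_config_error")
  }
  cfg
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(cfg, tmp, version = 2)
  unname(tools::md5sum(tmp))
}

#' Run the full disproportionality pipeline
#'
#' Stages execute in a fixed order: ingest (or simulate), deduplicate,
#' primary-suspect filter, contingency and prior fit, scoring at PT (and
#' optionally SOC) level, then the requested stratified, exclusion,
#' comparator, demographic and time-to-onset analyses. All tables are
#' written as CSV under `outdir` together with the quality log and a JSON
#' manifest (configuration hash, seed, per-stage row counts). Any stage
#' failure aborts with a stage-named error and removes partial outputs.
#'
#' @param config A list, or path to a YAML file, with elements: exactly
#'   one of `synthetic` (arguments for [synthetic_config()]) or `input`
#'   (paths for [read_faers_ascii()]); `target_drug`; optional
#'   `vocabulary` / `dictionary` paths (the bundled toy files are the
#'   default); `thresholds`; `strata`; `exclusion`; `comparators`;
#'   `onset`; `seed`.
#' @param outdir Output directory.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, outdir) {
  cfg <- read_run_config(config)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  written <- character(0)
  emit <- function(writer, obj, name) {
    path <- file.path(outdir, name)
    writer(obj, path)
    written <<- c(written, path)
    path
  }
  manifest <- list(config_hash = config_hash(cfg), seed = cfg$seed,
                   stages = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      pv_stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
              "pv_stage_error")
    })
  }
  log_stage <- function(name, rows) {
    manifest$stages[[name]] <<- rows
    message(sprintf("[%s] %s", name, paste(sprintf("%s=%s", names(rows), rows),
                                           collapse = " ")))
  }

  synth_cfg <- NULL
  raw <- stage("ingest", {
    if (!is.null(cfg$synthetic)) {
      synth_cfg <- do.call(synthetic_config, cfg$synthetic)
      generate_reports(synth_cfg, seed = cfg$seed)
    } else {
      dict <- if (!is.null(cfg$dictionary)) load_drug_dictionary(cfg$dictionary)
      read_faers_ascii(cfg$input, dictionary = dict)
    }
  })
  log_stage("ingest", c(reports = nrow(raw$demo)))

  vocab <- stage("vocabulary", {
    if (!is.null(cfg$vocabulary)) {
      load_vocabulary(cfg$vocabulary)
    } else if (!is.null(synth_cfg)) {
      catalog_vocabulary(synth_cfg)
    } else {
      load_vocabulary(pv_example("toy_meddra.tsv"))
    }
  })
  dictionary <- stage("dictionary", {
    load_drug_dictionary(cfg$dictionary %||% pv_example("toy_drugs.tsv"))
  })

  dedup <- stage("deduplicate", deduplicate_reports(raw))
  log_stage("deduplicate", c(reports = nrow(dedup$demo)))

  target <- cfg$target_drug
  ps <- stage("ps_filter", select_primary_suspect(dedup, target))
  log_stage("ps_filter", c(reports = nrow(ps$demo)))

  th <- do.call(signal_thresholds, cfg$thresholds)
  scan_pt <- stage("score_pt", signal_scan(dedup, target, vocab, "PT", th))
  log_stage("score_pt", c(events = nrow(scan_pt$scores),
                          signals = sum(scan_pt$scores$signal %||% 0)))
  emit(export_signal_table, scan_pt, "signal_pt.csv")
  emit(export_contingency, scan_pt$tables, "contingency_pt.csv")
  if (isTRUE(cfg$soc_level)) {
    scan_soc <- stage("score_soc", signal_scan(dedup, target, vocab, "SOC", th))
    log_stage("score_soc", c(events = nrow(scan_soc$scores),
                             signals = sum(scan_soc$scores$signal %||% 0)))
    emit(export_signal_table, scan_soc, "signal_soc.csv")
  }
  hyper_path <- file.path(outdir, "mgps_hyperparameters.csv")
  utils::write.csv(data.frame(parameter = names(coef(scan_pt$hyper)),
                              value = unname(coef(scan_pt$hyper))),
                   hyper_path, row.names = FALSE)
  written <- c(written, hyper_path)

  stage("profiles", {
    emit(function(o, p) utils::write.csv(do.call(
      rbind, lapply(c("sex", "age_group", "reporter", "country", "route",
                      "outcomes"),
                    function(b) cbind(variable = b, o[[b]]))), p,
      row.names = FALSE),
      report_demographics(ps), "demographics.csv")
    if (isTRUE(cfg$onset)) {
      emit(function(o, p) utils::write.csv(o$counts, p, row.names = FALSE),
           onset_analysis(ps, target), "onset_bins.csv")
    }
  })

  for (dim in cfg$strata) {
    stage(paste0("stratify_", dim), {
      strata <- stratify_reports(dedup, dim)
      rows <- lapply(names(strata), function(l) {
        s <- strata[[l]]
        if (!any(s$drugs$name_standard == target & s$drugs$role == "PS")) {
          return(NULL)
        }
        sc <- signal_scan(s, target, vocab, "PT", th, hyper = scan_pt$hyper)
        if (nrow(sc$scores)) cbind(stratum = l, sc$scores) else NULL
      })
      out <- do.call(rbind, rows)
      if (!is.null(out)) {
        emit(function(o, p) utils::write.csv(o, p, row.names = FALSE),
             out, sprintf("signal_by_%s.csv", dim))
      }
    })
  }

  if (isTRUE(cfg$exclusion)) {
    stage("exclusion", {
      ex <- exclusion_analysis(dedup, target, dictionary, vocab, "PT", th)
      log_stage("exclusion", c(excluded = ex$n_excluded,
                               events = nrow(ex$scores)))
      emit(export_signal_table, ex, "signal_excluding_antithrombotics.csv")
    })
  }

  if (length(cfg$comparators)) {
    stage("comparators", {
      cmp <- comparator_analysis(dedup, unique(c(target, cfg$comparators)),
                                 vocab, "PT", th)
      emit(function(o, p) utils::write.csv(
        o[, setdiff(names(o), "level")], p, row.names = FALSE),
        cmp, "comparators.csv")
    })
  }

  emit(function(o, p) write_quality_log(o, p), raw, "quality_log.csv")
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
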