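# End-to-end orchestration: ingest (or simulate) -> deduplicate -> cohorts
# -> signal / onset / outcome analyses, with every table written as TSV
# with a leading `#` metadata block and a manifest recording input hashes,
# the config echo, package version and seed. Reruns with identical inputs
# produce byte-identical outputs.

#' Default pipeline run configuration
#'
#' @param out_dir output directory
#' @param seed integer seed (used by the simulate stage and recorded)
#' @param input_dir directory of FAERS ASCII files, or NULL to simulate
#' @param simulate overrides for [default_sim_config()] elements (used
#'   only when `input_dir` is NULL)
#' @param drugs study drug labels (must exist in the synonym table)
#' @param dictionary path to the event-dictionary YAML
#' @param window `c(start, end)` quarter labels or NULL
#' @param analyses character subset of `c("summary", "signals", "pt_scan",
#'   "head_to_head", "onset", "outcomes")`
#' @return `run_config` list
#' @export
run_config <- function(out_dir, seed = 1L, input_dir = NULL,
                       simulate = list(),
                       drugs = c("bevacizumab", "ramucirumab", "aflibercept"),
                       dictionary = example_dictionary_path(),
                       window = NULL,
                       analyses = c("summary", "signals", "pt_scan",
                                    "head_to_head", "onset", "outcomes")) {
  if (!is.null(input_dir) && length(simulate)) {
    stop("give exactly one of input_dir or a simulate block")
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 input_dir = input_dir, simulate = simulate, drugs = drugs,
                 dictionary = dictionary, window = window,
                 analyses = analyses),
            class = "run_config")
}

# Internal: TSV with `#` metadata header block.
write_table <- function(dt, path, meta) {
  con <- file(path, "w")
  writeLines(sprintf("# %s: %s", names(meta), unlist(meta)), con)
  close(con)
  data.table::fwrite(dt, path, sep = "\t", append = TRUE, col.names = TRUE)
  path
}

#' Run the full analysis pipeline
#'
#' @param config `run_config`
#' @return invisibly, a list with the in-memory artifacts (`reports`,
#'   `cohorts`, `universe`, the analysis tables) and `paths` of written
#'   files
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(tool = paste0("faerstee ",
                             as.character(utils::packageVersion("faerstee"))),
               seed = config$seed)
  paths <- character()
  gen <- NULL

  if (is.null(config$input_dir)) {
    sim <- modifyList(default_sim_config(seed = config$seed),
                      config$simulate)
    class(sim) <- "sim_config"
    input_dir <- file.path(config$out_dir, "archive")
    gen <- generate_faers(sim, input_dir)
  } else {
    input_dir <- config$input_dir
  }
  ascii <- list.files(input_dir, pattern = "\\.txt$", recursive = TRUE,
                      full.names = TRUE)
  meta$input_md5 <- paste(unname(tools::md5sum(sort(ascii))), collapse = ",")

  tabs <- read_faers_archive(input_dir)
  reports <- deduplicate(assemble_reports(tabs))
  paths <- c(paths, write_rejects(reports$rejects,
                                  file.path(config$out_dir, "rejects.tsv")))

  dict <- load_event_dictionary(config$dictionary)
  cohorts <- lapply(setNames(config$drugs, config$drugs), function(dg) {
    select_cohort(reports, cohort_spec(dg, window = config$window), dict)
  })
  rows <- data.table::rbindlist(cohorts)
  out <- list(reports = reports, cohorts = cohorts, gen = gen)

  if ("summary" %in% config$analyses) {
    out$summary <- descriptive_summary(rows)
    paths <- c(paths, write_table(out$summary,
                                  file.path(config$out_dir, "table1_summary.tsv"),
                                  meta))
  }
  universe <- label_universe(reports, dict, cohorts)
  out$universe <- universe
  if ("signals" %in% config$analyses) {
    out$signals <- signal_table(universe)
    paths <- c(paths, write_table(out$signals,
                                  file.path(config$out_dir, "table2_signals.tsv"),
                                  meta))
  }
  if ("pt_scan" %in% config$analyses) {
    scans <- lapply(setNames(config$drugs, config$drugs), function(dg) {
      s <- pt_level_scan(universe, dg)
      if (nrow(s)) s[, drug := dg]
      s
    })
    out$pt_scan <- data.table::rbindlist(scans[vapply(scans, nrow, 0L) > 0])
    paths <- c(paths, write_table(out$pt_scan,
                                  file.path(config$out_dir, "fig2_pt_scan.tsv"),
                                  meta))
  }
  if ("head_to_head" %in% config$analyses && length(config$drugs) >= 2L) {
    prs <- utils::combn(config$drugs, 2L, simplify = FALSE)
    hh <- data.table::rbindlist(lapply(prs, function(p) {
      est <- head_to_head(cohorts[[p[[1L]]]], cohorts[[p[[2L]]]],
                          "overall_TEE")
      cbind(data.table::data.table(drugA = p[[1L]], drugB = p[[2L]]), est)
    }))
    out$head_to_head <- hh
    paths <- c(paths, write_table(hh,
                                  file.path(config$out_dir, "head_to_head.tsv"),
                                  meta))
  }
  if ("onset" %in% config$analyses) {
    tee <- rows[overall_TEE == TRUE & !is.na(onset_days)]
    samples <- split(tee$onset_days, tee$drug)
    samples <- samples[lengths(samples) > 0L]
    onset_out <- list()
    if (length(samples) >= 2L) {
      kw <- kruskal_wallis(samples)
      onset_out$kw <- data.table::data.table(
        comparison = "by_drug", test = "kruskal_wallis",
        statistic = kw$statistic, p_value = kw$p_value,
        n = sum(kw$n_per_group))
    }
    fx <- tee$onset_days[tee$fatal]; fy <- tee$onset_days[!tee$fatal]
    if (length(fx) && length(fy)) {
      mw <- mann_whitney(fx, fy)
      onset_out$mw <- data.table::data.table(
        comparison = "fatal_vs_nonfatal", test = "mann_whitney",
        statistic = mw$statistic, p_value = mw$p_value,
        n = sum(mw$n_per_group))
    }
    out$onset_tests <- data.table::rbindlist(onset_out)
    if (length(samples)) {
      out$cumulative_incidence <- cumulative_incidence(samples)
      paths <- c(paths, write_table(out$cumulative_incidence,
                                    file.path(config$out_dir,
                                              "fig1_cumulative_incidence.tsv"),
                                    meta))
    }
    if (nrow(out$onset_tests %||% data.table::data.table())) {
      paths <- c(paths, write_table(out$onset_tests,
                                    file.path(config$out_dir,
                                              "onset_tests.tsv"), meta))
    }
  }
  if ("outcomes" %in% config$analyses) {
    subgroup_drug <- intersect("bevacizumab", config$drugs)
    subgroups <- if (length(subgroup_drug)) {
      setNames(list(c("colorectal", "nsclc", "ovarian", "glioblastoma")),
               subgroup_drug)
    } else list()
    out$forest <- mortality_association(rows, subgroups = subgroups)
    paths <- c(paths, write_table(out$forest,
                                  file.path(config$out_dir, "fig3_forest.tsv"),
                                  meta))
  }

  manifest <- list(tool = meta$tool, seed = config$seed,
                   input_dir = input_dir, input_md5 = meta$input_md5,
                   analyses = config$analyses, drugs = config$drugs,
                   outputs = setNames(as.list(unname(tools::md5sum(paths))),
                                      basename(paths)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  out$paths <- c(paths, file.path(config$out_dir, "manifest.json"))
  invisible(out)
}
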