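#' Run the full signal-detection pipeline
#'
#' Orchestrates the analysis end to end: load (or simulate) the report
#' database, de-duplicate, classify exposure, produce the descriptive
#' table, screen the toxicity spectrum for every configured exposure,
#' run the configured subgroup ROR comparisons, summarize time to onset per
#' (exposure, group) with between-group tests, and write every artifact to
#' `out_dir` together with a machine-readable run log (seed, package
#' version, record counts per stage). Given the same configuration and
#' seed, two runs produce byte-identical files. On any stage failure the
#' partially written outputs are removed before the error propagates.
#'
#' @param config Either a list or a path to a YAML/JSON run configuration
#'   with elements:
#'   * `input` — path of an ICSR file, or `simulate` — a list of
#'     [simulate_config()] arguments (one of the two is required);
#'   * `catalog` — optional path of a term-catalog file (default: built-in
#'     endocrine catalog);
#'   * `queries` — optional character vector of groups/terms to screen;
#'   * `ic_method` — `"approx"` or `"gamma"`;
#'   * `min_count` — ROR minimum-count rule (default 3);
#'   * `subgroups` — optional list of comparisons, each a list with
#'     `a`, `b` (names of exposure selectors) and `query`;
#'   * `onset_groups` — optional character vector of groups for the onset
#'     analysis (default: all catalog groups except the all-terms union);
#'   * `seed` — master seed (also forwarded to the simulator).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with the in-memory results (`reports`,
#'   `descriptive`, `spectrum`, `subgroups`, `onset`, `log`) and the paths
#'   written.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::fromJSON(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  stage <- "configuration"
  on_fail <- function(e) {
    unlink(written)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
    catalog <- if (is.null(config$catalog)) builtin_endocrine_catalog()
               else read_term_catalog(config$catalog)
    ic_method <- if (is.null(config$ic_method)) "approx" else config$ic_method
    min_count <- if (is.null(config$min_count)) 3 else config$min_count

    stage <- "load"
    raw <- if (!is.null(config$input)) {
      read_icsr(config$input)
    } else if (!is.null(config$simulate)) {
      args <- config$simulate
      args$seed <- seed
      simulate_icsr(do.call(simulate_config, args))
    } else {
      stop("config needs either 'input' or 'simulate'")
    }

    stage <- "deduplicate"
    reports <- deduplicate_reports(raw)

    stage <- "classify"
    exposure <- classify_exposure(reports)
    selectors <- exposure_selectors()
    present <- vapply(selectors, function(s) any(s(reports)), logical(1))
    selectors <- selectors[present]

    stage <- "descriptive"
    desc <- descriptive_summary(reports, exposure)
    p_desc <- file.path(out_dir, "descriptive.tsv")
    write_tsv(descriptive_to_frame(desc), p_desc)
    written <- c(written, p_desc)

    stage <- "spectrum"
    queries <- if (is.null(config$queries)) {
      c(names(catalog$groups), catalog$terms)
    } else config$queries
    spectrum <- screen_spectrum(reports, catalog, selectors, queries,
                                ic_method = ic_method,
                                min_count = min_count)
    p_spec <- file.path(out_dir, c("spectrum.tsv", "spectrum.json"))
    write_tsv(round_cols(as.data.frame(spectrum), 2), p_spec[1])
    jsonlite::write_json(as.data.frame(spectrum), p_spec[2],
                         auto_unbox = TRUE, digits = NA, na = "null")
    written <- c(written, p_spec)

    stage <- "subgroups"
    subgroups <- lapply(config$subgroups, function(cmp) {
      fit <- compare_subgroups(reports, selectors[[cmp$a]],
                               selectors[[cmp$b]], cmp$query,
                               catalog = catalog, ic_method = ic_method,
                               min_count = min_count,
                               labels = c(cmp$a, cmp$b))
      as_row(fit)
    })
    p_sub <- character()
    if (length(subgroups)) {
      sub_df <- do.call(rbind, subgroups)
      p_sub <- file.path(out_dir, "subgroups.tsv")
      write_tsv(round_cols(sub_df, 2), p_sub)
      written <- c(written, p_sub)
    }

    stage <- "onset"
    onset_groups <- if (is.null(config$onset_groups)) {
      setdiff(names(catalog$groups), "endocrine_all")
    } else config$onset_groups
    onset <- onset_export(reports, catalog, selectors, onset_groups)
    p_onset <- file.path(out_dir, "onset.tsv")
    write_tsv(round_cols(onset, 2), p_onset)
    written <- c(written, p_onset)

    stage <- "log"
    log <- list(seed = seed,
                package = "pvsignal",
                version = as.character(utils::packageVersion("pvsignal")),
                n_loaded = nrow(raw),
                n_after_dedup = nrow(reports),
                n_exposure = as.list(table(exposure)),
                n_spectrum_rows = nrow(spectrum),
                n_subgroup_rows = length(subgroups),
                ic_method = ic_method,
                min_count = min_count)
    p_log <- file.path(out_dir, "run_log.json")
    jsonlite::write_json(log, p_log, auto_unbox = TRUE, digits = NA)
    written <- c(written, p_log)

    invisible(list(reports = reports, descriptive = desc,
                   spectrum = spectrum,
                   subgroups = if (length(subgroups))
                     do.call(rbind, subgroups) else NULL,
                   onset = onset, log = log, paths = written))
  }, error = on_fail)
}

onset_export <- function(reports, catalog, selectors, groups) {
  rows <- list()
  for (ex in names(selectors)) {
    exposed <- selectors[[ex]](reports)
    for (g in groups) {
      hit <- match_query(reports, catalog, g) & exposed
      s <- summarize_onset(reports$onset_weeks[hit])
      rows[[length(rows) + 1L]] <- data.frame(
        exposure = ex, query = g, n = s$n,
        median_weeks = s$median_weeks, q1_weeks = s$q1_weeks,
        q3_weeks = s$q3_weeks,
        p_0_12 = s$bin_proportions[[1]], p_12_24 = s$bin_proportions[[2]],
        p_24_48 = s$bin_proportions[[3]], p_over_48 = s$bin_proportions[[4]],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

round_cols <- function(df, digits) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  df
}
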