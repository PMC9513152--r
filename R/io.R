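.iit_meta_cols <- c("project_id", "research_type", "research_field",
                    "centers", "funding_band", "status", "stage",
                    "enrolled_count", "planned_enrollment",
                    "budget_spent", "budget_planned")
.iit_numeric_cols <- c("enrolled_count", "planned_enrollment",
                       "budget_spent", "budget_planned")

#' Read project records from CSV or JSON
#'
#' The flat CSV dialect has one row per project: the metadata and quantity
#' columns of the data dictionary plus one `<index>__<k>` column per
#' subindex slot with tokens Y/N/CA/NA (case-insensitive). The JSON dialect
#' nests the responses in a `responses` map per record; both encode the same
#' information and round-trip losslessly.
#'
#' Validation reports every offender (row and column) in one error:
#' missing mandatory columns, duplicate project ids, unknown response or
#' enumeration tokens.
#'
#' @param path file ending in `.csv` or `.json`
#' @param instrument the instrument whose subindex ids define the response
#'   columns
#' @return validated records data.frame
#' @export
read_records <- function(path, instrument = iit_instrument()) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    df <- utils::read.csv(path, colClasses = "character",
                          na.strings = NULL, check.names = FALSE)
  } else if (ext == "json") {
    raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    df <- do.call(rbind, lapply(raw, function(r) {
      flat <- r[setdiff(names(r), "responses")]
      resp <- r$responses
      as.data.frame(c(flat, resp), stringsAsFactors = FALSE)
    }))
    df[] <- lapply(df, as.character)
  } else stop("unsupported records format: ", ext)
  validate_records(df, instrument)
}

#' @rdname read_records
#' @param records records data.frame
#' @export
validate_records <- function(records, instrument = iit_instrument()) {
  problems <- character(0)
  need <- c("project_id", "stage", "enrolled_count", "planned_enrollment",
            "budget_spent", "budget_planned")
  absent <- setdiff(need, names(records))
  if (length(absent))
    problems <- c(problems,
                  paste("missing mandatory column(s):",
                        paste(absent, collapse = ", ")))
  if ("project_id" %in% names(records)) {
    dup <- unique(records$project_id[duplicated(records$project_id)])
    if (length(dup))
      problems <- c(problems,
                    paste("duplicate project_id:", paste(dup, collapse = ", ")))
  }
  sub_ids <- intersect(instrument_subindex_ids(instrument), names(records))
  for (col in sub_ids) {
    x <- toupper(trimws(as.character(records[[col]])))
    bad <- which(!(x %in% c("Y", "N", "CA", "NA", "YES", "NO",
                            "CANT_ANSWER", "NOT_APPLICABLE")) & !is.na(x))
    for (r in bad)
      problems <- c(problems, sprintf(
        "row %d, column %s: unknown response token '%s'",
        r, col, records[[col]][r]))
  }
  enums <- list(research_type = .iit_research_types,
                research_field = .iit_fields,
                centers = .iit_centers, status = .iit_statuses,
                stage = .iit_stages)
  for (col in intersect(names(enums), names(records))) {
    x <- tolower(as.character(records[[col]]))
    bad <- which(!(x %in% enums[[col]]))
    for (r in bad)
      problems <- c(problems, sprintf(
        "row %d, column %s: unknown token '%s'", r, col, records[[col]][r]))
  }
  if (length(problems))
    stop("invalid records:\n  ", paste(problems, collapse = "\n  "))
  for (col in intersect(.iit_numeric_cols, names(records)))
    records[[col]] <- as.numeric(records[[col]])
  for (col in sub_ids)
    records[[col]] <- c(Y = "Y", N = "N", CA = "CA", "NA" = "NA",
                        YES = "Y", NO = "N", CANT_ANSWER = "CA",
                        NOT_APPLICABLE = "NA")[
                          toupper(trimws(as.character(records[[col]])))]
  records
}

#' @rdname read_records
#' @export
write_records <- function(records, path, instrument = iit_instrument()) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  } else if (ext == "json") {
    sub_ids <- intersect(instrument_subindex_ids(instrument), names(records))
    recs <- lapply(seq_len(nrow(records)), function(i) {
      row <- as.list(records[i, setdiff(names(records), sub_ids)])
      row$responses <- as.list(records[i, sub_ids])
      row
    })
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  } else stop("unsupported records format: ", ext)
  invisible(path)
}

#' Run the full assessment pipeline
#'
#' Scores a cohort, writes the scorecards and cohort summary, fits the CFA
#' validation model when the sample is large enough (otherwise records the
#' reason for skipping in the manifest), and renders radar charts. All
#' outputs land in `out_dir` together with a run manifest
#' (`manifest.json`: configuration, seed, package version, artifact list).
#'
#' @param records records data.frame or path readable by [read_records()]
#' @param out_dir output directory, created if needed
#' @param config list: `mode` (`"deduction"`/`"proportional"`), `weights`
#'   (`"unweighted"`/`"loading"`), `group_by` metadata column for the radar
#'   chart, `seed`, `cfa` (logical), `instrument` path or `"builtin"`
#' @return invisible list of artifact paths
#' @export
run_pipeline <- function(records, out_dir, config = list()) {
  cfg <- utils::modifyList(
    list(mode = "deduction", weights = "unweighted",
         group_by = "research_type", seed = NULL, cfa = TRUE,
         instrument = "builtin"), config)
  instrument <- if (identical(cfg$instrument, "builtin")) iit_instrument()
    else read_instrument(cfg$instrument)
  if (is.character(records)) records <- read_records(records, instrument)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- list()
  message("scoring ", nrow(records), " projects")
  cards <- score_cohort(records, instrument, mode = cfg$mode,
                        weights = cfg$weights)
  artifacts$scorecards <- file.path(out_dir, "scorecards.csv")
  utils::write.csv(as.data.frame(cards), artifacts$scorecards,
                   row.names = FALSE)
  summary_ok <- all(c("status", "research_type") %in% names(records))
  if (summary_ok) {
    cs <- summarize_cohort(records)
    artifacts$cohort_summary <- file.path(out_dir, "cohort_summary.csv")
    utils::write.csv(as.data.frame(cs), artifacts$cohort_summary,
                     row.names = FALSE)
  }
  model <- cfa_model()
  cfa_skip_reason <- NULL
  if (!isTRUE(cfg$cfa)) {
    cfa_skip_reason <- "disabled in config"
  } else if (nrow(records) <= model$n_free) {
    cfa_skip_reason <- sprintf(
      "n = %d does not exceed the %d free CFA parameters",
      nrow(records), model$n_free)
  } else {
    fit <- iit_cfa(as.data.frame(cards)[, model$indicator_ids],
                   model = model)
    artifacts$cfa_estimates <- file.path(out_dir, "cfa_estimates.csv")
    utils::write.csv(fit$table, artifacts$cfa_estimates, row.names = FALSE)
    artifacts$cfa_fit <- file.path(out_dir, "cfa_fit.json")
    jsonlite::write_json(
      list(chisq = fit$chisq, df = fit$df, indices = fit$indices,
           converged = fit$converged, heywood = fit$heywood),
      artifacts$cfa_fit, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(cfa_skip_reason))
    message("CFA skipped: ", cfa_skip_reason)
  group <- if (!is.null(cfg$group_by) && cfg$group_by %in% names(records))
    records[[cfg$group_by]] else NULL
  radar <- build_radar(cards, group, instrument)
  artifacts$radar <- file.path(out_dir, "radar.svg")
  write_radar_svg(radar, artifacts$radar)
  manifest <- list(
    package = "iitqa",
    version = as.character(utils::packageVersion("iitqa")),
    config = cfg[c("mode", "weights", "group_by", "instrument")],
    seed = cfg$seed,
    n_projects = nrow(records),
    cfa_skipped = cfa_skip_reason,
    artifacts = lapply(artifacts, basename))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       null = "null")
  artifacts$manifest <- manifest_path
  invisible(artifacts)
}
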