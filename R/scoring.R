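#' Score a checklist index from its subindex responses
#'
#' Each checklist index starts at 10 points and loses one point per "no" or
#' "cant_answer" response, floored at 0. "not_applicable" never deducts; an
#' index whose applicable responses are all absent (empty vector or all
#' "not_applicable") has no evidence and scores `NA`.
#'
#' The alternative `proportional` mode scores `10 * #yes / #applicable`,
#' reading the scoring rule as a proportion of satisfied components instead
#' of a deduction budget.
#'
#' @param responses character vector of responses: `"yes"`, `"no"`,
#'   `"cant_answer"`, `"not_applicable"` (or the CSV tokens Y/N/CA/NA,
#'   case-insensitively).
#' @param mode `"deduction"` (default) or `"proportional"`.
#' @return numeric score in `[0, 10]`, or `NA_real_` if no subindex applies.
#' @examples
#' score_checklist(c("yes", "yes", "yes", "yes"))          # 10
#' score_checklist(c("yes", "no", "cant_answer", "yes"))   # 8
#' score_checklist(rep("no", 12))                          # 0 (floored)
#' @export
score_checklist <- function(responses, mode = c("deduction", "proportional")) {
  mode <- match.arg(mode)
  responses <- parse_responses(responses)
  applicable <- responses != "not_applicable"
  if (!any(applicable)) return(NA_real_)
  if (mode == "deduction") {
    deductions <- sum(responses %in% c("no", "cant_answer"))
    max(0, 10 - deductions)
  } else {
    10 * sum(responses == "yes") / sum(applicable)
  }
}

# Normalize response tokens; error names every offending value.
parse_responses <- function(responses) {
  x <- tolower(as.character(responses))
  x[x == "y"] <- "yes"
  x[x == "n"] <- "no"
  x[x == "ca"] <- "cant_answer"
  x[x == "na" | is.na(responses)] <- "not_applicable"
  bad <- !(x %in% .iit_responses)
  if (any(bad))
    stop("unknown response token(s): ",
         paste(unique(responses[bad]), collapse = ", "))
  x
}

#' Score a ratio index (achieved over planned)
#'
#' Enrollment progress is enrolled/planned subjects; budget implementation is
#' spent/planned budget. The quotient is capped at 1 (over-enrollment or
#' overspend is neither rewarded nor penalized) and scaled to 10.
#'
#' @param numerator achieved amount, `>= 0`
#' @param denominator planned amount, `> 0`
#' @param project_id,field used in the error message for invalid records
#' @return numeric score in `[0, 10]`
#' @export
score_ratio <- function(numerator, denominator, project_id = NULL,
                        field = "ratio index") {
  if (!is.finite(denominator) || denominator <= 0)
    stop("invalid record", if (!is.null(project_id)) paste0(" '", project_id, "'"),
         ": non-positive denominator for ", field)
  if (!is.finite(numerator) || numerator < 0)
    stop("invalid record", if (!is.null(project_id)) paste0(" '", project_id, "'"),
         ": negative numerator for ", field)
  10 * min(1, numerator / denominator)
}

#' Score the overall-progress stage index
#'
#' The four recruitment stages are mapped monotonically onto the 0-10 scale;
#' the default mapping is equally spaced.
#'
#' @param stage one of `"not_enrolled"`, `"enrolled"`,
#'   `"treatment_completed"`, `"follow_up_completed"`
#' @param mapping named numeric vector giving the score of each stage
#' @return numeric score in `[0, 10]`
#' @export
score_stage <- function(stage,
                        mapping = stage_score_mapping()) {
  stage <- tolower(as.character(stage))
  if (!stage %in% names(mapping))
    stop("unknown stage token: ", stage)
  unname(mapping[stage])
}

#' @rdname score_stage
#' @export
stage_score_mapping <- function() {
  stats::setNames(c(0, 10 / 3, 20 / 3, 10), .iit_stages)
}

#' Score one project against an instrument
#'
#' Dispatches every index of the instrument to the scorer matching its
#' measurement kind, then aggregates: an attribute score is the unweighted
#' mean of its present (non-`NA`) member index scores, and the overall score
#' the unweighted mean of the present attribute scores. With
#' `weights = "loading"` the aggregation instead weights by the standardized
#' factor loadings of the shipped validation model
#' ([reference_loadings()]).
#'
#' @param record a single-row data.frame (or coercible list) in the records
#'   dialect: metadata and quantity columns plus one `<index>__<k>` column
#'   per subindex slot. See [read_records()].
#' @param instrument an [iit_instrument()]
#' @param mode checklist scoring mode, see [score_checklist()]
#' @param weights `"unweighted"` (default) or `"loading"`
#' @return An object of class `iit_scorecard`: list with `index_scores`
#'   (named numeric, `NA` = missing), `attribute_scores`, and `overall`.
#' @export
score_project <- function(record, instrument = iit_instrument(),
                          mode = c("deduction", "proportional"),
                          weights = c("unweighted", "loading")) {
  mode <- match.arg(mode)
  weights <- match.arg(weights)
  record <- as.list(record)
  known <- c("project_id", "research_type", "research_field", "centers",
             "funding_band", "status", "stage", "enrolled_count",
             "planned_enrollment", "budget_spent", "budget_planned",
             instrument_subindex_ids(instrument))
  extra <- setdiff(names(record)[grepl("__", names(record), fixed = TRUE)],
                   known)
  if (length(extra))
    stop("response(s) reference unknown subindex id(s): ",
         paste(extra, collapse = ", "))
  ix <- instrument$indexes
  scores <- vapply(seq_len(nrow(ix)), function(i) {
    id <- ix$id[i]
    switch(ix$kind[i],
      checklist = {
        cols <- instrument$subindex_ids[[id]]
        present <- intersect(cols, names(record))
        score_checklist(unlist(record[present]), mode = mode)
      },
      ratio = {
        if (id == "enrollment_progress")
          score_ratio(as.numeric(record$enrolled_count),
                      as.numeric(record$planned_enrollment),
                      record$project_id, "planned_enrollment")
        else
          score_ratio(as.numeric(record$budget_spent),
                      as.numeric(record$budget_planned),
                      record$project_id, "budget_planned")
      },
      staged = score_stage(record$stage))
  }, numeric(1))
  names(scores) <- ix$id
  agg <- aggregate_scores(scores, instrument, weights = weights)
  structure(list(project_id = record$project_id,
                 index_scores = scores,
                 attribute_scores = agg$attribute_scores,
                 overall = agg$overall),
            class = "iit_scorecard")
}

#' Aggregate index scores into attribute and overall scores
#'
#' @param index_scores named numeric vector keyed by instrument index ids;
#'   `NA` marks a missing index score and is excluded from means. An
#'   attribute is `NA` only when all its member indexes are.
#' @inheritParams score_project
#' @return list with `attribute_scores` (named numeric over the four
#'   attributes) and `overall`.
#' @export
aggregate_scores <- function(index_scores, instrument = iit_instrument(),
                             weights = c("unweighted", "loading")) {
  weights <- match.arg(weights)
  ix <- instrument$indexes
  w_first <- if (weights == "loading") reference_loadings()$first_order else
    stats::setNames(rep(1, nrow(ix)), ix$id)
  attribute_scores <- vapply(instrument$attribute_order, function(a) {
    ids <- ix$id[ix$attribute == a]
    s <- index_scores[ids]
    w <- w_first[ids]
    ok <- !is.na(s)
    if (!any(ok)) return(NA_real_)
    sum(w[ok] * s[ok]) / sum(w[ok])
  }, numeric(1))
  w_second <- if (weights == "loading") reference_loadings()$second_order else
    stats::setNames(rep(1, length(instrument$attribute_order)),
                    instrument$attribute_order)
  ok <- !is.na(attribute_scores)
  overall <- if (!any(ok)) NA_real_ else
    sum(w_second[ok] * attribute_scores[ok]) / sum(w_second[ok])
  list(attribute_scores = attribute_scores, overall = overall)
}

#' @export
print.iit_scorecard <- function(x, ...) {
  cat("Scorecard", if (!is.null(x$project_id)) paste0("for ", x$project_id),
      "\n  overall:", formatC(x$overall, digits = 2, format = "f"), "\n")
  for (a in names(x$attribute_scores))
    cat(sprintf("  %-14s %5.2f\n", a, x$attribute_scores[a]))
  invisible(x)
}

#' Score every project of a cohort
#'
#' @param records records data.frame, one row per project ([read_records()])
#' @inheritParams score_project
#' @return data.frame of class `iit_scorecards`: `project_id`, one column
#'   per index, one per attribute, and `overall`.
#' @export
score_cohort <- function(records, instrument = iit_instrument(),
                         mode = c("deduction", "proportional"),
                         weights = c("unweighted", "loading")) {
  mode <- match.arg(mode)
  weights <- match.arg(weights)
  cards <- lapply(seq_len(nrow(records)), function(i)
    score_project(records[i, , drop = FALSE], instrument,
                  mode = mode, weights = weights))
  out <- data.frame(project_id = records$project_id,
                    stringsAsFactors = FALSE)
  for (id in instrument$indexes$id)
    out[[id]] <- vapply(cards, function(c) c$index_scores[[id]], numeric(1))
  for (a in instrument$attribute_order)
    out[[paste0("attr_", a)]] <-
      vapply(cards, function(c) c$attribute_scores[[a]], numeric(1))
  out$overall <- vapply(cards, function(c) c$overall, numeric(1))
  class(out) <- c("iit_scorecards", "data.frame")
  out
}

#' The standardized loadings of the shipped validation model
#'
#' Standardized first-order loadings (index on attribute) and second-order
#' loadings (attribute on overall quality) of the instrument's confirmatory
#' validation, used as the default generating values of the cohort simulator
#' and as optional aggregation weights.
#'
#' @return list with named vectors `first_order` (13) and `second_order` (4).
#' @export
reference_loadings <- function() {
  ids <- default_index_table()$id
  list(
    first_order = stats::setNames(
      c(0.747, 0.375, 0.496,
        0.321, 0.645, 0.500, 0.308,
        0.459, 0.367, 0.786,
        0.306, 0.318, 0.387), ids),
    second_order = stats::setNames(
      c(0.967, 0.425, 0.581, 0.779), .iit_attributes))
}
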