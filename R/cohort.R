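# Percentages are reported half-up at 2 decimals, matching how cohort
# tables in this literature are printed (base round() is half-even).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Summarize the basic characteristics of a cohort
#'
#' Counts and percentages per category of each characteristic item:
#' research status, funding band, research field, research type, number of
#' centers, planned sample-size band, and enrollment-rate band. Percentages
#' are `100 * count / N`, rounded half-up to 2 decimals.
#'
#' @param records records data.frame, one row per project
#' @return object of class `iit_cohort_summary`: data.frame with columns
#'   `item`, `category`, `n`, `percent`, plus attribute `total`.
#' @export
summarize_cohort <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0)
    stop("summarize_cohort() needs a nonempty records data.frame")
  n_total <- nrow(records)
  items <- list(
    research_status = factor(records$status, levels = .iit_statuses),
    funding_band = factor(records$funding_band,
                          levels = sort(unique(records$funding_band))),
    research_field = factor(records$research_field, levels = .iit_fields),
    research_type = factor(records$research_type,
                           levels = .iit_research_types),
    centers = factor(records$centers, levels = .iit_centers),
    sample_size = factor(sample_size_band(records$planned_enrollment),
                         levels = c("<100", "100-500", ">500")),
    enrollment_rate = factor(
      enrollment_rate_band(records$enrolled_count,
                           records$planned_enrollment),
      levels = c("completed", "more_than_half", "less_than_half")))
  rows <- lapply(names(items), function(item) {
    tab <- table(items[[item]])
    data.frame(item = item, category = names(tab),
               n = as.integer(tab),
               percent = round_half_up(100 * as.integer(tab) / n_total),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "total") <- n_total
  class(out) <- c("iit_cohort_summary", "data.frame")
  out
}

sample_size_band <- function(planned) {
  ifelse(planned < 100, "<100", ifelse(planned <= 500, "100-500", ">500"))
}

enrollment_rate_band <- function(enrolled, planned) {
  rate <- enrolled / planned
  ifelse(rate >= 1, "completed",
         ifelse(rate >= 0.5, "more_than_half", "less_than_half"))
}

#' @export
print.iit_cohort_summary <- function(x, ...) {
  cat("Cohort of", attr(x, "total"), "projects\n")
  for (item in unique(x$item)) {
    cat(" ", item, "\n")
    rows <- x[x$item == item, ]
    for (i in seq_len(nrow(rows)))
      cat(sprintf("    %-18s %4d  %6.2f%%\n", rows$category[i],
                  rows$n[i], rows$percent[i]))
  }
  invisible(x)
}

#' Mean index scores by group
#'
#' Arithmetic mean of each index score within each group; `NA` (missing)
#' scores are excluded from the mean. Groups with zero members are dropped
#' with a warning.
#'
#' @param scorecards an `iit_scorecards` data.frame from [score_cohort()]
#' @param group_labels vector of group labels aligned with the scorecards'
#'   rows
#' @param instrument the instrument whose index order defines the columns
#' @return list with `means` (matrix, one row per group, 13 index columns)
#'   and `sizes` (named integer vector of group sizes)
#' @export
mean_scores_by_group <- function(scorecards, group_labels,
                                 instrument = iit_instrument()) {
  stopifnot(nrow(scorecards) == length(group_labels))
  ids <- instrument$indexes$id
  groups <- if (is.factor(group_labels)) levels(group_labels) else
    unique(as.character(group_labels))
  empty <- setdiff(groups, as.character(group_labels))
  if (length(empty)) {
    warning("dropping empty group(s): ", paste(empty, collapse = ", "))
    groups <- setdiff(groups, empty)
  }
  means <- t(vapply(groups, function(g) {
    rows <- scorecards[as.character(group_labels) == g, ids, drop = FALSE]
    colMeans(as.matrix(rows), na.rm = TRUE)
  }, numeric(length(ids))))
  means[is.nan(means)] <- NA_real_
  rownames(means) <- groups
  sizes <- vapply(groups, function(g)
    sum(as.character(group_labels) == g), integer(1))
  list(means = means, sizes = sizes)
}
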