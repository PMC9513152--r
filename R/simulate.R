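#' Category proportions of the reference IIT cohort
#'
#' Default metadata-generating probabilities of the simulator: the category
#' shares of the 272-project funded cohort used to develop the instrument
#' (each item's counts divided by 272).
#'
#' @return named list of items; each a named count vector.
#' @export
reference_cohort_counts <- function() {
  list(
    status = c(assessed = 257L, terminated = 11L, not_applicable = 4L),
    funding_band = c("150-200" = 38L, "80-100" = 33L, "60-80" = 48L,
                     "30-50" = 119L, "15" = 34L),
    research_field = c(internal_medicine = 113L, surgery = 109L,
                       other = 50L),
    research_type = c(rct = 164L, prospective_cohort = 71L,
                      retrospective = 11L, real_world = 6L, other = 20L),
    centers = c(single = 160L, multi = 112L),
    sample_size = c("<100" = 73L, "100-500" = 156L, ">500" = 43L),
    enrollment_rate = c(completed = 135L, more_than_half = 70L,
                        less_than_half = 67L))
}

#' @rdname reference_cohort_counts
#' @export
reference_cohort_proportions <- function() {
  lapply(reference_cohort_counts(), function(x) x / sum(x))
}

#' Simulation configuration for synthetic IIT cohorts
#'
#' Bundles the generating values of the cohort simulator: the standardized
#' first- and second-order loadings of the latent quality model (defaults:
#' the shipped validation loadings, [reference_loadings()]), the affine map
#' from standardized scores to the 0-10 scale, truncation, metadata category
#' probabilities, and optional per-research-type mean shifts on chosen
#' indexes.
#'
#' @param loadings list with `first_order` (13 named values in (-1,1)) and
#'   `second_order` (4 named values in (-1,1))
#' @param score_mean,score_sd per-index affine map applied to the
#'   standardized scores (scalars or vectors of 13)
#' @param truncate clamp mapped scores into \[0, 10\]
#' @param metadata_proportions named list of per-item category probabilities
#' @param group_shifts optional named list: research type -> named numeric
#'   vector of additive score-scale mean offsets per index, applied before
#'   truncation (e.g. `list(rct = c(enrollment_progress = -1.5))`)
#' @return list of class `sim_config`
#' @export
sim_config <- function(loadings = reference_loadings(),
                       score_mean = 8, score_sd = 1.5,
                       truncate = TRUE,
                       metadata_proportions = reference_cohort_proportions(),
                       group_shifts = NULL) {
  l1 <- loadings$first_order; l2 <- loadings$second_order
  if (any(abs(l1) >= 1) || any(abs(l2) >= 1))
    stop("standardized loadings must lie in (-1, 1)")
  for (item in names(metadata_proportions)) {
    pr <- metadata_proportions[[item]]
    if (abs(sum(pr) - 1) > 1e-8)
      stop("probabilities for item '", item, "' must sum to 1")
  }
  structure(list(loadings = loadings, score_mean = score_mean,
                 score_sd = score_sd, truncate = truncate,
                 metadata_proportions = metadata_proportions,
                 group_shifts = group_shifts),
            class = "sim_config")
}

#' Simulate index scores from the second-order latent quality model
#'
#' Draws overall quality `xi ~ N(0,1)`; attribute scores
#' `eta_k = gamma_k xi + zeta_k` with unit variance; index scores
#' `y_j = lambda_j eta_f(j) + eps_j` with unit variance; then maps them to
#' the 0-10 scale (`score_mean + score_sd * y`, truncated if configured).
#' Truncation attenuates the model-implied correlations, so
#' parameter-recovery experiments should run with `truncate = FALSE` and
#' `standardized = TRUE`.
#'
#' @param n cohort size
#' @param config a [sim_config()]
#' @param seed optional integer seed (`set.seed`); `NULL` uses the current
#'   RNG state
#' @param truncate,standardized override the config: `standardized = TRUE`
#'   returns the unit-variance scores without the affine map
#' @return list with `scores` (n x 13 matrix, columns in instrument order),
#'   `eta` (n x 4 attribute scores), `xi` (overall quality), and the
#'   generating `config`
#' @export
simulate_scores <- function(n, config = sim_config(), seed = NULL,
                            truncate = config$truncate,
                            standardized = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  l1 <- config$loadings$first_order
  l2 <- config$loadings$second_order
  ids <- names(l1)
  fac <- default_index_table()$attribute
  xi <- stats::rnorm(n)
  eta <- sapply(seq_along(l2), function(k)
    l2[k] * xi + sqrt(1 - l2[k]^2) * stats::rnorm(n))
  colnames(eta) <- names(l2)
  y <- sapply(seq_along(l1), function(j)
    l1[j] * eta[, fac[j]] + sqrt(1 - l1[j]^2) * stats::rnorm(n))
  colnames(y) <- ids
  if (!standardized) {
    y <- sweep(sweep(y, 2, rep_len(config$score_sd, 13), `*`),
               2, rep_len(config$score_mean, 13), `+`)
    if (truncate) y <- pmin(pmax(y, 0), 10)
  }
  list(scores = y, eta = eta, xi = xi, config = config)
}

#' Model-implied correlation of the simulator's standardized scores
#'
#' Closed-form target used by convergence tests: same-factor indicators
#' correlate `lambda_i lambda_j`; cross-factor indicators
#' `lambda_i lambda_j gamma_a gamma_b`.
#'
#' @param config a [sim_config()]
#' @return 13 x 13 correlation matrix
#' @export
simulator_implied_correlation <- function(config = sim_config()) {
  l1 <- config$loadings$first_order
  l2 <- config$loadings$second_order
  fac <- default_index_table()$attribute
  k <- match(fac, names(l2))
  R <- outer(seq_along(l1), seq_along(l1), function(i, j) {
    same <- k[i] == k[j]
    l1[i] * l1[j] * ifelse(same, 1, l2[k[i]] * l2[k[j]])
  })
  diag(R) <- 1
  dimnames(R) <- list(names(l1), names(l1))
  R
}

#' Draw cohort metadata from category proportions
#'
#' @param n number of projects
#' @param proportions named list as in [reference_cohort_proportions()]
#' @param seed optional seed
#' @return data.frame of metadata columns; planned enrollment is drawn
#'   uniformly within the drawn sample-size band.
#' @export
sample_metadata <- function(n, proportions = reference_cohort_proportions(),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  draw <- function(item) {
    pr <- proportions[[item]]
    sample(names(pr), n, replace = TRUE, prob = pr)
  }
  band <- draw("sample_size")
  planned <- ifelse(band == "<100", sample(30:99, n, replace = TRUE),
             ifelse(band == "100-500", sample(100:500, n, replace = TRUE),
                    sample(501:2000, n, replace = TRUE)))
  data.frame(
    project_id = sprintf("IIT-%05d", seq_len(n)),
    research_type = draw("research_type"),
    research_field = draw("research_field"),
    centers = draw("centers"),
    funding_band = draw("funding_band"),
    status = draw("status"),
    planned_enrollment = as.integer(planned),
    budget_planned = 100,
    stringsAsFactors = FALSE)
}

#' Synthesize project records that score to given targets
#'
#' Inverse of the scoring engine, used for round-trip testing: for each
#' checklist index with target `s`, emits `round(10 - s)` "no" responses and
#' "yes" for the remaining slots, so the deduction scorer returns the
#' rounded target exactly; for ratio indexes the numerator is
#' `round(s/10 * denominator)`; the staged index snaps to the nearest stage
#' level.
#'
#' @param target_scores n x 13 matrix of target index scores in \[0, 10\]
#'   (columns in instrument order)
#' @param instrument an [iit_instrument()]
#' @param metadata optional data.frame from [sample_metadata()]; generated
#'   with default proportions if omitted
#' @param seed optional seed (used only when metadata is generated)
#' @return records data.frame in the flat dialect of [read_records()]
#' @export
synthesize_records <- function(target_scores,
                               instrument = iit_instrument(),
                               metadata = NULL, seed = NULL) {
  target_scores <- as.matrix(target_scores)
  if (any(!is.finite(target_scores)) ||
      any(target_scores < 0) || any(target_scores > 10))
    stop("target scores must lie in [0, 10]")
  n <- nrow(target_scores)
  if (is.null(metadata)) metadata <- sample_metadata(n, seed = seed)
  stopifnot(nrow(metadata) == n)
  ix <- instrument$indexes
  colnames(target_scores) <- ix$id
  rec <- metadata
  stage_map <- stage_score_mapping()
  rec$stage <- names(stage_map)[
    apply(abs(outer(target_scores[, "overall_progress"], stage_map, `-`)),
          1, which.min)]
  rec$enrolled_count <- as.integer(round(
    target_scores[, "enrollment_progress"] / 10 * rec$planned_enrollment))
  rec$budget_spent <- round(
    target_scores[, "budget_implementation"] / 10 * rec$budget_planned, 2)
  for (id in ix$id[ix$kind == "checklist"]) {
    slots <- instrument$subindex_ids[[id]]
    k_no <- pmin(pmax(round(10 - target_scores[, id]), 0), length(slots))
    for (s in seq_along(slots))
      rec[[slots[s]]] <- ifelse(s <= k_no, "N", "Y")
  }
  rec
}

#' Simulate a full synthetic IIT cohort
#'
#' Combines [simulate_scores()], [sample_metadata()] and
#' [synthesize_records()]: latent quality drives the 13 index scores, which
#' are rendered as checklist responses, enrollment counts and budget
#' figures; metadata is drawn from the configured category proportions.
#' Optional `group_shifts` in the config move chosen index scores of chosen
#' research types before truncation (e.g. an RCT enrollment deficit).
#'
#' @inheritParams simulate_scores
#' @param instrument an [iit_instrument()]
#' @return list with `records` (data.frame), `target_scores` (the n x 13
#'   score-scale targets before synthesis), and `truth` (generating
#'   loadings and config)
#' @export
simulate_cohort <- function(n, config = sim_config(), seed = NULL,
                            instrument = iit_instrument()) {
  if (!is.null(seed)) set.seed(seed)
  meta <- sample_metadata(n, config$metadata_proportions)
  sim <- simulate_scores(n, config, truncate = FALSE)
  scores <- sim$scores
  if (!is.null(config$group_shifts)) {
    for (ty in names(config$group_shifts)) {
      shift <- config$group_shifts[[ty]]
      rows <- meta$research_type == ty
      for (id in names(shift))
        scores[rows, id] <- scores[rows, id] + shift[[id]]
    }
  }
  scores <- pmin(pmax(scores, 0), 10)
  records <- synthesize_records(scores, instrument, metadata = meta)
  list(records = records, target_scores = scores,
       truth = list(loadings = config$loadings, config = config))
}

#' Build the reference cohort with the published category counts
#'
#' Deterministically replicates each characteristic item's printed category
#' counts (272 projects) into a records data.frame: items are assigned
#' independently row-wise, so every item's marginal counts are exact. Used
#' to reproduce the cohort-summary percentages; the records carry no
#' checklist responses.
#'
#' @return records data.frame of 272 rows
#' @export
reference_cohort <- function() {
  cts <- reference_cohort_counts()
  n <- sum(cts$research_type)
  expand <- function(x) rep(names(x), times = x)
  band <- expand(cts$sample_size)
  planned <- c("<100" = 50L, "100-500" = 200L, ">500" = 1000L)[band]
  rate <- expand(cts$enrollment_rate)
  frac <- c(completed = 1, more_than_half = 0.7, less_than_half = 0.3)[rate]
  data.frame(
    project_id = sprintf("REF-%03d", seq_len(n)),
    research_type = expand(cts$research_type),
    research_field = expand(cts$research_field),
    centers = expand(cts$centers),
    funding_band = expand(cts$funding_band),
    status = expand(cts$status),
    stage = "enrolled",
    planned_enrollment = unname(planned),
    enrolled_count = as.integer(round(unname(planned * frac))),
    budget_planned = 100,
    budget_spent = 75,
    stringsAsFactors = FALSE)
}
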