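test_that("checklist deduction scoring follows the 10-minus-deductions rule", {
  cases <- list(
    list(resp = rep("yes", 4), want = 10),
    list(resp = c("yes", "no", "cant_answer", "yes"), want = 8),
    list(resp = rep("no", 12), want = 0),            # floored at 0
    list(resp = rep("cant_answer", 11), want = 0),
    list(resp = c("yes", "not_applicable", "no"), want = 9),
    list(resp = character(0), want = NA_real_),
    list(resp = rep("not_applicable", 2), want = NA_real_))
  for (cs in cases)
    expect_identical(score_checklist(cs$resp), cs$want)
})

test_that("checklist scorer accepts CSV tokens case-insensitively", {
  expect_identical(score_checklist(c("Y", "n", "CA", "y")), 8)
  expect_identical(score_checklist(c("NA", "NA")), NA_real_)
  expect_error(score_checklist(c("yes", "maybe")), "maybe")
})

test_that("proportional checklist mode scores the fraction of yes answers", {
  expect_equal(score_checklist(c("yes", "yes", "no", "no"),
                               mode = "proportional"), 5)
  expect_equal(score_checklist(c("yes", "no", "not_applicable"),
                               mode = "proportional"), 5)
  expect_identical(score_checklist(rep("not_applicable", 3),
                                   mode = "proportional"), NA_real_)
})

test_that("ratio index scores the capped achieved/planned quotient", {
  expect_equal(score_ratio(200, 200), 10)
  expect_equal(score_ratio(0, 200), 0)
  expect_equal(score_ratio(150, 200), 7.5)
  expect_equal(score_ratio(250, 200), 10)   # over-achievement capped
  expect_error(score_ratio(10, 0, project_id = "P9"), "P9")
  expect_error(score_ratio(-1, 10), "negative")
})

test_that("stage index maps the four stages monotonically onto 0..10", {
  expect_equal(score_stage("not_enrolled"), 0)
  expect_equal(score_stage("enrolled"), 10 / 3)
  expect_equal(score_stage("treatment_completed"), 20 / 3)
  expect_equal(score_stage("follow_up_completed"), 10)
  expect_error(score_stage("finished"), "finished")
})

test_that("score_project handles the maximal and minimal records", {
  top <- score_project(make_record())
  expect_true(all(top$index_scores == 10))
  expect_true(all(top$attribute_scores == 10))
  expect_equal(top$overall, 10)

  bottom <- score_project(make_record(checklist = "no",
                                      stage = "not_enrolled",
                                      enrolled = 0, spent = 0))
  expect_true(all(bottom$index_scores == 0))
  expect_equal(bottom$overall, 0)
})

test_that("a missing index is excluded from its attribute mean", {
  instr <- iit_instrument()
  rec <- make_record()
  # knock out one quality index entirely
  for (sid in instr$subindex_ids[["data_management"]]) rec[[sid]] <- "NA"
  card <- score_project(rec, instr)
  expect_true(is.na(card$index_scores["data_management"]))
  expect_equal(unname(card$attribute_scores["quality"]), 10)  # mean of other 3
  expect_equal(card$overall, 10)
})

test_that("aggregation is the unweighted mean of present members", {
  instr <- iit_instrument()
  s <- setNames(rep(NA_real_, 13), instr$indexes$id)
  s[c("overall_progress", "enrollment_progress", "budget_implementation")] <-
    c(10, 5, 0)
  agg <- aggregate_scores(s, instr)
  expect_equal(unname(agg$attribute_scores["progress"]), 5)
  expect_true(all(is.na(agg$attribute_scores[c("quality", "regulation",
                                               "scientificity")])))
  expect_equal(agg$overall, 5)   # only one attribute present

  s[] <- c(8, 8, 8, 6, 6, 6, 6, 10, 10, 10, 4, 4, 4)
  expect_equal(aggregate_scores(s, instr)$overall, 7)
})

test_that("loading-weighted aggregation uses the reference loadings", {
  instr <- iit_instrument()
  s <- setNames(rep(5, 13), instr$indexes$id)
  s["overall_progress"] <- 10
  agg <- aggregate_scores(s, instr, weights = "loading")
  w <- reference_loadings()$first_order
  want <- (10 * w["overall_progress"] + 5 * w["enrollment_progress"] +
             5 * w["budget_implementation"]) /
    sum(w[c("overall_progress", "enrollment_progress",
            "budget_implementation")])
  expect_equal(unname(agg$attribute_scores["progress"]), unname(want))
})

test_that("responses naming unknown subindex ids are rejected", {
  rec <- make_record()
  rec$bogus__1 <- "Y"
  expect_error(score_project(rec), "bogus__1")
})

test_that("every score stays in [0,10] over random records", {
  set.seed(42)
  instr <- iit_instrument()
  for (i in 1:25) {
    rec <- make_record(
      stage = sample(c("not_enrolled", "enrolled", "treatment_completed",
                       "follow_up_completed"), 1),
      enrolled = sample(0:300, 1), planned = sample(1:300, 1),
      spent = runif(1, 0, 120), budget = runif(1, 1, 100))
    for (sid in instrument_subindex_ids(instr))
      rec[[sid]] <- sample(c("Y", "N", "CA", "NA"), 1)
    card <- score_project(rec, instr)
    ok <- !is.na(card$index_scores)
    expect_true(all(card$index_scores[ok] >= 0 & card$index_scores[ok] <= 10))
    if (!is.na(card$overall))
      expect_true(card$overall >= 0 && card$overall <= 10)
  }
})

test_that("flipping any yes to no never increases a score", {
  set.seed(43)
  instr <- iit_instrument()
  rec <- make_record()
  sids <- instrument_subindex_ids(instr)
  for (sid in sids) rec[[sid]] <- sample(c("Y", "N", "CA", "NA"), 1)
  base <- score_project(rec, instr)
  yes_cols <- sids[unlist(rec[sids]) == "Y"]
  for (sid in sample(yes_cols, min(10, length(yes_cols)))) {
    worse <- rec
    worse[[sid]] <- "N"
    card <- score_project(worse, instr)
    cmp <- card$index_scores <= base$index_scores
    expect_true(all(cmp | is.na(cmp)))
    expect_lte(card$overall, base$overall)
  }
})
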