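# Builders for hand-made project records used across test files.

# A record scoring `target` on every checklist index, with configurable
# quantitative fields.
make_record <- function(checklist = "yes", stage = "follow_up_completed",
                        enrolled = 100, planned = 100,
                        spent = 50, budget = 50, id = "P1",
                        instrument = iit_instrument()) {
  rec <- list(project_id = id, research_type = "rct",
              research_field = "surgery", centers = "single",
              funding_band = "30-50", status = "assessed",
              stage = stage, enrolled_count = enrolled,
              planned_enrollment = planned, budget_spent = spent,
              budget_planned = budget)
  for (sid in instrument_subindex_ids(instrument)) rec[[sid]] <- checklist
  as.data.frame(rec, stringsAsFactors = FALSE)
}
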