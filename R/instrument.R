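#' @keywords internal
"_PACKAGE"

# Closed vocabularies used throughout the package.
.iit_attributes <- c("progress", "quality", "regulation", "scientificity")
.iit_kinds <- c("checklist", "ratio", "staged")
.iit_responses <- c("yes", "no", "cant_answer", "not_applicable")
.iit_response_tokens <- c(Y = "yes", N = "no", CA = "cant_answer", NA. = "not_applicable")
.iit_stages <- c("not_enrolled", "enrolled", "treatment_completed",
                 "follow_up_completed")
.iit_research_types <- c("rct", "prospective_cohort", "retrospective",
                         "real_world", "other")
.iit_fields <- c("internal_medicine", "surgery", "other")
.iit_centers <- c("single", "multi")
.iit_statuses <- c("assessed", "terminated", "not_applicable")

#' Define a quality-assessment instrument
#'
#' An instrument is the framework that maps observed quality indexes to the
#' four latent quality attributes (progress, quality, regulation,
#' scientificity) and records how each index is measured: `checklist`
#' (Yes / No / Can't answer / Not applicable subindex items scored by
#' deduction), `ratio` (an achieved/planned quotient such as enrollment
#' progress), or `staged` (an ordered recruitment stage).
#'
#' @param indexes data.frame with columns `id`, `name`, `attribute`, `kind`
#'   and `n_subindex` (number of checklist slots; 0 for non-checklist
#'   indexes). Defaults to the built-in 13-index IIT instrument.
#' @return An object of class `iit_instrument`: the `indexes` table plus a
#'   named list `subindex_ids` keyed by checklist index id.
#' @examples
#' instr <- iit_instrument()
#' instr$indexes[, c("id", "attribute", "kind")]
#' @export
iit_instrument <- function(indexes = default_index_table()) {
  stopifnot(is.data.frame(indexes),
            all(c("id", "name", "attribute", "kind", "n_subindex") %in%
                  names(indexes)))
  if (anyDuplicated(indexes$id))
    stop("index ids must be unique")
  if (!all(indexes$attribute %in% .iit_attributes))
    stop("unknown attribute: ",
         paste(setdiff(indexes$attribute, .iit_attributes), collapse = ", "))
  if (!all(indexes$kind %in% .iit_kinds))
    stop("unknown measurement kind: ",
         paste(setdiff(indexes$kind, .iit_kinds), collapse = ", "))
  bad <- indexes$kind == "checklist" & indexes$n_subindex < 1
  if (any(bad))
    stop("checklist index without subindices: ",
         paste(indexes$id[bad], collapse = ", "))
  sub_ids <- lapply(seq_len(nrow(indexes)), function(i) {
    if (indexes$kind[i] != "checklist") return(character(0))
    paste0(indexes$id[i], "__", seq_len(indexes$n_subindex[i]))
  })
  names(sub_ids) <- indexes$id
  structure(
    list(indexes = indexes,
         attribute_order = .iit_attributes,
         subindex_ids = sub_ids),
    class = "iit_instrument")
}

#' The built-in IIT index table
#'
#' Thirteen indexes in four attributes: progress holds the three quantitative
#' indexes (overall progress stage, enrollment progress ratio, budget
#' implementation ratio); quality, regulation and scientificity hold the ten
#' checklist indexes. Every checklist index carries 10 subindex slots so the
#' 1-point-per-deduction rule spans the full 0-10 range.
#'
#' @return data.frame with one row per index.
#' @export
default_index_table <- function() {
  data.frame(
    id = c("overall_progress", "enrollment_progress", "budget_implementation",
           "protocol_compliance", "data_management", "subject_management",
           "quality_control",
           "ethical_approval", "subject_safety", "informed_consent",
           "level_of_evidence", "research_method", "protocol_dissemination"),
    name = c("Overall progress", "Enrollment progress",
             "Budget implementation rate",
             "Study protocol compliance", "Data management",
             "Subject management", "Quality control",
             "Ethical approval", "Subject safety", "Informed consent",
             "Level of evidence", "Appropriate research method",
             "Study protocol dissemination"),
    attribute = c(rep("progress", 3), rep("quality", 4),
                  rep("regulation", 3), rep("scientificity", 3)),
    kind = c("staged", "ratio", "ratio", rep("checklist", 10)),
    n_subindex = c(0L, 0L, 0L, rep(10L, 10)),
    stringsAsFactors = FALSE)
}

#' @export
print.iit_instrument <- function(x, ...) {
  cat("IIT quality-assessment instrument:",
      nrow(x$indexes), "indexes /", length(x$attribute_order),
      "attributes\n")
  for (attr in x$attribute_order) {
    rows <- x$indexes[x$indexes$attribute == attr, ]
    cat(sprintf("  %-14s %s\n", attr,
                paste(sprintf("%s [%s]", rows$id, rows$kind),
                      collapse = ", ")))
  }
  invisible(x)
}

#' All subindex ids of an instrument, in index order
#' @param instrument an [iit_instrument()]
#' @return character vector of subindex ids
#' @export
instrument_subindex_ids <- function(instrument) {
  unlist(instrument$subindex_ids, use.names = FALSE)
}

#' Read or write an instrument specification
#'
#' Instruments serialize to YAML or JSON as the index table; the data
#' dictionary CSV written by [write_data_dictionary()] is the flat documented
#' form.
#'
#' @param path file path; format chosen by extension (`.yaml`/`.yml`/`.json`)
#' @return [read_instrument()] returns an `iit_instrument`.
#' @export
read_instrument <- function(path) {
  ext <- tolower(tools::file_ext(path))
  tab <- if (ext %in% c("yaml", "yml")) {
    raw <- yaml::read_yaml(path)
    do.call(rbind, lapply(raw$indexes, function(r)
      data.frame(id = r$id, name = r$name, attribute = r$attribute,
                 kind = r$kind, n_subindex = as.integer(r$n_subindex),
                 stringsAsFactors = FALSE)))
  } else if (ext == "json") {
    as.data.frame(jsonlite::fromJSON(path)$indexes)
  } else stop("unsupported instrument format: ", ext)
  iit_instrument(tab)
}

#' @rdname read_instrument
#' @param instrument an `iit_instrument`
#' @export
write_instrument <- function(instrument, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(
      list(indexes = lapply(seq_len(nrow(instrument$indexes)), function(i)
        as.list(instrument$indexes[i, ]))), path)
  } else if (ext == "json") {
    jsonlite::write_json(list(indexes = instrument$indexes), path,
                         dataframe = "rows", auto_unbox = TRUE)
  } else stop("unsupported instrument format: ", ext)
  invisible(path)
}

#' @rdname read_instrument
#' @export
write_data_dictionary <- function(instrument, path) {
  ix <- instrument$indexes
  dict <- data.frame(
    column = c("project_id", "research_type", "research_field", "centers",
               "funding_band", "status", "stage", "enrolled_count",
               "planned_enrollment", "budget_spent", "budget_planned",
               instrument_subindex_ids(instrument)),
    kind = c(rep("metadata", 7), rep("quantity", 4),
             rep("response", length(instrument_subindex_ids(instrument)))),
    values = c("free text", paste(.iit_research_types, collapse = "|"),
               paste(.iit_fields, collapse = "|"),
               paste(.iit_centers, collapse = "|"), "free text",
               paste(.iit_statuses, collapse = "|"),
               paste(.iit_stages, collapse = "|"),
               "integer >= 0", "integer > 0", "number >= 0", "number > 0",
               rep("Y|N|CA|NA", length(instrument_subindex_ids(instrument)))),
    stringsAsFactors = FALSE)
  utils::write.csv(dict, path, row.names = FALSE)
  invisible(path)
}
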