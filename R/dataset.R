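## Canonical record schema for extracted sequential-herbivory comparisons.
## One row = one comparison of a subsequent-herbivore (or plant) response on an
## induced plant (treatment) vs. a previously undamaged plant (control).

.seqherb_schema <- list(
  character = c(
    "record_id", "study_id", "treatment_id", "response_category", "outcome",
    "setting", "plant_species", "inducer_species", "subsequent_species",
    "plant_life_cycle", "plant_growth_form", "plant_status",
    "inducer_guild", "subsequent_guild", "inducer_diet", "subsequent_diet",
    "inducer_location", "subsequent_location"
  ),
  numeric = c(
    "mean_treatment", "mean_control", "sd_treatment", "sd_control",
    "duration_first", "duration_second"
  ),
  integer = c(
    "n_treatment", "n_control", "events_treatment", "events_control",
    "publication_year"
  ),
  logical = c("inducer_removed", "same_species")
)

.seqherb_mandatory <- c(
  "record_id", "study_id", "treatment_id", "response_category", "outcome",
  "n_treatment", "n_control", "publication_year"
)

.seqherb_enums <- list(
  response_category = c("herbivore_performance", "herbivore_preference",
                        "plant_performance"),
  outcome = c("survival", "growth", "fecundity", "development_time",
              "feeding_choice", "oviposition_choice", "biomass", "damage",
              "reproduction"),
  setting = c("glasshouse", "field"),
  plant_life_cycle = c("annual", "perennial"),
  plant_growth_form = c("herbaceous", "woody"),
  plant_status = c("wild", "cultivated"),
  inducer_diet = c("generalist", "specialist"),
  subsequent_diet = c("generalist", "specialist"),
  inducer_location = c("aboveground", "belowground"),
  subsequent_location = c("aboveground", "belowground")
)

#' Canonical column names of a sequential-herbivory dataset
#'
#' @return Character vector of all canonical field names, in storage order.
#' @export
dataset_fields <- function() unlist(.seqherb_schema, use.names = FALSE)

.as_seqherb_dataset <- function(records, provenance) {
  rownames(records) <- NULL
  structure(records,
            provenance = provenance,
            class = c("seqherb_dataset", "data.frame"))
}

#' Read and validate an extracted effect-size table
#'
#' Reads a CSV/TSV table in the deposited-data schema, optionally translating
#' its headers to canonical field names through a column-mapping file, coerces
#' column types, and validates every row. Rows violating type or range
#' constraints are rejected and reported; structural problems (missing
#' mandatory columns, duplicated record ids, a treatment id spanning two
#' studies) are errors.
#'
#' @param path Path to a CSV (`.csv`) or TSV (`.tsv`/`.txt`) file with a
#'   header row, UTF-8 encoded.
#' @param schema Optional column mapping: a named character vector
#'   (`canonical = "source header"`) or the path to a YAML file holding one
#'   under the key `columns`. Unmapped canonical columns are looked up under
#'   their own names.
#' @return A `seqherb_dataset`: a data frame of validated records in file
#'   order with attributes `provenance` (source path, schema version) and
#'   `validation` (per-row rejection report, see [validation_report()]).
#' @seealso [write_dataset()], [subset_records()], [validation_report()]
#' @export
read_dataset <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  raw <- read.csv(path, sep = sep, check.names = FALSE,
                  stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                  colClasses = "character")
  map <- .resolve_schema(schema)
  dataset_from_table(raw, map = map,
                     provenance = list(source = normalizePath(path),
                                       schema_version = "1.0"))
}

.resolve_schema <- function(schema) {
  if (is.null(schema)) return(NULL)
  if (is.character(schema) && length(schema) == 1 && file.exists(schema)) {
    y <- yaml::read_yaml(schema)
    cols <- if (!is.null(y$columns)) y$columns else y
    return(unlist(cols))
  }
  if (!is.character(schema) || is.null(names(schema)))
    stop("schema must be a named character vector or a YAML file path")
  schema
}

#' Build a validated dataset from an in-memory table
#'
#' Workhorse behind [read_dataset()]; useful when the table already lives in R
#' (e.g. straight from the synthetic generator or a spreadsheet import).
#'
#' @param table A data frame in the deposited schema (canonical or mapped
#'   headers); values may be character, they are coerced.
#' @param map Optional named character vector `canonical = "source header"`.
#' @param provenance List recorded on the result (source, schema_version).
#' @return A `seqherb_dataset`; invalid rows are dropped with a warning and
#'   listed in the `validation` attribute.
#' @export
dataset_from_table <- function(table, map = NULL,
                               provenance = list(source = "<memory>",
                                                 schema_version = "1.0")) {
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  if (!is.null(map)) {
    missing_src <- setdiff(unname(map), names(table))
    if (length(missing_src))
      stop("schema error: mapped source column(s) absent from table: ",
           paste(missing_src, collapse = ", "))
    names(table)[match(unname(map), names(table))] <- names(map)
  }
  absent <- setdiff(.seqherb_mandatory, names(table))
  if (length(absent))
    stop("schema error: missing mandatory column(s): ",
         paste(absent, collapse = ", "))

  all_fields <- dataset_fields()
  for (f in setdiff(all_fields, names(table))) table[[f]] <- NA
  table <- table[, all_fields]

  coerce <- function(x, type) {
    x[x %in% c("", "NA")] <- NA
    switch(type,
           character = as.character(x),
           numeric   = suppressWarnings(as.numeric(x)),
           integer   = suppressWarnings(as.integer(as.numeric(x))),
           logical   = {
             if (is.logical(x)) x
             else as.logical(toupper(trimws(as.character(x))))
           })
  }
  bad_cell <- rep(FALSE, nrow(table))
  for (type in names(.seqherb_schema)) {
    for (f in .seqherb_schema[[type]]) {
      before_na <- is.na(table[[f]]) | table[[f]] %in% c("", "NA")
      table[[f]] <- coerce(table[[f]], type)
      bad_cell <- bad_cell | (!before_na & is.na(table[[f]]))
    }
  }

  errors <- .validate_rows(table)
  errors$unparseable <- errors$unparseable | bad_cell
  reject <- Reduce(`|`, errors)
  report <- .build_report(table, errors, reject)
  if (any(reject)) {
    warning(sum(reject), " record(s) rejected during validation: ",
            paste(head(table$record_id[reject], 10L), collapse = ", "),
            if (sum(reject) > 10L) " ..." else "")
    table <- table[!reject, , drop = FALSE]
  }

  .check_structure(table)
  ds <- .as_seqherb_dataset(table, provenance)
  attr(ds, "validation") <- report
  ds
}

.validate_rows <- function(tab) {
  n_ok <- function(n) !is.na(n) & n >= 1
  has_mean <- !is.na(tab$mean_treatment) & !is.na(tab$mean_control)
  has_events <- !is.na(tab$events_treatment) & !is.na(tab$events_control)
  list(
    unparseable    = is.na(tab$record_id) | is.na(tab$study_id) |
                     is.na(tab$treatment_id),
    bad_category   = !(tab$response_category %in% .seqherb_enums$response_category),
    bad_outcome    = !(tab$outcome %in% .seqherb_enums$outcome),
    bad_n          = !n_ok(tab$n_treatment) | !n_ok(tab$n_control),
    negative_sd    = (!is.na(tab$sd_treatment) & tab$sd_treatment < 0) |
                     (!is.na(tab$sd_control)   & tab$sd_control   < 0),
    events_exceed_n = has_events &
      (tab$events_treatment > tab$n_treatment |
       tab$events_control   > tab$n_control  |
       tab$events_treatment < 0 | tab$events_control < 0),
    no_summaries   = !has_mean & !has_events,
    bad_year       = is.na(tab$publication_year) |
                     tab$publication_year < 1800 | tab$publication_year > 2100,
    negative_duration = (!is.na(tab$duration_first)  & tab$duration_first  < 0) |
                        (!is.na(tab$duration_second) & tab$duration_second < 0)
  )
}

.build_report <- function(tab, errors, reject) {
  rows <- which(reject)
  details <- lapply(rows, function(i) {
    list(record_id = tab$record_id[i],
         row = i,
         violations = names(errors)[vapply(errors, `[`, logical(1), i)])
  })
  list(n_read = nrow(tab), n_rejected = length(rows), rejected = details)
}

.check_structure <- function(tab) {
  if (anyDuplicated(tab$record_id))
    stop("record_id values are not unique: ",
         paste(unique(tab$record_id[duplicated(tab$record_id)])[1:3],
               collapse = ", "))
  key <- paste(tab$study_id, tab$treatment_id, sep = "\r")
  span <- tapply(tab$study_id, tab$treatment_id,
                 function(s) length(unique(s)))
  if (any(span > 1))
    stop("treatment_id mapped to more than one study_id: ",
         paste(names(span)[span > 1][1:3], collapse = ", "))
  both <- !is.na(tab$inducer_species) & !is.na(tab$subsequent_species) &
          !is.na(tab$same_species)
  mismatch <- both &
    (tab$same_species != (tab$inducer_species == tab$subsequent_species))
  if (any(mismatch))
    stop("same_species inconsistent with species columns for record(s): ",
         paste(head(tab$record_id[mismatch], 3L), collapse = ", "))
  invisible(TRUE)
}

#' Row-level validation report of a dataset
#'
#' @param dataset A `seqherb_dataset`.
#' @param json If `TRUE`, return the report serialized as a JSON string.
#' @return The validation report recorded at read time: number of rows read
#'   and rejected, and for each rejected row its record id and the violated
#'   constraints.
#' @export
validation_report <- function(dataset, json = FALSE) {
  rep <- attr(dataset, "validation")
  if (is.null(rep))
    rep <- list(n_read = nrow(dataset), n_rejected = 0L, rejected = list())
  if (json) jsonlite::toJSON(rep, auto_unbox = TRUE, pretty = TRUE) else rep
}

#' Write a dataset back to CSV
#'
#' Inverse of [read_dataset()]: emits the canonical columns in record order so
#' a read/write/read round trip is the identity on records.
#'
#' @param dataset A `seqherb_dataset`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  write.csv(as.data.frame(dataset)[, dataset_fields()], path,
            row.names = FALSE, fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Subset a dataset by field/value clauses
#'
#' All clauses are combined conjunctively; record order is preserved and an
#' empty result is allowed. Two successive calls are equivalent to one call
#' with the union of the clauses.
#'
#' @param dataset A `seqherb_dataset` (or any data frame with the fields).
#' @param ... Clauses `field = values`; a record matches a clause when its
#'   field value is in `values` (NA never matches).
#' @param filter Alternatively, a named list of clauses.
#' @return A `seqherb_dataset` with the matching records.
#' @export
subset_records <- function(dataset, ..., filter = NULL) {
  clauses <- c(list(...), filter)
  if (!length(clauses)) return(dataset)
  if (is.null(names(clauses)) || any(names(clauses) == ""))
    stop("all filter clauses must be named")
  unknown <- setdiff(names(clauses), names(dataset))
  if (length(unknown))
    stop("unknown field(s) in filter: ", paste(unknown, collapse = ", "))
  keep <- rep(TRUE, nrow(dataset))
  for (f in names(clauses))
    keep <- keep & !is.na(dataset[[f]]) & dataset[[f]] %in% clauses[[f]]
  out <- dataset[keep, , drop = FALSE]
  .as_seqherb_dataset(as.data.frame(out), attr(dataset, "provenance"))
}

#' @export
print.seqherb_dataset <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat("<seqherb_dataset> ", nrow(x), " records, ",
      length(unique(x$study_id)), " studies, ",
      length(unique(paste(x$study_id, x$treatment_id))), " treatments\n",
      sep = "")
  if (!is.null(prov)) cat("source:", prov$source, "\n")
  tab <- table(x$response_category)
  if (length(tab)) print(tab)
  invisible(x)
}
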