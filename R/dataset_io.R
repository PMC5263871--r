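# Tabular schema for outcome measures: reading, validation, writing.

.mandatory_cols <- c("study_id", "metric", "x_start", "x_end", "x_ref", "t_years")
.numeric_cols <- c("x_start", "x_end", "x_ref", "t_years", "variance",
                   "n_recovery_sites", "n_reference_sites", "area_km2",
                   "disturbance_duration_years")
.enum_cols <- c("metric", "submetric", "ecosystem", "disturbance")
.optional_cols <- c("outcome_id", "submetric", "ecosystem", "disturbance",
                    "variance", "organism", "koppen", "n_recovery_sites",
                    "n_reference_sites", "area_km2", "disturbance_duration_years")

#' Read a database of outcome measures
#'
#' Reads a comma-separated, UTF-8 file in which each row is one comparison of a
#' recovering ecosystem against its reference: the value of a metric at the
#' start of recovery (`x_start`), at the end (`x_end`), the reference value
#' (`x_ref`) and the elapsed time in years (`t_years`). A column mapping lets
#' the same reader ingest files whose headers differ from the canonical schema.
#'
#' Rows whose numeric cells cannot be parsed, or whose category labels cannot
#' be matched to the canonical enums (see [debt_levels]), are collected into a
#' rejects table (attached as attribute `"rejects"`, see [io_rejects()]) and
#' the run continues. A *missing mandatory column* is a schema error and stops
#' the run.
#'
#' @param path Path to a CSV file with a header row.
#' @param mapping Optional named character vector or list, or a path to a YAML
#'   file, mapping canonical column names (names) to the source file's headers
#'   (values), e.g. `c(x_start = "Start.value")`. Canonical names absent from
#'   the mapping are looked up verbatim (case-insensitively).
#' @return A tibble of validated outcome measures with canonical columns; one
#'   row per accepted record, each carrying its source data-row number in
#'   `.row`. Rejected rows are in `attr(x, "rejects")`.
#' @seealso [validate_outcome_measures()], [write_results()]
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("study_id,metric,x_start,x_end,x_ref,t_years",
#'              "s1,abundance,2,8,10,10",
#'              "s1,diversity,5,9,12,4"), f)
#' read_outcome_measures(f)
read_outcome_measures <- function(path, mapping = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  mapping <- resolve_mapping(mapping)

  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE,
                         locale = readr::locale(encoding = "UTF-8"))
  names(raw) <- trimws(names(raw))

  # Resolve each canonical column to a source header.
  all_cols <- c(.mandatory_cols, .optional_cols)
  src <- vapply(all_cols, function(cn) {
    header <- mapping[[cn]] %||% cn
    hit <- which(tolower(names(raw)) == tolower(header))
    if (length(hit)) names(raw)[hit[1]] else NA_character_
  }, character(1))
  missing_mand <- .mandatory_cols[is.na(src[.mandatory_cols])]
  if (length(missing_mand)) {
    abort(paste0("mandatory column(s) missing from ", path, ": ",
                 paste(missing_mand, collapse = ", ")))
  }

  out <- tibble::tibble(.row = seq_len(nrow(raw)))
  for (cn in all_cols) {
    out[[cn]] <- if (!is.na(src[[cn]])) raw[[src[[cn]]]] else NA_character_
  }

  rejects <- tibble::tibble(.row = integer(), reason = character())
  note <- function(rows, reason) {
    if (length(rows)) rejects <<- dplyr::bind_rows(rejects,
      tibble::tibble(.row = rows, reason = reason))
  }

  for (cn in intersect(.numeric_cols, all_cols)) {
    val <- suppressWarnings(as.numeric(out[[cn]]))
    blank <- is.na(out[[cn]]) | trimws(out[[cn]]) == "" |
      tolower(trimws(out[[cn]])) %in% c("na", "nan")
    bad <- which(!blank & is.na(val))
    mand <- cn %in% .mandatory_cols
    note(bad, paste0("unparseable numeric in ", cn))
    if (mand) note(which(blank), paste0("missing value in mandatory column ", cn))
    val[blank] <- NA_real_
    out[[cn]] <- val
  }
  for (cn in .enum_cols) {
    lab <- normalize_enum(out[[cn]], cn)
    blank <- is.na(out[[cn]]) | trimws(out[[cn]]) == ""
    if (cn == "metric") {
      note(which(blank), "missing value in mandatory column metric")
    } else {
      lab[blank] <- if (cn == "submetric") "none" else NA_character_
    }
    note(which(!blank & is.na(lab)), paste0("unrecognized ", cn, " label"))
    out[[cn]] <- lab
  }
  out$submetric[is.na(out$submetric)] <- "none"
  note(which(is.na(out$study_id) | trimws(out$study_id) == ""),
       "missing value in mandatory column study_id")
  if (all(is.na(out$outcome_id))) {
    out$outcome_id <- paste0(out$study_id, "_", out$.row)
  }

  # Invariant violations are rejects too at read time.
  viol <- validate_outcome_measures(out)
  note(viol$.row, paste0("invariant: ", viol$field, " ", viol$rule))

  rejects <- dplyr::distinct(dplyr::arrange(rejects, .data$.row))
  keep <- !(out$.row %in% rejects$.row)
  accepted <- out[keep, , drop = FALSE]
  stopifnot(nrow(accepted) + length(unique(rejects$.row)) == nrow(raw))
  attr(accepted, "rejects") <- rejects
  accepted
}

#' Rejected rows from a read
#'
#' @param x A tibble returned by [read_outcome_measures()].
#' @return A tibble with columns `.row` (source data-row number) and `reason`.
#' @export
io_rejects <- function(x) {
  attr(x, "rejects") %||% tibble::tibble(.row = integer(), reason = character())
}

resolve_mapping <- function(mapping) {
  if (is.null(mapping)) return(list())
  if (is.character(mapping) && length(mapping) == 1 && is.null(names(mapping)) &&
      file.exists(mapping)) {
    mapping <- yaml::read_yaml(mapping)
  }
  as.list(mapping)
}

#' Validate outcome-measure records
#'
#' Checks the type invariants of the schema: positive recovery time, finite
#' start/end/reference values, non-negative variance where present, and
#' metric/submetric compatibility (richness and diversity indexes only under
#' the diversity metric; pools and fluxes only under carbon or nitrogen).
#'
#' Violations are returned as data, one row per violated rule, so a pipeline
#' can report them without stopping.
#'
#' @param df A data frame of outcome measures (canonical columns).
#' @return A tibble with columns `.row`, `field`, `rule`; zero rows iff every
#'   record satisfies every invariant.
#' @export
validate_outcome_measures <- function(df) {
  n <- nrow(df)
  rowid <- if (".row" %in% names(df)) df$.row else seq_len(n)
  v <- list()
  add <- function(bad, field, rule) {
    if (any(bad, na.rm = TRUE)) v[[length(v) + 1]] <<- tibble::tibble(
      .row = rowid[which(bad)], field = field, rule = rule)
  }
  num <- function(cn) if (cn %in% names(df)) df[[cn]] else rep(NA_real_, n)

  add(!is.finite(num("t_years")) | num("t_years") <= 0, "t_years", "must be > 0")
  for (cn in c("x_start", "x_end", "x_ref")) {
    add(!is.finite(num(cn)), cn, "must be finite")
  }
  vv <- num("variance")
  add(!is.na(vv) & vv < 0, "variance", "must be >= 0 when present")
  for (cn in c("n_recovery_sites", "n_reference_sites")) {
    add(!is.na(num(cn)) & num(cn) < 1, cn, "must be >= 1 when present")
  }
  for (cn in c("area_km2", "disturbance_duration_years")) {
    add(!is.na(num(cn)) & num(cn) < 0, cn, "must be >= 0 when present")
  }
  if (all(c("metric", "submetric") %in% names(df))) {
    sm <- df$submetric
    m <- df$metric
    add(sm %in% c("richness", "diversity_index") & !is.na(m) & m != "diversity",
        "submetric", "richness/diversity_index require metric diversity")
    add(sm %in% c("pool", "flux") & !is.na(m) & !m %in% c("carbon", "nitrogen"),
        "submetric", "pool/flux require metric carbon or nitrogen")
  }
  if (length(v)) dplyr::bind_rows(v) else
    tibble::tibble(.row = integer(), field = character(), rule = character())
}

#' Write a result table to CSV
#'
#' Writes any result tibble (per-record debt results, pooled fits, report
#' tables) as UTF-8 comma-separated text with a header row, keeping numeric
#' cells at full precision so a write/read roundtrip is lossless to within
#' floating-point representation.
#'
#' @param rows A non-empty data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(rows, path) {
  if (!is.data.frame(rows) || nrow(rows) == 0) {
    abort("write_results() requires a non-empty table")
  }
  readr::write_csv(rows, path, progress = FALSE)
  invisible(path)
}
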