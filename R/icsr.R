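#' Individual case safety report sets
#'
#' An `icsr_set` is a data frame with one row per spontaneous report
#' (individual case safety report, ICSR) and list columns for the
#' multi-valued fields. Columns:
#'
#' * `report_id` — opaque identifier, character. Unique after
#'   [deduplicate_reports()]; duplicated IDs are permitted before.
#' * `drugs` — list of character vectors, lower-cased suspected drug names
#'   (non-empty).
#' * `events` — list of character vectors, coded adverse-event preferred
#'   terms (non-empty).
#' * `year` — integer calendar year of the report, `NA` when unknown.
#' * `gender` — `"male"`, `"female"` or `"unknown"`.
#' * `age_group` — `"under65"`, `"over65"` or `"unknown"`.
#' * `region` — `"Americas"`, `"Asia"`, `"Europe"`, `"Oceania"`, `"Africa"`
#'   or `"unknown"`.
#' * `notifier` — `"health_professional"`, `"other"` or `"unknown"`.
#' * `indication` — free-text primary tumor label, `"unknown"` when missing.
#' * `onset_weeks` — non-negative weeks from therapy initiation to event
#'   onset, `NA` when not reported.
#' * `outcomes` — list of character vectors with labels from
#'   `death`, `life_threatening`, `hospitalization`,
#'   `other_medically_critical`, `not_recovered`, `recovered`, `unknown`.
#'
#' @param report_id,drugs,events,year,gender,age_group,region,notifier,indication,onset_weeks,outcomes
#'   Field values as described above; the list columns also accept a single
#'   character vector which is recycled row-wise as length-1 entries.
#' @return An object of class `icsr_set` (a data frame).
#' @examples
#' icsr_set(report_id = c("R1", "R2"),
#'          drugs = list("nivolumab", c("ipilimumab", "nivolumab")),
#'          events = list("hypothyroidism", "hypophysitis"))
#' @export
icsr_set <- function(report_id,
                     drugs,
                     events,
                     year = NA_integer_,
                     gender = "unknown",
                     age_group = "unknown",
                     region = "unknown",
                     notifier = "unknown",
                     indication = "unknown",
                     onset_weeks = NA_real_,
                     outcomes = list("unknown")) {
  n <- length(report_id)
  as_listcol <- function(x) {
    if (!is.list(x)) x <- as.list(x)
    x <- rep_len(x, n)
    lapply(x, function(v) unique(as.character(v)))
  }
  df <- data.frame(report_id = as.character(report_id),
                   year = rep_len(as.integer(year), n),
                   gender = rep_len(as.character(gender), n),
                   age_group = rep_len(as.character(age_group), n),
                   region = rep_len(as.character(region), n),
                   notifier = rep_len(as.character(notifier), n),
                   indication = rep_len(as.character(indication), n),
                   onset_weeks = rep_len(as.numeric(onset_weeks), n),
                   stringsAsFactors = FALSE)
  df$drugs <- as_listcol(drugs)
  df$events <- as_listcol(events)
  df$outcomes <- as_listcol(outcomes)
  df <- df[, icsr_columns()]
  class(df) <- c("icsr_set", "data.frame")
  validate_icsr_set(df)
}

icsr_columns <- function() {
  c("report_id", "drugs", "events", "year", "gender", "age_group",
    "region", "notifier", "indication", "onset_weeks", "outcomes")
}

icsr_levels <- list(
  gender = c("male", "female", "unknown"),
  age_group = c("under65", "over65", "unknown"),
  region = c("Americas", "Asia", "Europe", "Oceania", "Africa", "unknown"),
  notifier = c("health_professional", "other", "unknown")
)

#' @rdname icsr_set
#' @param x An object to validate or test.
#' @export
is_icsr_set <- function(x) inherits(x, "icsr_set")

validate_icsr_set <- function(x) {
  stopifnot(is.data.frame(x), all(icsr_columns() %in% names(x)))
  if (any(!nzchar(x$report_id)) || anyNA(x$report_id)) {
    stop("every report must carry a non-empty report_id", call. = FALSE)
  }
  if (any(lengths(x$drugs) == 0L)) {
    stop("every report must list at least one suspected drug", call. = FALSE)
  }
  if (any(lengths(x$events) == 0L)) {
    stop("every report must list at least one event term", call. = FALSE)
  }
  bad <- !is.na(x$onset_weeks) & x$onset_weeks < 0
  if (any(bad)) {
    stop("onset_weeks must be >= 0 (rows ",
         paste(utils::head(which(bad), 5L), collapse = ", "), ")",
         call. = FALSE)
  }
  for (f in names(icsr_levels)) {
    x[[f]][is.na(x[[f]])] <- "unknown"
    unknown <- !(x[[f]] %in% icsr_levels[[f]])
    x[[f]][unknown] <- "unknown"
  }
  x$indication[is.na(x$indication) | !nzchar(x$indication)] <- "unknown"
  x
}

#' @export
print.icsr_set <- function(x, ...) {
  cat("ICSR set:", nrow(x), "report record(s),",
      length(unique(x$report_id)), "unique report ID(s)\n")
  cat("  drugs :", length(unique(unlist(x$drugs))), "distinct\n")
  cat("  events:", length(unique(unlist(x$events))), "distinct\n")
  invisible(x)
}

# Fields whose absence counts against a record when resolving duplicates.
missing_field_count <- function(x) {
  n_unknown <- function(f) as.integer(x[[f]] == "unknown")
  (is.na(x$year)) + n_unknown("gender") + n_unknown("age_group") +
    n_unknown("region") + n_unknown("notifier") + n_unknown("indication") +
    is.na(x$onset_weeks) +
    vapply(x$outcomes, function(o) identical(o, "unknown"), logical(1))
}

#' Remove duplicate reports
#'
#' Duplicates are records sharing a `report_id`. Among records with the same
#' ID the most complete one is kept (fewest unknown/missing fields), ties
#' resolved in favour of the first occurrence, so the operation is
#' deterministic and idempotent.
#'
#' @param reports An [icsr_set()].
#' @return An `icsr_set` with unique `report_id` values, in first-occurrence
#'   order of the retained records.
#' @examples
#' x <- icsr_set(c("R1", "R1", "R2"),
#'               drugs = list("ipilimumab", "ipilimumab", "nivolumab"),
#'               events = list("hypophysitis", "hypophysitis", "thyroiditis"),
#'               gender = c("unknown", "male", "female"))
#' deduplicate_reports(x)$gender  # the complete R1 record wins
#' @export
deduplicate_reports <- function(reports) {
  stopifnot(is_icsr_set(reports))
  if (nrow(reports) == 0L) return(reports)
  miss <- missing_field_count(reports)
  ord <- order(match(reports$report_id, reports$report_id), miss,
               seq_len(nrow(reports)))
  keep <- !duplicated(reports$report_id[ord])
  out <- reports[ord[keep], , drop = FALSE]
  out <- out[order(match(out$report_id, unique(reports$report_id))), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("icsr_set", "data.frame")
  out
}

#' Flag medically critical (fatal-type) outcomes
#'
#' A report is flagged when any recorded outcome is death, a
#' life-threatening condition, hospitalization (initial or prolonged), or
#' another medically critical condition.
#'
#' @param reports An [icsr_set()].
#' @return Logical vector, one element per report.
#' @export
flag_fatal <- function(reports) {
  stopifnot(is_icsr_set(reports))
  critical <- c("death", "life_threatening", "hospitalization",
                "other_medically_critical")
  vapply(reports$outcomes, function(o) any(o %in% critical), logical(1))
}

#' Read and write ICSR files
#'
#' Two plain-text dialects are supported. `format = "csv"` is long form:
#' UTF-8, comma-separated, header
#' `report_id,drug,event,year,gender,age_group,region,notifier,indication,onset_weeks,outcomes`,
#' one row per (report, drug, event) combination with the report-level
#' attributes repeated and outcomes pipe-delimited within the cell; rows are
#' aggregated by `report_id` on reading, so row order never affects the
#' result. `format = "jsonl"` is one JSON object per report with
#' `drugs`/`events`/`outcomes` as arrays; each line is one report record, so
#' duplicated IDs survive a JSON-lines round trip (in CSV they merge).
#'
#' @param path File to read or write.
#' @param format `"csv"` or `"jsonl"`; default guessed from the file
#'   extension (`.jsonl`/`.ndjson` means JSON-lines, anything else CSV).
#' @return `read_icsr()` returns an [icsr_set()]; `write_icsr()` returns
#'   `path` invisibly.
#' @export
read_icsr <- function(path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(jsonl|ndjson)$", path)) "jsonl" else "csv"
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "csv") read_icsr_csv(path) else read_icsr_jsonl(path)
}

read_icsr_csv <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE)
  required <- c("report_id", "drug", "event")
  absent <- setdiff(required, names(raw))
  if (length(absent)) {
    stop("schema error: missing required column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  optional <- c("year", "gender", "age_group", "region", "notifier",
                "indication", "onset_weeks", "outcomes")
  for (f in optional) if (is.null(raw[[f]])) raw[[f]] <- rep("", nrow(raw))
  if (nrow(raw) == 0L) return(empty_icsr_set())
  onset <- parse_onset(raw$onset_weeks)
  ids <- unique(raw$report_id)
  first <- match(ids, raw$report_id)
  rows <- split(seq_len(nrow(raw)), factor(raw$report_id, levels = ids))
  icsr_set(
    report_id = ids,
    drugs = lapply(rows, function(i) canonical_drug(raw$drug[i])),
    events = lapply(rows, function(i) unique(trimws(raw$event[i]))),
    year = suppressWarnings(as.integer(blank_na(raw$year[first]))),
    gender = blank_unknown(raw$gender[first]),
    age_group = blank_unknown(raw$age_group[first]),
    region = blank_unknown(raw$region[first]),
    notifier = blank_unknown(raw$notifier[first]),
    indication = blank_unknown(raw$indication[first]),
    onset_weeks = onset[first],
    outcomes = lapply(strsplit(blank_unknown(raw$outcomes[first]), "|",
                               fixed = TRUE), unique)
  )
}

read_icsr_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(empty_icsr_set())
  recs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
  required <- c("report_id", "drugs", "events")
  for (i in seq_along(recs)) {
    absent <- setdiff(required, names(recs[[i]]))
    if (length(absent)) {
      stop("schema error: record ", i, " missing field(s): ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
  }
  field <- function(name, default) {
    vapply(recs, function(r) {
      v <- r[[name]]
      if (is.null(v) || length(v) == 0L || is.na(v)[1]) default
      else as.character(v[[1]])
    }, character(1))
  }
  icsr_set(
    report_id = field("report_id", ""),
    drugs = lapply(recs, function(r) canonical_drug(r$drugs)),
    events = lapply(recs, function(r) unique(trimws(as.character(r$events)))),
    year = suppressWarnings(as.integer(blank_na(field("year", "")))),
    gender = field("gender", "unknown"),
    age_group = field("age_group", "unknown"),
    region = field("region", "unknown"),
    notifier = field("notifier", "unknown"),
    indication = field("indication", "unknown"),
    onset_weeks = parse_onset(field("onset_weeks", "")),
    outcomes = lapply(recs, function(r) {
      o <- r$outcomes
      if (is.null(o) || length(o) == 0L) "unknown" else unique(as.character(o))
    })
  )
}

#' @rdname read_icsr
#' @param reports An [icsr_set()] to serialize.
#' @export
write_icsr <- function(reports, path, format = c("auto", "csv", "jsonl")) {
  stopifnot(is_icsr_set(reports))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(jsonl|ndjson)$", path)) "jsonl" else "csv"
  }
  if (format == "csv") {
    rows <- lapply(seq_len(nrow(reports)), function(i) {
      grid <- expand.grid(drug = reports$drugs[[i]],
                          event = reports$events[[i]],
                          stringsAsFactors = FALSE)
      data.frame(report_id = reports$report_id[i],
                 drug = grid$drug, event = grid$event,
                 year = na_blank(reports$year[i]),
                 gender = reports$gender[i],
                 age_group = reports$age_group[i],
                 region = reports$region[i],
                 notifier = reports$notifier[i],
                 indication = reports$indication[i],
                 onset_weeks = na_blank(reports$onset_weeks[i]),
                 outcomes = paste(reports$outcomes[[i]], collapse = "|"),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    if (is.null(out)) {
      out <- data.frame(report_id = character(), drug = character(),
                        event = character(), year = character(),
                        gender = character(), age_group = character(),
                        region = character(), notifier = character(),
                        indication = character(), onset_weeks = character(),
                        outcomes = character())
    }
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
  } else {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    for (i in seq_len(nrow(reports))) {
      rec <- list(report_id = reports$report_id[i],
                  drugs = reports$drugs[[i]],
                  events = reports$events[[i]],
                  year = reports$year[i],
                  gender = reports$gender[i],
                  age_group = reports$age_group[i],
                  region = reports$region[i],
                  notifier = reports$notifier[i],
                  indication = reports$indication[i],
                  onset_weeks = reports$onset_weeks[i],
                  outcomes = reports$outcomes[[i]])
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                  na = "null"), con)
    }
  }
  invisible(path)
}

empty_icsr_set <- function() {
  df <- data.frame(report_id = character(), year = integer(),
                   gender = character(), age_group = character(),
                   region = character(), notifier = character(),
                   indication = character(), onset_weeks = numeric(),
                   stringsAsFactors = FALSE)
  df$drugs <- list()
  df$events <- list()
  df$outcomes <- list()
  df <- df[, icsr_columns()]
  class(df) <- c("icsr_set", "data.frame")
  df
}

canonical_drug <- function(x) unique(tolower(trimws(as.character(x))))

blank_na <- function(x) {
  x[!nzchar(trimws(x))] <- NA_character_
  x
}

blank_unknown <- function(x) {
  x <- trimws(x)
  x[!nzchar(x) | is.na(x)] <- "unknown"
  x
}

na_blank <- function(x) ifelse(is.na(x), "", as.character(x))

parse_onset <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(NA_real_, length(x))
  has <- nzchar(x) & !is.na(x) & tolower(x) != "na" & tolower(x) != "null"
  val <- suppressWarnings(as.numeric(x[has]))
  if (anyNA(val)) {
    bad <- which(has)[is.na(val)]
    stop("value error: unparseable onset_weeks at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  out[has] <- val
  out
}
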