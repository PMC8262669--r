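#' Store-and-forward journals
#'
#' Data capture is offline-first: every completed task is appended to a
#' durable local *journal* and later synced, idempotently, to a remote
#' store. The journal is append-only; records are never mutated in place,
#' and replaying a journal into an empty remote reproduces the remote
#' state exactly, whatever prefix of earlier syncs failed.
#'
#' Records carry a provenance categorization: `H` (collected at home),
#' `V0` (initial visit), `V1` (follow-up visit).
#'
#' @return `ema_journal()` returns an empty journal; `ema_remote()` an
#'   empty remote store. Both share the `ema_store` class.
#' @name journal
NULL

new_store <- function(role) {
  e <- new.env(parent = emptyenv())
  e$records <- list()
  e$ids <- new.env(parent = emptyenv())
  e$synced <- logical(0)
  e$role <- role
  class(e) <- c(paste0("ema_", role), "ema_store")
  e
}

#' @rdname journal
#' @export
ema_journal <- function() new_store("journal")

#' @rdname journal
#' @export
ema_remote <- function() new_store("remote")

#' Append a record to a journal
#'
#' Validates the record (required fields, known `record_type` and
#' categorization) and appends it. Appending is local and always succeeds
#' regardless of connectivity; the record starts unsynced. A duplicate
#' `record_id` is rejected.
#'
#' @param store An `ema_store`.
#' @param record Named list with at least `record_id`, `patient_id`,
#'   `record_type` (one of scales, fit_test, sleep_diary, anchor,
#'   interaction), `categorization` (H/V0/V1), `created_at` (POSIXct).
#'   Optional: `session_kind`, `study_day`, `date`, `hand`, `payload`.
#' @return The store, invisibly (stores have reference semantics).
#' @export
append_record <- function(store, record) {
  need <- c("record_id", "patient_id", "record_type", "categorization",
            "created_at")
  missing_f <- setdiff(need, names(record))
  if (length(missing_f) > 0) {
    stop("record is missing field(s): ", paste(missing_f, collapse = ", "),
         call. = FALSE)
  }
  if (!record$record_type %in% c("scales", "fit_test", "sleep_diary",
                                 "anchor", "interaction")) {
    stop("unknown record_type '", record$record_type, "'", call. = FALSE)
  }
  if (!record$categorization %in% CATEGORIZATIONS) {
    stop("categorization must be one of H, V0, V1", call. = FALSE)
  }
  id <- as.character(record$record_id)
  if (!is.null(store$ids[[id]])) {
    stop("duplicate record_id '", id, "'", call. = FALSE)
  }
  n <- length(store$records) + 1L
  store$records[[n]] <- record
  store$ids[[id]] <- n
  store$synced[n] <- FALSE
  invisible(store)
}

#' Materialize a store as a tibble
#'
#' @param store An `ema_store`.
#' @return Tibble with one row per record, in append order; `payload` is a
#'   list-column.
#' @export
store_records <- function(store) {
  if (length(store$records) == 0) {
    return(tibble::tibble(
      record_id = character(), patient_id = character(),
      record_type = character(), session_kind = character(),
      study_day = integer(), date = as.Date(character()),
      hand = character(), categorization = character(),
      created_at = as.POSIXct(character()), synced = logical(),
      payload = list()
    ))
  }
  field_chr <- function(nm) {
    vapply(store$records, function(r) {
      v <- r[[nm]]
      if (is.null(v) || length(v) == 0 || is.na(v)) NA_character_
      else as.character(v)
    }, character(1))
  }
  field_num <- function(nm) {
    vapply(store$records, function(r) {
      v <- r[[nm]]
      if (is.null(v) || length(v) == 0) NA_real_ else as.numeric(v)
    }, numeric(1))
  }
  tibble::tibble(
    record_id = field_chr("record_id"),
    patient_id = field_chr("patient_id"),
    record_type = field_chr("record_type"),
    session_kind = field_chr("session_kind"),
    study_day = as.integer(field_num("study_day")),
    date = as.Date(field_num("date"), origin = "1970-01-01"),
    hand = field_chr("hand"),
    categorization = field_chr("categorization"),
    created_at = as.POSIXct(field_num("created_at"),
                            origin = "1970-01-01", tz = "UTC"),
    synced = store$synced,
    payload = lapply(store$records, function(r) r$payload)
  )
}

#' Sync a journal to a remote store
#'
#' At-least-once push with idempotent deduplication by `record_id`:
#' unsynced records are pushed in append order; a record whose id already
#' exists remotely is skipped (and marked synced). A transport failure may
#' be injected after a given number of successful pushes; unacknowledged
#' records stay unsynced, so the next sync resumes exactly where this one
#' stopped. Running sync twice in a row pushes nothing the second time.
#'
#' @param journal An `ema_journal`.
#' @param remote An `ema_remote`.
#' @param fail_after Inject a transport failure after this many successful
#'   pushes in this call (default `Inf`, no failure).
#' @return One-row tibble: `pushed`, `skipped`, `failed` (logical).
#' @export
sync_journal <- function(journal, remote, fail_after = Inf) {
  pushed <- 0L
  skipped <- 0L
  failed <- FALSE
  for (i in seq_along(journal$records)) {
    if (journal$synced[i]) next
    rec <- journal$records[[i]]
    id <- as.character(rec$record_id)
    if (!is.null(remote$ids[[id]])) {
      skipped <- skipped + 1L
      journal$synced[i] <- TRUE
      next
    }
    if (pushed >= fail_after) {
      failed <- TRUE
      break
    }
    n <- length(remote$records) + 1L
    remote$records[[n]] <- rec
    remote$ids[[id]] <- n
    remote$synced[n] <- TRUE
    journal$synced[i] <- TRUE
    pushed <- pushed + 1L
  }
  tibble::tibble(pushed = pushed, skipped = skipped, failed = failed)
}

#' Filter records portal-style
#'
#' Conjunctive filtering over the portal's filter set — patient, date
#' range, session kind, record type, hand (for tapping trials), and data
#' categorization — returning rows in the canonical order (patient, date,
#' session kind, creation time).
#'
#' @param store An `ema_store` or a record tibble from [store_records()].
#' @param patient,session_kind,record_type,hand,categorization Optional
#'   filter values (vectors allowed; `NULL` means no filter).
#' @param from,to Optional inclusive date bounds.
#' @return Filtered, canonically ordered tibble of records.
#' @export
filter_records <- function(store, patient = NULL, from = NULL, to = NULL,
                           session_kind = NULL, record_type = NULL,
                           hand = NULL, categorization = NULL) {
  recs <- if (inherits(store, "ema_store")) store_records(store)
          else tibble::as_tibble(store)
  keep <- rep(TRUE, nrow(recs))
  if (!is.null(patient)) keep <- keep & recs$patient_id %in% patient
  if (!is.null(from)) keep <- keep & !is.na(recs$date) & recs$date >= as.Date(from)
  if (!is.null(to)) keep <- keep & !is.na(recs$date) & recs$date <= as.Date(to)
  if (!is.null(session_kind)) keep <- keep & recs$session_kind %in% session_kind
  if (!is.null(record_type)) keep <- keep & recs$record_type %in% record_type
  if (!is.null(hand)) keep <- keep & !is.na(recs$hand) & recs$hand %in% hand
  if (!is.null(categorization)) keep <- keep & recs$categorization %in% categorization
  out <- recs[keep, , drop = FALSE]
  out[order(out$patient_id, out$date, session_rank(out$session_kind),
            out$created_at), , drop = FALSE]
}

#' Write / read a journal file
#'
#' The on-disk journal is newline-delimited JSON, one record per line, in
#' append order; timestamps are ISO-8601 UTC. Reading a journal file and
#' appending its records into a fresh store reconstructs the original
#' exactly, which is what makes crash recovery a pure replay.
#'
#' @param store An `ema_store`.
#' @param path File path.
#' @return `write_journal()` returns `path` invisibly; `read_journal()`
#'   returns an `ema_journal`.
#' @export
write_journal <- function(store, path) {
  lines <- vapply(store$records, function(r) {
    r$created_at <- format_iso8601(r$created_at, tz = "UTC")
    if (!is.null(r$date)) r$date <- format(r$date)
    jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA, null = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_journal
#' @export
read_journal <- function(path) {
  store <- ema_journal()
  for (line in readLines(path)) {
    r <- jsonlite::fromJSON(line, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
    r$created_at <- parse_iso8601(r$created_at)
    if (!is.null(r$date)) r$date <- as.Date(r$date)
    if (!is.null(r$payload)) r$payload <- restore_payload(r$payload, r$record_type)
    append_record(store, r)
  }
  store
}

# Payloads survive JSON round-trips as nested lists; coerce the tabular
# ones back to the in-memory representation.
restore_payload <- function(payload, record_type) {
  rebuild <- function(rows) {
    tibble::as_tibble(
      do.call(rbind.data.frame, c(rows, stringsAsFactors = FALSE)))
  }
  if (record_type %in% c("scales", "sleep_diary") && !is.null(payload$answers)) {
    payload$answers <- rebuild(payload$answers)
  }
  if (record_type == "fit_test" && !is.null(payload$scores)) {
    # one-row score tables serialize as a named list of scalars
    payload$scores <- if (is.null(names(payload$scores))) {
      rebuild(payload$scores)
    } else {
      tibble::as_tibble(payload$scores)
    }
  }
  payload
}

# Column layout per record type for portal-style CSV export.
export_columns <- function(record_type) {
  switch(record_type,
    fit_test = c("patient_id", "date", "session_kind", "hand",
                 "kinesia_score", "akinesia_time", "incoordination_score",
                 "dysmetria_score", "categorization", "record_id", "created_at"),
    scales = ,
    sleep_diary = c("patient_id", "date", "session_kind", "question_id",
                    "value", "categorization", "record_id", "created_at"),
    anchor = c("patient_id", "date", "kind", "at", "categorization",
               "record_id", "created_at"),
    interaction = c("patient_id", "date", "session_kind", "hits", "touches",
                    "categorization", "record_id", "created_at"),
    stop("no CSV export defined for record_type '", record_type, "'",
         call. = FALSE)
  )
}

# Flatten records of one type into the export table.
flatten_records <- function(recs) {
  type <- unique(recs$record_type)
  rows <- purrr::pmap(recs, function(...) {
    r <- list(...)
    p <- r$payload
    base <- tibble::tibble(
      patient_id = r$patient_id, date = format(r$date),
      session_kind = r$session_kind, categorization = r$categorization,
      record_id = r$record_id,
      created_at = format_iso8601(r$created_at, tz = "UTC")
    )
    switch(type,
      fit_test = dplyr::bind_cols(
        base,
        tibble::tibble(hand = r$hand,
                       kinesia_score = p$scores$kinesia_score,
                       akinesia_time = p$scores$akinesia_time,
                       incoordination_score = p$scores$incoordination_score,
                       dysmetria_score = p$scores$dysmetria_score)
      ),
      scales = ,
      sleep_diary = dplyr::bind_cols(
        base[rep(1, nrow(p$answers)), ],
        tibble::tibble(question_id = p$answers$question_id,
                       value = as.character(p$answers$value))
      ),
      anchor = dplyr::bind_cols(
        base, tibble::tibble(kind = p$kind, at = p$at)
      ),
      interaction = dplyr::bind_cols(
        base, tibble::tibble(hits = p$hits, touches = p$touches)
      )
    )
  })
  dplyr::bind_rows(rows)[, export_columns(type)]
}

#' Export records to CSV
#'
#' RFC-4180-style CSV (comma separated, double-quote escaping, UTF-8, a
#' header row) with a stable column order per record type and ISO-8601
#' timestamps. Records must be homogeneous in `record_type`. The export
#' round-trips: reading the file back and re-exporting it is
#' byte-identical.
#'
#' @param records Record tibble (e.g. from [filter_records()]), all of one
#'   `record_type`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
export_records_csv <- function(records, path) {
  records <- tibble::as_tibble(records)
  if ("payload" %in% names(records)) {
    types <- unique(records$record_type)
    if (length(types) != 1) {
      stop("records must be homogeneous in record_type; got: ",
           paste(types, collapse = ", "), call. = FALSE)
    }
    records <- flatten_records(records)
  }
  readr::write_csv(records, path, progress = FALSE)
  invisible(path)
}

#' @rdname export_records_csv
#' @param col_types Passed to [readr::read_csv()] (defaults keep every
#'   column as written).
#' @export
read_records_csv <- function(path, col_types = readr::cols(.default = "c")) {
  readr::read_csv(path, col_types = col_types, progress = FALSE)
}

#' @export
print.ema_store <- function(x, ...) {
  cat("<ema_", x$role, "> ", length(x$records), " records (",
      sum(x$synced), " synced)\n", sep = "")
  invisible(x)
}
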