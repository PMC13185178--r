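#' @section Data model:
#' A *portfolio* is a named list of study frames. A *study frame* holds the
#' participant table (one row per participant with the visit count used as
#' exposure denominator and the cumulative PD count) and the narrative
#' table (one row per recorded deviation narrative) for one study.
#' @name core-io
NULL

participant_cols <- c("study_id", "site_id", "country", "participant_id",
                      "n_visits", "n_pds")
deviation_cols <- c("study_id", "site_id", "country", "participant_id",
                    "n_visits", "narrative")
narrative_cols <- c("study_id", "site_id", "country", "participant_id",
                    "narrative_id", "narrative", "topic_label",
                    "category_label")

#' Construct a study frame
#'
#' @param study_id single study identifier.
#' @param participants tibble with columns `study_id`, `site_id`, `country`,
#'   `participant_id`, `n_visits` (integer, >= 1), `n_pds` (integer, >= 0).
#' @param narratives optional tibble of deviation narratives with columns
#'   `study_id`, `site_id`, `country`, `participant_id`, `narrative_id`,
#'   `narrative` and optional `topic_label`, `category_label`. Every
#'   narrative must belong to a listed participant.
#' @return An object of class `study_frame`: a list with elements
#'   `study_id`, `participants`, `narratives` and `site_index` (a mapping
#'   of site id to participant row indices).
#' @export
study_frame <- function(study_id, participants, narratives = NULL) {
  participants <- as_tibble(participants)
  stopifnot(all(participant_cols %in% names(participants)))
  if (nrow(participants) == 0L) abort("a study frame needs at least one participant")
  if (length(unique(participants$site_id)) < 1L) abort("a study frame needs at least one site")
  check_participant_invariants(participants)
  if (is.null(narratives)) {
    narratives <- empty_narratives()
  } else {
    narratives <- as_tibble(narratives)
    for (col in c("topic_label", "category_label")) {
      if (!col %in% names(narratives)) narratives[[col]] <- NA_character_
    }
    stopifnot(all(narrative_cols %in% names(narratives)))
    if (nrow(narratives) > 0L) {
      key_p <- paste(participants$site_id, participants$participant_id, sep = "\r")
      key_n <- paste(narratives$site_id, narratives$participant_id, sep = "\r")
      if (!all(key_n %in% key_p)) {
        abort("narratives refer to (site_id, participant_id) pairs absent from the participant table")
      }
      if (any(!nonblank(narratives$narrative))) {
        abort("narrative text must be non-empty")
      }
    }
  }
  structure(
    list(
      study_id = as.character(study_id),
      participants = participants,
      narratives = narratives,
      site_index = split(seq_len(nrow(participants)), participants$site_id)
    ),
    class = "study_frame"
  )
}

empty_narratives <- function() {
  tibble(study_id = character(), site_id = character(), country = character(),
         participant_id = character(), narrative_id = character(),
         narrative = character(), topic_label = character(),
         category_label = character())
}

check_participant_invariants <- function(participants) {
  if (any(participants$n_visits < 1L)) abort("n_visits must be >= 1")
  if (any(participants$n_pds < 0L)) abort("n_pds must be >= 0")
  key <- paste(participants$study_id, participants$participant_id, sep = "\r")
  if (anyDuplicated(key)) abort("(study_id, participant_id) must be unique")
  invisible(participants)
}

#' Assemble a portfolio from participant and narrative tables
#'
#' Splits the tables by `study_id` into one [study_frame()] per study.
#' Row order of the inputs never affects the result: frames are keyed and
#' ordered by study id, and tables within a frame are sorted by site and
#' participant id.
#'
#' @param participants participant-grain tibble (see [study_frame()]).
#' @param narratives optional narrative tibble.
#' @return A named list of `study_frame` objects with class `pd_portfolio`.
#' @export
as_portfolio <- function(participants, narratives = NULL) {
  participants <- as_tibble(participants)
  stopifnot(all(participant_cols %in% names(participants)))
  participants <- arrange(participants, .data$study_id, .data$site_id,
                          .data$participant_id)
  if (!is.null(narratives) && nrow(as_tibble(narratives)) > 0L) {
    narratives <- arrange(as_tibble(narratives), .data$study_id,
                          .data$site_id, .data$participant_id,
                          .data$narrative_id)
    nsplit <- split(narratives, narratives$study_id)
  } else {
    nsplit <- list()
  }
  ids <- sort(unique(participants$study_id))
  frames <- lapply(ids, function(id) {
    study_frame(id,
                participants[participants$study_id == id, , drop = FALSE],
                nsplit[[id]])
  })
  names(frames) <- ids
  structure(frames, class = "pd_portfolio")
}

#' @export
print.pd_portfolio <- function(x, ...) {
  np <- sum(vapply(x, function(s) nrow(s$participants), 0L))
  nn <- sum(vapply(x, function(s) nrow(s$narratives), 0L))
  cat(sprintf("<pd_portfolio> %d stud%s, %d participants, %d narratives\n",
              length(x), if (length(x) == 1) "y" else "ies", np, nn))
  invisible(x)
}

#' @export
print.study_frame <- function(x, ...) {
  cat(sprintf("<study_frame> %s: %d sites, %d participants, %d narratives\n",
              x$study_id, length(x$site_index), nrow(x$participants),
              nrow(x$narratives)))
  invisible(x)
}

#' Bind the participant tables of a portfolio into one tibble
#' @param portfolio a `pd_portfolio`.
#' @return A tibble of all participant rows.
#' @export
portfolio_participants <- function(portfolio) {
  bind_rows(lapply(portfolio, function(s) s$participants))
}

#' Bind the narrative tables of a portfolio into one tibble
#' @param portfolio a `pd_portfolio`.
#' @return A tibble of all narrative rows.
#' @export
portfolio_narratives <- function(portfolio) {
  bind_rows(lapply(portfolio, function(s) s$narratives))
}

detect_delim <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) return(",")
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

#' Read a protocol-deviation portfolio from a delimited text file
#'
#' Accepts two input grains. *Participant grain* has one row per
#' participant with a pre-aggregated deviation count (`n_pds`).
#' *Deviation grain* has one row per recorded deviation carrying its
#' narrative text; the per-participant count is the number of such rows,
#' and a row with a blank narrative declares a participant with zero
#' deviations. Malformed rows are not fatal: they are dropped and reported
#' with their file line numbers in the `rejected` attribute of the result.
#'
#' @param path delimited text file (comma or tab; auto-detected from the
#'   header line unless `delim` is given).
#' @param grain `"participant"` or `"deviation"`.
#' @param schema optional named character vector mapping the canonical
#'   column names (`study_id`, `site_id`, `country`, `participant_id`,
#'   `n_visits`, and `n_pds` or `narrative`) to the names used in the file.
#' @param narratives_path optional companion narrative file (participant
#'   grain only) with columns `study_id`, `site_id`, `country`,
#'   `participant_id`, `narrative` and optional `topic_label`,
#'   `category_label`.
#' @param delim field delimiter override.
#' @return A `pd_portfolio` with attribute `rejected`: a tibble of
#'   `(line, reason)` for every dropped input row.
#' @export
read_portfolio <- function(path, grain = c("participant", "deviation"),
                           schema = NULL, narratives_path = NULL,
                           delim = NULL) {
  grain <- match.arg(grain)
  raw <- read_raw_table(path, delim)
  required <- if (grain == "participant") participant_cols else deviation_cols
  raw <- apply_schema(raw, schema, required)

  if (grain == "participant") {
    parsed <- parse_participant_rows(raw)
    participants <- parsed$rows
    rejected <- parsed$rejected
    narratives <- NULL
    if (!is.null(narratives_path)) {
      nr <- read_raw_table(narratives_path, delim)
      nr <- apply_schema(nr, schema,
                         c("study_id", "site_id", "country",
                           "participant_id", "narrative"))
      narratives <- normalize_narratives(nr)
    }
  } else {
    parsed <- parse_deviation_rows(raw)
    participants <- parsed$rows
    rejected <- parsed$rejected
    narratives <- parsed$narratives
  }

  if (nrow(participants) == 0L) {
    abort("no valid participant rows: empty portfolio", class = "pdsentinel_empty_portfolio")
  }

  # orphan narratives are logged, not fatal
  if (!is.null(narratives) && nrow(narratives) > 0L) {
    key_p <- paste(participants$study_id, participants$site_id,
                   participants$participant_id, sep = "\r")
    key_n <- paste(narratives$study_id, narratives$site_id,
                   narratives$participant_id, sep = "\r")
    orphan <- !(key_n %in% key_p)
    if (any(orphan)) {
      rejected <- bind_rows(rejected, tibble(
        line = NA_integer_,
        reason = sprintf("narrative %s refers to unknown participant %s",
                         narratives$narrative_id[orphan],
                         narratives$participant_id[orphan])
      ))
      narratives <- narratives[!orphan, , drop = FALSE]
    }
  }

  out <- as_portfolio(participants, narratives)
  attr(out, "rejected") <- rejected
  out
}

read_raw_table <- function(path, delim = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (file.size(path) == 0L) {
    abort("input file is empty: empty portfolio", class = "pdsentinel_empty_portfolio")
  }
  delim <- delim %||% detect_delim(path)
  raw <- readr::read_delim(path, delim = delim,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE, show_col_types = FALSE,
                           trim_ws = TRUE)
  if (nrow(raw) == 0L) {
    abort("input file has a header but no data rows: empty portfolio",
          class = "pdsentinel_empty_portfolio")
  }
  raw
}

apply_schema <- function(raw, schema, required) {
  if (!is.null(schema)) {
    stopifnot(!is.null(names(schema)))
    for (canon in names(schema)) {
      actual <- schema[[canon]]
      if (actual %in% names(raw)) names(raw)[names(raw) == actual] <- canon
    }
  }
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    abort(sprintf("schema error: missing required column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "pdsentinel_schema_error")
  }
  raw
}

is_int_string <- function(x) !is.na(x) & grepl("^-?[0-9]+$", x)

nonblank <- function(x) !is.na(x) & nzchar(trimws(x))

parse_participant_rows <- function(raw) {
  line <- seq_len(nrow(raw)) + 1L  # header is line 1
  reasons <- character(nrow(raw))
  id_ok <- nonblank(raw$study_id) & nonblank(raw$site_id) & nonblank(raw$participant_id)
  reasons[!id_ok] <- "missing identifier"
  v_ok <- is_int_string(raw$n_visits)
  reasons[id_ok & !v_ok] <- "n_visits is not an integer"
  p_ok <- is_int_string(raw$n_pds)
  reasons[id_ok & v_ok & !p_ok] <- "n_pds is not an integer"
  ok <- id_ok & v_ok & p_ok
  nv <- suppressWarnings(as.integer(raw$n_visits))
  np <- suppressWarnings(as.integer(raw$n_pds))
  bad_v <- ok & nv < 1L
  reasons[bad_v] <- "n_visits < 1"
  bad_p <- ok & !bad_v & np < 0L
  reasons[bad_p] <- "n_pds < 0"
  ok <- ok & !bad_v & !bad_p
  key <- paste(raw$study_id, raw$participant_id, sep = "\r")
  dup <- ok & duplicated(key)
  reasons[dup] <- "duplicate (study_id, participant_id)"
  ok <- ok & !dup
  rows <- tibble(
    study_id = raw$study_id[ok], site_id = raw$site_id[ok],
    country = raw$country[ok], participant_id = raw$participant_id[ok],
    n_visits = nv[ok], n_pds = np[ok]
  )
  list(rows = rows,
       rejected = tibble(line = line[!ok], reason = reasons[!ok]))
}

parse_deviation_rows <- function(raw) {
  line <- seq_len(nrow(raw)) + 1L
  reasons <- character(nrow(raw))
  id_ok <- nonblank(raw$study_id) & nonblank(raw$site_id) & nonblank(raw$participant_id)
  reasons[!id_ok] <- "missing identifier"
  v_ok <- is_int_string(raw$n_visits)
  reasons[id_ok & !v_ok] <- "n_visits is not an integer"
  ok <- id_ok & v_ok
  nv <- suppressWarnings(as.integer(raw$n_visits))
  bad_v <- ok & nv < 1L
  reasons[bad_v] <- "n_visits < 1"
  ok <- ok & !bad_v
  rejected <- tibble(line = line[!ok], reason = reasons[!ok])
  raw <- raw[ok, , drop = FALSE]
  nv <- nv[ok]

  key <- paste(raw$study_id, raw$site_id, raw$participant_id, sep = "\r")
  # a participant's visit count must be consistent across their rows
  vtab <- tapply(nv, key, function(v) length(unique(v)))
  inconsistent <- names(vtab)[vtab > 1L]
  if (length(inconsistent)) {
    drop <- key %in% inconsistent
    rejected <- bind_rows(rejected, tibble(
      line = line[ok][drop], reason = "inconsistent n_visits for participant"))
    raw <- raw[!drop, , drop = FALSE]
    nv <- nv[!drop]
    key <- key[!drop]
  }

  has_narr <- nonblank(raw$narrative)
  counts <- tapply(has_narr, key, sum)
  first <- !duplicated(key)
  participants <- tibble(
    study_id = raw$study_id[first], site_id = raw$site_id[first],
    country = raw$country[first], participant_id = raw$participant_id[first],
    n_visits = nv[first],
    n_pds = as.integer(counts[key[first]])
  )
  narr_rows <- raw[has_narr, , drop = FALSE]
  narratives <- normalize_narratives(narr_rows)
  list(rows = participants, narratives = narratives, rejected = rejected)
}

normalize_narratives <- function(nr) {
  nr <- as_tibble(nr)
  keep <- nonblank(nr$narrative %||% character())
  nr <- nr[keep, , drop = FALSE]
  tibble(
    study_id = nr$study_id, site_id = nr$site_id, country = nr$country,
    participant_id = nr$participant_id,
    narrative_id = if ("narrative_id" %in% names(nr) && any(nzchar(nr$narrative_id %||% "")))
      nr$narrative_id else sprintf("N%06d", seq_len(nrow(nr))),
    narrative = nr$narrative,
    topic_label = if ("topic_label" %in% names(nr)) nr$topic_label else NA_character_,
    category_label = if ("category_label" %in% names(nr)) nr$category_label else NA_character_
  )
}

#' Write an analysis result to disk
#'
#' Tabular results (site results, distributions, assignments) round-trip
#' through delimited text with full double precision; structured results
#' (validation reports, risk profiles, taxonomies) serialise to JSON.
#'
#' @param x a tibble/data frame, or an object with its own serialisation
#'   (`validation_report`, `risk_profiles`, `pd_taxonomy`).
#' @param path output path; format inferred from the extension when
#'   `format = "auto"` (".json" means JSON, anything else delimited).
#' @param format `"auto"`, `"delimited"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, format = c("auto", "delimited", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "delimited"
  }
  if (format == "json") {
    obj <- if (inherits(x, c("validation_report", "pd_taxonomy", "risk_profiles")))
      unclass(x) else x
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null", pretty = TRUE)
  } else {
    if (!is.data.frame(x)) abort("delimited output requires a data frame")
    readr::write_csv(as_tibble(x), path, progress = FALSE)
  }
  invisible(path)
}

#' Read back a delimited report written by [write_report()]
#' @param path a delimited file.
#' @return A tibble; doubles are recovered to full precision.
#' @export
read_report <- function(path) {
  readr::read_csv(path, progress = FALSE, show_col_types = FALSE)
}
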