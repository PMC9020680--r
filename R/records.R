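PROCEDURE_TYPES <- c("PLN", "LAPAROSCOPIC")
INFECTION_LEVELS <- c("INFECTED", "UNINFECTED")
DRUG_CLASSES <- c("ANTIBIOTIC", "NSAID", "OPIOID", "OTHER")
EVENT_KINDS <- c("PRESCRIPTION", "NOTE")
SPECIES_LEVELS <- c("RHESUS", "CYNOMOLGUS")

#' Default drug-name to drug-class dictionary
#'
#' Maps lowercase drug names to the four drug classes used by the
#' complication flagging rules. Unknown names fall back to `"OTHER"`.
#' The defaults cover the perioperative drugs of a typical primate surgical
#' service: first-generation cephalosporins used for antimicrobial
#' prophylaxis, common NSAIDs, and buprenorphine formulations.
#'
#' @param extra named character vector of additional `name = class` entries;
#'   classes must be one of `ANTIBIOTIC`, `NSAID`, `OPIOID`, `OTHER`.
#'   Entries override defaults of the same name.
#' @return named character vector (names are lowercase drug names).
#' @export
#' @examples
#' drug_class_dictionary()[c("cefazolin", "meloxicam")]
drug_class_dictionary <- function(extra = NULL) {
  dict <- c(
    cefazolin = "ANTIBIOTIC",
    cephalexin = "ANTIBIOTIC",
    meloxicam = "NSAID",
    carprofen = "NSAID",
    ibuprofen = "NSAID",
    ketoprofen = "NSAID",
    buprenorphine = "OPIOID",
    "buprenorphine sr" = "OPIOID",
    hydromorphone = "OPIOID",
    fentanyl = "OPIOID"
  )
  if (!is.null(extra)) {
    if (is.null(names(extra)) || any(!nzchar(names(extra))))
      stop("'extra' must be a named character vector", call. = FALSE)
    bad <- setdiff(unique(extra), DRUG_CLASSES)
    if (length(bad))
      stop("unknown drug class(es): ", paste(bad, collapse = ", "),
           call. = FALSE)
    dict[tolower(names(extra))] <- unname(extra)
  }
  dict
}

#' Classify drug names into flagging classes
#'
#' @param name character vector of drug names (case-insensitive).
#' @param dictionary dictionary from [drug_class_dictionary()].
#' @return character vector of drug classes; names absent from the
#'   dictionary map to `"OTHER"`.
#' @export
classify_drug <- function(name, dictionary = drug_class_dictionary()) {
  cls <- unname(dictionary[tolower(trimws(name))])
  cls[is.na(cls)] <- "OTHER"
  cls
}

stop_rows <- function(what, rows, file = NULL) {
  loc <- if (is.null(file)) "" else paste0(" in '", file, "'")
  stop(what, loc, " (row", if (length(rows) > 1) "s", " ",
       paste(utils::head(rows, 10), collapse = ", "),
       if (length(rows) > 10) ", ...", ")", call. = FALSE)
}

require_columns <- function(df, cols, file) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("missing required column(s) in '", file, "': ",
         paste(missing, collapse = ", "), call. = FALSE)
}

parse_enum <- function(x, levels, field, file) {
  up <- toupper(trimws(x))
  bad <- which(!up %in% levels)
  if (length(bad))
    stop_rows(sprintf("invalid %s value(s) %s", field,
                      paste(sQuote(unique(x[bad])), collapse = ", ")),
              bad, file)
  up
}

parse_iso_date <- function(x, field, file) {
  d <- as.Date(trimws(x), format = "%Y-%m-%d")
  bad <- which(is.na(d) | !grepl("^\\d{4}-\\d{2}-\\d{2}$", trimws(x)))
  if (length(bad))
    stop_rows(sprintf("unparseable ISO-8601 %s", field), bad, file)
  d
}

parse_flag <- function(x, field, file) {
  map <- c("TRUE" = TRUE, "FALSE" = FALSE, "1" = TRUE, "0" = FALSE,
           "YES" = TRUE, "NO" = FALSE, "T" = TRUE, "F" = FALSE)
  v <- map[toupper(trimws(x))]
  bad <- which(is.na(v))
  if (length(bad))
    stop_rows(sprintf("invalid logical %s", field), bad, file)
  unname(v)
}

read_delim_file <- function(path, delim) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  utils::read.table(path, header = TRUE, sep = delim, quote = "\"",
                    stringsAsFactors = FALSE, colClasses = "character",
                    comment.char = "", fill = FALSE,
                    fileEncoding = "UTF-8")
}

#' Read surgical procedure records
#'
#' Reads a delimited file with one row per surgical procedure and validates
#' every field. Enum fields are case-folded to upper case; dates must be
#' ISO-8601. Validation failures name the offending rows.
#'
#' Expected columns: `procedure_id`, `animal_id`, `surgery_date`,
#' `procedure_type` (`PLN` or `LAPAROSCOPIC`), `infection_status`
#' (`INFECTED` or `UNINFECTED`), `prophylaxis` (logical), and
#' `observation_days` (non-negative integer: post-operative observation
#' length).
#'
#' @param path file path.
#' @param delim field delimiter (default comma).
#' @return data.frame of validated procedures, one row per procedure, with
#'   typed columns and `surgery_date` as `Date`.
#' @export
read_procedures <- function(path, delim = ",") {
  df <- read_delim_file(path, delim)
  cols <- c("procedure_id", "animal_id", "surgery_date", "procedure_type",
            "infection_status", "prophylaxis", "observation_days")
  require_columns(df, cols, path)

  out <- data.frame(
    procedure_id = trimws(df$procedure_id),
    animal_id = trimws(df$animal_id),
    surgery_date = parse_iso_date(df$surgery_date, "surgery_date", path),
    procedure_type = parse_enum(df$procedure_type, PROCEDURE_TYPES,
                                "procedure_type", path),
    infection_status = parse_enum(df$infection_status, INFECTION_LEVELS,
                                  "infection_status", path),
    prophylaxis = parse_flag(df$prophylaxis, "prophylaxis", path),
    observation_days = suppressWarnings(
      as.integer(trimws(df$observation_days))),
    stringsAsFactors = FALSE
  )

  bad <- which(is.na(out$observation_days) | out$observation_days < 0)
  if (length(bad))
    stop_rows("observation_days must be a non-negative integer", bad, path)
  dup <- which(duplicated(out$procedure_id))
  if (length(dup))
    stop_rows("duplicate procedure_id", dup, path)
  if (any(!nzchar(out$procedure_id)))
    stop_rows("empty procedure_id", which(!nzchar(out$procedure_id)), path)
  out
}

#' Read prescription events
#'
#' Reads a delimited file of drug prescriptions (one row per prescription).
#' Expected columns: `animal_id`, `event_date`, `drug_name`, `drug_class`,
#' `indication`. A blank `drug_class` is filled in from the drug dictionary;
#' a stated class must be one of `ANTIBIOTIC`, `NSAID`, `OPIOID`, `OTHER`.
#'
#' @inheritParams read_procedures
#' @param dictionary drug dictionary used to fill in missing classes.
#' @return data.frame of care events with `kind = "PRESCRIPTION"`.
#' @export
read_prescriptions <- function(path, delim = ",",
                               dictionary = drug_class_dictionary()) {
  df <- read_delim_file(path, delim)
  require_columns(df, c("animal_id", "event_date", "drug_name",
                        "drug_class", "indication"), path)
  cls <- trimws(df$drug_class)
  blank <- !nzchar(cls)
  cls[blank] <- classify_drug(df$drug_name[blank], dictionary)
  cls[!blank] <- parse_enum(cls[!blank], DRUG_CLASSES, "drug_class", path)
  data.frame(
    animal_id = trimws(df$animal_id),
    event_date = parse_iso_date(df$event_date, "event_date", path),
    kind = "PRESCRIPTION",
    drug_class = cls,
    drug_name = trimws(df$drug_name),
    note_text = "",
    indication = trimws(df$indication),
    stringsAsFactors = FALSE
  )
}

#' Read observation notes
#'
#' Expected columns: `animal_id`, `event_date`, `note_text` (non-empty
#' free text).
#'
#' @inheritParams read_procedures
#' @return data.frame of care events with `kind = "NOTE"`.
#' @export
read_notes <- function(path, delim = ",") {
  df <- read_delim_file(path, delim)
  require_columns(df, c("animal_id", "event_date", "note_text"), path)
  txt <- trimws(df$note_text)
  if (any(!nzchar(txt)))
    stop_rows("empty note_text", which(!nzchar(txt)), path)
  data.frame(
    animal_id = trimws(df$animal_id),
    event_date = parse_iso_date(df$event_date, "event_date", path),
    kind = "NOTE",
    drug_class = NA_character_,
    drug_name = NA_character_,
    note_text = txt,
    indication = NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Read animal demographics
#'
#' Expected columns: `animal_id`, `species` (`RHESUS` or `CYNOMOLGUS`),
#' `sex` (`M`/`F`), `age_years`, `bcs` (body condition score, 1-5 scale).
#'
#' @inheritParams read_procedures
#' @param age_range allowed age range in years.
#' @return data.frame of per-animal demographics.
#' @export
read_demographics <- function(path, delim = ",", age_range = c(0, 40)) {
  df <- read_delim_file(path, delim)
  require_columns(df, c("animal_id", "species", "sex", "age_years", "bcs"),
                  path)
  out <- data.frame(
    animal_id = trimws(df$animal_id),
    species = parse_enum(df$species, SPECIES_LEVELS, "species", path),
    sex = parse_enum(df$sex, c("M", "F"), "sex", path),
    age_years = suppressWarnings(as.numeric(df$age_years)),
    bcs = suppressWarnings(as.numeric(df$bcs)),
    stringsAsFactors = FALSE
  )
  bad <- which(is.na(out$age_years) | out$age_years < age_range[1] |
                 out$age_years > age_range[2])
  if (length(bad)) stop_rows("age_years out of plausible range", bad, path)
  bad <- which(is.na(out$bcs) | out$bcs < 1 | out$bcs > 5)
  if (length(bad)) stop_rows("bcs must lie in [1, 5]", bad, path)
  dup <- which(duplicated(out$animal_id))
  if (length(dup)) stop_rows("duplicate animal_id", dup, path)
  out
}

#' Read manual adjudication overrides
#'
#' Overrides model a curated records review: an entry is authoritative for
#' its procedure. Expected columns: `procedure_id`, `complication`
#' (0/1), `reason`.
#'
#' @inheritParams read_procedures
#' @return data.frame with logical `complication`.
#' @export
read_overrides <- function(path, delim = ",") {
  df <- read_delim_file(path, delim)
  require_columns(df, c("procedure_id", "complication", "reason"), path)
  data.frame(
    procedure_id = trimws(df$procedure_id),
    complication = parse_flag(df$complication, "complication", path),
    reason = trimws(df$reason),
    stringsAsFactors = FALSE
  )
}

#' Write a records bundle to delimited files
#'
#' Writes `procedures.csv`, `prescriptions.csv`, `notes.csv` and, when
#' present, `demographics.csv`, `overrides.csv` and `ground_truth.csv`
#' under `dir` using the same schemas the readers expect, so that a
#' write/read cycle round-trips field for field.
#'
#' @param bundle named list of data.frames as produced by
#'   [generate_cohort()] or assembled from the readers.
#' @param dir output directory (created if absent).
#' @param delim field delimiter.
#' @return `dir`, invisibly.
#' @export
write_records <- function(bundle, dir, delim = ",") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  put <- function(df, file, cols) {
    df <- df[, cols, drop = FALSE]
    for (ch in names(df)[vapply(df, inherits, TRUE, "Date")])
      df[[ch]] <- format(df[[ch]], "%Y-%m-%d")
    utils::write.table(df, file.path(dir, file), sep = delim,
                       row.names = FALSE, quote = TRUE,
                       fileEncoding = "UTF-8")
  }
  put(bundle$procedures, "procedures.csv",
      c("procedure_id", "animal_id", "surgery_date", "procedure_type",
        "infection_status", "prophylaxis", "observation_days"))
  pres <- bundle$prescriptions
  if (is.null(pres)) {
    ev <- bundle$events
    pres <- ev[ev$kind == "PRESCRIPTION", , drop = FALSE]
  }
  put(pres, "prescriptions.csv",
      c("animal_id", "event_date", "drug_name", "drug_class", "indication"))
  notes <- bundle$notes
  if (is.null(notes)) {
    ev <- bundle$events
    notes <- ev[ev$kind == "NOTE", , drop = FALSE]
  }
  put(notes, "notes.csv", c("animal_id", "event_date", "note_text"))
  if (!is.null(bundle$demographics))
    put(bundle$demographics, "demographics.csv",
        c("animal_id", "species", "sex", "age_years", "bcs"))
  if (!is.null(bundle$overrides))
    put(bundle$overrides, "overrides.csv",
        c("procedure_id", "complication", "reason"))
  if (!is.null(bundle$ground_truth))
    put(bundle$ground_truth, "ground_truth.csv",
        c("procedure_id", "complication", "planted_evidence"))
  invisible(dir)
}

#' Read a records bundle from a directory
#'
#' Inverse of [write_records()]: reads whichever of the standard files are
#' present under `dir`.
#'
#' @inheritParams write_records
#' @param dictionary drug dictionary passed to [read_prescriptions()].
#' @return named list of data.frames (`procedures`, `prescriptions`,
#'   `notes`, plus `demographics`/`overrides` when present, and a combined
#'   `events` frame).
#' @export
read_records <- function(dir, delim = ",",
                         dictionary = drug_class_dictionary()) {
  bundle <- list(
    procedures = read_procedures(file.path(dir, "procedures.csv"), delim),
    prescriptions = read_prescriptions(file.path(dir, "prescriptions.csv"),
                                       delim, dictionary),
    notes = read_notes(file.path(dir, "notes.csv"), delim)
  )
  demo <- file.path(dir, "demographics.csv")
  if (file.exists(demo)) bundle$demographics <- read_demographics(demo, delim)
  ov <- file.path(dir, "overrides.csv")
  if (file.exists(ov)) bundle$overrides <- read_overrides(ov, delim)
  bundle$events <- rbind(bundle$prescriptions, bundle$notes)
  bundle
}

#' Link care events to procedures by post-operative day window
#'
#' Attaches each care event (prescription or note) to every procedure of
#' the same animal whose post-operative window contains the event. The
#' surgery day is day 0; an event at calendar-day difference `d` attaches
#' when `window[1] <= d <= window[2]`. The default window is days 1 through
#' 8 after surgery, the screening window of the flagging rules. An event
#' may attach to several procedures of one animal when windows overlap
#' (e.g. two biopsies under one anesthetic event).
#'
#' @param procedures validated procedures data.frame.
#' @param events care-event data.frame ([read_prescriptions()] /
#'   [read_notes()] rows, possibly mixed).
#' @param window integer pair `(lo, hi)`, `1 <= lo <= hi`.
#' @return data.frame with one row per (procedure, event) attachment:
#'   the procedure_id, all event columns, and `day_offset`. Procedures with
#'   no events simply contribute no rows.
#' @export
link_events <- function(procedures, events, window = c(1L, 8L)) {
  stopifnot(length(window) == 2)
  window <- as.integer(window)
  if (is.na(window[1]) || window[1] < 1 || window[1] > window[2])
    stop("window must satisfy 1 <= lo <= hi", call. = FALSE)

  empty <- data.frame(
    procedure_id = character(), animal_id = character(),
    event_date = as.Date(character()), kind = character(),
    drug_class = character(), drug_name = character(),
    note_text = character(), indication = character(),
    day_offset = integer(), stringsAsFactors = FALSE)
  if (nrow(procedures) == 0 || is.null(events) || nrow(events) == 0)
    return(empty)

  proc <- procedures[, c("procedure_id", "animal_id", "surgery_date")]
  merged <- merge(proc, events, by = "animal_id")
  if (nrow(merged) == 0) return(empty)
  merged$day_offset <- as.integer(merged$event_date - merged$surgery_date)
  keep <- merged$day_offset >= window[1] & merged$day_offset <= window[2]
  merged <- merged[keep, , drop = FALSE]
  merged <- merged[order(merged$procedure_id, merged$day_offset,
                         merged$kind, merged$drug_name, merged$note_text), ]
  rownames(merged) <- NULL
  merged[, c("procedure_id", "animal_id", "event_date", "kind",
             "drug_class", "drug_name", "note_text", "indication",
             "day_offset")]
}
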