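#' Complication flagging criteria
#'
#' Screening rules that mark a procedure as a *potential* complication:
#' any prescription of a flagged drug class in the post-operative window,
#' or a post-operative observation period at or beyond the extended
#' threshold. Defaults encode the screening used on the macaque biopsy
#' cohort: drugs in days 1 through 8 after surgery, and observation of 9 or
#' more days against a standard duration of 7-8 days.
#'
#' @param window integer pair of post-operative days (closed interval,
#'   surgery day = day 0).
#' @param drug_classes drug classes whose prescription raises a flag.
#' @param extended_observation observation length (days) at or above which
#'   a procedure is flagged regardless of prescriptions.
#' @return object of class `flag_criteria`.
#' @export
flag_criteria <- function(window = c(1L, 8L),
                          drug_classes = c("ANTIBIOTIC", "NSAID", "OPIOID"),
                          extended_observation = 9L) {
  stopifnot(length(window) == 2, window[1] >= 1, window[1] <= window[2])
  drug_classes <- match.arg(drug_classes, DRUG_CLASSES, several.ok = TRUE)
  extended_observation <- as.integer(extended_observation)
  stopifnot(length(extended_observation) == 1, extended_observation >= 0)
  structure(list(window = as.integer(window),
                 drug_classes = drug_classes,
                 extended_observation = extended_observation),
            class = "flag_criteria")
}

#' Adverse-finding keyword lexicon
#'
#' Lowercase phrases whose case-insensitive substring match in a
#' post-operative observation note counts as evidence of a surgical
#' complication during adjudication. The default set covers the findings a
#' clinical records review treats as possible complications: inappetence,
#' inflammation, swelling, bruising, pain, incision discharge, abscess,
#' suture removal, ulceration, and dehiscence.
#'
#' @param terms character vector of lowercase phrases (non-empty).
#' @return character vector of class `keyword_lexicon`.
#' @export
adverse_lexicon <- function(terms = c(
  "inappetence", "inflammation", "swelling", "bruising", "pain",
  "discharge", "abscess", "suture removal", "ulceration", "dehiscence")) {
  terms <- tolower(trimws(terms))
  if (!length(terms) || any(!nzchar(terms)))
    stop("lexicon must be a non-empty set of non-empty phrases",
         call. = FALSE)
  structure(unique(terms), class = "keyword_lexicon")
}

note_matches_lexicon <- function(text, lexicon) {
  if (!length(text)) return(logical(0))
  low <- tolower(text)
  hit <- rep(FALSE, length(low))
  for (term in lexicon)
    hit <- hit | grepl(term, low, fixed = TRUE)
  hit
}

#' Flag procedures for potential post-operative complications
#'
#' Stage one of complication identification. A procedure is flagged when
#' it has at least one linked prescription whose drug class is in
#' `criteria$drug_classes`, or when its observation period meets the
#' extended-observation threshold. Triggers name every satisfied
#' criterion, e.g. `ANTIBIOTIC_DAY_3` or `OBSERVATION_EXTENDED`.
#'
#' @param procedures validated procedures data.frame.
#' @param linked linked events from [link_events()] (already
#'   window-filtered).
#' @param criteria [flag_criteria()] object.
#' @return data.frame with one row per procedure: `procedure_id`,
#'   `flagged`, and `triggers` (list column of character vectors, empty
#'   when not flagged).
#' @export
flag_procedures <- function(procedures, linked,
                            criteria = flag_criteria()) {
  stopifnot(inherits(criteria, "flag_criteria"))
  n <- nrow(procedures)
  triggers <- rep(list(character(0)), n)
  idx <- stats::setNames(seq_len(n), procedures$procedure_id)

  rx <- linked[linked$kind == "PRESCRIPTION" &
                 linked$drug_class %in% criteria$drug_classes, ,
               drop = FALSE]
  if (nrow(rx)) {
    rx <- rx[order(rx$procedure_id, rx$day_offset, rx$drug_class), ]
    tok <- paste0(rx$drug_class, "_DAY_", rx$day_offset)
    by_proc <- split(tok, rx$procedure_id)
    for (pid in names(by_proc))
      triggers[[idx[[pid]]]] <- unique(by_proc[[pid]])
  }

  ext <- which(procedures$observation_days >= criteria$extended_observation)
  for (i in ext)
    triggers[[i]] <- c(triggers[[i]], "OBSERVATION_EXTENDED")

  flagged <- lengths(triggers) > 0
  out <- data.frame(procedure_id = procedures$procedure_id,
                    flagged = flagged, stringsAsFactors = FALSE)
  out$triggers <- triggers
  out
}

#' Adjudicate flagged procedures into complication calls
#'
#' Stage two: confirm or clear each flag, emulating a clinical records
#' review. An override entry for a procedure is authoritative (it models a
#' curated manual review). Otherwise a flagged procedure is a confirmed
#' complication when any of: a treatment-class prescription trigger is
#' present; a linked note matches the adverse-keyword lexicon; or the flag
#' came from extended observation. Unflagged procedures are never
#' complications.
#'
#' @param procedures validated procedures data.frame.
#' @param flags output of [flag_procedures()].
#' @param linked linked events from [link_events()]; only `NOTE` rows are
#'   consulted here.
#' @param lexicon [adverse_lexicon()] object.
#' @param overrides optional data.frame (`procedure_id`, `complication`,
#'   `reason`) from [read_overrides()] or [generate_cohort()].
#' @return data.frame of complication calls: `procedure_id`, `flagged`,
#'   `complication`, `triggers` (list column) and `adjudication_rule`
#'   (one of `NOT_FLAGGED`, `OVERRIDE`, `TREATMENT_TRIGGER`,
#'   `NOTE_KEYWORD`, `OBSERVATION_EXTENDED`, `CLEARED`).
#' @export
adjudicate <- function(procedures, flags, linked,
                       lexicon = adverse_lexicon(), overrides = NULL) {
  stopifnot(identical(procedures$procedure_id, flags$procedure_id))
  if (!is.null(overrides)) {
    unknown <- setdiff(overrides$procedure_id, procedures$procedure_id)
    if (length(unknown))
      stop("override references unknown procedure_id: ",
           paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }

  notes <- linked[linked$kind == "NOTE", , drop = FALSE]
  note_hit_ids <- unique(notes$procedure_id[
    note_matches_lexicon(notes$note_text, lexicon)])
  matched_terms <- function(pid) {
    txt <- tolower(notes$note_text[notes$procedure_id == pid])
    terms <- lexicon[vapply(lexicon, function(tm)
      any(grepl(tm, txt, fixed = TRUE)), TRUE)]
    paste0("NOTE_KEYWORD:", terms)
  }

  ov_idx <- if (is.null(overrides)) character(0) else overrides$procedure_id
  n <- nrow(procedures)
  complication <- logical(n)
  rule <- character(n)
  triggers <- flags$triggers

  for (i in seq_len(n)) {
    pid <- procedures$procedure_id[i]
    if (!flags$flagged[i]) {
      rule[i] <- "NOT_FLAGGED"
      next
    }
    trig <- triggers[[i]]
    if (pid %in% ov_idx) {
      complication[i] <- overrides$complication[match(pid, ov_idx)]
      rule[i] <- "OVERRIDE"
    } else if (any(trig != "OBSERVATION_EXTENDED")) {
      # any drug-class trigger is a treatment prescription
      complication[i] <- TRUE
      rule[i] <- "TREATMENT_TRIGGER"
    } else if (pid %in% note_hit_ids) {
      complication[i] <- TRUE
      rule[i] <- "NOTE_KEYWORD"
      trig <- c(trig, matched_terms(pid))
    } else if ("OBSERVATION_EXTENDED" %in% trig) {
      complication[i] <- TRUE
      rule[i] <- "OBSERVATION_EXTENDED"
    } else {
      rule[i] <- "CLEARED"
    }
    triggers[[i]] <- trig
  }

  out <- data.frame(procedure_id = procedures$procedure_id,
                    flagged = flags$flagged,
                    complication = complication,
                    adjudication_rule = rule,
                    stringsAsFactors = FALSE)
  out$triggers <- triggers
  out[, c("procedure_id", "flagged", "complication", "triggers",
          "adjudication_rule")]
}

#' Flag and adjudicate in one step
#'
#' Convenience wrapper: [link_events()] with the criteria window,
#' [flag_procedures()], then [adjudicate()].
#'
#' @inheritParams adjudicate
#' @param events care-event data.frame (prescriptions and notes).
#' @param criteria [flag_criteria()] object.
#' @return complication-call data.frame, see [adjudicate()].
#' @export
call_complications <- function(procedures, events,
                               criteria = flag_criteria(),
                               lexicon = adverse_lexicon(),
                               overrides = NULL) {
  linked <- link_events(procedures, events, criteria$window)
  flags <- flag_procedures(procedures, linked, criteria)
  adjudicate(procedures, flags, linked, lexicon, overrides)
}

#' Tally complications by stratum
#'
#' Joins complication calls to their procedures and counts complications
#' and procedures per stratum. The complication rate is the number of
#' confirmed complications divided by the number of procedures in the
#' stratum, reported in percent.
#'
#' @param calls complication calls from [adjudicate()].
#' @param procedures validated procedures data.frame.
#' @param by character vector of stratifier column names in `procedures`
#'   (e.g. `c("procedure_type", "prophylaxis")`); empty for a single
#'   overall stratum.
#' @return data.frame with the stratifier columns plus `complications`,
#'   `procedures` and `rate_percent`.
#' @export
tally_complications <- function(calls, procedures,
                                by = c("procedure_type", "prophylaxis")) {
  orphan <- setdiff(calls$procedure_id, procedures$procedure_id)
  if (length(orphan))
    stop("complication call(s) with no matching procedure: ",
         paste(utils::head(orphan, 5), collapse = ", "), call. = FALSE)
  df <- merge(procedures, calls[, c("procedure_id", "complication")],
              by = "procedure_id")
  if (nrow(df) == 0) {
    out <- df[, by, drop = FALSE]
    out$complications <- integer(0)
    out$procedures <- integer(0)
    out$rate_percent <- numeric(0)
    return(out)
  }
  if (length(by) == 0) {
    out <- data.frame(complications = sum(df$complication),
                      procedures = nrow(df))
  } else {
    grp <- df[, by, drop = FALSE]
    agg <- stats::aggregate(df$complication, by = grp,
                            FUN = function(z) c(sum(z), length(z)))
    out <- agg[, by, drop = FALSE]
    out$complications <- as.integer(agg$x[, 1])
    out$procedures <- as.integer(agg$x[, 2])
    ord <- do.call(order, out[, by, drop = FALSE])
    out <- out[ord, , drop = FALSE]
    rownames(out) <- NULL
  }
  out$rate_percent <- 100 * out$complications / out$procedures
  out
}
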