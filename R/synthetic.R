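#' Specify a synthetic surgical cohort
#'
#' Describes a cohort for the synthetic record generator: per-stratum
#' procedure counts and true complication probabilities, the number of
#' animals and how procedures spread over them, demographic marginals,
#' and noise processes that inject care events unrelated to any
#' complication. The defaults reproduce the reference macaque biopsy
#' cohort: its eight strata (procedure type x infection status x
#' prophylaxis) at the published sizes and rates, 1,056 animals for 3,629
#' procedures (mean 3.4 procedures per animal), its species/sex mix and
#' age/BCS ranges, and its 2018-05-01 to 2021-01-19 study window.
#'
#' @param strata data.frame with columns `procedure_type`,
#'   `infection_status`, `prophylaxis`, `n_procedures`, `true_rate`;
#'   defaults to the eight reference strata with rates from the published
#'   cells.
#' @param n_animals number of animals in the cohort.
#' @param mean_procedures target mean procedures per animal; per-animal
#'   loads are geometric-like (1 + geometric) with this mean.
#' @param max_procedures_per_animal feasibility cap per animal.
#' @param demographics list with `species` and `sex` proportion vectors,
#'   `age_range` and `bcs_range`.
#' @param noise list with `unrelated_prescription_rate` (probability that
#'   a complication-free procedure draws an in-window prescription for an
#'   unrelated clinical concern, cleared in the override table) and
#'   `benign_note_rate` (probability of a benign observation note).
#' @param evidence_mix probabilities that a planted complication
#'   materializes as an in-window antibiotic prescription, NSAID
#'   prescription, or extended post-operative observation.
#' @param adverse_note_rate probability that a planted complication also
#'   leaves an adverse-keyword observation note.
#' @param study_window Date pair over which surgery dates are placed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(strata = NULL,
                        n_animals = 1056L,
                        mean_procedures = 3.4,
                        max_procedures_per_animal = 60L,
                        demographics = NULL,
                        noise = list(unrelated_prescription_rate = 0.02,
                                     benign_note_rate = 0.05),
                        evidence_mix = c(ANTIBIOTIC = 1/3, NSAID = 1/3,
                                         EXTENDED = 1/3),
                        adverse_note_rate = 0.3,
                        study_window = NULL) {
  ref <- reference_demographics()
  if (is.null(strata)) {
    cells <- reference_cells()
    g <- cells[cells$role == "group" & cells$infection_status != "ALL", ]
    strata <- data.frame(
      procedure_type = g$procedure_type,
      infection_status = g$infection_status,
      prophylaxis = g$prophylaxis,
      n_procedures = g$n,
      true_rate = g$rate_percent / 100,
      stringsAsFactors = FALSE
    )
  }
  stopifnot(all(c("procedure_type", "infection_status", "prophylaxis",
                  "n_procedures", "true_rate") %in% names(strata)),
            all(strata$true_rate >= 0), all(strata$true_rate <= 1),
            all(strata$n_procedures >= 0))
  if (is.null(demographics))
    demographics <- list(
      species = ref$species / sum(ref$species),
      sex = ref$sex / sum(ref$sex),
      age_range = ref$age_range,
      bcs_range = ref$bcs_range
    )
  if (is.null(study_window)) study_window <- ref$study_window
  study_window <- as.Date(study_window)
  stopifnot(length(study_window) == 2, study_window[1] < study_window[2],
            abs(sum(evidence_mix) - 1) < 1e-8, all(evidence_mix >= 0))
  total <- sum(strata$n_procedures)
  if (total > n_animals * max_procedures_per_animal)
    stop("infeasible cohort: ", total, " procedures exceed ",
         n_animals, " animals x ", max_procedures_per_animal,
         " procedures/animal", call. = FALSE)
  structure(list(strata = strata, n_animals = as.integer(n_animals),
                 mean_procedures = mean_procedures,
                 max_procedures_per_animal =
                   as.integer(max_procedures_per_animal),
                 demographics = demographics, noise = noise,
                 evidence_mix = evidence_mix,
                 adverse_note_rate = adverse_note_rate,
                 study_window = study_window),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort spec: %d procedures in %d strata, %d animals\n",
    sum(x$strata$n_procedures), nrow(x$strata), x$n_animals))
  print(x$strata)
  invisible(x)
}

BENIGN_NOTES <- c(
  "bright, alert and responsive; incision clean and dry",
  "normal appetite, incision intact",
  "active in enclosure, suture line intact",
  "no abnormal findings on cage-side exam"
)

ADVERSE_NOTES <- c(
  "moderate swelling at incision site",
  "serous discharge from incision",
  "evidence of pain on palpation of surgical site",
  "incision dehiscence noted, surgical site abscess suspected",
  "inappetence observed, moderate inflammation at incision"
)

#' Generate a synthetic cohort with known ground truth
#'
#' Materializes a [cohort_spec()] into the record streams the pipeline
#' consumes, with complication status known per procedure. Within each
#' stratum the number of complications is Binomial(`n_procedures`,
#' `true_rate`); each planted complication leaves evidence satisfying at
#' least one flagging criterion (an in-window antibiotic or NSAID
#' prescription with a surgical indication, or extended post-operative
#' observation), per the spec's evidence mix. Noise injects in-window
#' prescriptions for unrelated clinical concerns (cleared in the override
#' table) and benign observation notes into complication-free procedures.
#' Surgery dates of one animal are spaced at least 9 days apart so each
#' care event falls in exactly one procedure's post-operative window.
#' Output is deterministic given `seed`.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed; the global RNG state is restored on exit.
#' @return named list of data.frames: `procedures`, `prescriptions`,
#'   `notes`, `demographics`, `overrides`, `ground_truth`, plus a
#'   combined `events` frame ready for [call_complications()].
#' @export
generate_cohort <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(
      rm(list = ".Random.seed", envir = globalenv())))
  }
  set.seed(seed)

  strata <- spec$strata
  total <- sum(strata$n_procedures)
  width <- max(4, nchar(as.character(spec$n_animals)))
  animal_ids <- sprintf(paste0("A%0", width, "d"), seq_len(spec$n_animals))

  # demographics
  demo <- spec$demographics
  bcs_grid <- seq(demo$bcs_range[1], demo$bcs_range[2], by = 0.5)
  demographics <- data.frame(
    animal_id = animal_ids,
    species = sample(names(demo$species), spec$n_animals, replace = TRUE,
                     prob = demo$species),
    sex = sample(names(demo$sex), spec$n_animals, replace = TRUE,
                 prob = demo$sex),
    age_years = round(runif(spec$n_animals, demo$age_range[1],
                            demo$age_range[2]), 2),
    bcs = sample(bcs_grid, spec$n_animals, replace = TRUE),
    stringsAsFactors = FALSE
  )

  # procedure -> animal allocation with geometric-like per-animal loads
  load <- 1 + stats::rgeom(spec$n_animals, 1 / spec$mean_procedures)
  owner <- sample(animal_ids, total, replace = TRUE, prob = load)

  # surgery dates: per animal, distinct 15-day strides keep post-operative
  # windows disjoint (within-animal gap >= 9 days > window upper bound 8)
  span <- as.integer(spec$study_window[2] - spec$study_window[1])
  strides <- seq(0L, span - 7L, by = 15L)
  date_offset <- integer(total)
  for (aid in unique(owner)) {
    rows <- which(owner == aid)
    if (length(rows) > length(strides))
      stop("animal ", aid, " drew more procedures (", length(rows),
           ") than available surgery slots (", length(strides), ")",
           call. = FALSE)
    base <- sort(sample(strides, length(rows)))
    date_offset[rows] <- base + sample(0:6, length(rows), replace = TRUE)
  }
  surgery_date <- spec$study_window[1] + date_offset

  stratum_of <- rep(seq_len(nrow(strata)), strata$n_procedures)
  procedures <- data.frame(
    procedure_id = sprintf("P%06d", seq_len(total)),
    animal_id = owner,
    surgery_date = surgery_date,
    procedure_type = strata$procedure_type[stratum_of],
    infection_status = strata$infection_status[stratum_of],
    prophylaxis = strata$prophylaxis[stratum_of],
    observation_days = sample(7:8, total, replace = TRUE),
    stringsAsFactors = FALSE
  )

  # plant complications per stratum
  complication <- logical(total)
  for (s in seq_len(nrow(strata))) {
    rows <- which(stratum_of == s)
    k <- rbinom(1, length(rows), strata$true_rate[s])
    if (k > 0) complication[sample(rows, k)] <- TRUE
  }

  rx <- list(); notes <- list(); overrides <- list()
  evidence <- rep("", total)
  add_rx <- function(i, drug, class, indication, day) {
    data.frame(animal_id = procedures$animal_id[i],
               event_date = procedures$surgery_date[i] + day,
               drug_name = drug, drug_class = class,
               indication = indication, stringsAsFactors = FALSE)
  }

  comp_rows <- which(complication)
  if (length(comp_rows)) {
    branch <- sample(names(spec$evidence_mix), length(comp_rows),
                     replace = TRUE, prob = spec$evidence_mix)
    for (j in seq_along(comp_rows)) {
      i <- comp_rows[j]
      day <- sample(1:8, 1)
      if (branch[j] == "ANTIBIOTIC") {
        drug <- sample(c("cefazolin", "cephalexin"), 1)
        rx[[length(rx) + 1]] <- add_rx(i, drug, "ANTIBIOTIC", "surgical",
                                       day)
        evidence[i] <- paste0("ANTIBIOTIC_DAY_", day)
      } else if (branch[j] == "NSAID") {
        drug <- sample(c("meloxicam", "carprofen"), 1)
        rx[[length(rx) + 1]] <- add_rx(i, drug, "NSAID", "surgical", day)
        evidence[i] <- paste0("NSAID_DAY_", day)
      } else {
        procedures$observation_days[i] <- sample(9:14, 1)
        evidence[i] <- "OBSERVATION_EXTENDED"
      }
      if (runif(1) < spec$adverse_note_rate) {
        notes[[length(notes) + 1]] <- data.frame(
          animal_id = procedures$animal_id[i],
          event_date = procedures$surgery_date[i] + sample(1:8, 1),
          note_text = sample(ADVERSE_NOTES, 1), stringsAsFactors = FALSE)
        evidence[i] <- paste(evidence[i], "ADVERSE_NOTE", sep = ";")
      }
    }
  }

  # noise on complication-free procedures
  clean_rows <- which(!complication)
  if (length(clean_rows)) {
    hit <- clean_rows[runif(length(clean_rows)) <
                        spec$noise$unrelated_prescription_rate]
    for (i in hit) {
      cls <- sample(c("ANTIBIOTIC", "NSAID", "OPIOID"), 1)
      drug <- switch(cls, ANTIBIOTIC = "cephalexin", NSAID = "meloxicam",
                     OPIOID = "buprenorphine")
      rx[[length(rx) + 1]] <- add_rx(i, drug, cls, "unrelated",
                                     sample(1:8, 1))
      overrides[[length(overrides) + 1]] <- data.frame(
        procedure_id = procedures$procedure_id[i], complication = FALSE,
        reason = "prescription unrelated to procedure",
        stringsAsFactors = FALSE)
    }
    hit <- clean_rows[runif(length(clean_rows)) <
                        spec$noise$benign_note_rate]
    for (i in hit) {
      notes[[length(notes) + 1]] <- data.frame(
        animal_id = procedures$animal_id[i],
        event_date = procedures$surgery_date[i] + sample(1:8, 1),
        note_text = sample(BENIGN_NOTES, 1), stringsAsFactors = FALSE)
    }
  }

  bind <- function(lst, template) {
    if (length(lst)) {
      out <- do.call(rbind, lst)
      rownames(out) <- NULL
      out
    } else template
  }
  prescriptions <- bind(rx, data.frame(
    animal_id = character(), event_date = as.Date(character()),
    drug_name = character(), drug_class = character(),
    indication = character(), stringsAsFactors = FALSE))
  note_df <- bind(notes, data.frame(
    animal_id = character(), event_date = as.Date(character()),
    note_text = character(), stringsAsFactors = FALSE))
  override_df <- bind(overrides, data.frame(
    procedure_id = character(), complication = logical(),
    reason = character(), stringsAsFactors = FALSE))

  prescriptions$kind <- NULL
  events <- rbind(
    data.frame(animal_id = prescriptions$animal_id,
               event_date = prescriptions$event_date,
               kind = "PRESCRIPTION",
               drug_class = prescriptions$drug_class,
               drug_name = prescriptions$drug_name,
               note_text = "", indication = prescriptions$indication,
               stringsAsFactors = FALSE),
    data.frame(animal_id = note_df$animal_id,
               event_date = note_df$event_date,
               kind = "NOTE", drug_class = NA_character_,
               drug_name = NA_character_, note_text = note_df$note_text,
               indication = NA_character_, stringsAsFactors = FALSE)
  )

  ground_truth <- data.frame(
    procedure_id = procedures$procedure_id,
    complication = complication,
    planted_evidence = evidence,
    stringsAsFactors = FALSE
  )

  list(procedures = procedures, prescriptions = prescriptions,
       notes = note_df, demographics = demographics,
       overrides = override_df, ground_truth = ground_truth,
       events = events, spec = spec, seed = as.integer(seed))
}
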