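#' Published summary cells of the reference macaque biopsy cohort
#'
#' Complication-rate cells, as printed, from a retrospective cohort of
#' 3,629 biopsy procedures (2,230 peripheral lymph node, 1,399
#' laparoscopic) in 1,056 macaques: for each stratum, the complication
#' rate in percent and the number of procedures. Counts were not printed
#' and are recovered with [reconstruct_count()]. The `role` column
#' distinguishes stratum cells from their marginal totals.
#'
#' @return data.frame with columns `procedure_type`, `infection_status`
#'   (`"ALL"` for cells pooled over infection status), `prophylaxis`
#'   (`NA` for totals pooled over prophylaxis), `rate_percent`, `n`,
#'   `role` (`"group"` or `"total"`).
#' @export
reference_cells <- function() {
  df <- rbind(
    # pooled over infection status
    data.frame(procedure_type = "PLN", infection_status = "ALL",
               prophylaxis = c(TRUE, FALSE, NA),
               rate_percent = c(2.37, 2.05, 2.20),
               n = c(1011L, 1219L, 2230L)),
    data.frame(procedure_type = "LAPAROSCOPIC", infection_status = "ALL",
               prophylaxis = c(TRUE, FALSE, NA),
               rate_percent = c(3.61, 0.76, 0.93),
               n = c(83L, 1316L, 1399L)),
    # by infection status
    data.frame(procedure_type = "PLN", infection_status = "INFECTED",
               prophylaxis = c(TRUE, FALSE, NA),
               rate_percent = c(2.64, 2.15, 2.31),
               n = c(455L, 885L, 1340L)),
    data.frame(procedure_type = "PLN", infection_status = "UNINFECTED",
               prophylaxis = c(TRUE, FALSE, NA),
               rate_percent = c(2.16, 1.80, 2.02),
               n = c(556L, 334L, 890L)),
    data.frame(procedure_type = "LAPAROSCOPIC",
               infection_status = "INFECTED",
               prophylaxis = c(TRUE, FALSE, NA),
               rate_percent = c(5.13, 0.24, 0.46),
               n = c(39L, 822L, 861L)),
    data.frame(procedure_type = "LAPAROSCOPIC",
               infection_status = "UNINFECTED",
               prophylaxis = c(TRUE, FALSE, NA),
               rate_percent = c(2.27, 1.62, 1.67),
               n = c(44L, 494L, 538L))
  )
  df$role <- ifelse(is.na(df$prophylaxis), "total", "group")
  df
}

ref_cell <- function(cells, type, infection, prophylaxis) {
  row <- cells[cells$procedure_type == type &
                 cells$infection_status == infection &
                 !is.na(cells$prophylaxis) &
                 cells$prophylaxis == prophylaxis, ]
  stopifnot(nrow(row) == 1)
  row
}

ref_total <- function(cells, type, infection) {
  row <- cells[cells$procedure_type == type &
                 cells$infection_status == infection &
                 is.na(cells$prophylaxis), ]
  stopifnot(nrow(row) == 1)
  row
}

#' Reconstructed 2x2 tables for the reference cohort comparisons
#'
#' Builds the eight stratum comparisons of the reference cohort as
#' [two_by_two()] tables, with counts reconstructed from the published
#' (rate, n) cells. Group 1 is the prophylaxis stratum for treatment
#' comparisons and the infected stratum for infection-status comparisons,
#' so the signed difference is oriented the way the cohort's tests were.
#'
#' @return named list of eight `two_by_two` tables:
#'   `pln_prophylaxis`, `lap_prophylaxis`, `pln_infection`,
#'   `pln_infected_prophylaxis`, `pln_uninfected_prophylaxis`,
#'   `lap_infection`, `lap_infected_prophylaxis`,
#'   `lap_uninfected_prophylaxis`.
#' @export
#' @examples
#' reference_tables()$lap_prophylaxis
reference_tables <- function() {
  cells <- reference_cells()
  tab <- function(r1, r2, labels) {
    two_by_two(reconstruct_count(r1$rate_percent, r1$n), r1$n,
               reconstruct_count(r2$rate_percent, r2$n), r2$n,
               labels = labels)
  }
  prop <- c("prophylaxis", "no prophylaxis")
  inf <- c("infected", "uninfected")
  list(
    pln_prophylaxis = tab(
      ref_cell(cells, "PLN", "ALL", TRUE),
      ref_cell(cells, "PLN", "ALL", FALSE), prop),
    lap_prophylaxis = tab(
      ref_cell(cells, "LAPAROSCOPIC", "ALL", TRUE),
      ref_cell(cells, "LAPAROSCOPIC", "ALL", FALSE), prop),
    pln_infection = tab(
      ref_total(cells, "PLN", "INFECTED"),
      ref_total(cells, "PLN", "UNINFECTED"), inf),
    pln_infected_prophylaxis = tab(
      ref_cell(cells, "PLN", "INFECTED", TRUE),
      ref_cell(cells, "PLN", "INFECTED", FALSE), prop),
    pln_uninfected_prophylaxis = tab(
      ref_cell(cells, "PLN", "UNINFECTED", TRUE),
      ref_cell(cells, "PLN", "UNINFECTED", FALSE), prop),
    lap_infection = tab(
      ref_total(cells, "LAPAROSCOPIC", "INFECTED"),
      ref_total(cells, "LAPAROSCOPIC", "UNINFECTED"), inf),
    lap_infected_prophylaxis = tab(
      ref_cell(cells, "LAPAROSCOPIC", "INFECTED", TRUE),
      ref_cell(cells, "LAPAROSCOPIC", "INFECTED", FALSE), prop),
    lap_uninfected_prophylaxis = tab(
      ref_cell(cells, "LAPAROSCOPIC", "UNINFECTED", TRUE),
      ref_cell(cells, "LAPAROSCOPIC", "UNINFECTED", FALSE), prop)
  )
}

#' Demographic marginals of the reference cohort
#'
#' Published cohort-level marginals used as defaults by the synthetic
#' generator: species and sex counts, age and body-condition-score ranges,
#' and the overall procedure and animal totals.
#'
#' @return named list.
#' @export
reference_demographics <- function() {
  list(
    n_animals = 1056L,
    n_procedures = 3629L,
    species = c(RHESUS = 1006L, CYNOMOLGUS = 50L),
    sex = c(M = 616L, F = 440L),
    age_range = c(0.04, 25.56),
    bcs_range = c(1.5, 5.0),
    study_window = as.Date(c("2018-05-01", "2021-01-19"))
  )
}
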