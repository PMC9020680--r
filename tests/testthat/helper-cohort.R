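# In-code fixture builders shared across test files.

make_procs <- function(n = 1, animal = "A1", date = "2020-01-01",
                       type = "PLN", infection = "UNINFECTED",
                       prophylaxis = FALSE, obs = 8L, id = NULL) {
  data.frame(
    procedure_id = id %||% paste0("P", seq_len(n)),
    animal_id = rep_len(animal, n),
    surgery_date = as.Date(rep_len(date, n)),
    procedure_type = rep_len(type, n),
    infection_status = rep_len(infection, n),
    prophylaxis = rep_len(prophylaxis, n),
    observation_days = as.integer(rep_len(obs, n)),
    stringsAsFactors = FALSE
  )
}

make_rx <- function(animal = "A1", date = "2020-01-03",
                    drug = "cefazolin", class = "ANTIBIOTIC",
                    indication = "surgical") {
  data.frame(animal_id = animal, event_date = as.Date(date),
             kind = "PRESCRIPTION", drug_class = class, drug_name = drug,
             note_text = "", indication = indication,
             stringsAsFactors = FALSE)
}

make_note <- function(animal = "A1", date = "2020-01-03",
                      text = "incision clean and dry") {
  data.frame(animal_id = animal, event_date = as.Date(date),
             kind = "NOTE", drug_class = NA_character_,
             drug_name = NA_character_, note_text = text,
             indication = NA_character_, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small cohort spec for pipeline tests: two PLN strata
small_spec <- function(n = 200L, rate1 = 0.025, rate2 = 0.02,
                       noise = list(unrelated_prescription_rate = 0.02,
                                    benign_note_rate = 0.05),
                       n_animals = 120L) {
  cohort_spec(
    strata = data.frame(
      procedure_type = "PLN",
      infection_status = "UNINFECTED",
      prophylaxis = c(TRUE, FALSE),
      n_procedures = as.integer(c(n, n)),
      true_rate = c(rate1, rate2),
      stringsAsFactors = FALSE),
    n_animals = n_animals,
    noise = noise)
}

small_plan <- function() {
  list(treatment = list(list(
    name = "pln_prophylaxis",
    stratum_a = list(procedure_type = "PLN", prophylaxis = TRUE),
    stratum_b = list(procedure_type = "PLN", prophylaxis = FALSE),
    label_a = "prophylaxis", label_b = "no prophylaxis")),
    infection = list())
}

# brute-force permutation p-value: enumerate every assignment of the
# pooled outcome vector to group 1 (all choose(N, n1) label subsets)
enumerate_p <- function(x1, n1, x2, n2) {
  N <- n1 + n2
  outcomes <- c(rep(1L, x1 + x2), rep(0L, N - x1 - x2))
  d_obs <- x1 / n1 - x2 / n2
  sets <- utils::combn(N, n1)
  d <- apply(sets, 2, function(idx)
    sum(outcomes[idx]) / n1 - sum(outcomes[-idx]) / n2)
  mean(d >= d_obs - 1e-12)
}
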