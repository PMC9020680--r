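#' Reproduce the reference cohort comparisons
#'
#' Runs the one-sided randomization test over the eight reconstructed 2x2
#' tables of the reference macaque biopsy cohort ([reference_tables()]):
#' prophylaxis vs none for each procedure type, infected vs uninfected for
#' each procedure type, and prophylaxis vs none within each infection
#' status. Each comparison's seed derives deterministically from `seed`.
#'
#' @param B permutations per comparison (default 50,000).
#' @param seed master seed.
#' @param alpha significance level for the asterisk annotation.
#' @return `comparison_set` of eight `rand_test` objects (print it for a
#'   publication-style table).
#' @export
#' @examples
#' reproduce_reference(B = 5000, seed = 1)
reproduce_reference <- function(B = 50000L, seed = 1L, alpha = 0.05) {
  tabs <- reference_tables()
  tests <- vector("list", length(tabs))
  names(tests) <- names(tabs)
  for (i in seq_along(tabs))
    tests[[i]] <- randomization_test(tabs[[i]], B = B, seed = seed + i,
                                     alpha = alpha)
  structure(tests, class = "comparison_set")
}

#' Default comparison plan for a fully stratified tally
#'
#' The eight-stratum comparison plan matching the reference cohort's
#' analysis, for a tally stratified by `procedure_type`,
#' `infection_status` and `prophylaxis` (treatment comparisons) or by
#' `procedure_type` and `infection_status` (infection comparisons).
#' [run_pipeline()] computes both tallies and runs the applicable half of
#' the plan on each.
#'
#' @return list with elements `treatment` and `infection`, each a plan
#'   for [run_comparisons()].
#' @export
comparison_plan <- function() {
  trt <- function(name, type, infection) {
    a <- list(procedure_type = type, prophylaxis = TRUE)
    b <- list(procedure_type = type, prophylaxis = FALSE)
    if (!is.null(infection)) {
      a$infection_status <- infection
      b$infection_status <- infection
    }
    list(name = name, stratum_a = a, stratum_b = b,
         label_a = "prophylaxis", label_b = "no prophylaxis")
  }
  inf <- function(name, type) {
    list(name = name,
         stratum_a = list(procedure_type = type,
                          infection_status = "INFECTED"),
         stratum_b = list(procedure_type = type,
                          infection_status = "UNINFECTED"),
         label_a = "infected", label_b = "uninfected")
  }
  list(
    treatment = list(
      trt("pln_prophylaxis", "PLN", NULL),
      trt("lap_prophylaxis", "LAPAROSCOPIC", NULL),
      trt("pln_infected_prophylaxis", "PLN", "INFECTED"),
      trt("pln_uninfected_prophylaxis", "PLN", "UNINFECTED"),
      trt("lap_infected_prophylaxis", "LAPAROSCOPIC", "INFECTED"),
      trt("lap_uninfected_prophylaxis", "LAPAROSCOPIC", "UNINFECTED")
    ),
    infection = list(
      inf("pln_infection", "PLN"),
      inf("lap_infection", "LAPAROSCOPIC")
    )
  )
}

#' Run the full complication-analysis pipeline
#'
#' End-to-end composition: link care events to procedures, flag and
#' adjudicate complications, tally per-stratum rates, and run the
#' comparison plan with the randomization test. Input is either a records
#' bundle (from [read_records()] or [generate_cohort()]) or a
#' [cohort_spec()] to generate one.
#'
#' @param bundle records bundle (list with `procedures` and `events`,
#'   optionally `overrides`); mutually exclusive with `spec`.
#' @param spec a [cohort_spec()] to generate a synthetic bundle from.
#' @param criteria [flag_criteria()].
#' @param lexicon [adverse_lexicon()].
#' @param plan comparison plan, defaults to [comparison_plan()].
#' @param use_overrides consult the bundle's override table during
#'   adjudication (default `TRUE`).
#' @param B permutations per comparison.
#' @param seed master seed (also seeds cohort generation in `spec` mode).
#' @param alpha significance level.
#' @return object of class `complication_report`: the complication calls,
#'   tallies at both stratification depths, the fitted tests, and the run
#'   configuration (seed, B, criteria).
#' @export
run_pipeline <- function(bundle = NULL, spec = NULL,
                         criteria = flag_criteria(),
                         lexicon = adverse_lexicon(),
                         plan = comparison_plan(),
                         use_overrides = TRUE,
                         B = 50000L, seed = 1L, alpha = 0.05) {
  if (is.null(bundle) == is.null(spec))
    stop("supply exactly one of 'bundle' or 'spec'", call. = FALSE)
  if (!is.null(spec)) bundle <- generate_cohort(spec, seed = seed)

  overrides <- if (use_overrides) bundle$overrides else NULL
  calls <- call_complications(bundle$procedures, bundle$events,
                              criteria = criteria, lexicon = lexicon,
                              overrides = overrides)
  tally_trt <- tally_complications(
    calls, bundle$procedures,
    by = c("procedure_type", "infection_status", "prophylaxis"))
  tally_trt_pooled <- tally_complications(
    calls, bundle$procedures, by = c("procedure_type", "prophylaxis"))
  tally_inf <- tally_complications(
    calls, bundle$procedures, by = c("procedure_type", "infection_status"))

  run_half <- function(half, tallies, offset) {
    if (!length(half)) return(list())
    res <- run_comparisons(tallies, half, B = B, seed = seed + offset,
                           alpha = alpha)
    unclass(res)
  }
  pooled_names <- c("pln_prophylaxis", "lap_prophylaxis")
  trt_plan <- plan$treatment
  pooled_plan <- Filter(function(p) p$name %in% pooled_names, trt_plan)
  strat_plan <- Filter(function(p) !p$name %in% pooled_names, trt_plan)
  tests <- c(
    run_half(pooled_plan, tally_trt_pooled, 0L),
    run_half(strat_plan, tally_trt, 100L),
    run_half(plan$infection, tally_inf, 200L)
  )
  tests <- structure(tests, class = "comparison_set")

  structure(list(
    calls = calls,
    tallies = list(treatment = tally_trt_pooled,
                   treatment_by_infection = tally_trt,
                   infection = tally_inf),
    tests = tests,
    config = list(B = as.integer(B), seed = as.integer(seed),
                  alpha = alpha, criteria = criteria,
                  use_overrides = use_overrides),
    bundle = bundle
  ), class = "complication_report")
}

format_rate_table <- function(tally, tests = NULL) {
  t <- tally
  t$rate <- sprintf("%.2f%% (n = %s)", t$rate_percent,
                    format(t$procedures, big.mark = ","))
  t
}

#' @export
print.complication_report <- function(x, ...) {
  cat("Post-operative complication analysis\n")
  cat(sprintf("  procedures: %d   confirmed complications: %d\n",
              nrow(x$calls), sum(x$calls$complication)))
  cat(sprintf("  B = %s permutations, seed = %d, alpha = %.2f\n\n",
              format(x$config$B, big.mark = ","), x$config$seed,
              x$config$alpha))
  cat("Complication rates by stratum:\n")
  print(format_rate_table(x$tallies$treatment_by_infection)[
    , c("procedure_type", "infection_status", "prophylaxis", "rate")],
    row.names = FALSE)
  cat("\n")
  print(x$tests)
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Emits `tally_*.tsv` rate tables (rate in percent to two decimals with
#' group sizes), `results.tsv` with one row per comparison (observed
#' difference, Monte-Carlo p, its standard error, exact p, seed, B,
#' significance at the configured alpha), and `run_log.txt` capturing the
#' configuration.
#'
#' @param report a `complication_report` from [run_pipeline()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, file)
    utils::write.table(df, file.path(dir, file), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  for (nm in names(report$tallies)) {
    t <- report$tallies[[nm]]
    t$rate_percent <- sprintf("%.2f", t$rate_percent)
    tsv(t, paste0("tally_", nm, ".tsv"))
  }
  res <- as.data.frame(report$tests)
  tsv(res, "results.tsv")
  cfg <- report$config
  writeLines(c(
    sprintf("B: %d", cfg$B),
    sprintf("seed: %d", cfg$seed),
    sprintf("alpha: %g", cfg$alpha),
    sprintf("window: [%d, %d]", cfg$criteria$window[1],
            cfg$criteria$window[2]),
    sprintf("flag_drug_classes: %s",
            paste(cfg$criteria$drug_classes, collapse = ",")),
    sprintf("extended_observation: %d", cfg$criteria$extended_observation),
    sprintf("use_overrides: %s", cfg$use_overrides)
  ), file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' Read a run configuration file
#'
#' Reads a YAML or JSON configuration with any of: `window` (two
#' integers), `drug_classes`, `extended_observation`, `lexicon` (adverse
#' phrases), `B`, `seed`, `alpha`, `drug_dictionary` (name: class map).
#' Missing entries fall back to package defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return list with `criteria`, `lexicon`, `dictionary`, `B`, `seed`,
#'   `alpha`.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML config requires the 'yaml' package",
           call. = FALSE)
    yaml::read_yaml(path)
  } else if (ext == "json") {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("reading JSON config requires the 'jsonlite' package",
           call. = FALSE)
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("config must be .yaml, .yml or .json", call. = FALSE)

  criteria <- flag_criteria(
    window = unlist(raw$window) %||% c(1L, 8L),
    drug_classes = unlist(raw$drug_classes) %||%
      c("ANTIBIOTIC", "NSAID", "OPIOID"),
    extended_observation = raw$extended_observation %||% 9L)
  lexicon <- if (is.null(raw$lexicon)) adverse_lexicon() else
    adverse_lexicon(unlist(raw$lexicon))
  dictionary <- if (is.null(raw$drug_dictionary)) drug_class_dictionary()
    else drug_class_dictionary(unlist(raw$drug_dictionary))
  list(criteria = criteria, lexicon = lexicon, dictionary = dictionary,
       B = as.integer(raw$B %||% 50000L),
       seed = as.integer(raw$seed %||% 1L),
       alpha = raw$alpha %||% 0.05)
}
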