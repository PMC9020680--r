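test_that("flagging criteria fire on prescriptions and extended
           observation", {
  procs <- make_procs(4, obs = c(7L, 9L, 8L, 7L))
  events <- rbind(
    make_rx("A1", "2020-01-03", drug = "meloxicam", class = "NSAID"),
    make_rx("A1", "2020-01-05", drug = "vitamin-supplement",
            class = "OTHER"))
  linked <- link_events(procs, events)
  # every event attaches to every same-animal procedure here; restrict to
  # one procedure each by id to isolate the branches
  linked1 <- linked[linked$procedure_id == "P1", ]
  f <- flag_procedures(procs,
                       linked[linked$drug_class == "NSAID" &
                                linked$procedure_id == "P1", ])
  expect_true(f$flagged[1])
  expect_equal(f$triggers[[1]], "NSAID_DAY_2")
  # P2: no events, observation 9 days -> extended-observation flag
  expect_true(f$flagged[2])
  expect_equal(f$triggers[[2]], "OBSERVATION_EXTENDED")
  # P3: observation 8 days, no events -> not flagged
  expect_false(f$flagged[3])
  expect_equal(f$triggers[[3]], character(0))
  # OTHER-class prescriptions never flag
  f2 <- flag_procedures(procs[4, ],
                        linked[linked$drug_class == "OTHER" &
                                 linked$procedure_id == "P4", ])
  expect_false(f2$flagged[1])
})

test_that("adjudication confirms, clears, and respects overrides", {
  procs <- make_procs(3, obs = c(7L, 7L, 8L))
  events <- make_rx("A1", "2020-01-04")
  linked <- link_events(procs[1:2, ], events)
  flags <- flag_procedures(procs, rbind(linked))
  calls <- adjudicate(procs, flags, linked)
  # treatment-class trigger confirms the complication
  expect_true(calls$complication[1])
  expect_equal(calls$adjudication_rule[1], "TREATMENT_TRIGGER")
  # unflagged procedure is never a complication
  expect_false(calls$complication[3])
  expect_equal(calls$adjudication_rule[3], "NOT_FLAGGED")
  expect_true(all(calls$complication <= calls$flagged))

  # an override marking the prescription unrelated clears the flag
  ov <- data.frame(procedure_id = "P1", complication = FALSE,
                   reason = "unrelated", stringsAsFactors = FALSE)
  cleared <- adjudicate(procs, flags, linked, overrides = ov)
  expect_false(cleared$complication[1])
  expect_equal(cleared$adjudication_rule[1], "OVERRIDE")

  bad <- data.frame(procedure_id = "NOPE", complication = TRUE,
                    reason = "", stringsAsFactors = FALSE)
  expect_error(adjudicate(procs, flags, linked, overrides = bad),
               "unknown procedure_id")
})

test_that("extended observation confirms via notes or on its own", {
  procs <- make_procs(1, obs = 10L)
  flags <- flag_procedures(procs, link_events(procs, make_rx()[0, ]))
  # no notes: extended observation is itself confirming evidence
  calls <- adjudicate(procs, flags, link_events(procs, make_rx()[0, ]))
  expect_true(calls$complication[1])
  expect_equal(calls$adjudication_rule[1], "OBSERVATION_EXTENDED")
  # adverse note takes precedence and records the matched keyword
  note <- make_note("A1", "2020-01-05", "incision Dehiscence noted")
  linked <- link_events(procs, note)
  calls2 <- adjudicate(procs, flags, linked)
  expect_true(calls2$complication[1])
  expect_equal(calls2$adjudication_rule[1], "NOTE_KEYWORD")
  expect_true("NOTE_KEYWORD:dehiscence" %in% calls2$triggers[[1]])
})

test_that("adding an adverse note never un-confirms a complication", {
  set.seed(11)
  for (rep in 1:25) {
    obs <- sample(c(7L, 8L, 9L, 10L), 1)
    with_rx <- runif(1) < 0.5
    procs <- make_procs(1, obs = obs)
    events <- if (with_rx) make_rx("A1", "2020-01-03") else make_rx()[0, ]
    before <- call_complications(procs, events)
    more <- rbind(events,
                  make_note("A1", "2020-01-04", "evidence of pain"))
    after <- call_complications(procs, more)
    expect_true(after$complication[1] >= before$complication[1])
  }
})

test_that("tallies conserve totals over any stratifier set", {
  sp <- small_spec(n = 150L)
  b <- generate_cohort(sp, seed = 9)
  calls <- call_complications(b$procedures, b$events,
                              overrides = b$overrides)
  total <- sum(calls$complication)
  for (by in list(character(0), "prophylaxis",
                  c("procedure_type", "prophylaxis"),
                  c("procedure_type", "infection_status",
                    "prophylaxis"))) {
    t <- tally_complications(calls, b$procedures, by = by)
    expect_equal(sum(t$complications), total)
    expect_equal(sum(t$procedures), nrow(b$procedures))
    expect_equal(t$rate_percent, 100 * t$complications / t$procedures)
  }
  # determinism under row permutation of inputs
  idx <- sample(nrow(b$procedures))
  calls2 <- call_complications(b$procedures[idx, ], b$events,
                               overrides = b$overrides)
  t1 <- tally_complications(calls, b$procedures, "prophylaxis")
  t2 <- tally_complications(calls2, b$procedures[idx, ], "prophylaxis")
  expect_equal(t1, t2)
})

test_that("tally handles empty input, unit rates, and orphan calls", {
  procs <- make_procs(1)
  calls <- call_complications(procs, make_rx("A1", "2020-01-03"))
  t <- tally_complications(calls, procs, by = character(0))
  expect_equal(t$rate_percent, 100)
  expect_equal(t$complications, 1L)

  empty <- tally_complications(calls[0, ], procs[0, ], "prophylaxis")
  expect_equal(nrow(empty), 0)

  orphan <- calls
  orphan$procedure_id <- "GHOST"
  expect_error(tally_complications(orphan, procs), "no matching procedure")
})
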