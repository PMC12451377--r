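test_that("departures are classified by the three-year return rule", {
  # absent in y+1, back in IMT1 in y+2: temporary break
  p <- person_df("a", c(`2015` = "FY2", `2017` = "IMT1"))
  expect_identical(classify_departure(p, 2015), "TEMPORARY_BREAK")

  # return in y+3 still counts as a break
  p <- person_df("b", c(`2015` = "IMT2", `2018` = "ST3"))
  expect_identical(classify_departure(p, 2015), "TEMPORARY_BREAK")

  # absent in y+1..y+3: exit (window end passed explicitly)
  p <- person_df("c", c(`2015` = "IMT2"))
  expect_identical(classify_departure(p, 2015, window_end = 2018), "EXIT")

  # observed the following year: not a departure
  p <- person_df("d", c(`2015` = "FY1", `2016` = "FY2"))
  expect_error(classify_departure(p, 2015),
               class = "physupply_precondition_error")

  # follow-up ends too early: truncation error, never a guess
  p <- person_df("e", c(`2015` = "ST3", `2016` = "ABSENT"))
  expect_error(classify_departure(p, 2015),
               class = "physupply_followup_truncated")
})

test_that("transition probabilities are destination counts over origin totals", {
  space <- build_state_space()
  # 100 people in IMT2 (male): 80 progress to ST3, 10 take a 1-year
  # break, 10 never return
  recs <- list()
  for (i in 1:80) {
    recs[[i]] <- person_df(sprintf("p%03d", i),
                           c(`2015` = "IMT2", `2016` = "ST3"),
                           sex = "M", ltft = FALSE)
  }
  for (i in 81:90) {
    recs[[i]] <- person_df(sprintf("p%03d", i),
                           c(`2015` = "IMT2", `2017` = "ST3"),
                           sex = "M", ltft = FALSE)
  }
  for (i in 91:100) {
    recs[[i]] <- person_df(sprintf("p%03d", i),
                           c(`2015` = "IMT2", `2019` = "ABSENT"),
                           sex = "M")
  }
  rec <- do.call(rbind, recs)
  rec$ltft[rec$stage %in% c("ST3")] <- FALSE
  est <- estimate_transitions(rec, space, cohort_years = 2015)
  o <- "IMT2|M|-|1"
  expect_equal(est$denominators[[o]], 100)
  expect_equal(est$probs[o, "ST3|M|FT|1"], 0.80)
  expect_equal(est$probs[o, "BREAK_POST_IMT|M|-|1"], 0.10)
  expect_equal(est$probs[o, "EXIT|-|-|1"], 0.10)
  expect_equal(sum(est$probs[o, ]), 1)
})

test_that("empty cohort set yields a fully flagged, still projectable result", {
  space <- build_state_space()
  rec <- person_df("a", c(`2015` = "FY1", `2016` = "FY2"))
  est <- estimate_transitions(rec, space, cohort_years = integer(0))
  expect_true(all(est$denominators == 0))
  # every non-absorbing origin flagged; rows still sum to one
  expect_equal(nrow(est$flagged), nrow(space$states) - 1L)
  expect_true(all(abs(rowSums(est$probs) - 1) < 1e-12))
  expect_true(is_clean(validate_transition_model(space, est$probs)))
})

test_that("unknown stage codes and truncated cohorts are rejected", {
  space <- build_state_space()
  rec <- person_df("a", c(`2015` = "REGISTRAR"))
  expect_error(estimate_transitions(rec, space, 2015),
               class = "physupply_parse_error")
  rec <- person_df("a", c(`2015` = "FY1", `2016` = "FY2"))
  expect_error(estimate_transitions(rec, space, cohort_years = 2015),
               class = "physupply_followup_truncated")
})

test_that("estimates converge to generator truth as the sample grows", {
  err_at <- function(n) {
    spec <- recovery_generator_spec(n_persons = n, seed = 99)
    rec <- generate_records(spec, n_years_observed = 20)
    est <- estimate_transitions(rec, spec$truth$space,
                                cohort_years = 2000:2016)
    tm <- spec$truth$matrix
    chk <- sweep(tm >= 0.02, 1, est$denominators > 0, "&")
    max(abs(est$probs - tm)[chk])
  }
  e_small <- err_at(2000)
  e_large <- err_at(20000)
  expect_lt(e_large, e_small)
  expect_lt(e_large, 0.02)
})

test_that("estimated models satisfy the transition-model contract", {
  spec <- recovery_generator_spec(n_persons = 3000, seed = 5)
  rec <- generate_records(spec, n_years_observed = 20)
  est <- estimate_transitions(rec, spec$truth$space,
                              cohort_years = 2000:2016)
  expect_true(is_clean(validate_transition_model(spec$truth$space,
                                                 est$probs)))
  expect_s3_class(as_transition_model(est), "transition_model")
})

test_that("CCT completion splits into the three post-CCT destinations", {
  expect_equal(unname(split_cct(1, 1, 0, 0)), c(1, 0, 0))
  expect_equal(unname(split_cct(0.9, 0.8, 0.1, 0.1)), c(0.72, 0.09, 0.09))
  expect_equal(unname(split_cct(0, 0.5, 0.25, 0.25)), c(0, 0, 0))
  expect_error(split_cct(0.9, 0.8, 0.1, 0.2),
               class = "physupply_validation_error")
})

test_that("consultant exit decomposes into retire-and-return and direct exit", {
  d <- consultant_exit_decomposition(0.05, 0.02)
  expect_equal(unlist(d), c(to_cons_rr = 0.02, to_exit = 0.03, stay = 0.95))
  d <- consultant_exit_decomposition(0.05, 0)
  expect_equal(d$to_exit, 0.05)
  expect_error(consultant_exit_decomposition(0.04, 0.05),
               class = "physupply_validation_error")
})

test_that("calibration rescales a destination group and renormalizes the rest", {
  space <- build_state_space()
  cfg <- default_configuration()
  model <- cfg$model
  # set a known row first: progress 0.8, break 0.1, exit 0.1
  m <- model$matrix
  r <- "FY2|F|-|1"
  m[r, ] <- 0
  m[r, "IMT1|F|-|1"] <- 0.8
  m[r, "BREAK_POST_FY|F|-|1"] <- 0.1
  m[r, "EXIT|-|-|1"] <- 0.1
  model <- transition_model(space, m)
  tg <- list(list(origin = list(stage = "FY2", sex = "F"),
                  destination = list(stage = "BREAK_POST_FY"),
                  target = 0.2))
  out <- calibrate(model, tg)
  expect_equal(out$matrix[r, "BREAK_POST_FY|F|-|1"], 0.2)
  expect_equal(out$matrix[r, "IMT1|F|-|1"], 0.8 * 0.8 / 0.9)
  expect_equal(out$matrix[r, "EXIT|-|-|1"], 0.1 * 0.8 / 0.9)
  expect_equal(sum(out$matrix[r, ]), 1)

  # fixed point: targeting the current marginal changes nothing
  same <- calibrate(model, list(list(
    origin = list(stage = "FY2", sex = "F"),
    destination = list(stage = "BREAK_POST_FY"), target = 0.1)))
  expect_equal(same$matrix, model$matrix)

  # idempotence
  twice <- calibrate(out, tg)
  expect_equal(twice$matrix, out$matrix, tolerance = 1e-12)

  # target 1.0 empties the rest of the row but keeps it stochastic
  all_in <- calibrate(model, list(list(
    origin = list(stage = "FY2", sex = "F"),
    destination = list(stage = "BREAK_POST_FY"), target = 1)))
  expect_equal(all_in$matrix[r, "BREAK_POST_FY|F|-|1"], 1)
  expect_equal(sum(all_in$matrix[r, ]), 1)

  # a zero-mass group cannot be scaled up
  expect_error(calibrate(model, list(list(
    origin = list(stage = "MS2"),
    destination = list(stage = "BREAK_POST_FY"), target = 0.1))),
    class = "physupply_calibration_error")

  # untargeted rows are untouched
  expect_equal(out$matrix["CONS|F|FT|1", ], model$matrix["CONS|F|FT|1", ])
})
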