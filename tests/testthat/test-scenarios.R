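test_that("intake ramp interpolates linearly and holds the end level", {
  cfg <- default_configuration()
  ramped <- apply_intake_ramp(cfg$inflows)
  e <- ramped$entries
  ms1 <- e[grepl("^MS1", e$state) & e$channel == "DOMESTIC_INTAKE", ]
  places <- setNames(ms1$count, ms1$year)
  expect_equal(places[["2023"]], 10000)
  expect_equal(places[["2027"]], 13500)   # midpoint of the ramp
  expect_equal(places[["2031"]], 17000)
  expect_equal(places[["2040"]], 17000)   # held after the ramp
  # other channels untouched
  expect_equal(e$count[e$channel == "OVERSEAS"],
               cfg$inflows$entries$count[cfg$inflows$entries$channel ==
                                           "OVERSEAS"])
  # equal endpoints leave the schedule unchanged
  same <- apply_intake_ramp(cfg$inflows, start_places = 10000,
                            end_places = 10000)
  expect_equal(same$entries, cfg$inflows$entries)
  # a schedule without an MS1 domestic channel is a configuration error
  expect_error(apply_intake_ramp(no_inflows()),
               class = "physupply_config_error")
})

test_that("exit overrides reallocate freed mass to progression proportionally", {
  space <- build_state_space()
  cfg <- default_configuration()
  m <- cfg$model$matrix
  # two-destination row: progress 0.84, exit 0.16 -> (0.95, 0.05)
  r <- "IMT1|F|-|1"
  m[r, ] <- 0
  m[r, "IMT2|F|-|1"] <- 0.84
  m[r, "EXIT|-|-|1"] <- 0.16
  # three-destination row: A 0.6, B 0.24, exit 0.16
  r2 <- "IMT2|F|-|1"
  m[r2, ] <- 0
  m[r2, "ST3|F|FT|1"] <- 0.6
  m[r2, "IMT3|F|-|1"] <- 0.24
  m[r2, "EXIT|-|-|1"] <- 0.16
  model <- transition_model(space, m)
  out <- apply_exit_reduction(model,
                              origin = list(stage = c("IMT1", "IMT2"),
                                            sex = "F"),
                              destination = list(stage = "EXIT"),
                              new_prob = 0.05)
  expect_equal(out$matrix[r, "IMT2|F|-|1"], 0.95)
  expect_equal(out$matrix[r, "EXIT|-|-|1"], 0.05)
  expect_equal(out$matrix[r2, "ST3|F|FT|1"], 0.6 * 0.95 / 0.84)   # 0.6786
  expect_equal(out$matrix[r2, "IMT3|F|-|1"], 0.24 * 0.95 / 0.84)  # 0.2714
  expect_equal(out$matrix[r2, "EXIT|-|-|1"], 0.05)
  expect_equal(round(out$matrix[r2, c("ST3|F|FT|1", "IMT3|F|-|1")], 4),
               c(`ST3|F|FT|1` = 0.6786, `IMT3|F|-|1` = 0.2714))

  # overriding with the current value changes nothing
  same <- apply_exit_reduction(model,
                               origin = list(stage = "IMT1", sex = "F"),
                               destination = list(stage = "EXIT"),
                               new_prob = 0.16)
  expect_equal(same$matrix, model$matrix)

  # a row with no progression destination cannot absorb freed mass
  m2 <- cfg$model$matrix
  r3 <- "CONS_RR|F|FT|2"   # only destination is EXIT
  expect_error(apply_exit_reduction(
    transition_model(space, m2),
    origin = list(stage = "CONS_RR", sex = "F", work_pattern = "FT",
                  dwell = 2),
    destination = list(stage = "EXIT"), new_prob = 0.5),
    class = "physupply_override_error")
})

test_that("overseas scaling multiplies only the overseas channel", {
  cfg <- default_configuration()
  half <- apply_overseas_scaling(cfg$inflows, 0.5)
  e0 <- cfg$inflows$entries
  e1 <- half$entries
  ov <- e0$channel == "OVERSEAS"
  expect_equal(e1$count[ov], e0$count[ov] / 2)
  expect_equal(e1$count[!ov], e0$count[!ov])
  expect_equal(apply_overseas_scaling(cfg$inflows, 1)$entries, e0)
  zero <- apply_overseas_scaling(cfg$inflows, 0)
  expect_true(all(zero$entries$count[zero$entries$channel ==
                                       "OVERSEAS"] == 0))
  expect_error(apply_overseas_scaling(cfg$inflows, -0.1),
               class = "physupply_validation_error")
})

test_that("LTFT drift shifts shares additively, capped, year by year", {
  cfg <- default_configuration()
  drifted <- suppressWarnings(
    apply_ltft_drift(cfg$model, start_year = 2023, horizon = 25))
  # the drift start year itself uses the unchanged base matrix
  expect_equal(resolve_matrix(drifted, 2023), cfg$model$matrix)

  # consultant entry from ST7: base LTFT share 0.31, +5pp/year, cap 0.70
  r <- "ST7|F|FT|1"
  pair <- c("CONS|F|FT|1", "CONS|F|LTFT|1")
  share_at <- function(model, yr) {
    m <- resolve_matrix(model, yr)
    m[r, pair[2]] / sum(m[r, pair])
  }
  expect_equal(share_at(drifted, 2024), 0.36)
  expect_equal(share_at(drifted, 2033), 0.70)       # 0.31 + 0.50 capped
  expect_equal(share_at(drifted, 2048), 0.70)
  # total progression mass into the pair is unchanged
  expect_equal(sum(resolve_matrix(drifted, 2048)[r, pair]),
               sum(cfg$model$matrix[r, pair]))
  # ST progression pair drifts at 1pp/year
  r2 <- "IMT2|F|-|1"
  pair2 <- c("ST3|F|FT|1", "ST3|F|LTFT|1")
  m10 <- resolve_matrix(drifted, 2033)
  expect_equal(m10[r2, pair2[2]] / sum(m10[r2, pair2]), 0.25 + 0.10)

  # cap equal to the base share freezes the shares
  frozen <- suppressWarnings(
    apply_ltft_drift(cfg$model, cap = 0.31, start_year = 2023,
                     horizon = 10))
  expect_equal(share_at(frozen, 2030), 0.31)

  # every yearly matrix re-validates
  expect_true(is_clean(validate_transition_model(cfg$space, drifted)))

  # a base share above the cap is held at base with a warning
  expect_warning(
    apply_ltft_drift(cfg$model, cap = 0.20, start_year = 2023,
                     horizon = 2),
    "held at base")
})

test_that("scenario composition concatenates modifiers and flags conflicts", {
  scs <- builtin_scenarios()
  cfg <- default_configuration()

  # identity composition
  none <- compose_scenarios()
  out <- apply_scenario(none, cfg$model, cfg$inflows, 2023, 25)
  expect_equal(out$model$matrix, cfg$model$matrix)
  expect_equal(out$inflows$entries, cfg$inflows$entries)

  # composing a single scenario is that scenario
  solo <- compose_scenarios(scs$intake_ramp)
  a <- apply_scenario(solo, cfg$model, cfg$inflows, 2023, 25)
  b <- apply_scenario(scs$intake_ramp, cfg$model, cfg$inflows, 2023, 25)
  expect_equal(a$inflows$entries, b$inflows$entries)

  # conflicting overrides of the same cell group are rejected
  s1 <- scenario("a", list(mod_exit_override(list(stage = "FY2"),
                                             list(stage = "EXIT"), 0.05)))
  s2 <- scenario("b", list(mod_exit_override(list(stage = "FY2"),
                                             list(stage = "EXIT"), 0.10)))
  expect_error(compose_scenarios(s1, s2),
               class = "physupply_composition_error")
  # agreeing duplicates are fine
  expect_s3_class(compose_scenarios(s1, s1), "scenario")
})

test_that("scenario monotonicity laws hold under full projections", {
  cfg <- default_configuration()
  scs <- builtin_scenarios()
  run <- function(sc, horizon = 25) {
    mod <- apply_scenario(sc, cfg$model, cfg$inflows, cfg$start_year,
                          horizon)
    expect_true(is_clean(validate_transition_model(cfg$space, mod$model)))
    project(cfg$initial, mod$model, mod$inflows, cfg$start_year, horizon)
  }
  base <- run(scs$baseline)
  ramp <- run(scs$intake_ramp)
  exitr <- run(scs$exit_reduction)
  comb <- run(scs$combined)
  over <- run(scs$overseas_half)
  drift <- suppressWarnings(run(scs$ltft_drift))

  expect_true(all(ramp$supply$wte - base$supply$wte > -1e-9))
  expect_true(all(exitr$supply$wte - base$supply$wte > -1e-9))
  expect_true(all(over$supply$wte - base$supply$wte < 1e-9))
  expect_true(all(drift$supply$wte - base$supply$wte < 1e-9))
  # combining beats each single intervention every year
  expect_true(all(comb$supply$wte - ramp$supply$wte > -1e-9))
  expect_true(all(comb$supply$wte - exitr$supply$wte > -1e-9))
})
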