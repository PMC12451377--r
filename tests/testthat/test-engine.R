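test_that("identity dynamics leave populations constant", {
  space <- build_state_space()
  labels <- space$states$label
  ident <- diag(length(labels))
  dimnames(ident) <- list(labels, labels)
  model <- transition_model(space, ident, validate = FALSE)
  init <- setNames(rep(0, length(labels)), labels)
  init[c("MS1|-|-|1", "CONS|F|FT|1")] <- c(100, 50)
  # identity self-loops are off the allowed mask for some states, which
  # is a (warned) modelling defect but still propagates
  pr <- suppressWarnings(project(init, model, no_inflows(), 2023, 10))
  expect_true(all(apply(pr$populations, 1, identical, y = init)))
  expect_equal(max_conservation_error(pr), 0)
})

test_that("a deterministic chain delivers unit mass after its length", {
  space <- build_state_space()
  model <- chain_model(space)
  init <- setNames(rep(0, nrow(space$states)), space$states$label)
  init["MS1|-|-|1"] <- 1
  pr <- project(init, model, no_inflows(), 2023, 14)
  expect_equal(unname(pr$populations["2037", "CONS|F|FT|1"]), 1)
  expect_equal(sum(pr$populations["2037", ]), 1)
})

test_that("projection totals match a two-line loop oracle on the default configuration", {
  cfg <- default_configuration()
  pr <- project(cfg$initial, cfg$model, cfg$inflows, cfg$start_year, 25)
  exit_col <- match("EXIT|-|-|1", cfg$space$states$label)
  inflow_by_year <- lapply(1:25, function(t) {
    physupply:::inflows_for_year(cfg$inflows, cfg$start_year + t,
                                 cfg$space)
  })
  oracle <- oracle_project_totals(cfg$initial, cfg$model$matrix,
                                  inflow_by_year, exit_col, 25)
  expect_equal(unname(rowSums(pr$populations)[-1]), oracle,
               tolerance = 1e-9)
})

test_that("conservation, linearity and inflow monotonicity hold", {
  cfg <- default_configuration()
  pr <- project(cfg$initial, cfg$model, cfg$inflows, cfg$start_year, 25)
  expect_lt(max_conservation_error(pr), 1e-9)

  # linearity: projecting a sum equals summing projections
  pr0 <- project(cfg$initial * 0.3, cfg$model, no_inflows(),
                 cfg$start_year, 10)
  pr1 <- project(cfg$initial * 0.7, cfg$model, cfg$inflows,
                 cfg$start_year, 10)
  both <- project(cfg$initial, cfg$model, cfg$inflows, cfg$start_year, 10)
  expect_equal(pr0$populations + pr1$populations, both$populations,
               tolerance = 1e-9)

  # adding inflow never decreases any later population
  extra <- cfg$inflows$entries
  extra <- rbind(extra, data.frame(year = 2026, state = "IMT1|F|-|1",
                                   count = 500,
                                   channel = "REENTRY"))
  more <- project(cfg$initial, cfg$model, inflow_schedule(extra),
                  cfg$start_year, 25)
  expect_true(all(more$populations - pr$populations > -1e-9))
})

test_that("WTE aggregation weights LTFT consultants at 0.65", {
  space <- build_state_space()
  pop <- setNames(rep(0, nrow(space$states)), space$states$label)
  pop["CONS|F|FT|1"] <- 100
  expect_equal(wte_supply(pop, space), 100)
  pop["CONS|F|FT|1"] <- 0
  pop["CONS|M|LTFT|1"] <- 100
  expect_equal(wte_supply(pop, space), 65)
  pop["CONS|M|LTFT|1"] <- 31
  pop["CONS_RR|F|FT|1"] <- 69
  expect_equal(wte_supply(pop, space), 89.15)
  # trainees never count toward consultant supply
  pop["ST5|F|FT|1"] <- 1000
  expect_equal(wte_supply(pop, space), 89.15)
  expect_error(wte_supply(pop, space, ltft_weight = 0),
               class = "physupply_validation_error")
})

test_that("cohort tracing reproduces deterministic and geometric first-passage times", {
  space <- build_state_space()
  model <- chain_model(space)
  tr <- trace_cohort(1000, model, max_years = 40)
  expect_equal(tr$mean_years, 14)
  expect_equal(tr$sd_years, 0)
  expect_equal(tr$fraction_reaching, 1)
  expect_equal(tr$arrivals$arrival[14], 1000)

  # geometric dwell stages: mean equals the sum of 1/p_advance
  model <- chain_model(space, advance = c(ST3 = 0.5, MS3 = 2 / 3))
  tr <- trace_cohort(1, model, max_years = 250)
  expect_equal(tr$mean_years, 12 + 1 / 0.5 + 1 / (2 / 3),
               tolerance = 1e-9)

  # with per-year exit the arrival fraction is strictly below one
  cfg <- default_configuration()
  tr <- trace_cohort(10000, cfg$model, max_years = 60)
  expect_lt(tr$fraction_reaching, 1)
  expect_gt(tr$fraction_reaching, 0)
  expect_lte(sum(tr$arrivals$arrival), 10000)

  # an empty cohort yields an empty trace
  tr0 <- trace_cohort(0, cfg$model, max_years = 60)
  expect_true(all(tr0$arrivals$arrival == 0))
})

test_that("retire-and-return mass exits after exactly two cycles", {
  cfg <- default_configuration()
  init <- setNames(rep(0, nrow(cfg$space$states)), cfg$space$states$label)
  init["CONS_RR|F|LTFT|1"] <- 100
  pr <- project(init, cfg$model, no_inflows(), 2023, 3)
  rr <- state_labels(cfg$space, stage = "CONS_RR")
  expect_equal(sum(pr$populations["2024", rr]), 100)   # moved to dwell 2
  expect_equal(sum(pr$populations["2025", ]), 0)       # fully exited
  expect_equal(sum(pr$ledger$exit), 100)
})

test_that("post-CCT break mass becomes consultant after exactly one cycle", {
  cfg <- default_configuration()
  init <- setNames(rep(0, nrow(cfg$space$states)), cfg$space$states$label)
  init["BREAK_POST_CCT|M|FT|1"] <- 100
  pr <- project(init, cfg$model, no_inflows(), 2023, 1)
  cons <- state_labels(cfg$space, stage = "CONS")
  expect_equal(sum(pr$populations["2024", cons]), 100)
  expect_equal(sum(pr$populations["2024", ]) -
                 sum(pr$populations["2024", cons]), 0)
})

test_that("microsimulation agrees with the deterministic engine", {
  space <- build_state_space()
  labels <- space$states$label
  ident <- diag(length(labels))
  dimnames(ident) <- list(labels, labels)
  model <- transition_model(space, ident, validate = FALSE)
  init <- setNames(rep(0, length(labels)), labels)
  init[c("MS1|-|-|1", "CONS|F|FT|1")] <- c(600, 400)
  ms <- suppressWarnings(microsim(init, model, no_inflows(), 2023, 5,
                                  n_agents = 1000, seed = 3))
  pr <- suppressWarnings(project(init, model, no_inflows(), 2023, 5))
  expect_equal(ms$populations, pr$populations)  # identity: exact

  # determinism: same seed, same run
  cfg <- default_configuration()
  a <- microsim(cfg$initial, cfg$model, cfg$inflows, 2023, 8,
                n_agents = 20000, seed = 11)
  b <- microsim(cfg$initial, cfg$model, cfg$inflows, 2023, 8,
                n_agents = 20000, seed = 11)
  expect_identical(a$populations, b$populations)
  c <- microsim(cfg$initial, cfg$model, cfg$inflows, 2023, 8,
                n_agents = 20000, seed = 12)
  expect_false(identical(a$populations, c$populations))
})

test_that("backcast agreement arithmetic is a rounded ratio", {
  expect_equal(agreement_percent(21302, 22183)$percent, 96L)
  expect_equal(agreement_percent(20604, 21102)$percent, 98L)
  expect_equal(agreement_percent(12345, 12345)$percent, 100L)
  expect_equal(agreement_percent(21302, 22183)$raw, 100 * 21302 / 22183)
  expect_error(agreement_percent(10, 0), class = "physupply_domain_error")
})

test_that("degenerate projection inputs are rejected", {
  cfg <- default_configuration()
  bad <- cfg$initial
  bad[1] <- -5
  expect_error(project(bad, cfg$model, cfg$inflows, 2023, 5),
               class = "physupply_validation_error")
  expect_error(project(cfg$initial, cfg$model, cfg$inflows, 2023, 0),
               class = "physupply_validation_error")
  # an override failing row-stochasticity is caught before propagation
  ov <- cfg$model$matrix
  ov["FY1|F|-|1", "FY2|F|-|1"] <- 0.5
  model2 <- transition_model(cfg$space, cfg$model$matrix,
                             overrides = list(`2025` = ov),
                             validate = FALSE)
  expect_error(project(cfg$initial, model2, cfg$inflows, 2023, 5),
               class = "physupply_validation_error")
})
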