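# Synthetic data: (a) longitudinal person-year records drawn from a known
# ground-truth transition model, for estimator-recovery validation; and
# (b) an illustrative, paper-magnitude default configuration standing in
# for restricted registry inputs (UK medical-education and staff-record
# sources are not publicly available).

#' Generator specification
#'
#' @param truth A valid [transition_model()]: the ground truth from which
#'   annual states are drawn.
#' @param cohorts Named numeric vector: entry calendar year -> number of
#'   entrants.
#' @param entry Named probability vector over state labels giving the
#'   entry-state distribution (default: all mass on MS1).
#' @param sex_split Probability a person whose trajectory never reaches a
#'   sex-stratified state is recorded female (cosmetic; default 0.5).
#' @param seed Integer seed making generation reproducible.
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(truth, cohorts, entry = NULL, sex_split = 0.5,
                           seed = 1L) {
  rep <- validate_transition_model(truth$space, truth)
  if (!is_clean(rep)) {
    .phys_error("generator truth fails transition-model validation",
                "physupply_validation_error")
  }
  labels <- truth$space$states$label
  if (is.null(entry)) {
    entry <- stats::setNames(1, state_labels(truth$space, stage = "MS1"))
  }
  if (!all(names(entry) %in% labels)) {
    .phys_error("entry distribution names unknown states",
                "physupply_structural_error")
  }
  if (abs(sum(entry) - 1) > 1e-9 || any(entry < 0)) {
    .phys_error("entry distribution must be a probability vector",
                "physupply_validation_error")
  }
  if (is.null(names(cohorts))) {
    .phys_error("`cohorts` must be named by calendar year",
                "physupply_structural_error")
  }
  if (sex_split < 0 || sex_split > 1) {
    .phys_error("`sex_split` must lie in [0, 1]",
                "physupply_validation_error")
  }
  structure(list(truth = truth, cohorts = cohorts, entry = entry,
                 sex_split = sex_split, seed = as.integer(seed)),
            class = "generator_spec")
}

#' Generate longitudinal person-year records
#'
#' Simulates each person's annual states from the ground-truth model.
#' Years spent in temporary-break states appear as `ABSENT` runs of 1-2
#' years followed by the correct return stage; exits appear as permanent
#' absence.  Output is reproducible given the spec's seed.
#'
#' The attribute `"departures"` holds the generator's own break/exit
#' labels (one row per departure from training whose outcome is decided
#' within the observation window), against which
#' [classify_departure()] can be checked.
#'
#' @param spec A [generator_spec()].
#' @param n_years_observed Length of the observation window in years
#'   (>= 4, so the three-year look-ahead can classify at least the first
#'   cohort's departures).
#' @return data.frame with columns `person_id`, `year`, `stage`
#'   (`"ABSENT"` during breaks), `sex`, `ltft`; attribute `"departures"`.
#' @export
generate_records <- function(spec, n_years_observed) {
  if (n_years_observed < 4) {
    .phys_error("`n_years_observed` must be >= 4 (three-year look-ahead)",
                "physupply_config_error")
  }
  space <- spec$truth$space
  st <- space$states
  labels <- st$label
  n_states <- length(labels)
  exit_i <- match(exit_label(space), labels)
  m <- spec$truth$matrix

  cohort_years <- as.integer(names(spec$cohorts))
  y0 <- min(cohort_years)
  years <- y0 + seq_len(n_years_observed) - 1L
  n_persons <- sum(spec$cohorts)
  entry_year <- rep(cohort_years, times = spec$cohorts)

  with_seed(spec$seed, {
    entry_idx <- match(names(spec$entry), labels)
    entry_state <- entry_idx[sample.int(length(entry_idx), n_persons,
                                        replace = TRUE, prob = spec$entry)]
    # states[p, t]: state index of person p in year t; 0 = not entered or
    # exited
    states <- matrix(0L, n_persons, n_years_observed)
    cur <- rep(0L, n_persons)
    for (t in seq_len(n_years_observed)) {
      entering <- entry_year == years[t]
      cur[entering] <- entry_state[entering]
      states[, t] <- cur
      if (t < n_years_observed) {
        nxt <- cur
        for (s in sort(unique(cur[cur > 0L]))) {
          ix <- which(cur == s)
          nxt[ix] <- sample.int(n_states, length(ix), replace = TRUE,
                                prob = m[s, ])
        }
        cur <- nxt
        cur[cur == exit_i] <- 0L
      }
    }

    # person-level sex: the first sex-stratified state on the path, else a
    # coin flip
    sex_of_state <- st$sex
    person_sex <- apply(states, 1L, function(row) {
      sx <- sex_of_state[row[row > 0L]]
      sx <- sx[!is.na(sx)]
      if (length(sx)) sx[1] else NA_character_
    })
    nosex <- is.na(person_sex)
    person_sex[nosex] <- ifelse(
      stats::runif(sum(nosex)) < spec$sex_split, "F", "M")
  })

  is_break <- st$domain == "BREAK"
  keep <- which(states > 0L, arr.ind = TRUE)
  s_idx <- states[keep]
  rec <- data.frame(
    person_id = sprintf("p%06d", keep[, 1]),
    year = years[keep[, 2]],
    stage = ifelse(is_break[s_idx], "ABSENT", st$stage[s_idx]),
    sex = person_sex[keep[, 1]],
    ltft = ifelse(is.na(st$work_pattern[s_idx]), NA,
                  st$work_pattern[s_idx] == "LTFT"),
    stringsAsFactors = FALSE)
  rec$ltft[rec$stage == "ABSENT"] <- NA
  rec <- rec[order(rec$person_id, rec$year), ]
  rownames(rec) <- NULL

  # generator ground-truth departure labels
  in_training <- states > 0L & !is_break[pmax(states, 1L)]
  dim(in_training) <- dim(states)
  dep_person <- integer(0); dep_year <- integer(0); dep_label <- character(0)
  w <- n_years_observed
  for (t in seq_len(w - 1L)) {
    if (t + 3L > w) break   # outcome not decided inside the window
    dep <- which(in_training[, t] & !in_training[, t + 1L])
    if (!length(dep)) next
    back <- in_training[dep, t + 2L, drop = TRUE] |
      in_training[dep, t + 3L, drop = TRUE]
    dep_person <- c(dep_person, dep)
    dep_year <- c(dep_year, rep(years[t], length(dep)))
    dep_label <- c(dep_label, ifelse(back, "TEMPORARY_BREAK", "EXIT"))
  }
  attr(rec, "departures") <- data.frame(
    person_id = sprintf("p%06d", dep_person), year = dep_year,
    label = dep_label, stringsAsFactors = FALSE)
  rec
}

#' Write / read person-year record tables
#'
#' CSV with columns `person_id,year,stage,sex,ltft`; `ABSENT` is encoded
#' as an empty stage field.
#'
#' @param records Record table (see [validate_person_records()]).
#' @param path CSV path.
#' @export
write_person_records <- function(records, path) {
  out <- records
  out$stage[out$stage == "ABSENT"] <- ""
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_person_records
#' @export
read_person_records <- function(path) {
  if (!file.exists(path)) {
    .phys_error(sprintf("records file not found: %s", path),
                "physupply_config_error")
  }
  rec <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(person_id = "character"))
  rec$stage[is.na(rec$stage) | rec$stage == ""] <- "ABSENT"
  if (is.character(rec$ltft)) rec$ltft <- as.logical(rec$ltft)
  if (is.logical(rec$sex)) rec$sex <- as.character(rec$sex)
  validate_person_records(rec)
  rec
}

# ---------------------------------------------------------------------------
# Default configuration: an illustrative parameter set at the published
# 2023 magnitudes (consultant headcount ~22,000, WTE ~20,000, consultant
# LTFT 31%, specialty-training LTFT 25%, medical-school intake ~10,000,
# post-IMT exit ~32-33%).  It is NOT a calibrated reproduction of the
# restricted registry inputs; values not anchored to a published
# magnitude are plausible placeholders.

.default_matrix <- function(space, cons_ltft = 0.31, st_ltft = 0.25) {
  labels <- space$states$label
  m <- matrix(0, length(labels), length(labels),
              dimnames = list(labels, labels))
  L <- function(stage, sex = NA, wp = NA, dwell = 1L) {
    state_label(stage, sex, wp, dwell)
  }
  split_wp <- function(stage, sex, p, ltft_share, dwell = 1L) {
    stats::setNames(c(p * (1 - ltft_share), p * ltft_share),
                    c(L(stage, sex, "FT", dwell),
                      L(stage, sex, "LTFT", dwell)))
  }
  EXIT <- exit_label(space)

  # medical school (sex-pooled; intercalated MS6 branch off MS5)
  for (k in 1:4) {
    m <- set_row(m, L(paste0("MS", k)), stats::setNames(
      c(0.96, 0.02, 0.02),
      c(L(paste0("MS", k + 1)), L(paste0("MS", k)), EXIT)))
  }
  fy_split <- c(F = 0.55, M = 0.45)   # women slightly outnumber men
  m <- set_row(m, L("MS5"), stats::setNames(
    c(0.14, 0.82 * fy_split[["F"]], 0.82 * fy_split[["M"]], 0.02, 0.02),
    c(L("MS6"), L("FY1", "F"), L("FY1", "M"), L("MS5"), EXIT)))
  m <- set_row(m, L("MS6"), stats::setNames(
    c(0.97 * fy_split[["F"]], 0.97 * fy_split[["M"]], 0.03),
    c(L("FY1", "F"), L("FY1", "M"), EXIT)))

  for (s in c("F", "M")) {
    m <- set_row(m, L("FY1", s), stats::setNames(
      c(0.97, 0.03), c(L("FY2", s), EXIT)))
    # FY2 exit mass covers both leaving UK medical training (0.15) and
    # moving to non-physician specialties, which also leaves this model
    m <- set_row(m, L("FY2", s), stats::setNames(
      c(0.17, 0.03, 0.80),
      c(L("IMT1", s), L("BREAK_POST_FY", s, dwell = 1L), EXIT)))
    m <- set_row(m, L("IMT1", s), stats::setNames(
      c(0.95, 0.05), c(L("IMT2", s), EXIT)))
    # post-IMT exit ~32% (M) / 33% (F): changed specialty + stopped training
    imt_exit <- if (s == "M") 0.32 else 0.33
    st3 <- 1 - imt_exit - 0.06 - 0.10
    m <- set_row(m, L("IMT2", s), c(
      split_wp("ST3", s, st3, st_ltft),
      stats::setNames(c(0.06, 0.10, imt_exit),
                      c(L("IMT3", s), L("BREAK_POST_IMT", s, dwell = 1L),
                        EXIT))))
    st4 <- 1 - imt_exit - 0.08
    m <- set_row(m, L("IMT3", s), c(
      split_wp("ST4", s, st4, st_ltft),
      stats::setNames(c(0.08, imt_exit),
                      c(L("BREAK_POST_IMT", s, dwell = 1L), EXIT))))

    # specialty training: LTFT rows progress more slowly (longer dwell)
    for (k in 3:6) {
      nxt <- paste0("ST", k + 1)
      skip <- if (k <= 5) paste0("ST", k + 2) else NA
      # full time
      probs <- stats::setNames(
        c(0.72, 0.04, 0.06, 0.10),
        c(L(nxt, s, "FT"), L(nxt, s, "LTFT"),
          L("BREAK_POST_ST", s, dwell = 1L), EXIT))
      if (!is.na(skip)) {
        probs <- c(probs, stats::setNames(0.02, L(skip, s, "FT")))
        probs <- c(probs, stats::setNames(0.06, L(paste0("ST", k), s, "FT")))
      } else {
        probs <- c(probs, stats::setNames(0.08, L(paste0("ST", k), s, "FT")))
      }
      m <- set_row(m, L(paste0("ST", k), s, "FT"), probs)
      # less than full time
      probs <- stats::setNames(
        c(0.55, 0.03, 0.06, 0.10),
        c(L(nxt, s, "LTFT"), L(nxt, s, "FT"),
          L("BREAK_POST_ST", s, dwell = 1L), EXIT))
      if (!is.na(skip)) {
        probs <- c(probs, stats::setNames(0.01, L(skip, s, "LTFT")))
        probs <- c(probs,
                   stats::setNames(0.25, L(paste0("ST", k), s, "LTFT")))
      } else {
        probs <- c(probs,
                   stats::setNames(0.26, L(paste0("ST", k), s, "LTFT")))
      }
      m <- set_row(m, L(paste0("ST", k), s, "LTFT"), probs)
    }

    # ST7: CCT completion combined with post-CCT destination survey split;
    # consultant-entry work pattern follows the initial consultant LTFT
    # proportion regardless of prior pattern
    for (wp in c("FT", "LTFT")) {
      p_complete <- if (wp == "FT") 0.80 else 0.65
      cct <- split_cct(p_complete, f_direct = 0.82, f_break1 = 0.08,
                       f_leave = 0.10)
      resid <- 1 - p_complete
      self_p <- if (wp == "FT") 0.12 else 0.25
      probs <- c(
        split_wp("CONS", s, cct[["to_cons"]], cons_ltft),
        split_wp("BREAK_POST_CCT", s, cct[["to_break_post_cct"]],
                 cons_ltft),
        stats::setNames(
          c(self_p, cct[["to_exit"]] + (resid - self_p)),
          c(L("ST7", s, wp), EXIT)))
      m <- set_row(m, L("ST7", s, wp), probs)
    }

    # temporary breaks: return to the stage that would have followed
    m <- set_row(m, L("BREAK_POST_FY", s, dwell = 1L), stats::setNames(
      c(0.55, 0.30, 0.15),
      c(L("IMT1", s), L("BREAK_POST_FY", s, dwell = 2L), EXIT)))
    m <- set_row(m, L("BREAK_POST_FY", s, dwell = 2L), stats::setNames(
      c(0.55, 0.45), c(L("IMT1", s), EXIT)))
    m <- set_row(m, L("BREAK_POST_IMT", s, dwell = 1L), c(
      split_wp("ST3", s, 0.38, st_ltft), split_wp("ST4", s, 0.10, st_ltft),
      stats::setNames(c(0.32, 0.20),
                      c(L("BREAK_POST_IMT", s, dwell = 2L), EXIT))))
    m <- set_row(m, L("BREAK_POST_IMT", s, dwell = 2L), c(
      split_wp("ST3", s, 0.38, st_ltft), split_wp("ST4", s, 0.10, st_ltft),
      stats::setNames(0.52, EXIT)))
    ret <- do.call(c, lapply(paste0("ST", 4:7), split_wp, sex = s,
                             p = 0.12, ltft_share = st_ltft))
    m <- set_row(m, L("BREAK_POST_ST", s, dwell = 1L), c(
      ret, stats::setNames(c(0.32, 0.20),
                           c(L("BREAK_POST_ST", s, dwell = 2L), EXIT))))
    m <- set_row(m, L("BREAK_POST_ST", s, dwell = 2L), c(
      ret, stats::setNames(0.52, EXIT)))
    for (wp in c("FT", "LTFT")) {
      m <- set_row(m, L("BREAK_POST_CCT", s, wp), split_wp("CONS", s, 1,
                                                           cons_ltft))
    }

    # consultants: total exit decomposed into retire-and-return and direct
    total_exit <- if (s == "M") 0.050 else 0.046
    rr <- if (s == "M") 0.012 else 0.010
    dec <- consultant_exit_decomposition(total_exit, rr)
    for (wp in c("FT", "LTFT")) {
      other <- if (wp == "FT") "LTFT" else "FT"
      m <- set_row(m, L("CONS", s, wp), stats::setNames(
        c(dec$stay * 0.98, dec$stay * 0.02, dec$to_cons_rr, dec$to_exit),
        c(L("CONS", s, wp), L("CONS", s, other),
          L("CONS_RR", s, wp, 1L), EXIT)))
      m <- set_row(m, L("CONS_RR", s, wp, 1L), stats::setNames(
        1, L("CONS_RR", s, wp, 2L)))
      m <- set_row(m, L("CONS_RR", s, wp, 2L), stats::setNames(1, EXIT))
    }
  }
  m <- set_row(m, EXIT, stats::setNames(1, EXIT))
  m
}

.default_initial <- function(space) {
  labels <- space$states$label
  v <- stats::setNames(rep(0, length(labels)), labels)
  L <- function(...) state_label(...)
  v[L("MS1", NA, NA, 1L)] <- 10000
  v[L("MS2", NA, NA, 1L)] <- 9800
  v[L("MS3", NA, NA, 1L)] <- 9600
  v[L("MS4", NA, NA, 1L)] <- 9400
  v[L("MS5", NA, NA, 1L)] <- 9200
  v[L("MS6", NA, NA, 1L)] <- 1300
  fy1 <- c(F = 5340, M = 4360); fy2 <- c(F = 5230, M = 4270)
  imt1 <- c(F = 880, M = 720); imt2 <- c(F = 850, M = 700)
  imt3 <- c(F = 50, M = 42)
  st_ft <- c(F = 650, M = 550); st_lt <- c(F = 270, M = 130)
  cons <- c(F = 9800, M = 11600)
  for (s in c("F", "M")) {
    v[L("FY1", s, NA, 1L)] <- fy1[[s]]
    v[L("FY2", s, NA, 1L)] <- fy2[[s]]
    v[L("IMT1", s, NA, 1L)] <- imt1[[s]]
    v[L("IMT2", s, NA, 1L)] <- imt2[[s]]
    v[L("IMT3", s, NA, 1L)] <- imt3[[s]]
    for (k in 3:7) {
      v[L(paste0("ST", k), s, "FT", 1L)] <- st_ft[[s]]
      v[L(paste0("ST", k), s, "LTFT", 1L)] <- st_lt[[s]]
    }
    v[L("BREAK_POST_FY", s, NA, 1L)] <- if (s == "F") 80 else 65
    v[L("BREAK_POST_FY", s, NA, 2L)] <- if (s == "F") 25 else 20
    v[L("BREAK_POST_IMT", s, NA, 1L)] <- if (s == "F") 85 else 70
    v[L("BREAK_POST_IMT", s, NA, 2L)] <- if (s == "F") 28 else 22
    v[L("BREAK_POST_ST", s, NA, 1L)] <- if (s == "F") 50 else 30
    v[L("BREAK_POST_ST", s, NA, 2L)] <- if (s == "F") 16 else 10
    v[L("BREAK_POST_CCT", s, "FT", 1L)] <- if (s == "F") 30 else 25
    v[L("BREAK_POST_CCT", s, "LTFT", 1L)] <- if (s == "F") 14 else 11
    # consultants: 31% LTFT, retire-and-return stock split over its
    # two-year dwell
    v[L("CONS", s, "FT", 1L)] <- cons[[s]] * 0.69
    v[L("CONS", s, "LTFT", 1L)] <- cons[[s]] * 0.31
    for (d in 1:2) {
      v[L("CONS_RR", s, "FT", d)] <- 104
      v[L("CONS_RR", s, "LTFT", d)] <- 46
    }
  }
  v
}

.default_inflows <- function(space, years) {
  L <- function(...) state_label(...)
  row <- function(state, count, channel) {
    data.frame(year = years, state = state, count = count,
               channel = channel, stringsAsFactors = FALSE)
  }
  entries <- rbind(
    row(L("MS1", NA, NA, 1L), 10000, "DOMESTIC_INTAKE"),
    # re-entry after >2-year training gaps
    row(L("IMT1", "F", NA, 1L), 30, "REENTRY"),
    row(L("IMT1", "M", NA, 1L), 25, "REENTRY"),
    row(L("ST3", "F", "FT", 1L), 20, "REENTRY"),
    row(L("ST3", "M", "FT", 1L), 15, "REENTRY"),
    # overseas doctors entering training and consultant posts
    row(L("IMT1", "F", NA, 1L), 110, "OVERSEAS"),
    row(L("IMT1", "M", NA, 1L), 90, "OVERSEAS"),
    row(L("ST3", "F", "FT", 1L), 120, "OVERSEAS"),
    row(L("ST3", "M", "FT", 1L), 100, "OVERSEAS"),
    row(L("ST3", "F", "LTFT", 1L), 50, "OVERSEAS"),
    row(L("ST3", "M", "LTFT", 1L), 30, "OVERSEAS"),
    row(L("ST4", "F", "FT", 1L), 120, "OVERSEAS"),
    row(L("ST4", "M", "FT", 1L), 100, "OVERSEAS"),
    row(L("ST4", "F", "LTFT", 1L), 50, "OVERSEAS"),
    row(L("ST4", "M", "LTFT", 1L), 30, "OVERSEAS"),
    row(L("CONS", "F", "FT", 1L), 170, "OVERSEAS"),
    row(L("CONS", "M", "FT", 1L), 180, "OVERSEAS"),
    row(L("CONS", "F", "LTFT", 1L), 80, "OVERSEAS"),
    row(L("CONS", "M", "LTFT", 1L), 70, "OVERSEAS"),
    # portfolio (non-training) route to consultant posts
    row(L("CONS", "F", "FT", 1L), 80, "PORTFOLIO"),
    row(L("CONS", "M", "FT", 1L), 90, "PORTFOLIO"),
    row(L("CONS", "F", "LTFT", 1L), 45, "PORTFOLIO"),
    row(L("CONS", "M", "LTFT", 1L), 35, "PORTFOLIO")
  )
  inflow_schedule(entries)
}

#' Default model configuration
#'
#' A complete, validated configuration of the projection model at
#' published 2023 magnitudes: ~22,000 consultant headcount (~20,000 WTE
#' at 31% LTFT and 0.65 WTE per LTFT consultant), ~10,000 annual
#' medical-school places, 25% specialty-training LTFT, post-IMT exit of
#' 32-33%, and base demand of 20,935 WTE growing at 1.8% (medium) or
#' 2.4% (high) per year.  It is illustrative -- NOT the calibrated input
#' set estimated from restricted registry data -- and is the
#' configuration against which the built-in scenarios are defined.
#'
#' @param start_year First projection year (default 2023).
#' @param horizon Projection horizon in years (default 25).
#' @return List with elements `space`, `initial`, `model`, `inflows`,
#'   `demand_medium`, `demand_high`, `start_year`, `horizon`,
#'   `ltft_weight`.
#' @export
default_configuration <- function(start_year = 2023L, horizon = 25L) {
  space <- build_state_space()
  model <- transition_model(space, .default_matrix(space))
  initial <- .default_initial(space)
  inflow_years <- start_year + 0:max(horizon, 40L)
  list(space = space, initial = initial, model = model,
       inflows = .default_inflows(space, inflow_years),
       demand_medium = demand_config(base_year = start_year,
                                     growth = 0.018, label = "medium"),
       demand_high = demand_config(base_year = start_year,
                                   growth = 0.024, label = "high"),
       start_year = as.integer(start_year), horizon = as.integer(horizon),
       ltft_weight = 0.65)
}

# ---------------------------------------------------------------------------
# Recovery fixture: a ground-truth model designed for estimator-recovery
# checks at 50,000 persons.  Mid-range probabilities sit only on rows
# whose person-year denominators make a +/-0.01 error bound comfortable
# at binomial sampling noise; thinly occupied rows (break dwell chains,
# post-CCT, retire-and-return) are degenerate and estimate exactly.

.recovery_matrix <- function(space) {
  labels <- space$states$label
  m <- matrix(0, length(labels), length(labels),
              dimnames = list(labels, labels))
  L <- function(stage, sex = NA, wp = NA, dwell = 1L) {
    state_label(stage, sex, wp, dwell)
  }
  EXIT <- exit_label(space)
  m <- set_row(m, L("MS1", NA, NA, 1L), stats::setNames(
    c(0.96, 0.02, 0.02), c(L("MS2", NA, NA, 1L), L("MS1", NA, NA, 1L),
                           EXIT)))
  for (k in 2:4) {
    m <- set_row(m, L(paste0("MS", k), NA, NA, 1L),
                 stats::setNames(1, L(paste0("MS", k + 1), NA, NA, 1L)))
  }
  m <- set_row(m, L("MS5", NA, NA, 1L), stats::setNames(
    c(0.49, 0.49, 0.02), c(L("FY1", "F"), L("FY1", "M"), EXIT)))
  for (s in c("F", "M")) {
    m <- set_row(m, L("FY1", s), stats::setNames(
      c(0.97, 0.03), c(L("FY2", s), EXIT)))
    m <- set_row(m, L("FY2", s), stats::setNames(
      c(0.85, 0.10, 0.05),
      c(L("IMT1", s), L("BREAK_POST_FY", s, dwell = 1L), EXIT)))
    # post-FY breaks always run the full two-year dwell
    m <- set_row(m, L("BREAK_POST_FY", s, dwell = 1L),
                 stats::setNames(1, L("BREAK_POST_FY", s, dwell = 2L)))
    m <- set_row(m, L("BREAK_POST_FY", s, dwell = 2L),
                 stats::setNames(1, L("IMT1", s)))
    m <- set_row(m, L("IMT1", s), stats::setNames(1, L("IMT2", s)))
    m <- set_row(m, L("IMT2", s), stats::setNames(
      c(0.95, 0.02, 0.02, 0.01),
      c(L("ST3", s, "FT"), L("ST3", s, "LTFT"),
        L("BREAK_POST_IMT", s, dwell = 1L), EXIT)))
    m <- set_row(m, L("BREAK_POST_IMT", s, dwell = 1L),
                 stats::setNames(1, L("ST3", s, "FT")))
    m <- set_row(m, L("BREAK_POST_IMT", s, dwell = 2L),
                 stats::setNames(1, L("ST3", s, "FT")))
    m <- set_row(m, L("IMT3", s), stats::setNames(1, L("ST4", s, "FT")))
    m <- set_row(m, L("ST3", s, "FT"), stats::setNames(
      c(0.94, 0.02, 0.02, 0.02),
      c(L("ST4", s, "FT"), L("ST5", s, "FT"), L("ST3", s, "FT"), EXIT)))
    m <- set_row(m, L("ST3", s, "LTFT"), stats::setNames(
      c(0.95, 0.02, 0.01, 0.02),
      c(L("ST4", s, "LTFT"), L("ST3", s, "LTFT"), L("ST4", s, "FT"),
        EXIT)))
    m <- set_row(m, L("ST4", s, "FT"), stats::setNames(
      c(0.95, 0.02, 0.03),
      c(L("ST5", s, "FT"), L("ST6", s, "FT"), EXIT)))
    m <- set_row(m, L("ST4", s, "LTFT"), stats::setNames(
      c(0.96, 0.02, 0.02),
      c(L("ST5", s, "LTFT"), L("ST4", s, "LTFT"), EXIT)))
    m <- set_row(m, L("ST5", s, "FT"), stats::setNames(
      c(0.94, 0.02, 0.02, 0.02),
      c(L("ST6", s, "FT"), L("ST7", s, "FT"),
        L("BREAK_POST_ST", s, dwell = 1L), EXIT)))
    m <- set_row(m, L("ST5", s, "LTFT"), stats::setNames(
      c(0.96, 0.02, 0.02),
      c(L("ST6", s, "LTFT"), L("ST5", s, "LTFT"), EXIT)))
    # breaks at ST level here only follow ST5, so the return is ST6
    m <- set_row(m, L("BREAK_POST_ST", s, dwell = 1L),
                 stats::setNames(1, L("ST6", s, "FT")))
    m <- set_row(m, L("BREAK_POST_ST", s, dwell = 2L),
                 stats::setNames(1, L("ST6", s, "FT")))
    m <- set_row(m, L("ST6", s, "FT"), stats::setNames(
      c(0.97, 0.03), c(L("ST7", s, "FT"), EXIT)))
    m <- set_row(m, L("ST6", s, "LTFT"), stats::setNames(
      c(0.97, 0.03), c(L("ST7", s, "LTFT"), EXIT)))
    m <- set_row(m, L("ST7", s, "FT"), stats::setNames(
      c(0.93, 0.02, 0.02, 0.03),
      c(L("CONS", s, "FT"), L("CONS", s, "LTFT"),
        L("BREAK_POST_CCT", s, "FT"), EXIT)))
    m <- set_row(m, L("ST7", s, "LTFT"), stats::setNames(
      c(0.95, 0.02, 0.03),
      c(L("CONS", s, "LTFT"), L("BREAK_POST_CCT", s, "LTFT"), EXIT)))
    for (wp in c("FT", "LTFT")) {
      m <- set_row(m, L("BREAK_POST_CCT", s, wp),
                   stats::setNames(1, L("CONS", s, wp)))
      m <- set_row(m, L("CONS", s, wp), stats::setNames(
        c(0.95, 0.02, 0.03),
        c(L("CONS", s, wp), L("CONS_RR", s, wp, 1L), EXIT)))
      m <- set_row(m, L("CONS_RR", s, wp, 1L),
                   stats::setNames(1, L("CONS_RR", s, wp, 2L)))
      m <- set_row(m, L("CONS_RR", s, wp, 2L), stats::setNames(1, EXIT))
    }
  }
  m <- set_row(m, EXIT, stats::setNames(1, EXIT))
  m
}

#' Recovery fixture for estimator validation
#'
#' A [generator_spec()] whose ground truth is designed so that, with
#' `n_persons` people observed over 20 years, every transition
#' probability of at least 0.02 on an occupied row can be recovered
#' within +/-0.01 of truth at binomial sampling noise.  70% of persons
#' enter at MS1; 30% enter directly into the ST3 LTFT strata so the
#' less-than-full-time rows are well occupied.  The intercalated MS6
#' branch is switched off.
#'
#' @param n_persons Number of simulated persons (default 50,000).
#' @param start_year Entry calendar year of the single cohort.
#' @param seed Integer seed.
#' @return A `generator_spec` whose `truth` field is the ground-truth
#'   [transition_model()].
#' @export
recovery_generator_spec <- function(n_persons = 50000L,
                                    start_year = 2000L, seed = 1L) {
  space <- build_state_space(include_ms6 = FALSE)
  truth <- transition_model(space, .recovery_matrix(space))
  entry <- stats::setNames(
    c(0.70, 0.15, 0.15),
    c(state_label("MS1", NA, NA, 1L),
      state_label("ST3", "F", "LTFT", 1L),
      state_label("ST3", "M", "LTFT", 1L)))
  generator_spec(truth,
                 cohorts = stats::setNames(n_persons,
                                           as.character(start_year)),
                 entry = entry, seed = seed)
}
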