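# Policy scenarios as composable modifiers of the inflow schedule and the
# transition model: medical-school intake ramp, reduced exit from
# training, overseas inflow scaling and less-than-full-time drift.

#' Linear medical-school intake ramp
#'
#' Replaces the DOMESTIC_INTAKE entries into MS1 with a linear ramp from
#' `start_places` in `start_year` to `end_places` in `end_year`, holding
#' `end_places` afterwards.  Other channels and states are untouched.
#'
#' @param inflows An [inflow_schedule()].
#' @param start_year,end_year Ramp interval (`end_year > start_year`).
#' @param start_places,end_places Annual MS1 places at the interval ends.
#' @return A modified `inflow_schedule`.
#' @examples
#' # midpoint of a 10,000 -> 17,000 ramp over 2023-2031 is 13,500 in 2027
#' @export
apply_intake_ramp <- function(inflows, start_year = 2023L,
                              end_year = 2031L, start_places = 10000,
                              end_places = 17000) {
  if (end_year <= start_year) {
    .phys_error("`end_year` must exceed `start_year`",
                "physupply_validation_error")
  }
  if (start_places < 0 || end_places < 0) {
    .phys_error("places must be >= 0", "physupply_validation_error")
  }
  e <- inflows$entries
  is_ms1 <- grepl("^MS1\\|", e$state) & e$channel == "DOMESTIC_INTAKE"
  if (!any(is_ms1)) {
    .phys_error("inflow schedule has no DOMESTIC_INTAKE entries into MS1",
                "physupply_config_error")
  }
  frac <- pmin(pmax((e$year - start_year) / (end_year - start_year), 0), 1)
  ramp <- start_places + (end_places - start_places) * frac
  e$count[is_ms1] <- ramp[is_ms1]
  inflow_schedule(e)
}

#' Reduce (or override) departure mass in transition rows
#'
#' Sets the summed probability mass on a destination group of each
#' selected origin row to `new_prob`; the freed mass is added to the
#' row's progression destinations -- forward-stage moves, excluding EXIT,
#' break states and self-loops -- proportionally to their existing
#' shares, modelling improved progression through training.
#'
#' @param model A [transition_model()] (the base matrix is modified).
#' @param origin Selector list for origin rows, passed to
#'   [state_labels()] (e.g. `list(stage = c("IMT2", "IMT3"))`).
#' @param destination Selector list for the departure destination group
#'   (e.g. `list(stage = "EXIT")`).
#' @param new_prob New summed probability for the group, in \[0, 1\].
#' @return A modified `transition_model`.
#' @examples
#' # a row (progress 0.84, exit 0.16) with exit overridden to 0.05
#' # becomes (0.95, 0.05)
#' @export
apply_exit_reduction <- function(model, origin, destination, new_prob) {
  if (new_prob < 0 || new_prob > 1) {
    .phys_error("`new_prob` must lie in [0, 1]",
                "physupply_validation_error")
  }
  space <- model$space
  st <- space$states
  rows <- do.call(state_labels, c(list(space), origin))
  cols <- do.call(state_labels, c(list(space), destination))
  if (!length(rows) || !length(cols)) {
    .phys_error("origin or destination group selects no states",
                "physupply_validation_error")
  }
  m <- model$matrix
  meta <- stage_table()
  stage_ord <- stats::setNames(seq_len(nrow(meta)), meta$stage)
  for (r in rows) {
    cur <- sum(m[r, cols])
    freed <- cur - new_prob
    r_stage <- st$stage[st$label == r]
    # progression destinations: positive-mass forward-stage moves
    dest_stage <- st$stage[match(colnames(m), st$label)]
    prog <- m[r, ] > 0 & !colnames(m) %in% cols &
      dest_stage != "EXIT" &
      !dest_stage %in% c("BREAK_POST_FY", "BREAK_POST_IMT",
                         "BREAK_POST_ST", "BREAK_POST_CCT") &
      dest_stage != r_stage
    p_tot <- sum(m[r, prog])
    if (abs(freed) < 1e-15) next
    if (p_tot <= 0) {
      .phys_error(sprintf(
        "row %s has no progression destination to absorb the freed mass", r),
        "physupply_override_error")
    }
    if (cur > 0) {
      m[r, cols] <- m[r, cols] * (new_prob / cur)
    } else {
      # no existing mass on the group: place it all on its first member
      m[r, cols[1]] <- new_prob
    }
    m[r, prog] <- m[r, prog] * ((p_tot + freed) / p_tot)
  }
  transition_model(space, m, model$overrides)
}

#' Scale overseas inflow entries
#'
#' Multiplies every OVERSEAS-channel entry by `factor`; other channels
#' are untouched.
#'
#' @param inflows An [inflow_schedule()].
#' @param factor Scaling factor (>= 0); 0.5 halves the overseas intake.
#' @return A modified `inflow_schedule`.
#' @export
apply_overseas_scaling <- function(inflows, factor) {
  if (factor < 0) {
    .phys_error("`factor` must be >= 0", "physupply_validation_error")
  }
  e <- inflows$entries
  e$count[e$channel == "OVERSEAS"] <- e$count[e$channel == "OVERSEAS"] *
    factor
  inflow_schedule(e)
}

#' Less-than-full-time drift
#'
#' For each projection year `t >= start_year`, the LTFT share of each
#' affected destination pair -- progressions into specialty-training
#' levels and consultant entry -- becomes
#' `min(base_share + increment * (t - start_year), cap)`, with the FT
#' share reduced correspondingly; the total progression mass of each row
#' is unchanged.  Increments are additive percentage points per year by
#' default; `relative = TRUE` compounds them multiplicatively instead.
#' Rows whose base share already exceeds the cap are held at base with a
#' warning.
#'
#' @param model A [transition_model()].
#' @param st_increment Annual increase of the LTFT share of
#'   specialty-training progressions (fraction/year; default 0.01).
#' @param cons_increment Annual increase of the LTFT share of consultant
#'   entry (default 0.05).
#' @param cap Maximum LTFT share (default 0.70).
#' @param start_year First projection year of the drift.
#' @param horizon Projection horizon (years beyond `start_year`).
#' @param relative Interpret increments as relative growth rates instead
#'   of additive percentage points?
#' @return A `transition_model` with per-year overrides for
#'   `start_year + 1 ... start_year + horizon`.
#' @export
apply_ltft_drift <- function(model, st_increment = 0.01,
                             cons_increment = 0.05, cap = 0.70,
                             start_year, horizon, relative = FALSE) {
  if (st_increment < 0 || cons_increment < 0) {
    .phys_error("increments must be >= 0", "physupply_validation_error")
  }
  if (cap <= 0 || cap > 1) {
    .phys_error("`cap` must lie in (0, 1]", "physupply_validation_error")
  }
  space <- model$space
  st <- space$states
  # destination pairs differing only in work pattern
  patterned <- !is.na(st$work_pattern)
  pair_key <- state_label(st$stage, st$sex, NA, st$dwell)
  pairs <- split(which(patterned), pair_key[patterned])
  pairs <- Filter(function(ix) length(ix) == 2L, pairs)
  pair_stage <- vapply(pairs, function(ix) st$stage[ix[1]], character(1))
  keep <- pair_stage %in% c(paste0("ST", 3:7), "CONS")
  pairs <- pairs[keep]
  pair_stage <- pair_stage[keep]

  warned <- FALSE
  overrides <- model$overrides
  for (t in seq_len(horizon)) {
    yr <- start_year + t
    m <- resolve_matrix(model, yr)
    for (k in seq_along(pairs)) {
      ix <- pairs[[k]]
      ft_i <- ix[st$work_pattern[ix] == "FT"]
      lt_i <- ix[st$work_pattern[ix] == "LTFT"]
      inc <- if (pair_stage[k] == "CONS") cons_increment else st_increment
      tot <- m[, ft_i] + m[, lt_i]
      # progressions and consultant entry only: stays/repeats (origin at
      # the pair's own stage) keep their work-pattern mix
      rows <- which(tot > 0 & st$stage != pair_stage[k])
      for (r in rows) {
        base <- m[r, lt_i] / tot[r]
        if (base > cap) {
          if (!warned) {
            warning("base LTFT share exceeds the cap for some transitions; held at base")
            warned <- TRUE
          }
          next
        }
        share <- if (relative) base * (1 + inc)^t else base + inc * t
        share <- min(share, cap)
        m[r, lt_i] <- share * tot[r]
        m[r, ft_i] <- (1 - share) * tot[r]
      }
    }
    overrides[[as.character(yr)]] <- m
  }
  transition_model(space, model$matrix, overrides)
}

#' Scenario objects and composition
#'
#' A scenario is a named, ordered list of modifier specifications, each
#' created by one of `mod_intake_ramp()`, `mod_exit_override()`,
#' `mod_overseas_scaling()` or `mod_ltft_drift()`.  [apply_scenario()]
#' applies the modifiers in order to a model and inflow schedule;
#' [compose_scenarios()] concatenates scenarios, failing if two exit
#' overrides target the same cell with different values.
#'
#' @param name Scenario label.
#' @param modifiers List of modifier specs.
#' @return An object of class `scenario`.
#' @export
scenario <- function(name, modifiers = list()) {
  structure(list(name = name, modifiers = modifiers), class = "scenario")
}

#' @rdname scenario
#' @inheritParams apply_intake_ramp
#' @export
mod_intake_ramp <- function(start_year = 2023L, end_year = 2031L,
                            start_places = 10000, end_places = 17000) {
  list(type = "intake_ramp", start_year = start_year, end_year = end_year,
       start_places = start_places, end_places = end_places)
}

#' @rdname scenario
#' @inheritParams apply_exit_reduction
#' @export
mod_exit_override <- function(origin, destination, new_prob) {
  list(type = "exit_override", origin = origin, destination = destination,
       new_prob = new_prob)
}

#' @rdname scenario
#' @inheritParams apply_overseas_scaling
#' @export
mod_overseas_scaling <- function(factor) {
  list(type = "overseas_scaling", factor = factor)
}

#' @rdname scenario
#' @inheritParams apply_ltft_drift
#' @export
mod_ltft_drift <- function(st_increment = 0.01, cons_increment = 0.05,
                           cap = 0.70, relative = FALSE) {
  list(type = "ltft_drift", st_increment = st_increment,
       cons_increment = cons_increment, cap = cap, relative = relative)
}

#' @export
print.scenario <- function(x, ...) {
  cat("<scenario>", x$name, "-", length(x$modifiers), "modifier(s):",
      paste(vapply(x$modifiers, `[[`, "", "type"), collapse = ", "), "\n")
  invisible(x)
}

#' Compose scenarios
#'
#' @param ... Scenarios, applied in order; `compose_scenarios()` with no
#'   arguments returns the identity scenario.
#' @param name Name of the composite (default: names joined with `+`).
#' @return A `scenario`.
#' @export
compose_scenarios <- function(..., name = NULL) {
  parts <- list(...)
  if (is.null(name)) {
    name <- if (length(parts)) {
      paste(vapply(parts, `[[`, "", "name"), collapse = "+")
    } else "identity"
  }
  mods <- do.call(c, c(lapply(parts, `[[`, "modifiers"), list(list())))
  # conflicting exit overrides: same origin/destination, different value
  ex <- Filter(function(m) m$type == "exit_override", mods)
  if (length(ex) > 1) {
    keys <- vapply(ex, function(m) {
      paste(paste(deparse(m$origin), collapse = ""),
            paste(deparse(m$destination), collapse = ""))
    }, character(1))
    for (k in unique(keys[duplicated(keys)])) {
      vals <- vapply(ex[keys == k], `[[`, numeric(1), "new_prob")
      if (length(unique(vals)) > 1) {
        .phys_error(sprintf(
          "conflicting exit overrides for the same cell group: %s", k),
          "physupply_composition_error")
      }
    }
  }
  scenario(name, mods)
}

#' Apply a scenario to a model and inflow schedule
#'
#' @param sc A [scenario()].
#' @param model A [transition_model()].
#' @param inflows An [inflow_schedule()].
#' @param start_year First projection year.
#' @param horizon Projection horizon in years.
#' @return List with modified `model` and `inflows`.
#' @export
apply_scenario <- function(sc, model, inflows, start_year, horizon) {
  for (m in sc$modifiers) {
    switch(m$type,
      intake_ramp = {
        inflows <- apply_intake_ramp(inflows, m$start_year, m$end_year,
                                     m$start_places, m$end_places)
      },
      exit_override = {
        model <- apply_exit_reduction(model, m$origin, m$destination,
                                      m$new_prob)
      },
      overseas_scaling = {
        inflows <- apply_overseas_scaling(inflows, m$factor)
      },
      ltft_drift = {
        model <- apply_ltft_drift(model, m$st_increment, m$cons_increment,
                                  m$cap, start_year, horizon, m$relative)
      },
      .phys_error(sprintf("unknown modifier type '%s'", m$type),
                  "physupply_config_error")
    )
  }
  list(model = model, inflows = inflows)
}

#' Built-in policy scenarios
#'
#' The five packaged scenarios, defined against the default
#' configuration: `baseline` (no modifiers), `intake_ramp`
#' (medical-school places 10,000 to 17,000 by 2031), `exit_reduction`
#' (post-IMT exit mass to 10%, i.e. both 16% components to 5%; post-FY
#' leaving component 15% to 5%, reducing that row's exit mass from 80% to
#' 70%), `combined` (ramp + exit reduction), `overseas_half` (overseas
#' inflow halved) and `ltft_drift` (+1pp/year specialty-training LTFT,
#' +5pp/year consultant-entry LTFT, capped at 70%).
#'
#' @return Named list of [scenario()] objects.
#' @export
builtin_scenarios <- function() {
  ramp <- scenario("intake_ramp", list(mod_intake_ramp()))
  exit_red <- scenario("exit_reduction", list(
    mod_exit_override(origin = list(stage = c("IMT2", "IMT3")),
                      destination = list(stage = "EXIT"), new_prob = 0.10),
    mod_exit_override(origin = list(stage = "FY2"),
                      destination = list(stage = "EXIT"), new_prob = 0.70)))
  list(
    baseline = scenario("baseline"),
    intake_ramp = ramp,
    exit_reduction = exit_red,
    combined = compose_scenarios(ramp, exit_red, name = "combined"),
    overseas_half = scenario("overseas_half",
                             list(mod_overseas_scaling(0.5))),
    ltft_drift = scenario("ltft_drift", list(mod_ltft_drift()))
  )
}
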