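# Deterministic annual projection engine, WTE aggregation, single-cohort
# tracing, an agent-level microsimulation cross-check and backcast
# agreement.
#
# Cycle order: the population is redistributed by the year's transition
# matrix, mass arriving in EXIT is moved to the outflow ledger, then the
# year's external inflow is added (new entrants make their first
# transition the following year).  Populations are continuous; nothing is
# rounded before reporting.

#' Inflow schedule
#'
#' Per-year, per-state external entries, each tagged by source channel.
#'
#' @param entries data.frame with columns `year`, `state` (a state
#'   label), `count` (>= 0) and `channel` (one of `DOMESTIC_INTAKE`,
#'   `OVERSEAS`, `PORTFOLIO`, `REENTRY`).
#' @return An object of class `inflow_schedule`.
#' @export
inflow_schedule <- function(entries) {
  need <- c("year", "state", "count", "channel")
  miss <- setdiff(need, names(entries))
  if (length(miss)) {
    .phys_error(paste("inflow entries missing column(s):",
                      paste(miss, collapse = ", ")),
                "physupply_structural_error")
  }
  ok_chan <- c("DOMESTIC_INTAKE", "OVERSEAS", "PORTFOLIO", "REENTRY")
  if (!all(entries$channel %in% ok_chan)) {
    .phys_error(paste("inflow channel must be one of:",
                      paste(ok_chan, collapse = ", ")),
                "physupply_validation_error")
  }
  if (any(!is.finite(entries$count)) || any(entries$count < 0)) {
    .phys_error("inflow counts must be finite and >= 0",
                "physupply_validation_error")
  }
  structure(list(entries = entries[order(entries$year, entries$state), ,
                                   drop = FALSE]),
            class = "inflow_schedule")
}

#' @export
print.inflow_schedule <- function(x, ...) {
  e <- x$entries
  cat("<inflow_schedule>", nrow(e), "entries, years",
      if (nrow(e)) paste(range(e$year), collapse = "-") else "(none)", "\n")
  if (nrow(e)) print(tapply(e$count, e$channel, sum))
  invisible(x)
}

# inflow vector over states for one calendar year
inflows_for_year <- function(inflows, year, space) {
  v <- stats::setNames(rep(0, nrow(space$states)), space$states$label)
  e <- inflows$entries
  e <- e[e$year == year, , drop = FALSE]
  if (nrow(e)) {
    bad <- setdiff(unique(e$state), space$states$label)
    if (length(bad)) {
      .phys_error(sprintf("inflow into unknown state(s): %s",
                          paste(bad, collapse = ", ")),
                  "physupply_structural_error")
    }
    agg <- tapply(e$count, e$state, sum)
    v[names(agg)] <- agg
  }
  v
}

#' Whole-time-equivalent consultant supply of a population vector
#'
#' Sums the consultant-role states (CONS and CONS_RR): full-time
#' consultants count 1 each, less-than-full-time consultants
#' `ltft_weight` each.
#'
#' @param population Named numeric vector over state labels (>= 0).
#' @param space A `state_space`.
#' @param ltft_weight Average WTE delivered by an LTFT consultant
#'   (default 0.65).
#' @return WTE count (scalar).
#' @examples
#' # 100 LTFT consultants deliver 65 WTE at the default weight
#' @export
wte_supply <- function(population, space, ltft_weight = 0.65) {
  if (any(population < 0)) {
    .phys_error("population must be non-negative",
                "physupply_validation_error")
  }
  if (ltft_weight <= 0 || ltft_weight > 1) {
    .phys_error("`ltft_weight` must lie in (0, 1]",
                "physupply_validation_error")
  }
  ft <- state_labels(space, stage = c("CONS", "CONS_RR"),
                     work_pattern = "FT")
  lt <- state_labels(space, stage = c("CONS", "CONS_RR"),
                     work_pattern = "LTFT")
  sum(population[ft]) + ltft_weight * sum(population[lt])
}

#' Project state populations over an annual horizon
#'
#' @param initial Named numeric vector of starting populations over the
#'   state labels (EXIT must be 0); non-negative.
#' @param model A [transition_model()]; per-year overrides are resolved
#'   before each cycle and every applied matrix must be valid.
#' @param inflows An [inflow_schedule()].
#' @param start_year First calendar year (the year of `initial`).
#' @param horizon Number of annual cycles (>= 1).
#' @param ltft_weight WTE weight of LTFT consultants (default 0.65).
#' @return An object of class `projection_result`: per-year `populations`
#'   matrix (rows = years `start_year ... start_year + horizon`), a
#'   `supply` data.frame (`year`, `headcount`, `wte`), and a `ledger`
#'   data.frame (`year`, `inflow`, `exit`) recording the annual outflow
#'   harvested from EXIT and inflow added.
#' @export
project <- function(initial, model, inflows, start_year, horizon,
                    ltft_weight = 0.65) {
  space <- model$space
  labels <- space$states$label
  if (is.null(names(initial))) {
    if (length(initial) != length(labels)) {
      .phys_error("`initial` length does not match the state space",
                  "physupply_structural_error")
    }
    names(initial) <- labels
  }
  initial <- initial[labels]
  initial[is.na(initial)] <- 0
  names(initial) <- labels
  if (any(initial < 0)) {
    .phys_error("`initial` must be non-negative",
                "physupply_validation_error")
  }
  if (initial[exit_label(space)] != 0) {
    .phys_error("`initial` must carry no mass in EXIT",
                "physupply_validation_error")
  }
  if (horizon < 1) {
    .phys_error("`horizon` must be >= 1", "physupply_validation_error")
  }
  .check_propagation_model(space, model)

  exit_i <- match(exit_label(space), labels)
  years <- start_year + 0:horizon
  pops <- matrix(0, horizon + 1L, length(labels),
                 dimnames = list(years, labels))
  pops[1L, ] <- initial
  ledger <- data.frame(year = years, inflow = 0, exit = 0)
  v <- initial
  for (t in seq_len(horizon)) {
    yr <- start_year + t
    m <- resolve_matrix(model, yr)
    v <- drop(v %*% m)
    ex <- v[exit_i]
    v[exit_i] <- 0
    infl <- inflows_for_year(inflows, yr, space)
    v <- v + infl
    pops[t + 1L, ] <- v
    ledger$inflow[t + 1L] <- sum(infl)
    ledger$exit[t + 1L] <- ex
  }

  cons <- consultant_labels(space)
  headcount <- rowSums(pops[, cons, drop = FALSE])
  wte <- apply(pops, 1L, wte_supply, space = space,
               ltft_weight = ltft_weight)
  structure(list(space = space, years = years, populations = pops,
                 supply = data.frame(year = years, headcount = headcount,
                                     wte = wte, row.names = NULL),
                 ledger = ledger, initial_total = sum(initial),
                 ltft_weight = ltft_weight),
            class = "projection_result")
}

#' @export
print.projection_result <- function(x, ...) {
  cat("<projection_result>", min(x$years), "-", max(x$years), "\n")
  print(utils::head(x$supply, 3))
  cat("  ...\n")
  print(utils::tail(x$supply, 3))
  invisible(x)
}

#' Maximum relative conservation error of a projection
#'
#' At every year, total population plus cumulative exits must equal the
#' initial total plus cumulative inflows.  Returns the largest relative
#' discrepancy over the horizon (relative to the initial total).
#'
#' @param result A `projection_result`.
#' @return Scalar (0 for an exactly conservative projection).
#' @export
max_conservation_error <- function(result) {
  tot <- rowSums(result$populations)
  cum_in <- cumsum(result$ledger$inflow)
  cum_ex <- cumsum(result$ledger$exit)
  ref <- max(result$initial_total, 1)
  max(abs(tot + cum_ex - result$initial_total - cum_in)) / ref
}

#' Write projection outputs as tidy CSV
#'
#' @param result A `projection_result`.
#' @param dir Output directory; writes `populations.csv`
#'   (`year,state,population`) and `supply.csv`
#'   (`year,headcount,wte,inflow,exit`).
#' @export
write_projection <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pops <- result$populations
  long <- data.frame(
    year = rep(as.integer(rownames(pops)), times = ncol(pops)),
    state = rep(colnames(pops), each = nrow(pops)),
    population = as.vector(pops), stringsAsFactors = FALSE)
  long <- long[order(long$year, long$state), ]
  utils::write.csv(long, file.path(dir, "populations.csv"),
                   row.names = FALSE)
  summ <- merge(result$supply, result$ledger, by = "year")
  utils::write.csv(summ, file.path(dir, "supply.csv"), row.names = FALSE)
  invisible(dir)
}

#' Trace a single entry cohort to consultant working
#'
#' Runs one cohort (no inflows) with consultant entry treated as
#' absorbing, recording the first-passage mass into CONS per year since
#' entry.  Mean and SD of time-to-consultant are computed over the
#' arriving mass only; the fraction never arriving is reported
#' separately.
#'
#' @param cohort_size Entering cohort size (0 gives an empty trace).
#' @param model A [transition_model()] (base matrix only).
#' @param max_years Years to iterate (default 40); must exceed the
#'   expected path length so the truncated tail is negligible.
#' @param entry_state Label of the entry state (default: the first
#'   medical-school state, MS1).
#' @return An object of class `cohort_trace`: `arrivals` data.frame
#'   (`years_since_entry`, `arrival`), `mean_years`, `sd_years`,
#'   `fraction_reaching`.
#' @export
trace_cohort <- function(cohort_size, model, max_years = 40L,
                         entry_state = NULL) {
  space <- model$space
  labels <- space$states$label
  if (is.null(entry_state)) entry_state <- state_labels(space, stage = "MS1")
  if (!entry_state %in% labels) {
    .phys_error(sprintf("unknown entry state '%s'", entry_state),
                "physupply_structural_error")
  }
  if (cohort_size < 0) {
    .phys_error("`cohort_size` must be >= 0", "physupply_validation_error")
  }
  m <- model$matrix
  cons <- state_labels(space, stage = "CONS")
  # consultant entry is absorbing for the trace
  for (cl in cons) {
    m[cl, ] <- 0
    m[cl, cl] <- 1
  }
  v <- stats::setNames(rep(0, length(labels)), labels)
  v[entry_state] <- 1
  arrived <- numeric(max_years)
  prev <- 0
  for (t in seq_len(max_years)) {
    v <- drop(v %*% m)
    cum <- sum(v[cons])
    arrived[t] <- cum - prev
    prev <- cum
  }
  f <- sum(arrived)
  if (cohort_size == 0 || f == 0) {
    mean_y <- NA_real_; sd_y <- NA_real_
  } else {
    w <- arrived / f
    t <- seq_len(max_years)
    mean_y <- sum(t * w)
    sd_y <- sqrt(max(sum(t^2 * w) - mean_y^2, 0))
  }
  structure(list(
    arrivals = data.frame(years_since_entry = seq_len(max_years),
                          arrival = arrived * cohort_size),
    mean_years = mean_y, sd_years = sd_y, fraction_reaching = f,
    cohort_size = cohort_size, entry_state = entry_state),
    class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat("<cohort_trace> entry", x$entry_state, "size", x$cohort_size, "\n")
  cat(sprintf("  mean time to consultant %.2f y (SD %.2f), %.1f%% reach\n",
              x$mean_years, x$sd_years, 100 * x$fraction_reaching))
  invisible(x)
}

#' Agent-level microsimulation of the projection
#'
#' Simulates individual agents drawing annual destinations from the
#' transition matrix (multinomial draws per occupied origin state), as a
#' stochastic cross-check of [project()].  The initial population is
#' allocated to `n_agents` agents by largest remainder; inflows enter as
#' agents at the same scale with stochastic rounding.  Reported
#' populations are rescaled to the deterministic model's mass.
#'
#' @inheritParams project
#' @param n_agents Number of agents representing the initial population.
#' @param seed Integer seed; the same seed reproduces the run exactly.
#' @return A `projection_result` (populations in deterministic-mass
#'   units) with attribute `"scale"` (mass per agent).
#' @export
microsim <- function(initial, model, inflows, start_year, horizon,
                     n_agents, seed, ltft_weight = 0.65) {
  if (n_agents < 1) {
    .phys_error("`n_agents` must be >= 1", "physupply_validation_error")
  }
  space <- model$space
  labels <- space$states$label
  if (is.null(names(initial))) names(initial) <- labels
  initial <- initial[labels]
  initial[is.na(initial)] <- 0
  names(initial) <- labels
  .check_propagation_model(space, model)
  total0 <- sum(initial)
  lambda <- n_agents / total0     # agents per unit of mass
  with_seed(seed, {
    # largest-remainder allocation of the initial population
    exact <- initial * lambda
    counts <- floor(exact)
    rem <- n_agents - sum(counts)
    if (rem > 0) {
      frac <- exact - counts
      top <- order(frac, decreasing = TRUE)[seq_len(rem)]
      counts[top] <- counts[top] + 1
    }
    counts <- stats::setNames(as.integer(counts), labels)
    exit_i <- match(exit_label(space), labels)
    years <- start_year + 0:horizon
    pops <- matrix(0, horizon + 1L, length(labels),
                   dimnames = list(years, labels))
    pops[1L, ] <- counts / lambda
    ledger <- data.frame(year = years, inflow = 0, exit = 0)
    for (t in seq_len(horizon)) {
      yr <- start_year + t
      m <- resolve_matrix(model, yr)
      new_counts <- integer(length(labels))
      occ <- which(counts > 0)
      for (i in occ) {
        new_counts <- new_counts +
          as.integer(stats::rmultinom(1, counts[i], m[i, ]))
      }
      ex <- new_counts[exit_i]
      new_counts[exit_i] <- 0L
      infl <- inflows_for_year(inflows, yr, space) * lambda
      add <- floor(infl)
      fr <- infl - add
      add <- add + (stats::runif(length(fr)) < fr)
      counts <- stats::setNames(as.integer(new_counts + add), labels)
      pops[t + 1L, ] <- counts / lambda
      ledger$inflow[t + 1L] <- sum(add) / lambda
      ledger$exit[t + 1L] <- ex / lambda
    }
  })
  cons <- consultant_labels(space)
  headcount <- rowSums(pops[, cons, drop = FALSE])
  wte <- apply(pops, 1L, wte_supply, space = space,
               ltft_weight = ltft_weight)
  out <- structure(list(space = space, years = years, populations = pops,
                        supply = data.frame(year = years,
                                            headcount = headcount,
                                            wte = wte, row.names = NULL),
                        ledger = ledger, initial_total = sum(counts) / lambda,
                        ltft_weight = ltft_weight),
                   class = "projection_result")
  attr(out, "scale") <- 1 / lambda
  out
}

#' Backcast agreement percentage
#'
#' `100 * predicted / reported`, rounded to the nearest integer percent,
#' with the unrounded value alongside.
#'
#' @param predicted Model-predicted count.
#' @param reported Externally reported count (> 0).
#' @return List with `percent` (integer) and `raw`.
#' @examples
#' agreement_percent(21302, 22183)$percent  # 96
#' @export
agreement_percent <- function(predicted, reported) {
  if (reported <= 0) {
    .phys_error("`reported` must be > 0", "physupply_domain_error")
  }
  raw <- 100 * predicted / reported
  list(percent = as.integer(round(raw)), raw = raw)
}

# A matrix is propagatable if every row is stochastic and non-negative;
# mass on a disallowed pair is a modelling defect but still propagates,
# so it only warns here (validate_transition_model reports it in full).
.check_propagation_model <- function(space, model) {
  rep <- validate_transition_model(space, model)
  if (is_clean(rep)) return(invisible(TRUE))
  hard <- rep$issues$type %in% c("row_sum", "negative")
  if (any(hard)) {
    print(rep)
    .phys_error("transition model failed validation",
                "physupply_validation_error")
  }
  warning(sprintf(
    "transition model carries mass on %d disallowed pair(s)",
    sum(!hard)))
  invisible(FALSE)
}

# evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
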