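# Estimation of annual transition probabilities from longitudinal
# person-year training records.
#
# Records are annual census-style snapshots: one row per person per year
# with the observed stage (or ABSENT), sex and LTFT flag.  Transition
# probabilities are the empirical destination frequencies of each origin
# state; departures from training are classified with a three-year
# look-ahead into temporary breaks (back in training within 3 years) and
# exits (not back within 3 years).

.TRAINING_STAGES <- function() {
  setdiff(stage_table()$stage,
          c("BREAK_POST_FY", "BREAK_POST_IMT", "BREAK_POST_ST",
            "BREAK_POST_CCT", "EXIT"))
}

#' Validate a person-year record table
#'
#' @param records data.frame with columns `person_id`, `year`, `stage`
#'   (a stage code or `"ABSENT"`), `sex` (`"F"`/`"M"`), `ltft` (logical,
#'   `NA` where work pattern does not apply).
#' @return The records, invisibly, or an error naming offending rows.
#' @export
validate_person_records <- function(records) {
  need <- c("person_id", "year", "stage", "sex", "ltft")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    .phys_error(paste("records are missing column(s):",
                      paste(miss, collapse = ", ")),
                "physupply_parse_error")
  }
  known <- c(.TRAINING_STAGES(), "ABSENT")
  bad <- which(!records$stage %in% known)
  if (length(bad)) {
    .phys_error(sprintf(
      "unknown stage code '%s' at row %d (person %s, year %s)",
      records$stage[bad[1]], bad[1], records$person_id[bad[1]],
      records$year[bad[1]]), "physupply_parse_error")
  }
  dup <- duplicated(records[, c("person_id", "year")])
  if (any(dup)) {
    i <- which(dup)[1]
    .phys_error(sprintf("duplicate record for person %s, year %s (row %d)",
                        records$person_id[i], records$year[i], i),
                "physupply_parse_error")
  }
  invisible(records)
}

#' Classify a departure from training as break or exit
#'
#' A person observed in training at `departure_year` and absent the
#' following year is on a temporary break if they reappear in a model
#' stage in any of years `departure_year + 2` to
#' `departure_year + lookahead`, and has exited otherwise.
#'
#' @param person_records Records (see [validate_person_records()]) for a
#'   single person; rows with stage `"ABSENT"` are ignored except for
#'   establishing coverage.
#' @param departure_year Calendar year of the last observation in
#'   training.
#' @param lookahead Years of follow-up required (default 3).
#' @param window_end Last calendar year covered by the observation
#'   window.  Defaults to the last year appearing in `person_records`;
#'   pass the dataset-wide window end when absences are encoded by
#'   missing rows rather than explicit `ABSENT` rows.
#' @return `"TEMPORARY_BREAK"` or `"EXIT"`.  Errors of class
#'   `physupply_followup_truncated` signal that the records end before
#'   `departure_year + lookahead`, in which case the caller must drop the
#'   cohort-year rather than guess.
#' @export
classify_departure <- function(person_records, departure_year,
                               lookahead = 3L, window_end = NULL) {
  if (length(unique(person_records$person_id)) > 1L) {
    .phys_error("`person_records` must cover a single person",
                "physupply_parse_error")
  }
  yrs <- person_records$year[person_records$stage != "ABSENT"]
  if (!departure_year %in% yrs) {
    .phys_error("person not observed in training at `departure_year`",
                "physupply_precondition_error")
  }
  if ((departure_year + 1L) %in% yrs) {
    .phys_error("not a departure: person observed in training the following year",
                "physupply_precondition_error")
  }
  window <- seq(departure_year + 2L, departure_year + lookahead)
  if (any(yrs %in% window)) return("TEMPORARY_BREAK")
  # no return observed: only a full follow-up window can establish an exit
  if (is.null(window_end)) window_end <- max(person_records$year)
  if (window_end < departure_year + lookahead) {
    .phys_error(sprintf(
      "follow-up truncated: records end at %d, need %d",
      window_end, departure_year + lookahead),
      "physupply_followup_truncated")
  }
  "EXIT"
}

# Map observed rows to state labels.  `dwell` must already be supplied
# (1 except for reconstructed CONS_RR runs).
.obs_labels <- function(stage, sex, ltft, dwell) {
  meta <- stage_table()
  sexed <- meta$sexed[match(stage, meta$stage)]
  patterned <- meta$patterned[match(stage, meta$stage)]
  wp <- ifelse(patterned, ifelse(!is.na(ltft) & ltft, "LTFT", "FT"),
               NA_character_)
  sx <- ifelse(sexed, sex, NA_character_)
  state_label(stage, sx, wp, dwell)
}

# Break stage implied by a gap between `stage_from` and `stage_to`
# (NA where the model has no break state for that context).
.break_stage_for <- function(stage_from, stage_to, gap) {
  ifelse(stage_from %in% c("FY1", "FY2"), "BREAK_POST_FY",
  ifelse(stage_from %in% c("IMT1", "IMT2", "IMT3"), "BREAK_POST_IMT",
  ifelse(stage_from == "ST7" & stage_to == "CONS" & gap == 1L,
         "BREAK_POST_CCT",
  ifelse(stage_from %in% paste0("ST", 3:7), "BREAK_POST_ST",
         NA_character_))))
}

#' Estimate annual transition probabilities from records
#'
#' Counts, for every origin state observed in a cohort year, the
#' destinations one year later, and divides by the number in the origin
#' state.  Departures from training are routed via the three-year rule
#' ([classify_departure()] logic) into the matching break state or EXIT;
#' one- and two-year absences followed by a return are reconstructed as
#' break-state dwell chains.  Rows are stratified by sex from FY1 onward
#' and by work pattern from ST3 onward; medical-school rows pool the
#' sexes.
#'
#' Origins never observed in a cohort year are flagged with denominator 0
#' and then filled, in order of preference, with the pooled-sex estimate
#' for the same stage/pattern/dwell or a deterministic forward fallback
#' (all mass to the first allowed non-self destination, else EXIT), so a
#' sparse sample still yields a projectable model.
#'
#' @param records Person-year records (see [validate_person_records()]).
#' @param space A [build_state_space()] object.
#' @param cohort_years Calendar years whose transitions are counted; each
#'   must have at least `lookahead` years of subsequent records.  An
#'   empty set returns a result with every origin flagged.
#' @param lookahead Follow-up horizon of the break/exit rule (default 3).
#' @return An object of class `estimated_transitions`: list with `probs`
#'   (row-stochastic matrix), `denominators`, `counts` (long-form
#'   data.frame), `flagged` (origins with denominator 0 and the fallback
#'   used) and `dropped` (transitions discarded because they have no
#'   model representation).
#' @export
estimate_transitions <- function(records, space, cohort_years,
                                 lookahead = 3L) {
  validate_person_records(records)
  labels <- space$states$label
  if (length(cohort_years)) {
    w_end <- max(records$year)
    short <- cohort_years[cohort_years + lookahead > w_end]
    if (length(short)) {
      .phys_error(sprintf(
        "cohort year(s) %s lack %d years of follow-up (records end %d)",
        paste(short, collapse = ", "), lookahead, w_end),
        "physupply_followup_truncated")
    }
  }

  trans <- .extract_transitions(records, space, lookahead)
  dropped <- trans$dropped
  tr <- trans$transitions
  tr <- tr[tr$year %in% cohort_years, , drop = FALSE]

  disallowed <- !space$allowed[cbind(match(tr$origin, labels),
                                     match(tr$destination, labels))]
  if (any(disallowed)) {
    warning(sprintf(
      "%d observed transition(s) have no allowed model pair and were dropped",
      sum(disallowed)))
    dropped <- dropped + sum(disallowed)
    tr <- tr[!disallowed, , drop = FALSE]
  }

  counts <- matrix(0, length(labels), length(labels),
                   dimnames = list(labels, labels))
  if (nrow(tr)) {
    tab <- table(factor(tr$origin, levels = labels),
                 factor(tr$destination, levels = labels))
    counts <- counts + unclass(tab)
  }
  denom <- rowSums(counts)

  probs <- matrix(0, length(labels), length(labels),
                  dimnames = list(labels, labels))
  pos <- denom > 0
  probs[pos, ] <- counts[pos, , drop = FALSE] / denom[pos]

  # fallbacks for unobserved origins
  st <- space$states
  flagged <- data.frame(label = character(0), fallback = character(0),
                        stringsAsFactors = FALSE)
  for (i in which(!pos)) {
    lab <- labels[i]
    if (st$stage[i] == "EXIT") {
      probs[i, i] <- 1
      next
    }
    filled <- FALSE
    if (!is.na(st$sex[i])) {
      # pooled-sex estimate: sum counts over both sexes of this
      # stage/pattern/dwell, re-sexing sexed destinations to this origin
      mates <- which(st$stage == st$stage[i] &
                       (is.na(st$work_pattern[i]) |
                          (!is.na(st$work_pattern) &
                             st$work_pattern == st$work_pattern[i])) &
                       st$dwell == st$dwell[i] & !is.na(st$sex))
      pooled <- colSums(counts[mates, , drop = FALSE])
      if (sum(pooled) > 0) {
        dest <- st
        resex <- !is.na(dest$sex)
        remapped <- stats::setNames(rep(0, length(labels)), labels)
        target_lab <- ifelse(resex,
                             state_label(dest$stage, st$sex[i],
                                         dest$work_pattern, dest$dwell),
                             dest$label)
        for (j in which(pooled > 0)) {
          remapped[target_lab[j]] <- remapped[target_lab[j]] + pooled[j]
        }
        probs[i, ] <- remapped / sum(remapped)
        flagged <- rbind(flagged, data.frame(label = lab,
                                             fallback = "pooled_sex"))
        filled <- TRUE
      }
    }
    if (!filled) {
      fwd <- which(space$allowed[i, ] & seq_along(labels) != i &
                     st$stage != "EXIT")
      j <- if (length(fwd)) fwd[1] else which(st$stage == "EXIT")
      probs[i, j] <- 1
      flagged <- rbind(flagged, data.frame(label = lab,
                                           fallback = "forward"))
    }
  }

  long <- NULL
  idx <- which(counts > 0, arr.ind = TRUE)
  long <- data.frame(origin = labels[idx[, 1]],
                     destination = labels[idx[, 2]],
                     count = counts[idx],
                     probability = probs[cbind(idx[, 1], idx[, 2])],
                     denominator = denom[idx[, 1]],
                     stringsAsFactors = FALSE)
  long <- long[order(idx[, 1], idx[, 2]), ]
  rownames(long) <- NULL

  structure(list(space = space, probs = probs, denominators = denom,
                 counts = long, flagged = flagged, dropped = dropped,
                 cohort_years = sort(unique(cohort_years)),
                 lookahead = lookahead),
            class = "estimated_transitions")
}

# Turn records into a table of (origin label, destination label, origin
# year) transitions, reconstructing break dwell chains from absences and
# CONS_RR dwell indices from consecutive runs.
.extract_transitions <- function(records, space, lookahead) {
  obs <- records[records$stage != "ABSENT", , drop = FALSE]
  obs <- obs[order(obs$person_id, obs$year), , drop = FALSE]
  w_end <- max(records$year)
  n <- nrow(obs)
  dropped <- 0L
  if (n == 0L) {
    return(list(transitions = data.frame(origin = character(0),
                                         destination = character(0),
                                         year = integer(0)),
                dropped = dropped))
  }

  # CONS_RR dwell reconstruction: second consecutive CONS_RR year -> dwell 2
  dwell <- rep(1L, n)
  if (n > 1L) {
    prev_rr <- c(FALSE, obs$person_id[-1] == obs$person_id[-n] &
                   obs$year[-1] == obs$year[-n] + 1L &
                   obs$stage[-1] == "CONS_RR" & obs$stage[-n] == "CONS_RR")
    dwell[prev_rr] <- 2L
  }
  lab <- .obs_labels(obs$stage, obs$sex, obs$ltft, dwell)

  origins <- character(0); dests <- character(0); years <- integer(0)
  add <- function(o, d, y) {
    origins <<- c(origins, o); dests <<- c(dests, d)
    years <<- c(years, as.integer(y))
  }

  if (n > 1L) {
    same <- obs$person_id[-1] == obs$person_id[-n]
    i1 <- which(same)          # index of first of pair
    gap <- obs$year[i1 + 1L] - obs$year[i1] - 1L

    # direct annual transitions
    d0 <- i1[gap == 0L]
    if (length(d0)) add(lab[d0], lab[d0 + 1L], obs$year[d0])

    # permanent departures mid-record (>= lookahead absent years)
    dx <- i1[gap >= lookahead]
    if (length(dx)) {
      add(lab[dx], rep(exit_label(space), length(dx)), obs$year[dx])
    }

    # 1- and 2-year absences: break dwell chains
    for (g in c(1L, 2L)) {
      db <- i1[gap == g]
      if (!length(db)) next
      bstage <- .break_stage_for(obs$stage[db], obs$stage[db + 1L], g)
      bad <- is.na(bstage) | (bstage == "BREAK_POST_CCT" & g > 1L)
      if (any(bad)) dropped <- dropped + sum(bad)
      db <- db[!bad]; bstage <- bstage[!bad]
      if (!length(db)) next
      meta <- stage_table()
      patterned <- meta$patterned[match(bstage, meta$stage)]
      # a post-CCT break carries the work pattern observed on return
      wp <- ifelse(patterned,
                   ifelse(!is.na(obs$ltft[db + 1L]) & obs$ltft[db + 1L],
                          "LTFT", "FT"),
                   NA_character_)
      b1 <- state_label(bstage, obs$sex[db], wp, 1L)
      add(lab[db], b1, obs$year[db])
      if (g == 1L) {
        add(b1, lab[db + 1L], obs$year[db] + 1L)
      } else {
        b2 <- state_label(bstage, obs$sex[db], wp, 2L)
        add(b1, b2, obs$year[db] + 1L)
        add(b2, lab[db + 1L], obs$year[db] + 2L)
      }
    }
  }

  # departures at the end of each person's record with full follow-up
  last <- c(which(obs$person_id[-1] != obs$person_id[-n]), n)
  lx <- last[obs$year[last] + lookahead <= w_end]
  if (length(lx)) {
    add(lab[lx], rep(exit_label(space), length(lx)), obs$year[lx])
  }

  list(transitions = data.frame(origin = origins, destination = dests,
                                year = years, stringsAsFactors = FALSE),
       dropped = dropped)
}

#' @export
print.estimated_transitions <- function(x, ...) {
  cat("<estimated_transitions>",
      sum(x$denominators > 0), "of", length(x$denominators),
      "origins observed;", sum(x$counts$count), "transitions counted\n")
  if (nrow(x$flagged)) {
    cat("  flagged (denominator 0):", nrow(x$flagged), "origin(s)\n")
  }
  if (x$dropped > 0) cat("  dropped:", x$dropped, "unrepresentable\n")
  invisible(x)
}

#' @export
as.data.frame.estimated_transitions <- function(x, ...) {
  x$counts[, c("origin", "destination", "probability", "denominator")]
}

#' Convert estimates to a transition model
#' @param est An `estimated_transitions`.
#' @return A [transition_model()].
#' @export
as_transition_model <- function(est) {
  stopifnot(inherits(est, "estimated_transitions"))
  transition_model(est$space, est$probs)
}

#' Write estimated probabilities as long-form CSV
#' @param est An `estimated_transitions`.
#' @param path CSV path.
#' @export
write_estimates <- function(est, path) {
  utils::write.csv(as.data.frame(est), path, row.names = FALSE)
  invisible(path)
}

#' Combine training-completion and post-CCT destination probabilities
#'
#' The probability of completing training in a cycle is combined with the
#' split of post-CCT destinations -- becoming a consultant directly,
#' taking a 1-year break first, or leaving the NHS -- to give the three
#' transition probabilities out of a final specialty-training state.
#'
#' @param p_complete Probability of completing training in the cycle.
#' @param f_direct,f_break1,f_leave Fractions over the post-CCT
#'   destinations; must sum to 1.
#' @return Named numeric vector `c(to_cons, to_break_post_cct, to_exit)`.
#' @examples
#' split_cct(0.9, 0.8, 0.1, 0.1)   # 0.72 0.09 0.09
#' @export
split_cct <- function(p_complete, f_direct, f_break1, f_leave) {
  if (abs(f_direct + f_break1 + f_leave - 1) > 1e-12) {
    .phys_error("post-CCT fractions must sum to 1",
                "physupply_validation_error")
  }
  if (p_complete < 0 || p_complete > 1 ||
      min(f_direct, f_break1, f_leave) < 0) {
    .phys_error("probabilities must lie in [0, 1]",
                "physupply_validation_error")
  }
  c(to_cons = p_complete * f_direct,
    to_break_post_cct = p_complete * f_break1,
    to_exit = p_complete * f_leave)
}

#' Decompose total consultant exit into retire-and-return and direct exit
#'
#' Consultants leaving their post either retire and return (entering the
#' two-year CONS_RR chain) or exit the model; direct exit is the total
#' exit probability minus the retire-and-return probability.
#'
#' @param total_exit Total annual probability of leaving a consultant
#'   state (vectorized over strata).
#' @param rr_prob Annual retire-and-return probability, same length.
#' @return data.frame with columns `to_cons_rr`, `to_exit`, `stay`.
#' @examples
#' consultant_exit_decomposition(0.05, 0.02)  # RR 0.02, exit 0.03, stay 0.95
#' @export
consultant_exit_decomposition <- function(total_exit, rr_prob) {
  if (length(rr_prob) != length(total_exit)) {
    rr_prob <- rep_len(rr_prob, length(total_exit))
  }
  if (any(total_exit < 0 | total_exit > 1 | rr_prob < 0)) {
    .phys_error("probabilities must lie in [0, 1]",
                "physupply_validation_error")
  }
  if (any(rr_prob > total_exit + 1e-12)) {
    .phys_error("retire-and-return probability exceeds total exit (negative direct exit)",
                "physupply_validation_error")
  }
  data.frame(to_cons_rr = rr_prob, to_exit = total_exit - rr_prob,
             stay = 1 - total_exit)
}

#' Calibrate destination-group marginals of transition rows
#'
#' Rescales, within each targeted origin row, the probability mass on a
#' destination group to a target marginal; all other destinations in the
#' row are scaled by a common factor so the row re-sums to 1.  Rows not
#' named by any target are unchanged.  Applying the same targets twice is
#' a no-op.
#'
#' @param x A [transition_model()] or [estimate_transitions()] result;
#'   only the base matrix is calibrated.
#' @param targets List of targets, each a list with elements `origin` and
#'   `destination` (selector lists passed to [state_labels()], e.g.
#'   `list(stage = "FY2")`) and `target` (the desired marginal in
#'   \[0, 1\]).
#' @return Object of the same class as `x` with the calibrated matrix.
#' @export
calibrate <- function(x, targets) {
  model <- if (inherits(x, "estimated_transitions")) x$probs else
    if (inherits(x, "transition_model")) x$matrix else
      .phys_error("`x` must be a transition model or estimation result",
                  "physupply_structural_error")
  space <- x$space
  m <- model
  for (tg in targets) {
    if (is.null(tg$target) || tg$target < 0 || tg$target > 1) {
      .phys_error("calibration target must lie in [0, 1]",
                  "physupply_validation_error")
    }
    rows <- do.call(state_labels, c(list(space), tg$origin))
    cols <- do.call(state_labels, c(list(space), tg$destination))
    if (!length(rows) || !length(cols)) {
      .phys_error("calibration target selects no states",
                  "physupply_validation_error")
    }
    for (r in rows) {
      g <- sum(m[r, cols])
      if (g == 0 && tg$target > 0) {
        .phys_error(sprintf(
          "infeasible calibration: row %s has no mass on the target group", r),
          "physupply_calibration_error")
      }
      other <- 1 - g
      if (other == 0 && tg$target < 1) {
        .phys_error(sprintf(
          "infeasible calibration: row %s has no mass outside the target group",
          r), "physupply_calibration_error")
      }
      if (g > 0) m[r, cols] <- m[r, cols] * (tg$target / g)
      if (other > 0) {
        oth <- setdiff(colnames(m)[m[r, ] > 0 | colnames(m) %in% cols],
                       cols)
        m[r, oth] <- m[r, oth] * ((1 - tg$target) / other)
      }
    }
  }
  if (inherits(x, "estimated_transitions")) {
    x$probs <- m
  } else {
    x$matrix <- m
  }
  x
}
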