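# Independent oracles, written against the model description rather than
# the package internals.

# Expected number of states by direct enumeration of the cross product
# stage x applicable sex x applicable work pattern x applicable dwell.
oracle_state_count <- function(include_ms6 = TRUE, max_break_dwell = 2) {
  n <- 0
  n <- n + (if (include_ms6) 6 else 5)           # medical school, pooled
  n <- n + 2 * 2                                 # FY1, FY2 x sex
  n <- n + 3 * 2                                 # IMT1-3 x sex
  n <- n + 5 * 2 * 2                             # ST3-7 x sex x pattern
  n <- n + 3 * 2 * max_break_dwell               # breaks post FY/IMT/ST
  n <- n + 1 * 2 * 2                             # break post CCT x sex x wp
  n <- n + 2 * 2                                 # CONS x sex x wp
  n <- n + 2 * 2 * 2                             # CONS_RR x sex x wp x dwell
  n + 1                                          # absorbing EXIT
}

# Hand-coded adjacency rule for a state pair, following the transition
# diagram: returns TRUE if origin -> destination is an allowed annual
# move.  States are rows of space$states.
oracle_allowed <- function(o, d, max_break_dwell = 2) {
  stg <- function(x) x$stage
  # absorbing exit
  if (stg(o) == "EXIT") return(stg(d) == "EXIT")
  if (stg(d) == "EXIT") return(TRUE)
  # sex is fixed once assigned; medical school fans out to either sex
  if (!is.na(o$sex) && !is.na(d$sex) && o$sex != d$sex) return(FALSE)
  if (!is.na(o$sex) && is.na(d$sex)) return(FALSE)

  edge <- paste(stg(o), stg(d))
  one_level <- c("MS1 MS2", "MS2 MS3", "MS3 MS4", "MS4 MS5", "MS5 MS6",
                 "MS5 FY1", "MS6 FY1", "FY1 FY2", "FY2 IMT1",
                 "IMT1 IMT2", "IMT2 IMT3", "IMT2 ST3", "IMT3 ST4",
                 "ST3 ST4", "ST4 ST5", "ST5 ST6", "ST6 ST7", "ST7 CONS")
  skips <- c("ST3 ST5", "ST4 ST6", "ST5 ST7")
  break_entry <- c("FY2 BREAK_POST_FY", "IMT2 BREAK_POST_IMT",
                   "IMT3 BREAK_POST_IMT", "ST3 BREAK_POST_ST",
                   "ST4 BREAK_POST_ST", "ST5 BREAK_POST_ST",
                   "ST6 BREAK_POST_ST", "ST7 BREAK_POST_CCT")
  break_return <- c("BREAK_POST_FY IMT1", "BREAK_POST_IMT ST3",
                    "BREAK_POST_IMT ST4", "BREAK_POST_ST ST4",
                    "BREAK_POST_ST ST5", "BREAK_POST_ST ST6",
                    "BREAK_POST_ST ST7", "BREAK_POST_CCT CONS")
  rr <- "CONS CONS_RR"

  if (stg(o) == stg(d)) {
    # dwell chains advance one step within the stratum
    if (startsWith(stg(o), "BREAK") || stg(o) == "CONS_RR") {
      return(identical(o$sex, d$sex) &&
               identical(o$work_pattern, d$work_pattern) &&
               d$dwell == o$dwell + 1)
    }
    # repeat year / stay in post (pattern may switch at ST and CONS)
    return(startsWith(stg(o), "MS") || startsWith(stg(o), "ST") ||
             stg(o) == "CONS")
  }
  if (d$dwell != 1) return(FALSE)
  edge %in% c(one_level, skips, break_entry, break_return, rr)
}

# Two-line deterministic propagation oracle: matrix-vector product, EXIT
# harvested, inflow added.
oracle_project_totals <- function(initial, matrix, inflow_by_year,
                                  exit_col, horizon) {
  v <- initial
  totals <- numeric(horizon)
  for (t in seq_len(horizon)) {
    v <- drop(v %*% matrix)
    v[exit_col] <- 0
    v <- v + inflow_by_year[[t]]
    totals[t] <- sum(v)
  }
  totals
}

# Build a single-branch deterministic chain MS1 -> ... -> ST7 -> CONS on
# the female/full-time branch, with optional per-stage advance
# probabilities (remainder self-loops where allowed).
chain_model <- function(space, advance = c()) {
  st <- space$states
  labels <- st$label
  m <- matrix(0, length(labels), length(labels),
              dimnames = list(labels, labels))
  path <- c("MS1|-|-|1", "MS2|-|-|1", "MS3|-|-|1", "MS4|-|-|1",
            "MS5|-|-|1", "FY1|F|-|1", "FY2|F|-|1", "IMT1|F|-|1",
            "IMT2|F|-|1", "ST3|F|FT|1", "ST4|F|FT|1", "ST5|F|FT|1",
            "ST6|F|FT|1", "ST7|F|FT|1", "CONS|F|FT|1")
  for (i in seq_len(length(path) - 1)) {
    stage <- st$stage[st$label == path[i]]
    p <- if (stage %in% names(advance)) advance[[stage]] else 1
    m[path[i], path[i + 1]] <- p
    if (p < 1) m[path[i], path[i]] <- 1 - p
  }
  m["CONS|F|FT|1", "CONS|F|FT|1"] <- 1
  for (i in which(rowSums(m) == 0)) {
    ex <- which(st$stage == "EXIT")
    m[i, ex] <- 1
  }
  transition_model(space, m)
}

# empty inflow schedule
no_inflows <- function() {
  inflow_schedule(data.frame(year = integer(0), state = character(0),
                             count = numeric(0), channel = character(0),
                             stringsAsFactors = FALSE))
}

# hand-made records for one person: named vector year -> stage
person_df <- function(id, stages, sex = "F", ltft = NA) {
  data.frame(person_id = id, year = as.integer(names(stages)),
             stage = unname(stages), sex = sex, ltft = ltft,
             stringsAsFactors = FALSE)
}
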