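# State space of the training-pipeline model.
#
# One model state = training stage x sex x work pattern x dwell index.
# Stages follow the UK physician pathway: medical school (MS1-MS5, optional
# intercalated MS6), foundation years (FY1-FY2), internal medicine training
# (IMT1-IMT3), specialty training (ST3-ST7), temporary-break states, the
# consultant grade (CONS), retired-and-returned consultants (CONS_RR) and an
# absorbing EXIT.

#' Stage metadata table
#'
#' One row per stage code: its domain, whether states at that stage are
#' stratified by sex and by work pattern, and the maximum dwell index
#' (`NA` for the temporary-break stages, whose maximum dwell is a
#' configuration option of [build_state_space()]).
#'
#' @return A data.frame with columns `stage`, `domain`, `sexed`,
#'   `patterned`, `dwell_max`.
#' @export
stage_table <- function() {
  data.frame(
    stage = c(paste0("MS", 1:6), "FY1", "FY2", paste0("IMT", 1:3),
              paste0("ST", 3:7), "BREAK_POST_FY", "BREAK_POST_IMT",
              "BREAK_POST_ST", "BREAK_POST_CCT", "CONS", "CONS_RR", "EXIT"),
    domain = c(rep("MS", 6), rep("FY", 2), rep("IMT", 3), rep("ST", 5),
               rep("BREAK", 4), "CONS", "CONS", "EXIT"),
    sexed = c(rep(FALSE, 6), rep(TRUE, 16), FALSE),
    patterned = c(rep(FALSE, 11), rep(TRUE, 5), FALSE, FALSE, FALSE,
                  TRUE, TRUE, TRUE, FALSE),
    dwell_max = c(rep(1L, 16), NA_integer_, NA_integer_, NA_integer_, 1L,
                  1L, 2L, 1L),
    stringsAsFactors = FALSE
  )
}

# Label for one state: "STAGE|sex|pattern|dwell", "-" marking an
# unstratified dimension.  Used as the canonical state identifier in
# matrices, vectors and serialized tables.
state_label <- function(stage, sex, work_pattern, dwell) {
  paste(stage,
        ifelse(is.na(sex), "-", sex),
        ifelse(is.na(work_pattern), "-", work_pattern),
        dwell, sep = "|")
}

.phys_error <- function(msg, class) {
  stop(structure(class = c(class, "physupply_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# Successor-stage map (forward moves of one level, the IMT->ST joins, the
# two-level ST skips, break entries, break returns and consultant entry).
.stage_successors <- function(include_ms6) {
  succ <- list(
    MS1 = "MS2", MS2 = "MS3", MS3 = "MS4", MS4 = "MS5",
    MS5 = if (include_ms6) c("MS6", "FY1") else "FY1",
    MS6 = "FY1",
    FY1 = "FY2",
    FY2 = c("IMT1", "BREAK_POST_FY"),
    IMT1 = "IMT2",
    IMT2 = c("IMT3", "ST3", "BREAK_POST_IMT"),
    IMT3 = c("ST4", "BREAK_POST_IMT"),
    ST3 = c("ST4", "ST5", "BREAK_POST_ST"),
    ST4 = c("ST5", "ST6", "BREAK_POST_ST"),
    ST5 = c("ST6", "ST7", "BREAK_POST_ST"),
    ST6 = c("ST7", "BREAK_POST_ST"),
    ST7 = c("CONS", "BREAK_POST_CCT"),
    BREAK_POST_FY = "IMT1",
    BREAK_POST_IMT = c("ST3", "ST4"),
    BREAK_POST_ST = c("ST4", "ST5", "ST6", "ST7"),
    BREAK_POST_CCT = "CONS",
    CONS = "CONS_RR",
    CONS_RR = character(0),
    EXIT = character(0)
  )
  if (!include_ms6) succ$MS5 <- "FY1"
  succ
}

# Stages at which a same-stage self-loop (repeat year / stay in post) is an
# allowed transition.  Medical-school repeats, ST-level repeats (LTFT
# trainees take more than one calendar year per level) and staying in a
# consultant post.
.SELF_LOOP_DOMAINS <- c("MS", "ST")

.allowed_pair <- function(o, d, succ) {
  # o, d: one-row lists with stage, domain, sex, work_pattern, dwell
  if (o$stage == "EXIT") return(d$stage == "EXIT")
  if (d$stage == "EXIT") return(TRUE)
  sex_ok <- is.na(o$sex) || is.na(d$sex) || o$sex == d$sex
  if (!sex_ok) return(FALSE)
  if (o$stage == d$stage) {
    dwell_chain <- o$domain == "BREAK" || o$stage == "CONS_RR"
    if (dwell_chain) {
      # advance the dwell clock: same stratum only
      return(identical(o$sex, d$sex) &&
               identical(o$work_pattern, d$work_pattern) &&
               d$dwell == o$dwell + 1L)
    }
    if (o$domain %in% .SELF_LOOP_DOMAINS || o$stage == "CONS") {
      # repeat year / stay in post; work-pattern switches allowed at ST and
      # consultant transitions
      return(d$dwell == 1L)
    }
    return(FALSE)
  }
  # cross-stage moves always enter at dwell 1
  if (d$dwell != 1L) return(FALSE)
  d$stage %in% succ[[o$stage]]
}

#' Build the model state space
#'
#' Enumerates every model state and the allowed annual transition mask.
#' States are ordered stage-major, then sex (F before M), work pattern
#' (FT before LTFT), then dwell index, giving a reproducible indexing for
#' serialized matrices.
#'
#' The mask encodes: one-level forward moves along
#' MS -> FY -> IMT -> ST -> CONS (with IMT2 -> ST3 and IMT3 -> ST4);
#' two-level skips from ST3, ST4 and ST5 only; entry into the matching
#' break state after FY2, IMT2/IMT3, ST3-ST6 and after CCT (from ST7);
#' return from a break to the stage that would have followed; the
#' consultant retire-and-return chain CONS -> CONS_RR(1) -> CONS_RR(2) ->
#' EXIT; work-pattern switches at every ST-level and consultant
#' transition; repeat-year self-loops at MS and ST stages and staying in
#' CONS; and exit to the absorbing EXIT state from every non-absorbing
#' state.
#'
#' @param include_ms6 Include the optional intercalated sixth
#'   medical-school year as a branch between MS5 and FY1?
#' @param max_break_dwell Maximum number of consecutive years spent in a
#'   temporary-break state (post-FY/IMT/ST) before the break counts as an
#'   exit; the post-CCT break always has a maximum dwell of 1.
#' @return An object of class `state_space`: a list with `states` (a
#'   data.frame with columns `label`, `stage`, `domain`, `sex`,
#'   `work_pattern`, `dwell`) and `allowed` (a logical matrix over state
#'   pairs, origin rows, destination columns).
#' @examples
#' space <- build_state_space()
#' nrow(space$states)
#' @export
build_state_space <- function(include_ms6 = TRUE, max_break_dwell = 2L) {
  if (!is.numeric(max_break_dwell) || length(max_break_dwell) != 1L ||
      is.na(max_break_dwell) || max_break_dwell < 1 ||
      max_break_dwell != round(max_break_dwell)) {
    .phys_error("`max_break_dwell` must be an integer >= 1",
                "physupply_config_error")
  }
  max_break_dwell <- as.integer(max_break_dwell)
  meta <- stage_table()
  if (!include_ms6) meta <- meta[meta$stage != "MS6", ]
  meta$dwell_max[meta$domain == "BREAK" & meta$stage != "BREAK_POST_CCT"] <-
    max_break_dwell

  rows <- lapply(seq_len(nrow(meta)), function(i) {
    m <- meta[i, ]
    sexes <- if (m$sexed) c("F", "M") else NA_character_
    pats <- if (m$patterned) c("FT", "LTFT") else NA_character_
    expand.grid(dwell = seq_len(m$dwell_max), work_pattern = pats,
                sex = sexes, stringsAsFactors = FALSE)[,
      c("sex", "work_pattern", "dwell")] -> g
    # expand.grid varies the first factor fastest; reorder so sex is the
    # slowest-varying, then work pattern, then dwell
    g <- g[order(g$sex, g$work_pattern, g$dwell, na.last = TRUE), ,
           drop = FALSE]
    data.frame(stage = m$stage, domain = m$domain, sex = g$sex,
               work_pattern = g$work_pattern, dwell = as.integer(g$dwell),
               stringsAsFactors = FALSE)
  })
  states <- do.call(rbind, rows)
  states$label <- state_label(states$stage, states$sex, states$work_pattern,
                              states$dwell)
  states <- states[, c("label", "stage", "domain", "sex", "work_pattern",
                       "dwell")]
  rownames(states) <- NULL

  succ <- .stage_successors(include_ms6)
  n <- nrow(states)
  allowed <- matrix(FALSE, n, n, dimnames = list(states$label, states$label))
  srows <- lapply(seq_len(n), function(i) as.list(states[i, ]))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      allowed[i, j] <- .allowed_pair(srows[[i]], srows[[j]], succ)
    }
  }
  structure(list(states = states, allowed = allowed,
                 config = list(include_ms6 = include_ms6,
                               max_break_dwell = max_break_dwell)),
            class = "state_space")
}

#' @export
print.state_space <- function(x, ...) {
  cat("<state_space>", nrow(x$states), "states,",
      sum(x$allowed), "allowed transitions\n")
  cat("  stages:", paste(unique(x$states$stage), collapse = " "), "\n")
  invisible(x)
}

#' Select state labels
#'
#' Filters the state list by stage, domain, sex, work pattern and/or
#' dwell, returning matching labels in state order.
#'
#' @param space A `state_space`.
#' @param stage,domain,sex,work_pattern,dwell Optional filters; each may
#'   be a vector of accepted values.
#' @return Character vector of state labels.
#' @export
state_labels <- function(space, stage = NULL, domain = NULL, sex = NULL,
                         work_pattern = NULL, dwell = NULL) {
  st <- space$states
  keep <- rep(TRUE, nrow(st))
  if (!is.null(stage)) keep <- keep & st$stage %in% stage
  if (!is.null(domain)) keep <- keep & st$domain %in% domain
  if (!is.null(sex)) keep <- keep & !is.na(st$sex) & st$sex %in% sex
  if (!is.null(work_pattern)) {
    keep <- keep & !is.na(st$work_pattern) & st$work_pattern %in% work_pattern
  }
  if (!is.null(dwell)) keep <- keep & st$dwell %in% dwell
  st$label[keep]
}

# labels of the consultant-role states (service-delivering supply)
consultant_labels <- function(space) {
  state_labels(space, stage = c("CONS", "CONS_RR"))
}

exit_label <- function(space) state_labels(space, stage = "EXIT")

#' Validate a transition model against a state space
#'
#' Checks that (a) no probability mass sits on a disallowed state pair,
#' (b) every row sums to 1 within `tol`, and (c) no entry is negative.
#' The base matrix and every per-year override are checked.
#'
#' @param space A `state_space`.
#' @param model A [transition_model()] or a bare numeric matrix indexed by
#'   the space's state labels.
#' @param tol Row-sum tolerance (default `1e-12`).
#' @return An object of class `tm_validation` holding a data.frame of
#'   issues (`matrix_id`, `row`, `type`, `detail`); an empty issue table
#'   means the model is valid (see [is_clean()]).
#' @export
validate_transition_model <- function(space, model, tol = 1e-12) {
  mats <- if (inherits(model, "transition_model")) {
    ov <- model$overrides
    if (length(ov)) names(ov) <- paste0("year_", names(ov))
    c(list(base = model$matrix), ov)
  } else {
    list(base = model)
  }
  labels <- space$states$label
  issues <- list()
  add <- function(matrix_id, row, type, detail) {
    issues[[length(issues) + 1L]] <<- data.frame(
      matrix_id = matrix_id, row = row, type = type, detail = detail,
      stringsAsFactors = FALSE)
  }
  for (id in names(mats)) {
    m <- mats[[id]]
    if (!is.matrix(m) || nrow(m) != length(labels) ||
        ncol(m) != length(labels)) {
      .phys_error(sprintf(
        "matrix '%s' has dimensions %s, expected %d x %d", id,
        paste(dim(m), collapse = " x "), length(labels), length(labels)),
        "physupply_structural_error")
    }
    if (!is.null(dimnames(m)) &&
        (!identical(rownames(m), labels) || !identical(colnames(m), labels))) {
      .phys_error(sprintf("matrix '%s' is not indexed by the space's states",
                          id), "physupply_structural_error")
    }
    neg <- which(m < 0, arr.ind = TRUE)
    if (nrow(neg) > 0) {
      for (k in seq_len(nrow(neg))) {
        add(id, labels[neg[k, 1]], "negative",
            sprintf("entry to %s is %.3g", labels[neg[k, 2]],
                    m[neg[k, 1], neg[k, 2]]))
      }
    }
    rs <- rowSums(m)
    bad <- which(abs(rs - 1) > tol)
    for (k in bad) {
      add(id, labels[k], "row_sum", sprintf("row sums to %.15g", rs[k]))
    }
    dis <- which(m > 0 & !space$allowed, arr.ind = TRUE)
    if (nrow(dis) > 0) {
      for (k in seq_len(nrow(dis))) {
        add(id, labels[dis[k, 1]], "disallowed",
            sprintf("mass %.3g on disallowed pair -> %s",
                    m[dis[k, 1], dis[k, 2]], labels[dis[k, 2]]))
      }
    }
  }
  issues <- if (length(issues)) do.call(rbind, issues) else
    data.frame(matrix_id = character(0), row = character(0),
               type = character(0), detail = character(0),
               stringsAsFactors = FALSE)
  structure(list(issues = issues, n_matrices = length(mats)),
            class = "tm_validation")
}

#' Is a validation report clean?
#' @param report A `tm_validation` from [validate_transition_model()].
#' @return `TRUE` if no issues were found.
#' @export
is_clean <- function(report) {
  stopifnot(inherits(report, "tm_validation"))
  nrow(report$issues) == 0L
}

#' @export
print.tm_validation <- function(x, ...) {
  if (is_clean(x)) {
    cat("<tm_validation> clean (", x$n_matrices, "matrix/matrices checked )\n")
  } else {
    cat("<tm_validation>", nrow(x$issues), "issue(s):\n")
    print(utils::head(x$issues, 20))
    if (nrow(x$issues) > 20) cat("  ...\n")
  }
  invisible(x)
}

#' Serialize a state space to CSV
#'
#' Writes the state table (one row per state) and the allowed-transition
#' mask (long form, allowed origin-destination pairs only).
#'
#' @param space A `state_space`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_state_space <- function(space, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  states_path <- file.path(dir, "states.csv")
  mask_path <- file.path(dir, "allowed_transitions.csv")
  utils::write.csv(space$states, states_path, row.names = FALSE)
  idx <- which(space$allowed, arr.ind = TRUE)
  mask <- data.frame(origin = rownames(space$allowed)[idx[, 1]],
                     destination = colnames(space$allowed)[idx[, 2]],
                     stringsAsFactors = FALSE)
  mask <- mask[order(idx[, 1], idx[, 2]), ]
  utils::write.csv(mask, mask_path, row.names = FALSE)
  invisible(c(states = states_path, mask = mask_path))
}
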