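# Transition model container: a row-stochastic annual transition matrix
# over the state space, with optional per-year override matrices for
# time-varying scenarios.

#' Create a transition model
#'
#' @param space A [build_state_space()] object.
#' @param matrix Square numeric matrix of annual transition probabilities,
#'   indexed (rows = origins, columns = destinations) by the space's state
#'   labels.  Unnamed matrices of the right dimension are accepted and
#'   labelled.
#' @param overrides Named list (names = calendar years) of full
#'   replacement matrices applied in those projection years.
#' @param validate Run [validate_transition_model()] and fail on issues?
#' @return An object of class `transition_model`.
#' @export
transition_model <- function(space, matrix, overrides = list(),
                             validate = TRUE) {
  labels <- space$states$label
  n <- length(labels)
  fix <- function(m) {
    if (!is.matrix(m) || nrow(m) != n || ncol(m) != n) {
      .phys_error("transition matrix dimensions do not match the state space",
                  "physupply_structural_error")
    }
    dimnames(m) <- list(labels, labels)
    m
  }
  matrix <- fix(matrix)
  overrides <- lapply(overrides, fix)
  if (length(overrides) &&
      anyNA(suppressWarnings(as.integer(names(overrides))))) {
    .phys_error("override names must be calendar years",
                "physupply_structural_error")
  }
  model <- structure(list(space = space, matrix = matrix,
                          overrides = overrides),
                     class = "transition_model")
  if (validate) {
    rep <- validate_transition_model(space, model)
    if (!is_clean(rep)) {
      print(rep)
      .phys_error("transition model failed validation",
                  "physupply_validation_error")
    }
  }
  model
}

#' Matrix in force for a projection year
#'
#' Returns the per-year override for `year` if one exists, otherwise the
#' base matrix.
#'
#' @param model A `transition_model`.
#' @param year Calendar year.
#' @return A numeric matrix.
#' @export
resolve_matrix <- function(model, year) {
  key <- as.character(year)
  if (key %in% names(model$overrides)) model$overrides[[key]] else model$matrix
}

#' @export
print.transition_model <- function(x, ...) {
  cat("<transition_model>", nrow(x$matrix), "states")
  if (length(x$overrides)) {
    cat(",", length(x$overrides), "per-year override(s):",
        paste(utils::head(names(x$overrides), 5), collapse = " "),
        if (length(x$overrides) > 5) "..." else "")
  }
  cat("\n")
  invisible(x)
}

# Replace one row of the base matrix with a sparse specification
# (named vector of destination probabilities); used by configuration
# builders.  No validation here -- callers validate the finished model.
set_row <- function(matrix, origin, probs) {
  if (!origin %in% rownames(matrix)) {
    .phys_error(sprintf("unknown origin state '%s'", origin),
                "physupply_structural_error")
  }
  missing <- setdiff(names(probs), colnames(matrix))
  if (length(missing)) {
    .phys_error(sprintf("unknown destination state(s): %s",
                        paste(missing, collapse = ", ")),
                "physupply_structural_error")
  }
  matrix[origin, ] <- 0
  matrix[origin, names(probs)] <- probs
  matrix
}

#' Write / read a transition matrix as long-form CSV
#'
#' Long form: `origin,destination,probability` (zero entries omitted).
#'
#' @param model A `transition_model` (base matrix only).
#' @param path CSV path.
#' @return `write_transition_model()` returns `path` invisibly;
#'   `read_transition_matrix()` returns a matrix over `space`'s labels.
#' @export
write_transition_model <- function(model, path) {
  m <- model$matrix
  idx <- which(m > 0, arr.ind = TRUE)
  df <- data.frame(origin = rownames(m)[idx[, 1]],
                   destination = colnames(m)[idx[, 2]],
                   probability = m[idx],
                   stringsAsFactors = FALSE)
  df <- df[order(idx[, 1], idx[, 2]), ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_transition_model
#' @param space State space indexing the matrix.
#' @export
read_transition_matrix <- function(path, space) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  labels <- space$states$label
  bad <- setdiff(unique(c(df$origin, df$destination)), labels)
  if (length(bad)) {
    .phys_error(sprintf("%s: unknown state label(s): %s", path,
                        paste(utils::head(bad, 5), collapse = ", ")),
                "physupply_parse_error")
  }
  m <- matrix(0, length(labels), length(labels),
              dimnames = list(labels, labels))
  m[cbind(df$origin, df$destination)] <- df$probability
  m
}
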