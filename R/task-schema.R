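# Component rating limits: the full extent of each ordinal rating column.
.rating_limits <- c(body_position = 12L, movement = 22L, support = 5L)

.rating_cols <- names(.rating_limits)

#' Validate a component rating triple
#'
#' Checks that a (body position, movement, support) triple lies inside the
#' ordinal rating schema: body position in 1-12, movement in 1-22, support in
#' 1-5. Validation is strict -- an out-of-range or non-integer value is an
#' error, never clamped, because the rating ranges define the full extent of
#' the construct and silently coercing a value would corrupt downstream
#' measures.
#'
#' @param body_position integer rating in 1-12 (supine ... airborne).
#' @param movement integer rating in 1-22 (no movement ... hopping on one foot).
#' @param support integer rating in 1-5 (full proximal and head support ...
#'   no support).
#' @return An object of class \code{component_ratings}: a named list with
#'   integer elements \code{body_position}, \code{movement}, \code{support}.
#' @examples
#' validate_ratings(1, 1, 1)    # lying supine, no movement, full support
#' validate_ratings(11, 14, 5)  # walking with hands free
#' @export
validate_ratings <- function(body_position, movement, support) {
  vals <- list(body_position = body_position, movement = movement,
               support = support)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (length(v) != 1L || !is.numeric(v) || !is.finite(v)) {
      stop(sprintf("%s must be a single finite number", nm), call. = FALSE)
    }
    if (v != round(v)) {
      stop(sprintf("%s must be an integer rating (got %g); legal range 1-%d",
                   nm, v, .rating_limits[[nm]]), call. = FALSE)
    }
    if (v < 1 || v > .rating_limits[[nm]]) {
      stop(sprintf("%s rating %g outside legal range 1-%d",
                   nm, v, .rating_limits[[nm]]), call. = FALSE)
    }
  }
  structure(lapply(vals, as.integer), class = "component_ratings")
}

#' @export
print.component_ratings <- function(x, ...) {
  cat(sprintf("Component ratings: body position %d, movement %d, support %d\n",
              x$body_position, x$movement, x$support))
  invisible(x)
}

#' Construct a task table
#'
#' A task table is a data frame of gross motor tasks, one row per task, with
#' columns \code{item_number} (unique positive integer id), \code{item_name}
#' (free text, never used as a key) and the three component rating columns.
#' Every rating triple is validated against the rating schema.
#'
#' @param df data frame with columns \code{item_number}, \code{item_name},
#'   \code{body_position}, \code{movement}, \code{support}.
#' @return The validated data frame with class \code{task_table} prepended.
#' @export
task_table <- function(df) {
  required <- c("item_number", "item_name", .rating_cols)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0) stop("no tasks: table is empty", call. = FALSE)
  if (anyDuplicated(df$item_number)) {
    dups <- unique(df$item_number[duplicated(df$item_number)])
    stop("duplicate item_number(s): ", paste(dups, collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_len(nrow(df))) {
    tryCatch(
      validate_ratings(df$body_position[i], df$movement[i], df$support[i]),
      error = function(e) {
        stop(sprintf("row %d (item %s): %s", i, df$item_number[i],
                     conditionMessage(e)), call. = FALSE)
      }
    )
  }
  df$item_number <- as.integer(df$item_number)
  for (col in .rating_cols) df[[col]] <- as.integer(df[[col]])
  df <- df[, required]
  class(df) <- c("task_table", "data.frame")
  df
}

#' Read a task rating table from CSV
#'
#' Canonical interchange format: comma-delimited UTF-8 with a header row
#' \code{item_number,item_name,body_position,movement,support}. Row order is
#' preserved; ratings are validated on read.
#'
#' @param path path to a CSV file (or a connection).
#' @return A \code{\link{task_table}}.
#' @export
read_task_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  task_table(df)
}

#' Write a task table to CSV
#'
#' @param table a \code{\link{task_table}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_task_table <- function(table, path) {
  stopifnot(inherits(table, "task_table"))
  utils::write.csv(table, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Bundled GMFM-66 component ratings
#'
#' The consensus component-measure ratings for all 66 items of the Gross
#' Motor Function Measure-66, in item-number order. These ratings are the
#' design matrix of the specification-equation regression and the input to
#' every GM-unit measurement of the bundled instrument.
#'
#' @return A \code{\link{task_table}} with 66 rows.
#' @examples
#' tab <- gmfm_ratings()
#' subset(tab, item_number == 69)  # walking with hands free: (11, 14, 5)
#' @export
gmfm_ratings <- function() {
  path <- system.file("extdata", "gmfm66_component_ratings.csv",
                      package = "gmunits", mustWork = TRUE)
  read_task_table(path)
}

#' Bundled GM-unit reference table
#'
#' The reference table for the bundled 66-item instrument: each item's
#' predicted task difficulty (specification-equation metric, two decimals)
#' and its integer measure in GM units, ordered by GM units. The anchors are
#' item 2 (0 GM units) and item 69 (100 GM units).
#'
#' The difficulty column holds the specification-equation predictions: items
#' sharing a rating triple share the value exactly.
#'
#' @return A data frame of class \code{gm_reference} with columns
#'   \code{item_number}, \code{item_name}, \code{predicted_difficulty},
#'   \code{gm_units}.
#' @export
gm_reference <- function() {
  path <- system.file("extdata", "gm_reference_table.csv",
                      package = "gmunits", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$item_number <- as.integer(df$item_number)
  df$gm_units <- as.integer(df$gm_units)
  class(df) <- c("gm_reference", "data.frame")
  df
}
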