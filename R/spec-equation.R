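#' Construct a specification equation
#'
#' A specification equation maps a task's component ratings to a predicted
#' difficulty on the interval difficulty metric:
#' \deqn{D = b_0 + b_1 BodyPosition + b_2 Movement + b_3 Support.}
#' Its predictive accuracy is what exposes the underlying gross-motor
#' construct theory to falsification.
#'
#' @param intercept intercept on the difficulty metric.
#' @param body_position,movement,support coefficients, difficulty units per
#'   rating step.
#' @param provenance \code{"fitted"} (estimated from data) or
#'   \code{"published"} (the fixed reference instance).
#' @return An object of class \code{specification_equation}.
#' @seealso \code{\link{published_equation}}, \code{\link{predict_difficulty}}
#' @export
specification_equation <- function(intercept, body_position, movement, support,
                                   provenance = c("fitted", "published")) {
  provenance <- match.arg(provenance)
  coefs <- c(body_position = body_position, movement = movement,
             support = support)
  if (!is.finite(intercept) || any(!is.finite(coefs))) {
    stop("specification equation coefficients must be finite", call. = FALSE)
  }
  structure(
    list(intercept = intercept, coefficients = coefs, provenance = provenance),
    class = "specification_equation"
  )
}

#' The published specification equation
#'
#' The reference equation, with coefficients carried at their printed
#' two-decimal precision:
#' \deqn{D = 6.76 + 1.23 BodyPosition + 1.21 Movement + 4.93 Support.}
#' Applied to the bundled ratings it reproduces the reference GM-unit table
#' exactly, which is only true of the two-decimal coefficients.
#'
#' @return A \code{\link{specification_equation}} with provenance
#'   \code{"published"}.
#' @examples
#' eq <- published_equation()
#' predict_difficulty(eq, validate_ratings(1, 1, 1))   # 14.13, the low anchor
#' predict_difficulty(eq, validate_ratings(11, 14, 5)) # 61.88, the high anchor
#' @export
published_equation <- function() {
  specification_equation(6.76, 1.23, 1.21, 4.93, provenance = "published")
}

#' @export
print.specification_equation <- function(x, ...) {
  cat(sprintf(
    "Specification equation (%s):\n  difficulty = %.4g + %.4g*body_position + %.4g*movement + %.4g*support\n",
    x$provenance, x$intercept, x$coefficients[["body_position"]],
    x$coefficients[["movement"]], x$coefficients[["support"]]))
  invisible(x)
}

#' Predict task difficulty from component ratings
#'
#' Evaluates the specification equation. The unrounded value is the working
#' metric; the two-decimal rounding (\code{rounded = TRUE}) matches the
#' printed precision used throughout the reference table pipeline.
#'
#' @param equation a \code{\link{specification_equation}}.
#' @param ratings a \code{\link{validate_ratings}} triple, or a
#'   \code{\link{task_table}} / data frame with the three rating columns
#'   (vectorized, one prediction per row).
#' @param rounded if \code{TRUE}, round to 2 decimal places.
#' @return Numeric vector of predicted difficulties.
#' @export
predict_difficulty <- function(equation, ratings, rounded = FALSE) {
  stopifnot(inherits(equation, "specification_equation"))
  if (inherits(ratings, "component_ratings")) {
    ratings <- as.data.frame(unclass(ratings))
  }
  if (!all(.rating_cols %in% names(ratings))) {
    stop("ratings must supply body_position, movement and support",
         call. = FALSE)
  }
  out <- equation$intercept +
    equation$coefficients[["body_position"]] * ratings$body_position +
    equation$coefficients[["movement"]] * ratings$movement +
    equation$coefficients[["support"]] * ratings$support
  if (rounded) round(out, 2) else out
}

#' Pearson product-moment correlation
#'
#' Correlation screen used to quantify the linear association between each
#' component measure and observed task difficulty, and to summarize agreement
#' between predicted and observed difficulties. Constant input is rejected
#' (the correlation is undefined) rather than returned as \code{NA}.
#'
#' @param x,y numeric vectors of equal length (at least 3).
#' @return Correlation in [-1, 1].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  stats::cor(x, y, method = "pearson")
}

#' Variance inflation factors
#'
#' For each predictor column, \eqn{VIF_j = 1 / (1 - R^2_j)} where
#' \eqn{R^2_j} comes from regressing predictor j on the remaining predictors
#' (with intercept). Predictors at or above the threshold are flagged as
#' collinear; an exactly collinear predictor is reported as infinite.
#'
#' @param predictors matrix or data frame, columns = predictors; at least two
#'   columns and more rows than predictors.
#' @param threshold flag level; the conventional cut of 10 is the default.
#' @return Data frame with columns \code{predictor}, \code{vif},
#'   \code{flagged}.
#' @export
compute_vif <- function(predictors, threshold = 10) {
  X <- as.data.frame(predictors)
  p <- ncol(X)
  if (p < 2) stop("need at least two predictors", call. = FALSE)
  if (nrow(X) <= p) stop("need more rows than predictors", call. = FALSE)
  vif <- vapply(seq_len(p), function(j) {
    fit <- stats::lm(X[[j]] ~ ., data = X[, -j, drop = FALSE])
    tss <- sum((X[[j]] - mean(X[[j]]))^2)
    r2 <- 1 - sum(stats::resid(fit)^2) / tss
    if (1 - r2 < 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  data.frame(predictor = names(X), vif = vif,
             flagged = vif >= threshold, row.names = NULL)
}

# Resolve an observed-difficulty argument (bare vector in table order, or a
# data frame keyed by item_number) into a vector aligned with `table`.
.align_difficulties <- function(difficulties, table) {
  if (is.data.frame(difficulties)) {
    if (!all(c("item_number", "observed_difficulty") %in% names(difficulties))) {
      stop("difficulty data frame needs columns item_number, observed_difficulty",
           call. = FALSE)
    }
    idx <- match(table$item_number, difficulties$item_number)
    if (anyNA(idx)) {
      orphans <- table$item_number[is.na(idx)]
      stop("no observed difficulty for item(s): ",
           paste(orphans, collapse = ", "), call. = FALSE)
    }
    difficulties$observed_difficulty[idx]
  } else {
    if (length(difficulties) != nrow(table)) {
      stop("need one observed difficulty per task", call. = FALSE)
    }
    as.numeric(difficulties)
  }
}

#' Forward stepwise fit of the specification equation
#'
#' Fits task difficulty on the three component ratings by pure forward
#' stepwise ordinary least squares. At each step the candidate predictor
#' giving the largest adjusted-R-squared increase is entered, admitted only
#' if its partial-F p-value is below \code{entry_alpha}; there is no removal
#' step. Zero-order Pearson correlations are screened first and variance
#' inflation factors are computed on the full candidate set; collinearity is
#' flagged, never silently acted on, unless \code{drop_collinear = TRUE}, in
#' which case the flagged predictor with the weaker zero-order correlation to
#' the outcome is excluded before stepping.
#'
#' The ratings enter as numeric integer codes. Because they are ordinal, the
#' coefficient estimates cannot themselves be read on an interval scale; the
#' report carries this caveat.
#'
#' @param difficulties observed difficulties: numeric vector in table order,
#'   or data frame with columns \code{item_number}, \code{observed_difficulty}.
#' @param table a \code{\link{task_table}} (at least 10 tasks).
#' @param entry_alpha partial-F entry criterion (default 0.05).
#' @param vif_threshold collinearity flag level (default 10).
#' @param drop_collinear drop the weaker of a flagged collinear pair before
#'   stepping (default \code{FALSE}).
#' @return A list of class \code{stepwise_fit} with elements
#'   \code{equation} (a \code{\link{specification_equation}}; predictors never
#'   entered get coefficient 0) and \code{report} (class
#'   \code{regression_report}) holding adjusted R-squared, overall F and its
#'   p-value, RMSE, the coefficient table (estimate, SE, p), VIFs, screening
#'   correlations, the step trace, and the Pearson correlation between fitted
#'   predictions and the observed difficulties.
#' @export
forward_stepwise_fit <- function(difficulties, table, entry_alpha = 0.05,
                                 vif_threshold = 10, drop_collinear = FALSE) {
  stopifnot(inherits(table, "data.frame"))
  if (nrow(table) < 10) stop("need at least 10 tasks", call. = FALSE)
  y <- .align_difficulties(difficulties, table)
  dat <- data.frame(y = y,
                    body_position = table$body_position,
                    movement = table$movement,
                    support = table$support)

  vif_tab <- compute_vif(dat[.rating_cols], threshold = vif_threshold)
  if (any(vif_tab$flagged)) {
    warning("collinearity flagged (VIF >= ", vif_threshold, "): ",
            paste(vif_tab$predictor[vif_tab$flagged], collapse = ", "),
            call. = FALSE)
  }

  constant_y <- stats::sd(y) == 0
  screen_r <- if (constant_y) {
    stats::setNames(rep(NA_real_, 3), .rating_cols)
  } else {
    vapply(.rating_cols, function(v) pearson_r(dat[[v]], y), numeric(1))
  }

  candidates <- .rating_cols
  if (drop_collinear && any(vif_tab$flagged)) {
    flagged <- vif_tab$predictor[vif_tab$flagged]
    drop <- flagged[which.min(abs(screen_r[flagged]))]
    candidates <- setdiff(candidates, drop)
  }

  current <- stats::lm(y ~ 1, data = dat)
  entered <- character(0)
  trace <- list()
  repeat {
    remaining <- setdiff(candidates, entered)
    if (length(remaining) == 0 || constant_y) break
    best <- NULL
    for (v in remaining) {
      form <- stats::reformulate(c(entered, v), response = "y")
      fit <- stats::lm(form, data = dat)
      adj <- summary(fit)$adj.r.squared
      if (is.null(best) || adj > best$adj) best <- list(v = v, fit = fit, adj = adj)
    }
    an <- stats::anova(current, best$fit)
    pval <- an[["Pr(>F)"]][2]
    fval <- an[["F"]][2]
    if (!is.na(pval) && pval < entry_alpha) {
      entered <- c(entered, best$v)
      current <- best$fit
      trace[[length(trace) + 1]] <- data.frame(
        step = length(entered), term = best$v, adjusted_r2 = best$adj,
        partial_f = fval, p_value = pval)
    } else break
  }

  if (length(entered) == 0) {
    warning("no predictor met the entry criterion; returning intercept-only model",
            call. = FALSE)
  }

  step_trace <- if (length(trace)) do.call(rbind, trace) else
    data.frame(step = integer(0), term = character(0),
               adjusted_r2 = numeric(0), partial_f = numeric(0),
               p_value = numeric(0))

  sm <- summary(current)
  coefs <- stats::coef(current)
  full <- stats::setNames(rep(0, 3), .rating_cols)
  full[entered] <- coefs[entered]
  equation <- specification_equation(
    intercept = unname(coefs[["(Intercept)"]]),
    body_position = full[["body_position"]],
    movement = full[["movement"]],
    support = full[["support"]],
    provenance = "fitted")

  coef_tab <- data.frame(
    term = rownames(sm$coefficients),
    estimate = sm$coefficients[, "Estimate"],
    std_error = sm$coefficients[, "Std. Error"],
    p_value = sm$coefficients[, "Pr(>|t|)"],
    row.names = NULL)

  fstat <- sm$fstatistic
  report <- structure(list(
    n = nrow(dat),
    adjusted_r2 = sm$adj.r.squared,
    f_value = if (is.null(fstat)) NA_real_ else unname(fstat[1]),
    f_p_value = if (is.null(fstat)) NA_real_ else
      unname(stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)),
    rmse = sm$sigma,
    coefficients = coef_tab,
    vif = vif_tab,
    screening_r = screen_r,
    step_trace = step_trace,
    pearson_r_predicted_vs_observed =
      if (length(entered) == 0 || constant_y) NA_real_ else
        pearson_r(stats::fitted(current), y),
    caveat = paste("ratings are ordinal; coefficient estimates cannot be",
                   "interpreted on an interval scale")),
    class = "regression_report")

  structure(list(equation = equation, report = report, fit = current),
            class = "stepwise_fit")
}

#' @export
print.regression_report <- function(x, digits = 4, ...) {
  cat(sprintf("Specification-equation fit (n = %d)\n", x$n))
  cat(sprintf("  adjusted R^2 = %.*g, F = %.*g (p = %.3g), RMSE = %.*g\n",
              digits, x$adjusted_r2, digits, x$f_value, x$f_p_value,
              digits, x$rmse))
  if (!is.na(x$pearson_r_predicted_vs_observed)) {
    cat(sprintf("  Pearson r (predicted vs observed) = %.2f\n",
                x$pearson_r_predicted_vs_observed))
  }
  cat("  Steps entered:",
      if (nrow(x$step_trace)) paste(x$step_trace$term, collapse = " -> ")
      else "(none)", "\n")
  cat("  Coefficients:\n")
  print(x$coefficients, digits = digits)
  cat("  VIF:\n")
  print(x$vif, digits = digits)
  cat("  Note:", x$caveat, "\n")
  invisible(x)
}

#' @export
print.stepwise_fit <- function(x, ...) {
  print(x$equation)
  print(x$report)
  invisible(x)
}

#' Serialize a regression report to JSON
#'
#' @param report a \code{regression_report}.
#' @param path optional output path; if \code{NULL} the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to \code{path}).
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "regression_report"))
  payload <- unclass(report)
  payload$screening_r <- as.list(payload$screening_r)
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
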