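# Partial credit model (PCM) simulation and joint maximum likelihood (JMLE)
# item calibration. The PCM is the adjacent-category Rasch model for ordered
# polytomous scores: for an item with categories 0..m and step parameters
# d_j = delta + tau_j,
#   P(X = k | theta) = exp(sum_{j<=k} (theta - d_j)) / Z,  empty sum = 0.
# The calibrator supplies the "observed item difficulty" vector that the
# specification-equation regression consumes, standing in for an external
# Rasch calibration of the instrument.

#' Construct a partial credit model item
#'
#' @param difficulty overall item difficulty delta, logits.
#' @param thresholds category step thresholds tau (logits), one per step
#'   (\code{n_categories - 1} of them); must sum to zero, the centering
#'   convention that separates delta from the steps. A dichotomous item has a
#'   single threshold, necessarily 0.
#' @param name optional item label.
#' @return Object of class \code{pcm_item} with fields \code{difficulty},
#'   \code{thresholds}, \code{n_categories}, \code{name}.
#' @examples
#' pcm_item(0.5)                       # dichotomous
#' pcm_item(-1, c(-0.8, 0, 0.8))      # 4 ordered categories (scored 0-3)
#' @export
pcm_item <- function(difficulty, thresholds = 0, name = NULL) {
  stopifnot(is.numeric(difficulty), length(difficulty) == 1,
            is.finite(difficulty), is.numeric(thresholds),
            all(is.finite(thresholds)))
  if (abs(sum(thresholds)) > 1e-8) {
    stop("thresholds must sum to zero (centering convention)", call. = FALSE)
  }
  structure(list(difficulty = difficulty, thresholds = as.numeric(thresholds),
                 n_categories = length(thresholds) + 1L, name = name),
            class = "pcm_item")
}

#' @export
print.pcm_item <- function(x, ...) {
  cat(sprintf("PCM item%s: difficulty %.3f logits, %d categories, thresholds (%s)\n",
              if (is.null(x$name)) "" else paste0(" ", x$name),
              x$difficulty, x$n_categories,
              paste(sprintf("%.3f", x$thresholds), collapse = ", ")))
  invisible(x)
}

# Category log-numerators for abilities `theta` (vector) and step parameters
# `d` (delta + tau): matrix length(theta) x (m + 1).
.pcm_lognum <- function(theta, d) {
  cumd <- c(0, cumsum(d))
  k <- 0:length(d)
  outer(theta, k) - matrix(cumd, nrow = length(theta), ncol = length(k),
                           byrow = TRUE)
}

# Row-normalized probabilities from a log-numerator matrix (stable).
.pcm_softmax <- function(L) {
  L <- L - apply(L, 1, max)
  E <- exp(L)
  E / rowSums(E)
}

#' Partial credit model category probabilities
#'
#' Probability of each score category for a person at ability \code{theta}
#' on one item: category k gets probability proportional to
#' \code{exp(sum_{j<=k} (theta - delta - tau_j))} with the empty sum equal
#' to 0.
#'
#' @param theta ability in logits (vectorized).
#' @param item a \code{\link{pcm_item}}.
#' @return For scalar \code{theta}, a probability vector of length
#'   \code{n_categories}; otherwise a matrix with one row per ability.
#' @examples
#' pcm_category_probabilities(0, pcm_item(0))  # (0.5, 0.5)
#' @export
pcm_category_probabilities <- function(theta, item) {
  stopifnot(inherits(item, "pcm_item"), is.numeric(theta), all(is.finite(theta)))
  d <- item$difficulty + item$thresholds
  P <- .pcm_softmax(.pcm_lognum(theta, d))
  if (length(theta) == 1) drop(P) else P
}

#' Simulate a PCM response matrix
#'
#' Draws each person-by-item cell independently from the model's category
#' probabilities. The same seed always yields the same matrix; the global
#' random number generator state is left untouched.
#'
#' @param items list of \code{\link{pcm_item}}.
#' @param abilities numeric vector of person abilities, logits.
#' @param seed integer seed (required).
#' @param missing_rate proportion of cells blanked to \code{NA} (default 0).
#' @return Integer matrix (persons x items) of category scores
#'   \code{0..n_categories-1}, \code{NA} = missing.
#' @export
simulate_responses <- function(items, abilities, seed, missing_rate = 0) {
  stopifnot(length(items) > 0, length(abilities) > 0,
            all(vapply(items, inherits, logical(1), "pcm_item")))
  if (missing(seed) || !is.numeric(seed)) {
    stop("an explicit integer seed is required", call. = FALSE)
  }
  stopifnot(missing_rate >= 0, missing_rate < 1)
  n <- length(abilities)
  withr::with_seed(as.integer(seed), {
    resp <- vapply(items, function(it) {
      P <- pcm_category_probabilities(abilities, it)
      if (is.null(dim(P))) P <- matrix(P, nrow = 1)
      cum <- t(apply(P, 1, cumsum))
      u <- stats::runif(n)
      as.integer(rowSums(u > cum))  # count of cumulative bins exceeded
    }, integer(n))
    resp <- matrix(resp, nrow = n,
                   dimnames = list(NULL, vapply(seq_along(items), function(i) {
                     if (is.null(items[[i]]$name)) paste0("item", i)
                     else items[[i]]$name
                   }, character(1))))
    if (missing_rate > 0) {
      blank <- stats::runif(length(resp)) < missing_rate
      resp[blank] <- NA_integer_
    }
    resp
  })
}

#' Write / read a response matrix as CSV
#'
#' Persons as rows, items as columns, blank cell = missing.
#'
#' @param responses integer matrix of category scores.
#' @param path CSV path.
#' @return \code{path} invisibly (write); integer matrix (read).
#' @export
write_response_matrix <- function(responses, path) {
  utils::write.csv(as.data.frame(responses), path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' @rdname write_response_matrix
#' @export
read_response_matrix <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as.matrix(sapply(df, as.integer))
}

#' Calibrate PCM item difficulties by joint maximum likelihood
#'
#' Alternating Newton-Raphson JMLE: person abilities and item step
#' parameters are updated in turn until the largest parameter change falls
#' below \code{tol}. Item difficulties are centered to mean zero each
#' iteration (the identification constraint), so estimates are reported on a
#' mean-zero logit metric. Persons with extreme score patterns (all-minimum
#' or all-maximum) carry no information about item locations and are
#' excluded from estimation; their abilities have no finite MLE. Items
#' observed in fewer than two distinct categories are flagged inestimable
#' and excluded with a warning. Missing responses are treated as ignorably
#' missing and skipped in all likelihood sums.
#'
#' @param responses integer matrix (persons x items), categories
#'   \code{0..K-1}, \code{NA} = missing.
#' @param n_categories number of score categories per item: single integer
#'   recycled to all items, or vector; default \code{NULL} infers
#'   max observed + 1 per item.
#' @param tol convergence tolerance on the maximum absolute parameter change
#'   (default 1e-6).
#' @param max_iter outer iteration cap (default 200).
#' @param bias_correction apply the standard (K-1)/K correction for the
#'   statistical bias of joint estimation, K the number of estimable items
#'   (default \code{TRUE}). Joint estimation overstates the spread of item
#'   locations by about K/(K-1) -- a factor of 2 in a two-item design,
#'   negligible at 66 items; the correction rescales the centered step
#'   parameters accordingly.
#' @return Object of class \code{pcm_calibration}: \code{difficulty} (named,
#'   centered to mean zero; \code{NA} for inestimable items),
#'   \code{thresholds} (list, centered per item), \code{se} (standard errors
#'   of the difficulties), \code{theta} (person abilities; \code{-Inf}/\code{Inf}
#'   for extreme patterns), \code{converged}, \code{iterations},
#'   \code{inestimable} (column indices).
#' @export
calibrate_pcm <- function(responses, n_categories = NULL, tol = 1e-6,
                          max_iter = 200, bias_correction = TRUE) {
  X <- as.matrix(responses)
  if (length(X) == 0 || nrow(X) == 0 || ncol(X) == 0) {
    stop("empty response matrix", call. = FALSE)
  }
  storage.mode(X) <- "integer"
  n_items <- ncol(X)
  item_names <- colnames(X)
  if (is.null(item_names)) item_names <- paste0("item", seq_len(n_items))

  K <- if (is.null(n_categories)) {
    apply(X, 2, function(x) max(x, na.rm = TRUE) + 1L)
  } else rep_len(as.integer(n_categories), n_items)
  if (any(K < 2, na.rm = TRUE)) stop("items need at least 2 categories",
                                     call. = FALSE)

  # Items observed in < 2 distinct categories are inestimable.
  n_distinct <- apply(X, 2, function(x) length(unique(x[!is.na(x)])))
  inestimable <- unname(which(n_distinct < 2))
  if (length(inestimable) > 0) {
    warning("item(s) with responses in a single category are inestimable and excluded: ",
            paste(item_names[inestimable], collapse = ", "), call. = FALSE)
  }
  est_items <- setdiff(seq_len(n_items), inestimable)
  if (length(est_items) == 0) stop("no estimable items", call. = FALSE)

  Xe <- X[, est_items, drop = FALSE]
  Ke <- K[est_items]
  m <- Ke - 1L  # steps per item

  # Person scores over estimable items; extreme patterns excluded.
  answered_max <- rowSums(t(t(!is.na(Xe)) * m))
  score <- rowSums(Xe, na.rm = TRUE)
  extreme <- rowSums(!is.na(Xe)) == 0 | score == 0 | score == answered_max
  use_p <- which(!extreme)
  if (length(use_p) == 0) {
    stop("no persons with non-extreme response patterns", call. = FALSE)
  }

  Xu <- Xe[use_p, , drop = FALSE]
  theta <- log((score[use_p] + 0.5) / (answered_max[use_p] - score[use_p] + 0.5))
  d <- lapply(seq_along(est_items), function(i) rep(0, m[i]))
  clamp <- function(x, lim = 15) pmin(pmax(x, -lim), lim)

  # P(X >= j) matrix for persons `th` on steps `dd`: n x m.
  survivor <- function(P) {
    Kc <- ncol(P)
    S <- P[, Kc:2, drop = FALSE]
    if (ncol(S) > 1) S <- t(apply(S, 1, cumsum))
    S[, ncol(S):1, drop = FALSE]
  }

  iter <- 0L
  converged <- FALSE
  repeat {
    iter <- iter + 1L
    max_change <- 0

    # --- person step: Newton on theta given items (vectorized, inner loop)
    for (inner in 1:10) {
      Eall <- numeric(length(use_p)); Vall <- numeric(length(use_p))
      for (i in seq_along(est_items)) {
        obs <- !is.na(Xu[, i])
        if (!any(obs)) next
        P <- .pcm_softmax(.pcm_lognum(theta[obs], d[[i]]))
        kk <- 0:m[i]
        Ei <- drop(P %*% kk)
        Vi <- drop(P %*% kk^2) - Ei^2
        Eall[obs] <- Eall[obs] + Ei
        Vall[obs] <- Vall[obs] + Vi
      }
      step <- (rowSums(Xu, na.rm = TRUE) - Eall) / pmax(Vall, 1e-10)
      step <- pmin(pmax(step, -1), 1)  # damped
      theta_new <- clamp(theta + step)
      moved <- max(abs(theta_new - theta))
      theta <- theta_new
      if (moved < tol) break
    }
    max_change <- max(max_change, moved)

    # --- item step: Newton on step parameters, a few steps per item
    for (i in seq_along(est_items)) {
      xi <- Xu[, i]
      obs <- !is.na(xi)
      x <- xi[obs]; th <- theta[obs]
      nj <- vapply(seq_len(m[i]), function(j) sum(x >= j), numeric(1))
      for (inner in 1:3) {
        P <- .pcm_softmax(.pcm_lognum(th, d[[i]]))
        S <- survivor(P)
        g <- colSums(S) - nj
        H <- matrix(0, m[i], m[i])
        for (j in seq_len(m[i])) for (l in seq_len(j)) {
          H[j, l] <- H[l, j] <- sum(S[, j] * S[, l] - S[, max(j, l)])
        }
        upd <- tryCatch(solve(H, g), error = function(e) g / diag(H))
        upd <- pmin(pmax(-upd, -2), 2)  # Newton ascent step, damped
        d_new <- clamp(d[[i]] + upd)
        moved <- max(abs(d_new - d[[i]]))
        d[[i]] <- d_new
        if (moved < tol) break
      }
      max_change <- max(max_change, moved)
    }

    # --- identification: center mean item difficulty at zero
    delta <- vapply(d, mean, numeric(1))
    shift <- mean(delta)
    d <- lapply(d, function(di) di - shift)
    theta <- theta - shift

    if (max_change < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }

  K_items <- length(est_items)
  if (bias_correction && K_items > 1) {
    d <- lapply(d, function(di) di * (K_items - 1) / K_items)
  }

  # Standard errors of delta_i = mean(d_i) from the observed information.
  se_est <- vapply(seq_along(est_items), function(i) {
    xi <- Xu[, i]; obs <- !is.na(xi)
    th <- theta[obs]
    P <- .pcm_softmax(.pcm_lognum(th, d[[i]]))
    S <- survivor(P)
    H <- matrix(0, m[i], m[i])
    for (j in seq_len(m[i])) for (l in seq_len(j)) {
      H[j, l] <- H[l, j] <- sum(S[, j] * S[, l] - S[, max(j, l)])
    }
    a <- rep(1 / m[i], m[i])
    v <- tryCatch(drop(t(a) %*% solve(-H, a)), error = function(e) NA_real_)
    if (is.na(v) || v < 0) NA_real_ else sqrt(v)
  }, numeric(1))

  difficulty <- rep(NA_real_, n_items)
  thresholds <- vector("list", n_items)
  se <- rep(NA_real_, n_items)
  delta <- vapply(d, mean, numeric(1))
  difficulty[est_items] <- delta
  se[est_items] <- se_est
  for (i in seq_along(est_items)) {
    thresholds[[est_items[i]]] <- d[[i]] - delta[i]
  }
  names(difficulty) <- item_names
  names(se) <- item_names
  names(thresholds) <- item_names

  theta_full <- rep(NA_real_, nrow(X))
  theta_full[use_p] <- theta
  theta_full[extreme & score == 0] <- -Inf
  theta_full[extreme & score > 0] <- Inf

  structure(list(difficulty = difficulty, thresholds = thresholds, se = se,
                 theta = theta_full, converged = converged, iterations = iter,
                 inestimable = inestimable),
            class = "pcm_calibration")
}

#' @export
print.pcm_calibration <- function(x, ...) {
  ok <- !is.na(x$difficulty)
  cat(sprintf(
    "PCM calibration: %d item(s) (%d inestimable), %s in %d iteration(s)\n",
    length(x$difficulty), length(x$inestimable),
    if (x$converged) "converged" else "NOT converged", x$iterations))
  cat(sprintf("  difficulty range: [%.3f, %.3f] logits (centered)\n",
              min(x$difficulty[ok]), max(x$difficulty[ok])))
  invisible(x)
}

#' Maximum likelihood ability estimate for one person
#'
#' Newton-Raphson MLE of theta under the PCM with item parameters fixed. An
#' all-minimum or all-maximum response pattern has no finite MLE; such
#' patterns are returned flagged \code{extreme = TRUE} with \code{theta}
#' \code{-Inf}/\code{Inf} rather than presented as an estimate.
#'
#' @param responses_row integer vector of one person's category scores
#'   (\code{NA} = missing), one per item.
#' @param items list of \code{\link{pcm_item}} of the same length.
#' @return List of class \code{ability_estimate}: \code{theta}, \code{se},
#'   \code{extreme}.
#' @export
estimate_person_ability <- function(responses_row, items) {
  stopifnot(length(responses_row) == length(items))
  obs <- which(!is.na(responses_row))
  if (length(obs) == 0) stop("no non-missing responses", call. = FALSE)
  x <- as.integer(responses_row[obs])
  its <- items[obs]
  maxs <- vapply(its, function(it) it$n_categories - 1L, integer(1))
  if (any(x < 0 | x > maxs)) stop("illegal category score", call. = FALSE)
  score <- sum(x)
  if (score == 0 || score == sum(maxs)) {
    return(structure(list(theta = if (score == 0) -Inf else Inf,
                          se = NA_real_, extreme = TRUE),
                     class = "ability_estimate"))
  }
  theta <- 0
  for (iter in 1:100) {
    E <- 0; V <- 0
    for (i in seq_along(its)) {
      p <- pcm_category_probabilities(theta, its[[i]])
      kk <- 0:(its[[i]]$n_categories - 1L)
      Ei <- sum(p * kk)
      E <- E + Ei
      V <- V + sum(p * kk^2) - Ei^2
    }
    step <- (score - E) / max(V, 1e-10)
    step <- min(max(step, -1), 1)
    theta <- min(max(theta + step, -15), 15)
    if (abs(step) < 1e-8) break
  }
  structure(list(theta = theta, se = 1 / sqrt(max(V, 1e-10)), extreme = FALSE),
            class = "ability_estimate")
}

#' @export
print.ability_estimate <- function(x, ...) {
  if (x$extreme) {
    cat("Ability estimate: extreme response pattern (no finite MLE), boundary",
        ifelse(is.finite(x$theta), x$theta, format(x$theta)), "\n")
  } else {
    cat(sprintf("Ability estimate: %.3f logits (SE %.3f)\n", x$theta, x$se))
  }
  invisible(x)
}

#' Rescale logit difficulties to a target interval metric
#'
#' Affine map sending the minimum of the input to \code{low_target} and the
#' maximum to \code{high_target}; order is preserved. Used to express a
#' calibrated logit metric on a conventional 0-100-style scale; downstream
#' anchoring is invariant to any such affine choice.
#'
#' @param difficulties numeric vector (non-constant).
#' @param low_target,high_target targets for the minimum and maximum
#'   (\code{low_target < high_target}).
#' @return Rescaled numeric vector.
#' @export
rescale_logits <- function(difficulties, low_target = 0, high_target = 100) {
  stopifnot(low_target < high_target)
  rng <- range(difficulties, na.rm = TRUE)
  if (diff(rng) == 0) stop("constant input cannot be rescaled", call. = FALSE)
  (difficulties - rng[1]) / diff(rng) * (high_target - low_target) + low_target
}

#' Generate synthetic observed difficulties for regression testing
#'
#' Emulates an external Rasch calibration of the instrument: each task's
#' observed difficulty is its specification-equation prediction plus
#' independent Gaussian noise. The default noise standard deviation, 6.09,
#' is the residual scale of the reference fit, so the default conditions
#' reproduce that fit's error structure. \code{noise_sd = 0} returns the
#' predictions exactly.
#'
#' @param equation a \code{\link{specification_equation}}.
#' @param table a \code{\link{task_table}} (default the bundled ratings).
#' @param noise_sd Gaussian noise standard deviation, difficulty units
#'   (>= 0; default 6.09).
#' @param seed integer seed (required when \code{noise_sd > 0}).
#' @return Data frame with columns \code{item_number},
#'   \code{observed_difficulty}.
#' @export
generate_difficulty_dataset <- function(equation, table = gmfm_ratings(),
                                        noise_sd = 6.09, seed = NULL) {
  stopifnot(inherits(equation, "specification_equation"))
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("noise_sd must be non-negative", call. = FALSE)
  }
  pred <- predict_difficulty(equation, table)
  noise <- if (noise_sd == 0) {
    rep(0, length(pred))
  } else {
    if (is.null(seed)) stop("an explicit integer seed is required when noise_sd > 0",
                            call. = FALSE)
    withr::with_seed(as.integer(seed), stats::rnorm(length(pred), 0, noise_sd))
  }
  data.frame(item_number = table$item_number,
             observed_difficulty = pred + noise)
}
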