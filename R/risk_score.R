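#' Derive a points-based diabetes risk score from an individual table
#'
#' The central fitting function of the package. A multivariable logistic
#' regression of the diabetes flag on the covariables is fitted
#' ([fit_logistic()]); each non-reference category's coefficient is turned
#' into integer points by [beta_to_points()] (round(10 * beta), halves away
#' from zero); the points maps are assembled into a [score_definition()].
#' An individual's aggregate score is the sum of their category points.
#'
#' @param table an `individual_table` (e.g. from [sample_individuals()] or
#'   [generate_individuals()]).
#' @param covariables covariables entering the score; defaults to all five:
#'   sex, age band, obesity, smoking, physical inactivity.
#' @param name score name recorded in the definition.
#' @param year optional year label.
#' @return an object of class `risk_score` with components `definition`
#'   (the `score_definition`), `fit` (the `logistic_fit`), `n`, and `call`.
#'   Methods: [print.risk_score()], [summary.risk_score()],
#'   [coef.risk_score()], [predict.risk_score()], [plot.risk_score()].
#' @examples
#' spec <- builtin_fixture(2020)
#' spec$n <- 4000
#' tab <- generate_individuals(spec)
#' rs <- derive_score(tab, name = "example score", year = 2020)
#' rs
#' head(predict(rs, tab))
#' @export
derive_score <- function(table, covariables = covariable_names(),
                         name = "derived score", year = NULL) {
  fit <- fit_logistic(table, covariables, mode = "multivariable")
  covs <- list()
  for (cv in unique(fit$terms$covariable)) {
    rows <- fit$terms[fit$terms$covariable == cv, ]
    covs[[cv]] <- stats::setNames(beta_to_points(rows$beta), rows$category)
  }
  definition <- score_definition(
    name = name, covariables = covs, year = year,
    provenance = list(type = "derived", n = fit$n,
                      rule = "points = round(10 * beta), halves away from zero"))
  structure(list(definition = definition, fit = fit, n = fit$n,
                 call = match.call()),
            class = "risk_score")
}

#' @export
print.risk_score <- function(x, ...) {
  cat(sprintf("Points-based risk score '%s' derived from n = %d (max %d points)\n",
              x$definition$name, x$n, max_points(x$definition)))
  print(x$definition)
  invisible(x)
}

#' Summarize a derived risk score
#'
#' Lays out, per covariable category, the adjusted odds ratio with its
#' confidence interval, the regression coefficient, and the integer points
#' — the conventional reporting table for a points-based score.
#'
#' @param object a `risk_score`.
#' @param ... unused.
#' @return a `summary.risk_score`: the layout as a data frame plus the
#'   model intercept.
#' @export
summary.risk_score <- function(object, ...) {
  tt <- object$fit$terms
  pts <- unlist(lapply(object$definition$covariables, as.vector), use.names = FALSE)
  tab <- data.frame(covariable = tt$covariable, category = tt$category,
                    aOR = tt$or, ci_lo = tt$or_lo, ci_hi = tt$or_hi,
                    beta = tt$beta, points = pts)
  structure(list(table = tab, intercept = object$fit$intercept,
                 n = object$n, name = object$definition$name,
                 loglik = object$fit$loglik),
            class = "summary.risk_score")
}

#' @export
print.summary.risk_score <- function(x, digits = 2, ...) {
  cat(sprintf("Risk score '%s' (n = %d)\n", x$name, x$n))
  tab <- x$table
  tab$`aOR (95% CI)` <- ifelse(tab$points == 0 & tab$beta == 0, "reference",
                               sprintf("%.*f (%.*f-%.*f)", digits, tab$aOR,
                                       digits, tab$ci_lo, digits, tab$ci_hi))
  tab$beta <- sprintf("%.*f", digits, tab$beta)
  print(tab[, c("covariable", "category", "aOR (95% CI)", "beta", "points")],
        row.names = FALSE)
  cat(sprintf("Constant %.2f\n", x$intercept))
  invisible(x)
}

#' Coefficients or points of a risk score
#'
#' @param object a `risk_score`.
#' @param type `"beta"` for regression coefficients (named, reference
#'   categories 0), `"points"` for the integer points.
#' @param ... unused.
#' @return named numeric vector over covariable categories.
#' @export
coef.risk_score <- function(object, type = c("beta", "points"), ...) {
  type <- match.arg(type)
  tt <- object$fit$terms
  nm <- paste(tt$covariable, tt$category, sep = ":")
  if (type == "beta") return(stats::setNames(tt$beta, nm))
  stats::setNames(unlist(lapply(object$definition$covariables, as.vector),
                         use.names = FALSE), nm)
}

#' Score individuals with a derived risk score
#'
#' @param object a `risk_score`.
#' @param newdata an `individual_table` (or coercible data frame).
#' @param type `"score"` for the integer aggregate score, `"link"` for the
#'   underlying linear predictor (intercept + sum of betas), `"response"`
#'   for the fitted diabetes probability.
#' @param ... unused.
#' @return numeric (or integer) vector, one value per row of `newdata`.
#' @export
predict.risk_score <- function(object, newdata,
                               type = c("score", "link", "response"), ...) {
  type <- match.arg(type)
  if (!inherits(newdata, "individual_table")) newdata <- as_individual_table(newdata)
  if (type == "score") return(apply_score(newdata, object$definition))
  tt <- object$fit$terms
  lp <- rep(object$fit$intercept, nrow(newdata))
  for (cv in unique(tt$covariable)) {
    rows <- tt[tt$covariable == cv, ]
    cats <- category_labels(cv, newdata[[cv]])
    hit <- match(cats, rows$category)
    if (anyNA(hit)) {
      stop(sprintf("category '%s' of covariable '%s' was not in the derivation sample",
                   unique(cats[is.na(hit)])[1], cv), call. = FALSE)
    }
    lp <- lp + rows$beta[hit]
  }
  if (type == "link") lp else expit(lp)
}

#' Plot the points profile of a risk score
#'
#' Horizontal bars of integer points per covariable category, grouped by
#' covariable — the "score card" at a glance.
#'
#' @param x a `risk_score` or `score_definition`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.risk_score <- function(x, ...) {
  def <- if (inherits(x, "risk_score")) x$definition else x
  pts <- unlist(lapply(names(def$covariables), function(cv) {
    stats::setNames(def$covariables[[cv]],
                    paste(cv, names(def$covariables[[cv]]), sep = ": "))
  }))
  op <- graphics::par(mar = c(4, 11, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(rev(pts), horiz = TRUE, las = 1, cex.names = 0.7,
                    xlab = "points", main = def$name, ...)
  invisible(x)
}

#' @export
plot.score_definition <- plot.risk_score
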