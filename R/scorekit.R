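covariable_names <- function() c("sex", "age_band", "obese", "smoker", "inactive")

# reference category first in every level set
covariable_levels <- function(cov, bands = 0:19) {
  switch(cov,
         sex = c("female", "male"),
         age_band = band_label(sort(bands)),
         obese = c("non-obese", "obese"),
         smoker = c("non-smoker", "smoker"),
         inactive = c("active", "inactive"),
         stop("unknown covariable: ", cov, call. = FALSE))
}

# numeric codes in an individual table -> category labels
category_labels <- function(cov, values) {
  if (cov == "age_band") return(band_label(values))
  covariable_levels(cov)[values + 1L]
}

covariable_factor <- function(table, cov) {
  if (cov == "age_band") {
    bands <- sort(unique(table$age_band))
    factor(band_label(table$age_band), levels = band_label(bands))
  } else {
    factor(category_labels(cov, table[[cov]]), levels = covariable_levels(cov))
  }
}

#' Fit logistic regression of diabetes on score covariables
#'
#' Maximum-likelihood logistic regression (IRLS via [stats::glm()]) of the
#' diabetes flag on categorical covariables. Age enters as five-year band
#' dummies against the youngest band present; sex, obesity, smoking and
#' inactivity against female / factor-absent references. No interaction
#' terms are ever included.
#'
#' @param table an `individual_table` with both outcome classes present.
#' @param covariables subset of `c("sex", "age_band", "obese", "smoker",
#'   "inactive")`.
#' @param mode `"multivariable"` (one joint fit) or `"univariable"` (one
#'   single-covariable fit per covariable, returned as a named list).
#' @param conf.level confidence level for the Wald odds-ratio intervals.
#' @return a `logistic_fit`: intercept and a per-category coefficient table
#'   (`beta`, `se`, `or`, `or_lo`, `or_hi`; reference rows carry beta = 0),
#'   plus `n`, `converged`, `loglik`. In univariable mode, a named list of
#'   such fits.
#' @export
fit_logistic <- function(table, covariables = covariable_names(),
                         mode = c("multivariable", "univariable"),
                         conf.level = 0.95) {
  stopifnot(inherits(table, "individual_table"))
  mode <- match.arg(mode)
  if (length(covariables)) {
    covariables <- match.arg(covariables, covariable_names(), several.ok = TRUE)
  } else {
    covariables <- character(0) # intercept-only model
  }
  if (nrow(table) == 0) stop("cannot fit on an empty table", call. = FALSE)
  if (length(unique(table$diabetic)) < 2) {
    stop("outcome must contain both diabetic and non-diabetic individuals", call. = FALSE)
  }
  if (mode == "univariable") {
    fits <- lapply(covariables, function(cv) fit_logistic(table, cv, "multivariable", conf.level))
    return(stats::setNames(fits, covariables))
  }

  mf <- data.frame(diabetic = table$diabetic)
  for (cv in covariables) mf[[cv]] <- covariable_factor(table, cv)
  form <- if (length(covariables)) diabetic ~ . else diabetic ~ 1

  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(form, family = stats::binomial(), data = mf,
               control = stats::glm.control(epsilon = 1e-10, maxit = 50)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  cf <- summary(fit)$coefficients
  if (sep_warn || any(abs(cf[, "Estimate"]) > 12)) {
    bad <- rownames(cf)[abs(cf[, "Estimate"]) > 12]
    offenders <- unique(unlist(lapply(covariables, function(cv) {
      if (any(startsWith(bad, cv))) cv else NULL
    })))
    stop("complete or quasi-separation detected for covariable(s): ",
         paste(if (length(offenders)) offenders else "unknown", collapse = ", "),
         call. = FALSE)
  }
  if (!fit$converged) {
    stop(sprintf("logistic fit did not converge in %d IRLS iterations", fit$iter),
         call. = FALSE)
  }

  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  rows <- list()
  for (cv in covariables) {
    levs <- levels(mf[[cv]])
    for (j in seq_along(levs)) {
      cname <- paste0(cv, levs[j])
      if (j == 1L) {
        rows[[length(rows) + 1L]] <- data.frame(
          covariable = cv, category = levs[j], reference = TRUE,
          beta = 0, se = NA_real_, or = 1, or_lo = NA_real_, or_hi = NA_real_,
          stringsAsFactors = FALSE)
      } else {
        if (!cname %in% rownames(cf)) {
          stop(sprintf("category '%s' of '%s' is not estimable (no observations)",
                       levs[j], cv), call. = FALSE)
        }
        b <- cf[cname, "Estimate"]; s <- cf[cname, "Std. Error"]
        rows[[length(rows) + 1L]] <- data.frame(
          covariable = cv, category = levs[j], reference = FALSE,
          beta = b, se = s, or = exp(b), or_lo = exp(b - z * s), or_hi = exp(b + z * s),
          stringsAsFactors = FALSE)
      }
    }
  }
  terms <- do.call(rbind, rows)
  structure(list(terms = terms,
                 intercept = unname(cf["(Intercept)", "Estimate"]),
                 intercept_se = unname(cf["(Intercept)", "Std. Error"]),
                 n = nrow(table), converged = fit$converged,
                 loglik = as.numeric(stats::logLik(fit)),
                 iterations = fit$iter, conf.level = conf.level,
                 covariables = covariables),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Logistic fit on n = %d (log-likelihood %.1f)\n", x$n, x$loglik))
  cat(sprintf("  intercept %.*f (SE %.*f)\n", digits, x$intercept, digits, x$intercept_se))
  tt <- x$terms
  tt$beta <- round(tt$beta, digits); tt$or <- round(tt$or, digits)
  print(tt[, c("covariable", "category", "beta", "or", "or_lo", "or_hi")],
        row.names = FALSE, digits = digits)
  invisible(x)
}

#' Convert a regression coefficient to integer score points
#'
#' The points rule of the score: the beta-coefficient is multiplied by 10
#' and rounded to the nearest integer (halves away from zero), applied to
#' the full-precision fitted coefficient. Reference categories (beta = 0)
#' map to 0. A negative coefficient yields negative points with a warning
#' rather than silent truncation.
#'
#' @param beta finite numeric coefficient(s).
#' @return integer points, vectorized over `beta`.
#' @examples
#' beta_to_points(1.40) # 14
#' beta_to_points(2.46) # 25
#' @export
beta_to_points <- function(beta) {
  if (any(!is.finite(beta))) stop("beta must be finite", call. = FALSE)
  pts <- as.integer(sign(beta) * floor(abs(10 * beta) + 0.5))
  if (any(pts < 0)) {
    warning("negative coefficient(s) yield negative points; the score is kept additive, not truncated at 0")
  }
  pts
}

#' Score definition: covariable -> category -> points
#'
#' The portable representation of a points-based risk score: for each
#' covariable a named map from category label to integer points, with the
#' reference category at 0. Serializable to JSON, so both scores derived
#' here and externally published scores can be applied and compared.
#'
#' @param name score name.
#' @param covariables named list; each element a named numeric vector of
#'   integer points per category, containing a 0-point reference.
#' @param year optional year label.
#' @param cutoff optional decision cut-off (half-integers allowed; flagged
#'   means score >= cutoff).
#' @param provenance free-form list (e.g. derived-from-fit vs external).
#' @return object of class `score_definition`.
#' @export
score_definition <- function(name, covariables, year = NULL, cutoff = NULL,
                             provenance = list(type = "external")) {
  if (!is.list(covariables) || is.null(names(covariables)) || length(covariables) == 0) {
    stop("'covariables' must be a nonempty named list", call. = FALSE)
  }
  bad <- setdiff(names(covariables), covariable_names())
  if (length(bad)) stop("unknown covariable(s): ", paste(bad, collapse = ", "), call. = FALSE)
  for (nm in names(covariables)) {
    pts <- covariables[[nm]]
    if (is.null(names(pts)) || anyNA(pts) || any(pts != round(pts))) {
      stop(sprintf("points for '%s' must be a named vector of integers", nm), call. = FALSE)
    }
    if (!any(pts == 0)) {
      stop(sprintf("covariable '%s' lacks a 0-point reference category", nm), call. = FALSE)
    }
    covariables[[nm]] <- stats::setNames(as.integer(pts), names(pts))
  }
  structure(list(name = name, year = year, covariables = covariables,
                 cutoff = cutoff, provenance = provenance),
            class = "score_definition")
}

#' Maximum attainable total of a score definition
#' @param definition a `score_definition`.
#' @return sum of the per-covariable maxima.
#' @export
max_points <- function(definition) {
  stopifnot(inherits(definition, "score_definition"))
  sum(vapply(definition$covariables, max, numeric(1)))
}

#' @export
print.score_definition <- function(x, ...) {
  cat(sprintf("Score definition '%s'%s (max %d points%s)\n", x$name,
              if (!is.null(x$year)) paste0(" [", x$year, "]") else "",
              max_points(x),
              if (!is.null(x$cutoff)) sprintf(", cut-off %.1f", x$cutoff) else ""))
  for (nm in names(x$covariables)) {
    pts <- x$covariables[[nm]]
    cat(sprintf("  %s: %s\n", nm,
                paste(sprintf("%s=%d", names(pts), pts), collapse = ", ")))
  }
  invisible(x)
}

#' Apply a score definition to an individual table
#'
#' Each individual's score is the sum of the points of their category on
#' every covariable in the definition (the additive rule: no interactions).
#'
#' @param table an `individual_table` containing every covariable of the
#'   definition.
#' @param definition a `score_definition`.
#' @return integer vector of scores, one per row of `table`.
#' @export
apply_score <- function(table, definition) {
  stopifnot(inherits(table, "individual_table"), inherits(definition, "score_definition"))
  total <- integer(nrow(table))
  for (cv in names(definition$covariables)) {
    pts <- definition$covariables[[cv]]
    cats <- category_labels(cv, table[[cv]])
    hit <- match(cats, names(pts))
    if (anyNA(hit)) {
      miss <- unique(cats[is.na(hit)])
      stop(sprintf("category '%s' of covariable '%s' is missing from score definition '%s'",
                   miss[1], cv, definition$name), call. = FALSE)
    }
    total <- total + pts[hit]
  }
  unname(total)
}

#' Write / read a score definition as JSON
#'
#' @param definition a `score_definition` (or a `risk_score`, whose
#'   definition is written).
#' @param path file path.
#' @export
write_score_json <- function(definition, path) {
  if (inherits(definition, "risk_score")) definition <- definition$definition
  stopifnot(inherits(definition, "score_definition"))
  doc <- list(name = definition$name, year = definition$year,
              covariables = lapply(definition$covariables, as.list),
              cutoff = definition$cutoff, provenance = definition$provenance)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_score_json
#' @return `read_score_json` returns a `score_definition`.
#' @export
read_score_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  covs <- lapply(doc$covariables, function(m) unlist(m))
  score_definition(name = doc$name, covariables = covs,
                   year = doc$year, cutoff = doc$cutoff,
                   provenance = doc$provenance %||% list(type = "external"))
}
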