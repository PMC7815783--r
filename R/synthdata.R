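#' Specification for a synthetic individual-level sample
#'
#' Describes a generator with known ground truth: covariate marginals (sex
#' split, age-band distribution over the 15-79 frame, per-factor
#' prevalences) plus a logistic disease model (intercept and per-category
#' coefficients). Covariates are drawn independently given sex and age
#' band; the diabetes flag is Bernoulli with probability
#' `plogis(linear predictor)`. Because the generating coefficients are
#' known, every downstream stage (fitting, points, evaluation) can be
#' tested against them.
#'
#' @param n sample size.
#' @param seed integer RNG seed.
#' @param sex_split proportion female.
#' @param age_bands band indices of the sampling frame (default 3..15 =
#'   ages 15-79).
#' @param age_dist probabilities over `age_bands` (default uniform).
#' @param p_obese,p_smoker,p_inactive marginal factor prevalences; scalar
#'   or named length-2 (`female`, `male`).
#' @param intercept disease-model intercept (log-odds scale).
#' @param beta named list of coefficient vectors per covariable, e.g.
#'   `list(sex = c(male = 0.20), age_band = c("20-24" = 0.59, ...),
#'   obese = c(obese = 1.40), ...)`; omitted categories have coefficient 0.
#' @param year optional year label carried into provenance.
#' @return object of class `generator_spec`.
#' @seealso [generate_individuals()], [builtin_fixture()].
#' @export
generator_spec <- function(n, seed = 1L, sex_split = 0.5,
                           age_bands = 3:15, age_dist = NULL,
                           p_obese = 0, p_smoker = 0, p_inactive = 0,
                           intercept = -Inf, beta = list(), year = NULL) {
  stopifnot(n >= 0, sex_split >= 0, sex_split <= 1)
  if (is.null(age_dist)) age_dist <- rep(1 / length(age_bands), length(age_bands))
  if (length(age_dist) != length(age_bands) || any(age_dist < 0)) {
    stop("'age_dist' must be nonnegative with one weight per band", call. = FALSE)
  }
  age_dist <- age_dist / sum(age_dist)
  as_sex_prob <- function(p, name) {
    if (length(p) == 1L) p <- c(female = unname(p), male = unname(p))
    p <- p[sex_levels()]
    if (anyNA(p) || any(p < 0) || any(p > 1)) {
      stop(sprintf("'%s' must be probabilities (scalar or named female/male)", name),
           call. = FALSE)
    }
    p
  }
  bad <- setdiff(names(beta), covariable_names())
  if (length(bad)) stop("unknown covariable(s) in beta: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  structure(list(n = as.integer(n), seed = as.integer(seed), sex_split = sex_split,
                 age_bands = as.integer(age_bands), age_dist = age_dist,
                 p_obese = as_sex_prob(p_obese, "p_obese"),
                 p_smoker = as_sex_prob(p_smoker, "p_smoker"),
                 p_inactive = as_sex_prob(p_inactive, "p_inactive"),
                 intercept = intercept, beta = beta, year = year),
            class = "generator_spec")
}

#' @export
print.generator_spec <- function(x, ...) {
  cat(sprintf("Synthetic-sample spec%s: n = %d, seed = %d\n",
              if (!is.null(x$year)) paste0(" [", x$year, "]") else "", x$n, x$seed))
  cat(sprintf("  marginals: obesity %.3f/%.3f, smoking %.3f/%.3f, inactivity %.3f/%.3f (f/m)\n",
              x$p_obese["female"], x$p_obese["male"], x$p_smoker["female"], x$p_smoker["male"],
              x$p_inactive["female"], x$p_inactive["male"]))
  cat(sprintf("  disease model: intercept %.2f, %d coefficient group(s)\n",
              x$intercept, length(x$beta)))
  invisible(x)
}

beta_lookup <- function(beta, cov, categories) {
  b <- beta[[cov]]
  if (is.null(b)) return(numeric(length(categories)))
  out <- b[categories]
  out[is.na(out)] <- 0
  unname(out)
}

#' Generate a synthetic individual table with known ground truth
#'
#' Draws covariates independently from the spec's marginals and the
#' diabetes flag from the spec's logistic model; deterministic given the
#' spec's seed.
#'
#' @param spec a [generator_spec()].
#' @return an `individual_table` with provenance recording the seed and
#'   generator settings.
#' @export
generate_individuals <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  n <- spec$n
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)
  sex <- stats::rbinom(n, 1, 1 - spec$sex_split) # 1 = male
  band <- spec$age_bands[sample.int(length(spec$age_bands), n, replace = TRUE,
                                    prob = spec$age_dist)]
  sx <- sex_levels()[sex + 1]
  obese <- stats::rbinom(n, 1, spec$p_obese[sx])
  smoker <- stats::rbinom(n, 1, spec$p_smoker[sx])
  inactive <- stats::rbinom(n, 1, spec$p_inactive[sx])
  lp <- rep(spec$intercept, n)
  lp <- lp + beta_lookup(spec$beta, "sex", category_labels("sex", sex))
  lp <- lp + beta_lookup(spec$beta, "age_band", band_label(band))
  lp <- lp + beta_lookup(spec$beta, "obese", category_labels("obese", obese))
  lp <- lp + beta_lookup(spec$beta, "smoker", category_labels("smoker", smoker))
  lp <- lp + beta_lookup(spec$beta, "inactive", category_labels("inactive", inactive))
  pr <- expit(lp)
  pr[lp == -Inf] <- 0
  diabetic <- stats::rbinom(n, 1, pr)
  as_individual_table(
    data.frame(id = seq_len(n), sex = sex, age_band = band, obese = obese,
               smoker = smoker, inactive = inactive, diabetic = diabetic),
    provenance = list(generator = "independent-marginals-logistic",
                      seed = spec$seed, n = n, year = spec$year))
}

# Printed multivariable disease models for the three projection years:
# age-band coefficients 20-24 .. 75-79 (reference 15-19), then sex/factor
# coefficients and the model constant, with the year's covariate marginals.
fixture_table <- function() {
  bands <- band_label(4:15)
  list(
    "2020" = list(
      constant = -4.10,
      age = stats::setNames(c(0.59, 1.02, 0.97, 1.42, 1.54, 1.79, 2.02, 2.46,
                              2.46, 2.39, 2.62, 2.45), bands),
      male = 0.20, obese = 1.40, smoker = 0.31, inactive = 0.53,
      p_obese = 0.407, p_smoker = 0.164, p_inactive = 0.493),
    "2030" = list(
      constant = -3.95,
      age = stats::setNames(c(0.42, 0.79, 0.88, 1.05, 1.33, 1.75, 1.96, 2.00,
                              2.37, 2.28, 2.36, 2.02), bands),
      male = 0.06, obese = 1.39, smoker = 0.36, inactive = 0.42,
      p_obese = 0.438, p_smoker = 0.166, p_inactive = 0.512),
    "2050" = list(
      constant = -3.67,
      age = stats::setNames(c(0.05, 0.31, 0.70, 0.79, 1.25, 1.48, 1.72, 1.91,
                              1.88, 1.99, 1.77, 2.18), bands),
      male = 0.29, obese = 1.48, smoker = 0.22, inactive = 0.37,
      p_obese = 0.484, p_smoker = 0.183, p_inactive = 0.570))
}

#' Built-in synthetic-sample fixtures for the three projection years
#'
#' Packaged generator specifications encoding the multivariable disease
#' model (constant and per-category coefficients) and the covariate
#' marginals of each projection year's simulated sample. The age-band
#' distribution is uniform over the 13 bands of the 15-79 frame and the
#' sex split is even; see the methods vignette for what the fixture does
#' and does not emulate.
#'
#' @param year one of 2020, 2030, 2050.
#' @param n sample size of the spec (default 5000).
#' @param seed RNG seed of the spec.
#' @return a [generator_spec()].
#' @examples
#' spec <- builtin_fixture(2020)
#' spec$beta$obese
#' @export
builtin_fixture <- function(year, n = 5000, seed = 1L) {
  key <- as.character(year)
  fx <- fixture_table()[[key]]
  if (is.null(fx)) stop("unsupported year: ", year, " (available: 2020, 2030, 2050)",
                        call. = FALSE)
  generator_spec(n = n, seed = seed, sex_split = 0.5, age_bands = 3:15,
                 p_obese = fx$p_obese, p_smoker = fx$p_smoker,
                 p_inactive = fx$p_inactive,
                 intercept = fx$constant,
                 beta = list(sex = c(male = fx$male),
                             age_band = fx$age,
                             obese = c(obese = fx$obese),
                             smoker = c(smoker = fx$smoker),
                             inactive = c(inactive = fx$inactive)),
                 year = as.integer(year))
}

#' Write / read a generator spec as JSON
#'
#' @param spec a `generator_spec`.
#' @param path file path.
#' @export
write_spec_json <- function(spec, path) {
  stopifnot(inherits(spec, "generator_spec"))
  doc <- unclass(spec)
  doc$beta <- lapply(doc$beta, as.list)
  doc$p_obese <- as.list(doc$p_obese)
  doc$p_smoker <- as.list(doc$p_smoker)
  doc$p_inactive <- as.list(doc$p_inactive)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_spec_json
#' @return `read_spec_json` returns a `generator_spec`.
#' @export
read_spec_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  unl <- function(x) unlist(x)
  generator_spec(n = doc$n, seed = doc$seed, sex_split = doc$sex_split,
                 age_bands = unl(doc$age_bands), age_dist = unl(doc$age_dist),
                 p_obese = unl(doc$p_obese), p_smoker = unl(doc$p_smoker),
                 p_inactive = unl(doc$p_inactive),
                 intercept = if (is.null(doc$intercept)) -Inf else doc$intercept,
                 beta = lapply(doc$beta, unl),
                 year = doc$year)
}
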