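#' In-silico population state
#'
#' A `compartment_state` holds the occupancy (person count, continuous) of
#' every stratum of the simulated population at one time point. Strata are
#' the cross of sex (2), five-year age band (20), the three binary risk
#' factors obesity / daily smoking / physical inactivity (8 profiles), and
#' diabetes status (2): 640 compartments in all.
#'
#' @param time calendar year (fractional allowed).
#' @param counts numeric array of dimension `c(2, 20, 2, 2, 2, 2)` in the
#'   order sex, age band, obese, smoker, inactive, diabetic; all entries
#'   must be nonnegative and finite.
#' @return an object of class `compartment_state`.
#' @seealso [make_state()] for a product-form constructor, [prevalence()],
#'   [simulate_model()].
#' @export
compartment_state <- function(time, counts) {
  if (!is.numeric(counts) || !identical(dim(counts), c(2L, 20L, 2L, 2L, 2L, 2L))) {
    stop("'counts' must be a numeric array of dim c(2, 20, 2, 2, 2, 2)", call. = FALSE)
  }
  if (anyNA(counts) || any(!is.finite(counts)) || any(counts < 0)) {
    stop("occupancies must be finite and nonnegative", call. = FALSE)
  }
  yn <- c("no", "yes")
  dimnames(counts) <- list(sex = sex_levels(), band = band_label(0:19),
                           obese = yn, smoker = yn, inactive = yn, diabetic = yn)
  structure(list(time = as.numeric(time), counts = counts),
            class = "compartment_state")
}

#' Build a product-form population state
#'
#' Convenience constructor: occupancies are the product of a sex split, an
#' age-band distribution, and independent per-stratum probabilities of
#' obesity, smoking, inactivity, and diabetes. Useful as an initial
#' condition for [simulate_model()] and for test fixtures.
#'
#' @param time calendar year of the state.
#' @param total total population size.
#' @param sex_split proportion female.
#' @param age_dist probabilities over the 20 bands (defaults to uniform);
#'   rescaled to sum to 1.
#' @param p_obese,p_smoker,p_inactive,p_diabetic probability of each
#'   condition; scalar or a 2 x 20 sex-by-band matrix.
#' @return a `compartment_state`.
#' @export
make_state <- function(time = 0, total = 1e5, sex_split = 0.5, age_dist = NULL,
                       p_obese = 0, p_smoker = 0, p_inactive = 0, p_diabetic = 0) {
  stopifnot(total >= 0, sex_split >= 0, sex_split <= 1)
  if (is.null(age_dist)) age_dist <- rep(1 / n_bands(), n_bands())
  if (length(age_dist) != n_bands() || any(age_dist < 0)) {
    stop("'age_dist' must be 20 nonnegative weights", call. = FALSE)
  }
  age_dist <- age_dist / sum(age_dist)
  probm <- function(p, name) {
    m <- as_rate_matrix(p, name)
    if (any(m > 1)) stop(sprintf("'%s' must lie in [0, 1]", name), call. = FALSE)
    m
  }
  po <- probm(p_obese, "p_obese"); ps <- probm(p_smoker, "p_smoker")
  pi_ <- probm(p_inactive, "p_inactive"); pd <- probm(p_diabetic, "p_diabetic")

  base <- outer(c(sex_split, 1 - sex_split) * total, age_dist) # 2 x 20
  counts <- array(0, dim = c(2L, 20L, 2L, 2L, 2L, 2L))
  for (o in 1:2) for (s in 1:2) for (i in 1:2) for (d in 1:2) {
    w <- (if (o == 2) po else 1 - po) * (if (s == 2) ps else 1 - ps) *
      (if (i == 2) pi_ else 1 - pi_) * (if (d == 2) pd else 1 - pd)
    counts[, , o, s, i, d] <- base * w
  }
  compartment_state(time, counts)
}

#' @export
print.compartment_state <- function(x, ...) {
  cat(sprintf("Compartment state at t = %.4g: %.6g persons in 640 strata\n",
              x$time, total_population(x)))
  cat(sprintf("  diabetes %.3f | obesity %.3f | smoking %.3f | inactivity %.3f\n",
              prevalence(x, "diabetes"), prevalence(x, "obesity"),
              prevalence(x, "smoking"), prevalence(x, "inactivity")))
  invisible(x)
}

#' Total population of a state
#' @param state a `compartment_state`.
#' @return total person count over all strata.
#' @export
total_population <- function(state) sum(state$counts)

quantity_dim <- function(quantity) {
  switch(match.arg(quantity, c("diabetes", "obesity", "smoking", "inactivity")),
         obesity = 3L, smoking = 4L, inactivity = 5L, diabetes = 6L)
}

#' Prevalence of diabetes or a risk factor in a population state
#'
#' The proportion of the (optionally filtered) occupancy in strata with the
#' requested condition.
#'
#' @param state a `compartment_state`.
#' @param quantity one of `"diabetes"`, `"obesity"`, `"smoking"`,
#'   `"inactivity"`.
#' @param sex optional `"female"` or `"male"` filter.
#' @param age_range optional inclusive age range in years, e.g. `c(15, 79)`;
#'   translated to the five-year bands it covers.
#' @param profile optional risk-profile filter: a named logical vector over
#'   `obese`, `smoker`, `inactive`, e.g. `c(obese = TRUE)` restricts to
#'   obese strata.
#' @return proportion in `[0, 1]`.
#' @examples
#' st <- make_state(2020, 1000, p_diabetic = 0.2)
#' prevalence(st, "diabetes")
#' @export
prevalence <- function(state, quantity, sex = NULL, age_range = NULL, profile = NULL) {
  stopifnot(inherits(state, "compartment_state"))
  d <- quantity_dim(quantity)
  A <- state$counts
  if (!is.null(sex)) {
    si <- match(match.arg(sex, sex_levels()), sex_levels())
    A <- slice6(A, 1L, si)
  }
  if (!is.null(age_range)) {
    A <- slice6(A, 2L, bands_in_range(age_range[1], age_range[2]) + 1L)
  }
  if (!is.null(profile)) {
    if (is.null(names(profile)) || !all(names(profile) %in% factor_names())) {
      stop("'profile' must be a named logical over obese/smoker/inactive", call. = FALSE)
    }
    for (f in names(profile)) {
      A <- slice6(A, 2L + match(f, factor_names()), if (isTRUE(profile[[f]])) 2L else 1L)
    }
  }
  tot <- sum(A)
  if (tot <= 0) stop("prevalence undefined: no occupancy in the selected strata", call. = FALSE)
  sum(slice6(A, d, 2L)) / tot
}

#' @describeIn compartment_state long-format view: one row per stratum with
#'   columns `time, sex, age_band, obese, smoker, inactive, diabetic, count`
#'   (sex coded 0 = female, 1 = male; flags 0/1; `age_band` the band index).
#' @param x a `compartment_state`.
#' @param row.names,optional,... passed on conventionally; unused.
#' @export
as.data.frame.compartment_state <- function(x, row.names = NULL, optional = FALSE, ...) {
  g <- expand.grid(sex = 0:1, age_band = 0:19, obese = 0:1, smoker = 0:1,
                   inactive = 0:1, diabetic = 0:1)
  data.frame(time = x$time, g, count = as.vector(x$counts))
}

#' Write / read a population state as long-format CSV
#'
#' Columns are `time, sex, age_band, obese, smoker, inactive, diabetic,
#' count` with 0/1 coding (sex 0 = female). A trajectory CSV (several time
#' points) can be read back one time point at a time via `time`.
#'
#' @param state a `compartment_state`.
#' @param path file path.
#' @export
write_state_csv <- function(state, path) {
  utils::write.csv(as.data.frame(state), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_state_csv
#' @param time which time point to extract when the file holds several;
#'   default: the last.
#' @return `read_state_csv` returns a `compartment_state`.
#' @export
read_state_csv <- function(path, time = NULL) {
  df <- utils::read.csv(path)
  need <- c("time", "sex", "age_band", "obese", "smoker", "inactive", "diabetic", "count")
  if (!all(need %in% names(df))) {
    stop("state CSV must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (is.null(time)) time <- max(df$time)
  df <- df[abs(df$time - time) < 1e-9, , drop = FALSE]
  if (nrow(df) == 0) stop("no rows at requested time", call. = FALSE)
  counts <- array(0, dim = c(2L, 20L, 2L, 2L, 2L, 2L))
  idx <- cbind(df$sex + 1L, df$age_band + 1L, df$obese + 1L,
               df$smoker + 1L, df$inactive + 1L, df$diabetic + 1L)
  counts[idx] <- df$count
  compartment_state(time, counts)
}
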