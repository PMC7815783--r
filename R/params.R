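#' Parameters of the compartmental diabetes model
#'
#' Bundles the demographic and epidemiological rates driving the simulator:
#' population entry, mortality, aging, risk-factor onset and reversal,
#' baseline diabetes incidence, and the relative risk of diabetes conferred
#' by each factor. All rates are per-capita per year unless noted.
#'
#' Scalars are expanded to full sex-by-band structures; a named length-2
#' vector (`female`, `male`) gives sex-specific constants; a 2 x 20 matrix
#' gives full sex-by-age-band detail. `onset` and `reversal` may be a single
#' value for all three factors or a named list with entries `obese`,
#' `smoker`, `inactive`. `mortality` may additionally be a 2 x 20 x 2 array
#' whose third dimension distinguishes non-diabetic from diabetic mortality.
#'
#' @param entry_rate persons/year entering the first age band (0-4), by sex.
#' @param mortality per-capita death rate; may depend on diabetes status.
#' @param aging_rate per-capita rate of moving to the next five-year band;
#'   the default 1/5 gives a mean band residence of five years.
#' @param onset per-capita rate of acquiring each risk factor.
#' @param reversal per-capita rate of losing each risk factor.
#' @param lambda0 baseline diabetes hazard/year for a person with no risk
#'   factors, by sex and age band.
#' @param rr relative risk of diabetes per factor (named, all > 0); risks of
#'   co-occurring factors combine multiplicatively.
#' @return an object of class `model_params`.
#' @examples
#' p <- model_params(lambda0 = 0.01, rr = c(obese = 2, smoker = 1.5, inactive = 1.3))
#' incidence_hazard(p, "female", 8, c("obese", "smoker", "inactive"))
#' @export
model_params <- function(entry_rate = c(female = 0, male = 0),
                         mortality = 0,
                         aging_rate = 1 / 5,
                         onset = 0,
                         reversal = 0,
                         lambda0 = 0,
                         rr = c(obese = 1, smoker = 1, inactive = 1)) {
  s <- sex_levels()
  if (length(entry_rate) == 1L) entry_rate <- stats::setNames(rep(entry_rate, 2), s)
  entry_rate <- entry_rate[s]
  if (anyNA(entry_rate) || any(entry_rate < 0)) {
    stop("'entry_rate' must be nonnegative, named female/male", call. = FALSE)
  }
  if (!(length(aging_rate) == 1L && aging_rate >= 0)) {
    stop("'aging_rate' must be a nonnegative scalar", call. = FALSE)
  }

  if (is.array(mortality) && length(dim(mortality)) == 3L) {
    if (!all(dim(mortality) == c(2L, n_bands(), 2L))) {
      stop("'mortality' array must be 2 x 20 x 2 (sex x band x disease)", call. = FALSE)
    }
    mort <- mortality
  } else {
    m <- as_rate_matrix(mortality, "mortality")
    mort <- array(m, dim = c(2L, n_bands(), 2L))
  }
  dimnames(mort) <- list(sex = s, band = band_label(0:19), diabetic = c("no", "yes"))
  if (any(mort < 0)) stop("'mortality' must be nonnegative", call. = FALSE)

  expand_factor_rates <- function(x, name) {
    f <- factor_names()
    if (!is.list(x)) x <- stats::setNames(rep(list(x), 3), f)
    if (!all(f %in% names(x))) {
      stop(sprintf("'%s' list must have entries %s", name, paste(f, collapse = ", ")),
           call. = FALSE)
    }
    lapply(stats::setNames(f, f), function(fn) as_rate_matrix(x[[fn]], paste0(name, ".", fn)))
  }
  onset <- expand_factor_rates(onset, "onset")
  reversal <- expand_factor_rates(reversal, "reversal")

  lambda0 <- as_rate_matrix(lambda0, "lambda0")

  if (length(rr) == 1L) rr <- stats::setNames(rep(rr, 3), factor_names())
  rr <- rr[factor_names()]
  if (anyNA(rr) || any(rr <= 0)) {
    stop("'rr' must be positive and named obese/smoker/inactive", call. = FALSE)
  }

  structure(list(entry_rate = entry_rate, mortality = mort,
                 aging_rate = aging_rate, onset = onset, reversal = reversal,
                 lambda0 = lambda0, rr = rr),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Compartmental model parameters\n")
  cat(sprintf("  entry_rate: female %.4g, male %.4g persons/year\n",
              x$entry_rate["female"], x$entry_rate["male"]))
  cat(sprintf("  aging_rate: %.4g /year\n", x$aging_rate))
  cat(sprintf("  relative risks: obese %.3g, smoker %.3g, inactive %.3g\n",
              x$rr["obese"], x$rr["smoker"], x$rr["inactive"]))
  cat(sprintf("  baseline hazard lambda0: mean %.4g /year (range %.4g-%.4g)\n",
              mean(x$lambda0), min(x$lambda0), max(x$lambda0)))
  invisible(x)
}

#' Read model configuration from YAML or JSON
#'
#' The configuration file holds a `params` block (keys as in
#' [model_params()]: `entry_rate`, `mortality`, `aging_rate`, `onset`,
#' `reversal`, `lambda0`, `rr`) and optionally an `initial` block
#' (`time`, `total`, and the product-form prevalences understood by
#' [make_state()]).
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return list with elements `params` (a `model_params`) and `initial`
#'   (a `compartment_state`, or `NULL` if no `initial` block is present).
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  pb <- cfg$params
  if (is.null(pb)) stop("config must contain a 'params' block", call. = FALSE)
  unlist_named <- function(x) if (is.list(x)) unlist(x) else x
  pargs <- list()
  for (key in c("entry_rate", "mortality", "aging_rate", "lambda0", "rr")) {
    if (!is.null(pb[[key]])) pargs[[key]] <- unlist_named(pb[[key]])
  }
  for (key in c("onset", "reversal")) {
    if (!is.null(pb[[key]])) {
      v <- pb[[key]]
      pargs[[key]] <- if (is.list(v)) lapply(v, unlist_named) else v
    }
  }
  params <- do.call(model_params, pargs)
  initial <- NULL
  if (!is.null(cfg$initial)) {
    ib <- cfg$initial
    initial <- make_state(time = ib$time %||% 0,
                          total = ib$total %||% 1e5,
                          sex_split = ib$sex_split %||% 0.5,
                          age_dist = unlist_named(ib$age_dist),
                          p_obese = ib$p_obese %||% 0,
                          p_smoker = ib$p_smoker %||% 0,
                          p_inactive = ib$p_inactive %||% 0,
                          p_diabetic = ib$p_diabetic %||% 0)
  }
  list(params = params, initial = initial)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
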