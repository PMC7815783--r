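#' Draw an individual-level Monte Carlo sample from a population state
#'
#' Emulates an in-silico cross-sectional survey: `n` individuals are drawn
#' with replacement from a multinomial over the strata of `state`,
#' restricted to an age range, with probabilities proportional to stratum
#' occupancy. Occupancies are continuous model masses, so sampling is with
#' replacement rather than finite-population.
#'
#' @param state a `compartment_state` (the sampling frame).
#' @param n number of individuals (>= 0; 0 gives an empty table).
#' @param age_range inclusive age range in years; the default `c(15, 79)`
#'   covers the 13 bands 15-19 .. 75-79.
#' @param seed integer RNG seed; identical inputs give identical tables.
#' @return an `individual_table`: a data frame with columns
#'   `id, sex, age_band, obese, smoker, inactive, diabetic` (sex 0 = female,
#'   1 = male; flags 0/1; `age_band` the five-year band index), carrying
#'   provenance (source time, seed, n, age range) as an attribute.
#' @export
sample_individuals <- function(state, n, age_range = c(15, 79), seed = 1L) {
  stopifnot(inherits(state, "compartment_state"), n >= 0)
  bands <- bands_in_range(age_range[1], age_range[2])
  A <- slice6(state$counts, 2L, bands + 1L)
  tot <- sum(A)
  if (tot <= 0) stop("empty sampling frame: no occupancy in the requested age range",
                     call. = FALSE)
  grid <- expand.grid(sex = 0:1, age_band = bands, obese = 0:1, smoker = 0:1,
                      inactive = 0:1, diabetic = 0:1)
  p <- as.vector(A) / tot
  if (n == 0) {
    tab <- grid[integer(0), , drop = FALSE]
    tab <- cbind(id = integer(0), tab)
  } else {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
    idx <- sample.int(nrow(grid), n, replace = TRUE, prob = p)
    tab <- cbind(id = seq_len(n), grid[idx, , drop = FALSE])
  }
  rownames(tab) <- NULL
  as_individual_table(tab, provenance = list(source_time = state$time,
                                             seed = as.integer(seed), n = as.integer(n),
                                             age_range = age_range,
                                             sampler = "multinomial-with-replacement"))
}

#' Coerce a data frame to an individual table
#'
#' Validates the column contract used throughout the package:
#' `sex` (0 = female, 1 = male), `age_band` (five-year band index 0..19),
#' and 0/1 flags `obese`, `smoker`, `inactive`, `diabetic`. An `id` column
#' is added when absent.
#'
#' @param df a data frame.
#' @param provenance optional named list recorded as an attribute.
#' @return an object of classes `individual_table`, `data.frame`.
#' @export
as_individual_table <- function(df, provenance = NULL) {
  need <- c("sex", "age_band", "obese", "smoker", "inactive", "diabetic")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (!("id" %in% names(df))) df$id <- seq_len(nrow(df))
  if (anyDuplicated(df$id)) stop("individual ids must be unique", call. = FALSE)
  for (col in c("sex", "obese", "smoker", "inactive", "diabetic")) {
    if (nrow(df) > 0 && !all(df[[col]] %in% c(0L, 1L))) {
      stop(sprintf("column '%s' must be 0/1", col), call. = FALSE)
    }
  }
  if (nrow(df) > 0 && !all(df$age_band %in% 0:19)) {
    stop("age_band must be an index in 0..19", call. = FALSE)
  }
  df <- df[, c("id", need)]
  class(df) <- c("individual_table", "data.frame")
  attr(df, "provenance") <- provenance
  df
}

#' Marginal summary of an individual table
#'
#' Proportions with diabetes and each risk factor, overall and broken down
#' by sex and by age band — the "characteristics of the sample" view.
#'
#' @param table an `individual_table` (nonempty).
#' @return list of class `individual_summary` with elements `n`, `overall`
#'   (named proportions), `by_sex` and `by_age_band` (data frames).
#' @export
describe_individuals <- function(table) {
  stopifnot(inherits(table, "individual_table"))
  if (nrow(table) == 0) stop("cannot summarize an empty table", call. = FALSE)
  vars <- c(diabetes = "diabetic", obesity = "obese", smoking = "smoker",
            inactivity = "inactive")
  overall <- vapply(vars, function(v) mean(table[[v]]), numeric(1))
  by_group <- function(g) {
    sp <- split(table, table[[g]])
    out <- data.frame(group = names(sp), n = vapply(sp, nrow, integer(1)))
    names(out)[1] <- g
    for (nm in names(vars)) {
      out[[nm]] <- vapply(sp, function(d) mean(d[[vars[nm]]]), numeric(1))
    }
    rownames(out) <- NULL
    out
  }
  structure(list(n = nrow(table), overall = overall,
                 by_sex = by_group("sex"), by_age_band = by_group("age_band")),
            class = "individual_summary")
}

#' @export
print.individual_summary <- function(x, ...) {
  cat(sprintf("Sample of %d individuals\n", x$n))
  cat(sprintf("  diabetes %.1f%% | obesity %.1f%% | smoking %.1f%% | inactivity %.1f%%\n",
              100 * x$overall["diabetes"], 100 * x$overall["obesity"],
              100 * x$overall["smoking"], 100 * x$overall["inactivity"]))
  invisible(x)
}

#' Write / read an individual table as CSV
#'
#' The CSV has header `id,sex,age_band,obese,smoker,inactive,diabetic` with
#' 0/1 coding (sex 0 = female, 1 = male). Provenance, when present, is
#' written to a JSON sidecar `<path>.provenance.json` and restored on read.
#'
#' @param table an `individual_table`.
#' @param path file path.
#' @export
write_individual_table <- function(table, path) {
  stopifnot(inherits(table, "individual_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  prov <- attr(table, "provenance")
  if (!is.null(prov)) {
    jsonlite::write_json(prov, paste0(path, ".provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_individual_table
#' @return `read_individual_table` returns an `individual_table`.
#' @export
read_individual_table <- function(path) {
  df <- utils::read.csv(path)
  prov <- NULL
  side <- paste0(path, ".provenance.json")
  if (file.exists(side)) prov <- jsonlite::read_json(side, simplifyVector = TRUE)
  as_individual_table(df, provenance = prov)
}
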