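# internal helpers shared across modules

sex_levels <- function() c("female", "male")

factor_names <- function() c("obese", "smoker", "inactive")

n_bands <- function() 20L

#' Label of a five-year age band
#'
#' Band `k` covers ages `[5k, 5k + 5)`; band 19 (95-99) is terminal.
#'
#' @param band integer band index in 0..19.
#' @return character label such as `"15-19"`.
#' @export
band_label <- function(band) {
  stopifnot(all(band >= 0L & band <= 19L))
  paste0(5L * band, "-", 5L * band + 4L)
}

# bands whose age range is contained in [lo, hi] (inclusive integer ages)
bands_in_range <- function(lo, hi) {
  if (hi < lo) stop("age range has hi < lo", call. = FALSE)
  b <- floor(lo / 5):floor(hi / 5)
  b[b >= 0 & b <= 19]
}

# index a 6-d array along one dimension, keeping shape
slice6 <- function(A, d, i) {
  idx <- lapply(dim(A), seq_len)
  idx[[d]] <- i
  do.call(`[`, c(list(A), idx, list(drop = FALSE)))
}

`slice6<-` <- function(A, d, i, value) {
  idx <- lapply(dim(A), seq_len)
  idx[[d]] <- i
  do.call(`[<-`, c(list(A), idx, list(value)))
}

# Wilson score interval for a binomial proportion
wilson_ci <- function(x, n, conf.level = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, centre - half), min(1, centre + half))
}

expit <- function(x) stats::plogis(x)

# expand a scalar or partially specified rate to a full sex x band matrix
as_rate_matrix <- function(x, name) {
  s <- sex_levels()
  if (is.null(x)) x <- 0
  if (is.matrix(x)) {
    if (!all(dim(x) == c(2L, n_bands()))) {
      stop(sprintf("'%s' matrix must be 2 x 20 (sex x age band)", name), call. = FALSE)
    }
    m <- x
  } else if (length(x) == 1L) {
    m <- matrix(x, 2L, n_bands())
  } else if (length(x) == 2L && !is.null(names(x))) {
    m <- matrix(rep(x[s], n_bands()), 2L, n_bands())
  } else {
    stop(sprintf("'%s' must be a scalar, a named length-2 vector, or a 2 x 20 matrix", name),
         call. = FALSE)
  }
  dimnames(m) <- list(sex = s, band = band_label(0:19))
  if (any(m < 0)) stop(sprintf("'%s' must be nonnegative", name), call. = FALSE)
  m
}
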