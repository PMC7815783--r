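#' Diabetes incidence hazard for a risk profile
#'
#' The hazard of developing diabetes for a non-diabetic person is the
#' baseline hazard `lambda0(sex, band)` multiplied by the relative risk of
#' every risk factor the profile carries: co-occurring factors compose
#' multiplicatively, the standard hazard-ratio composition.
#'
#' @param params a [model_params()] object.
#' @param sex `"female"` or `"male"`.
#' @param age_band band index 0..19.
#' @param profile risk profile: a character vector naming the active factors
#'   (subset of `"obese"`, `"smoker"`, `"inactive"`), or a named logical
#'   vector over those factors.
#' @return hazard per year.
#' @export
incidence_hazard <- function(params, sex, age_band, profile = character()) {
  stopifnot(inherits(params, "model_params"))
  si <- match(match.arg(sex, sex_levels()), sex_levels())
  if (age_band < 0 || age_band > 19) stop("age_band must be in 0..19", call. = FALSE)
  if (is.logical(profile)) profile <- names(profile)[profile]
  if (!all(profile %in% factor_names())) {
    stop("unknown risk factor(s): ", paste(setdiff(profile, factor_names()), collapse = ", "),
         call. = FALSE)
  }
  params$lambda0[si, age_band + 1L] * prod(params$rr[profile])
}

# hazard over all (sex, band, obese, smoker, inactive): dim c(2,20,2,2,2)
hazard_array <- function(params) {
  h <- array(params$lambda0, dim = c(2L, 20L, 2L, 2L, 2L))
  h[, , 2L, , ] <- h[, , 2L, , ] * params$rr["obese"]
  h[, , , 2L, ] <- h[, , , 2L, ] * params$rr["smoker"]
  h[, , , , 2L] <- h[, , , , 2L] * params$rr["inactive"]
  h
}

#' Advance the population state by one time step
#'
#' First-order (forward-Euler) compartmental flows over `dt` years: entry of
#' new persons into the first band (no risk factors, non-diabetic), aging
#' between adjacent bands at `aging_rate`, death, one-factor-at-a-time risk
#' factor onset and reversal, and diabetes incidence at the profile-specific
#' hazard. Diabetes is absorbing: there is no remission flow.
#'
#' The step errors if `dt` times the total per-capita outflow rate exceeds 1
#' in any stratum, which is the condition under which occupancies could go
#' negative; reduce `dt` in that case.
#'
#' @param state a `compartment_state`.
#' @param params a `model_params`.
#' @param dt step size in years (default 0.1, must be positive and at most
#'   0.25).
#' @return the `compartment_state` at `state$time + dt`.
#' @export
step_state <- function(state, params, dt = 0.1) {
  stopifnot(inherits(state, "compartment_state"), inherits(params, "model_params"))
  if (!(dt > 0)) stop("dt must be positive", call. = FALSE)
  if (dt > 0.25) stop("dt must be <= 0.25 year to keep per-step transition probabilities valid",
                      call. = FALSE)
  N <- state$counts
  dims <- dim(N)
  dN <- array(0, dims)

  # per-capita outflow rate accumulator, for the dt validity check
  outrate <- array(0, dims)

  # aging: band k -> k + 1; terminal band does not age out
  ag <- params$aging_rate * N
  ag[, 20L, , , , ] <- 0
  dN <- dN - ag
  dN[, 2:20, , , , ] <- dN[, 2:20, , , , ] + ag[, 1:19, , , , ]
  outrate[, 1:19, , , , ] <- outrate[, 1:19, , , , ] + params$aging_rate

  # entry into band 0: factor-free, non-diabetic
  dN[, 1L, 1L, 1L, 1L, 1L] <- dN[, 1L, 1L, 1L, 1L, 1L] + params$entry_rate

  # mortality (may differ by diabetes status)
  for (d in 1:2) {
    m <- array(params$mortality[, , d], dims[1:5])
    dN[, , , , , d] <- dN[, , , , , d] - m * N[, , , , , d]
    outrate[, , , , , d] <- outrate[, , , , , d] + m
  }

  # risk-factor onset and reversal, one factor per flow term
  for (k in seq_along(factor_names())) {
    fd <- 2L + k
    r_on <- array(params$onset[[k]], dims)    # recycles over trailing dims
    r_off <- array(params$reversal[[k]], dims)
    flow_on <- slice6(r_on, fd, 1L) * slice6(N, fd, 1L)
    flow_off <- slice6(r_off, fd, 2L) * slice6(N, fd, 2L)
    slice6(dN, fd, 1L) <- slice6(dN, fd, 1L) - flow_on + flow_off
    slice6(dN, fd, 2L) <- slice6(dN, fd, 2L) + flow_on - flow_off
    slice6(outrate, fd, 1L) <- slice6(outrate, fd, 1L) + slice6(r_on, fd, 1L)
    slice6(outrate, fd, 2L) <- slice6(outrate, fd, 2L) + slice6(r_off, fd, 2L)
  }

  # diabetes incidence: non-diabetic -> diabetic, absorbing
  hz <- hazard_array(params)
  inc <- hz * N[, , , , , 1L]
  dN[, , , , , 1L] <- dN[, , , , , 1L] - inc
  dN[, , , , , 2L] <- dN[, , , , , 2L] + inc
  outrate[, , , , , 1L] <- outrate[, , , , , 1L] + hz

  if (max(outrate) * dt > 1 + 1e-12) {
    stop(sprintf(paste0("dt = %g too large: per-step transition probability ",
                        "%.3f > 1 in some stratum"), dt, max(outrate) * dt),
         call. = FALSE)
  }
  newN <- N + dt * dN
  if (any(newN < 0)) {
    if (min(newN) < -1e-9 * max(sum(N), 1)) {
      stop("negative occupancy after step: dt too large or inconsistent rates", call. = FALSE)
    }
    newN[newN < 0] <- 0 # round-off only
  }
  compartment_state(state$time + dt, newN)
}

#' Simulate the population forward in time
#'
#' Repeatedly applies [step_state()] from `initial$time` to `t_end`,
#' recording every intermediate state. The final step is shortened if the
#' horizon is not a multiple of `dt`, so the trajectory always ends exactly
#' at `t_end`.
#'
#' @param initial starting `compartment_state`.
#' @param params a `model_params`.
#' @param t_end end year (`> initial$time`).
#' @param dt step size in years.
#' @return a `compartment_trajectory`: ordered list of states with the
#'   parameters attached; supports `as.data.frame()` and
#'   [state_at()].
#' @export
simulate_model <- function(initial, params, t_end, dt = 0.1) {
  stopifnot(inherits(initial, "compartment_state"))
  if (!(t_end > initial$time)) stop("t_end must exceed the initial time", call. = FALSE)
  times <- seq(initial$time, t_end, by = dt)
  if (times[length(times)] < t_end - 1e-9) times <- c(times, t_end)
  states <- vector("list", length(times))
  states[[1]] <- initial
  for (i in seq_along(times)[-1]) {
    states[[i]] <- step_state(states[[i - 1]], params, times[i] - times[i - 1])
  }
  structure(list(states = states, times = times, params = params),
            class = "compartment_trajectory")
}

#' @export
print.compartment_trajectory <- function(x, ...) {
  cat(sprintf("Compartment trajectory: %d states over t = %.4g .. %.4g\n",
              length(x$states), x$times[1], x$times[length(x$times)]))
  invisible(x)
}

#' Extract the state nearest a requested time from a trajectory
#' @param trajectory a `compartment_trajectory`.
#' @param time requested year.
#' @return the `compartment_state` whose time is closest to `time`.
#' @export
state_at <- function(trajectory, time) {
  stopifnot(inherits(trajectory, "compartment_trajectory"))
  trajectory$states[[which.min(abs(trajectory$times - time))]]
}

#' @export
as.data.frame.compartment_trajectory <- function(x, row.names = NULL, optional = FALSE, ...) {
  do.call(rbind, lapply(x$states, as.data.frame))
}

#' Prevalence targets for calibration
#'
#' @param year calendar year at which the model prevalence is matched.
#' @param quantity `"diabetes"`, `"obesity"`, `"smoking"` or `"inactivity"`.
#' @param value target prevalence in `[0, 1]`.
#' @param sex optional sex filter (`NA` = both).
#' @param age_lo,age_hi optional inclusive age range (default: everyone).
#' @param weight nonnegative weight in the least-squares loss.
#' @return one-row data frame; rows from several calls can be `rbind`-ed.
#' @export
prevalence_target <- function(year, quantity, value, sex = NA, age_lo = 0, age_hi = 99,
                              weight = 1) {
  stopifnot(value >= 0, value <= 1, weight >= 0)
  quantity <- match.arg(quantity, c("diabetes", "obesity", "smoking", "inactivity"))
  data.frame(year = year, quantity = quantity, value = value,
             sex = as.character(sex), age_lo = age_lo, age_hi = age_hi, weight = weight,
             stringsAsFactors = FALSE)
}

# resolve a dot path ("rr.obese", "lambda0", "onset.smoker") within params;
# length-1 leaves are free values, longer leaves are scaled by a multiplier
resolve_param <- function(params, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  node <- params[[parts[1]]]
  if (is.null(node)) stop("unknown parameter path: ", path, call. = FALSE)
  for (p in parts[-1]) {
    node <- if (is.list(node)) node[[p]] else node[p]
    if (is.null(node) || (length(node) == 1 && is.na(node))) {
      stop("unknown parameter path: ", path, call. = FALSE)
    }
  }
  node
}

assign_param <- function(params, path, theta) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  cur <- resolve_param(params, path)
  value <- if (length(cur) == 1L) theta else cur * theta # scale multiplier for arrays
  if (length(parts) == 1L) {
    params[[parts[1]]] <- value
  } else if (is.list(params[[parts[1]]])) {
    params[[parts[1]]][[parts[2]]] <- value
  } else {
    params[[parts[1]]][parts[2]] <- value
  }
  params
}

#' Calibrate model parameters to prevalence targets
#'
#' Bounded least squares: minimizes the weighted sum of squared differences
#' between model prevalences and targets over a named set of free
#' parameters, using `optim(method = "L-BFGS-B")` from the supplied
#' parameters as the start. Deterministic: no stochastic search.
#'
#' Free parameters are addressed by dot paths into the parameter object,
#' e.g. `"rr.obese"`, `"aging_rate"`, `"entry_rate.female"`. A path that
#' resolves to a scalar is fitted directly; a path resolving to a whole
#' rate table (e.g. `"lambda0"`, `"onset.obese"`) is fitted as a single
#' multiplicative scale on that table (start 1).
#'
#' @param initial initial `compartment_state` (its time is the simulation
#'   start).
#' @param params starting `model_params`.
#' @param targets data frame of targets from [prevalence_target()].
#' @param free named list: `path = c(lower, upper)` bounds per free
#'   parameter. Empty list returns `params` and its loss unchanged.
#' @param dt simulation step in years.
#' @return list of class `model_calibration` with elements `params`
#'   (fitted), `loss`, `start_loss`, `theta` (fitted raw values /
#'   multipliers), `convergence`, `message`.
#' @export
calibrate_model <- function(initial, params, targets, free = list(), dt = 0.1) {
  stopifnot(inherits(initial, "compartment_state"), inherits(params, "model_params"))
  if (!is.data.frame(targets) || nrow(targets) < 1) {
    stop("at least one prevalence target is required", call. = FALSE)
  }
  if (length(free) > nrow(targets)) {
    warning("more free parameters than targets: the fit may be unidentifiable")
  }
  t_max <- max(targets$year)
  if (!(t_max > initial$time)) stop("all target years must exceed the initial time", call. = FALSE)

  loss_for <- function(p) {
    traj <- simulate_model(initial, p, t_max, dt)
    sum(vapply(seq_len(nrow(targets)), function(i) {
      tg <- targets[i, ]
      st <- state_at(traj, tg$year)
      sexf <- if (is.na(tg$sex) || tg$sex == "NA") NULL else tg$sex
      pv <- prevalence(st, tg$quantity, sex = sexf, age_range = c(tg$age_lo, tg$age_hi))
      tg$weight * (pv - tg$value)^2
    }, numeric(1)))
  }

  start_loss <- loss_for(params)
  if (length(free) == 0) {
    return(structure(list(params = params, loss = start_loss, start_loss = start_loss,
                          theta = numeric(0), convergence = 0L, message = "no free parameters"),
                     class = "model_calibration"))
  }
  paths <- names(free)
  lower <- vapply(free, `[`, numeric(1), 1)
  upper <- vapply(free, `[`, numeric(1), 2)
  start <- vapply(paths, function(p) {
    cur <- resolve_param(params, p)
    if (length(cur) == 1L) as.numeric(cur) else 1
  }, numeric(1))
  start <- pmin(pmax(start, lower), upper)

  apply_theta <- function(theta) {
    p <- params
    for (i in seq_along(paths)) p <- assign_param(p, paths[i], theta[i])
    p
  }
  obj <- function(theta) loss_for(apply_theta(theta))
  fit <- tryCatch(
    stats::optim(start, obj, method = "L-BFGS-B", lower = lower, upper = upper,
                 control = list(factr = 1e7)),
    error = function(e) stop("calibration optimizer failed: ", conditionMessage(e),
                             call. = FALSE))
  # an abnormal line-search exit (flat ridge, unidentifiable spec) still
  # returns a usable point; keep whichever of start/end has the lower loss
  if (fit$value <= start_loss) {
    out_params <- apply_theta(fit$par); out_loss <- fit$value; theta <- fit$par
  } else {
    out_params <- params; out_loss <- start_loss; theta <- start
  }
  structure(list(params = out_params, loss = out_loss, start_loss = start_loss,
                 theta = stats::setNames(theta, paths), convergence = fit$convergence,
                 message = fit$message %||% ""),
            class = "model_calibration")
}

#' @export
print.model_calibration <- function(x, ...) {
  cat(sprintf("Model calibration: loss %.3e (start %.3e)\n", x$loss, x$start_loss))
  if (length(x$theta)) {
    for (nm in names(x$theta)) cat(sprintf("  %s = %.6g\n", nm, x$theta[nm]))
  } else cat("  no free parameters\n")
  invisible(x)
}
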