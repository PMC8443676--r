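#' Integrate plasmid dynamics with classical fixed-step Runge-Kutta
#'
#' Classical fourth-order Runge-Kutta with a fixed step. Components driven
#' slightly negative by discretization (above `-1e-12`) are clipped to zero;
#' larger negative excursions abort with a step-size error.
#'
#' @param params A plasmid parameter object, or any function
#'   `function(state) -> derivatives` for generic systems (e.g. the
#'   multiplasmid right-hand sides).
#' @param state0 Initial state, a named nonnegative numeric vector.
#' @param duration Total integration time (> 0).
#' @param step Time step (default 0.01).
#' @param record_every Record every this-many steps (default: about 500
#'   evenly spaced records). The initial and final states are always kept.
#' @return A `plasmid_trajectory`: list with `times` (strictly increasing)
#'   and `states` (matrix, one row per time, named columns).
#' @export
#' @examples
#' p <- conjugation_params(Delta = 0.5, gamma_c = 0.01, delta = 0.1, S = 1)
#' tr <- integrate_dynamics(p, plasmid_free_equilibrium(p), duration = 10)
#' tail(tr$states, 1)
integrate_dynamics <- function(params, state0, duration, step = 0.01,
                               record_every = NULL) {
  stopifnot(duration > 0, step > 0)
  if (is.function(params)) {
    rhs <- params
    state0 <- check_nonneg_state(state0)
  } else {
    rhs <- rhs_function(params)
    state0 <- check_state(state0, state_components(params))
  }
  n_steps <- max(1L, ceiling(duration / step))
  if (is.null(record_every))
    record_every <- max(1L, floor(n_steps / 500))
  record_every <- min(record_every, n_steps)
  rec_idx <- unique(c(seq.int(record_every, n_steps, by = record_every),
                      n_steps))
  out <- matrix(NA_real_, nrow = length(rec_idx) + 1L, ncol = length(state0),
                dimnames = list(NULL, names(state0)))
  times <- numeric(length(rec_idx) + 1L)
  x <- unname(state0)
  out[1L, ] <- x; times[1L] <- 0
  r <- 1L
  next_rec <- rec_idx[r]
  for (i in seq_len(n_steps)) {
    x <- rk4_step(rhs, x, step)
    if (i == next_rec) {
      out[r + 1L, ] <- x
      times[r + 1L] <- i * step
      r <- r + 1L
      next_rec <- if (r <= length(rec_idx)) rec_idx[r] else -1L
    }
  }
  structure(list(times = times, states = out),
            class = "plasmid_trajectory")
}

rk4_step <- function(rhs, x, h) {
  k1 <- rhs(x)
  k2 <- rhs(clip_state(x + h / 2 * k1))
  k3 <- rhs(clip_state(x + h / 2 * k2))
  k4 <- rhs(clip_state(x + h * k3))
  clip_state(x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4))
}

clip_state <- function(x, tol = 1e-12) {
  neg <- x < 0
  if (any(neg)) {
    if (any(x < -tol))
      stop(sprintf(
        "state went negative (min %.3e); reduce the integration step",
        min(x)), call. = FALSE)
    x[neg] <- 0
  }
  x
}

check_nonneg_state <- function(state0) {
  if (is.null(names(state0)))
    names(state0) <- paste0("x", seq_along(state0))
  if (any(!is.finite(state0)) || any(state0 < 0))
    stop("initial state must be finite and nonnegative", call. = FALSE)
  state0
}

#' @export
print.plasmid_trajectory <- function(x, ...) {
  cat(sprintf("<plasmid_trajectory> %d records over t = [%g, %g]\n",
              length(x$times), min(x$times), max(x$times)))
  cat("final state:\n")
  print(x$states[nrow(x$states), ])
  invisible(x)
}

#' @export
as.data.frame.plasmid_trajectory <- function(x, ...) {
  data.frame(time = x$times, x$states, check.names = FALSE)
}

#' Integrate until a steady state is reached
#'
#' Runs [integrate_dynamics()] in chunks, stopping once the maximum
#' derivative relative to the overall state scale,
#' `max(|dx/dt|) / max(|x|, 1e-12)`, falls below `tol`.
#'
#' @inheritParams integrate_dynamics
#' @param tol Steady-state tolerance on the relative derivative
#'   (default 1e-9).
#' @param t_max Give up (with an error if `must_converge`) after this much
#'   model time (default 1e5).
#' @param chunk Model time integrated between convergence checks.
#' @param must_converge Error on non-convergence (default `TRUE`); otherwise
#'   return the final state with attribute `converged = FALSE`.
#' @return The steady state, a named numeric vector with attributes
#'   `converged` (logical) and `t_reached`.
#' @export
run_to_steady_state <- function(params, state0, step = 0.01, tol = 1e-9,
                                t_max = 1e5, chunk = 50, must_converge = TRUE) {
  if (is.function(params)) {
    rhs <- params
    x <- check_nonneg_state(state0)
  } else {
    rhs <- rhs_function(params)
    x <- check_state(state0, state_components(params))
  }
  t <- 0
  repeat {
    deriv <- rhs(x)
    rel <- max(abs(deriv)) / max(abs(x), 1e-12)
    if (rel < tol) {
      attr(x, "converged") <- TRUE
      attr(x, "t_reached") <- t
      return(x)
    }
    if (t >= t_max) {
      if (must_converge)
        stop(sprintf(paste0("no steady state by t = %g ",
                            "(max relative derivative %.3e)"), t_max, rel),
             call. = FALSE)
      attr(x, "converged") <- FALSE
      attr(x, "t_reached") <- t
      return(x)
    }
    tr <- integrate_dynamics(rhs, x, duration = min(chunk, t_max - t),
                             step = step, record_every = 1e9)
    x <- tr$states[nrow(tr$states), ]
    t <- t + max(tr$times)
  }
}
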