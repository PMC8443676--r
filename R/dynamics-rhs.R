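#' Time derivatives of the conjugative single-plasmid model
#'
#' The model tracks plasmid-free cells `rho`, plasmid-bearing cells `rho_p`
#' and a shared nutrient `C` in a flow-through habitat supplied at rate `S`:
#' \deqn{d\rho/dt = \alpha C \rho - \gamma_c \rho \rho_p
#'       + p_\ell (1-\Delta)\alpha C \rho_p - \delta\rho}
#' \deqn{d\rho_p/dt = (1-\Delta)\alpha C \rho_p + \gamma_c \rho \rho_p
#'       - p_\ell (1-\Delta)\alpha C \rho_p - \delta\rho_p}
#' \deqn{dC/dt = S - \alpha C \rho - (1-\Delta)\alpha C \rho_p}
#'
#' @param state Named numeric vector with components `rho`, `rho_p`, `C`,
#'   all nonnegative.
#' @param params A [conjugation_params()] object.
#' @return Named numeric vector of derivatives `(rho, rho_p, C)`.
#' @export
#' @examples
#' p <- conjugation_params(Delta = 0.1, gamma_c = 0.2, delta = 0.1, S = 1)
#' conjugation_rhs(c(rho = 1, rho_p = 1, C = 1), p)
conjugation_rhs <- function(state, params) {
  stopifnot(inherits(params, "conjugation_params"))
  st <- check_state(state, c("rho", "rho_p", "C"))
  rho <- st[["rho"]]; rho_p <- st[["rho_p"]]; C <- st[["C"]]
  with(params, {
    growth_p <- (1 - Delta) * alpha * C * rho_p
    conj <- gamma_c * rho * rho_p
    c(rho   = alpha * C * rho - conj + p_ell * growth_p - delta * rho,
      rho_p = growth_p + conj - p_ell * growth_p - delta * rho_p,
      C     = S - alpha * C * rho - growth_p)
  })
}

#' Time derivatives of the transformative single-plasmid model
#'
#' As [conjugation_rhs()], with a fourth state variable `P`: free plasmids
#' released on cell death (`n_eff` viable copies per death), decaying at
#' rate `delta_p`, and infecting plasmid-free cells by mass action at rate
#' `gamma_t`:
#' \deqn{dP/dt = n_{eff}\,\delta\,\rho_p - \gamma_t \rho P - \delta_p P}
#'
#' @param state Named numeric vector with components `rho`, `rho_p`, `C`,
#'   `P`, all nonnegative.
#' @param params A [transformation_params()] object.
#' @return Named numeric vector of derivatives `(rho, rho_p, C, P)`.
#' @export
transformation_rhs <- function(state, params) {
  stopifnot(inherits(params, "transformation_params"))
  st <- check_state(state, c("rho", "rho_p", "C", "P"))
  rho <- st[["rho"]]; rho_p <- st[["rho_p"]]; C <- st[["C"]]; P <- st[["P"]]
  with(params, {
    growth_p <- (1 - Delta) * alpha * C * rho_p
    uptake <- gamma_t * rho * P
    c(rho   = alpha * C * rho - uptake + p_ell * growth_p - delta * rho,
      rho_p = growth_p + uptake - p_ell * growth_p - delta * rho_p,
      C     = S - alpha * C * rho - growth_p,
      P     = n_eff * delta * rho_p - uptake - delta_p * P)
  })
}

check_state <- function(state, comps) {
  if (is.null(names(state))) {
    if (length(state) != length(comps))
      stop(sprintf("state must have components (%s)",
                   paste(comps, collapse = ", ")), call. = FALSE)
    names(state) <- comps
  }
  missing <- setdiff(comps, names(state))
  if (length(missing))
    stop("state is missing component(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  st <- state[comps]
  if (any(!is.finite(st)))
    stop("state components must be finite", call. = FALSE)
  if (any(st < 0))
    stop("state components must be nonnegative", call. = FALSE)
  st
}

#' Dispatch to the right-hand side for a parameter set
#'
#' Returns an unvalidated closure over the parameters (positional state
#' access) for use in integration hot loops; the exported `*_rhs` functions
#' are the validating interface.
#'
#' @param params A plasmid parameter object.
#' @return A function `function(state)` returning derivatives.
#' @keywords internal
rhs_function <- function(params) {
  alpha <- params$alpha; Delta <- params$Delta; p_ell <- params$p_ell
  delta <- params$delta; S <- params$S
  if (mechanism_of(params) == "conjugation") {
    gamma_c <- params$gamma_c
    function(state) {
      rho <- state[[1L]]; rho_p <- state[[2L]]; C <- state[[3L]]
      growth_p <- (1 - Delta) * alpha * C * rho_p
      conj <- gamma_c * rho * rho_p
      c(alpha * C * rho - conj + p_ell * growth_p - delta * rho,
        growth_p + conj - p_ell * growth_p - delta * rho_p,
        S - alpha * C * rho - growth_p)
    }
  } else {
    gamma_t <- params$gamma_t; n_eff <- params$n_eff
    delta_p <- params$delta_p
    function(state) {
      rho <- state[[1L]]; rho_p <- state[[2L]]; C <- state[[3L]]
      P <- state[[4L]]
      growth_p <- (1 - Delta) * alpha * C * rho_p
      uptake <- gamma_t * rho * P
      c(alpha * C * rho - uptake + p_ell * growth_p - delta * rho,
        growth_p + uptake - p_ell * growth_p - delta * rho_p,
        S - alpha * C * rho - growth_p,
        n_eff * delta * rho_p - uptake - delta_p * P)
    }
  }
}

state_components <- function(params) {
  switch(mechanism_of(params),
         conjugation = c("rho", "rho_p", "C"),
         transformation = c("rho", "rho_p", "C", "P"))
}

#' Plasmid-free equilibrium
#'
#' Without plasmids the habitat settles at `rho* = S / delta` cells and
#' nutrient `C* = delta / alpha`.
#'
#' @param params A plasmid parameter object.
#' @return Named state vector (including `P = 0` for transformation) that
#'   zeroes the model right-hand side.
#' @export
#' @examples
#' p <- conjugation_params(Delta = 0.5, gamma_c = 0.01, delta = 0.1, S = 1)
#' plasmid_free_equilibrium(p)  # rho = 10, C = 0.1
plasmid_free_equilibrium <- function(params) {
  if (params$delta <= 0) stop("'delta' must be > 0", call. = FALSE)
  if (params$alpha <= 0) stop("'alpha' must be > 0", call. = FALSE)
  st <- c(rho = params$S / params$delta, rho_p = 0,
          C = params$delta / params$alpha)
  if (mechanism_of(params) == "transformation") st <- c(st, P = 0)
  st
}

#' Critical conjugation rate for plasmid invasion
#'
#' A conjugative plasmid can invade the plasmid-free equilibrium when its
#' transfer rate exceeds
#' \deqn{\gamma_c^* = \delta\,(\Delta + p_\ell(1-\Delta)) / \rho^*}
#' with `rho* = S / delta`: conjugation must outpace the combined losses from
#' the growth-rate deficit and segregational loss. Equality is treated as
#' non-invading.
#'
#' @param params A [conjugation_params()] object (its `gamma_c` is ignored).
#' @return The critical rate `gamma_c*`.
#' @export
#' @examples
#' p <- conjugation_params(Delta = 0.5, gamma_c = 0, delta = 0.1, S = 1)
#' conjugation_invasion_threshold(p)  # 0.005
conjugation_invasion_threshold <- function(params) {
  stopifnot(inherits(params, "conjugation_params"))
  if (params$S <= 0)
    stop("'S' must be > 0: plasmid-free equilibrium undefined", call. = FALSE)
  rho_star <- params$S / params$delta
  params$delta * (params$Delta + params$p_ell * (1 - params$Delta)) / rho_star
}

#' Critical transformation rate for plasmid invasion
#'
#' The plasmid-free equilibrium is unstable to a transformative plasmid when
#' \deqn{\gamma_t \rho^* > \delta_p \frac{\Delta + p_\ell(1-\Delta)}
#'       {n_{eff} - \Delta - p_\ell(1-\Delta)}.}
#' When the released-plasmid yield `n_eff` does not exceed the total
#' replication deficit `Delta + p_ell (1 - Delta)` the inequality reverses
#' and no transformation rate allows invasion; `Inf` is returned as the
#' no-invasion sentinel.
#'
#' @param params A [transformation_params()] object (its `gamma_t` is
#'   ignored).
#' @return The critical rate `gamma_t*`, or `Inf` if invasion is impossible.
#' @export
transformation_invasion_threshold <- function(params) {
  stopifnot(inherits(params, "transformation_params"))
  if (params$S <= 0)
    stop("'S' must be > 0: plasmid-free equilibrium undefined", call. = FALSE)
  deficit <- params$Delta + params$p_ell * (1 - params$Delta)
  denom <- params$n_eff - deficit
  if (denom <= 0) return(Inf)
  rho_star <- params$S / params$delta
  params$delta_p * deficit / (rho_star * denom)
}

#' Invasion barrier of a conjugative plasmid as a function of copy number
#'
#' The right-hand side of the conjugative invasion condition, with cost and
#' loss expressed through copy number (`Delta = Delta_p * n_p`,
#' `p_ell = 2^(1 - n_p)`):
#' \deqn{\delta\,(\Delta_p n_p + 2^{1-n_p}(1 - \Delta_p n_p)).}
#' The barrier has a minimum at finite `n_p`: few copies are often lost at
#' division, many copies burden the host.
#'
#' @param n_p Copy number(s), >= 1. Vectorized.
#' @param Delta_p Per-copy fitness cost (> 0).
#' @param delta Cell death rate.
#' @return Barrier value(s); invasion requires `gamma_c * rho*` to exceed it.
#' @export
#' @examples
#' conjugative_invasion_barrier(1:8, Delta_p = 0.05, delta = 1)
conjugative_invasion_barrier <- function(n_p, Delta_p, delta) {
  stopifnot(Delta_p > 0, all(n_p >= 1))
  Delta <- Delta_p * n_p
  if (any(Delta >= 1))
    stop("'Delta_p * n_p' must be < 1: total cost exceeds the host budget",
         call. = FALSE)
  delta * (Delta + 2^(1 - n_p) * (1 - Delta))
}

#' Optimal plasmid copy number
#'
#' For a conjugative plasmid the optimum minimizes the invasion barrier
#' [conjugative_invasion_barrier()] over integer copy numbers, balancing
#' segregational loss against host burden; the optimum is moderate. For a
#' transformative plasmid the barrier decreases as the host budget is
#' consumed, so the optimum is the phage-like extreme `n_p = 1 / Delta_p`,
#' at which host growth is driven to zero. That optimum only supports
#' invasion if the released plasmids outnumber the replication deficit,
#' i.e. `p_v * n_p > 1` at the optimum; otherwise `NA` is returned.
#'
#' @param copy_params A [copy_number_params()] object (`n_p` ignored).
#' @param mechanism `"conjugation"` or `"transformation"`.
#' @param delta Cell death rate (conjugation barrier scale; does not move
#'   the optimum).
#' @return A list with `n_p` (the optimum; integer for conjugation, real for
#'   transformation, `NA` if no copy number permits invasion), `barrier`
#'   (conjugation only) and `n_p_continuous` (conjugation only, the
#'   real-valued minimizer, for diagnostics).
#' @export
#' @examples
#' optimal_copy_number(copy_number_params(Delta_p = 0.05), "conjugation")
#' optimal_copy_number(copy_number_params(Delta_p = 0.01), "transformation")
optimal_copy_number <- function(copy_params, mechanism = c("conjugation",
                                                           "transformation"),
                                delta = 1) {
  mechanism <- match.arg(mechanism)
  Delta_p <- copy_params$Delta_p
  if (Delta_p >= 1)
    stop("'Delta_p' must be < 1: a single copy already exceeds the budget",
         call. = FALSE)
  if (mechanism == "transformation") {
    n_opt <- 1 / Delta_p
    # at Delta = 1 the deficit is 1, so invasion needs n_eff = p_v * n_p > 1
    if (copy_params$p_v * n_opt <= 1) return(list(n_p = NA_real_))
    return(list(n_p = n_opt))
  }
  n_max <- floor((1 - 1e-12) / Delta_p)
  grid <- seq_len(n_max)
  b <- conjugative_invasion_barrier(grid, Delta_p, delta)
  n_int <- grid[which.min(b)]  # which.min takes the first (smallest) tie
  opt <- stats::optimize(function(n) conjugative_invasion_barrier(n, Delta_p,
                                                                  delta),
                         interval = c(1, n_max))
  list(n_p = n_int, barrier = min(b), n_p_continuous = opt$minimum)
}
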