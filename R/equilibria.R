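#' Analytic Jacobian of the single-plasmid models
#'
#' Hand-derived Jacobian of [conjugation_rhs()] or [transformation_rhs()]
#' with respect to the state, used for linear stability analysis.
#'
#' @param state Named state vector.
#' @param params A plasmid parameter object.
#' @return A square matrix (3x3 conjugation, 4x4 transformation).
#' @export
dynamics_jacobian <- function(state, params) {
  st <- check_state(state, state_components(params))
  rho <- st[["rho"]]; rho_p <- st[["rho_p"]]; C <- st[["C"]]
  a <- params$alpha; D <- params$Delta; p <- params$p_ell
  d <- params$delta
  g1 <- (1 - D) * a  # growth coefficient of plasmid-bearing cells
  if (mechanism_of(params) == "conjugation") {
    g <- params$gamma_c
    J <- matrix(c(
      a * C - g * rho_p - d,  -g * rho + p * g1 * C,  a * rho + p * g1 * rho_p,
      g * rho_p,              (1 - p) * g1 * C + g * rho - d, (1 - p) * g1 * rho_p,
      -a * C,                 -g1 * C,                -a * rho - g1 * rho_p),
      nrow = 3, byrow = TRUE,
      dimnames = list(c("rho", "rho_p", "C"), c("rho", "rho_p", "C")))
  } else {
    g <- params$gamma_t
    P <- st[["P"]]
    n_eff <- params$n_eff; d_p <- params$delta_p
    J <- matrix(c(
      a * C - g * P - d, p * g1 * C,             a * rho + p * g1 * rho_p, -g * rho,
      g * P,             (1 - p) * g1 * C - d,   (1 - p) * g1 * rho_p,      g * rho,
      -a * C,            -g1 * C,                -a * rho - g1 * rho_p,     0,
      -g * P,            n_eff * d,              0,                        -g * rho - d_p),
      nrow = 4, byrow = TRUE,
      dimnames = list(c("rho", "rho_p", "C", "P"),
                      c("rho", "rho_p", "C", "P")))
  }
  J
}

new_equilibrium <- function(state, kind, params) {
  structure(list(state = state, kind = kind, stability = NA_character_,
                 marginal = NA, eigenvalues = NULL,
                 residual = max(abs(rhs_function(params)(unname(state))))),
            class = "plasmid_equilibrium")
}

#' @export
print.plasmid_equilibrium <- function(x, ...) {
  cat(sprintf("<equilibrium: %s, %s%s>\n", x$kind,
              ifelse(is.na(x$stability), "unclassified", x$stability),
              if (isTRUE(x$marginal)) ", marginal" else ""))
  print(x$state)
  invisible(x)
}

#' Linear stability of an equilibrium
#'
#' Computes the eigenvalues of the analytic Jacobian at the equilibrium
#' state and classifies it as stable when every eigenvalue real part is
#' below `-tol_eig`. Eigenvalues with real part within `tol_eig` of zero
#' mark the equilibrium as marginal.
#'
#' @param eq A `plasmid_equilibrium` (from [find_equilibria()]) or a named
#'   state vector known to zero the right-hand side.
#' @param params A plasmid parameter object.
#' @param tol_eig Tolerance on eigenvalue real parts (default 1e-8).
#' @return The equilibrium with `stability` (`"stable"`/`"unstable"`),
#'   `marginal` and `eigenvalues` filled in.
#' @export
classify_stability <- function(eq, params, tol_eig = 1e-8) {
  if (!inherits(eq, "plasmid_equilibrium"))
    eq <- new_equilibrium(check_state(eq, state_components(params)),
                          kind = "unknown", params)
  ev <- eigen(dynamics_jacobian(eq$state, params),
              only.values = TRUE)$values
  re <- Re(ev)
  eq$eigenvalues <- ev
  eq$stability <- if (all(re < -tol_eig)) "stable" else "unstable"
  eq$marginal <- any(abs(re) <= tol_eig)
  eq
}

# interior (rho, rho_p > 0) equilibria by scalar reduction: at any steady
# state the total cell density is T = S/delta; parametrizing by rho gives
# closed expressions for the other components, leaving one residual equation
# (nutrient balance) to root-find in rho.
interior_equilibria <- function(params, n_scan = 2000, tol = 1e-10) {
  d <- params$delta; S <- params$S; a <- params$alpha
  D <- params$Delta; p <- params$p_ell
  g1 <- (1 - p) * (1 - D) * a
  T_tot <- S / d
  conj <- mechanism_of(params) == "conjugation"
  g <- if (conj) params$gamma_c else params$gamma_t
  if (g <= 0 || g1 <= 0) return(list())
  C_of_rho <- if (conj) {
    function(rho) (d - g * rho) / g1
  } else {
    n_eff <- params$n_eff; d_p <- params$delta_p
    function(rho) (d - g * rho * n_eff * d / (g * rho + d_p)) / g1
  }
  resid <- function(rho) {
    C <- C_of_rho(rho)
    S - a * C * (rho + (1 - D) * (T_tot - rho))
  }
  eps <- T_tot * 1e-7
  upper <- T_tot - eps
  if (conj) upper <- min(upper, d / g - eps)  # keep C positive
  if (upper <= eps) return(list())
  grid <- seq(eps, upper, length.out = n_scan)
  C_grid <- C_of_rho(grid)
  ok <- C_grid > 0
  grid <- grid[ok]
  if (length(grid) < 2) return(list())
  r <- resid(grid)
  sgn <- sign(r)
  flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  roots <- lapply(flips, function(i) {
    stats::uniroot(resid, lower = grid[i], upper = grid[i + 1],
                   tol = 1e-14)$root
  })
  full_rhs <- rhs_function(params)
  out <- list()
  for (rho in roots) {
    rho_p <- T_tot - rho
    C <- C_of_rho(rho)
    st <- c(rho = rho, rho_p = rho_p, C = C)
    if (!conj) {
      P <- params$n_eff * d * rho_p / (g * rho + params$delta_p)
      st <- c(st, P = P)
    }
    if (any(st < 0)) next
    scale <- max(abs(st), 1)
    if (max(abs(full_rhs(unname(st)))) / scale > tol) next
    out[[length(out) + 1L]] <- st
  }
  out
}

#' Locate the equilibria of a single-plasmid model
#'
#' Returns the plasmid-free equilibrium (always present, closed form), the
#' plasmid-only equilibrium when it exists (closed form; only an exact
#' equilibrium when `p_ell = 0`, since segregational loss regenerates
#' plasmid-free cells), and any coexistence equilibria with
#' `rho, rho_p > 0`, found by reducing the steady-state conditions to a
#' scalar equation in `rho` and scanning for sign changes. Every returned
#' state zeroes the right-hand side to within `tol` (relative), and each is
#' classified for stability.
#'
#' @param params A plasmid parameter object.
#' @param tol Residual tolerance for accepting an equilibrium.
#' @param tol_eig Eigenvalue tolerance passed to [classify_stability()].
#' @return A list of `plasmid_equilibrium` objects with fields `state`,
#'   `kind` (`"no_plasmid"`, `"plasmid_only"`, `"coexistence"`),
#'   `stability`, `eigenvalues`, `residual`.
#' @export
#' @examples
#' p <- conjugation_params(Delta = 0.5, gamma_c = 0.02, delta = 0.1, S = 1)
#' sapply(find_equilibria(p), function(e) e$kind)
find_equilibria <- function(params, tol = 1e-10, tol_eig = 1e-8) {
  eqs <- list(new_equilibrium(plasmid_free_equilibrium(params),
                              "no_plasmid", params))
  d <- params$delta; S <- params$S; a <- params$alpha
  D <- params$Delta
  if (params$p_ell == 0 && D < 1) {
    st <- c(rho = 0, rho_p = S / d, C = d / ((1 - D) * a))
    if (mechanism_of(params) == "transformation")
      st <- c(st, P = params$n_eff * S / params$delta_p)
    eq <- new_equilibrium(st, "plasmid_only", params)
    if (eq$residual / max(abs(st), 1) <= tol)
      eqs <- c(eqs, list(eq))
  }
  for (st in interior_equilibria(params, tol = tol))
    eqs <- c(eqs, list(new_equilibrium(st, "coexistence", params)))
  lapply(eqs, classify_stability, params = params, tol_eig = tol_eig)
}

#' Ecological phase diagram over plasmid cost and transfer rate
#'
#' Labels every point of a (Delta, transfer-rate) grid by the stable
#' long-run outcome(s) implied by linear stability of its equilibria:
#' `no_plasmid` (only the plasmid-free state is stable), `coexistence`
#' (a stable interior equilibrium exists), `plasmid_only` (only the
#' plasmid-only state is stable), or `bistable` (plasmid-free and
#' plasmid-only states both locally stable, as arises for transformative
#' plasmids with `n_eff < 1`).
#'
#' @param params Base parameter object supplying all rates other than
#'   `Delta` and the transfer rate (the grid overrides those two). The
#'   default grids assume `p_ell = 0`.
#' @param delta_axis Grid of plasmid costs in (0, 1); default 100 linear
#'   points over (0.01, 0.99).
#' @param gamma_axis Grid of transfer rates; default 100 log-spaced points
#'   spanning the invasion threshold range of the cost axis.
#' @return A `phase_diagram`: list with `delta_axis`, `gamma_axis`, `labels`
#'   (character matrix, costs in rows, rates in columns).
#' @export
#' @examples
#' p <- conjugation_params(Delta = 0.5, gamma_c = 0.01, delta = 0.1, S = 1)
#' pd <- phase_diagram(p, delta_axis = seq(0.1, 0.9, by = 0.2),
#'                     gamma_axis = 10^seq(-4, -1, length.out = 8))
#' table(pd$labels)
phase_diagram <- function(params, delta_axis = NULL, gamma_axis = NULL) {
  mech <- mechanism_of(params)
  if (is.null(delta_axis))
    delta_axis <- seq(0.01, 0.99, length.out = 100)
  if (is.null(gamma_axis)) {
    thr <- sapply(delta_axis, function(D) {
      q <- params; q$Delta <- D
      if (mech == "conjugation") conjugation_invasion_threshold(q)
      else transformation_invasion_threshold(q)
    })
    thr <- thr[is.finite(thr) & thr > 0]
    lo <- if (length(thr)) min(thr) / 10 else 1e-4
    hi <- if (length(thr)) max(thr) * 100 else 1
    gamma_axis <- 10^seq(log10(lo), log10(hi), length.out = 100)
  }
  labels <- matrix(NA_character_, nrow = length(delta_axis),
                   ncol = length(gamma_axis))
  for (i in seq_along(delta_axis)) {
    for (j in seq_along(gamma_axis)) {
      q <- params
      q$Delta <- delta_axis[i]
      if (mech == "conjugation") q$gamma_c <- gamma_axis[j]
      else q$gamma_t <- gamma_axis[j]
      labels[i, j] <- classify_phase_point(q)
    }
  }
  structure(list(delta_axis = delta_axis, gamma_axis = gamma_axis,
                 labels = labels, mechanism = mech),
            class = "phase_diagram")
}

classify_phase_point <- function(params) {
  eqs <- find_equilibria(params)
  kinds <- vapply(eqs, function(e) e$kind, "")
  stable <- vapply(eqs, function(e) identical(e$stability, "stable"), NA)
  if (any(kinds == "coexistence" & stable)) return("coexistence")
  np <- any(kinds == "no_plasmid" & stable)
  po <- any(kinds == "plasmid_only" & stable)
  if (np && po) return("bistable")
  if (po) return("plasmid_only")
  if (np) return("no_plasmid")
  "unresolved"
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat(sprintf("<phase_diagram: %s, %d x %d grid>\n", x$mechanism,
              length(x$delta_axis), length(x$gamma_axis)))
  print(table(x$labels))
  invisible(x)
}

#' @export
as.data.frame.phase_diagram <- function(x, ...) {
  data.frame(Delta = rep(x$delta_axis, times = length(x$gamma_axis)),
             gamma = rep(x$gamma_axis, each = length(x$delta_axis)),
             label = as.vector(x$labels))
}
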