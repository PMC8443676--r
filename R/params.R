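#' Parameters for the conjugative single-plasmid model
#'
#' Bundles the rates of the chemostat-style model of competition between
#' plasmid-free and plasmid-bearing cells where the plasmid spreads by
#' conjugation (mass-action cell-cell contact).
#'
#' @param alpha Per-nutrient growth-rate coefficient (1/(nutrient x time)).
#' @param Delta Plasmid fitness cost, dimensionless, in `[0, 1)`. Plasmid-free
#'   cells grow at rate `alpha * C`, plasmid-bearing cells at
#'   `(1 - Delta) * alpha * C`.
#' @param gamma_c Conjugation rate (mass action, 1/(cell density x time)).
#' @param p_ell Probability that a daughter cell of a plasmid-bearing mother
#'   receives no plasmid at division, in `[0, 1]`.
#' @param delta Cell death rate (1/time).
#' @param S Nutrient supply rate (nutrient/time).
#'
#' @return An object of class `conjugation_params`.
#' @seealso [transformation_params()], [conjugation_rhs()],
#'   [conjugation_invasion_threshold()]
#' @export
#' @examples
#' conjugation_params(Delta = 0.5, gamma_c = 0.01, delta = 0.1, S = 1)
conjugation_params <- function(alpha = 1, Delta, gamma_c, p_ell = 0,
                               delta, S) {
  p <- list(alpha = alpha, Delta = Delta, gamma_c = gamma_c,
            p_ell = p_ell, delta = delta, S = S)
  validate_single_plasmid_params(p, mechanism = "conjugation")
  structure(p, class = c("conjugation_params", "plasmid_params"))
}

#' Parameters for the transformative single-plasmid model
#'
#' As [conjugation_params()], but the plasmid spreads by transformation:
#' cell death releases free plasmids that infect plasmid-free cells by mass
#' action.
#'
#' @inheritParams conjugation_params
#' @param gamma_t Transformation (free-plasmid uptake) rate.
#' @param n_eff Number of viable free plasmids released per cell death
#'   (dimensionless, >= 0).
#' @param delta_p Free-plasmid decay rate (1/time).
#'
#' @return An object of class `transformation_params`.
#' @export
#' @examples
#' transformation_params(Delta = 0.2, gamma_t = 0.02, delta = 0.1, S = 1,
#'                       n_eff = 0.6, delta_p = 0.3)
transformation_params <- function(alpha = 1, Delta, gamma_t, p_ell = 0,
                                  delta, S, n_eff, delta_p) {
  p <- list(alpha = alpha, Delta = Delta, gamma_t = gamma_t,
            p_ell = p_ell, delta = delta, S = S,
            n_eff = n_eff, delta_p = delta_p)
  validate_single_plasmid_params(p, mechanism = "transformation")
  structure(p, class = c("transformation_params", "plasmid_params"))
}

validate_single_plasmid_params <- function(p, mechanism) {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop(sprintf("'%s' must be a single finite number", nm), call. = FALSE)
  }
  for (nm in names(p)) num1(p[[nm]], nm)
  if (p$alpha < 0 || p$delta < 0 || p$S < 0)
    stop("rates 'alpha', 'delta', 'S' must be nonnegative", call. = FALSE)
  if (p$Delta < 0 || p$Delta >= 1)
    stop("'Delta' must lie in [0, 1)", call. = FALSE)
  if (p$p_ell < 0 || p$p_ell > 1)
    stop("'p_ell' must lie in [0, 1]", call. = FALSE)
  if (mechanism == "conjugation" && p$gamma_c < 0)
    stop("'gamma_c' must be nonnegative", call. = FALSE)
  if (mechanism == "transformation") {
    if (p$gamma_t < 0 || p$n_eff < 0 || p$delta_p < 0)
      stop("'gamma_t', 'n_eff', 'delta_p' must be nonnegative", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.plasmid_params <- function(x, ...) {
  cat(sprintf("<%s>\n", class(x)[1]))
  vals <- unlist(x)
  cat(paste(sprintf("  %-8s %g", names(vals), vals), collapse = "\n"), "\n")
  invisible(x)
}

#' Which transfer mechanism does a parameter set describe?
#'
#' @param params A `conjugation_params` or `transformation_params` object.
#' @return `"conjugation"` or `"transformation"`.
#' @export
mechanism_of <- function(params) {
  if (inherits(params, "conjugation_params")) return("conjugation")
  if (inherits(params, "transformation_params")) return("transformation")
  stop("not a plasmid parameter object", call. = FALSE)
}

#' Copy-number parameters
#'
#' Copy number enters the single-plasmid models through three scalings: the
#' total fitness cost `Delta = Delta_p * n_p`, the segregation-loss
#' probability `p_ell = 2^(1 - n_p)` (the chance that a daughter receives
#' zero of `n_p` randomly segregated copies), and, for transformative
#' plasmids, the released-plasmid count `n_eff = p_v * n_p`.
#'
#' @param Delta_p Fitness cost of a single plasmid copy (> 0).
#' @param n_p Plasmid copy number (>= 1).
#' @param p_v Probability that a released plasmid copy is viable, in `[0, 1]`.
#'
#' @return An object of class `copy_number_params`.
#' @export
copy_number_params <- function(Delta_p, n_p = 1, p_v = 1) {
  if (!is.numeric(Delta_p) || Delta_p <= 0)
    stop("'Delta_p' must be > 0", call. = FALSE)
  if (!is.numeric(n_p) || n_p < 1)
    stop("'n_p' must be >= 1", call. = FALSE)
  if (p_v < 0 || p_v > 1) stop("'p_v' must lie in [0, 1]", call. = FALSE)
  structure(list(Delta_p = Delta_p, n_p = n_p, p_v = p_v),
            class = "copy_number_params")
}

#' Segregation-loss probability implied by a copy number
#'
#' @param n_p Copy number (>= 1).
#' @return `2^(1 - n_p)`, the probability that random segregation of `n_p`
#'   copies leaves a daughter cell empty.
#' @export
segregation_loss_probability <- function(n_p) {
  stopifnot(all(n_p >= 1))
  2^(1 - n_p)
}
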