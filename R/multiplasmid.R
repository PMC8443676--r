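#' Parameters for multiplasmid co-infection dynamics
#'
#' Describes a community of `m` compatible plasmid types (distinct
#' incompatibility groups) spreading by conjugation through a single
#' well-mixed population. All types share the same per-plasmid cost,
#' transfer rate and loss probability; fitness costs combine across carried
#' types according to `cost_model`.
#'
#' @param m Number of unique plasmid types (integer >= 1).
#' @param Delta Per-plasmid fitness cost, in `[0, 1)`.
#' @param cost_model `"multiplicative"` (`Delta_tot = 1 - (1 - Delta)^k`) or
#'   `"additive"` (`Delta_tot = min(k * Delta, 1)`).
#' @param gamma_c Per-type conjugation rate.
#' @param p_ell Per-type segregation-loss probability per division.
#' @param delta,S,alpha As in [conjugation_params()].
#' @param symmetric Plasmid types are identical and start at equal
#'   abundances, enabling the reduced type-count system.
#' @return An object of class `community_params`.
#' @export
community_params <- function(m, Delta, cost_model = c("multiplicative",
                                                      "additive"),
                             gamma_c, p_ell = 0, delta, S, alpha = 1,
                             symmetric = TRUE) {
  cost_model <- match.arg(cost_model)
  if (m < 1 || m != round(m)) stop("'m' must be a positive integer",
                                   call. = FALSE)
  base <- conjugation_params(alpha = alpha, Delta = Delta, gamma_c = gamma_c,
                             p_ell = p_ell, delta = delta, S = S)
  structure(c(unclass(base),
              list(m = as.integer(m), cost_model = cost_model,
                   symmetric = isTRUE(symmetric))),
            class = "community_params")
}

#' Total fitness cost of carrying k plasmid types
#'
#' @param k Number of carried plasmid types (vectorized, >= 0).
#' @param Delta Per-plasmid cost.
#' @param cost_model `"multiplicative"` or `"additive"` (clamped at 1: the
#'   growth rate cannot go negative).
#' @return Total cost `Delta_tot(k)` in `[0, 1]`.
#' @export
#' @examples
#' total_cost(0:4, Delta = 0.05, "multiplicative")
total_cost <- function(k, Delta, cost_model = c("multiplicative",
                                                "additive")) {
  cost_model <- match.arg(cost_model)
  stopifnot(all(k >= 0))
  if (cost_model == "multiplicative") 1 - (1 - Delta)^k
  else pmin(k * Delta, 1)
}

#' Full subset-resolved co-infection dynamics
#'
#' Builds the derivative function of the `2^m + 1`-dimensional model that
#' tracks the density of every plasmid-content class (each subset of the
#' `m` types) plus the nutrient. A class carrying set `A` grows at rate
#' `(1 - Delta_tot(|A|)) * alpha * C * x_A`; at each division the new cell
#' retains each carried type independently with probability `1 - p_ell`
#' (the mother regenerates its full content), so offspring land in subset
#' `B` of `A` with weight `(1-p_ell)^|B| * p_ell^(|A|-|B|)`. Any cell
#' carrying type `i` donates it by conjugation to any cell lacking it at
#' rate `gamma_c` per donor-recipient pair; transfers of different types
#' are independent, one type per event. At `m = 1` the system is exactly
#' the single-plasmid conjugation model.
#'
#' @param params A [community_params()] object with `m <= 12`.
#' @return A function `function(state)` where `state` is
#'   `c(x_<subset 0..2^m-1>, C)` (subsets indexed by bitmask) returning the
#'   derivative vector.
#' @export
build_full_rhs <- function(params) {
  m <- params$m
  if (m > 12)
    stop("full subset system capped at m <= 12; use the reduced ",
         "type-count system (build_reduced_rhs)", call. = FALSE)
  n_sub <- 2^m
  subsets <- 0:(n_sub - 1)
  ksize <- vapply(subsets, bitcount, 0L)
  gcoef <- (1 - total_cost(ksize, params$Delta, params$cost_model)) *
    params$alpha
  p <- params$p_ell
  # segregation redistribution matrix M[B+1, A+1], B subset of A
  if (p > 0) {
    M <- matrix(0, n_sub, n_sub)
    for (A in subsets) {
      Bs <- sub_subsets(A)
      kA <- ksize[A + 1]
      kB <- vapply(Bs, bitcount, 0L)
      M[Bs + 1, A + 1] <- (1 - p)^kB * p^(kA - kB)
    }
  } else M <- NULL
  # conjugation index pairs per type
  gamma_c <- params$gamma_c
  delta <- params$delta; S <- params$S
  type_bits <- 2^(0:(m - 1))
  carriers <- lapply(type_bits, function(b) which(bitwAnd(subsets, b) > 0))
  lacking  <- lapply(type_bits, function(b) which(bitwAnd(subsets, b) == 0))
  function(state) {
    x <- state[seq_len(n_sub)]
    C <- state[n_sub + 1]
    g <- gcoef * C * x
    births <- if (is.null(M)) g else drop(M %*% g)
    dx <- births - delta * x
    if (gamma_c > 0) {
      for (i in seq_len(m)) {
        D_i <- sum(x[carriers[[i]]])
        recip <- lacking[[i]]
        flux <- gamma_c * x[recip] * D_i
        dx[recip] <- dx[recip] - flux
        dx[recip + type_bits[i]] <- dx[recip + type_bits[i]] + flux
      }
    }
    c(dx, S - sum(g))
  }
}

bitcount <- function(x) {
  n <- 0L
  while (x > 0) {
    n <- n + bitwAnd(x, 1L)
    x <- bitwShiftR(x, 1L)
  }
  n
}

# all subsets of bitmask A (including A and 0)
sub_subsets <- function(A) {
  if (A == 0) return(0L)
  bits <- which(bitwAnd(A, 2^(0:30)) > 0) - 1L
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(bits)))
  apply(combos, 1, function(sel) sum(2^bits[sel]))
}

#' Reduced type-count co-infection dynamics
#'
#' For identical plasmid types starting at equal abundances the full
#' `2^m + 1` system collapses onto the number of carried types: densities
#' `x_k`, `k = 0..m`, plus nutrient. Division of class `k` sends the new
#' cell to class `j <= k` with binomial weight
#' `choose(k, j) (1-p_ell)^j p_ell^(k-j)`; conjugative promotion `k -> k+1`
#' occurs at rate `gamma_c * (m - k) * x_k * D`, where
#' `D = sum_j x_j * j / m` is the carrier density of any fixed type under
#' symmetry.
#'
#' @param params A [community_params()] object with `symmetric = TRUE`.
#' @return A function `function(state)` with `state = c(x_0..x_m, C)`.
#' @export
build_reduced_rhs <- function(params) {
  if (!isTRUE(params$symmetric))
    stop("the reduced system requires symmetric = TRUE", call. = FALSE)
  m <- params$m
  k <- 0:m
  gcoef <- (1 - total_cost(k, params$Delta, params$cost_model)) *
    params$alpha
  p <- params$p_ell
  W <- if (p > 0) {
    outer(k, k, function(j, kk)
      ifelse(j <= kk, choose(kk, j) * (1 - p)^j * p^(kk - j), 0))
  } else NULL
  gamma_c <- params$gamma_c
  delta <- params$delta; S <- params$S
  frac <- k / m
  m_minus_k <- m - k
  function(state) {
    x <- state[seq_len(m + 1)]
    C <- state[m + 2]
    g <- gcoef * C * x
    births <- if (is.null(W)) g else drop(W %*% g)
    dx <- births - delta * x
    if (gamma_c > 0) {
      D <- sum(x * frac)
      up <- gamma_c * m_minus_k * x * D
      dx <- dx - up
      dx[-1] <- dx[-1] + up[-(m + 1)]
    }
    c(dx, S - sum(g))
  }
}

#' Critical per-type conjugation rate in the community model
#'
#' The invasion threshold of a single plasmid with the community's
#' per-plasmid cost and loss probability; community transfer rates are
#' conveniently expressed as multiples of it.
#'
#' @param params A [community_params()] object.
#' @return `gamma_c*` for one plasmid type invading the plasmid-free state.
#' @export
community_invasion_threshold <- function(params) {
  conjugation_invasion_threshold(
    conjugation_params(alpha = params$alpha, Delta = params$Delta,
                       gamma_c = 0, p_ell = params$p_ell,
                       delta = params$delta, S = params$S))
}

#' Steady-state distribution of plasmid types per cell
#'
#' Integrates the co-infection dynamics from a nearly plasmid-free state
#' (inoculum `1e-6 * rho*` in each single-type class) to steady state and
#' normalizes the cell-class densities into a distribution over the number
#' of carried types `k = 0..m`.
#'
#' @param params A [community_params()] object.
#' @param gamma_multiplier Conjugation rate as a multiple of the single-type
#'   invasion threshold [community_invasion_threshold()]; overrides
#'   `params$gamma_c` when non-`NULL`.
#' @param system `"reduced"` (default; requires symmetry) or `"full"`.
#' @param step,tol,t_max Integrator controls, see [run_to_steady_state()].
#' @return Named numeric vector of probabilities over `k = 0..m`, with
#'   attributes `gamma_c` and `state` (the full steady state).
#' @export
#' @examples
#' cp <- community_params(m = 3, Delta = 0.1, gamma_c = 0, p_ell = 0.05,
#'                        delta = 1, S = 1)
#' steady_state_type_distribution(cp, gamma_multiplier = 2)
steady_state_type_distribution <- function(params, gamma_multiplier = NULL,
                                           system = c("reduced", "full"),
                                           step = 0.01, tol = 1e-9,
                                           t_max = 1e5) {
  system <- match.arg(system)
  if (!is.null(gamma_multiplier))
    params$gamma_c <- gamma_multiplier * community_invasion_threshold(params)
  m <- params$m
  rho_star <- params$S / params$delta
  C_star <- params$delta / params$alpha
  inoc <- 1e-6 * rho_star
  if (system == "reduced") {
    rhs <- build_reduced_rhs(params)
    x0 <- c(rho_star, m * inoc, rep(0, m - 1), C_star)
    names(x0) <- c(paste0("x", 0:m), "C")
    ss <- run_to_steady_state(rhs, x0, step = step, tol = tol, t_max = t_max)
    dens <- ss[seq_len(m + 1)]
  } else {
    rhs <- build_full_rhs(params)
    n_sub <- 2^m
    x0 <- numeric(n_sub + 1)
    x0[1] <- rho_star
    x0[1 + 2^(0:(m - 1))] <- inoc
    x0[n_sub + 1] <- C_star
    names(x0) <- c(paste0("s", 0:(n_sub - 1)), "C")
    ss <- run_to_steady_state(rhs, x0, step = step, tol = tol, t_max = t_max)
    ksize <- vapply(0:(n_sub - 1), bitcount, 0L)
    dens <- as.vector(tapply(ss[seq_len(n_sub)], ksize, sum))
  }
  probs <- pmax(dens, 0)
  probs <- probs / sum(probs)
  names(probs) <- 0:m
  attr(probs, "gamma_c") <- params$gamma_c
  attr(probs, "state") <- ss
  probs
}

#' Exact Poisson-binomial distribution
#'
#' Distribution of the number of successes among independent Bernoulli
#' trials with per-trial probabilities `p`, computed by iterative
#' convolution. With identical `p` this is `Binomial(length(p), p)`; it is
#' the reference distribution for independently transferring plasmids that
#' individually infect fractions `p_i` of the population.
#'
#' @param p Vector of probabilities in `[0, 1]`.
#' @return Numeric probability vector over `0..length(p)` successes
#'   (named by count).
#' @export
#' @examples
#' poisson_binomial(c(0.5, 0.2))  # (0.4, 0.5, 0.1)
poisson_binomial <- function(p) {
  stopifnot(all(p >= 0), all(p <= 1))
  probs <- 1
  for (pi in p)
    probs <- c(probs * (1 - pi), 0) + c(0, probs * pi)
  names(probs) <- seq_along(probs) - 1
  probs
}

#' Total variation distance between discrete distributions
#'
#' @param d1,d2 Probability vectors (shorter one is zero-padded).
#' @return Half the L1 distance, in `[0, 1]`.
#' @export
tv_distance <- function(d1, d2) {
  n <- max(length(d1), length(d2))
  d1 <- c(d1, rep(0, n - length(d1)))
  d2 <- c(d2, rep(0, n - length(d2)))
  sum(abs(d1 - d2)) / 2
}

#' Mean carried types and mean host fitness under a type-count distribution
#'
#' @param dist Probability vector over `k = 0..length(dist)-1` carried types.
#' @param Delta Per-plasmid cost.
#' @param cost_model Cost combination rule, see [total_cost()].
#' @return List with `mean_types` (`E[k]`) and `mean_fitness`
#'   (`E[1 - Delta_tot(k)]`, the mean relative growth rate of hosts).
#' @export
mean_types_and_fitness <- function(dist, Delta,
                                   cost_model = c("multiplicative",
                                                  "additive")) {
  cost_model <- match.arg(cost_model)
  stopifnot(all(dist >= 0), abs(sum(dist) - 1) < 1e-8)
  k <- seq_along(dist) - 1
  list(mean_types = sum(k * dist),
       mean_fitness = sum((1 - total_cost(k, Delta, cost_model)) * dist))
}
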