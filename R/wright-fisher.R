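#' Epistasis specification for multiplasmid fitness costs
#'
#' Maps the number of unique plasmid types carried, `m`, to a total fitness
#' cost `Delta_tot(m)`:
#' \describe{
#'   \item{none}{independent (multiplicative) costs,
#'     `Delta_tot = 1 - (1 - Delta)^m`.}
#'   \item{positive}{sub-multiplicative burden: all plasmids beyond the
#'     first are free, `Delta_tot = Delta` for `m > 0`.}
#'   \item{negative}{super-multiplicative burden,
#'     `Delta_tot = 1 - (1 - Delta)^(m^(3/2))`.}
#'   \item{power}{tunable interpolation,
#'     `Delta_tot = 1 - (1 - Delta)^(m^a)`; `a = 1` is `none`, `a -> 0`
#'     approaches `positive`, `a = 3/2` is `negative`.}
#'   \item{custom}{arbitrary table or function of `m`.}
#' }
#'
#' @param form One of `"none"`, `"positive"`, `"negative"`, `"power"`,
#'   `"custom"`.
#' @param Delta Base per-plasmid cost in `[0, 1)`.
#' @param a Exponent for the `"power"` form.
#' @param custom_costs For `"custom"`: either a function `m -> Delta_tot(m)`
#'   or a numeric vector whose element `m + 1` is the cost at `m` (must
#'   start with 0 at `m = 0`).
#' @return An object of class `epistasis_spec`.
#' @export
#' @examples
#' epistasis_spec("positive", Delta = 0.01)
epistasis_spec <- function(form = c("none", "positive", "negative", "power",
                                    "custom"),
                           Delta = NULL, a = NULL, custom_costs = NULL) {
  form <- match.arg(form)
  if (form != "custom") {
    if (is.null(Delta) || Delta < 0 || Delta >= 1)
      stop("'Delta' in [0, 1) is required", call. = FALSE)
  }
  if (form == "power" && (is.null(a) || a < 0))
    stop("the 'power' form needs an exponent a >= 0", call. = FALSE)
  if (form == "custom") {
    if (is.null(custom_costs))
      stop("the 'custom' form needs 'custom_costs'", call. = FALSE)
    if (is.numeric(custom_costs) && custom_costs[1] != 0)
      stop("custom costs must be 0 at m = 0", call. = FALSE)
  }
  structure(list(form = form, Delta = Delta, a = a,
                 custom_costs = custom_costs),
            class = "epistasis_spec")
}

#' Total cost of m plasmid types under an epistasis specification
#'
#' @param m Plasmid-type counts (vectorized, >= 0).
#' @param spec An [epistasis_spec()].
#' @return `Delta_tot(m)` in `[0, 1]`, with `Delta_tot(0) = 0`.
#' @export
epistasis_cost <- function(m, spec) {
  stopifnot(inherits(spec, "epistasis_spec"), all(m >= 0))
  out <- switch(spec$form,
    none = 1 - (1 - spec$Delta)^m,
    positive = ifelse(m > 0, spec$Delta, 0),
    negative = 1 - (1 - spec$Delta)^(m^1.5),
    # m = 0 carries no cost for any exponent (0^0 would say otherwise);
    # at a = 0 the form is exactly the constant-cost (positive) limit
    power = ifelse(m == 0, 0, 1 - (1 - spec$Delta)^(m^spec$a)),
    custom = {
      if (is.function(spec$custom_costs)) spec$custom_costs(m)
      else {
        if (any(m + 1 > length(spec$custom_costs)))
          stop("custom cost table has no entry for m = ",
               max(m), call. = FALSE)
        spec$custom_costs[m + 1]
      }
    })
  if (any(out < 0 | out > 1))
    stop("epistasis costs must lie in [0, 1]", call. = FALSE)
  out
}

#' Population fitness given carried plasmid types
#'
#' @inheritParams epistasis_cost
#' @param i Plasmid-type counts (vectorized).
#' @return `w_i = 1 - Delta_tot(i)`.
#' @export
#' @examples
#' wf_fitness(0:5, epistasis_spec("positive", Delta = 0.01))
wf_fitness <- function(i, spec) 1 - epistasis_cost(i, spec)

#' Per-epoch resampling probabilities of the metapopulation model
#'
#' One Wright-Fisher epoch replaces all `N` demes by `N` draws from a
#' multinomial whose category probabilities weight each plasmid-count class
#' by abundance and fitness, split between staying at `i` (no invasion,
#' probability `1 - q`) and arriving from `i - 1` via invasion:
#' \deqn{p_0 = n_0 w_0 (1-q) / \sum_j n_j w_j,\qquad
#'       p_i = (n_i w_i (1-q) + n_{i-1} w_{i-1} q) / \sum_j n_j w_j.}
#'
#' @param counts Nonnegative integer vector `n_0..n_imax` of demes carrying
#'   each number of plasmid types.
#' @param spec An [epistasis_spec()].
#' @param q Per-epoch plasmid invasion probability in `[0, 1)`. May also be
#'   a vector of length `length(counts)` giving `q_i` per current count
#'   (generalized model).
#' @return Probability vector over `i = 0..i_max + 1` (the last entry is
#'   mass invading past the current support); sums to 1.
#' @export
#' @examples
#' sp <- epistasis_spec("none", Delta = 0.01)
#' epoch_probabilities(c(1, 1), sp, q = 0.005)
epoch_probabilities <- function(counts, spec, q) {
  stopifnot(all(counts >= 0), all(q >= 0), all(q < 1))
  i_max <- length(counts) - 1L
  w <- wf_fitness(0:i_max, spec)
  if (length(q) == 1L) q <- rep(q, i_max + 1L)
  stopifnot(length(q) == i_max + 1L)
  wbar <- sum(counts * w)
  if (wbar <= 0)
    stop("no viable population: all n_j * w_j are zero", call. = FALSE)
  stay <- counts * w * (1 - q) / wbar
  invade <- counts * w * q / wbar
  c(stay, 0) + c(0, invade)
}

#' Simulate Wright-Fisher epochs of the plasmid metapopulation
#'
#' Each epoch synchronously replaces all `N` demes with one multinomial draw
#' of size `N` from [epoch_probabilities()]; mass invading beyond `i_max` is
#' folded back into `i_max` (with a one-time warning).
#'
#' @param N Number of demes.
#' @param epochs Number of epochs to simulate.
#' @param spec An [epistasis_spec()].
#' @param q Per-epoch invasion probability (scalar or per-count vector of
#'   length `i_max + 1`).
#' @param i_max Truncation cap on the per-deme type count (default 50).
#' @param init Initial counts `n_0..n_imax` summing to `N`; default all
#'   demes plasmid-free.
#' @param seed Optional seed for reproducibility (applied locally; the
#'   caller's RNG state is preserved).
#' @return Integer matrix `epochs x (i_max + 1)` of deme counts after each
#'   epoch (columns named `0..i_max`).
#' @export
simulate_epochs <- function(N, epochs, spec, q, i_max = 50, init = NULL,
                            seed = NULL) {
  stopifnot(N >= 1, epochs >= 1, i_max >= 1)
  if (is.null(init)) init <- c(N, rep(0L, i_max))
  if (length(init) != i_max + 1L || sum(init) != N)
    stop("'init' must have length i_max + 1 and sum to N", call. = FALSE)
  local_seed(seed)
  out <- matrix(0L, nrow = epochs, ncol = i_max + 1L,
                dimnames = list(NULL, 0:i_max))
  counts <- as.integer(init)
  warned <- FALSE
  qv <- if (length(q) == 1L) rep(q, i_max + 1L) else q
  for (e in seq_len(epochs)) {
    p <- epoch_probabilities(counts, spec, qv)
    draw <- stats::rmultinom(1L, N, p)[, 1L]
    if (draw[i_max + 2L] > 0L && !warned) {
      warning("type counts reached the truncation cap i_max = ", i_max,
              "; overflow folded into the top bin", call. = FALSE)
      warned <- TRUE
    }
    counts <- draw[seq_len(i_max + 1L)]
    counts[i_max + 1L] <- counts[i_max + 1L] + draw[i_max + 2L]
    out[e, ] <- counts
  }
  out
}

#' Stationary distribution of plasmid types per deme
#'
#' Deterministic (infinite-N) fixed point of the epoch resampling: with
#' `w_0 = 1`, the stationary frequencies obey the recursion
#' \deqn{f_i = f_{i-1}\, w_{i-1}\, q \,/\, ((1-q)(1 - w_i)),\quad i \ge 1,}
#' normalized over `0..i_max`. Under strongly positive epistasis
#' (constant cost) the consecutive ratio is constant and the distribution is
#' exponential-like; with no epistasis the ratios shrink with `i`, giving a
#' Poisson-like shape; negative epistasis thins the tail further.
#'
#' @param spec An [epistasis_spec()] with `Delta_tot(i) > 0` for all
#'   `i >= 1`.
#' @param q Invasion probability in `(0, 1)` (scalar); `q = 0` returns a
#'   point mass at 0.
#' @param i_max Truncation; `NULL` (default) grows the support until the
#'   tail mass beyond it is below `tail_tol`.
#' @param tail_tol Tail-mass tolerance for automatic truncation.
#' @return Object of class `wf_stationary`: list with `f` (named
#'   probabilities over `0..i_max`), `q`, `spec`.
#' @export
#' @examples
#' stationary_distribution(epistasis_spec("positive", Delta = 0.01),
#'                         q = 0.005)
stationary_distribution <- function(spec, q, i_max = NULL,
                                    tail_tol = 1e-10) {
  stopifnot(q >= 0, q < 1)
  if (q == 0) {
    f <- c(`0` = 1)
    return(structure(list(f = f, q = q, spec = spec),
                     class = "wf_stationary"))
  }
  auto <- is.null(i_max)
  if (auto) i_max <- 50
  repeat {
    i <- 1:i_max
    w <- wf_fitness(0:i_max, spec)
    if (any(w[-1] >= 1 - 1e-15))
      stop("Delta_tot(i) must be > 0 for all i >= 1: a cost-free class ",
           "has no stationary cap", call. = FALSE)
    ratio_num <- w[i] * q          # w_{i-1} q
    ratio_den <- (1 - q) * (1 - w[i + 1])
    log_f <- c(0, cumsum(log(ratio_num) - log(ratio_den)))
    if (max(log_f) == Inf || all(!is.finite(log_f)))
      stop("stationary recursion diverged; increase Delta relative to q",
           call. = FALSE)
    f <- exp(log_f - max(log_f))
    f <- f / sum(f)
    tail_ok <- f[i_max + 1] < tail_tol
    increasing_tail <- f[i_max + 1] > f[i_max]
    if (!auto || tail_ok) break
    if (increasing_tail && i_max >= 5000)
      stop("stationary tail does not decay (ratio >= 1); ",
           "increase Delta relative to q", call. = FALSE)
    if (i_max >= 100000)
      stop("stationary support exceeded 1e5 bins without tail convergence",
           call. = FALSE)
    i_max <- i_max * 4
  }
  names(f) <- 0:i_max
  structure(list(f = f, q = q, spec = spec), class = "wf_stationary")
}

#' @export
print.wf_stationary <- function(x, ...) {
  cat(sprintf("<wf_stationary: %s epistasis, q = %g, support 0..%d>\n",
              if (!is.null(x$spec$form)) x$spec$form else "generalized",
              if (is.function(x$q)) NA else x$q, length(x$f) - 1))
  print(utils::head(x$f, 10))
  invisible(x)
}

#' Stationary distribution with count-dependent cost and invasion
#'
#' Generalized fixed point where both the total fitness cost and the
#' invasion probability are arbitrary functions of the current type count:
#' \deqn{f_i = f_{i-1}\, w_{i-1}\, q_{i-1} \,/\,
#'       (w_0 (1-q_0) - w_i (1-q_i)),}
#' normalized. With constant `q` and an [epistasis_spec()] cost this reduces
#' exactly to [stationary_distribution()]. An exact geometric (pure
#' exponential) distribution results whenever the per-step ratio is constant
#' in `i` — e.g. when cost and invasion probability no longer depend on the
#' count beyond the first plasmid.
#'
#' @param cost_fn Function `i -> Delta_tot(i)` (vectorized, `cost_fn(0)`
#'   must be 0).
#' @param q_fn Function `i -> q_i` (vectorized, values in `[0, 1)`).
#' @param i_max Support cap (default 200).
#' @return A `wf_stationary` object (its `q` field holds `q_fn`).
#' @export
generalized_stationary_distribution <- function(cost_fn, q_fn, i_max = 200) {
  i_all <- 0:i_max
  w <- 1 - cost_fn(i_all)
  qi <- q_fn(i_all)
  stopifnot(all(w >= 0), all(w <= 1), all(qi >= 0), all(qi < 1))
  if (abs(w[1] - 1) > 1e-12)
    stop("cost_fn(0) must be 0", call. = FALSE)
  denom <- w[1] * (1 - qi[1]) - w[-1] * (1 - qi[-1])
  if (any(denom <= 0))
    stop("need w_0 (1 - q_0) > w_i (1 - q_i) for all i >= 1", call. = FALSE)
  steps <- w[-(i_max + 1)] * qi[-(i_max + 1)] / denom
  log_f <- c(0, cumsum(log(steps)))
  f <- exp(log_f - max(log_f))
  f <- f / sum(f)
  names(f) <- i_all
  structure(list(f = f, q = q_fn,
                 spec = list(form = "generalized", cost_fn = cost_fn)),
            class = "wf_stationary")
}

#' Consecutive-ratio diagnostics of a type-count distribution
#'
#' Computes the ratios `f_{i+1} / f_i` for `i >= 1` and flags whether they
#' are constant (maximum relative deviation from their geometric mean below
#' `tol`), the signature of an exponential tail.
#'
#' @param f A `wf_stationary` object or a probability vector over `0..n`.
#' @param tol Constancy tolerance (default 1e-9).
#' @return List with `ratios`, `geometric_mean`, `max_relative_deviation`,
#'   `constant` (logical).
#' @export
tail_ratio_diagnostics <- function(f, tol = 1e-9) {
  if (inherits(f, "wf_stationary")) f <- f$f
  pos <- f > 0
  if (sum(pos) < 3)
    stop("need at least 3 positive entries to diagnose tail ratios",
         call. = FALSE)
  idx <- which(pos)
  if (any(diff(idx) != 1))
    stop("positive support must be contiguous", call. = FALSE)
  fpos <- f[idx]
  # ratios between consecutive entries from the second positive bin on
  ratios <- fpos[-(1:2)] / fpos[-c(1, length(fpos))]
  if (!length(ratios))
    stop("support too short for tail ratios beyond the first bin",
         call. = FALSE)
  gm <- exp(mean(log(ratios)))
  dev <- max(abs(ratios / gm - 1))
  list(ratios = unname(ratios), geometric_mean = gm,
       max_relative_deviation = dev, constant = dev < tol)
}
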