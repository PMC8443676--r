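test_that("epistasis forms map type counts to the stated costs", {
  expect_equal(wf_fitness(0, epistasis_spec("negative", 0.5)), 1)
  expect_equal(wf_fitness(5, epistasis_spec("positive", 0.01)), 0.99)
  expect_equal(wf_fitness(4, epistasis_spec("negative", 0.05)), 0.95^8)
  expect_equal(wf_fitness(0:4, epistasis_spec("none", 0.1)),
               (1 - 0.1)^(0:4))
  # power form: a = 1 is no epistasis, a = 3/2 is the negative form,
  # a = 0 is the constant-cost (positive) limit
  m <- 0:6
  expect_equal(epistasis_cost(m, epistasis_spec("power", 0.07, a = 1)),
               epistasis_cost(m, epistasis_spec("none", 0.07)))
  expect_equal(epistasis_cost(m, epistasis_spec("power", 0.07, a = 1.5)),
               epistasis_cost(m, epistasis_spec("negative", 0.07)))
  expect_equal(epistasis_cost(m, epistasis_spec("power", 0.07, a = 0)),
               epistasis_cost(m, epistasis_spec("positive", 0.07)))
  # custom: table and function
  sp_tab <- epistasis_spec("custom", custom_costs = c(0, 0.1, 0.15))
  expect_equal(epistasis_cost(0:2, sp_tab), c(0, 0.1, 0.15))
  expect_error(epistasis_cost(3, sp_tab), "no entry")
  sp_fn <- epistasis_spec("custom", custom_costs = function(m) m / (m + 9))
  expect_equal(epistasis_cost(3, sp_fn), 0.25)
  expect_error(epistasis_spec("custom", custom_costs = c(0.1, 0.2)),
               "0 at m = 0")
})

test_that("epoch probabilities implement fitness-weighted resampling with invasion", {
  sp <- epistasis_spec("none", 0.01)
  # one deme at 0, one at 1: hand-computed probabilities
  p <- epoch_probabilities(c(1, 1), sp, q = 0.005)
  expect_equal(unname(p), c(0.995 / 1.99, 0.99005 / 1.99, 0.00495 / 1.99))
  expect_equal(round(unname(p), 6), c(0.5, 0.497513, 0.002487))
  # q = 0 and a single occupied class: point mass there
  p0 <- epoch_probabilities(c(0, 0, 5, 0), sp, q = 0)
  expect_equal(unname(p0), c(0, 0, 1, 0, 0))
  # probability vector for random inputs
  set.seed(11)
  for (i in 1:10) {
    counts <- rpois(8, 3)
    counts[1] <- counts[1] + 1
    pv <- epoch_probabilities(counts,
                              epistasis_spec("power", runif(1, 0.01, 0.3),
                                             a = runif(1, 0.1, 2)),
                              q = runif(1, 0, 0.5))
    expect_true(all(pv >= 0))
    expect_equal(sum(pv), 1)
  }
  expect_error(epoch_probabilities(c(0, 0), sp, q = 0.1), "no viable")
})

test_that("epoch simulation is reproducible, absorbing at q = 0, and neutral on average", {
  sp <- epistasis_spec("none", 0.01)
  a <- simulate_epochs(N = 50, epochs = 30, spec = sp, q = 0.02,
                       i_max = 10, seed = 99)
  b <- simulate_epochs(N = 50, epochs = 30, spec = sp, q = 0.02,
                       i_max = 10, seed = 99)
  expect_identical(a, b)
  expect_true(all(rowSums(a) == 50))
  # q = 0 from the all-plasmid-free state is absorbing
  z <- simulate_epochs(N = 40, epochs = 20, spec = sp, q = 0, i_max = 5,
                       seed = 1)
  expect_true(all(z[, 1] == 40))
  # neutral drift (equal fitness, q = 0) preserves expected counts
  spn <- epistasis_spec("none", 0)
  init <- c(60, 30, 10, 0)
  finals <- sapply(1:300, function(s)
    simulate_epochs(N = 100, epochs = 5, spec = spn, q = 0, i_max = 3,
                    init = init, seed = 1000 + s)[5, ])
  avg <- rowMeans(finals)
  # multinomial sd of the 5-epoch mean over 300 replicates is < 1.5 demes
  expect_lt(max(abs(avg - init)), 4.5)
})

test_that("the analytic stationary distribution is the fixed point of one epoch", {
  for (form in c("none", "positive", "negative")) {
    sp <- epistasis_spec(form, 0.01)
    st <- stationary_distribution(sp, q = 0.005)
    p <- epoch_probabilities(st$f, sp, q = 0.005)
    n <- length(st$f)
    expect_lt(max(abs(p[1:n] - st$f)), 1e-12)
    expect_lt(p[n + 1], 1e-9)  # negligible leak past the support
  }
})

test_that("stationary shapes: exponential, Poisson-like, and thin-tailed", {
  pos <- stationary_distribution(epistasis_spec("positive", 0.01),
                                 q = 0.005)
  td <- tail_ratio_diagnostics(pos)
  expect_true(td$constant)
  expect_equal(td$geometric_mean, 0.99 * 0.005 / (0.995 * 0.01),
               tolerance = 1e-12)
  expect_equal(round(td$geometric_mean, 6), 0.497487)

  none <- stationary_distribution(epistasis_spec("none", 0.01), q = 0.005)
  r_none <- none$f[-(1:2)] / none$f[-c(1, length(none$f))]
  expect_true(all(diff(r_none) < 0))  # Poisson-like decaying ratios
  expect_false(tail_ratio_diagnostics(none)$constant)

  neg <- stationary_distribution(epistasis_spec("negative", 0.01),
                                 q = 0.005)
  tail_mass <- sapply(list(pos, none, neg),
                      function(s) sum(s$f[-(1:4)]))
  expect_true(tail_mass[1] > tail_mass[2])
  expect_true(tail_mass[2] > tail_mass[3])
  # all stationary distributions arrest the runaway: finite mean
  for (s in list(pos, none, neg)) {
    expect_equal(sum(s$f), 1)
    expect_true(is.finite(sum(as.integer(names(s$f)) * s$f)))
  }

  expect_equal(unname(stationary_distribution(epistasis_spec("positive",
                                                             0.01),
                                              q = 0)$f), 1)
  # cost-free classes or dominant invasion have no stationary cap
  expect_error(stationary_distribution(
    epistasis_spec("custom",
                   custom_costs = function(m) rep(0, length(m))),
    q = 0.005),
    "cost-free|> 0")
  expect_error(stationary_distribution(epistasis_spec("positive", 0.001),
                                       q = 0.5), "does not decay")
})

test_that("stochastic epochs reproduce the analytic stationary distribution", {
  # many demes: the mean-field fixed point applies (at small N the
  # plasmid-free class can drift extinct and the population ratchets up)
  sp <- epistasis_spec("positive", 0.01)
  st <- stationary_distribution(sp, q = 0.005)
  for (s in 1:2) {
    cm <- simulate_epochs(N = 1e5, epochs = 3000, spec = sp, q = 0.005,
                          i_max = 50, seed = s)
    emp <- colSums(cm[1001:3000, ]); emp <- emp / sum(emp)
    expect_lt(tv_distance(emp, unname(st$f)), 0.02)
  }
})

test_that("the generalized stationary solver nests and extends the basic one", {
  sp <- epistasis_spec("positive", 0.01)
  st <- stationary_distribution(sp, q = 0.005, i_max = 60)
  gen <- generalized_stationary_distribution(
    function(i) epistasis_cost(i, sp), function(i) rep(0.005, length(i)),
    i_max = 60)
  expect_equal(gen$f, st$f, tolerance = 1e-12)

  # count-independent cost AND invasion beyond the first plasmid gives an
  # exact geometric distribution: q_0 = w q makes every step ratio equal
  w <- 0.99; q <- 0.005
  gg <- generalized_stationary_distribution(
    function(i) ifelse(i > 0, 1 - w, 0),
    function(i) ifelse(i == 0, w * q, q), i_max = 100)
  r <- gg$f[-1] / gg$f[-length(gg$f)]
  expect_lt(max(abs(r - r[1])), 1e-12)
  expect_equal(unname(gg$f), dgeom(0:100, 1 - r[[1]]) / pgeom(100, 1 - r[[1]]),
               tolerance = 1e-9)

  # invasion only from the plasmid-free class: support {0, 1}
  g01 <- generalized_stationary_distribution(
    function(i) ifelse(i > 0, 0.2, 0),
    function(i) ifelse(i == 0, 0.1, 0), i_max = 20)
  expect_equal(sum(g01$f[1:2]), 1)
  expect_error(generalized_stationary_distribution(
    function(i) rep(0, length(i)), function(i) rep(0.1, length(i))),
    "w_0")
})

test_that("tail-ratio diagnostics distinguish exponential from Poisson tails", {
  geo <- dgeom(0:30, 0.4)
  d <- tail_ratio_diagnostics(geo / sum(geo))
  expect_true(d$constant)
  expect_equal(d$max_relative_deviation, 0, tolerance = 1e-12)
  pois <- dpois(0:30, 2)
  expect_false(tail_ratio_diagnostics(pois / sum(pois))$constant)
  expect_error(tail_ratio_diagnostics(c(0.5, 0.5)), "3 positive")
})
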