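test_that("analytic Jacobians match central differences", {
  set.seed(3)
  for (i in 1:5) {
    st <- c(rho = runif(1, 0.1, 10), rho_p = runif(1, 0.1, 10),
            C = runif(1, 0.05, 1))
    p <- conjugation_params(Delta = runif(1, 0, 0.8),
                            gamma_c = runif(1, 0, 0.5),
                            p_ell = runif(1, 0, 0.3),
                            delta = runif(1, 0.05, 1), S = runif(1, 0.5, 2))
    J_num <- numeric_jacobian(function(x) conjugation_rhs(x, p), st)
    expect_equal(unname(dynamics_jacobian(st, p)), J_num,
                 tolerance = 1e-6)
    tp <- transformation_params(Delta = runif(1, 0, 0.8),
                                gamma_t = runif(1, 0, 0.5),
                                p_ell = runif(1, 0, 0.3),
                                delta = runif(1, 0.05, 1),
                                S = runif(1, 0.5, 2),
                                n_eff = runif(1, 0, 2),
                                delta_p = runif(1, 0.05, 1))
    stt <- c(st, P = runif(1, 0, 5))
    J_numt <- numeric_jacobian(function(x) transformation_rhs(x, tp), stt)
    expect_equal(unname(dynamics_jacobian(stt, tp)), J_numt,
                 tolerance = 1e-6)
  }
})

test_that("all returned equilibria zero the dynamics and balance nutrient", {
  params_list <- list(
    fig_conj(Delta = 0.5, gamma_c = 0.007),             # coexistence band
    fig_conj(Delta = 0.5, gamma_c = 0.02),              # plasmid-only
    fig_conj(Delta = 0.3, gamma_c = 0.0005),            # below threshold
    conjugation_params(Delta = 0.4, gamma_c = 0.006, p_ell = 0.05,
                       delta = 0.1, S = 1),             # finite loss
    fig_trans(Delta = 0.2, gamma_t = 0.014),            # bistable
    fig_trans(Delta = 0.2, gamma_t = 0.02))             # plasmid-only
  for (p in params_list) {
    eqs <- find_equilibria(p)
    expect_gte(length(eqs), 1)
    kinds <- vapply(eqs, function(e) e$kind, "")
    expect_true("no_plasmid" %in% kinds)
    for (e in eqs) {
      expect_lt(e$residual / max(abs(e$state), 1), 1e-10)
      st <- e$state
      balance <- p$S - p$alpha * st[["C"]] * st[["rho"]] -
        (1 - p$Delta) * p$alpha * st[["C"]] * st[["rho_p"]]
      expect_lt(abs(balance), 1e-8)
      expect_true(e$stability %in% c("stable", "unstable"))
    }
  }
})

test_that("the coexistence band holds three equilibria with the closed forms", {
  p <- fig_conj(Delta = 0.5, gamma_c = 0.007)
  eqs <- find_equilibria(p)
  kinds <- vapply(eqs, function(e) e$kind, "")
  expect_setequal(kinds, c("no_plasmid", "plasmid_only", "coexistence"))
  co <- eqs[[which(kinds == "coexistence")]]
  # closed form for p_ell = 0: C = S gamma / (alpha delta Delta)
  C_exp <- p$S * p$gamma_c / (p$alpha * p$delta * p$Delta)
  expect_equal(co$state[["C"]], C_exp, tolerance = 1e-9)
  expect_equal(co$state[["rho"]] + co$state[["rho_p"]], p$S / p$delta,
               tolerance = 1e-9)
  po <- eqs[[which(kinds == "plasmid_only")]]
  expect_equal(unname(po$state),
               c(0, p$S / p$delta, p$delta / ((1 - p$Delta) * p$alpha)))
  # without transfer, a costly lossless plasmid has no interior equilibrium
  p0 <- fig_conj(Delta = 0.5, gamma_c = 0)
  expect_false("coexistence" %in%
                 vapply(find_equilibria(p0), function(e) e$kind, ""))
})

test_that("plasmid-free stability flips exactly at the invasion threshold", {
  p <- fig_conj(Delta = 0.5, gamma_c = 0)
  gc_star <- conjugation_invasion_threshold(p)
  for (mult in c(0.5, 0.9, 1.1, 2)) {
    p$gamma_c <- mult * gc_star
    eqs <- find_equilibria(p)
    np <- eqs[[which(vapply(eqs, function(e) e$kind, "") == "no_plasmid")]]
    expect_identical(np$stability,
                     if (mult < 1) "stable" else "unstable")
  }
  tp <- fig_trans(Delta = 0.2, gamma_t = 0)
  gt_star <- transformation_invasion_threshold(tp)
  for (mult in c(0.9, 1.1)) {
    tp$gamma_t <- mult * gt_star
    eqs <- find_equilibria(tp)
    np <- eqs[[which(vapply(eqs, function(e) e$kind, "") == "no_plasmid")]]
    expect_identical(np$stability,
                     if (mult < 1) "stable" else "unstable")
  }
})

test_that("low-yield transformation admits bistability with a separatrix", {
  tp <- fig_trans(Delta = 0.2, gamma_t = 0.014, n_eff = 0.6)
  eqs <- find_equilibria(tp)
  kinds <- vapply(eqs, function(e) e$kind, "")
  stab <- vapply(eqs, function(e) e$stability, "")
  expect_identical(stab[kinds == "no_plasmid"], "stable")
  expect_identical(stab[kinds == "plasmid_only"], "stable")
  expect_identical(stab[kinds == "coexistence"], "unstable")
  # trajectories from the two sides of the separatrix diverge
  lo <- c(rho = 10, rho_p = 1e-6, C = 0.1, P = 0)
  hi <- c(rho = 1e-6, rho_p = 10, C = 0.25, P = 2)
  tr_lo <- integrate_dynamics(tp, lo, duration = 3000, step = 0.02,
                              record_every = 1e6)
  tr_hi <- integrate_dynamics(tp, hi, duration = 3000, step = 0.02,
                              record_every = 1e6)
  expect_lt(tr_lo$states[nrow(tr_lo$states), "rho_p"], 1e-7)
  expect_gt(tr_hi$states[nrow(tr_hi$states), "rho_p"], 9)
})

test_that("stability classification predicts long-run integration outcomes", {
  # spot-check basin membership across the three conjugation phases
  cases <- list(list(Delta = 0.5, gamma_c = 0.003, label = "no_plasmid"),
                list(Delta = 0.5, gamma_c = 0.007, label = "coexistence"),
                list(Delta = 0.5, gamma_c = 0.02, label = "plasmid_only"),
                list(Delta = 0.2, gamma_c = 0.0015, label = "no_plasmid"),
                list(Delta = 0.2, gamma_c = 0.0022, label = "coexistence"))
  for (cs in cases) {
    p <- fig_conj(Delta = cs$Delta, gamma_c = cs$gamma_c)
    eqs <- find_equilibria(p)
    stable <- eqs[vapply(eqs, function(e) e$stability == "stable", NA)]
    expect_length(stable, 1)
    expect_identical(stable[[1]]$kind, cs$label)
    x0 <- plasmid_free_equilibrium(p)
    x0["rho_p"] <- 1e-4 * x0[["rho"]]
    ss <- run_to_steady_state(p, x0, step = 0.02, tol = 1e-8)
    expect_lt(max(abs(ss - stable[[1]]$state)), 1e-4)
  }
})

test_that("phase diagrams tile the grid with ordered phases", {
  d_axis <- seq(0.15, 0.9, length.out = 10)
  g_axis <- 10^seq(-3.5, -0.5, length.out = 12)
  pd <- phase_diagram(fig_conj(), d_axis, g_axis)
  expect_false(any(is.na(pd$labels)))
  expect_false(any(pd$labels == "bistable"))
  ord <- c(no_plasmid = 1, coexistence = 2, plasmid_only = 3)
  for (i in seq_along(d_axis))
    expect_true(all(diff(ord[pd$labels[i, ]]) >= 0))
  df <- as.data.frame(pd)
  expect_equal(nrow(df), length(d_axis) * length(g_axis))

  pdt <- phase_diagram(fig_trans(), d_axis, g_axis)
  expect_false(any(is.na(pdt$labels)))
  expect_gt(sum(pdt$labels == "bistable"), 0)
})
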