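# Shared fixtures: the parameter regimes exercised throughout the suite.

# conjugation regime of the main phase diagram (dilute chemostat)
fig_conj <- function(Delta = 0.5, gamma_c = 0.01, p_ell = 0) {
  conjugation_params(alpha = 1, Delta = Delta, gamma_c = gamma_c,
                     p_ell = p_ell, delta = 0.1, S = 1)
}

# transformation regime with n_eff < 1 (bistability-capable)
fig_trans <- function(Delta = 0.5, gamma_t = 0.01, n_eff = 0.6,
                      p_ell = 0) {
  transformation_params(alpha = 1, Delta = Delta, gamma_t = gamma_t,
                        p_ell = p_ell, delta = 0.1, S = 1,
                        n_eff = n_eff, delta_p = 0.3)
}

# community regime of the multi-type steady-state distributions
fig_community <- function(m, Delta = 0.1, gamma_c = 0, p_ell = 0.05) {
  community_params(m = m, Delta = Delta, gamma_c = gamma_c, p_ell = p_ell,
                   delta = 1, S = 1, alpha = 1)
}

# central-difference numeric Jacobian, the oracle for the analytic one
numeric_jacobian <- function(f, x, h = 1e-6) {
  n <- length(x)
  J <- matrix(0, length(f(x)), n)
  for (j in seq_len(n)) {
    e <- numeric(n); e[j] <- h
    J[, j] <- (f(x + e) - f(x - e)) / (2 * h)
  }
  J
}

# small assembly-table fixture written to a temp file
write_fixture_table <- function(rows, path = tempfile(fileext = ".tsv")) {
  header <- "assembly_accession\treplicon_name\treplicon_role\tlength_bp\tgenus"
  writeLines(c(header, rows), path)
  path
}
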