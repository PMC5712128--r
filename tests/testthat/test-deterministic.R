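test_that("dimerization flux cancels in the total-protein balance", {
  rc <- rate_constants(r_g_scale = 2e-3)
  cc <- cell_cycle_params(40)
  s <- deterministic_state(0.7, 0.4, 3, 1, 50, 20, 40, 9)
  dy <- ode_rhs(s, rc, cc)
  er <- effective_rates(rc, cc, volume = 2 * volume_at_age(cc, 0))
  dil <- log(2) / (cc$T * 60)
  for (g in c("ori", "ter")) {
    tot <- s[[paste0("P_", g)]] + 2 * s[[paste0("D_", g)]]
    expect_equal(dy[[paste0("P_", g)]] + 2 * dy[[paste0("D_", g)]],
                 er$k_p * s[[paste0("M_", g)]] - dil * tot)
  }
})

test_that("uncoupled steady state matches the closed-form solution", {
  rc <- rate_constants(r_g_scale = 0)
  for (Tm in c(20, 40, 120)) {
    cc <- cell_cycle_params(Tm)
    er <- effective_rates(rc, cc, volume = 2 * volume_at_age(cc, 0))
    dil <- log(2) / (cc$T * 60)
    ss <- relax_to_steady_state(deterministic_state(), rc, cc)
    expect_true(attr(ss, "converged"))
    loci <- default_loci()
    for (g in c("ori", "ter")) {
      S <- mean_copies(loci[[g]], cc)
      M <- S * er$k_m / (er$r_m + dil)
      # quadratic for P from the monomer/dimer balance
      a <- er$k_d * dil / (er$r_d + dil)
      P <- (-dil + sqrt(dil^2 + 4 * a * er$k_p * M)) / (2 * a)
      D <- (er$k_d / 2) * P^2 / (er$r_d + dil)
      expect_equal(ss[[paste0("G_", g)]], 1, tolerance = 1e-8)
      expect_equal(ss[[paste0("M_", g)]], M, tolerance = 1e-6)
      expect_equal(ss[[paste0("P_", g)]], P, tolerance = 1e-5)
      expect_equal(ss[[paste0("D_", g)]], D, tolerance = 1e-5)
    }
  }
})

test_that("strong repression sustains two distinct steady states at T = 40", {
  rc <- rate_constants(r_g_scale = 3.5e-3)
  cc <- cell_cycle_params(40)
  up <- relax_to_steady_state(deterministic_state(1, 1, 10, 0, 200, 0, 100, 0),
                              rc, cc)
  dn <- relax_to_steady_state(deterministic_state(1, 1, 0, 10, 0, 200, 0, 100),
                              rc, cc)
  expect_true(attr(up, "converged") && attr(dn, "converged"))
  expect_gt(log2(state_protein_ratio(up)), 1)
  expect_lt(log2(state_protein_ratio(dn)), -1)
})

test_that("state constructor normalizes and validates", {
  s <- deterministic_state(G_ori = 0.5, P_ori = c(a = 10))
  expect_named(s, c("G_ori", "G_ter", "M_ori", "M_ter",
                    "P_ori", "P_ter", "D_ori", "D_ter"))
  expect_equal(s[["P_ori"]], 10)
  expect_error(deterministic_state(G_ori = 1.5), "0, 1")
  expect_error(deterministic_state(P_ori = -1), ">= 0")
  expect_equal(state_protein_ratio(deterministic_state(P_ori = 10, D_ori = 5,
                                                       P_ter = 4, D_ter = 3)),
               2)
})
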