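test_that("effective_kobs follows the rapid pre-equilibrium formula", {
  expect_equal(effective_kobs(rate_constants(0, 1, 5)), 5)  # K_H = 0
  expect_equal(effective_kobs(rate_constants(2, 1, 3)), 1)  # K_H = 2
  expect_error(effective_kobs(rate_constants(1, 0, 3)), "infinite")
  # monotone: decreasing in k_H, increasing in k_on_L
  kH <- seq(0, 20, by = 0.5)
  v <- vapply(kH, function(k) effective_kobs(rate_constants(k, 2, 7)),
              numeric(1))
  expect_true(all(diff(v) < 0))
  kon <- seq(0.1, 10, by = 0.1)
  v2 <- vapply(kon, function(k) effective_kobs(rate_constants(3, 2, k)),
               numeric(1))
  expect_true(all(diff(v2) > 0))
  # rates_from_kobs inverts it
  for (kobs in c(0.12, 0.34, 1.75)) {
    expect_equal(effective_kobs(rates_from_kobs(kobs, K_H = 9)), kobs)
  }
})

test_that("pseudo-first-order closed forms behave at limits and at the
           published WT_ox rate", {
  expect_equal(pseudo_first_order_bound_fraction(1.75, 0, 5e-4, 0, "paper"), 0)
  expect_equal(
    pseudo_first_order_bound_fraction(1.75, 0, 5e-4, 0, "reversible"), 0)
  t <- seq(0, 5e4, length.out = 11)
  expect_equal(
    pseudo_first_order_bound_fraction(1.75, 0, 5e-4, t, "reversible"),
    pseudo_first_order_bound_fraction(1.75, 0, 5e-4, t, "paper"))
  # kobs = 1.75 /M/s at 500 uM: time constant 1/(kobs L) ~ 1143 s ~ 19 min
  tau <- 1 / (1.75 * 500e-6)
  expect_equal(tau, 1142.857, tolerance = 1e-4)
  expect_equal(tau / 60, 19.0, tolerance = 0.005)
  expect_equal(
    pseudo_first_order_bound_fraction(1.75, 0, 500e-6, tau, "paper"),
    1 - exp(-1))
})

test_that("mass_action_rhs implements the scheme and conserves matter", {
  cfg <- single_isomer_config(kobs = 2, K_H = 4)
  st <- initial_state(cfg)
  # no open channel: all-hexa with k_minus_H = 0
  cfg0 <- simulation_config(
    isomer_spec("A", 1e-6, rate_constants(1, 0, 5)), 5e-4, 100)
  d0 <- mass_action_rhs(initial_state(cfg0), cfg0)
  expect_equal(unname(unlist(d0)), rep(0, 4))
  # bound derivative is the mass-action definition
  r <- cfg$isomers[[1]]$rates
  p <- 3e-7; b <- 2e-7; L <- 4e-4
  st2 <- system_state(0, hexa = c(WT_ox.A = 5e-7), penta = c(WT_ox.A = p),
                      bound = c(WT_ox.A = b), ligand_free = L)
  d <- mass_action_rhs(st2, cfg)
  expect_equal(unname(d$bound), r$k_on_L * p * L - r$k_off_L * b)
  # conservation by construction, over random states
  set.seed(11)
  for (i in 1:25) {
    y <- runif(3, 0, 1e-4)
    sti <- system_state(0, hexa = c(WT_ox.A = y[1]),
                        penta = c(WT_ox.A = y[2]),
                        bound = c(WT_ox.A = y[3]),
                        ligand_free = runif(1, 0, 1e-3))
    di <- mass_action_rhs(sti, cfg)
    expect_equal(unname(di$hexa + di$penta + di$bound), 0)
    expect_equal(unname(di$ligand_free), -sum(di$bound))
  }
  # unknown isomer and negative concentrations are rejected
  stX <- system_state(0, hexa = c(TM.B = 1e-6), penta = c(TM.B = 0),
                      bound = c(TM.B = 0), ligand_free = 0)
  expect_error(mass_action_rhs(stX, cfg), "do not match")
  expect_error(system_state(0, hexa = c(WT_ox.A = -1e-9),
                            penta = c(WT_ox.A = 0), bound = c(WT_ox.A = 0),
                            ligand_free = 0),
               "negative")
})

test_that("reoxidation transfers reduced to oxidised protein but keeps
           orientation totals", {
  mk <- function(tag, tot) {
    isomer_spec("A", tot, rates_from_kobs(0.3, k_off_L = 1e-4), tag)
  }
  cfg <- simulation_config(
    list(mk("WT_red", 60e-6), mk("WT_ox", 40e-6)),
    ligand_total = 500e-6, duration = 3600,
    output_times = seq(0, 3600, length.out = 13),
    reoxidation_tau = 3600)
  tr <- integrate_kinetics(cfg)
  red_tot <- tr$hexa.WT_red.A + tr$penta.WT_red.A + tr$bound.WT_red.A
  ox_tot <- tr$hexa.WT_ox.A + tr$penta.WT_ox.A + tr$bound.WT_ox.A
  expect_true(all(diff(red_tot) < 0))
  expect_true(all(diff(ox_tot) > 0))
  expect_equal(red_tot + ox_tot, rep(100e-6, 13), tolerance = 1e-8)
  # after one tau, roughly 1/e of the reduced protein remains
  expect_equal(red_tot[13] / red_tot[1], exp(-1), tolerance = 0.01)
  # a reduced isomer without its oxidised partner is a config error
  expect_error(
    simulation_config(list(mk("WT_red", 60e-6)), 5e-4, 100,
                      reoxidation_tau = 3600),
    "matching oxidised")
})

test_that("integration matches the closed form when binding is
           effectively irreversible and ligand is in excess", {
  cfg <- single_isomer_config(kobs = 2, K_H = 9, total = 1e-9,
                              ligand = 500e-6, duration = 4000)
  tr <- integrate_kinetics(cfg)
  kobs <- effective_kobs(cfg$isomers[[1]]$rates)
  expected <- 1 - exp(-kobs * 500e-6 * tr$time_s)
  got <- tr$bound.WT_ox.A / 1e-9
  expect_true(all(abs(got - expected) <= 0.01 * pmax(expected, 1e-6)))
})

test_that("zero-duration integration returns the initial state", {
  cfg <- simulation_config(
    isomer_spec("A", 1e-6, rates_from_kobs(1)), 5e-4,
    duration = 0, output_times = 0)
  tr <- integrate_kinetics(cfg)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$hexa.WT_ox.A, 1e-6)
  expect_equal(tr$ligand_free, 5e-4)
})

test_that("long-time ODE state agrees with the equilibrium solver", {
  cfg <- simulation_config(
    list(isomer_spec("A", 33.3e-6,
                     rates_from_kobs(0.26, k_off_L = 153e-6 * 0.26),
                     "WT_red"),
         isomer_spec("B", 66.7e-6,
                     rates_from_kobs(0.12, k_off_L = 316e-6 * 0.12),
                     "WT_red")),
    ligand_total = 500e-6, duration = 5e5, output_times = c(0, 5e5))
  tr <- integrate_kinetics(cfg)
  eq <- solve_equilibrium(induced_equilibrium_spec(cfg))
  expect_equal(tr$bound.WT_red.A[2], unname(eq$bound["WT_red.A"]),
               tolerance = 1e-3)
  expect_equal(tr$bound.WT_red.B[2], unname(eq$bound["WT_red.B"]),
               tolerance = 1e-3)
  expect_equal(tr$ligand_free[2], eq$ligand_free, tolerance = 1e-3)
})

test_that("trajectories conserve protein and ligand and are
           deterministic", {
  set.seed(4)
  for (i in 1:5) {
    cfg <- simulation_config(
      list(isomer_spec("A", runif(1, 1e-6, 1e-4),
                       rates_from_kobs(runif(1, 0.1, 2), K_H = runif(1, 1, 20),
                                       k_off_L = runif(1, 0, 1e-4))),
           isomer_spec("B", runif(1, 1e-6, 1e-4),
                       rates_from_kobs(runif(1, 0.1, 2), K_H = runif(1, 1, 20),
                                       k_off_L = runif(1, 0, 1e-4)))),
      ligand_total = runif(1, 1e-4, 1e-3), duration = 36000,
      output_times = seq(0, 36000, length.out = 25))
    tr <- integrate_kinetics(cfg)
    prot_A <- tr$hexa.WT_ox.A + tr$penta.WT_ox.A + tr$bound.WT_ox.A
    prot_B <- tr$hexa.WT_ox.B + tr$penta.WT_ox.B + tr$bound.WT_ox.B
    lig <- tr$ligand_free + tr$bound.WT_ox.A + tr$bound.WT_ox.B
    expect_lt(max(abs(prot_A / prot_A[1] - 1)), 1e-8)
    expect_lt(max(abs(prot_B / prot_B[1] - 1)), 1e-8)
    expect_lt(max(abs(lig / lig[1] - 1)), 1e-8)
    tr2 <- integrate_kinetics(cfg)
    expect_identical(as.data.frame(tr), as.data.frame(tr2))
  }
})

test_that("solve_equilibrium handles trivial and excess-ligand cases", {
  # no ligand: everything free
  sp0 <- equilibrium_spec(
    data.frame(label = "x", total_conc = 1e-5, K_d = 1e-4), 0)
  s0 <- solve_equilibrium(sp0)
  expect_equal(s0$ligand_free, 0)
  expect_equal(unname(s0$bound), 0)
  # trace protein in excess ligand follows the simple isotherm
  sp1 <- equilibrium_spec(
    data.frame(label = "x", total_conc = 1e-9, K_d = 2e-4), 5e-4)
  s1 <- solve_equilibrium(sp1)
  expect_equal(unname(s1$bound) / 1e-9, 5e-4 / (5e-4 + 2e-4),
               tolerance = 0.01)
})

test_that("solve_equilibrium matches a dense grid scan on the two-isomer
           depletion problem", {
  tot <- c(33.3e-6, 66.7e-6)
  kd <- c(153e-6, 316e-6)
  sp <- equilibrium_spec(
    data.frame(label = c("A", "B"), total_conc = tot, K_d = kd), 500e-6)
  sol <- solve_equilibrium(sp)
  # independent single-pass dense scan (1e6 + 1 points)
  Lg <- seq(0, 500e-6, length.out = 1e6 + 1)
  gg <- Lg + tot[1] * Lg / (Lg + kd[1]) + tot[2] * Lg / (Lg + kd[2])
  Lstar <- Lg[which.min(abs(gg - 500e-6))]
  expect_equal(signif(sol$ligand_free, 4), signif(Lstar, 4))
  # frozen values from the same oracle
  expect_equal(sol$ligand_free, 4.366448e-4, tolerance = 1e-6)
  expect_equal(unname(sol$bound), c(2.465937e-5, 3.869582e-5),
               tolerance = 1e-6)
  # conservation
  expect_equal(sol$ligand_free + sum(sol$bound), 500e-6, tolerance = 1e-9)
})

test_that("solve_equilibrium equals the grid-scan oracle over random
           specifications", {
  set.seed(99)
  for (i in 1:100) {
    n <- sample(1:4, 1)
    tot <- runif(n, 1e-7, 2e-4)
    kd <- 10^runif(n, -6, -2)
    Ltot <- runif(1, 1e-6, 2e-3)
    sp <- equilibrium_spec(
      data.frame(label = paste0("s", 1:n), total_conc = tot, K_d = kd),
      Ltot)
    sol <- solve_equilibrium(sp)
    oracle <- grid_scan_equilibrium(tot, kd, Ltot)
    expect_equal(signif(sol$ligand_free, 4), signif(oracle, 4))
  }
})

test_that("effective_kobs agrees with the ODE-fitted rate in the rapid
           pre-equilibrium regime", {
  # k_on_L * [L] = 2e-3 /s << min(k_H, k_minus_H) = 10 /s
  r <- rate_constants(k_H = 50, k_minus_H = 10, k_on_L = 20)
  kobs <- effective_kobs(r)
  L <- 100e-6
  cfg <- simulation_config(isomer_spec("A", 1e-9, r), ligand_total = L,
                           duration = 5 / (kobs * L),
                           output_times = seq(0, 5 / (kobs * L),
                                              length.out = 40))
  tr <- integrate_kinetics(cfg)
  bf <- tr$bound.WT_ox.A / 1e-9
  ts <- tr$time_s
  fit <- stats::nls(bf ~ 1 - exp(-k * ts), start = list(k = kobs * L))
  expect_equal(unname(coef(fit)) / L, kobs, tolerance = 0.05)
})

test_that("trajectory CSV export round-trips", {
  cfg <- single_isomer_config(duration = 1000, n_out = 6)
  tr <- integrate_kinetics(cfg)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, f)
  df <- read_trajectory(f)
  expect_setequal(unique(df$species),
                  c("hexa", "penta", "bound", "ligand_free"))
  b <- df[df$species == "bound" & df$isomer == "A", ]
  b <- b[order(b$time_min), ]
  expect_equal(b$conc_M, tr$bound.WT_ox.A)
  expect_equal(b$time_min, tr$time_s / 60)
})
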