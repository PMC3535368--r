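# shared fixture builders: everything is generated in code at test time

# the canonical two-peak met spectrum: B:A = 2:1 populations
two_peak_table <- function() {
  rbind(peak_def("M8B", 35.4, "WT_ox:met-B"),
        peak_def("M5A", 34.5, "WT_ox:met-A"))
}

two_peak_conc <- function() {
  c("WT_ox:met-B" = 66.7e-6, "WT_ox:met-A" = 33.3e-6)
}

# single-isomer configuration with an effectively irreversible step
single_isomer_config <- function(kobs = 2, K_H = 9, k_off_L = 0,
                                 total = 1e-6, ligand = 500e-6,
                                 duration = 2000, n_out = 21) {
  simulation_config(
    isomer_spec("A", total, rates_from_kobs(kobs, K_H = K_H,
                                            k_off_L = k_off_L)),
    ligand_total = ligand, duration = duration,
    output_times = seq(0, duration, length.out = n_out))
}

# independent brute-force equilibrium oracle: bisection-free grid scan of
# the ligand-conservation function (coarse pass + local refinement)
grid_scan_equilibrium <- function(tot, kd, ligand_total,
                                  n_coarse = 1e4, n_fine = 1e4) {
  g <- function(L) {
    vapply(L, function(l) l + sum(tot * l / (l + kd)), numeric(1))
  }
  L1 <- seq(0, ligand_total, length.out = n_coarse)
  i <- which.min(abs(g(L1) - ligand_total))
  lo <- L1[max(1, i - 1)]
  hi <- L1[min(n_coarse, i + 1)]
  L2 <- seq(lo, hi, length.out = n_fine)
  L2[which.min(abs(g(L2) - ligand_total))]
}

# noiseless monoexponential decay sampled like the NMR schedule
synthetic_decay <- function(T_min = 19, plateau = 0, duration = 300,
                            interval = 20, I0 = 1) {
  t <- seq(0, duration, by = interval)
  time_course(t, plateau + (I0 - plateau) * exp(-t / T_min), "decay")
}
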