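#' Peak-intensity time course for one resonance
#'
#' @param times Acquisition times, minutes, strictly increasing, >= 4
#'   points.
#' @param intensities Peak intensities or volumes, arbitrary units.
#' @param direction `"decay"` (unbound-protein resonance vanishing) or
#'   `"buildup"` (bound-protein resonance growing).
#' @param label Resonance name.
#' @param state Protein state tag.
#' @param isomer `"A"` or `"B"`.
#' @return An object of class `"time_course"`.
#' @export
time_course <- function(times, intensities, direction = c("decay", "buildup"),
                        label = "", state = "", isomer = "") {
  direction <- match.arg(direction)
  stopifnot(length(times) == length(intensities), length(times) >= 4L,
            all(diff(times) > 0))
  structure(list(times = as.numeric(times),
                 intensities = as.numeric(intensities),
                 direction = direction, label = label,
                 state = state, isomer = isomer),
            class = "time_course")
}

#' @export
print.time_course <- function(x, ...) {
  cat(sprintf("time course %s [%s %s, %s]: %d points, %.0f..%.0f min\n",
              x$label, x$state, x$isomer, x$direction, length(x$times),
              min(x$times), max(x$times)))
  invisible(x)
}

#' Fit a monoexponential to a peak-intensity time course
#'
#' Least-squares fit of
#' \deqn{I(t) = \mathrm{plateau} + (I_0 - \mathrm{plateau})\,e^{-t/T}}
#' with \eqn{I_0} the intensity at t = 0 (decay: \eqn{I_0 >} plateau;
#' buildup: \eqn{I_0 <} plateau).  Initial guesses come from a log-linear
#' regression on plateau-subtracted intensities, with the mean of the
#' last 10% of points as the plateau estimate.
#'
#' @param tc A [time_course()].
#' @return An object of class `"exp_fit"`: `T` (time constant, minutes),
#'   `I0`, `plateau`, `amplitude` (`I0 - plateau`), `rss`, `n`, plus the
#'   source metadata.
#' @section Errors: a series with no resolvable exponential component
#'   (constant input, or fitted amplitude indistinguishable from zero)
#'   and non-convergent or non-positive-T fits raise errors.
#' @export
fit_monoexponential <- function(tc) {
  stopifnot(inherits(tc, "time_course"))
  t <- tc$times
  y <- tc$intensities
  if (stats::sd(y) == 0) {
    stop("fit error: constant intensity series has no exponential component")
  }
  n_tail <- max(2L, ceiling(0.1 * length(y)))
  plateau0 <- mean(tail(y, n_tail))
  z <- if (tc$direction == "decay") y - plateau0 else plateau0 - y
  # log-linear initial guess, restricted to points clearly above the
  # residual noise floor so that decayed tails do not flatten the slope
  pos <- z > 0.05 * max(z)
  T_range <- diff(range(t))
  if (sum(pos) >= 3L) {
    ll <- stats::lm(log(z[pos]) ~ t[pos])
    T0 <- unname(-1 / coef(ll)[2])
    amp0 <- unname(exp(coef(ll)[1])) * if (tc$direction == "decay") 1 else -1
  } else {
    T0 <- T_range / 3
    amp0 <- y[1] - plateau0
  }
  if (!is.finite(T0) || T0 <= 0 || T0 > 100 * T_range) T0 <- T_range / 3
  if (!is.finite(amp0) || amp0 == 0) amp0 <- y[1] - plateau0

  do_fit <- function(p0, a0, T0) {
    minpack.lm::nlsLM(
      y ~ plateau + amp * exp(-t / Tc),
      start = list(plateau = p0, amp = a0, Tc = T0),
      lower = c(plateau = -Inf, amp = -Inf, Tc = 1e-9),
      control = minpack.lm::nls.lm.control(maxiter = 500))
  }
  fit <- tryCatch(
    do_fit(plateau0, amp0, T0),
    error = function(e) tryCatch(
      do_fit(plateau0, y[1] - plateau0, T_range / 3),
      error = function(e2) {
        stop("fit error: monoexponential fit did not converge (",
             conditionMessage(e2), ")")
      }))
  p <- coef(fit)
  if (!is.finite(p["Tc"]) || p["Tc"] <= 0) {
    stop("fit error: non-positive time constant")
  }
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  scale <- max(abs(y))
  amp_se <- se["amp"]
  if (abs(p["amp"]) < 1e-6 * scale ||
      (is.finite(amp_se) && abs(p["amp"]) < 2 * amp_se)) {
    stop("fit error: amplitude indistinguishable from zero ",
         "(no exponential component)")
  }
  structure(list(T = unname(p["Tc"]),
                 plateau = unname(p["plateau"]),
                 amplitude = unname(p["amp"]),
                 I0 = unname(p["plateau"] + p["amp"]),
                 rss = sum(resid(fit)^2),
                 se_T = unname(se["Tc"]),
                 n = length(y),
                 direction = tc$direction, label = tc$label,
                 state = tc$state, isomer = tc$isomer),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf(
    "monoexponential fit %s [%s %s]: T = %.4g min, I0 = %.4g, plateau = %.4g\n",
    x$label, x$state, x$isomer, x$T, x$I0, x$plateau))
  invisible(x)
}

#' Second-order rate constant from a fitted time constant
#'
#' Under the pseudo-first-order convention `1/T = k_obs * [L]`, a time
#' constant `T` (minutes) observed at ligand concentration `L` (molar)
#' gives
#' \deqn{k_{obs} = \frac{1}{T \cdot 60 \cdot L} \quad
#'   [\mathrm{M^{-1} s^{-1}}].}
#'
#' @param T_min Time constant, minutes (> 0).
#' @param ligand_conc Ligand concentration, molar (> 0).
#' @return Second-order rate constant, per molar per second.
#' @examples
#' kobs_from_time_constant(19, 500e-6)   # 1.75 /M/s at 2 decimals
#' @export
kobs_from_time_constant <- function(T_min, ligand_conc) {
  stopifnot(all(T_min > 0), all(ligand_conc > 0))
  1 / (T_min * 60 * ligand_conc)
}

#' Dissociation constant from the equilibrium free fraction
#'
#' Inverts the single-site isotherm: if a fraction `free_fraction` of the
#' protein remains unbound at equilibrium in the presence of free ligand
#' `L`, then
#' \deqn{K_d = \frac{f_{free}}{1 - f_{free}} \, L.}
#' `mode = "total"` takes `L` as the total ligand (free ligand
#' approximately equal to total, the convention of excess-ligand
#' analyses); `mode = "depleted"` subtracts the ligand bound to protein.
#'
#' @param free_fraction Fraction of protein unbound at equilibrium,
#'   strictly between 0 and 1.
#' @param ligand_total Total ligand, molar.
#' @param bound_total Total ligand sequestered in complexes, molar
#'   (used by `mode = "depleted"`).
#' @param mode `"total"` (default) or `"depleted"`.
#' @return Dissociation constant, molar.
#' @examples
#' kd_from_free_fraction(0.80, 500e-6)   # 2.0 mM
#' @export
kd_from_free_fraction <- function(free_fraction, ligand_total,
                                  bound_total = 0,
                                  mode = c("total", "depleted")) {
  mode <- match.arg(mode)
  if (any(free_fraction <= 0) || any(free_fraction >= 1)) {
    stop("free_fraction must lie strictly between 0 and 1 ",
         "(K_d undefined at the endpoints)")
  }
  stopifnot(ligand_total > bound_total, bound_total >= 0)
  L <- if (mode == "total") ligand_total else ligand_total - bound_total
  free_fraction / (1 - free_fraction) * L
}

#' Off-rate from dissociation constant and on-rate
#'
#' \eqn{k_{off} = K_d \cdot k_{obs}}.
#'
#' @param kd Dissociation constant, molar (> 0).
#' @param kobs Second-order association rate, per molar per second
#'   (>= 0).
#' @return First-order dissociation rate, per second.
#' @export
koff_from <- function(kd, kobs) {
  stopifnot(all(kd > 0), all(kobs >= 0))
  kd * kobs
}

#' Bootstrap uncertainty of the fitted time constant
#'
#' Residual-resampling bootstrap around the monoexponential fit: the
#' fitted curve is perturbed by residuals resampled with replacement and
#' refitted `n_boot` times.
#'
#' @param tc A [time_course()].
#' @param n_boot Number of bootstrap replicates (>= 100).
#' @param seed Integer RNG seed (deterministic output per seed).
#' @return A list: `T` (point estimate, minutes), `se_T`, `ci`
#'   (2.5%/97.5% quantiles), `n_failed`, `unstable` (`TRUE` when more
#'   than 20% of replicates failed, with a warning).
#' @export
bootstrap_uncertainty <- function(tc, n_boot = 200L, seed = 1L) {
  stopifnot(inherits(tc, "time_course"), n_boot >= 100L)
  base <- fit_monoexponential(tc)
  pred <- base$plateau + base$amplitude * exp(-tc$times / base$T)
  # leverage-corrected residuals: raw residuals of a p-parameter fit
  # underestimate the noise by sqrt((n - p)/n)
  n <- length(pred)
  res <- (tc$intensities - pred) * sqrt(n / max(n - 3, 1))

  old_seed <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  Ts <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    yb <- pred + sample(res, length(res), replace = TRUE)
    tb <- tc
    tb$intensities <- yb
    fb <- tryCatch(fit_monoexponential(tb), error = function(e) NULL)
    if (!is.null(fb)) Ts[b] <- fb$T
  }
  n_failed <- sum(is.na(Ts))
  unstable <- n_failed > 0.2 * n_boot
  if (unstable) {
    warning(sprintf("bootstrap unstable: %d/%d replicates failed",
                    n_failed, n_boot))
  }
  ok <- Ts[!is.na(Ts)]
  list(T = base$T,
       se_T = stats::sd(ok),
       ci = unname(quantile(ok, c(0.025, 0.975))),
       n_failed = n_failed, unstable = unstable)
}

# parse "WT_ox:met-A" -> list(state, ligation, isomer)
.parse_species_tag <- function(tag) {
  m <- regmatches(tag, regexec("^(.+):(met|cyanomet)-([AB])$", tag))[[1]]
  if (length(m) != 4L) stop("malformed species tag: ", tag)
  list(state = m[2], ligation = m[3], isomer = m[4])
}

#' Extract per-resonance time courses from a spectra series
#'
#' For each peak, the lineshape (centre and width) is first determined
#' by a full windowed Lorentzian fit ([quantify_peak()]) on the
#' reference spectrum of the series — the first spectrum for decaying
#' (met) resonances, the last for growing (cyanomet) resonances — and
#' every spectrum is then quantified with that shape held fixed, leaving
#' only the volume and a constant baseline as (linear) unknowns.  Fixing
#' the shape keeps the volume estimate well defined when the resonance
#' has decayed into the noise.  If the reference fit does not converge,
#' the peak table's nominal shift and width are used instead.
#'
#' @param spectra List of [nmr_spectrum()] with acquisition times set
#'   (e.g. from [generate_experiment()] or [read_spectra_series()]).
#' @param peaks A `"peak_table"` data frame.
#' @param window Quantification window, ppm (full width per peak).
#' @return A list of [time_course()], one per peak-table row.
#' @export
timecourses_from_spectra <- function(spectra, peaks, window = 0.4) {
  stopifnot(length(spectra) >= 4L)
  times <- vapply(spectra, `[[`, numeric(1), "time_min")
  ord <- order(times)
  spectra <- spectra[ord]
  times <- times[ord]
  lapply(seq_len(nrow(peaks)), function(i) {
    tg <- .parse_species_tag(peaks$species_tag[i])
    decay <- tg$ligation == "met"
    ref <- if (decay) spectra[[1]] else spectra[[length(spectra)]]
    rf <- quantify_peak(ref, peaks$shift_ppm[i], window)
    x0 <- if (rf$converged) rf$shift else peaks$shift_ppm[i]
    w <- if (rf$converged) rf$fwhm else peaks$fwhm_ppm[i]
    vols <- vapply(spectra, function(s) {
      .fixed_shape_volume(s, x0, w, peaks$shift_ppm[i], window)
    }, numeric(1))
    time_course(times, vols,
                direction = if (decay) "decay" else "buildup",
                label = peaks$label[i], state = tg$state,
                isomer = tg$isomer)
  })
}

# volume of a Lorentzian of known centre/width by linear least squares
# (volume + constant baseline) within the window
.fixed_shape_volume <- function(spectrum, x0, fwhm, centre, window) {
  sel <- spectrum$ppm >= centre - window / 2 &
    spectrum$ppm <= centre + window / 2
  x <- spectrum$ppm[sel]
  y <- spectrum$intensity[sel]
  f <- .lorentzian(x, x0, fwhm)
  X <- cbind(1, f)
  unname(stats::lm.fit(X, y)$coefficients[2])
}

#' Assemble a binding report from time courses or a spectra series
#'
#' Runs the full quantitative chain of the real-time binding analysis:
#' (spectra are first reduced to per-resonance time courses), decay
#' intensities are normalised to their t = 0 value and fitted to
#' monoexponentials; each fitted time constant is converted to a
#' second-order rate with `1/T = k_obs [L]`; when the decay plateau
#' indicates incomplete binding the equilibrium free fraction
#' (plateau / initial intensity) is inverted to a dissociation constant
#' and `k_off = K_d k_obs`.  One report row is produced per
#' state/orientation; the headline time constant comes from the decay
#' (unbound-protein) resonance, with buildup fits reported alongside.
#'
#' @param x An `"nmr_experiment"`, a list of [nmr_spectrum()] (then
#'   `peaks` is required), or a list of [time_course()] objects.
#' @param ligand_conc Ligand concentration, molar (taken from the
#'   experiment's configuration when `x` is an `"nmr_experiment"`).
#' @param mode `"paper"`: `k_obs = 1/(T 60 L)` regardless of plateau
#'   (rate and equilibrium treated separately).  `"reversible"`: the
#'   observed rate is split as `1/(T 60) = k_obs L + k_off` using the
#'   equilibrium free fraction, so `k_obs = (1 - f_free)/(T 60 L)` and
#'   `k_off = f_free/(T 60)` (identical to `"paper"` when binding is
#'   complete).
#' @param kd_mode Ligand convention for the K_d inversion, see
#'   [kd_from_free_fraction()].
#' @param peaks,window Passed to [timecourses_from_spectra()] when `x`
#'   holds spectra.
#' @param plateau_threshold Minimum plateau/initial ratio treated as
#'   genuine incomplete binding rather than fit noise (default 0.05).
#' @return An object of class `"binding_report"`: a data frame with one
#'   row per state/orientation and columns `state, isomer, T_min,
#'   se_T_min, k_obs, free_fraction_eq, K_d_M, k_off, mode,
#'   resonance, note`, with the A/B ratio table from [ratio_report()]
#'   attached as attribute `"ratios"` and all buildup fits as attribute
#'   `"buildup_fits"`.
#' @export
build_table <- function(x, ligand_conc = NULL,
                        mode = c("paper", "reversible"),
                        kd_mode = c("total", "depleted"),
                        peaks = NULL, window = 0.4,
                        plateau_threshold = 0.05) {
  mode <- match.arg(mode)
  kd_mode <- match.arg(kd_mode)
  if (inherits(x, "nmr_experiment")) {
    if (is.null(ligand_conc)) ligand_conc <- x$config$ligand_total
    tcs <- timecourses_from_spectra(x$spectra, x$peaks, window)
  } else if (is.list(x) && length(x) &&
             inherits(x[[1]], "nmr_spectrum")) {
    if (is.null(peaks)) stop("'peaks' is required with a bare spectra list")
    tcs <- timecourses_from_spectra(x, peaks, window)
  } else if (is.list(x) && length(x) &&
             inherits(x[[1]], "time_course")) {
    tcs <- x
  } else if (inherits(x, "time_course")) {
    tcs <- list(x)
  } else {
    stop("unsupported input: expected an experiment, spectra or ",
         "time courses")
  }
  if (is.null(ligand_conc)) stop("'ligand_conc' is required")

  key <- vapply(tcs, function(tc) paste(tc$state, tc$isomer), character(1))
  dirs <- vapply(tcs, `[[`, character(1), "direction")
  rows <- list()
  buildups <- list()
  for (k in unique(key)) {
    grp <- tcs[key == k]
    gd <- dirs[key == k]
    dec <- grp[gd == "decay"]
    bld <- grp[gd == "buildup"]
    for (b in bld) {
      bf <- tryCatch(fit_monoexponential(b), error = function(e) NULL)
      if (!is.null(bf)) buildups[[length(buildups) + 1L]] <- bf
    }
    src <- if (length(dec)) dec[[1]] else if (length(bld)) bld[[1]] else NULL
    if (is.null(src)) next
    note <- ""
    row <- tryCatch({
      tc <- src
      if (tc$direction == "decay") {
        # normalise to the t = 0 intensity
        tc$intensities <- tc$intensities / tc$intensities[1]
      }
      f <- fit_monoexponential(tc)
      f_free <- NA_real_
      kd <- NA_real_
      koff <- NA_real_
      if (tc$direction == "decay") {
        pf <- f$plateau / f$I0
        if (is.finite(pf) && pf > plateau_threshold && pf < 1) {
          f_free <- pf
        }
      }
      kobs <- if (mode == "paper" || is.na(f_free)) {
        kobs_from_time_constant(f$T, ligand_conc)
      } else {
        (1 - f_free) / (f$T * 60 * ligand_conc)
      }
      if (!is.na(f_free)) {
        bound_total <- NA_real_
        kd <- if (kd_mode == "total") {
          kd_from_free_fraction(f_free, ligand_conc, mode = "total")
        } else {
          stop("kd_mode = \"depleted\" needs per-state protein totals; ",
               "use kd_from_free_fraction() directly")
        }
        koff <- if (mode == "paper") {
          koff_from(kd, kobs)
        } else {
          f_free / (f$T * 60)
        }
      }
      data.frame(state = src$state, isomer = src$isomer,
                 T_min = f$T, se_T_min = f$se_T, k_obs = kobs,
                 free_fraction_eq = f_free, K_d_M = kd, k_off = koff,
                 mode = mode, resonance = src$label, note = note,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(state = src$state, isomer = src$isomer,
                 T_min = NA_real_, se_T_min = NA_real_, k_obs = NA_real_,
                 free_fraction_eq = NA_real_, K_d_M = NA_real_,
                 k_off = NA_real_, mode = mode, resonance = src$label,
                 note = paste("failed:", conditionMessage(e)),
                 stringsAsFactors = FALSE)
    })
    rows[[length(rows) + 1L]] <- row
  }
  if (!length(rows)) stop("no usable time courses")
  rep <- do.call(rbind, rows)
  rep <- rep[order(rep$state, rep$isomer), , drop = FALSE]
  rownames(rep) <- NULL
  structure(rep, class = c("binding_report", "data.frame"),
            ratios = ratio_report(rep), buildup_fits = buildups)
}

#' A/B isomer ratios and fold-differences per protein state
#'
#' Ratios are computed from the stored full-precision values and rounded
#' to one decimal; the A/B on-rate fold-difference is additionally
#' rounded to the nearest integer for "n-fold" phrasing.
#'
#' @param reports A `"binding_report"` data frame (or any data frame with
#'   columns `state, isomer, k_obs` and optionally `K_d_M`).
#' @return Data frame with one row per state: `kobs_ratio_AB`
#'   (\eqn{k_{obs}^A / k_{obs}^B}, 1 decimal), `kd_ratio_BA`
#'   (\eqn{K_d^B / K_d^A}, 1 decimal), `fold_AB` (integer).  Missing
#'   isomers yield `NA`, not an error.
#' @export
ratio_report <- function(reports) {
  stopifnot(is.data.frame(reports),
            all(c("state", "isomer", "k_obs") %in% names(reports)))
  states <- unique(reports$state)
  out <- lapply(states, function(st) {
    a <- reports[reports$state == st & reports$isomer == "A", ]
    b <- reports[reports$state == st & reports$isomer == "B", ]
    kr <- if (nrow(a) && nrow(b)) a$k_obs[1] / b$k_obs[1] else NA_real_
    kdr <- if (nrow(a) && nrow(b) && "K_d_M" %in% names(reports) &&
               !is.na(a$K_d_M[1]) && !is.na(b$K_d_M[1])) {
      b$K_d_M[1] / a$K_d_M[1]
    } else NA_real_
    data.frame(state = st,
               kobs_ratio_AB = round(kr, 1),
               kd_ratio_BA = round(kdr, 1),
               fold_AB = if (is.na(kr)) NA_integer_ else as.integer(round(kr)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
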