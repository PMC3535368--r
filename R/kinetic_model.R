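#' @importFrom stats median quantile coef resid fitted rnorm runif setNames
#' @importFrom utils read.csv write.csv head tail
NULL

.REDOX_TAGS <- c("WT_ox", "WT_red", "C120S_ox", "C120S_red", "TM")

#' Specification of one heme-orientation isomer
#'
#' Heme b lacks true twofold symmetry and sits in the pocket in two stable
#' orientations (A and B, related by 180 degrees rotation about the
#' alpha-gamma meso axis).  The two isomers are chemically distinct,
#' interconvert only on very long timescales, and bind ligand with
#' different kinetics, so each is modelled as an independent protein
#' species competing for the shared ligand pool.
#'
#' @param label `"A"` or `"B"`.
#' @param total_conc Total protein concentration of this isomer, molar.
#' @param rates A [rate_constants()] object.
#' @param redox_tag Protein state: one of `"WT_ox"`, `"WT_red"`,
#'   `"C120S_ox"`, `"C120S_red"`, `"TM"`.
#' @return An object of class `"isomer_spec"`.
#' @export
isomer_spec <- function(label, total_conc, rates, redox_tag = "WT_ox") {
  stopifnot(label %in% c("A", "B"),
            is.numeric(total_conc), length(total_conc) == 1L, total_conc > 0,
            inherits(rates, "rate_constants"),
            redox_tag %in% .REDOX_TAGS)
  structure(list(label = label, total_conc = total_conc,
                 rates = rates, redox_tag = redox_tag),
            class = "isomer_spec")
}

isomer_id <- function(iso) paste(iso$redox_tag, iso$label, sep = ".")

#' Simulation configuration for the shared-ligand kinetic model
#'
#' @param isomers List of [isomer_spec()] objects (distinct
#'   state/orientation combinations) sharing one ligand pool.
#' @param ligand_total Total ligand concentration, molar.
#' @param duration Simulated time span, seconds.
#' @param output_times Strictly increasing times (seconds) within
#'   `[0, duration]` at which states are reported.  Default: 101 evenly
#'   spaced points.
#' @param reoxidation_tau Optional time constant (seconds) of slow
#'   first-order air reoxidation: every `*_red`-tagged sub-species
#'   transfers to the matching `*_ox` sub-species of the same orientation
#'   and ligation state at rate `1/reoxidation_tau`.  `NULL` (default)
#'   disables the process.
#' @param rel_tol,abs_tol Integrator tolerances (relative, and absolute in
#'   molar).
#' @return An object of class `"simulation_config"`.
#' @export
simulation_config <- function(isomers, ligand_total, duration,
                              output_times = NULL,
                              reoxidation_tau = NULL,
                              rel_tol = 1e-8, abs_tol = 1e-12) {
  if (inherits(isomers, "isomer_spec")) isomers <- list(isomers)
  stopifnot(length(isomers) >= 1L,
            all(vapply(isomers, inherits, logical(1), "isomer_spec")),
            is.numeric(ligand_total), ligand_total >= 0,
            is.numeric(duration), duration >= 0)
  ids <- vapply(isomers, isomer_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicated isomer (state, orientation) pairs: ",
         paste(ids[duplicated(ids)], collapse = ", "))
  }
  names(isomers) <- ids
  if (is.null(output_times)) {
    output_times <- seq(0, duration, length.out = 101L)
  }
  stopifnot(all(diff(output_times) > 0) || length(output_times) == 1L,
            min(output_times) >= 0, max(output_times) <= duration)
  if (!is.null(reoxidation_tau)) {
    stopifnot(is.numeric(reoxidation_tau), reoxidation_tau > 0)
    red <- ids[grepl("_red\\.", ids)]
    partner <- sub("_red\\.", "_ox.", red)
    missing <- partner[!partner %in% ids]
    if (length(missing)) {
      stop("reoxidation requires matching oxidised isomers: missing ",
           paste(missing, collapse = ", "))
    }
  }
  structure(list(isomers = isomers, ligand_total = ligand_total,
                 duration = duration, output_times = output_times,
                 reoxidation_tau = reoxidation_tau,
                 rel_tol = rel_tol, abs_tol = abs_tol),
            class = "simulation_config")
}

#' System state of the multi-species binding model
#'
#' Concentrations of every protein sub-species (hexacoordinate,
#' pentacoordinate, ligand-bound) for each isomer, plus the free ligand,
#' at one time point.
#'
#' @param time Time, seconds.
#' @param hexa,penta,bound Named numeric vectors (molar), one element per
#'   isomer id (`"<redox_tag>.<label>"`), identically named.
#' @param ligand_free Free ligand concentration, molar.
#' @return An object of class `"system_state"`.
#' @export
system_state <- function(time, hexa, penta, bound, ligand_free) {
  stopifnot(identical(names(hexa), names(penta)),
            identical(names(hexa), names(bound)),
            !is.null(names(hexa)))
  conc <- c(hexa, penta, bound, ligand_free)
  if (any(conc < 0)) stop("system_state: negative concentration")
  structure(list(time = time, hexa = hexa, penta = penta, bound = bound,
                 ligand_free = ligand_free),
            class = "system_state")
}

#' All-hexacoordinate initial state
#'
#' The resting met protein is fully hexacoordinate (bis-histidine ligated)
#' and ligand is injected free at t = 0.
#'
#' @param config A [simulation_config()].
#' @return A [system_state()] at `time = 0`.
#' @export
initial_state <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  ids <- names(config$isomers)
  tot <- vapply(config$isomers, `[[`, numeric(1), "total_conc")
  zero <- setNames(numeric(length(ids)), ids)
  system_state(0, hexa = setNames(tot, ids), penta = zero, bound = zero,
               ligand_free = config$ligand_total)
}

# pack/unpack between system_state and the flat vector used by deSolve:
# layout c(hexa[ids], penta[ids], bound[ids], L)
.pack_state <- function(state, ids) {
  c(state$hexa[ids], state$penta[ids], state$bound[ids], state$ligand_free)
}

.unpack_state <- function(y, ids, time) {
  n <- length(ids)
  system_state(time,
               hexa = setNames(y[seq_len(n)], ids),
               penta = setNames(y[n + seq_len(n)], ids),
               bound = setNames(y[2 * n + seq_len(n)], ids),
               ligand_free = y[3 * n + 1])
}

# derivative of the packed vector; shared by mass_action_rhs() and the
# deSolve callback.  y may be momentarily slightly negative inside the
# integrator; rates are evaluated as written (mass action is linear in
# each concentration so this is harmless).
.rhs_vec <- function(y, config) {
  ids <- names(config$isomers)
  n <- length(ids)
  hexa <- y[seq_len(n)]
  penta <- y[n + seq_len(n)]
  bound <- y[2 * n + seq_len(n)]
  L <- y[3 * n + 1]

  kH  <- vapply(config$isomers, function(i) i$rates$k_H, numeric(1))
  kmH <- vapply(config$isomers, function(i) i$rates$k_minus_H, numeric(1))
  kon <- vapply(config$isomers, function(i) i$rates$k_on_L, numeric(1))
  koff <- vapply(config$isomers, function(i) i$rates$k_off_L, numeric(1))

  open_flux  <- kmH * hexa - kH * penta        # hexa -> penta net
  bind_flux  <- kon * penta * L                # penta + L -> bound
  rel_flux   <- koff * bound                   # bound -> penta + L

  d_hexa  <- -open_flux
  d_penta <- open_flux - bind_flux + rel_flux
  d_bound <- bind_flux - rel_flux
  d_L     <- sum(rel_flux) - sum(bind_flux)

  if (!is.null(config$reoxidation_tau)) {
    k_reox <- 1 / config$reoxidation_tau
    red_idx <- grep("_red\\.", ids)
    for (i in red_idx) {
      j <- match(sub("_red\\.", "_ox.", ids[i]), ids)
      d_hexa[i] <- d_hexa[i] - k_reox * hexa[i]
      d_hexa[j] <- d_hexa[j] + k_reox * hexa[i]
      d_penta[i] <- d_penta[i] - k_reox * penta[i]
      d_penta[j] <- d_penta[j] + k_reox * penta[i]
      d_bound[i] <- d_bound[i] - k_reox * bound[i]
      d_bound[j] <- d_bound[j] + k_reox * bound[i]
    }
  }
  c(d_hexa, d_penta, d_bound, d_L)
}

#' Mass-action time derivative of a system state
#'
#' Implements the two-step competitive ligation scheme for every isomer:
#' hexa -> penta at `k_minus_H`, penta -> hexa at `k_H`, penta + L ->
#' bound at `k_on_L * [L]`, bound -> penta + L at `k_off_L`; plus, when
#' `reoxidation_tau` is set, ligation-state-preserving first-order
#' transfer of every reduced sub-species to its oxidised counterpart.
#' Protein and ligand are conserved by construction.
#'
#' @param state A [system_state()] whose isomer ids all appear in
#'   `config`.
#' @param config A [simulation_config()].
#' @return A list with the same shape as `state` (`hexa`, `penta`,
#'   `bound`, `ligand_free`) holding d(conc)/dt in molar per second.
#' @export
mass_action_rhs <- function(state, config) {
  stopifnot(inherits(state, "system_state"),
            inherits(config, "simulation_config"))
  ids <- names(config$isomers)
  if (!setequal(names(state$hexa), ids)) {
    stop("state isomers (", paste(names(state$hexa), collapse = ", "),
         ") do not match configuration (", paste(ids, collapse = ", "), ")")
  }
  dy <- .rhs_vec(.pack_state(state, ids), config)
  n <- length(ids)
  list(hexa = setNames(dy[seq_len(n)], ids),
       penta = setNames(dy[n + seq_len(n)], ids),
       bound = setNames(dy[2 * n + seq_len(n)], ids),
       ligand_free = dy[3 * n + 1])
}

#' Integrate the kinetic model
#'
#' Deterministic numerical integration of the mass-action system with an
#' adaptive stiff-capable method (`deSolve::lsoda`).
#'
#' @param config A [simulation_config()].
#' @param initial Optional [system_state()]; defaults to
#'   [initial_state()] (all protein hexacoordinate, all ligand free).
#' @return An object of class `"ngb_trajectory"`: a data frame with
#'   column `time_s` and one column per species
#'   (`hexa.<id>`, `penta.<id>`, `bound.<id>`, `ligand_free`), one row per
#'   output time.  The configuration is attached as attribute `"config"`.
#' @export
integrate_kinetics <- function(config, initial = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(initial)) initial <- initial_state(config)
  ids <- names(config$isomers)
  y0 <- .pack_state(initial, ids)
  times <- config$output_times
  if (config$duration == 0 || length(times) == 1L) {
    out <- matrix(y0, nrow = length(times), ncol = length(y0), byrow = TRUE)
    res <- data.frame(time_s = times, out)
  } else {
    tt <- times
    prepend0 <- tt[1] > 0
    if (prepend0) tt <- c(0, tt)
    sol <- deSolve::lsoda(
      y = y0, times = tt,
      func = function(t, y, parms) list(.rhs_vec(y, config)),
      rtol = config$rel_tol, atol = config$abs_tol)
    if (attr(sol, "istate")[1] < 0 || nrow(sol) < length(tt)) {
      got <- if (nrow(sol) >= 1) sol[nrow(sol), 1] else tt[1]
      stop(sprintf(
        "integration failed in interval [%g, %g] s (solver stopped at t = %g)",
        got, tt[length(tt)], got))
    }
    if (prepend0) sol <- sol[-1, , drop = FALSE]
    res <- data.frame(time_s = sol[, 1], sol[, -1, drop = FALSE])
  }
  names(res) <- c("time_s",
                  paste0("hexa.", ids), paste0("penta.", ids),
                  paste0("bound.", ids), "ligand_free")
  # solver output is kept as computed (tiny negative round-off, within
  # abs_tol, is clamped only when single states are extracted) so that
  # conservation sums reflect the integration itself
  .check_conservation(res, config)
  structure(res, class = c("ngb_trajectory", "data.frame"), config = config)
}

.check_conservation <- function(res, config, tol = 1e-8) {
  ids <- names(config$isomers)
  tot <- vapply(config$isomers, `[[`, numeric(1), "total_conc")
  # protein totals per orientation, summed across redox tags (reoxidation
  # moves protein between tags but preserves the orientation total)
  lab <- sub("^.*\\.", "", ids)
  for (lb in unique(lab)) {
    sel <- ids[lab == lb]
    p <- rowSums(res[, c(paste0("hexa.", sel), paste0("penta.", sel),
                         paste0("bound.", sel)), drop = FALSE])
    expect <- sum(tot[lab == lb])
    if (any(abs(p - expect) > tol * max(expect, config$abs_tol))) {
      stop("protein conservation violated for orientation ", lb)
    }
  }
  lig <- res$ligand_free +
    rowSums(res[, paste0("bound.", ids), drop = FALSE])
  lig_tot <- config$ligand_total
  if (lig_tot > 0 && any(abs(lig - lig_tot) > tol * lig_tot)) {
    stop("ligand conservation violated")
  }
  invisible(TRUE)
}

#' Extract one system state from a trajectory
#'
#' @param traj An `"ngb_trajectory"` from [integrate_kinetics()].
#' @param i Row index (default: last row).
#' @return A [system_state()].
#' @export
trajectory_state <- function(traj, i = nrow(traj)) {
  config <- attr(traj, "config")
  ids <- names(config$isomers)
  y <- unlist(traj[i, -1], use.names = FALSE)
  y[y < 0] <- 0
  .unpack_state(y, ids, traj$time_s[i])
}

#' Specification of a coupled binding equilibrium
#'
#' Several protein species with independent single-site dissociation
#' constants compete for one ligand pool of finite total concentration.
#'
#' @param species Data frame with columns `label` (character),
#'   `total_conc` (molar, >= 0) and `K_d` (molar, > 0).
#' @param ligand_total Total ligand, molar (>= 0).
#' @return An object of class `"equilibrium_spec"`.
#' @export
equilibrium_spec <- function(species, ligand_total) {
  stopifnot(is.data.frame(species),
            all(c("label", "total_conc", "K_d") %in% names(species)),
            all(species$total_conc >= 0), all(species$K_d > 0),
            is.numeric(ligand_total), ligand_total >= 0)
  structure(list(species = species, ligand_total = ligand_total),
            class = "equilibrium_spec")
}

#' Solve a coupled binding equilibrium with ligand depletion
#'
#' Finds the unique free-ligand concentration `L` in `[0, ligand_total]`
#' satisfying mass conservation
#' \deqn{L + \sum_i \frac{tot_i \, L}{L + K_{d,i}} = L_{total},}
#' by bisection (the left-hand side is strictly increasing in `L`, so a
#' single root always exists).  Bound concentrations follow from the
#' single-site isotherm \eqn{bound_i = tot_i \, L / (L + K_{d,i})}.
#'
#' @param spec An [equilibrium_spec()].
#' @param rel_tol Relative bisection tolerance on `L` (default 1e-10).
#' @return A list with elements `ligand_free` (molar), `bound` and `free`
#'   (named numeric vectors per species, molar).
#' @export
solve_equilibrium <- function(spec, rel_tol = 1e-10) {
  stopifnot(inherits(spec, "equilibrium_spec"))
  tot <- spec$species$total_conc
  kd <- spec$species$K_d
  Ltot <- spec$ligand_total
  lab <- as.character(spec$species$label)
  if (Ltot == 0) {
    L <- 0
  } else {
    g <- function(L) L + sum(tot * L / (L + kd)) - Ltot
    lo <- 0
    hi <- Ltot
    # g(0) = -Ltot < 0, g(Ltot) >= 0; bisect until the bracket is
    # relatively tight
    while ((hi - lo) > rel_tol * max(hi, .Machine$double.xmin)) {
      mid <- (lo + hi) / 2
      if (mid == lo || mid == hi) break
      if (g(mid) < 0) lo <- mid else hi <- mid
    }
    L <- (lo + hi) / 2
  }
  bound <- tot * L / (L + kd)
  if (Ltot == 0) bound[] <- 0
  list(ligand_free = L,
       bound = setNames(bound, lab),
       free = setNames(tot - bound, lab))
}

#' Equilibrium specification induced by a simulation configuration
#'
#' Collapses each isomer's two-step scheme to a single site with
#' `K_d = k_off_L / effective_kobs(rates)`; isomers with `k_off_L = 0`
#' are given an effectively zero `K_d` (binding to completion).
#'
#' @param config A [simulation_config()].
#' @return An [equilibrium_spec()].
#' @export
induced_equilibrium_spec <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  ids <- names(config$isomers)
  kd <- vapply(config$isomers, function(i) {
    kobs <- effective_kobs(i$rates)
    if (i$rates$k_off_L == 0 || kobs == 0) {
      .Machine$double.xmin  # strictly positive stand-in for K_d -> 0
    } else {
      i$rates$k_off_L / kobs
    }
  }, numeric(1))
  tot <- vapply(config$isomers, `[[`, numeric(1), "total_conc")
  equilibrium_spec(
    data.frame(label = ids, total_conc = unname(tot), K_d = unname(kd)),
    ligand_total = config$ligand_total)
}

#' Export a trajectory as a long-format CSV
#'
#' Columns: `time_min,state,isomer,species,conc_M` with `species` one of
#' `hexa`, `penta`, `bound`, `ligand_free` (ligand rows carry empty
#' `state`/`isomer`).  Times are written in minutes.
#'
#' @param traj An `"ngb_trajectory"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "ngb_trajectory"))
  config <- attr(traj, "config")
  ids <- names(config$isomers)
  rows <- list()
  for (sp in c("hexa", "penta", "bound")) {
    for (id in ids) {
      parts <- strsplit(id, ".", fixed = TRUE)[[1]]
      rows[[length(rows) + 1L]] <- data.frame(
        time_min = sec_to_min(traj$time_s),
        state = parts[1], isomer = parts[2], species = sp,
        conc_M = traj[[paste0(sp, ".", id)]])
    }
  }
  rows[[length(rows) + 1L]] <- data.frame(
    time_min = sec_to_min(traj$time_s),
    state = "", isomer = "", species = "ligand_free",
    conc_M = traj$ligand_free)
  long <- do.call(rbind, rows)
  long <- long[order(long$time_min, long$state, long$isomer, long$species), ]
  write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a long-format trajectory CSV written by [write_trajectory()]
#'
#' @param path File path.
#' @return A data frame with columns
#'   `time_min,state,isomer,species,conc_M`.
#' @export
read_trajectory <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(state = "character", isomer = "character"))
  need <- c("time_min", "state", "isomer", "species", "conc_M")
  if (!all(need %in% names(df))) {
    stop("trajectory file misses column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  df
}
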