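# Driver layer over the compiled constant-pH Metropolis Monte Carlo core:
# single runs, pH scans, stoichiometric pKa extraction, charge-shift maps
# and net proton uptake.

#' Run a constant-pH Metropolis Monte Carlo simulation
#'
#' Samples conformations (translation, pivot, crankshaft moves on flexible
#' beads) and protonation states (charge-swap moves with trial energy
#' `ln(10)(pH - pKa0) + du_elec`) of a bead topology. Statistics are
#' collected after the equilibration fraction; standard errors come from
#' block averaging. Runs are reproducible bit-for-bit given the seed.
#'
#' @param topology An `mc_topology` from [build_monomer_topology()] or
#'   [build_fibril_topology()].
#' @param params An [energy_params()].
#' @param config An [mc_config()].
#' @return An `mc_result`: `sites` data.frame (chain, position, kind, acid,
#'   pKa0, mean_protonation, se, mean_charge, ionization), `acceptance`
#'   data.frame, `mean_energy`, `energy_running` vs `energy_recomputed`
#'   (bookkeeping check), `net_charge`, `coords`, and the configuration.
#' @export
run_mc <- function(topology, params, config) {
  stopifnot(inherits(topology, "mc_topology"),
            inherits(params, "energy_params"),
            inherits(config, "mc_config"))
  beads <- topology$beads
  weights <- config$moves
  if (!any(beads$flexible))
    weights[c("translation", "pivot", "crankshaft")] <- 0
  if (all(weights == 0))
    stop("no applicable moves for this topology", call. = FALSE)
  sites <- topology$sites
  # deterministic initial protonation: ideal-state majority at this pH
  prot_init <- config$pH < sites$pKa0
  set.seed(config$seed)
  n_equil <- as.integer(floor(config$n_sweeps * config$equilibration_fraction))
  res <- mc_core_run(
    coords = as.matrix(beads[, c("x", "y", "z")]),
    flexible = beads$flexible,
    bonds = topology$bonds,
    segments = topology$segments,
    site_bead = as.integer(sites$bead),
    site_acid = sites$acid,
    site_pka0 = sites$pKa0,
    site_prot_init = as.logical(prot_init),
    params = list(lB = params$bjerrum_length,
                  screen = if (is.finite(params$debye_length))
                    1 / params$debye_length else 0,
                  sigma = params$lj_sigma, eps = params$lj_epsilon,
                  bond_eq = params$bond_eq, bond_k = params$bond_k,
                  cutoff = if (is.finite(params$cutoff)) params$cutoff else 0,
                  container_radius = params$container_radius),
    config = list(pH = config$pH, n_sweeps = config$n_sweeps,
                  n_equil = n_equil, weights = unname(weights),
                  max_disp = config$max_disp, n_blocks = config$n_blocks))
  if (sum(res$accepts) == 0)
    stop("zero accepted moves over the whole run; check the configuration",
         call. = FALSE)
  bm <- res$block_means
  se <- apply(bm, 1, function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 2) return(NA_real_)
    sd(v) / sqrt(length(v))
  })
  out_sites <- sites
  out_sites$mean_protonation <- res$site_mean_protonation
  out_sites$se <- se
  out_sites$mean_charge <- ifelse(sites$acid,
                                  -(1 - out_sites$mean_protonation),
                                  out_sites$mean_protonation)
  out_sites$ionization <- ifelse(sites$acid,
                                 1 - out_sites$mean_protonation,
                                 out_sites$mean_protonation)
  acc <- data.frame(move = c("translation", "pivot", "crankshaft",
                             "charge_swap"),
                    attempts = res$attempts, accepts = res$accepts)
  acc$rate <- ifelse(acc$attempts > 0, acc$accepts / acc$attempts, NA)
  structure(list(sites = out_sites, acceptance = acc,
                 mean_energy = res$mean_energy,
                 energy_running = res$energy_running,
                 energy_recomputed = res$energy_recomputed,
                 net_charge = sum(out_sites$mean_charge),
                 coords = res$coords, pH = config$pH,
                 n_sweeps = config$n_sweeps, seed = config$seed,
                 topology = topology, params = params),
            class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf(paste0("mc_result: pH %.2f, %d sweeps, %d sites, net charge ",
                     "%.2f, <E> = %.2f kT\n"),
              x$pH, x$n_sweeps, nrow(x$sites), x$net_charge, x$mean_energy))
  invisible(x)
}

#' Titration scan: one MC run per pH value
#'
#' @param topology,params As in [run_mc()].
#' @param pH_grid Increasing pH values.
#' @param config Base [mc_config()]; run `i` uses seed `seed + i - 1`.
#' @return An `mc_titration`: list of `mc_result`s plus an ionization
#'   matrix (site x pH).
#' @export
titration_scan <- function(topology, params, pH_grid, config) {
  if (is.unsorted(pH_grid, strictly = TRUE))
    stop("pH_grid must be strictly increasing", call. = FALSE)
  runs <- lapply(seq_along(pH_grid), function(i) {
    cfg <- config
    cfg$pH <- pH_grid[i]
    cfg$seed <- config$seed + i - 1L
    run_mc(topology, params, cfg)
  })
  ion <- vapply(runs, function(r) r$sites$ionization,
                numeric(nrow(runs[[1]]$sites)))
  ion <- matrix(ion, nrow = nrow(runs[[1]]$sites))
  rownames(ion) <- paste0(runs[[1]]$sites$kind, runs[[1]]$sites$position,
                          ".", runs[[1]]$sites$chain)
  structure(list(runs = runs, pH = pH_grid, ionization = ion,
                 sites = runs[[1]]$sites[, c("chain", "position", "kind",
                                             "acid", "pKa0")]),
            class = "mc_titration")
}

#' Stoichiometric pKa from a simulated titration curve
#'
#' The stoichiometric (apparent) pKa of a site is the pH at which its
#' degree of ionization is 0.5, obtained by linear interpolation between
#' the bracketing grid points. Sites whose curve does not cross 0.5 within
#' the grid get `NA`.
#'
#' @param scan An `mc_titration` from [titration_scan()], or a list with
#'   elements `pH` and `ionization` (site x pH matrix).
#' @return Data.frame of sites with a `pKa_stoich` column.
#' @export
stoichiometric_pka <- function(scan) {
  ion <- scan$ionization
  pH <- scan$pH
  pk <- apply(ion, 1, function(v) {
    above <- v - 0.5
    for (i in seq_len(length(v) - 1)) {
      if (above[i] == 0) return(pH[i])
      if (above[i] * above[i + 1] < 0)
        return(pH[i] + (0.5 - v[i]) * (pH[i + 1] - pH[i]) / (v[i + 1] - v[i]))
    }
    if (above[length(v)] == 0) return(pH[length(v)])
    NA_real_
  })
  out <- if (!is.null(scan$sites)) scan$sites else
    data.frame(site = if (!is.null(rownames(ion))) rownames(ion)
               else seq_len(nrow(ion)), stringsAsFactors = FALSE)
  out$pKa_stoich <- unname(pk)
  out
}

interior_chains <- function(result) {
  chains <- unique(result$topology$beads$chain)
  if (result$topology$mode == "fibril" && length(chains) >= 3)
    chains[-c(1, length(chains))]
  else chains
}

site_means_by_residue <- function(result, chains, column) {
  s <- result$sites[result$sites$chain %in% chains, , drop = FALSE]
  agg <- stats::aggregate(s[[column]],
                          by = list(position = s$position, kind = s$kind),
                          FUN = mean)
  names(agg)[3] <- column
  agg[order(agg$position), , drop = FALSE]
}

#' Per-residue charge-shift map between monomer and fibril
#'
#' Fibrillar mean charge minus monomeric mean charge, per titratable
#' residue, at matched pH. Fibril values are averaged over interior chains
#' (the two end planes are excluded when three or more planes are present).
#'
#' @param mono,fib `mc_result`s for the monomer and the fibril at the same
#'   pH and for the same sequence.
#' @return Data.frame with columns `position`, `kind`, `mono_charge`,
#'   `fib_charge`, `shift` (fibril minus monomer).
#' @export
charge_shift_map <- function(mono, fib) {
  if (abs(mono$pH - fib$pH) > 1e-9)
    stop("monomer and fibril runs are at different pH", call. = FALSE)
  mm <- site_means_by_residue(mono, interior_chains(mono), "mean_charge")
  ff <- site_means_by_residue(fib, interior_chains(fib), "mean_charge")
  merged <- merge(mm, ff, by = c("position", "kind"),
                  suffixes = c("_mono", "_fib"))
  if (nrow(merged) != nrow(mm))
    stop("site mismatch between monomer and fibril runs", call. = FALSE)
  out <- data.frame(position = merged$position, kind = merged$kind,
                    mono_charge = merged$mean_charge_mono,
                    fib_charge = merged$mean_charge_fib,
                    shift = merged$mean_charge_fib - merged$mean_charge_mono)
  out[order(out$position), , drop = FALSE]
}

#' Net proton uptake per monomer on fibril incorporation
#'
#' Sum over titratable sites of (fibrillar mean protonation - monomeric
#' mean protonation), per interior fibril chain.
#'
#' @inheritParams charge_shift_map
#' @return Protons per monomer (positive = uptake).
#' @export
net_proton_uptake <- function(mono, fib) {
  if (abs(mono$pH - fib$pH) > 1e-9)
    stop("monomer and fibril runs are at different pH", call. = FALSE)
  mm <- site_means_by_residue(mono, interior_chains(mono), "mean_protonation")
  ff <- site_means_by_residue(fib, interior_chains(fib), "mean_protonation")
  merged <- merge(mm, ff, by = c("position", "kind"),
                  suffixes = c("_mono", "_fib"))
  sum(merged$mean_protonation_fib - merged$mean_protonation_mono)
}

#' Total interaction energy of a topology with given bead charges
#'
#' Exposes the compiled energy function (all non-bonded pairs plus bonds)
#' for diagnostics such as translation-invariance checks.
#'
#' @param topology An `mc_topology`.
#' @param params An [energy_params()].
#' @param charges Optional per-bead charge vector; defaults to the ideal
#'   majority protonation state at `pH`.
#' @param pH Used only to build the default charges.
#' @return Energy in kT.
#' @export
topology_energy <- function(topology, params, charges = NULL, pH = 7) {
  beads <- topology$beads
  if (is.null(charges)) {
    charges <- numeric(nrow(beads))
    s <- topology$sites
    prot <- pH < s$pKa0
    qs <- ifelse(s$acid, ifelse(prot, 0, -1), ifelse(prot, 1, 0))
    for (i in seq_len(nrow(s)))
      charges[s$bead[i]] <- charges[s$bead[i]] + qs[i]
  }
  mc_total_energy_cpp(as.matrix(beads[, c("x", "y", "z")]), charges,
                      topology$bonds,
                      list(lB = params$bjerrum_length,
                           screen = if (is.finite(params$debye_length))
                             1 / params$debye_length else 0,
                           sigma = params$lj_sigma, eps = params$lj_epsilon,
                           bond_eq = params$bond_eq, bond_k = params$bond_k,
                           cutoff = if (is.finite(params$cutoff))
                             params$cutoff else 0))
}
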