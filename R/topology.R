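# Coarse-grained bead topologies and energy parameters for the constant-pH
# Monte Carlo model: one bead per residue, harmonic bonds along flexible
# segments, rigid fibril core, screened Coulomb + Lennard-Jones
# interactions.

#' Energy and interaction parameters
#'
#' Defaults follow the published coarse-grained model where stated (Bjerrum
#' length 7 Angstrom, i.e. water at 300 K; 0.5 mM 1:1 salt for fibril runs)
#' and documented in-house values elsewhere (uniform LJ sigma 7 A, epsilon
#' 0.05 kT, bond length 4.9 A, spring constant 0.76 kT/A^2). Energies are
#' in units of kT throughout.
#'
#' @param bjerrum_length Angstrom (7 = water, 300 K). Zero switches
#'   electrostatics off (ideal-titration limit).
#' @param ionic_strength Molar 1:1 salt (5e-4 for fibril runs, 0.015 for
#'   monomer validation runs). Zero means no screening.
#' @param lj_sigma,lj_epsilon Lennard-Jones size (A) and depth (kT).
#' @param bond_eq,bond_k Harmonic bond length (A) and spring constant
#'   (kT/A^2); bond energy is `k/2 (r - r0)^2`.
#' @param temperature Kelvin (bookkeeping only; energies are in kT).
#' @param container_radius Spherical confinement radius for flexible beads
#'   (A).
#' @param cutoff_factor Electrostatic interactions are truncated at
#'   `cutoff_factor * debye_length` (no truncation when unscreened).
#' @return An `energy_params` list including the derived `debye_length`.
#' @export
energy_params <- function(bjerrum_length = 7, ionic_strength = 5e-4,
                          lj_sigma = 7, lj_epsilon = 0.05,
                          bond_eq = 4.9, bond_k = 0.76, temperature = 300,
                          container_radius = 250, cutoff_factor = 4) {
  stopifnot(bjerrum_length >= 0, ionic_strength >= 0, lj_sigma > 0,
            lj_epsilon >= 0, bond_eq > 0, bond_k >= 0, container_radius > 0)
  dl <- debye_length(ionic_strength, bjerrum_length)
  structure(list(bjerrum_length = bjerrum_length,
                 ionic_strength = ionic_strength, debye_length = dl,
                 lj_sigma = lj_sigma, lj_epsilon = lj_epsilon,
                 bond_eq = bond_eq, bond_k = bond_k,
                 temperature = temperature,
                 container_radius = container_radius,
                 cutoff = if (is.finite(dl)) cutoff_factor * dl else Inf),
            class = "energy_params")
}

#' Debye screening length
#'
#' `1 / sqrt(8 pi lB N_A I)` in Angstrom for a 1:1 electrolyte of ionic
#' strength `I` (molar). About 137 A at 0.5 mM and 25 A at 15 mM with
#' `lB = 7 A`.
#'
#' @param ionic_strength Molar.
#' @param bjerrum_length Angstrom.
#' @return Length in Angstrom (`Inf` for zero ionic strength).
#' @export
debye_length <- function(ionic_strength, bjerrum_length = 7) {
  if (ionic_strength <= 0 || bjerrum_length <= 0) return(Inf)
  # N_A per liter -> per Angstrom^3: 6.02214076e23 / 1e27
  1 / sqrt(8 * pi * bjerrum_length * 6.02214076e-4 * ionic_strength)
}

#' Pairwise bead-bead interaction energy
#'
#' Combined Lennard-Jones and screened Coulomb potential,
#' `u = 4 eps [(sigma/r)^12 - (sigma/r)^6] + lB q_i q_j exp(-r/kappa) / r`
#' in kT units. Two unit charges 7 A apart in unscreened water interact
#' with exactly 1 kT (the definition of the Bjerrum length).
#'
#' @param q_i,q_j Charges (elementary units).
#' @param r Separation (Angstrom, > 0); vectorized.
#' @param params An [energy_params()] object.
#' @return Energy in kT.
#' @export
pair_energy <- function(q_i, q_j, r, params) {
  if (any(r <= 0)) stop("pair separation must be positive", call. = FALSE)
  sr6 <- (params$lj_sigma / r)^6
  u <- 4 * params$lj_epsilon * (sr6^2 - sr6)
  screen <- if (is.finite(params$debye_length)) exp(-r / params$debye_length) else 1
  u + params$bjerrum_length * q_i * q_j * screen / r
}

#' Trial energy of a protonation-state swap move
#'
#' `du = ln(10) (pH - pKa0) + du_elec` for protonation; deprotonation
#' negates the chemical term. Acceptance is `min(1, exp(-du))`.
#'
#' @param direction `"protonate"` or `"deprotonate"`.
#' @param pH Solution pH.
#' @param pKa0 Intrinsic pKa of the site.
#' @param du_elec Electrostatic energy change of the swap (kT).
#' @return Trial energy in kT.
#' @export
swap_move_energy <- function(direction = c("protonate", "deprotonate"),
                             pH, pKa0, du_elec = 0) {
  direction <- match.arg(direction)
  chem <- log(10) * (pH - pKa0)
  if (direction == "deprotonate") chem <- -chem
  chem + du_elec
}

new_topology <- function(beads, bonds, segments, sites, mode, n_chains) {
  stopifnot(is.matrix(bonds) || nrow(bonds) == 0)
  structure(list(beads = beads, bonds = bonds, segments = segments,
                 sites = sites, mode = mode, n_chains = n_chains),
            class = "mc_topology")
}

#' @export
print.mc_topology <- function(x, ...) {
  cat("mc_topology (", x$mode, "): ", nrow(x$beads), " beads, ",
      nrow(x$bonds), " bonds, ", sum(!x$beads$flexible), " rigid, ",
      nrow(x$sites), " titratable sites\n", sep = "")
  invisible(x)
}

map_sites_to_beads <- function(sites, chain_id, offset, n_res) {
  bead_local <- pmin(pmax(sites$position, 1L), n_res)  # termini -> end beads
  data.frame(bead = offset + bead_local, chain = chain_id,
             position = sites$position, kind = sites$kind,
             acid = sites$acid, pKa0 = sites$pKa0,
             stringsAsFactors = FALSE)
}

#' Build the flexible single-chain (monomer) topology
#'
#' 140 beads connected by 139 harmonic bonds, no rigid beads. The initial
#' conformation is a clash-free serpentine at the equilibrium bond length,
#' centered at the origin so it fits the spherical container. Every
#' titratable residue plus both termini carries a charge-swap site (the
#' terminal sites sit on the first/last bead).
#'
#' @param spec A [protein_spec()].
#' @param params An [energy_params()].
#' @return An `mc_topology`.
#' @export
build_monomer_topology <- function(spec, params = energy_params()) {
  chars <- strsplit(spec$sequence, "")[[1]]
  n <- length(chars)
  row_len <- 20L; row_gap <- 6
  idx <- seq_len(n) - 1L
  row <- idx %/% row_len
  col <- idx %% row_len
  col <- ifelse(row %% 2 == 0, col, row_len - 1L - col)
  x <- col * params$bond_eq; y <- row * row_gap
  beads <- data.frame(chain = 1L, position = seq_len(n), kind = chars,
                      x = x - mean(x), y = y - mean(y), z = 0,
                      flexible = TRUE, stringsAsFactors = FALSE)
  bonds <- cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)
  segments <- matrix(c(1L, n, 2L), nrow = 1)
  sites <- map_sites_to_beads(enumerate_all_titratable(spec), 1L, 0L, n)
  new_topology(beads, bonds, segments, sites, "monomer", 1L)
}

#' Build the fibril topology: rigid core, flexible termini
#'
#' Per chain, beads 29-100 are fixed at the supplied residue mass centers;
#' beads 1-28 and 101-140 are flexible, bonded consecutively, and
#' initialized as self-avoiding walks grafted to the core anchors (bonds
#' 28-29 and 100-101 included: 68 bonds per chain).
#'
#' @param spec A [protein_spec()].
#' @param centers A `residue_centers` covering the core range for every
#'   chain (from [read_pdb_mass_centers()] or [synthetic_fibril()]).
#' @param params An [energy_params()].
#' @param seed RNG seed for the self-avoiding-walk initialization.
#' @param min_clash Minimum allowed distance when growing the initial
#'   tails (Angstrom).
#' @return An `mc_topology` with one chain per plane, ordered as in
#'   `centers`.
#' @export
build_fibril_topology <- function(spec, centers, params = energy_params(),
                                  seed = 1L, min_clash = 3.0) {
  set.seed(seed)
  chars <- strsplit(spec$sequence, "")[[1]]
  n <- length(chars)
  rng <- centers$residue_range
  chains <- unique(centers$centers$chain)
  placed <- matrix(numeric(0), ncol = 3)
  bead_rows <- list(); bond_rows <- list(); seg_rows <- list(); site_rows <- list()
  # place all rigid cores first so tail growth avoids every core
  core_xyz <- list()
  for (ci in seq_along(chains)) {
    cc <- centers$centers[centers$centers$chain == chains[ci], , drop = FALSE]
    cc <- cc[order(cc$position), , drop = FALSE]
    if (!identical(cc$position, seq.int(rng[1], rng[2])))
      stop("chain ", chains[ci], " does not cover residues ", rng[1], "-",
           rng[2], call. = FALSE)
    core_xyz[[ci]] <- as.matrix(cc[, c("x", "y", "z")])
    placed <- rbind(placed, core_xyz[[ci]])
  }
  grow_tail <- function(anchor, len, placed) {
    out <- matrix(NA_real_, nrow = len, ncol = 3)
    prev <- anchor
    i <- 1L
    tries_total <- 0L
    while (i <= len) {
      ok <- FALSE
      for (try in 1:300) {
        d <- rnorm(3); d <- d / sqrt(sum(d^2))
        cand <- prev + params$bond_eq * d
        if (sqrt(sum(cand^2)) > params$container_radius) next
        all_pts <- rbind(placed, out[seq_len(i - 1L), , drop = FALSE])
        if (nrow(all_pts) > 0) {
          dd <- sqrt(rowSums(sweep(all_pts, 2, cand)^2))
          if (min(dd) < min_clash) next
        }
        ok <- TRUE; break
      }
      if (!ok) {
        # backtrack one step (or restart the tail)
        tries_total <- tries_total + 1L
        if (tries_total > 50L)
          stop("failed to grow a clash-free initial tail", call. = FALSE)
        i <- max(1L, i - 1L)
        prev <- if (i == 1L) anchor else out[i - 1L, ]
        next
      }
      out[i, ] <- cand
      prev <- cand
      i <- i + 1L
    }
    out
  }
  for (ci in seq_along(chains)) {
    off <- (ci - 1L) * n
    xyz <- matrix(NA_real_, nrow = n, ncol = 3)
    xyz[rng[1]:rng[2], ] <- core_xyz[[ci]]
    # N-tail grown outward from residue rng[1]: positions rng[1]-1 ... 1
    n_len <- rng[1] - 1L
    if (n_len > 0) {
      tail_n <- grow_tail(xyz[rng[1], ], n_len, placed)
      xyz[(rng[1] - 1L):1L, ] <- tail_n
      placed <- rbind(placed, tail_n)
    }
    c_len <- n - rng[2]
    if (c_len > 0) {
      tail_c <- grow_tail(xyz[rng[2], ], c_len, placed)
      xyz[(rng[2] + 1L):n, ] <- tail_c
      placed <- rbind(placed, tail_c)
    }
    flexible <- rep(TRUE, n); flexible[rng[1]:rng[2]] <- FALSE
    bead_rows[[ci]] <- data.frame(chain = ci, position = seq_len(n),
                                  kind = chars, x = xyz[, 1], y = xyz[, 2],
                                  z = xyz[, 3], flexible = flexible,
                                  stringsAsFactors = FALSE)
    # consecutive bonds along each flexible stretch incl. the graft bond
    nb <- rbind(cbind(1:(rng[1] - 1L), 2:rng[1]),
                cbind(rng[2]:(n - 1L), (rng[2] + 1L):n))
    bond_rows[[ci]] <- nb + off
    seg_rows[[ci]] <- rbind(c(off + 1L, off + rng[1] - 1L, -1L),
                            c(off + rng[2] + 1L, off + n, 1L))
    site_rows[[ci]] <- map_sites_to_beads(enumerate_all_titratable(spec),
                                          ci, off, n)
  }
  new_topology(do.call(rbind, bead_rows), do.call(rbind, bond_rows),
               do.call(rbind, seg_rows), do.call(rbind, site_rows),
               "fibril", length(chains))
}

#' Monte Carlo run configuration
#'
#' @param pH Solution pH (constant-pH ensemble).
#' @param n_sweeps Number of sweeps; each sweep makes `n_beads` trial
#'   moves. The desk-scale default is 2e4; production-scale runs use 1e6.
#' @param moves Named weights for the move mix
#'   (`translation`, `pivot`, `crankshaft`, `charge_swap`).
#' @param max_disp Maximum translation displacement (Angstrom).
#' @param seed RNG seed (all randomness flows through R's RNG).
#' @param equilibration_fraction Fraction of sweeps discarded before
#'   statistics are collected.
#' @param n_blocks Blocks for standard-error estimation.
#' @return An `mc_config` list.
#' @export
mc_config <- function(pH, n_sweeps = 20000,
                      moves = c(translation = 0.5, pivot = 0.15,
                                crankshaft = 0.15, charge_swap = 0.2),
                      max_disp = 3, seed = 1L,
                      equilibration_fraction = 0.25, n_blocks = 20) {
  stopifnot(n_sweeps >= 1, all(moves >= 0), any(moves > 0),
            equilibration_fraction >= 0, equilibration_fraction < 1)
  need <- c("translation", "pivot", "crankshaft", "charge_swap")
  if (!all(need %in% names(moves)))
    stop("moves must name ", paste(need, collapse = ", "), call. = FALSE)
  structure(list(pH = pH, n_sweeps = as.integer(n_sweeps),
                 moves = moves[need], max_disp = max_disp,
                 seed = as.integer(seed),
                 equilibration_fraction = equilibration_fraction,
                 n_blocks = as.integer(n_blocks)),
            class = "mc_config")
}
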