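# Ideal (Henderson-Hasselbalch) titration layer: per-site protonation,
# averages, net charge, proton-binding capacitance and titration curves.
# Site-site coupling is deliberately absent here; it is the Monte Carlo
# module's job.

#' Degree of protonation of a single site
#'
#' `Q = 1 / (1 + 10^(pH - pKa))`: the fraction of the site's population
#' carrying the proton. Identical form for acids and bases; the charge
#' convention differs (acid: deprotonated is -1; base: protonated is +1).
#'
#' @param pH,pKa Finite numerics (vectorized).
#' @return Fraction in `[0, 1]`.
#' @export
degree_of_protonation <- function(pH, pKa) {
  stopifnot(all(is.finite(pH)), all(is.finite(pKa)))
  1 / (1 + 10^(pH - pKa))
}

#' Average protonation of an acidic site set
#'
#' Arithmetic mean of the per-site protonation degrees at a given pH.
#'
#' @param set A `titration_set` of acid sites.
#' @param pH Scalar pH.
#' @return Mean protonation fraction.
#' @export
average_protonation <- function(set, pH) {
  sites <- set$sites
  if (nrow(sites) == 0L) stop("empty titration set", call. = FALSE)
  if (any(!sites$acid))
    stop("average_protonation expects acid sites only; use net_charge for ",
         "mixed sets", call. = FALSE)
  mean(degree_of_protonation(pH, sites$pKa_assigned))
}

#' Net charge of a titratable site set
#'
#' Acids contribute `-(1 - Q)`, bases `+Q`, with
#' `Q = 1 / (1 + 10^(pH - pKa))` for both.
#'
#' @param set A `titration_set` (acids and/or bases).
#' @param pH Scalar pH.
#' @return Signed net charge in elementary units.
#' @export
net_charge <- function(set, pH) {
  sites <- set$sites
  q <- degree_of_protonation(pH, sites$pKa_assigned)
  sum(ifelse(sites$acid, -(1 - q), q))
}

#' Proton-binding capacitance
#'
#' `C = ln(10) * sum_i Q_i (1 - Q_i)`: the magnitude of the derivative of
#' the total number of bound protons with respect to pH. A single site is
#' maximally buffering at `pH = pKa`, where its contribution is
#' `ln(10)/4 ~ 0.576`.
#'
#' @param set A `titration_set`.
#' @param pH Scalar pH.
#' @param per_site Report the per-site average instead of the per-molecule
#'   sum.
#' @return Non-negative capacitance.
#' @export
capacitance <- function(set, pH, per_site = FALSE) {
  q <- degree_of_protonation(pH, set$sites$pKa_assigned)
  val <- log(10) * sum(q * (1 - q))
  if (per_site) val / nrow(set$sites) else val
}

#' Ideal titration curve of a site set
#'
#' Evaluates per-site protonation, the site average, net charge and
#' capacitance over a pH grid. With `reference = TRUE` the curve uses the
#' intrinsic `pKa0` values instead of the assigned ones (the "nonperturbed"
#' reference curve).
#'
#' @param set A `titration_set`.
#' @param pH_grid Increasing numeric vector.
#' @param reference Use `pKa0` instead of `pKa_assigned`.
#' @return A `titration_curve`: list with `pH`, matrix `per_site`
#'   (site x pH protonation fractions), `average`, `net_charge`,
#'   `capacitance` and the site table.
#' @export
titration_curve <- function(set, pH_grid, reference = FALSE) {
  if (is.unsorted(pH_grid, strictly = TRUE))
    stop("pH_grid must be strictly increasing", call. = FALSE)
  sites <- set$sites
  pka <- if (reference) sites$pKa0 else sites$pKa_assigned
  per_site <- outer(pka, pH_grid, function(k, p) degree_of_protonation(p, k))
  rownames(per_site) <- paste0(sites$kind, sites$position)
  qq <- per_site * (1 - per_site)
  chg <- sweep(1 - per_site, 1, ifelse(sites$acid, -1, 0), "*") +
    sweep(per_site, 1, ifelse(sites$acid, 0, 1), "*")
  structure(list(pH = pH_grid, per_site = per_site,
                 average = colMeans(per_site),
                 net_charge = colSums(chg),
                 capacitance = log(10) * colSums(qq),
                 sites = sites, reference = reference),
            class = "titration_curve")
}

#' @export
as.data.frame.titration_curve <- function(x, ...) {
  data.frame(pH = x$pH, average_protonation = x$average,
             net_charge = x$net_charge, capacitance = x$capacitance,
             t(x$per_site), check.names = FALSE)
}

#' Export a titration curve as CSV
#'
#' One row per pH value: average protonation, net charge (elementary
#' units), capacitance (protons per pH unit) and per-site columns.
#'
#' @param curve A `titration_curve`.
#' @param path Output file.
#' @export
write_curve_csv <- function(curve, path) {
  write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}
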