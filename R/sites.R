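# Titratable-site enumeration and monomer pKa assignment schemes.

# Model-compound (intrinsic) pKa values. Asp/Glu follow the tabulated
# intrinsic values used for alpha-synuclein; the remaining kinds are a
# standard model-compound set kept in this one editable table.
INTRINSIC_PKA <- c(Asp = 4.0, Glu = 4.4, His = 6.3, Tyr = 10.1,
                   Lys = 10.4, Nterm = 8.0, Cterm = 3.6)

# Regional NMR-derived monomer pKa values for alpha-synuclein (Croke et al.
# scheme): the acidic C-terminal tail is upshifted relative to the
# N-terminal/NAC region. The C-terminal carboxyl is not listed in that
# table; it defaults to 3.6 (terminal alpha-COOH model-compound value),
# overridable via `cterm_pka`.
CROKE_PKA <- list(ctail = c(Asp = 4.2, Glu = 4.6),
                  other = c(Asp = 3.6, Glu = 4.2),
                  cterm = 3.6)

ACID_KINDS <- c("Asp", "Glu", "Cterm", "Tyr")
BASE_KINDS <- c("His", "Lys", "Nterm")

KIND_FROM_LETTER <- c(D = "Asp", E = "Glu", H = "His", Y = "Tyr", K = "Lys")

new_site_df <- function(position, kind, region) {
  data.frame(position = as.integer(position), kind = kind,
             acid = kind %in% ACID_KINDS, region = region,
             pKa0 = unname(INTRINSIC_PKA[kind]),
             pKa_assigned = NA_real_, stringsAsFactors = FALSE)
}

#' Enumerate the titratable acidic groups of a protein
#'
#' Lists the Asp/Glu carboxyls (plus, optionally, the C-terminal carboxyl)
#' either over the whole chain or restricted to the acidic C-terminal tail.
#' For wild-type alpha-synuclein the tail set has 15 members (14 side-chain
#' carboxyls plus the C-terminus) and the full set 25.
#'
#' @param spec A [protein_spec()].
#' @param site_set `"tail_only"` (C-terminal-tail region) or `"all_acidic"`.
#' @param include_cterm Include the C-terminal carboxyl as a site (it is a
#'   sentinel position `nchar(sequence) + 1`, region `ctail`).
#' @return Site data.frame ordered by position with columns `position`,
#'   `kind`, `acid`, `region`, `pKa0`, `pKa_assigned` (the latter `NA` until
#'   [assign_pkas()] is applied).
#' @examples
#' nrow(enumerate_acidic_sites(protein_spec("wt"), "tail_only"))  # 15
#' @export
enumerate_acidic_sites <- function(spec,
                                   site_set = c("tail_only", "all_acidic"),
                                   include_cterm = TRUE) {
  site_set <- match.arg(site_set)
  chars <- strsplit(spec$sequence, "")[[1]]
  pos <- which(chars %in% c("D", "E"))
  region <- region_of(pos, spec$region_bounds)
  if (site_set == "tail_only") {
    keep <- region == "ctail"
    pos <- pos[keep]; region <- region[keep]
  }
  sites <- new_site_df(pos, unname(KIND_FROM_LETTER[chars[pos]]), region)
  if (include_cterm) {
    n <- nchar(spec$sequence)
    sites <- rbind(sites, new_site_df(n + 1L, "Cterm",
                                      region_of(n, spec$region_bounds)))
  }
  sites[order(sites$position), , drop = FALSE]
}

#' Enumerate all titratable sites (acids and bases)
#'
#' Includes Asp, Glu, His, Tyr, Lys side chains and both chain termini, as
#' used by the constant-pH Monte Carlo model in which every residue of the
#' protein is represented.
#'
#' @inheritParams enumerate_acidic_sites
#' @return Site data.frame ordered by position (N-terminus first at the
#'   sentinel position 0, C-terminus last at `length + 1`).
#' @export
enumerate_all_titratable <- function(spec) {
  chars <- strsplit(spec$sequence, "")[[1]]
  pos <- which(chars %in% names(KIND_FROM_LETTER))
  sites <- new_site_df(pos, unname(KIND_FROM_LETTER[chars[pos]]),
                       region_of(pos, spec$region_bounds))
  n <- length(chars)
  sites <- rbind(new_site_df(0L, "Nterm", region_of(1L, spec$region_bounds)),
                 sites,
                 new_site_df(n + 1L, "Cterm", region_of(n, spec$region_bounds)))
  sites[order(sites$position), , drop = FALSE]
}

#' Assign monomer pKa values to a site set
#'
#' @param sites Site data.frame from [enumerate_acidic_sites()] or
#'   [enumerate_all_titratable()].
#' @param scheme `"croke_regional"` (NMR-derived Asp/Glu values split by
#'   region, C-terminus per `cterm_pka`; acid sites only),
#'   `"intrinsic"` (model-compound values for every kind), or a single
#'   number applied uniformly to all sites.
#' @param cterm_pka Monomer pKa of the C-terminal carboxyl under
#'   `croke_regional` (default 3.6).
#' @param label Optional label stored on the result.
#' @return A `titration_set`: list with elements `sites` (the data.frame
#'   with `pKa_assigned` filled) and `label`.
#' @examples
#' set <- assign_pkas(enumerate_acidic_sites(protein_spec("wt")), "croke_regional")
#' mean(set$sites$pKa_assigned)
#' @export
assign_pkas <- function(sites, scheme = "croke_regional", cterm_pka = 3.6,
                        label = NULL) {
  if (is.numeric(scheme)) {
    stopifnot(length(scheme) == 1L, is.finite(scheme))
    sites$pKa_assigned <- scheme
    label <- label %||% sprintf("uniform(%g)", scheme)
  } else if (identical(scheme, "intrinsic")) {
    sites$pKa_assigned <- sites$pKa0
    label <- label %||% "intrinsic"
  } else if (identical(scheme, "croke_regional")) {
    bad <- setdiff(unique(sites$kind), c("Asp", "Glu", "Cterm"))
    if (length(bad))
      stop("croke_regional covers Asp/Glu/Cterm only; site kind(s) ",
           paste(bad, collapse = ","), " not covered by the scheme",
           call. = FALSE)
    tab <- ifelse(sites$region == "ctail",
                  CROKE_PKA$ctail[sites$kind], CROKE_PKA$other[sites$kind])
    tab[sites$kind == "Cterm"] <- cterm_pka
    sites$pKa_assigned <- unname(tab)
    label <- label %||% "croke_regional"
  } else {
    stop("unknown pKa scheme: ", deparse(scheme), call. = FALSE)
  }
  if (any(!is.finite(sites$pKa_assigned)) ||
      any(sites$pKa_assigned <= 0 | sites$pKa_assigned >= 14))
    stop("assigned pKa values must lie in (0, 14)", call. = FALSE)
  structure(list(sites = sites, label = label), class = "titration_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.titration_set <- function(x, ...) {
  cat("titration_set '", x$label, "': ", nrow(x$sites), " sites, mean pKa ",
      round(mean(x$sites$pKa_assigned), 3), "\n", sep = "")
  invisible(x)
}

#' Export a site table as CSV
#'
#' Columns: position, kind, region, pKa0, pKa_assigned.
#'
#' @param set A `titration_set` (or a raw site data.frame).
#' @param path Output file.
#' @export
write_sites_csv <- function(set, path) {
  sites <- if (inherits(set, "titration_set")) set$sites else set
  write.csv(sites[, c("position", "kind", "region", "pKa0", "pKa_assigned")],
            path, row.names = FALSE)
  invisible(path)
}
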