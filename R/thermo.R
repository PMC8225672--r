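#' @keywords internal
GAS_CONSTANT_KCAL <- 1.98720425e-3  # kcal mol^-1 K^-1

#' FRET transfer efficiency from a sensitized-emission lifetime
#'
#' Computes the resonance energy transfer efficiency
#' \eqn{E = 1 - \tau_{ad}/\tau_d} from the donor lifetime in the presence of
#' the acceptor (`tau_ad`, measured through the acceptor sensitized
#' emission) and the donor-only lifetime `tau_d`. A lifetime longer than the
#' donor-only lifetime is non-physical; the (negative) efficiency is then
#' returned flagged with a warning rather than silently clipped.
#'
#' @param tau_ad Sensitized-emission lifetime, µs (> 0). Vectorized.
#' @param tau_d Donor-only lifetime, µs (> 0).
#' @return Transfer efficiency (dimensionless, < 1). Attribute
#'   `"nonphysical"` marks entries with `tau_ad >= tau_d`.
#' @examples
#' fret_efficiency(557.8, tau_d = 1508.414)
#' @export
fret_efficiency <- function(tau_ad, tau_d) {
  stopifnot(all(tau_ad > 0), tau_d > 0)
  e <- 1 - tau_ad / tau_d
  bad <- tau_ad > tau_d
  if (any(bad))
    rlang::warn("tau_ad > tau_d for some entries: negative efficiency is non-physical (flagged, not clipped).")
  structure(e, nonphysical = if (any(bad)) bad else NULL)
}

#' Donor-acceptor distance from a FRET efficiency
#'
#' Inverts the Forster relation \eqn{E = R_0^6 / (R_0^6 + R^6)} to
#' \eqn{R = R_0 (1/E - 1)^{1/6}}. The result is strictly decreasing in `E`,
#' with `R = R0` exactly at `E = 0.5`.
#'
#' @param efficiency Transfer efficiency in (0, 1). Vectorized.
#' @param r0 Forster radius of the donor-acceptor pair, in Angstrom. There
#'   is no default: `r0` is a property of the probe pair and must be
#'   supplied.
#' @return Distance in the same units as `r0`.
#' @examples
#' distance_from_efficiency(0.5, r0 = 38.25)
#' @export
distance_from_efficiency <- function(efficiency, r0) {
  stopifnot(r0 > 0)
  if (any(efficiency <= 0 | efficiency >= 1))
    rlang::abort("Efficiency must lie strictly between 0 and 1.")
  r0 * (1 / efficiency - 1)^(1 / 6)
}

#' Donor-acceptor distance directly from lifetimes
#'
#' Convenience composition of [fret_efficiency()] and
#' [distance_from_efficiency()].
#'
#' @inheritParams fret_efficiency
#' @inheritParams distance_from_efficiency
#' @return Distance in the units of `r0`.
#' @export
distance_from_lifetime <- function(tau_ad, tau_d, r0) {
  e <- fret_efficiency(tau_ad, tau_d)
  distance_from_efficiency(as.numeric(e), r0)
}

# normalize a populations argument to a length-2 numeric (inactive, active)
as_two_state <- function(pops, active_index = 2L) {
  if (is.data.frame(pops)) pops <- pops$fraction_pct
  if (length(pops) != 2)
    rlang::abort("Exactly two state populations are required.")
  if (any(pops <= 0))
    rlang::abort("Both populations must be positive (a zero population gives an infinite equilibrium constant).")
  c(inactive = pops[-active_index], active = pops[active_index])
}

#' Two-state equilibrium constant from state populations
#'
#' \eqn{K = A_{active} / A_{inactive}} for a receptor exchanging between an
#' inactive and an active/active-like conformation.
#'
#' @param pops Two state populations: a length-2 numeric (percent or
#'   fraction; only the ratio matters) or a [molecular_fractions()] tibble.
#' @param active_index Which entry is the active state (default 2, the slow
#'   LRET component).
#' @return The equilibrium constant (dimensionless).
#' @examples
#' equilibrium_constant(c(35.3, 64.7))
#' @export
equilibrium_constant <- function(pops, active_index = 2L) {
  p <- as_two_state(pops, active_index)
  unname(p["active"] / p["inactive"])
}

#' Free-energy shift of a conformational equilibrium between two conditions
#'
#' Quantifies how a perturbation (a lipid, a G protein, a change of bilayer)
#' shifts the inactive/active free-energy difference of a two-state
#' receptor: \eqn{\Delta\Delta G = -RT \ln(K_{test}/K_{ref})} with
#' \eqn{K = A_{active}/A_{inactive}}. Stabilization of the active state in
#' the test condition gives a negative value. The function is antisymmetric
#' under swapping reference and test and additive along chains of
#' conditions.
#'
#' @param pops_reference,pops_test State populations of the reference and
#'   test conditions (see [equilibrium_constant()]).
#' @param temperature_k Absolute temperature in Kelvin, in the physiological
#'   assay window 273-320 K (default 298.15 K).
#' @param active_index Which entry is the active state (default 2).
#' @return A tibble with columns `k_reference`, `k_test`, `ddg_kcal_mol`
#'   (signed) and `abs_ddg_kcal_mol`.
#' @examples
#' delta_delta_g(c(35.3, 64.7), c(21.8, 78.2))
#' @export
delta_delta_g <- function(pops_reference, pops_test,
                          temperature_k = 298.15, active_index = 2L) {
  stopifnot(temperature_k >= 273, temperature_k <= 320)
  k_ref <- equilibrium_constant(pops_reference, active_index)
  k_test <- equilibrium_constant(pops_test, active_index)
  ddg <- -GAS_CONSTANT_KCAL * temperature_k * log(k_test / k_ref)
  tibble::tibble(k_reference = k_ref, k_test = k_test,
                 ddg_kcal_mol = ddg, abs_ddg_kcal_mol = abs(ddg))
}

#' Free-energy shifts for a table of condition pairs
#'
#' Tidy wrapper around [delta_delta_g()]: given a table of per-condition
#' state populations (such as [ghsr_lifetimes()]) and a table of
#' (reference, test) condition pairs, computes the equilibrium constants and
#' the free-energy shift for every pair.
#'
#' @param populations A data frame with columns `condition`, `a1_pct`
#'   (inactive/fast fraction) and `a2_pct` (active/slow fraction).
#' @param pairs A data frame with columns `reference` and `test` naming
#'   conditions present in `populations`.
#' @inheritParams delta_delta_g
#' @return `pairs` augmented with `k_reference`, `k_test`, `ddg_kcal_mol`,
#'   `abs_ddg_kcal_mol`.
#' @examples
#' ddg_table(ghsr_lifetimes(),
#'           tibble::tibble(reference = "GHSR/ghrelin/POPC",
#'                          test = "GHSR/ghrelin/POPC + PIP2"))
#' @export
ddg_table <- function(populations, pairs, temperature_k = 298.15) {
  stopifnot(all(c("condition", "a1_pct", "a2_pct") %in% names(populations)),
            all(c("reference", "test") %in% names(pairs)))
  missing <- setdiff(c(pairs$reference, pairs$test), populations$condition)
  if (length(missing))
    rlang::abort(paste0("Conditions absent from `populations`: ",
                        paste(missing, collapse = ", ")))
  lookup <- function(cond) {
    row <- populations[populations$condition == cond, ][1, ]
    c(row$a1_pct, row$a2_pct)
  }
  dplyr::bind_cols(
    tibble::as_tibble(pairs),
    purrr::map2_dfr(pairs$reference, pairs$test,
                    ~ delta_delta_g(lookup(.x), lookup(.y),
                                    temperature_k = temperature_k))
  )
}
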