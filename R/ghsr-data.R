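#' Sensitized-emission lifetimes and molecular fractions for GHSR
#'
#' Reference table of two-component LRET decay parameters for the ghrelin
#' receptor (GHSR) in nanodiscs under fourteen lipid / ligand / G-protein
#' conditions: fast and slow sensitized-emission lifetimes (`tau1_us`,
#' `tau2_us`, in microseconds) with their uncertainties, and the molecular
#' fractions of the two conformational states (`a1_pct`, `a2_pct`, in percent
#' of the total population). The fast component is assigned to the inactive
#' state and the slow component to the active/active-like state (for
#' receptor-alone measurements) or to the active receptor:G-protein complex
#' (for measurements in the presence of Gq or Gi2).
#'
#' These parameters are the natural inputs of [generate_decay()] (to rebuild
#' a decay curve for a condition) and of [delta_delta_g()] (to quantify how a
#' lipid shifts the inactive/active equilibrium).
#'
#' @return A tibble with columns `condition`, `tau1_us`, `tau1_sd`,
#'   `a1_pct`, `a1_sd`, `tau2_us`, `tau2_sd`, `a2_pct`, `a2_sd`.
#' @examples
#' ghsr_lifetimes()
#' @export
ghsr_lifetimes <- function() {
  tibble::tribble(
    ~condition, ~tau1_us, ~tau1_sd, ~a1_pct, ~a1_sd, ~tau2_us, ~tau2_sd, ~a2_pct, ~a2_sd,
    "GHSR/ghrelin/POPC",             294.0,  7.2, 35.3, 0.7,  826.8, 13.8, 64.7, 0.3,
    "GHSR/ghrelin/POPC + PIP2",      289.4,  8.4, 21.8, 0.3,  815.7, 14.7, 78.2, 1.1,
    "GHSR/DMoPC",                    267.2, 18.7, 63.7, 0.8,  557.8, 12.2, 36.3, 0.9,
    "GHSR/DOPC",                     275.9, 11.5, 64.2, 0.9,  854.7, 17.9, 35.8, 0.2,
    "GHSR/ghrelin/DMoPC",            281.7,  8.2, 39.1, 0.5,  547.2, 14.3, 60.9, 0.8,
    "GHSR/ghrelin/DOPC",             286.3,  9.6, 34.8, 0.2,  834.6, 17.9, 65.2, 0.3,
    "GHSR/ghrelin/POPC/Gq",          599.3,  9.0, 25.0, 0.8, 1070.2,  9.9, 75.0, 1.0,
    "GHSR/ghrelin/POPC + PIP2/Gq",   617.2, 13.5, 11.7, 1.1, 1062.0, 11.3, 88.3, 1.3,
    "GHSR/ghrelin/POPC/Gi2",         891.7, 14.1,  4.3, 0.3, 1074.6, 18.9, 95.7, 0.2,
    "GHSR/ghrelin/POPC + PIP2/Gi2",  881.2, 15.7,  2.7, 0.5, 1049.3, 19.3, 97.3, 0.9,
    "GHSR/ghrelin/DMoPC/Gq",         613.6, 16.3, 92.5, 0.8, 1074.7,  7.7,  7.5, 0.5,
    "GHSR/ghrelin/DOPC/Gq",          595.2, 14.9, 24.8, 1.2, 1069.4, 11.7, 75.2, 1.3,
    "GHSR/ghrelin/DMoPC/Gi2",        918.4,  6.8, 96.4, 1.0, 1026.3, 13.3,  3.6, 1.2,
    "GHSR/ghrelin/DOPC/Gi2",         898.1, 12.1,  3.2, 0.9, 1029.8,  8.1, 96.8, 0.7
  )
}

#' Intracellular PIP2-binding sites of GHSR
#'
#' Residue definitions of the three basic-residue clusters on the cytoplasmic
#' face of GHSR that bind the phosphoinositide PIP2: site 1 at the TM1/ICL1 +
#' TM4 junction, site 2 on TM5/TM6, and site 3 at the TM7/H8 interface.
#' Residues carry Ballesteros-Weinstein generic labels where the position
#' falls inside a transmembrane helix. `max_lipids` is the maximum number of
#' lipids observed simultaneously bound at the site.
#'
#' Use with [lipid_bound_to_site()] and [occupancy_histogram()] to score
#' contact tables against these sites.
#'
#' @return A tibble with columns `site`, `residue_id`, `bw_label`,
#'   `max_lipids`.
#' @examples
#' ghsr_pip2_sites()
#' @export
ghsr_pip2_sites <- function() {
  tibble::tribble(
    ~site,   ~residue_id, ~bw_label, ~max_lipids,
    "site1",  70L, "1.59", 2L,
    "site1",  72L, NA,     2L,
    "site1", 157L, "4.39", 2L,
    "site1", 161L, "4.43", 2L,
    "site2", 237L, "5.63", 2L,
    "site2", 242L, "5.68", 2L,
    "site2", 243L, "5.69", 2L,
    "site2", 244L, "5.70", 2L,
    "site2", 259L, "6.31", 2L,
    "site3", 328L, "8.48", 1L,
    "site3", 331L, "8.51", 1L
  )
}
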