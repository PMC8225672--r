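#' Call lipid-residue contacts from minimal distances
#'
#' Converts a per-frame lipid-residue minimal-distance table into boolean
#' contacts: an entry is a contact iff `min_distance_nm <= cutoff`
#' (inclusive boundary). A table that already carries a logical `contact`
#' column is returned unchanged (idempotent); a table mixing distance and
#' contact information with missing values is rejected.
#'
#' @param traj A long data frame with at least columns `frame`, `lipid_id`,
#'   `residue_id` and either `min_distance_nm` (positive) or a logical
#'   `contact`.
#' @param cutoff Contact cutoff in nm (> 0). 0.6 nm between lipid headgroup
#'   and residue beads is common coarse-grained practice.
#' @return The input with a logical `contact` column.
#' @examples
#' traj <- generate_contact_trajectory(ghsr_pip2_sites(), n_frames = 100, seed = 1)
#' contacts_from_distances(traj)
#' @export
contacts_from_distances <- function(traj, cutoff = 0.6) {
  stopifnot(cutoff > 0)
  check_contact_columns(traj)
  if ("contact" %in% names(traj)) {
    if (anyNA(traj$contact))
      rlang::abort("`contact` column contains missing values (mixed boolean/distance input).")
    return(traj)
  }
  if (anyNA(traj$min_distance_nm) || any(traj$min_distance_nm <= 0))
    rlang::abort("`min_distance_nm` must be positive with no missing values.")
  dplyr::mutate(traj, contact = .data$min_distance_nm <= cutoff)
}

check_contact_columns <- function(traj) {
  need <- c("frame", "lipid_id", "residue_id")
  if (!all(need %in% names(traj)))
    rlang::abort(paste0("Contact table needs columns: ",
                        paste(need, collapse = ", "), "."))
  if (!any(c("min_distance_nm", "contact") %in% names(traj)))
    rlang::abort("Contact table needs either `min_distance_nm` or `contact`.")
  invisible(traj)
}

#' Per-frame bound lipids at a binding site
#'
#' A lipid is bound to a site in a frame iff it contacts at least
#' `min_residues` of the site's residues in that frame (the multi-residue
#' requirement suppresses grazing single-residue contacts). Optional dwell
#' smoothing closes unbound gaps of at most `gap` frames inside a bound run,
#' treating brief excursions as part of one binding event.
#'
#' @param traj A contact table (see [contacts_from_distances()]; distances
#'   are converted with `cutoff` if no `contact` column is present).
#' @param site A data frame with column `residue_id` listing the residues of
#'   one site (e.g. one site of [ghsr_pip2_sites()]).
#' @param min_residues Minimum simultaneous residue contacts for "bound"
#'   (default 2).
#' @param gap Dwell-smoothing gap in frames (default 0 = off).
#' @param cutoff Contact cutoff in nm, used only when `traj` has no
#'   `contact` column.
#' @return A tibble with one row per (frame, lipid): `frame`, `lipid_id`,
#'   `species` (if present in `traj`), `bound`.
#' @examples
#' traj <- generate_contact_trajectory(ghsr_pip2_sites(), n_frames = 200, seed = 1)
#' site3 <- dplyr::filter(ghsr_pip2_sites(), site == "site3")
#' head(lipid_bound_to_site(traj, site3))
#' @export
lipid_bound_to_site <- function(traj, site, min_residues = 2, gap = 0,
                                cutoff = 0.6) {
  stopifnot(min_residues >= 1, gap >= 0)
  res <- unique(site$residue_id)
  if (length(res) == 0) rlang::abort("Site has no residues.")
  missing <- setdiff(res, unique(traj$residue_id))
  if (length(missing))
    rlang::abort(paste0("Site residues absent from the trajectory: ",
                        paste(missing, collapse = ", ")))
  traj <- contacts_from_distances(traj, cutoff)
  frames <- sort(unique(traj$frame))
  has_species <- "species" %in% names(traj)

  bound <- traj |>
    dplyr::filter(.data$residue_id %in% res) |>
    dplyr::group_by(.data$frame, .data$lipid_id) |>
    dplyr::summarise(n_contacts = sum(.data$contact),
                     species = if (has_species) dplyr::first(.data$species) else NA_character_,
                     .groups = "drop") |>
    dplyr::mutate(bound = .data$n_contacts >= min_residues) |>
    dplyr::select(-"n_contacts")
  # complete to the full frame x lipid grid (absent rows are unbound)
  lip <- dplyr::distinct(traj, .data$lipid_id,
                         species = if (has_species) .data$species else NA_character_)
  grid <- tidyr::expand_grid(frame = frames, lip)
  bound <- grid |>
    dplyr::left_join(bound, by = c("frame", "lipid_id", "species")) |>
    dplyr::mutate(bound = !is.na(.data$bound) & .data$bound) |>
    dplyr::arrange(.data$lipid_id, .data$frame)
  if (gap > 0) {
    bound <- bound |>
      dplyr::group_by(.data$lipid_id) |>
      dplyr::mutate(bound = close_gaps(.data$bound, gap)) |>
      dplyr::ungroup()
  }
  if (!has_species) bound$species <- NULL
  bound
}

# close FALSE runs of length <= gap that are flanked by TRUE on both sides
close_gaps <- function(bound, gap) {
  r <- rle(bound)
  n <- length(r$values)
  if (n >= 3) {
    interior <- which(!r$values & r$lengths <= gap &
                        seq_len(n) > 1 & seq_len(n) < n)
    r$values[interior] <- TRUE
  }
  inverse.rle(r)
}

#' Occupancy histogram of a binding site
#'
#' Distribution of the number of simultaneously bound lipids at a site: the
#' percentage of frames with exactly N bound lipids, N = 0, 1, 2, ... The
#' percentages form an exact partition (sum 100, no negative bins).
#'
#' @param bound A per-frame bound table from [lipid_bound_to_site()].
#' @param max_lipids Optional expected maximum simultaneous occupancy; a
#'   larger observed N triggers a warning.
#' @return A tibble with columns `n_bound` and `pct_frames`.
#' @examples
#' traj <- generate_contact_trajectory(ghsr_pip2_sites(), n_frames = 500, seed = 1)
#' site3 <- dplyr::filter(ghsr_pip2_sites(), site == "site3")
#' occupancy_histogram(lipid_bound_to_site(traj, site3))
#' @export
occupancy_histogram <- function(bound, max_lipids = NULL) {
  stopifnot(all(c("frame", "bound") %in% names(bound)))
  per_frame <- bound |>
    dplyr::group_by(.data$frame) |>
    dplyr::summarise(n_bound = sum(.data$bound), .groups = "drop")
  n_max <- max(per_frame$n_bound)
  if (!is.null(max_lipids) && n_max > max_lipids)
    rlang::warn(sprintf("Observed up to %d bound lipids; site maximum is %d.",
                        n_max, max_lipids))
  counts <- tabulate(per_frame$n_bound + 1L, nbins = n_max + 1L)
  tibble::tibble(n_bound = 0:n_max,
                 pct_frames = 100 * counts / nrow(per_frame))
}

#' Full occupancy profile of a contact trajectory
#'
#' Combines the per-residue and per-site views of a lipid-contact
#' trajectory: the fraction of frames in which each residue is contacted by
#' any lipid, and, for each site, the bound-lipid count histogram and its
#' mean.
#'
#' @inheritParams lipid_bound_to_site
#' @param sites A site-definition table with columns `site`, `residue_id`
#'   (e.g. [ghsr_pip2_sites()]).
#' @return An object of class `occupancy_profile`: a list with
#'   `per_residue` (tibble: `residue_id`, `contact_fraction`), `per_site`
#'   (tibble: `site`, `n_bound`, `pct_frames`), `mean_occupancy` (tibble:
#'   `site`, `mean_bound`), plus the `cutoff` and `min_residues` used.
#'   Supports [tidy()] and [ggplot2::autoplot()].
#' @examples
#' traj <- generate_contact_trajectory(ghsr_pip2_sites(), n_frames = 300, seed = 2)
#' occupancy_profile(traj, ghsr_pip2_sites())
#' @export
occupancy_profile <- function(traj, sites, cutoff = 0.6, min_residues = 2,
                              gap = 0) {
  traj <- contacts_from_distances(traj, cutoff)
  n_frames <- dplyr::n_distinct(traj$frame)
  per_residue <- traj |>
    dplyr::filter(.data$contact) |>
    dplyr::distinct(.data$frame, .data$residue_id) |>
    dplyr::count(.data$residue_id) |>
    dplyr::mutate(contact_fraction = .data$n / n_frames) |>
    dplyr::select("residue_id", "contact_fraction") |>
    dplyr::right_join(dplyr::distinct(sites, .data$residue_id),
                      by = "residue_id") |>
    dplyr::mutate(contact_fraction = dplyr::coalesce(.data$contact_fraction, 0)) |>
    dplyr::arrange(.data$residue_id)
  site_names <- unique(sites$site)
  hists <- purrr::map(site_names, function(s) {
    b <- lipid_bound_to_site(traj, sites[sites$site == s, ],
                             min_residues = min_residues, gap = gap,
                             cutoff = cutoff)
    dplyr::mutate(occupancy_histogram(b), site = s, .before = 1)
  })
  per_site <- dplyr::bind_rows(hists)
  mean_occ <- per_site |>
    dplyr::group_by(.data$site) |>
    dplyr::summarise(mean_bound = sum(.data$n_bound * .data$pct_frames) / 100,
                     .groups = "drop")
  structure(list(per_residue = per_residue, per_site = per_site,
                 mean_occupancy = mean_occ,
                 cutoff = cutoff, min_residues = min_residues,
                 n_frames = n_frames),
            class = "occupancy_profile")
}

#' Lipid competition summary across species
#'
#' Mean bound-lipid count per site and species for a trajectory containing
#' two or more lipid species competing for the same sites, optionally paired
#' with a matched reference trajectory without the competitor. The
#' displacement statistic is the per-site, per-species difference in mean
#' occupancy between the two conditions.
#'
#' @inheritParams occupancy_profile
#' @param reference Optional matched contact trajectory (same sites) without
#'   the competitor; when supplied, occupancy differences
#'   (`delta_mean_bound` = traj - reference) are reported for the species
#'   common to both.
#' @return A tibble with columns `site`, `species`, `mean_bound` and, with a
#'   reference, `mean_bound_reference`, `delta_mean_bound`.
#' @export
competition_summary <- function(traj, sites, reference = NULL,
                                cutoff = 0.6, min_residues = 2) {
  if (!"species" %in% names(traj))
    rlang::abort("Competition analysis needs a `species` column.")
  if (dplyr::n_distinct(traj$species) < 2 && is.null(reference))
    rlang::abort("At least two lipid species (or a reference trajectory) are required.")
  summarise_one <- function(tr) {
    tr <- contacts_from_distances(tr, cutoff)
    purrr::map_dfr(unique(sites$site), function(s) {
      b <- lipid_bound_to_site(tr, sites[sites$site == s, ],
                               min_residues = min_residues, cutoff = cutoff)
      b |>
        dplyr::group_by(.data$frame, .data$species) |>
        dplyr::summarise(n_bound = sum(.data$bound), .groups = "drop") |>
        dplyr::group_by(.data$species) |>
        dplyr::summarise(mean_bound = mean(.data$n_bound), .groups = "drop") |>
        dplyr::mutate(site = s, .before = 1)
    })
  }
  out <- summarise_one(traj)
  if (!is.null(reference)) {
    ref <- summarise_one(reference) |>
      dplyr::rename(mean_bound_reference = "mean_bound")
    out <- out |>
      dplyr::left_join(ref, by = c("site", "species")) |>
      dplyr::mutate(delta_mean_bound = .data$mean_bound - .data$mean_bound_reference)
  }
  out
}
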