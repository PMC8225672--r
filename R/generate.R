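#' Generate a multi-exponential sensitized-emission decay trace
#'
#' Simulates the raw observable of an LRET experiment: the acceptor
#' sensitized-emission intensity as a sum of exponential components
#' \eqn{I(t) = b + \sum_i \alpha_i e^{-t/\tau_i}}, sampled on a regular time
#' grid and peak-normalized to 1 before noise is added (instrument output is
#' reported as normalized fluorescence intensity). Each component is one
#' conformational species; its amplitude share is its molecular fraction.
#'
#' @param lifetimes_us Component lifetimes in microseconds (all > 0).
#' @param shares Amplitude shares, one per component; must sum to 1.
#' @param baseline Constant offset, in the same (normalized) intensity units.
#' @param t_start,t_stop,t_step Time grid in microseconds. The default
#'   0--4000 µs at 2 µs covers more than four times the slowest lifetime in
#'   the reference conditions of [ghsr_lifetimes()].
#' @param noise One of `"none"`, `"gaussian"` (additive, sd =
#'   `noise_level` x peak) or `"poisson"` (counting noise with
#'   `peak_counts` expected counts at the peak).
#' @param noise_level Gaussian noise sd as a fraction of the peak intensity.
#' @param peak_counts Expected photon counts at the peak for Poisson noise.
#' @param label Free-text species descriptor copied into the output.
#' @param seed Optional integer seed; fixing it makes the noisy trace
#'   reproducible without touching the caller's RNG stream.
#'
#' @return A tibble with columns `time_us`, `intensity`, `label`, carrying
#'   the generating parameters in attribute `"truth"`.
#' @examples
#' tr <- generate_decay(c(294, 826.8), c(0.353, 0.647))
#' head(tr)
#' @seealso [fit_decay()] for the inverse operation.
#' @export
generate_decay <- function(lifetimes_us, shares,
                           baseline = 0,
                           t_start = 0, t_stop = 4000, t_step = 2,
                           noise = c("none", "gaussian", "poisson"),
                           noise_level = 0.01, peak_counts = 1e4,
                           label = "synthetic", seed = NULL) {
  noise <- rlang::arg_match(noise)
  stopifnot(length(lifetimes_us) == length(shares), all(lifetimes_us > 0),
            all(shares >= 0), baseline >= 0, t_step > 0, t_stop > t_start)
  if (abs(sum(shares) - 1) > 1e-8)
    rlang::abort("`shares` must sum to 1.")
  if (t_step > min(lifetimes_us) / 10)
    rlang::warn("Time step exceeds one tenth of the fastest lifetime; the fast component is under-sampled.")
  t <- seq(t_start, t_stop, by = t_step)
  y <- baseline + colSums(shares * exp(outer(-1 / lifetimes_us, t)))
  peak <- max(y)
  y <- y / peak
  if (noise != "none") {
    y <- local_seed(seed, {
      switch(noise,
        gaussian = y + stats::rnorm(length(y), sd = noise_level),
        poisson  = stats::rpois(length(y), lambda = pmax(y, 0) * peak_counts) / peak_counts
      )
    })
  }
  out <- tibble::tibble(time_us = t, intensity = y, label = label)
  attr(out, "truth") <- list(lifetimes_us = lifetimes_us, shares = shares,
                             baseline = baseline / peak, noise = noise)
  out
}

#' Generate a Tr-FRET lipid titration series
#'
#' Simulates the acceptor/donor Tr-FRET ratio as a function of lipid load
#' (lipid-to-receptor molar ratio) under a hyperbolic specific component plus
#' a linear nonspecific term:
#' \eqn{r(x) = \mathrm{offset} + B_{max} x / (K_{1/2} + x) + s\,x}.
#' With `bmax = 0` the series is the control-lipid (nonspecific-only) limit.
#'
#' @param x Lipid load grid (non-negative, non-decreasing).
#' @param bmax Specific plateau, in ratio units.
#' @param k_half Half-saturation load, same units as `x`. The default 0.24
#'   puts the 95%-of-plateau point (19 k_half) at a lipid-to-receptor ratio
#'   of about 4.6, the saturation regime of the reference assay.
#' @param ns_slope Nonspecific slope, ratio units per unit `x`.
#' @param offset Ratio at zero lipid.
#' @param noise_sd Additive Gaussian noise sd, in ratio units.
#' @param lipid_label Label copied into the output.
#' @param seed Optional integer seed.
#'
#' @return A tibble with columns `x`, `ratio`, `lipid_label`, with the
#'   generating parameters in attribute `"truth"`.
#' @seealso [fit_saturation()]
#' @export
generate_titration <- function(x = seq(0, 7, by = 0.5),
                               bmax = 0.30, k_half = 0.24,
                               ns_slope = 0.005, offset = 0.05,
                               noise_sd = 0, lipid_label = "Bodipy-FL PIP2",
                               seed = NULL) {
  stopifnot(all(x >= 0), !is.unsorted(x), bmax >= 0, k_half > 0, ns_slope >= 0)
  r <- offset + bmax * x / (k_half + x) + ns_slope * x
  if (noise_sd > 0)
    r <- local_seed(seed, r + stats::rnorm(length(r), sd = noise_sd))
  out <- tibble::tibble(x = x, ratio = r, lipid_label = lipid_label)
  attr(out, "truth") <- list(bmax = bmax, k_half = k_half,
                             ns_slope = ns_slope, offset = offset)
  out
}

#' Generate a Gaussian-band emission spectrum
#'
#' Simulates a single-band fluorescence emission spectrum, the input of
#' [emission_lambda_max()]: a Gaussian profile centered at `lambda_max` with
#' sd `width_nm`, scaled to `peak_intensity`, with optional additive noise.
#'
#' @param wavelength_nm Wavelength grid in nm.
#' @param lambda_max Band center, nm.
#' @param width_nm Gaussian sd of the band, nm.
#' @param peak_intensity Intensity at the band center.
#' @param noise_level Gaussian noise sd as a fraction of the peak.
#' @param condition Label copied into the output.
#' @param seed Optional integer seed.
#' @return A tibble with columns `wavelength_nm`, `intensity`, `condition`.
#' @export
generate_spectrum <- function(wavelength_nm = seq(400, 560, by = 1),
                              lambda_max = 470, width_nm = 25,
                              peak_intensity = 1, noise_level = 0,
                              condition = "synthetic", seed = NULL) {
  stopifnot(width_nm > 0, peak_intensity > 0)
  y <- peak_intensity * exp(-(wavelength_nm - lambda_max)^2 / (2 * width_nm^2))
  if (noise_level > 0)
    y <- local_seed(seed, y + stats::rnorm(length(y), sd = noise_level * peak_intensity))
  tibble::tibble(wavelength_nm = wavelength_nm, intensity = y,
                 condition = condition)
}

#' Generate a two-state Markov lipid-residue contact trajectory
#'
#' Stands in for contact tables exported from coarse-grained simulations of a
#' membrane receptor: for every lipid x site pair, a bound/unbound two-state
#' Markov chain is evolved in discrete frames with per-frame binding
#' (`on_rate`) and unbinding (`off_rate`) probabilities, so the stationary
#' bound probability is `on_rate / (on_rate + off_rate)` in closed form.
#' While bound, the lipid sits at `cutoff - delta` nm from every residue of
#' the site; while unbound at `cutoff + delta`, so a downstream contact call
#' at `cutoff` is unambiguous.
#'
#' @param sites Site definition tibble with columns `site`, `residue_id`
#'   (e.g. [ghsr_pip2_sites()]).
#' @param n_frames Number of frames to simulate.
#' @param lipids Tibble with one row per lipid: columns `lipid_id`,
#'   `species`, `leaflet`, and per-lipid `on_rate`, `off_rate` (probabilities
#'   per frame, in (0, 1)). A lipid interacts with every site with the same
#'   rates; distinct chains are evolved per site.
#' @param cutoff,delta Distance bookkeeping in nm (see above).
#' @param start_bound Logical; start each chain in the bound state instead of
#'   drawing the initial state from the stationary distribution.
#' @param seed Optional integer seed.
#'
#' @return A long tibble with columns `frame`, `lipid_id`, `species`,
#'   `leaflet`, `residue_id`, `min_distance_nm`.
#' @seealso [contacts_from_distances()], [lipid_bound_to_site()]
#' @export
generate_contact_trajectory <- function(sites, n_frames = 1000,
                                        lipids = tibble::tibble(
                                          lipid_id = "PIP2_1", species = "PIP2",
                                          leaflet = "intracellular",
                                          on_rate = 0.03, off_rate = 0.02),
                                        cutoff = 0.6, delta = 0.1,
                                        start_bound = FALSE, seed = NULL) {
  stopifnot(all(c("site", "residue_id") %in% names(sites)),
            all(c("lipid_id", "species", "on_rate", "off_rate") %in% names(lipids)),
            all(lipids$on_rate > 0 & lipids$on_rate < 1),
            all(lipids$off_rate >= 0 & lipids$off_rate < 1),
            cutoff > 0, delta > 0, delta < cutoff)
  if (n_frames < 100)
    rlang::warn("Fewer than 100 frames; occupancy estimates will be unstable.")
  if (!"leaflet" %in% names(lipids)) lipids$leaflet <- "intracellular"
  site_split <- split(sites$residue_id, sites$site)
  local_seed(seed, {
    rows <- purrr::map(seq_len(nrow(lipids)), function(i) {
      lp <- lipids[i, ]
      purrr::map(names(site_split), function(s) {
        bound <- markov_chain(n_frames, lp$on_rate, lp$off_rate, start_bound)
        res <- site_split[[s]]
        tibble::tibble(
          frame = rep(seq_len(n_frames), each = length(res)),
          lipid_id = lp$lipid_id, species = lp$species, leaflet = lp$leaflet,
          residue_id = rep(res, times = n_frames),
          min_distance_nm = ifelse(rep(bound, each = length(res)),
                                   cutoff - delta, cutoff + delta)
        )
      })
    })
    dplyr::bind_rows(rows)
  })
}

# evolve one two-state chain; returns logical vector of bound states
markov_chain <- function(n, on, off, start_bound = FALSE) {
  bound <- logical(n)
  p_stat <- on / (on + off)
  bound[1] <- if (start_bound) TRUE else stats::runif(1) < p_stat
  u <- stats::runif(n)
  for (i in seq_len(n - 1L)) {
    bound[i + 1L] <- if (bound[i]) u[i] >= off else u[i] < on
  }
  bound
}

# evaluate `expr` under a temporary RNG state when seed is given
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}
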