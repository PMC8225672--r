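sites <- ghsr_pip2_sites()
site3 <- sites[sites$site == "site3", ]

mini_traj <- function(dist) {
  tidyr::expand_grid(frame = 1:3, lipid_id = "L1", species = "PIP2",
                     residue_id = site3$residue_id) |>
    dplyr::mutate(min_distance_nm = dist)
}

test_that("contact call: inclusive boundary, monotone in cutoff, idempotent", {
  tr <- mini_traj(0.6)
  expect_true(all(contacts_from_distances(tr, 0.6)$contact))   # boundary contact
  expect_false(any(contacts_from_distances(tr, 0.59)$contact))
  # shrinking the cutoff never creates contacts
  tr2 <- mini_traj(runif(nrow(mini_traj(1)), 0.2, 1.2))
  big <- contacts_from_distances(tr2, 0.8)$contact
  small <- contacts_from_distances(tr2, 0.4)$contact
  expect_true(all(big[small]))
  # already-boolean input passes through unchanged
  withc <- contacts_from_distances(tr2, 0.8)
  expect_identical(contacts_from_distances(withc, 0.1), withc)
})

test_that("mixed boolean/distance input and bad distances are rejected", {
  tr <- contacts_from_distances(mini_traj(0.5), 0.6)
  tr$contact[2] <- NA
  expect_error(contacts_from_distances(tr, 0.6), "mixed")
  bad <- mini_traj(0.5); bad$min_distance_nm[1] <- -1
  expect_error(contacts_from_distances(bad, 0.6), "positive")
})

test_that("binding requires min_residues simultaneous contacts", {
  tr <- mini_traj(0.5)  # touches both site-3 residues every frame
  expect_true(all(lipid_bound_to_site(tr, site3, min_residues = 2)$bound))
  one_res <- dplyr::mutate(tr,
    min_distance_nm = ifelse(residue_id == 328, 0.5, 0.9))
  expect_false(any(lipid_bound_to_site(one_res, site3,
                                       min_residues = 2)$bound))
  expect_true(all(lipid_bound_to_site(one_res, site3,
                                      min_residues = 1)$bound))
  expect_error(lipid_bound_to_site(tr, sites[sites$site == "site1", ]),
               "absent")
})

test_that("dwell smoothing closes short unbound gaps only", {
  expect_identical(
    lretlipid:::close_gaps(c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE), 1),
    c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_identical(lretlipid:::close_gaps(c(FALSE, FALSE, TRUE), 5),
                   c(FALSE, FALSE, TRUE))  # leading gap untouched
})

test_that("occupancy histograms are exact partitions", {
  tr <- generate_contact_trajectory(site3, n_frames = 500, seed = 8)
  h <- occupancy_histogram(lipid_bound_to_site(tr, site3))
  expect_equal(sum(h$pct_frames), 100, tolerance = 1e-9)
  expect_true(all(h$pct_frames >= 0))
  # constant single bound lipid -> 100% at N = 1
  always <- lipid_bound_to_site(mini_traj(0.5), site3)
  h1 <- occupancy_histogram(always)
  expect_equal(h1$pct_frames[h1$n_bound == 1], 100)
  # empty site -> 100% at N = 0
  never <- lipid_bound_to_site(mini_traj(0.9), site3)
  h0 <- occupancy_histogram(never)
  expect_equal(h0$pct_frames[h0$n_bound == 0], 100)
})

test_that("independent per-frame binding at p = 0.65 gives ~65% single-occupancy", {
  set.seed(99)
  n <- 1e4
  bound <- tibble::tibble(frame = 1:n, lipid_id = "L1",
                          bound = runif(n) < 0.65)
  h <- occupancy_histogram(bound)
  se <- 100 * sqrt(0.65 * 0.35 / n)
  expect_lt(abs(h$pct_frames[h$n_bound == 1] - 65), 3 * se)
})

test_that("estimated occupancy converges to the Markov stationary value", {
  # stationary 0.4 and 0.6, the regime of the site-3 active/inactive contrast
  for (rates in list(c(0.02, 0.03, 0.4), c(0.03, 0.02, 0.6))) {
    for (n in c(1e3, 1e5)) {
      tr <- generate_contact_trajectory(site3, n_frames = n,
        lipids = tibble::tibble(lipid_id = "L1", species = "PIP2",
                                leaflet = "intracellular",
                                on_rate = rates[1], off_rate = rates[2]),
        seed = 21)
      b <- lipid_bound_to_site(tr, site3)
      expect_lt(abs(mean(b$bound) - rates[3]), 3 * markov_se(rates[1], rates[2], n))
    }
  }
})

test_that("subsampling frames 1:10 leaves mean occupancy within 3 SE", {
  tr <- generate_contact_trajectory(site3, n_frames = 2e4, seed = 31)
  b <- lipid_bound_to_site(tr, site3)
  full <- mean(b$bound)
  sub <- mean(b$bound[b$frame %% 10 == 0])
  expect_lt(abs(full - sub), 3 * markov_se(0.03, 0.02, 2e3))
})

test_that("competition: null competitor leaves occupancy unchanged; symmetric rates share the site", {
  lips <- tibble::tibble(
    lipid_id = c("P1", "G1"), species = c("PIP2", "GM3"),
    leaflet = "intracellular",
    on_rate = c(0.03, 1e-9), off_rate = c(0.02, 0.9))
  tr <- generate_contact_trajectory(site3, n_frames = 5000, lipids = lips,
                                    seed = 41)
  cs <- competition_summary(tr, site3)
  pip2 <- cs$mean_bound[cs$species == "PIP2"]
  expect_lt(abs(pip2 - 0.6), 3 * markov_se(0.03, 0.02, 5000))
  expect_lt(cs$mean_bound[cs$species == "GM3"], 0.01)
  # equal rates: each species occupies about half the frames
  lips_eq <- tibble::tibble(
    lipid_id = c("P1", "G1"), species = c("PIP2", "GM3"),
    leaflet = "intracellular", on_rate = 0.05, off_rate = 0.05)
  tr_eq <- generate_contact_trajectory(site3, n_frames = 5000,
                                       lipids = lips_eq, seed = 43)
  cs_eq <- competition_summary(tr_eq, site3)
  expect_lt(max(abs(cs_eq$mean_bound - 0.5)), 3 * markov_se(0.05, 0.05, 5000))
})

test_that("removing the competitor reproduces the single-species histogram exactly", {
  lips <- tibble::tibble(
    lipid_id = c("P1", "G1"), species = c("PIP2", "GM3"),
    leaflet = "intracellular", on_rate = c(0.03, 0.04),
    off_rate = c(0.02, 0.04))
  tr <- generate_contact_trajectory(site3, n_frames = 1000, lipids = lips,
                                    seed = 47)
  solo <- dplyr::filter(tr, species == "PIP2")
  h_from_pair <- occupancy_histogram(
    dplyr::filter(lipid_bound_to_site(tr, site3), species == "PIP2"))
  h_solo <- occupancy_histogram(lipid_bound_to_site(solo, site3))
  expect_equal(h_from_pair, h_solo)
  expect_error(competition_summary(solo, site3), "two lipid species")
})

test_that("occupancy_profile assembles per-residue and per-site views", {
  tr <- generate_contact_trajectory(sites, n_frames = 300, seed = 53)
  prof <- occupancy_profile(tr, sites)
  expect_setequal(prof$per_residue$residue_id, unique(sites$residue_id))
  expect_true(all(prof$per_residue$contact_fraction >= 0 &
                    prof$per_residue$contact_fraction <= 1))
  sums <- tapply(prof$per_site$pct_frames, prof$per_site$site, sum)
  expect_equal(as.vector(sums), rep(100, 3), tolerance = 1e-9)
  expect_s3_class(tidy(prof), "tbl_df")
})
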