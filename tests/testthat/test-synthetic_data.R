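test_that("Markov chain honours its stationary occupancy", {
  site1 <- site_definition("s", "A", 1)
  # symmetric rates at L = 10: stationary occupancy 50%
  m <- kinetic_site_model(0.01, 0.1, n_residues = 1L)
  ser <- simulate_contact_series(m, free_ligand = 10, frames = 4e4L, seed = 1)
  occ <- site_occupancy(ser, site1)
  expect_lt(abs(occ - 50), 2)
  # absorbing bound state
  m0 <- kinetic_site_model(0.05, 0, n_residues = 1L)
  ser0 <- simulate_contact_series(m0, 10, 500L, seed = 2)
  expect_equal(site_occupancy(ser0, site1), 100)
  # stationary occupancy matches L/(Kd+L) within a binomial CI at several L
  for (L in c(2.5, 10, 30)) {
    ser <- simulate_contact_series(m, L, 2e4L, seed = 100 + L)
    p <- L / (10 + L)
    # effective samples ~ frames / correlation time; generous 5-sigma band
    tol <- 5 * sqrt(p * (1 - p) / (2e4 / 10)) * 100
    expect_lt(abs(site_occupancy(ser, site1) - 100 * p), tol)
  }
})

test_that("rates too large for the frame step are rejected", {
  m <- kinetic_site_model(0.2, 0.1)
  expect_error(simulate_contact_series(m, free_ligand = 10, frames = 10,
                                       seed = 1), "probability > 1")
})

test_that("emission probability thins residue contacts while bound", {
  m <- kinetic_site_model(0.05, 0, n_residues = 6L,
                          residue_emission_prob = 0.5)
  ser <- simulate_contact_series(m, 10, 5000L, seed = 3)  # always bound
  site <- site_definition("s", rep("A", 6), 1:6)
  expect_lt(abs(site_occupancy(ser, site) - 50), 3)
})

test_that("generate_saturation_dataset is deterministic and truthful", {
  m <- kinetic_site_model(0.01, 0.1)
  d1 <- generate_saturation_dataset(m, concentrations = c(1, 5, 20),
                                    replicates = 2L, frames = 500L,
                                    base_seed = 9L)
  d2 <- generate_saturation_dataset(m, concentrations = c(1, 5, 20),
                                    replicates = 2L, frames = 500L,
                                    base_seed = 9L)
  expect_identical(d1$points, d2$points)
  expect_equal(d1$ground_truth_kd, 10)
  expect_equal(d1$ground_truth_bmax, 100)
  d3 <- generate_saturation_dataset(m, concentrations = c(1, 5, 20),
                                    replicates = 2L, frames = 500L,
                                    base_seed = 10L)
  expect_false(identical(d1$points$y, d3$points$y))
  expect_error(generate_saturation_dataset(m, concentrations = c(1, 5)),
               ">= 3")
})

test_that("snapshot ensemble conserves counts and responds to well depth", {
  m <- spatial_ensemble_model(n_chol = 40L, n_popc = 30L)
  ens <- simulate_snapshot_ensemble(m, frames = 5L, seed = 21)
  sys <- ens$system
  expect_equal(length(molecules_of(sys, "CHOL")), 40L)
  expect_equal(length(molecules_of(sys, "POPC")), 30L)
  expect_equal(n_frames(sys), 5L)
  # determinism
  ens2 <- simulate_snapshot_ensemble(m, frames = 5L, seed = 21)
  expect_identical(sys$coords, ens2$system$coords)
  # site occupancy count grows with |well depth|
  in_site <- function(e) {
    sel <- which(e$system$molecule_species[e$system$bead_molecule] == "CHOL")
    d2 <- sweep(matrix(e$system$coords[sel, , 1], ncol = 3), 2,
                m$site_centers[1, ])
    sum(rowSums(d2^2) < m$site_radii[1]^2)
  }
  m_flat <- spatial_ensemble_model(n_chol = 40L, n_popc = 30L, well_depths = 0)
  deep <- mean(vapply(1:10, function(s) {
    in_site(simulate_snapshot_ensemble(m, 1L, seed = s))
  }, numeric(1)))
  flat <- mean(vapply(1:10, function(s) {
    in_site(simulate_snapshot_ensemble(m_flat, 1L, seed = s))
  }, numeric(1)))
  expect_gt(deep, flat)
})

test_that("uniform (zero-well) ensemble gives a near-zero free energy", {
  m <- spatial_ensemble_model(n_chol = 200L, well_depths = 0)
  ens <- simulate_snapshot_ensemble(m, frames = 40L, seed = 33)
  sys <- ens$system
  sel <- which(sys$molecule_species[sys$bead_molecule] == "CHOL")
  g <- accumulate_density(sys, sel, grid_spec(c(0, 0, 0), sys$box[1, ], 0.1))
  site <- site_mask(g, m$site_centers[1, ], m$site_radii[1] - 0.1)
  bulk <- bulk_mask(g, sys, z_slab = c(3.2, 6.8), min_protein_distance = 2,
                    exclude = list(site_mask(g, m$site_centers[1, ],
                                             m$site_radii[1] + 0.2)))
  expect_lt(abs(binding_free_energy(g, site, bulk, 310)), 0.6)
})

test_that("site regions overlapping the protein proxy are rejected", {
  expect_error(spatial_ensemble_model(site_centers = matrix(c(5.5, 5, 6), 1)),
               "overlaps")
  expect_error(spatial_ensemble_model(site_centers = matrix(c(9.9, 5, 6), 1)),
               "outside the box")
  expect_error(spatial_ensemble_model(well_depths = 2), "well_depths")
})

test_that("written ensembles reload identically through the file path", {
  tmp <- withr::local_tempdir()
  m <- spatial_ensemble_model(n_chol = 4L, n_popc = 3L)
  ens <- simulate_snapshot_ensemble(m, frames = 3L, seed = 12)
  paths <- write_ensemble(ens, file.path(tmp, "ens"))
  expect_true(all(file.exists(paths)))
  ld <- load_system(paths["gro"], paths["dcd"],
                    species_map = list(PROT = "protein", CHOL = "CHOL",
                                       POPC = "POPC"))
  expect_lt(max(abs(ld$system$coords - ens$system$coords)), 1e-5)
  truth <- jsonlite::read_json(paths["truth"], simplifyVector = TRUE)
  expect_equal(truth$well_depths_kj, -10)
})
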