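test_that("single bead lands in exactly one voxel; counts are conserved", {
  sys <- make_toy_system(n_res = 1L, n_chol = 1L, n_popc = 0L,
                         beads_per_res = 1L, beads_per_lipid = 1L,
                         frames = 1L, seed = 3)
  sys$coords[2, , 1] <- c(2.52, 2.52, 2.52)
  spec <- grid_spec(c(0, 0, 0), c(5, 5, 5), 0.1)
  g <- accumulate_density(sys, selection = 2L, spec)
  expect_equal(g$samples, 1L)
  expect_equal(sum(g$counts > 0), 1L)
  expect_equal(g$counts[26, 26, 26], 1L)
})

test_that("total counts equal beads x frames inside extents", {
  sys <- make_toy_system(n_chol = 4L, frames = 7L, seed = 13)
  sel <- which(sys$molecule_species[sys$bead_molecule] == "CHOL")
  g <- accumulate_density(sys, sel, grid_spec(c(0, 0, 0), c(5, 5, 5), 0.25))
  expect_equal(g$samples + g$n_outside, length(sel) * 7L)
  expect_equal(g$n_outside, 0L)  # toy coords are wrapped into the box
  expect_equal(sum(g$counts), g$samples)
})

test_that("uniform samples give voxel counts consistent with multinomial", {
  set.seed(99)
  n <- 1e4L
  co <- array(runif(3 * n, 0, 4), c(n, 3, 1))
  sys <- bead_system(co, seq_len(n), rep("CHOL", n), rep(NA, n), rep(NA, n),
                     rep("CHOL", n), c(4, 4, 4))
  g <- accumulate_density(sys, seq_len(n), grid_spec(c(0, 0, 0), c(4, 4, 4), 1))
  # chi-square over 64 equiprobable voxels: generous 99.9% bound
  expected <- n / 64
  chi2 <- sum((g$counts - expected)^2 / expected)
  expect_lt(chi2, qchisq(0.999, df = 63))
})

test_that("site_mask selects a sphere of voxel centres", {
  sys <- make_toy_system(frames = 1L, seed = 1)
  g <- accumulate_density(sys, 1:4, grid_spec(c(0, 0, 0), c(5, 5, 5), 0.1))
  expect_error(site_mask(g, c(2.5, 2.5, 2.5), 0.05), "exceed the bin")
  m_small <- site_mask(g, c(2.5, 2.5, 2.5), 0.11)
  expect_gte(sum(m_small$mask), 1L)
  m_all <- site_mask(g, c(2.5, 2.5, 2.5), 10)
  expect_true(all(m_all$mask))
  # volume check at r = 10 * bin
  r <- 1.0
  m <- site_mask(g, c(2.5, 2.5, 2.5), r)
  vol <- sum(m$mask) * 0.1^3
  expect_lt(abs(vol - 4 / 3 * pi * r^3) / (4 / 3 * pi * r^3), 0.1)
})

test_that("bulk_mask respects slab, protein clearance, and site exclusion", {
  sys <- make_toy_system(frames = 1L, seed = 2)
  g <- accumulate_density(sys, 1:4, grid_spec(c(0, 0, 0), c(5, 5, 5), 0.25))
  all_m <- bulk_mask(g, sys = NULL, z_slab = c(0, 5))
  expect_true(all(all_m$mask))
  site <- site_mask(g, c(2.5, 2.5, 2.5), 0.6)
  b <- bulk_mask(g, sys = NULL, z_slab = c(0, 5), exclude = list(site))
  expect_false(any(b$mask & site$mask))
  expect_error(bulk_mask(g, sys, z_slab = c(0, 5),
                         min_protein_distance = 50), "empty bulk")
})

test_that("binding_free_energy identities: ratio 1 -> 0, known ratios, scaling", {
  spec <- grid_spec(c(0, 0, 0), c(2, 2, 2), 0.5)
  g <- list(spec = spec, counts = array(4L, spec$dims),
            density = array(1, spec$dims), samples = 256L, n_frames = 1L)
  class(g) <- "density_grid"
  site <- structure(list(mask = array(c(TRUE, rep(FALSE, 63)), spec$dims),
                         kind = "site"), class = "region_mask")
  bulk <- structure(list(mask = array(c(FALSE, TRUE, rep(FALSE, 62)), spec$dims),
                         kind = "bulk"), class = "region_mask")
  expect_equal(binding_free_energy(g, site, bulk, 310), 0)
  g50 <- g; g50$density[1] <- 50
  expect_equal(binding_free_energy(g50, site, bulk, 310), -10.08,
               tolerance = 1e-3)
  g10 <- g; g10$density[1] <- 10
  expect_equal(binding_free_energy(g10, site, bulk, 310), -5.93,
               tolerance = 1e-3)
  # doubling every count/density leaves dG unchanged
  g2 <- g10; g2$density <- 2 * g10$density
  expect_equal(binding_free_energy(g2, site, bulk, 310),
               binding_free_energy(g10, site, bulk, 310))
  # monotone decreasing in site density
  g20 <- g; g20$density[1] <- 20
  expect_lt(binding_free_energy(g20, site, bulk, 310),
            binding_free_energy(g10, site, bulk, 310))
  gz <- g; gz$density[1] <- 0
  expect_warning(out <- binding_free_energy(gz, site, bulk, 310), "Inf")
  expect_identical(out, Inf)
})

test_that("alignment restores a translated + z-rotated protein pose", {
  sys <- make_toy_system(n_res = 4L, frames = 3L, seed = 17, jitter = 0)
  th <- 0.4; shift <- c(0.8, -0.5, 0.3)
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- sys
  for (f in 2:3) moved$coords[, , f] <- sweep(sys$coords[, , f] %*% rot, 2, shift, "+")
  aligned <- align_to_protein(moved)
  prot <- protein_beads(sys)
  for (f in 2:3) {
    expect_equal(aligned$coords[prot, , f], sys$coords[prot, , f],
                 tolerance = 1e-8)
  }
})

test_that("OpenDX export writes a well-formed grid", {
  tmp <- withr::local_tempfile(fileext = ".dx")
  sys <- make_toy_system(frames = 1L, seed = 4)
  g <- accumulate_density(sys, 1:6, grid_spec(c(0, 0, 0), c(5, 5, 5), 1))
  write_opendx(g, tmp, what = "counts")
  lines <- readLines(tmp)
  expect_match(lines[1], "counts 5 5 5")
  vals <- scan(text = paste(grep("^[-0-9. e+]+$", lines, value = TRUE),
                            collapse = " "), quiet = TRUE)
  expect_equal(sum(vals), g$samples)
})

test_that("synthetic Boltzmann well is recovered by the density estimator", {
  # scaled-down recovery: 30 frames x 150 chol = 4.5e3 samples; the full
  # 1e5-sample check lives in the acceptance suite
  m <- spatial_ensemble_model(n_chol = 150L, well_depths = -6)
  ens <- simulate_snapshot_ensemble(m, frames = 30L, seed = 19)
  sys <- ens$system
  sel <- which(sys$molecule_species[sys$bead_molecule] == "CHOL")
  g <- accumulate_density(sys, sel, grid_spec(c(0, 0, 0), sys$box[1, ], 0.1))
  site <- site_mask(g, m$site_centers[1, ], m$site_radii[1] - 0.1)
  bulk <- bulk_mask(g, sys, z_slab = c(3.2, 6.8), min_protein_distance = 2,
                    exclude = list(site_mask(g, m$site_centers[1, ],
                                             m$site_radii[1] + 0.2)))
  dg <- binding_free_energy(g, site, bulk, 310)
  expect_lt(abs(dg - (-6)), 1.0)
})
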