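test_that("residue occupancy is 100 * F_x / F_t", {
  st <- matrix(c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0), 1, 10) > 0
  rownames(st) <- "A:1"
  ser <- series_from_states(st)
  expect_equal(residue_occupancy(ser, "A:1"), 30)
  expect_equal(residue_occupancy(series_from_states(st & FALSE), "A:1"), 0)
  expect_equal(residue_occupancy(series_from_states(st | TRUE), "A:1"), 100)
  expect_error(residue_occupancy(ser, "A:9"), "absent")
})

test_that("site occupancy is the mean over site residues, order-invariant", {
  st <- rbind(c(1, 1, 0, 0, 0), c(1, 1, 1, 1, 0)) > 0  # 40% and 80%
  rownames(st) <- c("A:1", "A:2")
  ser <- series_from_states(st)
  site <- site_definition("S", c("A", "A"), c(1, 2))
  expect_equal(site_occupancy(ser, site), 60)
  site_rev <- site_definition("S", c("A", "A"), c(2, 1))
  expect_equal(site_occupancy(ser, site_rev), 60)
  one <- site_definition("S", "A", 1)
  expect_equal(site_occupancy(ser, one), residue_occupancy(ser, "A:1"))
  expect_error(site_definition("S", c("A", "A"), c(1, 1)), "unique")
})

test_that("occupancy on concatenated windows is the frame-weighted mean", {
  set.seed(30)
  for (rep in 1:20) {
    n1 <- sample(3:40, 1); n2 <- sample(3:40, 1)
    s1 <- matrix(runif(n1) < 0.4, 1); s2 <- matrix(runif(n2) < 0.6, 1)
    rownames(s1) <- rownames(s2) <- "A:1"
    occ1 <- residue_occupancy(series_from_states(s1), "A:1")
    occ2 <- residue_occupancy(series_from_states(s2), "A:1")
    occ12 <- residue_occupancy(series_from_states(cbind(s1, s2)), "A:1")
    expect_equal(occ12, (n1 * occ1 + n2 * occ2) / (n1 + n2))
  }
})

test_that("nonspecific band is a closed interval with warning when empty", {
  occ <- c(r1 = 10, r2 = 35, r3 = 45, r4 = 60)
  expect_setequal(nonspecific_residues(occ), c("r2", "r3"))
  expect_setequal(nonspecific_residues(c(a = 30.0, b = 50.0)), c("a", "b"))
  expect_warning(out <- nonspecific_residues(c(a = 5, b = 90)), "band")
  expect_length(out, 0)
})

test_that("free_ligand_fraction counts unbound CHOL over unbound lipids", {
  # protein bead at origin; lipids placed at controlled distances
  build <- function(chol_d, popc_d, frames = 1L) {
    n <- 1L + length(chol_d) + length(popc_d)
    co <- array(0, c(n, 3, frames))
    co[1, , ] <- 5
    for (f in seq_len(frames)) {
      co[-1, 1, f] <- 5 + c(chol_d, popc_d)
      co[-1, 2, f] <- 5; co[-1, 3, f] <- 5
    }
    bead_system(co, seq_len(n),
                c("protein", rep("CHOL", length(chol_d)),
                  rep("POPC", length(popc_d))),
                c("A", rep(NA, n - 1L)), c(1L, rep(NA, n - 1L)),
                c("PROT", rep("CHOL", length(chol_d)),
                  rep("POPC", length(popc_d))),
                c(20, 20, 20))
  }
  # 3 unbound CHOL, 6 unbound POPC (all beyond 0.8), 1 bound CHOL
  sys <- build(c(rep(2, 3), 0.5), rep(3, 6))
  expect_equal(free_ligand_fraction(sys), 100 * 3 / 9)
  # all CHOL within 0.8 -> 0%
  sys0 <- build(rep(0.5, 3), rep(3, 6))
  expect_equal(free_ligand_fraction(sys0), 0)
  # boundary: exactly 0.8 nm is bound (criterion is strictly greater)
  sysb <- build(c(0.8, 2), rep(3, 2))
  expect_equal(free_ligand_fraction(sysb), 100 * 1 / 3)
})

test_that("free_ligand_fraction averages per frame", {
  # frame 1: 3/10 free CHOL; frame 2: 5/10 -> mean 40%
  n <- 11L
  co <- array(0, c(n, 3, 2))
  co[1, , ] <- 5
  co[-1, 2, ] <- 5; co[-1, 3, ] <- 5
  co[2:11, 1, 1] <- 5 + c(rep(2, 3), rep(0.3, 7))  # 3 CHOL free
  co[2:11, 1, 2] <- 5 + c(rep(2, 5), rep(0.3, 5))  # 5 CHOL free
  # no POPC: denominator is unbound CHOL only -> 100% each frame; add POPC
  co2 <- array(0, c(n + 7L, 3, 2))
  co2[seq_len(n), , ] <- co
  co2[(n + 1L):(n + 7L), 1, ] <- 12; co2[(n + 1L):(n + 7L), 2:3, ] <- 5
  sys <- bead_system(co2, seq_len(n + 7L),
                     c("protein", rep("CHOL", 10), rep("POPC", 7)),
                     c("A", rep(NA, n + 6L)), c(1L, rep(NA, n + 6L)),
                     c("PROT", rep("CHOL", 10), rep("POPC", 7)),
                     c(30, 30, 30))
  expect_equal(free_ligand_fraction(sys), 100 * mean(c(3 / 10, 5 / 12)))
})

test_that("synthetic surface enrichment keeps free fraction below total mol%", {
  m <- spatial_ensemble_model(n_chol = 60L, n_popc = 40L)
  ens <- simulate_snapshot_ensemble(m, frames = 30L, seed = 77)
  expect_lt(free_ligand_fraction(ens$system), 60)
})
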