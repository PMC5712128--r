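test_that("copies_at_age follows the replication schedule", {
  cc <- cell_cycle_params(45)
  ori <- locus_spec(0); ter <- locus_spec(1)
  # x_ori = C + D = 60: base 2^floor(60/45) = 2 copies, doubling at
  # age T - (x mod T) = 30 min
  expect_equal(copies_at_age(ori, cc, c(0, 29.9)), c(2, 2))
  expect_equal(copies_at_age(ori, cc, c(30, 44.9)), c(4, 4))
  # x_ter = D = 20 -> doubling at age 25 min
  expect_equal(copies_at_age(ter, cc, c(0, 24.9)), c(1, 1))
  expect_equal(copies_at_age(ter, cc, 25), 2)
  # x a multiple of T: the count is constant over the whole cycle
  cc20 <- cell_cycle_params(20)
  expect_equal(copies_at_age(ori, cc20, seq(0, 19.9, by = 0.1)),
               rep(8, 200))
  expect_equal(copies_at_age(ter, cc20, seq(0, 19.9, by = 0.1)),
               rep(2, 200))
  expect_error(copies_at_age(ori, cc, 45), "age")
  expect_error(copies_at_age(ori, cc, -1), "age")
})

test_that("copy number doubles exactly once per cycle", {
  for (Tm in c(22, 35, 47, 63, 88, 111)) {
    cc <- cell_cycle_params(Tm)
    for (L in c(0, 0.3, 0.7, 1)) {
      loc <- locus_spec(L, 2L)
      grid <- seq(0, Tm - 1e-9, length.out = 4001)
      cop <- copies_at_age(loc, cc, grid)
      jumps <- diff(cop)
      expect_true(all(jumps >= 0))
      expect_true(sum(jumps > 0) <= 1)
      expect_true(all(cop %in% c(cop[1], 2 * cop[1])))
    }
  }
})

test_that("mean_copies equals the time average of the instantaneous count", {
  for (Tm in c(20, 33.5, 40, 59, 60, 97, 120)) {
    cc <- cell_cycle_params(Tm)
    for (L in c(0, 0.25, 0.5, 1)) {
      loc <- locus_spec(L, 3L)
      grid <- seq(0, Tm, length.out = 200001)
      grid <- grid[-length(grid)]
      expect_equal(mean(copies_at_age(loc, cc, grid)), mean_copies(loc, cc),
                   tolerance = 1e-4)
    }
  }
})

test_that("genome-average copy number matches direct integration over loci", {
  for (Tm in c(21, 29, 30, 45, 60, 75, 120)) {
    cc <- cell_cycle_params(Tm)
    direct <- stats::integrate(function(L)
      vapply(L, function(l) mean_copies(locus_spec(l), cc), numeric(1)),
      0, 1, subdivisions = 2000, rel.tol = 1e-9)$value
    expect_equal(genome_average_copies(cc), direct, tolerance = 1e-6)
    # smooth variant stays within a few percent of the exact form
    expect_equal(genome_average_copies(cc, approx = TRUE), direct,
                 tolerance = 0.05)
  }
})

test_that("dosage ratio and balancing distance are exact inverses", {
  cc <- cell_cycle_params(40)
  expect_equal(dosage_ratio(0, 1, cc), 2)
  expect_equal(dosage_ratio(0, 1, cell_cycle_params(20)), 4)
  expect_equal(dosage_ratio(0.5, 0.5, cc), 1)
  for (Tm in c(20, 40, 77, 120)) for (R in c(1/4, 1/2, 3/5, 4/5)) {
    ccT <- cell_cycle_params(Tm)
    L2 <- balanced_locus(R, ccT)
    expect_equal(R * 2^((ccT$C / ccT$T) * L2), 1, tolerance = 1e-12)
    if (L2 <= 1)  # on-chromosome solutions invert through dosage_ratio too
      expect_equal(dosage_ratio(0, L2, ccT) * 1 / R, 1 / R^2,
                   tolerance = 1e-12)
  }
  expect_error(balanced_locus(0, cc), "ratio")
  expect_error(balanced_locus(1.2, cc), "ratio")
  expect_error(dosage_ratio(-0.1, 1, cc), "distance")
})

test_that("best balanced design picks the farthest on-chromosome locus", {
  des40 <- best_balanced_design(cell_cycle_params(40))
  expect_true(des40$admissible)
  expect_equal(des40$ratio, 1/2)
  expect_equal(des40$L2, 1)
  # at fast growth only mild ratios fit on the chromosome
  des20 <- best_balanced_design(cell_cycle_params(20))
  expect_true(des20$admissible)
  expect_true(des20$L2 <= 1)
  expect_equal(des20$L2, balanced_locus(des20$ratio, cell_cycle_params(20)))
  # no admissible design when all candidates balance beyond ter
  none <- best_balanced_design(cell_cycle_params(120), candidate_ratios = 1/4)
  expect_false(none$admissible)
  expect_true(is.na(none$ratio) && is.na(none$L2))
})

test_that("cell volume grows exponentially from V0 to 2 V0", {
  for (Tm in c(20, 40, 120)) {
    cc <- cell_cycle_params(Tm)
    v0 <- volume_at_age(cc, 0)
    expect_equal(volume_at_age(cc, Tm), 2 * v0)
    expect_equal(volume_at_age(cc, Tm / 2), sqrt(2) * v0)
  }
  expect_equal(volume_at_age(cell_cycle_params(40), 0), 0.5)
  expect_error(volume_at_age(cell_cycle_params(40), 41), "age")
})

test_that("constructors validate their domains", {
  expect_error(cell_cycle_params(10), "20")
  expect_error(cell_cycle_params(150), "120")
  expect_error(cell_cycle_params(40, C_min = -1), "positive")
  expect_error(locus_spec(1.5), "0, 1")
  expect_error(locus_spec(0.5, 0L), "positive integer")
  expect_s3_class(cell_cycle_params(40), "cell_cycle_params")
})
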