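coarse <- function(name, rby = 0.05, Bby = 0.05) {
  scenario_preset(name, r_grid = seq(0, 2, by = rby),
                  B_grid = seq(Bby, 1, by = Bby))
}

test_that("sweeps are deterministic and cover every grid cell", {
  cfg <- coarse("high_tolerance_high_control")
  s1 <- sweep_scenario(cfg)
  s2 <- sweep_scenario(cfg)
  expect_identical(tibble::as_tibble(s1), tibble::as_tibble(s2))
  expect_identical(nrow(s1),
                   length(cfg$r_grid) * length(cfg$B_grid))
  expect_true(all(!is.na(s1$label)))
})

test_that("a growth-rate column crosses dominance, then the coexistence pair", {
  cfg <- scenario_preset("high_tolerance_high_control")
  col <- sweep_scenario(scenario_config(
    social = cfg$social, econ = cfg$econ,
    r_grid = cfg$r_grid, B_grid = 0.3))
  labs <- as.character(col$label)
  runs <- rle(labs)
  expect_identical(runs$values,
                   c("cooperative_dominance", "cooperative_coexistence",
                     "noncooperative_coexistence"))
  # boundaries refined by bisection fall between the differing grid cells
  b_dom <- boundary_r(cfg, "cooperative_dominance",
                      "cooperative_coexistence", B_prime = 0.3)
  expect_equal(b_dom$r_star, 1.185925, tolerance = 1e-5)
  last_dom <- max(col$r[labs == "cooperative_dominance"])
  first_cc <- min(col$r[labs == "cooperative_coexistence"])
  expect_gt(b_dom$r_star, last_dom)
  expect_lt(b_dom$r_star, first_cc)

  b_half <- boundary_r(cfg, "cooperative_coexistence",
                       "noncooperative_coexistence", B_prime = 0.3)
  expect_equal(b_half$r_star, 1.347046, tolerance = 1e-5)
  last_cc <- max(col$r[labs == "cooperative_coexistence"])
  first_nc <- min(col$r[labs == "noncooperative_coexistence"])
  expect_gt(b_half$r_star, last_cc)
  expect_lt(b_half$r_star, first_nc)
})

test_that("the weak-control low-tolerance scenario loses dominance early", {
  cfg <- scenario_preset("low_tolerance_low_control")
  b <- boundary_r(cfg, "cooperative_dominance",
                  "noncooperative_coexistence", B_prime = 0.3)
  expect_equal(b$r_star, 0.1208887, tolerance = 1e-5)
})

test_that("absent transitions raise a no-boundary signal", {
  # dominance holds for every r below 0.4 in the strong-control scenario
  cfg <- scenario_preset("high_tolerance_high_control",
                         r_grid = seq(0, 0.4, by = 0.01))
  expect_warning(
    b <- boundary_r(cfg, "cooperative_dominance",
                    "cooperative_coexistence", B_prime = 0.3),
    class = "fisherygame_no_boundary")
  expect_true(is.na(b$r_star))
  expect_error(
    boundary_r(cfg, "cooperative_dominance", "cooperative_dominance",
               B_prime = 0.3),
    class = "fisherygame_domain_error")
})

test_that("stronger control enlarges the cooperative-dominance region", {
  hi <- sweep_scenario(coarse("high_tolerance_high_control"))
  lo <- sweep_scenario(coarse("high_tolerance_low_control"))
  dom_hi <- hi$label == "cooperative_dominance"
  dom_lo <- lo$label == "cooperative_dominance"
  expect_true(all(dom_lo <= dom_hi))   # subset, cell by cell
  expect_gt(sum(dom_hi), sum(dom_lo))
})

test_that("lower risk tolerance shrinks the cooperative-dominance region", {
  tol_hi <- sweep_scenario(coarse("high_tolerance_high_control"))
  tol_lo <- sweep_scenario(coarse("low_tolerance_high_control"))
  expect_true(all(
    (tol_lo$label == "cooperative_dominance") <=
      (tol_hi$label == "cooperative_dominance")))
})

test_that("band thresholds aggregate per-column boundaries across B'", {
  cfg <- coarse("high_tolerance_high_control", rby = 0.01, Bby = 0.01)
  bt <- band_thresholds(cfg)
  per_dom <- boundary_r(cfg, "cooperative_dominance",
                        "cooperative_coexistence")
  per_half <- boundary_r(cfg, "cooperative_coexistence",
                         "noncooperative_coexistence")
  expect_equal(bt$r_dominance, min(per_dom$r_star), tolerance = 1e-9)
  expect_equal(bt$r_all_noncooperative, max(per_half$r_star),
               tolerance = 1e-9)
  # every grid cell with r below the dominance threshold is dominant,
  # and every cell beyond the non-cooperative threshold is red
  sw <- sweep_scenario(cfg)
  below <- sw[sw$r < bt$r_dominance & sw$viable, ]
  expect_true(all(below$label == "cooperative_dominance"))
  above <- sw[sw$r > bt$r_all_noncooperative & sw$viable, ]
  expect_true(all(above$label == "noncooperative_coexistence"))
})

test_that("equilibrium frequency curves decrease with growth rate and overlap across B'", {
  cfg <- scenario_preset("high_tolerance_high_control",
                         B_grid = c(0.2, 0.5, 1.0))
  fc <- frequency_curves(cfg)
  for (b in unique(fc$B_prime)) {
    cx <- fc[fc$B_prime == b &
               fc$label %in% c("cooperative_coexistence",
                               "noncooperative_coexistence"), ]
    expect_true(all(diff(cx$x_C_eq) < 0))
  }
  # with alpha = 1 the penalty at r = 0 is total: cheaters earn nothing
  at0 <- fc[fc$r == 0, ]
  expect_true(all(at0$x_C_eq == 1))
  # pointwise spread across stock sizes stays small where all coexist
  wide <- tidyr::pivot_wider(fc[, c("B_prime", "r", "x_C_eq", "label")],
                             names_from = "B_prime",
                             values_from = c("x_C_eq", "label"))
  co <- wide[rowSums(sapply(wide[5:7], `%in%`,
                            c("cooperative_coexistence",
                              "noncooperative_coexistence"))) == 3, ]
  spread <- apply(co[, 2:4], 1, function(v) diff(range(v)))
  expect_gt(nrow(co), 10)
  expect_lt(max(spread), 0.1)
})

test_that("disabling the penalty leaves only cheater-biased coexistence", {
  cfg <- coarse("high_tolerance_high_control")
  sw <- sweep_scenario(cfg, delta_override = 0.5)
  viable <- sw[sw$viable, ]
  expect_identical(unique(as.character(viable$label)),
                   "noncooperative_coexistence")
})
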