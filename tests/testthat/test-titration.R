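# Titration oracles: closed-form Henderson-Hasselbalch behaviour for
# uncoupled sites, an explicit 4-state Boltzmann sum for one coupled pair,
# and exact enumeration as the reference for the Monte Carlo sampler.

# one uncoupled site with the given intrinsic pKa
single_site_system <- function(aa = "ASP", pka = 4.0) {
  sites <- data.frame(chain = "C", resno = 1L, insert = "", resid = aa,
                      model_pka = pka,
                      ionized_charge = satmut:::SITE_CHARGE[[aa]],
                      intrinsic_pka = pka, stringsAsFactors = FALSE)
  new_titration_system(sites, matrix(0, 1, 1))
}

test_that("single acid: protonation 0.5 at pH = pKa, HH curve elsewhere", {
  sys <- single_site_system("ASP", 4.0)
  cur <- titration_curve(sys, ph_grid = c(2, 4, 6))
  expect_equal(unname(cur[2, 1]), 0.5, tolerance = 1e-12)
  # Henderson-Hasselbalch: protonated fraction = 1/(1+10^(pH-pKa))
  expect_equal(unname(cur[, 1]), 1 / (1 + 10^(c(2, 4, 6) - 4.0)),
               tolerance = 1e-9)
})

test_that("single base titrates in the opposite direction", {
  sys <- single_site_system("LYS", 10.4)
  cur <- titration_curve(sys, ph_grid = c(8, 10.4, 13))
  expect_equal(unname(cur[2, 1]), 0.5, tolerance = 1e-12)
  expect_gt(cur[1, 1], 0.99)  # protonated (charged) well below pKa
  expect_lt(cur[3, 1], 0.01)
})

test_that("uncoupled multi-site systems recover model pKas within 0.05", {
  sys <- make_titration_fixture(8, coupling_scale = 0, seed = 11)
  pk <- compute_pkas_system(sys)
  expect_false(any(pk$out_of_range))
  expect_equal(pk$pka, pk$intrinsic_pka, tolerance = 0.05)
})

test_that("with zero coupling the joint system factorizes into single sites", {
  sys <- make_titration_fixture(6, coupling_scale = 0, seed = 3)
  grid <- seq(2, 12, by = 0.5)
  joint <- titration_curve(sys, ph_grid = grid)
  for (j in seq_len(6)) {
    solo <- new_titration_system(sys$sites[j, , drop = FALSE],
                                 matrix(0, 1, 1))
    expect_equal(unname(joint[, j]),
                 unname(titration_curve(solo, ph_grid = grid)[, 1]),
                 tolerance = 1e-9)
  }
})

test_that("two coupled acids match the explicit 4-state Boltzmann oracle", {
  W12 <- 1.364
  sites <- data.frame(chain = "C", resno = 1:2, insert = "",
                      resid = c("ASP", "GLU"), model_pka = c(4.0, 4.4),
                      ionized_charge = c(-1, -1),
                      intrinsic_pka = c(4.0, 4.4), stringsAsFactors = FALSE)
  W <- matrix(c(0, W12, W12, 0), 2, 2)
  sys <- new_titration_system(sites, W)
  grid <- seq(2, 8, by = 0.25)
  cur <- titration_curve(sys, ph_grid = grid)
  kt <- 1.364 / log(10)
  oracle <- t(vapply(grid, function(ph) {
    h <- 1.364 * (c(4.0, 4.4) - ph)  # ionized-form energies of the acids
    states <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
    E <- states %*% h + states[, 1] * states[, 2] * W12
    w <- exp(-(E - min(E)) / kt)
    x <- colSums(states * as.vector(w)) / sum(w)
    1 - x  # protonated fraction of an acid = 1 - ionized fraction
  }, numeric(2)))
  expect_equal(unname(cur), unname(oracle), tolerance = 1e-9)
  # repulsive coupling spreads the two transitions apart
  pk <- compute_pkas_system(sys)
  expect_gt(max(pk$pka) - min(pk$pka), 4.4 - 4.0)
})

test_that("Monte Carlo matches enumeration and is seed-reproducible", {
  sys <- make_titration_fixture(6, coupling_scale = 0.8, seed = 5)
  grid <- seq(2, 12, by = 1)
  ce <- titration_curve(sys, ph_grid = grid)
  cm <- titration_curve(sys, ph_grid = grid, method = "monte_carlo",
                        seed = 42, sweeps = 50000L)
  expect_lt(max(abs(cm - ce)), 0.02)
  cm2 <- titration_curve(sys, ph_grid = grid, method = "monte_carlo",
                         seed = 42, sweeps = 50000L)
  expect_identical(cm, cm2)
  expect_error(titration_curve(sys, ph_grid = grid, method = "monte_carlo"),
               "seed")
})

test_that("enumeration refuses > 20 sites; system constructor validates W", {
  sys <- make_titration_fixture(21, coupling_scale = 0, seed = 1)
  expect_error(titration_curve(sys, method = "enumerate"), "20 sites")
  sites <- make_titration_fixture(3, coupling_scale = 0, seed = 2)$sites
  Wbad <- matrix(c(0, 1, 0, 0, 0, 0, 0, 0, 0), 3, 3)
  expect_error(new_titration_system(sites, Wbad), "not symmetric")
  Wdiag <- diag(3) * 0.5
  expect_error(new_titration_system(sites, Wdiag), "diagonal not zero")
})

test_that("out-of-range pKas are reported as sentinels, not numbers", {
  lo <- single_site_system("ASP", -5)   # always ionized on the grid
  hi <- single_site_system("ASP", 20)   # never ionized on the grid
  pk_lo <- compute_pkas_system(lo)
  pk_hi <- compute_pkas_system(hi)
  expect_true(pk_lo$out_of_range)
  expect_equal(pk_lo$pka, -1)
  expect_true(pk_hi$out_of_range)
  expect_equal(pk_hi$pka, 15)
})

test_that("structure pipeline: toy monomer yields finite shifted pKas and a
           symmetric coupling matrix", {
  s <- split_monomers(get_toy_dimer())$C
  p <- default_forcefields("ff_a")[[1]]
  sp <- assign_parameters(s, p)
  sys <- build_titration_system(sp, p)
  expect_gt(nrow(sys$sites), 0)
  expect_equal(sys$W, t(sys$W), tolerance = 1e-12)
  expect_equal(unname(diag(sys$W)), rep(0, nrow(sys$W)))
  # burial always shifts an acid's intrinsic pKa up, a base's down
  acid <- sys$sites$ionized_charge < 0
  expect_true(all(sys$sites$intrinsic_pka[acid] >=
                    sys$sites$model_pka[acid] - 1e-9))
  expect_true(all(sys$sites$intrinsic_pka[!acid] <=
                    sys$sites$model_pka[!acid] + 1e-9))
})

test_that("pKa shift bookkeeping: sums of absolute shifts, unpaired counting", {
  base <- data.frame(chain = "C", resno = c(2, 8), insert = "",
                     resid = c("LYS", "GLU"), model_pka = c(10.4, 4.4),
                     ionized_charge = c(1, -1), intrinsic_pka = c(10.4, 4.4),
                     pka = c(10.0, 4.5), stringsAsFactors = FALSE)
  mut <- base
  mut$pka <- c(10.7, 4.0)  # shifts +0.7 and -0.5
  rep1 <- pka_shift_report(base, mut)
  expect_equal(rep1$sum_abs, 1.2, tolerance = 1e-12)
  expect_equal(rep1$per_site$dpka, c(0.7, -0.5), tolerance = 1e-12)
  expect_equal(rep1$n_unpaired, 0)
  # identity comparison: all shifts exactly zero
  rep0 <- pka_shift_report(base, base)
  expect_identical(rep0$sum_abs, 0)
  # a site type change breaks the pairing and is counted, not summed
  mut2 <- mut
  mut2$resid[2] <- "ASP"
  rep2 <- pka_shift_report(base, mut2)
  expect_equal(rep2$n_sites, 1)
  expect_equal(rep2$n_unpaired, 2)
  expect_equal(rep2$sum_abs, 0.7, tolerance = 1e-12)
  expect_error(pka_shift_report(base[0, ], mut), "no paired")
})

test_that("monomer-ionized / dimer-neutral sites are flagged at pH 7", {
  mk <- function(pka) {
    data.frame(chain = "C", resno = 56L, insert = "", resid = "HIS",
               model_pka = 6.3, ionized_charge = 1, intrinsic_pka = pka,
               pka = pka, stringsAsFactors = FALSE)
  }
  # monomer pKa 7.1 (mostly ionized at pH 7) vs dimer pKa 4 (neutral)
  f <- flag_ionization_discrepancy(mk(7.1), mk(4.0),
                                   list(chain = "C", resno = 56))
  expect_true(f$flag)
  expect_gt(f$ionized_monomer, 0.5)
  expect_lt(f$ionized_dimer, 0.01)
  # no discrepancy when both contexts agree
  f2 <- flag_ionization_discrepancy(mk(7.1), mk(7.0),
                                    list(chain = "C", resno = 56))
  expect_false(f2$flag)
  expect_error(flag_ionization_discrepancy(mk(7.1)[0, ], mk(4.0),
                                           list(chain = "C", resno = 56)),
               "monomer")
})
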