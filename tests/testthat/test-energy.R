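test_that("Coulomb closed form: unit charges at 1 A give 332.0636 kcal/mol", {
  s <- ion_structure(rbind(c(0, 0, 0), c(1, 0, 0)), q = c(1, 1))
  expect_equal(coulomb_energy(s), 332.0636, tolerance = 1e-9)
  # opposite charges flip the sign; doubling the distance halves the energy
  s2 <- ion_structure(rbind(c(0, 0, 0), c(1, 0, 0)), q = c(1, -1))
  expect_equal(coulomb_energy(s2), -332.0636, tolerance = 1e-9)
  s3 <- ion_structure(rbind(c(0, 0, 0), c(2, 0, 0)), q = c(1, 1))
  expect_equal(coulomb_energy(s3), 332.0636 / 2, tolerance = 1e-9)
  # interior dielectric scales it down
  expect_equal(coulomb_energy(s, eps_int = 4), 332.0636 / 4, tolerance = 1e-9)
})

test_that("LJ closed form: minimum -epsilon at 2^(1/6) sigma, zero at sigma", {
  sig <- 3.5; eps <- 0.25
  rmin <- 2^(1 / 6) * sig
  s <- ion_structure(rbind(c(0, 0, 0), c(rmin, 0, 0)), q = 0,
                     sigma = sig, epsilon = eps)
  expect_equal(lj_energy(s), -eps, tolerance = 1e-9)
  s0 <- ion_structure(rbind(c(0, 0, 0), c(sig, 0, 0)), q = 0,
                      sigma = sig, epsilon = eps)
  expect_equal(lj_energy(s0), 0, tolerance = 1e-9)
  # repulsive inside the minimum, attractive outside
  sin_ <- ion_structure(rbind(c(0, 0, 0), c(0.9 * sig, 0, 0)), q = 0,
                        sigma = sig, epsilon = eps)
  expect_gt(lj_energy(sin_), 0)
  sout <- ion_structure(rbind(c(0, 0, 0), c(1.5 * sig, 0, 0)), q = 0,
                        sigma = sig, epsilon = eps)
  expect_lt(lj_energy(sout), 0)
})

test_that("single-ion Born energy matches the analytic formula", {
  rho <- 2.0; q <- 1.0; es <- 78.5
  s <- ion_structure(rbind(c(0, 0, 0)), q = q, gbr = rho)
  analytic <- -0.5 * (1 - 1 / es) * 332.0636 * q^2 / rho
  expect_equal(gb_energy(s, eps_int = 1, eps_solv = es), analytic,
               tolerance = 1e-6)
  # a lone atom has no descreening neighbours: B equals its intrinsic radius
  expect_equal(born_radii(s), rho, tolerance = 1e-12)
})

test_that("two far-separated ions: exact screened asymptotics to 1e-6", {
  rho <- 2.0; es <- 78.5; r <- 1e4
  s1 <- ion_structure(rbind(c(0, 0, 0)), q = 1, gbr = rho)
  s2 <- ion_structure(rbind(c(0, 0, 0), c(r, 0, 0)), q = c(1, 1), gbr = rho)
  # Born radii unaffected across the gap
  expect_equal(born_radii(s2), c(rho, rho), tolerance = 1e-12)
  # gb + coulomb = two isolated self energies + fully screened interaction
  e_single <- gb_energy(s1, eps_int = 1, eps_solv = es)
  lhs <- gb_energy(s2, eps_int = 1, eps_solv = es) +
    coulomb_energy(s2, eps_int = 1, eps_solv = es)
  rhs <- 2 * e_single + 332.0636 / (es * r)
  expect_equal(lhs, rhs, tolerance = 1e-6)
})

test_that("descreening raises effective Born radii above intrinsic radii", {
  s <- get_toy_dimer()
  p <- default_forcefields("ff_a")[[1]]
  sp <- assign_parameters(s, p)
  B <- born_radii(sp)
  expect_true(all(B >= sp$atoms$gbr - 1e-9))
  expect_true(all(is.finite(B)) && all(B > 0))
})

test_that("total energy is invariant under rotation and translation", {
  s <- get_toy_dimer()
  p <- default_forcefields("ff_a")[[1]]
  e0 <- total_energy(s, p)$total
  th <- 0.7; ph <- 1.3
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3) %*%
    matrix(c(1, 0, 0, 0, cos(ph), -sin(ph), 0, sin(ph), cos(ph)), 3, 3)
  xyz <- coords(s) %*% t(R)
  s2 <- s
  s2$atoms$x <- xyz[, 1] + 11.3
  s2$atoms$y <- xyz[, 2] - 4.9
  s2$atoms$z <- xyz[, 3] + 250
  e1 <- total_energy(s2, p)$total
  expect_equal(e1, e0, tolerance = 1e-6)
})

test_that("breakdown decomposes: total = lj + coulomb + gb, kernel matches R oracle", {
  s <- make_chain(c("ALA", "SER", "LEU", "ASP"))
  p <- default_forcefields("ff_b")[[1]]
  sp <- assign_parameters(s, p)
  eb <- total_energy(sp, p)
  expect_equal(eb$total, eb$lj + eb$coulomb + eb$gb, tolerance = 1e-12)

  # plain-R double-loop oracle over the same pair list and Born radii
  pairs <- satmut:::nonbonded_pairs(sp)
  a <- sp$atoms; xyz <- coords(sp)
  B <- born_radii(sp)
  ei <- p$interior_dielectric; es <- p$solvent_dielectric
  lj <- 0; cou <- 0
  for (k in seq_along(pairs$i)) {
    i <- pairs$i[k] + 1L; j <- pairs$j[k] + 1L
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    sij <- 0.5 * (a$sigma[i] + a$sigma[j])
    eij <- sqrt(a$epsilon[i] * a$epsilon[j])
    lj <- lj + pairs$w[k] * 4 * eij * ((sij / r)^12 - (sij / r)^6)
    cou <- cou + pairs$w[k] * 332.0636 * a$charge[i] * a$charge[j] / (ei * r)
  }
  tau <- 1 / ei - 1 / es
  gb <- sum(-0.5 * tau * 332.0636 * a$charge^2 / B)
  n <- nrow(a)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    r2 <- sum((xyz[i, ] - xyz[j, ])^2)
    f <- sqrt(r2 + B[i] * B[j] * exp(-r2 / (4 * B[i] * B[j])))
    gb <- gb - tau * 332.0636 * a$charge[i] * a$charge[j] / f
  }
  expect_equal(eb$lj, lj, tolerance = 1e-9)
  expect_equal(eb$coulomb, cou, tolerance = 1e-9)
  expect_equal(eb$gb, gb, tolerance = 1e-9)
})

test_that("pair mask excludes 1-2/1-3, halves 1-4, keeps the rest at 1", {
  s <- make_chain(c("ALA", "ALA"))
  pairs <- satmut:::nonbonded_pairs(s)
  a <- s$atoms
  key <- function(e1, r1, e2, r2) {
    i <- which(a$elety == e1 & a$resno == r1)
    j <- which(a$elety == e2 & a$resno == r2)
    hit <- which((pairs$i == i - 1 & pairs$j == j - 1) |
                   (pairs$i == j - 1 & pairs$j == i - 1))
    if (length(hit) == 0) NA_real_ else pairs$w[hit]
  }
  expect_true(is.na(key("N", 1, "CA", 1)))    # 1-2 bonded
  expect_true(is.na(key("N", 1, "C", 1)))     # 1-3
  expect_true(is.na(key("C", 1, "N", 2)))     # peptide bond
  expect_true(is.na(key("CA", 1, "N", 2)))    # 1-3 across the peptide bond
  expect_equal(key("N", 1, "O", 1), 0.5)      # 1-4: N-CA-C-O
  expect_equal(key("CB", 1, "O", 1), 0.5)     # 1-4: CB-CA-C-O
  expect_equal(key("CA", 1, "CA", 2), 0.5)    # 1-4 across the peptide bond
  expect_equal(key("N", 1, "N", 2), 0.5)      # 1-4: N-CA-C-N
  expect_equal(key("N", 1, "CA", 2), 1)       # 4 bonds apart: full weight
  expect_equal(key("O", 1, "O", 2), 1)
})

test_that("energy evaluation refuses unparameterized structures", {
  s <- make_chain(c("ALA", "GLY"))
  expect_error(total_energy(s), "parameterized")
  expect_error(born_radii(s), "parameterized")
})

test_that("assign_parameters fills all atoms and errors name the culprit", {
  s <- make_chain(c("ALA", "TRP", "ARG"))
  p <- default_forcefields("ff_c")[[1]]
  sp <- assign_parameters(s, p)
  expect_false(anyNA(sp$atoms$charge))
  expect_false(anyNA(sp$atoms$sigma))
  expect_identical(sp$param_set, "ff_c")
  # an alien atom name is reported with atom and residue
  s2 <- s
  s2$atoms$elety[5] <- "XX"
  expect_error(assign_parameters(s2, p), "unparameterized atom XX")
})

test_that("the three bundled parameter sets differ but agree on net charge", {
  ffs <- default_forcefields()
  expect_length(ffs, 3)
  s <- make_chain(c("ASP", "LYS", "ALA", "GLU", "ARG", "HIS"))
  qs <- vapply(ffs, function(p) net_charge(assign_parameters(s, p)), numeric(1))
  # formal charges: -1 +1 0 -1 +1 +1 = +1 under every set
  expect_equal(unname(qs), rep(1, 3), tolerance = 1e-9)
  e <- vapply(ffs, function(p) total_energy(s, p)$total, numeric(1))
  expect_gt(diff(range(e)), 1e-3)  # the sets are genuinely different
})

test_that("read_forcefield validates files", {
  expect_error(read_forcefield(tempfile()), "not found")
  f <- withr::local_tempfile(fileext = ".prm")
  writeLines("JUNK line", f)
  expect_error(read_forcefield(f), "malformed")
  f2 <- withr::local_tempfile(fileext = ".prm")
  writeLines(c("CHARGE ALA CA 0.1 C", "CLASS C 3.5 -0.1 1.9"), f2)
  expect_error(read_forcefield(f2), "negative")
})

test_that("relaxation never raises the energy and respects tol = Inf", {
  s <- make_chain(c("ALA", "MET", "LEU", "GLU", "LYS"))
  p <- default_forcefields("ff_a")[[1]]
  e0 <- total_energy(s, p)$total
  r <- relax(s, p, max_sweeps = 3L)
  expect_lte(attr(r, "energy")$total, e0 + 1e-9)
  expect_type(attr(r, "converged"), "logical")
  # tol = Inf is the identity protocol: coordinates unchanged
  r0 <- relax(s, p, tol = Inf)
  expect_identical(coords(r0), coords(s))
})

test_that("relax moves only the scoped side chains, never the backbone", {
  s <- make_chain(c("ALA", "MET", "LEU", "GLU", "LYS"))
  p <- default_forcefields("ff_a")[[1]]
  scope <- data.frame(chain = "A", resno = 2L)
  r <- relax(s, p, scope, max_sweeps = 3L)
  bb <- s$atoms$elety %in% c("N", "CA", "C", "O")
  expect_equal(coords(r)[bb, ], coords(s)[bb, ], tolerance = 1e-9,
               ignore_attr = TRUE)
  outside <- !bb & s$atoms$resno != 2
  expect_equal(coords(r)[outside, ], coords(s)[outside, ], tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("set/measure chi angles round-trip", {
  s <- make_chain(c("ALA", "GLU", "ALA"))
  s2 <- satmut:::set_sidechain(s, "A", 2, "GLU", c(-65, 170, -40))
  chis <- satmut:::measure_chis(s2, "A", 2)
  wrap <- function(x) ((x + 180) %% 360) - 180
  expect_equal(wrap(chis - c(-65, 170, -40)), rep(0, 3), tolerance = 1e-6)
})
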