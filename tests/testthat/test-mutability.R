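# A 19-vector with exactly the requested population mean and sd.
vec_with <- function(mean, sd, seed = 1) {
  set.seed(seed)
  x <- rnorm(19)
  (x - mean(x)) / pop_sd(x) * sd + mean
}

test_that("HSTD is exactly half the population standard deviation", {
  for (sigma in c(3.8, 6.2, 5.2, 7.2, 1.6, 4.9)) {
    p <- site_profile(vec_with(0, sigma), "folding")
    expect_equal(p$std, sigma, tolerance = 1e-12)
    expect_equal(p$hstd, sigma / 2, tolerance = 1e-12)
  }
  # the five literature-style printed pairs at one decimal
  printed <- rbind(c(3.8, 1.9), c(6.2, 3.1), c(5.2, 2.6), c(7.2, 3.6),
                   c(1.6, 0.8))
  for (k in seq_len(nrow(printed))) {
    p <- site_profile(vec_with(0, printed[k, 1]), "folding")
    expect_equal(round(p$hstd, 1), printed[k, 2])
  }
  # the sixth pair is printed as 2.5 in the literature style (4.9/2 = 2.45)
  p6 <- site_profile(vec_with(0, 4.9), "binding")
  expect_equal(p6$hstd, 2.45, tolerance = 1e-12)
  expect_lt(abs(p6$hstd - 2.5), 0.05)
})

test_that("z-scores standardize any non-degenerate 19-vector", {
  set.seed(99)
  for (k in 1:100) {
    x <- rnorm(19, mean = runif(1, -10, 10), sd = runif(1, 0.1, 8))
    p <- site_profile(x, "binding")
    expect_lt(abs(mean(p$zscores)), 1e-9)
    expect_lt(abs(pop_sd(p$zscores) - 1), 1e-9)
    # z-scores are an affine map: order preserved
    expect_identical(order(p$zscores), order(p$effects))
  }
})

test_that("site_profile enforces its input contract", {
  expect_error(site_profile(rnorm(18), "folding"), "exactly 19")
  expect_error(site_profile(rnorm(20), "folding"), "exactly 19")
  expect_error(site_profile(c(rnorm(18), NA), "folding"), "non-finite")
  expect_error(site_profile(rep(1, 19), "folding"), "degenerate")
  # sample mode uses divide-by-(n-1)
  x <- vec_with(1, 2)
  ps <- site_profile(x, "folding", std_mode = "sample")
  expect_equal(ps$std, sd(x), tolerance = 1e-12)
  pp <- site_profile(x, "folding", std_mode = "population")
  expect_lt(pp$std, ps$std)
})

test_that("tolerance rule: strictly |mean| > HSTD, sign-independent", {
  # mean exactly equal to HSTD is still tolerable (strict inequality);
  # set the fields exactly to avoid floating-point boundary noise
  p_eq <- site_profile(vec_with(1, 2), "folding")
  p_eq$mean <- 1; p_eq$hstd <- 1
  expect_identical(classify_tolerance(p_eq), "tolerable")
  p_eq$mean <- -1
  expect_identical(classify_tolerance(p_eq), "tolerable")
  x <- vec_with(1, 2)  # hstd ~ 1, mean ~ 1
  expect_identical(classify_tolerance(site_profile(x + 0.01, "folding")),
                   "non-tolerable")
  expect_identical(classify_tolerance(site_profile(-(x + 0.01), "folding")),
                   "non-tolerable")
  expect_identical(classify_tolerance(site_profile(x - 0.01, "folding")),
                   "tolerable")
  expect_identical(classify_tolerance(site_profile(vec_with(0.5, 2),
                                                   "binding")), "tolerable")
  expect_error(classify_tolerance(site_profile(abs(vec_with(3, 0.5)), "pka")),
               "classify_pka")
})

test_that("specificity rule: >20% beyond HSTD and in both directions", {
  rule <- function(x) {
    p <- site_profile(x, "folding")
    ex <- x[abs(x) > p$hstd]
    want <- if (length(ex) / 19 > 0.20 && any(ex > 0) && any(ex < 0))
      "specific" else "non-specific"
    expect_identical(classify_specificity(p), want)
    classify_specificity(p)
  }
  # hand-built: 15 tiny effects, 4 large ones split across signs -> specific
  x1 <- c(rep(0.01, 15), 8, 9, -8, -9) * 1.0
  expect_identical(rule(x1), "specific")
  # all large effects on one side -> non-specific no matter how many
  x2 <- c(rep(0.01, 13), -6, -7, -8, -9, -10, -11)
  expect_identical(rule(x2), "non-specific")
  # both signs but too few exceeders (3/19 < 20%) -> non-specific
  x3 <- c(rep(0.3, 8), rep(-0.3, 8), 9, -9, 8)
  ex3 <- sum(abs(x3) > site_profile(x3, "folding")$hstd)
  expect_identical(rule(x3), if (ex3 / 19 > 0.2) "specific" else "non-specific")
  # property check over random vectors: classifier always equals the rule
  set.seed(7)
  for (k in 1:50) rule(rnorm(19, 0, runif(1, 0.5, 5)))
})

test_that("pKa rules: mean > 2 sensitive, spread > 2 specific (strict)", {
  flat <- rep(c(2.0, 2.0), length.out = 19)
  expect_identical(unname(classify_pka(flat)),
                   c("non-sensitive", "non-specific"))
  hot <- rep(2.5, 19)
  expect_identical(classify_pka(hot)[["sensitivity"]], "sensitive")
  expect_identical(classify_pka(hot)[["specificity"]], "non-specific")
  spread <- c(rep(0.1, 18), 2.2)
  expect_identical(classify_pka(spread)[["sensitivity"]], "non-sensitive")
  expect_identical(classify_pka(spread)[["specificity"]], "specific")
  expect_error(classify_pka(rep(1, 18)), "19")
  expect_error(classify_pka(c(rep(1, 18), -0.1)), "non-negative")
})

test_that("classify_site records both labels, rationale and prose override", {
  x <- effect_table_fixture("g56", "folding", seed = 1)
  p <- site_profile(x, "folding", site_id = "site11", substitutions = names(x))
  cl <- classify_site(p)
  expect_identical(cl$tolerance, classify_tolerance(p))
  expect_identical(cl$specificity, classify_specificity(p))
  expect_match(cl$rationale, "HSTD")
  expect_null(cl$prose_override)
  cl2 <- classify_site(p, prose_override = "treated as tolerable in prose")
  expect_identical(cl2$tolerance, cl$tolerance)  # formal label unchanged
  expect_identical(cl2$prose_override, "treated as tolerable in prose")
})

test_that("site reports round-trip through JSON and order z-scores ascending", {
  xs <- list(effect_table_fixture("v132", "folding", seed = 4),
             effect_table_fixture("v132", "binding", seed = 4))
  profiles <- mapply(function(x, m) {
    site_profile(x, m, site_id = "site15", substitutions = names(x))
  }, xs, c("folding", "binding"), SIMPLIFY = FALSE)
  cls <- lapply(profiles, classify_site)
  path <- file.path(withr::local_tempdir(), "report")
  site_report(profiles, cls, path)
  expect_true(file.exists(paste0(path, ".json")))
  expect_true(file.exists(paste0(path, ".tsv")))
  tsv <- read.table(paste0(path, ".tsv"), header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  expect_equal(nrow(tsv), 38)  # 19 per metric
  for (m in c("folding", "binding")) {
    z <- tsv$zscore[tsv$metric == m]
    expect_true(all(diff(z) >= 0))  # ascending
  }
  js <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_match(js$specificity_rule, "20%")
  back <- read_site_report(path)
  for (k in 1:2) {
    expect_equal(sort(back$profiles[[k]]$effects),
                 sort(profiles[[k]]$effects), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_identical(back$classifications[[k]]$tolerance, cls[[k]]$tolerance)
    expect_identical(back$classifications[[k]]$specificity,
                     cls[[k]]$specificity)
  }
})
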