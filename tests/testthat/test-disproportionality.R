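test_that("contingency tables partition reports into the four cells", {
  rows <- c(rep(list(list(drugs = "D", events = "E")), 2),
            rep(list(list(drugs = "D", events = "OTHER")), 3),
            rep(list(list(drugs = "X", events = "E")), 1),
            rep(list(list(drugs = "X", events = "OTHER")), 4))
  t <- build_contingency(reports_from_rows(rows), "D", "E")
  expect_equal(c(t$a, t$b, t$c, t$d), c(2, 3, 1, 4))
  expect_equal(t$N, 10)
  # set semantics: a drug listed twice counts once
  t2 <- build_contingency(reports_from_rows(list(
    list(drugs = c("D", "D "), events = "E"))), "D", "E")
  expect_equal(t2$a, 1)
  expect_error(build_contingency(reports_from_rows(list())[0, ], "D", "E"),
               "empty")
})

test_that("contingency construction matches the brute-force oracle", {
  for (seed in 1:10) {
    reports <- deduplicate_reports(random_reports(100, seed = seed + 100))
    for (pair in list(c("DRUG A", "EVENT 1"), c("DRUG C", "EVENT 5"))) {
      t <- build_contingency(reports, pair[1], pair[2])
      expect_equal(c(a = t$a, b = t$b, c = t$c, d = t$d),
                   brute_contingency(reports, pair[1], pair[2]))
    }
  }
})

test_that("ROR and PRR match hand-computed values on the worked table", {
  t <- as_table(20, 80, 10, 890)
  r <- compute_ror(t)
  expect_equal(r$point, 22.25, tolerance = 1e-6)
  expect_equal(r$ci_lower, 10.07, tolerance = 0.01 / 10.07)
  expect_equal(r$ci_upper, 49.17, tolerance = 0.01 / 49.17)
  expect_false(r$corrected)
  p <- compute_prr(t)
  expect_equal(p$point, 18, tolerance = 1e-6)
  # symmetric table gives 1 for both
  sym <- as_table(10, 10, 10, 10)
  expect_equal(compute_ror(sym)$point, 1)
  expect_equal(compute_prr(sym)$point, 1)
})

test_that("zero cells trigger the shared continuity correction", {
  t <- as_table(0, 10, 5, 100)
  r <- compute_ror(t)
  expect_true(r$corrected)
  expect_equal(r$point, (0.5 * 100.5) / (10.5 * 5.5), tolerance = 1e-9)
  expect_true(compute_prr(t)$corrected)
  expect_true(all(c(r$point, r$ci_lower, r$ci_upper) > 0))
})

test_that("chi-square matches hand values, Yates and uncorrected", {
  t <- as_table(20, 80, 10, 890)
  expect_equal(chi_square(t, yates = TRUE), 103.95, tolerance = 0.01 / 103.95)
  expect_equal(chi_square(t, yates = FALSE), 110.35, tolerance = 0.01 / 110.35)
  # exact independence gives 0 uncorrected
  expect_equal(chi_square(as_table(1, 9, 9, 81), yates = FALSE), 0)
  # zero margin is defined as 0 with a warning
  expect_warning(z <- chi_square(as_table(0, 0, 5, 5)), "zero margin")
  expect_equal(z, 0)
})

test_that("chi-square agrees with an independent implementation", {
  # cross-check against stats::chisq.test on a handful of tables
  tables <- list(c(20, 80, 10, 890), c(5, 45, 50, 400), c(3, 7, 11, 79),
                 c(12, 3, 4, 21))
  for (cells in tables) {
    m <- matrix(cells, 2, 2, byrow = TRUE)
    # suppress chisq.test's small-expected-count advisory; the statistic
    # itself is exact
    ref_raw <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    ref_yates <- suppressWarnings(stats::chisq.test(m, correct = TRUE))
    expect_equal(chi_square(as_table(cells[1], cells[2], cells[3], cells[4]),
                            yates = FALSE),
                 unname(ref_raw$statistic), tolerance = 1e-9)
    expect_equal(chi_square(as_table(cells[1], cells[2], cells[3], cells[4]),
                            yates = TRUE),
                 unname(ref_yates$statistic), tolerance = 1e-9)
  }
})

test_that("BCPNN IC is zero at balanced independence and shrinks correctly", {
  ic <- bcpnn_ic(as_table(10, 10, 10, 10))
  expect_lt(abs(ic$ic), 0.1)
  expect_lt(ic$ic_minus_2sd, ic$ic)
  # large-sample limit approaches the relative reporting ratio
  k <- 1000
  ic2 <- bcpnn_ic(as_table(2 * k, 8 * k, 1 * k, 89 * k))
  expect_lt(abs(ic2$ic - log2(2 * 100 / (10 * 3))), 0.05)
  # ic_minus_2sd < ic on arbitrary tables
  for (seed in 1:20) {
    set.seed(seed)
    cells <- sample(0:30, 4, replace = TRUE)
    v <- bcpnn_ic(as_table(cells[1], cells[2], cells[3], cells[4] + 1))
    expect_lt(v$ic_minus_2sd, v$ic)
  }
})

test_that("Wald intervals obey the geometric-mean identity and symmetries", {
  set.seed(42)
  for (i in 1:50) {
    cells <- sample(1:200, 4, replace = TRUE)
    t <- as_table(cells[1], cells[2], cells[3], cells[4])
    r <- compute_ror(t)
    expect_equal(r$point, sqrt(r$ci_lower * r$ci_upper), tolerance = 1e-9)
    p <- compute_prr(t)
    expect_equal(p$point, sqrt(p$ci_lower * p$ci_upper), tolerance = 1e-9)
    # transpose symmetry: drug/event exchange leaves the ROR unchanged
    rt <- compute_ror(as_table(cells[1], cells[3], cells[2], cells[4]))
    expect_equal(r$point, rt$point, tolerance = 1e-12)
  }
  # monotonicity: with b, c, d fixed, ROR strictly increases in a
  rors <- vapply(1:20, function(a) compute_ror(as_table(a, 30, 20, 400))$point,
                 numeric(1))
  expect_true(all(diff(rors) > 0))
})

test_that("sign(ROR - PRR) always equals sign(ROR - 1)", {
  grid <- expand.grid(a = 1:6, b = 1:6, c = 1:6, d = 1:6)
  ror <- (grid$a * grid$d) / (grid$b * grid$c)
  prr <- (grid$a / (grid$a + grid$b)) / (grid$c / (grid$c + grid$d))
  expect_true(all(sign(round(ror - prr, 12)) == sign(round(ror - 1, 12))))
})

test_that("screening flags implement the three-method conjunction", {
  th <- signal_thresholds()
  m <- signal_metrics(as_table(20, 80, 10, 890), th)
  expect_true(m$flag_ror && m$flag_prr && m$flag_bcpnn && m$flag_overall)
  # minimum-count rule beats a huge ROR
  m2 <- signal_metrics(as_table(2, 1, 1, 996), th)
  expect_false(m2$flag_ror)
  expect_false(m2$flag_overall)
  # strict inequality on the lower bound
  m3 <- data.frame(a = 10, ror_lo = 1.0, prr = 5, chi2 = 10, ic025 = 1)
  expect_false(evaluate_signal(m3, th)$flag_ror)
  # overall is the conjunction of the three method flags
  for (seed in 1:10) {
    set.seed(seed)
    cells <- sample(1:50, 4, replace = TRUE)
    mm <- signal_metrics(as_table(cells[1], cells[2], cells[3], cells[4]), th)
    expect_equal(mm$flag_overall,
                 mm$flag_ror && mm$flag_prr && mm$flag_bcpnn)
  }
  # thresholds are overridable, including disjunctive combination
  loose <- signal_thresholds(min_a = 1, combine = "any")
  m4 <- signal_metrics(as_table(2, 1, 1, 996), loose)
  expect_true(m4$flag_overall)
})

test_that("the all-pairs signal table agrees with per-pair computation", {
  reports <- deduplicate_reports(random_reports(150, seed = 300))
  st <- signal_table(reports)
  expect_true(all(st$a > 0))
  for (i in sample(nrow(st), 5)) {
    t <- build_contingency(reports, st$drug[i], st$pt[i])
    expect_equal(c(t$a, t$b, t$c, t$d),
                 c(st$a[i], st$b[i], st$c[i], st$d[i]))
    expect_equal(compute_ror(t)$point, st$ror[i], tolerance = 1e-12)
    expect_equal(bcpnn_ic(t)$ic_minus_2sd, st$ic025[i], tolerance = 1e-12)
  }
})
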