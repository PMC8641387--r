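make_avail <- function(m, countries = sprintf("C%d", seq_len(nrow(m))),
                       indicators = sprintf("I%d", seq_len(ncol(m)))) {
  matrix(as.logical(m), nrow(m), ncol(m),
         dimnames = list(countries, indicators))
}

test_that("homogenization is a no-op on a complete, well-populated panel", {
  av <- make_avail(matrix(1, 4, 3))
  pops <- setNames(rep(10, 4), rownames(av))
  h <- homogenize_panel(av, pops, min_populations = 5)
  expect_identical(h$countries, rownames(av))
  expect_identical(h$indicators, colnames(av))
  expect_identical(nrow(h$audit), 0L)
})

test_that("a country holding 20 of 42 indicators falls at step 1", {
  av <- make_avail(rbind(matrix(1, 5, 42), c(rep(1, 20), rep(0, 22))))
  pops <- setNames(rep(200, 6), rownames(av))
  h <- homogenize_panel(av, pops, min_populations = 1)
  expect_false("C6" %in% h$countries)
  expect_identical(h$audit$step[h$audit$entity == "C6"], 1L)
  # 21 of 42 survives step 1 ("at least half"); it can still fall at the
  # complete-case step 3, which is where any removal must now come from
  av2 <- make_avail(rbind(matrix(1, 5, 42), c(rep(1, 21), rep(0, 21))))
  h2 <- homogenize_panel(av2, pops, min_populations = 1)
  expect_false(any(h2$audit$entity == "C6" & h2$audit$step == 1L))
  expect_true(all(h2$audit$step[h2$audit$entity == "C6"] == 3L))
})

test_that("a hand-enumerated 4x3 panel reproduces the three steps in order", {
  # C4 has only 1 of 3 indicators -> removed at step 1 (needs >= 2).
  # After that, I3 reaches 12 + 3 = 15 populations < 16 -> removed at
  # step 2. C3 lacks the retained I2 -> removed at step 3.
  av <- make_avail(rbind(c(1, 1, 1),
                         c(1, 1, 0),
                         c(1, 0, 1),
                         c(0, 0, 1)))
  pops <- setNames(c(12, 10, 3, 50), rownames(av))
  h <- homogenize_panel(av, pops, min_indicator_fraction = 0.5,
                        min_populations = 16)
  expect_identical(h$countries, c("C1", "C2"))
  expect_identical(h$indicators, c("I1", "I2"))
  expect_identical(h$audit$entity[h$audit$step == 1], "C4")
  expect_identical(h$audit$entity[h$audit$step == 2], "I3")
  expect_identical(h$audit$entity[h$audit$step == 3], "C3")
  # the order is load-bearing: counting C4's 50 populations before the step-1
  # removal would have kept I3 (12 + 3 + 50 >= 16); it is removed because
  # step 1 runs first
})

test_that("homogenization is idempotent", {
  set.seed(17)
  for (i in 1:10) {
    av <- make_avail(matrix(runif(20) < 0.75, 5, 4))
    pops <- setNames(sample(1:30, 5), rownames(av))
    h <- tryCatch(homogenize_panel(av, pops, min_populations = 15),
                  error = function(e) NULL)
    if (is.null(h)) next
    av2 <- av[h$countries, h$indicators, drop = FALSE]
    h2 <- homogenize_panel(av2, pops[h$countries], min_populations = 15)
    expect_identical(h2$countries, h$countries)
    expect_identical(h2$indicators, h$indicators)
    expect_identical(nrow(h2$audit), 0L)
  }
})

test_that("an emptied panel raises a named error", {
  av <- make_avail(matrix(c(1, 0, 0, 1), 2, 2))
  pops <- setNames(c(1, 1), rownames(av))
  expect_error(homogenize_panel(av, pops, min_populations = 1000),
               "homogenization emptied panel")
})

test_that("z-scoring centers, scales and orients indicator trends", {
  tr <- data.frame(country = c("A", "B", "C"), indicator_code = "i1",
                   mean_trend = c(1, 2, 3))
  z <- zscore_orient(tr)$z
  expect_equal(z$z, c(-1, 0, 1))
  zi <- zscore_orient(tr, invert = c(i1 = TRUE))$z
  expect_equal(zi$z, c(1, 0, -1))
  # per-indicator mean 0, SD 1 after normalization
  expect_lt(abs(mean(z$z)), 1e-12)
  expect_lt(abs(sd(z$z) - 1), 1e-12)
  # degenerate SD is excluded with a logged reason
  cz <- zscore_orient(data.frame(country = c("A", "B"), indicator_code = "i2",
                                 mean_trend = c(2, 2)))
  expect_identical(nrow(cz$z), 0L)
  expect_identical(cz$excluded$reason, "zero cross-country SD")
})

test_that("assembly cross-joins populations with their country's indicators", {
  w <- data.frame(population_id = c("P1", "P2", "P3"),
                  binomial = "Sp", order_name = "O", region = "R",
                  country = c("A", "A", "X"), taxon_class = "bird",
                  mean_trend = c(0.1, -0.1, 0.3), stringsAsFactors = FALSE)
  z <- data.frame(country = rep(c("A", "B"), each = 3),
                  indicator_code = rep(c("i1", "i2", "i3"), 2),
                  z = c(-1, 0, 1, 1, 0, -1), stringsAsFactors = FALSE)
  meta <- data.frame(country = c("A", "B"), land_area_km2 = c(1e5, 2e5),
                     hpd_1996 = c(50, 80), stringsAsFactors = FALSE)
  asm <- assemble_model_rows(w, z, meta)
  expect_identical(nrow(asm$rows), 6L)  # 2 populations x 3 indicators
  expect_identical(asm$dropped$population_id, "P3")
  expect_equal(unique(asm$rows$log_land_area), 5)
  expect_setequal(unique(asm$rows$indicator_code), c("i1", "i2", "i3"))
})

test_that("correlation table is symmetric with unit diagonal", {
  set.seed(23)
  n <- 200
  z <- rbind(
    data.frame(country = sprintf("C%03d", 1:n), indicator_code = "a",
               z = rnorm(n)),
    data.frame(country = sprintf("C%03d", 1:n), indicator_code = "b",
               z = rnorm(n)))
  z2 <- z[z$indicator_code == "a", ]
  z2$indicator_code <- "c"; z2$z <- -z2$z
  ct <- indicator_correlations(rbind(z, z2))
  r <- function(a, b) ct$r[ct$ind_a == a & ct$ind_b == b]
  expect_equal(r("a", "a"), 1)
  expect_equal(r("a", "c"), -1, tolerance = 1e-12)
  expect_equal(r("a", "b"), r("b", "a"))
  # two independent indicators over 200 countries: |r| < 0.2 whp
  expect_lt(abs(r("a", "b")), 0.2)
  # pairs below the minimum sample size are undefined
  small <- data.frame(country = c("C1", "C2"), indicator_code = "d",
                      z = c(1, -1))
  ct2 <- indicator_correlations(rbind(z[z$indicator_code == "a", ][1:2, ], small))
  expect_true(is.na(ct2$r[ct2$ind_a == "a" & ct2$ind_b == "d"]))
})
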