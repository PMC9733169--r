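make_table <- function(fits_df, roots, days, voxel = 1) {
  vec <- rsa_vector(roots, voxel, max(days))
  growth_table(fits_df, vec, days)
}

test_that("length at a day follows the relative-length identity", {
  expect_equal(length_at_day(100, 0.25), 75)
  expect_equal(length_at_day(42, 1), 0)
  expect_equal(length_at_day(42, 0), 42)
  expect_equal(length_at_day(10, c(0, 0.5, 1)), c(10, 5, 0))
  expect_error(length_at_day(10, 1.2), "outside")
  expect_error(length_at_day(-1, 0.5), ">= 0")
})

test_that("growth table lengths are monotone, 0 before x1 and full after x2", {
  days <- 7:27
  fits <- data.frame(root_id = "a", x1 = 10, x2 = 20, ythr = 1, mse = 0,
                     classification = "basic")
  tab <- make_table(fits, list(make_straight_root("a", n = 21, spacing = 5)), days)
  len <- tab$lengths$length_mm
  expect_true(all(diff(len) >= -1e-12))
  expect_equal(len[days < 10], rep(0, sum(days < 10)))
  expect_equal(len[days >= 20], rep(100, sum(days >= 20)), tolerance = 1e-12)
  expect_true(all(len >= 0 & len <= 100 + 1e-12))
})

test_that("root counts apply the positive-length rule with pre-existing roots", {
  days <- 7:20
  fits <- data.frame(root_id = c("a", "b", "c"),
                     x1 = c(9.5, 14.5, NA), x2 = c(15, 19, NA),
                     ythr = c(1, 1, NA), mse = 0,
                     classification = c("basic", "basic", "pre_existing"))
  roots <- list(make_straight_root("a", n = 11, spacing = 2),
                make_straight_root("b", n = 11, spacing = 3, y0 = 30),
                make_straight_root("c", n = 11, spacing = 4, y0 = 50))
  tab <- make_table(fits, roots, days)
  counts <- root_count_series(tab)
  manual <- sapply(days, function(d) sum(d > c(9.5, 14.5)) + 1)
  expect_equal(counts$count, as.integer(manual))
  expect_true(all(diff(counts$count) >= 0))
  # day before any emergence: only the pre-existing root
  expect_equal(counts$count[counts$day == 7], 1L)

  all_pre <- fits; all_pre$classification <- "pre_existing"
  expect_equal(unique(root_count_series(make_table(all_pre, roots, days))$count), 3L)
})

test_that("elongation rate is final length over elongation duration", {
  expect_equal(elongation_rate(100, 10, 20), 10)
  expect_error(elongation_rate(100, 20, 10), "x2 > x1")
  days <- 7:20
  fits <- data.frame(root_id = c("a", "b"), x1 = c(9, NA), x2 = c(14, NA),
                     ythr = 1, mse = 0,
                     classification = c("basic", "pre_existing"))
  roots <- list(make_straight_root("a", n = 11, spacing = 2),
                make_straight_root("b", n = 11, spacing = 3, y0 = 30))
  tab <- make_table(fits, roots, days)
  expect_equal(tab$roots$elongation_rate_mm_day, c(20 / 5, NA))
})

test_that("emergence-rate correlation handles collinear and degenerate input", {
  days <- 7:27
  n <- 8
  x1 <- seq(8, 18, length.out = n)
  roots <- lapply(seq_len(n), function(i)
    make_straight_root(sprintf("r%d", i), n = 11, spacing = (2 + 0.4 * (i - 1)),
                       y0 = 5 * i))
  fits <- data.frame(root_id = sprintf("r%d", 1:n), x1 = x1, x2 = x1 + 5,
                     ythr = 1, mse = 0, classification = "basic")
  tab <- make_table(fits, roots, days)
  ct <- emergence_rate_correlation(tab)
  expect_equal(ct$r, 1, tolerance = 1e-9)      # rate is linear in x1 here
  expect_lt(ct$p_value, 0.05)
  expect_equal(ct$n, n)

  # constant rates: undefined correlation, flagged not thrown
  same <- lapply(seq_len(n), function(i)
    make_straight_root(sprintf("r%d", i), n = 11, spacing = 2, y0 = 5 * i))
  tab2 <- make_table(fits, same, days)
  expect_warning(ct2 <- emergence_rate_correlation(tab2), "degenerate")
  expect_true(is.na(ct2$r))

  few <- fits[1:2, ]
  expect_error(emergence_rate_correlation(make_table(few, roots[1:2], days)),
               "at least 3")
})

test_that("phantom-derived rates correlate with emergence when built that way", {
  days <- 7:27
  n <- 20
  withr::with_seed(55, {
    x1 <- runif(n, 8, 18)
    rate <- 1.5 + 0.2 * (x1 - 8) + rnorm(n, 0, 0.1)
    dur <- runif(n, 4, 7)
    roots <- lapply(seq_len(n), function(i)
      make_straight_root(sprintf("r%02d", i), n = 11,
                         spacing = rate[i] * dur[i] / 10, y0 = 2 * i))
    fits <- data.frame(root_id = sprintf("r%02d", 1:n), x1 = x1, x2 = x1 + dur,
                       ythr = 1, mse = 0, classification = "basic")
    tab <- make_table(fits, roots, days)
    ct <- emergence_rate_correlation(tab)
    expect_gt(ct$r, 0)
    expect_lt(ct$p_value, 0.05)
  })
})

test_that("vector reconstruction truncates by arc length from the tip", {
  u <- make_straight_root("a", n = 11, spacing = 2)
  vec <- rsa_vector(list(u), 1, 27)
  rl <- data.frame(root_id = "a", day = c(20, 23, 25, 27), rl = c(1, 0.5, 0, 0))
  out <- reconstruct_vectors(vec, rl)
  expect_equal(names(out), c("20", "23", "25", "27"))

  # RL 1: root omitted
  expect_equal(length(out[["20"]]), 0L)
  # RL 0.5: retained arc is half the total, cut node interpolated
  kept <- out[["23"]]$roots[["a"]]$nodes
  arc <- max(rsa4d:::polyline_arclength(kept))
  expect_equal(arc, 10, tolerance = 1e-9)
  # RL 0 and the last day: exactly the input polyline
  expect_equal(out[["25"]]$roots[["a"]]$nodes, u$nodes)
  expect_identical(out[["27"]]$roots[["a"]]$nodes, u$nodes)

  expect_error(reconstruct_vectors(vec, transform(rl, rl = rl + 1)), "outside")
})
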