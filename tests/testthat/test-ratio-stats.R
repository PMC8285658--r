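exact_hist <- function(A = 100, x0 = 1.0, gamma = 0.3, width = 0.2,
                       from = 0, to = 3) {
  centers <- seq(from + width / 2, to, by = width)
  structure(list(breaks = seq(from, by = width,
                              length.out = length(centers) + 1L),
                 centers = centers,
                 counts = A / (1 + ((centers - x0) / gamma)^2),
                 bin_width = width, origin = from),
            class = "ratio_histogram")
}

test_that("ratios reproduce the published 3-decimal table values", {
  tab <- locust_abundance_table()
  r <- ratios_from_log_table(tab)
  lookup <- function(id) r$ratio[r$transcript_id == id]
  expect_equal(round(lookup("SCH_0029"), 3), 1.799)
  expect_equal(round(lookup("SCH_0044"), 3), 0.069)
  expect_equal(round(lookup("SCH_0350"), 3), 3.020)
  # equal logs give ratio exactly 1
  expect_equal(
    ratios_from_log_table(tibble::tibble(transcript_id = "t",
                                         log10_control = -1.2,
                                         log10_noise = -1.2))$ratio, 1.0)
  expect_error(
    ratios_from_log_table(tibble::tibble(transcript_id = "bad",
                                         log10_control = NA_real_,
                                         log10_noise = 0)),
    "bad")
})

test_that("histogram binning is half-open, conserving, and anchored", {
  h <- build_histogram(c(0.1, 0.3, 0.31), bin_width = 0.2, origin = 0)
  expect_equal(h$counts[1:2], c(1L, 2L))
  expect_equal(sum(h$counts), 3L)
  expect_equal(h$breaks[1], 0)

  # empty input -> all-zero histogram
  h <- build_histogram(numeric(0))
  expect_equal(sum(h$counts), 0L)

  # a value on an edge goes to the right-hand bin
  h <- build_histogram(c(0.1, 0.2), bin_width = 0.2, origin = 0)
  expect_equal(h$counts, c(1L, 1L))
  expect_equal(h$breaks, c(0, 0.2, 0.4))

  # the 500 bundled ratios: total conserved, modal bin contains 1.0
  r <- ratios_from_log_table(locust_abundance_table())
  h <- build_histogram(r, 0.2, 0)
  expect_equal(sum(h$counts), 500L)
  modal <- which.max(h$counts)
  expect_true(h$breaks[modal] <= 1 && 1 < h$breaks[modal + 1L])

  expect_error(build_histogram(1:3, bin_width = 0), "positive")
})

test_that("the Cauchy curve and CDF satisfy their defining identities", {
  fit <- structure(list(A = 50, x0 = 1.2, gamma = 0.4), class = "cauchy_fit")
  expect_equal(cauchy_f(1.2, fit), 50)
  expect_equal(cauchy_f(1.2 + 0.4, fit), 25)
  expect_equal(cauchy_f(1.2 - 0.4, fit), 25)
  d <- seq(0.1, 2, by = 0.3)
  expect_equal(cauchy_f(1.2 + d, fit), cauchy_f(1.2 - d, fit))
  expect_equal(cauchy_cdf(1.2, fit), 0.5)
  expect_equal(cauchy_cdf(1.2 + d, fit) + cauchy_cdf(1.2 - d, fit),
               rep(1, length(d)))
  expect_equal(cauchy_cdf(1.2 + 0.4, fit), 0.75)
})

test_that("exact-curve histograms are fitted to machine precision", {
  h <- exact_hist(A = 100, x0 = 1.0, gamma = 0.3)
  fit <- fit_cauchy(h)
  expect_lt(abs(fit$A - 100) / 100, 1e-6)
  expect_lt(abs(fit$x0 - 1.0), 1e-6)
  expect_lt(abs(fit$gamma - 0.3) / 0.3, 1e-6)
  expect_lt(fit$sse, 1e-10)

  # symmetric +/-1 count perturbations move x0 by less than half a bin
  h2 <- exact_hist()
  n <- length(h2$counts)
  h2$counts <- h2$counts + rep_len(c(1, -1), n)
  fit2 <- fit_cauchy(h2)
  expect_lt(abs(fit2$x0 - 1.0), 0.1)

  # degenerate histograms are refused
  h3 <- exact_hist()
  h3$counts <- c(5, rep(0, n - 2L), 3)
  expect_error(fit_cauchy(h3), "degenerate")
})

test_that("CDF inversion matches the closed-form quantile", {
  fit <- structure(list(A = 10, x0 = 1.007, gamma = 0.087),
                   class = "cauchy_fit")
  expect_equal(invert_cdf(0.5, fit), fit$x0, tolerance = 1e-9)
  expect_equal(invert_cdf(0.75, fit), fit$x0 + fit$gamma, tolerance = 1e-9)
  for (p in seq(0.01, 0.99, by = 0.07)) {
    closed <- fit$x0 + fit$gamma * tan(pi * (p - 0.5))
    expect_lt(abs(invert_cdf(p, fit) - closed), 1e-9)
    expect_lt(abs(cauchy_cdf(invert_cdf(p, fit), fit) - p), 1e-9)
  }
  expect_error(invert_cdf(0, fit), "inside")
  expect_error(invert_cdf(1.2, fit), "inside")
})

test_that("tail selection is strict, order-invariant, and finds planted outliers", {
  fit <- structure(list(A = 10, x0 = 1, gamma = 0.05), class = "cauchy_fit")

  # all ratios at the median -> both tails empty
  r <- tibble::tibble(transcript_id = sprintf("t%d", 1:10), ratio = rep(1, 10))
  sel <- select_tails(r, fit)
  expect_equal(nrow(sel$decreased) + nrow(sel$increased), 0L)

  # planted construction: 480 null ratios near 1 plus 10 at 5.0, 10 at 0.05
  set.seed(73)
  null_r <- numeric(0)
  while (length(null_r) < 480) {
    x <- 1 + 0.05 * tan(pi * (runif(1000) - 0.5))
    null_r <- c(null_r, x[x >= 0.8 & x <= 1.2])
  }
  null_r <- null_r[1:480]
  ratios <- tibble::tibble(
    transcript_id = sprintf("t%03d", 1:500),
    ratio = c(null_r, rep(5.0, 10), rep(0.05, 10))
  )
  h <- build_histogram(ratios, 0.2, 0.05)
  fit2 <- fit_cauchy(h)
  sel <- select_tails(ratios, fit2)
  expect_setequal(sel$increased$transcript_id, sprintf("t%03d", 481:490))
  expect_setequal(sel$decreased$transcript_id, sprintf("t%03d", 491:500))

  # order invariance
  sel2 <- select_tails(ratios[sample(500), ], fit2)
  expect_equal(sel2$increased, sel$increased)
  expect_equal(sel2$decreased, sel$decreased)

  # a ratio exactly on a cutoff is excluded, with a message
  r3 <- tibble::tibble(transcript_id = c("onecut", "below"),
                       ratio = c(sel$upper_cutoff, 0.0001))
  expect_message(sel3 <- select_tails(r3, fit2), "onecut")
  expect_false("onecut" %in% sel3$increased$transcript_id)

  # widening gamma never grows the selection
  sizes <- vapply(c(0.05, 0.1, 0.2), function(g) {
    f <- structure(list(A = 10, x0 = 1, gamma = g), class = "cauchy_fit")
    s <- select_tails(ratios, f)
    nrow(s$decreased) + nrow(s$increased)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("the bundled dataset reproduces the curated reference analysis", {
  a <- locust_noise_analysis()
  ref <- locust_reference_selection()

  # every curated ratio is reproduced within the 3-decimal rounding slack
  r <- a$ratios
  m <- match(ref$transcript_id, r$transcript_id)
  expect_true(all(abs(r$ratio[m] - ref$ratio) <= 0.005))

  # the selected identifier sets match the curated lists
  expect_setequal(a$selection$increased$transcript_id,
                  ref$transcript_id[ref$direction == "increased"])
  expect_setequal(a$selection$decreased$transcript_id,
                  ref$transcript_id[ref$direction == "decreased"])
})
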