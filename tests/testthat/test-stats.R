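test_that("roi_mean computes masked summaries", {
  labs <- array(0L, dim = c(3, 2, 1)); labs[1:3] <- 2L
  m <- array(7, dim = c(3, 2, 1))
  expect_equal(roi_mean(m, labs, 2L), list(mean = 7, sd = 0, n = 3))
  m[1:3] <- c(1, 2, 3)
  r <- roi_mean(m, labs, 2L)
  expect_equal(c(r$mean, r$sd, r$n), c(2, 1, 3))
  expect_error(roi_mean(m, labs, 4L), "absent")
  expect_error(roi_mean(array(0, dim = c(2, 2, 1)), labs, 2L), "identical shape")
})

test_that("paired t-test matches the closed form and the reference", {
  r <- paired_t_test(c(0.29, 0.31, 0.27), c(0.15, 0.14, 0.16))
  # hand computation: d = (.14,.17,.11), mean .14, sd .03,
  # t = .14/(.03/sqrt(3)); df=2 t-CDF closed form: P(|T|>t) = 1 - t/sqrt(2+t^2)
  t_hand <- 0.14 / (0.03 / sqrt(3))
  expect_equal(r$t, t_hand, tolerance = 1e-12)
  expect_equal(r$df, 2)
  expect_equal(r$p, 1 - t_hand / sqrt(2 + t_hand^2), tolerance = 1e-12)
  expect_equal(round(r$t, 3), 8.083)
  expect_equal(round(r$p, 4), 0.0150)

  # identical vectors and sign symmetry
  expect_equal(paired_t_test(1:5, 1:5), list(t = 0, df = 4, p = 1))
  swap <- paired_t_test(c(0.15, 0.14, 0.16), c(0.29, 0.31, 0.27))
  expect_equal(swap$t, -r$t); expect_equal(swap$p, r$p)

  # agreement with the independent reference implementation
  set.seed(10)
  for (i in 1:20) {
    a <- rnorm(sample(3:12, 1)); b <- rnorm(length(a))
    ours <- paired_t_test(a, b)
    ref <- t.test(a, b, paired = TRUE)
    expect_lt(abs(ours$t - unname(ref$statistic)), 1e-10)
    expect_lt(abs(ours$p - ref$p.value), 1e-10)
  }
  expect_error(paired_t_test(1, 1), "n >= 2")
  expect_warning(r0 <- paired_t_test(c(2, 3), c(1, 2)), "zero-variance")
  expect_equal(r0$p, 0)
})

test_that("pearson_r matches hand values and the reference", {
  x <- 1:4
  expect_equal(pearson_r(x, 2 * x)$r, 1)
  expect_equal(pearson_r(x, -x + 7)$r, -1)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4))$r, 0.8)
  set.seed(20)
  for (i in 1:20) {
    a <- rnorm(sample(4:15, 1)); b <- rnorm(length(a))
    ours <- pearson_r(a, b)
    ref <- cor.test(a, b)
    expect_lt(abs(ours$r - unname(ref$estimate)), 1e-10)
    expect_lt(abs(ours$p - ref$p.value), 1e-10)
  }
  # affine invariance, sign follows the slope
  a <- rnorm(10); b <- rnorm(10)
  expect_equal(pearson_r(3 * a - 2, b)$r, pearson_r(a, b)$r, tolerance = 1e-12)
  expect_equal(pearson_r(-a, b)$r, -pearson_r(a, b)$r, tolerance = 1e-12)
  expect_error(pearson_r(1:2, 1:2), "n >= 3")
  expect_error(pearson_r(rep(1, 5), rnorm(5)), "zero variance")
})

make_fits <- function(n_sub, params, classes = names(tissue_classes()),
                      gen = function(cl, ph, p, n) rnorm(n)) {
  do.call(rbind, lapply(classes, function(cl) {
    do.call(rbind, lapply(time_phases(), function(ph) {
      do.call(rbind, lapply(params, function(p) {
        data.frame(subject = sprintf("s%02d", 1:n_sub), class = cl,
                   phase = ph, param = p, value = gen(cl, ph, p, n_sub))
      }))
    }))
  }))
}

test_that("group-comparison tables: flags, null case, missing phase", {
  set.seed(30)
  fits <- make_fits(10, c("f", "D"))
  # after == before: all t = 0, no flags
  same <- fits
  v <- same[same$phase == "BEFORE", "value"]
  same[same$phase == "AFTER", "value"] <- v
  tab <- build_parameter_tables(same)
  expect_true(all(tab$t == 0) && all(tab$flag == ""))

  # flags are a pure function of p at the 0.05 / 0.01 thresholds
  set.seed(31)
  tab2 <- build_parameter_tables(make_fits(8, c("f", "Ktrans", "BF")))
  expect_identical(tab2$flag,
                   ifelse(tab2$p < 0.01, "**", ifelse(tab2$p < 0.05, "*", "")))
  expect_true(all(tab2$df == 7))

  broken <- fits[!(fits$subject == "s01" & fits$phase == "AFTER" &
                     fits$param == "f" & fits$class == "T_RFA"), ]
  expect_error(build_parameter_tables(broken), "missing phase")
})

test_that("correlation table: layout, perfect-correlation sanity, small n", {
  params <- c("BF", "BV", "PMB", "Ktrans", "Ve", "Kep", "D_star", "f")
  set.seed(40)
  fits <- make_fits(10, params)
  tab <- build_correlation_table(fits)
  expect_equal(nrow(tab), 4 * 6 * 2)
  expect_true(all(tab$n == 10))
  expect_true(all(tab$r >= -1 & tab$r <= 1) && all(tab$p >= 0 & tab$p <= 1))

  # feeding the same values as perfusion and IVIM parameter gives r = 1
  dup <- fits
  for (cl in names(tissue_classes())) for (ph in time_phases()) {
    src <- dup$class == cl & dup$phase == ph & dup$param == "f"
    dst <- dup$class == cl & dup$phase == ph & dup$param == "BF"
    dup$value[dst] <- dup$value[src]
  }
  td <- build_correlation_table(dup)
  expect_true(all(td$r[td$perfusion_param == "BF" & td$ivim_param == "f"] == 1))

  expect_error(build_correlation_table(make_fits(2, params)), "n >= 3")
  expect_error(build_correlation_table(fits[fits$param != "BV", ]),
               "missing parameter")
})

test_that("independent draws produce no systematic correlation (null envelope)", {
  params <- c("BF", "BV", "PMB", "Ktrans", "Ve", "Kep", "D_star", "f")
  set.seed(50)
  rs <- unlist(lapply(1:20, function(rep) {
    build_correlation_table(make_fits(10, params))$r
  }))
  # critical |r| at alpha=0.05, df=8 is 0.632; the exceedance rate over
  # 960 independent cells should sit near 5% (3-sigma binomial envelope)
  rate <- mean(abs(rs) >= 0.6319)
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / length(rs)))
  expect_lt(abs(mean(rs)), 3 * sd(rs) / sqrt(length(rs)) + 0.02)
})
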