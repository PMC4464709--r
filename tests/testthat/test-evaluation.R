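test_that("Bland-Altman statistics reproduce hand arithmetic on the bundled tables", {
  # three-patient volume comparison from the bundled table
  tab <- patient_volume_table()
  ba <- bland_altman(tab$cine_ml, tab$reference_ml)
  expect_equal(ba$mean_diff, -8 / 3, tolerance = 1e-9)
  # identity
  id <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(id$mean_diff, 0)
  expect_equal(id$sd_diff, 0)
  expect_equal(id$r2, 1)
  # antisymmetry of the differences, symmetry of r2
  a <- c(51, 45.7, 55.3, 48.2, 65.8); b <- c(54, 51, 61, 55, 70)
  expect_equal(bland_altman(a, b)$mean_diff, -bland_altman(b, a)$mean_diff)
  expect_equal(bland_altman(a, b)$r2, bland_altman(b, a)$r2)
  # limits of agreement at +/- 2 SD
  ab <- bland_altman(a, b)
  expect_equal(ab$loa_high - ab$loa_low, 4 * ab$sd_diff)
  # percent differences use the pairwise mean as denominator
  expect_error(bland_altman(1:3, 1:4), class = "atriarecon_stats_error")
  expect_equal(tidy(ab)$pct_diff[2], 100 * (45.7 - 51) / ((45.7 + 51) / 2))
  expect_equal(round(tidy(ab)$pct_diff[2], 2), -10.96)
})

test_that("paired t-test matches hand computation and flags zero variance", {
  b <- c(10, 20, 30, 40)
  a <- b + c(1, 2, 3, 4)
  pt <- paired_t(a, b)
  expect_equal(pt$t, 2.5 / (sd(c(1, 2, 3, 4)) / 2), tolerance = 1e-9)
  expect_equal(pt$t, 3.872983, tolerance = 1e-6)
  expect_equal(pt$df, 3)
  expect_error(paired_t(b + 2, b), class = "atriarecon_stats_error")
  jit <- b + c(0, 1e-3, -1e-3, 0)
  expect_lt(abs(paired_t(jit, b)$t), 1) # a = b up to jitter: t near 0
})

test_that("2x2 repeated-measures ANOVA interaction equals the paired-t double difference", {
  set.seed(42)
  for (k in 1:5) {
    d <- expand.grid(subject = paste0("s", 1:6), a = c("A", "B"), m = c("X", "Y"))
    d$value <- rnorm(24) + rep(rnorm(6), 4)
    an <- rm_anova_2x2(d, subject = "subject", a = "a", m = "m", value = "value")
    cells <- with(d, tapply(value, list(subject, a, m), mean))
    dd <- (cells[, 2, 2] - cells[, 1, 2]) - (cells[, 2, 1] - cells[, 1, 1])
    ht <- t.test(dd)
    expect_equal(an$p_interaction, ht$p.value, tolerance = 1e-12)
    expect_equal(an$F_interaction, unname(ht$statistic)^2, tolerance = 1e-9)
  }
  # pure interaction pattern: zero main effects, positive interaction F
  d <- expand.grid(subject = paste0("s", 1:4), a = c("A", "B"), m = c("X", "Y"))
  delta <- 2
  d$value <- rep(rnorm(4, sd = 5), 4) +
    delta * ifelse((d$a == "B") == (d$m == "Y"), 1, -1)
  an <- rm_anova_2x2(d, subject = "subject", a = "a", m = "m", value = "value")
  expect_equal(an$effects$F[1], 0)
  expect_equal(an$effects$F[2], 0)
  expect_gt(an$F_interaction, 0)
  # all cells equal per subject: no interaction at all
  d$value <- rep(1:4, 4)
  an0 <- rm_anova_2x2(d, subject = "subject", a = "a", m = "m", value = "value")
  expect_equal(an0$F_interaction, 0)
  d_inc <- d[-1, ]
  expect_error(rm_anova_2x2(d_inc, subject = "subject", a = "a", m = "m",
                            value = "value"), class = "atriarecon_stats_error")
})

test_that("border sharpness measures the 20-80% edge transition over 8 rays", {
  nr <- 101
  # disk with a linear edge ramp of width 10 px: sharpness 1/6 per ray
  img <- outer(1:nr, 1:nr, function(r, c) {
    d <- sqrt((r - 51)^2 + (c - 51)^2)
    pmax(0, pmin(1, (35 - d) / 10 + 0.5))
  })
  wall <- circle_contour(35, 128, c(51, 51))
  e <- endocardial_border_sharpness(img, wall, c(51, 51))
  expect_equal(e$n_used, 8)
  expect_equal(e$ebs, 1 / 6, tolerance = 0.005)
  # radial symmetry: all profiles agree
  expect_lt(diff(range(e$per_profile)), 1e-3)
  # ideal step edge: capped at 1
  img2 <- outer(1:nr, 1:nr, function(r, c) (sqrt((r - 51)^2 + (c - 51)^2) <= 35) + 0)
  expect_equal(endocardial_border_sharpness(img2, wall, c(51, 51))$ebs, 1)
  # rays that exit the image are dropped and flagged
  off <- circle_contour(35, 128, c(51, 95))
  img3 <- outer(1:nr, 1:nr, function(r, c) (sqrt((r - 51)^2 + (c - 95)^2) <= 35) + 0)
  expect_warning(e3 <- endocardial_border_sharpness(img3, off, c(51, 95)), "dropped")
  expect_lt(e3$n_used, 8)
  expect_error(endocardial_border_sharpness(img, wall, c(2, 2)),
               class = "atriarecon_stats_error")
})
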