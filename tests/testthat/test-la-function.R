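test_that("functional indices reproduce the bundled patient worked examples", {
  tab <- patient_function_table()
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    idx <- la_indices_from_volumes(r$v_max, r$v_min, r$v_pre_a, lv_sv = r$lv_sv)
    expect_equal(round(idx$total_emptying, 1), r$total_conduit)
    expect_equal(round(idx$total_ef, 1), r$total_ef)
    expect_equal(round(idx$passive_emptying, 1), r$passive_emptying)
    expect_equal(round(idx$active_emptying, 1), r$active_emptying)
    expect_equal(round(idx$passive_fraction), r$passive_fraction)
    expect_equal(round(idx$active_fraction), r$active_fraction)
    expect_equal(round(idx$passive_la_flow, 1), r$passive_la_flow)
  }
})

test_that("emptying volumes are conserved and fractions sum to 100", {
  set.seed(3)
  for (k in 1:20) {
    v <- sort(runif(3, 30, 120))
    idx <- la_indices_from_volumes(v[3], v[1], v[2])
    expect_equal(idx$passive_emptying + idx$active_emptying, idx$total_emptying)
    expect_equal(idx$passive_fraction + idx$active_fraction, 100)
    expect_gte(idx$total_ef, 0); expect_lt(idx$total_ef, 100)
  }
  expect_error(la_indices_from_volumes(50, 60, 55), class = "atriarecon_curve_error")
  expect_error(la_indices_from_volumes(80, 40, 90), class = "atriarecon_curve_error")
})

test_that("phase location finds maximum, minimum and the pre-contraction shoulder", {
  pc <- atriarecon:::.prescribed_curve(82.6, 43.6, 64.4, 34)
  cv <- tv_curve(0:33, (0:33) * 30, pc$volumes, rr_ms = 34 * 30)
  ph <- locate_phases(cv)
  expect_equal(ph$i_max, pc$i_max)
  expect_equal(ph$i_min, 0)
  expect_equal(ph$i_pre_a, pc$i_pre)
  expect_equal(ph$confidence, "ok")
  # explicit override wins
  expect_equal(locate_phases(cv, pre_a_frame = 20)$i_pre_a, 20)
  # NA encodes absent atrial contraction
  expect_equal(locate_phases(cv, pre_a_frame = NA)$i_pre_a, ph$i_min)
  # flat curve has no cardiac variation
  flat <- tv_curve(0:9, (0:9) * 30, rep(60, 10))
  expect_error(locate_phases(flat), class = "atriarecon_curve_error")
  # monotone decay without a shoulder: flagged low confidence
  mono <- tv_curve(0:15, (0:15) * 30, c(60, 80, seq(79, 40, length.out = 14)))
  expect_equal(locate_phases(mono)$confidence, "low")
})

test_that("indices from an analytic curve match the prescription exactly", {
  pc <- atriarecon:::.prescribed_curve(82.6, 43.6, 64.4, 34)
  cv <- tv_curve(0:33, (0:33) * 30, pc$volumes, rr_ms = 34 * 30)
  idx <- la_indices(cv, lv_sv = 104)
  expect_equal(idx$v_max, 82.6, tolerance = 1e-9)
  expect_equal(idx$v_min, 43.6, tolerance = 1e-9)
  expect_equal(idx$v_pre_a, 64.4, tolerance = 1e-9)
  expect_equal(idx$passive_la_flow, 65)
  # mean phase rates: phase volume over phase duration
  expect_equal(idx$passive_rate, (82.6 - 64.4) / ((pc$i_pre - pc$i_max) * 30))
  expect_equal(idx$active_rate, (64.4 - 43.6) / ((34 - pc$i_pre) * 30))
})

test_that("indices are invariant to rotating the starting frame", {
  pc <- atriarecon:::.prescribed_curve(82.6, 43.6, 64.4, 34)
  for (shift in c(5, 12, 21)) {
    rot <- c((shift + 1):34, 1:shift)
    cv <- tv_curve(0:33, (0:33) * 30, pc$volumes[rot], rr_ms = 34 * 30)
    idx <- la_indices(cv)
    expect_equal(idx$v_max, 82.6, tolerance = 1e-9)
    expect_equal(idx$v_pre_a, 64.4, tolerance = 1e-9)
    expect_equal(idx$total_ef, 100 * 39 / 82.6, tolerance = 1e-9)
  }
})

test_that("tidy and glance expose the index table", {
  idx <- la_indices_from_volumes(82.6, 43.6, 64.4, lv_sv = 104)
  td <- tidy(idx)
  expect_named(td, c("index", "value", "unit"))
  expect_equal(td$value[td$index == "Total conduit volume"], 39)
  g <- glance(idx)
  expect_equal(g$total_ef, 100 * 39 / 82.6)
})
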