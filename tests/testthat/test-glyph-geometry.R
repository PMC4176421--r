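# Value resolution and chart geometry in the unit box.

test_that("series resolve from literals, scalars, and list columns", {
  node <- node_record("n1",
    scalars = list(gal1RGexp = -2.4, gal4RGexp = 0.5, gal80Rexp = 1.1),
    lists = list(Values = c(1, 2, 0.5))
  )
  s <- resolve_series(parse_instruction('piechart: values="1,1,2"'), node)
  expect_equal(s$value, c(1, 1, 2))
  expect_equal(nrow(s), 3)
  expect_length(unique(s$color), 3)

  hs <- resolve_series(parse_instruction(galactose_heatstrip), node)
  expect_equal(hs$value, c(-2.4, 0.5, 1.1))
  expect_equal(hs$label, c("gal1RGexp", "gal4RGexp", "gal80Rexp"))

  lv <- resolve_series(parse_instruction('linechart: attributelist="Values"'), node)
  expect_equal(lv$value, c(1, 2, 0.5))

  expect_error(
    resolve_series(parse_instruction('barchart: attributelist="nope"'), node),
    class = "glyph_error_missing_attribute"
  )
  node2 <- node_record("n2", scalars = list(a = "abc"))
  expect_error(
    resolve_series(parse_instruction('barchart: attributelist="a"'), node2),
    class = "glyph_error_type"
  )
})

test_that("updown colorlists color each value by sign", {
  node <- node_record("n", scalars = list(a = 2, b = -1, c = 0))
  s <- resolve_series(
    parse_instruction('barchart: attributelist="a,b,c" colorlist="up:red,down:blue"'),
    node
  )
  expect_equal(s$color, c("#FF0000FF", "#0000FFFF", "#000000FF"))
})

test_that("normalization is symmetric about zero for straddling ranges", {
  expect_equal(normalize_value(3, c(-3, 3)), 1)
  expect_equal(normalize_value(0, c(-3, 3)), 0)
  expect_equal(normalize_value(-1.5, c(-3, 3)), -0.5)
  # asymmetric straddling range still divides by the larger magnitude
  expect_equal(normalize_value(1, c(-1, 4)), 0.25)
  # out-of-range clamps
  expect_equal(normalize_value(10, c(-3, 3)), 1)
  expect_equal(normalize_value(-10, c(-3, 3)), -1)
  expect_error(normalize_value(1, c(3, -3)), class = "glyph_error_range")
})

test_that("non-straddling ranges map affinely onto [0, 1]", {
  withr::with_seed(5, {
    for (i in 1:50) {
      lo <- stats::runif(1, 0, 5); hi <- lo + stats::runif(1, 0.1, 5)
      v <- stats::runif(1, lo - 1, hi + 1)
      expect_equal(normalize_value(v, c(lo, hi)), oracle_affine(v, lo, hi))
    }
  })
})

test_that("normalize_value is monotone nondecreasing in v", {
  withr::with_seed(17, {
    for (i in 1:20) {
      lo <- stats::runif(1, -5, 2); hi <- lo + stats::runif(1, 0.5, 6)
      v <- sort(stats::runif(10, lo - 1, hi + 1))
      t <- normalize_value(v, c(lo, hi))
      expect_true(all(diff(t) >= -1e-12))
    }
  })
})

test_that("pie slices are proportional, ordered, and validated", {
  s <- make_series(c(1, 1, 2))
  p <- pie_layout(s)
  expect_equal(p$extent, c(90, 90, 180))
  expect_equal(p$start_angle, c(0, 90, 180))
  expect_equal(unique(p$inner_radius), 0)
  expect_equal(unique(p$outer_radius), 0.5)

  srt <- pie_layout(s, sortslices = TRUE)
  expect_equal(srt$value, c(2, 1, 1))
  # stable under ties: equal values keep their input order
  tied <- make_series(c(5, 3, 5), labels = c("first", "mid", "second"))
  expect_equal(pie_layout(tied, sortslices = TRUE)$label,
               c("first", "second", "mid"))

  expect_error(pie_layout(make_series(c(0, 0))), class = "glyph_error_degenerate_pie")
  expect_error(pie_layout(make_series(c(1, -1))), class = "glyph_error_negative_slice")
})

test_that("pie respects arcstart", {
  p <- pie_layout(make_series(c(1, 1)), arcstart = 90)
  expect_equal(p$start_angle, c(90, 270))
})

test_that("circos rings stack radially from firstarc", {
  ring <- make_series(c(1, 1))
  one <- circos_layout(list(ring), firstarc = 0.4, firstarcwidth = 0.2)
  expect_equal(unique(one$inner_radius), 0.2)
  expect_equal(unique(one$outer_radius), 0.3)
  expect_equal(one$extent, c(180, 180))

  two <- circos_layout(list(ring, ring), firstarc = 0.4, firstarcwidth = 0.2,
                       arcwidth = 0.2)
  r1 <- two[two$ring == 2, ]
  expect_equal(unique(r1$inner_radius), 0.3)
  expect_equal(unique(r1$outer_radius), 0.4)

  expect_error(
    circos_layout(list(ring, ring, ring), firstarc = 0.5, firstarcwidth = 0.3,
                  arcwidth = 0.3),
    class = "glyph_error_overflow"
  )
})

test_that("extents in every ring sum to 360 degrees", {
  withr::with_seed(23, {
    for (i in 1:40) {
      n <- sample(1:8, 1)
      s <- make_series(stats::runif(n, 0, 10) + 1e-6)
      expect_equal(sum(pie_layout(s)$extent), 360, tolerance = 1e-12)
      rings <- lapply(1:sample(1:3, 1), function(k) {
        make_series(stats::runif(sample(1:6, 1), 0, 5) + 1e-6)
      })
      cl <- circos_layout(rings, firstarc = 0.2, firstarcwidth = 0.15,
                          arcwidth = 0.15)
      sums <- tapply(cl$extent, cl$ring, sum)
      expect_true(all(abs(sums - 360) < 1e-9))
    }
  })
})

test_that("bars extend from the baseline by the normalized value", {
  b <- bar_layout(make_series(1), ybase = "bottom")
  expect_equal(c(b$y0, b$y1), c(0, 1))
  expect_equal(c(b$x0, b$x1), c(0, 1))

  b2 <- bar_layout(make_series(c(1, -1)), ybase = "middle")
  expect_equal(c(b2$y0[1], b2$y1[1]), c(0, 0.5))
  expect_equal(c(b2$y0[2], b2$y1[2]), c(0.5, 1))

  expect_error(bar_layout(make_series(1:3), separation = 60),
               class = "glyph_error_overflow")
})

test_that("separation is measured in 100-unit reference units", {
  b <- bar_layout(make_series(c(1, 1)), separation = 10)
  expect_equal(b$x0[2] - b$x1[1], 0.1)
  expect_equal(b$x1[2], 1)
})

test_that("heat strips share bar geometry and add gradient fills", {
  yb <- ramp_for_keyword("yellowblue")
  s <- make_series(c(3, -3, 0))
  bars <- bar_layout(s, range = c(-3, 3))
  strips <- heatstrip_layout(s, ramp = yb, range = c(-3, 3))
  expect_equal(strips[c("x0", "x1", "y0", "y1")], bars[c("x0", "x1", "y0", "y1")])
  expect_equal(strips$t, c(1, -1, 0))
  expect_equal(strips$tip_color, c("#FFFF00FF", "#0000FFFF", "#808080FF"))
  # zero value gives a zero-height bar
  expect_equal(strips$y0[3], strips$y1[3])
  # fill gradients run from tip to the ramp's zero color
  f <- strips$fill[[1]]
  expect_equal(f$stops[[1]]$color, "#FFFF00FF")
  expect_equal(f$stops[[2]]$color, "#808080FF")
})

test_that("line charts place points at i/(n-1) about the baseline", {
  flat <- line_layout(make_series(c(0, 0, 0), colors = rep("#000000FF", 3)),
                      ybase = "middle", range = c(-1, 1))
  expect_equal(flat$points$y, rep(0.5, 3))
  seg <- line_layout(make_series(c(-1, 1), colors = rep("#000000FF", 2)),
                     ybase = "middle")
  expect_equal(seg$points$x, c(0, 1))
  expect_equal(seg$points$y, c(1, 0))
  expect_error(line_layout(make_series(5)), class = "glyph_error_too_few_points")
  expect_equal(line_layout(make_series(c(1, 2)), linewidth = 2)$linewidth, 0.02)
})

test_that("stripes partition the box equally in palette order", {
  s <- stripe_layout(c("#AA0000FF", "#00AA00FF", "#0000AAFF"))
  expect_equal(s$x0, c(0, 1, 2) / 3)
  expect_equal(s$x1, c(1, 2, 3) / 3)
  expect_equal(s$color[1], "#AA0000FF")
  whole <- stripe_layout("#123456FF")
  expect_equal(c(whole$x0, whole$x1, whole$y0, whole$y1), c(0, 1, 0, 1))
})

test_that("gradient frames carry axis, center, and stops", {
  lg <- gradient_frame(parse_instruction(
    'lingrad: start="0,0" end="1,0" stoplist="255,255,255,255,0|0,0,255,255,1"'
  ))
  expect_equal(lg$type, "linear")
  expect_equal(c(lg$x1, lg$y1, lg$x2, lg$y2), c(0, 0, 1, 0))
  expect_length(lg$stops, 2)

  rg <- gradient_frame(parse_instruction(
    'radgrad: center="0.5,0.5" radius="0.5" stoplist="255,0,0,255,0"'
  ))
  expect_equal(rg$type, "radial")
  expect_equal(c(rg$cx, rg$cy, rg$r), c(0.5, 0.5, 0.5))

  expect_error(
    gradient_frame(parse_instruction(
      'lingrad: start="0.5,0.5" end="0.5,0.5" stoplist="255,0,0,255,0"'
    )),
    class = "glyph_error_degenerate_axis"
  )
})

test_that("all chart geometry stays inside the unit box", {
  withr::with_seed(31, {
    for (i in 1:60) {
      n <- sample(1:8, 1)
      values <- stats::runif(n, -10, 10)
      series <- make_series(values)
      ybase <- sample(list("top", "middle", "bottom", stats::runif(1)), 1)[[1]]
      rng <- if (stats::runif(1) < 0.5) c(-10, 10) else NULL
      b <- bar_layout(series, separation = stats::runif(1, 0, 80 / max(n, 2)),
                      ybase = ybase, range = rng)
      expect_true(all(b$x0 >= -1e-9 & b$x1 <= 1 + 1e-9))
      expect_true(all(b$y0 >= -1e-9 & b$y1 <= 1 + 1e-9))
      expect_true(all(b$x0 < b$x1))
      expect_true(all(b$y0 <= b$y1))
      if (n >= 2) {
        l <- line_layout(series, ybase = ybase, range = rng)
        expect_true(all(l$points$x >= 0 & l$points$x <= 1))
        expect_true(all(l$points$y >= -1e-9 & l$points$y <= 1 + 1e-9))
      }
      p <- pie_layout(make_series(abs(values) + 1e-9))
      expect_true(all(p$outer_radius <= 0.5))
      expect_true(all(p$extent >= 0))
    }
  })
})

test_that("missing values render at zero extent with a warning", {
  expect_warning(
    b <- bar_layout(make_series(c(1, NA, -1)), ybase = "middle", range = c(-1, 1)),
    class = "glyph_warning_missing_value"
  )
  expect_equal(b$y0[2], b$y1[2])
})
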