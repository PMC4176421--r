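# Instruction mini-language: tokenizing, typed argument parsing, schema
# validation, and canonical serialization.

test_that("tokenizer splits prefix and name=value pairs", {
  tok <- tokenize_instruction('piechart: values="1,1,2" colorlist="rainbow"')
  expect_equal(tok$prefix, "piechart")
  expect_equal(tok$args, list(values = "1,1,2", colorlist = "rainbow"))

  tok <- tokenize_instruction(paste0(
    'heatstripchart: attributelist="gal1RGexp,gal4RGexp,gal80Rexp" ',
    'colorlist="yellowblue" range="-3.0,3.0"'
  ))
  expect_equal(tok$prefix, "heatstripchart")
  expect_equal(tok$args$attributelist, "gal1RGexp,gal4RGexp,gal80Rexp")
  expect_equal(tok$args$range, "-3.0,3.0")

  # prefixes are lowercased before validation
  expect_equal(tokenize_instruction("PieChart: values=1")$prefix, "piechart")
})

test_that("tokenizer handles quoting, whitespace, and malformed input", {
  # quoted values may contain spaces and '='
  tok <- tokenize_instruction('barchart: labels="a=1 b=2" values=3,4')
  expect_equal(tok$args$labels, "a=1 b=2")
  expect_equal(tok$args$values, "3,4")
  # newlines separate pairs like any whitespace
  tok <- tokenize_instruction("piechart:\n  values=\"1,2\"\n  sortslices=true")
  expect_equal(tok$args$sortslices, "true")

  expect_error(tokenize_instruction('donut: values="1"'),
               class = "glyph_error_unknown_type")
  expect_error(tokenize_instruction("piechart: values=1 values=2"),
               class = "glyph_error_duplicate_arg")
  err <- tryCatch(tokenize_instruction('piechart: values="1,2'),
                  glyph_error = identity)
  expect_true(is_glyph_error(err, "syntax"))
  expect_true(is.numeric(err$offset) && err$offset > 0)
})

test_that("color tokens parse to bounded RGBA", {
  expect_equal(unclass(parse_color("#FF0000")), c(255L, 0L, 0L, 255L),
               ignore_attr = TRUE)
  expect_equal(unclass(parse_color("#00000080")), c(0L, 0L, 0L, 128L),
               ignore_attr = TRUE)
  expect_equal(parse_color("#ff00Ff"), parse_color("#FF00FF"))
  expect_equal(unclass(parse_color("red")), c(255L, 0L, 0L, 255L),
               ignore_attr = TRUE)
  expect_error(parse_color("blurple"), class = "glyph_error_color_parse")
  expect_error(parse_color("#12345"), class = "glyph_error_color_parse")
})

test_that("stoplists decode, validate bounds, and sort by position", {
  stops <- parse_stoplist("255,0,0,255,0|0,0,255,255,1")
  expect_length(stops, 2)
  expect_equal(stops[[1]]$color, rgba(255, 0, 0))
  expect_equal(stops[[2]]$position, 1)

  sorted <- parse_stoplist("255,255,0,255,0.5|255,0,0,255,0.0")
  expect_equal(sorted[[1]]$color, rgba(255, 0, 0))
  expect_equal(sorted[[1]]$position, 0)
  expect_equal(sorted[[2]]$position, 0.5)

  expect_error(parse_stoplist("0,0,0,256,0"), class = "glyph_error_range")
  expect_error(parse_stoplist("0,0,0,255,1.5"), class = "glyph_error_range")
  expect_error(parse_stoplist("0,0,0,255"), class = "glyph_error_arity")
})

test_that("colorlists classify into keyword, gradient, updown, explicit", {
  expect_equal(parse_colorlist("rainbow"), list(mode = "keyword", keyword = "rainbow"))
  expect_equal(parse_colorlist("yellowblue"),
               list(mode = "gradient_keyword", keyword = "yellowblue"))
  ud <- parse_colorlist("up:red,down:blue")
  expect_equal(ud$mode, "updown")
  expect_equal(ud$up, rgba(255, 0, 0))
  expect_equal(ud$down, rgba(0, 0, 255))
  expect_equal(ud$zero, rgba(0, 0, 0))  # default zero is opaque black
  ud2 <- parse_colorlist("up:#FF0000,down:#0000FF,zero:#FFFFFF")
  expect_equal(ud2$zero, rgba(255, 255, 255))
  ex <- parse_colorlist("#FF0000,#00FF00")
  expect_equal(ex$mode, "explicit")
  expect_length(ex$colors, 2)
  expect_error(parse_colorlist("up:red,blue"), class = "glyph_error_syntax")
})

test_that("parse_instruction applies the per-prefix schema", {
  lg <- parse_instruction(
    'lingrad: start="0,0" end="1,0" stoplist="255,255,255,255,0|0,0,255,255,1"'
  )
  expect_equal(lg$prefix, "lingrad")
  expect_equal(lg$chart$start, c(0, 0))
  expect_equal(lg$chart$end, c(1, 0))
  expect_length(lg$chart$stoplist, 2)

  cc <- parse_instruction(
    'circoschart: attributelist="Circle1,Circle2" firstarc=0.4 arcwidth=0.3'
  )
  expect_equal(cc$common$attributelist, c("Circle1", "Circle2"))
  expect_equal(cc$chart$firstarc, 0.4)

  # forbidden and unknown arguments are hard, typed errors
  expect_error(parse_instruction('piechart: values="1,1,2" range="0,10"'),
               class = "glyph_error_forbidden_arg")
  expect_error(parse_instruction('circoschart: attributelist="a" ybase=middle'),
               class = "glyph_error_forbidden_arg")
  expect_error(parse_instruction('stripechart: colorlist="#FF0000" showlabels=true'),
               class = "glyph_error_forbidden_arg")
  expect_error(parse_instruction('piechart: values="1" colourlist="rainbow"'),
               class = "glyph_error_unknown_arg")

  # required arguments
  expect_error(parse_instruction('lingrad: start="0,0" end="1,1"'),
               class = "glyph_error_missing_required")
  expect_error(parse_instruction("piechart: sortslices=true"),
               class = "glyph_error_missing_required")
  expect_error(
    parse_instruction('barchart: values="1,2" attributelist="a,b"'),
    class = "glyph_error_forbidden_arg"
  )
  # heatstrip colorlist is restricted to ramps and updown colors
  expect_error(parse_instruction('heatstripchart: values="1" colorlist="rainbow"'),
               class = "glyph_error_value_type")
  expect_error(parse_instruction("linechart: values=1,2 scale=0"),
               class = "glyph_error_range")
})

test_that("labels default to attribute names and defaults are filled", {
  s <- parse_instruction('barchart: attributelist="a,b,c"')
  expect_equal(s$common$labels, c("a", "b", "c"))
  expect_equal(s$common$scale, 1)
  expect_true(s$common$showlabels)
  expect_equal(s$common$ybase, "bottom")
  expect_equal(s$chart$separation, 0)
})

test_that("argument order never affects the parsed spec", {
  a <- parse_instruction('barchart: values="1,2" colorlist="rainbow" scale=2')
  b <- parse_instruction('barchart: scale=2 colorlist="rainbow" values="1,2"')
  expect_identical(a, b)
})

test_that("serialization is canonical and round-trips", {
  s <- parse_instruction('piechart: values="1,1,2"')
  expect_equal(serialize_instruction(s), 'piechart: values="1.0,1.0,2.0"')

  hs <- parse_instruction(galactose_heatstrip)
  expect_identical(parse_instruction(serialize_instruction(hs)), hs)

  # serialize . parse . serialize == serialize . parse (fixed point)
  once <- serialize_instruction(hs)
  expect_identical(serialize_instruction(parse_instruction(once)), once)
})

test_that("scientific notation is rejected as a numeric literal", {
  expect_error(parse_instruction("barchart: values=1e3,2"),
               class = "glyph_error_value_type")
})

test_that("round-trip property holds over generated specs", {
  withr::with_seed(421, {
    for (i in 1:1000) {
      text <- random_instruction()
      spec <- parse_instruction(text)
      expect_identical(parse_instruction(serialize_instruction(spec)), spec,
                       label = sprintf("round-trip of %s", text))
    }
  })
})

test_that("parsing is total: arbitrary text gives a spec or one typed error", {
  withr::with_seed(99, {
    alphabet <- c(letters, LETTERS, 0:9, ":", "=", '"', ",", "|", " ", "#", ".", "-")
    for (i in 1:300) {
      text <- paste(sample(alphabet, sample(3:40, 1), replace = TRUE), collapse = "")
      res <- tryCatch(parse_instruction(text), glyph_error = identity)
      expect_true(inherits(res, "glyph_spec") || is_glyph_error(res),
                  label = sprintf("total parse of %s", text))
    }
    # and with a valid prefix grafted on
    for (i in 1:200) {
      text <- paste0(sample(glyph_prefixes(), 1), ": ",
                     paste(sample(alphabet, sample(0:30, 1), replace = TRUE),
                           collapse = ""))
      res <- tryCatch(parse_instruction(text), glyph_error = identity)
      expect_true(inherits(res, "glyph_spec") || is_glyph_error(res))
    }
  })
})

test_that("tidy and glance summarize specs", {
  s <- parse_instruction(galactose_heatstrip)
  td <- tidy(s)
  expect_true(all(c("attributelist", "colorlist", "range") %in% td$argument))
  g <- glance(s)
  expect_equal(g$prefix, "heatstripchart")
  expect_equal(g$category, "chart")
  expect_true(g$uses_attributes)
})
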