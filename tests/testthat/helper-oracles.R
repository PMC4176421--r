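# Shared helpers: independent scalar oracles and a random instruction
# generator used by the property suites.

# Brute-force per-channel linear interpolation between two rgba colors,
# kept deliberately independent of the package's vectorized path.
oracle_lerp <- function(c0, c1, w) {
  out <- integer(4)
  for (k in 1:4) {
    v <- as.numeric(c0[[k]]) * (1 - w) + as.numeric(c1[[k]]) * w
    out[[k]] <- floor(v + 0.5)
  }
  out
}

# Affine normalization oracle for non-negative ranges.
oracle_affine <- function(v, lo, hi) {
  t <- (v - lo) / (hi - lo)
  min(max(t, 0), 1)
}

rand_color_hex <- function() {
  sprintf("#%02X%02X%02X%02X", sample(0:255, 1), sample(0:255, 1),
          sample(0:255, 1), sample(0:255, 1))
}

rand_colorlist <- function() {
  switch(sample(4, 1),
    sample(c("contrasting", "modulated", "rainbow", "random"), 1),
    sample(gradient_keywords(), 1),
    sprintf("up:%s,down:%s", rand_color_hex(), rand_color_hex()),
    paste(replicate(sample(1:4, 1), rand_color_hex()), collapse = ",")
  )
}

rand_num <- function(lo, hi) round(stats::runif(1, lo, hi), 3)

rand_stoplist <- function() {
  n <- sample(1:4, 1)
  paste(replicate(n, paste(
    c(sample(0:255, 3, replace = TRUE), sample(0:255, 1), rand_num(0, 1)),
    collapse = ","
  )), collapse = "|")
}

# A random, syntactically valid instruction string. Arguments are emitted
# in shuffled order and with a random quoting style, to exercise the
# parser's order- and quoting-independence.
random_instruction <- function() {
  prefix <- sample(glyph_prefixes(), 1)
  args <- character()
  add <- function(name, value, quote = sample(c(TRUE, FALSE), 1)) {
    quote <- quote || grepl("\\s", value)
    args[[name]] <<- if (quote) sprintf('%s="%s"', name, value) else
      sprintf("%s=%s", name, value)
  }
  if (prefix %in% c("lingrad", "radgrad")) {
    add("stoplist", rand_stoplist(), quote = TRUE)
    if (prefix == "lingrad") {
      if (stats::runif(1) < 0.7) add("start", paste(rand_num(0, 1), rand_num(0, 1), sep = ","))
      if (stats::runif(1) < 0.7) add("end", paste(rand_num(0, 1), rand_num(0, 1), sep = ","))
    } else {
      if (stats::runif(1) < 0.7) add("center", paste(rand_num(0, 1), rand_num(0, 1), sep = ","))
      if (stats::runif(1) < 0.7) add("radius", as.character(rand_num(0, 1)))
    }
  } else if (prefix == "stripechart") {
    add("colorlist", paste(replicate(sample(1:5, 1), rand_color_hex()), collapse = ","),
        quote = TRUE)
  } else {
    n <- sample(2:5, 1)
    if (stats::runif(1) < 0.5) {
      add("values", paste(replicate(n, rand_num(-5, 5)), collapse = ","), quote = TRUE)
    } else {
      add("attributelist", paste(sprintf("col%d", seq_len(n)), collapse = ","),
          quote = TRUE)
    }
    cl <- if (prefix == "heatstripchart") {
      if (stats::runif(1) < 0.5) sample(gradient_keywords(), 1) else
        sprintf("up:%s,down:%s", rand_color_hex(), rand_color_hex())
    } else {
      rand_colorlist()
    }
    if (stats::runif(1) < 0.8) add("colorlist", cl, quote = TRUE)
    if (stats::runif(1) < 0.4) {
      add("labels", paste(sample(letters, n), collapse = ","), quote = TRUE)
    }
    if (stats::runif(1) < 0.3) add("labelcolor", rand_color_hex())
    if (stats::runif(1) < 0.3) {
      add("labelstyle", sample(c("italics", "bold", "bolditalic", "plain"), 1))
    }
    if (stats::runif(1) < 0.3) add("showlabels", sample(c("true", "false"), 1))
    if (!prefix %in% c("piechart", "circoschart")) {
      if (stats::runif(1) < 0.4) {
        lo <- rand_num(-10, 0); hi <- rand_num(0.5, 10)
        add("range", paste(lo, hi, sep = ","), quote = TRUE)
      }
      if (stats::runif(1) < 0.3) add("scale", as.character(rand_num(0.2, 3)))
      if (stats::runif(1) < 0.3) {
        add("ybase", sample(c("top", "middle", "bottom", as.character(rand_num(0, 1))), 1))
      }
    }
    if (prefix %in% c("barchart", "heatstripchart") && stats::runif(1) < 0.4) {
      add("separation", as.character(rand_num(0, 5)))
    }
    if (prefix == "linechart" && stats::runif(1) < 0.4) {
      add("linewidth", as.character(rand_num(0.5, 4)))
    }
    if (prefix %in% c("piechart", "circoschart")) {
      if (stats::runif(1) < 0.4) add("arcstart", as.character(rand_num(0, 359)))
      if (stats::runif(1) < 0.4) add("sortslices", sample(c("true", "false"), 1))
    }
    if (prefix == "circoschart") {
      if (stats::runif(1) < 0.4) add("firstarc", as.character(rand_num(0, 0.4)))
      if (stats::runif(1) < 0.4) add("firstarcwidth", as.character(rand_num(0.05, 0.3)))
      if (stats::runif(1) < 0.4) add("arcwidth", as.character(rand_num(0.05, 0.3)))
      if (stats::runif(1) < 0.3) add("labelcircles", sample(c("true", "false"), 1))
    }
  }
  paste0(prefix, ": ", paste(sample(args), collapse = " "))
}

# A small resolved series for layout tests.
make_series <- function(values, labels = rep("", length(values)),
                        colors = generate_palette("rainbow", length(values))) {
  tibble::tibble(value = values, label = labels, color = colors)
}

galactose_heatstrip <- paste0(
  'heatstripchart: attributelist="gal1RGexp,gal4RGexp,gal80Rexp" ',
  'colorlist="yellowblue" range="-3.0,3.0"'
)
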