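#!/usr/bin/env Rscript
# Command-line front end for the nodeglyphs package.
#
#   Rscript scripts/glyphctl.R render --network net.graphml --table nodes.tsv \
#       --config config.yaml --out out.svg [--skip-bad-nodes] [--seed N]
#   Rscript scripts/glyphctl.R validate --table nodes.tsv --column instr
#   Rscript scripts/glyphctl.R demo --out figures/ [--seed N]
#
# Exit status is 0 iff no typed error occurred; warnings (clamped values,
# font fallbacks, skipped nodes) go to stderr and never fail a run.

suppressMessages(library(nodeglyphs))

usage <- function() {
  cat(
    "usage: glyphctl.R <command> [options]\n",
    "commands:\n",
    "  render    --network FILE --table FILE --config FILE --out FILE\n",
    "            [--skip-bad-nodes] [--seed N]\n",
    "  validate  --table FILE --column NAME\n",
    "  demo      --out DIR [--seed N]\n",
    sep = ""
  )
}

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1L) {
  usage()
  quit(status = 2)
}
command <- args[[1L]]
rest <- args[-1L]
opt <- function(flag, default = NULL) {
  i <- which(rest == flag)
  if (length(i) == 1L && i < length(rest)) rest[[i + 1L]] else default
}
has_flag <- function(flag) flag %in% rest

run <- function(expr) {
  withCallingHandlers(
    tryCatch(expr, glyph_error = function(e) {
      cat("error: ", conditionMessage(e), "\n", sep = "", file = stderr())
      quit(status = 1)
    }),
    glyph_warning = function(w) {
      cat("warning: ", conditionMessage(w), "\n", sep = "", file = stderr())
      invokeRestart("muffleWarning")
    }
  )
}

if (command == "render") {
  out <- opt("--out")
  if (is.null(out) || is.null(opt("--config"))) {
    usage(); quit(status = 2)
  }
  run(cmd_render(
    network_path = opt("--network"),
    table_path = opt("--table"),
    config_path = opt("--config"),
    out = out,
    skip_bad_nodes = has_flag("--skip-bad-nodes"),
    seed = if (!is.null(opt("--seed"))) as.integer(opt("--seed"))
  ))
  cat("wrote ", out, "\n", sep = "")
} else if (command == "validate") {
  table_path <- opt("--table"); column <- opt("--column")
  if (is.null(table_path) || is.null(column)) {
    usage(); quit(status = 2)
  }
  res <- run(cmd_validate(table_path, column))
  bad <- res$report[!res$report$ok, ]
  for (i in seq_len(nrow(bad))) {
    cat(sprintf("%s: %s\n", bad$id[[i]], bad$error[[i]]))
  }
  cat(sprintf("%d ok, %d errors\n", res$n_ok, res$n_error))
  quit(status = if (res$n_error > 0) 1 else 0)
} else if (command == "demo") {
  out_dir <- opt("--out")
  if (is.null(out_dir)) {
    usage(); quit(status = 2)
  }
  paths <- run(cmd_demo(out_dir, seed = as.integer(opt("--seed", "1"))))
  for (p in paths) cat("wrote ", p, "\n", sep = "")
} else {
  usage()
  quit(status = 2)
}
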