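#!/usr/bin/env Rscript
# Thin command-line wrapper over the ftrcop package.
#
#   Rscript scripts/ftrcop.R simulate  --out DIR --n-low 10 --n-high 28 --seed 1
#   Rscript scripts/ftrcop.R analyze   --session DIR --out report.json
#   Rscript scripts/ftrcop.R reliability --trials trials.csv --out rel.json
#   Rscript scripts/ftrcop.R classify  --features features.csv --seed 1 --out models.json
#   Rscript scripts/ftrcop.R predict   --ftr12 2.5 [--cutoff 2.83]
#
# Exit codes: 0 ok, 2 usage/config error, 3 data error.

suppressPackageStartupMessages({
  library(optparse)
  library(ftrcop)
})

fail <- function(msg, code) { message(msg); quit(status = code) }
`%||%` <- function(a, b) if (is.null(a)) b else a

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1L)
  fail("usage: ftrcop.R <simulate|analyze|reliability|classify|predict> [options]", 2)
cmd <- args[[1L]]
rest <- args[-1L]

opt_spec <- list(
  make_option("--out", type = "character", default = NULL),
  make_option("--seed", type = "integer", default = NULL),
  make_option("--n-low", type = "integer", default = 10L, dest = "n_low"),
  make_option("--n-high", type = "integer", default = 28L, dest = "n_high"),
  make_option("--session", type = "character", default = NULL),
  make_option("--trials", type = "character", default = NULL),
  make_option("--features", type = "character", default = NULL),
  make_option("--ftr12", type = "double", default = NULL),
  make_option("--cutoff", type = "double", default = 2.83)
)
o <- tryCatch(parse_args(OptionParser(option_list = opt_spec), args = rest),
              error = function(e) fail(conditionMessage(e), 2))

run <- function(expr) {
  tryCatch(expr,
           ftrcop_parameter_error = function(e) fail(conditionMessage(e), 2),
           error = function(e) fail(conditionMessage(e), 3))
}

if (cmd == "simulate") {
  if (is.null(o$seed) || is.null(o$out)) fail("simulate requires --seed and --out", 2)
  run({
    cohort <- make_cohort(o$n_low, o$n_high, seed = o$seed)
    for (i in seq_along(cohort))
      write_session(cohort[[i]], file.path(o$out, cohort[[i]]$subject$subject_id))
    message("wrote ", length(cohort), " sessions under ", o$out)
  })
} else if (cmd == "analyze") {
  if (is.null(o$session)) fail("analyze requires --session", 2)
  run({
    an <- analyze_session(read_session(o$session))
    out <- o$out %||% file.path(o$session, "ftr_report.json")
    jsonlite::write_json(list(trials = an$trials, conditions = an$conditions),
                         out, auto_unbox = TRUE, digits = NA, dataframe = "rows")
    readr::write_csv(an$conditions, sub("\\.json$", ".csv", out))
    message("wrote ", out)
  })
} else if (cmd == "reliability") {
  if (is.null(o$trials)) fail("reliability requires --trials (per-repetition CSV)", 2)
  run({
    rel <- reliability_table(readr::read_csv(o$trials, show_col_types = FALSE))
    out <- o$out %||% "reliability.json"
    jsonlite::write_json(rel, out, auto_unbox = TRUE, digits = NA, dataframe = "rows")
    message("wrote ", out)
  })
} else if (cmd == "classify") {
  if (is.null(o$features) || is.null(o$seed)) fail("classify requires --features and --seed", 2)
  run({
    cmp <- classify_cohort(readr::read_csv(o$features, show_col_types = FALSE),
                           seed = o$seed)
    out <- o$out %||% "models.json"
    jsonlite::write_json(cmp, out, auto_unbox = TRUE, digits = NA, dataframe = "rows")
    message("best model: ", cmp$model[cmp$best], " (CAIC ", round(min(cmp$caic), 2), ")")
    message("wrote ", out)
  })
} else if (cmd == "predict") {
  if (is.null(o$ftr12)) fail("predict requires --ftr12", 2)
  run(cat(apply_threshold(o$ftr12, cutoff = o$cutoff), "\n"))
} else {
  fail(paste0("unknown command '", cmd, "'"), 2)
}
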