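#!/usr/bin/env Rscript
# Thin command-line front end over the mdscape package.
#
#   Rscript scripts/mdscape.R generate --preset substrate --n-frames 1000 \
#       --seed 1 --outdir fixtures/sub1
#   Rscript scripts/mdscape.R analyze --config run.yaml
#
# Exit codes: 0 success, 1 user error (bad arguments/config), 2 internal.

suppressMessages({
  library(mdscape)
  library(optparse)
})

usage <- function() {
  cat("usage: mdscape.R <generate|analyze> [options]\n",
      "  generate --preset NAME --n-frames N --seed S --outdir DIR",
      " [--format dcd|pdb]\n",
      "  analyze  --config FILE.yaml\n", sep = "")
}

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1) { usage(); quit(status = 1) }
cmd <- args[1]
rest <- args[-1]

run <- function(expr) {
  tryCatch(expr, user_error = function(e) {
    message("error: ", conditionMessage(e)); usage(); quit(status = 1)
  }, error = function(e) {
    message("internal error: ", conditionMessage(e)); quit(status = 2)
  })
}

user_stop <- function(...) stop(errorCondition(paste0(...),
                                               class = "user_error"))

if (cmd == "generate") {
  opts <- parse_args(OptionParser(option_list = list(
    make_option("--preset", type = "character"),
    make_option("--n-frames", type = "integer", dest = "n_frames"),
    make_option("--seed", type = "integer", default = 1L),
    make_option("--outdir", type = "character"),
    make_option("--format", type = "character", default = "dcd"))),
    args = rest)
  run({
    if (is.null(opts$preset) || is.null(opts$n_frames) ||
        is.null(opts$outdir))
      user_stop("generate requires --preset, --n-frames and --outdir")
    if (!opts$preset %in% names(preset_model()))
      user_stop("unknown preset '", opts$preset, "' (available: ",
                paste(names(preset_model()), collapse = ", "), ")")
    paths <- generate_fixture(opts$preset, opts$n_frames, opts$seed,
                              opts$outdir, opts$format)
    cat("wrote:\n"); for (p in paths) cat(" ", p, "\n")
  })
} else if (cmd == "analyze") {
  opts <- parse_args(OptionParser(option_list = list(
    make_option("--config", type = "character"))), args = rest)
  run({
    if (is.null(opts$config)) user_stop("analyze requires --config")
    cfg <- tryCatch(run_config(opts$config),
                    error = function(e) user_stop(conditionMessage(e)))
    res <- analyze_run(cfg)
    m <- res$minimum
    cat(sprintf("pooled landscape minimum: (%.2f, %.2f) A, %.2f%% of observations\n",
                m$x, m$y, m$percent))
    cat("report bundle in", cfg$output_dir, "\n")
  })
} else {
  usage(); quit(status = 1)
}
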