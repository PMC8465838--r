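#!/usr/bin/env Rscript

# Thin command-line wrapper over the neuroTE package.
#
#   Rscript scripts/neurote.R simulate  --out DIR [--seed N] [--duration MS]
#                                       [--realizations N] [--gI MV]
#   Rscript scripts/neurote.R pipeline  --out DIR [--seed N] [--duration MS]
#                                       [--realizations N] [--gI MV]
#                                       [--bin MS] [--noise]
#   Rscript scripts/neurote.R infer     --raster FILE --out DIR [--kx N]
#                                       [--ky N] [--delay N]
#   Rscript scripts/neurote.R evaluate  --te FILE --truth FILE --out FILE
#   Rscript scripts/neurote.R fixtures  --kind KIND --out DIR [--bins N]
#                                       [--seed N]
#   Rscript scripts/neurote.R reproduce --table N --out FILE [--seed N]
#                                       [--realizations N] [--duration MS]
#
# `infer` accepts any delimited 0/1 neurons-x-bins matrix, so the TE stage
# can run on non-simulated data.

suppressPackageStartupMessages({
  library(optparse)
  library(neuroTE)
})

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1)
  stop("usage: neurote.R {simulate|pipeline|infer|evaluate|fixtures|reproduce} ...")
cmd <- args[1]

ol <- list(
  make_option("--seed", type = "integer", default = 1L),
  make_option("--out", type = "character", default = "neurote_out"),
  make_option("--duration", type = "double", default = 300000),
  make_option("--realizations", type = "integer", default = 1L),
  make_option("--gI", type = "double", default = 400),
  make_option("--bin", type = "double", default = 10),
  make_option("--noise", action = "store_true", default = FALSE),
  make_option("--raster", type = "character", default = NULL),
  make_option("--te", type = "character", default = NULL),
  make_option("--truth", type = "character", default = NULL),
  make_option("--kx", type = "integer", default = 1L),
  make_option("--ky", type = "integer", default = 2L),
  make_option("--delay", type = "integer", default = 0L),
  make_option("--roi-sweep", type = "integer", default = 20L,
              dest = "roi_sweep"),
  make_option("--kind", type = "character", default = "copier"),
  make_option("--bins", type = "integer", default = 1000L),
  make_option("--table", type = "integer", default = 1L)
)
opt <- parse_args(OptionParser(option_list = ol), args[-1])

switch(cmd,
  simulate = {
    dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
    reals <- simulate_realizations(opt$realizations, duration = opt$duration,
                                   seed = opt$seed,
                                   synapse = synapse_params(g_I = opt$gI))
    write_topology(reals[[1]]$topology, file.path(opt$out, "topology"))
    for (r in seq_along(reals))
      write_spikes(reals[[r]]$spikes,
                   file.path(opt$out, sprintf("spikes_%02d.tsv", r)))
    message("wrote ", opt$out)
  },
  pipeline = {
    bm <- run_pipeline(list(n_realizations = opt$realizations,
                            duration = opt$duration, g_I = opt$gI,
                            bin_size = opt$bin, noisy = opt$noise),
                       opt$out, seed = opt$seed)
    print(bm)
  },
  infer = {
    if (is.null(opt$raster)) stop("--raster is required")
    ras <- read_raster(opt$raster, bin_size = opt$bin)
    res <- te_matrix(ras, te_config(opt$kx, opt$ky, opt$delay))
    dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
    for (comp in c("te_total", "te_E", "te_I"))
      write.table(res[[comp]][, , 1],
                  file.path(opt$out, paste0(comp, ".tsv")),
                  sep = "\t", row.names = FALSE, col.names = FALSE)
    message("wrote ", opt$out)
  },
  evaluate = {
    if (is.null(opt$te) || is.null(opt$truth))
      stop("--te and --truth are required")
    sc <- as.matrix(read.table(opt$te, sep = "\t"))
    tr <- as.matrix(read.table(opt$truth, sep = "\t")) != 0
    roc <- roc_curve(sc, tr)
    out <- data.frame(auc = roc$auc, j = roc$youden_j,
                      sensitivity = roc$sensitivity_at_j,
                      specificity = roc$specificity_at_j)
    write.table(out, opt$out, sep = "\t", row.names = FALSE, quote = FALSE)
    print(roc)
  },
  fixtures = {
    fx <- make_fixtures(opt$kind, T_ = opt$bins, seed = opt$seed)
    dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
    write_raster(fx$raster, file.path(opt$out, "raster.tsv"))
    write.table(fx$truth_signed, file.path(opt$out, "truth_signed.tsv"),
                sep = "\t", row.names = FALSE, col.names = FALSE)
    message("wrote ", opt$out)
  },
  reproduce = {
    tab <- reproduce_table(opt$table, n_realizations = opt$realizations,
                           duration = opt$duration, seed = opt$seed)
    write.table(tab, opt$out, sep = "\t", row.names = FALSE, quote = FALSE)
    message("wrote ", opt$out)
  },
  stop("unknown subcommand: ", cmd)
)
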