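#!/usr/bin/env Rscript

## Thin command-line wrapper over kbdvh::runPipeline():
##   Rscript scripts/run_pipeline.R --site hn --n-train 70 --n-test 20 \
##     --seed 1 --out runs/hn-seed1 [--methods idvhs,dth_cpdvh]
##     [--grid 96,96,48] [--spacing 0.2,0.2,0.3]

suppressMessages({
  library(optparse)
  library(kbdvh)
})

parser <- OptionParser(option_list = list(
  make_option("--site", default = "hn", help = "hn or pelvis [%default]"),
  make_option("--n-train", type = "integer", default = NA_integer_,
              dest = "nTrain", help = "training patients (site default)"),
  make_option("--n-test", type = "integer", default = NA_integer_,
              dest = "nTest", help = "test patients (site default)"),
  make_option("--seed", type = "integer", default = 1L,
              help = "master seed [%default]"),
  make_option("--methods", default = "idvhs,dth_cpdvh",
              help = "comma-separated feature methods [%default]"),
  make_option("--grid", default = "96,96,48",
              help = "grid shape nx,ny,nz [%default]"),
  make_option("--spacing", default = "0.2,0.2,0.3",
              help = "voxel spacing cm [%default]"),
  make_option("--out", default = "kbdvh-run",
              help = "output directory [%default]")
))
opt <- parse_args(parser)

triple <- function(s, f = as.numeric) f(strsplit(s, ",")[[1]])
cfg <- runConfig(
  site = toupper(opt$site),
  nTrain = if (is.na(opt$nTrain)) NULL else opt$nTrain,
  nTest = if (is.na(opt$nTest)) NULL else opt$nTest,
  methods = toupper(strsplit(opt$methods, ",")[[1]]),
  seed = opt$seed,
  grid = gridSpec(triple(opt$grid, as.integer), triple(opt$spacing)),
  outDir = opt$out
)
res <- runPipeline(cfg, verbose = TRUE)
message("report tables written under ", opt$out)
for (nm in names(res$report)) {
  message("== ", nm, " ==")
  print(res$report[[nm]], digits = 3)
}
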