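# Shared configuration for the analysis workflow. Run the numbered scripts
# in order from the repository root:
#   Rscript analysis/01_simulate.R && Rscript analysis/02_detect.R && ...
# Every stage reads and writes under results/ and is fully reproducible
# from SEED.

suppressMessages(library(ISmobilome))

SEED <- 20170411L
RESULTS <- "results"
dir.create(RESULTS, recursive = TRUE, showWarnings = FALSE)

rpath <- function(...) file.path(RESULTS, ...)

# Study-scale replicon layout (scaled-down chromosome + megaplasmid):
# 33 planted copies split 21/12, variant copy numbers 28/4/1 and the
# directed-repeat length census {7:24, 6:4, 8:4, 5:1} of the survey.
REPLICONS <- list(
  chromosome = list(length = 120000L, gc = 0.618, circular = TRUE,
                    n_copies = 21L,
                    variants = c(rep("ISS12_A", 18), rep("ISS12_C", 2), "ISS12_D"),
                    tsd_lens = c(rep(7L, 15), rep(6L, 3), rep(8L, 2), 5L)),
  plasmid = list(length = 60000L, gc = 0.578, circular = TRUE,
                 n_copies = 12L,
                 variants = c(rep("ISS12_A", 10), rep("ISS12_C", 2)),
                 tsd_lens = c(rep(7L, 9), 6L, rep(8L, 2)))
)

# sites also present in the "previous" genome: 6 chromosome + 4 plasmid
N_PREVIOUS <- c(chromosome = 6L, plasmid = 4L)

read_truth <- function() {
  tr <- utils::read.delim(rpath("truth.tsv"), stringsAsFactors = FALSE)
  tibble::as_tibble(tr)
}
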