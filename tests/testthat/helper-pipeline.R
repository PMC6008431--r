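## Build a small but complete screen-shaped run on disk: 9 probes + control,
## 3 wells each, 16 antibodies, plus an inhibition matrix over 5 kinases.
make_run_inputs <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n_ab <- 16L
  probes <- sprintf("probe%02d", 1:9)
  treatments <- rep(c("control", probes), each = 3)
  n_wells <- length(treatments)
  plate <- plate_map(sprintf("w%02d", seq_len(n_wells)),
                     unname(simulate_barcodes(n_wells, 10, 3,
                                              seed = seed + 1L)),
                     covariates = data.frame(
                       treatment = treatments,
                       replicate = rep(paste0("r", 1:3), times = 10)))
  panel <- simulate_panel(n_ab, seed = seed + 2L)
  lay <- read_layout()
  set.seed(seed + 3L)
  truth <- matrix(rpois(n_ab * n_wells, 25L), n_ab, n_wells)
  sim <- simulate_fastq(panel, plate, lay, truth, 0.05, 0.002,
                        seed = seed + 4L,
                        path = file.path(dir, "reads.fastq.gz"))
  ## counts for the differential stage come from the reads; the inhibition
  ## matrix marks probes 1-2 as strong inhibitors of kinases K1/K2
  set.seed(seed + 5L)
  inh <- matrix(round(runif(9 * 5, 0, 25), 1), 9, 5,
                dimnames = list(probes, paste0("K", 1:5)))
  inh[1:3, "K1"] <- c(88, 92, 85)
  inh[c(1, 2, 4), "K2"] <- c(90, 86, 91)
  write.csv(data.frame(probe = rownames(inh), inh, check.names = FALSE),
            file.path(dir, "inhibition.csv"), row.names = FALSE, quote = FALSE)
  write.table(data.frame(antibody_id = panel$ids,
                         barcode = unname(panel$barcodes)),
              file.path(dir, "panel.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cbind(data.frame(well_id = plate$ids,
                               barcode = unname(plate$barcodes)),
                    plate$covariates),
              file.path(dir, "plate.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- list(fastq = "reads.fastq.gz", panel = "panel.tsv",
              plate = "plate.tsv", inhibition = "inhibition.csv",
              model = list(treatment = "treatment", blocks = "replicate",
                           reference = "control"),
              screen = list(k = 4L, pc = 1L, fraction = 0.34, alpha = 0.05,
                            fdr = 0.25, n_perm = 200L, min_set_size = 3L,
                            seed = 11L),
              outdir = file.path(dir, "out"))
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  file.path(dir, "config.yaml")
}

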