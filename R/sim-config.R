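#' Configuration for the synthetic-data generators
#'
#' Bundles every knob of the simulation into one validated list. The
#' defaults encode the study conditions the pipeline is designed around:
#' biological coefficient of variation 0.4, planted fold change 1.5, a
#' doubling of B+ coverage over planted B-blocks at 60x baseline depth,
#' and small-RNA reads of 17-27 nt carrying the 3' adapter TGGAA.
#'
#' @param seed Single integer seed. Each generator draws from its own
#'   stream derived from this seed (a fixed per-generator offset), so
#'   outputs are reproducible and independent of call order.
#' @param n_contigs Number of genome contigs.
#' @param contig_len Length of each contig in bases.
#' @param n_precursors Number of hairpin precursors to plant.
#' @param cluster_fraction Proportion of precursors placed in genomic
#'   clusters (inter-precursor gap <= 5000 bases on one contig).
#' @param n_bblocks Number of duplicated blocks to plant (doubled B+
#'   coverage).
#' @param bblock_len Length of each planted block in bases (aligned to the
#'   depth-track window grid).
#' @param base_depth Mean sequencing depth (x) of each genomic library.
#' @param bcv Biological coefficient of variation of the count model;
#'   counts are NB with dispersion `bcv^2` (`bcv = 0` gives Poisson).
#' @param n_replicates Samples per group in each B+/B- contrast.
#' @param planted_fc Linear fold change planted on DE miRNAs (>= 1); up-
#'   and downregulated miRNAs get `mu * fc` and `mu / fc` respectively.
#' @param arm_bias Proportion of a precursor's reads drawn from its
#'   dominant arm.
#' @param n_utrs Number of 3'UTR sequences to simulate.
#' @param site_plant_rate Proportion of (miRNA, UTR) pairs receiving a
#'   planted seed site.
#' @param de_fraction Proportion of mature miRNAs that are differentially
#'   expressed in each contrast.
#'
#' @return A list of class `"sim_config"`.
#' @examples
#' cfg <- sim_config(seed = 1, n_precursors = 10)
#' cfg$bcv
#' @export
sim_config <- function(seed = 1L,
                       n_contigs = 3L,
                       contig_len = 150000L,
                       n_precursors = 20L,
                       cluster_fraction = 0.3,
                       n_bblocks = 5L,
                       bblock_len = 10000L,
                       base_depth = 60,
                       bcv = 0.4,
                       n_replicates = 3L,
                       planted_fc = 1.5,
                       arm_bias = 0.8,
                       n_utrs = 40L,
                       site_plant_rate = 0.15,
                       de_fraction = 0.2) {
  stopifnot_scalar_num(seed, "seed")
  for (nm in c("n_contigs", "contig_len", "n_precursors", "n_bblocks",
               "bblock_len", "n_replicates", "n_utrs")) {
    stopifnot_scalar_num(get(nm), nm, min = 0)
  }
  for (nm in c("cluster_fraction", "arm_bias", "site_plant_rate",
               "de_fraction")) {
    stopifnot_scalar_num(get(nm), nm, min = 0, max = 1)
  }
  stopifnot_scalar_num(base_depth, "base_depth", min = 0)
  stopifnot_scalar_num(bcv, "bcv", min = 0)
  stopifnot_scalar_num(planted_fc, "planted_fc", min = 1)
  cfg <- list(
    seed = as.integer(seed), n_contigs = as.integer(n_contigs),
    contig_len = as.integer(contig_len),
    n_precursors = as.integer(n_precursors),
    cluster_fraction = cluster_fraction, n_bblocks = as.integer(n_bblocks),
    bblock_len = as.integer(bblock_len), base_depth = base_depth,
    bcv = bcv, n_replicates = as.integer(n_replicates),
    planted_fc = planted_fc, arm_bias = arm_bias,
    n_utrs = as.integer(n_utrs), site_plant_rate = site_plant_rate,
    de_fraction = de_fraction
  )
  class(cfg) <- "sim_config"
  cfg
}

# One RNG stream per generator: seed + fixed offset, restored on exit so
# generators do not disturb the caller's RNG state.
#' @noRd
with_sim_seed <- function(config, offset, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(config$seed + offset)
  expr
}
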