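#' Simulate a miRNA count matrix with a sample design
#'
#' Counts are negative binomial with dispersion `bcv^2` around a
#' per-miRNA baseline mean (log-uniform in 20-200). For each
#' tissue-by-sex contrast, a fraction `de_fraction` of mature miRNAs is
#' planted as differentially expressed: the B+ group mean is multiplied
#' by `planted_fc` (up) or divided by it (down). `bcv = 0` degenerates to
#' Poisson counts.
#'
#' @param truth Truth list from [gen_genome()]; its `matures` table
#'   defines the miRNA universe. Pass `NULL` to simulate `n_mirnas`
#'   free-standing miRNAs instead.
#' @param config A [sim_config()] object.
#' @param tissues,sexes Factors of the design grid.
#' @param n_mirnas Number of miRNAs when `truth` is `NULL`.
#' @return A list with `counts` (integer matrix, miRNAs x samples),
#'   `design` (sample_id, tissue, sex, b_status) and `de_truth`
#'   (mirna_id, tissue, sex, direction, fold_change).
#' @examples
#' gc <- gen_counts(NULL, sim_config(seed = 1), tissues = "gonad",
#'                  sexes = "F", n_mirnas = 50)
#' dim(gc$counts)
#' @export
gen_counts <- function(truth, config, tissues = c("brain", "gonad", "muscle"),
                       sexes = c("F", "M"), n_mirnas = 100L) {
  stopifnot(inherits(config, "sim_config"))
  with_sim_seed(config, 3L, {
    ids <- if (!is.null(truth) && nrow(truth$matures)) {
      truth$matures$mirna_id
    } else {
      sprintf("mir_%04d", seq_len(n_mirnas))
    }
    g <- length(ids)
    design <- expand.grid(
      replicate = seq_len(config$n_replicates),
      b_status = c("Bminus", "Bplus"), sex = sexes, tissue = tissues,
      stringsAsFactors = FALSE
    )
    design$sample_id <- sprintf("%s_%s_%s_%d", design$tissue, design$sex,
                                design$b_status, design$replicate)
    design <- design[, c("sample_id", "tissue", "sex", "b_status")]

    mu0 <- exp(runif(g, log(20), log(200)))
    n_de <- round(config$de_fraction * g)
    de_rows <- list()
    counts <- matrix(0L, nrow = g, ncol = nrow(design),
                     dimnames = list(ids, design$sample_id))
    for (ti in tissues) for (sx in sexes) {
      de_idx <- if (n_de > 0L) sample.int(g, n_de) else integer(0)
      dir <- sample(c("up", "down"), length(de_idx), replace = TRUE)
      fc_mult <- rep(1, g)
      fc_mult[de_idx] <- ifelse(dir == "up", config$planted_fc,
                                1 / config$planted_fc)
      if (length(de_idx)) {
        de_rows[[paste(ti, sx)]] <- data.frame(
          mirna_id = ids[de_idx], tissue = ti, sex = sx, direction = dir,
          fold_change = config$planted_fc, stringsAsFactors = FALSE
        )
      }
      for (bs in c("Bminus", "Bplus")) {
        cols <- which(design$tissue == ti & design$sex == sx &
                        design$b_status == bs)
        mu <- if (bs == "Bplus") mu0 * fc_mult else mu0
        for (cl in cols) {
          counts[, cl] <- if (config$bcv > 0) {
            rnbinom(g, mu = mu, size = 1 / config$bcv^2)
          } else {
            rpois(g, mu)
          }
        }
      }
    }
    de_truth <- if (length(de_rows)) {
      res <- do.call(rbind, de_rows)
      rownames(res) <- NULL
      res
    } else {
      data.frame(mirna_id = character(), tissue = character(),
                 sex = character(), direction = character(),
                 fold_change = numeric(), stringsAsFactors = FALSE)
    }
    list(counts = counts, design = design, de_truth = de_truth)
  })
}

# Internal scan used by the generator for bookkeeping of accidental
# (residual) sites; mirrors the site taxonomy of find_seed_sites but is
# only used to record truth.
#' @noRd
scan_sites_raw <- function(mature, utr_seq) {
  find_seed_sites(
    list(id = "tmp", sequence = mature),
    list(transcript_id = "tmp", sequence = utr_seq)
  )
}

#' Simulate 3'UTR sequences with planted miRNA seed sites
#'
#' Backgrounds are uniform over A/C/G/T with accidental seed cores for
#' the supplied miRNAs scrubbed out; each (miRNA, UTR) pair then receives
#' a planted canonical site (8mer, 7mer-m8 or 7mer-1A) with probability
#' `site_plant_rate`. Any residual site that survives scrubbing (e.g.
#' created at a planting boundary) is recorded in the returned truth.
#'
#' @param truth Truth list from [gen_genome()] (uses `matures`), or a
#'   data frame with `mirna_id` and `sequence` columns.
#' @param config A [sim_config()] object.
#' @param len_range Min/max UTR length in bases.
#' @param tissues Tissue labels sampled into `tissue_expression`.
#' @param scrub_background Remove accidental seed cores from the
#'   background before planting.
#' @return List with `utrs` (a data frame: transcript_id, sequence,
#'   gene_symbol, tissue_expression as comma-joined labels),
#'   `planted_sites` (mirna_id, transcript_id, site_type, position) and
#'   `residual_sites` in the same layout.
#' @export
gen_utrs <- function(truth, config, len_range = c(200L, 800L),
                     tissues = c("brain", "gonad", "muscle"),
                     scrub_background = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  matures <- if (is.data.frame(truth)) truth else truth$matures
  stopifnot(nrow(matures) > 0)
  with_sim_seed(config, 4L, {
    n <- config$n_utrs
    cores <- unique(revcomp(substr(dna_norm(matures$sequence), 2L, 7L)))
    utr_seq <- character(n)
    for (i in seq_len(n)) {
      len <- sample(len_range[1]:len_range[2], 1L)
      s <- rand_dna(len)
      if (scrub_background) {
        for (it in 1:20) {
          hit <- FALSE
          for (core in cores) {
            m <- gregexpr(core, s, fixed = TRUE)[[1]]
            if (m[1] != -1L) {
              hit <- TRUE
              for (p in m) {
                substr(s, p, p + nchar(core) - 1L) <- rand_dna(nchar(core))
              }
            }
          }
          if (!hit) break
        }
      }
      utr_seq[i] <- s
    }
    tissue_expr <- vapply(seq_len(n), function(i) {
      k <- sample(seq_along(tissues), 1L)
      paste(sort(sample(tissues, k)), collapse = ",")
    }, "")
    utrs <- data.frame(
      transcript_id = sprintf("tx_%04d", seq_len(n)),
      sequence = utr_seq,
      gene_symbol = sprintf("GENE%04d", seq_len(n)),
      tissue_expression = tissue_expr, stringsAsFactors = FALSE
    )

    planted <- list()
    occupied <- vector("list", n)
    for (mi in seq_len(nrow(matures))) {
      m <- dna_norm(matures$sequence[mi])
      seed7 <- substr(m, 2L, 8L)
      site_m8 <- revcomp(seed7)            # pairs miRNA positions 2-8
      core6 <- substr(site_m8, 2L, 7L)     # pairs positions 2-7
      comp8 <- substr(site_m8, 1L, 1L)
      for (ui in seq_len(n)) {
        if (runif(1) >= config$site_plant_rate) next
        type <- sample(c("8mer", "7mer-m8", "7mer-1A"), 1L)
        insert <- switch(type,
          "8mer" = paste0(site_m8, "A"),
          "7mer-m8" = paste0(site_m8,
                             sample(setdiff(DNA_BASES, "A"), 1L)),
          "7mer-1A" = paste0(sample(setdiff(DNA_BASES, comp8), 1L),
                             core6, "A")
        )
        len <- nchar(utrs$sequence[ui])
        w <- nchar(insert)
        if (len < w + 4L) next
        pos <- NA_integer_  # 0-based insert start
        for (try in 1:50) {
          cand <- sample.int(len - w - 1L, 1L)  # keep off both edges
          occ <- occupied[[ui]]
          if (is.null(occ) ||
              !any(occ$start < cand + w + 7L & occ$end > cand - 7L)) {
            pos <- cand
            break
          }
        }
        if (is.na(pos)) next
        substr(utrs$sequence[ui], pos + 1L, pos + w) <- insert
        occupied[[ui]] <- rbind(occupied[[ui]],
                                data.frame(start = pos, end = pos + w))
        site_pos <- if (type == "7mer-1A") pos + 1L else pos
        planted[[length(planted) + 1L]] <- data.frame(
          mirna_id = matures$mirna_id[mi],
          transcript_id = utrs$transcript_id[ui],
          site_type = type, position = site_pos, stringsAsFactors = FALSE
        )
      }
    }
    planted <- if (length(planted)) {
      do.call(rbind, planted)
    } else {
      data.frame(mirna_id = character(), transcript_id = character(),
                 site_type = character(), position = integer(),
                 stringsAsFactors = FALSE)
    }

    # Bookkeeping: record every detectable site that was not planted.
    residual <- list()
    for (mi in seq_len(nrow(matures))) {
      for (ui in seq_len(n)) {
        hits <- scan_sites_raw(matures$sequence[mi], utrs$sequence[ui])
        if (!nrow(hits)) next
        pl <- planted[planted$mirna_id == matures$mirna_id[mi] &
                        planted$transcript_id == utrs$transcript_id[ui], ]
        extra <- hits[!(hits$utr_position %in% pl$position), , drop = FALSE]
        if (nrow(extra)) {
          residual[[length(residual) + 1L]] <- data.frame(
            mirna_id = matures$mirna_id[mi],
            transcript_id = utrs$transcript_id[ui],
            site_type = extra$site_type, position = extra$utr_position,
            stringsAsFactors = FALSE
          )
        }
      }
    }
    residual <- if (length(residual)) {
      do.call(rbind, residual)
    } else {
      planted[0, ]
    }
    list(utrs = utrs, planted_sites = planted, residual_sites = residual)
  })
}

#' Simulate interaction, integrity, GO annotation and Cq tables
#'
#' Produces a BioGRID-like interaction table seeded with known defects
#' (swapped-order duplicates, self-loops, non-target-taxon rows, rows with
#' disallowed MI detection codes), per-group target sets with a known
#' shared core, a B-gene integrity table, a gene-to-GO-term annotation,
#' and a qPCR Cq table encoding known gene dose ratios through planted
#' per-sample delta-Cq offsets.
#'
#' @param truth Unused placeholder for pipeline symmetry (the gene
#'   universe is generated here); may be `NULL`.
#' @param config A [sim_config()] object.
#' @param n_genes Size of the gene universe.
#' @param n_interactions Clean interaction rows before defects are added.
#' @param dose_ratios Named numeric vector of planted gene dose ratios
#'   (target genes of the Cq table).
#' @param cq_sd Per-sample Cq measurement noise, in cycles.
#' @param n_cq_samples Samples per B-status group in the Cq table.
#' @param taxid Target taxon for clean rows.
#' @return List with `interactions`, `row_truth` (per-row defect flags),
#'   `per_group_targets`, `shared_targets`, `integrity`, `go_annotation`,
#'   `cq` and `dose_ratios`.
#' @export
gen_interactions <- function(truth, config, n_genes = 60L,
                             n_interactions = 120L,
                             dose_ratios = c(targetA = 2, targetB = 1),
                             cq_sd = 0.2, n_cq_samples = 4L,
                             taxid = 9606L) {
  stopifnot(inherits(config, "sim_config"))
  with_sim_seed(config, 5L, {
    genes <- sprintf("GENE%04d", seq_len(n_genes))
    allowed_mi <- c("MI:0004", "MI:0114", "MI:0047", "MI:0055", "MI:0090",
                    "MI:0045", "MI:0018")
    pick_pair <- function() sort(sample(genes, 2L))
    base <- t(replicate(n_interactions, pick_pair()))
    base <- base[!duplicated(paste(base[, 1], base[, 2])), , drop = FALSE]
    clean <- data.frame(
      symbol_a = base[, 1], symbol_b = base[, 2],
      taxid_a = taxid, taxid_b = taxid,
      mi_code = sample(allowed_mi, nrow(base), replace = TRUE),
      defect = "none", stringsAsFactors = FALSE
    )
    n_dup <- max(1L, nrow(clean) %/% 10L)
    dup_idx <- sample.int(nrow(clean), n_dup)
    dups <- clean[dup_idx, ]
    dups[, c("symbol_a", "symbol_b")] <- dups[, c("symbol_b", "symbol_a")]
    dups$defect <- "duplicate"
    selfs <- data.frame(
      symbol_a = sample(genes, 3L), symbol_b = NA,
      taxid_a = taxid, taxid_b = taxid,
      mi_code = sample(allowed_mi, 3L, replace = TRUE),
      defect = "self_loop", stringsAsFactors = FALSE
    )
    selfs$symbol_b <- selfs$symbol_a
    other_taxon <- data.frame(
      symbol_a = sample(genes, 4L), symbol_b = sample(genes, 4L),
      taxid_a = c(taxid, 10090L, 10090L, taxid),
      taxid_b = c(10090L, taxid, 10090L, 10090L),
      mi_code = sample(allowed_mi, 4L, replace = TRUE),
      defect = "taxon", stringsAsFactors = FALSE
    )
    bad_mi <- data.frame(
      symbol_a = sample(genes, 4L), symbol_b = sample(genes, 4L),
      taxid_a = taxid, taxid_b = taxid,
      mi_code = sample(c("MI:0686", "MI:0364"), 4L, replace = TRUE),
      defect = "mi_code", stringsAsFactors = FALSE
    )
    tab <- rbind(clean, dups, selfs, other_taxon, bad_mi)
    tab <- tab[sample.int(nrow(tab)), ]
    rownames(tab) <- NULL
    interactions <- tab[, c("symbol_a", "symbol_b", "taxid_a", "taxid_b",
                            "mi_code")]

    # Per-group target sets with a known shared core.
    shared <- sort(sample(genes, max(3L, n_genes %/% 6L)))
    rest <- setdiff(genes, shared)
    groups <- c("brain", "gonad", "muscle")
    per_group <- lapply(groups, function(gp) shared)
    names(per_group) <- groups
    for (g in rest) {
      # each non-core gene joins at most 2 groups, never all 3
      k <- sample(0:2, 1L)
      if (k > 0L) {
        for (gp in sample(groups, k)) {
          per_group[[gp]] <- c(per_group[[gp]], g)
        }
      }
    }
    per_group <- lapply(per_group, sort)

    n_bgenes <- min(20L, n_genes)
    integrity <- data.frame(
      gene_name = tolower(sprintf("%s-like", sample(genes, n_bgenes))),
      protein_symbol = sample(genes, n_bgenes),
      integrity = round(runif(n_bgenes, 30, 100), 2),
      stringsAsFactors = FALSE
    )

    terms <- sprintf("GO:%07d", seq_len(12L))
    go_annotation <- do.call(rbind, lapply(genes, function(g) {
      data.frame(gene = g, term = sample(terms, sample(1:3, 1L)),
                 stringsAsFactors = FALSE)
    }))

    samples <- c(sprintf("Bminus_%d", seq_len(n_cq_samples)),
                 sprintf("Bplus_%d", seq_len(n_cq_samples)))
    group <- rep(c("Bminus", "Bplus"), each = n_cq_samples)
    cq_rows <- list()
    for (s in seq_along(samples)) {
      ref_cq <- 20 + runif(1, -1, 1)   # per-sample offset, removed by dCq
      cq_rows[[length(cq_rows) + 1L]] <- data.frame(
        sample = samples[s], gene = "UBCE",
        cq = ref_cq + stats::rnorm(1, 0, cq_sd), group = group[s],
        stringsAsFactors = FALSE
      )
      for (g in names(dose_ratios)) {
        base_dcq <- 2  # target amplifies 2 cycles after the reference in B-
        dcq <- base_dcq -
          if (group[s] == "Bplus") log2(dose_ratios[[g]]) else 0
        cq_rows[[length(cq_rows) + 1L]] <- data.frame(
          sample = samples[s], gene = g,
          cq = ref_cq + dcq + stats::rnorm(1, 0, cq_sd), group = group[s],
          stringsAsFactors = FALSE
        )
      }
    }
    cq <- do.call(rbind, cq_rows)
    rownames(cq) <- NULL

    list(interactions = interactions, row_truth = tab$defect,
         per_group_targets = per_group, shared_targets = shared,
         integrity = integrity, go_annotation = go_annotation,
         cq = cq, dose_ratios = dose_ratios)
  })
}
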