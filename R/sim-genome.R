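#' Simulate a genome with planted miRNA hairpins and duplicated blocks
#'
#' Generates random contigs and plants two-arm inverted-repeat hairpin
#' precursors (arms 20-24 nt, perfectly reverse-complementary, loop 8-15
#' nt). A configurable fraction of precursors is placed in genomic
#' clusters whose inter-precursor gap is at most 5000 bases; all other
#' precursors sit more than 5000 bases from any neighbour. Duplicated
#' "B-blocks" (regions later given doubled B+ coverage) are placed on a
#' 1-kb grid without overlapping any precursor.
#'
#' @param config A [sim_config()] object.
#' @return A list with components:
#' \describe{
#'   \item{genome}{Named character vector of contig sequences.}
#'   \item{truth}{List with `precursors` (id, contig, 0-based half-open
#'     start/end, strand, cluster_id, dominant_arm), `matures` (mirna_id,
#'     precursor_id, arm, sequence, dominant), and `bblocks`
#'     (contig, start, end).}
#' }
#' @examples
#' sim <- gen_genome(sim_config(seed = 1, n_precursors = 6, n_bblocks = 1,
#'                              contig_len = 30000))
#' sim$truth$precursors
#' @export
gen_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_sim_seed(config, 0L, {
    contig_names <- sprintf("contig_%02d", seq_len(config$n_contigs))
    genome <- setNames(
      vapply(contig_names, function(x) rand_dna(config$contig_len), ""),
      contig_names
    )

    truth <- list(
      precursors = data.frame(
        id = character(), contig = character(), start = integer(),
        end = integer(), strand = character(), cluster_id = integer(),
        dominant_arm = character(), stringsAsFactors = FALSE
      ),
      matures = data.frame(
        mirna_id = character(), precursor_id = character(),
        arm = character(), sequence = character(), dominant = logical(),
        stringsAsFactors = FALSE
      ),
      bblocks = data.frame(
        contig = character(), start = integer(), end = integer(),
        stringsAsFactors = FALSE
      )
    )

    n_pre <- config$n_precursors
    if (n_pre > 0L) {
      # Partition precursors into placement units: clusters of 2-3 and
      # singletons. Units are separated by > 5000 bases; within-cluster
      # gaps are <= 5000 by construction.
      n_clustered <- round(config$cluster_fraction * n_pre)
      if (n_clustered == 1L) n_clustered <- 0L
      sizes <- integer(0)
      rem <- n_clustered
      while (rem >= 2L) {
        s <- if (rem == 3L) 3L else 2L
        sizes <- c(sizes, s)
        rem <- rem - s
      }
      if (rem == 1L && length(sizes)) {
        sizes[length(sizes)] <- sizes[length(sizes)] + 1L
      }
      units <- c(as.list(sizes), as.list(rep(1L, n_pre - sum(sizes))))

      cursors <- setNames(rep(500L, config$n_contigs), contig_names)
      margin <- 500L
      pre_rows <- vector("list", n_pre)
      mat_rows <- vector("list", n_pre)
      k <- 0L
      cluster_counter <- 0L
      for (u in seq_along(units)) {
        size <- units[[u]]
        cluster_counter <- cluster_counter + (size > 1L)
        cid <- if (size > 1L) cluster_counter else NA_integer_
        # worst-case span of this unit
        need <- 9000L + size * (63L + 3000L)
        ok <- names(which(cursors + need + margin <= config$contig_len))
        if (!length(ok)) {
          stop("sizing error: contigs too short to host the requested ",
               "precursors/clusters; increase contig_len or n_contigs",
               call. = FALSE)
        }
        ctg <- ok[(u - 1L) %% length(ok) + 1L]
        cursors[ctg] <- cursors[ctg] + sample(5500:9000, 1L)
        for (j in seq_len(size)) {
          if (j > 1L) cursors[ctg] <- cursors[ctg] + sample(200:3000, 1L)
          arm_len <- sample(20:24, 1L)
          loop_len <- sample(8:15, 1L)
          arm1 <- rand_dna(arm_len)
          hairpin <- paste0(arm1, rand_dna(loop_len), revcomp(arm1))
          start0 <- cursors[[ctg]]
          end0 <- start0 + nchar(hairpin)
          substr(genome[[ctg]], start0 + 1L, end0) <- hairpin
          cursors[ctg] <- end0
          k <- k + 1L
          id <- sprintf("pre_%04d", k)
          strand <- sample(c("+", "-"), 1L)
          dom <- sample(c("5p", "3p"), 1L, prob = c(0.55, 0.45))
          pre_rows[[k]] <- data.frame(
            id = id, contig = ctg, start = start0, end = end0,
            strand = strand, cluster_id = cid, dominant_arm = dom,
            stringsAsFactors = FALSE
          )
          mat_rows[[k]] <- data.frame(
            mirna_id = paste0(id, c("-5p", "-3p")),
            precursor_id = id, arm = c("5p", "3p"),
            sequence = c(arm1, revcomp(arm1)),
            dominant = c("5p", "3p") == dom,
            stringsAsFactors = FALSE
          )
        }
      }
      truth$precursors <- do.call(rbind, pre_rows)
      truth$matures <- do.call(rbind, mat_rows)
    }

    if (config$n_bblocks > 0L) {
      grid <- 1000L
      if (config$bblock_len %% grid != 0L || config$bblock_len <= 0L) {
        stop("sizing error: bblock_len must be a positive multiple of 1000",
             call. = FALSE)
      }
      blocks <- list()
      occupied <- truth$precursors[, c("contig", "start", "end")]
      for (b in seq_len(config$n_bblocks)) {
        placed <- FALSE
        for (try in seq_len(200L)) {
          ctg <- sample(contig_names, 1L)
          max_start <- config$contig_len - config$bblock_len
          if (max_start < 0L) break
          start0 <- sample.int(max_start %/% grid + 1L, 1L) * grid - grid
          end0 <- start0 + config$bblock_len
          clash <- function(df) {
            nrow(df) && any(df$contig == ctg & df$start < end0 &
                              df$end > start0)
          }
          if (!clash(occupied) &&
              !(length(blocks) && clash(do.call(rbind, blocks)))) {
            blocks[[b]] <- data.frame(contig = ctg, start = start0,
                                      end = end0, stringsAsFactors = FALSE)
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          stop("sizing error: could not place ", config$n_bblocks,
               " non-overlapping B-blocks; increase contig_len",
               call. = FALSE)
        }
      }
      truth$bblocks <- do.call(rbind, blocks)
      truth$bblocks <- truth$bblocks[order(truth$bblocks$contig,
                                           truth$bblocks$start), ,
                                     drop = FALSE]
      rownames(truth$bblocks) <- NULL
    }

    list(genome = genome, truth = truth)
  })
}

#' Simulate paired B-/B+ windowed depth tracks
#'
#' Per-window depth is Poisson with mean `base_depth` for the B- library
#' everywhere and for the B+ library outside planted blocks; inside a
#' planted block the B+ mean doubles (partial overlap scales the mean by
#' the overlapping fraction).
#'
#' @param genome Named character vector of contigs (from [gen_genome()]).
#' @param truth Truth list from [gen_genome()] (uses `bblocks`).
#' @param config A [sim_config()] object.
#' @param track_window Window width of the emitted track, in bases.
#' @return List with `bminus` and `bplus` data frames
#'   (contig, start, end, depth; 0-based half-open windows).
#' @export
gen_depth_tracks <- function(genome, truth, config, track_window = 1000L) {
  stopifnot(inherits(config, "sim_config"))
  with_sim_seed(config, 1L, {
    per_contig <- lapply(names(genome), function(ctg) {
      len <- nchar(genome[[ctg]])
      start <- seq.int(0L, len - 1L, by = track_window)
      end <- pmin(start + track_window, len)
      blocks <- truth$bblocks[truth$bblocks$contig == ctg, , drop = FALSE]
      frac <- numeric(length(start))
      if (nrow(blocks)) {
        for (i in seq_len(nrow(blocks))) {
          ov <- pmax(0L, pmin(end, blocks$end[i]) -
                       pmax(start, blocks$start[i]))
          frac <- frac + ov / (end - start)
        }
        frac <- pmin(frac, 1)
      }
      data.frame(contig = ctg, start = start, end = end, frac = frac,
                 stringsAsFactors = FALSE)
    })
    win <- do.call(rbind, per_contig)
    bminus <- bplus <- win[, c("contig", "start", "end")]
    bminus$depth <- rpois(nrow(win), config$base_depth)
    bplus$depth <- rpois(nrow(win), config$base_depth * (1 + win$frac))
    list(bminus = bminus, bplus = bplus)
  })
}

#' Simulate small-RNA reads from mature arms
#'
#' Reads are drawn from the mature arms of each planted precursor with
#' probability `arm_bias` for the truth dominant arm. A configurable
#' fraction of reads carries the literal 3' adapter suffix `TGGAA` plus a
#' short random tail; read lengths after trimming fall in 17-27 nt.
#'
#' @param truth Truth list from [gen_genome()].
#' @param config A [sim_config()] object.
#' @param reads_per_precursor Reads drawn per precursor.
#' @param adapter_fraction Proportion of reads given the adapter suffix.
#' @param adapter Adapter sequence appended before the random tail.
#' @return Data frame with read_id, precursor_id, arm, from_dominant,
#'   has_adapter and sequence columns.
#' @export
gen_srna_reads <- function(truth, config, reads_per_precursor = 200L,
                           adapter_fraction = 0.3, adapter = "TGGAA") {
  stopifnot(inherits(config, "sim_config"))
  with_sim_seed(config, 2L, {
    pre <- truth$precursors
    if (is.null(pre) || !nrow(pre)) {
      return(data.frame(read_id = character(), precursor_id = character(),
                        arm = character(), from_dominant = logical(),
                        has_adapter = logical(), sequence = character(),
                        stringsAsFactors = FALSE))
    }
    out <- vector("list", nrow(pre))
    for (i in seq_len(nrow(pre))) {
      dom <- pre$dominant_arm[i]
      arms <- ifelse(runif(reads_per_precursor) < config$arm_bias,
                     dom, setdiff(c("5p", "3p"), dom))
      mat <- truth$matures[truth$matures$precursor_id == pre$id[i], ]
      seqs <- setNames(mat$sequence, mat$arm)[arms]
      with_ad <- runif(reads_per_precursor) < adapter_fraction
      tails <- vapply(seq_len(reads_per_precursor), function(j) {
        if (with_ad[j]) paste0(adapter, rand_dna(sample(0:8, 1L))) else ""
      }, "")
      out[[i]] <- data.frame(
        read_id = sprintf("%s_r%04d", pre$id[i],
                          seq_len(reads_per_precursor)),
        precursor_id = pre$id[i], arm = arms, from_dominant = arms == dom,
        has_adapter = with_ad, sequence = paste0(seqs, tails),
        stringsAsFactors = FALSE
      )
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}
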