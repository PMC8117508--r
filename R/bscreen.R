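#' Re-window paired depth tracks onto a common grid
#'
#' Computes the per-window mean depth of the B- and B+ genomic libraries
#' on a fixed grid. Input tracks may be per-base or already windowed
#' (any segmentation); means are overlap-weighted. Terminal partial
#' windows are retained with their true length.
#'
#' @param track_bminus,track_bplus Data frames with `contig`, `start`,
#'   `end` (0-based half-open) and `depth` columns.
#' @param window Window width in bases.
#' @return Data frame with `contig`, `start`, `end`, `depth_bminus`,
#'   `depth_bplus`.
#' @export
window_coverage <- function(track_bminus, track_bplus, window = 1000L) {
  for (tr in list(track_bminus, track_bplus)) {
    stopifnot(all(c("contig", "start", "end", "depth") %in% names(tr)))
  }
  only_a <- setdiff(unique(track_bminus$contig), unique(track_bplus$contig))
  only_b <- setdiff(unique(track_bplus$contig), unique(track_bminus$contig))
  if (length(only_a) || length(only_b)) {
    stop("contigs present in one track only: ",
         paste(c(only_a, only_b), collapse = ", "), call. = FALSE)
  }

  rewindow <- function(tr, ctg, len) {
    tr <- tr[tr$contig == ctg, , drop = FALSE]
    starts <- seq.int(0L, len - 1L, by = window)
    ends <- pmin(starts + window, len)
    num <- den <- numeric(length(starts))
    for (i in seq_len(nrow(tr))) {
      w1 <- tr$start[i] %/% window + 1L
      w2 <- (tr$end[i] - 1L) %/% window + 1L
      for (w in w1:w2) {
        ov <- min(tr$end[i], ends[w]) - max(tr$start[i], starts[w])
        num[w] <- num[w] + tr$depth[i] * ov
        den[w] <- den[w] + ov
      }
    }
    data.frame(contig = ctg, start = starts, end = ends,
               depth = ifelse(den > 0, num / den, NA_real_),
               stringsAsFactors = FALSE)
  }

  out <- lapply(sort(unique(track_bminus$contig)), function(ctg) {
    len <- max(track_bminus$end[track_bminus$contig == ctg],
               track_bplus$end[track_bplus$contig == ctg])
    a <- rewindow(track_bminus, ctg, len)
    b <- rewindow(track_bplus, ctg, len)
    data.frame(contig = a$contig, start = a$start, end = a$end,
               depth_bminus = a$depth, depth_bplus = b$depth,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Library-normalized B+/B- coverage ratio per window
#'
#' Each library is scaled by its genome-wide median window depth (median
#' rather than mean so that the planted/duplicated blocks themselves do
#' not distort the normalizer), then the per-window ratio is
#' `(bplus/median_bplus) / (bminus/median_bminus)`. Windows with zero
#' B- depth get an undefined (`NA`) ratio and are flagged `excluded`.
#'
#' @param windows Output of [window_coverage()].
#' @return `windows` with `norm_ratio` and `excluded` columns added.
#' @export
normalize_and_ratio <- function(windows) {
  med_m <- median(windows$depth_bminus, na.rm = TRUE)
  med_p <- median(windows$depth_bplus, na.rm = TRUE)
  if (!isTRUE(med_m > 0) || !isTRUE(med_p > 0)) {
    stop("zero median depth in a library; cannot normalize", call. = FALSE)
  }
  windows$norm_ratio <- (windows$depth_bplus / med_p) /
    (windows$depth_bminus / med_m)
  windows$excluded <- !is.finite(windows$norm_ratio)
  windows$norm_ratio[windows$excluded] <- NA_real_
  windows
}

#' Call duplicated blocks (B-blocks) from normalized coverage ratios
#'
#' A block is a run of at least `min_windows` windows with
#' `norm_ratio >= ratio_min`, allowing interruptions of up to
#' `merge_gap` consecutive below-threshold (or excluded) windows.
#' `mean_ratio` and `n_windows` are computed over the above-threshold
#' member windows, so `mean_ratio >= ratio_min` always holds. Output
#' intervals are disjoint and sorted.
#'
#' @param windows Output of [normalize_and_ratio()].
#' @param ratio_min Ratio threshold (the expectation for a single-copy
#'   duplication is 2; the default 1.5 admits sampling noise around it).
#' @param min_windows Minimum above-threshold windows per block.
#' @param merge_gap Maximum run of below-threshold windows bridged
#'   inside one block.
#' @return Data frame with `contig`, `start`, `end`, `mean_ratio`,
#'   `n_windows`.
#' @export
call_bblocks <- function(windows, ratio_min = 1.5, min_windows = 3L,
                         merge_gap = 1L) {
  stopifnot("norm_ratio" %in% names(windows))
  out <- list()
  for (ctg in unique(windows$contig)) {
    win <- windows[windows$contig == ctg, , drop = FALSE]
    win <- win[order(win$start), , drop = FALSE]
    above <- which(!is.na(win$norm_ratio) & win$norm_ratio >= ratio_min)
    if (!length(above)) next
    grp <- cumsum(c(1L, diff(above) > merge_gap + 1L))
    for (g in unique(grp)) {
      members <- above[grp == g]
      if (length(members) < min_windows) next
      out[[length(out) + 1L]] <- data.frame(
        contig = ctg, start = win$start[members[1L]],
        end = win$end[members[length(members)]],
        mean_ratio = mean(win$norm_ratio[members]),
        n_windows = length(members), stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), mean_ratio = numeric(),
                      n_windows = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$contig, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Precursors overlapping called B-blocks
#'
#' Reports every precursor whose interval overlaps a block by at least
#' one base, with the overlap fraction of the precursor. An empty
#' result is a valid outcome (no miRNA locus with B-chromosome-level
#' coverage).
#'
#' @param blocks Data frame from [call_bblocks()] (or any
#'   contig/start/end table).
#' @param precursors Data frame with `id`, `contig`, `start`, `end`.
#' @return Data frame with precursor id/coordinates, the overlapping
#'   block coordinates, `overlap` (bases) and `overlap_fraction`.
#' @export
intersect_annotations <- function(blocks, precursors) {
  out <- list()
  for (i in seq_len(nrow(precursors))) {
    p <- precursors[i, ]
    hit <- blocks[blocks$contig == p$contig & blocks$start < p$end &
                    blocks$end > p$start, , drop = FALSE]
    for (j in seq_len(nrow(hit))) {
      ov <- min(p$end, hit$end[j]) - max(p$start, hit$start[j])
      out[[length(out) + 1L]] <- data.frame(
        id = p$id, contig = p$contig, start = p$start, end = p$end,
        block_start = hit$start[j], block_end = hit$end[j],
        overlap = ov, overlap_fraction = ov / (p$end - p$start),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(id = character(), contig = character(),
                      start = numeric(), end = numeric(),
                      block_start = numeric(), block_end = numeric(),
                      overlap = numeric(), overlap_fraction = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Rescue reads that align only to the B+ genome assembly
#'
#' Reads with no alignment to the primary (A-genome) reference at up to
#' `max_mismatches` are searched against the B+ assembly; their
#' alignment positions are chained into candidate regions (gap up to
#' `merge_gap` bases), and each region is labelled B+-exclusive when its
#' supporting reads come only from B+ samples. Matching is exact /
#' few-mismatch substring search on the forward strand, appropriate for
#' 17-27 nt reads.
#'
#' @param reads Data frame with `read_id`, `sequence` and `b_status`
#'   (`"Bminus"`/`"Bplus"`) columns.
#' @param reference_a,reference_bplus Named character vectors of contig
#'   sequences.
#' @param max_mismatches Mismatch tolerance of the substring search.
#' @param merge_gap Maximum gap between read alignments chained into
#'   one candidate region.
#' @return Data frame with one row per candidate region: `contig`,
#'   `start`, `end` (0-based half-open), `n_reads`, `n_bplus`,
#'   `n_bminus`, `bplus_exclusive`.
#' @export
rescue_unaligned <- function(reads, reference_a, reference_bplus,
                             max_mismatches = 1L, merge_gap = 50L) {
  empty <- data.frame(contig = character(), start = integer(),
                      end = integer(), n_reads = integer(),
                      n_bplus = integer(), n_bminus = integer(),
                      bplus_exclusive = logical(), stringsAsFactors = FALSE)
  if (!nrow(reads)) return(empty)
  subj_a <- Biostrings::DNAStringSet(dna_norm(reference_a))
  subj_b <- Biostrings::DNAStringSet(dna_norm(reference_bplus))

  match_any <- function(seq, subject) {
    m <- Biostrings::vmatchPattern(seq, subject,
                                   max.mismatch = max_mismatches)
    lens <- S4Vectors::elementNROWS(m)
    which(lens > 0L)
  }
  hits <- list()
  for (i in seq_len(nrow(reads))) {
    seq <- dna_norm(reads$sequence[i])
    if (length(match_any(seq, subj_a))) next   # aligns to A genome
    m <- Biostrings::vmatchPattern(seq, subj_b,
                                   max.mismatch = max_mismatches)
    for (ci in which(S4Vectors::elementNROWS(m) > 0L)) {
      r <- m[[ci]]
      hits[[length(hits) + 1L]] <- data.frame(
        contig = names(subj_b)[ci],
        start = BiocGenerics::start(r) - 1L,
        end = BiocGenerics::end(r),
        read_id = reads$read_id[i], b_status = reads$b_status[i],
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(hits)) return(empty)
  hits <- do.call(rbind, hits)

  out <- list()
  for (ctg in unique(hits$contig)) {
    h <- hits[hits$contig == ctg, , drop = FALSE]
    h <- h[order(h$start, h$end), , drop = FALSE]
    run_end <- -Inf
    grp <- integer(nrow(h))
    gid <- 0L
    for (i in seq_len(nrow(h))) {
      if (h$start[i] - run_end > merge_gap) gid <- gid + 1L
      grp[i] <- gid
      run_end <- max(run_end, h$end[i])
    }
    for (g in unique(grp)) {
      rows <- h[grp == g, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        contig = ctg, start = min(rows$start), end = max(rows$end),
        n_reads = length(unique(rows$read_id)),
        n_bplus = length(unique(rows$read_id[rows$b_status == "Bplus"])),
        n_bminus = length(unique(rows$read_id[rows$b_status == "Bminus"])),
        bplus_exclusive = all(rows$b_status == "Bplus"),
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$contig, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}
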