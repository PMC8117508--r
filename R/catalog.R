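#' Trim 3' adapters and filter small-RNA reads by length
#'
#' Each read is truncated at the first occurrence of the adapter (the
#' adapter and everything downstream are removed); reads whose trimmed
#' length falls outside `[min_len, max_len]` are dropped. The operation
#' is idempotent on its own output.
#'
#' @param reads Character vector of read sequences (A/C/G/T/U/N; U is
#'   mapped to T).
#' @param adapter Adapter sequence (default the TruSeq-style `TGGAA`).
#' @param min_len,max_len Retained length range, inclusive.
#' @return List with `reads` (retained sequences), `n_input`,
#'   `n_trimmed` (reads in which an adapter was found) and `n_dropped`.
#' @examples
#' trim_and_filter_reads(c("ACGTACGTACGTACGTACGTTGGAACCC", "ACGT"))
#' @export
trim_and_filter_reads <- function(reads, adapter = "TGGAA",
                                  min_len = 17L, max_len = 27L) {
  if (!is.character(adapter) || length(adapter) != 1L || !nzchar(adapter)) {
    stop("adapter must be a nonempty string", call. = FALSE)
  }
  reads <- dna_norm(reads)
  pos <- regexpr(adapter, reads, fixed = TRUE)
  trimmed <- ifelse(pos > 0L, substr(reads, 1L, pos - 1L), reads)
  len <- nchar(trimmed)
  keep <- len >= min_len & len <= max_len
  list(reads = trimmed[keep],
       n_input = length(reads),
       n_trimmed = sum(pos > 0L),
       n_dropped = sum(!keep))
}

#' Collapse a mature miRNA reference to a nonredundant set
#'
#' Exact duplicates and sequences that are full-length substrings of a
#' longer retained sequence are collapsed to a single representative:
#' the longest sequence, ties broken by the lexicographically smallest
#' id.
#'
#' @param matures Named character vector (id -> mature sequence).
#' @return List with `reference` (retained named sequences) and
#'   `mapping` (named character: removed id -> representative id).
#' @examples
#' collapse_reference(c(a = "ACGTACG", b = "ACGTACG", c = "CGTA"))
#' @export
collapse_reference <- function(matures) {
  stopifnot(is.character(matures), !is.null(names(matures)))
  seqs <- dna_norm(matures)
  ord <- order(-nchar(seqs), names(seqs))
  kept_ids <- character(0)
  mapping <- character(0)
  for (i in ord) {
    id <- names(seqs)[i]
    hosts <- kept_ids[vapply(kept_ids, function(k) {
      grepl(seqs[[i]], seqs[[k]], fixed = TRUE)
    }, logical(1))]
    if (length(hosts)) {
      # representative: longest host, then smallest id (kept order is
      # already longest-first / id-sorted, so the first host wins)
      mapping[id] <- hosts[1L]
    } else {
      kept_ids <- c(kept_ids, id)
    }
  }
  keep <- names(seqs) %in% kept_ids
  list(reference = matures[keep][order(names(matures[keep]))],
       mapping = mapping)
}

#' @noRd
pair_ok <- function(b1, b2, allow_wobble = TRUE) {
  wc <- (b1 == "A" & b2 == "T") | (b1 == "T" & b2 == "A") |
    (b1 == "C" & b2 == "G") | (b1 == "G" & b2 == "C")
  if (allow_wobble) {
    wc <- wc | (b1 == "G" & b2 == "T") | (b1 == "T" & b2 == "G")
  }
  wc
}

#' Test a sequence window for a miRNA-like hairpin
#'
#' Scores every partition of the window into (arm1, loop, arm2) with arm
#' length in `arm_len_range` and loop length in `loop_range` (arms equal
#' length, partition spanning the whole window). The score of a
#' partition is the fraction of arm positions that form Watson-Crick
#' pairs between arm1 and the reverse of arm2; G.U (G.T in DNA) wobbles
#' count as paired when `allow_wobble` is `TRUE`. A hairpin is called
#' when the best score reaches `min_arm_complementarity`.
#'
#' @param window Sequence window (character scalar).
#' @param arm_len_range,loop_range Integer length-2 vectors.
#' @param min_arm_complementarity Calling threshold in `[0, 1]`.
#' @param allow_wobble Count G.U pairs as paired.
#' @return List with `call` (logical), `complementarity`, `arm_len`,
#'   `loop_len`. Windows admitting no valid partition give a no-call
#'   with `NA` complementarity.
#' @examples
#' arm <- "ACGTACGTACGTACGTACGTAC"
#' hp <- paste0(arm, "TTTTTTTTTT",
#'              as.character(Biostrings::reverseComplement(
#'                Biostrings::DNAString(arm))))
#' detect_hairpin(hp)$complementarity
#' @export
detect_hairpin <- function(window, arm_len_range = c(20L, 24L),
                           loop_range = c(8L, 15L),
                           min_arm_complementarity = 0.6,
                           allow_wobble = TRUE) {
  window <- dna_norm(window)
  n <- nchar(window)
  no_call <- list(call = FALSE, complementarity = NA_real_,
                  arm_len = NA_integer_, loop_len = NA_integer_)
  if (n < 2L * arm_len_range[1] + loop_range[1]) return(no_call)
  chars <- strsplit(window, "")[[1]]
  best <- no_call
  for (a in seq.int(arm_len_range[1], arm_len_range[2])) {
    l <- n - 2L * a
    if (l < loop_range[1] || l > loop_range[2]) next
    arm1 <- chars[seq_len(a)]
    arm2_rev <- rev(chars[seq.int(a + l + 1L, n)])
    comp <- mean(pair_ok(arm1, arm2_rev, allow_wobble))
    if (is.na(best$complementarity) || comp > best$complementarity) {
      best <- list(call = comp >= min_arm_complementarity,
                   complementarity = comp, arm_len = a, loop_len = l)
    }
  }
  best
}

#' Classify a precursor as known or novel and assign its seed family
#'
#' A precursor is `known` when one of its mature arms matches a
#' reference mature sequence of the same length with at most
#' `max_mismatches` mismatches *and* an identical seed (nucleotides
#' 2-8). Novel precursors whose seed exactly matches a reference seed
#' inherit that reference id as `seed_family` (ties broken by fewest
#' full-sequence mismatches, then lexicographically smallest id).
#'
#' @param pre List or one-row data frame with `mature_5p` and/or
#'   `mature_3p` sequence fields (`NA`/`NULL` for an absent arm).
#' @param reference Named character vector of reference mature
#'   sequences.
#' @param max_mismatches Full-length mismatch tolerance for `known`.
#' @return List with `status` (`"known"` or `"novel"`) and
#'   `seed_family` (reference id or `NA`).
#' @export
classify_precursor <- function(pre, reference, max_mismatches = 2L) {
  arms <- c(pre$mature_5p, pre$mature_3p)
  arms <- dna_norm(arms[!is.na(arms) & nzchar(arms)])
  if (!length(arms)) stop("precursor has no mature arm", call. = FALSE)
  if (!length(reference)) {
    warning("empty reference: all precursors classified novel")
    return(list(status = "novel", seed_family = NA_character_))
  }
  ref <- dna_norm(reference)
  ref_seed <- seed_of(ref)

  candidates <- data.frame(id = character(), mm = numeric(),
                           known = logical(), stringsAsFactors = FALSE)
  for (arm in arms) {
    arm_seed <- seed_of(arm)
    mm <- vapply(ref, function(r) hamming(arm, r), numeric(1))
    seed_same <- ref_seed == arm_seed
    candidates <- rbind(candidates, data.frame(
      id = names(ref), mm = mm,
      known = seed_same & mm <= max_mismatches,
      seed_match = seed_same, stringsAsFactors = FALSE
    ))
  }
  pick <- function(df) {
    df <- df[order(df$mm, df$id), , drop = FALSE]
    df$id[1L]
  }
  if (any(candidates$known)) {
    return(list(status = "known",
                seed_family = pick(candidates[candidates$known, ])))
  }
  fam <- candidates[candidates$seed_match, , drop = FALSE]
  list(status = "novel",
       seed_family = if (nrow(fam)) pick(fam) else NA_character_)
}

#' Assign the dominant arm of a precursor from arm read counts
#'
#' The arm with the strictly greater summed read count dominates; a tie
#' (including the zero-evidence case of two zero counts) is resolved to
#' 5p and flagged.
#'
#' @param count_5p,count_3p Nonnegative read counts.
#' @return List with `arm` (`"5p"`/`"3p"`), `tie` and `zero_evidence`
#'   logical flags.
#' @examples
#' assign_dominant_arm(100, 10)
#' assign_dominant_arm(7, 7)
#' @export
assign_dominant_arm <- function(count_5p, count_3p) {
  stopifnot(count_5p >= 0, count_3p >= 0)
  list(arm = if (count_3p > count_5p) "3p" else "5p",
       tie = count_5p == count_3p,
       zero_evidence = count_5p == 0 && count_3p == 0)
}

#' Cluster precursors by genomic proximity
#'
#' Single-linkage chaining per contig: precursors are sorted by start,
#' and consecutive precursors whose gap (next start minus previous end)
#' is at most `max_gap` join one cluster. Overlapping precursors
#' (gap <= 0) join. Chains of size one are reported as singletons;
#' clusters have at least two members. Strand is ignored.
#'
#' @param precursors Data frame with `id`, `contig`, `start`, `end`
#'   columns (numeric coordinates, any consistent convention).
#' @param max_gap Maximum joining gap in bases (inclusive).
#' @return List of class `"mirna_clusters"` with `membership` (input
#'   rows plus `group_id` and `clustered`), `clusters` (one row per
#'   cluster of size >= 2: group_id, contig, n_members, start, end,
#'   members) and `singletons` (ids).
#' @export
cluster_mirnas <- function(precursors, max_gap = 5000) {
  stopifnot(all(c("id", "contig", "start", "end") %in% names(precursors)),
            all(precursors$start < precursors$end))
  df <- precursors[order(precursors$contig, precursors$start,
                         precursors$end), , drop = FALSE]
  df$group_id <- NA_integer_
  gid <- 0L
  for (ctg in unique(df$contig)) {
    idx <- which(df$contig == ctg)
    run_end <- -Inf
    for (i in idx) {
      if (df$start[i] - run_end > max_gap) gid <- gid + 1L
      df$group_id[i] <- gid
      run_end <- max(run_end, df$end[i])
    }
  }
  sizes <- table(df$group_id)
  df$clustered <- sizes[as.character(df$group_id)] >= 2L
  clusters <- do.call(rbind, lapply(
    names(sizes)[sizes >= 2L], function(g) {
      rows <- df[df$group_id == as.integer(g), ]
      data.frame(group_id = as.integer(g), contig = rows$contig[1L],
                 n_members = nrow(rows), start = min(rows$start),
                 end = max(rows$end),
                 members = paste(rows$id, collapse = ","),
                 stringsAsFactors = FALSE)
    }))
  if (is.null(clusters)) {
    clusters <- data.frame(group_id = integer(), contig = character(),
                           n_members = integer(), start = numeric(),
                           end = numeric(), members = character(),
                           stringsAsFactors = FALSE)
  }
  rownames(df) <- NULL
  structure(list(membership = df, clusters = clusters,
                 singletons = df$id[!df$clustered]),
            class = "mirna_clusters")
}

#' @export
print.mirna_clusters <- function(x, ...) {
  cat(sprintf("miRNA clustering: %d precursors, %d clusters (>= 2), %d singletons\n",
              nrow(x$membership), nrow(x$clusters), length(x$singletons)))
  if (nrow(x$clusters)) print(x$clusters, row.names = FALSE)
  invisible(x)
}

#' Summarize a miRNA catalog
#'
#' Counts and two-decimal percentages (half-even rounding) of known vs
#' novel precursors, clustered precursors, strand of transcription and
#' 5p arm dominance.
#'
#' @param catalog Data frame with one row per precursor and columns
#'   `status` (`"known"`/`"novel"`), `clustered` (logical), `strand`
#'   (`"+"`/`"-"`) and `dominant_arm` (`"5p"`/`"3p"`).
#' @return List of class `"catalog_summary"` with count (`n_*`) and
#'   percentage (`pct_*`) fields.
#' @export
summarize_catalog <- function(catalog) {
  needed <- c("status", "clustered", "strand", "dominant_arm")
  stopifnot(all(needed %in% names(catalog)))
  n <- nrow(catalog)
  if (n < 1L) stop("empty catalog", call. = FALSE)
  pct <- function(k) round(100 * k / n, 2)
  s <- list(
    n_total = n,
    n_known = sum(catalog$status == "known"),
    n_novel = sum(catalog$status == "novel"),
    n_clustered = sum(catalog$clustered),
    n_minus = sum(catalog$strand == "-"),
    n_plus = sum(catalog$strand == "+"),
    n_5p_dominant = sum(catalog$dominant_arm == "5p")
  )
  s$pct_known <- pct(s$n_known)
  s$pct_novel <- pct(s$n_novel)
  s$pct_clustered <- pct(s$n_clustered)
  s$pct_minus <- pct(s$n_minus)
  s$pct_plus <- pct(s$n_plus)
  s$pct_5p_dominant <- pct(s$n_5p_dominant)
  structure(s, class = "catalog_summary")
}

#' @export
print.catalog_summary <- function(x, ...) {
  cat(sprintf("miRNA catalog: %d precursors\n", x$n_total))
  cat(sprintf("  known:      %4d (%.2f%%)\n", x$n_known, x$pct_known))
  cat(sprintf("  novel:      %4d (%.2f%%)\n", x$n_novel, x$pct_novel))
  cat(sprintf("  clustered:  %4d (%.2f%%)\n", x$n_clustered,
              x$pct_clustered))
  cat(sprintf("  minus strand: %2d (%.2f%%), plus strand: %d (%.2f%%)\n",
              x$n_minus, x$pct_minus, x$n_plus, x$pct_plus))
  cat(sprintf("  5p dominant: %3d (%.2f%%)\n", x$n_5p_dominant,
              x$pct_5p_dominant))
  invisible(x)
}
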