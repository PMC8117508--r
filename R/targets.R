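# Longest-ORF search: ATG..stop on both strands, three frames each,
# requiring at least min_codons codons (stop excluded from the count).
#' @noRd
longest_orf <- function(seq, min_codons = 100L) {
  seq <- dna_norm(seq)
  stops <- c("TAA", "TAG", "TGA")
  best <- NULL
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    n <- nchar(s)
    codons_at <- function(from) {
      substring(s, seq.int(from, n - 2L, by = 3L),
                seq.int(from + 2L, n, by = 3L))
    }
    for (frame in 0:2) {
      if (n - frame < 3L) next
      cod <- codons_at(frame + 1L)
      is_start <- cod == "ATG"
      is_stop <- cod %in% stops
      open <- NA_integer_
      for (i in seq_along(cod)) {
        if (is.na(open) && is_start[i]) open <- i
        if (!is.na(open) && is_stop[i]) {
          len_codons <- i - open  # coding codons before the stop
          if (len_codons >= min_codons &&
              (is.null(best) || len_codons > best$len_codons)) {
            start0 <- frame + (open - 1L) * 3L
            end0 <- frame + i * 3L      # includes the stop codon
            best <- list(strand = strand, start = start0, end = end0,
                         len_codons = len_codons)
          }
          open <- NA_integer_
        }
      }
    }
  }
  best
}

#' Extract 3'UTRs from transcript sequences
#'
#' The 3'UTR is the subsequence strictly downstream of the stop codon to
#' the transcript end, on the coding strand. ORF coordinates may be
#' supplied (0-based half-open, stop codon included, forward strand
#' unless `strand` says otherwise); without an annotation the longest
#' ORF (ATG to stop, at least `min_codons` codons, both strands
#' searched) is located first. Transcripts with no downstream sequence
#' are skipped; malformed annotation rows are skipped with a warning.
#'
#' @param transcripts Named character vector of transcript sequences.
#' @param orf_annotations Optional data frame with `transcript_id`,
#'   `orf_start`, `orf_end` and optionally `strand` columns.
#' @param min_codons Minimum ORF length for de novo ORF search.
#' @param tissue_expression Optional named character vector
#'   (transcript_id -> comma-joined tissue labels) carried through.
#' @param gene_symbols Optional named character vector
#'   (transcript_id -> protein symbol) carried through.
#' @return Data frame with `transcript_id`, `sequence` (the 3'UTR),
#'   `utr_start` (0-based offset on the coding strand), `gene_symbol`,
#'   `tissue_expression`.
#' @export
extract_utrs <- function(transcripts, orf_annotations = NULL,
                         min_codons = 100L, tissue_expression = NULL,
                         gene_symbols = NULL) {
  stopifnot(is.character(transcripts), !is.null(names(transcripts)))
  out <- list()
  for (tx in names(transcripts)) {
    seq <- dna_norm(transcripts[[tx]])
    n <- nchar(seq)
    orf <- NULL
    if (!is.null(orf_annotations) &&
        tx %in% orf_annotations$transcript_id) {
      row <- orf_annotations[orf_annotations$transcript_id == tx, ][1L, ]
      strand <- if ("strand" %in% names(row)) row$strand else "+"
      if (is.na(row$orf_start) || is.na(row$orf_end) ||
          row$orf_start < 0 || row$orf_end > n ||
          row$orf_start >= row$orf_end) {
        warning("malformed ORF coordinates for ", tx, "; skipped")
        next
      }
      orf <- list(strand = strand, start = row$orf_start,
                  end = row$orf_end)
    } else {
      orf <- longest_orf(seq, min_codons)
      if (is.null(orf)) next
    }
    coding <- if (orf$strand == "-") revcomp(seq) else seq
    if (orf$end >= n) next  # ORF runs to the transcript end: no 3'UTR
    utr <- substr(coding, orf$end + 1L, n)
    out[[length(out) + 1L]] <- data.frame(
      transcript_id = tx, sequence = utr, utr_start = orf$end,
      gene_symbol = if (!is.null(gene_symbols) && tx %in% names(gene_symbols))
        gene_symbols[[tx]] else NA_character_,
      tissue_expression = if (!is.null(tissue_expression) &&
                              tx %in% names(tissue_expression))
        tissue_expression[[tx]] else NA_character_,
      stringsAsFactors = FALSE
    )
  }
  if (!length(out)) {
    return(data.frame(transcript_id = character(), sequence = character(),
                      utr_start = integer(), gene_symbol = character(),
                      tissue_expression = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Find canonical seed sites of a miRNA in a 3'UTR
#'
#' Scans for matches of the 6-nt seed core (reverse complement of miRNA
#' positions 2-7). Each core match at UTR position `q` (0-based) is
#' classified by two flanking features: position-8 pairing (the UTR base
#' at `q - 1` complements miRNA position 8) and the 1A anchor (the UTR
#' base at `q + 6`, opposite miRNA position 1, is A):
#' both give an `8mer`, pairing only a `7mer-m8`, the anchor only a
#' `7mer-1A`; a bare core is not reported. Candidate sites closer than
#' 7 nt are mutually exclusive; the stronger type wins
#' (8mer > 7mer-m8 > 7mer-1A), then the 5'-most. Reported positions are
#' the 0-based start of the seed-paired region (`q - 1` for m8-paired
#' types, `q` otherwise).
#'
#' @param mirna List or one-row data frame with `id` (or `mirna_id`) and
#'   `sequence` (>= 8 nt).
#' @param utr List or one-row data frame with `transcript_id` and
#'   `sequence`.
#' @return Data frame with `mirna_id`, `transcript_id`, `site_type`,
#'   `utr_position`, sorted by position.
#' @export
find_seed_sites <- function(mirna, utr) {
  m <- dna_norm(mirna$sequence)
  stopifnot(nchar(m) >= 8L)
  mid <- if (!is.null(mirna$id)) mirna$id else mirna$mirna_id
  useq <- dna_norm(utr$sequence)
  n <- nchar(useq)
  core6 <- revcomp(substr(m, 2L, 7L))
  comp8 <- revcomp(substr(m, 8L, 8L))
  empty <- data.frame(mirna_id = character(), transcript_id = character(),
                      site_type = character(), utr_position = integer(),
                      stringsAsFactors = FALSE)
  if (n < 7L) return(empty)
  hits <- gregexpr(core6, useq, fixed = TRUE)[[1]]
  if (hits[1] == -1L) return(empty)
  cand <- list()
  for (h in hits) {
    q <- h - 1L  # 0-based core start
    m8 <- q >= 1L && substr(useq, q, q) == comp8
    a1 <- q + 7L <= n && substr(useq, q + 7L, q + 7L) == "A"
    type <- if (m8 && a1) "8mer" else if (m8) "7mer-m8" else
      if (a1) "7mer-1A" else NA_character_
    if (is.na(type)) next
    cand[[length(cand) + 1L]] <- data.frame(
      site_type = type, utr_position = if (m8) q - 1L else q,
      stringsAsFactors = FALSE
    )
  }
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  rank <- c("8mer" = 1L, "7mer-m8" = 2L, "7mer-1A" = 3L)
  cand <- cand[order(rank[cand$site_type], cand$utr_position), ,
               drop = FALSE]
  kept <- cand[0, ]
  for (i in seq_len(nrow(cand))) {
    if (!nrow(kept) ||
        all(abs(kept$utr_position - cand$utr_position[i]) >= 7L)) {
      kept <- rbind(kept, cand[i, ])
    }
  }
  kept <- kept[order(kept$utr_position), , drop = FALSE]
  data.frame(mirna_id = mid, transcript_id = utr$transcript_id,
             site_type = kept$site_type,
             utr_position = kept$utr_position,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Default per-site context-score contributions
#'
#' Implementation constants patterned on published mean context
#' contributions of the canonical site types; negative is favorable.
#' @return Named numeric vector.
#' @export
default_site_scores <- function() {
  c("8mer" = -0.31, "7mer-m8" = -0.16, "7mer-1A" = -0.10)
}

#' Score a miRNA:3'UTR interaction from its seed sites
#'
#' The total context score is the sum of per-site contributions; the
#' interaction is significant when the total is strictly below -0.2.
#'
#' @param sites Data frame from [find_seed_sites()].
#' @param site_scores Named contributions per site type.
#' @param cutoff Significance cutoff (strict `<`).
#' @return List with `mirna_id`, `transcript_id`, `sites`,
#'   `total_score`, `significant`.
#' @examples
#' s <- data.frame(mirna_id = "m", transcript_id = "t",
#'                 site_type = c("7mer-m8", "7mer-m8"),
#'                 utr_position = c(10L, 40L))
#' score_interaction(s)$total_score
#' @export
score_interaction <- function(sites, site_scores = default_site_scores(),
                              cutoff = -0.2) {
  unknown <- setdiff(unique(sites$site_type), names(site_scores))
  if (length(unknown)) {
    stop("unknown site type: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  total <- if (nrow(sites)) sum(site_scores[sites$site_type]) else 0
  list(mirna_id = if (nrow(sites)) sites$mirna_id[1L] else NA_character_,
       transcript_id = if (nrow(sites)) sites$transcript_id[1L]
       else NA_character_,
       sites = sites, total_score = total,
       significant = total < cutoff)
}

#' Predict all significant miRNA:3'UTR interactions in a tissue
#'
#' Runs the seed-site scan and context scoring over every (miRNA,
#' transcript) pair whose transcript is expressed in `tissue`, keeping
#' significant interactions only, in deterministic
#' (mirna_id, transcript_id) order.
#'
#' @param mirnas Data frame with `mirna_id` and `sequence` columns.
#' @param utrs Data frame with `transcript_id`, `sequence`,
#'   `gene_symbol` and `tissue_expression` (comma-joined labels).
#' @param tissue Tissue label; `NULL` disables the expression filter.
#' @param site_scores,cutoff Passed to [score_interaction()].
#' @return Data frame with `mirna_id`, `transcript_id`, `gene_symbol`,
#'   `n_sites`, `total_score`, `significant` (all `TRUE`).
#' @export
predict_all <- function(mirnas, utrs, tissue = NULL,
                        site_scores = default_site_scores(),
                        cutoff = -0.2) {
  if (!is.null(tissue)) {
    expressed <- vapply(strsplit(utrs$tissue_expression, ","),
                        function(z) tissue %in% z, logical(1))
    utrs <- utrs[expressed, , drop = FALSE]
  }
  out <- list()
  for (mi in seq_len(nrow(mirnas))) for (ui in seq_len(nrow(utrs))) {
    sites <- find_seed_sites(
      list(id = mirnas$mirna_id[mi], sequence = mirnas$sequence[mi]),
      utrs[ui, ]
    )
    if (!nrow(sites)) next
    sc <- score_interaction(sites, site_scores, cutoff)
    if (!sc$significant) next
    out[[length(out) + 1L]] <- data.frame(
      mirna_id = mirnas$mirna_id[mi],
      transcript_id = utrs$transcript_id[ui],
      gene_symbol = if ("gene_symbol" %in% names(utrs))
        utrs$gene_symbol[ui] else NA_character_,
      n_sites = nrow(sites), total_score = sc$total_score,
      significant = TRUE, stringsAsFactors = FALSE
    )
  }
  if (!length(out)) {
    return(data.frame(mirna_id = character(), transcript_id = character(),
                      gene_symbol = character(), n_sites = integer(),
                      total_score = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$mirna_id, res$transcript_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
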