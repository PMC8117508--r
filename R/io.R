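#' Read / write sequences as FASTA
#'
#' Thin wrappers around Biostrings for the package's character-vector
#' sequence convention.
#'
#' @param path File path.
#' @return `read_fasta()`: named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(dna_norm(seqs)), path)
  invisible(path)
}

#' Read / write a windowed depth track
#'
#' Tab-delimited `contig, start, end, depth` with 0-based half-open
#' windows.
#' @param path File path.
#' @return `read_depth_track()`: data frame.
#' @export
read_depth_track <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("contig", "start", "end", "depth") %in% names(df)))
  df
}

#' @rdname read_depth_track
#' @param track Data frame with contig/start/end/depth.
#' @export
write_depth_track <- function(track, path) {
  write.table(track, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write precursor annotations as GFF3
#'
#' Internal coordinates are 0-based half-open; GFF3 is emitted 1-based
#' inclusive. Attributes carry status, seed family and dominant arm
#' when present.
#'
#' @param precursors Data frame with `id`, `contig`, `start`, `end`,
#'   `strand` and optionally `status`, `seed_family`, `dominant_arm`.
#' @param path Output path.
#' @export
write_precursor_gff3 <- function(precursors, path) {
  attr_of <- function(i) {
    p <- precursors[i, ]
    parts <- sprintf("ID=%s", p$id)
    for (f in c("status", "seed_family", "dominant_arm")) {
      if (f %in% names(precursors) && !is.na(p[[f]])) {
        parts <- c(parts, sprintf("%s=%s", f, p[[f]]))
      }
    }
    paste(parts, collapse = ";")
  }
  lines <- c("##gff-version 3",
             vapply(seq_len(nrow(precursors)), function(i) {
               p <- precursors[i, ]
               paste(p$contig, "bmirnet", "pre_miRNA", p$start + 1L,
                     p$end, ".", p$strand, ".", attr_of(i), sep = "\t")
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

#' Read precursor annotations from GFF3 written by
#' [write_precursor_gff3()]
#' @param path File path.
#' @return Data frame with 0-based half-open coordinates.
#' @export
read_precursor_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  get_attr <- function(attrs, key) {
    m <- regmatches(attrs, regexpr(paste0(key, "=[^;]+"), attrs))
    if (length(m)) sub(paste0(key, "="), "", m) else NA_character_
  }
  do.call(rbind, lapply(fields, function(f) {
    data.frame(
      id = get_attr(f[9], "ID"), contig = f[1],
      start = as.integer(f[4]) - 1L, end = as.integer(f[5]),
      strand = f[7],
      status = get_attr(f[9], "status"),
      seed_family = get_attr(f[9], "seed_family"),
      dominant_arm = get_attr(f[9], "dominant_arm"),
      stringsAsFactors = FALSE
    )
  }))
}

#' Read a BioGRID-style interaction table
#'
#' Tab-delimited with configurable column positions for the two
#' interactor symbols, the two taxon ids and the detection-method
#' field; the `MI:nnnn` token is extracted downstream by
#' [filter_interactions()].
#'
#' @param path File path.
#' @param col_symbol_a,col_symbol_b,col_taxid_a,col_taxid_b,col_mi
#'   1-based column indices.
#' @param header Whether the file has a header line.
#' @return Data frame with the five standard columns.
#' @export
read_interaction_table <- function(path, col_symbol_a = 1L,
                                   col_symbol_b = 2L, col_taxid_a = 3L,
                                   col_taxid_b = 4L, col_mi = 5L,
                                   header = TRUE) {
  raw <- read.delim(path, header = header, stringsAsFactors = FALSE)
  data.frame(symbol_a = raw[[col_symbol_a]],
             symbol_b = raw[[col_symbol_b]],
             taxid_a = raw[[col_taxid_a]],
             taxid_b = raw[[col_taxid_b]],
             mi_code = raw[[col_mi]], stringsAsFactors = FALSE)
}

#' Write called blocks as BED
#'
#' 0-based half-open, with mean ratio as the score column.
#' @param blocks Data frame from [call_bblocks()].
#' @param path Output path.
#' @export
write_blocks_bed <- function(blocks, path) {
  bed <- data.frame(blocks$contig, blocks$start, blocks$end,
                    sprintf("bblock_%d", seq_len(nrow(blocks))),
                    round(blocks$mean_ratio, 4), ".")
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Bundled dataset: clustered B-DE-miRNA loci of A. latifasciata
#'
#' Published coordinates and fold changes of the mature B-DE-miRNAs
#' found in five clustered genomic regions of the *Astatotilapia
#' latifasciata* genome (contrast codes: BR/GO/MU = brain/gonad/muscle,
#' F/M = female/male). One row per (mature miRNA, contrast); precursor
#' coordinates repeat across their matures.
#'
#' @return Data frame with contig, precursor_id, strand, pre_start,
#'   pre_end, seed_similarity, mature_id, contrast, direction,
#'   fold_change.
#' @export
bde_cluster_loci <- function() {
  read.delim(system.file("extdata", "bde_mirna_cluster_loci.tsv",
                         package = "bmirnet"),
             stringsAsFactors = FALSE)
}

#' Precursor-level view of [bde_cluster_loci()]
#'
#' One row per precursor (id, contig, start, end, strand), ready for
#' [cluster_mirnas()].
#' @return Data frame.
#' @export
bde_cluster_precursors <- function() {
  loci <- bde_cluster_loci()
  pre <- unique(loci[, c("precursor_id", "contig", "strand",
                         "pre_start", "pre_end")])
  data.frame(id = pre$precursor_id, contig = pre$contig,
             start = pre$pre_start, end = pre$pre_end,
             strand = pre$strand, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Bundled dataset: coding integrity of B-chromosome gene copies
#'
#' Published integrity percentages (fraction of the coding region
#' intact relative to the A-chromosome copy) for the 42 B-genes present
#' in the B-miR-net, split into B-related proteins (targets of
#' B-DE-miRNAs or their interactors) and other proteins.
#'
#' @return Data frame with gene_name, protein_symbol, integrity,
#'   category.
#' @export
bgene_integrity <- function() {
  read.delim(system.file("extdata", "bgene_integrity.tsv",
                         package = "bmirnet"),
             stringsAsFactors = FALSE)
}
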