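#' Intersect per-group target sets into the B-related protein set
#'
#' The exact intersection of protein symbols targeted in every compared
#' group defines the B-related proteins. For exactly three groups the
#' seven Venn region counts are also reported.
#'
#' @param per_group_target_sets Named list (group -> character vector of
#'   protein symbols), length >= 2.
#' @return List with `shared` (the intersection, sorted) and `venn`
#'   (named region counts for 3 groups, else `NULL`).
#' @examples
#' intersect_target_sets(list(g1 = c("A", "B", "C"), g2 = c("B", "C"),
#'                            g3 = c("B", "C", "D")))$shared
#' @export
intersect_target_sets <- function(per_group_target_sets) {
  stopifnot(length(per_group_target_sets) >= 2L)
  sets <- lapply(per_group_target_sets, function(s) unique(toupper(s)))
  if (any(lengths(sets) == 0L)) {
    warning("a group has an empty target set; intersection is empty")
  }
  shared <- sort(Reduce(intersect, sets))
  venn <- NULL
  if (length(sets) == 3L) {
    all_ids <- unique(unlist(sets))
    inset <- vapply(sets, function(s) all_ids %in% s,
                    logical(length(all_ids)))
    if (length(all_ids)) {
      inset <- matrix(inset, nrow = length(all_ids))
      key <- apply(inset, 1L, function(z) {
        paste(names(sets)[z], collapse = "&")
      })
      venn <- table(key)
      venn <- setNames(as.integer(venn), names(venn))
    } else {
      venn <- integer(0)
    }
  }
  list(shared = shared, venn = venn)
}

#' Default allowed PSI-MI detection-method codes
#'
#' Affinity chromatography (MI:0004), X-ray crystallography (MI:0114),
#' far western blotting (MI:0047), FRET (MI:0055), protein
#' complementation assay (MI:0090), experimental interaction detection
#' (MI:0045) and two-hybrid (MI:0018).
#' @return Character vector of MI codes.
#' @export
default_allowed_mi <- function() {
  c("MI:0004", "MI:0114", "MI:0047", "MI:0055", "MI:0090", "MI:0045",
    "MI:0018")
}

#' Filter a protein-protein interaction table
#'
#' Keeps rows where both interactors belong to the target taxon and the
#' detection method is in the allowed MI-code set, canonicalizes each
#' pair (upper-cased, sorted symbols), and drops self-loops and
#' duplicate pairs. The MI token is extracted from the detection-method
#' field by pattern (`MI:nnnn`), so full BioGRID-style
#' `psi-mi:"MI:0004"(...)` values are accepted.
#'
#' @param records Data frame with `symbol_a`, `symbol_b`, `taxid_a`,
#'   `taxid_b`, `mi_code` columns.
#' @param allowed_mi Allowed detection-method codes.
#' @param taxid Required taxon for both interactors (9606 = human).
#' @return Data frame of canonical undirected edges (`node_a < node_b`)
#'   with a `removed` attribute counting rows dropped per rule.
#' @export
filter_interactions <- function(records, allowed_mi = default_allowed_mi(),
                                taxid = 9606L) {
  needed <- c("symbol_a", "symbol_b", "taxid_a", "taxid_b", "mi_code")
  stopifnot(all(needed %in% names(records)))
  ok_row <- !is.na(records$symbol_a) & !is.na(records$symbol_b) &
    nzchar(records$symbol_a) & nzchar(records$symbol_b)
  n_malformed <- sum(!ok_row)
  if (n_malformed) message(n_malformed, " malformed rows skipped")
  records <- records[ok_row, , drop = FALSE]

  mi <- regmatches(records$mi_code,
                   regexpr("MI:[0-9]{4}", records$mi_code))
  mi_tok <- rep(NA_character_, nrow(records))
  has_tok <- grepl("MI:[0-9]{4}", records$mi_code)
  mi_tok[has_tok] <- mi
  keep_tax <- records$taxid_a == taxid & records$taxid_b == taxid
  keep_mi <- !is.na(mi_tok) & mi_tok %in% allowed_mi
  kept <- records[keep_tax & keep_mi, , drop = FALSE]

  a <- toupper(kept$symbol_a)
  b <- toupper(kept$symbol_b)
  node_a <- pmin(a, b)
  node_b <- pmax(a, b)
  not_self <- node_a != node_b
  edges <- data.frame(node_a = node_a[not_self], node_b = node_b[not_self],
                      stringsAsFactors = FALSE)
  dup <- duplicated(paste(edges$node_a, edges$node_b, sep = "\r"))
  edges <- edges[!dup, , drop = FALSE]
  edges <- edges[order(edges$node_a, edges$node_b), , drop = FALSE]
  rownames(edges) <- NULL
  attr(edges, "removed") <- c(
    malformed = n_malformed,
    taxon = sum(!keep_tax),
    mi_code = sum(keep_tax & !keep_mi),
    self_loop = sum(!not_self),
    duplicate = sum(dup)
  )
  edges
}

#' Extract the subnetwork induced on a seed set
#'
#' Returns the subgraph induced on the seed symbols: only edges with
#' both endpoints in the seed set survive, and seed nodes left without
#' any edge are dropped (so the node count can be far below the seed
#' count). Symbols are case-folded to upper case before matching.
#'
#' @param edges Data frame with `node_a`, `node_b` columns (undirected).
#' @param seed_symbols Character vector of seed protein symbols.
#' @return List with `edges` (data frame) and `nodes` (character).
#' @export
extract_subnetwork <- function(edges, seed_symbols) {
  stopifnot(length(seed_symbols) >= 1L)
  seeds <- unique(toupper(seed_symbols))
  g <- igraph::graph_from_data_frame(
    data.frame(from = toupper(edges$node_a), to = toupper(edges$node_b)),
    directed = FALSE
  )
  sub <- igraph::induced_subgraph(g, intersect(igraph::V(g)$name, seeds))
  sub <- igraph::delete_vertices(sub, which(igraph::degree(sub) == 0))
  el <- igraph::as_data_frame(sub, what = "edges")
  out <- data.frame(node_a = pmin(el$from, el$to),
                    node_b = pmax(el$from, el$to),
                    stringsAsFactors = FALSE)
  out <- out[order(out$node_a, out$node_b), , drop = FALSE]
  rownames(out) <- NULL
  list(edges = out, nodes = sort(igraph::V(sub)$name))
}

#' Assemble the merged protein + miRNA network (B-miR-net)
#'
#' Merges the seeded PPI subnetwork with directed miRNA-to-protein
#' regulatory edges. Regulatory edges are deduplicated (multiple
#' transcripts of one gene contribute one edge); edges pointing to a
#' protein absent from both the subnetwork and the tissue-specific
#' target list are dropped with a message. Node provenance distinguishes
#' B-genes, B-related proteins (subnetwork members), tissue-specific
#' targets and miRNAs; per-node degree is reported.
#'
#' @param subgraph List from [extract_subnetwork()] (or a data frame of
#'   `node_a`/`node_b` PPI edges).
#' @param regulatory_edges Data frame with `mirna_id` and
#'   `gene_symbol` columns.
#' @param tissue_specific_targets Character vector of protein symbols
#'   targeted outside the shared core.
#' @param b_genes Character vector of protein symbols reported on the B
#'   chromosome (provenance labelling only).
#' @return List of class `"bmirnet"` with `protein_nodes`,
#'   `mirna_nodes`, `ppi_edges`, `regulatory_edges`, `provenance`,
#'   `degree`.
#' @export
assemble_bmirnet <- function(subgraph, regulatory_edges,
                             tissue_specific_targets = character(),
                             b_genes = character()) {
  ppi <- if (is.data.frame(subgraph)) subgraph else subgraph$edges
  sub_nodes <- unique(c(ppi$node_a, ppi$node_b))
  targets_ok <- unique(toupper(c(sub_nodes, tissue_specific_targets)))

  reg <- data.frame(mirna_id = regulatory_edges$mirna_id,
                    gene_symbol = toupper(regulatory_edges$gene_symbol),
                    stringsAsFactors = FALSE)
  reg <- reg[!duplicated(paste(reg$mirna_id, reg$gene_symbol)), ,
             drop = FALSE]
  dropped <- !(reg$gene_symbol %in% targets_ok)
  if (any(dropped)) {
    message(sum(dropped),
            " regulatory edges to unknown proteins dropped")
  }
  reg <- reg[!dropped, , drop = FALSE]
  rownames(reg) <- NULL

  protein_nodes <- sort(unique(c(sub_nodes, reg$gene_symbol)))
  mirna_nodes <- sort(unique(reg$mirna_id))
  provenance <- setNames(rep("tissue-specific target",
                             length(protein_nodes)), protein_nodes)
  provenance[protein_nodes %in% sub_nodes] <- "B-related"
  provenance[protein_nodes %in% toupper(b_genes)] <- "B-gene"

  deg <- setNames(rep(0L, length(protein_nodes) + length(mirna_nodes)),
                  c(protein_nodes, mirna_nodes))
  tab <- table(c(ppi$node_a, ppi$node_b, reg$gene_symbol, reg$mirna_id))
  deg[names(tab)] <- as.integer(tab)

  structure(list(protein_nodes = protein_nodes,
                 mirna_nodes = mirna_nodes,
                 ppi_edges = ppi, regulatory_edges = reg,
                 provenance = provenance, degree = deg),
            class = "bmirnet")
}

#' @export
print.bmirnet <- function(x, ...) {
  cat(sprintf(
    "B-miR-net: %d nodes (%d proteins, %d miRNAs), %d edges (%d PPI + %d regulatory)\n",
    length(x$protein_nodes) + length(x$mirna_nodes),
    length(x$protein_nodes), length(x$mirna_nodes),
    nrow(x$ppi_edges) + nrow(x$regulatory_edges),
    nrow(x$ppi_edges), nrow(x$regulatory_edges)))
  print(table(x$provenance))
  invisible(x)
}

#' Partition B-genes by coding integrity
#'
#' Splits gene-integrity records at a strict threshold: genes whose
#' coding region is more than `threshold` percent intact are potentially
#' translated; the rest likely yield truncated products. Both partitions
#' are sorted by descending integrity.
#'
#' @param records Data frame with `gene_name`, `protein_symbol`,
#'   `integrity` (percent, in `[0, 100]`).
#' @param threshold Integrity threshold in percent (strict `>`).
#' @return List with `above` and `at_or_below` data frames.
#' @export
integrity_partition <- function(records, threshold = 80) {
  bad <- which(records$integrity < 0 | records$integrity > 100 |
                 is.na(records$integrity))
  if (length(bad)) {
    stop("integrity out of [0, 100] for: ",
         paste(records$protein_symbol[bad], collapse = ", "),
         call. = FALSE)
  }
  ord <- records[order(-records$integrity, records$protein_symbol), ,
                 drop = FALSE]
  rownames(ord) <- NULL
  list(above = ord[ord$integrity > threshold, , drop = FALSE],
       at_or_below = ord[ord$integrity <= threshold, , drop = FALSE])
}

#' Hypergeometric term enrichment with BH correction
#'
#' For each annotation term present in the selected set, computes the
#' hypergeometric upper-tail probability of observing at least `k`
#' annotated genes among `n` selected from a background of `N` with `K`
#' annotated, then Benjamini-Hochberg q-values over the tested terms.
#' Terms with no selected gene are untested.
#'
#' @param selected Character vector of selected genes (subset of
#'   `background`).
#' @param background Character vector of background genes.
#' @param annotation Data frame with `gene` and `term` columns.
#' @return Data frame with `term`, `k`, `K`, `n`, `N`, `p_value`,
#'   `q_value`, sorted by p-value.
#' @export
enrich_terms <- function(selected, background, annotation) {
  selected <- unique(selected)
  background <- unique(background)
  if (!all(selected %in% background)) {
    stop("selected genes must be a subset of the background",
         call. = FALSE)
  }
  ann <- annotation[annotation$gene %in% background, , drop = FALSE]
  n <- length(selected)
  N <- length(background)
  terms <- unique(ann$term[ann$gene %in% selected])
  out <- lapply(terms, function(tm) {
    genes_tm <- unique(ann$gene[ann$term == tm])
    K <- length(genes_tm)
    k <- length(intersect(genes_tm, selected))
    data.frame(term = tm, k = k, K = K, n = n, N = N,
               p_value = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  if (!length(out)) {
    return(data.frame(term = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p_value = numeric(),
                      q_value = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res$q_value <- p.adjust(res$p_value, "BH")
  res <- res[order(res$p_value, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Exclusive and shared enriched terms between two gene groups
#'
#' @param terms_a,terms_b Character vectors of enriched term ids
#'   (computed at a common q cutoff).
#' @return List with `exclusive_a` (`a \\ b`), `exclusive_b` and
#'   `shared`.
#' @export
exclusive_terms <- function(terms_a, terms_b) {
  list(exclusive_a = sort(setdiff(terms_a, terms_b)),
       exclusive_b = sort(setdiff(terms_b, terms_a)),
       shared = sort(intersect(terms_a, terms_b)))
}
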