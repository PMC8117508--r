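test_that("target-set intersection is exact and emits Venn counts", {
  got <- intersect_target_sets(list(g1 = c("A", "B", "C"),
                                    g2 = c("B", "C"),
                                    g3 = c("B", "C", "D")))
  expect_identical(got$shared, c("B", "C"))
  expect_identical(unname(got$venn[["g1&g2&g3"]]), 2L)
  expect_identical(unname(got$venn[["g1"]]), 1L)
  same <- intersect_target_sets(list(a = c("X", "Y"), b = c("X", "Y")))
  expect_identical(same$shared, c("X", "Y"))
  expect_warning(
    empty <- intersect_target_sets(list(a = "X", b = character(0))),
    "empty"
  )
  expect_length(empty$shared, 0L)
})

test_that("planted shared-target sets are recovered exactly", {
  gi <- gen_interactions(NULL, sim_config(seed = 60))
  got <- intersect_target_sets(gi$per_group_targets)
  expect_identical(got$shared, gi$shared_targets)
})

test_that("interaction filtering applies taxon, MI, self-loop and dedup rules", {
  records <- data.frame(
    symbol_a = c("TP53", "BRCA1", "TP53",  "EGFR", "KRAS", "MYC", "sun1"),
    symbol_b = c("MDM2", "TP53",  "MDM2",  "EGFR", "TP53", "MAX", "SYNE1"),
    taxid_a =  c(9606,   9606,    9606,    9606,   9606,   10090, 9606),
    taxid_b =  c(9606,   9606,    9606,    9606,   9606,   9606,  9606),
    mi_code = c("MI:0004", "MI:0018", "MI:0114", "MI:0004", "MI:0686",
                "MI:0018", 'psi-mi:"MI:0045"(experimental)')
  )
  edges <- filter_interactions(records)
  expect_identical(edges$node_a, c("BRCA1", "MDM2", "SUN1"))
  expect_identical(edges$node_b, c("TP53", "TP53", "SYNE1"))
  removed <- attr(edges, "removed")
  expect_identical(unname(removed[["taxon"]]), 1L)
  expect_identical(unname(removed[["mi_code"]]), 1L)
  expect_identical(unname(removed[["self_loop"]]), 1L)
  expect_identical(unname(removed[["duplicate"]]), 1L)
  # reversed duplicate collapses to one edge
  rev2 <- data.frame(symbol_a = c("A", "B"), symbol_b = c("B", "A"),
                     taxid_a = 9606, taxid_b = 9606, mi_code = "MI:0004")
  expect_identical(nrow(filter_interactions(rev2)), 1L)
})

test_that("interaction filtering is idempotent and cleans simulated defects", {
  gi <- gen_interactions(NULL, sim_config(seed = 61))
  edges <- filter_interactions(gi$interactions)
  expect_identical(anyDuplicated(paste(edges$node_a, edges$node_b)), 0L)
  expect_true(all(edges$node_a != edges$node_b))
  again <- filter_interactions(data.frame(
    symbol_a = edges$node_a, symbol_b = edges$node_b,
    taxid_a = 9606, taxid_b = 9606, mi_code = "MI:0004"))
  expect_identical(again$node_a, edges$node_a)
  expect_identical(again$node_b, edges$node_b)
  # clean rows survive exactly (defect-free subset is the identity)
  clean <- gi$interactions[gi$row_truth == "none", ]
  clean_edges <- filter_interactions(clean)
  expect_identical(nrow(clean_edges), nrow(clean))
})

test_that("subnetwork extraction equals the brute-force edge scan", {
  set.seed(62)
  for (rep in 1:10) {
    n <- sample(10:50, 1)
    nodes <- sprintf("N%02d", 1:n)
    m <- sample(10:80, 1)
    edges <- unique(data.frame(
      node_a = nodes[sample(n, m, TRUE)],
      node_b = nodes[sample(n, m, TRUE)]
    ))
    edges <- edges[edges$node_a != edges$node_b, ]
    canon <- data.frame(node_a = pmin(edges$node_a, edges$node_b),
                        node_b = pmax(edges$node_a, edges$node_b))
    canon <- canon[!duplicated(paste(canon$node_a, canon$node_b)), ]
    seeds <- sample(nodes, sample(3:n, 1))
    got <- extract_subnetwork(canon, seeds)
    keep <- canon$node_a %in% seeds & canon$node_b %in% seeds
    want <- canon[keep, , drop = FALSE]
    want <- want[order(want$node_a, want$node_b), , drop = FALSE]
    expect_identical(got$edges$node_a, want$node_a)
    expect_identical(got$edges$node_b, want$node_b)
    expect_setequal(got$nodes, unique(c(want$node_a, want$node_b)))
  }
})

test_that("subnetwork extraction drops isolated seeds and is idempotent", {
  k4 <- data.frame(node_a = c("A", "A", "A", "B", "B", "C"),
                   node_b = c("B", "C", "D", "C", "D", "D"))
  tri <- extract_subnetwork(k4, c("A", "B", "C"))
  expect_identical(nrow(tri$edges), 3L)
  expect_setequal(tri$nodes, c("A", "B", "C"))
  # no adjacent seed pair: empty result
  path <- data.frame(node_a = c("A", "B"), node_b = c("B", "C"))
  none <- extract_subnetwork(path, c("A", "C"))
  expect_identical(nrow(none$edges), 0L)
  expect_length(none$nodes, 0L)
  twice <- extract_subnetwork(tri$edges, c("A", "B", "C"))
  expect_identical(twice$edges, tri$edges)
})

test_that("B-miR-net assembly merges, deduplicates and labels provenance", {
  ppi <- data.frame(node_a = c("P1", "P1", "P2"),
                    node_b = c("P2", "P3", "P3"))
  reg <- data.frame(
    mirna_id = c("m1", "m1", "m1", "m2", "m2", "m2", "m1"),
    gene_symbol = c("P1", "P2", "T1", "P1", "P2", "T1", "P1")  # one dup
  )
  net <- assemble_bmirnet(ppi, reg, tissue_specific_targets = "T1",
                          b_genes = "P3")
  expect_identical(nrow(net$ppi_edges), 3L)
  expect_identical(nrow(net$regulatory_edges), 6L)
  expect_setequal(net$protein_nodes, c("P1", "P2", "P3", "T1"))
  expect_setequal(net$mirna_nodes, c("m1", "m2"))
  expect_identical(unname(net$provenance[c("P1", "P3", "T1")]),
                   c("B-related", "B-gene", "tissue-specific target"))
  expect_identical(unname(net$degree[["P1"]]), 4L)  # 2 PPI + 2 regulatory
  # regulatory edge to an unknown protein is dropped with a message
  reg_bad <- rbind(reg, data.frame(mirna_id = "m3", gene_symbol = "ZZ"))
  expect_message(net2 <- assemble_bmirnet(ppi, reg_bad, "T1"), "dropped")
  expect_false("ZZ" %in% net2$protein_nodes)
  # empty regulatory set reduces to the subgraph
  net3 <- assemble_bmirnet(ppi, reg[0, ])
  expect_identical(nrow(net3$regulatory_edges), 0L)
  expect_setequal(net3$protein_nodes, c("P1", "P2", "P3"))
})

test_that("integrity partitioning is strict at the threshold and exhaustive", {
  rec <- data.frame(gene_name = c("a", "b", "c", "d"),
                    protein_symbol = c("A", "B", "C", "D"),
                    integrity = c(80.25, 80.00, 79.90, 100))
  part <- integrity_partition(rec, 80)
  expect_setequal(part$above$protein_symbol, c("A", "D"))
  expect_setequal(part$at_or_below$protein_symbol, c("B", "C"))
  expect_identical(nrow(part$above) + nrow(part$at_or_below), nrow(rec))
  expect_true(all(diff(part$at_or_below$integrity) <= 0))
  empty <- integrity_partition(rec[0, ], 80)
  expect_identical(nrow(empty$above), 0L)
  bad <- data.frame(gene_name = "x", protein_symbol = "X",
                    integrity = 104)
  expect_error(integrity_partition(bad), "X")
})

test_that("hypergeometric enrichment matches closed forms and enumeration", {
  background <- sprintf("g%02d", 1:20)
  selected <- background[1:5]
  ann <- data.frame(gene = background[1:5], term = "T1")
  res <- enrich_terms(selected, background, ann)
  expect_equal(res$p_value, 1 / choose(20, 5))

  # selected = background makes every term p = 1
  ann2 <- data.frame(gene = background, term = rep(c("T1", "T2"), 10))
  res2 <- enrich_terms(background, background, ann2)
  expect_true(all(res2$p_value == 1))

  # small-N enumeration oracle
  set.seed(63)
  bg <- sprintf("h%02d", 1:12)
  ann3 <- do.call(rbind, lapply(bg, function(g) {
    data.frame(gene = g, term = sample(c("A", "B", "C"), sample(1:2, 1)))
  }))
  sel <- sample(bg, 5)
  res3 <- enrich_terms(sel, bg, ann3)
  for (i in seq_len(nrow(res3))) {
    K <- res3$K[i]
    n <- res3$n[i]
    N <- res3$N[i]
    mass <- vapply(0:min(K, n), function(k) {
      choose(K, k) * choose(N - K, n - k) / choose(N, n)
    }, numeric(1))
    expect_equal(res3$p_value[i], sum(mass[(res3$k[i] + 1):length(mass)]),
                 tolerance = 1e-12)
  }
  expect_error(enrich_terms(c("zz"), bg, ann3), "subset")
})

test_that("enrichment p is monotone nonincreasing in k", {
  ps <- vapply(1:5, function(k) {
    phyper(k - 1, 5, 15, 5, lower.tail = FALSE)
  }, numeric(1))
  expect_true(all(diff(ps) <= 0))
  sel <- sprintf("g%02d", 1:5)
  bg <- sprintf("g%02d", 1:20)
  ann <- data.frame(gene = c(sel[1:3], bg[6:7]), term = "T")
  expect_equal(enrich_terms(sel, bg, ann)$p_value,
               phyper(2, 5, 15, 5, lower.tail = FALSE))
})

test_that("exclusive-term comparison returns differences and the shared set", {
  got <- exclusive_terms(c("x", "y", "z"), c("y"))
  expect_identical(got$exclusive_a, c("x", "z"))
  expect_identical(got$shared, "y")
  expect_length(exclusive_terms(c("a", "b"), c("a", "b"))$exclusive_a, 0L)
})

test_that("planted exclusive terms are recovered from synthetic annotation", {
  set.seed(64)
  bg <- sprintf("g%03d", 1:60)
  sel <- bg[1:12]
  # terms: EX1 only annotates selected genes; SH annotates everyone
  ann <- rbind(
    data.frame(gene = sel[1:8], term = "EX1"),
    data.frame(gene = bg, term = "SH"),
    data.frame(gene = bg[30:50], term = "BG1")
  )
  res_sel <- enrich_terms(sel, bg, ann)
  res_all <- enrich_terms(bg, bg, ann)
  sig_sel <- res_sel$term[res_sel$q_value < 0.05]
  sig_all <- res_all$term[res_all$q_value < 0.05]
  expect_identical(exclusive_terms(sig_sel, sig_all)$exclusive_a, "EX1")
})
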