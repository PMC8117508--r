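# Independent brute-force oracles used across the suite.

base_comp <- c(A = "T", C = "G", G = "C", T = "A")

naive_revcomp <- function(x) {
  paste(rev(base_comp[strsplit(x, "")[[1]]]), collapse = "")
}

# Naive O(n*m) seed-site scan: walks every UTR offset, compares the core
# character by character, then applies the same flank classification and
# overlap-resolution rules as the package function.
naive_seed_scan <- function(mirna_seq, utr_seq) {
  m <- strsplit(toupper(mirna_seq), "")[[1]]
  u <- strsplit(toupper(utr_seq), "")[[1]]
  core <- rev(base_comp[m[2:7]])  # reverse complement of positions 2-7
  comp8 <- base_comp[[m[8]]]
  cand <- list()
  for (q0 in 0:(length(u) - 6)) {
    if (q0 < 0) next
    if (!all(u[(q0 + 1):(q0 + 6)] == core)) next
    m8 <- q0 >= 1 && u[q0] == comp8
    a1 <- (q0 + 7) <= length(u) && u[q0 + 7] == "A"
    type <- if (m8 && a1) "8mer" else if (m8) "7mer-m8" else
      if (a1) "7mer-1A" else NA
    if (is.na(type)) next
    cand[[length(cand) + 1]] <- list(type = type,
                                     pos = if (m8) q0 - 1 else q0)
  }
  if (!length(cand)) {
    return(data.frame(site_type = character(), utr_position = integer()))
  }
  rank <- c("8mer" = 1, "7mer-m8" = 2, "7mer-1A" = 3)
  ord <- order(vapply(cand, function(z) rank[[z$type]], 1),
               vapply(cand, function(z) z$pos, 1))
  kept <- list()
  for (i in ord) {
    ok <- all(vapply(kept, function(z) abs(z$pos - cand[[i]]$pos) >= 7,
                     TRUE))
    if (ok) kept[[length(kept) + 1]] <- cand[[i]]
  }
  out <- data.frame(
    site_type = vapply(kept, function(z) z$type, ""),
    utr_position = vapply(kept, function(z) z$pos, 1)
  )
  out[order(out$utr_position), , drop = FALSE]
}

# All-pairs transitive-closure clustering oracle.
closure_clusters <- function(precursors, max_gap = 5000) {
  n <- nrow(precursors)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (precursors$contig[i] != precursors$contig[j]) next
    gap <- max(precursors$start[i], precursors$start[j]) -
      min(precursors$end[i], precursors$end[j])
    adj[i, j] <- gap <= max_gap
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        comp[c(i, j)] <- min(comp[i], comp[j])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  split(precursors$id, comp)
}

# Exhaustive conditional NB p-value for small totals.
enumerate_exact_p <- function(y1, y2, phi) {
  n1 <- length(y1)
  n2 <- length(y2)
  s1 <- sum(y1)
  t <- s1 + sum(y2)
  mu <- t / (n1 + n2)
  pr <- vapply(0:t, function(a) {
    dnbinom(a, size = n1 / phi, mu = n1 * mu) *
      dnbinom(t - a, size = n2 / phi, mu = n2 * mu)
  }, numeric(1))
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[s1 + 1] * (1 + 1e-12)])
}

# Recall/precision of called blocks against planted blocks (a truth
# block is recovered when any call overlaps it; a call is a true
# positive when it overlaps any truth block).
block_recall_precision <- function(called, truth) {
  overlaps <- function(a, b) {
    any(b$contig == a$contig & b$start < a$end & b$end > a$start)
  }
  recall <- if (nrow(truth)) {
    mean(vapply(seq_len(nrow(truth)), function(i) {
      overlaps(truth[i, ], called)
    }, TRUE))
  } else NA_real_
  precision <- if (nrow(called)) {
    mean(vapply(seq_len(nrow(called)), function(i) {
      overlaps(called[i, ], truth)
    }, TRUE))
  } else NA_real_
  c(recall = recall, precision = precision)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
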