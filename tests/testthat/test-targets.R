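test_that("3'UTR extraction honors annotated ORF coordinates", {
  set.seed(50)
  tx <- random_dna(300)
  ann <- data.frame(transcript_id = "t1", orf_start = 10, orf_end = 250)
  utr <- extract_utrs(c(t1 = tx), ann)
  expect_identical(utr$sequence, substr(tx, 251, 300))
  expect_identical(nchar(utr$sequence), 50L)
  # ORF running to the transcript end leaves no UTR
  ann2 <- data.frame(transcript_id = "t1", orf_start = 0, orf_end = 300)
  expect_identical(nrow(extract_utrs(c(t1 = tx), ann2)), 0L)
  ann3 <- data.frame(transcript_id = "t1", orf_start = 100, orf_end = 50)
  expect_warning(out <- extract_utrs(c(t1 = tx), ann3), "malformed")
  expect_identical(nrow(out), 0L)
})

test_that("de novo UTR extraction matches a six-frame longest-ORF oracle", {
  set.seed(51)
  oracle_utr <- function(seq) {
    stops <- c("TAA", "TAG", "TGA")
    best <- NULL
    for (strand in c("+", "-")) {
      s <- if (strand == "+") seq else naive_revcomp(seq)
      ch <- strsplit(s, "")[[1]]
      for (frame in 0:2) {
        i <- frame + 1
        open <- NA
        ncod <- 0
        while (i + 2 <= length(ch)) {
          cod <- paste(ch[i:(i + 2)], collapse = "")
          if (is.na(open) && cod == "ATG") { open <- i; ncod <- 0 }
          else if (!is.na(open)) ncod <- ncod + 0
          if (!is.na(open) && cod %in% stops) {
            len <- (i - open) / 3
            if (len >= 20 && (is.null(best) || len > best$len)) {
              best <- list(len = len, strand = strand, stop_end = i + 2)
            }
            open <- NA
          }
          i <- i + 3
        }
      }
    }
    if (is.null(best)) return(NULL)
    s <- if (best$strand == "+") seq else naive_revcomp(seq)
    if (best$stop_end >= nchar(s)) return(NULL)
    substr(s, best$stop_end + 1, nchar(s))
  }
  for (rep in 1:20) {
    # plant an ORF on a random strand so most cases have a real answer
    orf <- paste0("ATG", paste(replicate(sample(25:60, 1), {
      repeat {
        cod <- random_dna(3)
        if (!cod %in% c("TAA", "TAG", "TGA")) break
      }
      cod
    }), collapse = ""), "TAA")
    if (runif(1) < 0.5) orf <- naive_revcomp(orf)
    tx <- paste0(random_dna(30), orf, random_dna(60))
    got <- extract_utrs(setNames(tx, "t"), min_codons = 20)
    want <- oracle_utr(tx)
    if (is.null(want)) {
      expect_identical(nrow(got), 0L)
    } else {
      expect_identical(got$sequence, want)
    }
  }
})

test_that("seed-site classification matches the forced constructions", {
  mirna <- list(id = "m1", sequence = "TGGAATGTAAAGAAGTATGTAT")
  seed7 <- substr(mirna$sequence, 2, 8)
  site_m8 <- naive_revcomp(seed7)
  # 8mer: full 7-nt match plus the A anchor
  utr8 <- list(transcript_id = "u", sequence = paste0(
    "CCCCCCCCCC", site_m8, "A", "CCCCCCCCCC"))
  got8 <- find_seed_sites(mirna, utr8)
  expect_identical(got8$site_type, "8mer")
  expect_identical(got8$utr_position, 10L)
  # 7mer-m8: position-8 pairing without the A
  utr7 <- list(transcript_id = "u", sequence = paste0(
    "CCCCCCCCCC", site_m8, "G", "CCCCCCCCCC"))
  expect_identical(find_seed_sites(mirna, utr7)$site_type, "7mer-m8")
  # 7mer-1A: core plus A, broken position-8 pairing
  core6 <- substr(site_m8, 2, 7)
  comp8 <- substr(site_m8, 1, 1)
  other <- setdiff(c("A", "C", "G", "T"), comp8)[1]
  utr1a <- list(transcript_id = "u", sequence = paste0(
    "CCCCCCCCC", other, core6, "A", "CCCCCCCCCC"))
  got1a <- find_seed_sites(mirna, utr1a)
  expect_identical(got1a$site_type, "7mer-1A")
  # poly-C UTR has no sites
  polyc <- list(transcript_id = "u", sequence = strrep("C", 60))
  expect_identical(nrow(find_seed_sites(mirna, polyc)), 0L)
})

test_that("seed-site finder matches the naive scan oracle on random pairs", {
  set.seed(52)
  for (i in 1:100) {
    mirna <- list(id = "m", sequence = random_dna(22))
    utr <- list(transcript_id = "u", sequence = random_dna(300))
    got <- find_seed_sites(mirna, utr)
    want <- naive_seed_scan(mirna$sequence, utr$sequence)
    expect_identical(got$site_type, want$site_type)
    expect_identical(as.integer(got$utr_position),
                     as.integer(want$utr_position))
  }
})

test_that("sites are stable under 3' extension of the UTR", {
  set.seed(53)
  mirna <- list(id = "m", sequence = random_dna(22))
  utr <- list(transcript_id = "u", sequence = paste0(
    random_dna(50), naive_revcomp(substr(mirna$sequence, 2, 8)), "A",
    random_dna(50)))
  base <- find_seed_sites(mirna, utr)
  longer <- utr
  longer$sequence <- paste0(longer$sequence, strrep("C", 100))
  ext <- find_seed_sites(mirna, longer)
  expect_identical(ext$site_type, base$site_type)
  expect_identical(ext$utr_position, base$utr_position)
})

test_that("context scoring is additive with a strict -0.2 cutoff", {
  mk <- function(types) {
    data.frame(mirna_id = rep("m", length(types)),
               transcript_id = rep("t", length(types)), site_type = types,
               utr_position = seq(0, by = 20, length.out = length(types)))
  }
  expect_false(score_interaction(mk(character(0)))$significant)
  expect_identical(score_interaction(mk(character(0)))$total_score, 0)
  one8 <- score_interaction(mk("8mer"))
  expect_equal(one8$total_score, -0.31)
  expect_true(one8$significant)
  one7 <- score_interaction(mk("7mer-m8"))
  expect_equal(one7$total_score, -0.16)
  expect_false(one7$significant)          # -0.16 > -0.2
  two7 <- score_interaction(mk(c("7mer-m8", "7mer-m8")))
  expect_equal(two7$total_score, -0.32)
  expect_true(two7$significant)
  expect_error(score_interaction(mk("9mer")), "unknown site type")
  # additivity over disjoint UTR fragments
  expect_equal(score_interaction(mk(c("8mer", "7mer-1A")))$total_score,
               score_interaction(mk("8mer"))$total_score +
                 score_interaction(mk("7mer-1A"))$total_score)
})

test_that("a more negative score configuration never shrinks the significant set", {
  set.seed(54)
  mirnas <- data.frame(mirna_id = c("m1", "m2"),
                       sequence = c(random_dna(22), random_dna(22)))
  utrs <- data.frame(
    transcript_id = sprintf("t%d", 1:20),
    sequence = vapply(1:20, function(i) paste0(
      random_dna(80),
      naive_revcomp(substr(mirnas$sequence[1 + i %% 2], 2, 8)),
      sample(c("A", "G"), 1), random_dna(80)), ""),
    gene_symbol = sprintf("G%d", 1:20),
    tissue_expression = "brain"
  )
  weak <- predict_all(mirnas, utrs, "brain")
  strong <- predict_all(mirnas, utrs, "brain",
                        site_scores = default_site_scores() * 2)
  key <- function(df) paste(df$mirna_id, df$transcript_id)
  expect_true(all(key(weak) %in% key(strong)))
})

test_that("tissue restriction and planted-site recovery work end to end", {
  cfg <- sim_config(seed = 55, n_utrs = 15, site_plant_rate = 0.25,
                    n_precursors = 4)
  sim <- gen_genome(cfg)
  gu <- gen_utrs(sim$truth, cfg)
  mirnas <- data.frame(mirna_id = sim$truth$matures$mirna_id,
                       sequence = sim$truth$matures$sequence)
  # transcripts not expressed in the tissue are excluded even with sites
  for (tis in c("brain", "gonad", "muscle")) {
    pred <- predict_all(mirnas, gu$utrs, tis)
    if (nrow(pred)) {
      expr <- gu$utrs$tissue_expression[
        match(pred$transcript_id, gu$utrs$transcript_id)]
      expect_true(all(grepl(tis, expr)))
    }
  }
  # every planted significant pair is recovered with no tissue filter
  pred_all <- predict_all(mirnas, gu$utrs, NULL)
  planted <- gu$planted_sites
  scores <- default_site_scores()
  pair_score <- tapply(scores[planted$site_type],
                       paste(planted$mirna_id, planted$transcript_id), sum)
  sig_pairs <- names(pair_score)[pair_score < -0.2]
  expect_true(all(sig_pairs %in%
                    paste(pred_all$mirna_id, pred_all$transcript_id)))
  expect_identical(nrow(predict_all(mirnas[0, ], gu$utrs, "brain")), 0L)
})
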