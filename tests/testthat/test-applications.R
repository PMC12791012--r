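test_that("repertoire annotation summarises scores per group", {
  fix <- sim_dataset(400, seed = 11)
  pairs <- fix$dataset$pairs[fix$dataset$pairs$label == "cognate", ][1:100, ]
  res <- annotate_repertoire(pairs, constant_scorer(0.7),
                             grouping = "isotype")
  expect_equal(sum(res$summary$n), 100)
  expect_true(all(res$summary$mean == 0.7))
  expect_true(all(res$pairs$pairing_score == 0.7))
  expect_setequal(res$summary$group, unique(pairs$heavy_isotype))
  expect_error(annotate_repertoire(pairs, constant_scorer(),
                                   grouping = "no_such_column"),
               "no_such_column")
})

test_that("annotation recovers a planted maturation trend", {
  rep <- sim_repertoire(1200)
  cfg <- synthetic_config(seed = 11, n_cells = 1200)
  pairs <- rep$pairs
  # plant an inverse relationship: v_identity decreasing with true
  # compatibility (higher-scoring pairs carry more mutated heavies)
  compat <- pair_compatibility(pairs, cfg)
  r <- rank(compat, ties.method = "first")
  pairs$heavy_v_identity <- 1 - (r / length(r)) * 0.3
  scorer <- oracle_scorer(pairs, cfg)
  res <- annotate_repertoire(pairs, scorer, grouping = "v_identity",
                             bins = 5)
  s <- res$summary
  lower <- as.numeric(sub("^[\\[(]", "",
                          vapply(strsplit(s$group, ","), `[`, "", 1)))
  ct <- suppressWarnings(cor.test(lower, s$mean, method = "spearman"))
  # group means fall as germline identity rises
  expect_lt(unname(ct$estimate), 0)
})

test_that("reshuffled controls derange lights and score lower", {
  fix <- sim_dataset(400, seed = 11)
  pairs <- fix$dataset$pairs[fix$dataset$pairs$label == "cognate", ]
  # two pairs: the only derangement is the swap
  ctrl2 <- reshuffled_control(pairs[1:2, ], constant_scorer(0.5), seed = 1)
  expect_equal(attr(ctrl2, "permutation"), c(2L, 1L))
  expect_error(reshuffled_control(pairs[1, ], constant_scorer()), "two")
  # no fixed points at any size
  for (seed in 1:3) {
    perm <- attr(reshuffled_control(pairs[1:25, ], constant_scorer(),
                                    seed = seed), "permutation")
    expect_false(any(perm == seq_along(perm)))
  }
  # on planted-rule data observed pairs outscore reshuffled controls
  cfg <- synthetic_config(seed = 11, n_cells = 400)
  sub <- pairs[1:150, ]
  # the oracle scorer must know the reshuffled combinations too
  light_cols <- paste0("light_", chain_fields())
  all_rows <- sub
  for (seed in 4:6) {
    perm <- igpair:::with_local_seed(seed,
                                     igpair:::derangement(nrow(sub)))
    shuf <- sub
    shuf[, light_cols] <- sub[perm, light_cols]
    all_rows <- dplyr::bind_rows(all_rows, shuf)
  }
  scorer <- oracle_scorer(all_rows, cfg)
  observed <- score_pairs(scorer, sub)
  control <- reshuffled_control(sub, scorer, seed = 5)
  expect_gt(mean(observed), mean(control))
})

test_that("cancer clone filtering applies each rule in order", {
  res <- filter_cancer_clonesets(cancer_fixture())
  expect_setequal(res$selected$sample_id, c("s1", "s6", "s8"))
  expect_equal(res$selected$light_locus[res$selected$sample_id == "s1"],
               "IGK")
  expect_equal(res$selected$light_locus[res$selected$sample_id == "s6"],
               "IGL")
  # highest-read-fraction heavy clone retained for s1
  expect_equal(
    res$selected$heavy_vdj_aa[res$selected$sample_id == "s1"], "QVQLVQSG")
  drop <- setNames(res$drop_log$rule, res$drop_log$sample_id)
  expect_equal(drop[["s2"]], "tcr_reads")
  expect_equal(drop[["s3"]], "few_ig_reads")
  expect_equal(drop[["s4"]], "no_heavy_reads")
  expect_equal(drop[["s5"]], "ambiguous_light_locus")
  expect_equal(drop[["s7"]], "out_of_frame")
})

test_that("cancer clone filtering is idempotent on its own output", {
  res <- filter_cancer_clonesets(cancer_fixture())
  # re-expressing the selected pairs as clone rows and re-filtering
  # reproduces the same selection
  again <- dplyr::bind_rows(lapply(seq_len(nrow(res$selected)), function(i) {
    s <- res$selected[i, ]
    tibble::tibble(sample_id = s$sample_id,
                   locus = c("IGH", s$light_locus),
                   read_count = c(1000, 1000),
                   read_fraction = 1,
                   vdj_aa = c(s$heavy_vdj_aa, s$light_vdj_aa),
                   in_frame = TRUE)
  }))
  res2 <- filter_cancer_clonesets(again)
  expect_equal(res2$selected$sample_id, res$selected$sample_id)
  expect_equal(res2$selected$heavy_vdj_aa, res$selected$heavy_vdj_aa)
  expect_equal(nrow(res2$drop_log), 0)
})

test_that("spatial candidates rank by prediction then score", {
  cand <- tibble::tibble(
    heavy_id = sprintf("h%d", 1:4), light_id = sprintf("l%d", 1:4),
    pairing_score = c(0.9, 0.4, 0.7, 0.6),
    colocalization_score = c(0.8, 0.9, 0.3, 0.7))
  ranked <- rank_spatial_candidates(cand, 0.5, 0.5)
  expect_equal(ranked$heavy_id[1:2], c("h1", "h4"))
  expect_equal(ranked$predicted, c(TRUE, TRUE, FALSE, FALSE))
  # without a colocalization threshold the pairing score decides alone
  ranked2 <- rank_spatial_candidates(cand, 0.5)
  expect_equal(sum(ranked2$predicted), 3)
  expect_error(
    rank_spatial_candidates(cand[, 1:3], colocalization_threshold = 0.5),
    "colocalization_score")
})

test_that("truth-set agreement matches a brute-force tally", {
  set.seed(61)
  cand <- tibble::tibble(
    pairing_score = round(runif(20), 2),
    confirmed = sample(c(TRUE, FALSE), 20, TRUE))
  ranked <- rank_spatial_candidates(cand, 0.5)
  agr <- attr(ranked, "agreement")
  pred <- cand$pairing_score >= 0.5
  expect_equal(agr[["TRUE", "TRUE"]], sum(pred & cand$confirmed))
  expect_equal(agr[["FALSE", "TRUE"]], sum(!pred & cand$confirmed))
  expect_equal(sum(agr), 20)
})

test_that("graft libraries cover V x J exactly with the CDRH3 verbatim", {
  g <- germline_reference()
  v <- g[g$locus == "IGH" & g$segment_type == "V", ][1:3, ]
  j <- g[g$locus == "IGH" & g$segment_type == "J", ][1:2, ]
  lib <- build_graft_library("CARDYW", v, j)
  expect_equal(nrow(lib), 6)
  expect_true(all(grepl("CARDYW", lib$vh_seq, fixed = TRUE)))
  expect_equal(lib$vh_seq[1],
               paste0(v$aa_seq[1], "CARDYW", j$aa_seq[1]))
  # deterministic (V name, then J name) ordering
  expect_equal(lib$v_name, rep(sort(v$name), each = 2))
  dup <- dplyr::bind_rows(v, v[1, ])
  expect_error(build_graft_library("CARDYW", dup, j), "duplicate")
  expect_error(build_graft_library("", v, j), "empty")
  expect_error(build_graft_library("CARDYW", v[0, ], j), "empty")
})

test_that("global-alignment identity matches an independent DP oracle", {
  expect_equal(pairwise_identity("ACDEFGHIKL", "ACDEFGHIKL"), 1)
  expect_equal(pairwise_identity("ACDEFGHIKL", "ACDEFGHIKV"), 0.9)
  expect_error(pairwise_identity("", "A"), "empty")
  # second, independently written needleman-wunsch (recursive with memo)
  oracle_nw <- function(a, b) {
    av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
    n <- length(av); m <- length(bv)
    S <- matrix(NA_real_, n + 1, m + 1)
    S[1, ] <- -(0:m); S[, 1] <- -(0:n)
    for (i in 1:n) for (j in 1:m) {
      S[i + 1, j + 1] <- max(S[i, j] + (av[i] == bv[j]),
                             S[i, j + 1] - 1, S[i + 1, j] - 1)
    }
    # traceback preferring the diagonal
    i <- n; j <- m; matches <- 0; cols <- 0
    while (i > 0 || j > 0) {
      cols <- cols + 1
      if (i > 0 && j > 0 &&
          S[i + 1, j + 1] == S[i, j] + (av[i] == bv[j])) {
        matches <- matches + (av[i] == bv[j]); i <- i - 1; j <- j - 1
      } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] - 1) {
        i <- i - 1
      } else j <- j - 1
    }
    matches / cols
  }
  set.seed(83)
  aa <- aa_alphabet(FALSE)
  for (k in 1:25) {
    a <- paste(sample(aa, 30, TRUE), collapse = "")
    b <- if (k %% 3 == 0) {
      # related pair: a with a few edits
      chars <- strsplit(a, "")[[1]]
      chars[sample(30, 4)] <- sample(aa, 4, TRUE)
      paste(chars[-sample(30, 2)], collapse = "")
    } else paste(sample(aa, sample(25:35, 1), TRUE), collapse = "")
    expect_equal(pairwise_identity(a, b), oracle_nw(a, b))
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  }
  # identical suffix appends leave identity at 1 for identical prefixes
  expect_equal(pairwise_identity("ACDEFG", "ACDEFG"),
               pairwise_identity("ACDEFGWWW", "ACDEFGWWW"))
})

test_that("library screens recover a reconstructible wild type exactly", {
  g <- germline_reference()
  v <- g[g$locus == "IGH" & g$segment_type == "V", ]
  j <- g[g$locus == "IGH" & g$segment_type == "J", ]
  rep <- sim_repertoire(120)
  wt <- rep$pairs[1, ]
  # the simulator builds VH = germline V + CDR3 + germline J with possible
  # V mutations; rebuild an unmutated wild type so it is reconstructible
  wt$heavy_sequence_vdj_aa <- paste0(
    v$aa_seq[v$name == wt$heavy_v_call], wt$heavy_cdr3_aa,
    j$aa_seq[j$name == wt$heavy_j_call])
  lib <- build_graft_library(wt$heavy_cdr3_aa, v, j)
  expect_equal(nrow(lib), nrow(v) * nrow(j))
  res <- screen_library(wt, lib, constant_scorer(0.7))
  expect_equal(res$best$identity_to_wt, 1)
  expect_equal(res$best$score_gap_to_wt, 0)
  expect_equal(res$best$v_name, wt$heavy_v_call)
  expect_equal(res$best$j_name, wt$heavy_j_call)
  expect_equal(res$wt_score, 0.7)
})

test_that("screen reports match a brute-force enumeration", {
  g <- germline_reference()
  v <- g[g$locus == "IGH" & g$segment_type == "V", ][1:3, ]
  j <- g[g$locus == "IGH" & g$segment_type == "J", ][1:2, ]
  rep <- sim_repertoire(120)
  wt <- rep$pairs[2, ]
  lib <- build_graft_library(wt$heavy_cdr3_aa, v, j)
  # hand-set scores keyed by candidate heavy sequence
  set.seed(29)
  score_map <- setNames(round(runif(nrow(lib) + 1), 3),
                        c(lib$vh_seq, wt$heavy_sequence_vdj_aa))
  scorer <- load_external_scorer(function(h, l) unname(score_map[h]))
  res <- screen_library(wt, lib, scorer)
  expect_equal(res$library$pairing_score, unname(score_map[lib$vh_seq]))
  best_idx <- which.max(res$library$pairing_score)
  expect_equal(res$best$vh_seq, lib$vh_seq[best_idx])
  expect_equal(res$library$score_gap_to_wt,
               abs(unname(score_map[lib$vh_seq]) -
                     unname(score_map[wt$heavy_sequence_vdj_aa])))
  # permutation invariance of the screen
  perm <- sample(nrow(lib))
  res2 <- screen_library(wt, lib[perm, ], scorer)
  expect_equal(res2$best, res$best)
  expect_equal(sum(res2$bin_summary$n), nrow(lib))
})

test_that("germline FASTA round-trips with a sidecar type map", {
  g <- germline_reference()[1:5, ]
  fasta <- withr::local_tempfile(fileext = ".fasta")
  side <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste0(">", g$name, "\n", g$aa_seq), fasta)
  write.table(g[, c("name", "segment_type", "locus")], side, sep = "\t",
              quote = FALSE, row.names = FALSE)
  got <- read_germline_fasta(fasta, side)
  expect_equal(got$aa_seq, g$aa_seq)
  expect_equal(got$segment_type, g$segment_type)
})
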