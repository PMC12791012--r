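crafted_pairs <- function(concats) {
  n <- length(concats)
  heavy <- tibble::tibble(
    sequence_id = sprintf("h%03d", seq_len(n)), locus = "IGH",
    v_call = "IGHVs1", j_call = "IGHJs1",
    cdr3_aa = substr(concats, 1, nchar(concats) %/% 2),
    sequence_vdj_aa = concats, isotype = "IGHM", v_identity = 1,
    cell_id = sprintf("cc%03d", seq_len(n)), donor_id = "d1",
    productive = TRUE, read_count = 1L)
  light <- heavy
  light$sequence_id <- sprintf("l%03d", seq_len(n))
  light$locus <- "IGK"
  light$isotype <- "none"
  light$cdr3_aa <- substr(concats, nchar(concats) %/% 2 + 1,
                          nchar(concats))
  make_pairs(heavy, light, label = "cognate")
}

test_that("ungapped identity matches its definition on crafted strings", {
  expect_equal(ungapped_identity("CARDYW", "CARDYW"), 1)
  # best alignment of a shifted substring covers the shorter fully
  expect_equal(ungapped_identity("XXCARDYW", "CARDYW"), 1)
  expect_equal(ungapped_identity("CARDYW", "CARDFW"), 5 / 6)
  expect_error(ungapped_identity("", "A"), "empty")
  set.seed(71)
  aa <- aa_alphabet(with_x = FALSE)
  for (i in 1:40) {
    a <- paste(sample(aa, sample(5:18, 1), TRUE), collapse = "")
    b <- paste(sample(aa, sample(5:18, 1), TRUE), collapse = "")
    expect_equal(ungapped_identity(a, b), oracle_identity(a, b))
  }
})

test_that("identical and dissimilar CDR3 pairs cluster as expected", {
  pairs <- crafted_pairs(c("CARDYWCQQYNSYPLTF", "CARDYWCQQYNSYPLTF",
                           "CWWAGHMKVNEEIPRAG"))
  cl <- cluster_pairs(pairs, 0.90)
  expect_equal(cl$cluster_id[1], cl$cluster_id[2])
  expect_false(cl$cluster_id[3] == cl$cluster_id[1])
  expect_error(cluster_pairs(pairs, 0), "identity_threshold")
})

test_that("greedy clustering matches the brute-force oracle", {
  set.seed(42)
  aa <- aa_alphabet(with_x = FALSE)
  base <- replicate(12, paste(sample(aa, sample(16:24, 1), TRUE),
                              collapse = ""))
  # near-duplicates: single substitutions of base sequences
  mutate1 <- function(s) {
    i <- sample(nchar(s), 1)
    substr(s, i, i) <- sample(aa, 1)
    s
  }
  seqs <- c(base, vapply(sample(base, 25, TRUE), mutate1, character(1)),
            replicate(13, paste(sample(aa, sample(16:24, 1), TRUE),
                                collapse = "")))
  pairs <- crafted_pairs(seqs)
  got <- cluster_pairs(pairs, 0.90)
  want <- oracle_cluster(seqs, 0.90)
  # same partition up to label names
  expect_equal(length(unique(got$cluster_id)), length(unique(want)))
  expect_true(all(table(got$cluster_id, want) %in%
                    c(0, table(want)[unique(want)])))
  co_got <- outer(got$cluster_id, got$cluster_id, "==")
  co_want <- outer(want, want, "==")
  expect_identical(co_got, co_want)
})

test_that("balance_sample draws the requested depth per source", {
  rep <- sim_repertoire(400)
  pairs <- rep$pairs
  counts <- table(pairs$source_id)
  n_min <- min(counts)
  got <- balance_sample(pairs, n_min, seed = 5)
  expect_true(all(table(got$source_id) == n_min))
  expect_identical(got, balance_sample(pairs, n_min, seed = 5))
  expect_error(balance_sample(pairs, max(counts) + 1, seed = 5),
               "take_all")
  all_of_them <- balance_sample(pairs, max(counts) + 1, seed = 5,
                                take_all = TRUE)
  expect_equal(nrow(all_of_them), nrow(pairs))
})

test_that("cluster-unique sampling takes at most one pair per cluster", {
  fix <- sim_dataset(400, seed = 11)
  ds <- fix$dataset
  pos <- ds$pairs[ds$pairs$label == "cognate", ]
  cl <- ds$clusters
  got <- balance_sample(pos, 10, seed = 2, clusters = cl,
                        cluster_unique = TRUE)
  got_cl <- cl$cluster_id[match(got$pair_id, cl$pair_id)]
  expect_false(any(duplicated(got_cl)))
})

test_that("a minimal pair of positives swaps into a balanced dataset", {
  rep <- sim_repertoire(400)
  pos <- rep$pairs
  idx <- which(pos$light_locus == "IGK")
  key <- paste(pos$source_id[idx], nchar(pos$light_cdr3_aa[idx]))
  biggest <- names(sort(table(key), decreasing = TRUE))[1]
  two <- pos[idx[key == biggest][1:2], ]
  ds <- make_pseudo_negatives(two, seed = 1)
  expect_equal(nrow(ds$pairs), 4)
  neg <- ds$pairs[ds$pairs$label == "shuffled", ]
  expect_setequal(neg$heavy_sequence_id, two$heavy_sequence_id)
  # each shuffled pair carries the other positive's light chain
  expect_equal(
    neg$light_sequence_id[match(two$heavy_sequence_id[1],
                                neg$heavy_sequence_id)],
    two$light_sequence_id[2])
})

test_that("positives with unique CDRL3 lengths drop after max_trials", {
  rep <- sim_repertoire(400)
  pos <- rep$pairs[1:5, ]
  pos$source_id <- "d1"
  pos$light_locus <- "IGK"
  # force five distinct CDRL3 lengths
  for (i in 1:5) {
    pos$light_cdr3_aa[i] <- paste(rep("A", 6 + i), collapse = "")
    pos$light_sequence_vdj_aa[i] <- paste0("QQ", pos$light_cdr3_aa[i],
                                           "FG")
  }
  expect_error(make_pseudo_negatives(pos, max_trials = 250, seed = 2),
               "no pseudo-negatives")
  # observable drop bookkeeping via the error-free two-length case:
  # two matchable positives plus one unique-length positive
  pos3 <- pos[1:3, ]
  pos3$light_cdr3_aa[2] <- pos3$light_cdr3_aa[1]
  pos3$light_sequence_vdj_aa[2] <- paste0("QA", pos3$light_cdr3_aa[1],
                                          "FG")
  ds <- make_pseudo_negatives(pos3, max_trials = 250, seed = 2)
  expect_equal(sum(ds$pairs$label == "cognate"), 2)
  drop <- ds$provenance$dropped
  expect_equal(nrow(drop), 1)
  expect_equal(drop$pair_id, pos3$pair_id[3])
  expect_true(drop$reason %in% c("max_trials", "unpartnered_leftover"))
  if (drop$reason == "max_trials") expect_equal(drop$trials, 250L)
})

test_that("swaps recreating an observed positive are rejected", {
  rep <- sim_repertoire(400)
  base <- rep$pairs[1:2, ]
  base$source_id <- "d1"
  base$light_locus <- "IGK"
  base$light_cdr3_aa <- "CAAAYGSWF"
  base$light_sequence_vdj_aa <- paste0("QSVL", base$light_cdr3_aa, "GGG",
                                       1:2)
  # third positive: heavy of pair 1 with light of pair 2 already observed
  third <- base[1, ]
  third$pair_id <- "dup_pair"
  third[, paste0("light_", chain_fields())] <-
    base[2, paste0("light_", chain_fields())]
  pos <- dplyr::bind_rows(base, third)
  # every possible swap recreates an observed positive -> all dropped
  expect_error(make_pseudo_negatives(pos, max_trials = 50, seed = 3),
               "no pseudo-negatives")
})

test_that("pseudo-negative datasets satisfy the curation invariants", {
  fix <- sim_dataset(1200, seed = 11)
  ds <- fix$dataset
  pos <- ds$pairs[ds$pairs$label == "cognate", ]
  neg <- ds$pairs[ds$pairs$label == "shuffled", ]
  expect_equal(nrow(pos), nrow(neg))
  # CDRL3 length preservation: the swapped-in light matches the length of
  # the light it replaced (positives were curated within CDRL3 length)
  orig_len <- setNames(nchar(pos$light_cdr3_aa), pos$heavy_sequence_id)
  expect_true(all(nchar(neg$light_cdr3_aa) ==
                    orig_len[neg$heavy_sequence_id]))
  # no shuffled pair duplicates a positive by full sequences
  key <- function(p) paste(p$heavy_sequence_vdj_aa,
                           p$light_sequence_vdj_aa)
  expect_length(intersect(key(neg), key(pos)), 0)
  # swaps conserve light locus and source
  orig_locus <- setNames(pos$light_locus, pos$heavy_sequence_id)
  expect_true(all(neg$light_locus == orig_locus[neg$heavy_sequence_id]))
  # each positive donates its light chain at most once
  expect_false(any(duplicated(neg$light_sequence_id)))
  # reproducibility
  rep <- sim_repertoire(1200, seed = 11)
  again <- make_pseudo_negatives(rep$pairs, seed = 5)
  expect_identical(again$pairs, ds$pairs)
})

test_that("cluster-disjoint splits never share clusters", {
  fix <- sim_dataset(1200, seed = 11)
  split <- fix$split
  cl <- fix$dataset$clusters
  part_of <- split$partition[match(cl$pair_id, split$pair_id)]
  # brute force: every cluster maps to exactly one partition
  spans <- tapply(part_of, cl$cluster_id,
                  function(x) length(unique(x)))
  expect_true(all(spans == 1))
  frac <- mean(split$partition == "test")
  expect_lt(abs(frac - 0.10), 0.03)
  expect_identical(split, split_by_cluster(fix$dataset, seed = 3))
})

test_that("singleton clusters split 10 test / 9 per fold", {
  concats <- replicate(100, paste(sample(aa_alphabet(FALSE), 30, TRUE),
                                  collapse = ""))
  pairs <- crafted_pairs(concats)
  ds <- structure(list(pairs = pairs, clusters = NULL,
                       provenance = list()), class = "pair_dataset")
  ds$pairs$label <- "cognate"
  ds <- attach_clusters(ds)
  expect_equal(length(unique(ds$clusters$cluster_id)), 100)
  split <- split_by_cluster(ds, test_fraction = 0.1, k_folds = 10,
                            seed = 1)
  expect_equal(sum(split$partition == "test"), 10)
  expect_true(all(table(split$partition[split$partition != "test"]) == 9))
  expect_error(split_by_cluster(ds, k_folds = 100, seed = 1), "clusters")
})
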