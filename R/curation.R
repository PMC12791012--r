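# Dataset curation: CDR3 clustering, per-source balancing, pseudo-negative
# simulation and cluster-disjoint train/test splitting.

#' Ungapped sequence identity over the shorter sequence
#'
#' Identity between two sequences defined as the number of exactly matching
#' positions in the best ungapped alignment (all relative offsets of the
#' two strings are considered), divided by the length of the shorter
#' sequence. This mirrors the greedy clustering convention of CD-HIT-style
#' tools.
#'
#' @param a,b Non-empty character strings.
#' @return Identity in `[0, 1]`.
#' @export
ungapped_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  na <- length(ca); nb <- length(cb)
  if (na == 0 || nb == 0) stop("empty sequence", call. = FALSE)
  best <- 0L
  for (off in seq(-(nb - 1L), na - 1L)) {
    ia <- max(1L, 1L + off):min(na, nb + off)
    ib <- ia - off
    m <- sum(ca[ia] == cb[ib])
    if (m > best) best <- m
  }
  best / min(na, nb)
}

# letter-composition upper bound on ungapped match count, used to skip
# exact comparisons that cannot reach the identity threshold
composition_counts <- function(seqs) {
  aa <- aa_alphabet()
  t(vapply(strsplit(seqs, ""), function(ch) {
    tabulate(match(ch, aa), nbins = length(aa))
  }, integer(length(aa))))
}

#' Greedy identity clustering of concatenated CDR3 pairs
#'
#' Clusters pairs on their concatenated CDRH3+CDRL3 strings, the segments
#' that define clonotype identity. Sequences are sorted by length
#' descending (ties lexicographic); each sequence joins the first existing
#' cluster whose representative reaches the identity threshold under
#' [ungapped_identity()], otherwise it founds a new cluster. Greedy
#' longest-first clustering with cluster representatives follows the
#' CD-HIT convention; the word-filter heuristics of that tool are replaced
#' by an exact composition bound, appropriate at desk scale.
#'
#' @param pairs A pair table with non-empty CDR3s.
#' @param identity_threshold Identity threshold in `(0, 1]` (default 0.90).
#' @return A `cluster_assignment` object: tibble with `pair_id`,
#'   `cluster_id`, plus a `representatives` attribute mapping cluster to
#'   its founding pair.
#' @export
cluster_pairs <- function(pairs, identity_threshold = 0.90) {
  if (identity_threshold <= 0 || identity_threshold > 1) {
    stop("identity_threshold must lie in (0, 1]", call. = FALSE)
  }
  concat <- paste0(pairs$heavy_cdr3_aa, pairs$light_cdr3_aa)
  if (any(pairs$heavy_cdr3_aa == "") || any(pairs$light_cdr3_aa == "")) {
    stop("all pairs must have non-empty CDR3s", call. = FALSE)
  }
  ord <- order(-nchar(concat), concat)
  n <- length(concat)
  comp <- composition_counts(concat)
  lens <- nchar(concat)
  cluster_of <- integer(n)
  rep_idx <- integer(0)      # original indices of representatives
  rep_comp <- NULL           # their composition rows
  for (i in ord) {
    assigned <- 0L
    if (length(rep_idx) > 0) {
      # bound: matches <= sum_a min(count_a(s), count_a(rep))
      bound <- colSums(pmin(t(rep_comp), comp[i, ]))
      need <- identity_threshold * pmin(lens[rep_idx], lens[i])
      for (k in which(bound >= need)) {
        if (ungapped_identity(concat[i], concat[rep_idx[k]]) >=
            identity_threshold) {
          assigned <- k
          break
        }
      }
    }
    if (assigned == 0L) {
      rep_idx <- c(rep_idx, i)
      rep_comp <- rbind(rep_comp, comp[i, , drop = FALSE])
      assigned <- length(rep_idx)
    }
    cluster_of[i] <- assigned
  }
  out <- tibble::tibble(pair_id = pairs$pair_id,
                        cluster_id = sprintf("cluster_%04d", cluster_of))
  attr(out, "representatives") <-
    setNames(pairs$pair_id[rep_idx],
             sprintf("cluster_%04d", seq_along(rep_idx)))
  class(out) <- c("cluster_assignment", class(out))
  out
}

#' Sample an equal number of pairs from every source
#'
#' Draws exactly `n_per_source` pairs (without replacement) from each
#' `source_id`, removing biases stemming from unequal dataset sizes.
#'
#' @param pairs A pair table.
#' @param n_per_source Pairs to draw per source.
#' @param seed Integer seed.
#' @param take_all Take all pairs of a source smaller than `n_per_source`
#'   instead of raising an error.
#' @param clusters Optional [cluster_pairs()] result; when supplied with
#'   `cluster_unique = TRUE`, at most one pair is sampled per cluster.
#' @param cluster_unique Enforce at most one sampled pair per cluster.
#' @return The sampled pair table.
#' @export
balance_sample <- function(pairs, n_per_source, seed, take_all = FALSE,
                           clusters = NULL, cluster_unique = FALSE) {
  if (cluster_unique && is.null(clusters)) {
    stop("cluster_unique requires a cluster assignment", call. = FALSE)
  }
  with_local_seed(seed, {
    keep <- integer(0)
    for (src in sort(unique(pairs$source_id))) {
      idx <- which(pairs$source_id == src)
      if (cluster_unique) {
        cl <- clusters$cluster_id[match(pairs$pair_id[idx],
                                        clusters$pair_id)]
        idx <- idx[!duplicated(cl[sample(length(cl))])]
      }
      if (length(idx) < n_per_source && !take_all) {
        stop("source '", src, "' has only ", length(idx),
             " pairs; needs ", n_per_source,
             " (set take_all = TRUE to keep them all)", call. = FALSE)
      }
      n_take <- min(n_per_source, length(idx))
      keep <- c(keep, sort(sample(idx, n_take)))
    }
    pairs[keep, ]
  })
}

# hash key identifying a pair by its full chain sequences
pair_key <- function(heavy_seq, light_seq) paste(heavy_seq, light_seq,
                                                 sep = "|")

#' Simulate pseudo-negative pairs by light-chain exchange
#'
#' Builds a balanced labeled dataset from cognate pairs: repeatedly selects
#' two positives with identical CDRL3 lengths and exchanges their light
#' chains, yielding two `shuffled` pairs. A candidate identical to any
#' observed positive (by full heavy+light variable-domain sequences) is
#' rejected and redrawn. A positive that fails to exchange its light chain
#' within `max_trials` consecutive draws is removed from the positive pool.
#' Each positive donates its light chain at most once, so the final dataset
#' is exactly balanced between cognate and shuffled pairs.
#'
#' @param positives Pair table of cognate pairs.
#' @param max_trials Consecutive failed draws before a positive is dropped
#'   (default 250).
#' @param seed Integer seed.
#' @param within_locus Restrict exchanges to the same light-chain locus
#'   (kappa with kappa, lambda with lambda).
#' @param within_source Restrict exchanges to the same `source_id`.
#' @return A `pair_dataset`: list with `pairs` (balanced cognate +
#'   shuffled), `clusters` (`NULL` until [attach_clusters()]) and
#'   `provenance` (seed, constraint flags, drop log).
#' @export
make_pseudo_negatives <- function(positives, max_trials = 250, seed = 1,
                                  within_locus = TRUE, within_source = TRUE) {
  stopifnot(all(positives$label == "cognate"))
  n <- nrow(positives)
  if (n < 2) stop("need at least two positives", call. = FALSE)
  len_l <- nchar(positives$light_cdr3_aa)
  pos_keys <- new.env(hash = TRUE, parent = emptyenv())
  for (k in pair_key(positives$heavy_sequence_vdj_aa,
                     positives$light_sequence_vdj_aa)) {
    assign(k, TRUE, envir = pos_keys)
  }
  with_local_seed(seed, {
    in_pool <- rep(TRUE, n)
    swapped_with <- rep(NA_integer_, n)
    dropped <- integer(0)
    drop_trials <- integer(0)
    while (sum(in_pool) >= 2) {
      pool <- which(in_pool)
      focal <- pool[sample.int(length(pool), 1)]
      others <- pool[pool != focal]
      trials <- 0L
      repeat {
        trials <- trials + 1L
        partner <- others[sample.int(length(others), 1)]
        ok <- len_l[focal] == len_l[partner] &&
          (!within_locus ||
             positives$light_locus[focal] == positives$light_locus[partner]) &&
          (!within_source ||
             positives$source_id[focal] == positives$source_id[partner])
        if (ok) {
          k1 <- pair_key(positives$heavy_sequence_vdj_aa[focal],
                         positives$light_sequence_vdj_aa[partner])
          k2 <- pair_key(positives$heavy_sequence_vdj_aa[partner],
                         positives$light_sequence_vdj_aa[focal])
          ok <- !exists(k1, envir = pos_keys, inherits = FALSE) &&
            !exists(k2, envir = pos_keys, inherits = FALSE)
        }
        if (ok) {
          swapped_with[focal] <- partner
          swapped_with[partner] <- focal
          in_pool[c(focal, partner)] <- FALSE
          break
        }
        if (trials >= max_trials) {
          in_pool[focal] <- FALSE
          dropped <- c(dropped, focal)
          drop_trials <- c(drop_trials, trials)
          break
        }
      }
    }
    leftover <- which(in_pool)
    done <- which(!is.na(swapped_with))
    if (length(done) == 0) {
      stop("no pseudo-negatives could be generated: no two positives ",
           "share a CDRL3 length under the active constraints",
           call. = FALSE)
    }
    keep_pos <- positives[done, ]
    light_cols <- paste0("light_", chain_fields())
    negatives <- keep_pos
    negatives[, light_cols] <- positives[swapped_with[done], light_cols]
    negatives$label <- "shuffled"
    negatives$pair_id <- paste0(keep_pos$pair_id, "_x",
                                positives$pair_id[swapped_with[done]])
    dataset <- dplyr::bind_rows(keep_pos, negatives)
    structure(list(
      pairs = dataset, clusters = NULL,
      provenance = list(
        seed = seed, max_trials = max_trials,
        within_locus = within_locus, within_source = within_source,
        n_positives_in = n, n_positives_kept = length(done),
        dropped = tibble::tibble(
          pair_id = positives$pair_id[c(dropped, leftover)],
          reason = c(rep("max_trials", length(dropped)),
                     rep("unpartnered_leftover", length(leftover))),
          trials = c(drop_trials, rep(0L, length(leftover)))))),
      class = "pair_dataset")
  })
}

#' Attach a cluster assignment to a labeled dataset
#'
#' Positives take their own cluster; a shuffled pair inherits the cluster
#' of the positive that donated its heavy chain, so that a positive and
#' every negative derived from its heavy chain always travel together in
#' splits.
#'
#' @param dataset A `pair_dataset` from [make_pseudo_negatives()].
#' @param clusters A [cluster_pairs()] result computed on the positives
#'   (if omitted, it is computed here at the default threshold).
#' @param identity_threshold Threshold used when computing clusters.
#' @return The dataset with `clusters` populated for every pair.
#' @export
attach_clusters <- function(dataset, clusters = NULL,
                            identity_threshold = 0.90) {
  stopifnot(inherits(dataset, "pair_dataset"))
  pos <- dataset$pairs[dataset$pairs$label == "cognate", ]
  if (is.null(clusters)) {
    clusters <- cluster_pairs(pos, identity_threshold)
  }
  by_heavy <- setNames(
    clusters$cluster_id[match(pos$pair_id, clusters$pair_id)],
    pos$heavy_sequence_id)
  cl <- ifelse(dataset$pairs$label == "cognate",
               clusters$cluster_id[match(dataset$pairs$pair_id,
                                         clusters$pair_id)],
               by_heavy[dataset$pairs$heavy_sequence_id])
  dataset$clusters <- tibble::tibble(pair_id = dataset$pairs$pair_id,
                                     cluster_id = unname(cl))
  dataset
}

#' Cluster-disjoint train/test and fold assignment
#'
#' Randomly assigns whole clusters (never individual pairs) to the test
#' partition until it reaches the target fraction, then deals the
#' remaining clusters round-robin into `k_folds` training folds. No
#' cluster ever spans two partitions, preventing clonotype leakage between
#' training and evaluation data.
#'
#' @param dataset A `pair_dataset` with clusters attached.
#' @param test_fraction Target fraction of pairs in the test partition.
#' @param k_folds Number of training folds.
#' @param seed Integer seed.
#' @return A tibble `pair_id`, `partition` with partition values `test`,
#'   `fold_01` ... `fold_<k>`.
#' @export
split_by_cluster <- function(dataset, test_fraction = 0.10, k_folds = 10,
                             seed = 1) {
  stopifnot(inherits(dataset, "pair_dataset"))
  if (is.null(dataset$clusters)) {
    stop("dataset has no cluster assignment; call attach_clusters() first",
         call. = FALSE)
  }
  cl <- dataset$clusters
  sizes <- table(cl$cluster_id)
  if (length(sizes) < k_folds + 1) {
    stop("need more clusters (", length(sizes), ") than k_folds + 1 (",
         k_folds + 1, ")", call. = FALSE)
  }
  with_local_seed(seed, {
    ids <- sample(names(sizes))
    n_total <- nrow(cl)
    target <- test_fraction * n_total
    cum <- cumsum(as.numeric(sizes[ids]))
    n_test <- which(cum >= target)[1]
    test_ids <- ids[seq_len(n_test)]
    rest <- ids[-seq_len(n_test)]
    fold_of <- setNames(rep_len(seq_len(k_folds), length(rest)), rest)
    partition <- ifelse(cl$cluster_id %in% test_ids, "test",
                        sprintf("fold_%02d", fold_of[cl$cluster_id]))
    frac <- mean(partition == "test")
    if (abs(frac - test_fraction) > max(sizes) / n_total) {
      warning(sprintf(
        "test fraction %.3f deviates from target %.2f (dominant cluster)",
        frac, test_fraction))
    }
    tibble::tibble(pair_id = cl$pair_id, partition = partition)
  })
}
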