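# Independent brute-force oracles shared across test files. These are
# deliberately written in the most literal style possible and never call
# the package's own implementations.

oracle_confusion <- function(labels, scores, threshold) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(labels)) {
    pred <- scores[i] >= threshold
    if (pred && labels[i] == 1) tp <- tp + 1L
    else if (pred && labels[i] == 0) fp <- fp + 1L
    else if (!pred && labels[i] == 0) tn <- tn + 1L
    else fn <- fn + 1L
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

# exhaustive pair counting over all positive x negative score pairs,
# ties contributing one half
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

oracle_metrics <- function(labels, scores, threshold = 0.5) {
  oc <- oracle_confusion(labels, scores, threshold)
  n <- length(labels)
  prec <- if (oc$tp + oc$fp == 0) NA_real_ else oc$tp / (oc$tp + oc$fp)
  rec <- if (oc$tp + oc$fn == 0) NA_real_ else oc$tp / (oc$tp + oc$fn)
  den <- sqrt(oc$tp + oc$fp) * sqrt(oc$tp + oc$fn) *
    sqrt(oc$tn + oc$fp) * sqrt(oc$tn + oc$fn)
  list(accuracy = (oc$tp + oc$tn) / n,
       precision = prec, recall = rec,
       f1 = if (is.na(prec) || is.na(rec) || prec + rec == 0) NA_real_
       else 2 * prec * rec / (prec + rec),
       mcc = if (den == 0) NA_real_ else
         (oc$tp * oc$tn - oc$fp * oc$fn) / den,
       auc = oracle_auc(labels, scores))
}

# ungapped best-offset identity by direct double loop
oracle_identity <- function(a, b) {
  ca <- utf8ToInt(a); cb <- utf8ToInt(b)
  best <- 0
  for (shift in -(length(cb) - 1):(length(ca) - 1)) {
    m <- 0
    for (i in seq_along(ca)) {
      j <- i - shift
      if (j >= 1 && j <= length(cb) && ca[i] == cb[j]) m <- m + 1
    }
    best <- max(best, m)
  }
  best / min(length(ca), length(cb))
}

# greedy longest-first clustering using the oracle identity
oracle_cluster <- function(seqs, threshold) {
  ord <- order(-nchar(seqs), seqs)
  reps <- integer(0)
  assignment <- integer(length(seqs))
  for (i in ord) {
    placed <- FALSE
    for (k in seq_along(reps)) {
      if (oracle_identity(seqs[i], seqs[reps[k]]) >= threshold) {
        assignment[i] <- k
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      assignment[i] <- length(reps)
    }
  }
  assignment
}

# hand-built eight-sample cancer clone table covering every filter rule
cancer_fixture <- function() {
  row <- function(sample, locus, count, frac, seq = "QVQLVQSG",
                  in_frame = TRUE) {
    tibble::tibble(sample_id = sample, locus = locus, read_count = count,
                   read_fraction = frac, vdj_aa = seq,
                   in_frame = in_frame)
  }
  dplyr::bind_rows(
    # s1: clean kappa line
    row("s1", "IGH", 5000, 0.9), row("s1", "IGH", 300, 0.1, "QVELVQSG"),
    row("s1", "IGK", 10000, 1.0), row("s1", "IGL", 50, 1.0),
    # s2: T cell contamination
    row("s2", "TR", 150, 1.0), row("s2", "IGH", 4000, 1.0),
    row("s2", "IGK", 3000, 1.0),
    # s3: too few immunoglobulin reads
    row("s3", "IGH", 40, 0.6), row("s3", "IGK", 30, 0.4),
    # s4: light chains only
    row("s4", "IGK", 9000, 1.0),
    # s5: ambiguous light locus (ratio 1.5)
    row("s5", "IGH", 2000, 1.0), row("s5", "IGK", 300, 1.0),
    row("s5", "IGL", 200, 1.0),
    # s6: clean lambda line
    row("s6", "IGH", 1500, 1.0), row("s6", "IGL", 2000, 1.0),
    # s7: top light clone out of frame
    row("s7", "IGH", 3000, 1.0), row("s7", "IGK", 5000, 0.7, "QSVL*TP",
                                     in_frame = FALSE),
    row("s7", "IGK", 100, 0.3),
    # s8: borderline TR reads just under the cutoff
    row("s8", "TR", 99, 1.0), row("s8", "IGH", 800, 1.0),
    row("s8", "IGK", 900, 1.0))
}
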