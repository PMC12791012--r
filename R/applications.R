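# Downstream procedures: maturation annotation with reshuffled controls,
# spatial candidate ranking, cancer clone-table filtering, and germline
# CDRH3-grafting library screens.

score_with <- function(scorer, pairs, ...) {
  if (inherits(scorer, "routed_scorer")) route_and_score(scorer, pairs, ...)
  else score_pairs(scorer, pairs, ...)
}

#' Score a repertoire and summarise pairing scores by group
#'
#' Routes and scores every pair, then summarises the pairing-score
#' distribution per group: by heavy-chain isotype (class-switch status),
#' by bins of heavy-chain germline identity (somatic hypermutation proxy),
#' by donor, or by an arbitrary column.
#'
#' @param pairs A pair table carrying the grouping fields.
#' @param scorer A `routed_scorer` (or plain `pair_scorer`).
#' @param grouping `"isotype"`, `"v_identity"`, `"donor"`, or the name of
#'   any column of `pairs`.
#' @param bins Number of equal-width germline-identity bins (used when
#'   `grouping = "v_identity"`).
#' @return List with `pairs` (input plus `pairing_score`) and `summary`
#'   (per group: n, mean, median, quartiles).
#' @export
annotate_repertoire <- function(pairs, scorer, grouping = "isotype",
                                bins = 10) {
  pairs$pairing_score <- as.numeric(score_with(scorer, pairs))
  group <- switch(grouping,
    isotype = pairs$heavy_isotype,
    donor = pairs$heavy_donor_id,
    v_identity = {
      id <- pairs$heavy_v_identity
      brk <- seq(min(id), max(id), length.out = bins + 1)
      as.character(cut(id, breaks = unique(brk), include.lowest = TRUE))
    },
    {
      if (!grouping %in% names(pairs)) {
        stop("grouping field '", grouping, "' not present in pairs",
             call. = FALSE)
      }
      as.character(pairs[[grouping]])
    })
  summary <- pairs |>
    dplyr::mutate(.group = group) |>
    dplyr::group_by(.data$.group) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$pairing_score),
      median = median(.data$pairing_score),
      q25 = quantile(.data$pairing_score, 0.25),
      q75 = quantile(.data$pairing_score, 0.75),
      .groups = "drop") |>
    dplyr::rename(group = ".group")
  list(pairs = pairs, summary = summary)
}

# seeded derangement: permutation without fixed points (fixed points are
# repaired by swapping with a neighbour)
derangement <- function(n) {
  if (n < 2) stop("need at least two elements", call. = FALSE)
  perm <- sample.int(n)
  for (i in seq_len(n)) {
    if (perm[i] == i) {
      j <- if (i < n) i + 1L else 1L
      tmp <- perm[i]; perm[i] <- perm[j]; perm[j] <- tmp
    }
  }
  perm
}

#' Reshuffled light-chain control scores
#'
#' Retains every observed heavy chain but pairs it with a randomly
#' reshuffled light-chain partner (a derangement, so no pair keeps its own
#' light chain), then scores the reshuffled pairs with the same scorer as
#' the observed pairs. Serves as the null distribution for repertoire
#' annotation.
#'
#' @param pairs A pair table (at least two pairs).
#' @param scorer A `routed_scorer` or `pair_scorer`.
#' @param seed Integer seed.
#' @return Numeric vector of control scores (aligned with `pairs` rows);
#'   the permutation used is attached as attribute `permutation`.
#' @export
reshuffled_control <- function(pairs, scorer, seed = 1) {
  n <- nrow(pairs)
  if (n < 2) stop("need at least two pairs to reshuffle", call. = FALSE)
  with_local_seed(seed, {
    perm <- derangement(n)
    shuffled <- pairs
    light_cols <- paste0("light_", chain_fields())
    shuffled[, light_cols] <- pairs[perm, light_cols]
    shuffled$label <- "unlabeled"
    scores <- as.numeric(score_with(scorer, shuffled))
    attr(scores, "permutation") <- perm
    scores
  })
}

#' Filter cancer cell-line clone tables to one H-L pair per sample
#'
#' Applies, in order: (1) drop samples with at least `tcr_max` reads mapped
#' to T cell receptor loci; (2) drop samples with fewer than `ig_min` total
#' immunoglobulin reads; (3) drop samples without any heavy-chain reads;
#' (4) assign the light-chain locus only when one light locus has at least
#' `ratio_min` times the reads of the other (else drop as ambiguous);
#' (5) keep the clone with the highest read fraction per retained locus and
#' drop the sample if a selected clone is out of frame. Emits at most one
#' heavy + light clone pair per sample; reapplying the filter to its own
#' output is a no-op.
#'
#' @param records Clone table: `sample_id`, `locus`
#'   (`IGH`/`IGK`/`IGL`/`TR`), `read_count`, `read_fraction`, `vdj_aa`,
#'   `in_frame`.
#' @param tcr_max,ig_min,ratio_min Filter thresholds (defaults 100, 100,
#'   100).
#' @return List with `selected` (tibble: sample_id, light locus, heavy and
#'   light clone fields) and `drop_log` (tibble: sample_id, rule that
#'   fired).
#' @export
filter_cancer_clonesets <- function(records, tcr_max = 100, ig_min = 100,
                                    ratio_min = 100) {
  stopifnot(all(c("sample_id", "locus", "read_count", "read_fraction",
                  "vdj_aa", "in_frame") %in% names(records)))
  selected <- list()
  dropped <- list()
  for (s in unique(records$sample_id)) {
    rows <- records[records$sample_id == s, ]
    drop <- function(rule) tibble::tibble(sample_id = s, rule = rule)
    tr_reads <- sum(rows$read_count[rows$locus == "TR"])
    ig_reads <- sum(rows$read_count[rows$locus %in% c("IGH", "IGK", "IGL")])
    igh_reads <- sum(rows$read_count[rows$locus == "IGH"])
    igk_reads <- sum(rows$read_count[rows$locus == "IGK"])
    igl_reads <- sum(rows$read_count[rows$locus == "IGL"])
    if (tr_reads >= tcr_max) { dropped[[s]] <- drop("tcr_reads"); next }
    if (ig_reads < ig_min) { dropped[[s]] <- drop("few_ig_reads"); next }
    if (igh_reads == 0) { dropped[[s]] <- drop("no_heavy_reads"); next }
    light_locus <- if (igk_reads > 0 &&
                       (igl_reads == 0 || igk_reads / igl_reads >= ratio_min))
      "IGK"
    else if (igl_reads > 0 &&
             (igk_reads == 0 || igl_reads / igk_reads >= ratio_min))
      "IGL"
    else NA_character_
    if (is.na(light_locus)) {
      dropped[[s]] <- drop(if (igk_reads + igl_reads == 0) "no_light_reads"
                           else "ambiguous_light_locus")
      next
    }
    top_clone <- function(locus) {
      cand <- rows[rows$locus == locus, ]
      cand[order(-cand$read_fraction, -cand$read_count), ][1, ]
    }
    h <- top_clone("IGH")
    l <- top_clone(light_locus)
    if (!h$in_frame || !l$in_frame) {
      dropped[[s]] <- drop("out_of_frame")
      next
    }
    selected[[s]] <- tibble::tibble(
      sample_id = s, light_locus = light_locus,
      heavy_vdj_aa = h$vdj_aa, heavy_read_fraction = h$read_fraction,
      light_vdj_aa = l$vdj_aa, light_read_fraction = l$read_fraction)
  }
  list(selected = if (length(selected)) dplyr::bind_rows(selected) else
         tibble::tibble(sample_id = character(), light_locus = character(),
                        heavy_vdj_aa = character(),
                        heavy_read_fraction = numeric(),
                        light_vdj_aa = character(),
                        light_read_fraction = numeric()),
       drop_log = if (length(dropped)) dplyr::bind_rows(dropped) else
         tibble::tibble(sample_id = character(), rule = character()))
}

#' Rank spatial H-L candidate pairs
#'
#' Flags a candidate as a predicted cognate pair when its pairing score
#' reaches `pairing_threshold` and, when a colocalization score column and
#' threshold are supplied, its colocalization score reaches
#' `colocalization_threshold` as well. Candidates are returned sorted by
#' (predicted, pairing score) descending. When a logical truth column
#' `confirmed` is present (e.g. pairs confirmed by parallel single-cell
#' sequencing), a 2x2 agreement table is attached.
#'
#' @param candidates Tibble with at least `pairing_score`; optionally
#'   `colocalization_score` and `confirmed`.
#' @param pairing_threshold Pairing-score decision threshold (default 0.5).
#' @param colocalization_threshold Optional colocalization threshold.
#' @return The ranked tibble with a `predicted` column; agreement table
#'   (when truth is available) as attribute `agreement`.
#' @export
rank_spatial_candidates <- function(candidates, pairing_threshold = 0.5,
                                    colocalization_threshold = NULL) {
  predicted <- candidates$pairing_score >= pairing_threshold
  if (!is.null(colocalization_threshold)) {
    if (!"colocalization_score" %in% names(candidates)) {
      stop("colocalization_threshold given but candidates lack a ",
           "colocalization_score column", call. = FALSE)
    }
    predicted <- predicted &
      candidates$colocalization_score >= colocalization_threshold
  }
  out <- candidates
  out$predicted <- predicted
  out <- out[order(-out$predicted, -out$pairing_score), ]
  if ("confirmed" %in% names(candidates)) {
    attr(out, "agreement") <- table(
      predicted = factor(out$predicted, levels = c(TRUE, FALSE)),
      confirmed = factor(out$confirmed, levels = c(TRUE, FALSE)))
  }
  out
}

#' Read germline V/J segments from FASTA with a segment-type sidecar
#'
#' Headers are segment names; `segment_type` comes from a sidecar TSV
#' (columns `name`, `segment_type`, optional `locus`) or, if absent, from a
#' `|V` / `|J` suffix in the header.
#'
#' @param fasta_path Amino-acid FASTA of segments.
#' @param sidecar_path Optional TSV mapping name to segment type.
#' @return A germline segment tibble (`name`, `segment_type`, `locus`,
#'   `aa_seq`).
#' @export
read_germline_fasta <- function(fasta_path, sidecar_path = NULL) {
  lines <- readLines(fasta_path)
  headers <- grep("^>", lines)
  if (length(headers) == 0) stop("no FASTA records", call. = FALSE)
  ends <- c(headers[-1] - 1L, length(lines))
  name <- sub("^>\\s*", "", lines[headers])
  seqs <- vapply(seq_along(headers), function(i) {
    paste(lines[(headers[i] + 1L):ends[i]], collapse = "")
  }, character(1))
  seg <- tibble::tibble(name = name, aa_seq = toupper(gsub("\\s", "", seqs)))
  if (!is.null(sidecar_path)) {
    side <- read.delim(sidecar_path, sep = "\t", colClasses = "character")
    seg$segment_type <- side$segment_type[match(seg$name, side$name)]
    seg$locus <- if ("locus" %in% names(side))
      side$locus[match(seg$name, side$name)] else NA_character_
  } else {
    parts <- strsplit(seg$name, "|", fixed = TRUE)
    seg$segment_type <- vapply(parts, function(p) p[length(p)],
                               character(1))
    seg$name <- vapply(parts, function(p) p[1], character(1))
    seg$locus <- NA_character_
  }
  if (!all(seg$segment_type %in% c("V", "J"))) {
    stop("segment_type must be V or J for every segment", call. = FALSE)
  }
  seg[, c("name", "segment_type", "locus", "aa_seq")]
}

#' Build a CDRH3-grafted germline recombination library
#'
#' Grafts an observed CDRH3 onto every combination of germline heavy V and
#' J segments: each candidate VH is `V + CDRH3 + J`. Candidates are ordered
#' by V name, then J name.
#'
#' @param cdrh3 Observed CDRH3 amino-acid sequence (non-empty).
#' @param v_segments,j_segments Germline segment tibbles (or character
#'   vectors named by segment) of unique V / J segments.
#' @return Tibble of `|V| x |J|` candidates: `v_name`, `j_name`, `vh_seq`.
#' @export
build_graft_library <- function(cdrh3, v_segments, j_segments) {
  as_seg <- function(x, what) {
    if (is.data.frame(x)) {
      out <- setNames(x$aa_seq, x$name)
    } else out <- x
    if (length(out) == 0) stop("empty ", what, " segment list",
                               call. = FALSE)
    if (anyDuplicated(names(out))) {
      stop("duplicate ", what, " segment names", call. = FALSE)
    }
    out
  }
  if (!nzchar(cdrh3)) stop("empty CDRH3", call. = FALSE)
  v <- as_seg(v_segments, "V")
  j <- as_seg(j_segments, "J")
  v <- v[order(names(v))]
  j <- j[order(names(j))]
  grid <- expand.grid(j_name = names(j), v_name = names(v),
                      stringsAsFactors = FALSE)[, c("v_name", "j_name")]
  grid <- grid[order(grid$v_name, grid$j_name), ]
  tibble::tibble(v_name = grid$v_name, j_name = grid$j_name,
                 vh_seq = paste0(v[grid$v_name], cdrh3, j[grid$j_name]))
}

#' Global-alignment sequence identity
#'
#' Needleman-Wunsch global alignment with match score 1, mismatch 0 and
#' linear gap penalty -1 (traceback ties resolved toward the diagonal);
#' identity is the fraction of alignment columns with identical residues.
#' Symmetric in its arguments.
#'
#' @param seq_a,seq_b Non-empty amino-acid strings.
#' @return Identity in `[0, 1]`.
#' @export
pairwise_identity <- function(seq_a, seq_b) {
  a <- strsplit(seq_a, "")[[1]]
  b <- strsplit(seq_b, "")[[1]]
  n <- length(a); m <- length(b)
  if (n == 0 || m == 0) stop("empty sequence", call. = FALSE)
  gap <- -1
  score <- matrix(0, n + 1, m + 1)
  score[1, ] <- gap * (0:m)
  score[, 1] <- gap * (0:n)
  for (i in seq_len(n)) {
    match_row <- score[i, 1:m] + (a[i] == b)
    up_col <- score[i, 2:(m + 1)] + gap
    prev <- score[i + 1, 1]
    for (jj in seq_len(m)) {
      best <- max(match_row[jj], up_col[jj], prev + gap)
      score[i + 1, jj + 1] <- best
      prev <- best
    }
  }
  # traceback, preferring diagonal moves on ties
  i <- n; jj <- m
  matches <- 0L
  cols <- 0L
  while (i > 0 || jj > 0) {
    cols <- cols + 1L
    if (i > 0 && jj > 0 &&
        score[i + 1, jj + 1] == score[i, jj] + (a[i] == b[jj])) {
      matches <- matches + (a[i] == b[jj])
      i <- i - 1L; jj <- jj - 1L
    } else if (i > 0 && score[i + 1, jj + 1] == score[i, jj + 1] + gap) {
      i <- i - 1L
    } else {
      jj <- jj - 1L
    }
  }
  matches / cols
}

#' Screen a grafted library against the observed light chain
#'
#' Scores every grafted VH candidate against the wild-type antibody's
#' observed light chain (routed by the observed light locus), computes each
#' candidate's global-alignment identity to the wild-type VH, and reports
#' the best-scoring candidate (ties broken by higher identity, then V/J
#' names), the absolute score gap between the best candidate and the
#' wild-type pair, and score-gap summaries in identity bins.
#'
#' @param wild_type One-row pair table: the observed antibody.
#' @param library A [build_graft_library()] tibble.
#' @param scorer A `routed_scorer` or `pair_scorer`.
#' @param cdrh3 The grafted CDRH3 (defaults to the wild type's CDRH3).
#' @param exclude_cdrh3 Compute identity on the VH with the CDRH3 segment
#'   removed.
#' @param bin_width Identity bin width (default 0.1).
#' @return List with `library` (scored, with `identity_to_wt` and
#'   `score_gap_to_wt`), `best` (one row), `wt_score`, and `bin_summary`.
#' @export
screen_library <- function(wild_type, library, scorer, cdrh3 = NULL,
                           exclude_cdrh3 = FALSE, bin_width = 0.1) {
  stopifnot(nrow(wild_type) == 1)
  if (is.null(cdrh3)) cdrh3 <- wild_type$heavy_cdr3_aa
  if (!all(grepl(cdrh3, library$vh_seq, fixed = TRUE))) {
    stop("library candidates must contain the grafted CDRH3 verbatim",
         call. = FALSE)
  }
  wt_score <- as.numeric(score_with(scorer, wild_type))
  n <- nrow(library)
  cand_heavy <- wild_type[rep(1, n), paste0("heavy_", chain_fields())]
  names(cand_heavy) <- chain_fields()
  cand_heavy$sequence_id <- paste0("graft_", library$v_name, "_",
                                   library$j_name)
  cand_heavy$v_call <- library$v_name
  cand_heavy$j_call <- library$j_name
  cand_heavy$cdr3_aa <- cdrh3
  cand_heavy$sequence_vdj_aa <- library$vh_seq
  cand_heavy$v_identity <- 1
  cand_light <- wild_type[rep(1, n), paste0("light_", chain_fields())]
  names(cand_light) <- chain_fields()
  cand_pairs <- make_pairs(cand_heavy, cand_light, label = "unlabeled",
                           pair_id = cand_heavy$sequence_id,
                           source_id = wild_type$source_id)
  scores <- as.numeric(score_with(scorer, cand_pairs))
  strip <- function(s) if (exclude_cdrh3) sub(cdrh3, "", s, fixed = TRUE)
    else s
  wt_vh <- strip(wild_type$heavy_sequence_vdj_aa)
  identity <- vapply(strip(library$vh_seq), pairwise_identity,
                     numeric(1), seq_b = wt_vh, USE.NAMES = FALSE)
  out <- library
  out$pairing_score <- scores
  out$identity_to_wt <- identity
  out$score_gap_to_wt <- abs(scores - wt_score)
  ord <- order(-out$pairing_score, -out$identity_to_wt, out$v_name,
               out$j_name)
  best <- out[ord[1], ]
  brk <- seq(0, 1, by = bin_width)
  bins <- cut(out$identity_to_wt, breaks = brk, include.lowest = TRUE)
  bin_summary <- out |>
    dplyr::mutate(identity_bin = bins) |>
    dplyr::group_by(.data$identity_bin, .drop = TRUE) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_score_gap = mean(.data$score_gap_to_wt),
                     median_score_gap = median(.data$score_gap_to_wt),
                     .groups = "drop")
  list(library = out, best = best, wt_score = wt_score,
       bin_summary = bin_summary)
}
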