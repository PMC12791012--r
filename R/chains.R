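#' @importFrom rlang .data
#' @importFrom stats predict quantile median rbinom runif setNames wilcox.test
#' @importFrom utils head read.delim write.table
NULL

#' Amino-acid alphabet used throughout the package
#'
#' The 20 canonical amino acids in alphabetical one-letter order, optionally
#' followed by `"X"` for unknown residues. This fixed ordering defines the
#' column layout of all one-hot encodings.
#'
#' @param with_x Include the `"X"` unknown symbol as the last letter.
#' @return Character vector of single-letter residue codes.
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function(with_x = TRUE) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  if (with_x) c(aa, "X") else aa
}

#' Column names of a chain record table
#'
#' One row per annotated immunoglobulin chain. `locus` is one of `IGH`,
#' `IGK`, `IGL`; `cdr3_aa` must occur as a contiguous substring of
#' `sequence_vdj_aa`; `isotype` is `"none"` except for heavy chains;
#' `v_identity` is the germline identity of the V region as a fraction.
#'
#' @return Character vector of required column names.
#' @export
chain_fields <- function() {
  c("sequence_id", "locus", "v_call", "j_call", "cdr3_aa",
    "sequence_vdj_aa", "isotype", "v_identity", "cell_id", "donor_id",
    "productive", "read_count")
}

valid_loci <- c("IGH", "IGK", "IGL")
valid_isotypes <- c("IGHM", "IGHD", "IGHG", "IGHA", "IGHE", "none")

#' Validate a chain record table
#'
#' Checks the structural invariants of a chain table: required columns,
#' legal locus and isotype values, residue alphabet, CDR3 containment in the
#' full variable-domain sequence, and `v_identity` within `[0, 1]`.
#'
#' @param chains A data frame of chain records (see [chain_fields()]).
#' @return `chains`, invisibly, after passing all checks.
#' @export
validate_chains <- function(chains) {
  missing_cols <- setdiff(chain_fields(), names(chains))
  if (length(missing_cols) > 0) {
    stop("chain table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_locus <- !chains$locus %in% valid_loci
  if (any(bad_locus)) {
    stop("invalid locus value(s) at row(s) ",
         paste(head(which(bad_locus), 5), collapse = ", "), call. = FALSE)
  }
  if (any(!chains$isotype %in% valid_isotypes)) {
    stop("invalid isotype value(s)", call. = FALSE)
  }
  if (any(chains$isotype != "none" & chains$locus != "IGH")) {
    stop("light chains must carry isotype 'none'", call. = FALSE)
  }
  ok_id <- is.na(chains$v_identity) |
    (chains$v_identity >= 0 & chains$v_identity <= 1)
  if (!all(ok_id)) stop("v_identity outside [0, 1]", call. = FALSE)
  pattern <- paste0("^[", paste(aa_alphabet(), collapse = ""), "]*$")
  if (!all(grepl(pattern, chains$cdr3_aa)) ||
      !all(grepl(pattern, chains$sequence_vdj_aa))) {
    stop("sequences contain letters outside the 20 canonical residues + X",
         call. = FALSE)
  }
  n <- nrow(chains)
  if (n > 0) {
    contained <- mapply(grepl, chains$cdr3_aa, chains$sequence_vdj_aa,
                        MoreArgs = list(fixed = TRUE))
    if (!all(contained)) {
      stop("cdr3_aa not found within sequence_vdj_aa for ",
           sum(!contained), " record(s)", call. = FALSE)
    }
  }
  invisible(chains)
}

# fixed column order of a flat pair table: pair metadata, then every chain
# field prefixed heavy_/light_
pair_fields <- function() {
  c("pair_id", "label", "pairing_score", "source_id",
    paste0("heavy_", chain_fields()), paste0("light_", chain_fields()))
}

valid_labels <- c("cognate", "shuffled", "unlabeled")

#' Combine heavy and light chain tables into a pair table
#'
#' Builds the flat pair representation used across the package: one row per
#' heavy-light pair, with all chain fields prefixed `heavy_` / `light_`.
#'
#' @param heavy,light Chain tables of equal row count; row `i` of `heavy` is
#'   paired with row `i` of `light`.
#' @param label Pair label, one of `"cognate"`, `"shuffled"`, `"unlabeled"`
#'   (recycled).
#' @param pair_id Optional pair identifiers; defaults to `pair_<i>`.
#' @param source_id Dataset/donor of origin; defaults to the heavy chain's
#'   `donor_id`.
#' @return A tibble with the columns of [pair_fields()].
#' @export
make_pairs <- function(heavy, light, label = "unlabeled", pair_id = NULL,
                       source_id = NULL) {
  stopifnot(nrow(heavy) == nrow(light))
  n <- nrow(heavy)
  if (is.null(pair_id)) pair_id <- sprintf("pair_%d", seq_len(n))
  if (is.null(source_id)) source_id <- heavy$donor_id
  if (n > 0 && any(heavy$locus != "IGH")) {
    stop("heavy slot must contain IGH chains", call. = FALSE)
  }
  if (n > 0 && any(!light$locus %in% c("IGK", "IGL"))) {
    stop("light slot must contain IGK or IGL chains", call. = FALSE)
  }
  label <- rep_len(label, n)
  if (n > 0 && !all(label %in% valid_labels)) {
    stop("label must be cognate, shuffled or unlabeled", call. = FALSE)
  }
  bad <- label == "cognate" & heavy$cell_id != light$cell_id
  if (n > 0 && any(bad)) {
    stop("cognate pairs must share a cell_id", call. = FALSE)
  }
  h <- heavy[, chain_fields()]
  l <- light[, chain_fields()]
  names(h) <- paste0("heavy_", names(h))
  names(l) <- paste0("light_", names(l))
  out <- tibble::tibble(pair_id = pair_id, label = label,
                        pairing_score = NA_real_,
                        source_id = source_id)
  out <- dplyr::bind_cols(out, h, l)
  out[, pair_fields()]
}

#' Numeric labels of a labeled pair table
#'
#' @param pairs A pair table with labels in `{cognate, shuffled}`.
#' @return Integer vector: 1 for cognate, 0 for shuffled.
#' @export
pair_labels <- function(pairs) {
  if (any(pairs$label == "unlabeled")) {
    stop("pair table contains unlabeled pairs", call. = FALSE)
  }
  as.integer(pairs$label == "cognate")
}

# strip allele suffix ("*01") from a gene call
strip_allele <- function(calls) sub("\\*.*$", "", calls)
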