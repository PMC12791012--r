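#' Default AIRR rearrangement column mapping
#'
#' Maps package chain-record fields to AIRR-C rearrangement column names.
#' `cdr3_aa` falls back to `junction_aa` (with conserved flanking residues
#' stripped) when no `cdr3_aa` column is present; `isotype` falls back to
#' `c_call`. Override entries to adapt to AIRR dialects.
#'
#' @return Named list: chain field -> AIRR column name.
#' @export
airr_column_map <- function() {
  list(sequence_id = "sequence_id", locus = "locus", v_call = "v_call",
       j_call = "j_call", cdr3_aa = "cdr3_aa", junction_aa = "junction_aa",
       sequence_vdj_aa = "sequence_alignment_aa", isotype = "c_call",
       v_identity = "v_identity", cell_id = "cell_id",
       donor_id = "donor_id", productive = "productive",
       read_count = "consensus_count")
}

as_logical_airr <- function(x) {
  if (is.logical(x)) return(x)
  tolower(as.character(x)) %in% c("t", "true", "1", "yes", "y")
}

#' Read an AIRR rearrangement TSV into a chain table
#'
#' Reads a tab-separated AIRR-C rearrangement file (header row required) and
#' returns one chain record per retained row. Rows are dropped (and counted
#' in the attached `read_log` attribute) when they are non-productive (if
#' `require_productive`), have an empty CDR3 or variable-domain sequence, or
#' carry more than `max_x_frac` unknown (`X`) residues. When only a
#' `junction_aa` column is available, the CDR3 is derived by stripping the
#' first and last (conserved anchor) residues. `v_identity` given in percent
#' is normalised to a fraction.
#'
#' @param path Path to the TSV file.
#' @param require_productive Drop rows whose productive flag is false.
#' @param column_map Column mapping, see [airr_column_map()].
#' @param max_x_frac Maximum tolerated fraction of `X` residues in the
#'   variable-domain sequence.
#' @return A tibble of chain records with a `read_log` attribute
#'   summarising drop counts.
#' @export
read_airr <- function(path, require_productive = TRUE,
                      column_map = airr_column_map(), max_x_frac = 0.1) {
  raw <- read.delim(path, sep = "\t", header = TRUE,
                    colClasses = "character", check.names = FALSE,
                    na.strings = NULL)
  need <- c("sequence_id", "locus", "v_call", "j_call", "sequence_vdj_aa",
            "cell_id", "productive")
  for (field in need) {
    if (!column_map[[field]] %in% names(raw)) {
      stop("AIRR file is missing required column '", column_map[[field]],
           "' (field ", field, ")", call. = FALSE)
    }
  }
  has_cdr3 <- column_map$cdr3_aa %in% names(raw)
  has_junction <- !is.null(column_map$junction_aa) &&
    column_map$junction_aa %in% names(raw)
  if (!has_cdr3 && !has_junction) {
    stop("AIRR file must contain a '", column_map$cdr3_aa, "' or '",
         column_map$junction_aa, "' column", call. = FALSE)
  }
  n_in <- nrow(raw)
  grab <- function(field, default) {
    col <- column_map[[field]]
    if (!is.null(col) && col %in% names(raw)) raw[[col]] else
      rep(default, n_in)
  }
  cdr3 <- if (has_cdr3) raw[[column_map$cdr3_aa]] else {
    junction <- raw[[column_map$junction_aa]]
    ifelse(nchar(junction) >= 2,
           substr(junction, 2, nchar(junction) - 1), "")
  }
  v_identity <- suppressWarnings(as.numeric(grab("v_identity", NA)))
  # percent-scale identities normalised to fractions
  v_identity <- ifelse(!is.na(v_identity) & v_identity > 1,
                       v_identity / 100, v_identity)
  chains <- tibble::tibble(
    sequence_id = raw[[column_map$sequence_id]],
    locus = toupper(raw[[column_map$locus]]),
    v_call = raw[[column_map$v_call]],
    j_call = raw[[column_map$j_call]],
    cdr3_aa = cdr3,
    sequence_vdj_aa = raw[[column_map$sequence_vdj_aa]],
    isotype = grab("isotype", "none"),
    v_identity = v_identity,
    cell_id = raw[[column_map$cell_id]],
    donor_id = grab("donor_id", "unknown"),
    productive = as_logical_airr(raw[[column_map$productive]]),
    read_count = {
      rc <- suppressWarnings(as.integer(grab("read_count", 1L)))
      ifelse(is.na(rc), 1L, rc)
    }
  )
  chains$isotype[chains$locus != "IGH" | chains$isotype == "" |
                   is.na(chains$isotype)] <- "none"
  bad_locus <- !chains$locus %in% valid_loci
  if (any(bad_locus)) {
    stop("unparseable locus value '", chains$locus[which(bad_locus)[1]],
         "' at row ", which(bad_locus)[1], call. = FALSE)
  }
  nonproductive <- if (require_productive) !chains$productive else
    rep(FALSE, n_in)
  empty_seq <- chains$cdr3_aa == "" | chains$sequence_vdj_aa == ""
  x_frac <- ifelse(nchar(chains$sequence_vdj_aa) > 0,
                   stringr::str_count(chains$sequence_vdj_aa, "X") /
                     nchar(chains$sequence_vdj_aa), 1)
  too_many_x <- !empty_seq & x_frac > max_x_frac
  keep <- !(nonproductive | empty_seq | too_many_x)
  out <- chains[keep, ]
  log <- list(n_read = n_in, n_kept = sum(keep),
              n_nonproductive = sum(nonproductive),
              n_empty_sequence = sum(empty_seq & !nonproductive),
              n_excess_x = sum(too_many_x & !nonproductive))
  if (log$n_kept < n_in) {
    message(sprintf(
      "read_airr: kept %d/%d records (%d non-productive, %d empty, %d >%d%% X)",
      log$n_kept, n_in, log$n_nonproductive, log$n_empty_sequence,
      log$n_excess_x, round(100 * max_x_frac)))
  }
  validate_chains(out)
  attr(out, "read_log") <- log
  out
}

#' Write a chain table as an AIRR rearrangement TSV
#'
#' Inverse of [read_airr()] under the default column mapping.
#'
#' @param chains A chain table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_airr <- function(chains, path) {
  validate_chains(chains)
  out <- data.frame(
    sequence_id = chains$sequence_id, locus = chains$locus,
    v_call = chains$v_call, j_call = chains$j_call,
    cdr3_aa = chains$cdr3_aa,
    sequence_alignment_aa = chains$sequence_vdj_aa,
    c_call = chains$isotype,
    v_identity = format_num(chains$v_identity),
    cell_id = chains$cell_id, donor_id = chains$donor_id,
    productive = ifelse(chains$productive, "T", "F"),
    consensus_count = chains$read_count,
    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble heavy-light pairs from per-cell chain records
#'
#' Groups chains by cell barcode and emits heavy-light pairs. Under
#' `strict_singlet`, only cells with exactly one productive heavy (IGH) and
#' exactly one productive light (IGK/IGL) chain yield a pair, labeled
#' `cognate`; under `all_combinations`, every heavy x light combination
#' within a cell yields a pair labeled `unlabeled`. Output order is
#' deterministic (cell barcode, then sequence identifiers).
#'
#' @param records A chain table.
#' @param policy `"strict_singlet"` or `"all_combinations"`.
#' @return A pair table (see [make_pairs()]); counts of contributing and
#'   skipped cells are attached as the `assembly_log` attribute.
#' @export
assemble_pairs <- function(records,
                           policy = c("strict_singlet", "all_combinations")) {
  policy <- match.arg(policy)
  validate_chains(records)
  recs <- records[order(records$cell_id, records$sequence_id), ]
  heavy <- recs[recs$locus == "IGH" & recs$productive, ]
  light <- recs[recs$locus %in% c("IGK", "IGL") & recs$productive, ]
  cells <- sort(unique(recs$cell_id))
  h_split <- split(seq_len(nrow(heavy)), heavy$cell_id)
  l_split <- split(seq_len(nrow(light)), light$cell_id)
  h_idx <- integer(0)
  l_idx <- integer(0)
  n_skipped <- 0L
  for (cell in cells) {
    hi <- h_split[[cell]]
    li <- l_split[[cell]]
    if (is.null(hi) || is.null(li)) { n_skipped <- n_skipped + 1L; next }
    if (policy == "strict_singlet") {
      if (length(hi) == 1 && length(li) == 1) {
        h_idx <- c(h_idx, hi); l_idx <- c(l_idx, li)
      } else n_skipped <- n_skipped + 1L
    } else {
      grid <- expand.grid(l = li, h = hi)
      grid <- grid[order(grid$h, grid$l), ]
      h_idx <- c(h_idx, grid$h); l_idx <- c(l_idx, grid$l)
    }
  }
  label <- if (policy == "strict_singlet") "cognate" else "unlabeled"
  out <- make_pairs(heavy[h_idx, ], light[l_idx, ], label = label,
                    pair_id = sprintf("%s:%s", heavy$cell_id[h_idx],
                                      seq_along(h_idx)))
  attr(out, "assembly_log") <- list(n_cells = length(cells),
                                    n_pairs = nrow(out),
                                    n_cells_skipped = n_skipped)
  out
}

# full-precision numeric formatting so TSV round-trips are lossless
format_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.17g", v)
  }, character(1))
  out
}

#' Write a pair table to a flat TSV
#'
#' One pair per row; all fields of both chains prefixed `heavy_`/`light_`,
#' plus `pair_id`, `label`, `pairing_score` and `source_id`. Numeric fields
#' are written at full precision so that [read_pairs()] reproduces the table
#' exactly; a missing pairing score round-trips to `NA`.
#'
#' @param pairs A pair table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  out <- as.data.frame(pairs[, pair_fields()])
  for (col in c("pairing_score", "heavy_v_identity", "light_v_identity")) {
    out[[col]] <- format_num(out[[col]])
  }
  for (col in c("heavy_productive", "light_productive")) {
    out[[col]] <- ifelse(out[[col]], "T", "F")
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pair table written by [write_pairs()]
#'
#' @param path Path to a pair TSV.
#' @return A tibble of pairs.
#' @export
read_pairs <- function(path) {
  raw <- read.delim(path, sep = "\t", header = TRUE,
                    colClasses = "character", check.names = FALSE,
                    na.strings = NULL)
  missing_cols <- setdiff(pair_fields(), names(raw))
  if (length(missing_cols) > 0) {
    stop("pair file missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- tibble::as_tibble(raw[, pair_fields()])
  for (col in c("pairing_score", "heavy_v_identity", "light_v_identity")) {
    out[[col]] <- suppressWarnings(as.numeric(ifelse(out[[col]] == "",
                                                     NA, out[[col]])))
  }
  for (col in c("heavy_productive", "light_productive")) {
    out[[col]] <- as_logical_airr(out[[col]])
  }
  for (col in c("heavy_read_count", "light_read_count")) {
    out[[col]] <- as.integer(out[[col]])
  }
  out
}
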