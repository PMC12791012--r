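# Model-ready encodings: gene-usage indicator vectors and CDR3 one-hot
# matrices.

#' Build a gene-usage vocabulary from training pairs
#'
#' Records the heavy V, heavy J, light V and light J gene names observed in
#' the training pairs, in first-seen order. Allele-level calls (e.g.
#' `IGHV1-69*01`) are normalised to gene level by stripping the `*` suffix
#' before entry.
#'
#' @param pairs A pair table.
#' @return A `gene_vocabulary` object: list with components `heavy_v`,
#'   `heavy_j`, `light_v`, `light_j`.
#' @export
build_vocabulary <- function(pairs) {
  if (nrow(pairs) == 0) stop("no training pairs", call. = FALSE)
  vocab <- list(heavy_v = unique(strip_allele(pairs$heavy_v_call)),
                heavy_j = unique(strip_allele(pairs$heavy_j_call)),
                light_v = unique(strip_allele(pairs$light_v_call)),
                light_j = unique(strip_allele(pairs$light_j_call)))
  structure(vocab, class = "gene_vocabulary")
}

#' Persist / reload a gene vocabulary as JSON
#'
#' @param vocab A `gene_vocabulary`.
#' @param path JSON file path.
#' @return `write_vocabulary`: `path` invisibly; `read_vocabulary`: the
#'   vocabulary.
#' @export
write_vocabulary <- function(vocab, path) {
  jsonlite::write_json(unclass(vocab), path, pretty = TRUE)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(raw[c("heavy_v", "heavy_j", "light_v", "light_j")],
            class = "gene_vocabulary")
}

#' One-hot encode V/J gene usage of pairs
#'
#' Each pair becomes the concatenation of four indicator blocks (heavy V,
#' heavy J, light V, light J) over the vocabulary. An out-of-vocabulary
#' gene encodes as an all-zero block; such events are counted in the
#' `oov_count` attribute.
#'
#' @param pairs A pair table.
#' @param vocab A [build_vocabulary()] result.
#' @return Numeric matrix (pairs x total vocabulary size) with attributes
#'   `pair_ids`, `scheme = "gene_usage"` and `vocab`.
#' @export
encode_gene_usage <- function(pairs, vocab) {
  stopifnot(inherits(vocab, "gene_vocabulary"))
  blocks <- list(heavy_v = strip_allele(pairs$heavy_v_call),
                 heavy_j = strip_allele(pairs$heavy_j_call),
                 light_v = strip_allele(pairs$light_v_call),
                 light_j = strip_allele(pairs$light_j_call))
  n <- nrow(pairs)
  oov <- 0L
  cols <- lapply(names(blocks), function(b) {
    m <- matrix(0, nrow = n, ncol = length(vocab[[b]]),
                dimnames = list(NULL, paste0(b, ":", vocab[[b]])))
    hit <- match(blocks[[b]], vocab[[b]])
    oov <<- oov + sum(is.na(hit))
    found <- which(!is.na(hit))
    m[cbind(found, hit[found])] <- 1
    m
  })
  out <- do.call(cbind, cols)
  if (oov > 0) {
    message("encode_gene_usage: ", oov, " out-of-vocabulary gene call(s)")
  }
  attr(out, "pair_ids") <- pairs$pair_id
  attr(out, "scheme") <- "gene_usage"
  attr(out, "vocab") <- vocab
  attr(out, "oov_count") <- oov
  out
}

# one CDR3 string -> max_len x 21 one-hot matrix (rows past the sequence
# stay zero)
onehot_matrix <- function(seq, max_len, alphabet) {
  m <- matrix(0, nrow = max_len, ncol = length(alphabet))
  chars <- strsplit(seq, "")[[1]]
  idx <- match(chars, alphabet)
  m[cbind(seq_along(idx), idx)] <- 1
  m
}

#' One-hot encode CDR3 sequences of pairs
#'
#' CDRH3 and CDRL3 are separately encoded as `max_len x 21` matrices: rows
#' are positions (right-padded with all-zero rows), columns the 20
#' canonical amino acids in alphabetical order followed by `X` as column
#' 21.
#'
#' @param pairs A pair table.
#' @param max_len_heavy,max_len_light Padded lengths; must accommodate the
#'   longest CDR3 unless `truncate = TRUE`.
#' @param truncate Truncate CDR3s longer than the padded length instead of
#'   raising an error.
#' @return List with 3-D arrays `heavy` and `light`
#'   (`pairs x max_len x 21`), integer vectors `len_heavy`/`len_light`, and
#'   attributes `pair_ids`, `scheme = "cdr3_onehot"`.
#' @export
encode_cdr3_onehot <- function(pairs, max_len_heavy = 22L,
                               max_len_light = 14L, truncate = FALSE) {
  alphabet <- aa_alphabet()
  enc_side <- function(seqs, max_len, side) {
    lens <- nchar(seqs)
    if (any(lens > max_len)) {
      if (!truncate) {
        stop(side, " CDR3 longer than max_len (", max(lens), " > ",
             max_len, "); raise max_len or set truncate = TRUE",
             call. = FALSE)
      }
      seqs <- substr(seqs, 1, max_len)
      lens <- nchar(seqs)
    }
    arr <- array(0, dim = c(length(seqs), max_len, length(alphabet)))
    for (i in seq_along(seqs)) {
      arr[i, , ] <- onehot_matrix(seqs[i], max_len, alphabet)
    }
    list(arr = arr, lens = lens)
  }
  h <- enc_side(pairs$heavy_cdr3_aa, max_len_heavy, "heavy")
  l <- enc_side(pairs$light_cdr3_aa, max_len_light, "light")
  out <- list(heavy = h$arr, light = l$arr,
              len_heavy = h$lens, len_light = l$lens)
  attr(out, "pair_ids") <- pairs$pair_id
  attr(out, "scheme") <- "cdr3_onehot"
  attr(out, "max_len") <- c(heavy = max_len_heavy, light = max_len_light)
  out
}
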