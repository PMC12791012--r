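# Shared fixtures, built in code at test time.

# hand-built chain table: 2 cells, one complete, one heavy-only
toy_chains <- function() {
  tibble::tibble(
    sequence_id = c("c1_H", "c1_K", "c2_H"),
    locus = c("IGH", "IGK", "IGH"),
    v_call = c("IGHV1-69*01", "IGKV1-5*02", "IGHV3-23*01"),
    j_call = c("IGHJ4*02", "IGKJ2*01", "IGHJ6*01"),
    cdr3_aa = c("CARDYW", "CQQYNSYPLTF", "CTTVDW"),
    sequence_vdj_aa = c("EVQLVCARDYWGQG", "DIQMTCQQYNSYPLTFGQ",
                        "QVQLVCTTVDWGKG"),
    isotype = c("IGHM", "none", "IGHG"),
    v_identity = c(0.98, 1, 0.91),
    cell_id = c("cell1", "cell1", "cell2"),
    donor_id = "donorA",
    productive = TRUE,
    read_count = 1L)
}

# deterministic small simulated repertoire (memoised per n_cells/seed so
# expensive fixtures are built once per test run)
.fixture_cache <- new.env(parent = emptyenv())

sim_repertoire <- function(n_cells = 400, seed = 11) {
  key <- paste0("rep_", n_cells, "_", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <-
      generate_repertoire(synthetic_config(seed = seed, n_cells = n_cells))
  }
  .fixture_cache[[key]]
}

# standard curated, clustered, split dataset used across model tests
sim_dataset <- function(n_cells = 1200, seed = 11) {
  key <- paste0("ds_", n_cells, "_", seed)
  if (is.null(.fixture_cache[[key]])) {
    rep <- sim_repertoire(n_cells, seed)
    ds <- attach_clusters(make_pseudo_negatives(rep$pairs, seed = 5))
    split <- split_by_cluster(ds, seed = 3)
    part <- split$partition[match(ds$pairs$pair_id, split$pair_id)]
    .fixture_cache[[key]] <- list(
      config = synthetic_config(seed = seed, n_cells = n_cells),
      dataset = ds, split = split,
      train = ds$pairs[part != "test", ],
      test = ds$pairs[part == "test", ])
  }
  .fixture_cache[[key]]
}

# constant-score external scorer
constant_scorer <- function(value = 0.7) {
  load_external_scorer(function(heavy, light) rep(value, length(heavy)))
}

# scorer that looks pairing scores up from the planted compatibility rule
# (squashed to [0, 1]); deterministic and sequence-addressed, so it can be
# built from any pair table without training
oracle_scorer <- function(pairs, config) {
  lookup <- new.env(hash = TRUE, parent = emptyenv())
  store <- function(p) {
    sc <- stats::plogis(pair_compatibility(p, config))
    keys <- paste(p$heavy_sequence_vdj_aa, p$light_sequence_vdj_aa,
                  sep = "|")
    for (i in seq_along(keys)) assign(keys[i], sc[i], envir = lookup)
  }
  store(pairs)
  load_external_scorer(function(heavy, light) {
    vapply(paste(heavy, light, sep = "|"), function(k) {
      if (exists(k, envir = lookup, inherits = FALSE))
        get(k, envir = lookup) else 0.5
    }, numeric(1), USE.NAMES = FALSE)
  })
}

# write a chain table as an AIRR TSV in a temp file
write_airr_fixture <- function(chains, productive_flags = NULL) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  if (!is.null(productive_flags)) chains$productive <- productive_flags
  write_airr(chains, path)
  path
}
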