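# Shared fixtures and independent oracles. The default community and the
# all-vs-all region table are expensive, so they are built lazily once per
# session and reused across test files.

.fixture_env <- new.env(parent = emptyenv())

default_comm <- function() {
  if (is.null(.fixture_env$comm)) {
    .fixture_env$comm <- simulate_community(seed = 1L)
  }
  .fixture_env$comm
}

default_hosts <- function() {
  if (is.null(.fixture_env$hosts)) {
    .fixture_env$hosts <- community_host_seqs(default_comm())
  }
  .fixture_env$hosts
}

# region tables for every virus against the full host db (computed once)
default_regions <- function() {
  if (is.null(.fixture_env$regions)) {
    comm <- default_comm()
    hosts <- default_hosts()
    scheme <- scoring_scheme()
    .fixture_env$regions <- lapply(
      setNames(names(comm$viruses), names(comm$viruses)),
      function(v) phagehost:::regions_vs_db(comm$viruses[[v]], hosts,
                                            scheme, virus_id = v))
  }
  .fixture_env$regions
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# independent string-level reverse complement (no package internals)
oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# naive per-window canonicalizing 4-mer counter: every window is mapped to
# min(window, revcomp(window)) via a lookup built from string operations
oracle_canonical_counts <- function(s) {
  if (is.null(.fixture_env$canon_map)) {
    b <- c("A", "C", "G", "T")
    all4 <- as.vector(outer(as.vector(outer(
      as.vector(outer(b, b, paste0)), b, paste0)), b, paste0))
    all4 <- sort(all4)
    .fixture_env$canon_map <- setNames(
      pmin(all4, vapply(all4, oracle_revcomp, character(1))), all4)
    .fixture_env$canon_levels <- sort(unique(.fixture_env$canon_map))
  }
  n <- nchar(s)
  win <- substring(s, 1:(n - 3), 4:n)
  win <- win[!grepl("[^ACGT]", win)]
  tab <- table(factor(.fixture_env$canon_map[win],
                      levels = .fixture_env$canon_levels))
  as.vector(tab)
}

# random lineage tables whose labels embed their full path, so the oracle
# LCA is the last shared element of the root-to-leaf label paths
random_lineage_table <- function(n_strains, max_depth = 7L) {
  ranks <- c("phylum", "class", "order", "family", "genus", "species")
  rows <- lapply(seq_len(n_strains), function(i) {
    path <- character(0)
    lab <- paste0("p", sample.int(3L, 1L))
    vals <- character(length(ranks))
    depth <- sample.int(min(max_depth - 1L, length(ranks)), 1L)
    for (j in seq_len(length(ranks))) {
      if (j <= depth) {
        lab <- if (j == 1L) lab else paste0(lab, ".", sample.int(2L, 1L))
        vals[j] <- lab
      } else {
        vals[j] <- ""
      }
    }
    c(strain_id = paste0("s", i), setNames(vals, ranks))
  })
  as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
}

# brute-force LCA on such a table: intersect full label paths
oracle_lca <- function(tab, strains) {
  paths <- lapply(strains, function(s) {
    row <- tab[tab$strain_id == s, , drop = FALSE]
    vals <- unlist(row[1, -1])
    c(vals[nzchar(vals)], s)
  })
  common <- Reduce(function(a, b) {
    k <- 0L
    while (k < min(length(a), length(b)) && a[k + 1L] == b[k + 1L]) {
      k <- k + 1L
    }
    if (k == 0L) character(0) else a[seq_len(k)]
  }, paths)
  if (length(common) == 0L) "Root" else unname(common[length(common)])
}

# naive O(n^2) scan for the longest direct terminal repeat
oracle_terminal_repeat <- function(s, min_len = 35L, max_scan = 1000L) {
  L <- nchar(s)
  best <- 0L
  for (k in seq_len(min(max_scan, L %/% 2L))) {
    if (substr(s, 1L, k) == substr(s, L - k + 1L, L)) best <- k
  }
  if (best >= min_len) best else 0L
}

# Hamming identity of two equal-length strings
oracle_identity <- function(a, b) {
  mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
}

# small single-genus taxonomy for unit tests
toy_lineage <- function() {
  data.frame(
    strain_id = c("PsA", "PsB", "AcA", "AcB", "BaA"),
    phylum = c("Proteobacteria", "Proteobacteria", "Proteobacteria",
               "Proteobacteria", "Firmicutes"),
    class = c("Gammaproteobacteria", "Gammaproteobacteria",
              "Betaproteobacteria", "Betaproteobacteria", "Bacilli"),
    order = c("Pseudomonadales", "Pseudomonadales", "Burkholderiales",
              "Burkholderiales", "Bacillales"),
    family = c("Pseudomonadaceae", "Pseudomonadaceae", "Comamonadaceae",
               "Comamonadaceae", "Bacillaceae"),
    genus = c("Pseudomonas", "Pseudomonas", "Acidovorax", "Acidovorax",
              "Bacillus"),
    species = c("Pseudomonas_sp1", "Pseudomonas_sp2", "Acidovorax_sp1",
                "Acidovorax_sp2", "Bacillus_sp1"),
    stringsAsFactors = FALSE)
}

# minimal domtblout writer for annotation fixtures
write_domtblout <- function(rows, path) {
  lines <- c("# --- full sequence --- -------------- this domain --------",
             "# target name accession tlen query ...")
  for (r in rows) {
    lines <- c(lines, paste(
      r$target, r$acc, 120, r$query, "-", 200,
      format(r$evalue_full %||% r$evalue, scientific = TRUE), r$score_full %||% r$score, 0.1,
      1, 1, format(r$cevalue %||% r$evalue, scientific = TRUE),
      format(r$evalue, scientific = TRUE), r$score, 0.1,
      1, 118, 5, 190, 4, 195, 0.95, r$desc))
  }
  writeLines(lines, path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a
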