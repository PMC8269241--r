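# Curation of protein-domain annotations on viral contigs. Domain hits
# (produced externally by an HMM search against Pfam and consumed here in
# the per-domain tabular "domtblout" dialect) are filtered on bit score and
# E-value and sorted into functional categories -- in particular the
# manually curated metal-resistance and antibiotic-resistance classes of
# auxiliary metabolic genes (AMGs) -- via an ordered, user-extensible
# keyword table.

#' Read per-domain HMM search results (domtblout dialect)
#'
#' Parses the whitespace-delimited per-domain table: `#` comment lines are
#' ignored; malformed (truncated) lines are skipped with a warning. The
#' per-domain independent E-value and per-domain bit score are used. The
#' query name is taken as the protein id; a `virus_id` is derived by
#' stripping a trailing `_p<digits>` protein suffix when present.
#'
#' @param path Path to a domtblout file.
#' @return data.frame of hits: `virus_id`, `protein_id`, `target_name`,
#'   `target_accession`, `description`, `bit_score`, `e_value`.
#' @export
read_domain_hits <- function(path) {
  if (!file.exists(path)) stop("cannot read domain table: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  rows <- list()
  for (ln in lines) {
    f <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(f) < 23L || is.na(suppressWarnings(as.numeric(f[13L]))) ||
        is.na(suppressWarnings(as.numeric(f[14L])))) {
      warning("skipping malformed domtblout line: ",
              substr(ln, 1L, 60L), call. = FALSE)
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      virus_id = sub("_p\\d+$", "", f[4L]), protein_id = f[4L],
      target_name = f[1L], target_accession = f[2L],
      description = paste(f[23:length(f)], collapse = " "),
      bit_score = as.numeric(f[14L]), e_value = as.numeric(f[13L]),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(virus_id = character(0), protein_id = character(0),
                      target_name = character(0),
                      target_accession = character(0),
                      description = character(0), bit_score = numeric(0),
                      e_value = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Filter domain hits on bit score and E-value
#'
#' Keeps hits with `bit_score >= min_bit` and `e_value <= max_e`
#' (defaults 30 and 1e-3).
#'
#' @param hits data.frame from [read_domain_hits()].
#' @param min_bit,max_e Thresholds.
#' @return Filtered data.frame.
#' @export
filter_hits <- function(hits, min_bit = 30, max_e = 1e-3) {
  hits[hits$bit_score >= min_bit & hits$e_value <= max_e, , drop = FALSE]
}

#' Load a curation rule table
#'
#' Rules are (category, pattern, priority) rows; patterns are
#' case-insensitive substrings matched against a hit's target name or
#' description, and the first matching rule (by ascending priority, then
#' file order) wins. The shipped default table covers the curated AMG
#' classes -- copper resistance, multiresistance beta-lactamase,
#' AcrB/AcrD/AcrF efflux pumps, streptomycin adenylyltransferase,
#' toxin-antitoxin systems -- ahead of generic phage-hallmark and
#' metabolism classes; unmatched hits fall through to "not_categorized".
#'
#' @param path TSV with columns category, pattern, priority; default the
#'   table shipped with the package.
#' @return data.frame of rules ordered by priority.
#' @export
load_curation_rules <- function(path = system.file(
    "extdata", "amg_curation_rules.tsv", package = "phagehost")) {
  rules <- read.delim(path, sep = "\t", header = TRUE,
                      colClasses = c("character", "character", "integer"))
  stopifnot(all(c("category", "pattern", "priority") %in% names(rules)))
  rules[order(rules$priority), , drop = FALSE]
}

#' Categorize domain hits with a curation rule table
#'
#' @param hits data.frame of (filtered) domain hits.
#' @param rules data.frame from [load_curation_rules()].
#' @return `hits` with a `category` column appended; the per-category
#'   counts (a partition of the input rows) are attached as attribute
#'   `category_counts`.
#' @export
categorize <- function(hits, rules = load_curation_rules()) {
  cat_of <- function(i) {
    hay <- tolower(paste(hits$target_name[i], hits$description[i]))
    for (j in seq_len(nrow(rules))) {
      if (grepl(tolower(rules$pattern[j]), hay, fixed = TRUE)) {
        return(rules$category[j])
      }
    }
    "not_categorized"
  }
  hits$category <- if (nrow(hits)) vapply(seq_len(nrow(hits)), cat_of,
                                          character(1)) else character(0)
  counts <- table(factor(hits$category,
                         levels = unique(c(rules$category,
                                           "not_categorized"))))
  attr(hits, "category_counts") <- counts
  hits
}

#' Per-virus category count matrix
#'
#' @param categorized data.frame from [categorize()].
#' @return data.frame: one row per virus, one column per category.
#' @export
category_matrix <- function(categorized) {
  tab <- table(categorized$virus_id, categorized$category)
  as.data.frame.matrix(tab)
}
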