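# Canonical tetranucleotide (4-mer) composition profiles and the
# mean-absolute-error distance d between them. Of the 256 4-mers, 16 are
# reverse-complement palindromes, leaving (256 - 16) / 2 + 16 = 136
# canonical 4-mers; every window is counted once under its canonical form
# (the lexicographic minimum of the word and its reverse complement).

# canonical fold: for each of the 256 4-mer codes, the canonical code
.canon256 <- local({
  idx <- 0:255
  b <- cbind(idx %/% 64L, (idx %/% 16L) %% 4L, (idx %/% 4L) %% 4L, idx %% 4L)
  rc <- (3L - b)[, 4:1, drop = FALSE]
  rc_code <- as.integer(rc %*% c(64L, 16L, 4L, 1L))
  pmin(idx, rc_code)
})
.canon_codes <- sort(unique(.canon256))  # 136 codes, lexicographic

#' The 136 canonical 4-mers
#'
#' @return Character vector of the canonical tetranucleotides in
#'   lexicographic order.
#' @export
canonical_kmers <- function() {
  vapply(.canon_codes, function(code) {
    int_to_seq(c(code %/% 64L, (code %/% 16L) %% 4L,
                 (code %/% 4L) %% 4L, code %% 4L))
  }, character(1))
}

#' Canonical tetranucleotide profile of a sequence set
#'
#' Counts every 4-bp window of the input under its canonical form and
#' normalizes to frequencies. Multi-contig inputs (e.g. a draft host
#' genome) are pooled at the count level before normalization, so longer
#' contigs carry proportionally more weight; windows are never taken across
#' contig boundaries. Windows containing non-ACGT letters are skipped.
#'
#' @param sequences Character vector of sequences, or a
#'   [Biostrings::DNAStringSet].
#' @param owner_id Identifier recorded on the profile (defaults to the
#'   first sequence name, if any).
#' @return A `kmer_profile`: `owner_id`, `counts` (136 named integers),
#'   `freqs` (136 reals summing to 1), `total_bp`.
#' @export
canonical_profile <- function(sequences, owner_id = NULL) {
  if (is.character(sequences)) {
    if (is.null(owner_id) && !is.null(names(sequences))) {
      owner_id <- names(sequences)[1L]
    }
    sequences <- Biostrings::DNAStringSet(toupper(sequences))
  }
  stopifnot(methods::is(sequences, "DNAStringSet"))
  counts256 <- colSums(Biostrings::oligonucleotideFrequency(sequences, 4L))
  counts <- as.integer(vapply(.canon_codes, function(code) {
    sum(counts256[.canon256 == code])
  }, numeric(1)))
  total <- sum(counts)
  if (total == 0) stop("no informative windows: no countable ACGT 4-mers")
  names(counts) <- canonical_kmers()
  structure(list(owner_id = owner_id %||% NA_character_,
                 counts = counts,
                 freqs = counts / total,
                 total_bp = sum(nchar(as.character(sequences)))),
            class = "kmer_profile")
}

#' @export
print.kmer_profile <- function(x, ...) {
  cat("<kmer_profile> ", x$owner_id, ": ", sum(x$counts),
      " canonical 4-mer windows\n", sep = "")
  invisible(x)
}

#' Mean-absolute-error distance between two 4-mer profiles
#'
#' The composition distance `d` is the mean of the absolute differences of
#' the two canonical tetranucleotide frequency vectors:
#' `d = (1/136) * sum(|p_i - q_i|)`. It is symmetric, zero iff the
#' frequency vectors are identical, and bounded above by 2/136 (the
#' total-variation bound).
#'
#' @param p,q `kmer_profile` objects.
#' @return The distance `d`, a non-negative scalar.
#' @export
mae_distance <- function(p, q) {
  stopifnot(inherits(p, "kmer_profile"), inherits(q, "kmer_profile"))
  for (x in list(p, q)) {
    if (abs(sum(x$freqs) - 1) > 1e-9) {
      stop("profile is not normalized: frequencies must sum to 1")
    }
  }
  mean(abs(p$freqs - q$freqs))
}

#' Precompute 4-mer profiles for a host genome database
#'
#' @param hosts Named list: strain id -> character vector of contig
#'   sequences (pooled per strain).
#' @return Named list of `kmer_profile` objects.
#' @export
host_kmer_db <- function(hosts) {
  stopifnot(is.list(hosts), !is.null(names(hosts)))
  lapply(setNames(names(hosts), names(hosts)), function(s) {
    canonical_profile(hosts[[s]], owner_id = s)
  })
}

#' Predict a viral contig's host from tetranucleotide composition
#'
#' Phages tend to share nucleotide composition with their hosts, so a small
#' 4-mer distance is evidence of a virus-host link. Hosts with
#' `d < d_max` are candidates; when several qualify, the `top_n` lowest
#' distances (with ties at the boundary included) are reduced to their
#' lowest common ancestor, which becomes the assigned taxon. With no
#' candidate the virus gets an explicit no-call row. The threshold is
#' strict: a host at exactly `d == d_max` is excluded.
#'
#' @param virus A `kmer_profile`, or a character sequence (profiled on the
#'   fly; give `virus_id` then).
#' @param host_db Named list of host `kmer_profile`s from [host_kmer_db()].
#' @param tree A `taxonomy_tree` covering the host strains.
#' @param d_max Strict upper bound on `d` for a candidate (default 0.001).
#' @param top_n Number of lowest-distance candidates fed to the LCA
#'   (default 5; boundary ties included).
#' @param virus_id Identifier used when `virus` is a raw sequence.
#' @return A one-row data.frame in the shared host-prediction dialect:
#'   `virus_id`, `method` ("4mer"), `status` ("predicted"/"no_call"),
#'   `taxon`, `rank`, `score` (best `d`), `n_candidates`, `evidence`
#'   (semicolon-joined `strain:d`), `low_confidence` (virus < 4 kb).
#' @export
predict_host_kmer <- function(virus, host_db, tree, d_max = 0.001,
                              top_n = 5, virus_id = NULL) {
  if (length(host_db) == 0L) stop("empty host profile database")
  if (!inherits(virus, "kmer_profile")) {
    virus <- canonical_profile(virus, owner_id = virus_id)
  }
  vid <- virus_id %||% virus$owner_id
  d <- vapply(host_db, mae_distance, numeric(1), q = virus)
  low_conf <- isTRUE(virus$total_bp < 4000)

  cand <- d[d < d_max]
  if (length(cand) == 0L) {
    return(prediction_row(vid, "4mer", status = "no_call",
                          score = min(d), low_confidence = low_conf))
  }
  cand <- sort(cand)
  cutoff <- cand[min(top_n, length(cand))]
  top <- cand[cand <= cutoff]  # include boundary ties
  node <- lca(names(top), tree)
  prediction_row(vid, "4mer", status = "predicted", taxon = node$name,
                 rank = node$rank, score = unname(top[1L]),
                 n_candidates = length(cand),
                 evidence = paste(sprintf("%s:%.6g", names(top), top),
                                  collapse = ";"),
                 low_confidence = low_conf)
}

# One row of the shared host-prediction table.
prediction_row <- function(virus_id, method, status,
                           taxon = NA_character_, rank = NA_character_,
                           score = NA_real_, n_candidates = 0L,
                           evidence = "", low_confidence = FALSE) {
  data.frame(virus_id = virus_id, method = method, status = status,
             taxon = taxon, rank = rank, score = score,
             n_candidates = as.integer(n_candidates), evidence = evidence,
             low_confidence = low_confidence, stringsAsFactors = FALSE)
}
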