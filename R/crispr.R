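# CRISPR-based host evidence. Arrays are detected de novo with CRT-style
# geometry (>= 3 repeats of 19-38 bp separated by 19-48 bp spacers, 8-bp
# search window); spacers are matched against viral contigs full-length and
# ungapped allowing at most 1 mismatch; matched spacers are back-validated
# against their host genome of origin at 0 mismatches before a strain-level
# prediction is emitted. A spacer is a fossil of a past infection, so a
# validated spacer -> virus match is direct evidence of a host link.

#' Detect CRISPR repeat-spacer arrays in a genome
#'
#' Seeds on exact `window`-length words recurring at spacings compatible
#' with the repeat/spacer geometry, chains at least `min_repeats`
#' occurrences, and extends the repeat maximally while all copies agree
#' (optionally tolerating `max_divergence` mismatches per copy against the
#' majority consensus). Candidate arrays whose repeat or spacer lengths
#' fall outside the CRT windows are discarded; overlapping candidates
#' resolve to the one with more repeats.
#'
#' @param genome Named character vector of contig sequences.
#' @param window Seed word length (default 8).
#' @param min_repeats Minimum repeat copies (default 3).
#' @param repeat_range,spacer_range Allowed repeat / spacer lengths in bp
#'   (defaults c(19, 38) and c(19, 48)).
#' @param max_divergence Mismatches tolerated per repeat copy against the
#'   consensus during extension (default 0: strict agreement, which keeps
#'   detected loci exact; raise to tolerate point mutations inside repeat
#'   copies).
#' @param host_strain Identifier stamped on the arrays.
#' @return List of `crispr_array` objects: `host_strain`, `contig`,
#'   `start`, `end` (0-based half-open), `repeat_consensus`, `n_repeats`,
#'   `spacers` (character vector, n_repeats - 1 of them).
#' @export
detect_crispr_arrays <- function(genome, window = 8L, min_repeats = 3L,
                                 repeat_range = c(19L, 38L),
                                 spacer_range = c(19L, 48L),
                                 max_divergence = 0L,
                                 host_strain = NA_character_) {
  if (is.null(names(genome))) names(genome) <- paste0("contig",
                                                      seq_along(genome))
  gmin <- repeat_range[1L] + spacer_range[1L]
  gmax <- repeat_range[2L] + spacer_range[2L]
  out <- list()
  for (cg in names(genome)) {
    xint <- seq_to_int(genome[[cg]])
    n <- length(xint)
    codes <- kmer_codes(xint, window)
    ok <- which(!is.na(codes))
    groups <- split(ok, codes[ok])
    groups <- groups[lengths(groups) >= min_repeats]
    cand <- list()
    for (pos in groups) {
      for (ch in chain_positions(pos, gmin, gmax, min_repeats)) {
        arr <- extend_repeats(xint, ch, window, repeat_range, spacer_range,
                              max_divergence)
        if (!is.null(arr)) cand[[length(cand) + 1L]] <- arr
      }
    }
    cand <- resolve_overlaps(cand)
    for (arr in cand) {
      out[[length(out) + 1L]] <- structure(
        c(list(host_strain = host_strain, contig = cg), arr),
        class = "crispr_array")
    }
  }
  out
}

# Greedy chaining of sorted positions with successive gaps in [gmin, gmax].
chain_positions <- function(pos, gmin, gmax, min_repeats) {
  pos <- sort(pos)
  chains <- list()
  used <- rep(FALSE, length(pos))
  for (i in seq_along(pos)) {
    if (used[i]) next
    ch <- pos[i]
    used[i] <- TRUE
    last <- pos[i]
    repeat {
      nxt <- which(!used & pos - last >= gmin & pos - last <= gmax)
      if (length(nxt) == 0L) break
      j <- nxt[1L]
      ch <- c(ch, pos[j])
      used[j] <- TRUE
      last <- pos[j]
    }
    if (length(ch) >= min_repeats) chains[[length(chains) + 1L]] <- ch
  }
  chains
}

# Maximal bidirectional extension of anchored repeat copies.
# anchors: starts (1-based) of the shared seed word in each copy.
extend_repeats <- function(xint, anchors, window, repeat_range,
                           spacer_range, max_divergence) {
  n <- length(xint)
  k <- length(anchors)
  mm <- integer(k)
  extend_dir <- function(offsets, mm) {
    ext <- 0L
    repeat {
      cols <- anchors + offsets(ext + 1L)
      if (any(cols < 1L | cols > n)) break
      bases <- xint[cols]
      if (anyNA(bases)) break
      tab <- tabulate(bases + 1L, 4L)
      cons <- which.max(tab) - 1L
      new_mm <- mm + (bases != cons)
      if (any(new_mm > max_divergence)) break
      mm <- new_mm
      ext <- ext + 1L
    }
    list(ext = ext, mm = mm)
  }
  left <- extend_dir(function(e) -e, mm)
  right <- extend_dir(function(e) window - 1L + e, left$mm)
  rep_len <- window + left$ext + right$ext
  if (rep_len < repeat_range[1L] || rep_len > repeat_range[2L]) return(NULL)
  starts <- anchors - left$ext
  ends <- starts + rep_len  # exclusive
  spacer_lens <- starts[-1L] - ends[-k]
  if (any(spacer_lens < spacer_range[1L] | spacer_lens > spacer_range[2L])) {
    return(NULL)
  }
  # consensus repeat
  consensus <- vapply(seq_len(rep_len), function(j) {
    which.max(tabulate(xint[starts + j - 1L] + 1L, 4L)) - 1L
  }, integer(1))
  spacers <- vapply(seq_len(k - 1L), function(i) {
    int_to_seq(xint[ends[i]:(starts[i + 1L] - 1L)])
  }, character(1))
  list(start = starts[1L] - 1L, end = ends[k] - 1L,
       repeat_consensus = int_to_seq(consensus),
       n_repeats = k, spacers = spacers)
}

# Keep the candidate with more repeats among overlapping arrays; dedupe
# identical loci (the same array is found once per seed offset).
resolve_overlaps <- function(cand) {
  if (length(cand) == 0L) return(cand)
  key <- vapply(cand, function(a) paste(a$start, a$end), character(1))
  cand <- cand[!duplicated(key)]
  ord <- order(vapply(cand, function(a) -a$n_repeats, numeric(1)),
               vapply(cand, function(a) a$start, numeric(1)))
  cand <- cand[ord]
  kept <- list()
  for (a in cand) {
    clash <- any(vapply(kept, function(b) {
      a$start < b$end && b$start < a$end
    }, logical(1)))
    if (!clash) kept[[length(kept) + 1L]] <- a
  }
  kept[order(vapply(kept, function(a) a$start, numeric(1)))]
}

#' @export
print.crispr_array <- function(x, ...) {
  cat("<crispr_array> ", x$host_strain, " ", x$contig, ":", x$start, "-",
      x$end, " (", x$n_repeats, " x ", nchar(x$repeat_consensus),
      " bp repeat, ", length(x$spacers), " spacers)\n", sep = "")
  invisible(x)
}

#' Match CRISPR spacers against viral contigs
#'
#' Full-length, ungapped scan of every spacer against every virus on both
#' strands, reporting placements with Hamming distance at most `max_mm`
#' (default 1; a spacer differing from its source by 2 substitutions does
#' not match). Identical spacers within one array are counted once.
#'
#' @param arrays List of `crispr_array` objects.
#' @param viruses Named character vector of viral contig sequences.
#' @param max_mm Maximum mismatches (default 1).
#' @return data.frame of matches: `host_strain`, `array_contig`,
#'   `spacer_seq`, `virus_id`, `v_pos` (0-based, plus-strand coordinates),
#'   `strand`, `mismatches`.
#' @export
match_spacers <- function(arrays, viruses, max_mm = 1L) {
  stopifnot(!is.null(names(viruses)))
  vobj <- lapply(viruses, Biostrings::DNAString)
  rows <- list()
  for (arr in arrays) {
    for (sp in unique(arr$spacers)) {
      pat <- Biostrings::DNAString(sp)
      rcp <- Biostrings::reverseComplement(pat)
      for (v in names(viruses)) {
        L <- length(vobj[[v]])
        for (strand in c("+", "-")) {
          p <- if (strand == "+") pat else rcp
          m <- Biostrings::matchPattern(p, vobj[[v]], max.mismatch = max_mm)
          for (j in seq_along(m)) {
            hit <- m[j]
            mm <- Biostrings::neditAt(p, vobj[[v]],
                                      at = Biostrings::start(hit))
            rows[[length(rows) + 1L]] <- data.frame(
              host_strain = arr$host_strain, array_contig = arr$contig,
              spacer_seq = sp, virus_id = v,
              v_pos = Biostrings::start(hit) - 1L, strand = strand,
              mismatches = as.integer(mm), stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(host_strain = character(0),
                      array_contig = character(0),
                      spacer_seq = character(0), virus_id = character(0),
                      v_pos = integer(0), strand = character(0),
                      mismatches = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Strain-level host predictions from spacer matches
#'
#' Back-validation step: a spacer match only supports a prediction if the
#' spacer still occurs exactly (0 mismatches, either strand) in its host
#' genome of origin. Validated matches are aggregated into one strain-rank
#' prediction per (virus, host) pair, with each supporting spacer listed as
#' evidence. Exact occurrences of a spacer in a different host's genome are
#' recorded (attribute `cross_host`) but never turned into predictions.
#'
#' @param matches data.frame from [match_spacers()].
#' @param hosts Named list strain -> character vector of contig sequences.
#' @return data.frame of prediction rows (method "crispr", rank "strain");
#'   `score` is the smallest mismatch count among supporting spacers.
#' @export
predict_host_crispr <- function(matches, hosts) {
  validated <- logical(nrow(matches))
  for (i in seq_len(nrow(matches))) {
    g <- hosts[[matches$host_strain[i]]]
    if (is.null(g)) stop("unknown host strain: ", matches$host_strain[i])
    validated[i] <- spacer_occurs_exactly(matches$spacer_seq[i], g)
  }
  keep <- matches[validated, , drop = FALSE]
  cross <- character(0)
  for (sp in unique(matches$spacer_seq)) {
    others <- setdiff(names(hosts),
                      matches$host_strain[matches$spacer_seq == sp])
    hitters <- others[vapply(others, function(s) {
      spacer_occurs_exactly(sp, hosts[[s]])
    }, logical(1))]
    if (length(hitters)) {
      cross <- c(cross, paste0(sp, "->", paste(hitters, collapse = ",")))
    }
  }
  rows <- list()
  if (nrow(keep)) {
    for (key in unique(paste(keep$virus_id, keep$host_strain, sep = "\r"))) {
      parts <- strsplit(key, "\r", fixed = TRUE)[[1L]]
      sub <- keep[keep$virus_id == parts[1L] &
                    keep$host_strain == parts[2L], ]
      rows[[length(rows) + 1L]] <- prediction_row(
        parts[1L], "crispr", status = "predicted", taxon = parts[2L],
        rank = "strain", score = min(sub$mismatches),
        n_candidates = nrow(sub),
        evidence = paste(sprintf("%s@%d%s:%dmm", sub$spacer_seq, sub$v_pos,
                                 sub$strand, sub$mismatches),
                         collapse = ";"))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    prediction_row("x", "crispr", "no_call")[0, ]
  attr(out, "cross_host") <- cross
  out
}

spacer_occurs_exactly <- function(spacer, contigs) {
  pat <- Biostrings::DNAString(spacer)
  rcp <- Biostrings::reverseComplement(pat)
  for (cg in contigs) {
    subj <- Biostrings::DNAString(cg)
    if (Biostrings::countPattern(pat, subj) > 0L ||
        Biostrings::countPattern(rcp, subj) > 0L) {
      return(TRUE)
    }
  }
  FALSE
}
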