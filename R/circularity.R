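# Circular-scaffold classification. A scaffold assembled from a circular
# template carries the assembly's terminal redundancy as a direct repeat at
# its two ends, and sequencing fragments that straddle the (arbitrary)
# linearization point leave read pairs mapping near opposite ends in an
# "outward" orientation. A scaffold is called circular when all three
# criteria hold: length > 2 kb, a terminal direct repeat of >= 35 bp, and
# >= 2 junction-spanning read pairs within 500 bp of the ends.

#' Length of the terminal direct repeat of a contig
#'
#' Finds the longest exact prefix of the contig that recurs as its suffix
#' in the same orientation (a direct repeat, as produced by assembling
#' across a circular junction; inverted repeats do not qualify). Only
#' repeats of at least `min_len` and at most `max_scan` are considered.
#'
#' @param contig Character scalar.
#' @param min_len Minimum repeat length to report (default 35 bp; a 34-bp
#'   repeat returns 0).
#' @param max_scan Longest repeat searched for (default 1000 bp).
#' @return Integer repeat length, 0 if none qualifies.
#' @export
find_terminal_repeat <- function(contig, min_len = 35L, max_scan = 1000L) {
  L <- nchar(contig)
  top <- min(max_scan, L %/% 2L)
  if (top < min_len) return(0L)
  u <- utf8ToInt(contig)
  for (k in seq(top, min_len)) {
    if (all(u[seq_len(k)] == u[(L - k + 1L):L])) return(as.integer(k))
  }
  0L
}

# Place one read on the contig by exact match, both strands.
# Returns list(pos = 0-based start, strand) or NULL if unplaced; ambiguous
# placements (more than one occurrence in total) return "ambiguous".
place_read <- function(read, contig_fwd, contig_rc, L) {
  fwd <- Biostrings::matchPattern(read, contig_fwd)
  rev_ <- Biostrings::matchPattern(read, contig_rc)
  n <- length(fwd) + length(rev_)
  if (n == 0L) return(NULL)
  if (n > 1L) return("ambiguous")
  if (length(fwd) == 1L) {
    list(pos = Biostrings::start(fwd)[1L] - 1L, strand = "+",
         len = nchar(read))
  } else {
    # position on the forward contig of a minus-strand read
    list(pos = L - Biostrings::end(rev_)[1L], strand = "-",
         len = nchar(read))
  }
}

#' Count junction-spanning read pairs on a contig
#'
#' Reads are placed by exact substring match on either strand (leftmost
#' and only occurrence; reads placing ambiguously exclude their pair). A
#' pair spans the junction of a circularized contig when its plus-strand
#' mate lies wholly within `end_window` of the right end and its
#' minus-strand mate wholly within `end_window` of the left end -- the
#' "outward" orientation produced by a fragment wrapping the origin.
#'
#' @param contig Character scalar.
#' @param read_pairs List with character vectors `r1` and `r2` (equal
#'   length, mate i of r1 pairs with mate i of r2).
#' @param end_window Maximum distance from the contig end (default 500 bp);
#'   a mate starting 501 bp from the end does not count.
#' @return Integer count of spanning pairs. The number of pairs dropped
#'   for ambiguous placement is attached as attribute `n_ambiguous`.
#' @export
count_spanning_pairs <- function(contig, read_pairs, end_window = 500L) {
  stopifnot(length(read_pairs$r1) == length(read_pairs$r2))
  L <- nchar(contig)
  fwd <- Biostrings::DNAString(contig)
  rc <- Biostrings::reverseComplement(fwd)
  n_span <- 0L
  n_amb <- 0L
  within_left <- function(p) p$pos >= 0L && p$pos + p$len <= end_window
  within_right <- function(p) p$pos >= L - end_window && p$pos + p$len <= L
  for (i in seq_along(read_pairs$r1)) {
    p1 <- place_read(read_pairs$r1[i], fwd, rc, L)
    p2 <- place_read(read_pairs$r2[i], fwd, rc, L)
    if (identical(p1, "ambiguous") || identical(p2, "ambiguous")) {
      n_amb <- n_amb + 1L
      next
    }
    if (is.null(p1) || is.null(p2)) next
    if (p1$strand == p2$strand) next
    plus <- if (p1$strand == "+") p1 else p2
    minus <- if (p1$strand == "-") p1 else p2
    if (within_right(plus) && within_left(minus)) n_span <- n_span + 1L
  }
  structure(n_span, n_ambiguous = n_amb)
}

#' Count junction-spanning pairs from a SAM file
#'
#' Alternative evidence source to exact-match placement: accepts read
#' placements from a SAM text file (mapped primary alignments only) and
#' applies the same end-window and orientation rules as
#' [count_spanning_pairs()].
#'
#' @param sam_path Path to a SAM file.
#' @param contig_id Reference name of the contig of interest.
#' @param contig_len Contig length in bp.
#' @param end_window See [count_spanning_pairs()].
#' @return Integer count of spanning pairs.
#' @export
count_spanning_pairs_sam <- function(sam_path, contig_id, contig_len,
                                     end_window = 500L) {
  lines <- readLines(sam_path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L) return(0L)
  f <- strsplit(lines, "\t")
  rec <- data.frame(
    qname = vapply(f, `[`, "", 1L),
    flag = as.integer(vapply(f, `[`, "", 2L)),
    rname = vapply(f, `[`, "", 3L),
    pos = as.integer(vapply(f, `[`, "", 4L)),
    len = nchar(vapply(f, `[`, "", 10L)),
    stringsAsFactors = FALSE)
  rec <- rec[rec$rname == contig_id &
               bitwAnd(rec$flag, 4L) == 0L &      # mapped
               bitwAnd(rec$flag, 256L) == 0L &    # primary
               bitwAnd(rec$flag, 2048L) == 0L, ]  # not supplementary
  n_span <- 0L
  for (qn in unique(rec$qname)) {
    mates <- rec[rec$qname == qn, ]
    if (nrow(mates) != 2L) next
    strands <- ifelse(bitwAnd(mates$flag, 16L) > 0L, "-", "+")
    if (strands[1L] == strands[2L]) next
    plus <- mates[strands == "+", ][1L, ]
    minus <- mates[strands == "-", ][1L, ]
    if (plus$pos - 1L >= contig_len - end_window &&
        plus$pos - 1L + plus$len <= contig_len &&
        minus$pos - 1L >= 0L &&
        minus$pos - 1L + minus$len <= end_window) {
      n_span <- n_span + 1L
    }
  }
  n_span
}

#' Classify a scaffold as circular
#'
#' Applies the three circularity criteria: (i) scaffold length > `min_len`
#' (2 kb), (ii) a terminal direct repeat of at least `min_repeat` (35 bp)
#' in the correct (direct) orientation, and (iii) at least `min_pairs` (2)
#' read pairs mapping on opposite ends of the contig within `end_window`
#' (500 bp) of the ends. Every unmet criterion is listed.
#'
#' @param contig Character scalar (optionally named; the name becomes
#'   `contig_id`).
#' @param read_pairs List with `r1`/`r2` character vectors (see
#'   [count_spanning_pairs()]); may be empty.
#' @param min_len,min_repeat,min_pairs,end_window Thresholds as above.
#' @param contig_id Identifier for the call.
#' @return A `circularity_call` list: `contig_id`, `length_bp`,
#'   `terminal_repeat_len`, `spanning_pairs`, `verdict` ("circular" /
#'   "not_circular"), `failed_criteria`.
#' @export
classify_circular <- function(contig, read_pairs = list(r1 = character(0),
                                                        r2 = character(0)),
                              min_len = 2000L, min_repeat = 35L,
                              min_pairs = 2L, end_window = 500L,
                              contig_id = NULL) {
  contig_id <- contig_id %||% names(contig) %||% NA_character_
  contig <- unname(contig)
  L <- nchar(contig)
  tr <- if (L >= 2L * min_repeat) find_terminal_repeat(contig, min_repeat)
        else 0L
  sp <- as.integer(count_spanning_pairs(contig, read_pairs, end_window))
  failed <- character(0)
  if (L <= min_len) failed <- c(failed, "length")
  if (tr < min_repeat) failed <- c(failed, "terminal_repeat")
  if (sp < min_pairs) failed <- c(failed, "spanning_pairs")
  structure(list(contig_id = contig_id, length_bp = L,
                 terminal_repeat_len = tr, spanning_pairs = sp,
                 verdict = if (length(failed) == 0L) "circular"
                           else "not_circular",
                 failed_criteria = failed),
            class = "circularity_call")
}

#' @export
print.circularity_call <- function(x, ...) {
  cat("<circularity_call> ", x$contig_id, ": ", x$verdict,
      " (", x$length_bp, " bp, repeat ", x$terminal_repeat_len,
      " bp, ", x$spanning_pairs, " spanning pairs)\n", sep = "")
  if (length(x$failed_criteria)) {
    cat("  failed: ", paste(x$failed_criteria, collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}
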