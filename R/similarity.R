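# Shared-region host evidence: an ungapped seed-and-extend search for
# locally similar virus <-> host segments (prophage integrations or
# horizontal transfers), plus the two prediction rules built on it:
# genus-level assignment from qualifying regions (>= 4.9 kb at >= 70%
# identity, top-5 by bit score, LCA) and strain-level whole-virus
# containment ("BLAST99": > 99% query coverage at > 99% identity with a
# vanishing E-value).

#' Ungapped nucleotide scoring scheme
#'
#' Match/mismatch scores with ungapped Karlin-Altschul constants used to
#' convert raw segment scores into bit scores and E-values:
#' `bit = (lambda * raw - ln K) / ln 2`, `E = m * n * 2^-bit` with `m` the
#' virus length and `n` the summed host genome length.
#'
#' @param match,mismatch Per-base scores (defaults +2 / -3).
#' @param lambda,k_param Karlin-Altschul constants (0.625, 0.41, the
#'   ungapped nucleotide defaults for +2/-3).
#' @param seed_len Exact-match seed length (default 11).
#' @return A `scoring_scheme` list.
#' @export
scoring_scheme <- function(match = 2, mismatch = -3, lambda = 0.625,
                           k_param = 0.41, seed_len = 11L) {
  stopifnot(match > 0, mismatch < 0, lambda > 0, k_param > 0, seed_len >= 4)
  structure(list(match = match, mismatch = mismatch, lambda = lambda,
                 k_param = k_param, seed_len = as.integer(seed_len)),
            class = "scoring_scheme")
}

bit_score <- function(raw, scheme) {
  (scheme$lambda * raw - log(scheme$k_param)) / log(2)
}

e_value <- function(bit, m, n) {
  as.numeric(m) * as.numeric(n) * 2^(-bit)
}

# Iterated maximal-scoring-segment search on a match/mismatch vector
# (vectorized Kadane). Returns start/end (1-based inclusive, local
# coordinates), n_match, raw score for every disjoint segment whose raw
# score reaches min_raw. Found segments are masked with a large negative
# score (finite, so cumsum stays well defined) and the scan repeats.
max_segments <- function(is_match, match, mismatch, min_raw) {
  score <- mismatch + (match - mismatch) * as.numeric(is_match)
  out <- list()
  repeat {
    cs <- cumsum(score)
    pre <- cummin(c(0, cs[-length(cs)]))
    gain <- cs - pre
    best <- max(gain)
    if (best < min_raw) break
    e <- which.max(gain)
    s <- which(c(0, cs)[seq_len(e)] == pre[e])[1L]
    out[[length(out) + 1L]] <- c(start = s, end = e,
                                 n_match = sum(is_match[s:e]),
                                 raw = best)
    score[s:e] <- -1e9
  }
  out
}

# Seed-and-extend on one strand against one host contig.
# vint: integer-encoded virus (already oriented); hint: host contig.
# Returns data.frame of segments in oriented-virus coordinates.
scan_strand <- function(vint, hint, scheme, min_raw,
                        max_diag_gap = 500L, margin = 600L) {
  k <- scheme$seed_len
  vcode <- kmer_codes(vint, k)
  hcode <- kmer_codes(hint, k)
  ok_v <- which(!is.na(vcode)); ok_h <- which(!is.na(hcode))
  if (length(ok_v) == 0L || length(ok_h) == 0L) return(NULL)

  vmap <- split(ok_v, vcode[ok_v])
  hmap <- split(ok_h, hcode[ok_h])
  shared <- intersect(names(vmap), names(hmap))
  if (length(shared) == 0L) return(NULL)
  vlist <- vmap[shared]; hlist <- hmap[shared]
  nv <- lengths(vlist); nh <- lengths(hlist)
  # drop hyper-frequent seeds (low-complexity), akin to seed masking
  ok <- nv * nh <= 200L
  if (!any(ok)) return(NULL)
  vlist <- vlist[ok]; hlist <- hlist[ok]; nv <- nv[ok]; nh <- nh[ok]
  vp <- rep(unlist(vlist, use.names = FALSE), times = rep(nh, times = nv))
  hp <- unlist(rep(hlist, times = nv), use.names = FALSE)
  diag <- hp - vp
  ord <- order(diag, vp)
  diag <- diag[ord]; vp <- vp[ord]
  # require two seeds on a diagonal within max_diag_gap of each other
  close_prev <- c(FALSE, diff(diag) == 0L & diff(vp) <= max_diag_gap)
  qual <- unique(diag[close_prev])
  if (length(qual) == 0L) return(NULL)
  keep <- diag %in% qual
  vsplit <- split(vp[keep], diag[keep])
  res <- list()
  for (i in seq_along(vsplit)) {
    dg <- as.integer(names(vsplit)[i])
    pv <- vsplit[[i]]
    lo <- max(1L, pv[1L] - margin)
    hi <- min(length(vint), pv[length(pv)] + k - 1L + margin)
    # clip to the host contig extent on this diagonal
    lo <- max(lo, 1L - dg)
    hi <- min(hi, length(hint) - dg)
    if (hi - lo + 1L < k) next
    is_match <- vint[lo:hi] == hint[(lo + dg):(hi + dg)]
    is_match[is.na(is_match)] <- FALSE
    segs <- max_segments(is_match, scheme$match, scheme$mismatch, min_raw)
    for (sg in segs) {
      res[[length(res) + 1L]] <- data.frame(
        v_start = lo + sg[["start"]] - 2L,        # 0-based
        v_end = lo + sg[["end"]] - 1L,            # half-open
        h_start = lo + dg + sg[["start"]] - 2L,
        h_end = lo + dg + sg[["end"]] - 1L,
        n_match = sg[["n_match"]], raw = sg[["raw"]],
        stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0L) NULL else do.call(rbind, res)
}

#' Find locally similar regions between a viral contig and a host genome
#'
#' Ungapped seed-and-extend: exact `seed_len`-mers shared by virus and host
#' anchor diagonals, and each anchored diagonal is resolved into its
#' maximal-scoring ungapped segments under the +2/-3 scheme. Both strands
#' are searched; minus-strand hits are reported in plus-strand virus
#' coordinates with `strand == "-"`. Because extension is ungapped, region
#' length is identical on virus and host and identity is the Hamming
#' identity of the aligned segment.
#'
#' @param virus Character scalar (viral contig sequence).
#' @param host Named character vector of host contig sequences.
#' @param scheme A [scoring_scheme()].
#' @param min_raw Minimum raw segment score to report (default 40,
#'   bit score about 37; prediction rules apply stricter filters on top).
#' @param virus_id,host_strain Identifiers stamped on the output rows.
#' @return data.frame of regions: `virus_id`, `host_strain`, `contig`,
#'   `v_start`, `v_end`, `h_start`, `h_end` (0-based half-open), `strand`,
#'   `length`, `identity`, `raw`, `bit`, `evalue`; NULL-safe (zero rows
#'   when nothing is found).
#' @export
find_similar_regions <- function(virus, host, scheme = scoring_scheme(),
                                 min_raw = 40, virus_id = NA_character_,
                                 host_strain = NA_character_) {
  stopifnot(is.character(virus), length(virus) == 1L)
  if (is.null(names(host))) names(host) <- paste0("contig", seq_along(host))
  vint <- seq_to_int(virus)
  vlen <- length(vint)
  nlen <- sum(nchar(host))
  rows <- list()
  for (cg in names(host)) {
    hint <- seq_to_int(host[[cg]])
    for (strand in c("+", "-")) {
      ov <- if (strand == "+") vint else rev(3L - vint)
      seg <- scan_strand(ov, hint, scheme, min_raw)
      if (is.null(seg)) next
      if (strand == "-") {
        tmp <- vlen - seg$v_end
        seg$v_end <- vlen - seg$v_start
        seg$v_start <- tmp
      }
      seg$contig <- cg
      seg$strand <- strand
      rows[[length(rows) + 1L]] <- seg
    }
  }
  if (length(rows) == 0L) return(empty_regions())
  out <- do.call(rbind, rows)
  out$length <- out$v_end - out$v_start
  out$identity <- out$n_match / out$length
  out$bit <- bit_score(out$raw, scheme)
  out$evalue <- e_value(out$bit, vlen, nlen)
  out$virus_id <- virus_id
  out$host_strain <- host_strain
  out <- out[order(-out$raw, out$v_start), c(
    "virus_id", "host_strain", "contig", "v_start", "v_end", "h_start",
    "h_end", "strand", "length", "identity", "n_match", "raw", "bit",
    "evalue")]
  rownames(out) <- NULL
  out
}

empty_regions <- function() {
  data.frame(virus_id = character(0), host_strain = character(0),
             contig = character(0), v_start = integer(0),
             v_end = integer(0), h_start = integer(0), h_end = integer(0),
             strand = character(0), length = integer(0),
             identity = numeric(0), n_match = integer(0), raw = numeric(0),
             bit = numeric(0), evalue = numeric(0), stringsAsFactors = FALSE)
}

# Regions for one virus against every strain in a host db
# (named list strain -> contig character vector). Precomputed regions can
# be substituted anywhere a `regions` argument is accepted, e.g. parsed
# from tabular BLAST output via read_blast_tab().
regions_vs_db <- function(virus, hosts, scheme, min_raw = 40,
                          virus_id = NA_character_) {
  do.call(rbind, lapply(names(hosts), function(s) {
    find_similar_regions(virus, hosts[[s]], scheme, min_raw,
                         virus_id = virus_id, host_strain = s)
  }))
}

#' Genus-level host prediction from shared regions
#'
#' A host strain qualifies when at least one virus-host region passes all
#' four filters: bit score >= `min_bit`, E-value <= `max_e`, length >=
#' `min_len` (4.9 kb) and identity >= `min_ident` (70%). Each qualifying
#' strain is collapsed to its single best region by bit score; the `top_n`
#' strains by best bit score (ties at the boundary included) are reduced to
#' their lowest common ancestor.
#'
#' @param virus Viral contig sequence (ignored if `regions` given).
#' @param hosts Named list strain -> contig character vector.
#' @param tree A `taxonomy_tree` covering the strains.
#' @param scheme A [scoring_scheme()].
#' @param min_bit,max_e,min_len,min_ident,top_n Filter and ranking
#'   parameters (defaults 50, 0.001, 4900, 0.70, 5).
#' @param virus_id Identifier for the output row.
#' @param regions Optional precomputed region table (e.g. from
#'   [read_blast_tab()]) replacing the built-in search.
#' @return One prediction row (method "blast"), or a no-call row.
#' @export
predict_host_blast <- function(virus, hosts, tree, scheme = scoring_scheme(),
                               min_bit = 50, max_e = 0.001, min_len = 4900,
                               min_ident = 0.70, top_n = 5,
                               virus_id = NA_character_, regions = NULL) {
  if (is.null(regions)) {
    regions <- regions_vs_db(virus, hosts, scheme, virus_id = virus_id)
  }
  q <- regions[which(regions$bit >= min_bit & regions$evalue <= max_e &
                       regions$length >= min_len &
                       regions$identity >= min_ident), ]
  if (nrow(q) == 0L) {
    return(prediction_row(virus_id, "blast", status = "no_call"))
  }
  best <- vapply(split(q$bit, q$host_strain), max, numeric(1))
  best <- sort(best, decreasing = TRUE)
  cutoff <- best[min(top_n, length(best))]
  top <- best[best >= cutoff]
  node <- lca(names(top), tree)
  prediction_row(virus_id, "blast", status = "predicted", taxon = node$name,
                 rank = node$rank, score = unname(top[1L]),
                 n_candidates = length(best),
                 evidence = paste(sprintf("%s:%.1f", names(top), top),
                                  collapse = ";"))
}

#' Strain-level whole-virus containment (BLAST99)
#'
#' Looks for the entire viral sequence inside a host genome: regions at
#' identity > `min_ident` with E-value below `max_e` are merged on the
#' virus axis, and a strain is called when the merged spans cover more than
#' `min_cov` of the virus length. Every qualifying strain yields its own
#' strain-rank prediction (a virus may be integrated in several strains of
#' one genus).
#'
#' @param virus Viral contig sequence (ignored if `regions` given).
#' @param hosts Named list strain -> contig character vector.
#' @param scheme A [scoring_scheme()].
#' @param min_cov,min_ident Strict lower bounds (defaults 0.99 both;
#'   comparisons are strict `>`).
#' @param max_e E-value ceiling standing in for "E = 0" (default 1e-180;
#'   literal zero is a floating-underflow artifact).
#' @param virus_id Identifier for the output rows.
#' @param regions Optional precomputed region table.
#' @return data.frame of strain-rank prediction rows (method "blast99");
#'   zero rows when no strain qualifies.
#' @export
predict_host_blast99 <- function(virus, hosts, scheme = scoring_scheme(),
                                 min_cov = 0.99, min_ident = 0.99,
                                 max_e = 1e-180, virus_id = NA_character_,
                                 regions = NULL) {
  if (is.null(regions)) {
    regions <- regions_vs_db(virus, hosts, scheme, virus_id = virus_id)
  }
  vlen <- nchar(virus)
  q <- regions[which(regions$identity > min_ident &
                       regions$evalue < max_e), ]
  rows <- list()
  for (s in unique(q$host_strain)) {
    qs <- q[q$host_strain == s, ]
    spans <- IRanges::reduce(IRanges::IRanges(qs$v_start + 1L, qs$v_end))
    cov <- sum(IRanges::width(spans)) / vlen
    if (cov > min_cov) {
      rows[[length(rows) + 1L]] <- prediction_row(
        virus_id, "blast99", status = "predicted", taxon = s,
        rank = "strain", score = max(qs$bit), n_candidates = 1L,
        evidence = sprintf("coverage:%.4f;identity:%.4f", cov,
                           max(qs$identity)))
    }
  }
  if (length(rows) == 0L) return(prediction_row(virus_id, "blast99",
                                                status = "no_call")[0, ])
  do.call(rbind, rows)
}

#' Read tabular BLAST output as a region table
#'
#' Parses the 12-column tabular dialect (`qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore`, 1-based
#' inclusive coordinates) into the internal region table, so externally
#' computed alignments can feed [predict_host_blast()] and
#' [predict_host_blast99()] through the same filters. `sseqid` is split on
#' the first `|` into strain and contig if present, otherwise used as both.
#'
#' @param path Tab-separated file without header.
#' @return Region data.frame in [find_similar_regions()] layout (gapped
#'   rows keep their reported identity; `raw` is back-computed from the
#'   bit score).
#' @export
read_blast_tab <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 12L) stop("expected 12 tab-separated columns")
  names(df)[1:12] <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                       "gapopen", "qstart", "qend", "sstart", "send",
                       "evalue", "bitscore")
  strain <- sub("\\|.*$", "", df$sseqid)
  contig <- ifelse(grepl("\\|", df$sseqid),
                   sub("^[^|]*\\|", "", df$sseqid), df$sseqid)
  minus <- df$sstart > df$send
  h_start <- ifelse(minus, df$send, df$sstart) - 1L
  h_end <- ifelse(minus, df$sstart, df$send)
  scheme <- scoring_scheme()
  data.frame(virus_id = df$qseqid, host_strain = strain, contig = contig,
             v_start = df$qstart - 1L, v_end = df$qend,
             h_start = h_start, h_end = h_end,
             strand = ifelse(minus, "-", "+"),
             length = df$length, identity = df$pident / 100,
             n_match = as.integer(round(df$length * df$pident / 100)),
             raw = (df$bitscore * log(2) + log(scheme$k_param)) /
               scheme$lambda,
             bit = df$bitscore, evalue = df$evalue,
             stringsAsFactors = FALSE)
}
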