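# Synthetic community generator. Emits host genomes and viral contigs from
# genus-specific order-3 Markov composition models (so the tetranucleotide
# signal consumed by the 4-mer method is directly controlled), plants full
# and partial prophages, CRISPR arrays whose spacers derive from the viral
# pool, and paired reads from circular or linear templates -- all with
# ground-truth tables, so every downstream stage is testable without
# external data. All generation is a pure function of (config, seed); one
# user seed expands into per-component child seeds via child_seed().

#' Build a genus-level nucleotide composition model
#'
#' An order-3 Markov model: each 3-mer context gets a Dirichlet-distributed
#' next-base distribution. Lower `divergence` (the Dirichlet concentration)
#' makes the genus composition more distinctive; as it grows the model
#' approaches uniform i.i.d. composition. Sequences emitted from one model
#' share tetranucleotide statistics -- the premise that phages resemble
#' their hosts in genome composition.
#'
#' @param seed Integer seed; the model is a deterministic function of it.
#' @param divergence Dirichlet concentration, > 0 (default 1).
#' @param genus_id Optional label.
#' @return A `composition_model`: `order` (3), `transition_probs` (64 x 4,
#'   rows sum to 1), `genus_id`.
#' @export
build_genus_model <- function(seed, divergence = 1, genus_id = NULL) {
  if (!is.numeric(divergence) || divergence <= 0) {
    stop("divergence (Dirichlet concentration) must be > 0")
  }
  set.seed(seed)
  p <- matrix(rgamma(64L * 4L, shape = divergence), nrow = 64L)
  p <- p / rowSums(p)
  rownames(p) <- vapply(0:63, function(code) {
    int_to_seq(c(code %/% 16L, (code %/% 4L) %% 4L, code %% 4L))
  }, character(1))
  colnames(p) <- .BASES
  structure(list(order = 3L, transition_probs = p,
                 genus_id = genus_id %||% NA_character_,
                 cum = t(apply(p, 1L, cumsum))),
            class = "composition_model")
}

#' @export
print.composition_model <- function(x, ...) {
  cat("<composition_model> order-3 Markov, genus ", x$genus_id, "\n",
      sep = "")
  invisible(x)
}

# Emit `length` bases from an order-3 Markov model (deterministic per seed).
emit_sequence <- function(model, length, seed) {
  stopifnot(inherits(model, "composition_model"))
  if (length < 4L * (model$order + 1L)) {
    stop("length too short for order-", model$order, " emission")
  }
  set.seed(seed)
  cp <- model$cum
  c1 <- cp[, 1L]; c2 <- cp[, 2L]; c3 <- cp[, 3L]
  u <- runif(length)
  out <- integer(length)
  ctx <- sample.int(64L, 1L) - 1L
  for (i in seq_len(length)) {
    r <- u[i]
    b <- (r > c1[ctx + 1L]) + (r > c2[ctx + 1L]) + (r > c3[ctx + 1L])
    out[i] <- b
    ctx <- (ctx %% 16L) * 4L + as.integer(b)
  }
  int_to_seq(out)
}

#' Generate a host genome from a genus model
#'
#' Emits a genome from the genus composition model, applies strain-level
#' point substitutions at `strain_mutation_rate`, and splits it into
#' `n_contigs` contigs (near-equal lengths summing to `length`).
#'
#' @param model A [build_genus_model()] model.
#' @param length Total genome length (>= 50 kb recommended so 4-mer
#'   statistics are stable; hard floor `4 * (order + 1)`).
#' @param strain_mutation_rate Per-base substitution probability relative
#'   to the emitted genus sequence (default 0.002).
#' @param n_contigs Number of contigs (default 1).
#' @param seed Integer seed.
#' @param strain_id Strain identifier.
#' @param lineage Named character vector of rank values (phylum ... species)
#'   recorded for the lineage table.
#' @return A `host_genome`: `strain_id`, `contigs` (named character),
#'   `lineage`, `genus_id`, `n_mutations`.
#' @export
generate_host_genome <- function(model, length = 100000L,
                                 strain_mutation_rate = 0.002,
                                 n_contigs = 1L, seed = 1L,
                                 strain_id = "strain1", lineage = NULL) {
  parent <- emit_sequence(model, length, seed)
  xint <- seq_to_int(parent)
  set.seed(child_seed(seed, "strain_mutations"))
  pos <- which(runif(length) < strain_mutation_rate)
  xint <- mutate_positions(xint, pos)
  seqs <- character(n_contigs)
  bounds <- round(seq(0L, length, length.out = n_contigs + 1L))
  for (i in seq_len(n_contigs)) {
    seqs[i] <- int_to_seq(xint[(bounds[i] + 1L):bounds[i + 1L]])
  }
  names(seqs) <- if (n_contigs == 1L) strain_id else
    paste0(strain_id, "_c", seq_len(n_contigs))
  structure(list(strain_id = strain_id, contigs = seqs,
                 lineage = lineage, genus_id = model$genus_id,
                 n_mutations = length(pos)),
            class = "host_genome")
}

#' Generate a viral contig
#'
#' Emits a virus either from a genus composition model (a host-linked
#' virus, sharing its host's tetranucleotide signature) or from a uniform
#' background (no composition link).
#'
#' @param model A `composition_model`, or NULL for uniform background.
#' @param length Contig length, within the observed viral span
#'   4,000..300,000 bp.
#' @param seed Integer seed.
#' @param virus_id Identifier (becomes the sequence name).
#' @return Named character scalar.
#' @export
generate_virus <- function(model = NULL, length = 40000L, seed = 1L,
                           virus_id = "virus1") {
  if (length < 4000L || length > 300000L) {
    stop("virus length must be in [4000, 300000] bp")
  }
  s <- if (is.null(model)) {
    set.seed(seed)
    random_dna(length)
  } else {
    emit_sequence(model, length, seed)
  }
  setNames(s, virus_id)
}

# empty truth table (one row per planted relationship)
empty_truth <- function() {
  data.frame(virus_id = character(0), true_host_strain = character(0),
             relation = character(0), contig = character(0),
             insert_pos = integer(0), v_start = integer(0),
             v_end = integer(0), region_len = integer(0),
             target_identity = numeric(0), observed_identity = numeric(0),
             spacer_seq = character(0), spacer_mismatches = integer(0),
             stringsAsFactors = FALSE)
}

truth_row <- function(virus_id, host, relation, contig = NA_character_,
                      insert_pos = NA_integer_, v_start = NA_integer_,
                      v_end = NA_integer_, region_len = NA_integer_,
                      target_identity = NA_real_,
                      observed_identity = NA_real_,
                      spacer_seq = NA_character_,
                      spacer_mismatches = NA_integer_) {
  data.frame(virus_id = virus_id, true_host_strain = host,
             relation = relation, contig = contig,
             insert_pos = insert_pos, v_start = v_start, v_end = v_end,
             region_len = region_len, target_identity = target_identity,
             observed_identity = observed_identity, spacer_seq = spacer_seq,
             spacer_mismatches = spacer_mismatches, stringsAsFactors = FALSE)
}

# pick an insertion point on the host's longest contig, >= 1 kb from both
# ends (keeps planted loci away from edge effects in region detection)
pick_insertion <- function(host, margin = 1000L) {
  lens <- nchar(host$contigs)
  cg <- names(lens)[which.max(lens)]
  L <- lens[[cg]]
  if (L <= 2L * margin + 1L) stop("contig too short for insertion margin")
  pos <- sample((margin + 1L):(L - margin), 1L)  # insert before this base
  list(contig = cg, pos = pos)
}

insert_into <- function(host, contig, pos, fragment) {
  s <- host$contigs[[contig]]
  host$contigs[[contig]] <- paste0(substr(s, 1L, pos - 1L), fragment,
                                   substr(s, pos, nchar(s)))
  host
}

#' Plant a prophage (full or partial) into a host genome
#'
#' Inserts either the entire virus (`mode = "full"`, an integrated
#' prophage detectable by whole-virus containment) or a
#' substitution-mutated segment (`mode = "partial"`, a degraded prophage /
#' horizontal transfer detectable as a shared region). Partial regions must
#' be >= 4.9 kb at a target identity in \[0.70, 1\] -- the detection
#' thresholds of the shared-region method. The insertion point is uniform
#' on the longest contig, at least 1 kb from its ends; host length grows by
#' exactly the inserted length.
#'
#' @param host A `host_genome`.
#' @param virus Named character scalar (the viral contig).
#' @param mode "full" or "partial".
#' @param region_len Partial mode: planted segment length.
#' @param target_identity Partial mode: per-base identity of the planted
#'   copy versus its source window (substitutions only, so identity is
#'   plain Hamming identity).
#' @param seed Integer seed.
#' @param .relation Truth-table relation label; the default follows `mode`.
#'   Used internally to label out-of-threshold negative controls, which
#'   also set `.validate = FALSE`.
#' @param .validate Enforce the partial-mode preconditions (default TRUE).
#' @return List: `host` (mutated), `truth` (one-row truth table).
#' @export
plant_prophage <- function(host, virus, mode = c("full", "partial"),
                           region_len = NULL, target_identity = 1,
                           seed = 1L, .relation = NULL, .validate = TRUE) {
  mode <- match.arg(mode)
  virus_id <- names(virus) %||% NA_character_
  vseq <- unname(virus)
  vlen <- nchar(vseq)
  set.seed(seed)
  if (mode == "full") {
    at <- pick_insertion(host)
    host <- insert_into(host, at$contig, at$pos, vseq)
    return(list(host = host, truth = truth_row(
      virus_id, host$strain_id, .relation %||% "full_prophage",
      contig = at$contig, insert_pos = at$pos - 1L, v_start = 0L,
      v_end = vlen, region_len = vlen, target_identity = 1,
      observed_identity = 1)))
  }
  if (is.null(region_len)) stop("partial mode requires region_len")
  if (region_len > vlen) stop("region_len exceeds virus length")
  if (.validate) {
    if (region_len < 4900L) {
      stop("partial prophage regions must be >= 4900 bp")
    }
    if (target_identity < 0.70 || target_identity > 1) {
      stop("target_identity must be in [0.70, 1]")
    }
  }
  v_start <- sample.int(vlen - region_len + 1L, 1L) - 1L  # 0-based
  seg <- seq_to_int(substr(vseq, v_start + 1L, v_start + region_len))
  pos <- which(runif(region_len) < 1 - target_identity)
  mut <- mutate_positions(seg, pos)
  obs <- hamming_identity(seg, mut)
  at <- pick_insertion(host)
  host <- insert_into(host, at$contig, at$pos, int_to_seq(mut))
  list(host = host, truth = truth_row(
    virus_id, host$strain_id, .relation %||% "partial_prophage",
    contig = at$contig, insert_pos = at$pos - 1L, v_start = v_start,
    v_end = v_start + region_len, region_len = region_len,
    target_identity = target_identity, observed_identity = obs))
}

#' Plant a CRISPR repeat-spacer array into a host genome
#'
#' Inserts a literal repeat-spacer-...-repeat array (`n_repeats` copies of
#' `repeat_seq`, hence `n_repeats - 1` spacers). Each spacer is either
#' copied from a window of a virus with exactly the requested number of
#' substitutions, or random. CRT-style geometry is enforced: repeat length
#' in \[19, 38\], spacer lengths in \[19, 48\], at least 3 repeats. The two
#' host bases flanking the insertion are adjusted (if needed) so that the
#' maximal shared extension of the repeat copies is exactly the repeat --
#' this keeps the planted locus identifiable at base resolution.
#'
#' @param host A `host_genome`.
#' @param repeat_seq Repeat sequence (19-38 bp).
#' @param n_repeats Number of repeat copies (>= 3); must equal
#'   `length(spacer_specs) + 1`.
#' @param spacer_specs List of specs, each a list with `source` (a virus id
#'   or "random"), `length` (19-48), and for virus-derived spacers
#'   `mismatches` (0, 1 or 2).
#' @param viruses Named character vector supplying virus-derived spacers.
#' @param seed Integer seed.
#' @return List: `host` (mutated), `array` (one-row array truth:
#'   host_strain, contig, start, end, repeat_consensus, n_repeats,
#'   spacers semicolon-joined), `truth` (crispr_spacer rows for
#'   virus-derived spacers).
#' @export
plant_crispr_array <- function(host, repeat_seq, n_repeats, spacer_specs,
                               viruses = character(0), seed = 1L) {
  rl <- nchar(repeat_seq)
  if (rl < 19L || rl > 38L) stop("repeat length must be in [19, 38] bp")
  if (n_repeats < 3L) stop("at least 3 repeats required")
  if (length(spacer_specs) != n_repeats - 1L) {
    stop("need exactly n_repeats - 1 spacer specs")
  }
  set.seed(seed)
  truth <- empty_truth()
  spacers <- character(length(spacer_specs))
  for (i in seq_along(spacer_specs)) {
    spec <- spacer_specs[[i]]
    slen <- spec$length
    if (slen < 19L || slen > 48L) stop("spacer length must be in [19, 48]")
    if (identical(spec$source, "random")) {
      spacers[i] <- random_dna(slen)
    } else {
      vseq <- viruses[[spec$source]]
      if (is.null(vseq)) stop("unknown spacer source virus: ", spec$source)
      mm <- spec$mismatches %||% 0L
      if (!mm %in% 0:2) stop("spacer mismatches must be 0, 1 or 2")
      start <- sample.int(nchar(vseq) - slen + 1L, 1L)
      w <- seq_to_int(substr(vseq, start, start + slen - 1L))
      mut <- mutate_positions(w, if (mm > 0L) sample.int(slen, mm) else
                                   integer(0))
      spacers[i] <- int_to_seq(mut)
      truth <- rbind(truth, truth_row(
        spec$source, host$strain_id, "crispr_spacer",
        v_start = start - 1L, v_end = start + slen - 1L,
        spacer_seq = spacers[i], spacer_mismatches = mm))
    }
  }
  parts <- character(2L * n_repeats - 1L)
  parts[seq(1L, by = 2L, length.out = n_repeats)] <- repeat_seq
  parts[seq(2L, by = 2L, length.out = n_repeats - 1L)] <- spacers
  array_seq <- paste(parts, collapse = "")

  at <- pick_insertion(host)
  contig_seq <- host$contigs[[at$contig]]
  # flank adjustment: left neighbours of each repeat copy are the host base
  # before the array plus each spacer's last base; if unanimous, the repeat
  # would extend one base past the planted locus -- bump the host base.
  left_host <- substr(contig_seq, at$pos - 1L, at$pos - 1L)
  left_cols <- c(left_host, substr(spacers, nchar(spacers), nchar(spacers)))
  if (length(unique(left_cols)) == 1L) {
    contig_seq <- bump_base(contig_seq, at$pos - 1L)
  }
  right_host <- substr(contig_seq, at$pos, at$pos)
  right_cols <- c(substr(spacers, 1L, 1L), right_host)
  if (length(unique(right_cols)) == 1L) {
    contig_seq <- bump_base(contig_seq, at$pos)
  }
  host$contigs[[at$contig]] <- contig_seq
  host <- insert_into(host, at$contig, at$pos, array_seq)

  array <- data.frame(
    host_strain = host$strain_id, contig = at$contig,
    start = at$pos - 1L, end = at$pos - 1L + nchar(array_seq),
    repeat_consensus = repeat_seq, n_repeats = n_repeats,
    spacers = paste(spacers, collapse = ";"), stringsAsFactors = FALSE)
  list(host = host, array = array, truth = truth)
}

# replace the base at 1-based position i by the next base cyclically
bump_base <- function(s, i) {
  b <- .base_lut[utf8ToInt(substr(s, i, i))]
  paste0(substr(s, 1L, i - 1L), .BASES[(b + 1L) %% 4L + 1L],
         substr(s, i + 1L, nchar(s)))
}

#' Simulate paired reads from a circular or linear template
#'
#' Draws fragments of truncated-normal insert size (minimum `read_len`,
#' maximum capped at `insert_cap` so junction fragments stay within
#' typical end windows) uniformly from the template; on a circular
#' topology fragments may wrap the origin. Reads are error-free by default
#' (`error_rate` adds uniform substitutions). Mates are emitted in FR
#' orientation with a random template strand (implemented as a mate swap).
#'
#' The truth table reports, per pair, `start` (0-based fragment start),
#' `insert`, `straddles` (fragment wraps the origin) and `spans_ends`
#' (both mates lie wholly on opposite sides of the junction:
#' `start + read_len <= L` and `end - L >= read_len`) -- the pairs an
#' end-window spanning-pair counter can recover on the bare template.
#'
#' @param template Character scalar (or named; the name becomes the read
#'   id prefix).
#' @param topology "circular" or "linear".
#' @param n_pairs Number of pairs (0 gives empty read sets).
#' @param read_len Read length (default 100).
#' @param insert_mean,insert_sd Insert size distribution (defaults 300,
#'   30); `insert_mean` must be below the template length and at least
#'   `read_len`.
#' @param insert_cap Upper truncation of the insert (default 450).
#' @param error_rate Per-base substitution rate (default 0).
#' @param seed Integer seed.
#' @return List: `r1`, `r2` (named character vectors), `truth`
#'   (data.frame pair_id, start, insert, straddles, spans_ends).
#' @export
simulate_read_pairs <- function(template, topology = c("circular", "linear"),
                                n_pairs, read_len = 100L, insert_mean = 300L,
                                insert_sd = 30L, insert_cap = 450L,
                                error_rate = 0, seed = 1L) {
  topology <- match.arg(topology)
  prefix <- names(template) %||% "template"
  template <- unname(template)
  L <- nchar(template)
  if (insert_mean >= L) stop("insert_mean must be below template length")
  if (read_len > insert_mean) stop("read_len must not exceed insert_mean")
  set.seed(seed)
  xint <- seq_to_int(template)
  r1 <- character(n_pairs); r2 <- character(n_pairs)
  truth <- data.frame(pair_id = character(n_pairs), start = integer(n_pairs),
                      insert = integer(n_pairs),
                      straddles = logical(n_pairs),
                      spans_ends = logical(n_pairs), stringsAsFactors = FALSE)
  if (n_pairs > 0L) {
    ins <- pmin(pmax(round(rnorm(n_pairs, insert_mean, insert_sd)),
                     read_len), min(L, insert_cap))
    start <- if (topology == "circular") {
      sample.int(L, n_pairs, replace = TRUE) - 1L
    } else {
      vapply(ins, function(k) sample.int(L - k + 1L, 1L) - 1L, integer(1))
    }
    swap <- runif(n_pairs) < 0.5
    for (i in seq_len(n_pairs)) {
      idx <- (start[i] + seq_len(ins[i]) - 1L) %% L + 1L
      frag <- xint[idx]
      if (error_rate > 0) {
        frag <- mutate_positions(frag, which(runif(ins[i]) < error_rate))
      }
      a <- int_to_seq(frag[seq_len(read_len)])
      b <- revcomp(int_to_seq(frag[(ins[i] - read_len + 1L):ins[i]]))
      if (swap[i]) { tmp <- a; a <- b; b <- tmp }
      r1[i] <- a; r2[i] <- b
      e <- start[i] + ins[i]
      truth$start[i] <- start[i]
      truth$insert[i] <- ins[i]
      truth$straddles[i] <- e > L
      truth$spans_ends[i] <- e > L && (e - L) >= read_len &&
        (start[i] + read_len) <= L
    }
    ids <- sprintf("%s_pair%04d", prefix, seq_len(n_pairs))
    names(r1) <- paste0(ids, "/1"); names(r2) <- paste0(ids, "/2")
    truth$pair_id <- ids
  }
  if (topology == "linear") truth$straddles <- truth$spans_ends <- FALSE
  list(r1 = r1, r2 = r2, truth = truth)
}

#' Write paired reads as FASTQ
#'
#' Phred-33 FASTQ with fixed quality "I"; files are suffixed `_R1.fastq`
#' and `_R2.fastq`.
#'
#' @param reads List with `r1`, `r2` from [simulate_read_pairs()].
#' @param prefix Output path prefix.
#' @return The two file paths, invisibly.
#' @export
write_fastq_pairs <- function(reads, prefix) {
  paths <- paste0(prefix, c("_R1.fastq", "_R2.fastq"))
  for (j in 1:2) {
    rr <- reads[[c("r1", "r2")[j]]]
    lines <- as.vector(rbind(paste0("@", names(rr)), unname(rr), "+",
                             strrep("I", nchar(rr))))
    writeLines(if (length(rr)) lines else character(0), paths[j])
  }
  invisible(paths)
}
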