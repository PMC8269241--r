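test_that("terminal direct repeats are found exactly", {
  set.seed(21)
  x <- random_seq(40)
  y <- random_seq(3000)
  expect_equal(find_terminal_repeat(paste0(x, y, x)), 40L)
  # 34 bp is below the bar
  x34 <- random_seq(34)
  expect_equal(find_terminal_repeat(paste0(x34, y, x34)), 0L)
  x35 <- random_seq(35)
  expect_equal(find_terminal_repeat(paste0(x35, y, x35)), 35L)
  # inverted (reverse-complement) end homology does not qualify
  expect_equal(find_terminal_repeat(paste0(x, y, oracle_revcomp(x))), 0L)
})

test_that("random contigs have no chance >=35 bp terminal repeat", {
  set.seed(22)
  for (i in 1:30) {
    s <- random_seq(3000)
    expect_equal(find_terminal_repeat(s), oracle_terminal_repeat(s))
    expect_equal(find_terminal_repeat(s), 0L)
  }
})

test_that("spanning pairs respect the 500-bp end windows and orientation", {
  set.seed(23)
  contig <- random_seq(5000)
  L <- 5000L
  sub <- function(a, b) substr(contig, a + 1L, b)  # 0-based half-open
  mk_pair <- function(plus_start, minus_start, len = 100L) {
    list(r1 = sub(plus_start, plus_start + len),
         r2 = oracle_revcomp(sub(minus_start, minus_start + len)))
  }
  # plus mate near the right end, minus mate near the left end -> counted
  good <- mk_pair(L - 150L, 10L)
  expect_equal(as.integer(count_spanning_pairs(
    contig, list(r1 = good$r1, r2 = good$r2))), 1L)
  # mate starting 501 bp from the end -> not counted
  far <- mk_pair(L - 501L, 10L)
  expect_equal(as.integer(count_spanning_pairs(
    contig, list(r1 = far$r1, r2 = far$r2))), 0L)
  # boundary: read wholly within the window (starts exactly at L-500)
  edge <- mk_pair(L - 500L, 400L)
  expect_equal(as.integer(count_spanning_pairs(
    contig, list(r1 = edge$r1, r2 = edge$r2))), 1L)
  # same-orientation mates are not junction-spanning
  same <- list(r1 = sub(L - 150L, L - 50L), r2 = sub(10L, 110L))
  expect_equal(as.integer(count_spanning_pairs(
    contig, list(r1 = same$r1, r2 = same$r2))), 0L)
  # ambiguous placement excludes the pair
  dup_contig <- paste0(contig, substr(contig, 1, 200))
  amb <- list(r1 = substr(contig, 1, 100),
              r2 = oracle_revcomp(substr(contig, 301, 400)))
  res <- count_spanning_pairs(dup_contig, amb)
  expect_equal(attr(res, "n_ambiguous"), 1L)
})

test_that("spanning counts equal the generator's spans_ends truth", {
  tmpl <- setNames(random_seq(5000), "circ")
  reads <- simulate_read_pairs(tmpl, "circular", n_pairs = 200, seed = 77)
  got <- count_spanning_pairs(unname(tmpl), reads)
  expect_equal(as.integer(got), sum(reads$truth$spans_ends))
  expect_gte(as.integer(got), 2L)
  # linear topology: no straddling pairs at all
  lin <- simulate_read_pairs(tmpl, "linear", n_pairs = 200, seed = 78)
  expect_equal(as.integer(count_spanning_pairs(unname(tmpl), lin)), 0L)
  expect_false(any(lin$truth$straddles))
})

test_that("straddle rate follows the binomial expectation", {
  tmpl <- setNames(random_seq(5000), "circ")
  reads <- simulate_read_pairs(tmpl, "circular", n_pairs = 200,
                               insert_mean = 300, seed = 79)
  p <- mean(reads$truth$insert) / 5000
  expected <- 200 * p
  sd3 <- 3 * sqrt(200 * p * (1 - p))
  expect_lt(abs(sum(reads$truth$straddles) - expected), sd3 + 1)
})

test_that("the three circularity criteria flip the verdict at their bounds", {
  set.seed(25)
  rep45 <- random_seq(45)
  core <- random_seq(2500)
  scaffold <- paste0(rep45, core, rep45)
  L <- nchar(scaffold)
  mk_span <- function(n) {
    r1 <- character(n); r2 <- character(n)
    for (i in seq_len(n)) {
      r1[i] <- substr(scaffold, L - 200L - i, L - 100L - i)
      r2[i] <- oracle_revcomp(substr(scaffold, 10L + i, 110L + i))
    }
    list(r1 = r1, r2 = r2)
  }
  good <- classify_circular(scaffold, mk_span(3), contig_id = "ok")
  expect_equal(good$verdict, "circular")
  expect_length(good$failed_criteria, 0L)

  # 1,999 bp total, otherwise perfect
  short <- paste0(rep45, random_seq(1999L - 90L), rep45)
  Ls <- nchar(short)
  sp <- list(r1 = substr(short, Ls - 200, Ls - 100),
             r2 = oracle_revcomp(substr(short, 11, 111)))
  sp$r1 <- c(sp$r1, substr(short, Ls - 220, Ls - 120))
  sp$r2 <- c(sp$r2, oracle_revcomp(substr(short, 31, 131)))
  bad_len <- classify_circular(short, sp)
  expect_equal(bad_len$verdict, "not_circular")
  expect_equal(bad_len$failed_criteria, "length")
  # 2,001 bp passes the length criterion
  ok_len <- paste0(rep45, random_seq(2001L - 90L), rep45)
  Lo <- nchar(ok_len)
  sp2 <- list(r1 = c(substr(ok_len, Lo - 200, Lo - 100),
                     substr(ok_len, Lo - 220, Lo - 120)),
              r2 = c(oracle_revcomp(substr(ok_len, 11, 111)),
                     oracle_revcomp(substr(ok_len, 31, 131))))
  expect_equal(classify_circular(ok_len, sp2)$verdict, "circular")

  # only one spanning pair
  one <- classify_circular(scaffold, mk_span(1))
  expect_equal(one$verdict, "not_circular")
  expect_equal(one$failed_criteria, "spanning_pairs")

  # 34-bp terminal repeat fails the repeat criterion
  rep34 <- random_seq(34)
  s34 <- paste0(rep34, core, rep34)
  L34 <- nchar(s34)
  sp34 <- list(r1 = c(substr(s34, L34 - 200, L34 - 100),
                      substr(s34, L34 - 220, L34 - 120)),
               r2 = c(oracle_revcomp(substr(s34, 11, 111)),
                      oracle_revcomp(substr(s34, 31, 131))))
  c34 <- classify_circular(s34, sp34)
  expect_equal(c34$verdict, "not_circular")
  expect_equal(c34$failed_criteria, "terminal_repeat")
})

test_that("more evidence never flips a circular call to not_circular", {
  set.seed(26)
  rep60 <- random_seq(60)
  scaffold <- paste0(rep60, random_seq(2500), rep60)
  L <- nchar(scaffold)
  pairs <- list(r1 = character(0), r2 = character(0))
  verdicts <- character(0)
  for (i in 1:5) {
    pairs$r1 <- c(pairs$r1, substr(scaffold, L - 200L - 7L * i,
                                   L - 100L - 7L * i))
    pairs$r2 <- c(pairs$r2,
                  oracle_revcomp(substr(scaffold, 10L + 7L * i,
                                        110L + 7L * i)))
    verdicts <- c(verdicts, classify_circular(scaffold, pairs)$verdict)
  }
  first_circ <- match("circular", verdicts)
  expect_false(is.na(first_circ))
  expect_true(all(verdicts[first_circ:length(verdicts)] == "circular"))
})

test_that("circular classification is invariant under rotation", {
  set.seed(27)
  core <- random_seq(4000)
  for (shift in c(0L, 1000L, 2500L)) {
    rotated <- paste0(substr(core, shift + 1L, 4000L),
                      substr(core, 1L, shift))
    scaffold <- paste0(rotated, substr(rotated, 1L, 45L))
    reads <- simulate_read_pairs(setNames(rotated, "t"), "circular",
                                 n_pairs = 300, seed = 30 + shift)
    call <- classify_circular(scaffold, reads)
    expect_equal(call$verdict, "circular")
  }
})

test_that("SAM ingestion applies the same windows", {
  set.seed(28)
  contig <- random_seq(4000)
  sam <- file.path(tempdir(), "pairs.sam")
  writeLines(c(
    "@HD\tVN:1.6",
    "@SQ\tSN:ctg\tLN:4000",
    # spanning pair: plus mate at 3850 (1-based 3851), minus mate at 11
    paste("p1", 97, "ctg", 3851, 60, "100M", "=", 11, 0,
          substr(contig, 3851, 3950), strrep("I", 100), sep = "\t"),
    paste("p1", 145, "ctg", 11, 60, "100M", "=", 3851, 0,
          substr(contig, 11, 110), strrep("I", 100), sep = "\t"),
    # non-spanning pair in the middle
    paste("p2", 97, "ctg", 2000, 60, "100M", "=", 2200, 0,
          substr(contig, 2000, 2099), strrep("I", 100), sep = "\t"),
    paste("p2", 145, "ctg", 2200, 60, "100M", "=", 2000, 0,
          substr(contig, 2200, 2299), strrep("I", 100), sep = "\t")),
    sam)
  expect_equal(count_spanning_pairs_sam(sam, "ctg", 4000L), 1L)
})
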