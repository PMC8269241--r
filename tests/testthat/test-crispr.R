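mk_host <- function(strain, len = 60000, seed = 1) {
  set.seed(seed)
  structure(list(strain_id = strain,
                 contigs = setNames(random_seq(len), strain),
                 lineage = NULL, genus_id = NA_character_,
                 n_mutations = 0L),
            class = "host_genome")
}

test_that("planted arrays are detected at exact loci with n-1 spacers", {
  set.seed(41)
  virus <- setNames(random_seq(20000), "vA")
  host <- mk_host("h1", seed = 42)
  rep_seq <- random_seq(28)
  res <- plant_crispr_array(host, rep_seq, n_repeats = 4,
                            spacer_specs = list(
                              list(source = "vA", length = 32,
                                   mismatches = 0),
                              list(source = "random", length = 35),
                              list(source = "random", length = 21)),
                            viruses = virus, seed = 43)
  arr <- detect_crispr_arrays(res$host$contigs, host_strain = "h1")
  expect_length(arr, 1L)
  a <- arr[[1]]
  expect_equal(a$start, res$array$start)
  expect_equal(a$end, res$array$end)
  expect_equal(a$n_repeats, 4L)
  expect_length(a$spacers, 3L)
  expect_equal(a$repeat_consensus, rep_seq)
  expect_equal(paste(a$spacers, collapse = ";"), res$array$spacers)
  # fencepost: repeats + spacers reconstruct the locus
  locus <- substr(res$host$contigs[[1]], a$start + 1L, a$end)
  rebuilt <- paste0(a$repeat_consensus,
                    paste0(a$spacers, a$repeat_consensus, collapse = ""))
  expect_equal(locus, rebuilt)
})

test_that("geometry violations are rejected", {
  set.seed(44)
  host <- mk_host("h1", seed = 45)
  expect_error(plant_crispr_array(host, random_seq(18), 4,
                                  replicate(3, list(source = "random",
                                                    length = 30),
                                            simplify = FALSE),
                                  seed = 1),
               "repeat length")
  expect_error(plant_crispr_array(host, random_seq(28), 2,
                                  list(list(source = "random",
                                            length = 30)), seed = 1),
               "3 repeats")
  expect_error(plant_crispr_array(host, random_seq(28), 4,
                                  replicate(3, list(source = "random",
                                                    length = 18),
                                            simplify = FALSE),
                                  seed = 1),
               "spacer length")
  # an 18-bp repeat physically planted is not detected (below minimum)
  rep18 <- random_seq(18)
  spacers <- replicate(3, random_seq(30))
  arr_seq <- paste0(rep18, spacers[1], rep18, spacers[2], rep18,
                    spacers[3], rep18)
  g <- host$contigs[[1]]
  planted <- paste0(substr(g, 1, 30000), arr_seq,
                    substr(g, 30001, nchar(g)))
  expect_length(detect_crispr_arrays(c(h1 = planted)), 0L)
})

test_that("random genomes contain no spurious arrays", {
  set.seed(46)
  hits <- vapply(1:20, function(i) {
    length(detect_crispr_arrays(c(g = random_seq(100000))))
  }, integer(1))
  expect_true(mean(hits == 0L) >= 0.95)
})

test_that("array detection is strand-symmetric", {
  set.seed(47)
  virus <- setNames(random_seq(20000), "vA")
  host <- mk_host("h1", seed = 48)
  res <- plant_crispr_array(host, random_seq(25), n_repeats = 3,
                            spacer_specs = list(
                              list(source = "vA", length = 30,
                                   mismatches = 1),
                              list(source = "random", length = 40)),
                            viruses = virus, seed = 49)
  g <- res$host$contigs[[1]]
  fwd <- detect_crispr_arrays(c(h = g))
  rc <- detect_crispr_arrays(c(h = oracle_revcomp(g)))
  expect_length(fwd, 1L)
  expect_length(rc, 1L)
  expect_equal(rc[[1]]$start, nchar(g) - fwd[[1]]$end)
  expect_equal(rc[[1]]$end, nchar(g) - fwd[[1]]$start)
  expect_equal(rc[[1]]$repeat_consensus,
               oracle_revcomp(fwd[[1]]$repeat_consensus))
})

test_that("spacer matching allows 0 or 1 mismatch, never 2", {
  set.seed(50)
  viruses <- c(vA = random_seq(15000), vB = random_seq(15000))
  arr <- structure(list(host_strain = "h1", contig = "h1",
                        start = 100L, end = 300L,
                        repeat_consensus = random_seq(25),
                        n_repeats = 4L, spacers = character(3)),
                   class = "crispr_array")
  # spacer 1: exact from vA; spacer 2: 1 mismatch; spacer 3: 2 mismatches
  w <- function(v, at, len) substr(viruses[[v]], at, at + len - 1L)
  s0 <- w("vA", 5001, 30)
  s1int <- phagehost:::seq_to_int(w("vA", 9001, 30))
  s1 <- phagehost:::int_to_seq(phagehost:::mutate_positions(s1int, 7L))
  s2int <- phagehost:::seq_to_int(w("vB", 2001, 30))
  s2 <- phagehost:::int_to_seq(phagehost:::mutate_positions(s2int,
                                                            c(3L, 19L)))
  arr$spacers <- c(s0, s1, s2)
  m <- match_spacers(list(arr), viruses)
  expect_equal(sort(unique(m$spacer_seq)), sort(c(s0, s1)))
  m0 <- m[m$spacer_seq == s0, ]
  expect_equal(m0$mismatches, 0L)
  expect_equal(m0$v_pos, 5000L)
  expect_equal(m0$virus_id, "vA")
  m1 <- m[m$spacer_seq == s1, ]
  expect_equal(m1$mismatches, 1L)
  expect_equal(m1$v_pos, 9000L)
  # a reverse-strand source is found with strand "-" at the right spot
  vrc <- c(vC = oracle_revcomp(viruses[["vA"]]))
  mrc <- match_spacers(list(arr), vrc)
  hit <- mrc[mrc$spacer_seq == s0, ]
  expect_equal(hit$strand, "-")
  expect_equal(hit$v_pos, 15000L - 5000L - 30L)
})

test_that("back-validation keeps only spacers still present in the host", {
  set.seed(51)
  virus <- setNames(random_seq(20000), "vA")
  host <- mk_host("h1", seed = 52)
  res <- plant_crispr_array(host, random_seq(28), n_repeats = 4,
                            spacer_specs = list(
                              list(source = "vA", length = 32,
                                   mismatches = 0),
                              list(source = "vA", length = 30,
                                   mismatches = 0),
                              list(source = "random", length = 21)),
                            viruses = virus, seed = 53)
  arr <- detect_crispr_arrays(res$host$contigs, host_strain = "h1")
  m <- match_spacers(arr, virus)
  expect_equal(nrow(m), 2L)
  hosts <- list(h1 = res$host$contigs)
  p <- predict_host_crispr(m, hosts)
  # two spacers from one array, same virus -> a single prediction
  expect_equal(nrow(p), 1L)
  expect_equal(p$taxon, "h1")
  expect_equal(p$rank, "strain")
  expect_equal(p$n_candidates, 2L)

  # ablate one spacer in the host copy: it must be dropped
  sp <- m$spacer_seq[1]
  ablated <- sub(sp, random_seq(nchar(sp)), res$host$contigs[[1]],
                 fixed = TRUE)
  p2 <- predict_host_crispr(m, list(h1 = c(h1 = ablated)))
  expect_equal(p2$n_candidates, 1L)
  expect_false(any(grepl(sp, p2$evidence, fixed = TRUE)))
  # ablating both spacers removes the prediction entirely
  sp2 <- m$spacer_seq[2]
  ablated2 <- sub(sp2, random_seq(nchar(sp2)), ablated, fixed = TRUE)
  p3 <- predict_host_crispr(m, list(h1 = c(h1 = ablated2)))
  expect_equal(nrow(p3), 0L)
})
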