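test_that("composition models are deterministic and well-formed", {
  m1 <- build_genus_model(123, divergence = 1)
  m2 <- build_genus_model(123, divergence = 1)
  expect_identical(m1$transition_probs, m2$transition_probs)
  expect_true(all(abs(rowSums(m1$transition_probs) - 1) < 1e-9))
  expect_true(all(m1$transition_probs >= 0))
  # huge concentration -> near-uniform next-base distributions
  flat <- build_genus_model(5, divergence = 1e6)
  expect_lt(max(abs(flat$transition_probs - 0.25)), 0.01)
  expect_error(build_genus_model(1, divergence = 0), "concentration")
  expect_error(build_genus_model(1, divergence = -2), "concentration")
})

test_that("host genomes honour length, contigs and mutation rate", {
  m <- build_genus_model(9, genus_id = "G")
  h0a <- generate_host_genome(m, 60000, strain_mutation_rate = 0,
                              seed = 4, strain_id = "a")
  h0b <- generate_host_genome(m, 60000, strain_mutation_rate = 0,
                              seed = 4, strain_id = "b")
  expect_identical(unname(h0a$contigs), unname(h0b$contigs))
  h3 <- generate_host_genome(m, 90000, n_contigs = 3, seed = 5,
                             strain_id = "c")
  expect_length(h3$contigs, 3L)
  expect_equal(sum(nchar(h3$contigs)), 90000L)
  expect_error(generate_host_genome(m, 10, seed = 1), "too short")
  # binomial oracle on the realized substitution fraction
  h <- generate_host_genome(m, 100000, strain_mutation_rate = 0.01,
                            seed = 6, strain_id = "d")
  parent <- generate_host_genome(m, 100000, strain_mutation_rate = 0,
                                 seed = 6, strain_id = "d0")
  frac <- 1 - oracle_identity(h$contigs[[1]], parent$contigs[[1]])
  expect_gte(frac, 0.008)
  expect_lte(frac, 0.012)
  # mutate_positions always changes the base, so the realized fraction
  # equals the number of drawn positions
  expect_equal(frac * 100000, h$n_mutations)
})

test_that("virus generation enforces the observed length span", {
  expect_error(generate_virus(NULL, 3999, seed = 1), "length")
  expect_error(generate_virus(NULL, 300001, seed = 1), "length")
  v <- generate_virus(NULL, 296356, seed = 1, virus_id = "big")
  expect_equal(nchar(v[[1]]), 296356L)
  expect_equal(names(v), "big")
})

test_that("prophage planting conserves length and hits target identity", {
  set.seed(61)
  host <- structure(list(strain_id = "h",
                         contigs = c(h = random_seq(40000)),
                         lineage = NULL, genus_id = NA, n_mutations = 0L),
                    class = "host_genome")
  virus <- setNames(random_seq(10000), "v")
  full <- plant_prophage(host, virus, mode = "full", seed = 2)
  expect_equal(nchar(full$host$contigs[[1]]), 50000L)
  expect_equal(full$truth$relation, "full_prophage")
  # exact copy present at the recorded locus
  at <- full$truth$insert_pos
  expect_equal(substr(full$host$contigs[[1]], at + 1L, at + 10000L),
               unname(virus))

  part <- plant_prophage(host, virus, mode = "partial", region_len = 6000,
                         target_identity = 0.80, seed = 3)
  expect_equal(nchar(part$host$contigs[[1]]), 46000L)
  tr <- part$truth
  planted <- substr(part$host$contigs[[1]], tr$insert_pos + 1L,
                    tr$insert_pos + 6000L)
  source_seg <- substr(unname(virus), tr$v_start + 1L, tr$v_end)
  ident <- oracle_identity(planted, source_seg)
  expect_equal(ident, tr$observed_identity)
  expect_gte(ident, 0.78)
  expect_lte(ident, 0.82)

  expect_error(plant_prophage(host, virus, mode = "partial",
                              region_len = 20000, seed = 1),
               "exceeds virus length")
  expect_error(plant_prophage(host, virus, mode = "partial",
                              region_len = 4000, seed = 1), "4900")
  expect_error(plant_prophage(host, virus, mode = "partial",
                              region_len = 6000, target_identity = 0.5,
                              seed = 1), "0.70")
})

test_that("planted spacers differ from their source by the exact count", {
  set.seed(62)
  virus <- setNames(random_seq(20000), "vA")
  host <- structure(list(strain_id = "h",
                         contigs = c(h = random_seq(40000)),
                         lineage = NULL, genus_id = NA, n_mutations = 0L),
                    class = "host_genome")
  for (mm in 0:2) {
    res <- plant_crispr_array(host, random_seq(28), n_repeats = 4,
                              spacer_specs = list(
                                list(source = "vA", length = 32,
                                     mismatches = mm),
                                list(source = "random", length = 35),
                                list(source = "random", length = 21)),
                              viruses = virus, seed = 70 + mm)
    tr <- res$truth
    src <- substr(virus[[1]], tr$v_start + 1L, tr$v_end)
    dist <- sum(strsplit(tr$spacer_seq, "")[[1]] !=
                  strsplit(src, "")[[1]])
    expect_equal(dist, mm)
    expect_equal(tr$spacer_mismatches, mm)
  }
})

test_that("read simulation honours topology and edge cases", {
  tmpl <- setNames(random_seq(5000), "t")
  expect_error(simulate_read_pairs(tmpl, "circular", 10,
                                   insert_mean = 6000, seed = 1),
               "below template length")
  expect_error(simulate_read_pairs(tmpl, "circular", 10, read_len = 400,
                                   insert_mean = 300, seed = 1),
               "read_len")
  none <- simulate_read_pairs(tmpl, "circular", 0, seed = 1)
  expect_length(none$r1, 0L)
  paths <- write_fastq_pairs(none, file.path(tempdir(), "empty"))
  expect_true(all(file.exists(paths)))
  expect_length(readLines(paths[1]), 0L)

  reads <- simulate_read_pairs(tmpl, "circular", 50, seed = 5)
  expect_length(reads$r1, 50L)
  expect_true(all(nchar(reads$r1) == 100L))
  # reads reconstruct from the recorded fragment coordinates
  tr <- reads$truth[1, ]
  idx <- (tr$start + seq_len(tr$insert) - 1L) %% 5000L + 1L
  frag <- paste(strsplit(tmpl[[1]], "")[[1]][idx], collapse = "")
  expect_true(reads$r1[1] == substr(frag, 1, 100) ||
                reads$r2[1] == substr(frag, 1, 100))
  # FASTQ round trip
  p <- write_fastq_pairs(reads, file.path(tempdir(), "pairs"))
  l1 <- readLines(p[1])
  expect_equal(length(l1), 200L)
  expect_true(all(startsWith(l1[seq(1, 200, 4)], "@")))
  expect_equal(l1[seq(2, 200, 4)], unname(reads$r1))
})

test_that("generation is a pure function of (config, seed)", {
  cfg <- community_config(host_length = 20000,
                          composition_virus_length = 8000,
                          background_virus_length = 6000,
                          n_background = 2)
  c1 <- simulate_community(seed = 11, config = cfg)
  c2 <- simulate_community(seed = 11, config = cfg)
  expect_identical(community_host_seqs(c1), community_host_seqs(c2))
  expect_identical(c1$viruses, c2$viruses)
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$scaffolds[[1]]$reads, c2$scaffolds[[1]]$reads)
  c3 <- simulate_community(seed = 12, config = cfg)
  expect_false(identical(c1$viruses, c3$viruses))
})

test_that("planted coordinates index into the emitted sequences", {
  comm <- default_comm()
  hosts <- default_hosts()
  tr <- comm$truth
  planted <- tr[!is.na(tr$insert_pos), ]
  for (i in seq_len(nrow(planted))) {
    r <- planted[i, ]
    contig <- hosts[[r$true_host_strain]][[r$contig]]
    expect_gte(r$insert_pos, 0L)
    expect_lte(r$insert_pos + r$region_len, nchar(contig))
    if (r$relation == "full_prophage") {
      expect_equal(substr(contig, r$insert_pos + 1L,
                          r$insert_pos + r$region_len),
                   unname(comm$viruses[[r$virus_id]]))
    }
  }
  # CRISPR array loci reconstruct from the arrays table
  for (i in seq_len(nrow(comm$arrays))) {
    a <- comm$arrays[i, ]
    contig <- hosts[[a$host_strain]][[a$contig]]
    locus <- substr(contig, a$start + 1L, a$end)
    spacers <- strsplit(a$spacers, ";")[[1]]
    rebuilt <- paste0(a$repeat_consensus,
                      paste0(spacers, a$repeat_consensus, collapse = ""))
    expect_equal(locus, rebuilt)
  }
})

test_that("truth tables round-trip through TSV", {
  comm <- default_comm()
  path <- file.path(tempdir(), "truth.tsv")
  write_truth(comm$truth, path)
  back <- read_truth(path)
  expect_equal(back, comm$truth, ignore_attr = TRUE)
  # empty truth -> header-only file
  write_truth(phagehost:::empty_truth(), path)
  expect_length(readLines(path), 1L)
  expect_equal(nrow(read_truth(path)), 0L)
})
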