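# The default synthetic study community: 6 genera across 4 phyla (13
# strains), 22 viruses covering every planted signal class, CRISPR arrays,
# negative controls, and read libraries for circularity calls. The
# defaults here ARE the conditions the test-suite properties are stated
# under; see the methods vignette for the rationale behind each value.

#' Default configuration of the synthetic community
#'
#' @param host_length Host genome length in bp (default 100,000; large
#'   enough for stable tetranucleotide statistics).
#' @param strain_mutation_rate Per-base strain-level substitution rate
#'   (default 0.002).
#' @param divergence Dirichlet concentration of the genus composition
#'   models (default 1; calibrated so same-model virus/host 4-mer
#'   distances fall below 0.001 and cross-model distances above it).
#' @param composition_virus_length Length of composition-linked viruses
#'   (default 40,000 bp).
#' @param background_virus_length Length of background viruses (default
#'   20,000 bp).
#' @param n_background Number of background (uniform-composition) viruses
#'   (default 4).
#' @return A named list of generator settings.
#' @export
community_config <- function(host_length = 100000L,
                             strain_mutation_rate = 0.002,
                             divergence = 1,
                             composition_virus_length = 40000L,
                             background_virus_length = 20000L,
                             n_background = 4L) {
  list(host_length = host_length,
       strain_mutation_rate = strain_mutation_rate,
       divergence = divergence,
       composition_virus_length = composition_virus_length,
       background_virus_length = background_virus_length,
       n_background = n_background)
}

# genus/lineage plan of the default community
.community_genera <- function() {
  data.frame(
    genus = c("Pseudomonas", "Acidovorax", "Castellaniella", "Bacillus",
              "Arthrobacter", "Flavobacterium"),
    family = c("Pseudomonadaceae", "Comamonadaceae", "Alcaligenaceae",
               "Bacillaceae", "Micrococcaceae", "Flavobacteriaceae"),
    order = c("Pseudomonadales", "Burkholderiales", "Burkholderiales",
              "Bacillales", "Micrococcales", "Flavobacteriales"),
    class = c("Gammaproteobacteria", "Betaproteobacteria",
              "Betaproteobacteria", "Bacilli", "Actinomycetia",
              "Flavobacteriia"),
    phylum = c("Proteobacteria", "Proteobacteria", "Proteobacteria",
               "Firmicutes", "Actinobacteria", "Bacteroidetes"),
    n_strains = c(2L, 3L, 2L, 2L, 2L, 2L),
    stringsAsFactors = FALSE)
}

#' Simulate the default synthetic virus-host community
#'
#' Builds the full study community: 13 host strains in 6 genera (4 phyla)
#' emitted from genus-specific composition models; 22 viruses comprising 6
#' composition-linked viruses (one per genus), 3 full prophages (one
#' integrated into all 3 Acidovorax strains), 4 partial prophages (6-kb
#' regions at identities 0.75 / 0.85 / 0.95 / 1.0), 2 below-threshold
#' negative controls (4.5 kb at 0.95 and 6 kb at 0.65), 3 CRISPR-targeted
#' viruses (spacers planted at 0, 1 and 2 mismatches), and 4 background
#' viruses; plus two read libraries over a circular and a linear scaffold.
#' Everything is a deterministic function of `(seed, config)`.
#'
#' @param seed Integer master seed; per-component seeds derive from it.
#' @param config From [community_config()].
#' @return A `synthetic_community` list: `hosts` (named list of
#'   `host_genome`), `lineage` (data.frame), `tree` (`taxonomy_tree`),
#'   `viruses` (named character), `truth`, `arrays`, `cluster_map`
#'   (data.frames), `scaffolds` (list of id, sequence, topology, reads),
#'   `seed`, `config`.
#' @export
simulate_community <- function(seed = 1L, config = community_config()) {
  genera <- .community_genera()
  models <- lapply(seq_len(nrow(genera)), function(i) {
    build_genus_model(child_seed(seed, paste0("model_", genera$genus[i])),
                      divergence = config$divergence,
                      genus_id = genera$genus[i])
  })
  names(models) <- genera$genus

  hosts <- list()
  lineage <- NULL
  for (i in seq_len(nrow(genera))) {
    for (j in seq_len(genera$n_strains[i])) {
      sid <- sprintf("%s_GW%d", genera$genus[i], j)
      lin <- c(phylum = genera$phylum[i], class = genera$class[i],
               order = genera$order[i], family = genera$family[i],
               genus = genera$genus[i],
               species = sprintf("%s_sp%d", genera$genus[i], j))
      n_contigs <- if (sid == "Pseudomonas_GW1") 2L else 1L
      hosts[[sid]] <- generate_host_genome(
        models[[i]], length = config$host_length,
        strain_mutation_rate = config$strain_mutation_rate,
        n_contigs = n_contigs, seed = child_seed(seed, sid),
        strain_id = sid, lineage = lin)
      lineage <- rbind(lineage, data.frame(strain_id = sid, t(lin),
                                           stringsAsFactors = FALSE))
    }
  }
  tree <- load_taxonomy(lineage)
  truth <- empty_truth()
  arrays <- NULL
  # keep previously planted loci valid when a later insertion lands
  # upstream of them in the same contig
  shift_loci <- function(strain, contig, pos0, len) {
    if (nrow(truth)) {
      hit <- !is.na(truth$insert_pos) & truth$true_host_strain == strain &
        truth$contig == contig & truth$insert_pos >= pos0
      truth$insert_pos[hit] <<- truth$insert_pos[hit] + len
    }
    if (!is.null(arrays) && nrow(arrays)) {
      hit <- arrays$host_strain == strain & arrays$contig == contig &
        arrays$start >= pos0
      arrays$start[hit] <<- arrays$start[hit] + len
      arrays$end[hit] <<- arrays$end[hit] + len
    }
  }
  viruses <- character(0)
  vnum <- 0L
  new_vid <- function() {
    vnum <<- vnum + 1L
    sprintf("vOTU_%03d", vnum)
  }
  add_virus <- function(model, length, link_host = NULL) {
    vid <- new_vid()
    v <- generate_virus(model, length, seed = child_seed(seed, vid),
                        virus_id = vid)
    viruses <<- c(viruses, v)
    if (!is.null(link_host)) {
      truth <<- rbind(truth, truth_row(vid, link_host, "composition_only"))
    }
    vid
  }
  # 6 composition-linked viruses, one per genus (linked to first strain)
  comp_ids <- vapply(genera$genus, function(g) {
    add_virus(models[[g]], config$composition_virus_length,
              link_host = sprintf("%s_GW1", g))
  }, character(1))

  plant_full <- function(vid, strains) {
    for (s in strains) {
      res <- plant_prophage(hosts[[s]], viruses[vid], mode = "full",
                            seed = child_seed(seed, paste0(vid, "_", s)))
      hosts[[s]] <<- res$host
      shift_loci(s, res$truth$contig, res$truth$insert_pos,
                 res$truth$region_len)
      truth <<- rbind(truth, res$truth)
    }
  }
  # 3 full prophages; the first integrated into all 3 Acidovorax strains
  fp1 <- add_virus(models[["Acidovorax"]], 12000L, "Acidovorax_GW1")
  fp2 <- add_virus(models[["Pseudomonas"]], 15000L, "Pseudomonas_GW1")
  fp3 <- add_virus(models[["Bacillus"]], 8000L, "Bacillus_GW1")
  plant_full(fp1, paste0("Acidovorax_GW", 1:3))
  plant_full(fp2, "Pseudomonas_GW1")
  plant_full(fp3, "Bacillus_GW1")

  plant_partial <- function(vid, s, region_len, identity,
                            relation = NULL, validate = TRUE) {
    res <- plant_prophage(hosts[[s]], viruses[vid], mode = "partial",
                          region_len = region_len,
                          target_identity = identity,
                          seed = child_seed(seed, paste0(vid, "_", s)),
                          .relation = relation, .validate = validate)
    hosts[[s]] <<- res$host
    shift_loci(s, res$truth$contig, res$truth$insert_pos,
               res$truth$region_len)
    truth <<- rbind(truth, res$truth)
  }
  # 4 partial prophages at graded identities
  pp <- data.frame(
    host = c("Castellaniella_GW1", "Arthrobacter_GW1",
             "Flavobacterium_GW1", "Pseudomonas_GW2"),
    identity = c(0.75, 0.85, 0.95, 1.0), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pp))) {
    g <- sub("_GW\\d+$", "", pp$host[i])
    vid <- add_virus(models[[g]], 12000L, pp$host[i])
    plant_partial(vid, pp$host[i], 6000L, pp$identity[i])
  }
  # 2 negative controls: below the length / identity thresholds
  nc1 <- add_virus(NULL, 12000L)
  plant_partial(nc1, "Bacillus_GW2", 4500L, 0.95,
                relation = "negative_control", validate = FALSE)
  nc2 <- add_virus(NULL, 12000L)
  plant_partial(nc2, "Acidovorax_GW1", 6000L, 0.65,
                relation = "negative_control", validate = FALSE)

  # 3 CRISPR-targeted viruses at 0 / 1 / 2 spacer mismatches
  cr <- data.frame(host = c("Pseudomonas_GW1", "Bacillus_GW1",
                            "Flavobacterium_GW2"),
                   mm = 0:2, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cr))) {
    g <- sub("_GW\\d+$", "", cr$host[i])
    vid <- add_virus(models[[g]], 30000L, cr$host[i])
    set.seed(child_seed(seed, paste0("repeat_", vid)))
    rep_seq <- random_dna(28L)
    res <- plant_crispr_array(
      hosts[[cr$host[i]]], rep_seq, n_repeats = 4L,
      spacer_specs = list(
        list(source = vid, length = 32L, mismatches = cr$mm[i]),
        list(source = "random", length = 35L),
        list(source = "random", length = 21L)),
      viruses = viruses, seed = child_seed(seed, paste0("array_", vid)))
    hosts[[cr$host[i]]] <- res$host
    shift_loci(cr$host[i], res$array$contig, res$array$start,
               res$array$end - res$array$start)
    arrays <- rbind(arrays, res$array)
    truth <- rbind(truth, res$truth)
  }

  # 4 background viruses (no planted relationship)
  bg_ids <- vapply(seq_len(config$n_background), function(i) {
    add_virus(NULL, config$background_virus_length)
  }, character(1))

  # circularity scaffolds: a circular 6-kb template (terminal 45-bp
  # repeat appended to its scaffold) and a linear 20-kb one
  circ_template <- generate_virus(NULL, 6000L,
                                  seed = child_seed(seed, "circ_template"),
                                  virus_id = "scaffold_circ")
  circ_scaffold <- setNames(paste0(unname(circ_template),
                                   substr(circ_template, 1L, 45L)),
                            "scaffold_circ")
  lin_template <- viruses[bg_ids[1L]]
  scaffolds <- list(
    list(id = "scaffold_circ", sequence = circ_scaffold,
         topology = "circular",
         reads = simulate_read_pairs(circ_template, "circular", 400L,
                                     seed = child_seed(seed, "circ_reads"))),
    list(id = bg_ids[1L], sequence = lin_template, topology = "linear",
         reads = simulate_read_pairs(lin_template, "linear", 200L,
                                     seed = child_seed(seed, "lin_reads"))))

  # viral clusters: per-genus clusters for composition viruses plus one
  # mixed Burkholderiales + Pseudomonadales cluster
  cluster_map <- data.frame(
    virus_id = c(comp_ids[["Pseudomonas"]], comp_ids[["Acidovorax"]],
                 fp1, fp2, fp3,
                 comp_ids[["Bacillus"]], comp_ids[["Flavobacterium"]]),
    cluster_id = c("VC_mixed", "VC_mixed",
                   "VC_acido", "VC_pseudo", "VC_bacillus",
                   "VC_bacillus", "VC_flavo"),
    stringsAsFactors = FALSE)

  structure(list(hosts = hosts, lineage = lineage, tree = tree,
                 viruses = viruses, truth = truth,
                 arrays = arrays %||% data.frame(),
                 cluster_map = cluster_map, scaffolds = scaffolds,
                 seed = seed, config = config),
            class = "synthetic_community")
}

#' @export
print.synthetic_community <- function(x, ...) {
  cat("<synthetic_community> ", length(x$hosts), " hosts, ",
      length(x$viruses), " viruses, ", nrow(x$truth),
      " truth records (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Host sequences of a community as a plain list
#'
#' @param comm A `synthetic_community`.
#' @return Named list strain -> character vector of contigs, the layout the
#'   prediction functions consume.
#' @export
community_host_seqs <- function(comm) {
  lapply(comm$hosts, function(h) h$contigs)
}

#' Write ground-truth tables as TSV
#'
#' @param truth A truth data.frame (e.g. `comm$truth`).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Read back a truth table written by [write_truth()]
#'
#' @param path TSV path.
#' @return data.frame with the truth-table column types restored.
#' @export
read_truth <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE,
                   colClasses = "character", na.strings = "")
  template <- empty_truth()
  for (cl in names(template)) {
    if (!cl %in% names(df)) next
    df[[cl]] <- switch(class(template[[cl]]),
                       integer = as.integer(df[[cl]]),
                       numeric = as.numeric(df[[cl]]),
                       df[[cl]])
  }
  df
}

#' Write a community to disk (FASTA / FASTQ / TSV)
#'
#' Writes host genomes (`hosts.fasta`, contigs named `strain|contig`),
#' viruses (`viruses.fasta`), the lineage table, truth tables, the cluster
#' map, and the scaffold read libraries as paired FASTQ.
#'
#' @param comm A `synthetic_community`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_community <- function(comm, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  host_seqs <- do.call(c, unname(lapply(comm$hosts, function(h) {
    setNames(h$contigs, paste0(h$strain_id, "|", names(h$contigs)))
  })))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(host_seqs),
                              file.path(dir, "hosts.fasta"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(comm$viruses),
                              file.path(dir, "viruses.fasta"))
  write.table(comm$lineage, file.path(dir, "lineage.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_truth(comm$truth, file.path(dir, "truth.tsv"))
  write.table(comm$arrays, file.path(dir, "arrays_truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(comm$cluster_map, file.path(dir, "cluster_map.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (sc in comm$scaffolds) {
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(sc$sequence),
      file.path(dir, paste0("scaffold_", sc$id, ".fasta")))
    write_fastq_pairs(sc$reads, file.path(dir, paste0("scaffold_", sc$id)))
  }
  invisible(dir)
}
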