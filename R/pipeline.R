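# Pipeline orchestration: run every stage over a community (simulated or
# loaded), merge per-method host predictions into a consensus, and report
# within-viral-cluster host consistency. All outputs are TSVs with headers
# plus a JSON manifest; outputs are a deterministic function of
# (config, seed) and independent of the `threads` setting.

.METHOD_PRIORITY <- c(crispr = 1L, blast99 = 2L, blast = 3L, `4mer` = 4L)
.RANK_DEPTH <- c(root = 1L, domain = 2L, phylum = 3L, class = 4L,
                 order = 5L, family = 6L, genus = 7L, species = 8L,
                 strain = 9L)

#' Merge per-method host predictions into a consensus table
#'
#' One row per virus with at least one prediction row (including explicit
#' no-calls). Strain-level methods (crispr, blast99) may emit several
#' strain rows per virus; these are collapsed to the lowest common
#' ancestor of the called strains for that method's column.
#' `genus_agreement` is computed over the methods that made a call:
#' `agree` when all calling methods' assignments, each taken at genus rank
#' (or at its own, shallower rank), lie on one root-to-leaf lineage chain;
#' `disagree` otherwise; `single-method` when only one method called.
#' `best_rank_call` is the deepest-rank assignment, ties broken by method
#' confidence (crispr > blast99 > blast > 4mer).
#'
#' @param predictions data.frame of prediction rows from the per-method
#'   predictors (shared dialect), stacked.
#' @param tree The `taxonomy_tree` the assignments refer to.
#' @return data.frame: `virus_id`, `taxon_4mer`, `rank_4mer`,
#'   `taxon_blast`, `rank_blast`, `taxon_blast99`, `rank_blast99`,
#'   `taxon_crispr`, `rank_crispr`, `n_methods`, `genus_agreement`,
#'   `best_method`, `best_taxon`, `best_rank`.
#' @export
consensus <- function(predictions, tree) {
  stopifnot(all(predictions$method %in% names(.METHOD_PRIORITY)))
  called <- predictions[predictions$status == "predicted", , drop = FALSE]
  dup <- duplicated(called[, c("virus_id", "method", "taxon")])
  called <- called[!dup, , drop = FALSE]
  # conflicting duplicate rows are an input error for LCA-rank methods
  for (m in c("4mer", "blast")) {
    key <- called$virus_id[called$method == m]
    if (anyDuplicated(key)) {
      stop("conflicting duplicate predictions for method ", m, ": ",
           paste(unique(key[duplicated(key)]), collapse = ", "))
    }
  }
  rows <- list()
  for (v in unique(predictions$virus_id)) {
    sub <- called[called$virus_id == v, , drop = FALSE]
    per <- list()
    for (m in names(.METHOD_PRIORITY)) {
      ms <- sub[sub$method == m, , drop = FALSE]
      if (nrow(ms) == 0L) {
        per[[m]] <- NULL
      } else if (nrow(ms) == 1L) {
        per[[m]] <- list(taxon = ms$taxon, rank = ms$rank,
                         node = find_node(tree, ms$taxon, ms$rank))
      } else {
        node <- lca_nodes(tree, vapply(seq_len(nrow(ms)), function(i) {
          find_node(tree, ms$taxon[i], ms$rank[i])
        }, integer(1)))
        per[[m]] <- list(taxon = node$name, rank = node$rank,
                         node = node$taxon_id)
      }
    }
    calling <- names(per)[!vapply(per, is.null, logical(1))]
    agreement <- if (length(calling) <= 1L) "single-method" else {
      pts <- vapply(calling, function(m) {
        node <- per[[m]]$node
        g <- ancestor_at_rank(tree, node, "genus")
        if (is.na(g)) node else g
      }, integer(1))
      deepest <- pts[which.max(tree$nodes$depth[pts])]
      if (all(vapply(pts, is_ancestor, logical(1), tree = tree,
                     id = deepest))) "agree" else "disagree"
    }
    best <- NA_character_
    if (length(calling)) {
      depth <- vapply(calling, function(m) {
        .RANK_DEPTH[[per[[m]]$rank]]
      }, integer(1))
      prio <- .METHOD_PRIORITY[calling]
      best <- calling[order(-depth, prio)][1L]
    }
    g <- function(m, f) if (is.null(per[[m]])) NA_character_ else per[[m]][[f]]
    rows[[length(rows) + 1L]] <- data.frame(
      virus_id = v,
      taxon_4mer = g("4mer", "taxon"), rank_4mer = g("4mer", "rank"),
      taxon_blast = g("blast", "taxon"), rank_blast = g("blast", "rank"),
      taxon_blast99 = g("blast99", "taxon"),
      rank_blast99 = g("blast99", "rank"),
      taxon_crispr = g("crispr", "taxon"), rank_crispr = g("crispr", "rank"),
      n_methods = length(calling), genus_agreement = agreement,
      best_method = best,
      best_taxon = if (is.na(best)) NA_character_ else per[[best]]$taxon,
      best_rank = if (is.na(best)) NA_character_ else per[[best]]$rank,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out[out$n_methods > 0L, , drop = FALSE]
}

#' Host-prediction consistency within viral clusters
#'
#' For each viral cluster (a genus-level grouping of viruses supplied as a
#' virus -> cluster map), takes the members' best-rank host assignments
#' and reduces them to their lowest common ancestor; the LCA's rank is the
#' rank at which the cluster's host predictions are consistent. Members
#' without predictions are counted but excluded from the LCA; clusters
#' where only one member has a prediction are flagged (`n_predicted`).
#'
#' @param consensus_rows data.frame from [consensus()].
#' @param cluster_map data.frame with columns `virus_id`, `cluster_id`.
#' @param tree The `taxonomy_tree`.
#' @return data.frame: `cluster_id`, `n_members`, `n_predicted`,
#'   `member_viruses`, `member_taxa`, `cluster_lca`, `consistent_at_rank`.
#' @export
cluster_consistency <- function(consensus_rows, cluster_map, tree) {
  stopifnot(all(c("virus_id", "cluster_id") %in% names(cluster_map)))
  rows <- list()
  for (cl in unique(cluster_map$cluster_id)) {
    members <- cluster_map$virus_id[cluster_map$cluster_id == cl]
    sub <- consensus_rows[consensus_rows$virus_id %in% members &
                            !is.na(consensus_rows$best_taxon), ,
                          drop = FALSE]
    missing <- setdiff(members, sub$virus_id)
    if (length(missing)) {
      message("cluster ", cl, ": no prediction for ",
              paste(missing, collapse = ", "))
    }
    if (nrow(sub) == 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        cluster_id = cl, n_members = length(members), n_predicted = 0L,
        member_viruses = paste(members, collapse = ";"),
        member_taxa = "", cluster_lca = NA_character_,
        consistent_at_rank = NA_character_, stringsAsFactors = FALSE)
      next
    }
    ids <- vapply(seq_len(nrow(sub)), function(i) {
      find_node(tree, sub$best_taxon[i], sub$best_rank[i])
    }, integer(1))
    node <- lca_nodes(tree, ids)
    rows[[length(rows) + 1L]] <- data.frame(
      cluster_id = cl, n_members = length(members),
      n_predicted = nrow(sub),
      member_viruses = paste(members, collapse = ";"),
      member_taxa = paste(sub$best_taxon, collapse = ";"),
      cluster_lca = node$name, consistent_at_rank = node$rank,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Run the full pipeline over a community
#'
#' Orchestrates every stage -- simulation (or user-supplied inputs),
#' circularity calls, the three host-prediction methods, optional
#' annotation curation, consensus and cluster consistency -- and writes
#' all outputs as TSVs plus a JSON run manifest (parameters, package
#' version, output checksums). Outputs are byte-identical across reruns
#' with the same config and do not depend on `threads` (stages execute
#' serially; the flag exists for interface compatibility).
#'
#' @param config A list (or path to a YAML/JSON file) with entries:
#'   `seed` (integer, required), `community` (list passed to
#'   [community_config()]), `stages` (subset of "circularity", "kmer",
#'   "similarity", "crispr", "annotate", "consensus"; default all),
#'   `domtblout` (optional path for the annotation stage), optional
#'   threshold overrides `d_max`, `top_n`, `min_bit`, `max_e`, `min_len`,
#'   `min_ident`, and optionally `inputs` -- a list of paths (`viruses`
#'   FASTA, `hosts` FASTA with `strain|contig` names, `lineage` TSV,
#'   optional `cluster_map` TSV) to analyse instead of the simulated
#'   community (the circularity stage is skipped then, since it needs
#'   read libraries).
#' @param out_dir Output directory.
#' @param threads Ignored beyond validation; results are independent of it.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_all <- function(config = list(seed = 1L), out_dir, threads = 1L) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  errs <- character(0)
  if (is.null(config$seed)) errs <- c(errs, "config$seed is required")
  if (!is.null(config$domtblout) && !file.exists(config$domtblout)) {
    errs <- c(errs, paste0("domtblout not found: ", config$domtblout))
  }
  if (!is.null(config$inputs)) {
    for (f in c("viruses", "hosts", "lineage")) {
      if (is.null(config$inputs[[f]])) {
        errs <- c(errs, paste0("inputs$", f, " path is required"))
      } else if (!file.exists(config$inputs[[f]])) {
        errs <- c(errs, paste0(f, " file not found: ", config$inputs[[f]]))
      }
    }
  }
  if (length(errs)) stop(paste(errs, collapse = "; "))
  stages <- config$stages %||% c("circularity", "kmer", "similarity",
                                 "crispr", "annotate", "consensus")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  comm <- if (is.null(config$inputs)) {
    simulate_community(as.integer(config$seed),
                       do.call(community_config,
                               config$community %||% list()))
  } else {
    load_community_inputs(config$inputs)
  }
  hosts <- community_host_seqs(comm)
  tsv <- function(df, name) {
    write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE, na = "")
    name
  }
  written <- c(tsv(comm$truth, "truth.tsv"),
               tsv(comm$lineage, "lineage.tsv"))
  results <- list(community = comm)

  if ("circularity" %in% stages && length(comm$scaffolds)) {
    calls <- do.call(rbind, lapply(comm$scaffolds, function(sc) {
      cc <- classify_circular(sc$sequence, sc$reads, contig_id = sc$id)
      data.frame(contig_id = cc$contig_id, length_bp = cc$length_bp,
                 terminal_repeat_len = cc$terminal_repeat_len,
                 spanning_pairs = cc$spanning_pairs, verdict = cc$verdict,
                 failed_criteria = paste(cc$failed_criteria,
                                         collapse = ","),
                 stringsAsFactors = FALSE)
    }))
    results$circularity <- calls
    written <- c(written, tsv(calls, "circularity.tsv"))
    message("circularity: ", sum(calls$verdict == "circular"), "/",
            nrow(calls), " scaffolds circular")
  }

  preds <- list()
  if ("kmer" %in% stages) {
    db <- host_kmer_db(hosts)
    preds$kmer <- do.call(rbind, lapply(names(comm$viruses), function(v) {
      predict_host_kmer(comm$viruses[[v]], db, comm$tree,
                        d_max = config$d_max %||% 0.001,
                        top_n = config$top_n %||% 5, virus_id = v)
    }))
    written <- c(written, tsv(preds$kmer, "predictions_4mer.tsv"))
    message("4mer: ", sum(preds$kmer$status == "predicted"), "/",
            nrow(preds$kmer), " viruses assigned")
  }
  if ("similarity" %in% stages) {
    scheme <- scoring_scheme()
    sim <- lapply(names(comm$viruses), function(v) {
      regions <- regions_vs_db(comm$viruses[[v]], hosts, scheme,
                               virus_id = v)
      rbind(predict_host_blast(comm$viruses[[v]], hosts, comm$tree, scheme,
                               min_bit = config$min_bit %||% 50,
                               max_e = config$max_e %||% 0.001,
                               min_len = config$min_len %||% 4900,
                               min_ident = config$min_ident %||% 0.70,
                               virus_id = v, regions = regions),
            predict_host_blast99(comm$viruses[[v]], hosts, scheme,
                                 virus_id = v, regions = regions))
    })
    preds$similarity <- do.call(rbind, sim)
    written <- c(written, tsv(preds$similarity, "predictions_blast.tsv"))
    message("blast/blast99: ",
            sum(preds$similarity$status == "predicted"), " calls")
  }
  if ("crispr" %in% stages) {
    arrays <- list()
    for (s in names(hosts)) {
      arrays <- c(arrays, detect_crispr_arrays(hosts[[s]],
                                               host_strain = s))
    }
    matches <- match_spacers(arrays, comm$viruses)
    preds$crispr <- predict_host_crispr(matches, hosts)
    no_call <- setdiff(names(comm$viruses), preds$crispr$virus_id)
    if (length(no_call)) {
      preds$crispr <- rbind(preds$crispr, do.call(rbind, lapply(
        no_call, prediction_row, method = "crispr", status = "no_call")))
    }
    written <- c(written, tsv(preds$crispr, "predictions_crispr.tsv"))
    message("crispr: ", length(arrays), " arrays, ",
            sum(preds$crispr$status == "predicted"), " strain calls")
  }
  if ("annotate" %in% stages && !is.null(config$domtblout)) {
    hits <- filter_hits(read_domain_hits(config$domtblout))
    cats <- categorize(hits)
    results$annotation <- cats
    written <- c(written, tsv(cats, "annotation_categories.tsv"),
                 tsv(category_matrix(cats), "annotation_matrix.tsv"))
  }
  if ("consensus" %in% stages && length(preds)) {
    all_preds <- do.call(rbind, unname(preds))
    cons <- consensus(all_preds, comm$tree)
    results$consensus <- cons
    written <- c(written, tsv(cons, "consensus.tsv"))
    cc <- cluster_consistency(cons, comm$cluster_map, comm$tree)
    results$cluster_consistency <- cc
    written <- c(written, tsv(cc, "cluster_consistency.tsv"))
  }
  results$predictions <- preds

  manifest <- list(
    package = "phagehost",
    version = as.character(utils::packageVersion("phagehost")),
    seed = as.integer(config$seed),
    stages = stages,
    parameters = config[setdiff(names(config), "stages")],
    outputs = as.list(tools::md5sum(file.path(out_dir, written))))
  names(manifest$outputs) <- written
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}

# Assemble a community-shaped object from user-supplied files. Host FASTA
# records are grouped into strains on the `strain|contig` name convention
# (a name without "|" is a single-contig strain).
load_community_inputs <- function(inputs) {
  vset <- Biostrings::readDNAStringSet(inputs$viruses)
  viruses <- setNames(as.character(vset), sub("\\s.*$", "", names(vset)))
  hset <- Biostrings::readDNAStringSet(inputs$hosts)
  hnames <- sub("\\s.*$", "", names(hset))
  strain <- sub("\\|.*$", "", hnames)
  contig <- ifelse(grepl("\\|", hnames), sub("^[^|]*\\|", "", hnames),
                   hnames)
  hosts <- lapply(split(seq_along(hset), strain), function(i) {
    setNames(as.character(hset[i]), contig[i])
  })
  lineage <- read.delim(inputs$lineage, sep = "\t", header = TRUE,
                        colClasses = "character")
  cluster_map <- if (!is.null(inputs$cluster_map)) {
    read.delim(inputs$cluster_map, sep = "\t", header = TRUE,
               colClasses = "character")
  } else {
    data.frame(virus_id = character(0), cluster_id = character(0),
               stringsAsFactors = FALSE)
  }
  list(hosts = lapply(names(hosts), function(s) {
         structure(list(strain_id = s, contigs = hosts[[s]],
                        lineage = NULL, genus_id = NA_character_,
                        n_mutations = NA_integer_), class = "host_genome")
       }) |> setNames(names(hosts)),
       lineage = lineage, tree = load_taxonomy(lineage),
       viruses = viruses, truth = empty_truth(),
       arrays = data.frame(), cluster_map = cluster_map,
       scaffolds = list(), seed = NA_integer_, config = NULL)
}
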