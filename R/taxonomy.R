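# Taxonomy store: a rooted, rank-labelled tree over strain lineages, with
# lowest-common-ancestor queries used by every host-prediction method.

.RANKS <- c("domain", "phylum", "class", "order", "family", "genus",
            "species", "strain")

#' Load a strain taxonomy from a lineage table
#'
#' Builds a rooted taxonomy tree from a tab-separated lineage table with one
#' row per strain. Identical lineage prefixes share nodes, so lowest common
#' ancestors are well defined. Blank cells denote missing intermediate ranks
#' and are collapsed: a strain with no species attaches directly to its
#' genus, and so on. Names are matched case-sensitively after whitespace
#' trimming.
#'
#' @param table Path to a TSV with header, or a data.frame. Must contain a
#'   `strain_id` column; recognised rank columns are `domain`, `phylum`,
#'   `class`, `order`, `family`, `genus`, `species` (any subset, in any
#'   order; `domain` is optional and usually absent for all-bacterial sets).
#' @return An object of class `taxonomy_tree` with a `nodes` data.frame
#'   (id, name, rank, parent, depth) rooted at node 1.
#' @export
load_taxonomy <- function(table) {
  df <- if (is.character(table)) {
    read.delim(table, sep = "\t", header = TRUE, colClasses = "character",
               check.names = FALSE)
  } else {
    as.data.frame(table, stringsAsFactors = FALSE)
  }
  if (!"strain_id" %in% names(df)) {
    stop("lineage table must have a 'strain_id' column")
  }
  rank_cols <- intersect(.RANKS[.RANKS != "strain"], names(df))

  ids <- integer(0); names_ <- character(0); ranks <- character(0)
  parents <- integer(0); depths <- integer(0)
  new_node <- function(name, rank, parent) {
    id <- length(ids) + 1L
    ids[id] <<- id; names_[id] <<- name; ranks[id] <<- rank
    parents[id] <<- parent
    depths[id] <<- if (id == 1L) 0L else depths[parent] + 1L
    id
  }
  new_node("Root", "root", 0L)
  key2id <- new.env(parent = emptyenv())
  strain_lineage <- new.env(parent = emptyenv())

  for (i in seq_len(nrow(df))) {
    strain <- trimws(df$strain_id[i])
    if (strain == "") stop("blank strain_id at row ", i)
    vals <- trimws(unlist(df[i, rank_cols, drop = TRUE]))
    keep <- !is.na(vals) & vals != ""
    lineage <- paste(rank_cols[keep], vals[keep], sep = ":", collapse = "|")
    if (!is.null(strain_lineage[[strain]])) {
      if (!identical(strain_lineage[[strain]], lineage)) {
        stop("duplicate strain id with conflicting lineage: ", strain)
      }
      next
    }
    strain_lineage[[strain]] <- lineage
    parent <- 1L
    key <- ""
    for (j in which(keep)) {
      key <- paste0(key, "|", rank_cols[j], ":", vals[j])
      id <- key2id[[key]]
      if (is.null(id)) {
        id <- new_node(vals[j], rank_cols[j], parent)
        key2id[[key]] <- id
      }
      parent <- id
    }
    skey <- paste0(key, "|strain:", strain)
    if (!is.null(key2id[[skey]])) stop("duplicate strain node: ", strain)
    key2id[[skey]] <- new_node(strain, "strain", parent)
  }

  nodes <- data.frame(id = ids, name = names_, rank = ranks,
                      parent = parents, depth = depths,
                      stringsAsFactors = FALSE)
  strain_idx <- setNames(nodes$id[nodes$rank == "strain"],
                         nodes$name[nodes$rank == "strain"])
  structure(list(nodes = nodes, strain_index = strain_idx),
            class = "taxonomy_tree")
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat("<taxonomy_tree> ", sum(x$nodes$rank == "strain"), " strains, ",
      nrow(x$nodes), " nodes\n", sep = "")
  invisible(x)
}

# Root-to-node path of node ids (root first).
node_path <- function(tree, id) {
  path <- integer(0)
  while (id != 0L) {
    path <- c(id, path)
    id <- tree$nodes$parent[id]
  }
  path
}

strain_node_id <- function(tree, strain) {
  id <- tree$strain_index[strain]
  if (any(is.na(id))) {
    stop("unknown strain id(s): ",
         paste(strain[is.na(id)], collapse = ", "))
  }
  unname(id)
}

as_taxon_node <- function(tree, id) {
  row <- tree$nodes[id, ]
  structure(list(taxon_id = row$id, name = row$name, rank = row$rank,
                 depth = row$depth, unresolved = identical(row$rank, "root")),
            class = "taxon_node")
}

#' @export
print.taxon_node <- function(x, ...) {
  cat("<taxon_node> ", x$name, " [", x$rank, "]",
      if (x$unresolved) " (unresolved)", "\n", sep = "")
  invisible(x)
}

#' Lowest common ancestor of a set of strains
#'
#' Returns the deepest taxonomy node ancestral to every strain in `taxa`.
#' The result may sit at any rank (genus, family, class, ...) depending on
#' where the lineages diverge. Invariant under permutation and duplication
#' of the input. If the strains only meet at the root (e.g. hits spanning
#' domains), the root node is returned with `unresolved = TRUE` rather than
#' guessing a rank.
#'
#' @param taxa Non-empty character vector of strain ids present in `tree`.
#' @param tree A `taxonomy_tree` from [load_taxonomy()].
#' @return A `taxon_node` list: `taxon_id`, `name`, `rank`, `depth`,
#'   `unresolved`.
#' @export
lca <- function(taxa, tree) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  if (length(taxa) == 0L) stop("lca() requires a non-empty strain set")
  ids <- strain_node_id(tree, unique(taxa))
  common <- node_path(tree, ids[1L])
  for (id in ids[-1L]) {
    common <- intersect(common, node_path(tree, id))
  }
  as_taxon_node(tree, common[length(common)])
}

# LCA over arbitrary node ids (used by consensus / cluster summaries).
lca_nodes <- function(tree, node_ids) {
  node_ids <- unique(node_ids)
  common <- node_path(tree, node_ids[1L])
  for (id in node_ids[-1L]) {
    common <- intersect(common, node_path(tree, id))
  }
  as_taxon_node(tree, common[length(common)])
}

# Look up a node id by (name, rank); names are unique within a rank in the
# lineage dialect used here.
find_node <- function(tree, name, rank) {
  hit <- which(tree$nodes$name == name & tree$nodes$rank == rank)
  if (length(hit) == 0L) stop("no taxonomy node ", name, " at rank ", rank)
  hit[1L]
}

# Is `anc` (node id) an ancestor of (or equal to) node id `id`?
is_ancestor <- function(tree, anc, id) {
  anc %in% node_path(tree, id)
}

# Ancestor of node `id` at `rank`, or NA if the lineage lacks that rank.
ancestor_at_rank <- function(tree, id, rank) {
  path <- node_path(tree, id)
  hit <- path[tree$nodes$rank[path] == rank]
  if (length(hit) == 0L) NA_integer_ else hit[1L]
}
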