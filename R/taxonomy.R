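# Taxonomy representation: a rooted, rank-labelled tree plus a genome -> leaf
# taxon map. Ranks live on the fixed ladder species < genus < family < order <
# class < phylum < superkingdom < root; lineages may skip ranks, never invert
# them. "root" (and NCBI's "cellular organisms") collapse into one root node
# that assignment never reports.

.LADDER <- c("species", "genus", "family", "order", "class", "phylum",
             "superkingdom", "root")

#' Taxonomic ranks, most to least specific
#'
#' @param include_root logical; append the synthetic `"root"` rank.
#' @return character vector of rank names.
#' @export
ladder_ranks <- function(include_root = FALSE) {
  if (include_root) .LADDER else .LADDER[-length(.LADDER)]
}

rank_pos <- function(rank) match(rank, .LADDER)

#' Next rank up the ladder
#'
#' Successor of a rank on species -> genus -> family -> order -> class ->
#' phylum -> superkingdom; `superkingdom` has no successor (classification
#' falls through to "unassigned" there).
#'
#' @param rank a rank name below `"root"`.
#' @return the next less specific rank, or `NA_character_` for superkingdom.
#' @export
next_higher_rank <- function(rank) {
  i <- rank_pos(rank)
  if (is.na(i) || rank == "root") stop("not a ladder rank: ", rank)
  if (rank == "superkingdom") return(NA_character_)
  .LADDER[i + 1L]
}

#' Construct a taxonomy
#'
#' @param nodes data.frame with columns `taxon_id`, `name`, `rank`,
#'   `parent_id` (`NA` for the root only). Exactly one root node of rank
#'   `"root"` is required; parent ranks must be strictly less specific than
#'   child ranks (ranks may be skipped).
#' @param genome_to_taxon named character vector mapping genome identifiers to
#'   leaf `taxon_id`s.
#' @return an object of class `"taxonomy"`.
#' @export
taxonomy <- function(nodes, genome_to_taxon = character()) {
  stopifnot(is.data.frame(nodes),
            all(c("taxon_id", "name", "rank", "parent_id") %in% names(nodes)))
  nodes <- data.frame(taxon_id = as.character(nodes$taxon_id),
                      name = as.character(nodes$name),
                      rank = as.character(nodes$rank),
                      parent_id = as.character(nodes$parent_id),
                      stringsAsFactors = FALSE)
  if (anyDuplicated(nodes$taxon_id))
    stop("duplicated taxon_id in taxonomy nodes")
  if (!all(nodes$rank %in% .LADDER))
    stop("unknown rank(s): ", paste(setdiff(nodes$rank, .LADDER), collapse = ", "))
  root <- nodes$taxon_id[is.na(nodes$parent_id)]
  if (length(root) != 1L || nodes$rank[match(root, nodes$taxon_id)] != "root")
    stop("taxonomy must have exactly one parentless node of rank 'root'")
  known <- nodes$parent_id %in% nodes$taxon_id | is.na(nodes$parent_id)
  if (!all(known))
    stop("parent_id not found for: ",
         paste(nodes$taxon_id[!known], collapse = ", "))
  obj <- structure(list(nodes = nodes,
                        root = root,
                        idx = setNames(seq_len(nrow(nodes)), nodes$taxon_id),
                        genome_to_taxon = genome_to_taxon),
                   class = "taxonomy")
  # walk every lineage once: catches cycles and rank inversions
  for (id in nodes$taxon_id) {
    lin <- lineage(obj, id)
    if (any(diff(rank_pos(lin$rank)) <= 0))
      stop("rank inversion on lineage of ", id)
  }
  if (length(genome_to_taxon)) {
    miss <- !(genome_to_taxon %in% nodes$taxon_id)
    if (any(miss))
      stop("genome(s) mapped to unknown taxa: ",
           paste(names(genome_to_taxon)[miss], collapse = ", "))
  }
  obj
}

node_field <- function(tree, ids, field) {
  tree$nodes[[field]][tree$idx[ids]]
}

#' Lineage of a taxon
#'
#' Walks parent links from a node to the root.
#'
#' @param tree a [taxonomy()].
#' @param taxon_id a taxon identifier present in `tree`.
#' @return data.frame with columns `rank`, `taxon_id`, `name`, ordered from
#'   the node itself up to the root.
#' @export
lineage <- function(tree, taxon_id) {
  i <- unname(tree$idx[as.character(taxon_id)])
  if (is.na(i)) stop("unknown taxon_id: ", taxon_id)
  ids <- character(); ranks <- character(); nms <- character()
  n <- nrow(tree$nodes)
  steps <- 0L
  while (!is.na(i)) {
    ids <- c(ids, tree$nodes$taxon_id[i])
    ranks <- c(ranks, tree$nodes$rank[i])
    nms <- c(nms, tree$nodes$name[i])
    steps <- steps + 1L
    if (steps > n) stop("cycle detected in taxonomy at ", taxon_id)
    p <- tree$nodes$parent_id[i]
    i <- if (is.na(p)) NA_integer_ else tree$idx[[p]]
  }
  data.frame(rank = ranks, taxon_id = ids, name = nms, stringsAsFactors = FALSE)
}

#' Reduce a taxon to a given rank
#'
#' Returns the ancestor (or the node itself) whose rank equals `rank`, or
#' `NA_character_` when the lineage skips that rank. Callers that must always
#' land somewhere use [reduce_or_ancestor()], which falls back to the nearest
#' present ancestor above the requested rank.
#'
#' @inheritParams lineage
#' @param rank target rank on the ladder.
#' @return a `taxon_id` or `NA_character_`.
#' @export
reduce_to_rank <- function(tree, taxon_id, rank) {
  if (!rank %in% .LADDER) stop("not a ladder rank: ", rank)
  lin <- lineage(tree, taxon_id)
  hit <- which(lin$rank == rank)
  if (length(hit)) lin$taxon_id[hit[1L]] else NA_character_
}

#' Reduce to a rank, falling back to the nearest present higher rank
#'
#' Vectorized over `taxon_ids`. Where a lineage has no node at the requested
#' rank (rank-sparse lineages), the nearest ancestor *above* that rank is
#' returned instead, so every fragment keeps contributing to convergence
#' counting rather than being dropped.
#'
#' @param tree a [taxonomy()].
#' @param taxon_ids character vector of taxon identifiers.
#' @param rank target rank.
#' @return character vector of taxon ids (possibly of ranks above `rank`).
#' @export
reduce_or_ancestor <- function(tree, taxon_ids, rank) {
  want <- rank_pos(rank)
  if (is.na(want)) stop("not a ladder rank: ", rank)
  uniq <- unique(as.character(taxon_ids))
  res <- vapply(uniq, function(id) {
    lin <- lineage(tree, id)
    pos <- rank_pos(lin$rank)
    hit <- which(pos == want)
    if (length(hit)) return(lin$taxon_id[hit[1L]])
    above <- which(pos > want)
    lin$taxon_id[above[1L]]       # root guarantees this exists
  }, character(1))
  unname(res[match(as.character(taxon_ids), uniq)])
}

#' Read a flat lineage table
#'
#' Tab-separated, UTF-8, one genome per line, header
#' `genome_id<TAB>superkingdom<TAB>phylum<TAB>class<TAB>order<TAB>family<TAB>genus<TAB>species`.
#' Empty fields mean the lineage skips that rank. Taxon names double as taxon
#' identifiers, so a name may not recur under two different parents.
#'
#' @param path file path.
#' @return a [taxonomy()]; each genome maps to its most specific named taxon.
#' @export
read_lineage_tsv <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  cols <- c("genome_id", "superkingdom", "phylum", "class", "order",
            "family", "genus", "species")
  if (!all(cols %in% names(tab)))
    stop("lineage TSV must have columns: ", paste(cols, collapse = ", "))
  ranks_desc <- cols[-1]                 # least to most specific
  nodes <- data.frame(taxon_id = "root", name = "root", rank = "root",
                      parent_id = NA_character_, stringsAsFactors = FALSE)
  seen_parent <- c(root = NA_character_); names(seen_parent) <- "root"
  g2t <- character()
  for (r in seq_len(nrow(tab))) {
    parent <- "root"
    leaf <- NA_character_
    for (rk in ranks_desc) {
      nm <- tab[[rk]][r]
      if (is.na(nm) || nm == "") next
      if (nm %in% nodes$taxon_id) {
        if (nodes$parent_id[match(nm, nodes$taxon_id)] != parent ||
            nodes$rank[match(nm, nodes$taxon_id)] != rk)
          stop("taxon name '", nm, "' recurs with a different parent or rank")
      } else {
        nodes <- rbind(nodes, data.frame(taxon_id = nm, name = nm, rank = rk,
                                         parent_id = parent,
                                         stringsAsFactors = FALSE))
      }
      parent <- nm
      leaf <- nm
    }
    if (is.na(leaf)) stop("genome ", tab$genome_id[r], " has an empty lineage")
    g2t[tab$genome_id[r]] <- leaf
  }
  taxonomy(nodes, g2t)
}

#' Write the flat lineage table dialect of [read_lineage_tsv()]
#'
#' @param tree a [taxonomy()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_lineage_tsv <- function(tree, path) {
  cols <- c("superkingdom", "phylum", "class", "order", "family", "genus",
            "species")
  rows <- lapply(names(tree$genome_to_taxon), function(g) {
    lin <- lineage(tree, tree$genome_to_taxon[[g]])
    out <- setNames(as.list(c(g, rep("", length(cols)))), c("genome_id", cols))
    for (i in seq_len(nrow(lin)))
      if (lin$rank[i] %in% cols) out[[lin$rank[i]]] <- lin$name[i]
    as.data.frame(out, stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read an NCBI-style nodes.dmp/names.dmp pair
#'
#' Alternative loader for the NCBI taxonomy dump dialect
#' (`<field>\t|\t<field>...` records). Nodes outside the 8-rank ladder are
#' collapsed onto their nearest ladder ancestor; `"cellular organisms"` and
#' the NCBI root both collapse into the single root node.
#'
#' @param nodes_path path to `nodes.dmp`.
#' @param names_path path to `names.dmp` (scientific names are used).
#' @param genome_to_taxid named character vector, genome id -> NCBI taxid.
#' @return a [taxonomy()].
#' @export
read_ncbi_dmp <- function(nodes_path, names_path, genome_to_taxid = character()) {
  parse_dmp <- function(p) {
    lines <- readLines(p, warn = FALSE)
    lapply(strsplit(sub("\t\\|$", "", lines), "\t\\|\t"), trimws)
  }
  nrec <- parse_dmp(nodes_path)
  taxid <- vapply(nrec, `[`, character(1), 1L)
  parent <- vapply(nrec, `[`, character(1), 2L)
  rank <- vapply(nrec, `[`, character(1), 3L)
  mrec <- parse_dmp(names_path)
  sci <- vapply(mrec, function(x) length(x) >= 4 && x[4] == "scientific name",
                logical(1))
  nm <- setNames(vapply(mrec[sci], `[`, character(1), 2L),
                 vapply(mrec[sci], `[`, character(1), 1L))
  parent_of <- setNames(parent, taxid)
  rank_of <- setNames(rank, taxid)
  # climb to the nearest ladder-ranked ancestor (root included)
  ladder_anc <- function(id) {
    seen <- 0L
    while (seen < length(taxid) + 1L) {
      if (identical(parent_of[[id]], id)) return("root-sentinel")
      if (rank_of[[id]] %in% .LADDER[-length(.LADDER)]) return(id)
      id <- parent_of[[id]]
      seen <- seen + 1L
    }
    stop("cycle in nodes.dmp")
  }
  keep <- taxid[rank_of %in% .LADDER[-length(.LADDER)]]
  nodes <- data.frame(taxon_id = "root", name = "root", rank = "root",
                      parent_id = NA_character_, stringsAsFactors = FALSE)
  for (id in keep) {
    p <- parent_of[[id]]
    p <- if (identical(p, id)) "root-sentinel" else ladder_anc(p)
    nodes <- rbind(nodes, data.frame(
      taxon_id = id,
      name = if (!is.null(nm[[id]]) && !is.na(nm[id])) nm[[id]] else id,
      rank = rank_of[[id]],
      parent_id = if (p == "root-sentinel") "root" else p,
      stringsAsFactors = FALSE))
  }
  g2t <- character()
  for (g in names(genome_to_taxid)) {
    id <- as.character(genome_to_taxid[[g]])
    if (!id %in% nodes$taxon_id) id <- ladder_anc(id)
    if (id == "root-sentinel")
      stop("genome ", g, " maps to no ladder-ranked taxon")
    g2t[g] <- id
  }
  taxonomy(nodes, g2t)
}

#' @export
print.taxonomy <- function(x, ...) {
  tab <- table(factor(x$nodes$rank, levels = rev(.LADDER)))
  cat("Taxonomy:", nrow(x$nodes), "nodes,",
      length(x$genome_to_taxon), "genomes\n")
  cat(paste(sprintf("  %-13s %d", names(tab), as.integer(tab)),
            collapse = "\n"), "\n")
  invisible(x)
}
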