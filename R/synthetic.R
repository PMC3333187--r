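# Synthetic genomes, taxonomies and reads. Genomes are order-3 Markov chains
# so tetranucleotide statistics are under direct control; clade models are
# derived by perturbing a root model recursively down the taxonomy, making
# expected compositional distance grow with the rank of two genomes' lowest
# common ancestor -- the signal the classifier exploits. A leave-clade-out
# helper reproduces the modified-reference-database evaluation design at toy
# scale. All generators are pure functions of their seeds.

#' Balanced synthetic taxonomy
#'
#' Rank-complete tree superkingdom -> phylum -> class -> order -> family ->
#' genus with deterministic dotted names (`p0`, `p0.c1`, ..., ending at e.g.
#' `p0.c1.o0.f1.g0`) and one genome per genus (`<genus>.G0`).
#'
#' @param n_phyla,classes_per_phylum,orders_per_class,families_per_order,genera_per_family
#'   branching factors, all >= 1.
#' @param seed unused source of randomness (the tree is deterministic); kept
#'   so all generators share one signature style.
#' @return a [taxonomy()].
#' @export
make_taxonomy <- function(n_phyla = 4L, classes_per_phylum = 2L,
                          orders_per_class = 2L, families_per_order = 2L,
                          genera_per_family = 2L, seed = 1L) {
  stopifnot(n_phyla >= 1, classes_per_phylum >= 1, orders_per_class >= 1,
            families_per_order >= 1, genera_per_family >= 1)
  nodes <- data.frame(taxon_id = c("root", "sk0"), name = c("root", "sk0"),
                      rank = c("root", "superkingdom"),
                      parent_id = c(NA_character_, "root"),
                      stringsAsFactors = FALSE)
  add <- function(id, rank, parent)
    nodes <<- rbind(nodes, data.frame(taxon_id = id, name = id, rank = rank,
                                      parent_id = parent,
                                      stringsAsFactors = FALSE))
  g2t <- character()
  for (p in seq_len(n_phyla) - 1L) {
    pid <- sprintf("p%d", p); add(pid, "phylum", "sk0")
    for (cc in seq_len(classes_per_phylum) - 1L) {
      cid <- sprintf("%s.c%d", pid, cc); add(cid, "class", pid)
      for (o in seq_len(orders_per_class) - 1L) {
        oid <- sprintf("%s.o%d", cid, o); add(oid, "order", cid)
        for (f in seq_len(families_per_order) - 1L) {
          fid <- sprintf("%s.f%d", oid, f); add(fid, "family", oid)
          for (g in seq_len(genera_per_family) - 1L) {
            gid <- sprintf("%s.g%d", fid, g); add(gid, "genus", fid)
            g2t[sprintf("%s.G0", gid)] <- gid
          }
        }
      }
    }
  }
  taxonomy(nodes, g2t)
}

#' Composition model: order-3 Markov chain over A/C/G/T
#'
#' @param weights 64 x 4 matrix of positive next-base weights, one row per
#'   3-base context (contexts in base-4 order, A=0..T=3). Rows are
#'   renormalized to sum to 1.
#' @param label identifier.
#' @return an object of class `"composition_model"`.
#' @export
composition_model <- function(weights, label = "model") {
  weights <- as.matrix(weights)
  if (!all(dim(weights) == c(64L, 4L))) stop("weights must be 64 x 4")
  if (any(weights <= 0)) stop("weights must be positive")
  structure(list(weights = weights / rowSums(weights), label = label),
            class = "composition_model")
}

#' Root composition model with concentrated 4-mer usage
#'
#' Transition rows are drawn from a Gamma(shape = `alpha`) prior and
#' renormalized (a Dirichlet(`alpha`) draw per context). Small `alpha`
#' concentrates the stationary tetranucleotide distribution, mimicking the
#' skewed oligonucleotide usage of real genomes; the default 0.3 puts the
#' distance of a read to fragments of its own genome well below the Sanger
#' genus threshold.
#'
#' @param alpha Gamma shape (> 0), default 0.3.
#' @param seed integer seed.
#' @return a `"composition_model"`.
#' @export
root_composition_model <- function(alpha = 0.3, seed = 1L) {
  set.seed(seed)
  composition_model(matrix(rgamma(256L, shape = alpha) + 1e-8, 64L, 4L),
                    label = "root")
}

perturb_model <- function(model, sigma) {
  w <- model$weights * exp(matrix(rnorm(256L, 0, sigma), 64L, 4L))
  w
}

#' Derive per-genus composition models down a taxonomy
#'
#' Starting from a root model, every child clade multiplies its parent's
#' transition weights by independent log-normal noise with sd
#' `divergence_per_rank` (then renormalizes), at each of the phylum, class,
#' order, family and genus levels. Perturbations accumulate along branches,
#' so the expected Manhattan distance between two genomes increases with the
#' rank of their lowest common ancestor.
#'
#' @param tree a [taxonomy()] (typically [make_taxonomy()]).
#' @param divergence_per_rank log-scale sd of the per-rank noise (> 0),
#'   default 0.4.
#' @param root a `"composition_model"`; default [root_composition_model()]
#'   seeded from `seed`.
#' @param seed integer seed.
#' @return named list, genus `taxon_id` -> `"composition_model"`.
#' @export
derive_clade_models <- function(tree, divergence_per_rank = 0.4,
                                root = NULL, seed = 1L) {
  stopifnot(divergence_per_rank >= 0)
  if (is.null(root)) root <- root_composition_model(seed = seed)
  set.seed(seed + 1L)
  models <- list()
  recurse <- function(node_id, w) {
    kids <- tree$nodes$taxon_id[!is.na(tree$nodes$parent_id) &
                                  tree$nodes$parent_id == node_id]
    rk <- node_field(tree, node_id, "rank")
    if (rk == "genus" || !length(kids)) {
      if (rk == "genus")
        models[[node_id]] <<- composition_model(w, label = node_id)
      return(invisible())
    }
    for (kid in kids) {
      wk <- if (divergence_per_rank > 0)
        composition_model(perturb_model(composition_model(w), divergence_per_rank))$weights
      else w
      recurse(kid, wk)
    }
  }
  recurse(tree$root, root$weights)
  models
}

#' Simulate a genome sequence from a composition model
#'
#' @param model a `"composition_model"`.
#' @param length sequence length (> 3).
#' @param seed integer seed; the draw is a pure function of it.
#' @return a DNA string (character).
#' @export
simulate_genome <- function(model, length, seed = 1L) {
  stopifnot(inherits(model, "composition_model"), length > 3)
  set.seed(seed)
  markov_sample(as.integer(length), model$weights)
}

# Real prokaryotic genomes approximately satisfy Chargaff's second rule at
# genome scale because coding regions switch strands; a raw Markov draw does
# not, which would make reverse-strand reads compositionally alien to every
# forward-counted fragment. Assembling genomes from alternating forward /
# reverse-complement blocks restores that strand structure.
strand_balanced_genome <- function(model, length, seed, block = 25000L) {
  raw <- simulate_genome(model, length, seed)
  starts <- seq.int(1L, nchar(raw), by = block)
  parts <- substring(raw, starts, pmin(starts + block - 1L, nchar(raw)))
  flip <- seq_along(parts) %% 2L == 0L
  if (any(flip))
    parts[flip] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(parts[flip])))
  paste0(parts, collapse = "")
}

#' Simulate a synthetic genome collection
#'
#' Builds the balanced taxonomy, derives per-genus composition models and
#' simulates one genome per genus. Each genome is assembled from
#' alternating forward and reverse-complement 25 kb blocks of its genus
#' model, emulating the strand-switching of coding regions that makes real
#' genomes obey Chargaff's second rule; reads from either strand then find
#' compositionally matching fragments under forward-only counting. The
#' defaults (4 phyla x 2 x 2 x 2 x 2 = 64 genera, 200 kb genomes) give
#' ~12,800 reference fragments, a scale at which the whole pipeline builds
#' and classifies in minutes.
#'
#' @inheritParams make_taxonomy
#' @param genome_length bp per genome.
#' @param divergence_per_rank see [derive_clade_models()].
#' @param alpha see [root_composition_model()].
#' @param seed master seed; all internal seeds derive from it.
#' @return an object of class `"simulated_collection"`: list with
#'   `taxonomy`, `genomes` (named character vector), `models`,
#'   `removed_clades` (empty data.frame) and `excluded_genomes` (empty).
#' @export
simulate_collection <- function(n_phyla = 4L, classes_per_phylum = 2L,
                                orders_per_class = 2L, families_per_order = 2L,
                                genera_per_family = 2L,
                                genome_length = 200000L,
                                divergence_per_rank = 0.4, alpha = 0.3,
                                seed = 1L) {
  tree <- make_taxonomy(n_phyla, classes_per_phylum, orders_per_class,
                        families_per_order, genera_per_family, seed)
  root <- root_composition_model(alpha, seed)
  models <- derive_clade_models(tree, divergence_per_rank, root, seed)
  genomes <- character()
  gmap <- tree$genome_to_taxon
  for (i in seq_along(gmap)) {
    g <- names(gmap)[i]
    genomes[g] <- strand_balanced_genome(models[[gmap[[g]]]], genome_length,
                                         seed = seed + 17L * i)
  }
  structure(list(taxonomy = tree, genomes = genomes, models = models,
                 removed_clades = data.frame(rank = character(),
                                             taxon_id = character(),
                                             stringsAsFactors = FALSE),
                 excluded_genomes = character()),
            class = "simulated_collection")
}

#' @export
print.simulated_collection <- function(x, ...) {
  cat("Simulated collection:", length(x$genomes), "genomes (",
      nchar(x$genomes[[1]]), "bp each ),",
      nrow(x$removed_clades), "removed clade(s)\n")
  invisible(x)
}

representation_status <- function(tree, genome_ids, removed_clades) {
  if (!nrow(removed_clades)) return(rep("known", length(genome_ids)))
  vapply(genome_ids, function(g) {
    lin <- lineage(tree, tree$genome_to_taxon[[g]])
    hit <- removed_clades$taxon_id %in% lin$taxon_id
    if (!any(hit)) return("known")
    # label by the least specific removed rank affecting this genome
    rks <- removed_clades$rank[hit]
    paste0(rks[which.max(rank_pos(rks))], "_unknown")
  }, character(1), USE.NAMES = FALSE)
}

#' Mark clades as absent from the reference database
#'
#' All genomes under each removed taxon are excluded from index building
#' while their reads stay in the query set, emulating queries from organisms
#' with no database representation at a known rank. Truth tables produced by
#' [simulate_reads()] on the returned collection carry a
#' `"<rank>_unknown"` status for affected reads.
#'
#' @param collection a `"simulated_collection"`.
#' @param removals data.frame with columns `rank`, `taxon_id` (taxa present
#'   in the collection's taxonomy).
#' @return the modified collection.
#' @export
make_leaveout <- function(collection, removals) {
  stopifnot(inherits(collection, "simulated_collection"),
            all(c("rank", "taxon_id") %in% names(removals)))
  tree <- collection$taxonomy
  bad <- !(removals$taxon_id %in% tree$nodes$taxon_id)
  if (any(bad))
    stop("removal taxa not in taxonomy: ",
         paste(removals$taxon_id[bad], collapse = ", "))
  excl <- names(tree$genome_to_taxon)[vapply(
    names(tree$genome_to_taxon), function(g)
      any(removals$taxon_id %in% lineage(tree, tree$genome_to_taxon[[g]])$taxon_id),
    logical(1))]
  if (length(excl) == length(tree$genome_to_taxon))
    stop("removals would exclude every genome; the index would be empty")
  collection$removed_clades <- removals[, c("rank", "taxon_id")]
  collection$excluded_genomes <- excl
  collection
}

#' Simulate reads with a truth table
#'
#' Reads are drawn uniformly over start positions (genomes weighted by their
#' number of valid start positions) and strands; substitution errors are
#' i.i.d. per base at `error_rate` (no indels). The truth table records each
#' read's source genome, true leaf taxon and representation status with
#' respect to the collection's removed clades.
#'
#' @param x a `"simulated_collection"`, or a named character vector /
#'   `DNAStringSet` of genomes.
#' @param n_reads number of reads.
#' @param read_length read length in bp; the nominal technology lengths are
#'   800, 400, 250 and 100.
#' @param error_rate per-base substitution probability in `[0, 1)`.
#' @param seed integer seed.
#' @param tree taxonomy used to resolve leaf taxa when `x` is not a
#'   collection (optional).
#' @return list with `reads` (named character vector) and `truth`
#'   (data.frame: `read_id`, `genome_id`, `taxon_id`, `strand`, `start`,
#'   `status`).
#' @export
simulate_reads <- function(x, n_reads, read_length = 800L, error_rate = 0,
                           seed = 1L, tree = NULL) {
  if (inherits(x, "simulated_collection")) {
    tree <- x$taxonomy
    genomes <- x$genomes
    removed <- x$removed_clades
  } else {
    genomes <- setNames(as.character(x), names(x))
    removed <- data.frame(rank = character(), taxon_id = character(),
                          stringsAsFactors = FALSE)
  }
  stopifnot(n_reads >= 1, error_rate >= 0, error_rate < 1)
  glen <- nchar(genomes)
  if (any(glen < read_length))
    stop("read_length ", read_length, " exceeds the shortest genome (",
         min(glen), " bp)")
  set.seed(seed)
  n_pos <- glen - read_length + 1L
  gi <- sample.int(length(genomes), n_reads, replace = TRUE,
                   prob = n_pos / sum(n_pos))
  start <- vapply(gi, function(j) sample.int(n_pos[j], 1L), integer(1))
  strand <- sample(c("+", "-"), n_reads, replace = TRUE)
  seqs <- substring(genomes[gi], start, start + read_length - 1L)
  rc <- strand == "-"
  if (any(rc))
    seqs[rc] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs[rc])))
  if (error_rate > 0) {
    mat <- matrix(unlist(strsplit(seqs, ""), use.names = FALSE),
                  nrow = n_reads, byrow = TRUE)
    hit <- which(matrix(runif(length(mat)) < error_rate, nrow = n_reads))
    if (length(hit)) {
      bases <- c("A", "C", "G", "T")
      repl <- vapply(mat[hit], function(b)
        sample(setdiff(bases, b), 1L), character(1))
      mat[hit] <- repl
    }
    seqs <- apply(mat, 1L, paste0, collapse = "")
  }
  ids <- sprintf("read_%05d", seq_len(n_reads))
  gids <- names(genomes)[gi]
  taxa <- if (!is.null(tree)) unname(tree$genome_to_taxon[gids]) else
    rep(NA_character_, n_reads)
  status <- if (!is.null(tree))
    representation_status(tree, gids, removed) else rep("known", n_reads)
  list(reads = setNames(seqs, ids),
       truth = data.frame(read_id = ids, genome_id = gids, taxon_id = taxa,
                          strand = strand, start = start, status = status,
                          stringsAsFactors = FALSE))
}

#' Fragment and index a simulated collection
#'
#' Convenience wrapper: fragments all genomes not excluded by
#' [make_leaveout()] and builds the clustered index against the collection's
#' taxonomy.
#'
#' @param collection a `"simulated_collection"`.
#' @param k,seed passed to [build_index()].
#' @param fragment_length,min_fragment_length,strand passed to
#'   [fragment_genomes()].
#' @return a `"fragment_index"`.
#' @export
index_collection <- function(collection, k = NULL, seed = 1L,
                             fragment_length = 1000L,
                             min_fragment_length = 500L,
                             strand = "forward") {
  keep <- setdiff(names(collection$genomes), collection$excluded_genomes)
  frags <- fragment_genomes(collection$genomes[keep], fragment_length,
                            min_fragment_length, strand)
  build_index(frags, collection$taxonomy, k = k, seed = seed)
}

#' Write a collection and reads to disk
#'
#' Emits the on-disk artifact set: one FASTA per genome under
#' `dir/genomes/`, `lineage.tsv`, `reads.fasta`, `truth.tsv` and
#' `removals.tsv`.
#'
#' @param collection a `"simulated_collection"`.
#' @param reads result of [simulate_reads()] (or `NULL` to skip reads).
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_collection <- function(collection, reads = NULL, dir) {
  dir.create(file.path(dir, "genomes"), recursive = TRUE, showWarnings = FALSE)
  for (g in names(collection$genomes)) {
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(setNames(collection$genomes[g], g)),
      file.path(dir, "genomes", paste0(g, ".fasta")))
  }
  write_lineage_tsv(collection$taxonomy, file.path(dir, "lineage.tsv"))
  write.table(collection$removed_clades, file.path(dir, "removals.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(reads)) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(reads$reads),
                                file.path(dir, "reads.fasta"))
    write.table(reads$truth, file.path(dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
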