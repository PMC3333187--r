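# Reference fragment database: genomes are split into non-overlapping 1 kb
# windows, each window's tetranucleotide vector is computed, and the vectors
# are k-means clustered so classification only scans the nearest cluster.
# The index also carries the per-rank database representation table (R_i)
# used by the normalization step.

INDEX_FORMAT <- "tetrabin-index/1"

new_fragment_set <- function(info, freq, n_counted, strand,
                             fragment_length, min_fragment_length) {
  structure(list(info = info, freq = freq, n_counted = n_counted,
                 strand = strand, fragment_length = fragment_length,
                 min_fragment_length = min_fragment_length),
            class = "fragment_set")
}

#' Split one genome into fixed-length fragments
#'
#' Consecutive non-overlapping windows `[0, L)`, `[L, 2L)`, ... in 0-based
#' half-open coordinates; a trailing window shorter than
#' `min_fragment_length` is discarded. Multi-record genomes (a
#' `DNAStringSet` with several contigs) are split per record, never across
#' contig boundaries.
#'
#' @param genome_id genome identifier attached to every fragment.
#' @param seq a DNA string or `DNAStringSet` of contigs.
#' @param fragment_length window length in bp (default 1000).
#' @param min_fragment_length shortest trailing window kept (default 500).
#' @param strand passed to the composition counter, see [tetra_vector()].
#' @return a `"fragment_set"`: fragment table (`info`), 4-mer frequency
#'   matrix (`freq`, one row per fragment) and valid-window counts.
#' @export
split_genome <- function(genome_id, seq, fragment_length = 1000L,
                         min_fragment_length = 500L,
                         strand = c("forward", "symmetric")) {
  strand <- match.arg(strand)
  if (fragment_length < min_fragment_length || min_fragment_length < 4L)
    stop("need fragment_length >= min_fragment_length >= 4")
  contigs <- as_dna_set(seq)
  pieces <- list(); starts <- integer(); ends <- integer(); contig_i <- integer()
  for (ci in seq_along(contigs)) {
    L <- Biostrings::width(contigs)[ci]
    if (L < min_fragment_length) next
    st <- seq.int(0L, L - 1L, by = fragment_length)
    en <- pmin(st + fragment_length, L)
    keep <- (en - st) >= min_fragment_length
    st <- st[keep]; en <- en[keep]
    if (!length(st)) next
    pieces[[length(pieces) + 1L]] <-
      Biostrings::extractAt(contigs[[ci]],
                            IRanges::IRanges(start = st + 1L, end = en))
    starts <- c(starts, st); ends <- c(ends, en)
    contig_i <- c(contig_i, rep.int(ci, length(st)))
  }
  if (!length(pieces)) {
    info <- data.frame(fragment_id = character(), genome_id = character(),
                       contig = integer(), start = integer(), end = integer(),
                       stringsAsFactors = FALSE)
    return(new_fragment_set(info, matrix(numeric(), 0, 256,
                                         dimnames = list(NULL, KMER_NAMES)),
                            integer(), strand, fragment_length,
                            min_fragment_length))
  }
  frag_seqs <- do.call(c, pieces)
  tm <- tetra_matrix(frag_seqs, strand)
  info <- data.frame(
    fragment_id = sprintf("%s:%d:%d-%d", genome_id, contig_i, starts, ends),
    genome_id = genome_id, contig = contig_i, start = starts, end = ends,
    stringsAsFactors = FALSE)
  # fragments >= min length always contain >= 1 clean window in practice;
  # drop degenerate ones (e.g. all-N stretches) defensively
  ok <- tm$n_counted > 0L
  new_fragment_set(info[ok, , drop = FALSE],
                   tm$freq[ok, , drop = FALSE], tm$n_counted[ok],
                   strand, fragment_length, min_fragment_length)
}

#' Fragment a genome collection
#'
#' @param genomes a named `DNAStringSet`/character vector (names are genome
#'   ids; repeated names are contigs of one genome), a named list of
#'   `DNAStringSet`s, or a path to a directory of FASTA files (one genome per
#'   file, file stem = genome id).
#' @inheritParams split_genome
#' @return a `"fragment_set"` covering all genomes.
#' @export
fragment_genomes <- function(genomes, fragment_length = 1000L,
                             min_fragment_length = 500L,
                             strand = c("forward", "symmetric")) {
  strand <- match.arg(strand)
  if (is.character(genomes) && length(genomes) == 1L && dir.exists(genomes)) {
    files <- sort(list.files(genomes, pattern = "\\.(fa|fasta|fna)(\\.gz)?$",
                             full.names = TRUE))
    if (!length(files)) stop("no FASTA files under ", genomes)
    genomes <- lapply(files, Biostrings::readDNAStringSet)
    names(genomes) <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(files))
  }
  if (!is.list(genomes)) {
    if (is.null(names(genomes)) || any(names(genomes) == ""))
      stop("genomes must be named by genome id")
    genomes <- split(as_dna_set(genomes), names(genomes))
  }
  sets <- lapply(names(genomes), function(g)
    split_genome(g, genomes[[g]], fragment_length, min_fragment_length, strand))
  new_fragment_set(do.call(rbind, lapply(sets, `[[`, "info")),
                   do.call(rbind, lapply(sets, `[[`, "freq")),
                   unlist(lapply(sets, `[[`, "n_counted"), use.names = FALSE),
                   strand, fragment_length, min_fragment_length)
}

#' @export
print.fragment_set <- function(x, ...) {
  cat("Fragment set:", nrow(x$info), "fragments from",
      length(unique(x$info$genome_id)), "genome(s);",
      x$fragment_length, "bp windows (min", x$min_fragment_length, "bp),",
      x$strand, "strand\n")
  invisible(x)
}

# deterministic k-means++ seeding (squared Euclidean weighting)
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1L] <- sample.int(n, 1L)
  d2 <- colSums((t(x) - x[centers[1L], ])^2)
  if (k > 1L) for (i in 2:k) {
    if (all(d2 == 0)) {
      centers[i] <- sample.int(n, 1L)
    } else {
      centers[i] <- sample.int(n, 1L, prob = d2)
    }
    d2 <- pmin(d2, colSums((t(x) - x[centers[i], ])^2))
  }
  x[centers, , drop = FALSE]
}

representation_table <- function(leaf_taxa, tree) {
  n <- length(leaf_taxa)
  out <- lapply(ladder_ranks(), function(rk) {
    bucket <- reduce_or_ancestor(tree, leaf_taxa, rk)
    tab <- table(bucket)
    data.frame(rank = rk, taxon_id = names(tab),
               n_fragments = as.integer(tab),
               percent = 100 * as.integer(tab) / n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Build the clustered reference index
#'
#' Clusters the fragment vectors with k-means (Lloyd iterations, k-means++
#' seeding, fixed seed recorded in the metadata), stores cluster centroids
#' (coordinate-wise member means), and computes the database representation
#' table: at every rank, the percentage of all fragments under each taxon,
#' the `R_i` consumed by proportion normalization.
#'
#' @param fragments a `"fragment_set"` from [fragment_genomes()] /
#'   [split_genome()].
#' @param tree a [taxonomy()] whose `genome_to_taxon` covers every fragment's
#'   genome.
#' @param k number of clusters; default `max(1, floor(sqrt(N)))` capped at
#'   2048.
#' @param seed integer seed controlling the clustering; rebuilding with the
#'   same inputs and seed is bit-identical.
#' @return an object of class `"fragment_index"`.
#' @export
build_index <- function(fragments, tree, k = NULL, seed = 1L) {
  stopifnot(inherits(fragments, "fragment_set"), inherits(tree, "taxonomy"))
  n <- nrow(fragments$info)
  if (n < 1L) stop("cannot build an index from zero fragments")
  if (is.null(k)) k <- min(max(1L, floor(sqrt(n))), 2048L)
  k <- as.integer(k)
  if (k > n) stop("k (", k, ") exceeds the number of fragments (", n, ")")
  miss <- setdiff(unique(fragments$info$genome_id), names(tree$genome_to_taxon))
  if (length(miss))
    stop("genomes absent from taxonomy: ", paste(miss, collapse = ", "))
  leaf <- unname(tree$genome_to_taxon[fragments$info$genome_id])
  info <- fragments$info
  info$taxon_id <- leaf

  x <- fragments$freq
  if (k == n) {
    membership <- seq_len(n)
    centroids <- x
  } else if (k == 1L) {
    membership <- rep.int(1L, n)
    centroids <- matrix(colMeans(x), 1L, ncol(x))
  } else {
    fit <- NULL
    for (attempt in 0:4) {        # deterministic retry on empty clusters
      set.seed(seed + attempt * 1000003L)
      fit <- tryCatch(
        suppressWarnings(kmeans(x, centers = kmeanspp_init(x, k),
                                iter.max = 300L, algorithm = "Lloyd")),
        error = function(e) NULL)
      if (!is.null(fit)) break
    }
    if (is.null(fit)) stop("k-means failed to produce ", k, " clusters")
    membership <- fit$cluster
    # enforce the coordinate-wise-mean invariant on the final memberships
    centroids <- rowsum(x, membership) /
      as.vector(table(factor(membership, levels = seq_len(k))))
  }
  dimnames(centroids) <- list(NULL, KMER_NAMES)

  structure(list(
    info = info,
    freq = x,
    n_counted = fragments$n_counted,
    membership = as.integer(membership),
    centroids = centroids,
    representation = representation_table(leaf, tree),
    metadata = list(format = INDEX_FORMAT, k = k, seed = as.integer(seed),
                    fragment_length = as.integer(fragments$fragment_length),
                    min_fragment_length = as.integer(fragments$min_fragment_length),
                    strand = fragments$strand,
                    n_fragments = n,
                    n_genomes = length(unique(info$genome_id)))),
    class = "fragment_index")
}

#' @export
print.fragment_index <- function(x, ...) {
  m <- x$metadata
  cat("Clustered fragment index (", m$format, ")\n", sep = "")
  cat("  fragments:", m$n_fragments, "from", m$n_genomes, "genomes;",
      m$fragment_length, "bp windows,", m$strand, "strand\n")
  cat("  clusters: ", m$k, " (k-means, seed ", m$seed, ")\n", sep = "")
  invisible(x)
}

#' @export
summary.fragment_index <- function(object, ...) {
  sizes <- as.integer(table(object$membership))
  rep_g <- object$representation[object$representation$rank == "genus", ]
  structure(list(metadata = object$metadata,
                 cluster_sizes = summary(sizes),
                 n_taxa_genus = nrow(rep_g),
                 top_genus = utils::head(
                   rep_g[order(-rep_g$percent),
                         c("taxon_id", "percent")], 5)),
            class = "summary.fragment_index")
}

#' @export
print.summary.fragment_index <- function(x, ...) {
  m <- x$metadata
  cat("Clustered fragment index:", m$n_fragments, "fragments,",
      m$k, "clusters\n")
  cat("  cluster sizes: "); print(x$cluster_sizes)
  cat("  genus-level taxa:", x$n_taxa_genus,
      "; largest database shares (%):\n")
  print(x$top_genus, row.names = FALSE)
  invisible(x)
}

fmt_full <- function(m) {
  out <- apply(m, 2, function(col) sprintf("%.17g", col))
  if (!is.matrix(out)) out <- matrix(out, nrow = nrow(m))
  out
}

#' Persist / load a fragment index
#'
#' `save_index()` writes a self-describing directory: `metadata.json`,
#' `fragments.tsv` (fragment table, cluster membership and integer 4-mer
#' counts — an exact rational representation of the frequency vectors),
#' `centroids.tsv` and `representation.tsv`. `load_index()` reproduces the
#' index exactly and refuses files whose format version does not match.
#'
#' @param index a `"fragment_index"`.
#' @param path directory to create/read.
#' @param expect_strand optional strand mode the caller is about to classify
#'   under; a mismatch with the stored metadata is a configuration error.
#' @return `load_index()` returns the `"fragment_index"`; `save_index()`
#'   returns `path` invisibly.
#' @export
save_index <- function(index, path) {
  stopifnot(inherits(index, "fragment_index"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(index$metadata, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  counts <- round(index$freq * index$n_counted)
  storage.mode(counts) <- "integer"
  colnames(counts) <- KMER_NAMES
  frag <- cbind(index$info,
                cluster = index$membership,
                n_counted = index$n_counted,
                as.data.frame(counts))
  data.table::fwrite(frag, file.path(path, "fragments.tsv"), sep = "\t")
  cent <- as.data.frame(fmt_full(index$centroids))
  names(cent) <- KMER_NAMES
  data.table::fwrite(cent, file.path(path, "centroids.tsv"), sep = "\t")
  data.table::fwrite(index$representation,
                     file.path(path, "representation.tsv"), sep = "\t")
  invisible(path)
}

#' @rdname save_index
#' @export
load_index <- function(path, expect_strand = NULL) {
  meta_path <- file.path(path, "metadata.json")
  if (!file.exists(meta_path)) stop("not an index directory: ", path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(meta$format, INDEX_FORMAT))
    stop("index format mismatch: found '", meta$format, "', expected '",
         INDEX_FORMAT, "'")
  if (!is.null(expect_strand) && !identical(meta$strand, expect_strand))
    stop("configuration mismatch: index was built with strand='",
         meta$strand, "' but strand='", expect_strand, "' was requested")
  frag <- as.data.frame(data.table::fread(file.path(path, "fragments.tsv"),
                                          sep = "\t"))
  cent <- as.matrix(data.table::fread(file.path(path, "centroids.tsv"),
                                      sep = "\t"))
  rep_tab <- as.data.frame(data.table::fread(
    file.path(path, "representation.tsv"), sep = "\t",
    colClasses = list(character = "taxon_id")))
  info_cols <- c("fragment_id", "genome_id", "contig", "start", "end",
                 "taxon_id")
  counts <- as.matrix(frag[, KMER_NAMES, drop = FALSE])
  n_counted <- as.integer(frag$n_counted)
  need <- c(meta[c("k", "seed", "fragment_length", "min_fragment_length",
                   "n_fragments", "n_genomes")])
  meta2 <- list(format = meta$format, k = as.integer(need$k),
                seed = as.integer(need$seed),
                fragment_length = as.integer(need$fragment_length),
                min_fragment_length = as.integer(need$min_fragment_length),
                strand = meta$strand,
                n_fragments = as.integer(need$n_fragments),
                n_genomes = as.integer(need$n_genomes))
  info <- frag[, info_cols]
  info$taxon_id <- as.character(info$taxon_id)
  info$genome_id <- as.character(info$genome_id)
  dimnames(cent) <- list(NULL, KMER_NAMES)
  structure(list(info = info,
                 freq = freq_from_counts(counts, n_counted),
                 n_counted = n_counted,
                 membership = as.integer(frag$cluster),
                 centroids = cent,
                 representation = rep_tab,
                 metadata = meta2),
            class = "fragment_index")
}
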