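# Per-read classification: cluster-pruned nearest-fragment search, the
# closest-subset rule, taxonomic-level gating, representation-bias
# normalization and rank-escalating convergence assignment.

#' Normalization configuration
#'
#' The database-representation normalization damps taxa that are
#' over-represented in the reference database:
#' `N_i' = P_i / (1 + a * log10(1 + R_i))`, renormalized to sum to 100.
#' `a = 0` is the identity. By default `a` follows the read-length class:
#' 2 for Sanger/Titanium/Standard-length reads, 0 for GS20-length reads
#' (short-read subsets are too small for damping to be informative).
#'
#' @param a `"auto"` (per-read-length default) or a single non-negative
#'   integer.
#' @param formula identifier of the normalization form; `"log_damp"` (the
#'   default above) is built in, and additional forms can be registered via
#'   the internal formula table.
#' @return an object of class `"norm_config"`.
#' @export
norm_config <- function(a = "auto", formula = "log_damp") {
  if (!identical(a, "auto")) {
    a <- as.numeric(a)
    if (is.na(a) || a < 0) stop("'a' must be 'auto' or a non-negative number")
  }
  if (!formula %in% names(NORM_FORMULAS))
    stop("unknown normalization formula: ", formula)
  structure(list(a = a, formula = formula), class = "norm_config")
}

NORM_FORMULAS <- list(
  log_damp = function(P, R, a) P / (1 + a * log10(1 + R))
)

a_for_class <- function(cfg, class_name) {
  if (!identical(cfg$a, "auto")) return(cfg$a)
  if (class_name == "gs20_100") 0 else 2
}

#' Closest-fragment subset for a query vector
#'
#' Selects the cluster whose centroid is nearest the query (Manhattan
#' distance), computes exact distances to every fragment in that cluster,
#' and retains all fragments within about `epsilon` of the minimum:
#' `d <= d_min / (1 - epsilon)`. With `d_min = 0` exactly the zero-distance
#' fragments are retained.
#'
#' @param index a `"fragment_index"`.
#' @param q a [tetra_vector()] (or numeric 256-vector); degenerate vectors
#'   are an error.
#' @param epsilon relative width of the retained band (default 0.01).
#' @return list with `d_min`, `cluster`, `idx` (fragment row indices into
#'   `index$info`) and `fragments` (the corresponding rows, with distances).
#' @export
closest_subset <- function(index, q, epsilon = 0.01) {
  stopifnot(inherits(index, "fragment_index"))
  v <- kv_values(q)
  cd <- row_l1(index$centroids, v)
  cl <- which.min(cd)
  members <- which(index$membership == cl)
  d <- row_l1(index$freq[members, , drop = FALSE], v)
  d_min <- min(d)
  keep <- d <= d_min / (1 - epsilon)
  idx <- members[keep]
  frags <- index$info[idx, , drop = FALSE]
  frags$distance <- d[keep]
  list(d_min = d_min, cluster = cl, idx = idx, fragments = frags)
}

#' Taxon proportions of a fragment subset at a rank
#'
#' Each fragment's leaf taxon is reduced to `rank` (falling back to the
#' nearest present higher rank on rank-sparse lineages), counted, and paired
#' with the database representation percentage `R` at the same rank.
#'
#' @param fragments data.frame with a `taxon_id` column (e.g.
#'   `closest_subset()$fragments`).
#' @param rank target rank.
#' @param tree a [taxonomy()].
#' @param index the `"fragment_index"` supplying the representation table.
#' @return a `"taxon_proportions"` data.frame with columns `taxon_id`, `P`
#'   (percent of the subset, summing to 100), `R` (percent of the database),
#'   and `N` (normalized percent, `NA` until [normalize_proportions()]),
#'   plus attribute `rank`.
#' @export
proportions_at <- function(fragments, rank, tree, index) {
  stopifnot(nrow(fragments) > 0)
  bucket <- reduce_or_ancestor(tree, fragments$taxon_id, rank)
  tab <- table(bucket)
  rep_tab <- index$representation[index$representation$rank == rank, ]
  R <- rep_tab$percent[match(names(tab), rep_tab$taxon_id)]
  out <- data.frame(taxon_id = names(tab),
                    P = 100 * as.integer(tab) / sum(tab),
                    R = R, N = NA_real_, stringsAsFactors = FALSE)
  attr(out, "rank") <- rank
  class(out) <- c("taxon_proportions", "data.frame")
  out
}

#' Normalize taxon proportions against database representation
#'
#' Applies the configured damping `N_i' = f(P_i, R_i, a)` and renormalizes so
#' the `N` column sums to 100. With `a = 0`, `N` equals `P` exactly; equal
#' `R` across all taxa also reduces to the identity (uniform damping cancels
#' under renormalization).
#'
#' @param p a `"taxon_proportions"` from [proportions_at()].
#' @param a non-negative damping weight.
#' @param formula normalization form identifier (see [norm_config()]).
#' @return `p` with the `N` column filled in.
#' @export
normalize_proportions <- function(p, a = 2, formula = "log_damp") {
  if (is.na(a) || a < 0) stop("'a' must be a non-negative number")
  f <- NORM_FORMULAS[[formula]]
  if (is.null(f)) stop("unknown normalization formula: ", formula)
  if (a == 0) {
    p$N <- p$P
    return(p)
  }
  raw <- f(p$P, p$R, a)
  p$N <- 100 * raw / sum(raw)
  p
}

# core of assign_read() once the query vector, its subset and the TL are
# known; shared with classify_reads() so the two stay identical by
# construction
convergence_assign <- function(sub, read_length, index, tree, thresholds,
                               cfg, tau) {
  tl <- determine_level(sub$d_min, read_length, thresholds)
  a <- a_for_class(cfg, read_length_class(read_length, thresholds))
  r <- tl
  while (!is.na(r)) {
    props <- proportions_at(sub$fragments, r, tree, index)
    props <- normalize_proportions(props, a, cfg$formula)
    ok <- props$N >= 100 * tau & node_field(tree, props$taxon_id, "rank") != "root"
    if (any(ok)) {
      cand <- props[ok, , drop = FALSE]
      win <- cand[cand$N == max(cand$N), , drop = FALSE]
      if (nrow(win) == 1L) {
        return(list(status = "assigned", taxon_id = win$taxon_id,
                    rank = node_field(tree, win$taxon_id, "rank"),
                    tl = tl, winning_N = win$N))
      }
      # exact tie: escalate rather than pick arbitrarily
    }
    r <- next_higher_rank(r)
  }
  list(status = "unassigned", taxon_id = NA_character_, rank = NA_character_,
       tl = tl, winning_N = NA_real_)
}

empty_assignment <- function(read_id, status, read_length) {
  n <- length(read_id)
  data.frame(read_id = read_id, status = rep_len(status, n),
             taxon_id = rep_len(NA_character_, n),
             taxon_name = rep_len(NA_character_, n),
             rank = rep_len(NA_character_, n),
             d_min = rep_len(NA_real_, n),
             tl = rep_len(NA_character_, n),
             subset_size = rep_len(0L, n),
             winning_N = rep_len(NA_real_, n),
             read_length = rep_len(as.integer(read_length), n),
             stringsAsFactors = FALSE)
}

#' Classify a single read
#'
#' Runs the full per-read pipeline: closest-fragment subset, taxonomic-level
#' gating, proportion normalization and rank-escalating convergence. A read
#' whose vector has no counted 4-mer window is returned with status
#' `too_short`; a read that fails to converge even at superkingdom is
#' `unassigned`.
#'
#' @param read_id identifier copied into the result.
#' @param q a [tetra_vector()] of the read.
#' @param read_length read length in bp (selects the threshold class).
#' @param index a `"fragment_index"`.
#' @param tree the [taxonomy()] the index was built against.
#' @param thresholds a [threshold_table()].
#' @param cfg a [norm_config()].
#' @param tau convergence threshold on the normalized proportion, as a
#'   fraction (default 0.80).
#' @param epsilon closest-subset band width, see [closest_subset()].
#' @return a one-row data.frame: `read_id`, `status`
#'   (`assigned`/`unassigned`/`too_short`), `taxon_id`, `taxon_name`,
#'   `rank`, `d_min`, `tl`, `subset_size`, `winning_N`, `read_length`.
#' @export
assign_read <- function(read_id, q, read_length, index, tree,
                        thresholds = threshold_table(), cfg = norm_config(),
                        tau = 0.80, epsilon = 0.01) {
  if (inherits(q, "kmer_vector") && q$n_counted == 0L)
    return(empty_assignment(read_id, "too_short", read_length))
  sub <- closest_subset(index, q, epsilon)
  res <- convergence_assign(sub, read_length, index, tree, thresholds, cfg, tau)
  data.frame(read_id = read_id, status = res$status,
             taxon_id = res$taxon_id,
             taxon_name = if (is.na(res$taxon_id)) NA_character_ else
               node_field(tree, res$taxon_id, "name"),
             rank = res$rank, d_min = sub$d_min, tl = res$tl,
             subset_size = length(sub$idx), winning_N = res$winning_N,
             read_length = read_length, stringsAsFactors = FALSE)
}

read_query_file <- function(path) {
  con <- gzfile(path, "rt"); first <- readLines(con, n = 1L); close(con)
  fmt <- if (length(first) && startsWith(first, "@")) "fastq" else "fasta"
  Biostrings::readDNAStringSet(path, format = fmt)
}

#' Classify a stream of reads
#'
#' Order-preserving per-read classification plus a cumulative taxonomic
#' profile: an assignment at some rank increments its own taxon and every
#' ladder-ranked ancestor, so counts at coarser ranks are cumulative.
#'
#' @param reads a `DNAStringSet`, a named character vector, or a path to a
#'   FASTA/FASTQ file (plain or gzip; qualities are ignored).
#' @inheritParams assign_read
#' @param strand strand mode for read vectors; must match the index build
#'   (defaults to the index metadata).
#' @return an object of class `"classification"`: list with `assignments`
#'   (one row per read, input order), `profile` (`rank`, `taxon_id`,
#'   `taxon_name`, `cumulative_count`, `percent_of_assigned`) and `counts`
#'   (assigned / unassigned / too_short totals).
#' @export
classify_reads <- function(reads, index, tree,
                           thresholds = threshold_table(),
                           cfg = norm_config(), tau = 0.80, epsilon = 0.01,
                           strand = NULL) {
  stopifnot(inherits(index, "fragment_index"))
  if (is.null(strand)) strand <- index$metadata$strand
  if (!identical(strand, index$metadata$strand))
    stop("configuration mismatch: index strand is '", index$metadata$strand,
         "' but strand='", strand, "' was requested")
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- read_query_file(reads)
  reads <- as_dna_set(reads)
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read_%d", seq_along(reads))
  n <- length(reads)
  if (n == 0L) {
    return(structure(list(
      assignments = empty_assignment(character(), character(), integer()),
      profile = data.frame(rank = character(), taxon_id = character(),
                           taxon_name = character(),
                           cumulative_count = integer(),
                           percent_of_assigned = numeric(),
                           stringsAsFactors = FALSE),
      counts = c(assigned = 0L, unassigned = 0L, too_short = 0L)),
      class = "classification"))
  }
  tm <- tetra_matrix(reads, strand)
  lens <- Biostrings::width(reads)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    if (tm$n_counted[i] == 0L) {
      rows[[i]] <- empty_assignment(ids[i], "too_short", lens[i])
      next
    }
    sub <- closest_subset(index, tm$freq[i, ], epsilon)
    res <- convergence_assign(sub, lens[i], index, tree, thresholds, cfg, tau)
    rows[[i]] <- data.frame(
      read_id = ids[i], status = res$status, taxon_id = res$taxon_id,
      taxon_name = if (is.na(res$taxon_id)) NA_character_ else
        node_field(tree, res$taxon_id, "name"),
      rank = res$rank, d_min = sub$d_min, tl = res$tl,
      subset_size = length(sub$idx), winning_N = res$winning_N,
      read_length = lens[i], stringsAsFactors = FALSE)
  }
  assignments <- do.call(rbind, rows)
  structure(list(assignments = assignments,
                 profile = cumulative_profile(assignments, tree),
                 counts = c(assigned = sum(assignments$status == "assigned"),
                            unassigned = sum(assignments$status == "unassigned"),
                            too_short = sum(assignments$status == "too_short"))),
            class = "classification")
}

# cumulative taxonomic profile: each assigned read counts at its taxon and at
# every ladder-ranked ancestor
cumulative_profile <- function(assignments, tree) {
  asg <- assignments[assignments$status == "assigned", , drop = FALSE]
  n_assigned <- nrow(asg)
  if (n_assigned == 0L)
    return(data.frame(rank = character(), taxon_id = character(),
                      taxon_name = character(), cumulative_count = integer(),
                      percent_of_assigned = numeric(),
                      stringsAsFactors = FALSE))
  per_taxon <- table(asg$taxon_id)
  acc <- new.env(parent = emptyenv())
  for (tid in names(per_taxon)) {
    lin <- lineage(tree, tid)
    lin <- lin[lin$rank != "root", , drop = FALSE]
    for (j in seq_len(nrow(lin))) {
      key <- paste(lin$rank[j], lin$taxon_id[j], sep = "\r")
      acc[[key]] <- (if (is.null(acc[[key]])) 0L else acc[[key]]) +
        as.integer(per_taxon[[tid]])
    }
  }
  keys <- ls(acc)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  prof <- data.frame(rank = vapply(parts, `[`, character(1), 1L),
                     taxon_id = vapply(parts, `[`, character(1), 2L),
                     cumulative_count = vapply(keys, function(k) acc[[k]],
                                               integer(1)),
                     stringsAsFactors = FALSE)
  prof$taxon_name <- node_field(tree, prof$taxon_id, "name")
  prof$percent_of_assigned <- 100 * prof$cumulative_count / n_assigned
  prof <- prof[order(-rank_pos(prof$rank), -prof$cumulative_count,
                     prof$taxon_id), ]
  rownames(prof) <- NULL
  prof[, c("rank", "taxon_id", "taxon_name", "cumulative_count",
           "percent_of_assigned")]
}

#' @export
print.classification <- function(x, ...) {
  n <- sum(x$counts)
  cat("Classified", n, "reads:",
      x$counts["assigned"], "assigned,",
      x$counts["unassigned"], "unassigned,",
      x$counts["too_short"], "too short\n")
  asg <- x$assignments[x$assignments$status == "assigned", ]
  if (nrow(asg)) {
    tab <- table(asg$rank)
    cat("  assignment ranks:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = " "),
        "\n")
  }
  invisible(x)
}

#' Classify reads with a fitted index
#'
#' `predict()` method running [classify_reads()].
#'
#' @param object a `"fragment_index"` from [build_index()].
#' @param reads query reads (see [classify_reads()]).
#' @param tree the [taxonomy()] the index was built against.
#' @param ... passed on to [classify_reads()].
#' @return a `"classification"` object.
#' @export
predict.fragment_index <- function(object, reads, tree, ...) {
  classify_reads(reads, object, tree, ...)
}

#' Write per-read assignments and the cumulative profile as TSV
#'
#' Columns are fixed: assignments as documented in [assign_read()]; profile
#' `rank`, `taxon_id`, `taxon_name`, `cumulative_count`,
#' `percent_of_assigned`.
#'
#' @param x a `"classification"`.
#' @param prefix output path prefix; writes `<prefix>.assignments.tsv` and
#'   `<prefix>.profile.tsv`.
#' @return the two paths, invisibly.
#' @export
write_classification <- function(x, prefix) {
  stopifnot(inherits(x, "classification"))
  pa <- paste0(prefix, ".assignments.tsv")
  pp <- paste0(prefix, ".profile.tsv")
  write.table(x$assignments, pa, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(x$profile, pp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(pa, pp))
}
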