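# Evaluation: score assignments against a truth table using the standard
# categories -- an assignment is correct when the assigned taxon lies on the
# read's true lineage, specific when it is also at phylum or below,
# non-specific when correct above phylum -- plus an end-to-end pipeline
# driver configured from YAML.

#' Score assignments against a truth table
#'
#' A read is *correct* iff its assigned taxon lies anywhere on the true
#' lineage of its source genome (up to superkingdom), *wrong* if assigned
#' off-lineage, and *unassigned* otherwise (including `too_short`). Correct
#' assignments split into *specific* (rank at phylum or below) and
#' *non-specific* (above phylum).
#'
#' @param assignments assignment data.frame (see [classify_reads()]) or a
#'   `"classification"` object.
#' @param truth truth table with `read_id`, `taxon_id` (true leaf taxon) and
#'   optionally `status` (representation status for the breakdown).
#' @param tree a [taxonomy()].
#' @return an object of class `"evaluation_report"`: list with `counts`,
#'   `percent`, `n_reads`, and `by_status` (per representation status) when
#'   available.
#' @export
score_assignments <- function(assignments, truth, tree) {
  if (inherits(assignments, "classification"))
    assignments <- assignments$assignments
  miss <- setdiff(assignments$read_id, truth$read_id)
  if (length(miss))
    stop("reads missing from truth table: ",
         paste(head(miss, 5), collapse = ", "))
  tr <- truth[match(assignments$read_id, truth$read_id), ]
  phylum_pos <- rank_pos("phylum")
  category <- character(nrow(assignments))
  for (i in seq_len(nrow(assignments))) {
    if (assignments$status[i] != "assigned") { category[i] <- "unassigned"; next }
    lin <- lineage(tree, tr$taxon_id[i])
    if (assignments$taxon_id[i] %in% lin$taxon_id) {
      category[i] <- if (rank_pos(assignments$rank[i]) <= phylum_pos)
        "specific" else "non_specific"
    } else category[i] <- "wrong"
  }
  tally <- function(cat) {
    n <- length(cat)
    counts <- c(correct = sum(cat %in% c("specific", "non_specific")),
                wrong = sum(cat == "wrong"),
                specific = sum(cat == "specific"),
                non_specific = sum(cat == "non_specific"),
                unassigned = sum(cat == "unassigned"))
    list(n_reads = n, counts = counts, percent = 100 * counts / n)
  }
  overall <- tally(category)
  by_status <- NULL
  if (!is.null(tr$status)) {
    by_status <- do.call(rbind, lapply(split(category, tr$status), function(cc) {
      t <- tally(cc)
      data.frame(n_reads = t$n_reads, t(t$percent))
    }))
    by_status <- cbind(status = rownames(by_status), by_status)
    rownames(by_status) <- NULL
  }
  structure(c(overall, list(by_status = by_status,
                            category = category)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Evaluation of", x$n_reads, "reads (% of reads):\n")
  p <- x$percent
  cat(sprintf("  correct %.1f (specific %.1f, non-specific %.1f)  wrong %.1f  unassigned %.1f\n",
              p["correct"], p["specific"], p["non_specific"], p["wrong"],
              p["unassigned"]))
  if (!is.null(x$by_status) && nrow(x$by_status) > 1L) {
    cat("  by representation status:\n")
    print(x$by_status, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Write an evaluation report as TSV and JSON
#'
#' @param report an `"evaluation_report"`.
#' @param prefix output prefix; writes `<prefix>.report.tsv` and
#'   `<prefix>.report.json`.
#' @return the two paths, invisibly.
#' @export
write_report <- function(report, prefix) {
  tab <- data.frame(category = names(report$counts),
                    count = as.integer(report$counts),
                    percent = as.numeric(report$percent))
  pt <- paste0(prefix, ".report.tsv")
  pj <- paste0(prefix, ".report.json")
  write.table(tab, pt, sep = "\t", quote = FALSE, row.names = FALSE)
  payload <- list(n_reads = report$n_reads,
                  counts = as.list(report$counts),
                  percent = as.list(report$percent))
  if (!is.null(report$by_status)) payload$by_status <- report$by_status
  jsonlite::write_json(payload, pj, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(pt, pj))
}

default_pipeline_config <- function() {
  list(
    seed = 1L,
    out = "tetrabin-run",
    simulate = list(n_phyla = 4L, classes_per_phylum = 2L,
                    orders_per_class = 2L, families_per_order = 2L,
                    genera_per_family = 2L, genome_length = 200000L,
                    divergence_per_rank = 0.4, alpha = 0.3,
                    n_reads = 2000L, read_length = 800L, error_rate = 0,
                    removals = NULL),
    build = list(k = NULL, fragment_length = 1000L,
                 min_fragment_length = 500L, strand = "forward"),
    classify = list(tau = 0.80, epsilon = 0.01, a = "auto")
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]) &&
        !is.data.frame(user[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Run the simulate/build/classify/score pipeline end to end
#'
#' Drives all stages from one config (YAML path or list; missing entries
#' take the defaults of the toy study design). Writes every artifact --
#' genomes, lineage TSV, reads FASTA, truth TSV, removals TSV, index
#' directory, per-read and profile TSVs, report TSV/JSON -- plus a
#' machine-readable `manifest.json` with the seeds and parameters actually
#' used. Reruns with the same config are bit-identical.
#'
#' @param config YAML file path or nested list; see
#'   `tetrabin:::default_pipeline_config()` for the keys.
#' @param quiet suppress per-stage log lines.
#' @return invisibly, a list with the collection, index, classification and
#'   report plus `out` (the output directory).
#' @export
run_pipeline <- function(config = list(), quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_pipeline_config(), config)
  out <- cfg$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log <- function(stage, ...) if (!quiet)
    message(sprintf("[%s] %s", stage, sprintf(...)))

  s <- cfg$simulate
  coll <- simulate_collection(s$n_phyla, s$classes_per_phylum,
                              s$orders_per_class, s$families_per_order,
                              s$genera_per_family, s$genome_length,
                              s$divergence_per_rank, s$alpha, cfg$seed)
  if (!is.null(s$removals) && NROW(s$removals) > 0) {
    rem <- if (is.data.frame(s$removals)) s$removals else
      do.call(rbind, lapply(s$removals, function(r)
        data.frame(rank = r$rank, taxon_id = r$taxon_id,
                   stringsAsFactors = FALSE)))
    coll <- make_leaveout(coll, rem)
  }
  reads <- simulate_reads(coll, s$n_reads, s$read_length, s$error_rate,
                          seed = cfg$seed + 101L)
  write_collection(coll, reads, out)
  log("simulate", "%d genomes, %d reads (%d bp), %d removed clade(s)",
      length(coll$genomes), s$n_reads, s$read_length,
      nrow(coll$removed_clades))

  b <- cfg$build
  index <- index_collection(coll, k = b$k, seed = cfg$seed,
                            fragment_length = b$fragment_length,
                            min_fragment_length = b$min_fragment_length,
                            strand = b$strand)
  save_index(index, file.path(out, "index"))
  log("build", "%d fragments in %d clusters",
      index$metadata$n_fragments, index$metadata$k)

  cl <- cfg$classify
  res <- classify_reads(reads$reads, index, coll$taxonomy,
                        cfg = norm_config(cl$a), tau = cl$tau,
                        epsilon = cl$epsilon)
  write_classification(res, file.path(out, "classify"))
  log("classify", "assigned %d / unassigned %d / too_short %d",
      res$counts["assigned"], res$counts["unassigned"],
      res$counts["too_short"])

  report <- score_assignments(res, reads$truth, coll$taxonomy)
  write_report(report, file.path(out, "score"))
  log("score", "correct %.1f%% (specific %.1f%%), wrong %.1f%%, unassigned %.1f%%",
      report$percent["correct"], report$percent["specific"],
      report$percent["wrong"], report$percent["unassigned"])

  manifest <- list(package = "tetrabin",
                   version = as.character(utils::packageVersion("tetrabin")),
                   config = cfg, index = index$metadata)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(collection = coll, reads = reads, index = index,
                 classification = res, report = report, out = out))
}
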