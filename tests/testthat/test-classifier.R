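# Engineered composition vectors: shift_vector(m) moves mass m off the first
# 4-mer, so its Manhattan distance to shift_vector(0) is exactly 2*m.

test_that("closest_subset applies the within-1%-of-minimum rule", {
  tree <- toy_tree()
  # distances to the query: 0.100, 0.1005, 0.200
  freq <- rbind(shift_vector(0.0500), shift_vector(0.05025),
                shift_vector(0.1000))
  mi <- manual_index(freq, c("gen1", "gen1", "gen1b"), tree)
  sub <- closest_subset(mi$index, shift_vector(0))
  expect_equal(sub$d_min, 0.1)
  expect_equal(sort(sub$fragments$distance), c(0.1, 0.1005))  # cutoff 0.10101
  expect_equal(length(sub$idx), 2L)
})

test_that("an exact database match retains only zero-distance fragments", {
  tree <- toy_tree()
  freq <- rbind(shift_vector(0), shift_vector(0), shift_vector(0.01))
  mi <- manual_index(freq, c("gen1", "gen1", "gen1b"), tree)
  sub <- closest_subset(mi$index, shift_vector(0))
  expect_equal(sub$d_min, 0)
  expect_equal(length(sub$idx), 2L)
  expect_true(all(sub$fragments$distance == 0))
})

test_that("centroid pruning with k = 1 equals an exhaustive scan", {
  tree <- toy_tree()
  set.seed(61)
  freq <- t(replicate(40, random_simplex(256)))
  taxa <- sample(c("gen1", "gen1b", "gen2"), 40, TRUE)
  mi <- manual_index(freq, taxa, tree, k = 1)
  for (i in 1:5) {
    q <- random_simplex(256)
    sub <- closest_subset(mi$index, q)
    d <- apply(freq, 1, function(r) sum(abs(r - q)))
    expect_equal(sub$d_min, min(d))
    expect_equal(sort(sub$idx), which(d <= min(d) / 0.99))
  }
})

test_that("proportions count reduced taxa and look up database shares", {
  tree <- toy_tree()
  freq <- rbind(shift_vector(0.01), shift_vector(0.011), shift_vector(0.012))
  mi <- manual_index(freq, c("gen1", "gen1", "gen1b"), tree)

  un <- proportions_at(mi$index$info[1:2, ], "genus", mi$tree, mi$index)
  expect_equal(un$P, 100)                       # unanimity

  p <- proportions_at(mi$index$info, "genus", mi$tree, mi$index)
  expect_equal(sort(p$P), c(100 / 3, 200 / 3))
  expect_equal(sum(p$P), 100)
  # R comes from the index representation table (2/3 vs 1/3 of fragments)
  expect_equal(p$R[p$taxon_id == "gen1"], 200 / 3)

  # gen2's lineage skips family: bucketed under its phylum at family rank
  mi2 <- manual_index(rbind(shift_vector(0.01), shift_vector(0.02)),
                      c("gen1", "gen2"), toy_tree())
  pf <- proportions_at(mi2$index$info, "family", mi2$tree, mi2$index)
  expect_setequal(pf$taxon_id, c("fam1", "phy2"))
})

test_that("normalization: identity at a = 0, damps over-represented taxa", {
  p <- data.frame(taxon_id = c("X", "Y"), P = c(60, 40), R = c(60, 0.5),
                  N = NA_real_)
  n0 <- normalize_proportions(p, a = 0)
  expect_identical(n0$N, n0$P)                  # exact identity

  n2 <- normalize_proportions(p, a = 2)
  expect_lt(n2$N[1], 60)                        # over-represented damped
  expect_gt(n2$N[2], 40)
  expect_equal(sum(n2$N), 100)
  # direct evaluation of the damping form
  raw <- c(60 / (1 + 2 * log10(61)), 40 / (1 + 2 * log10(1.5)))
  expect_equal(n2$N, 100 * raw / sum(raw))

  # equal R: uniform damping cancels under renormalization
  pe <- data.frame(taxon_id = c("X", "Y"), P = c(70, 30), R = c(12.5, 12.5),
                   N = NA_real_)
  expect_equal(normalize_proportions(pe, a = 2)$N, pe$P)

  expect_error(normalize_proportions(p, a = -1), "non-negative")
  expect_error(normalize_proportions(p, a = 2, formula = "nope"), "unknown")
  expect_error(norm_config(a = -2), "non-negative")
})

test_that("assignment converges at the first rank where one taxon dominates", {
  tree <- toy_tree()
  # unanimous subset at zero distance: genus-level assignment, N = 100
  freq <- rbind(shift_vector(0), shift_vector(0), shift_vector(0))
  mi <- manual_index(freq, c("gen1", "gen1", "gen1"), tree)
  a <- assign_read("r1", structure(list(values = shift_vector(0),
                                        n_counted = 997L, strand = "forward"),
                                   class = "kmer_vector"),
                   800, mi$index, mi$tree)
  expect_equal(a$status, "assigned")
  expect_equal(a$taxon_id, "gen1")
  expect_equal(a$rank, "genus")
  expect_equal(a$tl, "genus")
  expect_equal(a$winning_N, 100)

  # 70/30 split between sibling genera: escalates to their shared family
  freq <- do.call(rbind, replicate(10, shift_vector(0), simplify = FALSE))
  mi <- manual_index(freq, c(rep("gen1", 7), rep("gen1b", 3)), tree)
  a <- assign_read("r2", structure(list(values = shift_vector(0),
                                        n_counted = 997L, strand = "forward"),
                                   class = "kmer_vector"),
                   800, mi$index, mi$tree, tau = 0.80)
  expect_equal(a$status, "assigned")
  expect_equal(a$taxon_id, "fam1")
  expect_equal(a$rank, "family")
  expect_equal(a$tl, "genus")
  expect_equal(a$winning_N, 100)
})

test_that("a 50/50 split across superkingdoms stays unassigned", {
  tree <- toy_tree()
  freq <- do.call(rbind, replicate(4, shift_vector(0), simplify = FALSE))
  mi <- manual_index(freq, c("gen1", "gen1", "gen2", "gen2"), tree)
  q <- structure(list(values = shift_vector(0), n_counted = 997L,
                      strand = "forward"), class = "kmer_vector")
  a <- assign_read("r3", q, 800, mi$index, mi$tree, tau = 0.80)
  expect_equal(a$status, "unassigned")
  expect_true(is.na(a$taxon_id))
  # even with tau = 0.5 the exact tie escalates rather than picking a side,
  # and at superkingdom it still cannot break -> unassigned
  a2 <- assign_read("r4", q, 800, mi$index, mi$tree, tau = 0.50)
  expect_equal(a2$status, "unassigned")
})

test_that("reads without a clean 4-mer window are flagged too_short", {
  a <- assign_read("r", tetra_vector("ACG"), 100, small_index(),
                   small_collection()$taxonomy)
  expect_equal(a$status, "too_short")

  reads <- c(ok = substr(small_collection()$genomes[[1]], 1, 800),
             bad = paste0(rep("N", 800), collapse = ""))
  res <- classify_reads(reads, small_index(), small_collection()$taxonomy)
  expect_equal(res$assignments$status[2], "too_short")
  expect_equal(unname(res$counts["too_short"]), 1L)
})

test_that("classification conserves reads and preserves input order", {
  rt <- small_reads()
  res <- classify_reads(rt$reads, small_index(), small_collection()$taxonomy)
  expect_equal(sum(res$counts), length(rt$reads))
  expect_identical(res$assignments$read_id, names(rt$reads))
  expect_true(all(res$assignments$status %in%
                    c("assigned", "unassigned", "too_short")))
  # assigned reads always satisfy rank >= TL and the convergence threshold
  asg <- res$assignments[res$assignments$status == "assigned", ]
  expect_true(all(match(asg$rank, ladder_ranks(TRUE)) >=
                    match(asg$tl, ladder_ranks(TRUE))))
  expect_true(all(asg$winning_N >= 80))
})

test_that("empty input classifies to empty output and empty profile", {
  res <- classify_reads(character(0), small_index(),
                        small_collection()$taxonomy)
  expect_equal(nrow(res$assignments), 0L)
  expect_equal(nrow(res$profile), 0L)
  expect_equal(sum(res$counts), 0L)
})

test_that("the taxonomic profile is cumulative up the tree", {
  rt <- small_reads()
  res <- classify_reads(rt$reads, small_index(), small_collection()$taxonomy)
  prof <- res$profile
  n_assigned <- unname(res$counts["assigned"])
  # total at superkingdom equals the number of assigned reads
  expect_equal(sum(prof$cumulative_count[prof$rank == "superkingdom"]),
               n_assigned)
  # every taxon's count is at least the sum of counts assigned below it
  tree <- small_collection()$taxonomy
  asg <- res$assignments[res$assignments$status == "assigned", ]
  for (i in seq_len(nrow(prof))) {
    direct_or_below <- sum(vapply(seq_len(nrow(asg)), function(j)
      prof$taxon_id[i] %in% lineage(tree, asg$taxon_id[j])$taxon_id,
      logical(1)))
    expect_equal(prof$cumulative_count[i], direct_or_below)
  }

  # all reads from one genome: its genus and all ancestors carry the total
  one <- rt$reads[rt$truth$genome_id == rt$truth$genome_id[1]][1:5]
  r1 <- classify_reads(one, small_index(), tree)
  if (all(r1$assignments$status == "assigned") &&
      length(unique(r1$assignments$taxon_id)) == 1L) {
    expect_true(all(r1$profile$cumulative_count == 5L))
  }
})

test_that("lowering tau never makes an assignment less specific", {
  rt <- small_reads()
  idx <- small_index(); tree <- small_collection()$taxonomy
  pos <- function(res) {
    p <- match(res$assignments$rank, ladder_ranks(TRUE))
    p[is.na(p)] <- length(ladder_ranks(TRUE)) + 1L
    p
  }
  taus <- c(0.95, 0.80, 0.60, 0.51)
  prev <- NULL
  for (tau in taus) {
    cur <- pos(classify_reads(rt$reads[1:60], idx, tree, tau = tau))
    if (!is.null(prev)) expect_true(all(cur <= prev), label = paste("tau", tau))
    prev <- cur
  }
})

test_that("with equal database representation, damping is a no-op", {
  # the balanced collection has identical R_i within every rank
  rt <- small_reads()
  idx <- small_index(); tree <- small_collection()$taxonomy
  r0 <- classify_reads(rt$reads, idx, tree, cfg = norm_config(a = 0))
  r2 <- classify_reads(rt$reads, idx, tree, cfg = norm_config(a = 2))
  expect_equal(r2$assignments, r0$assignments)
})

test_that("reads load identically from vectors, FASTA and gzipped FASTQ", {
  rt <- small_reads()
  reads <- rt$reads[1:20]
  idx <- small_index(); tree <- small_collection()$taxonomy
  direct <- classify_reads(reads, idx, tree)

  fa <- withr::local_tempfile(fileext = ".fasta")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(reads), fa)
  expect_equal(classify_reads(fa, idx, tree)$assignments, direct$assignments)

  fq <- withr::local_tempfile(fileext = ".fastq.gz")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(reads), fq,
                              format = "fastq", compress = TRUE)
  expect_equal(classify_reads(fq, idx, tree)$assignments, direct$assignments)
})

test_that("predict() on the index matches classify_reads()", {
  rt <- small_reads()
  a <- predict(small_index(), rt$reads[1:10], small_collection()$taxonomy)
  b <- classify_reads(rt$reads[1:10], small_index(),
                      small_collection()$taxonomy)
  expect_equal(a$assignments, b$assignments)
})
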