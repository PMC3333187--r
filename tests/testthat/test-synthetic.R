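test_that("make_taxonomy builds balanced, deterministic trees", {
  chain <- make_taxonomy(1, 1, 1, 1, 1)
  expect_equal(length(chain$genome_to_taxon), 1L)
  lin <- lineage(chain, chain$genome_to_taxon[[1]])
  expect_equal(lin$rank, c("genus", "family", "order", "class", "phylum",
                           "superkingdom", "root"))

  t2 <- make_taxonomy(2, 1, 1, 1, 2)
  expect_equal(sum(t2$nodes$rank == "genus"), 4L)
  expect_equal(sum(t2$nodes$rank == "phylum"), 2L)

  expect_identical(make_taxonomy(seed = 5), make_taxonomy(seed = 5))
})

test_that("simulate_genome follows its Markov model", {
  uni <- composition_model(matrix(1, 64, 4))
  s <- simulate_genome(uni, 1e5, seed = 2)
  f <- tetra_vector(s)$values
  expect_true(all(abs(f - 1 / 256) < 0.002))   # law of large numbers

  at_rich <- composition_model(matrix(rep(c(4, 1, 1, 4), each = 64), 64, 4))
  s2 <- simulate_genome(at_rich, 5e4, seed = 3)
  gc <- mean(strsplit(s2, "")[[1]] %in% c("G", "C"))
  expect_lt(gc, 0.5)

  expect_equal(nchar(simulate_genome(uni, 4, seed = 1)), 4L)
  expect_identical(simulate_genome(uni, 1000, seed = 9),
                   simulate_genome(uni, 1000, seed = 9))
})

test_that("clade models diverge with the rank of the common ancestor", {
  tree <- make_taxonomy(2, 1, 1, 2, 2)   # 8 genera
  models0 <- derive_clade_models(tree, divergence_per_rank = 0, seed = 4)
  w <- lapply(models0, `[[`, "weights")
  for (m in w[-1]) expect_equal(m, w[[1]])   # null divergence: one model

  expect_identical(derive_clade_models(tree, 0.4, seed = 4),
                   derive_clade_models(tree, 0.4, seed = 4))

  # mean fragment distance: within-family pairs < cross-phylum pairs
  models <- derive_clade_models(tree, divergence_per_rank = 0.4, seed = 4)
  gen <- function(g, seed) simulate_genome(models[[g]], 30000, seed)
  fr <- function(s) tetra_matrix(substring(s, seq(1, 29001, 1000),
                                           seq(1000, 30000, 1000)))$freq
  fA  <- fr(gen("p0.c0.o0.f0.g0", 11))
  fA2 <- fr(gen("p0.c0.o0.f0.g1", 12))   # same family
  fB  <- fr(gen("p1.c0.o0.f1.g1", 13))   # different phylum
  mean_d <- function(x, y)
    mean(vapply(seq_len(nrow(x)), function(i)
      mean(tetrabin:::row_l1(y, x[i, ])), numeric(1)))
  expect_lt(mean_d(fA, fA2), mean_d(fA, fB))
})

test_that("simulated reads are genuine genome substrings with exact truth", {
  coll <- small_collection()
  rt <- simulate_reads(coll, 40, 400, error_rate = 0, seed = 8)
  expect_equal(nrow(rt$truth), 40L)
  expect_false(anyDuplicated(rt$truth$read_id) > 0)
  expect_identical(names(rt$reads), rt$truth$read_id)
  for (i in seq_len(10)) {
    g <- coll$genomes[[rt$truth$genome_id[i]]]
    r <- rt$reads[[i]]
    if (rt$truth$strand[i] == "-")
      r <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(r)))
    expect_equal(substr(g, rt$truth$start[i],
                        rt$truth$start[i] + 399), r)
  }
  expect_identical(simulate_reads(coll, 40, 400, 0, seed = 8)$reads, rt$reads)
})

test_that("substitution errors hit at the configured rate", {
  coll <- small_collection()
  rt0 <- simulate_reads(coll, 300, 800, error_rate = 0, seed = 9)
  rt1 <- simulate_reads(coll, 300, 800, error_rate = 0.01, seed = 9)
  mism <- mapply(function(a, b)
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]), rt0$reads, rt1$reads)
  expect_equal(mean(mism), 8, tolerance = 0.15)   # 800 * 0.01
  expect_error(simulate_reads(coll, 5, 10^6, 0, seed = 1), "exceeds")
})

test_that("leave-clade-out marks excluded genomes and truth statuses", {
  coll <- simulate_collection(2, 1, 1, 1, 2, genome_length = 25000, seed = 6)
  # genera: p0.c0.o0.f0.{g0,g1}, p1.c0.o0.f0.{g0,g1}
  lo <- make_leaveout(coll, data.frame(rank = "genus",
                                       taxon_id = "p0.c0.o0.f0.g0"))
  expect_equal(lo$excluded_genomes, "p0.c0.o0.f0.g0.G0")
  rt <- simulate_reads(lo, 60, 400, 0, seed = 2)
  st <- rt$truth$status[rt$truth$genome_id == "p0.c0.o0.f0.g0.G0"]
  expect_true(all(st == "genus_unknown"))
  expect_true(all(rt$truth$status[rt$truth$genome_id != "p0.c0.o0.f0.g0.G0"]
                  == "known"))

  # removing a phylum labels every read under it phylum_unknown
  lo2 <- make_leaveout(coll, data.frame(rank = "phylum", taxon_id = "p0"))
  expect_setequal(lo2$excluded_genomes,
                  c("p0.c0.o0.f0.g0.G0", "p0.c0.o0.f0.g1.G0"))
  rt2 <- simulate_reads(lo2, 60, 400, 0, seed = 2)
  expect_true(all(rt2$truth$status[startsWith(rt2$truth$genome_id, "p0")]
                  == "phylum_unknown"))

  # no removals: everything known
  rt3 <- simulate_reads(coll, 20, 400, 0, seed = 2)
  expect_true(all(rt3$truth$status == "known"))

  expect_error(make_leaveout(coll, data.frame(rank = "superkingdom",
                                              taxon_id = "sk0")),
               "every genome")
  expect_error(make_leaveout(coll, data.frame(rank = "genus",
                                              taxon_id = "ghost")),
               "not in taxonomy")
})

test_that("excluded genomes are absent from the rebuilt index", {
  coll <- simulate_collection(2, 1, 1, 1, 2, genome_length = 25000, seed = 6)
  lo <- make_leaveout(coll, data.frame(rank = "genus",
                                       taxon_id = "p1.c0.o0.f0.g1"))
  idx <- index_collection(lo, seed = 6)
  expect_false("p1.c0.o0.f0.g1.G0" %in% idx$info$genome_id)
  expect_false("p1.c0.o0.f0.g1" %in%
                 idx$representation$taxon_id[idx$representation$rank == "genus"])
})

test_that("strand-balanced genomes expose both orientations to the index", {
  m <- root_composition_model(alpha = 0.3, seed = 13)
  g <- tetrabin:::strand_balanced_genome(m, 100000, seed = 13)
  expect_equal(nchar(g), 100000L)
  # a reverse-strand read must find a close fragment despite forward counting
  frags <- split_genome("g", g)
  read <- substr(g, 40201, 41000)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  d <- tetrabin:::row_l1(frags$freq, tetra_vector(rc)$values)
  expect_lt(min(d), 0.35)
})
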