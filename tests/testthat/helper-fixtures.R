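# Shared fixtures, built in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- force(expr)
  .fixture_cache[[name]]
}

# hand-built taxonomy: two superkingdoms; one lineage rank-complete to genus,
# one genus hanging directly under a phylum (family/order/class skipped)
toy_tree <- function() {
  nodes <- data.frame(
    taxon_id  = c("root", "sk1", "sk2", "phy1", "cls1", "ord1", "fam1",
                  "gen1", "gen1b", "phy2", "gen2"),
    name      = c("root", "sk1", "sk2", "phy1", "cls1", "ord1", "fam1",
                  "gen1", "gen1b", "phy2", "gen2"),
    rank      = c("root", "superkingdom", "superkingdom", "phylum", "class",
                  "order", "family", "genus", "genus", "phylum", "genus"),
    parent_id = c(NA, "root", "root", "sk1", "phy1", "cls1", "ord1",
                  "fam1", "fam1", "sk2", "phy2"),
    stringsAsFactors = FALSE)
  taxonomy(nodes, c(gA = "gen1", gB = "gen1b", gC = "gen2"))
}

# fabricate an index directly from a matrix of composition vectors (rows),
# one fragment per row, bypassing sequence handling; taxa parallel the rows
manual_index <- function(freq, taxa, tree, k = 1L, seed = 1L) {
  n <- nrow(freq)
  genome_ids <- paste0("G_", taxa, "_", seq_len(n))
  g2t <- setNames(taxa, genome_ids)
  tree$genome_to_taxon <- c(tree$genome_to_taxon, g2t)
  info <- data.frame(fragment_id = sprintf("f%d", seq_len(n)),
                     genome_id = genome_ids, contig = 1L,
                     start = 0L, end = 1000L, stringsAsFactors = FALSE)
  fs <- tetrabin:::new_fragment_set(info, freq, rep(997L, n), "forward",
                                    1000L, 500L)
  list(index = build_index(fs, tree, k = k, seed = seed), tree = tree)
}

# unit mass moved between two 4-mers: distance to the base vector is 2*mass
shift_vector <- function(mass, from = 1L, to = 2L) {
  v <- rep(0, 256)
  v[from] <- 1
  v[from] <- v[from] - mass
  v[to] <- v[to] + mass
  v
}

random_simplex <- function(n) {
  x <- rexp(n)
  x / sum(x)
}

# small simulated collection shared by classifier/eval tests
small_collection <- function() {
  cached("small_coll", simulate_collection(
    n_phyla = 2L, classes_per_phylum = 1L, orders_per_class = 1L,
    families_per_order = 2L, genera_per_family = 2L,
    genome_length = 50000L, seed = 42L))
}

small_index <- function() {
  cached("small_index", index_collection(small_collection(), seed = 42L))
}

small_reads <- function() {
  cached("small_reads",
         simulate_reads(small_collection(), 120L, 800L, 0, seed = 7L))
}
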