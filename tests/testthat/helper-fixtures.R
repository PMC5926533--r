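# Shared fixtures. Heavy simulated bundles are built once per run and
# memoised so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

# default study-condition bundle (2 x 5 Mb, 40 hubs, 200k pairs) plus its
# filtered pairs and called/classified HOCIs
default_bundle <- function() {
  if (is.null(.fixture_cache$bundle)) {
    b <- simulate_bundle(sim_config(seed = 1))
    flt <- filter_pairs(b$pairs, b$fragments)
    hoci <- call_hoci(build_coverage(flt$valid, b$assembly))
    hoci <- classify_hoci(hoci, b$peaks$h3k4me3, b$peaks$h3k4me1,
                          b$peaks$h3k27ac, b$genes, b$assembly)
    .fixture_cache$bundle <- list(b = b, flt = flt, hoci = hoci)
  }
  .fixture_cache$bundle
}

# a genome of 'A's with GATC planted at the given 0-based cut positions:
# fragment boundaries are exactly the planted positions
make_genome <- function(lens, cut_positions = list()) {
  seqs <- lapply(names(lens), function(ch) {
    s <- rep("A", lens[[ch]])
    for (p in cut_positions[[ch]]) s[(p + 1):(p + 4)] <- c("G", "A", "T", "C")
    paste(s, collapse = "")
  })
  names(seqs) <- names(lens)
  genome_assembly(lens, unlist(seqs))
}

# wrap a plain counts matrix as a ContactMatrix
toy_cm <- function(counts, resolution = 1000, chrom = "c") {
  n <- nrow(counts)
  structure(list(chrom = chrom, resolution = resolution,
                 bins = data.frame(chrom = chrom,
                                   start = (seq_len(n) - 1) * resolution,
                                   end = seq_len(n) * resolution),
                 counts = counts, weights = NULL,
                 masked = rep(FALSE, n), balanced = FALSE,
                 total_pairs = sum(counts[upper.tri(counts, diag = TRUE)])),
            class = "ContactMatrix")
}

# symmetric Poisson block-model matrix from a class label vector
block_model_matrix <- function(classes, within = 5, between = 1, scale = 20,
                               seed = 4) {
  set.seed(seed)
  n <- length(classes)
  rate <- ifelse(outer(classes, classes, "=="), within, between) * scale
  m <- matrix(stats::rpois(n * n, rate), n)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

# independent brute-force pair classifier following the written rules
brute_classify <- function(p, frag_df, mapq_min = 1, min_separation = 1000) {
  frag_of <- function(chrom, pos) {
    i <- which(frag_df$chrom == chrom & frag_df$start <= pos &
                 pos < frag_df$end)
    stopifnot(length(i) == 1)
    i
  }
  if (p$mapq1 < mapq_min || p$mapq2 < mapq_min) return("LOW_MAPQ")
  if (p$chrom1 != p$chrom2) return("VALID_TRANS")
  f1 <- frag_of(p$chrom1, p$pos1); f2 <- frag_of(p$chrom2, p$pos2)
  if (f1 == f2) {
    if (p$strand1 == p$strand2) return("SAME_STRAND_DUMPED")
    first <- if (p$pos1 <= p$pos2) p$strand1 else p$strand2
    return(if (first == "+") "DANGLING_END" else "SELF_CIRCLE")
  }
  mid <- function(i) (frag_df$start[i] + frag_df$end[i]) / 2
  if (abs(mid(f1) - mid(f2)) < min_separation) return("TOO_CLOSE")
  "VALID_CIS"
}
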