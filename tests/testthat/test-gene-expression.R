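typing_fixture <- function() {
  g <- genome_assembly(c(c1 = 200000))
  hocis <- data.frame(chrom = "c1", start = c(10000, 100000),
                      end = c(11000, 101000), name = c("H1", "H2"))
  genes <- data.frame(gene_id = c("hub", "inter", "diss"),
                      chrom = "c1", strand = "+",
                      tss = c(11500, 50000, 150000))
  # one valid pair links inter's promoter (49000) to H2
  valid <- read_pairs("c1", 49000, "+", "c1", 100500, "-")
  list(g = g, hocis = hocis, genes = genes, valid = valid)
}

test_that("genes are typed hub / interacting / dissociative", {
  f <- typing_fixture()
  ty <- type_genes(f$genes, f$hocis, f$valid, f$g)
  expect_equal(as.character(ty), c("HUB", "INTERACTING", "DISSOCIATIVE"))
  expect_equal(sum(table(ty)), nrow(f$genes))   # partition
  # min_pairs knob: requiring 2 pairs demotes the interacting gene
  ty2 <- type_genes(f$genes, f$hocis, f$valid, f$g, min_pairs = 2)
  expect_equal(as.character(ty2[2]), "DISSOCIATIVE")
})

test_that("adding HOCIs never demotes a gene", {
  f <- typing_fixture()
  rank_of <- c(DISSOCIATIVE = 1, INTERACTING = 2, HUB = 3)
  ty_small <- type_genes(f$genes, f$hocis[1, ], f$valid, f$g)
  ty_big <- type_genes(f$genes, f$hocis, f$valid, f$g)
  expect_true(all(rank_of[as.character(ty_big)] >=
                    rank_of[as.character(ty_small)]))
  extra <- rbind(f$hocis,
                 data.frame(chrom = "c1", start = 149000, end = 151000,
                            name = "H3"))
  ty_max <- type_genes(f$genes, extra, f$valid, f$g)
  expect_true(all(rank_of[as.character(ty_max)] >=
                    rank_of[as.character(ty_big)]))
})

test_that("planted gene types are recovered end to end", {
  bd <- default_bundle()
  ty <- type_genes(bd$b$genes, bd$hoci, bd$flt$valid, bd$b$assembly)
  expect_gte(mean(as.character(ty) == bd$b$genes$planted_type), 0.95)
})

test_that("expression by type reports ordered medians and strict cutoff", {
  set.seed(3)
  n <- 300
  types <- factor(rep(c("HUB", "INTERACTING", "DISSOCIATIVE"), each = n),
                  levels = c("HUB", "INTERACTING", "DISSOCIATIVE"))
  rpkm <- c(stats::rlnorm(n, log(20), 1), stats::rlnorm(n, log(5), 1),
            stats::rlnorm(n, log(0.2), 1))
  eb <- expression_by_type(types, rpkm)
  s <- eb$summary
  expect_true(s$median_rpkm[s$type == "HUB"] >
                s$median_rpkm[s$type == "INTERACTING"])
  expect_true(s$median_rpkm[s$type == "INTERACTING"] >
                s$median_rpkm[s$type == "DISSOCIATIVE"])
  expect_true(all(eb$tests$p_value < 1e-10))
  expect_equal(sum(s$prop_all), 1)

  # RPKM exactly at the cutoff is not expressed (strict inequality)
  ty3 <- factor(c("HUB", "HUB", "INTERACTING", "INTERACTING"),
                levels = levels(types))
  eb3 <- suppressWarnings(expression_by_type(ty3, c(0.5, 2, 0.5, 3)))
  expect_equal(eb3$summary$prop_expressed[1:2], c(0.5, 0.5))

  # single-type input skips all comparisons (with warnings)
  one <- suppressWarnings(
    expression_by_type(factor(rep("HUB", 5), levels(types)),
                       stats::rlnorm(5, 1, 1)))
  expect_null(one$tests)
})

test_that("condition comparison categorises type changes correctly", {
  g <- genome_assembly(c(c1 = 1e6))
  genes <- data.frame(gene_id = c("g1", "g2", "g3"), chrom = "c1",
                      strand = "+", tss = c(10000, 20000, 30000))
  prom_hoci <- function(tss) data.frame(chrom = "c1", start = tss - 1000,
                                        end = tss - 500)
  ha <- prom_hoci(10000)                 # g1 promoter is a HOCI in A only
  hb <- prom_hoci(20000)                 # g2 promoter is a HOCI in B only
  ta <- factor(c("HUB", "INTERACTING", "HUB"),
               levels = c("HUB", "INTERACTING", "DISSOCIATIVE"))
  tb <- factor(c("DISSOCIATIVE", "HUB", "HUB"), levels = levels(ta))
  cc <- compare_conditions(genes, ta, tb, c(8, 1, 5), c(0.1, 4, 5),
                           ha, hb, g)
  expect_equal(cc$genes$category,
               c("hub_dissociative", "other_change", "same_type"))
  expect_equal(cc$genes$promoter_hoci_changed, c(TRUE, TRUE, FALSE))
  expect_equal(cc$genes$log2fc[3], 0)
  # missing expression excludes the gene but reports it
  cc2 <- compare_conditions(genes, ta, tb, c(8, NA, 5), c(0.1, 4, 5),
                            ha, hb, g)
  expect_equal(cc2$excluded, 1)
  expect_equal(nrow(cc2$genes), 2)
})

test_that("planted expression drops separate changed from unchanged genes", {
  set.seed(5)
  n <- 200
  g <- genome_assembly(c(c1 = 1e7))
  tss <- seq(10000, by = 20000, length.out = 2 * n)
  genes <- data.frame(gene_id = sprintf("g%03d", seq_len(2 * n)),
                      chrom = "c1", strand = "+", tss = tss)
  changed <- seq_len(n)                   # first half lose their promoter HOCI
  ha <- data.frame(chrom = "c1", start = tss[changed] - 1500,
                   end = tss[changed] - 500)
  hb <- ha[0, ]
  rpkm_a <- stats::rlnorm(2 * n, log(10), 0.5)
  drop <- ifelse(seq_len(2 * n) %in% changed, 4, 1)
  rpkm_b <- rpkm_a / drop * stats::rlnorm(2 * n, 0, 0.2)
  ta <- factor(ifelse(seq_len(2 * n) %in% changed, "HUB", "INTERACTING"),
               levels = c("HUB", "INTERACTING", "DISSOCIATIVE"))
  tb <- factor(ifelse(seq_len(2 * n) %in% changed, "DISSOCIATIVE",
                      "INTERACTING"), levels = levels(ta))
  cc <- compare_conditions(genes, ta, tb, rpkm_a, rpkm_b, ha, hb, g)
  expect_equal(sum(cc$genes$promoter_hoci_changed), n)
  p_up <- cc$tests$p_value[cc$tests$direction == "up"]
  expect_lt(p_up, 0.01)
})

test_that("expression tables round-trip", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  x <- c(geneA = 1.5, geneB = 0, geneC = 12.25)
  write_expression(x, tmp)
  expect_equal(read_expression(tmp), x)
})
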