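test_that("pair binning is symmetric and conserves pair counts", {
  g <- genome_assembly(c(c1 = 200000))
  v <- read_pairs("c1", 10000, "+", "c1", 90000, "-")
  cm <- bin_pairs(v, g, "c1", 40000)
  expect_equal(cm$counts[1, 3], 1)
  expect_equal(cm$counts[3, 1], 1)
  expect_equal(sum(cm$counts), 2)

  none <- bin_pairs(v[0, ], g, "c1", 40000)
  expect_equal(sum(none$counts), 0)

  diag1 <- bin_pairs(read_pairs("c1", 100, "+", "c1", 200, "-"),
                     g, "c1", 40000)
  expect_equal(diag1$counts[1, 1], 1)

  set.seed(51)
  n <- 500
  v2 <- read_pairs(rep("c1", n), sample.int(2e5, n) - 1, rep("+", n),
                   rep("c1", n), sample.int(2e5, n) - 1, rep("-", n))
  cm2 <- bin_pairs(v2, g, "c1", 10000)
  expect_equal(sum(cm2$counts[upper.tri(cm2$counts, diag = TRUE)]), n)
  expect_true(isSymmetric(cm2$counts))
  expect_error(bin_pairs(v2, g, "c9"), "unknown chromosome")
})

test_that("ICE balancing converges and recovers planted biases", {
  set.seed(1)
  n <- 200
  m <- matrix(stats::rgamma(n * n, 2), n)
  m <- m + t(m)
  cm <- toy_cm(m)
  cmb <- ice_balance(cm, mask_quantile = 0)
  s <- rowSums(cmb$counts)[!cmb$masked]
  expect_lt(stats::sd(s) / mean(s), 1e-4)
  expect_lte(cmb$n_iter, 100)

  # planted factorisable bias on a doubly balanced core
  T0 <- m
  for (i in 1:400) {
    rs <- rowSums(T0)
    T0 <- T0 / outer(rs, rs) * mean(rs)
  }
  b <- exp(stats::rnorm(n, 0, 0.3))
  cmb2 <- ice_balance(toy_cm(outer(b, b) * T0), mask_quantile = 0)
  w <- cmb2$weights / mean(cmb2$weights)
  bn <- b / mean(b)
  expect_lt(max(abs(w - bn) / bn), 0.05)

  # a balanced matrix is an immediate fixed point
  cmb3 <- ice_balance(toy_cm(T0), mask_quantile = 0)
  expect_lte(cmb3$n_iter, 2)
  expect_lt(max(abs(cmb3$weights - 1)), 0.01)

  # zeros stay zero; scaling the input rescales the output globally
  mz <- m; mz[2, 5] <- 0; mz[5, 2] <- 0
  bz <- ice_balance(toy_cm(mz), mask_quantile = 0)
  expect_equal(bz$counts[2, 5], 0)
  b1 <- ice_balance(toy_cm(m), mask_quantile = 0)
  b2 <- ice_balance(toy_cm(3 * m), mask_quantile = 0)
  ratio <- b2$counts[b1$counts > 0] / b1$counts[b1$counts > 0]
  expect_lt(stats::sd(ratio) / mean(ratio), 1e-3)

  expect_error(ice_balance(toy_cm(matrix(0, 4, 4))), "all-zero")
})

test_that("compartments recover an interleaved two-class block model", {
  cls <- rep(rep(c(0, 1), each = 10), 5)
  m <- block_model_matrix(cls, within = 5, between = 1, seed = 4)
  cmb <- ice_balance(toy_cm(m), mask_quantile = 0)
  track_a <- data.frame(chrom = "c", start = (which(cls == 0) - 1) * 1000,
                        end = which(cls == 0) * 1000)
  comp <- compartments(cmb, track_a)
  agree <- mean((comp$compartment == "A") == (cls == 0), na.rm = TRUE)
  expect_gte(agree, 0.95)

  # flipping the orientation track flips every label
  track_b <- data.frame(chrom = "c", start = (which(cls == 1) - 1) * 1000,
                        end = which(cls == 1) * 1000)
  comp_b <- compartments(cmb, track_b)
  expect_true(all(comp$compartment != comp_b$compartment, na.rm = TRUE))
})

test_that("structureless matrices give no reliable compartments", {
  m <- matrix(50, 40, 40)
  cmb <- ice_balance(toy_cm(m), mask_quantile = 0)
  comp <- compartments(cmb, data.frame(chrom = "c", start = 0, end = 5000))
  expect_false(attr(comp, "reliable"))
  expect_true(all(abs(comp$pc1) < 1e-6, na.rm = TRUE))

  small <- ice_balance(toy_cm(matrix(5, 4, 4)), mask_quantile = 0)
  expect_error(compartments(small, data.frame(chrom = "c", start = 0,
                                              end = 100)),
               "unmasked bins")
  expect_error(compartments(toy_cm(m), data.frame(chrom = "c", start = 0,
                                                  end = 100)),
               "balance")
})

test_that("insulation finds the planted block junction and nothing else", {
  cls <- rep(c(0, 1), each = 30)
  m <- block_model_matrix(cls, within = 10, between = 1, scale = 10,
                          seed = 5)
  cmb <- ice_balance(toy_cm(m), mask_quantile = 0)
  ins <- insulation_boundaries(cmb, window_bins = 8, delta_threshold = 0.5)
  found <- ins$bin[ins$is_boundary]
  expect_equal(length(found), 1)
  expect_lte(abs(found - 30), 1)

  flat <- ice_balance(toy_cm(matrix(20, 60, 60)), mask_quantile = 0)
  ins2 <- insulation_boundaries(flat, window_bins = 8,
                                delta_threshold = 0.2)
  expect_equal(sum(ins2$is_boundary), 0)
  expect_error(insulation_boundaries(cmb, window_bins = 1), ">= 2")
  expect_error(insulation_boundaries(ice_balance(toy_cm(matrix(5, 6, 6)),
                                                 mask_quantile = 0),
                                     window_bins = 10), "smaller")
})

test_that("HOCIs planted at boundaries show permutation enrichment", {
  # irregular block widths: the boundary set is aperiodic, so no circular
  # shift of the HOCI positions can realign them all with boundaries
  widths <- c(9, 16, 7, 13, 11, 18, 8, 18)
  cls <- rep(rep(c(0, 1), 4), widths)
  m <- block_model_matrix(cls, within = 8, between = 1, scale = 10,
                          seed = 9)
  cmb <- ice_balance(toy_cm(m), mask_quantile = 0)
  ins <- insulation_boundaries(cmb, window_bins = 5, delta_threshold = 0.2)
  bbins <- ins$bin[ins$is_boundary]
  expect_gte(length(bbins), 3)
  hocis <- data.frame(chrom = "c", start = (bbins - 1) * 1000 + 400,
                      end = (bbins - 1) * 1000 + 600,
                      name = paste0("h", seq_along(bbins)))
  enr <- boundary_hoci_enrichment(ins, hocis, cmb,
                                  n_permutations = 1000, seed = 9)
  expect_gt(enr$fold, 2)
  expect_lte(enr$p_value, 0.001)
})

test_that("HOCI-filtered matrices keep exactly the HOCI-touching pairs", {
  g <- genome_assembly(c(c1 = 200000))
  hocis <- data.frame(chrom = "c1", start = 10000, end = 11000, name = "h")
  v <- read_pairs(rep("c1", 5), c(10500, 10800, 10900, 50000, 60000),
                  rep("+", 5),
                  rep("c1", 5), c(90000, 120000, 10100, 150000, 160000),
                  rep("-", 5))
  fm <- hoci_filtered_matrix(v, hocis, g, "c1", 40000)
  expect_equal(sum(fm$counts[upper.tri(fm$counts, diag = TRUE)]), 3)

  all_fm <- hoci_filtered_matrix(v[1:3, ], hocis, g, "c1", 40000)
  direct <- bin_pairs(v[1:3, ], g, "c1", 40000)
  expect_equal(all_fm$counts, direct$counts)

  none <- hoci_filtered_matrix(
    v, data.frame(chrom = "c1", start = 195000, end = 196000, name = "x"),
    g, "c1", 40000)
  expect_equal(sum(none$counts), 0)
})

test_that("compartment reordering is a pure permutation", {
  m <- matrix(1:16, 4); m <- m + t(m)
  cm <- toy_cm(m)
  track <- data.frame(bin = 1:4, chrom = "c", start = (0:3) * 1000,
                      end = (1:4) * 1000, pc1 = c(-1, 1, -1, 1),
                      compartment = c("B", "A", "B", "A"))
  ro <- reorder_by_compartment(cm, track)
  expect_equal(ro$bin_order, c(2, 4, 1, 3))
  expect_equal(sort(as.vector(ro$counts)), sort(as.vector(m)))
  expect_equal(eigen(ro$counts)$values, eigen(m)$values)

  # applying the inverse permutation restores the original
  inv <- order(ro$bin_order)
  expect_equal(ro$counts[inv, inv], m)

  all_a <- track; all_a$compartment <- "A"
  expect_equal(reorder_by_compartment(cm, all_a)$bin_order, 1:4)
  expect_error(reorder_by_compartment(cm, track[1:3, ]), "cover")
})

test_that("compartment proportions of HOCIs and partners are recovered", {
  n <- 100
  track <- data.frame(bin = 1:n, chrom = "c", start = (0:(n - 1)) * 1000,
                      end = (1:n) * 1000, pc1 = 0,
                      compartment = rep(c("A", "B"), each = n / 2))
  cm <- toy_cm(matrix(1, n, n))
  set.seed(6)
  # 500 HOCIs, planted 80% in A bins
  in_a <- stats::runif(500) < 0.8
  bin_of <- ifelse(in_a, sample.int(n / 2, 500, TRUE),
                   n / 2 + sample.int(n / 2, 500, TRUE))
  hocis <- data.frame(chrom = "c", start = (bin_of - 1) * 1000 + 100,
                      end = (bin_of - 1) * 1000 + 200,
                      name = paste0("h", 1:500))
  v <- read_pairs(character(), numeric(), character(), character(),
                  numeric(), character())
  pr <- hoci_compartment_proportions(hocis, v, track, cm)
  expect_lt(abs(pr$hoci_prop[["A"]] - 0.8), 0.04)

  # partners: mate loci of pairs with one end in a HOCI
  v2 <- read_pairs(rep("c", 4), hocis$start[1:4] + 10, rep("+", 4),
                   rep("c", 4), c(500, 1500, 60500, 70500), rep("-", 4))
  pr2 <- hoci_compartment_proportions(hocis, v2, track, cm)
  expect_equal(pr2$partner_prop[["A"]], 0.5)
  no_lab <- track; no_lab$compartment <- NA_character_
  expect_error(hoci_compartment_proportions(hocis, v2, no_lab, cm),
               "labels")
})

test_that("contact matrices round-trip through COO text", {
  tmp <- withr::local_tempdir()
  g <- genome_assembly(c(c1 = 200000))
  set.seed(52)
  n <- 100
  v <- read_pairs(rep("c1", n), sample.int(2e5, n) - 1, rep("+", n),
                  rep("c1", n), sample.int(2e5, n) - 1, rep("-", n))
  cm <- bin_pairs(v, g, "c1", 20000)
  write_contact_matrix(cm, file.path(tmp, "m"))
  coo <- utils::read.table(file.path(tmp, "m.coo.txt"))
  back <- matrix(0, nrow(cm$counts), ncol(cm$counts))
  for (k in seq_len(nrow(coo))) {
    back[coo[k, 1], coo[k, 2]] <- coo[k, 3]
    back[coo[k, 2], coo[k, 1]] <- coo[k, 3]
  }
  expect_equal(back, cm$counts)
})
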