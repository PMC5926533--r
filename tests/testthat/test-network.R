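net_fixture <- function() {
  hocis <- data.frame(chrom = "c1",
                      start = c(1000, 50000, 90000),
                      end = c(2000, 51000, 91000),
                      name = c("A", "B", "C"),
                      class = c("PROMOTER", "ENHANCER", "OTHER"))
  valid <- read_pairs(
    chrom1 = rep("c1", 5),
    pos1 = c(1500, 1600, 1700, 1100, 1200),
    strand1 = rep("+", 5),
    chrom2 = rep("c1", 5),
    pos2 = c(50500, 50600, 90500, 1900, 30000),
    strand2 = rep("-", 5))
  # pairs: (A,B) x2, (A,C) x1, within-A x1, (A, none) x1
  list(hocis = hocis, valid = valid)
}

test_that("network edges, degrees and interaction counts are exact", {
  f <- net_fixture()
  net <- build_network(f$valid, f$hocis)
  expect_equal(net$edges$weight[net$edges$node_i == 1 &
                                  net$edges$node_j == 2], 2)
  expect_equal(net$edges$weight[net$edges$node_i == 1 &
                                  net$edges$node_j == 3], 1)
  expect_equal(nrow(net$edges), 2)
  expect_equal(net$nodes$degree, c(2, 1, 1))
  expect_equal(net$nodes$interaction_count, c(5, 2, 1))
  expect_equal(igraph::gsize(net$graph), 2)

  none <- build_network(f$valid[0, ], f$hocis)
  expect_equal(nrow(none$edges), 0)
  expect_equal(none$nodes$interaction_count, c(0, 0, 0))

  heavy <- build_network(f$valid, f$hocis, min_weight = 2)
  expect_equal(nrow(heavy$edges), 1)

  bad <- f$hocis
  bad$start[2] <- 1500; bad$end[2] <- 2500   # overlaps hub A
  expect_error(build_network(f$valid, bad), "overlap")
})

test_that("edge bookkeeping conserves pair end incidences", {
  f <- net_fixture()
  net <- build_network(f$valid, f$hocis)
  h1 <- point_in_intervals(f$valid$chrom1, f$valid$pos1, f$hocis)
  h2 <- point_in_intervals(f$valid$chrom2, f$valid$pos2, f$hocis)
  total_incidences <- sum(!is.na(h1)) + sum(!is.na(h2))
  within <- sum(!is.na(h1) & !is.na(h2) & h1 == h2)
  single <- sum(xor(is.na(h1), is.na(h2)))
  expect_equal(2 * sum(net$edges$weight) + 2 * within + single,
               total_incidences)
})

test_that("pair categories follow the two-end precedence", {
  f <- net_fixture()
  valid <- read_pairs(
    chrom1 = rep("c1", 6),
    pos1 = c(1500, 50100, 1500, 1500, 50100, 20000),
    strand1 = rep("+", 6),
    chrom2 = rep("c1", 6),
    pos2 = c(1900, 50900, 50500, 30000, 30000, 30500),
    strand2 = rep("-", 6))
  out <- categorize_pairs(valid, f$hocis)
  expect_equal(as.character(out$category),
               c("PROMOTER_HOCI", "ENHANCER_HOCI", "PROMOTER_ENHANCER_HOCI",
                 "PROMOTER_HOCI_RELATED", "ENHANCER_HOCI_RELATED", "OTHER"))
  expect_equal(sum(table(out$category)), nrow(valid))  # partition
  expect_error(categorize_pairs(valid, f$hocis[, -5]), "classified")
})

test_that("distance summaries use the lower-middle median", {
  mk <- function(d) {
    v <- read_pairs(rep("c1", length(d)), rep(1500, length(d)),
                    rep("+", length(d)), rep("c1", length(d)),
                    1500 + d, rep("-", length(d)))
    categorize_pairs(v, net_fixture()$hocis)
  }
  expect_equal(distance_summary(mk(c(10, 30, 50)))$median, 30)
  expect_equal(distance_summary(mk(42))$median, 42)
  expect_equal(distance_summary(mk(c(10, 20)))$median, 10)  # even n: lower
  # absent categories are dropped, not reported as zero
  out <- distance_summary(mk(c(10, 30)))
  expect_false("ENHANCER_HOCI" %in% out$category)
})

test_that("planted distance medians are recovered by the full chain", {
  bd <- default_bundle()
  cats <- categorize_pairs(bd$flt$valid, bd$hoci)
  ds <- distance_summary(cats)
  med <- function(cc) ds$median[ds$category == cc]
  cfg <- bd$b$config
  expect_lt(abs(med("PROMOTER_HOCI") - cfg$dist_medians[["pp"]]) /
              cfg$dist_medians[["pp"]], 0.10)
  expect_lt(abs(med("ENHANCER_HOCI") - cfg$dist_medians[["ee"]]) /
              cfg$dist_medians[["ee"]], 0.10)
  expect_lt(abs(med("PROMOTER_ENHANCER_HOCI") - cfg$dist_medians[["pe"]]) /
              cfg$dist_medians[["pe"]], 0.10)
})

test_that("interactions per peak and the two-sample comparison behave", {
  iv <- data.frame(chrom = "c1", start = c(1000, 5000), end = c(2000, 6000))
  v <- read_pairs(rep("c1", 4), c(1100, 1200, 1300, 5100), rep("+", 4),
                  rep("c1", 4), c(5200, 5300, 9000, 9500), rep("-", 4))
  r <- interactions_per_peak(v, iv)
  expect_equal(r$counts, c(3, 3))
  expect_equal(r$mean, 3)

  same <- interactions_per_peak(v, iv, other = v)
  expect_gt(same$p_value, 0.5)
  expect_error(interactions_per_peak(v, iv[0, ]), "empty")

  # planted 10x enrichment across 200 intervals
  set.seed(11)
  iv200 <- data.frame(chrom = "c1", start = (0:199) * 5000,
                      end = (0:199) * 5000 + 1000)
  mk_ends <- function(lambda) {
    n <- stats::rpois(200, lambda)
    pos <- unlist(lapply(1:200, function(i)
      iv200$start[i] + sample.int(1000, n[i], replace = TRUE) - 1))
    read_pairs(rep("c1", length(pos)), pos, rep("+", length(pos)),
               rep("c1", length(pos)), rep(2e6, length(pos)),
               rep("-", length(pos)))
  }
  enriched <- interactions_per_peak(mk_ends(20), iv200,
                                    other = mk_ends(2))
  expect_lt(enriched$p_value, 1e-6)
})

test_that("planted hub-hub edges appear with their planted weights", {
  bd <- default_bundle()
  net <- build_network(bd$flt$valid, bd$hoci)
  hubs <- bd$b$truth$hubs
  cfg <- bd$b$config
  # map each called HOCI to the planted hub it overlaps
  hit <- overlap_list(bd$hoci, hubs)
  node_of_hub <- rep(NA_integer_, nrow(hubs))
  node_of_hub[hit$subject_idx] <- hit$query_idx
  groups <- split(hubs, hubs$group)
  checked <- 0
  for (grp in groups) {
    p <- grp$hub_id[grp$class == "PROMOTER"]
    ni <- node_of_hub[match(p[1], hubs$hub_id)]
    nj <- node_of_hub[match(p[2], hubs$hub_id)]
    if (is.na(ni) || is.na(nj)) next
    w <- net$edges$weight[net$edges$node_i == min(ni, nj) &
                            net$edges$node_j == max(ni, nj)]
    expect_equal(length(w), 1)
    expect_gte(w, cfg$pairs_per_edge * 0.95)   # planted pairs minus dedup
    expect_lte(w, cfg$pairs_per_edge * 1.25)   # plus accidental contacts
    checked <- checked + 1
  }
  expect_gte(checked, 6)
})
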