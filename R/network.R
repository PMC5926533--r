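PAIR_CATEGORIES <- c("PROMOTER_HOCI", "ENHANCER_HOCI", "PROMOTER_ENHANCER_HOCI",
                     "PROMOTER_HOCI_RELATED", "ENHANCER_HOCI_RELATED", "OTHER")

# map each read end (5' point) to the index of the containing HOCI, or NA;
# HOCIs must be non-overlapping for the assignment to be unambiguous
.ends_to_hoci <- function(valid, hocis) {
  if (nrow(hocis) > 1) {
    ord <- order(hocis$chrom, hocis$start)
    h <- hocis[ord, ]
    ovl <- any(h$chrom[-1] == h$chrom[-nrow(h)] &
                 h$start[-1] < h$end[-nrow(h)])
    if (ovl) stop("HOCIs overlap; end assignment would be ambiguous")
  }
  list(h1 = point_in_intervals(valid$chrom1, valid$pos1, hocis),
       h2 = point_in_intervals(valid$chrom2, valid$pos2, hocis))
}

#' Build the HOCI-HOCI interaction network
#'
#' Nodes are HOCIs; an edge connects two HOCIs with weight equal to the
#' number of valid pairs having one 5' end inside each. Pairs with both ends
#' in the same HOCI contribute to that node's interaction count but form no
#' edge. Each node's `interaction_count` is the number of valid pairs with
#' at least one end in it.
#'
#' @param valid valid-pair data.frame.
#' @param hocis non-overlapping HOCI data.frame (optionally classified).
#' @param min_weight drop edges with fewer pairs than this (default 1).
#' @return list: `nodes` (hocis + degree, interaction_count), `edges`
#'   (data.frame node_i, node_j, weight with i < j), `graph` (igraph object).
#' @export
build_network <- function(valid, hocis, min_weight = 1) {
  e <- .ends_to_hoci(valid, hocis)
  touch1 <- !is.na(e$h1); touch2 <- !is.na(e$h2)
  # interaction_count: pairs with >=1 end in the node (both-in counts once)
  ic <- tabulate(unique_node_hits(e$h1, e$h2, nrow(hocis)),
                 nbins = nrow(hocis))
  both <- touch1 & touch2 & e$h1 != e$h2
  edges <- data.frame(node_i = pmin(e$h1[both], e$h2[both]),
                      node_j = pmax(e$h1[both], e$h2[both]))
  if (nrow(edges)) {
    agg <- stats::aggregate(list(weight = rep(1L, nrow(edges))),
                            edges, FUN = sum)
    agg <- agg[agg$weight >= min_weight, , drop = FALSE]
    agg <- agg[order(agg$node_i, agg$node_j), , drop = FALSE]
  } else {
    agg <- data.frame(node_i = integer(), node_j = integer(),
                      weight = integer())
  }
  nodes <- hocis
  nodes$interaction_count <- ic
  deg <- tabulate(c(agg$node_i, agg$node_j), nbins = nrow(hocis))
  nodes$degree <- deg
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(agg$node_i),
               to = as.character(agg$node_j), weight = agg$weight),
    directed = FALSE,
    vertices = data.frame(name = as.character(seq_len(nrow(hocis))),
                          hoci = hocis$name))
  rownames(agg) <- NULL
  list(nodes = nodes, edges = agg, graph = g)
}

# pairs hitting each node at least once: index list without double-counting
# a pair whose two ends fall in the same node
unique_node_hits <- function(h1, h2, n_nodes) {
  a <- h1[!is.na(h1)]
  b <- h2[!is.na(h2) & (is.na(h1) | h1 != h2)]
  c(a, b)
}

#' Categorize valid pairs by the HOCI classes of their ends
#'
#' Precedence: both ends in promoter HOCIs -> `PROMOTER_HOCI`; both in
#' enhancer HOCIs -> `ENHANCER_HOCI`; one of each -> `PROMOTER_ENHANCER_HOCI`;
#' else at least one end in a promoter HOCI -> `PROMOTER_HOCI_RELATED`; else
#' at least one in an enhancer HOCI -> `ENHANCER_HOCI_RELATED`; else `OTHER`.
#'
#' @param valid valid-pair data.frame.
#' @param hocis classified HOCI data.frame (`class` column).
#' @return `valid` with `category` (factor) and `cis_distance` columns;
#'   trans pairs have `cis_distance` NA.
#' @export
categorize_pairs <- function(valid, hocis) {
  if (is.null(hocis$class)) stop("hocis must be classified (class column)")
  e <- .ends_to_hoci(valid, hocis)
  cls1 <- ifelse(is.na(e$h1), NA_character_, hocis$class[e$h1])
  cls2 <- ifelse(is.na(e$h2), NA_character_, hocis$class[e$h2])
  p1 <- !is.na(cls1) & cls1 == "PROMOTER"; p2 <- !is.na(cls2) & cls2 == "PROMOTER"
  e1 <- !is.na(cls1) & cls1 == "ENHANCER"; e2 <- !is.na(cls2) & cls2 == "ENHANCER"
  cat <- rep("OTHER", nrow(valid))
  cat[p1 | p2] <- "PROMOTER_HOCI_RELATED"
  cat[!(p1 | p2) & (e1 | e2)] <- "ENHANCER_HOCI_RELATED"
  cat[(p1 & e2) | (e1 & p2)] <- "PROMOTER_ENHANCER_HOCI"
  cat[e1 & e2] <- "ENHANCER_HOCI"
  cat[p1 & p2] <- "PROMOTER_HOCI"
  valid$category <- factor(cat, levels = PAIR_CATEGORIES)
  if (is.null(valid$cis_distance))
    valid$cis_distance <- ifelse(valid$chrom1 == valid$chrom2,
                                 abs(valid$pos1 - valid$pos2), NA_real_)
  valid
}

# lower-of-the-two-middle-values median (exact for even n, documented)
median_low <- function(x) {
  x <- sort(x)
  x[ceiling(length(x) / 2)]
}

#' Per-category cis-distance summaries
#'
#' Medians use the lower of the two middle values for even sample sizes.
#' Categories with no cis pairs are reported as absent (dropped), not zero.
#'
#' @param categorized output of [categorize_pairs()].
#' @return data.frame: category, n, median, q25, q75.
#' @export
distance_summary <- function(categorized) {
  cis <- categorized[!is.na(categorized$cis_distance), , drop = FALSE]
  cats <- levels(cis$category)[table(cis$category) > 0]
  out <- lapply(cats, function(cc) {
    d <- cis$cis_distance[cis$category == cc]
    data.frame(category = cc, n = length(d), median = median_low(d),
               q25 = unname(stats::quantile(d, 0.25)),
               q75 = unname(stats::quantile(d, 0.75)))
  })
  do.call(rbind, out)
}

#' Interactions per peak, with an optional two-sample comparison
#'
#' Counts valid-pair end hits per interval (each end counts one hit). When a
#' second pair set is supplied, the per-interval counts of the two sets over
#' the same intervals are compared with a Mann-Whitney (default) or Welch
#' t-test.
#'
#' @param valid valid-pair data.frame.
#' @param intervals interval data.frame (e.g. HOCIs).
#' @param other optional second valid-pair data.frame.
#' @param test `"wilcox"` (default) or `"t"`.
#' @return list: `counts`, `mean`, and when `other` is given
#'   `counts_other`, `mean_other`, `p_value`.
#' @export
interactions_per_peak <- function(valid, intervals, other = NULL,
                                  test = c("wilcox", "t")) {
  test <- match.arg(test)
  if (!nrow(intervals)) stop("empty interval set")
  hit_counts <- function(v) {
    i1 <- point_in_intervals(v$chrom1, v$pos1, intervals)
    i2 <- point_in_intervals(v$chrom2, v$pos2, intervals)
    tabulate(c(i1[!is.na(i1)], i2[!is.na(i2)]), nbins = nrow(intervals))
  }
  cnt <- hit_counts(valid)
  out <- list(counts = cnt, mean = mean(cnt))
  if (!is.null(other)) {
    cnt2 <- hit_counts(other)
    p <- if (test == "wilcox")
      stats::wilcox.test(cnt, cnt2, exact = FALSE)$p.value
    else stats::t.test(cnt, cnt2)$p.value
    if (is.nan(p)) p <- 1   # all-tied samples carry no evidence

    out$counts_other <- cnt2
    out$mean_other <- mean(cnt2)
    out$p_value <- p
  }
  out
}

#' Export network edges as BEDPE / edge-list TSV
#' @param network list from [build_network()].
#' @param path output file.
#' @export
write_network_bedpe <- function(network, path) {
  h <- network$nodes
  e <- network$edges
  out <- data.frame(chrom1 = h$chrom[e$node_i], start1 = h$start[e$node_i],
                    end1 = h$end[e$node_i], chrom2 = h$chrom[e$node_j],
                    start2 = h$start[e$node_j], end2 = h$end[e$node_j],
                    name = sprintf("edge%d", seq_len(nrow(e))),
                    score = e$weight, strand1 = ".", strand2 = ".")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
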