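#' @name pair_classes
#' @title Read-pair classes
#' @description Every aligned read pair receives exactly one class:
#' `VALID_CIS`, `VALID_TRANS`, `DANGLING_END` (same fragment, inward),
#' `SELF_CIRCLE` (same fragment, outward), `SAME_STRAND_DUMPED` (same
#' fragment, equal strands), `TOO_CLOSE` (different fragments closer than
#' the separation threshold) or `LOW_MAPQ`.
NULL

PAIR_CLASSES <- c("VALID_CIS", "VALID_TRANS", "DANGLING_END", "SELF_CIRCLE",
                  "SAME_STRAND_DUMPED", "TOO_CLOSE", "LOW_MAPQ")

#' Construct a read-pair table
#'
#' @param chrom1,pos1,strand1,chrom2,pos2,strand2 mapped 5' coordinate and
#'   strand of each mate (0-based positions, strands `+`/`-`).
#' @param mapq1,mapq2 mapping qualities.
#' @param pair_id optional labels.
#' @return data.frame with one row per pair.
#' @export
read_pairs <- function(chrom1, pos1, strand1, chrom2, pos2, strand2,
                       mapq1 = 30L, mapq2 = 30L, pair_id = NULL) {
  n <- length(pos1)
  if (!all(c(strand1, strand2) %in% c("+", "-")))
    stop("strands must be '+' or '-'")
  data.frame(pair_id = if (is.null(pair_id)) sprintf("pair%d", seq_len(n))
             else pair_id,
             chrom1 = chrom1, pos1 = as.numeric(pos1), strand1 = strand1,
             chrom2 = chrom2, pos2 = as.numeric(pos2), strand2 = strand2,
             mapq1 = rep_len(mapq1, n), mapq2 = rep_len(mapq2, n),
             stringsAsFactors = FALSE)
}

#' Read aligned pairs from a BEDPE file
#'
#' Expected columns: chrom1 start1 end1 chrom2 start2 end2 name score
#' strand1 strand2 \[mapq1 mapq2\]. The 5' position of each mate is taken as
#' `start` for `+` strand and `end - 1` for `-` strand.
#' @param path BEDPE file.
#' @export
read_pairs_bedpe <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 10) stop("BEDPE needs >= 10 columns")
  mapq1 <- if (ncol(df) >= 12) df[[11]] else 30L
  mapq2 <- if (ncol(df) >= 12) df[[12]] else 30L
  read_pairs(chrom1 = df[[1]],
             pos1 = ifelse(df[[9]] == "+", df[[2]], df[[3]] - 1),
             strand1 = df[[9]],
             chrom2 = df[[4]],
             pos2 = ifelse(df[[10]] == "+", df[[5]], df[[6]] - 1),
             strand2 = df[[10]],
             mapq1 = mapq1, mapq2 = mapq2, pair_id = as.character(df[[7]]))
}

#' Classify read pairs into valid and artifact classes
#'
#' Decision order per pair: (1) either MAPQ < `mapq_min` gives `LOW_MAPQ`;
#' (2) different chromosomes give `VALID_TRANS`; (3) both ends in one
#' restriction fragment give `DANGLING_END` / `SELF_CIRCLE` /
#' `SAME_STRAND_DUMPED` by orientation (mates are first put in coordinate
#' order, so the result is mate-order invariant: leading `+` then `-` is
#' inward = dangling end, leading `-` then `+` is outward = self-circle);
#' (4) different fragments closer than `min_separation` give `TOO_CLOSE`;
#' (5) otherwise `VALID_CIS`.
#'
#' @param pairs read-pair data.frame (see [read_pairs()]).
#' @param map `FragmentMap` covering all positions.
#' @param mapq_min pairs with either MAPQ below this are dropped
#'   (default 1, i.e. only MAPQ 0 multi-mappers are removed).
#' @param min_separation bp; cis pairs whose fragments are closer than this
#'   are discarded (default 1000).
#' @param distance_mode `"midpoint"` (default; distance between fragment
#'   midpoints) or `"edge"` (gap between fragment inner edges).
#' @return factor of classes, levels [PAIR_CLASSES].
#' @export
classify_pairs <- function(pairs, map, mapq_min = 1, min_separation = 1000,
                           distance_mode = c("midpoint", "edge")) {
  distance_mode <- match.arg(distance_mode)
  n <- nrow(pairs)
  cls <- rep(NA_character_, n)
  fid1 <- assign_fragment(map, pairs$chrom1, pairs$pos1)
  fid2 <- assign_fragment(map, pairs$chrom2, pairs$pos2)

  low <- pairs$mapq1 < mapq_min | pairs$mapq2 < mapq_min
  cls[low] <- "LOW_MAPQ"
  trans <- is.na(cls) & pairs$chrom1 != pairs$chrom2
  cls[trans] <- "VALID_TRANS"

  same <- is.na(cls) & fid1 == fid2
  if (any(same)) {
    # canonical orientation: sort mates by coordinate (mate order agnostic)
    first_plus <- ifelse(pairs$pos1 <= pairs$pos2,
                         pairs$strand1, pairs$strand2) == "+"
    second_plus <- ifelse(pairs$pos1 <= pairs$pos2,
                          pairs$strand2, pairs$strand1) == "+"
    cls[same & (pairs$strand1 == pairs$strand2)] <- "SAME_STRAND_DUMPED"
    cls[same & is.na(cls) & first_plus & !second_plus] <- "DANGLING_END"
    cls[same & is.na(cls) & !first_plus & second_plus] <- "SELF_CIRCLE"
  }

  rest <- is.na(cls)
  if (any(rest)) {
    if (distance_mode == "midpoint") {
      mids <- fragment_midpoints(map)
      d <- abs(mids[fid1[rest] + 1] - mids[fid2[rest] + 1])
    } else {
      fr <- map$fragments
      lo <- pmin(fid1[rest], fid2[rest]) + 1
      hi <- pmax(fid1[rest], fid2[rest]) + 1
      d <- pmax(0, fr$start[hi] - fr$end[lo])
    }
    cls[rest][d < min_separation] <- "TOO_CLOSE"
    cls[rest][d >= min_separation] <- "VALID_CIS"
  }
  factor(cls, levels = PAIR_CLASSES)
}

#' @rdname classify_pairs
#' @param chrom1,pos1,strand1,chrom2,pos2,strand2,mapq1,mapq2 a single pair.
#' @param ... passed to [classify_pairs()].
#' @export
classify_pair <- function(chrom1, pos1, strand1, chrom2, pos2, strand2,
                          map, mapq1 = 30, mapq2 = 30, ...) {
  as.character(classify_pairs(read_pairs(chrom1, pos1, strand1, chrom2, pos2,
                                         strand2, mapq1, mapq2), map, ...))
}

#' Filter a read-pair table into the valid-pair set
#'
#' Applies [classify_pairs()], reports counts per class (a partition of the
#' input), and returns the valid pairs annotated with fragment ids, the
#' read-position cis distance and the fragment-midpoint distance. Exact
#' coordinate+strand duplicates (PCR duplicates) among valid pairs are
#' removed by default after putting mates in canonical coordinate order.
#'
#' @inheritParams classify_pairs
#' @param dedup remove exact duplicates among valid pairs (default TRUE).
#' @return list with `valid` (data.frame: pair columns + `class`,
#'   `fragment_id1`, `fragment_id2`, `cis_distance` (|pos1-pos2|, NA for
#'   trans), `frag_distance`), `counts` (named integer vector over all
#'   classes, summing to the input pair count) and `n_duplicates_removed`.
#' @export
filter_pairs <- function(pairs, map, mapq_min = 1, min_separation = 1000,
                         distance_mode = "midpoint", dedup = TRUE) {
  cls <- classify_pairs(pairs, map, mapq_min, min_separation, distance_mode)
  counts <- table(cls)
  counts <- stats::setNames(as.integer(counts), names(counts))
  keep <- cls %in% c("VALID_CIS", "VALID_TRANS")
  valid <- pairs[keep, , drop = FALSE]
  valid$class <- as.character(cls[keep])

  # canonical mate order: (chrom1,pos1) <= (chrom2,pos2)
  swap <- valid$chrom1 > valid$chrom2 |
    (valid$chrom1 == valid$chrom2 & valid$pos1 > valid$pos2)
  if (any(swap)) {
    tmp <- valid[swap, c("chrom1", "pos1", "strand1", "mapq1")]
    valid[swap, c("chrom1", "pos1", "strand1", "mapq1")] <-
      valid[swap, c("chrom2", "pos2", "strand2", "mapq2")]
    valid[swap, c("chrom2", "pos2", "strand2", "mapq2")] <- tmp
  }

  n_dup <- 0L
  if (dedup && nrow(valid) > 0) {
    key <- paste(valid$chrom1, valid$pos1, valid$strand1,
                 valid$chrom2, valid$pos2, valid$strand2)
    dup <- duplicated(key)
    n_dup <- sum(dup)
    valid <- valid[!dup, , drop = FALSE]
  }

  if (nrow(valid) > 0) {
    valid$fragment_id1 <- assign_fragment(map, valid$chrom1, valid$pos1)
    valid$fragment_id2 <- assign_fragment(map, valid$chrom2, valid$pos2)
    mids <- fragment_midpoints(map)
    cis <- valid$class == "VALID_CIS"
    valid$cis_distance <- ifelse(cis, abs(valid$pos1 - valid$pos2), NA_real_)
    valid$frag_distance <- ifelse(cis, abs(mids[valid$fragment_id1 + 1] -
                                           mids[valid$fragment_id2 + 1]),
                                  NA_real_)
  } else {
    valid$fragment_id1 <- integer(0); valid$fragment_id2 <- integer(0)
    valid$cis_distance <- numeric(0); valid$frag_distance <- numeric(0)
  }
  rownames(valid) <- NULL
  list(valid = valid, counts = counts, n_duplicates_removed = n_dup)
}

#' Write / read a valid-pair set as annotated .pairs-style text
#' @param valid valid-pair data.frame from [filter_pairs()].
#' @param path output file.
#' @export
write_valid_pairs <- function(valid, path) {
  cols <- c("pair_id", "chrom1", "pos1", "strand1", "chrom2", "pos2",
            "strand2", "mapq1", "mapq2", "class")
  utils::write.table(valid[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_valid_pairs
#' @export
read_valid_pairs <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write the per-class pair report
#' @param counts named counts from [filter_pairs()].
#' @param path TSV output.
#' @export
write_pair_report <- function(counts, path) {
  utils::write.table(data.frame(class = names(counts),
                                n = as.integer(counts),
                                fraction = as.integer(counts) / sum(counts)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
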