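#' Bin cis valid pairs into a per-chromosome contact matrix
#'
#' @param valid valid-pair data.frame.
#' @param assembly `GenomeAssembly`.
#' @param chrom chromosome to bin.
#' @param resolution bin size in bp (default 40000).
#' @return `ContactMatrix`: list with `chrom`, `resolution`, `bins`
#'   (data.frame chrom/start/end), symmetric dense `counts`, `weights`
#'   (NULL until balanced), `masked` (logical), `balanced` flag, and the
#'   raw `total_pairs`.
#' @export
bin_pairs <- function(valid, assembly, chrom, resolution = 40000) {
  if (resolution <= 0) stop("resolution must be > 0")
  if (!chrom %in% names(assembly$lengths))
    stop("unknown chromosome: ", chrom)
  len <- assembly$lengths[[chrom]]
  n <- ceiling(len / resolution)
  cis <- valid[valid$chrom1 == chrom & valid$chrom2 == chrom, , drop = FALSE]
  m <- matrix(0, n, n)
  if (nrow(cis)) {
    b1 <- cis$pos1 %/% resolution + 1
    b2 <- cis$pos2 %/% resolution + 1
    for (k in seq_along(b1)) {
      m[b1[k], b2[k]] <- m[b1[k], b2[k]] + 1
      if (b1[k] != b2[k]) m[b2[k], b1[k]] <- m[b2[k], b1[k]] + 1
    }
  }
  starts <- (seq_len(n) - 1) * resolution
  structure(list(chrom = chrom, resolution = resolution,
                 bins = data.frame(chrom = chrom, start = starts,
                                   end = pmin(starts + resolution, len)),
                 counts = m, weights = NULL,
                 masked = rep(FALSE, n), balanced = FALSE,
                 total_pairs = nrow(cis)),
            class = "ContactMatrix")
}

#' @export
print.ContactMatrix <- function(x, ...) {
  cat("ContactMatrix:", x$chrom, "at", x$resolution, "bp,",
      nrow(x$counts), "bins,", x$total_pairs, "pairs",
      if (x$balanced) "(ICE balanced)" else "(raw)", "\n")
  invisible(x)
}

#' ICE matrix balancing (iterative correction)
#'
#' Repeatedly divides rows and columns by their marginal sums (normalised to
#' mean 1 over unmasked bins) until the coefficient of variation of the
#' unmasked row sums drops below `tol` or `max_iter` is reached. Bins in the
#' lowest `mask_quantile` of coverage (and all-zero bins) are masked and
#' excluded.
#'
#' @param cm `ContactMatrix`.
#' @param max_iter maximum iterations (default 100).
#' @param tol convergence tolerance on the row-sum CV (default 1e-4).
#' @param mask_quantile fraction of lowest-coverage bins masked
#'   (default 0.02).
#' @return balanced `ContactMatrix` with `weights` (bias vector, NA on
#'   masked bins) and `n_iter`.
#' @export
ice_balance <- function(cm, max_iter = 100, tol = 1e-4, mask_quantile = 0.02) {
  m <- cm$counts
  cov <- rowSums(m)
  if (all(cov == 0)) stop("all-zero contact matrix cannot be balanced")
  masked <- cov == 0
  if (mask_quantile > 0) {
    thr <- stats::quantile(cov[!masked], mask_quantile)
    masked <- masked | cov <= thr & cov < max(cov)
  }
  w <- rep(1, nrow(m))
  mm <- m
  mm[masked, ] <- 0; mm[, masked] <- 0
  n_iter <- 0L
  for (it in seq_len(max_iter)) {
    s <- rowSums(mm)
    su <- s[!masked]
    cv <- stats::sd(su) / mean(su)
    n_iter <- it - 1L
    if (cv < tol) break
    s_norm <- s / mean(su)
    s_norm[masked | s_norm == 0] <- 1
    w <- w * s_norm
    mm <- mm / outer(s_norm, s_norm)
    n_iter <- it
  }
  w[masked] <- NA
  cm$counts <- mm
  cm$weights <- w
  cm$masked <- masked
  cm$balanced <- TRUE
  cm$n_iter <- n_iter
  cm
}

# observed/expected by diagonal: expected = mean of each diagonal over
# unmasked entries; diagonals with no unmasked entry are skipped (left 0)
.obs_exp <- function(m, masked) {
  n <- nrow(m)
  oe <- matrix(0, n, n)
  ok <- !masked
  for (d in 0:(n - 1)) {
    i <- seq_len(n - d)
    j <- i + d
    use <- ok[i] & ok[j]
    if (!any(use)) next
    e <- mean(m[cbind(i[use], j[use])])
    if (e == 0) next
    oe[cbind(i[use], j[use])] <- m[cbind(i[use], j[use])] / e
    oe[cbind(j[use], i[use])] <- oe[cbind(i[use], j[use])]
  }
  oe
}

#' A/B compartments from the contact correlation matrix
#'
#' Observed/expected by diagonal, Pearson correlation matrix over unmasked
#' bins, first principal component (leading eigenvector); the sign is
#' oriented so that bins richer in `orientation_track` (e.g. HOCIs or gene
#' density) get positive values. A = positive PC1, B = negative.
#'
#' @param cm balanced `ContactMatrix`.
#' @param orientation_track interval data.frame used to orient the sign.
#' @param min_unmasked minimum unmasked bins required (default 10).
#' @param reliability_sd PC1 standard deviations below this flag the track
#'   unreliable (default 1e-8).
#' @return `CompartmentTrack` data.frame: bin, chrom, start, end, pc1,
#'   compartment (`A`/`B`, NA on masked bins); attribute `reliable`.
#' @export
compartments <- function(cm, orientation_track, min_unmasked = 10,
                         reliability_sd = 1e-8) {
  if (!cm$balanced) stop("balance the matrix first (ice_balance)")
  ok <- !cm$masked
  if (sum(ok) < min_unmasked) stop("too few unmasked bins (< ", min_unmasked, ")")
  oe <- .obs_exp(cm$counts, cm$masked)
  sub <- oe[ok, ok, drop = FALSE]
  keep <- apply(sub, 1, stats::sd) > 0
  pc1 <- rep(NA_real_, nrow(cm$counts))
  if (sum(keep) < 2) {
    # structureless matrix: flat observed/expected, no compartment signal
    pc1[ok] <- 0
    reliable <- FALSE
  } else {
    cc <- stats::cor(sub[keep, keep, drop = FALSE])
    cc[is.na(cc)] <- 0
    ev <- eigen(cc, symmetric = TRUE)
    pc1_sub <- ev$vectors[, 1]
    pc1[which(ok)[keep]] <- pc1_sub
    reliable <- stats::sd(pc1_sub) > reliability_sd
  }
  # orient: bins overlapped by the orientation track should be positive
  rich <- overlap_count(cm$bins, orientation_track)
  usable <- !is.na(pc1)
  if (any(usable) && stats::sd(rich[usable]) > 0 &&
      stats::sd(pc1[usable]) > 0) {
    if (stats::cor(pc1[usable], rich[usable]) < 0) pc1 <- -pc1
  }
  out <- data.frame(bin = seq_len(nrow(cm$bins)), cm$bins,
                    pc1 = pc1,
                    compartment = ifelse(is.na(pc1), NA_character_,
                                         ifelse(pc1 >= 0, "A", "B")))
  attr(out, "reliable") <- reliable
  out
}

#' Insulation score and boundary calls
#'
#' The insulation score of bin i is the mean contact count in the
#' `window_bins` x `window_bins` square crossing i (rows i-w..i-1 by
#' columns i+1..i+w). Boundaries are local minima of the log2-normalised
#' score whose boundary strength (lowest flanking local maximum minus the
#' minimum) exceeds `delta_threshold`.
#'
#' @param cm balanced `ContactMatrix`.
#' @param window_bins half-window in bins (default 10, >= 2).
#' @param delta_threshold minimum boundary strength (default 0.1, in log2
#'   units of the normalised score).
#' @return `BoundarySet` data.frame: bin, start, end, insulation (log2
#'   normalised; NA near edges/masked), is_boundary, strength.
#' @export
insulation_boundaries <- function(cm, window_bins = 10, delta_threshold = 0.1) {
  if (window_bins < 2) stop("window_bins must be >= 2")
  n <- nrow(cm$counts)
  if (n <= 2 * window_bins) stop("matrix smaller than the insulation window")
  m <- cm$counts
  m[cm$masked, ] <- NA; m[, cm$masked] <- NA
  w <- window_bins
  raw <- rep(NA_real_, n)
  for (i in (w + 1):(n - w)) {
    sq <- m[(i - w):(i - 1), (i + 1):(i + w), drop = FALSE]
    if (all(is.na(sq))) next
    raw[i] <- mean(sq, na.rm = TRUE)
  }
  score <- log2(raw / mean(raw, na.rm = TRUE))
  score[is.infinite(score)] <- NA

  is_boundary <- logical(n)
  strength <- rep(NA_real_, n)
  idx <- which(!is.na(score))
  for (i in idx) {
    lo <- score[i]
    left <- score[max(1, i - 1)]; right <- score[min(n, i + 1)]
    if (is.na(left) || is.na(right) || lo > left || lo > right) next
    if (lo == left && i > 1) next   # plateau: keep leftmost
    lwin <- score[max(1, i - w):(i - 1)]
    rwin <- score[(i + 1):min(n, i + w)]
    if (all(is.na(lwin)) || all(is.na(rwin))) next
    delta <- min(max(lwin, na.rm = TRUE), max(rwin, na.rm = TRUE)) - lo
    strength[i] <- delta
    if (delta >= delta_threshold) is_boundary[i] <- TRUE
  }
  data.frame(bin = seq_len(n), cm$bins, insulation = score,
             is_boundary = is_boundary, strength = strength)
}

#' HOCI enrichment at boundaries by circular permutation
#'
#' Observed = number of HOCI midpoints falling in boundary bins. The null
#' rotates each HOCI midpoint independently around the chromosome
#' (circular shift by a uniform offset) `n_permutations` times; this
#' preserves each position's marginal uniformity while treating HOCI
#' locations as exchangeable.
#'
#' @param boundaries output of [insulation_boundaries()].
#' @param hocis HOCI data.frame (same chromosome as the matrix).
#' @param cm the `ContactMatrix` the boundaries came from.
#' @param n_permutations number of circular shifts (default 1000).
#' @param seed RNG seed.
#' @return list: `observed`, `expected` (permutation mean), `fold`,
#'   `p_value` (permutation rank, add-one corrected).
#' @export
boundary_hoci_enrichment <- function(boundaries, hocis, cm,
                                     n_permutations = 1000, seed = 1) {
  len <- max(cm$bins$end)
  res <- cm$resolution
  h <- hocis[hocis$chrom == cm$chrom, , drop = FALSE]
  mids <- (h$start + h$end) / 2
  bbins <- boundaries$bin[boundaries$is_boundary]
  count_in <- function(p) sum((p %/% res + 1) %in% bbins)
  observed <- count_in(mids)
  set.seed(seed)
  perm <- vapply(seq_len(n_permutations), function(i) {
    count_in((mids + stats::runif(length(mids), 0, len)) %% len)
  }, 0)
  expected <- mean(perm)
  list(observed = observed, expected = expected,
       fold = if (expected > 0) observed / expected else Inf,
       p_value = (1 + sum(perm >= observed)) / (n_permutations + 1))
}

#' Contact matrix restricted to HOCI-related pairs
#'
#' Bins only the valid pairs with at least one 5' end inside a HOCI.
#' @inheritParams bin_pairs
#' @param hocis HOCI data.frame.
#' @export
hoci_filtered_matrix <- function(valid, hocis, assembly, chrom,
                                 resolution = 40000) {
  in1 <- !is.na(point_in_intervals(valid$chrom1, valid$pos1, hocis))
  in2 <- !is.na(point_in_intervals(valid$chrom2, valid$pos2, hocis))
  bin_pairs(valid[in1 | in2, , drop = FALSE], assembly, chrom, resolution)
}

#' Reorder matrix bins by compartment (A first, genomic order within)
#'
#' A pure permutation of rows/columns: A bins first, then B bins, then
#' unlabelled bins, each group in genomic order.
#' @param cm `ContactMatrix`.
#' @param track `CompartmentTrack` from [compartments()] covering its bins.
#' @return `ContactMatrix` with permuted `counts`/`bins` and a
#'   `bin_order` field (original indices in new order).
#' @export
reorder_by_compartment <- function(cm, track) {
  if (nrow(track) != nrow(cm$counts))
    stop("compartment track does not cover the matrix bins")
  ord <- c(which(!is.na(track$compartment) & track$compartment == "A"),
           which(!is.na(track$compartment) & track$compartment == "B"),
           which(is.na(track$compartment)))
  cm$counts <- cm$counts[ord, ord, drop = FALSE]
  cm$bins <- cm$bins[ord, , drop = FALSE]
  cm$masked <- cm$masked[ord]
  if (!is.null(cm$weights)) cm$weights <- cm$weights[ord]
  cm$bin_order <- ord
  cm
}

#' Compartment occupancy of HOCIs and their interaction partners
#'
#' Each HOCI is assigned the compartment of its midpoint bin; partner loci
#' are the 5' ends whose mate lies inside a HOCI. Proportions are over
#' labelled bins only.
#'
#' @param hocis HOCI data.frame.
#' @param valid valid-pair data.frame.
#' @param track `CompartmentTrack`.
#' @param cm `ContactMatrix` the track belongs to.
#' @return list: `hoci_prop` (named A/B proportions), `partner_prop`,
#'   `n_hoci_labelled`, `n_partner_labelled`.
#' @export
hoci_compartment_proportions <- function(hocis, valid, track, cm) {
  if (all(is.na(track$compartment))) stop("no compartment labels available")
  res <- cm$resolution
  label_of <- function(pos) {
    b <- pos %/% res + 1
    out <- rep(NA_character_, length(b))
    inb <- b >= 1 & b <= nrow(track)
    out[inb] <- track$compartment[b[inb]]
    out
  }
  h <- hocis[hocis$chrom == cm$chrom, , drop = FALSE]
  hoci_lab <- label_of((h$start + h$end) / 2)

  in1 <- !is.na(point_in_intervals(valid$chrom1, valid$pos1, hocis))
  in2 <- !is.na(point_in_intervals(valid$chrom2, valid$pos2, hocis))
  part_pos <- c(valid$pos2[in1 & valid$chrom2 == cm$chrom],
                valid$pos1[in2 & valid$chrom1 == cm$chrom])
  part_lab <- label_of(part_pos)

  prop <- function(lab) {
    lab <- lab[!is.na(lab)]
    if (!length(lab)) return(c(A = NA_real_, B = NA_real_))
    c(A = mean(lab == "A"), B = mean(lab == "B"))
  }
  list(hoci_prop = prop(hoci_lab), partner_prop = prop(part_lab),
       n_hoci_labelled = sum(!is.na(hoci_lab)),
       n_partner_labelled = sum(!is.na(part_lab)))
}

#' Write a contact matrix as COO text plus a bin BED sidecar
#' @param cm `ContactMatrix`.
#' @param path output prefix; writes `<path>.coo.txt` and `<path>.bins.bed`.
#' @export
write_contact_matrix <- function(cm, path) {
  m <- cm$counts
  ut <- which(upper.tri(m, diag = TRUE) & m != 0, arr.ind = TRUE)
  utils::write.table(data.frame(bin1 = ut[, 1], bin2 = ut[, 2],
                                count = m[ut]),
                     paste0(path, ".coo.txt"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_bed(cm$bins, paste0(path, ".bins.bed"))
  invisible(path)
}
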