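#' Build 1D read-end coverage from valid pairs
#'
#' Both ends of every valid pair contribute one event each: a hub is seen as
#' a pile-up of ligation-product ends at open chromatin.
#'
#' @param valid valid-pair data.frame ([filter_pairs()]).
#' @param assembly `GenomeAssembly` (lengths suffice).
#' @param bin_bp bin size in bp (default 50).
#' @return `CoverageTrack`: list with per-chromosome integer count vectors,
#'   `bin_bp` and `total_ends`.
#' @export
build_coverage <- function(valid, assembly, bin_bp = 50) {
  counts <- lapply(assembly$chroms, function(ch) {
    nb <- ceiling(assembly$lengths[[ch]] / bin_bp)
    pos <- c(valid$pos1[valid$chrom1 == ch], valid$pos2[valid$chrom2 == ch])
    tabulate(pos %/% bin_bp + 1L, nbins = nb)
  })
  names(counts) <- assembly$chroms
  structure(list(counts = counts, bin_bp = bin_bp,
                 total_ends = sum(vapply(counts, sum, 0))),
            class = "CoverageTrack")
}

#' @export
print.CoverageTrack <- function(x, ...) {
  cat("CoverageTrack:", length(x$counts), "chromosomes, bin", x$bin_bp,
      "bp,", x$total_ends, "read ends\n")
  invisible(x)
}

# centered running mean with truncated windows at the edges
.running_mean <- function(x, w) {
  if (w >= length(x)) return(rep(mean(x), length(x)))
  half <- w %/% 2
  cs <- cumsum(c(0, x))
  n <- length(x)
  lo <- pmax(0L, seq_len(n) - 1L - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1] - cs[lo + 1]) / (hi - lo)
}

#' Call hubs of open chromatin interactions (HOCIs)
#'
#' MACS-style peak caller on the binned end coverage: each non-empty bin is
#' tested against a Poisson null with local rate
#' `lambda = max(genome-wide rate, mean in each local window)`; p-values are
#' Benjamini-Hochberg adjusted over all tested bins genome-wide; significant
#' bins closer than `merge_gap` are merged; merged peaks shorter than
#' `min_width` are dropped. `mode = "broad"` merges within `4 * merge_gap`
#' before width filtering.
#'
#' @param track `CoverageTrack`.
#' @param q_threshold BH q-value cutoff (default 0.05).
#' @param local_bg_windows local background window sizes in bp
#'   (default `c(5000, 20000)`).
#' @param min_width minimum peak width in bp (default 150).
#' @param merge_gap maximum gap between significant bins merged into one
#'   peak, bp (default 200).
#' @param mode `"narrow"` (default) or `"broad"`.
#' @return data.frame (`HOCISet`): chrom, start, end, name, score
#'   (-log10 q of the best bin), summit (bp of the maximum bin center),
#'   qvalue, enrichment (max count / local lambda), n_bins.
#' @export
call_hoci <- function(track, q_threshold = 0.05,
                      local_bg_windows = c(5000, 20000),
                      min_width = 150, merge_gap = 200,
                      mode = c("narrow", "broad")) {
  mode <- match.arg(mode)
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), name = character(), score = numeric(),
                      summit = numeric(), qvalue = numeric(),
                      enrichment = numeric(), n_bins = integer())
  if (track$total_ends == 0) {
    warning("empty coverage track; no peaks called")
    return(empty)
  }
  bin <- track$bin_bp
  n_bins_total <- sum(lengths(track$counts))
  lambda_bg <- track$total_ends / n_bins_total

  tested <- list()
  for (ch in names(track$counts)) {
    x <- track$counts[[ch]]
    idx <- which(x > 0)
    if (!length(idx)) next
    lam <- rep(lambda_bg, length(idx))
    for (w_bp in local_bg_windows) {
      lam <- pmax(lam, .running_mean(x, max(1L, round(w_bp / bin)))[idx])
    }
    p <- stats::ppois(x[idx] - 1, lam, lower.tail = FALSE)
    tested[[ch]] <- data.frame(chrom = ch, idx = idx, count = x[idx],
                               lambda = lam, p = p)
  }
  if (!length(tested)) return(empty)
  tb <- do.call(rbind, tested)
  # deterministic order (ties in BH ranking broken by genomic order)
  tb <- tb[order(match(tb$chrom, names(track$counts)), tb$idx), ]
  tb$q <- stats::p.adjust(tb$p, method = "BH")
  sig <- tb[tb$q <= q_threshold, , drop = FALSE]
  if (!nrow(sig)) return(empty)

  gap <- if (mode == "broad") 4 * merge_gap else merge_gap
  peaks <- list()
  for (ch in unique(sig$chrom)) {
    s <- sig[sig$chrom == ch, , drop = FALSE]
    # merge bins whose start-to-start gap (minus the bin itself) < gap
    brk <- c(TRUE, (diff(s$idx) - 1) * bin >= gap)
    grp <- cumsum(brk)
    for (g in unique(grp)) {
      b <- s[grp == g, , drop = FALSE]
      start <- (min(b$idx) - 1) * bin
      end <- max(b$idx) * bin
      if (end - start < min_width) next
      top <- b[which.max(b$count), ]
      peaks[[length(peaks) + 1]] <- data.frame(
        chrom = ch, start = start, end = end,
        score = -log10(max(min(b$q), 1e-300)),
        summit = (top$idx - 0.5) * bin,
        qvalue = min(b$q),
        enrichment = top$count / top$lambda,
        n_bins = nrow(b))
    }
  }
  if (!length(peaks)) return(empty)
  out <- do.call(rbind, peaks)
  out <- out[order(match(out$chrom, names(track$counts)), out$start), ]
  out <- data.frame(chrom = out$chrom, start = out$start, end = out$end,
                    name = sprintf("hoci_%d", seq_len(nrow(out))),
                    out[, c("score", "summit", "qvalue", "enrichment",
                            "n_bins")])
  rownames(out) <- NULL
  out
}

#' Sequencing-depth saturation of HOCI discovery
#'
#' Downsamples the valid-pair set without replacement at each fraction and
#' re-calls peaks; deterministic for a given seed.
#'
#' @param valid valid-pair data.frame.
#' @param assembly `GenomeAssembly`.
#' @param fractions fractions in (0, 1].
#' @param seed RNG seed.
#' @param ... forwarded to [build_coverage()] / [call_hoci()].
#' @param bin_bp coverage bin size.
#' @return data.frame(fraction, n_pairs, n_peaks).
#' @export
saturation_curve <- function(valid, assembly, fractions, seed, bin_bp = 50,
                             ...) {
  if (any(fractions <= 0 | fractions > 1))
    stop("fractions must be in (0, 1]")
  set.seed(seed)
  out <- lapply(fractions, function(f) {
    n <- floor(f * nrow(valid))
    sub <- valid[sample.int(nrow(valid), n), , drop = FALSE]
    pk <- call_hoci(build_coverage(sub, assembly, bin_bp), ...)
    data.frame(fraction = f, n_pairs = n, n_peaks = nrow(pk))
  })
  do.call(rbind, out)
}
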