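#' Stitch enhancers into candidate super-enhancer regions
#'
#' Enhancers falling inside a TSS exclusion zone (default: fully contained
#' in TSS +/- `tss_exclusion`, classic ROSE behaviour) are treated as
#' promoters and removed; the remaining enhancers are merged transitively
#' whenever the gap between consecutive enhancers is below `stitch_gap`.
#'
#' @param enhancers interval data.frame (e.g. H3K27ac peaks).
#' @param tss data.frame with `chrom` and `tss` (0-based bp) per gene.
#' @param stitch_gap maximum gap merged, bp (default 12500).
#' @param tss_exclusion half-width of the promoter exclusion zone, bp
#'   (default 2000).
#' @param exclusion_mode `"contained"` (default) removes enhancers fully
#'   inside a TSS zone; `"any"` removes on any overlap.
#' @return data.frame of stitched regions (chrom, start, end,
#'   n_constituents) with a `constituents` attribute mapping stitched row
#'   to constituent rows of the filtered enhancer table.
#' @export
stitch_enhancers <- function(enhancers, tss, stitch_gap = 12500,
                             tss_exclusion = 2000,
                             exclusion_mode = c("contained", "any")) {
  exclusion_mode <- match.arg(exclusion_mode)
  if (nrow(tss)) {
    zones <- data.frame(chrom = tss$chrom,
                        start = pmax(0, tss$tss - tss_exclusion),
                        end = tss$tss + tss_exclusion)
    if (exclusion_mode == "contained") {
      hits <- overlap_list(enhancers, zones)
      contained <- logical(nrow(enhancers))
      if (nrow(hits)) {
        ok <- enhancers$start[hits$query_idx] >= zones$start[hits$subject_idx] &
          enhancers$end[hits$query_idx] <= zones$end[hits$subject_idx]
        contained[unique(hits$query_idx[ok])] <- TRUE
      }
      enhancers <- enhancers[!contained, , drop = FALSE]
    } else {
      enhancers <- enhancers[!overlap_any(enhancers, zones), , drop = FALSE]
    }
  }
  if (!nrow(enhancers))
    return(structure(data.frame(chrom = character(), start = numeric(),
                                end = numeric(), n_constituents = integer()),
                     constituents = list()))
  ord <- order(enhancers$chrom, enhancers$start, enhancers$end)
  e <- enhancers[ord, , drop = FALSE]
  grp <- integer(nrow(e)); grp[1] <- 1L
  cur_end <- e$end[1]
  for (i in seq_len(nrow(e))[-1]) {
    if (e$chrom[i] == e$chrom[i - 1] && e$start[i] - cur_end < stitch_gap) {
      grp[i] <- grp[i - 1]
      cur_end <- max(cur_end, e$end[i])
    } else {
      grp[i] <- grp[i - 1] + 1L
      cur_end <- e$end[i]
    }
  }
  out <- do.call(rbind, lapply(split(seq_len(nrow(e)), grp), function(ix) {
    data.frame(chrom = e$chrom[ix[1]], start = min(e$start[ix]),
               end = max(e$end[ix]), n_constituents = length(ix))
  }))
  rownames(out) <- NULL
  attr(out, "constituents") <- split(ord, grp)
  out
}

#' Sum background-subtracted signal over stitched regions
#'
#' Ranking signal = sum over the region of (ChIP - input) per-bp signal,
#' floored at 0 (rpm x bp when the tracks are in rpm/bp).
#'
#' @param stitched stitched-region data.frame.
#' @param signal ChIP bedGraph data.frame (chrom, start, end, value).
#' @param input optional control bedGraph subtracted from `signal`.
#' @return numeric vector of ranking signals.
#' @export
score_stitched <- function(stitched, signal, input = NULL) {
  sum_track <- function(track) {
    hits <- overlap_list(stitched, track)
    if (!nrow(hits)) return(numeric(nrow(stitched)))
    w <- pmin(stitched$end[hits$query_idx], track$end[hits$subject_idx]) -
      pmax(stitched$start[hits$query_idx], track$start[hits$subject_idx])
    v <- w * track$value[hits$subject_idx]
    out <- numeric(nrow(stitched))
    agg <- tapply(v, hits$query_idx, sum)
    out[as.integer(names(agg))] <- agg
    out
  }
  s <- sum_track(signal)
  if (!is.null(input)) s <- s - sum_track(input)
  pmax(0, s)
}

#' Slope-1 tangent cutoff on the ranked signal curve (ROSE-style)
#'
#' Regions are sorted by ascending ranking signal; rank is scaled to
#' x in \[0,1\] and signal to y in \[0,1\]. The cutoff is the point where a
#' slope-1 line is tangent to the (convex, ascending) curve, found exactly
#' as `argmax(x - y)` with ties broken to the rightmost index. Entries
#' strictly to the right of the cutoff are super-enhancers; the entry at
#' the cutoff is not.
#'
#' @param stitched stitched-region data.frame.
#' @param signal non-negative ranking signal per region.
#' @return `stitched` sorted by ascending signal with columns `rank`,
#'   `ranking_signal`, `scaled_x`, `scaled_y`, `is_super`; attributes
#'   `cutoff_index` (1-based index into the sorted table) and
#'   `cutoff_signal`.
#' @export
rank_and_cut <- function(stitched, signal) {
  n <- nrow(stitched)
  if (n < 3) stop("need at least 3 stitched enhancers")
  if (any(signal < 0)) stop("ranking signal must be >= 0")
  ord <- order(signal)
  out <- stitched[ord, , drop = FALSE]
  s <- signal[ord]
  out$rank <- seq_len(n)
  out$ranking_signal <- s
  out$scaled_x <- (out$rank - 1) / (n - 1)
  if (diff(range(s)) == 0) {
    warning("all ranking signals equal; no super-enhancers")
    out$scaled_y <- rep(0, n)
  } else {
    out$scaled_y <- (s - min(s)) / (max(s) - min(s))
  }
  d <- out$scaled_x - out$scaled_y
  cutoff <- max(which(d == max(d)))   # rightmost argmax
  out$is_super <- out$rank > cutoff
  rownames(out) <- NULL
  attr(out, "cutoff_index") <- cutoff
  attr(out, "cutoff_signal") <- s[cutoff]
  out
}

#' Call broad domains as the widest fraction of peaks
#'
#' Peaks are ranked by width (descending, ties broken by genomic order) and
#' the top `ceiling(top_frac * N)` are flagged broad. Alternatively a fixed
#' minimum width can be used (`min_width`), in which case `top_frac` is
#' ignored.
#'
#' @param peaks interval data.frame.
#' @param top_frac fraction flagged broad (default 0.05).
#' @param min_width optional width threshold in bp overriding `top_frac`.
#' @return `peaks` with `width`, `width_rank` and `is_broad` columns.
#' @export
call_broad_domains <- function(peaks, top_frac = 0.05, min_width = NULL) {
  if (!nrow(peaks)) stop("need at least one peak")
  peaks$width <- peaks$end - peaks$start
  ord <- order(-peaks$width, match(peaks$chrom, unique(peaks$chrom)),
               peaks$start)
  rank <- integer(nrow(peaks)); rank[ord] <- seq_len(nrow(peaks))
  peaks$width_rank <- rank
  if (is.null(min_width)) {
    n_broad <- ceiling(top_frac * nrow(peaks))
    peaks$is_broad <- rank <= n_broad
  } else {
    peaks$is_broad <- peaks$width > min_width
  }
  peaks
}

#' Overlap of regulatory domains with HOCIs
#'
#' Thin wrapper around [overlap_report()] for super-enhancer / broad-domain
#' vs HOCI intersection statistics.
#' @param domains interval data.frame (e.g. super-enhancers).
#' @param hocis HOCI data.frame.
#' @param assembly `GenomeAssembly`.
#' @param bin_bp Fisher background bin size.
#' @export
domain_hoci_overlap <- function(domains, hocis, assembly, bin_bp = 1000) {
  overlap_report(domains, hocis, assembly, bin_bp)
}
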