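#' Strand-aware promoter windows
#'
#' Default window is upstream-only: `[TSS - up, TSS)` for `+` genes and
#' `(TSS, TSS + up]` for `-` genes (0-based half-open), clipped to the
#' chromosome. `mode = "symmetric"` gives `TSS +/- up`.
#'
#' @param genes data.frame with `gene_id`, `chrom`, `strand` (`+`/`-`),
#'   `tss` (0-based bp).
#' @param assembly `GenomeAssembly` used for clipping.
#' @param up window size upstream of the TSS, bp (default 2000).
#' @param mode `"upstream"` (default) or `"symmetric"`.
#' @return interval data.frame (chrom, start, end, gene_id).
#' @export
promoter_windows <- function(genes, assembly, up = 2000,
                             mode = c("upstream", "symmetric")) {
  mode <- match.arg(mode)
  if (any(is.na(genes$strand)) || !all(genes$strand %in% c("+", "-")))
    stop("genes must carry '+'/'-' strand (promoter window undefined)")
  len <- assembly$lengths[genes$chrom]
  if (mode == "upstream") {
    start <- ifelse(genes$strand == "+", genes$tss - up, genes$tss + 1)
    end <- ifelse(genes$strand == "+", genes$tss, genes$tss + 1 + up)
  } else {
    start <- genes$tss - up
    end <- genes$tss + up
  }
  data.frame(chrom = genes$chrom,
             start = pmax(0, start),
             end = pmin(unname(len), end),
             gene_id = genes$gene_id,
             stringsAsFactors = FALSE)
}

#' Classify HOCIs as promoter, enhancer or other
#'
#' A HOCI overlapping both an H3K4me3 peak and a gene promoter window is a
#' `PROMOTER` HOCI; otherwise, one overlapping both an H3K4me1 and an
#' H3K27ac peak is an `ENHANCER` HOCI; everything else is `OTHER`.
#' Promoter takes precedence over enhancer.
#'
#' @param hocis HOCI data.frame ([call_hoci()]).
#' @param h3k4me3,h3k4me1,h3k27ac interval data.frames of ChIP-seq peaks.
#' @param genes gene data.frame (see [promoter_windows()]).
#' @param assembly `GenomeAssembly`.
#' @param promoter_up promoter window size (default 2000 bp).
#' @param promoter_mode passed to [promoter_windows()].
#' @return `hocis` with a `class` column (`PROMOTER`/`ENHANCER`/`OTHER`).
#' @export
classify_hoci <- function(hocis, h3k4me3, h3k4me1, h3k27ac, genes, assembly,
                          promoter_up = 2000, promoter_mode = "upstream") {
  prom <- promoter_windows(genes, assembly, promoter_up, promoter_mode)
  is_prom <- overlap_any(hocis, h3k4me3) & overlap_any(hocis, prom)
  is_enh <- !is_prom & overlap_any(hocis, h3k4me1) & overlap_any(hocis, h3k27ac)
  hocis$class <- ifelse(is_prom, "PROMOTER", ifelse(is_enh, "ENHANCER", "OTHER"))
  hocis
}

#' Count distinct DNA-binding proteins occupying each HOCI
#'
#' A factor counts once per HOCI however many of its peaks overlap it
#' (>= 1 bp overlap).
#'
#' @param hocis HOCI data.frame.
#' @param factor_peaks named list of peak interval data.frames, one per
#'   DNA-binding protein.
#' @return list with `per_hoci` (integer vector), `mean`, and `factors`
#'   (logical HOCI x factor matrix).
#' @export
count_binding_proteins <- function(hocis, factor_peaks) {
  if (!length(factor_peaks)) stop("need at least one factor peak set")
  m <- vapply(factor_peaks, function(pk) overlap_any(hocis, pk),
              logical(nrow(hocis)))
  m <- matrix(m, nrow = nrow(hocis),
              dimnames = list(hocis$name, names(factor_peaks)))
  counts <- rowSums(m)
  list(per_hoci = as.integer(counts), mean = mean(counts), factors = m)
}

#' Element-level overlap report with a binned-genome Fisher test
#'
#' Counts how many elements of A overlap any element of B (>= 1 bp) and vice
#' versa, and computes a Fisher exact p-value from a 2x2 table of fixed-size
#' genome bins labelled by membership in A and in B (the genome-background
#' null).
#'
#' @param a,b interval data.frames.
#' @param assembly `GenomeAssembly`.
#' @param bin_bp Fisher background bin size (default 1000).
#' @return list: `n_a`, `n_b`, `n_a_overlap`, `n_b_overlap`, `frac_a`,
#'   `frac_b`, `fisher_p`, `odds_ratio`, `table`.
#' @export
overlap_report <- function(a, b, assembly, bin_bp = 1000) {
  n_a_overlap <- sum(overlap_any(a, b))
  n_b_overlap <- sum(overlap_any(b, a))
  bins <- do.call(rbind, lapply(assembly$chroms, function(ch) {
    starts <- seq(0, assembly$lengths[[ch]] - 1, by = bin_bp)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + bin_bp, assembly$lengths[[ch]]))
  }))
  in_a <- overlap_any(bins, a)
  in_b <- overlap_any(bins, b)
  tab <- table(factor(in_a, c(FALSE, TRUE)), factor(in_b, c(FALSE, TRUE)))
  ft <- stats::fisher.test(tab)
  list(n_a = nrow(a), n_b = nrow(b),
       n_a_overlap = n_a_overlap, n_b_overlap = n_b_overlap,
       frac_a = if (nrow(a)) n_a_overlap / nrow(a) else NA_real_,
       frac_b = if (nrow(b)) n_b_overlap / nrow(b) else NA_real_,
       fisher_p = ft$p.value, odds_ratio = unname(ft$estimate), table = tab)
}
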