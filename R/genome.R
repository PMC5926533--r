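#' Genome assembly object
#'
#' Bundles chromosome names, lengths and (optionally) sequence. All coordinates
#' in this package are 0-based, half-open (BED convention); conversion to
#' 1-based happens only inside the overlap engine and at text export.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param sequence optional named character vector or `Biostrings::DNAStringSet`
#'   of chromosome sequences; names and widths must match `chrom_lengths`.
#' @return an object of class `GenomeAssembly`.
#' @export
genome_assembly <- function(chrom_lengths, sequence = NULL) {
  if (is.null(names(chrom_lengths)) || anyDuplicated(names(chrom_lengths)))
    stop("chrom_lengths must be uniquely named")
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be > 0")
  if (!is.null(sequence)) {
    if (is.character(sequence)) sequence <- Biostrings::DNAStringSet(sequence)
    if (!all(names(chrom_lengths) %in% names(sequence)))
      stop("sequence missing for some chromosomes")
    sequence <- sequence[names(chrom_lengths)]
    if (!all(Biostrings::width(sequence) == unname(chrom_lengths)))
      stop("sequence widths do not match chrom_lengths")
  }
  structure(list(chroms = names(chrom_lengths),
                 lengths = stats::setNames(as.numeric(chrom_lengths),
                                           names(chrom_lengths)),
                 sequence = sequence),
            class = "GenomeAssembly")
}

#' Read a genome from a (possibly multi-record, wrapped) FASTA file
#' @param path FASTA file.
#' @param include optional character vector restricting which chromosomes
#'   are kept (in the given order).
#' @return `GenomeAssembly` with sequence.
#' @export
read_genome_fasta <- function(path, include = NULL) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (!is.null(include)) {
    missing <- setdiff(include, names(seqs))
    if (length(missing)) stop("chromosomes not in FASTA: ",
                              paste(missing, collapse = ", "))
    seqs <- seqs[include]
  }
  genome_assembly(stats::setNames(Biostrings::width(seqs), names(seqs)), seqs)
}

#' Write a genome assembly to FASTA
#' @param assembly `GenomeAssembly` carrying sequence.
#' @param path output file.
#' @export
write_genome_fasta <- function(assembly, path) {
  if (is.null(assembly$sequence)) stop("assembly carries no sequence")
  Biostrings::writeXStringSet(assembly$sequence, path, width = 70L)
  invisible(path)
}

#' @export
print.GenomeAssembly <- function(x, ...) {
  cat("GenomeAssembly:", length(x$chroms), "chromosomes,",
      format(sum(x$lengths), big.mark = ","), "bp",
      if (!is.null(x$sequence)) "(with sequence)" else "(lengths only)", "\n")
  invisible(x)
}

#' In-silico restriction digestion
#'
#' Cuts every occurrence of `site` (cut position = match start, blunt-end
#' convention; the wet-lab 5' overhang fill-in does not move the mapped cut).
#' `N` bases never match. Zero-length fragments (a site at position 0 or a
#' site ending at the chromosome end) are suppressed.
#'
#' @param assembly `GenomeAssembly` with sequence.
#' @param site recognition sequence, uppercase ACGT (default `"GATC"`, MboI).
#' @return a `FragmentMap`: fragments tiling each chromosome without gaps,
#'   with genome-wide consecutive 0-based `fragment_id`s.
#' @export
digest_genome <- function(assembly, site = "GATC") {
  if (is.null(assembly$sequence)) stop("digest requires assembly sequence")
  if (!nzchar(site) || grepl("[^ACGT]", site))
    stop("recognition site must be non-empty uppercase ACGT")
  frags <- vector("list", length(assembly$chroms))
  index <- vector("list", length(assembly$chroms))
  next_id <- 0L
  for (i in seq_along(assembly$chroms)) {
    chrom <- assembly$chroms[i]
    len <- assembly$lengths[[chrom]]
    m <- Biostrings::matchPattern(site, assembly$sequence[[chrom]], fixed = TRUE)
    cuts <- IRanges::start(m) - 1        # 0-based cut at match start
    cuts <- cuts[cuts > 0 & cuts < len]  # suppress zero-length fragments
    breaks <- c(0, cuts, len)
    n <- length(breaks) - 1L
    ids <- seq.int(next_id, length.out = n)
    frags[[i]] <- data.frame(chrom = chrom,
                             start = breaks[-length(breaks)],
                             end = breaks[-1],
                             fragment_id = ids,
                             row.names = NULL)
    index[[chrom]] <- list(starts = breaks[-length(breaks)],
                           first_id = next_id, length = len)
    next_id <- next_id + n
  }
  structure(list(fragments = do.call(rbind, frags), index = index),
            class = "FragmentMap")
}

#' @export
print.FragmentMap <- function(x, ...) {
  cat("FragmentMap:", nrow(x$fragments), "fragments on",
      length(x$index), "chromosomes\n")
  invisible(x)
}

#' Locate the restriction fragment containing each position
#'
#' Binary-search lookup (via `findInterval`) in the sorted per-chromosome
#' fragment starts.
#'
#' @param map `FragmentMap` from [digest_genome()].
#' @param chrom,pos vectors (recycled to common length) of chromosome and
#'   0-based position; `pos` must lie in `[0, chrom_length)`.
#' @return integer vector of genome-wide fragment ids.
#' @export
assign_fragment <- function(map, chrom, pos) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n); pos <- rep_len(pos, n)
  out <- integer(n)
  for (ch in unique(chrom)) {
    idx <- map$index[[ch]]
    if (is.null(idx)) stop("chromosome not in fragment map: ", ch)
    sel <- which(chrom == ch)
    p <- pos[sel]
    if (any(p < 0 | p >= idx$length))
      stop("position out of range [0, ", idx$length, ") on ", ch)
    out[sel] <- idx$first_id + findInterval(p, idx$starts) - 1L
  }
  out
}

#' Fragment midpoints indexed by fragment id
#' @param map `FragmentMap`.
#' @return numeric vector, midpoint of fragment id `i` at position `i + 1`.
#' @export
fragment_midpoints <- function(map) {
  (map$fragments$start + map$fragments$end) / 2
}

# internal: interval data.frame (0-based half-open) -> GRanges (1-based closed)
.as_gr <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1, end = df$end))
}

# internal: point positions -> width-1 GRanges
.as_gr_points <- function(chrom, pos) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = pos + 1, width = 1))
}

#' Interval overlap predicates (half-open convention)
#'
#' Two intervals `[a,b)` and `[c,d)` overlap iff `a < d` and `c < b`
#' (at least one shared bp). A chromosome mismatch is simply a non-overlap,
#' never an error.
#'
#' @param query,subject data.frames with columns `chrom`, `start`, `end`.
#' @return `overlap_any`: logical per query row; `overlap_count`: integer per
#'   query row; `overlap_list`: data.frame of (query_idx, subject_idx) hits.
#' @export
overlap_any <- function(query, subject) {
  if (nrow(subject) == 0) return(rep(FALSE, nrow(query)))
  suppressWarnings(GenomicRanges::countOverlaps(.as_gr(query), .as_gr(subject))) > 0
}

#' @rdname overlap_any
#' @export
overlap_count <- function(query, subject) {
  if (nrow(subject) == 0) return(rep(0L, nrow(query)))
  suppressWarnings(GenomicRanges::countOverlaps(.as_gr(query), .as_gr(subject)))
}

#' @rdname overlap_any
#' @export
overlap_list <- function(query, subject) {
  if (nrow(query) == 0 || nrow(subject) == 0)
    return(data.frame(query_idx = integer(), subject_idx = integer()))
  h <- suppressWarnings(GenomicRanges::findOverlaps(.as_gr(query), .as_gr(subject)))
  data.frame(query_idx = S4Vectors::queryHits(h),
             subject_idx = S4Vectors::subjectHits(h))
}

#' Index of the interval containing each point (or NA)
#'
#' Intervals are assumed non-overlapping; with overlapping intervals the
#' first (in row order) match is returned.
#' @param chrom,pos point coordinates (0-based).
#' @param intervals interval data.frame.
#' @return integer row index into `intervals`, NA where uncovered.
#' @export
point_in_intervals <- function(chrom, pos, intervals) {
  if (nrow(intervals) == 0 || length(pos) == 0)
    return(rep(NA_integer_, length(pos)))
  suppressWarnings(
    GenomicRanges::findOverlaps(.as_gr_points(chrom, pos), .as_gr(intervals),
                                select = "first"))
}

#' Read a BED3/BED6 file
#' @param path BED file (no header).
#' @return data.frame with chrom/start/end and, when present, name, score,
#'   strand.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  names(df) <- cols[seq_len(min(ncol(df), 6))]
  df
}

#' @rdname read_bed
#' @param df interval data.frame.
#' @export
write_bed <- function(df, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(df))
  out <- df[, cols, drop = FALSE]
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read/write ENCODE narrowPeak (BED6+4, summit offset in column 10)
#' @param path file path.
#' @export
read_narrowpeak <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df) <- c("chrom", "start", "end", "name", "score", "strand",
                 "signal", "pvalue", "qvalue", "peak")[seq_len(ncol(df))]
  df
}

#' @rdname read_narrowpeak
#' @param hocis HOCI data.frame as returned by [call_hoci()].
#' @export
write_narrowpeak <- function(hocis, path) {
  out <- data.frame(chrom = hocis$chrom,
                    start = format(hocis$start, scientific = FALSE, trim = TRUE),
                    end = format(hocis$end, scientific = FALSE, trim = TRUE),
                    name = hocis$name,
                    score = round(pmin(1000, 10 * hocis$score)),
                    strand = ".",
                    signal = signif(hocis$enrichment, 5),
                    pvalue = -1,
                    qvalue = signif(hocis$score, 5),
                    peak = hocis$summit - hocis$start)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export a fragment map as BED (fragment_id in the name column)
#' @param map `FragmentMap`.
#' @param path output BED.
#' @export
write_fragments_bed <- function(map, path) {
  df <- map$fragments
  write_bed(data.frame(chrom = df$chrom, start = df$start, end = df$end,
                       name = df$fragment_id), path)
}

#' Read a bedGraph signal file
#' @param path bedGraph (chrom start end value, no header).
#' @export
read_bedgraph <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  names(df) <- c("chrom", "start", "end", "value")
  df
}
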