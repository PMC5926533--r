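GENE_TYPES <- c("HUB", "INTERACTING", "DISSOCIATIVE")

#' Type genes by their promoter's relationship to HOCIs
#'
#' `HUB`: the promoter window overlaps a HOCI. `INTERACTING`: the promoter
#' is not a HOCI but at least `min_pairs` valid pairs link it (one end in
#' the window) to any HOCI (other end). `DISSOCIATIVE`: neither.
#'
#' @param genes gene data.frame (`gene_id`, `chrom`, `strand`, `tss`).
#' @param hocis HOCI data.frame.
#' @param valid valid-pair data.frame.
#' @param assembly `GenomeAssembly`.
#' @param promoter_up promoter window size (default 2000 bp).
#' @param promoter_mode passed to [promoter_windows()].
#' @param min_pairs minimum valid pairs for `INTERACTING` (default 1).
#' @return factor of gene types aligned with `genes` rows.
#' @export
type_genes <- function(genes, hocis, valid, assembly, promoter_up = 2000,
                       promoter_mode = "upstream", min_pairs = 1) {
  prom <- promoter_windows(genes, assembly, promoter_up, promoter_mode)
  hub <- overlap_any(prom, hocis)

  in_hoci1 <- !is.na(point_in_intervals(valid$chrom1, valid$pos1, hocis))
  in_hoci2 <- !is.na(point_in_intervals(valid$chrom2, valid$pos2, hocis))
  # pair ends linking a promoter window to a HOCI at the opposite end
  link1 <- overlap_list(prom, data.frame(chrom = valid$chrom1,
                                         start = valid$pos1,
                                         end = valid$pos1 + 1))
  link2 <- overlap_list(prom, data.frame(chrom = valid$chrom2,
                                         start = valid$pos2,
                                         end = valid$pos2 + 1))
  links <- c(link1$query_idx[in_hoci2[link1$subject_idx]],
             link2$query_idx[in_hoci1[link2$subject_idx]])
  n_links <- tabulate(links, nbins = nrow(genes))

  type <- ifelse(hub, "HUB",
                 ifelse(n_links >= min_pairs, "INTERACTING", "DISSOCIATIVE"))
  factor(type, levels = GENE_TYPES)
}

#' Expression distributions by gene type
#'
#' Reports per-type medians and proportions among all genes and among
#' expressed genes (RPKM strictly greater than `expressed_cutoff`), plus
#' one-sided Mann-Whitney tests for the ordering
#' hub > interacting > dissociative.
#'
#' @param types factor from [type_genes()].
#' @param rpkm numeric expression vector aligned with `types`.
#' @param expressed_cutoff RPKM cutoff for "expressed" (default 0.5, strict).
#' @return list: `summary` (data.frame type, n, median_rpkm, prop_all,
#'   prop_expressed), `tests` (data.frame comparison, p_value; one-sided,
#'   alternative = first group greater).
#' @export
expression_by_type <- function(types, rpkm, expressed_cutoff = 0.5) {
  expressed <- rpkm > expressed_cutoff
  summ <- do.call(rbind, lapply(GENE_TYPES, function(tt) {
    sel <- types == tt
    data.frame(type = tt, n = sum(sel),
               median_rpkm = if (any(sel)) stats::median(rpkm[sel]) else NA,
               prop_all = mean(sel),
               prop_expressed = if (any(expressed))
                 sum(sel & expressed) / sum(expressed) else NA)
  }))
  combos <- list(c("HUB", "INTERACTING"), c("INTERACTING", "DISSOCIATIVE"),
                 c("HUB", "DISSOCIATIVE"))
  tests <- lapply(combos, function(cp) {
    x <- rpkm[types == cp[1]]; y <- rpkm[types == cp[2]]
    if (length(x) < 2 || length(y) < 2) {
      warning("type absent or too small; skipping ", cp[1], " vs ", cp[2])
      return(NULL)
    }
    data.frame(comparison = paste(cp[1], ">", cp[2]),
               p_value = stats::wilcox.test(x, y, alternative = "greater",
                                            exact = FALSE)$p.value)
  })
  list(summary = summ, tests = do.call(rbind, tests))
}

#' Compare gene types and expression between two conditions
#'
#' Assigns each gene a change category (`same_type`, `hub_dissociative` for
#' a hub-to-dissociative switch in either direction, `other_change`) and a
#' `promoter_hoci_changed` flag (promoter window overlaps a HOCI in exactly
#' one condition). Expression change is `log2((rpkm_a + eps)/(rpkm_b + eps))`.
#' Among down-regulated (log2fc < 0 means higher in B) and up-regulated
#' genes separately, the |log2fc| of promoter-HOCI-changed genes is tested
#' against unchanged genes (one-sided Mann-Whitney, changed greater).
#'
#' @param genes shared gene data.frame.
#' @param types_a,types_b gene-type factors per condition.
#' @param rpkm_a,rpkm_b expression per condition (aligned with `genes`).
#' @param hocis_a,hocis_b HOCI sets per condition.
#' @param assembly `GenomeAssembly`.
#' @param promoter_up,promoter_mode promoter window parameters.
#' @param eps pseudocount for log fold changes (default 0.01 RPKM).
#' @return list: `genes` (per-gene data.frame with category, flags, log2fc),
#'   `tests` (data.frame direction, p_value), `excluded` (genes with missing
#'   expression, count).
#' @export
compare_conditions <- function(genes, types_a, types_b, rpkm_a, rpkm_b,
                               hocis_a, hocis_b, assembly,
                               promoter_up = 2000, promoter_mode = "upstream",
                               eps = 0.01) {
  ok <- !is.na(rpkm_a) & !is.na(rpkm_b)
  excluded <- sum(!ok)
  g <- genes[ok, , drop = FALSE]
  ta <- as.character(types_a[ok]); tb <- as.character(types_b[ok])
  a <- rpkm_a[ok]; b <- rpkm_b[ok]

  category <- ifelse(ta == tb, "same_type",
                     ifelse((ta == "HUB" & tb == "DISSOCIATIVE") |
                              (ta == "DISSOCIATIVE" & tb == "HUB"),
                            "hub_dissociative", "other_change"))
  prom <- promoter_windows(g, assembly, promoter_up, promoter_mode)
  hoci_a <- overlap_any(prom, hocis_a)
  hoci_b <- overlap_any(prom, hocis_b)
  changed <- xor(hoci_a, hoci_b)
  log2fc <- log2((a + eps) / (b + eps))

  res <- data.frame(gene_id = g$gene_id, type_a = ta, type_b = tb,
                    category = category, promoter_hoci_a = hoci_a,
                    promoter_hoci_b = hoci_b,
                    promoter_hoci_changed = changed,
                    rpkm_a = a, rpkm_b = b, log2fc = log2fc)

  tests <- lapply(list(down = log2fc < 0, up = log2fc > 0), function(sel) {
    x <- abs(log2fc[sel & changed]); y <- abs(log2fc[sel & !changed])
    if (length(x) < 2 || length(y) < 2) return(NA_real_)
    stats::wilcox.test(x, y, alternative = "greater", exact = FALSE)$p.value
  })
  list(genes = res,
       tests = data.frame(direction = names(tests),
                          p_value = unlist(tests), row.names = NULL),
       excluded = excluded)
}

#' Read an expression table (gene_id, RPKM TSV)
#' @param path TSV with header columns `gene_id` and `rpkm`.
#' @return named numeric vector of RPKM.
#' @export
read_expression <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stats::setNames(df$rpkm, df$gene_id)
}

#' @rdname read_expression
#' @param rpkm named numeric vector.
#' @export
write_expression <- function(rpkm, path) {
  utils::write.table(data.frame(gene_id = names(rpkm), rpkm = unname(rpkm)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write gene models as TSV (gene_id, chrom, strand, tss)
#' @param path file path.
#' @export
read_genes <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' @rdname read_genes
#' @param genes gene data.frame.
#' @export
write_genes <- function(genes, path) {
  utils::write.table(genes[, c("gene_id", "chrom", "strand", "tss")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
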