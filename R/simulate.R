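#' Simulation configuration with planted ground truth
#'
#' Defaults describe the standard study conditions used throughout the test
#' suite: 2 chromosomes of 5 Mb, 40 hubs arranged in 8 groups of
#' \{2 promoter, 2 enhancer, 1 other\}, 200,000 read pairs with 5% of each
#' same-fragment/too-close artifact class, distance-decay background
#' (P(d) ~ d^-alpha), planted hub-hub contacts at class-pair distances with
#' medians 44 kb (promoter-promoter), 13 kb (enhancer-enhancer) and 117 kb
#' (promoter-enhancer), 500 genes (20% hub, 40% interacting, 40%
#' dissociative) with log-normal expression medians 20 / 5 / 0.2 RPKM, and
#' alternating 1-Mb A/B compartment blocks.
#'
#' @param seed mandatory RNG seed.
#' @param ... overrides for any default listed below.
#' @return a validated `SimulationConfig` list.
#' @export
sim_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    chrom_lengths = c(simA = 5e6, simB = 5e6),
    site = "GATC",
    n_pairs = 200000L,
    frac_artifact = c(dangling = 0.05, self_circle = 0.05,
                      same_strand = 0.05, too_close = 0.05),
    frac_low_mapq = 0.02,
    frac_trans = 0.05,
    frac_hub_pairs = 0.30,
    alpha = 1.0,
    min_cis_distance = 2000,
    max_cis_distance = 4.5e6,
    n_groups = 8L,
    hub_width_meanlog = log(800),
    hub_width_sdlog = 0.25,
    dist_medians = c(pp = 44000, ee = 13000, pe = 117000),
    dist_jitter_sdlog = 0.1,
    pairs_per_edge = 300L,
    n_genes = 500L,
    gene_type_props = c(hub = 0.2, interacting = 0.4, dissociative = 0.4),
    pairs_per_interacting_gene = 8L,
    expr_medians = c(hub = 20, interacting = 5, dissociative = 0.2),
    expr_sdlog = 1,
    compartment_block_bp = 1e6,
    frac_hubs_in_A = 0.8,
    cross_compartment_factor = 0.5,
    mark_margin = 500,
    gene_hub_margin = 10000,
    hub_halo_pad = 5000)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @param cfg configuration list.
#' @export
validate_sim_config <- function(cfg) {
  if (is.null(cfg$seed)) stop("seed is mandatory")
  fr <- c(cfg$frac_artifact, low_mapq = cfg$frac_low_mapq)
  if (any(fr < 0 | fr > 1) || sum(fr) >= 1)
    stop("artifact fractions must lie in [0,1] and sum below 1")
  if (cfg$frac_trans < 0 || cfg$frac_trans > 1 ||
      cfg$frac_hub_pairs < 0 || cfg$frac_hub_pairs > 1)
    stop("frac_trans / frac_hub_pairs must lie in [0,1]")
  if (abs(sum(cfg$gene_type_props) - 1) > 1e-8)
    stop("gene_type_props must sum to 1")
  if (cfg$min_cis_distance >= cfg$max_cis_distance)
    stop("min_cis_distance must be < max_cis_distance")
  if (exp(cfg$hub_width_meanlog + 3 * cfg$hub_width_sdlog) >
      min(cfg$chrom_lengths))
    stop("hub widths exceed chromosome length")
  invisible(cfg)
}

#' Truncated power-law distance CDF (P(d) ~ d^-alpha on [min, max])
#' @param q quantiles (bp).
#' @param alpha decay exponent.
#' @param min,max support bounds (bp).
#' @export
pdecay <- function(q, alpha, min, max) {
  q <- pmin(pmax(q, min), max)
  if (abs(alpha - 1) < 1e-12) {
    log(q / min) / log(max / min)
  } else {
    (q^(1 - alpha) - min^(1 - alpha)) / (max^(1 - alpha) - min^(1 - alpha))
  }
}

# inverse-CDF sampler for the truncated power law
.rdecay <- function(n, alpha, min, max) {
  u <- stats::runif(n)
  if (abs(alpha - 1) < 1e-12) {
    min * (max / min)^u
  } else {
    (min^(1 - alpha) + u * (max^(1 - alpha) - min^(1 - alpha)))^(1 / (1 - alpha))
  }
}

# compartment label (A/B) of positions under alternating fixed-size blocks
.block_label <- function(pos, block_bp) {
  ifelse((pos %/% block_bp) %% 2 == 0, "A", "B")
}

# place hub groups; returns hub table (one row per hub)
.place_hubs <- function(cfg, assembly) {
  if (cfg$n_groups == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), class = character(),
                      group = integer(), hub_id = integer()))
  chroms <- assembly$chroms
  per_chrom <- ceiling(cfg$n_groups / length(chroms))
  hubs <- list()
  hub_id <- 0L
  block <- cfg$compartment_block_bp
  for (g in seq_len(cfg$n_groups)) {
    ch <- chroms[(g - 1) %% length(chroms) + 1]
    len <- assembly$lengths[[ch]]
    slot_i <- (g - 1) %/% length(chroms)
    slot <- len * (slot_i + 0.5) / per_chrom
    want_a <- stats::runif(1) < cfg$frac_hubs_in_A
    for (try in 1:100) {
      # nearest block of the wanted label around the slot, wide enough to
      # hold the whole group span (about -60 kb .. +190 kb of the anchor)
      bidx <- round(slot / block + stats::runif(1, -1.2, 1.2))
      bidx <- max(0, min(floor((len - 1) / block), bidx))
      if ((bidx %% 2 == 0) != want_a) bidx <- bidx + sample(c(-1, 1), 1)
      if (bidx < 0 || (bidx + 1) * block > len) next
      anchor <- stats::runif(1, bidx * block + 70000,
                             (bidx + 1) * block - 200000)
      jit <- function(m) m * exp(stats::rnorm(1, 0, cfg$dist_jitter_sdlog))
      centers <- c(P1 = anchor,
                   P2 = anchor + jit(cfg$dist_medians[["pp"]]),
                   E1 = anchor + jit(cfg$dist_medians[["pe"]]),
                   O1 = anchor - 50000)
      centers <- c(centers,
                   E2 = unname(centers["E1"]) + jit(cfg$dist_medians[["ee"]]))
      w <- stats::rlnorm(5, cfg$hub_width_meanlog, cfg$hub_width_sdlog)
      cand <- data.frame(chrom = ch,
                         start = round(centers - w / 2),
                         end = round(centers + w / 2),
                         class = c("PROMOTER", "PROMOTER", "ENHANCER",
                                   "OTHER", "ENHANCER"),
                         group = g, row.names = NULL)
      if (any(cand$start < 0 | cand$end > len)) next
      clash <- FALSE
      if (length(hubs)) {
        prev <- do.call(rbind, hubs)
        pad <- data.frame(chrom = cand$chrom, start = cand$start - 5000,
                          end = cand$end + 5000)
        clash <- any(overlap_any(pad, prev))
      }
      if (any(diff(sort(centers)) < 5000)) clash <- TRUE
      if (!clash) break
    }
    cand$hub_id <- hub_id + seq_len(nrow(cand))
    hub_id <- hub_id + nrow(cand)
    hubs[[g]] <- cand
  }
  out <- do.call(rbind, hubs)
  rownames(out) <- NULL
  out
}

# place genes given hubs; returns gene table with planted types
.place_genes <- function(cfg, assembly, hubs) {
  n_hub <- round(cfg$gene_type_props[["hub"]] * cfg$n_genes)
  n_int <- round(cfg$gene_type_props[["interacting"]] * cfg$n_genes)
  n_dis <- cfg$n_genes - n_hub - n_int
  phubs <- hubs[hubs$class == "PROMOTER", , drop = FALSE]
  if (!nrow(phubs) && n_hub > 0) stop("no promoter hubs to attach genes to")

  genes <- list()
  # hub genes: promoter window must overlap the assigned promoter hub
  for (k in seq_len(n_hub)) {
    h <- phubs[(k - 1) %% nrow(phubs) + 1, ]
    strand <- sample(c("+", "-"), 1)
    tss <- if (strand == "+") h$end + round(stats::runif(1, 100, 1500))
           else h$start - round(stats::runif(1, 100, 1500))
    genes[[k]] <- data.frame(gene_id = sprintf("gene%04d", k),
                             chrom = h$chrom, strand = strand, tss = tss,
                             planted_type = "HUB",
                             hub_id = h$hub_id)
  }
  # interacting/dissociative genes: away from all hubs
  margin <- cfg$gene_hub_margin
  hub_pad <- data.frame(chrom = hubs$chrom, start = pmax(0, hubs$start - margin),
                        end = hubs$end + margin)
  placed <- 0L
  need <- n_int + n_dis
  pos_list <- list()
  while (placed < need) {
    m <- (need - placed) * 3
    ch <- sample(assembly$chroms, m, replace = TRUE,
                 prob = assembly$lengths / sum(assembly$lengths))
    tss <- floor(stats::runif(m, 3000, assembly$lengths[ch] - 3000))
    cand <- data.frame(chrom = ch, start = pmax(0, tss - 2500),
                       end = tss + 2500, tss = tss)
    ok <- !overlap_any(cand, hub_pad)
    cand <- cand[ok, , drop = FALSE]
    if (nrow(cand)) {
      take <- utils::head(cand, need - placed)
      pos_list[[length(pos_list) + 1]] <- take
      placed <- placed + nrow(take)
    }
  }
  pos <- do.call(rbind, pos_list)
  types <- sample(rep(c("INTERACTING", "DISSOCIATIVE"), c(n_int, n_dis)))
  for (k in seq_len(need)) {
    genes[[n_hub + k]] <- data.frame(
      gene_id = sprintf("gene%04d", n_hub + k),
      chrom = pos$chrom[k], strand = sample(c("+", "-"), 1),
      tss = pos$tss[k], planted_type = types[k], hub_id = NA_integer_)
  }
  out <- do.call(rbind, genes)
  rownames(out) <- NULL
  out
}

# uniform integer positions inside an interval row of `iv` per element of idx
.pos_in <- function(iv, idx) {
  floor(stats::runif(length(idx), iv$start[idx], iv$end[idx]))
}

# drop pairs that would link a dissociative promoter to a (padded) hub
.reject_diss_links <- function(p1_chrom, p1, p2_chrom, p2, diss_win, hub_pad) {
  if (!nrow(diss_win)) return(rep(TRUE, length(p1)))
  d1 <- !is.na(point_in_intervals(p1_chrom, p1, diss_win))
  d2 <- !is.na(point_in_intervals(p2_chrom, p2, diss_win))
  h1 <- !is.na(point_in_intervals(p1_chrom, p1, hub_pad))
  h2 <- !is.na(point_in_intervals(p2_chrom, p2, hub_pad))
  !((d1 & h2) | (d2 & h1))
}

# core pair generator shared by simulate() and the two-condition bundle;
# `hubs` is the active hub set, `genes` carries planted types for the
# condition being generated
.generate_pairs <- function(cfg, assembly, frag, hubs, genes, id_prefix = "p") {
  lens <- assembly$lengths
  chroms <- assembly$chroms
  block <- cfg$compartment_block_bp
  n <- cfg$n_pairs
  n_art <- round(n * cfg$frac_artifact)
  n_low <- round(n * cfg$frac_low_mapq)
  n_valid <- n - sum(n_art) - n_low
  n_trans <- round(n_valid * cfg$frac_trans)
  n_cis <- n_valid - n_trans
  n_hub_budget <- round(n_cis * cfg$frac_hub_pairs)

  int_genes <- genes[genes$planted_type == "INTERACTING", , drop = FALSE]
  n_gene_pairs <- nrow(int_genes) * cfg$pairs_per_interacting_gene
  groups <- split(hubs, hubs$group)
  edges <- list()
  for (grp in groups) {
    pick <- function(cls, k) {
      rows <- which(grp$class == cls)
      if (length(rows) >= k) rows[k] else NA
    }
    p1 <- pick("PROMOTER", 1); p2 <- pick("PROMOTER", 2)
    e1 <- pick("ENHANCER", 1); e2 <- pick("ENHANCER", 2)
    add <- function(i, j, what) {
      if (!is.na(i) && !is.na(j))
        edges[[length(edges) + 1]] <<- data.frame(
          a = grp$hub_id[i], b = grp$hub_id[j], kind = what)
    }
    add(p1, p2, "edge_pp"); add(e1, e2, "edge_ee"); add(p1, e1, "edge_pe")
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(a = integer(), b = integer(), kind = character())
  n_edge_pairs <- nrow(edges) * cfg$pairs_per_edge
  n_hub_generic <- n_hub_budget - n_edge_pairs - n_gene_pairs
  if (n_hub_generic < 0)
    stop("hub pair budget too small for planted edges and gene links")
  if (nrow(hubs) == 0 && n_hub_generic > 0)
    stop("frac_hub_pairs > 0 requires at least one hub")
  n_background <- n_cis - n_hub_budget

  diss <- genes[genes$planted_type == "DISSOCIATIVE", , drop = FALSE]
  diss_win <- if (nrow(diss)) promoter_windows(diss, assembly, 2000)
              else data.frame(chrom = character(), start = numeric(),
                              end = numeric())
  hub_pad <- data.frame(chrom = hubs$chrom,
                        start = pmax(0, hubs$start - cfg$hub_halo_pad),
                        end = hubs$end + cfg$hub_halo_pad)

  out <- list()
  emit <- function(chrom1, pos1, chrom2, pos2, provenance,
                   strand1 = NULL, strand2 = NULL, mapq1 = 30L, mapq2 = 30L) {
    m <- length(pos1)
    if (is.null(strand1)) strand1 <- sample(c("+", "-"), m, replace = TRUE)
    if (is.null(strand2)) strand2 <- sample(c("+", "-"), m, replace = TRUE)
    out[[length(out) + 1]] <<- data.frame(
      chrom1 = chrom1, pos1 = pos1, strand1 = strand1,
      chrom2 = chrom2, pos2 = pos2, strand2 = strand2,
      mapq1 = rep_len(mapq1, m), mapq2 = rep_len(mapq2, m),
      provenance = provenance)
  }

  # --- background cis with distance decay, compartment thinning and
  #     dissociative-promoter protection
  gen_background <- function(m, mapq1 = 30L, provenance = "background") {
    got <- 0L
    while (got < m) {
      k <- max(1000L, (m - got) * 2L)
      ch <- sample(chroms, k, replace = TRUE, prob = lens / sum(lens))
      d <- round(.rdecay(k, cfg$alpha, cfg$min_cis_distance,
                         cfg$max_cis_distance))
      # anchor the pair uniformly on the span that keeps both ends on the
      # chromosome, so the marginal distance law is exactly the decay law
      ok <- d < lens[ch]
      up <- stats::runif(k) < 0.5
      p1 <- ifelse(up, floor(stats::runif(k, 0, lens[ch] - d)),
                   floor(stats::runif(k, d, lens[ch])))
      p2 <- ifelse(up, p1 + d, p1 - d)
      # compartment checkerboard: cross-label contacts thinned
      same <- .block_label(p1, block) == .block_label(p2, block)
      ok <- ok & (same | stats::runif(k) < cfg$cross_compartment_factor)
      ok <- ok & .reject_diss_links(ch, p1, ch, p2, diss_win, hub_pad)
      ch <- ch[ok]; p1 <- p1[ok]; p2 <- p2[ok]
      take <- min(length(p1), m - got)
      if (take > 0) {
        sel <- seq_len(take)
        emit(ch[sel], p1[sel], ch[sel], p2[sel], provenance, mapq1 = mapq1)
        got <- got + take
      }
    }
  }
  gen_background(n_background)

  # --- trans background
  if (n_trans > 0 && length(chroms) > 1) {
    got <- 0L
    while (got < n_trans) {
      k <- max(500L, (n_trans - got) * 2L)
      c1 <- sample(chroms, k, replace = TRUE, prob = lens / sum(lens))
      shift <- sample(length(chroms) - 1, k, replace = TRUE)
      c2 <- chroms[(match(c1, chroms) - 1 + shift) %% length(chroms) + 1]
      p1 <- floor(stats::runif(k, 0, lens[c1]))
      p2 <- floor(stats::runif(k, 0, lens[c2]))
      same <- .block_label(p1, block) == .block_label(p2, block)
      ok <- same | stats::runif(k) < cfg$cross_compartment_factor
      ok <- ok & .reject_diss_links(c1, p1, c2, p2, diss_win, hub_pad)
      take <- min(sum(ok), n_trans - got)
      if (take > 0) {
        sel <- which(ok)[seq_len(take)]
        emit(c1[sel], p1[sel], c2[sel], p2[sel], "trans")
        got <- got + take
      }
    }
  }

  # --- planted hub-hub edges (contact distances carry the class-pair medians)
  if (nrow(edges)) {
    idx_a <- match(edges$a, hubs$hub_id)
    idx_b <- match(edges$b, hubs$hub_id)
    for (e in seq_len(nrow(edges))) {
      kk <- cfg$pairs_per_edge
      emit(rep(hubs$chrom[idx_a[e]], kk),
           floor(stats::runif(kk, hubs$start[idx_a[e]], hubs$end[idx_a[e]])),
           rep(hubs$chrom[idx_b[e]], kk),
           floor(stats::runif(kk, hubs$start[idx_b[e]], hubs$end[idx_b[e]])),
           edges$kind[e])
    }
  }

  # --- planted promoter-to-hub links for interacting genes
  if (nrow(int_genes)) {
    win <- promoter_windows(int_genes, assembly, 2000)
    for (g in seq_len(nrow(int_genes))) {
      kk <- cfg$pairs_per_interacting_gene
      targets <- which(hubs$chrom == int_genes$chrom[g])
      if (!length(targets)) targets <- seq_len(nrow(hubs))
      t_idx <- sample(rep(targets, 2), kk, replace = TRUE)
      emit(rep(win$chrom[g], kk),
           floor(stats::runif(kk, win$start[g], win$end[g])),
           hubs$chrom[t_idx], .pos_in(hubs, t_idx), "gene_link")
    }
  }

  # --- generic hub-anchored pairs (one end in a hub, mate decay-distributed)
  if (n_hub_generic > 0) {
    got <- 0L
    while (got < n_hub_generic) {
      k <- max(1000L, (n_hub_generic - got) * 2L)
      hidx <- sample(nrow(hubs), k, replace = TRUE)
      p1 <- .pos_in(hubs, hidx)
      ch <- hubs$chrom[hidx]
      d <- .rdecay(k, cfg$alpha, cfg$min_cis_distance, cfg$max_cis_distance)
      p2 <- round(p1 + sample(c(-1, 1), k, replace = TRUE) * d)
      ok <- p2 >= 0 & p2 < lens[ch]
      ok <- ok & .reject_diss_links(ch, p1, ch, p2, diss_win, hub_pad)
      take <- min(sum(ok), n_hub_generic - got)
      if (take > 0) {
        sel <- which(ok)[seq_len(take)]
        emit(ch[sel], p1[sel], ch[sel], p2[sel], "hub")
        got <- got + take
      }
    }
  }

  # --- artifact classes on real restriction fragments
  fr <- frag$fragments
  wide <- which(fr$end - fr$start >= 30)
  same_frag_pair <- function(m, s1, s2, provenance) {
    idx <- sample(wide, m, replace = TRUE)
    a <- .pos_in(fr, idx); b <- .pos_in(fr, idx)
    lo <- pmin(a, b); hi <- pmax(a, b)
    bump <- lo == hi
    hi[bump] <- pmin(fr$end[idx][bump] - 1, hi[bump] + 1)
    lo[bump] <- pmax(fr$start[idx][bump], lo[bump] - 1)
    emit(fr$chrom[idx], lo, fr$chrom[idx], hi, provenance,
         strand1 = rep(s1, m), strand2 = rep(s2, m))
  }
  if (n_art[["dangling"]] > 0)
    same_frag_pair(n_art[["dangling"]], "+", "-", "dangling")
  if (n_art[["self_circle"]] > 0)
    same_frag_pair(n_art[["self_circle"]], "-", "+", "self_circle")
  if (n_art[["same_strand"]] > 0) {
    m <- n_art[["same_strand"]]
    s <- sample(c("+", "-"), m, replace = TRUE)
    idx <- sample(wide, m, replace = TRUE)
    emit(fr$chrom[idx], .pos_in(fr, idx), fr$chrom[idx], .pos_in(fr, idx),
         "same_strand", strand1 = s, strand2 = s)
  }
  if (n_art[["too_close"]] > 0) {
    mids <- fragment_midpoints(frag)
    elig <- which(fr$chrom[-nrow(fr)] == fr$chrom[-1] &
                    diff(mids) < 1000 & diff(mids) > 0)
    idx <- sample(elig, n_art[["too_close"]], replace = TRUE)
    emit(fr$chrom[idx], .pos_in(fr, idx), fr$chrom[idx + 1],
         .pos_in(fr, idx + 1), "too_close")
  }
  if (n_low > 0) {
    # background-shaped pairs flagged as multi-mappers
    gen_background(n_low, mapq1 = 0L, provenance = "low_mapq")
  }

  pairs <- do.call(rbind, out)
  # random mate order, shuffled row order, stable ids
  swap <- stats::runif(nrow(pairs)) < 0.5
  tmp <- pairs[swap, c("chrom1", "pos1", "strand1", "mapq1")]
  pairs[swap, c("chrom1", "pos1", "strand1", "mapq1")] <-
    pairs[swap, c("chrom2", "pos2", "strand2", "mapq2")]
  pairs[swap, c("chrom2", "pos2", "strand2", "mapq2")] <- tmp
  pairs <- pairs[sample.int(nrow(pairs)), , drop = FALSE]
  pairs$pair_id <- sprintf("%s%07d", id_prefix, seq_len(nrow(pairs)))
  rownames(pairs) <- NULL
  pairs[, c("pair_id", "chrom1", "pos1", "strand1", "chrom2", "pos2",
            "strand2", "mapq1", "mapq2", "provenance")]
}

# histone peak sets implied by the hub classes and gene promoters
.make_marks <- function(cfg, hubs) {
  m <- cfg$mark_margin
  mk <- function(sel) {
    h <- hubs[sel, , drop = FALSE]
    data.frame(chrom = h$chrom, start = pmax(0, h$start - m),
               end = h$end + m)
  }
  list(h3k4me3 = mk(hubs$class == "PROMOTER"),
       h3k4me1 = mk(hubs$class == "ENHANCER"),
       h3k27ac = mk(hubs$class == "ENHANCER"))
}

#' Generate a fully specified synthetic input bundle
#'
#' Produces a random MboI-digestible genome, planted hub groups with
#' class-specific pairwise contacts, genes of the three planted interaction
#' types with ordered expression, histone peaks co-located with hubs, and a
#' read-pair table mixing background distance-decay contacts, hub-anchored
#' contacts and ligation artifacts. Everything is reproducible from
#' `config$seed`.
#'
#' @param config `SimulationConfig` from [sim_config()].
#' @return bundle list: `assembly`, `fragments` (FragmentMap), `pairs`
#'   (read-pair table with a `provenance` column), `genes`, `expression`
#'   (named RPKM vector), `peaks` (list h3k4me3/h3k4me1/h3k27ac), `truth`
#'   (hubs, genes, compartment blocks, boundaries, counts), `config`.
#' @export
simulate_bundle <- function(config = sim_config()) {
  validate_sim_config(config)
  set.seed(config$seed)
  seqs <- lapply(config$chrom_lengths, function(len) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  })
  assembly <- genome_assembly(config$chrom_lengths,
                              Biostrings::DNAStringSet(unlist(seqs)))
  frag <- digest_genome(assembly, config$site)
  hubs <- .place_hubs(config, assembly)
  genes <- .place_genes(config, assembly, hubs)
  expr <- stats::rlnorm(nrow(genes),
                        log(config$expr_medians[tolower(genes$planted_type)]),
                        config$expr_sdlog)
  names(expr) <- genes$gene_id
  pairs <- .generate_pairs(config, assembly, frag, hubs, genes)
  marks <- .make_marks(config, hubs)

  blocks <- do.call(rbind, lapply(assembly$chroms, function(ch) {
    starts <- seq(0, assembly$lengths[[ch]] - 1, by = config$compartment_block_bp)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + config$compartment_block_bp,
                          assembly$lengths[[ch]]),
               label = ifelse(seq_along(starts) %% 2 == 1, "A", "B"))
  }))
  boundaries <- blocks[-1, c("chrom", "start")]
  boundaries <- boundaries[boundaries$start > 0, , drop = FALSE]

  list(assembly = assembly, fragments = frag, pairs = pairs, genes = genes,
       expression = expr, peaks = marks,
       truth = list(hubs = hubs, genes = genes, blocks = blocks,
                    boundaries = boundaries,
                    provenance_counts = table(pairs$provenance)),
       config = config)
}

#' Two-condition bundle with planted hub losses
#'
#' Generates condition A with [simulate_bundle()], then removes a set of
#' promoter hubs in condition B: their planted contacts and H3K4me3 marks
#' disappear and the expression of their genes drops `expr_drop`-fold
#' (times log-normal noise). Gene models are shared between conditions.
#'
#' @param config base configuration; the default enlarges the standard
#'   conditions to 18 hub groups with 2 hub genes per promoter hub so that
#'   `n_hub_loss_hubs = 25` removed hubs yield 50 hub-loss genes.
#' @param n_hub_loss_hubs promoter hubs removed in condition B.
#' @param expr_drop fold expression drop of hub-loss genes (default 4).
#' @param expr_noise_sdlog log-normal noise between conditions (default 0.15).
#' @return list `a`, `b` (bundles) and `truth` (removed hubs, hub-loss gene
#'   ids, planted fold change).
#' @export
two_condition_bundle <- function(config = NULL, n_hub_loss_hubs = 25,
                                 expr_drop = 4, expr_noise_sdlog = 0.15) {
  if (is.null(config))
    config <- sim_config(seed = 1, n_groups = 18L, n_genes = 360L)
  a <- simulate_bundle(config)
  phubs <- a$truth$hubs$hub_id[a$truth$hubs$class == "PROMOTER"]
  if (n_hub_loss_hubs > length(phubs))
    stop("not enough promoter hubs to remove")
  removed <- sort(sample(phubs, n_hub_loss_hubs))

  hubs_b <- a$truth$hubs[!(a$truth$hubs$hub_id %in% removed), , drop = FALSE]
  genes_b <- a$genes
  loss <- !is.na(genes_b$hub_id) & genes_b$hub_id %in% removed
  genes_b$planted_type[loss] <- "DISSOCIATIVE"

  pairs_b <- .generate_pairs(config, a$assembly, a$fragments, hubs_b,
                             genes_b, id_prefix = "q")
  marks_b <- .make_marks(config, hubs_b)
  noise <- stats::rlnorm(nrow(genes_b), 0, expr_noise_sdlog)
  expr_b <- a$expression * noise / ifelse(loss, expr_drop, 1)

  b <- list(assembly = a$assembly, fragments = a$fragments, pairs = pairs_b,
            genes = genes_b, expression = expr_b, peaks = marks_b,
            truth = list(hubs = hubs_b, genes = genes_b,
                         blocks = a$truth$blocks,
                         boundaries = a$truth$boundaries,
                         provenance_counts = table(pairs_b$provenance)),
            config = config)
  list(a = a, b = b,
       truth = list(removed_hubs = removed,
                    hub_loss_genes = a$genes$gene_id[loss],
                    expr_drop = expr_drop))
}

#' Write a simulated bundle to a directory of standard-format files
#'
#' FASTA genome, BEDPE pairs, gene TSV, expression TSV, histone peak BEDs
#' and a ground-truth JSON.
#' @param bundle from [simulate_bundle()].
#' @param dir output directory (created).
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome_fasta(bundle$assembly, file.path(dir, "genome.fa"))
  p <- bundle$pairs
  bedpe <- data.frame(chrom1 = p$chrom1, start1 = p$pos1, end1 = p$pos1 + 1,
                      chrom2 = p$chrom2, start2 = p$pos2, end2 = p$pos2 + 1,
                      name = p$pair_id, score = ".", strand1 = p$strand1,
                      strand2 = p$strand2, mapq1 = p$mapq1, mapq2 = p$mapq2)
  utils::write.table(bedpe, file.path(dir, "pairs.bedpe"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_genes(bundle$genes, file.path(dir, "genes.tsv"))
  write_expression(bundle$expression, file.path(dir, "expression.tsv"))
  for (mk in names(bundle$peaks))
    write_bed(bundle$peaks[[mk]], file.path(dir, paste0(mk, ".bed")))
  truth <- bundle$truth
  truth$provenance_counts <- as.list(truth$provenance_counts)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
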