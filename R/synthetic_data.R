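# Seeded generators for every pipeline input, with planted truth: a compact
# genome with adjacent gene pairs of known orientation/fold-change class,
# subject genomes derived from it by planted rearrangements, a methylome
# with planted UMRs, and reporter readings with planted insulator strengths.

#' Generator configuration
#'
#' One seeded configuration drives all four generators. Defaults encode the
#' study conditions the package is exercised under: a 4-chromosome genome of
#' 200 genes (100 adjacent pairs) with 20 divergent and 20 convergent
#' candidates planted among single-rule negatives; planted candidate gaps
#' at most 1 kb with probability 0.427; methylome backgrounds of 0.6/0.45/0.4
#' (CG/CHG/CHH) against planted UMR levels of 0.01 at 20x coverage; and a
#' three-replicate reporter assay whose default construct strengths include
#' the measured ratios of the two validated insulators (0.155 and 0.261 of
#' the spacer control).
#'
#' @param seed integer seed; fully determines all generator output.
#' @param n_chrom,units_per_chrom chromosome count and gene pairs (units)
#'   per chromosome; each unit contributes two genes and one planted locus.
#' @param p_divergent,p_convergent fraction of units planted as passing
#'   divergent / convergent candidates. The remainder are explicit
#'   single-rule negatives (tandem orientation, sub-threshold fold change,
#'   both genes lowly expressed, gap below 50 bp, gap above 20 kb).
#' @param short_prob probability that a planted candidate gap is <= 1 kb.
#' @param gene_len_meanlog,gene_len_sdlog log-normal gene length parameters
#'   (bp).
#' @param separator_gap range (bp) of the gap between consecutive units;
#'   kept above the miner's length ceiling so between-unit loci never pass.
#' @param n_subject_genomes number of derived subject genomes.
#' @param inversion_rate,insertion_rate,deletion_rate,big_insertion_rate
#'   per-planted-locus probabilities of rearrangement in each subject
#'   genome (flip one flanking gene; insert 1..`max_inserted` genes between
#'   the pair; delete one flanking gene; insert `max_between + 1` genes).
#'   The remainder of probability mass leaves the locus intact.
#' @param max_inserted maximum genes inserted by an ordinary insertion.
#' @param dropout_rate per-ortholog probability that its BLAST hit is lost.
#' @param cytosine_density cytosines per bp of methylome.
#' @param context_props named proportions of CG/CHG/CHH cytosines.
#' @param background_levels named per-context methylation probability
#'   outside planted UMRs.
#' @param umr_level methylation probability inside planted UMRs.
#' @param depth mean read coverage (Poisson).
#' @param umrs_per_chrom,umr_len_range planted UMR count per sequence and
#'   length range (bp; lengths are multiples of 100).
#' @param n_replicates biological replicates per construct.
#' @param assay_noise_cv multiplicative coefficient of variation of the
#'   reporter ratio (0 = noiseless).
#' @param base_mcherry,base_ratio mCherry scale and control GFP:mCherry
#'   ratio of the assay generator.
#' @param strengths named construct strengths (ratio relative to the
#'   control, which must be present with strength 1).
#' @param params [miner_params()] the genome generator plants against.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             n_chrom = 4L,
                             units_per_chrom = 25L,
                             p_divergent = 0.2,
                             p_convergent = 0.2,
                             short_prob = 0.427,
                             gene_len_meanlog = log(1500),
                             gene_len_sdlog = 0.5,
                             separator_gap = c(20500, 30000),
                             n_subject_genomes = 3L,
                             inversion_rate = 0,
                             insertion_rate = 0,
                             deletion_rate = 0,
                             big_insertion_rate = 0,
                             max_inserted = 3L,
                             dropout_rate = 0,
                             cytosine_density = 0.08,
                             context_props = c(CG = 0.25, CHG = 0.25, CHH = 0.5),
                             background_levels = c(CG = 0.6, CHG = 0.45, CHH = 0.4),
                             umr_level = 0.01,
                             depth = 20,
                             umrs_per_chrom = 4L,
                             umr_len_range = c(500, 2000),
                             n_replicates = 3L,
                             assay_noise_cv = 0.05,
                             base_mcherry = 20000,
                             base_ratio = 0.5,
                             strengths = c(spacer21 = 1, Ugi21 = 0.155,
                                           Ugi22 = 0.261, UgiA = 0.8,
                                           UgiB = 1.1),
                             params = miner_params()) {
  cfg <- as.list(environment())
  stopifnot(n_chrom >= 1, units_per_chrom >= 1)
  probs <- c(p_divergent, p_convergent, inversion_rate, insertion_rate,
             deletion_rate, big_insertion_rate, dropout_rate, short_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (p_divergent + p_convergent > 1) {
    stop("p_divergent + p_convergent must be <= 1")
  }
  if (inversion_rate + insertion_rate + deletion_rate + big_insertion_rate > 1) {
    stop("rearrangement rates must sum to <= 1")
  }
  stopifnot(all(sort(names(context_props)) == sort(METH_CONTEXTS)),
            all(sort(names(background_levels)) == sort(METH_CONTEXTS)),
            umr_level >= 0, umr_level <= 1, depth >= 0,
            separator_gap[1] > params$max_len)
  if (!any(strengths == 1)) stop("strengths must include a control with 1")
  structure(cfg, class = "generator_config")
}

# Unit classes: two positives and five single-rule negatives. Counts are
# deterministic (not per-unit draws) so planted totals are exact; lowfc and
# bothlow are balanced so exactly half of all genes land in the top
# expression pool and the top-50% cutoff separates the pools cleanly.
unit_class_counts <- function(cfg) {
  n_units <- cfg$n_chrom * cfg$units_per_chrom
  n_div <- round(cfg$p_divergent * n_units)
  n_conv <- round(cfg$p_convergent * n_units)
  n_neg <- n_units - n_div - n_conv
  q <- n_neg %/% 5L
  r <- n_neg %% 5L
  c(divergent = n_div, convergent = n_conv,
    tandem = q + r, lowfc = q, bothlow = q, shortgap = q, longgap = q)
}

#' Generate a synthetic annotated genome with planted candidates
#'
#' Lays genes out left to right in two-gene units separated by gaps above
#' the miner's length ceiling. Each unit is planted as a passing divergent
#' or convergent candidate, or as a negative violating exactly one miner
#' rule (tandem orientation; fold change below 1.5; neither gene highly
#' expressed; gap below the length floor; gap above the length ceiling).
#' Expression values occupy two separated pools (top >= 8 FPKM,
#' bottom <= 4) with exactly half of all genes in the top pool, so the
#' empirical top-50% cutoff falls between the pools and planted intent is
#' realized exactly.
#'
#' @param config a [generator_config()].
#' @return list of class `synthetic_genome`: `index` ([genome_index()]),
#'   `expression` (data.frame `gene_id`, `fpkm`), `truth` (data.frame with
#'   one row per unit locus: `region_id`, coordinates, flanking genes,
#'   `class`, `orientation`, `planted`, `planted_fc`, `is_short`) and
#'   `config`.
#' @export
gen_genome <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  p <- config$params
  counts <- unit_class_counts(config)
  classes <- sample(rep(names(counts), counts))
  genes <- list()
  truth <- list()
  unit <- 0L
  for (ch in seq_len(config$n_chrom)) {
    seqid <- sprintf("chr%d", ch)
    pos <- round(stats::runif(1, 200, 800))
    for (u in seq_len(config$units_per_chrom)) {
      unit <- unit + 1L
      cls <- classes[unit]
      lens <- pmin(pmax(round(stats::rlnorm(2, config$gene_len_meanlog,
                                            config$gene_len_sdlog)), 200), 10000)
      spec <- plant_unit(cls, p, config$short_prob)
      idx <- (u - 1L) * 2L
      gid <- sprintf("%s.g%03d", seqid, idx + 1:2)
      a_start <- pos
      a_end <- a_start + lens[1]
      b_start <- a_end + spec$gap
      b_end <- b_start + lens[2]
      genes[[length(genes) + 1L]] <- data.frame(
        gene_id = gid, seqid = seqid,
        start = c(a_start, b_start), end = c(a_end, b_end),
        strand = spec$strands, fpkm = spec$fpkm, stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        region_id = sprintf("%s:%d-%d", seqid, a_end, b_start),
        seqid = seqid, start = a_end, end = b_start, length = spec$gap,
        left_gene_id = gid[1], right_gene_id = gid[2],
        class = cls,
        orientation = pair_orientation(spec$strands[1], spec$strands[2]),
        planted = cls %in% c("divergent", "convergent"),
        planted_fc = max(spec$fpkm) / min(spec$fpkm),
        is_short = spec$gap <= p$short_max,
        stringsAsFactors = FALSE)
      pos <- b_end + round(stats::runif(1, config$separator_gap[1],
                                        config$separator_gap[2]))
    }
  }
  genes <- do.call(rbind, genes)
  truth <- do.call(rbind, truth)
  index <- genome_index(genes, genome_id = "query")
  structure(list(index = index,
                 expression = genes[, c("gene_id", "fpkm")],
                 truth = truth, config = config),
            class = "synthetic_genome")
}

# Draw strands, FPKM pair and gap for one unit of the given class.
# Top-pool values are >= 8, bottom-pool values <= 4; each class keeps the
# global half/half pool balance (lowfc is all-top, bothlow all-bottom, and
# their unit counts are equal by construction).
plant_unit <- function(cls, p, short_prob) {
  runif <- stats::runif
  flip <- function(x) if (runif(1) < 0.5) rev(x) else x
  div_or_conv <- function() {
    if (runif(1) < 0.5) c("-", "+") else c("+", "-")
  }
  mid_gap <- function() round(runif(1, max(p$min_len, 100),
                                    min(p$max_len, 5000)))
  if (cls %in% c("divergent", "convergent")) {
    lo <- runif(1, 1, 4)
    fc <- runif(1, max(2, 8.5 / lo), 20)
    fpkm <- flip(c(lo * fc, lo))
    strands <- if (cls == "divergent") c("-", "+") else c("+", "-")
    gap <- if (runif(1) < short_prob) {
      round(runif(1, p$min_len, p$short_max))
    } else {
      round(runif(1, p$short_max + 1, p$max_len))
    }
    return(list(strands = strands, fpkm = fpkm, gap = gap))
  }
  switch(cls,
    tandem = list(strands = if (runif(1) < 0.5) c("+", "+") else c("-", "-"),
                  fpkm = flip(c(runif(1, 8, 80), runif(1, 0.2, 4))),
                  gap = mid_gap()),
    lowfc = {
      a <- runif(1, 12, 80)
      list(strands = div_or_conv(),
           fpkm = flip(c(a, a / runif(1, 1.05, 1.45))),
           gap = mid_gap())
    },
    bothlow = {
      lo <- runif(1, 0.2, 1.5)
      list(strands = div_or_conv(),
           fpkm = flip(c(lo * runif(1, 2, 2.6), lo)),
           gap = mid_gap())
    },
    shortgap = list(strands = div_or_conv(),
                    fpkm = flip(c(runif(1, 8, 80), runif(1, 0.2, 4))),
                    gap = round(runif(1, 0, p$min_len - 1))),
    longgap = list(strands = div_or_conv(),
                   fpkm = flip(c(runif(1, 8, 80), runif(1, 0.2, 4))),
                   gap = round(runif(1, p$max_len + 1, p$max_len + 8000))),
    stop("unknown unit class: ", cls)
  )
}

#' Derive subject genomes with planted rearrangements and hit tables
#'
#' Each subject genome starts as a copy of the query gene order. At every
#' planted candidate locus one action is drawn from the configured
#' rearrangement rates: leave intact (intended class `high_quality`), flip
#' the right flanking gene's strand (`inversion`), insert 1..`max_inserted`
#' genes between the pair (`indel`), delete one flanking gene (`none`), or
#' insert `max_between + 1` genes (`none`). Orthologs then emit one BLAST
#' hit each, subject to the configured dropout; a locus losing a flanking
#' hit becomes `none` in the truth.
#'
#' @param genome a `synthetic_genome` from [gen_genome()].
#' @param n_genomes number of subject genomes (default from config).
#' @param config generator configuration (default: the genome's).
#' @param max_between the scanner's intervening-gene ceiling the `none`
#'   insertions must exceed (default 5).
#' @return list of class `synthetic_subjects`: `indexes` (named list of
#'   [genome_index()]), `hits` (named list of parsed hit tables with
#'   `query_gene_id`, `subject_gene_id`, `evalue`, `bitscore`), `truth`
#'   (data.frame `region_id`, `genome_id`, `klass`).
#' @export
gen_subject_genomes <- function(genome, n_genomes = NULL, config = NULL,
                                max_between = 5) {
  stopifnot(inherits(genome, "synthetic_genome"))
  if (is.null(config)) config <- genome$config
  if (is.null(n_genomes)) n_genomes <- config$n_subject_genomes
  set.seed(config$seed + 1L)
  planted <- genome$truth[genome$truth$planted, , drop = FALSE]
  qgenes <- genome$index$genes
  rates <- c(inversion = config$inversion_rate,
             insertion = config$insertion_rate,
             deletion = config$deletion_rate,
             big_insertion = config$big_insertion_rate)
  rates <- c(rates, intact = 1 - sum(rates))

  indexes <- list()
  hit_tables <- list()
  truth <- list()
  for (s in seq_len(n_genomes)) {
    gid <- sprintf("sub%02d", s)
    actions <- sample(names(rates), nrow(planted), replace = TRUE,
                      prob = rates)
    names(actions) <- planted$region_id
    flip_right <- planted$right_gene_id[actions == "inversion"]
    delete_left <- actions == "deletion" & stats::runif(nrow(planted)) < 0.5
    deleted <- c(planted$left_gene_id[delete_left],
                 planted$right_gene_id[actions == "deletion" & !delete_left])
    n_ins <- integer(nrow(planted))
    n_ins[actions == "insertion"] <-
      sample(seq_len(config$max_inserted),
             sum(actions == "insertion"), replace = TRUE)
    n_ins[actions == "big_insertion"] <- max_between + 1L
    insert_after <- setNames(n_ins, planted$left_gene_id)

    rows <- list()
    ins_counter <- 0L
    for (sq in unique(qgenes$seqid)) {
      qq <- qgenes[qgenes$seqid == sq, ]
      qq <- qq[order(qq$rank), ]
      pos <- 500
      for (i in seq_len(nrow(qq))) {
        g <- qq[i, ]
        if (!(g$gene_id %in% deleted)) {
          len <- g$end - g$start
          strand <- g$strand
          if (g$gene_id %in% flip_right) strand <- if (strand == "+") "-" else "+"
          rows[[length(rows) + 1L]] <- data.frame(
            gene_id = paste0(gid, ".", g$gene_id), seqid = sq,
            start = pos, end = pos + len, strand = strand,
            query_gene_id = g$gene_id, stringsAsFactors = FALSE)
          pos <- pos + len + 500
        }
        k <- insert_after[g$gene_id]
        if (!is.na(k) && k > 0) {
          for (j in seq_len(k)) {
            ins_counter <- ins_counter + 1L
            rows[[length(rows) + 1L]] <- data.frame(
              gene_id = sprintf("%s.ins%03d", gid, ins_counter), seqid = sq,
              start = pos, end = pos + 1000, strand = "+",
              query_gene_id = NA_character_, stringsAsFactors = FALSE)
            pos <- pos + 1500
          }
        }
      }
    }
    rows <- do.call(rbind, rows)
    orth <- rows[!is.na(rows$query_gene_id), , drop = FALSE]
    dropped <- stats::runif(nrow(orth)) < config$dropout_rate
    kept <- orth[!dropped, , drop = FALSE]
    hits <- data.frame(query_gene_id = kept$query_gene_id,
                       subject_gene_id = kept$gene_id,
                       evalue = rep(1e-50, nrow(kept)),
                       bitscore = rep(500, nrow(kept)),
                       stringsAsFactors = FALSE)

    klass <- c(intact = "high_quality", inversion = "inversion",
               insertion = "indel", deletion = "none",
               big_insertion = "none")[actions]
    lost <- !(planted$left_gene_id %in% hits$query_gene_id) |
            !(planted$right_gene_id %in% hits$query_gene_id)
    klass[lost] <- "none"
    truth[[gid]] <- data.frame(region_id = planted$region_id,
                               genome_id = gid, klass = unname(klass),
                               stringsAsFactors = FALSE)
    indexes[[gid]] <- genome_index(rows[, c("gene_id", "seqid", "start",
                                            "end", "strand")],
                                   genome_id = gid)
    hit_tables[[gid]] <- hits
  }
  structure(list(indexes = indexes, hits = hit_tables,
                 truth = do.call(rbind, c(truth, make.row.names = FALSE)),
                 config = config),
            class = "synthetic_subjects")
}

#' Write a parsed hit table as BLAST outfmt-6 TSV
#'
#' Filler alignment columns (pident, lengths, coordinates) are emitted so
#' the file is a valid 12-column table for [read_ortholog_hits()].
#'
#' @param hits data.frame with `query_gene_id`, `subject_gene_id`,
#'   `evalue`, `bitscore`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_hit_table <- function(hits, path) {
  out <- data.frame(hits$query_gene_id, hits$subject_gene_id,
                    95.0, 300L, 10L, 1L, 1L, 300L, 1L, 300L,
                    format(hits$evalue, scientific = TRUE),
                    hits$bitscore)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Generate a synthetic methylome with planted unmethylated regions
#'
#' Cytosines are placed uniformly at the configured density; coverage is
#' Poisson around `depth`; methylated read counts are binomial with the
#' per-context background probability outside planted UMRs and the (low)
#' planted level inside.
#'
#' @param seqlens named vector of sequence lengths (bp).
#' @param config a [generator_config()].
#' @param planted_umrs optional data.frame `seqid`, `start`, `end`
#'   (0-based half-open, each >= 300 bp, pairwise disjoint). When `NULL`,
#'   `umrs_per_chrom` tile-aligned UMRs per sequence are placed in evenly
#'   spaced blocks.
#' @return list of class `synthetic_methylome`: `sites` (0-based site
#'   table as from [read_allc()]), `planted` (the UMR intervals),
#'   `seqlens`, `config`.
#' @export
gen_methylome <- function(seqlens, config = generator_config(),
                          planted_umrs = NULL) {
  stopifnot(inherits(config, "generator_config"),
            !is.null(names(seqlens)), all(seqlens > 0))
  set.seed(config$seed + 2L)
  if (is.null(planted_umrs)) {
    planted_umrs <- do.call(rbind, lapply(names(seqlens), function(sq) {
      L <- seqlens[[sq]]
      n <- config$umrs_per_chrom
      block <- floor(L / n / 100) * 100
      lens <- 100 * sample(seq(config$umr_len_range[1] %/% 100,
                               config$umr_len_range[2] %/% 100),
                           n, replace = TRUE)
      lens <- pmin(lens, pmax(300, block - 400))
      offs <- vapply(seq_len(n), function(i) {
        slack <- max(0, block - lens[i] - 400)
        100 * sample.int(slack %/% 100 + 1L, 1) - 100
      }, numeric(1))
      start <- (seq_len(n) - 1) * block + offs
      data.frame(seqid = sq, start = start, end = start + lens,
                 stringsAsFactors = FALSE)
    }))
  }
  check_disjoint(planted_umrs)
  if (any(planted_umrs$end - planted_umrs$start < 300)) {
    stop("planted UMRs must be >= 300 bp")
  }
  sites <- do.call(rbind, lapply(names(seqlens), function(sq) {
    L <- seqlens[[sq]]
    n <- round(L * config$cytosine_density)
    if (n == 0) return(NULL)
    pos <- sort(sample.int(L, min(n, L))) - 1
    ctx <- sample(names(config$context_props), length(pos), replace = TRUE,
                  prob = config$context_props)
    u <- planted_umrs[planted_umrs$seqid == sq, , drop = FALSE]
    inside <- rep(FALSE, length(pos))
    for (i in seq_len(nrow(u))) {
      inside <- inside | (pos >= u$start[i] & pos < u$end[i])
    }
    p <- ifelse(inside, config$umr_level,
                config$background_levels[ctx])
    cov <- stats::rpois(length(pos), config$depth)
    data.frame(seqid = sq, pos = pos,
               strand = sample(c("+", "-"), length(pos), replace = TRUE),
               context = ctx,
               mc_reads = stats::rbinom(length(pos), cov, p),
               total_reads = cov, stringsAsFactors = FALSE)
  }))
  rownames(sites) <- NULL
  structure(list(sites = sites, planted = planted_umrs,
                 seqlens = seqlens, config = config),
            class = "synthetic_methylome")
}

check_disjoint <- function(iv) {
  for (sq in unique(iv$seqid)) {
    x <- iv[iv$seqid == sq, , drop = FALSE]
    x <- x[order(x$start), , drop = FALSE]
    if (nrow(x) > 1 && any(x$start[-1] < x$end[-nrow(x)])) {
      stop("planted UMRs overlap on ", sq)
    }
  }
  invisible(iv)
}

#' Write a site table as allc-style TSV
#'
#' Positions are converted back to the file convention (1-based).
#'
#' @param sites site table (0-based `pos`).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_allc <- function(sites, path) {
  out <- data.frame(sites$seqid, sites$pos + 1, sites$strand, sites$context,
                    sites$mc_reads, sites$total_reads)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Generate synthetic dual-reporter readings with planted strengths
#'
#' Per replicate, mCherry is log-normal around `base_mcherry` and GFP is
#' `strength * base_ratio * mcherry` times a multiplicative log-normal
#' noise with unit mean and coefficient of variation `assay_noise_cv`.
#' At zero noise the downstream fold change of a construct with strength
#' `s` is exactly `s - 1`.
#'
#' @param config a [generator_config()].
#' @param strengths named strengths (default from config; must include the
#'   control at 1).
#' @return data.frame `construct_id`, `replicate`, `gfp`, `mcherry`.
#' @export
gen_assay <- function(config = generator_config(),
                      strengths = config$strengths) {
  stopifnot(inherits(config, "generator_config"))
  if (!any(strengths == 1)) stop("strengths must include a control with 1")
  set.seed(config$seed + 3L)
  cv <- config$assay_noise_cv
  sdlog <- sqrt(log(1 + cv^2))
  out <- lapply(names(strengths), function(cid) {
    mch <- stats::rlnorm(config$n_replicates, log(config$base_mcherry), 0.15)
    noise <- if (cv == 0) rep(1, config$n_replicates) else
      stats::rlnorm(config$n_replicates, -sdlog^2 / 2, sdlog)
    data.frame(construct_id = cid,
               replicate = seq_len(config$n_replicates),
               gfp = strengths[[cid]] * config$base_ratio * mch * noise,
               mcherry = mch, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write reporter readings as TSV
#'
#' @param records assay table from [gen_assay()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_assay <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read reporter readings from TSV
#'
#' @param path TSV with header `construct_id`, `replicate`, `gfp`, `mcherry`.
#' @return data.frame in the form [ratios()] consumes.
#' @export
read_assay <- function(path) {
  if (!file.exists(path)) stop("assay file not found: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("construct_id", "replicate", "gfp", "mcherry")
  if (!all(need %in% names(tab))) {
    stop("assay table needs columns: ", paste(need, collapse = ", "))
  }
  tab
}
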