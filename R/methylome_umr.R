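# Tile-based methylome summarisation and unmethylated-region (UMR) calling.
# Contexts are CG, CHG, CHH; levels are weighted (reads, not sites).

METH_CONTEXTS <- c("CG", "CHG", "CHH")

#' Read per-cytosine methylation records (allc-style TSV)
#'
#' @param path tab-separated file without header: seqid, position (1-based),
#'   strand, context (CG/CHG/CHH), methylated reads, total reads, and an
#'   optional seventh call column (ignored).
#' @return data.frame `seqid`, `pos` (0-based), `strand`, `context`,
#'   `mc_reads`, `total_reads`.
#' @export
read_allc <- function(path) {
  if (!file.exists(path)) stop("allc file not found: ", path)
  if (file.size(path) == 0) {
    return(data.frame(seqid = character(0), pos = numeric(0),
                      strand = character(0), context = character(0),
                      mc_reads = numeric(0), total_reads = numeric(0)))
  }
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 6) stop("expected >= 6 allc columns in ", path)
  sites <- data.frame(seqid = as.character(tab[[1]]),
                      pos = as.numeric(tab[[2]]) - 1,  # 1-based -> 0-based
                      strand = as.character(tab[[3]]),
                      context = as.character(tab[[4]]),
                      mc_reads = as.numeric(tab[[5]]),
                      total_reads = as.numeric(tab[[6]]),
                      stringsAsFactors = FALSE)
  validate_sites(sites)
  sites
}

validate_sites <- function(sites) {
  if (nrow(sites) == 0) return(invisible(sites))
  if (!all(sites$context %in% METH_CONTEXTS)) {
    stop("context must be one of ", paste(METH_CONTEXTS, collapse = ", "))
  }
  if (any(sites$pos < 0)) stop("negative position in methylation records")
  if (any(sites$mc_reads < 0 | sites$mc_reads > sites$total_reads)) {
    stop("need 0 <= mc_reads <= total_reads")
  }
  invisible(sites)
}

#' Summarise methylation in fixed non-overlapping tiles
#'
#' Assigns each cytosine to the tile `floor(pos / tile_size)` and computes
#' per-context cytosine counts, methylated/total read sums and weighted
#' levels, plus the tile's mean coverage (mean total reads per cytosine with
#' at least one read). Tiles without any site are emitted as `missing` so
#' that tiles partition each sequence.
#'
#' @param sites site table as from [read_allc()] (0-based positions).
#' @param tile_size tile width in bp (default 100).
#' @param seqlens optional named vector of sequence lengths; when given,
#'   tiles cover `[0, seqlen)` per sequence (the terminal tile may be
#'   shorter) and sequences without sites still produce tiles. Without it,
#'   tiles run through the last occupied tile of each sequence present.
#' @param ... status parameters passed to [call_tile_status()].
#' @return data.frame with one row per tile: `seqid`, `start`, `end`, per
#'   context `n_<ctx>`, `mc_<ctx>`, `cov_<ctx>`, `level_<ctx>`, then
#'   `n_all`, `mean_coverage`, `status`.
#' @export
tile_methylome <- function(sites, tile_size = 100, seqlens = NULL, ...) {
  validate_sites(sites)
  seqs <- if (!is.null(seqlens)) names(seqlens) else unique(sites$seqid)
  tiles <- lapply(seqs, function(sq) {
    s <- sites[sites$seqid == sq, , drop = FALSE]
    if (!is.null(seqlens)) {
      L <- seqlens[[sq]]
      if (nrow(s) > 0 && any(s$pos >= L)) {
        stop("site beyond declared length of ", sq)
      }
      n_tiles <- max(1L, as.integer(ceiling(L / tile_size)))
    } else {
      if (nrow(s) == 0) return(NULL)
      L <- Inf
      n_tiles <- as.integer(max(floor(s$pos / tile_size)) + 1)
    }
    start <- (seq_len(n_tiles) - 1) * tile_size
    end <- pmin(start + tile_size, L)
    tl <- data.frame(seqid = sq, start = start, end = end,
                     stringsAsFactors = FALSE)
    idx <- as.integer(floor(s$pos / tile_size)) + 1L
    for (ctx in METH_CONTEXTS) {
      in_ctx <- s$context == ctx
      tl[[paste0("n_", ctx)]] <-
        tabulate_sum(idx[in_ctx], rep(1, sum(in_ctx)), n_tiles)
      tl[[paste0("mc_", ctx)]] <-
        tabulate_sum(idx[in_ctx], s$mc_reads[in_ctx], n_tiles)
      tl[[paste0("cov_", ctx)]] <-
        tabulate_sum(idx[in_ctx], s$total_reads[in_ctx], n_tiles)
      tl[[paste0("level_", ctx)]] <-
        ifelse(tl[[paste0("cov_", ctx)]] > 0,
               tl[[paste0("mc_", ctx)]] / tl[[paste0("cov_", ctx)]],
               NA_real_)
    }
    tl$n_all <- tl$n_CG + tl$n_CHG + tl$n_CHH
    covered <- s$total_reads > 0
    n_cov <- tabulate_sum(idx[covered], rep(1, sum(covered)), n_tiles)
    cov_tot <- tabulate_sum(idx[covered], s$total_reads[covered], n_tiles)
    tl$mean_coverage <- ifelse(n_cov > 0, cov_tot / n_cov, 0)
    tl
  })
  tiles <- do.call(rbind, tiles)
  if (is.null(tiles)) stop("no sites and no seqlens: nothing to tile")
  rownames(tiles) <- NULL
  tiles$status <- call_tile_status(tiles, ...)
  tiles
}

tabulate_sum <- function(idx, w, nbins) {
  out <- numeric(nbins)
  if (length(idx) == 0) return(out)
  agg <- tapply(w, idx, sum)
  out[as.integer(names(agg))] <- as.numeric(agg)
  out
}

#' Call the methylation status of tiles
#'
#' A tile is `missing` when it holds fewer than `min_cytosines` cytosines
#' or (default rule) has mean coverage below `min_coverage`; it is
#' `unmethylated` when every context represented in the tile has a weighted
#' level strictly below `max_level`; otherwise it is `methylated`. Contexts
#' with cytosines but zero covering reads carry no level information and
#' pass vacuously (such tiles are usually `missing` anyway).
#'
#' @param tiles tile table from [tile_methylome()].
#' @param min_cytosines minimum cytosines per tile (default 2).
#' @param min_coverage minimum mean coverage (default 5).
#' @param max_level strict per-context level ceiling for an unmethylated
#'   call (default 0.10).
#' @param missing_rule `"or"` (default: either low cytosine count or low
#'   coverage makes a tile missing) or `"and"` (both required).
#' @return character vector of statuses, one per tile.
#' @export
call_tile_status <- function(tiles, min_cytosines = 2, min_coverage = 5,
                             max_level = 0.10,
                             missing_rule = c("or", "and")) {
  missing_rule <- match.arg(missing_rule)
  few_c <- tiles$n_all < min_cytosines
  low_cov <- tiles$mean_coverage < min_coverage
  missing <- if (missing_rule == "or") few_c | low_cov else few_c & low_cov
  low_all <- rep(TRUE, nrow(tiles))
  for (ctx in METH_CONTEXTS) {
    lvl <- tiles[[paste0("level_", ctx)]]
    has <- tiles[[paste0("n_", ctx)]] > 0 & !is.na(lvl)
    low_all <- low_all & (!has | lvl < max_level)
  }
  ifelse(missing, "missing", ifelse(low_all, "unmethylated", "methylated"))
}

#' Merge tiles into unmethylated regions
#'
#' Takes maximal runs of consecutive tiles whose status is `unmethylated`
#' or `missing`, trims leading and trailing missing tiles (so UMR boundaries
#' are supported by data), and keeps a run as a UMR iff its span is at least
#' `min_span` bp and its missing-tile fraction is at most
#' `max_missing_frac`.
#'
#' @param tiles tile table with a `status` column.
#' @param min_span minimum UMR span in bp (default 300).
#' @param max_missing_frac maximum fraction of missing tiles (default 1/3,
#'   inclusive).
#' @return data.frame `seqid`, `start`, `end`, `n_tiles`, `n_missing`,
#'   `missing_fraction`.
#' @export
merge_umrs <- function(tiles, min_span = 300, max_missing_frac = 1/3) {
  empty <- data.frame(seqid = character(0), start = numeric(0),
                      end = numeric(0), n_tiles = integer(0),
                      n_missing = integer(0), missing_fraction = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(tiles) == 0) return(empty)
  out <- lapply(split(tiles, tiles$seqid), function(tl) {
    tl <- tl[order(tl$start), , drop = FALSE]
    eligible <- tl$status %in% c("unmethylated", "missing")
    r <- rle(eligible)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    runs <- which(r$values)
    rows <- lapply(runs, function(k) {
      i <- starts[k]:ends[k]
      # trim flanking missing tiles
      um <- which(tl$status[i] == "unmethylated")
      if (length(um) == 0) return(NULL)
      i <- i[um[1]:um[length(um)]]
      span <- tl$end[i[length(i)]] - tl$start[i[1]]
      n_missing <- sum(tl$status[i] == "missing")
      frac <- n_missing / length(i)
      if (span < min_span || frac > max_missing_frac) return(NULL)
      data.frame(seqid = tl$seqid[1], start = tl$start[i[1]],
                 end = tl$end[i[length(i)]], n_tiles = length(i),
                 n_missing = n_missing, missing_fraction = frac,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}

#' Genome-wide weighted methylation levels per context
#'
#' @param sites site table as from [read_allc()].
#' @return named list with per-context weighted levels (`CG`, `CHG`, `CHH`:
#'   sum of methylated reads over sum of total reads across sites with
#'   coverage) plus `all` (all contexts pooled). Contexts with no covered
#'   sites are `NA`.
#' @export
global_levels <- function(sites) {
  if (nrow(sites) == 0) stop("empty site set")
  covered <- sites[sites$total_reads > 0, , drop = FALSE]
  lev <- lapply(METH_CONTEXTS, function(ctx) {
    s <- covered[covered$context == ctx, , drop = FALSE]
    if (nrow(s) == 0) return(NA_real_)
    sum(s$mc_reads) / sum(s$total_reads)
  })
  names(lev) <- METH_CONTEXTS
  lev$all <- if (nrow(covered) == 0) NA_real_ else
    sum(covered$mc_reads) / sum(covered$total_reads)
  lev
}

#' Overlap candidate regions with UMRs
#'
#' A candidate overlaps when it shares at least one base with any UMR
#' (half-open coordinates; abutting intervals do not overlap).
#'
#' @param candidates interval table with `seqid`, `start`, `end`.
#' @param umrs UMR table from [merge_umrs()].
#' @return list: `n_overlapping`, `n_candidates`, `pct` (1 decimal),
#'   `mean_candidate_length`, `mean_umr_length`, and `overlaps` (logical
#'   vector along `candidates`).
#' @export
overlap_candidates <- function(candidates, umrs) {
  if (nrow(candidates) == 0) {
    return(list(n_overlapping = 0L, n_candidates = 0L, pct = NA_real_,
                mean_candidate_length = NA_real_,
                mean_umr_length = if (nrow(umrs)) mean(umrs$end - umrs$start)
                                  else NA_real_,
                overlaps = logical(0)))
  }
  hit <- rep(FALSE, nrow(candidates))
  nonzero <- candidates$end > candidates$start
  if (nrow(umrs) > 0 && any(nonzero)) {
    cr <- GenomicRanges::GRanges(
      candidates$seqid[nonzero],
      IRanges::IRanges(start = candidates$start[nonzero] + 1,
                       end = candidates$end[nonzero]))
    ur <- GenomicRanges::GRanges(
      umrs$seqid, IRanges::IRanges(start = umrs$start + 1, end = umrs$end))
    hit[nonzero] <- IRanges::overlapsAny(cr, ur)
  }
  list(n_overlapping = sum(hit),
       n_candidates = nrow(candidates),
       pct = pct1(sum(hit), nrow(candidates)),
       mean_candidate_length = mean(candidates$end - candidates$start),
       mean_umr_length = if (nrow(umrs)) mean(umrs$end - umrs$start)
                         else NA_real_,
       overlaps = hit)
}
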