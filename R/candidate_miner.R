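# Candidate mining: intergenic regions between adjacent gene pairs,
# classified by flanking-gene orientation and expression fold change.

#' Miner parameters
#'
#' Thresholds of the candidate classifier. All length bounds are inclusive.
#'
#' @param min_len minimum intergenic length in bp (default 50).
#' @param max_len maximum intergenic length in bp (default 20000).
#' @param min_fc minimum FPKM fold change between the flanking genes,
#'   higher/lower (default 1.5, inclusive).
#' @param top_fraction fraction of all transcripts that defines the
#'   "highly expressed" set (default 0.5: the top 50%).
#' @param short_max length cutoff of the short-candidate subset used for
#'   engineering applications (default 1000 bp, inclusive).
#' @return A list of class `miner_params`.
#' @export
miner_params <- function(min_len = 50, max_len = 20000, min_fc = 1.5,
                         top_fraction = 0.5, short_max = 1000) {
  if (!(min_len > 0 && min_len <= max_len)) {
    stop("need 0 < min_len <= max_len")
  }
  if (min_fc < 1) stop("min_fc must be >= 1")
  if (!(top_fraction > 0 && top_fraction <= 1)) {
    stop("top_fraction must be in (0, 1]")
  }
  structure(list(min_len = min_len, max_len = max_len, min_fc = min_fc,
                 top_fraction = top_fraction, short_max = short_max),
            class = "miner_params")
}

#' Extract intergenic regions between adjacent gene pairs
#'
#' One region per pair of genes with consecutive positional ranks on the same
#' sequence, spanning from the left gene's end to the right gene's start.
#' Pairs whose genes overlap (including nesting) yield no region; they do not
#' block the formation of the next consecutive pair.
#'
#' @param index a [genome_index()].
#' @return data.frame with `region_id`, `seqid`, `start`, `end`, `length`,
#'   `left_gene_id`, `right_gene_id`, `orientation`
#'   (divergent / convergent / tandem). Zero-length regions (abutting genes)
#'   are kept; downstream length filters remove them.
#' @export
extract_intergenic <- function(index) {
  stopifnot(inherits(index, "genome_index"))
  g <- index$genes
  out <- lapply(split(g, g$seqid), function(gg) {
    gg <- gg[order(gg$rank), , drop = FALSE]
    n <- nrow(gg)
    if (n < 2) return(NULL)
    i <- seq_len(n - 1)
    left <- gg[i, ]
    right <- gg[i + 1, ]
    ok <- right$start >= left$end  # overlapping or nested pairs: no region
    if (!any(ok)) return(NULL)
    left <- left[ok, ]
    right <- right[ok, ]
    data.frame(
      region_id = sprintf("%s:%d-%d", left$seqid, left$end, right$start),
      seqid = left$seqid,
      start = left$end,
      end = right$start,
      length = right$start - left$end,
      left_gene_id = left$gene_id,
      right_gene_id = right$gene_id,
      orientation = pair_orientation(left$strand, right$strand),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(region_id = character(0), seqid = character(0),
                      start = numeric(0), end = numeric(0),
                      length = numeric(0), left_gene_id = character(0),
                      right_gene_id = character(0),
                      orientation = character(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Orientation class of a gene pair
#'
#' Head-to-head pairs (left gene on `-`, right gene on `+`, transcription
#' pointing away from the shared intergenic space) are divergent;
#' tail-to-tail pairs (`+`,`-`) are convergent; co-oriented pairs are tandem.
#'
#' @param left_strand,right_strand strand of the left/right gene
#'   (by coordinate), each `"+"` or `"-"`. Vectorised.
#' @return character vector: `"divergent"`, `"convergent"` or `"tandem"`.
#' @export
pair_orientation <- function(left_strand, right_strand) {
  ifelse(left_strand == "-" & right_strand == "+", "divergent",
         ifelse(left_strand == "+" & right_strand == "-", "convergent",
                "tandem"))
}

#' Expression cutoff for the "highly expressed" transcript set
#'
#' Returns the FPKM value such that transcripts with `fpkm >= cutoff`
#' constitute the top `top_fraction` of all transcripts. With `n` values the
#' cutoff is the `ceiling(top_fraction * n)`-th largest value, so ties at the
#' cutoff are counted as highly expressed.
#'
#' @param all_fpkm numeric vector of FPKM values for every transcript.
#' @param top_fraction fraction defining the top set (default 0.5).
#' @return The FPKM cutoff.
#' @export
expression_threshold <- function(all_fpkm, top_fraction = 0.5) {
  if (length(all_fpkm) == 0) stop("empty FPKM collection")
  stopifnot(top_fraction > 0, top_fraction <= 1)
  k <- ceiling(top_fraction * length(all_fpkm))
  sort(all_fpkm, decreasing = TRUE)[k]
}

#' Call insulator-like candidate regions
#'
#' Applies the orientation + expression classification to intergenic
#' regions. A region passes the core filter iff all of:
#' length within `[min_len, max_len]`; orientation divergent or convergent
#' (never tandem); FPKM fold change (higher/lower flanking gene)
#' `>= min_fc`; the higher-expressed flanking gene is in the top
#' `top_fraction` of all transcripts; and, for convergent pairs, exactly one
#' flanking gene is in that top set.
#'
#' @param regions output of [extract_intergenic()].
#' @param index the [genome_index()] the regions came from (provides the
#'   FPKM of every transcript for the top-set cutoff).
#' @param params a [miner_params()].
#' @return `regions` augmented with `fpkm_left`, `fpkm_right`,
#'   `fold_change` (`Inf` when the lower FPKM is 0 and the higher positive;
#'   `NA` when both are 0), `high_gene_id`, `passes_core_filter`,
#'   `is_short` (length `<= short_max`).
#' @details Fold change is `max(f1,f2)/min(f1,f2)` with no pseudo-count: a
#'   zero lower FPKM against a positive higher one is treated as infinite
#'   (it passes any `min_fc`); a pair with both FPKM 0 never passes.
#' @export
call_candidates <- function(regions, index, params = miner_params()) {
  stopifnot(inherits(index, "genome_index"), inherits(params, "miner_params"))
  g <- index$genes
  cutoff <- expression_threshold(g$fpkm, params$top_fraction)
  fl <- g$fpkm[match(regions$left_gene_id, g$gene_id)]
  fr <- g$fpkm[match(regions$right_gene_id, g$gene_id)]
  if (anyNA(fl) || anyNA(fr)) stop("region references gene absent from index")
  hi <- pmax(fl, fr)
  lo <- pmin(fl, fr)
  fc <- ifelse(hi == 0, NA_real_, ifelse(lo == 0, Inf, hi / lo))
  high_gene <- ifelse(fl >= fr, regions$left_gene_id, regions$right_gene_id)
  high_gene[hi == 0] <- NA_character_
  left_top <- fl >= cutoff
  right_top <- fr >= cutoff
  high_top <- hi >= cutoff
  exactly_one_top <- xor(left_top, right_top)

  len_ok <- regions$length >= params$min_len & regions$length <= params$max_len
  orient_ok <- regions$orientation %in% c("divergent", "convergent")
  fc_ok <- !is.na(fc) & fc >= params$min_fc
  conv_ok <- regions$orientation != "convergent" | exactly_one_top

  regions$fpkm_left <- fl
  regions$fpkm_right <- fr
  regions$fold_change <- fc
  regions$high_gene_id <- high_gene
  regions$passes_core_filter <-
    len_ok & orient_ok & fc_ok & high_top & conv_ok
  regions$is_short <- regions$length <= params$short_max
  attr(regions, "expression_cutoff") <- cutoff
  regions
}

#' Restrict passing candidates to the short subset
#'
#' @param candidates output of [call_candidates()].
#' @param short_max inclusive length cutoff in bp (default 1000).
#' @return The passing candidates with `length <= short_max`; the attribute
#'   `"retained_fraction"` carries the retained share of all passing
#'   candidates (`NA` when none pass).
#' @export
filter_short <- function(candidates, short_max = 1000) {
  passing <- candidates[candidates$passes_core_filter, , drop = FALSE]
  short <- passing[passing$length <= short_max, , drop = FALSE]
  frac <- if (nrow(passing) == 0) NA_real_ else nrow(short) / nrow(passing)
  attr(short, "retained_fraction") <- frac
  short
}
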