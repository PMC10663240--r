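# Microsynteny scanning: is the gene pair flanking a candidate region
# conserved in a subject genome, and if so, how was it rearranged?

#' Classify microsynteny of one candidate's flanking pair in one subject genome
#'
#' Considers every pair (h1, h2) where h1 is an ortholog hit of the left
#' flanking gene and h2 of the right, both on one subject sequence with at
#' most `max_between` genes between them (and, symmetrically, at most
#' `max_between` genes between the pair in the query). Among admissible
#' pairs, the one with the fewest intervening subject genes is selected
#' (ties: smaller summed e-value, then lexicographic subject gene ids) and
#' classified:
#' \itemize{
#'   \item relative orientation conserved and intervening gene counts equal
#'     -> `high_quality`;
#'   \item orientation conserved, counts differ -> `indel`;
#'   \item exactly one gene's relative orientation flipped, counts equal
#'     -> `inversion`;
#'   \item otherwise, or no admissible pair -> `none`.
#' }
#' Orientation is compared on the relative configuration of the pair (each
#' gene's direction along the axis from the left-flank ortholog towards the
#' right-flank ortholog), not on absolute strands, so reversing an entire
#' subject sequence changes no call.
#'
#' @param candidate one row of the [call_candidates()] table (needs
#'   `region_id`, `left_gene_id`, `right_gene_id`).
#' @param query_index [genome_index()] of the query genome.
#' @param subject_index [genome_index()] of the subject genome.
#' @param hits hit table for that subject genome, as from
#'   [read_ortholog_hits()] (already e-value filtered).
#' @param max_between maximum number of intervening genes (inclusive,
#'   default 5).
#' @return One-row data.frame: `region_id`, `subject_genome_id`, `klass`,
#'   `subject_left_gene`, `subject_right_gene`, `intervening_query`,
#'   `intervening_subject` (the last four `NA` when `klass` is `"none"` with
#'   no admissible pair).
#' @export
scan_region <- function(candidate, query_index, subject_index, hits,
                        max_between = 5) {
  qg <- query_index$genes
  lid <- candidate$left_gene_id
  rid <- candidate$right_gene_id
  ql <- qg[qg$gene_id == lid, ]
  qr <- qg[qg$gene_id == rid, ]
  stopifnot(nrow(ql) == 1, nrow(qr) == 1)
  none <- data.frame(region_id = candidate$region_id,
                     subject_genome_id = subject_index$genome_id,
                     klass = "none",
                     subject_left_gene = NA_character_,
                     subject_right_gene = NA_character_,
                     intervening_query = NA_integer_,
                     intervening_subject = NA_integer_,
                     stringsAsFactors = FALSE)
  iq <- abs(qr$rank - ql$rank) - 1L
  if (ql$seqid != qr$seqid || iq > max_between) return(none)

  hl <- hits[hits$query_gene_id == lid, , drop = FALSE]
  hr <- hits[hits$query_gene_id == rid, , drop = FALSE]
  if (nrow(hl) == 0 || nrow(hr) == 0) return(none)

  sg <- subject_index$genes
  il <- match(hl$subject_gene_id, sg$gene_id)
  ir <- match(hr$subject_gene_id, sg$gene_id)
  hl <- hl[!is.na(il), , drop = FALSE]; il <- il[!is.na(il)]
  hr <- hr[!is.na(ir), , drop = FALSE]; ir <- ir[!is.na(ir)]
  if (nrow(hl) == 0 || nrow(hr) == 0) return(none)

  pairs <- expand.grid(a = seq_len(nrow(hl)), b = seq_len(nrow(hr)))
  sa <- sg[il[pairs$a], ]
  sb <- sg[ir[pairs$b], ]
  keep <- sa$seqid == sb$seqid & sa$gene_id != sb$gene_id &
    abs(sb$rank - sa$rank) - 1L <= max_between
  if (!any(keep)) return(none)
  pairs <- pairs[keep, , drop = FALSE]
  sa <- sa[keep, , drop = FALSE]
  sb <- sb[keep, , drop = FALSE]
  between <- abs(sb$rank - sa$rank) - 1L
  esum <- hl$evalue[pairs$a] + hr$evalue[pairs$b]
  ord <- order(between, esum, sa$gene_id, sb$gene_id)
  best <- ord[1]

  klass <- classify_pair(
    query_strands = c(ql$strand, qr$strand),
    subject_strands = c(sa$strand[best], sb$strand[best]),
    subject_forward = sb$rank[best] > sa$rank[best],
    intervening_query = iq,
    intervening_subject = between[best]
  )
  data.frame(region_id = candidate$region_id,
             subject_genome_id = subject_index$genome_id,
             klass = klass,
             subject_left_gene = sa$gene_id[best],
             subject_right_gene = sb$gene_id[best],
             intervening_query = iq,
             intervening_subject = between[best],
             stringsAsFactors = FALSE)
}

# Relative-configuration comparison. subject_strands are given in query
# order (ortholog of the left flank first). When the subject pair runs
# against subject coordinates (subject_forward FALSE), each subject strand
# is flipped so both pairs are read along the same axis.
classify_pair <- function(query_strands, subject_strands, subject_forward,
                          intervening_query, intervening_subject) {
  eff <- subject_strands
  if (!subject_forward) eff <- ifelse(eff == "+", "-", "+")
  flips <- sum(eff != query_strands)
  counts_equal <- intervening_query == intervening_subject
  if (flips == 0 && counts_equal) return("high_quality")
  if (flips == 0) return("indel")
  if (flips == 1 && counts_equal) return("inversion")
  "none"
}

#' Build the candidate-by-genome presence/absence matrix
#'
#' Runs [scan_region()] for every candidate against every subject genome and
#' tabulates the conservation classes.
#'
#' @param candidates candidate table ([call_candidates()] rows; typically
#'   the passing subset).
#' @param query_index [genome_index()] of the query genome.
#' @param subject_indexes named list of subject `genome_index` objects.
#' @param hit_tables named list (same names) of hit tables.
#' @param max_between see [scan_region()].
#' @return A list of class `synteny_matrix`: `matrix` (character, regions x
#'   genomes, values high_quality/indel/inversion/none), `calls` (long-form
#'   data.frame of all scan results), `breadth` (named integer: genomes with
#'   a non-`none` call per region), `per_genome_syntenic` (named integer:
#'   regions with a non-`none` call per genome).
#' @export
build_matrix <- function(candidates, query_index, subject_indexes,
                         hit_tables, max_between = 5) {
  stopifnot(length(subject_indexes) == length(hit_tables))
  if (length(subject_indexes) > 0) {
    stopifnot(!is.null(names(subject_indexes)),
              identical(sort(names(subject_indexes)), sort(names(hit_tables))))
  }
  genomes <- names(subject_indexes)
  mat <- matrix("none", nrow = nrow(candidates), ncol = length(genomes),
                dimnames = list(candidates$region_id, genomes))
  calls <- list()
  for (gid in genomes) {
    res <- lapply(seq_len(nrow(candidates)), function(i) {
      scan_region(candidates[i, ], query_index, subject_indexes[[gid]],
                  hit_tables[[gid]], max_between = max_between)
    })
    res <- do.call(rbind, res)
    calls[[gid]] <- res
    mat[, gid] <- res$klass
  }
  calls <- if (length(calls)) do.call(rbind, c(calls, make.row.names = FALSE))
           else data.frame()
  breadth <- if (ncol(mat) > 0) rowSums(mat != "none") else
    setNames(rep(0L, nrow(candidates)), candidates$region_id)
  per_genome <- if (ncol(mat) > 0) colSums(mat != "none") else integer(0)
  structure(list(matrix = mat, calls = calls,
                 breadth = breadth, per_genome_syntenic = per_genome),
            class = "synteny_matrix")
}

#' High-confidence conserved candidates
#'
#' A syntenic candidate is high confidence when it is at most `len_max` bp
#' long, shows a strictly greater than `fc_min` expression fold change
#' between its flanking genes, and has a `high_quality` microsynteny call
#' (orientation and gene count conserved) in at least one subject genome.
#'
#' @param candidates candidate table with `fold_change` and `length`.
#' @param synteny a `synteny_matrix` from [build_matrix()].
#' @param fc_min strict fold-change floor (default 10).
#' @param len_max inclusive length ceiling in bp (default 1000).
#' @return list: `region_ids`, `n`, `n_syntenic` (candidates with any
#'   non-`none` call) and `pct_of_syntenic` (1 decimal).
#' @export
high_confidence <- function(candidates, synteny, fc_min = 10,
                            len_max = 1000) {
  mat <- synteny$matrix
  stopifnot(identical(rownames(mat), candidates$region_id))
  any_hq <- if (ncol(mat) > 0) rowSums(mat == "high_quality") > 0
            else rep(FALSE, nrow(candidates))
  ok <- candidates$length <= len_max &
    !is.na(candidates$fold_change) & candidates$fold_change > fc_min &
    any_hq
  n_syntenic <- sum(synteny$breadth > 0)
  list(region_ids = candidates$region_id[ok],
       n = sum(ok),
       n_syntenic = n_syntenic,
       pct_of_syntenic = pct1(sum(ok), n_syntenic))
}

#' Rank candidates for in vivo validation
#'
#' Two shortlists of `k` candidates each, both ignoring orientation class:
#' list A sorts by fold change descending (infinite fold changes first,
#' ordered among themselves by the high gene's FPKM descending); list B
#' sorts by synteny breadth (number of genomes with any conservation call)
#' descending, regardless of fold change. Ties in both lists are broken by
#' region length ascending, then region id.
#'
#' @param candidates candidate table (typically passing candidates).
#' @param synteny a `synteny_matrix` covering the same regions.
#' @param k shortlist size (default 9). When `k` exceeds the number of
#'   candidates, all are returned with a warning.
#' @return list with data.frames `by_fold_change` and `by_breadth` (the
#'   latter with a `breadth` column).
#' @export
select_for_validation <- function(candidates, synteny, k = 9) {
  stopifnot(identical(rownames(synteny$matrix), candidates$region_id))
  if (k > nrow(candidates)) {
    warning("k = ", k, " exceeds candidate count ", nrow(candidates),
            "; returning all", call. = FALSE)
    k <- nrow(candidates)
  }
  g_hi <- pmax(candidates$fpkm_left, candidates$fpkm_right)
  fc_key <- candidates$fold_change
  fc_key[is.na(fc_key)] <- -Inf
  inf_tiebreak <- ifelse(is.infinite(fc_key) & fc_key > 0, -g_hi, 0)
  ord_a <- order(-fc_key, inf_tiebreak, candidates$length,
                 candidates$region_id)
  breadth <- as.integer(synteny$breadth)
  ord_b <- order(-breadth, candidates$length, candidates$region_id)
  by_b <- candidates[ord_b[seq_len(k)], , drop = FALSE]
  by_b$breadth <- breadth[ord_b[seq_len(k)]]
  list(by_fold_change = candidates[ord_a[seq_len(k)], , drop = FALSE],
       by_breadth = by_b)
}
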