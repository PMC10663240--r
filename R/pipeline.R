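# End-to-end orchestration: mine candidates -> microsynteny -> UMR overlap
# -> reporter assay, from one declarative config, with a machine-readable
# summary report.

pipeline_defaults <- function() {
  list(
    inputs = list(annotation = NULL, expression = NULL,
                  subject_annotations = NULL, hits = NULL,
                  allc = NULL, seqlens = NULL, assay = NULL),
    miner = list(min_len = 50, max_len = 20000, min_fc = 1.5,
                 top_fraction = 0.5, short_max = 1000),
    synteny = list(max_between = 5, evalue_max = 1e-5,
                   fc_min_hc = 10, len_max_hc = 1000, k_select = 9),
    umr = list(tile_size = 100, min_cytosines = 2, min_coverage = 5,
               max_level = 0.10, max_missing_frac = 1/3, min_span = 300,
               missing_rule = "or"),
    assay = list(control = "spacer21", alpha = 0.05),
    out_dir = NULL,
    seed = 1L
  )
}

#' Validate and normalize a pipeline configuration
#'
#' Accepts a nested list (sections `inputs`, `miner`, `synteny`, `umr`,
#' `assay`, plus `out_dir` and `seed`) or the path of a YAML file with the
#' same structure. Missing keys are filled with documented defaults;
#' unknown keys and out-of-bounds parameters are errors.
#'
#' @param config nested list or YAML file path. `NULL` yields all defaults.
#' @return The normalized configuration list.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (is.null(config)) config <- list()
  stopifnot(is.list(config))
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- defaults
  for (sec in names(config)) {
    if (is.list(defaults[[sec]])) {
      bad <- setdiff(names(config[[sec]]), names(defaults[[sec]]))
      if (length(bad) > 0) {
        stop("unknown key(s) in '", sec, "': ", paste(bad, collapse = ", "))
      }
      cfg[[sec]][names(config[[sec]])] <- config[[sec]]
    } else {
      cfg[[sec]] <- config[[sec]]
    }
  }
  m <- cfg$miner
  do.call(miner_params, m)  # bounds checks
  s <- cfg$synteny
  if (s$max_between < 0) stop("max_between must be >= 0")
  if (s$evalue_max <= 0) stop("evalue_max must be > 0")
  if (s$k_select < 1) stop("k_select must be >= 1")
  u <- cfg$umr
  if (u$tile_size < 1) stop("tile_size must be >= 1")
  if (u$max_level <= 0 || u$max_level > 1) stop("max_level must be in (0, 1]")
  if (u$max_missing_frac < 0 || u$max_missing_frac > 1) {
    stop("max_missing_frac must be in [0, 1]")
  }
  if (!u$missing_rule %in% c("or", "and")) {
    stop("missing_rule must be 'or' or 'and'")
  }
  if (cfg$assay$alpha <= 0 || cfg$assay$alpha >= 1) {
    stop("alpha must be in (0, 1)")
  }
  cfg
}

#' Run the full candidate-mining pipeline
#'
#' Stages run in order: candidate mining (always; needs annotation +
#' expression inputs), microsynteny (when hit tables and subject
#' annotations are configured), UMR calling and overlap (when an allc path
#' is configured), reporter assay (when an assay path is configured).
#' Stages without inputs are skipped cleanly and marked so in the report.
#'
#' @param config configuration list or YAML path; see [validate_config()].
#' @return The summary report (a nested list, also written as
#'   `report.json` plus per-stage TSV/BED files when `out_dir` is set).
#'   Every percentage in the report is accompanied by its numerator and
#'   denominator, and every threshold used is echoed under `parameters`.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  if (is.null(cfg$inputs$annotation)) {
    stop("stage miner: annotation input is required")
  }
  out_dir <- cfg$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(df, name) {
    if (!is.null(out_dir)) {
      write.table(df, file.path(out_dir, name), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
  }
  report <- list(parameters = cfg[c("miner", "synteny", "umr", "assay")],
                 seed = cfg$seed)

  ## miner
  message("[miner] reading gene models")
  index <- read_gene_models(cfg$inputs$annotation, cfg$inputs$expression)
  params <- do.call(miner_params, cfg$miner)
  regions <- extract_intergenic(index)
  cands <- call_candidates(regions, index, params)
  passing <- cands[cands$passes_core_filter, , drop = FALSE]
  short <- filter_short(cands, params$short_max)
  n_div <- sum(passing$orientation == "divergent")
  n_conv <- sum(passing$orientation == "convergent")
  report$candidates <- list(
    n_genes = nrow(index$genes),
    n_intergenic = nrow(regions),
    n_passing = nrow(passing),
    n_divergent = n_div,
    n_convergent = n_conv,
    n_short = nrow(short),
    short_pct = pct1(nrow(short), nrow(passing))
  )
  stopifnot(n_div + n_conv == nrow(passing))
  emit(cands, "candidates.tsv")
  if (!is.null(out_dir)) {
    bed <- passing
    bed$name <- bed$region_id
    bed$score <- bed$fold_change
    write_bed(bed, file.path(out_dir, "candidates.bed"))
  }
  message(sprintf("[miner] %d intergenic regions, %d passing (%d divergent, %d convergent)",
                  nrow(regions), nrow(passing), n_div, n_conv))

  ## synteny
  if (!is.null(cfg$inputs$hits)) {
    message("[synteny] scanning ", length(cfg$inputs$hits), " subject genome(s)")
    sub_paths <- cfg$inputs$subject_annotations
    if (is.null(sub_paths) ||
        !identical(sort(names(sub_paths)), sort(names(cfg$inputs$hits)))) {
      stop("stage synteny: subject_annotations must name the same genomes as hits")
    }
    subs <- lapply(names(sub_paths), function(g) {
      read_gene_models(sub_paths[[g]], genome_id = g)
    })
    names(subs) <- names(sub_paths)
    hits <- lapply(names(cfg$inputs$hits), function(g) {
      read_ortholog_hits(cfg$inputs$hits[[g]],
                         evalue_max = cfg$synteny$evalue_max,
                         subject_index = subs[[g]])
    })
    names(hits) <- names(cfg$inputs$hits)
    syn <- build_matrix(passing, index, subs, hits,
                        max_between = cfg$synteny$max_between)
    hc <- high_confidence(passing, syn, fc_min = cfg$synteny$fc_min_hc,
                          len_max = cfg$synteny$len_max_hc)
    sel <- select_for_validation(passing, syn, k = cfg$synteny$k_select)
    report$synteny <- list(
      n_syntenic = hc$n_syntenic,
      per_genome_syntenic = as.list(syn$per_genome_syntenic),
      n_high_confidence = hc$n,
      high_confidence_pct = hc$pct_of_syntenic
    )
    emit(syn$calls, "synteny_calls.tsv")
    emit(data.frame(region_id = rownames(syn$matrix), syn$matrix,
                    check.names = FALSE), "synteny_matrix.tsv")
    emit(sel$by_fold_change, "shortlist_fold_change.tsv")
    emit(sel$by_breadth, "shortlist_breadth.tsv")
    message(sprintf("[synteny] %d syntenic, %d high confidence (%.1f%%)",
                    hc$n_syntenic, hc$n,
                    ifelse(is.na(hc$pct_of_syntenic), 0, hc$pct_of_syntenic)))
  } else {
    report$synteny <- "skipped"
  }

  ## methylome / UMR
  if (!is.null(cfg$inputs$allc)) {
    message("[umr] tiling methylome")
    sites <- read_allc(cfg$inputs$allc)
    seqlens <- cfg$inputs$seqlens
    if (!is.null(seqlens)) seqlens <- unlist(seqlens)
    u <- cfg$umr
    tiles <- tile_methylome(sites, tile_size = u$tile_size,
                            seqlens = seqlens,
                            min_cytosines = u$min_cytosines,
                            min_coverage = u$min_coverage,
                            max_level = u$max_level,
                            missing_rule = u$missing_rule)
    umrs <- merge_umrs(tiles, min_span = u$min_span,
                       max_missing_frac = u$max_missing_frac)
    lev <- global_levels(sites)
    ov <- overlap_candidates(passing, umrs)
    report$methylation <- list(
      global_levels = lev,
      n_umrs = nrow(umrs),
      mean_umr_length = ov$mean_umr_length,
      mean_candidate_length = ov$mean_candidate_length,
      n_overlapping = ov$n_overlapping,
      n_candidates = ov$n_candidates,
      overlap_pct = ov$pct
    )
    emit(umrs, "umrs.tsv")
    if (!is.null(out_dir)) {
      bed <- umrs
      bed$name <- sprintf("UMR%04d", seq_len(nrow(umrs)))
      write_bed(bed, file.path(out_dir, "umrs.bed"))
    }
    message(sprintf("[umr] %d UMRs; %d/%d candidates overlap (%.1f%%)",
                    nrow(umrs), ov$n_overlapping, ov$n_candidates,
                    ifelse(is.na(ov$pct), 0, ov$pct)))
  } else {
    report$methylation <- "skipped"
  }

  ## reporter assay
  if (!is.null(cfg$inputs$assay)) {
    message("[assay] computing reporter statistics")
    records <- read_assay(cfg$inputs$assay)
    rt <- ratios(records)
    summ <- fold_change_vs_control(rt$summary, control = cfg$assay$control)
    grp <- compare_groups(rt$per_replicate, alpha = cfg$assay$alpha)
    summ$letters <- grp$letters$letters[match(summ$construct_id,
                                              grp$letters$construct_id)]
    report$assay <- list(
      control = cfg$assay$control,
      anova_p = grp$anova_p,
      constructs = summ
    )
    emit(summ, "assay_summary.tsv")
    message(sprintf("[assay] %d constructs, ANOVA p = %.3g",
                    nrow(summ), grp$anova_p))
  } else {
    report$assay <- "skipped"
  }

  if (!is.null(out_dir)) {
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows", force = TRUE)
  }
  report
}
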