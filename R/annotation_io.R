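#' @importFrom utils read.delim write.table head
#' @importFrom stats setNames
NULL

# Internal coordinate model: 0-based half-open [start, end) everywhere.
# GFF3 I/O converts at the boundary (GFF3 is 1-based inclusive).

#' Build a genome index from a gene table
#'
#' A genome index is the shared container for all pair logic: a table of gene
#' models (one row per gene) sorted by position within each sequence, with a
#' positional rank assigned per sequence. Coordinates are 0-based half-open.
#'
#' @param genes data.frame with columns `gene_id`, `seqid`, `start`, `end`,
#'   `strand` and optionally `fpkm` (defaults to 0).
#' @param genome_id identifier for the genome the genes belong to.
#' @return An object of class `genome_index`: a list with elements
#'   `genome_id` and `genes` (the validated table with an added integer
#'   `rank` column, 0-based within each `seqid`).
#' @details Sorting is by `start`, ties broken by `end` then `gene_id`, so
#'   ranks are reproducible. Invalid coordinates (`start < 0` or
#'   `start >= end`), strands outside `{+,-}`, negative FPKM and duplicated
#'   gene ids are hard errors.
#' @export
genome_index <- function(genes, genome_id = "genome") {
  stopifnot(is.data.frame(genes))
  required <- c("gene_id", "seqid", "start", "end", "strand")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols) > 0) {
    stop("gene table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(genes$fpkm)) genes$fpkm <- 0
  genes <- genes[, c(required, "fpkm")]
  genes$gene_id <- as.character(genes$gene_id)
  genes$seqid <- as.character(genes$seqid)
  genes$strand <- as.character(genes$strand)
  genes$start <- as.numeric(genes$start)
  genes$end <- as.numeric(genes$end)
  genes$fpkm <- as.numeric(genes$fpkm)

  bad <- which(is.na(genes$start) | is.na(genes$end) |
                 genes$start < 0 | genes$start >= genes$end)
  if (length(bad) > 0) {
    stop("invalid coordinates for gene(s): ",
         paste(genes$gene_id[head(bad, 5)], collapse = ", "))
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'")
  }
  if (any(is.na(genes$fpkm) | genes$fpkm < 0)) {
    stop("fpkm must be non-negative")
  }
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup) > 0) {
    stop("duplicate gene_id: ", paste(unique(dup), collapse = ", "))
  }

  ord <- order(genes$seqid, genes$start, genes$end, genes$gene_id)
  genes <- genes[ord, , drop = FALSE]
  genes$rank <- NA_integer_
  for (sq in unique(genes$seqid)) {
    idx <- which(genes$seqid == sq)
    genes$rank[idx] <- seq_along(idx) - 1L
  }
  rownames(genes) <- NULL
  structure(list(genome_id = genome_id, genes = genes),
            class = "genome_index")
}

#' @export
print.genome_index <- function(x, ...) {
  cat(sprintf("<genome_index> %s: %d genes on %d sequence(s)\n",
              x$genome_id, nrow(x$genes), length(unique(x$genes$seqid))))
  invisible(x)
}

#' Read gene models and expression values into a genome index
#'
#' Reads gene models from GFF3 (via rtracklayer) or from a plain TSV already
#' in the internal 0-based half-open convention, attaches one FPKM value per
#' gene from an expression table, and returns a [genome_index()].
#'
#' @param path GFF3 file (`.gff`/`.gff3`) or TSV with columns
#'   `gene_id`, `seqid`, `start`, `end`, `strand` (0-based half-open).
#' @param expression_path optional TSV with header; must contain `gene_id`
#'   plus either a single `fpkm` column or several numeric tissue columns.
#' @param feature_type GFF3 feature type to keep (default `"gene"`).
#' @param genome_id identifier stored in the index.
#' @param aggregate how to collapse multiple tissue columns into one FPKM
#'   (default [max]); ignored when a single `fpkm` column is present.
#' @return A `genome_index`.
#' @details Genes absent from a provided expression table are kept with
#'   `fpkm = 0` (a warning is raised per missing gene) so that the
#'   intergenic interval structure is preserved; with no expression table
#'   all genes get `fpkm = 0` silently. GFF3 1-based inclusive coordinates are converted
#'   to 0-based half-open at this boundary.
#' @export
read_gene_models <- function(path, expression_path = NULL,
                             feature_type = "gene", genome_id = "genome",
                             aggregate = max) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[as.character(gr$type) == feature_type]
    if (length(gr) == 0) stop("no '", feature_type, "' features in ", path)
    ids <- as.character(gr$ID)
    if (anyNA(ids)) ids[is.na(ids)] <- as.character(gr$Name)[is.na(ids)]
    if (anyNA(ids)) stop("gene feature without ID attribute in ", path)
    genes <- data.frame(
      gene_id = ids,
      seqid = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,  # 1-based incl -> 0-based half-open
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      stringsAsFactors = FALSE
    )
    if (any(genes$strand == "*")) {
      stop("unstranded gene feature(s) in ", path)
    }
  } else {
    genes <- read.delim(path, stringsAsFactors = FALSE)
  }
  if (is.null(expression_path)) {
    genes$fpkm <- 0
  } else {
    fpkm <- read_expression(expression_path, aggregate = aggregate)
    hit <- match(genes$gene_id, fpkm$gene_id)
    genes$fpkm <- fpkm$fpkm[hit]
    for (g in genes$gene_id[is.na(hit)]) {
      warning("no expression value for gene '", g, "'; using fpkm = 0",
              call. = FALSE)
    }
    genes$fpkm[is.na(hit)] <- 0
  }
  genome_index(genes, genome_id = genome_id)
}

# Expression table reader: gene_id + fpkm, or gene_id + tissue columns
# collapsed with `aggregate` (default max across tissues).
read_expression <- function(path, aggregate = max) {
  if (is.null(path)) {
    return(data.frame(gene_id = character(0), fpkm = numeric(0)))
  }
  if (!file.exists(path)) stop("expression file not found: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(tab)) stop("expression table needs a gene_id column")
  if ("fpkm" %in% names(tab)) {
    vals <- as.numeric(tab$fpkm)
  } else {
    value_cols <- setdiff(names(tab), "gene_id")
    if (length(value_cols) == 0) stop("expression table has no value columns")
    vals <- apply(as.matrix(tab[, value_cols, drop = FALSE]), 1,
                  function(r) aggregate(as.numeric(r)))
  }
  if (anyNA(vals)) stop("non-numeric FPKM value in expression table")
  data.frame(gene_id = as.character(tab$gene_id), fpkm = vals,
             stringsAsFactors = FALSE)
}

#' Write a genome index as GFF3 plus an expression TSV
#'
#' The inverse of [read_gene_models()]: internal 0-based half-open
#' coordinates are converted back to GFF3 1-based inclusive.
#'
#' @param index a `genome_index`.
#' @param gff_path output GFF3 path.
#' @param expression_path optional output TSV path (`gene_id`, `fpkm`).
#' @return Invisibly, `gff_path`.
#' @export
write_gene_models <- function(index, gff_path, expression_path = NULL) {
  stopifnot(inherits(index, "genome_index"))
  g <- index$genes
  gr <- GenomicRanges::GRanges(
    seqnames = g$seqid,
    ranges = IRanges::IRanges(start = g$start + 1L, end = g$end),
    strand = g$strand
  )
  gr$source <- "insulatr"
  gr$type <- "gene"
  gr$ID <- g$gene_id
  rtracklayer::export(gr, gff_path, format = "gff3")
  if (!is.null(expression_path)) {
    write.table(g[, c("gene_id", "fpkm")], expression_path,
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(gff_path)
}

#' Write located intervals as BED6
#'
#' @param regions data.frame with `seqid`, `start`, `end` (0-based half-open)
#'   and optionally `name`/`region_id`, `score` (fold change; 0 when
#'   undefined) and `strand` (defaults to `"."` for intergenic regions).
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(regions, path) {
  stopifnot(is.data.frame(regions))
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (nrow(regions) == 0) return(invisible(path))
  if (any(regions$start < 0 | regions$end < regions$start)) {
    stop("invalid interval in BED output")
  }
  name <- if (!is.null(regions$name)) regions$name
          else if (!is.null(regions$region_id)) regions$region_id
          else sprintf("region%04d", seq_len(nrow(regions)))
  score <- if (!is.null(regions$score)) regions$score else 0
  score[!is.finite(score)] <- 0
  strand <- if (!is.null(regions$strand)) regions$strand else "."
  bed <- data.frame(regions$seqid, format(regions$start, scientific = FALSE, trim = TRUE),
                    format(regions$end, scientific = FALSE, trim = TRUE),
                    name, score, strand)
  write.table(bed, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 file back into an interval table
#'
#' @param path BED file written by [write_bed()] (or any BED6).
#' @return data.frame with `seqid`, `start`, `end`, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0) {
    return(data.frame(seqid = character(0), start = numeric(0),
                      end = numeric(0), name = character(0),
                      score = numeric(0), strand = character(0)))
  }
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(tab)[1:6] <- c("seqid", "start", "end", "name", "score", "strand")
  tab[, 1:6]
}

#' Read a BLAST tabular (outfmt 6) ortholog hit table
#'
#' @param path 12-column tab-separated BLAST output: qseqid, sseqid, pident,
#'   length, mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore.
#' @param evalue_max inclusive e-value cutoff; hits with larger e-values are
#'   dropped (default `1e-5`).
#' @param subject_index optional `genome_index` for the subject genome; hits
#'   whose subject gene is absent from it are dropped with a warning.
#' @return data.frame with `query_gene_id`, `subject_gene_id`, `evalue`,
#'   `bitscore`, sorted as read.
#' @export
read_ortholog_hits <- function(path, evalue_max = 1e-5, subject_index = NULL) {
  if (!file.exists(path)) stop("hit table not found: ", path)
  if (file.size(path) == 0) {
    return(data.frame(query_gene_id = character(0),
                      subject_gene_id = character(0),
                      evalue = numeric(0), bitscore = numeric(0)))
  }
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  if (ncol(tab) < 12) stop("expected >= 12 BLAST outfmt-6 columns in ", path)
  ev <- suppressWarnings(as.numeric(tab[[11]]))
  if (anyNA(ev)) {
    stop("non-numeric evalue at line ", which(is.na(ev))[1], " of ", path)
  }
  hits <- data.frame(query_gene_id = tab[[1]], subject_gene_id = tab[[2]],
                     evalue = ev,
                     bitscore = suppressWarnings(as.numeric(tab[[12]])),
                     stringsAsFactors = FALSE)
  hits <- hits[hits$evalue <= evalue_max, , drop = FALSE]
  if (!is.null(subject_index)) {
    known <- hits$subject_gene_id %in% subject_index$genes$gene_id
    if (any(!known)) {
      warning(sum(!known), " hit(s) reference unknown subject genes; dropped",
              call. = FALSE)
    }
    hits <- hits[known, , drop = FALSE]
  }
  rownames(hits) <- NULL
  hits
}

# Percentage with 1 decimal, the rounding used in all reports.
pct1 <- function(num, den) {
  if (den == 0) return(NA_real_)
  round(100 * num / den, 1)
}
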