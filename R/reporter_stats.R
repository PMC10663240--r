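# Dual-reporter (GFP:mCherry) assay statistics: per-replicate ratios,
# construct summaries, fold change versus the 21-bp spacer control, and
# ANOVA + Tukey-HSD group letters.

#' Per-replicate reporter ratios and construct summaries
#'
#' @param records data.frame with `construct_id`, `replicate`, `gfp`,
#'   `mcherry` (relative fluorescence units, both non-negative).
#' @return list: `per_replicate` (the records with a `ratio = gfp/mcherry`
#'   column, replicates with `mcherry == 0` excluded) and `summary`
#'   (per construct: `n`, `mean_ratio`, `sd_ratio`).
#' @details Replicates with zero mCherry signal have no defined ratio and
#'   are dropped with a warning; a construct left with no usable replicate
#'   is an error. Ratios are GFP/mCherry throughout, matching the fold
#'   change formula's convention.
#' @export
ratios <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("construct_id", "replicate", "gfp", "mcherry") %in%
                  names(records)))
  if (any(records$gfp < 0 | records$mcherry < 0)) {
    stop("fluorescence readings must be non-negative")
  }
  zero <- records$mcherry == 0
  if (any(zero)) {
    warning(sum(zero), " replicate(s) with mcherry = 0 excluded",
            call. = FALSE)
  }
  usable <- records[!zero, , drop = FALSE]
  lost <- setdiff(unique(records$construct_id), unique(usable$construct_id))
  if (length(lost) > 0) {
    stop("construct(s) without usable replicates: ",
         paste(lost, collapse = ", "))
  }
  usable$ratio <- usable$gfp / usable$mcherry
  spl <- split(usable$ratio, usable$construct_id)
  summary <- data.frame(
    construct_id = names(spl),
    n = vapply(spl, length, integer(1)),
    mean_ratio = vapply(spl, mean, numeric(1)),
    sd_ratio = vapply(spl, stats::sd, numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(summary) <- NULL
  list(per_replicate = usable, summary = summary)
}

#' Fold change of each construct versus the spacer control
#'
#' The insulator-screening statistic: for construct i with mean
#' GFP:mCherry ratio \eqn{r_i} and control mean ratio \eqn{r_0},
#' \deqn{FC_i = (r_i - r_0) / r_0.}
#' A construct behaving exactly like the bare 21-bp spacer has FC 0; an
#' insulator that silences GFP completely has FC -1.
#'
#' @param summary construct summary from [ratios()].
#' @param control construct id of the minimal-spacer control
#'   (default `"spacer21"`).
#' @return `summary` with an `fc` column (the control row has `fc = 0`).
#' @export
fold_change_vs_control <- function(summary, control = "spacer21") {
  i <- which(summary$construct_id == control)
  if (length(i) != 1) stop("control construct '", control, "' not found")
  r0 <- summary$mean_ratio[i]
  if (!(r0 > 0)) stop("control mean ratio must be positive")
  summary$fc <- (summary$mean_ratio - r0) / r0
  summary
}

#' Compare constructs by one-way ANOVA with Tukey-HSD letters
#'
#' Fits a one-way ANOVA of per-replicate ratios on construct, runs all-pairs
#' Tukey HSD at `alpha`, and derives a compact letter display: two
#' constructs share no letter iff their Tukey comparison is significant.
#'
#' @param per_replicate per-replicate ratio table from [ratios()].
#' @param alpha familywise significance level (default 0.05).
#' @return list: `letters` (data.frame `construct_id`, `mean_ratio`,
#'   `letters`, ordered by mean descending), `anova_p`, `tukey`
#'   (the Tukey p-value matrix).
#' @export
compare_groups <- function(per_replicate, alpha = 0.05) {
  d <- per_replicate
  d$construct_id <- factor(d$construct_id)
  if (nlevels(d$construct_id) < 2) stop("need at least 2 constructs")
  if (any(table(d$construct_id) < 2)) {
    stop("need at least 2 replicates per construct")
  }
  fit <- stats::aov(ratio ~ construct_id, data = d)
  anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$construct_id
  groups <- levels(d$construct_id)
  pmat <- matrix(1, length(groups), length(groups),
                 dimnames = list(groups, groups))
  cmp <- strsplit(rownames(tk), "-", fixed = TRUE)
  for (i in seq_along(cmp)) {
    a <- cmp[[i]][1]; b <- cmp[[i]][2]
    pmat[a, b] <- pmat[b, a] <- tk[i, "p adj"]
  }
  means <- tapply(d$ratio, d$construct_id, mean)
  letters <- letter_display(pmat < alpha, means)
  out <- data.frame(construct_id = names(means),
                    mean_ratio = as.numeric(means),
                    letters = letters[names(means)],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mean_ratio, out$construct_id), ]
  rownames(out) <- NULL
  list(letters = out, anova_p = anova_p, tukey = pmat)
}

# Compact letter display by insert-and-absorb over the significance graph:
# start from one set holding all groups; for each significant pair split
# every set containing both; absorb sets contained in others. Letters are
# assigned to sets ordered by their best (largest) member mean, so output
# is deterministic.
letter_display <- function(signif_mat, means) {
  groups <- rownames(signif_mat)
  sets <- list(groups)
  pairs <- which(signif_mat & upper.tri(signif_mat), arr.ind = TRUE)
  for (p in seq_len(nrow(pairs))) {
    a <- groups[pairs[p, 1]]; b <- groups[pairs[p, 2]]
    new_sets <- list()
    for (s in sets) {
      if (a %in% s && b %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, a)), list(setdiff(s, b)))
      } else {
        new_sets <- c(new_sets, list(s))
      }
    }
    new_sets <- new_sets[lengths(new_sets) > 0]
    new_sets <- unique(lapply(new_sets, sort))
    # absorb: drop sets strictly contained in another
    keep <- vapply(seq_along(new_sets), function(i) {
      !any(vapply(seq_along(new_sets), function(j) {
        length(new_sets[[i]]) < length(new_sets[[j]]) &&
          all(new_sets[[i]] %in% new_sets[[j]])
      }, logical(1)))
    }, logical(1))
    sets <- new_sets[keep]
  }
  best <- vapply(sets, function(s) max(means[s]), numeric(1))
  sets <- sets[order(-best, vapply(sets, function(s) sort(s)[1],
                                   character(1)))]
  out <- setNames(rep("", length(groups)), groups)
  for (k in seq_along(sets)) {
    for (g in sets[[k]]) out[g] <- paste0(out[g], letters[k])
  }
  out
}
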