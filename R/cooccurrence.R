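# Area-normalized strain occurrence in blocked vs open flow regions, and
# the replicate-level pooled t-tests with Bonferroni correction.

#' Area-normalized occurrence of each strain by flow class
#'
#' For each strain and flow class (open/blocked), the occurrence frequency
#' is the effective area of regions in that class occupied by the strain,
#' divided by the total effective area of the class, so frequencies are
#' normalized to the total area of blocked versus open flow.  A
#' \code{"count"} weighting (region counts instead of areas) is available
#' for sensitivity analysis.
#'
#' @param calls data.frame with columns \code{flow} ("open"/"blocked"),
#'   \code{wt_call}, \code{mut_call} (logical) and \code{area_um2}; the
#'   per-region call table from [analyzeChamberImages()] or a ground truth
#'   joined with areas.
#' @param weighting \code{"area"} (default) or \code{"count"}.
#' @return data.frame with one row per strain x flow class:
#'   \code{strain}, \code{flow_class}, \code{area_occupied_um2},
#'   \code{area_total_um2}, \code{frequency}.  A class with zero total area
#'   gets \code{frequency = NA}.
#' @export
occurrenceByFlowClass <- function(calls, weighting = c("area", "count")) {
  weighting <- match.arg(weighting)
  need <- c("flow", "wt_call", "mut_call", "area_um2")
  if (!is.data.frame(calls) || !all(need %in% names(calls)))
    stop("'calls' must contain columns ", paste(need, collapse = ", "),
         call. = FALSE)
  flow <- as.character(calls$flow)
  if (!all(flow %in% c("open", "blocked")))
    stop("flow calls must be 'open' or 'blocked'", call. = FALSE)
  w <- if (weighting == "area") calls$area_um2 else rep(1, nrow(calls))
  grid <- expand.grid(strain = c("wt", "mutant"),
                      flow_class = c("open", "blocked"),
                      stringsAsFactors = FALSE)
  occ <- list(wt = calls$wt_call, mutant = calls$mut_call)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    cls <- flow == grid$flow_class[i]
    tot <- sum(w[cls])
    occA <- sum(w[cls & occ[[grid$strain[i]]]])
    data.frame(strain = grid$strain[i], flow_class = grid$flow_class[i],
               area_occupied_um2 = occA, area_total_um2 = tot,
               frequency = if (tot > 0) occA / tot else NA_real_)
  })
  do.call(rbind, res)
}

#' Pooled-variance two-sample t-test
#'
#' Two-tailed two-sample t-test with pooled variance and
#' df = n1 + n2 - 2, matching the convention used for replicate-level
#' occurrence and growth-rate comparisons.  Degenerate samples with zero
#' pooled variance give t = 0, p = 1 when the means are equal and an
#' infinite t (p = 0) otherwise.
#'
#' @param x,y numeric samples with at least 2 finite values each.
#' @return list with \code{t}, \code{df}, \code{p}.
#' @examples
#' pooledTwoSampleT(c(1, 2, 3), c(4, 5, 6))
#' @export
pooledTwoSampleT <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L)
    stop("both samples need at least 2 finite values", call. = FALSE)
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / df
  delta <- mean(x) - mean(y)
  if (sp2 <= 0) {
    if (delta == 0) return(list(t = 0, df = df, p = 1))
    return(list(t = sign(delta) * Inf, df = df, p = 0))
  }
  t <- delta / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Bonferroni significance flags
#'
#' Flags p-values significant at a family-wise level \code{alpha} corrected
#' for \code{length(p)} comparisons: flag_i = (p_i < alpha / m).
#'
#' @param p numeric p-values in \[0, 1\].
#' @param alpha family-wise error level in (0, 1).
#' @return logical vector of significance flags.
#' @export
bonferroniFlags <- function(p, alpha = 0.05) {
  if (!length(p)) stop("'p' must be non-empty", call. = FALSE)
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("all p-values must lie in [0, 1]", call. = FALSE)
  assertScalarNum(alpha, "alpha", lower = 0, upper = 1, strictLower = TRUE)
  p < alpha / length(p)
}

#' Replicate-level co-occurrence test
#'
#' For each strain, compares its occurrence frequency in blocked regions
#' against open regions across replicate chambers with a pooled two-sample
#' t-test, then applies Bonferroni correction over the two strain
#' comparisons.  Replicates with an undefined class frequency (zero class
#' area) are dropped from the corresponding test.
#'
#' @param summaries data.frame of stacked per-replicate occurrence
#'   summaries (from [occurrenceByFlowClass()] with a \code{replicate}
#'   column, or [simulateOccurrenceExperiment()]).
#' @param alpha family-wise significance level.
#' @return data.frame with one row per strain: \code{strain}, \code{t},
#'   \code{df}, \code{p}, \code{significant},
#'   \code{mean_blocked}, \code{mean_open}.
#' @export
cooccurrenceTest <- function(summaries, alpha = 0.05) {
  need <- c("replicate", "strain", "flow_class", "frequency")
  if (!all(need %in% names(summaries)))
    stop("'summaries' must contain ", paste(need, collapse = ", "),
         call. = FALSE)
  strains <- c("wt", "mutant")
  rows <- lapply(strains, function(s) {
    sub <- summaries[summaries$strain == s, ]
    bl <- sub$frequency[sub$flow_class == "blocked"]
    op <- sub$frequency[sub$flow_class == "open"]
    tt <- pooledTwoSampleT(bl, op)
    data.frame(strain = s, t = tt$t, df = tt$df, p = tt$p,
               mean_blocked = mean(bl, na.rm = TRUE),
               mean_open = mean(op, na.rm = TRUE))
  })
  out <- do.call(rbind, rows)
  out$significant <- bonferroniFlags(out$p, alpha)
  out[, c("strain", "t", "df", "p", "significant", "mean_blocked",
          "mean_open")]
}
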