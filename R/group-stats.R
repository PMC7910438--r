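#' Pairwise Wilcoxon comparisons with compact letter display
#'
#' All pairwise two-tailed Wilcoxon tests between groups — signed-rank when
#' `paired`, rank-sum otherwise — with Benjamini-Hochberg adjustment across
#' the pairwise family and a compact letter display at `alpha`. Exact p
#' values are used for group sizes below 25 without ties; otherwise the
#' normal approximation with continuity correction.
#'
#' @param values Numeric vector of responses.
#' @param groups Factor or character vector of group labels.
#' @param paired Use the paired signed-rank test? Requires equal group
#'   sizes with replicates aligned by position within group.
#' @param alpha Significance level for the letter display (default 0.05).
#' @return A list with `comparisons` (data.frame: group1, group2,
#'   statistic, p_raw, p_adj) and `letters` (named character vector, one
#'   label per group; groups sharing no letter differ significantly).
#' @examples
#' set.seed(1)
#' compareGroups(c(rnorm(8), rnorm(8, 5)), rep(c("a", "b"), each = 8))
#' @export
compareGroups <- function(values, groups, paired = FALSE, alpha = 0.05) {
  groups <- as.character(groups)
  gl <- unique(groups)
  if (length(gl) < 2) stop("at least two groups required")
  splitv <- split(values, factor(groups, levels = gl))
  if (any(lengths(splitv) < 2)) stop("each group needs at least 2 values")
  if (paired && length(unique(lengths(splitv))) != 1)
    stop("paired comparisons require equal group sizes")
  pairs <- utils::combn(gl, 2)
  res <- apply(pairs, 2, function(p) {
    x <- splitv[[p[1]]]; y <- splitv[[p[2]]]
    exact <- length(x) < 25 && length(y) < 25 &&
      !any(duplicated(if (paired) x - y else c(x, y)))
    wt <- suppressWarnings(stats::wilcox.test(
      x, y, paired = paired, exact = exact, correct = TRUE,
      alternative = "two.sided"))
    c(statistic = unname(wt$statistic), p = wt$p.value)
  })
  comparisons <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                            statistic = res["statistic", ],
                            p_raw = res["p", ],
                            p_adj = stats::p.adjust(res["p", ],
                                                    method = "BH"))
  letters <- compactLetterDisplay(gl, comparisons$group1,
                                  comparisons$group2,
                                  comparisons$p_adj < alpha)
  list(comparisons = comparisons, letters = letters)
}

#' Compact letter display by insert-absorb
#'
#' Assigns letters to groups so that two groups share a letter if and only
#' if they were not declared significantly different. Implements the
#' insert-and-absorb heuristic: start from one column holding all groups;
#' for every significant pair found together in a column, split the column
#' into two (each lacking one member of the pair) and absorb columns that
#' became subsets of others.
#'
#' @param groups Character vector of group names.
#' @param group1,group2 Pair columns.
#' @param significant Logical vector, one per pair.
#' @return Named character vector of letter labels.
#' @export
compactLetterDisplay <- function(groups, group1, group2, significant) {
  cols <- list(groups)
  for (k in which(significant)) {
    a <- group1[k]; b <- group2[k]
    hit <- which(vapply(cols, function(cl) a %in% cl && b %in% cl,
                        logical(1)))
    for (h in hit) {
      cl <- cols[[h]]
      cols[[h]] <- setdiff(cl, a)
      cols <- c(cols, list(setdiff(cl, b)))
    }
    ## absorb: drop columns contained in another column
    keep <- rep(TRUE, length(cols))
    for (i in seq_along(cols)) for (j in seq_along(cols))
      if (i != j && keep[i] && keep[j] &&
          all(cols[[i]] %in% cols[[j]]) &&
          !(all(cols[[j]] %in% cols[[i]]) && i < j))
        keep[i] <- FALSE
    cols <- cols[keep]
  }
  cols <- cols[order(vapply(cols, function(cl)
    min(match(cl, groups)), numeric(1)))]
  out <- stats::setNames(rep("", length(groups)), groups)
  for (i in seq_along(cols))
    out[cols[[i]]] <- paste0(out[cols[[i]]], letters[i])
  out
}

#' Boxplot summary statistics
#'
#' Median and quartiles by linear interpolation (quantile type 7), with
#' whiskers at the most extreme data points within 1.5 interquartile ranges
#' of the quartiles.
#'
#' @param x Numeric vector.
#' @return A one-row data.frame: `n`, `median`, `q1`, `q3`, `whisker_lo`,
#'   `whisker_hi`.
#' @examples
#' boxplotStats(1:7)
#' @export
boxplotStats <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x))
    return(data.frame(n = 0L, median = NA_real_, q1 = NA_real_,
                      q3 = NA_real_, whisker_lo = NA_real_,
                      whisker_hi = NA_real_))
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo <- min(x[x >= q[1] - 1.5 * iqr])
  hi <- max(x[x <= q[3] + 1.5 * iqr])
  data.frame(n = length(x), median = q[2], q1 = q[1], q3 = q[3],
             whisker_lo = lo, whisker_hi = hi)
}

#' Bin genes by uridylation propensity and compare a response across bins
#'
#' Genes are assigned to uridylation-percentage bins (left-closed,
#' right-open intervals; the last bin is closed on both sides) and the
#' response (e.g. mRNA half-life, or siRNA accumulation) is summarized per
#' bin with boxplot statistics and compared between bins by unpaired
#' two-tailed Wilcoxon tests with BH adjustment.
#'
#' @param geneTable A data.frame with a `uridylation_pct` column and the
#'   response column.
#' @param binEdges Numeric vector of bin edges (length >= 2).
#' @param response Name of the response column (default `"half_life"`).
#' @param alpha Significance level for the letter display.
#' @return A list with `stats` (per-bin boxplot statistics; empty bins are
#'   flagged with `n = 0`), `comparisons` and `letters` (both `NULL` when
#'   fewer than two bins are populated).
#' @export
binByUridylation <- function(geneTable, binEdges,
                             response = "half_life", alpha = 0.05) {
  stopifnot("uridylation_pct" %in% names(geneTable),
            response %in% names(geneTable), length(binEdges) >= 2)
  u <- geneTable$uridylation_pct
  bin <- cut(u, breaks = binEdges, right = FALSE,
             include.lowest = FALSE)
  ## close the final bin on the right
  lastEdge <- binEdges[length(binEdges)]
  bin[u == lastEdge] <- levels(bin)[nlevels(bin)]
  stats <- do.call(rbind, lapply(levels(bin), function(b)
    cbind(bin = b, boxplotStats(geneTable[[response]][!is.na(bin) &
                                                       bin == b]))))
  populated <- levels(bin)[table(bin)[levels(bin)] >= 2]
  cmp <- NULL; lett <- NULL
  if (length(populated) >= 2) {
    keep <- !is.na(bin) & bin %in% populated
    cg <- compareGroups(geneTable[[response]][keep],
                        as.character(bin[keep]), paired = FALSE,
                        alpha = alpha)
    cmp <- cg$comparisons; lett <- cg$letters
  }
  list(stats = stats, comparisons = cmp, letters = lett)
}
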