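## Nonparametric group comparisons: Kruskal-Wallis omnibus tests, Dunn post
## hoc comparisons with tie correction, Benjamini-Hochberg adjustment, and a
## condition/modality significance grid over an outcome table.

#' Kruskal-Wallis rank sum test
#'
#' Rank-based H statistic with tie correction and a chi-square p-value on
#' k - 1 degrees of freedom (delegates to [stats::kruskal.test()]). Being
#' rank-based, the result is invariant to any monotone transformation of the
#' values.
#'
#' @param values numeric vector.
#' @param groups grouping vector/factor of the same length (>= 2 non-empty
#'   groups).
#' @return list with `H`, `df`, `p`.
#' @export
kruskalWallis <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(droplevels(groups[!is.na(values)])) < 2L)
    stop("need at least 2 non-empty groups")
  ## degenerate case: every observation tied -> no evidence against the null
  if (length(unique(values[!is.na(values)])) == 1L)
    return(list(H = 0, df = nlevels(droplevels(groups)) - 1L, p = 1))
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value)
}

#' Dunn post hoc comparisons with Benjamini-Hochberg adjustment
#'
#' All pairwise Dunn z-statistics on the joint ranks,
#' z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/n_i + 1/n_j))
#' with tie correction T = sum(t^3 - t) over tied groups, two-sided normal
#' p-values, and Benjamini-Hochberg step-up adjustment across the family of
#' pairwise comparisons for this outcome.
#'
#' @param values numeric vector.
#' @param groups grouping vector/factor (>= 2 groups).
#' @return data.frame with `group1`, `group2`, `z`, `p`, `pAdj`.
#' @export
dunnPosthocBH <- function(values, groups) {
  keep <- !is.na(values)
  values <- values[keep]
  groups <- droplevels(factor(groups[keep]))
  k <- nlevels(groups)
  if (k < 2L) stop("need at least 2 groups")
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  ties <- table(values)
  Tcorr <- sum(ties^3 - ties)
  v0 <- N * (N + 1) / 12 - Tcorr / (12 * (N - 1))
  pairs <- utils::combn(levels(groups), 2L)
  z <- p <- numeric(ncol(pairs))
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1L, i]; b <- pairs[2L, i]
    se <- sqrt(v0 * (1 / n[[a]] + 1 / n[[b]]))
    z[i] <- (rbar[[a]] - rbar[[b]]) / se
    p[i] <- 2 * stats::pnorm(-abs(z[i]))
  }
  data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ], z = z, p = p,
             pAdj = stats::p.adjust(p, method = "BH"))
}

.stars <- function(p) {
  if (is.na(p)) return("")
  if (p < 0.001) return("***")
  if (p < 0.01) return("**")
  if (p < 0.05) return("*")
  ""
}

#' Condition/modality significance grid over an outcome table
#'
#' For every outcome column, tests the main effect of lung condition
#' (baseline vs injured, across all rows) and the effect of ventilation
#' modality separately under baseline and injured conditions, each by
#' Kruskal-Wallis at the 0.05 level. For outcomes with a significant
#' modality effect, Dunn post hoc comparisons with Benjamini-Hochberg
#' adjustment (within the outcome's three modality pairs) are attached.
#'
#' @param table data.frame with factor columns `condition` (baseline,
#'   injured) and `modality` (CMV, HFOV, MFOV) plus numeric outcome columns.
#' @param outcomes character vector of outcome column names; defaults to all
#'   numeric columns except identifiers.
#' @param alpha omnibus significance level gating the post hoc step.
#' @return list with `effects`: data.frame (per outcome: p-values and
#'   significance stars for the condition effect and the two
#'   modality-within-condition effects), and `posthoc`: named list of Dunn
#'   tables for outcome x condition cells with a significant modality
#'   effect. Missing cells are tolerated and reported via `nMissing`.
#' @export
buildOutcomeReport <- function(table, outcomes = NULL, alpha = 0.05) {
  stopifnot(all(c("condition", "modality") %in% names(table)))
  if (is.null(outcomes)) {
    num <- vapply(table, is.numeric, logical(1))
    outcomes <- setdiff(names(table)[num], c("subject"))
  }
  posthoc <- list()
  rows <- lapply(outcomes, function(oc) {
    v <- table[[oc]]
    pCond <- tryCatch(kruskalWallis(v, table$condition)$p,
                      error = function(e) NA_real_)
    pMod <- vapply(c("baseline", "injured"), function(cond) {
      i <- table$condition == cond
      tryCatch(kruskalWallis(v[i], table$modality[i])$p,
               error = function(e) NA_real_)
    }, numeric(1))
    for (cond in names(pMod)) {
      if (!is.na(pMod[[cond]]) && pMod[[cond]] < alpha) {
        i <- table$condition == cond
        posthoc[[paste(oc, cond, sep = ".")]] <<-
          dunnPosthocBH(table[[oc]][i], table$modality[i])
      }
    }
    data.frame(outcome = oc, pCondition = pCond,
               starsCondition = .stars(pCond),
               pModalityBaseline = pMod[["baseline"]],
               starsModalityBaseline = .stars(pMod[["baseline"]]),
               pModalityInjured = pMod[["injured"]],
               starsModalityInjured = .stars(pMod[["injured"]]),
               nMissing = sum(is.na(v)))
  })
  list(effects = do.call(rbind, rows), posthoc = posthoc)
}
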