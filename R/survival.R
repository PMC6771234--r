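# Expression coding and survival stratification. Patients receive a binary
# E-code over an ordered gene list (bit = 1 iff expression is strictly
# above the cohort mean for that gene); code groups are compared by
# Kaplan-Meier curves and the log-rank test. The product-limit estimator
# and the log-rank statistic come from the survival package.

#' Construct a CohortTable
#'
#' @param expression nonnegative patients x genes matrix (column names =
#'   gene symbols).
#' @param time positive follow-up times.
#' @param event logical (or 0/1) event indicators.
#' @param patientIds optional ids; defaults to `p1, p2, ...`.
#' @return a [CohortTable-class] (E-codes unset).
#' @export
cohortTable <- function(expression, time, event, patientIds = NULL) {
  expression <- as.matrix(expression)
  if (is.null(patientIds))
    patientIds <- if (!is.null(rownames(expression))) rownames(expression)
                  else paste0("p", seq_len(nrow(expression)))
  new("CohortTable", patientIds = as.character(patientIds),
      expression = expression, time = as.numeric(time),
      event = as.logical(event), ecode = character(0),
      geneOrder = character(0))
}

#' Binarize patient expression into E-codes
#'
#' For each gene in `genes` (in order), a patient's bit is 1 iff their
#' expression is strictly greater than the cohort mean for that gene (a
#' value exactly at the mean codes 0). E.g. with order (FOXA1, NR2F2,
#' GATA3), "110" marks patients with high FOXA1 and NR2F2 but low GATA3.
#'
#' @param cohort a [CohortTable-class].
#' @param genes ordered gene list; all must be expression columns.
#' @return the cohort with `ecode` and `geneOrder` set.
#' @export
encodeExpression <- function(cohort, genes) {
  stopifnot(is(cohort, "CohortTable"))
  missing <- setdiff(genes, colnames(cohort@expression))
  if (length(missing))
    stop("genes not in expression matrix: ", paste(missing, collapse = ", "))
  ex <- cohort@expression[, genes, drop = FALSE]
  sds <- apply(ex, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant expression (zero variance) for gene(s): ",
         paste(genes[sds == 0], collapse = ", "))
  bits <- t(t(ex) > colMeans(ex)) + 0L
  cohort@ecode <- apply(bits, 1L, paste0, collapse = "")
  cohort@geneOrder <- genes
  validObject(cohort)
  cohort
}

#' E-code group sizes with small-group exclusion
#'
#' Groups with fewer than `minGroup` patients are flagged for exclusion
#' from downstream survival comparisons (and listed in a message).
#'
#' @param cohort an encoded [CohortTable-class].
#' @param minGroup minimum group size to keep (default 5).
#' @return list with `counts` (named integer per observed code), `kept`
#'   and `excluded` code vectors.
#' @export
ecodeGroups <- function(cohort, minGroup = 5) {
  if (!length(cohort@ecode)) stop("cohort has no E-codes; run encodeExpression first")
  tab <- table(cohort@ecode)
  counts <- setNames(as.integer(tab), names(tab))
  kept <- names(counts)[counts >= minGroup]
  excluded <- setdiff(names(counts), kept)
  if (length(excluded))
    message("excluding small E-code group(s): ",
            paste(sprintf("%s (n=%d)", excluded, counts[excluded]), collapse = ", "))
  list(counts = counts, kept = kept, excluded = excluded)
}

#' Kaplan-Meier product-limit curve for one group
#'
#' S(t) is the product over event times <= t of (1 - d_i / n_i); censored
#' subjects leave the risk set without contributing a factor. The curve is
#' prepended with S(0) = 1.
#'
#' @param time positive follow-up times.
#' @param event logical (or 0/1) event indicators.
#' @param label group label.
#' @return a [SurvivalCurve-class].
#' @export
kmEstimate <- function(time, event, label = "all") {
  if (!length(time)) stop("need at least one subject")
  fit <- survival::survfit(survival::Surv(time, as.integer(event)) ~ 1,
                           conf.type = "none")
  new("SurvivalCurve", times = c(0, fit$time),
      survival = c(1, fit$surv),
      atRisk = c(length(time), fit$n.risk), label = label)
}

#' Kaplan-Meier curves per kept E-code group
#'
#' @param cohort an encoded [CohortTable-class].
#' @param minGroup minimum group size (see [ecodeGroups]).
#' @return named list of [SurvivalCurve-class], one per kept code.
#' @export
kmByCode <- function(cohort, minGroup = 5) {
  grp <- ecodeGroups(cohort, minGroup)
  setNames(lapply(grp$kept, function(cd) {
    i <- cohort@ecode == cd
    kmEstimate(cohort@time[i], cohort@event[i], label = cd)
  }), grp$kept)
}

#' Log-rank test across groups
#'
#' Chi-square log-rank statistic with (g - 1) degrees of freedom via
#' `survival::survdiff`. A permutation-mode p-value (shuffling group
#' labels) is available as a small-sample alternative.
#'
#' @param time positive follow-up times.
#' @param event logical (or 0/1) event indicators (>= 1 event overall).
#' @param group group labels (>= 2 nonempty groups).
#' @param nPermutations if > 0, also compute a permutation p-value from
#'   this many label shuffles.
#' @param seed RNG seed for the permutations.
#' @return list with `statistic`, `df`, `p_value`, and `p_permutation`
#'   (NA unless requested).
#' @export
logrankTest <- function(time, event, group, nPermutations = 0, seed = 1) {
  group <- as.factor(as.character(group))
  if (nlevels(group) < 2L) stop("need at least 2 nonempty groups")
  event <- as.integer(event)
  if (sum(event) == 0L) stop("no events: log-rank test undefined")
  sd0 <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- nlevels(group) - 1L
  stat <- sd0$chisq
  p <- pchisq(stat, df, lower.tail = FALSE)
  p_perm <- NA_real_
  if (nPermutations > 0) {
    set.seed(seed)
    exceed <- 0L
    for (b in seq_len(nPermutations)) {
      gp <- sample(group)
      sb <- survival::survdiff(survival::Surv(time, event) ~ gp)
      if (sb$chisq >= stat) exceed <- exceed + 1L
    }
    p_perm <- (1 + exceed) / (nPermutations + 1)
  }
  list(statistic = stat, df = df, p_value = p, p_permutation = p_perm)
}
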