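#' Round half-up to one decimal
#' @noRd
round1_half_up <- function(x) floor(x * 10 + 0.5) / 10

#' Session success rate
#'
#' Percentage of correct placements, rounded half-up to one decimal as
#' conventionally printed (e.g. 33/56 -> 58.9, 50/56 -> 89.3).
#'
#' @param correct number of correct placements.
#' @param total session size (> 0).
#' @return percent, one decimal.
#' @export
success_rate <- function(correct, total) {
  if (!is.numeric(total) || total <= 0) stop("total must be > 0")
  if (correct < 0 || correct > total) stop("need 0 <= correct <= total")
  round1_half_up(100 * correct / total)
}

#' Improvement in percentage points between sessions
#'
#' Difference of success proportions (after minus before), computed on the
#' unrounded proportions and then rounded half-up to one decimal.
#'
#' @param before,after length-2 `c(correct, total)` per session.
#' @return percentage points, one decimal.
#' @export
improvement_pp <- function(before, after) {
  if (before[2] != after[2]) stop("sessions must have equal totals")
  if (before[2] <= 0) stop("total must be > 0")
  round1_half_up(100 * (after[1] / after[2] - before[1] / before[2]))
}

#' Paired 2x2 cross table
#'
#' Before/after outcomes of the paired placements: `a` correct in both
#' sessions, `b` incorrect before but correct after, `c` correct before but
#' incorrect after, `d` incorrect in both.
#'
#' @param a,b,c,d non-negative cell counts.
#' @return An object of class `paired_table`.
#' @export
paired_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers")
  structure(list(a = a, b = b, c = c, d = d, n = a + b + c + d),
            class = "paired_table")
}

#' @export
print.paired_table <- function(x, ...) {
  # rows: before; columns: after. a = C/C, b = I/C, c = C/I, d = I/I
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2, byrow = TRUE,
              dimnames = list("before" = c("Correct", "Incorrect"),
                              "after" = c("Correct", "Incorrect")))
  cat("<paired_table> (rows: before, cols: after)\n")
  print(m)
  invisible(x)
}

#' Exact McNemar test for paired proportions
#'
#' Two-sided exact binomial test on the discordant pairs: conditional on
#' `b + c`, `b` is Binomial(b + c, 1/2) under the null of equal marginal
#' proportions; `p = min(1, 2 * min(P(X <= min(b,c)), P(X >= max(b,c))))`,
#' and `p = 1` when there are no discordant pairs.
#'
#' @param table a [paired_table()].
#' @return p-value in (0, 1].
#' @export
mcnemar_exact <- function(table) {
  stopifnot(inherits(table, "paired_table"))
  b <- table$b; cc <- table$c
  n <- b + cc
  if (n == 0) return(1)
  lo <- pbinom(min(b, cc), n, 0.5)
  hi <- pbinom(max(b, cc) - 1, n, 0.5, lower.tail = FALSE)
  min(1, 2 * min(lo, hi))
}

#' Asymptotic (chi-square) McNemar test
#'
#' `statistic = (|b - c| - k)^2 / (b + c)` with continuity correction
#' `k = 1` (clamped at zero) when enabled, referred to chi-square with one
#' degree of freedom.
#'
#' @param table a [paired_table()].
#' @param continuity apply the continuity correction (default `TRUE`).
#' @return `list(statistic, p_value)`.
#' @export
mcnemar_chi2 <- function(table, continuity = TRUE) {
  stopifnot(inherits(table, "paired_table"))
  b <- table$b; cc <- table$c
  if (b + cc == 0) stop("undefined: no discordant pairs")
  k <- if (continuity) 1 else 0
  stat <- max(abs(b - cc) - k, 0)^2 / (b + cc)
  list(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' ICC(A,k): absolute agreement, average of k raters
#'
#' Two-way model intraclass correlation for the average of `k` raters under
#' absolute agreement, from the two-way mean squares (rows = subjects MSR,
#' columns = raters MSC, residual MSE):
#' `ICC(A,k) = (MSR - MSE) / (MSR + (MSC - MSE) / n)`.
#' The F statistic is `MSR / MSE` on `(n - 1, (n - 1)(k - 1))` degrees of
#' freedom. The confidence interval follows the McGraw-Wong construction for
#' absolute-agreement ICCs: single-measure bounds from F quantiles with a
#' Satterthwaite-approximated denominator df, stepped up to average measures
#' via Spearman-Brown. The point estimate is interpreted on the standard
#' bands (< 0.5 poor, 0.5-0.75 moderate, 0.75-0.9 good, >= 0.9 excellent).
#'
#' @param ratings numeric matrix, `n` subjects x `k` raters, no missing cells.
#' @param conf_level confidence level (default 0.95).
#' @return An object of class `icc_result`: `icc`, `ci_low`, `ci_high`,
#'   `f_value`, `df1`, `df2`, `p_value`, `model`, `interpretation`, and the
#'   mean squares.
#' @export
icc_a_k <- function(ratings, conf_level = 0.95) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 raters")
  if (anyNA(ratings)) stop("missing cells are not supported")
  df <- data.frame(y = as.vector(ratings),
                   subject = factor(rep(seq_len(n), times = k)),
                   rater = factor(rep(seq_len(k), each = n)))
  # anova() warns about its own F-tests on perfect fits; only the mean
  # squares are used here (F is recomputed below)
  ms <- suppressWarnings(anova(aov(y ~ subject + rater,
                                   data = df))[["Mean Sq"]])
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  if (msr < 1e-14 && mse < 1e-14)
    stop("degenerate ratings: no variance anywhere in the table")
  icc <- (msr - mse) / (msr + (msc - mse) / n)
  fv <- msr / mse
  df1 <- n - 1
  df2 <- (n - 1) * (k - 1)
  p <- pf(fv, df1, df2, lower.tail = FALSE)
  if (mse < 1e-12 * msr && msc < 1e-12 * msr) {
    # perfect agreement: no rater or residual variance at all
    return(structure(list(icc = 1, ci_low = 1, ci_high = 1, f_value = Inf,
                          df1 = df1, df2 = df2, p_value = 0,
                          model = "two-way mixed, absolute agreement, average measures",
                          interpretation = interpret_icc(1),
                          ms = c(MSR = msr, MSC = msc, MSE = mse),
                          conf_level = conf_level),
                     class = "icc_result"))
  }

  # McGraw-Wong CI for A,1 then Spearman-Brown step-up to A,k
  alpha <- 1 - conf_level
  icc1 <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  aa <- k * icc1 / (n * (1 - icc1))
  bb <- 1 + k * icc1 * (n - 1) / (n * (1 - icc1))
  v <- (aa * msc + bb * mse)^2 /
    ((aa * msc)^2 / (k - 1) + (bb * mse)^2 / ((n - 1) * (k - 1)))
  fl <- qf(1 - alpha / 2, n - 1, v)
  fu <- qf(1 - alpha / 2, v, n - 1)
  # Spearman-Brown step-up of the single-measure bounds. The step-up has a
  # pole at -1/(k - 1); a single-measure bound beyond it means this
  # construction cannot bound the coefficient on that side (tiny n with
  # subject variance indistinguishable from zero), reported as -Inf / 1.
  pole <- -1 / (k - 1)
  sb <- function(r) k * r / (1 + (k - 1) * r)
  l1 <- n * (msr - fl * mse) /
    (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
  u1 <- n * (fu * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * fu * msr)
  lo <- if (l1 > pole) sb(l1) else -Inf
  hi <- if (u1 > pole) sb(u1) else 1
  # when MSE exceeds MSR the ratio estimator leaves its meaningful range
  # (numerator and denominator both negative can exceed 1); agreement worse
  # than chance is reported raw but banded as poor
  interp <- interpret_icc(if (msr <= mse) min(icc, 0) else icc)
  structure(list(icc = icc, ci_low = lo, ci_high = hi,
                 f_value = fv, df1 = df1, df2 = df2, p_value = p,
                 model = "two-way mixed, absolute agreement, average measures",
                 interpretation = interp,
                 ms = c(MSR = msr, MSC = msc, MSE = mse),
                 conf_level = conf_level),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(A,%s) = %.3f, %d%% CI (%.3f, %.3f) - %s reliability\n",
              "k", x$icc, round(100 * x$conf_level), x$ci_low, x$ci_high,
              x$interpretation))
  cat(sprintf("F(%d, %d) = %.3f, p = %.4g  [%s]\n", x$df1, x$df2, x$f_value,
              x$p_value, x$model))
  invisible(x)
}

#' Reliability band of an ICC value
#'
#' Standard interpretation bands: below 0.5 poor, 0.5 to below 0.75 moderate,
#' 0.75 to below 0.9 good, 0.9 and above excellent.
#'
#' @param icc scalar ICC (<= 1).
#' @return one of `"poor"`, `"moderate"`, `"good"`, `"excellent"`.
#' @export
interpret_icc <- function(icc) {
  if (!is.numeric(icc) || icc > 1) stop("icc must be a number <= 1")
  if (icc < 0.5) "poor"
  else if (icc < 0.75) "moderate"
  else if (icc < 0.9) "good"
  else "excellent"
}

#' Exact power of the two-sided exact McNemar test
#'
#' Enumerates the trinomial distribution of the discordant cells over `n`
#' pairs, with per-pair probabilities `p01` (incorrect -> correct), `p10`
#' (correct -> incorrect) and `1 - p01 - p10` (concordant), and sums the
#' probability of all tables whose [mcnemar_exact()] p-value is at most
#' `alpha`.
#'
#' @param p01,p10 discordant-cell probabilities, `p01 + p10 <= 1`.
#' @param n number of pairs.
#' @param alpha significance level.
#' @return exact rejection probability in `[0, 1]`.
#' @export
mcnemar_power_exact <- function(p01, p10, n, alpha = 0.05) {
  if (any(c(p01, p10) < 0) || p01 + p10 > 1 + 1e-12)
    stop("need p01, p10 >= 0 and p01 + p10 <= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (n < 1) return(0)
  pd <- p01 + p10
  if (pd == 0) return(0)
  q <- p01 / pd
  power <- 0
  for (d in 0:n) {
    pdd <- dbinom(d, n, pd)
    if (pdd < 1e-300) next
    b <- 0:d
    # conditional exact two-sided p-value for each (b, d - b)
    lo <- pbinom(pmin(b, d - b), d, 0.5)
    hi <- pbinom(pmax(b, d - b) - 1, d, 0.5, lower.tail = FALSE)
    pv <- pmin(1, 2 * pmin(lo, hi))
    if (d == 0) pv <- 1
    power <- power + pdd * sum(dbinom(b, d, q)[pv <= alpha])
  }
  power
}

#' Simulate the two-session rater study
#'
#' Emulates the study bookkeeping: each of `n_raters` surgeons places one
#' virtual screw in each of `n_scapulae` scapulae, the first half in the
#' "before" session and the second half in the "after" session (sessions use
#' disjoint scapula subsets, 7 + 7 in the original design). Scores are
#' independent Bernoulli draws with per-session success probabilities; the
#' defaults are the observed session rates (33/56 and 50/56).
#'
#' @param n_raters number of raters (default 8).
#' @param n_scapulae total scapulae, must be even (default 14).
#' @param p_before,p_after per-placement success probabilities.
#' @param seed integer seed; the simulation is deterministic given the seed.
#' @return An object of class `placement_record_set`: data.frame `records`
#'   (`scapula_id`, `rater_id`, `session`, `score`) plus the design.
#' @export
simulate_study <- function(n_raters = 8, n_scapulae = 14,
                           p_before = 33 / 56, p_after = 50 / 56, seed = 1) {
  if (n_scapulae %% 2 != 0)
    stop("n_scapulae must be even: sessions use disjoint halves")
  if (any(c(p_before, p_after) < 0) || any(c(p_before, p_after) > 1))
    stop("probabilities must be in [0, 1]")
  half <- n_scapulae / 2
  rec <- expand.grid(scapula_id = seq_len(n_scapulae),
                     rater_id = seq_len(n_raters))
  rec$session <- ifelse(rec$scapula_id <= half, "before", "after")
  p <- ifelse(rec$session == "before", p_before, p_after)
  rec$score <- with_seed(seed,
                         ifelse(rbinom(nrow(rec), 1, p) == 1, "Correct",
                                "Incorrect"))
  structure(list(records = rec[, c("scapula_id", "rater_id", "session",
                                   "score")],
                 design = list(n_raters = n_raters, n_scapulae = n_scapulae,
                               pairing = "(rater, scapula-rank within session)",
                               seed = seed)),
            class = "placement_record_set")
}

#' @export
print.placement_record_set <- function(x, ...) {
  cat(sprintf("<placement_record_set> %d records (%d raters x %d scapulae)\n",
              nrow(x$records), x$design$n_raters, x$design$n_scapulae))
  invisible(x)
}

#' Collapse a record set into the paired 2x2 table
#'
#' Pairs placements by (rater, scapula rank within session): a rater's k-th
#' "before" scapula is paired with the same rater's k-th "after" scapula.
#' The study does not state its pairing rule; this choice is recorded in the
#' table's `pairing` attribute.
#'
#' @param records a [simulate_study()] result, or any data.frame with columns
#'   `scapula_id`, `rater_id`, `session`, `score`.
#' @return A [paired_table()] with attribute `pairing`.
#' @export
tabulate_pairs <- function(records) {
  rec <- if (inherits(records, "placement_record_set")) records$records
         else as.data.frame(records)
  before <- rec[rec$session == "before", ]
  after <- rec[rec$session == "after", ]
  if (nrow(before) != nrow(after))
    stop("unbalanced sessions: cannot form pairs")
  ord <- function(d) d[order(d$rater_id, d$scapula_id), ]
  before <- ord(before); after <- ord(after)
  if (!all(before$rater_id == after$rater_id))
    stop("unbalanced sessions within raters: cannot form pairs")
  bc <- before$score == "Correct"
  ac <- after$score == "Correct"
  tab <- paired_table(a = sum(bc & ac), b = sum(!bc & ac),
                      c = sum(bc & !ac), d = sum(!bc & !ac))
  attr(tab, "pairing") <- "(rater, scapula-rank within session)"
  tab
}

#' Full statistics report of a simulated (or recorded) study
#'
#' Success rates per session, improvement in percentage points, exact (and
#' asymptotic) McNemar test on the paired table, ICC(A,k) of the
#' scapula-by-rater score matrix of each session, and the exact power of the
#' McNemar test at the observed discordance.
#'
#' @param records a [simulate_study()] result.
#' @param alpha significance level for the power computation.
#' @return A list with components `before`, `after`, `improvement_pp`,
#'   `mcnemar`, `icc`, `power`; serializable with [report_to_json()].
#' @export
study_report <- function(records, alpha = 0.05) {
  rec <- records$records
  tab <- tabulate_pairs(records)
  sess <- function(s) {
    r <- rec[rec$session == s, ]
    list(correct = sum(r$score == "Correct"), total = nrow(r),
         rate = success_rate(sum(r$score == "Correct"), nrow(r)))
  }
  before <- sess("before"); after <- sess("after")
  n_pairs <- tab$n
  icc <- tryCatch({
    m <- score_matrix(records, "after")
    icc_a_k(m)
  }, error = function(e) NULL)
  pw <- mcnemar_power_exact(tab$b / n_pairs, tab$c / n_pairs, n_pairs, alpha)
  list(before = before, after = after,
       improvement_pp = improvement_pp(c(before$correct, before$total),
                                       c(after$correct, after$total)),
       mcnemar = list(b = tab$b, c = tab$c, p_exact = mcnemar_exact(tab),
                      pairing = attr(tab, "pairing")),
       icc = icc,
       power = list(alpha = alpha, n = n_pairs, value = pw))
}

#' Session score matrix (scapulae x raters)
#'
#' Binary (1 = Correct) matrix of one session, suitable as [icc_a_k()] input
#' with scapulae as subjects and raters as the k raters.
#'
#' @param records a [simulate_study()] result.
#' @param session `"before"` or `"after"`.
#' @return numeric matrix, scapulae in rows, raters in columns.
#' @export
score_matrix <- function(records, session = "after") {
  rec <- records$records
  r <- rec[rec$session == session, ]
  ids <- sort(unique(r$scapula_id))
  raters <- sort(unique(r$rater_id))
  m <- matrix(NA_real_, base::length(ids), base::length(raters),
              dimnames = list(ids, raters))
  m[cbind(match(r$scapula_id, ids), match(r$rater_id, raters))] <-
    as.numeric(r$score == "Correct")
  m
}

#' Write records / reports to disk
#'
#' @param records a [simulate_study()] result.
#' @param path CSV output path (header `scapula_id,rater_id,session,score`).
#' @return `path`, invisibly.
#' @export
records_to_csv <- function(records, path) {
  write.csv(records$records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname records_to_csv
#' @export
records_from_csv <- function(path) {
  rec <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("scapula_id", "rater_id", "session", "score")
  if (!all(need %in% names(rec)))
    stop("records CSV must have columns ", paste(need, collapse = ", "))
  structure(list(records = rec[, need],
                 design = list(n_raters = base::length(unique(rec$rater_id)),
                               n_scapulae = base::length(unique(rec$scapula_id)),
                               pairing = "(rater, scapula-rank within session)",
                               seed = NA)),
            class = "placement_record_set")
}

#' @rdname records_to_csv
#' @param report a [study_report()] result.
#' @export
report_to_json <- function(report, path = NULL) {
  rep2 <- report
  if (!is.null(rep2$icc))
    rep2$icc <- rep2$icc[c("icc", "ci_low", "ci_high", "f_value", "df1",
                           "df2", "model", "interpretation")]
  js <- jsonlite::toJSON(rep2, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
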