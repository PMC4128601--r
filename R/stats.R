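# paired statistical test battery: directional tests, TOST equivalence with
# the study margins, normality checks and Wilcoxon recomputation

#' One-tailed paired inequality test
#'
#' Paired Student t-test of the directional hypothesis mean(a) > mean(b)
#' (direction = +1) or mean(a) < mean(b) (direction = -1), with a
#' Kolmogorov-Smirnov normality check of the paired differences and a
#' Wilcoxon signed-rank recomputation.
#'
#' @param a,b paired value vectors (one entry per subject)
#' @param direction +1 tests a > b, -1 tests a < b
#' @return list of class \code{eit_test}: p-value, statistic, n, family,
#'   pass (p < alpha), alpha, normality p, Wilcoxon p
#' @param alpha significance level (default 0.05)
#' @export
paired_inequality_test <- function(a, b, direction = 1, alpha = 0.05) {
  check_paired(a, b)
  alt <- if (direction >= 0) "greater" else "less"
  d <- a - b
  if (stats::sd(d) == 0) {
    # degenerate: t statistic 0 (p = 0.5) for zero differences, decisive
    # otherwise
    p <- if (mean(d) == 0) 0.5 else if (sign(mean(d)) == sign(direction)) 0 else 1
    return(structure(list(kind = "inequality", p = p,
                          statistic = if (mean(d) == 0) 0 else NA_real_,
                          n = length(a), family = "t", pass = p < alpha,
                          alpha = alpha, normality_p = NA_real_,
                          wilcoxon_p = p, direction = direction),
                     class = "eit_test"))
  }
  tt <- stats::t.test(a, b, paired = TRUE, alternative = alt)
  wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                            alternative = alt, exact = FALSE))
  structure(list(kind = "inequality", p = tt$p.value,
                 statistic = unname(tt$statistic), n = length(a),
                 family = "t", pass = tt$p.value < alpha, alpha = alpha,
                 normality_p = ks_normality_p(a - b),
                 wilcoxon_p = wt$p.value, direction = direction),
            class = "eit_test")
}

#' Paired equivalence test (TOST)
#'
#' Two one-sided paired t-tests of H0: |mean(a) - mean(b)| >= margin; the
#' reported p is the larger of the two one-sided p-values, so p < alpha
#' establishes equivalence within the margin. A relative margin (e.g. the
#' 10\% tidal-volume criterion) is resolved against the grand mean of the
#' two conditions; an absolute margin (e.g. 0.03 CoV, half a pixel height of
#' a 32x32 image) is used as given. The Wilcoxon recomputation replaces each
#' one-sided t-test with a one-sided signed-rank test on the shifted
#' differences.
#'
#' @inheritParams paired_inequality_test
#' @param margin equivalence margin; interpreted per \code{margin_type}
#' @param margin_type "absolute" or "relative"
#' @export
paired_equivalence_test <- function(a, b, margin, margin_type = c("absolute", "relative"),
                                    alpha = 0.05) {
  check_paired(a, b)
  margin_type <- match.arg(margin_type)
  if (!is.numeric(margin) || margin <= 0)
    stop("configuration error: equivalence margin must be > 0")
  m <- if (margin_type == "relative") margin * abs(mean(c(mean(a), mean(b)))) else margin
  if (m <= 0) stop("resolved equivalence margin is not positive")
  d <- a - b
  if (stats::sd(d) == 0) {
    # degenerate: decisive by comparison of the exact difference to the margin
    p <- if (abs(mean(d)) < m) 0 else 1
    return(structure(list(kind = "equivalence", p = p, statistic = NA_real_,
                          n = length(a), family = "t", pass = p < alpha,
                          alpha = alpha, margin = m,
                          normality_p = NA_real_, wilcoxon_p = p),
                     class = "eit_test"))
  }
  p_upper <- stats::t.test(d - m, alternative = "less")$p.value    # H1: mean(d) < m
  p_lower <- stats::t.test(d + m, alternative = "greater")$p.value # H1: mean(d) > -m
  p <- max(p_upper, p_lower)
  wu <- suppressWarnings(stats::wilcox.test(d - m, alternative = "less",
                                            exact = FALSE))$p.value
  wl <- suppressWarnings(stats::wilcox.test(d + m, alternative = "greater",
                                            exact = FALSE))$p.value
  structure(list(kind = "equivalence", p = p,
                 statistic = unname(mean(d) / (stats::sd(d) / sqrt(length(d)))),
                 n = length(a), family = "t", pass = p < alpha, alpha = alpha,
                 margin = m, normality_p = ks_normality_p(d),
                 wilcoxon_p = max(wu, wl)),
            class = "eit_test")
}

check_paired <- function(a, b) {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  if (length(a) < 2) stop("need n >= 2 paired observations")
  if (any(!is.finite(a)) || any(!is.finite(b))) stop("non-finite values")
  invisible(TRUE)
}

# Kolmogorov-Smirnov test of the differences against a fitted normal
ks_normality_p <- function(d) {
  if (stats::sd(d) == 0) return(NA_real_)
  suppressWarnings(stats::ks.test((d - mean(d)) / stats::sd(d), "pnorm"))$p.value
}

#' @export
print.eit_test <- function(x, ...) {
  cat(sprintf("%s test: p = %.4g (%s at alpha = %g), n = %d; KS p = %.3g, Wilcoxon p = %.4g\n",
              x$kind, x$p, if (x$pass) "significant" else "ns", x$alpha, x$n,
              x$normality_p, x$wilcoxon_p))
  invisible(x)
}

#' Default battery of expected-findings hypotheses
#'
#' The twelve rows of the functional test battery over the six recording
#' stages (Z21a, P21a, Z100, P100, Z21b, P21b; Z/P = zero/positive
#' end-expiratory pressure, 21/100 = FiO2 percent, a/b = first/second
#' repetition): V_T equivalence under PEEP, under FiO2, and across
#' repetitions (relative margin 10\%); CoV decrease with PEEP at both FiO2
#' levels, CoV increase with 100\% FiO2 at both pressures, and CoV
#' equivalence across repetitions (absolute margin 0.03, half a pixel height
#' of a 32x32 image).
#'
#' @return data.frame of hypothesis specifications
#' @export
default_battery_specs <- function() {
  data.frame(
    id = c("VT_Z100_eq_P100", "VT_Z21_eq_P21",
           "VT_Z21_eq_Z100", "VT_P21_eq_P100",
           "VT_Z21a_eq_Z21b", "VT_P21a_eq_P21b",
           "CoV_P21_lt_Z21", "CoV_P100_lt_Z100",
           "CoV_Z100_gt_Z21", "CoV_P100_gt_P21",
           "CoV_Z21a_eq_Z21b", "CoV_P21a_eq_P21b"),
    measure = c(rep("vt", 6), rep("cov", 6)),
    kind = c(rep("equivalence", 6), rep("inequality", 4),
             rep("equivalence", 2)),
    cond_a = c("Z100", "Z21a", "Z21a", "P21a", "Z21a", "P21a",
               "P21a", "P100", "Z100", "P100", "Z21a", "P21a"),
    cond_b = c("P100", "P21a", "Z100", "P100", "Z21b", "P21b",
               "Z21a", "Z100", "Z21a", "P21a", "Z21b", "P21b"),
    direction = c(rep(NA, 6), -1, -1, 1, 1, NA, NA),
    margin = c(rep(0.10, 6), NA, NA, NA, NA, 0.03, 0.03),
    margin_type = c(rep("relative", 6), NA, NA, NA, NA,
                    "absolute", "absolute"),
    stringsAsFactors = FALSE)
}

#' Run the statistical test battery on a functional-results table
#'
#' Applies each hypothesis of the battery to every algorithm present in the
#' results, pairing values by subject. Each row reports the t-family
#' p-value, the Kolmogorov-Smirnov normality p of the paired differences,
#' and the Wilcoxon signed-rank recomputation.
#'
#' @param results data.frame with columns \code{subject}, \code{condition}
#'   (levels as in \code{\link{default_battery_specs}}), \code{algorithm},
#'   \code{vt}, \code{cov}
#' @param specs hypothesis table (default \code{\link{default_battery_specs}})
#' @param alpha significance level (default 0.05)
#' @return data.frame: one row per (hypothesis, algorithm) with columns
#'   \code{id}, \code{algorithm}, \code{measure}, \code{kind}, \code{p},
#'   \code{pass}, \code{n}, \code{normality_p}, \code{wilcoxon_p},
#'   \code{wilcoxon_pass}
#' @export
run_battery <- function(results, specs = default_battery_specs(), alpha = 0.05) {
  need <- c("subject", "condition", "algorithm", "vt", "cov")
  if (!all(need %in% names(results)))
    stop("results must have columns ", paste(need, collapse = ", "))
  algs <- unique(results$algorithm)
  conds <- unique(c(specs$cond_a, specs$cond_b))
  # completeness check
  missing <- character(0)
  for (alg in algs) for (cc in conds) {
    subj <- unique(results$subject)
    have <- results$subject[results$algorithm == alg & results$condition == cc]
    lack <- setdiff(subj, have)
    if (length(lack))
      missing <- c(missing, sprintf("%s/%s: subject(s) %s", alg, cc,
                                    paste(lack, collapse = ",")))
  }
  if (length(missing))
    stop("missing (subject, condition, algorithm) cells:\n  ",
         paste(missing, collapse = "\n  "))

  out <- list()
  for (alg in algs) {
    sub <- results[results$algorithm == alg, ]
    for (i in seq_len(nrow(specs))) {
      sp <- specs[i, ]
      wide_a <- sub[sub$condition == sp$cond_a, ]
      wide_b <- sub[sub$condition == sp$cond_b, ]
      wide_b <- wide_b[match(wide_a$subject, wide_b$subject), ]
      va <- wide_a[[sp$measure]]
      vb <- wide_b[[sp$measure]]
      tst <- if (sp$kind == "inequality") {
        paired_inequality_test(va, vb, direction = sp$direction, alpha = alpha)
      } else {
        paired_equivalence_test(va, vb, margin = sp$margin,
                                margin_type = sp$margin_type, alpha = alpha)
      }
      out[[length(out) + 1]] <- data.frame(
        id = sp$id, algorithm = alg, measure = sp$measure, kind = sp$kind,
        p = tst$p, pass = tst$pass, n = tst$n,
        normality_p = tst$normality_p, wilcoxon_p = tst$wilcoxon_p,
        wilcoxon_pass = tst$wilcoxon_p < alpha,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("eit_battery", "data.frame")
  res
}

#' Render a battery result as a hypotheses x algorithms grid
#'
#' @param battery output of \code{\link{run_battery}}
#' @param value which column to tabulate (default "p")
#' @return data.frame, rows = hypothesis ids, columns = algorithms
#' @export
battery_grid <- function(battery, value = "p") {
  ids <- unique(battery$id)
  algs <- unique(battery$algorithm)
  grid <- data.frame(id = ids, stringsAsFactors = FALSE)
  for (alg in algs)
    grid[[alg]] <- battery[[value]][match(paste(ids, alg),
                                          paste(battery$id, battery$algorithm))]
  grid
}
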