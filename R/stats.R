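#' Background-to-true-background ratio
#'
#' @param bg_conc background column VOI concentration (counts/ml).
#' @param tb_conc true-background VOI concentration (counts/ml, > 0).
#' @return bg_conc / tb_conc.
#' @export
btr <- function(bg_conc, tb_conc) {
  if (!is.finite(tb_conc) || tb_conc <= 0)
    stop("true background concentration must be > 0")
  bg_conc / tb_conc
}

#' Coefficient of variation, in percent
#'
#' 100 times the sample standard deviation (n - 1 denominator) over the mean.
#'
#' @param values numeric vector, length >= 2, non-zero mean.
#' @return CV in percent.
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values for a CV")
  m <- mean(values)
  if (m == 0) stop("CV undefined for zero mean")
  100 * stats::sd(values) / m
}

#' Fraction of negative-net-count flags, in percent
#'
#' @param flags logical vector, length >= 1.
#' @return Percentage of TRUE flags.
#' @export
negative_fraction <- function(flags) {
  if (!length(flags)) stop("empty flag list")
  100 * mean(as.logical(flags))
}

#' Relative activity concentration against the SPECT reference
#'
#' @param method_ac planar estimate (counts/ml).
#' @param spect_ac volumetric reference (counts/ml, > 0).
#' @return method_ac / spect_ac.
#' @export
relative_ac <- function(method_ac, spect_ac) {
  if (!is.finite(spect_ac) || spect_ac <= 0)
    stop("SPECT reference concentration must be > 0")
  method_ac / spect_ac
}

#' Paired two-sided t-test
#'
#' Computes t = mean(d) / (sd(d) / sqrt(n)) on d = a - b and the two-sided p
#' from the Student t distribution with n - 1 degrees of freedom. All-zero
#' differences return p = 1 by convention.
#'
#' @param a,b paired numeric vectors of equal length n >= 2.
#' @return Two-sided p value.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b)) stop("paired samples must have equal length")
  n <- length(a)
  if (n < 2L) stop("need at least 2 pairs")
  d <- a - b
  s <- stats::sd(d)
  if (s == 0) return(if (mean(d) == 0) 1 else 0)
  tt <- mean(d) / (s / sqrt(n))
  2 * stats::pt(-abs(tt), df = n - 1)
}

#' Assemble the cohort study report
#'
#' Summarises per-subject quantification rows into (i) a background-accuracy
#' table: per ROI and kidney side the mean BTR, its CV, and the percentages
#' of subjects with negative net counts under the conjugate-view (CNC) and
#' posterior-view (PNC) methods; and (ii) a relative-accuracy table: per ROI,
#' side and method the mean and CV of the planar/SPECT concentration ratio,
#' computed only over subjects without negative nets for that method and only
#' for ROIs whose negative-count fraction is at most `max_negative_pct`. A
#' paired two-sided t-test compares the two methods over subjects valid under
#' both (pairwise exclusion).
#'
#' @param runs data.frame with columns subject, side, bg_label, btr,
#'   conjv_negative, postv_negative, rel_ac_conjv, rel_ac_postv (the relative
#'   AC columns are NA where the method refused).
#' @param max_negative_pct inclusion threshold for the method summaries (%).
#' @param alpha significance level for the method comparison.
#' @return A list of class `study_report` with data.frames `table1`
#'   (roi, side, mean_btr, cv_pct, cnc_pct, pnc_pct) and `fig4`
#'   (roi, side, method, mean_rel_ac, cv_pct, n, p_value, significant).
#' @export
build_study_report <- function(runs, max_negative_pct = 10, alpha = 0.05) {
  need <- c("subject", "side", "bg_label", "btr",
            "conjv_negative", "postv_negative", "rel_ac_conjv", "rel_ac_postv")
  if (!all(need %in% names(runs))) stop("missing columns in quantification rows")
  if (length(unique(runs$subject)) < 2L) stop("need at least 2 subjects")

  groups <- unique(runs[c("bg_label", "side")])
  groups <- groups[order(groups$side,
                         as.integer(sub("^B", "", groups$bg_label))), ]
  t1 <- f4 <- list()
  for (i in seq_len(nrow(groups))) {
    g <- runs[runs$bg_label == groups$bg_label[i] & runs$side == groups$side[i], ]
    cnc <- negative_fraction(g$conjv_negative)
    pnc <- negative_fraction(g$postv_negative)
    t1[[i]] <- data.frame(
      roi = groups$bg_label[i], side = groups$side[i],
      mean_btr = mean(g$btr), cv_pct = coefficient_of_variation(g$btr),
      cnc_pct = cnc, pnc_pct = pnc)

    both <- !g$conjv_negative & !g$postv_negative
    p <- if (sum(both) >= 2L && cnc <= max_negative_pct && pnc <= max_negative_pct)
      paired_t_test(g$rel_ac_conjv[both], g$rel_ac_postv[both]) else NA_real_
    summarise <- function(method, vals, neg_pct) {
      ok <- !is.na(vals)
      include <- neg_pct <= max_negative_pct && sum(ok) >= 2L
      data.frame(
        roi = groups$bg_label[i], side = groups$side[i], method = method,
        mean_rel_ac = if (include) mean(vals[ok]) else NA_real_,
        cv_pct = if (include) coefficient_of_variation(vals[ok]) else NA_real_,
        n = sum(ok), p_value = p,
        significant = if (is.na(p)) NA else p < alpha)
    }
    f4[[length(f4) + 1L]] <- summarise("ConjV", g$rel_ac_conjv, cnc)
    f4[[length(f4) + 1L]] <- summarise("PostV", g$rel_ac_postv, pnc)
  }
  structure(list(table1 = do.call(rbind, t1), fig4 = do.call(rbind, f4),
                 max_negative_pct = max_negative_pct, alpha = alpha),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("Background accuracy (BTR / CV / negative-net fractions):\n")
  print(x$table1, row.names = FALSE, digits = 3)
  cat("\nRelative activity concentration vs SPECT reference:\n")
  print(x$fig4, row.names = FALSE, digits = 3)
  invisible(x)
}
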