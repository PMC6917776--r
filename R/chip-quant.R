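# ChIP-qPCR enrichment with exponential-scale error limits.
#
# Enrichment of a target locus over input chromatin is 2^-dCq with
# dCq = Cq_target - Cq_input. Because 2^-x is convex, a symmetric Cq-space
# standard deviation s = sqrt(sd_input^2 + sd_target^2) maps to asymmetric
# linear-scale limits |2^-(dCq +/- s) - 2^-dCq|.

#' ChIP-qPCR enrichment with propagated error limits
#'
#' Computes `dCq = cq_target - cq_input`, `enrichment = 2^-dCq`,
#' `s = sqrt(sd_input^2 + sd_target^2)` and the upper/lower limits
#' `|2^-(dCq -/+ s) - 2^-dCq|` (absolute deviations on the linear scale).
#'
#' @param cq_target,cq_input mean quantification cycles.
#' @param sd_target,sd_input their standard deviations (>= 0).
#' @param dilution_offset optional additive Cq correction for the input
#'   dilution (percent-input style), subtracted from `cq_input`.
#' @return list of class `enrichment_result`: `dcq`, `enrichment`, `s`,
#'   `upper_limit`, `lower_limit`.
#' @examples
#' enrichment_with_limits(25, 23, sd_target = 0.4, sd_input = 0.3)
#' @export
enrichment_with_limits <- function(cq_target, cq_input, sd_target = 0,
                                   sd_input = 0, dilution_offset = 0) {
  if (any(c(sd_target, sd_input) < 0)) stop("standard deviations must be >= 0")
  dcq <- cq_target - (cq_input - dilution_offset)
  s <- sqrt(sd_input^2 + sd_target^2)
  e <- 2^(-dcq)
  structure(list(
    dcq = dcq, enrichment = e, s = s,
    upper_limit = abs(2^(-(dcq - s)) - e),
    lower_limit = abs(2^(-(dcq + s)) - e)
  ), class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment> 2^-dCq = %.4g (+%.3g/-%.3g), dCq = %.3f, s = %.3f\n",
              x$enrichment, x$upper_limit, x$lower_limit, x$dcq, x$s))
  invisible(x)
}

#' Normalize a methylation-mark enrichment to the total-H3 track
#'
#' Ratio of enrichments `2^-(dcq_mark - dcq_h3)`. Uncertainty is propagated in
#' log2 (Cq) space -- the two s values add in quadrature -- and the same
#' exponential-scale limit form is then applied to the ratio. This convention
#' is recorded in the returned object.
#'
#' @param mark an `enrichment_result` for the mark (e.g. H3K4me3).
#' @param h3 an `enrichment_result` for total H3.
#' @return list of class `enrichment_result` (ratio scale) with
#'   `normalization = "h3_log2_quadrature"`.
#' @export
normalize_to_h3 <- function(mark, h3) {
  stopifnot(inherits(mark, "enrichment_result"), inherits(h3, "enrichment_result"))
  if (!is.finite(h3$enrichment) || h3$enrichment <= 0) {
    stop("degenerate H3 enrichment; cannot normalize")
  }
  dcq_ratio <- mark$dcq - h3$dcq
  s <- sqrt(mark$s^2 + h3$s^2)
  r <- 2^(-dcq_ratio)
  structure(list(
    dcq = dcq_ratio, enrichment = r, s = s,
    upper_limit = abs(2^(-(dcq_ratio - s)) - r),
    lower_limit = abs(2^(-(dcq_ratio + s)) - r),
    normalization = "h3_log2_quadrature"
  ), class = "enrichment_result")
}

#' Left-tailed two-sample t-test
#'
#' One-sided (lower-tail) test of `mean(x) < mean(y)` analog: the alternative
#' is that the first sample mean is smaller. `equal_variance = TRUE` uses the
#' pooled-variance Student test; `FALSE` uses Welch-Satterthwaite degrees of
#' freedom. When both samples have zero variance and equal means the p-value
#' is 0.5 by convention (the symmetric null).
#'
#' @param x,y numeric samples (each n >= 2).
#' @param equal_variance pooled (Student) vs Welch.
#' @return list: `statistic`, `df`, `p_value`, `estimate` (mean difference).
#' @export
left_tailed_t <- function(x, y, equal_variance = TRUE) {
  if (length(x) < 2L || length(y) < 2L) stop("each sample needs n >= 2")
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y)) {
      return(list(statistic = 0, df = NA_real_, p_value = 0.5,
                  estimate = 0))
    }
    return(list(statistic = if (mean(x) < mean(y)) -Inf else Inf,
                df = NA_real_,
                p_value = if (mean(x) < mean(y)) 0 else 1,
                estimate = mean(x) - mean(y)))
  }
  tt <- stats::t.test(x, y, alternative = "less", var.equal = equal_variance)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, estimate = mean(x) - mean(y))
}

#' Per-locus enrichment table from a long-format Cq table
#'
#' Summarizes technical replicates (mean/SD of Cq per locus, antibody and
#' condition), computes target-vs-input enrichment with limits for each
#' antibody track, and normalizes the mark track to the H3 track when both
#' are present.
#'
#' @param cq data.frame with columns `locus`, `antibody` (e.g. "H3K4me3",
#'   "H3", and "input" rows per antibody), `condition`, `replicate`, `cq`.
#'   Input rows are identified by `antibody == "input"` (shared) or
#'   `fraction == "input"` when a `fraction` column distinguishes
#'   target/input wells per antibody.
#' @param mark antibody name of the methylation mark (default "H3K4me3").
#' @param h3 antibody name of the total-histone control (default "H3").
#' @return data.frame with one row per locus x condition: enrichments, limits
#'   and H3-normalized values.
#' @export
chip_enrichment_table <- function(cq, mark = "H3K4me3", h3 = "H3") {
  need <- c("locus", "antibody", "condition", "replicate", "cq")
  if (!"fraction" %in% names(cq)) {
    stop("cq table needs a 'fraction' column with values 'target'/'input'")
  }
  if (!all(need %in% names(cq))) {
    stop("cq table needs columns: ", paste(need, collapse = ", "))
  }
  summ <- stats::aggregate(cq$cq,
                           by = list(locus = cq$locus, antibody = cq$antibody,
                                     condition = cq$condition, fraction = cq$fraction),
                           FUN = function(v) c(mean = mean(v), sd = stats::sd(v), n = length(v)))
  summ <- cbind(summ[, 1:4], as.data.frame(summ$x))
  out <- list()
  for (loc in unique(summ$locus)) {
    for (cond in unique(summ$condition[summ$locus == loc])) {
      get <- function(ab, fr) summ[summ$locus == loc & summ$condition == cond &
                                     summ$antibody == ab & summ$fraction == fr, ]
      res <- list(locus = loc, condition = cond)
      er <- list()
      for (ab in c(mark, h3)) {
        tg <- get(ab, "target"); ip <- get(ab, "input")
        if (nrow(tg) == 1L && nrow(ip) == 1L) {
          er[[ab]] <- enrichment_with_limits(tg$mean, ip$mean, tg$sd, ip$sd)
          res[[paste0("enrichment_", ab)]] <- er[[ab]]$enrichment
          res[[paste0("upper_", ab)]] <- er[[ab]]$upper_limit
          res[[paste0("lower_", ab)]] <- er[[ab]]$lower_limit
        }
      }
      if (!is.null(er[[mark]]) && !is.null(er[[h3]])) {
        nr <- normalize_to_h3(er[[mark]], er[[h3]])
        res$h3_normalized <- nr$enrichment
        res$h3_normalized_upper <- nr$upper_limit
        res$h3_normalized_lower <- nr$lower_limit
      }
      out[[length(out) + 1L]] <- as.data.frame(res, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
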