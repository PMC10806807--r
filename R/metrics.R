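# Virtual-screening enrichment metrics over labelled score lists.

#' Construct screen records
#'
#' One row per screened molecule: id, score (kcal/mol, lower is better) and
#' an active/decoy label. Molecules with no score (e.g. rejected by the
#' clash filter, which prevents them from being scored at all) are kept:
#' they are ranked after every scored molecule, in input order, and their
#' count is reported as attribute `n_unscored` — the molecule still
#' occupies a rank.
#'
#' @param id character ids.
#' @param score numeric scores (NA allowed for unscored molecules).
#' @param label `"active"` or `"decoy"` per molecule.
#' @return data.frame of class `screen_records`.
#' @export
screen_records <- function(id, score, label) {
  label <- as.character(label)
  if (!all(label %in% c("active", "decoy"))) {
    stop("labels must be 'active' or 'decoy'", call. = FALSE)
  }
  score <- as.numeric(score)
  if (any(!is.finite(score) & !is.na(score))) {
    stop("scores must be finite or NA", call. = FALSE)
  }
  df <- data.frame(id = as.character(id), score = score, label = label,
                   stringsAsFactors = FALSE)
  attr(df, "n_unscored") <- sum(is.na(score))
  class(df) <- c("screen_records", class(df))
  df
}

check_records <- function(records) {
  if (!all(c("id", "score", "label") %in% names(records))) {
    stop("records need columns id, score, label", call. = FALSE)
  }
  n_act <- sum(records$label == "active")
  n_dec <- sum(records$label == "decoy")
  if (n_act < 1L) stop("metric undefined: no actives in records",
                       call. = FALSE)
  if (n_dec < 1L) stop("metric undefined: no decoys in records",
                       call. = FALSE)
  invisible(list(n_actives = n_act, n_decoys = n_dec))
}

# stable rank: scored ascending by score, unscored last in input order
rank_records <- function(records) {
  ord <- order(is.na(records$score), records$score, method = "radix")
  records[ord, , drop = FALSE]
}

#' Enrichment factor at a screened fraction
#'
#' `EF_f` = (fraction of actives found in the top `ceiling(f N)` molecules
#' by score) / f. A random ranking gives EF about 1; for `f = 0.01` a
#' perfect screen of 10 actives in 1000 molecules gives 100. Ties are
#' broken by stable input order; a warning is issued when tied scores span
#' the cutoff rank.
#'
#' @param records a `screen_records` data.frame (or any data.frame with
#'   `id`, `score`, `label`).
#' @param fraction screened fraction, 0 < fraction <= 1 (default 0.01).
#' @return the enrichment factor (ratio >= 0).
#' @export
ef_at_fraction <- function(records, fraction = 0.01) {
  stopifnot(fraction > 0, fraction <= 1)
  counts <- check_records(records)
  rr <- rank_records(records)
  n_top <- ceiling(fraction * nrow(rr))
  if (n_top < nrow(rr)) {
    s_in <- rr$score[n_top]
    s_out <- rr$score[n_top + 1L]
    if (!is.na(s_in) && !is.na(s_out) && s_in == s_out) {
      warning(sprintf(
        "tied scores (%.6g) span the top-%d cutoff; ties broken by input order",
        s_in, n_top), call. = FALSE)
    }
  }
  found <- sum(rr$label[seq_len(n_top)] == "active")
  (found / counts$n_actives) / fraction
}

#' Adjusted logAUC (early-recognition semilog ROC area)
#'
#' The fraction of actives found is integrated against the log10 of the
#' screened decoy fraction (the convention of the DOCK enrichment
#' literature; `x_axis = "database"` switches the x variable to the
#' fraction of all molecules screened) over `[lambda_min, 1]`, normalized
#' by `log10(1/lambda_min)`, expressed in percent, and the random-curve
#' value of 14.462 (for lambda_min = 0.001) is subtracted. A perfect
#' ranking scores 85.538; a random one about 0; worse-than-random rankings
#' go negative. The ROC curve is piecewise-linear through the per-decoy
#' points and the area uses exact trapezoids on the log axis.
#'
#' @param records as for [ef_at_fraction()].
#' @param lambda_min lower integration limit (default 0.001).
#' @param x_axis `"decoy"` (default) or `"database"`.
#' @return adjusted logAUC on the percent scale.
#' @export
adjusted_logauc <- function(records, lambda_min = 0.001,
                            x_axis = c("decoy", "database")) {
  stopifnot(lambda_min > 0, lambda_min < 1)
  x_axis <- match.arg(x_axis)
  counts <- check_records(records)
  rr <- rank_records(records)
  is_act <- rr$label == "active"
  cum_act <- cumsum(is_act) / counts$n_actives
  if (x_axis == "decoy") {
    at <- which(!is_act)
    xs <- seq_along(at) / counts$n_decoys
    ys <- cum_act[at]
    # actives ranked above the first decoy are already found at x -> 0
    y0 <- if (at[1] > 1L) cum_act[at[1] - 1L] else 0
  } else {
    xs <- seq_len(nrow(rr)) / nrow(rr)
    ys <- cum_act
    y0 <- 0
  }
  xs <- c(0, xs)
  ys <- c(y0, ys)
  # integrate the piecewise-linear y(x) against d(log10 x) over [lambda, 1]
  area <- 0
  for (i in seq_len(length(xs) - 1L)) {
    a <- xs[i]
    b <- xs[i + 1L]
    if (b <= lambda_min) next
    ya <- ys[i]
    yb <- ys[i + 1L]
    if (a < lambda_min) {
      ya <- ya + (yb - ya) * (lambda_min - a) / (b - a)
      a <- lambda_min
    }
    if (b <= a) next
    slope <- (yb - ya) / (b - a)
    area <- area + ((ya - slope * a) * log(b / a) + slope * (b - a)) / log(10)
  }
  random_area <- (1 - lambda_min) / log(10) # integral of y = x
  denom <- log10(1 / lambda_min)
  100 * (area - random_area) / denom
}

#' Full enrichment report
#'
#' @param records as for [ef_at_fraction()].
#' @param fraction EF fraction (default 0.01).
#' @param lambda_min logAUC lower limit (default 0.001).
#' @param x_axis see [adjusted_logauc()].
#' @return list of class `enrichment_report`: `adjusted_logauc`,
#'   `ef_at_fraction`, `fraction`, `lambda_min`, `n_actives`, `n_decoys`,
#'   `n_unscored`.
#' @export
enrichment_report <- function(records, fraction = 0.01, lambda_min = 0.001,
                              x_axis = "decoy") {
  counts <- check_records(records)
  out <- list(
    adjusted_logauc = adjusted_logauc(records, lambda_min, x_axis),
    ef_at_fraction = ef_at_fraction(records, fraction),
    fraction = fraction,
    lambda_min = lambda_min,
    n_actives = counts$n_actives,
    n_decoys = counts$n_decoys,
    n_unscored = sum(is.na(records$score)))
  class(out) <- "enrichment_report"
  out
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat(sprintf(
    "<enrichment_report> adjusted logAUC %.2f, EF%g%% %.2f (%d actives, %d decoys, %d unscored)\n",
    x$adjusted_logauc, 100 * x$fraction, x$ef_at_fraction, x$n_actives,
    x$n_decoys, x$n_unscored))
  invisible(x)
}
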