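#' Session counts of failed and successful reaches per paw
#'
#' @param failed_right,failed_left,successful_right,successful_left
#'   non-negative integer counts.
#' @return A list of class `session_counts`.
#' @export
session_counts <- function(failed_right = 0L, failed_left = 0L,
                           successful_right = 0L, successful_left = 0L) {
  counts <- c(failed_right = failed_right, failed_left = failed_left,
              successful_right = successful_right,
              successful_left = successful_left)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("session counts must be non-negative", call. = FALSE)
  }
  structure(as.list(counts), class = "session_counts")
}

#' Session-level training metrics
#'
#' Computes the standard single-pellet training quantities from the per-paw
#' reach counts of one session:
#' \itemize{
#'   \item total reaches = failed right + failed left + successful right +
#'     successful left;
#'   \item percentage of right reaches = (failed right + successful right) /
#'     total x 100;
#'   \item paw dominance: the dominant paw is the paw used for *more than*
#'     70% of all reaches (successful and failed) -- strictly above 70%
#'     right, strictly below 30% left, otherwise none;
#'   \item success rate = successful / (successful + failed);
#'   \item shaping criterion: at least 20 reaches in the session and a
#'     determined paw dominance;
#'   \item learner: success rate at or above the 30% literature threshold.
#' }
#' With zero total reaches the rates are undefined (`NA`) and both flags
#' are `FALSE`, with `rates_defined = FALSE`.
#'
#' @param counts a [session_counts()] (or list with the four count fields).
#' @return A list of class `session_metrics` with fields `total_reaches`,
#'   `pct_right`, `dominant_paw`, `success_rate`, `shaping_pass`, `learner`,
#'   `rates_defined`.
#' @export
compute_metrics <- function(counts) {
  fr <- counts$failed_right; fl <- counts$failed_left
  sr <- counts$successful_right; sl <- counts$successful_left
  four <- c(fr, fl, sr, sl)
  if (any(!is.finite(four)) || any(four < 0)) {
    stop("session counts must be non-negative", call. = FALSE)
  }
  total <- fr + fl + sr + sl
  if (total == 0) {
    out <- list(total_reaches = 0L, pct_right = NA_real_,
                dominant_paw = "none", success_rate = NA_real_,
                shaping_pass = FALSE, learner = FALSE,
                rates_defined = FALSE)
    class(out) <- "session_metrics"
    return(out)
  }
  pct_right <- (fr + sr) / total * 100
  dominant <- if (pct_right > 70) "right" else if (pct_right < 30) "left" else "none"
  success_rate <- (sr + sl) / total
  out <- list(
    total_reaches = as.integer(total),
    pct_right = pct_right,
    dominant_paw = dominant,
    success_rate = success_rate,
    shaping_pass = total >= 20 && dominant != "none",
    learner = success_rate >= 0.30,
    rates_defined = TRUE)
  class(out) <- "session_metrics"
  out
}

#' @export
print.session_metrics <- function(x, ...) {
  cat(sprintf(paste0("<session_metrics> %d reaches, %.1f%% right ",
                     "(dominant: %s), success rate %.2f, shaping %s, ",
                     "learner %s\n"),
              x$total_reaches,
              if (x$rates_defined) x$pct_right else NaN,
              x$dominant_paw,
              if (x$rates_defined) x$success_rate else NaN,
              if (x$shaping_pass) "pass" else "fail",
              if (x$learner) "yes" else "no"))
  invisible(x)
}

#' Cohort learning curve
#'
#' Per-day mean and standard error of a session metric across animals, the
#' summary behind 7-day training curves (total reaches or success rate per
#' day, mean +/- SEM over the cohort).
#'
#' @param values long data.frame with columns `animal`, `day`, `value`
#'   (missing sessions simply absent), or a matrix with one row per animal
#'   and one column per day.
#' @return data.frame with one row per day: `day`, `mean`,
#'   `sem` (= SD / sqrt(n); 0 with `n_flag = TRUE` when n = 1) and `n`.
#' @export
learning_curve <- function(values) {
  if (is.matrix(values)) {
    values <- data.frame(
      animal = rep(seq_len(nrow(values)), ncol(values)),
      day = rep(seq_len(ncol(values)), each = nrow(values)),
      value = as.vector(values))
  }
  stopifnot(all(c("animal", "day", "value") %in% names(values)))
  values <- values[is.finite(values$value), , drop = FALSE]
  if (nrow(values) == 0L) stop("empty cohort", call. = FALSE)
  days <- sort(unique(values$day))
  out <- do.call(rbind, lapply(days, function(d) {
    v <- values$value[values$day == d]
    n <- length(v)
    data.frame(day = d, mean = mean(v),
               sem = if (n > 1L) stats::sd(v) / sqrt(n) else 0,
               n = n, n_flag = n == 1L)
  }))
  rownames(out) <- NULL
  out
}
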