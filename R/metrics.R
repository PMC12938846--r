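## Landmark evaluation metrics: percentage of correct landmarks (PCL),
## mean position error (MPE), area under the PCL-threshold curve, and
## per-level reporting.
##
## An evaluation set is a data.frame of matched prediction / ground-truth
## pairs (matching is by slot index within each sample).  Ground-truth
## landmarks whose prediction was filtered out by the presence rule are
## kept as rows with `valid = FALSE`: they count as failures at every
## threshold and are excluded from MPE (the exclusion count is reported).

#' Build an evaluation pair table
#'
#' @param pred n x k matrix of predicted coordinates (k = 2 for pixels,
#'   3 for mm)
#' @param gt n x k matrix of ground-truth coordinates
#' @param level optional character vector of vertebral level labels
#' @param valid optional logical vector (defaults to all TRUE)
#' @return data.frame with an `error` column (Euclidean distance; NA for
#'   invalid predictions)
#' @export
eval_pairs <- function(pred, gt, level = NULL, valid = NULL) {
  pred <- as.matrix(pred); gt <- as.matrix(gt)
  stopifnot(all(dim(pred) == dim(gt)))
  n <- nrow(pred)
  if (is.null(valid)) valid <- rep(TRUE, n)
  if (is.null(level)) level <- rep("all", n)
  err <- sqrt(rowSums((pred - gt)^2))
  err[!valid] <- NA_real_
  data.frame(level = level, error = err, valid = valid)
}

#' Percentage of correct landmarks at threshold tau
#'
#' The fraction of ground-truth landmarks whose prediction lies strictly
#' within Euclidean distance `tau`; invalid (filtered) predictions count as
#' failures.
#'
#' @param pairs from [eval_pairs()]
#' @param tau threshold in the pairs' units (px or mm), > 0
#' @return fraction in `[0, 1]`
#' @export
pcl <- function(pairs, tau) {
  if (nrow(pairs) == 0) stop("empty evaluation: no landmark pairs")
  if (tau <= 0) stop("tau must be > 0")
  hits <- !is.na(pairs$error) & pairs$error < tau
  sum(hits) / nrow(pairs)
}

#' Mean position error
#'
#' Arithmetic mean of Euclidean errors over matched valid landmarks;
#' invalid predictions are excluded and their count is attached as the
#' `n_excluded` attribute.
#'
#' @param pairs from [eval_pairs()]
#' @return mean distance (px or mm)
#' @export
mpe <- function(pairs) {
  if (nrow(pairs) == 0) stop("empty evaluation: no landmark pairs")
  ok <- !is.na(pairs$error)
  if (!any(ok)) stop("empty evaluation: no valid predictions")
  structure(mean(pairs$error[ok]), n_excluded = sum(!ok))
}

#' Normalized area under the PCL curve
#'
#' Trapezoidal integral of `tau -> PCL@tau` over `[lower, upper]`, divided
#' by `upper - lower` when `normalize` (the default), so a method that is
#' perfect from the lower threshold on scores 1.
#'
#' @param pairs from [eval_pairs()]
#' @param lower,upper integration limits in the pairs' units
#' @param step integration step (default 1 unit)
#' @param normalize divide by the threshold range (default TRUE)
#' @return value in `[0, 1]` when normalized
#' @export
auc_pcl <- function(pairs, lower = 10, upper = 50, step = 1, normalize = TRUE) {
  if (lower >= upper) stop("lower must be < upper")
  if (step <= 0) stop("step must be > 0")
  taus <- seq(lower, upper, by = step)
  if (taus[length(taus)] < upper) taus <- c(taus, upper)
  p <- vapply(taus, function(t) pcl(pairs, t), numeric(1))
  area <- sum(diff(taus) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)
  if (normalize) area / (upper - lower) else area
}

#' Per-level metric report
#'
#' Groups pairs by vertebral level label and reports PCL at a threshold and
#' MPE per level, plus counts.
#'
#' @param pairs from [eval_pairs()]
#' @param tau PCL threshold (default 10)
#' @param file optional CSV path to write the table to
#' @return data.frame with columns `level, n, n_excluded, pcl, mpe`
#' @export
per_level_report <- function(pairs, tau = 10, file = NULL) {
  levels <- unique(pairs$level)
  rows <- lapply(levels, function(lv) {
    sub <- pairs[pairs$level == lv, , drop = FALSE]
    m <- tryCatch(mpe(sub), error = function(e) NA_real_)
    data.frame(level = lv, n = nrow(sub),
               n_excluded = sum(is.na(sub$error)),
               pcl = pcl(sub, tau), mpe = as.numeric(m))
  })
  out <- do.call(rbind, rows)
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}
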