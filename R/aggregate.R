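#' Aggregate a track by bin means (resampling to a fixed length)
#'
#' Splits the series into `nb` contiguous, near-equal bins (remainder
#' frames go to the leading bins) and returns the bin means. This
#' downsamples tracks of variable length and frame rate to a fixed-length
#' vector.
#'
#' @param values Numeric series (length >= `nb`).
#' @param nb Number of bins (>= 1).
#' @return Numeric vector of length `nb`.
#' @examples
#' aggregate_resample(c(1, 2, 3, 4), 2)  # 1.5 3.5
#' @export
aggregate_resample <- function(values, nb) {
  n <- length(values)
  if (nb < 1) abort("`nb` must be >= 1", class = "frailmotion_validation_error")
  if (n < nb) {
    abort(sprintf("Track of length %d cannot fill %d bins", n, nb),
          class = "frailmotion_aggregation_error")
  }
  sizes <- rep(n %/% nb, nb)
  r <- n %% nb
  if (r > 0) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
  idx <- rep.int(seq_len(nb), sizes)
  as.vector(rowsum(values, idx)) / sizes
}

#' Aggregate a track by histogram probabilities
#'
#' Computes the fraction of samples falling in each of `nb` equal-width
#' bins over a predefined range. Samples outside the range are excluded
#' from the counts but not from the denominator, so the entries sum to at
#' most 1 (exactly 1 when every sample is in range). The range is
#' predefined — in the pipeline it is fitted on the training rows and
#' frozen (see [build_feature_table()]).
#'
#' @param values Numeric series.
#' @param nb Number of bins (>= 1).
#' @param range Length-2 numeric `(lo, hi)`, `lo < hi`. Values equal to
#'   `hi` fall in the last bin.
#' @return Numeric vector of length `nb` summing to <= 1.
#' @export
aggregate_histogram <- function(values, nb, range) {
  if (nb < 1) abort("`nb` must be >= 1", class = "frailmotion_validation_error")
  if (length(range) != 2 || !is.finite(range[1]) || !is.finite(range[2]) ||
      range[1] >= range[2]) {
    abort("`range` must be finite (lo, hi) with lo < hi",
          class = "frailmotion_validation_error")
  }
  breaks <- seq(range[1], range[2], length.out = nb + 1)
  bin <- findInterval(values, breaks, rightmost.closed = TRUE)
  bin <- bin[bin >= 1 & bin <= nb]
  tabulate(bin, nbins = nb) / length(values)
}

#' Standard-scale a feature table
#'
#' Transforms each feature column to zero mean and unit variance. The mean
#' and standard deviation are estimated on `fit_rows` only (the training
#' split) and applied to all rows, so held-out subjects never influence the
#' scaling. Zero-variance features map to 0. The fitted parameters are
#' attached as attribute `"scaling"` (a tibble `feature`, `mean`, `sd`).
#'
#' @param features A feature table: tibble with metadata columns
#'   (`subject_id`, `label`, anything non-numeric) plus numeric feature
#'   columns.
#' @param fit_rows Integer/logical row subset used to fit the parameters;
#'   `NULL` fits on all rows.
#' @return The scaled feature table (same shape), with scaling parameters
#'   attached.
#' @export
standard_scale <- function(features, fit_rows = NULL) {
  features <- tibble::as_tibble(features)
  fcols <- feature_columns(features)
  if (is.null(fit_rows)) fit_rows <- seq_len(nrow(features))
  if (length(fit_rows) == 0 ||
      (is.logical(fit_rows) && !any(fit_rows))) {
    abort("`fit_rows` must select at least one row",
          class = "frailmotion_validation_error")
  }
  m <- as.matrix(features[fcols])
  fit <- m[fit_rows, , drop = FALSE]
  mu <- colMeans(fit)
  sg <- apply(fit, 2, sd)
  scaled <- sweep(m, 2, mu, "-")
  scaled <- sweep(scaled, 2, ifelse(sg > 0, sg, 1), "/")
  scaled[, sg == 0] <- 0
  features[fcols] <- as.data.frame(scaled)
  attr(features, "scaling") <- tibble::tibble(feature = fcols, mean = mu, sd = sg)
  features
}

# Feature columns = numeric columns that are not recognised metadata.
feature_columns <- function(features) {
  meta <- c("subject_id", "label", "gender", "fs", "frailty_class",
            "exercise", "repetition")
  setdiff(names(features)[vapply(features, is.numeric, logical(1))], meta)
}
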