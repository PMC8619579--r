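# Effective dimensionality of multichannel activity: the participation ratio
# of the channel covariance eigenvalues, Dim(C) = (sum lambda)^2 / sum lambda^2,
# ranging from 1 (perfectly correlated channels) to the channel count
# (independent channels of equal variance).

#' Covariance spectrum of a multichannel epoch
#'
#' Row-mean-removed sample covariance (denominator N - 1) across channels,
#' with eigenvalues from a symmetric eigendecomposition; small negative
#' eigenvalues from numerical error are clipped to zero.
#'
#' @param epoch A `recording` or a channels x samples matrix with >= 2 samples.
#' @return An object of class `covariance_spectrum`: list with `C` (channels x
#'   channels covariance) and `eigenvalues` (sorted descending).
#' @export
covariance <- function(epoch) {
  X <- as_recording_matrix(epoch)
  if (ncol(X) < 2L) stopf("need at least 2 samples to estimate a covariance")
  C <- stats::cov(t(X))
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  ev[ev < 0] <- 0
  structure(list(C = C, eigenvalues = ev), class = "covariance_spectrum")
}

#' @export
print.covariance_spectrum <- function(x, ...) {
  cat(sprintf("<covariance_spectrum> %d channels, top eigenvalues: %s\n",
              nrow(x$C),
              paste(signif(utils::head(x$eigenvalues, 4L), 4L), collapse = ", ")))
  invisible(x)
}

#' Participation-ratio dimensionality
#'
#' `Dim(C) = (sum_i lambda_i)^2 / sum_i lambda_i^2`, an effective count of
#' covariance dimensions in `[1, n_channels]`. Equals the channel count for an
#' isotropic covariance and 1 for a rank-one covariance; invariant to positive
#' rescaling of the covariance.
#'
#' @param x A `covariance_spectrum`, a covariance matrix, or anything accepted
#'   by [covariance()] (a `recording` / channels x samples matrix is treated
#'   as raw data only when non-square; square matrices are taken to be
#'   covariances).
#' @return The dimensionality (scalar).
#' @export
participation_ratio <- function(x) {
  ev <- if (inherits(x, "covariance_spectrum")) {
    x$eigenvalues
  } else if (is.matrix(x) && nrow(x) == ncol(x) &&
             isTRUE(all.equal(x, t(x), tolerance = 1e-8, check.attributes = FALSE))) {
    e <- eigen(x, symmetric = TRUE, only.values = TRUE)$values
    e[e < 0] <- 0
    e
  } else {
    covariance(x)$eigenvalues
  }
  s <- sum(ev)
  if (s <= 0) stopf("dimensionality undefined for an all-zero covariance spectrum")
  s^2 / sum(ev^2)
}

#' Per-band, per-epoch dimensionality of a recording
#'
#' Pipeline `subband filter -> segment -> covariance -> participation ratio`
#' for each requested band and epoch, plus a broadband row computed on the
#' unfiltered (typically already 0.5-30 Hz band-passed) recording.
#'
#' @param rec A `recording`.
#' @param bands List of `band_definition` (default [default_bands()]).
#' @param epoch_len_s Epoch length in seconds.
#' @param broadband Include a `"broadband"` set of rows computed without
#'   sub-band filtering.
#' @return `data.frame` with columns `subject`, `condition`, `band`, `epoch`,
#'   `dimensionality`.
#' @export
band_dimensionality <- function(rec, bands = default_bands(), epoch_len_s = 10,
                                broadband = TRUE) {
  stopifnot(inherits(rec, "recording"))
  per_band <- function(r, name) {
    eps <- segment(r, epoch_len_s)
    data.frame(subject = r$subject_id, condition = r$condition, band = name,
               epoch = seq_along(eps$epochs),
               dimensionality = vapply(eps$epochs, function(e) {
                 participation_ratio(covariance(e))
               }, numeric(1)), row.names = NULL)
  }
  rows <- list()
  if (broadband) rows$broadband <- per_band(rec, "broadband")
  for (b in bands) rows[[b$name]] <- per_band(subband(rec, b), b$name)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
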