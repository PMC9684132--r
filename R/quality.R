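# Quality measures for a CFES run: the Welch-type fat-muscle separability
# tau, the binary per-slice misclassification verdict d and its rates, and
# the relative error of the fat-ratio estimate.

#' Fat-muscle separability tau
#'
#' A Welch-statistic-like measure of how distinguishable the fat and muscle
#' grey-value peaks of a slice are:
#' \deqn{\tau = \frac{E_M - E_F}{\sqrt{S_M^2/Q_M + S_F^2/Q_F}}
#'            = \frac{\sqrt{Q}\,(E_M - E_F)}{\sqrt{S_F^2/z + S_M^2/(1-z)}}}
#' with \eqn{Q_F = zQ}, \eqn{Q_M = (1-z)Q}.  Evaluated with estimated
#' parameters it yields \eqn{\tau^*}, with the true parameters of a phantom
#' \eqn{\tau^+}.  Under the canonical orientation `e_f < e_m` it is
#' non-negative; it grows with the peak distance, shrinks with the component
#' SDs, and scales as \eqn{\sqrt{Q}}.
#'
#' @param theta a [mixture_params()] with `0 < z < 1`.
#' @param q_total total pixel count \eqn{Q > 0}.
#' @return The dimensionless separability.
#' @examples
#' separability_tau(mixture_params(-80, 50, 10, 10, 0.3), 262144)
#' @export
separability_tau <- function(theta, q_total) {
  .check_theta(theta)
  if (!is.numeric(q_total) || length(q_total) != 1L || q_total <= 0) {
    stop("`q_total` must be a single positive count", call. = FALSE)
  }
  if (theta$z <= 0 || theta$z >= 1) {
    stop("separability is undefined for z in {0, 1}", call. = FALSE)
  }
  sqrt(q_total) * (theta$e_m - theta$e_f) /
    sqrt(theta$s_f^2 / theta$z + theta$s_m^2 / (1 - theta$z))
}

#' Single-slice misclassification verdict d
#'
#' The binary verdict whether a quasi-segmentation is anatomically wrong.
#' On real scans this is an informed observer's judgement; here it is
#' operationalized against a reference label map (a phantom's ground truth
#' or an observer-supplied map): `d = 1` iff the fraction of reference
#' non-excluded pixels whose labels disagree *exceeds* `epsilon` (strict
#' inequality), else `d = 0`.  Observer verdicts recorded in a manifest can
#' bypass this oracle entirely, see [read_verdict_manifest()] and
#' [scan_pipeline()].
#'
#' @param result,reference [label_map()]s of identical shape; `reference`
#'   supplies the mask (its `LABEL_EXCLUDED` pixels are ignored).
#' @param epsilon tolerated pixel disagreement rate (default 0.02).
#' @return `0L` or `1L`.
#' @export
misclassification_d <- function(result, reference, epsilon = 0.02) {
  stopifnot(inherits(result, "label_map"), inherits(reference, "label_map"))
  if (!identical(dim(result$labels), dim(reference$labels))) {
    stop("label map shapes do not match", call. = FALSE)
  }
  m <- reference$labels != LABEL_EXCLUDED
  if (!any(m)) stop("reference has no non-excluded pixels", call. = FALSE)
  rate <- mean(result$labels[m] != reference$labels[m])
  as.integer(rate > epsilon)
}

#' Misclassification rate (mean of verdicts)
#'
#' The arithmetic mean of binary misclassification verdicts.  Applied to the
#' slices of one scan it is the per-scan rate \eqn{D}; applied to per-scan
#' rates over a sample of scans it is the sample rate \eqn{F}.
#'
#' @param d_values non-empty vector of verdicts (or of per-scan rates).
#' @return The mean rate in `[0, 1]`.
#' @export
misclassification_rate <- function(d_values) {
  if (length(d_values) == 0L) {
    stop("`d_values` must be non-empty", call. = FALSE)
  }
  if (!is.numeric(d_values) || anyNA(d_values)) {
    stop("`d_values` must be numeric without NA", call. = FALSE)
  }
  mean(d_values)
}

#' Relative error of the fat-ratio estimate
#'
#' \deqn{RE_z = |z^* - z^+| / z^+}
#'
#' @param z_true true fat ratio \eqn{z^+ > 0}.
#' @param z_est estimated fat ratio \eqn{z^*}.
#' @return The non-negative relative error.
#' @export
relative_error_z <- function(z_true, z_est) {
  if (!is.numeric(z_true) || any(z_true <= 0)) {
    stop("`z_true` must be positive", call. = FALSE)
  }
  abs(z_est - z_true) / z_true
}

#' Read an observer-verdict manifest
#'
#' A plain-text, two-column table (slice identifier, verdict 0/1) recording
#' an informed observer's misclassification judgements.  Lines starting with
#' `#` are comments.
#'
#' @param path file path.
#' @return A data frame with columns `id` (character) and `verdict`
#'   (integer 0/1).
#' @export
read_verdict_manifest <- function(path) {
  df <- read.table(path, header = FALSE, comment.char = "#",
                   col.names = c("id", "verdict"),
                   colClasses = c("character", "integer"))
  if (!all(df$verdict %in% c(0L, 1L))) {
    stop("verdicts must be 0 or 1", call. = FALSE)
  }
  df
}

#' Write a quality-record table as CSV
#'
#' Writes per-slice quality records (or any experiment table) as CSV with an
#' optional commented metadata header for provenance.
#'
#' @param records a data frame.
#' @param path output file path.
#' @param meta optional named list written as `# key: value` header lines.
#' @return `path`, invisibly.
#' @export
write_quality_csv <- function(records, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta)) {
    for (k in names(meta)) {
      writeLines(sprintf("# %s: %s", k, paste(format(meta[[k]]), collapse = " ")),
                 con)
    }
  }
  write.csv(records, con, row.names = FALSE)
  invisible(path)
}
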