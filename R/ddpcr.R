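#' Poisson-corrected mean copies per droplet
#'
#' Standard ddPCR quantification: with random partitioning, the fraction of
#' negative droplets estimates `exp(-lambda)`, so
#' `lambda = -ln((total - positive) / total)`.
#'
#' @param positive Number of positive droplets (vectorised).
#' @param total Total droplets.
#' @return Numeric mean copies per droplet.
#' @export
poisson_lambda <- function(positive, total) {
  if (any(total == 0)) stop_allelescope("empty_input", "no droplets")
  if (any(positive < 0 | positive > total)) {
    stop_allelescope("domain_error", "positive must lie in [0, total]")
  }
  if (any(positive == total)) {
    stop_allelescope("saturated",
                     "all droplets positive; lambda is unbounded")
  }
  -log((total - positive) / total)
}

#' Allelic drop-off fraction from paired ddPCR channels
#'
#' Quantifies the fraction of target (HBB) alleles that fail short-amplicon
#' droplet PCR relative to a diploid reference gene:
#' `1 - lambda_target / lambda_reference`. Alleles that fail to amplify are
#' inferred to carry large gene modifications; large deletions dominate, so
#' the pooled LD+LOA quantity is conventionally labelled LD. Technical
#' replicates are pooled by summing counts before the Poisson correction.
#' A negative point value (target above reference, sampling noise) clamps
#' to 0 with a warning.
#'
#' @param droplets Tibble with columns `channel` (`target`/`reference`),
#'   `positive`, `total`, e.g. from [simulate_droplets()]. Alternatively
#'   supply `target` and `reference` as `c(positive, total)` pairs.
#' @param target,reference Optional count pairs used when `droplets` is
#'   missing.
#' @param conf_level If non-`NULL`, delta-method confidence level for the
#'   drop-off.
#' @return A `dropoff_estimate`: list with `dropoff`, `lambda_target`,
#'   `lambda_reference`, and optionally `conf_int`.
#' @export
dropoff_fraction <- function(droplets = NULL, target = NULL, reference = NULL,
                             conf_level = NULL) {
  if (!is.null(droplets)) {
    pooled <- droplets |>
      group_by(.data$channel) |>
      summarise(positive = sum(.data$positive), total = sum(.data$total),
                .groups = "drop")
    get <- function(ch) {
      row <- pooled[pooled$channel == ch, ]
      if (nrow(row) != 1) {
        stop_allelescope("parse_error",
                         sprintf("droplets must contain channel '%s'", ch))
      }
      c(row$positive, row$total)
    }
    target <- get("target"); reference <- get("reference")
  }
  lt <- poisson_lambda(target[1], target[2])
  lr <- poisson_lambda(reference[1], reference[2])
  if (lr == 0) {
    stop_allelescope("domain_error", "reference channel has zero occupancy")
  }
  d <- 1 - lt / lr
  if (d < 0) {
    warn_allelescope("clamp",
                     sprintf("negative drop-off %.4f clamped to 0", d))
    d <- 0
  }
  out <- structure(list(dropoff = d, lambda_target = lt,
                        lambda_reference = lr, conf_int = NULL,
                        conf_level = conf_level),
                   class = "dropoff_estimate")
  if (!is.null(conf_level)) {
    # delta method: var(lambda_hat) = p / ((1 - p) n) for p = positive/total
    var_l <- function(cnt) {
      p <- cnt[1] / cnt[2]
      p / ((1 - p) * cnt[2])
    }
    vd <- (1 / lr)^2 * var_l(target) + (lt / lr^2)^2 * var_l(reference)
    z <- qnorm(1 - (1 - conf_level) / 2)
    out$conf_int <- c(max(0, d - z * sqrt(vd)), min(1, d + z * sqrt(vd)))
  }
  out
}

#' @export
print.dropoff_estimate <- function(x, ...) {
  cat(sprintf(
    "<dropoff_estimate> drop-off %.3f (lambda target %.4f / reference %.4f)%s\n",
    x$dropoff, x$lambda_target, x$lambda_reference,
    if (!is.null(x$conf_int)) {
      sprintf("; %d%% CI %.3f-%.3f", round(100 * x$conf_level),
              x$conf_int[1], x$conf_int[2])
    } else ""))
  invisible(x)
}
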