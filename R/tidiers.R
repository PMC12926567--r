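#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a LOA estimate
#'
#' @param x A `loa_estimate` from [estimate_loa()].
#' @param ... Unused.
#' @return One-row tibble with `affected`, `estimate`, `r`, `n_reads` and,
#'   when a bootstrap interval was requested, `conf_low`, `conf_high`.
#' @method tidy loa_estimate
#' @export
tidy.loa_estimate <- function(x, ...) {
  out <- tibble(affected = x$affected, estimate = x$estimate, r = x$r,
                n_reads = x$n_reads)
  if (!is.null(x$conf_int)) {
    out$conf_low <- x$conf_int[1]
    out$conf_high <- x$conf_int[2]
  }
  out
}

#' @rdname tidy.loa_estimate
#' @method glance loa_estimate
#' @export
glance.loa_estimate <- function(x, ...) tidy(x, ...)

#' Tidy a drop-off estimate
#'
#' @param x A `dropoff_estimate` from [dropoff_fraction()].
#' @param ... Unused.
#' @return One-row tibble with `dropoff`, `lambda_target`,
#'   `lambda_reference` and optional interval columns.
#' @method tidy dropoff_estimate
#' @export
tidy.dropoff_estimate <- function(x, ...) {
  out <- tibble(dropoff = x$dropoff, lambda_target = x$lambda_target,
                lambda_reference = x$lambda_reference)
  if (!is.null(x$conf_int)) {
    out$conf_low <- x$conf_int[1]
    out$conf_high <- x$conf_int[2]
  }
  out
}

#' Tidy a cluster heatmap into long format
#'
#' @param x A `cluster_heatmap`.
#' @param ... Unused.
#' @return Tibble with `bfp_level`, `gfp_level`, `value`.
#' @method tidy cluster_heatmap
#' @export
tidy.cluster_heatmap <- function(x, ...) {
  m <- unclass(x)
  attributes(m) <- attributes(m)[c("dim", "dimnames")]
  out <- as_tibble(as.table(m), .name_repair = "minimal")
  names(out) <- c("bfp_level", "gfp_level", "value")
  out$bfp_level <- factor(out$bfp_level, levels = BFP_LEVELS, ordered = TRUE)
  out$gfp_level <- factor(out$gfp_level, levels = GFP_LEVELS, ordered = TRUE)
  as_tibble(out)
}

#' Tidy a fraction table
#'
#' @param x A `fraction_table`.
#' @param ... Unused.
#' @return Tibble with `class`, `fraction`, `basis`.
#' @method tidy fraction_table
#' @export
tidy.fraction_table <- function(x, ...) {
  tibble(class = x$class, fraction = x$fraction, basis = attr(x, "basis"))
}
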