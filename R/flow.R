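#' Gate thresholds for the 4 x 5 GFP/BFP cluster grid
#'
#' Five GFP levels (`neg`, `dim`, `low`, `med`, `high`) require four
#' ascending MFI boundaries; the BFP channel resolves only four levels
#' (`neg`, `low`, `med`, `high` -- the dim and neg populations collapse
#' under spillover), requiring three. An event equal to a boundary gates
#' into the higher level.
#'
#' @param gfp_cuts Four strictly ascending MFI boundaries.
#' @param bfp_cuts Three strictly ascending MFI boundaries.
#' @return A `gate_thresholds` object.
#' @export
gate_thresholds <- function(gfp_cuts, bfp_cuts) {
  if (length(gfp_cuts) != 4 || is.unsorted(gfp_cuts, strictly = TRUE)) {
    stop_allelescope("config_error", "gfp_cuts must be 4 strictly ascending values")
  }
  if (length(bfp_cuts) != 3 || is.unsorted(bfp_cuts, strictly = TRUE)) {
    stop_allelescope("config_error", "bfp_cuts must be 3 strictly ascending values")
  }
  structure(list(gfp_cuts = as.numeric(gfp_cuts),
                 bfp_cuts = as.numeric(bfp_cuts)),
            class = "gate_thresholds")
}

#' Derive default gate thresholds from the optics model
#'
#' Places each boundary at the geometric midpoint between adjacent class
#' medians, mirroring gating on single-class control populations. The BFP
#' negative level absorbs the dim mode together with its typical spillover
#' contribution from a bright GFP allele, so its upper boundary sits between
#' that collapsed mode and the low mode.
#'
#' @param optics Optics list as in [default_optics()].
#' @return A [gate_thresholds()] object.
#' @export
derive_gate_thresholds <- function(optics = default_optics()) {
  med <- exp(optics$meanlog)[EXPRESSION_CLASSES]  # neg, dim, low, med, high order
  gfp_cuts <- sqrt(med[-1] * med[-5])
  collapsed <- med["LD"] + optics$spillover * med["IN"]
  bfp_cuts <- c(sqrt(collapsed * med["NS_LATE"]),
                sqrt(med["NS_LATE"] * med["NS_EARLY"]),
                sqrt(med["NS_EARLY"] * med["IN"]))
  gate_thresholds(unname(gfp_cuts), unname(bfp_cuts))
}

#' Assign flow events to grid clusters
#'
#' Each event's level on a channel is the number of boundaries at or below
#' its MFI (ties go to the higher level), so every finite non-negative
#' event lands in exactly one of the 20 bins.
#'
#' @param events Tibble with `gfp_mfi` and `bfp_mfi` columns.
#' @param thresholds A [gate_thresholds()].
#' @return The events tibble with ordered-factor columns `gfp_level`
#'   (`neg`/`dim`/`low`/`med`/`high`) and `bfp_level`
#'   (`neg`/`low`/`med`/`high`).
#' @export
assign_clusters <- function(events, thresholds) {
  g <- events$gfp_mfi
  b <- events$bfp_mfi
  if (any(!is.finite(g) | !is.finite(b) | g < 0 | b < 0)) {
    stop_allelescope("invalid_event", "MFIs must be finite and non-negative")
  }
  events$gfp_level <- factor(
    GFP_LEVELS[findInterval(g, thresholds$gfp_cuts) + 1L],
    levels = GFP_LEVELS, ordered = TRUE)
  events$bfp_level <- factor(
    BFP_LEVELS[findInterval(b, thresholds$bfp_cuts) + 1L],
    levels = BFP_LEVELS, ordered = TRUE)
  events
}

new_cluster_heatmap <- function(values, kind, n_events = NA_integer_) {
  structure(values, class = "cluster_heatmap", kind = kind,
            n_events = n_events)
}

#' Cluster-percentage heatmap
#'
#' Gates the events and tabulates the percentage of cells in each of the
#' 20 bins as a 4 (BFP levels, rows neg to high) x 5 (GFP levels, columns
#' neg to high) matrix mirroring the layout of the flow plots. Percentages
#' sum to 100.
#'
#' @param events Tibble with `gfp_mfi`, `bfp_mfi`.
#' @param thresholds A [gate_thresholds()].
#' @return A `cluster_heatmap` (4 x 5 numeric matrix with dimnames).
#' @export
cluster_heatmap <- function(events, thresholds) {
  if (nrow(events) == 0) stop_allelescope("empty_input", "no events")
  ev <- assign_clusters(events, thresholds)
  counts <- table(ev$bfp_level, ev$gfp_level)
  m <- matrix(as.numeric(counts), nrow = 4, ncol = 5,
              dimnames = list(bfp = BFP_LEVELS, gfp = GFP_LEVELS))
  new_cluster_heatmap(100 * m / nrow(ev), kind = "percent",
                      n_events = nrow(ev))
}

#' Fold change between two cluster heatmaps
#'
#' Elementwise ratio `b / a` of two heatmaps gated on the same grid, e.g.
#' RNP-only versus RNP+ssODN conditions. Bins empty in `a` yield `NaN`
#' (undefined, never silently dropped).
#'
#' @param heatmap_a,heatmap_b `cluster_heatmap` objects with identical
#'   layout.
#' @return A `cluster_heatmap` of ratios.
#' @export
fold_change <- function(heatmap_a, heatmap_b) {
  if (!identical(dim(heatmap_a), dim(heatmap_b)) ||
      !identical(dimnames(heatmap_a), dimnames(heatmap_b))) {
    stop_allelescope("shape_error", "heatmap layouts differ")
  }
  vals <- unclass(heatmap_b) / unclass(heatmap_a)
  vals[unclass(heatmap_a) == 0] <- NaN
  new_cluster_heatmap(vals, kind = "fold_change")
}

#' Per-cluster phenotype rates
#'
#' Percentage of phenotype-positive cells in each bin. Bins with fewer than
#' `min_events` events are flagged low-confidence (attribute
#' `low_confidence`); empty bins are `NaN`.
#'
#' @param events Tibble with `gfp_mfi`, `bfp_mfi` and a logical phenotype
#'   column.
#' @param thresholds A [gate_thresholds()].
#' @param phenotype Name of the logical phenotype column
#'   (e.g. `"hbf_pos"`, `"annexin_pos"`).
#' @param min_events Minimum events per bin for a confident rate.
#' @return A `cluster_heatmap` of percent-positive values with a logical
#'   `low_confidence` attribute matrix.
#' @export
phenotype_by_cluster <- function(events, thresholds, phenotype,
                                 min_events = 30) {
  if (nrow(events) == 0) stop_allelescope("empty_input", "no events")
  if (!phenotype %in% names(events) || !is.logical(events[[phenotype]])) {
    stop_allelescope("parse_error",
                     sprintf("events need a logical '%s' column", phenotype))
  }
  ev <- assign_clusters(events, thresholds)
  n <- table(ev$bfp_level, ev$gfp_level)
  pos <- table(ev$bfp_level[ev[[phenotype]]], ev$gfp_level[ev[[phenotype]]])
  dn <- list(bfp = BFP_LEVELS, gfp = GFP_LEVELS)
  n_m <- matrix(as.numeric(n), 4, 5, dimnames = dn)
  pos_m <- matrix(as.numeric(pos), 4, 5, dimnames = dn)
  vals <- 100 * pos_m / n_m  # NaN where empty
  out <- new_cluster_heatmap(vals, kind = paste0("percent_", phenotype),
                             n_events = nrow(ev))
  attr(out, "low_confidence") <- n_m < min_events
  out
}

#' Predict a cell's cluster from its allele expression classes
#'
#' Maps each allele's expression class to its expected fluorescence level
#' (`IN` to high, `NS_EARLY` to med, `NS_LATE` to low, `LD` to dim,
#' `LOA_CLASS` to neg) on its channel, then collapses the BFP dim level
#' into neg, reflecting the four-level BFP resolution.
#'
#' @param gfp_class,bfp_class Expression classes (vectorised).
#' @return Tibble with ordered-factor `gfp_level` and `bfp_level`.
#' @export
predict_cluster <- function(gfp_class, bfp_class) {
  map <- c(LOA_CLASS = "neg", LD = "dim", NS_LATE = "low",
           NS_EARLY = "med", IN = "high")
  g <- unname(map[gfp_class])
  b <- unname(map[bfp_class])
  b[b == "dim"] <- "neg"
  tibble(
    gfp_level = factor(g, levels = GFP_LEVELS, ordered = TRUE),
    bfp_level = factor(b, levels = BFP_LEVELS, ordered = TRUE)
  )
}

#' @export
print.cluster_heatmap <- function(x, ...) {
  cat(sprintf("<cluster_heatmap> %s%s\n", attr(x, "kind"),
              if (!is.na(attr(x, "n_events") %||% NA)) {
                sprintf(", %d events", attr(x, "n_events"))
              } else ""))
  print(round(unclass(x), 2))
  invisible(x)
}
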