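# Evaluation metrics for volumetric segmentation: Dice, Dice per case (DPC),
# global Dice (DG), volumetric overlap error (VOE), relative absolute volume
# difference (RAVD), average symmetric surface distance (ASSD) and the 95th
# percentile Hausdorff distance (HD95).
#
# Surface metrics are spacing-aware: boundaries are foreground pixels with at
# least one background face-neighbour (4-connectivity in 2D, 6-connectivity
# in 3D) and directed distances are Euclidean in physical units, computed
# with an exact distance transform.

#' Binary mask with physical spacing
#'
#' @param data logical (or 0/1) 2D or 3D array.
#' @param spacing positive physical size per axis in mm (recycled).
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(data, spacing = 1) {
  if (is.null(dim(data))) stop("mask must be a 2D or 3D array", call. = FALSE)
  nd <- length(dim(data))
  if (nd < 2L || nd > 3L) stop("mask must be 2D or 3D", call. = FALSE)
  spacing <- rep(as.numeric(spacing), length.out = nd)
  if (any(spacing <= 0)) stop("spacing must be strictly positive", call. = FALSE)
  structure(list(data = array(as.logical(data), dim(data)), spacing = spacing),
            class = "binary_mask")
}

bm <- function(x, spacing = 1) {
  if (inherits(x, "binary_mask")) x else binary_mask(x, spacing)
}

check_same_shape <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data))) {
    stop("masks must share a shape", call. = FALSE)
  }
  invisible(TRUE)
}

#' Dice similarity coefficient
#'
#' `2|A n B| / (|A| + |B|)`; two empty masks score 1 by convention.
#'
#' @param a,b binary masks ([binary_mask()] or plain logical arrays) of equal
#'   shape.
#' @return Scalar in `[0, 1]`.
#' @export
dice <- function(a, b) {
  a <- bm(a); b <- bm(b)
  check_same_shape(a, b)
  sa <- sum(a$data); sb <- sum(b$data)
  if (sa + sb == 0) return(1)
  2 * sum(a$data & b$data) / (sa + sb)
}

#' Volumetric overlap error
#'
#' `1 - |A n B| / |A u B|`; two empty masks score 0.
#'
#' @inheritParams dice
#' @return Scalar in `[0, 1]`.
#' @export
voe <- function(a, b) {
  a <- bm(a); b <- bm(b)
  check_same_shape(a, b)
  un <- sum(a$data | b$data)
  if (un == 0) return(0)
  1 - sum(a$data & b$data) / un
}

#' Relative absolute volume difference
#'
#' `||A| - |B|| / |A|` (unsigned). Undefined for an empty ground truth, which
#' returns `NA` with a warning and is excluded from aggregation.
#'
#' @param a ground-truth mask; `b` predicted mask.
#' @inheritParams dice
#' @return Scalar `>= 0`, or `NA` when `|A| = 0`.
#' @export
ravd <- function(a, b) {
  a <- bm(a); b <- bm(b)
  check_same_shape(a, b)
  sa <- sum(a$data)
  if (sa == 0) {
    warning("RAVD undefined for empty ground truth; returning NA")
    return(NA_real_)
  }
  abs(sa - sum(b$data)) / sa
}

#' Dice per case
#'
#' Mean of per-case Dice coefficients.
#'
#' @param cases list of `list(a =, b =)` mask pairs.
#' @return Scalar in `[0, 1]`.
#' @export
dpc <- function(cases) {
  if (length(cases) == 0L) stop("DPC needs at least one case", call. = FALSE)
  mean(vapply(cases, function(cs) dice(cs$a, cs$b), 0))
}

#' Global Dice
#'
#' Dice on pooled counts over the case list:
#' `2 sum_i |A_i n B_i| / (sum_i |A_i| + sum_i |B_i|)`.
#'
#' @inheritParams dpc
#' @return Scalar in `[0, 1]`.
#' @export
dg <- function(cases) {
  if (length(cases) == 0L) stop("DG needs at least one case", call. = FALSE)
  inter <- tot <- 0
  for (cs in cases) {
    a <- bm(cs$a); b <- bm(cs$b)
    check_same_shape(a, b)
    inter <- inter + sum(a$data & b$data)
    tot <- tot + sum(a$data) + sum(b$data)
  }
  if (tot == 0) return(1)
  2 * inter / tot
}

# Boundary voxels: foreground with at least one background face-neighbour
# (outside the array counts as background).
boundary_mask <- function(m) {
  d <- dim(m)
  nd <- length(d)
  interior <- array(TRUE, d)
  shift_covered <- function(axis, dir) {
    idx <- rep(list(quote(expr = )), nd)
    src <- rep(list(quote(expr = )), nd)
    n <- d[axis]
    if (n == 1L) return(array(FALSE, d))
    out <- array(FALSE, d)
    if (dir > 0) {
      idx[[axis]] <- seq_len(n - 1L)
      src[[axis]] <- seq.int(2L, n)
    } else {
      idx[[axis]] <- seq.int(2L, n)
      src[[axis]] <- seq_len(n - 1L)
    }
    out <- do.call(`[<-`, c(list(out), idx, list(value = do.call(`[`, c(list(m), src, list(drop = FALSE))))))
    out
  }
  for (axis in seq_len(nd)) {
    for (dir in c(-1, 1)) {
      interior <- interior & shift_covered(axis, dir)
    }
  }
  m & !interior
}

# Directed nearest-boundary distances from every boundary voxel of `from` to
# the boundary of `to`, in physical units.
directed_boundary_distances <- function(from, to, spacing) {
  bf <- boundary_mask(from)
  bt <- boundary_mask(to)
  d <- dim(from)
  d3 <- if (length(d) == 3L) d[3L] else 1L
  sp3 <- if (length(d) == 3L) spacing else c(spacing, 1)
  dt <- edt_cpp(as.logical(bt), d[1L], d[2L], d3, sp3)
  dt[as.logical(bf)]
}

surface_distance_sets <- function(a, b) {
  a <- bm(a); b <- bm(b)
  check_same_shape(a, b)
  if (!identical(a$spacing, b$spacing)) {
    stop("masks must share voxel spacing", call. = FALSE)
  }
  if (sum(a$data) == 0 || sum(b$data) == 0) return(NULL)
  list(
    ab = directed_boundary_distances(a$data, b$data, a$spacing),
    ba = directed_boundary_distances(b$data, a$data, a$spacing)
  )
}

#' Average symmetric surface distance
#'
#' `ASSD = (ASD(A,B) + ASD(B,A)) / 2` where each directed term averages the
#' nearest-boundary distances. Undefined when either mask is empty (`NA` with
#' a warning; excluded from aggregation).
#'
#' @inheritParams dice
#' @return Scalar distance in the mask's physical units, or `NA`.
#' @export
assd <- function(a, b) {
  ds <- surface_distance_sets(a, b)
  if (is.null(ds)) {
    warning("surface distance undefined for an empty mask; returning NA")
    return(NA_real_)
  }
  (mean(ds$ab) + mean(ds$ba)) / 2
}

#' 95th percentile Hausdorff distance
#'
#' The 95th percentile (linear interpolation between order statistics) of the
#' merged set of both directed nearest-boundary distance lists.
#'
#' @inheritParams dice
#' @return Scalar distance, or `NA` when a mask is empty.
#' @export
hd95 <- function(a, b) {
  ds <- surface_distance_sets(a, b)
  if (is.null(ds)) {
    warning("surface distance undefined for an empty mask; returning NA")
    return(NA_real_)
  }
  as.numeric(stats::quantile(c(ds$ab, ds$ba), 0.95, type = 7))
}

#' Extract class masks from an integer label volume
#'
#' LiTS convention: label 0 background, 1 liver, 2 tumor; the liver mask
#' includes tumor voxels (`label >= 1`), the tumor mask is `label == 2`.
#'
#' @param labels integer array with values in `{0, 1, 2}`.
#' @param class_spec `"liver"` or `"tumor"`.
#' @param spacing physical spacing passed to [binary_mask()].
#' @return A [binary_mask()].
#' @export
extract_class_masks <- function(labels, class_spec = c("liver", "tumor"), spacing = 1) {
  class_spec <- match.arg(class_spec)
  lv <- if (inherits(labels, "binary_mask")) labels$data else labels
  if (!all(lv %in% 0:2)) {
    stop("labels must take values in {0, 1, 2} (background, liver, tumor)", call. = FALSE)
  }
  m <- if (class_spec == "liver") lv >= 1 else lv == 2
  binary_mask(array(m, dim(lv)), spacing)
}

#' Per-case and aggregate metric report
#'
#' Computes all six metrics per case and class and the aggregate row per
#' class (DPC, DG and means of the remaining metrics over the cases where
#' they are defined).
#'
#' @param truth,pred lists of integer label volumes (equal length/shapes).
#' @param spacing voxel spacing in mm (shared).
#' @param case_ids optional case identifiers.
#' @return `list(per_case = data.frame, aggregate = data.frame)` of class
#'   `metric_report`.
#' @export
metric_report <- function(truth, pred, spacing = 1, case_ids = NULL) {
  stopifnot(length(truth) == length(pred), length(truth) >= 1L)
  if (is.null(case_ids)) case_ids <- sprintf("case_%03d", seq_along(truth))
  classes <- c("liver", "tumor")
  rows <- list()
  for (i in seq_along(truth)) {
    for (cl in classes) {
      a <- extract_class_masks(truth[[i]], cl, spacing)
      b <- extract_class_masks(pred[[i]], cl, spacing)
      rows[[length(rows) + 1L]] <- data.frame(
        case = case_ids[i], class = cl,
        dice = dice(a, b), voe = voe(a, b),
        ravd = suppressWarnings(ravd(a, b)),
        assd = suppressWarnings(assd(a, b)),
        hd95 = suppressWarnings(hd95(a, b)),
        stringsAsFactors = FALSE
      )
    }
  }
  per_case <- do.call(rbind, rows)
  agg <- lapply(classes, function(cl) {
    sub <- per_case[per_case$class == cl, ]
    pairs <- lapply(seq_along(truth), function(i) {
      list(a = extract_class_masks(truth[[i]], cl, spacing),
           b = extract_class_masks(pred[[i]], cl, spacing))
    })
    data.frame(
      class = cl, dpc = mean(sub$dice), dg = dg(pairs),
      voe = mean(sub$voe, na.rm = TRUE), ravd = mean(sub$ravd, na.rm = TRUE),
      assd = mean(sub$assd, na.rm = TRUE), hd95 = mean(sub$hd95, na.rm = TRUE),
      stringsAsFactors = FALSE
    )
  })
  out <- list(per_case = per_case, aggregate = do.call(rbind, agg))
  class(out) <- "metric_report"
  out
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Aggregate metrics:\n")
  print(x$aggregate, row.names = FALSE, digits = 4)
  cat(sprintf("(%d case rows; see $per_case)\n", nrow(x$per_case)))
  invisible(x)
}

#' Write a metric report to CSV / JSON
#'
#' @param report a [metric_report()].
#' @param csv,json optional output paths.
#' @export
write_metric_report <- function(report, csv = NULL, json = NULL) {
  if (!is.null(csv)) {
    utils::write.csv(rbind(
      cbind(section = "per_case", report$per_case[, c("case", "class")],
            report$per_case[, c("dice", "voe", "ravd", "assd", "hd95")]),
      cbind(section = "aggregate", case = "ALL", class = report$aggregate$class,
            dice = report$aggregate$dpc, voe = report$aggregate$voe,
            ravd = report$aggregate$ravd, assd = report$aggregate$assd,
            hd95 = report$aggregate$hd95)
    ), csv, row.names = FALSE)
  }
  if (!is.null(json)) {
    jsonlite::write_json(list(per_case = report$per_case,
                              aggregate = report$aggregate),
                         json, dataframe = "rows", digits = NA)
  }
  invisible(report)
}

#' Ablation delta table
#'
#' Reporting-layer arithmetic for module-removal experiments: for every
#' variant row, the gain of the full model is `full - variant` per metric for
#' Dice-type metrics (higher is better).
#'
#' @param full named numeric vector (or 1-row data frame) of the full model's
#'   aggregate metrics.
#' @param variants data frame of variant aggregates with a `method` column.
#' @param metrics metric columns to difference.
#' @return Data frame of deltas (`full - variant`), one row per variant.
#' @export
ablation_deltas <- function(full, variants,
                            metrics = intersect(c("dpc", "dg", "voe", "ravd", "assd"),
                                                names(variants))) {
  if (is.data.frame(full)) full <- unlist(full[1L, metrics, drop = FALSE])
  out <- variants[, "method", drop = FALSE]
  for (mcol in metrics) {
    out[[mcol]] <- as.numeric(full[[mcol]]) - as.numeric(variants[[mcol]])
  }
  out
}
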