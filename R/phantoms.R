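# Synthetic CT phantoms emulating LiTS-style liver/tumor cases: a bright,
# smoothly deformed elliptical "liver" on a darker background, containing
# darker tumor blobs in three clinical diameter strata (<2 cm, 2-5 cm,
# >5 cm), with per-region Hounsfield statistics, partial-volume blur of the
# intensities and optional additive Gaussian noise.

#' Phantom specification
#'
#' Default Hounsfield statistics (background -50 +/- 20, liver 100 +/- 15,
#' tumor 60 +/- 12) keep both tissues inside the [-17, 201] HU preprocessing
#' window and make the published z-normalization constants plausible.
#'
#' @param image_size square slice size in pixels.
#' @param spacing in-plane spacing in mm/pixel.
#' @param slices slices per case.
#' @param liver_axes_frac range of liver semi-axes as a fraction of the image.
#' @param tumor_count_range inclusive range of tumors per case (0-5 allowed).
#' @param tumor_stratum `"small"` (< 2 cm), `"medium"` (2-5 cm) or `"large"`
#'   (> 5 cm) maximum diameter. Sampled diameters are additionally capped at
#'   80% of the liver's minor diameter so the blob fits strictly inside; if
#'   even the stratum minimum cannot fit, generation errors.
#' @param tumor_diameter_mm optional fixed diameter (overrides the stratum
#'   sampling; must still belong to the declared stratum).
#' @param hu_background,hu_liver,hu_tumor `(mean, sd)` Hounsfield statistics.
#' @param noise_sd additive Gaussian noise SD in HU (0 = clean).
#' @param seed integer seed; regeneration with the same spec is bit-identical.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 96L,
                         spacing = 0.7676,
                         slices = 4L,
                         liver_axes_frac = c(0.30, 0.40),
                         tumor_count_range = c(1L, 3L),
                         tumor_stratum = c("medium", "small", "large"),
                         tumor_diameter_mm = NULL,
                         hu_background = c(-50, 20),
                         hu_liver = c(100, 15),
                         hu_tumor = c(60, 12),
                         noise_sd = 0,
                         seed = 42L) {
  tumor_stratum <- match.arg(tumor_stratum)
  stopifnot(image_size >= 32L, spacing > 0, slices >= 1L,
            noise_sd >= 0, length(tumor_count_range) == 2L)
  if (any(tumor_count_range < 0L) || any(tumor_count_range > 5L)) {
    stop("tumor count range must lie within 0..5", call. = FALSE)
  }
  if (abs(hu_liver[1L] - hu_tumor[1L]) < 1e-9) {
    stop("tumor and liver mean HU must differ (nonzero contrast)", call. = FALSE)
  }
  if (!is.null(tumor_diameter_mm) &&
      diameter_stratum(tumor_diameter_mm) != tumor_stratum) {
    stop(sprintf("a %.1f mm tumor is not in the '%s' stratum",
                 tumor_diameter_mm, tumor_stratum), call. = FALSE)
  }
  spec <- list(
    image_size = as.integer(image_size), spacing = spacing,
    slices = as.integer(slices), liver_axes_frac = liver_axes_frac,
    tumor_count_range = as.integer(tumor_count_range),
    tumor_stratum = tumor_stratum,
    tumor_diameter_mm = tumor_diameter_mm,
    hu_background = hu_background, hu_liver = hu_liver, hu_tumor = hu_tumor,
    noise_sd = noise_sd, seed = as.integer(seed)
  )
  class(spec) <- "phantom_spec"
  spec
}

stratum_range_mm <- function(stratum) {
  switch(stratum,
         small = c(8, 19.5),
         medium = c(20, 50),
         large = c(50.5, 75))
}

#' Diameter stratum of a tumor
#'
#' Boundary convention: `[0, 20)` mm small, `[20, 50]` mm medium,
#' `(50, Inf)` mm large (the 20 mm boundary belongs to medium, matching the
#' inclusive 2-5 cm reading).
#'
#' @param diameter_mm maximum tumor diameter in mm.
#' @return `"small"`, `"medium"` or `"large"`.
#' @export
diameter_stratum <- function(diameter_mm) {
  ifelse(diameter_mm < 20, "small", ifelse(diameter_mm <= 50, "medium", "large"))
}

# Star-shaped wobble: radius multiplier over angle built from a few low
# frequency cosine modes.
radial_wobble <- function(theta, amp, n_modes = 3L) {
  r <- rep(1, length(theta))
  for (k in seq_len(n_modes) + 1L) {
    r <- r + stats::rnorm(1L, sd = amp) * cos(k * theta + stats::runif(1L, 0, 2 * pi))
  }
  r
}

# Gaussian blur matrix with replicate borders (sigma in pixels).
gauss_matrix <- function(n, sigma = 1) {
  key <- sprintf("gm_%d_%g", n, sigma)
  m <- .dga$cache[[key]]
  if (!is.null(m)) return(m)
  half <- max(1L, ceiling(3 * sigma))
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- pmin(pmax(i + (-half:half), 1L), n)
    w <- exp(-((-half:half)^2) / (2 * sigma^2))
    for (t in seq_along(j)) m[i, j[t]] <- m[i, j[t]] + w[t]
  }
  m <- m / rowSums(m)
  .dga$cache[[key]] <- m
  m
}

#' Generate one synthetic phantom case
#'
#' @param spec a [phantom_spec()].
#' @return A list of class `phantom_case`: `hu_volume` and `label_volume`
#'   (`(slices, H, W)` arrays; labels 0 background, 1 liver, 2 tumor),
#'   `spacing`, the spec, and a `tumors` data frame (center, requested and
#'   measured diameter in mm, stratum).
#' @export
generate_case <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  local_seed(spec$seed, generate_case_impl(spec))
}

generate_case_impl <- function(spec) {
  n <- spec$image_size
  S <- spec$slices
  px <- spec$spacing
  xs <- matrix(rep(seq_len(n), each = n), n, n) # column index
  ys <- matrix(rep(seq_len(n), times = n), n, n) # row index
  cx <- n / 2 + stats::runif(1L, -0.04, 0.04) * n
  cy <- n / 2 + stats::runif(1L, -0.04, 0.04) * n
  ax <- stats::runif(1L, spec$liver_axes_frac[1L], spec$liver_axes_frac[2L]) * n
  ay <- stats::runif(1L, spec$liver_axes_frac[1L], spec$liver_axes_frac[2L]) * n
  theta <- atan2(ys - cy, xs - cx)
  wob_amp <- 0.04
  wob <- radial_wobble(as.vector(theta), wob_amp)
  rnorm2 <- sqrt(((xs - cx) / ax)^2 + ((ys - cy) / ay)^2)
  # per-slice scale shrinks the liver slightly toward the stack ends
  mid <- (S + 1) / 2
  scales <- 1 - 0.08 * abs(seq_len(S) - mid) / max(mid - 1, 1)
  liver_slices <- lapply(scales, function(sc) {
    matrix(as.vector(rnorm2) <= wob * sc, n, n)
  })

  # tumors: extruded through all slices; fully inside the smallest liver mask
  liver_core <- Reduce(`&`, liver_slices)
  n_t <- if (spec$tumor_count_range[1L] == spec$tumor_count_range[2L]) {
    spec$tumor_count_range[1L]
  } else {
    sample(seq(spec$tumor_count_range[1L], spec$tumor_count_range[2L]), 1L)
  }
  dr <- stratum_range_mm(spec$tumor_stratum)
  # cap at 80% of the liver minor diameter so the blob can fit inside
  cap_mm <- 0.8 * 2 * min(ax, ay) * min(scales) * px
  if (is.null(spec$tumor_diameter_mm) && n_t > 0L && dr[1L] > cap_mm) {
    stop(sprintf(
      "a '%s'-stratum tumor (>= %.0f mm) cannot fit this liver (cap %.1f mm); use a larger liver/image or a smaller stratum",
      spec$tumor_stratum, dr[1L], cap_mm
    ), call. = FALSE)
  }
  tumor_mask <- matrix(FALSE, n, n)
  recs <- list()
  sc_min <- min(scales)
  try_place <- function(d_try, tumor_mask) {
    r0 <- d_try / px / 2
    # feasible center region: the liver ellipse shrunk by the blob radius
    fx <- ax * sc_min - 1.15 * r0 - 2
    fy <- ay * sc_min - 1.15 * r0 - 2
    if (fx <= 0 || fy <= 0) return(NULL)
    for (try in seq_len(120L)) {
      ang <- stats::runif(1L, 0, 2 * pi)
      rad <- sqrt(stats::runif(1L))
      tx <- cx + rad * cos(ang) * fx
      ty <- cy + rad * sin(ang) * fy
      th <- atan2(ys - ty, xs - tx)
      wv <- radial_wobble(as.vector(th), 0.05)
      rr <- sqrt((xs - tx)^2 + (ys - ty)^2)
      cand_r <- r0 * matrix(wv, n, n)
      # rescale the wobble so the maximum opposite-radius sum (the caliper
      # diameter of the star-shaped blob) matches the requested diameter
      tg <- seq(0, 2 * pi, length.out = 361L)[-361L]
      wt <- approx_wobble(th, wv, tg)
      fer <- max(wt[1:180] + wt[181:360])
      cand_r <- cand_r * 2 / fer
      cand <- rr <= cand_r
      if (!any(cand)) next
      if (all(liver_core[cand]) && !any(tumor_mask[cand])) {
        return(list(cand = cand, tx = tx, ty = ty))
      }
    }
    NULL
  }
  # The case's stratum is set by its largest lesion, so only the first tumor
  # must hit the declared stratum; secondary lesions are smaller (as in real
  # multifocal cases) and are dropped when the liver is too crowded.
  d_first <- NA_real_
  for (t in seq_len(n_t)) {
    fixed <- !is.null(spec$tumor_diameter_mm)
    first <- t == 1L
    d_mm <- if (fixed) {
      spec$tumor_diameter_mm
    } else if (first) {
      stats::runif(1L, dr[1L], max(dr[1L], min(dr[2L], cap_mm)))
    } else {
      stats::runif(1L, 6, max(6, min(d_first, cap_mm)))
    }
    floor_mm <- if (first) dr[1L] else 6
    d_try <- d_mm
    hit <- NULL
    repeat {
      hit <- try_place(d_try, tumor_mask)
      if (!is.null(hit) || fixed) break
      if (d_try <= floor_mm + 1e-9) break # back off before giving up
      d_try <- max(floor_mm, 0.85 * d_try)
    }
    if (is.null(hit)) {
      if (!first && !fixed) next # crowded liver: drop the secondary lesion
      stop(sprintf(
        "could not place a %.1f mm tumor inside the liver; use a larger liver/image or a smaller stratum",
        d_try
      ), call. = FALSE)
    }
    if (first) d_first <- d_try
    tumor_mask <- tumor_mask | hit$cand
    recs[[length(recs) + 1L]] <- data.frame(
      center_x = hit$tx, center_y = hit$ty, requested_mm = d_try,
      measured_mm = feret_diameter(hit$cand, px),
      stratum = diameter_stratum(d_try), stringsAsFactors = FALSE
    )
  }

  hu <- array(0, c(S, n, n))
  lab <- array(0L, c(S, n, n))
  G <- gauss_matrix(n, 1)
  for (s in seq_len(S)) {
    lv <- liver_slices[[s]]
    tm <- tumor_mask & lv
    img <- matrix(stats::rnorm(n * n, spec$hu_background[1L], spec$hu_background[2L]), n, n)
    img[lv] <- stats::rnorm(sum(lv), spec$hu_liver[1L], spec$hu_liver[2L])
    img[tm] <- stats::rnorm(sum(tm), spec$hu_tumor[1L], spec$hu_tumor[2L])
    img <- G %*% img %*% t(G) # partial-volume blur of intensities only
    if (spec$noise_sd > 0) {
      img <- img + matrix(stats::rnorm(n * n, 0, spec$noise_sd), n, n)
    }
    hu[s, , ] <- img
    l <- matrix(0L, n, n)
    l[lv] <- 1L
    l[tm] <- 2L
    lab[s, , ] <- l
  }
  tumors <- if (length(recs)) do.call(rbind, recs) else
    data.frame(center_x = numeric(0), center_y = numeric(0),
               requested_mm = numeric(0), measured_mm = numeric(0),
               stratum = character(0), stringsAsFactors = FALSE)
  out <- list(hu_volume = hu, label_volume = lab, spacing = px,
              spec = spec, tumors = tumors)
  class(out) <- "phantom_case"
  out
}

# Wobble value at arbitrary angles, interpolated from the per-pixel field.
approx_wobble <- function(theta_field, wobble_field, angles) {
  o <- order(as.vector(theta_field))
  th <- as.vector(theta_field)[o]
  wv <- wobble_field[o]
  idx <- findInterval(((angles + pi) %% (2 * pi)) - pi, th, all.inside = TRUE)
  wv[idx]
}

#' Maximum Feret (caliper) diameter of a 2D mask
#'
#' Maximum pairwise distance between boundary pixel centers plus one pixel
#' (accounting for pixel extent), in physical units.
#'
#' @param mask logical matrix.
#' @param spacing mm per pixel.
#' @return Diameter in mm (0 for an empty mask).
#' @export
feret_diameter <- function(mask, spacing = 1) {
  if (!any(mask)) return(0)
  b <- boundary_mask(mask)
  idx <- which(b, arr.ind = TRUE)
  if (nrow(idx) == 1L) return(spacing)
  hull <- grDevices::chull(idx[, 1L], idx[, 2L])
  pts <- idx[hull, , drop = FALSE]
  dmax <- max(stats::dist(pts))
  (dmax + 1) * spacing
}

#' Connected components of a 2D mask (4-connectivity)
#'
#' @param mask logical matrix.
#' @return Integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask) {
  d <- dim(mask)
  lab <- matrix(0L, d[1L], d[2L])
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- (p - 1L) %% d[1L] + 1L
      cc <- (p - 1L) %/% d[1L] + 1L
      for (nb in list(c(r - 1L, cc), c(r + 1L, cc), c(r, cc - 1L), c(r, cc + 1L))) {
        if (nb[1L] < 1L || nb[1L] > d[1L] || nb[2L] < 1L || nb[2L] > d[2L]) next
        q <- (nb[2L] - 1L) * d[1L] + nb[1L]
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- cur
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}

#' Add Gaussian noise to a phantom case
#'
#' Adds i.i.d. `N(0, sd^2)` HU noise to the intensity volume; labels are
#' untouched.
#'
#' @param case a [generate_case()] result.
#' @param sd noise standard deviation in HU (`>= 0`).
#' @param seed optional seed for the noise draw (default: derived from the
#'   case seed so repeated calls are deterministic).
#' @return The noisy `phantom_case`.
#' @export
add_gaussian_noise <- function(case, sd, seed = NULL) {
  stopifnot(inherits(case, "phantom_case"))
  if (sd < 0) stop("noise sd must be non-negative", call. = FALSE)
  if (sd == 0) return(case)
  if (is.null(seed)) seed <- (case$spec$seed + 777L) %% .Machine$integer.max
  local_seed(seed, {
    case$hu_volume <- case$hu_volume +
      array(stats::rnorm(length(case$hu_volume), 0, sd), dim(case$hu_volume))
  })
  case
}

#' Stratify cases by maximum tumor diameter
#'
#' Assigns each case to the stratum of its largest tumor (measured maximum
#' Feret diameter); cases without tumors are dropped with a note attribute.
#'
#' @param cases list of `phantom_case` objects.
#' @param strata stratum names to keep.
#' @return Named list mapping stratum to the indices of its cases.
#' @export
stratify_cases <- function(cases, strata = c("small", "medium", "large")) {
  idx <- lapply(strata, function(s) integer(0))
  names(idx) <- strata
  for (i in seq_along(cases)) {
    tu <- cases[[i]]$tumors
    if (nrow(tu) == 0L) next
    s <- diameter_stratum(max(tu$measured_mm))
    if (s %in% strata) idx[[s]] <- c(idx[[s]], i)
  }
  idx
}
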