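#' Binary cortical cross-section mask
#'
#' Wraps a binary pixel grid (TRUE = cortex) with its physical pixel size
#' and the in-plane anterior reference direction. Grids use matrix
#' convention: rows are y, columns are x; angles are measured
#' counterclockwise from the anterior direction.
#'
#' @param grid logical or 0/1 matrix, TRUE/1 = cortex.
#' @param pixel_size_um pixel edge length, micrometers.
#' @param anterior_deg angle of the anterior direction from the +x axis,
#'   degrees.
#' @param id optional specimen id.
#' @return Object of class `cross_section_mask`.
#' @export
cross_section_mask <- function(grid, pixel_size_um, anterior_deg = 0,
                               id = NULL) {
  if (pixel_size_um <= 0) stop_input("pixel_size_um must be > 0")
  grid <- grid != 0
  if (!any(grid)) stop_input("mask contains no cortex pixels")
  structure(list(grid = grid, pixel_size_um = pixel_size_um,
                 anterior_deg = anterior_deg, id = id),
            class = "cross_section_mask")
}

#' Read a cross-section mask from file
#'
#' Supports whitespace-delimited 0/1 text grids, and single-channel PNG or
#' TIFF images (nonzero = cortex) when the `png`/`tiff` packages are
#' available.
#'
#' @param path file path (`.txt`, `.png`, `.tif`/`.tiff`).
#' @param pixel_size_um pixel edge length, micrometers.
#' @param ... passed to [cross_section_mask()].
#' @return A `cross_section_mask`.
#' @export
read_mask <- function(path, pixel_size_um, ...) {
  ext <- tolower(tools::file_ext(path))
  grid <- switch(ext,
    txt = as.matrix(read.table(path)),
    png = {
      if (!requireNamespace("png", quietly = TRUE)) {
        stop_input("reading PNG masks needs the png package")
      }
      img <- png::readPNG(path)
      if (length(dim(img)) == 3) img <- img[, , 1]
      img > 0
    },
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop_input("reading TIFF masks needs the tiff package")
      }
      img <- tiff::readTIFF(path)
      if (length(dim(img)) == 3) img <- img[, , 1]
      img > 0
    },
    stop_input("unsupported mask format: .%s", ext))
  cross_section_mask(grid, pixel_size_um,
                     id = sub("\\.[^.]*$", "", basename(path)), ...)
}

#' Segment a mask into cortex, marrow and outside
#'
#' Background pixels are labelled by connected components (4-connectivity
#' via `EBImage::bwlabel`); components touching the grid border are
#' outside, the single enclosed component is the marrow cavity. The cortex
#' must form exactly one connected component enclosing exactly one cavity,
#' otherwise a topology error is raised (e.g. a cortical break lets the
#' cavity leak to the outside).
#'
#' @param mask a [cross_section_mask()].
#' @return Object of class `cortical_section`: integer `labels` matrix
#'   (0 = outside, 1 = cortex, 2 = marrow) plus pixel size and metadata.
#' @export
segment_compartments <- function(mask) {
  if (!inherits(mask, "cross_section_mask")) {
    stop_input("mask must be a cross_section_mask")
  }
  g <- mask$grid
  cortex_lab <- EBImage::bwlabel(g * 1L)
  n_cortex <- max(cortex_lab)
  if (n_cortex != 1) {
    stop_input("topology error: expected 1 cortex component, found %d", n_cortex)
  }
  bg_lab <- EBImage::bwlabel((!g) * 1L)
  border <- unique(c(bg_lab[1, ], bg_lab[nrow(g), ], bg_lab[, 1],
                     bg_lab[, ncol(g)]))
  border <- border[border > 0]
  inner <- setdiff(seq_len(max(bg_lab)), border)
  if (length(inner) == 0) {
    stop_input("topology error: cortex does not enclose a marrow cavity")
  }
  if (length(inner) > 1) {
    stop_input("topology error: cortex encloses %d cavities, expected 1",
               length(inner))
  }
  labels <- matrix(0L, nrow(g), ncol(g))
  labels[g] <- 1L
  labels[bg_lab == inner] <- 2L
  structure(list(labels = labels, pixel_size_um = mask$pixel_size_um,
                 anterior_deg = mask$anterior_deg, id = mask$id),
            class = "cortical_section")
}

# pixel-center coordinates (x = column, y = row), in pixels
pixel_centers <- function(labels, which_labels) {
  hit <- matrix(labels %in% which_labels, nrow(labels))
  idx <- which(hit, arr.ind = TRUE)
  data.frame(x = idx[, 2], y = idx[, 1])
}

#' Area centroid of the total section
#'
#' Mean of the pixel centers of cortex plus marrow (the total section), in
#' pixels and millimeters. Set `of = "cortex"` for the cortex-only
#' centroid.
#'
#' @param section a [segment_compartments()] result.
#' @param of `"total"` (default) or `"cortex"`.
#' @return List with `x_px`, `y_px`, `x_mm`, `y_mm`.
#' @export
compute_centroid <- function(section, of = c("total", "cortex")) {
  of <- match.arg(of)
  lab <- if (of == "total") c(1L, 2L) else 1L
  pc <- pixel_centers(section$labels, lab)
  px_mm <- section$pixel_size_um / 1000
  list(x_px = mean(pc$x), y_px = mean(pc$y),
       x_mm = mean(pc$x) * px_mm, y_mm = mean(pc$y) * px_mm)
}

# bilinear interpolation of matrix m at (x = col, y = row) point sets
bilinear <- function(m, x, y) {
  x0 <- floor(x); y0 <- floor(y)
  x0 <- pmin(pmax(x0, 1L), ncol(m) - 1L)
  y0 <- pmin(pmax(y0, 1L), nrow(m) - 1L)
  fx <- x - x0; fy <- y - y0
  i00 <- cbind(y0, x0); i01 <- cbind(y0, x0 + 1L)
  i10 <- cbind(y0 + 1L, x0); i11 <- cbind(y0 + 1L, x0 + 1L)
  m[i00] * (1 - fx) * (1 - fy) + m[i01] * fx * (1 - fy) +
    m[i10] * (1 - fx) * fy + m[i11] * fx * fy
}

#' Radial profile of a cortical section
#'
#' Casts `n_angles` rays from the centroid (0.5-degree steps by default,
#' measured counterclockwise from the anterior direction) and records, per
#' ray, the endocortical radius (first marrow-to-cortex crossing) and the
#' periosteal radius (last cortex-to-outside crossing). Crossings are the
#' 0.5-level of the bilinearly interpolated cortex indicator, located by
#' linear interpolation between ray samples.
#'
#' @param section a [segment_compartments()] result.
#' @param centroid optional centroid (defaults to the total-section
#'   centroid).
#' @param n_angles number of rays (720 gives 0.5-degree steps).
#' @param step_px radial sampling step, pixels.
#' @return Object of class `radial_profile`: data.frame `angle_deg`,
#'   `endo_mm`, `peri_mm` with the centroid as attribute.
#' @export
radial_profile <- function(section, centroid = NULL, n_angles = 720,
                           step_px = 0.25) {
  if (is.null(centroid)) centroid <- compute_centroid(section)
  g <- (section$labels == 1L) * 1
  cx <- centroid$x_px; cy <- centroid$y_px
  at_centroid <- section$labels[round(cy), round(cx)]
  if (at_centroid == 0L) stop_input("centroid lies outside the section")

  r_max <- sqrt(nrow(g)^2 + ncol(g)^2)
  r <- seq(0, r_max, by = step_px)
  theta <- (section$anterior_deg + (seq_len(n_angles) - 1) * 360 / n_angles) *
    pi / 180
  px_mm <- section$pixel_size_um / 1000

  endo <- numeric(n_angles)
  peri <- numeric(n_angles)
  for (a in seq_len(n_angles)) {
    x <- cx + r * cos(theta[a])
    y <- cy + r * sin(theta[a])
    keep <- x >= 1 & x <= ncol(g) & y >= 1 & y <= nrow(g)
    v <- bilinear(g, x[keep], y[keep])
    rr <- r[keep]
    up <- which(v[-1] >= 0.5 & v[-length(v)] < 0.5)
    dn <- which(v[-1] < 0.5 & v[-length(v)] >= 0.5)
    if (!length(dn) || (v[1] < 0.5 && !length(up))) {
      stop_input("ray at %.1f degrees never crosses the cortex",
                 theta[a] * 180 / pi)
    }
    cross_at <- function(i) {
      t <- (0.5 - v[i]) / (v[i + 1] - v[i])
      rr[i] + t * (rr[i + 1] - rr[i])
    }
    endo[a] <- if (v[1] >= 0.5) 0 else cross_at(up[1])
    peri[a] <- cross_at(dn[length(dn)])
  }
  prof <- data.frame(angle_deg = (seq_len(n_angles) - 1) * 360 / n_angles,
                     endo_mm = endo * px_mm, peri_mm = peri * px_mm)
  attr(prof, "centroid") <- centroid
  class(prof) <- c("radial_profile", "data.frame")
  prof
}

# marching-squares contour length of a binary indicator, after 3x3 box
# smoothing (raw binary contours overestimate circle perimeters by ~6%;
# presmoothing brings discs within ~1% of the closed form)
contour_perimeter <- function(indicator, px_mm) {
  m <- indicator * 1
  sm <- matrix(0, nrow(m), ncol(m))
  cnt <- matrix(0, nrow(m), ncol(m))
  for (di in -1:1) for (dj in -1:1) {
    i1 <- max(1, 1 + di); i2 <- min(nrow(m), nrow(m) + di)
    j1 <- max(1, 1 + dj); j2 <- min(ncol(m), ncol(m) + dj)
    sm[i1:i2, j1:j2] <- sm[i1:i2, j1:j2] + m[(i1:i2) - di, (j1:j2) - dj]
    cnt[i1:i2, j1:j2] <- cnt[i1:i2, j1:j2] + 1
  }
  sm <- sm / cnt
  cl <- contourLines(x = seq_len(nrow(m)), y = seq_len(ncol(m)), z = sm,
                     levels = 0.5)
  if (!length(cl)) stop_input("no contour found")
  sum(vapply(cl, function(s) {
    sum(sqrt(diff(s$x)^2 + diff(s$y)^2))
  }, numeric(1))) * px_mm
}

#' Cortical geometry metrics from a segmented section
#'
#' Areas are pixel counts times pixel area; perimeters are
#' marching-squares contour lengths of the periosteal (total section) and
#' endocortical (marrow) boundaries; cortical thickness is the mean over
#' angles of the periosteal minus endocortical radius from the radial
#' profile.
#'
#' @param section a [segment_compartments()] result.
#' @param profile optional precomputed [radial_profile()].
#' @return One-row data.frame: `Tt.Ar`, `Ma.Ar`, `Ct.Ar` (mm^2),
#'   `Ct.Ar_Tt.Ar` (%), `Ct.Th` (mm), `Ps.Pm`, `Ec.Pm` (mm).
#' @export
geometry_metrics <- function(section, profile = NULL) {
  px_mm <- section$pixel_size_um / 1000
  a <- px_mm^2
  n_ct <- sum(section$labels == 1L)
  n_ma <- sum(section$labels == 2L)
  if (is.null(profile)) profile <- radial_profile(section)
  data.frame(
    Tt.Ar = (n_ct + n_ma) * a,
    Ma.Ar = n_ma * a,
    Ct.Ar = n_ct * a,
    Ct.Ar_Tt.Ar = 100 * n_ct / (n_ct + n_ma),
    Ct.Th = mean(profile$peri_mm - profile$endo_mm),
    Ps.Pm = contour_perimeter(section$labels >= 1L, px_mm),
    Ec.Pm = contour_perimeter(section$labels == 2L, px_mm))
}

#' Principal second moments of area of the cortex
#'
#' Second moments of the cortex pixel region about its own centroid, by
#' pixel summation with the per-pixel self moment (`p^4/12`) included;
#' `Imax`/`Imin` are the eigenvalues of the 2x2 inertia tensor.
#'
#' @param section a [segment_compartments()] result.
#' @return Named numeric vector `c(Imax, Imin)`, mm^4.
#' @export
moments_of_inertia <- function(section) {
  px_mm <- section$pixel_size_um / 1000
  pc <- pixel_centers(section$labels, 1L)
  x <- (pc$x - mean(pc$x)) * px_mm
  y <- (pc$y - mean(pc$y)) * px_mm
  a <- px_mm^2
  self <- px_mm^4 / 12
  ixx <- sum(y^2) * a + length(x) * self
  iyy <- sum(x^2) * a + length(x) * self
  ixy <- sum(x * y) * a
  mid <- (ixx + iyy) / 2
  rad <- sqrt(((ixx - iyy) / 2)^2 + ixy^2)
  c(Imax = mid + rad, Imin = mid - rad)
}

#' Average radial profiles across animals
#'
#' Per-angle mean of the endocortical and periosteal radii over a group of
#' animals, the construction behind group-average cross-section (radar)
#' plots: each animal contributes one profile, then the group average is
#' taken.
#'
#' @param profiles list of [radial_profile()] objects on a common angular
#'   grid.
#' @return A `radial_profile` with the per-angle group means and attribute
#'   `n_animals`.
#' @export
average_profile <- function(profiles) {
  if (!length(profiles)) stop_input("need at least one profile")
  ref <- profiles[[1]]$angle_deg
  for (p in profiles) {
    if (!isTRUE(all.equal(p$angle_deg, ref))) {
      stop_input("profiles are on different angular grids")
    }
  }
  endo <- rowMeans(sapply(profiles, function(p) p$endo_mm))
  peri <- rowMeans(sapply(profiles, function(p) p$peri_mm))
  out <- data.frame(angle_deg = ref, endo_mm = endo, peri_mm = peri)
  attr(out, "n_animals") <- length(profiles)
  class(out) <- c("radial_profile", "data.frame")
  out
}

#' All cortical metrics for one mask
#'
#' Convenience wrapper: segment, profile, metrics and moments in one call.
#'
#' @param mask a [cross_section_mask()].
#' @return One-row data.frame with the [geometry_metrics()] columns plus
#'   `Imax` and `Imin`.
#' @export
cortical_metrics <- function(mask) {
  section <- segment_compartments(mask)
  prof <- radial_profile(section)
  cbind(geometry_metrics(section, prof), t(moments_of_inertia(section)))
}
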