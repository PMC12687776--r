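#' Trim the compliance toe and zero a bend curve at the preload
#'
#' Samples before the force first reaches the lower preload bound are
#' discarded and displacement is re-zeroed at the preload crossing. If the
#' crossing falls between samples it is located by linear interpolation and
#' an interpolated sample is inserted at displacement zero. Trailing
#' post-failure samples are kept so failure detection can see them.
#'
#' @param curve data.frame with `displacement_um` (strictly increasing)
#'   and `force_n`.
#' @param preload lower preload bound, N.
#' @return The trimmed, re-zeroed curve (attribute `zero_um` records the
#'   absolute displacement of the new zero).
#' @export
preprocess_curve <- function(curve, preload = 0.2) {
  d <- curve$displacement_um
  f <- curve$force_n
  if (length(d) < 2 || any(diff(d) <= 0)) {
    stop_input("displacement must be strictly increasing")
  }
  i <- which(f >= preload)[1]
  if (is.na(i)) stop_input("force never reaches the %.2f N preload; unusable curve",
                           preload)
  if (i == 1 || f[i] == preload) {
    zero <- d[i]
    keep <- seq(i, length(d))
    out <- data.frame(displacement_um = d[keep] - zero, force_n = f[keep])
  } else {
    t <- (preload - f[i - 1]) / (f[i] - f[i - 1])
    zero <- d[i - 1] + t * (d[i] - d[i - 1])
    keep <- seq(i, length(d))
    out <- data.frame(displacement_um = c(0, d[keep] - zero),
                      force_n = c(preload, f[keep]))
  }
  attr(out, "zero_um") <- zero
  class(out) <- c("bend_curve", "data.frame")
  out
}

#' Beam-theory stress-strain transform for three-point bending
#'
#' Standard three-point-bend beam equations at midspan:
#' stress `sigma = F L c / (4 I)` (MPa with F in N, lengths in mm) and
#' strain `epsilon = 6 c d / L^2` (reported in microstrain). The transform
#' is pointwise and preserves the sample count.
#'
#' @param curve preprocessed bend curve.
#' @param span_mm support span L, mm.
#' @param c_mm distance from the section centroid to the surface along the
#'   loading direction, mm.
#' @param i_mm4 second moment of area about the bending axis, mm^4 (the
#'   minimum principal moment for anterior-posterior loading).
#' @return data.frame with `strain_ue` and `stress_mpa`.
#' @export
to_stress_strain <- function(curve, span_mm, c_mm, i_mm4) {
  if (span_mm <= 0 || c_mm <= 0 || i_mm4 <= 0) {
    stop_input("span, c and I must all be positive")
  }
  data.frame(
    strain_ue = 6 * c_mm * curve$displacement_um * 1000 / span_mm^2,
    stress_mpa = curve$force_n * span_mm * c_mm / (4 * i_mm4))
}

# windowed least squares: slope and R^2 from cumulative sums
window_fit <- function(cs, i, j) {
  n <- j - i + 1
  sx <- cs$x[j + 1] - cs$x[i]
  sy <- cs$y[j + 1] - cs$y[i]
  sxx <- cs$xx[j + 1] - cs$xx[i]
  syy <- cs$yy[j + 1] - cs$yy[i]
  sxy <- cs$xy[j + 1] - cs$xy[i]
  vx <- sxx - sx^2 / n
  vy <- syy - sy^2 / n
  cxy <- sxy - sx * sy / n
  slope <- cxy / vx
  # a flat-force window explains nothing about stiffness: score it 0
  r2 <- if (vy <= 0) 0 else min(1, max(0, cxy^2 / (vx * vy)))
  list(slope = slope, r2 = r2)
}

#' Fit stiffness on the linear portion of a bend curve
#'
#' Deterministic window search: among contiguous sample windows spanning at
#' least `min_frac` of the pre-ultimate samples whose forces lie between
#' `f_lo` and `f_hi` of the ultimate force, the window maximizing the
#' regression R-squared is chosen; exact ties are broken toward the
#' earlier start, then the larger window, so on an ideal piecewise-linear
#' curve the elastic (first) segment is selected rather than an equally
#' linear post-yield segment. Stiffness is that window's least-squares
#' slope.
#'
#' @param curve preprocessed bend curve.
#' @param f_lo,f_hi force bounds as fractions of ultimate force.
#' @param min_frac minimum window length as a fraction of pre-ultimate
#'   samples.
#' @param r2_min below this R-squared a low-linearity warning is issued
#'   (the best window is still used).
#' @return List with `stiffness_n_mm`, `window` (index range), `r2`,
#'   `low_linearity`.
#' @export
fit_stiffness <- function(curve, f_lo = 0.10, f_hi = 0.90, min_frac = 0.15,
                          r2_min = 0.90) {
  d <- curve$displacement_um / 1000  # mm, so slope is N/mm
  f <- curve$force_n
  iult <- which.max(f)
  if (iult < 20) stop_input("need at least 20 samples before the ultimate point")
  f_ult <- f[iult]
  eligible <- which(seq_along(f) <= iult & f >= f_lo * f_ult & f <= f_hi * f_ult)
  if (length(eligible) < 2) stop_input("no linear window candidates")
  min_len <- max(2L, ceiling(min_frac * iult))

  # contiguous runs of eligible indices
  runs <- split(eligible, cumsum(c(1, diff(eligible) != 1)))
  best <- NULL
  for (run in runs) {
    if (length(run) < min_len) next
    lo <- run[1]
    x <- d[run]; y <- f[run]
    cs <- list(x = c(0, cumsum(x)), y = c(0, cumsum(y)),
               xx = c(0, cumsum(x^2)), yy = c(0, cumsum(y^2)),
               xy = c(0, cumsum(x * y)))
    nr <- length(run)
    for (i in seq_len(nr - min_len + 1)) {
      for (j in seq(i + min_len - 1, nr)) {
        w <- window_fit(cs, i, j)
        cand <- list(r2 = w$r2, len = j - i + 1, start = lo + i - 1,
                     slope = w$slope, window = c(lo + i - 1, lo + j - 1))
        if (is.null(best) ||
            cand$r2 > best$r2 + 1e-12 ||
            (abs(cand$r2 - best$r2) <= 1e-12 &&
             (cand$start < best$start ||
              (cand$start == best$start && cand$len > best$len)))) {
          best <- cand
        }
      }
    }
  }
  if (is.null(best)) stop_input("no window of at least %d samples in the force band",
                                min_len)
  low <- best$r2 < r2_min
  if (low) {
    warning(sprintf("low linearity: best window R^2 = %.3f", best$r2),
            call. = FALSE)
  }
  list(stiffness_n_mm = best$slope, window = best$window, r2 = best$r2,
       low_linearity = low)
}

#' Elastic modulus from beam theory
#'
#' `E = k L^3 / (48 I)`, reported in GPa.
#'
#' @param stiffness_n_mm stiffness, N/mm.
#' @param span_mm support span, mm.
#' @param i_mm4 second moment of area, mm^4.
#' @return Modulus in GPa.
#' @export
beam_modulus <- function(stiffness_n_mm, span_mm, i_mm4) {
  stiffness_n_mm * span_mm^3 / (48 * i_mm4) / 1000
}

#' Locate the 0.2 percent offset yield point
#'
#' Intersects the stress-strain curve with the elastic line offset by
#' 2000 microstrain: `sigma = S (eps - offset)`, `S` the elastic
#' stress-strain slope in MPa per unit strain. The first crossing is
#' located by linear interpolation between the bracketing samples; the
#' same interpolation fraction defines yield on the force-displacement
#' curve. A curve that never crosses the offset line before failure (e.g.
#' perfectly linear to break) gets `no_yield = TRUE` with yield set at the
#' ultimate point.
#'
#' @param ss stress-strain curve from [to_stress_strain()].
#' @param slope_mpa elastic slope of the stress-strain curve, MPa per unit
#'   strain.
#' @param offset_ue offset, microstrain.
#' @param end_index last sample to search (the failure index).
#' @return List with `index` (left bracket), `frac` (interpolation
#'   fraction), `strain_ue`, `stress_mpa`, `no_yield`.
#' @export
find_yield <- function(ss, slope_mpa, offset_ue = 2000,
                       end_index = nrow(ss)) {
  eps <- ss$strain_ue[seq_len(end_index)]
  sig <- ss$stress_mpa[seq_len(end_index)]
  line <- slope_mpa * (eps - offset_ue) * 1e-6
  g <- sig - line
  below <- which(g <= 0)
  below <- below[below > 1]
  if (!length(below)) {
    k <- which.max(sig)
    return(list(index = k, frac = 0, strain_ue = eps[k], stress_mpa = sig[k],
                no_yield = TRUE))
  }
  k <- below[1]
  t <- g[k - 1] / (g[k - 1] - g[k])
  list(index = k - 1L, frac = t,
       strain_ue = eps[k - 1] + t * (eps[k] - eps[k - 1]),
       stress_mpa = sig[k - 1] + t * (sig[k] - sig[k - 1]),
       no_yield = FALSE)
}

#' Locate the ultimate and failure points
#'
#' Ultimate is the maximum force (first occurrence on ties). Failure is
#' the first post-ultimate sample where force drops below `drop_frac` of
#' the ultimate force; if force never drops that far the last sample is
#' used and the curve is flagged `no_failure` (such specimens are excluded
#' downstream, mirroring tests stopped at maximum machine displacement).
#'
#' @param curve preprocessed bend curve.
#' @param drop_frac failure threshold as a fraction of ultimate force.
#' @return List with `ultimate_index`, `failure_index`, `no_failure`.
#' @export
find_ultimate_failure <- function(curve, drop_frac = 0.10) {
  f <- curve$force_n
  iult <- which.max(f)
  post <- which(seq_along(f) > iult & f < drop_frac * f[iult])
  if (length(post)) {
    list(ultimate_index = iult, failure_index = post[1], no_failure = FALSE)
  } else {
    list(ultimate_index = iult, failure_index = length(f), no_failure = TRUE)
  }
}

trapz <- function(x, y) {
  if (length(x) < 2) return(0)
  sum((y[-1] + y[-length(y)]) / 2 * diff(x))
}

# area under (x, y) from the start to interpolated point (index k, fraction t)
area_to <- function(x, y, k, t) {
  xs <- x[seq_len(k)]
  ys <- y[seq_len(k)]
  if (t > 0 && k < length(x)) {
    xs <- c(xs, x[k] + t * (x[k + 1] - x[k]))
    ys <- c(ys, y[k] + t * (y[k + 1] - y[k]))
  }
  trapz(xs, ys)
}

#' Extract the full mechanical property panel from a bend curve
#'
#' Runs preprocessing, the stress-strain transform, stiffness fitting,
#' offset-yield and ultimate/failure detection, then reads off the nine
#' whole-bone (extrinsic) and seven tissue-level (intrinsic) properties:
#' yield/ultimate force and stress, displacements and strains, stiffness
#' and modulus, works (trapezoidal areas under force-displacement, mJ)
#' and resilience/toughness (areas under stress-strain to yield/failure,
#' MPa).
#'
#' @param curve raw bend curve (data.frame `displacement_um`, `force_n`).
#' @param span_mm,c_mm,i_mm4 section geometry (see [to_stress_strain()]).
#' @param preload preload lower bound, N.
#' @param drop_frac failure threshold (fraction of ultimate force).
#' @param offset_ue yield offset in microstrain.
#' @return One-row data.frame of class `mechanical_summary` with the
#'   extrinsic and intrinsic properties plus `no_yield`, `no_failure` and
#'   `excluded` flags.
#' @export
summarize_mechanics <- function(curve, span_mm, c_mm, i_mm4,
                                preload = 0.2, drop_frac = 0.10,
                                offset_ue = 2000) {
  cur <- preprocess_curve(curve, preload = preload)
  ss <- to_stress_strain(cur, span_mm, c_mm, i_mm4)
  lm_ <- find_ultimate_failure(cur, drop_frac = drop_frac)
  stiff <- fit_stiffness(cur)
  # elastic stress-strain slope implied by the fitted stiffness:
  # sigma/F = Lc/4I, eps/d = 6c/L^2  =>  dsigma/deps = k L^3 / (24 I)
  ss_slope <- stiff$stiffness_n_mm * span_mm^3 / (24 * i_mm4)
  yld <- find_yield(ss, ss_slope, offset_ue = offset_ue,
                    end_index = lm_$failure_index)

  d <- cur$displacement_um
  f <- cur$force_n
  k <- yld$index; t <- yld$frac
  d_yield <- d[k] + t * (d[min(k + 1, length(d))] - d[k])
  f_yield <- f[k] + t * (f[min(k + 1, length(f))] - f[k])
  ifail <- lm_$failure_index
  iult <- lm_$ultimate_index
  d_total <- d[ifail]

  d_mm <- d / 1000
  work_yield <- area_to(d_mm, f, k, t)
  work_total <- trapz(d_mm[seq_len(ifail)], f[seq_len(ifail)])
  eps <- ss$strain_ue * 1e-6
  sig <- ss$stress_mpa
  resilience <- area_to(eps, sig, k, t)
  toughness <- trapz(eps[seq_len(ifail)], sig[seq_len(ifail)])

  out <- data.frame(
    yield_force_n = f_yield,
    ultimate_force_n = f[iult],
    displacement_to_yield_um = d_yield,
    postyield_displacement_um = d_total - d_yield,
    total_displacement_um = d_total,
    stiffness_n_mm = stiff$stiffness_n_mm,
    work_to_yield_mj = work_yield,
    postyield_work_mj = work_total - work_yield,
    total_work_mj = work_total,
    yield_stress_mpa = yld$stress_mpa,
    ultimate_stress_mpa = sig[iult],
    strain_to_yield_ue = yld$strain_ue,
    total_strain_ue = ss$strain_ue[ifail],
    modulus_gpa = beam_modulus(stiff$stiffness_n_mm, span_mm, i_mm4),
    resilience_mpa = resilience,
    toughness_mpa = toughness,
    no_yield = yld$no_yield,
    no_failure = lm_$no_failure,
    excluded = lm_$no_failure)
  class(out) <- c("mechanical_summary", "data.frame")
  out
}

#' Batch mechanical analysis from per-specimen CSV files
#'
#' Each curve file is a two-column CSV (displacement in micrometers, force
#' in N); the geometry sidecar CSV has columns `specimen_id`, `span_mm`,
#' `c_mm`, `i_mm4`.
#'
#' @param curve_paths named character vector of CSV paths (names are
#'   specimen ids; defaults to file names).
#' @param geometry data.frame or path to the geometry sidecar CSV.
#' @return data.frame with one [summarize_mechanics()] row per specimen.
#' @export
analyze_bend_curves <- function(curve_paths, geometry) {
  if (is.character(geometry)) geometry <- read.csv(geometry)
  need <- c("specimen_id", "span_mm", "c_mm", "i_mm4")
  if (!all(need %in% names(geometry))) {
    stop_input("geometry sidecar needs columns %s", paste(need, collapse = ", "))
  }
  ids <- names(curve_paths)
  if (is.null(ids)) ids <- sub("\\.csv$", "", basename(curve_paths))
  rows <- lapply(seq_along(curve_paths), function(i) {
    g <- geometry[geometry$specimen_id == ids[i], , drop = FALSE]
    if (nrow(g) != 1) stop_input("geometry for specimen %s not found", ids[i])
    cv <- read.csv(curve_paths[i])
    names(cv)[1:2] <- c("displacement_um", "force_n")
    cbind(specimen_id = ids[i],
          summarize_mechanics(cv, g$span_mm, g$c_mm, g$i_mm4))
  })
  do.call(rbind, rows)
}
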