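# Shared fixtures: all built in code at test time.

# small single-model cohort config (one sex/age keeps strata simple)
tiny_config <- function(n = 8, seed = 101, models = "Ts66Yah", effects = NULL,
                        sexes = "M") {
  cohort_config(n_per_group = n, models = models,
                genotypes = c("euploid", "trisomic"),
                sexes = sexes, ages = "6wk", effects = effects, seed = seed)
}

# binary mask of an elliptical annulus from the implicit equation;
# semi-axes in mm, optional rotation (degrees)
ellipse_annulus_grid <- function(a_out, b_out, a_in = 0, b_in = 0,
                                 pixel_size_um = 10, rot_deg = 0) {
  px_mm <- pixel_size_um / 1000
  half <- ceiling(max(a_out, b_out) / px_mm) + 3L
  n <- 2L * half + 1L
  cx <- half + 1
  xx <- matrix(rep(seq_len(n), each = n), n)   # column index
  yy <- matrix(rep(seq_len(n), times = n), n)  # row index
  x <- (xx - cx) * px_mm
  y <- (yy - cx) * px_mm
  th <- rot_deg * pi / 180
  u <- x * cos(th) + y * sin(th)
  v <- -x * sin(th) + y * cos(th)
  inside <- (u / a_out)^2 + (v / b_out)^2 <= 1
  if (a_in > 0) inside <- inside & (u / a_in)^2 + (v / b_in)^2 > 1
  inside
}

# ideal bilinear stress-strain curve sampled on a strain grid (ue)
bilinear_ss <- function(modulus_mpa, yield_stress_mpa, post_slope_mpa = 0,
                        max_strain_ue = 80000, step_ue = 50) {
  eps <- seq(0, max_strain_ue, by = step_ue)
  eps_y <- yield_stress_mpa / modulus_mpa * 1e6
  sig <- ifelse(eps <= eps_y,
                modulus_mpa * eps * 1e-6,
                yield_stress_mpa + post_slope_mpa * (eps - eps_y) * 1e-6)
  data.frame(strain_ue = eps, stress_mpa = sig)
}

# brute-force 0.2%-offset yield: dense grid intersection search
oracle_offset_yield <- function(ss, slope_mpa, offset_ue = 2000, n = 2e5) {
  eps <- seq(min(ss$strain_ue), max(ss$strain_ue), length.out = n)
  sig <- approx(ss$strain_ue, ss$stress_mpa, eps)$y
  g <- sig - slope_mpa * (eps - offset_ue) * 1e-6
  k <- which(g <= 0 & seq_along(g) > 1)[1]
  t <- g[k - 1] / (g[k - 1] - g[k])
  list(strain_ue = eps[k - 1] + t * (eps[k] - eps[k - 1]),
       stress_mpa = sig[k - 1] + t * (sig[k] - sig[k - 1]))
}

# brute-force stiffness window enumeration with lm(); mirrors the
# documented selection rule (R^2 max; ties -> earlier start, larger window)
oracle_stiffness <- function(curve, f_lo = 0.10, f_hi = 0.90,
                             min_frac = 0.15) {
  d <- curve$displacement_um / 1000
  f <- curve$force_n
  iult <- which.max(f)
  elig <- which(seq_along(f) <= iult & f >= f_lo * f[iult] &
                  f <= f_hi * f[iult])
  min_len <- max(2L, ceiling(min_frac * iult))
  runs <- split(elig, cumsum(c(1, diff(elig) != 1)))
  best <- NULL
  for (run in runs) {
    nr <- length(run)
    if (nr < min_len) next
    for (i in seq_len(nr - min_len + 1)) {
      for (j in seq(i + min_len - 1, nr)) {
        w <- run[i:j]
        fit <- lm(f[w] ~ d[w])
        ssr <- sum(residuals(fit)^2)
        sst <- sum((f[w] - mean(f[w]))^2)
        r2 <- if (sst <= 0) 0 else min(1, max(0, 1 - ssr / sst))
        cand <- list(r2 = r2, start = w[1], len = length(w),
                     slope = unname(coef(fit)[2]), window = range(w))
        if (is.null(best) || cand$r2 > best$r2 + 1e-12 ||
            (abs(cand$r2 - best$r2) <= 1e-12 &&
             (cand$start < best$start ||
              (cand$start == best$start && cand$len > best$len)))) {
          best <- cand
        }
      }
    }
  }
  best
}
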