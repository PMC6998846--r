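# Axisymmetric-plus-bulge description of the aortic root lumen.
# Coordinates: right-handed, z = flow axis, z = 0 at the annulus plane,
# positive toward the aorta, units mm throughout.

# cubic smoothstep on [0, 1], clamped outside
.smoothstep <- function(t) {
  t <- pmin(1, pmax(0, t))
  t * t * (3 - 2 * t)
}

#' Build the parametric lumen radius model of the aortic root
#'
#' Constructs the inner-lumen radius function r(z, theta) of the phantom:
#' an LVOT cylinder below the annulus, the sinus segment with `n_leaflets`
#' rotationally symmetric sinus-of-Valsalva bulges, the sinotubular waist,
#' and the tubular ascending aorta. The base (bulge-free) radius blends
#' between the named diameters with C1 smoothstep transitions; the bulge is
#' a multiplicative term
#' \deqn{r(z,\theta) = r_{base}(z)\,[1 + a \sin^2(\pi z/H)\max(0,\cos n\theta)^p]}
#' (a C1 bump vanishing with zero slope at the annulus and the sinotubular
#' junction)
#' over the sinus segment of height H, whose amplitude `a` is solved
#' numerically so that the maximum lumen radius equals
#' `sinus_max_diameter / 2` to 1e-9 mm.
#'
#' @param params A [root_params()] object.
#' @param bulge_sharpness Exponent p controlling how sharply each sinus bulge
#'   is confined to its sector (default 2).
#' @param transition_fraction Fraction of `ascending_aorta_length` used to
#'   blend the sinotubular diameter into the ascending aorta diameter.
#' @return An object of class `root_profile` with elements `params`,
#'   `radius_fn(z, theta)` (vectorised), `r_base(z)` (the theta-minimum core
#'   radius), `bulge_amplitude`, `z_min`, `z_max`, `n_fold`.
#' @export
#' @examples
#' pr <- build_root_profile(root_params())
#' pr$radius_fn(0, 0)    # annulus radius
build_root_profile <- function(params, bulge_sharpness = 2,
                               transition_fraction = 0.15) {
  validate_root_params(params)
  p <- params
  r_lv  <- p$lvot_diameter / 2
  r_ann <- p$annulus_diameter / 2
  r_stj <- p$sinotubular_diameter / 2
  r_asc <- p$ascending_aorta_diameter / 2
  r_sin <- p$sinus_max_diameter / 2
  H     <- p$sinus_height
  n     <- p$n_leaflets
  t_lv  <- min(5, p$lvot_length / 2)
  t_asc <- transition_fraction * p$ascending_aorta_length
  z_min <- -p$lvot_length
  z_max <- H + p$ascending_aorta_length

  r_base <- function(z) {
    r <- numeric(length(z))
    r[z <= -t_lv] <- r_lv
    i <- z > -t_lv & z < 0
    r[i] <- r_lv + (r_ann - r_lv) * .smoothstep((z[i] + t_lv) / t_lv)
    i <- z >= 0 & z <= H
    r[i] <- r_ann + (r_stj - r_ann) * .smoothstep(z[i] / H)
    i <- z > H & z < H + t_asc
    r[i] <- r_stj + (r_asc - r_stj) * .smoothstep((z[i] - H) / t_asc)
    r[z >= H + t_asc] <- r_asc
    r
  }

  # bulge amplitude: solve max_z r_base(z) (1 + a sin(pi z / H)) = r_sin
  a <- 0
  if (r_sin > max(r_ann, r_stj) + 1e-12) {
    peak_for <- function(a) {
      g <- function(z) r_base(z) * (1 + a * sin(pi * z / H)^2)
      zs <- seq(0, H, length.out = 2001)
      k <- which.max(g(zs))
      lo <- zs[max(1, k - 1)]; hi <- zs[min(length(zs), k + 1)]
      stats::optimize(g, c(lo, hi), maximum = TRUE, tol = 1e-12)$objective
    }
    f <- function(a) peak_for(a) - r_sin
    upper <- 2 * r_sin / min(r_base(seq(0, H, length.out = 101))) # generous
    a <- stats::uniroot(f, c(0, upper), tol = 1e-13)$root
  }

  sharp <- bulge_sharpness
  radius_fn <- function(z, theta) {
    m <- max(length(z), length(theta))
    z <- rep_len(z, m); theta <- rep_len(theta, m)
    r <- r_base(z)
    i <- z > 0 & z < H
    if (any(i)) {
      bump <- a * sin(pi * z[i] / H)^2 * pmax(0, cos(n * theta[i]))^sharp
      r[i] <- r[i] * (1 + bump)
    }
    r
  }

  structure(list(params = p, radius_fn = radius_fn, r_base = r_base,
                 bulge_amplitude = a, z_min = z_min, z_max = z_max,
                 n_fold = n, bulge_sharpness = sharp),
            class = "root_profile")
}

#' @export
print.root_profile <- function(x, ...) {
  cat("Aortic root lumen profile\n")
  cat(sprintf("  axial extent       : z in [%.1f, %.1f] mm\n", x$z_min, x$z_max))
  cat(sprintf("  annulus radius     : %.3f mm\n", x$radius_fn(0, 0)))
  cat(sprintf("  sinus bulge factor : %.4f (%d-fold symmetric)\n",
              x$bulge_amplitude, x$n_fold))
  invisible(x)
}

# numerical partial derivatives of the lumen radius (used for surface normals
# and the core-radius slope in flow synthesis)
.radius_dz <- function(profile, z, theta, h = 1e-5) {
  (profile$radius_fn(z + h, theta) - profile$radius_fn(z - h, theta)) / (2 * h)
}
.radius_dtheta <- function(profile, z, theta, h = 1e-5) {
  (profile$radius_fn(z, theta + h) - profile$radius_fn(z, theta - h)) / (2 * h)
}
.rbase_dz <- function(profile, z, h = 1e-5) {
  (profile$r_base(z + h) - profile$r_base(z - h)) / (2 * h)
}
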