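#' Synthetic lung-slice phantom specification
#'
#' Describes a synthetic 2-D CT slice with known ground truth: dark
#' exterior, a soft-tissue body ellipse filling most of the frame, two
#' dark lung fields, one tumor blob of controllable physical diameter
#' and shape inside the left lung, optional thin bright vessel-like
#' polylines in the right lung (cross-section area below 1 cm^2, the
#' prior filter's vessel floor), and additive Gaussian noise.
#'
#' Default intensities (tumor 200, body 120, lung 60, exterior 0 on
#' 8-bit) keep the tumor-vs-lung contrast well above the 20% range
#' tolerance, so a noise-free phantom is segmented essentially exactly.
#'
#' @param shape_px image dimensions `c(rows, cols)`.
#' @param spacing_mm pixel spacing in mm/pixel.
#' @param tumor_diameter_cm maximum tumor size in cm.
#' @param tumor_shape `"disk"`, `"ellipse"` or `"concave-crescent"`.
#' @param tumor_intensity,lung_intensity,body_intensity,background_intensity
#'   8-bit gray levels.
#' @param vessel_count number of vessel-like distractor polylines.
#' @param noise_sd standard deviation of additive Gaussian noise, in
#'   gray levels.
#' @param rng_seed integer; the same seed reproduces the phantom
#'   bit-identically.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape_px = c(512L, 512L), spacing_mm = 0.7,
                         tumor_diameter_cm = 3,
                         tumor_shape = c("disk", "ellipse",
                                         "concave-crescent"),
                         tumor_intensity = 200, lung_intensity = 60,
                         body_intensity = 120, background_intensity = 0,
                         vessel_count = 3L, noise_sd = 0, rng_seed = 1L) {
  tumor_shape <- match.arg(tumor_shape)
  ints <- c(tumor_intensity, lung_intensity, body_intensity,
            background_intensity)
  if (any(ints < 0 | ints > 255))
    stop("intensities must lie in [0, 255]", call. = FALSE)
  if (tumor_diameter_cm <= 0)
    stop("tumor_diameter_cm must be positive", call. = FALSE)
  structure(
    list(shape_px = as.integer(shape_px), spacing_mm = spacing_mm,
         tumor_diameter_cm = tumor_diameter_cm, tumor_shape = tumor_shape,
         tumor_intensity = tumor_intensity, lung_intensity = lung_intensity,
         body_intensity = body_intensity,
         background_intensity = background_intensity,
         vessel_count = as.integer(vessel_count), noise_sd = noise_sd,
         rng_seed = as.integer(rng_seed)),
    class = "phantom_spec")
}

# Evaluate RNG-dependent code under a fixed seed, restoring the
# caller's RNG state afterwards.
with_phantom_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic lung-slice phantom
#'
#' Renders the phantom described by `spec` and the exact ground-truth
#' tumor mask.  Deterministic: the same `rng_seed` yields bit-identical
#' output.
#'
#' @param spec a [phantom_spec()].
#' @return list of class `phantom`: `slice` (a [ct_slice()]), `truth`
#'   (logical mask marking exactly the tumor pixels), `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  nr <- spec$shape_px[1L]; nc <- spec$shape_px[2L]
  rg <- matrix(seq_len(nr), nr, nc)
  cg <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  ell <- function(ctr, semi) {
    ((rg - ctr[1L]) / semi[1L])^2 + ((cg - ctr[2L]) / semi[2L])^2 <= 1
  }

  body_semi <- c(0.49 * nr, 0.48 * nc)
  body_ctr <- c(nr, nc) / 2
  lung_semi <- c(0.26 * nr, 0.155 * nc)
  lung_l_ctr <- c(nr / 2, nc / 2 - 0.19 * nc)
  lung_r_ctr <- c(nr / 2, nc / 2 + 0.19 * nc)

  r_px <- spec$tumor_diameter_cm * 10 / spec$spacing_mm / 2
  if (r_px + 4 > min(lung_semi))
    stop(sprintf("tumor radius %.1f px does not fit inside the lung field",
                 r_px), call. = FALSE)
  t_ctr <- round(lung_l_ctr)
  d2r <- rg - t_ctr[1L]; d2c <- cg - t_ctr[2L]
  truth <- switch(spec$tumor_shape,
    disk = d2r^2 + d2c^2 <= r_px^2,
    ellipse = (d2r / r_px)^2 + (d2c / (0.72 * r_px))^2 <= 1,
    `concave-crescent` = {
      main <- d2r^2 + d2c^2 <= r_px^2
      bite <- d2r^2 + (d2c - 0.9 * r_px)^2 <= (0.55 * r_px)^2
      main & !bite
    })

  img <- matrix(spec$background_intensity, nr, nc)
  img[ell(body_ctr, body_semi)] <- spec$body_intensity
  img[ell(lung_l_ctr, lung_semi)] <- spec$lung_intensity
  img[ell(lung_r_ctr, lung_semi)] <- spec$lung_intensity
  img[truth] <- spec$tumor_intensity

  with_phantom_seed(spec$rng_seed, {
    if (spec$vessel_count > 0L) {
      vess_int <- min(spec$tumor_intensity + 30, 255)
      in_lung_r <- ell(lung_r_ctr, lung_semi * 0.92)
      for (v in seq_len(spec$vessel_count)) {
        p <- lung_r_ctr + runif(2, -0.3, 0.3) * lung_semi
        ang <- runif(1, 0, 2 * pi)
        len <- round(runif(1, 45, 70))
        for (s in seq_len(len)) {
          ang <- ang + rnorm(1, 0, 0.12)
          p <- p + c(cos(ang), sin(ang))
          pr <- round(p[1L]); pc <- round(p[2L])
          for (dr in -1:0) for (dc in -1:0) {   # 2 px wide stroke
            r <- pr + dr; c <- pc + dc
            if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
                in_lung_r[r, c])
              img[r, c] <- vess_int
          }
        }
      }
    }
    if (spec$noise_sd > 0) {
      img <- img + rnorm(length(img), 0, spec$noise_sd)
      img <- round(pmin(pmax(img, 0), 255))
    }
  })
  storage.mode(img) <- "integer"
  structure(
    list(slice = ct_slice(img, spec$spacing_mm, "<synthetic phantom>", 8L),
         truth = truth, spec = spec),
    class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf(
    "<phantom> %d x %d px, %s tumor %.2f cm, noise sd %g, seed %d\n",
    x$spec$shape_px[1L], x$spec$shape_px[2L], x$spec$tumor_shape,
    x$spec$tumor_diameter_cm, x$spec$noise_sd, x$spec$rng_seed))
  invisible(x)
}

#' Generate a reproducible suite of phantoms
#'
#' `n` phantoms with tumor diameters sampled uniformly in
#' `[diameter_range[1], diameter_range[2]]` cm (default 2.2-4.8, inside
#' the prior window), shapes cycling through disk / ellipse /
#' concave-crescent, and per-phantom noise sd sampled uniformly in
#' `[0, base_spec$noise_sd]`.  The same `seed` reproduces the whole
#' suite exactly.
#'
#' @param n number of phantoms.
#' @param base_spec template [phantom_spec()]; its `noise_sd` is the
#'   suite's noise ceiling.
#' @param seed integer master seed.
#' @param diameter_range tumor-diameter sampling window in cm.
#' @return list of `n` `phantom` objects.
#' @export
generate_suite <- function(n, base_spec = phantom_spec(noise_sd = 10),
                           seed = 1L, diameter_range = c(2.2, 4.8)) {
  stopifnot(n >= 1L, inherits(base_spec, "phantom_spec"))
  shapes <- c("disk", "ellipse", "concave-crescent")
  draws <- with_phantom_seed(seed, list(
    diam = runif(n, diameter_range[1L], diameter_range[2L]),
    noise = runif(n, 0, base_spec$noise_sd),
    seeds = sample.int(.Machine$integer.max, n)))
  lapply(seq_len(n), function(i) {
    sp <- base_spec
    sp$tumor_diameter_cm <- draws$diam[i]
    sp$tumor_shape <- shapes[(i - 1L) %% 3L + 1L]
    sp$noise_sd <- draws$noise[i]
    sp$rng_seed <- draws$seeds[i]
    generate_phantom(sp)
  })
}
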