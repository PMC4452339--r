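#' Synthetic phantoms: Gaussian dots, Gaussian-profile lines, vessel models
#'
#' The phantom generator produces every synthetic input the detection
#' pipeline is tested on: isolated Gaussian dots (the circular nodule
#' model), line structures with a Gaussian cross-profile (the vessel
#' model), the five-dot / three-line demonstration panel, single / Y / X
#' vessel models, and attached-nodule scenes with ground truth.
#'
#' The dot model is `d(x, y) = A * exp(-((x - cx)^2 + (y - cy)^2) / (2 sigma^2))`;
#' the line model applies the same Gaussian profile to the perpendicular
#' distance from a finite segment (capped ends — vessel ends must exist,
#' because end-of-vessel blob responses are precisely the false positives
#' the classifier must reject). Elements are composited by addition and
#' clipped to `[0, 255]`.
#'
#' @name phantoms
NULL

# distance from every pixel center to segment p0-p1 (points are (row, col))
.seg_distance_field <- function(nr, nc, p0, p1) {
  r <- matrix(seq_len(nr), nr, nc)
  c <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  vr <- p1[1] - p0[1]; vc <- p1[2] - p0[2]
  len2 <- vr^2 + vc^2
  t <- ((r - p0[1]) * vr + (c - p0[2]) * vc) / len2
  t <- pmin(pmax(t, 0), 1)
  sqrt((r - (p0[1] + t * vr))^2 + (c - (p0[2] + t * vc))^2)
}

#' Render a Gaussian dot
#'
#' @param center numeric `(row, col)` of the dot center (may be fractional).
#' @param sigma dot scale in pixels (> 0).
#' @param amplitude peak intensity (default 255, the 8-bit maximum).
#' @param grid `(nrow, ncol)` of the output image.
#' @param spacing_mm mm per pixel.
#' @return [image2d()] with `amplitude * exp(-d^2 / (2 sigma^2))` at squared
#'   distance `d^2` from `center`.
#' @export
render_dot <- function(center, sigma, amplitude = 255, grid = c(128L, 128L),
                       spacing_mm = 0.6) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("render_dot: `sigma` must be a single positive number", call. = FALSE)
  }
  if (any(grid < 1)) stop("render_dot: empty grid", call. = FALSE)
  nr <- as.integer(grid[1]); nc <- as.integer(grid[2])
  r <- matrix(seq_len(nr), nr, nc)
  c <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  v <- amplitude * exp(-((r - center[1])^2 + (c - center[2])^2) / (2 * sigma^2))
  image2d(v, spacing_mm)
}

#' Render a line with Gaussian cross-profile
#'
#' Intensity is `amplitude * exp(-u^2 / (2 sigma^2))` where `u` is the
#' distance to the finite segment from `p_start` to `p_end` (perpendicular
#' distance along the interior, radial distance beyond the capped ends).
#'
#' @param p_start,p_end `(row, col)` endpoints; must differ.
#' @param sigma cross-profile scale in pixels (> 0).
#' @param taper_px amplitude taper length at each end (pixels). `0`
#'   (default) gives hard capped ends — the geometry of a vessel segment,
#'   whose end produces a blob-like dot-filter response. A positive taper
#'   fades the amplitude smoothly to zero over `taper_px` along the axis,
#'   yielding a pure line structure with no blob-like termination (used by
#'   the dot/line demonstration panel, which illustrates line suppression
#'   only).
#' @inheritParams render_dot
#' @export
render_line <- function(p_start, p_end, sigma, amplitude = 255,
                        grid = c(128L, 128L), spacing_mm = 0.6,
                        taper_px = 0) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("render_line: `sigma` must be a single positive number", call. = FALSE)
  }
  if (all(p_start == p_end)) {
    stop("render_line: endpoints must not coincide", call. = FALSE)
  }
  nr <- as.integer(grid[1]); nc <- as.integer(grid[2])
  u <- .seg_distance_field(nr, nc, p_start, p_end)
  v <- amplitude * exp(-u^2 / (2 * sigma^2))
  if (taper_px > 0) {
    # smoothstep amplitude ramp over taper_px from each endpoint inward
    r <- matrix(seq_len(nr), nr, nc)
    c <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    vr <- p_end[1] - p_start[1]; vc <- p_end[2] - p_start[2]
    len <- sqrt(vr^2 + vc^2)
    t <- ((r - p_start[1]) * vr + (c - p_start[2]) * vc) / len  # axial coord, px
    ramp <- function(s) {
      s <- pmin(pmax(s / taper_px, 0), 1)
      s * s * (3 - 2 * s)
    }
    v <- v * ramp(t) * ramp(len - t)
  }
  image2d(v, spacing_mm)
}

#' Phantom scene specification and renderer
#'
#' A `phantom_spec` is a declarative description of a scene: grid shape,
#' pixel spacing, a list of dot and line elements, an additive Gaussian
#' noise level and a seed. Rendering composites all elements by addition,
#' adds noise (reproducibly from the seed), then clips to `[0, 255]`.
#'
#' @param shape `(nrow, ncol)` in pixels.
#' @param spacing_mm mm per pixel (default 0.6).
#' @param elements list of elements, each a list with `type = "dot"`
#'   (`center`, `sigma`, `amplitude`) or `type = "line"` (`p_start`,
#'   `p_end`, `sigma`, `amplitude`).
#' @param noise_sd standard deviation of additive Gaussian noise (intensity
#'   units; 0 = noise free).
#' @param seed integer RNG seed used for the noise.
#' @param combine `"sum"` (default): elements add, then clip to `[0, 255]`
#'   — linear superposition, right for demonstration scenes whose elements
#'   do not overlap. `"max"`: per-pixel maximum — the union-of-tissue
#'   model used for adhesion scenes, where summing two near-saturation
#'   structures would clip into a plateau that no longer has either
#'   structure's center.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(256L, 256L), spacing_mm = 0.6,
                         elements = list(), noise_sd = 0, seed = 0L,
                         combine = c("sum", "max")) {
  combine <- match.arg(combine)
  stopifnot(length(shape) == 2L, all(shape >= 1))
  if (noise_sd < 0) stop("phantom_spec: noise_sd must be >= 0", call. = FALSE)
  for (el in elements) {
    if (!el$type %in% c("dot", "line")) {
      stop("phantom_spec: unknown element type ", el$type, call. = FALSE)
    }
    if (el$sigma <= 0) stop("phantom_spec: sigma must be > 0", call. = FALSE)
    ctr <- if (el$type == "dot") list(el$center) else list(el$p_start, el$p_end)
    for (p in ctr) {
      if (p[1] < 1 || p[1] > shape[1] || p[2] < 1 || p[2] > shape[2]) {
        stop("phantom_spec: element reference point outside the grid", call. = FALSE)
      }
    }
  }
  structure(list(shape = as.integer(shape), spacing_mm = spacing_mm,
                 elements = elements, noise_sd = noise_sd,
                 seed = as.integer(seed), combine = combine),
            class = "phantom_spec")
}

#' @rdname phantom_spec
#' @param spec a `phantom_spec`.
#' @export
render_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  acc <- matrix(0, spec$shape[1], spec$shape[2])
  comb <- if (identical(spec$combine, "max")) pmax else `+`
  for (el in spec$elements) {
    img <- if (el$type == "dot") {
      render_dot(el$center, el$sigma, el$amplitude, spec$shape, spec$spacing_mm)
    } else {
      render_line(el$p_start, el$p_end, el$sigma, el$amplitude, spec$shape,
                  spec$spacing_mm,
                  taper_px = if (is.null(el$taper_px)) 0 else el$taper_px)
    }
    acc <- comb(acc, as_plain_matrix(img))
  }
  if (spec$noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(spec$seed)
    acc <- acc + matrix(stats::rnorm(length(acc), 0, spec$noise_sd),
                        nrow(acc), ncol(acc))
  }
  acc <- pmin(pmax(acc, 0), 255)
  image2d(acc, spec$spacing_mm)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Five-dot / three-line demonstration panel
#'
#' Reproduces the classic dot-filter demonstration scene: five Gaussian
#' dots of scale 2, 4, 6, 8 and 10 pixels plus three line structures
#' (horizontal, vertical, diagonal), all with amplitude 255, none touching
#' the image border, dots spaced so that their tails do not overlap.
#'
#' @param seed noise seed (only relevant with `noise_sd > 0`).
#' @param noise_sd additive noise SD (default 0).
#' @param spacing_mm mm per pixel.
#' @return list with `image` ([image2d()]), `dot_centers` (5 x 2 matrix),
#'   `dot_sigmas`, and `line_segments` (list of endpoint pairs).
#' @export
make_dotline_panel <- function(seed = 0L, noise_sd = 0, spacing_mm = 0.6) {
  shape <- c(320L, 320L)
  sig <- c(2, 4, 6, 8, 10)
  centers <- rbind(c(60, 40), c(60, 100), c(60, 165), c(60, 235),
                   c(150, 60))
  lines <- list(
    list(p_start = c(215, 50),  p_end = c(215, 270), sigma = 2),  # horizontal
    list(p_start = c(110, 275), p_end = c(270, 275), sigma = 2),  # vertical
    list(p_start = c(255, 60),  p_end = c(278, 215), sigma = 2)   # oblique
  )
  # panel lines are pure line structures (amplitude tapered at the ends):
  # the demonstration is line suppression; capped vessel ends and their
  # blob-like responses belong to the vessel models, not this panel
  els <- c(
    lapply(seq_along(sig), function(i) {
      list(type = "dot", center = centers[i, ], sigma = sig[i], amplitude = 255)
    }),
    lapply(lines, function(l) {
      list(type = "line", p_start = l$p_start, p_end = l$p_end,
           sigma = l$sigma, amplitude = 255, taper_px = 30)
    })
  )
  spec <- phantom_spec(shape, spacing_mm, els, noise_sd, seed)
  list(image = render_phantom(spec), dot_centers = centers, dot_sigmas = sig,
       line_segments = lines, spec = spec)
}

#' Vessel models: single line, Y junction, X crossing
#'
#' @param kind one of `"single"`, `"Y"`, `"X"`.
#' @param shape grid `(nrow, ncol)`.
#' @param sigma cross-profile scale in pixels.
#' @param amplitude peak intensity.
#' @param spacing_mm mm per pixel.
#' @param noise_sd,seed optional additive noise.
#' @return list with `image` and `segments` (list of `(p_start, p_end)` pairs).
#' @export
make_vessel_phantom <- function(kind = c("single", "Y", "X"),
                                shape = c(192L, 192L), sigma = 3,
                                amplitude = 255, spacing_mm = 0.6,
                                noise_sd = 0, seed = 0L) {
  kind <- match.arg(kind)
  ctr <- (shape + 1) / 2
  segs <- switch(kind,
    single = list(list(p_start = c(ctr[1], 30), p_end = c(ctr[1], shape[2] - 30))),
    Y = list(
      list(p_start = ctr, p_end = ctr + c(-60, -55)),
      list(p_start = ctr, p_end = ctr + c(-60, 55)),
      list(p_start = ctr, p_end = ctr + c(65, 0))
    ),
    X = list(
      list(p_start = ctr + c(-60, -60), p_end = ctr + c(60, 60)),
      list(p_start = ctr + c(-60, 60), p_end = ctr + c(60, -60))
    )
  )
  els <- lapply(segs, function(s) {
    list(type = "line", p_start = s$p_start, p_end = s$p_end, sigma = sigma,
         amplitude = amplitude)
  })
  # union-of-tissue compositing: crossing arms must not sum into a
  # saturated plateau at the junction
  spec <- phantom_spec(shape, spacing_mm, els, noise_sd, seed, combine = "max")
  list(image = render_phantom(spec), segments = segs, kind = kind, spec = spec)
}

#' Attached-nodule phantom with ground truth
#'
#' A straight vessel plus one Gaussian nodule placed near one vessel end at
#' a caller-specified perpendicular distance from the vessel axis. The
#' nodule overlaps the vessel (adhesion) but its center sits off-axis; the
#' perpendicular offset is the quantity the d1 distance rule should
#' recover.
#'
#' @param offset_px perpendicular distance (pixels) from the nodule center
#'   to the vessel axis (the infinite line through the segment).
#' @param nodule_sigma nodule scale in pixels.
#' @param vessel_sigma vessel cross-profile scale in pixels.
#' @param along_px signed position of the nodule center along the vessel
#'   axis beyond the near end of the segment; `0` puts the nodule center
#'   exactly on the tip (the nodule then swallows the vessel end). The
#'   default `NULL` places the nodule outward like a ball on the end of a
#'   stick — as far along as the adhesion constraint allows, capped at one
#'   nodule sigma: `min(nodule_sigma, sqrt(max(reach^2 - offset^2, 0)))`
#'   with `reach = 1.16 * (nodule_sigma + vessel_sigma) - 1`, the contact
#'   distance of the two structures' gray-threshold footprints (a Gaussian
#'   of amplitude 255 crosses the 130 threshold at radius 1.16 sigma).
#' @param angle_deg vessel orientation in degrees (0 = horizontal).
#' @param shape,amplitude,spacing_mm,noise_sd,seed as elsewhere.
#' @return list with `image`, and `truth` (nodule center, sigma, vessel
#'   segment, requested perpendicular offset in px and mm).
#' @export
make_attached_nodule_phantom <- function(offset_px = 6, nodule_sigma = 5,
                                         vessel_sigma = 3, along_px = NULL,
                                         angle_deg = 0,
                                         shape = c(192L, 192L),
                                         amplitude = 255, spacing_mm = 0.6,
                                         noise_sd = 0, seed = 0L) {
  ctr <- (shape + 1) / 2
  th <- angle_deg * pi / 180
  u <- c(sin(th), cos(th))        # unit vector along the vessel (row, col)
  nvec <- c(cos(th), -sin(th))    # unit normal
  if (is.null(along_px)) {
    reach <- 1.16 * (nodule_sigma + vessel_sigma) - 1
    along_px <- min(nodule_sigma, sqrt(max(reach^2 - offset_px^2, 0)))
  }
  half <- 55
  p0 <- ctr - half * u            # far end
  p1 <- ctr + half * u            # near end (nodule end)
  nod <- p1 + along_px * u + offset_px * nvec
  if (nod[1] < 1 || nod[1] > shape[1] || nod[2] < 1 || nod[2] > shape[2]) {
    stop("make_attached_nodule_phantom: nodule center off-grid", call. = FALSE)
  }
  els <- list(
    list(type = "line", p_start = p0, p_end = p1, sigma = vessel_sigma,
         amplitude = amplitude),
    list(type = "dot", center = nod, sigma = nodule_sigma, amplitude = amplitude)
  )
  # adhesion = union of two soft-tissue structures, not doubled density
  spec <- phantom_spec(shape, spacing_mm, els, noise_sd, seed, combine = "max")
  list(image = render_phantom(spec),
       truth = list(nodule_center = nod, nodule_sigma = nodule_sigma,
                    vessel_p0 = p0, vessel_p1 = p1,
                    offset_px = offset_px,
                    offset_mm = offset_px * spacing_mm),
       spec = spec)
}
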