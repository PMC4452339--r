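#' Distance-rule classification of suspect nodules
#'
#' The dot filter fires not only on true nodules but also at vessel ends
#' and crossings. These false positives sit *on* the vessel centerline,
#' whereas a vessel-attached nodule's center of mass sits off the axis.
#' Two distances separate the cases:
#'
#' * `d1` — perpendicular distance from the suspect's center of mass to
#'   the line fitted through the skeleton pixels nearest the suspect;
#' * `d2` — minimum distance from the center of mass to any skeleton
#'   pixel.
#'
#' With threshold t (default 1.5 mm): `d1 <= t` and `d2 <= t` means the
#' suspect lies on the centerline itself (a vessel intersection or end
#' still covered by skeleton); `d1 <= t` and `d2 > t` means it is
#' collinear with, but beyond, the skeleton (a vessel end); `d1 > t`
#' means its mass sits off the vessel axis — an attached nodule.
#'
#' @name classify
NULL

#' d1/d2 distances from a suspect centroid to the skeleton
#'
#' @param suspect one-row data.frame (or list) with `centroid_row`,
#'   `centroid_col`.
#' @param skel skeleton matrix.
#' @param spacing_mm mm per pixel (default taken from the skeleton).
#' @param window number of nearest skeleton pixels used for the local line
#'   fit (default 15).
#' @return named numeric `c(d1_mm, d2_mm)`.
#' @export
suspect_distances <- function(suspect, skel, spacing_mm = NULL, window = 15L) {
  if (is.null(spacing_mm)) spacing_mm <- attr(skel, "spacing_mm")
  if (is.null(spacing_mm)) stop("suspect_distances: spacing_mm missing", call. = FALSE)
  m <- as_plain_matrix(skel)
  idx <- which(m != 0)
  if (length(idx) == 0L) {
    stop("suspect_distances: empty skeleton — suspect unclassifiable", call. = FALSE)
  }
  ctr <- c(suspect$centroid_row, suspect$centroid_col)
  r <- ((idx - 1L) %% nrow(m)) + 1L
  cc <- ((idx - 1L) %/% nrow(m)) + 1L
  d2_px <- sqrt(min((r - ctr[1])^2 + (cc - ctr[2])^2))
  d1_px <- if (length(idx) == 1L) {
    d2_px   # a single skeleton pixel defines no line; fall back to d2
  } else {
    fit <- fit_line_local(m, ctr, window)
    abs(fit$alpha * ctr[2] + fit$beta * ctr[1] + fit$gamma)
  }
  c(d1_mm = d1_px * spacing_mm, d2_mm = d2_px * spacing_mm)
}

#' Three-branch distance decision rule
#'
#' @param d1_mm,d2_mm distances in mm (non-negative).
#' @param threshold_mm decision threshold (default 1.5 mm). Equality is
#'   assigned to the vessel classes (conservative: fewer nodule calls).
#' @return one of `"attached_nodule"`, `"vessel_end"`,
#'   `"vessel_intersection_or_end"`.
#' @export
decide <- function(d1_mm, d2_mm, threshold_mm = 1.5) {
  if (threshold_mm <= 0) stop("decide: threshold must be > 0", call. = FALSE)
  if (any(d1_mm < 0) || any(d2_mm < 0)) {
    stop("decide: distances must be non-negative", call. = FALSE)
  }
  ifelse(d1_mm > threshold_mm, "attached_nodule",
         ifelse(d2_mm > threshold_mm, "vessel_end",
                "vessel_intersection_or_end"))
}

#' Full detection pipeline
#'
#' Runs the complete chain on one 2D slice:
#' soft-tissue thresholding, Gaussian pre-smoothing, multiscale dot
#' filtering (response restricted to the tissue mask), suspect
#' extraction, removal of suspect footprints from the tissue mask, gap
#' filling, thinning, spur pruning, d1/d2 computation and the distance
#' rule.
#'
#' @param image [image2d()] (or matrix; spacing then from `config`).
#' @param config [pipeline_config()] list of tunables.
#' @param keep_intermediates return masks, response and skeleton alongside
#'   the decisions (default TRUE).
#' @return object of class `detection_report`: list with `decisions`
#'   (data.frame: suspect id, centroid, area, best scale, peak response,
#'   d1_mm, d2_mm, label), `config`, and intermediates (`tissue_mask`,
#'   `response`, `suspects`, `vessel_mask`, `skeleton`).
#' @export
run_pipeline <- function(image, config = pipeline_config(),
                         keep_intermediates = TRUE) {
  config <- pipeline_config_validate(config)
  sp <- attr(image, "spacing_mm")
  if (is.null(sp)) {
    sp <- config$spacing_mm
    if (is.null(sp)) stop("run_pipeline: pixel spacing missing", call. = FALSE)
    image <- image2d(as_plain_matrix(image), sp)
  }
  tissue <- extract_soft_tissue(image, config$threshold)
  if (sum(tissue) == 0L) {
    warning("run_pipeline: empty tissue mask; nothing to detect")
    return(.empty_report(config))
  }
  smooth <- gaussian_smooth(image, config$presmooth_sigma)
  sched <- sigma_schedule(config$r0_mm, config$r1_mm, config$n_scales)
  mf <- multiscale_dot_filter(smooth, sched, config$scale_normalize)
  resp <- as_plain_matrix(mf$response) * as_plain_matrix(tissue)
  resp <- image2d(resp, sp)
  suspects <- extract_suspects(resp, mf$scale_mm, config$suspect_rel_threshold,
                               config$min_area_px)
  fp <- attr(suspects, "footprint")
  vessel <- as_plain_matrix(tissue)
  vessel[fp > 0L] <- 0L
  vessel <- binary_mask(vessel, sp)
  vessel <- fill_gaps(vessel, fp, config$max_gap_px)
  skel <- thin(vessel)
  skel <- prune_spurs(skel, config$prune_iterations)
  n <- nrow(suspects)
  d1 <- d2 <- rep(NA_real_, n)
  lab <- rep(NA_character_, n)
  if (n > 0L && sum(skel) > 0L) {
    for (i in seq_len(n)) {
      d <- suspect_distances(suspects[i, ], skel, sp, config$fit_window)
      d1[i] <- d[["d1_mm"]]
      d2[i] <- d[["d2_mm"]]
      lab[i] <- decide(d1[i], d2[i], config$d_threshold_mm)
    }
  }
  decisions <- cbind(suspects[, c("id", "centroid_row", "centroid_col",
                                  "area_px", "peak_response", "best_scale_mm")],
                     d1_mm = d1, d2_mm = d2, label = lab)
  rownames(decisions) <- NULL
  structure(list(decisions = decisions, config = config,
                 tissue_mask = if (keep_intermediates) tissue else NULL,
                 response = if (keep_intermediates) resp else NULL,
                 suspects = if (keep_intermediates) suspects else NULL,
                 vessel_mask = if (keep_intermediates) vessel else NULL,
                 skeleton = if (keep_intermediates) skel else NULL),
            class = "detection_report")
}

.empty_report <- function(config) {
  structure(list(decisions = data.frame(id = integer(), centroid_row = numeric(),
                                        centroid_col = numeric(),
                                        area_px = integer(),
                                        peak_response = numeric(),
                                        best_scale_mm = numeric(),
                                        d1_mm = numeric(), d2_mm = numeric(),
                                        label = character()),
                 config = config, tissue_mask = NULL, response = NULL,
                 suspects = NULL, vessel_mask = NULL, skeleton = NULL),
            class = "detection_report")
}

#' @export
print.detection_report <- function(x, ...) {
  d <- x$decisions
  cat(sprintf("<detection_report> %d suspect(s): %d attached nodule(s), %d vessel end(s), %d intersection/end(s)\n",
              nrow(d), sum(d$label == "attached_nodule", na.rm = TRUE),
              sum(d$label == "vessel_end", na.rm = TRUE),
              sum(d$label == "vessel_intersection_or_end", na.rm = TRUE)))
  if (nrow(d) > 0L) print(format(d, digits = 4))
  invisible(x)
}
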