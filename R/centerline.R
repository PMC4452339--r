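#' Vessel centerline extraction by two-subiteration thinning
#'
#' The centerline (skeleton) of a binary vessel mask is obtained by
#' iteratively deleting border pixels with a two-subiteration thinning
#' scheme. The 8-neighborhood of a pixel p1 is labelled p2..p9 clockwise
#' starting at the north neighbor:
#'
#' ```
#'   p9 p2 p3
#'   p8 p1 p4
#'   p7 p6 p5
#' ```
#'
#' A border pixel is flagged in subiteration 1 when (a) 2 <= N(p1) <= 6,
#' (b) T(p1) = 1, (c) p2*p4*p6 = 0, (d) p4*p6*p8 = 0; and in subiteration
#' 2 when (a), (b) hold and (c') p2*p4*p8 = 0, (d') p2*p6*p8 = 0. N(p1) is
#' the number of nonzero neighbors and T(p1) the number of 0-to-1
#' transitions in the cyclic sequence p2, p3, ..., p9, p2. Flagged pixels
#' are deleted simultaneously after the whole subiteration; the two
#' subiterations alternate until a full pass deletes nothing. The result
#' is one pixel wide, a subset of the input foreground, and preserves
#' 8-connectivity.
#'
#' @name centerline
NULL

# p2..p9 offsets (row, col), clockwise from north
.nb_offsets <- rbind(c(-1L, 0L), c(-1L, 1L), c(0L, 1L), c(1L, 1L),
                     c(1L, 0L), c(1L, -1L), c(0L, -1L), c(-1L, -1L))

#' Neighborhood operators N(p1) and T(p1)
#'
#' `neighbor_count` is the number of nonzero entries among the 8 neighbors
#' p2..p9; `transition_count` is the number of 0-to-1 transitions scanning
#' the cyclic sequence p2, p3, ..., p9 and back to p2.
#'
#' @param nb binary vector of length 8, ordered (p2, p3, ..., p9).
#' @return integer count.
#' @export
neighbor_count <- function(nb) {
  stopifnot(length(nb) == 8L, all(nb %in% c(0, 1)))
  as.integer(sum(nb))
}

#' @rdname neighbor_count
#' @export
transition_count <- function(nb) {
  stopifnot(length(nb) == 8L, all(nb %in% c(0, 1)))
  nxt <- c(nb[-1], nb[1])
  as.integer(sum(nb == 0 & nxt == 1))
}

# neighbor stacks for a 0-padded binary matrix: list of 8 shifted copies
.nb_stack <- function(m) {
  lapply(seq_len(8L), function(i) {
    shift_mat(m, -.nb_offsets[i, 1], -.nb_offsets[i, 2])
  })
}

# vectorized T(p1) over the whole image from the neighbor stack
.trans_mat <- function(nb) {
  tm <- matrix(0L, nrow(nb[[1]]), ncol(nb[[1]]))
  for (i in seq_len(8L)) {
    j <- if (i == 8L) 1L else i + 1L
    tm <- tm + (nb[[i]] == 0L & nb[[j]] == 1L)
  }
  tm
}

#' Thin a binary mask to its skeleton
#'
#' @param mask [binary_mask()] or 0/1 matrix.
#' @param max_iter safety cap on full passes (default 1000).
#' @return a `skeleton` object: the 0/1 matrix with class `skeleton`,
#'   spacing carried over; see [skeleton_points()] for endpoints and
#'   branch points.
#' @export
thin <- function(mask, max_iter = 1000L) {
  sp <- spacing_mm(mask)
  m <- matrix(as.integer(as_plain_matrix(mask) != 0), nrow(mask), ncol(mask))
  # 1-px zero frame so every pixel has all 8 neighbors defined
  p <- matrix(0L, nrow(m) + 2L, ncol(m) + 2L)
  p[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m
  # simultaneous deletion can extinguish a small compact component in one
  # subiteration (e.g. a 2x2 remnant satisfies all conditions at once);
  # thinning must not destroy connectivity, so one pixel of a dying
  # component is spared (the smallest linear index, deterministically).
  # labels are computed once: thinning only ever removes pixels.
  lab0 <- label_components(p, 8)
  n0 <- attr(lab0, "n")
  for (it in seq_len(max_iter)) {
    changed <- FALSE
    for (step in 1:2) {
      nb <- .nb_stack(p)
      nsum <- Reduce(`+`, nb)
      tmat <- .trans_mat(nb)
      cond <- p == 1L & nsum >= 2L & nsum <= 6L & tmat == 1L
      if (step == 1L) {
        cond <- cond & (nb[[1]] * nb[[3]] * nb[[5]] == 0L) &  # p2*p4*p6
                       (nb[[3]] * nb[[5]] * nb[[7]] == 0L)    # p4*p6*p8
      } else {
        cond <- cond & (nb[[1]] * nb[[3]] * nb[[7]] == 0L) &  # p2*p4*p8
                       (nb[[1]] * nb[[5]] * nb[[7]] == 0L)    # p2*p6*p8
      }
      if (any(cond)) {
        rem <- tabulate(lab0[p == 1L], nbins = n0)
        del <- tabulate(lab0[cond], nbins = n0)
        for (id in which(del > 0L & del == rem)) {
          cond[which(cond & lab0 == id)[1L]] <- FALSE
        }
        if (any(cond)) {
          p[cond] <- 0L
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  out <- p[2:(nrow(m) + 1L), 2:(ncol(m) + 1L), drop = FALSE]
  structure(out, spacing_mm = sp, class = c("skeleton", "matrix", "array"))
}

#' @export
print.skeleton <- function(x, ...) {
  pts <- skeleton_points(x)
  cat(sprintf("<skeleton> %d x %d, %d px, %d endpoints, %d branch points\n",
              nrow(x), ncol(x), sum(x), nrow(pts$endpoints),
              nrow(pts$branch_points)))
  invisible(x)
}

#' Skeleton pixel inventory
#'
#' Endpoints are skeleton pixels with exactly one skeleton neighbor.
#' Branch points are pixels whose crossing number — the cyclic 0-to-1
#' transition count T(p1) around the 8-neighborhood, i.e. the number of
#' distinct branches leaving the pixel — is at least 3. (Raw neighbor
#' counting misclassifies the two-pixel staircase steps that this thinning
#' family leaves on near-diagonal lines, where interior path pixels have
#' three mutually adjacent neighbors but only two outgoing branches.)
#'
#' @param skel skeleton (0/1 matrix).
#' @return list: `pixels` (n x 2 matrix of (row, col)), `endpoints`,
#'   `branch_points`, `n_neighbors` (neighbor-count matrix),
#'   `n_branches` (crossing-number matrix).
#' @export
skeleton_points <- function(skel) {
  m <- matrix(as.integer(as_plain_matrix(skel) != 0), nrow(skel), ncol(skel))
  nb <- .nb_stack(m)
  nbm <- Reduce(`+`, nb)
  tm <- .trans_mat(nb)
  idx <- which(m == 1L)
  pix <- cbind(row = ((idx - 1L) %% nrow(m)) + 1L,
               col = ((idx - 1L) %/% nrow(m)) + 1L)
  deg <- nbm[idx]
  cross <- tm[idx]
  list(pixels = pix,
       endpoints = pix[deg == 1L, , drop = FALSE],
       branch_points = pix[cross >= 3L, , drop = FALSE],
       n_neighbors = nbm * m,
       n_branches = tm * m)
}

# walk from an endpoint along the skeleton until a branch point, another
# endpoint, or `limit` steps; returns the steps taken and what terminated
# the walk ("branch", "end", or "limit")
.branch_walk <- function(m, ep, limit) {
  nr <- nrow(m)
  cur <- ep
  visited <- (ep[2] - 1L) * nr + ep[1]
  steps <- 0L
  repeat {
    if (steps >= limit) return(list(steps = limit, terminal = "limit"))
    nbs <- matrix(rep(cur, each = 8L), 8L, 2L) + .nb_offsets
    ok <- nbs[, 1] >= 1L & nbs[, 1] <= nr & nbs[, 2] >= 1L & nbs[, 2] <= ncol(m)
    nbs <- nbs[ok, , drop = FALSE]
    on <- nbs[m[nbs] == 1L, , drop = FALSE]
    if (nrow(on) > 0L) {
      lin <- (on[, 2] - 1L) * nr + on[, 1]
      on <- on[!(lin %in% visited), , drop = FALSE]
    }
    if (nrow(on) == 0L) return(list(steps = steps, terminal = "end"))
    # stop on junction contact: a true junction pixel has crossing number
    # (cyclic 0-to-1 transitions) >= 3, while the two mutually adjacent
    # forward neighbors of a staircase step do not
    cross <- vapply(seq_len(nrow(on)), function(j) {
      nbv <- vapply(seq_len(8L), function(i) {
        r <- on[j, 1] + .nb_offsets[i, 1]; c <- on[j, 2] + .nb_offsets[i, 2]
        if (r < 1L || c < 1L || r > nr || c > ncol(m)) 0L else m[r, c]
      }, integer(1))
      sum(nbv == 0L & c(nbv[-1], nbv[1]) == 1L)
    }, integer(1))
    if (any(cross >= 3L)) return(list(steps = steps, terminal = "branch"))
    cur <- on[1L, ]
    visited <- c(visited, (cur[2] - 1L) * nr + cur[1])
    steps <- steps + 1L
  }
}

#' Remove short spurs (burrs) from a skeleton
#'
#' Each iteration deletes the current endpoints of short side branches: an
#' endpoint is removed only when walking along its branch reaches a branch
#' point within `protect_len` steps. Endpoints of pure paths (the walk
#' meets another endpoint — an unbranched vessel) and of branches longer
#' than `protect_len` (genuine vessel limbs) are protected, so burrs left
#' by thinning of a noisy boundary disappear while main vessels keep their
#' full length. Isolated single pixels are removed as well — a lone pixel
#' is not a centerline.
#'
#' @param skel skeleton matrix.
#' @param iterations number of pruning passes (default 8; `0` = identity).
#' @param protect_len branches longer than this many pixels keep their
#'   endpoint (default `5 * iterations`).
#' @return pruned skeleton.
#' @export
prune_spurs <- function(skel, iterations = 8L, protect_len = 5L * iterations) {
  if (iterations < 0) stop("prune_spurs: iterations must be >= 0", call. = FALSE)
  sp <- spacing_mm(skel)
  m <- matrix(as.integer(as_plain_matrix(skel) != 0), nrow(skel), ncol(skel))
  for (it in seq_len(iterations)) {
    pts <- skeleton_points(m)
    iso <- pts$pixels[pts$n_neighbors[pts$pixels] == 0L, , drop = FALSE]
    if (nrow(iso) > 0L) m[iso] <- 0L   # isolated pixels are not centerlines
    eps <- pts$endpoints
    if (nrow(eps) == 0L) break
    kill <- logical(nrow(eps))
    for (i in seq_len(nrow(eps))) {
      w <- .branch_walk(m, eps[i, ], protect_len + 1L)
      kill[i] <- w$terminal == "branch" && w$steps <= protect_len
    }
    if (!any(kill)) break
    m[eps[kill, , drop = FALSE]] <- 0L
  }
  if (iterations > 0L) {
    # deleting endpoints can leave corner stubs whose pixel count as
    # 3-neighbor "branch points" of a junction; one re-thinning pass
    # restores a valid one-pixel-wide skeleton
    m <- unclass(thin(m))[, ]
  }
  structure(m, spacing_mm = sp, class = c("skeleton", "matrix", "array"))
}

#' Reconnect vessel fragments across removed suspect regions
#'
#' Deleting suspect-region footprints from the tissue mask can cut a
#' vessel into pieces (e.g. an X crossing loses its center). For each
#' removed region with at least two mask components nearby, every nearby
#' component is bridged to the region's centroid with a straight
#' one-pixel line, restoring a single connected vessel so the skeleton
#' passes through the crossing. Components farther from the region than
#' `max_gap_px` are left alone. Never increases the component count.
#'
#' @param mask binary mask after suspect removal.
#' @param removed_regions integer label matrix of the removed footprints
#'   (0 = nothing removed there), e.g. the `footprint` attribute of
#'   [extract_suspects()].
#' @param max_gap_px maximum bridging distance in pixels; default
#'   `NULL` = twice the equivalent diameter of each removed region.
#' @return [binary_mask()].
#' @export
fill_gaps <- function(mask, removed_regions, max_gap_px = NULL) {
  sp <- spacing_mm(mask)
  m <- matrix(as.integer(as_plain_matrix(mask) != 0), nrow(mask), ncol(mask))
  if (is.null(removed_regions) || all(removed_regions == 0)) {
    return(binary_mask(m, sp))
  }
  lab <- label_components(m, 8)
  ids <- setdiff(unique(as.vector(removed_regions)), 0L)
  for (rid in ids) {
    ridx <- which(removed_regions == rid)
    rr <- ((ridx - 1L) %% nrow(m)) + 1L
    rc <- ((ridx - 1L) %/% nrow(m)) + 1L
    gap <- if (is.null(max_gap_px)) {
      2 * 2 * sqrt(length(ridx) / pi)   # 2 x equivalent diameter
    } else max_gap_px
    ctr <- c(round(mean(rr)), round(mean(rc)))
    # components with a pixel within `gap` of the removed region
    near <- list()
    for (cid in seq_len(attr(lab, "n"))) {
      cidx <- which(lab == cid)
      cr <- ((cidx - 1L) %% nrow(m)) + 1L
      cc <- ((cidx - 1L) %/% nrow(m)) + 1L
      # distance from each component pixel to the nearest region pixel
      keep <- abs(cr - ctr[1]) <= gap + max(abs(rr - ctr[1])) &
              abs(cc - ctr[2]) <= gap + max(abs(rc - ctr[2]))
      if (!any(keep)) next
      crk <- cr[keep]; cck <- cc[keep]
      d2 <- outer(crk, rr, `-`)^2 + outer(cck, rc, `-`)^2
      dmin <- sqrt(min(d2))
      if (dmin > gap) next
      # a severed vessel part continues beyond the bridging range; a
      # component confined to the removed blob's neighborhood is debris of
      # the eliminated suspect structure (e.g. its sub-threshold rim) and
      # is deleted rather than bridged
      reach <- sqrt(max((cr - ctr[1])^2 + (cc - ctr[2])^2))
      if (reach > gap) {
        dctr <- sqrt((crk - ctr[1])^2 + (cck - ctr[2])^2)
        j <- which.min(dctr)
        near[[length(near) + 1L]] <- c(crk[j], cck[j])
      } else {
        m[cidx] <- 0L
      }
    }
    if (length(near) >= 2L) {
      for (p in near) {
        m[bresenham(ctr, p)] <- 1L
      }
    }
  }
  binary_mask(m, sp)
}

#' Total-least-squares line through local skeleton pixels
#'
#' Fits the principal axis of the `window` skeleton pixels nearest to
#' `anchor_point`, in the implicit form `alpha*x + beta*y + gamma = 0`
#' with `x` = column, `y` = row and `alpha^2 + beta^2 = 1` (sign chosen so
#' `beta >= 0`, and `alpha > 0` for vertical lines).
#'
#' @param skel skeleton matrix.
#' @param anchor_point `(row, col)` around which to fit.
#' @param window number of nearest skeleton pixels used (default 15).
#' @return object of class `line_fit`: list with `alpha`, `beta`, `gamma`,
#'   `slope` (`-alpha/beta`, `NA` for vertical lines), `intercept`
#'   (`-gamma/beta`), `n_points`.
#' @export
fit_line_local <- function(skel, anchor_point, window = 15L) {
  m <- as_plain_matrix(skel)
  idx <- which(m != 0)
  if (length(idx) < 2L) {
    stop("fit_line_local: fewer than 2 skeleton pixels", call. = FALSE)
  }
  r <- ((idx - 1L) %% nrow(m)) + 1L
  cc <- ((idx - 1L) %/% nrow(m)) + 1L
  d2 <- (r - anchor_point[1])^2 + (cc - anchor_point[2])^2
  ord <- order(d2)[seq_len(min(window, length(idx)))]
  y <- r[ord]; x <- cc[ord]
  if (length(x) < 2L) {
    stop("fit_line_local: fewer than 2 skeleton pixels in window", call. = FALSE)
  }
  mx <- mean(x); my <- mean(y)
  sxx <- mean((x - mx)^2); syy <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  ev <- eigen(matrix(c(sxx, sxy, sxy, syy), 2L, 2L), symmetric = TRUE)
  dir <- ev$vectors[, 1]            # principal axis (dx, dy)
  ab <- c(-dir[2], dir[1])          # normal (alpha, beta)
  if (ab[2] < 0 || (ab[2] == 0 && ab[1] < 0)) ab <- -ab
  gamma <- -(ab[1] * mx + ab[2] * my)
  structure(list(alpha = ab[1], beta = ab[2], gamma = gamma,
                 slope = if (ab[2] == 0) NA_real_ else -ab[1] / ab[2],
                 intercept = if (ab[2] == 0) NA_real_ else -gamma / ab[2],
                 n_points = length(x)),
            class = "line_fit")
}

#' Stability of centerline extraction: spread of fitted-line parameters
#'
#' Given line fits from replicate extractions of the same scene (e.g.
#' under different noise realizations), reports the population standard
#' deviation of the slope `-alpha/beta` and intercept `-gamma/beta`.
#' Small deviations indicate a stable extraction algorithm.
#'
#' @param fits list of `line_fit` objects (>= 2).
#' @return named numeric `c(delta_slope, delta_intercept)`.
#' @export
fit_deviation <- function(fits) {
  if (length(fits) < 2L) stop("fit_deviation: need >= 2 replicate fits", call. = FALSE)
  betas <- vapply(fits, function(f) f$beta, numeric(1))
  if (any(betas == 0)) {
    stop("fit_deviation: vertical line in replicates (beta = 0, slope undefined)",
         call. = FALSE)
  }
  slope <- vapply(fits, function(f) -f$alpha / f$beta, numeric(1))
  itc <- vapply(fits, function(f) -f$gamma / f$beta, numeric(1))
  psd <- function(v) sqrt(mean((v - mean(v))^2))
  c(delta_slope = psd(slope), delta_intercept = psd(itc))
}
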