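#' 2D grayscale image with physical pixel spacing
#'
#' An `image2d` is a numeric matrix of intensities with a `spacing_mm`
#' attribute giving the (isotropic) physical size of one pixel in
#' millimetres. The coordinate convention used throughout the package is
#' (row, col), 1-based as usual in R, with pixel centers at integer
#' coordinates; row index increases downwards, column index to the right.
#'
#' @param x numeric matrix of intensities.
#' @param spacing_mm physical pixel size in mm/pixel (isotropic). Default
#'   0.6, the in-plane spacing of the thin-section CT data the method
#'   targets.
#' @return an object of class `image2d` (a matrix with a `spacing_mm`
#'   attribute).
#' @export
image2d <- function(x, spacing_mm = 0.6) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("image2d: `x` must be a numeric matrix", call. = FALSE)
  }
  if (!is.numeric(spacing_mm) || length(spacing_mm) != 1L || spacing_mm <= 0) {
    stop("image2d: `spacing_mm` must be a single positive number", call. = FALSE)
  }
  structure(x, spacing_mm = as.numeric(spacing_mm), class = c("image2d", "matrix", "array"))
}

#' @rdname image2d
#' @export
is_image2d <- function(x) inherits(x, "image2d")

#' @rdname image2d
#' @export
spacing_mm <- function(x) {
  s <- attr(x, "spacing_mm")
  if (is.null(s)) 0.6 else s
}

#' @export
print.image2d <- function(x, ...) {
  cat(sprintf("<image2d> %d x %d, spacing %.3g mm/px, range [%.4g, %.4g]\n",
              nrow(x), ncol(x), spacing_mm(x), min(x), max(x)))
  invisible(x)
}

# Strip class/attributes down to a plain numeric matrix.
as_plain_matrix <- function(x) {
  m <- unclass(x)
  attr(m, "spacing_mm") <- NULL
  m
}

#' Binary mask constructor
#'
#' A `binary_mask` is an integer 0/1 matrix with the same spacing
#' convention as [image2d()].
#'
#' @param x matrix coercible to 0/1 (logical or numeric).
#' @param spacing_mm mm per pixel.
#' @return object of class `binary_mask`.
#' @export
binary_mask <- function(x, spacing_mm = 0.6) {
  if (!is.matrix(x)) stop("binary_mask: `x` must be a matrix", call. = FALSE)
  m <- matrix(as.integer(x != 0), nrow(x), ncol(x))
  structure(m, spacing_mm = as.numeric(spacing_mm),
            class = c("binary_mask", "matrix", "array"))
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d, %d foreground px, spacing %.3g mm/px\n",
              nrow(x), ncol(x), sum(x), spacing_mm(x)))
  invisible(x)
}

# ---- shared low-level helpers -----------------------------------------------

# Shift a matrix by (dr, dc), filling vacated cells with `fill`.
shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  if (length(rs) == 0 || length(cs) == 0) return(out)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Reflective padding by `k` pixels on each side.
pad_reflect <- function(m, k) {
  if (k == 0) return(m)
  nr <- nrow(m); nc <- ncol(m)
  ridx <- c(rev(seq_len(min(k, nr))), seq_len(nr), nr + 1 - rev(seq_len(min(k, nr))))
  if (k > nr) ridx <- rep(ridx, length.out = nr + 2 * k)  # degenerate tiny images
  cidx <- c(rev(seq_len(min(k, nc))), seq_len(nc), nc + 1 - rev(seq_len(min(k, nc))))
  m[ridx, cidx, drop = FALSE]
}

# Separable convolution with 1D kernels along rows (kr) and columns (kc),
# reflective boundary. Kernels must have odd length.
conv_sep <- function(m, kr, kc) {
  hr <- (length(kr) - 1L) %/% 2L
  hc <- (length(kc) - 1L) %/% 2L
  k <- max(hr, hc)
  p <- pad_reflect(m, k)
  # along rows (vertical direction): convolve each column
  if (length(kr) > 1L || kr[1] != 1) {
    acc <- matrix(0, nrow(p), ncol(p))
    for (j in seq_along(kr)) {
      off <- j - 1L - hr
      acc <- acc + kr[j] * shift_mat(p, off, 0L)
    }
    p <- acc
  } else p <- p * kr[1]
  if (length(kc) > 1L || kc[1] != 1) {
    acc <- matrix(0, nrow(p), ncol(p))
    for (j in seq_along(kc)) {
      off <- j - 1L - hc
      acc <- acc + kc[j] * shift_mat(p, 0L, off)
    }
    p <- acc
  } else p <- p * kc[1]
  p[(k + 1):(k + nrow(m)), (k + 1):(k + ncol(m)), drop = FALSE]
}

# 1D Gaussian kernel and derivatives, truncated at 4 sigma.
gauss_kernel <- function(sigma, order = 0L, trunc = 4) {
  stopifnot(sigma > 0)
  h <- max(1L, ceiling(trunc * sigma))
  x <- seq(-h, h)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  switch(as.character(order),
    "0" = g,
    "1" = -x / sigma^2 * g,   # odd symmetry: zero-sum by construction
    "2" = {
      k <- (x^2 - sigma^2) / sigma^4 * g
      k - mean(k)             # enforce zero response to constants
    },
    stop("gauss_kernel: order must be 0, 1 or 2", call. = FALSE)
  )
}

#' 8-connected (or 4-connected) component labelling
#'
#' Labels connected foreground components of a binary mask. Backed by
#' [igraph::components()] on the pixel adjacency graph.
#'
#' @param mask binary matrix (non-zero = foreground).
#' @param connectivity 8 (default) or 4.
#' @return integer matrix of the same shape; 0 = background, components
#'   numbered 1..n. Attribute `n` holds the component count.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  m <- mask != 0
  nr <- nrow(m); nc <- ncol(m)
  idx <- which(m)
  lab <- matrix(0L, nr, nc)
  if (length(idx) == 0L) {
    attr(lab, "n") <- 0L
    return(lab)
  }
  pos <- matrix(0L, nr, nc)
  pos[idx] <- seq_along(idx)
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  ef <- integer(0); et <- integer(0)
  r <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  for (o in offs) {
    r2 <- r + o[1]; c2 <- cc + o[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    if (!any(ok)) next
    j <- (c2[ok] - 1L) * nr + r2[ok]
    nb <- m[j]
    if (!any(nb)) next
    ef <- c(ef, pos[idx[ok][nb]])
    et <- c(et, pos[j[nb]])
  }
  g <- igraph::make_graph(rbind(ef, et), n = length(idx), directed = FALSE)
  comp <- igraph::components(g)
  lab[idx] <- comp$membership
  attr(lab, "n") <- comp$no
  lab
}

# Integer pixel chain between two (row, col) points, inclusive (Bresenham).
bresenham <- function(p0, p1) {
  r0 <- p0[1]; c0 <- p0[2]; r1 <- p1[1]; c1 <- p1[2]
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- sign(r1 - r0); sc <- sign(c1 - c0)
  err <- dc - dr
  out <- matrix(0L, dr + dc + 2L, 2L)
  n <- 0L
  repeat {
    n <- n + 1L
    out[n, ] <- c(r0, c0)
    if (r0 == r1 && c0 == c1) break
    e2 <- 2L * err
    if (e2 > -dr) { err <- err - dr; c0 <- c0 + sc }
    if (e2 <  dc) { err <- err + dc; r0 <- r0 + sr }
  }
  out[seq_len(n), , drop = FALSE]
}
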