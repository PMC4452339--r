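# Independent oracles and fixture builders. Everything here is written
# from the definitions directly (scalar loops, closed forms), never by
# calling the package's vectorized implementations.

# direct-definition N and T for one neighborhood vector (p2..p9)
oracle_neighbor_count <- function(nb) {
  s <- 0L
  for (i in 1:8) if (nb[i] == 1) s <- s + 1L
  s
}

oracle_transition_count <- function(nb) {
  s <- 0L
  for (i in 1:8) {
    j <- if (i == 8) 1 else i + 1
    if (nb[i] == 0 && nb[j] == 1) s <- s + 1L
  }
  s
}

# scalar BFS component labelling (independent of the package's igraph path)
oracle_label <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (m[r0, c0] == 0L || lab[r0, c0] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(r0, c0)); lab[r0, c0] <- nxt
    while (length(queue) > 0) {
      q <- queue[[1]]; queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        r <- q[1] + dr; c <- q[2] + dc
        if (r < 1 || c < 1 || r > nr || c > nc) next
        if (m[r, c] == 1L && lab[r, c] == 0L) {
          lab[r, c] <- nxt
          queue[[length(queue) + 1]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# scalar reference implementation of the two-subiteration thinning rules:
# per pass, flag border pixels pixel-by-pixel, delete simultaneously; a
# component whose every remaining pixel is flagged keeps its smallest
# linear-index flagged pixel (connectivity must survive thinning)
oracle_thin <- function(m) {
  m <- matrix(as.integer(m != 0), nrow(m), ncol(m))
  pad <- matrix(0L, nrow(m) + 2, ncol(m) + 2)
  pad[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
  lab <- oracle_label(pad)
  # p2..p9 clockwise from north, (row, col) offsets
  off <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
              c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      flag <- NULL
      for (r in 2:(nrow(pad) - 1)) for (c in 2:(ncol(pad) - 1)) {
        if (pad[r, c] != 1L) next
        nb <- vapply(off, function(o) pad[r + o[1], c + o[2]], numeric(1))
        n <- oracle_neighbor_count(nb)
        if (n < 2 || n > 6) next
        if (oracle_transition_count(nb) != 1) next
        if (step == 1) {
          if (nb[1] * nb[3] * nb[5] != 0) next  # p2*p4*p6
          if (nb[3] * nb[5] * nb[7] != 0) next  # p4*p6*p8
        } else {
          if (nb[1] * nb[3] * nb[7] != 0) next  # p2*p4*p8
          if (nb[1] * nb[5] * nb[7] != 0) next  # p2*p6*p8
        }
        flag <- rbind(flag, c(r, c))
      }
      if (!is.null(flag)) {
        # spare the smallest-linear-index flagged pixel of dying components
        lin <- (flag[, 2] - 1L) * nrow(pad) + flag[, 1]
        keep <- rep(TRUE, nrow(flag))
        for (id in unique(lab[flag])) {
          flagged_id <- which(lab[flag] == id)
          if (length(flagged_id) == sum(pad == 1L & lab == id)) {
            keep[flagged_id[which.min(lin[flagged_id])]] <- FALSE
          }
        }
        flag <- flag[keep, , drop = FALSE]
      }
      if (!is.null(flag) && nrow(flag) > 0) {
        pad[flag] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  pad[2:(nrow(m) + 1), 2:(ncol(m) + 1)]
}

# seeded blobby binary mask: union of a few random Gaussian dots, thresholded
make_blob_mask <- function(seed, shape = c(40L, 40L)) {
  set.seed(seed)
  n <- sample(2:4, 1)
  acc <- matrix(0, shape[1], shape[2])
  for (i in seq_len(n)) {
    ctr <- c(runif(1, 8, shape[1] - 8), runif(1, 8, shape[2] - 8))
    img <- render_dot(ctr, runif(1, 2, 5), 255, shape)
    acc <- pmax(acc, unclass(img))
  }
  (acc >= 100) * 1L
}

# bilinear rotation about the image center by `deg` degrees
rotate_bilinear <- function(m, deg) {
  th <- deg * pi / 180
  nr <- nrow(m); nc <- ncol(m)
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  out <- matrix(0, nr, nc)
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    src <- c(cr, cc) + drop(R %*% c(r - cr, c - cc))
    r0 <- floor(src[1]); c0 <- floor(src[2])
    if (r0 < 1 || c0 < 1 || r0 >= nr || c0 >= nc) next
    fr <- src[1] - r0; fc <- src[2] - c0
    out[r, c] <- (1 - fr) * (1 - fc) * m[r0, c0] +
                 (1 - fr) * fc * m[r0, c0 + 1] +
                 fr * (1 - fc) * m[r0 + 1, c0] +
                 fr * fc * m[r0 + 1, c0 + 1]
  }
  out
}

# rotate a (row, col) point about the image center (forward rotation used
# to locate a landmark in the rotated image)
rotate_point <- function(p, deg, shape) {
  th <- deg * pi / 180
  ctr <- (shape + 1) / 2
  d <- p - ctr
  # inverse of the sampling map used in rotate_bilinear (its R is applied
  # output -> source, so a landmark moves by R^T)
  ctr + c(cos(th) * d[1] - sin(th) * d[2], sin(th) * d[1] + cos(th) * d[2])
}

count_components <- function(mask) attr(label_components(mask, 8), "n")
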