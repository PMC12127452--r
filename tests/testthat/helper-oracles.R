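# Independent oracles used to freeze expected values. These deliberately use
# brute force (grid search, exhaustive path enumeration, double loops) and
# never call the implementation paths they check.

# hierarchical grid search for the largest inscribed circle: coarse lattice,
# then a 0.01-unit lattice around the best coarse cell
oracle_inscribed_radius <- function(poly, coarse = 0.25, fine = 0.01) {
  bb <- polygon_bbox(poly)
  gx <- seq(bb["xmin"], bb["xmax"], by = coarse)
  gy <- seq(bb["ymin"], bb["ymax"], by = coarse)
  g <- expand.grid(x = gx, y = gy)
  d <- polygon_distance(g$x, g$y, poly)
  i <- which.max(d)
  fx <- seq(g$x[i] - 2 * coarse, g$x[i] + 2 * coarse, by = fine)
  fy <- seq(g$y[i] - 2 * coarse, g$y[i] + 2 * coarse, by = fine)
  f <- expand.grid(x = fx, y = fy)
  max(c(d[i], polygon_distance(f$x, f$y, poly)))
}

# smallest radius of a circle centred at the origin covering the i nearest
# whole pixels: enumerate candidate radii and count pixels fully inside
oracle_standard_radius <- function(i, L) {
  if (i == 0) return(0)
  m <- 5
  g <- expand.grid(a = -m:m, b = -m:m)
  far_corner <- sqrt((abs(g$a) + 0.5)^2 + (abs(g$b) + 0.5)^2) * L
  radii <- sort(unique(far_corner))
  for (r in radii) {
    if (sum(far_corner <= r + 1e-9) >= i) return(r)
  }
  stop("enumeration window too small")
}

# exhaustive enumeration of all monotone warping paths (match/insert/delete)
oracle_twdtw <- function(x, y, dates_x, dates_y, alpha, beta) {
  g <- abs(outer(dates_x, dates_y, "-"))
  cost <- abs(outer(x, y, "-")) + 1 / (1 + exp(-alpha * (g - beta)))
  n <- length(x); m <- length(y)
  best <- Inf
  walk <- function(i, j, acc) {
    acc <- acc + cost[i, j]
    if (acc >= best) return(invisible())  # prune only on completed-prefix cost
    if (i == n && j == m) { best <<- min(best, acc); return(invisible()) }
    if (i < n && j < m) walk(i + 1, j + 1, acc)
    if (i < n) walk(i + 1, j, acc)
    if (j < m) walk(i, j + 1, acc)
  }
  walk(1, 1, 0)
  best
}

oracle_gas <- function(mat) {
  n <- nrow(mat)
  total <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    total <- total + if (i == j) 1 else stats::cor(mat[i, ], mat[j, ])
  }
  total / n^2
}

oracle_tas <- function(mat, typical) {
  mean(apply(mat, 1, function(s) stats::cor(s, typical)))
}

# assorted random simple polygons for geometry property tests
random_test_polygon <- function(seed) {
  withr::with_seed(seed, {
    kind <- sample(c("star", "rect", "lshape"), 1)
    if (kind == "rect") {
      w <- runif(1, 8, 40); h <- runif(1, 8, 40)
      x0 <- runif(1, 0, 5); y0 <- runif(1, 0, 5)
      pitt_polygon(rbind(c(x0, y0), c(x0 + w, y0), c(x0 + w, y0 + h), c(x0, y0 + h)))
    } else if (kind == "lshape") {
      a <- runif(1, 15, 40); b <- runif(1, 6, 14)
      pitt_polygon(rbind(c(0, 0), c(a, 0), c(a, b), c(b, b), c(b, a), c(0, a)))
    } else {
      n_v <- sample(8:14, 1)
      ang <- sort(runif(n_v, 0, 2 * pi))
      rad <- runif(n_v, 6, 20)
      pitt_polygon(cbind(20 + rad * cos(ang), 20 + rad * sin(ang)))
    }
  })
}

# two clearly separated z-normalized shape families
two_family_series <- function(n_per = 20, t_ = 10, noise = 0.15, seed = 11) {
  withr::with_seed(seed, {
    peak <- sin(seq(0, pi, length.out = t_))
    ramp <- seq(1, -1, length.out = t_)
    mk <- function(base, tag) {
      m <- t(vapply(seq_len(n_per), function(i) {
        v <- base + rnorm(t_, 0, noise)
        (v - mean(v)) / sqrt(mean((v - mean(v))^2))
      }, numeric(t_)))
      rownames(m) <- sprintf("%s%03d", tag, seq_len(n_per))
      colnames(m) <- paste0("V", seq_len(t_))
      m
    }
    list(a = mk(peak, "a"), b = mk(ramp, "b"))
  })
}

# striped texture chip fixtures: two families with orthogonal orientations
striped_chips <- function(n_per = 15, side = 32, seed = 5, period = 8,
                          contrast = 0.4, noise = 0.03) {
  s_ <- side
  withr::with_seed(seed, {
    mk <- function(theta, tag) {
      tibble::tibble(
        parcel_id = sprintf("%s%03d", tag, seq_len(n_per)),
        side = s_, resized_to = NA_integer_,
        chip = lapply(seq_len(n_per), function(i) {
          idx <- outer(seq_len(s_), seq_len(s_), function(r, c)
            r * sin(theta) + c * cos(theta))
          v <- 0.5 + contrast * sin(2 * pi * idx / period + runif(1, 0, 2 * pi)) +
            matrix(rnorm(s_^2, 0, noise), s_, s_)
          array(rep(v, 3), c(s_, s_, 3))
        }))
    }
    dplyr::bind_rows(mk(0, "h"), mk(pi / 2, "v"))
  })
}

# richer two-family chip fixture: families differ in orientation, contrast
# and base intensity, like distinct crop textures
two_texture_families <- function(n_per = 10, seed = 5) {
  a <- striped_chips(n_per = n_per, contrast = 0.45, seed = seed)[seq_len(n_per), ]
  b <- striped_chips(n_per = n_per, contrast = 0.15, seed = seed + 1)
  b <- b[n_per + seq_len(n_per), ]
  b$chip <- lapply(b$chip, function(c_) c_ + 0.15)
  dplyr::bind_rows(a, b)
}
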