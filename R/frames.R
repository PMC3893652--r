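#' Rendering specification for synthetic swarm videos
#'
#' Describes how agent positions are rasterised into 8-bit grey frames:
#' animals appear as dark filled discs on a light background, matching the
#' appearance of animal groups filmed from above against an arena floor.
#' The default test-scale frame is 160 x 107 (the same 3:2 aspect as the
#' 960 x 640 experimental videos); use `render_spec(960, 640)` for the
#' full-scale profile.
#'
#' @param width,height frame size in pixels (>= 8).
#' @param agent_radius disc radius in pixels.
#' @param background_intensity,agent_intensity grey levels in 0..255; must
#'   differ.
#' @return An object of class `render_spec`.
#' @export
render_spec <- function(width = 160, height = 107, agent_radius = 3,
                        background_intensity = 220, agent_intensity = 30) {
  check_scalar(width, "width"); check_scalar(height, "height")
  check_scalar(agent_radius, "agent_radius")
  check_scalar(background_intensity, "background_intensity")
  check_scalar(agent_intensity, "agent_intensity")
  if (width < 8 || height < 8) stop("width and height must be >= 8 pixels")
  if (background_intensity < 0 || background_intensity > 255 ||
      agent_intensity < 0 || agent_intensity > 255) {
    stop("intensities must lie in 0..255")
  }
  if (agent_intensity == background_intensity) {
    stop("agent_intensity must differ from background_intensity")
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 agent_radius = agent_radius,
                 background_intensity = as.integer(background_intensity),
                 agent_intensity = as.integer(agent_intensity)),
            class = "render_spec")
}

#' Render a swarm trajectory into a grey-scale frame stack
#'
#' One frame per stored step. World coordinates are mapped to pixels by a
#' single linear scale `(width - 1) / domain_size` applied to both axes
#' (aspect preserved; if `height < width` the top of the square arena is
#' cropped, as a camera with a 3:2 sensor would). The image y-axis points
#' down. Each agent is a filled disc: a pixel is foreground when its centre
#' lies within `agent_radius` (inclusive) of the agent's scaled position.
#'
#' @param trajectory a `swarm_trajectory`.
#' @param spec a [render_spec()].
#' @return A [frame_stack()] whose rows are the flattened frames.
#' @export
render_frames <- function(trajectory, spec) {
  stopifnot(inherits(trajectory, "swarm_trajectory"), inherits(spec, "render_spec"))
  ns <- dim(trajectory$positions)[1]
  na <- dim(trajectory$positions)[2]
  L <- trajectory$params$domain_size
  if (ns < 1) stop("trajectory has no steps")
  px <- matrix(trajectory$positions[, , 1], ns, na)
  py <- matrix(trajectory$positions[, , 2], ns, na)
  if (any(px < 0 | px > L | py < 0 | py > L)) {
    stop("agent positions outside [0, domain_size]^2; renderer requires simulator invariants")
  }
  w <- spec$width; h <- spec$height
  scale <- (w - 1) / L
  r <- spec$agent_radius
  ri <- ceiling(r)
  data <- matrix(as.integer(spec$background_intensity), ns, w * h)

  for (t in seq_len(ns)) {
    frame_cols <- integer(0)
    for (a in seq_len(na)) {
      cx <- px[t, a] * scale                 # pixel column coordinate (0-based)
      cy <- (h - 1) - py[t, a] * scale       # pixel row coordinate, y down
      xs <- max(0L, floor(cx - ri)):min(w - 1L, ceiling(cx + ri))
      ys <- max(0L, floor(cy - ri)):min(h - 1L, ceiling(cy + ri))
      if (length(xs) == 0L || length(ys) == 0L) next
      gx <- rep(xs, times = length(ys))
      gy <- rep(ys, each = length(xs))
      inside <- (gx - cx)^2 + (gy - cy)^2 <= r * r
      if (any(inside)) {
        # row-major flattening: pixel (row gy, col gx) -> gy * w + gx + 1
        frame_cols <- c(frame_cols, gy[inside] * w + gx[inside] + 1L)
      }
    }
    if (length(frame_cols)) data[t, unique(frame_cols)] <- spec$agent_intensity
  }
  frame_stack(data, width = w, height = h)
}

#' Sample a point cloud on a known manifold
#'
#' Ground-truth fixtures for the dimensionality-estimation contract: points
#' on a manifold of known intrinsic dimension, embedded in `ambient_dim`
#' dimensions by a seeded random orthogonal map, with optional isotropic
#' Gaussian noise.
#'
#' Kinds: `line` (segment, intrinsic dim 1), `circle` (unit circle, 1),
#' `plane` (uniform square patch, 2), `swiss_roll` (the classical benchmark
#' spiral sheet, 2; requires `ambient_dim >= 3`).
#'
#' @param kind one of `"line"`, `"circle"`, `"plane"`, `"swiss_roll"`.
#' @param n number of points (>= 10).
#' @param ambient_dim ambient dimension (>= the manifold's natural embedding
#'   dimension).
#' @param noise_sd isotropic Gaussian noise sd added after embedding.
#' @param seed integer seed.
#' @return Object of class `manifold_cloud`: list with `points` (`n x
#'   ambient_dim`), `kind`, `intrinsic_dim`, `noise_sd`, and `latent` (the
#'   intrinsic parameters, useful for oracles).
#' @export
make_manifold_cloud <- function(kind, n, ambient_dim = NULL, noise_sd = 0,
                                seed = 1L) {
  kind <- match.arg(kind, c("line", "circle", "plane", "swiss_roll"))
  check_scalar(n, "n")
  if (n < 10) stop("n must be >= 10")
  intrinsic <- switch(kind, line = 1L, circle = 1L, plane = 2L, swiss_roll = 2L)
  natural <- switch(kind, line = 1L, circle = 2L, plane = 2L, swiss_roll = 3L)
  if (is.null(ambient_dim)) ambient_dim <- natural
  check_scalar(ambient_dim, "ambient_dim")
  if (ambient_dim < natural) {
    stop("ambient_dim must be >= ", natural, " for kind '", kind, "'")
  }
  with_seed(seed, {
    if (kind == "line") {
      t1 <- sort(runif(n, 0, 10))
      base <- cbind(t1)
      latent <- t1
    } else if (kind == "circle") {
      th <- runif(n, 0, 2 * pi)
      base <- cbind(cos(th), sin(th))
      latent <- th
    } else if (kind == "plane") {
      u <- runif(n, 0, 5); v <- runif(n, 0, 5)
      base <- cbind(u, v)
      latent <- cbind(u, v)
    } else {
      # one full turn (t in [1.5pi, 3.5pi]) with width comparable to the
      # unrolled arc length (~49 x 35): both intrinsic directions carry
      # similar extent (so the roll is genuinely two-dimensional under the
      # residual-variance criterion) and the inter-coil gap (2pi) stays well
      # above nu-NN edge lengths at the fixture densities, preventing
      # shortcut edges across coils
      u <- runif(n); v <- runif(n, 0, 35)
      t1 <- 1.5 * pi + 2 * pi * u
      base <- cbind(t1 * cos(t1), v, t1 * sin(t1))
      latent <- cbind(t1, v)
    }
    D <- as.integer(ambient_dim)
    X <- cbind(base, matrix(0, n, D - ncol(base)))
    if (D > 1L) {
      Q <- qr.Q(qr(matrix(rnorm(D * D), D, D)))  # random orthogonal map
      X <- X %*% Q
    }
    if (noise_sd > 0) X <- X + matrix(rnorm(n * D, 0, noise_sd), n, D)
    structure(list(points = unname(X), kind = kind, intrinsic_dim = intrinsic,
                   noise_sd = noise_sd, latent = latent),
              class = "manifold_cloud")
  })
}

#' Write frames of a stack as zero-padded 8-bit grey PNG files
#'
#' @param stack a [frame_stack()].
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @return Character vector of file paths, invisibly.
#' @export
write_frames_png <- function(stack, dir, prefix = "frame") {
  stopifnot(inherits(stack, "frame_stack"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- nrow(stack$data)
  pad <- max(4L, nchar(as.character(n)))
  paths <- file.path(dir, sprintf("%s_%0*d.png", prefix, pad, seq_len(n)))
  for (i in seq_len(n)) {
    img <- matrix(stack$data[i, ], nrow = stack$height, ncol = stack$width,
                  byrow = TRUE)
    png::writePNG(img / 255, paths[i])
  }
  invisible(paths)
}
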