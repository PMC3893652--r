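#' @useDynLib swarmdim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor dist pf pt rnorm runif sd aov anova lm var
#' @importFrom utils read.csv write.csv head combn
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so package randomness never perturbs user code.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

check_scalar <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || (finite && !is.finite(x))) {
    stop("'", name, "' must be a single finite number", call. = FALSE)
  }
  invisible(x)
}

#' Parameters of the self-propelled-particle swarm
#'
#' Bundles the parameters of a discrete-time Vicsek-type model: agents move at
#' constant speed in a square arena, align with the mean heading of neighbours
#' within `interaction_radius` (self included), are optionally attracted toward
#' the nearest of up to two stimuli, and receive uniform angular noise in
#' `[-noise_eta, +noise_eta]`. This is the kind of particle system used as
#' training material for human observers of collective behaviour: groups whose
#' coordination is tuned by the noise level and by zero, one, or two attractive
#' stimuli.
#'
#' @param n_agents number of agents (>= 1).
#' @param domain_size side of the square arena (arbitrary length units).
#' @param speed displacement per time step (> 0).
#' @param noise_eta half-width (radians, in `[0, pi]`) of the uniform heading
#'   perturbation. Named presets: low 0.1, moderate 1.0, high 2.5 (see
#'   [noise_presets]).
#' @param interaction_radius alignment neighbourhood radius.
#' @param stimuli `NULL`, or a matrix/data.frame with up to 2 rows of (x, y)
#'   stimulus positions inside the arena.
#' @param stimulus_strength non-negative weight mixing the attraction heading
#'   into the alignment heading (0 = ignore stimuli).
#' @param boundary `"reflective"` (agents bounce specularly off walls) or
#'   `"periodic"` (agents wrap to the opposite wall).
#' @param seed integer seed controlling initialization and noise.
#' @return An object of class `swarm_params`.
#' @seealso [simulate_swarm()], [noise_presets]
#' @export
swarm_params <- function(n_agents = 50, domain_size = 100, speed = 1,
                         noise_eta = 0.1, interaction_radius = 10,
                         stimuli = NULL, stimulus_strength = 0,
                         boundary = c("reflective", "periodic"), seed = 1L) {
  boundary <- match.arg(boundary)
  check_scalar(n_agents, "n_agents"); check_scalar(domain_size, "domain_size")
  check_scalar(speed, "speed"); check_scalar(noise_eta, "noise_eta")
  check_scalar(interaction_radius, "interaction_radius")
  check_scalar(stimulus_strength, "stimulus_strength")
  if (n_agents < 1 || n_agents != round(n_agents)) stop("n_agents must be an integer >= 1")
  if (speed <= 0) stop("speed must be > 0")
  if (domain_size <= 0) stop("domain_size must be > 0")
  if (noise_eta < 0 || noise_eta > pi) stop("noise_eta must lie in [0, pi]")
  if (stimulus_strength < 0) stop("stimulus_strength must be >= 0")
  if (!is.null(stimuli)) {
    stimuli <- as.matrix(stimuli)
    if (ncol(stimuli) != 2L || nrow(stimuli) > 2L) {
      stop("stimuli must have at most 2 rows of (x, y) coordinates")
    }
    if (nrow(stimuli) == 0L) stimuli <- NULL
    if (!is.null(stimuli) && (!all(is.finite(stimuli)) ||
        any(stimuli < 0) || any(stimuli > domain_size))) {
      stop("stimuli must be finite positions inside [0, domain_size]^2")
    }
  }
  structure(list(
    n_agents = as.integer(n_agents), domain_size = domain_size, speed = speed,
    noise_eta = noise_eta, interaction_radius = interaction_radius,
    stimuli = stimuli, stimulus_strength = stimulus_strength,
    boundary = boundary, seed = as.integer(seed)
  ), class = "swarm_params")
}

#' Noise-level presets for the swarm simulator
#'
#' Half-widths (radians) of the uniform heading noise corresponding to the
#' qualitative low / moderate / high noise levels used when generating
#' training swarms: 0.1 keeps the group deep in the ordered (aligned) regime,
#' 1.0 is near the order-disorder transition, 2.5 is deep in the disordered
#' regime.
#'
#' @format Named numeric vector with entries `low`, `moderate`, `high`.
#' @export
noise_presets <- c(low = 0.1, moderate = 1.0, high = 2.5)

# Wrap headings to (-pi, pi].
wrap_angle <- function(a) atan2(sin(a), cos(a))

#' Simulate a swarm of self-propelled particles
#'
#' Advances the Vicsek-type model of [swarm_params()] for `n_steps` stored
#' states (the first state is the random initial configuration; `n_steps - 1`
#' updates are applied). Each update sets an agent's heading to the circular
#' mean of the headings of all agents within `interaction_radius` (itself
#' included), mixes in a unit attraction vector toward the nearest stimulus
#' with weight `stimulus_strength`, adds uniform noise in
#' `[-noise_eta, +noise_eta]`, then moves the agent a distance `speed` along
#' the new heading, applying the boundary rule. Periodic neighbourhoods use
#' minimum-image distances; reflective runs use plain Euclidean distances.
#'
#' @param params a [swarm_params()] object.
#' @param n_steps number of stored states (>= 1).
#' @param init_positions optional `n_agents x 2` matrix of starting positions
#'   (default: uniform over the arena, from the seed).
#' @param init_headings optional length-`n_agents` vector of starting
#'   headings in radians (default: uniform on `(-pi, pi]`, from the seed).
#' @return An object of class `swarm_trajectory`: list with `positions`
#'   (`n_steps x n_agents x 2` array), `headings` (`n_steps x n_agents`
#'   matrix, radians) and `params`.
#' @examples
#' tr <- simulate_swarm(swarm_params(n_agents = 20, seed = 7), n_steps = 50)
#' polarization(tr$headings[50, ])
#' @export
simulate_swarm <- function(params, n_steps, init_positions = NULL,
                           init_headings = NULL) {
  if (!inherits(params, "swarm_params")) stop("params must be a swarm_params object")
  check_scalar(n_steps, "n_steps")
  if (n_steps < 1 || n_steps != round(n_steps)) stop("n_steps must be an integer >= 1")
  n <- params$n_agents
  L <- params$domain_size
  n_steps <- as.integer(n_steps)

  pos <- array(NA_real_, dim = c(n_steps, n, 2L))
  hdg <- matrix(NA_real_, n_steps, n)

  if (!is.null(init_positions)) {
    init_positions <- as.matrix(init_positions)
    stopifnot(nrow(init_positions) == n, ncol(init_positions) == 2L,
              all(init_positions >= 0), all(init_positions <= L))
  }
  if (!is.null(init_headings)) stopifnot(length(init_headings) == n)

  with_seed(params$seed, {
    p <- if (is.null(init_positions)) matrix(runif(2L * n, 0, L), n, 2L) else init_positions
    h <- if (is.null(init_headings)) runif(n, -pi, pi) else wrap_angle(init_headings)
    pos[1L, , ] <- p
    hdg[1L, ] <- h
    if (n_steps > 1L) for (t in 2L:n_steps) {
      upd <- step_swarm(p, h, params)
      p <- upd$p; h <- upd$h
      pos[t, , ] <- p
      hdg[t, ] <- h
    }
  })
  structure(list(positions = pos, headings = hdg, params = params),
            class = "swarm_trajectory")
}

# One synchronous update of positions p (n x 2) and headings h.
# Draws exactly n noise deviates regardless of boundary rule, so that periodic
# and reflective runs from the same seed share their random streams.
step_swarm <- function(p, h, params) {
  n <- nrow(p)
  L <- params$domain_size
  r <- params$interaction_radius

  dx <- outer(p[, 1], p[, 1], "-")
  dy <- outer(p[, 2], p[, 2], "-")
  if (params$boundary == "periodic") {
    dx <- dx - L * round(dx / L)
    dy <- dy - L * round(dy / L)
  }
  nb <- (dx * dx + dy * dy) <= r * r   # includes self (diagonal TRUE)

  cs <- cos(h); sn <- sin(h)
  mean_c <- as.vector(nb %*% cs) / rowSums(nb)
  mean_s <- as.vector(nb %*% sn) / rowSums(nb)
  vx <- mean_c; vy <- mean_s
  nrm <- sqrt(vx * vx + vy * vy)
  # degenerate circular mean (perfectly opposed neighbours): keep own heading
  deg <- nrm < 1e-12
  vx[deg] <- cos(h[deg]); vy[deg] <- sin(h[deg])
  nrm[deg] <- 1
  vx <- vx / nrm; vy <- vy / nrm

  if (!is.null(params$stimuli) && params$stimulus_strength > 0) {
    st <- params$stimuli
    d2 <- sapply(seq_len(nrow(st)), function(k) {
      (p[, 1] - st[k, 1])^2 + (p[, 2] - st[k, 2])^2
    })
    d2 <- matrix(d2, nrow = n)
    nearest <- max.col(-d2, ties.method = "first")
    ax <- st[nearest, 1] - p[, 1]
    ay <- st[nearest, 2] - p[, 2]
    an <- sqrt(ax * ax + ay * ay)
    ok <- an > 1e-12
    ax[ok] <- ax[ok] / an[ok]; ay[ok] <- ay[ok] / an[ok]
    ax[!ok] <- 0; ay[!ok] <- 0
    vx <- vx + params$stimulus_strength * ax
    vy <- vy + params$stimulus_strength * ay
  }

  h_new <- atan2(vy, vx) + runif(n, -params$noise_eta, params$noise_eta)
  h_new <- wrap_angle(h_new)

  x <- p[, 1] + params$speed * cos(h_new)
  y <- p[, 2] + params$speed * sin(h_new)

  if (params$boundary == "periodic") {
    x <- x %% L
    y <- y %% L
  } else {
    # specular reflection; loop handles (rare) multiple bounces per step
    for (i in seq_len(n)) {
      while (x[i] < 0 || x[i] > L || y[i] < 0 || y[i] > L) {
        if (x[i] < 0) { x[i] <- -x[i]; h_new[i] <- wrap_angle(pi - h_new[i]) }
        if (x[i] > L) { x[i] <- 2 * L - x[i]; h_new[i] <- wrap_angle(pi - h_new[i]) }
        if (y[i] < 0) { y[i] <- -y[i]; h_new[i] <- wrap_angle(-h_new[i]) }
        if (y[i] > L) { y[i] <- 2 * L - y[i]; h_new[i] <- wrap_angle(-h_new[i]) }
      }
    }
  }
  list(p = cbind(x, y), h = h_new)
}

#' Group polarization
#'
#' Magnitude of the mean unit-heading vector: 1 when all agents point the same
#' way, near 0 for incoherent headings. Low polarization corresponds to high
#' observer-assigned collective behaviour scores (less coordination).
#'
#' @param headings numeric vector of headings in radians (length >= 1).
#' @return A number in `[0, 1]`.
#' @examples
#' polarization(c(0, 0, 0))        # 1
#' polarization(c(0, pi))          # 0
#' polarization(c(0, pi / 2))      # sqrt(2)/2
#' @export
polarization <- function(headings) {
  if (length(headings) < 1L || !is.numeric(headings) || anyNA(headings)) {
    stop("headings must be a non-empty numeric vector")
  }
  sqrt(mean(cos(headings))^2 + mean(sin(headings))^2)
}

#' Simulate paired observer scores for a set of trials
#'
#' Emulates the scoring protocol in which each trial video is rated by two
#' independent observers on an integer collective behaviour measure (CBM) from
#' 1 (most interaction) to 12 (least). Each score is
#' `clip(round(intercept + slope * true_dim + N(0, noise_sd)), 1, 12)`. The
#' affine map defaults to the identity because the CBM scale was constructed
#' to be directly comparable to the embedding-manifold dimensionality.
#'
#' @param true_dims integer vector of true per-trial dimensionalities (>= 1).
#' @param noise_sd standard deviation of the observer noise (>= 0).
#' @param seed integer seed.
#' @param intercept,slope affine map from dimensionality to expected score.
#' @return data.frame with columns `trial_id`, `cbm_a`, `cbm_b`.
#' @export
simulate_observer_scores <- function(true_dims, noise_sd = 1, seed = 1L,
                                     intercept = 0, slope = 1) {
  if (length(true_dims) < 1L || any(!is.finite(true_dims)) || any(true_dims < 1)) {
    stop("true_dims entries must be finite and >= 1")
  }
  check_scalar(noise_sd, "noise_sd")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  n <- length(true_dims)
  mu <- intercept + slope * true_dims
  with_seed(seed, {
    a <- pmin(pmax(round(mu + rnorm(n, 0, noise_sd)), 1), 12)
    b <- pmin(pmax(round(mu + rnorm(n, 0, noise_sd)), 1), 12)
    data.frame(trial_id = seq_len(n), cbm_a = as.integer(a), cbm_b = as.integer(b))
  })
}

#' Write / read a swarm trajectory as CSV with a key-value sidecar
#'
#' The CSV has columns `step`, `agent`, `x`, `y`, `heading`; the sidecar
#' (`<path>.params`) stores the simulation parameters as `key: value` lines.
#'
#' @param trajectory a `swarm_trajectory`.
#' @param path CSV file path.
#' @return `write_trajectory_csv` returns `path` invisibly;
#'   `read_trajectory_csv` returns the long-format data.frame.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "swarm_trajectory"))
  ns <- dim(trajectory$positions)[1]
  na <- dim(trajectory$positions)[2]
  df <- data.frame(
    step = rep(seq_len(ns), each = na),
    agent = rep(seq_len(na), times = ns),
    x = as.vector(t(matrix(trajectory$positions[, , 1], ns, na))),
    y = as.vector(t(matrix(trajectory$positions[, , 2], ns, na))),
    heading = as.vector(t(trajectory$headings))
  )
  write.csv(df, path, row.names = FALSE)
  p <- trajectory$params
  keys <- c(n_agents = p$n_agents, domain_size = p$domain_size, speed = p$speed,
            noise_eta = p$noise_eta, interaction_radius = p$interaction_radius,
            stimulus_strength = p$stimulus_strength, seed = p$seed)
  lines <- c(paste0(names(keys), ": ", keys), paste0("boundary: ", p$boundary))
  if (!is.null(p$stimuli)) {
    lines <- c(lines, paste0("stimulus_", seq_len(nrow(p$stimuli)), ": ",
                             p$stimuli[, 1], ",", p$stimuli[, 2]))
  }
  writeLines(lines, paste0(path, ".params"))
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  read.csv(path)
}

#' Write observer scores as CSV
#'
#' @param scores data.frame from [simulate_observer_scores()].
#' @param path CSV file path.
#' @export
write_scores_csv <- function(scores, path) {
  write.csv(scores[, c("trial_id", "cbm_a", "cbm_b")], path, row.names = FALSE)
  invisible(path)
}

#' @export
print.swarm_trajectory <- function(x, ...) {
  d <- dim(x$positions)
  cat("Swarm trajectory:", d[2], "agents,", d[1], "steps,",
      x$params$boundary, "boundary\n")
  cat("Final polarization:", round(polarization(x$headings[d[1], ]), 4), "\n")
  invisible(x)
}
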