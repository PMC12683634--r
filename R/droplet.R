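# Toy droplet construction and Langevin sampling under the mapping potential.

## rigid water geometry used for initial placement (Angstrom / degrees)
.r_oh <- 0.9572
.theta_hoh <- 104.52

## random rotation matrix from a quaternion (uses current RNG stream)
.rand_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

## local water coordinates: O at origin, H1 along +x, H2 in the xy plane
.water_local <- function() {
  th <- .theta_hoh * pi / 180
  rbind(c(0, 0, 0),
        c(.r_oh, 0, 0),
        c(.r_oh * cos(th), .r_oh * sin(th), 0))
}

#' Build a water droplet containing one reactive hydrogen-bonded dimer
#'
#' Places the reactive donor-acceptor water pair at the droplet center with
#' an O...O separation of 2.8 Angstrom and the transferring hydrogen on the
#' hydrogen-bond axis, then packs the remaining waters at random
#' non-overlapping positions (minimum O-O distance 2.6 Angstrom) inside the
#' confinement sphere, with random orientations.  Deterministic for a fixed
#' seed; the caller's RNG state is left untouched.
#'
#' @param n_waters number of water molecules (>= 2).
#' @param radius droplet confinement radius in Angstrom.
#' @param seed integer RNG seed.
#' @param ... further arguments passed to [protolysis_topology()].
#' @return list with \code{topology} (an \code{"evb_topology"}) and
#'   \code{frame} (an \code{"evb_frame"}: coords, elements).
#' @examples
#' d <- build_droplet(10, 6, seed = 1)
#' d$topology
#' @export
build_droplet <- function(n_waters, radius, seed, ...) {
  stopifnot(n_waters >= 2, radius > 0)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))

  coords <- matrix(0, 3 * n_waters, 3)
  ## donor water: O1 at origin, H* toward the acceptor (+x), H1b in-plane
  th <- .theta_hoh * pi / 180
  coords[1, ] <- c(0, 0, 0)
  coords[2, ] <- c(.r_oh, 0, 0)
  coords[3, ] <- c(.r_oh * cos(th), .r_oh * sin(th), 0)
  ## acceptor water: O2 on the h-bond axis, hydrogens pointing away
  d_oo <- 2.8
  coords[4, ] <- c(d_oo, 0, 0)
  half <- th / 2
  coords[5, ] <- c(d_oo + .r_oh * cos(half), 0,  .r_oh * sin(half))
  coords[6, ] <- c(d_oo + .r_oh * cos(half), 0, -.r_oh * sin(half))

  o_pos <- rbind(coords[1, ], coords[4, ])
  wl <- .water_local()
  pack_radius <- max(radius - 0.7, 1)
  attempts <- 0L
  max_attempts <- 4000L * n_waters
  for (w in seq_len(n_waters - 2L)) {
    repeat {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop("droplet packing failed after ", max_attempts, " attempts; ",
             "increase 'radius' or decrease 'n_waters'")
      p <- stats::runif(3, -pack_radius, pack_radius)
      if (sum(p^2) > pack_radius^2) next
      if (min(sqrt(colSums((t(o_pos) - p)^2))) < 2.6) next
      break
    }
    R <- .rand_rotation()
    mol <- wl %*% t(R)
    base <- 6L + 3L * (w - 1L)
    coords[base + 1:3, ] <- sweep(mol, 2, p, "+")
    o_pos <- rbind(o_pos, p)
  }

  topo <- protolysis_topology(n_waters, radius, positions = coords, ...)
  frame <- structure(list(coords = coords,
                          elements = topo$atoms$element,
                          velocities = NULL),
                     class = "evb_frame")
  list(topology = topo, frame = frame)
}

#' Sampler configuration for the droplet Langevin engine
#'
#' @param temperature target temperature in K; default 300.
#' @param timestep integration time step in fs; default 1.
#' @param friction Langevin friction in ps^-1; default 1 (0 disables the
#'   thermostat, giving plain velocity Verlet).
#' @param n_steps production steps per window; default 2000 (2 ps).
#' @param equil_steps discarded equilibration steps per window; default 500.
#' @param stride record the diabatic energies every this many production
#'   steps; default 10.
#' @param frame_stride store coordinates every this many production steps
#'   (0 = never); default 0.
#' @param seed integer RNG seed; windows within a schedule derive their own
#'   seeds from it.
#' @param frozen_solvent if TRUE, only the six reactive-dimer atoms move;
#'   the solvent is held fixed (used to probe the role of solvent
#'   electrostatic response).
#' @param max_energy divergence threshold on |V(lambda)| in kcal/mol.
#' @return a \code{"sampler_config"} list.
#' @export
sampler_config <- function(temperature = 300, timestep = 1, friction = 1,
                           n_steps = 2000, equil_steps = 500, stride = 10,
                           frame_stride = 0, seed = 1L,
                           frozen_solvent = FALSE, max_energy = 1e8) {
  stopifnot(temperature > 0, timestep > 0, n_steps >= 1, equil_steps >= 0,
            stride >= 1, friction >= 0)
  structure(list(temperature = temperature, timestep = timestep,
                 friction = friction, n_steps = n_steps,
                 equil_steps = equil_steps, stride = stride,
                 frame_stride = frame_stride, seed = as.integer(seed),
                 frozen_solvent = frozen_solvent, max_energy = max_energy),
            class = "sampler_config")
}

.maxwell_velocities <- function(mass, temperature) {
  n <- length(mass)
  sd <- sqrt(kBT(temperature) * .kcal_to_akma / mass)
  matrix(stats::rnorm(3 * n), n, 3) * sd
}

.mobile_mask <- function(topology, config) {
  n <- nrow(topology$atoms)
  mobile <- rep(TRUE, n)
  if (isTRUE(config$frozen_solvent))
    mobile[setdiff(seq_len(n), topology$evb_region)] <- FALSE
  mobile
}

#' Sample one lambda window with Langevin (BAOAB) dynamics
#'
#' Propagates the droplet on the mapping potential
#' \eqn{V(\lambda) = \lambda\epsilon_1 + (1-\lambda)\epsilon_2} (raw
#' diabats; coupling and gas shift enter only at analysis time) and records
#' the per-frame diabatic energies at a fixed stride.  Fully deterministic
#' for a fixed (topology, frame, config, seed).
#'
#' @param topology an \code{"evb_topology"}.
#' @param start an \code{"evb_frame"}; if it carries velocities they are
#'   used, otherwise Maxwell-Boltzmann velocities are drawn.
#' @param lam mapping parameter in [0, 1] (1 = reactant potential).
#' @param config a \code{"sampler_config"}.
#' @return a \code{"traj_window"}: lambda, eps1, eps2, vmap, step,
#'   mean_temperature, final_frame (with velocities), frames (if
#'   \code{frame_stride > 0}), seed.
#' @export
run_window <- function(topology, start, lam, config = sampler_config()) {
  if (lam < 0 || lam > 1) stop("'lam' must lie in [0, 1]")
  stopifnot(inherits(config, "sampler_config"))
  prep <- .prepare_engine(topology)
  xyz <- .frame_coords(start, prep$n)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed)
  vel <- if (!is.null(start$velocities)) start$velocities
         else .maxwell_velocities(prep$mass, config$temperature)
  mobile <- .mobile_mask(topology, config)
  res <- evb_run_window_cpp(prep, xyz, vel, lam,
                            as.integer(config$n_steps),
                            as.integer(config$equil_steps),
                            config$timestep, config$friction / 1000,
                            config$temperature, as.integer(config$stride),
                            mobile, as.integer(config$frame_stride),
                            config$max_energy)
  structure(list(
    lambda = lam, eps1 = res$eps1, eps2 = res$eps2,
    vmap = lam * res$eps1 + (1 - lam) * res$eps2,
    step = res$step, mean_temperature = res$mean_temperature,
    final_frame = structure(list(coords = res$coords,
                                 elements = topology$atoms$element,
                                 velocities = res$vel),
                            class = "evb_frame"),
    frames = res$frames, seed = config$seed, window_index = NA_integer_),
    class = "traj_window")
}

#' @export
print.traj_window <- function(x, ...) {
  cat(sprintf("lambda window %.3f: %d records, <T> = %.1f K\n",
              x$lambda, length(x$eps1),
              ifelse(is.null(x$mean_temperature), NA, x$mean_temperature)))
  invisible(x)
}

#' Run a chained schedule of lambda windows
#'
#' Runs the windows of \code{lambdas} in sequence, each starting from its
#' predecessor's final frame.  With \code{ts_lambda} set, the schedule is
#' split at the transition-state window and run bidirectionally outward
#' (toward the reactant, lambda increasing to 1, and toward the product,
#' lambda decreasing to 0), both branches starting from \code{start} - the
#' initialization that minimizes hysteresis bias toward either end state.
#' Per-window seeds are \code{config$seed + window position}.
#'
#' @param topology an \code{"evb_topology"}.
#' @param start starting \code{"evb_frame"} (for TS-centered runs, a frame
#'   pre-equilibrated at \code{ts_lambda}).
#' @param lambdas vector of lambda values in [0, 1].
#' @param config a \code{"sampler_config"}.
#' @param ts_lambda transition-state lambda at which to split the schedule,
#'   or NULL for plain sequential chaining in the given order.
#' @return list of \code{"traj_window"} objects sorted by decreasing
#'   lambda, with \code{window_index} set.
#' @export
run_schedule <- function(topology, start, lambdas, config = sampler_config(),
                         ts_lambda = NULL) {
  if (any(lambdas < 0 | lambdas > 1)) stop("lambdas must lie in [0, 1]")
  run_branch <- function(lams, frame, seed_base) {
    out <- list()
    for (k in seq_along(lams)) {
      cfg <- config
      cfg$seed <- as.integer(seed_base + k)
      w <- tryCatch(run_window(topology, frame, lams[k], cfg),
                    error = function(e)
                      stop("window ", k, " (lambda = ", lams[k], "): ",
                           conditionMessage(e), call. = FALSE))
      out[[k]] <- w
      frame <- w$final_frame
    }
    out
  }
  if (is.null(ts_lambda)) {
    wins <- run_branch(lambdas, start, config$seed)
  } else {
    up <- sort(lambdas[lambdas >= ts_lambda])            # TS -> reactant
    down <- sort(lambdas[lambdas < ts_lambda], decreasing = TRUE)  # TS -> product
    wins <- c(run_branch(up, start, config$seed),
              run_branch(down, start, config$seed + length(up)))
  }
  ord <- order(vapply(wins, `[[`, numeric(1), "lambda"), decreasing = TRUE)
  wins <- wins[ord]
  for (k in seq_along(wins)) wins[[k]]$window_index <- k
  wins
}

#' Equilibrate a frame at a fixed lambda
#'
#' Convenience wrapper: runs dynamics at \code{lam} and returns only the
#' final frame (used to prepare a transition-state starting configuration
#' before a bidirectional schedule).
#'
#' @inheritParams run_window
#' @param steps number of equilibration steps.
#' @return an \code{"evb_frame"} with velocities.
#' @export
equilibrate_frame <- function(topology, start, lam, config = sampler_config(),
                              steps = 2000) {
  cfg <- config
  cfg$n_steps <- as.integer(steps)
  cfg$equil_steps <- 0L
  cfg$stride <- as.integer(steps)
  cfg$frame_stride <- 0L
  run_window(topology, start, lam, cfg)$final_frame
}
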