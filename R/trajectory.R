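# --- trajectory container ---------------------------------------------------

#' Construct a molecular trajectory
#'
#' Frames x atoms x 3 coordinates (Angstrom) with per-atom metadata, a
#' frame interval (ns) and an optional per-frame applied pulling force.
#'
#' @param coords Numeric array `[frames, atoms, 3]`, Angstrom.
#' @param atoms Data frame with columns `name`, `element`, `resname`,
#'   `resid`, `chain` (one row per atom).
#' @param frame_interval_ns Time between stored frames, ns (> 0).
#' @param force_pN Optional numeric vector, one applied force per frame.
#' @param metadata Named list (ground truth, provenance).
#' @return Object of class `pg_trajectory`.
#' @export
pg_trajectory <- function(coords, atoms, frame_interval_ns = 0.4,
                          force_pN = NULL, metadata = list()) {
  pg_assert(is.array(coords) && length(dim(coords)) == 3 &&
              dim(coords)[3] == 3,
            "coords must be a frames x atoms x 3 array")
  atoms <- as_tibble(atoms)
  pg_assert(nrow(atoms) == dim(coords)[2],
            "atoms table must have one row per atom")
  pg_assert(all(c("name", "element", "resname", "resid", "chain") %in%
                  names(atoms)),
            "atoms needs name, element, resname, resid, chain columns")
  pg_assert(frame_interval_ns > 0, "frame_interval_ns must be positive")
  if (!is.null(force_pN)) {
    pg_assert(length(force_pN) == dim(coords)[1],
              "force_pN must have one value per frame")
  }
  structure(list(coords = coords, atoms = atoms,
                 frame_interval_ns = frame_interval_ns,
                 force_pN = force_pN, metadata = metadata),
            class = "pg_trajectory")
}

#' @export
print.pg_trajectory <- function(x, ...) {
  cat(sprintf("<pg_trajectory> %d frames x %d atoms, dt = %.3g ns%s\n",
              dim(x$coords)[1], dim(x$coords)[2], x$frame_interval_ns,
              if (!is.null(x$force_pN)) ", with applied-force series" else ""))
  invisible(x)
}

n_frames <- function(traj) dim(traj$coords)[1]

# --- correlated-fluctuation generator ---------------------------------------

#' Specification of programmed inter-node correlation structure
#'
#' Defines pseudo-atom nodes whose frame-to-frame displacements are drawn
#' from a zero-mean multivariate Gaussian with a prescribed correlation
#' matrix (the same scalar correlation applied to each Cartesian axis).
#' Used to hand the network-analysis stage inputs with known answers.
#'
#' @param target_correlation Symmetric positive-semidefinite matrix with
#'   unit diagonal, entries in `[-1, 1]`.
#' @param mean_positions n x 3 matrix of node mean positions, Angstrom.
#'   Default: nodes spaced 4 Angstrom along x.
#' @param fluctuation_sd Per-axis displacement standard deviation,
#'   Angstrom. Default 1.
#' @return Object of class `correlation_spec`.
#' @export
correlation_spec <- function(target_correlation, mean_positions = NULL,
                             fluctuation_sd = 1) {
  C <- as.matrix(target_correlation)
  pg_assert(nrow(C) == ncol(C), "target_correlation must be square")
  pg_assert(max(abs(C - t(C))) < 1e-10, "target_correlation must be symmetric")
  pg_assert(max(abs(diag(C) - 1)) < 1e-10,
            "target_correlation must have unit diagonal")
  pg_assert(all(abs(C) <= 1 + 1e-12), "correlations must lie in [-1, 1]")
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  pg_assert(min(ev) > -1e-8, "target_correlation must be positive semidefinite")
  n <- nrow(C)
  if (is.null(mean_positions)) {
    mean_positions <- cbind(4 * (seq_len(n) - 1), 0, 0)
  }
  mean_positions <- as.matrix(mean_positions)
  pg_assert(nrow(mean_positions) == n && ncol(mean_positions) == 3,
            "mean_positions must be n x 3")
  pg_assert(fluctuation_sd > 0, "fluctuation_sd must be positive")
  structure(list(n_nodes = n, target_correlation = C,
                 mean_positions = mean_positions,
                 fluctuation_sd = fluctuation_sd),
            class = "correlation_spec")
}

#' Generate a trajectory with programmed correlation structure
#'
#' Per-frame node displacements are i.i.d. draws from a zero-mean
#' multivariate Gaussian whose correlation matrix equals the
#' specification's target, applied independently to each Cartesian axis.
#' The empirical motional correlation converges to the target as the
#' number of frames grows.
#'
#' @param spec A [correlation_spec()].
#' @param n_frames Number of frames (>= 2).
#' @param seed Integer seed.
#' @param frame_interval_ns Frame spacing, ns. Default 0.4.
#' @return A [pg_trajectory()] of pseudo-CA nodes.
#' @export
generate_correlated_trajectory <- function(spec, n_frames, seed = 1,
                                           frame_interval_ns = 0.4) {
  pg_assert(inherits(spec, "correlation_spec"),
            "spec must be a correlation_spec")
  pg_assert(n_frames >= 2,
            "need at least 2 frames for a defined correlation")
  set.seed(seed)
  n <- spec$n_nodes
  e <- eigen(spec$target_correlation, symmetric = TRUE)
  L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), n) %*% t(e$vectors)
  coords <- array(0, dim = c(n_frames, n, 3))
  for (ax in 1:3) {
    Z <- matrix(rnorm(n_frames * n), n_frames, n)
    coords[, , ax] <- sweep(spec$fluctuation_sd * (Z %*% L), 2,
                            spec$mean_positions[, ax], "+")
  }
  atoms <- tibble(name = "CA", element = "C", resname = "GLY",
                  resid = seq_len(n), chain = "A")
  pg_trajectory(coords, atoms, frame_interval_ns,
                metadata = list(generator = "correlated",
                                target_correlation = spec$target_correlation,
                                seed = seed))
}

# --- toy steered-pulling generator ------------------------------------------

#' Toy constant-velocity pulling model
#'
#' A minimal overdamped harmonic chain pulled at constant velocity through
#' a harmonic spring, emulating the shape of a constant-velocity steered-MD
#' run: a force ramp, a load-triggered opening of a lid ("loop") atom, and
#' a terminal detachment. It exists to give the trajectory-analysis stages
#' inputs with known ground truth, not to model a real force field.
#'
#' @param n_nodes Chain length. Default 10.
#' @param bond_k Chain bond stiffness, kcal/(mol A^2). Default 10.
#' @param spring_constant Pulling spring constant, kcal/(mol A^2).
#'   Default 1.0.
#' @param pull_velocity Pulling velocity, A/ns. Default 0.5.
#' @param anchor_node,pull_node Restrained and pulled chain nodes.
#' @param lid_anchor Chain node carrying the lid atom.
#' @param loop_open_force Load (pN) above which the lid is released.
#'   Default 300. `Inf` disables the opening.
#' @param loop_open_offset Programmed increase of the lid pair distance on
#'   opening, Angstrom. Default 8.
#' @param detach_force Load (pN) at which the pulled bond detaches.
#'   Default 500. `Inf` disables rupture.
#' @param kBT_kcal Thermal energy, kcal/mol. Default 0.596 (300 K).
#' @return Object of class `toy_pull_model`.
#' @export
toy_pull_model <- function(n_nodes = 10, bond_k = 5, spring_constant = 1.0,
                           pull_velocity = 0.5, anchor_node = 1,
                           pull_node = n_nodes, lid_anchor = 5,
                           loop_open_force = 300, loop_open_offset = 8,
                           detach_force = 500, kBT_kcal = 0.596) {
  pg_assert(anchor_node != pull_node, "anchor and pull nodes must differ")
  pg_assert(loop_open_force > 0, "loop_open_force must be positive")
  pg_assert(n_nodes >= 3, "need at least 3 chain nodes")
  pg_assert(lid_anchor %in% seq_len(n_nodes), "lid_anchor must be a chain node")
  structure(list(n_nodes = n_nodes, bond_k = bond_k,
                 spring_constant = spring_constant,
                 pull_velocity = pull_velocity,
                 anchor_node = anchor_node, pull_node = pull_node,
                 lid_anchor = lid_anchor,
                 loop_open_force = loop_open_force,
                 loop_open_offset = loop_open_offset,
                 detach_force = detach_force, kBT_kcal = kBT_kcal),
            class = "toy_pull_model")
}

#' Generate a toy constant-velocity pulling trajectory
#'
#' Overdamped Langevin integration of the [toy_pull_model()]: the chain is
#' stretched along z by a spring moving at constant velocity, the recorded
#' force is spring extension times spring constant (in pN), the lid atom's
#' rest offset jumps by the programmed amount when the force first exceeds
#' `loop_open_force`, and the pulled bond detaches when the force exceeds
#' `detach_force`. Ground truth (loop-open frame, rupture frame, offset)
#' is stored in the trajectory metadata.
#'
#' @param model A [toy_pull_model()].
#' @param n_frames Number of stored frames.
#' @param seed Integer seed.
#' @param frame_interval_ns Frame spacing, ns. Default 0.4.
#' @param substeps Integration substeps per frame. Default 40.
#' @return A [pg_trajectory()] with the force series in `$force_pN`.
#' @export
generate_smd_pull_trajectory <- function(model, n_frames, seed = 1,
                                         frame_interval_ns = 0.4,
                                         substeps = 40) {
  pg_assert(inherits(model, "toy_pull_model"),
            "model must be a toy_pull_model")
  set.seed(seed)
  n <- model$n_nodes
  spacing <- 4
  kcal_per_A_to_pN <- 69.478577  # 1 kcal/(mol A) in pN
  # chain along z, lid atom offset in x from its anchor node
  pos <- cbind(0, 0, spacing * (seq_len(n) - 1))
  lid_rest_closed <- 4
  lid <- c(lid_rest_closed, 0, pos[model$lid_anchor, 3])
  x <- rbind(pos, lid)
  lid_idx <- n + 1L
  mu_dt <- 0.02            # mobility x substep timestep, A^2 mol / kcal
  noise_sd <- sqrt(2 * mu_dt * model$kBT_kcal)
  dt_frame <- frame_interval_ns
  coords <- array(NA_real_, dim = c(n_frames, n + 1L, 3))
  force <- numeric(n_frames)
  lid_rest <- lid_rest_closed
  open_frame <- NA_integer_
  rupture_frame <- NA_integer_
  attached <- TRUE
  z0 <- x[model$pull_node, 3]
  chain <- seq_len(n)
  for (f in seq_len(n_frames)) {
    t_ns <- (f - 1) * dt_frame
    for (ss in seq_len(substeps)) {
      ts <- t_ns + (ss - 1) * dt_frame / substeps
      grad <- matrix(0, n + 1L, 3)
      # chain bonds (vectorised over bonds)
      dv <- x[chain[-1], , drop = FALSE] - x[chain[-n], , drop = FALSE]
      r <- sqrt(rowSums(dv^2))
      fb <- (model$bond_k * (r - spacing) / r) * dv
      grad[chain[-n], ] <- grad[chain[-n], ] + fb
      grad[chain[-1], ] <- grad[chain[-1], ] - fb
      # lid tether: spring toward its anchor node plus rest offset in x
      target <- x[model$lid_anchor, ] + c(lid_rest, 0, 0)
      grad[lid_idx, ] <- grad[lid_idx, ] +
        model$bond_k * (target - x[lid_idx, ])
      # pulling spring along z
      if (attached) {
        zs <- z0 + model$pull_velocity * ts
        grad[model$pull_node, 3] <- grad[model$pull_node, 3] +
          model$spring_constant * (zs - x[model$pull_node, 3])
      }
      grad[model$anchor_node, ] <- 0  # position restraint
      x <- x + mu_dt * grad +
        matrix(rnorm(3 * (n + 1L), sd = noise_sd), n + 1L, 3)
      x[model$anchor_node, ] <- c(0, 0, 0)
    }
    coords[f, , ] <- x
    fr <- if (attached) {
      zs <- z0 + model$pull_velocity * (t_ns + dt_frame * (substeps - 1) /
                                          substeps)
      model$spring_constant * (zs - x[model$pull_node, 3]) *
        kcal_per_A_to_pN
    } else 0
    force[f] <- fr
    if (is.na(open_frame) && fr > model$loop_open_force) {
      open_frame <- f
      lid_rest <- lid_rest_closed + model$loop_open_offset
    }
    if (attached && fr > model$detach_force) {
      rupture_frame <- f
      attached <- FALSE
    }
  }
  atoms <- tibble(name = c(rep("CA", n), "LID"),
                  element = "C",
                  resname = c(rep("GLY", n), "LID"),
                  resid = c(seq_len(n), n + 1L),
                  chain = "A")
  pg_trajectory(coords, atoms, frame_interval_ns, force_pN = force,
                metadata = list(generator = "smd_pull",
                                loop_open_frame = open_frame,
                                rupture_frame = rupture_frame,
                                loop_open_offset = model$loop_open_offset,
                                lid_pair = c(lid_idx, model$lid_anchor),
                                seed = seed))
}
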