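#' Langevin simulation parameters
#'
#' Defaults follow the coarse-grained protocol used throughout the
#' package: a 0.02 ps time step at 298 K in the canonical (NVT) ensemble.
#' The friction constant is a thermostat coupling, not a physical solvent
#' viscosity; 5 ps^-1 balances sampling speed against thermostat fidelity.
#'
#' @param nSteps number of integration steps.
#' @param dt time step, ps.
#' @param temperature target temperature, K.
#' @param friction Langevin friction, ps^-1; 0 gives the deterministic
#'   velocity-Verlet limit (useful for energy-conservation checks).
#' @param saveEvery save a frame every this many steps.
#' @param seed RNG seed; recorded in the trajectory metadata so a run is
#'   fully reproducible.
#' @return a \linkS4class{SimulationParams}.
#' @export
simulationParams <- function(nSteps, dt = 0.02, temperature = 298,
                             friction = 5, saveEvery = 10L, seed = 1L) {
  new("SimulationParams", dt = as.numeric(dt), nSteps = as.integer(nSteps),
      temperature = as.numeric(temperature), friction = as.numeric(friction),
      saveEvery = as.integer(saveEvery), seed = as.integer(seed))
}

.maxFrequency <- function(net) {
  # largest angular frequency (ps^-1) of the mass-weighted network
  h <- anmHessian(net)
  s <- rep(1 / sqrt(net@masses), each = 3L)
  hw <- h * outer(s, s)
  lmax <- max(eigen((hw + t(hw)) / 2, symmetric = TRUE,
                    only.values = TRUE)$values)
  sqrt(max(lmax, 0) * .KCAL_TO_AKMA)
}

#' Run Langevin dynamics on an elastic network
#'
#' BAOAB-split Langevin integration of the harmonic network potential.
#' Initial velocities are Maxwell-Boltzmann at the target temperature;
#' center-of-mass drift is removed at every save point. The step size is
#' checked against the harmonic stability bound dt < 2 / omega_max
#' computed from the stiffest mass-weighted mode. Identical seed and
#' parameters reproduce the trajectory bit for bit.
#'
#' @param net an \linkS4class{ElasticNetwork}.
#' @param params a \linkS4class{SimulationParams}.
#' @param initCoords starting coordinates (default: the network reference).
#' @return a \linkS4class{Trajectory} (origin "cgmd") with per-frame
#'   velocities and a metadata record of all parameters.
#' @export
runLangevin <- function(net, params, initCoords = NULL) {
  validObject(params)
  if (is.null(initCoords)) initCoords <- net@refCoords
  initCoords <- .checkCoords(net, initCoords)
  wmax <- .maxFrequency(net)
  if (wmax > 0 && params@dt >= 2 / wmax)
    stop(sprintf(
      "dt = %g ps is unstable for this network: the harmonic stability bound is dt < %.4g ps",
      params@dt, 2 / wmax))
  if (params@nSteps < params@saveEvery)
    stop("nSteps must be at least saveEvery (no frame would be saved)")
  set.seed(params@seed)
  res <- .langevinRun(
    .flatten(initCoords), net@edges[, 1L] - 1L, net@edges[, 2L] - 1L,
    net@pairGamma, net@refDist, net@masses, params@dt, params@nSteps,
    params@temperature, params@friction, params@saveEvery)
  if (res$divergedStep > 0L)
    stop(sprintf("simulation diverged (non-finite coordinates) at step %d",
                 res$divergedStep))
  trajectory(res$xyz, dt = params@dt * params@saveEvery, origin = "cgmd",
             velocities = res$vel,
             meta = list(seed = params@seed, dt = params@dt,
                         nSteps = params@nSteps,
                         temperature = params@temperature,
                         friction = params@friction,
                         saveEvery = params@saveEvery,
                         cutoff = net@cutoff, gamma = net@gamma,
                         weightExponent = net@weightExponent))
}

#' Kinetic temperature of a trajectory or velocity set
#'
#' T_kin = sum_i m_i v_i^2 / (dof kB). For a trajectory with stored
#' velocities the running mean over frames is returned (the last element
#' is the time average); since the integrator removes center-of-mass
#' momentum, the trajectory form counts dof = 3N - 3. For a single
#' N x 3 velocity matrix (e.g. freshly drawn Maxwell-Boltzmann
#' velocities) a scalar over the full 3N degrees of freedom is returned.
#'
#' @param x a \linkS4class{Trajectory} with velocities, or an N x 3
#'   velocity matrix in A/ps.
#' @param mass bead masses in amu.
#' @return running-mean kinetic temperature(s), K. The per-frame
#'   instantaneous values are attached as attribute "instantaneous".
#' @export
kineticTemperature <- function(x, mass = NULL) {
  if (is(x, "Trajectory")) {
    if (!nrow(x@velocities))
      stop("trajectory carries no velocities")
    if (is.null(mass)) stop("bead masses are required")
    m3 <- rep(mass, each = 3L)
    ke <- 0.5 * (x@velocities^2 %*% m3) / .KCAL_TO_AKMA  # kcal/mol per frame
    dof <- 3 * nBeads(x) - 3  # COM momentum is removed in saved frames
    inst <- as.numeric(2 * ke / (dof * .KB_KCAL))
    run <- cumsum(inst) / seq_along(inst)
    attr(run, "instantaneous") <- inst
    run
  } else {
    v <- as.matrix(x)
    if (is.null(mass)) stop("bead masses are required")
    ke <- 0.5 * sum(mass * rowSums(v^2)) / .KCAL_TO_AKMA
    2 * ke / (3 * nrow(v) * .KB_KCAL)
  }
}
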