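# Config-driven end-to-end runs: structure -> {ANM normal modes,
# CG Langevin dynamics + essential dynamics} -> B-factor tracks, DCCMs,
# overlap table -> plain-text report bundle with a manifest.

.defaultConfig <- function() {
  list(
    structure = list(synthetic = list(nCore = 60L, nInsert = 30L,
                                      linkerLength = 4L, seed = 1L)),
    nma = list(cutoff = 10, gamma = 1, weightExponent = 2.5,
               nModes = 3L, temperature = 298),
    cmd = list(cutoff = 8, gamma = 1, weightExponent = 0, dt = 0.02,
               nSteps = 20000L, temperature = 298, friction = 5,
               saveEvery = 10L, seed = 17L),
    eda = list(burnInFraction = 1 / 6, nComponents = 3L, gridBins = 20L,
               useCluster = TRUE)
  )
}

#' Read a pipeline run configuration
#'
#' Plain YAML with nested sections `structure`, `nma`, `cmd`, `eda` and
#' optionally `domains`; unspecified values fall back to the package
#' defaults (normal modes: cutoff 10 A, distance-weight exponent 2.5;
#' dynamics: cutoff 8 A, gamma 1 kcal mol^-1 A^-2, uniform springs,
#' 0.02 ps step at 298 K).
#'
#' @param path YAML file.
#' @return a config list for \code{\link{runPipeline}}.
#' @export
readRunConfig <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- .defaultConfig()
  for (sec in names(user)) {
    if (is.list(user[[sec]]) && sec %in% names(cfg)) {
      if (sec == "structure") cfg$structure <- user$structure
      else cfg[[sec]][names(user[[sec]])] <- user[[sec]]
    } else {
      cfg[[sec]] <- user[[sec]]
    }
  }
  cfg
}

.validateConfig <- function(config) {
  for (sec in c("nma", "cmd")) {
    if (config[[sec]]$cutoff <= 0)
      stop(sprintf("config: %s cutoff must be positive", sec))
    if (config[[sec]]$gamma <= 0)
      stop(sprintf("config: %s gamma must be positive", sec))
  }
  if (config$cmd$dt <= 0) stop("config: cmd dt must be positive")
  if (config$cmd$nSteps < 1) stop("config: cmd nSteps must be >= 1")
  b <- config$eda$burnInFraction
  if (b < 0 || b >= 1) stop("config: eda burnInFraction must be in [0, 1)")
  invisible(TRUE)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

.writeMatrixCSV <- function(m, path, resid) {
  df <- as.data.frame(m)
  colnames(df) <- resid
  df <- cbind(resid = resid, df)
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
}

#' Run the full coarse-grained dynamics pipeline
#'
#' Executes the workflow end to end: load or generate a Calpha structure;
#' ANM normal modes (B-factors, DCCM of combined modes 1-3); Langevin
#' dynamics on the uniform-spring network followed by essential dynamics
#' (superposition, covariance PCA, densest-cluster selection, DCCM and
#' B-factors); then cross-method comparison (normalized B-factor table,
#' index-paired mode/PC overlap table over the full protein and each
#' domain, composite DCCM). All parameters and seeds are serialized into
#' the manifest; two runs from the same config produce identical numeric
#' outputs.
#'
#' @param config a config list (see \code{\link{readRunConfig}}; defaults
#'   used for anything missing).
#' @param outDir output directory, created if needed. Writes
#'   bfactors.tsv, overlaps.tsv, dccm_nma.csv, dccm_eda.csv,
#'   dccm_composite.csv and manifest.json.
#' @return invisibly, a list with the intermediate objects (model,
#'   networks, modes, trajectory, pca, tables).
#' @export
runPipeline <- function(config = list(), outDir) {
  cfg <- .defaultConfig()
  for (sec in names(config)) {
    if (is.list(config[[sec]]) && sec %in% names(cfg) && sec != "structure")
      cfg[[sec]][names(config[[sec]])] <- config[[sec]]
    else cfg[[sec]] <- config[[sec]]
  }
  .validateConfig(cfg)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  model <- .stage("structure", {
    st <- cfg$structure
    if (!is.null(st$synthetic)) {
      syn <- do.call(makeTwoDomainStructure, st$synthetic)
      syn$model
    } else if (!is.null(st$pdb)) {
      m <- readCalphaPDB(st$pdb, chain = st$chain)
      if (!is.null(cfg$domains)) {
        defs <- lapply(cfg$domains, function(d)
          domainDefinition(d$name, unlist(d$start), unlist(d$end)))
        m <- assignDomains(m, defs)
      }
      m
    } else stop("config must give structure$synthetic or structure$pdb")
  })
  resid <- residLabels(model)
  domainNames <- unique(stats::na.omit(domains(model)))
  domainSel <- lapply(domainNames, function(d) domainIndices(model, d))
  names(domainSel) <- domainNames

  nmaOut <- .stage("nma", {
    net <- buildNetwork(model, cutoff = cfg$nma$cutoff,
                        gamma = cfg$nma$gamma,
                        weightExponent = cfg$nma$weightExponent)
    modes <- computeModes(anmHessian(net))
    list(net = net, modes = modes,
         bfac = nmaBfactors(modes, cfg$nma$temperature, resid = resid),
         dccm = nmaDccm(modes, seq_len(cfg$nma$nModes),
                        cfg$nma$temperature))
  })

  cedaOut <- .stage("cgmd+eda", {
    net <- buildNetwork(model, cutoff = cfg$cmd$cutoff,
                        gamma = cfg$cmd$gamma,
                        weightExponent = cfg$cmd$weightExponent)
    params <- simulationParams(
      nSteps = cfg$cmd$nSteps, dt = cfg$cmd$dt,
      temperature = cfg$cmd$temperature, friction = cfg$cmd$friction,
      saveEvery = cfg$cmd$saveEvery, seed = cfg$cmd$seed)
    traj <- runLangevin(net, params)
    fitted <- superpose(traj, coords(model))
    pca <- covariancePCA(fitted, cfg$eda$burnInFraction)
    cl <- NULL
    if (isTRUE(cfg$eda$useCluster) && nrow(pca@projections) >= 10L)
      cl <- clusterSelect(pca, cfg$eda$nComponents, cfg$eda$gridBins)
    pcs <- seq_len(cfg$eda$nComponents)
    list(net = net, traj = traj, pca = pca, cluster = cl,
         bfac = edaBfactors(pca, cl, resid = resid, source = "ceda"),
         dccm = edaDccm(pca, pcs, cl, method = "ceda"))
  })

  cmp <- .stage("compare", {
    tracks <- list()
    if (any(!is.na(model@bfactorExp)) && sd(model@bfactorExp, na.rm = TRUE) > 0)
      tracks$crystal <- normalizeBfactors(
        new("BFactorProfile", values = model@bfactorExp,
            normalization = "raw", source = "crystal", resid = resid))
    tracks$nma <- normalizeBfactors(nmaOut$bfac)
    tracks$ceda <- normalizeBfactors(cedaOut$bfac)
    ov <- modeOverlapTable(nmaOut$modes, cedaOut$pca@modes,
                           nModes = cfg$nma$nModes, domains = domainSel)
    regions <- NULL
    if (length(domainSel) >= 2L) {
      regions <- list(list(rows = domainSel[[1L]], cols = domainSel[[2L]]))
      names(regions) <- paste(names(domainSel)[1:2], collapse = "x")
    }
    pair <- dccmPairReport(cedaOut$dccm, nmaOut$dccm, regions)
    list(tracks = tracks, overlaps = ov, pair = pair)
  })

  .stage("report", {
    bdf <- data.frame(resid = resid)
    for (nm in names(cmp$tracks)) bdf[[nm]] <- cmp$tracks[[nm]]@values
    utils::write.table(bdf, file.path(outDir, "bfactors.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(cmp$overlaps, file.path(outDir, "overlaps.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    .writeMatrixCSV(correlations(nmaOut$dccm),
                    file.path(outDir, "dccm_nma.csv"), resid)
    .writeMatrixCSV(correlations(cedaOut$dccm),
                    file.path(outDir, "dccm_eda.csv"), resid)
    .writeMatrixCSV(cmp$pair$composite,
                    file.path(outDir, "dccm_composite.csv"), resid)
    manifest <- list(
      package = "enmdyn",
      version = as.character(utils::packageVersion("enmdyn")),
      config = cfg,
      nBeads = nBeads(model),
      domains = as.list(vapply(domainSel, length, 0L)),
      nmaZeroModes = numZeroModes(nmaOut$modes),
      framesSaved = nFrames(cedaOut$traj),
      meanKineticTemperature = unname(rev(kineticTemperature(
        cedaOut$traj, masses(model)))[1L]))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })

  invisible(list(model = model, nma = nmaOut, ceda = cedaOut,
                 compare = cmp, outDir = outDir))
}
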