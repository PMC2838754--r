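# End-to-end experiment: simulate -> QC -> relationship matrices ->
# relationship-constrained splits -> fits -> accuracy estimation and
# LD decomposition, all driven by one config with deterministic
# per-stage seeds fanned out from the master seed.

# stable stage-seed derivation: adding a scenario must not perturb the
# seeds of the others, so each stage hashes its own name
.stageSeed <- function(master, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 1000003
  as.integer(((master %% 1000003) * 1009 + h) %% 2147483647L)
}

# order-insensitive-enough FNV-style hash of the deparsed config,
# used only as a provenance fingerprint in the manifest
.configHash <- function(config) {
  txt <- paste(deparse(config), collapse = "\n")
  h <- 2166136261
  for (ch in utf8ToInt(txt)) h <- (bitwXor(h, ch) * 16777619) %% 2^32
  sprintf("%08x", h)
}

#' Default experiment configuration
#'
#' Desk-scale emulation of a progeny-testing dairy population: a
#' three-generation pedigree with right-skewed paternal half-sib
#' families (mean size ~6), about 1,000 genotyped non-founder bulls,
#' ~2,200 simulated loci on 5 chromosomes at ~0.064 Mb mean spacing
#' with drift-calibrated LD, one yield-like trait (h2 of a daughter
#' record 0.53) governed by 100 hidden QTL with heavy-tailed effects
#' (a few major genes, many small ones), the four a_max scenarios
#' 0.6/0.49/0.249/0.1249 with 15 replicate training/validation pairs
#' each, and training sizes 700 and 350.  Every element can be
#' overridden by name.
#'
#' @param masterSeed master seed; all stage seeds derive from it.
#' @param ... named overrides of top-level config elements.
#' @return a config list accepted by [runExperiment()].
#' @export
experimentConfig <- function(masterSeed = 1, ...) {
  cfg <- list(
    seed = masterSeed,
    simulation = list(
      nGenerations = 3, foundersPerSex = c(120, 600),
      siresPerGeneration = 110, offspringPerSire = 6,
      fullSibRate = 0.06, familySizeDispersion = 0.35,
      nChromosomes = 5, nSnpsPerChrom = 440,
      chromLengthBp = 28.16e6, effectivePopSize = 50,
      recombRatePerBp = 1e-8),
    qc = list(maxMissingRate = 0.05, minMaf = 0.03),
    traits = list(
      list(name = "milk_like", h2 = 0.53, sigma2A = 1, nQtl = 100,
           effectDistribution = "gamma")),
    scenarios = list(
      list(aMax = 0.6, valSize = 20, minValSize = 10),
      list(aMax = 0.49, valSize = 20, minValSize = 10),
      list(aMax = 0.249, valSize = 20, minValSize = 10),
      list(aMax = 0.1249, valSize = 12, minValSize = 6)),
    trainSize = 700,
    halfTrainSize = 350,
    nReplicates = 15,
    methods = c("BayesB", "G-BLUP", "P-BLUP"),
    mcmc = list(pi = 0.01, chainLength = 2500, burnIn = 1000,
                thin = 15),
    evaluation = list(ldBinMb = 0.02, ldMaxMb = 1))
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  cfg
}

#' Read an experiment configuration from YAML
#'
#' @param path YAML file; keys mirror [experimentConfig()].
#' @return config list.
#' @export
readExperimentConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- experimentConfig(masterSeed = if (!is.null(cfg$seed))
    cfg$seed else 1)
  for (nm in names(cfg)) base[[nm]] <- cfg[[nm]]
  base
}

.knownMethods <- c("BayesB", "G-BLUP", "P-BLUP")

.validateExperimentConfig <- function(config) {
  bad <- setdiff(config$methods, .knownMethods)
  if (length(bad))
    stop("validation error: unknown method name(s): ",
         paste(bad, collapse = ", "), " (known: ",
         paste(.knownMethods, collapse = ", "), ")")
  if (!length(config$scenarios))
    stop("validation error: at least one a_max scenario is required")
  for (sc in config$scenarios)
    if (is.null(sc$aMax)) stop("validation error: scenario without aMax")
  if (!length(config$traits))
    stop("validation error: at least one trait is required")
  for (tr in config$traits)
    if (is.null(tr$h2) || tr$h2 <= 0 || tr$h2 > 1)
      stop("validation error: trait h2 must be in (0, 1]")
  if (!is.null(config$halfTrainSize) &&
      config$halfTrainSize >= config$trainSize)
    stop("validation error: halfTrainSize must be below trainSize")
  invisible(TRUE)
}

#' Run the full genomic-prediction experiment
#'
#' Executes simulate -> QC -> A and G matrices -> relationship-
#' constrained splits -> BayesB / G-BLUP / P-BLUP fits -> accuracy
#' estimation per (method, trait, a_max, training size) -> the LD
#' accuracy regression per GS method, plus the LD r2 decay profile.
#' Re-running with the same config reproduces every stage bit for bit.
#'
#' @param config list from [experimentConfig()] or
#'   [readExperimentConfig()].
#' @param verbose emit progress messages.
#' @return list with elements `accuracies` (data.frame: method, trait,
#'   aMax, trainSize, accuracy, rawCorrelation, nPooled),
#'   `ldRegressions` (data.frame: method, trait, trainSize, rhoLD, d),
#'   `ldProfile` (see [ldR2Profile()]), `population` (pedigree,
#'   genotype data, phenotypes, architectures, splits), and `manifest`
#'   (config hash, stage seeds, package version).
#' @export
runExperiment <- function(config = experimentConfig(), verbose = TRUE) {
  .validateExperimentConfig(config)
  say <- function(...) if (verbose) message(...)
  sim <- config$simulation
  seeds <- list()
  stage <- function(nm) (seeds[[nm]] <<- .stageSeed(config$seed, nm))

  say("simulating pedigree ...")
  ped <- simulatePedigree(
    sim$nGenerations, sim$foundersPerSex, sim$siresPerGeneration,
    sim$offspringPerSire, sim$fullSibRate, sim$familySizeDispersion,
    seed = stage("pedigree"))
  say("simulating founder haplotypes and gene dropping ...")
  fh <- simulateFounderHaplotypes(
    length(founderIds(ped)), sim$nChromosomes, sim$nSnpsPerChrom,
    sim$chromLengthBp, sim$effectivePopSize, seed = stage("founders"))
  fh@ids <- founderIds(ped)
  rownames(fh@alleles) <- paste0(rep(fh@ids, each = 2L), c("_1", "_2"))
  haps <- geneDrop(ped, fh, sim$recombRatePerBp, seed = stage("genedrop"))

  df <- pedRecords(ped)
  candidates <- df$id[df$sex == "male" & !is.na(df$sire)]

  say("trait architectures and DYD phenotypes ...")
  archs <- list(); phenos <- list()
  for (tr in config$traits) {
    archs[[tr$name]] <- traitArchitecture(
      haps, tr$nQtl, sigma2A = tr$sigma2A, h2 = tr$h2,
      effectDistribution = tr$effectDistribution,
      referenceIds = candidates, trait = tr$name,
      seed = stage(paste0("arch:", tr$name)))
    phenos[[tr$name]] <- simulatePhenotypes(
      haps, archs[[tr$name]], ids = candidates,
      seed = stage(paste0("pheno:", tr$name)))
  }

  # markers = simulated loci minus the (hidden) QTL of every trait
  qtlIds <- unique(unlist(lapply(archs, function(a) a@qtlIds)))
  markerIds <- setdiff(haps@map$id, qtlIds)
  markerHaps <- haps[candidates, markerIds]
  gd <- asGenotypeData(markerHaps, ped)
  gd <- filterSnps(gd, config$qc$maxMissingRate, config$qc$minMaf)
  say(ncol(gd), " genotyped bulls x ", nrow(gd), " markers after QC")

  say("relationship matrices ...")
  A <- numeratorRelationshipMatrix(ped, candidates)
  G <- genomicRelationshipMatrix(gd)

  say("LD profile ...")
  ldProf <- ldR2Profile(
    markerHaps,
    binEdgesMb = seq(0, config$evaluation$ldMaxMb,
                     by = config$evaluation$ldBinMb))

  sizes <- c(full = config$trainSize)
  if (!is.null(config$halfTrainSize))
    sizes <- c(sizes, half = config$halfTrainSize)

  accRows <- list(); ldRows <- list()
  splitsByScenario <- list()
  for (sc in config$scenarios) {
    scName <- as.character(sc$aMax)
    say("scenario aMax = ", scName, " ...")
    cn <- splitConstraints(
      aMax = sc$aMax, trainSize = config$trainSize,
      valSize = sc$valSize, minValSize = sc$minValSize,
      nReplicates = config$nReplicates)
    splits <- sampleSplits(A, ped, candidates, cn,
                           seed = stage(paste0("split:", scName)))
    splitsByScenario[[scName]] <- splits
    for (sz in names(sizes)) {
      reps <- if (sz == "full") splits else lapply(splits, function(s)
        downsampleTraining(s, sizes[[sz]], A,
                           seed = stage(paste0("half:", scName, ":",
                                               s@replicate))))
      for (tr in config$traits) {
        ph <- phenos[[tr$name]]
        # plug-in residual variance consistent with the DYD noise
        # model on average (floored away from zero for stability)
        vc <- list(sigma2A = tr$sigma2A,
                   sigma2E = max(tr$sigma2A * (1 - mean(ph$weight)),
                                 0.05 * tr$sigma2A))
        ebvs <- setNames(
          lapply(config$methods, function(m) vector("list",
                                                    length(reps))),
          config$methods)
        for (i in seq_along(reps)) {
          s <- reps[[i]]
          trn <- ph[match(s@train, ph$id), , drop = FALSE]
          val <- s@validation
          for (m in config$methods) {
            e <- switch(m,
              "BayesB" = {
                fit <- fitBayesB(
                  trn, gd[, s@train], vc,
                  bayesBConfig(pi = config$mcmc$pi,
                               chainLength = config$mcmc$chainLength,
                               burnIn = config$mcmc$burnIn,
                               thin = config$mcmc$thin),
                  seed = stage(paste0("bayesb:", scName, ":", sz, ":",
                                      tr$name, ":", i)))
                ebv(predictGebv(fit, gd[, val]))
              },
              "G-BLUP" = ebv(fitBlup(trn, G, vc, targets = val))[val],
              "P-BLUP" = ebv(fitBlup(trn, A, vc, targets = val))[val])
            ebvs[[m]][[i]] <- e
          }
        }
        for (m in config$methods) {
          est <- estimateAccuracy(ebvs[[m]], ph, tr$h2)
          accRows[[length(accRows) + 1L]] <- data.frame(
            method = m, trait = tr$name, aMax = sc$aMax,
            trainSize = sizes[[sz]], accuracy = est$accuracy,
            rawCorrelation = est$rawCorrelation,
            nPooled = est$nPooled, stringsAsFactors = FALSE)
        }
      }
    }
  }
  accuracies <- do.call(rbind, accRows)

  refAmax <- as.character(max(vapply(config$scenarios,
                                     function(s) s$aMax, numeric(1))))
  if ("P-BLUP" %in% config$methods && length(config$scenarios) >= 3) {
    for (sz in names(sizes)) {
      for (tr in config$traits) {
        sub <- accuracies[accuracies$trait == tr$name &
                            accuracies$trainSize == sizes[[sz]], ]
        pb <- setNames(sub$accuracy[sub$method == "P-BLUP"],
                       as.character(sub$aMax[sub$method == "P-BLUP"]))
        for (m in setdiff(config$methods, "P-BLUP")) {
          ga <- setNames(sub$accuracy[sub$method == m],
                         as.character(sub$aMax[sub$method == m]))
          reg <- ldAccuracyRegression(ga, pb, refAmax)
          ldRows[[length(ldRows) + 1L]] <- data.frame(
            method = m, trait = tr$name, trainSize = sizes[[sz]],
            rhoLD = reg$rhoLD, d = reg$d, stringsAsFactors = FALSE)
        }
      }
    }
  }
  ldRegressions <- if (length(ldRows)) do.call(rbind, ldRows) else NULL

  manifest <- list(
    configHash = .configHash(config),
    masterSeed = config$seed,
    stageSeeds = seeds,
    nCandidates = length(candidates),
    nMarkers = nrow(gd),
    packageVersion = as.character(utils::packageVersion("gebvcv")))

  list(accuracies = accuracies, ldRegressions = ldRegressions,
       ldProfile = ldProf,
       population = list(pedigree = ped, genotypes = gd,
                         haplotypes = haps, phenotypes = phenos,
                         architectures = archs,
                         splits = splitsByScenario,
                         A = A, G = G),
       manifest = manifest)
}
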