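#' Create a synthetic cohort configuration
#'
#' Defaults mirror a large multi-site resting-state study: 116 AAL regions,
#' 230 timepoints, ten sites totalling 1160 subjects with a mild patient
#' excess (600 patients, 560 controls). Smaller configurations are
#' recommended for unit-scale work.
#'
#' @param nRois,nTimepoints dimensions of each subject's time-series matrix.
#' @param sites data.frame (`site_id`, `n_patients`, `n_controls`); default
#'   ten sites of 60 patients and 56 controls each.
#' @param effectEdges two-column matrix of ROI pairs (i < j) carrying the
#'   group effect; default none.
#' @param effectSize latent correlation shift on effect edges, in [0, 1).
#' @param baseDensity fraction of nonzero off-diagonal latent correlations.
#' @param siteShiftSd sd of per-site per-ROI gain (lognormal) and offset.
#' @param siteCorrSd sd of the per-site latent-correlation perturbation.
#' @param seed integer seed; the whole cohort is a deterministic function
#'   of the configuration.
#' @return A [CohortConfig-class] object.
#' @examples
#' cfg <- CohortConfig(nRois = 10, nTimepoints = 50,
#'                     sites = data.frame(site_id = "s1", n_patients = 5,
#'                                        n_controls = 5), seed = 1)
#' @export
CohortConfig <- function(nRois = 116L, nTimepoints = 230L,
                         sites = data.frame(
                           site_id = sprintf("site%02d", 1:10),
                           n_patients = 60L, n_controls = 56L),
                         effectEdges = matrix(integer(), 0L, 2L),
                         effectSize = 0, baseDensity = 0.15,
                         siteShiftSd = 0.1, siteCorrSd = 0.05,
                         seed = 1L) {
  ee <- rbind(effectEdges)
  storage.mode(ee) <- "integer"
  new("CohortConfig", nRois = as.integer(nRois),
      nTimepoints = as.integer(nTimepoints),
      sites = as.data.frame(sites), effectEdges = ee,
      effectSize = as.numeric(effectSize),
      baseDensity = as.numeric(baseDensity),
      siteShiftSd = as.numeric(siteShiftSd),
      siteCorrSd = as.numeric(siteCorrSd), seed = as.integer(seed))
}

## Latent machinery. All draws come from the config's seed through one
## generator stream, so a config maps to exactly one cohort.

baseCorrelation <- function(config) {
  n <- config@nRois
  pairs <- edgePairs(n)
  nE <- nrow(pairs)
  r <- numeric(nE)
  nz <- which(stats::runif(nE) < config@baseDensity)
  r[nz] <- stats::runif(length(nz), -0.6, 0.6)
  nearestCorrelation(upperUnvec(r, n, diag = 1))
}

applyEffect <- function(base, config) {
  if (!nrow(config@effectEdges) || config@effectSize == 0) return(base)
  m <- base
  for (k in seq_len(nrow(config@effectEdges))) {
    i <- config@effectEdges[k, 1L]; j <- config@effectEdges[k, 2L]
    ## shift toward +1 but never past it; clip keeps |r| <= 0.99 pre-projection
    m[i, j] <- m[j, i] <- min(m[i, j] + config@effectSize, 0.99)
  }
  nearestCorrelation(m)
}

#' Latent group and site correlation structure of a configuration
#'
#' Reconstructs, deterministically from the seed, the per-site latent
#' correlation matrices actually used by [generateCohort()]. Because the
#' group effect and the site perturbations pass through a projection back
#' to a valid correlation matrix, the realized patient-control difference
#' on the effect edges can be smaller than the nominal `effectSize`; tests
#' and power calculations should use the realized values returned here.
#'
#' @param config a [CohortConfig-class].
#' @return A list with `base` (control latent correlation before site
#'   effects), `patient` (its shifted counterpart), per-site lists
#'   `control` and `patient`, and `realizedEffect`, the mean over sites and
#'   effect edges of patient minus control latent correlation.
#' @export
latentStructure <- function(config) {
  validObject(config)
  withSeed(config@seed, {
    base <- baseCorrelation(config)
    pat <- applyEffect(base, config)
    siteC <- list(); siteP <- list()
    for (s in config@sites$site_id) {
      ## one perturbation per site, shared by both groups
      n <- config@nRois
      delta <- if (config@siteCorrSd > 0)
        stats::rnorm(n * (n - 1) / 2, sd = config@siteCorrSd) else 0
      proj <- function(m) {
        v <- pmin(pmax(upperVec(m) + delta, -0.99), 0.99)
        nearestCorrelation(upperUnvec(v, n, diag = 1))
      }
      siteC[[s]] <- proj(base)
      siteP[[s]] <- proj(pat)
    }
    realized <- 0
    if (nrow(config@effectEdges)) {
      diffs <- vapply(config@sites$site_id, function(s) {
        d <- siteP[[s]] - siteC[[s]]
        mean(d[config@effectEdges])
      }, numeric(1))
      realized <- mean(diffs)
    }
    list(base = base, patient = pat, control = siteC, patientBySite = siteP,
         realizedEffect = realized)
  })
}

#' Generate a synthetic multi-site cohort of ROI time series
#'
#' Each subject's rows are i.i.d. draws from a multivariate normal whose
#' correlation matrix is the subject's group-and-site latent matrix; the
#' signal is then rescaled per ROI by the site's lognormal gain and shifted
#' by its offset (emulating scanner units; invisible to correlation-based
#' networks). The cohort is a deterministic function of the configuration,
#' including its seed.
#'
#' @param config a [CohortConfig-class].
#' @return A list of [RoiTimeSeries-class], patients before controls within
#'   each site, sites in configuration order.
#' @examples
#' cfg <- CohortConfig(nRois = 8, nTimepoints = 40,
#'                     sites = data.frame(site_id = "s1", n_patients = 3,
#'                                        n_controls = 3), seed = 7)
#' cohort <- generateCohort(cfg)
#' length(cohort)  # 6
#' @export
generateCohort <- function(config) {
  validObject(config)
  latent <- latentStructure(config)
  withSeed(subSeed(config@seed, 1L), {
    out <- list()
    n <- config@nRois; T <- config@nTimepoints
    for (s in seq_len(nrow(config@sites))) {
      sid <- config@sites$site_id[s]
      gain <- exp(stats::rnorm(n, sd = config@siteShiftSd))
      offset <- stats::rnorm(n, sd = config@siteShiftSd)
      for (grp in c("patient", "control")) {
        ns <- if (grp == "patient") config@sites$n_patients[s]
              else config@sites$n_controls[s]
        if (ns == 0) next
        R <- if (grp == "patient") latent$patientBySite[[sid]]
             else latent$control[[sid]]
        L <- chol(R)
        for (k in seq_len(ns)) {
          z <- matrix(stats::rnorm(T * n), T, n) %*% L
          x <- sweep(sweep(z, 2L, gain, `*`), 2L, offset, `+`)
          id <- sprintf("%s_%s_%03d", sid, substr(grp, 1, 3), k)
          colnames(x) <- sprintf("ROI%03d", seq_len(n))
          out[[id]] <- new("RoiTimeSeries", data = x, subjectId = id,
                           siteId = sid, label = grp)
        }
      }
    }
    unname(out)
  })
}

#' Ground-truth effect edges in vectorized coordinates
#'
#' Maps the configuration's effect edges through the same row-major
#' strict-upper-triangle convention used by [vectorizeUpper()], so recovery
#' experiments can compare selected edge indices directly.
#'
#' @param config a [CohortConfig-class].
#' @return Sorted integer vector of edge indices.
#' @export
groundTruthEdges <- function(config) {
  validObject(config)
  if (!nrow(config@effectEdges)) return(integer())
  sort(edgeIndexOf(config@effectEdges, config@nRois))
}

#' @describeIn latentStructure Mean realized patient-control latent
#'   correlation difference on the effect edges.
#' @export
realizedEffect <- function(config) latentStructure(config)$realizedEffect

setMethod("show", "CohortConfig", function(object) {
  cat(sprintf(
    "CohortConfig: %d ROIs x %d timepoints, %d site(s), %d+%d subjects\n",
    object@nRois, object@nTimepoints, nrow(object@sites),
    sum(object@sites$n_patients), sum(object@sites$n_controls)))
  cat(sprintf("  effect: %.2f on %d edge(s); density %.2f; site sd %.2f/%.2f; seed %d\n",
              object@effectSize, nrow(object@effectEdges), object@baseDensity,
              object@siteShiftSd, object@siteCorrSd, object@seed))
})

setMethod("show", "RoiTimeSeries", function(object) {
  cat(sprintf("RoiTimeSeries %s (site %s, %s): %d timepoints x %d ROIs\n",
              object@subjectId, object@siteId, object@label,
              nrow(object@data), ncol(object@data)))
})

#' Accessors for subject metadata
#' @param x a [RoiTimeSeries-class] or a list of them.
#' @return Character vector(s) of ids, sites or labels; `tsData` returns
#'   the numeric matrix.
#' @export
subjectId <- function(x) if (is(x, "RoiTimeSeries")) x@subjectId else
  vapply(x, subjectId, character(1))

#' @rdname subjectId
#' @export
siteId <- function(x) if (is(x, "RoiTimeSeries")) x@siteId else
  vapply(x, siteId, character(1))

#' @rdname subjectId
#' @export
subjectLabel <- function(x) if (is(x, "RoiTimeSeries")) x@label else
  vapply(x, subjectLabel, character(1))

#' @rdname subjectId
#' @export
tsData <- function(x) x@data
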