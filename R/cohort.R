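#' Ground-truth connectivity templates for a synthetic cohort
#'
#' Builds, for every (group, timepoint) cell of the design, a valid
#' correlation matrix used as the sampling covariance of that cell's ROI
#' time series. A single base correlation matrix is drawn by randomly
#' orthogonally mixing independent factors with geometrically decaying
#' variances and normalizing to unit diagonal, so off-diagonal correlations
#' of realistic magnitude arise. For each non-NC group a fixed random subset
#' of `affectedEdgeFraction * R(R-1)/2` edges is shrunk toward 0 by a factor
#' `edgeEffect`, plus `t * progressionRate` additional shrinkage at follow-up
#' timepoint index t (1 for 12m, 2 for 24m) for the progressive groups pMCI
#' and AD. Trajectory-only mode is the longitudinal control: all groups
#' share the baseline template and the progressive groups carry the full
#' `edgeEffect` at the 12m and 24m scans, so each follow-up is exactly as
#' discriminable as in the static design, the baseline is uninformative,
#' and the group difference lives entirely in the trajectory.
#' Each perturbed matrix is projected back to the nearest valid correlation
#' matrix (eigenvalue clipping and re-normalization).
#'
#' @param spec a [CohortSpec-class].
#' @return A list with `templates` (nested list `templates[[group]][[tp]]`,
#'   each an R x R correlation matrix), `affectedEdges` (integer indices
#'   into the upper-triangle vector), and `base` (the unperturbed template).
#' @export
#' @examples
#' tpl <- buildTemplates(cohortSpec(roiCount = 6, groups = c(NC = 3, AD = 3),
#'                                  framesPerScan = 30, seed = 7))
#' names(tpl$templates)
buildTemplates <- function(spec) {
  validObject(spec)
  R <- spec@roiCount
  set.seed(deriveSeed(spec@seed, "templates"))
  # random orthogonal mixing of independent factors -> covariance -> correlation
  Q <- qr.Q(qr(matrix(stats::rnorm(R * R), R, R)))
  ev <- exp(-3 * (seq_len(R) - 1) / max(R - 1, 1))
  S <- Q %*% (ev * t(Q))
  base <- stats::cov2cor(S)
  nEdges <- R * (R - 1) / 2
  nAffected <- max(1L, round(spec@affectedEdgeFraction * nEdges))
  affected <- sort(sample.int(nEdges, nAffected))
  tps <- timepointLevels()
  progressive <- c("pMCI", "AD")
  templates <- list()
  for (g in names(spec@groups)) {
    templates[[g]] <- list()
    for (ti in seq_along(tps)) {
      shrink <- 0
      if (g != "NC") {
        if (spec@trajectoryOnly) {
          # trajectory-only control: groups are identical at baseline and
          # the progressive groups carry the full edgeEffect at both
          # follow-up scans, so each follow-up is as discriminable as in
          # the static design, the baseline is uninformative, and only a
          # model that uses the follow-up scans can separate the groups
          if (g %in% progressive && ti > 1)
            shrink <- spec@edgeEffect
        } else {
          shrink <- spec@edgeEffect
          if (g %in% progressive)
            shrink <- shrink + (ti - 1) * spec@progressionRate
        }
      }
      shrink <- min(shrink, 1)
      v <- upperTriVec(base)
      v[affected] <- v[affected] * (1 - shrink)
      m <- vecToSymmetric(v, diagValue = 1)
      templates[[g]][[tps[ti]]] <- nearestCorrelation(m)
    }
  }
  list(templates = templates, affectedEdges = affected, base = base)
}

# Project a symmetric unit-diagonal matrix to a valid (PSD) correlation
# matrix by alternating eigenvalue clipping and diagonal re-normalization.
nearestCorrelation <- function(m, minEigen = 1e-8, maxIter = 50) {
  for (i in seq_len(maxIter)) {
    e <- eigen(m, symmetric = TRUE)
    if (min(e$values) >= -1e-10) break
    vals <- pmax(e$values, minEigen)
    m <- e$vectors %*% (vals * t(e$vectors))
    d <- sqrt(diag(m))
    m <- m / outer(d, d)
    m <- (m + t(m)) / 2
    diag(m) <- 1
  }
  m <- pmin(pmax(m, -1), 1)
  diag(m) <- 1
  m
}

# Draw n frames from N(0, sigma) via Cholesky (ridge-stabilized).
rmvn <- function(n, sigma) {
  ch <- tryCatch(chol(sigma),
                 error = function(e) chol(sigma + diag(1e-6, nrow(sigma))))
  matrix(stats::rnorm(n * nrow(sigma)), n) %*% ch
}

#' Simulate a synthetic longitudinal cohort
#'
#' Draws, for every subject and timepoint, a zero-mean multivariate-normal
#' ROI time series whose covariance is the (group, timepoint) template of
#' [buildTemplates()] perturbed by subject-specific correlation jitter of
#' scale `subjectNoiseSd` (re-projected to a valid correlation matrix).
#' Under a Gaussian generative model the Pearson FC matrix fully
#' characterizes the dependence structure, so the templates are exactly the
#' quantity the downstream pipeline estimates. The cohort is a deterministic
#' function of the spec (including its seed).
#'
#' @param spec a [CohortSpec-class].
#' @param dir optional directory; when given, series are written as TSV
#'   files, the manifest as `manifest.tsv`, and the spec (with seed) as a
#'   JSON sidecar `cohort_spec.json`.
#' @return A list with `manifest` (data.frame: subjectId, group, timepoint,
#'   seriesPath), `series` (named list of [ROITimeSeries-class], names
#'   `subject.timepoint`), `templates`, and `spec`.
#' @export
#' @examples
#' ch <- simulateCohort(cohortSpec(roiCount = 5, framesPerScan = 20,
#'                                 groups = c(NC = 2, AD = 2), seed = 3))
#' head(ch$manifest)
simulateCohort <- function(spec, dir = NULL) {
  validObject(spec)
  tpl <- buildTemplates(spec)
  tps <- timepointLevels()
  set.seed(deriveSeed(spec@seed, "cohort"))
  series <- list()
  rows <- list()
  idx <- 0L
  for (g in names(spec@groups)) {
    for (s in seq_len(spec@groups[[g]])) {
      idx <- idx + 1L
      sid <- sprintf("%s%03d", g, s)
      for (tp in tps) {
        sigma <- tpl$templates[[g]][[tp]]
        if (spec@subjectNoiseSd > 0) {
          v <- upperTriVec(sigma) +
            stats::rnorm(length(upperTriVec(sigma)), sd = spec@subjectNoiseSd)
          sigma <- nearestCorrelation(vecToSymmetric(pmin(pmax(v, -1), 1)))
        }
        x <- rmvn(spec@framesPerScan, sigma)
        colnames(x) <- sprintf("ROI%d", seq_len(spec@roiCount))
        ts <- roiTimeSeries(x, subjectId = sid, timepoint = tp)
        key <- paste(sid, tp, sep = ".")
        series[[key]] <- ts
        path <- if (is.null(dir)) NA_character_ else
          file.path(dir, sprintf("%s_%s.tsv", sid, tp))
        rows[[length(rows) + 1L]] <- data.frame(
          subjectId = sid, group = g, timepoint = tp, seriesPath = path,
          stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (i in seq_len(nrow(manifest))) {
      key <- paste(manifest$subjectId[i], manifest$timepoint[i], sep = ".")
      writeRoiSeries(series[[key]], manifest$seriesPath[i])
    }
    utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(cohortSpecAsList(spec),
                         file.path(dir, "cohort_spec.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(manifest = manifest, series = series, templates = tpl, spec = spec)
}

cohortSpecAsList <- function(spec) {
  list(roiCount = spec@roiCount, framesPerScan = spec@framesPerScan,
       groups = as.list(spec@groups), edgeEffect = spec@edgeEffect,
       progressionRate = spec@progressionRate,
       affectedEdgeFraction = spec@affectedEdgeFraction,
       subjectNoiseSd = spec@subjectNoiseSd,
       trajectoryOnly = spec@trajectoryOnly, seed = spec@seed)
}

#' Assemble per-subject longitudinal FC samples for a binary task
#'
#' Computes the Pearson FC matrix of every scan in a simulated cohort and
#' packs, for the two groups of the requested task, each subject's ordered
#' (BL, 12m, 24m) triple into a [LongitudinalSample-class]. The positive
#' class (label 1) is the more-diseased group: AD for `"nc-ad"`, pMCI for
#' `"smci-pmci"`.
#'
#' @param cohort result of [simulateCohort()].
#' @param task `"nc-ad"` or `"smci-pmci"`.
#' @return List of [LongitudinalSample-class] objects.
#' @export
cohortSamples <- function(cohort, task = c("nc-ad", "smci-pmci")) {
  task <- match.arg(task)
  groups <- if (task == "nc-ad") c(neg = "NC", pos = "AD")
            else c(neg = "sMCI", pos = "pMCI")
  man <- cohort$manifest
  missing <- setdiff(groups, unique(man$group))
  if (length(missing))
    stop("cohort lacks group(s) required for task ", task, ": ",
         paste(missing, collapse = ", "))
  keep <- man[man$group %in% groups, ]
  samples <- list()
  for (sid in unique(keep$subjectId)) {
    g <- keep$group[keep$subjectId == sid][1L]
    fcs <- lapply(timepointLevels(), function(tp) {
      pearsonFC(cohort$series[[paste(sid, tp, sep = ".")]])
    })
    samples[[sid]] <- longitudinalSample(
      fcs, label = as.integer(g == groups[["pos"]]), subjectId = sid)
  }
  samples
}
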