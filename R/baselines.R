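# Reference separation algorithms for the PI-versus-iterations comparison,
# plus a small registry so further algorithms can be plugged in externally.

.baselineRegistry <- new.env(parent = emptyenv())

#' Register a baseline separation algorithm
#'
#' Plug-in hook for additional reference algorithms (e.g. JADE or NSS-JD
#' implementations supplied by the user).  The function must accept
#' `(rec, truth, seed, ...)` and return a [BaselineResult-class].
#'
#' @param name algorithm tag.
#' @param fun the algorithm function.
#' @return Invisibly, the registered name.
#' @export
registerBaseline <- function(name, fun) {
  stopifnot(is.character(name), is.function(fun))
  assign(name, fun, envir = .baselineRegistry)
  invisible(name)
}

#' List registered baseline algorithms
#' @return Character vector of algorithm tags.
#' @export
listBaselines <- function() sort(ls(.baselineRegistry))

# Joint approximate diagonalization of a set of symmetric matrices by Jacobi
# rotations (Cardoso-Souloumiac sweeps over all index pairs).  Returns the
# orthogonal V maximizing the sum of squared diagonals, plus per-sweep V's.
jointDiagonalize <- function(mats, tol = 1e-8, maxSweeps = 100L) {
  N <- nrow(mats[[1]])
  V <- diag(N)
  sweepsV <- list()
  for (sweepIdx in seq_len(maxSweeps)) {
    rotated <- FALSE
    for (p in seq_len(N - 1)) for (q in (p + 1):N) {
      g11 <- 0; g12 <- 0; g22 <- 0
      for (Mk in mats) {
        h1 <- Mk[p, p] - Mk[q, q]
        h2 <- 2 * Mk[p, q]
        g11 <- g11 + h1 * h1; g12 <- g12 + h1 * h2; g22 <- g22 + h2 * h2
      }
      theta <- 0.5 * atan2(2 * g12, g11 - g22) / 2
      if (abs(theta) > tol) {
        rotated <- TRUE
        cth <- cos(theta); sth <- sin(theta)
        for (i in seq_along(mats)) {
          Mk <- mats[[i]]
          rp <- cth * Mk[p, ] + sth * Mk[q, ]
          rq <- -sth * Mk[p, ] + cth * Mk[q, ]
          Mk[p, ] <- rp; Mk[q, ] <- rq
          cp <- cth * Mk[, p] + sth * Mk[, q]
          cq <- -sth * Mk[, p] + cth * Mk[, q]
          Mk[, p] <- cp; Mk[, q] <- cq
          mats[[i]] <- Mk
        }
        rp <- cth * V[, p] + sth * V[, q]
        rq <- -sth * V[, p] + cth * V[, q]
        V[, p] <- rp; V[, q] <- rq
      }
    }
    sweepsV[[sweepIdx]] <- V
    if (!rotated) break
  }
  list(V = V, sweeps = sweepsV)
}

#' Second-order blind identification (SOBI)
#'
#' Whitens the recording, then jointly diagonalizes the symmetrized lagged
#' covariance matrices over `lags` by Jacobi rotation sweeps.  When ground
#' truth is supplied, PI is recorded after each sweep; iterations are
#' reported as samples processed (`sweep * nSamples`), with the sweep count
#' in the curve.
#'
#' @param rec a [Recording-class] (zero-mean per channel is enforced).
#' @param lags integer lags in samples (>= 2 of them).
#' @param truth optional list with `sources` and `model` for PI scoring.
#' @param nKeep components to keep at the whitening step (`"auto"` or count).
#' @param tol Jacobi rotation tolerance.
#' @return A [BaselineResult-class].
#' @export
sobi <- function(rec, lags = 1:10, truth = NULL, nKeep = "auto",
                 tol = 1e-8) {
  if (length(lags) < 2) stop("at least 2 lags are required", call. = FALSE)
  sw <- spatialWhiten(rec, nKeep = nKeep)
  xb <- sw$xbar
  n <- ncol(xb)
  mats <- lapply(as.integer(lags), function(tk) {
    a <- xb[, (tk + 1):n, drop = FALSE]
    b <- xb[, 1:(n - tk), drop = FALSE]
    Rt <- a %*% t(b) / (n - tk)
    (Rt + t(Rt)) / 2
  })
  # near-identical lagged covariances: rotation not identifiable
  if (all(vapply(mats, function(Mk)
    norm(Mk - mean(diag(Mk)) * diag(nrow(Mk)), "F"), numeric(1)) <
    1e-6 * nrow(xb)))
    warning("degenerate lag structure: sources not identifiable from these lags",
            call. = FALSE)
  jd <- jointDiagonalize(mats, tol = tol)
  Wtot <- t(jd$V) %*% sw$state@B
  piCurve <- data.frame(iteration = numeric(0), pi = numeric(0),
                        sweep = integer(0))
  itTo <- c("0.1" = NA_real_, "0.05" = NA_real_)
  if (!is.null(truth)) {
    sds <- apply(sources(truth$sources), 1, sd)
    GA <- mixingMatrix(truth$model) %*% diag(sds, length(sds))
    pis <- vapply(jd$sweeps, function(Vk)
      performanceIndex(t(Vk) %*% sw$state@B %*% GA), numeric(1))
    piCurve <- data.frame(iteration = seq_along(pis) * n, pi = pis,
                          sweep = seq_along(pis))
    for (thr in c(0.1, 0.05)) {
      w <- which(pis < thr)
      if (length(w)) itTo[as.character(thr)] <- w[1] * n
    }
  }
  new("BaselineResult", algorithm = "sobi", W = Wtot, piCurve = piCurve,
      iterationsToThreshold = itTo)
}

#' Plain NPCA baseline
#'
#' The separation-stage learning rule alone: exact batch whitening
#' (`R_xx^{-1/2}`), then the NPCA rule streamed from `W(0) = I`, with no
#' pre-separation stage.  This is the natural single-stage reference for the
#' full pipeline's convergence comparison.
#'
#' @param rec a [Recording-class].
#' @param gamma separation forgetting factor.
#' @param passes passes over the data.
#' @param truth optional ground truth for the PI curve.
#' @param nKeep components kept at whitening.
#' @param rule update rule, as in [separationState()].
#' @param scoreEvery PI sampling interval in samples.
#' @return A [BaselineResult-class].
#' @export
plainNpca <- function(rec, gamma = 0.002, passes = 1L, truth = NULL,
                      nKeep = "auto", rule = "npca", scoreEvery = 50L) {
  sw <- spatialWhiten(rec, nKeep = nKeep)   # exact batch whitening
  u <- sw$xbar
  scoreFun <- NULL
  if (!is.null(truth)) {
    sds <- apply(sources(truth$sources), 1, sd)
    GA <- mixingMatrix(truth$model) %*% diag(sds, length(sds))
    B <- sw$state@B
    scoreFun <- function(W, iter) performanceIndex(t(W) %*% B %*% GA)
  }
  res <- npcaStream(u, diag(nrow(u)), 1 / 0.1, gamma, rule, 100L,
                    as.integer(passes), scoreEvery = as.integer(scoreEvery),
                    scoreFun = scoreFun)
  piCurve <- data.frame(iteration = res$iters, pi = res$scores)
  itTo <- c("0.1" = NA_real_, "0.05" = NA_real_)
  for (thr in c(0.1, 0.05)) {
    w <- which(res$scores < thr)
    if (length(w)) itTo[as.character(thr)] <- res$iters[w[1]]
  }
  new("BaselineResult", algorithm = "plain_npca",
      W = t(res$W) %*% sw$state@B, piCurve = piCurve,
      iterationsToThreshold = itTo)
}

#' Compare separation algorithms on a known mixture
#'
#' Runs the requested algorithms (`"anpca"`, `"sobi"`, `"plain_npca"`, plus
#' any registered via [registerBaseline()]) over a set of seeds and tabulates
#' the final PI and the iterations (samples processed) to reach PI below 0.1
#' and 0.05.
#'
#' @param algorithms character vector of algorithm tags.
#' @param seeds integer seeds; one synthetic session is generated per seed.
#' @param nBlocks,params,passes session and run parameters.
#' @param file optional path; when given the table is also written as CSV.
#' @return A data.frame with one row per algorithm x seed.
#' @export
compareAlgorithms <- function(algorithms = c("anpca", "sobi", "plain_npca"),
                              seeds = 1:6, nBlocks = 10L,
                              params = sourceParams(), passes = 2L,
                              file = NULL) {
  rows <- list()
  for (seed in seeds) {
    sess <- simulateSession(nBlocks = nBlocks, params = params, seed = seed,
                            duration = 7000 / 256)
    truth <- list(sources = sess$sources, model = sess$model)
    for (alg in algorithms) {
      row <- switch(alg,
        anpca = {
          cfg <- anpcaConfig(seed = seed, passes = passes,
                             filter = list(enabled = FALSE),
                             classify = list(enabled = FALSE),
                             input = sess$recording, events = sess$events,
                             truth = truth)
          out <- runPipeline(cfg)
          traj <- piTrajectory(out$report)
          toThr <- function(thr) {
            w <- which(traj$pi < thr)
            if (length(w)) traj$iteration[w[1]] else NA_real_
          }
          data.frame(algorithm = "anpca", seed = seed,
                     finalPi = piValue(out$report),
                     itersTo0.1 = toThr(0.1), itersTo0.05 = toThr(0.05))
        },
        sobi = {
          b <- sobi(sess$recording, truth = truth)
          data.frame(algorithm = "sobi", seed = seed,
                     finalPi = utils::tail(b@piCurve$pi, 1),
                     itersTo0.1 = unname(b@iterationsToThreshold["0.1"]),
                     itersTo0.05 = unname(b@iterationsToThreshold["0.05"]))
        },
        plain_npca = {
          b <- plainNpca(sess$recording, passes = passes, truth = truth)
          data.frame(algorithm = "plain_npca", seed = seed,
                     finalPi = utils::tail(b@piCurve$pi, 1),
                     itersTo0.1 = unname(b@iterationsToThreshold["0.1"]),
                     itersTo0.05 = unname(b@iterationsToThreshold["0.05"]))
        },
        {
          fun <- get0(alg, envir = .baselineRegistry)
          if (is.null(fun)) stop("unknown algorithm: ", alg, call. = FALSE)
          b <- fun(sess$recording, truth = truth, seed = seed)
          data.frame(algorithm = alg, seed = seed,
                     finalPi = utils::tail(b@piCurve$pi, 1),
                     itersTo0.1 = unname(b@iterationsToThreshold["0.1"]),
                     itersTo0.05 = unname(b@iterationsToThreshold["0.05"]))
        })
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}
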