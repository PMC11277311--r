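## Per-sample longitudinal metrics: tumor mutation rate per megabase of
## capture, MATH intra-tumor heterogeneity, and VAF Gaussian-mixture
## clonality. All three are computed on the level-1-passing variant set:
## technical quality is enforced, but no biological-relevance filtering
## that would bias the VAF distribution.

#' Tumor mutation rate
#'
#' Mutations per megabase of the capture region and its log10. This is a
#' longitudinal comparison measure over all level-1-passing variants — not
#' the clinical tumor mutational burden (TMB), which is computed from
#' classified variants only.
#'
#' @param total_mutations number of (level-1-passing) variants.
#' @param capture_mb capture size in megabases (default 42).
#' @return list with \code{per_mb} (exactly total/capture) and
#'   \code{log10_per_mb} (\code{NA} when \code{per_mb} is 0); raw
#'   precision — round for presentation with \code{\link{tmrRow}}.
#' @export
tmr <- function(total_mutations, capture_mb = 42) {
  if (capture_mb <= 0) stop("capture_mb must be positive")
  if (total_mutations < 0) stop("total_mutations must be >= 0")
  per_mb <- total_mutations / capture_mb
  list(per_mb = per_mb,
       log10_per_mb = if (per_mb > 0) log10(per_mb) else NA_real_)
}

#' Presentation row for a tumor mutation rate
#'
#' Half-up rounding to 2 decimals for report tables; the raw values are
#' carried alongside.
#'
#' @param sample_id sample label.
#' @inheritParams tmr
#' @return one-row data.frame: sample_id, total_mutations, per_mb,
#'   log10_per_mb (rounded), per_mb_raw, log10_per_mb_raw.
#' @export
tmrRow <- function(sample_id, total_mutations, capture_mb = 42) {
  t <- tmr(total_mutations, capture_mb)
  data.frame(sample_id = sample_id, total_mutations = total_mutations,
             per_mb = roundHalfUp(t$per_mb, 2),
             log10_per_mb = roundHalfUp(t$log10_per_mb, 2),
             per_mb_raw = t$per_mb, log10_per_mb_raw = t$log10_per_mb,
             stringsAsFactors = FALSE)
}

#' Scaled median absolute deviation
#'
#' \code{median(|x - median(x)|) * mad_scale}. The default scale 1.4826 is
#' the normal-consistency constant used by the original MATH definition;
#' set \code{mad_scale = 1} for the raw MAD. Delegates to
#' \code{stats::mad}.
#'
#' @param values non-empty numeric vector.
#' @param mad_scale scale constant (default 1.4826).
#' @return the scaled MAD.
#' @export
scaledMad <- function(values, mad_scale = 1.4826) {
  if (length(values) == 0L) stop("values must be non-empty")
  stats::mad(values, constant = mad_scale)
}

#' MATH intra-tumor heterogeneity score
#'
#' \code{100 * MAD(vafs) / median(vafs)}: the width of the VAF distribution
#' relative to its center. Higher scores indicate more intra-tumor
#' heterogeneity. Scale-invariant: rescaling all VAFs by a constant leaves
#' the score unchanged.
#'
#' @param vafs non-empty vector of variant allele fractions in (0, 1].
#' @param mad_scale MAD scale constant (default 1.4826, as in the original
#'   score; 1 gives the unscaled ratio).
#' @return the MATH score, or \code{NA} (with a warning) when the median
#'   VAF is 0.
#' @export
mathScore <- function(vafs, mad_scale = 1.4826) {
  if (length(vafs) == 0L) stop("vafs must be non-empty")
  med <- stats::median(vafs)
  if (med == 0) {
    warning("median VAF is 0; MATH score undefined")
    return(NA_real_)
  }
  100 * scaledMad(vafs, mad_scale) / med
}

## One EM run for a k-component 1-D Gaussian mixture.
## family "E": pooled (equal) variance; "V": free per-component variance.
## Deterministic quantile-based initialization; variance floored at 1e-6
## to keep components from collapsing onto single points.
.emFit <- function(x, k, family = c("E", "V"), tol = 1e-8,
                   max_iter = 500L, init_means = NULL) {
  family <- match.arg(family)
  n <- length(x)
  mu <- if (is.null(init_means))
    as.numeric(stats::quantile(x, probs = (seq_len(k) - 0.5) / k))
  else init_means
  w <- rep(1 / k, k)
  v0 <- max(stats::var(x), 1e-6)
  if (k == 1L || is.na(v0)) v0 <- max(v0, 1e-6, na.rm = TRUE)
  v <- rep(v0, k)
  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    dens <- vapply(seq_len(k), function(j)
      w[j] * stats::dnorm(x, mu[j], sqrt(v[j])), numeric(n))
    if (n == 1L) dens <- matrix(dens, nrow = 1L)
    tot <- rowSums(dens)
    tot[tot < 1e-300] <- 1e-300
    ll <- sum(log(tot))
    trace <- c(trace, ll)
    if (is.finite(ll) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    resp <- dens / tot
    nk <- colSums(resp)
    nk[nk < 1e-12] <- 1e-12
    w <- nk / n
    mu <- colSums(resp * x) / nk
    if (family == "V") {
      v <- vapply(seq_len(k), function(j)
        sum(resp[, j] * (x - mu[j])^2) / nk[j], numeric(1L))
    } else {
      v <- rep(sum(vapply(seq_len(k), function(j)
        sum(resp[, j] * (x - mu[j])^2), numeric(1L))) / n, k)
    }
    v <- pmax(v, 1e-6)
  }
  nparam <- if (family == "V") 3L * k - 1L else 2L * k
  list(k = k, family = family, weights = w, means = mu, variances = v,
       loglik = trace[length(trace)],
       bic = -2 * trace[length(trace)] + nparam * log(n),
       trace = trace, converged = converged, iterations = iter)
}

#' Fit a Gaussian mixture to a VAF distribution
#'
#' For each candidate number of components k = 1..\code{max_components},
#' fits a one-dimensional Gaussian mixture by expectation-maximization in
#' both the equal-variance ("E") and free-variance ("V") families, and
#' selects the candidate minimizing the Bayesian information criterion.
#' Initialization is deterministic (component means at the k mid-quantiles
#' of the data), so the fit is order-invariant and reproducible; the seed
#' is only consumed when \code{restarts > 0} adds randomly jittered
#' initializations. The per-iteration log-likelihood is checked to be
#' non-decreasing on every fit.
#'
#' Fewer than \code{2 * max_components} observations reduce the candidate
#' range (down to a single component) with a warning.
#'
#' @param vafs numeric vector of variant allele fractions.
#' @param max_components largest number of components tried (default 5).
#' @param seed integer seed recorded with the fit and used for restarts.
#' @param restarts number of extra jittered-initialization EM runs per
#'   candidate (default 0; the deterministic run is always kept).
#' @param tol log-likelihood convergence tolerance (default 1e-8).
#' @param max_iter EM iteration cap (default 500).
#' @return a \code{\linkS4class{MixtureFit}}.
#' @export
fitVafMixture <- function(vafs, max_components = 5L, seed = 1L,
                          restarts = 0L, tol = 1e-8, max_iter = 500L) {
  stopifnot(max_components >= 1L, length(vafs) >= 1L)
  kmax <- min(max_components, floor(length(vafs) / 2))
  if (kmax < 1L) kmax <- 1L
  if (kmax < max_components)
    warning("too few observations for ", max_components,
            " components; trying up to k = ", kmax)
  fits <- list()
  cand <- list()
  if (restarts > 0L) set.seed(seed)
  for (k in seq_len(kmax)) {
    for (fam in c("E", "V")) {
      fit <- .emFit(vafs, k, fam, tol = tol, max_iter = max_iter)
      if (restarts > 0L) {
        for (r in seq_len(restarts)) {
          jitter_mu <- sort(stats::runif(k, min(vafs), max(vafs)))
          alt <- .emFit(vafs, k, fam, tol = tol, max_iter = max_iter,
                        init_means = jitter_mu)
          if (alt$loglik > fit$loglik) fit <- alt
        }
      }
      if (any(diff(fit$trace) < -1e-6))
        warning("EM log-likelihood decreased during iteration (k=", k,
                ", family=", fam, ")")
      fits[[paste0(k, fam)]] <- fit
      cand[[paste0(k, fam)]] <- data.frame(k = k, family = fam,
                                           loglik = fit$loglik,
                                           bic = fit$bic,
                                           converged = fit$converged,
                                           iterations = fit$iterations)
    }
  }
  candidates <- do.call(rbind, cand)
  rownames(candidates) <- NULL
  best <- fits[[which.min(candidates$bic)]]
  ord <- order(best$means)
  new("MixtureFit", nComponents = as.integer(best$k),
      weights = best$weights[ord],
      means = pmin(pmax(best$means[ord], 0), 1),
      variances = best$variances[ord], family = best$family,
      candidates = candidates, converged = best$converged,
      seed = as.integer(seed))
}

#' Write the mixture model-selection diagnostics
#'
#' One TSV row per (k, family) candidate with log-likelihood and BIC.
#'
#' @param fit a \code{MixtureFit}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeMixtureDiagnostics <- function(fit, path) {
  utils::write.table(fit@candidates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Compute all longitudinal metrics for one sample
#'
#' Takes the sample's level-1-passing variants (see
#' \code{\link{applyCascade}} with \code{levels = 1}) and computes the
#' tumor mutation rate, the MATH score and the VAF mixture fit.
#'
#' @param records level-1-passing \code{VariantSet}.
#' @param capture_mb capture size in megabases (default 42).
#' @param mad_scale MATH MAD scale constant (default 1.4826).
#' @param max_components mixture candidate cap (default 5).
#' @param seed seed recorded with the mixture fit.
#' @return a \code{\linkS4class{SampleMetrics}}.
#' @export
sampleMetrics <- function(records, capture_mb = 42, mad_scale = 1.4826,
                          max_components = 5L, seed = 1L) {
  n <- nVariants(records)
  t <- tmr(n, capture_mb)
  vafs <- variantTable(records)$vaf
  math <- if (n > 0L) mathScore(vafs, mad_scale) else NA_real_
  mix <- if (n >= 2L)
    suppressWarnings(fitVafMixture(vafs, max_components, seed = seed))
  else NULL
  new("SampleMetrics", sampleId = sampleId(records),
      total_mutations = as.integer(n), capture_mb = capture_mb,
      per_mb = t$per_mb, log10_per_mb = t$log10_per_mb,
      math_score = math, mixture = mix)
}

#' Heterogeneity trend between a pair's samples
#'
#' Sign of (recurrent MATH - primary MATH).
#'
#' @param metrics_P,metrics_R \code{SampleMetrics} objects (or bare MATH
#'   scores) for the primary and recurrent samples.
#' @return one of \code{"increasing"}, \code{"decreasing"}, \code{"equal"}.
#' @export
heterogeneityTrend <- function(metrics_P, metrics_R) {
  m_p <- if (is(metrics_P, "SampleMetrics")) metrics_P@math_score
         else metrics_P
  m_r <- if (is(metrics_R, "SampleMetrics")) metrics_R@math_score
         else metrics_R
  if (is.na(m_p) || is.na(m_r))
    stop("heterogeneity trend requires two defined MATH scores")
  if (m_r > m_p) "increasing" else if (m_r < m_p) "decreasing" else "equal"
}
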