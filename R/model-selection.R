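#' Multi-model occupancy covariate selection and conditional averaging
#'
#' The full stage-one inference chain for one species:
#' \enumerate{
#'   \item univariate Royle-Nichols fits per candidate covariate, keeping
#'     those with Wald p below \code{alpha} on the abundance coefficient;
#'   \item pairwise-correlation screen at \code{corThreshold}, dropping
#'     the higher-AICc member of each collinear pair;
#'   \item all-subsets fits over the survivors (including the
#'     intercept-only model);
#'   \item AICc ranking with Akaike weights
#'     \eqn{w_m \propto \exp(-\Delta_m / 2)};
#'   \item conditional model averaging over the \eqn{\Delta AICc \le
#'     deltaAicc} support set: \eqn{\bar\beta_j = \sum_m w_m \beta_{jm} /
#'     \sum_m w_m} over the supported models containing covariate j.
#' }
#'
#' @param dh a [DetectionHistorySet-class] with the candidate covariates
#'   among its site covariates.
#' @param candidates candidate covariate names (at most 10).
#' @param alpha univariate Wald significance level (default 0.05).
#' @param corThreshold |r| collinearity threshold (default 0.70).
#' @param deltaAicc support-set width (default 2).
#' @param K Poisson truncation (NULL = adaptive).
#' @param seed seed forwarded to the fits.
#' @return list with \code{averaged} (data.frame term, estimate, weight),
#'   \code{ranking} (per-model AICc table with weights), \code{univariate}
#'   (screening table), \code{retained} (post-screen covariates) and
#'   \code{fits} (the supported fits).
#' @export
modelSelection <- function(dh, candidates, alpha = 0.05,
                           corThreshold = 0.70, deltaAicc = 2, K = NULL,
                           seed = 1) {
  if (length(candidates) > 10)
    stop("all-subsets search supports at most 10 candidates")
  if (!all(candidates %in% names(dh@siteCovs)))
    stop("candidates missing from site covariates")
  ## (1) univariate screening
  uni <- lapply(seq_along(candidates), function(i)
    fitOccupancy("royle_nichols", dh, covariates = candidates[i], K = K,
                 seed = childSeed(seed, i)))
  uniTab <- do.call(rbind, lapply(seq_along(candidates), function(i) {
    wt <- waldTable(uni[[i]])
    row <- wt[wt$term == paste0("lambda(", candidates[i], ")"), ]
    data.frame(covariate = candidates[i], estimate = row$estimate,
               se = row$se, p = row$p, aicc = uni[[i]]@aicc)
  }))
  sig <- uniTab$covariate[!is.na(uniTab$p) & uniTab$p < alpha]
  if (length(sig) == 0) {
    warning("no covariate survives univariate screening; ",
            "returning intercept-only result")
    f0 <- fitOccupancy("royle_nichols", dh, K = K, seed = childSeed(seed, 0))
    return(list(averaged = data.frame(term = "lambda(Int)",
                                      estimate = unname(f0@estimates[1]),
                                      weight = 1),
                ranking = data.frame(model = "(intercept)", k = 2,
                                     aicc = f0@aicc, delta = 0, weight = 1),
                univariate = uniTab, retained = character(0),
                fits = list(f0)))
  }
  ## (2) collinearity screen, worse-AICc member dropped
  aiccVec <- setNames(uniTab$aicc, uniTab$covariate)
  retained <- correlationScreen(dh@siteCovs[sig], aiccVec[sig],
                                threshold = corThreshold)
  ## (3) all subsets of survivors, intercept-only included
  subsets <- list(character(0))
  for (m in seq_along(retained))
    subsets <- c(subsets, combn(retained, m, simplify = FALSE))
  fits <- lapply(seq_along(subsets), function(i)
    fitOccupancy("royle_nichols", dh, covariates = subsets[[i]], K = K,
                 seed = childSeed(seed, 100 + i)))
  aiccAll <- vapply(fits, aicc, 0)
  ## (4) ranking and Akaike weights over the full candidate set
  delta <- aiccAll - min(aiccAll)
  w <- exp(-delta / 2); w <- w / sum(w)
  ranking <- data.frame(
    model = vapply(subsets, function(s)
      if (length(s)) paste(s, collapse = "+") else "(intercept)", ""),
    k = vapply(subsets, function(s) length(s) + 2, 0),
    aicc = aiccAll, delta = delta, weight = w)
  ord <- order(ranking$aicc)
  ranking <- ranking[ord, ]; fits <- fits[ord]; subsets <- subsets[ord]
  rownames(ranking) <- NULL
  ## (5) conditional averaging over the support set
  top <- which(ranking$delta <= deltaAicc)
  terms <- c("lambda(Int)",
             paste0("lambda(", retained, ")"), "r(logit)")
  avg <- do.call(rbind, lapply(terms, function(tm) {
    has <- vapply(top, function(i) tm %in% names(fits[[i]]@estimates), TRUE)
    if (!any(has)) return(NULL)
    idx <- top[has]
    wts <- ranking$weight[idx]
    est <- vapply(idx, function(i) unname(fits[[i]]@estimates[tm]), 0)
    data.frame(term = tm, estimate = sum(wts * est) / sum(wts),
               weight = sum(wts) / sum(ranking$weight[top]))
  }))
  rownames(avg) <- NULL
  list(averaged = avg, ranking = ranking, univariate = uniTab,
       retained = retained, fits = fits[top])
}

#' Predict a relative-abundance surface from averaged coefficients
#'
#' \eqn{\lambda(x) = \exp(a_0 + \bar a^T x)} per cell, using the averaged
#' coefficient table from [modelSelection()].  The stack must carry every
#' averaged covariate, standardized with the fitting-time record.
#'
#' @param averaged averaged coefficient table (term, estimate).
#' @param stack a [CovariateStack-class].
#' @return a [RasterGrid-class] of strictly positive relative abundance.
#' @export
predictAbundance <- function(averaged, stack) {
  g <- stack@grid
  int <- averaged$estimate[averaged$term == "lambda(Int)"]
  if (length(int) == 0) int <- 0
  eta <- matrix(int, g@nrow, g@ncol)
  covTerms <- grep("^lambda\\((?!Int\\))", averaged$term, perl = TRUE,
                   value = TRUE)
  for (tm in covTerms) {
    nm <- sub("^lambda\\((.*)\\)$", "\\1", tm)
    if (!nm %in% names(stack@layers)) stop("missing layer: ", nm)
    eta <- eta + averaged$estimate[averaged$term == tm] * getLayer(stack, nm)
  }
  rasterGrid(exp(eta), g)
}
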