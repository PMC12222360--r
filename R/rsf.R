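#' Demographic class factor levels
#'
#' Reference class first (adult female), matching the reporting
#' convention: all class coefficients are relative to adult females.
#' @export
demographicClasses <- function()
  c("adult female", "subadult female", "adult male", "subadult male")

#' Build a used-available resource selection design
#'
#' For every home range (individual-season), pairs the used fixes with
#' \code{ratio} times as many available points drawn uniformly inside that
#' range's isopleth (cells sampled uniformly - all cells share one area -
#' then a uniform point within the cell), extracts covariates at all
#' points and standardizes them with one shared record.  If the stack's
#' layers are already standardized, their record is reused (so
#' coefficients stay on the stack's z-scale); otherwise a record is
#' computed over the design points.
#'
#' @param uds named list of [UtilizationDistribution-class] (from
#'   [homeRanges()]).
#' @param clean cleaned daily-location table (as used for the UDs).
#' @param stack a [CovariateStack-class] of covariate layers.
#' @param covariates layer names to extract.
#' @param ratio available:used ratio (default 4).
#' @param seed integer seed for the available draws.
#' @return an [RSFDesign-class].
#' @export
buildDesign <- function(uds, clean, stack, covariates, ratio = 4, seed = 1) {
  if (!all(covariates %in% names(stack@layers)))
    stop("missing layer(s): ",
         paste(setdiff(covariates, names(stack@layers)), collapse = ", "))
  keys <- paste(clean$individual, clean$season, sep = ".")
  rows <- list()
  withSeed(seed, {
    for (key in names(uds)) {
      u <- uds[[key]]
      f <- clean[keys == key, ]
      used <- cbind(f$x, f$y)
      nAvail <- ratio * nrow(used)
      g <- u@ud@grid
      cells <- which(u@isoMask)          # column-major cell indices
      ymax <- g@ymin + g@nrow * g@cellsize
      ## uniform within the isopleth clipped to the covariate extent:
      ## cells share one area, so uniform cell choice + uniform jitter,
      ## redrawing the (rare) draws that leave the raster
      avail <- matrix(NA_real_, 0, 2)
      for (try in 1:50) {
        need <- nAvail - nrow(avail)
        if (need <= 0) break
        pick <- cells[sample.int(length(cells), need, replace = TRUE)]
        i <- (pick - 1L) %% nrow(u@isoMask) + 1L
        j <- (pick - 1L) %/% nrow(u@isoMask) + 1L
        ax <- g@xmin + (j - 1L) * g@cellsize + runif(need) * g@cellsize
        ay <- ymax - i * g@cellsize + runif(need) * g@cellsize
        inside <- !is.na(extractValues(stack, cbind(ax, ay),
                                       covariates[1])[[1]])
        avail <- rbind(avail, cbind(ax, ay)[inside, , drop = FALSE])
      }
      if (nrow(avail) < nAvail)
        stop("home range of ", key, " barely overlaps the covariate raster")
      pts <- rbind(used, avail)
      vals <- extractValues(stack, pts, covariates)
      if (anyNA(vals))
        stop("point extraction outside the covariate raster for ", key)
      rows[[key]] <- data.frame(
        used = rep(c(1L, 0L), c(nrow(used), nAvail)),
        class = u@demographicClass, individual = u@id,
        rangeSeason = key, x = pts[, 1], y = pts[, 2], vals,
        check.names = FALSE)
    }
  })
  d <- do.call(rbind, rows)
  rownames(d) <- NULL
  d$class <- factor(d$class, levels = demographicClasses())
  preStd <- covariates %in% stack@standardization$layer
  if (all(preStd)) {
    rec <- stack@standardization[
      match(covariates, stack@standardization$layer), ]
  } else {
    rec <- data.frame(layer = covariates,
                      mean = vapply(covariates, function(v) mean(d[[v]]), 0),
                      sd = vapply(covariates, function(v) sd(d[[v]]), 0))
    for (v in covariates) d[[v]] <- (d[[v]] - rec$mean[rec$layer == v]) /
      rec$sd[rec$layer == v]
  }
  rownames(rec) <- NULL
  new("RSFDesign", data = d, standardization = rec, ratio = ratio,
      covariates = covariates)
}

#' @describeIn designData design table of an RSF design
setMethod("designData", "RSFDesign", function(object) object@data)
#' Design table accessor
#' @param object an [RSFDesign-class].
#' @name designData
NULL

setMethod("show", "RSFDesign", function(object) {
  d <- object@data
  cat(sprintf(paste0("RSFDesign: %d used / %d available points (1:%g), ",
                     "%d range-seasons, covariates: %s\n"),
              sum(d$used == 1), sum(d$used == 0), object@ratio,
              length(unique(d$rangeSeason)),
              paste(object@covariates, collapse = ", ")))
})

.rsfFormula <- function(covariates, classInteractions, randomTerms,
                        includeClass = TRUE) {
  fixed <- paste(c(covariates, if (includeClass) "class",
                   if (length(classInteractions))
                     paste0(classInteractions, ":class")),
                 collapse = " + ")
  if (!nzchar(fixed)) fixed <- "1"
  rhs <- paste(c(fixed, randomTerms), collapse = " + ")
  as.formula(paste("used ~", rhs))
}

.wrapGlmmFit <- function(model, fixedFormula, randomTerms) {
  if (inherits(model, "glmerMod")) {
    cf <- lme4::fixef(model)
    se <- sqrt(diag(as.matrix(vcov(model))))
    vc <- lme4::VarCorr(model)
    reVar <- unlist(lapply(names(vc), function(gr) {
      v <- diag(vc[[gr]])
      setNames(v, paste(gr, names(v), sep = ":"))
    }))
    singular <- lme4::isSingular(model)
    conv <- length(model@optinfo$conv$lme4) == 0
    aicVal <- AIC(model)
  } else {
    cf <- coef(model)
    se <- sqrt(diag(vcov(model)))
    reVar <- setNames(numeric(0), character(0))
    singular <- FALSE
    conv <- model$converged
    aicVal <- AIC(model)
  }
  z <- cf / se
  new("GLMMFit", model = model,
      fixed = data.frame(term = names(cf), beta = unname(cf),
                         se = unname(se), z = unname(z),
                         p = 2 * pnorm(-abs(unname(z)))),
      reVar = reVar, logLik = as.numeric(logLik(model)), aic = aicVal,
      converged = conv, singular = singular,
      fixedFormula = fixedFormula, randomTerms = randomTerms)
}

#' Fit a logistic mixed-effects resource selection function
#'
#' Fixed effects are the covariate main effects plus the demographic-class
#' main effect and the requested covariate-by-class interactions (treatment
#' contrasts, adult female reference).  Random terms are lme4 bar terms
#' over the design's grouping factors (e.g. \code{"(1 | individual)"},
#' \code{"(1 | individual/rangeSeason)"}); estimation is
#' Laplace-approximated maximum likelihood via \code{lme4::glmer}.  With an
#' empty random specification the model reduces to ordinary logistic
#' regression.
#'
#' @param design an [RSFDesign-class].
#' @param covariates fixed-effect covariates (default: all design
#'   covariates).
#' @param classInteractions covariates interacted with class (default: all
#'   of \code{covariates}).
#' @param randomTerms character vector of lme4 random-effect terms
#'   (possibly empty).
#' @return a [GLMMFit-class]; non-convergence and singular variance
#'   components are flagged, not errors.
#' @export
fitGlmm <- function(design, covariates = NULL, classInteractions = NULL,
                    randomTerms = "(1 | individual/rangeSeason)") {
  covariates <- covariates %||% design@covariates
  classInteractions <- classInteractions %||% covariates
  d <- design@data
  d$class <- droplevels(d$class)
  hasClass <- nlevels(d$class) > 1
  if (!hasClass) classInteractions <- character(0)
  if (length(randomTerms) && length(unique(d$individual)) < 2)
    stop("need >= 2 grouping levels")
  form <- .rsfFormula(covariates, classInteractions, randomTerms, hasClass)
  fixedOnly <- deparse(.rsfFormula(covariates, classInteractions,
                                   character(0), hasClass))
  if (length(randomTerms) == 0) {
    m <- glm(form, family = binomial(), data = d)
    return(.wrapGlmmFit(m, fixedOnly, character(0)))
  }
  m <- suppressMessages(suppressWarnings(
    lme4::glmer(form, family = binomial(), data = d, nAGQ = 1,
                control = lme4::glmerControl(calc.derivs = FALSE,
                                             check.conv.singular = "ignore"))))
  .wrapGlmmFit(m, fixedOnly, randomTerms)
}

#' @describeIn fixedEffects fixed-effect table of a GLMM fit
setMethod("fixedEffects", "GLMMFit", function(object) object@fixed)
#' Fixed-effect table accessor
#' @param object a [GLMMFit-class].
#' @name fixedEffects
NULL

#' @describeIn ranefVariances random-effect variances of a GLMM fit
setMethod("ranefVariances", "GLMMFit", function(object) object@reVar)
#' Random-effect variance accessor
#' @param object a [GLMMFit-class].
#' @name ranefVariances
NULL

setMethod("show", "GLMMFit", function(object) {
  cat(sprintf("GLMMFit: logLik %.1f, AIC %.1f%s%s\n", object@logLik,
              object@aic, if (object@singular) " (singular)" else "",
              if (object@converged) "" else " (NOT converged)"))
  print(transform(object@fixed, beta = round(beta, 3), se = round(se, 3),
                  z = round(z, 2), p = signif(p, 2)))
  if (length(object@reVar)) {
    cat("Random-effect variances:\n")
    print(round(object@reVar, 4))
  }
})

#' Parsimonious random-effects structure
#'
#' Starting from the maximal structure (random intercept plus a random
#' slope per covariate for home range within individual, with
#' correlations), iteratively simplifies: correlations are dropped first
#' (when the correlated fit is singular or fails), then slope terms whose
#' variance falls below \code{varTol} on the standardized scale or whose
#' removal changes the log-likelihood by less than half the 5%
#' chi-square(1) critical value; the floor is a random intercept only.
#'
#' @param design an [RSFDesign-class].
#' @param covariates fixed-effect covariates (default: design covariates).
#' @param classInteractions covariates interacted with class.
#' @param slopes covariates given random slopes in the maximal structure
#'   (default: \code{covariates}).
#' @param group grouping expression (default
#'   \code{"individual/rangeSeason"}).
#' @param varTol variance threshold (default 1e-4).
#' @return list with \code{randomTerms}, \code{fit} (the final
#'   [GLMMFit-class]) and \code{trace} of the decisions.
#' @export
reduceReStructure <- function(design, covariates = NULL,
                              classInteractions = NULL, slopes = NULL,
                              group = "individual/rangeSeason",
                              varTol = 1e-4) {
  covariates <- covariates %||% design@covariates
  classInteractions <- classInteractions %||% covariates
  slopes <- slopes %||% covariates
  trace <- character(0)
  tryFit <- function(terms) {
    tryCatch(fitGlmm(design, covariates, classInteractions, terms),
             error = function(e) NULL)
  }
  mkTerm <- function(sl, corr) {
    if (!length(sl)) sprintf("(1 | %s)", group)
    else sprintf("(1 + %s %s %s)", paste(sl, collapse = " + "),
                 if (corr) "|" else "||", group)
  }
  ## correlations first
  corr <- TRUE
  fit <- tryFit(mkTerm(slopes, TRUE))
  if (is.null(fit) || fit@singular || !fit@converged) {
    corr <- FALSE
    trace <- c(trace, "dropped random-effect correlations")
    fit <- tryFit(mkTerm(slopes, FALSE))
    if (is.null(fit)) stop("maximal uncorrelated structure failed to fit")
  }
  ## then slopes, smallest variance first
  repeat {
    if (!length(slopes)) break
    slopeVar <- vapply(slopes, function(sl) {
      v <- fit@reVar[grepl(paste0(":", sl, "$"), names(fit@reVar))]
      if (length(v)) sum(v) else 0
    }, 0)
    cand <- slopes[which.min(slopeVar)]
    reduced <- tryFit(mkTerm(setdiff(slopes, cand), corr))
    dropIt <- FALSE
    if (min(slopeVar) < varTol) {
      dropIt <- TRUE
    } else if (!is.null(reduced) &&
               2 * (fit@logLik - reduced@logLik) < 0.5 * qchisq(0.95, 1)) {
      dropIt <- TRUE
    }
    if (!dropIt || is.null(reduced)) break
    trace <- c(trace, sprintf("dropped random slope for %s (var %.2g)",
                              cand, min(slopeVar)))
    slopes <- setdiff(slopes, cand)
    fit <- reduced
  }
  list(randomTerms = mkTerm(slopes, corr), fit = fit, trace = trace)
}

#' Single-term deletions with likelihood ratio tests
#'
#' Tests every covariate-by-class interaction first (each against the full
#' model; df = number of classes minus 1), removes the non-significant
#' interactions jointly, then tests the main effects of covariates not
#' involved in a retained interaction (df = 1) and removes the
#' non-significant ones.  The final model keeps every significant term and
#' any main effect under a retained interaction.
#'
#' @param design an [RSFDesign-class].
#' @param covariates fixed-effect covariates.
#' @param classInteractions covariates interacted with class (default: all
#'   of \code{covariates}).
#' @param randomTerms random structure used throughout.
#' @param alpha significance level (default 0.05).
#' @return list with \code{table} (term, type, df, chisq, p, retained),
#'   \code{final} ([GLMMFit-class]), \code{covariates} and
#'   \code{classInteractions} of the final model.
#' @export
lrtTermDeletion <- function(design, covariates = NULL,
                            classInteractions = NULL,
                            randomTerms = "(1 | individual/rangeSeason)",
                            alpha = 0.05) {
  covariates <- covariates %||% design@covariates
  classInteractions <- classInteractions %||% covariates
  nClass <- length(unique(design@data$class))
  full <- fitGlmm(design, covariates, classInteractions, randomTerms)
  rows <- list()
  testDrop <- function(covs, ints, base) {
    function(term, type) {
      red <- tryCatch(
        fitGlmm(design,
                if (type == "main") setdiff(covs, term) else covs,
                if (type == "interaction") setdiff(ints, term) else ints,
                randomTerms),
        error = function(e) NULL)
      if (is.null(red) || !red@converged)
        return(data.frame(term = term, type = type, df = NA, chisq = NA,
                          p = NA, retained = TRUE))
      df <- if (type == "interaction") nClass - 1 else 1
      chisq <- 2 * (base@logLik - red@logLik)
      p <- pchisq(max(chisq, 0), df, lower.tail = FALSE)
      data.frame(term = term, type = type, df = df, chisq = chisq, p = p,
                 retained = p < alpha)
    }
  }
  tester <- testDrop(covariates, classInteractions, full)
  intTab <- do.call(rbind, lapply(classInteractions, tester,
                                  type = "interaction"))
  keptInts <- if (is.null(intTab)) character(0) else
    intTab$term[intTab$retained]
  ## refit without the jointly removed interactions
  current <- fitGlmm(design, covariates, keptInts, randomTerms)
  mains <- setdiff(covariates, keptInts)
  tester <- testDrop(covariates, keptInts, current)
  mainTab <- do.call(rbind, lapply(mains, tester, type = "main"))
  keptMains <- if (is.null(mainTab)) character(0) else
    mainTab$term[mainTab$retained]
  finalCovs <- union(keptInts, keptMains)
  final <- fitGlmm(design, finalCovs, keptInts, randomTerms)
  tab <- rbind(intTab, mainTab)
  rownames(tab) <- NULL
  list(table = tab, final = final, covariates = finalCovs,
       classInteractions = keptInts)
}

#' Odds ratios with 95% confidence intervals
#'
#' \eqn{OR = e^\beta}, \eqn{CI = [e^{\beta - 1.96\,SE},
#' e^{\beta + 1.96\,SE}]}.
#'
#' @param beta coefficient vector.
#' @param se standard errors.
#' @return data.frame with \code{or}, \code{lower}, \code{upper} and a
#'   2-decimal \code{formatted} column \code{"OR (lo-hi)"}.
#' @export
oddsRatios <- function(beta, se) {
  or <- exp(beta); lo <- exp(beta - 1.96 * se); hi <- exp(beta + 1.96 * se)
  data.frame(or = or, lower = lo, upper = hi,
             formatted = sprintf("%.2f (%.2f-%.2f)", or, lo, hi))
}

#' Marginal and conditional R-squared for a logistic mixed model
#'
#' Variance-partition coefficients on the latent scale with logistic link
#' variance \eqn{\pi^2/3}: marginal
#' \eqn{\sigma^2_f / (\sigma^2_f + \sigma^2_r + \pi^2/3)} and conditional
#' \eqn{(\sigma^2_f + \sigma^2_r) / (\sigma^2_f + \sigma^2_r + \pi^2/3)},
#' where \eqn{\sigma^2_f} is the variance of the fixed-effect linear
#' predictor over the design and \eqn{\sigma^2_r} the summed
#' random-effect variances.
#'
#' @param fit a [GLMMFit-class].
#' @param design the fitted [RSFDesign-class].
#' @return named numeric vector \code{c(marginal, conditional)}.
#' @export
r2Nakagawa <- function(fit, design) {
  m <- fit@model
  X <- if (inherits(m, "glmerMod")) lme4::getME(m, "X") else
    stats::model.matrix(m)
  beta <- fit@fixed$beta
  sigmaF <- var(as.vector(X %*% beta))
  sigmaR <- sum(fit@reVar)
  denom <- sigmaF + sigmaR + pi^2 / 3
  c(marginal = sigmaF / denom, conditional = (sigmaF + sigmaR) / denom)
}

#' Per-class relative-selection surface
#'
#' Exponential selection weight \eqn{w(x) = \exp(\beta_{main}^T x +
#' \beta_{class} + \beta_{interaction}^T x)} for the requested class, on a
#' stack standardized with the design's record; also returned linearly
#' rescaled to [0, 1] for display.
#'
#' @param fit a [GLMMFit-class].
#' @param stack a [CovariateStack-class] of raw layers (standardized
#'   internally with \code{design}'s record).
#' @param class demographic class to map.
#' @param design the [RSFDesign-class] carrying the standardization record.
#' @return list with \code{raw} and \code{scaled} [RasterGrid-class]
#'   surfaces.
#' @export
predictRsfMap <- function(fit, stack, class, design) {
  cls <- match.arg(class, demographicClasses())
  g <- stack@grid
  fx <- fit@fixed
  terms <- fx$term
  eta <- matrix(0, g@nrow, g@ncol)
  stdLayer <- function(nm) {
    if (!nm %in% names(stack@layers)) stop("missing layer: ", nm)
    ## layers already standardized in the stack are on the fitting scale;
    ## raw layers are z-scored with the design's record
    if (nm %in% stack@standardization$layer) return(getLayer(stack, nm))
    rec <- design@standardization
    (getLayer(stack, nm) - rec$mean[rec$layer == nm]) /
      rec$sd[rec$layer == nm]
  }
  clsTag <- paste0("class", cls)
  for (k in seq_along(terms)) {
    tm <- terms[k]; b <- fx$beta[k]
    if (tm == "(Intercept)") next
    if (grepl(":", tm, fixed = TRUE)) {
      parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
      covNm <- parts[!startsWith(parts, "class")]
      whichCls <- parts[startsWith(parts, "class")]
      if (whichCls == clsTag) eta <- eta + b * stdLayer(covNm)
    } else if (startsWith(tm, "class")) {
      if (tm == clsTag) eta <- eta + b
    } else {
      eta <- eta + b * stdLayer(tm)
    }
  }
  raw <- exp(eta)
  rng <- range(raw)
  scaled <- if (diff(rng) > 0) (raw - rng[1]) / diff(rng) else raw * 0
  list(raw = rasterGrid(raw, g), scaled = rasterGrid(scaled, g))
}
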