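#' Build detection histories from survey records
#'
#' Turns a long-format survey record table (site, replicate index,
#' detection) into a [DetectionHistorySet-class], preserving the
#' along-road replicate order within each site, and optionally attaching
#' site covariates.
#'
#' @param records data.frame with columns \code{site}, \code{replicate},
#'   \code{detection}.
#' @param siteCovs optional data.frame of site covariates with a
#'   \code{site} column (one row per site).
#' @param replicateLength replicate segment length (m; default 2000).
#' @return a [DetectionHistorySet-class].
#' @export
buildDetectionHistories <- function(records, siteCovs = NULL,
                                    replicateLength = 2000) {
  sites <- unique(records$site)
  J <- vapply(sites, function(s) sum(records$site == s), 0L)
  y <- matrix(NA_integer_, length(sites), max(J))
  for (k in seq_along(sites)) {
    r <- records[records$site == sites[k], ]
    r <- r[order(r$replicate), ]
    y[k, seq_len(nrow(r))] <- as.integer(r$detection)
  }
  sc <- data.frame(row.names = seq_along(sites))
  if (!is.null(siteCovs)) {
    m <- match(sites, siteCovs$site)
    if (anyNA(m)) stop("siteCovs missing sites: ",
                       paste(sites[is.na(m)], collapse = ", "))
    sc <- siteCovs[m, setdiff(names(siteCovs), "site"), drop = FALSE]
    rownames(sc) <- NULL
  }
  new("DetectionHistorySet", y = y, siteId = as.character(sites),
      siteCovs = sc, replicateLength = replicateLength,
      transectLength = J * replicateLength)
}

#' @describeIn detections detection matrix of a history set
setMethod("detections", "DetectionHistorySet", function(object) object@y)
#' Detection matrix accessor
#' @param object a [DetectionHistorySet-class].
#' @name detections
NULL

#' @describeIn siteCovs site covariates of a history set
setMethod("siteCovs", "DetectionHistorySet", function(object) object@siteCovs)
#' Site covariate accessor
#' @param object a [DetectionHistorySet-class].
#' @name siteCovs
NULL

#' @describeIn nSites sites in a history set
setMethod("nSites", "DetectionHistorySet", function(object) nrow(object@y))

setMethod("show", "DetectionHistorySet", function(object) {
  J <- rowSums(!is.na(object@y))
  cat(sprintf(paste0("DetectionHistorySet: %d sites, %d-%d replicates of ",
                     "%g m, naive occupancy %.2f\n"),
              nrow(object@y), min(J), max(J), object@replicateLength,
              mean(rowSums(object@y, na.rm = TRUE) > 0)))
})

#' Aggregate consecutive replicates into longer segments
#'
#' Merges \code{k} consecutive base replicates into one, with detection
#' the OR of the members; a trailing remainder shorter than the new length
#' is discarded.  Sites left with no complete replicate are dropped.
#'
#' @param dh a [DetectionHistorySet-class] at the base replicate length.
#' @param k integer aggregation factor (new length = k x base length).
#' @return a [DetectionHistorySet-class] at the aggregated length.
#' @export
aggregateReplicates <- function(dh, k) {
  if (abs(k - round(k)) > 1e-8)
    stop("aggregated length must be a multiple of the base segment length")
  k <- as.integer(round(k))
  if (k < 1) stop("aggregation factor must be >= 1")
  if (k == 1) return(dh)
  y <- dh@y
  J <- rowSums(!is.na(y))
  Jnew <- J %/% k
  keep <- Jnew >= 1L
  if (!any(keep)) stop("no site retains a complete aggregated replicate")
  yk <- matrix(NA_integer_, sum(keep), max(Jnew[keep]))
  rows <- which(keep)
  for (ii in seq_along(rows)) {
    i <- rows[ii]
    for (j in seq_len(Jnew[i])) {
      block <- y[i, ((j - 1) * k + 1):(j * k)]
      yk[ii, j] <- as.integer(any(block == 1L))
    }
  }
  new("DetectionHistorySet", y = yk, siteId = dh@siteId[keep],
      siteCovs = dh@siteCovs[keep, , drop = FALSE],
      replicateLength = dh@replicateLength * k,
      transectLength = Jnew[keep] * dh@replicateLength * k)
}

#' Choose the replicate length removing spatial dependence
#'
#' Stepwise doubles, in increments of the base segment length, the
#' replicate length until the constant-detection model without Markovian
#' dependence outperforms the Markov-dependence model by at least
#' \code{deltaAicc} AICc units; detections correlated between consecutive
#' short segments favour the Markov model, and aggregation washes the
#' correlation out.
#'
#' @param dh a [DetectionHistorySet-class] at the base replicate length.
#' @param maxLength largest replicate length to try (m; default 20000).
#' @param deltaAicc required AICc margin (default 2).
#' @param seed seed forwarded to the fits.
#' @return list with \code{chosen} (m), \code{trace} (data.frame of both
#'   AICc values per length) and \code{satisfied} (logical; FALSE when the
#'   rule never held and the maximum was returned, with a warning).
#' @export
selectReplicateLength <- function(dh, maxLength = 20000, deltaAicc = 2,
                                  seed = 1) {
  base <- dh@replicateLength
  if (all(dh@y == 0, na.rm = TRUE)) stop("degenerate survey: no detections")
  lengths <- seq(base, maxLength, by = base)
  trace <- data.frame(length = numeric(), aiccMackenzie = numeric(),
                      aiccMarkov = numeric(), nSites = integer())
  chosen <- NA_real_
  for (L in lengths) {
    dhL <- tryCatch(aggregateReplicates(dh, L / base),
                    error = function(e) NULL)
    if (is.null(dhL)) break
    fm <- fitOccupancy("mackenzie", dhL, seed = childSeed(seed, L))
    fk <- fitOccupancy("markov", dhL, seed = childSeed(seed, L + 1))
    trace <- rbind(trace, data.frame(length = L, aiccMackenzie = fm@aicc,
                                     aiccMarkov = fk@aicc,
                                     nSites = nrow(dhL@y)))
    if (is.finite(fm@aicc) && is.finite(fk@aicc) &&
        fm@aicc <= fk@aicc - deltaAicc) {
      chosen <- L
      break
    }
  }
  satisfied <- !is.na(chosen)
  if (!satisfied) {
    warning("independence rule never satisfied; returning the maximum ",
            "length tried")
    chosen <- max(trace$length)
  }
  list(chosen = chosen, trace = trace, satisfied = satisfied)
}
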