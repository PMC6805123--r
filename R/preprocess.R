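#' Collapse detections into independent events
#'
#' Within each site x species stream (sorted by time), a detection opens a new
#' event if and only if the gap to the previous detection is strictly greater
#' than the independence interval; detections separated by exactly the
#' interval or less belong to the same event. The default interval is 5
#' minutes. Input order is irrelevant; sorting is internal.
#'
#' @param records data.frame with columns `site`, `species` and `timestamp`
#'   (POSIXct, or numeric seconds).
#' @param interval_minutes independence interval in minutes (`>= 0`).
#' @return data.frame `site`, `species`, `events` (one row per observed
#'   site x species combination).
#' @export
collapse_events <- function(records, interval_minutes = 5) {
  if (interval_minutes < 0) stop("interval must be non-negative")
  req <- c("site", "species", "timestamp")
  if (!all(req %in% names(records))) stop("records need columns site, species, timestamp")
  ts <- records$timestamp
  if (inherits(ts, "POSIXt")) ts <- as.numeric(ts)
  if (!is.numeric(ts)) stop("unparseable timestamps: need POSIXct or numeric seconds")
  if (anyNA(ts)) stop("unparseable timestamps: NA after conversion")
  ord <- order(records$site, records$species, ts)
  d <- data.frame(site = records$site[ord], species = records$species[ord],
                  t = ts[ord], stringsAsFactors = FALSE)
  gap_sec <- interval_minutes * 60
  key <- paste(d$site, d$species, sep = "\r")
  new_stream <- c(TRUE, key[-1] != key[-nrow(d)])
  gap <- c(Inf, diff(d$t))
  new_event <- new_stream | gap > gap_sec   # strictly greater opens an event
  ev <- tapply(new_event, key, sum)
  first <- !duplicated(key)
  out <- data.frame(site = d$site[first], species = d$species[first],
                    events = as.integer(ev[key[first]]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$site, out$species), , drop = FALSE]
}

#' Standardize covariate columns
#'
#' Centres and scales every column to mean 0 / SD 1, using the population SD
#' (divisor `n`), and keeps the transform so prediction-time inputs can be
#' mapped through the same standardization.
#'
#' @param table data.frame or matrix of numeric covariates.
#' @param record an existing standardization record to apply instead of
#'   fitting a new one (for prediction-time inputs).
#' @return a `standardization` list: `data` (transformed table), `center`,
#'   `scale` (named per column).
#' @export
standardize_covariates <- function(table, record = NULL) {
  X <- as.matrix(table)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  if (!is.numeric(X)) stop("covariates must be numeric")
  if (is.null(record)) {
    center <- colMeans(X)
    scale <- sqrt(colMeans(sweep(X, 2, center)^2))
    if (any(scale == 0))
      stop("zero-variance column: ", paste(colnames(X)[scale == 0], collapse = ", "))
  } else {
    center <- record$center[colnames(X)]
    scale <- record$scale[colnames(X)]
    if (anyNA(center) || anyNA(scale)) stop("record does not cover all columns")
  }
  Z <- sweep(sweep(X, 2, center), 2, scale, `/`)
  out <- list(data = if (is.data.frame(table)) as.data.frame(Z) else Z,
              center = center, scale = scale)
  class(out) <- "standardization"
  out
}

#' Screen covariate pairs for collinearity
#'
#' Reports every unordered pair of columns whose absolute Pearson correlation
#' reaches the threshold; an empty result means the covariate set passes the
#' screen. The conventional cut-off for including both members of a pair in
#' one model is |r| < 0.7.
#'
#' @param table data.frame or matrix with at least 2 numeric columns and 3 rows.
#' @param threshold report pairs with `|r| >= threshold`.
#' @return data.frame `var1`, `var2`, `r` (possibly zero rows).
#' @export
screen_collinearity <- function(table, threshold = 0.7) {
  X <- as.matrix(table)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  if (ncol(X) < 2) stop("need at least two columns")
  if (nrow(X) < 3) stop("need at least three rows")
  R <- cor(X)
  pr <- combn(colnames(X), 2)
  r <- R[cbind(pr[1, ], pr[2, ])]
  keep <- abs(r) >= threshold
  data.frame(var1 = pr[1, keep], var2 = pr[2, keep], r = r[keep],
             stringsAsFactors = FALSE)
}
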