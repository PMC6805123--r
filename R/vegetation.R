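#' Plot-level browsing intensity
#'
#' The proportion of browsed individuals among tree saplings in the taller
#' (`>= 30 cm`) height class, per plot. Plots with no saplings in that class
#' get `NA` (the index is undefined there) and are dropped from downstream
#' model fits.
#'
#' @param plots long-format plot records as produced by
#'   [simulate_vegetation_plots()]: columns `plot`, `cluster`, `reserve`,
#'   `species`, `n_small`, `n_tall`, `n_browsed`.
#' @return data.frame `plot`, `cluster`, `reserve`, `intensity`.
#' @export
browsing_intensity <- function(plots) {
  req <- c("plot", "n_tall", "n_browsed")
  if (!all(req %in% names(plots))) stop("plot records lack required columns")
  if (any(plots$n_browsed > plots$n_tall)) stop("browsed exceeds total in a class")
  if (any(plots$n_tall < 0 | plots$n_small < 0)) stop("negative counts")
  tall <- tapply(plots$n_tall, plots$plot, sum)
  browsed <- tapply(plots$n_browsed, plots$plot, sum)
  first <- !duplicated(plots$plot)
  ids <- plots$plot[first]
  key <- as.character(ids)
  data.frame(plot = ids,
             cluster = plots$cluster[first],
             reserve = plots$reserve[first],
             intensity = ifelse(tall[key] > 0, browsed[key] / tall[key], NA_real_),
             row.names = NULL)
}

#' Recruitment shift of a focal species
#'
#' The difference between the two height classes in the focal species'
#' proportional share of all saplings:
#' `share_tall(species) - share_small(species)`, in `[-1, 1]`. Positive values
#' mean the species gains share while growing through the browsing-exposed
#' class. Plots with an empty height class get `NA`. Typical focal species are
#' the browsing-tolerant *Carpinus betulus* and the browsing-sensitive
#' *Acer platanoides*.
#'
#' @param plots long-format plot records (see [browsing_intensity()]).
#' @param species focal species name.
#' @return data.frame `plot`, `cluster`, `reserve`, `shift`.
#' @export
recruitment_shift <- function(plots, species = "Carpinus") {
  tot_small <- tapply(plots$n_small, plots$plot, sum)
  tot_tall <- tapply(plots$n_tall, plots$plot, sum)
  sp <- plots[plots$species == species, ]
  if (nrow(sp) == 0) stop("species not found in plot records: ", species)
  key <- as.character(sp$plot)
  share_small <- ifelse(tot_small[key] > 0, sp$n_small / tot_small[key], NA_real_)
  share_tall <- ifelse(tot_tall[key] > 0, sp$n_tall / tot_tall[key], NA_real_)
  data.frame(plot = sp$plot, cluster = sp$cluster, reserve = sp$reserve,
             shift = share_tall - share_small, row.names = NULL)
}

#' Factorial linear model: response ~ herbiscape x reserve
#'
#' Ordinary least squares with the full interaction of the herbivory-regime
#' (cluster) factor and the reserve factor, plus predicted means and standard
#' errors for every factor combination. Missing responses are dropped; factor
#' combinations without data are flagged unavailable.
#'
#' @param data data.frame with the response and `cluster`, `reserve` columns
#'   (e.g. output of [browsing_intensity()] or [recruitment_shift()]).
#' @param response name of the response column.
#' @return list: `model` (the `lm` fit), `coefficients` (coefficient table),
#'   `predictions` (data.frame `cluster`, `reserve`, `fit`, `se`,
#'   `available`).
#' @export
fit_herbiscape_lm <- function(data, response = "intensity") {
  d <- data.frame(y = data[[response]],
                  cluster = factor(data$cluster),
                  reserve = factor(data$reserve))
  d <- d[complete.cases(d), ]
  if (nrow(d) < 2) stop("not enough non-missing observations")
  if (nlevels(droplevels(d$cluster)) < 1) stop("no cluster with data")
  d$cluster <- droplevels(d$cluster)
  d$reserve <- droplevels(d$reserve)
  fml <- if (nlevels(d$cluster) > 1 && nlevels(d$reserve) > 1) y ~ cluster * reserve
         else if (nlevels(d$cluster) > 1) y ~ cluster
         else if (nlevels(d$reserve) > 1) y ~ reserve
         else y ~ 1
  fit <- lm(fml, data = d)
  grid <- expand.grid(cluster = levels(d$cluster), reserve = levels(d$reserve))
  have <- interaction(d$cluster, d$reserve, drop = FALSE)
  grid$available <- interaction(grid$cluster, grid$reserve) %in% levels(droplevels(have))
  pr <- suppressWarnings(predict(fit, newdata = grid, se.fit = TRUE))
  grid$fit <- ifelse(grid$available, pr$fit, NA_real_)
  grid$se <- ifelse(grid$available, pr$se.fit, NA_real_)
  cf <- summary(fit)$coefficients
  list(model = fit,
       coefficients = data.frame(term = rownames(cf), cf, row.names = NULL,
                                 check.names = FALSE),
       predictions = grid[, c("cluster", "reserve", "fit", "se", "available")])
}
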