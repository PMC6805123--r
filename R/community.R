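#' Default ungulate biomass weights (kg per individual)
#'
#' Average body masses used to convert relative densities to biomass:
#' red deer female 90, red deer male 150, roe deer 20, wild boar 80,
#' moose 200, European bison 400 kg.
#'
#' @return named numeric vector.
#' @export
default_biomass_weights <- function() {
  c(red_deer_female = 90, red_deer_male = 150, roe_deer = 20,
    wild_boar = 80, moose = 200, european_bison = 400)
}

#' Biomass surfaces from relative-density surfaces
#'
#' `biomass[s, j] = w_s * lambda[s, j]`; total biomass per cell is the sum
#' over species.
#'
#' @param surfaces named list of `density_surface` objects (or numeric cell
#'   vectors), one per species, on the same grid.
#' @param weights named vector of per-individual masses (kg) covering every
#'   species in `surfaces`.
#' @return data.frame with one biomass column per species plus `total`.
#' @export
biomass_surfaces <- function(surfaces, weights = default_biomass_weights()) {
  if (is.null(names(surfaces)) || any(!nzchar(names(surfaces))))
    stop("surfaces must be a named list")
  missing <- setdiff(names(surfaces), names(weights))
  if (length(missing)) stop("missing weight for species: ",
                            paste(missing, collapse = ", "))
  vals <- lapply(surfaces, function(s) if (is.data.frame(s)) s$mean else as.numeric(s))
  G <- length(vals[[1]])
  if (!all(vapply(vals, length, 1L) == G)) stop("surfaces differ in grid size")
  if (any(weights[names(surfaces)] <= 0)) stop("weights must be positive")
  out <- as.data.frame(mapply(function(v, w) w * v, vals,
                              weights[names(surfaces)], SIMPLIFY = FALSE))
  out$total <- rowSums(out)
  out
}

#' Functional dispersion (FDis) on mixed traits
#'
#' Species are embedded by principal-coordinate analysis of their Gower
#' dissimilarities (range-normalized quantitative traits, 0/1 categorical
#' mismatches, equal weights); FDis is the abundance-weighted mean distance of
#' species to the abundance-weighted centroid:
#' `c = sum(a_k x_k) / sum(a_k)`, `FDis = sum(a_k ||x_k - c||) / sum(a_k)`.
#' A Cailliez correction is applied if the Gower matrix is not Euclidean
#' (negative PCoA eigenvalue below `-1e-8`).
#'
#' @param traits data.frame with a `species` column (or rownames) and trait
#'   columns; factors/characters are treated as categorical.
#' @param abundances numeric vector (one community) or matrix/data.frame with
#'   one row per community (e.g. grid cell) and one column per species, in the
#'   order of `traits`. Non-negative, each row not all zero.
#' @return scalar FDis, or a vector (one value per row of `abundances`).
#' @export
compute_fdis <- function(traits, abundances) {
  tr <- as.data.frame(traits)
  if ("species" %in% names(tr)) {
    rownames(tr) <- tr$species
    tr$species <- NULL
  }
  if (anyNA(tr)) stop("traits must be complete")
  n_sp <- nrow(tr)
  A <- if (is.null(dim(abundances))) matrix(abundances, nrow = 1)
       else as.matrix(abundances)
  if (ncol(A) != n_sp) stop("abundances must have one value per species")
  if (any(A < 0)) stop("abundances must be non-negative")
  if (any(rowSums(A) == 0)) stop("all-zero abundance vector")
  if (n_sp == 1) {
    out <- rep(0, nrow(A))
    return(if (is.null(dim(abundances))) out[1] else out)
  }
  for (j in seq_along(tr)) if (is.character(tr[[j]])) tr[[j]] <- factor(tr[[j]])
  d <- cluster::daisy(tr, metric = "gower")
  d[is.na(d)] <- 0
  pc <- ape::pcoa(d)
  corr_needed <- min(pc$values$Eigenvalues) < -1e-8
  if (corr_needed) pc <- ape::pcoa(d, correction = "cailliez")
  vec_col <- if (corr_needed && !is.null(pc$vectors.cor)) pc$vectors.cor else pc$vectors
  X <- as.matrix(vec_col)
  W <- A / rowSums(A)
  centroids <- W %*% X                              # communities x axes
  fdis <- vapply(seq_len(nrow(W)), function(r) {
    z <- sqrt(rowSums(sweep(X, 2, centroids[r, ])^2))
    sum(W[r, ] * z)
  }, numeric(1))
  if (is.null(dim(abundances))) fdis[1] else fdis
}

#' Pairwise spatial overlap of density surfaces
#'
#' Pearson correlation matrix of per-cell values across species; a constant
#' surface (undefined correlation) yields `NA` entries with a warning.
#'
#' @param surfaces named list of `density_surface` objects or numeric vectors
#'   on one grid.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
pairwise_overlap <- function(surfaces) {
  if (length(surfaces) < 2) stop("need at least two surfaces")
  vals <- vapply(surfaces,
                 function(s) if (is.data.frame(s)) s$mean else as.numeric(s),
                 numeric(if (is.data.frame(surfaces[[1]])) nrow(surfaces[[1]])
                         else length(surfaces[[1]])))
  const <- apply(vals, 2, sd) == 0
  if (any(const)) warning("constant surface(s): ",
                          paste(colnames(vals)[const], collapse = ", "))
  R <- suppressWarnings(cor(vals))
  diag(R) <- 1
  R
}

#' Herbiscape clustering (hierarchical clustering on principal components)
#'
#' Standardizes the per-cell feature table (species biomasses, total biomass,
#' FDis), projects it onto principal components, builds a Ward (Euclidean)
#' tree on the component scores, cuts it into `k` clusters and, by default,
#' consolidates the partition with one k-means run seeded at the cluster
#' centroids. The inertia-gain curve (between-cluster inertia added by each
#' successive split) supports the choice of `k`; `k = 5` is the documented
#' default for temperate-forest ungulate communities.
#'
#' @param features data.frame/matrix, one row per grid cell.
#' @param k number of clusters (`>= 2`).
#' @param consolidate run the k-means consolidation step?
#' @param n_components number of principal components retained (default: all).
#' @param seed RNG seed for the consolidation step.
#' @return a `herbiscape_clustering` list: `labels` (contiguous `1..k`),
#'   `inertia_gain` (named by number of clusters after the split), `tree`
#'   (hclust), `scores` (PCA scores), `profiles` (per-cluster feature means).
#' @export
hcpc_cluster <- function(features, k = 5, consolidate = TRUE,
                         n_components = NULL, seed = 1L) {
  X <- as.matrix(features)
  if (k < 2) stop("k must be >= 2")
  if (k > nrow(unique(X))) stop("k exceeds the number of distinct rows")
  pca <- prcomp(X, center = TRUE, scale. = TRUE)
  nc <- if (is.null(n_components)) ncol(pca$x) else min(n_components, ncol(pca$x))
  sc <- pca$x[, seq_len(nc), drop = FALSE]
  tree <- hclust(dist(sc), method = "ward.D2")
  # inertia gained by each split = squared merge height / (2n) in ward.D2 units
  h <- rev(tree$height)
  gain <- h^2 / (2 * nrow(sc))
  names(gain) <- seq_along(gain) + 1  # clusters after the split
  labels <- cutree(tree, k = k)
  if (consolidate) {
    centers <- apply(sc, 2, function(col) tapply(col, labels, mean))
    centers <- matrix(centers, nrow = k)
    km <- with_seed(seed, kmeans(sc, centers = centers, iter.max = 100))
    labels <- km$cluster
  }
  labels <- match(labels, sort(unique(labels)))  # contiguous 1..k
  prof <- aggregate(as.data.frame(X), by = list(cluster = labels), FUN = mean)
  structure(list(labels = labels, inertia_gain = gain[seq_len(min(10, length(gain)))],
                 tree = tree, scores = sc, pca = pca, profiles = prof, k = k),
            class = "herbiscape_clustering")
}
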