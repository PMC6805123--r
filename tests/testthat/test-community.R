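test_that("biomass surfaces scale densities by species weights and conserve totals", {
  w <- default_biomass_weights()
  expect_equal(sum(w), 940)  # unit densities of all six species
  surfaces <- setNames(lapply(names(w), function(s) rep(1, 10)), names(w))
  bio <- biomass_surfaces(surfaces, w)
  expect_equal(bio$total, rep(940, 10))
  # cellwise conservation holds exactly
  expect_equal(bio$total, rowSums(bio[, names(w)]))
  # all-zero surfaces give zero biomass
  zero <- biomass_surfaces(setNames(lapply(names(w), function(s) rep(0, 5)),
                                    names(w)), w)
  expect_true(all(zero == 0))
  # linearity: doubling one surface doubles its biomass and shifts the total
  s2 <- surfaces; s2$moose <- s2$moose * 2
  bio2 <- biomass_surfaces(s2, w)
  expect_equal(bio2$moose, 2 * bio$moose)
  expect_equal(bio2$total - bio$total, bio$moose)
  expect_error(biomass_surfaces(list(unknown_species = rep(1, 5)), w),
               "missing weight")
})

test_that("FDis matches its two-point closed forms and invariances", {
  tr <- data.frame(species = c("a", "b"), mass = c(10, 30),
                   gut = c("x", "y"), diet = c("p", "p"))
  # gower: mass |10-30|/range 1, gut mismatch 1, diet 0 -> d = 2/3
  d <- 2 / 3
  expect_equal(compute_fdis(tr, c(1, 1)), d / 2, tolerance = 1e-10)
  expect_equal(compute_fdis(tr, c(0.75, 0.25)), 0.375 * d, tolerance = 1e-10)
  expect_equal(compute_fdis(tr[1, ], 5), 0)
  # rescaling all abundances leaves FDis unchanged
  expect_equal(compute_fdis(tr, c(3, 9)), compute_fdis(tr, c(1, 3) * 1e4),
               tolerance = 1e-12)
  expect_error(compute_fdis(tr, c(0, 0)), "all-zero")
  expect_error(compute_fdis(tr, c(-1, 1)), "non-negative")
})

test_that("FDis with equal abundances is the unweighted mean distance to the centroid", {
  tr <- simulate_trait_table(6)
  a_eq <- rep(1, 6)
  f <- compute_fdis(tr, a_eq)
  # independent computation in raw embedding space
  t2 <- tr; rownames(t2) <- t2$species; t2$species <- NULL
  t2$gut_type <- factor(t2$gut_type); t2$diet_type <- factor(t2$diet_type)
  d <- cluster::daisy(t2, metric = "gower")
  pc <- ape::pcoa(d)
  if (min(pc$values$Eigenvalues) < -1e-8) {  # same embedding rule as the package
    pc <- ape::pcoa(d, correction = "cailliez")
    X <- if (!is.null(pc$vectors.cor)) pc$vectors.cor else pc$vectors
  } else X <- pc$vectors
  cen <- colMeans(X)
  expect_equal(f, mean(sqrt(rowSums(sweep(X, 2, cen)^2))), tolerance = 1e-10)
  # per-cell mapping: a matrix of abundances gives one value per row
  A <- rbind(a_eq, c(5, 1, 1, 1, 1, 1))
  ff <- compute_fdis(tr, A)
  expect_length(ff, 2)
  expect_equal(ff[1], f, tolerance = 1e-12)
})

test_that("pairwise overlap is a unit-diagonal correlation matrix", {
  set.seed(8)
  a <- rnorm(2500); b <- rnorm(2500)
  R <- pairwise_overlap(list(a = a, b = b, self = a, anti = -(a - mean(a)) + mean(a)))
  expect_equal(diag(R), setNames(rep(1, 4), c("a", "b", "self", "anti")))
  expect_equal(R, t(R))
  expect_equal(unname(R["a", "self"]), 1)
  expect_equal(unname(R["a", "anti"]), -1)
  expect_lt(abs(R["a", "b"]), 0.1)  # independent surfaces
  expect_warning(pairwise_overlap(list(a = a, const = rep(1, 2500))), "constant")
})

test_that("Ward merge heights match a brute-force Lance-Williams agglomeration", {
  set.seed(14)
  X <- matrix(rnorm(12), 6, 2)
  d2 <- as.matrix(dist(X))^2
  # exhaustive Lance-Williams on squared distances; heights are sqrt(cost)
  n <- rep(1, 6); active <- 1:6; heights <- numeric(0); D <- d2
  for (s in 1:5) {
    m <- Inf
    for (i in active) for (j in active)
      if (i < j && D[i, j] < m) { m <- D[i, j]; mi <- i; mj <- j }
    heights <- c(heights, sqrt(m))
    for (k in setdiff(active, c(mi, mj)))
      D[mi, k] <- D[k, mi] <-
        ((n[mi] + n[k]) * D[mi, k] + (n[mj] + n[k]) * D[mj, k] - n[k] * m) /
        (n[mi] + n[mj] + n[k])
    n[mi] <- n[mi] + n[mj]; active <- setdiff(active, mj)
  }
  tree <- hclust(dist(X), method = "ward.D2")
  expect_equal(tree$height, heights, tolerance = 1e-10)
})

test_that("herbiscape clustering recovers separated structure and ignores row order", {
  set.seed(23)
  blob <- rbind(matrix(rnorm(120, 0), ncol = 2),
                matrix(rnorm(120, 8), ncol = 2))
  truth <- rep(1:2, each = 60)
  cl <- hcpc_cluster(data.frame(f1 = blob[, 1], f2 = blob[, 2]), k = 2, seed = 1)
  expect_setequal(unique(cl$labels), 1:2)
  # perfect recovery of blob membership (up to label swap)
  agree <- max(mean(cl$labels == truth), mean(cl$labels == 3 - truth))
  expect_equal(agree, 1)
  # permuting rows permutes labels identically (up to renaming)
  perm <- sample(nrow(blob))
  cl2 <- hcpc_cluster(data.frame(f1 = blob[perm, 1], f2 = blob[perm, 2]),
                      k = 2, seed = 1)
  tab <- table(cl$labels[perm], cl2$labels)
  expect_equal(sum(tab > 0), 2)  # one-to-one label correspondence
  expect_error(hcpc_cluster(blob, k = 1), "k must be")
  # inertia gains are reported for successive splits
  expect_true(all(cl$inertia_gain >= 0))
  expect_equal(names(cl$inertia_gain)[1], "2")
})

test_that("planted community regimes are recovered end to end", {
  # 5 contiguous column-bands of a 30x30 grid, distinct species mixes per band
  nx <- 30; ny <- 30; G <- nx * ny
  band <- pmin(5L, 1L + ((seq_len(G) - 1L) %% nx) %/% 6L)
  w <- default_biomass_weights()
  base <- rbind(c(4, 1, 1, 1, 1), c(1, 4, 1, 1, 1), c(1, 1, 4, 1, 1),
                c(1, 1, 1, 4, 1), c(1, 1, 1, 1, 4), c(2, 2, 1, 1, 2))
  set.seed(77)
  lam <- sapply(seq_along(names(w)), function(s)
    base[s, band] * exp(rnorm(G, 0, 0.15)))
  colnames(lam) <- names(w)
  surfaces <- setNames(lapply(names(w), function(s) lam[, s]), names(w))
  bio <- biomass_surfaces(surfaces, w)
  fdis <- compute_fdis(simulate_trait_table(6), lam)
  cl <- hcpc_cluster(cbind(bio, fdis = fdis), k = 5, seed = 3)
  ari <- mclust::adjustedRandIndex(cl$labels, band)
  expect_gt(ari, 0.8)
})
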