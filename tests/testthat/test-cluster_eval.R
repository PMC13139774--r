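fixture_Z <- matrix(c(0, 0.1, 10, 10.1), ncol = 1,
                    dimnames = list(c("a", "b", "c", "d"), NULL))

test_that("k-means recovers the minimum-WSS partition on the 1-D fixture", {
  cl <- kmeans_cluster(fixture_Z, k = 2, seed = 1)
  expect_equal(unname(cl$labels), c(0, 0, 1, 1))
  expect_equal(cl$k, 2)
  expect_equal(sort(cl$cohorts), sort(rownames(fixture_Z)))
  # k = n: every point its own cluster, zero within-SS
  cln <- kmeans_cluster(fixture_Z, k = 4, seed = 1)
  expect_equal(sort(unname(cln$labels)), 0:3)
  # duplicating every point preserves the partition structure
  Z2 <- rbind(fixture_Z, fixture_Z)
  rownames(Z2) <- paste0("r", 1:8)
  cl2 <- kmeans_cluster(Z2, k = 2, seed = 1)
  expect_equal(unname(cl2$labels[1:4]), unname(cl2$labels[5:8]))
  expect_error(kmeans_cluster(fixture_Z, k = 5), "exceeds")
  # determinism
  expect_identical(kmeans_cluster(fixture_Z, 2, seed = 3)$labels,
                   kmeans_cluster(fixture_Z, 2, seed = 3)$labels)
})

test_that("internal metrics reproduce hand-derived fixture values", {
  m <- internal_metrics(fixture_Z, c(0, 0, 1, 1))
  # outer points: a = 0.1, b = mean(10, 10.1) = 10.05; inner: b = 9.95
  sil_hand <- mean(c((10.05 - 0.1) / 10.05, (9.95 - 0.1) / 9.95,
                     (9.95 - 0.1) / 9.95, (10.05 - 0.1) / 10.05))
  expect_equal(m$silhouette, sil_hand, tolerance = 1e-12)
  expect_equal(m$silhouette, 0.990, tolerance = 1e-4)
  # S1 = S2 = 0.05, centroid distance M12 = 10.05 - 0.05 = 10
  expect_equal(m$davies_bouldin, 0.1 / 10, tolerance = 1e-12)
  # BSS = 100, WSS = 0.01, k-1 = 1, n-k = 2
  expect_equal(m$calinski_harabasz, 20000, tolerance = 1e-9)
  expect_equal(m$space_tag, "original")

  # two co-located pairs at distance d: sil = 1, DBI = 0, CH = Inf guarded
  Zc <- matrix(c(0, 0, 5, 5), ncol = 1)
  mc <- internal_metrics(Zc, c(1, 1, 2, 2))
  expect_equal(mc$silhouette, 1)
  expect_equal(mc$davies_bouldin, 0)
  expect_true(is.infinite(mc$calinski_harabasz))

  # singleton-cluster silhouette terms are defined as zero
  Zs <- matrix(c(0, 0.2, 9), ncol = 1)
  ms <- internal_metrics(Zs, c(1, 1, 2))
  expect_equal(ms$silhouette, mean(c((9 - 0.2) / 9, (8.8 - 0.2) / 8.8, 0)),
               tolerance = 1e-12)
  expect_error(internal_metrics(fixture_Z, rep(1, 4)), "at least 2")
})

test_that("internal metrics match the sklearn reference on random data", {
  set.seed(10)
  for (rep in 1:5) {
    n <- 30; d <- sample(c(2, 6), 1); k <- sample(2:4, 1)
    Z <- matrix(rnorm(n * d), n)
    labels <- sample(k, n, replace = TRUE)
    if (length(unique(labels)) < k) next
    ref <- sklearn_metrics(Z, labels)
    m <- internal_metrics(Z, labels)
    expect_equal(m$silhouette, ref$silhouette, tolerance = 1e-9)
    expect_equal(m$davies_bouldin, ref$davies_bouldin, tolerance = 1e-9)
    expect_equal(m$calinski_harabasz, ref$calinski_harabasz, tolerance = 1e-9)
  }
})

test_that("silhouette agrees with cluster::silhouette", {
  set.seed(20)
  Z <- matrix(rnorm(40), 20, 2)
  labels <- rep(1:2, each = 10)
  sil <- cluster::silhouette(labels, stats::dist(Z))
  expect_equal(internal_metrics(Z, labels)$silhouette,
               mean(sil[, "sil_width"]), tolerance = 1e-12)
})

test_that("metrics are invariant to rigid motions; scale behaves as stated", {
  set.seed(30)
  Z <- matrix(rnorm(60), 20, 3)
  labels <- rep(1:2, 10)
  m0 <- internal_metrics(Z, labels)
  # translation
  mt <- internal_metrics(sweep(Z, 2, c(5, -3, 100), "+"), labels)
  # rotation
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  mr <- internal_metrics(Z %*% Q, labels)
  # global scaling
  ms <- internal_metrics(Z * 7, labels)
  for (f in c("silhouette", "davies_bouldin", "calinski_harabasz")) {
    expect_equal(mt[[f]], m0[[f]], tolerance = 1e-9)
    expect_equal(mr[[f]], m0[[f]], tolerance = 1e-9)
    expect_equal(ms[[f]], m0[[f]], tolerance = 1e-9)
  }
  expect_gte(m0$silhouette, -1); expect_lte(m0$silhouette, 1)
  expect_gte(m0$davies_bouldin, 0)
})

test_that("cosine matrix is symmetric with unit diagonal and cluster blocks", {
  set.seed(2)
  Z <- diag(4)
  rownames(Z) <- letters[1:4]
  M <- cosine_matrix(Z)
  expect_equal(M, diag(4), ignore_attr = TRUE)
  Zr <- matrix(rnorm(50), 10, 5)
  Mr <- cosine_matrix(Zr)
  expect_equal(Mr, t(Mr))
  expect_equal(diag(Mr), rep(1, 10))
  expect_error(cosine_matrix(rbind(c(0, 0), c(1, 1))), "zero row")
  # unit-circle fixture: within-pair cos 5deg, between-pair ~ cos 90deg
  ang <- c(0, 5, 90, 95) * pi / 180
  Zc <- cbind(cos(ang), sin(ang))
  rownames(Zc) <- c("a1", "a2", "b1", "b2")
  Mc <- cosine_matrix(Zc, labels = c(0, 0, 1, 1))
  expect_equal(Mc["a1", "a2"], cos(5 * pi / 180), tolerance = 1e-12)
  expect_equal(Mc["a1", "b1"], cos(90 * pi / 180), tolerance = 1e-12)
  within <- mean(c(Mc["a1", "a2"], Mc["b1", "b2"]))
  between <- mean(Mc[c("a1", "a2"), c("b1", "b2")])
  expect_gt(within, between)
  summ <- cosine_cluster_summary(Zc, c(0, 0, 1, 1))
  expect_equal(unname(summ$within["cluster0"]), cos(5 * pi / 180),
               tolerance = 1e-12)
})

test_that("prototypes maximize mean within-cluster cosine with alphabetical ties", {
  u <- c(1, 0); v <- c(sqrt(0.5), sqrt(0.5))
  Z <- rbind(u, u, v, c(0, 1))
  rownames(Z) <- c("beta", "alpha", "uva", "solo")
  pro <- cluster_prototypes(Z, c(1, 1, 1, 2))
  expect_equal(unname(pro["cluster0"]), "alpha")  # tie between the two u-members
  expect_equal(unname(pro["cluster1"]), "solo")   # singleton is its own prototype
  # a u-member beats the v outlier
  sims_u <- mean(c(1, sum(u * v)))
  sims_v <- mean(c(sum(u * v), sum(u * v)))
  expect_gt(sims_u, sims_v)
})

test_that("nearest neighbors agree with a brute-force all-pairs scan", {
  set.seed(40)
  Z <- matrix(rnorm(8 * 6), 8)
  rownames(Z) <- paste0("c", 1:8)
  nn <- nearest_neighbors(Z, m = 3)
  M <- cosine_matrix(Z)
  for (i in 1:8) {
    sims <- M[i, -i]
    expect_equal(sort(nn$score[nn$cohort == rownames(Z)[i]], decreasing = TRUE),
                 sort(sims, decreasing = TRUE)[1:3], ignore_attr = TRUE,
                 tolerance = 1e-12)
  }
  # scores descending, no self neighbors
  expect_true(all(tapply(nn$score, nn$cohort, function(s) all(diff(s) <= 0))))
  expect_true(all(nn$cohort != nn$neighbor))
  # a duplicated row is its twin's rank-1 neighbor with score 1
  Z2 <- rbind(Z, Z[1, , drop = FALSE]); rownames(Z2)[9] <- "dup"
  nn2 <- nearest_neighbors(Z2, m = 3)
  expect_equal(nn2$neighbor[nn2$cohort == "dup" & nn2$rank == 1], "c1")
  expect_equal(nn2$score[nn2$cohort == "dup" & nn2$rank == 1], 1)
  expect_error(nearest_neighbors(Z[1:3, ], m = 3), "more than")
})

test_that("cluster spectra average cohort totals with equal weight", {
  r1 <- toy_records(cohort = "c1", gene = rep("G1", 4), ref = rep("C", 4),
                    alt = rep("T", 4), chromosome = rep("1", 4))
  r2 <- toy_records(cohort = "c2", gene = rep("G1", 2), ref = rep("C", 2),
                    alt = rep("T", 2), chromosome = rep("1", 2))
  gs <- list(build_gene_signature(r1), build_gene_signature(r2))
  cs <- list(build_chromosome_signature(r1), build_chromosome_signature(r2))
  labels <- c(c1 = 1, c2 = 1)
  sp <- cluster_spectra(gs, cs, labels)
  expect_equal(unname(sp$substitution["cluster0", "C>T"]), 3)  # mean of 4 and 2
  expect_equal(unname(sp$chromosome_load["cluster0", "1"]),
               mean(c(4, 2) / grch38_chrom_lengths()[["1"]]))
  # single-cohort clusters equal the cohort's own totals
  sp2 <- cluster_spectra(gs, cs, c(c1 = 1, c2 = 2))
  expect_equal(unname(sp2$substitution["cluster0", "C>T"]), 4)
  expect_error(cluster_spectra(gs, cs, c(c1 = 1)), "missing")
})

test_that("gene-set overlap computes Venn counts", {
  mk <- function(cohort, genes) {
    recs <- toy_records(cohort = cohort, gene = rep(genes, each = 2),
                        ref = "C", alt = "T", chromosome = "1")
    build_gene_signature(recs)
  }
  gs <- list(mk("c1", c("A", "B", "C")), mk("c2", c("B", "C", "D")))
  ov <- gene_set_overlap(gs, c(c1 = 1, c2 = 2))
  expect_equal(ov$counts[["shared"]], 2)
  expect_equal(ov$counts[["unique_cluster0"]], 1)
  expect_equal(ov$counts[["unique_cluster1"]], 1)
  # identical sets
  ov2 <- gene_set_overlap(list(mk("c1", c("A", "B")), mk("c2", c("A", "B"))),
                          c(c1 = 1, c2 = 2))
  expect_equal(unname(ov2$counts), c(2, 0, 0))
  # disjoint sets
  ov3 <- gene_set_overlap(list(mk("c1", c("A", "B")), mk("c2", c("X", "Y"))),
                          c(c1 = 1, c2 = 2))
  expect_equal(ov3$counts[["shared"]], 0)
})

test_that("2-D projections have the right shape and are seed-deterministic", {
  set.seed(50)
  Z <- rbind(matrix(rnorm(24, 0), 12), matrix(rnorm(24, 6), 12))
  rownames(Z) <- paste0("c", 1:24)
  for (method in c("pca", "tsne", "umap")) {
    P1 <- project_2d(Z, method = method, seed = 9)
    expect_equal(dim(P1), c(24, 2))
    expect_true(all(is.finite(P1)))
    P2 <- project_2d(Z, method = method, seed = 9)
    expect_equal(P1, P2)
  }
  expect_error(project_2d(Z[1:3, ], method = "pca"), "at least 4")
  # separable data stays separable after PCA projection
  labels <- rep(1:2, each = 12)
  m0 <- internal_metrics(Z, labels)
  mp <- internal_metrics(project_2d(Z, "pca", seed = 1), labels,
                         space_tag = "projected_2d")
  expect_equal(mp$space_tag, "projected_2d")
  expect_gte(mp$silhouette, m0$silhouette - 0.05)
})
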