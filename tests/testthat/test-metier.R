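test_that("Bray-Curtis matches its definition, a worked pair and vegan", {
  expect_equal(bray_curtis(c(A = 6, B = 2), c(A = 2, B = 6)), 0.5)
  expect_equal(bray_curtis(c(A = 3, B = 1), c(A = 3, B = 1)), 0)
  expect_equal(bray_curtis(c(A = 5, B = 0), c(A = 0, B = 7)), 1)
  expect_error(bray_curtis(c(A = 0), c(A = 0)), "all-zero")
  set.seed(7)
  x <- matrix(rgamma(40, 2), 10, 4, dimnames = list(NULL, LETTERS[1:4]))
  expect_equal(cross_dissim(x, x, "bray_curtis"),
               as.matrix(vegan::vegdist(x, "bray")), ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("Bray-Curtis algebra holds on random profile pairs", {
  set.seed(8)
  for (i in 1:200) {
    x <- rgamma(6, 1); y <- rgamma(6, 1)
    d <- bray_curtis(x, y)
    expect_gte(d, 0); expect_lte(d, 1)
    expect_equal(d, bray_curtis(y, x))
    lambda <- runif(1, 0.1, 50)
    expect_equal(bray_curtis(lambda * x, lambda * y), d, tolerance = 1e-12)
  }
  expect_equal(bray_curtis(rep(1, 4), rep(1, 4)), 0)
})

test_that("k = 1 medoid minimises the summed dissimilarity exhaustively", {
  set.seed(12)
  for (meth in c("bray_curtis", "euclidean", "manhattan")) {
    x <- matrix(rgamma(8 * 3, 2), 8, 3)
    d <- cross_dissim(x, x, meth)
    fit <- pam_medoids(x, 1, meth)
    expect_equal(fit$cost, min(colSums(d)))
    expect_equal(fit$medoids, which.min(colSums(d)))
  }
})

test_that("PAM separates two well-apart blobs and is invariant to duplication", {
  set.seed(14)
  blob1 <- matrix(rnorm(12, 0, 0.1), 6, 2)
  blob2 <- matrix(rnorm(12, 10, 0.1), 6, 2)
  x <- abs(rbind(blob1, blob2)) + 0.01
  fit <- pam_medoids(x, 2, "euclidean")
  expect_setequal(fit$assignment[1:6], 1)
  expect_setequal(fit$assignment[7:12], 2)
  d <- cross_dissim(x, x, "euclidean")
  expect_equal(fit$cost, exhaustive_kmedoids_cost(d, 2))
  # duplicated dataset: same medoid profiles (cost scales by 2)
  x2 <- rbind(x, x)
  fit2 <- pam_medoids(x2, 2, "euclidean")
  expect_equal(sort(x2[fit2$medoids, 1]) , sort(x[fit$medoids, 1]))
  expect_equal(fit2$cost, 2 * fit$cost)
  expect_error(pam_medoids(x, 12, "euclidean"), "smaller")
})

test_that("SWAP never increases cost and stops at a swap-local optimum", {
  set.seed(15)
  for (r in 1:20) {
    n <- sample(6:10, 1); k <- sample(2:3, 1)
    x <- matrix(rgamma(n * 3, 2), n, 3)
    d <- cross_dissim(x, x, "bray_curtis")
    fit <- pam_medoids(x, k, dmat = d)
    # local optimality: no single swap lowers the cost
    for (m in fit$medoids) for (h in setdiff(seq_len(n), fit$medoids)) {
      alt <- c(setdiff(fit$medoids, m), h)
      altcost <- sum(apply(d[, alt, drop = FALSE], 1, min))
      expect_gte(altcost, fit$cost - 1e-12)
    }
  }
})

test_that("PAM matches the exhaustive optimum on most tiny instances and never
           trails the reference implementation", {
  set.seed(16)
  eq <- 0; n_inst <- 60
  for (r in seq_len(n_inst)) {
    n <- sample(5:10, 1); k <- sample(1:3, 1)
    meth <- c("bray_curtis", "euclidean", "manhattan")[(r %% 3) + 1]
    x <- matrix(rgamma(n * 3, 2), n, 3)
    d <- cross_dissim(x, x, meth)
    fit <- pam_medoids(x, k, dmat = d)
    ref <- cluster::pam(stats::as.dist(d), k)
    refcost <- sum(apply(d[, ref$id.med, drop = FALSE], 1, min))
    expect_lte(fit$cost, refcost + 1e-9)
    if (abs(fit$cost - exhaustive_kmedoids_cost(d, k)) < 1e-9) eq <- eq + 1
  }
  expect_gte(eq / n_inst, 0.9)
})

test_that("CLARA degenerates to PAM on small data and is seed-deterministic", {
  set.seed(17)
  x <- rdirichlet_profiles(40, c(4, 1, 1))
  colnames(x) <- c("HKE", "MUT", "DPS")
  fit_p <- pam_medoids(x, 2, "bray_curtis")
  fit_c <- clara_medoids(x, 2, n_samples = 5, sample_size = 100,
                         method = "bray_curtis", seed = 1)
  expect_equal(fit_c$medoids, fit_p$medoids)
  expect_equal(fit_c$cost, fit_p$cost)
  f1 <- clara_medoids(x, 2, n_samples = 4, sample_size = 20, seed = 99)
  f2 <- clara_medoids(x, 2, n_samples = 4, sample_size = 20, seed = 99)
  expect_identical(f1, f2)
})

test_that("CLARA on subsamples stays close to direct PAM on planted profiles", {
  set.seed(18)
  alphas <- list(c(20, 2, 1, 0.1, 0.1), c(0.1, 1, 20, 3, 0.1),
                 c(0.1, 0.1, 1, 3, 20))
  x <- do.call(rbind, lapply(alphas, function(a) rdirichlet_profiles(400, a)))
  colnames(x) <- c("HKE", "MUT", "DPS", "PIL", "ANE")
  cl <- clara_medoids(x, 3, n_samples = 5, sample_size = 150,
                      method = "bray_curtis", seed = 5)
  sub <- sample(nrow(x), 300)
  direct <- pam_medoids(x[sub, ], 3, "bray_curtis")
  dmed <- cross_dissim(x, x[sub[direct$medoids], , drop = FALSE], "bray_curtis")
  direct_avg <- mean(apply(dmed, 1, min))
  expect_lt(abs(cl$avg_dissim - direct_avg) / direct_avg, 0.05)
})

test_that("silhouette matches cluster::silhouette and handles degeneracy", {
  set.seed(19)
  x <- matrix(rgamma(90, 2), 30, 3)
  lab <- sample(1:3, 30, replace = TRUE)
  for (meth in c("euclidean", "manhattan")) {
    ours <- asw(x, lab, meth, block = 7)  # exercise the blockwise sweep
    d <- cross_dissim(x, x, meth)
    ref <- mean(cluster::silhouette(lab, stats::as.dist(d))[, 3])
    expect_equal(ours, ref, tolerance = 1e-8)
  }
  # two tight distant blobs -> ASW near 1; random labels -> near 0
  blobs <- rbind(matrix(rnorm(20, 0, 0.05), 10, 2),
                 matrix(rnorm(20, 20, 0.05), 10, 2))
  expect_gt(asw(blobs, rep(1:2, each = 10), "euclidean"), 0.9)
  one_blob <- matrix(rnorm(200, 5, 1), 100, 2)
  expect_lt(abs(asw(one_blob, sample(1:2, 100, TRUE), "euclidean")), 0.1)
  # all-identical points split arbitrarily: a = b = 0 -> s = 0
  same <- matrix(1, 10, 2)
  expect_equal(asw(same, rep(1:2, 5), "euclidean"), 0)
  expect_error(asw(x, rep(1, 30)), "2 clusters")
})

test_that("discovery recovers the planted number of metiers and compositions", {
  set.seed(20)
  alphas <- list(OTB = c(HKE = 20, MUT = 8, DPS = 4, PIL = 0.1, ANE = 0.1),
                 PS = c(HKE = 0.1, MUT = 0.1, DPS = 0.2, PIL = 20, ANE = 8),
                 MIX = c(HKE = 4, MUT = 0.1, DPS = 16, PIL = 0.1, ANE = 6))
  truth <- rep(names(alphas), each = 300)
  x <- do.call(rbind, lapply(alphas, function(a) {
    p <- rdirichlet_profiles(300, a); colnames(p) <- names(a); p
  }))
  mod <- discover_metiers(x, k_range = 2:5, n_samples = 4, sample_size = 250,
                          seed = 3)
  prof <- attr(mod, "silhouette_profile")
  expect_equal(prof$k[which.max(prof$asw)], 3L)
  expect_equal(mod$k, 3L)
  hard <- classify_metier(x, mod)$label
  expect_gt(mclust::adjustedRandIndex(hard, truth), 0.9)
  # medoid compositions sit near the planted Dirichlet means
  ref <- t(vapply(alphas, function(a) a / sum(a), numeric(5)))
  colnames(ref) <- colnames(x)
  d <- cross_dissim(mod$medoids / rowSums(mod$medoids), ref, "bray_curtis")
  expect_lt(max(apply(d, 1, min)), 0.1)
})

test_that("discovery honours a single-k range and degenerate duplicates", {
  x <- rdirichlet_profiles(30, c(5, 1)); colnames(x) <- c("HKE", "MUT")
  mod <- discover_metiers(x, k_range = 2, n_samples = 3, sample_size = 50)
  expect_equal(mod$k, 2L)
  expect_equal(nrow(attr(mod, "silhouette_profile")), 1L)
  dup <- matrix(rep(c(3, 1), each = 12), 12, 2,
                dimnames = list(NULL, c("HKE", "MUT")))
  expect_no_error(discover_metiers(dup, k_range = 2, n_samples = 2,
                                   sample_size = 20))
  expect_error(discover_metiers(x, k_range = integer(0)), "empty")
})

test_that("fuzzy memberships sum to one, zero distance wins, ties split evenly", {
  med <- rbind(c(HKE = 10, MUT = 0), c(HKE = 0, MUT = 10))
  mod <- metier_model(med, labels = c("A", "B"), m = 2)
  rec <- rbind(c(HKE = 10, MUT = 0),   # equal to medoid 1
               c(HKE = 5, MUT = 5),    # equidistant
               c(HKE = 0, MUT = 0))    # unclassifiable
  cls <- classify_metier(rec, mod)
  expect_equal(cls$u_A[1], 1); expect_equal(cls$label[1], "A")
  expect_equal(cls$u_A[2], 0.5); expect_equal(cls$u_B[2], 0.5)
  expect_equal(cls$label[2], "A")      # tie to the lower index
  expect_true(is.na(cls$label[3]))
  set.seed(23)
  x <- rdirichlet_profiles(100, c(2, 2)); colnames(x) <- c("HKE", "MUT")
  u <- as.matrix(classify_metier(x, mod)[, c("u_A", "u_B")])
  expect_equal(rowSums(u), rep(1, 100))
  # permutation equivariance in cluster order
  mod_swap <- metier_model(med[2:1, ], labels = c("B", "A"), m = 2)
  u2 <- as.matrix(classify_metier(x, mod_swap)[, c("u_B", "u_A")])
  expect_equal(u[, "u_A"], u2[, "u_A"], tolerance = 1e-12)
})

test_that("memberships approach the crisp nearest-medoid rule as m -> 1+", {
  set.seed(24)
  med <- rdirichlet_profiles(4, c(3, 1, 1, 2)); colnames(med) <- LETTERS[1:4]
  x <- rdirichlet_profiles(300, c(1, 1, 1, 1)); colnames(x) <- LETTERS[1:4]
  d <- cross_dissim(x, med, "bray_curtis")
  nearest <- max.col(-d, ties.method = "first")
  mod <- metier_model(med, m = 1.001)
  hard <- classify_metier(x, mod)$label
  expect_equal(hard, mod$labels[nearest])
})

test_that("new species align as zero columns between records and model", {
  med <- rbind(c(HKE = 10, MUT = 2)); mod <- metier_model(med, labels = "A")
  rec <- rbind(c(HKE = 10, MUT = 2, NEP = 0), c(NEP = 4, HKE = 8, MUT = 2))
  cls <- classify_metier(rec, mod)
  expect_equal(cls$u_A, c(1, 1))
  expect_lt(bray_curtis(c(10, 2, 0), c(8, 2, 4)), 1)  # sanity on the padding
})

test_that("metier models round-trip through their text format", {
  med <- rbind(c(HKE = 10.5, MUT = 2.25), c(HKE = 1, MUT = 9))
  mod <- metier_model(med, labels = c("OTB_DES_>=40_0_0", "PS_SPF_>=14_0_0"),
                      method = "bray_curtis", m = 2)
  f <- withr::local_tempfile()
  write_metier_model(mod, f)
  mod2 <- read_metier_model(f)
  expect_equal(mod2$medoids, mod$medoids)
  expect_equal(mod2$labels, mod$labels)
  expect_equal(mod2$method, mod$method)
  expect_equal(mod2$m, mod$m)
})

test_that("label assignment maps medoids onto nearest reference profiles", {
  ref <- rbind(OTB = c(HKE = 0.7, PIL = 0), PS = c(HKE = 0, PIL = 0.8))
  med <- rbind(c(HKE = 1, PIL = 20), c(HKE = 15, PIL = 0.5))
  mod <- label_metiers(metier_model(med), ref)
  expect_equal(mod$labels, c("PS", "OTB"))
})
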